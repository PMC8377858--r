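# End-to-end orchestration: initiate (windows), expand (designs), rank
# (predicted efficiency), report (tables + skip file).

#' Deterministic design ranking
#'
#' Sorts designs by predicted efficiency descending. Ties are broken by
#' shorter template (rtt_len), then PBS length closest to 13 nt, then
#' ngRNA nick distance closest to +60 (PE2 designs, which have no ngRNA,
#' use the sentinel distance 0 here), then lexicographic extension
#' sequence — a fixed, platform-independent order.
#'
#' @param designs data.frame with design columns and a
#'   `predicted_efficiency` column.
#' @return the data.frame sorted, with a contiguous `rank` column.
#' @export
rank_designs <- function(designs) {
  stopifnot(all(is.finite(designs$predicted_efficiency)))
  ng <- ifelse(is.na(designs$ngrna_pos), 0L, designs$ngrna_pos)
  ord <- order(-designs$predicted_efficiency, designs$rtt_len,
               abs(designs$pbs_len - 13L), abs(ng - 60L),
               designs$ext_seq, designs$ngrna_seq, method = "radix")
  out <- designs[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Design and rank pegRNAs for a set of variants
#'
#' The full pipeline for each variant: extract the design window,
#' enumerate all spacer x extension x (ngRNA or none) combinations,
#' assemble the 23 features, score designs with the PE3 model (designs
#' with an ngRNA) or the PE2 model (no ngRNA), and rank. Variants for
#' which no design exists are reported with a reason instead of rows.
#'
#' @param variants list of [genomic_variant()] (or a single one).
#' @param reference named contig sequences or FASTA path.
#' @param model_pe2,model_pe3 `efficiency_model` objects; their schemas
#'   must match the package's feature schema.
#' @param config a [peg_config()].
#' @param scorer Cas9 activity scorer.
#' @param fold_engine folding engine for [compute_bpp()].
#' @param top_n designs reported per variant (`Inf` for all); default
#'   from `config`.
#' @return list with `table` (ranked design data.frame across variants),
#'   `full` (all scored designs) and `skipped` (data.frame variant_id,
#'   reason).
#' @export
run_design <- function(variants, reference, model_pe2, model_pe3,
                       config = peg_config(), scorer = scorer_surrogate(),
                       fold_engine = "simple", top_n = NULL) {
  if (inherits(variants, "genomic_variant")) variants <- list(variants)
  stopifnot(inherits(model_pe2, "efficiency_model"),
            inherits(model_pe3, "efficiency_model"))
  if (model_pe2$model_type != "pe2" || model_pe3$model_type != "pe3")
    stop("run_design: model_pe2/model_pe3 have the wrong model_type")
  for (m in list(model_pe2, model_pe3))
    if (!identical(m$schema_id, schema_id(feature_schema(m$model_type))))
      stop("run_design: model schema does not match this package's features")
  if (is.null(top_n)) top_n <- config$top_n
  tables <- list(); full <- list(); skipped <- list()
  for (v in variants) {
    res <- tryCatch(
      design_one(v, reference, model_pe2, model_pe3, config, scorer,
                 fold_engine),
      error = function(e) structure(list(reason = conditionMessage(e)),
                                    class = "design_skip"))
    if (inherits(res, "design_skip") || nrow(res) == 0L) {
      reason <- if (inherits(res, "design_skip")) res$reason
                else attr(res, "skip_reason") %||% "no design found"
      skipped[[length(skipped) + 1L]] <-
        data.frame(variant_id = v$id, reason = reason, stringsAsFactors = FALSE)
      next
    }
    full[[length(full) + 1L]] <- res
    tables[[length(tables) + 1L]] <- head(res, min(top_n, nrow(res)))
  }
  bind <- function(x, skeleton) if (length(x)) do.call(rbind, x) else skeleton
  list(table = bind(tables, ranked_skeleton()),
       full = bind(full, ranked_skeleton()),
       skipped = bind(skipped, data.frame(variant_id = character(),
                                          reason = character(),
                                          stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

design_one <- function(variant, reference, model_pe2, model_pe3, config,
                       scorer, fold_engine) {
  window <- extract_window(variant, reference, config$flank)
  designs <- assemble_designs(window, config)
  if (nrow(designs) == 0L) return(designs)
  feats <- assemble_features(designs, window, scorer = scorer,
                             fold_engine = fold_engine,
                             scaffold = config$scaffold)
  is_pe3 <- designs$ngrna_seq != "."
  pred <- numeric(nrow(designs))
  if (any(is_pe3))
    pred[is_pe3] <- predict(model_pe3, feats[is_pe3, , drop = FALSE])
  if (any(!is_pe3))
    pred[!is_pe3] <- predict(model_pe2, feats[!is_pe3, , drop = FALSE])
  designs$predicted_efficiency <- pred
  designs$cas9_score <- feats$cas9_score
  rank_designs(designs)
}

ranked_skeleton <- function() {
  sk <- design_table_skeleton()
  sk$predicted_efficiency <- numeric(0)
  sk$cas9_score <- numeric(0)
  sk$rank <- integer(0)
  sk
}

#' Write a ranked design table as tab-delimited text
#' @param table design data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_design_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a design table written by [write_design_table()]
#' @param path file.
#' @return data.frame.
#' @export
read_design_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(variant_id = "character", strand = "character",
                            ngrna_seq = "character"))
}

#' Batch design over many variants
#'
#' Streams [run_design()] over a variant file (VCF or the FASTA dialect)
#' or an in-memory variant list, continuing past per-variant failures,
#' and returns aggregate counts alongside the tables: variants designed
#' and skipped, designs emitted, PAM-disrupting designs, and designs at
#' or above an efficiency threshold.
#'
#' @param variants variant file path or list of [genomic_variant()].
#' @param reference named contig sequences or FASTA path (optional when a
#'   FASTA-dialect file carries its own windows).
#' @param efficiency_threshold percent; designs predicted at or above it
#'   are counted as high-efficiency (default 40).
#' @inheritParams run_design
#' @return list with `summary` (named counts), `table`, `full`,
#'   `skipped`.
#' @export
batch_design <- function(variants, reference = NULL, model_pe2, model_pe3,
                         config = peg_config(), scorer = scorer_surrogate(),
                         fold_engine = "simple", top_n = NULL,
                         efficiency_threshold = 40) {
  if (is.character(variants) && length(variants) == 1L) {
    vs <- read_variants(variants, reference)
    if (is.null(reference)) reference <- attr(vs, "reference")
    variants <- vs
  }
  if (length(variants) == 0L) {
    res <- list(table = ranked_skeleton(), full = ranked_skeleton(),
                skipped = data.frame(variant_id = character(),
                                     reason = character()))
  } else {
    res <- run_design(variants, reference, model_pe2, model_pe3, config,
                      scorer, fold_engine, top_n)
  }
  res$summary <- c(
    n_variants = length(variants),
    n_designed = length(unique(res$table$variant_id)),
    n_skipped = nrow(res$skipped),
    n_designs = nrow(res$full),
    n_pam_disrupting = sum(res$full$is_dPAM == 1L),
    n_above_threshold = sum(res$full$predicted_efficiency >=
                              efficiency_threshold))
  res
}
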