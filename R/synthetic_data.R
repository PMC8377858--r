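# Synthetic fixtures and simulations: engineered toy loci exercising
# every enumeration corner case, and training tables whose efficiency is
# a documented function of the extracted features — so the whole stack is
# testable without any external dataset.

#' Simulation configuration
#'
#' @param seed master seed for all randomness.
#' @param n_rows target number of training rows.
#' @param flank half-width of the simulated design windows (nt).
#' @param edit_mix named proportions of SNV / insertion / deletion edits
#'   (must sum to 1).
#' @param effects named per-feature effect sizes on *standardized*
#'   features (percent efficiency per SD); defaults follow the package's
#'   documented simulation: strong Cas9-activity, first-position folding,
#'   PBS-GC, PAM-disruption, nick-distance and downstream-homology
#'   effects, weak edit-operation effects.
#' @param mu baseline efficiency (percent).
#' @param sigma Gaussian noise SD (percent), >= 0.
#' @param designs_per_variant designs sampled per simulated variant.
#' @param pbs_range,rtt_range,ngrna_window enumeration ranges used for
#'   the simulated designs (narrower than the design defaults to keep
#'   simulation compact).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_rows = 2000L, flank = 60L,
                       edit_mix = c(snv = 0.6, ins = 0.2, del = 0.2),
                       effects = c(cas9_score = 12, fold_d1 = -10, pbs_gc = 6,
                                   is_dPAM = 5, target_pos = -6,
                                   target_end_flank = 3, n_sub = -0.5,
                                   n_ins = -0.5, n_del = -0.5),
                       mu = 40, sigma = 5, designs_per_variant = 20L,
                       pbs_range = 9:13, rtt_range = 10:16,
                       ngrna_window = 60L) {
  stopifnot(abs(sum(edit_mix) - 1) < 1e-9, sigma >= 0,
            all(names(effects) %in% feature_schema("full")))
  structure(list(seed = as.integer(seed), n_rows = as.integer(n_rows),
                 flank = as.integer(flank), edit_mix = edit_mix,
                 effects = effects, mu = mu, sigma = sigma,
                 designs_per_variant = as.integer(designs_per_variant),
                 pbs_range = pbs_range, rtt_range = rtt_range,
                 ngrna_window = as.integer(ngrna_window)),
            class = "sim_config")
}

rand_dna <- function(n, bases = DNA_BASES) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Background of A/T only: guarantees no NGG/CCN motif other than the
# engineered ones.
at_background <- function(n) strsplit(rand_dna(n, c("A", "T")), "")[[1]]

#' Deterministic toy locus with engineered PAM placements
#'
#' Builds a small reference (seven 160-nt contigs) plus matched variants
#' covering the enumeration corner cases: a single reachable spacer
#' (PE2-only), multiple spacers with an opposite-strand nicking site, no
#' spacer at all, an engineered PE3b site (the ngRNA protospacer covers
#' the edit), a PAM-disrupting SNV, and anchored insertion and deletion
#' edits. Contig backgrounds are A/T-only so the engineered NGG/CCN
#' motifs are the only ones present. Identical output for identical
#' seeds.
#'
#' @param seed integer seed.
#' @param dir if non-NULL, the reference FASTA (`toy_ref.fa`) and variant
#'   VCF (`toy_variants.vcf`) are written there.
#' @return list with `reference` (named contig sequences), `variants`
#'   (list of [genomic_variant()]) and, when written, `fasta`/`vcf`
#'   paths.
#' @export
make_toy_locus <- function(seed = 1L, dir = NULL) {
  set.seed(derive_seed(seed, 42L))
  L <- 160L
  contig <- function(motifs) {
    ch <- at_background(L)
    for (m in motifs) for (k in seq_along(m$bases))
      ch[m$at + k] <- m$bases[k]  # m$at is 0-based
    paste(ch, collapse = "")
  }
  # engineered motifs (0-based `at`): GG of a + strand PAM whose
  # protospacer starts at p; CC of a - strand PAM whose protospacer
  # starts at a (+ strand coordinates)
  GG <- function(p) list(at = p + 21L, bases = c("G", "G"))
  CC <- function(a) list(at = a - 3L, bases = c("C", "C"))
  ref <- c(
    single_spacer = contig(list(GG(55L))),
    multi         = contig(list(GG(55L), GG(60L), CC(103L))),
    no_spacer     = contig(list()),
    pe3b          = contig(list(GG(55L), CC(63L))),
    pam_disrupt   = contig(list(GG(58L))),
    ins_site      = contig(list(GG(55L))),
    del_site      = contig(list(GG(55L))))
  base_at <- function(chrom, pos0) substr(ref[[chrom]], pos0 + 1L, pos0 + 1L)
  other <- function(b, choices = c("C", "G")) choices[choices != b][1]
  variants <- list(
    genomic_variant("v_single", "single_spacer", 80L,
                    base_at("single_spacer", 79L), "C"),
    genomic_variant("v_multi", "multi", 85L, base_at("multi", 84L), "C"),
    genomic_variant("v_none", "no_spacer", 81L, base_at("no_spacer", 80L),
                    other(base_at("no_spacer", 80L), c("T", "A"))),
    genomic_variant("v_pe3b", "pe3b", 80L, base_at("pe3b", 79L), "G"),
    genomic_variant("v_dpam", "pam_disrupt", 80L, "G", "A"),
    genomic_variant("v_ins", "ins_site", 80L, base_at("ins_site", 79L),
                    paste0(base_at("ins_site", 79L), "TT")),
    genomic_variant("v_del", "del_site", 80L,
                    substr(ref[["del_site"]], 80L, 84L),
                    base_at("del_site", 79L)))
  out <- list(reference = ref, variants = variants)
  # internal sanity: the engineered geometry must hold
  w <- extract_window(variants[[3]], ref, 60L)
  if (nrow(find_spacers(w)) != 0L)
    stop("make_toy_locus: no_spacer contig unexpectedly has a spacer")
  w <- extract_window(variants[[1]], ref, 60L)
  if (nrow(find_spacers(w)) < 1L)
    stop("make_toy_locus: single_spacer contig has no spacer")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fasta <- file.path(dir, "toy_ref.fa")
    ss <- Biostrings::DNAStringSet(ref)
    Biostrings::writeXStringSet(ss, fasta)
    vcf <- file.path(dir, "toy_variants.vcf")
    write_variants(variants, vcf, format = "vcf")
    out$fasta <- fasta
    out$vcf <- vcf
  }
  out
}

#' Simulate a training table with known feature effects
#'
#' Generates random design windows (balanced ACGT background, so PAM
#' sites are plentiful), places an SNV/insertion/deletion edit at the
#' centre per `edit_mix`, enumerates real designs, samples up to
#' `designs_per_variant` of them, assembles their true 23-feature
#' vectors, and simulates efficiency as
#' `clip(mu + sum_f effect_f * z(feature_f) + N(0, sigma), 0, 100)`
#' where `z` is the per-column standardization over the generated table.
#' `group_id` is the variant identity (contig + position + target
#' allele), so grouped CV splits are meaningful. The injected effects are
#' recoverable by the efficiency model, which is what the model-protocol
#' tests exercise; the generator emulates design-feature geometry, not
#' the biochemical error structure of real amplicon sequencing data.
#'
#' @param config a [sim_config()].
#' @param scorer,fold_engine feature-extraction backends.
#' @return data.frame `group_id`, the 23 features, `efficiency`, with the
#'   generating truth (`effects`, `mu`, `sigma`) in `attr(, "truth")`.
#' @export
simulate_training_table <- function(config = sim_config(),
                                    scorer = scorer_surrogate(),
                                    fold_engine = "simple") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 9L))
  enum_cfg <- peg_config(pbs_min = min(config$pbs_range),
                         pbs_max = max(config$pbs_range),
                         rtt_min = min(config$rtt_range),
                         rtt_max = max(config$rtt_range),
                         ngrna_window = config$ngrna_window,
                         flank = max(30L, config$flank))
  rows <- list(); total <- 0L; vi <- 0L
  while (total < config$n_rows && vi < 20L * ceiling(config$n_rows /
                                                     config$designs_per_variant)) {
    vi <- vi + 1L
    L <- 2L * config$flank + 6L
    seq <- rand_dna(L)
    e <- config$flank
    kind <- sample(names(config$edit_mix), 1L, prob = config$edit_mix)
    refb <- substr(seq, e + 1L, e + 1L)
    edit <- switch(kind,
      snv = list(ref = refb, alt = sample(setdiff(DNA_BASES, refb), 1L)),
      ins = list(ref = refb, alt = paste0(refb, rand_dna(sample(1:3, 1L)))),
      del = {
        dl <- sample(1:3, 1L)
        list(ref = substr(seq, e + 1L, e + 1L + dl), alt = refb)
      })
    if (edit$ref == edit$alt) next
    win <- tryCatch(target_window(seq, e, edit$ref, edit$alt,
                                  id = sprintf("sim%04d", vi)),
                    error = function(cond) NULL)
    if (is.null(win)) next
    designs <- assemble_designs(win, enum_cfg)
    if (nrow(designs) == 0L) next
    keep <- if (nrow(designs) > config$designs_per_variant)
      sort(sample.int(nrow(designs), config$designs_per_variant))
    else seq_len(nrow(designs))
    designs <- designs[keep, , drop = FALSE]
    feats <- assemble_features(designs, win, scorer = scorer,
                               fold_engine = fold_engine)
    feats$group_id <- sprintf("%s:%d:%s", win$variant$chrom, win$variant$pos,
                              win$variant$alt)
    rows[[length(rows) + 1L]] <- feats
    total <- total + nrow(feats)
  }
  tab <- do.call(rbind, rows)
  if (nrow(tab) > config$n_rows) tab <- tab[seq_len(config$n_rows), ]
  feat <- as.matrix(tab[, feature_schema("full")])
  zs <- scale(feat)
  const <- attr(zs, "scaled:scale") == 0 | !is.finite(attr(zs, "scaled:scale"))
  zs[, const] <- 0
  zs[!is.finite(zs)] <- 0
  eff_vec <- stats::setNames(rep(0, ncol(feat)), colnames(feat))
  eff_vec[names(config$effects)] <- config$effects
  active <- names(config$effects)[config$effects != 0]
  degen <- active[active %in% colnames(feat)[const]]
  if (length(degen) > 0)
    warning("simulate_training_table: zero variance in effect feature(s): ",
            paste(degen, collapse = ", "))
  signal <- as.numeric(zs %*% eff_vec)
  eff <- pmin(100, pmax(0, config$mu + signal +
                          rnorm(nrow(tab), 0, config$sigma)))
  out <- cbind(data.frame(group_id = tab$group_id,
                          design_id = tab$design_id,
                          stringsAsFactors = FALSE),
               as.data.frame(feat))
  out$efficiency <- eff
  attr(out, "truth") <- list(effects = config$effects, mu = config$mu,
                             sigma = config$sigma)
  rownames(out) <- NULL
  out
}

#' Write a training table as tab-delimited text
#' @param table training table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_training_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a training table written by [write_training_table()]
#' @param path file.
#' @return data.frame.
#' @export
read_training_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(group_id = "character"))
}
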