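# The 23-feature vector per design, in five categories: Cas9 activity,
# oligo (PBS/RTT length and GC), target-mutation (edit-op counts, PAM
# disruption, PE3b), position (target_pos, ngrna_pos, target_end_flank)
# and the 10 RNA-folding disruption scores.

FEATURE_NAMES <- c("cas9_score", "pbs_len", "rtt_len", "pbs_gc", "rtt_gc",
                   "is_dPAM", "is_PE3b", "n_sub", "n_ins", "n_del",
                   "target_pos", "ngrna_pos", "target_end_flank",
                   paste0("fold_d", 1:10))

PE2_EXCLUDED <- c("ngrna_pos", "is_PE3b")

#' Canonical feature schema
#'
#' The 23 model-input names in canonical order, or the subset used by one
#' model type. The PE2 model drops the two ngRNA-specific features
#' (`ngrna_pos`, `is_PE3b`); the PE3 model uses all 23.
#'
#' @param model_type `"full"`, `"pe2"` or `"pe3"`.
#' @return character vector of feature names.
#' @export
feature_schema <- function(model_type = c("full", "pe3", "pe2")) {
  model_type <- match.arg(model_type)
  if (model_type == "pe2") setdiff(FEATURE_NAMES, PE2_EXCLUDED) else FEATURE_NAMES
}

#' Schema fingerprint
#'
#' A stable string identifying a feature schema; models store it and
#' refuse prediction on a mismatch.
#' @param names character vector of feature names.
#' @return character scalar.
#' @export
schema_id <- function(names) paste(names, collapse = "|")

#' Count substitutions, insertions and deletions of an edit
#'
#' Equal-length alleles are compared position-wise (Hamming); otherwise
#' the alleles are globally aligned (match +1, mismatch -1, gap open -2,
#' gap extend -1, ties broken toward substitutions) and aligned columns
#' are counted. An anchored pure indel (one allele a prefix of the other)
#' therefore yields its length difference as pure insertion/deletion.
#'
#' @param ref,alt the two alleles (nonempty, different).
#' @return named integer vector `n_sub`, `n_ins`, `n_del`.
#' @export
edit_op_counts <- function(ref, alt) {
  stopifnot(is_dna(ref), is_dna(alt), ref != alt)
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  if (length(r) == length(a))
    return(c(n_sub = sum(r != a), n_ins = 0L, n_del = 0L))
  align_ops(r, a)
}

# Affine-gap Needleman-Wunsch on short allele strings. States: M
# (aligned column), X (gap in alt = deletion), Y (gap in ref =
# insertion). Gap of length L costs open + extend * L. Traceback prefers
# M over X over Y, resolving score ties toward substitutions.
align_ops <- function(r, a, match = 1, mismatch = -1, open = -2, extend = -1) {
  n <- length(r); m <- length(a)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1L, 1] <- open + extend * i
  for (j in seq_len(m)) Y[1, j + 1L] <- open + extend * j
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (r[i] == a[j]) match else mismatch
    M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1L, j + 1L] <- max(M[i, j + 1L] + open + extend,
                             X[i, j + 1L] + extend)
    Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + open + extend,
                             Y[i + 1L, j] + extend)
  }
  i <- n; j <- m
  scores <- c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  state <- which.max(scores)  # ties -> M first
  nsub <- 0L; nins <- 0L; ndel <- 0L
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      if (r[i] != a[j]) nsub <- nsub + 1L
      prev <- c(M[i, j], X[i, j], Y[i, j])
      i <- i - 1L; j <- j - 1L
      state <- which.max(prev)
    } else if (state == 2L) {
      ndel <- ndel + 1L
      from_m <- M[i, j + 1L] + open + extend
      from_x <- X[i, j + 1L] + extend
      i <- i - 1L
      state <- if (from_m >= from_x) 1L else 2L
    } else {
      nins <- nins + 1L
      from_m <- M[i + 1L, j] + open + extend
      from_y <- Y[i + 1L, j] + extend
      j <- j - 1L
      state <- if (from_m >= from_y) 1L else 3L
    }
  }
  c(n_sub = nsub, n_ins = nins, n_del = ndel)
}

#' Table-backed Cas9 activity scorer
#'
#' Looks spacers up in a user-supplied table of activity scores (e.g.
#' DeepSpCas9 predictions computed elsewhere). This is the fidelity path
#' for feeding an external activity predictor into the pipeline.
#'
#' @param scores named numeric vector (names = 20-nt spacers) or a
#'   two-column whitespace/tab-delimited file (spacer, score; no header).
#' @return a scorer function `f(context30)`.
#' @export
scorer_table <- function(scores) {
  if (is.character(scores) && length(scores) == 1L) {
    tab <- read.delim(scores, header = FALSE, sep = "", stringsAsFactors = FALSE)
    scores <- stats::setNames(as.numeric(tab[[2]]), toupper(tab[[1]]))
  }
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  function(context30) {
    if (nchar(context30) != 30L)
      stop("cas9_activity: context must be 30 nt")
    spacer <- substr(context30, 5L, 24L)
    if (!spacer %in% names(scores))
      stop("cas9_activity: no table entry for spacer ", spacer)
    unname(scores[[spacer]])
  }
}

# Position-nucleotide weights of the surrogate scorer: protospacer
# positions 1..20 (context positions 5..24). Seed-proximal G enrichment,
# T depletion, and a strong preference for G at position 20 next to the
# PAM; plus a GC-optimum term and a poly-T penalty below. Deterministic
# by construction.
SURROGATE_PWM <- local({
  W <- matrix(0, nrow = 4, ncol = 20, dimnames = list(c("A", "C", "G", "T"), NULL))
  W["G", 20] <- 0.60; W["C", 20] <- 0.20; W["T", 20] <- -0.40
  for (p in 13:19) { W["G", p] <- 0.15; W["A", p] <- 0.05; W["T", p] <- -0.15 }
  W["G", 1] <- 0.10; W["T", 1] <- -0.10
  W
})

#' Self-contained surrogate Cas9 activity scorer
#'
#' A documented, deterministic heuristic standing in for an external
#' activity predictor when none is supplied: a position-nucleotide weight
#' matrix over the protospacer (seed-proximal G bonus, T penalty, strong
#' G preference adjacent to the PAM), a quadratic penalty for GC content
#' away from 0.55, and -0.5 per TTTT run in the protospacer (Pol III
#' terminator-like stretches). The raw sum is squashed through a logistic
#' to (0, 1). It is a fixed, documented heuristic, not a trained model.
#'
#' @return a scorer function `f(context30)` returning a score in (0, 1).
#' @export
scorer_surrogate <- function() {
  function(context30) {
    if (nchar(context30) != 30L)
      stop("cas9_activity: context must be 30 nt")
    proto <- substr(context30, 5L, 24L)
    b <- strsplit(proto, "", fixed = TRUE)[[1]]
    raw <- sum(SURROGATE_PWM[cbind(match(b, rownames(SURROGATE_PWM)),
                                   seq_len(20L))])
    raw <- raw - 3 * (gc_content(proto) - 0.55)^2
    tt <- gregexpr("TTTT", proto, fixed = TRUE)[[1]]
    if (tt[1] != -1L) raw <- raw - 0.5 * length(tt)
    1 / (1 + exp(-raw))
  }
}

#' Cas9 activity score for one design context
#'
#' @param context30 30-nt context (4 nt upstream + protospacer + PAM +
#'   3 nt downstream).
#' @param scorer a scorer function ([scorer_table()], [scorer_surrogate()]
#'   or any user adapter `f(context30) -> numeric`).
#' @return numeric score.
#' @export
cas9_activity <- function(context30, scorer = scorer_surrogate()) {
  stopifnot(is.function(scorer))
  val <- scorer(context30)
  if (!is.finite(val)) stop("cas9_activity: scorer returned a non-finite value")
  val
}

#' Position features of a design
#'
#' @param design one design row ([assemble_designs()] output).
#' @return named vector `target_pos`, `ngrna_pos` (0 for PE2 designs),
#'   `target_end_flank`.
#' @export
position_features <- function(design) {
  if (design$target_end_flank < 0L)
    stop("position_features: template does not cover the edit")
  c(target_pos = design$target_pos,
    ngrna_pos = if (is.na(design$ngrna_pos)) 0L else design$ngrna_pos,
    target_end_flank = design$target_end_flank)
}

#' Assemble the 23-feature matrix for a design table
#'
#' Computes every model input for each design row: the activity score
#' from `scorer`, oligo lengths/GC, edit-operation counts from the
#' variant alleles, PAM-disruption and PE3b flags, position features, and
#' the 10 folding disruption scores of the full pegRNA (cached per unique
#' pegRNA sequence; ngRNA choice does not change folding).
#'
#' @param designs data.frame from [assemble_designs()].
#' @param window the `target_window` the designs came from.
#' @param scorer Cas9 activity scorer function.
#' @param fold_engine engine passed to [compute_bpp()].
#' @param scaffold scaffold used to build `pegrna_full` (for the layout).
#' @return data.frame of 23 feature columns in canonical order, row-bound
#'   to the designs' `design_id`.
#' @export
assemble_features <- function(designs, window, scorer = scorer_surrogate(),
                              fold_engine = "simple",
                              scaffold = default_scaffold()) {
  stopifnot(is.data.frame(designs))
  if (nrow(designs) == 0L)
    return(cbind(data.frame(design_id = character()),
                 as.data.frame(matrix(numeric(0), 0, length(FEATURE_NAMES),
                                      dimnames = list(NULL, FEATURE_NAMES)))))
  v <- window$variant
  ops <- edit_op_counts(v$ref, v$alt)
  fold_cache <- new.env(parent = emptyenv())
  fold_for <- function(peg, ext_len) {
    key <- peg
    if (!is.null(fold_cache[[key]])) return(fold_cache[[key]])
    bpp <- compute_bpp(peg, engine = fold_engine)
    lay <- peg_layout(20L, nchar(scaffold), ext_len)
    d <- disruption_scores(bpp, lay, k = 10L)
    fold_cache[[key]] <- d
    d
  }
  n <- nrow(designs)
  F <- matrix(NA_real_, n, length(FEATURE_NAMES),
              dimnames = list(NULL, FEATURE_NAMES))
  for (i in seq_len(n)) {
    d <- designs[i, ]
    fold <- fold_for(d$pegrna_full, nchar(d$ext_seq))
    pf <- position_features(d)
    F[i, ] <- c(cas9_activity(d$context30, scorer),
                d$pbs_len, d$rtt_len,
                gc_content(d$pbs_seq), gc_content(d$rtt_seq),
                d$is_dPAM, d$is_PE3b,
                ops[["n_sub"]], ops[["n_ins"]], ops[["n_del"]],
                pf[["target_pos"]], pf[["ngrna_pos"]],
                pf[["target_end_flank"]], fold)
  }
  if (any(!is.finite(F))) stop("assemble_features: non-finite feature value")
  cbind(data.frame(design_id = designs$design_id, stringsAsFactors = FALSE),
        as.data.frame(F))
}
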