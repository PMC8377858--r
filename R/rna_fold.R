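# pegRNA secondary-structure probabilities and scaffold-disruption scores.
#
# The pegRNA (spacer + scaffold + 3' extension, RNA alphabet) is folded as
# one molecule and the base-pair probability matrix P(i,j) is reduced to a
# per-extension-position disruption score
#   D(i) = max_j P(ext_start + i - 1, j),  j over the scaffold,
# the maximal probability that extension position i pairs anywhere into
# the scaffold. High D flags designs whose extension (notably a C at the
# first template position, which can pair with the scaffold G81 of the
# 20-nt-spacer pegRNA) is predicted to disrupt the scaffold structure.

SPCAS9_SCAFFOLD <- "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGC"

#' Default 76-nt SpCas9 sgRNA scaffold (DNA alphabet)
#' @return character scalar.
#' @export
default_scaffold <- function() SPCAS9_SCAFFOLD

#' Base-pair probability matrix of an RNA sequence
#'
#' Computes McCaskill-style partition-function pairing probabilities.
#' Engine `"simple"` uses the package's own exact inside-outside
#' recursion under a uniform energy model: every Watson-Crick or GU pair
#' has energy -1 (Boltzmann weight `exp(beta)`), no stacking, minimum
#' hairpin loop of 3 unpaired bases. This model is deliberately small
#' enough to verify against exhaustive structure enumeration. Engines
#' `"nearest_neighbor"` and `"external"` both delegate to the ViennaRNA
#' `RNAfold -p` global partition function (full nearest-neighbor
#' thermodynamics at 37 C), which must be on the PATH.
#'
#' @param seq RNA string (ACGU; T is accepted and converted).
#' @param engine `"simple"`, `"nearest_neighbor"` or `"external"`.
#' @param beta positive scale applied to the simple-engine pair energy;
#'   the pair weight is `exp(beta)`.
#' @param max_len length cap (guards the O(n^3) recursion).
#' @return object of class `bpp_matrix`: list with `seq` and the symmetric
#'   probability matrix `P` (1-based positions).
#' @export
compute_bpp <- function(seq, engine = c("simple", "nearest_neighbor", "external"),
                        beta = 1, max_len = 500L) {
  engine <- match.arg(engine)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- dna_to_rna(toupper(seq))
  if (grepl("[^ACGU]", seq)) stop("compute_bpp: sequence must be ACGU/ACGT")
  n <- nchar(seq)
  if (n < 8L) stop("compute_bpp: sequence shorter than 8 nt")
  if (n > max_len) stop("compute_bpp: sequence longer than max_len = ", max_len)
  if (engine == "simple") {
    stopifnot(beta > 0)
    codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "U")) - 1L
    P <- .bpp_simple_cpp(codes, exp(beta))
  } else {
    P <- bpp_vienna(seq)
  }
  structure(list(seq = seq, P = P, engine = engine), class = "bpp_matrix")
}

bpp_vienna <- function(seq) {
  exe <- Sys.which("RNAfold")
  if (exe == "")
    stop("compute_bpp: the 'nearest_neighbor'/'external' engine needs RNAfold on the PATH")
  wd <- tempfile("vienna"); dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE), add = TRUE)
  writeLines(c(">q", seq), file.path(wd, "in.fa"))
  old <- setwd(wd); on.exit(setwd(old), add = TRUE)
  status <- system2(exe, c("-p", "--noPS"), stdin = "in.fa",
                    stdout = "out.txt", stderr = "err.txt")
  if (status != 0L || !file.exists("q_dp.ps"))
    stop("compute_bpp: RNAfold failed: ",
         paste(readLines("err.txt", warn = FALSE), collapse = " "))
  n <- nchar(seq)
  P <- matrix(0, n, n)
  for (ln in grep(" ubox$", readLines("q_dp.ps", warn = FALSE), value = TRUE)) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) != 4L) next
    i <- as.integer(f[1]); j <- as.integer(f[2]); p <- as.numeric(f[3])^2
    P[i, j] <- p; P[j, i] <- p
  }
  P
}

#' @export
print.bpp_matrix <- function(x, ...) {
  cat(sprintf("<bpp_matrix> %d nt (%s engine), %d pairs with P > 0.01\n",
              nchar(x$seq), x$engine, sum(x$P[upper.tri(x$P)] > 0.01)))
  invisible(x)
}

#' Write a base-pair probability matrix as plain text
#'
#' Three columns (i, j, probability), upper triangle, nonzero entries only.
#' @param bpp a `bpp_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bpp <- function(bpp, path) {
  stopifnot(inherits(bpp, "bpp_matrix"))
  idx <- which(upper.tri(bpp$P) & bpp$P > 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], prob = bpp$P[idx])
  df <- df[order(df$i, df$j), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Describe the segment layout of a pegRNA
#'
#' @param spacer_len,scaffold_len,ext_len segment lengths (nt).
#' @return list of 1-based index ranges `spacer`, `scaffold`, `extension`.
#' @export
peg_layout <- function(spacer_len, scaffold_len, ext_len) {
  stopifnot(spacer_len >= 0, scaffold_len >= 1, ext_len >= 1)
  list(spacer = if (spacer_len > 0) seq_len(spacer_len) else integer(0),
       scaffold = spacer_len + seq_len(scaffold_len),
       extension = spacer_len + scaffold_len + seq_len(ext_len))
}

#' RNA-folding disruption scores D(i)
#'
#' `D(i)` is the maximal pairing probability between position `i` of the
#' 3' extension and any scaffold position. Position 1 is the extension
#' base adjacent to the scaffold 3' end (the first template base); when
#' the template is shorter than `i`, indexing simply continues into the
#' primer-binding segment of the extension. Positions beyond the extension
#' length score 0.
#'
#' @param bpp a `bpp_matrix` of the full pegRNA.
#' @param layout a [peg_layout()] consistent with the matrix.
#' @param k number of positions to score (default 10, the model's folding
#'   features; 16 is used for the position-correlation analysis).
#' @return numeric vector `D` of length `k`, values in \[0, 1\].
#' @export
disruption_scores <- function(bpp, layout, k = 10L) {
  stopifnot(inherits(bpp, "bpp_matrix"))
  n <- nchar(bpp$seq)
  idx_all <- c(layout$spacer, layout$scaffold, layout$extension)
  if (length(layout$extension) < 1L || max(idx_all) != n ||
      !identical(idx_all, seq_len(n)))
    stop("disruption_scores: layout inconsistent with matrix size")
  vapply(seq_len(k), function(i) {
    if (i > length(layout$extension)) return(0)
    max(bpp$P[layout$extension[i], layout$scaffold])
  }, numeric(1))
}

#' Per-position correlation of disruption scores with efficiency
#'
#' For each extension position i, the Spearman correlation between D(i)
#' across designs and observed (or simulated) editing efficiency, with a
#' permutation p-value. This reproduces the position-wise trend analysis:
#' scaffold pairing of the first few template positions anticorrelates
#' with efficiency, and the association decays with distance.
#'
#' @param D matrix of disruption scores, one row per design, at least
#'   `max(positions)` columns.
#' @param efficiency numeric vector, one value per design.
#' @param positions integer positions to profile (default 1..16).
#' @param n_perm permutations for the p-value.
#' @param seed RNG seed for the permutations.
#' @return data.frame with columns `position`, `rho`, `p_perm`; `rho` is
#'   `NA` for constant D columns.
#' @export
position_correlation_profile <- function(D, efficiency, positions = 1:16,
                                         n_perm = 199L, seed = 1L) {
  D <- as.matrix(D)
  stopifnot(nrow(D) == length(efficiency), max(positions) <= ncol(D))
  if (nrow(D) < 20L)
    stop("position_correlation_profile: need at least 20 observations")
  set.seed(derive_seed(seed, 77L))
  perms <- replicate(n_perm, sample.int(length(efficiency)))
  out <- lapply(positions, function(i) {
    d <- D[, i]
    if (sd(d) == 0 || sd(efficiency) == 0)
      return(data.frame(position = i, rho = NA_real_, p_perm = NA_real_))
    rho <- cor(d, efficiency, method = "spearman")
    null <- apply(perms, 2, function(p) cor(d, efficiency[p], method = "spearman"))
    p <- (1 + sum(abs(null) >= abs(rho))) / (n_perm + 1)
    data.frame(position = i, rho = rho, p_perm = p)
  })
  do.call(rbind, out)
}
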