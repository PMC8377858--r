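# Independent brute-force oracles. These deliberately re-derive expected
# values by exhaustive enumeration or direct string surgery, sharing no
# code with the implementation paths they check.

# ---- RNA folding: exhaustive structure enumeration -------------------

# All non-crossing pairings with hairpin loops >= 3; each Watson-Crick or
# GU pair carries Boltzmann weight q. Pair probabilities by direct
# summation over every structure.
oracle_bpp <- function(seq, q = exp(1)) {
  b <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(b)
  canp <- function(i, j) (j - i >= 4) &&
    paste0(b[i], b[j]) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  structs <- function(i, j) {
    if (j <= i) return(list(list()))
    out <- structs(i, j - 1)
    ks <- if (j - 4 >= i) i:(j - 4) else integer(0)
    for (k in ks) if (canp(k, j)) {
      for (L in structs(i, k - 1)) for (R in structs(k + 1, j - 1))
        out[[length(out) + 1]] <- c(L, R, list(c(k, j)))
    }
    out
  }
  ss <- structs(1, n)
  P <- matrix(0, n, n)
  Z <- 0
  for (s in ss) {
    w <- q^length(s)
    Z <- Z + w
    for (pr in s) P[pr[1], pr[2]] <- P[pr[1], pr[2]] + w
  }
  P <- P / Z
  P + t(P)
}

# ---- edit normalization (own copy for the scanners) ------------------

oracle_core <- function(ref, alt) {
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  k <- 0L
  while (k < length(r) && k < length(a) && r[k + 1] == a[k + 1]) k <- k + 1L
  r2 <- if (k > 0L) r[-seq_len(k)] else r
  a2 <- if (k > 0L) a[-seq_len(k)] else a
  s <- 0L
  while (s < length(r2) && s < length(a2) &&
         r2[length(r2) - s] == a2[length(a2) - s]) s <- s + 1L
  list(shift = k,
       ref_core = paste(utils::head(r2, length(r2) - s), collapse = ""),
       alt_core = paste(utils::head(a2, length(a2) - s), collapse = ""))
}

# frame sequence and frame-coordinate edit start / core lengths for one
# strand of a window
oracle_frame <- function(window, strand) {
  v <- window$variant
  L <- nchar(window$seq)
  core <- oracle_core(v$ref, v$alt)
  cs <- window$edit_offset + core$shift
  lr <- nchar(core$ref_core); la <- nchar(core$alt_core)
  if (strand == "+") {
    list(f = window$seq, ef = apply_edit(window), cs = cs, lr = lr, la = la)
  } else {
    list(f = revcomp(window$seq), ef = revcomp(apply_edit(window)),
         cs = L - cs - lr, lr = lr, la = la)
  }
}

# ---- spacer / extension / ngRNA scanners -----------------------------

oracle_spacers <- function(window, max_target_pos = 25L) {
  out <- list()
  for (strand in c("+", "-")) {
    fr <- oracle_frame(window, strand)
    f <- fr$f; L <- nchar(f)
    if (L < 23L) next
    for (p in 0:(L - 23L)) {
      if (substr(f, p + 22L, p + 23L) != "GG") next
      nick <- p + 17L
      tpos <- fr$cs - nick + 1L
      if (tpos >= 1L && tpos <= max_target_pos && p >= 4L && p + 26L <= L)
        out[[length(out) + 1L]] <- data.frame(
          strand = strand, proto_start = p, target_pos = tpos,
          spacer_seq = substr(f, p + 1L, p + 20L),
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(strand = character(), proto_start = integer(),
                      target_pos = integer(), spacer_seq = character()))
  do.call(rbind, out)
}

# number of admissible (pbs, rtt) pairs for one oracle spacer row
oracle_extension_count <- function(window, strand, proto_start, pbs_range,
                                   rtt_range, min_end_flank = 5L) {
  fr <- oracle_frame(window, strand)
  nick <- proto_start + 17L
  tpos <- fr$cs - nick + 1L
  n <- 0L
  for (pbs in pbs_range) for (rtt in rtt_range) {
    if (nick - pbs < 0L) next
    if (nick + rtt > nchar(fr$ef)) next
    if (rtt - (tpos - 1L) - fr$la < min_end_flank) next
    n <- n + 1L
  }
  n
}

oracle_ngrnas <- function(window, strand, proto_start, ngrna_window = 150L) {
  fr <- oracle_frame(window, strand)
  ef <- fr$ef; eL <- nchar(ef)
  nick <- proto_start + 17L
  edit_lo <- fr$cs; edit_hi <- fr$cs + fr$la
  out <- list()
  if (eL >= 23L) for (a in 3:(eL - 20L)) {
    if (substr(ef, a - 2L, a - 1L) != "CC") next
    pos <- a + 3L - nick
    if (abs(pos) > ngrna_window) next
    plus23 <- substr(ef, a - 2L, a + 20L)
    overlaps <- (a - 3L) < edit_hi && (a + 20L) > edit_lo
    pe3b <- overlaps && !grepl(plus23, fr$f, fixed = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      ngrna_pos = pos, is_PE3b = as.integer(pe3b),
      ngrna_seq = revcomp(substr(ef, a + 1L, a + 20L)),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(ngrna_pos = integer(), is_PE3b = integer(),
                      ngrna_seq = character()))
  do.call(rbind, out)
}

# ---- alignment: exhaustive enumeration -------------------------------

# Every global alignment of two short strings, scored match +1, mismatch
# -1, gap open -2, gap extend -1 (opening charged once per gap run plus
# one extension per residue). Returns the optimal score and the set of
# (n_sub, n_ins, n_del) triples attaining it.
oracle_align <- function(ref, alt) {
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  best <- new.env(); best$score <- -Inf; best$sets <- list()
  rec <- function(i, j, score, nsub, nins, ndel, last) {
    if (i > length(r) && j > length(a)) {
      if (score > best$score) { best$score <- score; best$sets <- list() }
      if (score == best$score)
        best$sets[[length(best$sets) + 1]] <- c(nsub, nins, ndel)
      return(invisible())
    }
    if (i <= length(r) && j <= length(a)) {
      s <- if (r[i] == a[j]) 1 else -1
      rec(i + 1, j + 1, score + s, nsub + (r[i] != a[j]), nins, ndel, "M")
    }
    if (i <= length(r))
      rec(i + 1, j, score - 1 - (last != "D") * 2, nsub, nins, ndel + 1, "D")
    if (j <= length(a))
      rec(i, j + 1, score - 1 - (last != "I") * 2, nsub, nins + 1, ndel, "I")
  }
  rec(1, 1, 0, 0L, 0L, 0L, "M")
  uniq <- unique(best$sets)
  list(score = best$score, triples = uniq)
}

# ---- random windows with edits ---------------------------------------

random_edit_window <- function(len = 80L, seed = NULL, kind = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  e <- len %/% 2L
  refb <- substr(seq, e + 1L, e + 1L)
  if (is.null(kind)) kind <- sample(c("snv", "ins", "del"), 1L)
  edit <- switch(kind,
    snv = list(ref = refb, alt = sample(setdiff(c("A", "C", "G", "T"), refb), 1L)),
    ins = list(ref = refb,
               alt = paste0(refb, paste(sample(c("A", "C", "G", "T"),
                                               sample(1:3, 1L), TRUE),
                                        collapse = ""))),
    del = {
      dl <- sample(1:3, 1L)
      list(ref = substr(seq, e + 1L, e + 1L + dl), alt = refb)
    })
  target_window(seq, e, edit$ref, edit$alt, id = paste0("rw", kind))
}

# mirror a window: reverse-complement the sequence and map the edit
mirror_window <- function(window) {
  v <- window$variant
  L <- nchar(window$seq)
  target_window(revcomp(window$seq),
                L - (window$edit_offset + nchar(v$ref)),
                revcomp(v$ref), revcomp(v$alt),
                id = paste0(v$id, "_m"))
}

# ---- engineered windows ----------------------------------------------

# A/T background with motifs placed at 0-based offsets: GG(p) writes the
# two PAM G's of a + strand protospacer starting at p; CC(a) writes the
# - strand PAM of a protospacer starting (in + coordinates) at a.
engineered_seq <- function(len, motifs, seed = 3L) {
  set.seed(seed)
  ch <- sample(c("A", "T"), len, TRUE)
  for (m in motifs) for (k in seq_along(m$bases)) ch[m$at + k] <- m$bases[k]
  paste(ch, collapse = "")
}
snv_window_at <- function(seq, offset0) {
  ref_at <- substr(seq, offset0 + 1L, offset0 + 1L)
  target_window(seq, offset0, ref_at, setdiff(c("C", "G"), ref_at)[1])
}
GG <- function(p) list(at = p + 21L, bases = c("G", "G"))
CC <- function(a) list(at = a - 3L, bases = c("C", "C"))
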