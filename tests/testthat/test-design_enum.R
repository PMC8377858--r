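test_that("spacer search finds exactly the engineered sites", {
  # no GG anywhere -> no spacer
  w0 <- target_window(paste(rep(c("A", "T"), 30), collapse = ""), 30L, "A", "G")
  expect_equal(nrow(find_spacers(w0)), 0L)
  # one GG placed so the nick is 5 nt 5' of the SNV -> 1 candidate, Target_pos 5
  p <- 20L; nick <- p + 17L
  w1 <- snv_window_at(engineered_seq(60L, list(GG(p)), seed = 5L), nick + 4L)
  sp <- find_spacers(w1)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$target_pos, 5L)
  expect_equal(sp$strand, "+")
  expect_equal(sp$nick_offset, nick)
  # brute-force scan agrees
  osp <- oracle_spacers(w1)
  expect_equal(sp[, c("strand", "proto_start", "target_pos")],
               osp[, c("strand", "proto_start", "target_pos")],
               ignore_attr = TRUE)
  # SNV moved 5' of every possible nick -> empty
  w2 <- target_window(w1$seq, 10L, substr(w1$seq, 11L, 11L),
                      setdiff(c("C", "G"), substr(w1$seq, 11L, 11L))[1])
  expect_equal(nrow(find_spacers(w2)), 0L)
  expect_equal(nrow(oracle_spacers(w2)), 0L)
})

test_that("extension enumeration matches count and coverage rules", {
  # unconstrained locus: nick far from both edges, Target_pos = 1
  p <- 40L; nick <- p + 17L
  w <- snv_window_at(engineered_seq(120L, list(GG(p)), seed = 6L), nick)
  sp <- find_spacers(w)
  expect_equal(nrow(sp), 1L)
  # pbs 13 x rtt 13, Target_pos 1 -> single extension with 12 nt end flank
  e1 <- enumerate_extensions(sp[1, ], w, 13L, 13L)
  expect_equal(nrow(e1), 1L)
  expect_equal(e1$target_end_flank, 12L)
  expect_equal(nchar(e1$ext_seq), 26L)
  # full default ranges -> 10 x 21 = 210 (no boundary or coverage losses)
  e2 <- enumerate_extensions(sp[1, ], w, 8:17, 10:30)
  expect_equal(nrow(e2), 210L)
  expect_equal(nrow(e2),
               oracle_extension_count(w, "+", p, 8:17, 10:30))
  # rtt shorter than Target_pos is excluded
  w5 <- target_window(w$seq, nick + 14L, substr(w$seq, nick + 15L, nick + 15L),
                      setdiff(c("C", "G"),
                              substr(w$seq, nick + 15L, nick + 15L))[1])
  sp5 <- find_spacers(w5)
  expect_equal(sp5$target_pos, 15L)
  expect_equal(nrow(enumerate_extensions(sp5[1, ], w5, 13L, 10:14)), 0L)
})

test_that("extension sequences implement PBS/RTT construction rules", {
  p <- 40L; nick <- p + 17L
  w <- snv_window_at(engineered_seq(120L, list(GG(p)), seed = 6L), nick)
  sp <- find_spacers(w)[1, ]
  ex <- enumerate_extensions(sp, w, 13L, 13L)
  # PBS: reverse complement of the 13 unedited bases 5' of the nick
  expect_equal(ex$pbs_seq, revcomp(substr(w$seq, nick - 12L, nick)))
  # RTT: reverse complement of the 13 *edited* bases 3' of the nick
  edited <- apply_edit(w)
  expect_equal(ex$rtt_seq, revcomp(substr(edited, nick + 1L, nick + 13L)))
  expect_equal(ex$ext_seq, paste0(ex$rtt_seq, ex$pbs_seq))
  # first-template-base C is flagged, never filtered
  expect_equal(ex$first_c,
               as.integer(startsWith(ex$rtt_seq, "C")))
})

test_that("ngRNA search finds engineered opposite-strand sites and PE3b state", {
  p <- 20L; nick <- p + 17L
  # opposite-strand PAM giving signed nick distance +52
  a <- nick + 49L
  w <- snv_window_at(engineered_seq(120L, list(GG(p), CC(a)), seed = 8L),
                     nick + 4L)
  sp <- find_spacers(w)[1, ]
  ng <- find_ngrnas(sp, w)
  expect_equal(nrow(ng), 1L)
  expect_equal(ng$ngrna_pos, 52L)
  expect_equal(ng$is_PE3b, 0L)  # protospacer does not cover the edit
  ong <- oracle_ngrnas(w, "+", p)
  expect_equal(ng[, c("ngrna_pos", "is_PE3b", "ngrna_seq")],
               ong[, c("ngrna_pos", "is_PE3b", "ngrna_seq")],
               ignore_attr = TRUE)
  # SNV inside the opposite-strand protospacer -> PE3b
  a2 <- nick - 3L
  w2 <- snv_window_at(engineered_seq(120L, list(GG(p), CC(a2)), seed = 9L),
                      nick + 4L)
  sp2 <- find_spacers(w2)[1, ]
  ng2 <- find_ngrnas(sp2, w2)
  expect_equal(nrow(ng2), 1L)
  expect_equal(ng2$is_PE3b, 1L)
  # the PE3b spacer matches the edited, not the unedited, sequence
  expect_true(grepl(revcomp(ng2$ngrna_seq), apply_edit(w2), fixed = TRUE))
  expect_false(grepl(revcomp(ng2$ngrna_seq), w2$seq, fixed = TRUE))
  expect_equal(oracle_ngrnas(w2, "+", p)$is_PE3b, 1L)
})

test_that("assembled designs are the full product and install the edit", {
  # 1 spacer x 210 extensions x (3 ngRNAs + none) = 840 designs
  p <- 60L; nick <- p + 17L
  motifs <- list(GG(p), CC(nick + 40L), CC(nick + 70L), CC(nick - 30L))
  w <- snv_window_at(engineered_seq(200L, motifs, seed = 10L), nick)
  cfg <- peg_config()
  d <- assemble_designs(w, cfg)
  expect_equal(nrow(find_spacers(w, cfg$max_target_pos)), 1L)
  expect_equal(nrow(d), 840L)
  expect_equal(sum(d$ngrna_seq == "."), 210L)
  # every design reconstructs the edited strand over its covered span
  check_installation <- function(d, w) {
    edited_plus <- apply_edit(w)
    for (i in seq_len(nrow(d))) {
      row <- d[i, ]
      f <- if (row$strand == "+") w$seq else revcomp(w$seq)
      ef <- if (row$strand == "+") edited_plus else revcomp(edited_plus)
      nick <- row$nick_offset
      synth <- paste0(substr(f, nick - row$pbs_len + 1L, nick),
                      revcomp(row$rtt_seq))
      want <- substr(ef, nick - row$pbs_len + 1L, nick + row$rtt_len)
      if (!identical(synth, want)) return(FALSE)
    }
    TRUE
  }
  expect_true(check_installation(d, w))
  # a variant with no reachable PAM yields a structured empty result
  w_none <- target_window(paste(rep(c("A", "T"), 40), collapse = ""), 40L,
                          "A", "G")
  d0 <- assemble_designs(w_none, cfg)
  expect_equal(nrow(d0), 0L)
  expect_match(attr(d0, "skip_reason"), "no spacer")
})

test_that("enumeration is strand-symmetric for unambiguous edits", {
  set.seed(12)
  n_checked <- 0L
  for (rep in 1:12) {
    w <- random_edit_window(80L, kind = "snv")
    wm <- mirror_window(w)
    d <- assemble_designs(w, fx_toy_config())
    dm <- assemble_designs(wm, fx_toy_config())
    expect_equal(nrow(d), nrow(dm))
    if (nrow(d) == 0L) next
    n_checked <- n_checked + 1L
    key <- function(x) {
      k <- x[order(x$spacer_seq, x$pbs_len, x$rtt_len, x$ngrna_seq),
             c("spacer_seq", "pam_seq", "target_pos", "pbs_seq", "rtt_seq",
               "ext_seq", "ngrna_seq", "ngrna_pos", "is_PE3b", "is_dPAM",
               "target_end_flank")]
      rownames(k) <- NULL
      k$strand <- NULL
      k
    }
    expect_equal(key(d), key(dm))
  }
  expect_gt(n_checked, 3L)
})
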