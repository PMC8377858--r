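test_that("GC content is the G+C fraction", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("GATC"), 0.5)
  expect_error(gc_content(""), "empty")
})

test_that("edit-operation counts follow the Hamming/indel/alignment rules", {
  expect_equal(edit_op_counts("T", "G"), c(n_sub = 1L, n_ins = 0L, n_del = 0L))
  expect_equal(edit_op_counts("A", "ATT"), c(n_sub = 0L, n_ins = 2L, n_del = 0L))
  expect_equal(edit_op_counts("ACGTG", "AGGTG"),
               c(n_sub = 1L, n_ins = 0L, n_del = 0L))
  expect_equal(edit_op_counts("ACGT", "AGT"),
               c(n_sub = 0L, n_ins = 0L, n_del = 1L))
})

test_that("complex-allele counts come from an optimal global alignment", {
  set.seed(61)
  bases <- c("A", "C", "G", "T")
  for (i in 1:60) {
    ref <- paste(sample(bases, sample(1:5, 1), TRUE), collapse = "")
    alt <- paste(sample(bases, sample(1:5, 1), TRUE), collapse = "")
    if (ref == alt) next
    got <- edit_op_counts(ref, alt)
    if (nchar(ref) == nchar(alt)) {
      # equal lengths use position-wise comparison by definition
      expect_equal(unname(got),
                   c(sum(strsplit(ref, "")[[1]] != strsplit(alt, "")[[1]]),
                     0L, 0L))
    } else {
      o <- oracle_align(ref, alt)
      hit <- any(vapply(o$triples, function(t)
        all(t == unname(got)), logical(1)))
      expect_true(hit, info = paste(ref, alt, paste(got, collapse = ",")))
    }
  }
})

test_that("PAM disruption rechecks NGG on the edited sequence", {
  p <- 20L; nick <- p + 17L
  seq <- engineered_seq(80L, list(GG(p)), seed = 62L)
  # SNV at PAM position 2 (first G) destroys the PAM
  w_g <- target_window(seq, p + 21L, "G", "T")
  sp <- find_spacers(w_g)
  expect_equal(nrow(sp), 1L)
  expect_equal(pam_disruption(sp[1, ], w_g), 1L)
  # SNV at PAM position 1 (the N) never disrupts
  ref_n <- substr(seq, p + 21L, p + 21L)
  w_n <- target_window(seq, p + 20L, substr(seq, p + 21L, p + 21L), "C")
  spn <- find_spacers(w_n)
  expect_equal(pam_disruption(spn[1, ], w_n), 0L)
  # deletion spanning the PAM disrupts (unless relocated bases read GG)
  del_ref <- substr(seq, p + 20L, p + 24L)
  w_d <- target_window(seq, p + 19L, del_ref, substr(del_ref, 1L, 1L))
  spd <- find_spacers(w_d)
  expect_equal(nrow(spd), 1L)
  expect_equal(pam_disruption(spd[1, ], w_d), 1L)
})

test_that("position features follow the nick-centred coordinate rules", {
  # +1 SNV with a 13-nt template: Target_pos 1, 12 nt downstream homology
  p <- 40L; nick <- p + 17L
  seq <- engineered_seq(120L, list(GG(p)), seed = 63L)
  w1 <- snv_window_at(seq, nick)
  d1 <- assemble_designs(w1, peg_config(pbs_min = 13L, pbs_max = 13L,
                                        rtt_min = 13L, rtt_max = 13L))
  expect_true(all(d1$target_pos == 1L & d1$target_end_flank == 12L))
  pf <- position_features(d1[1, ])
  expect_equal(unname(pf["target_pos"]), 1L)
  expect_equal(unname(pf["target_end_flank"]), 12L)
  expect_equal(unname(pf["ngrna_pos"]), 0L)  # PE2 sentinel
  # +5 SNV with a 20-nt template: flank = 20 - 4 - 1 = 15
  w5 <- snv_window_at(seq, nick + 4L)
  d5 <- assemble_designs(w5, peg_config(pbs_min = 13L, pbs_max = 13L,
                                        rtt_min = 20L, rtt_max = 20L))
  expect_true(all(d5$target_end_flank == 15L))
  # +1 insertion of 3 nt, 13-nt template: flank = 13 - 0 - 3 = 10
  anchor <- substr(seq, nick, nick)
  wi <- target_window(seq, nick - 1L, anchor, paste0(anchor, "TTT"))
  di <- assemble_designs(wi, peg_config(pbs_min = 13L, pbs_max = 13L,
                                        rtt_min = 13L, rtt_max = 13L))
  expect_true(nrow(di) > 0L)
  expect_true(all(di$target_pos == 1L & di$target_end_flank == 10L))
  # the reconstructed strand really carries 10 homology nt 3' of the insert
  row <- di[1, ]
  new_strand <- revcomp(row$rtt_seq)
  expect_equal(substr(new_strand, 4L, 13L),
               substr(seq, nick + 1L, nick + 10L))
})

test_that("activity scorers are deterministic and validated", {
  ctx <- function(proto) paste0("AATT", proto, "TGGC", "AT")
  proto <- strrep("GACT", 5)
  c30 <- ctx(proto)
  expect_equal(nchar(c30), 30L)
  # table scorer: lookup by spacer, errors on unknowns
  sc <- scorer_table(stats::setNames(0.73, proto))
  expect_equal(cas9_activity(c30, sc), 0.73)
  expect_error(cas9_activity(ctx(strrep("A", 20)), sc), "no table entry")
  expect_error(cas9_activity("ACGT", sc), "30 nt")
  # file-backed table
  tf <- tempfile()
  writeLines(paste(proto, "0.42"), tf)
  expect_equal(cas9_activity(c30, scorer_table(tf)), 0.42)
  # surrogate: deterministic, poly-T protospacers score low
  sur <- scorer_surrogate()
  expect_identical(cas9_activity(c30, sur), cas9_activity(c30, sur))
  set.seed(64)
  pool <- replicate(40, paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                              collapse = ""))
  scores <- vapply(pool, function(p) cas9_activity(ctx(p), sur), numeric(1))
  polyt <- cas9_activity(ctx(strrep("T", 20)), sur)
  expect_lt(polyt, median(scores))
  expect_true(all(scores > 0 & scores < 1))
})

test_that("feature assembly yields the stable 23-column schema", {
  expect_length(feature_schema("full"), 23L)
  expect_length(feature_schema("pe2"), 21L)
  expect_false(any(c("ngrna_pos", "is_PE3b") %in% feature_schema("pe2")))
  expect_identical(schema_id(feature_schema("full")),
                   schema_id(feature_schema("full")))
  toy <- fx_toy()
  w <- extract_window(toy$variants[[4]], toy$reference, 60L)  # PE3b contig
  d <- assemble_designs(w, fx_toy_config())
  f <- assemble_features(d, w)
  expect_identical(setdiff(names(f), "design_id"), feature_schema("full"))
  expect_true(all(vapply(f[feature_schema("full")],
                         function(x) all(is.finite(x)), logical(1))))
  # PE3b design rows carry the flag
  expect_identical(f$is_PE3b, as.numeric(d$is_PE3b))
  # two designs differing only in PBS length differ only in pbs features
  same_rtt <- d[d$ngrna_seq == "." & d$rtt_len == max(d$rtt_len), ]
  i1 <- which(d$design_id == same_rtt$design_id[1])
  i2 <- which(d$design_id == same_rtt$design_id[2])
  diffs <- names(f)[-1][as.numeric(f[i1, -1]) != as.numeric(f[i2, -1])]
  expect_true(all(diffs %in% c("pbs_len", "pbs_gc",
                               paste0("fold_d", 1:10))))
  expect_true("pbs_len" %in% diffs)
})

test_that("folding features depend only on the pegRNA sequence", {
  # permuting window context outside the design footprint leaves the
  # fold features unchanged (rtt >= 10 so all 10 positions are template)
  p <- 40L; nick <- p + 17L
  seq <- engineered_seq(120L, list(GG(p)), seed = 65L)
  w <- snv_window_at(seq, nick)
  cfg <- peg_config(pbs_min = 12L, pbs_max = 12L, rtt_min = 12L,
                    rtt_max = 12L)
  d <- assemble_designs(w, cfg)
  f <- assemble_features(d, w)
  # shuffle the last 20 window bases (outside spacer/PBS/RTT footprint)
  set.seed(66)
  tail_perm <- paste(sample(strsplit(substr(seq, 101, 120), "")[[1]]),
                     collapse = "")
  seq2 <- paste0(substr(seq, 1, 100), tail_perm)
  w2 <- snv_window_at(seq2, nick)
  d2 <- assemble_designs(w2, cfg)
  f2 <- assemble_features(d2, w2)
  fold_cols <- paste0("fold_d", 1:10)
  expect_equal(f[f$design_id %in% d2$design_id, fold_cols],
               f2[, fold_cols], ignore_attr = TRUE)
})
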