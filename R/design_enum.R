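# Enumeration of pegRNA designs: spacers with NGG PAMs on both strands,
# PBS/RTT extension combinations, and nicking guides (PE3/PE3b).
#
# All geometry is computed in the "PAM-strand frame": the window sequence
# oriented so the protospacer reads 5'->3' with its NGG PAM immediately
# 3'. For '-'-strand candidates the frame is the reverse complement of the
# window and the edit is mapped into it, so plus- and minus-strand designs
# share one set of coordinate rules. The nick sits between protospacer
# positions 17 and 18 (3 nt 5' of the PAM); `target_pos` is the 1-based
# distance from the nick to the first edited base (+1 = the base
# immediately 3' of the nick), `target_end_flank` the number of template
# bases 3' of the edit (downstream homology), and `ngrna_pos` the signed
# nick-to-nick distance on the PAM-strand axis (positive = 3' of the
# pegRNA nick).

#' Design configuration
#'
#' Enumeration and ranking parameters. Defaults span the ranges tested in
#' the original prime-editing literature and are all overridable, per
#' value or via a key=value config file ([read_peg_config()]).
#'
#' @param pbs_min,pbs_max primer-binding-site length range (nt).
#' @param rtt_min,rtt_max reverse-transcription-template length range (nt).
#' @param ngrna_window max absolute ngRNA-to-pegRNA nick distance (nt).
#' @param min_end_flank minimum downstream homology 3' of the edit (nt).
#' @param max_target_pos max nick-to-edit distance; default
#'   `rtt_max - min_end_flank`.
#' @param flank design window half-width (nt).
#' @param scaffold sgRNA scaffold (DNA alphabet); spacers must be 20 nt.
#' @param top_n designs reported per variant.
#' @return list of class `peg_config`.
#' @export
peg_config <- function(pbs_min = 8L, pbs_max = 17L, rtt_min = 10L, rtt_max = 30L,
                       ngrna_window = 150L, min_end_flank = 5L,
                       max_target_pos = NULL, flank = 200L,
                       scaffold = default_scaffold(), top_n = 3L) {
  stopifnot(pbs_min >= 1, pbs_max >= pbs_min, rtt_min >= 1, rtt_max >= rtt_min,
            ngrna_window >= 0, min_end_flank >= 0, flank >= 30)
  if (is.null(max_target_pos)) max_target_pos <- rtt_max - min_end_flank
  stopifnot(max_target_pos >= 1)
  structure(list(pbs_min = as.integer(pbs_min), pbs_max = as.integer(pbs_max),
                 rtt_min = as.integer(rtt_min), rtt_max = as.integer(rtt_max),
                 ngrna_window = as.integer(ngrna_window),
                 min_end_flank = as.integer(min_end_flank),
                 max_target_pos = as.integer(max_target_pos),
                 flank = as.integer(flank), scaffold = toupper(scaffold),
                 top_n = as.integer(top_n)),
            class = "peg_config")
}

#' Read a key=value design configuration file
#'
#' Keys match the arguments of [peg_config()]; unknown keys error, missing
#' keys keep their defaults. Lines starting with `#` are comments.
#' @param path config file.
#' @return a `peg_config`.
#' @export
read_peg_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nchar(lines) > 0 & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("read_peg_config: malformed line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(formals(peg_config)))
      stop("read_peg_config: unknown key: ", key)
    args[[key]] <- if (key == "scaffold") val else as.integer(val)
  }
  do.call(peg_config, args)
}

#' Write a design configuration file
#' @param config a `peg_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peg_config <- function(config, path) {
  stopifnot(inherits(config, "peg_config"))
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, as.character, character(1))), path)
  invisible(path)
}

# PAM-strand frame for one strand of a window: sequence, mapped edit core
# and edited sequence. Core edit positions are 0-based half-open.
window_frame <- function(window, strand) {
  v <- window$variant
  L <- nchar(window$seq)
  core <- normalize_edit(v$ref, v$alt)
  cs <- window$edit_offset + core$shift
  lr <- nchar(core$ref_core)
  if (strand == "+") {
    f <- window$seq
    edit <- list(start = cs, ref_core = core$ref_core, alt_core = core$alt_core)
  } else {
    f <- revcomp(window$seq)
    edit <- list(start = L - cs - lr,
                 ref_core = revcomp(core$ref_core),
                 alt_core = revcomp(core$alt_core))
  }
  edited <- paste0(substr0(f, 0L, edit$start), edit$alt_core,
                   substr0(f, edit$start + nchar(edit$ref_core), nchar(f)))
  list(seq = f, edited = edited, edit = edit, strand = strand, L = L)
}

# First edited base (0-based, frame coords); valid for the unedited and,
# because the edit is 3' of any admissible nick, for positions <= start
# in the edited frame as well.
frame_edit_start <- function(frame) frame$edit$start

#' Find candidate pegRNA spacers in a window
#'
#' Scans both strands for 20-nt protospacers with an NGG PAM (checked on
#' the unedited window) whose nick lies 1..`max_target_pos` nt 5' of the
#' first edited base on the PAM strand, and whose 30-nt activity context
#' (4 nt + protospacer + PAM + 3 nt) fits inside the window.
#'
#' @param window a `target_window`.
#' @param max_target_pos maximum nick-to-edit distance (nt).
#' @return data.frame, one row per candidate: `strand`, `proto_start`
#'   (0-based frame offset of the protospacer 5' end, on its own strand),
#'   `spacer_seq`, `pam_seq`, `nick_offset` (0-based frame boundary
#'   index), `target_pos`, `context30`. Empty data.frame when no site
#'   qualifies.
#' @export
find_spacers <- function(window, max_target_pos = 25L) {
  stopifnot(inherits(window, "target_window"))
  if (grepl("[^ACGT]", window$seq))
    stop("find_spacers: window contains non-ACGT bases")
  rows <- list()
  for (strand in c("+", "-")) {
    fr <- window_frame(window, strand)
    f <- fr$seq; L <- fr$L
    cs <- frame_edit_start(fr)
    if (L < 23L) next
    for (p in 0:(L - 23L)) {
      if (substr0(f, p + 21L, p + 23L) != "GG") next
      nick <- p + 17L
      tpos <- cs - nick + 1L
      if (tpos < 1L || tpos > max_target_pos) next
      if (p < 4L || p + 26L > L) next
      rows[[length(rows) + 1L]] <- data.frame(
        strand = strand, proto_start = p,
        spacer_seq = substr0(f, p, p + 20L),
        pam_seq = substr0(f, p + 20L, p + 23L),
        nick_offset = nick, target_pos = tpos,
        context30 = substr0(f, p - 4L, p + 26L),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(strand = character(), proto_start = integer(),
                      spacer_seq = character(), pam_seq = character(),
                      nick_offset = integer(), target_pos = integer(),
                      context30 = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Enumerate PBS/RTT extensions for one spacer
#'
#' Cartesian product of PBS and RTT lengths, keeping combinations whose
#' template fully covers the edit with at least `min_end_flank` nt of
#' downstream homology and whose sequences fit in the window. The PBS is
#' the reverse complement of the PAM-strand bases 5' of the nick; the
#' template (RTT) is the reverse complement of the *edited* PAM-strand
#' bases 3' of the nick. Extensions whose first template base is C are
#' kept but flagged (`first_c`): the efficiency model learns the scaffold-
#' pairing penalty through the folding features rather than a hard filter.
#'
#' @param spacer one row of [find_spacers()] output.
#' @param window the `target_window` the spacer came from.
#' @param pbs_range,rtt_range integer vectors of lengths to try.
#' @param min_end_flank minimum downstream homology (nt).
#' @return data.frame: `pbs_len`, `rtt_len`, `pbs_seq`, `rtt_seq`,
#'   `ext_seq` (RTT then PBS, 5'->3'; position 1 abuts the scaffold),
#'   `target_end_flank`, `first_c`.
#' @export
enumerate_extensions <- function(spacer, window, pbs_range = 8:17,
                                 rtt_range = 10:30, min_end_flank = 5L) {
  stopifnot(length(pbs_range) >= 1, length(rtt_range) >= 1)
  fr <- window_frame(window, spacer$strand)
  nick <- spacer$nick_offset
  tpos <- spacer$target_pos
  la <- nchar(fr$edit$alt_core)
  eL <- nchar(fr$edited)
  rows <- list()
  for (pbs in sort(unique(as.integer(pbs_range)))) {
    if (nick - pbs < 0L) next
    pbs_seq <- revcomp(substr0(fr$seq, nick - pbs, nick))
    for (rtt in sort(unique(as.integer(rtt_range)))) {
      if (nick + rtt > eL) next
      tef <- rtt - (tpos - 1L) - la
      if (tef < min_end_flank) next
      rtt_seq <- revcomp(substr0(fr$edited, nick, nick + rtt))
      rows[[length(rows) + 1L]] <- data.frame(
        pbs_len = pbs, rtt_len = rtt, pbs_seq = pbs_seq, rtt_seq = rtt_seq,
        ext_seq = paste0(rtt_seq, pbs_seq), target_end_flank = tef,
        first_c = as.integer(startsWith(rtt_seq, "C")),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(pbs_len = integer(), rtt_len = integer(),
                      pbs_seq = character(), rtt_seq = character(),
                      ext_seq = character(), target_end_flank = integer(),
                      first_c = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Find nicking-guide (ngRNA) candidates for one spacer
#'
#' Scans the strand opposite the pegRNA PAM strand of the *edited* window
#' for 20-nt protospacers with their own NGG PAM, within
#' `ngrna_pos_range` of the pegRNA nick. `is_PE3b` = 1 iff the
#' protospacer+PAM 23-mer overlaps the edit and does not occur on the
#' unedited window's opposite strand, i.e. the guide binds only the
#' edited sequence.
#'
#' @param spacer one row of [find_spacers()] output.
#' @param window the `target_window`.
#' @param ngrna_pos_range length-2 numeric, allowed signed nick distance.
#' @return data.frame: `ngrna_seq`, `ngrna_pam`, `ngrna_nick` (frame
#'   boundary, edited coordinates), `ngrna_pos`, `is_PE3b`.
#' @export
find_ngrnas <- function(spacer, window, ngrna_pos_range = c(-150L, 150L)) {
  fr <- window_frame(window, spacer$strand)
  ef <- fr$edited; eL <- nchar(ef)
  nick <- spacer$nick_offset
  cs <- fr$edit$start; la <- nchar(fr$edit$alt_core)
  rows <- list()
  if (eL >= 23L) {
    for (a in 3:(eL - 20L)) {
      if (substr0(ef, a - 3L, a - 1L) != "CC") next
      ng_nick <- a + 3L
      pos <- ng_nick - nick
      if (pos < ngrna_pos_range[1] || pos > ngrna_pos_range[2]) next
      plus23 <- substr0(ef, a - 3L, a + 20L)
      overlaps <- (a - 3L) < (cs + la) && (a + 20L) > cs
      pe3b <- overlaps && !grepl(plus23, fr$seq, fixed = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        ngrna_seq = revcomp(substr0(ef, a, a + 20L)),
        ngrna_pam = revcomp(substr0(ef, a - 3L, a)),
        ngrna_nick = ng_nick, ngrna_pos = pos, is_PE3b = as.integer(pe3b),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(ngrna_seq = character(), ngrna_pam = character(),
                      ngrna_nick = integer(), ngrna_pos = integer(),
                      is_PE3b = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Assemble all pegRNA designs for a window
#'
#' Crosses every spacer with every admissible extension and every ngRNA
#' (plus the no-ngRNA PE2 design), builds the full pegRNA sequence, and
#' verifies the edit-installation round trip: in-silico reverse
#' transcription of the template from the PBS-primed nick must reproduce
#' the edited sequence over the covered span.
#'
#' @param window a `target_window`.
#' @param config a [peg_config()].
#' @return data.frame of designs (one wide row each); when no design
#'   exists the data.frame is empty and carries a `skip_reason` attribute.
#' @export
assemble_designs <- function(window, config = peg_config()) {
  stopifnot(inherits(window, "target_window"), inherits(config, "peg_config"))
  empty <- function(reason) {
    d <- design_table_skeleton()
    attr(d, "skip_reason") <- reason
    d
  }
  if (grepl("[^ACGT]", window$seq)) return(empty("non-ACGT base in window"))
  spacers <- find_spacers(window, config$max_target_pos)
  if (nrow(spacers) == 0L) return(empty("no spacer with reachable PAM"))
  if (nchar(config$scaffold) < 1L) stop("assemble_designs: empty scaffold")
  rows <- list()
  vid <- window$variant$id
  for (si in seq_len(nrow(spacers))) {
    sp <- spacers[si, ]
    if (nchar(sp$spacer_seq) != 20L)
      stop("assemble_designs: spacers must be 20 nt")
    exts <- enumerate_extensions(sp, window, config$pbs_min:config$pbs_max,
                                 config$rtt_min:config$rtt_max,
                                 config$min_end_flank)
    if (nrow(exts) == 0L) next
    ngs <- find_ngrnas(sp, window, c(-config$ngrna_window, config$ngrna_window))
    fr <- window_frame(window, sp$strand)
    dpam <- pam_disruption(sp, window)
    ng_list <- c(list(NULL), split(ngs, seq_len(nrow(ngs))))
    for (ei in seq_len(nrow(exts))) {
      ex <- exts[ei, ]
      check_round_trip(fr, sp, ex)
      peg <- dna_to_rna(paste0(sp$spacer_seq, config$scaffold, ex$ext_seq))
      for (ng in ng_list) {
        rows[[length(rows) + 1L]] <- data.frame(
          variant_id = vid, strand = sp$strand, proto_start = sp$proto_start,
          spacer_seq = sp$spacer_seq, pam_seq = sp$pam_seq,
          nick_offset = sp$nick_offset, target_pos = sp$target_pos,
          context30 = sp$context30,
          pbs_len = ex$pbs_len, rtt_len = ex$rtt_len,
          pbs_seq = ex$pbs_seq, rtt_seq = ex$rtt_seq, ext_seq = ex$ext_seq,
          first_c = ex$first_c, target_end_flank = ex$target_end_flank,
          ngrna_seq = if (is.null(ng)) "." else ng$ngrna_seq,
          ngrna_pos = if (is.null(ng)) NA_integer_ else ng$ngrna_pos,
          is_PE3b = if (is.null(ng)) 0L else ng$is_PE3b,
          is_dPAM = dpam,
          pegrna_full = peg,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty("no extension covers the edit"))
  out <- do.call(rbind, rows)
  out$design_id <- sprintf("%s|%s%d|pbs%d|rtt%d|%s", out$variant_id, out$strand,
                           out$proto_start, out$pbs_len, out$rtt_len,
                           ifelse(out$ngrna_seq == ".", "pe2",
                                  paste0("ng", out$ngrna_pos)))
  rownames(out) <- NULL
  out
}

design_table_skeleton <- function() {
  data.frame(variant_id = character(), strand = character(),
             proto_start = integer(), spacer_seq = character(),
             pam_seq = character(), nick_offset = integer(),
             target_pos = integer(), context30 = character(),
             pbs_len = integer(), rtt_len = integer(), pbs_seq = character(),
             rtt_seq = character(), ext_seq = character(),
             first_c = integer(), target_end_flank = integer(),
             ngrna_seq = character(), ngrna_pos = integer(),
             is_PE3b = integer(), is_dPAM = integer(),
             pegrna_full = character(), design_id = character(),
             stringsAsFactors = FALSE)
}

# Edit-installation round trip: priming from the PBS at the nick and
# copying the template must reproduce the edited PAM-strand sequence over
# the covered interval.
check_round_trip <- function(frame, spacer, ext) {
  nick <- spacer$nick_offset
  synthesized <- paste0(substr0(frame$seq, nick - ext$pbs_len, nick),
                        revcomp(ext$rtt_seq))
  expected <- substr0(frame$edited, nick - ext$pbs_len, nick + ext$rtt_len)
  if (synthesized != expected)
    stop("assemble_designs: edit-installation round trip failed for spacer at ",
         spacer$proto_start, " (", spacer$strand, " strand)")
  invisible(TRUE)
}

#' Does the edit disrupt the spacer's PAM?
#'
#' Re-checks the NGG match at the PAM location of the *edited* PAM-strand
#' sequence (only the two G positions can disrupt; position 1 is N). An
#' edit that shifts sequence into the PAM window counts as disrupting
#' unless the relocated bases still read GG.
#'
#' @param spacer one row of [find_spacers()] output.
#' @param window the `target_window`.
#' @return 0 or 1.
#' @export
pam_disruption <- function(spacer, window) {
  fr <- window_frame(window, spacer$strand)
  p <- spacer$proto_start
  gg <- substr0(fr$edited, p + 21L, p + 23L)
  as.integer(!identical(gg, "GG"))
}
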