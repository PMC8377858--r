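# Variant and reference I/O: VCF or an edit-encoding FASTA dialect in,
# edit-centred design windows out.

#' Construct a genomic variant (one desired edit)
#'
#' A variant is one desired edit: the reference allele `ref` at 1-based
#' position `pos` of `chrom` is replaced by `alt`. Pure insertions and
#' deletions follow the VCF convention of a single shared anchor base
#' (e.g. ref `"A"`, alt `"ATT"`); internally the shared prefix/suffix is
#' stripped for edit-length accounting.
#'
#' @param id character label.
#' @param chrom sequence (contig) name.
#' @param pos 1-based reference position of the first ref-allele base.
#' @param ref uppercase DNA string, at least one base.
#' @param alt uppercase DNA string, different from `ref`.
#' @return an object of class `genomic_variant`.
#' @export
genomic_variant <- function(id, chrom, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(length(pos) == 1L, pos >= 1)
  if (!is_dna(ref) || !is_dna(alt))
    stop("genomic_variant: ref/alt must be nonempty ACGT strings (variant ", id, ")")
  if (ref == alt) stop("genomic_variant: ref == alt for variant ", id)
  structure(
    list(id = as.character(id), chrom = as.character(chrom),
         pos = as.integer(pos), ref = ref, alt = alt),
    class = "genomic_variant")
}

#' @export
print.genomic_variant <- function(x, ...) {
  cat(sprintf("<genomic_variant> %s %s:%d %s>%s\n", x$id, x$chrom, x$pos, x$ref, x$alt))
  invisible(x)
}

# Strip the longest common prefix, then the longest common suffix, of
# ref/alt. Returns the "core" edit: 0-based offset shift, ref_core,
# alt_core (either may be empty, not both).
normalize_edit <- function(ref, alt) {
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  k <- 0L
  while (k < length(r) && k < length(a) && r[k + 1L] == a[k + 1L]) k <- k + 1L
  r2 <- r[seq_len(length(r) - k) + k]; a2 <- a[seq_len(length(a) - k) + k]
  s <- 0L
  while (s < length(r2) && s < length(a2) &&
         r2[length(r2) - s] == a2[length(a2) - s]) s <- s + 1L
  list(shift = k,
       ref_core = paste(r2[seq_len(length(r2) - s)], collapse = ""),
       alt_core = paste(a2[seq_len(length(a2) - s)], collapse = ""))
}

read_fasta_upper <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
}

#' Read variants from VCF or the edit-encoding FASTA dialect
#'
#' Two input formats are supported. (1) VCF 4.x: columns CHROM, POS, ID,
#' REF, ALT are used, everything else is ignored; multi-allelic records are
#' expanded to one variant per alternative allele; every REF allele is
#' verified against the supplied reference FASTA. (2) A self-contained
#' FASTA dialect in which each record carries its own reference window and
#' the desired edit in the header: `>id|pos=201|ref=A|alt=ATT` with `pos`
#' 1-based within the record sequence. For FASTA input the per-record
#' sequences are attached to the result as `attr(, "reference")` so the
#' records serve as their own reference.
#'
#' @param path VCF (`.vcf`) or FASTA (`.fa`/`.fasta`) file.
#' @param reference reference FASTA path or a named character vector of
#'   contig sequences; required for VCF input.
#' @return list of [genomic_variant()] objects (possibly with a
#'   `reference` attribute); empty list with a warning for an empty file.
#' @export
read_variants <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("read_variants: no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) {
    warning("read_variants: empty file ", path)
    return(list())
  }
  if (startsWith(first, ">")) read_variants_fasta(path)
  else read_variants_vcf(path, reference)
}

read_variants_vcf <- function(path, reference) {
  if (is.null(reference))
    stop("read_variants: a reference FASTA is required for VCF input")
  ref_seqs <- if (is.character(reference) && length(reference) == 1L &&
                  file.exists(reference)) read_fasta_upper(reference) else reference
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (!is.null(fx) && is.null(dim(fx)))  # single records drop to a vector
    fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  if (is.null(fx) || nrow(fx) == 0L) {
    warning("read_variants: no records in ", path)
    return(list())
  }
  fx <- as.data.frame(fx, stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(fx))) {
    chrom <- fx$CHROM[i]; pos <- as.integer(fx$POS[i])
    id <- fx$ID[i]
    if (is.na(id) || id == ".") id <- sprintf("%s_%d", chrom, pos)
    ref <- toupper(fx$REF[i])
    alts <- strsplit(toupper(fx$ALT[i]), ",", fixed = TRUE)[[1]]
    if (!chrom %in% names(ref_seqs))
      stop("read_variants: unknown chrom '", chrom, "' in record ", id)
    have <- substr(ref_seqs[[chrom]], pos, pos + nchar(ref) - 1L)
    if (have != ref)
      stop("read_variants: REF mismatch for record ", id, " at ", chrom, ":",
           pos, " (VCF says ", ref, ", reference has ", have, ")")
    for (j in seq_along(alts)) {
      vid <- if (length(alts) > 1L) sprintf("%s_alt%d", id, j) else id
      out[[length(out) + 1L]] <- genomic_variant(vid, chrom, pos, ref, alts[j])
    }
  }
  out
}

read_variants_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) {
    warning("read_variants: no records in ", path)
    return(list())
  }
  seqs <- toupper(as.character(ss))
  out <- list(); refs <- character()
  for (i in seq_along(seqs)) {
    hdr <- names(seqs)[i]
    parts <- strsplit(hdr, "|", fixed = TRUE)[[1]]
    id <- trimws(parts[1])
    kv <- parts[-1]
    get <- function(key) {
      hit <- grep(paste0("^", key, "="), kv, value = TRUE)
      if (length(hit) != 1L)
        stop("read_variants: FASTA header of '", id, "' lacks ", key, "= field")
      sub(paste0("^", key, "="), "", hit)
    }
    pos <- as.integer(get("pos")); ref <- toupper(get("ref")); alt <- toupper(get("alt"))
    seq <- seqs[[i]]
    have <- substr(seq, pos, pos + nchar(ref) - 1L)
    if (have != ref)
      stop("read_variants: ref mismatch for FASTA record ", id,
           " (header says ", ref, " at pos ", pos, ", sequence has ", have, ")")
    out[[length(out) + 1L]] <- genomic_variant(id, id, pos, ref, alt)
    refs[[id]] <- seq
  }
  attr(out, "reference") <- refs
  out
}

#' Write variants to VCF or the edit-encoding FASTA dialect
#'
#' @param variants list of [genomic_variant()].
#' @param path output file.
#' @param format `"vcf"` or `"fasta"`; default inferred from the extension.
#' @param reference named contig sequences (or FASTA path); required for
#'   FASTA output (each record carries its contig sequence).
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, format = NULL, reference = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fa", "fasta", "fna")) "fasta" else "vcf"
  }
  if (format == "vcf") {
    lines <- c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    for (v in variants)
      lines <- c(lines, sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                                v$chrom, v$pos, v$id, v$ref, v$alt))
    writeLines(lines, path)
  } else {
    if (is.null(reference))
      stop("write_variants: FASTA output needs the reference sequences")
    ref_seqs <- if (is.character(reference) && length(reference) == 1L &&
                    file.exists(reference)) read_fasta_upper(reference) else reference
    seqs <- character(); nms <- character()
    for (v in variants) {
      if (!v$chrom %in% names(ref_seqs))
        stop("write_variants: unknown chrom ", v$chrom)
      nms <- c(nms, sprintf("%s|pos=%d|ref=%s|alt=%s", v$id, v$pos, v$ref, v$alt))
      seqs <- c(seqs, ref_seqs[[v$chrom]])
    }
    ss <- Biostrings::DNAStringSet(seqs); names(ss) <- nms
    Biostrings::writeXStringSet(ss, path)
  }
  invisible(path)
}

#' Extract the edit-centred design window around a variant
#'
#' Cuts `flank` nt on each side of the variant's reference allele
#' (truncated at contig ends). All downstream design arithmetic happens in
#' window coordinates (0-based half-open internally; 1-based only at the
#' VCF/FASTA boundary).
#'
#' @param variant a [genomic_variant()].
#' @param reference named contig sequences or a FASTA path.
#' @param flank nt on each side, >= 30.
#' @return object of class `target_window` with fields `variant`, `seq`,
#'   `window_start` (1-based reference coordinate of the first window
#'   base), `edit_offset` (0-based offset of the variant's first ref base
#'   in `seq`) and `flank`.
#' @export
extract_window <- function(variant, reference, flank = 200L) {
  stopifnot(inherits(variant, "genomic_variant"))
  if (flank < 30L) stop("extract_window: flank must be >= 30")
  ref_seqs <- if (is.character(reference) && length(reference) == 1L &&
                  file.exists(reference)) read_fasta_upper(reference) else reference
  if (!variant$chrom %in% names(ref_seqs))
    stop("extract_window: unknown chrom ", variant$chrom)
  contig <- toupper(ref_seqs[[variant$chrom]])
  L <- nchar(contig)
  if (variant$pos + nchar(variant$ref) - 1L > L)
    stop("extract_window: variant ", variant$id, " exceeds contig end")
  have <- substr(contig, variant$pos, variant$pos + nchar(variant$ref) - 1L)
  if (have != variant$ref)
    stop("extract_window: ref mismatch for ", variant$id,
         " (expected ", variant$ref, ", found ", have, ")")
  ws <- max(1L, variant$pos - as.integer(flank))
  we <- min(L, variant$pos + nchar(variant$ref) - 1L + as.integer(flank))
  seq <- substr(contig, ws, we)
  if (nchar(seq) < 30L)
    stop("extract_window: window too small for variant ", variant$id)
  structure(
    list(variant = variant, seq = seq, window_start = ws,
         edit_offset = variant$pos - ws, flank = as.integer(flank)),
    class = "target_window")
}

#' Build a target window directly from a sequence
#'
#' Convenience constructor used with the FASTA dialect and in tests: the
#' supplied sequence is the whole window.
#'
#' @param seq window sequence (uppercased).
#' @param edit_offset 0-based offset of the first ref base within `seq`.
#' @param ref,alt the edit alleles.
#' @param id variant label.
#' @param window_start 1-based reference coordinate of `seq[1]`.
#' @return a `target_window`.
#' @export
target_window <- function(seq, edit_offset, ref, alt, id = "v",
                          window_start = 1L) {
  seq <- toupper(seq)
  v <- genomic_variant(id, id, window_start + edit_offset, ref, alt)
  if (substr0(seq, edit_offset, edit_offset + nchar(ref)) != toupper(ref))
    stop("target_window: seq does not carry ref at edit_offset")
  structure(
    list(variant = v, seq = seq, window_start = as.integer(window_start),
         edit_offset = as.integer(edit_offset), flank = NA_integer_),
    class = "target_window")
}

#' @export
print.target_window <- function(x, ...) {
  cat(sprintf("<target_window> %s: %d nt, edit %s>%s at offset %d\n",
              x$variant$id, nchar(x$seq), x$variant$ref, x$variant$alt,
              x$edit_offset))
  invisible(x)
}

#' Apply the window's edit in sequence space
#'
#' @param window a `target_window`.
#' @return the edited window sequence; its length differs from the input
#'   by `nchar(alt) - nchar(ref)`.
#' @export
apply_edit <- function(window) {
  stopifnot(inherits(window, "target_window"))
  v <- window$variant
  e <- window$edit_offset
  paste0(substr0(window$seq, 0L, e), v$alt,
         substr0(window$seq, e + nchar(v$ref), nchar(window$seq)))
}
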