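#' Pairwise alignment container
#'
#' Holds a reference sequence and its aligned partner (equal length, gap
#' character `-`, alphabet `A C G T N -`, case-insensitive), plus the
#' reference name and 1-based reference start coordinate used when
#' reporting genomic positions.
#'
#' @param reference,partner aligned sequences as single strings of equal
#'   length.
#' @param name reference sequence name.
#' @param ref_start 1-based coordinate of the first reference base.
#' @return An `alignment_pair` object.
#' @seealso [read_alignment_fasta()], [sliding_identity()]
#' @export
alignment_pair <- function(reference, partner, name = "", ref_start = 1L) {
  if (!is.character(reference) || !is.character(partner) ||
      length(reference) != 1L || length(partner) != 1L)
    stopf("sequences must be single strings")
  if (nchar(reference) != nchar(partner))
    stopf("aligned sequences must have equal length (%d vs %d)",
          nchar(reference), nchar(partner))
  if (nchar(reference) == 0L) stopf("alignment is empty")
  reference <- toupper(reference)
  partner <- toupper(partner)
  ok <- function(s) !grepl("[^ACGTN-]", s)
  if (!ok(reference) || !ok(partner))
    stopf("alphabet must be {A, C, G, T, N, -}")
  structure(list(reference = reference, partner = partner, name = name,
                 ref_start = as.integer(ref_start)),
            class = "alignment_pair")
}

#' Read a pairwise alignment from aligned FASTA
#'
#' Expects exactly two records of equal aligned length; the first record
#' is the reference. Malformed files are reported with the offending line
#' number.
#'
#' @param path aligned FASTA file.
#' @param ref_start 1-based reference start coordinate.
#' @return An [alignment_pair()].
#' @export
read_alignment_fasta <- function(path, ref_start = 1L) {
  lines <- readLines(path)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) stopf("%s: empty FASTA (line 1)", path)
  if (!startsWith(trimws(lines[nonempty[1L]]), ">"))
    stopf("%s: expected FASTA header at line %d", path, nonempty[1L])
  headers <- which(startsWith(trimws(lines), ">"))
  if (length(headers) != 2L)
    stopf("%s: expected exactly 2 records, found %d (first header at line %d)",
          path, length(headers), headers[1L])
  seqs <- Biostrings::readBStringSet(path)
  if (length(unique(Biostrings::width(seqs))) != 1L)
    stopf("%s: records differ in aligned length (record 2 starts at line %d)",
          path, headers[2L])
  alignment_pair(as.character(seqs[[1L]]), as.character(seqs[[2L]]),
                 name = names(seqs)[1L], ref_start = ref_start)
}

#' @param pair an [alignment_pair()] to write.
#' @rdname read_alignment_fasta
#' @export
write_alignment_fasta <- function(pair, path) {
  seqs <- Biostrings::BStringSet(c(pair$reference, pair$partner))
  names(seqs) <- c(if (nzchar(pair$name)) pair$name else "reference",
                   "partner")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# split an alignment into reference-base columns: drops columns where the
# reference is gapped (partner insertions), so windows are counted in
# reference base pairs as VISTA-style plots do
ref_columns <- function(pair) {
  r <- strsplit(pair$reference, "")[[1L]]
  p <- strsplit(pair$partner, "")[[1L]]
  keep <- r != "-"
  list(ref = r[keep], partner = p[keep])
}

#' Sliding-window percent identity profile
#'
#' For every window of `window_bp` consecutive reference bases (sliding by
#' one base), the percent identity is `100 * matches / window_bp`, where a
#' column counts as a match only when reference and partner carry the same
#' unambiguous base. Gap columns opposite reference bases (deletions in
#' the partner) and `N`s count as mismatches; insertions in the partner
#' (gaps in the reference) are skipped entirely so the window width stays
#' defined in reference base pairs. The profile value is reported at the
#' window's reference start position.
#'
#' @param pair an [alignment_pair()].
#' @param window_bp window width in reference base pairs.
#' @return A `conservation_profile` data frame with `pos` (1-based
#'   reference coordinate of the window start) and `identity` (percent, in
#'   `[0, 100]`), with attributes `window_bp` and `ref_length`.
#' @export
sliding_identity <- function(pair, window_bp = 100) {
  if (!inherits(pair, "alignment_pair"))
    stopf("`pair` must be an alignment_pair")
  if (!is_count(window_bp)) stopf("`window_bp` must be a positive integer")
  cols <- ref_columns(pair)
  L <- length(cols$ref)
  if (window_bp > L)
    stopf("window (%d bp) longer than ungapped reference (%d bp)",
          window_bp, L)
  match <- as.integer(cols$ref == cols$partner & cols$ref %in%
                        c("A", "C", "G", "T") & cols$partner %in%
                        c("A", "C", "G", "T"))
  cs <- c(0L, cumsum(match))
  starts <- seq_len(L - window_bp + 1L)
  ident <- 100 * (cs[starts + window_bp] - cs[starts]) / window_bp
  structure(data.frame(pos = starts, identity = ident),
            class = c("conservation_profile", "data.frame"),
            window_bp = as.integer(window_bp), ref_length = L)
}

#' Call conserved elements from a conservation profile
#'
#' Takes the union of all windows whose identity is strictly greater than
#' the threshold, merges overlapping or adjacent spans into maximal
#' reference intervals, and keeps intervals at least `min_width_bp` wide
#' (the VISTA-style defaults are a 100-bp window, 80% identity and 100-bp
#' minimum width). Elements are disjoint, sorted, and reported in 1-based
#' closed reference coordinates.
#'
#' @param profile a [sliding_identity()] profile.
#' @param identity_threshold percent identity; windows must exceed it
#'   strictly.
#' @param min_width_bp minimum element width in reference base pairs.
#' @return A `conserved_elements` data frame with `start`, `end`, `width`
#'   and `mean_identity` (mean over the qualifying windows of the run).
#' @export
call_conserved <- function(profile, identity_threshold = 80,
                           min_width_bp = 100) {
  if (!inherits(profile, "conservation_profile"))
    stopf("`profile` must be a conservation_profile")
  w <- attr(profile, "window_bp")
  L <- attr(profile, "ref_length")
  qual <- profile$identity > identity_threshold
  empty <- data.frame(start = integer(0), end = integer(0),
                      width = integer(0), mean_identity = numeric(0))
  if (!any(qual))
    return(structure(empty, class = c("conserved_elements", "data.frame")))
  covered <- logical(L)
  for (q in profile$pos[qual]) covered[q:(q + w - 1L)] <- TRUE
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_width_bp
  if (!any(keep))
    return(structure(empty, class = c("conserved_elements", "data.frame")))
  out <- data.frame(start = starts[keep], end = ends[keep],
                    width = runs$lengths[keep])
  out$mean_identity <- vapply(seq_len(nrow(out)), function(i) {
    in_run <- qual & profile$pos >= out$start[i] &
      profile$pos + w - 1L <= out$end[i]
    mean(profile$identity[in_run])
  }, numeric(1))
  structure(out, class = c("conserved_elements", "data.frame"))
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Scan a sequence for a consensus motif with mismatches
#'
#' Reports every position (on both strands unless disabled) whose Hamming
#' distance to the consensus motif is at most `max_mismatch`; `N` counts
#' as a mismatch. The default consensus is the T-box binding motif
#' `TCACACCT` with a single substitution allowed. Minus-strand hits are
#' reported at their leftmost coordinate on the forward strand, with the
#' matched substring given in motif orientation (reverse complement of the
#' forward-strand window).
#'
#' @param sequence ungapped nucleotide sequence (string).
#' @param motif consensus motif over `{A, C, G, T}`.
#' @param max_mismatch maximum Hamming distance.
#' @param both_strands scan the reverse complement as well.
#' @return A `motif_hits` data frame with `position` (1-based forward
#'   coordinate), `strand` (`+`/`-`), `mismatches` and `match`. A motif
#'   longer than the sequence yields zero hits (not an error).
#' @export
motif_scan <- function(sequence, motif = "TCACACCT", max_mismatch = 1,
                       both_strands = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stopf("`sequence` must be a single string")
  sequence <- toupper(sequence)
  motif <- toupper(motif)
  if (grepl("-", sequence, fixed = TRUE))
    stopf("`sequence` must be ungapped")
  if (grepl("[^ACGT]", motif)) stopf("motif must be over {A, C, G, T}")
  s <- strsplit(sequence, "")[[1L]]
  m <- nchar(motif)
  L <- length(s)
  empty <- data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0), match = character(0))
  if (m > L)
    return(structure(empty, class = c("motif_hits", "data.frame")))

  scan_one <- function(pat) {
    pc <- strsplit(pat, "")[[1L]]
    n_pos <- L - m + 1L
    mm <- integer(n_pos)
    for (j in seq_len(m))
      mm <- mm + (s[j:(n_pos + j - 1L)] != pc[j])
    which(mm <= max_mismatch) -> hit
    list(pos = hit, mm = mm[hit])
  }
  fwd <- scan_one(motif)
  res <- data.frame(position = fwd$pos,
                    strand = rep("+", length(fwd$pos)),
                    mismatches = fwd$mm,
                    match = vapply(fwd$pos, function(p)
                      substr(sequence, p, p + m - 1L), character(1)))
  if (both_strands) {
    rev <- scan_one(revcomp(motif))
    res <- rbind(res, data.frame(
      position = rev$pos,
      strand = rep("-", length(rev$pos)),
      mismatches = rev$mm,
      match = vapply(rev$pos, function(p)
        revcomp(substr(sequence, p, p + m - 1L)), character(1))))
  }
  res <- res[order(res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("motif_hits", "data.frame"))
}

#' Extract an upstream fragment relative to a transcription start site
#'
#' Coordinates are TSS-relative and negative: position -1 is the base
#' immediately 5' of the TSS. The closed range `[upstream_from,
#' upstream_to]` (for example the -3462 to -3045 enhancer fragment) has
#' length `upstream_to - upstream_from + 1`.
#'
#' @param sequence ungapped nucleotide sequence.
#' @param tss_position 1-based index of the TSS (first transcribed base).
#' @param upstream_from,upstream_to closed TSS-relative coordinate range;
#'   both must be negative and within the sequence.
#' @return The upstream subsequence as a string.
#' @export
extract_upstream <- function(sequence, tss_position,
                             upstream_from = -3462, upstream_to = -3045) {
  if (upstream_to >= 0 || upstream_from >= 0)
    stopf("upstream coordinates must be negative (upstream only)")
  if (upstream_from > upstream_to)
    stopf("`upstream_from` must not exceed `upstream_to`")
  i0 <- tss_position + upstream_from
  i1 <- tss_position + upstream_to
  if (i0 < 1L || i1 > nchar(sequence))
    stopf("upstream interval [%d, %d] outside the sequence",
          upstream_from, upstream_to)
  substr(sequence, i0, i1)
}

#' Write conservation outputs in standard formats
#'
#' The profile is written as a two-column tab-separated file
#' (`pos`, `identity`), conserved elements as BED (0-based, half-open,
#' converted from the internal 1-based closed coordinates, offset by the
#' pair's `ref_start`), and motif hits as a tab-separated table with
#' 1-based positions.
#'
#' @param profile,elements,hits objects from [sliding_identity()],
#'   [call_conserved()] and [motif_scan()].
#' @param path output file.
#' @param name BED feature name prefix.
#' @param chrom,ref_start BED chromosome and 1-based offset of reference
#'   base 1.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
write_elements_bed <- function(elements, path, chrom = "ref",
                               ref_start = 1L, name = "conserved") {
  bed <- data.frame(chrom = rep(chrom, nrow(elements)),
                    start = elements$start - 1L + (ref_start - 1L),
                    end = elements$end + (ref_start - 1L),
                    name = sprintf("%s_%d", name, seq_len(max(nrow(elements), 0L))),
                    score = round(elements$mean_identity))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
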