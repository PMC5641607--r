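#' Find restriction cut positions on a linear sequence
#'
#' Scans both strands for every (possibly overlapping) occurrence of the
#' recognition pattern. Matching is IUPAC-aware on the enzyme side only:
#' ambiguity codes in the template never match (no phantom sites). For a
#' top-strand occurrence starting at 0-based index `s` the cut position is
#' `s + cut_offset`; for a bottom-strand occurrence the complementary cut
#' `s + (site_length - cut_offset)` is reported in top-strand coordinates.
#' Duplicate positions (palindromic sites) are collapsed.
#'
#' Cut positions are returned as prefix lengths: the number of bases 5' of
#' the cut on the forward strand, i.e. "cuts at 251 and 455" means fragments
#' 1-251, 252-455, 456-end.
#'
#' @param seq DNA string or [seq_record()].
#' @param enzyme a [restriction_enzyme()].
#' @return strictly ascending integer vector of cut positions (possibly
#'   empty). Cuts falling at position 0 or at the sequence end are dropped
#'   (they do not cleave a linear molecule).
#' @export
#' @examples
#' find_sites("AGCT", alui())      # 2
#' find_sites("AGCTAGCT", alui())  # 2, 6
find_sites <- function(seq, enzyme) {
  rec <- as_seq_record(seq)
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  chars <- seq_chars(rec$residues)
  n <- length(chars)
  m <- nchar(enzyme$recognition)
  top <- scan_pattern(chars, enzyme$recognition) - 1L + enzyme$cut_offset
  bottom <- scan_pattern(chars, revcomp(enzyme$recognition)) - 1L +
    (m - enzyme$cut_offset)
  cuts <- sort(unique(c(top, bottom)))
  cuts[cuts > 0L & cuts < n]
}

#' Fragment lengths from cut positions
#'
#' Successive differences of the cut positions plus the terminal fragment,
#' in map order (left to right along the molecule). The lengths always sum
#' to the amplicon length.
#'
#' @param amplicon_length total length in nt.
#' @param cuts strictly ascending cut positions in `(0, amplicon_length)`.
#' @return integer vector of `length(cuts) + 1` fragment lengths.
#' @export
#' @examples
#' fragments_from_cuts(710, c(251, 455))  # 251 204 255
fragments_from_cuts <- function(amplicon_length, cuts) {
  amplicon_length <- as.integer(amplicon_length)
  cuts <- as.integer(cuts)
  if (length(cuts) > 0) {
    if (is.unsorted(cuts, strictly = TRUE))
      stop("cut positions must be strictly ascending", call. = FALSE)
    if (cuts[1] <= 0L || cuts[length(cuts)] >= amplicon_length)
      stop("cut positions must lie strictly inside (0, ", amplicon_length,
           ")", call. = FALSE)
  }
  diff(c(0L, cuts, amplicon_length))
}

#' Digest an amplicon with one enzyme
#'
#' @param amplicon an `amplicon` from [extract_amplicon()], a
#'   [seq_record()], or a DNA string.
#' @param enzyme a [restriction_enzyme()].
#' @return object of class `digest_profile`: enzyme name, amplicon id and
#'   length, cut positions (prefix lengths) and map-order fragment lengths.
#' @export
digest <- function(amplicon, enzyme) {
  sq <- if (inherits(amplicon, "amplicon")) amplicon$sequence
        else as_seq_record(amplicon)$residues
  id <- if (inherits(amplicon, "amplicon")) amplicon$template_id
        else if (inherits(amplicon, "seq_record")) amplicon$id else "seq"
  cuts <- find_sites(sq, enzyme)
  structure(
    list(enzyme = enzyme$name, amplicon_id = id,
         amplicon_length = nchar(sq), cut_positions = cuts,
         fragment_lengths = fragments_from_cuts(nchar(sq), cuts)),
    class = "digest_profile"
  )
}

#' @export
print.digest_profile <- function(x, ...) {
  cat(sprintf("<digest_profile> %s x %s (%d bp)\n", x$enzyme, x$amplicon_id,
              x$amplicon_length))
  cat("  cuts:      ", if (length(x$cut_positions))
    paste(x$cut_positions, collapse = ", ") else "(none)", "\n", sep = "")
  cat("  fragments: ", paste(x$fragment_lengths, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Text physical map of a digest
#'
#' Human-readable restriction map: cut positions (1-based prefix lengths)
#' and the 1-based inclusive span of every fragment.
#'
#' @param profile a [digest()] result.
#' @return character scalar (multi-line).
#' @export
#' @examples
#' cat(physical_map(digest(strrep("A", 248), alui())))
physical_map <- function(profile) {
  stopifnot(inherits(profile, "digest_profile"))
  cuts <- profile$cut_positions
  bounds <- c(0L, cuts, profile$amplicon_length)
  spans <- sprintf("%d-%d", bounds[-length(bounds)] + 1L, bounds[-1])
  paste0(
    sprintf("%s map of %s (%d bp)\n", profile$enzyme, profile$amplicon_id,
            profile$amplicon_length),
    "cuts: ", if (length(cuts)) paste(cuts, collapse = ", ") else "none",
    "\n",
    paste(spans, collapse = " | "), "\n"
  )
}

#' Digest profiles as a TSV-ready data frame
#'
#' @param profiles list of [digest()] results.
#' @return data.frame with columns `enzyme`, `amplicon_id`, `cuts`
#'   (comma-joined), `fragments` (comma-joined, map order).
#' @export
profiles_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) data.frame(
    enzyme = p$enzyme, amplicon_id = p$amplicon_id,
    amplicon_length = p$amplicon_length,
    cuts = paste(p$cut_positions, collapse = ","),
    fragments = paste(p$fragment_lengths, collapse = ","),
    stringsAsFactors = FALSE
  )))
}
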