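#' Optimal global alignment of two DNA sequences
#'
#' Needleman-Wunsch alignment under a linear gap scheme. Ties during
#' traceback are broken deterministically (diagonal, then gap in `b`, then
#' gap in `a`), so the same inputs always yield the same alignment. The
#' defaults (+1/-1/-5) suit the near-gapless barcode comparisons this
#' package performs.
#'
#' @param a,b non-empty DNA sequence strings.
#' @param match,mismatch,gap alignment scores (gap is per gapped column).
#'   The gap default is stiff relative to the mismatch cost so that pairs of
#'   compensating gaps cannot masquerade as matches in divergent sequences;
#'   substitution-only comparisons stay gapless.
#' @return object of class `aligned_pair`: list with equal-length
#'   `a_gapped`, `b_gapped` and the optimal `score`. Removing gaps recovers
#'   the inputs exactly; no column is gap/gap.
#' @export
#' @examples
#' global_align("ACGT", "AGT")
global_align <- function(a, b, match = 1, mismatch = -1, gap = -5) {
  for (s in list(a, b)) {
    if (!is.character(s) || length(s) != 1L || nchar(s) == 0L)
      stop("sequences must be non-empty strings", call. = FALSE)
  }
  a <- toupper(a); b <- toupper(b)
  assert_iupac(a, "sequence a"); assert_iupac(b, "sequence b")
  res <- .nw_align(a, b, match, mismatch, gap)
  structure(res, class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("<aligned_pair> %d columns, score %g\n",
              nchar(x$a_gapped), x$score))
  invisible(x)
}

#' DNA percent identity of an aligned pair
#'
#' `100 * identical columns / comparable columns`, where comparable columns
#' are those with no gap in either row (end- and internal-gap columns are
#' excluded from the denominator, mirroring identity over the mutual
#' ungapped window).
#'
#' @param pair an [global_align()] result, or a list with `a_gapped`,
#'   `b_gapped`.
#' @return percent in `[0, 100]`.
#' @export
percent_identity_dna <- function(pair) {
  ca <- seq_chars(pair$a_gapped)
  cb <- seq_chars(pair$b_gapped)
  if (length(ca) != length(cb))
    stop("aligned rows differ in length", call. = FALSE)
  comparable <- ca != "-" & cb != "-"
  if (!any(comparable))
    stop("undefined identity: no comparable columns", call. = FALSE)
  100 * sum(ca[comparable] == cb[comparable]) / sum(comparable)
}

#' Translate DNA using the invertebrate mitochondrial code
#'
#' Uses NCBI translation table 5 by default (ATA = Met, TGA = Trp,
#' AGA/AGG = Ser), the code under which the COI barcode of insects is read.
#' Codons containing any ambiguity code translate to `X`; stops to `*`; a
#' trailing partial codon is dropped.
#'
#' @param seq DNA string.
#' @param frame 0, 1 or 2 (bases skipped before the first codon).
#' @param code NCBI genetic-code id (default `"5"`).
#' @return protein string of `floor((nchar(seq) - frame) / 3)` residues.
#' @export
#' @examples
#' translate_dna("ATA")  # "M" under the invertebrate mitochondrial code
#' translate_dna("TGA")  # "W"
translate_dna <- function(seq, frame = 0L, code = "5") {
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2", call. = FALSE)
  seq <- toupper(seq)
  n <- nchar(seq) - frame
  if (n < 3L) stop("sequence too short to translate in frame ", frame,
                   call. = FALSE)
  gc <- Biostrings::getGeneticCode(code)
  starts <- seq(frame + 1L, frame + 3L * (n %/% 3L), by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Amino-acid percent identity of two equal-length proteins
#'
#' `X` residues are compared literally (an X only matches an X).
#'
#' @param a,b protein strings of equal length.
#' @return percent in `[0, 100]`.
#' @export
percent_identity_aa <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("protein sequences differ in length (", nchar(a), " vs ",
         nchar(b), ")", call. = FALSE)
  if (nchar(a) == 0L) stop("empty protein sequence", call. = FALSE)
  100 * mean(seq_chars(a) == seq_chars(b))
}

#' A-T content of a DNA sequence
#'
#' `100 * (A + T) / (A + C + G + T)`; ambiguity codes are excluded from both
#' numerator and denominator.
#'
#' @param seq DNA string.
#' @return percent in `[0, 100]`.
#' @export
at_content <- function(seq) {
  chars <- assert_iupac(toupper(seq), "sequence")
  concrete <- chars[chars %in% c("A", "C", "G", "T")]
  if (length(concrete) == 0L)
    stop("undefined A-T content: no unambiguous bases", call. = FALSE)
  100 * mean(concrete %in% c("A", "T"))
}

#' Choose the reading frame minimizing internal stop codons
#'
#' The barcode fragment's frame is not annotated, so it is inferred: the
#' frame whose translations accumulate the fewest internal stops across the
#' given sequences wins; ties go to the lowest frame.
#'
#' @param seqs character vector of DNA sequences.
#' @param code NCBI genetic-code id.
#' @return frame in `0:2`.
#' @export
choose_reading_frame <- function(seqs, code = "5") {
  stops <- vapply(0:2, function(f) {
    sum(vapply(seqs, function(s) {
      aa <- translate_dna(s, f, code)
      internal <- substr(aa, 1L, nchar(aa) - 1L)
      lengths(regmatches(internal, gregexpr("*", internal, fixed = TRUE)))
    }, numeric(1)))
  }, numeric(1))
  which.min(stops) - 1L
}

#' Apply synonymous-only substitutions to a coding sequence
#'
#' Replaces codons with same-amino-acid codons (differing in at least one
#' base) at randomly chosen codon positions. Used to emulate the silent
#' substitution structure of the COI barcode: DNA identity drops while
#' amino-acid identity stays at exactly 100.
#'
#' @param seq DNA string read in `frame`.
#' @param n_codons number of codons to substitute.
#' @param frame reading frame (0:2).
#' @param code NCBI genetic-code id.
#' @param seed integer seed.
#' @return mutated DNA string.
#' @export
mutate_synonymous <- function(seq, n_codons, frame = 0L, code = "5",
                              seed = 1L) {
  gc <- Biostrings::getGeneticCode(code)
  n <- (nchar(seq) - frame) %/% 3L
  starts <- frame + 1L + 3L * (seq_len(n) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  # codon -> synonymous alternatives (concrete codons only)
  syn <- lapply(codons, function(cd) {
    if (is.na(gc[cd])) return(character(0))
    setdiff(names(gc)[gc == gc[cd]], cd)
  })
  editable <- which(lengths(syn) > 0L)
  if (length(editable) < n_codons)
    stop("only ", length(editable), " codons have synonymous alternatives",
         call. = FALSE)
  with_local_seed(seed, {
    pick <- sample(editable, n_codons)
    chars <- seq_chars(seq)
    for (i in pick) {
      alt <- sample(syn[[i]], 1L)
      chars[starts[i]:(starts[i] + 2L)] <- seq_chars(alt)
    }
    paste(chars, collapse = "")
  })
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stable per-label RNG stream: hash (seed, label) into [1, 2^31 - 2] so that
# adding a species never perturbs the draws of another.
derive_seed <- function(seed, label) {
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 2147483647
  as.integer(h + 1)
}
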