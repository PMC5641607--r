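# IUPAC nucleotide machinery shared by primer matching, digestion and
# alphabet validation.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_CHARS <- names(IUPAC_SETS)

# complement map covering the full ambiguity alphabet
IUPAC_FROM <- "ACGTRYSWKMBDHVN"
IUPAC_TO   <- "TGCAYRSWMKVHDBN"

#' Reverse complement of an IUPAC nucleotide string
#'
#' Complements every IUPAC code (R to Y, K to M, ...) and reverses the
#' sequence.
#'
#' @param seq single upper-case IUPAC nucleotide string.
#' @return reverse-complemented string.
#' @export
#' @examples
#' revcomp("AGCT")   # palindromic: "AGCT"
#' revcomp("GGTCA")
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  rc <- chartr(IUPAC_FROM, IUPAC_TO, seq)
  paste(rev(strsplit(rc, "", fixed = TRUE)[[1]]), collapse = "")
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

is_iupac_dna <- function(chars) all(chars %in% IUPAC_CHARS)

assert_iupac <- function(seq, what = "sequence") {
  chars <- seq_chars(seq)
  bad <- setdiff(unique(chars), IUPAC_CHARS)
  if (length(bad) > 0)
    stop(what, " contains non-IUPAC characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(chars)
}

# Primer-vs-template matching: TRUE iff the template base's concrete set is a
# subset of the primer base's set; an ambiguous template N never matches
# (conservative -- an unread template base is not evidence of annealing).
build_primer_match_table <- function() {
  m <- matrix(FALSE, 15L, 15L, dimnames = list(IUPAC_CHARS, IUPAC_CHARS))
  for (p in IUPAC_CHARS) for (t in IUPAC_CHARS) {
    if (t == "N") next
    m[p, t] <- all(IUPAC_SETS[[t]] %in% IUPAC_SETS[[p]])
  }
  m
}
PRIMER_MATCH <- build_primer_match_table()

#' Asymmetric IUPAC base matching for primer annealing
#'
#' A primer base matches a template base when every concrete nucleotide the
#' template base could be is covered by the primer base's ambiguity set.
#' The relation is deliberately asymmetric: a degenerate primer base (say R)
#' matches a concrete template A, but a concrete primer A does not match a
#' degenerate template R. A template N never matches.
#'
#' @param primer_base,template_base single IUPAC nucleotide characters.
#' @return logical.
#' @export
#' @examples
#' match_iupac("R", "A")  # TRUE
#' match_iupac("A", "R")  # FALSE
#' match_iupac("N", "N")  # FALSE: template N is never trusted
match_iupac <- function(primer_base, template_base) {
  if (!primer_base %in% IUPAC_CHARS || !template_base %in% IUPAC_CHARS)
    stop("non-IUPAC input: ", primer_base, " / ", template_base, call. = FALSE)
  PRIMER_MATCH[primer_base, template_base]
}

# Recognition-site matching used by digestion: the template base must be a
# concrete A/C/G/T contained in the pattern base's set (template ambiguity
# codes never yield a phantom cut site).
build_site_match_table <- function() {
  m <- matrix(FALSE, 15L, 15L, dimnames = list(IUPAC_CHARS, IUPAC_CHARS))
  for (p in IUPAC_CHARS) for (t in c("A", "C", "G", "T")) {
    m[p, t] <- t %in% IUPAC_SETS[[p]]
  }
  m
}
SITE_MATCH <- build_site_match_table()

# Vectorised scan: start positions (1-based) where `pattern` matches `chars`
# under the site-matching rule. Overlapping occurrences are all reported.
scan_pattern <- function(chars, pattern) {
  m <- nchar(pattern)
  n <- length(chars)
  if (m > n) return(integer(0))
  pat <- seq_chars(pattern)
  ok <- rep(TRUE, n - m + 1L)
  for (k in seq_len(m)) {
    ok <- ok & SITE_MATCH[pat[k], chars[k:(n - m + k)]]
  }
  which(ok)
}
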