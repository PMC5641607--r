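#' Construct a PCR primer
#'
#' @param name primer name.
#' @param sequence IUPAC nucleotide string written 5' to 3'; at least 10 nt.
#' @param role `"forward"` or `"reverse"`.
#' @return object of class `primer`.
#' @export
primer <- function(name, sequence, role = c("forward", "reverse")) {
  role <- match.arg(role)
  sequence <- toupper(sequence)
  assert_iupac(sequence, paste0("primer ", name))
  if (nchar(sequence) < 10L)
    stop("primer ", name, " shorter than 10 nt", call. = FALSE)
  structure(list(name = name, sequence = sequence, role = role),
            class = "primer")
}

#' The barcode primer pair
#'
#' The universal COI barcode primers LCO1490 (forward, 25 nt) and HCO2198
#' (reverse, 27 nt) as used for the 710 bp cockroach amplicon. Note: this
#' HCO2198 string carries one extra leading T relative to the canonical
#' 26 nt Folmer HCO2198; the published assay string is kept verbatim and not
#' "corrected".
#'
#' @return list with elements `forward` and `reverse`, both [primer()]s.
#' @export
folmer_primers <- function() {
  list(
    forward = primer("LCO1490", "GGTCAACAAATCATAAAGATATTGG", "forward"),
    reverse = primer("HCO2198", "TTAAACTTCAGGGTGACCAAAAAATCA", "reverse")
  )
}

#' Locate primer annealing sites on a template
#'
#' Scans both strands for positions where at most `max_mismatch` primer bases
#' fail [match_iupac()]; the primer's 3'-terminal base must always match
#' exactly (polymerase-extension realism). On the minus strand the reverse
#' complement of the primer is matched against the forward strand, so `start`
#' and `end` are always forward-strand coordinates.
#'
#' @param template a [seq_record()] (DNA) or plain sequence string.
#' @param prm a [primer()].
#' @param max_mismatch mismatch budget (default 0).
#' @return data.frame with columns `template_id`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`), `mismatches`, sorted by `start`.
#' @export
find_primer_sites <- function(template, prm, max_mismatch = 0L) {
  rec <- as_seq_record(template)
  if (rec$moltype != "dna") stop("template must be DNA", call. = FALSE)
  chars <- seq_chars(rec$residues)
  hits_one <- function(primer_seq, strand) {
    pat <- seq_chars(primer_seq)
    m <- length(pat); n <- length(chars)
    if (m > n) return(NULL)
    mism <- rep(0L, n - m + 1L)
    for (k in seq_len(m)) {
      mism <- mism + !PRIMER_MATCH[pat[k], chars[k:(n - m + k)]]
    }
    # exact 3'-terminal match: last primer base on +, first pattern base on -
    anchor <- if (strand == "+") m else 1L
    exact <- PRIMER_MATCH[pat[anchor], chars[anchor:(n - m + anchor)]]
    keep <- which(mism <= max_mismatch & exact)
    if (length(keep) == 0L) return(NULL)
    data.frame(template_id = rec$id, start = keep - 1L,
               end = keep - 1L + m, strand = strand,
               mismatches = mism[keep], stringsAsFactors = FALSE)
  }
  out <- rbind(hits_one(prm$sequence, "+"),
               hits_one(revcomp(prm$sequence), "-"))
  if (is.null(out))
    return(data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  out[order(out$start, out$strand), , drop = FALSE]
}

as_seq_record <- function(x, id = "seq") {
  if (inherits(x, "seq_record")) return(x)
  if (is.character(x) && length(x) == 1L) return(seq_record(id, x))
  stop("expected a seq_record or a sequence string", call. = FALSE)
}

#' Extract the PCR amplicon delimited by a primer pair
#'
#' Finds the unique pairing of a forward-primer site upstream of a
#' reverse-primer site and excises the product spanning both primer
#' footprints (forward-primer 5' end through reverse-primer 5' end). If the
#' pair anneals in the opposite orientation the product is reverse
#' complemented, so the returned amplicon always reads from the forward
#' primer (`normalize = TRUE`); restriction cut positions are therefore
#' comparable across templates.
#'
#' @param template a [seq_record()] or sequence string.
#' @param forward,reverse [primer()]s.
#' @param max_mismatch mismatch budget per primer (default 0).
#' @param normalize orient the product on the forward-primer strand.
#' @return object of class `amplicon` with fields `template_id`, `start`,
#'   `end` (0-based half-open on the template's forward strand), `sequence`,
#'   `length`.
#' @export
#' @examples
#' p <- folmer_primers()
#' tmpl <- paste0("GATTACA", p$forward$sequence,
#'                strrep("ACGTTG", 20), revcomp(p$reverse$sequence), "TTGACA")
#' extract_amplicon(tmpl, p$forward, p$reverse)
extract_amplicon <- function(template, forward, reverse, max_mismatch = 0L,
                             normalize = TRUE) {
  rec <- as_seq_record(template)
  fhits <- find_primer_sites(rec, forward, max_mismatch)
  rhits <- find_primer_sites(rec, reverse, max_mismatch)
  # plus-orientation product: forward on +, reverse on -, forward upstream
  fwd_plus <- fhits[fhits$strand == "+", , drop = FALSE]
  rev_minus <- rhits[rhits$strand == "-", , drop = FALSE]
  cand <- list()
  for (i in seq_len(nrow(fwd_plus))) for (j in seq_len(nrow(rev_minus))) {
    if (fwd_plus$end[i] <= rev_minus$start[j])
      cand[[length(cand) + 1L]] <- list(start = fwd_plus$start[i],
                                        end = rev_minus$end[j],
                                        orient = "+")
  }
  # minus-orientation product: reverse on +, forward on -, reverse upstream
  rev_plus <- rhits[rhits$strand == "+", , drop = FALSE]
  fwd_minus <- fhits[fhits$strand == "-", , drop = FALSE]
  for (i in seq_len(nrow(rev_plus))) for (j in seq_len(nrow(fwd_minus))) {
    if (rev_plus$end[i] <= fwd_minus$start[j])
      cand[[length(cand) + 1L]] <- list(start = rev_plus$start[i],
                                        end = fwd_minus$end[j],
                                        orient = "-")
  }
  if (length(cand) == 0L)
    stop("no amplification: primer pair does not delimit a product on '",
         rec$id, "'", call. = FALSE)
  if (length(cand) > 1L) {
    spans <- vapply(cand, function(cc)
      sprintf("%d-%d(%s)", cc$start + 1L, cc$end, cc$orient), character(1))
    stop("ambiguous amplification on '", rec$id, "': ", length(cand),
         " candidate products [", paste(spans, collapse = ", "), "]",
         call. = FALSE)
  }
  cc <- cand[[1]]
  sq <- substr(rec$residues, cc$start + 1L, cc$end)
  if (normalize && cc$orient == "-") sq <- revcomp(sq)
  structure(list(template_id = rec$id, start = cc$start, end = cc$end,
                 sequence = sq, length = cc$end - cc$start),
            class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon> %s:%d-%d (%d bp)\n", x$template_id,
              x$start + 1L, x$end, x$length))
  invisible(x)
}

#' Amplify every species of a panel
#'
#' Applies [extract_amplicon()] to the representative template of each
#' species. A species whose template yields no product is skipped with a
#' warning rather than aborting the run.
#'
#' @param panel a [species_panel()] of templates.
#' @param primers list with `forward` and `reverse` [primer()]s.
#' @param max_mismatch mismatch budget.
#' @return named list of `amplicon` objects.
#' @export
amplify_panel <- function(panel, primers = folmer_primers(),
                          max_mismatch = 0L) {
  stopifnot(inherits(panel, "species_panel"))
  out <- list()
  for (sp in names(panel)) {
    amp <- tryCatch(
      extract_amplicon(panel[[sp]][[1]], primers$forward, primers$reverse,
                       max_mismatch),
      error = function(e) {
        warning("species '", sp, "' skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(amp)) out[[sp]] <- amp
  }
  out
}
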