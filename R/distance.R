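# Published reference values for the five-species cockroach panel: COI
# barcode similarity rates, AluI restriction maps, and the study's printed
# fragment profiles. These are the inputs the diagnostic assay was designed
# from and the defaults of the synthetic generator.

REF_SPECIES <- c("American", "Oriental", "Turkestan", "German", "Brown-banded")

REF_BINOMIALS <- c(
  American = "Periplaneta americana", Oriental = "Blatta orientalis",
  Turkestan = "Shelfordella lateralis", German = "Blattella germanica",
  `Brown-banded` = "Supella longipalpa"
)

.ref_matrix <- function(vals) {
  m <- matrix(100, 5, 5, dimnames = list(REF_SPECIES, REF_SPECIES))
  k <- 1L
  for (i in 1:4) for (j in (i + 1):5) {
    m[i, j] <- m[j, i] <- vals[k]
    k <- k + 1L
  }
  m
}

#' Published COI similarity matrix of the five-species panel
#'
#' Percent identity among the barcode sequences of American, Oriental,
#' Turkestan, German and Brown-banded cockroaches, as reported for the
#' study panel: DNA-level values over the 648 bp shared window, amino-acid
#' values over the translated window.
#'
#' @param level `"dna"` or `"aa"`.
#' @return symmetric 5x5 percent matrix with 100 on the diagonal, ordered
#'   American, Oriental, Turkestan, German, Brown-banded.
#' @export
#' @examples
#' 100 - reference_similarity("dna")  # divergence; max 22.26, min 11.57
reference_similarity <- function(level = c("dna", "aa")) {
  level <- match.arg(level)
  # pair order: Am-Or Am-Tu Am-Ge Am-Bb Or-Tu Or-Ge Or-Bb Tu-Ge Tu-Bb Ge-Bb
  vals <- if (level == "dna") {
    c(88.43, 87.65, 82.10, 77.74, 88.27, 83.49, 80.53, 82.56, 80.53, 79.44)
  } else {
    c(98.57, 100.00, 96.19, 92.38, 98.57, 95.71, 91.90, 96.19, 92.38, 92.86)
  }
  m <- .ref_matrix(vals)
  attr(m, "metric") <- paste0(level, "_identity")
  m
}

#' Published AluI cut maps of the five 710 bp amplicons
#'
#' Cut positions as 1-based prefix lengths on the forward-oriented amplicon
#' (the "cuts at 251 and 455" idiom). The German and Brown-banded maps are
#' the running sums of their 8-band fragment profiles.
#'
#' @return named list of integer vectors.
#' @export
reference_alui_maps <- function() {
  list(
    American = c(167L, 251L, 392L, 612L),
    Oriental = c(251L, 275L),
    Turkestan = c(251L, 455L),
    German = c(296L, 311L, 335L, 368L, 392L, 612L, 662L),
    `Brown-banded` = c(65L, 119L, 158L, 296L, 335L, 467L, 554L)
  )
}

#' Published AluI fragment profiles (map order)
#' @return named list of integer vectors, each summing to 710.
#' @export
reference_fragments <- function() {
  list(
    American = c(167L, 84L, 141L, 220L, 98L),
    Oriental = c(251L, 24L, 435L),
    Turkestan = c(251L, 204L, 255L),
    German = c(296L, 15L, 24L, 33L, 24L, 220L, 50L, 48L),
    `Brown-banded` = c(65L, 54L, 39L, 138L, 39L, 132L, 87L, 156L)
  )
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Pairwise similarity matrix of a species panel
#'
#' Aligns every species pair globally, then measures percent identity at the
#' DNA level or, after dropping gap columns and translating the mutual
#' ungapped window, at the amino-acid level. The reading frame is chosen
#' once for the whole panel by [choose_reading_frame()]. Values are rounded
#' to 2 decimals (half-up).
#'
#' @param panel a [species_panel()], or a named character vector / named
#'   list of sequences (one representative per species).
#' @param level `"dna"` or `"aa"`.
#' @param representative `"first"` (default) compares one representative per
#'   species; `"all"` averages identity over all cross-species record pairs.
#' @param match,mismatch,gap alignment scores, see [global_align()].
#' @param code genetic-code id for `level = "aa"`.
#' @return symmetric percent matrix with `metric` attribute
#'   (`dna_identity` / `aa_identity`), diagonal 100.
#' @export
similarity_matrix <- function(panel, level = c("dna", "aa"),
                              representative = c("first", "all"),
                              match = 1, mismatch = -1, gap = -5,
                              code = "5") {
  level <- match.arg(level)
  representative <- match.arg(representative)
  seqs_by_sp <- panel_sequences(panel, representative)
  labs <- names(seqs_by_sp)
  if (length(labs) < 2L) stop("need at least 2 species", call. = FALSE)
  frame <- if (level == "aa")
    choose_reading_frame(unlist(seqs_by_sp, use.names = FALSE), code) else 0L
  pair_value <- function(a, b) {
    pr <- global_align(a, b, match, mismatch, gap)
    if (level == "dna") return(percent_identity_dna(pr))
    w <- degap_pair(pr)
    percent_identity_aa(translate_dna(w[1], frame, code),
                        translate_dna(w[2], frame, code))
  }
  n <- length(labs)
  m <- matrix(100, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    vals <- c()
    for (a in seqs_by_sp[[i]]) for (b in seqs_by_sp[[j]])
      vals <- c(vals, pair_value(a, b))
    m[i, j] <- m[j, i] <- round_half_up(mean(vals), 2)
  }
  attr(m, "metric") <- paste0(level, "_identity")
  m
}

panel_sequences <- function(panel, representative = "first") {
  if (inherits(panel, "species_panel")) {
    if (representative == "first") {
      lapply(unclass(panel), function(r) r[[1]]$residues)
    } else {
      lapply(unclass(panel), function(r)
        vapply(r, function(x) x$residues, character(1)))
    }
  } else if (is.character(panel) && !is.null(names(panel))) {
    as.list(panel)
  } else if (is.list(panel) && !is.null(names(panel))) {
    lapply(panel, function(x) {
      if (inherits(x, "amplicon")) x$sequence
      else if (inherits(x, "seq_record")) x$residues
      else as.character(x)
    })
  } else stop("panel must be a species_panel or a named set of sequences",
              call. = FALSE)
}

# mutual ungapped window of an aligned pair
degap_pair <- function(pair) {
  ca <- seq_chars(pair$a_gapped)
  cb <- seq_chars(pair$b_gapped)
  keep <- ca != "-" & cb != "-"
  c(paste(ca[keep], collapse = ""), paste(cb[keep], collapse = ""))
}

#' Divergence matrix (100 - similarity)
#'
#' @param sim a similarity matrix as from [similarity_matrix()] or
#'   [reference_similarity()].
#' @return matrix of percent divergences, zero diagonal, `metric` attribute
#'   `dna_divergence`.
#' @export
divergence_matrix <- function(sim) {
  d <- 100 - sim
  diag(d) <- 0
  attr(d, "metric") <- "dna_divergence"
  d
}

#' Divergence time under a strict molecular clock
#'
#' `time = divergence / rate`. The conventional insect mtDNA clock of 2%
#' pairwise divergence per million years is the default.
#'
#' @param divergence percent pairwise divergence (>= 0).
#' @param rate percent divergence per million years (> 0).
#' @return million years.
#' @export
#' @examples
#' divergence_time(22.26)  # 11.13 MY
divergence_time <- function(divergence, rate = 2.0) {
  if (any(rate <= 0)) stop("clock rate must be positive", call. = FALSE)
  if (any(divergence < 0)) stop("divergence must be >= 0", call. = FALSE)
  divergence / rate
}

#' Intra-species polymorphism of one species in a panel
#'
#' Pairwise p-distances among all records of a species. Both the mean and
#' the maximum are reported because a single "intra-species divergence"
#' figure is ambiguous between the two conventions.
#'
#' @param panel a [species_panel()].
#' @param species species label.
#' @return list with `n_records`, `mean_pct` and `max_pct` (both `NA` when
#'   the species has fewer than 2 records).
#' @export
intra_species_divergence <- function(panel, species) {
  stopifnot(inherits(panel, "species_panel"))
  if (!species %in% names(panel))
    stop("unknown species: ", species, call. = FALSE)
  seqs <- vapply(panel[[species]], function(x) x$residues, character(1))
  if (length(seqs) < 2L)
    return(list(n_records = length(seqs), mean_pct = NA_real_,
                max_pct = NA_real_))
  pd <- c()
  for (i in seq_len(length(seqs) - 1L)) for (j in (i + 1L):length(seqs)) {
    pr <- global_align(seqs[i], seqs[j])
    pd <- c(pd, 100 - percent_identity_dna(pr))
  }
  list(n_records = length(seqs),
       mean_pct = round_half_up(mean(pd), 2),
       max_pct = round_half_up(max(pd), 2))
}

#' Combined similarity layout (DNA below, amino acid above the diagonal)
#'
#' Renders the classic barcode-study table: DNA percent identities in the
#' lower triangle, amino-acid identities in the upper triangle, `***` on the
#' diagonal.
#'
#' @param dna,aa similarity matrices over the same taxa.
#' @return character matrix ready for printing or TSV export.
#' @export
format_similarity_layout <- function(dna, aa) {
  stopifnot(identical(dimnames(dna), dimnames(aa)))
  n <- nrow(dna)
  out <- matrix("***", n, n, dimnames = dimnames(dna))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) out[i, j] <- sprintf("%.2f", aa[i, j])
    if (i > j) out[i, j] <- sprintf("%.2f", dna[i, j])
  }
  out
}

#' Write a taxa-by-taxa matrix as TSV
#'
#' @param m matrix with dimnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
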