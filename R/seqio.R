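#' Construct a sequence record
#'
#' The basic unit carried through the pipeline: an identified nucleotide (or
#' protein) sequence with free-text metadata, mirroring one FASTA entry.
#'
#' @param id unique identifier; no whitespace allowed.
#' @param residues sequence string; upper-cased on construction. For
#'   `moltype = "dna"` every character must be an IUPAC nucleotide code
#'   (`ACGTRYSWKMBDHVN`); `U` is normalized to `T`.
#' @param description free text (species name, origin, ...).
#' @param moltype `"dna"` or `"protein"`.
#' @return object of class `seq_record`.
#' @export
#' @examples
#' seq_record("x", "acgu")  # residues become "ACGT"
seq_record <- function(id, residues, description = "", moltype = "dna") {
  moltype <- match.arg(moltype, c("dna", "protein"))
  if (!is.character(id) || length(id) != 1L || nchar(id) == 0L)
    stop("id must be a non-empty string", call. = FALSE)
  if (grepl("[[:space:]]", id))
    stop("id must not contain whitespace: ", id, call. = FALSE)
  if (!is.character(residues) || length(residues) != 1L || nchar(residues) == 0L)
    stop("residues must be non-empty", call. = FALSE)
  residues <- toupper(residues)
  if (moltype == "dna") {
    residues <- chartr("U", "T", residues)
    assert_iupac(residues, paste0("record '", id, "'"))
  }
  structure(
    list(id = id, description = description, residues = residues,
         moltype = moltype),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%s, %d %s)\n", x$id, x$moltype,
              nchar(x$residues),
              if (x$moltype == "dna") "nt" else "aa"))
  if (nzchar(x$description)) cat("  ", x$description, "\n", sep = "")
  invisible(x)
}

#' Group sequence records into a species panel
#'
#' @param entries named list: species label -> list of [seq_record()]s. The
#'   first record of each species is its representative in matrix-building
#'   unless stated otherwise.
#' @return object of class `species_panel`.
#' @export
species_panel <- function(entries) {
  if (!is.list(entries) || is.null(names(entries)) ||
      any(!nzchar(names(entries))))
    stop("entries must be a fully named list", call. = FALSE)
  if (anyDuplicated(names(entries)))
    stop("species labels must be unique", call. = FALSE)
  for (sp in names(entries)) {
    recs <- entries[[sp]]
    if (!is.list(recs) || length(recs) == 0L)
      stop("species '", sp, "' has no records", call. = FALSE)
    ok <- vapply(recs, inherits, logical(1), what = "seq_record")
    if (!all(ok)) stop("species '", sp, "' holds non-seq_record entries",
                       call. = FALSE)
  }
  structure(entries, class = "species_panel")
}

#' @export
print.species_panel <- function(x, ...) {
  cat(sprintf("<species_panel> %d species\n", length(x)))
  for (sp in names(x))
    cat(sprintf("  %-14s %d record(s), %d nt\n", sp, length(x[[sp]]),
                nchar(x[[sp]][[1]]$residues)))
  invisible(x)
}

#' Representative sequence of each species (first record)
#'
#' @param panel a [species_panel()].
#' @return named character vector of residues.
#' @export
panel_representatives <- function(panel) {
  stopifnot(inherits(panel, "species_panel"))
  vapply(panel, function(recs) recs[[1]]$residues, character(1))
}

#' Read a FASTA file
#'
#' Dialect: the first whitespace-delimited token after `>` is the id, the
#' remainder the description; blank lines between records are tolerated;
#' lower-case and `U` are normalized on read. Malformed input raises a parse
#' error naming the offending line.
#'
#' @param path FASTA file.
#' @param moltype passed to [seq_record()].
#' @return list of [seq_record()]s in file order.
#' @export
read_fasta <- function(path, moltype = "dna") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  records <- list()
  id <- NULL; desc <- ""; chunks <- character(0); header_line <- 0L
  flush <- function() {
    if (is.null(id)) return()
    residues <- paste(chunks, collapse = "")
    if (nchar(residues) == 0L)
      stop("parse error at line ", header_line, ": record '", id,
           "' has an empty sequence", call. = FALSE)
    records[[length(records) + 1L]] <<-
      seq_record(id, residues, desc, moltype)
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (nchar(line) == 0L) next
    if (startsWith(line, ">")) {
      flush()
      header <- sub("^>", "", line)
      if (nchar(trimws(header)) == 0L)
        stop("parse error at line ", i, ": empty FASTA header", call. = FALSE)
      toks <- strsplit(trimws(header), "[[:space:]]+")[[1]]
      id <- toks[1]
      desc <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else ""
      chunks <- character(0)
      header_line <- i
    } else {
      if (is.null(id))
        stop("parse error at line ", i,
             ": sequence data before any header", call. = FALSE)
      candidate <- chartr("U", "T", toupper(line))
      if (moltype == "dna" && !is_iupac_dna(seq_chars(candidate)))
        stop("parse error at line ", i, ": illegal character in sequence",
             call. = FALSE)
      chunks <- c(chunks, candidate)
    }
  }
  flush()
  if (length(records) == 0L) stop("no records in ", path, call. = FALSE)
  records
}

#' Write records to a FASTA file
#'
#' @param records non-empty list of [seq_record()]s.
#' @param path output file.
#' @param line_width wrap width for sequence lines.
#' @return `path`, invisibly. `read_fasta(write_fasta(r))` reproduces ids and
#'   residues exactly.
#' @export
write_fasta <- function(records, path, line_width = 70L) {
  if (length(records) == 0L) stop("records must be non-empty", call. = FALSE)
  if (!is.numeric(line_width) || line_width < 1L)
    stop("line_width must be a positive integer", call. = FALSE)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  for (rec in records) {
    header <- if (nzchar(rec$description))
      paste0(">", rec$id, " ", rec$description) else paste0(">", rec$id)
    writeLines(header, con)
    n <- nchar(rec$residues)
    starts <- seq(1L, n, by = line_width)
    writeLines(substring(rec$residues, starts,
                         pmin(starts + line_width - 1L, n)), con)
  }
  invisible(path)
}

#' Construct a restriction enzyme
#'
#' @param name enzyme name.
#' @param recognition IUPAC recognition sequence (e.g. `"AGCT"` for AluI).
#' @param cut_offset bases 5' of the cut within the recognition site on the
#'   top strand; must lie in `[0, nchar(recognition)]`. AluI is
#'   `("AGCT", 2)`: blunt, palindromic, cutting AG^CT.
#' @return object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  assert_iupac(recognition, paste0("recognition site of ", name))
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(recognition))
    stop("cut_offset of ", name, " out of range [0, ",
         nchar(recognition), "]", call. = FALSE)
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  site <- paste0(substr(x$recognition, 1, x$cut_offset), "^",
                 substr(x$recognition, x$cut_offset + 1,
                        nchar(x$recognition)))
  cat(sprintf("<restriction_enzyme> %s  %s\n", x$name, site))
  invisible(x)
}

#' AluI (AGCT, blunt cut after position 2)
#' @return a [restriction_enzyme()].
#' @export
alui <- function() restriction_enzyme("AluI", "AGCT", 2L)

#' Read a tab-separated enzyme library
#'
#' Format: header row `name<TAB>recognition<TAB>cut_offset`; lines starting
#' with `#` are ignored.
#'
#' @param path TSV file.
#' @return list of [restriction_enzyme()]s.
#' @export
read_enzyme_library <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "recognition", "cut_offset")
  if (!all(need %in% names(tab)))
    stop("enzyme library must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L) stop("enzyme library is empty", call. = FALSE)
  lapply(seq_len(nrow(tab)), function(i)
    restriction_enzyme(tab$name[i], tab$recognition[i], tab$cut_offset[i]))
}

#' Bundled enzyme library of common blunt/sticky cutters
#' @return list of [restriction_enzyme()]s read from the package's
#'   `extdata/enzymes.tsv`.
#' @export
default_enzyme_library <- function() {
  read_enzyme_library(system.file("extdata", "enzymes.tsv",
                                  package = "barcodeRFLP", mustWork = TRUE))
}
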