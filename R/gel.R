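#' Agarose-gel visibility model
#'
#' Encodes what a reader can actually resolve on a stained agarose gel:
#' bands below `min_visible` nt are treated as invisible, and two bands
#' co-migrate (appear as one) when `|a - b| <= comigration_tol * max(a, b)`.
#' The defaults reflect routine 2-2.5% agarose practice against a 100 bp
#' ladder: sub-100 bp bands are not reliably visible and bands within ~4%
#' of each other are hard to call apart.
#'
#' @param min_visible minimum visible band size in nt (default 100).
#' @param comigration_tol relative co-migration tolerance in `[0, 1)`
#'   (default 0.04).
#' @param ladder marker rung sizes in nt (default 100 bp ladder to 1 kb).
#' @return object of class `gel_model`.
#' @export
gel_model <- function(min_visible = 100, comigration_tol = 0.04,
                      ladder = seq(100L, 1000L, by = 100L)) {
  if (min_visible < 0) stop("min_visible must be >= 0", call. = FALSE)
  if (comigration_tol < 0 || comigration_tol >= 1)
    stop("comigration_tol must be in [0, 1)", call. = FALSE)
  structure(list(min_visible = min_visible,
                 comigration_tol = comigration_tol,
                 ladder = sort(as.integer(ladder))),
            class = "gel_model")
}

comigrate <- function(a, b, gel) abs(a - b) <= gel$comigration_tol * pmax(a, b)

#' Visible band signature of a digest on a gel
#'
#' Sorts the fragment sizes descending, drops bands below the visibility
#' threshold, then greedily merges runs of co-migrating bands left-to-right:
#' the merged band size is the rounded (half-up) mean of the run and is
#' re-checked against the next band. The result is what a human would score
#' from the lane.
#'
#' @param profile a [digest()] result (or a numeric vector of fragment
#'   sizes).
#' @param gel a [gel_model()].
#' @param label lane label; defaults to the profile's amplicon id.
#' @return object of class `gel_signature`: `label` plus `bands`, a
#'   descending vector in which no band is below threshold and no two bands
#'   co-migrate. Possibly empty.
#' @export
#' @examples
#' visible_bands(c(251, 204, 255), gel_model())  # 253, 204
visible_bands <- function(profile, gel = gel_model(), label = NULL) {
  stopifnot(inherits(gel, "gel_model"))
  if (inherits(profile, "digest_profile")) {
    sizes <- profile$fragment_lengths
    if (is.null(label)) label <- profile$amplicon_id
  } else {
    sizes <- as.numeric(profile)
    if (is.null(label)) label <- "lane"
  }
  sizes <- sort(sizes[sizes >= gel$min_visible], decreasing = TRUE)
  bands <- numeric(0)
  if (length(sizes) > 0) {
    run <- sizes[1]
    cur <- sizes[1]
    for (b in sizes[-1]) {
      if (gel$comigration_tol > 0 && comigrate(cur, b, gel)) {
        run <- c(run, b)
        cur <- round_half_up(mean(run))
      } else {
        bands <- c(bands, cur)
        run <- b
        cur <- b
      }
    }
    bands <- c(bands, cur)
  }
  structure(list(label = label, bands = bands), class = "gel_signature")
}

#' @export
print.gel_signature <- function(x, ...) {
  cat(sprintf("<gel_signature> %s: %s\n", x$label,
              if (length(x$bands)) paste(x$bands, collapse = ", ")
              else "(no visible bands)"))
  invisible(x)
}

#' Can two gel signatures be told apart?
#'
#' FALSE iff the two signatures have the same number of visible bands and
#' every positional pair of bands co-migrates under the gel tolerance;
#' TRUE otherwise. This compares what is read off the gel, not the raw
#' fragment lists.
#'
#' @param a,b [visible_bands()] signatures from the same gel model.
#' @param gel the shared [gel_model()].
#' @return logical; symmetric in `a` and `b`.
#' @export
profiles_distinguishable <- function(a, b, gel = gel_model()) {
  stopifnot(inherits(a, "gel_signature"), inherits(b, "gel_signature"))
  if (length(a$bands) != length(b$bands)) return(TRUE)
  if (length(a$bands) == 0L) return(FALSE)
  !all(comigrate(a$bands, b$bands, gel))
}

#' Screen an enzyme library for single-enzyme species diagnostics
#'
#' For every enzyme: digest each species' amplicon, derive gel signatures,
#' and count the species pairs whose signatures are distinguishable. An
#' enzyme distinguishing all pairs is flagged fully diagnostic. Results are
#' ranked by pairs distinguished (descending), then total visible band count
#' (ascending; simpler gels are easier to read), then name.
#'
#' @param amplicons named list/vector: species label -> amplicon (an
#'   `amplicon`, [seq_record()] or DNA string). At least 2 species.
#' @param library list of [restriction_enzyme()]s.
#' @param gel a [gel_model()].
#' @return data.frame with one row per enzyme: `enzyme`,
#'   `pairs_distinguished`, `pairs_total`, `fully_diagnostic`,
#'   `total_visible_bands`, `signatures` (semicolon-joined
#'   `species:b1|b2|...`). Attribute `signatures` holds the raw signature
#'   lists.
#' @export
screen_enzymes <- function(amplicons, library, gel = gel_model()) {
  if (length(library) == 0L) stop("enzyme library is empty", call. = FALSE)
  seqs <- panel_sequences(as.list(amplicons))
  species <- names(seqs)
  if (length(species) < 2L) stop("need at least 2 species", call. = FALSE)
  pairs <- combn(species, 2, simplify = FALSE)
  rows <- list(); sigs_all <- list()
  for (enz in library) {
    sigs <- lapply(species, function(sp)
      visible_bands(digest(seqs[[sp]], enz), gel, label = sp))
    names(sigs) <- species
    ok <- vapply(pairs, function(p)
      profiles_distinguishable(sigs[[p[1]]], sigs[[p[2]]], gel), logical(1))
    rows[[enz$name]] <- data.frame(
      enzyme = enz$name,
      pairs_distinguished = sum(ok),
      pairs_total = length(pairs),
      fully_diagnostic = all(ok),
      total_visible_bands = sum(vapply(sigs, function(s)
        length(s$bands), numeric(1))),
      signatures = paste(vapply(species, function(sp)
        paste0(sp, ":", paste(sigs[[sp]]$bands, collapse = "|")),
        character(1)), collapse = ";"),
      stringsAsFactors = FALSE
    )
    sigs_all[[enz$name]] <- sigs
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$pairs_distinguished, out$total_visible_bands,
                   out$enzyme), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "signatures") <- sigs_all
  out
}

#' Render signatures as a text virtual gel
#'
#' Fixed-width lane diagram: a ladder lane followed by one lane per
#' signature, with band rows placed by log-size interpolation against the
#' ladder. Deterministic output suitable for snapshot comparison.
#'
#' @param signatures list of [visible_bands()] signatures.
#' @param gel a [gel_model()] (supplies the ladder).
#' @param height number of text rows for the separation range.
#' @return character scalar (multi-line). Bands above the top ladder rung
#'   are drawn on the first row with a warning.
#' @export
render_gel <- function(signatures, gel = gel_model(), height = 20L) {
  stopifnot(length(signatures) >= 1L)
  ladder <- gel$ladder
  lmin <- min(ladder); lmax <- max(ladder)
  size_to_row <- function(s) {
    r <- 1L + round((log10(lmax) - log10(s)) /
                      (log10(lmax) - log10(lmin)) * (height - 1L))
    as.integer(pmin(pmax(r, 1L), height))
  }
  labels <- vapply(signatures, function(s) s$label, character(1))
  lane_w <- max(8L, nchar(labels) + 2L)
  pad <- function(x) formatC(x, width = lane_w)
  grid <- matrix(strrep(" ", lane_w), nrow = height,
                 ncol = length(signatures) + 1L)
  for (s in ladder) grid[size_to_row(s), 1L] <- pad(sprintf("%d -", s))
  overflow <- FALSE
  for (k in seq_along(signatures)) {
    for (b in signatures[[k]]$bands) {
      if (b > lmax) overflow <- TRUE
      grid[size_to_row(b), k + 1L] <- pad(strrep("=", min(6L, lane_w - 2L)))
    }
  }
  if (overflow)
    warning("band(s) larger than the top ladder rung drawn above the ladder",
            call. = FALSE)
  header <- paste(c(pad("ladder"), vapply(labels, pad, character(1))),
                  collapse = "")
  body <- apply(grid, 1, paste, collapse = "")
  paste(c(header, body), collapse = "\n")
}
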