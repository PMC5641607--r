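# Synthetic species panels with known structure: target pairwise
# divergences, A-T content, planted restriction maps, primer-flanked
# templates and optional intra-species variants. The generator is the
# package's test bed: every downstream claim (similarity recovery, RFLP
# diagnosability, tree structure) is checked against panels whose truth is
# known by construction.

#' Configuration of a synthetic species panel
#'
#' Defaults reproduce the published five-species cockroach study design: a
#' 710 bp amplicon bounded by the LCO1490/HCO2198 primer footprints, the
#' published pairwise DNA divergences, 65.7% A-T content, the five published
#' AluI cut maps, 2.62% intra-species polymorphism for the American label
#' and none elsewhere, and EcoRI as a guaranteed-absent control enzyme.
#'
#' @param species character vector of species labels.
#' @param amplicon_length amplicon size in nt.
#' @param divergence_targets symmetric percent matrix (zero diagonal) over
#'   `species`.
#' @param at_target mean A-T content of the panel, percent.
#' @param planted_maps named list: species -> ascending cut positions
#'   (1-based prefix lengths) strictly inside the amplicon.
#' @param enzyme the [restriction_enzyme()] whose maps are planted.
#' @param control_enzymes enzymes guaranteed to have zero sites anywhere in
#'   the panel (negative controls for screening).
#' @param primers forward/reverse [primer()] pair forming the amplicon ends.
#' @param n_variants_per_species records per species (scalar or named).
#' @param intra_divergence percent divergence of each extra variant from its
#'   species representative (scalar or named; default 2.62 for "American",
#'   0 otherwise).
#' @param flank5,flank3 template flank lengths outside the amplicon.
#' @param seed master seed; all randomness derives from it.
#' @return object of class `panel_config`.
#' @export
panel_config <- function(species = REF_SPECIES,
                         amplicon_length = 710L,
                         divergence_targets =
                           divergence_matrix(reference_similarity("dna")),
                         at_target = 65.7,
                         planted_maps = reference_alui_maps(),
                         enzyme = alui(),
                         control_enzymes =
                           list(restriction_enzyme("EcoRI", "GAATTC", 1L)),
                         primers = folmer_primers(),
                         n_variants_per_species = 1L,
                         intra_divergence = NULL,
                         flank5 = 30L, flank3 = 40L,
                         seed = 1L) {
  if (is.null(intra_divergence)) {
    intra_divergence <- setNames(rep(0, length(species)), species)
    if ("American" %in% species) intra_divergence["American"] <- 2.62
  }
  intra_divergence <- expand_by_species(intra_divergence, species)
  n_variants_per_species <-
    expand_by_species(n_variants_per_species, species)
  if (!all(species %in% rownames(divergence_targets)))
    stop("divergence_targets must cover all species", call. = FALSE)
  divergence_targets <- divergence_targets[species, species, drop = FALSE]
  if (max(abs(divergence_targets - t(divergence_targets))) > 1e-8 ||
      any(diag(divergence_targets) != 0))
    stop("divergence_targets must be symmetric with zero diagonal",
         call. = FALSE)
  planted_maps <- planted_maps[intersect(names(planted_maps), species)]
  structure(list(
    species = species, amplicon_length = as.integer(amplicon_length),
    divergence_targets = divergence_targets, at_target = at_target,
    planted_maps = planted_maps, enzyme = enzyme,
    control_enzymes = control_enzymes, primers = primers,
    n_variants_per_species = n_variants_per_species,
    intra_divergence = intra_divergence,
    flank5 = as.integer(flank5), flank3 = as.integer(flank3),
    seed = as.integer(seed)
  ), class = "panel_config")
}

expand_by_species <- function(x, species) {
  if (is.null(names(x))) {
    if (length(x) == 1L) return(setNames(rep(x, length(species)), species))
    if (length(x) == length(species)) return(setNames(x, species))
    stop("per-species parameter has wrong length", call. = FALSE)
  }
  out <- setNames(rep(if (is.numeric(x)) 0 else x[0], length(species)),
                  species)
  out[names(x)[names(x) %in% species]] <- x[names(x) %in% species]
  out
}

# all recognition patterns (both strands, deduplicated) of a set of enzymes
enzyme_patterns <- function(enzymes) {
  pats <- unlist(lapply(enzymes, function(e)
    unique(c(e$recognition, revcomp(e$recognition)))))
  unique(pats)
}

# start positions (1-based) of any pattern occurrence in chars
pattern_occurrences <- function(chars, patterns) {
  out <- list()
  for (p in patterns) {
    s <- scan_pattern(chars, p)
    if (length(s)) out[[length(out) + 1L]] <-
        data.frame(start = s, end = s + nchar(p) - 1L, pattern = p)
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      pattern = character(0)))
  unique(do.call(rbind, out))
}

# Remove every occurrence of `patterns` from chars by single-base edits at
# non-protected positions, never recreating an occurrence. Deterministic.
destroy_occurrences <- function(chars, patterns, protected) {
  base_order <- c("A", "T", "C", "G")
  for (iter in 1:500) {
    occ <- pattern_occurrences(chars, patterns)
    occ <- occ[!(occ$start %in% protected$keep_starts), , drop = FALSE]
    if (nrow(occ) == 0L) return(chars)
    o <- occ[order(occ$start), , drop = FALSE][1, ]
    span <- o$start:o$end
    editable <- setdiff(span, protected$positions)
    if (length(editable) == 0L)
      stop("cannot destroy recognition site at ", o$start,
           ": all bases protected", call. = FALSE)
    fixed <- FALSE
    # prefer a central editable base; try AT-preserving swap first
    mid <- editable[order(abs(editable - mean(span)))]
    for (pos in mid) {
      cur <- chars[pos]
      for (repl in unique(c(chartr("ACGT", "TGCA", cur),
                            setdiff(base_order, cur)))) {
        old <- chars[pos]
        chars[pos] <- repl
        occ2 <- pattern_occurrences(chars, patterns)
        occ2 <- occ2[!(occ2$start %in% protected$keep_starts), , drop = FALSE]
        if (nrow(occ2) < nrow(occ)) { fixed <- TRUE; break }
        chars[pos] <- old
      }
      if (fixed) break
    }
    if (!fixed)
      stop("cannot destroy recognition site at ", o$start, call. = FALSE)
  }
  stop("site destruction did not converge", call. = FALSE)
}

#' Plant restriction sites at exact cut positions
#'
#' Writes the enzyme's recognition sequence so that each requested cut
#' position (1-based prefix length) is produced, then destroys every other
#' occurrence of the pattern (both strands) by minimal single-base edits
#' that avoid recreating a site. Post-condition:
#' `find_sites(result, enzyme)` equals `cut_positions` exactly.
#'
#' Requires a blunt palindromic cutter (or a non-palindromic site), so that
#' one planted occurrence yields one cut coordinate.
#'
#' @param seq DNA string.
#' @param enzyme a [restriction_enzyme()].
#' @param cut_positions ascending positions strictly inside the sequence,
#'   pairwise at least `nchar(recognition)` apart.
#' @param protected_intervals list of `c(start, end)` 1-based inclusive
#'   intervals that must not be edited (e.g. primer footprints).
#' @return DNA string.
#' @export
#' @examples
#' s <- plant_sites(strrep("ATTACCGT", 89), alui(), c(251, 455))
#' find_sites(s, alui())  # 251 455
plant_sites <- function(seq, enzyme, cut_positions,
                        protected_intervals = list()) {
  chars <- seq_chars(toupper(seq))
  n <- length(chars)
  m <- nchar(enzyme$recognition)
  cut_positions <- sort(as.integer(cut_positions))
  if (length(cut_positions) > 1L &&
      any(diff(cut_positions) < m))
    stop("unsatisfiable spacing: cut positions closer than ", m, " nt",
         call. = FALSE)
  starts <- cut_positions - enzyme$cut_offset + 1L
  if (length(cut_positions) > 0 &&
      (starts[1] < 1L || starts[length(starts)] + m - 1L > n))
    stop("planted site would fall outside the sequence", call. = FALSE)
  prot_pos <- unlist(lapply(protected_intervals, function(iv)
    iv[1]:iv[2]))
  site_chars <- seq_chars(enzyme$recognition)
  for (s in starts) {
    if (any((s:(s + m - 1L)) %in% prot_pos))
      stop("planted site at cut ", s + enzyme$cut_offset - 1L,
           " overlaps a protected interval", call. = FALSE)
    chars[s:(s + m - 1L)] <- site_chars
  }
  pats <- enzyme_patterns(list(enzyme))
  chars <- destroy_occurrences(
    chars, pats,
    list(keep_starts = starts,
         positions = unique(c(prot_pos,
                              unlist(lapply(starts, function(s)
                                s:(s + m - 1L)))))))
  out <- paste(chars, collapse = "")
  got <- find_sites(out, enzyme)
  if (!identical(got, sort(unique(cut_positions))))
    stop("plant_sites post-condition failed: wanted [",
         paste(cut_positions, collapse = ","), "], produced [",
         paste(got, collapse = ","), "] (non-blunt palindromic cutter?)",
         call. = FALSE)
  out
}

#' Mutate a sequence to a target p-distance
#'
#' Applies `round(target/100 * length)` substitutions at uniformly drawn
#' positions outside the protected intervals, using the
#' composition-stationary swap A<->T, C<->G (no indels). Draws are seeded
#' and reproducible.
#'
#' @param seq DNA string.
#' @param target percent divergence in `[0, 100)`.
#' @param seed integer seed.
#' @param protected_intervals list of `c(start, end)` 1-based inclusive
#'   intervals left untouched.
#' @return mutated DNA string with p-distance to `seq` within 0.3 points of
#'   `target` (errors if the protected intervals make that unreachable).
#' @export
evolve_to_divergence <- function(seq, target, seed = 1L,
                                 protected_intervals = list()) {
  if (target < 0 || target >= 100)
    stop("target must be in [0, 100)", call. = FALSE)
  chars <- seq_chars(toupper(seq))
  n <- length(chars)
  k <- round(target / 100 * n)
  if (abs(100 * k / n - target) > 0.3)
    stop("target divergence not representable within 0.3 points at n = ", n,
         call. = FALSE)
  if (k == 0L) return(paste(chars, collapse = ""))
  prot <- unlist(lapply(protected_intervals, function(iv) iv[1]:iv[2]))
  eligible <- setdiff(seq_len(n), prot)
  if (length(eligible) < k)
    stop("target unreachable: only ", length(eligible),
         " mutable positions for ", k, " substitutions", call. = FALSE)
  with_local_seed(seed, {
    pos <- sample(eligible, k)
    chars[pos] <- chartr("ACGT", "TGCA", chars[pos])
    paste(chars, collapse = "")
  })
}

# percent hamming distance of equal-length strings (no alignment)
p_distance <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  stopifnot(length(ca) == length(cb))
  100 * mean(ca != cb)
}

# Decompose a matrix of pairwise difference counts over tree bipartitions
# (cut-cone NNLS, then greedy +-1 integer refinement). Returns a list of
# splits (index vectors) and their integer column counts.
decompose_bipartitions <- function(counts) {
  n <- nrow(counts)
  pairs <- t(combn(n, 2))
  b <- counts[pairs]
  subsets <- list()
  others <- 2:n
  for (mask in seq_len(2^(n - 1) - 1))
    subsets[[mask]] <- others[bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0]
  A <- vapply(subsets, function(S)
    as.numeric(xor(pairs[, 1] %in% S, pairs[, 2] %in% S)),
    numeric(nrow(pairs)))
  A <- matrix(A, nrow = nrow(pairs))
  x <- pmax(pracma::lsqnonneg(A, b)$x, 0)
  x <- round(x)
  err <- function(x) sum((A %*% x - b)^2)
  for (iter in 1:500) {
    e0 <- err(x)
    if (e0 == 0) break
    best <- NULL; best_e <- e0
    for (s in seq_along(subsets)) for (dlt in c(1, -1)) {
      if (x[s] + dlt < 0) next
      x2 <- x; x2[s] <- x2[s] + dlt
      e2 <- err(x2)
      if (e2 < best_e) { best_e <- e2; best <- x2 }
    }
    if (is.null(best)) break
    x <- best
  }
  keep <- which(x > 0)
  list(splits = subsets[keep], counts = x[keep],
       residual = matrix((A %*% x - b), nrow = nrow(pairs)),
       pairs = pairs)
}

#' Simulate a species panel with known structure
#'
#' Builds one ancestor amplicon at the target A-T content, bounded by the
#' primer footprints; realizes the pairwise divergence targets by assigning
#' disjoint alignment columns to tree bipartitions of the species set (so
#' realized p-distances match the targets to within a column or two);
#' plants each species' restriction map exactly (site-planting base changes
#' are counted into the divergence budget beforehand); guarantees zero
#' sites for the control enzymes; and adds seeded intra-species variants.
#' Substitutions never fall inside primer footprints or site windows.
#'
#' @param config a [panel_config()].
#' @param seed master seed (defaults to `config$seed`); per-species streams
#'   are derived from it by stable hashing, so adding a species never
#'   perturbs another's draws.
#' @return object of class `synthetic_panel`: a list with
#'   `panel` (a [species_panel()] of amplicon records), `templates`
#'   (list of [seq_record()]s with flanks, amplifiable with the configured
#'   primers), `manifest` (data.frame: species, variant, id, at_pct,
#'   planted cuts), `realized_divergence` (percent matrix measured on the
#'   representatives), `ancestor`, `config`, `seed`.
#' @export
#' @examples
#' \donttest{
#' sp <- simulate_panel(panel_config(seed = 42))
#' digest(sp$panel$Turkestan[[1]], alui())$fragment_lengths  # 251 204 255
#' }
simulate_panel <- function(config = panel_config(), seed = config$seed) {
  L <- config$amplicon_length
  species <- config$species
  enzymes_all <- c(list(config$enzyme), config$control_enzymes)
  pats <- enzyme_patterns(enzymes_all)
  maxlen <- max(nchar(pats))
  m <- nchar(config$enzyme$recognition)
  fwd <- config$primers$forward$sequence
  rev3 <- revcomp(config$primers$reverse$sequence)
  nf <- nchar(fwd); nr <- nchar(rev3)
  if (nf + nr >= L) stop("amplicon shorter than the primer footprints",
                         call. = FALSE)
  primer_pos <- c(1:nf, (L - nr + 1L):L)

  # planted windows (1-based spans) per species and their union
  win_of <- function(cuts) lapply(cuts, function(cp) {
    s <- cp - config$enzyme$cut_offset + 1L
    c(s, s + m - 1L)
  })
  maps <- lapply(species, function(sp) {
    cuts <- config$planted_maps[[sp]]
    if (is.null(cuts)) integer(0) else sort(as.integer(cuts))
  })
  names(maps) <- species
  for (sp in species) {
    if (length(maps[[sp]]) > 1L && any(diff(maps[[sp]]) < m))
      stop("species '", sp, "': planted cuts closer than ", m, " nt",
           call. = FALSE)
    for (w in win_of(maps[[sp]])) {
      if (w[1] < 1L || w[2] > L)
        stop("species '", sp, "': planted site outside the amplicon",
             call. = FALSE)
      if (any((w[1]:w[2]) %in% primer_pos))
        stop("conflict: planted site of '", sp,
             "' lies inside a primer footprint", call. = FALSE)
    }
  }
  union_cuts <- sort(unique(unlist(maps)))
  union_wins <- win_of(union_cuts)
  if (length(union_cuts) > 1L) {
    ends <- vapply(union_wins, `[`, numeric(1), 2)
    starts <- vapply(union_wins, `[`, numeric(1), 1)
    if (any(starts[-1] <= ends[-length(ends)]))
      stop("planted site windows of different species overlap", call. = FALSE)
  }
  win_pos <- unlist(lapply(union_wins, function(w) w[1]:w[2]))

  # ancestor: primers + composition-tuned interior + near-site placeholders
  placeholder <- local({
    sc <- seq_chars(config$enzyme$recognition)
    last <- sc[m]
    sc[m] <- chartr("ACGT", "TGCA", last)  # AT-class preserving
    sc
  })
  free_pos <- setdiff(seq_len(L), c(primer_pos, win_pos))
  at_fixed <- sum(seq_chars(paste0(fwd, rev3)) %in% c("A", "T")) +
    sum(placeholder %in% c("A", "T")) * length(union_cuts)
  q <- (config$at_target / 100 * L - at_fixed) / length(free_pos)
  q <- min(max(q, 0.05), 0.95)
  anc <- character(L)
  anc[1:nf] <- seq_chars(fwd)
  anc[(L - nr + 1L):L] <- seq_chars(rev3)
  # fixed-count base multiset, shuffled: composition is exact, not binomial
  n_free <- length(free_pos)
  n_at <- round(q * n_free)
  n_a <- n_at %/% 2L; n_t <- n_at - n_a
  n_c <- (n_free - n_at) %/% 2L; n_g <- n_free - n_at - n_c
  anc[free_pos] <- with_local_seed(derive_seed(seed, "ancestor"),
    sample(rep(c("A", "T", "C", "G"), c(n_a, n_t, n_c, n_g))))
  for (w in union_wins) anc[w[1]:w[2]] <- placeholder
  anc <- destroy_occurrences(
    anc, pats, list(keep_starts = integer(0),
                    positions = c(primer_pos, win_pos)))

  # divergence budget: planting differences first, then bipartition columns
  nsp <- length(species)
  P <- matrix(0L, nsp, nsp, dimnames = list(species, species))
  for (i in seq_len(nsp - 1)) for (j in (i + 1):nsp) {
    P[i, j] <- P[j, i] <-
      length(union(maps[[i]], maps[[j]])) -
      length(intersect(maps[[i]], maps[[j]]))
  }
  Tcnt <- round(config$divergence_targets / 100 * L)
  Bcnt <- Tcnt - P
  if (any(Bcnt[upper.tri(Bcnt)] < 0)) {
    warning("site-planting differences exceed some divergence targets; ",
            "those pairs are floored at the planting distance",
            call. = FALSE)
    Bcnt[Bcnt < 0] <- 0L
  }
  dec <- if (nsp >= 2) decompose_bipartitions(Bcnt) else
    list(splits = list(), counts = integer(0))

  # eligible mutation columns: free interior, clear of padded site windows
  pad_pos <- unlist(lapply(union_wins, function(w)
    max(1L, w[1] - (maxlen - 1L)):min(L, w[2] + (maxlen - 1L))))
  eligible <- setdiff(seq_len(L), c(primer_pos, pad_pos))
  order_cols <- with_local_seed(derive_seed(seed, "columns"),
                                sample(eligible))
  need <- sum(dec$counts)
  if (need > length(order_cols))
    stop("not enough mutable columns (", length(order_cols), ") for ",
         need, " substitutions; lower the divergence targets", call. = FALSE)
  assign_cols <- list()
  ptr <- 0L
  for (s in seq_along(dec$splits)) {
    assign_cols[[s]] <- order_cols[(ptr + 1L):(ptr + dec$counts[s])]
    ptr <- ptr + dec$counts[s]
  }
  spare <- order_cols[seq.int(ptr + 1L, length.out = length(order_cols) - ptr)]

  build_species <- function() {
    seqs <- lapply(seq_len(nsp), function(i) anc)
    names(seqs) <- species
    for (s in seq_along(dec$splits)) {
      members <- dec$splits[[s]]
      cols <- assign_cols[[s]]
      for (i in members)
        seqs[[i]][cols] <- chartr("ACGT", "TGCA", seqs[[i]][cols])
    }
    seqs
  }
  # redraw columns whose substitution creates a recognition site
  for (attempt in 1:300) {
    seqs <- build_species()
    bad <- NULL
    for (i in seq_len(nsp)) {
      occ <- pattern_occurrences(seqs[[i]], pats)
      if (nrow(occ) > 0L) { bad <- list(sp = i, occ = occ[1, ]); break }
    }
    if (is.null(bad)) break
    span <- bad$occ$start:bad$occ$end
    moved <- FALSE
    for (s in seq_along(dec$splits)) {
      if (!(bad$sp %in% dec$splits[[s]])) next
      hit <- which(assign_cols[[s]] %in% span)
      if (length(hit) > 0L) {
        if (length(spare) == 0L)
          stop("ran out of spare columns while avoiding site creation",
               call. = FALSE)
        assign_cols[[s]][hit[1]] <- spare[1]
        spare <- spare[-1]
        moved <- TRUE
        break
      }
    }
    if (!moved)
      stop("unexpected recognition site not caused by a substitution",
           call. = FALSE)
  }
  if (!is.null(bad) && !is.null(bad$sp) && attempt == 300L)
    stop("column redraw did not converge", call. = FALSE)

  # plant each species' map and verify it exactly
  site_chars <- seq_chars(config$enzyme$recognition)
  for (i in seq_len(nsp)) {
    for (w in win_of(maps[[i]]))
      seqs[[i]][w[1]:w[2]] <- site_chars
    got <- find_sites(paste(seqs[[i]], collapse = ""), config$enzyme)
    if (!identical(got, maps[[i]]))
      stop("internal error: map verification failed for '", species[i],
           "' (got ", paste(got, collapse = ","), ")", call. = FALSE)
    for (ctrl in config$control_enzymes) {
      if (length(find_sites(paste(seqs[[i]], collapse = ""), ctrl)) > 0L)
        stop("internal error: control enzyme ", ctrl$name,
             " has sites in '", species[i], "'", call. = FALSE)
    }
  }

  # intra-species variants from the representative
  entries <- list()
  manifest <- list()
  used <- setdiff(eligible, unlist(assign_cols))
  for (i in seq_len(nsp)) {
    sp <- species[i]
    nvar <- max(1L, as.integer(config$n_variants_per_species[[sp]]))
    recs <- list()
    rep_seq <- seqs[[i]]
    for (v in seq_len(nvar)) {
      vchars <- rep_seq
      if (v > 1L && config$intra_divergence[[sp]] > 0) {
        k <- round(config$intra_divergence[[sp]] / 100 * L)
        vseed <- derive_seed(seed, paste0(sp, "/variant", v))
        pool <- with_local_seed(vseed, sample(used))
        taken <- 0L; idx <- 1L
        while (taken < k && idx <= length(pool)) {
          pos <- pool[idx]; idx <- idx + 1L
          old <- vchars[pos]
          vchars[pos] <- chartr("ACGT", "TGCA", old)
          lo <- max(1L, pos - maxlen + 1L)
          hi <- min(L, pos + maxlen - 1L)
          if (nrow(pattern_occurrences(vchars[lo:hi], pats)) > 0L) {
            vchars[pos] <- old  # would create a site; redraw
          } else taken <- taken + 1L
        }
        if (taken < k)
          stop("could not place intra-species substitutions for '", sp, "'",
               call. = FALSE)
      }
      id <- sprintf("%s_%d", gsub("[^A-Za-z0-9]", "", sp), v)
      sq <- paste(vchars, collapse = "")
      desc <- paste(if (sp %in% names(REF_BINOMIALS)) REF_BINOMIALS[[sp]]
                    else sp, "synthetic barcode amplicon")
      recs[[v]] <- seq_record(id, sq, desc)
      manifest[[length(manifest) + 1L]] <- data.frame(
        species = sp, variant = v, id = id, length = L,
        at_pct = round_half_up(at_content(sq), 2),
        planted_cuts = paste(maps[[i]], collapse = ","),
        stringsAsFactors = FALSE)
    }
    entries[[sp]] <- recs
  }
  panel <- species_panel(entries)

  # templates: random flanks around each variant amplicon
  base_probs <- c(q / 2, q / 2, (1 - q) / 2, (1 - q) / 2)
  templates <- list()
  for (sp in species) {
    fl <- with_local_seed(derive_seed(seed, paste0(sp, "/flanks")), list(
      f5 = paste(sample(c("A", "T", "C", "G"), config$flank5, TRUE,
                        base_probs), collapse = ""),
      f3 = paste(sample(c("A", "T", "C", "G"), config$flank3, TRUE,
                        base_probs), collapse = "")))
    for (rec in panel[[sp]]) {
      tid <- paste0(rec$id, "_template")
      templates[[tid]] <- seq_record(
        tid, paste0(fl$f5, rec$residues, fl$f3),
        paste(rec$description, "with flanks"))
    }
  }

  reps <- vapply(seq_len(nsp), function(i)
    paste(seqs[[i]], collapse = ""), character(1))
  realized <- matrix(0, nsp, nsp, dimnames = list(species, species))
  for (i in seq_len(nsp - 1)) for (j in (i + 1):nsp)
    realized[i, j] <- realized[j, i] <-
      round_half_up(p_distance(reps[i], reps[j]), 2)

  structure(list(
    panel = panel, templates = templates,
    manifest = do.call(rbind, manifest),
    realized_divergence = realized,
    ancestor = paste(anc, collapse = ""),
    config = config, seed = as.integer(seed)
  ), class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf("<synthetic_panel> %d species, %d bp amplicons, seed %d\n",
              length(x$panel), x$config$amplicon_length, x$seed))
  print(x$manifest)
  invisible(x)
}
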