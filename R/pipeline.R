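#' Run the full barcode PCR-RFLP analysis
#'
#' End-to-end composition of the package's modules: amplify templates with
#' the primer pair, build DNA and amino-acid similarity matrices (with the
#' combined lower/upper-triangle layout), infer and root the
#' neighbor-joining tree, digest every amplicon with every library enzyme,
#' screen the library for a fully diagnostic single enzyme, render the
#' virtual gel for the top enzyme, and tabulate molecular-clock divergence
#' times. All artifacts are written under `out_dir`; a machine-readable
#' JSON summary ties them together. Each stage is logged; a stage failure
#' aborts with a stage-named error while earlier outputs are retained.
#'
#' @param templates named list of [seq_record()]s (or a `synthetic_panel`'s
#'   `templates`); if `NULL`, a default synthetic panel is simulated with
#'   `seed`.
#' @param out_dir output directory (created if needed).
#' @param primers forward/reverse [primer()] pair.
#' @param enzyme_library list of [restriction_enzyme()]s; defaults to the
#'   bundled library.
#' @param gel a [gel_model()].
#' @param outgroup taxon label used to root the tree; defaults to the most
#'   divergent taxon (largest mean divergence).
#' @param clock_rate percent divergence per million years.
#' @param seed recorded in the summary and used for simulation when
#'   `templates` is `NULL`.
#' @param quiet suppress stage logging.
#' @return (invisibly) list with `amplicons`, `similarity_dna`,
#'   `similarity_aa`, `tree`, `profiles`, `screen`, `divergence_times`,
#'   `summary` (the JSON-serialized list), `out_dir`.
#' @export
run_pipeline <- function(templates = NULL, out_dir = tempfile("rflp_"),
                         primers = folmer_primers(),
                         enzyme_library = default_enzyme_library(),
                         gel = gel_model(), outgroup = NULL,
                         clock_rate = 2.0, seed = 1L, quiet = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(...) {
    if (!quiet)
      message(sprintf("[%6.2fs] ", proc.time()[["elapsed"]] - t0), ...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(templates)) {
    log_stage("simulate: default synthetic panel (seed ", seed, ")")
    templates <- stage("simulate",
                       simulate_panel(panel_config(seed = seed))$templates)
  }

  log_stage("amplify: ", length(templates), " templates")
  amplicons <- stage("amplify", {
    out <- list()
    for (rec in templates) {
      amp <- tryCatch(extract_amplicon(rec, primers$forward,
                                       primers$reverse),
                      error = function(e) {
                        warning("template '", rec$id, "' skipped: ",
                                conditionMessage(e), call. = FALSE)
                        NULL
                      })
      if (!is.null(amp)) out[[rec$id]] <- amp
    }
    if (length(out) == 0L) stop("no template amplified")
    out
  })
  # one amplicon per species label (strip _<variant>_template suffixes)
  species_of <- function(id) sub("_[0-9]+(_template)?$", "",
                                 sub("_template$", "", id))
  reps <- amplicons[!duplicated(vapply(names(amplicons), species_of,
                                       character(1)))]
  names(reps) <- vapply(names(reps), species_of, character(1))
  write_fasta(lapply(names(reps), function(sp)
    seq_record(sp, reps[[sp]]$sequence, "barcode amplicon")),
    file.path(out_dir, "amplicons.fa"))

  log_stage("distance: ", length(reps), " species at DNA and AA level")
  sim_dna <- stage("distance", similarity_matrix(reps, "dna"))
  sim_aa <- stage("distance", similarity_matrix(reps, "aa"))
  write_matrix_tsv(sim_dna, file.path(out_dir, "similarity_dna.tsv"))
  write_matrix_tsv(sim_aa, file.path(out_dir, "similarity_aa.tsv"))
  write_matrix_tsv(format_similarity_layout(sim_dna, sim_aa),
                   file.path(out_dir, "similarity_combined.tsv"))
  divg <- divergence_matrix(sim_dna)

  log_stage("tree: neighbor joining")
  tree <- stage("tree", {
    tr <- neighbor_joining(divg)
    og <- outgroup
    if (is.null(og)) og <- rownames(divg)[which.max(rowMeans(divg))]
    root_with_outgroup(tr, og)
  })
  writeLines(write_newick(tree), file.path(out_dir, "tree.nwk"))

  log_stage("digest: ", length(enzyme_library), " enzymes x ",
            length(reps), " amplicons")
  profiles <- stage("digest", {
    out <- list()
    for (enz in enzyme_library) for (sp in names(reps)) {
      p <- digest(reps[[sp]], enz)
      p$amplicon_id <- sp
      out[[paste(enz$name, sp, sep = ":")]] <- p
    }
    out
  })
  prof_tab <- profiles_table(profiles)
  write.table(prof_tab, file.path(out_dir, "digest_profiles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  log_stage("screen: single-enzyme diagnostics")
  screen <- stage("screen", screen_enzymes(reps, enzyme_library, gel))
  write.table(screen[, setdiff(names(screen), "pairs_total")],
              file.path(out_dir, "screen.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  log_stage("gel: virtual lanes for ", screen$enzyme[1])
  gel_txt <- stage("gel", {
    sigs <- attr(screen, "signatures")[[screen$enzyme[1]]]
    render_gel(sigs, gel)
  })
  writeLines(gel_txt, file.path(out_dir, "gel.txt"))

  log_stage("clock: divergence times at ", clock_rate, "%/MY")
  times <- stage("clock", {
    prs <- combn(rownames(divg), 2, simplify = FALSE)
    tab <- data.frame(
      pair = vapply(prs, paste, character(1), collapse = " vs "),
      divergence_pct = vapply(prs, function(p) divg[p[1], p[2]], numeric(1)),
      stringsAsFactors = FALSE)
    tab$time_my <- round_half_up(divergence_time(tab$divergence_pct,
                                                 clock_rate), 2)
    tab
  })
  write.table(times, file.path(out_dir, "divergence_times.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    seed = seed,
    n_templates = length(templates),
    species = names(reps),
    amplicon_lengths = vapply(reps, function(a) a$length, numeric(1)),
    similarity_dna = sim_dna,
    similarity_aa = sim_aa,
    tree_newick = write_newick(tree),
    fragments = lapply(profiles, function(p) p$fragment_lengths),
    top_enzyme = screen$enzyme[1],
    top_enzyme_pairs = screen$pairs_distinguished[1],
    fully_diagnostic_enzymes =
      screen$enzyme[screen$fully_diagnostic],
    divergence_times = times
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done: outputs in ", out_dir)
  invisible(list(amplicons = reps, similarity_dna = sim_dna,
                 similarity_aa = sim_aa, tree = tree, profiles = profiles,
                 screen = screen, divergence_times = times,
                 summary = summary, out_dir = out_dir))
}
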