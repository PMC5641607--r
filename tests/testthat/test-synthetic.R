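test_that("plant_sites writes exactly the requested map", {
  s <- rand_dna(710, seed = 70)
  planted <- plant_sites(s, alui(), c(251, 455))
  expect_equal(find_sites(planted, alui()), c(251L, 455L))
  expect_equal(nchar(planted), 710L)

  none <- plant_sites(s, alui(), integer(0))
  expect_equal(find_sites(none, alui()), integer(0))

  am <- plant_sites(s, alui(), c(167, 251, 392, 612))
  expect_equal(digest(am, alui())$fragment_lengths,
               c(167L, 84L, 141L, 220L, 98L))

  expect_error(plant_sites(s, alui(), c(251, 253)), "spacing")
  expect_error(plant_sites(s, alui(), 709), "outside the sequence")
})

test_that("plant_sites respects protected intervals", {
  p <- folmer_primers()
  s <- paste0(p$forward$sequence, rand_dna(658, seed = 71),
              revcomp(p$reverse$sequence))
  planted <- plant_sites(s, alui(), c(251, 455),
                         protected_intervals = list(c(1, 25), c(684, 710)))
  expect_identical(substr(planted, 1, 25), p$forward$sequence)
  expect_identical(substr(planted, 684, 710), revcomp(p$reverse$sequence))
  expect_error(plant_sites(s, alui(), 10,
                           protected_intervals = list(c(1, 25))),
               "protected")
})

test_that("evolve_to_divergence hits its target and is reproducible", {
  s <- rand_dna(710, seed = 72)
  expect_identical(evolve_to_divergence(s, 0, seed = 1), s)
  m1 <- evolve_to_divergence(s, 11.57, seed = 7)
  m2 <- evolve_to_divergence(s, 11.57, seed = 7)
  expect_identical(m1, m2)
  expect_equal(percent_identity_dna(global_align(s, m1)), 88.43,
               tolerance = 0.3 / 88)
  # protected intervals untouched
  m3 <- evolve_to_divergence(s, 20, seed = 8,
                             protected_intervals = list(c(1, 50)))
  expect_identical(substr(m3, 1, 50), substr(s, 1, 50))
  expect_error(evolve_to_divergence(s, 90, seed = 9,
                                    protected_intervals = list(c(1, 700))),
               "unreachable")
})

test_that("substitutions preserve base composition exactly", {
  s <- rand_dna(710, seed = 73, at = 0.657)
  m <- evolve_to_divergence(s, 20, seed = 10)
  expect_equal(at_content(m), at_content(s))
})

test_that("the default panel reproduces the published study structure", {
  sp <- simulate_panel(panel_config(seed = 303))
  expect_s3_class(sp$panel, "species_panel")
  expect_length(sp$panel, 5L)
  # every printed fragment profile, exactly
  frags <- reference_fragments()
  for (nm in names(sp$panel)) {
    expect_identical(digest(sp$panel[[nm]][[1]], alui())$fragment_lengths,
                     frags[[nm]], info = nm)
  }
  # pairwise divergences within half a point of the published matrix
  target <- divergence_matrix(reference_similarity("dna"))
  expect_lt(max(abs(sp$realized_divergence - target)), 0.5)
  # A-T content near the published mean
  at <- mean(vapply(sp$panel, function(r) at_content(r[[1]]$residues),
                    numeric(1)))
  expect_lt(abs(at - 65.7), 1.5)
  # control enzyme has no sites anywhere
  for (nm in names(sp$panel))
    expect_length(find_sites(sp$panel[[nm]][[1]]$residues,
                             restriction_enzyme("EcoRI", "GAATTC", 1)), 0L)
})

test_that("panels are byte-identical for a fixed seed", {
  a <- simulate_panel(panel_config(seed = 77))
  b <- simulate_panel(panel_config(seed = 77))
  fa <- withr::local_tempfile(fileext = ".fa")
  fb <- withr::local_tempfile(fileext = ".fa")
  write_fasta(a$templates, fa)
  write_fasta(b$templates, fb)
  expect_identical(readLines(fa), readLines(fb))
  c_ <- simulate_panel(panel_config(seed = 78))
  expect_false(identical(a$templates[[1]]$residues,
                         c_$templates[[1]]$residues))
})

test_that("templates amplify back to the planted 710 bp maps (many seeds)", {
  p <- folmer_primers()
  maps <- reference_alui_maps()
  for (seed in 401:422) {
    sp <- simulate_panel(panel_config(seed = seed))
    for (nm in names(sp$panel)) {
      tmpl <- sp$templates[[paste0(sp$panel[[nm]][[1]]$id, "_template")]]
      amp <- extract_amplicon(tmpl, p$forward, p$reverse)
      expect_equal(amp$length, 710L)
      expect_identical(digest(amp, alui())$cut_positions, maps[[nm]],
                       info = paste(seed, nm))
    }
  }
})

test_that("variants honour the intra-species divergence setting", {
  cfg <- panel_config(seed = 79, n_variants_per_species = 3,
                      intra_divergence = 0)
  sp <- simulate_panel(cfg)
  for (nm in names(sp$panel)) {
    expect_length(sp$panel[[nm]], 3L)
    expect_identical(sp$panel[[nm]][[2]]$residues,
                     sp$panel[[nm]][[1]]$residues)
  }
  cfg2 <- panel_config(seed = 80,
                       n_variants_per_species = c(American = 3))
  sp2 <- simulate_panel(cfg2)
  st <- intra_species_divergence(sp2$panel, "American")
  expect_equal(st$n_records, 3L)
  expect_gt(st$mean_pct, 0)
  # variants keep the planted map
  expect_identical(digest(sp2$panel$American[[3]], alui())$cut_positions,
                   reference_alui_maps()$American)
})

test_that("NJ on a simulated panel groups the Blattidae", {
  sp <- simulate_panel(panel_config(seed = 304))
  tr <- root_with_outgroup(neighbor_joining(sp$realized_divergence),
                           "Brown-banded")
  expect_true(is_monophyletic(tr, c("American", "Oriental", "Turkestan")))
})

test_that("conflicting constraints are reported by name", {
  expect_error(
    simulate_panel(panel_config(
      species = c("A", "B"),
      divergence_targets = matrix(c(0, 10, 10, 0), 2,
                                  dimnames = list(c("A", "B"),
                                                  c("A", "B"))),
      planted_maps = list(A = 10L, B = 300L), seed = 1)),
    "primer footprint")
})
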