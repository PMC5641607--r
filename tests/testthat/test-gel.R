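test_that("visible bands drop sub-threshold fragments and merge comigrants", {
  gel <- gel_model()  # min_visible 100, tol 0.04
  # sub-100 bands invisible, no comigration among the survivors
  am <- visible_bands(c(167, 84, 141, 220, 98), gel)
  expect_equal(am$bands, c(220, 167, 141))
  # 251/255 comigrate (|255-251| = 4 <= 0.04 * 255): merged to the mean
  tu <- visible_bands(c(251, 204, 255), gel)
  expect_equal(tu$bands, c(253, 204))
  # at 4% tolerance 138 vs 132 is just resolvable (6 > 0.04 * 138)
  bb <- visible_bands(c(65, 54, 39, 138, 39, 132, 87, 156), gel)
  expect_equal(bb$bands, c(156, 138, 132))
  # ...but merges at 5%
  bb5 <- visible_bands(c(65, 54, 39, 138, 39, 132, 87, 156),
                       gel_model(comigration_tol = 0.05))
  expect_equal(bb5$bands, c(156, 135))
  expect_equal(visible_bands(c(40, 99, 12), gel)$bands, numeric(0))
})

test_that("signature extraction is idempotent", {
  withr::with_seed(60, {
    for (k in 1:20) {
      gel <- gel_model(min_visible = sample(c(0, 50, 100), 1),
                       comigration_tol = runif(1, 0, 0.1))
      frags <- sample(10:800, sample(1:10, 1))
      sig <- visible_bands(frags, gel)
      again <- visible_bands(sig$bands, gel)
      expect_equal(again$bands, sig$bands)
    }
  })
})

test_that("stricter gels never show more bands (monotonicity)", {
  withr::with_seed(61, {
    for (k in 1:20) {
      frags <- sample(10:800, sample(2:10, 1))
      n0 <- length(visible_bands(frags, gel_model(100, 0.04))$bands)
      expect_lte(length(visible_bands(frags, gel_model(150, 0.04))$bands), n0)
      expect_lte(length(visible_bands(frags, gel_model(100, 0.08))$bands), n0)
    }
  })
})

test_that("a perfect gel reduces signatures to the raw fragment multiset", {
  ideal <- gel_model(min_visible = 0, comigration_tol = 0)
  withr::with_seed(62, {
    for (k in 1:10) {
      fa <- sample(10:800, sample(1:8, 1), replace = TRUE)
      fb <- sample(10:800, sample(1:8, 1), replace = TRUE)
      expect_equal(visible_bands(fa, ideal)$bands,
                   sort(fa, decreasing = TRUE))
      expect_equal(
        profiles_distinguishable(visible_bands(fa, ideal),
                                 visible_bands(fb, ideal), ideal),
        !identical(sort(fa), sort(fb)))
    }
  })
})

test_that("distinguishability reads positional band pairs symmetrically", {
  gel <- gel_model()
  sig <- function(b) structure(list(label = "x", bands = b),
                               class = "gel_signature")
  expect_false(profiles_distinguishable(sig(c(253, 204)),
                                        sig(c(253, 204)), gel))
  expect_true(profiles_distinguishable(sig(c(253, 204)),
                                       sig(c(435, 251)), gel))
  expect_false(profiles_distinguishable(sig(200), sig(205), gel))
  expect_true(profiles_distinguishable(sig(200), sig(c(200, 400)), gel))
  withr::with_seed(63, {
    for (k in 1:10) {
      a <- sig(sort(sample(100:800, sample(1:5, 1)), decreasing = TRUE))
      b <- sig(sort(sample(100:800, sample(1:5, 1)), decreasing = TRUE))
      expect_equal(profiles_distinguishable(a, b, gel),
                   profiles_distinguishable(b, a, gel))
    }
  })
})

test_that("gel model construction validates its parameters", {
  expect_error(gel_model(min_visible = -1), "min_visible")
  expect_error(gel_model(comigration_tol = 1), "comigration_tol")
})

test_that("the enzyme screen flags AluI as fully diagnostic", {
  sp <- simulate_panel(panel_config(seed = 301))
  amps <- lapply(sp$panel, function(r) r[[1]]$residues)
  lib <- list(alui(), restriction_enzyme("EcoRI", "GAATTC", 1))
  scr <- screen_enzymes(amps, lib, gel_model())
  alu <- scr[scr$enzyme == "AluI", ]
  eco <- scr[scr$enzyme == "EcoRI", ]
  expect_equal(alu$pairs_distinguished, 10L)
  expect_true(alu$fully_diagnostic)
  expect_equal(eco$pairs_distinguished, 0L)
  expect_false(eco$fully_diagnostic)
  expect_equal(scr$enzyme[1], "AluI")  # ranked first
})

test_that("screen degenerate cases: empty library, identical amplicons", {
  s <- rand_dna(500, seed = 64)
  expect_error(screen_enzymes(list(a = s, b = s), list()), "empty")
  expect_error(screen_enzymes(list(a = s), list(alui())), "at least 2")
  scr <- screen_enzymes(list(a = s, b = s), list(alui()))
  expect_equal(scr$pairs_distinguished, 0L)
  expect_false(scr$fully_diagnostic)
})

test_that("the virtual gel renders one lane per signature plus the ladder", {
  sp <- simulate_panel(panel_config(seed = 302))
  gel <- gel_model()
  sigs <- lapply(names(sp$panel), function(nm)
    visible_bands(digest(sp$panel[[nm]][[1]], alui()), gel, label = nm))
  txt <- render_gel(sigs, gel)
  lines <- strsplit(txt, "\n")[[1]]
  expect_match(lines[1], "ladder")
  for (nm in names(sp$panel)) expect_match(lines[1], nm)
  expect_identical(txt, render_gel(sigs, gel))  # deterministic
  # a band equal to a ladder rung lands on that rung's row
  one <- list(structure(list(label = "x", bands = 300),
                        class = "gel_signature"))
  txt1 <- strsplit(render_gel(one, gel), "\n")[[1]]
  rung_row <- grep("300 -", txt1)
  expect_match(txt1[rung_row], "=")
  # empty signature: lane exists, no bands anywhere
  none <- list(structure(list(label = "x", bands = numeric(0)),
                         class = "gel_signature"))
  expect_false(grepl("=", render_gel(none, gel)))
  expect_warning(
    render_gel(list(structure(list(label = "x", bands = 5000),
                              class = "gel_signature")), gel),
    "larger than the top ladder")
})
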