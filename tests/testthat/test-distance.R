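test_that("global alignment matches exhaustive and library oracles", {
  # frozen case, verified by exhaustive recursion: one gap opposite C
  pr <- global_align("ACGT", "AGT", match = 1, mismatch = -1, gap = -2)
  expect_equal(pr$score, 1)
  expect_equal(pr$score, bf_align_score("ACGT", "AGT", gap = -2))
  expect_identical(pr$a_gapped, "ACGT")
  expect_identical(pr$b_gapped, "A-GT")

  expect_equal(global_align("ACGT", "ACGT")$score, 4)
  expect_equal(global_align("A", "T")$score, -1)

  # random tiny pairs against the exhaustive-recursion oracle
  withr::with_seed(31, {
    for (k in 1:25) {
      a <- rand_dna(sample(1:6, 1))
      b <- rand_dna(sample(1:6, 1))
      g <- sample(c(-2, -5), 1)
      expect_equal(global_align(a, b, gap = g)$score,
                   bf_align_score(a, b, gap = g), info = paste(a, b, g))
    }
  })

  # longer random pairs against Biostrings' Needleman-Wunsch
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  withr::with_seed(32, {
    for (k in 1:10) {
      a <- rand_dna(40); b <- rand_dna(35)
      ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                           substitutionMatrix = sm,
                                           gapOpening = 0, gapExtension = 5)
      expect_equal(global_align(a, b)$score, Biostrings::score(ref))
    }
  })
})

test_that("aligned pairs are well-formed: degapping recovers the inputs", {
  withr::with_seed(33, {
    for (k in 1:10) {
      a <- rand_dna(sample(5:50, 1)); b <- rand_dna(sample(5:50, 1))
      pr <- global_align(a, b)
      expect_equal(nchar(pr$a_gapped), nchar(pr$b_gapped))
      expect_identical(gsub("-", "", pr$a_gapped), a)
      expect_identical(gsub("-", "", pr$b_gapped), b)
      cols <- cbind(strsplit(pr$a_gapped, "")[[1]],
                    strsplit(pr$b_gapped, "")[[1]])
      expect_false(any(cols[, 1] == "-" & cols[, 2] == "-"))
    }
  })
  expect_error(global_align("", "ACGT"), "non-empty")
})

test_that("DNA percent identity excludes gap columns and is symmetric", {
  ident <- rand_dna(648, seed = 34)
  expect_equal(percent_identity_dna(global_align(ident, ident)), 100)
  expect_equal(percent_identity_dna(list(a_gapped = "ACGT",
                                         b_gapped = "ACGA")), 75)
  # gap columns out of the denominator: 3 comparable, all identical
  expect_equal(percent_identity_dna(list(a_gapped = "AC-GT",
                                         b_gapped = "ACTA-")), 100 * 2 / 3)
  expect_error(percent_identity_dna(list(a_gapped = "A-", b_gapped = "-A")),
               "no comparable")
  withr::with_seed(35, {
    a <- rand_dna(60); b <- rand_dna(55)
    expect_equal(percent_identity_dna(global_align(a, b)),
                 percent_identity_dna(global_align(b, a)))
  })
})

test_that("translation follows the invertebrate mitochondrial code", {
  expect_identical(translate_dna("ATA"), "M")   # table 5: ATA = Met
  expect_identical(translate_dna("TGA"), "W")   # table 5: TGA = Trp
  expect_identical(translate_dna("AGA"), "S")   # table 5: AGA = Ser
  expect_identical(translate_dna("ACGT", frame = 1), "R")
  expect_identical(translate_dna("ATGNAATAA"), "MX*")
  expect_equal(nchar(translate_dna(rand_dna(710, seed = 36))), 236L)
  expect_error(translate_dna("ATA", frame = 3), "frame")
})

test_that("amino-acid identity compares literally, X included", {
  expect_equal(percent_identity_aa(strrep("M", 210), strrep("M", 210)), 100)
  expect_equal(percent_identity_aa("MW", "MF"), 50)
  expect_equal(percent_identity_aa("MX", "MX"), 100)
  expect_error(percent_identity_aa("MW", "MWF"), "differ in length")
})

test_that("synonymous-only substitution leaves protein identity at 100", {
  dna <- paste(rep(c("ATG", "CTT", "GGA", "TCA", "AAA", "CGG"), 12),
               collapse = "")
  mut <- mutate_synonymous(dna, n_codons = 20, seed = 37)
  expect_lt(percent_identity_dna(global_align(dna, mut)), 100)
  expect_equal(percent_identity_aa(translate_dna(dna), translate_dna(mut)),
               100)
})

test_that("A-T content counts only unambiguous bases", {
  expect_equal(at_content("ATAT"), 100)
  expect_equal(at_content("GCGC"), 0)
  expect_equal(at_content("ATGCNNNN"), 50)
  expect_error(at_content("NNRY"), "undefined")
})

test_that("divergence time is divergence over clock rate", {
  expect_equal(divergence_time(20, 2), 10)
  expect_equal(divergence_time(22.26, 2), 11.13)
  expect_equal(divergence_time(0, 2), 0)
  expect_error(divergence_time(5, 0), "positive")
  expect_error(divergence_time(-1, 2), ">= 0")
  withr::with_seed(38, {
    d <- runif(20, 0, 30); r <- runif(20, 0.5, 5)
    expect_equal(divergence_time(d, r) * r, d)
  })
})

test_that("similarity matrices are symmetric with a 100 diagonal", {
  s <- rand_dna(300, seed = 39)
  m <- similarity_matrix(c(a = s, b = s))
  expect_equal(unname(m), matrix(100, 2, 2), ignore_attr = TRUE)
  panel <- c(a = s, b = evolve_to_divergence(s, 10, seed = 40),
             c = evolve_to_divergence(s, 20, seed = 41))
  m <- similarity_matrix(panel)
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 3))
  expect_true(all(m >= 0 & m <= 100))
  expect_equal(m["a", "b"], 90, tolerance = 0.01)
  expect_error(similarity_matrix(c(a = s)), "at least 2")
})

test_that("the published divergence extrema and reference tables cohere", {
  d <- divergence_matrix(reference_similarity("dna"))
  expect_equal(max(d), 22.26)
  expect_equal(min(d[upper.tri(d)]), 11.57)
  aa <- reference_similarity("aa")
  expect_equal(aa["American", "Turkestan"], 100)
  # every published fragment profile sums to the amplicon length and is the
  # successive difference of its cut map
  maps <- reference_alui_maps()
  frags <- reference_fragments()
  for (sp in names(maps)) {
    expect_equal(sum(frags[[sp]]), 710, info = sp)
    expect_equal(cumsum(frags[[sp]])[seq_along(maps[[sp]])],
                 as.numeric(maps[[sp]]), info = sp)
  }
})

test_that("intra-species polymorphism reports mean and max pairwise", {
  base <- rand_dna(710, seed = 42)
  panel <- species_panel(list(Am = list(
    seq_record("a1", base),
    seq_record("a2", evolve_to_divergence(base, 2.62, seed = 43)),
    seq_record("a3", evolve_to_divergence(base, 2.62, seed = 44)))))
  st <- intra_species_divergence(panel, "Am")
  expect_equal(st$n_records, 3L)
  expect_gte(st$max_pct, st$mean_pct)
  expect_equal(min(st$mean_pct, st$max_pct) > 0, TRUE)
  expect_error(intra_species_divergence(panel, "Or"), "unknown species")
})

test_that("the combined layout places DNA below and AA above the diagonal", {
  dna <- reference_similarity("dna")
  aa <- reference_similarity("aa")
  lay <- format_similarity_layout(dna, aa)
  expect_identical(lay["Oriental", "American"], "88.43")
  expect_identical(lay["American", "Oriental"], "98.57")
  expect_identical(diag(lay), setNames(rep("***", 5), rownames(dna)))
})
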