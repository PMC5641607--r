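# Independent oracles and small fixture builders used across the suite.

rand_dna <- function(n, seed = NULL, at = 0.5) {
  draw <- function() paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
                                  prob = c(at / 2, at / 2,
                                           (1 - at) / 2, (1 - at) / 2)),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Exhaustive-recursion optimal global alignment score (no DP table, no
# traceback): max over all alignments of two short strings.
bf_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) +
                    if (ca[i] == cb[j]) match else mismatch)
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(ca), length(cb))
}

# Naive both-strand substring scan for a concrete (unambiguous) recognition
# site; returns the cut positions a digestion should report.
naive_cut_positions <- function(seq, recognition, cut_offset) {
  m <- nchar(recognition)
  n <- nchar(seq)
  hits <- function(pat) {
    starts <- which(vapply(seq_len(n - m + 1L), function(i)
      substr(seq, i, i + m - 1L) == pat, logical(1)))
    starts
  }
  top <- hits(recognition) - 1L + cut_offset
  bot <- hits(revcomp(recognition)) - 1L + (m - cut_offset)
  cuts <- sort(unique(c(top, bot)))
  cuts[cuts > 0L & cuts < n]
}

# Least-squares tree search: fit branch lengths to every unrooted topology
# (phangorn::allTrees + nnls.tree) and return the minimum-RSS tree.
# Independent of the package's NJ implementation.
ls_best_topology <- function(d) {
  trees <- phangorn::allTrees(nrow(d), rooted = FALSE,
                              tip.label = rownames(d))
  rss <- vapply(trees, function(tr) {
    fit <- phangorn::nnls.tree(d, tr, method = "unrooted")
    sum((as.matrix(stats::cophenetic(fit))[rownames(d), rownames(d)] - d)^2)
  }, numeric(1))
  trees[[which.min(rss)]]
}

# Additive distance matrix from a random tree with positive branch lengths.
additive_matrix <- function(n_tips, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_tips, rooted = FALSE,
                     br = function(k) stats::runif(k, 0.5, 3))
    list(tree = tr,
         d = as.matrix(stats::cophenetic(tr))[tr$tip.label, tr$tip.label])
  })
}

rf_dist <- function(a, b) phangorn::RF.dist(a, b)

expect_same_topology <- function(a, b) {
  testthat::expect_equal(rf_dist(ape::unroot(a), ape::unroot(b)), 0)
}
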