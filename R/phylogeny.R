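#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q-criterion `Q(i,j) = (r - 2) d(i,j) - R(i) - R(j)` is joined, with
#' branch lengths from the standard three-point formulas and the reduced
#' matrix `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Ties in Q are broken by
#' the lowest (row, column) index pair so trees are bit-reproducible.
#' Negative branch lengths (possible on non-additive input) are clamped to
#' zero with a warning. On additive matrices the generating tree and its
#' branch lengths are recovered exactly.
#'
#' @param d symmetric numeric matrix of pairwise distances with unique
#'   dimnames (typically percent divergence = 100 - similarity); at least 3
#'   taxa.
#' @return unrooted tree of class `phylo` (ape).
#' @export
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' neighbor_joining(d)  # pendant branches 1, 1, 3
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be symmetric", call. = FALSE)
  labs <- rownames(d)
  if (is.null(labs) || anyDuplicated(labs))
    stop("distance matrix needs unique row/column names", call. = FALSE)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  d <- unname(d * 1.0)
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  fmt <- function(x) sprintf("%.10g", x)
  # each active node carries its newick substring
  nwk <- sprintf("'%s'", gsub("'", "''", labs))
  plain <- !grepl("[\\s()\\[\\]:;,']", labs, perl = TRUE)
  nwk[plain] <- labs[plain]
  active <- seq_len(n)
  while (length(active) > 3L) {
    r <- length(active)
    dd <- d[active, active, drop = FALSE]
    R <- rowSums(dd)
    q <- (r - 2) * dd - outer(R, R, `+`)
    diag(q) <- Inf
    # lowest (row, col) pair among minima, upper triangle
    q[lower.tri(q)] <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    li <- clamp(dd[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    lj <- clamp(dd[i, j] - (dd[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))))
    ai <- active[i]; aj <- active[j]
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[ai], fmt(li), nwk[aj], fmt(lj))
    # reuse slot ai for the merged node
    for (k in active) {
      if (k == ai || k == aj) next
      dnew <- (d[ai, k] + d[aj, k] - d[ai, aj]) / 2
      d[ai, k] <- d[k, ai] <- dnew
    }
    nwk[ai] <- new_nwk
    active <- setdiff(active, aj)
  }
  a <- active[1]; b <- active[2]; cc <- active[3]
  la <- clamp((d[a, b] + d[a, cc] - d[b, cc]) / 2)
  lb <- clamp((d[a, b] + d[b, cc] - d[a, cc]) / 2)
  lc <- clamp((d[a, cc] + d[b, cc] - d[a, b]) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[a], fmt(la), nwk[b], fmt(lb),
                 nwk[cc], fmt(lc))
  if (clamped)
    warning("negative NJ branch length(s) clamped to 0", call. = FALSE)
  read_newick(txt)
}

#' Root a tree on an outgroup taxon
#'
#' Places the root at the midpoint of the outgroup's pendant edge; all other
#' relationships and all leaf-to-leaf path lengths are preserved. Rooting
#' twice on the same taxon is idempotent.
#'
#' @param tree a `phylo` tree.
#' @param outgroup leaf label.
#' @return rooted `phylo` tree whose root has the outgroup as an immediate
#'   child.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup %in% tree$tip.label)
    stop("unknown taxon: ", outgroup, call. = FALSE)
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  # split the pendant edge evenly between the two root edges
  root_node <- length(rooted$tip.label) + 1L
  kids <- which(rooted$edge[, 1] == root_node)
  if (length(kids) == 2L && !is.null(rooted$edge.length)) {
    tot <- sum(rooted$edge.length[kids])
    rooted$edge.length[kids] <- tot / 2
  }
  rooted
}

#' Is a taxon set monophyletic in a rooted tree?
#'
#' TRUE iff some clade's leaf set equals `taxa` exactly.
#'
#' @param tree rooted `phylo` tree.
#' @param taxa character vector of leaf labels.
#' @return logical.
#' @export
is_monophyletic <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown) > 0)
    stop("unknown taxa: ", paste(unknown, collapse = ", "), call. = FALSE)
  ape::is.monophyletic(tree, taxa)
}

#' Parse a Newick string or file
#'
#' Parentheses are balance-checked first so malformed input fails with the
#' offending character position rather than a silent mis-parse.
#'
#' @param text Newick string (must contain the terminating `;`).
#' @return `phylo` tree.
#' @export
read_newick <- function(text) {
  depth <- 0L
  chars <- seq_chars(text)
  in_quote <- FALSE
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error: unbalanced ')' at position ", k,
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("newick parse error: ", depth, " unclosed '(' at end of input",
         call. = FALSE)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("newick parse error: unreadable tree", call. = FALSE)
  tr
}

#' Serialize a tree to Newick
#'
#' @param tree `phylo` tree.
#' @param digits branch-length precision (default 6).
#' @return Newick string. Round-trips through [read_newick()] preserve
#'   topology, labels, and branch lengths to `digits` decimals.
#' @export
write_newick <- function(tree, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}
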