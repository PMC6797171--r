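#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration producing an ultrametric rooted tree:
#' at each step the pair of clusters with the smallest average distance is
#' merged at height d/2, and distances to the merged cluster are
#' size-weighted averages. Ties are broken deterministically by merging
#' the pair whose (sorted) smallest member labels are lexicographically
#' smallest, so the result is permutation-invariant.
#'
#' @param d symmetric distance matrix (or `dist`) with labels.
#' @return An `ape::phylo` rooted ultrametric tree.
#' @export
upgmaTree <- function(d) {
    m <- as.matrix(d)
    .checkDistanceMatrix(m)
    labs <- rownames(m)
    n <- nrow(m)
    if (n < 2) stop("need at least two tips")
    # cluster state: newick fragment, height, size, representative label
    nwk <- labs
    height <- rep(0, n)
    size <- rep(1L, n)
    repLab <- labs
    active <- rep(TRUE, n)
    D <- m
    for (step in seq_len(n - 1L)) {
        idx <- which(active)
        best <- NULL; bestD <- Inf
        for (a in seq_along(idx)) {
            for (b in seq_len(a - 1L)) {
                i <- idx[b]; j <- idx[a]   # i < j in index order
                dij <- D[i, j]
                key <- sort(c(repLab[i], repLab[j]))
                if (dij < bestD - 1e-12 ||
                    (abs(dij - bestD) <= 1e-12 && !is.null(best) &&
                     .lexLess(key, best$key))) {
                    bestD <- dij
                    best <- list(i = i, j = j, key = key)
                }
            }
        }
        i <- best$i; j <- best$j
        h <- bestD / 2
        bi <- h - height[i]; bj <- h - height[j]
        nwk[i] <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], bi, nwk[j], bj)
        height[i] <- h
        # size-weighted average distances to the merged cluster
        for (t in which(active)) {
            if (t == i || t == j) next
            D[i, t] <- D[t, i] <-
                (size[i] * D[i, t] + size[j] * D[j, t]) / (size[i] + size[j])
        }
        size[i] <- size[i] + size[j]
        repLab[i] <- min(repLab[i], repLab[j])
        active[j] <- FALSE
    }
    root <- which(active)
    ape::read.tree(text = paste0(nwk[root], ";"))
}

.lexLess <- function(a, b) {
    if (a[1] != b[1]) return(a[1] < b[1])
    a[2] < b[2]
}

.checkDistanceMatrix <- function(m) {
    if (nrow(m) != ncol(m) || !isSymmetric(unname(m), tol = 1e-8))
        stop("distance matrix must be square and symmetric")
    if (any(diag(m) != 0))
        stop("distance matrix must have a zero diagonal")
    if (any(m < 0))
        stop("distances must be non-negative")
    if (is.null(rownames(m)))
        stop("distance matrix must carry labels")
    invisible(TRUE)
}

#' Build a population tree from a pairwise F_ST distance matrix
#'
#' Summarizes pairwise differentiation (typically [meanPdFstMatrix()]) as
#' a tree over population labels. `"upgma"` (default) gives a rooted
#' ultrametric dendrogram; `"nj"` gives a neighbor-joining tree via
#' `ape::nj`.
#'
#' @param d symmetric distance matrix with population labels.
#' @param method `"upgma"` or `"nj"`.
#' @param file optional path; when given, the tree is also written as
#'   newick via `ape::write.tree`.
#' @return An `ape::phylo` tree.
#' @examples
#' m <- matrix(c(0, .1, .4, .1, 0, .4, .4, .4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' buildPopulationTree(m)
#' @export
buildPopulationTree <- function(d, method = c("upgma", "nj"), file = NULL) {
    method <- match.arg(method)
    m <- as.matrix(d)
    .checkDistanceMatrix(m)
    tree <- if (method == "upgma") upgmaTree(m) else ape::nj(stats::as.dist(m))
    if (!is.null(file)) ape::write.tree(tree, file)
    tree
}
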