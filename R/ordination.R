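#' Principal coordinates analysis of a genetic distance matrix
#'
#' Metric multidimensional scaling: Gower-center \eqn{-\frac{1}{2} d^2} about
#' row and column means, eigendecompose, order axes by decreasing eigenvalue,
#' and express each positive eigenvalue as a percentage of the positive-part
#' total. For distance matrices that already hold *squared* distances (the
#' codominant squared genotypic distance), set `squared = TRUE` so the matrix
#' is not squared a second time.
#'
#' @param d An [ssr_dist] or symmetric zero-diagonal matrix.
#' @param squared Are the entries of `d` already squared distances? Defaults
#'   to `TRUE` for an [ssr_dist] of kind `"squared"`.
#' @param n_axes Number of axes to retain (default: all with positive
#'   eigenvalue).
#' @return An object of class `ssr_pcoa` with elements `coordinates` (tibble:
#'   `id`, `axis1`, `axis2`, ...), `eigenvalues`, `percent`, and
#'   `cumulative_percent` (percentages over positive eigenvalues only).
#' @examples
#' g <- simulate_ssr(ssr_sim_spec(seed = 1))$genotypes
#' ord <- pcoa(individual_squared_distances(g))
#' ord$percent[1:3]
#' @export
pcoa <- function(d, squared = NULL,
                 n_axes = NULL) {
  m <- unclass(d)
  if (is.null(squared)) {
    squared <- inherits(d, "ssr_dist") && identical(attr(d, "kind"), "squared")
  }
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("PCoA needs a symmetric matrix", call. = FALSE)
  }
  d2 <- if (squared) m else m^2
  b <- -0.5 * d2
  b <- sweep(b, 1, rowMeans(b))
  b <- sweep(b, 2, colMeans(b))
  eig <- eigen(b, symmetric = TRUE)
  pos <- eig$values > 1e-9 * max(abs(eig$values), 1e-12)
  if (!any(pos)) stop("no positive eigenvalue: degenerate distances", call. = FALSE)
  keep <- which(pos)
  if (!is.null(n_axes)) keep <- keep[seq_len(min(n_axes, length(keep)))]
  coords <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eig$values[keep]), length(keep))
  colnames(coords) <- paste0("axis", seq_along(keep))
  pct <- 100 * eig$values[keep] / sum(eig$values[pos])
  labels <- rownames(m) %||% paste0("item", seq_len(nrow(m)))
  structure(list(
    coordinates = dplyr::bind_cols(tibble(id = labels), as_tibble(coords)),
    eigenvalues = eig$values[keep],
    percent = pct,
    cumulative_percent = cumsum(pct)
  ), class = "ssr_pcoa")
}

#' @export
print.ssr_pcoa <- function(x, ...) {
  k <- min(3, length(x$percent))
  cat(sprintf(
    "Principal coordinates: %d items, %d axes; first %d axes explain %.2f%%\n",
    nrow(x$coordinates), length(x$percent), k, x$cumulative_percent[k]
  ))
  invisible(x)
}

#' @export
tidy.ssr_pcoa <- function(x, ...) {
  tidyr::pivot_longer(x$coordinates, -"id", names_to = "axis",
                      values_to = "coordinate")
}

#' @export
glance.ssr_pcoa <- function(x, ...) {
  k <- min(3, length(x$percent))
  tibble(
    n_axes = length(x$percent),
    percent_axis1 = x$percent[1],
    percent_axis2 = if (length(x$percent) > 1) x$percent[2] else NA_real_,
    percent_axis3 = if (length(x$percent) > 2) x$percent[3] else NA_real_,
    cumulative_first3 = x$cumulative_percent[k]
  )
}

#' UPGMA dendrogram of a distance matrix
#'
#' Agglomerative clustering with group-average linkage weighted by cluster
#' sizes; each merge node sits at half the merge distance, so the tree is
#' ultrametric with cophenetic distances equal to the merge distances. Ties
#' are broken deterministically by the lexicographically smallest pair of
#' cluster labels (a cluster is labelled by its smallest member).
#'
#' @param d An [ssr_dist] or symmetric zero-diagonal matrix with at least two
#'   items.
#' @return An `ssr_upgma` object: `tree` (an [ape::phylo]), `merge_heights`,
#'   and `newick` (the serialized tree). Write it with [write_newick()].
#' @examples
#' m <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(ssr_dist(m))
#' @export
upgma <- function(d) {
  m <- unclass(d)
  n <- nrow(m)
  if (n < 2) stop("UPGMA needs at least two items", call. = FALSE)
  labels <- rownames(m) %||% paste0("item", seq_len(n))
  active <- seq_len(n)
  size <- rep(1L, n)
  height <- rep(0, n)
  newick <- labels
  key <- labels            # lexicographic tie-break key: smallest member label
  dm <- m
  merge_heights <- numeric(0)
  for (step in seq_len(n - 1)) {
    best <- NULL
    for (ii in seq_along(active)[-1]) for (jj in seq_len(ii - 1)) {
      i <- active[ii]
      j <- active[jj]
      dij <- dm[i, j]
      pair_key <- sort(c(key[i], key[j]))
      if (is.null(best) || dij < best$d - 1e-12 ||
          (abs(dij - best$d) <= 1e-12 &&
           (pair_key[1] < best$key[1] ||
            (pair_key[1] == best$key[1] && pair_key[2] < best$key[2])))) {
        best <- list(i = i, j = j, d = dij, key = pair_key)
      }
    }
    i <- best$i
    j <- best$j
    h <- best$d / 2
    new <- length(size) + 1L
    size[new] <- size[i] + size[j]
    height[new] <- h
    key[new] <- min(key[i], key[j])
    newick[new] <- sprintf("(%s:%.10g,%s:%.10g)",
                           newick[i], h - height[i], newick[j], h - height[j])
    # size-weighted average linkage
    drow <- (size[i] * dm[i, active] + size[j] * dm[j, active]) /
      (size[i] + size[j])
    dm <- rbind(cbind(dm, 0), 0)
    dm[new, active] <- drow
    dm[active, new] <- drow
    dm[new, new] <- 0
    active <- c(setdiff(active, c(i, j)), new)
    merge_heights <- c(merge_heights, best$d)
  }
  tree <- ape::read.tree(text = paste0(newick[length(newick)], ";"))
  structure(list(tree = tree, merge_heights = merge_heights,
                 newick = paste0(newick[length(newick)], ";"),
                 labels = labels),
            class = "ssr_upgma")
}

#' @export
print.ssr_upgma <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram: %d leaves, root height %.4g\n",
              length(x$labels), max(x$merge_heights) / 2))
  invisible(x)
}

#' @rdname upgma
#' @param x An `ssr_upgma` object.
#' @param path Output Newick file.
#' @export
write_newick <- function(x, path) {
  stopifnot(inherits(x, "ssr_upgma"))
  writeLines(x$newick, path)
  invisible(path)
}

#' Cophenetic distances of a UPGMA dendrogram
#'
#' @param x An `ssr_upgma` object.
#' @return A `dist` of cophenetic (merge) distances between leaves.
#' @export
cophenetic.ssr_upgma <- function(x) stats::cophenetic(x$tree)
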