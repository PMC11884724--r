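#' Symmetric genetic distance matrices
#'
#' Thin matrix class tagging which genetic distance a symmetric, zero-diagonal
#' matrix holds (`"fst"`, `"nei"`, `"nm"`, `"squared"` genotypic,
#' `"shared_allele"`, or `"generic"`). [tidy()] turns one into a long tibble
#' of unordered pairs.
#'
#' @param m Symmetric numeric matrix with a zero diagonal and dimnames.
#' @param kind Distance kind tag.
#' @return An `ssr_dist` matrix.
#' @export
ssr_dist <- function(m, kind = "generic") {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("item", seq_len(nrow(m)))
  }
  fin <- is.finite(m)
  if (!isTRUE(all.equal(m[fin], t(m)[fin], tolerance = 1e-8))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(m)) > 1e-8, na.rm = TRUE)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  structure(m, kind = kind, class = c("ssr_dist", "matrix", "array"))
}

#' @export
print.ssr_dist <- function(x, ...) {
  cat(sprintf("<ssr_dist kind=%s> %d x %d\n", attr(x, "kind"), nrow(x), ncol(x)))
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' @export
tidy.ssr_dist <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(
    item1 = rownames(m)[idx[, 1]], item2 = colnames(m)[idx[, 2]],
    distance = m[idx], kind = attr(x, "kind")
  )
}

#' Squared genotypic distance between individuals
#'
#' Codominant squared distance (Smouse & Peakall), summed over the loci both
#' individuals have genotyped. Per locus the distance equals
#' \eqn{\frac{1}{2}\sum_a (x_a - y_a)^2} over allele dosage vectors, which
#' reproduces the canonical case table: identical genotypes 0; one shared
#' allele between heterozygotes, or heterozygote vs. its embedded homozygote,
#' 1; disjoint heterozygotes 2; homozygote vs. disjoint heterozygote 3;
#' disjoint homozygotes 4.
#'
#' @param g An [ssr_genotypes] table.
#' @return An [ssr_dist] matrix of kind `"squared"` over individuals.
#' @export
individual_squared_distances <- function(g) {
  ix <- genotype_index_matrices(g)
  n <- nrow(ix$a1)
  d <- matrix(0, n, n, dimnames = list(rownames(ix$a1), rownames(ix$a1)))
  shared <- matrix(0L, n, n)
  for (j in seq_len(ncol(ix$a1))) {
    a1 <- ix$a1[, j]
    a2 <- ix$a2[, j]
    ok <- a1 > 0L
    if (!any(ok)) next
    # dosage matrix individuals x alleles
    dos <- matrix(0, n, ix$n_alleles[j])
    dos[cbind(seq_len(n)[ok], a1[ok])] <- dos[cbind(seq_len(n)[ok], a1[ok])] + 1
    dos[cbind(seq_len(n)[ok], a2[ok])] <- dos[cbind(seq_len(n)[ok], a2[ok])] + 1
    sq <- rowSums(dos^2)
    cross <- tcrossprod(dos)
    dj <- 0.5 * (outer(sq, sq, "+") - 2 * cross)
    dj[!ok, ] <- 0
    dj[, !ok] <- 0
    d <- d + dj
    shared <- shared + outer(ok, ok, "&")
  }
  if (any(shared[upper.tri(shared)] == 0)) {
    stop("individual pair(s) share no genotyped locus", call. = FALSE)
  }
  diag(d) <- 0
  ssr_dist(d, kind = "squared")
}

#' Shared-allele distance between individuals
#'
#' \eqn{d(x, y) = 1 - \bar{s}/2} where, at each co-genotyped locus, `s` counts
#' the alleles the two diploid genotypes share (0, 1 or 2, matching allele
#' copies one-to-one) and the bar averages over those loci. The conventional
#' individual-level distance for SSR accession trees.
#'
#' @param g An [ssr_genotypes] table.
#' @return An [ssr_dist] matrix of kind `"shared_allele"`.
#' @export
shared_allele_distance <- function(g) {
  ix <- genotype_index_matrices(g)
  n <- nrow(ix$a1)
  s <- matrix(0, n, n)
  shared <- matrix(0L, n, n)
  for (j in seq_len(ncol(ix$a1))) {
    a1 <- ix$a1[, j]
    a2 <- ix$a2[, j]
    ok <- a1 > 0L
    if (!any(ok)) next
    # matched shared alleles between (p,q) and (r,t): the better of the two
    # one-to-one pairings equals the multiset intersection size
    m1 <- outer(a1, a1, "==") + outer(a2, a2, "==")
    m2 <- outer(a1, a2, "==") + outer(a2, a1, "==")
    sj <- pmax(m1, m2)
    sj[!ok, ] <- 0
    sj[, !ok] <- 0
    s <- s + sj
    shared <- shared + outer(ok, ok, "&")
  }
  if (any(shared[upper.tri(shared)] == 0)) {
    stop("individual pair(s) share no genotyped locus", call. = FALSE)
  }
  d <- 1 - (s / pmax(shared, 1L)) / 2
  diag(d) <- 0
  dimnames(d) <- list(rownames(ix$a1), rownames(ix$a1))
  ssr_dist(d, kind = "shared_allele")
}
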