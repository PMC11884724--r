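#' Codominant SSR genotype tables
#'
#' `ssr_genotypes()` validates a long genotype table and returns the package's
#' central data structure: one row per individual x locus, two allele columns
#' holding fragment sizes in base pairs. A diploid call is always stored as an
#' ordered pair `(a1 <= a2)`; a single observed band is scored as a homozygote
#' (the standard reading of codominant SSR gels); a missing call blanks both
#' slots. Every individual carries a population label.
#'
#' @param x A data frame with columns `id`, `pop`, `locus`, `a1`, `a2`
#'   (allele sizes, positive numbers; `NA` in both slots marks a missing call).
#'   A missing `a2` with an observed `a1` is promoted to a homozygote.
#' @param individuals,loci Optional character vectors fixing row/column order;
#'   defaults to order of first appearance.
#'
#' @return A tibble of class `ssr_genotypes` with attributes `individuals`,
#'   `loci` and `pops` recording display order.
#' @examples
#' g <- ssr_genotypes(data.frame(
#'   id = c("i1", "i1", "i2", "i2"), pop = "A",
#'   locus = c("L1", "L2", "L1", "L2"),
#'   a1 = c(150, 200, 154, NA), a2 = c(154, NA, 154, NA)
#' ))
#' n_individuals(g)
#' @export
ssr_genotypes <- function(x, individuals = NULL, loci = NULL) {
  x <- as_tibble(x)
  need <- c("id", "pop", "locus", "a1", "a2")
  if (!all(need %in% names(x))) {
    stop("genotype table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x <- dplyr::mutate(x,
    id = as.character(.data$id),
    pop = as.character(.data$pop),
    locus = as.character(.data$locus),
    a1 = as.numeric(.data$a1),
    a2 = as.numeric(.data$a2)
  )
  # single observed band -> homozygote
  one <- !is.na(x$a1) & is.na(x$a2)
  x$a2[one] <- x$a1[one]
  one <- is.na(x$a1) & !is.na(x$a2)
  x$a1[one] <- x$a2[one]
  # canonical (min, max) within the unordered pair
  swap <- !is.na(x$a1) & x$a1 > x$a2
  if (any(swap)) {
    tmp <- x$a1[swap]
    x$a1[swap] <- x$a2[swap]
    x$a2[swap] <- tmp
  }
  if (any(!is.na(x$a1) & x$a1 <= 0)) {
    stop("allele sizes must be positive", call. = FALSE)
  }
  pop_map <- dplyr::distinct(x, .data$id, .data$pop)
  if (anyDuplicated(pop_map$id)) {
    bad <- pop_map$id[duplicated(pop_map$id)]
    stop("individual(s) with more than one population label: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  individuals <- individuals %||% unique(x$id)
  loci <- loci %||% unique(x$locus)
  if (length(loci) < 1) stop("at least one locus required", call. = FALSE)
  if (length(individuals) < 2) {
    stop("at least two individuals required", call. = FALSE)
  }
  if (anyDuplicated(paste(x$id, x$locus))) {
    stop("duplicated (individual, locus) rows", call. = FALSE)
  }
  # complete the grid so every (id, locus) cell exists (missing call if absent)
  full <- tidyr::expand_grid(id = individuals, locus = loci)
  x <- dplyr::left_join(full, x, by = c("id", "locus"))
  x <- dplyr::left_join(
    dplyr::select(x, -"pop"), pop_map,
    by = "id"
  )
  x <- dplyr::select(x, "id", "pop", "locus", "a1", "a2")
  if (anyNA(x$pop)) {
    stop("individual(s) without a population label", call. = FALSE)
  }
  structure(x,
    individuals = individuals, loci = loci,
    pops = unique(pop_map$pop[match(individuals, pop_map$id)]),
    class = c("ssr_genotypes", class(x))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname ssr_genotypes
#' @param g An `ssr_genotypes` table.
#' @export
n_individuals <- function(g) length(attr(g, "individuals"))

#' @rdname ssr_genotypes
#' @export
n_loci <- function(g) length(attr(g, "loci"))

#' @rdname ssr_genotypes
#' @export
loci_of <- function(g) attr(g, "loci")

#' @rdname ssr_genotypes
#' @export
individuals_of <- function(g) attr(g, "individuals")

#' @rdname ssr_genotypes
#' @export
pops_of <- function(g) attr(g, "pops")

#' Population assignment of each individual
#'
#' @param g An `ssr_genotypes` table.
#' @return A tibble with columns `id`, `pop`, one row per individual in
#'   display order, and population sizes via [dplyr::count()].
#' @export
pop_table <- function(g) {
  tb <- dplyr::distinct(as_tibble(g), .data$id, .data$pop)
  tb[match(attr(g, "individuals"), tb$id), ]
}

#' @export
print.ssr_genotypes <- function(x, ...) {
  cat(sprintf(
    "<ssr_genotypes> %d individuals x %d loci, %d populations, %d missing calls\n",
    n_individuals(x), n_loci(x), length(attr(x, "pops")), sum(is.na(x$a1))
  ))
  NextMethod()
}

# allele matrix view used by distance and admixture code: two integer matrices
# (individual x locus) of allele-class indices per locus, 0 = missing
genotype_index_matrices <- function(g) {
  ids <- attr(g, "individuals")
  loci <- attr(g, "loci")
  a1 <- matrix(0L, length(ids), length(loci), dimnames = list(ids, loci))
  a2 <- a1
  n_alleles <- integer(length(loci))
  alleles <- vector("list", length(loci))
  for (j in seq_along(loci)) {
    sub <- g[g$locus == loci[j], ]
    sub <- sub[match(ids, sub$id), ]
    lev <- sort(unique(c(sub$a1, sub$a2)))
    lev <- lev[!is.na(lev)]
    alleles[[j]] <- lev
    n_alleles[j] <- length(lev)
    a1[, j] <- ifelse(is.na(sub$a1), 0L, match(sub$a1, lev))
    a2[, j] <- ifelse(is.na(sub$a2), 0L, match(sub$a2, lev))
  }
  list(a1 = a1, a2 = a2, alleles = alleles, n_alleles = n_alleles,
       pops = pop_table(g)$pop)
}
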