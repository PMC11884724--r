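#' Mean allelic patterns across populations
#'
#' Per population, averaged over loci: number of different alleles (Na), Na
#' restricted to alleles at frequency >= 5%, effective number of alleles
#' \eqn{Ne = 1/\sum p_i^2}, Shannon's information index
#' \eqn{I = -\sum p_i \ln p_i}, counts of private alleles (alleles seen in no
#' other population) and of locally common alleles (frequency >= 5% here,
#' present in at most 25% resp. 50% of populations — alleles confined to a
#' single population are private, not locally common, so they are excluded
#' from both counts), observed and expected heterozygosity, unbiased expected
#' heterozygosity \eqn{uHe = 2N/(2N-1) \cdot He}, and the fixation index
#' \eqn{F = 1 - Ho/He}.
#'
#' `F` is undefined at a monomorphic locus (`He = 0`); such loci are excluded
#' from the population's mean `F` only.
#'
#' @param g An [ssr_genotypes] table with at least one population.
#' @return A tibble with one row per population and columns `pop`, `na`,
#'   `na_freq5`, `ne`, `shannon_i`, `private`, `lcomm25`, `lcomm50`, `ho`,
#'   `he`, `uhe`, `f`. Append printed-style Max/Min rows with
#'   [add_summary_rows()].
#' @export
allelic_patterns <- function(g) {
  fr <- allele_frequencies(g, by = "pop")
  ho <- observed_heterozygosity(g, by = "pop")
  pops <- unique(pop_table(g)$pop)
  k <- length(pops)
  genotyped <- dplyr::distinct(fr, .data$locus, .data$pop)
  none <- setdiff(pops, unique(genotyped$pop))
  if (length(none)) {
    stop("population(s) with no genotyped individual at any locus: ",
         paste(none, collapse = ", "), call. = FALSE)
  }
  # in how many populations is each (locus, allele) present?
  occ <- dplyr::summarise(dplyr::group_by(fr, .data$locus, .data$allele),
                          n_pops = dplyr::n(), .groups = "drop")
  fr <- dplyr::left_join(fr, occ, by = c("locus", "allele"))
  per_cell <- dplyr::summarise(
    dplyr::group_by(fr, .data$pop, .data$locus),
    na = dplyr::n(),
    na_freq5 = sum(.data$freq >= 0.05),
    ne = 1 / sum(.data$freq^2),
    shannon_i = -sum(.data$freq * log(.data$freq)),
    private = sum(.data$n_pops == 1),
    lcomm25 = sum(.data$freq >= 0.05 & .data$n_pops >= 2 &
                    .data$n_pops <= floor(0.25 * k)),
    lcomm50 = sum(.data$freq >= 0.05 & .data$n_pops >= 2 &
                    .data$n_pops <= floor(0.50 * k)),
    he = 1 - sum(.data$freq^2),
    n = .data$n[1],
    .groups = "drop"
  )
  per_cell$uhe <- 2 * per_cell$n / (2 * per_cell$n - 1) * per_cell$he
  per_cell <- dplyr::left_join(per_cell, ho, by = c("pop", "locus", "n"))
  per_cell$f <- ifelse(per_cell$he > 0, 1 - per_cell$ho / per_cell$he, NA)
  out <- dplyr::summarise(
    dplyr::group_by(per_cell, .data$pop),
    dplyr::across(c("na", "na_freq5", "ne", "shannon_i", "private",
                    "lcomm25", "lcomm50", "ho", "he", "uhe"), mean),
    f = mean(.data$f, na.rm = TRUE),
    .groups = "drop"
  )
  out[match(pops, out$pop), ]
}
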