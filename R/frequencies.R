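#' Allele frequencies per locus
#'
#' Counts gene copies (2 per genotyped individual) and returns allele
#' frequencies either within each population or pooled over the whole sample.
#' Per-locus sample sizes `n` count genotyped individuals only: a missing call
#' drops both gene copies of that individual at that locus.
#'
#' @param g An [ssr_genotypes] table.
#' @param by `"pop"` for population-wise frequencies, `"total"` for the pooled
#'   sample.
#' @return A tibble with columns `locus`, (`pop`,) `allele`, `count`, `freq`,
#'   `n` (genotyped individuals behind the frequency). Each (locus, pop)
#'   frequency vector sums to 1. A locus with no genotyped individual in a
#'   population contributes no rows for that cell.
#' @export
allele_frequencies <- function(g, by = c("pop", "total")) {
  by <- match.arg(by)
  tb <- dplyr::filter(as_tibble(g), !is.na(.data$a1))
  long <- tidyr::pivot_longer(tb, c("a1", "a2"), values_to = "allele")
  keys <- if (by == "pop") c("locus", "pop") else "locus"
  n_tb <- dplyr::summarise(dplyr::group_by(tb, dplyr::across(dplyr::all_of(keys))),
                           n = dplyr::n(), .groups = "drop")
  out <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(c(keys, "allele")))),
    count = dplyr::n(), .groups = "drop"
  )
  out <- dplyr::left_join(out, n_tb, by = keys)
  out$freq <- out$count / (2 * out$n)
  dplyr::arrange(out, dplyr::across(dplyr::all_of(c(keys, "allele"))))
}

#' Observed heterozygosity per locus
#'
#' Fraction of genotyped individuals carrying two distinct alleles, per locus
#' (and optionally per population).
#'
#' @inheritParams allele_frequencies
#' @return A tibble `locus`, (`pop`,) `ho`, `n`.
#' @export
observed_heterozygosity <- function(g, by = c("pop", "total")) {
  by <- match.arg(by)
  tb <- dplyr::filter(as_tibble(g), !is.na(.data$a1))
  keys <- if (by == "pop") c("locus", "pop") else "locus"
  dplyr::summarise(
    dplyr::group_by(tb, dplyr::across(dplyr::all_of(keys))),
    ho = mean(.data$a1 != .data$a2), n = dplyr::n(), .groups = "drop"
  )
}
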