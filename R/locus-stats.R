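#' Per-locus diversity summary
#'
#' Pooled-sample marker statistics: major allele frequency (MAF), number of
#' alleles (Na), gene diversity \eqn{GD = 1 - \sum p_i^2}, polymorphic
#' information content
#' \eqn{PIC = 1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2} (Botstein's measure,
#' as computed by PowerMarker), and observed heterozygosity Ho. All
#' frequencies are taken over the pooled sample, which is how per-marker
#' screening tables are conventionally reported.
#'
#' @param g An [ssr_genotypes] table.
#' @return A tibble with one row per locus: `locus`, `maf`, `n`, `n_alleles`,
#'   `pic`, `ho`, `gene_diversity`. Loci with no genotyped individual are
#'   dropped.
#' @examples
#' g <- simulate_ssr(ssr_sim_spec(seed = 1))$genotypes
#' locus_summary(g)
#' @export
locus_summary <- function(g) {
  fr <- allele_frequencies(g, by = "total")
  ho <- observed_heterozygosity(g, by = "total")
  out <- dplyr::summarise(
    dplyr::group_by(fr, .data$locus),
    maf = max(.data$freq),
    n = .data$n[1],
    n_alleles = sum(.data$freq > 0),
    pic = pic_from_freqs(.data$freq),
    gene_diversity = 1 - sum(.data$freq^2),
    .groups = "drop"
  )
  out <- dplyr::left_join(out, dplyr::select(ho, "locus", "ho"), by = "locus")
  out <- dplyr::select(out, "locus", "maf", "n", "n_alleles", "pic", "ho",
                       "gene_diversity")
  out[match(intersect(loci_of(g), out$locus), out$locus), ]
}

pic_from_freqs <- function(p) {
  # 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2 ;
  # the cross term equals (sum p^2)^2 - sum p^4
  s2 <- sum(p^2)
  1 - s2 - (s2^2 - sum(p^4))
}

#' Mean / maximum / minimum rows for a per-locus or per-population table
#'
#' Appends the arithmetic-mean, maximum and minimum rows conventionally
#' printed under marker summary tables. Non-numeric columns carry the row
#' label in the first column.
#'
#' @param tb A tibble whose first column labels rows.
#' @param digits Optional rounding applied to the summary rows only.
#' @return `tb` with `Mean`, `Max`, `Min` rows appended.
#' @export
add_summary_rows <- function(tb, digits = NULL) {
  num <- vapply(tb, is.numeric, logical(1))
  smry <- function(f, label) {
    row <- tb[1, ]
    row[1, 1] <- label
    for (j in which(num)) {
      v <- f(tb[[j]][is.finite(tb[[j]])])
      row[[j]] <- if (is.null(digits)) v else round(v, digits)
    }
    for (j in which(!num)[-1]) row[[j]] <- NA
    row
  }
  dplyr::bind_rows(tb, smry(mean, "Mean"), smry(max, "Max"), smry(min, "Min"))
}

#' Grade a marker's informativeness from its PIC value
#'
#' Standard interpretation bands: PIC above 0.5 is highly informative,
#' 0.25–0.5 moderately informative, below 0.25 slightly informative.
#'
#' @param pic Numeric vector in `[0, 1]`.
#' @return Factor with levels `slightly`, `moderately`, `highly` informative.
#' @examples
#' classify_pic(c(0.8, 0.25, 0.1))
#' @export
classify_pic <- function(pic) {
  if (any(is.na(pic)) || any(pic < 0 | pic > 1)) {
    stop("PIC values must lie in [0, 1]", call. = FALSE)
  }
  lev <- c("slightly informative", "moderately informative",
           "highly informative")
  # bands: [0, 0.25) / [0.25, 0.5] / (0.5, 1]
  factor(lev[1 + (pic >= 0.25) + (pic > 0.5)], levels = lev)
}
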