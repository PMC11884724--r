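#' Per-locus F-statistics and gene flow over all populations
#'
#' For each locus, population-wise expected and observed heterozygosities are
#' averaged arithmetically (unweighted) over the populations in which the
#' locus is genotyped. Total expected heterozygosity uses the total allele
#' frequency \eqn{tp_i}: by default the unweighted mean of the population
#' frequencies (the GenAlEx convention, consistent with the unweighted mean
#' He), optionally the pooled gene-copy count. Then
#' \deqn{F_{IS} = (\bar{He} - \bar{Ho})/\bar{He},\quad
#'       F_{IT} = (H_T - \bar{Ho})/H_T,\quad
#'       F_{ST} = (H_T - \bar{He})/H_T,\quad
#'       N_m = ((1/F_{ST}) - 1)/4.}
#'
#' `Fis` is undefined where `mean He = 0`, and `Nm` is `Inf` where `Fst = 0`;
#' undefined cells are excluded from the column means that
#' [add_summary_rows()] appends.
#'
#' @param g An [ssr_genotypes] table with at least two populations.
#' @param total_freq `"mean"` (unweighted average of population frequencies,
#'   default) or `"pooled"` (gene-copy counts pooled over populations).
#' @return A tibble with one row per locus: `locus`, `ht`, `mean_he`,
#'   `mean_ho`, `fis`, `fit`, `fst`, `nm`.
#' @examples
#' g <- simulate_ssr(ssr_sim_spec(seed = 1))$genotypes
#' per_locus_fstats(g)
#' @export
per_locus_fstats <- function(g, total_freq = c("mean", "pooled")) {
  total_freq <- match.arg(total_freq)
  if (length(unique(pop_table(g)$pop)) < 2) {
    stop("F-statistics need at least two populations", call. = FALSE)
  }
  fr <- allele_frequencies(g, by = "pop")
  ho <- observed_heterozygosity(g, by = "pop")
  per_pop <- dplyr::summarise(
    dplyr::group_by(fr, .data$locus, .data$pop),
    he = 1 - sum(.data$freq^2), .groups = "drop"
  )
  per_pop <- dplyr::left_join(per_pop, ho, by = c("locus", "pop"))
  means <- dplyr::summarise(
    dplyr::group_by(per_pop, .data$locus),
    mean_he = mean(.data$he), mean_ho = mean(.data$ho),
    n_pops = dplyr::n(), .groups = "drop"
  )
  ht <- total_heterozygosity(fr, g, total_freq)
  out <- dplyr::left_join(means, ht, by = "locus")
  out$fis <- ifelse(out$mean_he > 0,
                    (out$mean_he - out$mean_ho) / out$mean_he, NA)
  out$fit <- ifelse(out$ht > 0, (out$ht - out$mean_ho) / out$ht, NA)
  out$fst <- ifelse(out$ht > 0, (out$ht - out$mean_he) / out$ht, NA)
  out$nm <- gene_flow(out$fst)
  out <- dplyr::select(out, "locus", "ht", "mean_he", "mean_ho",
                       "fis", "fit", "fst", "nm")
  out[match(intersect(loci_of(g), out$locus), out$locus), ]
}

total_heterozygosity <- function(fr_pop, g, total_freq) {
  if (total_freq == "mean") {
    # tp_i = unweighted mean of population frequencies (0 where absent)
    tp <- dplyr::summarise(
      dplyr::group_by(fr_pop, .data$locus, .data$allele),
      s = sum(.data$freq), .groups = "drop_last"
    )
    npop <- dplyr::summarise(
      dplyr::group_by(dplyr::distinct(fr_pop, .data$locus, .data$pop), .data$locus),
      k = dplyr::n(), .groups = "drop"
    )
    tp <- dplyr::left_join(dplyr::ungroup(tp), npop, by = "locus")
    tp$tp <- tp$s / tp$k
  } else {
    tot <- allele_frequencies(g, by = "total")
    tp <- dplyr::rename(tot, tp = "freq")
  }
  dplyr::summarise(dplyr::group_by(tp, .data$locus),
                   ht = 1 - sum(.data$tp^2), .groups = "drop")
}

#' Gene flow from genetic differentiation
#'
#' Effective number of migrants per generation under the island model:
#' \eqn{N_m = ((1/F_{ST}) - 1)/4}. Applied elementwise; `Fst = 0` maps to
#' `Inf` (unrestricted gene flow) and `Fst = 1` to 0.
#'
#' @param fst Numeric vector, matrix, or [pairwise_fst()] result with values
#'   in `[0, 1]`.
#' @return Object of the same shape with Nm values.
#' @examples
#' gene_flow(c(0.2, 1))
#' @export
gene_flow <- function(fst) {
  if (inherits(fst, "ssr_dist")) {
    m <- unclass(fst)
    nm <- gene_flow(m)
    diag(nm) <- 0
    return(ssr_dist(nm, kind = "nm"))
  }
  ok <- !is.na(fst)
  if (any(ok & (fst < 0 | fst > 1))) {
    stop("Fst values must lie in [0, 1]", call. = FALSE)
  }
  ifelse(ok & fst > 0, ((1 / fst) - 1) / 4, ifelse(ok, Inf, NA))
}

#' Pairwise population differentiation (Fst)
#'
#' For every pair of populations, the two-population Fst is computed per locus
#' as \eqn{(H_T - \bar{He})/H_T} from the pair's mean-frequency \eqn{H_T} and
#' unweighted mean He, then averaged arithmetically over loci (loci
#' monomorphic across the pair are undefined and excluded from the average).
#'
#' @param g An [ssr_genotypes] table.
#' @return An [ssr_dist] matrix of kind `"fst"`.
#' @export
pairwise_fst <- function(g) {
  fr <- allele_frequencies(g, by = "pop")
  per_pop_he <- dplyr::summarise(
    dplyr::group_by(fr, .data$locus, .data$pop),
    he = 1 - sum(.data$freq^2), .groups = "drop"
  )
  pops <- unique(pop_table(g)$pop)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-1]) for (j in seq_len(i - 1)) {
    sub <- dplyr::filter(fr, .data$pop %in% pops[c(i, j)])
    both <- intersect(sub$locus[sub$pop == pops[i]],
                      sub$locus[sub$pop == pops[j]])
    if (!length(both)) {
      m[i, j] <- m[j, i] <- NA
      next
    }
    sub <- dplyr::filter(sub, .data$locus %in% both)
    ht <- dplyr::summarise(
      dplyr::group_by(sub, .data$locus, .data$allele),
      tp = sum(.data$freq) / 2, .groups = "drop_last"
    )
    ht <- dplyr::summarise(ht, ht = 1 - sum(.data$tp^2), .groups = "drop")
    he <- dplyr::summarise(
      dplyr::group_by(
        dplyr::filter(per_pop_he, .data$pop %in% pops[c(i, j)],
                      .data$locus %in% both),
        .data$locus
      ),
      mean_he = mean(.data$he), .groups = "drop"
    )
    d <- dplyr::left_join(ht, he, by = "locus")
    fst_l <- ifelse(d$ht > 0, (d$ht - d$mean_he) / d$ht, NA)
    m[i, j] <- m[j, i] <- mean(fst_l, na.rm = TRUE)
  }
  ssr_dist(m, kind = "fst")
}

#' Nei genetic distance between populations
#'
#' Standard genetic distance \eqn{D = -\ln(J_{xy} / \sqrt{J_x J_y})}, where
#' the gene identities \eqn{J_{xy} = \sum_l \sum_i p_{xi} p_{yi}},
#' \eqn{J_x = \sum_l \sum_i p_{xi}^2} are accumulated over all shared loci.
#' The unbiased variant replaces each within-population identity by its
#' small-sample-corrected value \eqn{(2N \sum p_i^2 - 1)/(2N - 1)} per locus.
#' Disjoint allele sets give `Inf` (\eqn{-\ln 0}).
#'
#' @param g An [ssr_genotypes] table.
#' @param variant `"nei1972"` (standard) or `"nei1978"` (unbiased).
#' @return An [ssr_dist] matrix of kind `"nei"`.
#' @export
nei_distance <- function(g, variant = c("nei1972", "nei1978")) {
  variant <- match.arg(variant)
  fr <- allele_frequencies(g, by = "pop")
  pops <- unique(pop_table(g)$pop)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-1]) for (j in seq_len(i - 1)) {
    x <- dplyr::filter(fr, .data$pop == pops[i])
    y <- dplyr::filter(fr, .data$pop == pops[j])
    both <- intersect(x$locus, y$locus)
    x <- dplyr::filter(x, .data$locus %in% both)
    y <- dplyr::filter(y, .data$locus %in% both)
    xy <- dplyr::inner_join(x, y, by = c("locus", "allele"),
                            suffix = c("_x", "_y"))
    jxy <- sum(xy$freq_x * xy$freq_y)
    jwithin <- function(tb) {
      per <- dplyr::summarise(dplyr::group_by(tb, .data$locus),
                              j = if (variant == "nei1978") {
                                (2 * .data$n[1] * sum(.data$freq^2) - 1) /
                                  (2 * .data$n[1] - 1)
                              } else sum(.data$freq^2),
                              .groups = "drop")
      sum(per$j)
    }
    d <- if (jxy <= 0) Inf else -log(jxy / sqrt(jwithin(x) * jwithin(y)))
    m[i, j] <- m[j, i] <- max(d, 0)
  }
  ssr_dist(m, kind = "nei")
}

#' Interpretation grades for differentiation and gene flow
#'
#' Conventional bands: Fst below 0.05 low, 0.05–0.15 medium, 0.15 and above
#' high differentiation; Nm of 1.0 or more high, 0.25–1.0 medium, below 0.25
#' low gene flow.
#'
#' @param fst,nm Non-negative numeric vectors.
#' @return Factor with levels `low`, `medium`, `high`.
#' @examples
#' grade_fst(c(0.19, 0.05, 0.01))
#' grade_nm(1.15)
#' @export
grade_fst <- function(fst) {
  if (any(fst < 0, na.rm = TRUE)) stop("Fst must be >= 0", call. = FALSE)
  lev <- c("low", "medium", "high")
  factor(lev[1 + (fst >= 0.05) + (fst >= 0.15)], levels = lev)
}

#' @rdname grade_fst
#' @export
grade_nm <- function(nm) {
  if (any(nm < 0, na.rm = TRUE)) stop("Nm must be >= 0", call. = FALSE)
  lev <- c("low", "medium", "high")
  factor(lev[1 + (nm >= 0.25) + (nm >= 1.0)], levels = lev)
}
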