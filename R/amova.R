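#' Analysis of molecular variance (AMOVA)
#'
#' Two-level, distance-based AMOVA partitioning squared genetic distances
#' among and within populations. With `N` individuals in `k` populations and
#' squared distances `d2`:
#' \deqn{SS_{total} = \frac{1}{N}\sum_{i<j} d^2_{ij},\qquad
#'       SS_{within} = \sum_p \frac{1}{n_p}\sum_{i<j \in p} d^2_{ij},}
#' \eqn{SS_{among} = SS_{total} - SS_{within}}; mean squares divide by
#' \eqn{df = (k-1, N-k)}; \eqn{\sigma^2_{within} = MS_{within}} and
#' \eqn{\sigma^2_{among} = (MS_{among} - MS_{within})/n_0} with
#' \eqn{n_0 = (N - \sum n_p^2/N)/(k-1)}. Negative components are truncated to
#' zero before percentages. Significance of the among-population component is
#' assessed by permuting individuals across populations and counting
#' permutations with \eqn{\sigma^2_{among}} at least the observed value,
#' with the observed configuration included:
#' \eqn{p = (\#\{\sigma^2_{perm} \ge \sigma^2_{obs}\} + 1)/(n_{perm} + 1)}.
#'
#' If every pairwise distance is zero the partition is reported as 0% among /
#' 100% within with `p = 1`.
#'
#' @param d An [ssr_dist] of squared distances between individuals (see
#'   [individual_squared_distances()]), or any symmetric squared-distance
#'   matrix with individual labels.
#' @param pops Population label per individual, in the matrix's row order, or
#'   a `pop_table()`-style data frame with `id`, `pop`.
#' @param n_perm Number of label permutations (default 999); `0` skips the
#'   test.
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `ssr_amova`; `tidy()` gives the
#'   Among/Within/Total table (`df`, `SS`, `MS`, variance component, percent),
#'   `glance()` the one-row summary with the permutation p-value.
#' @examples
#' g <- simulate_ssr(ssr_sim_spec(seed = 1))$genotypes
#' fit <- run_amova(individual_squared_distances(g), pop_table(g), n_perm = 99)
#' tidy(fit)
#' @export
run_amova <- function(d, pops, n_perm = 999, seed = 1L) {
  m <- unclass(d)
  if (is.data.frame(pops)) {
    pops <- pops$pop[match(rownames(m), pops$id)]
  }
  pops <- as.character(pops)
  stopifnot(length(pops) == nrow(m))
  sizes <- table(pops)
  if (length(sizes) < 2) stop("AMOVA needs at least two populations", call. = FALSE)
  if (any(sizes < 2)) {
    stop("singleton population(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  n <- nrow(m)
  k <- length(sizes)
  comp <- amova_components(m, pops)
  df <- c(k - 1, n - k, n - 1)
  ss <- c(comp$ss_among, comp$ss_within, comp$ss_among + comp$ss_within)
  ms <- c(ss[1] / df[1], ss[2] / df[2], NA)
  sigma <- c(comp$var_among, comp$var_within)
  total_var <- sum(sigma)
  pct <- if (total_var > 0) 100 * sigma / total_var else c(0, 100)
  p_value <- NA_real_
  if (n_perm >= 1) {
    if (total_var == 0) {
      p_value <- 1
    } else {
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(seed)
      hits <- 0L
      for (b in seq_len(n_perm)) {
        vb <- amova_components(m, sample(pops))$var_among
        if (vb >= comp$var_among) hits <- hits + 1L
      }
      p_value <- (hits + 1) / (n_perm + 1)
    }
  }
  structure(list(
    table = tibble(
      source = c("Among Pops", "Within Pops", "Total"),
      df = df, SS = ss, MS = ms,
      variance = c(sigma, total_var),
      percent = c(pct, 100)
    ),
    p_value = p_value, n_perm = if (n_perm >= 1) n_perm else 0L,
    seed = seed, sizes = as.integer(sizes)
  ), class = "ssr_amova")
}

amova_components <- function(m, pops) {
  n <- nrow(m)
  k <- length(unique(pops))
  half <- m
  half[lower.tri(half, diag = TRUE)] <- 0
  ss_total <- sum(half) / n
  ss_within <- 0
  for (p in unique(pops)) {
    sel <- pops == p
    ss_within <- ss_within + sum(half[sel, sel]) / sum(sel)
  }
  ss_among <- ss_total - ss_within
  sizes <- table(pops)
  n0 <- (n - sum(sizes^2) / n) / (k - 1)
  ms_within <- ss_within / (n - k)
  ms_among <- ss_among / (k - 1)
  list(
    ss_among = ss_among, ss_within = ss_within,
    var_within = ms_within,
    var_among = max((ms_among - ms_within) / n0, 0)
  )
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' @export
print.ssr_amova <- function(x, ...) {
  cat("Analysis of molecular variance\n")
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  if (!is.na(x$p_value)) {
    cat(sprintf("Among-population p-value: %.4g (%d permutations)\n",
                x$p_value, x$n_perm))
  }
  invisible(x)
}

#' @export
tidy.ssr_amova <- function(x, ...) x$table

#' @export
glance.ssr_amova <- function(x, ...) {
  tibble(
    percent_among = x$table$percent[1],
    percent_within = x$table$percent[2],
    p_value = x$p_value,
    n_perm = x$n_perm,
    n_populations = length(x$sizes),
    n_individuals = sum(x$sizes)
  )
}
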