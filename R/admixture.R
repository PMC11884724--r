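#' Bayesian admixture clustering of SSR genotypes
#'
#' Model-based clustering in the STRUCTURE family: each individual's genome is
#' a mixture over `k` clusters with proportions `Q`, each cluster holds allele
#' frequencies `P` per locus, and the correlated-allele-frequencies (F-model)
#' prior ties cluster frequencies to ancestral frequencies through per-cluster
#' drift parameters. Inference is a Gibbs sampler over allele-copy origins,
#' `P`, `Q`, with Metropolis moves for the ancestral frequencies, the drift
#' parameters and the Dirichlet ancestry parameter `alpha`. The data
#' log-likelihood is recorded every post-burn-in sweep and summarised as
#' STRUCTURE's model evidence estimate
#' \eqn{\ln P(D) = \overline{\ln L} - \mathrm{var}(\ln L)/2}.
#' Missing calls contribute nothing to the likelihood.
#'
#' Defaults follow common SSR practice (burn-in 30000, 15000 recorded sweeps,
#' `alpha` initial 1 with a uniform(0, 10) hyperprior and proposal sd 0.025,
#' drift initial 0.01, frequency prior strength `lambda = 1`). A burn-in
#' longer than the recorded run is legitimate but unusual; it is noted with a
#' message.
#'
#' @param g An [ssr_genotypes] table.
#' @param k Number of ancestral clusters (>= 1).
#' @param burnin Discarded sweeps before recording.
#' @param reps Recorded sweeps.
#' @param seed Integer seed; identical seed and input give identical traces.
#' @param lambda Strength of the ancestral-frequency prior.
#' @param alpha_init,alpha_max,alpha_prop_sd Initial value, uniform-prior
#'   upper bound and Metropolis step of the ancestry Dirichlet parameter.
#' @param f_init,f_prior_mean,f_prior_sd Initial drift value and its gamma
#'   prior moments.
#' @return An `ssr_admixture` object: `Q` (posterior-mean ancestry tibble with
#'   `id`, `pop`, `cluster1..k`), `P` (per-locus cluster allele frequencies),
#'   `loglik` and `alpha` traces, `ln_pd`, `k`, `burnin`, `reps`, `seed`.
#' @examples
#' g <- simulate_ssr(ssr_sim_spec(
#'   sizes = c(25, 25), fst = 0.3, fis = 0, seed = 1
#' ))$genotypes
#' fit <- run_admixture(g, k = 2, burnin = 200, reps = 200, seed = 1)
#' glance(fit)
#' @export
run_admixture <- function(g, k, burnin = 30000, reps = 15000, seed = 1L,
                          lambda = 1, alpha_init = 1, alpha_max = 10,
                          alpha_prop_sd = 0.025, f_init = 0.01,
                          f_prior_mean = 0.01, f_prior_sd = 0.05) {
  stopifnot(inherits(g, "ssr_genotypes"), k >= 1)
  if (reps < 1) stop("reps must be >= 1 to estimate ln P(D)", call. = FALSE)
  if (burnin > reps) {
    message("burn-in (", burnin, ") exceeds recorded sweeps (", reps,
            "); proceeding as requested")
  }
  ix <- genotype_index_matrices(g)
  n_distinct_mlg <- nrow(unique(cbind(ix$a1, ix$a2)))
  if (k > n_distinct_mlg) {
    warning("k exceeds the number of distinct multilocus genotypes (",
            n_distinct_mlg, ")", call. = FALSE)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  fit <- .admixture_gibbs(ix$a1, ix$a2, ix$n_alleles, as.integer(k),
                          as.integer(burnin), as.integer(reps),
                          lambda, alpha_init, alpha_max, alpha_prop_sd,
                          f_init, f_prior_mean, f_prior_sd)
  q <- fit$Q
  colnames(q) <- paste0("cluster", seq_len(k))
  pt <- pop_table(g)
  names(fit$P) <- loci_of(g)
  for (l in seq_along(fit$P)) colnames(fit$P[[l]]) <- ix$alleles[[l]]
  ll <- as.numeric(fit$loglik)
  structure(list(
    Q = dplyr::bind_cols(pt, as_tibble(q)),
    P = fit$P,
    loglik = ll,
    alpha = as.numeric(fit$alpha),
    drift = as.numeric(fit$F),
    ln_pd = mean(ll) - var_or_zero(ll) / 2,
    k = as.integer(k), burnin = as.integer(burnin), reps = as.integer(reps),
    seed = as.integer(seed)
  ), class = "ssr_admixture")
}

var_or_zero <- function(x) if (length(x) > 1) stats::var(x) else 0

#' @export
print.ssr_admixture <- function(x, ...) {
  cat(sprintf("Admixture fit: k = %d, ln P(D) = %.2f (%d + %d sweeps, seed %d)\n",
              x$k, x$ln_pd, x$burnin, x$reps, x$seed))
  invisible(x)
}

#' @export
tidy.ssr_admixture <- function(x, ...) {
  tidyr::pivot_longer(x$Q, dplyr::starts_with("cluster"),
                      names_to = "cluster", values_to = "ancestry")
}

#' @export
glance.ssr_admixture <- function(x, ...) {
  tibble(k = x$k, ln_pd = x$ln_pd,
         mean_loglik = mean(x$loglik), sd_loglik = stats::sd(x$loglik),
         mean_alpha = mean(x$alpha), burnin = x$burnin, reps = x$reps,
         seed = x$seed)
}

#' Align cluster labels across admixture runs
#'
#' Cluster labels are arbitrary, so independent runs of the same `k` can name
#' the same clusters differently (label switching). This permutes each run's
#' cluster columns to best match the first run, greedily pairing columns by
#' smallest summed absolute difference in ancestry.
#'
#' @param runs List of `ssr_admixture` fits sharing `k` and individuals.
#' @return The list with `Q` (and `P`, `drift`) columns consistently permuted.
#' @export
align_labels <- function(runs) {
  stopifnot(length(runs) >= 1)
  ks <- vapply(runs, function(r) r$k, integer(1))
  if (length(unique(ks)) != 1) {
    stop("runs must share the same k", call. = FALSE)
  }
  k <- ks[1]
  if (k == 1 || length(runs) == 1) return(runs)
  q_cols <- function(r) as.matrix(r$Q[paste0("cluster", seq_len(k))])
  ref <- q_cols(runs[[1]])
  for (r in seq_along(runs)[-1]) {
    qr <- q_cols(runs[[r]])
    cost <- matrix(0, k, k)
    for (a in seq_len(k)) for (b in seq_len(k)) {
      cost[a, b] <- sum(abs(ref[, a] - qr[, b]))
    }
    perm <- integer(k)
    taken <- rep(FALSE, k)
    for (a in order(apply(cost, 1, min))) {
      b <- order(cost[a, ])
      b <- b[!taken[b]][1]
      perm[a] <- b
      taken[b] <- TRUE
    }
    runs[[r]]$Q[paste0("cluster", seq_len(k))] <- qr[, perm, drop = FALSE]
    runs[[r]]$P <- lapply(runs[[r]]$P, function(p) p[perm, , drop = FALSE])
    runs[[r]]$drift <- runs[[r]]$drift[perm]
  }
  runs
}

#' Evanno delta-K selection of the number of clusters
#'
#' Summarises replicate admixture runs over consecutive `k` values by
#' \eqn{L(K)} = mean \eqn{\ln P(D)}, its successive differences
#' \eqn{L'(K)}, \eqn{|L''(K)|}, and
#' \eqn{\Delta K = |L''(K)| / \mathrm{sd}(L(K))}. The selected `k` maximises
#' \eqn{\Delta K} over interior `k` values; if no \eqn{\Delta K} is defined
#' (e.g. perfectly linear \eqn{L(K)}, or zero run-to-run spread) the selection
#' is reported as `NA` (inconclusive).
#'
#' @param runs List of `ssr_admixture` fits covering at least three
#'   consecutive `k` values with at least two runs each.
#' @return An `ssr_evanno` object: `table` (tibble with `k`, `n_runs`,
#'   `mean_ln_pd`, `sd_ln_pd`, `l_prime`, `l_second`, `delta_k`) and
#'   `selected_k`.
#' @export
evanno <- function(runs) {
  ks <- vapply(runs, function(r) r$k, integer(1))
  tb <- tibble(
    k = ks, ln_pd = vapply(runs, function(r) r$ln_pd, numeric(1))
  )
  smry <- dplyr::summarise(
    dplyr::group_by(tb, .data$k),
    n_runs = dplyr::n(),
    mean_ln_pd = mean(.data$ln_pd),
    sd_ln_pd = stats::sd(.data$ln_pd),
    .groups = "drop"
  )
  smry <- dplyr::arrange(smry, .data$k)
  if (nrow(smry) < 3 || any(diff(smry$k) != 1)) {
    stop("evanno needs at least three consecutive k values", call. = FALSE)
  }
  if (any(smry$n_runs < 2)) {
    stop("evanno needs at least two runs per k", call. = FALSE)
  }
  m <- smry$mean_ln_pd
  nk <- nrow(smry)
  l_prime <- c(NA, diff(m))
  l_second <- c(NA, abs(diff(m, differences = 2)), NA)
  delta_k <- l_second / smry$sd_ln_pd
  zero_sd <- !is.na(l_second) & smry$sd_ln_pd == 0
  if (any(zero_sd)) {
    warning("zero run-to-run spread at k = ",
            paste(smry$k[zero_sd], collapse = ", "),
            "; delta-K undefined there", call. = FALSE)
    delta_k[zero_sd] <- NA
  }
  smry$l_prime <- l_prime
  smry$l_second <- l_second
  smry$delta_k <- delta_k
  usable <- which(!is.na(delta_k) & delta_k > 0)
  selected <- if (length(usable)) smry$k[usable[which.max(delta_k[usable])]] else NA_integer_
  structure(list(table = smry, selected_k = selected), class = "ssr_evanno")
}

#' @export
print.ssr_evanno <- function(x, ...) {
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  cat("selected k:", x$selected_k, "\n")
  invisible(x)
}

#' @export
tidy.ssr_evanno <- function(x, ...) x$table

#' @export
glance.ssr_evanno <- function(x, ...) {
  tibble(selected_k = x$selected_k,
         max_delta_k = suppressWarnings(max(x$table$delta_k, na.rm = TRUE)))
}
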