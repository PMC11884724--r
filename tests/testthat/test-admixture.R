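two_cluster_fit <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      sim <- simulate_ssr(ssr_sim_spec(sizes = c(30, 30), fst = 0.3, fis = 0,
                                       n_alleles = rep(8, 13), seed = 5))
      memo <<- list(
        g = sim$genotypes,
        fit = run_admixture(sim$genotypes, k = 2, burnin = 500, reps = 500,
                            seed = 11)
      )
    }
    memo
  }
})

test_that("k = 1 forces unit ancestry and a finite ln P(D)", {
  g <- simulate_ssr(ssr_sim_spec(sizes = c(5, 5), seed = 2))$genotypes
  fit <- run_admixture(g, k = 1, burnin = 50, reps = 100, seed = 1)
  expect_true(all(fit$Q$cluster1 == 1))
  expect_true(is.finite(fit$ln_pd))
  expect_length(fit$loglik, 100)
})

test_that("identical seed and input reproduce the traces exactly", {
  g <- simulate_ssr(ssr_sim_spec(sizes = c(6, 6), seed = 3))$genotypes
  f1 <- run_admixture(g, k = 2, burnin = 50, reps = 80, seed = 9)
  f2 <- run_admixture(g, k = 2, burnin = 50, reps = 80, seed = 9)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$Q, f2$Q)
  f3 <- run_admixture(g, k = 2, burnin = 50, reps = 80, seed = 10)
  expect_false(identical(f1$loglik, f3$loglik))
})

test_that("posterior means stay on the simplex and traces are finite", {
  fit <- two_cluster_fit()$fit
  q <- as.matrix(fit$Q[c("cluster1", "cluster2")])
  expect_equal(unname(rowSums(q)), rep(1, nrow(q)), tolerance = 1e-9)
  expect_true(all(q >= 0))
  for (p in fit$P) expect_equal(unname(rowSums(p)), rep(1, nrow(p)),
                                tolerance = 1e-9)
  expect_true(all(is.finite(fit$loglik)))
  expect_length(fit$alpha, fit$reps)
})

test_that("well-separated clusters are recovered", {
  memo <- two_cluster_fit()
  q <- as.matrix(memo$fit$Q[c("cluster1", "cluster2")])
  assign <- apply(q, 1, which.max)
  truth <- rep(1:2, each = 30)
  acc <- max(mean(assign == truth), mean(assign == 3 - truth))
  expect_gte(acc, 0.9)
})

test_that("likelihood climbs during burn-in on separable data", {
  g <- two_cluster_fit()$g
  fit <- run_admixture(g, k = 2, burnin = 0, reps = 600, seed = 4)
  ll <- fit$loglik
  early <- mean(ll[1:50])
  late <- mean(ll[(length(ll) - 99):length(ll)])
  expect_gt(late, early)
})

test_that("missing calls are tolerated and excluded from the likelihood", {
  sim <- simulate_ssr(ssr_sim_spec(sizes = c(10, 10), fst = 0.3, fis = 0,
                                   missing_rate = 0.3, seed = 8))
  fit <- run_admixture(sim$genotypes, k = 2, burnin = 100, reps = 100, seed = 2)
  expect_true(all(is.finite(fit$loglik)))
  n_calls <- sum(!is.na(sim$genotypes$a1))
  # per-copy mean log-likelihood should be a sane categorical log-probability
  expect_lt(mean(fit$loglik) / (2 * n_calls), 0)
})

test_that("label alignment undoes a column swap and is a no-op for k = 1", {
  fit <- two_cluster_fit()$fit
  swapped <- fit
  swapped$Q[c("cluster1", "cluster2")] <- fit$Q[c("cluster2", "cluster1")]
  swapped$P <- lapply(fit$P, function(p) p[2:1, , drop = FALSE])
  swapped$drift <- fit$drift[2:1]
  aligned <- align_labels(list(fit, swapped))
  expect_equal(aligned[[2]]$Q, fit$Q)
  expect_equal(aligned[[2]]$P, fit$P)
  g <- two_cluster_fit()$g
  f1 <- run_admixture(g, k = 1, burnin = 10, reps = 20, seed = 1)
  expect_identical(align_labels(list(f1, f1)), list(f1, f1))
  expect_error(align_labels(list(fit, f1)), "same k")
})

test_that("independent seeds agree after alignment on separable data", {
  g <- two_cluster_fit()$g
  f1 <- run_admixture(g, k = 2, burnin = 400, reps = 400, seed = 21)
  f2 <- run_admixture(g, k = 2, burnin = 400, reps = 400, seed = 22)
  al <- align_labels(list(f1, f2))
  dq <- abs(as.matrix(al[[1]]$Q[c("cluster1", "cluster2")]) -
              as.matrix(al[[2]]$Q[c("cluster1", "cluster2")]))
  expect_lt(mean(dq), 0.1)
})

test_that("an admixed individual's ancestry is estimated near one half", {
  set.seed(1)
  sim <- simulate_ssr(ssr_sim_spec(sizes = c(30, 30), fst = 0.35, fis = 0,
                                   n_alleles = rep(10, 13), seed = 13))
  g <- sim$genotypes
  # graft one synthetic F1: one gene copy from each cluster at every locus
  tb <- as.data.frame(g)
  p1 <- tb[tb$id == "ind001", ]
  p2 <- tb[tb$id == "ind031", ]
  f1 <- p1
  f1$id <- "hybrid"
  f1$a2 <- p2$a1
  aug <- ssr_genotypes(rbind(tb, f1))
  fit <- run_admixture(aug, k = 2, burnin = 1000, reps = 1000, seed = 3)
  qh <- as.numeric(fit$Q[fit$Q$id == "hybrid", c("cluster1", "cluster2")])
  expect_lt(abs(qh[1] - 0.5), 0.15)
})

test_that("evanno table and degenerate contracts", {
  mk <- function(k, lnpd) structure(list(k = k, ln_pd = lnpd),
                                    class = "ssr_admixture")
  # perfectly linear L(K): no delta-K maximum -> inconclusive
  runs <- list()
  for (k in 1:4) for (r in 1:2) {
    runs[[length(runs) + 1]] <- mk(k, -1000 + 10 * k + c(0.5, -0.5)[r])
  }
  ev <- evanno(runs)
  expect_true(is.na(ev$selected_k))
  expect_equal(ev$table$l_prime[2:4], rep(10, 3))
  expect_equal(ev$table$l_second[2:3], c(0, 0))
  # a kink at k = 2 is selected
  runs2 <- list()
  vals <- c(-1200, -1000, -990, -985)
  for (k in 1:4) for (r in 1:2) {
    runs2[[length(runs2) + 1]] <- mk(k, vals[k] + c(1, -1)[r])
  }
  ev2 <- evanno(runs2)
  expect_equal(ev2$selected_k, 2)
  # guards
  expect_error(evanno(runs2[1:4]), "consecutive")
  expect_error(evanno(runs2[c(1, 3, 5, 7)]), "two runs")
  # zero spread -> delta-K undefined with warning
  runs3 <- list()
  for (k in 1:3) for (r in 1:2) runs3[[length(runs3) + 1]] <- mk(k, vals[k])
  expect_warning(ev3 <- evanno(runs3), "zero run-to-run")
  expect_true(is.na(ev3$table$delta_k[2]))
})
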