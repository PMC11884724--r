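test_that("squared genotypic distance reproduces the case table", {
  expect_equal(unname(individual_squared_distances(
    one_locus_genotypes(list(c(1, 1), c(2, 2)))
  )[1, 2]), 4)
  expect_equal(unname(individual_squared_distances(
    one_locus_genotypes(list(c(1, 1), c(1, 1)))
  )[1, 2]), 0)
  cases <- list(
    list(x = c(1, 2), y = c(1, 2), d = 0),
    list(x = c(1, 1), y = c(1, 2), d = 1),
    list(x = c(1, 2), y = c(1, 3), d = 1),
    list(x = c(1, 2), y = c(3, 4), d = 2),
    list(x = c(1, 1), y = c(2, 3), d = 3),
    list(x = c(1, 1), y = c(2, 2), d = 4)
  )
  for (cs in cases) {
    g <- one_locus_genotypes(list(cs$x, cs$y))
    expect_equal(unname(individual_squared_distances(g)[1, 2]), cs$d)
  }
})

test_that("multilocus distances match the exhaustive per-pair oracle", {
  set.seed(31)
  for (rep in 1:5) {
    sim <- simulate_ssr(ssr_sim_spec(sizes = c(3, 2), n_alleles = c(4, 3, 5),
                                     fis = 0.3, missing_rate = 0.2, seed = rep))
    g <- sim$genotypes
    tb <- as.data.frame(g)
    ids <- individuals_of(g)
    ok <- TRUE
    d <- try(individual_squared_distances(g), silent = TRUE)
    if (inherits(d, "try-error")) next # a pair without shared loci
    for (i in seq_along(ids)[-1]) for (j in seq_len(i - 1)) {
      acc <- 0
      for (l in loci_of(g)) {
        gi <- tb[tb$id == ids[i] & tb$locus == l, c("a1", "a2")]
        gj <- tb[tb$id == ids[j] & tb$locus == l, c("a1", "a2")]
        if (anyNA(gi) || anyNA(gj)) next
        acc <- acc + sp_case_oracle(as.numeric(gi), as.numeric(gj))
      }
      expect_equal(unname(d[ids[i], ids[j]]), acc)
    }
  }
})

test_that("AMOVA degrees of freedom and sum-of-squares identity", {
  g <- simulate_ssr(ssr_sim_spec(seed = 14))$genotypes  # 91 in 5 pops
  am <- run_amova(individual_squared_distances(g), pop_table(g), n_perm = 0)
  expect_equal(am$table$df, c(4, 86, 90))
  expect_equal(am$table$SS[3], am$table$SS[1] + am$table$SS[2], tolerance = 1e-6)
  expect_equal(sum(am$table$percent[1:2]), 100)
  expect_equal(am$table$MS[1:2], am$table$SS[1:2] / am$table$df[1:2])
})

test_that("relabeling populations leaves the AMOVA unchanged", {
  g <- simulate_ssr(ssr_sim_spec(sizes = c(6, 7, 5), fst = 0.2, seed = 3))$genotypes
  d <- individual_squared_distances(g)
  pops <- pop_table(g)$pop
  relab <- c(pop1 = "Z", pop2 = "Y", pop3 = "X")[pops]
  a1 <- run_amova(d, pops, n_perm = 49, seed = 7)
  a2 <- run_amova(d, unname(relab), n_perm = 49, seed = 7)
  expect_equal(a1$table$SS, a2$table$SS)
  expect_equal(a1$table$variance, a2$table$variance)
})

test_that("identical individuals give the degenerate 0/100 partition with p = 1", {
  g <- one_locus_genotypes(list(c(1, 1), c(1, 1), c(1, 1), c(1, 1)),
                           pops = c("A", "A", "B", "B"))
  am <- run_amova(individual_squared_distances(g), pop_table(g), n_perm = 99)
  expect_equal(am$table$SS, c(0, 0, 0))
  expect_equal(am$table$percent[1:2], c(0, 100))
  expect_equal(am$p_value, 1)
})

test_that("among-population percentage rises with nominal differentiation", {
  pct <- vapply(c(0.001, 0.1, 0.3), function(f) {
    g <- simulate_ssr(ssr_sim_spec(sizes = c(25, 25), fst = f, fis = 0,
                                   n_alleles = rep(8, 8), seed = 77))$genotypes
    am <- run_amova(individual_squared_distances(g), pop_table(g), n_perm = 0)
    am$table$percent[1]
  }, numeric(1))
  expect_true(all(diff(pct) > 0))
})

test_that("permutation p-value is small under true structure", {
  g <- simulate_ssr(ssr_sim_spec(sizes = c(20, 20), fst = 0.25, fis = 0,
                                 seed = 6))$genotypes
  am <- run_amova(individual_squared_distances(g), pop_table(g),
                  n_perm = 199, seed = 5)
  expect_lt(am$p_value, 0.05)
})

test_that("singleton populations are rejected by name", {
  g <- one_locus_genotypes(list(c(1, 1), c(1, 2), c(2, 2)),
                           pops = c("A", "A", "B"))
  expect_error(run_amova(individual_squared_distances(g), pop_table(g)),
               "singleton.*B")
})
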