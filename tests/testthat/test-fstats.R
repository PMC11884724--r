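test_that("definitional ratios hold exactly on every computed row", {
  g <- simulate_ssr(ssr_sim_spec(sizes = c(8, 9, 7), fst = 0.2, fis = 0.5,
                                 seed = 21))$genotypes
  fs <- per_locus_fstats(g)
  expect_equal(fs$fis, (fs$mean_he - fs$mean_ho) / fs$mean_he)
  expect_equal(fs$fit, (fs$ht - fs$mean_ho) / fs$ht)
  expect_equal(fs$fst, (fs$ht - fs$mean_he) / fs$ht)
  expect_equal(fs$nm, ((1 / fs$fst) - 1) / 4)
})

test_that("zero observed heterozygosity forces Fis = Fit = 1 when He > 0", {
  g <- one_locus_genotypes(list(c(1, 1), c(2, 2), c(1, 1), c(3, 3)),
                           pops = c("A", "A", "B", "B"))
  fs <- per_locus_fstats(g)
  expect_gt(fs$mean_he, 0)
  expect_identical(fs$fis, 1)
  expect_identical(fs$fit, 1)
})

test_that("complete differentiation and no differentiation limits", {
  # two populations fixed for different alleles
  g <- one_locus_genotypes(list(c(1, 1), c(1, 1), c(2, 2), c(2, 2)),
                           pops = c("A", "A", "B", "B"))
  fs <- per_locus_fstats(g)
  expect_equal(fs$ht, 0.5)
  expect_equal(fs$mean_he, 0)
  expect_equal(fs$fst, 1)
  expect_equal(fs$nm, 0)
  pw <- pairwise_fst(g)
  expect_equal(pw["A", "B"], 1)
  # identical frequencies in both populations
  h <- one_locus_genotypes(list(c(1, 2), c(1, 2), c(1, 2), c(1, 2)),
                           pops = c("A", "A", "B", "B"))
  fh <- per_locus_fstats(h)
  expect_equal(fh$fst, 0)
  expect_equal(fh$ht, fh$mean_he)
  expect_equal(fh$nm, Inf)
})

test_that("a population duplicated against itself has pairwise Fst 0", {
  sim <- simulate_ssr(ssr_sim_spec(sizes = c(10, 10), fst = c(0.2, 0.2), seed = 5))
  tb <- as.data.frame(sim$genotypes)
  dup <- tb
  dup$pop <- "copy"
  dup$id <- paste0(dup$id, "_copy")
  g <- ssr_genotypes(rbind(tb[tb$pop == "pop1", ], dup[dup$id %in%
    paste0(tb$id[tb$pop == "pop1"], "_copy"), ]))
  pw <- pairwise_fst(g)
  expect_equal(unname(pw["pop1", "copy"]), 0, tolerance = 1e-12)
})

test_that("Nei distance matches the hand-computed identity ratio", {
  # 2 loci, 2 pops with known frequencies
  g <- ssr_genotypes(tibble::tribble(
    ~id, ~pop, ~locus, ~a1, ~a2,
    "x1", "X", "L1", 1, 1,
    "x1", "X", "L2", 1, 2,
    "x2", "X", "L1", 1, 2,
    "x2", "X", "L2", 1, 1,
    "y1", "Y", "L1", 2, 2,
    "y1", "Y", "L2", 1, 1,
    "y2", "Y", "L1", 1, 2,
    "y2", "Y", "L2", 1, 2
  ))
  # X: L1 p = (.75, .25), L2 p = (.75, .25); Y: L1 p = (.25, .75), L2 (.75, .25)
  jxy <- (0.75 * 0.25 + 0.25 * 0.75) + (0.75 * 0.75 + 0.25 * 0.25)
  jx <- (0.75^2 + 0.25^2) * 2
  jy <- (0.25^2 + 0.75^2) + (0.75^2 + 0.25^2)
  d <- nei_distance(g)
  expect_equal(unname(d["X", "Y"]), -log(jxy / sqrt(jx * jy)))
  # identical frequency vectors -> 0
  expect_equal(unname(nei_distance(g)["X", "X"]), 0)
})

test_that("disjoint allele sets give an infinite Nei distance", {
  g <- one_locus_genotypes(list(c(1, 2), c(1, 2), c(3, 4), c(3, 4)),
                           pops = c("A", "A", "B", "B"))
  expect_equal(unname(nei_distance(g)["A", "B"]), Inf)
})

test_that("unbiased Nei variant shrinks within-population identity bias", {
  g <- simulate_ssr(ssr_sim_spec(sizes = c(6, 6), fst = 0.2, seed = 9))$genotypes
  d72 <- nei_distance(g, "nei1972")
  d78 <- nei_distance(g, "nei1978")
  expect_false(identical(unclass(d72), unclass(d78)))
  expect_true(all(unclass(d78) >= 0))
})

test_that("gene flow formula and grades", {
  expect_equal(gene_flow(0.2), 1.0)
  expect_equal(gene_flow(1), 0)
  expect_equal(gene_flow(0), Inf)
  expect_error(gene_flow(1.5), "\\[0, 1\\]")
  expect_equal(as.character(grade_fst(c(0.19, 0.05, 0.01))),
               c("high", "medium", "low"))
  expect_equal(as.character(grade_nm(c(1.15, 0.5, 0.1))),
               c("high", "medium", "low"))
  expect_error(grade_fst(-0.1), ">= 0")
})

test_that("pairwise Nm applies the island-model formula elementwise", {
  g <- simulate_ssr(ssr_sim_spec(sizes = c(8, 8, 8), fst = 0.15, seed = 2))$genotypes
  pw <- pairwise_fst(g)
  nm <- gene_flow(pw)
  off <- upper.tri(nm)
  expect_equal(unclass(nm)[off], ((1 / unclass(pw)[off]) - 1) / 4)
})
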