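test_that("two points give one axis carrying 100% of the variation", {
  m <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord <- pcoa(ssr_dist(m))
  expect_equal(ord$percent[1], 100)
  expect_equal(abs(diff(ord$coordinates$axis1)), 3)
})

test_that("collinear points embed exactly on one axis", {
  m <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m["A", "B"] <- m["B", "A"] <- 1
  m["B", "C"] <- m["C", "B"] <- 1
  m["A", "C"] <- m["C", "A"] <- 2
  ord <- pcoa(ssr_dist(m))
  expect_equal(ord$percent[1], 100)
  expect_equal(length(ord$percent), 1)
})

test_that("PCoA reconstructs Euclidean distances", {
  set.seed(12)
  pts <- matrix(rnorm(8 * 3), 8)
  m <- as.matrix(dist(pts))
  ord <- pcoa(ssr_dist(m))
  rec <- as.matrix(dist(as.matrix(ord$coordinates[, -1])))
  expect_equal(unname(rec), unname(m), tolerance = 1e-8)
  expect_true(all(diff(ord$cumulative_percent) >= -1e-12))
})

test_that("non-symmetric input is rejected", {
  m <- matrix(c(0, 1, 2, 0), 2)
  expect_error(pcoa(m), "symmetric")
})

test_that("textbook three-taxon UPGMA", {
  m <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(ssr_dist(m))
  expect_equal(sort(tr$merge_heights), c(2, 6))
  cop <- as.matrix(stats::cophenetic(tr$tree))
  expect_equal(cop["A", "B"], 2)
  expect_equal(cop["A", "C"], 6)
  expect_equal(cop["B", "C"], 6)
})

test_that("UPGMA agrees with an independent implementation on random matrices", {
  for (seed in 1:5) {
    m <- random_dist(10, seed)
    tr <- upgma(ssr_dist(m))
    ref <- phangorn::upgma(as.dist(m))
    expect_equal(as.matrix(stats::cophenetic(tr$tree))[rownames(m), rownames(m)],
                 as.matrix(stats::cophenetic(ref))[rownames(m), rownames(m)],
                 tolerance = 1e-8)
  }
})

test_that("UPGMA trees are ultrametric and reproduce ultrametric inputs", {
  m <- random_dist(8, 42)
  tr <- upgma(ssr_dist(m))
  expect_true(ape::is.ultrametric(tr$tree, tol = 1e-8))
  # feeding back its own cophenetic distances reproduces them exactly
  cop <- as.matrix(stats::cophenetic(tr$tree))[rownames(m), rownames(m)]
  tr2 <- upgma(ssr_dist(cop))
  cop2 <- as.matrix(stats::cophenetic(tr2$tree))[rownames(m), rownames(m)]
  expect_equal(cop2, cop, tolerance = 1e-8)
})

test_that("equidistant taxa resolve deterministically by label order", {
  m <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m) <- 0
  tr1 <- upgma(ssr_dist(m))
  tr2 <- upgma(ssr_dist(m))
  expect_identical(tr1$newick, tr2$newick)
  expect_match(tr1$newick, "\\(a:0.5,b:0.5\\)|\\(b:0.5,a:0.5\\)")
})

test_that("newick export round-trips through ape", {
  m <- random_dist(6, 3)
  tr <- upgma(ssr_dist(m))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, rownames(m))
})

test_that("shared-allele distance on hand-worked cases", {
  expect_equal(unname(shared_allele_distance(
    one_locus_genotypes(list(c(1, 2), c(1, 2)))
  )[1, 2]), 0)
  expect_equal(unname(shared_allele_distance(
    one_locus_genotypes(list(c(1, 2), c(3, 4)))
  )[1, 2]), 1)
  # 2 loci: share 1 of 2 alleles at L1, both at L2 -> d = 1 - mean(0.5, 1)/1
  g <- ssr_genotypes(tibble::tribble(
    ~id, ~pop, ~locus, ~a1, ~a2,
    "u", "P", "L1", 1, 2,
    "u", "P", "L2", 5, 5,
    "v", "P", "L1", 1, 3,
    "v", "P", "L2", 5, 5
  ))
  expect_equal(unname(shared_allele_distance(g)["u", "v"]),
               1 - mean(c(1, 2)) / 2)
  # homozygote against an overlapping heterozygote shares exactly one allele
  expect_equal(unname(shared_allele_distance(
    one_locus_genotypes(list(c(1, 1), c(1, 2)))
  )[1, 2]), 0.5)
})

test_that("two synthetic clusters separate on the first PCoA axis", {
  g <- simulate_ssr(ssr_sim_spec(sizes = c(20, 20), fst = 0.3, fis = 0,
                                 n_alleles = rep(8, 13), seed = 10))$genotypes
  ord <- pcoa(individual_squared_distances(g))
  ax1 <- ord$coordinates$axis1
  lab <- pop_table(g)$pop
  # mean silhouette on axis 1 is positive when clusters separate
  sil <- vapply(seq_along(ax1), function(i) {
    own <- mean(abs(ax1[i] - ax1[lab == lab[i]][-match(i, which(lab == lab[i]))]))
    oth <- mean(abs(ax1[i] - ax1[lab != lab[i]]))
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gt(mean(sil, na.rm = TRUE), 0)
})
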