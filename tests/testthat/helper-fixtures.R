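# shared fixtures and independent oracles

# a tiny hand-built table: 4 individuals, 2 pops, 2 loci
tiny_genotypes <- function() {
  ssr_genotypes(tibble::tribble(
    ~id, ~pop, ~locus, ~a1, ~a2,
    "i1", "A", "L1", 150, 150,
    "i1", "A", "L2", 200, 204,
    "i2", "A", "L1", 150, 154,
    "i2", "A", "L2", 200, 200,
    "i3", "B", "L1", 154, 154,
    "i3", "B", "L2", 204, 204,
    "i4", "B", "L1", 158, 154,
    "i4", "B", "L2", NA, NA
  ))
}

# genotype matrix with given per-pop allele pairs (one locus)
one_locus_genotypes <- function(pairs, pops = rep("A", length(pairs))) {
  ssr_genotypes(tibble::tibble(
    id = sprintf("i%d", seq_along(pairs)),
    pop = pops,
    locus = "L1",
    a1 = vapply(pairs, `[`, numeric(1), 1),
    a2 = vapply(pairs, `[`, numeric(1), 2)
  ))
}

# exhaustive codominant squared-distance oracle: the published case table
sp_case_oracle <- function(x, y) {
  x <- sort(x)
  y <- sort(y)
  hx <- x[1] != x[2]
  hy <- y[1] != y[2]
  shared <- length(intersect(x, y))
  if (identical(x, y)) return(0)
  if (hx && hy) {
    if (shared == 2) return(0)
    if (shared == 1) return(1)
    return(2)
  }
  if (!hx && !hy) return(4)          # distinct homozygotes
  if (shared >= 1) return(1)         # (ii) vs (ij)
  3                                  # (ii) vs (jk)
}

# brute-force allele frequency tally from raw gene copies
freq_oracle <- function(g, by_pop = TRUE) {
  tb <- as.data.frame(g)
  tb <- tb[!is.na(tb$a1), ]
  copies <- rbind(
    data.frame(pop = tb$pop, locus = tb$locus, allele = tb$a1),
    data.frame(pop = tb$pop, locus = tb$locus, allele = tb$a2)
  )
  if (!by_pop) copies$pop <- "all"
  tab <- as.data.frame(table(copies$locus, copies$pop, copies$allele))
  names(tab) <- c("locus", "pop", "allele", "count")
  tab <- tab[tab$count > 0, ]
  tab$allele <- as.numeric(as.character(tab$allele))
  totals <- stats::aggregate(count ~ locus + pop, tab, sum)
  names(totals)[3] <- "total"
  tab <- merge(tab, totals)
  tab$freq <- tab$count / tab$total
  tab
}

# random symmetric zero-diagonal distance matrix
random_dist <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.1, 5)
  m <- m + t(m)
  dimnames(m) <- list(letters[seq_len(n)], letters[seq_len(n)])
  m
}
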