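#' Specification of a synthetic SSR dataset
#'
#' The generator emulates the study design the package targets: a selfing
#' cereal collection genotyped at a modest SSR panel. Defaults describe 91
#' diploid accessions in 5 collection zones of unequal size, 13 loci with
#' 6–15 alleles each, strong homozygote excess (`fis = 0.79`), moderate
#' differentiation (`fst = 0.19`), and fragment sizes on a dinucleotide
#' ladder.
#'
#' Population allele frequencies follow the Balding–Nichols model: ancestral
#' frequencies per locus are symmetric-Dirichlet draws, each population's
#' frequencies are Dirichlet with parameter
#' \eqn{p_{anc} (1 - F)/F}, so the drift parameter `F` is the nominal Fst of
#' that population. Selfing is modelled as instantaneous autozygosity: with
#' probability `fis` an individual's two gene copies at a locus are one draw
#' duplicated. `admixture_alpha` switches on an admixed design where each
#' individual's ancestry vector over the `length(sizes)` source clusters is
#' Dirichlet(`alpha`), and each gene copy picks its source cluster from it.
#'
#' @param sizes Individuals per population.
#' @param n_alleles Alleles per locus (recycled to `n_loci`).
#' @param n_loci Number of loci.
#' @param fst Nominal drift parameter per population (recycled); `0` means
#'   population frequencies equal the ancestral frequencies.
#' @param fis Autozygosity probability in `[0, 1)`... `1` is accepted and
#'   forces complete homozygosity.
#' @param admixture_alpha `NULL` for discrete populations, or a positive
#'   scalar Dirichlet parameter for admixed ancestries.
#' @param missing_rate Probability that a call (both gene copies) is masked.
#' @param ladder_offset,ladder_repeat Fragment-size ladder: allele class `a`
#'   at any locus is reported as `offset + repeat * a` bp.
#' @param anc_dirichlet Symmetric Dirichlet parameter for ancestral
#'   frequencies.
#' @param seed Integer seed; same spec and seed give the identical dataset.
#' @return A `ssr_sim_spec` list.
#' @export
ssr_sim_spec <- function(sizes = c(7, 22, 13, 44, 5),
                         n_alleles = c(13, 11, 8, 6, 15, 11, 10, 11, 11, 8, 9, 9, 14),
                         n_loci = length(n_alleles),
                         fst = 0.19, fis = 0.79,
                         admixture_alpha = NULL, missing_rate = 0,
                         ladder_offset = 100, ladder_repeat = 2,
                         anc_dirichlet = 1, seed = 1L) {
  n_alleles <- rep_len(n_alleles, n_loci)
  fst <- rep_len(fst, length(sizes))
  stopifnot(all(sizes >= 1), all(n_alleles >= 2),
            all(fst >= 0 & fst < 1), fis >= 0, fis <= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(
    sizes = as.integer(sizes), n_loci = as.integer(n_loci),
    n_alleles = as.integer(n_alleles), fst = fst, fis = fis,
    admixture_alpha = admixture_alpha, missing_rate = missing_rate,
    ladder_offset = ladder_offset, ladder_repeat = ladder_repeat,
    anc_dirichlet = anc_dirichlet, seed = as.integer(seed)
  ), class = "ssr_sim_spec")
}

rdirichlet <- function(n, par) {
  x <- matrix(stats::rgamma(n * length(par), shape = par), n, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a codominant SSR dataset
#'
#' Draws a genotype table under a [ssr_sim_spec()] together with the truth
#' record needed for parameter-recovery tests (ancestral and population
#' frequencies, individual ancestries in admixed mode, the drift and
#' inbreeding parameters used).
#'
#' @param spec An [ssr_sim_spec()].
#' @return List with `genotypes` (an [ssr_genotypes]) and `truth`.
#' @examples
#' sim <- simulate_ssr(ssr_sim_spec(sizes = c(10, 10), fst = 0.1, seed = 7))
#' sim$genotypes
#' @export
simulate_ssr <- function(spec = ssr_sim_spec()) {
  stopifnot(inherits(spec, "ssr_sim_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(spec$seed)
  k <- length(spec$sizes)
  n <- sum(spec$sizes)
  pops <- rep(sprintf("pop%d", seq_len(k)), spec$sizes)
  ids <- sprintf("ind%03d", seq_len(n))
  admixed <- !is.null(spec$admixture_alpha)
  p_anc <- lapply(spec$n_alleles, function(a) {
    as.numeric(rdirichlet(1, rep(spec$anc_dirichlet, a)))
  })
  p_pop <- lapply(seq_len(spec$n_loci), function(l) {
    t(vapply(seq_len(k), function(p) {
      f <- spec$fst[p]
      if (f == 0) return(p_anc[[l]])
      as.numeric(rdirichlet(1, p_anc[[l]] * (1 - f) / f))
    }, numeric(spec$n_alleles[l])))
  })
  q_mat <- if (admixed) {
    rdirichlet(n, rep(spec$admixture_alpha, k))
  } else {
    diag(k)[rep(seq_len(k), spec$sizes), , drop = FALSE]
  }
  a1 <- matrix(NA_real_, n, spec$n_loci)
  a2 <- a1
  for (l in seq_len(spec$n_loci)) {
    draw_copy <- function() {
      src <- vapply(seq_len(n), function(i) {
        sample.int(k, 1, prob = q_mat[i, ])
      }, integer(1))
      vapply(seq_len(n), function(i) {
        sample.int(spec$n_alleles[l], 1, prob = p_pop[[l]][src[i], ])
      }, integer(1))
    }
    c1 <- draw_copy()
    c2 <- draw_copy()
    auto <- runif(n) < spec$fis
    c2[auto] <- c1[auto]
    a1[, l] <- spec$ladder_offset + spec$ladder_repeat * c1
    a2[, l] <- spec$ladder_offset + spec$ladder_repeat * c2
    gone <- runif(n) < spec$missing_rate
    a1[gone, l] <- NA
    a2[gone, l] <- NA
  }
  loci <- sprintf("L%02d", seq_len(spec$n_loci))
  tb <- tibble(
    id = rep(ids, spec$n_loci),
    pop = rep(pops, spec$n_loci),
    locus = rep(loci, each = n),
    a1 = as.vector(a1), a2 = as.vector(a2)
  )
  list(
    genotypes = ssr_genotypes(tb, individuals = ids, loci = loci),
    truth = list(
      p_anc = p_anc, p_pop = p_pop, q = q_mat,
      fst = spec$fst, fis = spec$fis, sizes = spec$sizes,
      missing_rate = spec$missing_rate, seed = spec$seed
    )
  )
}
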