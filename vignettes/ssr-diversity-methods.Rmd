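---
title: "Models and methods behind ssrpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ssrpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrpop)
```

ssrpop analyses codominant microsatellite (SSR) genotype tables — diploid
fragment-size calls at a panel of loci, with a population label per
individual — and carries them through the statistics that SSR diversity
studies conventionally report: per-marker diversity, per-population allelic
patterns, Wright's F-statistics and gene flow, Nei distances, AMOVA, PCoA,
UPGMA trees, and Bayesian admixture clustering with Evanno ΔK model
selection. This vignette explains the models, the conventions, and the
design choices where more than one defensible option existed.

## The data model

A genotype call is an unordered pair of allele sizes in base pairs,
canonically stored as `(min, max)`. A single scored band is interpreted as a
homozygote — the standard reading of codominant SSR gels, and the only
reading consistent with reporting a nonzero observed heterozygosity from
band data. A call is missing as a whole: either both gene copies are
observed or neither is, and per-locus sample sizes count genotyped
individuals only. Two plain-text dialects are supported, the GenAlEx
codominant CSV layout and a long one-row-per-call table; `read_genotypes()`
and `write_genotypes()` are exact inverses for both.

Raw gel sizes rarely sit exactly on the repeat ladder, so `bin_alleles()`
offers two binning rules: single-linkage clustering of the distinct sizes at
a locus with a bp tolerance (in one dimension this reduces to cutting sorted
gaps wider than the tolerance), or snapping to an arithmetic ladder
`offset + repeat × round(·)`. All rounding of representative sizes uses
round-half-to-even so binning is platform-stable. Binning can only merge
allele classes, never split them, and a zero tolerance is the identity.

## Per-marker and per-population statistics

For allele frequencies $p_i$ at a locus, the package computes gene diversity
$GD = 1 - \sum_i p_i^2$ and Botstein's polymorphic information content

$$PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2,$$

the convention used by PowerMarker-style marker screens. The cross term is
evaluated as $(\sum p_i^2)^2 - \sum p_i^4$ over the full index range, which
is algebraically identical and $O(n)$. Marker-level summaries
(`locus_summary()`) use pooled-sample frequencies, the convention of
per-marker screening tables; the F-statistics below use per-population
frequencies. This distinction is why a "gene diversity" column of a marker
table and a "total heterozygosity" column of an F-statistics table can
differ slightly for the same locus.

Per population and locus, `allelic_patterns()` reports the observed allele
count, the count at frequency ≥ 5%, the effective number of alleles
$N_e = 1/\sum p_i^2$, Shannon's index $I = -\sum p_i \ln p_i$ (with
$0 \ln 0 = 0$), private alleles (present in no other population), locally
common alleles (frequency ≥ 5% here, present in at most 25% resp. 50% of
populations — alleles confined to a single population are private, not
locally common, and are excluded, matching GenAlEx's counts: with five
populations "≤ 25%" means one population and the column is structurally
zero), expected heterozygosity, its small-sample-unbiased version
$uHe = \frac{2N}{2N-1} He$, and the fixation index $F = 1 - Ho/He$. $F$ is
undefined at monomorphic loci and such loci are dropped from its mean only.

## F-statistics, gene flow and distances

Following the unweighted (GenAlEx) convention, for each locus the
population-wise $He$ and $Ho$ are averaged arithmetically across the
populations where the locus is genotyped, and the total frequency of an
allele is the unweighted mean of its population frequencies. With
$H_T = 1 - \sum \overline{p}_i^2$:

$$F_{IS} = \frac{\bar{He} - \bar{Ho}}{\bar{He}}, \quad
  F_{IT} = \frac{H_T - \bar{Ho}}{H_T}, \quad
  F_{ST} = \frac{H_T - \bar{He}}{H_T}, \quad
  N_m = \frac{(1/F_{ST}) - 1}{4}.$$

These are definitional ratios, not the Weir–Cockerham variance-component
estimators; the familiar identity $F_{IT} = F_{IS} + F_{ST} - F_{IS}F_{ST}$
does **not** hold for them in general, and the tests assert the three ratios
directly instead. A locus with zero mean observed heterozygosity and
positive mean expected heterozygosity has $F_{IS} = F_{IT} = 1$ exactly — a
useful internal consistency check for any published table. Pairwise
population $F_{ST}$ applies the same two-population construction per locus
and averages over loci; pairwise $N_m$ applies the island-model formula
elementwise to the pairwise $F_{ST}$ matrix. Note that published pairwise
$N_m$ tables are not always consistent with their own pairwise $F_{ST}$
tables under this formula; ssrpop always derives $N_m$ from $F_{ST}$, so a
mismatch with such a table indicates the table's own derivation, not a
computation difference you can toggle.

Nei's standard distance between populations $X$ and $Y$ accumulates gene
identities over loci, $D = -\ln(J_{XY}/\sqrt{J_X J_Y})$; the 1978 unbiased
variant replaces each within-population identity by
$(2N\sum p_i^2 - 1)/(2N - 1)$. Disjoint allele sets give $D = \infty$.

### What the Gst-style estimator actually targets

A point worth making explicit, because it governs how parameter recovery is
tested. If $k$ populations each drift from a common ancestor with
Balding–Nichols parameter $F$ (so $\mathrm{Var}(p_d) = F\,p(1-p)$ around the
ancestral $p$), the ratio $(H_T - \bar{He})/H_T$ computed among those $k$
populations has expectation approximately

$$G(F, k) = \frac{F\,(1 - 1/k)}{1 - F/k},$$

because $H_T$ is measured about the mean of the sampled demes rather than
the ancestor: with two demes the statistic targets roughly $F/2$, and only
as $k$ grows does it approach $F$. In addition, finite samples inflate the
among-population variance by roughly $(1-F)\,\overline{1/(2n_d)}$, which is
material when zones hold fewer than ten individuals. The test suite
therefore checks recovery of the nominal drift parameter in a many-deme
design (8 × 50) where $G(F,k) \approx F$, and checks the two-deme case
against the closed form $G(F,2)$; both behaviours are properties of the
definitional estimator, not implementation artifacts.

Interpretation grades follow the conventional bands: differentiation below
0.05 low, 0.05–0.15 medium, 0.15 and above high; gene flow at or above 1
migrant per generation high, 0.25–1 medium, below 0.25 low; PIC above 0.5
highly informative, 0.25–0.5 (both ends included) moderately informative,
below 0.25 slightly informative.

## AMOVA

The two-level AMOVA partitions the codominant squared genotypic distance
(`individual_squared_distances()`), which per locus equals
$\frac12\sum_a (x_a - y_a)^2$ over allele dosage vectors and reproduces the
canonical case values $\{0, 1, 2, 3, 4\}$, summed over co-genotyped loci.
Sums of squares come from the standard distance identities, the
among-population variance component from
$(MS_{among} - MS_{within})/n_0$ with
$n_0 = (N - \sum n_p^2/N)/(k-1)$; negative components are truncated to zero
before percentages. Significance uses permutation of individuals across
populations; the p-value includes the observed configuration,
$(\#\{\ge obs\} + 1)/(n_{perm} + 1)$, the convention that avoids reporting
zero p-values. Degenerate all-zero distance input reports 0% among / 100%
within with $p = 1$.

## Ordination and trees

`pcoa()` Gower-centres $-\frac12 d^2$ and eigendecomposes; axis percentages
use positive eigenvalues only. Because the genotypic distance above is
already a squared distance, `pcoa()` takes a `squared` switch (defaulting
correctly for tagged matrices) rather than squaring blindly — this is also
why base `cmdscale()` is not used directly. For Euclidean inputs the
embedding reproduces the input distances to machine precision, which the
tests assert.

`upgma()` implements size-weighted average-linkage agglomeration with node
heights at half the merge distance, so trees are ultrametric with cophenetic
distances equal to merge distances. Ties are broken by the lexicographically
smallest pair of cluster labels (a cluster is labelled by its smallest
member), making output deterministic on degenerate inputs where generic
implementations are order-dependent; on random matrices it agrees with an
independent implementation to numerical precision. Individual-level trees
default to the shared-allele distance $1 - \bar{s}/2$ (with $s$ the
per-locus multiset intersection of the two genotypes), the conventional
choice for SSR accession dendrograms; the squared genotypic distance is
available as an alternative since the field's software does not pin this
choice down.

## Admixture model

`run_admixture()` is a Gibbs sampler for the admixture model with correlated
allele frequencies: individual ancestries $q_i \sim \mathrm{Dir}(\alpha)$,
cluster frequencies
$p_{kl} \sim \mathrm{Dir}(\lambda\, p^{anc}_{l}\,(1-F_k)/F_k)$, and each
allele copy drawn from the cluster its latent origin indicates. Per sweep:
allele-copy origins are sampled $\propto q_{ik} p_{kl}(a)$; $P$ and $Q$ are
conjugate Dirichlet updates; the ancestral frequencies move by a symmetric
mass-transfer Metropolis step; the drift parameters $F_k$ by a log-normal
random walk against a gamma prior (mean 0.01, sd 0.05); and $\alpha$ by a
normal random walk (sd 0.025) under a uniform(0, 10) prior. Defaults
($\alpha_0 = 1$, $\lambda = 1$, burn-in 30000, 15000 recorded sweeps) follow
common SSR practice; chain lengths are fully configurable and the model
evidence is summarised by the standard harmonic-style estimator
$\ln P(D) = \overline{\ln L} - \tfrac12 \mathrm{var}(\ln L)$. Missing calls
simply contribute no likelihood term. The sampler is written in C++ (Rcpp)
and draws all randomness from R's RNG, so a seed fixes the entire run.

Label switching across runs is handled by `align_labels()`, a greedy
column-matching of ancestry matrices against the first run — sufficient for
summarising replicate runs, though not a full CLUMPP-style optimisation.
`evanno()` computes $L(K)$, $L'(K)$, $|L''(K)|$ and
$\Delta K = |L''(K)|/\mathrm{sd}(L(K))$ over a consecutive grid with
replicate runs, selecting the interior $K$ maximising $\Delta K$; a
perfectly linear $L(K)$ profile, or zero run-to-run spread, yields an
explicit "inconclusive" (`NA`) rather than an arbitrary pick.

## The synthetic generator

`simulate_ssr()` is the test harness for everything above. Ancestral
frequencies per locus are symmetric Dirichlet draws; population frequencies
follow the Balding–Nichols parameterization
$\mathrm{Dir}(p^{anc}(1-F)/F)$, which makes the per-population drift
parameter a direct simulator input; selfing is modelled as instantaneous
autozygosity (with probability $F_{IS}$ the two gene copies of a call are
one draw duplicated), which is sufficient for testing heterozygosity-based
statistics though it does not reproduce multi-generation identity
disequilibrium; an admixed mode draws individual ancestries from a
Dirichlet and each gene copy's source cluster from them. Allele indices map
onto a fragment-size ladder and calls are masked whole at the missing rate.

Defaults emulate the kind of study the package targets: 91 accessions of a
selfing crop in 5 collection zones, 13 SSR loci with 6–15 alleles, strong
homozygote excess ($F_{IS} = 0.79$), moderate differentiation (drift 0.19).
The default zone sizes (7, 22, 13, 44, 5) encode a realistically unbalanced
collection in which the ratios of unbiased to plain expected heterozygosity
$\tfrac{2N}{2N-1}$ differ visibly between zones, as they do in real
collection tables. What passing tests on this generator do **not** show:
behaviour under stepwise mutation dynamics, linkage between loci, or the
idiosyncratic geographic structure of any real collection — the PCoA axis
percentages of a neutral Balding–Nichols draw, for instance, are flatter
than those of real structured collections.

## Numerical conventions and problem sizes

Frequencies are validated to sum to 1 within $10^{-9}$; distance matrices to
be symmetric within $10^{-8}$ with zero diagonals; ultrametricity is checked
at $10^{-8}$. Statistics are computed at full precision and only rendered
tables are rounded (2 decimals, matching the conventional presentation).
Infinite sentinels are used where the definitions force them ($N_m$ at
$F_{ST}=0$, Nei distance at zero shared identity) and undefined cells are
excluded from column means rather than zero-filled. The test suite sizes its
simulations to desk scale: parameter-recovery runs use 100 seeds per
setting, admixture recovery uses a 4 × 4 grid of short chains (2000 + 2000
sweeps) on a 91-individual two-group design — chain lengths chosen because
the separable test datasets mix within a few hundred sweeps, as the
likelihood traces confirm.
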