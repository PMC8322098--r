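---
title: "Genotype-likelihood population genomics: models, estimators and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-likelihood population genomics: models, estimators and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

glpop analyzes low-coverage (3–10×) resequencing data of structured
populations — the setting of multi-colony seabird surveys — without ever
calling hard genotypes. This vignette documents the statistical models,
the tunable parameters and their defaults, the synthetic-data generator
that defines the package's test conditions, and the design decisions
taken where the methodology left genuine choices.

On interface style: the package's core containers (likelihood arrays,
spectra, distance matrices, trees) are matrix/S3 objects in the idiom of
the phylogenetics and ordination packages they interoperate with, while
every tabular result (window tracks, Evanno tables, filter reports,
trajectories) is a tibble, and fitted objects carry `tidy()`/`glance()`
and `autoplot()` methods for pipeline-style downstream work.

## Genotype likelihoods

Every observation is a biallelic likelihood triple
$L(g), g \in \{0,1,2\}$ minor-allele copies, from the standard
read-sampling model: each read reports the minor allele with probability
$(g/2)(1-\epsilon) + (1-g/2)\epsilon$, base error $\epsilon$ (default
0.01). Triples are stored rescaled to maximum 1; a site with no reads in
an individual is a flat triple, which every downstream EM treats as an
uninformative factor. Panels are read and written in the Beagle-GL text
format; biallelic VCFs with GL or PL fields import through `vcfR`.

Panel construction mirrors the practice for such data: sites are kept
when the EM minor-allele frequency is at least `maf_min` (default 0.05,
exposed because the exact threshold in comparable studies is usually a
supplementary detail) and the missing fraction is at most `max_missing`
(default 0 — sites covered in all individuals). Linkage pruning computes
$r^2$ between posterior mean genotypes (composite LD — appropriate for
unphased low-coverage data) of site pairs within `max_dist_bp` (default
100 kb, a bounded search keeping the scan linear), takes connected
components of the $r^2 > 0.2$ graph as linked blocks, and keeps the
member closest to the block's bp midpoint, ties to the lower position.
"Most central" is read positionally rather than by index; the
alternative reading would differ only for irregularly spaced blocks.

## Site-frequency spectra and diversity

The folded SFS is estimated by EM on
$\sum_s \log \sum_k \eta_k P(\mathrm{data}_s \mid k)$, with
$P(\mathrm{data}\mid k)$ computed by a dynamic program over individuals
using the per-genotype multiplicities $(1,2,1)$ and the
$\binom{2N}{k}$ normalization; the observed log-likelihood is monotone
and asserted so in tests. The 2D spectrum uses the outer product of the
two populations' class likelihoods. Folding is performed after
estimation; the fold is an involution and the pairwise-difference
weights below are fold-invariant.

From a folded spectrum: $\theta_\pi$ uses weights $k(n-k)/\binom{n}{2}$,
$\theta_W = S/a_n$, and Tajima's D uses the 1989 variance constants; D
is reported missing when $S = 0$. Individual heterozygosity is the
$k=1$ mass of a single-individual spectrum.

Windowed heterozygosity uses 100-kb windows sliding by 50 kb, anchored
at multiples of the step from position 0 and truncated at chromosome
ends; trailing windows shorter than one step are dropped (deterministic
tiling eases testing; the protocols this emulates do not state their
boundary rule). Windows with fewer than `min_sites = 10` sites are
flagged unusable — variance control at 3× depth. The RoH cutoff is the
10% quantile (linear interpolation, R type 7) of per-window
heterozygosity averaged across individuals; the alternative pooled
reading is noted but the per-window mean matches the cited protocol
style. RoHs are runs of at least two consecutive usable below-cutoff
windows, spanning from the first window start to the last window end;
F_RoH divides the summed length of segments ≥ 150 kb by the union of the
individual's scanned (usable) windows.

## Structure: PCA, admixture EM, Evanno

PCA standardizes posterior mean genotypes by $\sqrt{2f(1-f)}$ at the EM
frequency (single-pass standardization; no iterative individual-allele-
frequency refinement — a deliberate simplification documented here, as
the iterative variant changes desk-scale results negligibly) and
averages the covariance over pairwise non-missing sites. Eigenvector
signs are fixed by making the largest-magnitude entry positive.

Admixture proportions use the classical binomial-mixture EM on
likelihood triples, floored cluster frequencies ($10^{-5}$), Dirichlet/
uniform random starts, and SQUAREM extrapolation with a monotonicity
safeguard (extrapolated points are accepted only if they improve the
observed log-likelihood, so the reported trace is non-decreasing).
Defaults: `tol = 1e-4` on the log-likelihood change, `max_iter = 2000`.

Replicate runs are aligned to the best-likelihood run by exact
assignment over column permutations (exhaustive up to K = 8, greedy
beyond), clustered by aligned RMSD (threshold 0.1), and the largest
cluster is averaged — an internal label-alignment procedure standing in
for external pipeline tooling.

Evanno's $\Delta K = |L'(K+1) - L'(K)| / \mathrm{sd}(L(K))$ requires
between-replicate spread in $L(K)$: it was proposed for stochastic
(MCMC) estimates. A fully converged deterministic EM gives essentially
zero spread at small K, making the ratio ill-defined — the degenerate
sd = 0 case is flagged and excluded from the argmax. For model-choice
scans we therefore recommend (and use in our own analyses) a bounded
iteration budget per replicate (`max_iter = 250, tol = 0.5` at
desk-scale panels), which restores the optimization variability the
heuristic presumes while leaving the likelihood ordering across K
intact; full-convergence settings remain the default for single-K
ancestry estimation.

## Divergence statistics

F_ST is the Hudson/Bhatia ratio of averages over the joint spectrum:
per-cell numerator $(\hat p_1-\hat p_2)^2 - \hat p_1(1-\hat p_1)/(n_1-1)
- \hat p_2(1-\hat p_2)/(n_2-1)$ and denominator
$\hat p_1(1-\hat p_2)+\hat p_2(1-\hat p_1)$, weighted by spectrum mass.
The engines this emulates do not state their exact estimator; Hudson was
chosen for its unbiasedness and additivity. Both members of a folded
cell pair give identical values (the formulas are invariant under
jointly complementing both frequencies), so the folded-spectrum
ambiguity is moot. Sliding windows (50 kb / 12.5 kb) sum per-site
posterior expectations of numerator and denominator under the global 2D
prior; window placement covers each site by exactly `window/step`
windows, making window sums exactly additive to the global estimate.

D-statistics sample one base per focal population per site (weighted by
the posterior allele frequency) against the outgroup consensus base;
sites whose outgroup minor-allele frequency exceeds 0.2 are treated as
polymorphic and skipped. The sampled-base mode matches consensus-base
outgroup construction; a frequency-weighted mode was considered and
rejected for symmetry with the emulated engine. f3 uses
$(\hat c-\hat a)(\hat c-\hat b) - \hat c(1-\hat c)/(n_C-1)$, requiring
at least two target diploids. Significance comes from a weighted
delete-one block jackknife (Busing form) over contiguous blocks, default
5 Mb — the emulated analyses do not state their jackknife configuration,
so the default is documented rather than asserted.

## Trees, geography, isolation by distance

Pairwise p-distances sample a consensus base per individual per site
from the posterior argmax genotype, heterozygotes resolved by a seeded
fair coin (the emulated engine's tie rule is unstated). Neighbor joining
delegates to `ape::nj` (canonical Saitou–Nei with the Studier–Keppler
criterion) with outgroup rooting; negative branch lengths are retained
raw and only clamped for display. Block-bootstrap support resamples
contiguous site blocks with replacement.

Least-cost sea distances run Dijkstra over the water cells of a raster
with 8-neighborhood moves and great-circle cell-center costs (lat/lon
input makes planar costs inappropriate); colonies snap to their nearest
water cell within two cells. The Mantel test is one-tailed (isolation by
distance is a directional hypothesis; the emulated analysis does not
state its tail) with $p = (\#\{r_\mathrm{perm} \ge r\}+1)/(n+1)$ over
999 permutations. MRM is OLS on vectorized lower triangles with
label-permutation significance, untransformed distances by default (a
log-distance flag exists). Progressive removal greedily deletes the
colony whose removal most increases the MRM $R^2$, stopping at
`max_removals = 4` (matching the emulated analysis' four removals), at a
minimum gain of 0.01, or when fewer than five colonies would remain.

## Mitochondrial analyses

Haplotypes collapse under equality at all co-called columns; sequences
differing only by missingness merge, represented by the most complete
member — the convention of network-building practice, flagged in the
report. Distances are plain counts of differing called positions (no
substitution-model correction; a config hook exists, since the emulated
pipeline's setting is unstated). Haplotype diversity is
$h = \frac{n}{n-1}(1-\sum p_i^2)$; $\pi$ is the mean pairwise difference
per site; Tajima's D reuses the spectrum constants with $n$ sequences.
Φ_ST and the hierarchical AMOVA use Excoffier-style sums of squares from
squared pairwise differences with moment-equation variance components
(reported raw, possibly negative). Permutation schemes: Φ_CT permutes
whole colonies among groups; Φ_SC permutes individuals among colonies
within groups; Φ_ST permutes individuals among all colonies; 999
permutations by default, matching the Mantel convention.

## The synthetic-data generator

The generator emulates a 12-colony, 72-diploid survey: four divergent
clusters (one isolated arctic-analog colony, a two-colony western
cluster, one isolated southern colony, and a central stepping-stone
chain of seven colonies), one admixed colony drawing ancestry
$\alpha = 0.5$ from the arctic colony and the nearest chain colony, and
RoH tracts implanted in the bottlenecked arctic colony (16 × 500 kb over
a 50-Mb genome, i.e. F_RoH ≈ 0.16, the level reported for the emulated
system). Coverage is uniform per individual on 3–10× and the error rate
0.01, matching the emulated survey's sequencing profile.

Drift follows Balding–Nichols Beta steps down a rooted tree
(analytically tractable, unlike forward simulation; the expected Hudson
ratio between two branches is simply the summed branch coefficients
halved, which the tests exploit). Ancestral frequencies are symmetric
Beta(0.8, 0.8) truncated to [0.05, 0.95] so sites are polymorphic.
Sites are independent by default; linkage exists only as an optional
block-copy correlation for testing the pruner, because all emulated
analyses run on pruned panels.

Two generator-design choices deserve emphasis:

* **Cluster drift is balanced against cluster size** (branch
  coefficients 0.15 for the two 6-diploid isolates, 0.075 for the
  12-diploid cluster, 0.02 plus per-step drift for the 48-diploid
  chain; chain steps are proportional to the sea distance between
  adjacent colonies at a uniform per-km rate totalling 0.012, and the
  chain colonies lie on a geographically monotone arc, so the
  within-cluster structure is genuine isolation by distance).
  Likelihood gains in model-choice scans scale roughly with the product
  of drift and the number of individuals separated; balancing them makes
  the four cluster splits contribute comparably, so "four clusters" is a
  well-posed truth for ΔK. A strongly hierarchical design (one dominant
  split) would make the optimal K genuinely ambiguous between 2 and 4 —
  as observed in the empirical system this emulates.
* **Divergence is scaled up relative to the empirical system**
  (between-cluster F_ST ≈ 0.05–0.15 versus < 0.01–0.08). A desk-scale
  panel of ~10⁴ sites carries ~100× less information than a ~10⁶-site
  genome-wide panel; preserving qualitative detectability (PCA
  separation, ΔK, f3/D significance) under the same sample sizes
  requires proportionally stronger signals. Within-chain steps stay an
  order of magnitude weaker than cluster splits, preserving the
  between ≫ within ordering.

The mitochondrial simulator uses a star-like genealogy (private Poisson
mutations per individual, default intensity 3 on a 2.5-kb sequence),
producing the excess of rare variants (negative Tajima's D) and the
near-one-haplotype-per-individual pattern of a recent expansion;
optional group-branch mutations create island structure for Φ_ST tests.
The geography is a 2°-cell lat/lon raster, mostly water with two
stylized land blocks, colonies placed so chain order matches geographic
order.

What the generator does **not** emulate: linkage disequilibrium and
recombination (sites independent), selection, base-quality
miscalibration, reference bias, and batch effects in coverage. Passing
tests therefore demonstrate correctness of the estimators under the
stated sampling models, not robustness to these real-data complications.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale: 50k sites
for spectrum recovery; a 20-Mb genome at 5 sites/kb with 1.2-Mb tracts
for RoH recovery (window heterozygosity needs several hundred sites per
window before the 10%-quantile cutoff separates cleanly from sampling
noise, and window-union segment coordinates inflate tracts much shorter
than ~1 Mb); 15k-site panels (default) for clustering, with a 20k-site,
≥8× panel for ancestry recovery (the regime in which mean absolute
error < 0.05 is an end-to-end property); 40k-site panels for f3/D
statistics (the sampled-base D needs a few thousand pattern-informative
sites for decisive Z-scores at α = 0.5); 12k+ sites with 1-Mb blocks
for bootstrap supports; and 999 permutations for all permutation
tests. All randomness flows from a
single seed per pipeline; identical configuration and seed give
byte-identical outputs, which the CLI tests assert via checksums.

## Known limitations

* The admixture EM estimates cluster frequencies jointly per panel; very
  small panels (≲ 500 sites) can leave replicate scans trapped in local
  optima regardless of acceleration.
* Φ_ST uses uncorrected differences; highly diverged haplotypes would
  need a substitution-model distance.
* The D-statistic's outgroup handling assumes a deeply diverged,
  near-monomorphic outgroup; a polymorphic outgroup loses sites.
* Negative variance components in AMOVA are reported raw; small or
  degenerate designs can make Φ ratios undefined (flagged `NA`).
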