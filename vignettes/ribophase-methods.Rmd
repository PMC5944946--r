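---
title: "ribophase: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribophase: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribophase)
```

# Scope

`ribophase` analyses paired 18S rDNA/rRNA amplicon time series of
planktonic microbial eukaryotes. Amplicons from the ribosomal gene (rDNA)
index which organisms are present and roughly how abundant they are;
amplicons from reverse-transcribed ribosomal RNA (rRNA) index ribosome
content, a proxy for relative cell activity. Sequencing both molecules
from the same water sample lets one ask, per taxon and per date, whether
activity tracks abundance — and, for bloom-forming taxa, whether activity
rises *before* abundance does.

The package covers five analysis stages — table I/O and filtering,
alpha diversity, environmental ordination, Bray-Curtis/SIMPROF community
clustering, and the rRNA:rDNA activity framework — plus a synthetic
community generator that provides ground truth for every stage.

# Preprocessing

OTU count tables arrive as tidy TSV or mothur `.shared` files, samples in
rows. The filtering chain is: dataset-wide singleton removal (an OTU whose
*total* count over all samples of a molecule's table is exactly 1 is
treated as a likely sequencing artefact), metazoan OTU removal via the
taxonomy table, rarefaction, and conversion to per-library relative
abundances. Each molecule's table is filtered independently, and the order
of steps is recorded in the output report.

Rarefaction deserves a note: depth normalisation across libraries can be
done several ways, and the package takes the most conservative common
choice — subsampling without replacement (via `vegan::rrarefy`) to the
minimum retained library depth, under a caller-supplied seed that is kept
in the output metadata. Scaling methods would preserve more information
but make richness estimators incomparable across libraries; since Chao-1
and observed richness are downstream consumers, rarefaction is the
default and the depth is configurable.

# Alpha diversity

Per sample the package reports observed richness, Chao-1, Simpson
dominance, Shannon diversity and equitability:

* **Chao-1** uses the bias-corrected form
  $S_{chao1} = S_{obs} + F_1(F_1-1) / (2(F_2+1))$ with $F_1, F_2$ the
  per-sample singleton and doubleton counts. The bias-corrected
  denominator keeps the estimator finite when a sample has no doubletons,
  which happens routinely in rarefied libraries; the classic
  $F_1^2/2F_2$ form is available via an argument.
* **Simpson** is reported in its dominance orientation
  $D = \sum_i p_i^2$ (1 = one taxon dominates), matching how the index
  is conventionally read in this survey literature.
* **Equitability** is Pielou's $J = H'/\ln S_{obs}$ with natural-log
  Shannon $H'$; it is flagged undefined when a sample has fewer than two
  OTUs.

`compare_diversity()` tests an index difference between two libraries by
pooling their reads and re-splitting the pool at the original depths
without replacement, `n_perm` times (default 1000), with the two-sided
add-one-smoothed p-value $(1 + \#\{|\Delta_{perm}| \ge
|\Delta_{obs}|\})/(n_{perm}+1)$. Randomisation schemes for index
comparison differ across legacy desktop packages and are rarely spelled
out; the pooled re-split null is the exchangeable-reads interpretation
and is calibrated by simulation in the test suite (rejection rate of
same-composition pairs within binomial bounds of the nominal 5%).

# Environmental ordination

Environmental variables (attenuation coefficient, PAR, temperature,
salinity, oxygen, pH, nutrients, particulate carbon/nitrogen, suspended
matter, chlorophyll *a*, N/P) have heterogeneous units and skewed
distributions. `pca_env()` therefore Box-Cox transforms each variable
(profile-likelihood lambda on a fine grid in [-2, 2]; variables with
non-positive values get a recorded location shift; constant variables are
passed through with a warning) and then runs correlation-matrix PCA
(centred, unit variance). Covariance PCA would let a single large-variance
variable dominate, which is rarely what is wanted with mixed units, so
correlation PCA is the default and only mode.

Variable contributions to each axis are $100 \times$ the squared
unit-norm loading; they sum to 100 per axis, and contributions above 10%
are flagged "strong" (threshold configurable). Sub-surface daily light is
computed from incident light, the diffuse attenuation coefficient and
sampling depth as $I = I_0(1 - e^{-K_d Z})/(K_d Z)$, implemented with
`expm1` so the optically-thin limit is exact.

`ward_groups()` clusters dates on their first-plane PCA coordinates
(Ward criterion, `ward.D2`, on Euclidean distances) and cuts at `k = 3`
by default, the three seasonal regimes (spring bloom, stratified summer,
nutrient-rich winter) expected of a temperate coastal station.

# Community clustering and SIMPROF

Community structure uses Bray-Curtis dissimilarity
$d = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$ and group-average (UPGMA)
agglomeration, the convention of the PRIMER lineage of community-ecology
software. Similarity is reported as $100(1-d)$ percent and flat labels
are produced by cutting the tree at requested similarity levels (defaults
25% and 40%).

Whether a dendrogram's bifurcations reflect real structure is tested with
SIMPROF (similarity profile permutation test), implemented natively (R
driver, C++ permutation core) since no installed dependency provides it:

1. the observed profile is the ordered vector of pairwise similarities of
   the node's samples;
2. each permutation shuffles every OTU's values independently across
   samples, destroying co-occurrence structure while keeping every OTU's
   marginal distribution;
3. the statistic $\pi$ is the mean absolute deviation of the observed
   ordered profile from the mean ordered profile of `n_expected`
   (default 1000) permutations;
4. the p-value compares $\pi$ against `n_test` (default 999) further
   permuted profiles, with add-one smoothing.

The test is applied top-down from the root; children are examined only
while their parent shows significant structure, and maximal
non-significant subtrees form the SIMPROF-homogeneous groups. The test
suite calibrates the procedure on exchangeable null tables (i.i.d.
multinomial libraries): across 200 null surveys of 30 samples x 200 OTUs
at depth 2000 the empirical type-I error stays within binomial 95% bounds
of the nominal 5%. Fixed-depth multinomial sampling makes OTUs within a
library weakly negatively dependent, which the within-OTU permutation
null ignores; at these depths the effect is not measurable in the
calibration, but very shallow libraries with few OTUs could make the test
slightly liberal.

Derived summaries: `pair_coupling()` counts date-matched rDNA/rRNA pairs
that form a cherry (the two leaves merge with each other first — the
operational version of appearing "side by side") and pairs sharing a flat
label at the 40% cut; `season_agreement()` matches clusters to season
groups by majority vote; `venn_partition()` reports the seven-region OTU
membership partition of three clusters (an OTU belongs to a cluster if it
has at least one read there) with nearest-integer percentages of the
union; `dataset_overlap()` is exact set arithmetic on the two molecule
inventories; `ks_compare_groups()` wraps the two-sample asymptotic
Kolmogorov-Smirnov test for comparing per-group OTU-count or
read-share distributions between surveys.

# The rRNA:rDNA activity framework

For an OTU at a date, with relative abundances $r_{DNA}$ and $r_{RNA}$ in
the two libraries, the raw activity ratio is $r = r_{RNA}/r_{DNA}$,
reported on a signed scale: $+r$ when $r \ge 1$, $-1/r$ when $r < 1$, so
magnitude is always $\ge 1$ and the sign separates relatively active from
relatively inactive states (-40 reads "40 times more rDNA than rRNA
signal"). Exactly balanced OTUs get $+1$. Dates where the OTU is absent
from either library are excluded (NA): the ratio is undefined there, and
the same exclusion applies to regression inputs.

**Prevalence regression.** Per higher taxonomic group, all (OTU, date)
points of the most abundant OTUs are pooled and a reduced major axis
line is fitted to $(\log_{10} r_{DNA}, \log_{10} r_{RNA})$: slope
$= \mathrm{sign}(\rho)\, s_y/s_x$, intercept $= \bar y - b\,\bar x$. RMA
is the right family here because neither axis is a controlled predictor —
both carry sampling and compositional noise. Standard errors come from a
case-resampling bootstrap (default 1000 replicates, seeded). A group is
called **RNA-prevalent** when $b - z\,SE > 1$ and **DNA-prevalent** when
$b + z\,SE < 1$, else neutral, with $z = 2$ by default. The choice
$z = 2$ (an approximate 95% interval) is deliberate: with a one-SE band a
group whose true slope is exactly 1 would be called non-neutral roughly a
third of the time purely by estimation noise, which makes the label
meaningless; the two-SE band keeps the false-prevalence rate near 5%.
Users who prefer a fixed cut (e.g. calling groups RNA-prevalent above
slope 1.25, a convention in the field literature) can read the slope and
SE off the returned fit directly.

**Quadrant phases.** An OTU-date is classified on the rDNA axis as rare
($\le$ 0.01% of the library, as a fraction `1e-4`) or abundant (> 0.1%,
`1e-3`), and on the rRNA axis with the same thresholds as low-activity or
active. The four corners are `rare-low`, `rare-active`,
`abundant-active`, `abundant-low`; any point with either coordinate in
the intermediate band is `transition`. Both thresholds are arguments:
they are operational conventions, not biology, and are affected by
extraction efficiency, primer bias and copy-number variation. Because the
thresholds apply to relative abundances, the classification is invariant
to rescaling a library's counts.

**Timelines and early warning.** `phase_timeline()` orders one OTU's
series, defines bloom intervals as maximal runs of `abundant-active`
dates (flagging senescence when a run ends by dropping to
`abundant-low`), and raises an early-warning at any date where the rRNA
signal has crossed the abundant threshold while the rDNA signal has not
(`rare-active`, or `transition` with $r_{RNA} >$ abundant and
$r_{DNA} \le$ abundant) before a later bloom. The reported lead is the
time to the next bloom start, in days and in sampling dates. This
operationalises "activity rises before abundance" as a threshold
crossing; it deliberately does not attempt changepoint detection, so its
resolution is one sampling interval and it requires sampling frequent
enough to place dates inside the lead window.

# The synthetic community generator

`synthetic_truth()` + `simulate_community()` generate paired tables with
known ground truth. The model:

* each OTU belongs to one of three seasonal guilds (spring/summer/winter
  peaks at days 105/210/350) with a Gaussian bump in log biomass: peak
  day jittered around the guild peak (sd 15 d), width 20-45 d, amplitude
  3.5-6 natural-log units, on a lognormal baseline (sd 2);
* per-date AR(1) log-noise (sd 0.4, autocorrelation 0.6) on biomass,
  shared between the two molecules of a date — the same water was
  sampled;
* rDNA sampling weight = group copy-number multiplier x biomass (the
  multipliers span 1-100x, dinoflagellates at the top); rRNA weight =
  activity x biomass with lognormal activity noise (sd 0.5), *without*
  the copy-number factor — copy number inflates gene counts, not
  ribosome counts;
* one designated bloom taxon (a *Phaeocystis*-like haptophyte, sharp
  spring bump of width 12 d and amplitude 8) whose activity profile has
  its rising edge shifted `bloom_lead_days` (default 21) earlier,
  plateaus at the peak value and decays together with biomass: ribosome
  build-up anticipates proliferation, senescence shuts both down. Its
  baseline is calibrated per molecule so that its off-season relative
  abundance is `bloom_base_rel` (0.001%) in both libraries — the two
  libraries have different normalising totals (only rDNA carries copy
  numbers), and without the per-molecule calibration a constant offset
  would masquerade as extra lead;
* reads are drawn multinomially at the configured depths (defaults
  20,000 rDNA / 10,000 rRNA per library, 30 roughly-monthly dates, 900
  OTUs — the scale of a multi-year coastal survey).

The seasonal amplitude default (3.5-6 log units, i.e. 30-400x swings) was
chosen so that the three guilds are recoverable as three clusters at the
25% similarity cut, the regime the framework is about; temperate
bloom-forming taxa routinely swing three to four orders of magnitude.
OTU-level parameters are drawn under `param_seed`, the sampling run under
`seed`, so changing only `seed` resamples reads around identical expected
values (the generator returns those expectations for parameter-recovery
tests).

What the generator does **not** emulate: zero-inflation beyond sampling
zeros, PCR/chimera artefacts, taxonomy misassignment, interannual regime
shifts, and inter-taxon interactions (each OTU's trajectory is
independent given its guild). Passing tests on this generator therefore
validate the statistical machinery, not robustness to those real-data
pathologies.

`simulate_null()` draws every library i.i.d. from one shared multinomial
— the exchangeable null used for SIMPROF and diversity-comparison
calibration. `simulate_rma_points()` draws from the symmetric
errors-in-variables model for which RMA is consistent ($x = t + e_x$,
$y = b + \beta t + e_y$ with $sd(e_y) = |\beta|\,sd(e_x)$), used for
slope-recovery tests at planted slopes 0.9 / 1.0 / 1.25.

# Numerical and design choices

* Ratio at exact balance returns +1 (no values inside (-1, 1) exist on
  the signed scale).
* Quadrant boundaries: rare means $\le$ the rare threshold, abundant
  means $>$ the abundant threshold; exact-threshold points fall in the
  transition band rather than a corner.
* Ties in `top_abundant_otus()` break lexicographically by OTU id, so
  selections are reproducible across platforms.
* `rarefy()` and every stochastic routine take an explicit integer seed
  and restore the caller's RNG state.
* Cutting a dendrogram at similarity $s$ uses height $1 - s/100$;
  because UPGMA heights are monotone, cutting at higher similarity never
  merges clusters separated at lower similarity.
* Degenerate inputs error early with named samples/OTUs in the message
  (zero-read libraries, counts that are negative or fractional,
  duplicate (date, molecule) pairs, all-zero vector pairs in
  Bray-Curtis).

## Problem sizes used by the test suite

Simulation-based tests run at sizes chosen to make their statistical
assertions sharp while keeping the whole suite fast on one CPU: SIMPROF
calibration on 200 null surveys of 30 x 200 at depth 2000 (the package's
default 1000/999 permutations each), RMA recovery on 20 seeds x 300
points per planted slope, early-warning recovery on 20 seeds of a
40-week weekly series with 300 background OTUs, and guild-recovery
clustering on 30 monthly dates x 300 OTUs at depth 5000. The full suite
runs in under two minutes.

# Known limitations

* rRNA:rDNA ratios conflate activity with copy-number and cell-size
  variation between taxa; the framework reads them as *relative* activity
  within an OTU across dates, and between-group slope comparisons should
  be interpreted with the same caution.
* SIMPROF p-values are permutation ranks; with the default 999 test
  permutations the smallest attainable p is 0.001.
* The early-warning rule is a threshold crossing; leads shorter than one
  sampling interval are invisible, and irregular sampling makes the
  "lead in sampling dates" unit heterogeneous.
* The Box-Cox grid search covers lambda in [-2, 2]; variables needing
  more extreme transforms hit the boundary (and say so via the returned
  lambda).
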