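---
title: "Scale decomposition of ancestry and recombination signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale decomposition of ancestry and recombination signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixwave)
```

## The model

`admixwave` analyzes genomic signals measured at evenly spaced positions
along chromosomes — above all the *local ancestry proportion* of an admixed
population, i.e. the fraction of sampled haplotypes assigned to one source
population at each position — and decomposes their variance and their
correlation with other signals (recombination rate, coding density) into
contributions from dyadic spatial scales.

The decomposition uses the maximal-overlap discrete wavelet transform
(MODWT) with Haar wavelets. A Haar wavelet of scale $\lambda$ ending at
position $i$ is $-c$ on the $\lambda/2$ positions before the midpoint and
$+c$ after; its inner product with the signal measures the difference of two
adjacent windowed means. Unlike the decimated transform, the MODWT places a
wavelet at every position, so it is shift-covariant and its per-scale
variance estimates are far less noisy; scales remain orthogonal in the sense
that the per-scale variances still partition the total signal variance.

### Normalization

We follow the Percival–Walden MODWT convention: the level-1 wavelet filter is
$(1/2, -1/2)$ and the level-$j$ equivalent filter has entries $\pm 2^{-j}$
over a support of $2^j$ grid points. Under this convention the energy
identity is exact: with the *biased* estimator (mean of squared coefficients
over all $L$ positions per level, circular convolution) the per-scale
variances plus the scaling variance equal the population variance of the
signal to machine precision, and white noise of variance $\sigma^2$ has
expected wavelet variance $\sigma^2 2^{-j}$ at level $j$. Any internally
consistent convention would do; this one is fixed by the package's oracle
tests (direct inner products with explicitly constructed wavelet vectors)
and used everywhere, including in the closed-form neutral expectation.

### Boundary coefficients and the two estimators

Circular convolution makes the first $2^j - 1$ coefficients at level $j$
wrap the chromosome end. The default `unbiased` estimator excludes them,
giving unbiased per-scale variances at the cost of the variance proportions
becoming approximate; the `biased` estimator keeps them and reconstructs
totals exactly. The exact-reconstruction tests therefore always use
`biased`; reported magnitudes default to `unbiased`.

### Genome-wide aggregation

Chromosomes differ in length, so a scale can exist on some chromosomes only.
Two averages are reported per scale: the raw magnitude (length-weighted mean
over chromosomes where the scale exists) and the contribution to total
genomic variance (zero assigned to chromosomes lacking the scale, so that
contributions plus the among-chromosome and scaling components sum to one).
The among-chromosome component is the length-weighted variance of chromosome
means — variance invisible to within-chromosome wavelets. The scaling
component is the leftover broad-scale smooth variance present whenever $L$
is not a power of two; with a fixed measurement resolution it is always
present but typically minor.

For two signals, the overall correlation decomposes as
$\mathrm{Cor}(x,y) = \sum_\lambda c_\lambda \rho_\lambda$ plus
among-chromosome and scaling terms. Per-scale correlations $\rho_\lambda$
are computed from coefficients pooled across chromosomes with length
weights, which is more stable at broad scales (few coefficients per
chromosome) than averaging per-chromosome correlations. The weight
$c_\lambda$ is the *geometric* mean of the two signals' per-scale variance
proportions: that is the choice under which the single-chromosome biased
decomposition reproduces the direct Pearson correlation exactly (the
arithmetic mean, offered as an option, does not).

### Confidence intervals

Uncertainty comes from a weighted delete-one-chromosome jackknife
(block-length-weighted pseudovalues; with equal weights it reduces to the
ordinary delete-one jackknife). Intervals are z-based and centered on the
full-sample estimate, and are omitted at scales with fewer than three
contributing chromosomes — at such scales the jackknife variance is not
meaningful, which is also why the largest scale of a genome, often present
on a single chromosome, should be interpreted with caution.

### Per-scale variance explained

`variance_explained_by_predictor()` regresses pooled non-boundary wavelet
coefficients of a response on those of one or more predictors, scale by
scale, without an intercept — wavelet coefficients are zero-mean by
construction, so an intercept would absorb nothing and cost a degree of
freedom. Under the assumption that only systematic selection can correlate
ancestry with recombination rate, the per-scale $R^2$ estimates the fraction
of ancestry variance attributable to selection at that scale.

## Preprocessing choices

* **Interpolation.** Irregular observations are interpolated onto grids
  anchored at the first observed position (avoiding extrapolation), with
  `linear` interpolation for proportion-like signals and `step` (nearest
  preceding observation) for piecewise-constant signals such as haploid
  ancestry state. Gaps are an interpolation concern: the transform itself
  requires complete grids.
* **Diploid dosage.** Genotype-posterior tracks reduce to the expected
  within-diploid frequency $\hat p = P(AA) + P(Aa)/2$; triples must sum to 1
  within $10^{-6}$.
* **LD-based maps.** Population-scaled maps ($\rho = 2N_e r$) are rescaled
  to Morgans by dividing by a genome-wide $2N_e$, estimated as the slope of
  a through-the-origin regression of cumulative $\rho$ lengths on crossover
  map lengths — a chromosome of zero crossover length must have zero $\rho$
  length, which fixes the intercept at zero. Because LD maps carry extreme
  outliers, per-interval rates above a user threshold are capped
  (winsorized) rather than removed, so the map still covers the chromosome.
* **Log rates.** Finely resolved rate maps are strongly right-skewed; an
  optional log transform uses offset equal to half the smallest positive
  rate, keeping zero rates finite while leaving well-separated values
  essentially untouched.

## The simulator and what it emulates

The Wright–Fisher junction simulator tracks ancestry switch points along
haplotypes on the genetic map. Founding (generation 0) consists of exactly
$\alpha \cdot 2N(0)$ pure introgressed haplotypes paired randomly into
diploids; each generation samples parents fitness-proportionally (uniformly
under neutrality) with replacement and forms gametes with
$\mathrm{Poisson}(\text{map length})$ crossovers placed uniformly on the
genetic map — no interference, which is immaterial on the map scale — and
independent assortment across chromosomes. Mating is monoecious with selfing
allowed (negligible at the population sizes used, and a simpler contract).

Selection follows the linear polygenic model $w_i = 1 - p_i S m(t)$, where
$p_i$ is the individual's mean introgressed dosage over the selected loci,
$S$ the total selection coefficient ($S = 1$ makes an F1 hybrid's fitness
exactly $1/2$), and $m(t) \in [-1, 1]$ a per-generation schedule (off,
active, reversed). Fitness is clamped at zero for safety at user-chosen
$S$. Selected loci are placed uniformly on the genetic map by default; with
a recombination map they may be placed uniformly on the *physical* map,
which is what creates ancestry–recombination correlations — low-rate regions
then carry more selected loci per Morgan. `run_selection_scenarios()`
packages the canonical timing experiments (continuous, first-10-generations,
onset-at-500, reversal-at-100, each against a matched-seed neutral control)
on a fixed, deterministic two-chromosome map (1 and 0.8 Morgans over 100 Mb
each) whose log-sinusoidal rate profile provides broad- and medium-scale
heterogeneity without consuming random numbers.

What a green simulation test does *not* establish: the simulator samples the
full population by default (a subsample option emulates finite samples), its
"ancestry" is true descent rather than inferred similarity, and signals are
computed directly on the genetic-map grid. Real data add local-ancestry
inference error (including systematic biases toward or against detection in
low-recombination regions), recombination-map error, and
physical-to-genetic interpolation noise — all of which propagate into the
wavelet statistics and can mimic or mask fine-scale selection signals.

## The neutral expectation

The expected wavelet variance of the ancestry proportion under pure drift is
obtained from the spatial covariance of ancestry frequency. For loci
separated by $d$ Morgans, trace one lineage per locus backward in time: a
pair in the same gamete splits onto the parent's two haplotypes with
probability $(1 - e^{-2d})/2$ per meiosis (Haldane's map function, exact for
the simulator's Poisson crossovers), and a pair in different haplotypes
coalesces with probability $1/2N(t)$ per generation. With $f(d)$ the
probability that the pair reaches the founding generation on a single
founder haplotype, exact-count founding gives

$$\mathrm{Cov}(d) = \alpha(1-\alpha)\left(f(d) - \frac{1-f(d)}{2N(0)-1}\right),$$

which reduces at $d = 0$ to the classical drift law
$\alpha(1-\alpha)(1 - (1 - 1/2N)^t)$ and vanishes identically at $t = 0$.
The expected level-$j$ wavelet variance is this covariance summed against
the exact (triangular) autocorrelation of the level-$j$ Haar MODWT filter,
and equals the expectation of the unbiased estimator. Arbitrary $2N(t)$
trajectories are supported by iterating the two-state lineage chain with
time-varying coalescence rates, so bottleneck and expansion scenarios use
the same code path. The package's tests verify the expectation against
simulated spectra (3 Monte-Carlo-SE bands) for constant and bottleneck
trajectories.

```{r theory-example}
expected_neutral_wavelet_variance(two_n = 200, generations = 10,
                                  levels = 1:8, resolution = 2^-10)
```

## Numerical and design notes

* Grid evenness is checked to a relative tolerance of $10^{-6}$; the maximum
  level defaults to $\lfloor \log_2 L \rfloor$.
* Zero wavelet variance at a scale makes the correlation there undefined; it
  is reported as `NA`, never as 0. Scales with fewer than three pooled
  coefficient pairs have undefined $R^2$.
* All stochastic paths run on R's RNG (including the C++ core), so a single
  `set.seed()` — or the `seed` recorded in a `sim_config` — reproduces every
  output byte-for-byte.
* Coordinates are 0-based with half-open map intervals $[start, end)$;
  genetic positions are cumulative Morgans from the chromosome start.
* Desk-scale test experiments shrink realistic settings (population
  sizes in the thousands rather than tens of thousands, two synthetic
  chromosomes rather than a genome-wide map) so the full suite runs in
  minutes; assertions are correspondingly formulated as orderings, sign
  patterns, and Monte-Carlo-SE bands rather than point reproduction.

## Known limitations

* Haar wavelets only; no other filters, 2-D transforms, or shrinkage.
* No continuous migration or hybrid-zone geography in the simulator; no
  mutation, dominance, or epistasis in the fitness model.
* The variance-explained regression inherits the assumption that nothing but
  selection correlates ancestry with the predictor; violations (e.g. biased
  ancestry calling by recombination environment) masquerade as selection.
* Local-ancestry inference itself is out of scope: the package consumes
  ancestry calls or posteriors, it does not produce them.
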