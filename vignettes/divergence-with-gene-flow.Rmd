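---
title: "Quantifying population-genetic divergence under gene flow with divflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying population-genetic divergence under gene flow with divflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divflow)
library(dplyr)
```

## The problem

Host-associated insect taxa that diverge while still exchanging genes — host
races, incipient species, and recently split sister species — leave a
characteristic population-genetic signature: allele-frequency differences that
must be actively maintained against the homogenizing pressure of migration.
divflow implements a complete analysis pipeline for multilocus microsatellite
surveys of such systems: within-population statistics (allele frequencies,
F~IS~), allelic richness by rarefaction, private-allele detection,
differentiation (Jost's D~EST~, Nei's D with neighbor-joining population
networks), a per-locus principal-component analysis of latitudinal clines, a
likelihood classifier for migrant and hybrid genotypes, and — at its core — a
two-island migration–selection equilibrium model that converts an observed
frequency difference and an assumed gross migration rate into the selection
coefficient required to maintain that difference.

All user-facing functions take a data frame first and return tibbles, so
analyses compose with the pipe. A long-format genotype table (`individual`,
`population`, `locus`, `allele_1`, `allele_2`, alleles as fragment lengths in
bp, `NA` = missing) and a population metadata table (`population`, `taxon`,
`latitude`, ...) are the shared currency; `read_genepop()` and
`read_genotypes_csv()` produce the former.

## The two-island migration–selection model

Consider one locus collapsed to two allele classes (below) in two demes of
equal size exchanging a symmetric gross migration fraction $m$ per
generation. Writing $p$ for the frequency of the locally favored class in its
resident deme, one generation applies migration

$$p \leftarrow (1-m)\,p_\text{resident} + m\,p_\text{immigrant}$$

and diploid viability selection with genotype fitnesses $(1,\; 1-hs,\; 1-s)$
for the favored homozygote, heterozygote and disfavored homozygote. With
additive fitness ($h = 1/2$, the package default) the one-generation
selection response is

$$\Delta p_\text{sel} = \frac{p q s / 2}{1 - q s}, \qquad q = 1 - p.$$

At equilibrium the selection gain exactly compensates the migration loss
$\Delta = m\,(p_\text{resident} - p_\text{immigrant})$, which inverts in
closed form to

$$\hat s = \frac{\Delta}{q\,(p/2 + \Delta)}.$$

`required_s()` exposes two conventions for where that balance is evaluated,
because the equilibrium bookkeeping admits both readings and they differ at
the third decimal for realistic values:

* **compensatory** (default): the selection response is evaluated at the
  observed resident frequency;
* **sequential**: migration acts first and selection must return the
  post-migration frequency to the observed value. This convention is the
  exact inverse of the migration-then-selection recursion: equilibria
  generated by `iterate_two_island_deterministic()` are inverted to machine
  precision (the test suite checks `1e-6`; observed error is `~1e-13`).

For general dominance the full diploid update is solved by bisection on
$s \in [0, 1]$ (`uniroot`, tolerance `1e-12`); at $h = 1/2$ the closed form
and the bisection agree to better than `1e-8` across the grid
$m \in \{0.01, 0.03, 0.05, 0.1\}$, $p_\text{resident} \in [0.55, 0.95]$,
$p_\text{immigrant} \in [0.05, 0.5]$.

A required $\hat s > 1$ means the observed difference cannot be maintained at
equilibrium under the assumed $m$: the value is reported as 1 with a `capped`
flag, and per-direction summaries (mean/min/max) are computed on the capped
values, matching how such coefficients are conventionally reported. A
resident class frequency of exactly 0 or 1 leaves no segregating variation
for selection to act on; those loci are additionally flagged `degenerate`.

**Interpretation.** The estimates are not literal per-locus selection
coefficients: the model assumes equilibrium, direct selection on each locus
independently, symmetric migration, and composite two-class frequencies.
They measure the magnitude of divergent selection — direct plus linked plus
genome-wide — needed to hold the observed differentiation in place.

### Allele-class pooling

Microsatellite loci carry many alleles; `pool_alleles()` collapses a locus at
one sympatric pair into a single frequency contrast by assigning every allele
that is more common in the ancestral population to the "ancestral" class and
the rest to the "derived" class. Ties — including alleles absent from both
populations — go to the ancestral class; they contribute identically to both
class frequencies, so the maintained difference $a_1 - a_2$ is unaffected and
$a_1 \ge a_2$ holds by construction. `pair_selection_profile()` then solves
for $s$ in both directions: against the derived class in the ancestral
population (resident $a_1$, immigrant $a_2$) and against the ancestral class
in the derived population (resident $1-a_2$, immigrant $1-a_1$).
`asymmetry_tests()` compares the directions with a paired t-test across loci
and an F test on the variance ratio (derived-direction variance in the
numerator, two-sided p).

Migration rates are inputs, never estimated. For surveys with several
sympatric pairs they live in the pair table of the pipeline configuration;
field estimates of gross migration (mark–recapture, observed hybridization
rates) are the intended source.

## Differentiation statistics

`jost_dest()` implements Jost's D from the Nei–Chesser bias-corrected
heterozygosities with the harmonic-mean sample size and the $n/(n-1)$ factor
($n = 2$ demes). D~EST~ partitions diversity by effective allele numbers and
is preferred here because the loci are highly polymorphic within populations,
which compresses the range of F~ST~-family measures. Slightly negative
estimates (identical populations plus sampling noise) are clamped to 0 and
flagged, with the raw value retained in `dest_raw`; a locus monomorphic
across both populations is 0 by convention.

`nei_d()` is the classical standard genetic distance: the normalized identity
is formed from sums over **all loci jointly** (not a mean of per-locus
distances), and $D = -\ln I$. `nj_tree()` wraps neighbor joining (via the ape
package) with validation and a clamp that moves negative branch lengths to
zero, transferring the deficit to the adjacent branch. `bootstrap_support()`
resamples **loci** with replacement, rebuilds the distance matrix and tree
per replicate (the per-locus identity components are precomputed, so
replicates are cheap), and reports the percentage of replicates containing
each bipartition of the all-loci tree. Supports are reproducible bit-for-bit
for a fixed seed. These networks describe current allele-frequency
dissimilarity; under ongoing gene flow they are not rootable as a historical
phylogeny.

## Rarefied allelic richness and private alleles

`rarefied_richness()` computes the expected number of distinct alleles in a
standardized subsample of $g$ gene copies from the hypergeometric
expectation

$$\alpha_g = \sum_i \left(1 - \binom{N - N_i}{g}\Big/\binom{N}{g}\right),$$

exact against exhaustive subset enumeration (the suite verifies every allele
configuration with $N \le 12$). The default standardization takes $g$ up to
the smallest gene-copy count among the populations being compared, so
populations with unequal sampling are comparable.

`fit_asymptote()` extrapolates each curve with the saturating two-parameter
form $\alpha(g) = A\,(1 - e^{-g/B})$, with $A$ constrained to at least the
observed curve maximum (bounded Levenberg–Marquardt via minpack.lm). The
negative-exponential form was chosen over the hyperbolic
(Michaelis–Menten) alternative after direct comparison: rarefaction curves
saturate quickly, and on data simulated from a known 15-allele population the
hyperbolic fit overshoots the true allele count by 20–50% while the
negative-exponential form lands within a few percent. `allelic_richness()`
averages the fitted asymptotes across loci per population, and
`compare_richness()` runs the one-way ANOVA across taxon groups on
population-level means with Tukey HSD letter groups (single-population groups
are excluded from the test, since they contribute no within-group variance).

`private_alleles()` flags alleles entirely absent from every reference-taxon
population and present in at least `min_pops` (default 2) focal populations —
the two-population rule screens out singleton mutations and site-local
variants; set `min_pops = 1` for taxa represented by a single population.
The reported taxon-wide frequency is gene-copy weighted across all focal
individuals.

## Latitudinal clines and the mosaic analysis

Clinally varying life-history loci in a widespread ancestral taxon are a
reservoir of standing variation from which derived taxa can assemble novel
phenologies. The package quantifies this in three steps:

1. `locus_pca()` collapses the allelic variation at one locus across the
   ancestral populations by PCA on the centered population × allele frequency
   matrix (populations are the observational unit; no scaling). The PC1 sign
   is fixed so that score correlates non-negatively with latitude — higher
   score = more northern — making reports deterministic.
2. `detect_clinal_loci()` flags "major clinal" loci with
   $|r(\text{PC1}, \text{latitude})| \ge 0.8$ and $p \le 0.05$. The
   threshold is configurable; 0.8 operationalizes "strongly correlated"
   and, with ≥ 14 ancestral populations, keeps the false-flag probability
   per locus below 0.1%.
3. `project_and_classify()` projects derived-taxon frequency vectors onto the
   ancestral axes (alleles unseen in the ancestral populations get zero
   loading — they carry no positional information — and are counted in the
   report). The taxon mean score receives a 95% CI: a percentile bootstrap
   over populations when the taxon has ≥ 3, otherwise a parametric bootstrap
   over gene copies (multinomial resampling of allele counts). The ancestral
   reference band is the pointwise 95% confidence band of the linear
   regression of ancestral score on latitude, evaluated across the derived
   taxon's latitude range; a taxon is `northern_like` at a locus if its CI
   lies entirely above the band, `southern_like` entirely below, else
   `mid_latitude`. The regression-band rule is the simplest defensible
   reading of "CI overlap" when the derived taxon must be compared to what
   the ancestral cline predicts *at its own latitudes*; the CI unit
   (populations vs gene copies) switches automatically with the data.

## Hybrid-class likelihoods

`classify_individuals()` is a transparent, deliberately simplified detector
of ongoing gene flow between one sympatric pair: it conditions on two
predefined parental pools rather than jointly inferring clusters by MCMC, so
its output is not a replacement for a full admixture analysis. Five
genotypic classes are scored per individual — pure natal, pure parental
migrant, F1, backcross to the natal pool, backcross to the other pool —
through explicit gamete-origin models (backcross = one gamete from the
parental pool, one from the even F1 gamete mixture; heterozygote factor 2
when sources are exchangeable). Ancestry deeper than two generations is not
modeled. Pool frequencies are estimated leave-one-out for the focal
individual's natal population; alleles unseen in a pool are floored at
$1/(2N+1)$ so likelihoods stay finite. The prior mass `migration_prior`
(default 0.01, the conservative end of the usual 0.01/0.05/0.1 ladder) is
split evenly across the four non-natal classes — a flat two-generation
ancestry prior; with identical parental pools every class likelihood is
equal and the posterior returns the prior exactly, which the suite asserts.
When the pools' mean D~EST~ falls below 0.05 the function warns that
genotypic detection of migrants and hybrids is not well supported — at the
host-race end of the divergence continuum this warning is the expected
result.

## The synthetic-data generator

`simulate_two_island()` is a Wright–Fisher implementation of the model above:
per generation, deterministic migration + selection expectation at the
class level, stepwise mutation (labels move ±2 bp, the dinucleotide repeat
unit, class inherited from the parental allele), and multinomial drift over
$2N_e$ gene copies per deme; individuals are sampled without replacement
from the final gene-copy pool. The life-cycle order (migration-then-selection
by default) is a flag, and both orders are supported by the deterministic
recursion too. `simulate_cline()` interpolates clinal allele frequencies
linearly along latitude with binomial sampling noise.

`make_rpsg_fixture()` composes these into a survey-shaped dataset: 33
populations from 6 taxa at 19 loci, ~1568 diploid individuals in total with
per-population sample sizes following the survey design (26–105), seven
latitudinal clines in the 14-population ancestral taxon spanning 29–46° N,
an apple-race-like recently derived taxon tracking the ancestral frequencies
at its latitude, three species-level taxa with private alleles injected at
5, 9 and 13 loci (two of the most divergent taxon's private alleles fixed),
reduced allelic richness in one taxon, and seven sympatric ancestral/derived
pairs with assumed migration rates of 0.045 (apple/downy hawthorn), 0.05
(mayhaw/green hawthorn), 0.04 (blueberry hawthorn/mayhaw), 0.03 (flowering
dogwood fly), 0.02 (blueberry fly) and 0.01 (snowberry fly); the
single-population taxon's pair carries no defensible rate and is excluded
from selection profiles. Everything is a deterministic function of one seed.

What the generator does *not* emulate — and hence what green tests do not
demonstrate about real data: linkage and inversion polymorphism (loci are
simulated independently), null alleles and genotyping error, asymmetric or
temporally varying migration, non-equilibrium demography (bottlenecks,
range expansion), and isolation by distance within taxa beyond the planted
clines.

## Numerical and design choices

* F~IS~ is `1 - H_obs/H_exp` with the small-sample-corrected expected
  heterozygosity `2n/(2n-1) (1 - Σp²)`; the across-loci value is a ratio of
  sums, and its 95% CI a percentile bootstrap over loci (10,000 replicates,
  seeded). Monomorphic loci are excluded with a message. The estimator
  choice matters little downstream — only the CI-overlaps-zero check is
  consumed.
* GENEPOP I/O treats any call containing a zero code as wholly missing, and
  never re-bins fragment lengths; an explicit code→bp sidecar table handles
  the 2/3-digit limit.
* Missing (population, locus) combinations yield `n_copies = 0` rows with
  `NA` frequencies — undefined, never silently zero.
* NJ tie-breaks follow the underlying implementation deterministically;
  trees and bootstrap supports are identical across reruns with one seed.
* All randomness flows from explicit seed arguments; the pipeline derives
  stage seeds deterministically from one master seed, and reruns are
  byte-identical.
* Default problem sizes in the test and acceptance runs — 50 Wright–Fisher
  recovery replicates at $N_e = 10^4$ and $n = 50$, 100 mosaic replicates,
  200 random trees, 1000-replicate null calibrations — were chosen as the
  smallest sizes at which the Monte-Carlo error is comfortably inside each
  check's tolerance.

## Known limitations

The selection estimates inherit every assumption of the equilibrium
two-island model; they are comparative magnitudes, not measurements. When
both demes fix (one direction's selection too weak against migration) the
observed frequencies carry no signature of $s$ and inversion is undefined —
the solver reports the capped/degenerate flags rather than a number
pretending otherwise. The hybrid classifier's backcross-to-natal class is
intrinsically hard to separate from pure natal genotypes at moderate
divergence; expect its accuracy to degrade first as differentiation drops.
The clinal classification depends on a linear score–latitude relationship in
the ancestral taxon; strongly sigmoid clines would need a different reference
band.
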