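---
title: "Methods: pedigree and SNP-based genetic diversity in herddiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree and SNP-based genetic diversity in herddiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herddiv)
```

herddiv quantifies the loss of genetic diversity in managed livestock
populations — dairy cattle being the motivating case — from two independent
data sources: the herd book (pedigree) and medium-density SNP genotypes.
This vignette documents the models and the choices behind them; it states
no empirical result that the package's tests do not themselves compute.

## Pedigree inbreeding and pedigree depth

`compute_fped()` computes, for every animal, the probability F that its two
alleles at a locus are identical by descent. The algorithm is the tabular
recursive-kinship method (the Meuwissen–Luo family): animals are processed
in topological order and each animal's F is accumulated in one descending
sweep over its ancestors' within-family segregation variances, giving
O(pedigree × depth) time without materializing an additive relationship
matrix. Correctness is not argued from the code: the test suite checks
exact (≤ 1e−12) agreement with an independent naive recursive-kinship
oracle on randomly generated pedigrees.

Conventions: an animal with at most one known parent has F = 0 (founders
are assumed unrelated and non-inbred); unknown parents referenced in the
file are auto-added as founders; a pedigree cycle is a hard error naming an
animal on the cycle.

The **complete generation equivalent** `compute_cge()` measures pedigree
depth as the sum over all known-ancestor paths of $(1/2)^g$ (parents
$g = 1$), computed by the recursion $\mathrm{CGE}_i = \sum_{p}
\tfrac12(1 + \mathrm{CGE}_p)$ over known parents $p$. Both parents known
and nothing deeper gives 1.0; parents plus all grandparents gives 2.0.
No published worked value exists to check against, so the tests pin the
recursion to the path-sum definition directly.

**Generation intervals** (`generation_intervals()`) are average parent ages
at offspring birth, split into the four classical selection pathways; the
offspring's sex routes the pair (male offspring → "of bulls"). Pairs with
missing birth years are skipped and tallied; non-positive intervals
(biologically impossible, usually data errors) are excluded with a warning
rather than silently kept — the data-cleaning convention, since the source
material is silent on the case.

## Pedigree-based effective population size

`pedigree_ne()` windows annual mean inbreeding into generation-length
cohorts (default 5 years, matching the overall dairy-cattle generation
interval) and converts the change in $\ln(1-\bar F)$ between consecutive
cohorts into a per-generation rate, $\Delta F_{gen} = 1 - (1-\bar
F_t)/(1-\bar F_{t-1})$, then $N_e = 1/(2\Delta F_{gen})$. Two open choices
had to be settled:

* *Per-boundary rather than one global regression.* Field reports show Ne
  trajectories per generation (rising and falling over decades), which a
  single regression slope cannot produce. The consecutive-cohort contrast
  is exactly the two-point form of the same $\ln(1-x)$ regression used by
  the trend module, so the rate machinery stays internally consistent
  while yielding a series. On data constructed with constant
  $\Delta F$ the series recovers Ne exactly (tested to 1e−9).
* *Window vs generation length.* When the window width differs from the
  stated generation interval the per-window rate is rescaled through
  compound decay, $(1-\Delta F_{win})^{g/w}$.

A non-positive rate (inbreeding flat or decreasing) is reported as an
`infinite_ne` flag, never as a number.

## SNP quality control

`qc_filter()` drops SNPs (never samples — sample curation belongs to the
upstream genotyping/imputation pipeline) by five criteria evaluated in a
fixed order, each dropped SNP recording the first failing criterion:
call rate < 0.95 → parent–offspring mismatch > 0.01 → MAF < 0.01 →
genotype-class frequency < 0.001 → exact HWE p < 0.005.

Two ambiguities were resolved as follows:

* *"Genotype frequency < 0.001"* is read as the frequency of the least
  frequent **observed** genotype class among non-missing calls, a criterion
  distinct from MAF (it catches, e.g., excess rare homozygotes at common
  SNPs). The threshold is configurable for users who prefer the
  per-SNP-missingness reading.
* *HWE test*: an exact conditional test (probability-ordering two-sided
  convention, computed with log-factorials) rather than chi-square, because
  the cut-off (p < 0.005) operates in the extreme tail where the chi-square
  approximation is unreliable at moderate counts. A mid-p variant is
  available behind a flag. The implementation is tested against a direct
  combinatorial enumeration oracle for all configurations up to n = 30.

The Mendelian criterion counts opposing-homozygote parent–offspring pairs
per SNP (an animal with two genotyped parents contributes two pairs) and is
silently skipped (`NA`) for SNPs with no informative pair.

Dosages are oriented to the lexicographically smaller observed allele at
read time; MAF, homozygosity, HWE and r² are orientation-invariant
(asserted by test), so this choice is cosmetic but makes outputs
deterministic.

## Runs of homozygosity and F_ROH

`detect_roh()` implements the consecutive-runs scan (the criteria map
one-to-one onto it; the sliding-window alternative needs extra window
parameters the criteria do not mention). Semantics, fixed precisely because
the tests compare against an exhaustive window-enumeration oracle:

1. A candidate run must start and end on a homozygous, non-missing call
   (a run may not *begin or end* on its one allowed heterozygous/missing
   SNP — allowing that would extend runs on non-evidence); contain at most
   one heterozygous and one missing call; and span no inter-SNP gap larger
   than 500 kb.
2. Candidates are selected left to right: each run is the longest
   admissible run starting at the leftmost available homozygous SNP, and
   runs of one sample/chromosome are disjoint. (Without a selection rule,
   overlapping maximal windows exist whenever two heterozygous calls are
   close together; leftmost-longest is deterministic and matches what a
   linear scan produces.)
3. Surviving candidates are filtered by ≥ 15 SNPs, length ≥ 1 Mb, and
   density ≥ 1 SNP / 100 kb — the density computed on the whole segment,
   not per window.

Segment length is `end_bp − start_bp` (the detectRUNS convention; the +1 bp
alternative is immaterial at Mb scale but the choice is fixed for
determinism).

`compute_froh()` divides each sample's summed segment length by `L_AUTO`,
by default the SNP-covered autosome length of the panel's own map (a fixed
published constant such as 2.48 Gbp is data-specific; a CLI override
`--l-auto` reproduces fixed-constant behavior). `froh_by_length_class()`
splits F_ROH over half-open length classes (1,2], (2,4], … (32,∞] Mbp —
long ROH mean recent inbreeding, short ROH old inbreeding — and the class
values sum exactly to the total per sample (tested as an identity).

`inbreeding_summary()` flags "highly inbred" animals above mean + 3 SD per
coefficient. The overlap of the two flag sets is reported both as Jaccard
(intersection over union) and as intersection over the smaller set, because
the denominator of the published "% in common" style statistic is not
standardized.

## LD-based effective population size

`pairwise_r2()` computes r² as the squared Pearson correlation of unphased
dosage vectors over pairwise-complete samples — the right convention for
cow data, which are unphased; phased-haplotype r² is out of scope. Pairs
are intra-chromosomal, distance-capped, and skipped below a MAF floor
(default 0.05).

`bin_pairs_by_generation()` uses the classical correspondence that LD at
recombination fraction c reflects effective size about $t = 1/(2c)$
generations ago. Physical distance converts to map distance at a flat rate
(default 1 cM/Mb; no genetic map is assumed) and then to c via a chosen
mapping: `linear` (c = d), `haldane` ($c = (1-e^{-2d})/2$), or
`sved_feldman`. For the last, the exact closed form used by legacy tools
could not be verified offline; the implemented hyperbolic form
$c = d/(1+2d)$ (c ≈ d for small d, saturating at 1/2) is the mapping under
which $1/E[r^2]$ grows linearly with distance in the drift-LD model, which
is that mapping's purpose. All package-internal validation uses the linear
mapping at small d, where the mapping choice is immaterial.

`estimate_ne()` inverts $E[r^2_{adj}] = 1/(\alpha + 4N_ec)$:
$N_e(t) = \frac{1}{4c_t}(1/r^2_{adj} - \alpha)$, after subtracting a
sample-size correction from the bin mean r² (default `1/n`, appropriate
for unphased dosage r²; `1/(2n)` and `none` available — legacy tools apply
their own unprinted corrections, so ours is explicit). α = 2.2 is the
conventional mutation modifier for cattle; α = 1 is correct for pure drift
without mutation, and is what the Wright–Fisher recovery test uses, since
the simulator has no mutation. Non-positive adjusted r² yields a flagged
row, never a silent drop. The recovery test demands the median estimate
across 10 simulations of a true-Ne-100 population to fall within ±30% for
every bin t ∈ [5, 20]; bins at larger t are narrower than 0.12 Mb of map
distance, which dictates the test map's 0.1 Mb SNP spacing.

## Inbreeding-rate trends and the two-era contrast

`delta_f_per_year()` regresses $\ln(1 - \bar F_{year})$ on birth year.
Under the classical recursion $(1-F_t) = (1-\Delta F)^t$ the slope b gives
$\Delta F = 1 - e^b$ exactly — the implemented default. (A literal "inverse
of the slope", 1/b, is dimensionally nonsensical; the first-order reading
$\Delta F = -b$ is available as `convention = "neg-slope"`, and the two
agree to $b^2$.) The estimator is exact on geometric constructions (tested
to 1e−12). `delta_f_per_generation()` multiplies by the generation
interval (default 5 years).

`segmented_gs_model()` contrasts two 5-year birth cohorts — progeny-test
era (default 2006–2010) and genomic-selection era (2015–2019), gap years
excluded — via a segmented regression of per-animal inbreeding on birth
year, with slope shift δ tested by ANOVA and relative change RC = δ/β.

Two genuinely open choices here, both settled by internal consistency of
published worked values:

* *Intercept structure.* The single-shared-intercept form (one α at
  calendar year 0) is the printed idealization, but implementing it showed
  that on any era-continuous data a single line through both cohort clouds
  is already a near-perfect least-squares fit, so the constrained δ
  absorbs level differences and sits near 0 regardless of the true slope
  change. Worked values of the form $b_{GS} = b_{PTS} + \delta$ with each
  b equal to its within-era slope are only reproducible by a
  free-intercept slope-contrast fit. The default is therefore per-era
  intercepts (δ = pure within-era slope contrast, the quantity of
  scientific interest); `shared_intercept = TRUE` gives the literal form.
  On noiseless data genuinely sharing one intercept the two variants agree
  exactly.
* *RC denominator.* The text convention "slope of the second period" is
  inconsistent with the published worked ratio (δ/β for the *first* period
  reproduces it; δ/β_GS does not). Default `rc_denominator = "pts"`, with
  `"gs"` behind the flag. RC of a fit with δ = 0 is exactly 0 by
  definition, avoiding 0/0.

`cohort_comparison()` is a Welch two-sample t-test (the variant is
unstated in the field sources; unequal variances are the safe default for
cohorts 10 years apart).

Annual means use all animals of a birth year, unweighted; years with fewer
than 10 animals are flagged in the output because small-n years produce
unstable correlations and rates.

## Synthetic data: what it emulates, what it does not

`simulate_pedigree()` produces an overlapping-generation herd: founders
spread over the decade before the first crop; each year's offspring draw
parents whose ages follow era-specific pathway distributions (defaults:
pre-switch sire pathways ≈ 7 years as under progeny testing, post-switch
≈ 3–3.5 years; dams ≈ 4–4.5 years throughout — the magnitudes reported for
Holstein programs). With `gi_sd = 0` parent ages are exact, which the GI
tests exploit. The `sire_dominant` scheme concentrates each year's
paternity in a top-k elite set, and `gs_transition_herd` shrinks k to 1 at
the switch year: a genuine inbreeding-rate acceleration produced by the
same mechanism (fewer, younger elite sires) believed to operate in real
genomic-selection programs.

`gene_drop()` transmits uniquely labeled founder haplotypes with Poisson
crossovers at 1 Morgan / 100 Mb (Haldane, no interference — deliberately
the same map scale the LD module assumes, so simulator and estimator
share one map). True autozygosity is exact interval arithmetic on the
labels, and SNP alleles are painted onto founder haplotypes at frequencies
drawn uniformly from (0.1, 0.9) — roughly an ascertained-array spectrum.
The expectation identity E[autozygous fraction] = F_ped holds by
construction and is verified by Monte Carlo.

`simulate_wright_fisher()` evolves 2N haplotypes by discrete-generation
random mating with the same recombination model, sites starting in linkage
equilibrium at frequency 0.5 and ascertained at final-generation MAF ≥
0.05 (array-like). Heterozygosity decays at 1/(2Ne) per generation
(tested within 15%).

Not emulated: genotyping error and missingness structure, selection on
(genomic) breeding values, mutation, interference, a non-flat
recombination map, age-structured culling, and real linkage-disequilibrium
ancestry at founding (founders are unrelated and in LE). A green test
therefore establishes algorithmic correctness and statistical calibration
under the stated model, not robustness to array artifacts.

One stated-world conflict: the LD-Ne recovery scenario was described with
200 sampled diploids from a population of effective size 100, but sampling
more individuals than the population contains is defined as an error;
the recovery test samples all 100.

## Numerical choices and degenerate inputs

* HWE p-values: probabilities are normalized in the het-count domain and
  ties at the observed probability count as "as extreme" with a 1e−12
  relative tolerance.
* Zero variance in a correlation → `NA` with a warning, never 0.
* A perfect (zero-residual) segmented fit has no valid F test → `p_delta = NA`.
* Monomorphic SNPs: HWE p = 1; r² pairs skipped and tallied.
* All generators are byte-deterministic per seed, and restore the caller's
  RNG state.

## Known limitations

* The pedigree algorithms are O(n × depth) per animal and comfortable to
  ~10^4–10^5 animals; national-scale pedigrees (~4 × 10^5) work but are not
  the optimization target.
* `read_plink()` reads text PED/MAP only (no binary BED) and loads the
  full dosage matrix in memory.
* Genotype imputation and low-to-medium-density harmonization are out of
  scope; panels are assumed imputation-complete.
* LD-based Ne inherits the usual caveats of the r²-inversion family:
  sensitivity to the sample-size correction at recent t, to the mutation
  modifier α at distant t, and to the assumed flat cM/Mb map.
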