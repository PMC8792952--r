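# herddiv

Genetic-diversity analysis for managed livestock populations from pedigree
and medium-density SNP data — built for breeding-program audits of the kind
routinely run on dairy cattle (e.g. Holstein) herds, where the question is
how fast inbreeding is accumulating, whether the move from progeny-test to
genomic selection changed that rate, and what the effective population size
has been doing.

## What it computes

**Pedigree side.** The inbreeding coefficient `F_ped` (probability that an
animal's two alleles at a locus are identical by descent) via the tabular
recursive-kinship method; the complete generation equivalent
`CGE = Σ_paths (1/2)^g` as a pedigree-depth measure; generation intervals
for the four selection pathways (sire/dam of bulls/cows); and effective
population size from the per-generation inbreeding rate,
`Ne = 1 / (2 ΔF_gen)`.

**Genomic side.** PLINK text PED/MAP input, five-criterion SNP quality
control (call rate ≥ 0.95, parent–offspring mismatch ≤ 0.01, MAF ≥ 0.01,
genotype-class frequency ≥ 0.001, exact Hardy–Weinberg p ≥ 0.005);
consecutive-runs detection of runs of homozygosity under the standard five
criteria (≥ 15 SNPs, ≥ 1 Mb, inter-SNP gap ≤ 500 kb, ≥ 1 SNP / 100 kb,
≤ 1 heterozygous and ≤ 1 missing call per run); the genomic inbreeding
coefficient

```
F_ROH = Σ L_ROH / L_AUTO
```

with its decomposition into segment-length classes (old vs recent
inbreeding); and historical Ne from linkage-disequilibrium decay,
`Ne(t) = (1/(4c)) (1/r²_adj − α)` with `c = 1/(2t)`.

**Trend side.** The annual inbreeding rate `ΔF_year = 1 − exp(b)` from the
regression of `ln(1 − F̄_year)` on birth year, its per-generation scaling
`ΔF_gen = ΔF_year × GI`, and a segmented two-era regression whose slope
shift δ (tested by ANOVA) and relative change `RC = δ/β` quantify the
change in inbreeding rate between breeding-program eras.

**Ground truth.** Every estimator is validated against simulators with
known answers: an overlapping-generation herd simulator with era-specific
pathway generation intervals, gene dropping of uniquely labeled founder
haplotypes (so true autozygous segments are known exactly), and a forward
Wright–Fisher simulator of known Ne.

## Worked example

Simulate a small herd, gene-drop genotypes through it, and run the core
statistics:

```r
library(herddiv)

sc   <- herd_scenario(n_founders = 20, years = c(2000, 2012),
                      offspring_per_year = 30,
                      genome = default_genome(3, 5e7, 1000), seed = 101)
sim  <- simulate_pedigree(sc)
drop <- gene_drop(sim$pedigree, sc$genome, seed = 102)

tab  <- inbreeding_table(sim$pedigree)        # F_ped + CGE per animal
segs <- detect_roh(drop$panel)                # ROH under the five criteria
froh <- compute_froh(segs, drop$panel)        # F_ROH per animal
idx  <- match(names(froh), tab$animal_id)
s    <- inbreeding_summary(tab$F_ped[idx], froh,
                           birth_years = tab$birth_year[idx],
                           cge = tab$CGE[idx])
```

This prints (for these seeds):

```
animals 410  segments 183
mean F_ped 0.0173  mean F_ROH 0.0207  r = 0.651
true-autozygosity corr: 0.998
```

410 animals descend from 20 founders over 13 years; 183 ROH segments are
detected. Mean genomic inbreeding (0.021) slightly exceeds mean pedigree
inbreeding (0.017) — `F_ped` ignores relatedness among founders and
Mendelian sampling, which ROH capture — and the two correlate at r = 0.65
across animals, while detected `F_ROH` matches the simulator's true
autozygous fraction almost exactly (r = 0.998), which is the point of the
gene-drop ground truth.

## Command line

```sh
inst/cli/herddiv all --pedigree pedigree.csv --ped geno.ped --map geno.map --out results/
inst/cli/herddiv simulate --scenario gs_transition_herd --out fixtures/
inst/cli/herddiv trends --pedigree pedigree.csv \
    --pts-range 2006:2010 --gs-range 2015:2019 --out results/
```

`all` runs QC → inbreeding → ROH → generation intervals → trends → Ne and
writes sorted TSVs plus a combined `summary.json`. Exit codes: 0 success,
1 analysis error, 2 usage/missing input.

## More

The methods vignette (`vignettes/genetic-diversity-methods.Rmd`) documents
the models, every tunable parameter with its default and rationale, what
the simulators do and do not emulate, and known limitations.
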