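# pollenkiller

Genetic modeling and analysis of **sporophytically gated pollen-killer
systems** — gametophytic loci whose heterozygotes selectively abort pollen
carrying one allele, with the killing switched on or off by unlinked
sporophytic partner loci (dominant activators or suppressors). Systems of
this kind underlie hybrid male sterility and transmission ratio distortion
in *indica* x *japonica* rice crosses, where an activator-gated killer and
a suppressor-gated killer form two independent genetic pathways.

The package is for geneticists who work with segregation data from such
crosses: it computes expected genotype frequencies under any standard cross
design, estimates the transmission parameter from progeny counts, tests
segregation ratios, simulates multilocus populations forward in time to
study pseudo-linkage between physically unlinked interacting loci, predicts
pollen-fertility phenotypes for multilocus genotypes, and fine-maps causal
loci from recombinant breakpoint panels.

## The model

A killer system pairs a **killer locus** (gametophytic) with a **partner
locus** (sporophytic). In a heterozygous sporophyte in which the system is
active, a targeted male gamete survives with probability *s*, so the
surviving pollen pool transmits the favoured allele with probability

```
k = 1 / (1 + s),    k in [0.5, 1]
```

(*k* = 0.5 Mendelian, *k* = 1 complete killing). Female transmission is
always Mendelian. Activation requires a heterozygous killer plus the
partner condition: an *activator* needs at least one donor allele (H or
II), a *suppressor* needs its absence (JJ). From these primitives follow
the selfing expectation (k/2, 1/2, (1-k)/2), the single-seed-descent
recursion with heterozygosity 2^-g and recombinant-inbred fixation at
k : 1-k, the testcross estimator k&#770; = n_H/(n_H + n_JJ), and the
pseudo-linkage phenomenon quantified by
(n_parental - n_recombinant)/(n_parental + n_recombinant).

## Worked example

```r
library(pollenkiller)

# 1. Estimate male transmission from a testcross (134 het : 17 JJ progeny)
estimate_k(count_data(n_H = 134, n_JJ = 17), design = "testcross")
#> <k estimate> k_hat = 0.8874  95% CI [0.8259, 0.9330]  (n = 151 informative, testcross design, clopper-pearson)

# 2. Project a recombinant-inbred population to its fixation limit
ssd_freq(0.89, generations = Inf)
#> <progeny freq> II=0.89  H=0  JJ=0.11
ri_fixation(0.89, n_lines = 148)
#>  II  JJ
#> 132  16
```

So a 148-line RI population under k = 0.89 is expected to fix 132 lines
for the donor allele and only 16 (11%) for the targeted allele, instead of
the Mendelian 74:74.

```r
# 3. Simulate an RI population where the killer (chr1) is gated by an
#    unlinked activator (chr5), and test the two unlinked loci for
#    association: gametic selection makes them look linked
map <- genetic_map(c("S35", "INK"), c("chr1", "chr5"), c(10, 25))
sys <- killer_system(locus("S35", "chr1", 3060000, "killer"),
                     locus("INK", "chr5", 1300000, "partner"),
                     "activator", "J", survival_s = survival_s(0.89))
ri <- simulate_population(cross_design("SSD_RI", 300, generations = 10,
                                       seed = 21), map, list(sys))
two_locus_association(ri, "S35", "INK")
#> <two-locus association> S35 x INK
#>   parental 162 : recombinant 137  excess = 0.0836
#>   independence X^2 = 9.242 (df = 1), p = 0.00237
```

The positive parental excess among double homozygotes — on loci that
recombine freely — is the pseudo-linkage signature of an activator-gated
killer.

```r
# 4. Classify observed pollen fertility percentages
classify_fertility(c(95.0, 43.1, 77.3))
#> [1] fertile         semisterile     partial_sterile
#> Levels: sterile < semisterile < partial_sterile < fertile

# 5. Fine-map a causal locus from a recombinant panel (synthetic panel
#    with the true position planted at 2.2 Mb)
g <- gen_recombinant_panel(10, 25, causal_pos = 2200000, seed = 55)
infer_interval(g$panel)
#> <candidate interval> chr1: (m04 @ 2,043,732 bp, m05 @ 2,342,370 bp), length 298,638 bp
#>   admissible regions: (m04,m05)
```

The inferred interval (open span between the closest contradicted flanking
markers) contains the planted causal position.

## Command line

An executable wrapper is installed with the package (`exec/pollenkiller`);
the same entry point is callable as `pollenkiller::pk_cli()`:

```sh
pollenkiller estimate-k --design testcross --counts H=134,JJ=17
pollenkiller expect --design ssd --k 0.89 --generations Inf
pollenkiller ri-expect --k 0.89 --n 148
pollenkiller gof --counts 17,134 --ratio 1,1 --method pearson
pollenkiller predict --genotype S35=H,INK=H,S24=JJ,EFS=JJ \
    --config inst/extdata/efs_s24_ink_s35.json
pollenkiller simulate --design ssd --lines 148 --generations 12 \
    --config systems.json --map map.tsv --seed 1 --out table.tsv
pollenkiller pseudolink --table table.tsv --a S35 --b INK
pollenkiller finemap --panel panel.tsv --map panel.tsv.map
```

Genotype tables and marker maps are plain TSV; killer systems are declared
in JSON (see `inst/extdata/efs_s24_ink_s35.json` for the bundled
two-pathway network).

## Documentation

The methods vignette (`vignettes/pollen-killer-model.Rmd`) describes the
model and its assumptions, the simulator's conventions (Haldane map
function, gamete-rejection selection, untracked-locus handling), the
observation model for stained-pollen counts, the fine-mapping semantics,
and known limitations.
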