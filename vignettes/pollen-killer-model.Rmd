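---
title: "Modeling sporophytically gated pollen killers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sporophytically gated pollen killers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenkiller)
```

## The genetic system

Hybrids between the two subspecies of Asian rice (*indica* x *japonica*)
are often partially pollen-sterile. One recurring cause is the *pollen
killer*: a locus whose heterozygote selectively aborts the pollen grains
carrying one of its two alleles. Because the killing happens in the haploid
gametophyte, the surviving pollen pool is enriched for the killer allele and
the locus distorts its own transmission through the male side, while female
transmission stays Mendelian.

`pollenkiller` models a refinement of this picture in which the killer
(gametophytic) locus is gated by an unlinked *sporophytic* partner locus:
whether killing happens at all is decided by the diploid genotype of the
parent plant, not by the gamete. Two partner modes occur:

* **activator** — the killer is active only when the parent carries at
  least one donor (I) allele at the partner locus (the `INK`-gated `S35`
  configuration);
* **suppressor** — the killer is active only when the parent carries *no*
  donor allele at the partner locus (the `EFS`-gated `S24` configuration).

Both modes are fully dominant: one partner allele suffices, and no dosage
model is used (`H` and `II` act alike). A sporophyte homozygous at the
killer locus is defined inactive — with only one allele class present there
is no targeted-versus-nontargeted contrast, and no phenotype is associated
with killer homozygotes.

## Transmission parameter

Killing is parameterised by the survival probability $s \in [0,1]$ of a
targeted pollen grain. In a heterozygous, active sporophyte, half the
pollen is targeted, so the surviving pool carries the favoured allele with
probability

$$k = \frac{1}{1+s}, \qquad k \in [0.5, 1],$$

with $s = 1$ Mendelian ($k = 0.5$) and $s = 0$ complete killing ($k = 1$).
We parameterise systems by $s$ rather than $k$ because survival composes
multiplicatively when several systems act in the same plant, while $k$ does
not. The reference value used throughout the examples, $k = 0.89$
($s \approx 0.124$), is the male-side transmission estimated from a
testcross segregating 134 heterozygous to 17 homozygous progeny:

```{r}
estimate_k(count_data(n_H = 134, n_JJ = 17), design = "testcross")
```

The reciprocal cross (heterozygote as female; 43:28) gives $\hat k = 0.61$
with a confidence interval covering 0.5, consistent with strictly Mendelian
female transmission. A weak female-side effect cannot be excluded by data of
this size; the model deliberately fixes female transmission at 0.5
(`female_gamete_distribution()` ignores all killer systems), and this
assumption is flagged here rather than hidden behind a parameter.

## Cross-design expectations

With male gametes $(k, 1-k)$ and female gametes $(0.5, 0.5)$:

* **testcross** (heterozygous male x JJ female): progeny are H with
  probability $k$;
* **selfing**: $p_{II} = k/2$, $p_H = 1/2$, $p_{JJ} = (1-k)/2$ — the
  heterozygote class is always one half, so selfed heterozygote counts are
  uninformative about $k$ and `estimate_k(..., "selfing")` uses only the
  two homozygous classes;
* **single-seed descent**: heterozygosity halves every generation,
  $p_H(g) = 2^{-g}$, and lines fix in ratio $k : 1-k$. The fixation limit
  of a recombinant-inbred population is $(k, 0, 1-k)$:

```{r}
ssd_freq(0.89, generations = Inf)
ri_fixation(0.89, n_lines = 148)
```

The second call reproduces the expected 132:16 split (11% JJ lines) for a
148-line RI population under $k = 0.89$. `ssd_freq()` iterates the
recursion generation by generation; the closed form is asserted against it
in the test suite rather than replacing it.

## Goodness of fit

`gof_test()` provides the standard Pearson statistic
$X^2 = \sum (O-E)^2/E$ with $df = \text{classes} - 1$, and an exact
multinomial test that enumerates every outcome at the observed total and
sums the probabilities of outcomes no more probable than the observed one.
The exact test is intended for small totals (its cost grows as
$n^{m-1}$); for two classes at totals of a few hundred it is still cheap.
The two p-values converge as the total grows, but not uniformly: at $n =
200$ under 1:1 the worst-case disagreement is about 0.056, concentrated at
counts adjacent to the centre where the exact test excludes the centre
point mass and the asymptotic chi-square does not. The test suite asserts
this measured envelope instead of a nominal one.

A caution for anyone comparing against published tables: chi-square values
printed alongside segregation counts in the source literature for this
system (45.9 for 17:134; 1.63 for 28:43) do not equal the standard Pearson
statistic for those counts (90.66; 3.17). The implementation uses the
standard formula and makes no attempt to reproduce the printed values,
whose derivation we could not recover.

## The forward simulator

`simulate_population()` is a forward Monte-Carlo engine over explicit
haplotypes:

* **Recombination** uses the Haldane map function,
  $r = \tfrac12(1 - e^{-2d/100})$ for $d$ cM, with one Bernoulli crossover
  draw per adjacent marker interval per meiosis and an independent
  coin-flip start per chromosome. No crossover interference is modeled;
  at the few-locus scale used here this is standard. Physical-to-genetic
  distance conversion is left to the map file — the system provides no map
  distances to hard-code.
* **Killing is gamete rejection**: each candidate male gamete carrying a
  targeted allele at an active killer locus is discarded with probability
  $1-s$ and the meiosis redrawn. Activation is evaluated on the parent
  sporophyte, never on the gamete. This matches pollen-stage action and
  automatically produces the $k = 1/(1+s)$ marginal. Collateral killing
  (`collateral_c`) affects only fertility phenotypes, never transmission:
  it removes non-targeted pollen indiscriminately, which changes how many
  grains stain but not the allele ratio among survivors.
* **Untracked loci**: a locus absent from the genetic map is held at its
  F1 state. A killer system whose killer locus is untracked is skipped; an
  untracked partner is treated as heterozygous, so an activator keeps its
  killer unconditionally active and a suppressor keeps it off. Tracking
  only the killer locus therefore reproduces the single-locus closed forms
  exactly; tracking the partner as well lets activation segregate, which
  is the interesting regime (below).
* **Reproducibility**: `cross_design(seed = )` makes every table
  bit-identical under a fixed seed. We use R's global generator seeded
  once per simulation rather than a passed-around generator object; this
  is idiomatic in R and equally reproducible.

## Pseudo-linkage

When the killer and its activator segregate on different chromosomes, RI
lines that fix the non-donor allele at the activator stop killing, while
lines that keep the activator continue to purge the targeted allele at the
killer locus. The result is an excess of parental two-locus classes
(II,II and JJ,JJ) over recombinant ones among physically unlinked loci —
apparent linkage without linkage. `two_locus_association()` quantifies
this with the parental-excess statistic
$(n_{par} - n_{rec})/(n_{par} + n_{rec})$ over double-homozygous lines
(0 under free recombination, 1 under complete linkage) plus a chi-square
independence test:

```{r}
map <- genetic_map(c("S35", "INK"), c("chr1", "chr5"), c(10, 25))
sys <- killer_system(
  killer = locus("S35", "chr1", 3060000, "killer"),
  partner = locus("INK", "chr5", 1300000, "partner"),
  partner_mode = "activator", targeted_allele = "J",
  survival_s = survival_s(0.89)
)
ri <- simulate_population(cross_design("SSD_RI", 300, generations = 10, seed = 21),
                          map, list(sys))
two_locus_association(ri, "S35", "INK")
```

## Fertility phenotypes

`predict_fertility()` computes the surviving-pollen fraction of a
multilocus sporophyte as

$$f = \tfrac12 \prod_{m \in \text{active}} (1 - c_m) \;+\;
      \tfrac12 \prod_{m \in \text{active}} s_m,$$

treating the targeted half of the pollen as shared across active systems.
This is a deliberate simplification: under independent assortment the
targeted cohorts of two unlinked killers overlap only partially and the
survival would be lower (0.314 rather than 0.507 for two systems with
$s = 0.12$). The shared-cohort form is used because it is the documented
contract of this operation, it preserves the orderings that matter (adding
an active system never increases fertility; both-active genotypes rank
below either single-active genotype), and per-genotype fertility means in
the source data are environment-dependent figure-level values that do not
support fitting a finer model.

Two observation parameters connect $f$ to stained-pollen counts:
`gamma`, the probability that an aborted grain is misscored as fertile
(arrested grains at late developmental stages stain partially; this
inflates observed fertility, matching the overestimation noted for killer
heterozygotes), and `baseline_f0`, the stained fraction of a fully fertile
plant (default 0.95; field-grown fertile plants rarely reach 100%).
Observed fertility is $f + \gamma(1-f)$, scaled by $f_0$, and
`sample_pollen_counts()` draws binomial counts at a configurable number of
scored grains (400 by default, the recommended scoring depth).

Default illustrative parameters are $s_{S35} = 0.1236$ (from $k = 0.89$),
$s_{S24} = 0.05$ (a conservative value inside the reported 90-99%
transmission range), $c = 0$ and $\gamma = 0.2$. A heterozygous killer
with $c = 0$ can never fall below 50% fertility, yet observed
semisterility of ~43% is on record for such genotypes; `collateral_c`
exists precisely to represent that gap and is the only way to push the
prediction below one half.

Fertility classes partition $[0, 100]$%: sterile $[0,40)$, semisterile
$[40,70)$, partial sterile $[70,90)$, fertile $[90,100]$. The conventional
band notation "<40%, 40-70%, 70-90%, >90%" is ambiguous exactly at the
boundaries; we let the upper class own each boundary and expose the
boundaries as an argument.

## Breakpoint fine mapping

`infer_interval()` implements deterministic breakpoint logic: for every
line, the causal locus must lie where the line's genotype predicts its
phenotype under the chosen carrier rule (`dominant-donor` for sporophytic
activators, `het` for gametophytic killers whose phenotype is
heterozygote-specific, `recessive-donor` for recessive factors).
Candidate positions are evaluated at markers *and* inter-marker gaps: a
gap across a genotype transition imposes no constraint, because the line's
breakpoint may fall on either side of the causal locus within it. This
segment resolution matters — with breakpoints falling anywhere in physical
coordinates, two lines can recombine inside the same gap on opposite sides
of the causal locus; their marker genotypes are then identical with
opposite phenotypes, and marker-only logic would wrongly declare the panel
inconsistent instead of localising the locus to that gap. A genuinely
inconsistent panel (no candidate position left) raises an error naming the
conflicting lines, which in practice signals a phenotyping error or a
second causal locus.

The interval is reported as the open span between the closest flanking
contradicted markers, matching how such intervals are quoted ("between
marker loci ..."), with the outermost markers as fallback when no
contradiction flanks a side.

## What the synthetic data do and do not establish

The generators (`gen_testcross_counts()`, `gen_selfed_table()`,
`gen_recombinant_panel()`, `simulate_population()`) emulate exactly the
statistical structure the estimators assume: binomial/multinomial sampling
of progeny classes under a known $k$, optional symmetric misgenotyping and
missingness, uniform single breakpoints per recombinant line with
phenotypes assigned deterministically from a planted causal position.
Panel sizes default to the scale of the motivating experiments (progeny in
the hundreds, RI populations of 148-300 lines, mapping populations of a
few hundred to a few thousand).

Real data deviate from this stated world in ways the generators do not
model: recombination suppression around the killer region (reported for
the S35 interval), environment-dependent penetrance, minor background
modifiers, double crossovers within a panel line, and non-random
missingness. A green test therefore establishes correctness of the
estimators and engines *under the model's own assumptions*, not robustness
to these field realities. Where the source data themselves conflict with
the model (printed chi-squares; sub-50% heterozygote fertility), the
discrepancy is documented rather than fitted.

## Numerical choices

* Probabilities are validated to sum to 1 within $10^{-12}$.
* Exact-test ties are compared with a relative tolerance of $10^{-7}$ on
  the point probability.
* `ri_fixation()` rounds $n k$ half away from zero; ties cannot occur for
  the documented inputs.
* Confidence intervals are exact Clopper-Pearson at 95% by default, with
  closed-form boundary handling at $\hat k \in \{0, 1\}$.
* Rejection sampling in the simulator is bounded (10,000 rounds); the
  bound is unreachable in valid configurations because activation requires
  a heterozygous killer, which always leaves a surviving gamete class.
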