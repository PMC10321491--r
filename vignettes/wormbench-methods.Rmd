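---
title: "Transmission genetics on a virtual picking bench: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmission genetics on a virtual picking bench: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormbench)
```

## What this package models

wormbench is a seeded forward-time simulator of *Caenorhabditis elegans*
transmission genetics, together with a "virtual bench" that executes the
plate-level laboratory protocols an automated worm-picking robot performs:
multi-generation crosses, balancer-based linkage mapping, and
genomic-integration screens. Everything runs on synthetic inputs; the point
is that every Mendelian expectation those protocols rely on is reproducible
by computation, without hardware, at desk scale.

The model sits at chromosome resolution. A genotype is a pair of haplotypes
for each of the five autosomes, plus two X haplotypes in hermaphrodites or
one in males; a haplotype is either a normal homolog carrying a set of
alleles or a balancer element (an inversion chromosome, or one half of a
reciprocal translocation). Extrachromosomal arrays ride alongside,
unattached to any chromosome.

## The transmission model

**Segregation.** Meiosis is decomposed into independent segregation groups.
Ordinary chromosomes contribute one of the parent's two haplotypes with
probability 1/2. A heterozygous reciprocal translocation makes its two
chromosome slots segregate jointly: a gamete receives either both
translocation halves or both normal homologs, each with probability 1/2
(alternate segregation). Unbalanced products — one half without its partner,
the aneuploid duplication/deficiency classes — are by default folded into
the redraw of inviable conceptions, because every statistic the protocols
compute conditions on viable, scorable animals. Setting
`wb_control(emit_unbalanced = TRUE)` emits them explicitly (total
probability 0.5) for brood-viability studies; they are then flagged
inviable at fertilization.

**Sex.** Hermaphrodite gametes always carry an X; male gametes carry the X
with probability 1/2 (nullo-X otherwise), which gives the 1:1 cross-progeny
sex ratio. Self-progeny are hermaphrodite apart from spontaneous
X-nondisjunction males at `spontaneous_male_rate` (default 0.002; stocks
differ and no canonical figure exists, so this is a configuration constant,
not a claim).

**Phenotype.** Dominant alleles express from one copy; recessive alleles
require every haplotype of their chromosome slot to carry them — two copies
in a diploid slot, one in the hemizygous male X (standard hemizygous
expression; the choice only matters for recessive X-linked markers, which
none of the stock procedures use). Balancer GFP markers are dominant, array
tags always express in carriers, and penetrance is 1 by default:
incomplete penetrance is modeled, where needed, as the bench's
per-observation `phenotype_error`, not as a property of the genotype map.

**Viability.** A conception dies iff it carries an unbalanced translocation
product or is homozygous for a balancer whose homozygote fate is lethal.
Balancer homozygote fates are not observable in the scored statistics (a
balancer homozygote is Green either way, and the linkage score conditions
on nonGreen animals), but they change brood composition, so they are
per-balancer configuration: hT2[qIs48] and nT1[qIs51] lethal, eT1 viable
with an Unc phenotype, mIn1[mIs14] viable (its brighter homozygous GFP is
not modeled). These follow the standard descriptions of the elements.

**Arrays.** An extrachromosomal array passes to each offspring of a carrier
parent with its transmission probability (default 0.65), independently of
chromosomal segregation — the "transmission rate" as geneticists measure it
on self-broods, so a brood's carrier count is Binomial(n, p). When both
parents of a mating carry the same array the per-offspring probability is
`1 - (1 - p)^2`. The single-gamete API (`make_gamete`) flags arrays
per-gamete with the same probability; brood generation and enumeration use
the per-offspring model so that selfing does not double-draw.

**Recombination.** Linkage is binary at chromosome scale: there is no
centimorgan map, and a balancer suppresses recombination completely over
the chromosomes it covers. A breakthrough-recombination probability
(`wb_control(recombination = ε)`, default 0) exists for robustness
experiments; it exchanges the non-marker alleles between the emitted
haplotype and its homolog with probability ε per balanced slot per meiosis.
Enumeration supports only ε = 0; the stochastic sampler handles ε > 0.

## The enumeration oracle

`enumerate_offspring()` computes the exact offspring distribution of a self
or a cross: the cartesian product of each parent's gamete classes with
their probabilities, array carry/no-carry branches, and (for selfing) the
spontaneous-male branch, aggregated by canonical genotype. It returns both
the unconditional distribution (viable plus inviable classes, summing to 1)
and the viability-conditioned one. The stochastic samplers (`self_cross`,
`mate`) draw per-offspring segregation choices from the same group
decomposition but never touch the probability arithmetic; the test suite
checks that their class frequencies converge on the enumerated
probabilities within binomial sampling error, and the classic anchors
(9:3:3:1, the 3/16 double positive, 100%/75% and 0%/50% scored fractions)
are frozen in the tests as independent expected values.

`brood_exact()` converts the viable distribution into a deterministic brood
by largest-remainder rounding, with classes spread evenly through the plate
(a low-discrepancy interleave) so that screening or picking any prefix of
the plate sees near-proportional class composition. This is what the bench's
"enumeration-backed" mode uses: it makes the full cross protocol an
expectation-level digital twin with no sampling noise, which is the right
baseline for verifying printed ratios.

## The linkage pipeline

The autosomal scheme crosses Green balancer-strain males to hermaphrodites
homozygous for the transgene of interest, selects a Red–Green F1
(transgene/+; balancer/normal), selfs it, and scores Red among nonGreen F2.
With the transgene on a balanced chromosome every nonGreen F2 is
homozygous for the transgene-bearing homolog, giving 100%; unlinked, the
transgene segregates 3:1, giving 75%. The X scheme mates a Red–Green F1
male (Green from a dominant helper array) to wild-type hermaphrodites and
scores Red among F2 males, who inherit their X from their mother: 0% if
X-linked, 50% if autosomal.

The Linkage Index normalizes an observed fraction against these two
expectations,

$$\mathrm{LI} = \frac{p_\mathrm{obs} - p_\mathrm{unlinked}}
                     {p_\mathrm{linked} - p_\mathrm{unlinked}},$$

clipped to $[-1, 1]$, so LI is 1 at the fully linked expectation and 0 at
the unlinked one for both test kinds. This normalized form is this
package's declared convention; it reproduces every stated property of the
statistic (range, monotonicity, the anchor points). Because LI alone has no
sampling theory, each test also reports an exact binomial p-value against
the unlinked null.

`n_scored` counts the animals that enter the score — nonGreen F2s in the
autosomal test, F2 males in the X test — so `scored_total == n_scored` and
the sampling error of `p_obs` is interpretable directly. Males are excluded
from the autosomal nonGreen scoring by default (`score_males` toggles
this); at the default spontaneous-male rate the choice is invisible.

Chromosome inference is coverage set algebra: a test is called linked when
LI ≥ 0.5 (about four standard errors from the unlinked expectation at 200
scored animals), and a chromosome is implicated iff it lies in every linked
test's coverage (hT2 → {I, III}, eT1 → {III, V}, nT1 → {IV, V},
mIn1 → {II}, X test → {X}) and in no unlinked test's coverage. No linked
test, or an inconsistent pattern, yields the empty set. The unintegrated
control scenario (`make_mapping_scenario(NA)`) keeps the Red transgene on
an extrachromosomal array: at 65% transmission every test reads below the
linked threshold and inference is empty, which is the diagnostic signature
of a marker that is not chromosomally linked at all.

## The virtual bench

Plates are barcoded records in a CSV-persistable database. Actions are
stochastic: a pick succeeds with probability
`pick_up_success × put_down_success` (defaults 0.9 × 0.9, the measured
robot performance), a transferred worm survives with probability 0.97, a
failed put-down occasionally loses the animal (1%), and screens
misclassify each worm independently with `phenotype_error` (default 0).
Contamination is a per-plate Bernoulli flag that voids the plate's
screens — 0 by default for the aseptic robot workflow, with a 3.4% preset
(`manual_bench_rates()`) matching the measured manual baseline. These
hardware-derived numbers enter *only* as configuration defaults; the
package makes no claim to reproduce the measurements themselves.

Protocol scripts form a strict low/mid/high hierarchy (atomic actions;
chained atoms such as PickNWorms; procedures such as CrossWorms, which
expands to two PickNWorms calls). `execute()` runs a script depth-first
with per-action logging; one seed gives a byte-identical log. Worms are
conserved: every animal is on exactly one plate or explicitly logged dead
or escaped. Developmental stage is a label advanced by plate growth, not
continuous time — timing is hardware-bound and out of scope.

The full cross protocol follows the singling chain F1 → F2 → F3 → F4 with
the homozygosity screen on F5 progeny. The generation labels in published
descriptions of such protocols are not perfectly consistent; this chain is
the arrangement that reproduces every printed checkpoint (F3 populations
100% Dpy and 75% Green when vsIs28-heterozygous; a line called homozygous
iff 100% of its screened F5s are Green).

The integration screen is modeled at the line level: each F1 line carries a
heterozygous integration of the array into a random autosome with
probability `p_integration`, the only parameter through which the
irradiation dose enters. The screened statistic is what matters: a
non-integrated carrier line passes a 30-animal screen over two generations
with probability $0.65^{60} \approx 6 \times 10^{-12}$, a heterozygous
founder passes even one screen with probability $0.75^{30} \approx
1.8\times10^{-4}$, and a homozygous founder always passes. The published
line counts (hundreds of F1/F2 singles, a handful of integrants) are
scale, not targets: no per-F1 integration probability is reported anywhere,
so the package exposes it as a free parameter and does not claim to
reproduce integrant counts.

## Numerical and design choices

* **Problem sizes.** Defaults are chosen so each analysis is exact or
  statistically decisive at desk scale: enumeration is exact and instant;
  stochastic checks use broods of 10,000 (binomial SE below 0.5% on mid
  probabilities) and mapping uses 200 scored animals per test, where the
  0.5 LI threshold sits about 4 SE from the unlinked expectation and the
  panel recovers every placement in ≥95% of seeds.
* **Chromosome placements.** dpy-5 is on chromosome I (a literature fact
  used as configuration); vsIs28 and vsIs33 have no published placement in
  the source material beyond the mapping result itself, so vsIs33 sits on
  chromosome V (the mapped answer) and vsIs28 on IV — any chromosome
  unlinked to I reproduces the cross.
* **Redraw semantics.** `n` in `self_cross`/`mate` counts scorable
  animals: inviable conceptions are redrawn, matching how plates are
  screened; `keep_inviable` switches to conception counting with dead
  records.
* **Degenerate inputs.** Zero-size broods return empty lists; scoring
  populations of probability zero, invalid karyotypes (0 or >2 X),
  unknown registry symbols, duplicate barcodes and hermaphrodite-only
  matings raise errors; protocols that cannot find required animals return
  failure *records* rather than throwing, because a bench must branch on
  them.
* **Ties and ordering.** Enumeration classes are ordered by probability
  then canonical key; exact-brood rounding uses largest remainders with
  deterministic tie order; all ids and barcodes come from counters so a
  seed fixes every artifact byte.

## What the generator does and does not emulate

The synthetic populations reproduce the structure the protocols depend on:
selfing broods, 1:1 cross-progeny sex ratios, dominant/recessive
expression, balancer segregation with inviable aneuploids, Bernoulli array
transmission, and stochastic picking/screening. They do not emulate brood
size biology over the reproductive span, sperm depletion, male mating
kinetics, crossover interference or partial balancer breakdown beyond the
single ε knob, mosaicism, or any image-level phenotyping noise structure
(misclassification is independent per worm). Passing tests therefore
demonstrate internal consistency of the genetic model and protocols under
idealized observation — not that a physical robot achieves these numbers.
One observed discrepancy is deliberately left unexplained: the real F2 of
the hybridization cross showed roughly 10% double positives where the
Mendelian expectation is 18.75%; the model computes the expectation and
logs the observation as out of scope rather than fitting a mechanism that
the data cannot identify.

## Limitations

Chromosome-scale linkage cannot distinguish placements within one
balancer's coverage except through the panel's set algebra; a transgene in
a region not covered by any balancer would be unmappable by design (the
empty inference set). Integration is heterozygous, single-copy and
autosomal by construction; X integrations and multi-copy events are not
modeled. The bench models outcome rates, not mechanics: there is no
trajectory, imaging or timing model, and throughput comparisons to human
experimenters are explicitly out of scope.
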