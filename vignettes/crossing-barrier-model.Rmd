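---
title: "Modelling the Tcb1 gametophytic crossing barrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the Tcb1 gametophytic crossing barrier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcbarrier)
```

## The system

Some teosinte populations (*Zea mays* ssp. *mexicana* and *parviglumis*)
grow intermixed with domesticated maize, flower in synchrony, and yet
rarely hybridise. The block acts after pollination: pistils (silks)
carrying the *Tcb1-s* haplotype arrest the pollen tubes of standard maize
(*tcb1*) pollen, while pollen carrying the linked male gene grows through
unharmed. The locus holds a tightly linked male/female gene pair, giving
four haplotypes:

| haplotype | male gene | female gene |
|-----------|-----------|-------------|
| `Tcb1-s`  | functional | functional |
| `Tcb1-m`  | functional | —          |
| `Tcb1-f`  | —          | functional |
| `tcb1`    | —          | —          |

Because the barrier is *gametophytic*, acceptance is decided by the pollen
grain's own haploid genotype, not by the diploid donor plant. `tcbarrier`
models this system end to end: the deterministic acceptance rules and
segregation expectations, stochastic simulators of the three field designs
used to probe the barrier, the scoring statistics applied to ear kernel
counts, a threshold model linking female-gene expression to barrier
function, and molecular dating of the female gene against its closest
homolog.

## The acceptance model

`pollen_acceptance(female, pollen, leak, threshold)` encodes three rules:

1. A pistil without an active barrier accepts every pollen grain.
2. An active barrier accepts any gamete containing a male-functional
   haplotype. Heterodiploid pollen (two haplotypes via a chromosome-4
   duplication) is accepted if *either* haplotype is male-functional — the
   OR rule reflects the dominance seen in trisomic tests, where
   `Tcb1-s + tcb1` pollen fertilises barrier females.
3. Pollen without male function sires kernels on a barrier ear only through
   a residual **leak**, a per-kernel probability defaulting to 0.03 —
   inside the 0–7% band of incompatible-pollen kernels observed on
   barrier ears.

Barrier activity itself is a threshold response:
`barrier_active()` is true when some allele is female-functional *and*
expresses at or above `threshold`. Expression is a property of the allele
(relative to a tubulin reference, full-strength lines at 1 on this scale),
so epigenetically silenced lineages and their *mop1* revertants are just
expression changes on an intact `Tcb1-f` allele. The default threshold of
0.1 places silenced lines (around 0.05 on this scale) below and partial
revertants (around 0.4, i.e. ~400-fold a standard maize line and 8-fold a
silenced line) above, consistent with the observed threshold behaviour.
Ovules are never selected: the model filters pollen only.

## Segregation expectations and the mutant screen

The knockout screen grows an open-pollinated block of repulsion
heterozygotes `Tcb1-s Su1 / tcb1 su1` with recombination fraction
`r = 0.06` (~6 cM; at this distance the difference between map distance
and recombination fraction is negligible, so the figure is used as a
fraction directly). On a barrier ear, accepted pollen is the
male-functional half of the cloud, of which a fraction `r` carries `su1`
by recombination; ovules transmit `su1` with probability 1/2:

```{r}
expected_marker_segregation(TRUE, 0.06)   # barrier ear: r/2
expected_marker_segregation(FALSE, 0.06)  # knockout ear: 1/4, any r
```

An ear segregating sugary kernels at ~25% instead of ~3% is a candidate
female-gene knockout. `flag_screen_outliers()` turns this into an explicit
rule: a one-sided exact binomial tail against the `r/2` null,
Bonferroni-corrected across all ears of the screen — strict family-wise
control chosen because a single screen inspects thousands of ears and a
false positive costs a season of follow-up crosses.

## The simulators

All three simulators draw each kernel's sire independently (multinomial
sampling): there is no silk-position, pollen-depletion or kernel-sector
structure, because no quantitative data constrain such effects. A kernel's
sire weight is the product of

* the donor's **mixing weight** in the pollen mix,
* a per-kernel **acceptance bias** between the `tcb1` and `Tcb1-s`
  competition classes — defaulting to 60:40, the calibrated share of
  kernels each class sires on a neutral ear under an equal mix — and
* the **acceptance probability** from the barrier model.

The bias multiplies the barrier rule rather than replacing it: the bias
captures pollen competition common to every ear, the barrier captures
rejection specific to barrier-active ears. Whether the bias reflects
viability, germination or tube growth rate cannot be distinguished from
kernel counts, so it is modelled as a single per-kernel siring weight.

`simulate_mixed_pollination()` reproduces the three-receiver design: a
`Tcb1-s` tester ear (verifies male function), the test ear, and a neutral
`tcb1` ear (calibrates the functional pollen ratio — two tassels never
shed equal pollen, so the neutral ear, not the nominal mix, is the
reference). Donors must differ in the `r1` colour marker; `R1-sc` pollen
sires purple kernels, so progeny are assigned to donors by sight, and the
simulator refuses a design in which both donors would sire the same
colour. The screen expectation applies no competition bias: its published
3%/25% predictions describe an unbiased pooled pollen cloud, and the
screen reads only the `su1` marker, not donor identity.

`simulate_reversion_experiment()` models the *mop1* epiallele test: each
female reverts with probability `reversion_prob` (default 0.18, the middle
of the observed ~14–22% range); reverted females rise to above-threshold
expression and a *partial* barrier whose leak is drawn uniformly from
`partial_leak_band` (default 0.05–0.35, spanning intermediate barriers
noticeably weaker than the 0–0.07 leak of full-strength ears). Because
only a correlation between expression and barrier strength is reported,
not a functional form, the general expression-to-leak mapping is exposed
separately as a monotone step function (`leak_from_expression()`), and the
reversion simulator keeps the band draw so that simulated cohorts show the
observed spread of partial barrier strengths.

Seeds are mandatory inputs with fixed defaults; every simulator output and
fixture records its seed, and regeneration under the same seed is
byte-identical.

## Scoring statistics

Ears are scored as 2×2 tables — (yellow, purple) kernels on the test ear
vs. the control ear. `exact_test_2x2()` implements the two-tailed exact
test conditional on both margins, summing the hypergeometric probabilities
of every table whose point probability does not exceed the observed one
(the conventional two-sided rule; the test is named in the source analyses
but the two-sided convention is not, so the conventional one is used). A
relative tolerance of 1e-7 guards tie detection against floating-point
rounding. The test suite checks the implementation against a brute-force
log-binomial enumeration oracle on *every* table with total up to 30 —
including the perfect-cosegregation geometry `(6,0;0,9)`, whose p-value is
exactly 1/5005 — and against `stats::fisher.test()` on random larger
tables.

`barrier_strength()` is the odds ratio of test-ear to control-ear donor
composition: 1.0 means no barrier. When any cell is zero, 0.5 is added to
all four cells (Haldane–Anscombe) and the result flagged; the correction
is applied only then, keeping exact ratios exact. `classify_ear()` applies
the published two-tier rule — strong at p < 0.0001, partial at
0.0001 ≤ p < 0.01 — and requires the effect direction (fewer
incompatible-pollen kernels on the test ear); significance in the wrong
direction is never a barrier. Kernel *counts*, not percentages, are
required throughout: exact tests are meaningless on re-scaled fractions.

## Expression and the threshold model

`relative_expression()` is plain delta-Ct with efficiency exactly 2 (no
standard curves are modelled). `summarize_expression()` averages technical
replicates on the Ct scale within each biological replicate first, then
takes the mean and SEM over biological replicates — the averaging order is
stated because it is not fixed by convention; it weights each biological
replicate equally regardless of technical scatter. Undetermined Ct values
are missing data, not a ceiling: a ceiling would fabricate a fold change.
`expression_barrier_association()` reports the Spearman rank correlation
between expression and barrier strength, plus whether every
below-threshold line sits at a barrier strength near 1 — the signature
separating a threshold response from a smooth dose response.

## Divergence dating

`count_differences()` counts mismatches over an existing alignment
(case-insensitive; columns with a gap or IUPAC ambiguity in either
sequence are excluded outright rather than partially matched — at the
divergences involved the information lost is negligible and the rule is
unambiguous). `divergence_time()` applies the strict molecular clock
`T = d / (2·mu)` with `mu = 3.3e-8` substitutions/site/year by default, a
rate consistent with calculated maize substitution rates. No multiple-hit
(Jukes–Cantor) correction is applied: at `d ≈ 0.0116` (15 differences in
1296 nt, the geometry of the female gene against its closest homolog) the
correction is below 1%, smaller than the uncertainty in `mu` itself.

```{r}
T_years <- divergence_time(15, 1296)
T_years
place_against_splits(T_years)
```

The estimate, ~175,000 years, predates both calibration splits
(*mexicana*/*parviglumis* ~60,000 years; *parviglumis*/*luxurians*
~140,000 years). Ties with a calibration point are reported as
`"coincident"`.

## What the synthetic data do and do not show

The generators in `make_fixture()` emulate the *designs* of the field
experiments with known ground truth: kernel counts under a specified mix,
bias and leak; screen populations at a stated recombination fraction; Ct
tables with planted fold changes and technical noise; aligned pairs with
planted substitutions. They deliberately do not emulate ear-to-ear
overdispersion, kernel sectors on an ear, pollen-amount fluctuation
between tassels, amplification-efficiency drift, or real sequence
composition. Passing tests therefore demonstrate that the *pipeline*
recovers parameters and classifies ears correctly when the model holds —
not that real ears are free of heterogeneity the model omits. Real
ear-level counts and expression measurements live in the original
experiments' source data and are not bundled here.

## Problem sizes and numerical choices

The test suite and the reproduction script use desk-scale sizes chosen to
pin each estimate well inside its tolerance: 100,000 kernels for the
segregation cross-check (3 binomial SE ≈ 0.16 percentage points), 10,000
kernels for the neutral-ear calibration, 20,000 for leak/bias recovery,
8 × 36 females for tier sensitivity/specificity, and exhaustive
enumeration up to table total 30 for the exact test. Degenerate inputs are
rejected loudly rather than patched: empty tables, zero comparable sites,
out-of-range recombination fractions and probabilities, donors sharing a
colour marker, and Ct tables missing reference rows are all errors.

## Limitations

* The acceptance bias is a single per-kernel weight; mechanistic stages of
  pollen competition are not separable from kernel counts.
* The expression-to-leak map is a step function; the data constrain only
  monotonicity and the existence of a threshold.
* Transmission of the chromosome-4 duplication through pollen is not
  measured anywhere; it is a config parameter defaulting to 0.5.
* The clock rate `mu` is a parameter, not an estimate; dating scales
  inversely with it.
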