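---
title: "Modeling a split homing gene drive with a gRNA-mediated effector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a split homing gene drive with a gRNA-mediated effector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitdrive)
```

## The system

`splitdrive` simulates a split CRISPR homing gene drive in *Drosophila
melanogaster*. The drive element (GDe) is inserted at the X-linked *white*
locus and carries two gRNAs — one targeting *white* itself (the driver) and
one targeting the unlinked X-linked *yellow* gene (a gRNA-mediated effector,
GME) — plus a GFP marker. Cas9 is supplied from a separate autosomal
transgene (RFP-marked) under one of four germline promoters (*nos*, *vas*,
*BicC*, *Ubi*). Drive activity requires both components, which confines
spread: this is the safety rationale of split designs.

In females heterozygous for the drive, a Cas9-induced double-strand break at
the homologous *white* allele is repaired either by HDR using the drive
chromosome as template — homing, which converts heterozygotes to homozygotes
and biases transmission above the Mendelian 50% — or by NHEJ, which creates
resistance alleles immune to re-cutting: in-frame, functional `R1` alleles
(phenotypically wild type) or frameshift/loss-of-function `R2` alleles.
Males are hemizygous, so homing is impossible in them. *yellow* has no
homology donor in the drive, so all *yellow* cuts resolve by NHEJ.

## The generative decomposition

The published quantities are *outcome frequencies* (homing %, R2 %,
intact %), not event probabilities. The model defines a generative
decomposition per gamete (`germline_event_params()`):

* `c_emb_w` — probability that a cleavable `w+` allele is cut in the early
  mitotic embryo, *before* the developmental stages at which HDR is
  efficient. Embryonic cuts therefore never produce homing; they are the
  mechanism by which maternally deposited Cas9 protein biases repair toward
  resistance.
* `c_germ_w` — probability that a still-intact `w+` is cut at the
  HDR-competent germline stage.
* `h` — probability that a germline-stage cut is repaired by HDR (homing);
  requires the drive homolog as donor.
* `r1_w` — in-frame fraction of NHEJ repairs at *white*; analogously `c_y`,
  `r1_y` (and `c_emb_y`) at *yellow*.

On the cleavable half of a heterozygous female's gamete pool this gives
homing = `(1 - c_emb_w) * c_germ_w * h`, with the complement partitioned
into `R1`, `R2` and uncut alleles; `fit_preset_from_observed()` inverts the
observed percentages: `c_germ_w = (100 - intact)/100`,
`h = homing / (homing + r2 + r1)`. The decomposition makes the observed
maternal-timing effect (lower homing with maternally inherited *Ubi*-Cas9
than with paternally inherited *Ubi*-Cas9) expressible as a difference in
`c_emb_w` alone.

Phenotype scoring cannot see in-frame repairs: `R1` alleles read as intact
at *white* (so true cleavage is underestimated by the `R1` fraction — the
estimator documents this, and the `r1_w` defaults are fitted from the
reported rise of phenotypically wild-type-but-resistant alleles between
successive generations) and as functional at *yellow* (so the fitted cut
rate is `c_y = LOF_obs / (1 - r1_y)`). `r1_y = 0.1` is a documented default
that no phenotype observation constrains.

## Deposition contexts

Which events fire depends on the individual's exposure
(`deposition_context()`):

* **Maternal protein, zygotic gRNA** (female classes 1 and 2): the mother
  carried Cas9; cutting happens in the F1 germline. Class 1 lacks the Cas9
  gene entirely, so any homing is driven purely by carried-over protein —
  the "shadow drive".
* **Zygotic only** (class 4): paternally inherited Cas9, no deposition;
  `c_emb = 0`.
* **Paternal protein only** (class 3): sperm carries no effective protein
  load; the zero-event slice.
* **RNP carryover** (classes 5 and 6): the mother carried *both* Cas9 and
  the drive, loading protein *and* gRNA into the egg. This is the only
  context with `c_emb > 0`, and it is the package's explanation of the
  F2-to-F3 collapse: class 5/6 females receive a fresh cleavable `w+` from
  their wild-type fathers, yet their germline output is dominated by `R2`.
  Since carryover cutting precedes HDR competence, the fresh allele is
  consumed embryonically. The per-promoter `c_emb_w` is fitted from the F3
  homing readout as `1 - homing_F3 / (c_germ_w * h)` and lands at 0.86-0.89
  for all four promoters — a coherent timing story rather than a
  per-promoter anomaly. This attribution is a modeling decision (the
  observations alone cannot distinguish carryover timing from other
  mechanisms); it is stored as a preset, not hard-coded.

Somatic mosaicism is a per-fly, per-locus Bernoulli "visibly mosaic" event
with context-specific penetrance (`p_som_white`, `p_som_yellow`), applied on
top of constitutive genetics. Mosaic and constitutive loss-of-function are
distinct phenotype values so the estimator can exclude somatic noise when
decoding germline-transmitted alleles — the reason the crossing design
scores progeny rather than parents.

## Preset fitting choices

Presets are data (`inst/extdata/promoter_presets.yaml`), regenerated by
`analysis/00_fit_presets.R` from the shipped observed-frequency table. Where
the observations left freedom, the choices are:

* The maternal-context *white* fits use the F2-generation per-promoter
  readouts for *nos*/*vas*, the maternal trans-heterozygous values for *Ubi*
  (the two reported *Ubi* maternal homing values, 67% and 78%, describe
  overlapping designs; the preset uses the value reported alongside the
  maternal-vs-paternal comparison, and the table retains both), and the
  shadow-drive observation set for *BicC*.
* Intact fractions not reported per promoter are set to 4.0%, the middle of
  the reported 1.2-5.1% range of uncut `w+` alleles.
* The zygotic germline slice equals the maternal one for *nos*, *vas* and
  *BicC* (no significant maternal/paternal difference was reported for
  them); *Ubi* gets its own zygotic fit (homing 88%).
* Zygotic *yellow* germline cutting: 0 for *nos*/*vas* (no maternal
  activity either), the maternal value for *Ubi*, and 0 for *BicC* (its
  zygotic expression produced only *white* mutations).

## Simulation mechanics and numerical choices

Crosses (`run_cross()`) default to the triplicate 10-female x 10-male vial
design with 200 scored progeny per replicate (configurable; true progeny
counts per vial were not published). Mothers within a vial are exchangeable;
gametes are independent draws from the exact per-mother gamete distribution
(no germline-stem-cell clustering — replicate SDs are the only clustering
signal available, and they are large). *white* and *yellow* events on the
same chromosome are independent Bernoulli draws (no linkage-of-outcome data
exists). Every run derives all randomness from one integer seed, with
per-replicate streams derived so that growing the replicate count leaves
earlier replicates unchanged. Gamete distributions are exact probability
tables (normalization enforced to 1e-12); the stochastic engine is tested
against the analytic convolution oracle (`expected_generation()`) at
n = 1e5 within binomial 3-sigma bounds.

The estimator (`estimate_frequencies()`) decodes maternal alleles from
markers plus color (GFP+ = drive; GFP- white = `R2`; GFP- red or mosaic =
intact), from all progeny in `w-` tester crosses and from sons only in `w+`
tester crosses (paternal `w+` masks maternal `R2` in daughters — scoring in
the recessive background inflates apparent intact alleles, as the
white-complementation caveat in the source data notes). *yellow* is always
read from sons. Percentages are normalized to the 50% heterozygous allele
pool and clamped to [0, 100]; the replicate is the statistical unit.
Whether the published `w+`-father percentages derive from sons only or from
a genotype-informed decoding of all progeny is not stated; sons-only is the
implemented rule.

## Architecture calculators

The rescue designs are exact calculators, not stochastic simulations. In
`HGD+R+GME` the drive sits inside a haplo-sufficient essential gene and
carries a recoded rescue; in `CGD+R+GME` ("cleavage-only") the construct
sits at a separate locus and `h` is structurally 0. Maternal deposition
cuts offspring wild-type essential-gene alleles with probability
`deposition * cut` (linear interpolation between the Mendelian and
full-cutting Punnett squares); an individual with no intact and no rescued
essential-gene allele is inviable (lethal biallelic mosaicism). The
essential gene and the effector-targeted host gene are modeled unlinked
(the general case; the designs allow either). Paternal carriers contribute
zygotic expression but no deposition — an explicit assumption, since the
designs only specify maternal deposition. "Refractoriness" is the fraction
of viable offspring with both host-gene alleles knocked out, using the same
deposition completeness. The spread recursion assumes random mating, an
infinite population, equal genotype frequencies in the sexes, and no
fitness costs beyond the viability rule.

## What the simulator does and does not emulate

The generator reproduces the statistical structure the estimators assume:
binomial gamete sampling from promoter- and context-specific event
probabilities, replicate-level variation, somatic-mosaicism penetrance, and
marker-linked selection of virgin females. It does not emulate fitness
costs of *white*/*yellow* loss (speculated but unquantified), per-mother
clustering, overlapping generations, population regulation, repair-pathway
kinetics, or DNA-level variation at the target beyond the symbolic allele
classes — so a passing test suite shows internal consistency of model,
estimator and published frequencies, not that real flies lack those
features. Amplicon classification operates on resolved sequences (no
chromatogram deconvolution); the seed/PAM substitution rule for calling
functional resistance is an operational proxy, and alignment gap placement
follows the aligner's deterministic convention (calls depend only on net
length change within a +/- 20 bp window of the cut, so ties cannot flip a
call).

## Problem sizes

The checked-in analyses and tests use 3 replicates x 400-500 progeny for
scheme-level runs, 1e5 progeny for oracle-equivalence and recovery checks,
15-generation spread recursions, and 200-500 generated amplicons per
classifier check — sizes at which every reported comparison is
sampling-stable on a single CPU in minutes.
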