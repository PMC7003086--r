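# splitdrive

Forward simulation and quantification of a split CRISPR homing gene drive
with a gRNA-mediated effector in *Drosophila melanogaster*.

## The problem

A homing gene drive (HGD) encodes Cas9 and a gRNA at its own insertion
site; in heterozygotes, cleavage of the homologous chromosome followed by
HDR copies the drive, biasing transmission above the Mendelian 50%. Split
designs separate the gRNA-bearing drive element (here **GDe**, inserted at
the X-linked *white* locus with a GFP marker and a second, cargo gRNA
against *yellow* — a gRNA-mediated effector, GME) from the autosomal,
RFP-marked Cas9 source (promoters *nos*, *vas*, *BicC*, *Ubi*), so drive
activity requires both components. Cleavage not resolved by HDR yields
NHEJ resistance alleles: in-frame functional **R1** (phenotypically wild
type, immune to re-cutting) and loss-of-function **R2**. This package is
for drive modelers and fly geneticists who want to simulate such crosses,
decode allele frequencies from scored phenotypes exactly as bench crosses
are scored, and explore rescue-based architectures that select against
resistance.

## The model

Per gamete of an active female, a cleavable `w+` allele is partitioned by

* `c_emb_w` — embryonic (pre-HDR) cut probability, non-zero only when the
  egg is loaded with both maternal Cas9 protein and maternal gRNA; these
  cuts can never home,
* `c_germ_w` — germline-stage cut probability, resolved by HDR with
  probability `h` (homing, requires the GDe homolog) or by NHEJ (in-frame
  fraction `r1_w`),
* `c_y`, `r1_y` — the same at *yellow*, which has no donor and never homes,

so homing = `(1 − c_emb_w)·c_germ_w·h` on the cleavable half of the pool.
Observed percentages invert to parameters via
`c_germ_w = (100 − intact)/100`, `h = homing/(homing + r2 + r1)`
(`fit_preset_from_observed()`). Frequencies are normalized to the 50%
heterozygous allele pool: homing% `= (f(GDe) − 0.5)/0.5·100`, and
replicate crosses (triplicate 10♀ × 10♂ vials by default) are the
statistical unit, compared with the pooled-variance two-sample t-test.
Rescue architectures (`HGD+R+GME`, cleavage-only `CGD+R+GME`) are exact
Punnett-square calculators with lethal biallelic mosaicism plus a
deterministic spread recursion.

## Worked example

Shadow drive: an F1 female heterozygous for the GDe, carrying maternally
deposited BicC-Cas9 protein but **no** Cas9 gene, crossed to `w−,y+`
males; her germline output is decoded from F2 phenotypes.

```r
library(splitdrive)
tbl <- run_cross(cross_spec(f1_female(1, "BicC"), tester_male("w-"),
                            n_replicates = 3, n_progeny = 500, seed = 7))
estimate_frequencies(tbl, "w-")[, c("quantity", "mean", "sd", "n_replicates")]
#>     quantity      mean        sd n_replicates
#> 1 cleavage_w 98.533333 0.6110101            3
#> 2     homing 58.533333 4.2770706            3
#> 3       r2_w 40.000000 3.6660606            3
#> 4   intact_w  1.466667 0.6110101            3
#> 5 cleavage_y 90.327106 0.5100065            3
```

Despite the absence of the Cas9 gene, 58.5% ± 4.3% of the cleavable `w+`
alleles were converted to the drive (homing), 40.0% became `R2`, and only
1.5% stayed intact; the cargo gRNA knocked out 90.3% of `y+` alleles in
the same germ cells. `intact_w` includes phenotypically invisible `R1`
alleles, so true cleavage is underestimated by that fraction.

The numbered drivers under `analysis/` run the full study: `00` refits the
promoter presets from the shipped observed-frequency table,
`01` surveys the four F1 female classes (somatic penetrance and germline
readouts), `02` chains F0→F3 to show resistance accumulation and the
homing collapse with t-tests, `03` computes the rescue-architecture
Punnett squares and spread trajectories, `04` demonstrates the cut-site
indel classifier. Each writes TSV tables under `results/`.

## Preset registry schema

`inst/extdata/promoter_presets.yaml` maps each promoter to three context
slices:

```yaml
BicC:
  maternal:   # maternally deposited Cas9 protein, germline cutting
    c_emb_w: 0.0    # embryonic white cut probability
    c_germ_w: 0.98  # germline white cut probability
    h: 0.605        # HDR fraction of germline cuts
    r1_w: 0.0       # in-frame fraction of NHEJ repairs at white
    c_y: 0.993      # germline yellow cut probability
    r1_y: 0.1       # in-frame fraction at yellow (unconstrained default)
    c_emb_y: 0.0
    p_som_white: 1.0   # somatic mosaicism penetrance
    p_som_yellow: 1.0
  zygotic: {...}  # paternally inherited Cas9 gene, no deposition
  rnp:            # protein + gRNA carryover (embryonic cutting only)
    c_emb_w: 0.872
    c_emb_y: 0.993
```

All values are probabilities in [0, 1], fitted from
`inst/extdata/observed_frequencies.tsv` by `analysis/00_fit_presets.R`.
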