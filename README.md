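# secmFluor

Zone-based synchronous fluorescence and miRNA expression analysis of spent
embryo culture medium (SECM).

## The problem

During IVF, an embryo grows to the blastocyst stage in a ~20 µl droplet of
culture medium. The medium left over at transfer carries the embryo's
secretome, and two cheap, non-invasive readouts of it may help select
embryos with high implantation potential:

1. **Synchronous fluorescence metabolomics.** Emission is scanned at a fixed
   offset Δλ above the excitation wavelength; scans over Δλ = 30–170 nm on
   the excitation interval 200–400 nm form a 3D "fluorescent fingerprint"
   dominated by the aromatic amino acids (tyrosine ≈223 nm, tryptophan
   ≈280 nm). Each sample is measured at 1:2500 dilution in PBS and in
   PBS:DMSO (1:1).
2. **Medium-normalized qPCR.** Relative expression of SECM miRNAs
   (miR-16-5p, miR-92a-3p) versus unused medium, since cell-free medium has
   no housekeeping gene.

Samples fall into groups **F** (successful implantation), **N**
(unsuccessful) and **M** (free, unused medium).

## The method

Maps are collapsed to profiles by a maximum projection over Δλ; the
*additive profile* of a sample is the point-wise sum of its PBS and
PBS:DMSO profiles. The additive profile is integrated over five excitation
zones (Z1 = 200–230, Z2 = 230–260, Z3 = 260–290, Z4 = 290–330,
Z5 = 330–400 nm; trapezoid rule, exactly conservative at the boundaries),
and zone values are normalized by subtracting the free-medium mean. Total
fluorescence decomposes as

```
metabolites = total − k·[HSA]         (calculated albumin fluorescence)
activity    = metabolites − metabolites(M)
R           = activity(N) / activity(F)
```

where `k` is a photometric HSA calibration (a.u. per g/L) and `activity`
is the embryo metabolic activity statistic. Group comparisons run per zone
through ROUT outlier removal (Q = 1%), a Shapiro–Wilk normality gate, and
a Mann–Whitney U (or unpaired t) test, two-tailed. qPCR relative
expression is `mean Ct(M) − mean Ct(group)` (log2 fold change vs medium),
and group contrasts are reported as percent differences with the larger
value's magnitude as denominator.

Because no SECM spectra are publicly deposited, the package includes a
synthetic cohort generator (separable Gaussian bands, solvent-dependent
quenching, HSA tied to concentration, N-group effect on Z1/Z2/Z4) whose
noiseless group means reproduce the reference decomposition table; all
statistical guarantees are demonstrated on it.

## Worked example

```r
library(secmFluor)

co       <- simulateCohort(cohortSpec(seed = 1))   # 30 F, 36 N, 3 M
profiles <- cohortProfiles(co$maps)
dec      <- decomposeCohort(profiles, co$manifest, hsaCalibration(1000))
round(dec$table, 1)
#>                    F        N        M
#> total       301719.7 313003.4 260239.1
#> hsa          45031.1  44838.0  20025.6
#> metabolites 256688.6 268165.3 240213.5
#> activity     16475.1  27951.8       NA
round(dec$ratioNF, 2)
#> [1] 1.7
```

The table reads: the N group's medium carries ~28,000 a.u. of fluorescence
attributable to embryo metabolism versus ~16,500 a.u. for F — embryos that
failed to implant left a markedly stronger metabolic footprint. Per-zone
statistics localise the difference:

```r
zn <- cohortZoneTable(profiles, co$manifest, normalize = "subtract")
zoneStats(zn, channels = "additive")[, c("zone", "test", "p")]
#>   zone       test        p
#> 1   Z1 unpaired t 6.51e-12
#> 2   Z2 unpaired t 1.87e-22
#> 3   Z3 unpaired t 3.46e-01
#> 4   Z4 unpaired t 1.20e-19
#> 5   Z5 unpaired t 5.31e-02
```

Z1, Z2 and Z4 (where the generator plants the N effect) are recovered;
Z3 and Z5 are not flagged. The qPCR side:

```r
ct <- simulateCtTable(c("5D F" = -0.328, "5D N" = 0.881),
                      duplicateSd = 0.15, mirnaId = "miR-16-5p", seed = 2)
relativeExpressionTable(ct)
#>    mirna_id group log2_rel_expr        sem n
#> 1 miR-16-5p  5D F    -0.2706825 0.08268532 2
#> 2 miR-16-5p  5D N     0.8506024 0.20448960 2
```

A one-call pipeline (`runPipeline(runConfig(outDir = "out", seed = 1))`)
chains simulate → profile → zones → decompose → stats → qPCR and writes
CSV artefacts plus a deterministic `report.json`. A thin CLI wrapper lives
at `inst/scripts/secmflow.R`.

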