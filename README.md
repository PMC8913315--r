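# xylokin

Kinetic characterization and subsite-affinity mapping of exo-acting
glycoside hydrolases assayed across substrate chain lengths.

β-Xylosidases (Bxls) release xylose one residue at a time from the
nonreducing end of xylooligosaccharides. How well a Bxl handles substrates
of different chain lengths (degree of polymerization, DP) is governed by
the architecture of its sugar-binding subsites: the active-center pair
−1/+1 that flanks the scissile bond, and any additional leaving-group
subsites +2, +3, … `xylokin` turns initial-rate assay data across DP 2–5
into that subsite picture, for enzymologists comparing exo-glycosidases.

## What it computes

**Michaelis–Menten fitting.** For each (enzyme, DP) dataset of initial
rates `v` at substrate concentrations `[S]`, nonlinear least squares on

    v = kcat [E]0 [S] / (KM + [S])

gives `kcat` and `KM` with Gauss–Newton standard errors (Hanes–Woolf
initialization, Levenberg–Marquardt optimization), and the specificity
constant `kcat/KM` with a first-order delta-method SE.

**Subsite mapping (Hiromi's method).** For an exo-enzyme, lengthening the
substrate from DP *n* to DP *n*+1 populates subsite +*n*, so its binding
affinity is

    A(+n) = RT ln[ (kcat/KM)_{n+1} / (kcat/KM)_n ]        (kcal/mol)

The intrinsic rate constant `k_int` is taken as the maximum `kcat` over
the series, and the summed active-center affinity follows from the DP 2
substrate, which spans only subsites −1 and +1:

    A(−1) + A(+1) = RT ln[ (kcat/KM)_2 / (c_w · k_int) ]

with `c_w = 0.018` L/mol (reciprocal water molarity; differences between
enzymes are independent of this convention constant). Subsites are counted
contiguously outward from +2 with a 0.4 kcal/mol existence threshold.

**Comparison report.** DP-specificity profiles `(kcat/KM)_n /
(kcat/KM)_2`, per-DP efficiency ratios between two enzymes, parameter
ranges, active-center affinity difference, and subsite counts, serialized
to JSON.

**Synthetic assays.** A generator emulating the endpoint HPLC assay
(30 °C, 30 min, 50 µM–5 mM substrate, 3% multiplicative CV) so the whole
pipeline is testable without instrument data.

The package ships the published kinetic parameters of two fungal GH3
β-xylosidases — PcBxl3 (*Phanerochaete chrysosporium*) and TrXyl3A
(*Trichoderma reesei*) — as `table2_series()`.

## Worked example

```r
library(xylokin)

series <- table2_series()          # packaged PcBxl3 / TrXyl3A parameters
as.data.frame(series$TrXyl3A)
#>   enzyme_label dp kcat_per_s kcat_se km_mM km_se spec_mM_s spec_se
#> 1      TrXyl3A  2       0.34    0.01 0.090 0.010       3.7     0.6
#> 2      TrXyl3A  3       0.39    0.01 0.024 0.005      16.0     4.0
#> 3      TrXyl3A  4       0.82    0.03 0.070 0.010      12.0     2.0
#> 4      TrXyl3A  5       0.56    0.01 0.066 0.003       8.5     0.5

build_profile(series$TrXyl3A)
#> <subsite_profile> TrXyl3A: k_int = 0.82 1/s, A(-1/+1) = 7.49 kcal/mol
#>   plus subsites (kcal/mol):
#>     +2: +0.88
#>     +3: -0.17
#>     +4: -0.21

build_report(series$TrXyl3A, series$PcBxl3)
#> <comparison_report> TrXyl3A vs PcBxl3
#>   active-center affinity difference: +0.92 kcal/mol
#>   subsite counts: TrXyl3A = 3, PcBxl3 = 2
#>   efficiency ratios (A/B) by DP: DP2 1.85, DP3 10, DP4 4.29, DP5 6.07
```

Reading: TrXyl3A's subsite +2 binds with ~0.9 kcal/mol (a typical
occupied glycosidase subsite, hence the count of 3 subsites), while
PcBxl3's +2 affinity is slightly negative — it has only the active-center
pair. TrXyl3A's active center binds ~0.9 kcal/mol more tightly, and it is
1.85–10× more efficient (`kcat/KM`) across DP 2–5, though PcBxl3 turns
substrate over faster (higher `kcat`).

To fit your own data, write one row per measurement to a CSV
(`enzyme_label, dp, substrate_conc, conc_unit, velocity, velocity_unit,
replicate`) and run the pipeline:

```r
cfg <- pipeline_config(enzymes = list(MyEnzyme = list(conc_nM = 25)))
out <- run_pipeline(cfg, rate_csv = "rates.csv", out_dir = "results")
```

A simulation mode (`run_pipeline(cfg, simulate = TRUE)`) regenerates a
full two-enzyme study from the packaged parameters under a seed. A thin
command-line wrapper is installed at `inst/cli/xylokin.R`.

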