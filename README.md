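# ims4d

Four-dimensional metabolite annotation for traveling-wave ion mobility mass
spectrometry (TWIMS-MS), in R.

Untargeted metabolomics by LC-MS struggles most with the smallest analytes:
very low-molecular-weight metabolites (VLMs, monoisotopic mass ≤ 250 Da) are
numerous, structurally diverse and heavily degenerate in mass, so an accurate
*m/z* plus an isotope pattern alone can leave thousands of isobaric and
isomeric candidates for a single detected ion. Ion mobility adds a fourth
molecular descriptor — the rotationally averaged collision cross-section
(CCS, Å²) — that is orthogonal to *m/z*, retention time (RT) and MS/MS
fragmentation. `ims4d` implements the complete matching workflow that
exploits all four dimensions against a library of authentic standards, for
anyone building or using 4D reference libraries on TWIMS-QTOF instruments
(HDMS^E-style acquisitions, HILIC or reversed-phase chromatography).

The package provides:

* **CCS calibration** for traveling-wave instruments. TWIMS does not yield
  CCS from first principles; after the enhanced-duty-cycle (EDC) flight-time
  correction *t′ = t − c·√(m/z)/1000* and reduced-mass normalization
  *Ω′ = Ω·√μ/z* with *μ = m·m_gas/(m + m_gas)*, the calibration is the
  standard power law fitted in log–log space,

  **Ω′ = A · t′^B**,

  with a single-point multiplicative lock-CCS correction against a
  continuously infused reference (leucine enkephalin) —
  `fit_ccs_calibration()`, `drift_to_ccs()`, `lock_ccs_correction()`.
* **Chemical-formula arithmetic**: Hill-notation parsing, monoisotopic
  masses, coarse isotope patterns by polynomial expansion, adduct *m/z* for
  [M+H]⁺, [M+Na]⁺, [M+H−H₂O]⁺, [M]⁺, [M−H]⁻ and [M+Na−2H]⁻, and signed ppm
  mass errors Δppm = 10⁶·(measured − theoretical)/theoretical.
* **The 4D matching engine**: per-dimension tolerance filters
  (±20 ppm precursor and product mass error, isotope similarity ≥ 80 %,
  RT ± 0.3 min, ΔCCS within ±2 % *or* ±4 Å² by default), a transparent
  equal-weight composite score, deterministic ranking, Metabolomics
  Standards Initiative (MSI) confidence levels, and the cumulative
  identification funnel (*m/z* + isotope → +RT → +MS/MS → +CCS) —
  `generate_candidates()`, `annotation_funnel()`, `run_annotate_workflow()`.
* **QC analytics**: inter-day precision (%RSD), accuracy against reference
  CCS sets (ΔCCS%), matrix-effect reports, per-class *m/z*–CCS power
  trendlines (CCS = a·(m/z)^b) and adduct CCS-shift statistics.
* **Seeded synthetic-data generators** (features, decoys) and a packaged
  reference library of 55 urinary metabolites identified at MSI level 1 on a
  UPLC/TWIMS-QTOF platform, with the originally reported per-record mass,
  RT and CCS errors and scores retained as annotation columns.

Everything is tidyverse-native: functions take data frames, return tibbles,
and fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Load the packaged urine library and summarize it:

```r
library(ims4d)
lib <- urine_reference_library()
summarize_library(lib)
#> 4D library: 55 compounds, 67 CCS values
#>   positive-mode entries: 23, negative-mode entries: 44
#>   VLMs (<= 250 Da): 53
#>   records per adduct:
#>     [M+H-H2O]+   2
#>     [M+H]+       21
#>     [M+Na-2H]-   1
#>     [M-H]-       43
```

Fifty-five compounds were confirmed against authentic standards (23 in
positive, 44 in negative electrospray; 12 in both), and 53 of the 55 are
VLMs — exactly the population for which the CCS dimension matters most.

The packaged worked example is a positive-mode urinary feature at
*m/z* 205.0968, RT 5.71 min, CCS 147.31 Å² matched against ten candidates
that all satisfy the mass, isotope and RT criteria:

```r
ex <- tryptophan_funnel_example()
annotation_funnel(ex$feature, ex$library)
#> Identification funnel
#>   stage 1 (m/z + isotope): 10 candidate(s)
#>   stage 2 (+ RT         ): 10 candidate(s)
#>   stage 3 (+ MS/MS      ): 5 candidate(s)
#>   stage 4 (+ CCS        ): 1 candidate(s)
#>   top candidate: l-Tryptophan ([M+H]+, composite 100.0, MSI level 1)
```

Accurate mass and isotope similarity cannot separate the ten isobars, and RT
removes none of them; fragment matching eliminates five, leaving the three
tryptophan stereo-forms and two water-loss dipeptide ions; only the CCS
criterion resolves l-tryptophan. Mass errors are plain arithmetic on the
packaged element masses:

```r
rec <- dplyr::filter(lib, name == "Xanthurenic acid", adduct == "[M+H]+")
ppm_error(rec$mz, adduct_mz(monoisotopic_mass(rec$formula), rec$adduct))
#> [1] 4.930191
```

A command-line front end wrapping the same functions ships in
`inst/scripts/ims4d` (subcommands `calibrate`, `annotate`, `simulate`,
`trendlines`, `evaluate`, `fixture`).

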