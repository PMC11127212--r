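---
title: "Methods: 4D metabolite annotation with traveling-wave ion mobility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 4D metabolite annotation with traveling-wave ion mobility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ims4d)
```

`ims4d` annotates small-molecule features from ion mobility–mass
spectrometry against four-dimensional reference libraries. This vignette is
the package's account of the underlying models, the parameters that matter,
the numerical choices made where several conventions exist, and what the
synthetic-data machinery does and does not establish.

## The measurement model

A feature is one detected ion: an ionization mode, an accurate *m/z*, a
retention time from the chromatographic method run in that mode, an optional
isotope envelope, optional high-energy fragments, and either a collision
cross-section (CCS) or a drift time convertible to CCS through a
calibration. A library record is the same quartet measured for one adduct of
an authentic standard. Identification is a per-dimension agreement test
followed by scoring and ranking.

### Traveling-wave CCS calibration

Traveling-wave mobility separates ions with a surfing voltage wave, so drift
time cannot be converted to CCS from first principles (unlike drift-tube
instruments, where the Mason–Schamp relation applies directly). The package
uses the standard empirical power-law calibration:

1. EDC correction: $t' = t - c\sqrt{m/z}/1000$ removes the post-mobility
   flight time. The coefficient $c$ is instrument-specific; it is a required
   argument, never defaulted, because a wrong $c$ silently biases every CCS.
   Test code uses $c = 1.41$ as a conventional placeholder.
2. Reduced-mass normalization: $\Omega' = \Omega\sqrt{\mu}/z$, with
   $\mu = m\,m_\mathrm{gas}/(m + m_\mathrm{gas})$ and the drift-gas mass
   defaulting to nitrogen (28.0134 Da), the gas in which the reference CCS
   values are expressed.
3. Ordinary least squares of $\ln\Omega'$ on $\ln t'$ gives
   $\Omega' = A\,t'^{B}$. Fitting in log space makes the multiplicative
   error model explicit and the fit linear.
4. A lock-CCS correction multiplies the output by
   (reference / measured) for a continuously infused lock compound. Ratios
   outside (0.5, 2) are rejected as gross miscalibration rather than
   silently applied.

On noiseless synthetic calibrants the round trip drift → CCS reproduces the
generating values to machine precision, and with 1 % multiplicative noise on
twelve calibrants the exponent is recovered with a median absolute error
well under 0.03 (both checked in the test suite and recomputed by
`scripts/acceptance.R`).

### Formula arithmetic and adduct conventions

Monoisotopic masses come from a packaged element table (C 12 exact,
H 1.00782503207, N 14.0030740048, O 15.9949146196, S 31.97207100,
Na 22.9897692809, P 30.97376163, …), editable as plain text. Adduct mass
deltas follow the charged-species convention: [M+H]⁺ adds the proton mass
(H atom minus electron, 1.0072765 Da), [M−H]⁻ subtracts it, [M+Na]⁺ adds
Na minus an electron, [M]⁺ removes only an electron, and composite adducts
combine the corresponding atom and electron masses. The alternative
convention (adding a neutral H atom) shifts computed mass errors by about
2.7 ppm at *m/z* 206 and does not reproduce the per-record mass errors
stored with the packaged library, so it is not used. All supported adducts
are singly charged; the charge field exists for forward compatibility.

Isotope patterns are aggregated by nominal mass shift (M, M+1, …, truncated
at four peaks and renormalized), computed by convolving per-element
multinomial isotope distributions with exponentiation by squaring.
Truncation before renormalization is exact for the retained peaks because a
truncated convolution preserves the leading coefficients. Fine isotopic
structure is deliberately out of scope: the pattern only feeds a coarse
similarity score.

## The matching engine

### Tolerances

`match_tolerances()` defaults encode the search criteria the packaged
library was built under:

| parameter      | default | unit | role |
|----------------|---------|------|------|
| `ppm`          | 20      | ppm  | precursor mass window |
| `fragment_ppm` | 20      | ppm  | product-ion mass window |
| `isotope_min`  | 80      | %    | minimum isotope similarity (≥, not >) |
| `rt`           | 0.3     | min  | RT window, same chromatographic mode only |
| `ccs_pct`      | 2       | %    | relative CCS window |
| `ccs_abs`      | 4       | Å²   | absolute CCS window |
| `msms_min`     | 10      | %    | minimum fragment-match score |

The CCS criterion passes when **either** bound holds. The dual rule exists
because a fixed percentage over-filters small ions: below ~200 Å², 2 %
is less than 4 Å², so the absolute branch is the effective one and prevents
discarding correct small-molecule matches. All thresholds are inclusive
(a deviation of exactly 2.000 % is within ±2 %).

`msms_min` is this package's own addition: a stage that "removes candidates
by fragment matching" needs an explicit pass rule, and vendor software does
not document one. The score is the intensity-weighted fraction of the
reference spectrum recovered by the observed fragments (greedy
nearest-*m/z* pairing in order of decreasing reference intensity, each
observed peak usable once), and a candidate passes when at least 10 % of
reference intensity is matched — permissive enough that a partial spectrum
still counts, strict enough that a single coincidental low-intensity match
does not.

### Scoring, ranking, confidence

Each available dimension contributes a subscore on [0, 100]: linear decay to
the tolerance edge for mass, RT and CCS
($100\,(1 - |\Delta|/\mathrm{tol})$), the similarity percentages directly
for isotopes and MS/MS. The composite is their unweighted mean. This is a
deliberate design choice: proprietary identification scores are opaque, and
an equal-weight mean is reproducible and interpretable; the original
per-record scores of the packaged library are retained as `*_printed`
annotation columns for context, never asserted. Ranking is descending
composite with ties broken by |Δppm| then compound name, so results never
depend on input order.

A dimension missing from the feature (no envelope, no fragments, no CCS) or
from the record (no reference spectrum, no CCS) is skipped for that
comparison and recorded in `dimensions_used`, rather than failing the
candidate — a workflow that adds dimensions incrementally must tolerate
sparse data.

MSI confidence levels follow the orthogonal-property reading of the
community guideline: level 1 requires an authentic standard matched on
accurate mass, RT and at least one of MS/MS or CCS (two orthogonal
properties beyond mass, measured in the same laboratory); a fragment match
without that support is level 2; mass + isotope alone is level 3; anything
weaker is level 4.

### The identification funnel

`annotation_funnel()` applies criteria cumulatively — (*m/z* + isotope),
+RT, +MS/MS, +CCS — and reports candidate counts per stage plus the
top-ranked survivor. Whether the final dimension *eliminates* the remaining
competitors or merely *re-ranks* them is genuinely ambiguous in practice;
the funnel encodes elimination (counts drop), but the report also exposes
the ranked stage-1 set with per-dimension pass flags so the re-ranking
reading is inspectable from the same object.

The packaged `tryptophan_funnel_example()` realizes the canonical narrative:
ten candidates pass mass + isotope + RT (three tryptophan stereo-forms, two
dipeptide water-loss ions — glycyl-phenylalanine and phenylalanyl-glycine
as [M+H−H₂O]⁺ are exact mass-twins of protonated tryptophan — and five
synthetic isobars), five survive fragment matching, and only l-tryptophan
sits inside the CCS window. The five fragment-failing isobars are synthetic
constructs (`SYN*` accessions) and all fragment spectra are in-silico
stand-ins; the example demonstrates the funnel mechanics, not real
fragmentation chemistry. Likewise the stereo-forms are given distinct CCS
values by construction — real enantiomers would not separate — because the
example encodes the candidate-set structure, not physics.

## The packaged urine library

`urine_reference_library()` returns 55 compounds (67 adduct records; 23
entries with a positive-mode record, 44 with a negative-mode record, 53 at
or below the 250 Da VLM threshold) identified at MSI level 1 in pooled
human urine on a UPLC/TWIMS-QTOF platform with separate acidic (positive)
and basic (negative) HILIC methods. Stored fields are the measured *m/z*,
RT, CCS per record plus the reported mass error, RT error, CCS error,
identification score, fragmentation score and isotope similarity as
pass-through annotations. Molecular formulas are implied by the HMDB
accessions rather than printed in the source table; every stored formula is
therefore verified against the stored monoisotopic mass (within 0.0005 Da)
on every load, so a transcription error cannot pass silently.

Two documented quirks:

* The glucuronic acid [M+H−H₂O]⁺ record is mathematically identical to the
  ascorbic acid [M+H]⁺ record (loss of water from C₆H₁₀O₇ gives C₆H₈O₆
  exactly, and the two share RT and CCS here). The two candidates are
  separated only by their isotope envelopes, which differ minutely; tests
  treat them as observational near-duplicates.
* Separate-analysis CCS values reported elsewhere for leucine (131.44 Å²)
  and isoleucine (133.13 Å²) differ from the per-record values stored here
  (131.50 Å² for both protonated ions): the library stores the values from
  its own identification runs, and within a ±2 % CCS tolerance the two
  isomers are not distinguishable anyway.

RT values are method-specific annotations; no RT projection between
chromatographic methods is attempted, and RT matching never crosses
ionization modes.

## Synthetic data: what it emulates, what it does not

`simulate_features()` draws noisy features from library records with
Gaussian noise expressed in the same domains as the tolerances — ppm for
mass, minutes for RT, percent (multiplicative) for CCS — so noise scales
relate directly to filter widths. Defaults (5 ppm, 0.075 min, 0.5 %) are
half-tolerance noise for a well-behaved acquisition: large enough that
filters are exercised, small enough that a correct library should mostly
win. Envelopes are the exact theoretical patterns of the record formulas;
fragments are copied with optional per-peak dropout. Everything is
deterministic under a fixed seed.

`make_decoys()` produces negatives: `mz_shift` breaks mass consistency by a
stated offset (decoys carry a marker exempting them from formula/mass
validation, which they fail by design), and `isomer` keeps formula and
*m/z* but moves RT by three noise SDs and CCS upward by
max(3 %, 4.5 Å²). The CCS shift is deliberately larger than a bare 3 %:
under the dual CCS criterion a 3 % shift still passes the ±4 Å² absolute
branch for CCS below ~133 Å², so a purely relative shift would let decoys
match. Isomer decoys also drop the reference spectrum, since an isomer need
not share fragmentation.

What passing these simulations shows: the filters, scores and rankings
behave correctly under the stated error model, and true identities are
recovered at rank 1 in ≥ 95 % of half-tolerance-noise draws against the
55-compound library. What it does not show: performance on real urine data,
where noise is non-Gaussian, features co-elute and overlap, envelopes are
distorted by interference, fragment spectra contain matrix peaks, and the
candidate space is a full structural database rather than a curated
library. Database-scale candidate counts and false-discovery calibration
against decoy libraries are out of scope (the decoy generator exists; FDR
calibration is future work).

## Numerical and reporting choices

* Trendline fits (`fit_class_trendlines()`) are OLS in log–log space and the
  reported $R^2$ is computed in that space — the space of the linear model —
  with the convention recorded in an `r2_space` column, since "power
  trendline $R^2$" is ambiguous between log-space and linear-space
  conventions. Classes with fewer than three ions are skipped with a
  message; a zero-variance response returns a flagged perfect fit rather
  than an error so batch runs survive degenerate classes.
* %RSD uses the sample standard deviation (n − 1), appropriate for
  triplicate inter-day designs.
* Sample sizes in the test and acceptance suites — 1,000 random instances
  for filter-oracle equivalence, 500 noisy features for rank-1 recovery,
  100 repetitions for calibration-exponent recovery, 10,000 draws for
  noise-magnitude checks — were chosen as the smallest round numbers at
  which the Monte-Carlo error of each check is comfortably below its
  assertion margin.
* Workflow outputs use fixed formatting (*m/z* to 4 decimals, RT/CCS and
  scores to 2) and stable ordering, so identical runs are byte-identical.
* Isotope envelopes are renormalized after text round trips to absorb
  serialization rounding.

## Known limitations

* No vendor raw-file parsing: feature tables are the ingestion boundary (an
  mzML reader is a natural extension point).
* No in-silico fragmentation engine — in-silico spectra are consumed, not
  generated — and no low/high-energy deconvolution.
* No multi-segment or polynomial CCS calibration, and no first-principles
  Mason–Schamp conversion (no pressure/temperature handling).
* Single-charge adducts only; no structure handling (SMILES/InChI), no fine
  isotope structure.
* The composite score is a transparent convention, not a calibrated
  posterior; its absolute values are comparable within a run, not across
  tools.
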