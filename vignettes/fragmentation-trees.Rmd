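---
title: "Fragmentation trees from multistage mass spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragmentation trees from multistage mass spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragtree)
```

## The problem

Multistage mass spectrometry (MS^n^) on ion-trap instruments isolates an
ion, fragments it, and repeats the cycle on the fragments, producing a
hierarchy of spectra: an MS^1^ survey scan, MS^2^ fragments of the selected
precursor, MS^3^ fragments of those fragments, and so on. The precursor
to product relations across stages carry structural information that a
single MS/MS spectrum does not: two ions with the same m/z observed in
different branches are different observations. `fragtree` turns such
hierarchies into *fragmentation trees* — rooted trees whose nodes are
fragment ions annotated with elemental formulas — and represents each tree
as a set of *elemental formula paths* (EFPs), the ordered formula lists
from the precursor down to each ion, serialized like
`C10H18N3O6S1||C5H11N2O3S1`. EFP sets are then the currency for
reproducibility analysis (consensus over repeated acquisitions) and for
compound comparison (Tanimoto similarity, clustering), which is
discriminative enough to separate positional isomers.

## Formula assignment under hierarchy constraints

Every peak is assigned a CHNOPS elemental formula for the *ion composition*
(protonation included; singly charged ions only, which is the regime of the
nano-ESI MS^n^ workflows this models). Candidates for an observed m/z are
all count vectors whose theoretical ion m/z

$$ m/z = \frac{\sum_e n_e \, m_e - z\,p\,m_{e^-}}{z}, \quad z = 1,\ p = \pm 1 $$

lies within the mass tolerance (default 6 ppm), where $m_{e^-}$ is the
electron mass — without it the theoretical masses are off by about 1.8 ppm
at m/z 300, which is visible at 3 printed decimals. Candidates are filtered
by three plausibility rules:

* **Hierarchy (the core constraint).** A fragment cannot contain more atoms
  of an element than its precursor, and the implied neutral loss
  (precursor minus fragment) must be non-negative element-wise. Both are
  enforced at once by enumerating candidates under an element-wise cap
  equal to the parent ion's assigned formula.
* **Element-ratio rules.** Heuristic ranges on elemental ratios
  (0.1 ≤ H/C ≤ 6, N/C ≤ 4, O/C ≤ 3, P/C ≤ 2, S/C ≤ 3) plus per-element
  maxima for the sub-500 Da window (C 39, H 72, N 20, O 20, P 9, S 10).
  The extended (rather than common) ranges are deliberate: fragment ions
  are more exotic than intact metabolites, and false rejections of true
  fragments cost an entire subtree. Carbon-free formulas skip the ratio
  checks and face only the maxima. Isotope-pattern scoring is deliberately
  absent: the acquisition scheme this package models isolates monoisotopic
  precursors, so no isotope information reaches the spectra.
* **Non-integer RDBE.** Ring-and-double-bond equivalents
  $C + 1 - H/2 + (N+P)/2$, computed **on the ion composition**, must sit on
  the half-integer grid and be ≥ −0.5. Even-electron CHNOPS cations and
  anions always give half-integers, so this rejects radical-like and
  ill-typed compositions; the −0.5 floor admits protonated saturated
  species. Computing on the ion (not the neutral) is a design choice: the
  assignment operates on ion compositions throughout, and all 21 ions of
  the packaged glutathione example pass it.

A peak with zero surviving candidates is discarded as an artifact — this is
the mechanism that removes electronic noise, side bands and other
interferences without any intensity heuristics. With several survivors the
best (minimum |ppm error|, ties by lexicographic token) is kept and flagged
ambiguous rather than dropped, preserving auditability. Assignment is a
single top-down pass using each parent's final formula as the cap; a global
constraint-refinement pass (revisiting a parent when its children are
informative) is a possible extension, not implemented. A fragmented peak
that loses its formula takes its whole subtree with it, since the
children's cap would be undefined.

On the packaged glutathione worked example all 20 fragment peaks are
*uniquely* assigned under their parent caps at 6 ppm — the hierarchy makes
formula assignment unambiguous where an uncapped search at the same
tolerance would return several candidates.

## Spectrum linking and tree construction

mzXML input is read through `mzR`. Each MS^n^ scan (n ≥ 2) is attached to
the most recent preceding scan one level up that contains a peak within the
linking tolerance of the recorded precursor m/z (an explicit
`precursorScanNum` is honoured first). The tolerance default of 0.5 m/z is
half a typical isolation width (isolation windows of 1–3 m/z are the norm);
it is an absolute window, not ppm, because precursor isolation is an
instrument operation with m/z-unit semantics. The most-recent-parent rule
is our convention for the case where the same m/z was fragmented in
different branches; the format does not disambiguate it. Each new MS^1^
scan opens a new repetition of the MS^n^ sequence, yielding one spectrum
tree per repetition.

Relative intensities are normalized per scan to base peak = 100. Peak
picking belongs upstream (inputs are assumed centroided); the only
in-package gate is a simple threshold filter (absolute counts and/or a
multiple of the scan's median intensity).

## Consensus trees

Acquisitions are repeated several times within a run; an EFP is retained in
the consensus iff it appears in at least `min_fraction` (default 0.4,
inclusive — a 2-of-5 EFP is kept) of the repetition trees. Per retained EFP
the mean and the sample (n−1) standard deviation of relative intensity are
computed **over the trees where the EFP is present**, not over all trees;
an EFP seen once reports sd 0. Filtering happens at the EFP level, where
presence is well-defined, rather than on raw peaks before assignment.

## Comparing trees

* **Tanimoto coefficient** over EFP *presence* sets:
  $|A \cap B| / (|A| + |B| - |A \cap B|)$, defined as 0 for two empty sets.
  Intensities are not used — presence/absence is what distinguishes
  isomers, and it is robust to the concentration-dependent intensity drift
  that repeated measurements show.
* **Occurrence-matrix clustering.** Trees become 0/1 rows over the EFP
  union; agglomerative clustering under Euclidean distance with complete
  linkage by default. Average ("mean") linkage is exposed as an option
  because both appear in the literature describing this analysis; complete
  linkage is the default as the bottom-up algorithm explicitly named.
  Rows are sorted by label before clustering so ties break deterministically.
* **Dot product** of composite spectra (all scans of a tree merged, peaks
  within a bin width coalesced at the intensity-weighted mean m/z) as the
  conventional baseline: greedy nearest-first one-to-one m/z alignment
  within the bin tolerance, then the cosine of the aligned intensity
  vectors. The EFP-based comparison is sharper because the same fragment
  mass observed in different branches contributes distinct features.

## The acquisition simulator

The simulator is the package's test bed: it emulates the data-dependent
MS^n^ method the package is designed for, so every stage — mzXML writing
and reading, linking, assignment, consensus, comparison — can be exercised
end-to-end with known ground truth.

* **Scheme.** One full scan; the precursor is fragmented; then the top 5
  peaks of each MS^2^ and MS^3^ spectrum and the top 3 of each MS^4^
  spectrum are fragmented, down to MS^5^. Saturated, that is
  1 + 1 + 5 + 25 + 75 = 107 scan events (`count_scan_events()`). A peak is
  only selected above a precursor intensity threshold of 4500 ion counts.
* **Intensity scale.** Ground-truth nodes carry per-spectrum relative
  intensities; absolute scales are not constrained by per-spectrum relative
  data, so the simulator fixes them once: the survey-scan precursor at 10^6^
  counts and a per-stage transfer efficiency of 0.5 (a fragment spectrum's
  base peak carries half its precursor peak's counts). These values keep
  every branch of the packaged glutathione tree above the 4500-count
  selection threshold, consistent with all 21 of its EFPs being observable
  at high analyte concentration, and put MS^5^ leaves at realistic
  thousands of counts.
* **Noise.** Mass errors are Normal in ppm on top of an optional per-node
  fixed shift (the glutathione fixture uses its reported per-path mass
  errors, −1.0 to +1.7 ppm, as fixed shifts so the reconstruction is
  exact); intensity noise is multiplicative log-normal parameterised by a
  CV; both default to zero.
* **Artifacts.** Poisson-many artifact peaks per fragmentation scan, with
  m/z rejection-sampled to lie at least two mass tolerances away from every
  valid sub-formula ion mass of the scan's precursor — so "artifact" is
  well-defined at generation time and the artifact-rejection invariant is
  testable. Their absolute intensities are drawn below the precursor
  threshold, modelling electronic-noise-like interferences that appear in
  spectra but never trigger data-dependent selection; the MS^1^ survey scan
  is kept artifact-free.
* **Determinism.** One master seed; per-repetition child seeds are derived
  by fixed arithmetic, so identical seeds give byte-identical scan lists.

What the simulator does *not* model: fragmentation chemistry (which peaks
exist and their intensities are given, not predicted), collision-energy
and isolation-width dependence, isotope envelopes (the modelled acquisition
excludes them by design), adducts other than ±H, multiply charged ions,
chromatography, and detector saturation. Passing round-trip tests therefore
demonstrates the correctness of the data processing — linking, constraint
propagation, artifact removal, aggregation — not the realism of gas-phase
fragmentation.

### The glutathione fixture

`glutathione_fixture()` packages the canonical worked example: the 21-path
fragmentation tree of protonated glutathione (root ion C10H18N3O6S,
m/z 308.091), with each path's MS level, relative intensity, reported mass
error and intensity standard deviation. Simulating it without random noise
and re-assigning recovers exactly the 21 EFPs with the reported ppm errors
— the package's primary acceptance check.

### The isomer-pair fixture

`make_isomer_pair_fixture(n_a, n_b, n_shared, seed)` grows two ground-truth
trees from a common root (default C20H31O5, a deprotonated
prostaglandin-like ion, negative mode) whose EFP sets have exactly the
requested sizes and intersection: a shared subtree is grown first, then
compound-characteristic branches are added to each tree while excluding
the other tree's paths. The reference parameterisation (25, 31, 13)
reproduces the published isomer-pair arithmetic: 43 EFPs in the union,
12 and 18 characteristic paths, Tanimoto 13/43 ≈ 0.30. Requesting
`n_shared = 0` is infeasible — the root path is common by construction —
and errors.

## Numerical choices and degenerate inputs

* Monoisotopic atomic masses are CODATA/IUPAC values at full precision;
  the electron mass is 5.48579909 × 10⁻⁴ Da.
* ppm errors are measured against the theoretical ion m/z (signed:
  observed minus theoretical), matching the usual sign convention of
  printed mass-error tables.
* Candidate enumeration solves the H count analytically per heavy-element
  combination inside the mass window, so the uncapped search below
  ~350 Da is exact, not sampled; an independent brute-force nested-loop
  oracle backs this in the tests.
* The 40% consensus rule is inclusive (≥), and 2/5 = 0.4 is exact in
  binary floating point, so the boundary case is stable.
* Empty candidate lists, empty scans, MS^1^-only trees, empty EFP sets
  (Tanimoto 0), and all-zero scans (normalization error) are all defined
  behaviours covered by tests.
* Within-scan duplicate EFPs (two peaks resolving to the same formula)
  are merged keeping the smaller |ppm|; ties anywhere resolve by
  lexicographic token order, so outputs are byte-deterministic.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on simulated data at
desk scale: the 21-node glutathione tree (15 scans per repetition, up to 5
repetitions), random ground-truth trees of 5–14 nodes (100 round trips),
oracle cross-checks at eight target masses up to 350 Da, and isomer
collections of up to 11 trees. The published large-scale results on real
prostaglandin and eicosanoid raw data are not reproducible here — that raw
data is not deposited — so the comparison module is validated on synthetic
fixtures constructed to the published set cardinalities instead.

## Known limitations

* Adducts other than protonation/deprotonation ([M+Na]^+^ and friends) and
  charge states beyond 1 are out of scope; trees are built from the
  (de-)protonated molecule.
* Elements beyond CHNOPS are rejected at construction.
* The single-pass top-down assignment cannot recover a true fragment whose
  parent peak was discarded.
* The CML export is a documented subset (schema in `inst/schema/`), not
  full CML conformance.
* mzXML is the one instrument format read; mzML/mzData readers would be a
  straightforward extension through the same `mzR` backend.
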