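# fragtree

Fragmentation trees from multistage (MS^n) mass spectrometry, for
metabolite structural characterisation.

Ion-trap instruments can isolate an ion, fragment it, and repeat the cycle
on the fragments (MS^1 → MS^2 → … → MS^5). The precursor–product relations
across stages determine a hierarchy of fragment ions that is far more
compound-specific than a single MS/MS spectrum. `fragtree` implements the
data-processing side of this idea:

* **Hierarchy-constrained formula assignment.** Every peak receives a
  CHNOPS elemental formula for its ion composition, enumerated within a
  ppm mass tolerance (default 6 ppm) and capped element-wise by its
  precursor ion's formula — a fragment cannot contain more atoms of an
  element than its precursor, and fragment + neutral loss must add up to
  the precursor exactly. Candidates are additionally filtered by
  element-ratio plausibility rules and by non-integer RDBE
  (`C + 1 − H/2 + (N+P)/2` must be half-integer for even-electron CHNOPS
  ions). Peaks admitting no formula under these constraints are removed as
  spectral artifacts.
* **Elemental formula paths (EFPs).** Each retained ion is identified by
  the formula path from the precursor down to it, e.g.
  `C10H18N3O6S1||C5H11N2O3S1`; a fragmentation tree is the set of its
  EFPs.
* **Consensus trees** over repeated acquisitions (EFPs present in ≥ 40% of
  repetitions are retained, with mean/sd relative intensities).
* **Tree comparison**: Tanimoto coefficient `|A∩B| / |A∪B|` over EFP sets,
  occurrence-matrix hierarchical clustering (Euclidean, complete linkage),
  and composite-spectrum dot product as a baseline — enough to separate
  isomeric compounds that classical spectra cannot.
* **A DDA simulator** emulating the acquisition method (top-5/5/3
  data-dependent selection to MS^5, 4500-count precursor threshold, ppm
  mass noise, artifact injection), writing mzXML, so the whole pipeline is
  testable end to end.

Input formats: mzXML (read via Bioconductor's `mzR`) and an internal JSON
peak-tree format; outputs: JSON, a documented CML (Chemical Markup
Language) subset, TSV matrices and Newick dendrograms.

## Worked example: glutathione

The package ships the canonical worked example: the 21-path fragmentation
tree of protonated glutathione (root ion C10H18N3O6S). Simulate its
acquisition, rebuild the tree from the spectra alone, and compare:

```r
library(fragtree)

fx <- glutathione_fixture()
scans <- simulate_acquisition(fx$truth, noise = noise_model(seed = 1))
run <- tempfile(fileext = ".mzXML")
write_mzxml(scans, run)

tree <- link_precursors(read_mzxml(run))[[1]]
ft <- assign_tree(tree)   # root formula inferred by enumeration
ft
#> <fragmentation_tree> root C10H18N3O6S1, 21 EFP(s), 0 message(s) logged

setequal(efp_strings(ft), fx$efp)
#> [1] TRUE

head(ft$nodes[c("efp", "display", "observed_mz", "rel_intensity", "ppm_error")], 4)
#>                         efp     display observed_mz rel_intensity ppm_error
#> 1              C10H18N3O6S1 C10H18N3O6S    308.0909           100      -0.5
#> 2  C10H18N3O6S1||C5H8N1O3S1    C5H8NO3S    162.0222            33       1.3
#> 3 C10H18N3O6S1||C5H11N2O3S1  C5H11N2O3S    179.0487           100       1.3
#> 4 C10H18N3O6S1||C8H13N2O4S1  C8H13N2O4S    233.0595            25       1.7
```

All 21 formula paths are recovered exactly, each uniquely assigned under
its parent's cap at 6 ppm, with the per-path mass errors (−1.0 to +1.7
ppm) reproduced. An isomer comparison at the published set sizes:

```r
fix <- make_isomer_pair_fixture(25, 31, 13, seed = 1)
tanimoto(fix$efp_a, fix$efp_b)
#> [1] 0.3023256          # = 13 / 43
lengths(characteristic_efps(fix$efp_a, fix$efp_b))
#> only_a only_b shared
#>     12     18     13
```

## Command line

`exec/fragtree` wires the same functions into a shell tool:

```sh
fragtree simulate --fixture glutathione --reps 5 --mass-ppm 2 --seed 42 -o run.mzXML
fragtree build --mzxml run.mzXML --root-formula C10H17N3O6S --polarity pos \
    --ppm 6 --min-fraction 0.4 -o tree.json
fragtree compare a.json b.json
fragtree cluster *.json --linkage complete -o dendro.newick --heatmap occ.tsv
fragtree export-cml tree.json -o tree.cml
```

(`--root-formula` takes the neutral molecule; a proton is added or removed
according to `--polarity`.)

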