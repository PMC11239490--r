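# glycrunch

Automated glycan structure elucidation from LC–MS/MS data, as an R package.

Glycomics tandem mass spectra are hard to interpret: isomeric glycans share a
precursor mass, fragment ions overlap, and annotating spectra by hand in
Domon–Costello nomenclature is slow. `glycrunch` implements the full stack a
glycomics lab needs to automate this at desk scale:

- **Glycan modeling** — rooted labeled trees parsed from IUPAC-condensed
  strings (`GlcNAcβ1-3(Neu5Acα2-6)GalNAc`), canonical serialization, motif
  fingerprints, cosine structure/composition distances, rooted subgraph tests
  and biosynthetic precursors.
- **Exhaustive fragmentation and annotation** — every induced connected
  subgraph of the tree becomes a fragment skeleton; boundary bonds break as
  B/C/Y/Z (cross-ring A/X optional), with Domon–Costello and IUPAC names,
  multiply charged ions, water/CO2 losses, and a tiered prioritization scheme
  for ambiguous peaks. B and Y complements reconstruct the intact mass
  exactly: mass(B_i) + mass(Y_{n−i}) = M.
- **Spectrum processing** — mzML/mzXML (via mzR) and plain TSV peak lists;
  intensity normalization; binning into 2048 half-open windows on
  [39.714, 3000) — nominal resolution 1.45 Da — with per-bin m/z remainder
  channels; retention-time normalization with a 30-minute floor; group
  averaging on the binned grid.
- **Classification** — a dilated residual convolutional network
  (dilations 1–32, max-pool 20, 1024-d trunk, 24-d metadata embeddings,
  dropout 0.2) trained with PolyLoss (label smoothing 0.1, ε = 1) plus
  structure- and composition-distance losses, AdamW, an LR-on-plateau
  schedule, early stopping, augmentation, Platt-scaled (factor 1.15)
  test-time-augmented inference. Compute-heavy kernels are compiled
  (Rcpp/RcppArmadillo); gradients are verified numerically in the tests.
- **Inference pipeline** — `wrapInference()` groups precursors at 0.5 Da
  discontinuities and retention isomers in 0.5-min chunks, keeps top-25
  candidates, applies domain filters (score floor 0.01, glycan class with a
  0.2 cross-class override, precursor mass at all charges, diagnostic ions),
  rescores against the biosynthetic network (+0.1 per observed precursor),
  extends zero-shot to unseen structures, and estimates relative abundances.
- **Synthetic data** — `generateLibrary()` and `simulateSpectrum()` build
  in-silico fragmented LC–MS/MS runs with controllable noise, so the entire
  stack is testable offline with a known ground truth.

## Worked example

```r
library(glycrunch)

g <- parseIUPAC("GlcNAcb1-3(Neu5Aca2-6)GalNAc", reduced = TRUE)
glycanMass(g)
#> [1] 717.2804
ionMz(glycanMass(g), ionSpec("negative", 1))
#> [1] 716.2731

fr <- enumerateFragments(g, ions = list(ionSpec("negative", 1)),
                         allow_cross_ring = FALSE, global_mods = character(0))
fr[fr$n_cleav == 1, c("theo_mz", "dc_name", "iupac_name")]
#>     theo_mz dc_name       iupac_name
#> 10 202.0721     B1β           GlcNAc
#> 11 220.0827     C1β           GlcNAc
#> 12 290.0881     B1α           Neu5Ac
#> 13 308.0987     C1α           Neu5Ac
#> 6  407.1671     Z1α GlcNAcβ1-3GalNAc
#> 5  425.1777     Y1α GlcNAcβ1-3GalNAc
#> 8  495.1832     Z1β Neu5Acα2-6GalNAc
#> 7  513.1937     Y1β Neu5Acα2-6GalNAc
```

The B1α ion at m/z 290.0881 is the sialic acid oxocarbenium-type fragment —
the same m/z the pipeline uses as the Neu5Ac diagnostic ion. An end-to-end
run on a simulated file:

```r
lib  <- generateLibrary(8, glycan_class = "O", seed = 42)
d    <- makeDataset(lib, spectra_per_glycan = 3, seed = 7)
pred <- cosineBaselinePredictor(lib)
tab  <- wrapInference(d$spectra, pred, expected_class = "O")
head(flattenPredictions(tab)[, c("precursor_mz", "rt_start", "evidence", "top1", "score1")])
```

Each row is one (precursor m/z, retention window) entity with up to five
ranked candidate structures, renormalized scores, an evidence category
(`strong` = classifier, `medium` = biosynthetic intermediate, `weak` =
substitution/composition match) and, when MS1 data are supplied, a relative
abundance. The neural classifier plugs into the same interface via
`nnPredictor()` after `trainModel()`.

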