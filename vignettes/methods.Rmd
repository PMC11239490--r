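---
title: "Methods: glycan structure prediction and fragment annotation in glycrunch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glycan structure prediction and fragment annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycrunch)
```

## The problem

Tandem mass spectrometry is the workhorse of glycomics, but a glycan MS/MS
spectrum does not directly reveal a structure: isomeric glycans share a
precursor mass, fragment ions overlap, and manual annotation in
Domon–Costello nomenclature is slow and inconsistent. `glycrunch` implements a
complete desk-scale stack for this problem: glycans as rooted labeled trees,
exhaustive in-silico fragmentation and peak annotation, LC–MS/MS spectrum
preprocessing, a convolutional classifier over binned spectra, and an
inference pipeline that curates ranked candidate structures with
domain-knowledge filters and biosynthetic rescoring. A synthetic-data module
generates in-silico fragmented spectra so that every stage runs and is tested
fully offline.

## Glycan model

A glycan is a rooted labeled tree (`GlycanGraph`): nodes are monosaccharides
(labels may carry site modifications such as `GlcNAc6S`), edges carry
glycosidic linkage labels following the grammar `[αβ?][12]-[1-9?]`, and the
root is the reducing-end residue, optionally reduced to an alditol (+2 H) as
produced by reductive β-elimination sample preparation. IUPAC-condensed
strings such as `GlcNAcβ1-3(Neu5Acα2-6)GalNAc` are parsed right-to-left; the
rightmost residue is the root.

**Canonical form.** Children of every node are ordered by (linkage label,
canonical subtree string). This makes serialization a canonical key, which is
what deduplication, library handling and biosynthetic-precursor generation
rely on. Wildcard linkages (`?1-?`) compare as their literal string in
canonicalization but match any linkage in rooted-subgraph tests, so
incompletely specified library structures still embed correctly.

**Fingerprints and distances.** A glycan's motif fingerprint counts its
monosaccharides and its linkage-typed disaccharides (e.g. `Galβ1-3GalNAc`)
over a vocabulary built from the reference library and then frozen;
out-of-vocabulary motifs at inference are ignored so the distance geometry
stays stable. Structure distance is one minus the cosine similarity of
fingerprints; composition distance is the analogous quantity on residue-class
count vectors. We chose linkage-typed (rather than linkage-agnostic)
disaccharide motifs because linkage position is exactly what distinguishes
the isomers this field cares about; the linkage-agnostic alternative would
fold e.g. α2-3 and α2-6 sialylation into one motif. A fingerprint that is
entirely out of vocabulary has an undefined cosine; we define its distance as
0 to a structurally identical glycan and 1 to anything else.

## Mass arithmetic

Residue masses are dehydrated monoisotopic masses computed from elemental
formulas (C 12, H 1.007825, O 15.994915, N 14.003074, S 31.972071,
Na 22.98977; proton 1.007276 Da). The intact neutral mass is the residue sum
plus one water, plus 2.015650 Da when the reducing end is an alditol. Sulfate
(SO3, 79.956815 Da) and phosphate (HPO3, 79.966331 Da) ride on the residue
labels. Negative-mode ions follow (M − z·p + Δ)/z with adduct shifts
Δ(acetate) = +60.021130 Da (giving [M+CH3COO]⁻) and Δ(sodium) = +21.981944 Da
(Na-for-H exchange); electron mass is neglected (≈0.0005 Da, far below the
0.5 Da working tolerance). Permethylation adds one methyl increment
(14.015650 Da) per free hydroxyl/amine site from a per-residue site table
(Hex 3, HexNAc 3, dHex 2, Pen 2, Neu5Ac 5, Neu5Gc 6, Kdn 5), each
sulfate/phosphate consuming one site; underivatized negative mode is the
reference configuration throughout.

## Fragment enumeration and annotation

Every fragment skeleton is an induced connected subgraph of the tree. For a
rooted tree these are enumerated exactly once by fixing the subgraph's
topmost node and taking, per child subtree, either nothing or any connected
subgraph topped at that child (memoized per node); the enumeration is
deterministic and is property-tested against brute-force subset enumeration
plus a connectivity check.

A subgraph's boundary bonds define its cleavages: the bond above its top
residue breaks as **B** (−H2O) or **C** (0), every bond to an excluded child
as **Y** (0) or **Z** (−H2O), relative to the base mass
(residue sum + H2O, + 2 H when the reduced root is included). These offsets
make B and Y complements exactly reconstruct the intact mass, a conservation
law the tests verify to 1e-6 Da for all glycosidic cleavages of several
glycans.

**Cross-ring ions.** The A/X catalog is a documented package convention: a
ring-bond pair splits the residue into a reducing-side part of mass
60.021130 (0,2), 90.031694 (0,3), 120.042259 (2,4) or 30.010565 Da (1,5),
with A = C − part and X = Y + part, so A/X complements reconstruct M + H2O.
Sialic acids admit only the 0,2 pair. A retained-carbon table filters ring
cleavages that are physically impossible given the linkage positions of the
retained children (e.g. a 2,4-cleavage cannot retain a child attached at
C3). Global modifications default to −H2O, −2H2O, and −CO2 (the latter only
on fragments containing a sialic acid).

**Naming.** B/C/A indices count from the non-reducing terminus of the branch
(the cleaved residue's height in the parent tree); Y/Z indices count bonds
from the reducing end; X carries the split residue's depth. Branch
designators are Greek letters assigned at each branching point by decreasing
branch mass (ties broken by canonical string); simultaneous cleavages join
with "/"; the intact species is "M". Names parse back to their cleavage
records, which the tests use as a round-trip check.

**Prioritization.** When several fragments explain one peak, ranking is
tiered: fewer cleavages; glycosidic before cross-ring; fewer global
modifications; higher corroboration (other matched fragments in the spectrum
that are complementary to, contained in, or containing the candidate's
residue set); smaller absolute mass error; name as a deterministic
tie-break. The tier order encodes prior plausibility (single glycosidic
cleavages dominate real trap spectra) and spectrum-level evidence, and every
tie-break is deterministic so annotation is reproducible.

## Spectrum processing

Spectra keep at most the 1000 most intense peaks; scans eluting before
2 minutes are dropped as noise. Intensities are normalized to total-ion
fractions. Binning uses 2048 equal, half-open windows on [39.714, 3000),
i.e. a nominal resolution of `r round(binWidth(), 2)` Da; each bin also
records the m/z remainder of its most intense peak relative to the left bin
edge, which restores sub-bin peak location for the model. Retention times
are divided by the run maximum, floored at 30 minutes; missing retention
times map to 0. Groups of co-eluting spectra are averaged bin-wise
(order-independent and deterministic), and a representative "median spectrum"
takes bin-wise median intensities with m/z reconstructed from median
remainders — this keeps approximate raw m/z available for diagnostic-ion
checks downstream.

## Classifier

The network maps (2048 binned intensities, 2048 remainders, precursor m/z,
normalized retention time, five categorical metadata codes) to class scores
over the reference library: a 1-D convolution plus leaky ReLU, six residual
dilated convolutions (dilations 1, 2, 4, 8, 16, 32), max-pooling with kernel
20 and a linear layer to 1024 features; scalars pass a linear layer, layer
normalization and leaky ReLU into 24 dimensions; categoricals are embedded
into 24 dimensions; the concatenation feeds two (linear, layer norm, leaky
ReLU, dropout 0.2) blocks and a final linear layer. Channel count (8),
kernel size (5) and head width (256) are package defaults exposed in
`modelConfig()`. Weights are He-initialized. The convolution, pooling and
activation kernels are compiled (src/conv1d.cpp); all analytic gradients are
verified against numerical differentiation in the test suite.

**Losses.** The base loss is PolyLoss — cross-entropy plus ε·(1 − p_target)
with ε = 1 — with label smoothing 0.1 applied to the targets first. Two
domain losses are added: the expectation, under the predicted class
distribution, of the structure-distance and composition-distance vectors to
the target glycan ("mean averaging" is read as the batch mean of per-sample
expectations). With all-zero distance matrices the total loss reduces
exactly to PolyLoss. These losses penalize confident but structurally
dissimilar predictions, pushing residual errors toward near-isomers.

**Optimization.** AdamW (weight decay 2e-5) with a schedule that multiplies
the learning rate by 1/5 after 4 epochs without validation improvement,
early stopping after 12, and restoration of the best-validation parameters.
The corpus-scale defaults (`trainConfig()`: learning rate 1e-4, batch 256,
up to 200 epochs) suit large training sets; the package's toy benchmarks —
20 classes × 50 synthetic spectra, an 800-spectrum training split — use a
toy-scale schedule (learning rate 1e-3, batch 64, at most 40 epochs), since
batch 256 would give only four parameter updates per epoch on 800 spectra.
Sharpness-aware minimization is not implemented; the plain optimizer is
deterministic across platforms, which the reproducibility tests rely on.

**Augmentation and calibration.** Training batches are augmented on the
binned representation: low-intensity peak removal, multiplicative intensity
jitter, spurious peak addition, precursor adduct formation (acetate/sodium)
and uniform noise on the precursor m/z (±0.5 Da) and retention time (±10%).
At inference, logits are divided by the Platt factor 1.15 before the
softmax, and predictions of five augmented inferences are averaged
(test-time augmentation). Calibration is monotone, so it never changes a
single inference's top prediction.

## Inference pipeline

`wrapInference()` runs: load spectra → group precursors at m/z
discontinuities > 0.5 Da (strict) → split each group into 0.5-minute
retention chunks (missing retention falls into chunk 0) → average each chunk
→ score with the predictor and keep the top 25 → domain filters → merge
adjacent windows with identical candidate lists → biosynthetic rescoring →
optional zero-shot extension → abundance estimation from MS1 features when
provided.

**Domain filters** remove candidates scoring below 0.01, candidates of the
wrong glycan class unless their score exceeds 0.2 (O-glycan preparations
often carry remnant N-glycans), candidates whose composition cannot match
the precursor within 0.5 Da at any charge up to the configured maximum, and
candidates containing a motif whose diagnostic ion (shipped table: sialic
acid B1 ions at m/z 290.0881/306.0831, fucose B1 at 145.0506, bisulfate at
96.9601) is absent from the representative spectrum.

**Biosynthetic rescoring** adds 0.1 to a candidate's score for each distinct
lower-mass top-1 prediction that embeds in it as a rooted subgraph (wildcard
linkages honored), re-sorts, renormalizes scores to 1 and keeps the top 5.
The precursor pool is taken from the pre-update top-1 set, which makes the
result independent of processing order; "largest first" ordering is by
neutral mass with node count as tie-break. We renormalize before the top-5
cut (the alternative — cut first — would make reported scores depend on the
discarded tail). After zero-shot extension, bonuses are donated only by
strong-evidence rows.

**Zero-shot extension** explains rows left without candidates: biosynthetic
intermediates (iterated leaf deletions of the strong top-1 structures)
matching the precursor mass within 0.5 Da at any charge join with evidence
"medium"; single Neu5Ac↔Neu5Gc substitutions (±15.9949 Da each) and, for
O-glycans, GlcNAc↔GlcNAc6S swaps join with evidence "weak" when their
diagnostic ions are present; reference-library composition matches join with
evidence "weak". Additions pass the same domain filters (the 0.01 score
floor is not applied to the uniform placeholder scores of zero-shot
candidates, which carry no classifier confidence). Zero-shot candidates
receive equal scores summing to one per row.

## Synthetic data

`generateLibrary()` grows structures from a class-specific core (GalNAc for
O-glycans) by biosynthetically plausible single-residue additions (core 1/2/3
extensions, LacNAc elongation, sialylation, fucosylation, occasional Neu5Gc),
with at most two children per residue and no two identical child labels on
one residue — so antennae stay mass-distinguishable and the self-consistency
tests are meaningful. `simulateSpectrum()` samples peaks from the glycan's
own theoretical singly charged glycosidic fragment list (cleavage order ≤ 2,
water-loss satellites), deduplicated to one fragment species per unique m/z
— mass-degenerate assignments such as Z versus Y−H2O are the same observable
peak, and the minimal-tier representative is kept. Defaults: each fragment
observed with probability 0.7, Gaussian m/z jitter 0.005 Da, five uniform
decoy peaks at 5% of the median true intensity, intensities decaying
exponentially with cleavage count (single-cleavage ions strongest) with
log-normal scatter, and per-glycan Gaussian elution. `makeDataset()`
organizes spectra into pseudo-sample "runs" (one spectrum per glycan per run,
glycan *i* eluting near 3 + 0.7·i minutes) and assigns whole runs to the
train or test side, so no run spans the split.

What the simulator does *not* emulate: learned or physical fragment
intensities, isotope envelopes, profile peak shapes, co-isolation chimeras,
or instrument-specific fragmentation preferences. Passing tests demonstrate
that the machinery — enumeration, matching, binning, grouping, learning — is
correct and internally consistent, not that the classifier's synthetic
accuracy transfers to real spectra.

## Numerical choices and degenerate inputs

Half-open bin intervals; strict inequality for precursor-group
discontinuities; floor-based retention chunking; 0.5 Da default matching
tolerance wherever masses are compared and 0.01 Da in the noiseless
self-consistency checks; softmax computed with column-max subtraction;
layer-norm ε 1e-5; all stochastic components (library growth, simulation,
shuffling, dropout, augmentation) run under explicit seeds through an
RNG-state-preserving helper, so identical seeds give identical results.
Empty spectra yield empty prediction tables; all-zero intensity vectors stay
all-zero with a warning; a single-residue glycan has no precursors and only
itself as a fragment skeleton.

## Benchmarks at desk scale

The shipped acceptance checks run, at fixed seeds: exact binning and
elemental arithmetic; subgraph-enumeration equality with brute force on 200
random trees of up to 8 residues; B/Y mass conservation to 1e-6 Da; 100%
rank-1 recovery of generating fragments on noiseless simulated spectra of 20
glycans at 0.01 Da tolerance; hand-computed grouping and rescoring fixtures;
and the 20-class × 50-spectrum learning benchmark described above, together
with a paired run without the distance losses.

On the paired comparison we assert two forms. The probability-weighted form
— the expected structure distance of the predicted distribution to the
target, averaged over the held-out set — is the quantity the distance losses
optimize and uses every test spectrum. The hard form — the mean structure
distance of the misclassified spectra only — is also asserted, but at ~97%
accuracy it rests on six or seven errors, nearly all of them one persistent
isomer confusion common to both models, and a single extra error can move
either mean by more than the effect size; at this error count that
comparison is not statistically identifiable, and its outcome at the fixed
seed should be read with that caveat.

## Known limitations

Fragment charge placement is purely combinatorial (no charge-site modeling);
the cross-ring mass catalog is a convention, not a gas-phase model; the
prioritization weights are a fixed tier order rather than learned
likelihoods; permethylated cross-ring masses are outside the documented site
table; multi-sample batch alignment, taxonomy-backed candidate databases and
drawing of structures are out of scope. The classifier's reported accuracy
is on synthetic spectra; real-data performance depends on fragmentation
behavior the simulator does not model.
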