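---
title: "Methods: structure-based cartography of C2 beta-sandwich domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based cartography of C2 beta-sandwich domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(C2Cartographer)
```

## The problem

Ferlins (dysferlin, myoferlin, otoferlin, Fer1L4/5/6) are very large membrane
proteins built almost entirely from tandem C2 domains — eight-stranded
antiparallel beta-sandwiches of roughly 130 residues arranged around a Greek
key. Sequence-only domain predictions have historically disagreed about how
many C2 domains these proteins contain and where each begins and ends,
because many ferlin C2 domains carry long loop insertions that break
sequence similarity to classical C2 domains. Given predicted 3D models, the
domains can instead be read directly off the backbone hydrogen-bond pattern.
This package implements that structural reading as a tested pipeline:

1. backbone hydrogen bonds are assigned with the Kabsch–Sander electrostatic
   model;
2. bonds are chained into beta-bridges, ladders, strands and sheets;
3. pairs of four-stranded sheets packing face to face are recognized as C2
   sandwich candidates;
4. each candidate's strand connectivity is classified as Type-I or Type-II
   (the two known C2 topologies, related by a single-step circular
   permutation);
5. domain boundaries run from the first residue of strand 1 that contributes
   a backbone hydrogen bond to a paired strand through the last such residue
   of strand 8;
6. inter-strand loops are named, the three calcium-pocket apex loops are
   identified geometrically, and loop insertions relative to a reference
   domain are detected and called as conserved subdomains across paralogs.

Sequence-level analytics used alongside the structural stages — residue
composition, isoelectric point, molar extinction coefficient,
transmembrane-span arithmetic and hydropathy scans — are included, as are
the two published ferlin reference tables (the FerI alignment and the
transmembrane spans) as packaged fixtures.

## The hydrogen-bond model and strand assignment

A backbone N–H...O=C bond between a donor and an acceptor residue is scored
as

$$E = 0.084 \cdot 332 \left( \frac{1}{r_{ON}} + \frac{1}{r_{CH}}
      - \frac{1}{r_{OH}} - \frac{1}{r_{CN}} \right) \ \mathrm{kcal/mol},$$

with distances in Ångström; a bond is assigned when $E < -0.5$ kcal/mol.
Amide hydrogens are placed at $N + \widehat{(C_{prev} - O_{prev})}$ (1.0 Å
from N, anti-parallel to the preceding carbonyl); experimentally present
hydrogens are kept. Prolines and chain-first residues never donate. Per
donor only the best two acceptors are retained, and any inter-atomic
distance below 0.5 Å is treated as a clash (no bond).

Beta-bridges follow the standard parallel/antiparallel bond patterns,
bridges chain into ladders, ladders merge across classic one-residue
beta-bulges (provided the bridge partners of the two ladders are contiguous
on the partner strand), and runs of at least `minStrandLen = 3` residues
become strands. Consecutive residues whose C-alpha atoms are more than
4.5 Å apart split every ladder (chain break). Strand pairings carry the
majority bridge orientation; sheets are the connected components of the
pairing graph.

A deliberately minimal helix state ('H', overlapping $i \to i+4$ turns) is
assigned only because the subdomain rule needs a secondary-structure class
for loop insertions; full eight-state assignment is out of scope.

## C2 recognition, topology and boundaries

A C2 candidate is two four-stranded sheets whose mean nearest C-alpha
distance is below `sandwichDist = 11` Å (typical beta-sandwich packing).
The candidate's eight strands are renumbered 1–8 along the sequence and the
observed pairing graph is matched against the canonical C2 adjacency
template and its single-step circular permutant; the better match gives
Type-I or Type-II, a tie gives "ambiguous". The template is data, not code
(`topologyTemplate()`): the canonical spatial order of the two sheets is
4-1-8-5 and 3-2-7-6 in sequence-strand indices, the classical C2
arrangement.

Boundaries use the hydrogen-bond rule exactly: the start is the minimum
residue of strand 1 participating (as donor or acceptor) in a bond to one
of strand 1's paired strands; the end is the corresponding maximum on
strand 8. Because strands 1 and 8 occupy sheet-interior slots in both C2
topologies, their terminal residues always carry direct reciprocal bonds
and the rule is exact on the synthetic models; edge strands (4, 5, 3 and 6
in Type-I indexing) may fray by one residue at their termini, which is why
strand-range recovery is guaranteed only to ±1 there.

Loops are the inter-strand segments (named `b1-2` … `b7-8`). The pocket
apex is found geometrically: the sandwich mid-plane is taken orthogonal to
the mean strand axis through the candidate centroid, and a loop is apical
when its midpoint C-alpha falls on the same side as loop `b1-2`; the first
three apical loops in sequence order become loop1–loop3. For a Type-II
domain loop1 coincides with `b1-2` by construction. When `b1-2` is empty
the apex test is declared degenerate and loops keep their `b` names only.

## Comparison, insertions and the subdomain rule

Two annotated domains of the same topology are compared by a
strand-anchored rigid alignment: a coarse Kabsch fit on the eight strand
centroids fixes the frame, the per-strand residue register is then chosen
as the integer shift minimizing the summed squared C-alpha distance, and a
final Kabsch fit over all strand-paired C-alpha gives the reported RMSD.
Loops are paired from both ends up to the shorter loop length, leaving the
middle of the longer loop unpaired.

Insertion lengths are loop-length differences against the reference domain
(`max(0, candidate - reference)` per loop), and a subdomain is called at a
loop when **more than 20** inserted residues (21 qualifies, 20 does not)
appear in **at least two** paralogs with agreeing secondary-structure class
(helix-rich / sheet-rich / coil, using a 40% plurality of the insertion's
residues). With a single paralog conservation cannot be evaluated and
candidates are returned flagged unconfirmed. The packaged reference is a
generator-built canonical Type-II model (`referenceC2()`); it is synthetic,
standing in for an experimental reference structure, and it carries its
construction register rather than a re-detected annotation — a reference is
a calibrated object, and using its known register keeps edge-strand fraying
out of every loop-length comparison made against it.

Overlapping fragment models are stitched by rigidly superposing each next
fragment onto the assembly over at least `minOverlap = 10` shared residues;
overlap coordinates come from the earlier fragment and junction RMSDs above
2.0 Å warn but still stitch.

## Sequence analytics

* **Isoelectric point**: Henderson–Hasselbalch net charge over the termini
  and D, E, C, Y, H, K, R with the Bjellqvist/ProtParam pKa set (including
  the residue-specific terminal corrections), bisected on pH 0–14 to a net
  charge below 1e-4. The bisection is not floored: two of the published
  FerI values lie below pH 4.05, where some reimplementations clamp.
* **Extinction coefficient** (280 nm): $5500\,n_W + 1490\,n_Y + 125\,
  n_{cystine}$, with cystines either `floor(nCys/2)` ("all-cystine") or 0
  ("all-reduced").
* **Transmembrane arithmetic**: span lengths are inclusive
  (`last - first + 1`); extracellular counts use the exclusive
  `last - first` convention — the two conventions that reproduce the
  published table's parentheticals. The conserved hinge proline is searched
  from four residues inside the span end to three past it, accommodating
  the one ferlin whose hinge proline falls inside the predicted span.
* **Identity/similarity** of gapped alignments count identical
  (or same-class) non-double-gap columns over columns where at least one
  row has a residue; the similarity classes are {ILVM, FWY, KRH, DE, ST,
  NQ, AG, C, P}, one common physico-chemical grouping (the original
  server's classes are not published).
* **Pocket census**: the six reference pocket slots are mapped through the
  strand-anchored correspondence and counted as acidic when the aligned
  candidate residue is D or E; four or more acidic slots give
  "binding-likely". When a cation-bound reference structure is available,
  `referencePocketPositions()` derives the slots as the residues within
  4.0 Å of the bound divalent cations.

Two cells of the published tables are internally inconsistent and are
surfaced rather than resolved: the myoferlin TM span 2026–2046 is 21
residues inclusive yet is printed as 23, and the Fer1L5 extracellular
interval 1982–2047 gives 65 under the end-minus-start convention yet is
printed as (75). Likewise, computing the FerI isoelectric points from the
printed sequences reproduces every printed value to printed precision
*except* that the otoferlin and myoferlin cells come out transposed
(computed otoferlin 4.40 = printed myoferlin; computed myoferlin 3.93 =
printed otoferlin), which strongly suggests a typesetting swap in the
published table. The package computes; it does not silently correct the
print.

## The synthetic-data generator

Every structural stage is validated against models with known ground truth
built by `buildSandwich()`. The geometry is an idealized beta-lattice:
strands rise 3.3 Å per residue with an alternating ±0.94 Å C-alpha pleat
(consecutive C-alpha 3.8 Å), carbonyls and amides alternate along the
hydrogen-bond axis, strands sit 4.13 Å apart within a sheet (giving
$r_{ON} = 2.90$ Å and bond energies near −2.9 kcal/mol) and the two sheets
pack 10.5 Å apart. Defaults emulate a canonical ferlin-like C2 domain:
eight 8-residue strands, nine-residue loops (a ~127-residue domain span),
Type-II connectivity, aspartates at the six pocket slots, 0.1 Å coordinate
noise. Loops are cubic-Bézier arcs resampled at 3.8 Å spacing, each in its
own tilted plane; helical insertions are ideal alpha-helices (1.5 Å rise,
100°/residue) spliced into a loop between proline connector pads.

Two generator choices deserve explanation:

* **Noise is a smooth per-residue rigid displacement field** (a moving
  average of iid Gaussians over a five-residue window, scaled so the
  marginal per-residue standard deviation equals `noiseSigma`). Model error
  in predicted structures is correlated at and below the residue scale;
  independent per-atom noise of 0.3 Å would produce C=O bond lengths of
  1.23 ± 0.4 Å and spurious chain breaks — stereochemistry no real model
  exhibits — and would randomize the amide-hydrogen placement direction,
  which is a function of the preceding carbonyl.
* **Coil residues are proline.** Loops, tails and connector pads cannot act
  as hydrogen-bond donors, so coils can never complete a beta-bridge
  pattern, and loop/tail geometry cannot masquerade as strand. This also
  mirrors the proline-rich character of the real inter-domain linkers.
  Coil carbonyl directions are additionally randomized about the local
  tangent (irregular dihedrals), except for the two junction residues at
  each coil end, which keep a deterministic outward carbonyl.

What passing the synthetic suite shows: the assignment, recognition,
classification, boundary, insertion and comparison logic is correct on
geometry whose ground truth is known exactly, and robust to 0.3 Å of
correlated coordinate noise. What it does not show: performance on real
predicted models, whose strands twist, whose loops pack against the domain
body, and whose errors are not Gaussian. The lattice is flat (no strand
twist), side chains are absent, and sequence realism is limited to
composition classes. The external-data checks (published extinction
coefficient, linker compositions, experimental cross-structure RMSD)
activate only when the user supplies the corresponding sequence or
coordinate files under `inst/extdata/`; they are part of the acceptance
suite and fail visibly when the data are absent.

## Numerical choices

* Kabsch superposition is computed by SVD with the determinant correction
  (proper rotation); collinear inputs (second singular value below
  1e-8 of the first) and fewer than three points raise a degeneracy error.
  Agreement with the independent quaternion (Horn) method is at the 1e-14 Å
  level over a thousand random instances.
* The pI bisection runs at most 100 halvings of pH 0–14 and stops at
  |charge| < 1e-4; the charge is monotone in pH so the root is unique.
* Greedy candidate resolution: earlier sequence start wins; ties in the
  topology template score give "ambiguous" rather than a guess.
* Problem sizes: the validation suite uses 50 seeded replicates at 0.3 Å
  noise (both topologies, with and without 21–45-residue insertions),
  1000 random superposition instances and five stitching round trips —
  sizes chosen to exercise every code path with comfortable statistical
  coverage at interactive runtimes.

## Known limitations

* The pipeline consumes coordinate models; it performs no structure
  prediction, relaxation, model quality assessment or spectroscopy — the
  upstream modelling stack of the original study is explicitly out of
  scope, as are flexible (hinge-bending) alignments.
* Sandwich detection expects two four-stranded sheets; heavily distorted
  or partially resolved domains (seven detectable strands) are reported as
  no candidate rather than guessed.
* The transmembrane hydropathy scan is a simple Kyte–Doolittle screen, a
  fallback rather than a replacement for a dedicated TM predictor; the
  packaged spans are the published predictions.
* Insertion lengths are measured between detected strand termini; at
  frayed edge-strand termini they carry a ±1-residue uncertainty per
  flanking terminus, far below the >20-residue subdomain threshold.
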