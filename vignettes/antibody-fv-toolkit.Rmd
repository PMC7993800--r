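---
title: "Curating antibody Fv template databases, interface constraints and fold-tree kinematics with abkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating antibody Fv template databases, interface constraints and fold-tree kinematics with abkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abkit)
library(dplyr)
```

## Scope and model

Antibody homology modeling by grafting assembles a variable fragment (Fv)
from per-region structural templates: each of the six complementarity
determining regions (CDRs L1–L3, H1–H3), the two framework scaffolds (FRL,
FRH) and the relative heavy/light orientation is modeled from the
crystal-structure fragment whose sequence best matches the query. The
quality of the resulting model is bounded by the quality and coverage of
the template database, so the curation rules matter as much as the
selection score. `abkit` implements that curation and selection
infrastructure, the automatic V~H~–V~L~ interface constraint, a
hierarchical fold-tree kinematic model for multi-body antibody–antigen
docking, and the metrics used to benchmark grafted models — as plain,
testable R functions over tidy tables, without any molecular-simulation
machinery.

Everything is keyed to the Chothia numbering convention. `chothia_regions()`
is the single source of truth for the region spans (CDR L1 24–34, L2
50–56, L3 89–97; H1 26–35, H2 50–65, H3 95–102; six FRL and five FRH
ranges; orientation anchors L5–L104 and H5–H109). The frameworks do not
exactly complement the CDRs — some non-CDR loops belong to neither — so
positions outside every range map to `"unassigned"` rather than being
forced into a framework. Insertion-coded residues (H100A, H100B, …)
inherit the region of their parent number, the standard reading of
Chothia insertion codes.

## Database curation

`build_database()` runs, per summary entry: antibody selection (first
reported row; scFv rows rejected), parsing, truncation to the Fv (light
1–109, heavy 1–112), quality control, full-Fv sequence deduplication,
CDR chainbreak detection, region-sequence extraction and per-CDR
B-factor averaging, then pools sequences by (region, length) —
`database.L1.11` holds every length-11 CDR-L1 sequence, indexed by PDB
id. The quality criteria are:

* **resolution** — strictly below 3 Å; entries with no reported
  resolution (NMR, low-resolution EM) fail;
* **loadability** — parseable coordinates, summary-named chains present,
  complete N/CA/C/O backbone, recognizable residue codes;
* **backbone geometry** — no C–N peptide bond over 2 Å, CA–C–N angles
  within 89.5–144.5° and C–N–CA within 95–151°;
* **occupancy** — no zero-occupancy atoms (partial occupancies pass;
  only exact zeros fail);
* **anchors** — no missing region-boundary or orientation-anchor
  residues. The set of "conserved" positions is not enumerated anywhere
  authoritative; we check every region-boundary position plus
  L5/L104/H5/H109, a documented superset guess, skipping the light-chain
  anchors for heavy-only (nanobody) entries.

Two design points were genuinely open. First, geometry violations could
either reject the structure outright or merely annotate it; we reject
only when the violating link lies in the frameworks, and when it lies in
a CDR we keep the entry but omit that CDR from pooling, matching the
separate "CDRs containing chainbreaks are omitted" rule. Second, a
missing interior Chothia number is only a chainbreak when its flanking
residues are spatially discontinuous: short CDRs legitimately skip
interior numbers with perfectly continuous geometry, and flagging them
would discard every short loop. Terminal absences are treated as
truncation, never as breaks.

Deduplication compares the concatenated light+heavy Fv sequence (the
heavy chain alone for nanobodies) and keeps the first entry in summary
order; per-chain deduplication would be stricter and is noted as the
alternative. Region sequences containing non-standard residues (mapped
to `X`) are unalignable and are excluded from pools but logged.

## Template selection

`select_templates()` mirrors the database layout: CDR queries search
only the pool of exactly matching length with ungapped scoring under
PAM30; framework and orientation queries search their region's pools
with gapped local (Smith–Waterman) alignment under BLOSUM62. The
matrices are the conventional short-fragment/long-fragment pairing; gap
penalties are not specified anywhere in the source material, so we ship
the standard pairings — open 11 / extend 1 for BLOSUM62 and open 9 /
extend 1 for PAM30 — under the convention that a gap of length *L*
costs open + *L*·extend. Two filters apply: `exclude_pdb`
(case-insensitive; the benchmarking device that keeps a query's own
crystal structure out of its template set) and the CDR-only proline
filter, which drops any template with a proline/non-proline mismatch
against the query. Whether offending templates should be demoted or
removed is unstated; we remove them from the ranking but keep them,
flagged, in verbose output. Ties break deterministically: higher score,
then lower resolution, then lower average CDR B-factor, then
lexicographic PDB id — the two structure-quality values are computed at
database build time precisely so they are available here.

## The Q–Q constraint and K-of-N composites

A conserved pair of glutamines — light 38 and heavy 39 — can form two
side-chain hydrogen bonds across the V~H~–V~L~ interface (each amide
NE2 donating to the partner's OE1). `find_qq_pairs()` returns the two
donor–acceptor pairings whenever both glutamines are present with
complete amides, and nothing otherwise (nanobodies simply disable the
constraint). The restraint is a flat harmonic,

$$ f(x) = \begin{cases} \left(\dfrac{|x - x_0| - d_m}{\sigma}\right)^2 & |x - x_0| > d_m \\ 0 & \text{otherwise,} \end{cases} $$

with shipped defaults $x_0 = 2.91$ Å and $\sigma = 0.23$ Å (the
database-wide fit over observed donor–acceptor N–O distances) and
$d_m = 0.5\sigma$, so no penalty applies within half a standard
deviation of the mean. Note a documented discrepancy: with these values
the formula yields a penalty of $((\sigma - 0.5\sigma)/\sigma)^2 = 0.25$
at one standard deviation, although the accompanying prose describes
0.5 REU there; we implement the formula as printed and test the 0.25
value. The boundary $|x - x_0| = d_m$ falls in the zero branch (the
penalized condition is a strict inequality). `fit_qq_parameters()` uses
the sample (n−1) standard deviation — population vs. sample is
unspecified and the difference is negligible at database scale — and
rejects degenerate inputs (fewer than two values, or zero variance).
Hydrogen-bond presence for reporting uses a plain geometric criterion,
N–O ≤ 3.5 Å.

`kofn_constraint()` composes flat harmonics: only the K lowest member
penalties count, the form used to restrain an epitope residue toward
its nearest CDR residues when experimental data (e.g. HX-MS) names the
residue but not its partner. `write_constraint_file()` emits the
conventional Rosetta text grammar (`AtomPair … FLAT_HARMONIC x0 sigma
dm`, three decimals; K-of-N blocks bracketed by `KofNConstraint K` /
`End`) so emitted files remain usable by the original modeling
software, and `read_constraint_file()` round-trips it.

## Fold-tree kinematics

A fold tree is a directed acyclic graph over residues that dictates how
coordinate changes propagate. The classic linear tree jumps between
consecutive chains' center-of-mass-proximal residues, so perturbing an
upstream jump drags every later chain along — correct, but it couples
motions that docking would like independent. The hierarchical builder
places virtual residues (position-only nodes, invisible to every energy
or QC computation) at each chain COM, each group COM and the complex
COM, with jumps root → group → chain → anchor residue. Perturbing the
inter-group jump then moves one subcomplex rigidly while the other is
untouched; peptide edges radiate from each chain's anchor so
within-chain modifications stay local. "Center of mass" is the
unweighted heavy-atom centroid — it serves only as an anchor location,
so mass weighting would change nothing material. The root sits at the
complex COM; any root choice preserves the independence properties, and
rooting at a neutral virtual node keeps the construction symmetric in
its groups. Jump updates are stored as rotation-matrix + translation
pairs and applied as a rotation about the jump's downstream anchor
followed by a translation; rigid-body conservation is asserted in the
tests to 10⁻⁶ Å. Loop-opening cutpoint management and atom-level
internal-coordinate kinematics are out of scope.

## Benchmark metrics

`backbone_rmsd()` superimposes the model on the native over the
framework (FRL + FRH) backbone atoms (N, CA, C, O — "backbone" is not
enumerated in the source, so we use the standard four) by least squares,
then measures the named region without re-fitting. This
framework-frame convention is the established way to report CDR
accuracy: it separates loop error from global placement error.

Fragment similarity uses the chord distance on backbone dihedrals,
$D^2(\theta_1, \theta_2) = 2 - 2\cos(\theta_2 - \theta_1)$, averaged
over a window:
$\langle D\rangle = \frac{1}{n}\sum_i (D^2_{\phi,i} + D^2_{\psi,i})/2$.
The rendering of the window average is ambiguous about a square root
over $(D_\phi^2 + D_\psi^2)/2$; only the no-square-root reading attains
the stated maximum of 4 when every dihedral differs by 180°, so that is
the form implemented. `similarity_cdf()` turns a set of loop–fragment
distances into the empirical probability of finding a fragment within a
given distance. Windows are compared only at equal length (3 or 9 in
typical use).

## The synthetic-fixture generator

`make_fixture_antibody()` and `make_fixture_corpus()` generate
everything the test suite consumes. Backbones are idealized extended
traces built by sequential internal-coordinate placement (C–N 1.329 Å,
CA–C–N 116.2°, C–N–CA 121.7°, φ/ψ/ω = −139°/135°/180°), Chothia-numbered
with insertion codes assigned alphabetically at each loop's canonical
insertion position (L1 at 30, L2 at 52, L3 at 95, H1 at 31, H2 at 52,
H3 at 100) when a requested CDR length exceeds its numbered span, and
interior numbers skipped — with geometry kept continuous — when it is
shorter, as real short Chothia loops do. Glutamines are placed at
L38/H39 with side-chain amides constructed so both inter-chain
donor–acceptor distances equal the requested target exactly (default
2.91 Å). Defects are injected surgically so each trips exactly one
criterion: long bonds translate everything downstream of one link,
bad angles move a single backbone nitrogen within its bond length,
zero-occupancy flips one atom, missing residues are excluded at build
time (so their absence does not fabricate a geometry violation), and
scFv entries only alter the summary row. The default corpus seed is
20190215.

What the generator does **not** emulate: realistic immunoglobulin
folds, side chains beyond the two glutamines, alternate locations,
crystallographic artifacts, or the sequence statistics of real
antibodies (positions are uniform over the 20 standard residues, so
e.g. the proline filter fires far more often than on real CDRs).
Passing tests therefore demonstrate the correctness of the rules and
algorithms — range arithmetic, filter logic, constraint math, rigid
kinematics, metric formulas — not performance on real structural data,
which additionally depends on the upstream numbering and the realism of
crystal-structure geometry.

## Numerical choices and problem sizes

Degenerate inputs are rejected loudly (empty regions, zero-variance
fits, K > N, empty complexes); boundary cases are assigned
deterministically (QC bounds as printed: resolution strict, geometry
windows inclusive; flat-harmonic boundary in the zero branch; blank
insertion code sorts before "A"). Alternate-location atoms other than
blank/"A" are dropped at parse time for deterministic parsing.
Resolution comes from the summary table, never from REMARK records,
whose dialects vary. The scFv rejection rule is equality of the heavy
and light chain ids in the summary row — the one signal the
summary-driven pipeline can check without attempting to renumber a
fused chain.

The test suite runs on corpora of 3–20 synthetic structures (~220
residues each), 10⁴-sample parameter-recovery draws, and 6-mer
alignment oracles — sizes chosen so the full suite completes in about
two minutes while still exercising every rule on multiple seeds.

## Known limitations

* No mmCIF input, no symmetry expansion, no hydrogen handling, no
  renumbering: inputs must already be Chothia-numbered, as SAbDab-style
  pre-processing provides.
* Template selection stops at ranked hits; no coordinate grafting,
  side-chain packing or minimization.
* The kink constraint for CDR-H3 C-terminal geometry and the V~H~–V~L~
  orientation-distance metric are defined in prior work and are not
  reimplemented; the database stores the anchor coordinates needed to
  compute orientation metrics downstream.
* Fold trees model rigid-body semantics only — no torsion-space
  minimization or Monte Carlo moves.
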