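---
title: "Methods: quantifying steric constraint of CDR-H3 by the light-chain loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying steric constraint of CDR-H3 by the light-chain loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrcage)
```

## The scientific question

Antibody antigen binding is dominated by the six complementarity-determining
region (CDR) loops of the paired variable domains (V~H~ and V~L~), and above
all by the hypervariable heavy-chain CDR-H3 loop. The five remaining "minor"
loops are conformationally conservative — they fall into discrete canonical
forms — and they pack against CDR-H3 on all sides. `cdrcage` implements a
set of analyses built around one physical picture: the minor loops form a
steric *cage* around CDR-H3, and attributes of the light chain (subtype,
V-genes, canonical forms, loop lengths) reshape that cage and with it the
conformational space CDR-H3 can occupy. The package quantifies this picture
four ways:

1. **Packing geometry** — radial distribution functions (RDFs) and minimum
   heavy-atom distances between loop pairs across a structure set.
2. **Conformational diversity** — a length-independent pairwise comparison
   of CDR-H3 loops (anchor-superposed dynamic time warping), stratified by
   light-chain attributes, with bootstrap significance.
3. **Ensemble flexibility** — post-processing of biased (metadynamics-style)
   conformational ensembles: reweighting, per-loop RMSD/RMSF,
   native-conformation fractions, and frame clustering.
4. **Pairing evidence** — structure pairs sharing an identical V~H~ but
   divergent V~L~ sequences, asking whether V~L~ divergence predicts CDR-H3
   conformational change.

All coordinates are handled in an IMGT-numbered Fv model (both chains
numbered 1–128; CDR1 = 27–38, CDR2 = 56–65, CDR3 = 105–117, framework =
the remainder), which makes heavy- and light-chain loops directly
comparable.

## The crystal-set filter

`filter_crystal_set()` encodes the inclusion rules for building an analysis
set from crystal structures: X-ray entries only, resolution ≤ 3 Å, paired
heavy/light chains, no single-chain constructs, all six CDRs fully resolved,
then redundancy removal by greedy clustering of the concatenated Fv sequence
at 95% identity (cluster representatives are kept). Choices the rules leave
open were fixed as follows:

* *Unresolved loop* means any CDR residue missing one of the backbone atoms
  N/CA/C, or an empty CDR — the weakest reading that is testable from
  coordinates alone. Interior numbering gaps are not second-guessed, since
  the expected position set depends on the numbering tool's length
  assignment.
* Missing resolution metadata rejects the record (conservative).
* Alternate locations keep the highest-occupancy atom, ties resolved by
  file order; only the first H/L pair in file order is read.
* Rejections are data: the filter returns a per-rule log, and
  rejected + kept always sums to the input count. The filter is idempotent.

## Radial distribution functions

For a loop pair, all cross heavy-atom distances up to 10 Å are histogrammed
in 0.1 Å bins. Each bin count is normalized by the spherical-shell volume
$\tfrac{4}{3}\pi(r_2^3 - r_1^3)$ between its edges and by the number of
possible atom pairs $n_a n_b$. There is deliberately no unit-cell volume
term: the profiles are comparable *trends*, not absolute frequencies.
Per-structure densities are treated as independent samples and averaged
(weighted, when ensemble frames carry reweighting weights), with t-based
95% confidence half-widths; this per-structure averaging is what makes
confidence bounds meaningful. Two profiles are compared bin-by-bin with a
Welch (unequal-variance) two-sided t-test; bins with zero variance in both
groups return p = 1 when means agree. **Caveat:** the per-bin p-values are
raw — no multiple-testing correction is applied across the 100 bins, so
isolated marginal bins should not be over-read.

Contacts use the conventional 0–4.5 Å heavy-atom range, with the upper
bound closed (4.5 Å is a contact).

## Length-independent CDR-H3 comparison

CDR-H3 loops of different lengths cannot be compared by plain RMSD. The
package's measure first superposes the loops on their ten anchoring
framework residues (IMGT 100–104 and 118–122, backbone N/CA/C/O — anchors
must be complete or the loop is ineligible), then aligns residues by
dynamic programming over a residue–residue cost matrix, where
$\mathrm{cost}(i,j)$ is the summed squared deviation over the four backbone
atoms. The recurrence
$D(i,j) = \mathrm{cost}(i,j) + \min\{D(i-1,j), D(i,j-1), D(i-1,j-1)\}$
finds the optimal monotone path, and the distance is
$\sqrt{\text{total path cost} / (4 \times \text{path length})}$.

Numerical/design choices:

* **Equal-length short-circuit.** An unconstrained step pattern can undercut
  the diagonal even at equal lengths, which would break the property that
  the measure reduces to a conventional RMSD there. Equal-length pairs
  therefore bypass the dynamic program and return the anchored backbone
  RMSD exactly.
* The path-length normalization (and the 4 atoms/residue factor) is chosen
  precisely so that the equal-length limit is literal RMSD, in ångström.
* Backtrace ties prefer diagonal, then vertical, then horizontal steps;
  this affects only the reported path, never the cost.
* In a pairwise matrix the lower-index loop is superposed onto the
  higher-index one; symmetry of the resulting matrix is verified by test
  rather than assumed (it holds to 10⁻⁹).
* When every loop in a collection has the same length and bit-identical
  anchors (the synthetic population regime), superposition is the identity
  and the whole matrix is computed in one vectorized pass; the fast path is
  asserted equal to the per-pair route by test.

## Stratified bootstrap diversity

Diversity of a set of CDR-H3 loops is the mean of all pairwise DTW
distances. A stratum's effect is its percent change versus the whole-set
baseline (the baseline *includes* the stratum — the comparison is stratum
vs overall, not stratum vs complement). Significance: each bootstrap
replicate draws as many ids from the whole set as the stratum holds
(without replacement by default — a random pseudo-stratum; with-replacement
is an option) and recomputes the delta. The two-sided p-value counts
replicates whose *magnitude* reaches the observed one, with +1 smoothing:
$p = (1 + \#\{|\Delta^*| \ge |\Delta|\})/(1 + B)$, so p is never exactly 0
at finite $B$. A one-sided option is exposed. The default is
$B = 10{,}000$ replicates.

Because the replicate draws depend only on the matrix, the stratum size,
the seed and the replacement mode, they can be precomputed once and shared
across equal-sized strata (`bootstrap_null_deltas()`); the result is
bit-identical to per-stratum recomputation and makes large calibration
studies cheap. `diversity_report()` does this caching internally.

## Ensemble post-processing

Biased ensembles are unbiased by the time-independent reweighting
$w(s) \propto \exp\!\big(V(s)/k_B T\big)$, with $V(s)$ the deposited bias
(kJ/mol) and $k_B$ in kJ/(mol·K). The maximum bias is subtracted before
exponentiation (overflow safety); weights are invariant to constant bias
shifts and sum to 1.

Per-loop flexibility uses a per-frame series: each frame's flank backbone
(3 residues on either side of the loop, in IMGT chain order) is superposed
onto the reference frame's flanks, and the loop backbone RMSD versus the
reference is recorded. The reference is the first frame (the conformation
at the start of the simulation); an external crystal reference can be
supplied. From the series:

* **RMSF** is defined as the *weighted time average of the RMSD series* —
  not the crystallographic root-mean-square fluctuation. This matters when
  comparing numbers across tools.
* **Native fraction** is the total weight of frames within 1 Å of the
  reference (the conventional bound for calling two loop conformations the
  same).

Frame clustering superposes frames on the framework backbone — excluding
the first two framework residues of each chain's N-terminus, which are
disproportionately flexible — and measures the joint backbone RMSD over all
six CDRs (a per-loop feature is an option; the joint feature is what makes
cluster representatives whole-paratope conformations). Agglomerative
average-linkage clustering is cut at 1.25 Å; each cluster's representative
is its medoid. Merge heights are verified against a naive O(F³) linkage
oracle in the tests.

## The V~H~/V~L~ pairing analysis

Sequences are clustered greedily in cd-hit style: descending length, ties
by id, each sequence joining the first cluster whose representative
identity reaches the threshold. Identity is Needleman–Wunsch global
alignment (match +5, mismatch −4, gap opening 10, extension 1 per position)
with matches counted over the *shorter* sequence (cd-hit's denominator).
An exact composition bound (aligned matches cannot exceed the per-letter
count overlap) screens hopeless candidates before alignment — the same
idea as cd-hit's word filter, with no effect on results. V~H~ clustering at
threshold 1.0 groups identical-V~H~ antibodies; singleton groups are
dropped; within each group V~L~ sequences are re-clustered at 0.4 and every
within-subcluster pair with V~L~ identity below 99% is emitted.

For each pair, structure b is superposed on structure a using the
heavy-chain framework backbone, and backbone RMSDs are reported for
CDR-H1, CDR-H2, FW-H and CDR-H3 without re-superposition. Pearson
correlations (two-sided t-based p) relate V~L~ identity to each region's
RMSD, and a Mann–Whitney U test (exact for both groups ≤ 20 without ties,
normal approximation with tie correction otherwise) compares pairs whose
V~L~ canonical forms all match against pairs with at least one changed
form.

## What the synthetic generators emulate — and what they do not

The generators produce every input the pipeline consumes, with known
ground truth, and they are first-class tested code: the package's principal
test harness re-measures every planted quantity with the analysis modules.

* `make_fv()` builds an idealized Fv: full 93-residue frameworks per chain
  (so anchors and flanks always exist), six CDR arcs with controllable
  lengths (defaults H1:8, H2:8, H3:13, L1:7, L2:3, L3:9 residues, bracketing
  typical CDR lengths) and controllable minimum inter-loop distances
  (realized within 0.5 Å by iterative adjustment, measured with the
  package's own distance kernel). The five framework residues flanking each
  CDR sit adjacent to the loop base, as in a real chain — this keeps
  flank-based superposition free of long lever arms. Geometry is
  deliberately pseudo-physical: arcs with fixed intra-residue atom offsets
  and two pseudo-side-chain heavy atoms, not Ramachandran-valid backbones.
  The analysis layer consumes coordinates only, so geometric realism is
  unnecessary for correctness testing — but it also means passing tests
  say nothing about force-field energetics or real loop shapes.
* `make_ensemble()` switches CDR-H3 between up to four template
  conformations (rigid translations along equal-separation directions, so
  inter-template loop RMSD equals the requested separation exactly) with
  Gaussian jitter everywhere. States are sampled uniformly — the flat
  landscape of a converged metadynamics run — and each frame carries the
  bias $V_k = \max(F) - F_k$ for planted free energies
  $F_k = (k-1)\cdot\text{bias\_strength}$, so reweighting must recover
  Boltzmann populations. Frame 1 is forced to state 1, the reference
  "crystal" conformation. A warning fires when separation < 3× jitter
  (states not separable at the 1.25 Å cutoff). Note that flank-based
  superposition amplifies positional jitter somewhat (the loop apex is far
  from the flanks), so native-fraction readouts against a 1 Å cutoff are
  cleanest at jitter ≲ 0.2 Å.
* `make_loop_population()` plants per-stratum diversity offsets by scaling
  stratum-specific Gaussian backbone perturbations around a common base
  loop with shared anchors, calibrating scales against the package's own
  DTW matrix until realized deltas are within 1 percentage point of their
  targets. Deltas can only be planted on a *subset* of strata: within- and
  cross-stratum pair means must average to the baseline, so targeting every
  stratum simultaneously is over-constrained in general; untargeted strata
  absorb the remainder. Unreachable plantings raise an error rather than
  silently drifting.
* `make_pairing_cohort()` builds identical-V~H~ families whose V~L~
  sequences differ by substitutions at disjoint positions; pair identities
  are *measured* with the package's aligner (at low identity a gapped
  alignment can legitimately beat the substitution diagonal, and ground
  truth must be what the analysis will see). CDR-H3 displacements are pure
  loop translations at fixed framework, so the realized pair RMSD equals
  the planted magnitude up to a small 0.05 Å jitter. The correlation
  between V~L~ identity and displacement is drawn at the requested value;
  in the `effect = "forms"` mode the displacement depends only on a
  canonical-form flip whose probability falls with identity, so the
  correlation is routed entirely through forms and must vanish within the
  forms-equal subgroup.

Every generator is a pure function of its spec including the seed.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| RDF bin width / range | 0.1 / 10 | Å | packing histograms |
| contact cutoff | 4.5 (closed) | Å | heavy-atom contact |
| DTW anchors | IMGT 100–104, 118–122 | — | loop superposition |
| loop flanks | 3 | residues | per-loop RMSD alignment |
| native cutoff | 1.0 | Å | same-conformation bound |
| cluster cutoff | 1.25 | Å | average-linkage flat cut |
| bootstrap replicates | 10,000 | — | stratum significance |
| redundancy threshold | 95 | % | crystal-set filter |
| V~H~ / V~L~ cluster thresholds | 1.0 / 0.4 | fraction | pairing analysis |
| pair identity bound | < 99 | % | divergent-V~L~ pairs |
| temperature | 300 | K | reweighting |

## Problem sizes in the shipped checks

The test suite and the acceptance script run everything at desk scale, as a
deliberate design choice: DTW oracles at loop lengths ≤ 6 against full path
enumeration; bootstrap calibration on a 500-structure matrix with 1,000
shuffled strata at 2,000 replicates; detection runs on 1,000-structure
matrices with a 100-member stratum compacted by 10%; ensembles of a few
hundred frames; pairing cohorts of 86 families at the planted correlation
−0.49 (and 250-family cohorts for the forms-routing check); reweighting
toys at 10⁵ frames. These sizes give the statistical checks enough power
to be meaningful while keeping a full run in minutes.

## Known limitations

* The RDF confidence bands assume per-structure independence; structures
  from related antibodies are correlated, so real-data bands are somewhat
  optimistic. No multiple-testing correction across bins or strata.
* The DTW step pattern and normalization are declared here, not canonical;
  other normalizations exist and give different absolute distances (the
  equal-length limit is the anchor to compare against).
* RMSF is a weighted mean RMSD, not the crystallographic RMSF.
* Greedy identity clustering at threshold 1.0 groups identical sequences
  (up to shorter-sequence containment); it does not reproduce every
  behaviour of word-filtered heuristic clusterers on length variants.
* The synthetic generators validate correctness of the computations; they
  do not validate biological conclusions on real structures, which require
  real coordinate sets and numbering.
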