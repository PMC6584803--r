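---
title: "Methods: antibody-hemichannel contact analysis, epitope mapping and selectivity prediction"
author: "connexitope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antibody-hemichannel contact analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connexitope)
```

## The scientific problem

Connexin hemichannels are hexameric plasma-membrane channels built from six
connexin protomers (P1-P6). Hyperactive ("leaky") hemichannels underlie a
group of pathologies, and the human-derived antibody abEC1.1 inhibits
hemichannels by binding their extracellular vestibule. This package
implements the computational analysis pipeline around that system:

1. **Contact statistics** — from a frame series of an antibody-hemichannel
   complex, the *interaction probability* of each residue pair: the fraction
   of analyzed simulation time in which the pair's minimum inter-atomic
   distance is below a fixed threshold, expressed as a percentage.
2. **Epitope mapping** — the antibody's footprint on the channel (residues
   above a probability cutoff), per-protomer binding maps, and the binding
   stoichiometry (6 protomers : 2 antibodies, symmetric about the pore
   axis, in the reference system).
3. **Pose filtering** — a reproducible surrogate for the manual selection of
   docking poses in which the three heavy-chain CDRs face the EC1 loops.
4. **Motif conservation scanning** — extraction of the epitope motif (EC1
   residues 54-58 plus EC2 residues 175-176, hCx26 numbering) from each
   member of the human connexin family, and a binary selectivity
   prediction: an identical motif predicts inhibition, any mismatch
   predicts weak or no inhibition.
5. **Electrophysiology validation** — residual hemichannel conductance
   (post-antibody conductance as % of control) from whole-cell current
   recordings, and concordance between motif predictions and measured
   inhibition.

The source trajectory and the raw patch-clamp recordings behind the
published per-residue probabilities and residual conductances are not
publicly deposited, so they are *not* recomputed here. Instead they ship as
transcribed reference tables (`cx_channel_contact_table()`,
`cx_antibody_contact_table()`, `cx_conductance_table()`,
`cx_motif_table()`), and every algorithm is validated on synthetic data
with known ground truth.

## The interaction-probability statistic

For residues $a$ (channel side) and $b$ (antibody side) with atom
coordinate sets $A_f$, $B_f$ in frame $f$, the pair is *in contact* in
frame $f$ iff

$$ d_f(a,b) \;=\; \min_{x \in A_f,\; y \in B_f} \lVert x - y\rVert \;<\; \theta, $$

with $\theta = 2\,$Å by default. The inequality is strict: a distance
exactly equal to the threshold is non-contact. The pair-level interaction
probability over $N$ frames is $100 \times N^{-1}\sum_f \mathbf{1}[d_f <
\theta]$ percent. The residue-level probability of $a$ against an antibody
is the frame-wise **union** over all of $a$'s pairs with that antibody's
residues — the fraction of frames in which *any* such pair is in contact.
Union is the only aggregation consistent with per-residue values that are
never smaller than any member pair's value, which the reference tables
exhibit (e.g. residue values of 100% alongside partial pair contacts).

Three points deserve justification:

- **Atom selection.** At a 2 Å threshold, inter-residue contact is only
  physically attainable between an acceptor/donor heavy atom and a
  *hydrogen*; a heavy-atom-only criterion would almost never fire at 2 Å.
  The default `atom_mode = "all"` therefore retains hydrogens when present;
  `"heavy"` and `"calpha"` modes are available for coarser data. No mode is
  asserted to be "the" published choice, which is unstated.
- **Frame times.** Multi-model PDB and XYZ frame series carry no time
  metadata, so `read_trajectory()` requires a stride (ns) and assigns
  `time = model index x stride`. Window selection (e.g. the last 10 ns of a
  150 ns run, `window = c(140, 150)`) is a closed interval and idempotent.
- **Neighbour search.** Candidate residue pairs are enumerated with a grid
  (cell-list) prefilter whose results provably equal the exhaustive
  enumeration; the per-pair minimum distance has both an exhaustive and an
  exact grid implementation, cross-checked against an independent
  brute-force oracle in the test suite.

## Synthetic data: what it emulates, and what it does not

All generators are seed-deterministic (`set.seed` under a restored RNG
state; identical seeds give bit-identical output).

`build_toy_complex()` places `n_protomers` (default 6) protomer chains with
cyclic symmetry about the z axis. Each protomer carries EC1 residues 54-58
and EC2 residues 172-179 at the extracellular top; each antibody entity has
heavy- and light-chain chains with CDR1/2/3 and constant regions. Residues
are minimal stacks of 3 pseudo-atoms (1.5 Å spacing): the design goal is
*controllability* — ground-truth contacts exact by construction, brute-force
oracles cheap — not realism. Each target protomer in the contact map
receives one designated CDR/loop residue placed 1.2 Å above its EC1 apex;
all other antibody atoms stay ≥ 6 Å from the channel, so a 2 Å contact
analysis of the built coordinates recovers exactly the requested protomer
sets.

`simulate_contact_trajectory()` realizes a per-pair contact schedule: in
each frame the mobile (antibody-side) residue of a scheduled pair is rigidly
translated so its minimum distance to the partner is exactly 1.5 Å
(contact) or 6 Å (apart), according to a Bernoulli draw at the target
fraction or a two-state Markov chain with stationary fraction equal to the
target and a configurable mean contact dwell (default 50 frames). The
Markov model produces bursty contacts whose estimates remain unbiased but
carry inflated variance — the realistic failure mode of short-trajectory
contact statistics.

What the toy data does *not* model: real side-chain geometry and packing,
correlated motions between pairs, solvent, force-field energetics, and
gradual distance distributions around the threshold. Tests passing on this
generator therefore establish the *estimator's* correctness (counting,
aggregation, thresholds, windowing), not the physical fidelity of any
particular simulation.

Default study conditions mirror the reference system: 6 protomers, 2
antibodies, contact map AB1 → P1-P4 and AB2 → P4, P5, P6, P1; 5000-frame
runs for rate estimation; generating rates taken from the bundled reference
tables (e.g. 0.82 for P1-EC1 Asn54, 0.98 for LC Thr182).

## Epitope footprints and stoichiometry

A footprint collects channel residues whose residue-level probability
against one antibody exceeds the cutoff (default 55%, strict `>`, per the
reference analysis; an inclusive mode is a flag). On the bundled channel
table this yields EC1 residues 54-58 and EC2 residues 175-177 across
protomers — the published epitope.

"Symmetric configuration relative to the pore axis" is operationalized as:
the two footprints' protomer sets are images of each other under rotation by
half the ring (3 positions on a hexamer). This is exact diametric symmetry;
it is only defined for exactly two non-empty footprints on an even ring and
reported `FALSE` otherwise. The reference arrangement
({P1,P2,P3,P4}, {P4,P5,P6,P1}) is symmetric under this test, shares the
diametrically opposed pair {P1, P4}, and is summarized as 6:2.

## Pose filtering

The published selection ("the only pose of 50 in which the three heavy-chain
CDRs face EC1") was a visual judgement. The surrogate here is, per CDR, the
conjunction of:

- **proximity** — some CDR x EC1 residue pair has minimum distance below
  8 Å (configurable); and
- **orientation** — the CDR centroid is nearer the EC1 centroid than the
  whole antibody's centroid is.

A pose is retained iff all three heavy-chain CDRs pass (an any-CDR mode is
a flag). The criterion is deterministic, permutation-invariant, and
validated on labelled synthetic pose sets; it is *not* claimed to reproduce
the authors' manual choice on their unavailable pose set.

## Motif scanning and selectivity

Epitope positions are transferred from the hCx26 reference onto each family
sequence by global Needleman-Wunsch alignment (BLOSUM62, gap open 10, gap
extend 0.5 — standard protein defaults, configurable and recorded).
Positions aligned to gaps are flagged "unalignable", never silently
dropped. The motif is the concatenation of EC1 54-58 (5 residues) and EC2
175-176 (2 residues); classification is position-wise identity over those 7
residues, and the prediction is deliberately binary (identical → inhibited;
otherwise → not or weakly inhibited) with no attempt to grade partial
mismatches. The bundled family table records, as annotations only, (i) the
note that hCx30's residue at position 177 is a Leu contacting the antibody
through main-chain atoms, and (ii) the naming discrepancy between the motif
table's "hCx30.2" (gene printed *GJG3*) and the functional data's
"hCx30.2/31.3" (*GJC3*); the concordance join resolves the latter through
an explicit alias map (`cx_isoform_aliases()`).

The family fixture sequences are **synthetic**: a fixed 200-residue
scaffold carrying each isoform's printed motif at the hCx26-numbered
positions. Three isoforms carry small indels away from the motifs
(N-terminal extension, internal deletion, internal insertion) so the
alignment-based mapping is exercised on shifted coordinates. True
full-length connexin sequences are not bundled and not required: only the
motif positions carry information.

## Conductance analysis

Membrane conductance is the mean current over the depolarizing step window
divided by the driving voltage (command minus reversal potential), in nS
(pA/mV); the command voltage must be constant over the window. Residual
conductance is $100 \times G_{\mathrm{post}} / G_{\mathrm{pre}}$, which is
scale-invariant in the current units. Leak subtraction is optional and uses
a blocked-condition recording (hemichannels blocked with divalent cations)
measured on the same window. Tail-current analysis is not implemented; the
step window (+40 mV depolarization) is the measurement convention
throughout.

The inhibition cutoff for the concordance check is 50%. The measured
residuals split bimodally (16-25% for inhibited isoforms vs 73-98% for the
rest), so any cutoff in (25, 73) yields the same classification; 50% is the
midpoint convention, not a fitted value.

## Numerical choices and degenerate inputs

- Strict `<` at the contact threshold; ties are non-contact.
- Residue identity is (chain, author residue number, insertion code);
  renumbering never happens silently. Insertion-coded residues are distinct.
- Probabilities are kept at full precision internally; rendered tables
  round to integer percent.
- Zero-frame trajectories, empty atom selections, empty time windows,
  unmapped chains, duplicate protomer labels, cutoffs outside [0, 100],
  non-positive control conductance, and empty prediction/measurement joins
  are all explicit errors (or explicit "undefined" reports), never silent.
- The grid minimum-distance search expands cell shells until the best
  distance found is provably optimal, so it equals the exhaustive scan
  exactly, including degenerate all-points-in-one-cell layouts.

## Problem sizes

The shipped analyses and tests run at deliberately desk-scale sizes chosen
to keep every oracle brute-forceable: toy complexes of 672 atoms (6
protomers + 2 antibodies) or 336 atoms (trimer variant), trajectories of
up to 5000 frames for rate recovery (binomial standard error at p = 0.82,
n = 5000 is 0.54 points) and 100-300 frames for exact-recount checks, 50
poses per filtering run, and 100-seed replicate sweeps for the recovery
property. These sizes are the package's validation conditions, not limits
of the implementation.

## Known limitations

- The contact statistic treats frames as the unit of evidence; no
  autocorrelation correction is applied (the Markov generator exists
  precisely to quantify that inflation).
- The pose "facing" criterion is a geometric surrogate; against other pose
  generators its 8 Å default may need adjustment.
- Selectivity prediction is binary by design and ignores chemistry-aware
  similarity between motif residues.
- The synthetic scaffold makes alignment-based position mapping nearly
  trivial by construction; mapping accuracy on genuinely divergent connexin
  sequences is not established here.
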