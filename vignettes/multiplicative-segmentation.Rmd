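---
title: "The multiplicative segmentation model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multiplicative segmentation model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(millisplit)
```

# The model

The multiplicative model of millipede trunk segmentation holds that the
ventral trunk is not specified one segment at a time. Instead, a small
number of embryonic *primary segments* each subdivide through `k` cycles
of binary splitting into `2^k` definitive ventral units (leg-pair
positions). `millisplit` implements this as a purely combinatorial
process — there is no spatial or continuous tissue model, and no claim
about the molecular identity of the hypothesized markers.

A `splitting_spec(k, P, t, markers, anterior_marker_positions,
taxon_profile)` fixes:

* `k` — splitting cycles per primary segment; the module width is `2^k`
  leg pairs. The julidan default is `k = 4` (16-unit modules), the
  polydesmidan default `k = 2` (4-unit modules), reflecting the much
  smaller trunks of polydesmidans.
* `P` — the number of *realized* primary segments. Trunk regions beyond
  the modeled anterior part are simply outside the grid; the posterior
  primary-segment count is left open by the theory and is not a model
  parameter.
* `t` — anterior truncation, in virtual leg-pair positions of primary
  segment 1 (`0 <= t < 2^k`). The splitting pattern is stereotyped but
  clipped anteriorly, where the collum and the three one-pair rings
  develop; `t` registers the dyadic grid against the leg-pair axis, so
  the realized trunk carries `L = P * 2^k - t` leg pairs.
* `markers` — *early* posterior-gonopod markers. Each sits on a node
  `(depth, index)` of a primary segment's splitting tree and is
  inherited by that node's block of `2^(k - depth)` leaves
  (`leaf_interval()`). This encodes marker extent purely by tree
  address: there is no graded abundance scalar.
* `anterior_marker_positions` — the *late* anterior-gonopod marker,
  addressed by global leg-pair position, applied after the splitting of
  the relevant region is complete. It overrides the early marker where
  both apply, which is why it is modeled as a position, not a node.

Coordinates are chosen to keep the dyadic arithmetic clean while matching
how positions are counted in specimens: leg pairs are 1-based and exclude
the collum; within-module offsets are 1-based; node indices are 0-based.
The collum is deliberately *not* a leaf of the splitting grid. Whether it
consumes a leaf of primary segment 1 is not decidable from the available
descriptions, and keeping it a body-plan element only leaves `t` a single
well-defined integer.

## The anchors t = 5 and t = 0

The julidan default `t = 5` is derived, not observed. The homeotic
*Ommatoiulus* pattern (gonopods at pairs 8–11 and 24–27) constrains the
anchor to `t ≡ 1 (mod 4)` within a 16-unit grid; among the four candidate
registrations (t = 1, 5, 9, 13, putting the marked block at nodes (2,2),
(2,3), (2,0), (2,1) respectively) only `t = 5` places the marked block on
the *posterior* quarter of its module, as expected if markers are
inherited by a posterior subset of a primary segment's products. Under
this anchor the normal gonopod pair 8–9 sits at offsets 13–14 — node
`(3,6)`, inside but not at the posterior edge of the posterior quarter.
That wrinkle is a real, unresolved feature of the model, not of the
implementation. The polydesmidan default `t = 0` puts primary segments in
register with leg pairs 1–4, 5–8, 9–12, and the *Nannaria* gonopods on
the posterior leaf `(2,3)` of three consecutive modules.

# The fitting procedure

`dyadic_fit(G, k)` asks whether a gonopod position set `G` is explainable
as **one** early marker event. It searches exhaustively over anchors
`t ∈ [0, 2^k)`; each position maps to module
`m = (p + t - 1) %/% 2^k + 1` and offset `o = (p + t - 1) %% 2^k + 1`,
and a candidate is feasible iff all occupied modules carry one identical
offset set, that set is the leaf interval of a single dyadic node, and
the occupied modules form a contiguous block. Every feasible fit is
verified by regeneration: simulating the fitted specification must
reproduce `G` exactly, and this check is wired into the operation itself.

**Tie-breaking.** A feasible pattern never identifies `(t, node)`
uniquely: shifting the anchor by the node width and sliding the node
index produce the same positions. The fit prefers, in order: minimal node
depth (the most parsimonious single marker — one broad inheritance rather
than an improbably aligned deep one), then the most *posterior* node
index (the posterior-subset inheritance expectation above), then the
smallest anchor. This ordering reproduces the homeotic julidan fit
(t = 5, node (2,3), primary segments 1–2) and the *Nannaria* fit (t = 0,
node (2,3), segments 1–3). For patterns confined to a single module —
e.g. the normal male's pairs 8–9 — the free-anchor fit is intrinsically
underdetermined, and the posterior preference lands on node `(3,7)` at
t = 7. When the grid registration is known, pass it: with
`anchor = 5` the normal pattern fits at node `(3,6)`, the reading used
for the julidan default spec. Tests of parameter recovery therefore
check the free fit by regeneration (anchor-equivalence class) and the
anchored fit by exact `(node, block)` identity.

**Costs.** `multiplicative_cost` is 1 for a feasible single-event fit;
otherwise it is the minimal number of anchored (node, contiguous-block)
marker events whose union is exactly `G`, found by exact search over
inclusion-maximal events (any event is a subset of a maximal one, so the
restriction loses nothing). `sequential_cost` is the number of maximal
contiguous runs — the most charitable concrete reading of a sequential
determination model, where each run is one independent event. The
comparison is parsimony in marker events, not a likelihood: the theory
under test offers no stochastic model, so no analytic hypothesis test is
attempted.

**Verdicts.** `compare_models()` scans `k = 1..6` by default (nothing in
the observed material constrains `k` above 4; 6 is a safety margin) and
reports `multiplicative-consistent` only when some `k` admits a feasible
single-event fit spanning more than one primary segment *and* the run
spacing is a power of 2. Single-run patterns fit trivially inside one
module at any `k` and are flagged `uninformative-one-run` — contiguous
extensions of the normal gonopod field (the *Pseudoeurydesmus* and
Madeira-type cases) carry no evidence about segmentation mechanisms.
Exact-match fitting is the default (`max_mismatch = 0`) because the
pattern argument is exact; a tolerance mode exists for exploring
near-miss patterns but plays no part in the reported classifications.

# The body plan

`build_ring_map(L, fusions)` lays out the standard trunk: collum (ring
1), three haplosegmental rings (2–4, leg pairs 1–3), then diplosegments
(ring `r >= 5` carrying pairs `2r - 6` and `2r - 5`). Fusions merge two
adjacent diplosegment positions into one physical ring with four leg
pairs. Both numberings — comparative (normal-specimen-equivalent) and
physical (count along the animal) — are carried everywhere and printed
together, because specimens with fusions are described in comparative
terms. Apodous rings and the telson are not modeled (the key specimen
has none); a trailing odd leg pair gets a final ring flagged
`incomplete`. The dorsal–ventral decoupling of millipede segmentation
enters only as this fusion mechanism: whether a fused ring is better
modeled as a truncated dorsal splitting product is left open by the
available evidence, and the package does not take a side.

# Encoded specimens

`fixtures()` ships six phenotypes. The homeotic and normal *O. moreleti*
are encoded at full trunk length (46 podous rings, hence
`L = 3 + 43 × 2 = 89` leg pairs); positions behind pair 27 are
walking-leg defaults annotated `default_low_confidence`, since only the
anterior region is described appendage by appendage. The polydesmidan
cases are encoded at `L = 31` (a typical adult polydesmidan trunk) and
the Madeira specimen at `L = 27` (the described anterior region): none of
these sources print ring counts, and only the anterior positions matter
for inference. Asymmetric transformations are encoded per side; a
position counts as gonopod-bearing if either side is transformed, with a
`bilateral_only` toggle, and whether the normal pairs 8–9 belong to the
pattern under explanation or to the baseline is exposed as the
`baseline` argument rather than decided once. Gonopod substructure
(reduced solenomerites, paracoxite states) is carried as free-text
annotation only.

# The synthetic experiment

The model-comparison argument is qualitative in origin; the synthetic
layer turns it into a measurable discrimination problem.

* `gen_multiplicative()` draws a node (depth uniform on `1..k`, index
  uniform at that depth) and a contiguous primary-segment block (uniform
  over all blocks), on the julidan grid `k = 4, P = 2, t = 5` by
  default. Draws whose marker block would be clipped by the anterior
  truncation are rejected and redrawn: a clipped pattern's parameters are
  unrecoverable in principle, so they are not part of the recovery
  claim. Depth 0 (a whole-module marker) is excluded from the random
  draw because adjacent whole-module blocks merge into a single run and
  carry no spacing signal.
* `gen_sequential()` places a configured number of runs (default 2,
  lengths uniform on 1–4, trunk `L = 27` — the modeled anterior region)
  uniformly at random, non-overlapping and non-adjacent so each run
  stays maximal.
* Noise imitates the observed teratologies: `p_asym` reverts one
  uniformly chosen side of a transformed position to a walking leg (the
  literature's unilateral cases), `p_atrophy` atrophies walking-leg
  positions. Noise never adds gonopods. All distributions are uniform —
  the theory specifies none, so uniform is the declared default rather
  than a tuned choice.
* Randomness: every generator derives its stream from a single root
  seed (kept below 2^31), and identical configurations yield
  byte-identical phenotype files.

`discrimination_experiment()` reports, per regime, the fraction of
informative replicates (at least two runs) classified
multiplicative-consistent: the recovery rate for multiplicative data
(1.0 without noise, by the ground-truth closure property) and the
false-positive rate for sequential data. The false-positive rate is not
negligible — two runs of width 1–2 land on a dyadic translate reasonably
often — which is itself informative: the strength of the observed case
lies in *two* independent powers-of-2 coincidences (run width 4 and
displacement 16) plus the repeat of the same effect at a different power
in a different taxon. `enumerate_two_run_rate()` computes the exact
two-run rate by exhausting all placements at small `L`, and the test
suite requires the Monte-Carlo estimate to agree with it within a
binomial 99% interval.

# Numerical choices and problem sizes

Everything is integer combinatorics; there are no tolerances to tune.
Degenerate inputs are kept legal where the model allows them (a
one-unit trunk builds a one-ring map; an empty gonopod set decomposes
into zero runs) and rejected with named bounds where it does not
(`t >= 2^k`, nodes outside `[0, 2^depth)`, fusions touching the collum
or haplosegmental rings). Markers falling entirely into the truncated
region warn rather than error: a marker with no phenotypic effect is a
meaningful model state.

The test suite exercises the fitting layer against brute-force oracles
(full enumeration of anchor–node–block triples for `k <= 3`, naive
subset enumeration for the event cover), 500 seeded recovery replicates,
and a 400-replicate Monte-Carlo check against the exact two-run
enumeration at `L = 24`; the whole suite runs in well under five minutes
on one CPU. These sizes are the package's own choice of desk-scale
reproduction: the combinatorial claims are exact, so scale buys
confidence in the stochastic layer only.

# Limitations

The package models pattern, not process: no tissue growth, no moulting
schedule (the moult-batch alternative explanation requires developmental
tables that are not available in usable form), no evolutionary dynamics
of segment number, and no molecular identity for either marker. The
synthetic generators emulate the *combinatorial* structure of the two
regimes and the gross form of the observed noise (unilaterality,
atrophy); they do not emulate graded gonopod reduction along the trunk,
left–right phase shifts, or correlated anomalies, so a high recovery
rate on synthetic data bounds only the combinatorial part of the
argument. Conclusions about real specimens rest on the exact fits, which
are deterministic and checked by regeneration.
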