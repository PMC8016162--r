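---
title: "poreflow: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{poreflow: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreflow)
```

This vignette documents the methods implemented in poreflow and the
conventions they follow, in the order the analysis pipeline applies
them.

## Input handling

Structures are read from PDB through `read_structure()` (backed by
bio3d, with additional validation: malformed records, insertion codes
and duplicate `(chain, residue, atom)` entries are errors rather than
silently tolerated). Trajectories are CHARMM-style DCD via
`read_trajectory()`; atom-count mismatches against the structure and
truncated files are errors. XTC is deliberately not supported — no
installed parser decodes its compressed-coordinate format reliably —
and `.xtc` input raises a clear error asking for conversion to DCD.

Derived per-frame quantities move through `feature_table()` objects
(first column `time_ns`, strictly increasing) with plain-CSV round
trips, and replica metadata through a YAML registry
(`load_replica_registry()`), which validates required fields per run.

## Featurization

The selectivity-filter selection (`sf_selection()`) names the four
P-loops by chain and first motif residue. `extract_sf_dihedrals()`
computes, per frame, the backbone φ/ψ of the five motif residues and
the threonine χ1 of each P-loop (44 angles total), with the IUPAC sign
convention and range (−180°, 180°]. Coincident or collinear consecutive
atoms make a dihedral undefined and raise an error. For distance-based
methods in angle space, `sincos_expand()` maps each angle to its
sine/cosine pair; alternatively the embedding can use the per-coordinate
wrapped ("periodic") metric directly.

## Sketch-map embedding

`sketchmap_embed()` implements sketch-map in three stages:

1. **Landmark selection** — farthest-point sampling
   (`select_landmarks()`): a seeded random first frame, then frames
   maximizing the minimum distance to the chosen set.
2. **Landmark optimization** — the stress
   $\chi^2 = \sum_{i<j} [F(R_{ij}) - f(r_{ij})]^2$ is minimized by BFGS
   with analytic gradients from a classical-MDS initialization, with
   seeded jittered restarts. $F$ and $f$ are the sigmoid
   $s(r) = 1 - (1 + (2^{p/q}-1)(r/\sigma)^p)^{-q/p}$ with
   high-/low-dimensional exponent pairs $(A, B)$ and $(a, b)$; $s$ is 0
   at 0 and exactly 1/2 at $r = \sigma$, so distances near $\sigma$ are
   preserved while shorter ones contract and longer ones saturate.
3. **Out-of-sample projection** — every non-landmark frame minimizes
   its single-point stress against the fixed landmarks
   (`project_out_of_sample()`): a coarse grid scan over the landmark
   bounding box (landmark positions included as candidate starts)
   initializes a vectorized damped Gauss–Newton refinement. Frames
   whose features exactly duplicate a landmark take that landmark's
   coordinates directly, so the embedding is consistent and fully
   deterministic given its inputs.

The characteristic length `sigma`, the exponents, the landmark count
and the DBSCAN scale below are analysis settings expressed in the units
of the chosen feature space and metric; the defaults in
`sketchmap_params()` and the pipeline configuration are tuned to
degree-valued dihedral features under the periodic metric. `pca()`
(column-centered SVD) is available as the linear baseline.

## State discovery and labeling

`dbscan_cluster()` is a standard sequential DBSCAN (a core point has at
least `min_points` neighbors within `eps`, counting itself; border
points join the first cluster that discovers them), with an `eps`-grid
spatial index so region queries scale to large maps, and an optional
analysis window outside of which frames are pre-labeled noise. The
`eps`/`window` values are in map units — the low-dimensional scale set
by the embedding — not in the units of the input features.

Filter conformations are labeled geometrically: `classify_flips()`
calls a motif carbonyl *flipped* when the inward radial cosine — the
cosine between the in-plane component of the C→O vector and the
in-plane unit vector from C toward the pore axis — is strictly
negative. Each frame gets a canonical flip-signature string
(`signature_string()`), e.g. `"A|S4-S3+C|S3-S2"`. `label_states()`
gives each DBSCAN cluster the modal signature of its member frames
(ties prefer fewer flips, then lexicographic order) and maps signatures
onto the recurrent-state vocabulary I, II, II′, III–VII (with `other`
for noise and unrecognized signatures): I is the native filter, II/II′
single S4–S3 flips distinguished by chain adjacency, III a single
S3–S2 flip, IV a single S2–S1 flip, V–VII multi-flip combinations.
`population_table()` turns labeled conditions into relative-population
rows summing to 100%.

In the synthetic pipeline the per-frame signatures come from the
generator's per-state signature table — the state path is the planted
ground truth — while the geometric classifier is validated separately
against `build_filter_coordinates()`, which plants flips in an
idealized filter geometry.

## Permeation and conductance

`detect_events()` runs a three-region state machine (below / inside /
above the filter, `filter_bounds()`) per ion: an event completes at the
first frame on the far side after entering from the near side;
excursions that return do not count; a within-interval jump across both
bounds counts as a pass-through. Conduction for conductance purposes is
the outward (direction +1) event count. When a water trace is present,
events are additionally gated on the first frame the filter empties of
water (`water_occupancy()`, `filter_events_after_water_exit()`).

`replica_conductance()` converts counts to conductance,
$G = N e / (T \Delta V)$, and `aggregate_conductance()` averages
replicas with the sample (n−1) standard deviation, printing one-decimal
half-up-rounded summaries. `constant_field()` gives the uniform-field
strength $\Delta V / L_z$ corresponding to an applied potential.

## Gating and lipids

`interface_distances()` measures per-frame distances between reference
atom pairs of the two TM2–TM4 interfaces. `classify_updown()` applies
the 8 Å threshold (strictly greater is *down*) and calls a state
prevalent only if it holds strictly more than 50% of frames;
`count_transitions()` counts debounced up↔down switches and
`distribution_mode()` reports KDE modes of the distance distribution.
`lipid_cavity_flag()` applies the analogous strict rule for lipid
penetration: in-plane headgroup distance strictly below 10 Å for
strictly more than half the frames. `lipid_atom_profile()` profiles the
standard phosphatidylcholine reference atoms
(`lipid_reference_atoms()`).

## Synthetic generators

Every analysis stage has a seeded generator with exact planted truth:
`build_filter_coordinates()` (idealized filter geometry with chosen
carbonyl flips), `simulate_dihedral_series()` (continuous-time Markov
state path with von Mises angle emissions), `simulate_ion_traces()`
(confined diffusion plus a chosen number of complete outward
crossings), `simulate_gating_trace()` (telegraph process around the up
and down distance means) and `simulate_lipid_trace()` (an exact
fraction of frames inside the cavity). `write_synthetic_replica()`
bundles them into the replica directory layout `run_pipeline()`
consumes, with a `truth.json` sidecar.

## Reproducibility

All stochastic steps take explicit seeds; reports embed the seed, a
configuration fingerprint and the package version, and rerunning an
identical configuration reproduces reports byte for byte.
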