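---
title: "Thermal titration scoring of docking poses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal titration scoring of docking poses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Docking programs are good at generating plausible protein-ligand binding
poses and notoriously mediocre at deciding which of them is the native
one. A physically motivated tiebreaker is *persistence*: the native
binding mode, being the free-energy minimum, should survive thermal
stress longer than a decoy. `ttmd` implements a thermal-titration
protocol around this idea: a pose is subjected to a series of dynamics
windows at progressively increasing temperature, each window is scored
for how much of the pose's native interaction pattern survives, and the
decay of that score over the ramp is condensed into a single number, the
MS coefficient, used to rank poses (lower = more persistent = more
native-like).

```{r, eval = FALSE}
library(ttmd)
```

## The interaction fingerprint and IFP_CS

The score is built on a per-residue interaction fingerprint. For a
complex with `r` protein residues, each frame is encoded as an integer
vector of length `r * 8`: residue `i`, class `c` occupies slot
`(i - 1) * 8 + c`, and the value counts the detected instances of that
class on that residue. The eight classes, in fixed slot order, are
hydrophobic contact, aromatic face-to-face, aromatic edge-to-face,
hydrogen bond (protein donor), hydrogen bond (protein acceptor), salt
bridge (protein positive), salt bridge (protein negative), and metal
ionic coordination.

A frame is scored against the reference complex (the pose being tested,
at its equilibrated starting geometry) by

$$\mathrm{IFP\_CS} = -\cos(\mathbf{f}_{\mathrm{ref}}, \mathbf{f}_{\mathrm{frame}})
  = -\frac{\mathbf{f}_{\mathrm{ref}} \cdot \mathbf{f}_{\mathrm{frame}}}
          {\lVert\mathbf{f}_{\mathrm{ref}}\rVert\,\lVert\mathbf{f}_{\mathrm{frame}}\rVert},$$

so IFP_CS ranges from $-1$ (the frame reproduces the native interaction
pattern exactly, up to a positive scaling) to $0$ (no reference feature
survives). An all-zero frame fingerprint is assigned similarity 0 by
convention — a fully dissociated ligand shares nothing with any
reference — which makes the early-termination test below exact. An
all-zero *reference* is an error: a pose with no detectable native
interactions cannot anchor a titration.

Fingerprints are occurrence counts rather than binary bits: one instance
per qualifying atom pair or ring pair. Counts preserve the weight of
residues that make several simultaneous contacts, which binary encoding
discards; either convention yields the same $[-1, 0]$ score range.

### Geometric detection rules and thresholds

Detection uses conventional interaction-fingerprint geometry (defaults
frozen in `geometry_config()` for reproducibility; all configurable):

| parameter | default | meaning |
|---|---|---|
| `hydrophobic_dmax` | 4.0 Å | hydrophobic heavy-atom pair distance |
| `hbond_dmax` | 3.5 Å | donor-acceptor heavy-atom distance |
| `hbond_angle_min` | 130° | donor-H...acceptor angle at the hydrogen |
| `saltbridge_dmax` | 4.0 Å | cation-anion heavy-atom distance |
| `ring_centroid_dmax` | 5.0 Å | aromatic centroid-centroid distance |
| `face_angle_max` | 30° | inter-normal angle, face-to-face stacking |
| `edge_angle_range` | 60-90° | inter-normal angle, edge-to-face |
| `metal_dmax` | 3.0 Å | metal to ligand anion/acceptor distance |

Protein atom typing is a fixed per-residue lookup for the standard amino
acids at pH 7.4 (Lys/Arg cationic, Asp/Glu anionic, His neutral by
default, backbone N donor / O acceptor, canonical His/Phe/Tyr/Trp
rings). Ligand typing is read from the input file's explicit bonds and
formal charges and never re-perceived: this keeps fixtures exact and
avoids embedding a cheminformatics perception stack. Hydrogens are used
when present — the hydrogen-bond test then requires the angular
criterion — and when a donor has no recorded hydrogen (trajectories are
often stripped) the test degrades to the distance-only criterion with a
warning. Both code paths are exercised in the tests.

## The titration protocol

`build_ramp()` defaults to the standard ramp: windows at 300 K to 450 K
in 10 K increments, 10 ns each (16 windows); window durations may differ
per window. Windows are *chained*: the final state of window $k$ seeds
window $k+1$, making the titration one continuous heating experiment
rather than independent restarts. The first production window runs at
the ramp start temperature (300 K); the titration's initial state is
represented by the anchor point $(T_{\mathrm{start}}, -1)$, i.e. the
equilibrated native complex. The anchor convention is a documented
choice — the alternative (using the first window's measured mean) is
available by constructing the profile manually.

After each window the mean IFP_CS across its frames is computed; if that
mean is exactly zero — achievable exactly because integer fingerprints
make every frame score 0 or strictly negative — the native binding mode
was absent for the entire window and the titration terminates early.
The default frame stride is 100 ps (100 frames per 10 ns window).

A backbone-RMSD fold monitor (Kabsch superposition on N, CA, C, O) is
logged per window and warns above 5 Å; it never terminates a run, since
its role is ramp design (a ramp hot enough to melt the receptor tells
you nothing about the ligand).

## The MS coefficient

The titration profile is the polyline through the anchor and the
per-window means. Its summary is the slope of the straight line joining
the initial and final state:

$$\mathrm{MS} \;=\; \frac{\overline{\mathrm{IFP\_CS}}(T_{\mathrm{end}}) - (-1)}
                        {(T_{\mathrm{end}} - T_{\mathrm{start}})/\Delta T},
  \qquad \text{capped at } 1,$$

where $T_{\mathrm{end}}$ is the last *completed* window,
$\overline{\mathrm{IFP\_CS}}(T_{\mathrm{end}})$ its window mean, and
$\Delta T$ the ramp increment. Measuring the temperature axis in
increment units is a deliberate normalization: a raw per-kelvin slope
cannot exceed $0.1$ under the default ramp (complete loss at the second
window gives $(0 + 1)/10\,\mathrm{K} = 0.1$, and it is undefined for
loss in the first window), so it cannot span the documented $[0, 1]$
range. With the increment
convention, full retention through the ramp gives
$\mathrm{MS} = 0/15 = 0$, and complete loss during the first window
(where $T_{\mathrm{end}} = T_{\mathrm{start}}$, denominator floored at
1) gives $\mathrm{MS} = 1$. Earlier loss always means a higher MS. Both
the normalized MS and the raw per-kelvin slope are reported in
`ms_coefficient()` output.

Per pose, five independent titrations are run and the replicate MS
values aggregated by a trimmed mean: drop exactly one maximum and one
minimum (one instance each on ties) and average the remaining three.
With $n \neq 5$ replicates the same drop-one-each rule applies for
$n \geq 3$. Poses are ranked by aggregated MS, ascending, ties broken by
pose id and flagged.

## The synthetic dynamics backend

Real temperature-ramp molecular dynamics needs a GPU engine and hundreds
of nanoseconds per pose; the package therefore defines a minimal
dynamics-backend contract (`run_window(state, temperature, duration,
stride, seed)` returning frames plus a chainable end state) and ships a
fully synthetic implementation with known ground truth, so the entire
protocol — file I/O, detection, scoring, termination, aggregation,
ranking — is testable end to end on one CPU.

`make_fixture_complex()` builds a complex realizing a declared
interaction list exactly: one site per interaction on a 25 Å grid, the
host residue carrying the protein-side template for its class (e.g. a
lysine ammonium for protein-positive salt bridges, a phenylalanine ring
for stacking), every other residue a glycine, and the ligand a
multi-fragment probe whose moieties sit strictly inside the detection
thresholds (margin at least 0.3 Å / 10°) while no undeclared interaction
approaches any threshold. Two template choices are worth noting: the
aromatic sites pair the protein phenylalanine ring with a ligand
1,3,5-triazine, whose carbons (each bonded to two nitrogens) are not
hydrophobic, so stacking cannot be contaminated by incidental
hydrophobic contacts; and donor hydrogens at charged sites point away
from the ligand, so near-threshold donor-acceptor distances are excluded
by at least 55° of angular margin where a pure distance margin is
geometrically impossible.

`synth_backend()` then evolves the ligand stochastically: per frame,
each native interaction $i$ is independently intact with probability

$$p_i(T) = \frac{1}{1 + \exp\!\big((T - T_i)/s\big)},$$

a logistic retention curve with characteristic temperature $T_i$ and
width $s$ (default 5 K) — the simplest monotone model that gives
controllable unbinding windows. An intact moiety keeps its template
geometry up to a 0.2 Å jitter (inside the detection margin); a lost
moiety is displaced at least 1 Å beyond every threshold. Only the moiety
involved moves, so partial loss of a binding mode (a solvent-exposed
tail detaching while the core holds) is representable. Once every
interaction has been absent for a full window the ligand is marked
dissociated and stays interaction-free unless a per-frame rebinding
probability is set. All randomness derives from one master seed through
counter-based splitting (`derive_seed()`), so replicates are independent
but the whole experiment reproduces from a single integer.

What the toy model does *not* emulate: forces, solvent, kinetic rates,
correlated loss of interactions, receptor flexibility, or pose
interconversion. Passing tests therefore demonstrate that the scoring
machinery measures what it claims on inputs with known truth — not that
the protocol discriminates poses on any particular real target.

## Synthetic validation experiment

The package's core self-check mirrors a pose-discrimination experiment:
`make_pose_set()` builds five poses sharing topology but differing in
characteristic temperature (320, 350, 380, 410, 440 K, i.e. a 30 K
spread; each pose's interactions are staggered ±4 K around its base so
loss is gradual), five replicates are titrated per pose under the
default ramp at 100 frames per window, and the trimmed-mean MS ranking
is compared against the construction's stability order with Spearman's
ρ. The acceptance suite requires ρ ≥ 0.8 in at least 8 of 10 master
seeds. These problem sizes (5 poses × 5 replicates × ≤16 windows × 100
frames) were chosen as the smallest faithful replica of the study
design that still gives stable rank statistics.

## Numerical choices and degenerate inputs

* Exact-zero termination, not a tolerance: integer fingerprints make a
  zero window mean exact.
* Cosine of an all-zero vector is 0 by convention; an all-zero reference
  aborts with an explicit error.
* Ring normals come from a least-squares plane fit (SVD); collinear ring
  atoms are an error at perception time.
* Kabsch superposition constrains the rotation to det = +1 and rejects
  collinear or sub-3-atom fits.
* Ties: replicate trimming drops one instance of max and min each;
  pose-ranking ties break lexicographically and are flagged; contact
  ranking ties break by residue order.
* A degenerate ramp (`t_start == t_end`) is a single window; termination
  there yields MS = 1.
* Alternate locations keep the highest-occupancy copy; residue keys
  include chain, insertion code and 1-based PDB numbering.

## Limitations

* Ligand aromaticity and formal charges are trusted from the input file;
  Kekulé-only SDF inputs without aromatic bond types will not yield
  rings for the stacking classes.
* No ligand symmetry correction in RMSD reporting.
* Water-mediated interactions, halogen bonds and cation-π are outside
  the eight-class vector.
* Trajectory input is DCD (with the model's PDB/SDF topology); XTC is
  not supported.
* The contact-frequency report is a geometric stand-in for per-residue
  interaction-energy decomposition: it ranks residues by how often they
  touch the ligand, not by how much energy they contribute.
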