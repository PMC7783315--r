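---
title: "Methods: contact-map compositing, ensemble superposition and triad geometry for PrtP models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact-map compositing, ensemble superposition and triad geometry for PrtP models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cepstruct)
```

## The problem

The cell-envelope proteinase (CEP, gene *prtP*) of *Lactococcus lactis* is a
~1900-residue cell-wall-anchored subtilisin-family serine protease organised
as a chain of domains: propeptide (PP), proteinase core (PR), a long
fibronectin-like A+B stalk, a helical domain (H), a variable cell-wall
domain (W) of 60-residue repeat units, and the anchor. No experimental
structure of the full-length protein exists; what is available instead is a
collection of *predicted* artifacts — per-segment residue–residue contact
maps from coevolution servers (which cap input length, so the sequence is
split into overlapping windows), and several independently predicted 3-D
models of the proteinase core from different servers.

`cepstruct` turns those artifacts into quantitative statements:

* stitch per-segment contact maps into one full-length composite and read
  off domain boundaries and tandem-repeat periodicity;
* superpose predicted models onto each other, score their agreement
  (RMSD, TM-score), and pick an ensemble reference;
* measure the geometry of the Asp–His–Ser catalytic triad in each model and
  classify it as assembled or displaced;
* translate residue numbers between the numbering schemes the CEP
  literature mixes (ORF vs mature vs SK11 coordinates);
* estimate overall molecular dimensions by naive axial stacking of domain
  models.

Every analysis stage can be exercised against synthetic inputs with planted
ground truth, generated by the `make_*` functions.

## Residue bookkeeping

All structures are `ChainModel`s: an ordered C-alpha trace whose residue
numbers are taken *verbatim* from the input PDB and interpreted in a
declared coordinate scheme. Nothing ever renumbers silently; conversions go
through `map_coordinates()`, which implements each scheme as a pure offset
against the ORF frame. The mature protein starts at the ORF aspartate 186
(`MS22337_mature` offset +185), and SK11 mature coordinates use +185 by
default. The published conversions are internally inconsistent by one
residue in one place (one mapping implies +186); we keep +185 as the
default because two independent conversions support it, and expose a
per-call offset override rather than guessing. The same ambiguity motivates
the `fig1_map` tag for the composite contact-map frame: it is defined
relative to the mature N-terminus, and the one published statement implying
a slightly different offset is treated as an inconsistency to be flagged,
not silently corrected.

Mature-sequence extraction (`extract_mature_sequence()`) cuts from a given
start position through the end of the *last* occurrence of a terminal
motif (the PKT that is covalently coupled to peptidoglycan), after removing
alignment gaps. Pairwise strain comparisons (`count_sequence_differences()`)
count differing alignment columns; columns containing a gap in either
sequence are dropped by default (`ignore_gap_columns`) so that indels such
as the 2-residue propeptide deletion are not conflated with substitutions.
A window argument restricts the count (strain comparisons in this
literature are reported within the first 1800 positions, because the
W-domain repeat number varies between strains and makes the tail
non-comparable).

## Superposition and scoring

`kabsch_superpose()` computes the least-squares rigid transform by SVD of
the 3×3 cross-covariance matrix with the usual reflection correction, so
the rotation is always proper. Degenerate inputs (<3 pairs, collinear
points) are errors, not warnings.

`tm_score()` implements the length-normalised similarity

$$\mathrm{TM} = \max_{\text{superpositions}} \frac{1}{L_\mathrm{norm}}
\sum_i \frac{1}{1 + (d_i/d_0)^2}, \qquad
d_0 = 1.24\,(L_\mathrm{norm}-15)^{1/3} - 1.8,$$

with $d_0$ clamped below at 0.5 Å (for $L_\mathrm{norm} \le 21$ the formula
drops under the clamp or becomes undefined). The maximisation is the
standard seed-and-extend search, fixed as follows: contiguous seed windows
of length $L$, $L/2$ and $L/4$ (minimum 4) at every offset; each seed is
superposed by Kabsch, then pairs within a distance cutoff are iteratively
re-included and re-superposed until the included set is stable, for a
cutoff schedule running from $d_0 + 1$ to 8 Å in 0.5 Å steps; the reported
score is the maximum over everything. This schedule is part of the
operation's definition — the tests validate it against an independently
coded enumeration of the same schedule built on bio3d's fitting engine.

Residue pairing between models is by *identical residue number* (optionally
within a window such as the 186–698 proteinase core), never by structural
alignment: the models being compared are predictions for the same sequence,
so sequence-independent alignment is out of scope. TM normalisation
defaults to the length of the target (column) model, which is why an
all-vs-all TM matrix (`compare_all()`) may be asymmetric; both directions
are stored, one per triangle. `select_reference()` picks the ensemble
medoid, by default maximising the worst-case symmetrised TM to any other
model, with lexicographic tie-breaking so selection is deterministic.

## Contact-map compositing

Segment maps arrive as sparse 3-column text `(i, j, p)` in local
coordinates with a known global offset. `stitch()` maps entries to the
global frame ($i_\mathrm{global} = i_\mathrm{local} + \mathrm{offset} - 1$)
and merges predictions for the same pair by `mean` (default), `max` or
`min`, recording per-pair coverage. The default is `mean` because
overlapping windows produce near-identical predictions in practice, making
the consensus choice low-stakes; it is still explicit and configurable.
Stitching is idempotent and permutation-invariant, which the tests assert.

`render_diagonal_band()` is the 45°-tilted representation natural for
segment-composited maps (which only cover pairs separated by up to a few
hundred residues): row = position, column = separation, default band 200.

### Domain boundaries

`detect_domain_boundaries()` performs greedy recursive min-cut on the
contact weights. A candidate cut after residue $k$ scores

$$s(k) = \frac{2\,W_\mathrm{cross}(k)}{W_\mathrm{left}(k) + W_\mathrm{right}(k)}$$

where the three weights sum contact probabilities within a
`min_domain`-sized window on each side of the cut (cross = pairs straddling
it). Two numerical choices matter:

* entries with $p <$ `p_min` (default 0.3) are ignored — contact maps
  carry many low-confidence entries that would otherwise swamp the
  statistic;
* scoring is restricted to separations up to the 90th percentile of the
  observed contact separations (floor 5). Long-range entries are sparse
  and, in noisy maps, dominated by spurious contacts whose window *area*
  is large; without the cap, uniform background noise contributes enough
  cross-weight to mask a true boundary.

The lowest-scoring cut (leftmost on ties, via `which.min`) is accepted
while $s < $ `threshold` (default 0.02), then each side is processed
recursively with the same `min_domain` (default 100). On the synthetic
generator's densities a featureless single-domain map scores ≈0.06 at every
position and is never cut, while a planted boundary with no cross-contacts
scores ≈0 even with 10% spurious contacts; 0.02 sits between those regimes
with a margin on both sides. Zero boundaries is a valid, common result.

### Repeat periodicity

`detect_repeat_period()` detects tandem structural repeats (the ~100-residue
fibronectin-like units; the 60-residue W units) as periodicity of the band
matrix along the position axis. The band rows within the query region are
column-centred first — subtracting each separation column's mean removes
the generic near-diagonal background, which is identical at every position
and would otherwise correlate at *every* lag. The normalised
autocorrelation is evaluated at lags 2..`max_period`; because a true period
$P$ also produces peaks at $2P, 3P, \dots$, the reported period is the
smallest lag reaching 90% of the peak correlation. `n_units` is the floor
of region length over period. A result with correlation below 0.2 is
flagged `weak`: that is the level featureless maps reach by chance in the
null simulations, so a weak flag means "no convincing periodicity", not a
smaller repeat.

## Catalytic-triad geometry

The subtilisin triad of MS22337 PrtP is D215, H279, S618 (ORF numbering;
the defaults of `triad_spec()`). `triad_distances()` measures the three
pairwise distances; `classify_triad()` calls the state from
$\max(d_{DH}, d_{HS})$ alone — the aspartate and serine coincide across
predicted models, and what varies is where the histidine sits. The default
threshold is 10 Å: the midpoint between the ≈6 Å histidine separation of
assembled models and the 15–18 Å of displaced ones, so the call is
insensitive to threshold choice within several Å on either side. Equality
with the threshold classifies as assembled; the signed `margin`
(threshold − worst distance) is reported so borderline calls are visible.

Distances default to CA–CA because the published figures do not state which
atoms were measured; a `functional_atom` rule (Ser OG, His NE2, Asp CG,
falling back to CA when absent) is available, and comparisons against
published distances should carry ±1.5 Å of slack to absorb exactly this
ambiguity.

`estimate_extent()` reports the coordinate range along the first principal
axis — the natural "height" of an elongated molecule. `assemble_domains()`
stacks domain models along z (each rotated so its principal axis is
vertical, oriented N→C upward) with a configurable gap. This is explicitly
a dimensional estimate, not docking: no linker modelling, no clash
minimisation, no interface optimisation. Its one guarantee is that the
assembled extent is at least the sum of the component extents.

## The synthetic-data generators

Every pipeline stage is testable offline because the generators plant known
truth; each is a pure function of (parameters, seed), with RNG state kept
local to the call.

* `make_helix_rod()` — deterministic helical CA trace (defaults rise 1.5 Å,
  turn 100°, radius 2.3 Å ≈ ideal α-helix; radius 0 gives an exact rod).
* `perturb_model()` — i.i.d. Gaussian coordinate noise; expected RMSD to
  the original is $\sigma\sqrt{3}$, which the tests recover within 10% at
  $n = 500$ over 20 seeds.
* `make_segmented_contact_fixture()` — multidomain contact truth:
  probability 0.9 for same-domain pairs at separation ≤ 4, 0.5 at 5–12,
  nothing across domains; an optional repeat region adds an inter-unit band
  at the planted period ($p$ 0.6) plus a random intra-unit motif repeated
  identically in every unit ($p$ 0.7) — the motif is what autocorrelation
  actually detects, mimicking repeats that share internal structure. A
  `noise_frac` (default 0.1) of spurious contacts with $p \sim U(0,1)$ is
  scattered uniformly; the truth is then decomposed into the requested
  overlapping windows (e.g. the mature-protein scheme 1–799, 301–1099,
  501–1299, 926–1725 — note the last window is 800 residues long, an
  irregularity we reproduce rather than correct). These densities were
  fixed once to make detection unambiguous at the default thresholds.
* `make_triad_fixture()` — a minimal chain embedding residues 215/279/618
  with $d_{DS}$ fixed at 7 Å and $d_{HS}$ drawn in 5–7 Å (assembled) or
  14–19 Å (displaced); the His placement angle is constrained so assembled
  fixtures also keep $d_{DH} \le 10$ Å.
* `make_synthetic_orf()` / `mutate_sequence()` — sequence stand-ins with a
  planted mature span (DAK…PKT) and planted exact Hamming distances.

What the generators deliberately do **not** emulate: realistic contact-map
error structure (server-specific false-positive patterns, secondary-
structure-dependent density), realistic decoy geometry, side-chain
chemistry, or inter-domain linkers. Consequently, passing the planted-truth
tests demonstrates that the *algorithms* recover what they are designed to
recover under controlled conditions; it does not certify performance on
real server output, where signal-to-noise is worse and thresholds may need
retuning via the exposed parameters.

Problem sizes used in the test-suite study conditions: 30-residue pairs for
the TM oracle comparisons, 500-residue chains for noise recovery, the
full-length 1725-residue composite for stitching/boundary/repeat recovery,
and six-model ensembles for the triad census. These sizes make every
planted effect unambiguous while keeping each check to seconds.

## Degenerate inputs and tie-breaking

* `kabsch_superpose()` refuses <3 pairs and collinear point sets (second
  singular value below 1e-8 of the first).
* TM identity is exact: identical models score exactly
  `n_pairs / L_norm` with no search noise.
* Boundary search takes the leftmost minimum; repeat detection takes the
  smallest near-peak lag; reference selection breaks ties lexicographically.
* `load_contact_map()` normalises lower-triangle entries, errors (with line
  numbers) on self-contacts and out-of-range probabilities, and collapses
  duplicate pairs to the maximum with a warning.
* Empty pairings are legal for `shared_residue_pairing()` (disjoint models)
  but an error for scoring operations.
* PDB reading rejects insertion codes and duplicated residue numbers
  outright, keeps altloc blank/'A', and requires a CA for every residue.

## The pipeline

`run_pipeline()` wires the stages together from a flat key–value
configuration: stitch → band → boundaries → core-window comparison →
reference selection → superposition onto the reference → triad report →
requested pair distances, writing TSV/PDB outputs plus a manifest (config
hash, package version, seed — no timestamps, so reruns are byte-identical).
Contact-only and structure-only runs are both supported; missing contact
inputs abort unless `allow_missing_contacts` is set, in which case the
contact stages are skipped with a warning. A thin command-line wrapper
(`inst/cli/cepstruct.R`) exposes the same operations as subcommands.

## Known limitations

* Pairing is by residue number only; models that disagree on numbering must
  be mapped first, and genuinely different sequences cannot be compared.
* TM-score here searches the fixed seed schedule above, not the larger
  heuristic repertoire of the original external programs; on difficult
  pairs the reported maximum is the schedule's maximum, which can sit
  slightly below an unrestricted search.
* Boundary detection assumes compact diagonal-block domains; interleaved or
  discontinuous domains will not be segmented correctly.
* Domain assembly is axial stacking only and says nothing about relative
  domain orientation.
* Published structural values for the real model ensemble can only be
  checked after downloading the deposited models; the test suite covers the
  measurement machinery with labelled synthetic stand-ins instead.
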