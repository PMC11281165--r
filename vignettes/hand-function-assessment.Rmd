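---
title: "Methods: hand-function assessment from 21 landmarks, and graph-based disease QA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hand-function assessment from 21 landmarks, and graph-based disease QA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handassess)
```

This vignette documents the models, conventions and numerical choices behind
`handassess`, in the order a reader meets them: the skeletal model, the
kinematic measurements, the scoring rubric, the synthetic generator used for
validation, and the knowledge-graph question-answering engine.

## The skeletal model

The hand is reduced to 21 landmarks: a single wrist/carpal node and four
nodes per finger including the fingertip. The carpal bones move very little
relative to one another in daily activity and the wrist is assumed to be in
a neutral, straight position, so a single proximal node suffices. Landmark
indexing follows the convention used by common monocular pose estimators
(0 = wrist; thumb 1–4 = CMC, MCP, IP, tip; every other finger MCP, PIP,
DIP, tip), because those estimators are the expected upstream data source —
see `?hand_topology` for the full table.

Fourteen hinge joints are measured: MCP/PIP/DIP for the index, middle, ring
and little fingers, and two thumb joints. The thumb lacks a middle phalanx,
so it has a single interphalangeal joint; clinical score sheets commonly
label it "thumb DIP", and we follow that (`thumb_DIP`, with `thumb_IP`
accepted as an alias). Only flexion/extension is measured: the finger IP
joints are anatomically hinge joints, and although the MCP joints also
abduct, the assessment standard implemented here grades flexion-extension
ROM only.

**Joint triplets.** Each angle needs one proximal and one distal reference
landmark around the vertex. For PIP and DIP joints the flanking landmarks
are unambiguous. For a finger MCP angle we anchor the proximal segment at
the wrist node, i.e. the triplet (wrist, MCP, PIP); for the thumb MCP we use
(CMC, MCP, IP). This is a convention, not an anatomical necessity — the
plausible alternative (a per-finger metacarpal direction) is not available
from 21 landmarks, whose only proximal reference is the wrist node. The
choice is applied consistently in measurement and in the synthetic
generator, so programmed and recovered angles agree by construction.

## Angle, ROM, opposition, thumb AROM

The flexion angle at vertex Y between bone vectors XY and YZ is
`arccos((XY·YZ)/(|XY||YZ|))`, in degrees; 0° is a fully extended chain.
Numerically we evaluate the equivalent form `atan2(|XY × YZ|, XY·YZ)`,
which is exact to machine precision near 0° and 180° where the arccos form
loses up to half its significant digits; this is what lets noise-free
round-trip tests assert recovery at 1e-9 degrees. Bone vectors shorter than
1e-9 mm raise a degenerate-segment error rather than returning an arbitrary
angle.

ROM is the global `max − min` of a joint's angle trajectory over the whole
recording. When a subject performs several open-to-fist repetitions the
global range is used, not a per-repetition average; repeated cycles
therefore do not change ROM, which the tests assert.

Thumb opposition is operationalised as the Euclidean distance between the
thumb tip (landmark 4) and the little-finger MCP (landmark 17), with a
contact margin of 3 cm: the test succeeds when the minimum distance over the
recording is strictly below 30 mm. The boundary case of exactly 30 mm is
*not achieved* — "below" is read strictly, and the choice is documented
here because a measured distance landing exactly on the margin is a
zero-probability event for real data but must still be deterministic.

Thumb AROM is the sum of the thumb MCP and interphalangeal ROMs; values
above 90° are considered healthy.

All coordinates are millimetres throughout; angles are degrees (the angle
formula yields radians; conversion is fixed at output).

## The scoring rubric

`score_bands()` implements the published functional-activity standard:

| class | bands (°) | scores |
|-------|-----------------------------|---------------------|
| MCP   | <30, 30–49, 50–69, 70–90    | 0–2.5, 2.5–5, 5–7.5, 7.5–10 |
| PIP   | <30, 30–59, 60–79, 80–100   | idem |
| DIP   | <15, 15–19, 20–29, 30–45    | idem |

Two details are under-specified by such printed tables and resolved here:

* the printed bands leave unit gaps (…–69 then 70–…). We implement
  contiguous half-open intervals ([50, 70), [70, ∞) for MCP, analogously
  elsewhere) so that any real-valued ROM falls in exactly one band;
* the printed score ranges ("7.5~10") come with no mapping rule. We
  interpolate linearly from the band's lower edge to its printed upper
  endpoint, which is continuous across band boundaries, monotone, and
  faithful at the printed endpoints (70° ↦ 7.5, 90° ↦ 10). Above the top
  band the score clamps at 10: hypermobility grading is out of scope, and
  such ROMs are classified `normal` but flagged `above_reference` in the
  report.

Opposition scores 10/5/0 for achieved / achievable-with-difficulty / not
achievable. The middle grade has no quantitative definition in the standard,
so by default only {achieved, not achieved} are produced; an optional second
distance margin (`hard_threshold_mm`, suggested 60 mm, off by default)
grades intermediate distances as "hard". Thumb AROM scores 10 above 90°, 5
for measurable motion at or below 90°, and 0 for stiffness (no motion).

The total score sums 14 joint scores plus opposition plus thumb AROM
(maximum 160).

## The surface-normal consistency metric

Every three consecutively connected landmarks — exactly the 14 joint
triplets — form a triangular "joint surface". Given a predicted and a
reference pose, the metric is

$$L_n = \sum_{f \in F} \sum_{(i,j) \subset f}
 \left| \widehat{(V_i - V_j)} \cdot n_f^{gt} \right|$$

with each predicted edge normalized once and `n` the unit normal of the
reference face. The value is zero iff every evaluated predicted edge lies in
its reference face plane, and is invariant to translation and uniform
scaling of the prediction. Reference faces whose vertices are collinear — a
fully extended finger — have no defined normal; they are skipped and
reported in `n_faces_skipped`, and a pose with no evaluable face at all
(fully open hand) raises an error instead of returning a vacuous zero.
Collinearity is detected by comparing the cross-product norm against
`collinear_tol` (default 1e-8) times the squared longest edge, a
scale-invariant test. A plausible alternative reading of such a metric
normalizes by edge length twice (weighting short edges up); we normalize
once, the standard form for normal-consistency penalties.

## The synthetic generator

`generate_pose()` chains bone vectors from the wrist: each finger has a base
direction fanned in the palm plane and a flexion plane; each hinge bends in
that plane by exactly the requested angle, so `joint_angle()` recovers
programmed values to machine precision and bone lengths are preserved by
construction. Default segment lengths are rounded adult-hand magnitudes in
millimetres (e.g. index 70/40/25/22) — implementation fixtures chosen for
realism, configurable, and not measured reference values.

The thumb's flexion plane is tilted 75° across the palm toward the ulnar
side. This reproduces the opposition component of thumb movement with
hinge-only kinematics: at the programmed fist peak (CMC 45°, MCP 90°, IP
45°) the thumb tip passes ≈16 mm from the little-finger MCP, inside the
30 mm contact margin. The tilt was chosen once from this geometry.

`generate_motion()` linearly interpolates per-joint breakpoint profiles and
optionally adds isotropic Gaussian landmark noise (per landmark, per frame,
per axis) emulating pose-estimator jitter; a seed is mandatory whenever
noise is requested, and the caller's RNG state is left untouched.
`preset_fist_cycle()` programs the standard assessment protocol — by
default 3 repetitions of open-palm-to-fist across 121 frames, peaks at the
top of each scoring band. Peaks land exactly on frames when
`n_frames − 1` is divisible by `2 × n_repetitions` (121 works for both 3
and 4 repetitions); otherwise the sampled maximum falls slightly short of
the programmed peak, as it would for any sampled real recording.

**What the generator does and does not emulate.** It produces kinematically
exact hinge motion with optional white landmark noise. Real pose-estimator
output additionally contains occlusion-driven drift (notoriously worst for
the flexed thumb), temporally correlated error, depth-scale wobble, and
abduction/adduction that the planar model omits. Passing recovery tests
therefore validates the measurement pipeline — formula, conventions,
bookkeeping — not the upstream vision model, whose errors are a property of
whatever estimator feeds the package.

A note on noisy validation: the ROM of a noisy trajectory is upward-biased
(it is a max minus a min), so recovered ROM under noise is compared against
a Monte-Carlo noise-propagation oracle — replicate simulations at the same
noise level — rather than against the programmed value, while per-frame
angle recovery is checked within 3σ directly. At 2 mm noise and 500 frames
the bias ranges from ≈6° (long proximal segments) to ≈25° (short distal
segments), which is worth remembering when interpreting noisy ROMs
clinically: smoothing the trajectory before taking extrema would trade that
bias for lag.

**Problem sizes.** The validation suites use 1000 random poses for the
angle-formula and rigid-invariance properties, 500-frame sequences at 2 mm
noise for recovery, 200 randomized dictionaries (≤50 patterns, ≤500-char
texts) for the matcher, and ≤12-record random graphs for load invariance —
sizes at which the brute-force oracles are comfortably exact.

## The knowledge graph

Disease records are line-delimited JSON with a fixed schema: eight scalar
attributes (`desc`, `cause`, `prevention`, `cure_lasttime`, `cure_way`,
`cured_probe`, `easy_get`, and the name), symptom phrases, and list fields
that become typed relations (`acompany_with` Disease→Disease, `belongs_to`
Disease→Department, `do_eat`/`no_eat`/`recommand_eat` Disease→Food,
`recommand_drug` Disease→Drug, `drugs_of` Producer→Drug). Symptoms are kept
as a disease attribute rather than entities, mirroring schemas whose entity
inventory has no Symptom type. The `drugs_of` orientation is asserted only
by example in the source material; we adopt Producer→Drug.

The store is in-memory (tibbles of entities, relations, attributes): no
graph-database dependency, loading is idempotent and order-invariant, and
referential integrity (no dangling endpoints) holds after every load.
Entity-name matching is exact after whitespace normalization; no fuzzy
matching. `kg_export_cypher()` emits CREATE statements for users who run a
graph database; the export is write-only and never parsed back.

The shipped fixture (`inst/extdata/hand_diseases.jsonl`) is a synthetic
eight-disease corpus written for the tests; a few entity names and two
example facts (a treatment duration of "1–3 weeks", a cure probability of
"80%", and a comorbidity triple) are kept verbatim so that documented
example queries have stable answers.

## Question answering

The pipeline is a single-step retrieve-and-render chain:

1. **Entity matching.** An Aho–Corasick automaton over all entity names
   (built by hand in R: character trie, BFS failure links, merged output
   sets — see `?ac_build`) finds every occurrence in one pass; overlapping
   matches resolve to the longest, ties leftmost. Matching is
   case-insensitive; surfaces are reported from the original text.
2. **Intent classification.** A closed taxonomy of 14 intents — one per
   attribute plus one per askable relation — driven by an English trigger
   table (`qa_keyword_table()`). Triggers are matched with the same
   automaton, restricted to word boundaries, with the same longest-match
   rule (so "cure rate" shadows "cure" and "not eat" shadows "eat"), and
   triggers inside an entity mention are ignored. An entity with no trigger
   defaults to the description intent; no entity yields a clarification
   message. The trigger table is a locale file, replaceable wholesale
   (e.g. for a Chinese-language deployment), and matching remains
   substring-based with no tokenizer dependency.
3. **Templates and retrieval.** Each intent maps to a fixed plan of
   primitives — attribute lookup or one-hop neighbor query
   (`build_query()`, `execute_query()`); results keep provenance of which
   primitive produced them. Multi-step reasoning formulations reduce here
   to one step (n = 1): that matches the concrete template system, and the
   plan abstraction leaves room for multi-hop plans without shipping any.
   The answer "ranking" is degenerate by design: every retrieved entity
   scores 1 against a threshold of 0, so the answer set equals the
   retrieved set, which the tests assert. Producer questions apply to
   matched Drug entities (incoming `drugs_of`); if only a disease is
   matched they fall back to its recommended-drug list, since
   disease→producer would need two hops.
4. **Rendering.** One fixed sentence template per intent; deterministic
   end-to-end (identical question and graph give byte-identical output).

## Limitations

* Flexion/extension only: no abduction, circumduction, or wrist angles.
* The rubric's score-range interpolation and band closure are this
  package's resolution of an under-specified printed standard; other
  implementations could step scores instead.
* The opposition test reduces "opposition" to one distance; pulp-to-pulp
  opposition quality is not graded.
* The QA engine answers from explicit facts only — no inference, no fuzzy
  matching, no learned ranking; unknown phrasing falls back to the
  description intent or a clarification.
* The shipped trigger table is an English reconstruction; recall on free
  text depends on it and should be localised per deployment.
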