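---
title: "Signal propagation on signed protein networks and in-silico drug-combination screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal propagation on signed protein networks and in-silico drug-combination screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netscreen)
```

## The problem

After traumatic avulsion of spinal nerve roots, motoneurons degenerate;
pharmacological neuroprotection is an adjuvant strategy to surgical
reimplantation. A network-centric route to finding such agents is to encode
what is known about the degenerative and protective signalling programmes as
condition-specific protein networks, turn the degeneration network into an
executable model, and search for drug combinations whose simulated
perturbation pushes the model toward the protective state while avoiding
adverse programmes such as neuropathic pain.

`netscreen` implements that pipeline end to end at desk scale: map
construction from curated seeds, a trainable signal-propagation model
constrained by a truth table of perturbation restrictions, an exhaustive
pairwise drug screen with synergy scoring, threshold- and eligibility-based
candidate selection, and mode-of-action node extraction. Because the
interactomes, proteomic restriction sets and drug-target curations behind
published screens of this kind are proprietary, the package ships a fully
seeded synthetic-data generator with planted ground truth, so every stage is
testable and benchmarkable without external data.

## The propagation model

A condition map is a directed graph with curated edge signs
$s_{ij} \in \{+1, -1\}$ and confidence weights $w_{ij} \in (0, 1]$. The
model attaches a strength $W_{ij}$ to every edge (sign-constrained:
$\mathrm{sign}(W_{ij}) \in \{0, s_{ij}\}$ at all times, including
mid-training) and a bias $b_j$ to every node. Node states
$x_j \in [-1, +1]$ evolve by the damped synchronous update

$$x_j^{(t+1)} = (1-\alpha)\, x_j^{(t)} + \alpha \tanh\Big(b_j + \sum_i W_{ij}\, x_i^{(t)}\Big),$$

with perturbed nodes *clamped* at their input values throughout. Iteration
stops when the largest per-node change falls below $\varepsilon$ or at the
iteration cap; non-converged runs are flagged honestly and the final iterate
is used. Key choices:

* **Activation.** A bounded, odd, monotone squashing rule; tanh is the
  default and the rule is a single dispatch point should alternatives be
  wanted. States therefore live in $[-1, +1]$ by construction.
* **Damping $\alpha = 0.5$.** Synchronous updates on cyclic signed graphs
  oscillate; averaging the update with the current state suppresses
  period-two oscillation without changing the fixed points. On acyclic maps
  the iteration converges to the unique fixed point computable in
  topological order — the package's tests exploit exactly that as an
  independent oracle (agreement to $10^{-9}$ on random DAGs).
* **Clamping as drug semantics.** Drugs hold their targets fixed at
  action-sign × dose for the whole simulation, the interpretation most
  consistent with sustained dosing (continuous infusion over weeks) rather
  than a transient stimulus. When two drugs hit one target the clamp is the
  clipped sum, so opposing actions cancel.
* **Defaults.** $\varepsilon = 10^{-6}$, 200 iterations, initial strengths
  small-random with curated signs, biases zero.

## Training against a truth table

A restriction row pairs a sparse input signature (a few clamped proteins)
with the required output states of a read-out node set, plus a tolerance
(default 0.5 on the $[-1,1]$ scale — qualitative agreement in direction and
magnitude class). A row is *satisfied* when every required output matches
the propagated fixed point within tolerance; the *satisfaction fraction* is
the headline fit statistic.

Training is seeded simulated annealing over strengths and biases:

* proposals perturb a random 15% of parameters with Gaussian steps and are
  projected back onto the sign constraints;
* the objective is the mean squared residual of required outputs, plus a
  small ridge term ($\lambda = 0.01$ times the mean squared parameter).
  The ridge matters: parameters the truth table does not constrain stay
  near zero, so perturbations the model has never been taught about
  produce weak responses instead of arbitrary ones — without it, screening
  a trained model yields spurious "synergies" from unconstrained corners of
  the parameter space;
* geometric cooling over 3,000 steps, then 1,500 greedy polish steps with
  smaller proposals (improvements only). The polish phase is what pins the
  *relative* magnitudes of single versus joint perturbation responses,
  which synergy scoring is sensitive to;
* the returned model is the best iterate by (satisfaction, then objective),
  so training can never degrade the initial model's satisfaction.

Gradient-based training was deliberately avoided: the sign-constraint
projection is trivial under annealing, the parameter count at desk scale is
a few hundred, and the dependency surface stays minimal. The package trains
one model per seed and exposes seeds, rather than maintaining an ensemble
machinery; ensembling can be done externally over seeds.

Cross-validation splits restriction rows into k folds keyed on sorted row
ids (fold assignment is invariant to table row order), trains on k−1 folds
and evaluates held-out satisfaction.

## Scoring combinations

Phenotype signatures are weighted desired-state vectors over read-out
proteins. For a propagated state $x$ and signature $(d, \omega)$,

$$\mathrm{score} = 100 \times \max\Big(0, \textstyle\sum_p \tilde\omega_p\, x_p\, \mathrm{sign}(d_p)\Big),$$

with $\tilde\omega$ the normalized weights — a directional-agreement
percentage. Efficacy uses the protection signature, adverse liability the
pain signature. Synergy follows the highest-single-agent convention: pair
efficacy minus the better single, in percentage points, unclipped. This is
the most conservative of the standard synergy conventions and the only one
available without dose–response curves; it is isolated in one function
should a different convention be wanted.

Candidate selection is two-tiered with exact boundary semantics: the pass
tier requires efficacy ≥ 23 (inclusive), adverse ≤ 17 (inclusive) and
synergy > 20 (strict); the top tier additionally requires efficacy > 75 and
adverse < 2.5 (both strict). Eligibility is metadata, not prediction: four
curated flags (safety profile, no pain liability, no known regeneration
effect, blood–brain-barrier penetration) must all be true for both drugs.
Ranking is the total order (efficacy desc, adverse asc, synergy desc,
canonical ids), so outputs are byte-reproducible.

Mode-of-action extraction ranks non-clamped nodes by
$|x^{AB}_p - x^{\mathrm{best}}_p|$, where $x^{\mathrm{best}}_p$ is the
single-drug state of larger magnitude at node $p$ — the node-wise analogue
of the highest-single-agent expectation. Nodes where the combination does
something neither single does rise to the top; ties break on node name and
the result is invariant to drug order.

## What the synthetic generator emulates

The generator is a pure function of a `scenario` object; every study object
derives from one master seed.

* **Interactome.** A directed random graph with heavy-tailed out-degree
  (Pareto-like source fitness), emulating the hubs-plus-leaves structure of
  curated signalling maps. The undirected mean degree is matched exactly by
  construction; components beyond the giant one are bridged. Defaults: 150
  nodes, mean degree 5, 25% inhibitory edges — a deliberate scale-down of
  curated disease maps (thousands of nodes, mean degree ~13) chosen so a
  full train-plus-screen cycle runs in seconds. A 500-node, mean-degree-13
  instance is generated in the reproduction script to check the generator
  at the reported statistics.
* **The planted mechanism.** Two mid-fitness regulator hubs receive
  activating edges (weight 0.6) onto a common six-node read-out set — an
  AND-gate-like convergence motif. Under tanh propagation each hub alone
  drives the read-outs to about $\tanh(0.6) \approx 0.54$ and the pair to
  about $\tanh(1.2) \approx 0.83$: each member alone moves the read-out
  weakly, the pair strongly. This is what makes the planted pair
  *mechanistically* synergistic, and it is also why the read-out nodes are
  the expected mode-of-action nodes. Mid-fitness hubs are used because the
  organic neighbourhood of top hubs adds background paths that saturate the
  read-outs and erode the planted contrast. Generation verifies the
  mechanism by direct simulation (synergy margin ≥ 18 points, single
  efficacies ≤ 62%) and retries with a derived sub-seed — bounded, then a
  hard error — when a random embedding fails.
* **Seeds and maps.** Seed proteins are drawn degree-weighted (curated seed
  lists are enriched for well-connected proteins); the planted hubs are
  always degeneration seeds, so the default 1-hop expansion contains the
  circuit. Two conditions share a configurable fraction of proteins and
  disagree on expected states with probability 0.5.
* **Ground truth and restrictions.** The hidden model draws strengths as
  sign × weight × U(0.8, 1.2) on the degeneration map's induced subgraph,
  so its restriction fixed points are representable by a trained model of
  the same family (on the full graph they would not be, and no trainable
  model could satisfy a noiseless table). The 40-row table holds six
  designed rows (each hub alone and jointly, both clamp directions —
  mirroring single-drug indication knowledge) and random 2–3-node
  perturbations, half influence-weighted and half uniform so the table also
  pins down which perturbations do *nothing*. Outputs are ground-truth
  fixed points over the read-outs plus the pain-signature nodes (a
  proteomic contrast profiles all markers, not only efficacy read-outs).
  Noise, when requested, negates all output values of a row with the given
  probability — restrictions are qualitative, so sign flips rather than
  Gaussian jitter.
* **Drug library.** 50 drugs: the planted pair (one hub each), a decoy pair
  that clamps complementary read-out halves directly but whose second
  member fails exactly one eligibility flag, two single actives clamping a
  fixed small read-out subset, and null drugs hitting 1–3 nodes from the
  bottom quartile of total absolute downstream influence (summed |state|
  under a unit clamp).

What the generator does **not** emulate: mass-spectrometry noise structure,
identifier mapping, dose–response pharmacology, literature curation bias,
and the sheer scale of production interactomes. Passing the package's
benchmarks therefore demonstrates that the machinery is correct and that
the method recovers a planted mechanism under realistic graph topology at
reduced scale — not that it would rank any particular real drug pair first.

## Numerical and design notes

* All tables are UTF-8 TSV with mandatory headers and `#` comments; loaders
  canonicalize order, so permuted inputs give identical objects. Duplicate
  edges with equal sign merge by max weight; with opposite signs loading
  fails loudly (silent sign choice would corrupt the model).
* Checkpoints print parameters with 17 significant digits and reload
  bit-exactly; ranked tables print at fixed 6-decimal precision and the
  written file re-reads to those values.
* The pipeline derives one seed per stage from the global seed and the
  stage name, so any stage can be re-run in isolation; identical config and
  seed give byte-identical artifacts.
* Problem sizes used by the test-suite benchmarks and the reproduction
  script: the default scenario (150-node interactome, ~25–45-node
  degeneration map, 40 restrictions, 50 drugs → 1,225 pairs), 5 seeds for
  the truth-table fit with shuffled controls, 10 seeds for planted-pair
  recovery, 100 random DAGs for the propagation oracle. These sizes were
  chosen so the whole benchmark cycle completes in a few minutes on one
  core while leaving each check statistically meaningful.

## Known limitations

* One model per seed; no ensemble averaging of solutions.
* The synergy convention is highest-single-agent; Bliss or Loewe scores
  need dose–response models the propagation framework does not provide.
* Restriction tolerance (0.5) is a qualitative-agreement default; a much
  smaller tolerance makes noiseless tables unsatisfiable within the default
  annealing budget.
* The planted-pair benchmark plants one pair per scenario; multi-mechanism
  libraries would need additional disjoint convergence motifs.

## A minimal session

```{r example, eval = FALSE}
library(netscreen)

dat <- generate_scenario_data(scenario(seed = 1), outdir = "results/demo")
fit <- train(build_model(dat$map_degeneration, seed = 101),
             dat$restrictions, seed = 101)
res <- screen_combinations(fit$model, dat$library, dat$signatures)
flt <- filter_candidates(res, library_metadata(dat$library))
flt$passing
extract_moa(fit$model,
            list(dat$library[[flt$passing$drug_a[1]]],
                 dat$library[[flt$passing$drug_b[1]]]),
            dat$signatures$protection, top_k = 10)
```

The numbered scripts under `analysis/` run the same stages as narrative
drivers and write their tables under `results/`.
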