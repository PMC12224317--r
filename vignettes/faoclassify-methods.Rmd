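---
title: "Models and methods behind faoclassify"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind faoclassify}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faoclassify)
```

# The scientific problem

Flavoprotein amine oxidoreductases (FAOs) oxidize C–N bonds using an FAD
cofactor; the reduced cofactor must then be reoxidized. Two physiological
routes exist: reaction with O₂ (the oxidase route, producing H₂O₂) and
electron transfer to a cytochrome *c* (the dehydrogenase route). Which
route an enzyme uses cannot be read reliably from its sequence, but two
genomic signposts correlate with the dehydrogenase lifestyle: a
twin-arginine (TAT) export signal peptide on the FAO, and a c-type
cytochrome gene immediately adjacent in the genome (sometimes fused into a
single polypeptide). `faoclassify` implements the quantitative chain from
stopped-flow kinetics to verdicts, and from genome annotations to ancestral
operon configurations on a phylogeny.

# The kinetic model

## Mechanism

The simulator (`simulateMechanism()`) integrates mass-action rate laws for
seven species: the enzyme-bound flavin in hydroquinone (E·FlH₂),
semiquinone (E·FlSQ) and oxidized (E·Flₒₓ) states, oxidized and reduced
cytochrome *c*, O₂ and H₂O₂.

* **O₂ branch.** A single bimolecular two-electron step,
  E·FlH₂ + O₂ → E·Flₒₓ + H₂O₂, with rate constant `k_O2` (M⁻¹s⁻¹).
  H₂O₂ is tracked as an inert product. Under oxidant excess this yields a
  mono-exponential rise at 450 nm, as observed experimentally.
* **Cytochrome-c branch.** Two sequential one-electron transfers,
  E·FlH₂ + Cₒₓ ⇌ E·FlSQ + C_red (`k1f`, `K1`) and
  E·FlSQ + Cₒₓ ⇌ E·Flₒₓ + C_red (`k2f`, `K2`). Both steps are reversible:
  experimentally, traces at modest cytochrome/enzyme ratios plateau at an
  equilibrium in which some electrons remain on the flavin, and trace
  amplitudes titrate with cytochrome concentration. The magnitudes of the
  reverse constants are not experimentally determined, so they are
  parameterized through per-step equilibrium constants (`kir = kif/Ki`,
  default `K1 = K2 = 10`, `Inf` = irreversible). These defaults are
  placeholders expressing "reversible but favourable", not inferred values.

The scheme assumes sequential binding of the two cytochrome molecules (no
ternary complex); whether the two transfers share one binding site is not
known, but under the rate-limiting-encounter interpretation (both observed
rates linear in oxidant concentration) the distinction does not affect the
observables modelled here.

Three conservation laws (total enzyme flavin, total cytochrome, total
reducing equivalents 2[FlH₂] + [FlSQ] + [C_red] + 2[H₂O₂]) hold along any
trajectory and are asserted in the tests to the 1 nM level.

## Spectral model

Absorbance is a Beer–Lambert sum over species. Anchored coefficients:
ε₄₅₀ = 11300 M⁻¹cm⁻¹ for enzyme-bound oxidized FAD (used for FAO
quantification) and ε₄₁₀ = 106000 M⁻¹cm⁻¹ for cytochrome *c*. The
remaining defaults are documented assumptions, exposed for override:
ε₄₅₀(FlH₂) = 900, ε₄₅₀(FlSQ) = 4000, reduced-minus-oxidized Δε₅₅₀ = 21000
for the cytochrome, and ε₅₅₀(FlSQ) = 0 with a documented positive option.
All concentrations everywhere in the package are **post-mix** values: the
stopped-flow instrument mixes 1:1, so 36 µM tonometer enzyme is observed at
18 µM, and 80–160 µM syringe cytochrome at 40–80 µM.

## Numerical integration

`deSolve::lsoda` with relative tolerance 1e-8 and absolute tolerance
1e-12 M. Round-off can push concentrations a few 1e-15 M negative; values
above −1e-12 M (the tolerance scale, a millionth of a µM) are clipped to
zero and anything larger is treated as a solver failure and reported with
the offending parameters. Simulation time grids are log-spaced from
1/(50·k_fast) to 7/k_slow so that both kinetic phases are resolved
regardless of their separation; the default is 600–800 points per trace.

# Trace fitting

Traces are fit to one or two exponential phases by Levenberg–Marquardt
least squares (`minpack.lm`), with rates parameterized on the log scale so
they remain positive. Initialization combines "peeling" (fit the tail as a
single exponential on a log-linear scale, subtract, fit the early residual)
with a 5-point log-spaced multistart on the rates spanning the observable
window; the best residual wins. On noiseless synthetic data the fits
round-trip the generating parameters to better than 1e-6 relative (tested).
The faster phase is always reported as `k_obs1`, matching the convention
that the first electron transfer is the faster one.

Phase-count selection returns 2 only when the two-phase fit improves the
small-sample-corrected AIC by more than 10 **and** both amplitudes exceed 3
times the residual noise estimate; otherwise 1. The residual sum of squares
is floored at n·1e-20 AU² so that noiseless traces (RSS at machine
precision) do not produce unbounded criterion differences.

The bimolecular constant is the ordinary-least-squares slope of `k_obs`
against oxidant concentration. The intercept is retained rather than forced
through zero: the experimental convention is not stated, and a free
intercept absorbs the offset caused by oxidant consumption (below) without
biasing the slope. The fitted window is the full trace.

## Pseudo-first-order bias

The slope-equals-constant interpretation assumes oxidant excess. At the
experimentally accessible cytochrome regime (18 µM enzyme, 40–80 µM
cytochrome — only 2–4.4-fold excess) the oxidant is appreciably consumed
during the reaction, the apparent rates fall below k·[Cₒₓ]₀, and the
regressed slope **underestimates** the true constant (about −7% for a
10⁶ M⁻¹s⁻¹ scheme; reported published constants are therefore lower
bounds). `pseudoFirstOrderBias()` measures this by simulating exact
second-order traces, running the standard fit-and-regress procedure, and
comparing with the generating constant. The bias decays toward zero with
increasing excess, though not strictly monotonically: a small overshoot
(~+0.2%) appears near 10–20-fold excess before the limit is reached, which
is why the ladder test asserts monotonicity only to a 0.005 tolerance.

## Phase amplitudes at 550 nm

Each electron transfer delivers one electron to one cytochrome, so with
kinetically well-separated phases the 550-nm signal change splits 50/50
between the phases when the semiquinone does not absorb there. The split is
exact only in the separated-rates limit: decomposing C_red(t) for the
sequential system gives a fast-phase fraction of |k1 − 2k2|/(k1 − k2)/2,
which is 0.495 at 100-fold separation but 0.42 at the 7.6-fold separation
of a fast characterized enzyme. A positive ε₅₅₀(FlSQ) moves amplitude into
the first phase (the semiquinone appears with the first transfer and decays
with the second): with ε₅₅₀(FlSQ) = 5000 the fraction is ≈0.6, matching the
observed ~60/40 split at saturating cytochrome. The acceptance test
therefore checks the 50/50 claim on a 1000-fold-separated scheme (1%
tolerance) and the >50% semiquinone claim at both separations.

# Oxidant-preference classification

The published reasoning is verbal; `classify()` encodes it as explicit,
configurable thresholds so every verdict is auditable (each call carries a
rationale string naming the rule that fired):

| rule | default | basis |
|---|---|---|
| dehydrogenase: ratio ≥ `r_dehydro` | 100 | smallest observed dehydrogenase ratio ≈ 294; 100 leaves headroom |
| dual: `k_ox_O2` ≥ `k_oxidase_floor` and 1 ≤ ratio < 100 | 10^3.5 | between free flavin (~250 M⁻¹s⁻¹) and the bona fide oxidase range |
| oxidase: no cytochrome data and `k_ox_O2` ≥ `k_oxidase_strict` | 10⁴ | low end of typical flavoprotein oxidases (10⁴–10⁶ M⁻¹s⁻¹) |
| indeterminate | — | everything else |

The indeterminate class is deliberate, not a failure mode: it covers the
clade-1 pattern (near-free-flavin O₂ rate with only modest cytochrome
reactivity — the partners there are membrane-anchored diheme c₄
cytochromes, and solution assays plausibly underreport their activity) and
slow-O₂ enzymes with a TAT signal but no detectable cytochrome partner,
which may use an unknown periplasmic oxidant. `faoReferenceRates()` ships
the published constants for the characterized enzymes; the tests verify the
rule set reproduces every published verbal assignment.

# The genomic screen

Signal-peptide calls use transparent motif heuristics rather than a trained
predictor: TAT requires the [S/T]-R-R-x-Φ consensus within the first 35
residues followed within 25 residues by ≥6 consecutive hydrophobics; Sec
(mutually exclusive with TAT) requires a K/R in residues 1–7, ≥7
consecutive hydrophobics within residues 5–25, and an A-x-A cleavage motif
in residues 15–35. These rules are exactly testable and are what the
synthetic genomes plant; users screening real proteomes should expect lower
sensitivity than a trained predictor and can substitute one through the
`signal_fun` plug-in of `scanFaoContext()`.

Cytochrome evidence counts non-overlapping CXXCH heme-attachment motifs:
one motif at ≤130 aa is the prototypical ~11 kDa class I monoheme; two
motifs at 150–250 aa is a ~20 kDa diheme c₄-type. Other combinations
(e.g. one motif in a large protein) are conservatively reported as
`not_cytc` — a known limitation for unusual cytochromes. Fusions are
recognized as TAT-positive proteins of ≥450 aa with a CXXCH in the
C-terminal 150 residues.

"Adjacent" is quantified as ≤3000 bp between gene boundaries and ≤2
intervening genes, strand-agnostic with a same-strand flag in the evidence
(the qualitative description "immediately upstream and downstream" fixes
neither number; these defaults are configurable). Categories: green =
fusion; blue = TAT + adjacent cytochrome; red = TAT only; black = neither.

Pairwise identity uses an ends-free global alignment (BLOSUM62, gap open
10, extend 0.5) with identity = matches / aligned columns, internal gaps
counted and terminal gaps excluded; the convention of the original
deduplication tool is unknown, so this choice is documented rather than
inferred. Deduplication is greedy single-linkage in input order at the
>98% cutoff, hence deterministic.

# Ancestral reconstruction

The four categories evolve under an equal-rates Mk model: `alpha` is the
total rate of leaving the current state, each alternative entered at
`alpha/3`, giving the closed-form transition matrix
P_ii(t) = 1/4 + (3/4)·exp(−4αt/3). The root prior is uniform. Likelihood is
computed by Felsenstein pruning with per-node rescaling; marginal node
probabilities by the standard two-pass (inside/outside) algorithm. Both are
verified against brute-force enumeration over all internal-node state
assignments on trees of up to 6 tips (1e-10 tolerance). The rate is
estimated by 1-D ML on the log scale over [1e-6, 1e3]; an all-same-tips
dataset returns the lower bound with an explicit boundary flag.

For plotting and transition counting each internal node takes the argmax of
its marginal probabilities, with ties broken toward the parent's state
(preorder) and then lexicographically, so output is deterministic.
Transition counts over these argmax states approximate the number of
independent origins of each configuration; because marginal argmax
reconstructions are parsimonious relative to the true history, counted
transitions are expected not to exceed the true number of change events
(checked on simulated histories). A joint (max-sum) reconstruction would be
the exact alternative and is out of scope.

Branch-length units are whatever the input tree carries; `alpha` is per
unit branch length. Richer models (asymmetric rates, non-uniform root
priors) are deliberately not implemented.

# Synthetic data: what it does and does not emulate

* **Traces** come from the exact mechanism plus i.i.d. Gaussian absorbance
  noise (default σ = 0.002 AU when enabled). Real instruments add dead
  time, correlated drift and photobleaching; passing recovery tests here
  shows the estimator chain is correct, not that it is robust to instrument
  artifacts.
* **Genomes** are feature tables with random-composition proteins carrying
  planted motifs, written/read as minimal GenBank flat files. They make
  recovery exactly decidable (precision = recall = 1 expected); they say
  nothing about motif sensitivity on real proteomes.
* **Trees** are Yule trees with characters evolved by the same Mk process
  the reconstruction assumes, so parameter-recovery tests are
  well-specified by construction.

Every generator is reproducible from (config, seed) alone.

# Problem sizes

The shipped tests and the acceptance script run at desk scale by choice:
4-concentration titrations with 400–800-point traces, genomes of 4–12
planted operons, enumeration cross-checks on ≤6-tip trees, and
rate-recovery simulations on 64-tip trees. Field-scale analyses (thousands
of sequences, bootstrapped phylogenies, topology tests) belong to external
alignment/tree-inference tools and are not reproduced here.
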