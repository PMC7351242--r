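---
title: "Sampling gene regulatory networks across the whole fitness range"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling gene regulatory networks across the whole fitness range}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`grnland` studies a deliberately minimal model of transcriptional
regulation. A gene regulatory network (GRN) is a signed directed graph on
N genes with exactly K edges: `J[i, j] = +1` when gene j activates gene i,
`-1` when it represses it, `0` otherwise. Self-regulation is excluded, and
so is mutual regulation of any gene pair — which removes the textbook
bistability motif (mutual repression plus self-activation) on purpose, so
that any bistability that appears must be a collective property of many
genes. The mean degree is C = 2K/N.

Gene 1 is the input gene: it receives an external signal I. Expression
levels x_i in [0, 1] evolve in discrete time,

    x_i(t+1) = R( I(t) [i = 1] + sum_{j != i} J_ij x_j(t) ),
    R(x) = 1 / (1 + exp(-a (x - b))),

with steepness `a = 1` and threshold `b = 0` by default, so an unregulated
gene sits at the spontaneous expression 0.5. The response of gene i to a
constant input, `xbar_i(I)`, is the fixed point reached from the uniform
0.5 start (or the temporal average if the orbit does not converge; see
Numerical choices). The per-gene sensitivity is

    s_i = | xbar_i(1) - xbar_i(0) |,

the output gene is the non-input gene with the largest sensitivity, and
its sensitivity is the fitness f in [0, 1]: how sharply the network
distinguishes input "off" from input "on". Networks in which the input
fails to reach some gene, or in which some gene has no path to the
selected output, are discarded as structurally invalid, so every retained
gene participates in the function.

## Two readings of the response function

Two parameterizations of this response are in circulation for this model
family and are easy to conflate: the logistic form above with `a = 1`,
and the hyperbolic form `(tanh x + 1)/2`, which is the same logistic
function at steepness `a = 2` (at `a = 1` the logistic equals
`(tanh(x/2) + 1)/2`). The package keeps `a = 1` as the default and
exposes `a` everywhere. The choice matters quantitatively: at N = 32,
C = 5 essentially all structurally valid random networks have f < 0.2
under `a = 1`, whereas under `a = 2` the fraction is about 88%.

The high-fitness phenomenology, however, is only reachable at desk scale
under the `tanh` reading. Under `a = 1` the density of states falls
extremely steeply with f — biased Metropolis walks with selection
strength beta = 80 equilibrate near f = 0.06, and simulated annealing up
to beta = 3000 stalls near f = 0.35 — so the fittest ensemble
f in [0.99, 1] is out of reach for short runs. Under `a = 2` a short
annealed walk reaches f > 0.99 at
N = 16 within 1e5 moves, and the resulting networks show exactly the
expected phenomenology: step-like responses, clear hysteresis, toggle and
one-way switch classes. The bistability, noise-robustness and mutation
analyses in this vignette and in the package's acceptance checks
therefore use `dyn_params(a = 2)`; the landscape-shape statistics use the
`a = 1` default. Both readings are a single parameter apart, and every
analysis function accepts either.

## Multicanonical sampling of the fitness landscape

High-fitness networks are exponentially rare, so plain random sampling
cannot reach them. `grn_landscape()` uses entropic sampling, a
multicanonical Monte Carlo scheme: fitness is binned into 100 equal bins
over [0, 1] (the default; the last bin is closed) and the Markov chain is
weighted by `w(bin) = 1/Omega(bin)`, the reciprocal of the number of
networks per bin, so that visits spread nearly uniformly across bins and
the chain freely crosses regions that are astronomically rare under
uniform sampling.

The weights are learned by the Wang-Landau method (`wang_landau()`): a
random walk over structurally valid networks using the elementary move
"relocate one uniformly chosen edge to a uniformly chosen admissible empty
position" (K stays constant; the relocated edge gets a fresh random sign
by default, matching the generative symmetry of the random ensemble —
`fresh_sign = FALSE` carries the sign instead). After every attempted
move the current bin's running estimate of ln Omega is raised by a
modification factor, and rejected proposals update the current state's
bin, as Markov-chain correctness requires. The factor starts at ln f0 = 1
and halves whenever the visit histogram is flat (minimum at least 0.8 of
the mean); learning stops when it falls below `final_log_f` (1e-8 by
default; coarser values are perfectly usable because the measurement
stage corrects residual weight error through the histogram).

Two schedule details matter in practice and are this package's own
choices; Wang-Landau schedules are not standardized and vary by
application. First, a
stage only ends when the current stage has revisited *every* bin seen so
far: flatness judged over a sub-range would let the factor decay while
the walk is still expanding its range or sits trapped behind an entropic
bottleneck, freezing the weights prematurely. Second, the walk can be
seeded with a user-supplied network (`init`); the stationary law is
independent of the start, but a high-fitness seed lets the walk discover
the rare end of the range top-down, which is often much cheaper than
climbing.

Measurement (`entropic_sample()`) is fixed-weight Metropolis: one Monte
Carlo step (MCS) is K attempted moves, and a sample is recorded every 10
MCS to damp autocorrelation. The density of states is then
`ln Omega(bin) = ln hist(bin) + ln g(bin)`, normalized to unit total mass
over resolved bins (`estimate_density()`); bins never hit stay `NA`
rather than silently zero. Networks whose fitness falls in a requested
range (for instance the fittest ensemble f in [0.99, 1]) are retained as
full objects for downstream analysis.

On systems small enough to enumerate (`choose(N(N-1)/2, K) * 4^K`
networks), `exact_density_small()` computes the exact landscape by brute
force; the package's tests require the sampled estimate to match it to a
Kullback-Leibler divergence below 0.05, and the measurement stage under
exact weights to produce a flat histogram.

## Bistability, switches, and noise

`hysteresis_scan()` sweeps the input quasistatically: I rises from 0 to 1
in steps of 0.001, each relaxation seeded with the previous steady state,
then falls back symmetrically. A network is called bistable when the two
branches of the output differ by more than 0.01 anywhere — a deliberate
lower-bound heuristic: bistable windows narrower than the grid or
shallower than the threshold go undetected. The bistable interval's
position classifies the switch (`classify_switch()`): strictly inside
(0, 1) is a *toggle* (flippable in both directions), touching one
endpoint a *one-way* switch, covering both *unswitchable*.

`step_protocol()` runs the dynamics through I = 0 for 1000 steps, 1 for
1000, 0 for 1000, and judges whether the output *follows* the input: the
tail means (last 200 steps of each phase) must swing by at least 0.5 and
return to within 0.1. Following is often judged visually; these three
constants are explicit, tunable operationalizations chosen because
fittest networks respond nearly 0/1.
On sampled fittest ensembles the correspondence is almost exact in both
directions: nearly every toggle follows, and nearly every one-way or
unswitchable network is trapped by the wrong fixed point (in one
N = 16 harvest of 1278 fittest networks, 539 of 540 toggles followed
and only 2 of 738 non-toggles did).

`noise_protocol()` repeats the step protocol with noise: *input* noise
adds an independent uniform draw in [-0.3, 0.3] to I at every step (I may
transiently go negative — harmless); *internal* noise adds an independent
uniform draw in [-0.1, 0.1] to each transmitted expression per regulatory
pair and per step. Noise streams are fresh draws per step from the
session RNG; amplitude 0 reproduces the noiseless run bit for bit.
Followers keep following under noise (the bistable pair of fixed points
acts as a low-pass filter), and some trapped networks are released by
noise — the noise-induced response (NIR), flagged when a network follows
only with noise.

## Mutational robustness

All scans hold the input and output genes fixed, re-evaluate the mutant
fitness f' from the same uniform start, and restore the network
afterwards (the scans are non-destructive; mutants are *not* re-validated
structurally — a disconnected mutant simply scores whatever the dynamics
give). `edge_deletion_scan()` deletes each edge in turn; an edge is
*lethal* when f' < 0.9, a deliberately high threshold that is nearly
insensitive in practice because mutant fitness is strongly bimodal (near
the original f or near 0). `node_knockout_scan()` silences each
non-terminal gene (expression clamped to 0, row and column zeroed — the
minimal reading of a knockout as absence of the gene product; removal
from the graph would be an alternative, but for fixed-output evaluation
the two coincide). `edge_addition_scan()` tries every admissible empty
position with both signs, mirroring the deletion threshold as the
criterion for "keeps high fitness". Toggle switches without a lethal edge
(`tswole_filter()`) combine bistability with complete single-deletion
robustness.

## Motifs

`count_motifs()` censuses gene triples carrying exactly three edges —
necessarily triangles under the no-self, no-mutual constraints — into
feedback loops (directed 3-cycles) and feedforward loops, positive/
coherent when the sign product is +1 (even number of repressions),
negative/incoherent otherwise. Triples with fewer edges are ignored. The
census is validated against an independently written exhaustive check,
and a global sign flip provably swaps the positive and negative classes,
which the tests assert. In random ensembles +FBL matches -FBL and +FFL
matches -FFL (signs are fair coins); in fittest ensembles the balance
breaks toward +FFL and +FBL.

## Numerical choices

* Fixed-point detection: max-norm change below 1e-10 (default), far below
  the 0.01 bistability threshold and the 0.001 sweep step, with a budget
  of 5000 steps; non-converged orbits are flagged and averaged over the
  trailing 1000 steps. All three are `dyn_params()` fields.
* Output-gene ties break toward the lowest gene index (measure-zero for
  generic networks, possible for symmetric toys).
* Bin assignment: `bin = floor(f * n_bins)`, last bin closed; bistable
  interval endpoints are reported at grid resolution, with no bisection
  refinement.
* The sweep relaxes fully at every grid point (quasistatic limit).
* Seeding: all randomness flows through R's RNG (`set.seed()` gives exact
  reproducibility, including inside the compiled core); the pipeline
  derives per-stage seeds from one master seed so that adding analyses
  never perturbs earlier stages.

## What the synthetic conditions do and do not show

Everything here is exercised on the model's own synthetic ensembles — the
generator *is* the study system, not a stand-in for data. The desk-scale
problem sizes used by the tests (exact oracles at N = 4-5; landscape
learning and the fittest-ensemble analyses at N = 16, C = 5; random-mass
checks at N = 32, C = 5) were chosen so the whole suite runs in minutes
while still crossing the qualitative thresholds of the full-scale study;
the full N = 32 landscape with converged 1e-8 weights and about 5000
samples per bin across 100 bins is an overnight single-CPU run with this
core. Passing tests demonstrate internal correctness of the sampler
(against exact enumeration) and the model's emergent phenomenology;
they say nothing about real transcriptional networks,
whose interaction strengths, degrees and noise are far richer than unit
signs and uniform disturbances.

## A worked session

```{r, eval = FALSE}
library(grnland)
set.seed(7)

# exact landscape of a toy system, and the sampler against it
ex <- exact_density_small(5, 6)
w  <- wang_landau(5, 6)
s  <- entropic_sample(w, n_mcs = 1e5)
kl_divergence(ex, estimate_density(s, w))  # ~7e-4

# fittest ensemble at N = 16, C = 5 under the tanh reading
p2 <- dyn_params(a = 2)
land <- grn_landscape(16, connectivity = 5, params = p2,
                      control = wl_control(final_log_f = 1e-3,
                                           max_proposals = 2e7),
                      n_mcs = 6e4, n_runs = 1, keep_range = c(0.99, 1))
nets <- land$samples$networks
scans <- lapply(nets, hysteresis_scan, params = p2)
table(vapply(scans, classify_switch, character(1)))
```
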