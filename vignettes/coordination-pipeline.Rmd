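---
title: "From EEG epochs to coordination prediction: methods and design choices"
author: "coordwalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From EEG epochs to coordination prediction: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coordwalk)
```

# The scientific question

Two players of a tacit coordination game succeed when they pick the same
option from a small set without communicating. The hypothesis behind this
pipeline is that the *spatial* organization of each player's EEG during
the decision — which scalp regions synchronize with which — carries a
signature of the choice process, so that two players who converged on the
same option show more similar synchronization topographies than two who
did not. The pipeline turns each player's epoch into a graph-valued
summary of that topography, compares players pairwise, and asks a
classifier to recover the coordination outcome. A second-level analysis
then relates classification quality to the game's difficulty.

# The coordination index

For one game with $N$ players, let $m_j$ be the number of players who
chose option $j$. The coordination index is

$$\mathrm{CI} \;=\; \frac{\sum_j m_j\,(m_j-1)}{N\,(N-1)},$$

the probability that two randomly drawn distinct players chose the same
option: 1 under unanimity (easiest game), 0 when no two players agreed.
`compute_ci()` implements it and is tested against the literal
pair-counting definition on random tallies. For multinomial choices with
option probabilities $p_j$, $E[m_j(m_j-1)] = N(N-1)p_j^2$, so
$E[\mathrm{CI}] = \sum_j p_j^2$ — the identity used to check the choice
generator (uniform choice over four options gives exactly 1/4).

# Signal chain

Each raw epoch is a 16-channel, 512 Hz, 1 s window (electrodes in a fixed
10–20 montage order; `montage_labels()`). The chain in
`preprocess_epoch()` is:

1. **Band-pass 1–32 Hz.** 4th-order Butterworth applied
   forward–backward (`signal::filtfilt`), so the passband is preserved
   with zero phase shift. The band covers delta through beta.
2. **Artifact hook.** A pass-through slot where ICA-style artifact
   removal would act on real recordings. The synthetic generator produces
   no ocular/muscular artifacts, and component rejection is inherently
   manual and data-dependent, so no ICA is bundled; the hook keeps the
   chain's position for it explicit.
3. **Common average reference** — every time point has zero mean across
   channels — then **baseline correction** over the full epoch (the
   synthetic design has no pre-stimulus segment, so the whole window is
   the only defensible baseline). Both are idempotent projections and the
   whole chain is linear, two properties the test suite checks directly.
4. **Downsampling to 64 Hz** via `signal::decimate` (8th-order Chebyshev
   anti-alias filter, forward–backward). Note that the 32 Hz band edge
   coincides with the post-decimation Nyquist frequency, so content right
   at 32 Hz is additionally attenuated; everything at or below ~28 Hz
   passes cleanly, which the sinusoid tests quantify.

The output is the first second at 64 Hz: a 16 × 64 analysis window.

# Coherence graphs

`pairwise_coherence()` estimates the magnitude-squared coherence (MSC)
between every channel pair by Welch's method: Hann-windowed 32-sample
segments with 50% overlap (three segments per 64-sample window), averaged
over the frequency bins in 1–32 Hz (bins at 2, 4, …, 32 Hz) to a single
scalar in $[0,1]$ per pair. MSC is invariant to channel sign and scale.
Choices made here, all config-exposed:

* **Band mean, not maximum.** One scalar per pair is required; the band
  mean is stable under the small segment count, whereas a maximum over
  bins inflates with estimator noise.
* **Known small-sample bias.** With three overlapping segments the MSC of
  two *independent* channels does not concentrate at 0; its band-averaged
  value sits near 0.34 (measured by simulation in the tests). This bias
  is well below the 0.5 edge threshold, which is what makes the binary
  graph meaningful; the tests pin the fraction of spurious edges on
  independent channels below 20%.

`threshold_graph()` sets an edge where coherence ≥ 0.5 — inclusive at the
boundary — excluding self-loops (a signal's coherence with itself is
always 1). A 16-node graph has at most $\binom{16}{2}=120$ edges and node
degree at most 15. Lowering the threshold can only add edges
(monotonicity, tested).

# Anonymous-walk embeddings

A walk on the graph visits nodes; its *anonymous* pattern replaces each
node by the order of first appearance (F3, Cz, F3, Pz → 1, 2, 1, 3). The
embedding of a graph is the probability distribution over all anonymous
patterns of $l$-step walks under the law: start node uniform over
non-isolated nodes, each step uniform over the current node's neighbors.

Conventions fixed here:

* **Length = steps.** An $l$-step walk has $l+1$ node entries. The number
  of patterns equals the Bell number $B(l)$ — 1, 2, 5, 15, 52, 203 for
  $l = 1\ldots 6$ — so the default $l = 5$ gives 52-dimensional
  embeddings. The test suite re-derives these counts from the Bell
  triangle.
* **Canonical order.** Patterns are enumerated lexicographically once;
  that order indexes every embedding vector and CSV header
  (`pattern_labels()`, e.g. `"1-2-1-3-2-4"`).
* **Exact by default.** The distribution is computed exactly by
  recursive traversal of the walk space in compiled code with
  incremental pattern encoding (at $n=16$, $l=5$ the space is at most
  $16 \cdot 15^5 \approx 1.2\times10^7$ walks). A sampling mode
  (`mode = "sampled"`) exists for parity with the sampling formulation of
  the method; tests verify total-variation convergence of sampled to
  exact and equality of the exact kernel with brute-force enumeration on
  all small graphs.
* **Degenerate graphs.** An edgeless graph admits no walks and embeds to
  the zero vector rather than an error; any graph with one edge embeds to
  a proper probability vector.
* **Isomorphism invariance.** Relabeling nodes leaves the embedding
  unchanged (tested by permuting adjacency matrices). This is the
  embedding's point — it compares *shapes* of connectivity — and it has a
  consequence for the synthetic generator discussed below.

`tune_walk_length()` reproduces the grid-search procedure for $l$: embed,
classify, and keep the candidate with the best cross-validated F1, ties
to the shorter walk. The candidate set is an argument, since no canonical
set exists.

# Pair dataset and classifier

For each of the $\binom{n}{2}$ player pairs and each game, the
observation is the elementwise absolute difference of the two embedding
vectors, labeled 1 exactly when the two players chose the same option —
with 10 players and 12 games, 45 × 12 = 540 observations
(`build_pair_dataset()`).

`train_predict_cv()` evaluates an XGBoost binary classifier under
stratified $k$-fold cross-validation ($k = 3$ by default; per-class fold
sizes differ by at most one). Every observation receives exactly one
out-of-fold probability; probabilities are thresholded at 0.5. The
booster hyperparameters — 100 trees, depth 3, learning rate 0.3, single
thread — are deliberately stock values, exposed in `cv_config()`; no
hyperparameter search is performed beyond the walk length. Undefined
metrics (0/0) are reported as `NA`, never coerced to 0
(`class_metrics()`).

Per-game positive-class recall, precision and F1 are computed from the
pooled out-of-fold predictions (`per_game_metrics()`), keeping the raw
fractions alongside the ratios. Pooling across folds before the per-game
split is a documented choice; computing per fold and averaging would
leave 2–7 positives per (game, fold) cell and mostly undefined metrics.

`metric_vs_ci_regression()` fits ordinary least squares of a per-game
metric on CI and reports slope, intercept, Pearson r, and the two-sided
$t$-test p-value for zero slope on $n-2$ degrees of freedom. For simple
regression this test coincides with the correlation test, so the
distinction does not matter here. `f1_spread()` summarizes per-game F1
dispersion as $(\max-\min)/\max \times 100$ — the normalization that
reproduces the reference study's printed spread from its printed F1
values, which is how it was disambiguated.

# The synthetic-study generator

`generate_study()` emulates the design the pipeline assumes: `n_players`
= 10, `n_games` = 12, `n_options` = 4, 16 channels at 512 Hz, 1 s epochs
— 120 epochs per study.

**Choices.** Player choices are independent draws from a single-focal
categorical: the focal option (always option 1) has probability
$s_g + (1-s_g)/4$, the rest share the remainder. The per-game saliency
vector defaults to `seq(0, 0.5, length.out = 12)`, chosen once so the
expected same-choice probability spans roughly 0.22–0.44 — the CI range
the reference study reported (0.178–0.444). A single-focal family cannot
produce CI below the uniform value $\sum p_j^2 = 0.25$ in expectation;
games below that arise only through sampling dispersion, which at
$N = 10$ is substantial.

**Epochs.** For every (game, option) the generator draws a partition of
the 16 channels into modules of size 2–6 (possibly one leftover
singleton). Channels in module $m$ carry
$x_i = \sqrt{\rho}\, z_m + \sqrt{1-\rho}\,\sigma\, n_i$ with one shared
band-limited (1–32 Hz) Gaussian source $z_m$ per module and independent
band-limited noise $n_i$; singletons are pure noise. Intra-module MSC is
then $\rho^2$ for $\sigma = 1$ (≈ 0.81 at the default $\rho = 0.9$),
increasing in $\rho$, while inter-module MSC is the estimator bias floor
regardless of $\rho$ — so the thresholded graph of a strong-coupling
epoch is the union of the template's cliques. Players who chose the same
option in a game share a template; their graphs, and hence embeddings,
agree up to estimator noise.

**Why templates differ in block sizes, not just in membership.** The
anonymous-walk embedding is isomorphism-invariant, so two partitions with
the same multiset of block sizes produce *indistinguishable* embeddings
even if they group different channels. Templates for different options of
one game are therefore required to differ in their block-size profile;
otherwise the generator would build in no recoverable choice signal and
the same-choice-similarity property could not hold by construction. With
very few channels the distinct profiles can run out, in which case the
generator falls back to distinct labeled partitions.

**Randomness.** All streams derive deterministically from the master
seed, split per (player, game, stage), so any subset of the study is
reproducible in isolation and `run_pipeline()` reruns are byte-identical.

**What the generator does not emulate** — and what passing tests
therefore do not show about real data: 1/f spectra, ocular and muscle
artifacts, volume conduction (which inflates neighboring-electrode
coherence), inter-subject variability in montage fit, and any genuine
neural correlate of decision-making. The generator validates the
*pipeline* — that the statistics recover structure that is present — not
the neuroscientific hypothesis.

# Behavior under the null, and leakage

With $\rho = 0$ the epochs carry no choice information, and the
out-of-fold AUC should hover near chance. It sits slightly above 0.5 on
average rather than exactly at it, for a structural reason: observations
are not independent. Each player's embedding enters nine pairs per game,
and labels of pairs sharing a player are correlated, so a flexible
classifier can exploit player identity leaking through shared feature
components. This is a property of the pair design itself (the default
folds stratify by class only, matching the original design);
`make_folds()` is the place a group-by-player scheme would plug in. The
acceptance checks bound the null AUC in $[0.4, 0.6]$ in the mean over
ten replicate studies.

# Problem sizes and runtimes

The test suite and the acceptance script use: full-size studies
(10 × 12 × 16 × 512) for the parameter-recovery and determinism checks —
ten seed replicates per condition for recovery; 500 two-channel epochs
for the coherence-bias measurement; brute-force walk enumeration up to
$n = 6$, $l = 4$; $10^5$ sampled walks for the convergence check. These
sizes put every stochastic assertion's Monte-Carlo error well inside its
asserted margin while keeping a full run in minutes on one CPU.

# Known limitations

* The single-focal choice model cannot generate games whose *expected*
  CI is below the uniform floor; bimodal-saliency games are outside its
  family.
* The Welch estimator with three overlapping segments has a high bias
  floor (~0.34); with a different epoch length or segment scheme the 0.5
  threshold's meaning changes, which is why the estimator settings are
  pinned in the coherence module rather than left free.
* EDF input/output is not provided; epochs interchange as delimited
  numeric matrices plus a manifest. Real-data users must convert their
  recordings to matrices (channels × samples) upstream.
* With very small cohorts, stratified 3-fold cross-validation fails by
  design when a class has fewer than three members; the error is
  explicit rather than silently degrading to fewer folds.
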