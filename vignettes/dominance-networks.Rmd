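---
title: "Inferring dominance hierarchies and temporal social networks from dyadic interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring dominance hierarchies and temporal social networks from dyadic interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dominet)
```

## The analysis problem

Small groups of socially complex animals — the motivating case is a captive
group of five female carrion crows observed over five roughly monthly video
sessions — produce streams of dyadic interaction records: at some moment in
a session, one identified individual directs a behaviour at another. Three
questions recur in behavioural ecology:

1. **Who dominates whom?** Infer a dominance hierarchy per observation day
   from the agonistic interactions (each with a winner, a loser, or a draw).
2. **Who interacts with whom, and how much?** Summarise each session as
   directed, weighted networks of agonistic and affiliative interaction
   rates.
3. **Are relationships stable?** Test whether individuals keep directing
   behaviour at the same partners from one session to the next.

`dominet` implements this pipeline end to end, together with a simulator
that generates data with the same statistical structure and a known ground
truth, so every inferential step can be validated.

## Data model

A dataset is two tables plus an ethogram. The *interaction table* has one
row per observed event: `session_id`, `order_index` (within-session temporal
order), `initiator_id`, `recipient_id`, `behaviour_code`, `outcome`. The
*session table* gives each session's date, duration in hours, and roster of
individuals present (individuals can be absent from some sessions — the
motivating group had one bird removed for health reasons and later
reintroduced). The *ethogram* maps every behaviour code to `agonistic`,
`affiliative`, or `ambiguous`.

Validation enforces the contracts downstream code relies on: known codes,
initiator ≠ recipient, rosters covering all participants, outcomes present
exactly for agonistic records, and strict temporal order. Ambiguous records
are retained and flagged but excluded from all analyses; draws remain
records (a draw is still an interaction and contributes to network edges)
but carry no winner, so they are excluded from both hierarchy methods.

## Dominance by randomized Elo-rating

Elo-rating treats each decided agonistic interaction as a contest. All
individuals start at $S_0 = 1000$; after a contest the winner receives and
the loser forfeits

$$\Delta = k \,\bigl(1 - p_{\text{win}}\bigr), \qquad
p_{\text{win}} = \frac{1}{1 + e^{-(S_w - S_l)/\sigma}},$$

with $k = 100$. The update is zero-sum, and an upset (low-rated beats
high-rated) moves scores more than an expected win. The expectation scale
defaults to $\sigma = 400/\ln 10 \approx 173.7$, the classic convention
under which a 200-point gap yields $p \approx 0.76$. A fixed-transfer
variant ($\Delta = k$ always) is available via `elo_config(update =
"fixed")` because the verbal description "points gained or lost each time
set to k" admits that reading; the expectation-weighted update is the
default since it is what the standard Elo literature and the animal-
dominance packages implement. Draws are excluded by default; a half-credit
update (`draw_credit = TRUE`) is provided for the sequential trajectory
function.

Because scores depend on the order in which contests are processed, and
individuals interact at very different rates, `randomized_elo()` recomputes
the final scores over 1000 uniformly random permutations of the day's
contest order and averages them. Permutations are drawn sequentially from
one seed, so permutation $j$ is identical for any number of randomizations
$\ge j$; results are exactly reproducible and the Monte-Carlo stream does
not depend on how many randomizations are requested. The permutation loop
runs in compiled code; the exported pure-R `run_elo_sequence()` is the
reference implementation against which the compiled path is tested.

Rankings order individuals by descending mean score; exact ties (which can
occur in tiny datasets) break by total wins, then identifier, and are
flagged.

## Dominance by David's scores

David's score is an order-independent index computed from the win-loss
matrix. With $n_{ij}$ interactions between $i$ and $j$ of which $i$ won
$w_{ij}$, the dyadic proportion is $P_{ij} = w_{ij}/n_{ij}$ and the
chance-corrected index is

$$D_{ij} = P_{ij} - \frac{P_{ij} - 0.5}{n_{ij} + 1},$$

which shrinks extreme proportions from sparsely observed dyads toward 0.5.
Non-interacting dyads contribute zero. Then $w_i = \sum_j D_{ij}$,
$w2_i = \sum_j D_{ij} w_j$, $l_i = \sum_j D_{ji}$,
$l2_i = \sum_j D_{ji} l_j$, and

$$DS_i = w_i + w2_i - l_i - l2_i, \qquad
normDS_i = \frac{DS_i + N(N-1)/2}{N} \in [0,\, N-1].$$

$\sum_i DS_i = 0$ holds identically. Both the corrected and the raw-$P$
variants are reported. `compare_rankings()` correlates Elo mean scores with
$DS$ (Pearson, with the two-sided $t$-transform p-value) and the two rank
orders (Spearman); because it is not knowable whether published comparisons
of this kind used scores or ranks, per day or pooled, the pipeline reports
per-day comparisons and a pooled comparison over all session-individual
pairs.

## Interaction networks and QAP consistency

For each session and each category, `build_network()` forms the directed
adjacency matrix of counts (initiator = row, recipient = column; draws
included) and divides by the session duration, giving interaction rates per
hour so sessions of different lengths are comparable. Nodes are ordered by
the session's dominance ranking (attribute-ordered networks).

Consistency through time is tested with a quadratic assignment procedure.
The *graph correlation* between two networks on the same individuals is the
Pearson correlation over corresponding off-diagonal cells (the diagonal is
structurally zero and excluded). The QAP null distribution relabels the
individuals of the second network — jointly permuting its rows and columns,
which preserves its internal structure — and recomputes the correlation.
In sampled mode (default, 1000 permutations) the one-tailed p-value is
$(\#\{r_{\text{null}} \ge r_{\text{obs}}\} + 1)/(n + 1)$, counting the
identity arrangement so p is never zero; `p_lesser` is reported
symmetrically, with `p_greater` the headline tail since temporal
consistency means positive association. In exact mode all $N!$ relabelings
are enumerated ($N \le 8$) and p-values are exact proportions. Only
networks with identical rosters are compared — a session observed before a
reintroduction (4 birds) is not comparable to one after it (5 birds) — and
`consistency_report()` tests consecutive pairs by default (all pairs behind
a flag), listing skipped pairs with the reason.

Numerical details worth stating: null-vs-observed comparisons use a
$10^{-12}$ tolerance so algebraically tied correlations (e.g. automorphic
relabelings) count as ties; a network with zero off-diagonal variance has
no defined correlation and the pair is reported as skipped rather than
silently dropped; and because Pearson correlation is scale-free, QAP
results are invariant to the duration normalization (tested as a property).

## The simulator and what it does (not) emulate

`group_params()`/`simulate_group()` generate data matching the statistical
structure the analysis assumes, with ground truth for validation. Defaults
encode the motivating study's conditions and are not tuning knobs:

* **5 individuals** named by colour band (`red` … `grey`), latent abilities
  on a logit scale spaced 2.2 apart with `steepness = 1`, so the
  higher-ranked bird of an adjacent dyad wins a decided contest with
  probability `plogis(2.2)` $\approx 0.90$ — a steep hierarchy with an
  uncontested top individual.
* **5 sessions of 3.2 h** at ~27-day intervals, matching the observed mean
  video length (≈193 min).
* **Per-session counts** drawn from a zero-truncated normal rounded
  half-up, agonistic mean 131.8 / SD 111.7 and affiliative mean 44.6 /
  SD 13.1 (the observed per-video rates). Because the SD is comparable to
  the mean, a Poisson model would be badly underdispersed, and naive
  truncation of a normal at zero would inflate the realized mean (to ≈157
  for the agonistic rate); the underlying location is therefore adjusted
  (by solving the truncated-mean identity) so the *realized* mean equals
  the stated rate. The realized SD is consequently somewhat below the
  nominal SD — the price of calibrating the mean.
* **Initiation bias**: ordered dyads are sampled with probability
  proportional to $(w_i w_j)^{b}$, where $w$ is a descending rank weight
  and $b = 2$, concentrating interactions among dominants as observed.
  Affiliative interactions are confined to the top three present ranks,
  mirroring their near-exclusive exchange among the dominant birds.
* **Draws** occur with probability 0.05; the observed draw rate is not
  reported anywhere we can calibrate to, so a realistic low rate was fixed
  once.
* **Roster dynamics**: `grey` is absent from sessions 1–2 and reintroduced
  from session 3; an ability shift raises `green` above `blue` for session
  4 only, reproducing a temporary mid-hierarchy rank switch.

The generator is deterministic given its seed (byte-identical tables). It
does **not** emulate behavioural sequences (recruitment, chases as multi-
event bouts), coalitionary attacks, vocalisations, spatial structure,
temporal autocorrelation within a session, or observer error; passing
recovery tests on these data shows the estimators work under the assumed
sampling model, not that real observation noise is harmless.

## Validation experiments

`recovery_experiment()` simulates replicate datasets, runs randomized Elo
and David's scores per session, and scores exact recovery of the latent
ability order plus rank agreement between the two estimators. The
headline experiment uses the steep hierarchy at a fixed 132 decided
contests per session with *uniform* dyad sampling (`initiation_bias = 0`),
isolating the effect of hierarchy steepness and sample size; under these
conditions exact recovery exceeds 95% and the Elo/David's Spearman
agreement exceeds 0.9. This uniform-sampling choice is deliberate: under
the default initiation bias the bottom-ranked dyad receives well under one
interaction per session, so the order of the two most subordinate birds is
statistically unidentifiable from ~130 events — a sampling limitation of
skewed interaction data worth knowing about, not an estimator defect.

QAP calibration is validated two ways: sampled p-values agree with full
enumeration within binomial error (N = 4 and 5), and on independent random
networks the test rejects at $\alpha = 0.05$ at its nominal rate
(±0.02 over 1000 replicates).

Problem sizes used by the test suite and the acceptance script — one
session-series per pipeline run, 100 recovery replicates, 1000 QAP
type-I replicates at 1000 permutations each — were chosen as the smallest
sizes at which the binomial/Monte-Carlo error bands above are meaningful.

## Known limitations

* Elo and David's scores assume independent dyadic contests; winner-loser
  effects and coalitionary support (two birds attacking one) violate this
  and are not modelled.
* With fewer than ~10 decided contests per individual, rankings below the
  top of the hierarchy are unstable; the randomization SD in
  `summary.elo_result()` is the diagnostic to inspect.
* QAP compares networks on identical rosters only; it cannot quantify
  consistency across a membership change, which is reported as a skipped
  pair rather than estimated.
* Hierarchy steepness and linearity indices are out of scope.
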