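---
title: "Error-driven discrimination learning of number words"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-driven discrimination learning of number words}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numlearn)
library(dplyr)
```

## The problem

Children hear number words constantly, yet learning which word matches
which quantity takes years. `numlearn` treats this as a *discrimination*
problem: a set of three balls offers the learner many candidate cues —
its numerosity, but also its color, shape and size, and the numerosities
of all the smaller sets nested inside it — and the learner must discover
which cue reliably predicts "three". The package simulates that process
with an error-driven associative learner and a synthetic "number world"
whose statistics mirror a child's linguistic environment, and provides
read-outs that mirror how number knowledge is tested behaviourally.

## The learning model

The learner maintains a matrix $V$ of predictive values indexed by
(cue, outcome). After each discrete learning event with cue set $C$ and
outcome set $O$, every pair of a present cue $c \in C$ and a lexicon
outcome $o$ is updated by the Rescorla–Wagner discrepancy rule

$$\Delta V(c, o) \;=\; \alpha\,\beta\,\Big(\lambda_o - \sum_{c_j \in C} V(c_j, o)\Big),
\qquad
\lambda_o = \begin{cases}\lambda & o \in O\\ 0 & o \notin O,\end{cases}$$

with all deltas computed from the pre-update state (simultaneous update;
a sequential within-trial scheme would make results depend on arbitrary
cue order). Three properties of this rule carry the whole analysis:

* **Negatively accelerated, asymptotic learning.** With constant
  reinforcement, total prediction approaches $\lambda$ along
  $\lambda(1-(1-\alpha\beta)^t)$; `rw_train()` reproduces this closed
  form to machine precision because both are the same recurrence.
* **Cue competition.** Co-present cues share one finite asymptote, so a
  reliable cue strips value from unreliable ones (blocking,
  overexpectation). This only operates when several cues are present
  at once — the Feature-to-Label (FL, postnominal) arrangement.
* **Unlearning from absence.** When a predicted outcome fails to occur,
  $\lambda_o = 0$ and the discrepancy is negative: cues with a high
  *background rate* are actively devalued. The lexicon
  (`known_outcomes`) is fixed before trial 1 and every member is updated
  on every trial; pairs at zero prediction receive a zero delta, so this
  is safe, and it is what lets rare words be learned *about* on trials
  where they do not occur.

### Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `alpha` | cue saliency, unitless in $[0,1]$ | 1 | set to 1 so relative cue value is shaped by informativity alone |
| `beta` | learning rate, unitless in $[0,1]$ | 0.2 | the single free parameter, held constant everywhere |
| `lambda` | outcome asymptote | 100 | a percentage-like 0–100 scale, so weights read as "percent of full prediction" |

Weights may go negative (net inhibition) and are never clipped: the
unlearning account depends on downward movement, and the equilibrium
solution for nested cues *requires* inhibitory weights (see below).

### A stability bound worth knowing

On a trial with $n$ co-present cues, the summed prediction for each
outcome moves by the factor $1 - n\alpha\beta$. The dynamics are stable
only while $|1 - n\alpha\beta| < 1$, i.e. $n < 2/(\alpha\beta)$. At the
default rate this means **at most 9 co-present cues**: a set of 10 or
more objects under the nested coding makes training oscillate
divergently. This bound, not memory or run time, is what limits the
training domains used by the simulation drivers (all stay at 9 cues or
fewer: 7 numerosity cues plus 2 feature cues at worst).

## The number world

`encode_set()` translates an object set into cues. Numerosity coding is
purely *nested*: a set of $n$ objects activates `num1 … numN`, so the cue
to one is present in every set and larger sets are strict supersets of
smaller ones. This is the minimal structure consistent with a learner who
can tell objects apart and can tell "part of a larger set" from "not",
and the nesting is the engine of the whole analysis: it makes larger sets
progressively more confusable, while the unique top cue `numN` is the
only perfectly reliable signal. No "exactly-$n$" summary cue is added.
Enabled feature dimensions contribute one `dimension:value` cue each.

`make_trial()` arranges the same event in two temporal orders: FL
(cues = encoded set, outcome = number word; postnominal phrasing) or LF
(cue = the word, outcomes = the encoded set; prenominal). They are exact
mirrors, and `mirror_trials()` converts a whole stream.

`build_schedule()` composes training streams in three modes: `equal`
(balanced, cyclically interleaved; a remainder is given to the smallest
sizes), `weighted-deterministic` (largest-remainder apportionment of
trial counts to weights — composition is within one trial of exact
proportionality — followed by a seeded shuffle), and `weighted-sampled`
(independent draws; used where a tiny block of trials cannot meaningfully
honour a distribution, as in the 18-trial baseline continuations).
Feature values rotate against labels on a mixed-radix walk of the
3×3×3 color–shape–size grid, per label, so every value co-occurs with
every label as evenly as divisibility allows and no feature value
predicts any label with conditional probability above 0.5. Pool sizes
(3 values per dimension) are a design choice: large enough that features
are plausible competitors, small enough that they recur and generate
error.

## The environment's statistics

The package embeds the published spoken frequencies of the number words
one–seven in English and Spanish (tokens per million; the Spanish entry
for 1 is the published weighted estimate, carried exactly as printed).
Frequency of mention is the proxy for how relevant each set size is in a
child's world. Two analyses are built on it:

```{r corpus}
fq <- number_word_frequencies()
crosslang_correlation(fq)
fit <- fit_inverse_power(number_word_frequencies("english"))
fit
```

The cross-language Pearson correlation of the relative frequency
profiles is 0.999 — the distributional shape is shared, not a quirk of
English. The decline with quantity is well described by an inverse power
function $f(n) = a\,n^{-b}$, fitted by ordinary least squares in log–log
space (the simplest estimator consistent with a power-law form; the
exponent is invariant to rescaling). `natural_weights()` splices the
observed counts for 1–7 with the fitted extrapolation for 8–20. One
honest wrinkle: the observed count for seven (87) sits *below* the
fitted trend, so the extrapolated weight for eight (≈105) is slightly
above it; within 8–20 the extrapolation decreases strictly.

## Read-outs

`activate()` sums weights of present cues per label — exactly additive,
linear in $V$. Three discrimination scores are offered because the
learned state supports genuinely different questions:

* **`relative`** (default): the correct label's positive-part activation
  from a featureless size-$n$ stimulus, normalised by the summed
  positive-part activations of all competing labels. Discrimination as
  *competition among labels*; scale-invariant; 0 on an empty state.
  Featureless probes are used so feature cues cannot leak information.
* **`raw`**: the single weight $V(\mathrm{num}_n, \mathrm{word}_n)$ —
  the raw mapping-value view of learning curves.
* **`cue_share`**: the correct set-size cue's positive-part share among
  all cues to its label. Discrimination as *informativity of the
  correct cue among its competitors*. This is the read-out under which
  unlearning erroneous competitor cues registers as improvement even
  when the correct cue is never touched, which is precisely the
  mechanism of the facilitation result (below).

Nesting has a consequence worth internalising: a merely "one-hot"
matrix ($V(\mathrm{num}_n,\mathrm{word}_n)=\lambda$, all else 0) does
*not* discriminate — a four-array contains `num2` and so activates "two"
just as strongly. Perfect discrimination requires the equilibrium
solution with inhibitory next-size weights
($V(\mathrm{num}_{n+1},\mathrm{word}_n)=-\lambda$), which is exactly
what error-driven learning converges toward and why negative weights are
never clipped.

`forced_choice()` mirrors a three-alternative behavioural test: each
candidate array is scored by the activation it lends the target word;
`argmax` breaks ties uniformly at random, `luce` samples proportionally
to positive parts. An all-zero state yields a three-way tie on every
trial, so chance is exactly 1/3:

```{r chance}
V0 <- rw_matrix(paste0("num", 1:6), number_word(c(2, 4, 6)))
forced_choice_accuracy(V0, c(2, 4, 6), n_trials = 10000, seed = 1)
```

## The three simulations

**Sequencing (`run_sim1`).** Sets of 2, 4, 6 with color/shape/size
competitors, equal frequency, 600 trials (200 per size — ample for
asymptote at $\beta=0.2$; the run length is a package choice, declared in
the result's config). The FL and LF arms consume mirrored streams with
identical event content. FL cue competition devalues the features to
nearly zero and the top set-size cue dominates; the LF learner, with the
word as its only cue, converges on conditional co-occurrence
probabilities $\lambda\,P(\text{feature}\mid\text{label})$ and competing
activations keep interfering at test. Final relative scores: FL ≈ 1 for
every size against LF at 1/3–1/2.

**Subitization (`run_sim2`).** Sets 1–7, numerosity cues only, 1000
trials apportioned to the spoken-frequency weights, snapshots every 10;
a comparison arm trains sizes 1–8 with equal frequency. Small sets are
discriminated almost immediately; the largest, rarest sets lag (size 7
is still the worst-discriminated size at trial 500), and the
equal-frequency arm flattens the spread by an order of magnitude — the
gradient comes from the environment plus the nested code, not from any
capacity parameter. Two caveats, both consequences of exact
Rescorla–Wagner dynamics under these conditions: by 1000 trials even
size 7 approaches ceiling, so the gradient is a *rate* difference rather
than a permanent deficit; and within a 1–7 training domain the
trials-to-half-maximum index is not strictly monotone in $n$ (size 6
profits from `num6` being nearly unique to six-or-larger sets, which are
rare). A training domain extending well beyond 7 would supply the
background error that keeps 6 and 7 down, but it is unreachable at the
default learning rate because of the stability bound above — an
instructive limitation of the printed parameterisation, not of the
implementation.

**Facilitation (`run_sim3`).** Both arms share 110 pretraining trials on
the natural distribution of sets 1–7 with shape and size competitors
(two dimensions, keeping the worst case at 9 co-present cues). The
treatment arm then receives `fl_blocks(6)`: six postnominal blocks of
2, 4, 6 — one item kind per block, small to large, 18 trials. The
baseline arm instead continues with 18 natural-frequency trials,
sampled under five distinct seeds whose learned states are averaged.
Improvement is score(128) − score(110), by design measured with the
`cue_share` metric: the blocks never present 5 or 7, so their correct
cues are (almost) untouched, and the entire effect consists of the
erroneous competitors to "five" and "seven" — smaller numerosity cues
and object features with high background rates — being unlearned,
raising the correct cues' predictive share. A stimulus-normalised score
cannot register this (the trained labels' activations grow and crowd the
denominator), which is why the metric choice is substantive, not
cosmetic; the other metrics remain available via the `metric` argument.

```{r sim3}
sim3 <- run_sim3()
tidy(sim3) |> filter(set_size %in% c(5, 7))
```

The treatment improvement exceeds the averaged baseline for both
untrained sizes, and beats each of the five individual baseline
continuations.

## Numerical choices, degenerate inputs, reproducibility

* Deterministic streams are checked at 1e-9 absolute on the 0–100
  scale; long-run stochastic or cycling estimates at 1.0 (asymptote) to
  2.0 (per-feature conditionals).
* Rotating or alternating event structures put single-cue weights in a
  stable limit cycle (alternating reinforcement at $\beta=0.2$ cycles
  between ≈44.4 and ≈55.6 around 50); the converging quantity is the
  time average, so asymptote read-outs use `tail_mean_state()` over a
  trailing window covering whole rotation cycles.
* Argmax ties are broken uniformly at random under the caller's seed;
  the Luce rule falls back to uniform when no activation is positive.
  Normalised scores return 0 on an all-non-positive denominator.
* Trials with no outcome (extinction) are legal; trials with no cue are
  not. Outcomes absent from the fixed lexicon, NaN/Inf states, and
  cue/outcome namespace collisions raise errors.
* Every stochastic step (schedule shuffles, sampled schedules, tie
  breaks, Monte-Carlo testing) flows through an explicit seed;
  rerunning any driver with the same configuration is bit-identical.

## What the generator does and does not emulate

The number world captures the statistics the analysis needs: nested
numerosity information, unreliable object features, power-law set-size
frequencies, and the two temporal arrangements of label and scene. It
deliberately omits perceptual noise (no Weber-fraction confusability —
confusability here is structural, from cue overlap), social and
attentional cues, polysemy and mislabelling (mislabelled events are
constructible but unused by the headline runs), and any visual
rendering. Passing tests therefore show that the *information structure*
of the environment produces the claimed orderings under error-driven
learning; they do not show that real children's input matches these
idealised statistics.

## Known limitations

The Rescorla–Wagner rule has no attentional modulation, no configural
cues and no within-compound associations, so phenomena outside its reach
are outside this package's. The relative discrimination score is noisy
over the first few dozen trials (tiny positive denominators), which
makes first-crossing statistics on it fragile early in training. And the
stability bound ties the usable set-size range to the learning rate;
exploring sets beyond nine objects requires lowering `beta` below
$2/n$, which the drivers expose via their `params` argument but do not
do by default.
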