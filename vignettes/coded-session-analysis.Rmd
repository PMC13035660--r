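---
title: "Quantifying multi-coder think-aloud sessions: alignment, agreement, and sequence structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multi-coder think-aloud sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thinkaloud)
```

## The problem

When several human coders independently annotate a recorded think-aloud
session — a surgeon exploring a 3D anatomical model in VR while verbalizing
their reasoning, in the motivating use case — each coder produces a stream of
timestamped, possibly overlapping code intervals drawn from a shared coding
framework (here organized into Cognition, Emotion, and 3D Interaction
categories). Unlike transcript coding, there is no natural shared unit of
analysis: every coder sets their own interval boundaries. Three quantitative
questions then arise:

1. **Reliability.** How well do the coders agree, given that they disagree
   not only about *which* code applies but also about *when*?
2. **Sequence structure.** Which code-to-code transitions recur, and are
   they directionally asymmetric (e.g., confirmation of anatomy leading to
   mental-model statements more often than the reverse)?
3. **Survey outcomes.** Do pre/post confidence ratings and workload scores
   (NASA-TLX) change across the session?

This package implements that full pipeline plus a synthetic multi-coder
session generator, so every stage can be validated without access to any
recorded sessions.

## Unitization and windowed alignment

All event endpoints are rounded to a 5-second grid (`round_to_grid()`,
half-up ties). Intervals are half-open `[start, end)`, so a code ending at
*t* is not active at *t*; this avoids double counting at shared grid
boundaries. An event whose rounded length is zero is retained and occupies
its start frame — silently dropping annotations would bias agreement
downward.

Because no shared unit exists, agreement is computed once per **reference
coder**: the reference's events are tiled into 5-s frames, and each
(frame, active reference code) pair is one unit (`unitize_reference()`).
Using one unit per active code, rather than forcing a primary code per
frame, keeps overlapping annotations lossless and is deterministic.

Each unit is then matched against every other coder (`align_frame()`):

* if the other coder has the **same code** active anywhere in the window
  `[t - w, t + w + 5)` around the frame (default `w = 10` s on either
  side), the frame counts as agreement;
* otherwise, among codes the other coder has active in the window, the one
  with **maximal overlap** with the window is recorded as the disagreement
  (ties break toward the smaller code id — a fixed, reproducible rule);
* if the other coder identified nothing in the window, the reserved code
  **0** is inserted and participates as a full category.

Window sidedness is genuinely ambiguous in practice, so it is exposed as
`window_mode = "symmetric"` (default) or `"trailing"` (`[t - w, t + 5)`),
and `window` itself is a parameter.

The per-unit ratings (the reference's own code plus one aligned code per
other coder) form a units × categories count matrix whose rows each sum to
the number of coders, the form Fleiss' kappa expects.

## Fleiss' kappa and its reporting

`fleiss_kappa()` implements the standard statistic: per-unit agreement
$P_i = \frac{\sum_j n_{ij}(n_{ij}-1)}{n(n-1)}$, observed agreement
$\bar P$ = mean $P_i$, chance agreement $\bar P_e = \sum_j p_j^2$ from the
pooled category proportions, and
$\kappa = (\bar P - \bar P_e)/(1 - \bar P_e)$. Interpretation bands follow
the conventional scale (`interpret_kappa()`): below 0.2 very poor, 0.2–0.4
fair, 0.4–0.6 moderate, 0.6–0.8 substantial, 0.8–1.0 almost perfect, with
boundaries assigned upward.

Two numerical edge cases are handled explicitly: an empty matrix returns
`NA` with a warning (kappa is undefined without units), and the degenerate
case $\bar P_e = 1$ (every rating in one category) returns 1 with a warning,
the limit of the formula under perfect single-category agreement.

Because each reference coder defines different units, a session yields one
kappa per reference; `kappa_range()` reports them all plus the min/max
range, never pooling across sessions. References with zero events are
excluded and flagged rather than treated as zero agreement.

A statistical subtlety worth knowing: because $\bar P_e$ is estimated from
the same ratings, the kappa estimator has a small negative finite-sample
bias under truly random labeling, $E[\hat\kappa] \approx -1/(Nn)$ for $N$
units and $n$ raters. The chance-behavior test in the suite checks the
Monte-Carlo mean against this analytic expectation rather than against an
idealized exact zero.

## Code transitions and shared counts

A transition is an ordered pair in which one code begins at least 5 s after
the previous code began. After grid rounding this is equivalent to grouping
events by start time into **co-start groups**: codes starting together are
not transitions of one another, but each transitions to every code in the
immediately following group (`extract_transitions()`). "Previous" means the
adjacent group only; long-range pairs are not counted.

To damp idiosyncratic coders, transition evidence is aggregated as **shared
counts** (`shared_transition_counts()`): per session and per unordered coder
pair, the intersection of the two coders' transition multisets (the
per-transition minimum of their counts) is summed over all pairs and
sessions. The multiset intersection preserves count information and reduces
to set intersection when all counts are ≤ 1; `intersection = "set"` is
available for the stricter membership-only reading. Directional structure is
quantified with `transition_asymmetry()`, which guards the ratio against a
zero reverse count.

## Surveys

`summarize_item()` reports median and IQR; quantiles use linear
interpolation (R type 7), the convention under which fractional IQRs such as
0.75 arise at n = 10, exposed as `quantile_type`. `welch_t()` wraps the
unequal-variance t test with Welch–Satterthwaite degrees of freedom and
`f_var_test()` the two-sided variance-ratio F test; both flag degenerate
zero-variance inputs instead of erroring or silently mis-testing.
`confidence_change_table()` pairs each session's pre/post rows, tallies
increased/unchanged/decreased sessions, and applies the Welch test to the
pre and post vectors. The unpaired Welch form is the fidelity-first default
for comparability with common practice on such data; since pre/post
responses from one session are in fact paired, `paired = TRUE` provides the
arguably more appropriate paired t test as a documented alternative.

## The synthetic generator

The generator exists because real multi-coder recordings cannot be shipped;
it emulates the statistical structure the analyses assume, not the content
of any session.

* **Truth process** (`generate_truth()`): a semi-Markov chain — codes follow
  a row-stochastic kernel, dwell times are exponential (mean
  `dwell_mean_s = 20` s), inter-event gaps exponential (mean
  `gap_mean_s = 5` s), and with `co_start_prob = 0.1` the next event starts
  simultaneously with the current one, producing overlap. The default
  kernel (`default_transition_matrix()`) up-weights the transition pairs
  that dominate real coded sessions, including a 2:1 asymmetry between
  confirmation-to-mental-model and its reverse, so directional recovery is
  a meaningful test. Defaults: 780-s sessions (the ~13-minute typical
  length), 5 coders, the 12-code default framework; `generate_study()`
  draws per-session lengths log-normally, clamped to the 6–45 minute range
  real sessions span.
* **Rater noise** (`corrupt_stream()`): per event and coder, a miss
  (`p_miss`), a code substitution (`p_sub`), Gaussian endpoint jitter
  (`jitter_sd_s`) applied *before* grid rounding so the rounding path is
  exercised, plus spurious insertions (`insertion_rate_per_min`). The four
  components map one-to-one onto the disagreement modes the alignment
  procedure must absorb: absence (code 0), wrong code, timing offset, and
  extra codes. Every coder's stream derives from `(seed, coder_index)`, so
  adding a coder never perturbs existing ones.
* **Calibration.** The default noise setting — `p_miss = 0.10`,
  `p_sub = 0.10`, `jitter_sd_s = 3`, `insertion_rate_per_min = 0.5` — was
  chosen once by simulating the kappa pipeline over a grid of settings and
  selecting the one whose per-session kappa ranges fall inside the
  moderate-to-substantial band (0.47–0.82) that real five-coder sessions of
  this kind produce; at that setting essentially all simulated sessions'
  ranges overlap the band.
* **Surveys** (`generate_surveys()`): pre-session confidence around
  configurable centers on 1–5, post = pre + item-wise shift (default +1 on
  anatomy, +0.25 on approach), NASA-TLX dimensions around low-workload
  centers on 1–10, and a conference mental-demand item emitted for the
  final 7 of 10 sessions only, mirroring its partial collection.

**What the generator does not model** — and hence what passing tests do not
establish about real data: coder errors are independent across coders and
events, whereas real coders plausibly miss the *same* ambiguous moments;
dwell times are memoryless; code content, emotion dynamics, and any coupling
between session length and behavior are absent. The generator validates the
*machinery*, not the behavioral claims.

## Problem sizes and numerical choices

The test suite and the acceptance script use 13-minute 5-coder sessions
(roughly 120–160 units per reference), 200 replicates for chance-level
checks, 50 replicates per noise level for the monotone-degradation study,
and 100 replicates for the calibration and asymmetry-recovery studies —
sizes at which the Monte-Carlo error is far smaller than the effects being
checked. Tie-breaks (alignment overlap ties to the smaller code id;
half-up rounding) are fixed so all outputs are bit-reproducible for a given
seed, and `run_study()` embeds every resolved parameter in its
`run_log.json` so each table can be regenerated by calling the underlying
function with the logged parameters.

## A worked example

```{r example, eval = FALSE}
cfg <- generator_config()            # documented defaults, seed 1
g   <- generate_session(cfg, seed = 1)
kr  <- kappa_range(g$annotations, cfg$codebook)
kr

sessions <- lapply(1:3, function(i)
  generate_session(cfg, session_id = paste0("s", i), seed = i)$annotations)
shared <- shared_transition_counts(sessions)
head(label_transitions(shared, cfg$codebook))

sv <- generate_surveys(cfg, n_sessions = 10, seed = 1)
survey_summary(sv)$confidence
```

## Known limitations

* The alignment window's sidedness and the set-vs-multiset intersection
  rule are under-determined by common practice; both are exposed as
  configuration with documented defaults rather than silently fixed.
* Kappa is computed over units defined by one reference at a time; no
  single pooled kappa across references is offered, because the units
  differ by construction.
* No significance testing of transition structure (raw counts only), and no
  Cohen's kappa / Krippendorff's alpha variants.
* The bundled 12-code framework is a convenience default; all analyses
  accept any user-supplied codebook.
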