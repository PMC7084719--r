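---
title: "The sociocog model: daily cognition, social norms, and unsafe behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sociocog model: daily cognition, social norms, and unsafe behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sociocog)
```

`sociocog` simulates a construction site as a population of interacting
agents: crews of workers, one foreman per crew, and site management
acting as a policy. Each simulated day, every worker runs a three-stage
cognitive process, and the outcome of each act feeds back into the
worker's own attitude and into the norms everyone else perceives. This
vignette explains the model, the free constants and how their defaults
were chosen, the numerical conventions at the edges of the equations,
and what the synthetic population does and does not capture about real
sites.

## The daily cognitive process

On day $t$, worker $i$ faces an actual hazard level $AR_{it}$ drawn from
a triangular distribution (default $\mathrm{Tri}(0.1, 0.5, 0.9)$, one
independent draw per worker per day).

**Stage 1 — hazard detection.** The worker registers the hazard with
probability $\min(1, SA_{it} \cdot KL_{it})$: awareness ($SA$) governs
whether he looks, knowledge ($KL$) whether he recognizes what he sees.
Both are recomputed each day from their baselines (0.8) plus the gains
of that day's interaction events: coworker conversations (+0.01 to
awareness each), a conversation with the foreman (+0.2), and a
site-wide safety meeting (+0.2 awareness, +0.1 knowledge). A missed
hazard short-circuits the remaining stages: perceived and understood
risk are zero, and any positive risk acceptance then yields an unsafe
act — the first failure class.

**Stage 2 — perception and understanding.** A registered hazard is
perceived as a memory-weighted blend
$PR_{it} = \lambda \, \overline{PR}_{i,<t} + (1-\lambda) AR_{it}$,
where $\overline{PR}$ is the mean of all previous days' perceptions.
Understanding scales perception by a coefficient,
$UR_{it} = p_{it} PR_{it}$; $p < 1$ means the worker underestimates the
hazard. The coefficient moves day to day with the worker's attitude and
knowledge changes, $p_{it} = p_{i,t-1} - a_1 \Delta AT + a_2 \Delta KL$
(floored at zero): a shift towards risk seeking deepens
underestimation, a knowledge gain counters it.

**Stage 3 — acceptance and behavior.** The worker tolerates risk up to
$$RA_{it} = (1-w)\,AT_{it} + w\,(a\,WN_{it} + b\,FN_{it} + c\,MN_{it}) + \varepsilon,$$
a social-identity-weighted blend of his own attitude and the perceived
coworker/foreman/manager norms (weights $a{=}0.2$, $b{=}0.45$,
$c{=}0.35$). He acts unsafely iff $RA > UR$. An unsafe act in an unsafe
environment state (probability $ER$) is an accident; otherwise it is a
near miss. Consequences update attitude: an accident pushes it towards
risk aversion by $c_1$, an unpunished gamble towards risk seeking by
$c_2$.

## The social channels

Norms are perceptions held by each worker, updated from four channels:

* **Demonstration** — observing another agent's act is read as a noisy
  signal of that agent's risk acceptance: uniform above the actual risk
  after an unsafe act, uniform below it after a safe one. Workers
  observe their crew-mates' previous-day acts and their foreman's
  same-day act (foremen act first each day, which keeps the update
  order within a day well defined).
* **Behavior feedback** — foreman and manager react to the previous
  day's act (negative feedback after unsafe acts with probability 0.6,
  positive after safe acts with probability 0.1). Feedback is read
  relative to the worker's own risk understanding: punished or praised
  acts pull the perceived norm below it, tacitly tolerated unsafe acts
  push it above.
* **Communication and training** raise awareness and knowledge as
  above; they do not move norms directly.

The foreman norm mixes demonstration and feedback with share $d$; the
coworker norm is demonstration-only; the manager norm is feedback-only
(management is a policy, not an embodied agent). All three updates are
convex blends with memory $m$, so norms can never leave $[0, 1]$ and
converge geometrically to a constant signal. As published, the memory
weight of the coworker norm sits on the previous value while the
foreman/manager updates put it on the new signal; we implement the
asymmetry as printed and expose `coworker_memory_harmonized` to flip
it.

**Foremen as agents.** Each foreman runs the full worker cognitive
loop. His risk acceptance has no foreman-norm term (nobody supervises
him inside the crew): the foreman weight is dropped and the remaining
weights renormalized. His coworker norm comes from observing his own
crew, his manager norm from manager feedback, and he receives safety
training and management communication at the site frequencies. This
matters: without the communication channel foremen detect hazards
noticeably less often than their crews (their awareness lacks the
foreman-conversation gain), act unsafely more often, and the
demonstration channel then *raises* the foreman norm instead of
lowering it.

## Free constants and their defaults

The site-level constants (crew structure, horizon, interaction
frequencies, norm weights, initial distributions, event gains) are the
published baseline. A handful of constants have no published value;
their defaults are fixed once, documented here, and recorded in run
metadata:

| constant | default | rationale |
|---|---|---|
| $\lambda$ (perception memory) | 0.5 | equal weight to memory and the day's hazard |
| $a_1, a_2$ (coefficient sensitivity) | 0.5, 0.5 | symmetric response to attitude and knowledge change |
| $c_1, c_2$ (attitude shifts) | 0.15, 0.01 | accident aversion must dominate: expected attitude drift per unsafe act $(1-ER)c_2 - ER\,c_1 < 0$ |
| $m$ (norm memory) | 0.5 | mid-range; geometric adaptation over a work week |
| $d$ (demonstration share) | 0.5 | the foreman's two roles weighted equally |
| $\varepsilon$ | $U(-0.01, 0.01)$ | the worked-example residual (0.004) fixes the scale |
| $ER$ (unsafe environment) | 0.10 | back-solved from the published near-miss:accident ratio ($\approx (1-ER)/ER$) and accident rate; 0.10 reconciles both |
| knowledge gains (coworker, foreman) | 0.01, 0.2 | mirrored from the printed awareness gains; only the training gain (0.1) is published |
| observation pool | all 19 crew-mates | crews are the visual boundary |
| conversation pool | 5 crew-mates/day | a realistic daily contact circle |

Numerical conventions at the edges: day 1 has no history, so perception
equals the actual risk, the understanding coefficient keeps its initial
draw, and norms keep their initial values (there is no previous
behavior to react to); the tie $RA = UR$ resolves to safe behavior (the
published decision rule leaves it open); attitude is clamped to
$[0,1]$ and $p$ floored at 0; awareness and knowledge are *not* capped
at 1 (printed worked cases show values above 1), only the detection
probability is. The perception memory mean includes the zeros of
non-detection days, as the printed summation runs over all previous
days; `pr_history_exclude_zeros` switches to detected days only.
Awareness and knowledge are recomputed each day from baseline rather
than accumulated — unbounded accumulation diverges over a 280-day
horizon while the printed case snapshots sit near 1; `sa_cumulative`
restores accumulation for sensitivity analysis.

## Determinism and the draw order

A run is a pure function of `(config, seed)`. All randomness flows
through one stream with a frozen block order per day: meeting draw;
worker communication counts; feedback uniforms (from day 2); foreman
norm-update, residual, hazard, detection and outcome draws; then the
same blocks for workers. Every block has a fixed length regardless of
which branches are taken, so traces are reproducible bit for bit; the
test suite holds the engine to a straight-line scalar reimplementation
of the whole daily loop on a small crew, and replicate $k$ of a batch
uses seed `base_seed + k - 1`.

## Validation statistics

* The **unsafe-behavior ratio** pools unsafe worker-day acts over all
  worker-day acts (foremen excluded by default;
  `include_foremen_in_ratio` adds them).
* The **accident rate** is expressed per 100 full-time workers *per
  day*, $100 \times \text{accidents} / (n_\text{workers} \cdot
  n_\text{days})$. This reading is the only one mutually consistent
  with the model's own unsafe ratio and near-miss:accident ratio
  ($100 \cdot \text{ratio} \cdot ER$ matches the published rate near
  3.35 at $ER = 0.10$); the per-run-total alternative is reported
  alongside.
* A **near miss** is an unsafe act that does not coincide with an
  unsafe environment state.
* The **attitude–acceptance regression** is ordinary least squares over
  pooled worker-day $(AT, RA)$ pairs of a run.
* The **awareness–communication correlation** is computed over
  worker-day pairs between the foreman-conversation indicator and that
  day's awareness. Pairing at the worker-day level is deliberate:
  population-mean daily series are dominated by the site-wide training
  indicator (awareness variance is almost entirely the ±0.2 training
  gain), which drives any daily-mean correlation with communication
  towards zero and the training correlation towards one. At the
  worker-day level the analogous training–awareness correlation lands
  where the published diagnostics put it, which is what identifies this
  pairing. The foreman conversation is the communication channel with
  the dominant printed awareness gain (0.2 versus 0.01 for coworker
  chat), hence the indicator used.

## Scenario experiments

`run_exclusion_table()` removes one norm from the risk-acceptance
equation with the remaining weights renormalized to sum to 1, or
removes the foreman's demonstration channel (feedback-only foreman
norm), using common random seeds across scenarios. An excluded norm has
exactly zero influence on risk acceptance — a property the test suite
asserts.

A caveat worth stating plainly: under renormalized exclusion the
foreman norm sits *between* the coworker norm (loosest — workers imitate
each other's unsafe acts) and the manager norm (strictest), so removing
it shifts weight both up and down and the net effect on the pooled
unsafe ratio is small or mildly negative; removing the demonstration
channel makes the foreman norm behave like the feedback-only manager
norm and likewise *lowers* acceptance. Reports of large positive
foreman-exclusion effects are only reproducible here under a different
exclusion semantics — the worker stops *updating* the excluded norm and
carries his initial perception unchanged — available as
`mode = "freeze"` (and `frozen_norm` in the configuration). The two
variants answer different questions: renormalization asks "what if this
norm carried no weight?", freezing asks "what if this group's behavior
were never observed again?". The default follows the published
exclusion equation (renormalization).

`sweep_single()` and `sweep_paired()` sweep the five management levers
(manager/foreman feedback frequency, foreman communication, training,
social identity) over 11 levels in $[0,1]$ with all other parameters at
baseline and common seeds across cells. Feedback levers set both the
positive and negative probability of the role to the level. The cell
statistic defaults to the pooled ratio over the full horizon
(`statistic = "final_day"` is available).

## What the generator emulates, and known limitations

The baseline emulates a mid-rise project: 5 crews of 20 plus foremen,
280 working days, moderate hazard levels, safety meetings every other
day. It does not model fatigue or physiology, spatial layout, task
assignment, inter-crew contact, or training intensity (only
frequency) — passing tests say nothing about those aspects of real
sites.

Two structural limitations are worth knowing. First, the opening level
of unsafe behavior is fixed by the published initial distributions: on
day 1 mean risk acceptance (≈0.65, from attitudes and norms drawn on
$U(0.4, 0.9)$) sits well above mean understood risk (≈0.45, the
understanding coefficient times a mid-level hazard), and missed
detections add their share of automatic unsafe acts, so roughly 85% of
workers act unsafely on day 1 under *any* free-constant setting —
substantially above the published starting level near 60%. The decline
towards the published final-day level, and all pooled statistics, are
unaffected. Second, the exclusion caveat above: the published large
positive foreman-norm and demonstration-role exclusion effects do not
emerge under the printed renormalization semantics.

## Problem sizes

The validation suite runs the full study protocol — 100 replicates of
the 105-agent, 280-day site — in roughly half a minute per batch;
property suites use $10^5$-draw Monte Carlo checks; the
engine-versus-oracle equivalence runs on a 1-crew site over a few days,
where a scalar reimplementation is tractable.
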