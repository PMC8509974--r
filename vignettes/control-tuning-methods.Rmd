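---
title: "Control tuning, interval timing, and skill-transfer analysis in autorbit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control tuning, interval timing, and skill-transfer analysis in autorbit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autorbit)
```

## The task

`autorbit` simulates and analyses a paced-shooting video game used to study
how action-timing skills transfer across speed perturbations of the same
environment. A ship orbits a balloon clockwise at fixed speed; the player
turns the nose in 15-degree steps (keys A/D) and fires missiles (key L).
Successful shots inflate the balloon one step at a time; at full inflation a
quick double shot (two presses less than 250 ms apart) bursts it for points.
Shots faster than the firing interval's lower bound pop the balloon back to
zero ("reset"); waiting past the upper bound starts a continuous deflation.
The game runs at a 16-ms tick for 3 minutes per game; a session is 15 games
in an ABA design (three 5-game phases) across two speeds:

| | multiplier | firing interval | points/burst |
|---|---|---|---|
| high | 1.0 | 500–1200 ms | 200 |
| low  | 0.5 | 1000–2400 ms | 300 |

The low speed halves every rate (orbital, missile, deflation) and doubles
both firing bounds; points are set independently because scoring
opportunities are rarer at low speed. The four conditions are HHH and LLL
(controls) and HLH and LHL (transfer at games 6 and 11).

## Engine conventions

Several geometric quantities are not printed anywhere and are fixed here so
that the one printed kinematic figure is exact:

* **Orbit radius 124.34 px.** With the high-speed orbital rate of
  0.5 px/tick, the circumference divided by the speed gives a revolution
  period of 25.0 s, the stated rotation time.
* **Balloon radius 8 px deflated, 18 px full**, one px per inflation step.
  The stated deflation rate, 0.5% of full size per tick, is then the stated
  0.09 px/tick. At the orbit radius these sizes subtend angular radii of
  3.7–8.3 degrees, which is also the scale of the aim-width tracker range
  below, so the three quantities are mutually consistent.
* **Hit test.** A missile inherits the nose direction at the press and hits
  iff its ray passes within the balloon circle; flight time is the distance
  to the entry point at the missile speed, discretised to ticks.
* **Press-edge semantics.** Actions trigger on hold-key edges; holding a
  key does not repeat. A shot that triggers a reset pops the balloon and
  its missile is absorbed (neither hit nor miss). A too-fast press at full
  vulnerability is exempt from the reset rule, since the required double
  shot is itself faster than any lower bound. Misses are logged as explicit
  `missile-miss` events, so the miss count equals fired missiles minus
  balloon hits.
* **Cycles.** A cycle runs from a balloon respawn to the next burst; the
  balloon respawns on the tick after a burst. At each respawn a disruptive
  rotation of 60–120 degrees (random sign) is scheduled with probability
  1/3, uniformly 1–4 s into the cycle, with a 4-s deflation grace period
  after it fires.
* **Scores may go negative** (misses at the start of a game); no floor is
  stated or applied.

The event log is written with 16-ms timestamps and round-trips losslessly
through TSV and JSONL (`write_log()`/`read_log()`).

## The control-tuning agent

The cognitive agent tunes four bounded parameters, each in its own tracker:
shot timing (10–30 clock ticks), aim offset (−18 to 0 degrees), aim width
(5–15 degrees) and turn threshold (−10 to 0 degrees). A tracker discretises
its range into 21 candidates and samples value $S$ with probability

$$P(S, t) = \frac{e^{V(S)/T(t)}}{\sum_x e^{V(x)/T(t)}}, \qquad
T(t) = \frac{A}{1 + B\,t},$$

with $A = 1$, $B = 1/180$ per second, and $t$ the tracker's own active
tuning time in seconds. $V(S)$ is a quadratic payoff estimate refit after
every outcome by weighted least squares on decayed moment statistics: all
accumulated weights shrink by $\lambda = 0.99$ per update before the new
observation enters with weight 1, so old experience is forgotten
exponentially and constant memory suffices. The grid is far finer than any
behavioral effect at stake; the fit is done in a range-scaled coordinate
with a $10^{-6}$ ridge so rank-deficient early fits stay near the flat
prior. The timing tracker is paid +1 per balloon hit and −1 per reset or
deflation onset, attributed to the sampled tick count; the aim trackers are
paid ±1 per hit/miss.

Waiting times are counted by a pacemaker-accumulator clock whose tick
durations grow geometrically, $t_{n+1} = 1.1\,t_n$ plus zero-mean logistic
noise with sd $0.0165\,t_n$. The start tick of 11 ms is forced by the
printed conversion of the 10–30-tick range to 175–1809 ms.

Planning follows a fixed operator cycle per shot: check and adjust aim,
wait out the sampled tick count, fire (double shot at full vulnerability),
and decide via the turn threshold whether aiming again takes the short path
(no extra turn) or the long one. Because turns are quantised to 15 degrees
while the aim error drains continuously at the orbital rate, the planner
zeroes the residual by shifting the fire time — capped at ±12 ticks
(±190 ms) so that pacing remains owned by the timing tracker. Production
compilation is abstracted as a two-path latency race: an interpreted chain
of four ~50-ms operator steps against a single-step compiled shortcut that
forms after 12 plans and inherits its parent's utility; both learn by the
difference rule $U \leftarrow U + \alpha (R - U)$ with $\alpha = 0.05$ and
reward equal to minus the elapsed planning time in seconds. Path selection
adds logistic noise of scale 0.1 to each utility — small relative to the
~0.15 utility gap the latencies produce, so the compiled path comes to
carry about three quarters of plans once learned, while the race stays
stochastic. Motor presses carry a
50-ms preparation mean and 10-ms Gaussian jitter on two independent hand
channels. Operator base-level learning is off.

### Speed-change handling and the three variants

The agent never reads the game index. It flags a speed change when penalty
feedback lands on selections near the tracker's own payoff peak twice in a
row. Simulation showed that the raw twice-in-a-row rule misfires during
ordinary tuning, so four qualifications apply, all still purely
feedback-driven: the two penalties must be of the same type (a real change
pushes the firing window in one direction — resets when the world slowed,
deflation onsets when it sped up); the detector only arms once the tracker
has substantial experience behind a confidently positive estimate (decayed
weight ≥ 50 and max $V$ > 0.5); a hit on an interval that already drew a
deflation onset does not count as disconfirming; and shots the aim logic
itself displaced by more than 50 ms are not probes of the timing estimate,
so their penalties are self-explained and carry no evidential weight. A
150-s refractory period follows any structural change.

On the first detected change the one-tracker variant does nothing —
relearning happens only through decay — which is exactly what produces its
characteristic game-6 reset/deflation spike and score drop. The two-tracker
variants suspend the timing tracker (freezing its estimate, experience and
tuning clock), explore for one cycle with uniform waiting times, and open a
fresh tracker on 0.6–1.4 times the tick count whose intervals drew a hit
and no penalty during exploration (clipped to 5–60 ticks). The keep-temp
variant gives the new tracker the old tracker's annealed tuning time; the
reset-temp variant starts it at $T = A$. On the next detected change the
original tracker is simply reactivated.

## The eight measures

Performance counts per game use all cycles: score (from the log header),
resets and deflation onsets capped at 100, misses capped at 200. The four
motor-learning measures use only rotation-free complete cycles:

* **Entropy.** Keypresses of eligible cycles are concatenated in time
  order and cut into non-overlapping triples from the first press
  (remainder dropped, partition running across cycle boundaries); the 27
  triple counts get add-one smoothing and enter the base-2 Shannon entropy,
  bounded by $\log_2 27 = 4.75$ bits. Games with no complete triple are
  flagged `NA`, never zero.
* **Shot timing variability.** Per cycle with at least two inter-shot
  intervals, the CV is the population SD over the mean; cycle CVs are
  averaged within the game and the natural log of the average is returned
  (base unstated in the field; natural chosen and fixed here). An average
  CV of zero is flagged, not substituted.
* **Shot periodicity and regularity.** Each eligible cycle's shot-key
  series (1 while L is held, per 16-ms tick) is autocorrelated over 125
  lags with the lag-0-normalised estimator; cycle ACFs, each computed on
  its own length, are averaged per lag (short cycles simply drop out of
  the high-lag average). The first strict local maximum at lag ≥ 1 with
  amplitude > 0.02 gives the periodicity (lag × 16 ms) and regularity
  (height); no qualifying peak flags the game invalid, mirroring the row
  filtering applied to such games in this analysis tradition.

## Transfer statistics

Scores are averaged per run within phase (Start 1–5, Middle 6–10, Final
11–15). Percent transfer at the low speed is

$$T_{low} = 100 \times
\frac{\mathrm{HLH}_{6\text{–}10} - \mathrm{Low}_{1\text{–}5}}
     {\mathrm{LLL}_{6\text{–}10} - \mathrm{Low}_{1\text{–}5}},$$

where the start baseline pools the two conditions that begin at low speed;
the high-speed formula swaps the roles. Cell summaries use the median
across runs by default. The bootstrap resamples runs with replacement
within each condition cell, recomputing phase summaries and the transfer
per draw (10,000 draws by default, seed-stable). Model fit against a
reference vector of game means uses RMSE and $\mathrm{BIC} = n \log
(\mathrm{RSS}/n)$ with the parameter-count term dropped, since competing
variants share their parameterisation — so BIC and RMSE order models
identically, which the tests assert.

## The synthetic generators

`periodic_shooter()` and `triple_sampler()` produce logs with known
statistical structure while bypassing the game physics: scripted shots hit
unless a scripted miss fires, intervals are the target plus Gaussian
jitter quantised to the tick grid, and shots are grouped into rotation-free
cycles of 12 so the per-cycle ACF averaging behaves as it does on simulated
games. They emulate exactly the moments the metrics consume — interval
mean and spread, triple distribution, cycle structure — and nothing else:
no fatigue, no drift, no inter-individual parameter variation, no aiming
dynamics. Passing recovery tests on them therefore certifies the metric
implementations, not the realism of any agent.

One property deserves note: with interval jitter the shot times follow a
random walk within a cycle, and at a jitter of 2 ticks the first-peak rule
occasionally (about 7% of runs) locks onto a shoulder of the broadened main
peak two lags early. Over the tested family of jitter sd 0–2 ticks the
±1-lag recovery rate is about 97%. The peak rule is kept exactly as
defined rather than patched, since it is part of the measure.

## Problem sizes and reproducibility

The packaged test suite simulates 20 sessions per condition for the
two-tracker agent (all four conditions) and 20 per transfer condition for
the one-tracker agent — the same 20-runs-per-cell size the transfer
medians are defined over — plus smaller batches for the behavioral module
tests. Every simulation is seed-derived and deterministic given (config,
seed, policy); the engine's only random draws are the cycle rotations and
the agent's own sampling, all on R's seeded stream.
`scripts/acceptance.R` regenerates the headline quantities (entropy bounds,
clock conversions, scripted periodicities, and the two-speed median
transfer of the two-tracker agent) from scratch at any seed.

## Known limitations

The agent is a simplified embodiment of the architecture it abstracts:
declarative-memory activation, visual attention and full production-rule
composition are out of scope, and the compiled path is a latency race
rather than rule composition. The hit geometry and balloon sizes are
reverse-engineered from printed rates, not measured from the original
game. Human logs are not distributed with the original study, so human
medians, drop percentages and the human-side fit tables cannot be
reproduced here; the analysis pipeline accepts external logs in the
documented format should such recordings exist.
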