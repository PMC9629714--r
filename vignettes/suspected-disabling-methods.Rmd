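---
title: "Detecting and explaining suspected AIS disabling: models and methods"
author: "darkgaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and explaining suspected AIS disabling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

Fishing vessels carry AIS transponders that broadcast position reports
receivable by satellite. A vessel that switches its transponder off goes
dark; but gaps in a vessel's message stream also arise for mundane reasons,
chiefly poor satellite reception. `darkgaps` implements a complete analysis
chain for this problem: map reception quality, detect and filter
transmission gaps, classify the remainder as suspected intentional
disabling with a tuned rule model, allocate the hidden hours onto a
quarter-degree grid, and model the spatial drivers of disabling with
boosted regression trees. Because real satellite AIS feeds and labelled
disabling events are proprietary, the package ships a synthetic world
generator that reproduces the statistical structure of the problem and
provides exact ground truth; every stage is developed and validated against
it.

## The synthetic world

`build_world()` evaluates, on a 0.25° WGS84 grid (15° × 20° by default,
shoreline on the western edge), a true satellite-reception field — a
constant background of 5 positions/vessel/day plus Gaussian patches of good
coverage (up to ~43) and three localized reception holes, with class B
devices receiving 0.6× class A — alongside eight driver rasters: distance
to shore, to marine protected areas and to piracy incidents (great-circle
km, clipped at 400 km), loitering hours, chlorophyll-a, eddy kinetic
energy, SST and SST variability (random smooth Gaussian-bump fields; SST
additionally has a latitudinal ramp). All distances use a sphere of radius
6371 km; one nautical mile is 1.852 km. Every cell is half-open
`[west, west+Δ) × [south, south+Δ)`, row 1 at the south.

`simulate_fleet()` moves vessels as an hourly correlated random walk
attracted to gear-specific fishing grounds, with periodic excursions to
random waypoints (40% of 72-hour blocks) so that tracks also cross
mid-ocean low-reception waters. Pings are an inhomogeneous Poisson process:
within each hour a vessel emits `Poisson(rate/24 × min(1, r/30))` messages,
where `rate` is its device-class broadcast rate (72/day class A, 60/day
class B at perfect reception) and `r` the true reception at its position.
Unintentional gaps therefore arise *implicitly* wherever reception is poor
— matching the causal story the classifier must untangle — rather than
being planted.

Intentional disabling is planted per vessel-day: a candidate anchor ping is
drawn and accepted with probability
`plogis(intercept + b_loiter·log10(loitering+1) + b_eez_band·band) ×
min(1, r/30)^rec_power`, where `band` indicates shore distance within 50
nautical miles of the 200-nautical-mile EEZ boundary. The reception factor
(`rec_power = 2` by default) encodes that switching off a transponder that
is barely tracked gains a vessel little, and keeps planted events
concentrated where broadcasting is dense — which is also where any labelled
real-world positive set necessarily comes from. Durations are log-normal
(median 30 h, σ_log = 0.7). All pings strictly inside a planted window are
deleted, and the truth log records the window anchored at the last ping
before and the first ping after, so planted gaps have exactly the endpoint
structure detected gaps have. The gap-cause mixture that results (roughly
four intentional events per reception-driven retained gap under the
defaults) is an assumption, not a calibrated value: the real mixture is
unknown.

## Reception maps

Observed reception is the average number of positions received per vessel
per day: each vessel-day is attributed to the 1° cell of the vessel's daily
mean position, and a cell's value is total messages over total vessel-days.
Cells with no vessel-days are *missing*, never zero — zero would conflate
"no vessels" with "no reception". The predicted 0.25° surface interpolates
the observed cell-centre values with a thin-plate-spline radial basis
function (`φ(r) = r² log r`) plus a linear polynomial, smoothing 0: the
surface passes exactly through the data, reproduces affine fields (hence
`predict(obs + c) = predict(obs) + c`), and is clamped at 0. The kernel
choice is the standard scattered-data default; with a few hundred observed
cells the dense solve is immediate.

## Gap detection, filters, and the rule classifier

A gap event is any pair of consecutive messages of one vessel spaced by at
least 12 h. For each gap the count of positions in the half-open lookback
window `(start − L, start]` is recorded for L ∈ {6, 12, 18, 24} h; the
gap's own starting ping counts once. Gaps are retained only in waters
strictly more than 50 nautical miles from shore, with predicted reception
strictly above 10 positions/day at the start position (class-matched
surface). All boundaries are deliberate: exactly 50 nmi and exactly 10
positions/day are excluded, exactly 12 h is included. Filters are
evaluated at the gap start position; the function is isolated so an
endpoint-based variant is a one-line change.

A rule model classifies a retained gap as suspected disabling iff the
lookback count is at least `k` and predicted reception exceeds
`reception_min`. The default is the headline rule (12 h lookback, k = 14,
reception over 10/day). `select_model()` scores every candidate over a grid
(lookback × k ∈ {2..30} × reception_min ∈ {10, 15, 20}) by F0.5 — chosen to
weight precision above recall, since false accusations are costlier than
misses — averaged over 10 repeats of 5-fold cross-validation with folds
stratified by truth label, ties broken by precision, then smaller k, then
shorter lookback. On the reference fixture the selected rule attains
precision ≈ 0.99 at a false-positive rate ≈ 2% against the truth log; the
separation is stronger than in real data because the synthetic world's
reception contrast is cleaner, so these numbers validate the machinery, not
the real-world error rates.

## Allocating hidden time

The linear method traverses the great circle from gap start to end at
constant speed and deposits `min(duration, 336 h)` in proportion to arc
length per cell, computed by sampling the arc at ≤ 0.01° steps (validated
against 10⁻⁴-degree brute force). The 336-hour (2-week) cap gives the lower
bound of time-lost estimates; the uncapped variant gives the upper.

The probabilistic method defines the feasible set as cells whose centre
satisfies `d(start, c) + d(c, end) ≤ max_speed × duration` (10 knots by
default) and weights feasible cells by
`(prior + 1e-9) × exp(−detour / 30 nmi)`, where `detour` is the extra
distance over the direct route. The exponential detour decay makes the
method a discrete bridge between the known endpoints — the standard way
movement ecology interpolates a position process between fixes — rather
than a uniform smear over a speed ellipse that no real track could fill;
`bridge_scale_nmi = Inf` recovers the uniform-ellipse variant. With the
default scale the two methods agree per cell at r ≈ 0.85 for sub-2-week
events, while long events still diverge, which is why summaries report
capped and uncapped bounds.

Broadcast activity (the denominator of "fraction obscured") splits each
inter-ping interval shorter than 12 h half/half between its endpoint cells;
intervals of 12 h or more are gap candidates and contribute nothing. The
obscured fraction is `disabling / (activity + disabling)` — the denominator
deliberately includes the hidden time itself, so the fraction is the share
of total at-sea time that is dark. Hot spots are cells above both a
fraction and an activity threshold, labelled by rook-adjacent connected
components.

## Driver models

Presences are cells with at least one suspected disabling event (event
start cells, not cells merely crossed by an allocated track); eligible
absences have fishing activity and no event; absences are drawn uniformly
without replacement to exactly 1:1, reproducibly from a seed. Models are
stagewise binomial-deviance boosted trees (depth 3, learning rate 0.01, bag
fraction 0.5 — the standard ecological BRT settings) with the ensemble size
chosen by internal 5-fold cross-validation up to 10,000 trees. Relative
importance is each driver's share of total split gain, normalised to 100%;
partial dependence sweeps each driver over a 100-point grid of its observed
range while averaging predictions over the data. Evaluation runs exactly 50
iterations: redraw absences (keeping 1:1), split 75/25 stratified, train,
score held-out AUC and TSS (sensitivity + specificity − 1 at the
TSS-maximising threshold). Explained deviance (1 − residual/null) is
computed on the final full-data fit — a training-data quantity,
deliberately, and read as a descriptive fit measure rather than an
out-of-sample one.

A caution the package's own experiments make vivid: with spatially smooth
driver fields and uneven fishing effort, *any* smooth field can partly
separate presence clumps from scattered absences, so importances leak to
nuisance drivers. The driver-recovery validation therefore uses study
conditions designed for identifiability — homogeneous coverage (pure
waypoint movement, uniform reception), a planted probability logistic in
loitering and shore distance only, rough independent nuisance fields, and a
shore-distance band placed inside the 400-km clip. Under those conditions
the planted drivers take the top-2 importance ranks in ≥ 90% of seeded
runs. Under confounded conditions they need not, and the same caveat
applies to any real-data use of this (or the original) protocol.

## Problem sizes and reproducibility

The reference fixture is 100 vessels × 90 days (≈ 0.4 M messages, ≈ 500
gap events); unit tests use worlds of 10–50 vessels over 5–60 days, and the
driver-recovery experiment 80 vessels × 60 days per seed — sizes chosen so
the full validation suite completes in minutes on one core while keeping
every estimate comfortably away from its threshold. Every stochastic step
takes an explicit integer seed; the pipeline derives per-stage seeds from
one global seed as `(seed·7919 + stage_index·10007) mod (2³¹−1)`, so stages
are individually reproducible and all seeds stay valid 32-bit integers.
Rasters are written as plain-text ESRI ASCII grids and tables as CSV with
ISO-8601 UTC timestamps, so every artefact diffs cleanly and round-trips
losslessly.

## What passing tests do and do not show

The generator emulates spatially varying reception, class A/B rate
differences, ground-attracted movement, covariate-dependent disabling and
implicit reception gaps. It does not emulate terrestrial receivers, message
collisions in crowded waters, multi-day port calls, gear-specific broadcast
behaviour, temporal (intra-day) reception cycles, or identity spoofing.
Consequently the validated claims are about the *methods* — filters honour
their boundaries, selection optimises what it says it optimises, allocation
conserves time, the driver protocol is faithful and recovers planted
signals when identifiable — and not about real-world disabling rates, which
depend on proprietary data this package does not consume.
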