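# clinedrift

Tools for analysing **moving species-replacement zones** (contact zones
without hybridization) from georeferenced host–parasite survey records.
The motivating system is a parapatric pair of chewing-louse species on
pocket gophers along a north–south river-valley transect, where the
northern species is actively replacing the southern one; the methods
apply to any transect survey in which each sampled host yields a
classifiable parasite sample (pure invader / mixed / pure resident) and
surveys are repeated over years.

The package is aimed at population biologists who have per-host survey
tables (position along a transect, collection year, per-species parasite
counts) and want to (i) estimate the geographic cline of the invading
species for each survey, (ii) track the cline's movement through time and
date the invasion, and (iii) test whether mixed-species samples are as
common as random association predicts.

## The model

Per survey, hosts are grouped into 200-m bins along the transect and the
frequency of hosts carrying the invader is computed with the
**half-count rule** (a host carrying both species counts as half an
invader host and half a resident host). The binned frequencies are fitted
with a **five-parameter asymmetric logistic** cline, decreasing southward:

```
f(x) = B + (T − B) / (1 + 10^{b (x − x_mid)})^s
```

with asymptotes `0 ≤ B < T ≤ 1`, decadic slope `b > 0` (per meter),
location `x_mid` and asymmetry `s > 0`. The curve is inverted in closed
form to place the conventional cline landmarks — the positions where the
invader is 80%, 50% and 20% of the parasite population (`x08`, `ip`,
`x02`) — and combined with the raw-record range extremes (`nGc`, the
northernmost resident record; `sGa`, the southernmost invader record)
into a per-survey set of zone metrics, including the full width
`sGa − nGc` and the conventional 0.2–0.8 width `x02 − x08`.

Drift inference then regresses each positional metric on survey year
(ordinary least squares, one-tailed *t* test of `r > 0` for the
directional southward-advance hypothesis). The regression slope of the
0.2–0.8 zone metrics estimates the hosts' mean annual dispersal distance
(diffusion dispersal); the `sGa` slope estimates the maximum annual
dispersal distance (jump dispersal); and the year at which a fitted line
crosses position 0 dates the arrival of that zone feature at the
transect origin (`travel_time()` does the equivalent back-extrapolation
from a single position and rate). Inside the 0.2–0.8 zone, pure-north :
mixed : pure-south sample counts are tested against the Hardy–Weinberg
**1:2:1** expectation with a Pearson chi-square test (df = 2); an exact
multinomial variant and a local-frequency-adjusted expectation are
available.

A seeded synthetic generator (`zone_sim_config()`, `simulate_survey()`)
produces multi-year surveys with a constant-velocity sigmoidal cline,
finite per-host louse samples, a tunable mixed-sample deficit, and
jump/lag tails, so the entire pipeline can be validated by parameter
recovery.

## Worked example

Run the full pipeline on a synthetic zone advancing at 150 m/year with a
1,000-m 0.2–0.8 width, surveyed in 1991/1996/2001/2016 at 15 hosts/km:

```r
library(clinedrift)
res <- run_pipeline(list(simulate = list(seed = 12)), quiet = TRUE)
res$metrics
#  year    nGc    x08     ip    x02    sGa full_width width_0208 gof weighted_gof
#  1991 1595.0 2954.9 3404.5 4234.9 5226.2     3631.2     1280.0 0.9            1
#  1996 2456.2 3780.6 4044.2 4573.0 5913.1     3456.9      792.5 0.9            1
#  2001 3477.4 4288.6 4797.4 5650.7 7165.0     3687.7     1362.1 0.9            1
#  2016 5677.8 7027.8 7226.0 7381.6 8657.2     2979.5      353.8 1.0            1

res$trends$ip
# Trend of ip: 154.64 m/year over 4 surveys
#   r = 0.999, t = 32.441 (df = 2), one-tailed p = 0.0004744
#   crosses position 0 in year 1969.5

res$mixed_test
#         Pearson chi-square test against 1:2:1 class proportions
# X-squared = 13.627, df = 2, p-value = 0.001099
```

Reading the output: the fitted 50% point (`ip`) advances ~155 m/year
(planted truth: 150), the fit dates the arrival of the front at the
transect origin to ~1970, and the in-zone sample classes reject the 1:2:1
expectation because the generator's default mixed-host probability is
deficient (0.65 of the Hardy–Weinberg value) — exactly the behaviour the
analysis is designed to detect.

Published per-survey positions can be pushed through drift inference
without raw records:

```r
tab <- zone_metrics_table(
  zone_metrics_row(1991, nGc = 2300, x08 = 2492, ip = 3420, x02 = 3760, sGa = 3900),
  zone_metrics_row(2016, nGc = 4900, x08 = 6558, ip = 7026, x02 = 7516, sGa = 9700))
drift_table(tab, digits = 0)
#    interval years nGc x08  ip x02 sGa
# 1 1991-2016    25 104 163 144 150 232
travel_time(9700, 232)
# [1] 41.81034
```

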