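# lickometry

Operant licking is a workhorse paradigm of behavioral neuroscience: a
rodent licks a drinking spout, a lickometer timestamps every tongue
contact, and a reinforcement schedule decides when those licks earn a drop
of solution. `lickometry` is a pure-software re-implementation of an
open-source lickometer rig: the schedule logic, the session controller,
the lick-microstructure analysis, and the environmental-monitoring
pipeline that normally run on acquisition hardware, plus a seeded
virtual-rat simulator that stands in for the animal. Everything an
analysis touches can therefore be generated, replayed and verified
deterministically, which makes the package useful for prototyping session
designs, validating analysis code against known ground truth, and
teaching schedule behavior without animals.

## What it implements

**Reinforcement schedules.** Deterministic state machines for

- **FR(n)** — fixed ratio: a reward every `n` counted licks;
- **VR(m)** — variable ratio: the requirement is redrawn after each
  reward, uniform on `{1, …, 2m−1}` so its mean is exactly `m` (an
  explicit requirement sequence can be supplied instead);
- **PR** — progressive ratio: the requirement for the k-th reward is
  `base + (k−1)·step` (defaults 10 and 5); the last ratio completed is
  the animal's break point.

After each reward a timeout (default 20 s) starts, during which licks are
logged but not counted, and a cue light turns on for a fixed period
(default 5 s). Sessions begin at an RFID scan of the subject's implanted
12-hex-character tag; a tag→schedule map selects the schedule, defaulting
to VR10. FR/VR sessions run a fixed hour; PR sessions end 10 min after
the last active-spout lick.

**Lick microstructure.** Licks within 0.5 s of each other form a
cluster; clusters with fewer than two licks are excluded. Cluster size
(licks per cluster) indexes reward palatability; the inter-lick interval
(ILI, within-cluster) sits near 0.15 s for rats licking sucrose. The
package segments spouts independently, summarizes size and ILI with SEMs,
builds cumulative records, bins motion activity into 1-min windows, and
compares active vs inactive responding with pooled-variance Student's
t-tests and conventional significance stars.

**Virtual rats.** A renewal-process generator: shifted-geometric cluster
sizes, truncated-normal within-cluster intervals, exponential pauses,
Bernoulli spout choice, Poisson motion. Presets emulate sucrose-like
(large fast clusters, ~5,000 licks/h) and water-like (small slow
clusters, a few hundred licks/h) behavior.

**Environmental monitoring.** Simulated 10-min-cadence sensor series
(temperature, humidity, barometric pressure, lux on a reverse light
cycle), device-to-device paired-difference statistics, debounced
light-cycle transition detection, and least-squares changepoint
estimation for climate steps.

## Worked example

Simulate an hour of sucrose-like licking, run it through an FR10 session,
and analyze the result:

```r
library(lickometry)
stream <- simulate_rat(sucrose_rat_params(), seed = 42)
rec <- run_session(stream, schedule_preset("fr10"))
rec
#> <session_record> subject 00000000002A, schedule FR10
#>   start 2016-07-01 09:00:00, duration 3600.0 s, 5737 events
#>   licks active/inactive 4815/385, rewards 85, motion 280

session_summary(rec)
#> # A tibble: 1 × 5
#>   subject_tag  schedule licks_active licks_inactive rewards
#>   <chr>        <chr>           <int>          <int>   <int>
#> 1 00000000002A FR10             4815            385      85

analyze_licks(rec)
#> # A tibble: 2 × 8
#>   spout    n_clusters mean_cluster_size sem_cluster_size mean_ili_s sem_ili_s
#>   <chr>         <int>             <dbl>            <dbl>      <dbl>     <dbl>
#> 1 active          142              33.9             2.72      0.150  0.000446
#> 2 inactive          7              55              19.5       0.147  0.00150
```

The virtual rat produced 4,815 active-spout licks and earned 85 rewards
in the hour — fewer than 4815/10 because licks during the 20 s
post-reward timeout are logged but never counted. The analysis recovers
the generator's microstructure: mean ILI 0.150 s against a generative
0.15 s, mean active-spout cluster size 33.9 against a generative 35.7
(sampling variation over 142 clusters). `plot_cumulative_record(rec)`
draws the classic cumulative record; `write_event_log(rec, path)` and
`read_event_log(path)` round-trip the session losslessly through a plain
CSV log.

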