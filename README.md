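# netent

Network entropy for the sequence analysis of dynamic EEG functional
connectivity.

## The problem

Sliding-window functional connectivity turns an ongoing multichannel EEG
recording into a sequence of graphs: electrodes are nodes, and the edge
between channels *i* and *j* in epoch *k* is the equal-time cross-correlation
of the two signals inside that window,

    gamma_ij = | CC(s_i, s_j)(0) | / sqrt( CC(s_i, s_i)(0) * CC(s_j, s_j)(0) ),

with `CC(x, y)(tau) = sum_t x(t + tau) y(t)` and `tau = 0`, so
`gamma_ij` lies in [0, 1]. Single-trial graph sequences built this way are
noisy and riddled with spurious interactions, which makes classical
topological summaries (clustering coefficient, path length, efficiency,
vulnerability) unstable from one epoch to the next.

The approach implemented here summarises each epoch's graph by its
**network entropy (NE)**: the strict upper-triangular edge weights
`{gamma_1, ..., gamma_n}` (n = E(E-1)/2 for E electrodes) are normalised to
a probability distribution `p_i = gamma_i / sum_j gamma_j`, and

    NE = - sum_i p_i * log2(p_i)      [bits],

the Shannon entropy of how evenly "interactive information" is spread over
the network's edges. NE is invariant to rescaling of all weights and to
channel relabelling, and is maximal (`log2 n`, about 7.418 bits for 19
channels) when all edges carry equal weight. Transient reorganisations of
the network — e.g. a subset of channels decoupling from the rest — make the
edge-weight distribution heterogeneous and show up as NE valleys.

Because single NE samples are still noisy, the NE time series is analysed
in time-frequency: a continuous wavelet transform (discrete Meyer "dmey"
wavelet, 1024 scales spanning the 0–0.5 Hz band of the 1 Hz NE series)
yields a scalogram, high-power activities in the 0–0.1 Hz band of interest
are extracted as supra-threshold runs of the power envelope, and the
power-weighted centerline of each run is the extracted event time, which can
be matched against independently recorded event timestamps.

The package is aimed at researchers doing event-related analysis of
continuous EEG (e.g. fatigue monitoring during prolonged tasks) who need a
single-trial, leakage-tolerant summary of dynamic network reorganisation.

## What is in the package

* `read_eeg()` / `read_edf()` / `write_edf()` — EDF and delimited-matrix I/O;
  `read_events()` / `write_events()` — TSV event tables.
* `band_select()`, `threshold_correct()` — wavelet preprocessing: retain the
  18.75–37.5 Hz dyadic detail band and zero coefficients above
  `mean(C) + 2 sd(C)` (two passes) to suppress movement/muscle artifacts.
* `build_fcgb_sequence()`, `ne_series()` — the connectivity-graph sequence
  and its network-entropy series.
* `ne_scalogram()`, `detect_high_power_regions()`, `match_events()` — the
  time-frequency event localisation chain.
* `find_threshold()`, `compute_metrics()`, `metrics_series()` —
  connectedness-based binarisation (largest threshold whose binary graph has
  a positive Fiedler value, searched from T = 1 downward in steps of 0.01)
  and the four classical comparison metrics.
* `synth_spec()`, `generate_recording()` — a synthetic 19-channel, 300 Hz
  generator with implanted, timestamped connectivity-drop events.
* `run_netent()`, `write_results()` — the composed pipeline and CSV/JSON
  writers; `exec/fcgb-netent` is a command-line front end
  (`run`, `simulate`, `metrics` subcommands).

## Worked example

Generate the default synthetic validation recording — six 8-second events at
55, 150, ..., 530 s in which half of the channels decouple from the shared
source — and run the full analysis:

```r
library(netent)

spec <- synth_spec(seed = 1)        # 19 ch, 300 Hz, 600 s, 6 events
sim  <- generate_recording(spec)
res  <- run_netent(sim$recording, events = sim$events, preprocess = FALSE)

print(res$ne)
print(res$matches)
```

which prints

```
<ne_series> 591 epochs @ 1 Hz, 171 edges (max 7.4179 bits), range 7.3088..7.4175 bits
<match_result> 6 events, 6 regions, 6 matched; |err|<=10s: 100.0%, <=30s: 100.0%, early: 6
  Pearson r = 1.00000 (p = 3.46e-13)
```

The NE series hovers just below its 171-edge maximum of `log2(171) = 7.418`
bits and dips by roughly 0.1 bits during each event. All six implanted
events are recovered with |error| ≤ 10 s; the extracted times precede the
recorded event centres by ~5 s because epochs are timestamped at the
*start* of their 10 s window. Per-region detail is in `res$regions`
(start/end/centerline per high-power activity), and
`write_results(res, "out/")` writes `ne_series.csv`, `regions.csv`,
`matches.csv`, `summary.json` and the scalogram axes.

The same analysis from a shell:

```sh
exec/fcgb-netent simulate --out sim --seed 1
exec/fcgb-netent run --eeg sim/recording.csv --events sim/events.tsv \
    --fs 300 --out results --no-preprocess
```

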