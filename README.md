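# shimmerwave

Single-agent analysis of shimmering-wave propagation in Giant honeybee
(*Apis dorsata*) colonies.

Giant honeybees defend their open nests with *shimmering*: surface bees flip
their abdomens upward in cascades that sweep across the bee curtain like
Mexican waves and repel scanning predatory wasps.  The null model of how
such a wave travels is *bucket bridging* — information is handed from one
bee to her immediate neighbour like a fire-brigade bucket — which makes
three testable predictions for any individual "focus bee" that joins a
wave:

* **linearity** — her trigger should come from the direction the wave comes
  from (*directed-trigger* hypothesis),
* **continuity** — most of her recently active neighbours should sit in
  that same trigger direction (*active-neighbours* hypothesis),
* **graduality** — her flip strength should be proportional to that of her
  previously active neighbours (strength coupling `ws_fb ~ k * ws_nb`,
  with `k > 0`).

`shimmerwave` implements the full measurement chain behind these tests:

1. **Motion metric** — pixel-wise luminance differencing of consecutive
   8-bit frames, summed over a 60 × 60 px region of interest per bee
   (`_rel_XYmov`; the quiescent level of ~3 per pixel sums to a normalized
   1.08, massive flips reach tenfold that).
2. **Incident detection** — a wave incident requires the supra-baseline
   excess to exceed the participation threshold for at least 5 successive
   frames; its onset `t0` is the frame before the sharp rise, and peaks are
   graded into eight wave-strength levels `c_ws`.
3. **Neighbourhood analysis** — near (r < 40 mm) and far (r < 100 mm)
   neighbourhoods, an 8-sector angular convention, trigger assignment
   (nearest near neighbour active at most 5 frames earlier in the same
   wave), and an automated plane-wave fit for the key wave direction
   (`dir_WAV` 1–4).
4. **The three statistics** — trigger-direction histograms with
   coincidence tests and two directedness estimates, active-neighbour
   profiles around the trigger angle with an excess rate, and
   direct-sector vs opposite-sector strength regressions with
   `100·r²` shares.
5. **Time courses** — ensembles synchronized at `t0`, threshold-crossing
   transfer times (14 levels, `_rel_XYmov` 1.0–2.3), and propagation speed.
6. **Synthetic data** — an agent-based excitable-media simulator (hexagonal
   lattice, 200 ms flip pulses, 800 ms refractory phase, tunable directed
   fraction `p_directed` and strength coupling `k_couple`) with full
   trigger ground truth, plus a grayscale frame renderer, so every stage is
   validated by parameter recovery without field video.

## Worked example

Simulate one half-directed wave sweeping left to right over ~500 agents,
run the whole analysis chain, and look at the linearity result:

```r
library(shimmerwave)

agents <- build_lattice(c(600, 600), seed = 1)
sim <- simulate_wave(agents, wave_params(dir_true = 3, p_directed = 0.5, seed = 7))
res <- run_pipeline(sim)
res
#> shimmer_result (config 23c2a35f)
#>   488 incidents on 504 agents; 420 focus, 68 untriggered-active
#>   1 wave(s), directions: 3
#>   linearity estimate_B = 44.29%; continuity excess = 31.93%
#>   transfer time 52.20 ms over 28.3 mm -> 0.541 m/s

res$linearity$histogram
#> Trigger-direction histogram (rel_n_fb, rows = dir_WAV):
#>        dir_trig
#> dir_wav    1    2    3    4 5    6    7    8
#>       3 0.25 0.29 0.12 0.59 1 0.54 0.04 0.18
res$linearity$coincidence
#>    3
#> TRUE
```

Reading this: the pipeline detected 488 incidents, classified the wave as
key direction 3 (from Left to Right) from the onset plane fit, and
assigned 420 focus bees a trigger neighbour.  The trigger histogram peaks
in sector 5 ("from Left") — the direction the wave came from — so the
coincidence test passes; with only half of the joins directed, 44% of the
normalized trigger mass sits above the stratum median (estimate B), and
the one-hop transfer time of ~52 ms corresponds to the simulator's
3-frame hop latency.  The classical speed check is a one-liner:

```r
propagation_speed(62, 47.29)$speed_m_s   # 62 mm per 47.29 ms
#> [1] 1.311059
```

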