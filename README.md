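# sertgain

Separable gain analysis of ongoing and evoked cortical activity.

## The scientific problem

Serotonergic (5-HT) input from the dorsal raphe nucleus modulates cortical
population activity, but it acts on two distinct components at once: the
internally generated ongoing ("spontaneous") activity and the sensory-evoked
response. `sertgain` is an analysis pipeline for trial-based experiments that
probe this separability in mouse primary visual cortex (V1): wide-field
calcium imaging movies and multi-unit spike counts recorded under a
four-condition design — visual stimulation (V), visual stimulation with
optogenetic photostimulation of DRN 5-HT neurons (V\_ph), spontaneous
activity (S), and spontaneous activity with photostimulation (S\_ph).

The package answers three quantitative questions:

1. **Is the suppression divisive or subtractive?** Average firing rates in
   4-s windows before and after photostimulation onset are fitted with the
   linear model

   ```
   fr_post = b1 + b2·ph + b3·fr_pre + b4·fr_pre·ph
   ```

   where `ph ∈ {0, 1}` flags photostimulation. `b2` is the subtractive term
   (intercept shift) and `b4` the divisive term (slope change): purely
   divisive suppression with gain `g_s` gives `b4 = g_s − 1`, `b2 = 0`.

2. **Does 5-HT implement contrast normalization?** Peak responses at five
   grating contrasts (100–6.25%) are fitted with the Naka-Rushton function

   ```
   R(c) = R_max · cⁿ / (cⁿ + c50ⁿ) + R0
   ```

   and the tuning of photostimulated responses, scaled by their own maximum
   at 100% contrast, is compared against control tuning. Because the
   Naka-Rushton shape parameters (`c50`, `n`) are invariant under a common
   multiplicative factor, a purely divisive gain collapses the scaled curves
   onto each other; an additive baseline shift does not.

3. **How do the components combine?** The control response is modeled as a
   gain-scaled linear combination of the evoked component
   `E_ph = V_ph − S_ph` (isolated by trialwise subtraction) and the baseline
   component approximated by `S_ph`:

   ```
   V = g · E_ph + g · S_ph ,   g > 1 under suppression
   ```

   The package estimates `g` from baseline-independent response magnitudes
   (|amplitude − baseline| per stimulus), computes the evoked and baseline
   component weights, and compares the awake and anesthetized regimes, where
   the gain and the weight of the baseline component differ.

Throughout, comparisons use one-sided t tests with max-statistic sign-flip
permutation correction for multiple comparisons across stimulus families
(exact enumeration up to 2¹² sign patterns, Monte-Carlo beyond).

Because the original in-vivo recordings are not required, the package ships
a first-class synthetic-data module: a generative model of trial movies
(evoked calcium transients with contrast-dependent amplitude, an
Ornstein-Uhlenbeck ongoing-activity process with divisive photostimulation
gain, an additive baseline shift, a late slow calcium ramp that never enters
the spike counts, heartbeat/respiration sinusoids, a 20-Hz corner-confined
photostimulation artifact, vignetted illumination, pixel noise) with the
ground truth recorded for every parameter-recovery test.

## Worked example

```r
library(sertgain)

protocol <- default_protocol()   # 100 Hz, 30 s, 10 stimuli, photostim 2.5-18.5 s
gt <- ground_truth(state = "anesthetized", seed = 42)
gt
#> <ground_truth> state=anesthetized g_e=0.52 g_s=0.6 offset=-0.02 seed=42

## divisive vs subtractive suppression of spontaneous spiking
s    <- generate_spike_counts(gt, protocol, condition_label("S", "off", "mua"),
                              n_units = 40, n_trials = 20)
s_ph <- generate_spike_counts(gt, protocol, condition_label("S", "on", "mua"),
                              n_units = 40, n_trials = 20)
rec <- build_prepost(rate_traces(s), rate_traces(s_ph), protocol, window_len = 2.5)
fit_suppression(filter_units(rec)$records)
#> <suppression_fit>
#>              b1      b2     b3      b4
#> estimate 0.0091 -0.0083 0.9876 -0.3814
#> se       0.0065  0.0092 0.0114  0.0163

## contrast tuning with and without photostimulation
cp <- contrast_protocol(trial_duration = 10)
m  <- contrast_metrics(gt, cp, n_trials = 20)
fit_naka_rushton(cp$contrasts, m$peaks$V)
#> <naka_rushton_fit> R_max=0.09174 c50=0.2558 n=2.18 R0=0.002223 R^2=1.000
fit_naka_rushton(cp$contrasts, m$peaks$V_ph)
#> <naka_rushton_fit> R_max=0.04927 c50=0.2544 n=2.04 R0=0.0006322 R^2=1.000

g <- estimate_gain(data.frame(magnitude = m$peaks$V,    contrast = cp$contrasts),
                   data.frame(magnitude = m$peaks$V_ph, contrast = cp$contrasts))
round(g$g, 2)
#> [1] 1.90 1.93 1.87 1.85 1.84
```

Reading the numbers: the regression slope change `b4 ≈ −0.38` recovers the
divisive spontaneous gain (`g_s = 0.6` gives a true `b4` of −0.4) while the
intercept term `b2` stays near zero — the suppression is divisive, not
subtractive. The two Naka-Rushton fits share `c50 ≈ 0.25` and `n ≈ 2` while
`R_max` is halved, and the per-contrast gain `g ≈ 1.9` is flat across
contrasts ≈ `1/g_e` — response-gain scaling that preserves contrast tuning.

The full pipeline (simulate → preprocess movies → component metrics →
regression → tuning → gain → report) runs as

```r
run_pipeline(pipeline_config(seed = 1))
```

or from a shell via the thin wrapper `inst/cli/sertgain.R`
(`Rscript inst/cli/sertgain.R all --seed 1 --out results`). Every stage
writes CSV/JSON outputs plus a run log, and repeated runs at the same seed
are byte-identical.

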