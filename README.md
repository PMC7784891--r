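# gammasynch

Quantitative analysis of cortical gamma-band synchrony across the
recording modalities used to characterize NMDAR-hypofunction phenotypes
and their pharmacological rescue: trial-structured LFP (40-Hz auditory
steady-state responses), paired spike trains, paired voltage-clamp sIPSC
recordings, immunofluorescence ROI measurements, and behaviour (Y-maze
spontaneous alternation, prepulse inhibition of acoustic startle).

It is written for electrophysiologists and methods developers who need
these analyses as tested, scriptable building blocks rather than ad-hoc
spreadsheet macros — and, because studies of this kind rarely deposit raw
recordings, it ships a synthetic-data module with genotype/treatment
presets so the complete pipeline can be exercised and validated end to
end with no animal data.

## What it computes

**ASSR metrics** (per channel, 35–44 Hz band, z-scored against the
pre-stimulus record):

- *evoked power* — band power of the trial-averaged LFP in the last
  200 ms of the 500-ms click train, minus the spontaneous band power at
  the mid-point of the inter-stimulus intervals. With n trials of
  uniformly random phase, E[evoked/total] = 1/n;
- *total power* — the same subtraction per trial, then averaged;
  evoked ≤ total always;
- *baseline power* — the last 10 s before the first train, split into
  50 × 200-ms segments;
- *intertrial coherence* — ITC(f,t) = |n⁻¹ Σₖ exp(iφₖ(f,t))| over STFT
  phases (0–100 Hz, 200-ms Hann windows, 60% overlap); under uniform
  phase E[ITC] = √(π/4n);
- *N1* — magnitude of the first prominent negative peak of the averaged
  ERP (10–100 ms search window).

**Spike synchrony** — zero-lag Pearson correlation of 5-ms binned counts
for unit pairs from one tetrode, a ±100-ms correlogram, and an
ISI-shuffle null (rate- and interval-multiset-preserving).

**Synchronous sIPSCs** — event detection on paired traces (strict
"> 5 pA" rule, running-median baseline, prominence pruning) and the
coincidence measure: an event is synchronous iff the other cell has an
event within a closed ±10 ms window; pct = 100(s_A + s_B)/(n_A + n_B).
For Poisson mixtures with total per-cell rate r and shared rate s the
expectation is 100·[s + (r−s)(1−e^(−2wr))]/r, implemented as
`expectedSynchronousPct()`.

**Scalar quantifiers** — corrected total cell fluorescence
(CTCF = integrated density − area × mean background) with
reference-normalized percentages; alternation index (overlapping distinct
triplets; chance = 50% with 3 arms); %PPI per prepulse intensity.

**Virtual experiment** — `runExperiment()` simulates the full battery per
condition preset (default 5 animals × 3 channels × 50 trials), aggregates
per animal / per channel, and reports the eight phenotype contrast signs
and the treated-preset restoration pattern.

## Worked example

```r
library(gammasynch)

x <- generateAssrTrials(makePreset("control"), nTrials = 50, seed = 1)
x
#> LFPTrialSet: 50 trials x 1500 samples @ 1000 Hz (raw uV)
#>   window [-0.5, 1] s; 50 mid-ISI segments; prestim 10.0 s
#>   subject s1, channel ch1

xz <- zscoreLfp(x)
assrPower(xz, "evoked")$value     #> 0.2793565
assrPower(xz, "total")$value      #> 0.3805806
baselinePower(xz)$value           #> 0.02924848
intertrialCoherence(xz)
#> ITCMatrix: 101 freqs x 17 times, 50 trials
#>   band metric (35-44 Hz, [0.3, 0.5] s): 0.887
n1Amplitude(xz)$amplitude         #> 2.597532
```

Evoked power (0.28 in z-scored power units) far exceeds the spontaneous
baseline (0.029) and phase locking is strong (ITC 0.89): the control
preset is firmly entrained. The same calls on
`makePreset("mutant")` give an evoked value near zero, roughly doubled
baseline power and ITC around 0.3.

```r
pair <- generateSpikePair(6, 0.3, duration = 300, seed = 2)
shuffleNull(pair, nShuffles = 100, seed = 3)
#> CrossCorrResult: zero-lag r = 0.2928 (5-ms bins, 60000 bins)
#>   shuffle null: mean -0.0000, sd 0.0042, observed quantile 1.000

tr <- generateEventTrainPair(2.848, 0.645, duration = 300, seed = 4)
synchronousFraction(tr)
#> SynchronyResult: 25.21% synchronous (+/-10 ms window)
#>   events: 1015 (A) / 1044 (B); mean IEI: 295.5 / 287.2 ms
expectedSynchronousPct(3.493, 0.645)
#> [1] 23.96709
```

The observed spike correlation (0.29 ≈ the generator's shared fraction
0.3) sits far above the shuffle null (quantile 1.000), and the single
sIPSC pair's 25.2% synchronous events scatters around the closed-form
expectation of 24.0% for its rates.

A full virtual experiment:

```r
res <- runExperiment(experimentConfig(seed = 1), outDir = "results/run1")
res$contrasts   # group means, contrast signs, restoration flags
```

`scripts/run_experiment.R` wraps this for the shell
(`Rscript scripts/run_experiment.R --out results/run1 --seed 1`).

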