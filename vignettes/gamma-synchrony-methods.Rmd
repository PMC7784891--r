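---
title: "Quantifying gamma-band synchrony: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gamma-band synchrony: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammasynch)
```

# The measurement problem

Cortical gamma oscillations (~30--80 Hz) are generated largely by
parvalbumin-positive (PV) GABAergic interneurons rhythmically inhibiting
pyramidal cells. When NMDA-receptor signalling in these interneurons is
impaired, a characteristic double dissociation appears: the gamma response
*evoked* by a periodic stimulus shrinks, while *spontaneous* (baseline)
gamma power grows. The same circuit defect shows up at three other levels
of observation: pairs of nearby pyramidal cells fire less synchronously in
vivo, pairs of simultaneously patched pyramidal cells receive fewer
synchronous spontaneous IPSCs ex vivo, and the animals perform worse in
spatial working memory (Y-maze alternation) and sensorimotor gating
(prepulse inhibition of startle).

`gammasynch` implements the complete quantitative battery for this kind of
study -- the auditory steady-state response (ASSR) power and phase
metrics, spike-pair cross-correlation with a shuffle null, sIPSC
coincidence detection, fluorescence and behaviour quantifiers -- together
with a synthetic-data generator whose condition presets let every stage be
exercised, end to end, without animal recordings.

# ASSR metrics

The stimulus is a 500-ms click train at 40 Hz, presented 50 times with a
20-s inter-stimulus interval (ISI); a continuous recording of at least
10 s precedes the first train. All LFP segments are z-scored against the
mean and SD of that pre-stimulus record (`zscoreLfp()`). The pre-stimulus
record is used as the normalization reference because it is the only
stimulus-free epoch guaranteed present in every recording.

Four quantities are computed per channel, all in the 35--44 Hz band:

* **Evoked power** (`assrPower(x, "evoked")`): band power of the
  *trial-averaged* trace in the last 200 ms of the stimulus, minus the
  spontaneous band power estimated from 200-ms segments taken at the
  mid-point of each preceding ISI. Sensitive to amplitude *and*
  cross-trial phase consistency: with $n$ trials of fixed amplitude and
  uniformly random phase, the expected evoked/total ratio is exactly
  $1/n$ (the expectation of the squared resultant of $n$ unit vectors).
* **Total power** (`assrPower(x, "total")`): the same subtraction applied
  per trial before averaging power. By a Jensen-type inequality evoked
  power never exceeds total power, a property the test suite checks on
  arbitrary inputs.
* **Baseline power** (`baselinePower()`): the final 10 s of the
  pre-stimulus record split into exactly 50 contiguous 200-ms segments,
  each decomposed, band power averaged.
* **Intertrial coherence** (`intertrialCoherence()`):
  $\mathrm{ITC}(f,t) = |n^{-1}\sum_k e^{i\phi_k(f,t)}|$ over per-trial
  STFT phases, computed 0--100 Hz; the band summary is the mean over
  35--44 Hz in the last 200 ms of the stimulus. Under uniform phase the
  expected resultant length is $\sqrt{\pi/4n}$ (Rayleigh), another
  tested oracle.

The **N1** is reported as the magnitude of the minimum of the
trial-averaged trace within a 10--100 ms post-onset search window. "First
prominent negative peak" needs an operational window; 10--100 ms brackets
the rodent auditory N1 latency. If the trace has no interior local
minimum there, the value at the window minimum is returned with a flag.

## Estimator choices

* **Morlet, 7 cycles, 1-Hz steps** for all band-power summaries. Seven
  cycles is the field-standard compromise between time and frequency
  resolution at gamma (at 40 Hz, $\sigma_t \approx 28$ ms).
* **Hann STFT, 200-ms windows, 60% overlap, zero-padded to a 1-Hz grid**
  for the ITC path. The overlap is the stated analysis convention; the
  200-ms window length is chosen to match the 200-ms spontaneous
  segments, so every power estimate in the pipeline is computed on the
  same segment length.
* **Identical-estimator principle**: the evoked/total window (200 ms),
  the mid-ISI segments (200 ms) and the baseline segments (200 ms) are
  all decomposed by the same Morlet estimator on equal-length segments.
  Wavelet edge attenuation then cancels in every subtraction and ratio,
  which is what makes "no evoked component $\Rightarrow$ stimulus-band
  power equals mid-ISI power" hold without correction factors.
* **Spontaneous subtraction in the power domain** (z-scored power
  units) is the default; a `spontaneous = "trace"` flag subtracts each
  trial's mid-ISI segment in the time domain instead. Power-domain is
  the default because subtracting a *power amplitude* is the only
  reading under which the spontaneous estimate, computed from segments
  recorded seconds away from the trial, is phase-free.
* **Zero-power bins** have no defined phase; ITC marks them excluded
  (NA) rather than substituting a value.
* Degenerate inputs error early and specifically: a flat pre-stimulus
  record (zero SD), a window outside the trial span, a record shorter
  than 10 s, frequencies above Nyquist.

# Spike-pair synchrony

Spike trains of two units from one tetrode are binned at 5 ms (half-open
bins over the session) and summarized by the zero-lag Pearson correlation
of the count vectors; a correlogram over $\pm 100$ ms is attached. No bin
width is canonical in the literature; 5 ms resolves near-coincident
firing while keeping per-bin counts informative, and the width is an
argument everywhere. "Synchrony" is deliberately operationalized as the
zero-lag coefficient (one number per pair); the peak over lags is
available from the correlogram.

The null (`shuffleNull()`) permutes the inter-spike intervals of one
train -- preserving its spike count, rate and ISI multiset exactly -- and
recomputes the coefficient; the observed value is reported with the null
mean, SD and its empirical quantile. A zero-variance count vector makes
the coefficient undefined; it is returned as a flagged missing value, not
as 0.

# Synchronous sIPSCs

Events are detected on rectified traces (positive IPSC magnitudes) as
local maxima of the running-median-subtracted signal exceeding a strict
5-pA threshold, pruned largest-first with a 2-ms minimum separation and a
prominence rule (a secondary peak must rise more than the threshold above
the trough separating it from its accepted neighbour) so that noise
riding a decay shoulder is not counted. An event of exactly 5 pA is
excluded -- the threshold is "> 5 pA".

A pair-level event is **synchronous** iff the other cell has at least one
event within a closed $\pm 10$ ms window. The headline percentage pools
both cells' events, $100(s_A + s_B)/(n_A + n_B)$, which makes the measure
symmetric and bounded; per-cell percentages are also reported. A
one-to-one matching scheme is deliberately *not* imposed: the original
detection rule defines a window, not a pairing, and the per-event
$\geq 1$-partner reading admits a closed-form null. For independent-plus-
shared Poisson trains with total per-cell rate $r$ and shared rate $s$,

$$\mathrm{E[pct]} = 100\,\frac{s + (r - s)\left(1 - e^{-2wr}\right)}{r},
\qquad w = 10\ \mathrm{ms},$$

implemented as `expectedSynchronousPct()` and used as the oracle for the
generator round-trip tests. Inter-event intervals are successive
differences per cell; the grand mean pools both cells.

# Behaviour and fluorescence

* **Y-maze alternation**: percentage of overlapping triplets of
  consecutive arm entries visiting three distinct arms. With three arms
  and entries that are always transitions, a memoryless random explorer
  scores exactly 50% -- the chance line -- which the test suite confirms
  by exhaustive enumeration of all equally likely 15-entry sessions.
* **%PPI**: per prepulse intensity,
  $100(\bar{S}_{\mathrm{pulse}} - \bar{S}_{\mathrm{prepulse}}) /
  \bar{S}_{\mathrm{pulse}}$ using trial means; facilitation yields a
  negative value, returned unclipped.
* **CTCF**: integrated density $-$ area $\times$ mean background (the
  standard ImageJ ROI correction; the upstream protocol is cited rather
  than restated in the source study, so the standard formula is assumed
  and documented). `normalizedFluorescence()` expresses each cell as a
  percentage of a reference group's mean CTCF, which maps the reference
  mean to 100% by construction.

# The synthetic generator

Each condition is a frozen `GenotypePreset` (see `presetTable()` for the
single versioned table). An ASSR trial is pink (1/f) noise, plus an
ongoing narrow-band 35--44 Hz Gaussian process present in every segment,
plus -- during the stimulus -- a 40-Hz sinusoid whose per-trial phase is
von Mises distributed (concentration $\kappa$ maps directly onto ITC;
$\kappa = 0$ is uniform phase), plus a negative Gaussian N1 (25-ms FWHM,
centred 40 ms post-onset). The entrained sinusoid ramps up quadratically
over its first 150 ms, emulating the build-up of steady-state entrainment
over the first cycles; this keeps the onset ERP separable from the
entrained oscillation while leaving the 300--500 ms analysis window at
full amplitude. Pink noise and the narrow-band process are synthesized by
spectral shaping (shaped amplitudes, random phases), which is cheap,
exactly seedable, and linear in the amplitude parameter -- so doubling
the baseline amplitude under a fixed seed exactly quadruples band power,
a property used in the tests.

sIPSC pairs are independent-plus-shared Poisson mixtures; shared events
are copied to both cells with independent $\pm 3$ ms uniform jitter, so
both copies always fall inside the $\pm 10$ ms window (relative offset
$\leq 6$ ms). Spike pairs superpose a shared Poisson component of rate
$p \cdot \mathrm{rate}$ injected into both trains and independent
components of rate $(1 - p)\mathrm{rate}$, giving marginal rate
`rate` per train and expected zero-lag count correlation exactly $p$ at
fine bins -- the thinned-Poisson oracle the tests check by simulation.

**Calibration.** The study the battery replicates reports its LFP effects
only as z-scored figure panels, so the presets are calibrated to (a) the
printed sIPSC and behaviour numbers where they exist -- control sIPSC
rates 2.848 + 0.645 Hz and mutant rates 2.151 + 0.180 Hz give total rates
of 3.493 and 2.331 Hz, i.e. mean inter-event intervals of 286.3 and
429.0 ms and expected synchronous percentages of 23.98% and 11.99% under
the closed form -- and (b) ordering relations everywhere else (mutant:
lower evoked amplitude and phase concentration, higher baseline gamma,
smaller N1, weaker spike sharing, chance-level alternation, reduced PPI).
The treated presets (`mutant_gsk3b_inhibited`, `mutant_gsk3b_knockdown`)
equal control on every field except the N1 depth, which stays at the
mutant level -- GSK3$\beta$ inhibition normalizes the oscillatory and
behavioural phenotype but not the N1 -- and `mutant_gsk3a_inhibited`
equals the mutant (no rescue). Amplitude-type values (evoked 25 vs 8 uV
over 15-uV pink noise, baseline gamma 6 vs 12 uV, N1 40 vs 20 uV,
$\kappa$ 6 vs 1.2) were chosen once as physiologically plausible
microvolt-scale settings that make the contrasts unambiguous at the
study's sample sizes, and live in `presetTable()`.

**What the generator does not emulate**: biophysical gamma generation
(no conductance-based network), recording artifacts and non-stationarity,
spike waveforms and sorting errors, IPSC kinetic diversity, habituation
of startle, and within-animal correlation across modalities (each
modality is simulated independently per animal). Passing tests therefore
demonstrate that the *analysis chain* is correct and recovers known
ground truth under realistic statistics -- not that it is robust to every
pathology of real recordings.

# The virtual experiment

`runExperiment()` simulates the full battery per condition -- by default
5 animals x 3 LFP channels (15 channels per condition, mirroring the
study design), 50 trials per channel, one spike pair, one sIPSC pair, one
Y-maze and one startle session per animal -- aggregates per animal and
per channel, and checks the eight phenotype contrast signs (evoked, ITC,
N1, spike r, sIPSC %, alternation, PPI lower in mutant; baseline power
higher) plus the restoration pattern of the treated presets (everything
restored except N1). All randomness derives from one master seed through
a fixed stream-derivation scheme, so reruns are byte-identical; group
statistics beyond descriptive means are intentionally left to standard
tools (`aov()`, `TukeyHSD()`) on the exported metric tables.

Problem sizes in the shipped tests were chosen to make every stochastic
check decisive at 3-Monte-Carlo-SE tolerances while keeping the whole
suite fast: e.g. 2000 Y-maze sessions, 10--11 sIPSC pairs of 300 s
(matching the study's pair counts), 20--40 replicate spike pairs of
150--200 s, 20-seed ASSR property loops, and 10 replicate virtual
experiments at the full 5 x 3 x 50 scale.

# Known limitations

* Absolute power values depend on the unit-gain Morlet convention
  (a sinusoid of amplitude $A$ has analytic power $A^2/4$ at its
  frequency); only differences, ratios and orderings are interpreted.
* Wavelet/STFT edge effects are not corrected, only cancelled by the
  equal-segment-length design; single-segment spectrograms show edge
  attenuation.
* The ISI shuffle preserves each train's interval statistics but not
  slow co-modulation of the pair; for strongly non-stationary sessions a
  jitter null would be a useful addition.
* The coincidence closed form assumes Poisson statistics; for bursty
  event trains it serves as an approximation, and the empirical detector
  remains the measurement.
* On-disk interchange is deliberately plain text (CSV/JSON/YAML) with
  documented schemas.
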