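---
title: "Methods: PLI connectivity, betweenness hubs, and the simulated cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLI connectivity, betweenness hubs, and the simulated cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

plihub analyzes resting-state EEG as a functional network: band-limited
phase coupling between electrodes defines a weighted graph, and the
betweenness centrality of each electrode quantifies its role as a hub.
This vignette documents the model, the estimation choices, the synthetic
cohort generator used to validate the chain end to end, and the known
limitations.

## Signal model and preprocessing

The expected input is a 16-channel recording on the 10-20 sites Fp1, Fp2,
F3, F4, Fz, F7, F8, C3, C4, P3, P4, Pz, T5, T6, O1, O2, sampled at 200 Hz,
with a 600-s artifact-free segment per subject. Each record is filtered
into five bands — delta 2–4, theta 4–8, alpha 8–13, beta 13–30, gamma
30–60 Hz — with a 4000th-order (4001-tap) linear-phase FIR filter designed
by the windowed-sinc method with a Hamming taper (`signal::fir1`). The
even order makes the filter type I: exactly symmetric coefficients, a
constant group delay of 2000 samples, and therefore no phase distortion,
which is what a phase-based connectivity metric requires. At this order
the transition width is about 0.16 Hz, with stopband loss well beyond
40 dB one transition width outside each edge.

Filtering is applied to the continuous record, once per band, before any
epoching. A 4001-tap filter cannot meaningfully be applied to a 1000-sample
epoch, so filtering-then-epoching is the only coherent ordering; the edge
epochs are excluded afterwards (below), which also absorbs any residual
startup transient. Implementation-wise, all five band filters share one
forward FFT of each (reflection-padded) channel; the group delay is removed
so outputs are time-aligned with the input. The padding is widened to a
power-of-two transform length when possible; this changes only the values
inside the reflected margin, never the retained samples, and the output is
verified in the tests against direct time-domain convolution.

An optional 58–62 Hz band-stop for mains interference can be enabled
(`analysis_options(notch = TRUE)`); it is off by default because the
synthetic data carry no line noise. The 1.5–60 Hz acquisition-side bandpass
of the emulated protocol is treated as a property of the input and is not
re-applied.

Each band-filtered record is cut into contiguous, non-overlapping 5-s
epochs (1000 samples), and the first and last epochs are dropped; a 600-s
record thus yields 118 analyzed epochs. Five seconds balances two
competing errors: the per-epoch phase-lag index falls with epoch length,
while very short epochs cannot capture slow delta cycles.

## Phase lag index

Within each epoch the instantaneous phase of every channel is the argument
of the analytic signal, computed over that epoch by the FFT method. For an
electrode pair with phase difference $\Delta\varphi(t_k)$, $k = 1,\dots,T$
(wrapped to $(-\pi, \pi]$), the phase lag index is

$$\mathrm{PLI} = \left| \frac{1}{T} \sum_{k=1}^{T}
  \operatorname{sign}\,\Delta\varphi(t_k) \right| \in [0, 1],$$

with $\operatorname{sign}(0) = 0$. A consistent nonzero-lag phase relation
gives values near 1; independent signals, and — crucially — signals mixed
instantaneously from a common source (volume conduction), give values near
0, because zero- and $\pi$-lag differences contribute no consistent sign.
The absolute value is applied so the statistic lands on the stated
$[0, 1]$ range; without it the sum is signed. Per-epoch PLI values are
averaged into one symmetric 16×16 matrix per subject and band.

Two estimation subtleties are worth recording. First, the per-epoch
absolute value gives the estimator a positive floor under independence
that does not vanish with more epochs (only with longer epochs); slow
bands, whose phase differences drift slowly, have the highest floor. This
is a property of the statistic, not a bug, and the tests assert it
explicitly: the single-epoch PLI of independent channels does fall toward
0 as the record grows. Second, the pipeline computes the sign of the
wrapped phase difference from the analytic samples directly
($\operatorname{sign}\,\mathrm{Im}\, z_a \bar z_b$), which is the same
sign except on a measure-zero boundary; the tests pin both routes to a
literal scalar re-coding of the definition.

## Inverse-PLI graphs and betweenness hubs

The functional graph is the complete weighted graph on the 16 electrodes
with edge length $1/\mathrm{PLI}$ — stronger coupling, shorter path. An
exactly zero PLI removes the edge (infinite length); disconnected pairs
simply contribute no shortest paths. No minimum-spanning-tree or
threshold backbone is applied: pruning weak edges changes global path
structure, and the hub statistic is intended to see the whole network.

For node $i$, betweenness is

$$b_i = \frac{1}{(n-1)(n-2)} \sum_{h \ne j,\ h \ne i,\ j \ne i}
  \frac{\rho_{hj}(i)}{\rho_{hj}},$$

summed over ordered pairs, where $\rho_{hj}$ counts minimum-length paths
and $\rho_{hj}(i)$ those passing through $i$. The ordered-pair sum with
the $(n-1)(n-2)$ normalization maps a star center to exactly 1. Shortest
paths are found by Brandes' dependency-accumulation scheme over a dense
Dijkstra; co-minimal paths share credit through the path counts, with a
relative tolerance of $10^{-12}$ when comparing floating-point lengths
(ties are never broken arbitrarily). The implementation is checked against
exhaustive path enumeration on random graphs up to seven nodes and against
igraph on tie-free weighted graphs.

By default betweenness is computed once per subject and band from the
epoch-averaged PLI matrix; `analysis_options(bc_per_epoch = TRUE)` instead
computes per-epoch profiles and averages those. The epoch-averaged default
is the conventional reading of building "the" functional network first;
the switch exists because the alternative ordering is defensible and the
choice is not settled by the emulated protocol.

## Group statistics

Per band, BC profiles enter a mixed repeated-measures ANOVA with group
(control vs patient) as the between-subject factor and electrode (16
levels) as the within-subject factor. Sums of squares come from the
standard split-plot decomposition (`stats::aov` error strata); with one
between factor, the group and group×node tests agree with the Type III
results of SPSS-style software (verified against `car::Anova`), while the
node main effect follows the sequential decomposition — immaterial here,
since inference rides on the group and interaction terms. Within-subject
effects receive the Greenhouse–Geisser correction, with
$\hat\varepsilon = \mathrm{tr}(E)^2 / (\mathrm{df}\,\mathrm{tr}(E^2))$,
$E = M^\top S M$ for orthonormal effect contrasts $M$ and the pooled
within-group covariance $S$, clipped to $[1/\mathrm{df}, 1]$; between-
subject degrees of freedom are left uncorrected. Effect sizes are partial
$\eta^2$ = SS~effect~/(SS~effect~ + SS~error~); the unqualified
$\eta^2$ printed by common repeated-measures software is the partial
form, so that is what is reported.

Post hoc electrode-level t-tests (pooled-variance two-sample for group
contrasts; paired for pre/post) run only in gated bands. The gate: a band
enters post hoc testing when its group main effect is significant at the
Greenhouse–Geisser-corrected $p < 0.05$, or when its interaction survives
Benjamini–Hochberg correction *across the five bands* at $q \le 0.05$ —
the two familywise scopes are reported side by side in the ANOVA table
(`p_gg` and `q_bands`). Within a gated band the 16 electrode p-values form
one BH family, with significance at $q \le 0.05$ (the classical step-up
rule $p_{(i)} \le i\,q/m$). Electrodes whose BC values are constant within
both groups but differ between them — possible in very small cohorts,
where betweenness takes exactly tied rational values — separate the groups
perfectly and are reported as infinite t with $p = 0$ rather than
aborting the family. Pearson correlations (two-sided, $\alpha = 0.05$) of
flagged BC values against symptom score and age, a paired t-test for
pre/post score changes, and a deterministic top-20% edge list
(lexicographic tie-breaking) complete the layer.

The pre/post treatment analysis is a two-within-factor ANOVA (condition ×
electrode) on paired subjects, with per-effect Greenhouse–Geisser epsilons
from the 32-cell covariance; the 2-level condition factor has
$\varepsilon \equiv 1$.

## The synthetic cohort generator

No clinical recordings accompany the emulated study, so validation rests
on a generator whose ground truth is known. Each subject is a sum of four
components:

1. **Band oscillations.** Every channel carries one narrowband oscillator
   per band: constant amplitude, phase advancing at the band center
   frequency plus a random-walk increment (a phase-diffusion, Lorentzian-
   linewidth process). Pure sinusoids would make every phase statistic
   degenerate; diffusing phases give epoch-to-epoch variability and
   realistic sub-1 PLI values. The linewidth defaults to 25% of each
   band's width. Diffusion steps are drawn once per 25 ms block with the
   step variance scaled to keep the linewidth unchanged. Default
   amplitudes (µV): delta 10, theta 8, alpha 15, beta 6, gamma 3 — an
   eyes-closed, alpha-dominant resting profile.
2. **Hub coupling.** A `hub_spec(electrode, band, targets, coupling c,
   lag)` injects the hub channel's oscillation into each target at a fixed
   phase lag: the target's band component becomes
   $\sqrt{1-c^2}\,\mathrm{own} + c\,\mathrm{hub}_{-\mathrm{lag}}$
   (variance-preserving). Injection at a fixed lag, rather than
   bidirectional dynamical coupling, gives direct control of the planted
   lag; the default lag is $\pi/4$, and lags of 0 or $\pi$ are rejected
   for active hubs because they are invisible to the PLI by construction.
3. **Common source.** One zero-lag broadband mixture (half-amplitude
   copies of per-band oscillators) is added identically to all channels,
   scaled by `common_source_gain` (default 1). This is the volume-
   conduction surrogate: it drives amplitude correlations toward 1 while
   leaving the PLI unmoved, a property the tests assert.
4. **Background.** 1/f-shaped noise per channel (spectral shaping of white
   noise, flattened below 1 Hz), `noise_gain` = 5 µV SD by default.

Group structure: both groups share hubs at (Fz, beta), (Pz, gamma) and
(O1, gamma); default couplings are 0.80/0.80/0.15 in controls and
0.35/0.35/0.60 in patients, so the patient group shows a frontal-beta BC
decrease, a parietal-gamma decrease and an occipital-gamma increase — the
default recovery scenario. The coupling levels are calibrated, once, to
make the full gated pipeline recover all three contrasts with correct
signs in at least 80% of study-sized replicate cohorts; no effect size in
the emulated study is convertible into a coupling strength, so power is
the calibration target. Per-subject coupling varies by a latent standard
normal `z` (SD 0.05 on the coupling scale), and patient BPRS scores are
drawn as $52.6 + 13.2\,(\rho z + \sqrt{1-\rho^2}\,e)$ with $\rho = 0$ by
default (the emulated study found no significant BC–symptom correlation).
Pre/post cohorts reuse each subject's latent state, scale couplings by a
treatment factor (1 by default), and draw score improvements with mean 13
and SD 16.3, matching a completer group of 14 with a paired t near 3.

Every subject derives a private RNG substream from (cohort seed, group,
index, session), so cohorts are bit-reproducible and adding subjects never
changes existing ones.

**What the generator does not emulate:** head-volume conduction geometry
(the common source is spatially uniform), artifacts (blinks, EMG, line
noise), non-stationarity across the recording, reference-electrode
effects, and cross-frequency coupling. Passing tests therefore demonstrate
that the pipeline recovers the structures it is designed to measure — not
that those structures are estimated without bias on real clinical EEG.

## Numerical and validation choices

* Phase differences are wrapped to $(-\pi,\pi]$ before taking signs;
  `sign(0) = 0` exactly.
* Path-length comparisons in Brandes accumulation use relative tolerance
  $10^{-12}$; betweenness agrees with exhaustive enumeration to
  $10^{-9}$ on random graphs with up to 7 nodes.
* Degenerate inputs fail loudly: all-zero epochs (undefined phase),
  zero-variance correlation inputs, non-symmetric covariances, unpaired
  pre/post tables. The one deliberate exception — constant-but-separated
  electrodes inside the gated post hoc family — is described above.
* Text outputs carry 17 significant digits, so persisted matrices re-read
  bit-exactly and two runs with the same seed are byte-identical. EDF
  output quantizes to 16 bits over a per-channel symmetric range (error
  at most half a quantization step); header timestamps are fixed rather
  than wall-clock so exports are also deterministic.
* Validation problem sizes: statistical calibration uses 200 null cohorts
  of 15 + 15 subjects with 60-s records (the null is two groups with
  identical hub specifications), and hub recovery uses 50 study-sized
  (31 + 21) cohorts at 60-s records; the acceptance script runs one full
  600-s study-sized cohort. The 60-s records keep simulation studies at
  10 analyzed epochs per subject, which is the main reason their absolute
  PLI levels sit above the 118-epoch values of the full protocol.

## Limitations

The gamma band is implemented exactly as specified (30–60 Hz), without a
high/low-gamma split; no re-referencing (for example a surface Laplacian)
is offered, matching the emulated acquisition with linked-earlobe
reference; directed and weighted PLI variants, coherence and amplitude-
envelope metrics are out of scope; and artifact detection is assumed to
have happened upstream of the 600-s segment.
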