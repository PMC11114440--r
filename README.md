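# plihub

Hub analysis of resting-state EEG functional networks: phase lag index
(PLI) connectivity, inverse-PLI weighted graphs, normalized betweenness
centrality (BC) per electrode, and the group-level statistics that turn
per-subject hub profiles into findings — mixed repeated-measures ANOVA
with Greenhouse–Geisser correction and Benjamini–Hochberg-controlled post
hoc electrode tests. It is written for EEG researchers who want a tested,
reproducible implementation of this analysis chain, together with a
coupled-oscillator cohort simulator that makes every stage verifiable
without access to clinical recordings.

## The analysis

For 16-channel 10-20 recordings (200 Hz, 600-s artifact-free segments),
each record is filtered into delta (2–4), theta (4–8), alpha (8–13), beta
(13–30) and gamma (30–60 Hz) bands with a 4001-tap linear-phase Hamming
FIR filter, cut into 5-s epochs (first and last excluded; 118 analyzed
epochs), and reduced to instantaneous phases by the Hilbert transform per
epoch. For each electrode pair the phase lag index

    PLI = | (1/T) * sum_k sign( delta_phi(t_k) ) |,   delta_phi in (-pi, pi]

measures consistent nonzero-lag phase coupling (0 = none or zero-lag
only, hence insensitivity to volume conduction; 1 = perfect fixed-lag
locking). Per-epoch values are averaged into one 16 x 16 matrix per
subject and band. The functional graph uses edge lengths 1/PLI, and each
electrode's betweenness

    b_i = [ sum_{h != j, both != i} rho_hj(i) / rho_hj ] / ((n-1)(n-2))

(Brandes accumulation, ordered pairs, whole weighted graph — no MST
pruning) quantifies hub status in [0, 1]. Per band, BC profiles enter a
mixed RM-ANOVA (group x electrode, Greenhouse–Geisser-corrected); bands
with a significant group effect, or an interaction surviving BH
correction across the five bands, proceed to per-electrode t-tests under
BH-FDR at q <= 0.05. See `vignette("plihub-methods")` for the full model
description, the simulator design, and numerical choices.

## Worked example

Simulate a small cohort with the default planted contrasts (patients:
weaker frontal-beta and parietal-gamma hub coupling, stronger
occipital-gamma) and run the whole chain:

```r
library(plihub)

cfg <- cohort_config(n_per_group = c(control = 8, patient = 8),
                     duration_s = 120, seed = 7)
cohort <- generate_cohort(cfg)
res <- analyze_cohort(cohort$recordings, cohort$meta)

subset(res$anova, band %in% c("beta", "gamma") & effect != "node")
#>   band     effect     F df1 df2 epsilon     p_gg  q_bands eta_p_sq
#>   beta      group 116.9   1  14      NA 3.52e-08       NA    0.893
#>   beta group:node 141.8  15 210  0.0932 2.24e-11 5.61e-11    0.910
#>  gamma      group  56.4   1  14      NA 2.84e-06       NA    0.801
#>  gamma group:node 107.4  15 210  0.2870 2.30e-27 1.15e-26    0.885

res$gated_bands
#> [1] "beta"  "gamma"

subset(res$posthoc, significant, c(band, electrode, t, q_bh, direction))
#>   band electrode      t     q_bh direction
#>   beta        Fz -13.10 4.82e-08        -1
#>  gamma        C3  -3.06 4.57e-02        -1
#>  gamma        Pz -17.99 7.17e-10        -1
#>  gamma        O1   6.65 8.81e-05         1
```

Reading the output: the beta and gamma bands show significant group and
group x electrode effects (`p_gg` is the Greenhouse–Geisser-corrected
p-value; `q_bands` the interaction p corrected across the five bands;
`eta_p_sq` partial eta squared), so those bands are gated into post hoc
testing. There, Fz in beta and Pz in gamma show significant BC decreases
in patients (negative t and direction: patient minus control), and O1 in
gamma a significant increase — recovering exactly the planted hub
contrasts. C3, a coupling target of the parietal hub, is also weakly
flagged. With null cohorts (identical hubs in both groups) the same
gated chain flags nothing in the vast majority of replicates.

The command-line interface mirrors this flow
(`simulate | analyze | stats | all`):

```sh
Rscript inst/exec/plihub all --config cohort.yaml --out results/
```

writing per-subject PLI matrices, tidy BC tables, ANOVA/post hoc/
correlation tables, top-20% edge lists and a deterministic JSON manifest;
`stats` re-runs the statistical stage from a previous run's persisted BC
tables. Recordings are read/written as EDF or delimited text.

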