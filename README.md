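# sleeplat

Inter-hemispheric lateralization of sleep EEG markers in focal epilepsy.

A lateralized epileptic focus perturbs the physiological hallmarks of sleep
in its hemisphere, not just the epileptiform discharges it generates.
`sleeplat` implements the full analysis chain that quantifies this: it
detects sleep slow oscillations (delta power, 0.5–4 Hz), discrete slow waves
(negative half-waves of 0.25–1 s on bipolar traces, cross-checked on the
average reference) and sleep spindles (11–16 Hz RMS-envelope detector on
C3-FT9/C4-FT10 during N2), measures the phase locking of spindles to slow
oscillations by inter-trial coherence

    ITC = (1/N) · | Σ_k exp(i·φ_k) |,

and reduces each of nine per-hemisphere features to a per-patient
lateralization index

    LI = (X_left − X_right) / (X_left + X_right).

Group statistics compare LI distributions between left- and right-focus
patients (Mann–Whitney for delta power; Kruskal–Wallis + Dunn's correction
for the slow-wave and spindle families; probability-of-superiority effect
sizes; paired Wilcoxon checks for hemisphere and two-night stability). A
CART decision tree with repeated stratified 5-fold cross-validation then
classifies the side of the focus from the nine LIs, benchmarked against a
label-shuffle null, with Fisher's exact test on the pooled contingency
table, per-feature importance, and the combination of sleep features with
interictal-discharge (IED) asymmetry.

Because clinical recordings cannot be redistributed, the package ships a
synthetic sleep-EEG cohort generator with exact ground truth (1/f
background, injected half-sine slow waves, Gaussian-envelope 13 Hz spindle
bursts with von Mises phase coupling, IED-like transients, configurable
left/right asymmetry of every feature), which the test suite uses for
end-to-end validation. Intended users: clinical neurophysiology and sleep
researchers working with scalp EEG biomarkers of focal epilepsy.

## Worked example

Simulate a small cohort with the default asymmetry profile (higher delta
power, slow-wave amplitude/slope and spindle amplitude on the epileptic
side; lower spindle density; strongly ipsilateral IEDs), then run the whole
study from the ground-truth feature matrices:

```r
library(sleeplat)

cohort <- simulate_cohort(cohort_spec(n_left = 34, n_right = 34, seed = 66),
                          signals = FALSE)
study <- run_full_study(cohort, run_config(n_iter = 150, seed = 12),
                        from_truth = TRUE)
study
```

```
<sleep_study>
Group LI tests (adjusted):
       feature         test        p_adj        es
1   sw_density kruskal_dunn 1.000000e+00 0.4878893
2 sw_amplitude kruskal_dunn 2.121074e-01 0.6332180
3  sw_duration kruskal_dunn 1.000000e+00 0.5458478
4     sw_slope kruskal_dunn 1.000000e+00 0.5726644
5   sp_density kruskal_dunn 4.274579e-05 0.2128028
6 sp_amplitude kruskal_dunn 1.131679e-03 0.7474048
7  sp_duration kruskal_dunn 6.371445e-01 0.5977509
8   sp_locking kruskal_dunn 1.000000e+00 0.5778547
9  delta_power mann_whitney 1.283213e-03 0.7275087

Classification accuracy:
  sleep      68.8% (SD 5.0%)
  shuffle    50.0% (SD 6.6%)
  ied        79.7% (SD 2.2%)
  sleep_ied  79.7% (SD 3.1%)
Fisher's exact p (pooled contingency): 3.95e-323
```

Reading this output: the spindle-density LI separates the groups (adjusted
p < 0.0001, effect size 0.21, i.e. a randomly chosen left-focus patient has
the lower spindle-density LI about 4 times out of 5), spindle amplitude and
delta power also reach significance in this draw, the sleep-only classifier
sits far above its shuffle null (69 % vs 50 %), and IED asymmetry — alone or
combined with sleep markers — does best (80 %): the same qualitative pattern
as on the clinical cohort the method was built for. The Fisher p-value is
extreme because the contingency table pools all 150 iterations.

Signal-level processing works the same way from raw recordings:

```r
rec <- read_recording("patient_night1.edf")     # 10-20 labels normalized
hyp <- read_hypnogram("patient_night1_hypnogram.csv")
features <- extract_night_features(rec, hyp, run_config())
```

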