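# actitraj

Minute-level step counts from wrist-worn activity trackers, turned into
cohort-level evidence for inflammatory arthritis research. The package
implements the full analysis chain used in 90-day observational tracker
studies of rheumatoid arthritis (RA) and axial spondyloarthritis (axSpA):

1. **Ingest & validity** — parse per-participant minute streams
   (`timestamp,steps` CSV), map them onto a 90-day observation window
   starting the first Monday strictly after device activation, apply the
   *full-day rule* (≥ 8 h between first and last steps) and the adherence
   filter (≥ 60 complete days of 90).
2. **Activity patterns** — cadence-based daily features: total steps,
   active minutes (cadence ≥ 20 steps/min), moderate-to-vigorous activity
   (MVPA, ≥ 100), vigorous activity (≥ 130), morning-step fraction;
   per-participant summaries and WHO-recommendation status
   (≥ 150 MVPA min/week or ≥ 75 vigorous min/week; 10,000 and 7,000
   steps/day translations); weekday-mean imputation of missing days;
   tracker-adherence summaries.
3. **Trajectory clustering** — K-means for longitudinal data on whole
   90-day trajectories (Lloyd iterations, multi-start, Euclidean
   distance, clusters relabelled low → high), Calinski–Harabasz partition
   quality `(B/(k-1))/(W/(n-k))` and `select_k()`, cluster profiling.
4. **Inference** — linear mixed models for RA-vs-axSpA comparisons
   (random intercept + day slope, optional power variance function for
   heteroscedasticity), adjusted logistic regressions for recommendation
   fulfillment and low-activity-cluster membership (BMI odds ratio per
   5 units, age dichotomized at 60), and the design-stage two-sample
   sample-size formula
   `n = ⌈2((z₁₋α/₂ + z₁₋β)σ/δ)²⌉`.
5. **Synthetic cohort** — a generator with known ground truth (three
   latent MVPA classes, Sunday dips, heterogeneous non-wear, partial
   days, covariate effects) so every stage is testable without raw
   device data; see the methods vignette
   (`vignettes/activity-trajectories.Rmd`) for what it does and does not
   emulate.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

```r
library(actitraj)

cfg <- pipeline_config(
  cohort = cohort_spec(n_participants = 178, seed = 43),
  seed   = 43
)
report <- run_pipeline(cfg)
report
#> <study_report>
#>   flowchart: 178 included = 156 analyzable + 22 excluded (>= 60 complete days)
#>   adherence: worn 79.4 days on average (88% of days)
#>   activity: 7471 steps/day, 15.1 MVPA min/day, 32.7% meet >=150 MVPA min/week
#>   clusters (mvpa_minutes): 1/156 (53.8%) mean 6.8; 2/156 (34.0%) mean 21.7; 3/156 (12.2%) mean 33.0
#>   imputed vs complete-case cluster agreement: 100.0%
```

Reading the output: of 178 included participants, 156 wore the tracker for
at least 60 complete days and are analyzable; they averaged ~7,500
steps/day but only ~15 min/day of MVPA, so only about a third reach the
150 MVPA-min/week recommendation. The trajectory clustering isolates a
low-activity cluster (~54% of patients at ~7 MVPA min/day), and the
conclusion is insensitive to missing-day imputation (100% of assignments
agree between the imputed and available-case analyses).

Individual stages compose with the pipe:

```r
cohort <- generate_cohort(cohort_spec(n_participants = 60, seed = 1))
flt <- assemble_days(cohort$steps, cohort$covariates) |> filter_adherent()
summ <- daily_features(flt$analyzable) |> participant_summary() |> who_status()
fit  <- fit_who_logistic(summ, cohort$covariates)
tidy(fit)                         # adjusted ORs with 95% Wald CIs
sample_size_two_means(1500, 3300) # 76 per group at 80% power, 5% alpha
```

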