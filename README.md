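# bcelldyn

Longitudinal B-cell receptor (BCR) repertoire analysis for B-cell depleting
therapy. In rheumatoid arthritis patients treated with rituximab, flow
cytometry loses sensitivity exactly when B-cell counts are lowest; UMI-based
AIRR sequencing of the heavy-chain repertoire does not. Because repopulating
B cells are antigen-naive and carry essentially unmutated IGHV genes, the
**percentage of unmutated clonotypes** in the repertoire tracks the influx
of naive B cells — falling as depletion takes hold and rising again at
repopulation. `bcelldyn` is for translational immunologists and
biostatisticians who want to run (or stress-test) this analysis:

* **Repertoire metrics** per patient-visit from AIRR Rearrangement TSVs
  with UMI consensus counts: clonal expansion as the Gini inequality
  coefficient of UMIs per clonotype,
  `G = (2 Σ_i i·x_(i)) / (n Σ x) − (n+1)/n`; clonal diversity as the
  Shannon entropy `H = −Σ p_i ln p_i` of clonotypes per clonal lineage
  (single-linkage junction clustering at normalized Hamming ≤ 0.15 within
  V-gene/J-gene/junction-length groups); IGHV mutation load (mutations/bp
  over the IMGT V region through FWR3); and percent unmutated clonotypes.
* **Endpoint calling**: the cohort threshold `mean − 2·SD` of baseline
  percent-unmutated (4.4% at the study-scale summary 40.0 ± 17.8); the
  *post-BCR-depletion* timepoint is the first visit strictly below it, the
  *post-BCR-repopulation* timepoint the first later visit at or above it;
  failed samples are imputed as complete depletion (never as repopulation);
  early/late depleter (month 1) and repopulator (within 6 months) classes;
  cumulative endpoint curves.
* **Clinical statistics**: normality-gated tests (D'Agostino–Pearson K²
  deciding between equal-variance t / one-way ANOVA + Bonferroni and
  Mann–Whitney / Kruskal–Wallis + Dunn), exact Fisher 2×2 in both
  sidednesses, ΔDAS28 contrasts by endpoint class, EULAR response
  classification, with sensitivity variants excluding imputed-sample and
  retreated patients.
* **A calibrated synthetic cohort generator** with planted ground truth
  (depletion/repopulation months, ADA status, DAS28 trajectories, missing
  samples), whose realized metrics are solved to match the study-scale
  summaries — so the entire pipeline is testable end to end without any
  patient data.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
cohort (`Rscript analysis/01_simulate_cohort.R` … `04_clinical_associations.R`),
writing tables under `results/`. Abridged output of a run:

```
Simulated 23 patients; wrote 110 AIRR tables to results/cohort
Sample status: failed_amplification=3, not_collected=2, ok=110
Planted threshold (baseline mean - 2 SD): 4.40% unmutated

Per-month repertoire summary (mean ± SD):
 visit_month  n        gini     shannon mutations_per_bp pct_unmutated
           0 23 0.28 ± 0.12 7.49 ± 0.15    0.040 ± 0.011   43.3 ± 18.0
           1 21 0.52 ± 0.07 4.78 ± 0.61    0.071 ± 0.012     4.2 ± 3.0
           3 21 0.52 ± 0.08 4.80 ± 0.71    0.067 ± 0.010    6.3 ± 11.9
           6 23 0.44 ± 0.11 5.39 ± 0.77    0.070 ± 0.017   17.1 ± 26.4
          12 22 0.37 ± 0.11 5.99 ± 0.61    0.058 ± 0.015   22.7 ± 23.0

BCR depletion/repopulation threshold: 7.34% unmutated (baseline mean 43.3, SD 18.0)
Cumulative depletion curve (%): M1=83 M3=96 M6=100 M12=100
Cumulative repopulation curve (%): M1=0 M3=9 M6=39 M12=57
  delta_das28_6_12   t_unpaired   -0.79 ± 1.12 (n=8) vs 0.28 ± 0.72 (n=13)  p = 0.015
EULAR response at month 6: good=6, moderate=6, none=9
```

Reading this: one month after treatment the repertoire collapses to fewer,
more expanded (Gini 0.28 → 0.52), less diverse (Shannon 7.5 → 4.8) and more
mutated (0.040 → 0.071 mutations/bp) clonotypes, and the percent of
unmutated clonotypes drops from ~43% to ~4%; recovery begins around month
6. Patients repopulating within 6 months improve more in DAS28 between
months 6 and 12 than late repopulators (−0.79 vs +0.28, p = 0.015). Note
also a deliberate lesson in the output: the *data-driven* threshold here
came out at 7.34% rather than the planted 4.4% — at 23 patients the
`mean − 2·SD` estimate is noisy, which is why the package's simulation
studies pin the threshold at its population value via the
`threshold` override of `call_endpoints()` (see the methods vignette,
`vignettes/bcr-repopulation-dynamics.Rmd`).

A minimal in-memory session:

```r
library(bcelldyn)
sim <- simulate_cohort(sim_config(seed = 1))
metrics <- cohort_metrics(sim)
ep <- call_endpoints(metrics, sim$clinical, threshold = sim$threshold)
associate_endpoints(sim$clinical, ep$calls)
```

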