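# antigenscreen

Candidate autoantibody discovery from immunoprecipitation shotgun mass
spectrometry, for presence-absence antigen screens of cerebrospinal fluid
(CSF) or other biofluids.

In this assay, IgG captured from a patient's CSF on protein-G beads pulls
cognate antigens out of a brain tissue lysate; the antigens are identified
by LC-MS/MS at 1% FDR, giving one presence-absence identification list per
individual. `antigenscreen` turns a folder of such lists plus a sample
manifest into a candidate report:

* **I/O** — long-TSV and wide "I"-mark identification dialects, manifests,
  blocklists, TSV/JSON reports.
* **Presence calling** — technical-replicate merging (union or
  intersection), optional q-value ceiling, protein x sample presence matrix
  with unique-peptide statistics.
* **Contaminant removal** — an editable blocklist of abundant serum protein
  families (hemoglobins, haptoglobin, hemopexin, immunoglobulins, keratins,
  apolipoproteins, serum albumin, complement).
* **Selection rule** — an antigen is a candidate for patient group *P*
  when it is detected in at most `max_control_detections` controls
  (default 1) **and** in at least `ceiling(min_patient_fraction * n_P)`
  patients (default half):

  `P_sel = P[Bin(n_c, p_c) <= k_max] * P[Bin(n_p, p_p) >= ceil(f * n_p)]`

  is its closed-form selection probability under independent Bernoulli
  detection, used to verify the rule's operating characteristics by
  simulation.
* **Reporting** — per-group candidate tables (individuals identified /
  total unique peptides / mean unique peptides), Venn-region overlap
  summaries, spiked kallikrein-6 (hK6) positive-control QC, and cohort
  demographic statistics (chi-square, Kruskal-Wallis, Dunn's post-hoc).
* **Synthetic studies** — a seeded generator of complete studies
  (manifest + identifications + truth labels) matching the detection
  structure of a real 30-sample screen, so everything is testable offline.

## Worked example

The package ships the per-group detection counts of a published 30-sample
CSF screen (10 headache controls, 10 Alzheimer's, 10 Parkinson's) and can
reconstruct them into a presence matrix:

```r
library(antigenscreen)

design <- reference_design()
pm     <- reference_presence_matrix()

ad <- select_candidates(pm, design, selection_criteria(), "AD")
nrow(ad)                                            # 16 candidates
nrow(select_candidates(pm, design, selection_criteria(), "PD"))  # 0

head(ad[, c("protein_name", "gene_symbol", "control_n_detected",
            "AD_n_detected", "AD_total_unique", "AD_mean_unique")], 5)
#>   protein_name       gene_symbol control_n_detected AD_n_detected AD_total_unique AD_mean_unique
#> 1 Glia-derived nexin SERPINE2                     0             8               7            2.3
#> 2 Cadherin-13        CDH13                        1             6               5            2
#> 3 Cathepsin F        CTSF                         1             6               5            2.3
#> 4 Fibromodulin       FMOD                         0             6               4            1.5
#> 5 Phospholipase D4   PLD4                         1             6               1            1
```

Sixteen antigens pass the rule for the AD group and none for PD; the top
candidate, glia-derived nexin (SERPINE2), is detected in 8 of 10 AD
patients with 7 unique peptides in the group (mean 2.3 per detected
patient) and in no control. Three candidates (SERPINE2, FMOD, NQO1) are
absent from every control sample.

The group-overlap summary for the same screen:

```r
ov <- compute_overlap(reference_overlap_matrix(), design)
ov$grand_total      # 1854 antigens detected in any group (after blocklist)
ov$n_common         # 1042 common to all three groups
ov$percent_common   # 56
```

A complete synthetic study exercises the same pipeline end to end:

```r
study <- generate_study(simulation_config(seed = 1))
paths <- write_study(study, "scratch/sim")
res <- run_screen(run_config(manifest = paths[["manifest"]],
                             identifications = paths[["identifications"]],
                             outdir = "scratch/sim/out"))
```

The run log records per-stage protein counts (total, after blocklist,
candidates per group) and the criteria actually applied, including the
resolved minimum patient count.

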