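---
title: "Presence-absence screening for CSF autoantibody candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence-absence screening for CSF autoantibody candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antigenscreen)
```

## The screening problem

Autoantibodies in a biofluid can be profiled indirectly: IgG captured from
cerebrospinal fluid (CSF) on protein-G beads is incubated with a brain tissue
lysate, and the antigens the antibodies pull down are identified by shotgun
mass spectrometry. The readout per individual is a *presence-absence* list of
protein identifications (each supported by one or more unique peptides), not
a quantitative abundance profile. Candidate autoantibody biomarkers for a
patient group are then antigens that are recurrently captured from patients
but essentially never from controls.

`antigenscreen` implements this analysis as a reusable pipeline:

1. read per-sample peptide/protein identification tables (long TSV or a wide
   "I"-mark dialect) and a sample manifest with group labels;
2. merge technical replicate injections;
3. build a protein x sample presence matrix with unique-peptide statistics;
4. remove abundant serum proteins with an editable blocklist;
5. apply a two-part group-frequency selection rule;
6. report candidates, group overlaps (Venn regions), positive-control QC and
   cohort demographic statistics.

A seeded synthetic-study generator reproduces the detection structure of a
real 30-sample screen so every stage, and the operating characteristics of
the selection rule itself, can be tested without any external data.

## The selection rule

For a control group of size $n_c$ and a patient group of size $n_p$, let
$d_c(a)$ and $d_p(a)$ be the number of samples in which antigen $a$ was
detected. The rule selects $a$ when

$$d_c(a) \le k_{\max} \quad \text{and} \quad d_p(a) \ge \lceil f \, n_p \rceil,$$

with defaults $k_{\max} = 1$ (near-absence in controls: "at most one of ten")
and $f = 0.5$ (recurrence: "at least half the patients", ceiling so the rule
is well defined for odd group sizes). Both thresholds are exposed in
`selection_criteria()`; each patient group is screened against the same
control group independently, with no cross-patient-group exclusion (a
candidate for one disease group may well be detected in another).

The rule is deliberately a frequency filter, not a significance test: with
ten samples per group a presence-absence contrast has little power for a
formal test, and the output is an explicitly *putative* candidate list for
orthogonal validation. The package therefore performs no permutation or FDR
computation on the candidate list; what it does provide is the closed-form
selection probability under independent Bernoulli detection,

$$P_{\text{sel}}(p_c, p_p) = P[\mathrm{Bin}(n_c, p_c) \le k_{\max}]
  \cdot P[\mathrm{Bin}(n_p, p_p) \ge \lceil f n_p \rceil],$$

(`analytic_selection_rate()`), which the test suite compares against
large simulations: at a null where every protein is detected with $p = 0.2$
everywhere the rule selects about 1.2% of proteins, while a true enrichment
profile ($p_c = 0.02$, $p_p = 0.8$) is selected with probability about 0.98.

## Presence calling and peptide statistics

Detection upstream is a database search at 1% FDR; the package consumes its
output and never re-runs it. A protein is called present in a sample when at
least `min_peptides` (default 1) distinct peptide sequences remain after an
optional q-value ceiling — single-peptide identifications count, because
reported candidate tables in this assay legitimately contain antigens
identified by one shared peptide across patients. Peptide identity is the
modification-stripped uppercase sequence; protein identity is the upstream
accession, with no isoform regrouping (protein inference already happened in
the search engine).

Technical duplicate injections are merged before presence calling. The
default policy is `union` (evidence in either injection counts), the
permissive reading of a protocol that reports one identification list per
individual; an `intersection` policy is provided for concordance-requiring
analyses, and it treats a replicate that produced no records at all as a
miss, which requires the declared replicate structure from the manifest.

Per group and antigen the package reports the triple used in candidate
tables: the number of individuals identified, the *total* unique peptides
(union over the group's detected samples) and the *mean* unique peptides
(arithmetic mean over detected samples only, printed half-up to one
decimal). The "detected samples only" denominator is the one consistent
with a five-patient antigen carrying one identical peptide per patient
having mean 1. Wide presence-mark tables without peptide rows record
presence but mark peptide statistics unavailable (`NA`) — counts are never
fabricated from presence marks.

## The blocklist

Abundant blood-derived proteins bind protein-G beads non-specifically and
are removed before selection: hemoglobins, haptoglobin, hemopexin,
immunoglobulins, keratins, apolipoproteins, serum albumin and complement.
Because screens name these as *families*, the shipped default blocklist
(`default_blocklist_path()`) encodes them as case-insensitive name
substrings plus gene-symbol prefixes (`HB`, `IGH/IGK/IGL`, `KRT`, `APO`,
`ALB`, `C1Q/C1R/C1S/C2`–`C9`, `CF`). Prefix rules are intentionally broad
and can over-match (e.g. `APO` also matches APOBEC-family genes); the file
is plain TSV precisely so users can tighten or extend it, and every run
writes the removed accessions so the effect of the list is diagnosable.
Group overlap (Venn) membership counts *identifications* after blocklist
removal, not candidates — a protein detected once in a group belongs to
that group's set.

## Cohort statistics

Demographic tables are compared the way neurology cohorts usually are:
Pearson chi-square without continuity correction for categorical variables
(the no-correction convention is what reproduces reported cohort p-values,
e.g. p = 0.5853 for a 6/6/4-female split across three groups of ten),
Kruskal-Wallis by ranks with midrank tie correction for continuous scores,
and Dunn's z-tests on mean-rank differences for pairwise follow-up. The
multiplicity adjustment inside Dunn's procedure is configurable
(`none`, `bonferroni`, `sidak`) and defaults to `none`, since published
pairwise values in this setting rarely state the adjustment and no choice
can be verified from printed data alone. Missing demographics are excluded
pairwise, and a variable observed in fewer than two groups (an ordinal
staging score recorded for a single disease group, say) is skipped rather
than imputed.

## What the synthetic generator does and does not emulate

`simulation_config()` defaults describe the study conditions the package is
designed around: three groups of ten run in technical duplicates; a
background proteome of 2,500 antigens detected with per-sample probability
0.35, which places per-sample detected-protein counts inside the empirically
observed 461–1192 range; 60 contaminant proteins named so the default
blocklist removes them by construction; 15 enriched antigens per patient
group with detection probability 0.8 in their group and 0.02 elsewhere; a
spiked kallikrein-6 control present in every sample with 9–13 unique
peptides; and per-detection unique-peptide counts following
$1 + \mathrm{Poisson}(\lambda - 1)$ with $\lambda = 2$, matching reported
mean-unique-peptide values of 1–2.3. Replicate concordance defaults to 0.8:
one randomly chosen injection always carries a detection and each peptide
recurs in the other injection with that probability, a construction chosen
so the union-merged per-sample detection probability equals the configured
Bernoulli probability exactly — which is what makes the closed-form binomial
oracle above an *exact* reference rather than an approximation.

The generator emulates detection structure only. It does not simulate
spectra, intensities, retention times, peptide physicochemistry, shared
peptides between proteins, or search-engine FDR behaviour; detections are
independent across proteins and samples, whereas real co-capture is
correlated. Passing simulation tests therefore validates the *bookkeeping
and the rule's operating characteristics*, not robustness to correlated
contamination or batch structure in real data.

## Numerical and design choices

* Reported means are rounded half away from zero to one decimal
  (`2.25` prints as `2.3`); base R's round-half-even would disagree with
  printed tables.
* The overlap percentage is rounded to the nearest integer
  (1042/1854 = 56.2% prints as 56%).
* Degenerate rank tests (all observations equal) report statistic 0 and
  p = 1 instead of 0/0.
* Empty candidate sets write a header-only TSV; an absent positive control
  yields a failing QC with all flags false rather than an error.
* Reconstruction of the shipped reference counts into per-sample peptide
  sets chooses the smallest per-sample count total consistent with the
  printed rounded mean and deals peptides cyclically, which provably
  reproduces every (individuals, total, mean) triple exactly.
* All generation is deterministic given `seed`; the generator restores the
  caller's RNG state.

## Problem sizes in the test suite

The shipped tests run the worked reference example (30 samples, 16
candidate antigens, an 1854-protein overlap structure), property checks
against brute-force oracles on hundreds of small random matrices, and two
10,000-protein simulations for the binomial operating-characteristic
checks; the full default synthetic study (2,500+ proteins, 30 samples, two
replicates, about 100,000 evidence rows) is generated once. These sizes
were chosen to make the binomial comparisons sharp (99% intervals a few
percent wide) while keeping the whole suite fast on a laptop.

## Known limitations

* The screen is presence-absence; no intensity-based differential
  abundance is attempted, and none should be inferred from the output.
* Exact reproduction of a published screen's post-blocklist counts depends
  on the blocklist matching the original removal choices; family rules are
  a faithful but not provably identical encoding, which is why removed
  accessions are always logged.
* With ten samples per group the rule's false-candidate rate at a common
  detection probability of 0.2 is roughly 1%, so a 1,500-protein background
  yields a handful of spurious candidates; candidate lists are starting
  points for validation, not endpoints.
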