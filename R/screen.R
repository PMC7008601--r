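# Abundant-serum-protein blocklist filtering, the two-part group-frequency
# candidate selection rule, group overlap (Venn) summaries and the
# positive-control QC.

#' Selection criteria for the two-part frequency rule
#'
#' A protein is a candidate for a patient group when it is (1) near-absent
#' in the control group: detected in at most `max_control_detections`
#' control individuals, and (2) recurrently detected in the patient group:
#' present in at least `min_patient_fraction` of the patients. With the
#' defaults and ten samples per group this is the classic "at most 1 of 10
#' controls, at least 5 of 10 patients" rule.
#'
#' @param max_control_detections Non-negative integer, default 1.
#' @param min_patient_fraction Fraction in (0, 1], default 0.5. The derived
#'   patient count is `ceiling(min_patient_fraction * n_patients)` ("at
#'   least half", well defined for odd group sizes).
#' @param min_patient_count Optional explicit patient count overriding the
#'   fraction-derived value.
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(max_control_detections = 1,
                               min_patient_fraction = 0.5,
                               min_patient_count = NULL) {
  assert_that(max_control_detections >= 0,
              "max_control_detections must be non-negative")
  assert_that(min_patient_fraction > 0 && min_patient_fraction <= 1,
              "min_patient_fraction must lie in (0, 1]")
  if (!is.null(min_patient_count)) {
    assert_that(min_patient_count >= 1, "min_patient_count must be >= 1")
  }
  structure(list(max_control_detections = as.integer(max_control_detections),
                 min_patient_fraction = min_patient_fraction,
                 min_patient_count = min_patient_count),
            class = "selection_criteria")
}

resolve_min_patient_count <- function(criteria, n_patients) {
  n <- criteria$min_patient_count %||%
    ceiling(criteria$min_patient_fraction * n_patients)
  as.integer(max(1L, n))
}

#' Remove abundant serum proteins with a blocklist
#'
#' Abundant blood-derived proteins (hemoglobin, haptoglobin, hemopexin,
#' immunoglobulins, keratins, apolipoproteins, serum albumin, complement)
#' bind beads non-specifically in immunoprecipitation experiments and are
#' excluded before candidate selection. A protein is removed when at least
#' one rule matches; kept and removed proteins partition the input set.
#'
#' @param pm A `presence_matrix`.
#' @param rules A blocklist tibble from [read_blocklist()]; an empty rule
#'   set is the identity.
#' @return A list with `matrix` (the filtered `presence_matrix`),
#'   `removed_accessions` and `removed` (tibble of removed proteins).
#' @export
apply_blocklist <- function(pm, rules) {
  prot <- pm$proteins
  hit <- rep(FALSE, nrow(prot))
  for (i in seq_len(nrow(rules))) {
    pat <- rules$pattern[i]
    hit <- hit | switch(
      rules$match_type[i],
      gene_prefix = !is.na(prot$gene_symbol) &
        startsWith(prot$gene_symbol, pat),
      name_substring = !is.na(prot$protein_name) &
        grepl(tolower(pat), tolower(prot$protein_name), fixed = TRUE),
      accession_exact = prot$accession == pat,
      stop("unknown blocklist match_type: ", rules$match_type[i])
    )
  }
  list(matrix = subset_presence(pm, prot$accession[!hit]),
       removed_accessions = prot$accession[hit],
       removed = prot[hit, ])
}

#' Select candidate antigens for one patient group
#'
#' Applies the two-part frequency rule of [selection_criteria()] to a
#' (blocklist-filtered) presence matrix and returns the candidates with
#' per-group unique-peptide statistics for every group, control first.
#' Candidates are ordered by descending patient-group detection count,
#' ties broken by protein name.
#'
#' @param pm A `presence_matrix`, blocklist already applied.
#' @param design A [study_design()].
#' @param criteria A [selection_criteria()].
#' @param patient_group A non-control group label.
#' @param detail Include per-group unique-peptide statistics (default); set
#'   to `FALSE` to return only detection counts, e.g. in large simulations.
#' @return A tibble with columns `protein_name`, `gene_symbol`, `accession`
#'   and, per group `g`, `<g>_n_detected`, `<g>_total_unique`,
#'   `<g>_mean_unique`. The resolved criteria are attached as attribute
#'   `criteria_resolved`.
#' @export
select_candidates <- function(pm, design, criteria = selection_criteria(),
                              patient_group, detail = TRUE) {
  assert_that(patient_group %in% design$group_labels,
              paste0("unknown group label: ", patient_group))
  assert_that(patient_group != design$control_group,
              "patient_group must differ from the control group")
  ctrl_samples <- intersect(group_samples(design, design$control_group),
                            pm$samples)
  pat_samples <- intersect(group_samples(design, patient_group), pm$samples)
  assert_that(criteria$max_control_detections <= length(ctrl_samples),
              "max_control_detections exceeds the control group size")
  min_count <- resolve_min_patient_count(criteria, length(pat_samples))
  n_ctrl <- rowSums(pm$detected[, ctrl_samples, drop = FALSE])
  n_pat <- rowSums(pm$detected[, pat_samples, drop = FALSE])
  sel <- n_ctrl <= criteria$max_control_detections & n_pat >= min_count
  accs <- pm$proteins$accession[sel]
  groups <- c(design$control_group,
              setdiff(design$group_labels, design$control_group))
  out <- tibble::tibble(protein_name = pm$proteins$protein_name[sel],
                        gene_symbol = pm$proteins$gene_symbol[sel],
                        accession = accs)
  for (g in groups) {
    s <- intersect(group_samples(design, g), pm$samples)
    out[[paste0(g, "_n_detected")]] <-
      as.integer(rowSums(pm$detected[sel, s, drop = FALSE]))
    if (detail) {
      stats <- lapply(accs, function(a) group_peptide_stats(pm, design, a, g))
      out[[paste0(g, "_total_unique")]] <-
        vapply(stats, function(x) as.integer(x$total_unique), integer(1))
      out[[paste0(g, "_mean_unique")]] <-
        vapply(stats, function(x) as.numeric(x$mean_unique), numeric(1))
    }
  }
  pat_col <- paste0(patient_group, "_n_detected")
  out <- out[order(-out[[pat_col]], out$protein_name), ]
  attr(out, "criteria_resolved") <- list(
    max_control_detections = criteria$max_control_detections,
    min_patient_count = min_count,
    patient_group = patient_group,
    control_group = design$control_group
  )
  out
}

#' Candidate report over all patient groups
#'
#' Runs [select_candidates()] for every non-control group against the same
#' control group (no cross-patient-group exclusion) and bundles the results
#' with the criteria and the blocklist removal record.
#'
#' @inheritParams select_candidates
#' @param removed_accessions Accessions removed by the blocklist step.
#' @return An object of class `candidate_report` with elements `groups`
#'   (named list of candidate tibbles), `criteria`,
#'   `n_removed_by_blocklist`, `removed_accessions`.
#' @export
candidate_report <- function(pm, design, criteria = selection_criteria(),
                             removed_accessions = character()) {
  patient_groups <- setdiff(design$group_labels, design$control_group)
  groups <- lapply(patient_groups, function(g)
    select_candidates(pm, design, criteria, g))
  names(groups) <- patient_groups
  structure(list(groups = groups,
                 criteria = criteria,
                 n_removed_by_blocklist = length(removed_accessions),
                 removed_accessions = removed_accessions),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("candidate_report (", x$n_removed_by_blocklist,
      " proteins removed by blocklist)\n", sep = "")
  for (g in names(x$groups)) {
    cat("  ", g, ": ", nrow(x$groups[[g]]), " candidates\n", sep = "")
  }
  invisible(x)
}

#' Group overlap (Venn) summary
#'
#' A protein belongs to a group when it is detected in at least one sample
#' of that group (identification, not candidacy). All `2^k - 1` exclusive
#' region counts are reported, along with per-group totals, the grand total
#' of proteins detected anywhere and the percentage common to all groups
#' (rounded to the nearest integer).
#'
#' @param pm A `presence_matrix` (blocklist applied, by convention).
#' @param design A [study_design()] with at least two groups.
#' @return An object of class `overlap_summary`: a list with
#'   `group_totals`, `regions` (named by `&`-joined group labels),
#'   `grand_total`, `n_common`, `percent_common`.
#' @export
compute_overlap <- function(pm, design) {
  groups <- design$group_labels
  assert_that(length(groups) >= 2, "overlap needs at least two groups")
  member <- vapply(groups, function(g) {
    s <- intersect(group_samples(design, g), pm$samples)
    rowSums(pm$detected[, s, drop = FALSE]) > 0
  }, logical(nrow(pm$proteins)))
  member <- matrix(member, ncol = length(groups),
                   dimnames = list(NULL, groups))
  in_any <- rowSums(member) > 0
  member <- member[in_any, , drop = FALSE]
  k <- length(groups)
  regions <- list()
  for (size in seq_len(k)) {
    for (combo in utils::combn(groups, size, simplify = FALSE)) {
      pattern <- groups %in% combo
      count <- sum(apply(member, 1, function(m) all(m == pattern)))
      regions[[paste(combo, collapse = "&")]] <- as.integer(count)
    }
  }
  group_totals <- as.list(setNames(as.integer(colSums(member)), groups))
  grand_total <- as.integer(nrow(member))
  n_common <- regions[[paste(groups, collapse = "&")]]
  structure(
    list(group_totals = group_totals,
         regions = regions,
         grand_total = grand_total,
         n_common = n_common,
         percent_common = as.integer(round_half_up(
           if (grand_total > 0) 100 * n_common / grand_total else 0, 0))),
    class = "overlap_summary"
  )
}

#' Positive-control QC
#'
#' Spiked-in kallikrein 6 (hK6/KLK6) antibody should pull its antigen down
#' in every sample; the QC passes when the control protein is detected in
#' all samples with at least `min_peptides` unique peptides. Cells whose
#' presence was recorded without peptide detail count as one peptide.
#'
#' @param pm A `presence_matrix`.
#' @param control Accession or gene symbol of the control protein
#'   (default `"KLK6"`).
#' @param min_peptides Minimum unique peptides per sample (default 1).
#' @return A list of class `qc_report`: `control_protein`,
#'   `accession_matched`, `min_peptides`, `samples`, `detected`,
#'   `n_peptides`, `pass`. An absent control yields `pass = FALSE` with all
#'   flags false.
#' @export
check_positive_control <- function(pm, control = "KLK6", min_peptides = 1) {
  prot <- pm$proteins
  idx <- which(prot$accession == control |
                 (!is.na(prot$gene_symbol) & prot$gene_symbol == control))
  if (length(idx) == 0) {
    return(structure(
      list(control_protein = control, accession_matched = NA_character_,
           min_peptides = as.integer(min_peptides),
           samples = as.list(pm$samples),
           detected = as.list(rep(FALSE, length(pm$samples))),
           n_peptides = as.list(rep(0L, length(pm$samples))),
           pass = FALSE),
      class = "qc_report"))
  }
  acc <- prot$accession[idx[1]]
  det <- unname(pm$detected[acc, ])
  counts <- unname(pm$n_peptides[acc, ])
  eff <- ifelse(is.na(counts), ifelse(det, 1, 0), counts)
  structure(
    list(control_protein = control, accession_matched = acc,
         min_peptides = as.integer(min_peptides),
         samples = as.list(pm$samples),
         detected = as.list(det),
         n_peptides = as.list(as.integer(eff)),
         pass = all(det) && all(eff >= min_peptides)),
    class = "qc_report"
  )
}

#' Analytic selection probability under independent Bernoulli detection
#'
#' Under a model where a protein is detected independently with probability
#' `p_control` in each of `n_control` control samples and `p_patient` in
#' each of `n_patient` patient samples, the probability that it passes the
#' two-part rule is the product of two binomial tail probabilities:
#' `P[Bin(n_control, p_control) <= max_control] *
#'  P[Bin(n_patient, p_patient) >= min_count]`.
#' Used as the closed-form reference for the simulation-based operating
#' characteristics of the rule.
#'
#' @param p_control,p_patient Per-sample detection probabilities.
#' @param n_control,n_patient Group sizes.
#' @param max_control Maximum allowed control detections.
#' @param min_count Minimum required patient detections.
#' @return The selection probability.
#' @export
analytic_selection_rate <- function(p_control, p_patient,
                                    n_control, n_patient,
                                    max_control = 1, min_count = 5) {
  pbinom(max_control, n_control, p_control) *
    (1 - pbinom(min_count - 1, n_patient, p_patient))
}
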