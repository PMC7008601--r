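# Reconstruction of the published reference screen used as a worked
# example: a 30-sample CSF autoantibody study (10 headache controls, 10 AD,
# 10 PD) whose reported per-group detection counts and unique-peptide
# summaries are shipped as a small TSV. The reconstruction produces a
# presence structure that reproduces every shipped (n_detected,
# total_unique, mean_unique) triple exactly.

#' Reported per-group detection counts of the reference candidates
#'
#' The sixteen AD candidate antigens of the reference CSF screen with, per
#' group (control / AD / PD), the number of individuals identified, the
#' total unique peptides over the group and the mean unique peptides per
#' detected individual.
#'
#' @return A tibble, one row per candidate antigen.
#' @export
reference_candidate_counts <- function() {
  path <- system.file("extdata", "reference_candidate_counts.tsv",
                      package = "antigenscreen", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

reference_groups <- c("control", "AD", "PD")

reference_sample_ids <- function() {
  unlist(lapply(reference_groups, function(g) sprintf("%s_%02d", g, 1:10)))
}

#' Reference study design
#'
#' Thirty samples in three groups of ten with demographics matching the
#' reference cohort's marginal structure: 6/6/4 females, younger controls
#' (median age 40 vs 76.5 and 74), control MMSE near ceiling, H-Y scores
#' only for PD and FRSSD only for the patient groups.
#'
#' @return A [study_design()].
#' @export
reference_design <- function() {
  sex <- c(rep(c("F", "M"), c(6, 4)), rep(c("F", "M"), c(6, 4)),
           rep(c("F", "M"), c(4, 6)))
  age <- c(38, 38, 39, 39, 40, 40, 44, 48, 50, 52,
           70, 72, 73, 74, 76, 77, 78, 80, 82, 84,
           65, 69, 70, 72, 74, 74, 76, 79, 80, 82)
  mmse <- c(27, 28, 28, 28, 28, 28, 28, 28, 29, 30,
            12, 14, 14, 16, 18, 18, 19, 20, 21, 22,
            17, 19, 19, 21, 22, 22, 24, 25, 26, 27)
  hy <- c(rep(NA_real_, 20), 1, 1.5, 1.5, 2, 2, 2, 2.5, 3, 3, 3)
  frssd <- c(rep(NA_real_, 10),
             7, 9, 9, 10, 10, 10, 11, 11, 12, 13,
             4, 6, 6, 10, 12, 12, 14, 16, 17, 18)
  study_design(
    tibble::tibble(
      sample_id = reference_sample_ids(),
      group = rep(reference_groups, each = 10),
      replicate_ids = replicate(30, "rep1", simplify = FALSE),
      sex = sex, age = age, mmse = mmse, hy = hy, frssd = frssd),
    group_labels = reference_groups,
    control_group = "control"
  )
}

# Smallest per-group peptide total S (sum of per-sample distinct counts)
# consistent with the reported rounded mean; needs S >= total so the cyclic
# assignment can cover the whole peptide union.
solve_peptide_total <- function(n, total, mean_reported) {
  if (n == 0) return(0L)
  cand <- max(n, total):(n * total)
  ok <- cand[round_half_up(cand / n, 1) == round_half_up(mean_reported, 1)]
  assert_that(length(ok) > 0,
              sprintf("no per-sample peptide counts realize n=%d total=%d mean=%.1f",
                      n, total, mean_reported))
  ok[which.min(abs(ok - mean_reported * n))]
}

# Per-sample distinct-peptide counts: start at one each, add the remainder
# round-robin, capped at the union size.
split_counts <- function(n, total, s) {
  counts <- rep(1L, n)
  extra <- s - n
  i <- 1
  while (extra > 0) {
    if (counts[i] < total) {
      counts[i] <- counts[i] + 1L
      extra <- extra - 1L
    }
    i <- if (i == n) 1 else i + 1
  }
  counts
}

#' Reconstruct the reference study as an identification table
#'
#' Builds a long-format identification table whose group-level statistics
#' reproduce [reference_candidate_counts()] exactly: for each antigen and
#' group, detections are placed in the first `n` samples of the group and
#' peptides are dealt cyclically from the antigen's peptide pool so that
#' the per-sample distinct counts sum to a value whose mean rounds to the
#' reported mean while their union has exactly the reported size. Peptide
#' sequences themselves are synthetic (deterministically generated) since
#' only their identity structure matters. The kallikrein-6 positive control
#' is included in every sample with 9-13 unique peptides.
#'
#' @param include_spike Include the positive-control protein.
#' @return A list with `design` ([reference_design()]) and `table`
#'   (an [identification_table()]).
#' @export
reference_study <- function(include_spike = TRUE) {
  counts <- reference_candidate_counts()
  design <- reference_design()
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(1854L)  # internal constant: reconstruction is deterministic

  rows <- list()
  for (i in seq_len(nrow(counts))) {
    prot <- counts[i, ]
    max_total <- max(prot$control_total, prot$AD_total, prot$PD_total)
    pool <- random_peptides(max(1, max_total))
    for (g in reference_groups) {
      n <- prot[[paste0(g, "_n")]]
      if (n == 0) next
      total <- prot[[paste0(g, "_total")]]
      s <- solve_peptide_total(n, total, prot[[paste0(g, "_mean")]])
      per_sample <- split_counts(n, total, s)
      ptr <- 0
      for (k in seq_len(n)) {
        take <- ((ptr + seq_len(per_sample[k]) - 1) %% total) + 1
        ptr <- ptr + per_sample[k]
        rows[[length(rows) + 1]] <- tibble::tibble(
          sample_id = sprintf("%s_%02d", g, k),
          replicate_id = "rep1",
          accession = prot$accession,
          protein_name = prot$protein_name,
          gene_symbol = prot$gene_symbol,
          peptide = pool[take],
          q_value = NA_real_,
          peptide_detail = TRUE)
      }
    }
  }
  if (include_spike) {
    spike_pool <- random_peptides(13)
    spike_counts <- rep(c(9, 10, 11, 12, 13), 6)
    for (j in seq_along(reference_sample_ids())) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = reference_sample_ids()[j],
        replicate_id = "rep1",
        accession = "Q92876",
        protein_name = "Kallikrein-6",
        gene_symbol = "KLK6",
        peptide = spike_pool[seq_len(spike_counts[j])],
        q_value = NA_real_,
        peptide_detail = TRUE)
    }
  }
  list(design = design,
       table = identification_table(dplyr::bind_rows(rows)))
}

#' Reference presence matrix
#'
#' Convenience wrapper: [reference_study()] merged and turned into a
#' presence matrix.
#'
#' @inheritParams reference_study
#' @return A `presence_matrix`.
#' @export
reference_presence_matrix <- function(include_spike = TRUE) {
  st <- reference_study(include_spike)
  build_presence_matrix(merge_replicates(st$table), st$design)
}

# Exclusive region counts of the reference screen's three-group overlap.
# Only the marginals are reported (grand total 1854, common 1042, group
# totals 1342/1562/1281, uniques 137/299/129); the three pairwise-only
# regions follow uniquely from them.
reference_region_counts <- function() {
  c("control" = 137L, "AD" = 299L, "PD" = 129L,
    "control&AD" = 137L, "control&PD" = 26L, "AD&PD" = 84L,
    "control&AD&PD" = 1042L)
}

#' Presence matrix realizing the reference screen's group overlap
#'
#' Builds a minimal presence structure (one detection in the first sample
#' of each member group) whose three-group Venn regions equal the reference
#' screen's overlap: 1854 antigens in total, 1042 common to all groups, and
#' group totals 1342 (control), 1562 (AD), 1281 (PD).
#'
#' @return A `presence_matrix` over the [reference_design()] samples.
#' @export
reference_overlap_matrix <- function() {
  regions <- reference_region_counts()
  samples <- reference_sample_ids()
  n <- sum(regions)
  accs <- sprintf("SYNV%04d", seq_len(n))
  detected <- matrix(FALSE, n, length(samples),
                     dimnames = list(accs, samples))
  first_sample <- setNames(sprintf("%s_01", reference_groups), reference_groups)
  row <- 0
  for (r in names(regions)) {
    member <- strsplit(r, "&", fixed = TRUE)[[1]]
    idx <- row + seq_len(regions[[r]])
    detected[idx, first_sample[member]] <- TRUE
    row <- row + regions[[r]]
  }
  n_pep <- matrix(0, n, length(samples), dimnames = list(accs, samples))
  n_pep[detected] <- 1
  structure(
    list(proteins = tibble::tibble(accession = accs,
                                   protein_name = accs,
                                   gene_symbol = NA_character_),
         samples = samples,
         detected = detected,
         n_peptides = n_pep,
         peptide_sets = setNames(vector("list", n), accs)),
    class = "presence_matrix"
  )
}
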