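# Seeded generator of complete synthetic studies (manifest + identification
# table + per-protein truth labels), emulating the detection structure of a
# 30-sample CSF immunoprecipitation screen: a large background of commonly
# detected antigens, blocklist-family contaminants, a spiked positive
# control present everywhere, and group-enriched antigens with high patient
# and near-zero control detection probability.

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_peptides <- function(n, min_len = 9, max_len = 16) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  chars <- sample(.aa20, sum(lens), replace = TRUE)
  out <- vapply(split(chars, rep(seq_len(n), lens)), paste, character(1),
                collapse = "")
  unname(out)
}

#' Configuration of a synthetic study
#'
#' Defaults emulate the study conditions of a three-group CSF screen:
#' 10 controls, 10 AD and 10 PD patients run in technical duplicates, with
#' a background proteome whose per-sample detection rate lands the
#' per-sample detected-protein count inside the empirical 461-1192 range,
#' ubiquitous contaminant families covered by the default blocklist, a
#' spiked kallikrein-6 control with 9-13 unique peptides everywhere, and
#' group-enriched antigens detected with high probability in their patient
#' group and rarely in controls.
#'
#' @param group_sizes Named integer vector of samples per group; the first
#'   name present among the labels that equals `control_group` is the
#'   control.
#' @param control_group Label of the control group.
#' @param n_background Number of background proteins detected with common
#'   probability `p_bg` in every sample.
#' @param p_bg Per-sample background detection probability.
#' @param n_enriched Number of enriched proteins per patient group.
#' @param p_ctrl_low Control-group detection probability of enriched
#'   proteins.
#' @param p_enriched Patient-group detection probability of enriched
#'   proteins (in their own group; other patient groups use `p_ctrl_low`).
#' @param n_contaminant Number of contaminant proteins, named so the default
#'   blocklist removes them by construction.
#' @param p_contam Per-sample contaminant detection probability.
#' @param replicates_per_sample Technical replicates per sample (>= 1).
#' @param replicate_concordance Probability that a detected peptide recurs
#'   in another replicate of the same sample (one randomly chosen primary
#'   replicate always carries the detection, so the union-merged per-sample
#'   detection probability equals the configured Bernoulli probability).
#' @param peptide_lambda Mean of the shifted-Poisson unique-peptide count
#'   per detection (`1 + Poisson(lambda - 1)`, minimum 1).
#' @param spike_control Whether to spike the positive control into every
#'   sample.
#' @param spike_peptide_range Inclusive range of the control's per-sample
#'   unique-peptide count.
#' @param demographics Whether to simulate demographics (sex, age, MMSE,
#'   plus H-Y for PD-labelled and FRSSD for patient groups), with younger
#'   controls and reduced patient MMSE so group differences are detectable.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(group_sizes = c(control = 10, AD = 10, PD = 10),
                              control_group = "control",
                              n_background = 2500, p_bg = 0.35,
                              n_enriched = 15, p_ctrl_low = 0.02,
                              p_enriched = 0.8,
                              n_contaminant = 60, p_contam = 0.9,
                              replicates_per_sample = 2,
                              replicate_concordance = 0.8,
                              peptide_lambda = 2,
                              spike_control = TRUE,
                              spike_peptide_range = c(9, 13),
                              demographics = TRUE,
                              seed = 1) {
  probs <- c(p_bg, p_ctrl_low, p_enriched, p_contam, replicate_concordance)
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  counts <- c(n_background, n_enriched, n_contaminant)
  assert_that(all(counts >= 0), "protein counts must be non-negative")
  assert_that(peptide_lambda >= 1, "peptide_lambda must be >= 1")
  assert_that(replicates_per_sample >= 1, "need at least one replicate")
  assert_that(!is.null(names(group_sizes)) && all(group_sizes >= 1),
              "group_sizes must be a named vector of positive counts")
  assert_that(control_group %in% names(group_sizes),
              "control_group must be among the group_sizes names")
  patient_groups <- setdiff(names(group_sizes), control_group)
  assert_that(n_enriched == 0 || length(patient_groups) > 0,
              "enriched proteins require at least one patient group")
  structure(
    list(group_sizes = group_sizes, control_group = control_group,
         n_background = n_background, p_bg = p_bg,
         n_enriched = n_enriched, p_ctrl_low = p_ctrl_low,
         p_enriched = p_enriched,
         n_contaminant = n_contaminant, p_contam = p_contam,
         replicates_per_sample = replicates_per_sample,
         replicate_concordance = replicate_concordance,
         peptide_lambda = peptide_lambda,
         spike_control = spike_control,
         spike_peptide_range = spike_peptide_range,
         demographics = demographics,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Contaminant family templates; names contain the family word matched by the
# default blocklist's name_substring rules, so removal holds by construction.
.contaminant_families <- list(
  list(name = "Hemoglobin synthetic subunit %d", gene = "HBS%d"),
  list(name = "Haptoglobin synthetic variant %d", gene = "HPTS%d"),
  list(name = "Hemopexin synthetic variant %d", gene = "HPXS%d"),
  list(name = "Immunoglobulin synthetic heavy chain %d", gene = "IGHS%d"),
  list(name = "Keratin, synthetic type %d", gene = "KRTS%d"),
  list(name = "Apolipoprotein synthetic %d", gene = "APOS%d"),
  list(name = "Serum albumin synthetic variant %d", gene = "ALBS%d"),
  list(name = "Complement component synthetic %d", gene = "C%dS")
)

simulate_demographics <- function(groups, control_group) {
  n <- length(groups)
  is_ctrl <- groups == control_group
  age <- ifelse(is_ctrl, stats::rnorm(n, 44, 5), stats::rnorm(n, 75, 5))
  mmse <- round(pmin(30, pmax(0, ifelse(is_ctrl, stats::rnorm(n, 28, 1),
                                        stats::rnorm(n, 18, 3)))))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  hy <- ifelse(grepl("PD", groups, fixed = TRUE),
               sample(c(1, 1.5, 2, 2.5, 3), n, replace = TRUE), NA_real_)
  frssd <- ifelse(is_ctrl, NA_real_, round(stats::rnorm(n, 11, 4)))
  tibble::tibble(sex = sex, age = round(age, 1), mmse = mmse, hy = hy,
                 frssd = frssd)
}

#' Generate a synthetic study
#'
#' Draws a complete study from a [simulation_config()]: a study design, a
#' long-format identification table with per-replicate peptide evidence,
#' and per-protein truth labels (`background`, `enriched:<group>`,
#' `contaminant`, `control`) for recovery scoring. Detections are
#' independent per-sample Bernoulli draws with class- and group-specific
#' probabilities; each detection carries `1 + Poisson(lambda - 1)` distinct
#' peptides drawn from the protein's peptide pool.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `design`, `table`, `truth` (tibble:
#'   accession, class) and `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  groups <- rep(names(config$group_sizes), config$group_sizes)
  sample_ids <- unlist(lapply(names(config$group_sizes), function(g)
    sprintf("%s_%02d", g, seq_len(config$group_sizes[[g]]))))
  reps <- paste0("rep", seq_len(config$replicates_per_sample))
  demo <- if (config$demographics) {
    simulate_demographics(groups, config$control_group)
  } else {
    tibble::tibble(sex = rep(NA_character_, length(groups)),
                   age = NA_real_, mmse = NA_real_, hy = NA_real_,
                   frssd = NA_real_)
  }
  design <- study_design(
    dplyr::bind_cols(
      tibble::tibble(sample_id = sample_ids, group = groups,
                     replicate_ids = replicate(length(sample_ids), reps,
                                               simplify = FALSE)),
      demo),
    group_labels = names(config$group_sizes),
    control_group = config$control_group
  )

  patient_groups <- setdiff(names(config$group_sizes), config$control_group)
  catalog <- list()
  if (config$n_background > 0) {
    i <- seq_len(config$n_background)
    catalog$bg <- tibble::tibble(
      accession = sprintf("SYNB%04d", i),
      protein_name = sprintf("Synthetic background antigen %d", i),
      gene_symbol = sprintf("SYB%d", i),
      class = "background")
  }
  for (g in patient_groups) {
    if (config$n_enriched > 0) {
      i <- seq_len(config$n_enriched)
      catalog[[paste0("enr_", g)]] <- tibble::tibble(
        accession = sprintf("SYNE%s%03d", g, i),
        protein_name = sprintf("Synthetic %s-enriched antigen %d", g, i),
        gene_symbol = sprintf("SE%s%d", g, i),
        class = paste0("enriched:", g))
    }
  }
  if (config$n_contaminant > 0) {
    i <- seq_len(config$n_contaminant)
    fam <- .contaminant_families[((i - 1) %% length(.contaminant_families)) + 1]
    catalog$contam <- tibble::tibble(
      accession = sprintf("SYNC%03d", i),
      protein_name = mapply(function(f, k) sprintf(f$name, k), fam, i),
      gene_symbol = mapply(function(f, k) sprintf(f$gene, k), fam, i),
      class = "contaminant")
  }
  if (config$spike_control) {
    catalog$spike <- tibble::tibble(
      accession = "SYNKLK6",
      protein_name = "Kallikrein-6 synthetic spike-in",
      gene_symbol = "KLK6",
      class = "control")
  }
  proteins <- dplyr::bind_rows(catalog)
  assert_that(nrow(proteins) > 0, "config generates no proteins")

  pool_size <- max(15, config$spike_peptide_range[2] + 2)
  pools <- lapply(seq_len(nrow(proteins)), function(i) {
    p <- random_peptides(pool_size)
    while (anyDuplicated(p)) p <- unique(c(p, random_peptides(pool_size)))[1:pool_size]
    p
  })

  # per-sample detection probability by protein class and sample group
  prob_for <- function(class, group) {
    if (class == "background") return(config$p_bg)
    if (class == "contaminant") return(config$p_contam)
    if (class == "control") return(1)
    enr_group <- sub("^enriched:", "", class)
    if (group == enr_group) config$p_enriched else config$p_ctrl_low
  }
  prob_mat <- outer(seq_len(nrow(proteins)), seq_along(sample_ids),
                    Vectorize(function(i, j)
                      prob_for(proteins$class[i], groups[j])))
  det <- matrix(runif(length(prob_mat)) < prob_mat, nrow = nrow(prob_mat))
  hits <- which(det, arr.ind = TRUE)

  n_hit <- nrow(hits)
  is_spike <- proteins$class[hits[, 1]] == "control"
  n_pep <- 1 + rpois(n_hit, config$peptide_lambda - 1)
  if (any(is_spike)) {
    rng <- config$spike_peptide_range
    n_pep[is_spike] <- sample(rng[1]:rng[2], sum(is_spike), replace = TRUE)
  }
  n_pep <- pmin(n_pep, pool_size)
  pep_list <- lapply(seq_len(n_hit), function(k)
    sample(pools[[hits[k, 1]]], n_pep[k]))

  # expand to peptide rows, then to replicates: one random primary replicate
  # carries the full detection; each peptide recurs elsewhere with
  # probability replicate_concordance
  primary <- sample.int(config$replicates_per_sample, n_hit, replace = TRUE)
  pep_rows <- tibble::tibble(
    hit = rep(seq_len(n_hit), n_pep),
    peptide = unlist(pep_list, use.names = FALSE))
  rep_frames <- lapply(seq_len(config$replicates_per_sample), function(r) {
    keep <- primary[pep_rows$hit] == r |
      runif(nrow(pep_rows)) < config$replicate_concordance
    out <- pep_rows[keep, ]
    out$replicate_id <- reps[r]
    out
  })
  all_rows <- dplyr::bind_rows(rep_frames)
  table <- identification_table(tibble::tibble(
    sample_id = sample_ids[hits[all_rows$hit, 2]],
    replicate_id = all_rows$replicate_id,
    accession = proteins$accession[hits[all_rows$hit, 1]],
    protein_name = proteins$protein_name[hits[all_rows$hit, 1]],
    gene_symbol = proteins$gene_symbol[hits[all_rows$hit, 1]],
    peptide = all_rows$peptide,
    q_value = signif(runif(nrow(all_rows), 0, 0.01), 3),
    peptide_detail = TRUE
  ), dialect = "long_tsv")

  list(design = design,
       table = table,
       truth = proteins[c("accession", "class")],
       config = config)
}

#' Write a synthetic study to disk
#'
#' Emits `manifest.tsv`, `identifications.tsv` (long dialect) and
#' `truth.tsv` into a directory.
#'
#' @param study Result of [generate_study()].
#' @param dir Output directory, created if needed.
#' @return Named character vector of paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    manifest = file.path(dir, "manifest.tsv"),
    identifications = file.path(dir, "identifications.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_manifest(study$design, paths["manifest"])
  write_identifications(study$table, paths["identifications"], "long_tsv")
  readr::write_tsv(study$truth, paths["truth"])
  paths
}

#' Score candidate recovery against simulation truth
#'
#' @param candidates A candidate tibble from [select_candidates()] for one
#'   patient group.
#' @param truth Truth labels from [generate_study()].
#' @param patient_group The patient group the candidates were selected for.
#' @return A list with `sensitivity` (selected enriched-for-group / total
#'   enriched-for-group), `false_candidate_rate` (selected background /
#'   total background) and the underlying counts.
#' @export
score_recovery <- function(candidates, truth, patient_group) {
  unknown <- setdiff(candidates$accession, truth$accession)
  assert_that(length(unknown) == 0,
              paste0("candidate protein(s) not in the truth universe: ",
                     paste(head(unknown, 3), collapse = ", ")))
  enr_class <- paste0("enriched:", patient_group)
  enr <- truth$accession[truth$class == enr_class]
  bg <- truth$accession[truth$class == "background"]
  sel <- candidates$accession
  list(
    sensitivity = if (length(enr) > 0) sum(enr %in% sel) / length(enr) else NA_real_,
    false_candidate_rate = if (length(bg) > 0) sum(bg %in% sel) / length(bg) else NA_real_,
    n_enriched = length(enr), n_enriched_selected = sum(enr %in% sel),
    n_background = length(bg), n_background_selected = sum(bg %in% sel)
  )
}
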