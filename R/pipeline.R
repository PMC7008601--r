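# End-to-end orchestration: read -> merge -> presence matrix -> blocklist ->
# candidate selection -> overlap -> QC -> cohort statistics -> reports.

#' Run configuration
#'
#' Bundles every path and threshold of a screen run. A YAML file with the
#' same keys can be loaded with [read_run_config()]; explicitly supplied
#' values win over the file.
#'
#' @param manifest Path to the sample manifest TSV.
#' @param identifications Path to the identification table.
#' @param outdir Output directory for reports.
#' @param dialect Identification dialect, `"long_tsv"` or `"wide_presence"`.
#' @param blocklist Path to a blocklist file; `NULL` uses the shipped
#'   default.
#' @param merge_policy Replicate merge policy, `"union"` (default) or
#'   `"intersection"`.
#' @param q_max Optional q-value ceiling.
#' @param min_peptides Minimum distinct peptides per detection call.
#' @param max_control_detections,min_patient_fraction,min_patient_count
#'   See [selection_criteria()].
#' @param control_group Control group label (`NULL`: manifest convention).
#' @param qc_protein Positive-control accession or gene symbol.
#' @param qc_min_peptides Minimum peptides for the QC pass.
#' @param seed Optional integer seed recorded in the run log.
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(manifest, identifications, outdir,
                       dialect = "long_tsv", blocklist = NULL,
                       merge_policy = "union", q_max = NULL,
                       min_peptides = 1,
                       max_control_detections = 1,
                       min_patient_fraction = 0.5,
                       min_patient_count = NULL,
                       control_group = NULL,
                       qc_protein = "KLK6", qc_min_peptides = 1,
                       seed = NULL, log_level = "info") {
  structure(
    list(manifest = manifest, identifications = identifications,
         outdir = outdir, dialect = dialect, blocklist = blocklist,
         merge_policy = merge_policy, q_max = q_max,
         min_peptides = min_peptides,
         max_control_detections = max_control_detections,
         min_patient_fraction = min_patient_fraction,
         min_patient_count = min_patient_count,
         control_group = control_group,
         qc_protein = qc_protein, qc_min_peptides = qc_min_peptides,
         seed = seed, log_level = log_level),
    class = "run_config"
  )
}

#' Read a run configuration from YAML, with overrides
#'
#' @param path Path to a YAML document whose keys mirror [run_config()]
#'   arguments.
#' @param overrides Named list of values that win over the file (CLI flags).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full candidate screen
#'
#' Executes every stage in order for each non-control group: manifest and
#' identification reading, replicate merging, presence-matrix construction,
#' blocklist removal, candidate selection, group overlap, positive-control
#' QC and (when demographics are present) cohort statistics; writes the
#' candidate TSVs, overlap/QC/cohort JSON reports and a run log with
#' per-stage protein counts and the criteria actually applied (including
#' the resolved minimum patient count). A stage failure aborts with a
#' stage-named error.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`design`,
#'   `matrix`, `report`, `overlap`, `qc`, `cohort`, `paths`, `log`).
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  note <- function(...) {
    line <- sprintf(...)
    if (identical(config$log_level, "info")) message(line)
    log_lines <<- c(log_lines, line)
  }

  design <- with_stage("read_manifest",
                       read_manifest(config$manifest,
                                     control_group = config$control_group))
  note("manifest: %d samples, groups %s (control: %s)",
       nrow(design$samples), paste(design$group_labels, collapse = "/"),
       design$control_group)
  table <- with_stage("read_identifications",
                      read_identifications(config$identifications,
                                           config$dialect))
  note("identifications: %d records (%s dialect)", nrow(table), config$dialect)
  merged <- with_stage("merge_replicates",
                       merge_replicates(table, config$merge_policy, design))
  pm <- with_stage("build_presence_matrix",
                   build_presence_matrix(merged, design,
                                         q_max = config$q_max,
                                         min_peptides = config$min_peptides))
  note("presence matrix: %d proteins x %d samples", nrow(pm$proteins),
       length(pm$samples))
  for (g in design$group_labels) {
    s <- group_samples(design, g)
    note("  %s: %d proteins detected in >=1 sample", g,
         sum(rowSums(pm$detected[, s, drop = FALSE]) > 0))
  }
  rules <- with_stage("read_blocklist",
                      read_blocklist(config$blocklist %||% default_blocklist_path()))
  filt <- with_stage("apply_blocklist", apply_blocklist(pm, rules))
  note("blocklist: removed %d of %d proteins; %d remain",
       length(filt$removed_accessions), nrow(pm$proteins),
       nrow(filt$matrix$proteins))
  for (g in design$group_labels) {
    s <- group_samples(design, g)
    note("  %s: %d proteins after blocklist", g,
         sum(rowSums(filt$matrix$detected[, s, drop = FALSE]) > 0))
  }
  criteria <- selection_criteria(config$max_control_detections,
                                 config$min_patient_fraction,
                                 config$min_patient_count)
  report <- with_stage("select_candidates",
                       candidate_report(filt$matrix, design, criteria,
                                        filt$removed_accessions))
  for (g in names(report$groups)) {
    res <- attr(report$groups[[g]], "criteria_resolved")
    note("  %s: %d candidates (max control %d, min patient count %d)",
         g, nrow(report$groups[[g]]),
         res$max_control_detections, res$min_patient_count)
  }
  overlap <- if (length(design$group_labels) >= 2) {
    with_stage("compute_overlap", compute_overlap(filt$matrix, design))
  } else NULL
  if (!is.null(overlap)) {
    note("overlap: %d proteins total, %d (%d%%) common to all groups",
         overlap$grand_total, overlap$n_common, overlap$percent_common)
  }
  qc <- with_stage("check_positive_control",
                   check_positive_control(pm, config$qc_protein,
                                          config$qc_min_peptides))
  note("positive control %s: %s", config$qc_protein,
       if (qc$pass) "PASS" else "FAIL")
  cohort <- if (any(!is.na(design$samples$age) | !is.na(design$samples$sex) |
                      !is.na(design$samples$mmse))) {
    with_stage("cohort_statistics",
               suppressWarnings(cohort_statistics(design)))
  } else NULL
  if (!is.null(config$seed)) note("seed: %d", config$seed)

  paths <- with_stage("write_reports",
                      write_reports(report, overlap, qc, config$outdir,
                                    cohort = cohort))
  removed_path <- file.path(config$outdir, "removed_accessions.txt")
  writeLines(sort(filt$removed_accessions), removed_path)
  paths["removed_accessions"] <- removed_path
  log_path <- file.path(config$outdir, "run_log.txt")
  writeLines(log_lines, log_path)
  paths["run_log"] <- log_path

  invisible(list(design = design, matrix = filt$matrix, report = report,
                 overlap = overlap, qc = qc, cohort = cohort,
                 paths = paths, log = log_lines))
}

#' Run only the cohort statistics
#'
#' @param config A [run_config()]; only `manifest`, `control_group` and
#'   `outdir` are used.
#' @return Invisibly, the cohort statistics list (also written to
#'   `cohort_stats.json`). Emits a warning and writes an empty document
#'   when no demographic variable is comparable.
#' @export
run_cohort_stats <- function(config) {
  stopifnot(inherits(config, "run_config"))
  design <- with_stage("read_manifest",
                       read_manifest(config$manifest,
                                     control_group = config$control_group))
  stats <- with_stage("cohort_statistics", cohort_statistics(design))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(config$outdir, "cohort_stats.json")
  jsonlite::write_json(stats, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(stats)
}
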