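# Reading and writing the external representations of a screen: sample
# manifests, identification tables (two dialects), blocklists and reports.

# ---- study design -----------------------------------------------------------

#' Construct a study design
#'
#' A study design holds the sample manifest of a screen: sample identifiers,
#' their group labels (one of which is the control group), the technical
#' replicate identifiers of every sample, and optional demographics
#' (sex, age, MMSE, Hoehn-Yahr and FRSSD scores).
#'
#' @param samples A tibble with columns `sample_id`, `group`,
#'   `replicate_ids` (list column of character vectors) and optional
#'   demographic columns `sex`, `age`, `mmse`, `hy`, `frssd`.
#' @param group_labels Ordered character vector of group labels. Defaults to
#'   the order of first appearance in `samples`.
#' @param control_group Label of the control group. Defaults to `"control"`
#'   when present among the labels, otherwise the first label.
#' @return An object of class `study_design`.
#' @export
study_design <- function(samples, group_labels = NULL, control_group = NULL) {
  stopifnot(is.data.frame(samples))
  assert_that(nrow(samples) > 0, "study design must contain at least one sample")
  for (col in c("sex", "age", "mmse", "hy", "frssd")) {
    if (!col %in% names(samples)) samples[[col]] <- NA
  }
  if (!"replicate_ids" %in% names(samples)) {
    samples$replicate_ids <- replicate(nrow(samples), "rep1", simplify = FALSE)
  }
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  assert_that(length(dup) == 0,
              paste0("duplicate sample_id in manifest: ", paste(unique(dup), collapse = ", ")))
  bad_rep <- vapply(samples$replicate_ids,
                    function(r) length(r) != length(unique(r)) || length(r) < 1,
                    logical(1))
  assert_that(!any(bad_rep),
              paste0("replicate ids must be unique and non-empty within a sample: ",
                     paste(samples$sample_id[bad_rep], collapse = ", ")))
  group_labels <- group_labels %||% unique(samples$group)
  assert_that(all(samples$group %in% group_labels),
              "every sample's group must be among the declared group labels")
  assert_that(all(group_labels %in% samples$group),
              "every declared group needs at least one sample")
  control_group <- control_group %||%
    (if ("control" %in% group_labels) "control" else group_labels[[1]])
  assert_that(control_group %in% group_labels,
              paste0("control group '", control_group, "' is not a declared group"))
  structure(
    list(samples = tibble::as_tibble(samples),
         group_labels = group_labels,
         control_group = control_group),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  sizes <- table(factor(x$samples$group, levels = x$group_labels))
  cat("study_design:", nrow(x$samples), "samples in",
      length(x$group_labels), "groups\n")
  cat(paste0("  ", names(sizes), ": n=", as.integer(sizes),
             ifelse(names(sizes) == x$control_group, " (control)", "")),
      sep = "\n")
  invisible(x)
}

group_samples <- function(design, group) {
  assert_that(group %in% design$group_labels,
              paste0("unknown group label: ", group))
  design$samples$sample_id[design$samples$group == group]
}

#' Read a sample manifest
#'
#' The manifest is a UTF-8 TSV with header columns `sample_id`, `group`,
#' `replicates` (semicolon-separated replicate identifiers) and optional
#' demographic columns `sex`, `age`, `mmse`, `hy`, `frssd`. Empty demographic
#' cells become typed missing values, never zeros. Unknown columns are
#' dropped with a warning; a duplicated `sample_id` or an empty file is an
#' error.
#'
#' @param path Path to the manifest TSV.
#' @inheritParams study_design
#' @return A [study_design()].
#' @export
read_manifest <- function(path, control_group = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  assert_that(nrow(df) > 0, paste0("manifest is empty: ", path))
  required <- c("sample_id", "group")
  missing <- setdiff(required, names(df))
  assert_that(length(missing) == 0,
              paste0("manifest is missing required column(s): ",
                     paste(missing, collapse = ", ")))
  known <- c(required, "replicates", "sex", "age", "mmse", "hy", "frssd")
  unknown <- setdiff(names(df), known)
  if (length(unknown) > 0) {
    warning("ignoring unknown manifest column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
    df <- df[known[known %in% names(df)]]
  }
  reps <- if ("replicates" %in% names(df)) {
    lapply(df$replicates, function(r) {
      if (is.na(r) || !nzchar(r)) "rep1" else strsplit(r, ";", fixed = TRUE)[[1]]
    })
  } else {
    replicate(nrow(df), "rep1", simplify = FALSE)
  }
  num <- function(col) if (col %in% names(df)) suppressWarnings(as.numeric(df[[col]])) else NA_real_
  samples <- tibble::tibble(
    sample_id = df$sample_id,
    group = df$group,
    replicate_ids = reps,
    sex = if ("sex" %in% names(df)) df$sex else NA_character_,
    age = num("age"),
    mmse = num("mmse"),
    hy = num("hy"),
    frssd = num("frssd")
  )
  study_design(samples, control_group = control_group)
}

#' Write a sample manifest
#'
#' @param design A [study_design()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(design, path) {
  df <- design$samples
  out <- tibble::tibble(
    sample_id = df$sample_id,
    group = df$group,
    replicates = vapply(df$replicate_ids, paste, character(1), collapse = ";"),
    sex = df$sex, age = df$age, mmse = df$mmse, hy = df$hy, frssd = df$frssd
  )
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

# ---- identification tables --------------------------------------------------

#' Construct an identification table
#'
#' The internal long representation of peptide-spectrum evidence: one row per
#' (sample, replicate, protein, peptide). Wide presence-mark tables that carry
#' no peptide rows are represented with a synthetic per-protein presence
#' marker and `peptide_detail = FALSE`, so that peptide-level statistics are
#' reported as unavailable rather than fabricated.
#'
#' @param records A data frame with columns `sample_id`, `replicate_id`,
#'   `accession`, `protein_name`, `gene_symbol`, `peptide`, `q_value`,
#'   `peptide_detail`.
#' @param dialect The source dialect, `"long_tsv"` or `"wide_presence"`.
#' @param merged Whether technical replicates have already been merged.
#' @return A tibble of class `identification_table`.
#' @export
identification_table <- function(records, dialect = "long_tsv", merged = FALSE) {
  records <- tibble::as_tibble(records)
  if (!"gene_symbol" %in% names(records)) records$gene_symbol <- NA_character_
  if (!"q_value" %in% names(records)) records$q_value <- NA_real_
  if (!"peptide_detail" %in% names(records)) records$peptide_detail <- TRUE
  needed <- c("sample_id", "replicate_id", "accession", "protein_name",
              "gene_symbol", "peptide", "q_value", "peptide_detail")
  missing <- setdiff(needed, names(records))
  assert_that(length(missing) == 0,
              paste0("identification records lack column(s): ",
                     paste(missing, collapse = ", ")))
  real <- records$peptide_detail
  bad <- real & !is_valid_peptide(records$peptide)
  assert_that(!any(bad),
              paste0("invalid peptide sequence(s), e.g.: ",
                     paste(head(unique(records$peptide[bad]), 3), collapse = ", ")))
  qv <- records$q_value
  assert_that(all(is.na(qv) | (qv >= 0 & qv <= 1)), "q_value must lie in [0, 1]")
  out <- records[needed]
  class(out) <- c("identification_table", class(tibble::tibble()))
  attr(out, "dialect") <- dialect
  attr(out, "merged") <- merged
  out
}

#' Read an identification table
#'
#' Two dialects are supported.
#'
#' * `long_tsv`: a TSV with header columns `sample_id`, `replicate_id`,
#'   `protein_accession`, `protein_name`, `peptide_sequence` and optional
#'   `gene_symbol`, `q_value`.
#' * `wide_presence`: protein-identifying columns (`protein_accession`,
#'   optional `protein_name`, `gene_symbol`, `peptide_sequence`) followed by
#'   one column per sample (or per `sample:replicate`), each cell either
#'   `"I"` (identified) or blank (absent). When no `peptide_sequence` column
#'   exists the table is protein-level: presence is recorded but unique
#'   peptide counts are marked unavailable downstream.
#'
#' @param path Path to the TSV file.
#' @param dialect `"long_tsv"` or `"wide_presence"`.
#' @return An [identification_table()].
#' @export
read_identifications <- function(path, dialect = c("long_tsv", "wide_presence")) {
  dialect <- match.arg(dialect)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, na = character())
  if (dialect == "long_tsv") {
    required <- c("sample_id", "replicate_id", "protein_accession",
                  "protein_name", "peptide_sequence")
    missing <- setdiff(required, names(df))
    assert_that(length(missing) == 0,
                paste0("long_tsv table is missing required column(s): ",
                       paste(missing, collapse = ", ")))
    recs <- tibble::tibble(
      sample_id = df$sample_id,
      replicate_id = df$replicate_id,
      accession = df$protein_accession,
      protein_name = df$protein_name,
      gene_symbol = if ("gene_symbol" %in% names(df))
        ifelse(nzchar(df$gene_symbol), df$gene_symbol, NA_character_) else NA_character_,
      peptide = df$peptide_sequence,
      q_value = if ("q_value" %in% names(df))
        suppressWarnings(as.numeric(ifelse(nzchar(df$q_value), df$q_value, NA))) else NA_real_,
      peptide_detail = TRUE
    )
    return(identification_table(recs, dialect = "long_tsv"))
  }

  id_cols <- intersect(c("protein_accession", "protein_name", "gene_symbol",
                         "peptide_sequence"), names(df))
  assert_that("protein_accession" %in% id_cols,
              "wide_presence table needs a protein_accession column")
  sample_cols <- setdiff(names(df), id_cols)
  assert_that(length(sample_cols) > 0, "wide_presence table has no sample columns")
  cells <- as.matrix(df[sample_cols])
  ok <- cells == "I" | cells == "" | is.na(cells)
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("unexpected cell value %s at row %d, column '%s' (expected \"I\" or blank)",
                 dQuote(cells[idx[1], idx[2]]), idx[1], sample_cols[idx[2]]),
         call. = FALSE)
  }
  present <- which(cells == "I", arr.ind = TRUE)
  split_col <- strsplit(sample_cols, ":", fixed = TRUE)
  col_sample <- vapply(split_col, `[`, character(1), 1)
  col_rep <- vapply(split_col, function(x) if (length(x) > 1) x[2] else "merged",
                    character(1))
  has_pep <- "peptide_sequence" %in% id_cols
  acc <- df$protein_accession[present[, 1]]
  recs <- tibble::tibble(
    sample_id = col_sample[present[, 2]],
    replicate_id = col_rep[present[, 2]],
    accession = acc,
    protein_name = if ("protein_name" %in% id_cols)
      df$protein_name[present[, 1]] else acc,
    gene_symbol = if ("gene_symbol" %in% id_cols) {
      g <- df$gene_symbol[present[, 1]]
      ifelse(nzchar(g), g, NA_character_)
    } else NA_character_,
    peptide = if (has_pep) df$peptide_sequence[present[, 1]]
      else paste0("presence:", acc),
    q_value = NA_real_,
    peptide_detail = has_pep
  )
  identification_table(recs, dialect = "wide_presence",
                       merged = all(col_rep == "merged"))
}

#' Write an identification table
#'
#' @inheritParams read_identifications
#' @param table An [identification_table()].
#' @param peptide_level For `wide_presence`: write one row per
#'   (protein, peptide) when peptide detail is available (default), or one
#'   presence row per protein when `FALSE`.
#' @return `path`, invisibly.
#' @export
write_identifications <- function(table, path,
                                  dialect = c("long_tsv", "wide_presence"),
                                  peptide_level = TRUE) {
  dialect <- match.arg(dialect)
  if (dialect == "long_tsv") {
    out <- tibble::tibble(
      sample_id = table$sample_id,
      replicate_id = table$replicate_id,
      protein_accession = table$accession,
      protein_name = table$protein_name,
      gene_symbol = table$gene_symbol,
      peptide_sequence = table$peptide,
      q_value = table$q_value
    )
    readr::write_tsv(out, path, na = "")
    return(invisible(path))
  }
  peptide_level <- peptide_level && all(table$peptide_detail)
  col_of <- function(s, r) ifelse(r == "merged", s, paste0(s, ":", r))
  tab <- tibble::as_tibble(table)
  tab$.col <- col_of(tab$sample_id, tab$replicate_id)
  cols <- unique(tab$.col)
  if (peptide_level) {
    keys <- unique(tab[c("accession", "protein_name", "gene_symbol", "peptide")])
    wide <- matrix("", nrow(keys), length(cols),
                   dimnames = list(NULL, cols))
    ridx <- match(paste(tab$accession, tab$peptide, sep = "\r"),
                  paste(keys$accession, keys$peptide, sep = "\r"))
    wide[cbind(ridx, match(tab$.col, cols))] <- "I"
    out <- cbind(
      tibble::tibble(protein_accession = keys$accession,
                     protein_name = keys$protein_name,
                     gene_symbol = keys$gene_symbol,
                     peptide_sequence = keys$peptide),
      tibble::as_tibble(as.data.frame(wide, check.names = FALSE))
    )
  } else {
    keys <- unique(tab[c("accession", "protein_name", "gene_symbol")])
    wide <- matrix("", nrow(keys), length(cols), dimnames = list(NULL, cols))
    ridx <- match(tab$accession, keys$accession)
    wide[cbind(ridx, match(tab$.col, cols))] <- "I"
    out <- cbind(
      tibble::tibble(protein_accession = keys$accession,
                     protein_name = keys$protein_name,
                     gene_symbol = keys$gene_symbol),
      tibble::as_tibble(as.data.frame(wide, check.names = FALSE))
    )
  }
  readr::write_tsv(tibble::as_tibble(out), path, na = "")
  invisible(path)
}

# ---- blocklist --------------------------------------------------------------

#' Read a blocklist of abundant serum protein rules
#'
#' A blocklist file has one rule per line, `match_type<TAB>pattern`, with
#' `#`-prefixed comment lines ignored. Match types are `gene_prefix`
#' (gene symbol starts with the pattern), `name_substring` (case-insensitive
#' substring of the protein name) and `accession_exact`.
#'
#' @param path Path to the blocklist file; defaults to the shipped list
#'   covering the eight abundant serum protein families typically removed in
#'   immunoprecipitation screens (hemoglobin, haptoglobin, hemopexin,
#'   immunoglobulins, keratins, apolipoproteins, serum albumin, complement).
#' @return A tibble with columns `match_type` and `pattern`, in file order.
#' @export
read_blocklist <- function(path = default_blocklist_path()) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) {
    return(tibble::tibble(match_type = character(), pattern = character()))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad_shape <- lengths(parts) < 2
  assert_that(!any(bad_shape),
              paste0("malformed blocklist line ", keep[bad_shape][1],
                     ": expected 'match_type<TAB>pattern'"))
  types <- vapply(parts, `[`, character(1), 1)
  patterns <- vapply(parts, `[`, character(1), 2)
  valid <- c("gene_prefix", "name_substring", "accession_exact")
  bad <- !types %in% valid
  assert_that(!any(bad),
              paste0("unknown blocklist match_type '", types[bad][1],
                     "' at line ", keep[bad][1]))
  assert_that(all(nzchar(patterns)), "blocklist patterns must be non-empty")
  tibble::tibble(match_type = types, pattern = patterns)
}

#' Path to the shipped default blocklist
#' @return A file path.
#' @export
default_blocklist_path <- function() {
  system.file("extdata", "blocklist_default.tsv", package = "antigenscreen",
              mustWork = TRUE)
}

# ---- reports ----------------------------------------------------------------

format_mean <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.1f", round_half_up(x, 1)))
}

candidate_tsv <- function(cand) {
  out <- cand
  mean_cols <- grep("_mean_unique$", names(out), value = TRUE)
  for (col in mean_cols) out[[col]] <- format_mean(out[[col]])
  out
}

#' Write candidate, overlap and QC reports
#'
#' Emits one candidate TSV per patient group (protein identity columns
#' followed by, for each group, the number of individuals identified, the
#' total unique peptides over the group and the mean unique peptides per
#' detected individual, means printed with one decimal), plus the group
#' overlap summary and positive-control QC as JSON. Cohort statistics, when
#' supplied, are written as a third JSON document.
#'
#' @param candidates A [candidate_report()].
#' @param overlap An overlap summary from [compute_overlap()], or `NULL`.
#' @param qc A QC report from [check_positive_control()], or `NULL`.
#' @param outdir Output directory, created if needed.
#' @param cohort Optional cohort statistics from [cohort_statistics()].
#' @return Named character vector of file paths written.
#' @export
write_reports <- function(candidates, overlap = NULL, qc = NULL, outdir,
                          cohort = NULL) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  assert_that(ok && file.access(outdir, 2) == 0,
              paste0("output directory is not writable: ", outdir))
  paths <- character()
  for (g in names(candidates$groups)) {
    p <- file.path(outdir, paste0("candidates_", g, ".tsv"))
    readr::write_tsv(candidate_tsv(candidates$groups[[g]]), p, na = "NA")
    paths[paste0("candidates_", g)] <- p
  }
  write_json <- function(x, name) {
    p <- file.path(outdir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    p
  }
  if (!is.null(overlap)) paths["overlap"] <- write_json(unclass(overlap), "overlap.json")
  if (!is.null(qc)) paths["qc"] <- write_json(unclass(qc), "qc.json")
  if (!is.null(cohort)) paths["cohort_stats"] <- write_json(cohort, "cohort_stats.json")
  paths
}
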