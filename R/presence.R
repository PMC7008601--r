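# Replicate merging and the protein x sample presence matrix with
# unique-peptide statistics.

#' Merge technical replicates
#'
#' Collapses per-replicate evidence to one record stream per sample. Under
#' the `union` policy a (protein, peptide) pair is kept if seen in at least
#' one replicate of the sample; under `intersection` it must appear in every
#' replicate. The union policy is the default: screens of this kind report a
#' single identification list per individual without requiring concordance
#' across injections.
#'
#' @param table An [identification_table()].
#' @param policy `"union"` or `"intersection"`.
#' @param design Optional [study_design()]; with `policy = "intersection"`
#'   it supplies the declared replicate count per sample, so that evidence
#'   from a replicate that produced no records still counts as a miss.
#' @return A merged [identification_table()] (replicate_id `"merged"`); the
#'   minimum q-value across replicates is retained.
#' @export
merge_replicates <- function(table, policy = c("union", "intersection"),
                             design = NULL) {
  policy <- match.arg(policy)
  tab <- tibble::as_tibble(table)
  if (policy == "intersection") {
    if (!is.null(design)) {
      n_rep <- setNames(lengths(design$samples$replicate_ids),
                        design$samples$sample_id)
    } else {
      obs <- unique(tab[c("sample_id", "replicate_id")])
      n_rep <- tapply(obs$replicate_id, obs$sample_id,
                      function(x) length(unique(x)))
    }
    zero <- names(n_rep)[is.na(n_rep) | n_rep < 1]
    assert_that(length(zero) == 0,
                paste0("intersection policy requires at least one replicate per sample; ",
                       "none declared for: ", paste(zero, collapse = ", ")))
  }
  merged <- tab |>
    dplyr::group_by(.data$sample_id, .data$accession, .data$peptide) |>
    dplyr::summarise(
      n_reps_seen = dplyr::n_distinct(.data$replicate_id),
      replicate_id = "merged",
      protein_name = .data$protein_name[1],
      gene_symbol = .data$gene_symbol[1],
      q_value = if (all(is.na(.data$q_value))) NA_real_ else
        min(.data$q_value, na.rm = TRUE),
      peptide_detail = all(.data$peptide_detail),
      .groups = "drop"
    )
  if (policy == "intersection") {
    merged <- merged[merged$n_reps_seen >= n_rep[merged$sample_id], ]
  }
  merged$n_reps_seen <- NULL
  identification_table(merged, dialect = attr(table, "dialect") %||% "long_tsv",
                       merged = TRUE)
}

#' Build the protein-by-sample presence matrix
#'
#' A protein is called detected in a sample when at least `min_peptides`
#' distinct peptide sequences remain after the optional q-value filter.
#' The matrix covers the union of proteins over all samples, and every
#' sample in the design (columns of samples without any identification are
#' all-absent). Records whose sample is not in the design are an error.
#'
#' @param table A replicate-merged [identification_table()].
#' @param design A [study_design()].
#' @param q_max Optional q-value ceiling; records with `q_value > q_max` are
#'   dropped (records without a q-value are kept).
#' @param min_peptides Minimum distinct peptides for a detection call
#'   (default 1, so single-peptide identifications count).
#' @return An object of class `presence_matrix` with elements `proteins`
#'   (tibble: accession, protein_name, gene_symbol), `samples`, `detected`
#'   (logical matrix), `n_peptides` (numeric matrix; `NA` where presence was
#'   recorded without peptide detail) and `peptide_sets` (nested list
#'   accession -> sample -> character vector of peptides).
#' @export
build_presence_matrix <- function(table, design, q_max = NULL, min_peptides = 1) {
  tab <- tibble::as_tibble(table)
  unknown <- setdiff(unique(tab$sample_id), design$samples$sample_id)
  assert_that(length(unknown) == 0,
              paste0("identification table references sample(s) absent from the design: ",
                     paste(unknown, collapse = ", ")))
  if (!is.null(q_max)) {
    tab <- tab[is.na(tab$q_value) | tab$q_value <= q_max, ]
  }
  cells <- tab |>
    dplyr::group_by(.data$accession, .data$sample_id) |>
    dplyr::summarise(
      protein_name = .data$protein_name[1],
      gene_symbol = .data$gene_symbol[1],
      peptides = list(unique(.data$peptide[.data$peptide_detail])),
      any_marker = any(!.data$peptide_detail),
      .groups = "drop"
    )
  cells$n_real <- lengths(cells$peptides)
  if (any(cells$any_marker & cells$n_real == 0) && min_peptides > 1) {
    warning("presence recorded without peptide detail; min_peptides > 1 cannot ",
            "be enforced for those cells", call. = FALSE)
  }
  proteins <- cells |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(
      protein_name = .data$protein_name[which(!is.na(.data$protein_name))[1] %na% 1],
      gene_symbol = .data$gene_symbol[which(!is.na(.data$gene_symbol))[1] %na% 1],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$accession)
  samples <- design$samples$sample_id
  accs <- proteins$accession
  detected <- matrix(FALSE, length(accs), length(samples),
                     dimnames = list(accs, samples))
  n_pep <- matrix(0, length(accs), length(samples),
                  dimnames = list(accs, samples))
  idx <- cbind(match(cells$accession, accs), match(cells$sample_id, samples))
  det_cell <- ifelse(cells$n_real > 0, cells$n_real >= min_peptides,
                     cells$any_marker)
  detected[idx] <- det_cell
  n_pep[idx] <- ifelse(cells$n_real > 0, cells$n_real,
                       ifelse(cells$any_marker, NA_real_, 0))
  n_pep[!detected & !is.na(n_pep)] <- 0
  keep <- cells$n_real > 0 & det_cell
  sets <- split(cells$peptides[keep],
                factor(cells$accession[keep], levels = accs))
  for (a in names(sets)) {
    names(sets[[a]]) <- NULL
  }
  set_names <- split(cells$sample_id[keep],
                     factor(cells$accession[keep], levels = accs))
  peptide_sets <- lapply(accs, function(a) setNames(sets[[a]], set_names[[a]]))
  names(peptide_sets) <- accs
  structure(
    list(proteins = proteins, samples = samples, detected = detected,
         n_peptides = n_pep, peptide_sets = peptide_sets),
    class = "presence_matrix"
  )
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence_matrix:", nrow(x$proteins), "proteins x",
      length(x$samples), "samples;",
      sum(x$detected), "detection calls\n")
  invisible(x)
}

subset_presence <- function(pm, keep_accessions) {
  keep <- pm$proteins$accession %in% keep_accessions
  structure(
    list(proteins = pm$proteins[keep, ],
         samples = pm$samples,
         detected = pm$detected[keep, , drop = FALSE],
         n_peptides = pm$n_peptides[keep, , drop = FALSE],
         peptide_sets = pm$peptide_sets[pm$proteins$accession[keep]]),
    class = "presence_matrix"
  )
}

#' Export a presence matrix as a wide TSV for inspection
#'
#' @param pm A `presence_matrix`.
#' @param path Output TSV path; cells are 1/0 detection flags.
#' @return `path`, invisibly.
#' @export
export_presence_matrix <- function(pm, path) {
  out <- cbind(pm$proteins,
               tibble::as_tibble(as.data.frame(pm$detected * 1L,
                                               check.names = FALSE)))
  readr::write_tsv(tibble::as_tibble(out), path)
  invisible(path)
}

#' Per-group unique-peptide statistics for one protein
#'
#' Returns the number of group samples with a detection, the size of the
#' union of peptide sets over those samples ("total unique peptides") and
#' the arithmetic mean of per-sample distinct-peptide counts over detected
#' samples only ("mean unique peptides", reported rounded half-up to one
#' decimal). When presence was recorded without peptide detail the peptide
#' statistics are `NA`, never fabricated.
#'
#' @param pm A `presence_matrix`.
#' @param design A [study_design()].
#' @param accession Protein accession (must exist in the matrix).
#' @param group Group label (must exist in the design).
#' @return A list with `n_detected`, `total_unique`, `mean_unique`.
#' @export
group_peptide_stats <- function(pm, design, accession, group) {
  assert_that(accession %in% pm$proteins$accession,
              paste0("unknown protein accession: ", accession))
  samples <- intersect(group_samples(design, group), pm$samples)
  det <- pm$detected[accession, samples]
  n_detected <- sum(det)
  if (n_detected == 0) {
    return(list(n_detected = 0L, total_unique = 0L, mean_unique = 0))
  }
  det_samples <- samples[det]
  counts <- pm$n_peptides[accession, det_samples]
  if (anyNA(counts)) {
    return(list(n_detected = n_detected, total_unique = NA_integer_,
                mean_unique = NA_real_))
  }
  sets <- pm$peptide_sets[[accession]][det_samples]
  list(
    n_detected = as.integer(n_detected),
    total_unique = length(unique(unlist(sets, use.names = FALSE))),
    mean_unique = round_half_up(mean(counts), 1)
  )
}
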