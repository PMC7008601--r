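# Shared fixture builders and independent brute-force oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

# valid peptide sequence i (AA alphabet only, distinct per i)
pepseq <- function(i) {
  vapply(i, function(k) paste0("ACDEF", strrep("G", k), "K"), character(1))
}

make_design <- function(sizes = c(control = 4, AD = 4), reps = 1) {
  ids <- unlist(mapply(function(g, n) sprintf("%s_%02d", g, seq_len(n)),
                       names(sizes), sizes, SIMPLIFY = FALSE), use.names = FALSE)
  study_design(tibble::tibble(
    sample_id = ids,
    group = rep(names(sizes), sizes),
    replicate_ids = replicate(length(ids), paste0("rep", seq_len(reps)),
                              simplify = FALSE)))
}

# presence_matrix from a named logical detection matrix; peptide detail is
# marked unavailable unless explicit sets are given
make_pm <- function(detected, peptide_sets = NULL, protein_names = NULL,
                    genes = NULL) {
  accs <- rownames(detected)
  if (is.null(peptide_sets)) {
    n_pep <- ifelse(detected, NA_real_, 0)
    dimnames(n_pep) <- dimnames(detected)
    peptide_sets <- stats::setNames(vector("list", nrow(detected)), accs)
  } else {
    n_pep <- matrix(0, nrow(detected), ncol(detected),
                    dimnames = dimnames(detected))
    for (a in accs) {
      for (s in names(peptide_sets[[a]])) {
        n_pep[a, s] <- length(peptide_sets[[a]][[s]])
      }
    }
  }
  structure(list(
    proteins = tibble::tibble(
      accession = accs,
      protein_name = protein_names %||% accs,
      gene_symbol = genes %||% rep(NA_character_, length(accs))),
    samples = colnames(detected),
    detected = detected,
    n_peptides = n_pep,
    peptide_sets = peptide_sets), class = "presence_matrix")
}

random_detected <- function(n_prot, samples, p = 0.4) {
  matrix(stats::runif(n_prot * length(samples)) < p, n_prot,
         dimnames = list(sprintf("P%03d", seq_len(n_prot)), samples))
}

# brute-force two-part rule: scan every protein
oracle_select <- function(detected, ctrl_samples, pat_samples,
                          max_ctrl, min_count) {
  hits <- character()
  for (a in rownames(detected)) {
    nc <- sum(detected[a, ctrl_samples])
    np <- sum(detected[a, pat_samples])
    if (nc <= max_ctrl && np >= min_count) hits <- c(hits, a)
  }
  hits
}

# brute-force exclusive Venn regions from per-group membership sets
oracle_regions <- function(sets) {
  groups <- names(sets)
  universe <- unique(unlist(sets))
  out <- list()
  for (size in seq_along(groups)) {
    for (combo in utils::combn(groups, size, simplify = FALSE)) {
      inside <- Reduce(intersect, sets[combo])
      outside <- unique(unlist(sets[setdiff(groups, combo)]))
      out[[paste(combo, collapse = "&")]] <- length(setdiff(inside, outside))
    }
  }
  out
}

# brute-force blocklist scan, rule by rule, protein by protein
oracle_blocked <- function(proteins, rules) {
  hits <- character()
  for (i in seq_len(nrow(proteins))) {
    p <- proteins[i, ]
    for (j in seq_len(nrow(rules))) {
      m <- switch(rules$match_type[j],
        gene_prefix = !is.na(p$gene_symbol) &&
          startsWith(p$gene_symbol, rules$pattern[j]),
        name_substring = grepl(tolower(rules$pattern[j]),
                               tolower(p$protein_name), fixed = TRUE),
        accession_exact = p$accession == rules$pattern[j])
      if (m) { hits <- c(hits, p$accession); break }
    }
  }
  hits
}

# random long-format identification table over a replicate structure
random_id_table <- function(design, n_prot = 6, n_pep = 5, p = 0.4) {
  rows <- list()
  for (i in seq_len(nrow(design$samples))) {
    s <- design$samples$sample_id[i]
    for (r in design$samples$replicate_ids[[i]]) {
      for (pr in seq_len(n_prot)) {
        for (pe in seq_len(n_pep)) {
          if (stats::runif(1) < p) {
            rows[[length(rows) + 1]] <- tibble::tibble(
              sample_id = s, replicate_id = r,
              accession = sprintf("P%02d", pr),
              protein_name = sprintf("Protein %02d", pr),
              gene_symbol = NA_character_,
              peptide = pepseq(pe), q_value = NA_real_,
              peptide_detail = TRUE)
          }
        }
      }
    }
  }
  identification_table(dplyr::bind_rows(rows))
}

# 99% central interval for an observed count under Binomial(n, p)
binom_ci99 <- function(n, p) {
  c(stats::qbinom(0.005, n, p), stats::qbinom(0.995, n, p))
}
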