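# Blocklist filtering, the two-part selection rule, overlap and QC.

test_that("blocklist matching removes serum proteins and partitions the input", {
  det <- random_detected(4, c("s1", "s2"), p = 1)
  pm <- make_pm(det,
                protein_names = c("Serum albumin", "Glia-derived nexin",
                                  "Keratin, type II cytoskeletal 1",
                                  "Complement C3"),
                genes = c("ALB", "SERPINE2", "KRT1", "C3"))
  rules <- tibble::tibble(match_type = "name_substring", pattern = "albumin")
  res <- apply_blocklist(pm, rules)
  expect_equal(res$removed_accessions, "P001")
  expect_setequal(res$matrix$proteins$accession, c("P002", "P003", "P004"))

  # empty rule list is the identity
  none <- apply_blocklist(pm, tibble::tibble(match_type = character(),
                                             pattern = character()))
  expect_equal(none$removed_accessions, character())
  expect_equal(nrow(none$matrix$proteins), 4)

  # default blocklist hits all three families, leaves the nexin
  full <- apply_blocklist(pm, read_blocklist())
  expect_setequal(full$removed_accessions, c("P001", "P003", "P004"))
})

test_that("random matrices and rules: removal matches a brute-force rule scan", {
  set.seed(31)
  pool_names <- c("Hemoglobin subunit alpha", "Synaptic protein X",
                  "Apolipoprotein E", "Tubulin beta", "Haptoglobin",
                  "Neurofilament light")
  pool_genes <- c("HBA1", "SYNX", "APOE", "TUBB", "HP", "NEFL")
  for (rep in 1:20) {
    n <- 6
    pm <- make_pm(random_detected(n, c("a", "b")),
                  protein_names = sample(pool_names, n, replace = TRUE),
                  genes = sample(pool_genes, n, replace = TRUE))
    rules <- tibble::tibble(
      match_type = sample(c("gene_prefix", "name_substring", "accession_exact"),
                          3, replace = TRUE),
      pattern = sample(c("HB", "apolipo", "P003", "hapto", "NE"), 3))
    res <- apply_blocklist(pm, rules)
    expect_setequal(res$removed_accessions, oracle_blocked(pm$proteins, rules))
    expect_equal(sort(c(res$removed_accessions, res$matrix$proteins$accession)),
                 sort(pm$proteins$accession))
  }
})

test_that("the reported screen's counts select 16 AD candidates and none for PD", {
  pm <- reference_presence_matrix()
  design <- reference_design()
  ad <- select_candidates(pm, design, selection_criteria(), "AD")
  expect_equal(nrow(ad), 16)
  expect_true("SERPINE2" %in% ad$gene_symbol)
  expect_equal(ad$control_n_detected[ad$gene_symbol == "SERPINE2"], 0L)
  expect_equal(ad$AD_n_detected[ad$gene_symbol == "SERPINE2"], 8L)
  # exactly three candidates absent from every control
  expect_equal(sum(ad$control_n_detected == 0), 3)
  expect_setequal(ad$gene_symbol[ad$control_n_detected == 0],
                  c("SERPINE2", "FMOD", "NQO1"))
  # candidates ordered by descending patient detections
  expect_true(all(diff(ad$AD_n_detected) <= 0))

  pd <- select_candidates(pm, design, selection_criteria(), "PD")
  expect_equal(nrow(pd), 0)

  expect_error(select_candidates(pm, design, selection_criteria(), "control"),
               "control")
  expect_error(select_candidates(pm, design, selection_criteria(), "XX"),
               "unknown group")
})

test_that("selection equals brute-force enumeration on random matrices", {
  set.seed(17)
  design <- make_design(c(control = 5, AD = 6))
  ctrl <- group_samples(design, "control")
  pat <- group_samples(design, "AD")
  for (rep in 1:50) {
    pm <- make_pm(random_detected(20, design$samples$sample_id, p = 0.35))
    crit <- selection_criteria(max_control_detections = sample(0:2, 1),
                               min_patient_fraction = stats::runif(1, 0.2, 0.9))
    got <- select_candidates(pm, design, crit, "AD", detail = FALSE)
    min_count <- attr(got, "criteria_resolved")$min_patient_count
    expect_equal(min_count, ceiling(crit$min_patient_fraction * length(pat)))
    expect_setequal(got$accession,
                    oracle_select(pm$detected, ctrl, pat,
                                  crit$max_control_detections, min_count))
  }
})

test_that("relaxing either threshold never removes a candidate", {
  set.seed(23)
  design <- make_design(c(control = 6, AD = 6))
  for (rep in 1:10) {
    pm <- make_pm(random_detected(30, design$samples$sample_id, p = 0.4))
    base <- select_candidates(pm, design,
                              selection_criteria(1, 0.5), "AD", detail = FALSE)
    looser_ctrl <- select_candidates(pm, design,
                                     selection_criteria(2, 0.5), "AD",
                                     detail = FALSE)
    looser_pat <- select_candidates(pm, design,
                                    selection_criteria(1, 0.3), "AD",
                                    detail = FALSE)
    expect_true(all(base$accession %in% looser_ctrl$accession))
    expect_true(all(base$accession %in% looser_pat$accession))
  }
})

test_that("the fully relaxed rule selects exactly the proteins seen in any patient", {
  set.seed(29)
  design <- make_design(c(control = 4, AD = 5))
  pm <- make_pm(random_detected(25, design$samples$sample_id, p = 0.25))
  got <- select_candidates(pm, design,
                           selection_criteria(max_control_detections = 4,
                                              min_patient_count = 1),
                           "AD", detail = FALSE)
  pat <- group_samples(design, "AD")
  expect_setequal(got$accession,
                  rownames(pm$detected)[rowSums(pm$detected[, pat]) >= 1])
})

test_that("overlap handles identical groups, reported totals, and random set algebra", {
  # three single-sample groups sharing the same five proteins
  design <- make_design(c(g1 = 1, g2 = 1, g3 = 1))
  det <- matrix(TRUE, 5, 3,
                dimnames = list(sprintf("P%03d", 1:5),
                                design$samples$sample_id))
  ov <- compute_overlap(make_pm(det), design)
  expect_equal(ov$regions[["g1&g2&g3"]], 5L)
  expect_equal(ov$percent_common, 100L)
  expect_equal(ov$grand_total, 5L)

  # reported marginals: 1854 total, 1042 common -> 56%
  ref <- compute_overlap(reference_overlap_matrix(), reference_design())
  expect_equal(ref$grand_total, 1854L)
  expect_equal(ref$n_common, 1042L)
  expect_equal(ref$percent_common, 56L)
  expect_equal(unlist(ref$group_totals),
               c(control = 1342L, AD = 1562L, PD = 1281L))
  expect_equal(ref$regions[["control"]], 137L)
  expect_equal(ref$regions[["AD"]], 299L)
  expect_equal(ref$regions[["PD"]], 129L)
  # regions sum to the grand total; group totals are region sums
  expect_equal(sum(unlist(ref$regions)), ref$grand_total)
  for (g in reference_design()$group_labels) {
    in_g <- vapply(names(ref$regions),
                   function(r) g %in% strsplit(r, "&", fixed = TRUE)[[1]],
                   logical(1))
    expect_equal(sum(unlist(ref$regions[in_g])), ref$group_totals[[g]])
  }

  expect_error(compute_overlap(make_pm(det), make_design(c(solo = 2))),
               "two groups")

  # random studies vs brute-force set algebra
  set.seed(47)
  design3 <- make_design(c(control = 2, AD = 2, PD = 2))
  for (rep in 1:10) {
    pm <- make_pm(random_detected(40, design3$samples$sample_id, p = 0.3))
    ov <- compute_overlap(pm, design3)
    sets <- lapply(design3$group_labels, function(g) {
      s <- group_samples(design3, g)
      rownames(pm$detected)[rowSums(pm$detected[, s, drop = FALSE]) > 0]
    })
    names(sets) <- design3$group_labels
    expect_equal(lapply(ov$regions, as.integer), oracle_regions(sets),
                 ignore_attr = TRUE)
  }
})

test_that("positive-control QC passes only when the spike is everywhere at depth", {
  st <- reference_study()
  pm <- build_presence_matrix(merge_replicates(st$table), st$design)
  qc <- check_positive_control(pm, "KLK6", min_peptides = 1)
  expect_true(qc$pass)
  counts <- unlist(qc$n_peptides)
  expect_true(all(counts >= 9 & counts <= 13))

  # a sample missing the spike fails and is flagged
  pm2 <- pm
  miss <- which(pm2$samples == "PD_10")
  acc <- qc$accession_matched
  pm2$detected[acc, miss] <- FALSE
  pm2$n_peptides[acc, miss] <- 0
  qc2 <- check_positive_control(pm2, "KLK6")
  expect_false(qc2$pass)
  expect_false(qc2$detected[[miss]])

  # unreachable peptide depth fails; absent protein fails with all-false flags
  expect_false(check_positive_control(pm, "KLK6", min_peptides = 14)$pass)
  ghost <- check_positive_control(pm, "NOSUCH")
  expect_false(ghost$pass)
  expect_true(all(!unlist(ghost$detected)))
})
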