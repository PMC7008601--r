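# Manifests, identification dialects, blocklists and report writers.

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a three-group manifest parses into a study design with typed missing demographics", {
  header <- "sample_id\tgroup\treplicates\tsex\tage\tmmse"
  rows <- c(
    sprintf("C%02d\tcontrol\trep1;rep2\tF\t4%d\t28", 1:10, 1:10 %% 10),
    sprintf("A%02d\tAD\trep1;rep2\tM\t7%d\t", 1:10, 1:10 %% 10),
    sprintf("P%02d\tPD\trep1;rep2\t\t\t22", 1:10)
  )
  design <- read_manifest(write_lines_tmp(c(header, rows)))
  expect_s3_class(design, "study_design")
  expect_equal(as.vector(table(factor(design$samples$group,
                                      levels = c("control", "AD", "PD")))),
               c(10, 10, 10))
  expect_equal(design$control_group, "control")
  expect_equal(design$samples$replicate_ids[[1]], c("rep1", "rep2"))
  # blanks are NA, never zero
  expect_true(all(is.na(design$samples$mmse[design$samples$group == "AD"])))
  expect_true(all(is.na(design$samples$sex[design$samples$group == "PD"])))
  expect_false(any(design$samples$age %in% 0))
})

test_that("manifest edge cases: one row, duplicates, unknown columns, empty file", {
  one <- read_manifest(write_lines_tmp(c("sample_id\tgroup", "s1\tg1")))
  expect_equal(nrow(one$samples), 1)
  expect_true(all(is.na(one$samples[c("sex", "age", "mmse", "hy", "frssd")])))

  dup <- write_lines_tmp(c("sample_id\tgroup", "s1\tg1", "s2\tg1", "s1\tg1"))
  expect_error(read_manifest(dup), "s1")

  unk <- write_lines_tmp(c("sample_id\tgroup\tshoe_size", "s1\tg1\t42"))
  expect_warning(d <- read_manifest(unk), "shoe_size")
  expect_false("shoe_size" %in% names(d$samples))

  expect_error(read_manifest(write_lines_tmp("sample_id\tgroup")), "empty")
})

test_that("wide presence cells normalize to one record per I mark", {
  wide <- write_lines_tmp(c(
    "protein_accession\tprotein_name\ts1\ts2\ts3",
    "P1\tProtein one\tI\t\tI",
    "P2\tProtein two\tI\tI\t"
  ))
  tab <- read_identifications(wide, "wide_presence")
  expect_equal(nrow(tab), 4)
  expect_true(all(!tab$peptide_detail))
  expect_setequal(tab$sample_id[tab$accession == "P1"], c("s1", "s3"))

  bad <- write_lines_tmp(c(
    "protein_accession\ts1\ts2",
    "P1\tI\tyes"
  ))
  expect_error(read_identifications(bad, "wide_presence"),
               "row 1.*column 's2'")
})

test_that("long TSV reads q-values and errors on missing required columns", {
  long <- write_lines_tmp(c(
    "sample_id\treplicate_id\tprotein_accession\tprotein_name\tpeptide_sequence\tq_value",
    "s1\trep1\tP1\tProtein one\tACDEFGK\t0.003",
    "s1\trep1\tP1\tProtein one\tMKLVNR\t"
  ))
  tab <- read_identifications(long, "long_tsv")
  expect_equal(tab$q_value, c(0.003, NA))
  expect_true(all(tab$peptide_detail))

  nocol <- write_lines_tmp(c("sample_id\tprotein_accession", "s1\tP1"))
  expect_error(read_identifications(nocol, "long_tsv"),
               "replicate_id")
})

test_that("write-read round-trips are the identity on record multisets in both dialects", {
  study <- generate_study(simulation_config(
    group_sizes = c(control = 2, AD = 2), n_background = 8, n_enriched = 3,
    n_contaminant = 2, replicates_per_sample = 2, seed = 11))
  tab <- study$table

  key <- function(t) sort(paste(t$sample_id, t$replicate_id, t$accession,
                                t$peptide, t$q_value))
  long_path <- withr::local_tempfile(fileext = ".tsv")
  write_identifications(tab, long_path, "long_tsv")
  expect_equal(key(read_identifications(long_path, "long_tsv")), key(tab))

  # wide dialect carries no q-values; compare the presence multiset
  key2 <- function(t) sort(paste(t$sample_id, t$replicate_id, t$accession, t$peptide))
  wide_path <- withr::local_tempfile(fileext = ".tsv")
  write_identifications(tab, wide_path, "wide_presence")
  expect_equal(key2(read_identifications(wide_path, "wide_presence")), key2(tab))
})

test_that("the two dialects yield identical detection matrices when peptide detail is suppressed", {
  study <- generate_study(simulation_config(
    group_sizes = c(control = 3, AD = 3), n_background = 10, n_enriched = 2,
    n_contaminant = 0, replicates_per_sample = 1, seed = 5))
  merged <- merge_replicates(study$table)
  long_path <- withr::local_tempfile(fileext = ".tsv")
  wide_path <- withr::local_tempfile(fileext = ".tsv")
  write_identifications(merged, long_path, "long_tsv")
  write_identifications(merged, wide_path, "wide_presence", peptide_level = FALSE)
  pm_long <- build_presence_matrix(
    merge_replicates(read_identifications(long_path, "long_tsv")), study$design)
  pm_wide <- build_presence_matrix(
    read_identifications(wide_path, "wide_presence"), study$design)
  expect_identical(pm_long$detected, pm_wide$detected)
  # protein-level wide reading must not fabricate peptide counts
  expect_true(all(is.na(pm_wide$n_peptides[pm_wide$detected])))
})

test_that("blocklist parsing covers the eight serum families and tolerates comments", {
  rules <- read_blocklist()
  families <- c("hemoglobin", "haptoglobin", "hemopexin", "immunoglobulin",
                "keratin", "apolipoprotein", "albumin", "complement")
  expect_true(all(families %in%
                    rules$pattern[rules$match_type == "name_substring"]))
  expect_gte(length(unique(rules$pattern)), 8)

  expect_equal(nrow(read_blocklist(write_lines_tmp(character()))), 0)
  expect_equal(nrow(read_blocklist(write_lines_tmp(c("# just", "# comments")))), 0)
  expect_error(read_blocklist(write_lines_tmp(c("# ok", "regex\tALB"))),
               "line 2")
})

test_that("candidate TSV reproduces reported rows and JSON summaries round-trip", {
  st <- reference_study()
  pm <- build_presence_matrix(merge_replicates(st$table), st$design)
  report <- candidate_report(pm, st$design, selection_criteria())
  overlap <- compute_overlap(reference_overlap_matrix(), reference_design())
  qc <- check_positive_control(pm)
  outdir <- withr::local_tempdir()
  paths <- write_reports(report, overlap, qc, outdir)

  ad <- readr::read_tsv(paths[["candidates_AD"]], show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  serpine2 <- ad[ad$gene_symbol == "SERPINE2", ]
  expect_equal(nrow(serpine2), 1)
  expect_equal(serpine2$control_n_detected, "0")
  expect_equal(serpine2$control_total_unique, "0")
  expect_equal(serpine2$control_mean_unique, "0.0")
  expect_equal(serpine2$AD_n_detected, "8")
  expect_equal(serpine2$AD_mean_unique, "2.3")

  # empty candidate set: header only
  strict <- candidate_report(pm, st$design,
                             selection_criteria(max_control_detections = 0,
                                                min_patient_count = 10))
  paths2 <- write_reports(strict, NULL, NULL, withr::local_tempdir())
  pd <- readr::read_tsv(paths2[["candidates_PD"]], show_col_types = FALSE)
  expect_equal(nrow(pd), 0)
  expect_true("protein_name" %in% names(pd))

  # JSON re-parse equals the in-memory overlap summary
  parsed <- jsonlite::fromJSON(paths[["overlap"]], simplifyVector = FALSE)
  expect_equal(parsed$regions, lapply(overlap$regions, as.integer),
               ignore_attr = TRUE)
  expect_equal(parsed$grand_total, overlap$grand_total)
  expect_equal(parsed$percent_common, overlap$percent_common)
  expect_equal(unlist(parsed$group_totals), unlist(overlap$group_totals))
})
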