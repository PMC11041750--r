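test_that("clone-size sampling respects the expanded-cell budget and law", {
  cfg0 <- small_sim_config(1, expanded_cell_fraction = 0)
  set.seed(1)
  sizes0 <- sample_clone_sizes(cfg0)
  expect_true(all(unlist(sizes0) == 1))
  expect_equal(vapply(sizes0, sum, numeric(1)),
               c(PBMC = 300, plaque = 300))

  # geometric(p) conditioned on size >= 2 has closed-form mean
  # E[X | X >= 2] = 2 + (1 - p)/p by memorylessness: 3 for p = 0.5
  p <- 0.5
  cfg <- simulation_config(n_patients = 1, cells_per_tissue = 10000,
                           expanded_cell_fraction = 0.3, geom_p = p,
                           seed = 2)
  set.seed(2)
  sizes <- sample_clone_sizes(cfg)[["PBMC"]]
  budget <- 3000
  law_part <- sizes[seq_len(which(cumsum(sizes) == budget)[1])]
  expect_equal(sum(law_part), budget)
  expect_true(all(law_part[-length(law_part)] >= 2))  # only the trim may be 1
  se <- stats::sd(law_part) / sqrt(length(law_part))
  expect_lt(abs(mean(law_part) - (2 + (1 - p) / p)), 3 * se + 0.05)
  expect_equal(sum(sizes), 10000)

  expect_error(simulation_config(geom_p = 1, expanded_cell_fraction = 0.3,
                                 seed = 1), "size-1")
})

test_that("repertoire generation is deterministic under the seed", {
  s1 <- generate_paired_repertoire(small_sim_config(33))
  s2 <- generate_paired_repertoire(small_sim_config(33))
  expect_identical(s1$contigs, s2$contigs)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$ground_truth, s2$ground_truth)
  s3 <- generate_paired_repertoire(small_sim_config(34))
  expect_false(identical(s1$contigs, s3$contigs))
})

test_that("generator conserves cell totals and matches its own ground truth", {
  cfg <- small_sim_config(17)
  sim <- generate_paired_repertoire(cfg)
  expect_equal(nrow(sim$cells), cfg$n_patients * 2 * cfg$cells_per_tissue)
  tab <- table(sim$cells$patient, sim$cells$tissue)
  expect_true(all(tab == cfg$cells_per_tissue))
  # ground-truth clone sizes equal observed per-tissue cell counts
  obs <- stats::aggregate(
    list(n = sim$cells$barcode),
    by = list(patient = sim$cells$patient, clone_id = sim$cells$clone_id,
              tissue = sim$cells$tissue), FUN = length)
  gt <- sim$ground_truth
  for (lbl in c("PBMC", "plaque")) {
    o <- obs[obs$tissue == lbl, ]
    idx <- match(paste(gt$patient, gt$clone_id),
                 paste(o$patient, o$clone_id))
    got <- ifelse(is.na(idx), 0L, o$n[idx])
    want <- if (lbl == "PBMC") gt$size_pbmc else gt$size_tissue
    expect_equal(got, want)
  }
  # clone members share identical chain sets: one clonotype per clone
  fr <- build_clonotypes(
    sim$contigs, sim$cells[c("barcode", "patient", "tissue", "cluster")])
  by_clone <- split(fr$clonotype, sim$cells$clone_id[
    match(fr$barcode, sim$cells$barcode)])
  expect_true(all(vapply(by_clone,
                         function(x) length(unique(x)) == 1, logical(1))))
})

test_that("hyperexpanded spike lands above 10% in blood and in Large in plaque", {
  cfg <- small_sim_config(5, cells_per_tissue = 400,
                          hyperexpanded_spike = TRUE)
  sim <- generate_paired_repertoire(cfg)
  spike <- sim$ground_truth[sim$ground_truth$spike, ]
  expect_equal(nrow(spike), 1)
  fr <- build_clonotypes(
    sim$contigs, sim$cells[c("barcode", "patient", "tissue", "cluster")])
  led <- compute_abundance(fr)
  row <- led[led$patient == spike$patient &
               led$clonotype == spike$clonotype, ]
  expect_equal(row$expansion_class_pbmc, "Hyperexpanded")
  expect_equal(row$expansion_class_tissue, "Large")
})

test_that("expression matrices plant exactly the intended QC violations", {
  cfg <- small_sim_config(8, qc_violation_rates = c(gene_count = 0,
                                                    flagged_gene = 0))
  sim <- generate_paired_repertoire(cfg)
  expr <- generate_expression_matrices(cfg, sim$cells)
  res <- qc_filter(expr$counts)
  expect_equal(length(res$passed), nrow(sim$cells))

  rate <- 0.05
  cfg2 <- small_sim_config(9, qc_violation_rates = c(gene_count = rate,
                                                     flagged_gene = 0))
  sim2 <- generate_paired_repertoire(cfg2)
  expr2 <- generate_expression_matrices(cfg2, sim2$cells)
  res2 <- qc_filter(expr2$counts)
  n <- nrow(sim2$cells)
  fail_frac <- 1 - length(res2$passed) / n
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(fail_frac - rate), 3 * se)
  # every failing cell is a planted violator and vice versa
  planted <- expr2$cell_flags$barcode[expr2$cell_flags$qc_violation != "none"]
  expect_setequal(setdiff(sim2$cells$barcode, res2$passed), planted)

  cfg3 <- small_sim_config(10, n_genes = 4000)
  sim3 <- generate_paired_repertoire(cfg3)
  expect_error(generate_expression_matrices(cfg3, sim3$cells),
               "max-gene")
})

test_that("flagged-gene violators breach exactly the flagged-gene rule", {
  cfg <- small_sim_config(12, qc_violation_rates = c(gene_count = 0,
                                                     flagged_gene = 0.1))
  sim <- generate_paired_repertoire(cfg)
  expr <- generate_expression_matrices(cfg, sim$cells)
  res <- qc_filter(expr$counts)
  flags <- expr$cell_flags
  failed <- setdiff(flags$barcode, res$passed)
  expect_setequal(failed,
                  flags$barcode[flags$qc_violation == "flagged_gene"])
  reasons <- res$report$failure_reasons[!res$report$passed]
  expect_true(all(grepl("KCNQ1OT1|UGDH-AS1|GHET1", reasons)))
})

test_that("ADT profiles let the gates recover the true cell types", {
  cfg <- small_sim_config(13)
  sim <- generate_paired_repertoire(cfg)
  expr <- generate_expression_matrices(cfg, sim$cells)
  norm <- clr_normalize(expr$adt)
  lab <- gate_cd4_cd8(norm)
  truth <- sim$cells$true_type
  cd4_recovery <- mean(lab[sim$cells$barcode][truth == "CD4T"] == "CD4")
  cd8_recovery <- mean(lab[sim$cells$barcode][truth == "CD8T"] == "CD8")
  expect_gte(cd4_recovery, 0.95)
  expect_gte(cd8_recovery, 0.95)
  kept <- gate_t_cells(norm)
  myeloid <- sim$cells$barcode[truth == "myeloid"]
  expect_lt(mean(myeloid %in% kept), 0.05)
})

test_that("emitted datasets round-trip through the package readers", {
  cfg <- small_sim_config(14, cells_per_tissue = 80, n_patients = 1L)
  sim <- generate_paired_repertoire(cfg)
  expr <- generate_expression_matrices(cfg, sim$cells)
  dir <- tempfile()
  emit_dataset(sim, expr, dir)
  expect_error(emit_dataset(sim, expr, dir), "not empty")
  expect_silent(emit_dataset(sim, expr, dir, overwrite = TRUE))

  files <- list.files(dir)
  expect_true(all(c("contigs_P1_PBMC.csv", "contigs_P1_plaque.csv",
                    "matrix.mtx", "features.tsv", "barcodes.tsv",
                    "adt.csv", "cells.csv", "ground_truth.csv",
                    "config.json") %in% files))
  contigs_back <- rbind(
    read_contigs(file.path(dir, "contigs_P1_PBMC.csv")),
    read_contigs(file.path(dir, "contigs_P1_plaque.csv")))
  meta <- sim$cells[c("barcode", "patient", "tissue", "cluster")]
  fr_mem <- build_clonotypes(sim$contigs, meta)
  fr_disk <- build_clonotypes(contigs_back, meta)
  expect_equal(fr_disk[order(fr_disk$barcode), ],
               fr_mem[order(fr_mem$barcode), ], ignore_attr = TRUE)
  counts_back <- read_count_matrix(file.path(dir, "matrix.mtx"),
                                   file.path(dir, "features.tsv"),
                                   file.path(dir, "barcodes.tsv"))
  expect_equal(as.matrix(counts_back[rownames(expr$counts),
                                     colnames(expr$counts)]),
               as.matrix(expr$counts))
  gt_back <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(gt_back), nrow(sim$ground_truth))
  expect_equal(sum(gt_back$size_pbmc) + sum(gt_back$size_tissue),
               nrow(sim$cells))
})
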