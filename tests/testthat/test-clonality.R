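test_that("clonotype keys are canonical over chain order and multiplicity", {
  chains <- data.frame(
    barcode = c("c1", "c1", "c2", "c2", "c3", "c3", "c3", "c4", "c5"),
    chain = c("TRA", "TRB", "TRB", "TRA", "TRA", "TRA", "TRB", "TRB", "TRB"),
    cdr3 = c("CAVR", "CASS", "CASS", "CAVR", "CAVR", "CAAA", "CASS",
             "CASS", "CASS"),
    productive = TRUE, stringsAsFactors = FALSE)
  meta <- data.frame(barcode = paste0("c", 1:5), patient = "P1",
                     tissue = "PBMC", stringsAsFactors = FALSE)
  fr <- build_clonotypes(chains, meta)
  expect_equal(fr$clonotype[fr$barcode == "c1"], "CAVR|CASS")
  # opposite row order gives the same key
  expect_equal(fr$clonotype[fr$barcode == "c2"], "CAVR|CASS")
  # two TRAs: sorted multiset
  expect_equal(fr$clonotype[fr$barcode == "c3"], "CAAA;CAVR|CASS")
  # beta-only cell
  expect_equal(fr$clonotype[fr$barcode == "c4"], "NA|CASS")
  fr2 <- build_clonotypes(chains, meta, require_both_chains = TRUE)
  expect_true(is.na(fr2$clonotype[fr2$barcode == "c4"]))
  expect_equal(fr2$clonotype[fr2$barcode == "c1"], "CAVR|CASS")
})

test_that("non-productive chains and unknown barcodes are handled by policy", {
  chains <- data.frame(
    barcode = c("c1", "c1", "ghost"),
    chain = c("TRB", "TRA", "TRB"),
    cdr3 = c("CASS", "CA*VR", "CXXX"),
    productive = c(TRUE, FALSE, TRUE), stringsAsFactors = FALSE)
  meta <- data.frame(barcode = c("c1", "c9"), patient = "P1",
                     tissue = "PBMC", stringsAsFactors = FALSE)
  expect_warning(fr <- build_clonotypes(chains, meta), "dropped")
  expect_equal(fr$clonotype[fr$barcode == "c1"], "NA|CASS")
  expect_true(is.na(fr$clonotype[fr$barcode == "c9"]))  # no TCR detected
  fr2 <- suppressWarnings(
    build_clonotypes(chains, meta, productive_only = FALSE))
  expect_equal(fr2$clonotype[fr2$barcode == "c1"], "CA*VR|CASS")
})

test_that("expansion classification honours bins and Single precedence", {
  th <- expansion_thresholds()
  expect_equal(classify_expansion(1, 10, th), "Single")   # 10% but one cell
  expect_equal(classify_expansion(2, 10000, th), "Small")  # 0.02%
  expect_equal(classify_expansion(10, 10000, th), "Small") # 0.1% boundary
  expect_equal(classify_expansion(11, 10000, th), "Medium")
  expect_equal(classify_expansion(100, 10000, th), "Medium") # 1% boundary
  expect_equal(classify_expansion(101, 10000, th), "Large")
  expect_equal(classify_expansion(1000, 10000, th), "Large") # 10% boundary
  expect_equal(classify_expansion(1500, 10000, th), "Hyperexpanded")
  expect_error(classify_expansion(0, 100, th), "count")
  expect_error(classify_expansion(11, 10, th), "exceeds")
})

test_that("expansion classes match the brute-force oracle on random repertoires", {
  set.seed(42)
  for (rep in seq_len(1000)) {
    n_cells <- sample(1:200, 1)
    n_clones <- sample(1:n_cells, 1)
    cells <- sample(paste0("cl", seq_len(n_clones)), n_cells, replace = TRUE)
    want <- oracle_classify_repertoire(cells)
    tab <- table(cells)
    got <- classify_expansion(as.integer(tab), length(cells))
    expect_equal(unname(got), unname(want[names(tab)]))
  }
})

test_that("expansion class rank is monotone in count at fixed denominator", {
  th <- expansion_thresholds()
  ranks <- stats::setNames(seq_along(expansion_levels()), expansion_levels())
  den <- 4000
  cls <- classify_expansion(2:den, den, th)
  expect_true(all(diff(ranks[cls]) >= 0))
})

test_that("abundance ledger: counts, frequencies and conservation", {
  fr <- toy_frame()
  led <- compute_abundance(fr)
  # clone A: 2 of 5 PBMC cells, 1 of 5 plaque cells
  a <- led[led$clonotype == "A", ]
  expect_equal(a$count_pbmc, 2)
  expect_equal(a$count_tissue, 1)
  expect_equal(a$freq_pbmc, 40)
  expect_equal(a$freq_tissue, 20)
  expect_equal(a$expansion_class_tissue, "Single")
  # frequencies sum to 100% per tissue
  expect_equal(sum(led$freq_pbmc[led$count_pbmc > 0]), 100)
  expect_equal(sum(led$freq_tissue[led$count_tissue > 0]), 100)
  # absent side labelled Absent
  expect_equal(led$expansion_class_pbmc[led$clonotype == "F"], "Absent")
  # permutation invariance over rows
  led2 <- compute_abundance(fr[sample(nrow(fr)), ])
  expect_equal(led2, led)
})

test_that("a clone can be Hyperexpanded in blood and Large in plaque", {
  n_b <- 100; n_t <- 100
  fr <- data.frame(
    barcode = sprintf("b%03d", seq_len(n_b + n_t)),
    patient = "P1",
    tissue = rep(c("PBMC", "plaque"), c(n_b, n_t)),
    cluster = NA, subset = "all",
    clonotype = c(rep("HOT", 12), paste0("u", 1:88),
                  rep("HOT", 5), paste0("v", 1:95)),
    stringsAsFactors = FALSE)
  led <- compute_abundance(fr)
  hot <- led[led$clonotype == "HOT", ]
  expect_equal(hot$expansion_class_pbmc, "Hyperexpanded")  # 12%
  expect_equal(hot$expansion_class_tissue, "Large")        # 5%
})

test_that("enrichment scoring covers all rule branches", {
  led <- data.frame(
    patient = "P1",
    clonotype = c("tisOnly", "single", "balanced", "tisUp", "bldUp",
                  "tisSingleSide"),
    scope = "all",
    count_pbmc = c(0L, 1L, 5L, 2L, 8L, 0L),
    count_tissue = c(5L, 0L, 5L, 8L, 2L, 1L),
    freq_pbmc = c(0, 0.1, 0.5, 0.2, 0.8, 0),
    freq_tissue = c(0.5, 0, 0.5, 0.8, 0.2, 0.1),
    expansion_class_pbmc = "x", expansion_class_tissue = "x",
    stringsAsFactors = FALSE)
  got <- score_enrichment(led, enrichment_params())
  expect_equal(got$enrichment_class,
               c("TissueEnriched",  # absent in blood, >= 2 tissue cells
                 "Single",          # one occurrence across both tissues
                 "Unenriched",      # identical frequencies
                 "TissueEnriched",  # 4-fold higher in tissue
                 "PBMCEnriched",    # mirrored
                 "Single"))         # one cell total, tissue side
  bad <- led[1, ]; bad$count_pbmc <- 0L; bad$count_tissue <- 0L
  expect_error(score_enrichment(bad), "neither tissue")
})

test_that("enrichment is antisymmetric under swapping the tissue labels", {
  set.seed(9)
  for (rep in 1:20) {
    n <- 120
    fr <- data.frame(
      barcode = sprintf("b%03d", 1:n), patient = "P1",
      tissue = sample(c("PBMC", "plaque"), n, replace = TRUE),
      cluster = NA, subset = "all",
      clonotype = sample(paste0("cl", 1:40), n, replace = TRUE),
      stringsAsFactors = FALSE)
    led <- score_enrichment(compute_abundance(fr))
    sw <- fr
    sw$tissue <- ifelse(fr$tissue == "PBMC", "plaque", "PBMC")
    led_sw <- score_enrichment(compute_abundance(sw))
    idx <- match(led$clonotype, led_sw$clonotype)
    mapped <- c(TissueEnriched = "PBMCEnriched",
                PBMCEnriched = "TissueEnriched",
                Unenriched = "Unenriched", Single = "Single")
    expect_equal(unname(mapped[led$enrichment_class]),
                 led_sw$enrichment_class[idx])
  }
})

test_that("cell-weighted quantification sums to one and matches hand counts", {
  fr <- toy_frame()
  led <- score_enrichment(compute_abundance(fr))
  q <- quantify_by_group(fr, led, group_by = "tissue")
  exp_pbmc <- q[q$tissue == "PBMC" & q$class_type == "expansion", ]
  # PBMC: clone A has 2 cells; B, C, D one each
  expect_equal(exp_pbmc$proportion[exp_pbmc$class == "Single"], 0.6)
  agg <- stats::aggregate(proportion ~ tissue + class_type, q, sum)
  expect_true(all(abs(agg$proportion - 1) < 1e-9))
  expect_error(quantify_by_group(fr, led, group_by = "flavour"), "group_by")
})

test_that("all-singleton repertoires quantify as 100% Single everywhere", {
  n <- 50
  fr <- data.frame(barcode = sprintf("b%02d", 1:n), patient = "P1",
                   tissue = rep(c("PBMC", "plaque"), each = n / 2),
                   cluster = NA, subset = "all",
                   clonotype = paste0("u", 1:n), stringsAsFactors = FALSE)
  led <- compute_abundance(fr)
  expect_true(all(led$freq_pbmc[led$count_pbmc > 0] == 100 / (n / 2)))
  q <- quantify_by_group(fr, led, group_by = "tissue")
  qe <- q[q$class_type == "expansion", ]
  expect_equal(qe$class, c("Single", "Single"))
  expect_equal(qe$proportion, c(1, 1))
})

test_that("cluster overlap intersects clonotype sets with deterministic order", {
  fr <- toy_frame()
  # C1 clonotypes: {A, D, E}; C2: {B, C, A, E, F}
  ov <- cluster_overlap(fr, "C1", "C2")
  expect_setequal(ov$clonotype, c("A", "E"))
  # A and E tie at 3 combined cells; lexicographic tie-break puts A first
  expect_equal(ov$clonotype, c("A", "E"))
  expect_equal(ov$count_total, c(3L, 3L))
  expect_true(all(diff(ov$count_total) <= 0))
  disjoint <- fr
  disjoint$cluster <- ifelse(disjoint$clonotype %in% c("A", "B"),
                             "X", "Y")
  expect_equal(nrow(cluster_overlap(disjoint, "X", "Y")), 0)
  expect_error(cluster_overlap(fr, "C1", "nope"), "unknown cluster")
})

test_that("annotation matching is exact and locus-aware", {
  fr <- data.frame(clonotype = c("CAVSDNYQLIW|CASSF", "NA|CAVSDNYQLIW"),
                   stringsAsFactors = FALSE)
  db <- data.frame(chain_locus = "TRA", cdr3_aa = "CAVSDNYQLIW",
                   antigen_species = "CMV", antigen_epitope = "NLVPMVATV",
                   source = "VDJdb", stringsAsFactors = FALSE)
  hits <- match_annotations(fr, db)
  # only the clonotype carrying the sequence on TRA matches
  expect_equal(nrow(hits), 1)
  expect_equal(hits$clonotype, "CAVSDNYQLIW|CASSF")
  expect_equal(hits$antigen_species, "CMV")
  empty <- match_annotations(fr, db[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("bulk clone tables classify with template counts and aggregate duplicates", {
  clones <- data.frame(
    cdr3b_aa = c("CASSA", "CASSB", "CASSB", rep("CASSC", 1),
                 "CASSA", "CASSD"),
    templates = c(150L, 10L, 5L, 1L, 30L, 834L),
    sample_id = "s", stringsAsFactors = FALSE,
    tissue = c("PBMC", "PBMC", "PBMC", "PBMC", "plaque", "plaque"),
    patient = "P1")
  led <- bulk_classify(clones)
  # PBMC total = 166 templates; plaque total = 864
  a <- led[led$clonotype == "CASSA", ]
  expect_equal(a$count_pbmc, 150)
  expect_equal(a$expansion_class_pbmc, "Hyperexpanded")  # 90%
  b <- led[led$clonotype == "CASSB", ]
  expect_equal(b$count_pbmc, 15)  # duplicate rows summed, classified once
  c3 <- led[led$clonotype == "CASSC", ]
  expect_equal(c3$expansion_class_pbmc, "Single")  # 1 template among 166
  expect_equal(c3$enrichment_class, "Single")
  expect_equal(a$enrichment_class, "PBMCEnriched")
})

test_that("scoped runs partition gated cells and rescale frequencies", {
  fr <- toy_frame()
  fr$subset <- c("CD4", "CD4", "CD8", "CD4", "CD8",
                 "CD4", "CD8", "CD4", "CD4", "double_positive")
  led_all <- compute_abundance(fr)
  led_cd4 <- compute_abundance(fr, scope = "CD4")
  led_cd8 <- compute_abundance(fr, scope = "CD8")
  n_all <- sum(led_all$count_pbmc + led_all$count_tissue)
  n_cd4 <- sum(led_cd4$count_pbmc + led_cd4$count_tissue)
  n_cd8 <- sum(led_cd8$count_pbmc + led_cd8$count_tissue)
  expect_equal(n_cd4 + n_cd8,
               n_all - sum(fr$subset == "double_positive"))
  # clone A is all-CD4: scoped frequency >= unscoped frequency
  expect_true(led_cd4$freq_pbmc[led_cd4$clonotype == "A"] >=
                led_all$freq_pbmc[led_all$clonotype == "A"])
  expect_equal(led_cd4$scope, rep("CD4", nrow(led_cd4)))
})
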