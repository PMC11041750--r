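#' Expansion-level thresholds
#'
#' Percentage bin edges for the five clonal expansion levels, applied to a
#' clone's frequency among the TCR-bearing cells of one tissue of one
#' patient: Single (exactly one occurrence, regardless of frequency), Small
#' (<= `small_max_pct`), Medium (> `small_max_pct` and <= `medium_max_pct`),
#' Large (> `medium_max_pct` and <= `large_max_pct`), Hyperexpanded
#' (> `large_max_pct`).
#'
#' @param small_max_pct,medium_max_pct,large_max_pct Upper bin edges in
#'   percent (inclusive); defaults 0.1, 1 and 10.
#' @return A list of class `expansion_thresholds`.
#' @export
expansion_thresholds <- function(small_max_pct = 0.1, medium_max_pct = 1,
                                 large_max_pct = 10) {
  stopifnot(0 < small_max_pct, small_max_pct < medium_max_pct,
            medium_max_pct < large_max_pct, large_max_pct < 100)
  structure(list(small_max_pct = small_max_pct,
                 medium_max_pct = medium_max_pct,
                 large_max_pct = large_max_pct),
            class = "expansion_thresholds")
}

#' Tissue-enrichment scoring parameters
#'
#' Operational definition of "frequency higher in one tissue versus the
#' other" for a clone observed in matched tissues of one patient: the clone
#' is enriched in a tissue when its frequency there is at least
#' `fold_threshold` times its frequency in the other tissue. When the clone
#' is absent from the other tissue (frequency 0), it qualifies as enriched
#' when it has at least `min_cells_expanded` cells in the tissue where it is
#' seen. These defaults are package conventions and every run should record
#' the values used; see the methods vignette.
#'
#' @param fold_threshold Frequency ratio (>= 1) required to call enrichment.
#' @param min_cells_expanded Minimum cell count for one-tissue-only clones.
#' @return A list of class `enrichment_params`.
#' @export
enrichment_params <- function(fold_threshold = 2, min_cells_expanded = 2L) {
  stopifnot(fold_threshold >= 1, min_cells_expanded >= 1)
  structure(list(fold_threshold = fold_threshold,
                 min_cells_expanded = as.integer(min_cells_expanded)),
            class = "enrichment_params")
}

# Canonical clonotype key: sorted unique TRA CDR3s ";"-joined, "|", sorted
# unique TRB CDR3s; an empty side renders as "NA".
make_clonotype_key <- function(tra, trb) {
  side <- function(x) {
    x <- sort(unique(x[!is.na(x) & x != ""]))
    if (length(x) == 0) "NA" else paste(x, collapse = ";")
  }
  paste(side(tra), side(trb), sep = "|")
}

# Inverse of make_clonotype_key: data.frame of (chain_locus, cdr3_aa) per key
parse_clonotype_key <- function(key) {
  sides <- strsplit(key, "|", fixed = TRUE)
  do.call(rbind, lapply(seq_along(key), function(i) {
    tra <- setdiff(strsplit(sides[[i]][1], ";", fixed = TRUE)[[1]], "NA")
    trb <- setdiff(strsplit(sides[[i]][2], ";", fixed = TRUE)[[1]], "NA")
    if (length(tra) + length(trb) == 0) return(NULL)
    data.frame(clonotype = key[i],
               chain_locus = c(rep("TRA", length(tra)),
                               rep("TRB", length(trb))),
               cdr3_aa = c(tra, trb), stringsAsFactors = FALSE)
  }))
}

#' Build per-cell clonotype calls from chain contigs
#'
#' Defines clonotypes from TCR CDR3 amino-acid sequences: for each cell the
#' productive TRA and TRB CDR3 sequences are collected, deduplicated per
#' chain, sorted, and joined into a canonical key, so that two cells carrying
#' the same multiset of chain sequences receive equal keys regardless of
#' contig row order. Gamma/delta chains do not enter the alpha/beta key.
#'
#' @param chains Contig table as returned by [read_contigs()].
#' @param cell_meta `data.frame` with columns `barcode`, `patient`, `tissue`
#'   and optionally `cluster` and `subset`; one row per cell to retain.
#'   Cells without any contig keep a missing clonotype.
#' @param productive_only Use only productive contigs with a CDR3 call
#'   (default `TRUE`, the common repertoire-analysis convention).
#' @param require_both_chains When `TRUE`, cells lacking either a TRA or a
#'   TRB contribution get a missing clonotype instead of a one-sided key.
#' @return A repertoire `data.frame` with one row per cell in `cell_meta`:
#'   `barcode`, `patient`, `tissue`, `cluster`, `subset`, `clonotype`
#'   (`NA` when no qualifying TCR was detected).
#' @export
build_clonotypes <- function(chains, cell_meta, productive_only = TRUE,
                             require_both_chains = FALSE) {
  stopifnot(all(c("barcode", "patient", "tissue") %in% names(cell_meta)))
  if (anyDuplicated(cell_meta[c("patient", "tissue", "barcode")])) {
    stop("cell_meta contains duplicated (patient, tissue, barcode) rows")
  }
  keep <- !is.na(chains$cdr3) & chains$chain %in% c("TRA", "TRB")
  if (productive_only) keep <- keep & chains$productive
  chains <- chains[keep, , drop = FALSE]
  unknown <- setdiff(unique(chains$barcode), cell_meta$barcode)
  if (length(unknown) > 0) {
    warning(length(unknown),
            " contig barcode(s) absent from cell_meta were dropped")
    chains <- chains[chains$barcode %in% cell_meta$barcode, , drop = FALSE]
  }
  key_by_bc <- character(0)
  if (nrow(chains) > 0) {
    split_chain <- split(chains[c("chain", "cdr3")], chains$barcode)
    key_by_bc <- vapply(split_chain, function(d) {
      tra <- d$cdr3[d$chain == "TRA"]
      trb <- d$cdr3[d$chain == "TRB"]
      if (require_both_chains && (length(tra) == 0 || length(trb) == 0)) {
        return(NA_character_)
      }
      make_clonotype_key(tra, trb)
    }, character(1))
  }
  out <- data.frame(
    barcode = cell_meta$barcode,
    patient = as.character(cell_meta$patient),
    tissue = as.character(cell_meta$tissue),
    cluster = if ("cluster" %in% names(cell_meta))
      as.character(cell_meta$cluster) else NA_character_,
    subset = if ("subset" %in% names(cell_meta))
      as.character(cell_meta$subset) else "all",
    stringsAsFactors = FALSE
  )
  out$clonotype <- unname(key_by_bc[out$barcode])
  out
}

#' Classify a clone's expansion level
#'
#' Assigns one of Single, Small, Medium, Large or Hyperexpanded from a
#' clone's cell count and the total number of TCR-bearing cells in the same
#' tissue of the same patient. A count of exactly one is Single regardless
#' of the implied percentage (occurrence takes precedence over frequency in
#' small repertoires); otherwise the percentage `100 * count / denominator`
#' is binned by [expansion_thresholds()].
#'
#' @param count Integer vector of clone cell (or template) counts, all >= 1.
#' @param denominator Integer vector (recycled) of scoped repertoire sizes.
#' @param thresholds An [expansion_thresholds()] object.
#' @return Character vector of expansion classes.
#' @export
classify_expansion <- function(count, denominator,
                               thresholds = expansion_thresholds()) {
  stopifnot(inherits(thresholds, "expansion_thresholds"))
  count <- as.numeric(count)
  denominator <- rep_len(as.numeric(denominator), length(count))
  if (any(count < 1)) {
    stop("classify_expansion requires count >= 1; absent clones are ",
         "labelled by the ledger, not here")
  }
  if (any(count > denominator)) {
    stop("clone count exceeds its denominator")
  }
  pct <- 100 * count / denominator
  out <- ifelse(count == 1, "Single",
         ifelse(pct <= thresholds$small_max_pct, "Small",
         ifelse(pct <= thresholds$medium_max_pct, "Medium",
         ifelse(pct <= thresholds$large_max_pct, "Large",
                "Hyperexpanded"))))
  out
}

#' Ordered factor levels for expansion classes
#' @export
expansion_levels <- function() {
  c("Single", "Small", "Medium", "Large", "Hyperexpanded")
}

#' Enrichment class labels
#' @export
enrichment_levels <- function() {
  c("Single", "Unenriched", "TissueEnriched", "PBMCEnriched")
}

#' Per-clonotype abundance ledger for matched tissues
#'
#' Counts cells per (patient, clonotype, tissue) and converts them to
#' frequencies: the percentage of cells expressing the clonotype among all
#' cells in which a TCR was detected in the same tissue of the same patient.
#' With a `CD4` or `CD8` scope, both numerator and denominator are
#' recomputed within the gated subset, so scoped frequencies are percentages
#' of all CD4+ (or CD8+) TCRs. Each tissue's count is classified with
#' [classify_expansion()]; a clone unobserved in one tissue is `Absent`
#' there.
#'
#' @param frame Repertoire `data.frame` from [build_clonotypes()].
#' @param scope `"all"`, `"CD4"` or `"CD8"`; non-`all` scopes filter on the
#'   frame's `subset` column before any counting.
#' @param thresholds An [expansion_thresholds()] object.
#' @param blood_label,tissue_label The two tissue labels of the matched
#'   design; `blood_label` plays the PBMC role in enrichment scoring.
#' @return A ledger `data.frame`, one row per (patient, clonotype):
#'   `patient`, `clonotype`, `scope`, `count_pbmc`, `count_tissue`,
#'   `freq_pbmc`, `freq_tissue` (percent), `expansion_class_pbmc`,
#'   `expansion_class_tissue`.
#' @export
compute_abundance <- function(frame, scope = c("all", "CD4", "CD8"),
                              thresholds = expansion_thresholds(),
                              blood_label = "PBMC", tissue_label = "plaque") {
  scope <- match.arg(scope)
  stopifnot(all(c("barcode", "patient", "tissue", "clonotype") %in%
                  names(frame)))
  if (scope != "all") frame <- frame[frame$subset %in% scope, , drop = FALSE]
  bad_tissue <- setdiff(unique(frame$tissue), c(blood_label, tissue_label))
  if (length(bad_tissue) > 0) {
    stop("unknown tissue label(s): ", paste(bad_tissue, collapse = ", "))
  }
  frame <- frame[!is.na(frame$clonotype), , drop = FALSE]
  if (nrow(frame) == 0) {
    warning("no TCR-bearing cells in scope ", scope)
    return(empty_ledger(scope))
  }
  denom <- stats::aggregate(list(n = frame$barcode),
                            by = list(patient = frame$patient,
                                      tissue = frame$tissue),
                            FUN = length)
  counts <- stats::aggregate(list(count = frame$barcode),
                             by = list(patient = frame$patient,
                                       clonotype = frame$clonotype,
                                       tissue = frame$tissue),
                             FUN = length)
  get_side <- function(lbl, col) {
    side <- counts[counts$tissue == lbl, c("patient", "clonotype", "count")]
    names(side)[3] <- col
    side
  }
  ledger <- merge(get_side(blood_label, "count_pbmc"),
                  get_side(tissue_label, "count_tissue"),
                  by = c("patient", "clonotype"), all = TRUE)
  ledger$count_pbmc[is.na(ledger$count_pbmc)] <- 0L
  ledger$count_tissue[is.na(ledger$count_tissue)] <- 0L
  denom_of <- function(patient, lbl) {
    idx <- match(paste(patient, lbl), paste(denom$patient, denom$tissue))
    d <- denom$n[idx]
    d[is.na(d)] <- 0L
    d
  }
  d_pbmc <- denom_of(ledger$patient, blood_label)
  d_tissue <- denom_of(ledger$patient, tissue_label)
  ledger$freq_pbmc <- ifelse(d_pbmc > 0, 100 * ledger$count_pbmc / d_pbmc, 0)
  ledger$freq_tissue <- ifelse(d_tissue > 0,
                               100 * ledger$count_tissue / d_tissue, 0)
  classify_side <- function(cnt, den) {
    out <- rep("Absent", length(cnt))
    pos <- cnt > 0
    out[pos] <- classify_expansion(cnt[pos], den[pos], thresholds)
    out
  }
  ledger$expansion_class_pbmc <- classify_side(ledger$count_pbmc, d_pbmc)
  ledger$expansion_class_tissue <- classify_side(ledger$count_tissue,
                                                 d_tissue)
  ledger$scope <- scope
  ledger <- ledger[order(ledger$patient, ledger$clonotype), , drop = FALSE]
  rownames(ledger) <- NULL
  ledger[c("patient", "clonotype", "scope", "count_pbmc", "count_tissue",
           "freq_pbmc", "freq_tissue", "expansion_class_pbmc",
           "expansion_class_tissue")]
}

empty_ledger <- function(scope) {
  data.frame(patient = character(), clonotype = character(),
             scope = character(), count_pbmc = integer(),
             count_tissue = integer(), freq_pbmc = numeric(),
             freq_tissue = numeric(), expansion_class_pbmc = character(),
             expansion_class_tissue = character(),
             stringsAsFactors = FALSE)
}

#' Score paired-tissue clonotype enrichment
#'
#' Adds the four-category tissue-enrichment score per (patient, clonotype):
#' `Single` when the clone occurs exactly once across both tissues of the
#' patient; `TissueEnriched` when its frequency in the non-blood tissue is at
#' least `fold_threshold` times its blood frequency (a clone unseen in blood
#' qualifies with at least `min_cells_expanded` tissue cells);
#' `PBMCEnriched` by the mirrored rule; `Unenriched` otherwise, i.e. similar
#' frequencies in both tissues. Enrichment is scored within each patient
#' separately; clonotypes are never pooled across patients.
#'
#' @param ledger Ledger from [compute_abundance()].
#' @param params An [enrichment_params()] object.
#' @return The ledger with an `enrichment_class` column appended.
#' @export
score_enrichment <- function(ledger, params = enrichment_params()) {
  stopifnot(inherits(params, "enrichment_params"))
  total <- ledger$count_pbmc + ledger$count_tissue
  if (any(total == 0)) {
    stop("clone present in neither tissue cannot be scored")
  }
  fold <- params$fold_threshold
  min_n <- params$min_cells_expanded
  te <- ifelse(ledger$freq_pbmc > 0,
               ledger$freq_tissue >= fold * ledger$freq_pbmc,
               ledger$count_tissue >= min_n)
  pe <- ifelse(ledger$freq_tissue > 0,
               ledger$freq_pbmc >= fold * ledger$freq_tissue,
               ledger$count_pbmc >= min_n)
  cls <- ifelse(te & pe, "Unenriched",
         ifelse(te, "TissueEnriched",
         ifelse(pe, "PBMCEnriched", "Unenriched")))
  cls[total == 1] <- "Single"
  ledger$enrichment_class <- cls
  ledger
}

#' Cell-weighted class proportions per group
#'
#' Quantifies expansion levels and enrichment scores the way repertoire bar
#' plots do: over cells, not clones. Each TCR-bearing cell inherits the
#' expansion class of its clonotype in the cell's own tissue and the
#' patient-level enrichment class of its clonotype; proportions are then
#' computed within each group defined by `group_by`.
#'
#' @param frame Repertoire `data.frame` (scoped consistently with `ledger`).
#' @param ledger Ledger from [compute_abundance()], optionally with
#'   `enrichment_class` from [score_enrichment()].
#' @param group_by Non-empty subset of `c("patient", "tissue", "cluster")`.
#' @param blood_label Tissue label playing the blood role, used to pick the
#'   per-tissue expansion class.
#' @return A `data.frame` with the grouping columns plus `class_type`
#'   (`"expansion"` or `"enrichment"`), `class`, `n_cells`, `proportion`;
#'   proportions sum to 1 within (group, class_type).
#' @export
quantify_by_group <- function(frame, ledger, group_by = "tissue",
                              blood_label = "PBMC") {
  allowed <- c("patient", "tissue", "cluster")
  if (length(group_by) == 0 || !all(group_by %in% allowed)) {
    stop("group_by must be a non-empty subset of: ",
         paste(allowed, collapse = ", "))
  }
  scope <- unique(ledger$scope)
  if (length(scope) == 1 && scope != "all") {
    frame <- frame[frame$subset %in% scope, , drop = FALSE]
  }
  frame <- frame[!is.na(frame$clonotype), , drop = FALSE]
  idx <- match(paste(frame$patient, frame$clonotype),
               paste(ledger$patient, ledger$clonotype))
  if (anyNA(idx)) {
    stop("frame contains clonotypes absent from the ledger; ",
         "recompute the ledger on the same scope")
  }
  exp_class <- ifelse(frame$tissue == blood_label,
                      ledger$expansion_class_pbmc[idx],
                      ledger$expansion_class_tissue[idx])
  pieces <- list(data.frame(frame[group_by], class_type = "expansion",
                            class = exp_class, stringsAsFactors = FALSE))
  if ("enrichment_class" %in% names(ledger)) {
    pieces[[2]] <- data.frame(frame[group_by], class_type = "enrichment",
                              class = ledger$enrichment_class[idx],
                              stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, pieces)
  agg <- stats::aggregate(list(n_cells = rep(1L, nrow(long))),
                          by = long[c(group_by, "class_type", "class")],
                          FUN = sum)
  group_tot <- stats::aggregate(list(total = agg$n_cells),
                                by = agg[c(group_by, "class_type")],
                                FUN = sum)
  m <- merge(agg, group_tot, by = c(group_by, "class_type"))
  m$proportion <- m$n_cells / m$total
  m$total <- NULL
  ord <- do.call(order, unname(m[c(group_by, "class_type", "class")]))
  m <- m[ord, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Clonotypes shared between two clusters
#'
#' Intersects the clonotype sets of two cell clusters and reports, per
#' shared clonotype, its cell counts in each cluster split by tissue. Rows
#' are ordered by combined cell count (descending), ties broken
#' lexicographically on the clonotype key, so top-N reporting is
#' deterministic.
#'
#' @param frame Repertoire `data.frame` with a `cluster` column.
#' @param cluster_a,cluster_b Cluster labels present in `frame`.
#' @param blood_label Tissue label playing the blood role.
#' @return A `data.frame`: `clonotype`, `count_a`, `count_b`,
#'   `count_a_pbmc`, `count_a_tissue`, `count_b_pbmc`, `count_b_tissue`,
#'   `count_total`.
#' @export
cluster_overlap <- function(frame, cluster_a, cluster_b,
                            blood_label = "PBMC") {
  known <- unique(frame$cluster[!is.na(frame$cluster)])
  for (cl in c(cluster_a, cluster_b)) {
    if (!cl %in% known) stop("unknown cluster label: ", cl)
  }
  frame <- frame[!is.na(frame$clonotype) & !is.na(frame$cluster), ,
                 drop = FALSE]
  in_a <- frame[frame$cluster == cluster_a, , drop = FALSE]
  in_b <- frame[frame$cluster == cluster_b, , drop = FALSE]
  shared <- intersect(unique(in_a$clonotype), unique(in_b$clonotype))
  count_in <- function(d, keys, blood) {
    d <- d[d$clonotype %in% keys, , drop = FALSE]
    if (!is.null(blood)) {
      d <- if (blood) d[d$tissue == blood_label, , drop = FALSE]
           else d[d$tissue != blood_label, , drop = FALSE]
    }
    tab <- table(factor(d$clonotype, levels = keys))
    as.integer(tab)
  }
  out <- data.frame(
    clonotype = shared,
    count_a = count_in(in_a, shared, NULL),
    count_b = count_in(in_b, shared, NULL),
    count_a_pbmc = count_in(in_a, shared, TRUE),
    count_a_tissue = count_in(in_a, shared, FALSE),
    count_b_pbmc = count_in(in_b, shared, TRUE),
    count_b_tissue = count_in(in_b, shared, FALSE),
    stringsAsFactors = FALSE
  )
  out$count_total <- out$count_a + out$count_b
  out <- out[order(-out$count_total, out$clonotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact CDR3 annotation matching against a VDJdb-style table
#'
#' A clonotype matches an annotation record iff any of its chain CDR3
#' amino-acid sequences equals the record's CDR3 on the same locus (a TRB
#' sequence never matches a TRA record). All hits are returned; a clonotype
#' can match several epitopes.
#'
#' @param frame Repertoire `data.frame` (or any data.frame with a
#'   `clonotype` column; unique keys are matched).
#' @param db Annotation table from [read_annotation_db()].
#' @param mode Matching mode; only `"exact_cdr3"` is supported.
#' @return A `data.frame` of hits: `clonotype`, `chain_locus`, `cdr3_aa`,
#'   `antigen_species`, `antigen_epitope`, `source`. Zero rows when nothing
#'   matches or the database is empty.
#' @export
match_annotations <- function(frame, db, mode = "exact_cdr3") {
  mode <- match.arg(mode, "exact_cdr3")
  keys <- unique(frame$clonotype)
  keys <- keys[!is.na(keys)]
  empty <- data.frame(clonotype = character(), chain_locus = character(),
                      cdr3_aa = character(), antigen_species = character(),
                      antigen_epitope = character(), source = character(),
                      stringsAsFactors = FALSE)
  if (length(keys) == 0 || nrow(db) == 0) return(empty)
  chains <- parse_clonotype_key(keys)
  if (is.null(chains) || nrow(chains) == 0) return(empty)
  hits <- merge(chains, db, by = c("chain_locus", "cdr3_aa"))
  if (nrow(hits) == 0) return(empty)
  hits <- hits[order(hits$clonotype, hits$chain_locus, hits$cdr3_aa,
                     hits$antigen_species, hits$antigen_epitope), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits[c("clonotype", "chain_locus", "cdr3_aa", "antigen_species",
         "antigen_epitope", "source")]
}

#' Classify bulk TCR-beta clones by the single-cell rules
#'
#' Re-scores a bulk TCR-beta clone table with the same expansion and
#' enrichment semantics as the single-cell path, using template counts in
#' place of cell counts: rows are aggregated per (patient, tissue, CDR3-beta)
#' by summing templates, the denominator is the total template count per
#' (patient, tissue), and [classify_expansion()] / [score_enrichment()] are
#' applied unchanged.
#'
#' @param clones `data.frame` from [read_bulk_clonetable()].
#' @param thresholds An [expansion_thresholds()] object.
#' @param params An [enrichment_params()] object.
#' @param blood_label,tissue_label Tissue labels of the matched design.
#' @return A ledger `data.frame` as from [compute_abundance()] +
#'   [score_enrichment()], with `clonotype` holding the CDR3-beta sequence
#'   and counts holding template counts.
#' @export
bulk_classify <- function(clones, thresholds = expansion_thresholds(),
                          params = enrichment_params(),
                          blood_label = "PBMC", tissue_label = "plaque") {
  stopifnot(all(c("cdr3b_aa", "templates", "tissue", "patient") %in%
                  names(clones)))
  bad_tissue <- setdiff(unique(clones$tissue), c(blood_label, tissue_label))
  if (length(bad_tissue) > 0) {
    stop("unknown tissue label(s): ", paste(bad_tissue, collapse = ", "))
  }
  agg <- stats::aggregate(list(count = clones$templates),
                          by = list(patient = clones$patient,
                                    clonotype = clones$cdr3b_aa,
                                    tissue = clones$tissue),
                          FUN = sum)
  denom <- stats::aggregate(list(n = agg$count),
                            by = list(patient = agg$patient,
                                      tissue = agg$tissue),
                            FUN = sum)
  get_side <- function(lbl, col) {
    side <- agg[agg$tissue == lbl, c("patient", "clonotype", "count")]
    names(side)[3] <- col
    side
  }
  ledger <- merge(get_side(blood_label, "count_pbmc"),
                  get_side(tissue_label, "count_tissue"),
                  by = c("patient", "clonotype"), all = TRUE)
  ledger$count_pbmc[is.na(ledger$count_pbmc)] <- 0L
  ledger$count_tissue[is.na(ledger$count_tissue)] <- 0L
  denom_of <- function(patient, lbl) {
    idx <- match(paste(patient, lbl), paste(denom$patient, denom$tissue))
    d <- denom$n[idx]
    d[is.na(d)] <- 0L
    d
  }
  d_pbmc <- denom_of(ledger$patient, blood_label)
  d_tissue <- denom_of(ledger$patient, tissue_label)
  ledger$freq_pbmc <- ifelse(d_pbmc > 0, 100 * ledger$count_pbmc / d_pbmc, 0)
  ledger$freq_tissue <- ifelse(d_tissue > 0,
                               100 * ledger$count_tissue / d_tissue, 0)
  classify_side <- function(cnt, den) {
    out <- rep("Absent", length(cnt))
    pos <- cnt > 0
    out[pos] <- classify_expansion(cnt[pos], den[pos], thresholds)
    out
  }
  ledger$expansion_class_pbmc <- classify_side(ledger$count_pbmc, d_pbmc)
  ledger$expansion_class_tissue <- classify_side(ledger$count_tissue,
                                                 d_tissue)
  ledger$scope <- "bulk"
  ledger <- ledger[order(ledger$patient, ledger$clonotype), , drop = FALSE]
  rownames(ledger) <- NULL
  ledger <- ledger[c("patient", "clonotype", "scope", "count_pbmc",
                     "count_tissue", "freq_pbmc", "freq_tissue",
                     "expansion_class_pbmc", "expansion_class_tissue")]
  score_enrichment(ledger, params)
}
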