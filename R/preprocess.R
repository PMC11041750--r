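#' Cell-level QC thresholds
#'
#' Bundles the constants of the cell-level quality filter: a cell is kept
#' when it detects between `min_genes` and `max_genes` genes (inclusive on
#' both ends) and each flagged stress/lncRNA marker gene contributes strictly
#' less than `max_flagged_pct` percent of the cell's total counts. The
#' defaults (200--5000 detected genes; KCNQ1OT1, UGDH-AS1 and GHET1 each
#' below 2%) target apoptotic cells, empty droplets and doublets in 5' 10x
#' data.
#'
#' @param min_genes,max_genes Inclusive bounds on the number of detected
#'   genes per cell.
#' @param flagged_genes Gene names whose relative expression flags dying or
#'   low-quality cells.
#' @param max_flagged_pct Exclusive upper bound, in percent of total counts,
#'   for each flagged gene.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200L, max_genes = 5000L,
                          flagged_genes = c("KCNQ1OT1", "UGDH-AS1", "GHET1"),
                          max_flagged_pct = 2) {
  stopifnot(min_genes > 0, min_genes <= max_genes,
            max_flagged_pct > 0, max_flagged_pct <= 100)
  structure(list(min_genes = as.integer(min_genes),
                 max_genes = as.integer(max_genes),
                 flagged_genes = as.character(flagged_genes),
                 max_flagged_pct = as.numeric(max_flagged_pct)),
            class = "qc_thresholds")
}

#' ADT gating thresholds
#'
#' Thresholds on CLR-normalized ADT (antibody-derived tag) values. The CD4
#' and CD8 single-positive gates use strict inequalities (`CD4 > cd4_min`,
#' `CD8 > cd8_min`). CD3/CD14 bounds select T cells (CD3 positive, CD14
#' negative); these two defaults are artifact conventions on normalized
#' units, tunable per dataset, since cluster-level selection is the common
#' alternative.
#'
#' @param cd4_min,cd8_min Exclusive lower bounds for the CD4/CD8 gates on
#'   normalized ADT units.
#' @param cd3_min Exclusive lower bound for CD3 positivity.
#' @param cd14_max Inclusive upper bound for "without CD14 expression".
#' @return A list of class `gate_thresholds`.
#' @export
gate_thresholds <- function(cd4_min = 0.75, cd8_min = 1.0,
                            cd3_min = 0.5, cd14_max = 0.5) {
  vals <- c(cd4_min, cd8_min, cd3_min, cd14_max)
  stopifnot(all(is.finite(vals)))
  structure(list(cd4_min = cd4_min, cd8_min = cd8_min,
                 cd3_min = cd3_min, cd14_max = cd14_max),
            class = "gate_thresholds")
}

#' Cell-level QC filter
#'
#' Applies the detected-gene-count and flagged-gene filters of
#' [qc_thresholds()] to a cells x genes count matrix. Every cell receives a
#' report; a cell passes iff its detected gene count lies inside
#' `[min_genes, max_genes]` and every flagged gene is strictly below
#' `max_flagged_pct` percent of the cell's total counts. Flagged genes
#' absent from the matrix contribute 0%. Cells with zero total counts fail
#' with reason `"zero counts"`.
#'
#' @param counts Cells x genes matrix (dense or [Matrix::sparseMatrix]) with
#'   barcode rownames and gene colnames.
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `passed` (character vector of passing barcodes) and
#'   `report` (data.frame with one row per cell: `barcode`,
#'   `n_genes_detected`, one `pct_<gene>` column per flagged gene, `passed`,
#'   `failure_reasons` as a `;`-joined string, empty iff passed).
#' @export
qc_filter <- function(counts, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry barcode rownames and gene colnames")
  }
  n_genes <- Matrix::rowSums(counts > 0)
  totals <- Matrix::rowSums(counts)
  flagged <- thresholds$flagged_genes
  pct <- matrix(0, nrow = nrow(counts), ncol = length(flagged),
                dimnames = list(rownames(counts), flagged))
  present <- intersect(flagged, colnames(counts))
  if (length(present) > 0) {
    sub <- as.matrix(counts[, present, drop = FALSE])
    pct[, present] <- 100 * sweep(sub, 1, pmax(totals, 1), "/")
  }
  reasons <- vector("list", nrow(counts))
  zero <- totals == 0
  low <- n_genes < thresholds$min_genes
  high <- n_genes > thresholds$max_genes
  for (i in seq_len(nrow(counts))) {
    r <- character()
    if (zero[i]) r <- c(r, "zero counts")
    if (low[i]) r <- c(r, sprintf("fewer than %d genes detected",
                                  thresholds$min_genes))
    if (high[i]) r <- c(r, sprintf("more than %d genes detected",
                                   thresholds$max_genes))
    over <- flagged[pct[i, ] >= thresholds$max_flagged_pct]
    if (length(over) > 0 && !zero[i]) {
      r <- c(r, paste0(over, " at or above ", thresholds$max_flagged_pct,
                       "% of counts"))
    }
    reasons[[i]] <- r
  }
  passed <- lengths(reasons) == 0
  report <- data.frame(barcode = rownames(counts),
                       n_genes_detected = as.integer(n_genes),
                       stringsAsFactors = FALSE)
  for (g in flagged) {
    report[[paste0("pct_", gsub("[^A-Za-z0-9]", "_", g))]] <- pct[, g]
  }
  report$passed <- passed
  report$failure_reasons <- vapply(reasons, paste, character(1),
                                   collapse = "; ")
  rownames(report) <- NULL
  list(passed = rownames(counts)[passed], report = report)
}

#' Centered log-ratio normalization of ADT counts
#'
#' Computes `ln((x + 1) / g)` where `g` is the geometric mean of `x + 1`
#' over the chosen axis: across cells for each protein (`per_feature`, the
#' feature-barcoding convention and the default) or across proteins within
#' each cell (`per_cell`). A slice of all zeros maps to all zeros. The
#' transform is monotone within each slice, so gating thresholds respect the
#' rank order of raw counts.
#'
#' @param adt Cells x proteins matrix of non-negative raw ADT counts with
#'   dimnames.
#' @param axis `"per_feature"` or `"per_cell"`.
#' @return A numeric matrix of normalized values, same shape and dimnames.
#' @export
clr_normalize <- function(adt, axis = c("per_feature", "per_cell")) {
  axis <- match.arg(axis)
  adt <- as.matrix(adt)
  if (any(adt < 0)) stop("ADT counts must be non-negative")
  lx <- log(adt + 1)
  margin <- if (axis == "per_feature") 2L else 1L
  centers <- apply(lx, margin, mean)
  sweep(lx, margin, centers, "-")
}

#' Gate T cells by CD3/CD14 ADT expression
#'
#' Keeps cells with CD3 above `cd3_min` and CD14 at or below `cd14_max` on
#' normalized ADT units, i.e. CD3-positive cells without CD14 (monocyte)
#' expression.
#'
#' @param adt_norm Cells x proteins matrix of CLR-normalized ADT values; must
#'   contain `CD3` and `CD14` columns.
#' @param gates A [gate_thresholds()] object.
#' @return Character vector of retained cell barcodes.
#' @export
gate_t_cells <- function(adt_norm, gates = gate_thresholds()) {
  stopifnot(inherits(gates, "gate_thresholds"))
  for (p in c("CD3", "CD14")) {
    if (!p %in% colnames(adt_norm)) {
      stop("ADT matrix lacks required feature: ", p)
    }
  }
  keep <- adt_norm[, "CD3"] > gates$cd3_min &
    adt_norm[, "CD14"] <= gates$cd14_max
  rownames(adt_norm)[keep]
}

#' Classify cells as CD4/CD8 single-positive by ADT gates
#'
#' Applies the single-positive rule on normalized ADT values: a cell is
#' labelled `CD4` iff `CD4 > cd4_min` and not `CD8 > cd8_min`, `CD8` by the
#' mirrored rule, `double_positive` when both strict gates fire and
#' `double_negative` when neither does. Every cell receives exactly one
#' label; double-positive and double-negative cells are excluded from
#' subset-scoped analyses downstream.
#'
#' @param adt_norm Cells x proteins matrix of CLR-normalized ADT values; must
#'   contain `CD4` and `CD8` columns.
#' @param gates A [gate_thresholds()] object.
#' @return Named character vector, barcode -> label in
#'   `c("CD4", "CD8", "double_positive", "double_negative")`.
#' @export
gate_cd4_cd8 <- function(adt_norm, gates = gate_thresholds()) {
  stopifnot(inherits(gates, "gate_thresholds"))
  for (p in c("CD4", "CD8")) {
    if (!p %in% colnames(adt_norm)) {
      stop("ADT matrix lacks required feature: ", p)
    }
  }
  cd4 <- adt_norm[, "CD4"] > gates$cd4_min
  cd8 <- adt_norm[, "CD8"] > gates$cd8_min
  label <- ifelse(cd4 & cd8, "double_positive",
           ifelse(cd4, "CD4",
           ifelse(cd8, "CD8", "double_negative")))
  stats::setNames(label, rownames(adt_norm))
}
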