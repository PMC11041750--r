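#' Library-size log-normalization of counts
#'
#' Scales each cell's counts to a common library size and applies
#' `log1p`, the conventional input to rank-based differential expression
#' (ranks within a gene are invariant to any monotone per-value transform,
#' but means and fold changes are reported on this scale).
#'
#' @param counts Cells x genes count matrix (dense or sparse).
#' @param scale_factor Target library size (default 1e4).
#' @return A sparse cells x genes matrix of normalized values.
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  totals <- Matrix::rowSums(counts)
  totals[totals == 0] <- 1
  m <- Matrix::Diagonal(x = scale_factor / totals) %*% counts
  dimnames(m) <- dimnames(counts)
  methods::as(log1p(m), "CsparseMatrix")
}

#' Specify a two-group contrast over clonality classes
#'
#' Describes which cells form the two sides of a differential-expression
#' contrast: by expansion class (e.g. Single vs all expanded Small--Large,
#' leaving Hyperexpanded cells in neither group), by enrichment class
#' (e.g. PBMCEnriched vs TissueEnriched, ignoring Unenriched and Single), or
#' by tissue within one cluster (e.g. a regulatory T-cell cluster in blood
#' vs plaque).
#'
#' @param type `"expansion"`, `"enrichment"` or `"tissue_within_cluster"`.
#' @param classes_a,classes_b For class-based types: disjoint sets of class
#'   labels defining groups A and B. For `tissue_within_cluster`: the tissue
#'   label of each group.
#' @param cluster Cluster label, required for `tissue_within_cluster`.
#' @param name_a,name_b Human-readable group names for reporting.
#' @return A list of class `group_spec`.
#' @export
group_spec <- function(type = c("expansion", "enrichment",
                                "tissue_within_cluster"),
                       classes_a, classes_b, cluster = NULL,
                       name_a = NULL, name_b = NULL) {
  type <- match.arg(type)
  if (length(intersect(classes_a, classes_b)) > 0) {
    stop("the two groups of a contrast must be disjoint")
  }
  if (type == "tissue_within_cluster" && is.null(cluster)) {
    stop("tissue_within_cluster contrasts need a cluster label")
  }
  structure(list(type = type, classes_a = classes_a, classes_b = classes_b,
                 cluster = cluster,
                 name_a = if (is.null(name_a))
                   paste(classes_a, collapse = "+") else name_a,
                 name_b = if (is.null(name_b))
                   paste(classes_b, collapse = "+") else name_b),
            class = "group_spec")
}

#' Resolve a contrast specification to two disjoint cell sets
#'
#' Maps a [group_spec()] onto concrete barcodes using the repertoire frame
#' and the classified ledger. For expansion contrasts each cell carries its
#' clone's expansion class in the cell's own tissue; for enrichment
#' contrasts, its clone's patient-level enrichment class. Cells whose class
#' is in neither side are excluded from the contrast entirely.
#'
#' @param frame Repertoire `data.frame`.
#' @param ledger Classified ledger ([compute_abundance()] +
#'   [score_enrichment()]), on the same scope as `frame` filtering.
#' @param spec A [group_spec()].
#' @param blood_label Tissue label playing the blood role.
#' @return `list(a = barcodes, b = barcodes)`; errors if either group is
#'   empty.
#' @export
define_groups <- function(frame, ledger, spec, blood_label = "PBMC") {
  stopifnot(inherits(spec, "group_spec"))
  scope <- unique(ledger$scope)
  if (length(scope) == 1 && scope %in% c("CD4", "CD8")) {
    frame <- frame[frame$subset %in% scope, , drop = FALSE]
  }
  frame <- frame[!is.na(frame$clonotype), , drop = FALSE]
  if (spec$type == "tissue_within_cluster") {
    sub <- frame[!is.na(frame$cluster) & frame$cluster == spec$cluster, ,
                 drop = FALSE]
    a <- sub$barcode[sub$tissue %in% spec$classes_a]
    b <- sub$barcode[sub$tissue %in% spec$classes_b]
  } else {
    idx <- match(paste(frame$patient, frame$clonotype),
                 paste(ledger$patient, ledger$clonotype))
    cls <- if (spec$type == "expansion") {
      ifelse(frame$tissue == blood_label,
             ledger$expansion_class_pbmc[idx],
             ledger$expansion_class_tissue[idx])
    } else {
      if (!"enrichment_class" %in% names(ledger)) {
        stop("ledger has no enrichment_class; run score_enrichment() first")
      }
      ledger$enrichment_class[idx]
    }
    a <- frame$barcode[!is.na(cls) & cls %in% spec$classes_a]
    b <- frame$barcode[!is.na(cls) & cls %in% spec$classes_b]
  }
  if (length(a) == 0) stop("contrast group is empty: ", spec$name_a)
  if (length(b) == 0) stop("contrast group is empty: ", spec$name_b)
  list(a = unique(a), b = unique(b))
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Tests each gene with a two-sided Wilcoxon rank-sum (Mann-Whitney) test
#' between two disjoint cell groups, on normalized expression values. The
#' exact null distribution is used for small groups without ties and the
#' tie-corrected normal approximation otherwise (the behaviour of
#' [stats::wilcox.test()]). P values are Bonferroni-corrected by
#' `total_genes`, the number of genes in the whole dataset. The fold change
#' is `log2((mean_B + pseudocount) / (mean_A + pseudocount))` of group mean
#' normalized expression, so positive values indicate higher expression in
#' group B. A gene is flagged significant when `p < p_cutoff` and
#' `|log2fc| >= lfc_cutoff` (defaults 1e-6 and 0.5).
#'
#' @param expression Cells x genes matrix of normalized expression with
#'   barcode rownames.
#' @param groups `list(a = barcodes, b = barcodes)` as from
#'   [define_groups()]; each group must contain at least 3 cells.
#' @param total_genes Bonferroni multiplier; defaults to `ncol(expression)`.
#' @param p_cutoff,lfc_cutoff Significance rule constants.
#' @param pseudocount Pseudocount applied to group means in the fold change.
#' @return A `data.frame` sorted by p ascending (ties: `|log2fc|`
#'   descending, then gene name): `gene`, `p_value`, `p_adj`, `log2fc`,
#'   `pct_in_a`, `pct_in_b`, `significant`.
#' @export
wilcoxon_de <- function(expression, groups, total_genes = ncol(expression),
                        p_cutoff = 1e-6, lfc_cutoff = 0.5,
                        pseudocount = 1) {
  a <- groups$a
  b <- groups$b
  if (length(intersect(a, b)) > 0) stop("groups must be disjoint")
  if (length(a) < 3 || length(b) < 3) {
    stop("each group needs at least 3 cells")
  }
  missing_bc <- setdiff(c(a, b), rownames(expression))
  if (length(missing_bc) > 0) {
    stop(length(missing_bc), " group barcode(s) absent from the ",
         "expression matrix")
  }
  xa <- expression[a, , drop = FALSE]
  xb <- expression[b, , drop = FALSE]
  genes <- colnames(expression)
  p <- numeric(length(genes))
  lfc <- numeric(length(genes))
  pct_a <- numeric(length(genes))
  pct_b <- numeric(length(genes))
  for (g in seq_along(genes)) {
    va <- as.numeric(xa[, g])
    vb <- as.numeric(xb[, g])
    pct_a[g] <- mean(va > 0)
    pct_b[g] <- mean(vb > 0)
    ma <- mean(va)
    mb <- mean(vb)
    # expression is expected non-negative; clamp so an all-negative input
    # (possible for already-centred values) cannot produce NaN fold changes
    lfc[g] <- log2(max(mb + pseudocount, .Machine$double.eps) /
                     max(ma + pseudocount, .Machine$double.eps))
    if (max(c(va, vb)) == min(c(va, vb))) {
      p[g] <- 1
      lfc[g] <- 0
      next
    }
    p[g] <- suppressWarnings(
      stats::wilcox.test(va, vb, alternative = "two.sided")$p.value)
  }
  out <- data.frame(gene = genes, p_value = p,
                    p_adj = pmin(1, p * total_genes), log2fc = lfc,
                    pct_in_a = pct_a, pct_in_b = pct_b,
                    stringsAsFactors = FALSE)
  out$significant <- out$p_value < p_cutoff & abs(out$log2fc) >= lfc_cutoff
  out <- out[order(out$p_value, -abs(out$log2fc), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
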