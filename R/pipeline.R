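#' Run the full paired-repertoire clonality pipeline
#'
#' Executes every stage on one dataset: acquire (simulate from a
#' [simulation_config()], or read a directory written by [emit_dataset()]),
#' cell-level QC, CLR normalization and ADT gating, clonotype calling,
#' per-scope abundance/expansion/enrichment ledgers, group quantification,
#' cluster overlap, annotation matching and differential expression, then
#' writes tidy result tables plus a manifest echoing every threshold used.
#' Each stage logs its input/output cell and clone counts; any stage error
#' aborts the run.
#'
#' @param sim_config A [simulation_config()]; ignored when `input_dir` is
#'   given.
#' @param input_dir Directory produced by [emit_dataset()] to read instead
#'   of simulating.
#' @param out_dir Output directory for result tables.
#' @param qc,gates,expansion,enrichment Threshold bundles; see
#'   [qc_thresholds()], [gate_thresholds()], [expansion_thresholds()],
#'   [enrichment_params()].
#' @param scopes Subset scopes to quantify; subset of `c("all","CD4","CD8")`.
#' @param contrasts List of `list(scope = , spec = group_spec(...))`
#'   differential-expression contrasts; `NULL` uses the two standard ones
#'   (Single vs Small--Large cells, PBMC-enriched vs tissue-enriched cells).
#' @param overlap_clusters Length-2 character vector of cluster labels for
#'   the clonotype-overlap table, or `NULL` to skip.
#' @param annotation_db Annotation table (from [read_annotation_db()]) or a
#'   path to one; `NULL` writes an empty hit table.
#' @param overwrite Allow writing into a non-empty `out_dir`.
#' @return Invisibly, a list with the in-memory results: `frame`, `ledgers`
#'   (per scope), `quantifications`, `overlap`, `annotation_hits`, `de`
#'   (per contrast), `qc_report`, `manifest`.
#' @export
run_pipeline <- function(sim_config = NULL, input_dir = NULL, out_dir,
                         qc = qc_thresholds(), gates = gate_thresholds(),
                         expansion = expansion_thresholds(),
                         enrichment = enrichment_params(),
                         scopes = c("all", "CD4", "CD8"),
                         contrasts = NULL,
                         overlap_clusters = c("C6", "C3"),
                         annotation_db = NULL,
                         overwrite = FALSE) {
  scopes <- match.arg(scopes, several.ok = TRUE)
  if (is.null(sim_config) && is.null(input_dir)) {
    stop("provide either sim_config or input_dir")
  }
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stop("output directory is not empty (use overwrite = TRUE): ", out_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[tcrpair] ", ...)

  # --- acquire ---------------------------------------------------------
  if (!is.null(input_dir)) {
    loaded <- load_dataset(input_dir)
    contigs <- loaded$contigs
    cells <- loaded$cells
    counts <- loaded$counts
    adt <- loaded$adt
    blood <- loaded$blood_label
    tissue_lbl <- loaded$tissue_label
    log_stage("read ", nrow(cells), " cells and ", nrow(contigs),
              " contigs from ", input_dir)
  } else {
    sim <- generate_paired_repertoire(sim_config)
    expr <- generate_expression_matrices(sim_config, sim$cells, qc = qc)
    contigs <- sim$contigs
    cells <- sim$cells
    counts <- expr$counts
    adt <- expr$adt
    blood <- sim_config$blood_label
    tissue_lbl <- sim_config$tissue_label
    log_stage("simulated ", nrow(cells), " cells (",
              sim_config$n_patients, " patients x 2 tissues), ",
              nrow(contigs), " contigs")
  }

  # --- qc --------------------------------------------------------------
  qc_res <- qc_filter(counts, qc)
  log_stage("QC: ", length(qc_res$passed), " of ", nrow(cells),
            " cells pass")

  # --- gate ------------------------------------------------------------
  adt_norm <- clr_normalize(adt, axis = "per_feature")
  t_cells <- gate_t_cells(adt_norm, gates)
  subset_label <- gate_cd4_cd8(adt_norm, gates)
  analysis_bcs <- intersect(qc_res$passed, t_cells)
  log_stage("gating: ", length(t_cells), " CD3+CD14- cells; ",
            length(analysis_bcs), " analysis cells after QC intersection")

  cell_meta <- cells[cells$barcode %in% analysis_bcs,
                     c("barcode", "patient", "tissue", "cluster"),
                     drop = FALSE]
  cell_meta$subset <- unname(subset_label[cell_meta$barcode])
  log_stage("subsets: ",
            paste(names(table(cell_meta$subset)),
                  table(cell_meta$subset), sep = "=", collapse = ", "))

  # --- clonotypes ------------------------------------------------------
  contigs_analysis <- contigs[contigs$barcode %in% analysis_bcs, ,
                              drop = FALSE]
  frame <- build_clonotypes(contigs_analysis, cell_meta,
                            productive_only = TRUE)
  n_tcr <- sum(!is.na(frame$clonotype))
  log_stage("clonotypes: ", n_tcr, " TCR-bearing cells, ",
            length(unique(stats::na.omit(frame$clonotype))),
            " distinct clonotypes")

  # --- classify + enrich per scope ------------------------------------
  ledgers <- list()
  for (sc in scopes) {
    led <- compute_abundance(frame, scope = sc, thresholds = expansion,
                             blood_label = blood,
                             tissue_label = tissue_lbl)
    led <- score_enrichment(led, enrichment)
    ledgers[[sc]] <- led
    log_stage("scope ", sc, ": ", nrow(led), " (patient, clonotype) rows")
  }

  # --- quantify --------------------------------------------------------
  quants <- list()
  for (sc in names(ledgers)) {
    quants[[paste0(sc, "_by_tissue")]] <-
      quantify_by_group(frame, ledgers[[sc]], group_by = "tissue",
                        blood_label = blood)
    quants[[paste0(sc, "_by_patient_tissue")]] <-
      quantify_by_group(frame, ledgers[[sc]],
                        group_by = c("patient", "tissue"),
                        blood_label = blood)
    quants[[paste0(sc, "_by_cluster_tissue")]] <-
      quantify_by_group(frame, ledgers[[sc]],
                        group_by = c("cluster", "tissue"),
                        blood_label = blood)
  }

  # --- overlap ---------------------------------------------------------
  overlap <- NULL
  if (!is.null(overlap_clusters)) {
    overlap <- cluster_overlap(frame, overlap_clusters[1],
                               overlap_clusters[2], blood_label = blood)
    log_stage("overlap ", overlap_clusters[1], "/", overlap_clusters[2],
              ": ", nrow(overlap), " shared clonotypes")
  }

  # --- annotate --------------------------------------------------------
  if (is.character(annotation_db)) {
    annotation_db <- read_annotation_db(annotation_db)
  }
  hits <- if (is.null(annotation_db)) {
    match_annotations(frame, data.frame(chain_locus = character(),
                                        cdr3_aa = character()))
  } else {
    match_annotations(frame, annotation_db)
  }
  log_stage("annotation: ", nrow(hits), " CDR3 hits")

  # --- de --------------------------------------------------------------
  if (is.null(contrasts)) {
    contrasts <- list(
      list(scope = "all",
           spec = group_spec("expansion", "Single",
                             c("Small", "Medium", "Large"),
                             name_a = "Single", name_b = "Expanded")),
      list(scope = "all",
           spec = group_spec("enrichment", "PBMCEnriched",
                             "TissueEnriched"))
    )
  }
  norm <- lognormalize(counts[frame$barcode, , drop = FALSE])
  de_results <- list()
  for (ct in contrasts) {
    sc <- ct$scope
    if (!sc %in% names(ledgers)) {
      ledgers[[sc]] <- score_enrichment(
        compute_abundance(frame, scope = sc, thresholds = expansion,
                          blood_label = blood, tissue_label = tissue_lbl),
        enrichment)
    }
    groups <- define_groups(frame, ledgers[[sc]], ct$spec,
                            blood_label = blood)
    res <- wilcoxon_de(norm, groups)
    nm <- paste(sc, ct$spec$name_a, "vs", ct$spec$name_b, sep = "_")
    de_results[[nm]] <- res
    log_stage("DE ", nm, ": |A|=", length(groups$a), " |B|=",
              length(groups$b), ", ", sum(res$significant),
              " significant genes")
  }

  manifest <- list(
    n_cells_input = nrow(cells),
    n_cells_qc_pass = length(qc_res$passed),
    n_cells_analysis = length(analysis_bcs),
    n_cells_tcr = n_tcr,
    thresholds = list(qc = unclass(qc), gates = unclass(gates),
                      expansion = unclass(expansion),
                      enrichment = unclass(enrichment)),
    scopes = scopes,
    blood_label = blood, tissue_label = tissue_lbl
  )
  results <- list(frame = frame, ledgers = ledgers,
                  quantifications = quants, overlap = overlap,
                  annotation_hits = hits, de = de_results,
                  qc_report = qc_res$report, manifest = manifest)
  make_report_tables(results, out_dir)
  log_stage("wrote result tables to ", out_dir)
  invisible(results)
}

# Read back a directory written by emit_dataset()
load_dataset <- function(input_dir) {
  contig_files <- list.files(input_dir, pattern = "^contigs_.*\\.csv$",
                             full.names = TRUE)
  if (length(contig_files) == 0) {
    stop("no contig tables found in ", input_dir)
  }
  contigs <- do.call(rbind, lapply(sort(contig_files), read_contigs))
  cells <- utils::read.csv(file.path(input_dir, "cells.csv"),
                           stringsAsFactors = FALSE)
  counts <- read_count_matrix(file.path(input_dir, "matrix.mtx"),
                              file.path(input_dir, "features.tsv"),
                              file.path(input_dir, "barcodes.tsv"))
  adt_df <- utils::read.csv(file.path(input_dir, "adt.csv"),
                            stringsAsFactors = FALSE, check.names = FALSE)
  adt <- as.matrix(adt_df[, setdiff(names(adt_df), "barcode"),
                          drop = FALSE])
  rownames(adt) <- adt_df$barcode
  cfg <- jsonlite::read_json(file.path(input_dir, "config.json"))
  list(contigs = contigs, cells = cells, counts = counts, adt = adt,
       blood_label = cfg$blood_label, tissue_label = cfg$tissue_label)
}

#' Write tidy result tables for a pipeline run
#'
#' Emits, per scope: expansion/enrichment class proportions by tissue
#' (pooled), by patient and tissue, and by cluster and tissue; plus the
#' ledgers, the cluster-overlap table, the annotation-hit table, one DE
#' table per contrast, the QC report and a JSON manifest echoing every
#' threshold used. All tables are written with deterministic row order.
#'
#' @param results Result list from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return Character vector of written file paths, invisibly.
#' @export
make_report_tables <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name, key_cols = NULL) {
    p <- file.path(out_dir, name)
    write_table(df, p, key_cols = key_cols)
    written <<- c(written, p)
  }
  for (nm in names(results$quantifications)) {
    emit(results$quantifications[[nm]],
         paste0("proportions_", nm, ".csv"))
  }
  for (sc in names(results$ledgers)) {
    emit(results$ledgers[[sc]], paste0("ledger_", sc, ".csv"),
         key_cols = c("patient", "clonotype"))
  }
  if (!is.null(results$overlap)) {
    # overlap and DE tables keep their rank order rather than key order
    p <- file.path(out_dir, "cluster_overlap.csv")
    utils::write.table(results$overlap, p, sep = ",", row.names = FALSE,
                       quote = FALSE)
    written <- c(written, p)
  }
  emit(results$annotation_hits, "annotation_hits.csv")
  for (nm in names(results$de)) {
    p <- file.path(out_dir, paste0("de_", nm, ".csv"))
    utils::write.table(results$de[[nm]], p, sep = ",", row.names = FALSE,
                       quote = FALSE)
    written <- c(written, p)
  }
  emit(results$qc_report, "qc_report.csv", key_cols = "barcode")
  jsonlite::write_json(results$manifest,
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, file.path(out_dir, "run_manifest.json"))
  invisible(written)
}
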