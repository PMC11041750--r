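#' Read a 10x-style VDJ contig annotation table
#'
#' Parses a comma-separated contig annotation table in the 10x Cell Ranger
#' `filtered_contig_annotations` dialect: one row per assembled chain contig,
#' identified by cell barcode. The reader is deliberately permissive about
#' column order and extra columns, and it never filters: non-productive
#' contigs and contigs without a CDR3 are retained with their flags so that
#' filtering stays an explicit, auditable downstream decision.
#'
#' @param path Path to the comma-separated contig table.
#' @param dialect Input dialect; only `"tenx_filtered"` is supported.
#' @return A `data.frame` with one row per retained contig and columns
#'   `barcode`, `chain`, `v_gene`, `j_gene`, `cdr3`, `cdr3_nt`, `productive`,
#'   `high_confidence`, `umis`. `cdr3`/`cdr3_nt` are `NA` where the table
#'   stored `"None"` or an empty string. Rows whose chain locus is not one of
#'   TRA/TRB/TRG/TRD (e.g. 10x `"Multi"` calls) are dropped with a warning.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "barcode,chain,v_gene,j_gene,cdr3,cdr3_nt,productive,high_confidence,umis",
#'   "AAAC-1,TRB,TRBV9,TRBJ2-7,CASSF,TGTGC,True,True,4"), tmp)
#' read_contigs(tmp)
#' @export
read_contigs <- function(path, dialect = "tenx_filtered") {
  dialect <- match.arg(dialect, "tenx_filtered")
  if (!file.exists(path)) {
    stop("contig file does not exist: ", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  required <- c("barcode", "chain", "v_gene", "j_gene", "cdr3", "productive")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("contig table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) {
    warning("contig table is empty: ", path)
    return(empty_contig_frame())
  }
  out <- data.frame(
    barcode = df$barcode,
    chain = df$chain,
    v_gene = df$v_gene,
    j_gene = df$j_gene,
    cdr3 = blank_to_na(df$cdr3),
    cdr3_nt = if ("cdr3_nt" %in% names(df)) blank_to_na(df$cdr3_nt)
              else NA_character_,
    productive = parse_tenx_logical(df$productive),
    high_confidence = if ("high_confidence" %in% names(df))
      parse_tenx_logical(df$high_confidence) else TRUE,
    umis = if ("umis" %in% names(df)) as.integer(df$umis) else NA_integer_,
    stringsAsFactors = FALSE
  )
  if (any(out$barcode == "" | is.na(out$barcode))) {
    stop("contig table contains rows with an empty barcode")
  }
  allowed <- c("TRA", "TRB", "TRG", "TRD")
  bad <- !(out$chain %in% allowed)
  if (any(bad)) {
    warning(sum(bad), " contig row(s) with chain locus outside ",
            paste(allowed, collapse = "/"), " were dropped")
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

empty_contig_frame <- function() {
  data.frame(barcode = character(), chain = character(),
             v_gene = character(), j_gene = character(),
             cdr3 = character(), cdr3_nt = character(),
             productive = logical(), high_confidence = logical(),
             umis = integer(), stringsAsFactors = FALSE)
}

# 10x writes python-style "True"/"False"; tolerate R/lowercase spellings too
parse_tenx_logical <- function(x) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1")] <- TRUE
  out[lx %in% c("false", "f", "0", "none", "")] <- FALSE
  if (anyNA(out)) {
    stop("cannot parse logical column value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

blank_to_na <- function(x) {
  x[x %in% c("", "None", "NA")] <- NA_character_
  x
}

#' Read a sparse gene-count matrix in MatrixMarket triplet format
#'
#' Reads a 10x-style trio of files (`matrix.mtx` plus line lists of feature
#' and barcode names) and returns the counts oriented cells x genes
#' regardless of the on-disk orientation. Orientation is detected by matching
#' the MatrixMarket header dimensions against the lengths of the two name
#' lists (10x writes genes x cells; other exporters write the transpose).
#'
#' @param mtx_path Path to the MatrixMarket coordinate file.
#' @param features_path Path to the feature (gene) name list; if the file is
#'   tab-separated with several columns (10x id/name/type), the second column
#'   is used as the gene name.
#' @param barcodes_path Path to the barcode line list.
#' @return A [`Matrix::sparseMatrix`] of non-negative integer counts with
#'   `rownames` = barcodes (cells) and `colnames` = features (genes).
#' @export
read_count_matrix <- function(mtx_path, features_path, barcodes_path) {
  m <- Matrix::readMM(mtx_path)
  features <- read_name_list(features_path)
  barcodes <- read_name_list(barcodes_path, column = 1L)
  vals <- m@x
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("count matrix contains negative or non-integer entries")
  }
  if (nrow(m) == length(barcodes) && ncol(m) == length(features)) {
    # already cells x genes
  } else if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)
  } else {
    stop("matrix dimensions ", nrow(m), " x ", ncol(m),
         " match neither orientation of ", length(barcodes), " barcodes x ",
         length(features), " features")
  }
  dimnames(m) <- list(barcodes, features)
  methods::as(m, "CsparseMatrix")
}

read_name_list <- function(path, column = NULL) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol_seen <- if (length(parts)) max(lengths(parts)) else 1L
  if (is.null(column)) column <- if (ncol_seen >= 2L) 2L else 1L
  vapply(parts, function(p) p[[min(column, length(p))]], character(1))
}

#' Read a bulk TCR-beta clone table
#'
#' Reads a tab-separated table of bulk TCR-beta sequencing clones, one row
#' per observed CDR3 amino-acid sequence with its template count. The reader
#' does not aggregate duplicate CDR3 rows; aggregation happens in
#' [bulk_classify()].
#'
#' @param path Path to the tab-separated clone table.
#' @param cdr3_col,templates_col,sample_col,tissue_col,patient_col Column
#'   names in the file (configurable to accommodate vendor exports).
#' @return A `data.frame` with columns `cdr3b_aa`, `templates` (integer),
#'   `sample_id`, `tissue`, `patient`.
#' @export
read_bulk_clonetable <- function(path,
                                 cdr3_col = "cdr3b_aa",
                                 templates_col = "templates",
                                 sample_col = "sample_id",
                                 tissue_col = "tissue",
                                 patient_col = "patient") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(cdr3_col, templates_col, sample_col, tissue_col, patient_col)) {
    if (!col %in% names(df)) {
      stop("bulk clone table is missing column: ", col)
    }
  }
  templates <- suppressWarnings(as.integer(df[[templates_col]]))
  bad <- which(is.na(templates) | templates < 1L)
  if (length(bad) > 0) {
    stop("non-positive or unparseable template count in row(s): ",
         paste(bad, collapse = ", "))
  }
  data.frame(
    cdr3b_aa = as.character(df[[cdr3_col]]),
    templates = templates,
    sample_id = as.character(df[[sample_col]]),
    tissue = as.character(df[[tissue_col]]),
    patient = as.character(df[[patient_col]]),
    stringsAsFactors = FALSE
  )
}

#' Read a VDJdb-style TCR annotation table
#'
#' Reads a tab-separated table linking TCR chain CDR3 amino-acid sequences to
#' antigen annotations (species and epitope). Chain labels are normalized to
#' TRA/TRB from common spellings ("TRA", "alpha", "TRB", "beta", case
#' insensitive).
#'
#' @param path Path to the tab-separated annotation table. Recognized column
#'   names: chain (`chain`/`gene`), CDR3 (`cdr3`/`cdr3_aa`),
#'   species (`antigen_species`/`antigen.species`),
#'   epitope (`antigen_epitope`/`antigen.epitope`), optional `source`.
#' @return A `data.frame` with columns `chain_locus`, `cdr3_aa`,
#'   `antigen_species`, `antigen_epitope`, `source`.
#' @export
read_annotation_db <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(cands, required = TRUE) {
    hit <- intersect(cands, names(df))
    if (length(hit) == 0) {
      if (required) stop("annotation table is missing a column among: ",
                         paste(cands, collapse = ", "))
      return(NULL)
    }
    df[[hit[[1]]]]
  }
  chain_raw <- pick(c("chain", "chain_locus", "gene", "Gene"))
  cdr3 <- pick(c("cdr3_aa", "cdr3", "CDR3"))
  species <- pick(c("antigen_species", "antigen.species", "Species"))
  epitope <- pick(c("antigen_epitope", "antigen.epitope", "Epitope"))
  src <- pick(c("source", "Reference"), required = FALSE)
  chain <- normalize_chain_label(chain_raw)
  if (any(is.na(cdr3) | cdr3 == "")) {
    stop("annotation table contains empty CDR3 value(s)")
  }
  data.frame(
    chain_locus = chain,
    cdr3_aa = as.character(cdr3),
    antigen_species = as.character(species),
    antigen_epitope = as.character(epitope),
    source = if (is.null(src)) NA_character_ else as.character(src),
    stringsAsFactors = FALSE
  )
}

normalize_chain_label <- function(x) {
  lx <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  out[lx %in% c("tra", "alpha", "a", "trav")] <- "TRA"
  out[lx %in% c("trb", "beta", "b", "trbv")] <- "TRB"
  if (anyNA(out)) {
    stop("unknown chain label(s) in annotation table: ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Write a result table deterministically
#'
#' Writes a data frame as csv or tsv after sorting rows by the given key
#' columns (all columns by default), so that logically equal tables produce
#' byte-identical files regardless of the order rows were assembled in.
#'
#' @param rows A `data.frame` of results (may have zero rows).
#' @param path Output file path.
#' @param format `"csv"` or `"tsv"`.
#' @param key_cols Character vector of columns to sort by; defaults to every
#'   column, left to right.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("csv", "tsv"),
                        key_cols = NULL) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  if (is.null(key_cols)) key_cols <- names(rows)
  key_cols <- intersect(key_cols, names(rows))
  if (nrow(rows) > 1 && length(key_cols) > 0) {
    ord <- do.call(order, unname(rows[key_cols]))
    rows <- rows[ord, , drop = FALSE]
  }
  sep <- if (format == "csv") "," else "\t"
  utils::write.table(rows, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
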