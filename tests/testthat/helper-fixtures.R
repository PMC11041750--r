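# Tiny in-code fixtures and independent oracles used across test files.

write_contig_fixture <- function(rows, path = tempfile(fileext = ".csv"),
                                 col_order = NULL) {
  if (is.null(col_order)) col_order <- names(rows)
  utils::write.csv(rows[col_order], path, row.names = FALSE, quote = FALSE)
  path
}

contig_fixture_rows <- function() {
  data.frame(
    barcode = c("AAAC-1", "AAAC-1", "AAAG-1", "AAAT-1"),
    chain = c("TRB", "TRA", "TRB", "TRB"),
    v_gene = c("TRBV9", "TRAV2", "TRBV9", "TRBV5-1"),
    j_gene = c("TRBJ2-7", "TRAJ4", "TRBJ2-7", "TRBJ1-1"),
    cdr3 = c("CASSF", "CAVRF", "CASSF", "None"),
    cdr3_nt = c("TGTGC", "TGCGC", "TGTGC", "None"),
    productive = c("True", "True", "True", "False"),
    high_confidence = c("True", "True", "True", "False"),
    umis = c(4L, 2L, 3L, 1L),
    stringsAsFactors = FALSE
  )
}

write_mtx_fixture <- function(m, dir = tempfile(), transpose = FALSE) {
  dir.create(dir)
  on_disk <- if (transpose) Matrix::t(m) else m
  Matrix::writeMM(methods::as(on_disk, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  # on disk we store genes x cells when transpose = TRUE (10x layout)
  writeLines(colnames(m), file.path(dir, "features.tsv"))
  writeLines(rownames(m), file.path(dir, "barcodes.tsv"))
  dir
}

# Literal reimplementation of the expansion bins, enumerating all clones of
# a repertoire given as a vector of per-cell clone ids. Independent of
# classify_expansion(): pure if-chains on the printed category definitions.
oracle_classify_repertoire <- function(clone_ids) {
  tab <- table(clone_ids)
  den <- length(clone_ids)
  out <- character(length(tab))
  for (i in seq_along(tab)) {
    n <- as.integer(tab[[i]])
    pct <- 100 * n / den
    out[i] <- if (n == 1) "Single"
    else if (pct <= 0.1) "Small"
    else if (pct <= 1) "Medium"
    else if (pct <= 10) "Large"
    else "Hyperexpanded"
  }
  stats::setNames(out, names(tab))
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# assignments of ranks to group 1 (no ties assumed); the null distribution
# of the rank sum is symmetric, so the two-sided p is the probability of a
# rank sum at least as far from its mean as the observed one.
oracle_ranksum_exact <- function(x, y) {
  n <- length(x)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n)])
  combs <- utils::combn(length(r), n)
  sums <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n * (length(r) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

small_sim_config <- function(seed, ...) {
  args <- list(n_patients = 2L, cells_per_tissue = 300L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

# Repertoire frame built directly (no simulator) for unit tests
toy_frame <- function() {
  data.frame(
    barcode = sprintf("BC%02d", 1:10),
    patient = "P1",
    tissue = rep(c("PBMC", "plaque"), each = 5),
    cluster = c("C1", "C1", "C2", "C2", "C1", "C2", "C2", "C1", "C1", "C2"),
    subset = "all",
    clonotype = c("A", "A", "B", "C", "D", "A", "E", "E", "E", "F"),
    stringsAsFactors = FALSE
  )
}
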