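#' Default per-cluster expansion propensity weights
#'
#' Cluster labels with sampling weights for singleton and expanded-clone
#' cells. The default emulates a T-cell subclustering in which one effector
#' cluster (C3) concentrates expanded clones, a migratory cluster (C6)
#' shares clones with it, and naive/memory clusters (C0--C2) hold mostly
#' singletons.
#'
#' @return A `data.frame` with columns `cluster`, `weight_single`,
#'   `weight_expanded`.
#' @export
default_cluster_profiles <- function() {
  data.frame(
    cluster = c("C0", "C1", "C2", "C3", "C5", "C6"),
    weight_single = c(0.25, 0.20, 0.20, 0.10, 0.15, 0.10),
    weight_expanded = c(0.10, 0.05, 0.05, 0.45, 0.15, 0.20),
    stringsAsFactors = FALSE
  )
}

#' Default ADT count profiles per true cell type
#'
#' Negative-binomial mean counts for the CD3/CD4/CD8/CD14 antibody panel,
#' per true cell type, plus a common dispersion (`size`). Positive markers
#' are drawn around 400-500 counts and negative markers below 1, giving a
#' wide CLR separation so that gating recovers the true types with a
#' comfortable margin at the default thresholds.
#'
#' @return A list with `mu` (type x protein matrix) and `size` (NB
#'   dispersion).
#' @export
default_adt_profiles <- function() {
  mu <- rbind(
    CD4T = c(CD3 = 500, CD4 = 400, CD8 = 0.5, CD14 = 0.5),
    CD8T = c(CD3 = 500, CD4 = 0.5, CD8 = 400, CD14 = 0.5),
    double_positive = c(CD3 = 500, CD4 = 400, CD8 = 400, CD14 = 0.5),
    myeloid = c(CD3 = 0.5, CD4 = 5, CD8 = 0.5, CD14 = 400)
  )
  list(mu = mu, size = 50)
}

#' Configuration for the paired-repertoire simulator
#'
#' Bundles and validates every tunable of the synthetic generator. The
#' defaults describe a study-like scenario: three patients with matched
#' blood ("PBMC") and tissue ("plaque") samples of 2,000 cells each, about a
#' quarter of cells drawn into law-distributed clones, half of the expanded
#' clones shared across tissues with a 4-fold frequency enrichment that
#' lands on the tissue side three times out of four, cluster-structured
#' expansion, and matched expression/ADT matrices carrying planted QC
#' violations and CD4/CD8 gating structure.
#'
#' @param n_patients Number of patients (matched tissue pairs).
#' @param cells_per_tissue Cells emitted per (patient, tissue).
#' @param expanded_cell_fraction Fraction of each tissue's cells allocated
#'   to expanded (size >= 2) clones; a single value applies to both
#'   tissues, a length-2 vector gives (blood, tissue) fractions. The
#'   default plants 23% expanded cells in blood and 29% in the tissue
#'   compartment.
#' @param clone_size_law `"geometric"` or `"zipf"`, truncated at
#'   `cells_per_tissue`.
#' @param geom_p Success probability of the geometric law (sizes
#'   `1 + rgeom`).
#' @param zipf_alpha Exponent of the Zipf law (`P(k) proportional to
#'   k^-alpha`).
#' @param shared_clone_fraction Probability a law-drawn clone is present in
#'   both tissues of its patient.
#' @param enrichment_factor Frequency multiplier (>= 1) applied to a shared
#'   clone's count on its designated enriched side.
#' @param enriched_tissue_probability Probability the enriched side is the
#'   tissue (vs blood) compartment.
#' @param cluster_profiles See [default_cluster_profiles()].
#' @param hyperexpanded_spike When `TRUE`, one clone per patient 1 is forced
#'   above 10% of blood cells and to 5% of tissue cells, emulating a
#'   virus-specific hyperexpanded clone.
#' @param dual_tra_rate Probability a clone's cells carry two TRA chains.
#' @param tra_dropout Probability a clone's cells carry no TRA chain.
#' @param nonproductive_rate Per-cell probability of one extra
#'   non-productive TRA contig (noise removed by productive-only calling).
#' @param qc_violation_rates Named fractions `gene_count` and `flagged_gene`
#'   of cells planted to violate the corresponding QC rule.
#' @param adt_profiles See [default_adt_profiles()].
#' @param doublet_rate,myeloid_rate Per-cell probabilities of overriding the
#'   ADT phenotype with a CD4/CD8 double-positive or a CD14+ myeloid
#'   profile (emulating doublets and myeloid admixture carrying spurious
#'   VDJ calls); these cells are removed by the gates.
#' @param cd4_fraction Probability a T-cell clone is CD4 (vs CD8).
#' @param n_genes Genes in the expression matrix (>= 5001 when max-gene QC
#'   violations are planted).
#' @param mean_genes_per_cell Centre of the detected-genes distribution for
#'   QC-passing cells.
#' @param blood_label,tissue_label Tissue labels used throughout.
#' @param seed Mandatory RNG seed; every generator output is deterministic
#'   given the config.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 3L,
                              cells_per_tissue = 2000L,
                              expanded_cell_fraction = c(0.23, 0.29),
                              clone_size_law = c("geometric", "zipf"),
                              geom_p = 0.5,
                              zipf_alpha = 2.5,
                              shared_clone_fraction = 0.5,
                              enrichment_factor = 4,
                              enriched_tissue_probability = 0.75,
                              cluster_profiles = default_cluster_profiles(),
                              hyperexpanded_spike = FALSE,
                              dual_tra_rate = 0.1,
                              tra_dropout = 0.15,
                              nonproductive_rate = 0.05,
                              qc_violation_rates = c(gene_count = 0.02,
                                                     flagged_gene = 0.02),
                              adt_profiles = default_adt_profiles(),
                              doublet_rate = 0.02,
                              myeloid_rate = 0.15,
                              cd4_fraction = 0.7,
                              n_genes = 6000L,
                              mean_genes_per_cell = 800L,
                              blood_label = "PBMC",
                              tissue_label = "plaque",
                              seed) {
  clone_size_law <- match.arg(clone_size_law)
  if (missing(seed) || !is.numeric(seed)) {
    stop("a numeric seed is mandatory for reproducibility")
  }
  if (!length(expanded_cell_fraction) %in% c(1L, 2L)) {
    stop("expanded_cell_fraction must have length 1 or 2 (blood, tissue)")
  }
  expanded_cell_fraction <- stats::setNames(
    rep_len(as.numeric(expanded_cell_fraction), 2L),
    c(blood_label, tissue_label))
  probs <- c(expanded_cell_fraction, shared_clone_fraction,
             enriched_tissue_probability, dual_tra_rate, tra_dropout,
             nonproductive_rate, doublet_rate, myeloid_rate, cd4_fraction,
             qc_violation_rates)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  stopifnot(enrichment_factor >= 1, n_patients >= 1, cells_per_tissue >= 1,
            geom_p > 0, geom_p <= 1, zipf_alpha > 1,
            all(c("gene_count", "flagged_gene") %in%
                  names(qc_violation_rates)))
  if (clone_size_law == "geometric" && geom_p == 1 &&
      any(expanded_cell_fraction > 0)) {
    stop("degenerate clone-size law (every draw has size-1 support); ",
         "cannot allocate an expanded cell fraction")
  }
  stopifnot(is.data.frame(cluster_profiles),
            all(c("cluster", "weight_single", "weight_expanded") %in%
                  names(cluster_profiles)))
  structure(list(
    n_patients = as.integer(n_patients),
    cells_per_tissue = as.integer(cells_per_tissue),
    expanded_cell_fraction = expanded_cell_fraction,
    clone_size_law = clone_size_law, geom_p = geom_p,
    zipf_alpha = zipf_alpha,
    shared_clone_fraction = shared_clone_fraction,
    enrichment_factor = enrichment_factor,
    enriched_tissue_probability = enriched_tissue_probability,
    cluster_profiles = cluster_profiles,
    hyperexpanded_spike = isTRUE(hyperexpanded_spike),
    dual_tra_rate = dual_tra_rate, tra_dropout = tra_dropout,
    nonproductive_rate = nonproductive_rate,
    qc_violation_rates = qc_violation_rates,
    adt_profiles = adt_profiles,
    doublet_rate = doublet_rate, myeloid_rate = myeloid_rate,
    cd4_fraction = cd4_fraction,
    n_genes = as.integer(n_genes),
    mean_genes_per_cell = as.integer(mean_genes_per_cell),
    blood_label = blood_label, tissue_label = tissue_label,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# Clone sizes follow the configured law conditioned on size >= min_size
# (expanded clones have at least two cells by definition) and truncated at
# cells_per_tissue. For the geometric law the conditioning is exact by
# memorylessness: X | X >= m  ~  (m - 1) + Geom(p) on {1, 2, ...}.
draw_clone_size <- function(config, min_size = 2L) {
  n_max <- config$cells_per_tissue
  if (config$clone_size_law == "geometric") {
    min(min_size + stats::rgeom(1L, config$geom_p), n_max)
  } else {
    k <- min_size:max(min_size, min(n_max, 10000L))
    if (length(k) == 1) k else sample(k, 1L, prob = k^(-config$zipf_alpha))
  }
}

stochastic_round <- function(x) {
  f <- floor(x)
  as.integer(f + (stats::runif(length(x)) < (x - f)))
}

#' Sample clone sizes for one patient's tissues
#'
#' For each tissue, draws expanded-clone sizes from the configured law
#' (conditioned on size >= 2, truncated at `cells_per_tissue`) until the
#' expanded-cell budget `round(cells_per_tissue * expanded_cell_fraction)`
#' is filled (the last clone is trimmed to fit exactly), then appends
#' singletons up to `cells_per_tissue`. With an expanded fraction of 0 the
#' result is all ones, so the planted expanded-cell fraction is recovered
#' exactly from the emitted sizes.
#'
#' @param config A [simulation_config()]; note this low-level helper does
#'   not seed the RNG (callers seed once).
#' @return A named list (one element per tissue label) of integer clone-size
#'   vectors summing to `cells_per_tissue`.
#' @export
sample_clone_sizes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  one_tissue <- function(frac) {
    n <- config$cells_per_tissue
    budget <- round(n * frac)
    sizes <- integer(0)
    used <- 0L
    while (used < budget) {
      s <- min(draw_clone_size(config), budget - used)
      sizes <- c(sizes, s)
      used <- used + s
    }
    c(sizes, rep(1L, n - used))
  }
  out <- lapply(config$expanded_cell_fraction, one_tissue)
  names(out) <- names(config$expanded_cell_fraction)
  out
}

random_cdr3 <- function(n, existing = character(0)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  out <- character(0)
  while (length(out) < n) {
    len <- sample(6:18, n - length(out), replace = TRUE)
    cand <- vapply(len, function(l) {
      paste0("C", paste(sample(aa, l, replace = TRUE), collapse = ""), "F")
    }, character(1))
    out <- unique(c(out, setdiff(cand, existing)))
  }
  out[seq_len(n)]
}

random_nt <- function(aa_seq) {
  vapply(nchar(aa_seq) * 3L, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

trav_genes <- paste0("TRAV", c("1-1", "1-2", "2", "3", "8-1", "12-1",
                               "13-1", "17", "21", "29"))
traj_genes <- paste0("TRAJ", c("4", "9", "12", "23", "33", "42", "49"))
trbv_genes <- paste0("TRBV", c("2", "4-1", "5-1", "6-5", "7-2", "9", "11-2",
                               "19", "20-1", "28"))
trbj_genes <- paste0("TRBJ", c("1-1", "1-2", "2-1", "2-3", "2-5", "2-7"))

#' Generate a paired blood/tissue single-cell TCR repertoire
#'
#' Builds, per patient, a set of T-cell clones with known per-tissue sizes:
#' law-distributed clone sizes fill the expanded-cell budget of each tissue,
#' a configurable fraction of clones is shared across tissues with the
#' count on the designated enriched side scaled by `enrichment_factor`
#' (stochastically rounded), and remaining cells are unique singletons.
#' Every clone carries one TRB CDR3 and 0-2 TRA CDR3s (dropout / dual-TRA),
#' identical across its member cells; CDR3 strings are unique across clones.
#' Cells receive cluster labels from the expansion-propensity weights and a
#' true ADT phenotype (CD4 T, CD8 T, double-positive or myeloid).
#'
#' @param config A [simulation_config()]. The RNG is seeded from
#'   `config$seed`, so equal configs give identical output.
#' @return A list of class `tcrpair_sim` with elements `contigs` (contig
#'   table as from [read_contigs()]), `cells` (barcode, patient, tissue,
#'   cluster, clone_id, true_type, expanded), `ground_truth` (per clone:
#'   patient, clone_id, clonotype, size_pbmc, size_tissue, shared,
#'   enriched_tissue, expanded, spike) and `config`.
#' @export
generate_paired_repertoire <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$cells_per_tissue
  blood <- config$blood_label
  tissue <- config$tissue_label
  all_cdr3 <- character(0)
  clone_rows <- list()
  cell_rows <- list()
  contig_rows <- list()
  clone_counter <- 0L

  for (p in seq_len(config$n_patients)) {
    patient <- paste0("P", p)
    budget <- round(n * config$expanded_cell_fraction[c(blood, tissue)])
    clones <- list()

    if (config$hyperexpanded_spike && p == 1L) {
      nb <- ceiling(0.12 * n)
      nt <- ceiling(0.05 * n)
      clones[[length(clones) + 1]] <-
        list(count = stats::setNames(c(nb, nt), c(blood, tissue)),
             shared = TRUE, enriched = blood, spike = TRUE)
      budget[blood] <- max(0L, budget[blood] - nb)
      budget[tissue] <- max(0L, budget[tissue] - nt)
    }

    while (any(budget > 0)) {
      s <- draw_clone_size(config)
      shared <- stats::runif(1) < config$shared_clone_fraction &&
        all(budget > 0)
      if (shared) {
        enriched <- if (stats::runif(1) < config$enriched_tissue_probability)
          tissue else blood
        other <- setdiff(c(blood, tissue), enriched)
        cnt <- stats::setNames(integer(2), c(blood, tissue))
        cnt[other] <- min(s, budget[other])
        cnt[enriched] <- min(stochastic_round(s * config$enrichment_factor),
                             budget[enriched])
        if (cnt[enriched] == 0L) cnt[enriched] <- min(1L, budget[enriched])
        clones[[length(clones) + 1]] <-
          list(count = cnt, shared = TRUE, enriched = enriched,
               spike = FALSE)
      } else {
        open <- names(budget)[budget > 0]
        side <- if (length(open) == 1) open else
          sample(open, 1L, prob = budget[open])
        cnt <- stats::setNames(integer(2), c(blood, tissue))
        cnt[side] <- min(s, budget[side])
        clones[[length(clones) + 1]] <-
          list(count = cnt, shared = FALSE, enriched = NA_character_,
               spike = FALSE)
      }
      budget <- budget - clones[[length(clones)]]$count
      budget[budget < 0] <- 0
    }
    # singletons fill the remainder of each tissue
    placed <- Reduce(`+`, lapply(clones, `[[`, "count"),
                     accumulate = FALSE)
    if (is.null(placed)) placed <- stats::setNames(c(0L, 0L),
                                                   c(blood, tissue))
    for (lbl in c(blood, tissue)) {
      n_single <- n - placed[[lbl]]
      for (k in seq_len(n_single)) {
        cnt <- stats::setNames(integer(2), c(blood, tissue))
        cnt[lbl] <- 1L
        clones[[length(clones) + 1]] <-
          list(count = cnt, shared = FALSE, enriched = NA_character_,
               spike = FALSE)
      }
    }

    # chain sets and cell emission per clone
    n_clones <- length(clones)
    trb <- random_cdr3(n_clones, all_cdr3)
    all_cdr3 <- c(all_cdr3, trb)
    n_tra <- ifelse(stats::runif(n_clones) < config$dual_tra_rate, 2L,
             ifelse(stats::runif(n_clones) < config$tra_dropout, 0L, 1L))
    tra_pool <- random_cdr3(sum(n_tra), all_cdr3)
    all_cdr3 <- c(all_cdr3, tra_pool)
    tra_idx <- c(0L, cumsum(n_tra))
    cell_seq <- stats::setNames(c(0L, 0L), c(blood, tissue))

    for (ci in seq_len(n_clones)) {
      cl <- clones[[ci]]
      clone_counter <- clone_counter + 1L
      clone_id <- paste0("clone", clone_counter)
      tras <- if (n_tra[ci] > 0)
        tra_pool[(tra_idx[ci] + 1L):tra_idx[ci + 1L]] else character(0)
      key <- make_clonotype_key(tras, trb[ci])
      type <- if (stats::runif(1) < config$cd4_fraction) "CD4T" else "CD8T"
      v_a <- sample(trav_genes, length(tras), replace = TRUE)
      j_a <- sample(traj_genes, length(tras), replace = TRUE)
      v_b <- sample(trbv_genes, 1L)
      j_b <- sample(trbj_genes, 1L)
      expanded <- sum(cl$count) >= 2L
      weights <- if (expanded) config$cluster_profiles$weight_expanded
                 else config$cluster_profiles$weight_single
      clone_rows[[clone_counter]] <- data.frame(
        patient = patient, clone_id = clone_id, clonotype = key,
        size_pbmc = unname(cl$count[blood]),
        size_tissue = unname(cl$count[tissue]),
        shared = cl$shared, enriched_tissue = cl$enriched,
        true_type = type, expanded = expanded, spike = cl$spike,
        stringsAsFactors = FALSE)
      for (lbl in c(blood, tissue)) {
        cnt <- cl$count[[lbl]]
        if (cnt == 0L) next
        bcs <- sprintf("%s_%s_BC%06d", patient, lbl,
                       cell_seq[[lbl]] + seq_len(cnt))
        cell_seq[lbl] <- cell_seq[[lbl]] + cnt
        u <- stats::runif(cnt)
        override <- ifelse(u < config$doublet_rate, "double_positive",
                    ifelse(u < config$doublet_rate + config$myeloid_rate,
                           "myeloid", type))
        cell_rows[[length(cell_rows) + 1]] <- data.frame(
          barcode = bcs, patient = patient, tissue = lbl,
          cluster = sample(config$cluster_profiles$cluster, cnt,
                           replace = TRUE, prob = weights),
          clone_id = clone_id, true_type = override, expanded = expanded,
          stringsAsFactors = FALSE)
        chain_per_cell <- 1L + length(tras)
        contig_rows[[length(contig_rows) + 1]] <- data.frame(
          barcode = rep(bcs, each = chain_per_cell),
          chain = rep(c("TRB", rep("TRA", length(tras))), cnt),
          v_gene = rep(c(v_b, v_a), cnt),
          j_gene = rep(c(j_b, j_a), cnt),
          cdr3 = rep(c(trb[ci], tras), cnt),
          stringsAsFactors = FALSE)
      }
    }
  }

  cells <- do.call(rbind, cell_rows)
  contigs <- do.call(rbind, contig_rows)
  contigs$cdr3_nt <- random_nt(contigs$cdr3)
  contigs$productive <- TRUE
  contigs$high_confidence <- TRUE
  contigs$umis <- 1L + stats::rpois(nrow(contigs), 3)
  # non-productive noise contigs, removed by productive-only calling
  noisy <- cells$barcode[stats::runif(nrow(cells)) <
                           config$nonproductive_rate]
  if (length(noisy) > 0) {
    junk <- random_cdr3(length(noisy), all_cdr3)
    noise <- data.frame(
      barcode = noisy, chain = "TRA",
      v_gene = sample(trav_genes, length(noisy), replace = TRUE),
      j_gene = sample(traj_genes, length(noisy), replace = TRUE),
      cdr3 = paste0(substr(junk, 1, 4), "*",
                    substr(junk, 5, nchar(junk))),
      cdr3_nt = random_nt(junk), productive = FALSE,
      high_confidence = FALSE,
      umis = 1L + stats::rpois(length(noisy), 1),
      stringsAsFactors = FALSE)
    contigs <- rbind(contigs, noise)
  }
  contigs <- contigs[order(contigs$barcode, contigs$chain, contigs$cdr3), ,
                     drop = FALSE]
  rownames(contigs) <- NULL
  contigs <- contigs[c("barcode", "chain", "v_gene", "j_gene", "cdr3",
                       "cdr3_nt", "productive", "high_confidence", "umis")]
  ground_truth <- do.call(rbind, clone_rows)
  rownames(cells) <- NULL
  structure(list(contigs = contigs, cells = cells,
                 ground_truth = ground_truth, config = config),
            class = "tcrpair_sim")
}

#' Generate matched expression and ADT count matrices
#'
#' Draws, for the simulated cells, a sparse gene-count matrix and an ADT
#' count matrix consistent with the planted QC and gating structure:
#' QC-violating cells breach exactly the intended rule (detected gene count
#' outside the configured window, or a flagged stress gene at >= 2% of
#' counts) while all other cells satisfy every rule, and ADT counts are
#' drawn from the per-type negative-binomial profiles so true CD4 T cells
#' pass the CD4 gate and fail the CD8 gate after CLR normalization (and
#' mirrored for CD8 T cells).
#'
#' @param config A [simulation_config()].
#' @param cells Cell table from [generate_paired_repertoire()].
#' @param qc A [qc_thresholds()] object the violations are planted against.
#' @return A list with `counts` (sparse cells x genes), `adt` (cells x
#'   proteins raw counts) and `cell_flags` (barcode, `qc_violation` in
#'   none/low_genes/high_genes/flagged_gene).
#' @export
generate_expression_matrices <- function(config, cells,
                                         qc = qc_thresholds()) {
  stopifnot(inherits(config, "simulation_config"))
  n_genes <- config$n_genes
  rate_gc <- config$qc_violation_rates[["gene_count"]]
  rate_fg <- config$qc_violation_rates[["flagged_gene"]]
  if (rate_gc > 0 && n_genes < qc$max_genes + 1L) {
    stop("n_genes must exceed max_genes (", qc$max_genes,
         ") to construct max-gene QC violations")
  }
  n_cells <- nrow(cells)
  flagged <- qc$flagged_genes
  genes <- c(flagged, sprintf("GENE%05d", seq_len(n_genes - length(flagged))))
  body_idx <- (length(flagged) + 1L):n_genes

  u <- stats::runif(n_cells)
  violation <- ifelse(u < rate_gc / 2, "low_genes",
               ifelse(u < rate_gc, "high_genes",
               ifelse(u < rate_gc + rate_fg, "flagged_gene", "none")))

  m <- config$mean_genes_per_cell
  lo <- max(qc$min_genes + 50L, round(0.6 * m))
  hi <- min(qc$max_genes - 50L, n_genes - length(flagged) - 1L,
            round(1.4 * m))
  k <- sample(lo:hi, n_cells, replace = TRUE)
  k[violation == "low_genes"] <-
    sample(20L:(qc$min_genes - 1L), sum(violation == "low_genes"),
           replace = TRUE)
  k[violation == "high_genes"] <-
    sample((qc$max_genes + 1L):min(n_genes, qc$max_genes + 200L),
           sum(violation == "high_genes"), replace = TRUE)

  ii <- vector("list", n_cells)
  jj <- vector("list", n_cells)
  xx <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    idx <- sample(body_idx, k[i])
    cnt <- 1L + stats::rpois(k[i], 0.4)
    if (violation[i] == "flagged_gene") {
      total <- sum(cnt)
      target_pct <- qc$max_flagged_pct / 100 + 0.005
      f <- ceiling(target_pct * total / (1 - target_pct)) + 1L
      g <- 1L + (i %% length(flagged))
      idx <- c(idx, g)
      cnt <- c(cnt, f)
    }
    ii[[i]] <- rep.int(i, length(idx))
    jj[[i]] <- idx
    xx[[i]] <- cnt
  }
  counts <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(n_cells, n_genes),
    dimnames = list(cells$barcode, genes))

  prof <- config$adt_profiles
  proteins <- colnames(prof$mu)
  adt <- matrix(0L, n_cells, length(proteins),
                dimnames = list(cells$barcode, proteins))
  type <- cells$true_type
  for (tt in rownames(prof$mu)) {
    sel <- type == tt
    if (!any(sel)) next
    for (pr in proteins) {
      adt[sel, pr] <- stats::rnbinom(sum(sel), mu = prof$mu[tt, pr],
                                     size = prof$size)
    }
  }
  list(counts = counts, adt = adt,
       cell_flags = data.frame(barcode = cells$barcode,
                               qc_violation = violation,
                               stringsAsFactors = FALSE))
}

#' Write a simulated dataset to disk in standard formats
#'
#' Emits the simulated repertoire as the same files the readers consume:
#' one 10x-dialect contig csv per (patient, tissue), a MatrixMarket count
#' matrix (genes x cells, the 10x on-disk orientation) with features/barcode
#' line lists, the ADT counts as csv, the cell table, the ground-truth clone
#' ledger, and the configuration as JSON. Re-reading through the package
#' readers reproduces the in-memory objects.
#'
#' @param sim Output of [generate_paired_repertoire()].
#' @param expr Output of [generate_expression_matrices()] (optional; when
#'   `NULL` only repertoire files are written).
#' @param out_dir Output directory; created if absent. A non-empty existing
#'   directory is refused unless `overwrite = TRUE`.
#' @param overwrite Allow writing into a non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
emit_dataset <- function(sim, expr = NULL, out_dir, overwrite = FALSE) {
  stopifnot(inherits(sim, "tcrpair_sim"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stop("output directory is not empty (use overwrite = TRUE): ", out_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cells <- sim$cells
  contigs <- sim$contigs
  for (patient in unique(cells$patient)) {
    for (lbl in unique(cells$tissue)) {
      bcs <- cells$barcode[cells$patient == patient & cells$tissue == lbl]
      sub <- contigs[contigs$barcode %in% bcs, , drop = FALSE]
      tenx <- data.frame(
        barcode = sub$barcode, is_cell = "True",
        contig_id = paste0(sub$barcode, "_contig_",
                           seq_len(nrow(sub))),
        high_confidence = ifelse(sub$high_confidence, "True", "False"),
        chain = sub$chain, v_gene = sub$v_gene, d_gene = "None",
        j_gene = sub$j_gene, c_gene = paste0(substr(sub$chain, 1, 3), "C"),
        full_length = "True",
        productive = ifelse(sub$productive, "True", "False"),
        cdr3 = ifelse(is.na(sub$cdr3), "None", sub$cdr3),
        cdr3_nt = ifelse(is.na(sub$cdr3_nt), "None", sub$cdr3_nt),
        reads = sub$umis * 10L, umis = sub$umis,
        stringsAsFactors = FALSE)
      utils::write.csv(tenx,
                       file.path(out_dir, sprintf("contigs_%s_%s.csv",
                                                  patient, lbl)),
                       row.names = FALSE, quote = FALSE)
    }
  }
  write_table(cells, file.path(out_dir, "cells.csv"),
              key_cols = c("patient", "tissue", "barcode"))
  write_table(sim$ground_truth, file.path(out_dir, "ground_truth.csv"),
              key_cols = c("patient", "clone_id"))
  cfg <- sim$config
  cfg$adt_profiles$mu <- as.data.frame(cfg$adt_profiles$mu)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  if (!is.null(expr)) {
    Matrix::writeMM(Matrix::t(expr$counts),
                    file.path(out_dir, "matrix.mtx"))
    writeLines(paste(colnames(expr$counts), colnames(expr$counts),
                     "Gene Expression", sep = "\t"),
               file.path(out_dir, "features.tsv"))
    writeLines(rownames(expr$counts), file.path(out_dir, "barcodes.tsv"))
    adt_df <- data.frame(barcode = rownames(expr$adt),
                         as.data.frame(expr$adt),
                         check.names = FALSE, stringsAsFactors = FALSE)
    write_table(adt_df, file.path(out_dir, "adt.csv"),
                key_cols = "barcode")
    write_table(expr$cell_flags, file.path(out_dir, "cell_flags.csv"),
                key_cols = "barcode")
  }
  invisible(out_dir)
}
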