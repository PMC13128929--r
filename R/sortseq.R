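#' UMI counts container for plate-based single-cell data
#'
#' Wraps a genes x cells UMI count matrix with the per-cell plate and
#' genotype annotations of a SORT-seq experiment. Gene order and cell
#' order are canonicalized (sorted by symbol, and by plate then barcode)
#' so downstream results do not depend on input file ordering.
#'
#' @param counts genes x cells matrix (base or [Matrix::Matrix]), rownames
#'   = gene symbols; non-negative, finite.
#' @param cells data frame with columns `barcode`, `plate_id`, `genotype`,
#'   one row per column of `counts` (matched by position).
#' @param normalized logical; `TRUE` once plate-depth scaling has run.
#' @return object of class `counts_matrix`.
#' @export
counts_matrix <- function(counts, cells, normalized = FALSE) {
  stopifnot(!is.null(rownames(counts)), nrow(cells) == ncol(counts),
            all(c("barcode", "plate_id", "genotype") %in% names(cells)))
  if (anyDuplicated(rownames(counts))) {
    stop("gene symbols must be unique", call. = FALSE)
  }
  key <- paste(cells$plate_id, cells$barcode, sep = ":")
  if (anyDuplicated(key)) {
    stop("duplicate (plate_id, barcode) pairs", call. = FALSE)
  }
  if (any(counts < 0) || any(!is.finite(as.matrix(counts)))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  cells <- tibble::as_tibble(cells)
  # radix ordering is locale-independent: canonical order must not depend
  # on the session's collation settings
  ord_c <- order(cells$plate_id, cells$barcode, method = "radix")
  ord_g <- order(rownames(counts), method = "radix")
  counts <- counts[ord_g, ord_c, drop = FALSE]
  cells <- cells[ord_c, , drop = FALSE]
  colnames(counts) <- paste(cells$plate_id, cells$barcode, sep = ":")
  structure(list(counts = counts, cells = cells,
                 normalized = isTRUE(normalized)),
            class = "counts_matrix")
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat(sprintf("<counts_matrix> %d genes x %d cells, %d plate(s)%s\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cells$plate_id)),
              if (x$normalized) ", plate-normalized" else ""))
  invisible(x)
}

#' @export
dim.counts_matrix <- function(x) dim(x$counts)

#' Per-cell total UMI counts
#' @param x a `counts_matrix`.
#' @return named numeric vector, one entry per cell.
#' @export
cell_totals <- function(x) {
  stopifnot(inherits(x, "counts_matrix"))
  Matrix::colSums(x$counts)
}

#' Read a counts matrix from MTX triplet files
#'
#' Standard MatrixMarket layout: the sparse matrix, a genes file (one
#' symbol per line, first column used) and a cells table with `barcode`,
#' `plate_id` and `genotype` columns (TSV with header).
#'
#' @param mtx,genes_file,cells_file file paths.
#' @return a [counts_matrix].
#' @export
read_counts_mtx <- function(mtx, genes_file, cells_file) {
  m <- as.matrix(Matrix::readMM(mtx))
  genes <- utils::read.table(genes_file, sep = "\t",
                             stringsAsFactors = FALSE)[, 1]
  cells <- utils::read.table(cells_file, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  rownames(m) <- genes
  counts_matrix(m, cells)
}

#' Write a counts matrix as MTX triplet files
#' @param x a `counts_matrix`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(x, dir) {
  stopifnot(inherits(x, "counts_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "genes.tsv"))
  utils::write.table(x$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

# ---- normalization and QC ----------------------------------------------

#' Normalize UMI counts across plates
#'
#' Each plate's median per-cell total UMI count (over wells with at least
#' one count) is computed and every cell's counts are scaled by
#' `max(medians) / own plate median`, i.e. all plates are brought up to
#' the plate with the highest median depth.
#'
#' @param x a `counts_matrix`.
#' @return a `counts_matrix` with `normalized = TRUE`.
#' @export
normalize_plates <- function(x) {
  stopifnot(inherits(x, "counts_matrix"))
  totals <- cell_totals(x)
  plates <- x$cells$plate_id
  med <- vapply(split(totals, plates), function(v) {
    v <- v[v > 0]
    if (length(v) == 0) return(NA_real_)
    stats::median(v)
  }, numeric(1))
  if (any(is.na(med))) {
    stop(sprintf("plate(s) with no non-zero cells: %s",
                 paste(names(med)[is.na(med)], collapse = ", ")),
         call. = FALSE)
  }
  factors <- max(med) / med
  x$counts <- sweep(x$counts, 2, factors[as.character(plates)], `*`)
  x$normalized <- TRUE
  x
}

#' Quality-control filter on total UMI and mitochondrial fraction
#'
#' Keeps cells with a total UMI count inside `[umi_min, umi_max]`
#' (inclusive) and a mitochondrial percentage strictly below `mito_max`.
#' Mitochondrial genes are identified by a case-insensitive symbol prefix.
#' Applied after plate normalization, matching the stated order of the
#' workflow.
#'
#' @param x a plate-normalized `counts_matrix`.
#' @param umi_min,umi_max inclusive total-UMI bounds (default 1000, 8000).
#' @param mito_max strict upper bound on the mitochondrial percentage (10).
#' @param mito_prefix gene-symbol prefix of mitochondrial genes (`"mt-"`).
#' @return list with `counts` (retained cells) and `qc`, a tibble of
#'   per-cell records: `cell`, `barcode`, `plate_id`, `total_umi`,
#'   `mito_pct`, `pass`.
#' @export
qc_filter <- function(x, umi_min = 1000, umi_max = 8000, mito_max = 10,
                      mito_prefix = "mt-") {
  stopifnot(inherits(x, "counts_matrix"))
  if (!x$normalized) {
    stop("counts must be plate-normalized before QC (run normalize_plates())",
         call. = FALSE)
  }
  totals <- cell_totals(x)
  mito <- startsWith(tolower(rownames(x$counts)), tolower(mito_prefix))
  if (!any(mito)) {
    warning(sprintf("no gene symbol starts with '%s'; mito_pct set to 0",
                    mito_prefix))
    mito_pct <- rep(0, ncol(x$counts))
  } else {
    mito_tot <- Matrix::colSums(x$counts[mito, , drop = FALSE])
    mito_pct <- ifelse(totals > 0, 100 * mito_tot / totals, 0)
  }
  pass <- unname(totals >= umi_min & totals <= umi_max & mito_pct < mito_max)
  qc <- tibble::tibble(cell = colnames(x$counts),
                       barcode = x$cells$barcode,
                       plate_id = x$cells$plate_id,
                       total_umi = as.numeric(totals),
                       mito_pct = as.numeric(mito_pct),
                       pass = pass)
  kept <- x
  kept$counts <- x$counts[, pass, drop = FALSE]
  kept$cells <- x$cells[pass, , drop = FALSE]
  list(counts = kept, qc = qc)
}

#' Marker-rule cell typing
#'
#' A QC-passing cell is endothelial when the endothelial marker has a UMI
#' count above zero and the pericyte marker does not, a pericyte in the
#' converse case, and excluded when it expresses both markers or neither.
#'
#' @param x a `counts_matrix` (QC-filtered).
#' @param ec_marker,pc_marker marker gene symbols (`Cldn5`, `Pdgfrb`).
#' @return tibble: `cell`, `barcode`, `plate_id`, `genotype`, `call` in
#'   `{endothelial, pericyte, excluded}`.
#' @export
assign_cell_types <- function(x, ec_marker = "Cldn5", pc_marker = "Pdgfrb") {
  stopifnot(inherits(x, "counts_matrix"))
  missing <- setdiff(c(ec_marker, pc_marker), rownames(x$counts))
  if (length(missing)) {
    stop(sprintf("marker gene(s) not in matrix: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ec <- as.numeric(x$counts[ec_marker, ]) > 0
  pc <- as.numeric(x$counts[pc_marker, ]) > 0
  call <- dplyr::case_when(ec & !pc ~ "endothelial",
                           pc & !ec ~ "pericyte",
                           TRUE ~ "excluded")
  tibble::tibble(cell = colnames(x$counts), barcode = x$cells$barcode,
                 plate_id = x$cells$plate_id, genotype = x$cells$genotype,
                 call = call)
}

#' Log-normalize UMI counts
#'
#' Per cell, counts are scaled to `scale_factor` total and log-transformed:
#' `log(1 + x * scale_factor / total)` (natural log, Seurat convention).
#'
#' @param x a `counts_matrix` with no zero-total cells (guaranteed after QC).
#' @param scale_factor library-size scale, default `1e4`.
#' @return genes x cells matrix of log-normalized expression.
#' @export
log_normalize <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "counts_matrix"))
  totals <- cell_totals(x)
  if (any(totals == 0)) {
    stop("cells with zero total UMI cannot be log-normalized", call. = FALSE)
  }
  m <- sweep(as.matrix(x$counts), 2, totals, `/`) * scale_factor
  log1p(m)
}

#' Per-gene z-scaling of an expression matrix
#'
#' Centers and scales each gene to mean 0, sd 1 (heatmap rendering);
#' zero-variance genes map to 0.
#'
#' @param expr genes x cells matrix.
#' @return matrix of the same shape.
#' @export
z_scale <- function(expr) {
  mu <- rowMeans(expr)
  sd <- apply(expr, 1, stats::sd)
  sd[sd == 0] <- 1
  sweep(sweep(expr, 1, mu, `-`), 1, sd, `/`)
}

# ---- differential expression -------------------------------------------

#' Differential expression by logistic regression and likelihood-ratio test
#'
#' For each gene, group membership is regressed on the log-normalized
#' expression (logistic regression fit by iteratively reweighted least
#' squares, max 25 iterations, tolerance 1e-8); the p-value is the
#' chi-squared(1) likelihood-ratio test of the expression term against the
#' intercept-only model. The log2 fold change compares group means on the
#' de-logged scale with a pseudo-count:
#' `log2((mean(expm1(expr[, g1])) + eps) / (mean(expm1(expr[, g2])) + eps))`.
#' A gene is significant at `p < p_cutoff` and `|log2fc| > fc_cutoff`.
#'
#' @param expr genes x cells log-normalized matrix.
#' @param group factor/character vector, one label per column of `expr`.
#' @param group1,group2 the two labels to compare (group1 vs group2).
#' @param fc_pseudo pseudo-count on the expm1-scale group means (1).
#' @param p_cutoff,fc_cutoff significance cutoffs (0.05 and 1).
#' @param min_pct optional prefilter: minimum fraction of cells expressing
#'   the gene in either group (0 = off).
#' @param logfc_prefilter optional prefilter on `|log2fc|` before fitting
#'   (0 = off).
#' @return tibble: `gene`, `log2fc`, `p_value`, `significant`,
#'   `converged`, `pct_1`, `pct_2`.
#' @export
differential_expression <- function(expr, group, group1, group2,
                                    fc_pseudo = 1, p_cutoff = 0.05,
                                    fc_cutoff = 1, min_pct = 0,
                                    logfc_prefilter = 0) {
  stopifnot(length(group) == ncol(expr))
  i1 <- which(group == group1)
  i2 <- which(group == group2)
  if (length(i1) < 3 || length(i2) < 3) {
    stop("both groups need at least 3 cells", call. = FALSE)
  }
  cells <- c(i1, i2)
  y <- rep(c(1, 0), c(length(i1), length(i2)))
  e1 <- expr[, i1, drop = FALSE]
  e2 <- expr[, i2, drop = FALSE]
  pct1 <- rowMeans(e1 > 0)
  pct2 <- rowMeans(e2 > 0)
  keep <- (pct1 > 0 | pct2 > 0) & pmax(pct1, pct2) >= min_pct
  m1 <- rowMeans(expm1(e1))
  m2 <- rowMeans(expm1(e2))
  l2fc <- log2((m1 + fc_pseudo) / (m2 + fc_pseudo))
  keep <- keep & abs(l2fc) >= logfc_prefilter
  genes <- rownames(expr)[keep]
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 25)
  fam <- stats::binomial()
  res <- purrr::map_dfr(genes, function(g) {
    xg <- expr[g, cells]
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, xg), y, family = fam, control = ctrl))
    stat <- max(0, fit$null.deviance - fit$deviance)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    tibble::tibble(gene = g, p_value = max(p, .Machine$double.xmin),
                   converged = isTRUE(fit$converged))
  })
  if (nrow(res) == 0) {
    return(tibble::tibble(gene = character(), log2fc = numeric(),
                          p_value = numeric(), significant = logical(),
                          converged = logical(), pct_1 = numeric(),
                          pct_2 = numeric()))
  }
  res$log2fc <- unname(l2fc[res$gene])
  res$pct_1 <- unname(pct1[res$gene])
  res$pct_2 <- unname(pct2[res$gene])
  res$significant <- res$p_value < p_cutoff & abs(res$log2fc) > fc_cutoff
  out <- res[, c("gene", "log2fc", "p_value", "significant", "converged",
                 "pct_1", "pct_2")]
  out <- out[order(out$p_value, out$gene), ]
  class(out) <- c("hyaloid_de", class(out))
  attr(out, "groups") <- c(group1, group2)
  attr(out, "n_cells") <- c(length(i1), length(i2))
  attr(out, "cutoffs") <- c(p = p_cutoff, fc = fc_cutoff)
  out
}

# ---- enrichment and panels ----------------------------------------------

#' Hypergeometric gene-set enrichment
#'
#' Over-representation test of an input gene list against gene sets, using
#' the hypergeometric upper tail `P(X >= k)` with population size
#' `N = |universe|`, `K = |set within universe|` successes and `n = |input|`
#' draws. A set is reported when the overlap is at least `min_overlap`
#' (default 5) and `p < p_cutoff` (default 0.01), both raw.
#'
#' @param input_genes character vector of genes of interest (e.g. DEG).
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @param universe character vector of all assayed genes; must contain
#'   `input_genes`.
#' @param min_overlap,p_cutoff reporting criteria.
#' @return tibble: `set_name`, `overlap_k`, `set_size_K`, `input_size_n`,
#'   `universe_N`, `p_value`, `reported`, `overlap_genes` (list-column).
#' @export
hypergeometric_enrichment <- function(input_genes, gene_sets, universe,
                                      min_overlap = 5, p_cutoff = 0.01) {
  input_genes <- unique(input_genes)
  universe <- unique(universe)
  if (length(universe) == 0 || length(input_genes) == 0) {
    stop("universe and input gene list must be non-empty", call. = FALSE)
  }
  if (!all(input_genes %in% universe)) {
    stop("input genes must be a subset of the universe", call. = FALSE)
  }
  N <- length(universe)
  n <- length(input_genes)
  purrr::imap_dfr(gene_sets, function(set, nm) {
    set <- intersect(unique(set), universe)
    K <- length(set)
    ov <- intersect(input_genes, set)
    k <- length(ov)
    p <- if (K == 0) 1 else {
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    }
    tibble::tibble(set_name = nm, overlap_k = k, set_size_K = K,
                   input_size_n = n, universe_N = N, p_value = p,
                   reported = k >= min_overlap & p < p_cutoff,
                   overlap_genes = list(sort(ov)))
  })
}

#' Screen differentially expressed genes against marker panels
#'
#' Intersects the significant DEG with each supplied panel (apoptosis
#' regulators, endothelial/mesenchymal markers, WNT, TGF-beta, ...) and
#' reports per-gene direction in group 1.
#'
#' @param deg tibble from [differential_expression()].
#' @param panels named list of character vectors (GMT-style).
#' @return tibble: `panel`, `gene`, `log2fc`, `p_value`, `direction`
#'   (`up_in_group1`/`down_in_group1`).
#' @export
panel_screen <- function(deg, panels) {
  sig <- deg[deg$significant, , drop = FALSE]
  purrr::imap_dfr(panels, function(set, nm) {
    if (length(set) == 0) {
      warning(sprintf("panel '%s' is empty", nm))
      return(NULL)
    }
    hit <- sig[sig$gene %in% set, , drop = FALSE]
    if (nrow(hit) == 0) return(NULL)
    tibble::tibble(panel = nm, gene = hit$gene, log2fc = hit$log2fc,
                   p_value = hit$p_value,
                   direction = ifelse(hit$log2fc > 0, "up_in_group1",
                                      "down_in_group1"))
  })
}

#' Read and write GMT gene-set files
#'
#' Reading wraps [fgsea::gmtPathways()]; writing emits the standard
#' tab-separated layout (name, description, genes...).
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param gene_sets named list of character vectors.
#' @param description description field (recycled).
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  lines <- purrr::imap_chr(gene_sets, function(set, nm) {
    paste(c(nm, description, set), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}
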