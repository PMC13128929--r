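# Shared raster builders for imaging tests. All fixtures are generated in
# code; coordinates are (row, col), 1-based while building, matching the
# package's internal matrix convention.

# distance of all pixels of an n x n grid to segment a-b (1-based coords)
seg_dist_grid <- function(n, a, b) {
  g <- cbind(rep(seq_len(n), n), rep(seq_len(n), each = n))
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) rep(0, nrow(g)) else {
    pmin(pmax(((g[, 1] - a[1]) * ab[1] + (g[, 2] - a[2]) * ab[2]) / len2,
              0), 1)
  }
  matrix(sqrt((a[1] + t * ab[1] - g[, 1])^2 +
                (a[2] + t * ab[2] - g[, 2])^2), n, n)
}

# binary disc in an n x n matrix
disc_mask <- function(n, center, radius) {
  g <- cbind(rep(seq_len(n), n), rep(seq_len(n), each = n))
  matrix((g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 <= radius^2, n, n)
}

# axis-aligned filled ellipse (semi-axes along rows/cols)
ellipse_mask <- function(n, center, semi_row, semi_col) {
  g <- cbind(rep(seq_len(n), n), rep(seq_len(n), each = n))
  matrix(((g[, 1] - center[1]) / semi_row)^2 +
           ((g[, 2] - center[2]) / semi_col)^2 <= 1, n, n)
}

# intensity image from a binary mask
mask_to_channel <- function(mask, background = 5, signal = 100) {
  ifelse(mask, background + signal, background) + 0
}

# one-channel flatmount image from a mask
mask_image <- function(mask, channel = "DAPI", pixel_size = 1,
                       background = 5, signal = 100) {
  ch <- list(mask_to_channel(mask, background, signal))
  names(ch) <- channel
  flatmount_image(ch, pixel_size = pixel_size)
}

# vessel_mask object directly from a logical matrix (bypasses thresholding)
as_vessel_mask <- function(mask, pixel_size = 1, channel = "CD31") {
  structure(list(mask = mask, source_channel = channel,
                 pixel_size = pixel_size, fill_state = TRUE),
            class = "vessel_mask")
}

# Gaussian spot added in place
add_spot <- function(m, center, sigma = 1.5, amplitude = 100) {
  n <- nrow(m)
  ext <- ceiling(4 * sigma)
  rr <- max(1, center[1] - ext):min(n, center[1] + ext)
  cc <- max(1, center[2] - ext):min(ncol(m), center[2] + ext)
  m[rr, cc] <- m[rr, cc] +
    amplitude * outer(rr - center[1], cc - center[2],
                      function(dr, dc) exp(-(dr^2 + dc^2) / (2 * sigma^2)))
  m
}

# match called nuclei to ground-truth nuclei by nearest centroid
match_nuclei_truth <- function(nuclei, truth) {
  vapply(seq_len(nrow(nuclei)), function(i) {
    which.min((truth$row - nuclei$centroid_row[i])^2 +
                (truth$col - nuclei$centroid_col[i])^2)
  }, integer(1))
}

# regressing-segment F1 against generator truth
regression_f1 <- function(result, truth) {
  ms <- match_segments(result$graph, truth)
  calls <- result$segment_calls
  called_edges <- calls$edge_id[calls$status == "regressing"]
  called_true <- unique(ms$true_edge[ms$edge_id %in% called_edges])
  true_reg <- truth$network_edges$edge[truth$network_edges$regressing]
  tp <- length(intersect(called_true, true_reg))
  prec <- if (length(called_edges) == 0) 1 else tp / length(called_edges)
  rec <- if (length(true_reg) == 0) 1 else tp / length(true_reg)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# small counts_matrix with fully specified totals on one plate
toy_counts <- function(totals, mito_counts = 0, genotype = "control",
                       extra_genes = NULL) {
  n <- length(totals)
  mito_counts <- rep_len(mito_counts, n)
  body <- totals - mito_counts
  stopifnot(all(body >= 0))
  counts <- rbind(
    Cldn5 = rep(1, n),
    Pdgfrb = rep(0, n),
    `mt-Nd1` = mito_counts,
    Filler = body - 1
  )
  if (!is.null(extra_genes)) counts <- rbind(counts, extra_genes)
  cells <- tibble::tibble(barcode = sprintf("BC%03d", seq_len(n)),
                          plate_id = "p1",
                          genotype = rep_len(genotype, n))
  counts_matrix(counts, cells)
}
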