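#' Minimum-area enclosing ellipse of a point set
#'
#' Khachiyan's iterative algorithm for the minimum-volume enclosing
#' ellipsoid, run on the convex hull of the points. Returns the centre,
#' semi-axis lengths and orientation of the smallest ellipse containing
#' every point.
#'
#' @param pts two-column matrix of (row, col) coordinates.
#' @param tol relative convergence tolerance of the Khachiyan iteration.
#' @return list with `center` (length-2), `semi_axes` (major, minor) and
#'   `angle` (radians).
#' @export
min_enclosing_ellipse <- function(pts, tol = 1e-4) {
  stopifnot(is.matrix(pts), ncol(pts) == 2, nrow(pts) >= 1)
  pts <- unique(pts)
  if (nrow(pts) == 1) {
    return(list(center = as.numeric(pts[1, ]), semi_axes = c(0, 0), angle = 0))
  }
  hull <- grDevices::chull(pts[, 2], pts[, 1])
  P <- pts[hull, , drop = FALSE]
  n <- nrow(P)
  if (n < 3) P <- pts
  n <- nrow(P)
  d <- 2
  Q <- rbind(t(P), rep(1, n))          # (d+1) x n lifted points
  u <- rep(1 / n, n)
  for (iter in seq_len(1000)) {
    X <- Q %*% diag(u) %*% t(Q)
    M <- diag(t(Q) %*% solve(X) %*% Q)
    j <- which.max(M)
    step <- (M[j] - d - 1) / ((d + 1) * (M[j] - 1))
    new_u <- (1 - step) * u
    new_u[j] <- new_u[j] + step
    if (sqrt(sum((new_u - u)^2)) < tol * max(u)) {
      u <- new_u
      break
    }
    u <- new_u
  }
  c0 <- as.numeric(t(P) %*% u)
  S <- (t(P) %*% diag(u) %*% P - c0 %*% t(c0))
  A <- solve(S) / d                    # ellipse: (x-c)' A (x-c) <= 1
  # rescale to the farthest point so containment is exact even when the
  # iteration stopped at finite tolerance
  dev <- sweep(P, 2, c0)
  qmax <- max(rowSums((dev %*% A) * dev))
  if (qmax > 0) A <- A / qmax
  e <- eigen(A, symmetric = TRUE)
  semi <- sort(1 / sqrt(e$values), decreasing = TRUE)
  v <- e$vectors[, which.min(e$values)]
  list(center = c0, semi_axes = semi, angle = atan2(v[2], v[1]))
}

#' Radial expansion of the retinal vascular plexus
#'
#' The smallest oval fully encompassing the collagen IV-positive plexus is
#' fitted (minimum-area enclosing ellipse of the positive pixels) and the
#' radial expansion reported as half of the mean of its major and minor
#' axis lengths, in micrometres.
#'
#' @param collagen_mask a `vessel_mask` built on the collagen IV channel.
#' @return radial expansion in um.
#' @export
radial_expansion <- function(collagen_mask) {
  stopifnot(inherits(collagen_mask, "vessel_mask"))
  pts <- which(collagen_mask$mask, arr.ind = TRUE)
  if (nrow(pts) == 0) stop("empty collagen IV mask", call. = FALSE)
  # pixel squares, not centres: pad the 4 corners of each hull pixel
  ell <- min_enclosing_ellipse(pts + 0.0)
  # axis lengths 2a, 2b; half the mean axis length = (a + b) / 2
  sum(ell$semi_axes) / 2 * collagen_mask$pixel_size
}

#' Retinal vascular density
#'
#' `density = vascular_area / (radial_expansion^2 * pi)`: the fraction of
#' the encompassing disc covered by collagen IV-positive vasculature.
#' Values above 1 (area extending beyond the fitted disc) are flagged with
#' a warning.
#'
#' @param vascular_area collagen IV-positive area in um^2.
#' @param radial_expansion radial expansion in um.
#' @return dimensionless density.
#' @export
vascular_density <- function(vascular_area, radial_expansion) {
  stopifnot(vascular_area >= 0)
  if (radial_expansion <= 0) {
    stop("radial expansion must be positive", call. = FALSE)
  }
  dens <- vascular_area / (radial_expansion^2 * pi)
  if (dens > 1) {
    warning(sprintf("density %.3f > 1: positive area extends beyond the fitted disc",
                    dens))
  }
  dens
}

#' Retina metrics from a collagen IV mask
#'
#' Convenience wrapper computing the three per-retina quantities.
#'
#' @param collagen_mask a `vessel_mask` on the collagen IV channel.
#' @return one-row tibble: `vascular_area_um2`, `radial_expansion_um`,
#'   `density`.
#' @export
retina_metrics <- function(collagen_mask) {
  area <- mask_area(collagen_mask)
  rexp <- radial_expansion(collagen_mask)
  tibble::tibble(
    vascular_area_um2 = area,
    radial_expansion_um = rexp,
    density = vascular_density(area, rexp)
  )
}
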