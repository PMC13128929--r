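#' @keywords internal
# run code with a locally fixed RNG state, restoring the caller's stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# distance from points (n x 2) to a segment a-b (all in pixel coords)
point_segment_distance <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((a[1] + t * ab[1] - pts[, 1])^2 + (a[2] + t * ab[2] - pts[, 2])^2)
}

# exact Delaunay edges by the empty-circumcircle test; n is small (~10-20)
delaunay_edges <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 3)
  edges <- matrix(integer(0), 0, 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    p1 <- pts[i, ]; p2 <- pts[j, ]; p3 <- pts[k, ]
    d <- 2 * (p1[1] * (p2[2] - p3[2]) + p2[1] * (p3[2] - p1[2]) +
                p3[1] * (p1[2] - p2[2]))
    if (abs(d) < 1e-9) next  # collinear
    ux <- (sum(p1^2) * (p2[2] - p3[2]) + sum(p2^2) * (p3[2] - p1[2]) +
             sum(p3^2) * (p1[2] - p2[2])) / d
    uy <- (sum(p1^2) * (p3[1] - p2[1]) + sum(p2^2) * (p1[1] - p3[1]) +
             sum(p3^2) * (p2[1] - p1[1])) / d
    r2 <- (p1[1] - ux)^2 + (p1[2] - uy)^2
    others <- setdiff(seq_len(n), c(i, j, k))
    d2 <- (pts[others, 1] - ux)^2 + (pts[others, 2] - uy)^2
    if (all(d2 > r2 * (1 + 1e-9))) {
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
    }
  }
  unique(edges)
}

#' Specification of a synthetic flatmount image
#'
#' Describes a ground-truthed rendering of a vitreous body flatmount: a
#' planar vessel network (Delaunay edges over random seed points) drawn as
#' tubes in the CD31 channel, endothelial nuclei on the tubes and
#' spindle-shaped pericyte plus rounder other nuclei outside them in DAPI,
#' TUNEL puncta (linear clusters on designated regressing segments, which
#' also carry sub-threshold CD31 gaps, plus isolated intravascular and
#' extravascular puncta), and optional nuclear/membrane marker channels.
#' All intensities are `background + signal` with optional additive
#' Gaussian noise expressed as a fraction of the signal level.
#'
#' @param size_px image side length in pixels (square image).
#' @param pixel_size micrometres per pixel.
#' @param n_seed_points vessel network seed points.
#' @param min_seed_sep_px minimum seed separation (controls segment length).
#' @param tube_radius_um vessel tube radius.
#' @param n_ec_nuclei,n_pericyte_nuclei,n_other_nuclei nucleus counts per
#'   class.
#' @param nucleus_radius_um equivalent (area-preserving) nucleus radius.
#' @param ec_axis_ratio,pericyte_axis_ratio,other_axis_ratio ellipse axis
#'   ratios; the pericyte default gives circularity well below 0.6, the
#'   other-class default well above.
#' @param background,signal channel background and signal levels (a.u.).
#' @param noise_frac Gaussian noise sd as a fraction of `signal` (0 = none).
#' @param n_regressing regressing segments to plant.
#' @param puncta_per_cluster TUNEL puncta per regressing-segment cluster.
#' @param cd31_gap_fraction fraction of a regressing segment's length with
#'   reduced CD31.
#' @param gap_signal_level residual CD31 in gaps, as a fraction of `signal`:
#'   regressing segments keep weak, clearly reduced staining (collapsed
#'   vessels retain some CD31), high enough that the solid mask stays
#'   connected across the gap, low enough that continuity sampling reads
#'   the segment as discontinuous.
#' @param n_isolated_puncta isolated puncta on intact segments.
#' @param n_extravascular_puncta puncta away from the vessel network.
#' @param nuclear_marker,membrane_marker optional channel names for a
#'   nuclear marker expressed in endothelial nuclei (LEF1-like) and a
#'   membrane marker filling the vessel footprint (VE-cadherin-like).
#' @param nuclear_marker_signal,membrane_marker_signal their signal levels.
#' @param seed RNG seed fixing the whole draw.
#' @return a list of class `flatmount_sim_spec`.
#' @export
flatmount_sim_spec <- function(size_px = 512, pixel_size = 1,
                               n_seed_points = 10, min_seed_sep_px = 80,
                               tube_radius_um = 4,
                               n_ec_nuclei = 20, n_pericyte_nuclei = 10,
                               n_other_nuclei = 8, nucleus_radius_um = 4.5,
                               ec_axis_ratio = 1.8, pericyte_axis_ratio = 5,
                               other_axis_ratio = 1.15,
                               background = 10, signal = 100,
                               noise_frac = 0,
                               n_regressing = 3, puncta_per_cluster = 4,
                               cd31_gap_fraction = 0.5,
                               gap_signal_level = 0.6,
                               n_isolated_puncta = 4,
                               n_extravascular_puncta = 3,
                               nuclear_marker = NULL,
                               membrane_marker = NULL,
                               nuclear_marker_signal = 80,
                               membrane_marker_signal = 60,
                               seed = 1) {
  stopifnot(tube_radius_um / pixel_size >= 2, n_seed_points >= 3,
            noise_frac >= 0, cd31_gap_fraction > 0, cd31_gap_fraction < 1,
            gap_signal_level >= 0, gap_signal_level < 1)
  spec <- as.list(environment())
  class(spec) <- "flatmount_sim_spec"
  spec
}

# sample network seed points + Delaunay edges with geometric guards so
# the rendered tube union has the same topology as the abstract graph:
# minimum seed separation, minimum inter-edge angle at shared nodes, and
# minimum clearance between non-adjacent edges. Offending edges are
# dropped (connectivity preserved) rather than rejecting the whole draw.
sample_network <- function(spec) {
  margin <- 30
  lo <- margin
  hi <- spec$size_px - margin
  r_tube_px <- spec$tube_radius_um / spec$pixel_size
  clearance <- 2 * r_tube_px + 12
  min_angle <- 30 * pi / 180
  for (attempt in seq_len(60)) {
    pts <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(pts) < spec$n_seed_points && tries < 4000) {
      cand <- stats::runif(2, lo, hi)
      if (nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >=
          spec$min_seed_sep_px) {
        pts <- rbind(pts, cand)
      }
      tries <- tries + 1
    }
    if (nrow(pts) < spec$n_seed_points) next
    ed <- delaunay_edges(pts)
    lens <- function(e) sqrt(rowSums((pts[e[, 1], , drop = FALSE] -
                                        pts[e[, 2], , drop = FALSE])^2))
    # drop overlong hull edges, keeping the MST backbone
    g_full <- igraph::graph_from_edgelist(ed, directed = FALSE)
    igraph::E(g_full)$weight <- lens(ed)
    mst_pairs <- igraph::as_edgelist(igraph::mst(g_full))
    key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    keep <- key(ed) %in% key(mst_pairs) |
      lens(ed) <= 1.9 * stats::median(lens(ed))
    ed <- ed[keep, , drop = FALSE]
    ok <- TRUE
    repeat {
      bad <- rep(0, nrow(ed))
      # (a) angles at shared nodes
      for (v in seq_len(nrow(pts))) {
        inc <- which(ed[, 1] == v | ed[, 2] == v)
        if (length(inc) < 2) next
        ang <- vapply(inc, function(e) {
          other <- setdiff(ed[e, ], v)
          atan2(pts[other, 2] - pts[v, 2], pts[other, 1] - pts[v, 1])
        }, numeric(1))
        o <- order(ang)
        gaps <- diff(c(ang[o], ang[o[1]] + 2 * pi))
        viol <- which(gaps < min_angle)
        for (g in viol) {
          pair <- inc[o][c(g, if (g == length(o)) 1 else g + 1)]
          bad[pair] <- bad[pair] + 1
        }
      }
      # (b) smooth way-points: a degree-2 seed is a bend in a vessel
      # path; hairpin bends (interior angle < 120 deg) are unrealistic
      # and are penalized so one of the edges is dropped
      deg_now <- tabulate(c(ed[, 1], ed[, 2]), nbins = nrow(pts))
      for (v in which(deg_now == 2)) {
        inc <- which(ed[, 1] == v | ed[, 2] == v)
        ang <- vapply(inc, function(e) {
          other <- setdiff(ed[e, ], v)
          atan2(pts[other, 2] - pts[v, 2], pts[other, 1] - pts[v, 1])
        }, numeric(1))
        sep <- abs(ang[1] - ang[2])
        sep <- min(sep, 2 * pi - sep)
        if (sep < 120 * pi / 180) bad[inc] <- bad[inc] + 1
      }
      # (c) clearance between edges not sharing a node
      if (nrow(ed) >= 2) {
        for (i in 1:(nrow(ed) - 1)) for (j in (i + 1):nrow(ed)) {
          if (length(intersect(ed[i, ], ed[j, ])) > 0) next
          a1 <- pts[ed[i, 1], ]; b1 <- pts[ed[i, 2], ]
          a2 <- pts[ed[j, 1], ]; b2 <- pts[ed[j, 2], ]
          d <- min(point_segment_distance(rbind(a1, b1), a2, b2),
                   point_segment_distance(rbind(a2, b2), a1, b1))
          if (d < clearance) bad[c(i, j)] <- bad[c(i, j)] + 1
        }
      }
      if (all(bad == 0)) break
      # drop the worst-offending edge whose removal keeps the network
      # connected; reject the draw only if none exists
      cand <- which(bad > 0)
      cand <- cand[order(-bad[cand], -lens(ed)[cand])]
      dropped <- FALSE
      for (ci in cand) {
        g_try <- igraph::graph_from_edgelist(ed[-ci, , drop = FALSE],
                                             directed = FALSE)
        g_try <- igraph::add_vertices(
          g_try, max(0, nrow(pts) - igraph::vcount(g_try)))
        if (igraph::is_connected(g_try)) {
          ed <- ed[-ci, , drop = FALSE]
          dropped <- TRUE
          break
        }
      }
      if (!dropped) { ok <- FALSE; break }
    }
    if (!ok) next
    if (min(lens(ed)) < 50) next
    deg <- tabulate(c(ed[, 1], ed[, 2]), nbins = nrow(pts))
    return(list(points = pts, edges = ed, lengths = lens(ed), degree = deg))
  }
  stop("could not sample a valid vessel network; enlarge the image or reduce seed points",
       call. = FALSE)
}

# filled-ellipse pixel set around (r0, c0) (1-based centre, px units)
ellipse_pixels <- function(r0, c0, semi_major, semi_minor, theta, size) {
  ext <- ceiling(semi_major) + 1
  rr <- max(1, floor(r0 - ext)):min(size, ceiling(r0 + ext))
  cc <- max(1, floor(c0 - ext)):min(size, ceiling(c0 + ext))
  grid <- expand.grid(r = rr, c = cc)
  dr <- grid$r - r0
  dc <- grid$c - c0
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / semi_major)^2 + (v / semi_minor)^2 <= 1
  cbind(grid$r[inside], grid$c[inside])
}

#' Render a ground-truthed synthetic flatmount
#'
#' Deterministic given `spec$seed`. Returns the multi-channel image plus a
#' ground-truth record of the vessel network (nodes, segments, regressing
#' set), every nucleus (class, centroid) and every TUNEL punctum (location
#' class, segment).
#'
#' @param spec a [flatmount_sim_spec].
#' @return list with `image` ([flatmount_image]) and `truth`: tibbles
#'   `network_nodes`, `network_edges`, `nuclei`, `puncta`; scalars
#'   `n_branch_nodes`, `n_endpoints`, `n_effective_segments` (degree-2
#'   seeds are geometric way-points that a skeleton cannot distinguish
#'   from the segment interior) and `tube_footprint_px`.
#' @export
generate_flatmount <- function(spec) {
  stopifnot(inherits(spec, "flatmount_sim_spec"))
  with_local_seed(spec$seed, {
    sz <- spec$size_px
    px <- spec$pixel_size
    r_tube <- spec$tube_radius_um / px
    net <- sample_network(spec)
    pts <- net$points
    ed <- net$edges
    n_edges <- nrow(ed)
    # distance of every pixel to every segment
    grid <- cbind(rep(seq_len(sz), sz), rep(seq_len(sz), each = sz))
    dmat <- vapply(seq_len(n_edges), function(e) {
      point_segment_distance(grid, pts[ed[e, 1], ], pts[ed[e, 2], ])
    }, numeric(nrow(grid)))
    dmin <- do.call(pmin, as.data.frame(dmat))
    footprint <- matrix(dmin <= r_tube, sz, sz)
    # regressing segments: branch-to-branch edges (the stated definition
    # covers segments between branch points / endpoints; avoiding edges
    # at pass-through seeds keeps the planted segment identity unambiguous)
    # eligible: segments between two topological nodes (branch point or
    # endpoint); edges ending at a pass-through seed are continued by the
    # neighbouring edge in any skeleton and carry no unambiguous identity
    interior <- which(net$degree[ed[, 1]] != 2 & net$degree[ed[, 2]] != 2)
    regressing <- sort(sample(interior,
                              min(spec$n_regressing, length(interior))))
    # CD31 channel: tube signal, with reduced-signal gap windows on
    # regressing segments
    cd31 <- matrix(spec$background, sz, sz)
    cd31[footprint] <- spec$background + spec$signal
    for (e in regressing) {
      a <- pts[ed[e, 1], ]; b <- pts[ed[e, 2], ]
      n_gaps <- 3
      gap_w <- spec$cd31_gap_fraction / n_gaps
      centers <- seq(0.25, 0.75, length.out = n_gaps)
      on_edge <- dmat[, e] <= r_tube + 0.5
      t_par <- ((grid[, 1] - a[1]) * (b[1] - a[1]) +
                  (grid[, 2] - a[2]) * (b[2] - a[2])) / sum((b - a)^2)
      in_gap <- rep(FALSE, nrow(grid))
      for (gc in centers) {
        in_gap <- in_gap | (t_par >= gc - gap_w / 2 & t_par <= gc + gap_w / 2)
      }
      sel_mat <- matrix(on_edge & in_gap, sz, sz) & footprint
      cd31[sel_mat] <- spec$background + spec$gap_signal_level * spec$signal
    }
    # ---- nuclei ----
    place_on_tubes <- function(n, min_sep, intact_only = TRUE) {
      cand_edges <- if (intact_only) setdiff(seq_len(n_edges), regressing)
                    else seq_len(n_edges)
      placed <- matrix(numeric(0), 0, 3)  # row, col, edge
      tries <- 0
      while (nrow(placed) < n && tries < 8000) {
        e <- sample(cand_edges, 1)
        t0 <- stats::runif(1, 0.12, 0.88)
        a <- pts[ed[e, 1], ]; b <- pts[ed[e, 2], ]
        p <- a + t0 * (b - a)
        if (nrow(placed) == 0 ||
            min(sqrt((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2)) >=
            min_sep) {
          placed <- rbind(placed, c(p, e))
        }
        tries <- tries + 1
      }
      if (nrow(placed) < n) {
        stop("network too dense to place requested nuclei; enlarge the image",
             call. = FALSE)
      }
      placed
    }
    place_outside <- function(n, min_dist_tube, min_sep, existing) {
      placed <- matrix(numeric(0), 0, 2)
      tries <- 0
      while (nrow(placed) < n && tries < 20000) {
        p <- stats::runif(2, 15, sz - 15)
        d_tube <- min(vapply(seq_len(n_edges), function(e) {
          point_segment_distance(matrix(p, 1), pts[ed[e, 1], ],
                                 pts[ed[e, 2], ])
        }, numeric(1)))
        all_pts <- rbind(existing, placed)
        sep_ok <- nrow(all_pts) == 0 ||
          min(sqrt((all_pts[, 1] - p[1])^2 + (all_pts[, 2] - p[2])^2)) >=
          min_sep
        if (d_tube >= min_dist_tube && sep_ok) placed <- rbind(placed, p)
        tries <- tries + 1
      }
      if (nrow(placed) < n) {
        stop("image too crowded to place requested objects; enlarge the image",
             call. = FALSE)
      }
      placed
    }
    r_nuc <- spec$nucleus_radius_um / px
    sep <- 3.2 * r_nuc
    ec_pos <- if (spec$n_ec_nuclei > 0) {
      place_on_tubes(spec$n_ec_nuclei, sep)
    } else matrix(numeric(0), 0, 3)
    out_pos <- if (spec$n_pericyte_nuclei + spec$n_other_nuclei > 0) {
      place_outside(spec$n_pericyte_nuclei + spec$n_other_nuclei,
                    r_tube + spec$pericyte_axis_ratio * r_nuc + 3, sep,
                    ec_pos[, 1:2, drop = FALSE])
    } else matrix(numeric(0), 0, 2)
    nuc <- tibble::tibble(
      true_class = c(rep("endothelial", spec$n_ec_nuclei),
                     rep("pericyte", spec$n_pericyte_nuclei),
                     rep("other_non_endothelial", spec$n_other_nuclei)),
      row = c(ec_pos[, 1], out_pos[, 1]),
      col = c(ec_pos[, 2], out_pos[, 2])
    )
    dapi <- matrix(spec$background, sz, sz)
    ratios <- c(endothelial = spec$ec_axis_ratio,
                pericyte = spec$pericyte_axis_ratio,
                other_non_endothelial = spec$other_axis_ratio)
    nuc_pixels <- vector("list", nrow(nuc))
    for (i in seq_len(nrow(nuc))) {
      ratio <- ratios[[nuc$true_class[i]]]
      a <- r_nuc * sqrt(ratio)
      b <- r_nuc / sqrt(ratio)
      theta <- if (nuc$true_class[i] == "endothelial") {
        e <- ec_pos[i, 3]
        atan2(pts[ed[e, 2], 2] - pts[ed[e, 1], 2],
              pts[ed[e, 2], 1] - pts[ed[e, 1], 1])
      } else stats::runif(1, 0, pi)
      pxs <- ellipse_pixels(nuc$row[i], nuc$col[i], a, b, theta, sz)
      dapi[pxs] <- spec$background + spec$signal
      nuc_pixels[[i]] <- pxs
    }
    # ---- TUNEL puncta ----
    spot_sigma <- 1.5
    puncta <- tibble::tibble(row = numeric(), col = numeric(),
                             true_location = character(),
                             true_edge = integer())
    for (e in regressing) {
      a <- pts[ed[e, 1], ]; b <- pts[ed[e, 2], ]
      tpos <- seq(0.25, 0.75, length.out = spec$puncta_per_cluster)
      for (t0 in tpos) {
        p <- a + t0 * (b - a)
        puncta <- dplyr::bind_rows(puncta, tibble::tibble(
          row = p[1], col = p[2], true_location = "regressing_segment",
          true_edge = as.integer(e)))
      }
    }
    intact_edges <- setdiff(seq_len(n_edges), regressing)
    if (spec$n_isolated_puncta > 0 && length(intact_edges) > 0) {
      es <- sample(rep(intact_edges, length.out = spec$n_isolated_puncta))
      for (e in es) {
        a <- pts[ed[e, 1], ]; b <- pts[ed[e, 2], ]
        t0 <- stats::runif(1, 0.3, 0.7)
        p <- a + t0 * (b - a)
        puncta <- dplyr::bind_rows(puncta, tibble::tibble(
          row = p[1], col = p[2], true_location = "intact_segment",
          true_edge = as.integer(e)))
      }
    }
    if (spec$n_extravascular_puncta > 0) {
      exv <- place_outside(spec$n_extravascular_puncta, r_tube + 14, 10,
                           rbind(as.matrix(nuc[, c("row", "col")]),
                                 as.matrix(puncta[, c("row", "col")])))
      puncta <- dplyr::bind_rows(puncta, tibble::tibble(
        row = exv[, 1], col = exv[, 2], true_location = "extravascular",
        true_edge = NA_integer_))
    }
    tunel <- matrix(spec$background / 2, sz, sz)
    for (i in seq_len(nrow(puncta))) {
      ext <- ceiling(4 * spot_sigma)
      rr <- max(1, floor(puncta$row[i] - ext)):
        min(sz, ceiling(puncta$row[i] + ext))
      cc <- max(1, floor(puncta$col[i] - ext)):
        min(sz, ceiling(puncta$col[i] + ext))
      g <- outer(rr - puncta$row[i], cc - puncta$col[i], function(dr, dc) {
        exp(-(dr^2 + dc^2) / (2 * spot_sigma^2))
      })
      tunel[rr, cc] <- tunel[rr, cc] + spec$signal * g
    }
    channels <- list(DAPI = dapi, CD31 = cd31, TUNEL = tunel)
    if (!is.null(spec$nuclear_marker)) {
      nm <- matrix(spec$background, sz, sz)
      for (i in which(nuc$true_class == "endothelial")) {
        nm[nuc_pixels[[i]]] <- spec$background + spec$nuclear_marker_signal
      }
      channels[[spec$nuclear_marker]] <- nm
    }
    if (!is.null(spec$membrane_marker)) {
      mm <- matrix(spec$background, sz, sz)
      mm[footprint] <- spec$background + spec$membrane_marker_signal
      channels[[spec$membrane_marker]] <- mm
    }
    if (spec$noise_frac > 0) {
      channels <- lapply(channels, function(m) {
        pmax(m + stats::rnorm(length(m), 0,
                              spec$noise_frac * spec$signal), 0)
      })
    }
    image <- flatmount_image(channels, pixel_size = px,
                             metadata = list(seed = spec$seed,
                                             generator = "generate_flatmount"))
    truth <- list(
      network_nodes = tibble::tibble(
        seed_id = seq_len(nrow(pts)), row = pts[, 1] - 1, col = pts[, 2] - 1,
        degree = net$degree,
        kind = ifelse(net$degree >= 3, "branch",
                      ifelse(net$degree == 1, "endpoint", "through"))),
      network_edges = tibble::tibble(
        edge = seq_len(n_edges), from = ed[, 1], to = ed[, 2],
        length_um = net$lengths * px,
        regressing = seq_len(n_edges) %in% regressing),
      n_branch_nodes = sum(net$degree >= 3),
      n_endpoints = sum(net$degree == 1),
      # degree-2 seeds are geometric way-points, not topological nodes:
      # each merges its two incident edges into one recovered segment
      n_effective_segments = n_edges - sum(net$degree == 2),
      nuclei = dplyr::mutate(nuc, row = .data$row - 1, col = .data$col - 1),
      puncta = dplyr::mutate(puncta, row = .data$row - 1,
                             col = .data$col - 1),
      tube_footprint_px = sum(footprint)
    )
    list(image = image, truth = truth)
  })
}

#' Match recovered skeleton segments to ground-truth network edges
#'
#' Each recovered edge is matched to the true segment with the smallest
#' mean distance from the recovered path pixels to the true segment line.
#'
#' @param graph a `vessel_graph` recovered from a generated image.
#' @param truth the `truth` list of [generate_flatmount()].
#' @return tibble: `edge_id`, `true_edge`, `mean_dist_px`.
#' @export
match_segments <- function(graph, truth) {
  ne <- truth$network_edges
  nn <- truth$network_nodes
  purrr::map_dfr(seq_len(nrow(graph$edges)), function(i) {
    p <- graph$edges$path[[i]]
    if (nrow(p) == 0) {
      return(tibble::tibble(edge_id = graph$edges$edge_id[i],
                            true_edge = NA_integer_,
                            mean_dist_px = NA_real_))
    }
    d <- vapply(seq_len(nrow(ne)), function(e) {
      a <- c(nn$row[ne$from[e]], nn$col[ne$from[e]])
      b <- c(nn$row[ne$to[e]], nn$col[ne$to[e]])
      mean(point_segment_distance(p, a, b))
    }, numeric(1))
    tibble::tibble(edge_id = graph$edges$edge_id[i],
                   true_edge = ne$edge[which.min(d)],
                   mean_dist_px = min(d))
  })
}

# ---- synthetic UMI counts ----------------------------------------------

#' Specification of a synthetic SORT-seq UMI experiment
#'
#' Emulates the plate-structured counts the analysis assumes: 384-well
#' SORT-seq plates (two per genotype by default) with plate depth effects,
#' negative-binomial gene counts, two marker-defined cell types (Cldn5 for
#' endothelial cells, Pdgfrb for pericytes, with planted dual/neither
#' cells), mitochondrial genes with controlled per-cell fractions, planted
#' QC failures on both total-UMI tails, and genotype-dependent DE genes
#' with known log2 fold changes per cell type.
#'
#' @param n_genes total genes, including markers and 13 `mt-` genes.
#' @param n_plates plates; genotypes alternate control/knockout pairs.
#' @param cells_per_plate sorted wells per plate.
#' @param plate_depth_factors multiplicative plate depth effects (recycled).
#' @param target_total mean per-cell total UMI before plate effects.
#' @param depth_sdlog per-cell lognormal depth spread.
#' @param dispersion negative-binomial size parameter; `Inf` gives Poisson.
#' @param frac_ec,frac_pc,frac_dual fractions of endothelial, pericyte and
#'   dual-marker cells (the remainder expresses neither marker).
#' @param n_low_umi,n_high_umi planted cells far below/above the UMI window.
#' @param n_high_mito planted cells with mitochondrial fraction above 10%.
#' @param mito_fail_frac,mito_base_frac target mito fractions for failing
#'   and ordinary cells.
#' @param n_de_genes planted DE genes per cell type.
#' @param de_log2fc vector of true log2 fold changes (control vs knockout),
#'   recycled over the planted genes.
#' @param seed RNG seed.
#' @return list of class `counts_sim_spec`.
#' @export
counts_sim_spec <- function(n_genes = 1000, n_plates = 4,
                            cells_per_plate = 48,
                            plate_depth_factors = c(1, 0.55, 0.85, 0.7),
                            target_total = 3500, depth_sdlog = 0.2,
                            dispersion = 2,
                            frac_ec = 0.45, frac_pc = 0.45,
                            frac_dual = 0.05,
                            n_low_umi = 6, n_high_umi = 6, n_high_mito = 8,
                            mito_fail_frac = 0.15, mito_base_frac = 0.03,
                            n_de_genes = 30, de_log2fc = c(2, -2, 3, -3),
                            seed = 1) {
  stopifnot(n_genes >= 50, n_plates >= 1, frac_ec + frac_pc + frac_dual <= 1,
            mito_fail_frac > 0.1, mito_base_frac < 0.1)
  spec <- as.list(environment())
  class(spec) <- "counts_sim_spec"
  spec
}

.mito_genes <- paste0("mt-", c("Nd1", "Nd2", "Nd3", "Nd4", "Nd4l", "Nd5",
                               "Nd6", "Co1", "Co2", "Co3", "Atp6", "Atp8",
                               "Cytb"))

#' Sample a ground-truthed synthetic UMI counts matrix
#'
#' Deterministic given `spec$seed`. Counts are negative-binomial around
#' cell-type and genotype dependent means, scaled by per-plate depth
#' factors and per-cell depth; mitochondrial counts are added on top with
#' controlled fractions so the planted QC outcome is unambiguous.
#'
#' @param spec a [counts_sim_spec].
#' @return list with `counts` (a [counts_matrix]) and `truth`: per-cell
#'   tibble (`cell`, `plate_id`, `genotype`, `true_type`, `mito_target`,
#'   `depth_class`) and `de_genes` tibble (`gene`, `cell_type`,
#'   `true_log2fc`).
#' @export
generate_counts <- function(spec) {
  stopifnot(inherits(spec, "counts_sim_spec"))
  with_local_seed(spec$seed, {
    n_cells <- spec$n_plates * spec$cells_per_plate
    plates <- rep(paste0("plate", seq_len(spec$n_plates)),
                  each = spec$cells_per_plate)
    genotype <- rep(rep(c("control", "knockout"),
                        length.out = spec$n_plates),
                    each = spec$cells_per_plate)
    barcode <- paste0("BC", formatC(rep(seq_len(spec$cells_per_plate),
                                        spec$n_plates), width = 3,
                                    flag = "0"))
    type_probs <- c(endothelial = spec$frac_ec, pericyte = spec$frac_pc,
                    dual = spec$frac_dual,
                    neither = 1 - spec$frac_ec - spec$frac_pc -
                      spec$frac_dual)
    true_type <- sample(names(type_probs), n_cells, replace = TRUE,
                        prob = type_probs)
    # gene universe: markers + mito + background genes
    n_bg <- spec$n_genes - 2 - length(.mito_genes)
    bg_genes <- paste0("Gene", formatC(seq_len(n_bg), width = 5, flag = "0"))
    genes <- c("Cldn5", "Pdgfrb", .mito_genes, bg_genes)
    # baseline means for background genes, scaled to the target total
    base_mu <- stats::rlnorm(n_bg, meanlog = 0, sdlog = 1.2)
    base_mu <- base_mu / sum(base_mu) * spec$target_total
    # planted DE genes per cell type (disjoint from markers and mito)
    de_ec <- bg_genes[seq_len(spec$n_de_genes)]
    de_pc <- bg_genes[spec$n_de_genes + seq_len(spec$n_de_genes)]
    l2fc_ec <- rep(spec$de_log2fc, length.out = spec$n_de_genes)
    l2fc_pc <- rep(rev(spec$de_log2fc), length.out = spec$n_de_genes)
    # DE genes need headroom above dropout: lift their baseline means
    mu_floor <- 3 * spec$target_total / 3500
    names(base_mu) <- bg_genes
    base_mu[de_ec] <- pmax(base_mu[de_ec], mu_floor)
    base_mu[de_pc] <- pmax(base_mu[de_pc], mu_floor)
    de_genes <- tibble::tibble(
      gene = c(de_ec, de_pc),
      cell_type = rep(c("endothelial", "pericyte"),
                      each = spec$n_de_genes),
      true_log2fc = c(l2fc_ec, l2fc_pc))
    # per-cell depth: lognormal, with planted out-of-window cells
    depth <- stats::rlnorm(n_cells, meanlog = -spec$depth_sdlog^2 / 2,
                           sdlog = spec$depth_sdlog)
    depth_class <- rep("in_window", n_cells)
    lo_idx <- sample(n_cells, min(spec$n_low_umi, n_cells))
    depth[lo_idx] <- stats::runif(length(lo_idx), 0.05, 0.15)
    depth_class[lo_idx] <- "low_umi"
    remaining <- setdiff(seq_len(n_cells), lo_idx)
    hi_idx <- sample(remaining, min(spec$n_high_umi, length(remaining)))
    depth[hi_idx] <- stats::runif(length(hi_idx), 3.2, 4.5)
    depth_class[hi_idx] <- "high_umi"
    plate_fac <- rep(spec$plate_depth_factors,
                     length.out = spec$n_plates)[
                       as.integer(factor(plates, levels = unique(plates)))]
    # high-mito cells drawn from the in-window pool
    mito_target <- rep(spec$mito_base_frac, n_cells)
    in_win <- which(depth_class == "in_window")
    hm_idx <- sample(in_win, min(spec$n_high_mito, length(in_win)))
    mito_target[hm_idx] <- stats::runif(length(hm_idx),
                                        spec$mito_fail_frac, 0.22)
    counts <- matrix(0, length(genes), n_cells,
                     dimnames = list(genes, NULL))
    nb_draw <- function(mu) {
      mu <- pmax(mu, 1e-9)
      if (is.infinite(spec$dispersion)) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), size = spec$dispersion, mu = mu)
    }
    for (ci in seq_len(n_cells)) {
      scale_c <- depth[ci] * plate_fac[ci]
      mu <- base_mu * scale_c
      tt <- true_type[ci]
      if (tt %in% c("endothelial", "pericyte")) {
        de <- if (tt == "endothelial") de_ec else de_pc
        l2 <- if (tt == "endothelial") l2fc_ec else l2fc_pc
        shift <- if (genotype[ci] == "control") l2 / 2 else -l2 / 2
        mu[de] <- mu[de] * 2^shift
      }
      counts[bg_genes, ci] <- nb_draw(mu)
      marker_mu <- 8 * scale_c
      if (tt %in% c("endothelial", "dual")) {
        counts["Cldn5", ci] <- max(1, nb_draw(marker_mu))
      }
      if (tt %in% c("pericyte", "dual")) {
        counts["Pdgfrb", ci] <- max(1, nb_draw(marker_mu))
      }
      # mitochondrial counts sized to hit the target fraction strictly
      nonmito <- sum(counts[, ci])
      f <- mito_target[ci]
      m_tot <- if (f > 0.1) ceiling(f / (1 - f) * nonmito) + 1
               else floor(f / (1 - f) * nonmito)
      if (m_tot > 0) {
        counts[.mito_genes, ci] <-
          stats::rmultinom(1, m_tot, rep(1, length(.mito_genes)))
      }
    }
    cells <- tibble::tibble(barcode = barcode, plate_id = plates,
                            genotype = genotype)
    cm <- counts_matrix(counts, cells)
    key <- paste(plates, barcode, sep = ":")
    truth_cells <- tibble::tibble(cell = key, plate_id = plates,
                                  genotype = genotype,
                                  true_type = true_type,
                                  mito_target = mito_target,
                                  depth_class = depth_class)
    truth_cells <- truth_cells[match(colnames(cm$counts),
                                     truth_cells$cell), ]
    list(counts = cm,
         truth = list(cells = truth_cells, de_genes = de_genes))
  })
}
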