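#' Parameters for vessel segment topology and regression calling
#'
#' The published criteria for a regressing segment — a linear cluster of
#' TUNEL puncta on a branch-to-branch segment with discontinuous CD31 —
#' were applied visually; these parameters are the explicit, configurable
#' operationalization used here.
#'
#' @param corridor_halfwidth_um maximum centroid-to-skeleton distance (um)
#'   for assigning a punctum to a segment.
#' @param min_cluster_puncta minimum assigned puncta for a linear cluster.
#' @param continuity_threshold CD31 intensity cutoff along the path;
#'   `NULL` means the Otsu level of the CD31 channel.
#' @param max_continuity_for_regressing maximal fraction of the path with
#'   supra-threshold CD31 for a segment to count as discontinuous.
#' @param prune_length_um skeleton spurs shorter than this are removed.
#' @param junction_merge_factor thinning can resolve one anatomical branch
#'   point (notably 4-way crossings) into several nearby skeleton
#'   junctions; branch-to-branch stubs shorter than this factor times the
#'   summed local vessel radii (distance-transform values) at their two
#'   nodes are contracted back into a single node.
#' @param pool_radius_px radius (px) of the maximum-pooling disc applied to
#'   CD31 before sampling along the skeleton (tolerance for the skeleton
#'   not running exactly mid-vessel).
#' @param cd31_smooth_sigma_px Gaussian smoothing of the CD31 channel
#'   before continuity thresholding/pooling (noise suppression; maximum
#'   pooling of raw noise would inflate continuity).
#' @return a list of class `topology_params`.
#' @export
topology_params <- function(corridor_halfwidth_um = 10,
                            min_cluster_puncta = 3,
                            continuity_threshold = NULL,
                            max_continuity_for_regressing = 0.8,
                            prune_length_um = 15,
                            junction_merge_factor = 2.5,
                            pool_radius_px = 3,
                            cd31_smooth_sigma_px = 1) {
  stopifnot(corridor_halfwidth_um > 0, min_cluster_puncta >= 2,
            max_continuity_for_regressing > 0,
            max_continuity_for_regressing < 1, prune_length_um >= 0)
  structure(list(
    corridor_halfwidth_um = corridor_halfwidth_um,
    min_cluster_puncta = min_cluster_puncta,
    continuity_threshold = continuity_threshold,
    max_continuity_for_regressing = max_continuity_for_regressing,
    prune_length_um = prune_length_um,
    junction_merge_factor = junction_merge_factor,
    pool_radius_px = pool_radius_px,
    cd31_smooth_sigma_px = cd31_smooth_sigma_px
  ), class = "topology_params")
}

# ---- skeletonization ----------------------------------------------------

# shift a logical/numeric matrix by (dr, dc), padding with 0/FALSE
shift_mat <- function(m, dr, dc) {
  out <- matrix(vector(typeof(m), 1), nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  r_src <- max(1, 1 - dr):min(nr, nr - dr)
  c_src <- max(1, 1 - dc):min(nc, nc - dc)
  out[r_src + dr, c_src + dc] <- m[r_src, c_src]
  out
}

# 8-neighbour offsets in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
.zs_offsets <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                    c(1, 0), c(1, -1), c(0, -1), c(-1, -1))

#' Topology-preserving skeletonization (Zhang-Suen thinning)
#'
#' Reduces a binary vessel mask to a 1-pixel-wide, 8-connected skeleton.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same size.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  b <- mask != 0
  if (!any(b)) return(b)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- lapply(.zs_offsets, function(o) shift_mat(b, o[1], o[2]))
      bp <- Reduce(`+`, p)
      # A(P): 0->1 transitions around the ring P2..P9..P2
      ring <- c(p, p[1])
      ap <- Reduce(`+`, lapply(seq_len(8), function(i) {
        (!ring[[i]]) & ring[[i + 1]]
      }))
      if (step == 1) {
        c1 <- !(p[[1]] & p[[3]] & p[[5]])  # P2*P4*P6 = 0
        c2 <- !(p[[3]] & p[[5]] & p[[7]])  # P4*P6*P8 = 0
      } else {
        c1 <- !(p[[1]] & p[[3]] & p[[7]])  # P2*P4*P8 = 0
        c2 <- !(p[[1]] & p[[5]] & p[[7]])  # P2*P6*P8 = 0
      }
      del <- b & bp >= 2 & bp <= 6 & ap == 1 & c1 & c2
      if (any(del)) {
        b[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  b
}

# Minimal-connectivity pixel adjacency of a skeleton: orthogonal links
# always; a diagonal link only when no orthogonal two-step path through a
# shared skeleton neighbour exists (removes spurious staircase junctions).
skeleton_adjacency <- function(skel) {
  pix <- which(skel, arr.ind = TRUE)
  n <- nrow(pix)
  idm <- matrix(0L, nrow(skel), ncol(skel))
  if (n > 0) idm[pix] <- seq_len(n)
  edges <- list()
  if (n > 0) {
    inb <- function(r, c) r >= 1 & r <= nrow(skel) & c >= 1 & c <= ncol(skel)
    at <- function(m, r, c) {
      v <- rep(FALSE, length(r))
      ok <- inb(r, c)
      v[ok] <- m[cbind(r[ok], c[ok])]
      v
    }
    for (o in list(c(0, 1), c(1, 0))) {
      nr <- pix[, 1] + o[1]; nc <- pix[, 2] + o[2]
      on <- at(skel, nr, nc)
      if (any(on)) {
        edges[[length(edges) + 1]] <-
          cbind(which(on), idm[cbind(nr[on], nc[on])])
      }
    }
    for (o in list(c(1, 1), c(1, -1))) {
      nr <- pix[, 1] + o[1]; nc <- pix[, 2] + o[2]
      on <- at(skel, nr, nc)
      # corner pixels of the diagonal step
      redundant <- at(skel, pix[, 1] + o[1], pix[, 2]) |
        at(skel, pix[, 1], pix[, 2] + o[2])
      keep <- on & !redundant
      if (any(keep)) {
        edges[[length(edges) + 1]] <-
          cbind(which(keep), idm[cbind(nr[keep], nc[keep])])
      }
    }
  }
  adj <- if (length(edges)) do.call(rbind, edges) else
    matrix(integer(0), 0, 2)
  list(pix = pix, adj = adj)
}

skeleton_igraph <- function(sa) {
  g <- igraph::graph_from_edgelist(sa$adj, directed = FALSE)
  igraph::add_vertices(g, max(0, nrow(sa$pix) - igraph::vcount(g)))
}

# spur pruning on the skeleton graph: walk from every endpoint to the
# nearest junction; branches shorter than max_px (and short isolated
# filaments) are removed, junction pixels are kept
prune_spurs <- function(skel, max_px) {
  if (max_px <= 0) return(skel)
  repeat {
    sa <- skeleton_adjacency(skel)
    if (nrow(sa$pix) == 0) return(skel)
    g <- skeleton_igraph(sa)
    deg <- igraph::degree(g)
    endpoints <- which(deg == 1)
    if (length(endpoints) == 0) return(skel)
    nbrs <- igraph::adjacent_vertices(g, seq_len(nrow(sa$pix)))
    drop <- integer(0)
    for (ep in endpoints) {
      path <- ep
      cur <- ep
      prev <- 0L
      len <- 0
      repeat {
        nxt <- setdiff(as.integer(nbrs[[cur]]), prev)
        if (length(nxt) == 0) {          # isolated filament
          drop <- c(drop, path)
          break
        }
        if (length(nxt) > 1) {           # cur borders a junction? no:
          drop <- c(drop, path)          # cur IS adjacent to >1 -> junction
          break                          # reached; spur = walked pixels
        }
        nxt <- nxt[1]
        len <- len + sqrt(sum((sa$pix[nxt, ] - sa$pix[cur, ])^2))
        if (len > max_px) break          # long branch: keep
        if (deg[nxt] > 2) {              # next is a junction pixel: stop
          drop <- c(drop, path)
          break
        }
        path <- c(path, nxt)
        prev <- cur
        cur <- nxt
      }
    }
    drop <- unique(drop)
    if (length(drop) == 0) return(skel)
    skel[sa$pix[drop, , drop = FALSE]] <- FALSE
  }
}

# ---- skeleton -> graph --------------------------------------------------

#' Reduce a vessel mask to a skeleton graph of segments
#'
#' Thins the solid vessel mask to a skeleton, prunes short spurs, and
#' traces the segments running between branch points and/or endpoints.
#' Nodes are maximal clusters of junction pixels (or single endpoints);
#' each edge carries its ordered skeleton path and physical length.
#'
#' @param mask a `vessel_mask`.
#' @param params a [topology_params].
#' @return object of class `vessel_graph`: `nodes` tibble (`node_id`,
#'   `kind` branch/endpoint, `row`, `col` 0-based), `edges` tibble
#'   (`edge_id`, `from`, `to`, `length_um`, list-column `path` of 0-based
#'   (row, col) matrices), plus the skeleton and pixel size.
#' @export
skeletonize_graph <- function(mask, params = topology_params()) {
  stopifnot(inherits(mask, "vessel_mask"))
  px <- mask$pixel_size
  skel <- skeletonize(mask$mask)
  skel <- prune_spurs(skel, params$prune_length_um / px)
  gr <- build_skeleton_graph(skel, px)
  merge_split_junctions(gr, mask, params$junction_merge_factor)
}

# contract branch-branch stub edges shorter than factor * (local vessel
# radius at node a + at node b); collapses junction structures that
# thinning split into multiple nearby triple-points
merge_split_junctions <- function(gr, mask, factor) {
  if (factor <= 0 || nrow(gr$edges) == 0) return(gr)
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask$mask * 1)))
  px <- gr$pixel_size
  nodes <- gr$nodes
  edges <- gr$edges
  node_radius <- function(n) {
    r <- pmin(pmax(round(nodes$row[n]) + 1, 1), nrow(dm))
    c <- pmin(pmax(round(nodes$col[n]) + 1, 1), ncol(dm))
    dm[cbind(r, c)]
  }
  repeat {
    is_branch <- nodes$kind == "branch"
    thr <- factor * (node_radius(edges$from) + node_radius(edges$to)) * px
    self_loop <- edges$from == edges$to
    cand <- which(!self_loop & is_branch[edges$from] &
                    is_branch[edges$to] & edges$length_um < thr)
    drop_loops <- which(self_loop & edges$length_um < thr)
    if (length(drop_loops)) {
      edges <- edges[-drop_loops, , drop = FALSE]
      next
    }
    if (length(cand) == 0) break
    e <- cand[which.min(edges$length_um[cand])]
    a <- edges$from[e]; b <- edges$to[e]
    nodes$row[a] <- mean(nodes$row[c(a, b)])
    nodes$col[a] <- mean(nodes$col[c(a, b)])
    edges <- edges[-e, , drop = FALSE]
    edges$from[edges$from == b] <- a
    edges$to[edges$to == b] <- a
    nodes$kind[b] <- "dropped"
  }
  # a node left with exactly two distinct incident segments is no branch
  # point: splice the segments through it
  repeat {
    if (nrow(edges) == 0) break
    incid <- c(edges$from, edges$to)
    degs <- tabulate(incid, nbins = nrow(nodes))
    cand <- which(degs == 2 & nodes$kind == "branch")
    cand <- cand[vapply(cand, function(n) {
      sum(edges$from == n & edges$to == n) == 0  # not a self-loop anchor
    }, logical(1))]
    if (length(cand) == 0) break
    n <- cand[1]
    ei <- which(edges$from == n | edges$to == n)
    if (length(ei) != 2) { nodes$kind[n] <- "spliced"; next }
    orient <- function(i) {
      p <- edges$path[[i]]
      npos <- c(nodes$row[n], nodes$col[n])
      if (nrow(p) < 2) return(p)
      d_first <- sum((p[1, ] - npos)^2)
      d_last <- sum((p[nrow(p), ] - npos)^2)
      if (d_first < d_last) p[nrow(p):1, , drop = FALSE] else p
    }
    other <- function(i) if (edges$from[i] == n) edges$to[i] else edges$from[i]
    p1 <- orient(ei[1])                     # ends at n
    p2 <- orient(ei[2])[, , drop = FALSE]   # ends at n -> reverse to start
    p2 <- p2[nrow(p2):1, , drop = FALSE]
    new_edge <- edges[ei[1], , drop = FALSE]
    new_edge$from <- other(ei[1])
    new_edge$to <- other(ei[2])
    new_edge$length_um <- edges$length_um[ei[1]] + edges$length_um[ei[2]]
    new_edge$n_path_px <- nrow(p1) + nrow(p2)
    new_edge$path <- list(rbind(p1, p2))
    edges <- dplyr::bind_rows(edges[-ei, , drop = FALSE], new_edge)
    nodes$kind[n] <- "dropped"
  }
  # drop isolated nodes created by contraction
  if (nrow(edges) > 0) {
    incid <- unique(c(edges$from, edges$to))
    iso <- setdiff(which(nodes$kind != "dropped"), incid)
    if (length(iso)) nodes$kind[iso] <- "dropped"
  }
  keep <- which(nodes$kind != "dropped")
  remap <- match(seq_len(nrow(nodes)), keep)
  nodes <- nodes[keep, , drop = FALSE]
  nodes$node_id <- seq_len(nrow(nodes))
  edges$from <- remap[edges$from]
  edges$to <- remap[edges$to]
  if (nrow(edges)) edges$edge_id <- seq_len(nrow(edges))
  gr$nodes <- nodes
  gr$edges <- edges
  gr
}

build_skeleton_graph <- function(skel, pixel_size) {
  empty <- structure(list(
    nodes = tibble::tibble(node_id = integer(), kind = character(),
                           row = numeric(), col = numeric()),
    edges = tibble::tibble(edge_id = integer(), from = integer(),
                           to = integer(), length_um = numeric(),
                           n_path_px = integer(), path = list()),
    skeleton = skel, pixel_size = pixel_size), class = "vessel_graph")
  sa <- skeleton_adjacency(skel)
  pix <- sa$pix
  if (nrow(pix) == 0) return(empty)
  adj <- sa$adj
  g <- skeleton_igraph(sa)
  deg <- igraph::degree(g)
  is_node_px <- deg != 2
  if (!any(is_node_px)) {
    # pure cycle(s): promote one pixel per component to a node
    comp <- igraph::components(g)$membership
    is_node_px[match(unique(comp), comp)] <- TRUE
    deg_kind <- rep("branch", nrow(pix))
  }
  # cluster adjacent node pixels into nodes
  sub <- igraph::induced_subgraph(g, which(is_node_px))
  sub_comp <- igraph::components(sub)$membership
  node_of_px <- rep(NA_integer_, nrow(pix))
  node_of_px[which(is_node_px)] <- sub_comp
  n_nodes <- max(sub_comp)
  node_rows <- tapply(pix[is_node_px, 1], sub_comp, mean) - 1
  node_cols <- tapply(pix[is_node_px, 2], sub_comp, mean) - 1
  node_kind <- vapply(seq_len(n_nodes), function(i) {
    degs <- deg[which(is_node_px)][sub_comp == i]
    if (max(degs) >= 3) "branch" else if (max(degs) == 1) "endpoint"
    else "branch"
  }, character(1))
  nodes <- tibble::tibble(node_id = seq_len(n_nodes), kind = node_kind,
                          row = as.numeric(node_rows),
                          col = as.numeric(node_cols))
  # chains: components of the graph minus node pixels
  chain_px <- which(!is_node_px)
  edge_list <- list()
  seen_direct <- character(0)
  if (length(chain_px) > 0) {
    gsub <- igraph::induced_subgraph(g, chain_px)
    comp <- igraph::components(gsub)$membership
    for (ci in seq_len(max(comp))) {
      members <- chain_px[comp == ci]
      # order the chain: endpoints have degree <= 1 within the chain
      cg <- igraph::induced_subgraph(g, members)
      cdeg <- igraph::degree(cg)
      ends <- which(cdeg <= 1)
      if (length(ends) == 0) {
        ord <- seq_along(members)  # cycle chain; arbitrary order
      } else {
        ord <- as.integer(igraph::dfs(cg, root = ends[1])$order)
      }
      chain <- members[ord]
      # nodes adjacent to the two chain ends
      end_nodes <- lapply(c(chain[1], chain[length(chain)]), function(p) {
        nb <- as.integer(igraph::neighbors(g, p))
        unique(stats::na.omit(node_of_px[nb]))
      })
      from <- if (length(end_nodes[[1]])) end_nodes[[1]][1] else NA_integer_
      to <- if (length(end_nodes[[2]])) {
        cand <- end_nodes[[2]]
        if (length(cand) > 1 && !is.na(from)) {
          # a chain touching two node clusters links them; only a chain
          # whose sole adjacent cluster is `from` is a genuine loop
          cand2 <- setdiff(cand, from)
          if (length(cand2) > 0) cand <- cand2
        }
        cand[1]
      } else NA_integer_
      path_px <- pix[chain, , drop = FALSE]
      edge_list[[length(edge_list) + 1]] <- list(from = from, to = to,
                                                 path = path_px)
    }
  }
  # direct node-node adjacencies (no interior chain pixels)
  if (nrow(adj) > 0) {
    both_nodes <- is_node_px[adj[, 1]] & is_node_px[adj[, 2]]
    if (any(both_nodes)) {
      dn <- adj[both_nodes, , drop = FALSE]
      n1 <- node_of_px[dn[, 1]]; n2 <- node_of_px[dn[, 2]]
      diffn <- n1 != n2
      if (any(diffn)) {
        pairs <- unique(cbind(pmin(n1[diffn], n2[diffn]),
                              pmax(n1[diffn], n2[diffn])))
        for (i in seq_len(nrow(pairs))) {
          edge_list[[length(edge_list) + 1]] <-
            list(from = pairs[i, 1], to = pairs[i, 2],
                 path = matrix(numeric(0), 0, 2))
        }
      }
    }
  }
  if (length(edge_list) == 0) {
    out <- empty
    out$nodes <- nodes
    out$skeleton <- skel
    return(out)
  }
  edges_tb <- purrr::imap_dfr(edge_list, function(e, i) {
    # full path includes the anchoring node pixels for length computation
    a <- e$from; b <- e$to
    anchor <- function(nid, ref) {
      if (is.na(nid)) return(NULL)
      c(nodes$row[nid] + 1, nodes$col[nid] + 1)
    }
    fp <- e$path
    pa <- anchor(a); pb <- anchor(b)
    full <- rbind(if (!is.null(pa)) round(pa), fp, if (!is.null(pb)) round(pb))
    seg_len <- if (nrow(full) >= 2) {
      sum(sqrt(rowSums((full[-1, , drop = FALSE] -
                          full[-nrow(full), , drop = FALSE])^2)))
    } else 1
    tibble::tibble(edge_id = i, from = a, to = b,
                   length_um = seg_len * pixel_size,
                   n_path_px = nrow(full),
                   path = list(full - 1))  # 0-based
  })
  structure(list(nodes = nodes, edges = edges_tb, skeleton = skel,
                 pixel_size = pixel_size), class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d nodes (%d branch, %d endpoint), %d segments\n",
              nrow(x$nodes), sum(x$nodes$kind == "branch"),
              sum(x$nodes$kind == "endpoint"), nrow(x$edges)))
  invisible(x)
}

#' Convert a vessel graph to an igraph object
#'
#' Nodes carry `kind` and position; edges carry `length_um`. Useful for
#' GraphML export via [igraph::write_graph()].
#'
#' @param graph a `vessel_graph`.
#' @return an [igraph::graph] object.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  g <- igraph::graph_from_edgelist(
    as.matrix(graph$edges[, c("from", "to")]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(graph$nodes) - igraph::vcount(g)))
  igraph::V(g)$kind <- graph$nodes$kind
  igraph::V(g)$row <- graph$nodes$row
  igraph::V(g)$col <- graph$nodes$col
  igraph::E(g)$length_um <- graph$edges$length_um
  igraph::E(g)$edge_id <- graph$edges$edge_id
  g
}

# ---- puncta assignment and segment classification -----------------------

#' Assign intravascular TUNEL puncta to vessel segments
#'
#' Each intravascular punctum is assigned to the segment whose skeleton
#' path lies nearest to its centroid, provided that distance is within the
#' corridor half-width; near-exact ties go to the lower `edge_id`. Puncta
#' beyond every corridor are re-labelled extravascular.
#'
#' @param graph a `vessel_graph`.
#' @param puncta tibble from [detect_tunel_puncta()].
#' @param params a [topology_params].
#' @return `puncta` with `segment_id`, `dist_to_segment_um` and
#'   `arc_pos_um` (arc-length of the nearest path point) filled in.
#' @export
assign_puncta_to_segments <- function(graph, puncta,
                                      params = topology_params()) {
  stopifnot(inherits(graph, "vessel_graph"))
  px <- graph$pixel_size
  puncta$segment_id <- NA_integer_
  puncta$dist_to_segment_um <- NA_real_
  puncta$arc_pos_um <- NA_real_
  if (nrow(puncta) == 0 || nrow(graph$edges) == 0) return(puncta)
  paths <- graph$edges$path
  arcs <- lapply(paths, function(p) {
    if (nrow(p) < 2) return(0)
    c(0, cumsum(sqrt(rowSums((p[-1, , drop = FALSE] -
                                p[-nrow(p), , drop = FALSE])^2))))
  })
  tol <- 1e-6
  for (i in seq_len(nrow(puncta))) {
    if (puncta$location_class[i] == "extravascular") next
    ctr <- c(puncta$centroid_row[i], puncta$centroid_col[i])
    best <- purrr::map_dfr(seq_along(paths), function(e) {
      p <- paths[[e]]
      if (nrow(p) == 0) return(NULL)
      d2 <- (p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2
      j <- which.min(d2)
      tibble::tibble(edge_id = graph$edges$edge_id[e],
                     dist = sqrt(d2[j]) * px, arc = arcs[[e]][j] * px)
    })
    if (nrow(best) == 0) next
    dmin <- min(best$dist)
    if (dmin <= params$corridor_halfwidth_um) {
      cand <- best[best$dist <= dmin + tol, , drop = FALSE]
      k <- which.min(cand$edge_id)
      puncta$segment_id[i] <- cand$edge_id[k]
      puncta$dist_to_segment_um[i] <- cand$dist[k]
      puncta$arc_pos_um[i] <- cand$arc[k]
    } else {
      puncta$location_class[i] <- "extravascular"
    }
  }
  puncta
}

#' Classify vessel segments as regressing or intact
#'
#' A segment is regressing when (a) it carries a linear cluster of TUNEL
#' puncta — at least `min_cluster_puncta` assigned puncta whose projections
#' span at least twice the corridor half-width along the path — and (b) its
#' CD31 staining is discontinuous: the fraction of path samples with
#' supra-threshold CD31 (after disc maximum pooling) is at most
#' `max_continuity_for_regressing`.
#'
#' When no explicit `continuity_threshold` is set, the cutoff is the Otsu
#' level of the CD31 intensities inside the vessel mask (if supplied) —
#' i.e. staining loss is judged relative to stained vessel, not to tissue
#' background — or of the whole channel otherwise.
#'
#' @param graph a `vessel_graph`.
#' @param puncta tibble with `segment_id`/`arc_pos_um` from
#'   [assign_puncta_to_segments()].
#' @param image a [flatmount_image] providing the CD31 channel.
#' @param cd31_channel channel name.
#' @param mask optional `vessel_mask` restricting the automatic continuity
#'   threshold to within-vessel intensities.
#' @param params a [topology_params].
#' @return tibble of segment calls: `edge_id`, `status`, `puncta_count`,
#'   `cd31_continuity`, `cluster_linearity`, `length_um`.
#' @export
classify_segments <- function(graph, puncta, image, cd31_channel = "CD31",
                              mask = NULL, params = topology_params()) {
  stopifnot(inherits(graph, "vessel_graph"))
  cd31 <- get_channel(image, cd31_channel)
  cd31 <- smooth_channel(cd31, params$cd31_smooth_sigma_px)
  thr <- params$continuity_threshold
  if (is.null(thr)) {
    thr <- if (!is.null(mask) && any(mask$mask)) {
      threshold_otsu(cd31[mask$mask])
    } else {
      threshold_otsu(cd31)
    }
  }
  pooled <- if (params$pool_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * params$pool_radius_px + 1, "disc")
    EBImage::imageData(EBImage::dilate(EBImage::Image(cd31), brush))
  } else cd31
  if (nrow(graph$edges) == 0) {
    return(tibble::tibble(edge_id = integer(), status = character(),
                          puncta_count = integer(),
                          cd31_continuity = numeric(),
                          cluster_linearity = logical(),
                          length_um = numeric()))
  }
  purrr::map_dfr(seq_len(nrow(graph$edges)), function(e) {
    eid <- graph$edges$edge_id[e]
    p <- graph$edges$path[[e]]
    cont <- if (nrow(p) == 0) 1 else {
      vals <- pooled[cbind(pmin(pmax(round(p[, 1]) + 1, 1), nrow(pooled)),
                           pmin(pmax(round(p[, 2]) + 1, 1), ncol(pooled)))]
      mean(vals >= thr)
    }
    on_seg <- !is.na(puncta$segment_id) & puncta$segment_id == eid
    n_puncta <- sum(on_seg)
    span <- if (n_puncta >= 2) diff(range(puncta$arc_pos_um[on_seg])) else 0
    linear <- n_puncta >= params$min_cluster_puncta &&
      span >= 2 * params$corridor_halfwidth_um
    status <- if (linear && cont <= params$max_continuity_for_regressing) {
      "regressing"
    } else "intact"
    tibble::tibble(edge_id = eid, status = status,
                   puncta_count = as.integer(n_puncta),
                   cd31_continuity = cont, cluster_linearity = linear,
                   length_um = graph$edges$length_um[e])
  })
}

#' Per-flatmount regression summary
#'
#' The four figure-level statistics: number of regressing segments, total
#' TUNEL puncta in regressing segments, mean puncta per regressing segment
#' (`NA` when there is none), and total puncta in intact segments.
#'
#' @param calls tibble from [classify_segments()].
#' @return one-row tibble.
#' @export
flatmount_regression_summary <- function(calls) {
  reg <- calls[calls$status == "regressing", , drop = FALSE]
  n_reg <- nrow(reg)
  tibble::tibble(
    n_regressing_segments = n_reg,
    total_puncta_in_regressing = sum(reg$puncta_count),
    mean_puncta_per_regressing_segment =
      if (n_reg > 0) sum(reg$puncta_count) / n_reg else NA_real_,
    total_puncta_in_intact =
      sum(calls$puncta_count[calls$status == "intact"])
  )
}
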