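#' Parameters for flatmount quantification
#'
#' Collects every tunable of the imaging stage. Defaults follow the
#' published workflow where one is stated (IsoData for nuclei, Yen for
#' TUNEL, pericyte circularity cutoff 0.6) and are explicit, configurable
#' stand-ins where the original analysis was interactive (Otsu for
#' vessel/positive-area masks, minimum object sizes replacing manual
#' artifact exclusion).
#'
#' @param circularity_cutoff nuclei outside the vessel mask with circularity
#'   `<=` this value are pericytes; in `(0, 1]`.
#' @param nuclear_threshold_method threshold for the DAPI channel.
#' @param puncta_threshold_method threshold for the TUNEL channel.
#' @param mask_threshold_method threshold for vessel masks and positive areas.
#' @param min_nucleus_area minimum nucleus area in um^2 (artifact filter).
#' @param min_punctum_area minimum punctum area in um^2.
#' @param min_mask_object_area minimum connected vessel-mask object in um^2.
#' @param max_hole_area_um2 holes in the vessel mask up to this area are
#'   filled (collapsed lumina and staining voids become part of the solid
#'   mask); larger enclosed regions -- the avascular faces of the vessel
#'   network mesh -- are left open.
#' @param closing_radius_px disc radius (pixels) for morphological closing of
#'   the vessel mask ("solid" mask).
#' @param watershed_tolerance minimum height of an object in the watershed
#'   height map to stay a separate object (EBImage convention).
#' @param smoothing_sigma_px Gaussian pre-smoothing (pixels) applied to a
#'   channel before thresholding and watershed; suppresses shot/readout
#'   noise during segmentation. Marker intensities are always measured on
#'   the raw channel.
#' @param puncta_smoothing_sigma_px pre-smoothing for the TUNEL channel;
#'   defaults to the typical punctum scale (matched filtering is the
#'   standard choice for spot detection).
#' @return a list of class `quant_params`.
#' @export
quant_params <- function(circularity_cutoff = 0.6,
                         nuclear_threshold_method = "isodata",
                         puncta_threshold_method = "yen",
                         mask_threshold_method = "otsu",
                         min_nucleus_area = 10,
                         min_punctum_area = 0.5,
                         min_mask_object_area = 50,
                         max_hole_area_um2 = 1000,
                         closing_radius_px = 3,
                         watershed_tolerance = 1,
                         smoothing_sigma_px = 1,
                         puncta_smoothing_sigma_px = 1.5) {
  stopifnot(circularity_cutoff > 0, circularity_cutoff <= 1,
            min_nucleus_area >= 0, min_punctum_area >= 0,
            min_mask_object_area >= 0, closing_radius_px >= 0)
  structure(list(
    circularity_cutoff = circularity_cutoff,
    nuclear_threshold_method = nuclear_threshold_method,
    puncta_threshold_method = puncta_threshold_method,
    mask_threshold_method = mask_threshold_method,
    min_nucleus_area = min_nucleus_area,
    min_punctum_area = min_punctum_area,
    min_mask_object_area = min_mask_object_area,
    max_hole_area_um2 = max_hole_area_um2,
    closing_radius_px = closing_radius_px,
    watershed_tolerance = watershed_tolerance,
    smoothing_sigma_px = smoothing_sigma_px,
    puncta_smoothing_sigma_px = puncta_smoothing_sigma_px
  ), class = "quant_params")
}

# ---- internal segmentation helpers -------------------------------------

smooth_channel <- function(m, sigma) {
  if (is.null(sigma) || sigma <= 0) return(m)
  EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

# Fill enclosed background components (holes) up to max_px pixels;
# background touching the image border is never a hole.
fill_small_holes <- function(mask, max_px) {
  if (max_px <= 0 || all(mask)) return(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image((!mask) * 1)))
  storage.mode(lab) <- "integer"
  if (max(lab) == 0) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  fill <- setdiff(which(sizes <= max_px), border)
  if (length(fill)) mask[lab %in% fill] <- TRUE
  mask
}

# Remove labelled objects smaller than min_px pixels; relabel 1..n.
filter_small_objects <- function(lab, min_px) {
  if (max(lab) == 0 || min_px <= 1) return(lab)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  drop <- which(sizes < min_px)
  if (length(drop)) {
    lab[lab %in% drop] <- 0L
    lab <- EBImage::imageData(EBImage::reenumerate(EBImage::Image(lab)))
  }
  storage.mode(lab) <- "integer"
  lab
}

# Perimeter of each labelled object from its oriented boundary contour:
# polygon length over the 8-connected boundary chain (closed).
contour_perimeters <- function(lab) {
  n <- max(lab)
  if (n == 0) return(numeric(0))
  oc <- EBImage::ocontour(EBImage::Image(lab))
  vapply(seq_len(n), function(i) {
    pts <- oc[[i]]
    if (is.null(pts) || nrow(pts) < 2) return(4) # isolated pixel: unit square
    d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2))
    sum(d)
  }, numeric(1))
}

# Object table (0-based centroids, px units) from a label matrix.
label_table <- function(lab) {
  n <- max(lab)
  if (n == 0) {
    return(tibble::tibble(id = integer(), area_px = numeric(),
                          centroid_row = numeric(), centroid_col = numeric()))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  area <- tabulate(l, nbins = n)
  cr <- as.numeric(tapply(idx[, 1], l, mean)) - 1
  cc <- as.numeric(tapply(idx[, 2], l, mean)) - 1
  tibble::tibble(id = seq_len(n), area_px = as.numeric(area),
                 centroid_row = cr, centroid_col = cc)
}

# Threshold + watershed segmentation shared by nuclei and puncta.
# height = "distance" (shape-based splitting) or "intensity".
segment_objects <- function(raster, threshold, height = c("distance",
                            "intensity"), min_area_px, tolerance) {
  height <- match.arg(height)
  bw <- raster > threshold
  if (!any(bw)) return(matrix(0L, nrow(raster), ncol(raster)))
  hm <- if (height == "distance") {
    EBImage::distmap(EBImage::Image(bw * 1))
  } else {
    # normalize so the watershed tolerance is on a comparable scale
    EBImage::Image((raster - threshold) / max(raster - threshold) * 10 * bw)
  }
  lab <- EBImage::imageData(EBImage::watershed(hm, tolerance = tolerance,
                                               ext = 1))
  storage.mode(lab) <- "integer"
  filter_small_objects(lab, min_area_px)
}

# ---- vessel mask --------------------------------------------------------

#' Build a solid vessel mask from an endothelial channel
#'
#' Automatic threshold (Otsu by default) on the CD31 channel, morphological
#' closing with a disc, size-limited hole filling (so collapsed lumina and
#' staining voids are part of the "solid" mask while the avascular mesh
#' faces between vessels stay open) and removal of small objects.
#'
#' @param image a [flatmount_image].
#' @param channel channel name, normally `"CD31"`.
#' @param params a [quant_params].
#' @return an object of class `vessel_mask`: logical matrix `mask`, the
#'   `source_channel`, `pixel_size` and `fill_state = TRUE`.
#' @export
build_vessel_mask <- function(image, channel = "CD31",
                              params = quant_params()) {
  m <- get_channel(image, channel)
  px <- image$pixel_size
  if (all(m == 0)) {
    warning(sprintf("channel '%s' is all zero: empty vessel mask", channel))
    return(new_vessel_mask(matrix(FALSE, nrow(m), ncol(m)), channel, px))
  }
  ms <- smooth_channel(m, params$smoothing_sigma_px)
  thr <- auto_threshold(ms, params$mask_threshold_method)
  bw <- ms > thr
  if (params$closing_radius_px > 0 && any(bw)) {
    brush <- EBImage::makeBrush(2 * params$closing_radius_px + 1, "disc")
    bw <- EBImage::imageData(EBImage::closing(EBImage::Image(bw * 1),
                                              brush)) > 0
  }
  bw <- fill_small_holes(bw, params$max_hole_area_um2 / px^2)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  storage.mode(lab) <- "integer"
  lab <- filter_small_objects(lab, params$min_mask_object_area / px^2)
  new_vessel_mask(lab > 0, channel, px)
}

new_vessel_mask <- function(mask, source_channel, pixel_size) {
  structure(list(mask = mask, source_channel = source_channel,
                 pixel_size = pixel_size, fill_state = TRUE),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> from '%s': %.0f um^2 positive (%d px)\n",
              x$source_channel, sum(x$mask) * x$pixel_size^2, sum(x$mask)))
  invisible(x)
}

#' Positive mask area in square micrometres
#' @param mask a `vessel_mask`.
#' @return area in um^2.
#' @export
mask_area <- function(mask) {
  stopifnot(inherits(mask, "vessel_mask"))
  sum(mask$mask) * mask$pixel_size^2
}

# ---- nuclei -------------------------------------------------------------

#' Segment nuclei from the DAPI channel
#'
#' IsoData global threshold on the DAPI raster, splitting of touching
#' nuclei by watershed on the Euclidean distance transform, and a minimum
#' area filter. Circularity is the Fiji-style index `4*pi*A/P^2` with the
#' perimeter measured on the boundary-following contour, clipped at 1.
#'
#' @inheritParams build_vessel_mask
#' @param dapi_channel DAPI channel name.
#' @return a tibble with one row per nucleus: `nucleus_id`, 0-based pixel
#'   centroid (`centroid_row`, `centroid_col`), `area_um2`, `perimeter_um`
#'   and `circularity`; the integer label matrix travels along as attribute
#'   `"label_matrix"` (pixel sets of all nuclei).
#' @export
segment_nuclei <- function(image, dapi_channel = "DAPI",
                           params = quant_params()) {
  m <- get_channel(image, dapi_channel)
  px <- image$pixel_size
  empty <- tibble::tibble(nucleus_id = integer(), centroid_row = numeric(),
                          centroid_col = numeric(), area_um2 = numeric(),
                          perimeter_um = numeric(), circularity = numeric())
  if (diff(range(m)) == 0) {
    attr(empty, "label_matrix") <- matrix(0L, nrow(m), ncol(m))
    attr(empty, "pixel_size") <- px
    return(empty)
  }
  ms <- smooth_channel(m, params$smoothing_sigma_px)
  thr <- auto_threshold(ms, params$nuclear_threshold_method)
  lab <- segment_objects(ms, thr, "distance",
                         min_area_px = params$min_nucleus_area / px^2,
                         tolerance = params$watershed_tolerance)
  tab <- label_table(lab)
  if (nrow(tab) == 0) {
    attr(empty, "label_matrix") <- lab
    attr(empty, "pixel_size") <- px
    return(empty)
  }
  per <- contour_perimeters(lab)
  out <- tibble::tibble(
    nucleus_id = tab$id,
    centroid_row = tab$centroid_row,
    centroid_col = tab$centroid_col,
    area_um2 = tab$area_px * px^2,
    perimeter_um = per * px,
    circularity = pmin(1, 4 * pi * tab$area_px / per^2)
  )
  attr(out, "label_matrix") <- lab
  attr(out, "pixel_size") <- px
  out
}

#' Classify nuclei as endothelial, pericyte or other
#'
#' A nucleus whose centroid falls inside the solid vessel mask is
#' endothelial; outside the mask, circularity `<=` the cutoff (default 0.6)
#' makes it a pericyte, otherwise `other_non_endothelial`.
#'
#' @param nuclei tibble from [segment_nuclei()].
#' @param mask a `vessel_mask` with `fill_state = TRUE`.
#' @param params a [quant_params].
#' @return `nuclei` with a `cell_class` factor column added.
#' @export
classify_cells <- function(nuclei, mask, params = quant_params()) {
  stopifnot(inherits(mask, "vessel_mask"), isTRUE(mask$fill_state))
  inside <- centroid_in_mask(nuclei$centroid_row, nuclei$centroid_col,
                             mask$mask)
  cls <- ifelse(inside, "endothelial",
                ifelse(nuclei$circularity <= params$circularity_cutoff,
                       "pericyte", "other_non_endothelial"))
  nuclei$cell_class <- factor(cls, levels = c("endothelial", "pericyte",
                                              "other_non_endothelial"))
  nuclei
}

# centroid membership at the nearest pixel (0-based centroids)
centroid_in_mask <- function(row0, col0, mask) {
  if (length(row0) == 0) return(logical(0))
  r <- pmin(pmax(round(row0) + 1, 1), nrow(mask))
  c <- pmin(pmax(round(col0) + 1, 1), ncol(mask))
  mask[cbind(r, c)]
}

# ---- marker intensities -------------------------------------------------

#' Background-corrected nuclear marker intensities
#'
#' Background is the mean marker intensity inside the vessel mask excluding
#' all nuclear pixels. Each nucleus gets an integrated intensity
#' `sum(pixels) - background * n_pixels`; negative values are retained.
#' The per-flatmount summary is the median over nuclei of each class.
#'
#' @param image a [flatmount_image].
#' @param marker_channel channel name of the nuclear marker (e.g. LEF1, ZEB1).
#' @param nuclei classified tibble from [classify_cells()] (the label matrix
#'   attribute of [segment_nuclei()] must still be attached).
#' @param mask a `vessel_mask`.
#' @return a list with `nuclei` (input tibble plus a column named after the
#'   marker holding corrected integrated intensities), `background` (mean
#'   background level) and `summary` (tibble of per-class medians).
#' @export
quantify_nuclear_marker <- function(image, marker_channel, nuclei, mask) {
  m <- get_channel(image, marker_channel)
  lab <- attr(nuclei, "label_matrix")
  stopifnot(!is.null(lab), inherits(mask, "vessel_mask"))
  bg_region <- mask$mask & lab == 0
  if (!any(bg_region)) {
    stop("empty background region (vessel mask minus nuclei)", call. = FALSE)
  }
  background <- mean(m[bg_region])
  n <- nrow(nuclei)
  vals <- numeric(n)
  if (n > 0) {
    inlab <- lab > 0
    l <- lab[inlab]
    sums <- rep(0, max(lab))
    s <- tapply(m[inlab], l, sum)
    sums[as.integer(names(s))] <- s
    sizes <- tabulate(l, nbins = max(lab))
    vals <- sums[nuclei$nucleus_id] - background * sizes[nuclei$nucleus_id]
  }
  nuclei[[marker_channel]] <- vals
  summary <- if (n > 0 && "cell_class" %in% names(nuclei)) {
    dplyr::summarise(dplyr::group_by(nuclei, .data$cell_class),
                     median_intensity = stats::median(.data[[marker_channel]]),
                     n_nuclei = dplyr::n(), .groups = "drop")
  } else {
    tibble::tibble(cell_class = factor(), median_intensity = numeric(),
                   n_nuclei = integer())
  }
  list(nuclei = nuclei, background = background, summary = summary)
}

#' Background-corrected membrane marker intensity
#'
#' For membrane markers (VE-cadherin) the background is taken outside the
#' vessel mask: the result is `mean(inside) - mean(outside)`, one value per
#' field.
#'
#' @inheritParams quantify_nuclear_marker
#' @return a single numeric, the background-corrected mean intensity.
#' @export
quantify_membrane_marker <- function(image, marker_channel, mask) {
  m <- get_channel(image, marker_channel)
  stopifnot(inherits(mask, "vessel_mask"))
  n_in <- sum(mask$mask)
  if (n_in == 0 || n_in == length(mask$mask)) {
    stop("degenerate vessel mask: inside and outside regions must both be non-empty",
         call. = FALSE)
  }
  mean(m[mask$mask]) - mean(m[!mask$mask])
}

# ---- TUNEL puncta -------------------------------------------------------

#' Detect TUNEL puncta
#'
#' Yen global threshold on the TUNEL channel, watershed splitting on the
#' masked intensity (so touching puncta with distinct maxima separate) and
#' a minimum-area filter. A punctum whose centroid lies outside the vessel
#' mask is `extravascular`; the rest are provisionally `intravascular`
#' until segments are assigned by [assign_puncta_to_segments()].
#'
#' @inheritParams build_vessel_mask
#' @param tunel_channel TUNEL channel name.
#' @param mask a `vessel_mask`.
#' @return tibble with one row per punctum: `punctum_id`, centroid (0-based
#'   px), `area_um2`, `location_class`, `segment_id` (NA before
#'   assignment); label matrix as attribute `"label_matrix"`.
#' @export
detect_tunel_puncta <- function(image, tunel_channel = "TUNEL", mask,
                                params = quant_params()) {
  m <- get_channel(image, tunel_channel)
  px <- image$pixel_size
  empty <- tibble::tibble(punctum_id = integer(), centroid_row = numeric(),
                          centroid_col = numeric(), area_um2 = numeric(),
                          location_class = character(),
                          segment_id = integer())
  if (diff(range(m)) == 0) {
    attr(empty, "label_matrix") <- matrix(0L, nrow(m), ncol(m))
    return(empty)
  }
  ms <- smooth_channel(m, params$puncta_smoothing_sigma_px)
  thr <- auto_threshold(ms, params$puncta_threshold_method)
  lab <- segment_objects(ms, thr, "intensity",
                         min_area_px = params$min_punctum_area / px^2,
                         tolerance = params$watershed_tolerance)
  tab <- label_table(lab)
  if (nrow(tab) == 0) {
    attr(empty, "label_matrix") <- lab
    return(empty)
  }
  inside <- centroid_in_mask(tab$centroid_row, tab$centroid_col, mask$mask)
  out <- tibble::tibble(
    punctum_id = tab$id,
    centroid_row = tab$centroid_row,
    centroid_col = tab$centroid_col,
    area_um2 = tab$area_px * px^2,
    location_class = ifelse(inside, "intravascular", "extravascular"),
    segment_id = NA_integer_
  )
  attr(out, "label_matrix") <- lab
  out
}

# ---- areas and replicates ----------------------------------------------

#' Positive area of a channel
#'
#' Thresholds a channel (Otsu by default, configurable) and reports the
#' positive area in um^2, optionally normalized to a denominator channel
#' and expressed as a percentage of a control-group mean ratio.
#'
#' @inheritParams build_vessel_mask
#' @param denominator_channel optional channel whose positive area divides
#'   the numerator (e.g. GPR124 area over CD31 area).
#' @param control_mean_ratio optional control-group mean of the same ratio;
#'   when given, `percent_of_control = 100 * ratio / control_mean_ratio`.
#' @return one-row tibble: `channel`, `area_um2`, and when requested
#'   `ratio` and `percent_of_control`.
#' @export
positive_area <- function(image, channel, params = quant_params(),
                          denominator_channel = NULL,
                          control_mean_ratio = NULL) {
  m <- get_channel(image, channel)
  px2 <- image$pixel_size^2
  pos_px <- function(x) {
    if (diff(range(x)) == 0) return(sum(x > 0))
    sum(x > auto_threshold(x, params$mask_threshold_method))
  }
  area <- pos_px(m) * px2
  out <- tibble::tibble(channel = channel, area_um2 = area)
  if (!is.null(denominator_channel)) {
    d <- get_channel(image, denominator_channel)
    denom_area <- pos_px(d) * px2
    if (denom_area <= 0) {
      stop(sprintf("denominator channel '%s' has zero positive area",
                   denominator_channel), call. = FALSE)
    }
    out$denominator <- denominator_channel
    out$ratio <- area / denom_area
    if (!is.null(control_mean_ratio)) {
      if (control_mean_ratio <= 0) stop("control mean ratio must be > 0",
                                        call. = FALSE)
      out$percent_of_control <- 100 * out$ratio / control_mean_ratio
    }
  }
  out
}

#' Average technical replicates into biological replicates
#'
#' Fields of view from one flatmount, and the two eyes of one animal, are
#' technical replicates: the biological replicate value is their mean, one
#' row per animal.
#'
#' @param data a data frame of per-field (or per-eye) measurements.
#' @param value column holding the measured value (tidy-eval).
#' @param animal column identifying the animal (tidy-eval).
#' @param ... additional grouping columns carried through (e.g. genotype).
#' @return tibble with one row per animal: grouping columns, `value`
#'   (mean over that animal's replicates) and `n_replicates`.
#' @export
aggregate_replicates <- function(data, value, animal, ...) {
  value <- rlang::enquo(value)
  animal <- rlang::enquo(animal)
  grps <- rlang::enquos(...)
  data <- dplyr::filter(data, !is.na(!!value))
  if (nrow(data) == 0) {
    warning("no non-missing values; returning empty table")
  }
  dplyr::summarise(
    dplyr::group_by(data, !!animal, !!!grps),
    value = mean(!!value),
    n_replicates = dplyr::n(),
    .groups = "drop"
  )
}
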