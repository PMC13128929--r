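#' Express per-animal values as a percentage of the control group
#'
#' Each biological-replicate value is divided by the mean of the control
#' group and multiplied by 100, so the control group averages 100% by
#' construction.
#'
#' @param data data frame of per-animal values.
#' @param value value column (tidy-eval).
#' @param group group column (tidy-eval).
#' @param control_group label of the control group.
#' @return `data` with a `percent_of_control` column added.
#' @export
percent_of_control <- function(data, value, group, control_group) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  gvals <- rlang::eval_tidy(group, data)
  vvals <- rlang::eval_tidy(value, data)
  ctrl <- vvals[gvals == control_group]
  if (length(ctrl) == 0) stop("control group is empty", call. = FALSE)
  m <- mean(ctrl)
  if (!is.finite(m) || m == 0) {
    stop("control group mean is zero or non-finite", call. = FALSE)
  }
  dplyr::mutate(data, percent_of_control = 100 * !!value / m)
}

#' Run the full flatmount quantification pipeline on one image
#'
#' Builds the solid CD31 mask, segments and classifies nuclei, quantifies
#' any requested nuclear/membrane markers, detects TUNEL puncta, traces
#' the vessel skeleton graph, assigns puncta to segments, classifies
#' segments as regressing or intact and assembles the per-flatmount
#' summary.
#'
#' @param image a [flatmount_image] with at least DAPI and CD31 channels.
#' @param dapi_channel,cd31_channel,tunel_channel channel names; set
#'   `tunel_channel = NULL` to skip puncta and topology.
#' @param nuclear_markers,membrane_markers character vectors of channel
#'   names to quantify.
#' @param params a [quant_params].
#' @param topo_params a [topology_params].
#' @return object of class `hyaloid_quant`: list with `mask`, `nuclei`,
#'   `puncta`, `graph`, `segment_calls`, `regression_summary`,
#'   `marker_summaries`, `membrane_intensities`, `params`.
#' @export
run_flatmount_pipeline <- function(image, dapi_channel = "DAPI",
                                   cd31_channel = "CD31",
                                   tunel_channel = "TUNEL",
                                   nuclear_markers = character(),
                                   membrane_markers = character(),
                                   params = quant_params(),
                                   topo_params = topology_params()) {
  stopifnot(inherits(image, "flatmount_image"))
  for (ch in c(dapi_channel, cd31_channel, tunel_channel,
               nuclear_markers, membrane_markers)) {
    get_channel(image, ch)  # fail early, naming the channel
  }
  mask <- build_vessel_mask(image, cd31_channel, params)
  nuclei <- segment_nuclei(image, dapi_channel, params)
  nuclei <- classify_cells(nuclei, mask, params)
  marker_summaries <- list()
  for (mk in nuclear_markers) {
    q <- quantify_nuclear_marker(image, mk, nuclei, mask)
    nuclei <- q$nuclei
    marker_summaries[[mk]] <- q$summary
  }
  membrane <- purrr::map_dbl(membrane_markers, function(mk) {
    quantify_membrane_marker(image, mk, mask)
  })
  names(membrane) <- membrane_markers
  puncta <- NULL; graph <- NULL; calls <- NULL; summary <- NULL
  if (!is.null(tunel_channel)) {
    puncta <- detect_tunel_puncta(image, tunel_channel, mask, params)
    graph <- skeletonize_graph(mask, topo_params)
    puncta <- assign_puncta_to_segments(graph, puncta, topo_params)
    calls <- classify_segments(graph, puncta, image, cd31_channel,
                               mask = mask, params = topo_params)
    summary <- flatmount_regression_summary(calls)
  }
  structure(list(mask = mask, nuclei = nuclei, puncta = puncta,
                 graph = graph, segment_calls = calls,
                 regression_summary = summary,
                 marker_summaries = marker_summaries,
                 membrane_intensities = membrane,
                 params = params, topo_params = topo_params,
                 pixel_size = image$pixel_size),
            class = "hyaloid_quant")
}

#' @export
print.hyaloid_quant <- function(x, ...) {
  cat("<hyaloid_quant>\n")
  cat(sprintf("  vessel mask: %.0f um^2\n", mask_area(x$mask)))
  if (nrow(x$nuclei)) {
    tab <- table(x$nuclei$cell_class)
    cat(sprintf("  nuclei: %d (%s)\n", nrow(x$nuclei),
                paste(names(tab), tab, sep = "=", collapse = ", ")))
  } else cat("  nuclei: 0\n")
  if (!is.null(x$puncta)) {
    cat(sprintf("  TUNEL puncta: %d\n", nrow(x$puncta)))
  }
  if (!is.null(x$regression_summary)) {
    s <- x$regression_summary
    cat(sprintf("  segments: %d regressing (of %d), %d puncta in regressing, %d in intact\n",
                s$n_regressing_segments, nrow(x$segment_calls),
                s$total_puncta_in_regressing, s$total_puncta_in_intact))
  }
  invisible(x)
}

#' Run the SORT-seq pipeline from UMI counts to DEG and enrichment
#'
#' Applies, in the stated order: plate-depth normalization, QC (total UMI
#' within `[umi_min, umi_max]`, mitochondrial percentage below
#' `mito_max`), marker-rule cell typing, log-normalization, per-cell-type
#' differential expression between genotypes (logistic regression +
#' likelihood-ratio test), and optional hypergeometric enrichment and
#' marker-panel screens when gene sets are supplied.
#'
#' @param counts a [counts_matrix].
#' @param group1,group2 genotype labels compared (group1 vs group2).
#' @param gene_sets optional named list of gene sets for enrichment of the
#'   significant DEG per cell type.
#' @param panels optional named list of marker panels for [panel_screen()].
#' @param umi_min,umi_max,mito_max,mito_prefix QC settings.
#' @param ec_marker,pc_marker cell-typing markers.
#' @param p_cutoff,fc_cutoff DE significance cutoffs.
#' @param min_cells_per_group cell types with fewer cells than this in
#'   either genotype are not tested.
#' @return object of class `hyaloid_sortseq`: `qc`, `cell_types`,
#'   `retained` counts, `expr` (log-normalized), `de` (named list of
#'   [differential_expression()] tibbles per cell type), `enrichment`,
#'   `panel_hits`.
#' @export
run_sortseq_pipeline <- function(counts, group1 = "control",
                                 group2 = "knockout", gene_sets = NULL,
                                 panels = NULL, umi_min = 1000,
                                 umi_max = 8000, mito_max = 10,
                                 mito_prefix = "mt-", ec_marker = "Cldn5",
                                 pc_marker = "Pdgfrb", p_cutoff = 0.05,
                                 fc_cutoff = 1, min_cells_per_group = 3) {
  stopifnot(inherits(counts, "counts_matrix"))
  norm <- normalize_plates(counts)
  qc <- qc_filter(norm, umi_min, umi_max, mito_max, mito_prefix)
  kept <- qc$counts
  types <- assign_cell_types(kept, ec_marker, pc_marker)
  expr <- log_normalize(kept)
  de <- list(); enr <- list(); hits <- list()
  for (ct in c("endothelial", "pericyte")) {
    sel <- types$call == ct
    if (sum(sel & types$genotype == group1) < min_cells_per_group ||
        sum(sel & types$genotype == group2) < min_cells_per_group) next
    e <- expr[, sel, drop = FALSE]
    g <- types$genotype[sel]
    d <- differential_expression(e, g, group1, group2,
                                 p_cutoff = p_cutoff,
                                 fc_cutoff = fc_cutoff)
    de[[ct]] <- d
    if (!is.null(gene_sets)) {
      sig <- d$gene[d$significant]
      if (length(sig) > 0) {
        enr[[ct]] <- hypergeometric_enrichment(sig, gene_sets,
                                               universe = rownames(e))
      }
    }
    if (!is.null(panels)) hits[[ct]] <- panel_screen(d, panels)
  }
  structure(list(qc = qc$qc, cell_types = types, retained = kept,
                 expr = expr, de = de, enrichment = enr,
                 panel_hits = hits, groups = c(group1, group2)),
            class = "hyaloid_sortseq")
}

#' @export
print.hyaloid_sortseq <- function(x, ...) {
  cat("<hyaloid_sortseq>\n")
  cat(sprintf("  QC: %d of %d cells retained\n", sum(x$qc$pass),
              nrow(x$qc)))
  tab <- table(x$cell_types$call, x$cell_types$genotype)
  cat("  cell types x genotype:\n")
  print(tab)
  for (ct in names(x$de)) {
    cat(sprintf("  %s DEG: %d significant of %d tested\n", ct,
                sum(x$de[[ct]]$significant), nrow(x$de[[ct]])))
  }
  invisible(x)
}
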