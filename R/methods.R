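#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for pipeline results
#'
#' `tidy()` returns the per-object table (nuclei for a flatmount run, one
#' row per gene for a DE result); `glance()` returns a one-row summary.
#'
#' @param x a `hyaloid_quant`, `hyaloid_de` or `hyaloid_sortseq` object.
#' @param ... unused.
#' @name hyaloidr-tidiers
NULL

#' @rdname hyaloidr-tidiers
#' @method tidy hyaloid_quant
#' @export
tidy.hyaloid_quant <- function(x, ...) {
  out <- x$nuclei
  attr(out, "label_matrix") <- NULL
  tibble::as_tibble(out)
}

#' @rdname hyaloidr-tidiers
#' @method glance hyaloid_quant
#' @export
glance.hyaloid_quant <- function(x, ...) {
  tab <- table(x$nuclei$cell_class)
  base <- tibble::tibble(
    mask_area_um2 = mask_area(x$mask),
    n_nuclei = nrow(x$nuclei),
    n_endothelial = as.integer(tab["endothelial"]),
    n_pericyte = as.integer(tab["pericyte"]),
    n_other = as.integer(tab["other_non_endothelial"]),
    n_puncta = if (is.null(x$puncta)) NA_integer_ else nrow(x$puncta)
  )
  if (!is.null(x$regression_summary)) {
    base <- dplyr::bind_cols(base, x$regression_summary)
  }
  base
}

#' @rdname hyaloidr-tidiers
#' @method tidy hyaloid_de
#' @export
tidy.hyaloid_de <- function(x, ...) {
  tibble::tibble(term = x$gene, estimate = x$log2fc, p.value = x$p_value,
                 significant = x$significant, converged = x$converged)
}

#' @rdname hyaloidr-tidiers
#' @method glance hyaloid_de
#' @export
glance.hyaloid_de <- function(x, ...) {
  grp <- attr(x, "groups")
  nc <- attr(x, "n_cells")
  tibble::tibble(n_genes_tested = nrow(x),
                 n_significant = sum(x$significant),
                 n_up_in_group1 = sum(x$significant & x$log2fc > 0),
                 n_down_in_group1 = sum(x$significant & x$log2fc < 0),
                 group1 = grp[1], group2 = grp[2],
                 n_cells_group1 = nc[1], n_cells_group2 = nc[2])
}

#' @rdname hyaloidr-tidiers
#' @method glance hyaloid_sortseq
#' @export
glance.hyaloid_sortseq <- function(x, ...) {
  tibble::tibble(
    n_cells_input = nrow(x$qc),
    n_cells_retained = sum(x$qc$pass),
    n_endothelial = sum(x$cell_types$call == "endothelial"),
    n_pericyte = sum(x$cell_types$call == "pericyte"),
    n_excluded = sum(x$cell_types$call == "excluded"),
    n_deg_endothelial = if ("endothelial" %in% names(x$de)) {
      sum(x$de$endothelial$significant)
    } else NA_integer_,
    n_deg_pericyte = if ("pericyte" %in% names(x$de)) {
      sum(x$de$pericyte$significant)
    } else NA_integer_
  )
}

#' Plot methods for pipeline results
#'
#' For a flatmount run: nucleus centroids coloured by class and TUNEL
#' puncta over the vessel skeleton. For a DE result: a volcano plot with
#' the significance cutoffs drawn.
#'
#' @param object a `hyaloid_quant` or `hyaloid_de` object.
#' @param ... unused.
#' @return a ggplot object.
#' @name hyaloidr-autoplot
NULL

#' @rdname hyaloidr-autoplot
#' @method autoplot hyaloid_quant
#' @export
autoplot.hyaloid_quant <- function(object, ...) {
  nuc <- tidy(object)
  p <- ggplot2::ggplot()
  skel <- object$graph$skeleton
  if (!is.null(skel) && any(skel)) {
    sk <- which(skel, arr.ind = TRUE)
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(row = sk[, 1] - 1, col = sk[, 2] - 1),
      ggplot2::aes(x = .data$col, y = .data$row),
      colour = "grey70", size = 0.1)
  }
  if (nrow(nuc)) {
    p <- p + ggplot2::geom_point(
      data = nuc,
      ggplot2::aes(x = .data$centroid_col, y = .data$centroid_row,
                   colour = .data$cell_class), size = 2)
  }
  if (!is.null(object$puncta) && nrow(object$puncta)) {
    p <- p + ggplot2::geom_point(
      data = object$puncta,
      ggplot2::aes(x = .data$centroid_col, y = .data$centroid_row),
      shape = 4, colour = "red", size = 1.5)
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
    ggplot2::labs(x = "col (px)", y = "row (px)", colour = "cell class",
                  title = "Flatmount quantification")
}

#' @rdname hyaloidr-autoplot
#' @method autoplot hyaloid_de
#' @export
autoplot.hyaloid_de <- function(object, ...) {
  cut <- attr(object, "cutoffs")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-cut[["fc"]], cut[["fc"]]),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(cut[["p"]]),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = "log2 fold change (group1 / group2)",
                  y = "-log10 p (LRT)", colour = "significant")
}
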