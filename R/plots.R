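#' Plot a residue cross-correlation map
#'
#' Heatmap of the map in the field's usual colouring: red for concerted
#' motion (+1), blue for anti-correlated motion (-1).
#'
#' @param object A `correlation_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$resno_i, y = .data$resno_j,
                               fill = .data$correlation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1),
                                  name = "C(i,j)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue i", y = "residue j",
                  title = sprintf("Cross-correlation map (%d modes)",
                                  attr(object, "n_modes_used"))) +
    ggplot2::theme_minimal()
}

#' Plot a per-residue B-factor profile
#'
#' @param object A `bfactor_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bfactor_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$resno, y = .data$bfactor)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "B-factor (arb. units)",
                  title = sprintf("B-factor profile (%s)",
                                  attr(object, "source") %||% "")) +
    ggplot2::theme_minimal()
}

#' Plot an RMSD time series
#'
#' @param object An `rmsd_series` from [trajectory_rmsd()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rmsd_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$rmsd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (reduced units)", y = "RMSD (Å)") +
    ggplot2::theme_minimal()
}

#' Plot WT-vs-mutant B-factor profiles of a report
#'
#' Overlays the per-variant NMA B-factor profiles (or trajectory-derived
#' profiles if the report was simulated), with the motif region shaded —
#' the at-a-glance answer to "does the mutation mobilise the motif?".
#'
#' @param object A `motif_report`.
#' @param source `"nma"` or `"trajectory"` (requires a simulated report).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motif_report <- function(object, source = c("nma", "trajectory"), ...) {
  source <- match.arg(source)
  prof <- purrr::map_dfr(object$variants, function(v) {
    b <- if (source == "nma") v$nma_bfactors else v$simulation$traj_bfactors
    dplyr::mutate(tibble::as_tibble(b), variant = v$label)
  })
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$resno, y = .data$bfactor,
                                     colour = .data$variant)) +
    ggplot2::annotate("rect", xmin = min(object$motif) - 0.5,
                      xmax = max(object$motif) + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "B-factor (arb. units)",
                  colour = "variant",
                  title = sprintf("Per-residue B-factors (%s); motif shaded",
                                  source)) +
    ggplot2::theme_minimal()
}
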