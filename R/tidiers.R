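#' Tidy a correlation map into long form
#'
#' @param x A `correlation_map`.
#' @param ... Unused.
#' @return A tibble with columns `resno_i`, `resno_j`, `correlation`.
#' @export
tidy.correlation_map <- function(x, ...) {
  resno <- attr(x, "resno")
  m <- unclass(x)
  attributes(m) <- attributes(m)["dim"]
  tibble::tibble(
    resno_i = rep(resno, times = length(resno)),
    resno_j = rep(resno, each = length(resno)),
    correlation = as.vector(m))
}

#' Tidy a mode set into an eigenvalue table
#'
#' @param x A `mode_set`.
#' @param ... Unused.
#' @return A tibble with columns `mode`, `lambda`, `is_zero`.
#' @export
tidy.mode_set <- function(x, ...) {
  tibble::tibble(mode = seq_along(x$values), lambda = x$values,
                 is_zero = seq_along(x$values) <= x$n_zero)
}

#' One-row summary of a mode set
#'
#' @param x A `mode_set`.
#' @param ... Unused.
#' @return A one-row tibble: `n_modes`, `n_zero`, `lambda_min_nonzero`,
#'   `lambda_max`.
#' @export
glance.mode_set <- function(x, ...) {
  tibble::tibble(
    n_modes = length(x$values), n_zero = x$n_zero,
    lambda_min_nonzero = if (length(x$values) > x$n_zero)
      x$values[x$n_zero + 1] else NA_real_,
    lambda_max = max(x$values))
}

#' One-row summary of an elastic-network model
#'
#' @param x An `enm_model`.
#' @param ... Unused.
#' @return A one-row tibble: `n_sites`, `n_contacts`, `cutoff`, `gamma`,
#'   `n_mutations`.
#' @export
glance.enm_model <- function(x, ...) {
  d2 <- as.matrix(stats::dist(coords(x$structure)))^2
  tibble::tibble(
    n_sites = nrow(x$structure),
    n_contacts = sum(d2 <= x$cutoff^2 & upper.tri(d2)),
    cutoff = x$cutoff, gamma = x$gamma, n_mutations = length(x$mutations))
}

#' Tidy a B-factor profile
#'
#' @param x A `bfactor_profile`.
#' @param ... Unused.
#' @return A tibble with `chain`, `resno`, `bfactor`, `source`.
#' @export
tidy.bfactor_profile <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x),
                source = attr(x, "source") %||% NA_character_)
}

#' Per-variant summary table of a motif report
#'
#' @param x A `motif_report`.
#' @param ... Unused.
#' @return A tibble, one row per variant: mean coupling of the mutation
#'   sites to the motif, mean NMA motif B-factor, and (when simulated)
#'   trailing-window mean RMSD (all sites and motif) and mean trajectory
#'   motif B-factor.
#' @export
tidy.motif_report <- function(x, ...) {
  purrr::map_dfr(x$variants, function(v) {
    tibble::tibble(
      variant = v$label,
      coupling = if (nrow(v$coupling) > 0) mean(v$coupling$coupling) else NA_real_,
      mean_motif_nma_bfactor = v$mean_motif_nma_bfactor,
      mean_rmsd_all = if (is.null(v$simulation)) NA_real_ else v$simulation$mean_rmsd_all,
      mean_rmsd_motif = if (is.null(v$simulation)) NA_real_ else v$simulation$mean_rmsd_motif,
      mean_motif_traj_bfactor = if (is.null(v$simulation)) NA_real_
        else v$simulation$mean_motif_bfactor)
  })
}

#' One-row overview of a motif report
#'
#' @param x A `motif_report`.
#' @param ... Unused.
#' @return A one-row tibble: structure size, motif size, variant count,
#'   modes used, whether the Langevin stage ran, and the config hash.
#' @export
glance.motif_report <- function(x, ...) {
  tibble::tibble(
    n_residues = nrow(x$structure),
    n_motif = length(x$motif),
    n_variants = length(x$variants),
    n_modes_used = attr(x$variants$WT$correlation, "n_modes_used"),
    simulated = !is.null(x$variants$WT$simulation),
    config_hash = x$provenance$config_hash)
}
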