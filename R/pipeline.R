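#' Run the full motif-perturbation analysis for a structure
#'
#' Orchestrates the whole comparison the package exists for: given a
#' structure, a motif, and one or more candidate mutations, it analyses
#' the wild type and each single-mutant elastic network and reports how
#' the mutation changes the motif's dynamics. Per variant:
#' [build_hessian()] -> [diagonalize()] -> [cross_correlation()] ->
#' [coupling_score()] (each mutation site vs. the motif) ->
#' [nma_bfactors()]; and, when `simulation` is supplied,
#' [simulate_enm()] -> [trajectory_rmsd()] (all sites and motif) ->
#' [mean_rmsd()] over the trailing window -> [trajectory_bfactors()].
#' When `ligand` is given, the minimum C-alpha distance from each
#' mutation site to the ligand-binding selection is reported.
#'
#' The wild type is always computed, even if only mutants are supplied,
#' because every mutant statement is a delta against it. All variants
#' share the same simulation parameters and seed (common random numbers),
#' so variant differences are not noise differences.
#'
#' @param structure A `ca_structure`, or a path to a PDB file.
#' @param motif Integer vector of motif residue numbers; defaults to the
#'   structure's motif annotation if present.
#' @param mutations A `mutation_spec` or list of them; each is analysed
#'   as its own single-mutant variant.
#' @param ligand Optional integer vector of ligand-binding residue
#'   numbers for distance reporting.
#' @param cutoff,gamma,n_modes,weighting,kT Elastic-network and NMA
#'   parameters; see [build_hessian()] and [cross_correlation()].
#' @param simulation Optional [sim_params()]; `NULL` skips the Langevin
#'   stage and the report is NMA-only.
#' @param window Trailing fraction of the trajectory analysed
#'   (default 0.5, the second half).
#' @param output_dir Optional directory; when given, every table behind
#'   the report is written as CSV (plus dense-matrix correlation files
#'   and a provenance file) before the report is returned.
#' @return A `motif_report`; see [tidy.motif_report()],
#'   [compare_variants()], [autoplot.motif_report()].
#' @examples
#' hlh <- make_structure(toy_spec("helix_loop_helix", 40))
#' rep <- run_pipeline(hlh, mutations = mutation_spec(attr(hlh, "mutation_sites")),
#'                     n_modes = 20)
#' tidy(rep)
#' @export
run_pipeline <- function(structure, motif = NULL, mutations = list(),
                         ligand = NULL, cutoff = 13, gamma = 1,
                         n_modes = 50,
                         weighting = c("inverse_lambda", "equal"),
                         kT = 1, simulation = NULL, window = 0.5,
                         output_dir = NULL) {
  weighting <- match.arg(weighting)
  if (is.character(structure)) structure <- read_structure(structure)
  stopifnot(inherits(structure, "ca_structure"))
  motif <- motif %||% attr(structure, "motif")
  if (is.null(motif)) {
    abort("no motif given and the structure carries no motif annotation",
          class = "flexmotif_argument_error")
  }
  mutations <- normalise_mutations(mutations)
  if (!is.null(simulation)) stopifnot(inherits(simulation, "sim_params"))

  # every selection must resolve before any computation starts
  motif_idx <- resolve_selection(structure, motif)
  for (m in mutations) resolve_selection(structure, m$resno, m$chain)
  ligand_idx <- if (!is.null(ligand)) resolve_selection(structure, ligand)

  mut_sites <- vapply(mutations, `[[`, integer(1), "resno")
  variants <- c(list(WT = NULL),
                setNames(lapply(mutations, list),
                         vapply(mutations, format, character(1))))

  results <- lapply(names(variants), function(label) {
    mut <- variants[[label]]
    model <- build_hessian(structure, cutoff, gamma,
                           mutations = if (is.null(mut)) NULL else mut[[1]],
                           masses = 1)
    ms <- diagonalize(model)
    cm <- cross_correlation(ms, n_modes, weighting)
    nma_b <- nma_bfactors(ms, n_modes, kT, weighting)
    coupling <- tibble::tibble(
      site = mut_sites,
      coupling = vapply(mut_sites, function(site)
        coupling_score(cm, site, motif), numeric(1)))
    sim <- NULL
    if (!is.null(simulation)) {
      traj <- simulate_enm(model, simulation)
      rmsd_all <- trajectory_rmsd(traj)
      rmsd_motif <- trajectory_rmsd(traj, motif_idx, "fit_all")
      traj_b <- trajectory_bfactors(traj, window)
      sim <- list(
        rmsd_all = rmsd_all, rmsd_motif = rmsd_motif, traj_bfactors = traj_b,
        mean_rmsd_all = mean_rmsd(rmsd_all, window),
        mean_rmsd_motif = mean_rmsd(rmsd_motif, window),
        mean_motif_bfactor = mean(traj_b$bfactor[motif_idx]))
    }
    list(label = label, mutation = mut, correlation = cm, nma_bfactors = nma_b,
         coupling = coupling, mean_motif_nma_bfactor = mean(nma_b$bfactor[motif_idx]),
         simulation = sim)
  })
  names(results) <- names(variants)

  ligand_distances <- NULL
  if (!is.null(ligand) && length(mut_sites) > 0) {
    ligand_distances <- tibble::tibble(
      site = mut_sites,
      min_distance = vapply(mut_sites, function(site)
        min_distance(structure, site, setdiff(ligand, site)), numeric(1)))
  }

  config <- list(motif = motif, cutoff = cutoff, gamma = gamma,
                 n_modes = n_modes, weighting = weighting, kT = kT,
                 window = window, simulation = simulation,
                 mutations = vapply(mutations, format, character(1)))
  report <- structure(
    list(structure = structure, motif = motif, motif_idx = motif_idx,
         variants = results, ligand_distances = ligand_distances,
         config = config,
         provenance = list(
           config_hash = rlang::hash(config),
           structure_hash = rlang::hash(coords(structure)),
           seed = if (is.null(simulation)) NA_integer_ else simulation$seed,
           package_version = as.character(packageVersion("flexmotif")))),
    class = "motif_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.motif_report <- function(x, ...) {
  cat(sprintf("<motif_report: %d variant(s), motif %s, %d residues%s>\n",
              length(x$variants), format_resno_range(x$motif),
              nrow(x$structure),
              if (is.null(x$variants$WT$simulation)) "" else ", simulated"))
  print(tidy(x), ...)
  invisible(x)
}

#' Write every table behind a report to disk
#'
#' One CSV per quantity and variant (coupling scores, B-factor profiles,
#' RMSD series), the correlation map both as labelled CSV and dense
#' whitespace matrix, a summary table, and a plain-text provenance file
#' (config hash, seed, package version) sufficient to reproduce the run.
#'
#' @param report A `motif_report`.
#' @param output_dir Directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(output_dir, paste0(...))
  for (label in names(report$variants)) {
    v <- report$variants[[label]]
    write_correlation_map(v$correlation, fp("correlation_", label, ".csv"), "csv")
    write_correlation_map(v$correlation, fp("correlation_", label, ".mat"), "matrix")
    write.csv(tibble::as_tibble(v$nma_bfactors), fp("nma_bfactors_", label, ".csv"),
              row.names = FALSE)
    write.csv(v$coupling, fp("coupling_", label, ".csv"), row.names = FALSE)
    if (!is.null(v$simulation)) {
      write.csv(tibble::as_tibble(v$simulation$rmsd_all),
                fp("rmsd_all_", label, ".csv"), row.names = FALSE)
      write.csv(tibble::as_tibble(v$simulation$rmsd_motif),
                fp("rmsd_motif_", label, ".csv"), row.names = FALSE)
      write.csv(tibble::as_tibble(v$simulation$traj_bfactors),
                fp("traj_bfactors_", label, ".csv"), row.names = FALSE)
    }
  }
  if (!is.null(report$ligand_distances)) {
    write.csv(report$ligand_distances, fp("ligand_distances.csv"),
              row.names = FALSE)
  }
  write.csv(tidy(report), fp("summary.csv"), row.names = FALSE)
  prov <- report$provenance
  writeLines(c(
    sprintf("config_hash %s", prov$config_hash),
    sprintf("structure_hash %s", prov$structure_hash),
    sprintf("seed %s", prov$seed),
    sprintf("package_version %s", prov$package_version),
    sprintf("motif %s", paste(report$motif, collapse = ",")),
    sprintf("mutations %s", paste(report$config$mutations, collapse = ","))
  ), fp("provenance.txt"))
  invisible(output_dir)
}

#' Per-variant deltas against the wild type
#'
#' One row per mutant: the change relative to WT in motif coupling score
#' (mean over mutation sites), trailing-window mean motif RMSD, and mean
#' motif B-factor (trajectory-derived when the report was simulated,
#' NMA-derived otherwise). Positive deltas mean the mutant's motif is
#' more mobile / more strongly coupled than the wild type's.
#'
#' @param report A `motif_report` with at least one mutant variant.
#' @return A tibble with columns `variant`, `delta_coupling`,
#'   `delta_mean_motif_rmsd`, `delta_mean_motif_bfactor`,
#'   `bfactor_source`.
#' @export
compare_variants <- function(report) {
  stopifnot(inherits(report, "motif_report"))
  if (is.null(report$variants$WT)) {
    abort("report contains no WT variant", class = "flexmotif_argument_error")
  }
  if (length(report$variants) < 2) {
    abort("report needs at least one mutant variant to compare",
          class = "flexmotif_argument_error")
  }
  wt <- report$variants$WT
  simulated <- !is.null(wt$simulation)
  wt_b <- if (simulated) wt$simulation$mean_motif_bfactor else wt$mean_motif_nma_bfactor
  purrr::map_dfr(
    report$variants[setdiff(names(report$variants), "WT")],
    function(v) {
      v_b <- if (simulated) v$simulation$mean_motif_bfactor else v$mean_motif_nma_bfactor
      tibble::tibble(
        variant = v$label,
        delta_coupling = mean(v$coupling$coupling) - mean(wt$coupling$coupling),
        delta_mean_motif_rmsd = if (simulated)
          v$simulation$mean_rmsd_motif - wt$simulation$mean_rmsd_motif
          else NA_real_,
        delta_mean_motif_bfactor = v_b - wt_b,
        bfactor_source = if (simulated) "trajectory" else "nma")
    })
}
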