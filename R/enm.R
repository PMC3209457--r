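#' Build an anisotropic elastic-network Hessian
#'
#' Connects every pair of C-alpha sites closer than `cutoff` with a
#' Hookean spring of stiffness `gamma` and assembles the standard
#' anisotropic-network Hessian: for a contact (i, j) with equilibrium
#' separation vector d, the off-diagonal 3 x 3 super-element is
#' \eqn{-\gamma_{ij}\, d d^T / |d|^2}, and each diagonal block is minus
#' the sum of the off-diagonal blocks in its row (so rigid translations
#' cost nothing). The input structure is the energy minimum by
#' construction; no prior minimisation is needed.
#'
#' Point mutations enter as local spring perturbations: for every contact
#' incident to a mutated residue, \eqn{\gamma_{ij}} is multiplied by that
#' mutation's `spring_scale` (if both endpoints are mutated the scales
#' multiply). `spring_scale < 1` models weakened local packing, e.g. a
#' hydrophobic residue replaced by a hydrophilic one inside a
#' hydrophobic patch.
#'
#' @param s A `ca_structure`; at least 3 non-collinear sites for a real
#'   model (a 2-site dimer, the textbook closed-form case, is also
#'   accepted: one stretch mode of stiffness 2*gamma and five zero modes).
#' @param cutoff Contact cutoff distance in Angstrom (default 13, common
#'   anisotropic-network practice for C-alpha models).
#' @param gamma Baseline spring constant, arbitrary units (default 1).
#' @param mutations A `mutation_spec`, or list of them, or `NULL`.
#' @param masses Per-site positive masses (default uniform 1, in which
#'   case mass weighting is the identity). Length-1 values are recycled.
#' @return An `enm_model` list: `structure`, `cutoff`, `gamma`, `masses`,
#'   `mutations`, and the 3N x 3N symmetric `hessian`.
#' @examples
#' helix <- make_structure(toy_spec("helix", 20))
#' mod <- build_hessian(helix)
#' mod
#' @export
build_hessian <- function(s, cutoff = 13, gamma = 1, mutations = NULL,
                          masses = 1) {
  stopifnot(inherits(s, "ca_structure"))
  n <- nrow(s)
  if (n < 2) {
    abort("elastic network needs at least 2 sites", class = "flexmotif_argument_error")
  }
  if (cutoff <= 0 || gamma <= 0) {
    abort("`cutoff` and `gamma` must be positive", class = "flexmotif_argument_error")
  }
  xyz <- coords(s)
  # a 2-site dimer is the textbook closed-form case and is allowed;
  # larger collinear arrangements are floppy and rejected here
  if (n >= 3 && is_collinear(xyz)) {
    abort("sites are collinear; the 3D network is degenerate",
          class = "flexmotif_argument_error")
  }
  masses <- rep_len(as.numeric(masses), n)
  if (any(!is.finite(masses) | masses <= 0)) {
    abort("`masses` must be positive and finite", class = "flexmotif_argument_error")
  }
  mutations <- normalise_mutations(mutations)
  scale_at <- rep(1, n)
  for (m in mutations) {
    i <- resolve_selection(s, m$resno, m$chain)
    scale_at[i] <- scale_at[i] * m$spring_scale
  }

  d2 <- as.matrix(stats::dist(xyz))^2
  contact <- d2 <= cutoff^2
  diag(contact) <- FALSE
  if (!is_connected(contact)) {
    abort(sprintf(
      "contact graph is disconnected at cutoff %g Angstrom; increase the cutoff",
      cutoff), class = "flexmotif_connectivity_error")
  }

  h <- matrix(0, 3 * n, 3 * n)
  pairs <- which(contact & upper.tri(contact), arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]
    j <- pairs[p, 2]
    d <- xyz[j, ] - xyz[i, ]
    k_ij <- gamma * scale_at[i] * scale_at[j]
    block <- -k_ij * tcrossprod(d) / sum(d^2)
    ri <- (3 * i - 2):(3 * i)
    rj <- (3 * j - 2):(3 * j)
    h[ri, rj] <- block
    h[rj, ri] <- block
    h[ri, ri] <- h[ri, ri] - block
    h[rj, rj] <- h[rj, rj] - block
  }

  structure(
    list(structure = s, cutoff = cutoff, gamma = gamma, masses = masses,
         mutations = mutations, hessian = h),
    class = "enm_model"
  )
}

normalise_mutations <- function(mutations) {
  if (is.null(mutations)) return(list())
  if (inherits(mutations, "mutation_spec")) return(list(mutations))
  if (is.list(mutations) && all(vapply(mutations, inherits, logical(1),
                                       "mutation_spec"))) {
    return(mutations)
  }
  abort("`mutations` must be a mutation_spec or a list of mutation_spec",
        class = "flexmotif_argument_error")
}

is_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier) > 0) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' @export
print.enm_model <- function(x, ...) {
  n <- nrow(x$structure)
  cat(sprintf("<enm_model: %d sites, cutoff %g A, gamma %g, %d mutation(s)>\n",
              n, x$cutoff, x$gamma, length(x$mutations)))
  invisible(x)
}

#' Normal mode analysis: diagonalize the mass-weighted Hessian
#'
#' Computes the full spectrum of \eqn{M^{-1/2} H M^{-1/2}} in ascending
#' order. A connected three-dimensional network has exactly six zero
#' modes (three rigid translations, three rigid rotations); these are
#' identified by \eqn{|\lambda| < 10^{-8} \lambda_{max}} and bookkept in
#' `n_zero`. More than six numerical zeros means the network is floppy
#' and the model is rejected.
#'
#' @param model An `enm_model` from [build_hessian()].
#' @return A `mode_set` list: `values` (eigenvalues ascending), `vectors`
#'   (orthonormal columns, mass-weighted coordinates), `n_zero`, `masses`.
#' @export
diagonalize <- function(model) {
  stopifnot(inherits(model, "enm_model"))
  w <- rep(1 / sqrt(model$masses), each = 3)
  hm <- model$hessian * outer(w, w)
  eig <- eigen(hm, symmetric = TRUE)
  ord <- order(eig$values)
  values <- eig$values[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  tol <- 1e-8 * max(abs(values))
  n_zero <- sum(abs(values) < tol)
  if (n_zero > 6) {
    abort(sprintf(
      "%d near-zero modes found (expected 6): the network is floppy at this cutoff",
      n_zero), class = "flexmotif_degeneracy_error")
  }
  structure(
    list(values = values, vectors = vectors, n_zero = n_zero,
         masses = model$masses, structure = model$structure),
    class = "mode_set"
  )
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf(
    "<mode_set: %d modes (%d zero), lowest nonzero lambda = %.4g>\n",
    length(x$values), x$n_zero,
    if (length(x$values) > x$n_zero) x$values[x$n_zero + 1] else NA_real_))
  invisible(x)
}

# Indices of the n_modes lowest nonzero modes, clamped with a warning.
nonzero_mode_indices <- function(ms, n_modes) {
  available <- length(ms$values) - ms$n_zero
  if (n_modes < 1) {
    abort("`n_modes` must be at least 1", class = "flexmotif_argument_error")
  }
  if (n_modes > available) {
    warn(sprintf("requested %d modes but only %d nonzero modes exist; using %d",
                 n_modes, available, available))
    n_modes <- available
  }
  ms$n_zero + seq_len(n_modes)
}

#' Residue covariance from a set of normal modes
#'
#' The 3N x 3N thermal displacement covariance of a harmonic model is
#' \eqn{k_B T \sum_k u_k u_k^T / \lambda_k} over nonzero modes (the
#' Moore-Penrose pseudo-inverse of the Hessian when all nonzero modes are
#' used). This function contracts it to the N x N per-residue matrix
#' \eqn{K_{ij} = \sum_k (u_{k,i} \cdot u_{k,j}) / \lambda_k}, with
#' \eqn{u_{k,i}} the 3-vector of site i in mode k (Cartesian, i.e. mass
#' de-weighted). `weighting = "equal"` drops the \eqn{1/\lambda_k}
#' factor, averaging mode shapes with equal weight instead of thermal
#' amplitudes; it is offered because "average correlation over modes" is
#' stated ambiguously in parts of the literature.
#'
#' @param ms A `mode_set`.
#' @param n_modes Number of lowest nonzero modes to use (clamped to the
#'   available count with a warning).
#' @param weighting `"inverse_lambda"` (default, thermal amplitudes) or
#'   `"equal"`.
#' @return N x N symmetric covariance matrix (arbitrary units, kT = 1).
#' @export
mode_covariance <- function(ms, n_modes = 50,
                            weighting = c("inverse_lambda", "equal")) {
  stopifnot(inherits(ms, "mode_set"))
  weighting <- match.arg(weighting)
  idx <- nonzero_mode_indices(ms, n_modes)
  wcoord <- rep(1 / sqrt(ms$masses), each = 3)
  u <- ms$vectors[, idx, drop = FALSE] * wcoord   # Cartesian mode shapes
  amp <- if (weighting == "inverse_lambda") 1 / sqrt(ms$values[idx]) else 1
  u <- sweep(u, 2, amp, `*`)
  n <- length(ms$masses)
  k <- matrix(0, n, n)
  for (a in 1:3) {
    rows <- seq(a, 3 * n, by = 3)
    k <- k + tcrossprod(u[rows, , drop = FALSE])
  }
  attr(k, "n_modes_used") <- length(idx)
  attr(k, "weighting") <- weighting
  k
}

#' Residue cross-correlation map from normal modes
#'
#' Normalised displacement covariance over the `n_modes` lowest nonzero
#' modes: \eqn{C_{ij} = K_{ij} / \sqrt{K_{ii} K_{jj}}}. +1 means two
#' residues move in concert, -1 in antiphase; long-range off-diagonal
#' structure is the signature of dynamic coupling between distant
#' segments (e.g. a binding motif and a remote helix carrying a disease
#' mutation).
#'
#' @inheritParams mode_covariance
#' @return A `correlation_map`: N x N matrix in \[-1, 1\] with unit
#'   diagonal, residue numbers as dimnames, attributes `resno`, `chain`,
#'   `n_modes_used`, `weighting`.
#' @examples
#' ms <- diagonalize(build_hessian(make_structure(toy_spec("helix", 25))))
#' cm <- cross_correlation(ms, n_modes = 20)
#' range(cm)
#' @export
cross_correlation <- function(ms, n_modes = 50,
                              weighting = c("inverse_lambda", "equal")) {
  weighting <- match.arg(weighting)
  k <- mode_covariance(ms, n_modes, weighting)
  d <- sqrt(diag(k))
  cm <- k / outer(d, d)
  cm <- pmin(pmax(cm, -1), 1)
  diag(cm) <- 1
  resno <- ms$structure$resno
  dimnames(cm) <- list(resno, resno)
  structure(cm, class = c("correlation_map", class(cm)),
            resno = resno, chain = ms$structure$chain,
            n_modes_used = attr(k, "n_modes_used"),
            weighting = weighting)
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map: %d x %d residues, %d mode(s), %s weighting>\n",
              nrow(x), ncol(x), attr(x, "n_modes_used"), attr(x, "weighting")))
  invisible(x)
}

#' Per-residue B-factors from normal modes
#'
#' \eqn{B_i = (8\pi^2/3)\, k_B T\, K_{ii}} with \eqn{K_{ii}} the
#' mean-square fluctuation of site i from [mode_covariance()]. Units are
#' Angstrom-squared times the arbitrary prefactor set by `gamma`; the
#' profile's shape (which residues are floppy relative to others) is the
#' meaningful quantity.
#'
#' @inheritParams mode_covariance
#' @param kT Thermal energy in reduced units (default 1).
#' @return A `bfactor_profile` tibble: `chain`, `resno`, `bfactor`, with
#'   attribute `source = "nma"`.
#' @export
nma_bfactors <- function(ms, n_modes = 50, kT = 1,
                         weighting = c("inverse_lambda", "equal")) {
  weighting <- match.arg(weighting)
  k <- mode_covariance(ms, n_modes, weighting)
  new_bfactor_profile(ms$structure, (8 * pi^2 / 3) * kT * diag(k),
                      source = "nma")
}

new_bfactor_profile <- function(s, values, source) {
  tibble::new_tibble(
    tibble::tibble(chain = s$chain, resno = s$resno, bfactor = values),
    source = source, class = "bfactor_profile"
  )
}

#' @export
print.bfactor_profile <- function(x, ...) {
  cat(sprintf("# A bfactor_profile (%s): %d residues\n",
              attr(x, "source") %||% "unknown", nrow(x)))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Dynamic coupling between one site and a motif
#'
#' Scalar summary of how strongly one residue's motion is correlated with
#' a motif: the mean absolute cross-correlation between the site and the
#' motif residues. 1 means perfectly (anti-)correlated with every motif
#' residue, 0 means dynamically decoupled. Useful for ranking mutation
#' sites by their coupling to a functional segment.
#'
#' @param cm A `correlation_map`.
#' @param site Residue number of the probe site.
#' @param motif Integer vector of motif residue numbers.
#' @param exclude_self Drop the site itself from the motif if present
#'   (default `TRUE`).
#' @return A number in \[0, 1\].
#' @export
coupling_score <- function(cm, site, motif, exclude_self = TRUE) {
  stopifnot(inherits(cm, "correlation_map"))
  resno <- attr(cm, "resno")
  i <- match(as.integer(site), resno)
  if (is.na(i)) {
    abort(sprintf("site residue %d not present in the map", site),
          class = "flexmotif_selection_error")
  }
  j <- match(sort(unique(as.integer(motif))), resno)
  if (anyNA(j)) {
    abort("motif contains residues not present in the map",
          class = "flexmotif_selection_error")
  }
  if (exclude_self) j <- setdiff(j, i)
  if (length(j) == 0) {
    abort("motif is empty after excluding the site itself",
          class = "flexmotif_selection_error")
  }
  mean(abs(cm[i, j]))
}

#' Export a correlation map as dense text or labelled CSV
#'
#' @param cm A `correlation_map`.
#' @param path Output file path.
#' @param format `"csv"` (residue-number labelled) or `"matrix"` (dense
#'   whitespace-separated values, one row per line).
#' @return `path`, invisibly.
#' @export
write_correlation_map <- function(cm, path, format = c("csv", "matrix")) {
  format <- match.arg(format)
  m <- unclass(cm)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  if (format == "csv") {
    write.csv(as.data.frame(m), path, row.names = TRUE)
  } else {
    writeLines(apply(format(m, digits = 10, trim = TRUE), 1, paste,
                     collapse = " "), path)
  }
  invisible(path)
}

#' Export a mode set as a plain-text table
#'
#' One record per mode: the eigenvalue followed by the 3N eigenvector
#' components.
#'
#' @param ms A `mode_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_modes <- function(ms, path) {
  tab <- cbind(lambda = ms$values, t(ms$vectors))
  writeLines(apply(format(tab, digits = 10, trim = TRUE), 1, paste,
                   collapse = " "), path)
  invisible(path)
}
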