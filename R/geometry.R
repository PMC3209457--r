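#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `mobile` onto `reference` (closed-form SVD solution; reflections are
#' excluded by flipping the sign of the smallest singular direction when
#' the determinant would be negative).
#'
#' @param mobile,reference N x 3 coordinate matrices (or `ca_structure`s)
#'   with equal N >= 3.
#' @return A `superposition` list with elements `rotation` (3 x 3, proper
#'   orthonormal), `translation` (length 3), and `rmsd` (Angstrom). The
#'   fitted coordinates are `mobile %*% t(rotation) + translation` (row
#'   convention).
#' @export
superpose <- function(mobile, reference) {
  a <- as_coord_matrix(mobile)
  b <- as_coord_matrix(reference)
  check_same_shape(a, b)
  if (nrow(a) < 3) {
    abort("superposition needs at least 3 sites", class = "flexmotif_degeneracy_error")
  }
  if (is_collinear(b)) {
    abort("reference sites are collinear; the fit is degenerate",
          class = "flexmotif_degeneracy_error")
  }
  ca <- colMeans(a)
  cb <- colMeans(b)
  am <- sweep(a, 2, ca)
  bm <- sweep(b, 2, cb)
  h <- crossprod(am, bm)          # 3x3 cross-covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- am %*% t(rot)
  rmsd_val <- sqrt(mean(rowSums((fitted - bm)^2)))
  structure(
    list(rotation = rot, translation = as.numeric(cb - ca %*% t(rot)),
         rmsd = rmsd_val),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: rmsd = %.4f Angstrom>\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition to a coordinate set
#'
#' @param sp A `superposition` from [superpose()].
#' @param xyz N x 3 coordinate matrix (or `ca_structure`).
#' @return Transformed N x 3 matrix.
#' @export
apply_superposition <- function(sp, xyz) {
  m <- as_coord_matrix(xyz)
  sweep(m %*% t(sp$rotation), 2, sp$translation, `+`)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param a,b N x 3 coordinate matrices (or `ca_structure`s), equal N.
#' @param fit If `TRUE` (default) superpose `a` onto `b` first
#'   (least-squares rigid fit); if `FALSE` measure in place.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, fit = TRUE) {
  am <- as_coord_matrix(a)
  bm <- as_coord_matrix(b)
  check_same_shape(am, bm)
  if (fit) {
    superpose(am, bm)$rmsd
  } else {
    sqrt(mean(rowSums((am - bm)^2)))
  }
}

#' RMSD of a motif subset after superposition
#'
#' The two fitting conventions answer different questions. `fit_all`
#' superposes on every site and then measures deviation over the motif
#' only: motion of the motif relative to the whole molecule's frame.
#' `fit_motif` superposes on the motif sites themselves: internal
#' deformation of the motif, blind to its rigid-body displacement. By
#' construction the `fit_motif` value is the least-squares minimum over
#' the motif, so it never exceeds the `fit_all` value.
#'
#' @param frame,reference N x 3 coordinate matrices (or `ca_structure`s).
#' @param motif Integer vector of 1-based site indices, valid in both sets.
#' @param fit_mode `"fit_all"` (default) or `"fit_motif"`.
#' @return RMSD over the motif sites, Angstrom.
#' @export
motif_rmsd <- function(frame, reference, motif,
                       fit_mode = c("fit_all", "fit_motif")) {
  fit_mode <- match.arg(fit_mode)
  fm <- as_coord_matrix(frame)
  rm_ <- as_coord_matrix(reference)
  check_same_shape(fm, rm_)
  motif <- as.integer(motif)
  if (length(motif) == 0) {
    abort("empty motif selection", class = "flexmotif_selection_error")
  }
  if (any(motif < 1 | motif > nrow(fm))) {
    abort("motif indices out of range", class = "flexmotif_selection_error")
  }
  fit_idx <- if (fit_mode == "fit_all") seq_len(nrow(fm)) else motif
  sp <- superpose(fm[fit_idx, , drop = FALSE], rm_[fit_idx, , drop = FALSE])
  fitted <- apply_superposition(sp, fm)
  sqrt(mean(rowSums((fitted[motif, , drop = FALSE] -
                       rm_[motif, , drop = FALSE])^2)))
}

#' Minimum distance between two residue selections
#'
#' The smallest C-alpha--C-alpha Euclidean distance over all cross pairs,
#' e.g. from a mutation site to the residues lining a cofactor pocket.
#' Note this is a coarse-grained backbone distance; all-atom contact
#' distances on the same structure are systematically shorter.
#'
#' @param s A `ca_structure`.
#' @param resno_a,resno_b Disjoint residue-number selections.
#' @param chain_a,chain_b Optional chain restrictions for each selection.
#' @return Minimum distance in Angstrom.
#' @export
min_distance <- function(s, resno_a, resno_b, chain_a = NULL, chain_b = NULL) {
  ia <- resolve_selection(s, resno_a, chain_a)
  ib <- resolve_selection(s, resno_b, chain_b)
  if (length(intersect(ia, ib)) > 0) {
    abort("selections overlap; minimum distance needs disjoint selections",
          class = "flexmotif_selection_error")
  }
  xyz <- coords(s)
  a <- xyz[ia, , drop = FALSE]
  b <- xyz[ib, , drop = FALSE]
  # |a_i - b_j|^2 = |a_i|^2 + |b_j|^2 - 2 a_i . b_j
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

as_coord_matrix <- function(x) {
  if (inherits(x, "ca_structure")) return(coords(x))
  m <- as.matrix(x)
  if (ncol(m) != 3) {
    abort("coordinates must be an N x 3 matrix", class = "flexmotif_shape_error")
  }
  if (!all(is.finite(m))) {
    abort("coordinates must be finite", class = "flexmotif_shape_error")
  }
  storage.mode(m) <- "double"
  m
}

check_same_shape <- function(a, b) {
  if (nrow(a) != nrow(b)) {
    abort(sprintf("coordinate sets differ in size (%d vs %d sites)",
                  nrow(a), nrow(b)),
          class = "flexmotif_shape_error")
  }
  invisible(TRUE)
}

is_collinear <- function(m, tol = 1e-10) {
  mm <- sweep(m, 2, colMeans(m))
  sv <- svd(mm, nu = 0, nv = 0)$d
  sum(sv > tol * max(sv, tol)) < 2
}
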