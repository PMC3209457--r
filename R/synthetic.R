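#' Specification of a synthetic C-alpha toy structure
#'
#' Seeded generators of compact folded C-alpha chains with the geometric
#' properties the elastic-network analysis assumes: enough contacts at
#' the default cutoff that the network is rigid (exactly six zero
#' modes). Three kinds:
#'
#' * `"helix"` — an ideal alpha-helical C-alpha trace. The defaults
#'   (rise 1.5 A per residue, twist 100 degrees, helix radius 2.3 A)
#'   are the canonical alpha-helix parameters and give the canonical
#'   ~3.8 A consecutive C-alpha spacing.
#' * `"helix_loop_helix"` — two packed antiparallel helices joined by a
#'   4-residue loop; a toy of a strand/helix arrangement whose
#'   connecting loop is a ligand-binding segment. The loop residues are
#'   annotated as the structure's motif and the residue preceding the
#'   loop as the default mutation site.
#' * `"cloud"` — points uniform in a sphere with a 3.5 A minimum
#'   separation (rejection sampling), a compact globule with no
#'   secondary structure.
#'
#' @param kind `"helix"`, `"helix_loop_helix"`, or `"cloud"`.
#' @param n_residues Number of sites (>= 3; >= 12 for helix_loop_helix).
#' @param rise Helical rise per residue, Angstrom (default 1.5).
#' @param twist Helical twist per residue, degrees (default 100).
#' @param radius Helix radius, Angstrom (default 2.3).
#' @param seed RNG seed for the stochastic kinds and for `noise_sigma`.
#' @param noise_sigma Isotropic Gaussian noise added to every coordinate,
#'   Angstrom (default 0 = ideal geometry).
#' @return A `toy_spec` list, consumed by [make_structure()].
#' @export
toy_spec <- function(kind = c("helix", "helix_loop_helix", "cloud"),
                     n_residues, rise = 1.5, twist = 100, radius = 2.3,
                     seed = 1L, noise_sigma = 0) {
  kind <- match.arg(kind)
  n_residues <- as.integer(n_residues)
  if (n_residues < 3) abort("`n_residues` must be >= 3", class = "flexmotif_argument_error")
  if (kind == "helix_loop_helix" && n_residues < 12) {
    abort("helix_loop_helix needs at least 12 residues", class = "flexmotif_argument_error")
  }
  if (rise <= 0 || radius <= 0) {
    abort("`rise` and `radius` must be positive", class = "flexmotif_argument_error")
  }
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0", class = "flexmotif_argument_error")
  structure(
    list(kind = kind, n_residues = n_residues, rise = rise, twist = twist,
         radius = radius, seed = as.integer(seed), noise_sigma = noise_sigma),
    class = "toy_spec"
  )
}

#' Generate a synthetic structure from a toy specification
#'
#' Deterministic given the spec's seed. See [toy_spec()] for the kinds.
#'
#' @param spec A [toy_spec()].
#' @return A `ca_structure`; for `helix_loop_helix` the motif and default
#'   mutation-site annotations are set (see [as_ca_structure()]).
#' @examples
#' hlh <- make_structure(toy_spec("helix_loop_helix", 40))
#' attr(hlh, "motif")
#' @export
make_structure <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  set.seed(spec$seed)
  out <- switch(spec$kind,
    helix = make_helix(spec),
    helix_loop_helix = make_hlh(spec),
    cloud = make_cloud(spec)
  )
  if (spec$noise_sigma > 0) {
    xyz <- coords(out) + matrix(rnorm(3 * nrow(out), sd = spec$noise_sigma),
                                ncol = 3)
    out <- set_coords(out, xyz)
  }
  out
}

helix_points <- function(n, rise, twist, radius, phase = 0, origin = c(0, 0, 0),
                         direction = 1) {
  i <- seq_len(n) - 1
  theta <- (phase + twist * i) * pi / 180
  cbind(origin[1] + radius * cos(theta),
        origin[2] + radius * sin(theta),
        origin[3] + direction * rise * i)
}

make_helix <- function(spec) {
  xyz <- helix_points(spec$n_residues, spec$rise, spec$twist, spec$radius)
  as_ca_structure(site_tibble(xyz))
}

make_hlh <- function(spec) {
  n <- spec$n_residues
  n_loop <- 4L
  n1 <- (n - n_loop) %/% 2L
  n2 <- n - n_loop - n1
  sep <- 10  # axis-to-axis spacing of the packed helices, Angstrom
  h1 <- helix_points(n1, spec$rise, spec$twist, spec$radius)
  top2 <- spec$rise * (n2 - 1)
  h2 <- helix_points(n2, spec$rise, spec$twist, spec$radius,
                     origin = c(sep, 0, top2), direction = -1)
  # loop: arc over the helix tops from the end of h1 to the start of h2
  p <- h1[n1, ]
  q <- h2[1, ]
  t <- seq_len(n_loop) / (n_loop + 1)
  loop <- sapply(seq_along(p), function(a) p[a] + (q[a] - p[a]) * t)
  loop[, 3] <- loop[, 3] + 4 * sin(pi * t)
  xyz <- rbind(h1, loop, h2)
  as_ca_structure(site_tibble(xyz),
                  motif = (n1 + 1L):(n1 + n_loop),
                  mutation_sites = n1)
}

make_cloud <- function(spec, min_sep = 3.5, max_attempts = 1e5) {
  n <- spec$n_residues
  r_sphere <- 3.0 * n^(1 / 3)
  pts <- matrix(NA_real_, n, 3)
  n_placed <- 0
  for (attempt in seq_len(max_attempts)) {
    p <- runif(3, -r_sphere, r_sphere)
    if (sum(p^2) > r_sphere^2) next
    if (n_placed > 0) {
      d2 <- rowSums(sweep(pts[seq_len(n_placed), , drop = FALSE], 2, p)^2)
      if (min(d2) < min_sep^2) next
    }
    n_placed <- n_placed + 1
    pts[n_placed, ] <- p
    if (n_placed == n) break
  }
  if (n_placed < n) {
    abort(sprintf("could not place %d points with %.1f A separation in %d attempts",
                  n, min_sep, max_attempts),
          class = "flexmotif_generation_error")
  }
  as_ca_structure(site_tibble(pts))
}

site_tibble <- function(xyz) {
  tibble::tibble(chain = "A", resno = seq_len(nrow(xyz)), resname = "ALA",
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

#' Add isotropic Gaussian noise to a structure
#'
#' @param s A `ca_structure`.
#' @param sigma Noise standard deviation per coordinate, Angstrom
#'   (`sigma = 0` returns `s` unchanged).
#' @param seed RNG seed.
#' @return A perturbed `ca_structure` (annotations preserved).
#' @export
perturb <- function(s, sigma, seed = 1L) {
  stopifnot(inherits(s, "ca_structure"))
  if (sigma < 0) abort("`sigma` must be >= 0", class = "flexmotif_argument_error")
  if (sigma == 0) return(s)
  set.seed(seed)
  set_coords(s, coords(s) + matrix(rnorm(3 * nrow(s), sd = sigma), ncol = 3))
}
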