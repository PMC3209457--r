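#' Build a C-alpha structure from a data frame of sites
#'
#' A `ca_structure` is the object every stage of the package consumes: an
#' ordered tibble with one row per residue site, columns `chain`, `resno`,
#' `resname`, `x`, `y`, `z` (coordinates in Angstrom). Rows are sorted by
#' chain then residue number; `(chain, resno)` pairs must be unique and
#' coordinates finite. Optional motif / mutation-site annotations travel as
#' attributes so downstream calls need no hand-typed selections.
#'
#' @param sites Data frame with columns `chain` (character), `resno`
#'   (integer), `resname` (character, 3-letter codes), `x`, `y`, `z`
#'   (numeric, Angstrom).
#' @param model_id Integer model identifier (default 1).
#' @param motif Optional integer vector of residue numbers annotating a
#'   functional motif (e.g. a cofactor-binding segment).
#' @param mutation_sites Optional integer vector of residue numbers of
#'   interest for perturbation analysis.
#' @return A `ca_structure` tibble.
#' @examples
#' s <- as_ca_structure(data.frame(
#'   chain = "A", resno = 1:3, resname = "GLY",
#'   x = c(0, 3.8, 7.6), y = 0, z = 0
#' ))
#' s
#' @export
as_ca_structure <- function(sites, model_id = 1L, motif = NULL,
                            mutation_sites = NULL) {
  sites <- tibble::as_tibble(sites)
  needed <- c("chain", "resno", "resname", "x", "y", "z")
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols) > 0) {
    abort(paste0("`sites` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "flexmotif_structure_error")
  }
  sites <- dplyr::mutate(sites[needed],
                         chain = as.character(.data$chain),
                         resno = as.integer(.data$resno),
                         resname = as.character(.data$resname))
  sites <- dplyr::arrange(sites, .data$chain, .data$resno)
  out <- tibble::new_tibble(sites, model_id = as.integer(model_id),
                            motif = motif, mutation_sites = mutation_sites,
                            class = "ca_structure")
  validate_ca_structure(out)
}

validate_ca_structure <- function(s) {
  if (nrow(s) < 2) {
    abort("a structure needs at least 2 sites", class = "flexmotif_structure_error")
  }
  xyz <- as.matrix(s[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    abort("coordinates must be finite", class = "flexmotif_structure_error")
  }
  key <- paste(s$chain, s$resno)
  if (anyDuplicated(key)) {
    abort(paste0("duplicated (chain, resno) pairs: ",
                 paste(unique(key[duplicated(key)]), collapse = ", ")),
          class = "flexmotif_structure_error")
  }
  s
}

#' @export
print.ca_structure <- function(x, ...) {
  cat(sprintf("# A ca_structure: %d sites, %d chain(s), model %d\n",
              nrow(x), length(unique(x$chain)), attr(x, "model_id") %||% 1L))
  motif <- attr(x, "motif")
  if (!is.null(motif)) {
    cat(sprintf("# motif residues: %s\n", format_resno_range(motif)))
  }
  muts <- attr(x, "mutation_sites")
  if (!is.null(muts)) {
    cat(sprintf("# mutation sites: %s\n", paste(muts, collapse = ", ")))
  }
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

format_resno_range <- function(r) {
  r <- sort(unique(as.integer(r)))
  if (all(diff(r) == 1) && length(r) > 2) {
    sprintf("%d-%d", min(r), max(r))
  } else {
    paste(r, collapse = ", ")
  }
}

#' Extract the N x 3 coordinate matrix of a structure
#'
#' @param s A `ca_structure`.
#' @return Numeric matrix with one row per site, columns x/y/z (Angstrom).
#' @export
coords <- function(s) {
  stopifnot(inherits(s, "ca_structure"))
  m <- as.matrix(s[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

set_coords <- function(s, xyz) {
  s$x <- xyz[, 1]
  s$y <- xyz[, 2]
  s$z <- xyz[, 3]
  s
}

#' Read the C-alpha trace of a PDB file
#'
#' Parses ATOM records (via bio3d), keeps only C-alpha atoms of protein
#' residues, drops alternate locations other than the first listed, and
#' rejects insertion codes (out of scope for the coarse-grained model).
#' Multi-model files are supported through `model`.
#'
#' @param path Path to a PDB file.
#' @param model 1-based model number for multi-model files (default 1).
#' @return A `ca_structure` with author residue numbering preserved.
#' @seealso [write_structure()], [resolve_selection()]
#' @export
read_structure <- function(path, model = 1L) {
  if (!file.exists(path)) {
    abort(paste0("cannot read PDB file: ", path), class = "flexmotif_io_error")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) {
      abort(paste0("failed to parse PDB file ", path, ": ", conditionMessage(e)),
            class = "flexmotif_io_error")
    }
  )
  n_models <- nrow(pdb$xyz)
  if (model < 1 || model > n_models) {
    abort(sprintf("model %d requested but file has %d model(s)", model, n_models),
          class = "flexmotif_range_error")
  }
  sel <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  if (length(sel$atom) == 0) {
    abort(paste0("no C-alpha atoms found in ", path),
          class = "flexmotif_structure_error")
  }
  atom <- pdb$atom[sel$atom, , drop = FALSE]
  if (any(!is.na(atom$insert) & atom$insert != "")) {
    abort("insertion codes are not supported; renumber the structure first",
          class = "flexmotif_structure_error")
  }
  # altloc: keep the first listed record per (chain, resno)
  atom$chain[is.na(atom$chain)] <- "A"
  keep <- !duplicated(paste(atom$chain, atom$resno))
  atom <- atom[keep, , drop = FALSE]
  xyz_idx <- sel$xyz[rep(keep, each = 3)]
  xyz <- matrix(pdb$xyz[model, xyz_idx], ncol = 3, byrow = TRUE)
  as_ca_structure(
    tibble::tibble(chain = atom$chain, resno = atom$resno,
                   resname = atom$resid,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    model_id = model
  )
}

#' Write a C-alpha structure as a PDB file
#'
#' Emits one CA ATOM record per site (wwPDB fixed columns, coordinates at
#' 3 decimals), so `read_structure(write_structure(s))` reproduces `s` up
#' to coordinate rounding.
#'
#' @param s A `ca_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "ca_structure"))
  ok <- tryCatch({
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(coords(s))),
                     resno = s$resno, chain = s$chain, resid = s$resname,
                     elety = rep("CA", nrow(s)))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(paste0("cannot write PDB file ", path, ": ", conditionMessage(ok)),
          class = "flexmotif_io_error")
  }
  invisible(path)
}

#' Resolve residue numbers to site indices
#'
#' Maps author residue numbers (the numbering the literature speaks in,
#' e.g. a motif "residues 71-90") to 1-based row indices of the structure.
#' Every requested residue must resolve to exactly one site: absent
#' residues raise an error naming them rather than silently shrinking the
#' selection, and an ambiguous number (present in several chains) must be
#' disambiguated with `chain`.
#'
#' @param s A `ca_structure`.
#' @param resno Integer vector of residue numbers (duplicates ignored).
#' @param chain Optional chain identifier restricting the lookup.
#' @return Strictly increasing integer vector of site indices.
#' @export
resolve_selection <- function(s, resno, chain = NULL) {
  stopifnot(inherits(s, "ca_structure"))
  resno <- sort(unique(as.integer(resno)))
  if (length(resno) == 0) {
    abort("empty selection", class = "flexmotif_selection_error")
  }
  pool <- seq_len(nrow(s))
  if (!is.null(chain)) pool <- pool[s$chain == chain]
  idx <- lapply(resno, function(r) pool[s$resno[pool] == r])
  n_hit <- lengths(idx)
  if (any(n_hit == 0)) {
    abort(paste0("residue number(s) not present in structure: ",
                 paste(resno[n_hit == 0], collapse = ", ")),
          class = "flexmotif_selection_error")
  }
  if (any(n_hit > 1)) {
    abort(paste0("residue number(s) ambiguous across chains (give `chain`): ",
                 paste(resno[n_hit > 1], collapse = ", ")),
          class = "flexmotif_selection_error")
  }
  sort(unlist(idx))
}

#' Declare a point mutation as a spring perturbation
#'
#' In the elastic-network representation a substitution at one site is
#' modelled by rescaling the spring constants of every contact incident to
#' that site. `spring_scale < 1` weakens the local packing (the natural
#' reading of a hydrophobic-to-hydrophilic substitution such as Ala->Thr or
#' Phe->Ser inside a hydrophobic patch); the default 0.5 halves the local
#' stiffness. Amino-acid codes are annotation only — the coarse-grained
#' model has no sidechains.
#'
#' @param resno Residue number of the mutated site.
#' @param from,to Amino-acid codes (1- or 3-letter), annotation only.
#' @param spring_scale Positive multiplier applied to every spring incident
#'   to the site (default 0.5).
#' @param chain Optional chain identifier.
#' @return A `mutation_spec` object.
#' @examples
#' mutation_spec(84, "A", "T")             # the classic hotspot A84T
#' mutation_spec(128, "PHE", "SER", 0.25)  # stronger local softening
#' @export
mutation_spec <- function(resno, from = "X", to = "X", spring_scale = 0.5,
                          chain = NULL) {
  if (!is.numeric(spring_scale) || length(spring_scale) != 1 ||
      !is.finite(spring_scale) || spring_scale <= 0) {
    abort("`spring_scale` must be a single positive number",
          class = "flexmotif_argument_error")
  }
  structure(
    list(resno = as.integer(resno), from = toupper(from), to = toupper(to),
         spring_scale = spring_scale, chain = chain),
    class = "mutation_spec"
  )
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat(sprintf("<mutation %s%d%s, spring_scale = %g>\n",
              x$from, x$resno, x$to, x$spring_scale))
  invisible(x)
}

#' @export
format.mutation_spec <- function(x, ...) {
  sprintf("%s%d%s", x$from, x$resno, x$to)
}
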