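# Element -> van der Waals radius (Angstrom), ProtOr-like defaults.
default_vdw <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80, H = 1.20)

#' Build an atom set
#'
#' The tabular container for SASA computations: one row per atom with
#' element, chain, residue and coordinates in Angstrom, plus a van der Waals
#' radius assigned from an element table.
#'
#' @param df Data frame with columns `element`, `chain`, `resid` (residue
#'   name), `resno`, `x`, `y`, `z` and optionally `radius`.
#' @param radii Named vector of element radii overriding/extending the
#'   defaults (C 1.70, N 1.55, O 1.52, P 1.80, S 1.80, H 1.20 A).
#' @return A tibble of class `atom_set`.
#' @export
atom_set <- function(df, radii = NULL) {
  need <- c("element", "chain", "resid", "resno", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop_bad_arg(sprintf("atom table needs columns: %s", paste(need, collapse = ", ")))
  }
  df <- as_tibble(df)
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))) {
    stop_bad_arg("atom coordinates must be finite.")
  }
  table <- default_vdw
  if (!is.null(radii)) table[names(radii)] <- radii
  if (!"radius" %in% names(df) || all(is.na(df$radius))) {
    el <- toupper(df$element)
    unknown <- setdiff(unique(el), names(table))
    if (length(unknown)) {
      stop_bad_arg(sprintf("no van der Waals radius for element(s): %s (supply `radii`).",
                           paste(unknown, collapse = ", ")))
    }
    df$radius <- unname(table[el])
  }
  if (any(!is.finite(df$radius) | df$radius <= 0)) {
    stop_bad_arg("atom radii must be positive.")
  }
  class(df) <- c("atom_set", class(df))
  df
}

#' Read a structure file into an atom set
#'
#' Parses PDB or mmCIF via bio3d, resolves alternate locations to the
#' highest-occupancy conformer, drops waters/ions/ligands by default, and
#' assigns element-based van der Waals radii.
#'
#' @param source Path to a `.pdb` or `.cif` file.
#' @param format `"pdb"` or `"mmcif"`; guessed from the extension by default.
#' @param keep_hetero Keep HETATM records (waters, ions, ligands)?
#' @param radii Optional element-radius overrides (see [atom_set()]).
#' @return An `atom_set` tibble.
#' @export
read_structure <- function(source, format = c("auto", "pdb", "mmcif"),
                           keep_hetero = FALSE, radii = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", source, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop_bad_arg("structure parsing requires the bio3d package.")
  }
  parsed <- if (format == "mmcif") {
    # bio3d's CIF reader warns about its beta status and absent helix/sheet
    # records; neither affects the atom table
    suppressWarnings(bio3d::read.cif(source))
  } else {
    bio3d::read.pdb(source)
  }
  at <- parsed$atom
  if (!keep_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop_bad_arg("no atoms retained from structure file.")

  # alternate locations: keep the highest-occupancy conformer per atom
  alt <- at$alt
  if (!is.null(alt) && any(!is.na(alt) & alt != "")) {
    keyed <- paste(at$chain, at$resno, at$resid, at$elety)
    occ <- if (!is.null(at$o)) at$o else rep(1, nrow(at))
    ord <- order(keyed, -occ)
    at <- at[ord[!duplicated(keyed[ord])], , drop = FALSE]
  }

  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(el == "")) {
    el <- substr(trimws(at$elety), 1, 1) # fall back to first atom-name letter
  }
  atom_set(tibble(element = toupper(trimws(el)), chain = at$chain,
                  resid = at$resid, resno = at$resno,
                  x = at$x, y = at$y, z = at$z),
           radii = radii)
}

#' Build a toy DNA-ring/occluder complex
#'
#' Deterministic fixture for accessibility-ratio computations: the "free"
#' set is a planar ring of DNA-labeled pseudo-atoms (chain `D`, residue
#' `DA`); the "bound" set adds a single spherical occluder pseudo-atom on a
#' separate chain `R` (residue `OCC`), standing in for a bound remodeler.
#'
#' @param ring_radius Radius of the ring (Angstrom).
#' @param n_dna_atoms Number of ring atoms (>= 3).
#' @param atom_radius Van der Waals radius of the ring atoms (A).
#' @param occluder Optional list `list(center = c(x, y, z), radius = r)`.
#' @return List with `free` and `bound` [atom_set()] tibbles.
#' @examples
#' toy <- make_toy_complex(40, 72, occluder = list(center = c(60, 0, 0), radius = 45))
#' @export
make_toy_complex <- function(ring_radius, n_dna_atoms, atom_radius = 2,
                             occluder = NULL) {
  check_scalar_number(ring_radius, "ring_radius", min = 1e-9)
  if (n_dna_atoms < 3) stop_bad_arg("need at least 3 ring atoms.")
  theta <- 2 * pi * (seq_len(n_dna_atoms) - 1) / n_dna_atoms
  ring <- tibble(element = "P", chain = "D", resid = "DA",
                 resno = seq_len(n_dna_atoms),
                 x = ring_radius * cos(theta), y = ring_radius * sin(theta),
                 z = 0, radius = atom_radius)
  free <- atom_set(ring)
  bound <- free
  if (!is.null(occluder)) {
    if (occluder$radius <= 0) stop_bad_arg("occluder radius must be > 0.")
    occ <- tibble(element = "C", chain = "R", resid = "OCC", resno = 1L,
                  x = occluder$center[1], y = occluder$center[2],
                  z = occluder$center[3], radius = occluder$radius)
    bound <- atom_set(dplyr::bind_rows(ring, occ))
  }
  list(free = free, bound = bound)
}
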