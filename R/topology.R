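#' Atomic masses used by the package (g/mol)
#'
#' Minimal element table covering the atoms emitted by the synthetic
#' generators and typical membrane systems.
#' @export
atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.973762, S = 32.06)

#' Create a topology
#'
#' Per-atom metadata plus molecule grouping. Atom and molecule indices are
#' 1-based throughout the package (the R convention); the JSON fixture
#' dialect stores 0-based indices and converts at the boundary.
#'
#' @param atoms data.frame with columns `name`, `element`, `mass` (g/mol),
#'   `resid`, `resname`.
#' @param molecules list of integer vectors; each vector holds the atom
#'   indices of one molecule. Every atom must belong to exactly one
#'   molecule.
#' @return object of class `topology`.
#' @export
make_topology <- function(atoms, molecules) {
  need <- c("name", "element", "mass", "resid", "resname")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms)))
    stop("'atoms' must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("atom masses must be positive and finite")
  idx <- sort(unlist(molecules, use.names = FALSE))
  if (!identical(as.integer(idx), seq_len(nrow(atoms))))
    stop("every atom must belong to exactly one molecule")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, molecules = lapply(molecules, as.integer)),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d atoms, %d molecules, %d residues\n",
              nrow(x$atoms), length(x$molecules),
              length(unique(x$atoms$resid))))
  invisible(x)
}

#' Number of atoms in a topology
#' @param topology a [make_topology()] object.
#' @export
n_atoms <- function(topology) nrow(topology$atoms)

#' Create a trajectory frame
#'
#' @param time time stamp in ns.
#' @param positions n x 3 matrix of Cartesian coordinates (nm).
#' @param cell a [triclinic_cell()].
#' @export
make_frame <- function(time, positions, cell) {
  positions <- rbind_coords(positions)
  if (ncol(positions) != 3L) stop("'positions' must be an n x 3 matrix")
  if (!inherits(cell, "triclinic_cell")) stop("'cell' must be a triclinic_cell")
  structure(list(time = as.numeric(time), positions = positions, cell = cell),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat(sprintf("<frame> t = %g ns, %d atoms\n", x$time, nrow(x$positions)))
  invisible(x)
}

#' Concatenate two systems into one topology
#'
#' Appends the atoms and molecules of `b` after those of `a`, reindexing
#' molecule atom lists. Useful for composing a bilayer with a nanoparticle.
#'
#' @param a,b [make_topology()] objects.
#' @return list with `topology` and `offset` (the atom-index offset applied
#'   to `b`, i.e. `n_atoms(a)`).
#' @export
combine_topologies <- function(a, b) {
  off <- n_atoms(a)
  atoms <- rbind(a$atoms, b$atoms)
  mols <- c(a$molecules, lapply(b$molecules, function(m) m + off))
  list(topology = make_topology(atoms, mols), offset = off)
}

validate_frames <- function(frames, topology) {
  nt <- n_atoms(topology)
  times <- vapply(frames, function(f) f$time, 0)
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$positions) != nt)
      stop(sprintf("frame %d has %d atoms, topology expects %d",
                   i, nrow(frames[[i]]$positions), nt))
  }
  if (length(times) > 1 && any(diff(times) < 0))
    stop("frame times must be non-decreasing")
  invisible(TRUE)
}
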