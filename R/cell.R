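#' Triclinic simulation cell
#'
#' A periodic unit cell stored as three lattice vectors in nm, row-wise, in
#' the lower-triangular MD convention: the first vector lies along the
#' laboratory x axis and the second in the xy plane. The hexagonal prism
#' used for membrane patches (equal in-plane vectors at 120 degrees) is a
#' special case, see [hexagonal_cell()].
#'
#' @param vectors 3x3 numeric matrix; row i is lattice vector i (nm).
#' @return An object of class `triclinic_cell`.
#' @examples
#' cell <- triclinic_cell(diag(c(10, 10, 10)))
#' cell_volume(cell)
#' @export
triclinic_cell <- function(vectors) {
  vectors <- as.matrix(vectors)
  if (!is.numeric(vectors) || any(dim(vectors) != c(3L, 3L)))
    stop("'vectors' must be a numeric 3x3 matrix (rows = lattice vectors)")
  if (!all(is.finite(vectors))) stop("cell vectors must be finite")
  tol <- 1e-9 * max(abs(vectors), 1)
  if (abs(vectors[1, 2]) > tol || abs(vectors[1, 3]) > tol ||
      abs(vectors[2, 3]) > tol)
    stop("cell must be lower-triangular: v1 along x, v2 in the xy plane")
  vectors[1, 2:3] <- 0
  vectors[2, 3] <- 0
  if (det(vectors) <= 0)
    stop("degenerate cell: volume must be positive")
  dimnames(vectors) <- list(c("v1", "v2", "v3"), c("x", "y", "z"))
  structure(list(vectors = vectors), class = "triclinic_cell")
}

#' Hexagonal prism cell
#'
#' Builds the hexagonal special case: in-plane vectors of equal length `a`
#' at 120 degrees, normal vector of length `c` along z.
#'
#' @param a in-plane lattice constant (nm).
#' @param c height of the prism (nm).
#' @export
hexagonal_cell <- function(a, c) {
  if (a <= 0 || c <= 0) stop("'a' and 'c' must be positive")
  triclinic_cell(rbind(c(a, 0, 0),
                       c(-a / 2, a * sqrt(3) / 2, 0),
                       c(0, 0, c)))
}

#' Rectangular (orthorhombic) cell
#' @param lx,ly,lz edge lengths (nm).
#' @export
rectangular_cell <- function(lx, ly, lz) {
  if (any(c(lx, ly, lz) <= 0)) stop("edge lengths must be positive")
  triclinic_cell(diag(c(lx, ly, lz)))
}

#' @export
print.triclinic_cell <- function(x, ...) {
  kind <- if (is_hexagonal(x)) "hexagonal" else "triclinic"
  cat(sprintf("<%s cell> volume %.4f nm^3, cross-section %.4f nm^2\n",
              kind, cell_volume(x), cell_cross_area(x)))
  print(x$vectors)
  invisible(x)
}

#' Is the cell hexagonal?
#'
#' TRUE when the in-plane vectors have equal length and a 120 degree angle,
#' within 1e-9 relative tolerance.
#' @param cell a [triclinic_cell()].
#' @export
is_hexagonal <- function(cell) {
  v1 <- cell$vectors[1, 1:2]
  v2 <- cell$vectors[2, 1:2]
  l1 <- sqrt(sum(v1^2))
  l2 <- sqrt(sum(v2^2))
  if (abs(l1 - l2) > 1e-9 * l1) return(FALSE)
  cosang <- sum(v1 * v2) / (l1 * l2)
  abs(cosang + 0.5) <= 1e-9
}

#' Cell volume (nm^3)
#' @param cell a [triclinic_cell()].
#' @export
cell_volume <- function(cell) abs(det(cell$vectors))

#' In-plane cross-section area (nm^2)
#'
#' Area of the parallelogram spanned by the two in-plane lattice vectors;
#' this is the quantity per-leaflet Voronoi areas must sum to.
#' @param cell a [triclinic_cell()].
#' @export
cell_cross_area <- function(cell) {
  v1 <- cell$vectors[1, 1:2]
  v2 <- cell$vectors[2, 1:2]
  unname(abs(v1[1] * v2[2] - v1[2] * v2[1]))
}

#' Cartesian to fractional coordinates
#' @param x n x 3 matrix of Cartesian coordinates (nm), or a length-3 vector.
#' @param cell a [triclinic_cell()].
#' @return n x 3 matrix of fractional coordinates.
#' @export
cart_to_frac <- function(x, cell) {
  x <- rbind_coords(x)
  x %*% solve(cell$vectors)
}

#' Fractional to Cartesian coordinates
#' @param f n x 3 matrix of fractional coordinates, or a length-3 vector.
#' @param cell a [triclinic_cell()].
#' @export
frac_to_cart <- function(f, cell) {
  f <- rbind_coords(f)
  f %*% cell$vectors
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  x
}

#' Wrap coordinates into the primary cell
#'
#' Maps every point to its image with fractional coordinates in [0, 1).
#' @inheritParams cart_to_frac
#' @export
wrap_coords <- function(x, cell) {
  f <- cart_to_frac(x, cell)
  frac_to_cart(f - floor(f), cell)
}

#' Minimum-image displacement
#'
#' Returns q - p shifted by the combination of lattice vectors that
#' minimises the Euclidean norm. Cells are assumed to follow the reduced
#' lower-triangular MD convention, for which a fractional nearest-integer
#' wrap followed by a search over the 27 surrounding images is exact.
#'
#' @param p,q length-3 Cartesian coordinates (nm).
#' @param cell a [triclinic_cell()].
#' @return length-3 displacement vector (nm).
#' @examples
#' cell <- rectangular_cell(10, 10, 10)
#' minimum_image_displacement(c(1, 0, 0), c(9, 0, 0), cell)  # (-2, 0, 0)
#' @export
minimum_image_displacement <- function(p, q, cell) {
  if (!all(is.finite(p)) || !all(is.finite(q)))
    stop("coordinates must be finite")
  drop(min_image_disp(matrix(q - p, nrow = 1L), cell))
}

# Vectorised minimum-image: d is an n x 3 matrix of raw displacements.
min_image_disp <- function(d, cell) {
  h <- cell$vectors
  if (det(h) <= 0) stop("degenerate cell: volume must be positive")
  f <- rbind_coords(d) %*% solve(h)
  f <- f - round(f)
  best <- f %*% h
  bn <- rowSums(best^2)
  for (s1 in -1:1) for (s2 in -1:1) for (s3 in -1:1) {
    if (s1 == 0 && s2 == 0 && s3 == 0) next
    cand <- sweep(f, 2L, c(s1, s2, s3), "+") %*% h
    cn <- rowSums(cand^2)
    imp <- cn < bn
    if (any(imp)) {
      best[imp, ] <- cand[imp, , drop = FALSE]
      bn[imp] <- cn[imp]
    }
  }
  best
}

#' Minimum-image distance
#' @inheritParams minimum_image_displacement
#' @export
minimum_image_distance <- function(p, q, cell) {
  sqrt(sum(minimum_image_displacement(p, q, cell)^2))
}

# Pairwise minimum-image squared distances between rows of x (n x 3).
# Returns an n x n matrix. O(27 n^2); intended for a few hundred points.
min_image_dist2_matrix <- function(x, cell) {
  n <- nrow(x)
  h <- cell$vectors
  f <- rbind_coords(x) %*% solve(h)
  best <- NULL
  for (s1 in -1:1) for (s2 in -1:1) for (s3 in -1:1) {
    fh <- sweep(f, 2L, c(s1, s2, s3), "+") %*% h
    d2 <- outer(rowSums(fh^2), rep(1, n)) +
      outer(rep(1, n), rowSums((f %*% h)^2)) - 2 * fh %*% t(f %*% h)
    best <- if (is.null(best)) d2 else pmin(best, d2)
  }
  pmax(best, 0)
}

#' Replicate points with in-plane periodic ghosts
#'
#' Adds, for every point, the copies shifted by the 8 neighbouring in-plane
#' lattice translations that land within `margin` (nm) of the primary cell.
#' Used to make planar tessellations periodic; a margin spanning the whole
#' cell reproduces full 8-image replication.
#'
#' @param points n x 2 matrix of in-plane Cartesian coordinates (nm),
#'   assumed wrapped into the primary cell.
#' @param cell a [triclinic_cell()]; only the in-plane vectors are used.
#' @param margin retention distance in nm (in fractional terms, a ghost is
#'   kept when its fractional coordinates lie within margin/|v_i| of the
#'   unit square).
#' @return list with `points` ((n + n_ghost) x 2 matrix, originals first)
#'   and `parent` (integer vector mapping every row to its original point).
#' @export
replicate_ghosts_2d <- function(points, cell, margin) {
  if (margin < 0) stop("'margin' must be non-negative")
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("'points' must be an n x 2 matrix")
  v1 <- cell$vectors[1, 1:2]
  v2 <- cell$vectors[2, 1:2]
  m1 <- margin / sqrt(sum(v1^2))
  m2 <- margin / sqrt(sum(v2^2))
  h2 <- rbind(v1, v2)
  f <- points %*% solve(h2)
  gx <- list(points)
  gp <- list(seq_len(nrow(points)))
  for (s1 in -1:1) for (s2 in -1:1) {
    if (s1 == 0 && s2 == 0) next
    fg <- sweep(f, 2L, c(s1, s2), "+")
    keep <- fg[, 1] >= -m1 & fg[, 1] <= 1 + m1 &
      fg[, 2] >= -m2 & fg[, 2] <= 1 + m2
    if (any(keep)) {
      gx[[length(gx) + 1L]] <- fg[keep, , drop = FALSE] %*% h2
      gp[[length(gp) + 1L]] <- which(keep)
    }
  }
  list(points = do.call(rbind, gx), parent = unlist(gp, use.names = FALSE))
}
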