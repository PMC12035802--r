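#' Frame-window selection
#'
#' `select_window` returns the indices of frames whose time lies in
#' `[window[1], window[2]]` (inclusive, 1e-9 ns tolerance). `last_window`
#' returns the window covering the final `width` ns of the trajectory,
#' defined as times strictly greater than `t_max - width`; with a 1 ns
#' stride, "last 50 ns" selects exactly the final 50 frames.
#'
#' @param frames list of frames.
#' @param window numeric length-2, ns.
#' @param width window width, ns.
#' @return integer frame indices.
#' @export
select_window <- function(frames, window = NULL) {
  times <- vapply(frames, function(f) f$time, 0)
  if (is.null(window)) return(seq_along(frames))
  if (length(window) != 2 || window[2] < window[1])
    stop("'window' must be c(t_start, t_end) with t_end >= t_start")
  idx <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  if (length(idx) == 0)
    stop(sprintf("empty window [%g, %g] ns: trajectory spans [%g, %g]",
                 window[1], window[2], min(times), max(times)))
  idx
}

#' @rdname select_window
#' @export
last_window <- function(frames, width) {
  times <- vapply(frames, function(f) f$time, 0)
  tmax <- max(times)
  which(times > tmax - width + 1e-9)
}

# normalise a leaflet assignment: either one label vector reused for all
# frames, or the labels matrix from assign_leaflets_trajectory()
labels_for_frame <- function(assignment, fi) {
  if (is.list(assignment) && !is.null(assignment$labels))
    assignment <- assignment$labels
  if (is.matrix(assignment)) assignment[fi, ] else as.character(assignment)
}

#' Per-lipid Voronoi areas under periodic boundaries
#'
#' For each leaflet separately, the in-plane phosphorus positions are
#' wrapped into the cell, replicated with the 8 neighbouring in-plane
#' periodic images, and each original site's Voronoi cell is computed by
#' half-plane clipping. The resulting per-leaflet areas tile the cell, so
#' they sum exactly to its cross-section area.
#'
#' Coincident sites (a degenerate tessellation) are perturbed once by
#' 1e-9 nm and recomputed; persisting duplicates raise an error.
#'
#' @param frame a [make_frame()].
#' @param assignment per-lipid leaflet labels (see [assign_leaflets()]).
#' @param lipid_selection a lipid selection.
#' @return data.frame with columns `lipid`, `leaflet`, `area` (nm^2).
#' @export
voronoi_apl <- function(frame, assignment, lipid_selection) {
  labels <- labels_for_frame(assignment, 1L)
  p_idx <- lipid_selection$phosphorus
  cell <- frame$cell
  out <- data.frame(lipid = seq_along(p_idx), leaflet = labels,
                    area = NA_real_)
  for (leaf in c("upper", "lower")) {
    sel <- which(labels == leaf)
    if (length(sel) == 0) next
    if (length(sel) < 4)
      stop("need >= 4 lipids per leaflet for a Voronoi tessellation")
    xy <- wrap_coords(frame$positions[p_idx[sel], , drop = FALSE],
                      cell)[, 1:2, drop = FALSE]
    out$area[sel] <- leaflet_voronoi_areas(xy, cell)
  }
  out
}

leaflet_voronoi_areas <- function(xy, cell) {
  for (attempt in 1:2) {
    if (anyDuplicated(round(xy / 1e-12)) > 0) {
      if (attempt == 2)
        stop("coincident phosphorus sites: degenerate Voronoi tessellation")
      # deterministic epsilon perturbation, documented in the vignette
      k <- seq_len(nrow(xy))
      xy <- xy + 1e-9 * cbind(cos(k), sin(k))
      next
    }
    break
  }
  margin <- sqrt(sum(cell$vectors[1, 1:2]^2)) +
    sqrt(sum(cell$vectors[2, 1:2]^2))
  gh <- replicate_ghosts_2d(xy, cell, margin)  # full 8-image replication
  bound <- margin
  voronoi_areas_cpp(gh$points, nrow(xy), bound)
}

#' Raster map over the in-plane unit cell
#'
#' Internal constructor for the `raster_map` container: an `nx x ny` value
#' grid over fractional in-plane coordinates (pixel `[i, j]` covers
#' fractional (i-0.5)/nx, (j-0.5)/ny; all pixels have equal area), a
#' per-pixel contributing-frame count, and the cell.
#'
#' @param values,counts ny x nx matrices (rows = second fractional axis).
#' @param cell a [triclinic_cell()].
#' @param quantity label, e.g. `"thickness_nm"`.
#' @return object of class `raster_map`.
#' @keywords internal
new_raster_map <- function(values, counts, cell, quantity) {
  structure(list(values = values, counts = counts, cell = cell,
                 grid = dim(values), quantity = quantity),
            class = "raster_map")
}

#' @export
print.raster_map <- function(x, ...) {
  cat(sprintf("<raster_map %s> %d x %d, mean %.4f, range [%.4f, %.4f]\n",
              x$quantity, x$grid[1], x$grid[2],
              mean(x$values, na.rm = TRUE), min(x$values, na.rm = TRUE),
              max(x$values, na.rm = TRUE)))
  invisible(x)
}

# nearest-site raster of per-site values for one leaflet in one frame
raster_fill <- function(sites_xy, values, cell, grid) {
  h2 <- cell$vectors[1:2, 1:2]
  nn <- raster_nearest_cpp(grid, grid, h2, sites_xy)
  matrix(values[nn$index], nrow(nn$index), ncol(nn$index))
}

#' Area-per-lipid raster maps
#'
#' For every frame in the window and each leaflet, each pixel of the
#' fractional grid takes the Voronoi area of the lipid whose phosphorus is
#' periodically nearest (so a single frame's map is the piecewise-constant
#' Voronoi image); maps are then averaged over the window. The
#' conventional colour-scale centre for display is 0.64 nm^2, the
#' unperturbed POPC average.
#'
#' @param frames list of frames.
#' @param assignment leaflet labels (vector, or trajectory labels matrix).
#' @param lipid_selection a lipid selection.
#' @param window time window in ns (`c(lo, hi)`), NULL for all frames;
#'   the reference convention is a 10 ns window at the end of the
#'   trajectory, see [last_window()].
#' @param grid raster resolution per axis (default 512).
#' @return list of `raster_map`s, elements `upper` and `lower`.
#' @export
apl_map <- function(frames, assignment, lipid_selection, window = NULL,
                    grid = 512) {
  idx <- select_window(frames, window)
  cell <- frames[[idx[1]]]$cell
  p_idx <- lipid_selection$phosphorus
  acc <- list(upper = matrix(0, grid, grid), lower = matrix(0, grid, grid))
  for (fi in idx) {
    labels <- labels_for_frame(assignment, fi)
    ar <- voronoi_apl(frames[[fi]], labels, lipid_selection)
    for (leaf in c("upper", "lower")) {
      sel <- which(labels == leaf)
      xy <- wrap_coords(frames[[fi]]$positions[p_idx[sel], , drop = FALSE],
                        cell)[, 1:2, drop = FALSE]
      acc[[leaf]] <- acc[[leaf]] +
        raster_fill(xy, ar$area[sel], cell, grid)
    }
  }
  nfr <- length(idx)
  counts <- matrix(nfr, grid, grid)
  lapply(acc, function(m)
    new_raster_map(m / nfr, counts, cell, "apl_nm2"))
}

#' Membrane thickness raster map
#'
#' Per frame, each pixel takes the phosphorus z of the periodically nearest
#' lipid of each leaflet; the lower-leaflet grid is subtracted from the
#' upper-leaflet grid and the difference averaged over the window. Values
#' in nm.
#'
#' @inheritParams apl_map
#' @return a `raster_map` of thickness (nm).
#' @export
thickness_map <- function(frames, assignment, lipid_selection,
                          window = NULL, grid = 512) {
  st <- thickness_accumulate(frames, assignment, lipid_selection, window,
                             grid)
  new_raster_map(st$mean, matrix(st$n, grid, grid),
                 frames[[select_window(frames, window)[1]]]$cell,
                 "thickness_nm")
}

# shared accumulation for thickness_map / mean_thickness (Welford over
# frames of per-frame thickness grids)
thickness_accumulate <- function(frames, assignment, lipid_selection,
                                 window, grid) {
  idx <- select_window(frames, window)
  cell <- frames[[idx[1]]]$cell
  p_idx <- lipid_selection$phosphorus
  mean_g <- matrix(0, grid, grid)
  m2_g <- matrix(0, grid, grid)
  n <- 0L
  for (fi in idx) {
    labels <- labels_for_frame(assignment, fi)
    zg <- list()
    for (leaf in c("upper", "lower")) {
      sel <- which(labels == leaf)
      if (length(sel) == 0)
        stop("leaflet '", leaf, "' has no lipids in frame ", fi)
      pos <- frames[[fi]]$positions[p_idx[sel], , drop = FALSE]
      xy <- wrap_coords(pos, cell)[, 1:2, drop = FALSE]
      zg[[leaf]] <- raster_fill(xy, pos[, 3], cell, grid)
    }
    thick <- zg$upper - zg$lower
    n <- n + 1L
    delta <- thick - mean_g
    mean_g <- mean_g + delta / n
    m2_g <- m2_g + delta * (thick - mean_g)
  }
  list(mean = mean_g, m2 = m2_g, n = n)
}

#' Mean membrane thickness over a window
#'
#' Pixel-weighted mean and standard deviation of the thickness raster over
#' all frames in the window (the Table-2-style scalar summary; the
#' reference convention averages over the last 50 ns).
#'
#' @inheritParams apl_map
#' @return named numeric `c(mean, sd)` in nm.
#' @export
mean_thickness <- function(frames, assignment, lipid_selection,
                           window = NULL, grid = 128) {
  st <- thickness_accumulate(frames, assignment, lipid_selection, window,
                             grid)
  npix <- length(st$mean) * st$n
  # combine across pixels: total variance = within-frame + between-pixel
  mu <- mean(st$mean)
  varw <- sum(st$m2) / max(npix - 1, 1)
  varb <- sum((st$mean - mu)^2) * st$n / max(npix - 1, 1)
  c(mean = mu, sd = sqrt(varw + varb))
}

#' Project a group outline onto the membrane plane
#'
#' Boolean pixel mask of the xy projection of a group of atoms (with its
#' periodic images), dilated by `dilation` nm — the construction used to
#' overlay a nanoparticle outline on APL maps.
#'
#' @param frame a [make_frame()].
#' @param group atom indices.
#' @param grid raster resolution.
#' @param dilation dilation radius in nm (>= 0).
#' @return `grid` x `grid` logical matrix.
#' @export
project_outline <- function(frame, group, grid = 512, dilation = 0.3) {
  if (length(group) == 0) stop("'group' must be non-empty")
  if (dilation < 0) stop("'dilation' must be >= 0")
  cell <- frame$cell
  xy <- wrap_coords(frame$positions[group, , drop = FALSE],
                    cell)[, 1:2, drop = FALSE]
  h2 <- cell$vectors[1:2, 1:2]
  nn <- raster_nearest_cpp(grid, grid, h2, xy)
  nn$dist <= dilation
}

#' Write a raster map as a plain-text grid
#'
#' Header lines (prefixed `#`) record the quantity, grid size and cell
#' vectors; the body is the ny x nx value grid, one row per line.
#' @param map a `raster_map` (or logical mask with `cell` attribute
#'   supplied via `cell`).
#' @param path output path.
#' @export
write_raster_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# membranemaps raster v1 quantity=%s", map$quantity),
    sprintf("# grid %d %d", map$grid[1], map$grid[2]),
    sprintf("# cell %s",
            paste(sprintf("%.9g", t(map$cell$vectors)), collapse = " "))),
    con)
  utils::write.table(format(map$values, digits = 9, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Raster map to long-format data.frame
#'
#' One row per pixel with fractional and Cartesian pixel-centre
#' coordinates and the value.
#' @param map a `raster_map`.
#' @export
raster_to_df <- function(map) {
  nx <- map$grid[2]
  ny <- map$grid[1]
  ij <- expand.grid(iy = seq_len(ny), ix = seq_len(nx))
  f1 <- (ij$ix - 0.5) / nx
  f2 <- (ij$iy - 0.5) / ny
  h2 <- map$cell$vectors[1:2, 1:2]
  xy <- cbind(f1, f2) %*% h2
  data.frame(ix = ij$ix, iy = ij$iy, frac1 = f1, frac2 = f2,
             x = xy[, 1], y = xy[, 2], value = as.vector(map$values))
}
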