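#' Acyl-chain deuterium order parameters
#'
#' Computes S_CD = <(3 cos^2 theta - 1) / 2> per acyl carbon, where theta
#' is the angle of each C-H bond to the membrane normal (the laboratory z
#' axis; the membrane is globally flat on average). The average runs over
#' hydrogens, lipids and frames; the magnitude |S_CD| is reported together
#' with the standard deviation of the per-sample values.
#'
#' @param frames list of frames.
#' @param lipid_selection a lipid selection with per-carbon hydrogen
#'   indices (see [make_flat_bilayer()]).
#' @param normal membrane normal (default laboratory z).
#' @return data.frame with columns `chain` ("sn1"/"sn2"), `carbon`,
#'   `s_cd_abs`, `sd`, `n`.
#' @export
order_parameters <- function(frames, lipid_selection,
                             normal = c(0, 0, 1)) {
  normal <- normal / sqrt(sum(normal^2))
  chains <- c("sn1", "sn2")
  nc <- length(lipid_selection$lipids[[1]]$chains$sn1$carbons)
  samples <- vector("list", 2 * nc)
  for (li in seq_along(lipid_selection$lipids)) {
    lip <- lipid_selection$lipids[[li]]
    for (ci in 1:2) {
      ch <- lip$chains[[chains[ci]]]
      for (k in seq_len(nc)) {
        if (length(ch$hydrogens[[k]]) < 1)
          stop(sprintf("lipid %d carbon %s/%d has no bonded hydrogen",
                       li, chains[ci], k))
      }
    }
  }
  for (ci in 1:2) {
    for (k in seq_len(nc)) {
      # gather all (C, H) index pairs for this carbon across lipids
      c_idx <- integer(0)
      h_idx <- integer(0)
      for (lip in lipid_selection$lipids) {
        ch <- lip$chains[[chains[ci]]]
        hs <- ch$hydrogens[[k]]
        c_idx <- c(c_idx, rep(ch$carbons[k], length(hs)))
        h_idx <- c(h_idx, hs)
      }
      vals <- unlist(lapply(frames, function(fr) {
        v <- min_image_disp(fr$positions[h_idx, , drop = FALSE] -
                              fr$positions[c_idx, , drop = FALSE], fr$cell)
        cth <- (v %*% normal) / sqrt(rowSums(v^2))
        (3 * cth^2 - 1) / 2
      }), use.names = FALSE)
      samples[[(ci - 1) * nc + k]] <-
        data.frame(chain = chains[ci], carbon = k,
                   s_cd_abs = abs(mean(vals)),
                   sd = if (length(vals) > 1) sd(vals) else 0,
                   n = length(vals))
    }
  }
  do.call(rbind, samples)
}

#' Mass-density profile along the membrane normal
#'
#' Histogram of group mass along z in bins of `bin_width` nm, converted to
#' g/cm^3 by dividing by the bin volume (bin width times the cell
#' cross-section area) and averaging over frames. When phosphorus indices
#' are supplied, z is referenced to the mean phosphorus midplane of each
#' frame; otherwise absolute z is used.
#'
#' @param frames list of frames.
#' @param topology a [make_topology()].
#' @param groups named list of atom-index vectors.
#' @param bin_width bin width, nm (> 0).
#' @param phosphorus optional atom indices defining the midplane reference.
#' @return data.frame with columns `z` (bin centre, nm), `group`,
#'   `density` (g/cm^3).
#' @export
mass_density_profile <- function(frames, topology, groups, bin_width = 0.1,
                                 phosphorus = NULL) {
  if (bin_width <= 0) stop("'bin_width' must be positive")
  if (length(groups) == 0) stop("'groups' must be non-empty")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("'groups' must be a named list")
  area <- cell_cross_area(frames[[1]]$cell)
  if (area <= 0) stop("zero in-plane cross-section area")
  zrel <- lapply(frames, function(fr) {
    ref <- if (is.null(phosphorus)) 0 else mean(fr$positions[phosphorus, 3])
    fr$positions[, 3] - ref
  })
  zmin <- min(vapply(zrel, min, 0))
  zmax <- max(vapply(zrel, max, 0))
  lo <- floor(zmin / bin_width) * bin_width
  nb <- ceiling((zmax - lo) / bin_width + 1e-9)
  nb <- max(nb, 1L)
  breaks <- lo + bin_width * (0:nb)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  masses <- topology$atoms$mass
  out <- list()
  for (g in names(groups)) {
    gi <- groups[[g]]
    acc <- numeric(nb)
    wt <- masses[gi]
    for (fi in seq_along(frames)) {
      b <- findInterval(zrel[[fi]][gi], breaks, rightmost.closed = TRUE)
      b[b < 1] <- 1L
      b[b > nb] <- nb
      rs <- rowsum(wt, b)
      acc[as.integer(rownames(rs))] <- acc[as.integer(rownames(rs))] + rs
    }
    acc <- acc / length(frames)
    # Da per nm^3 -> g/cm^3: 1 Da = 1.66054e-24 g, 1 nm^3 = 1e-21 cm^3
    dens <- acc * 1.66054e-3 / (area * bin_width)
    out[[g]] <- data.frame(z = centers, group = g, density = dens)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Unwrap molecules across periodic boundaries
#'
#' Makes each molecule whole by chaining minimum-image displacements along
#' its atom order, then places molecules relative to the first one by the
#' minimum-image shift of their centroids (adequate for compact
#' assemblies). Needed before mass-weighted moments: periodic wrapping
#' corrupts the centre of mass and the radius of gyration.
#'
#' @param positions n x 3 coordinate matrix (nm).
#' @param molecules list of atom-index vectors (each in bond order).
#' @param cell a [triclinic_cell()].
#' @return unwrapped n x 3 matrix.
#' @export
make_whole <- function(positions, molecules, cell) {
  out <- positions
  anchors <- matrix(0, length(molecules), 3)
  for (mi in seq_along(molecules)) {
    idx <- molecules[[mi]]
    if (length(idx) > 1) {
      # chaining min-image steps equals cumulating min-image diffs
      steps <- min_image_disp(diff(positions[idx, , drop = FALSE]), cell)
      out[idx[-1], ] <- rep(positions[idx[1], ], each = length(idx) - 1) +
        apply(steps, 2, cumsum)
    }
    anchors[mi, ] <- colMeans(out[idx, , drop = FALSE])
  }
  if (length(molecules) > 1) {
    ref <- anchors[1, ]
    for (mi in seq_along(molecules)[-1]) {
      idx <- molecules[[mi]]
      target <- ref + min_image_disp(
        matrix(anchors[mi, ] - ref, 1), cell)[1, ]
      shift <- target - anchors[mi, ]
      out[idx, ] <- sweep(out[idx, , drop = FALSE], 2L, shift, "+")
    }
  }
  out
}

# molecules of the topology intersecting a group, restricted to the group
group_molecules <- function(topology, group) {
  mols <- lapply(topology$molecules, function(m) intersect(m, group))
  mols[vapply(mols, length, 0L) > 0]
}

group_com <- function(positions, masses, group) {
  w <- masses[group]
  colSums(positions[group, , drop = FALSE] * w) / sum(w)
}

#' Radius of gyration time series
#'
#' Mass-weighted radius of gyration of a group per frame, with the group
#' made whole across periodic boundaries first.
#'
#' @param frames list of frames.
#' @param topology a [make_topology()].
#' @param group atom indices (>= 1 atom with positive mass).
#' @return data.frame with `time` (ns) and `rg` (nm).
#' @export
radius_of_gyration <- function(frames, topology, group) {
  if (length(group) < 1) stop("'group' must contain at least one atom")
  masses <- topology$atoms$mass
  if (sum(masses[group]) <= 0) stop("group has zero total mass")
  mols <- group_molecules(topology, group)
  rg <- vapply(frames, function(fr) {
    pos <- make_whole(fr$positions, mols, fr$cell)
    com <- group_com(pos, masses, group)
    d2 <- rowSums(sweep(pos[group, , drop = FALSE], 2L, com, "-")^2)
    sqrt(sum(masses[group] * d2) / sum(masses[group]))
  }, 0)
  data.frame(time = vapply(frames, function(f) f$time, 0), rg = rg)
}

#' End-to-end distance per chain
#'
#' Minimum-image distance between the designated first and last backbone
#' atoms of each chain, per frame.
#'
#' @param frames list of frames.
#' @param chain_ends integer matrix with one row per chain and columns
#'   (first_atom, last_atom).
#' @return data.frame with `time`, `chain`, `d_ee` (nm).
#' @export
end_to_end <- function(frames, chain_ends) {
  chain_ends <- as.matrix(chain_ends)
  if (ncol(chain_ends) != 2 || any(!is.finite(chain_ends)))
    stop("'chain_ends' must be a 2-column matrix of end-atom indices")
  out <- lapply(seq_len(nrow(chain_ends)), function(ci) {
    d <- vapply(frames, function(fr) {
      sqrt(sum(minimum_image_displacement(
        fr$positions[chain_ends[ci, 1], ],
        fr$positions[chain_ends[ci, 2], ], fr$cell)^2))
    }, 0)
    data.frame(time = vapply(frames, function(f) f$time, 0),
               chain = ci, d_ee = d)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Centre-of-mass trajectory along the membrane normal
#'
#' Group COM z relative to the mean-phosphorus midplane per frame, plus
#' the two leaflets' mean phosphorus z levels (also midplane-relative) for
#' plotting as the customary dashed guide lines.
#'
#' @param frames list of frames.
#' @param topology a [make_topology()].
#' @param group atom indices of the tracked group.
#' @param lipid_selection a lipid selection.
#' @param assignment leaflet labels (vector or trajectory labels matrix).
#' @return data.frame with `time`, `z_com` (nm, midplane-relative),
#'   `z_upper`, `z_lower`.
#' @export
com_trajectory <- function(frames, topology, group, lipid_selection,
                           assignment) {
  if (length(group) == 0) stop("'group' must be non-empty")
  masses <- topology$atoms$mass
  mols <- group_molecules(topology, group)
  p_idx <- lipid_selection$phosphorus
  rows <- lapply(seq_along(frames), function(fi) {
    fr <- frames[[fi]]
    labels <- labels_for_frame(assignment, fi)
    zu <- mean(fr$positions[p_idx[labels == "upper"], 3])
    zl <- mean(fr$positions[p_idx[labels == "lower"], 3])
    mid <- (zu + zl) / 2
    pos <- make_whole(fr$positions, mols, fr$cell)
    com <- group_com(pos, masses, group)
    data.frame(time = fr$time, z_com = com[3] - mid,
               z_upper = zu - mid, z_lower = zl - mid)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
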