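## Synthetic trajectory generators with planted, recoverable ground truth.
## These emulate the geometry of a phospholipid bilayer / polystyrene
## nanoparticle system well enough to exercise every analysis stage; they
## are kinematic (no force field, no dynamics).

# Carbon-carbon step along an acyl chain and C-H bond length, nm.
.bond_cc <- 0.125
.bond_ch <- 0.109

# factor n into m1 x m2 with the most balanced aspect ratio
balanced_factors <- function(n) {
  divs <- which(n %% seq_len(floor(sqrt(n))) == 0)
  m1 <- max(divs)
  m2 <- n %/% m1
  if (max(m1, m2) / min(m1, m2) > 3)
    stop("n_per_leaflet = ", n, " has no balanced lattice factorisation; ",
         "choose a value with divisors near sqrt(n)")
  c(m1, m2)
}

# minimal lipid: phosphorus bead + two acyl chains of carbons, each carbon
# carrying two hydrogens at a controlled angle to the membrane normal.
# Returns local coordinates (lipid origin at the phosphorus) and the
# within-lipid selection indices.
lipid_template <- function(carbons_per_chain, tilt_deg, ch_angle_deg,
                           leaflet_sign) {
  nc <- carbons_per_chain
  tilt <- tilt_deg * pi / 180
  alpha <- ch_angle_deg * pi / 180
  # chains point from the headgroup towards the midplane
  dir <- c(sin(tilt), 0, -leaflet_sign * cos(tilt))
  coords <- matrix(0, nrow = 1 + 2 * nc * 3, ncol = 3)
  name <- character(nrow(coords))
  name[1] <- "P"
  chains <- list()
  row <- 1L
  for (ch in 1:2) {
    lat <- c(0.2 * (ch - 1.5), 0.1, 0)  # small lateral offset between chains
    carbons <- integer(nc)
    hydrogens <- vector("list", nc)
    for (k in seq_len(nc)) {
      cpos <- lat + k * .bond_cc * dir
      row <- row + 1L
      coords[row, ] <- cpos
      name[row] <- sprintf("C%d%d", ch, k)
      carbons[k] <- row
      hs <- integer(2)
      for (hh in 1:2) {
        phi <- if (hh == 1) 0 else pi
        # unit vector at angle alpha to the laboratory normal (+z)
        u <- c(sin(alpha) * cos(phi), sin(alpha) * sin(phi), cos(alpha))
        row <- row + 1L
        coords[row, ] <- cpos + .bond_ch * u
        name[row] <- sprintf("H%d%d%d", ch, k, hh)
        hs[hh] <- row
      }
      hydrogens[[k]] <- hs
    }
    chains[[c("sn1", "sn2")[ch]]] <- list(carbons = carbons,
                                          hydrogens = hydrogens)
  }
  list(coords = coords, name = name, chains = chains)
}

bilayer_cell <- function(n_per_leaflet, apl, thickness, cell_kind, mfac,
                         h = 0) {
  area <- n_per_leaflet * apl
  lz <- thickness + 2 * h + 4
  if (cell_kind == "hexagonal") {
    hexagonal_cell(a = sqrt(2 * area / sqrt(3)), c = lz)
  } else {
    lx <- sqrt(area * mfac[1] / mfac[2])
    rectangular_cell(lx, area / lx, lz)
  }
}

#' Generate a flat two-leaflet bilayer with planted geometry
#'
#' Phosphorus beads sit on a fractional lattice whose per-site Voronoi area
#' is exactly `apl`; the leaflet planes sit at +/- `thickness`/2 around the
#' cell's mid-height. Each lipid carries two acyl chains of carbons with
#' explicit hydrogens at a controlled angle to the membrane normal, so
#' order parameters are planted too. Per frame, every lipid is rigidly
#' displaced by isotropic Gaussian jitter of standard deviation `jitter`.
#'
#' @param n_per_leaflet lipids per leaflet (>= 4); must factor into a
#'   lattice with aspect ratio <= 3. Default 180 per leaflet in a hexagonal
#'   cell, close to the 178 + 178 arrangement of the reference system.
#' @param apl planted area per lipid, nm^2 (default 0.64).
#' @param thickness planted phosphorus-to-phosphorus distance, nm
#'   (default 3.93).
#' @param cell_kind `"hexagonal"` or `"rectangular"`.
#' @param jitter per-frame Gaussian displacement sigma, nm.
#' @param n_frames number of frames; `dt` their spacing in ns.
#' @param dt frame spacing, ns.
#' @param carbons_per_chain acyl carbons per chain.
#' @param tilt_deg chain tilt from the membrane normal, degrees.
#' @param ch_angle_deg planted C-H angle to the normal, degrees
#'   (90 gives |S_CD| = 0.5).
#' @param seed RNG seed; generation is bitwise reproducible.
#' @return list with `topology`, `frames`, `selection` (a lipid selection,
#'   see Details), and `truth` (planted parameters incl. per-lipid leaflet).
#'
#' @details The lipid selection is a list of class `lipid_selection` with
#' `phosphorus` (atom index per lipid) and `lipids` (per lipid: `p`, and
#' `chains$sn1`/`chains$sn2` each holding `carbons` and a per-carbon list
#' `hydrogens`).
#' @export
make_flat_bilayer <- function(n_per_leaflet = 180, apl = 0.64,
                              thickness = 3.93, cell_kind = "hexagonal",
                              jitter = 0.05, n_frames = 1, dt = 1,
                              carbons_per_chain = 8, tilt_deg = 0,
                              ch_angle_deg = 90, seed = 1) {
  make_bump_bilayer(n_per_leaflet = n_per_leaflet, apl = apl,
                    thickness = thickness, h = 0, sigma = 1,
                    cell_kind = cell_kind, jitter = jitter,
                    n_frames = n_frames, dt = dt,
                    carbons_per_chain = carbons_per_chain,
                    tilt_deg = tilt_deg, ch_angle_deg = ch_angle_deg,
                    seed = seed)
}

#' Generate a bilayer deformed by a Gaussian bump
#'
#' As [make_flat_bilayer()], but both leaflets are displaced outward by
#' `h * exp(-r^2 / (2 sigma^2))` around the in-plane cell centre, so the
#' planted thickness at the centre is `thickness + 2 h` (the regime where a
#' lipid-covered inclusion locally doubles the membrane thickness).
#'
#' @inheritParams make_flat_bilayer
#' @param h bump height per leaflet, nm (>= 0; 0 recovers the flat bilayer).
#' @param sigma bump width, nm (> 0).
#' @export
make_bump_bilayer <- function(n_per_leaflet = 180, apl = 0.64,
                              thickness = 3.93, h = 1.965, sigma = 2,
                              cell_kind = "hexagonal", jitter = 0.05,
                              n_frames = 1, dt = 1, carbons_per_chain = 8,
                              tilt_deg = 0, ch_angle_deg = 90, seed = 1) {
  if (n_per_leaflet < 4) stop("n_per_leaflet must be >= 4 (Voronoi undefined)")
  if (apl <= 0 || thickness <= 0) stop("'apl' and 'thickness' must be positive")
  if (h < 0) stop("'h' must be >= 0")
  if (sigma <= 0) stop("'sigma' must be positive")
  cell_kind <- match.arg(cell_kind, c("hexagonal", "rectangular"))
  mfac <- balanced_factors(n_per_leaflet)
  cell <- bilayer_cell(n_per_leaflet, apl, thickness, cell_kind, mfac, h)
  zmid <- cell$vectors[3, 3] / 2
  n_lip <- 2L * n_per_leaflet
  h2 <- cell$vectors[1:2, 1:2]
  center <- drop(c(0.5, 0.5) %*% h2)

  # fractional lattice; lower leaflet offset half a spacing to avoid
  # perfectly stacked leaflets
  ij <- expand.grid(i = seq_len(mfac[1]) - 1L, j = seq_len(mfac[2]) - 1L)
  f_up <- cbind((ij$i + 0.5) / mfac[1], (ij$j + 0.5) / mfac[2])
  f_lo <- cbind((ij$i + 1.0) / mfac[1], (ij$j + 1.0) / mfac[2]) %% 1
  lattice_xy <- rbind(f_up, f_lo) %*% h2
  leaflet <- rep(c("upper", "lower"), each = n_per_leaflet)
  zsign <- ifelse(leaflet == "upper", 1, -1)

  # topology: one template per leaflet orientation
  tmpl_up <- lipid_template(carbons_per_chain, tilt_deg, ch_angle_deg, 1)
  tmpl_lo <- lipid_template(carbons_per_chain, tilt_deg, ch_angle_deg, -1)
  nal <- nrow(tmpl_up$coords)
  atoms <- data.frame(
    name = rep(tmpl_up$name, n_lip),
    element = guess_element(rep(tmpl_up$name, n_lip)),
    mass = NA_real_,
    resid = rep(seq_len(n_lip), each = nal),
    resname = "LIP", stringsAsFactors = FALSE)
  atoms$mass <- unname(atomic_masses[atoms$element])
  molecules <- split(seq_len(nal * n_lip), atoms$resid)
  topology <- make_topology(atoms, unname(molecules))

  lipids <- vector("list", n_lip)
  phosphorus <- integer(n_lip)
  for (l in seq_len(n_lip)) {
    off <- (l - 1L) * nal
    tm <- if (leaflet[l] == "upper") tmpl_up else tmpl_lo
    chains <- lapply(tm$chains, function(ch) list(
      carbons = ch$carbons + off,
      hydrogens = lapply(ch$hydrogens, function(hs) hs + off)))
    phosphorus[l] <- off + 1L
    lipids[[l]] <- list(p = off + 1L, chains = chains)
  }
  selection <- structure(list(phosphorus = phosphorus, lipids = lipids),
                         class = "lipid_selection")

  bump <- function(xy) {
    d <- xy - matrix(center, nrow(xy), 2, byrow = TRUE)
    # in-plane minimum-image distance to the bump centre
    f <- d %*% solve(h2)
    f <- f - round(f)
    d <- f %*% h2
    h * exp(-rowSums(d^2) / (2 * sigma^2))
  }

  local_up <- tmpl_up$coords
  local_lo <- tmpl_lo$coords
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(fi) {
      disp <- matrix(rnorm(3 * n_lip, sd = jitter), ncol = 3)
      origin_xy <- lattice_xy + disp[, 1:2]
      origin_z <- zmid + zsign * (thickness / 2 + bump(origin_xy)) + disp[, 3]
      pos <- matrix(0, nal * n_lip, 3)
      for (l in seq_len(n_lip)) {
        tm <- if (leaflet[l] == "upper") local_up else local_lo
        rows <- ((l - 1L) * nal + 1L):(l * nal)
        pos[rows, ] <- sweep(tm, 2L,
                             c(origin_xy[l, ], origin_z[l]), "+")
      }
      make_frame((fi - 1) * dt, pos, cell)
    })
  })

  truth <- list(apl = apl, thickness = thickness, h = h, sigma = sigma,
                bump_center = center, tilt_deg = tilt_deg,
                ch_angle_deg = ch_angle_deg, jitter = jitter,
                leaflet = leaflet, z_mid = zmid, seed = seed,
                s_cd = abs((3 * cos(ch_angle_deg * pi / 180)^2 - 1) / 2))
  list(topology = topology, frames = frames, selection = selection,
       truth = truth)
}

#' Molecular weight of a hydrogen-capped polystyrene chain
#'
#' Sum of atomic masses of `units` styrene repeat units (C8H8) plus the two
#' capping hydrogens, in kDa. A 40-unit chain weighs about 4.2 kDa.
#'
#' @param units_per_chain number of repeat units (>= 1).
#' @return chain mass in kDa.
#' @examples
#' chain_molecular_weight(40)
#' @export
chain_molecular_weight <- function(units_per_chain) {
  if (units_per_chain < 1) stop("'units_per_chain' must be >= 1")
  repeat_mass <- 8 * atomic_masses[["C"]] + 8 * atomic_masses[["H"]]
  (units_per_chain * repeat_mass + 2 * atomic_masses[["H"]]) / 1000
}

# one styrene molecule's atom block (8 C + 8 H), jittered around a centre
styrene_atoms <- function() {
  data.frame(name = c(paste0("C", 1:8), paste0("H", 1:8)),
             element = rep(c("C", "H"), each = 8),
             mass = unname(atomic_masses[rep(c("C", "H"), each = 8)]),
             stringsAsFactors = FALSE)
}

#' Generate a compact polystyrene blob with optional probe molecules
#'
#' Packs `n_chains` collapsed random-walk chains of `units_per_chain`
#' styrene units into a sphere whose radius follows from bulk polystyrene
#' density (1.05 g/cm^3), and embeds probe (styrene monomer) molecules at
#' radii set by their planted mobility class: `immobile` probes in the
#' core, `released` near the surface, `escaped` at/outside the surface.
#'
#' @param n_chains number of chains (>= 1); default 14.
#' @param units_per_chain repeat units per chain (>= 1); default 40.
#' @param probe_classes character vector of planted classes
#'   (`"immobile"`, `"released"`, `"escaped"`), one per probe; NULL for no
#'   probes.
#' @param n_frames number of static frames to emit; `dt` their spacing (ns).
#' @param dt frame spacing, ns.
#' @param cell optional [triclinic_cell()]; default a cubic box 4 blob
#'   radii wide.
#' @param center blob centre, nm; default the cell centre.
#' @param seed RNG seed.
#' @return list with `topology`, `frames`, `groups` (atom-index vectors:
#'   `ps`, one per probe in `probes`; `chain_ends` matrix), and `truth`.
#' @export
make_ps_blob <- function(n_chains = 14, units_per_chain = 40,
                         probe_classes = NULL, n_frames = 1, dt = 1,
                         cell = NULL, center = NULL, seed = 1) {
  if (n_chains < 1 || units_per_chain < 1)
    stop("'n_chains' and 'units_per_chain' must be >= 1")
  if (!is.null(probe_classes) &&
      !all(probe_classes %in% c("immobile", "released", "escaped")))
    stop("probe classes must be in {immobile, released, escaped}")
  total_mass_da <- 1000 * n_chains * chain_molecular_weight(units_per_chain) +
    length(probe_classes) * (8 * atomic_masses[["C"]] + 8 * atomic_masses[["H"]])
  vol_nm3 <- total_mass_da * 1.66054e-3 / 1.05  # bulk PS density 1.05 g/cm3
  r_blob <- (3 * vol_nm3 / (4 * pi))^(1 / 3)
  if (is.null(cell)) {
    side <- max(4 * r_blob, 2 * r_blob + 4)
    cell <- rectangular_cell(side, side, side)
  }
  if (is.null(center)) center <- drop(c(0.5, 0.5, 0.5) %*% cell$vectors)

  sty <- styrene_atoms()
  res <- with_seed(seed, {
    atoms_list <- list()
    mols <- list()
    coords <- list()
    chain_ends <- matrix(0L, n_chains, 2)
    off <- 0L
    rand_dir <- function() {
      v <- rnorm(3)
      v / sqrt(sum(v^2))
    }
    for (ci in seq_len(n_chains)) {
      # confined random walk for the backbone
      bb <- matrix(0, units_per_chain, 3)
      p <- center + 0.6 * r_blob * runif(1)^(1 / 3) * rand_dir()
      bb[1, ] <- p
      for (k in seq_len(units_per_chain - 1)) {
        repeat {
          cand <- bb[k, ] + .25 * rand_dir()
          if (sum((cand - center)^2) <= r_blob^2) break
        }
        bb[k + 1, ] <- cand
      }
      nunit <- nrow(sty)
      ca <- do.call(rbind, lapply(seq_len(units_per_chain), function(k) {
        jit <- matrix(rnorm(3 * nunit, sd = 0.08), ncol = 3)
        jit[1, ] <- 0  # first carbon is the backbone bead
        sweep(jit, 2L, bb[k, ], "+")
      }))
      caps <- rbind(bb[1, ] + c(0, 0, .05),
                    bb[units_per_chain, ] + c(0, 0, -.05))
      at <- rbind(
        do.call(rbind, replicate(units_per_chain, sty, simplify = FALSE)),
        data.frame(name = c("HC1", "HC2"), element = "H",
                   mass = atomic_masses[["H"]], stringsAsFactors = FALSE))
      at$resid <- ci
      at$resname <- "PS"
      atoms_list[[ci]] <- at
      coords[[ci]] <- rbind(ca, caps)
      n_at <- nrow(at)
      mols[[ci]] <- off + seq_len(n_at)
      chain_ends[ci, ] <- off + c(1L, (units_per_chain - 1L) * nunit + 1L)
      off <- off + n_at
    }
    probe_groups <- list()
    if (length(probe_classes) > 0) {
      for (pi in seq_along(probe_classes)) {
        rr <- switch(probe_classes[pi],
                     immobile = 0.3 * r_blob * runif(1)^(1 / 3),
                     released = r_blob * runif(1, 0.7, 0.95),
                     escaped = r_blob * runif(1, 0.9, 1.1))
        cpos <- center + rr * rand_dir()
        jit <- matrix(rnorm(3 * nrow(sty), sd = 0.08), ncol = 3)
        at <- sty
        at$resid <- n_chains + pi
        at$resname <- "STY"
        atoms_list[[n_chains + pi]] <- at
        coords[[n_chains + pi]] <- sweep(jit, 2L, cpos, "+")
        mols[[n_chains + pi]] <- off + seq_len(nrow(sty))
        probe_groups[[pi]] <- off + seq_len(nrow(sty))
        off <- off + nrow(sty)
      }
    }
    list(atoms = do.call(rbind, atoms_list), mols = mols,
         pos = do.call(rbind, coords), chain_ends = chain_ends,
         probes = probe_groups)
  })
  topology <- make_topology(res$atoms, res$mols)
  ps_atoms <- unlist(res$mols[seq_len(n_chains)], use.names = FALSE)
  frames <- lapply(seq_len(n_frames), function(fi)
    make_frame((fi - 1) * dt, res$pos, cell))
  truth <- list(r_blob = r_blob, center = center, seed = seed,
                probe_classes = probe_classes,
                chain_mass_kda = chain_molecular_weight(units_per_chain))
  list(topology = topology, frames = frames,
       groups = list(ps = ps_atoms, probes = res$probes,
                     chain_ends = res$chain_ends),
       truth = truth)
}

#' Generate planted probe-release distance series
#'
#' Emulates per-molecule time series of the distance between a probe's
#' centre of mass and the nanoparticle's: `immobile` probes stay at a
#' constant distance plus small noise, `released` probes wander within a
#' bounded band (a stationary AR(1) walk), and `escaped` probes follow a
#' drifting random walk with large excursions. The planted per-class
#' dispersions `stds` must be strictly increasing.
#'
#' @param n_molecules number of probes (>= 3). Default 32.
#' @param class_fractions named fractions for immobile / released /
#'   escaped, summing to 1. Default 6/32, 18/32, 8/32.
#' @param stds target distance-dispersion (nm) per class, strictly
#'   increasing.
#' @param n_frames series length; `dt` spacing in ns.
#' @param dt frame spacing, ns.
#' @param seed RNG seed.
#' @return list with `time` (ns), `series` (n_frames x n_molecules matrix,
#'   nm) and `truth` (planted classes per molecule, counts, stds, seed).
#' @export
make_release_series <- function(n_molecules = 32,
                                class_fractions = c(immobile = 6 / 32,
                                                    released = 18 / 32,
                                                    escaped = 8 / 32),
                                stds = c(0.05, 0.5, 2.0),
                                n_frames = 500, dt = 1, seed = 1) {
  if (n_molecules < 3) stop("'n_molecules' must be >= 3 (k = 3 infeasible)")
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("'class_fractions' must sum to 1")
  if (length(stds) != 3 || any(diff(stds) <= 0))
    stop("'stds' must be strictly increasing across the three classes")
  if (n_frames < 2) stop("'n_frames' must be >= 2")
  classes <- c("immobile", "released", "escaped")
  # largest-remainder apportionment of molecules to classes
  raw <- class_fractions * n_molecules
  counts <- floor(raw)
  rem <- n_molecules - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  labels <- rep(classes, counts)
  res <- with_seed(seed, {
    labels <- sample(labels)
    series <- matrix(0, n_frames, n_molecules)
    for (m in seq_len(n_molecules)) {
      series[, m] <- switch(
        labels[m],
        immobile = 0.5 + abs(rnorm(1, sd = 0.2)) +
          rnorm(n_frames, sd = stds[1]),
        released = {
          mu <- runif(1, 2, 3)
          phi <- 0.95
          x <- numeric(n_frames)
          x[1] <- mu + rnorm(1, sd = stds[2])
          innov <- rnorm(n_frames, sd = stds[2] * sqrt(1 - phi^2))
          for (t in 2:n_frames)
            x[t] <- mu + phi * (x[t - 1] - mu) + innov[t]
          x
        },
        escaped = {
          # drift-dominated departure: the linear ramp pins the series
          # dispersion near stds[3]; the walk adds excursions on top
          v <- stds[3] * sqrt(12) / n_frames
          step <- 0.15 * stds[3] / sqrt(n_frames / 3)
          x <- 2.5 + v * seq_len(n_frames) + cumsum(rnorm(n_frames,
                                                          sd = step))
          pmax(x, 0.2)
        })
    }
    list(labels = labels, series = series)
  })
  colnames(res$series) <- sprintf("mol_%02d", seq_len(n_molecules))
  list(time = (seq_len(n_frames) - 1) * dt, series = res$series,
       truth = list(classes = res$labels,
                    counts = setNames(counts, classes),
                    stds = stds, seed = seed))
}

#' Compose a bilayer plus a descending nanoparticle blob
#'
#' Builds a flat bilayer and a polystyrene blob whose centre of mass
#' descends linearly along the membrane normal from `z_start` to `z_end`
#' (nm, relative to the bilayer midplane) over the trajectory — the planted
#' analogue of a nanoparticle sinking into the membrane within ~180 ns.
#'
#' @param n_frames trajectory length; `dt` spacing (ns).
#' @param dt frame spacing, ns.
#' @param z_start,z_end blob COM height relative to the midplane, nm.
#' @param n_per_leaflet,jitter,seed forwarded to [make_flat_bilayer()].
#' @param n_chains,units_per_chain,probe_classes forwarded to
#'   [make_ps_blob()].
#' @return list with `topology`, `frames`, `selection`, `groups`
#'   (`ps`, `probes`, `chain_ends`) and `truth` (incl. the planted
#'   `slope_nm_per_frame`).
#' @export
make_descent_system <- function(n_frames = 180, dt = 1, z_start = 4,
                                z_end = 0, n_per_leaflet = 64,
                                jitter = 0.02, n_chains = 14,
                                units_per_chain = 40, probe_classes = NULL,
                                seed = 1) {
  bil <- make_flat_bilayer(n_per_leaflet = n_per_leaflet, jitter = jitter,
                           n_frames = n_frames, dt = dt, seed = seed)
  cell <- bil$frames[[1]]$cell
  blob <- make_ps_blob(n_chains = n_chains,
                       units_per_chain = units_per_chain,
                       probe_classes = probe_classes, n_frames = 1,
                       cell = cell, seed = seed + 1)
  comb <- combine_topologies(bil$topology, blob$topology)
  off <- comb$offset
  masses <- blob$topology$atoms$mass
  blob_pos <- blob$frames[[1]]$positions
  com0 <- colSums(blob_pos * masses) / sum(masses)
  z_targets <- seq(z_start, z_end, length.out = n_frames) + bil$truth$z_mid
  frames <- lapply(seq_len(n_frames), function(fi) {
    shift <- c(0, 0, z_targets[fi] - com0[3])
    make_frame(bil$frames[[fi]]$time,
               rbind(bil$frames[[fi]]$positions,
                     sweep(blob_pos, 2L, shift, "+")),
               cell)
  })
  groups <- list(ps = blob$groups$ps + off,
                 probes = lapply(blob$groups$probes, function(g) g + off),
                 chain_ends = blob$groups$chain_ends + off)
  truth <- c(bil$truth,
             list(z_start = z_start, z_end = z_end,
                  slope_nm_per_frame = (z_end - z_start) /
                    max(n_frames - 1, 1),
                  blob = blob$truth))
  list(topology = comb$topology, frames = frames, selection = bil$selection,
       groups = groups, truth = truth)
}

#' Write generator ground truth as a JSON sidecar
#' @param truth the `truth` element returned by a generator.
#' @param path output path.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
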