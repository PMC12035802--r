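test_that("order parameters obey the closed forms", {
  # planted C-H angle 90 degrees: |S_CD| = 1/2 at every carbon
  b <- make_flat_bilayer(n_per_leaflet = 16, ch_angle_deg = 90,
                         jitter = 0.02, n_frames = 2, seed = 4)
  op <- order_parameters(b$frames, b$selection)
  expect_equal(op$s_cd_abs, rep(0.5, nrow(op)), tolerance = 1e-9)
  expect_equal(op$sd, rep(0, nrow(op)), tolerance = 1e-9)
  expect_equal(nrow(op), 2 * 8)
  # magic angle: S_CD vanishes
  magic <- acos(1 / sqrt(3)) * 180 / pi
  bm <- make_flat_bilayer(n_per_leaflet = 16, ch_angle_deg = magic,
                          jitter = 0, n_frames = 1, seed = 4)
  opm <- order_parameters(bm$frames, bm$selection)
  expect_lt(max(opm$s_cd_abs), 1e-6)
})

test_that("order parameters equal a direct average over planted angles", {
  b <- make_flat_bilayer(n_per_leaflet = 9, ch_angle_deg = 35, jitter = 0.1,
                         n_frames = 2, seed = 6)
  op <- order_parameters(b$frames, b$selection)
  # independent recomputation straight from coordinates
  for (k in c(1, 5)) {
    vals <- c()
    for (fr in b$frames) for (lip in b$selection$lipids) {
      ch <- lip$chains$sn1
      cpos <- fr$positions[ch$carbons[k], ]
      for (hi in ch$hydrogens[[k]]) {
        v <- fr$positions[hi, ] - cpos
        cth <- v[3] / sqrt(sum(v^2))
        vals <- c(vals, (3 * cth^2 - 1) / 2)
      }
    }
    row <- op[op$chain == "sn1" & op$carbon == k, ]
    expect_equal(row$s_cd_abs, abs(mean(vals)), tolerance = 1e-12)
    expect_equal(row$sd, sd(vals), tolerance = 1e-12)
  }
  expect_true(all(op$s_cd_abs >= 0 & op$s_cd_abs <= 1))
})

test_that("mass density profiles conserve mass and normalise correctly", {
  # uniform slab: 200 atoms of known mass evenly spaced across 2 nm
  cell <- rectangular_cell(4, 5, 10)
  n <- 200
  atoms <- data.frame(name = "C", element = "C", mass = 12.011,
                      resid = seq_len(n), resname = "SLB")
  topo <- make_topology(atoms, as.list(seq_len(n)))
  z <- 4 + 2 * (seq_len(n) - 0.5) / n
  fr <- make_frame(0, cbind(runif(n, 0, 4), runif(n, 0, 5), z), cell)
  prof <- mass_density_profile(list(fr), topo, list(slab = seq_len(n)),
                               bin_width = 0.25)
  inside <- prof$density[prof$z > 4.1 & prof$z < 5.9]
  expected <- n * 12.011 * 1.66054e-3 / (20 * 2)  # M/(A w) in g/cm^3
  expect_equal(inside, rep(expected, length(inside)), tolerance = 1e-9)
  # conservation: integral x area = total group mass
  total <- sum(prof$density) * 0.25 * 20 / 1.66054e-3
  expect_equal(total, n * 12.011, tolerance = 1e-9)
  # Gaussian-placed group matches the analytic profile within binning error
  zg <- 5 + qnorm((seq_len(n) - 0.5) / n) * 0.5
  frg <- make_frame(0, cbind(rep(1, n), rep(1, n), zg), cell)
  pg <- mass_density_profile(list(frg), topo, list(g = seq_len(n)),
                             bin_width = 0.2)
  ana <- n * 12.011 * 1.66054e-3 / 20 *
    (pnorm(pg$z + 0.1, 5, 0.5) - pnorm(pg$z - 0.1, 5, 0.5)) / 0.2
  expect_lt(max(abs(pg$density - ana)), 0.05 * max(ana))
  expect_error(mass_density_profile(list(fr), topo, list()), "non-empty")
  expect_error(mass_density_profile(list(fr), topo,
                                    list(g = 1:2), bin_width = 0),
               "positive")
})

test_that("radius of gyration matches closed forms and the direct formula", {
  cell <- rectangular_cell(10, 10, 10)
  atoms <- data.frame(name = "C", element = "C", mass = 12,
                      resid = c(1, 1), resname = "AB")
  topo <- make_topology(atoms, list(1:2))
  fr <- make_frame(0, rbind(c(1, 1, 1), c(1, 1, 2.4)), cell)
  expect_equal(radius_of_gyration(list(fr), topo, 1:2)$rg, 0.7)
  expect_equal(radius_of_gyration(list(fr), topo, 1L)$rg, 0)
  # random 100-atom configuration vs direct formula
  set.seed(3)
  n <- 100
  atoms <- data.frame(name = "C", element = "C",
                      mass = runif(n, 1, 30), resid = rep(1, n),
                      resname = "BLB")
  topo <- make_topology(atoms, list(seq_len(n)))
  pos <- matrix(runif(3 * n, 4, 6), ncol = 3)  # compact: no wrapping
  fr <- make_frame(0, pos, cell)
  com <- colSums(pos * atoms$mass) / sum(atoms$mass)
  ref <- sqrt(sum(atoms$mass * rowSums(sweep(pos, 2, com)^2)) /
                sum(atoms$mass))
  expect_equal(radius_of_gyration(list(fr), topo, seq_len(n))$rg, ref,
               tolerance = 1e-12)
  # invariance under lattice translation of the whole group
  fr2 <- make_frame(0, sweep(pos, 2, cell$vectors[1, ], "+"), cell)
  expect_equal(radius_of_gyration(list(fr2), topo, seq_len(n))$rg, ref,
               tolerance = 1e-12)
})

test_that("make_whole reassembles molecules split by the boundary", {
  cell <- rectangular_cell(6, 6, 6)
  # a 4-bead chain crossing the x boundary
  raw <- rbind(c(5.8, 1, 1), c(0.1, 1, 1), c(0.4, 1, 1), c(0.7, 1, 1))
  whole <- make_whole(raw, list(1:4), cell)
  expect_equal(whole[, 1], c(5.8, 6.1, 6.4, 6.7), tolerance = 1e-12)
})

test_that("end-to-end distances follow the minimum-image oracle", {
  cell <- rectangular_cell(10, 10, 10)
  pos <- rbind(c(1, 1, 1), c(1, 1, 1.15), c(1, 1, 1.30),
               c(9.9, 5, 5), c(0.4, 5, 5))
  fr <- make_frame(0, pos, cell)
  ends <- rbind(c(1L, 3L), c(4L, 5L), c(2L, 2L))
  d <- end_to_end(list(fr), ends)
  expect_equal(d$d_ee[d$chain == 1], 0.30, tolerance = 1e-12)
  expect_equal(d$d_ee[d$chain == 2], 0.5, tolerance = 1e-12)  # wraps
  expect_equal(d$d_ee[d$chain == 3], 0)
  set.seed(9)
  for (i in 1:20) {
    cellr <- random_reduced_cell()
    p <- random_point_in_cell(cellr)
    q <- random_point_in_cell(cellr)
    frr <- make_frame(0, rbind(p, q), cellr)
    got <- end_to_end(list(frr), cbind(1L, 2L))$d_ee
    expect_equal(got, sqrt(sum(brute_min_image(p, q, cellr)^2)),
                 tolerance = 1e-12)
  }
})

test_that("COM trajectory is midplane-referenced and equivariant", {
  ds <- make_descent_system(n_frames = 10, z_start = 3, z_end = 3,
                            n_per_leaflet = 16, jitter = 0, seed = 4)
  asg <- assign_leaflets(ds$frames[[1]], ds$selection)
  com <- com_trajectory(ds$frames, ds$topology, ds$groups$ps,
                        ds$selection, asg)
  expect_equal(com$z_com, rep(3, 10), tolerance = 1e-9)
  expect_equal(com$z_upper, rep(3.93 / 2, 10), tolerance = 1e-9)
  expect_equal(com$z_lower, rep(-3.93 / 2, 10), tolerance = 1e-9)
  # rigid +1 nm shift of the tracked group shifts the series by +1 nm
  fr <- ds$frames[[1]]
  pos <- fr$positions
  pos[ds$groups$ps, 3] <- pos[ds$groups$ps, 3] + 1
  com2 <- com_trajectory(list(make_frame(0, pos, fr$cell)), ds$topology,
                         ds$groups$ps, ds$selection, asg)
  expect_equal(com2$z_com, com$z_com[1] + 1, tolerance = 1e-9)
})
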