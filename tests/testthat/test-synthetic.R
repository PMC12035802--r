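test_that("generators are bitwise reproducible and do not touch the RNG", {
  set.seed(99)
  before <- .Random.seed
  a <- make_flat_bilayer(n_per_leaflet = 16, n_frames = 2, seed = 7)
  expect_identical(.Random.seed, before)
  b <- make_flat_bilayer(n_per_leaflet = 16, n_frames = 2, seed = 7)
  expect_identical(a$frames, b$frames)
  r1 <- make_release_series(n_molecules = 8, n_frames = 50, seed = 3)
  r2 <- make_release_series(n_molecules = 8, n_frames = 50, seed = 3)
  expect_identical(r1$series, r2$series)
  p1 <- make_ps_blob(n_chains = 2, units_per_chain = 5, seed = 2)
  p2 <- make_ps_blob(n_chains = 2, units_per_chain = 5, seed = 2)
  expect_identical(p1$frames[[1]]$positions, p2$frames[[1]]$positions)
})

test_that("flat bilayer plants its geometry exactly at zero jitter", {
  b <- make_flat_bilayer(n_per_leaflet = 64, apl = 0.64, thickness = 3.93,
                         jitter = 0, n_frames = 1, seed = 1)
  p <- b$frames[[1]]$positions[b$selection$phosphorus, ]
  up <- b$truth$leaflet == "upper"
  # every upper-lower pair separated by exactly the planted thickness in z
  expect_equal(unique(round(p[up, 3] - mean(p[!up, 3]), 9)), 3.93)
  expect_equal(cell_cross_area(b$frames[[1]]$cell), 64 * 0.64,
               tolerance = 1e-12)
  # lattice symmetry: every Voronoi area is exactly the planted APL
  ar <- voronoi_apl(b$frames[[1]], b$truth$leaflet, b$selection)
  expect_equal(ar$area, rep(0.64, 128), tolerance = 1e-9)
  expect_error(make_flat_bilayer(n_per_leaflet = 3), ">= 4")
})

test_that("bump bilayer reduces to flat at h = 0 and doubles at center", {
  f0 <- make_flat_bilayer(n_per_leaflet = 16, jitter = 0.02, seed = 9)
  b0 <- make_bump_bilayer(n_per_leaflet = 16, h = 0, jitter = 0.02,
                          seed = 9)
  expect_identical(f0$frames, b0$frames)
  bb <- make_bump_bilayer(n_per_leaflet = 64, h = 1.965, sigma = 2,
                          jitter = 0, n_frames = 1, seed = 1)
  p <- bb$frames[[1]]$positions[bb$selection$phosphorus, ]
  up <- bb$truth$leaflet == "upper"
  # at the bump centre the planted thickness is base + 2h
  d <- p[, 1:2] - matrix(bb$truth$bump_center, nrow(p), 2, byrow = TRUE)
  r <- sqrt(rowSums(d^2))
  iu <- which(up)[which.min(r[up])]
  il <- which(!up)[which.min(r[!up])]
  expect_gt(p[iu, 3] - p[il, 3], 3.93 + 2 * 1.965 * 0.9)
  expect_error(make_bump_bilayer(sigma = 0), "sigma")
  expect_error(make_bump_bilayer(h = -1), "h")
})

test_that("chain molecular weight matches a topology mass sum", {
  expect_equal(round(chain_molecular_weight(40), 1), 4.2)
  expect_equal(chain_molecular_weight(1),
               (8 * 12.011 + 10 * 1.008) / 1000, tolerance = 1e-12)
  expect_error(chain_molecular_weight(0), ">= 1")
  # oracle: the generator's 1-chain topology must sum to the same mass
  blob <- make_ps_blob(n_chains = 1, units_per_chain = 7, seed = 3)
  expect_equal(sum(blob$topology$atoms$mass) / 1000,
               chain_molecular_weight(7), tolerance = 1e-12)
})

test_that("ps blob has the advertised composition and stable size", {
  blob <- make_ps_blob(n_chains = 14, units_per_chain = 40, seed = 1)
  expect_length(blob$topology$molecules, 14)
  expect_true(all(vapply(blob$topology$molecules, length, 0L) ==
                    40 * 16 + 2))
  rgs <- vapply(1:5, function(s) {
    bl <- make_ps_blob(n_chains = 14, units_per_chain = 40, seed = s)
    radius_of_gyration(bl$frames, bl$topology, bl$groups$ps)$rg
  }, 0)
  expect_lt((max(rgs) - min(rgs)) / mean(rgs), 0.15)
})

test_that("release series plant ordered dispersions", {
  rs <- make_release_series(seed = 2)
  expect_equal(dim(rs$series), c(500L, 32L))
  expect_equal(unname(rs$truth$counts),
               c(6L, 18L, 8L))
  f <- release_feature(rs$series)
  m <- tapply(f, rs$truth$classes, mean)
  expect_true(m[["immobile"]] < m[["released"]],
              label = "immobile < released dispersion")
  expect_true(m[["released"]] < m[["escaped"]],
              label = "released < escaped dispersion")
  # zero-noise immobile class has exactly zero dispersion
  rz <- make_release_series(n_molecules = 8, stds = c(0, 0.5, 2),
                            n_frames = 40, seed = 1)
  zi <- rz$truth$classes == "immobile"
  expect_equal(unname(apply(rz$series[, zi, drop = FALSE], 2, sd)),
               rep(0, sum(zi)))
  expect_error(make_release_series(n_molecules = 2), ">= 3")
  expect_error(make_release_series(stds = c(1, 1, 2)), "increasing")
  expect_error(make_release_series(class_fractions = c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("descent system plants a linear COM drift", {
  ds <- make_descent_system(n_frames = 30, z_start = 4, z_end = 1,
                            n_per_leaflet = 16, jitter = 0, seed = 2)
  asg <- assign_leaflets(ds$frames[[1]], ds$selection)
  com <- com_trajectory(ds$frames, ds$topology, ds$groups$ps,
                        ds$selection, asg)
  expect_equal(com$z_com[1], 4, tolerance = 1e-9)
  expect_equal(com$z_com[30], 1, tolerance = 1e-9)
  expect_equal(max(abs(diff(com$z_com) - (1 - 4) / 29)), 0,
               tolerance = 1e-9)
})
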