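test_that("window selection follows the strict last-width convention", {
  frames <- lapply(0:19, function(t) make_frame(t, matrix(0, 1, 3),
                                                rectangular_cell(5, 5, 5)))
  expect_equal(last_window(frames, 5), 16:20)
  expect_equal(select_window(frames, c(3, 7)), 4:8)
  expect_equal(select_window(frames, NULL), 1:20)
  expect_error(select_window(frames, c(50, 60)), "empty window")
  expect_error(select_window(frames, c(7, 3)), "t_end")
})

test_that("Voronoi areas conserve the cell cross-section", {
  set.seed(21)
  for (cell in list(hexagonal_cell(9, 8), rectangular_cell(7, 11, 8))) {
    for (rep in 1:3) {
      sys <- p_only_system(40, cell, seed = rep * 13)
      ar <- voronoi_apl(sys$frame, sys$labels, sys$selection)
      for (leaf in c("upper", "lower"))
        expect_equal(sum(ar$area[ar$leaflet == leaf]),
                     cell_cross_area(cell), tolerance = 1e-9)
      expect_true(all(ar$area > 0))
    }
  }
})

test_that("Voronoi areas match the pixel-count oracle", {
  cell <- hexagonal_cell(9, 8)
  sys <- p_only_system(40, cell, seed = 31)
  ar <- voronoi_apl(sys$frame, sys$labels, sys$selection)
  up <- sys$labels == "upper"
  xy <- wrap_coords(sys$frame$positions[sys$selection$phosphorus[up], ],
                    cell)[, 1:2]
  oracle <- membranemaps:::pixel_count_areas_cpp(1024L,
                                                 cell$vectors[1:2, 1:2], xy)
  expect_lt(max(abs(ar$area[up] - oracle) / ar$area[up]), 0.01)
})

test_that("coincident sites are perturbed once, then rejected", {
  cell <- rectangular_cell(8, 8, 8)
  sys <- p_only_system(10, cell, seed = 41)
  fr <- sys$frame
  fr$positions[2, ] <- fr$positions[1, ]  # duplicate in the upper leaflet
  ar <- voronoi_apl(fr, sys$labels, sys$selection)
  expect_equal(sum(ar$area[sys$labels == "upper"]), cell_cross_area(cell),
               tolerance = 1e-6)
})

test_that("APL maps average Voronoi images and stay conservative", {
  b <- make_flat_bilayer(n_per_leaflet = 16, jitter = 0, n_frames = 2,
                         seed = 2)
  asg <- assign_leaflets_trajectory(b$frames, b$selection)
  maps <- apl_map(b$frames, asg, b$selection, grid = 64)
  expect_equal(as.vector(maps$upper$values), rep(0.64, 64 * 64),
               tolerance = 1e-9)
  expect_equal(as.vector(maps$lower$values), rep(0.64, 64 * 64),
               tolerance = 1e-9)
  # vacancy: removing one lipid raises neighbours, keeps the sum
  sysc <- p_only_system(20, hexagonal_cell(6, 8), seed = 7)
  ar_full <- voronoi_apl(sysc$frame, sysc$labels, sysc$selection)
  keep <- setdiff(which(sysc$labels == "upper"), 3L)
  sel2 <- structure(list(phosphorus = sysc$selection$phosphorus[keep]),
                    class = "lipid_selection")
  ar_less <- voronoi_apl(
    make_frame(0, sysc$frame$positions, sysc$frame$cell),
    sysc$labels[keep], sel2)
  expect_equal(sum(ar_less$area), cell_cross_area(sysc$frame$cell),
               tolerance = 1e-9)
  expect_gt(mean(ar_less$area), mean(ar_full$area[sysc$labels == "upper"]))
})

test_that("map pixel mean approximates the area-weighted per-lipid mean", {
  cell <- hexagonal_cell(9, 8)
  sys <- p_only_system(30, cell, seed = 51)
  b_asg <- sys$labels
  ar <- voronoi_apl(sys$frame, b_asg, sys$selection)
  maps <- apl_map(list(sys$frame), b_asg, sys$selection, grid = 256)
  up <- b_asg == "upper"
  aw_mean <- sum(ar$area[up]^2) / sum(ar$area[up])
  expect_equal(mean(maps$upper$values), aw_mean, tolerance = 0.01)
})

test_that("thickness maps are antisymmetric and recover planted values", {
  b <- make_flat_bilayer(n_per_leaflet = 16, jitter = 0, n_frames = 1,
                         seed = 2)
  asg <- as.character(assign_leaflets(b$frames[[1]], b$selection))
  tm <- thickness_map(b$frames, asg, b$selection, grid = 32)
  expect_equal(as.vector(tm$values), rep(3.93, 32 * 32), tolerance = 1e-9)
  swapped <- ifelse(asg == "upper", "lower", "upper")
  tm2 <- thickness_map(b$frames, swapped, b$selection, grid = 32)
  expect_equal(tm2$values, -tm$values, tolerance = 1e-12)
  mt <- mean_thickness(b$frames, asg, b$selection, grid = 32)
  expect_equal(unname(mt), c(3.93, 0), tolerance = 1e-9)
  # bump: map maximum near base + 2h, mean strictly above base
  bb <- make_bump_bilayer(n_per_leaflet = 64, h = 1.965, sigma = 2,
                          jitter = 0.02, n_frames = 4, seed = 3)
  asgb <- assign_leaflets_trajectory(bb$frames, bb$selection)
  tmb <- thickness_map(bb$frames, asgb, bb$selection, grid = 128)
  expect_equal(max(tmb$values), 3.93 + 2 * 1.965, tolerance = 0.05)
  expect_gt(mean_thickness(bb$frames, asgb, bb$selection,
                           grid = 64)[["mean"]], 3.93)
})

test_that("maps are invariant under lattice translation of all coordinates", {
  b <- make_flat_bilayer(n_per_leaflet = 16, jitter = 0.04, n_frames = 1,
                         seed = 13)
  fr <- b$frames[[1]]
  asg <- as.character(assign_leaflets(fr, b$selection))
  tm <- thickness_map(list(fr), asg, b$selection, grid = 32)
  shifted <- make_frame(fr$time,
                        sweep(fr$positions, 2L, fr$cell$vectors[1, ], "+"),
                        fr$cell)
  tm2 <- thickness_map(list(shifted), asg, b$selection, grid = 32)
  expect_equal(tm2$values, tm$values, tolerance = 1e-9)
  m1 <- apl_map(list(fr), asg, b$selection, grid = 32)
  m2 <- apl_map(list(shifted), asg, b$selection, grid = 32)
  expect_equal(m2$upper$values, m1$upper$values, tolerance = 1e-9)
})

test_that("outline projection wraps and dilates", {
  cell <- hexagonal_cell(8, 8)
  center <- frac_to_cart(c(0.5, 0.5, 0.5), cell)
  fr <- make_frame(0, center, cell)
  m <- project_outline(fr, 1L, grid = 64, dilation = 1)
  expect_true(m[32, 32])
  expect_false(m[1, 1])
  frc <- make_frame(0, matrix(c(0, 0, 0), 1), cell)
  mc <- project_outline(frc, 1L, grid = 64, dilation = 1)
  # periodic wrap: all four raster corners covered
  expect_true(mc[1, 1] && mc[1, 64] && mc[64, 1] && mc[64, 64])
  # monotone growth with dilation radius
  areas <- vapply(c(0.5, 1, 2), function(r)
    sum(project_outline(fr, 1L, grid = 64, dilation = r)), 0L)
  expect_true(all(diff(areas) > 0))
  expect_error(project_outline(fr, integer(0)), "non-empty")
})

test_that("raster maps export and convert", {
  b <- make_flat_bilayer(n_per_leaflet = 16, jitter = 0, seed = 2)
  asg <- as.character(assign_leaflets(b$frames[[1]], b$selection))
  tm <- thickness_map(b$frames, asg, b$selection, grid = 16)
  tf <- tempfile(fileext = ".dat")
  write_raster_map(tm, tf)
  lines <- readLines(tf)
  expect_match(lines[1], "thickness_nm")
  expect_equal(length(lines), 3 + 16)
  df <- raster_to_df(tm)
  expect_equal(nrow(df), 256)
  expect_equal(unique(round(df$value, 9)), 3.93)
})
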