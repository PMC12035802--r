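test_that("cell constructors enforce the lower-triangular convention", {
  expect_error(triclinic_cell(matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 1), 3,
                                     byrow = TRUE)), "lower-triangular")
  expect_error(triclinic_cell(diag(c(1, 1, -1))), "degenerate")
  hex <- hexagonal_cell(8, 10)
  expect_true(is_hexagonal(hex))
  expect_false(is_hexagonal(rectangular_cell(8, 8, 10)))
  expect_equal(cell_volume(hex), 8 * 8 * sin(2 * pi / 3) * 10)
  expect_equal(cell_cross_area(hex), 8 * 8 * sin(2 * pi / 3))
})

test_that("fractional wrap then unwrap is the identity", {
  set.seed(11)
  for (rep in 1:5) {
    cell <- random_reduced_cell()
    x <- matrix(runif(60, -30, 30), ncol = 3)
    expect_equal(frac_to_cart(cart_to_frac(x, cell), cell), x,
                 tolerance = 1e-12, ignore_attr = TRUE)
    w <- wrap_coords(x, cell)
    f <- cart_to_frac(w, cell)
    expect_true(all(f >= -1e-12 & f < 1 + 1e-12))
    # wrapping moved each point by an integer lattice combination
    shift <- cart_to_frac(x - w, cell)
    expect_equal(shift, round(shift), tolerance = 1e-9)
  }
})

test_that("minimum image matches exhaustive enumeration on random cells", {
  set.seed(12)
  for (rep in 1:8) {
    cell <- random_reduced_cell()
    for (i in 1:25) {
      p <- random_point_in_cell(cell)
      q <- random_point_in_cell(cell)
      got <- minimum_image_displacement(p, q, cell)
      ref <- brute_min_image(p, q, cell)
      expect_equal(sqrt(sum(got^2)), sqrt(sum(ref^2)), tolerance = 1e-12)
    }
  }
  cube <- rectangular_cell(10, 10, 10)
  expect_equal(minimum_image_displacement(c(1, 0, 0), c(9, 0, 0), cube),
               c(x = -2, y = 0, z = 0))
  expect_equal(minimum_image_displacement(c(2, 3, 4), c(2, 3, 4), cube),
               c(x = 0, y = 0, z = 0))
  expect_error(minimum_image_displacement(c(0, 0, NA), c(0, 0, 0), cube),
               "finite")
})

test_that("ghost replication keeps the right images", {
  cell <- hexagonal_cell(8, 10)
  center <- frac_to_cart(c(0.5, 0.5, 0), cell)[, 1:2, drop = FALSE]
  g <- replicate_ghosts_2d(center, cell, margin = 0.1 * 8)
  expect_equal(nrow(g$points), 1L)
  corner <- matrix(c(0, 0), 1)
  g <- replicate_ghosts_2d(corner, cell, margin = 8)
  expect_equal(nrow(g$points), 9L)
  expect_true(all(g$parent == 1L))
  expect_error(replicate_ghosts_2d(corner, cell, margin = -1),
               "non-negative")
})

test_that("GRO round trip preserves coordinates to format precision", {
  b <- make_flat_bilayer(n_per_leaflet = 16, n_frames = 1, jitter = 0.03,
                         seed = 4)
  tf <- tempfile(fileext = ".gro")
  write_gro(b$topology, b$frames[[1]], tf)
  rt <- read_structure(tf)
  expect_equal(n_atoms(rt$topology), n_atoms(b$topology))
  expect_equal(rt$topology$atoms$name, b$topology$atoms$name)
  expect_equal(rt$frame$positions, b$frames[[1]]$positions,
               tolerance = 5e-4, ignore_attr = TRUE)
  expect_equal(rt$frame$cell$vectors, b$frames[[1]]$cell$vectors,
               tolerance = 1e-4)
})

test_that("JSON trajectory dialect round-trips exactly enough", {
  b <- make_flat_bilayer(n_per_leaflet = 16, n_frames = 3, seed = 5)
  tf <- tempfile(fileext = ".json")
  write_trajectory_json(b$topology, b$frames, tf)
  frames <- read_trajectory(tf, b$topology)
  expect_length(frames, 3)
  expect_equal(vapply(frames, function(f) f$time, 0), c(0, 1, 2))
  for (i in 1:3)
    expect_equal(frames[[i]]$positions, b$frames[[i]]$positions,
                 tolerance = 1e-10, ignore_attr = TRUE)
  # atom-count mismatch is reported with expected vs found
  small <- make_flat_bilayer(n_per_leaflet = 8, n_frames = 1, seed = 5)
  expect_error(read_trajectory(tf, small$topology), "expects")
})

test_that("structure readers reject broken files", {
  tf <- tempfile(fileext = ".gro")
  writeLines(c("title", "2", "bad line"), tf)
  expect_error(read_structure(tf), "shorter|parse")
  tp <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  P   LIP     1      10.000  10.000  10.000",
               "END"), tp)
  expect_error(read_structure(tp), "CRYST1")
  expect_error(read_structure(tempfile(fileext = ".gro")), "not found")
})

test_that("PDB structures read with CRYST1 box conversion", {
  tp <- tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
            80, 80, 100, 90, 90, 120),
    "ATOM      1  P   LIP A   1      10.000  20.000  30.000  1.00  0.00           P",
    "ATOM      2  C11 LIP A   1      11.000  21.000  31.000  1.00  0.00           C",
    "END"), tp)
  st <- read_structure(tp)
  expect_equal(n_atoms(st$topology), 2L)
  expect_true(is_hexagonal(st$frame$cell))
  expect_equal(st$frame$positions[1, ], c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(st$topology$atoms$mass[1], atomic_masses[["P"]])
})

test_that("topology validation catches bad input", {
  atoms <- data.frame(name = "X", element = "C", mass = 12, resid = 1,
                      resname = "A")
  expect_error(make_topology(atoms, list()), "exactly one molecule")
  atoms$mass <- -1
  expect_error(make_topology(atoms, list(1L)), "positive")
})
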