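# Independent oracles used across the suite. These deliberately avoid the
# package's production code paths.

# brute-force minimum image: enumerate all (2r+1)^3 lattice image shifts
brute_min_image <- function(p, q, cell, range = 2) {
  h <- cell$vectors
  d0 <- q - p
  best <- d0
  bn <- sum(d0^2)
  for (s1 in -range:range) for (s2 in -range:range) for (s3 in -range:range) {
    cand <- d0 + s1 * h[1, ] + s2 * h[2, ] + s3 * h[3, ]
    cn <- sum(cand^2)
    if (cn < bn) {
      bn <- cn
      best <- cand
    }
  }
  best
}

# random triclinic cell in the reduced lower-triangular MD convention
# (off-diagonal elements at most half the corresponding diagonal)
random_reduced_cell <- function() {
  lx <- runif(1, 5, 12)
  ly <- runif(1, 5, 12)
  lz <- runif(1, 5, 12)
  triclinic_cell(rbind(
    c(lx, 0, 0),
    c(runif(1, -0.5, 0.5) * lx, ly, 0),
    c(runif(1, -0.5, 0.5) * lx, runif(1, -0.5, 0.5) * ly, lz)))
}

# a uniform random point inside the cell (so +/-2 image shifts always
# cover the true minimum image for any pair)
random_point_in_cell <- function(cell) {
  drop(frac_to_cart(runif(3), cell))
}

# exhaustive optimal 1-D k-means by dynamic programming on sorted values:
# returns minimal total within-cluster SS and the cluster id (1..k by
# ascending value) per input element
dp_kmeans_1d <- function(x, k) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  sse <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  dp <- matrix(Inf, k, n)
  cut <- matrix(0L, k, n)
  for (j in 1:n) dp[1, j] <- sse(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n) {
    for (i in m:j) {
      v <- dp[m - 1, i - 1] + sse(i, j)
      if (v < dp[m, j]) {
        dp[m, j] <- v
        cut[m, j] <- i
      }
    }
  }
  labs_sorted <- integer(n)
  j <- n
  for (m in k:1) {
    i <- if (m > 1) cut[m, j] else 1L
    labs_sorted[i:j] <- m
    j <- i - 1L
  }
  labs <- integer(n)
  labs[ord] <- labs_sorted
  list(tot_withinss = dp[k, n], cluster = labs)
}

# minimal phosphorus-only "lipid selection" for tessellation tests
p_only_system <- function(n_per_leaflet, cell, seed) {
  n <- 2L * n_per_leaflet
  atoms <- data.frame(name = "P", element = "P",
                      mass = atomic_masses[["P"]],
                      resid = seq_len(n), resname = "LIP")
  topo <- make_topology(atoms, as.list(seq_len(n)))
  sel <- structure(list(phosphorus = seq_len(n),
                        lipids = lapply(seq_len(n), function(i)
                          list(p = i, chains = NULL))),
                   class = "lipid_selection")
  zs <- rep(c(0.75, 0.25) * cell$vectors[3, 3], each = n_per_leaflet)
  pos <- withr_seed_pos(n, cell, zs, seed)
  list(topology = topo, selection = sel,
       frame = make_frame(0, pos, cell),
       labels = rep(c("upper", "lower"), each = n_per_leaflet))
}

withr_seed_pos <- function(n, cell, zs, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  f <- cbind(runif(n), runif(n), 0)
  pos <- frac_to_cart(f, cell)
  pos[, 3] <- zs
  pos
}
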