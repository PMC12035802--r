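#' Probe-to-nanoparticle distance series
#'
#' Periodic-aware distance between the centre of mass of the nanoparticle
#' group and each probe molecule, per frame.
#'
#' @param frames list of frames (non-empty).
#' @param topology a [make_topology()].
#' @param np_group atom indices of the nanoparticle.
#' @param molecules list of atom-index vectors, one per probe molecule.
#' @return matrix (n_frames x n_molecules) of distances in nm, with the
#'   frame times as the `time` attribute.
#' @export
distance_series <- function(frames, topology, np_group, molecules) {
  if (length(frames) == 0) stop("empty trajectory")
  if (length(np_group) == 0 || length(molecules) == 0)
    stop("'np_group' and 'molecules' must be non-empty")
  masses <- topology$atoms$mass
  np_mols <- group_molecules(topology, np_group)
  out <- matrix(0, length(frames), length(molecules))
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    np_pos <- make_whole(fr$positions, np_mols, fr$cell)
    np_com <- group_com(np_pos, masses, np_group)
    for (mi in seq_along(molecules)) {
      g <- molecules[[mi]]
      pos <- make_whole(fr$positions, list(g), fr$cell)
      com <- group_com(pos, masses, g)
      out[fi, mi] <- sqrt(sum(minimum_image_displacement(np_com, com,
                                                         fr$cell)^2))
    }
  }
  colnames(out) <- names(molecules)
  attr(out, "time") <- vapply(frames, function(f) f$time, 0)
  out
}

#' Dispersion feature of a distance series
#'
#' Sample standard deviation (n - 1 denominator) of each molecule's
#' distance series — the one-dimensional feature on which release states
#' are clustered.
#'
#' @param series numeric vector, or a matrix with one column per molecule.
#' @return scalar, or one value per column.
#' @export
release_feature <- function(series) {
  if (is.matrix(series)) {
    if (nrow(series) < 2) stop("series length must be >= 2")
    return(apply(series, 2, sd))
  }
  if (length(series) < 2) stop("series length must be >= 2")
  sd(series)
}

#' Classify probe molecules by k-means on their dispersion feature
#'
#' Lloyd's k-means with `restarts` random initialisations on the 1-D
#' feature; the best-inertia solution is kept. Clusters are labelled by
#' ascending centroid: the lowest-dispersion cluster is `immobile`, then
#' `released`, then `escaped` (for k = 3; other k get `state_1..k`).
#'
#' @param features numeric vector, one dispersion value per molecule.
#' @param k number of clusters (default 3).
#' @param seed RNG seed; classification is deterministic given
#'   (features, seed, restarts).
#' @param restarts number of random restarts (default 10).
#' @return object of class `release_classification`: data.frame with
#'   `molecule`, `feature`, `label`, plus attributes `centroids` (ascending)
#'   and `seed`.
#' @export
classify_release <- function(features, k = 3, seed = 1, restarts = 10) {
  if (length(features) < k)
    stop("need at least k = ", k, " molecules")
  if (length(unique(features)) < k)
    stop("fewer than k = ", k,
         " distinct feature values; reduce k")
  fit <- with_seed(seed,
                   kmeans(matrix(features, ncol = 1), centers = k,
                          nstart = restarts, iter.max = 100,
                          algorithm = "Lloyd"))
  ord <- order(fit$centers[, 1])
  rank_of <- match(fit$cluster, ord)
  lab_names <- if (k == 3) c("immobile", "released", "escaped")
  else sprintf("state_%d", seq_len(k))
  labels <- factor(lab_names[rank_of], levels = lab_names)
  out <- data.frame(molecule = if (!is.null(names(features)))
    names(features) else seq_along(features),
    feature = unname(features), label = labels)
  attr(out, "centroids") <- unname(fit$centers[ord, 1])
  attr(out, "seed") <- seed
  attr(out, "tot_withinss") <- fit$tot.withinss
  class(out) <- c("release_classification", "data.frame")
  out
}

#' @export
print.release_classification <- function(x, ...) {
  cat(sprintf("<release_classification> %d molecules; centroids: %s\n",
              nrow(x),
              paste(sprintf("%.3g", attr(x, "centroids")), collapse = ", ")))
  print(table(x$label))
  invisible(x)
}

#' Write a release classification as CSV
#'
#' Columns: molecule id, dispersion feature, label, and the centroid of
#' the assigned cluster.
#' @param classification a [classify_release()] result.
#' @param path output path.
#' @export
write_release_csv <- function(classification, path) {
  cent <- attr(classification, "centroids")
  df <- data.frame(molecule = classification$molecule,
                   feature = sprintf("%.10g", classification$feature),
                   label = classification$label,
                   centroid = sprintf(
                     "%.10g", cent[as.integer(classification$label)]))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
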