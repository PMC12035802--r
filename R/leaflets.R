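#' Assign lipids to leaflets
#'
#' Groups lipids into the two leaflets of a bilayer by connected components
#' of a graph on phosphorus atoms, with edges wherever the periodic
#' (minimum-image) distance is below `cutoff`. This stays correct on curved
#' membranes whose leaflet z-ranges overlap, where a plain z threshold
#' fails. The component with the greater mean z is labelled `"upper"`.
#'
#' If more than two components form (e.g. an isolated lipid), the smallest
#' components are merged into the component with the nearest centroid until
#' two remain, with a warning. A single component means the cutoff bridges
#' the leaflets; an error suggests reducing it.
#'
#' @param frame a [make_frame()].
#' @param lipid_selection a lipid selection (see [make_flat_bilayer()]).
#' @param cutoff edge distance in nm; default 1.2 (a ceiling on the P-P
#'   nearest-neighbour distance at typical lipid packing).
#' @return character vector, one `"upper"`/`"lower"` label per lipid, class
#'   `leaflet_assignment`.
#' @export
assign_leaflets <- function(frame, lipid_selection, cutoff = 1.2) {
  if (cutoff <= 0) stop("'cutoff' must be positive")
  p_idx <- lipid_selection$phosphorus
  n <- length(p_idx)
  if (n < 2) stop("need at least 2 lipids to assign leaflets")
  pos <- frame$positions[p_idx, , drop = FALSE]
  d2 <- min_image_dist2_matrix(pos, frame$cell)
  adj <- d2 < cutoff^2
  comp <- graph_components(adj)
  ncomp <- max(comp)
  if (ncomp == 1)
    stop("leaflet graph is fully connected at cutoff ", cutoff,
         " nm; reduce the cutoff")
  if (ncomp > 2) {
    warning(ncomp, " leaflet components at cutoff ", cutoff,
            " nm; merging smallest into nearest")
    comp <- merge_to_two(comp, pos, frame$cell)
  }
  mz <- tapply(pos[, 3], comp, mean)
  upper_comp <- as.integer(names(mz)[which.max(mz)])
  labels <- ifelse(comp == upper_comp, "upper", "lower")
  structure(labels, class = "leaflet_assignment")
}

# connected components of a logical adjacency matrix by BFS
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

merge_to_two <- function(comp, pos, cell) {
  while (max(comp) > 2 || length(unique(comp)) > 2) {
    sizes <- table(comp)
    ids <- as.integer(names(sizes))
    small <- ids[which.min(sizes)]
    cents <- t(vapply(ids, function(i)
      colMeans(pos[comp == i, , drop = FALSE]), numeric(3)))
    rest <- ids[ids != small]
    d <- vapply(rest, function(i)
      sum(minimum_image_displacement(cents[ids == small, ],
                                     cents[ids == i, ], cell)^2), 0)
    comp[comp == small] <- rest[which.min(d)]
    comp <- match(comp, sort(unique(comp)))
  }
  comp
}

#' Assign leaflets along a trajectory
#'
#' Either reassigns every frame (`mode = "every"`) or assigns on the first
#' frame and reuses the labels (`mode = "first"`). With per-frame
#' assignment, lipids whose label changes between consecutive frames
#' (flip-flop candidates) are counted and reported.
#'
#' @param frames list of frames.
#' @param lipid_selection a lipid selection.
#' @param cutoff see [assign_leaflets()].
#' @param mode `"every"` or `"first"`.
#' @return list with `labels` (n_frames x n_lipids character matrix) and
#'   `flip_flops` (integer count of label changes).
#' @export
assign_leaflets_trajectory <- function(frames, lipid_selection,
                                       cutoff = 1.2,
                                       mode = c("every", "first")) {
  mode <- match.arg(mode)
  if (length(frames) == 0) stop("empty trajectory")
  first <- assign_leaflets(frames[[1L]], lipid_selection, cutoff)
  labels <- matrix(NA_character_, length(frames), length(first))
  labels[1L, ] <- first
  if (mode == "first") {
    for (i in seq_along(frames)[-1L]) labels[i, ] <- first
  } else {
    for (i in seq_along(frames)[-1L])
      labels[i, ] <- assign_leaflets(frames[[i]], lipid_selection, cutoff)
  }
  flips <- if (nrow(labels) > 1)
    sum(labels[-1L, , drop = FALSE] != labels[-nrow(labels), , drop = FALSE])
  else 0L
  list(labels = labels, flip_flops = as.integer(flips))
}

#' Export a leaflet assignment as CSV
#'
#' Long format: one row per (frame, lipid) with the leaflet label.
#' @param assignment result of [assign_leaflets_trajectory()].
#' @param path output path.
#' @export
write_leaflets_csv <- function(assignment, path) {
  lab <- assignment$labels
  df <- data.frame(frame = rep(seq_len(nrow(lab)), ncol(lab)),
                   lipid = rep(seq_len(ncol(lab)), each = nrow(lab)),
                   leaflet = as.vector(lab))
  df <- df[order(df$frame, df$lipid), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
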