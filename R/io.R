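#' Read a structure file
#'
#' Reads a GRO or PDB structure (or a single-frame JSON fixture) into a
#' topology plus one coordinate frame. Coordinates are returned in nm
#' regardless of the file's native unit.
#'
#' @param path file path; format chosen by extension (`.gro`, `.pdb`,
#'   `.json`).
#' @return list with elements `topology` and `frame`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         gro = read_gro(path),
         pdb = read_pdb(path),
         json = {
           tr <- read_trajectory_json(path)
           if (length(tr$frames) < 1L) stop("JSON fixture has no frames")
           list(topology = tr$topology, frame = tr$frames[[1L]])
         },
         stop("unsupported structure format: .", ext))
}

#' Read a trajectory
#'
#' Reads frames from the versioned JSON fixture dialect (see
#' [write_trajectory_json()] for the schema). Frames are returned in time
#' order; an empty frame list is valid and yields an empty list.
#'
#' @param path file path.
#' @param topology a [make_topology()]; frame atom counts are checked
#'   against it.
#' @return list of [make_frame()] objects.
#' @export
read_trajectory <- function(path, topology) {
  tr <- read_trajectory_json(path)
  validate_frames(tr$frames, topology)
  tr$frames
}

num <- function(s, line, what) {
  v <- suppressWarnings(as.numeric(s))
  if (any(is.na(v)))
    stop(sprintf("cannot parse %s in line: '%s'", what, line))
  v
}

guess_element <- function(name) {
  # first alphabetic character of the atom name; adequate for H/C/N/O/P/S
  el <- toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", name))
  ifelse(el %in% names(atomic_masses), el, "C")
}

molecules_from_resid <- function(resid) {
  grp <- cumsum(c(1L, as.integer(diff(as.integer(resid)) != 0L)))
  unname(split(seq_along(resid), grp))
}

#' @rdname read_structure
#' @export
read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("truncated GRO file: ", path)
  natoms <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(natoms)) stop("cannot parse atom count in line: '", lines[2L], "'")
  if (length(lines) < 3L + natoms) stop("GRO file shorter than atom count")
  al <- lines[3:(2 + natoms)]
  resid <- as.integer(num(substr(al, 1, 5), al[1], "residue id"))
  resname <- trimws(substr(al, 6, 10))
  name <- trimws(substr(al, 11, 15))
  x <- num(substr(al, 21, 28), al[1], "x coordinate")
  y <- num(substr(al, 29, 36), al[1], "y coordinate")
  z <- num(substr(al, 37, 44), al[1], "z coordinate")
  boxline <- trimws(lines[3L + natoms])
  if (nchar(boxline) == 0) stop("missing box line in GRO file")
  b <- num(strsplit(boxline, "\\s+")[[1L]], boxline, "box vector")
  vec <- if (length(b) >= 9) {
    rbind(c(b[1], b[4], b[5]), c(b[6], b[2], b[7]), c(b[8], b[9], b[3]))
  } else if (length(b) >= 3) {
    diag(b[1:3])
  } else stop("missing box: GRO box line needs 3 or 9 numbers")
  el <- guess_element(name)
  atoms <- data.frame(name = name, element = el,
                      mass = unname(atomic_masses[el]),
                      resid = resid, resname = resname,
                      stringsAsFactors = FALSE)
  topo <- make_topology(atoms, molecules_from_resid(resid))
  list(topology = topo,
       frame = make_frame(0, cbind(x, y, z), triclinic_cell(vec)))
}

#' Write a GRO structure file
#'
#' @param topology a [make_topology()].
#' @param frame a [make_frame()].
#' @param path output path.
#' @export
write_gro <- function(topology, frame, path) {
  a <- topology$atoms
  n <- nrow(a)
  lines <- character(n + 3L)
  lines[1L] <- "written by membranemaps"
  lines[2L] <- sprintf("%5d", n)
  lines[3:(n + 2)] <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              a$resid %% 100000L, substr(a$resname, 1, 5),
                              substr(a$name, 1, 5), seq_len(n) %% 100000L,
                              frame$positions[, 1], frame$positions[, 2],
                              frame$positions[, 3])
  v <- frame$cell$vectors
  lines[n + 3L] <- if (all(v[lower.tri(v) | upper.tri(v)] == 0))
    sprintf("%10.5f%10.5f%10.5f", v[1, 1], v[2, 2], v[3, 3])
  else
    paste(sprintf("%10.5f", c(v[1, 1], v[2, 2], v[3, 3], v[1, 2], v[1, 3],
                              v[2, 1], v[2, 3], v[3, 1], v[3, 2])),
          collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_structure
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0) stop("missing box: no CRYST1 record in ", path)
  cl <- cl[1L]
  abc <- num(c(substr(cl, 7, 15), substr(cl, 16, 24), substr(cl, 25, 33)),
             cl, "cell length") / 10  # Angstrom -> nm
  ang <- num(c(substr(cl, 34, 40), substr(cl, 41, 47), substr(cl, 48, 54)),
             cl, "cell angle") * pi / 180
  ca <- cos(ang[1]); cb <- cos(ang[2]); cg <- cos(ang[3]); sg <- sin(ang[3])
  v3y <- abc[3] * (ca - cb * cg) / sg
  v3z <- sqrt(max(abc[3]^2 - (abc[3] * cb)^2 - v3y^2, 0))
  vec <- rbind(c(abc[1], 0, 0),
               c(abc[2] * cg, abc[2] * sg, 0),
               c(abc[3] * cb, v3y, v3z))
  al <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  if (length(al) == 0) stop("no ATOM/HETATM records in ", path)
  name <- trimws(substr(al, 13, 16))
  resname <- trimws(substr(al, 18, 21))
  resid <- as.integer(num(substr(al, 23, 26), al[1], "residue id"))
  x <- num(substr(al, 31, 38), al[1], "x coordinate") / 10
  y <- num(substr(al, 39, 46), al[1], "y coordinate") / 10
  z <- num(substr(al, 47, 54), al[1], "z coordinate") / 10
  el <- trimws(substr(al, 77, 78))
  el <- ifelse(el %in% names(atomic_masses), el, guess_element(name))
  atoms <- data.frame(name = name, element = el,
                      mass = unname(atomic_masses[el]),
                      resid = resid, resname = resname,
                      stringsAsFactors = FALSE)
  topo <- make_topology(atoms, molecules_from_resid(resid))
  list(topology = topo,
       frame = make_frame(0, cbind(x, y, z), triclinic_cell(vec)))
}

#' Write / read the JSON trajectory fixture dialect
#'
#' A self-contained plain-text trajectory format used for fixtures and
#' pipeline exchange, so tests need no binary readers. Schema (version 1):
#' ```
#' {"format": "membranemaps-trajectory", "version": 1,
#'  "topology": {"atoms": [{"name","element","mass","resid","resname"},...],
#'               "molecules": [[0-based atom indices], ...]},
#'  "frames": [{"time": ns, "cell": [[3x3 row-wise nm]],
#'              "positions": [[x,y,z nm], ...]}, ...]}
#' ```
#' Atom indices are 0-based on disk and converted to the package's 1-based
#' convention on read.
#'
#' @param topology a [make_topology()].
#' @param frames list of [make_frame()] objects.
#' @param path file path.
#' @return `write_trajectory_json` returns `path`; `read_trajectory_json`
#'   a list with `topology` and `frames`.
#' @export
write_trajectory_json <- function(topology, frames, path) {
  validate_frames(frames, topology)
  obj <- list(
    format = "membranemaps-trajectory",
    version = 1L,
    topology = list(
      atoms = topology$atoms,
      molecules = lapply(topology$molecules, function(m) m - 1L)),
    frames = lapply(frames, function(f) list(
      time = f$time,
      cell = unname(f$cell$vectors),
      positions = unname(f$positions))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory_json
#' @export
read_trajectory_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE,
                             simplifyMatrix = TRUE)
  if (!identical(obj$format, "membranemaps-trajectory"))
    stop("not a membranemaps trajectory JSON file: ", path)
  mols <- obj$topology$molecules
  if (is.matrix(mols)) mols <- split(mols, row(mols))  # uniform lengths
  topo <- make_topology(obj$topology$atoms,
                        lapply(mols, function(m) as.integer(m) + 1L))
  fr <- obj$frames
  frames <- list()
  if (length(fr) > 0) {
    # jsonlite may simplify the frame list to a data.frame of list-columns
    if (is.data.frame(fr)) {
      frames <- lapply(seq_len(nrow(fr)), function(i)
        make_frame(fr$time[[i]],
                   as.matrix(fr$positions[[i]]),
                   triclinic_cell(as.matrix(fr$cell[[i]]))))
    } else {
      frames <- lapply(fr, function(f)
        make_frame(f$time, as.matrix(f$positions),
                   triclinic_cell(as.matrix(f$cell))))
    }
  }
  validate_frames(frames, topo)
  list(topology = topo, frames = frames)
}
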