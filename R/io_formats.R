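#' Uniformly sampled time series
#'
#' Light container for a uniformly sampled signal. Internal time unit is
#' nanoseconds throughout the analysis layer.
#'
#' @param values numeric vector, length >= 2.
#' @param dt sampling interval (ns).
#' @param t0 time of the first sample (ns).
#' @param label,units descriptive strings.
#' @return an object of class `loop_ts` with fields `values`, `dt`, `t0`,
#'   `label`, `units`.
#' @export
time_series <- function(values, dt, t0 = 0, label = "", units = "") {
  check_number(dt, "dt", positive = TRUE)
  if (!is.numeric(values) || length(values) < 2L)
    stop_looplab("looplab_parameter_error", "'values' must have length >= 2")
  structure(list(values = as.numeric(values), dt = dt, t0 = t0,
                 label = label, units = units),
            class = "loop_ts")
}

#' @export
print.loop_ts <- function(x, ...) {
  cat(sprintf("<time series> %d samples, dt = %g ns, span %.4g ns%s\n",
              length(x$values), x$dt, x$dt * (length(x$values) - 1L),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' @export
length.loop_ts <- function(x) length(x$values)

ts_times <- function(x) x$t0 + (seq_along(x$values) - 1) * x$dt

#' Read a two-column time-series CSV
#'
#' Expects a one-line header and columns (time_ns, value). The sampling
#' interval is inferred from the median spacing; grids whose spacing
#' deviates by more than a relative tolerance are rejected.
#'
#' @param path file path.
#' @param tol relative non-uniformity tolerance (default `1e-6`).
#' @return a [time_series()] object.
#' @export
read_timeseries <- function(path, tol = 1e-6) {
  if (!file.exists(path))
    stop_looplab("looplab_parse_error", "file not found: %s", path)
  df <- tryCatch(read.csv(path), error = function(e)
    stop_looplab("looplab_parse_error", "cannot parse '%s': %s", path,
                 conditionMessage(e)))
  if (nrow(df) < 2L || ncol(df) < 2L)
    stop_looplab("looplab_parse_error", "'%s': need >= 2 rows of (time, value)", path)
  t <- as.numeric(df[[1L]]); v <- as.numeric(df[[2L]])
  if (any(!is.finite(t)) || is.unsorted(t, strictly = TRUE))
    stop_looplab("looplab_parse_error", "'%s': times must be finite and increasing", path)
  dts <- diff(t)
  dt <- median(dts)
  if (any(abs(dts - dt) > tol * dt))
    stop_looplab("looplab_grid_error",
                 "'%s': non-uniform sampling (max deviation %.3g of dt)",
                 path, max(abs(dts - dt)) / dt)
  time_series(v, dt = dt, t0 = t[1L], label = names(df)[2L])
}

#' Write a time series as a two-column CSV
#'
#' Columns `time_ns`, `value`; values are written with 15 significant
#' digits so a read/write round trip preserves them to at least 12.
#'
#' @param series a [time_series()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  stopifnot(inherits(series, "loop_ts"))
  df <- data.frame(time_ns = format(ts_times(series), digits = 15, trim = TRUE),
                   value = format(series$values, digits = 15, trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# structures and trajectories

#' Build a molecular structure from an atom table
#'
#' @param atoms data.frame with columns `atom_name`, `element`,
#'   `residue_index` (1-based, non-decreasing), `residue_name`, `chain_id`,
#'   and coordinates `x`, `y`, `z` in nm.
#' @return object of class `peptide_structure`.
#' @export
structure_from_atoms <- function(atoms) {
  need <- c("atom_name", "element", "residue_index", "residue_name",
            "chain_id", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop_looplab("looplab_parameter_error", "atom table lacks column(s): %s",
                 paste(miss, collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz)))
    stop_looplab("looplab_parameter_error", "non-finite coordinates")
  if (is.unsorted(atoms$residue_index))
    stop_looplab("looplab_parameter_error", "residue indices must be non-decreasing")
  structure(list(atoms = as.data.frame(atoms)), class = "peptide_structure")
}

#' @export
print.peptide_structure <- function(x, ...) {
  cat(sprintf("<structure> %d atoms, %d residues\n",
              nrow(x$atoms), length(unique(x$atoms$residue_index))))
  invisible(x)
}

n_residues <- function(structure) length(unique(structure$atoms$residue_index))

#' Assemble a trajectory from structures or a coordinate array
#'
#' @param frames list of `peptide_structure` objects with identical
#'   topology, or a single structure plus a `coords` array.
#' @param dt time between stored frames (ns).
#' @param origin_time time of the first frame (ns).
#' @param coords optional `n_frames x n_atoms x 3` array (nm) used with a
#'   single-topology `frames`.
#' @return object of class `peptide_trajectory` with fields `topology`
#'   (atom table without coordinates), `coords`, `dt`, `origin_time`.
#' @export
trajectory <- function(frames, dt, origin_time = 0, coords = NULL) {
  check_number(dt, "dt", positive = TRUE)
  if (inherits(frames, "peptide_structure")) {
    topo <- frames$atoms
    if (is.null(coords)) {
      coords <- array(as.matrix(topo[, c("x", "y", "z")]),
                      dim = c(1L, nrow(topo), 3L))
    }
  } else {
    if (!length(frames))
      stop_looplab("looplab_topology_error", "a trajectory needs >= 1 frame")
    na <- vapply(frames, function(f) nrow(f$atoms), 0L)
    if (length(unique(na)) != 1L)
      stop_looplab("looplab_topology_error",
                   "inconsistent atom counts across frames: %s",
                   paste(unique(na), collapse = ", "))
    topo <- frames[[1L]]$atoms
    coords <- array(0, dim = c(length(frames), na[1L], 3L))
    for (i in seq_along(frames))
      coords[i, , ] <- as.matrix(frames[[i]]$atoms[, c("x", "y", "z")])
  }
  topo$x <- topo$y <- topo$z <- NULL
  structure(list(topology = topo, coords = coords, dt = dt,
                 origin_time = origin_time),
            class = "peptide_trajectory")
}

#' @export
print.peptide_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, dt = %g ns\n",
              dim(x$coords)[1L], dim(x$coords)[2L], x$dt))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1L]

#' Extract one frame of a trajectory as a structure
#' @param traj a `peptide_trajectory`.
#' @param i frame index (1-based).
#' @return a `peptide_structure`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "peptide_trajectory"))
  if (i < 1L || i > n_frames(traj))
    stop_looplab("looplab_parameter_error", "frame %d out of range", i)
  at <- traj$topology
  at$x <- traj$coords[i, , 1L]
  at$y <- traj$coords[i, , 2L]
  at$z <- traj$coords[i, , 3L]
  structure_from_atoms(at)
}

# ---------------------------------------------------------------------------
# PDB / XYZ

#' Read a structure from a PDB or XYZ file
#'
#' PDB parsing is delegated to \pkg{bio3d}; coordinates are converted from
#' Angstrom to nm. A multi-MODEL file yields the first model (use
#' [read_trajectory()] for all of them). XYZ files carry element symbols
#' only; atoms are assigned to one residue.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @return a `peptide_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (format == "xyz") {
    fr <- read_xyz_frames(path)
    return(fr$structure)
  }
  pdb <- read_pdb_checked(path)
  atoms_from_bio3d(pdb, model = 1L)
}

read_pdb_checked <- function(path) {
  if (!file.exists(path))
    stop_looplab("looplab_parse_error", "file not found: %s", path)
  tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
           error = function(e)
             stop_looplab("looplab_parse_error", "cannot parse PDB '%s': %s",
                          path, conditionMessage(e)))
}

atoms_from_bio3d <- function(pdb, model = 1L) {
  a <- pdb$atom
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  at <- data.frame(
    atom_name = a$elety, element = ifelse(is.na(a$elesy) | a$elesy == "",
                                          substr(a$elety, 1L, 1L), a$elesy),
    residue_index = a$resno, residue_name = a$resid,
    chain_id = ifelse(is.na(a$chain), "A", a$chain),
    x = xyz[, 1L] / 10, y = xyz[, 2L] / 10, z = xyz[, 3L] / 10,
    stringsAsFactors = FALSE)
  structure_from_atoms(at)
}

#' Read a multi-frame trajectory from a multi-MODEL PDB or multi-frame XYZ
#'
#' @param path file path.
#' @param dt time between frames (ns).
#' @param format `"auto"`, `"pdb"` or `"xyz"`.
#' @param origin_time time of the first frame (ns).
#' @return a `peptide_trajectory`.
#' @export
read_trajectory <- function(path, dt, format = c("auto", "pdb", "xyz"),
                            origin_time = 0) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (format == "xyz") {
    fr <- read_xyz_frames(path)
    return(trajectory(fr$structure, dt = dt, origin_time = origin_time,
                      coords = fr$coords))
  }
  pdb <- read_pdb_checked(path)
  nm <- nrow(pdb$xyz)
  first <- atoms_from_bio3d(pdb, model = 1L)
  coords <- array(0, dim = c(nm, nrow(first$atoms), 3L))
  for (m in seq_len(nm))
    coords[m, , ] <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE) / 10
  trajectory(first, dt = dt, origin_time = origin_time, coords = coords)
}

#' Write a structure or trajectory to PDB
#'
#' Fixed-width ATOM records in Angstrom; trajectories are written as one
#' MODEL block per frame.
#'
#' @param x a `peptide_structure` or `peptide_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  fmt_atom <- function(i, at, xyz_nm) {
    nm <- at$atom_name[i]
    nm4 <- sprintf("%-4s", if (nchar(nm) < 4L) paste0(" ", nm) else nm)
    sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, nm4, at$residue_name[i], substr(at$chain_id[i], 1L, 1L),
            at$residue_index[i],
            xyz_nm[i, 1L] * 10, xyz_nm[i, 2L] * 10, xyz_nm[i, 3L] * 10,
            1, 0, at$element[i])
  }
  con <- file(path, "w"); on.exit(close(con))
  if (inherits(x, "peptide_structure")) {
    xyz <- as.matrix(x$atoms[, c("x", "y", "z")])
    for (i in seq_len(nrow(x$atoms)))
      writeLines(fmt_atom(i, x$atoms, xyz), con)
    writeLines("END", con)
  } else if (inherits(x, "peptide_trajectory")) {
    for (m in seq_len(n_frames(x))) {
      writeLines(sprintf("MODEL     %4d", m), con)
      xyz <- x$coords[m, , , drop = TRUE]
      if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
      for (i in seq_len(nrow(x$topology)))
        writeLines(fmt_atom(i, x$topology, xyz), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else stop_looplab("looplab_parameter_error", "cannot write object of this class")
  invisible(path)
}

#' Write a structure or trajectory as (multi-frame) XYZ
#'
#' Standard XYZ blocks: atom count, comment, element + coordinates.
#' Coordinates are written in Angstrom.
#'
#' @param x a `peptide_structure` or `peptide_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  write_block <- function(el, xyz, comment) {
    writeLines(as.character(length(el)), con)
    writeLines(comment, con)
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f", el,
                       xyz[, 1L] * 10, xyz[, 2L] * 10, xyz[, 3L] * 10), con)
  }
  if (inherits(x, "peptide_structure")) {
    write_block(x$atoms$element, as.matrix(x$atoms[, c("x", "y", "z")]),
                "frame 1")
  } else if (inherits(x, "peptide_trajectory")) {
    for (m in seq_len(n_frames(x))) {
      xyz <- x$coords[m, , , drop = TRUE]
      if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
      write_block(x$topology$element, xyz, sprintf("frame %d", m))
    }
  } else stop_looplab("looplab_parameter_error", "cannot write object of this class")
  invisible(path)
}

# parse a (multi-frame) XYZ file: returns first-frame structure + coord array
read_xyz_frames <- function(path) {
  if (!file.exists(path))
    stop_looplab("looplab_parse_error", "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  frames <- list(); i <- 1L
  while (i <= length(lines)) {
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na) || na < 1L || i + 1L + na > length(lines))
      stop_looplab("looplab_parse_error", "malformed XYZ near line %d of '%s'",
                   i, path)
    block <- lines[(i + 2L):(i + 1L + na)]
    tok <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(vapply(tok, length, 0L) < 4L)
    if (length(bad))
      stop_looplab("looplab_parse_error", "malformed XYZ record at line %d of '%s'",
                   i + 1L + bad[1L], path)
    el <- vapply(tok, `[[`, "", 1L)
    xyz <- t(vapply(tok, function(w) as.numeric(w[2:4]), numeric(3L))) / 10
    frames[[length(frames) + 1L]] <- list(el = el, xyz = xyz)
    i <- i + 2L + na
  }
  na <- vapply(frames, function(f) length(f$el), 0L)
  if (length(unique(na)) != 1L)
    stop_looplab("looplab_topology_error",
                 "inconsistent atom counts across XYZ frames")
  el <- frames[[1L]]$el
  at <- data.frame(atom_name = el, element = el,
                   residue_index = 1L, residue_name = "UNK", chain_id = "A",
                   x = frames[[1L]]$xyz[, 1L], y = frames[[1L]]$xyz[, 2L],
                   z = frames[[1L]]$xyz[, 3L], stringsAsFactors = FALSE)
  coords <- array(0, dim = c(length(frames), na[1L], 3L))
  for (m in seq_along(frames)) coords[m, , ] <- frames[[m]]$xyz
  list(structure = structure_from_atoms(at), coords = coords)
}
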