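#' Construct a binary open/closed state series
#'
#' Carrier for the fluorescence-style signal I(t): 1 = open/fluorescent,
#' 0 = closed/quenched, uniform sampling.
#'
#' @param states integer 0/1 vector, length >= 2.
#' @param dt sampling interval (ns).
#' @param cutoff_nm distance cutoff that produced the series (NA if not
#'   derived from distances).
#' @param group_spec free-text description of the two atom groups or of the
#'   generator that produced the signal.
#' @return object of class `state_series`.
#' @export
state_series <- function(states, dt, cutoff_nm = NA_real_, group_spec = "") {
  if (!all(states %in% c(0L, 1L)))
    stop_looplab("looplab_parameter_error", "states must be 0/1")
  if (length(states) < 2L)
    stop_looplab("looplab_parameter_error", "need >= 2 samples")
  check_number(dt, "dt", positive = TRUE)
  structure(list(states = as.integer(states), dt = dt, cutoff_nm = cutoff_nm,
                 group_spec = group_spec),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat(sprintf(
    "<state series> %d samples, dt = %g ns, open fraction %.3f%s\n",
    length(x$states), x$dt, mean(x$states),
    if (is.finite(x$cutoff_nm)) sprintf(", cutoff %.3g nm", x$cutoff_nm) else ""))
  invisible(x)
}

#' @export
length.state_series <- function(x) length(x$states)

#' Atom-group selections for the end-to-end minimum distance
#'
#' `group_spec()` builds an explicit selection; `group_preset()` returns the
#' named presets. The `"labelled"` preset pairs the dye ring carbons
#' (residue name `DYE`) against the Trp ring atoms; `"unlabelled"` pairs
#' the Trp rings plus the C-terminal carboxylate against the N-terminal
#' amide group. The exact Trp "ring + C-terminal group" atom list is an
#' interpretation (all ring heavy atoms plus the terminal C/O atoms) since
#' no exhaustive enumeration is standard.
#'
#' @param a,b data.frames with columns `residue_index`, `atom_name`
#'   (either may be `NULL` entries meaning "any atom of that residue" when
#'   `atom_name` is NA).
#' @return object of class `group_spec` with elements `a`, `b`, `label`.
#' @export
group_spec <- function(a, b) {
  chk <- function(g, nm) {
    if (!is.data.frame(g) || !nrow(g) ||
        !all(c("residue_index", "atom_name") %in% names(g)))
      stop_looplab("looplab_selection_error",
                   "group '%s' needs rows of (residue_index, atom_name)", nm)
    g
  }
  a <- chk(a, "a"); b <- chk(b, "b")
  ov <- merge(a, b, by = c("residue_index", "atom_name"))
  if (nrow(ov))
    stop_looplab("looplab_selection_error", "groups must be disjoint")
  structure(list(a = a, b = b, label = "custom"), class = "group_spec")
}

#' @rdname group_spec
#' @param name `"labelled"`, `"unlabelled"`, or `"termini"` (first vs last
#'   residue, any atom; the natural choice for bead chains).
#' @param n_residues total residue count of the target topology (needed to
#'   address the terminal residues).
#' @export
group_preset <- function(name = c("termini", "labelled", "unlabelled"),
                         n_residues) {
  name <- match.arg(name)
  check_count(n_residues, "n_residues", min = 2L)
  any_atom <- NA_character_
  trp_rings <- c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
  g <- switch(name,
    termini = list(
      a = data.frame(residue_index = 1L, atom_name = any_atom),
      b = data.frame(residue_index = n_residues, atom_name = any_atom)),
    labelled = list(
      a = data.frame(residue_index = 1L, atom_name = any_atom),       # dye rings
      b = data.frame(residue_index = n_residues, atom_name = trp_rings)),
    unlabelled = list(
      a = data.frame(residue_index = 1L, atom_name = c("N", "H", "CA")), # N-terminal group
      b = data.frame(residue_index = n_residues,
                     atom_name = c(trp_rings, "C", "O", "OXT"))))
  out <- structure(list(a = g$a, b = g$b, label = name), class = "group_spec")
  out
}

select_atoms <- function(topology, g) {
  idx <- integer(0)
  for (r in unique(g$residue_index)) {
    names_r <- g$atom_name[g$residue_index == r]
    in_res <- which(topology$residue_index == r)
    if (!length(in_res))
      stop_looplab("looplab_selection_error", "residue %s not in topology", r)
    if (all(is.na(names_r))) idx <- c(idx, in_res)
    else {
      hit <- in_res[topology$atom_name[in_res] %in% names_r]
      idx <- c(idx, hit)
    }
  }
  idx <- sort(unique(idx))
  if (!length(idx))
    stop_looplab("looplab_selection_error", "empty atom selection")
  idx
}

#' Per-frame minimum distance between two atom groups
#'
#' For every frame, the minimum over all inter-group atom pairs of the
#' Euclidean distance (nm). Periodic images are ignored: inputs are assumed
#' non-periodic (pre-imaged).
#'
#' @param traj a `peptide_trajectory`.
#' @param groups a [group_spec()] / [group_preset()] selection.
#' @return a [time_series()] of minimum distances (nm), dt taken from the
#'   trajectory.
#' @export
min_distance_series <- function(traj, groups) {
  stopifnot(inherits(traj, "peptide_trajectory"),
            inherits(groups, "group_spec"))
  ia <- select_atoms(traj$topology, groups$a)
  ib <- select_atoms(traj$topology, groups$b)
  if (length(intersect(ia, ib)))
    stop_looplab("looplab_selection_error", "groups share atoms")
  nf <- n_frames(traj)
  if (nf < 2L)
    stop_looplab("looplab_parameter_error",
                 "a distance time series needs >= 2 frames; use min_distance()")
  out <- numeric(nf)
  for (m in seq_len(nf)) {
    A <- matrix(traj$coords[m, ia, , drop = FALSE], ncol = 3L)
    B <- matrix(traj$coords[m, ib, , drop = FALSE], ncol = 3L)
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    out[m] <- sqrt(max(0, min(d2)))
  }
  time_series(out, dt = traj$dt, t0 = traj$origin_time,
              label = sprintf("min_distance_%s", groups$label), units = "nm")
}

#' Minimum inter-group distance of a single structure
#' @param structure a `peptide_structure`.
#' @param groups a [group_spec()].
#' @return minimum distance (nm).
#' @export
min_distance <- function(structure, groups) {
  stopifnot(inherits(structure, "peptide_structure"),
            inherits(groups, "group_spec"))
  ia <- select_atoms(structure$atoms, groups$a)
  ib <- select_atoms(structure$atoms, groups$b)
  A <- as.matrix(structure$atoms[ia, c("x", "y", "z")])
  B <- as.matrix(structure$atoms[ib, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Binarize a distance series into open/closed states
#'
#' A frame is closed (state 0, quenched) when the distance is less than or
#' equal to the cutoff, open (state 1, fluorescent) otherwise. The
#' inclusive-closed tie-break at exact equality is a documented convention.
#'
#' @param series a [time_series()] of distances (nm).
#' @param cutoff_nm distance cutoff (nm), > 0. See [gs_cutoffs] for the
#'   conventional labelled/unlabelled defaults.
#' @return a [state_series()].
#' @export
binarize <- function(series, cutoff_nm) {
  stopifnot(inherits(series, "loop_ts"))
  check_number(cutoff_nm, "cutoff_nm", positive = TRUE)
  state_series(as.integer(series$values > cutoff_nm), dt = series$dt,
               cutoff_nm = cutoff_nm, group_spec = series$label)
}

#' Dwell times of a binary state series
#'
#' Maximal constant-state runs converted to durations (ns). Runs touching
#' either record boundary are truncated observations; they are reported
#' separately and excluded from the open/closed dwell lists.
#'
#' @param series a [state_series()].
#' @return list with `open`, `closed` (interior dwell durations, ns),
#'   `truncated` (durations of boundary runs, ns), and `mean_open`,
#'   `mean_closed` (NA when no interior dwell exists).
#' @export
dwell_times <- function(series) {
  stopifnot(inherits(series, "state_series"))
  r <- runs_cpp(series$states)
  dur <- r$length * series$dt
  interior <- r$truncated == 0L
  open <- dur[interior & r$state == 1L]
  closed <- dur[interior & r$state == 0L]
  list(open = open, closed = closed, truncated = dur[!interior],
       mean_open = if (length(open)) mean(open) else NA_real_,
       mean_closed = if (length(closed)) mean(closed) else NA_real_)
}
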