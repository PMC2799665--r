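# Backbone hydrogen-bond detection, beta-segment ladders, Ramachandran
# statistics, and open-state structural summaries.

res_atom <- function(st, res, name) {
  a <- st$atoms
  i <- which(a$residue_index == res & a$atom_name == name)
  if (!length(i)) return(NULL)
  as.numeric(a[i[1L], c("x", "y", "z")])
}

#' Reconstruct missing amide hydrogens
#'
#' United-atom models omit the backbone amide H that both the geometric
#' and the Kabsch-Sander criteria need. The H is placed 0.101 nm from N in
#' the peptide plane, anti to the preceding carbonyl oxygen (trans to
#' C(i-1)=O). The first residue (no preceding carbonyl) is left without H.
#'
#' @param structure a `peptide_structure` with backbone N, CA, C, O.
#' @return the structure with H atoms added where they were missing.
#' @export
reconstruct_amide_h <- function(structure) {
  st <- structure
  resids <- sort(unique(st$atoms$residue_index))
  add <- list()
  for (k in seq_along(resids)[-1L]) {
    r <- resids[k]; rp <- resids[k - 1L]
    if (!is.null(res_atom(st, r, "H"))) next
    N <- res_atom(st, r, "N"); CA <- res_atom(st, r, "CA")
    Cp <- res_atom(st, rp, "C"); Op <- res_atom(st, rp, "O")
    # residues without the reference atoms (chain breaks, acceptor-only
    # fragments) are left without an amide H: they simply cannot donate
    if (is.null(N) || is.null(CA) || is.null(Cp) || is.null(Op)) next
    # bisector placement in the peptide plane: H anti to C(i-1)=O for a
    # planar trans peptide, 0.101 nm from N
    d1 <- N - Cp; d1 <- d1 / sqrt(sum(d1^2))
    d2 <- N - CA; d2 <- d2 / sqrt(sum(d2^2))
    hdir <- d1 + d2
    # project out-of-plane wobble: keep H in the Cp, N, CA plane
    nrm <- pracma_cross(d1, d2)
    if (sqrt(sum(nrm^2)) > 1e-9) {
      nrm <- nrm / sqrt(sum(nrm^2))
      hdir <- hdir - sum(hdir * nrm) * nrm
    }
    hdir <- hdir / sqrt(sum(hdir^2))
    H <- N + 0.101 * hdir
    rn <- st$atoms$residue_name[st$atoms$residue_index == r][1L]
    ch <- st$atoms$chain_id[st$atoms$residue_index == r][1L]
    add[[length(add) + 1L]] <- data.frame(
      atom_name = "H", element = "H", residue_index = r, residue_name = rn,
      chain_id = ch, x = H[1L], y = H[2L], z = H[3L], stringsAsFactors = FALSE)
  }
  if (length(add)) {
    at <- rbind(st$atoms, do.call(rbind, add))
    at <- at[order(at$residue_index), ]
    st <- structure_from_atoms(at)
  }
  st
}

#' Kabsch-Sander hydrogen-bond energy of a donor/acceptor residue pair
#'
#' The DSSP electrostatic model:
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol with
#' distances in Angstrom, donor = backbone N-H, acceptor = backbone C=O.
#' A hydrogen bond is assigned when `E < -0.5` kcal/mol (the DSSP default
#' cutoff).
#'
#' @param structure a `peptide_structure` (H reconstructed if absent).
#' @param donor_res,acceptor_res 1-based residue indices.
#' @return energy in kcal/mol.
#' @export
kabsch_sander_energy <- function(structure, donor_res, acceptor_res) {
  st <- structure
  if (is.null(res_atom(st, donor_res, "H")))
    st <- reconstruct_amide_h(st)
  ks_pair_energy(st, donor_res, acceptor_res)
}

# internal: assumes H present where possible; returns +Inf-free large value
ks_pair_energy <- function(st, donor_res, acceptor_res) {
  N <- res_atom(st, donor_res, "N"); H <- res_atom(st, donor_res, "H")
  C <- res_atom(st, acceptor_res, "C"); O <- res_atom(st, acceptor_res, "O")
  if (is.null(N) || is.null(C) || is.null(O))
    stop_looplab("looplab_topology_error",
                 "missing backbone atoms for residues %d/%d",
                 donor_res, acceptor_res)
  if (is.null(H)) return(0)  # N-terminal residue cannot donate
  d <- function(a, b) {
    r <- sqrt(sum((a - b)^2)) * 10  # nm -> Angstrom
    if (r < 1e-6)
      stop_looplab("looplab_geometry_error", "coincident atoms in K-S energy")
    r
  }
  0.084 * 332 * (1 / d(O, N) + 1 / d(C, H) - 1 / d(O, H) - 1 / d(C, N))
}

#' Kabsch-Sander hydrogen-bond cutoff (kcal/mol)
#' @export
ks_cutoff_kcal <- -0.5

#' Detect backbone hydrogen bonds in one frame
#'
#' Geometric criterion: donor-acceptor heavy-atom (N...O) distance at most
#' 0.35 nm and H-N...O angle at most 30 degrees. Kabsch-Sander criterion:
#' energy below -0.5 kcal/mol. Partners closer than `min_sep` residues in
#' sequence are excluded (trivially bonded neighbours).
#'
#' @param structure a `peptide_structure`.
#' @param criterion `"kabsch_sander"` (default) or `"geometric"`.
#' @param dist_cutoff geometric N...O cutoff (nm).
#' @param angle_cutoff geometric H-N...O angle cutoff (degrees).
#' @param min_sep minimum |donor - acceptor| residue separation (default 2).
#' @return data.frame with columns `donor`, `acceptor` (residue indices),
#'   `energy` (kcal/mol, NA under the geometric criterion), `criterion`.
#' @export
detect_hbonds <- function(structure,
                          criterion = c("kabsch_sander", "geometric"),
                          dist_cutoff = 0.35, angle_cutoff = 30,
                          min_sep = 2L) {
  criterion <- match.arg(criterion)
  st <- reconstruct_amide_h(structure)
  resids <- sort(unique(st$atoms$residue_index))
  out <- list()
  for (d_ in resids) {
    H <- res_atom(st, d_, "H"); N <- res_atom(st, d_, "N")
    if (is.null(H) || is.null(N)) next
    for (a_ in resids) {
      if (abs(d_ - a_) < min_sep) next
      O <- res_atom(st, a_, "O"); C <- res_atom(st, a_, "C")
      if (is.null(O) || is.null(C)) next
      if (criterion == "geometric") {
        rno <- sqrt(sum((N - O)^2))
        if (rno > dist_cutoff) next
        u <- H - N; v <- O - N
        ang <- acos(pmin(1, pmax(-1, sum(u * v) /
                                   sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
        if (ang > angle_cutoff) next
        out[[length(out) + 1L]] <- data.frame(donor = d_, acceptor = a_,
                                              energy = NA_real_,
                                              criterion = criterion)
      } else {
        if (sqrt(sum((N - O)^2)) > 0.7) next  # K-S energies are negligible beyond
        e <- ks_pair_energy(st, d_, a_)
        if (e < ks_cutoff_kcal)
          out[[length(out) + 1L]] <- data.frame(donor = d_, acceptor = a_,
                                                energy = e,
                                                criterion = criterion)
      }
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(0), acceptor = integer(0),
                      energy = numeric(0), criterion = character(0)))
  do.call(rbind, out)
}

#' @rdname detect_hbonds
#' @export
detect_hbonds_geometric <- function(structure, dist_cutoff = 0.35,
                                    angle_cutoff = 30, min_sep = 2L) {
  detect_hbonds(structure, "geometric", dist_cutoff, angle_cutoff, min_sep)
}

#' @rdname detect_hbonds
#' @export
detect_hbonds_ks <- function(structure, min_sep = 2L) {
  detect_hbonds(structure, "kabsch_sander", min_sep = min_sep)
}

#' Group inter-strand hydrogen bonds into beta-segment ladders
#'
#' A beta segment is a run of at least two consecutive inter-strand
#' hydrogen bonds between two strands with consistent register:
#' antiparallel ladders conserve the residue-index sum (donor + acceptor),
#' parallel ladders conserve the difference. Bonds closer than 3 residues
#' in sequence cannot span two strands and are ignored.
#'
#' @param hbonds data.frame from [detect_hbonds()] (columns `donor`,
#'   `acceptor`).
#' @param min_ladder minimum number of bonds in a ladder (default 2).
#' @return list of `beta_segment` lists: `orientation`, `bonds`
#'   (data.frame), `strand_a`, `strand_b` (residue ranges), `n_bonds`.
#' @export
beta_segments <- function(hbonds, min_ladder = 2L) {
  hb <- hbonds[abs(hbonds$donor - hbonds$acceptor) >= 3L, , drop = FALSE]
  if (!nrow(hb)) return(list())
  mk_groups <- function(key) {
    # an ideal ladder conserves its register key (donor + acceptor for
    # antiparallel, donor - acceptor for parallel) across all its bonds
    ord <- order(key, pmin(hb$donor, hb$acceptor))
    ks <- key[ord]
    grp <- cumsum(c(1L, diff(ks) > 0L))
    split(ord, grp)
  }
  segs <- list()
  collect <- function(idx, orientation) {
    if (length(idx) < min_ladder) return()
    b <- hb[idx, , drop = FALSE]
    lo <- pmin(b$donor, b$acceptor); hi <- pmax(b$donor, b$acceptor)
    # consecutive along both strands: neighbouring bonds shift by <= 2
    o <- order(lo)
    b <- b[o, ]; lo <- lo[o]; hi <- hi[o]
    brk <- cumsum(c(1L, diff(lo) > 2L))
    for (g in split(seq_len(nrow(b)), brk)) {
      if (length(g) < min_ladder) next
      segs[[length(segs) + 1L]] <<- structure(list(
        orientation = orientation,
        bonds = b[g, c("donor", "acceptor")],
        strand_a = range(lo[g]), strand_b = range(hi[g]),
        n_bonds = length(g)), class = "beta_segment")
    }
  }
  for (idx in mk_groups(hb$donor + hb$acceptor)) collect(idx, "antiparallel")
  anti_used <- unlist(lapply(segs, function(s) rownames(s$bonds)))
  rest <- setdiff(rownames(hb), anti_used)
  if (length(rest)) {
    hb2 <- hb[rest, , drop = FALSE]
    key2 <- hb2$donor - hb2$acceptor
    ord <- order(key2, pmin(hb2$donor, hb2$acceptor))
    ks <- key2[ord]
    grp <- cumsum(c(1L, diff(ks) > 0L))
    for (idx in split(ord, grp)) {
      if (length(idx) < min_ladder) next
      b <- hb2[idx, , drop = FALSE]
      lo <- pmin(b$donor, b$acceptor); hi <- pmax(b$donor, b$acceptor)
      o <- order(lo); b <- b[o, ]; lo <- lo[o]; hi <- hi[o]
      brk <- cumsum(c(1L, diff(lo) > 2L))
      for (g in split(seq_len(nrow(b)), brk)) {
        if (length(g) < min_ladder) next
        segs[[length(segs) + 1L]] <- structure(list(
          orientation = "parallel",
          bonds = b[g, c("donor", "acceptor")],
          strand_a = range(lo[g]), strand_b = range(hi[g]),
          n_bonds = length(g)), class = "beta_segment")
      }
    }
  }
  segs
}

#' Backbone dihedrals of a structure or trajectory
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1).
#' Terminal residues (missing a neighbour) are skipped.
#'
#' @param x a `peptide_structure` or `peptide_trajectory`.
#' @return data.frame with columns `frame`, `residue_index`,
#'   `residue_name`, `phi`, `psi` (degrees).
#' @export
phi_psi <- function(x) {
  frames <- if (inherits(x, "peptide_trajectory"))
    lapply(seq_len(n_frames(x)), function(i) get_frame(x, i))
  else list(x)
  out <- list()
  for (f in seq_along(frames)) {
    st <- frames[[f]]
    resids <- sort(unique(st$atoms$residue_index))
    if (length(resids) < 3L)
      stop_looplab("looplab_topology_error", "need >= 1 internal residue")
    for (k in seq_along(resids)) {
      if (k == 1L || k == length(resids)) next
      r <- resids[k]
      Cp <- res_atom(st, resids[k - 1L], "C")
      N <- res_atom(st, r, "N"); CA <- res_atom(st, r, "CA")
      C <- res_atom(st, r, "C"); Nn <- res_atom(st, resids[k + 1L], "N")
      if (is.null(Cp) || is.null(N) || is.null(CA) || is.null(C) || is.null(Nn))
        stop_looplab("looplab_topology_error",
                     "residue %d lacks backbone atoms for dihedrals", r)
      out[[length(out) + 1L]] <- data.frame(
        frame = f, residue_index = r,
        residue_name = st$atoms$residue_name[st$atoms$residue_index == r][1L],
        phi = dihedral_angle(Cp, N, CA, C),
        psi = dihedral_angle(N, CA, C, Nn))
    }
  }
  do.call(rbind, out)
}

#' Ramachandran histogram and named region occupancies
#'
#' Bins (phi, psi) pairs of non-glycine residues and reports the fraction
#' falling in rectangular regions of +/- `half_width` degrees around the
#' beta-sheet center (-135, 135) and the polyproline-II center (-75, 140),
#' plus the `other` remainder. Rectangles wrap across the +/-180 seam.
#'
#' @param dihedrals data.frame from [phi_psi()].
#' @param bin_width histogram bin width (degrees, default 10).
#' @param half_width half-width of the named rectangles (degrees, default 30).
#' @param exclude_glycine drop GLY residues from the statistics (default
#'   TRUE, glycine's achiral backbone floods the plot).
#' @return object of class `rama_histogram`: `counts` (matrix), `breaks`,
#'   `fractions` (named: beta, ppii, other), `n`.
#' @export
rama_histogram <- function(dihedrals, bin_width = 10, half_width = 30,
                           exclude_glycine = TRUE) {
  d <- dihedrals
  if (exclude_glycine) d <- d[d$residue_name != "GLY", , drop = FALSE]
  if (!nrow(d))
    stop_looplab("looplab_input_error", "no (non-glycine) residues to bin")
  breaks <- seq(-180, 180, by = bin_width)
  ix <- findInterval(d$phi, breaks, rightmost.closed = TRUE)
  iy <- findInterval(d$psi, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1L
  counts <- matrix(0L, nb, nb)
  for (i in seq_len(nrow(d))) counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1L
  in_rect <- function(phi0, psi0) {
    wrap <- function(a) ((a + 180) %% 360) - 180
    dphi <- abs(wrap(d$phi - phi0)); dpsi <- abs(wrap(d$psi - psi0))
    dphi <= half_width & dpsi <= half_width
  }
  beta <- in_rect(-135, 135); ppii <- in_rect(-75, 140)
  fr <- c(beta = mean(beta & !ppii) + mean(beta & ppii) / 2,
          ppii = mean(ppii & !beta) + mean(beta & ppii) / 2)
  fr["other"] <- 1 - sum(fr)
  structure(list(counts = counts, breaks = breaks, fractions = fr,
                 n = nrow(d), bin_width = bin_width, half_width = half_width),
            class = "rama_histogram")
}

#' @rdname rama_histogram
#' @param hist a `rama_histogram`.
#' @export
region_fractions <- function(hist) {
  stopifnot(inherits(hist, "rama_histogram"))
  hist$fractions
}

#' Per-frame hydrogen-bond existence matrix of a trajectory
#'
#' Runs [detect_hbonds()] on every frame and assembles the union of
#' observed bonds into a frames x bonds existence matrix, with per-bond
#' labels marking membership in a beta segment in any frame (`in_beta`).
#'
#' @param traj a `peptide_trajectory`.
#' @param criterion passed to [detect_hbonds()].
#' @param min_sep passed to [detect_hbonds()].
#' @return an `hbond_matrix` with `labels` attribute and bond names
#'   `"donor>acceptor"`.
#' @export
hbond_existence_matrix <- function(traj, criterion = "kabsch_sander",
                                   min_sep = 2L) {
  stopifnot(inherits(traj, "peptide_trajectory"))
  nf <- n_frames(traj)
  per_frame <- vector("list", nf)
  seg_bonds <- character(0)
  for (m in seq_len(nf)) {
    hb <- detect_hbonds(get_frame(traj, m), criterion, min_sep = min_sep)
    per_frame[[m]] <- hb
    for (s in beta_segments(hb))
      seg_bonds <- union(seg_bonds,
                         paste0(s$bonds$donor, ">", s$bonds$acceptor))
  }
  keys <- unique(unlist(lapply(per_frame, function(hb)
    if (nrow(hb)) paste0(hb$donor, ">", hb$acceptor) else character(0))))
  if (!length(keys))
    stop_looplab("looplab_input_error", "no hydrogen bonds observed")
  h <- matrix(0L, nf, length(keys), dimnames = list(NULL, keys))
  for (m in seq_len(nf)) {
    hb <- per_frame[[m]]
    if (nrow(hb)) h[m, paste0(hb$donor, ">", hb$acceptor)] <- 1L
  }
  hbond_matrix(h, dt = traj$dt,
               labels = ifelse(keys %in% seg_bonds, "in_beta", "not_in_beta"))
}

#' Structural statistics of the open-state ensemble
#'
#' Restricted to frames labelled open (state 1): the fraction carrying at
#' least one intra-backbone hydrogen bond, the fraction carrying at least
#' one beta segment, and the mean hydrogen-bond count. Pure per-frame set
#' statistics: invariant under frame reordering.
#'
#' @param traj a `peptide_trajectory`.
#' @param states a [state_series()] aligned frame-by-frame with `traj`.
#' @param criterion passed to [detect_hbonds()].
#' @return list: `n_open`, `fraction_with_hbond`, `fraction_with_beta`,
#'   `mean_hbond_count`.
#' @export
open_state_structure_stats <- function(traj, states,
                                       criterion = "kabsch_sander") {
  stopifnot(inherits(traj, "peptide_trajectory"),
            inherits(states, "state_series"))
  if (length(states$states) != n_frames(traj))
    stop_looplab("looplab_input_error",
                 "states (%d) and trajectory (%d frames) are not aligned",
                 length(states$states), n_frames(traj))
  open <- which(states$states == 1L)
  if (!length(open))
    stop_looplab("looplab_empty_state_error", "no open frames")
  nhb <- integer(length(open)); nbeta <- integer(length(open))
  for (k in seq_along(open)) {
    hb <- detect_hbonds(get_frame(traj, open[k]), criterion)
    nhb[k] <- nrow(hb)
    nbeta[k] <- length(beta_segments(hb))
  }
  list(n_open = length(open),
       fraction_with_hbond = mean(nhb > 0),
       fraction_with_beta = mean(nbeta > 0),
       mean_hbond_count = mean(nhb))
}
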