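# Ideal backbone geometry construction.
#
# Internal coordinates (lengths in nm, angles in degrees) follow standard
# peptide covalent geometry; atoms are placed sequentially with the
# natural-extension reference frame (NeRF) construction.

.bb <- list(
  b_N_CA = 0.1458, b_CA_C = 0.1525, b_C_N = 0.1329, b_C_O = 0.1231,
  b_N_H = 0.101,
  a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7,
  a_CA_C_O = 120.8, a_C_N_H = 119.2, omega = 180)

# place atom D given A-B-C, bond |CD|, angle B-C-D, dihedral A-B-C-D (deg)
nerf_place <- function(A, B, C, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- -dihedral * pi / 180  # sign fixed so measured A-B-C-D equals the request
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- pracma_cross(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) {  # collinear reference: pick any perpendicular
    ref <- if (abs(bc[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- pracma_cross(ref, bc); nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  C + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

pracma_cross <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Measure the dihedral angle of four points
#' @param p1,p2,p3,p4 length-3 coordinate vectors (nm).
#' @return signed dihedral in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  a <- atan2(y, x) * 180 / pi
  if (a <= -180) a + 360 else a
}

# build backbone coordinates for given per-residue (phi, psi); omega = 180.
# Returns a list of named atom coordinate matrices per residue.
build_backbone <- function(phi, psi, sequence) {
  n <- length(phi)
  g <- .bb
  res <- vector("list", n)
  # seed residue 1: N at origin, CA along x, C in the xy-plane
  N1 <- c(0, 0, 0)
  CA1 <- c(g$b_N_CA, 0, 0)
  a <- g$a_N_CA_C * pi / 180
  C1 <- CA1 + g$b_CA_C * c(cos(pi - a), sin(pi - a), 0)
  res[[1L]] <- list(N = N1, CA = CA1, C = C1)
  for (i in 2:n) {
    prev <- res[[i - 1L]]
    Ni <- nerf_place(prev$N, prev$CA, prev$C, g$b_C_N, g$a_CA_C_N, psi[i - 1L])
    CAi <- nerf_place(prev$CA, prev$C, Ni, g$b_N_CA, g$a_C_N_CA, g$omega)
    Hi <- nerf_place(prev$CA, prev$C, Ni, g$b_N_H, g$a_C_N_H, 0)
    Ci <- nerf_place(prev$C, Ni, CAi, g$b_CA_C, g$a_N_CA_C, phi[i])
    res[[i]] <- list(N = Ni, H = Hi, CA = CAi, C = Ci)
    # carbonyl O of residue i-1: anti to the new N across the C(i-1) plane
    res[[i - 1L]]$O <- nerf_place(prev$N, prev$CA, prev$C, g$b_C_O,
                                  g$a_CA_C_O, psi[i - 1L] - 180)
  }
  # terminal carbonyl: use the residue's own psi convention
  last <- res[[n]]
  res[[n]]$O <- nerf_place(last$N, last$CA, last$C, g$b_C_O, g$a_CA_C_O,
                           psi[n] - 180)
  res
}

backbone_to_structure <- function(res, sequence) {
  n <- length(res)
  three <- c(G = "GLY", S = "SER", A = "ALA")
  rows <- list()
  for (i in seq_len(n)) {
    rn <- three[[substr(sequence, i, i)]] %||% "GLY"
    for (nm in c("N", "H", "CA", "C", "O")) {
      p <- res[[i]][[nm]]
      if (is.null(p)) next
      rows[[length(rows) + 1L]] <- data.frame(
        atom_name = nm, element = substr(nm, 1L, 1L),
        residue_index = i, residue_name = rn, chain_id = "A",
        x = p[1L], y = p[2L], z = p[3L], stringsAsFactors = FALSE)
    }
  }
  structure_from_atoms(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_gs_sequence <- function(n) {
  paste(rep_len(c("G", "S"), n), collapse = "")
}

#' Build an ideal peptide backbone geometry
#'
#' Constructs an all-backbone-atom (N, H, CA, C, O) peptide with standard
#' covalent geometry and the requested backbone dihedrals at every
#' non-terminal residue. Kinds:
#' \describe{
#' \item{`extended`}{phi = psi = 180 degrees.}
#' \item{`custom_phi_psi`}{uniform user-supplied (phi, psi); use
#'   (-75, 140) for polyproline II.}
#' \item{`beta_hairpin`}{two antiparallel strands joined by an ideal
#'   two-residue type-I' turn; the four turn dihedrals are numerically
#'   refined so the flanking rungs of the inter-strand hydrogen-bond
#'   ladder satisfy the Kabsch-Sander energy criterion.}
#' }
#'
#' @param kind `"extended"`, `"custom_phi_psi"` or `"beta_hairpin"`.
#' @param n_residues number of residues (>= 2; >= 8 and even for a
#'   hairpin).
#' @param phi,psi dihedrals in degrees, in `[-180, 180]`
#'   (`custom_phi_psi` only).
#' @param sequence one-letter residue string; default alternating G/S.
#' @return a `peptide_structure`.
#' @examples
#' ppii <- build_ideal_geometry("custom_phi_psi", 6, phi = -75, psi = 140)
#' @export
build_ideal_geometry <- function(kind = c("extended", "custom_phi_psi",
                                          "beta_hairpin"),
                                 n_residues, phi = NULL, psi = NULL,
                                 sequence = NULL) {
  kind <- match.arg(kind)
  check_count(n_residues, "n_residues", min = 2L)
  if (is.null(sequence)) sequence <- default_gs_sequence(n_residues)
  if (nchar(sequence) != n_residues)
    stop_looplab("looplab_parameter_error", "sequence length != n_residues")
  if (kind == "extended") { phi <- 180; psi <- 180; kind <- "custom_phi_psi" }
  if (kind == "custom_phi_psi") {
    check_number(phi, "phi"); check_number(psi, "psi")
    if (abs(phi) > 180 || abs(psi) > 180)
      stop_looplab("looplab_parameter_error", "angles must be in [-180, 180]")
    res <- build_backbone(rep(phi, n_residues), rep(psi, n_residues), sequence)
    st <- backbone_to_structure(res, sequence)
    check_self_intersection(st)
    return(st)
  }
  build_beta_hairpin(n_residues, sequence)
}

check_self_intersection <- function(st, tol = 0.05) {
  # non-bonded heavy atoms closer than tol nm indicate an impossible request
  a <- st$atoms[st$atoms$element != "H", ]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  sep <- abs(outer(a$residue_index, a$residue_index, "-"))
  bad <- d < tol & sep >= 2
  diag(bad) <- FALSE
  if (any(bad))
    stop_looplab("looplab_geometry_error",
                 "backbone self-intersection beyond tolerance (%g nm)", tol)
  invisible(st)
}

# hairpin: strands with ideal antiparallel-sheet dihedrals, type-I' turn,
# turn-flank dihedrals refined against the Kabsch-Sander ladder energies.
build_beta_hairpin <- function(n_residues, sequence) {
  if (n_residues < 8L || n_residues %% 2L != 0L)
    stop_looplab("looplab_parameter_error",
                 "a hairpin needs an even n_residues >= 8")
  h <- (n_residues - 2L) %/% 2L  # last residue of strand A
  strand <- c(-139, 135)
  turn <- c(60, 30, 90, 0)       # type I': (phi,psi) of the two turn residues
  make <- function(par) {
    phi <- rep(strand[1L], n_residues)
    psi <- rep(strand[2L], n_residues)
    psi[h] <- par[1L]
    phi[h + 1L] <- par[2L]; psi[h + 1L] <- par[3L]
    phi[h + 2L] <- par[4L]; psi[h + 2L] <- par[5L]
    phi[h + 3L] <- par[6L]
    build_backbone(phi, psi, sequence)
  }
  # intended antiparallel register: residue i pairs with n+1-i
  rungs <- lapply(seq(h, 1L, by = -2L), function(i) c(i, n_residues + 1L - i))
  # Kabsch-Sander energy straight from the coordinate list, clipped from
  # below: the raw 1/r form is unbounded and would reward atom collapse
  ks_raw <- function(res, dres, ares) {
    N <- res[[dres]]$N; H <- res[[dres]]$H
    C <- res[[ares]]$C; O <- res[[ares]]$O
    if (is.null(H)) return(0)
    d <- function(a, b) max(sqrt(sum((a - b)^2)) * 10, 0.5)
    e <- 0.084 * 332 * (1 / d(O, N) + 1 / d(C, H) - 1 / d(O, H) - 1 / d(C, N))
    max(e, -4)
  }
  objective <- function(par) {
    res <- make(par)
    e <- 0
    for (rg in rungs) {
      i <- rg[1L]; j <- rg[2L]
      e <- e + ks_raw(res, j, i) + ks_raw(res, i, j)
    }
    # soft steric guard on CA-CA overlaps
    ca <- t(vapply(res, `[[`, numeric(3L), "CA"))
    d <- dist(ca)
    e + sum(pmax(0, 0.35 - d)^2) * 1e4
  }
  start <- c(135, turn, -139)
  opt <- optim(start, objective, method = "Nelder-Mead",
               control = list(maxit = 600, reltol = 1e-8))
  st <- backbone_to_structure(make(opt$par), sequence)
  check_self_intersection(st)
  st
}
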