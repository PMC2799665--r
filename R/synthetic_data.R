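#' Simulate a two-state telegraph (open/closed) signal
#'
#' Continuous-time two-state Markov process with exponential dwell times,
#' sampled onto a uniform grid. Dwell times are drawn exactly (per-state
#' exponential variates) and then the process is point-sampled at multiples
#' of `dt`, so short-dwell statistics are not biased by per-step flip
#' approximations even when the mean dwell approaches `dt`.
#'
#' State coding follows the fluorescence convention: 1 = open/fluorescent,
#' 0 = closed/quenched. `k_close` is the open -> closed rate (the reciprocal
#' mean closing time), `k_open` the closed -> open rate.
#'
#' @param k_close,k_open transition rates (1/ns); at least one must be > 0,
#'   none negative.
#' @param dt sampling interval (ns).
#' @param n_steps number of samples (>= 2).
#' @param seed integer seed; fixed seed gives identical output.
#' @param initial_state `"stationary"` (default, drawn from the stationary
#'   distribution), `"open"`, or `"closed"`.
#' @return a `state_series` object (see [state_series()]).
#' @examples
#' s <- gen_telegraph(k_close = 1/50, k_open = 1/80, dt = 0.1,
#'                    n_steps = 1e5, seed = 1)
#' mean(s$states)  # ~ k_open / (k_close + k_open)
#' @export
gen_telegraph <- function(k_close, k_open, dt, n_steps, seed = NULL,
                          initial_state = c("stationary", "open", "closed")) {
  check_number(k_close, "k_close", nonneg = TRUE)
  check_number(k_open, "k_open", nonneg = TRUE)
  if (k_close <= 0 && k_open <= 0)
    stop_looplab("looplab_parameter_error", "at least one rate must be > 0")
  check_number(dt, "dt", positive = TRUE)
  check_count(n_steps, "n_steps", min = 2L)
  initial_state <- match.arg(initial_state)
  if (!is.null(seed)) set.seed(seed)

  p_open <- if (k_close + k_open > 0) k_open / (k_close + k_open) else 0.5
  s0 <- switch(initial_state,
               stationary = as.integer(runif(1L) < p_open),
               open = 1L, closed = 0L)

  total <- n_steps * dt
  # alternate exponential dwells until the record is covered
  sw <- numeric(0)  # switch times
  t_acc <- 0; s <- s0
  # grow in chunks to avoid a slow one-by-one loop
  while (t_acc < total) {
    n_chunk <- max(64L, ceiling((total - t_acc) *
                                  (k_close * p_open + k_open * (1 - p_open)) * 1.2))
    rate_seq <- if (s == 1L) rep_len(c(k_close, k_open), n_chunk)
                else rep_len(c(k_open, k_close), n_chunk)
    if (any(rate_seq == 0)) {
      # absorbing state: first zero-rate dwell never ends
      i0 <- which(rate_seq == 0)[1L]
      if (i0 == 1L) break
      rate_seq <- rate_seq[seq_len(i0 - 1L)]
      d <- rexp(length(rate_seq), rate_seq)
      sw <- c(sw, t_acc + cumsum(d))
      t_acc <- Inf  # after entering the absorbing state nothing switches
      break
    }
    d <- rexp(n_chunk, rate_seq)
    sw <- c(sw, t_acc + cumsum(d))
    t_acc <- sw[length(sw)]
    s <- if ((length(sw)) %% 2L == 0L) s0 else 1L - s0
  }
  tgrid <- (seq_len(n_steps) - 1) * dt
  parity <- findInterval(tgrid, sw) %% 2L
  states <- if (s0 == 1L) 1L - parity else parity
  state_series(states, dt = dt,
               group_spec = sprintf("telegraph k_close=%g k_open=%g", k_close, k_open))
}

#' Simulate independent on/off hydrogen-bond existence series
#'
#' Each bond is an independent two-state Markov process: intact (1) breaks
#' with rate `k_break`, broken (0) reforms with rate `k_reform`. Dwell times
#' are sampled exactly as in [gen_telegraph()]; each bond gets its own
#' child seed derived from `seed`.
#'
#' @param k_break,k_reform rates (1/ns), non-negative, not both zero.
#' @param n_bonds number of bonds (>= 1).
#' @param dt sampling interval (ns).
#' @param n_steps samples per bond (>= 2).
#' @param seed master integer seed.
#' @param initial_state passed to each bond's telegraph
#'   (`"stationary"`, `"open"` = intact, `"closed"` = broken).
#' @return an `hbond_matrix`: integer matrix `n_steps x n_bonds` with
#'   attributes `dt` (ns) and class `"hbond_matrix"`.
#' @export
gen_hbond_series <- function(k_break, k_reform, n_bonds, dt, n_steps,
                             seed = NULL,
                             initial_state = c("stationary", "open", "closed")) {
  check_count(n_bonds, "n_bonds", min = 1L)
  initial_state <- match.arg(initial_state)
  seeds <- child_seeds(seed, n_bonds)
  h <- matrix(0L, nrow = n_steps, ncol = n_bonds)
  for (b in seq_len(n_bonds)) {
    # intact plays the role of "open": it ends with rate k_break
    s <- gen_telegraph(k_close = k_break, k_open = k_reform, dt = dt,
                       n_steps = n_steps, seed = seeds[[b]],
                       initial_state = initial_state)
    h[, b] <- s$states
  }
  hbond_matrix(h, dt = dt)
}

#' Construct a hydrogen-bond existence matrix
#' @param h integer 0/1 matrix, frames in rows, bonds in columns.
#' @param dt frame spacing (ns).
#' @param labels optional per-bond grouping labels (e.g. in-beta vs not).
#' @return classed matrix for [hbond_existence_autocorrelation()].
#' @export
hbond_matrix <- function(h, dt, labels = NULL) {
  h <- as.matrix(h)
  if (!all(h %in% c(0L, 1L)))
    stop_looplab("looplab_parameter_error", "existence matrix must be 0/1")
  check_number(dt, "dt", positive = TRUE)
  if (!is.null(labels) && length(labels) != ncol(h))
    stop_looplab("looplab_parameter_error", "one label per bond required")
  structure(h, dt = dt, labels = labels,
            class = c("hbond_matrix", class(h)))
}

#' Simulate an overdamped bead-spring chain and its end-to-end distance
#'
#' Brownian (position-Langevin) dynamics of a linear bead-spring chain, one
#' bead per residue, in the nm / ps / kJ/mol unit system with
#' `kB = 0.0083145` kJ/mol/K. Beads carry unit mass, so `friction` (1/ps)
#' equals the friction coefficient and the free-bead diffusion constant is
#' `kB*T/friction` (nm^2/ps). Optional terms: bending stiffness, a smooth
#' short-range pairwise attraction between beads at least 3 apart in
#' sequence (a minimal, non-directional surrogate for intra-backbone
#' hydrogen bonding), and a soft-core excluded volume. With all optional
#' terms zero the chain is an ideal (phantom) freely jointed chain with
#' near-rigid bonds.
#'
#' @param n_beads number of beads (>= 3).
#' @param bond_length equilibrium bond length b (nm).
#' @param bond_stiffness harmonic bond constant (kJ/mol/nm^2).
#' @param bending_stiffness bending constant (kJ/mol); 0 = freely jointed.
#' @param attraction_eps depth of the short-range intra-chain attraction
#'   (kJ/mol); 0 disables it (the "no hydrogen bonds" analog).
#' @param attraction_range range of the attraction well (nm).
#' @param excluded_volume_sigma soft-core diameter (nm); 0 = phantom chain.
#' @param temperature K.
#' @param friction 1/ps.
#' @param dt integration time step (ps).
#' @param n_steps number of integration steps.
#' @param seed integer seed.
#' @param distance_stride record the end-to-end distance every this many
#'   steps (default 10).
#' @param frame_stride record full frames every this many steps; 0 (default)
#'   records no frames.
#' @param equilibration_steps steps discarded before recording (default
#'   `n_steps %/% 10`).
#' @return list with `distances` (a [time_series()], nm vs ns),
#'   `trajectory` (a `peptide_trajectory` of CA-like beads, or `NULL`),
#'   and `params` (the echoed parameter list).
#' @export
gen_chain_trajectory <- function(n_beads, bond_length = 0.38,
                                 bond_stiffness = 8000, bending_stiffness = 0,
                                 attraction_eps = 0, attraction_range = 0.5,
                                 excluded_volume_sigma = 0,
                                 temperature = 293, friction = 500,
                                 dt = 0.01, n_steps = 1e5, seed = NULL,
                                 distance_stride = 10L, frame_stride = 0L,
                                 equilibration_steps = NULL) {
  check_count(n_beads, "n_beads", min = 3L)
  check_number(bond_length, "bond_length", positive = TRUE)
  check_number(bond_stiffness, "bond_stiffness", positive = TRUE)
  check_number(bending_stiffness, "bending_stiffness", nonneg = TRUE)
  check_number(attraction_eps, "attraction_eps", nonneg = TRUE)
  check_number(attraction_range, "attraction_range", positive = TRUE)
  check_number(excluded_volume_sigma, "excluded_volume_sigma", nonneg = TRUE)
  check_number(temperature, "temperature", nonneg = TRUE)
  check_number(friction, "friction", positive = TRUE)
  check_number(dt, "dt", positive = TRUE)
  check_count(n_steps, "n_steps", min = 1L)
  if (is.null(equilibration_steps)) equilibration_steps <- n_steps %/% 10L
  if (!is.null(seed)) set.seed(seed)

  # initial condition: random walk with the equilibrium bond length
  x0 <- matrix(0, n_beads, 3L)
  for (i in 2:n_beads) {
    v <- rnorm(3L)
    x0[i, ] <- x0[i - 1L, ] + bond_length * v / sqrt(sum(v * v))
  }

  rng_seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  if (equilibration_steps > 0L) {
    eq <- langevin_chain_cpp(n_beads, bond_length, bond_stiffness,
                             bending_stiffness, attraction_eps,
                             attraction_range, excluded_volume_sigma,
                             temperature, friction, dt,
                             as.numeric(equilibration_steps),
                             as.integer(equilibration_steps), 0L, x0,
                             as.numeric(rng_seeds[1L]))
    x0 <- eq$x_final
  }
  out <- langevin_chain_cpp(n_beads, bond_length, bond_stiffness,
                            bending_stiffness, attraction_eps,
                            attraction_range, excluded_volume_sigma,
                            temperature, friction, dt, as.numeric(n_steps),
                            as.integer(distance_stride),
                            as.integer(frame_stride), x0,
                            as.numeric(rng_seeds[2L]))
  dt_ns <- dt * distance_stride * 1e-3  # ps -> ns
  distances <- time_series(out$end_to_end, dt = dt_ns,
                           label = "end_to_end_distance", units = "nm")
  traj <- NULL
  if (frame_stride > 0L && out$n_frames >= 1) {
    topo <- data.frame(atom_name = "CA", element = "C",
                       residue_index = seq_len(n_beads),
                       residue_name = "GLY", chain_id = "A",
                       stringsAsFactors = FALSE)
    nf <- as.integer(out$n_frames)
    # frames rows are bead-major: (x1,y1,z1,x2,y2,z2,...)
    coords <- array(0, dim = c(nf, n_beads, 3L))
    for (m in seq_len(nf))
      coords[m, , ] <- matrix(out$frames[m, ], ncol = 3L, byrow = TRUE)
    topo$x <- coords[1L, , 1L]; topo$y <- coords[1L, , 2L]; topo$z <- coords[1L, , 3L]
    traj <- trajectory(structure_from_atoms(topo),
                       dt = dt * frame_stride * 1e-3, coords = coords)
  }
  params <- list(n_beads = n_beads, bond_length = bond_length,
                 bond_stiffness = bond_stiffness,
                 bending_stiffness = bending_stiffness,
                 attraction_eps = attraction_eps,
                 attraction_range = attraction_range,
                 excluded_volume_sigma = excluded_volume_sigma,
                 temperature = temperature, friction = friction, dt = dt,
                 n_steps = n_steps, seed = seed,
                 note = paste("coarse-grained statistical surrogate;",
                              "all defaults are package choices, not",
                              "derived from any atomistic force field"))
  list(distances = distances, trajectory = traj, params = params)
}

#' Echo generator parameters to a JSON sidecar
#' @param params parameter list (e.g. `gen_chain_trajectory()$params`).
#' @param path output path for the JSON file.
#' @return `path` invisibly.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
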