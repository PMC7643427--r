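#' Configuration of the coarse-grained chromosome-arm simulation
#'
#' Parameters of a bead-spring chain evolved by overdamped Langevin
#' (Brownian) dynamics with Euler integration.  The default chain — 2436
#' beads of 25 nm radius, one bead per 10 nucleosomes, confined to a
#' 4.5 um sphere — represents a 3.6 Mb fission yeast chromosome arm;
#' the sphere is large enough that confinement barely constrains the
#' chain.  Excluded volume is a constant-magnitude repulsion applied to
#' overlapping bead pairs, so beads can partially ingress into each
#' other (a bead stands for a stretch of chain, not a rigid body).
#'
#' Lengths are micrometres.  Time is in simulation units: the thermal
#' energy `kT` and friction `zeta` set the free-bead diffusion
#' coefficient `D = kT/zeta` (um^2 per time unit), and all delays scale
#' with it.  MSD exponents — the quantity of interest — are independent
#' of the time mapping.  Remaining defaults: the bond rest length equals
#' the bead diameter; the bond stiffness puts the bond-length standard
#' deviation near 10% of the rest length; the repulsion force allows
#' overlaps of roughly 20% of the bead radius at steady state; the time
#' step keeps the RMS Euler step a small fraction of the bead radius.
#'
#' @param n_beads chain length (default 2436; 400-600 is typical for
#'   desk-scale runs).
#' @param bead_radius um (default 0.025).
#' @param nucleosomes_per_bead bookkeeping only (default 10).
#' @param confinement_radius um (default 4.5).
#' @param bond_rest_length um (default one bead diameter).
#' @param bond_stiffness spring constant, force per unit length.
#' @param repulsion_force constant repulsion magnitude on overlap.
#' @param confinement_force constant inward radial force outside sphere.
#' @param friction drag coefficient zeta.
#' @param kT thermal energy scale.
#' @param dt integration time step (simulation time units).
#' @param n_steps sampled steps after equilibration.
#' @param equilibration_steps steps discarded before sampling.
#' @param sampling_stride record positions every this many steps.
#' @param excluded_volume,confinement logical switches.
#' @param reflect_boundary use radial reflection instead of the inward
#'   constant force.
#' @param track_fraction central fraction of the chain exported as
#'   tracks (default 0.5: the middle 50%, away from the free ends).
#' @param seed integer seed used by [run_simulation()] and
#'   [initialize_chain()].
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_beads = 2436L, bead_radius = 0.025,
                       nucleosomes_per_bead = 10L,
                       confinement_radius = 4.5,
                       bond_rest_length = 2 * bead_radius,
                       bond_stiffness = 100,
                       repulsion_force = 1,
                       confinement_force = 1,
                       friction = 1, kT = 0.0025,
                       dt = 0.002, n_steps = 50000L,
                       equilibration_steps = 10000L,
                       sampling_stride = 25L,
                       excluded_volume = TRUE, confinement = TRUE,
                       reflect_boundary = FALSE,
                       track_fraction = 0.5, seed = 1L) {
  cfg <- list(n_beads = as.integer(n_beads), bead_radius = bead_radius,
              nucleosomes_per_bead = as.integer(nucleosomes_per_bead),
              confinement_radius = confinement_radius,
              bond_rest_length = bond_rest_length,
              bond_stiffness = bond_stiffness,
              repulsion_force = repulsion_force,
              confinement_force = confinement_force,
              friction = friction, kT = kT, dt = dt,
              n_steps = as.integer(n_steps),
              equilibration_steps = as.integer(equilibration_steps),
              sampling_stride = as.integer(sampling_stride),
              excluded_volume = isTRUE(excluded_volume),
              confinement = isTRUE(confinement),
              reflect_boundary = isTRUE(reflect_boundary),
              track_fraction = track_fraction, seed = as.integer(seed))
  with(cfg, {
    if (n_beads < 2L) stop("n_beads must be at least 2")
    if (any(c(bead_radius, confinement_radius, bond_rest_length, dt,
              friction) <= 0)) stop("lengths, dt and friction must be positive")
    if (kT < 0) stop("kT must be non-negative")
    if (sampling_stride < 1L) stop("sampling_stride must be >= 1")
    if (track_fraction <= 0 || track_fraction > 1)
      stop("track_fraction must be in (0, 1]")
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Read or write a simulation configuration file
#'
#' Plain `key = value` text, one parameter per line; unknown keys error.
#' @param path file path.
#' @param cfg a `sim_config`.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  known <- names(formals(sim_config))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- lapply(vals, function(v) {
    if (v %in% c("TRUE", "FALSE", "true", "false"))
      as.logical(toupper(v)) else as.numeric(v)
  })
  names(args) <- keys
  do.call(sim_config, args)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, format, character(1))), path)
  invisible(path)
}

#' Initial chain conformation
#'
#' A self-avoiding-biased random walk with step length equal to the bond
#' rest length, grown inside the confinement sphere: each proposed bead
#' must lie in the sphere and (when excluded volume is on) at least one
#' bead diameter from the previous few beads; after a bounded number of
#' failed proposals the constraint is relaxed so that growth always
#' terminates.  Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return n_beads x 3 matrix of positions (um).
#' @export
initialize_chain <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_beads
  b0 <- config$bond_rest_length
  R <- config$confinement_radius
  if (config$confinement && b0 > 2 * R)
    stop("confinement sphere too small for the bond length")
  pos <- matrix(0, n, 3)
  # expected random-walk extent must fit the sphere comfortably
  if (config$confinement && b0 * sqrt(n) > 20 * R)
    stop("confinement sphere too small to hold the chain")
  lookback <- 10L
  avoid2 <- (2 * config$bead_radius)^2
  for (i in 2:n) {
    placed <- FALSE
    for (try in 1:50) {
      u <- stats::rnorm(3)
      cand <- pos[i - 1, ] + b0 * u / sqrt(sum(u^2))
      if (config$confinement && sum(cand^2) > R^2) next
      if (config$excluded_volume) {
        lo <- max(1L, i - 1L - lookback)
        prev <- pos[lo:(i - 2L), , drop = FALSE]
        if (nrow(prev) > 0 &&
            any(rowSums(sweep(prev, 2L, cand)^2) < avoid2)) next
      }
      placed <- TRUE
      break
    }
    if (!placed) {  # relax self-avoidance, keep the sphere constraint
      repeat {
        u <- stats::rnorm(3)
        cand <- pos[i - 1, ] + b0 * u / sqrt(sum(u^2))
        if (!config$confinement || sum(cand^2) <= R^2) break
      }
    }
    pos[i, ] <- cand
  }
  pos
}

#' Run the bead-spring Brownian dynamics simulation
#'
#' Evolves the chain by Euler integration of the overdamped Langevin
#' equation and returns the recorded trajectories of the tracked beads
#' (by default the middle 50% of the chain, away from the free ends) as
#' a 3D [track_set()] whose `dt` is `sampling_stride * dt` simulation
#' time units.  Tracks feed directly into [msd_tracks()] and
#' [fit_exponents()].
#'
#' @param config a [sim_config()].
#' @param state optional starting conformation (matrix from
#'   [initialize_chain()] or a previous run's `final` attribute).
#' @param record_beads optional integer vector of bead indices to
#'   record, overriding `track_fraction`.
#' @return a `track_set` (3D) with attributes `final` (final
#'   conformation) and `config`.
#' @export
run_simulation <- function(config, state = NULL, record_beads = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(state)) state <- initialize_chain(config)
  stopifnot(is.matrix(state), nrow(state) == config$n_beads,
            ncol(state) == 3L)
  if (is.null(record_beads)) {
    n <- config$n_beads
    half <- config$track_fraction / 2
    record_beads <- seq.int(max(1L, ceiling(n * (0.5 - half))),
                            min(n, floor(n * (0.5 + half))))
  }
  set.seed(config$seed + 1L)  # distinct stream from initialization
  res <- bd_integrate(state,
                      n_steps = config$n_steps,
                      equil_steps = config$equilibration_steps,
                      stride = config$sampling_stride,
                      dt = config$dt,
                      k_bond = config$bond_stiffness,
                      b0 = config$bond_rest_length,
                      excluded = config$excluded_volume,
                      f_rep = config$repulsion_force,
                      rep_cutoff = 2 * config$bead_radius,
                      confined = config$confinement,
                      conf_radius = config$confinement_radius,
                      f_conf = config$confinement_force,
                      reflect = config$reflect_boundary,
                      kT = config$kT, zeta = config$friction,
                      max_step = config$bead_radius,
                      record = as.integer(record_beads))
  traj <- res$trajectory
  dt_frame <- config$sampling_stride * config$dt
  tracks <- lapply(seq_along(record_beads), function(r)
    track(paste0("bead", record_beads[r]), traj[, , r], dt = dt_frame))
  ts <- track_set(tracks, condition = if (config$excluded_volume)
    "excluded_volume" else "phantom")
  attr(ts, "final") <- res$final
  attr(ts, "config") <- config
  ts
}

#' Project 3D tracks onto a random plane
#'
#' Orthogonal projection onto a plane through the origin whose normal is
#' drawn uniformly on the sphere (one plane per call, fixed by `seed`),
#' mimicking single-focal-plane imaging of 3D motion.  Output tracks are
#' 2D, in the plane's own orthonormal coordinates.
#'
#' @param ts a 3D `track_set`.
#' @param seed integer seed for the plane orientation.
#' @return a 2D `track_set`; the plane normal is attached as attribute
#'   `normal`.
#' @export
project_to_plane <- function(ts, seed = 1L) {
  stopifnot(inherits(ts, "track_set"))
  if (ts$dim != 3L) stop("tracks must be 3D")
  set.seed(seed)
  nrm <- stats::rnorm(3)
  nrm <- nrm / sqrt(sum(nrm^2))
  # orthonormal in-plane basis
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * nrm) * nrm
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  basis <- cbind(e1, e2)
  tracks <- lapply(ts$tracks, function(tr)
    track(tr$id, tr$positions %*% basis, dt = tr$dt))
  out <- track_set(tracks, condition = ts$condition)
  attr(out, "normal") <- nrm
  out
}
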