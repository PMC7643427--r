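#' Recipe for synthetic subdiffusive trajectories
#'
#' Describes a mixture of trajectory populations.  Each component is a
#' stationary-increment fractional Gaussian motion with Hurst exponent
#' `H = alpha/2`, so the ensemble MSD is exactly
#' `mobility * tau^alpha` (um^2, all axes summed) — the
#' anomalous-diffusion structure the mobility pipeline assumes.
#' Optional localization noise adds an independent Gaussian error to
#' every frame (default 0).
#'
#' @param n_tracks number of tracks.
#' @param n_frames frames per track.
#' @param dt frame interval (s; default 0.02).
#' @param components data.frame with columns `weight`, `alpha`
#'   (0 < alpha < 2) and `mobility` (um^2 s^-alpha, total over axes).
#' @param noise_sd localization noise sd per axis (um, default 0).
#' @param confinement_sd optional stationary sd per axis (um); when set,
#'   increments get an additional mean-reverting drift toward the
#'   origin, so long tracks plateau (approximate for alpha != 1).
#' @param dim 2 or 3 (default 2).
#' @param seed integer seed.
#' @return list of class `"trajectory_recipe"`.
#' @export
trajectory_recipe <- function(n_tracks = 200L, n_frames = 100L, dt = 0.02,
                              components = data.frame(weight = 1,
                                                      alpha = 0.5,
                                                      mobility = 0.01),
                              noise_sd = 0, confinement_sd = NULL,
                              dim = 2L, seed = 1L) {
  stopifnot(all(c("weight", "alpha", "mobility") %in% names(components)))
  if (any(components$weight < 0) || abs(sum(components$weight) - 1) > 1e-8)
    stop("component weights must be non-negative and sum to 1")
  if (any(components$alpha <= 0 | components$alpha >= 2))
    stop("target MSD exponents must lie in (0, 2)")
  if (any(components$mobility <= 0)) stop("mobility scales must be positive")
  structure(list(n_tracks = as.integer(n_tracks),
                 n_frames = as.integer(n_frames), dt = dt,
                 components = components, noise_sd = noise_sd,
                 confinement_sd = confinement_sd, dim = as.integer(dim),
                 seed = as.integer(seed)),
            class = "trajectory_recipe")
}

# Cholesky factor of the fractional-Gaussian-noise covariance for n
# unit-variance increments at Hurst H:
# gamma(k) = (|k+1|^2H - 2|k|^2H + |k-1|^2H) / 2.
fgn_cholesky <- function(n, H) {
  k <- 0:(n - 1)
  g <- (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H)) / 2
  t(chol(stats::toeplitz(g)))
}

#' Generate a synthetic track set
#'
#' Draws each track's component by the recipe weights, builds exact
#' fractional Gaussian increments from the Cholesky factor of their
#' covariance (one factorization per component, reused across tracks
#' and axes), integrates to positions starting at the origin, and adds
#' localization noise.  Bit-reproducible under the recipe seed.
#'
#' @param recipe a [trajectory_recipe()].
#' @return a [track_set()]; each track carries its generating component
#'   index in the id (`t0001.c1`).
#' @export
generate_tracks <- function(recipe) {
  stopifnot(inherits(recipe, "trajectory_recipe"))
  set.seed(recipe$seed)
  comp <- recipe$components
  d <- recipe$dim
  nf <- recipe$n_frames
  ninc <- nf - 1L
  which_comp <- sample.int(nrow(comp), recipe$n_tracks, replace = TRUE,
                           prob = comp$weight)
  chol_cache <- lapply(seq_len(nrow(comp)), function(ci)
    fgn_cholesky(ninc, comp$alpha[ci] / 2))
  phi <- if (!is.null(recipe$confinement_sd))
    exp(-recipe$dt / (2 * recipe$confinement_sd)) else NULL
  tracks <- vector("list", recipe$n_tracks)
  for (t in seq_len(recipe$n_tracks)) {
    ci <- which_comp[t]
    # per-axis increment sd so that summed-axis MSD(tau) = G * tau^alpha
    sd_inc <- sqrt(comp$mobility[ci] / d) * recipe$dt^(comp$alpha[ci] / 2)
    inc <- chol_cache[[ci]] %*% matrix(stats::rnorm(ninc * d), ninc, d)
    inc <- inc * sd_inc
    pos <- rbind(0, apply(inc, 2L, cumsum))
    if (!is.null(phi)) {  # mean-reverting damping toward the origin
      for (f in 2:nf)
        pos[f, ] <- phi * pos[f - 1L, ] + (pos[f, ] - pos[f - 1L, ])
    }
    if (recipe$noise_sd > 0)
      pos <- pos + matrix(stats::rnorm(nf * d, sd = recipe$noise_sd), nf, d)
    tracks[[t]] <- track(sprintf("t%04d.c%d", t, ci), pos, dt = recipe$dt)
  }
  ts <- track_set(tracks, condition = "synthetic")
  attr(ts, "component") <- which_comp
  ts
}

#' Generate confined (mean-reverting) tracks
#'
#' Each axis follows an exact stationary Ornstein-Uhlenbeck process:
#' `x[n+1] = phi x[n] + s sqrt(1 - phi^2) eps`, `phi =
#' exp(-dt/relaxation_time)`, started from the stationary law.  Long
#' tracks have a length of constraint converging to
#' `stationary_sd * sqrt(dim)` and an MSD plateau of
#' `2 * dim * stationary_sd^2`.
#'
#' @param n_tracks,n_frames,dt as in [trajectory_recipe()].
#' @param stationary_sd per-axis stationary sd (um).
#' @param relaxation_time OU relaxation time (s).
#' @param dim 2 or 3.
#' @param seed integer seed.
#' @return a [track_set()].
#' @export
generate_confined_tracks <- function(n_tracks = 50L, n_frames = 200L,
                                     dt = 0.02, stationary_sd = 0.08,
                                     relaxation_time = 0.2, dim = 2L,
                                     seed = 1L) {
  stopifnot(stationary_sd >= 0, relaxation_time > 0)
  set.seed(seed)
  phi <- exp(-dt / relaxation_time)
  innov_sd <- stationary_sd * sqrt(1 - phi^2)
  tracks <- lapply(seq_len(n_tracks), function(t) {
    pos <- matrix(0, n_frames, dim)
    pos[1, ] <- stats::rnorm(dim, sd = stationary_sd)
    if (n_frames > 1L)
      for (f in 2:n_frames)
        pos[f, ] <- phi * pos[f - 1L, ] + stats::rnorm(dim, sd = innov_sd)
    track(sprintf("ou%04d", t), pos, dt = dt)
  })
  track_set(tracks, condition = "confined")
}
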