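#' Per-track mean squared displacement
#'
#' For each delay `tau = k * dt` up to `tau_max`, the MSD of track i is
#' the average of the squared displacements `|r(t + tau) - r(t)|^2` over
#' all `n - k` overlapping frame pairs.  Alongside the mean, the
#' population variance `sigma_i^2(tau)` of those squared displacements
#' and the pair count `N_i(tau)` are retained: both are needed for the
#' exact standard error of the weighted ensemble mean.
#'
#' @param track a [track()].
#' @param tau_max largest delay in seconds (default 0.5 s, beyond which
#'   imaging noise typically dominates single-locus recordings).
#' @return a data.frame of class `"msd_curve"` with columns
#'   `tau`, `msd` (um^2), `var_sq` (um^4), `n_pairs`, and attribute
#'   `track_id`.
#' @examples
#' tr <- track("a", cbind(0:3, 0), dt = 1)
#' msd_track(tr, tau_max = 3)   # ballistic: msd = tau^2
#' @export
msd_track <- function(track, tau_max = 0.5) {
  stopifnot(inherits(track, "track"))
  if (tau_max < track$dt) stop("tau_max must be at least dt")
  n <- n_frames(track)
  kmax <- min(n - 1L, floor(tau_max / track$dt + 1e-9))
  pos <- track$positions
  tau <- msd <- vs <- numeric(kmax)
  np <- integer(kmax)
  for (k in seq_len(kmax)) {
    d <- pos[(k + 1L):n, , drop = FALSE] - pos[1L:(n - k), , drop = FALSE]
    sq <- rowSums(d * d)
    tau[k] <- k * track$dt
    msd[k] <- mean(sq)
    vs[k] <- if (length(sq) > 1L) mean((sq - msd[k])^2) else 0
    np[k] <- length(sq)
  }
  structure(data.frame(tau = tau, msd = msd, var_sq = vs, n_pairs = np),
            class = c("msd_curve", "data.frame"), track_id = track$id)
}

#' @rdname msd_track
#' @param ts a `track_set`.
#' @return `msd_tracks()` returns a list of `msd_curve`s.
#' @export
msd_tracks <- function(ts, tau_max = 0.5) {
  stopifnot(inherits(ts, "track_set"))
  lapply(ts$tracks, msd_track, tau_max = tau_max)
}

#' Weighted ensemble mean MSD with exact standard error
#'
#' Each track's MSD at delay tau is weighted by its displacement count
#' `N_i(tau)`, so the ensemble mean equals the plain average over all
#' individual squared displacements pooled across tracks:
#' \deqn{\langle m(\tau)\rangle = \sum_i N_i m_i / \sum_i N_i.}
#' The variance of that mean is computed exactly from the per-track
#' moments rather than by a weighted-sample-variance heuristic:
#' \deqn{\sigma^2_{\langle m\rangle} = \frac{1}{N}\Big(\frac{1}{N}\sum_i
#'   N_i (m_i^2 + \sigma_i^2) - \langle m\rangle^2\Big),}
#' with `N = sum_i N_i`; the inner bracket is the pooled population
#' variance of all squared displacements.
#'
#' @param curves list of `msd_curve` objects on a common delay grid (the
#'   intersection of grids is used).
#' @return data.frame of class `"mean_msd"`: `tau`, `msd`, `se`,
#'   `n_pairs`, `n_tracks`.
#' @export
weighted_mean_msd <- function(curves) {
  if (inherits(curves, "msd_curve")) curves <- list(curves)
  if (length(curves) == 0L) stop("no MSD curves supplied")
  taus <- Reduce(intersect, lapply(curves, function(cv) cv$tau))
  if (length(taus) == 0L) stop("curves share no common delays")
  taus <- sort(taus)
  out <- lapply(taus, function(tv) {
    mi <- vi <- ni <- numeric(0)
    for (cv in curves) {
      j <- match(tv, cv$tau)
      if (!is.na(j)) {
        mi <- c(mi, cv$msd[j]); vi <- c(vi, cv$var_sq[j])
        ni <- c(ni, cv$n_pairs[j])
      }
    }
    N <- sum(ni)
    m <- sum(ni * mi) / N
    v <- (sum(ni * (mi^2 + vi)) / N - m^2) / N
    c(m, sqrt(max(v, 0)), N, length(mi))
  })
  out <- do.call(rbind, out)
  structure(data.frame(tau = taus, msd = out[, 1], se = out[, 2],
                       n_pairs = as.integer(out[, 3]),
                       n_tracks = as.integer(out[, 4])),
            class = c("mean_msd", "data.frame"))
}

#' Two-stage power-law fit of an MSD curve
#'
#' Fits `m(tau) = a * tau^alpha` over `tau_min < tau <= tau_max` by
#' unweighted least squares: a Nelder-Mead simplex search first (robust
#' to poor starting values), then a gradient-based nonlinear
#' least-squares refinement whose parameter covariance supplies the
#' exponent uncertainty `dalpha`.  The tau = 0 point is never part of
#' the objective.  For numerically perfect fits `dalpha` is floored at
#' `dalpha_floor` so downstream `1/dalpha^2` weights stay finite.
#'
#' @param curve an `msd_curve`.
#' @param tau_max upper end of the fit window in seconds (default 0.5).
#' @param tau_min delays at or below this are excluded (default 0).
#' @param dalpha_floor lower bound on the reported uncertainty.
#' @return one-row data.frame of class `"exponent_fit"`:
#'   `track_id, a, alpha, dalpha, tau_min, tau_max, converged`.
#' @export
fit_power_law <- function(curve, tau_max = 0.5, tau_min = 0,
                          dalpha_floor = 1e-6) {
  sel <- curve$tau > tau_min & curve$tau <= tau_max + 1e-12
  tau <- curve$tau[sel]; m <- curve$msd[sel]
  id <- attr(curve, "track_id")
  fail <- function() data.frame(track_id = id, a = NA_real_,
                                alpha = NA_real_, dalpha = NA_real_,
                                tau_min = tau_min, tau_max = tau_max,
                                converged = FALSE)
  if (length(tau) < 3L) stop("need at least 3 delays in the fit window")
  if (all(m <= 0)) return(structure(fail(), class = c("exponent_fit", "data.frame")))
  # log-log regression start values (positive points only)
  pos <- m > 0
  st <- if (sum(pos) >= 2L) {
    cf <- stats::lm.fit(cbind(1, log(tau[pos])), log(m[pos]))$coefficients
    c(a = exp(cf[[1]]), alpha = cf[[2]])
  } else c(a = mean(m) / mean(tau), alpha = 1)
  obj <- function(p) sum((m - exp(p[1]) * tau^p[2])^2)
  nm <- stats::optim(c(log(st[1]), st[2]), obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
  a0 <- unname(exp(nm$par[1])); al0 <- unname(nm$par[2])
  fit <- tryCatch(
    minpack.lm::nlsLM(m ~ a * tau^alpha,
                      data = data.frame(tau = tau, m = m),
                      start = list(a = a0, alpha = al0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    if (nm$convergence != 0) return(structure(fail(),
                                    class = c("exponent_fit", "data.frame")))
    a <- a0; alpha <- al0; dal <- dalpha_floor
  } else {
    cf <- summary(fit)$coefficients
    a <- cf["a", "Estimate"]; alpha <- cf["alpha", "Estimate"]
    dal <- cf["alpha", "Std. Error"]
    if (!is.finite(dal)) dal <- dalpha_floor
  }
  structure(data.frame(track_id = id, a = a, alpha = alpha,
                       dalpha = max(dal, dalpha_floor),
                       tau_min = tau_min, tau_max = tau_max,
                       converged = TRUE),
            class = c("exponent_fit", "data.frame"))
}

#' Fit power laws to every track of a set
#'
#' @param ts a `track_set` (or a list of `msd_curve`s).
#' @inheritParams fit_power_law
#' @param drop_failed drop non-converged fits (default TRUE); they carry
#'   no usable weight either way.
#' @return data.frame of per-track exponent fits.
#' @export
fit_exponents <- function(ts, tau_max = 0.5, tau_min = 0,
                          drop_failed = TRUE, dalpha_floor = 1e-6) {
  curves <- if (inherits(ts, "track_set")) msd_tracks(ts, tau_max) else ts
  fits <- do.call(rbind, lapply(curves, fit_power_law, tau_max = tau_max,
                                tau_min = tau_min,
                                dalpha_floor = dalpha_floor))
  if (drop_failed) fits <- fits[fits$converged, , drop = FALSE]
  fits
}

#' Length of constraint of a tracked locus
#'
#' The standard deviation of the locus position about its time-averaged
#' position: `L_c = sqrt(mean_t |r_t - rbar|^2)` with all coordinate
#' dimensions summed.  It estimates the radius of the region the locus
#' explored during the recording, and is invariant under translation and
#' rotation of the coordinate frame.
#'
#' @param track a `track` (or a `track_set`, which returns one value per
#'   track).
#' @return length of constraint in micrometres.
#' @examples
#' length_of_constraint(track("a", rbind(c(1, 0), c(-1, 0)), dt = 1))  # 1
#' @export
length_of_constraint <- function(track) {
  if (inherits(track, "track_set"))
    return(vapply(track$tracks, length_of_constraint, numeric(1)))
  stopifnot(inherits(track, "track"))
  pos <- track$positions
  ctr <- colMeans(pos)
  dev <- sweep(pos, 2L, ctr)
  sqrt(mean(rowSums(dev * dev)))
}

#' Condition-level mobility summary
#'
#' Convenience report: the exponent of the weighted mean MSD (slope fit),
#' the distribution of per-track exponents (mean and, when a two-component
#' description is selected, the component weights and means), and
#' quantiles of the length of constraint.
#'
#' @param ts a `track_set`.
#' @param tau_max fit window (s).
#' @param rho residual-ratio threshold passed to [select_model()].
#' @return a list of class `"mobility_report"`.
#' @export
mobility_report <- function(ts, tau_max = 0.5, rho = 0.5) {
  curves <- msd_tracks(ts, tau_max)
  mm <- weighted_mean_msd(curves)
  slope_fit <- fit_power_law(structure(
    data.frame(tau = mm$tau, msd = mm$msd,
               var_sq = 0 * mm$tau, n_pairs = mm$n_pairs),
    class = c("msd_curve", "data.frame"), track_id = "ensemble"),
    tau_max = tau_max)
  fits <- fit_exponents(curves, tau_max = tau_max)
  dens <- exponent_density(fits)
  single <- fit_gaussians(dens, 1L)
  double <- tryCatch(fit_gaussians(dens, 2L), error = function(e) NULL)
  choice <- if (is.null(double)) "single" else select_model(single, double, rho)
  lc <- length_of_constraint(ts)
  structure(list(
    condition = ts$condition,
    n_tracks = length(ts$tracks),
    mean_msd = mm,
    ensemble_alpha = slope_fit$alpha,
    mean_track_alpha = stats::weighted.mean(fits$alpha, 1 / fits$dalpha^2),
    model_choice = choice,
    single = single$model, double = if (!is.null(double)) double$model,
    lc_quantiles = stats::quantile(lc, c(0.25, 0.5, 0.75))),
    class = "mobility_report")
}

#' @export
print.mobility_report <- function(x, ...) {
  cat(sprintf("mobility report%s (%d tracks)\n",
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
              x$n_tracks))
  cat(sprintf("  ensemble (weighted-mean-MSD slope) alpha: %.3f\n",
              x$ensemble_alpha))
  cat(sprintf("  mean per-track alpha (1/dalpha^2-weighted): %.3f\n",
              x$mean_track_alpha))
  cat(sprintf("  exponent distribution model: %s\n", x$model_choice))
  if (x$model_choice == "double" && !is.null(x$double))
    cat(sprintf("    components: w = %.2f at alpha = %.3f; %.2f at %.3f\n",
                x$double["w"], x$double["mean1"],
                1 - x$double["w"], x$double["mean2"]))
  q <- x$lc_quantiles
  cat(sprintf("  L_c quartiles (um): %.3f / %.3f / %.3f\n", q[1], q[2], q[3]))
  invisible(x)
}
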