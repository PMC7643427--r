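#' Weighted density of MSD exponents
#'
#' Summarizes per-track anomalous-diffusion exponents as a weighted,
#' density-normalized histogram and a weighted Gaussian-kernel density
#' estimate.  Track i enters with weight `1/dalpha_i^2`, so precisely
#' fitted tracks dominate the distribution.
#'
#' @param fits data.frame of exponent fits (from [fit_exponents()]);
#'   rows with `converged == FALSE` or non-finite values are dropped.
#' @param grid evaluation grid over alpha; default 512 points spanning
#'   the weighted sample plus 3 bandwidths each side.
#' @param bandwidth kernel bandwidth; default Silverman's rule on the
#'   weighted sample (effective sample size `(sum w)^2 / sum w^2`).
#' @param breaks histogram breaks (number or vector); default 30 bins.
#' @return list of class `"exponent_density"`: `alpha`, `weights`,
#'   `grid`, `kde`, `hist` (data.frame mid/density), `bandwidth`.
#' @export
exponent_density <- function(fits, grid = NULL, bandwidth = NULL,
                             breaks = 30L) {
  ok <- fits$converged & is.finite(fits$alpha) & is.finite(fits$dalpha) &
    fits$dalpha > 0
  a <- fits$alpha[ok]
  w <- 1 / fits$dalpha[ok]^2
  if (length(a) < 10L) stop("need at least 10 converged fits")
  if (!any(is.finite(w)) || sum(w) <= 0) stop("all fit weights are invalid")
  w <- w / sum(w)
  n_eff <- 1 / sum(w^2)
  mu <- sum(w * a)
  sdw <- sqrt(sum(w * (a - mu)^2))
  if (is.null(bandwidth)) {
    iqr <- unname(diff(weighted_quantile(a, w, c(0.25, 0.75))))
    spread <- min(sdw, iqr / 1.349)
    if (spread <= 0) spread <- max(sdw, 1e-3)
    bandwidth <- 0.9 * spread * n_eff^(-1 / 5)
  }
  if (is.null(grid))
    grid <- seq(min(a) - 3 * bandwidth, max(a) + 3 * bandwidth,
                length.out = 512L)
  kde <- vapply(grid, function(x)
    sum(w * stats::dnorm((x - a) / bandwidth)) / bandwidth, numeric(1))
  if (length(breaks) == 1L)
    breaks <- seq(min(a), max(a), length.out = breaks + 1L)
  bin <- cut(a, breaks, include.lowest = TRUE)
  bw_hist <- diff(breaks)
  dens <- as.numeric(tapply(w, bin, sum, default = 0)) / bw_hist
  hist <- data.frame(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                     density = dens, width = bw_hist)
  structure(list(alpha = a, weights = w, grid = grid, kde = kde,
                 hist = hist, bandwidth = bandwidth, model = NULL,
                 n_components = 0L, rss = NA_real_),
            class = "exponent_density")
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which.min(abs(cw - p))], numeric(1))
}

gauss1 <- function(x, mean, sd) stats::dnorm(x, mean, sd)
gauss2 <- function(x, w, m1, s1, m2, s2)
  w * stats::dnorm(x, m1, s1) + (1 - w) * stats::dnorm(x, m2, s2)

#' Gaussian description of the exponent density
#'
#' Least-squares fit of a one- or two-component Gaussian probability
#' density to the kernel density estimate (the fit targets the smoothed
#' curve, as is common in single-particle-tracking exponent analyses;
#' an EM fit to the raw weighted sample is available via
#' `method = "em"`).  For two components the mixing weight is
#' constrained to [0, 1] and components are reported with
#' `mean1 <= mean2`.
#'
#' @param dens an `exponent_density`.
#' @param n_components 1 or 2.
#' @param method `"kde"` (default): least squares on the KDE curve;
#'   `"em"`: normal-mixture EM on the raw exponents (unweighted),
#'   using \pkg{mclust} when available.
#' @return the input with `model` (named parameter vector), `rss`
#'   (residual sum of squares on the KDE grid) and `n_components` set.
#' @export
fit_gaussians <- function(dens, n_components = 1L, method = c("kde", "em")) {
  stopifnot(inherits(dens, "exponent_density"),
            n_components %in% c(1L, 2L))
  method <- match.arg(method)
  if (method == "em") return(fit_gaussians_em(dens, n_components))
  x <- dens$grid; y <- dens$kde
  mu <- sum(dens$weights * dens$alpha)
  sdw <- sqrt(sum(dens$weights * (dens$alpha - mu)^2))
  # a component of the KDE curve can never be narrower than the kernel:
  # fitted sd = sqrt(bandwidth^2 + free^2) keeps the fit from chasing
  # smoothing wiggles with spuriously sharp spikes
  bw <- if (is.finite(dens$bandwidth)) dens$bandwidth else 0
  sd_of <- function(p) sqrt(bw^2 + exp(2 * p))
  p_of_sd <- function(s) log(sqrt(max(s^2 - bw^2, (s / 10)^2)))
  if (n_components == 1L) {
    obj <- function(p) sum((y - gauss1(x, p[1], sd_of(p[2])))^2)
    op <- stats::optim(c(mu, p_of_sd(max(sdw, 1e-3))), obj,
                       method = "BFGS",
                       control = list(maxit = 1000, reltol = 1e-14))
    if (!is.finite(op$value)) stop("single-Gaussian fit failed")
    model <- c(mean = op$par[1], sd = sd_of(op$par[2]))
  } else {
    q <- weighted_quantile(dens$alpha, dens$weights, c(0.25, 0.75))
    s0 <- p_of_sd(max(sdw / 2, 1e-3))
    starts <- list(c(0, q[1], s0, q[2], s0),
                   c(stats::qlogis(0.9), mu, s0, mu + 2 * sdw, s0),
                   c(stats::qlogis(0.9), mu - 0.5 * sdw, s0,
                     mu + 1.5 * sdw, s0))
    obj <- function(p) sum((y - gauss2(x, stats::plogis(p[1]), p[2],
                                       sd_of(p[3]), p[4], sd_of(p[5])))^2)
    ops <- lapply(starts, function(st)
      tryCatch(stats::optim(st, obj, method = "BFGS",
                            control = list(maxit = 2000, reltol = 1e-14)),
               error = function(e) list(value = Inf)))
    op <- ops[[which.min(vapply(ops, `[[`, numeric(1), "value"))]]
    if (!is.finite(op$value))
      stop("two-Gaussian fit failed: no start converged (grid range ",
           round(min(x), 3), "..", round(max(x), 3), ")")
    w <- stats::plogis(op$par[1])
    m1 <- op$par[2]; s1 <- sd_of(op$par[3])
    m2 <- op$par[4]; s2 <- sd_of(op$par[5])
    if (m1 > m2) {  # report components in increasing mean order
      tmp <- c(m1, s1); m1 <- m2; s1 <- s2; m2 <- tmp[1]; s2 <- tmp[2]
      w <- 1 - w
    }
    model <- c(w = w, mean1 = m1, sd1 = s1, mean2 = m2, sd2 = s2)
  }
  dens$model <- model
  dens$n_components <- n_components
  dens$rss <- if (n_components == 1L)
    sum((y - gauss1(x, model["mean"], model["sd"]))^2)
  else sum((y - gauss2(x, model["w"], model["mean1"], model["sd1"],
                       model["mean2"], model["sd2"]))^2)
  dens
}

fit_gaussians_em <- function(dens, n_components) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    em <- mclust::Mclust(dens$alpha, G = n_components,
                         modelNames = if (n_components == 1L) "X" else "V",
                         verbose = FALSE)
    p <- em$parameters
    model <- if (n_components == 1L)
      c(mean = unname(p$mean[1]), sd = sqrt(unname(p$variance$sigmasq[1])))
    else {
      o <- order(p$mean)
      sig <- sqrt(p$variance$sigmasq)
      if (length(sig) == 1L) sig <- rep(sig, 2L)
      c(w = unname(p$pro[o][1]), mean1 = unname(p$mean[o][1]),
        sd1 = unname(sig[o][1]), mean2 = unname(p$mean[o][2]),
        sd2 = unname(sig[o][2]))
    }
  } else stop("method = 'em' requires the mclust package")
  dens$model <- model
  dens$n_components <- n_components
  x <- dens$grid
  dens$rss <- if (n_components == 1L)
    sum((dens$kde - gauss1(x, model["mean"], model["sd"]))^2)
  else sum((dens$kde - gauss2(x, model["w"], model["mean1"], model["sd1"],
                              model["mean2"], model["sd2"]))^2)
  dens
}

#' Choose between one- and two-Gaussian exponent models
#'
#' The two-component description is preferred only when it improves the
#' residual sum of squares on the KDE curve by a large factor AND the
#' component means are separated by more than the first component's
#' width — otherwise the extra component is fitting smoothing artefacts.
#'
#' @param single,double `exponent_density` objects fitted with 1 and 2
#'   components on the same KDE.
#' @param rho residual-ratio threshold: "double" requires
#'   `rss_double / rss_single < rho` (default 0.5).
#' @param w_floor smallest mixing weight a genuine minor population may
#'   have (default 0.05); a second component carrying less weight is
#'   treated as a fitting artefact.
#' @return `"single"` or `"double"`.
#' @export
select_model <- function(single, double, rho = 0.5, w_floor = 0.05) {
  stopifnot(single$n_components == 1L, double$n_components == 2L)
  m <- double$model
  sep_ok <- abs(m["mean2"] - m["mean1"]) > m["sd1"]
  w_ok <- min(m["w"], 1 - m["w"]) >= w_floor
  if (is.finite(double$rss) && single$rss > 0 &&
      double$rss / single$rss < rho && sep_ok && w_ok) "double" else "single"
}
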