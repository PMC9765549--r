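# Thermal preferenda of picocyanobacterial strains.
#
# Growth rates are the slopes of ln N(t) over the exponential phase
# (dN/dt = mu * N). The rate-vs-temperature response is modelled with the
# Cardinal Temperature Model with Inflection (CTMI):
#
#   mu_max(T) = 0                      for T <= Tmin or T >= Tmax
#             = mu_opt * phi(T)        for Tmin < T < Tmax
#
#   phi(T) = (T - Tmax)(T - Tmin)^2 /
#            { (Topt - Tmin) [ (Topt - Tmin)(T - Topt)
#                              - (Topt - Tmax)(Topt + Tmin - 2T) ] }
#
# phi(Topt) = 1 so mu_max(Topt) = mu_opt. The four parameters are the
# cardinal temperatures (Tmin, Topt, Tmax, degrees C) and the optimal rate
# mu_opt (per day). Fitting minimizes the residual sum of squares with a
# bounded quasi-Newton search from multiple Latin-hypercube starts.

#' Growth rate from one cell-density time series
#'
#' Ordinary least squares of ln N on t over the exponential phase. When no
#' window is supplied, contiguous windows of at least 4 points (or all
#' points when fewer) are scanned for the highest R-squared with a positive
#' slope, ties going to the longest window. Curves with no positive-slope
#' window (non-growing or declining cultures) yield mu = 0, since the
#' thermal model predicts zero growth outside the viable range.
#'
#' @param time sampling times (days), strictly increasing
#' @param n cell densities (cells/mL), positive
#' @param window optional c(t_start, t_end) delimiting the exponential phase
#' @return list with \code{mu} (per day), \code{stderr}, \code{n_points},
#'   \code{window}, \code{r_squared} and \code{clamped} (TRUE when a
#'   non-positive slope was clamped to zero).
#' @examples
#' t <- 0:4
#' fit_exponential_rate(t, 1e4 * exp(0.5 * t))$mu  # 0.5
#' @export
fit_exponential_rate <- function(time, n, window = NULL) {
  if (length(time) != length(n)) stop("'time' and 'n' differ in length")
  if (any(n <= 0)) stop("cell densities must be positive")
  if (is.unsorted(time, strictly = TRUE))
    stop("'time' must be strictly increasing")
  if (!is.null(window)) {
    keep <- time >= window[1] & time <= window[2]
    time <- time[keep]; n <- n[keep]
  }
  if (length(time) < 3L)
    stop("need at least 3 samples in the window to estimate a rate")
  y <- log(n)

  slope_fit <- function(idx) {
    fit <- stats::lm(y[idx] ~ time[idx])
    s <- summary(fit)$coefficients
    list(mu = s[2L, 1L], stderr = s[2L, 2L],
         r2 = summary(fit)$r.squared, idx = idx)
  }

  if (!is.null(window)) {
    best <- slope_fit(seq_along(time))
  } else {
    n_pts <- length(time)
    w_min <- min(4L, n_pts)
    best <- NULL
    for (len in w_min:n_pts) for (s in 1:(n_pts - len + 1L)) {
      f <- slope_fit(s:(s + len - 1L))
      if (f$mu <= 0) next
      if (is.null(best) || f$r2 > best$r2 + 1e-12 ||
          (abs(f$r2 - best$r2) <= 1e-12 && len > length(best$idx)))
        best <- f
    }
    if (is.null(best)) best <- slope_fit(seq_len(n_pts))  # flat/declining
  }

  clamped <- best$mu < 0
  list(mu = max(best$mu, 0), stderr = best$stderr,
       n_points = length(best$idx),
       window = c(time[best$idx[1L]], time[best$idx[length(best$idx)]]),
       r_squared = best$r2, clamped = clamped)
}

#' Growth rates for a table of growth curves
#'
#' Applies \code{\link{fit_exponential_rate}} to every strain x temperature
#' x replicate series.
#'
#' @param curves data.frame with columns \code{strain}, \code{temperature_C},
#'   \code{replicate}, \code{time_days}, \code{cells_per_ml}
#' @return data.frame \code{strain, temperature_C, replicate, mu_per_day,
#'   stderr, n_points}.
#' @export
fit_rates <- function(curves) {
  need <- c("strain", "temperature_C", "replicate", "time_days",
            "cells_per_ml")
  miss <- setdiff(need, names(curves))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  key <- interaction(curves$strain, curves$temperature_C, curves$replicate,
                     drop = TRUE)
  rows <- lapply(split(curves, key), function(d) {
    d <- d[order(d$time_days), ]
    f <- fit_exponential_rate(d$time_days, d$cells_per_ml)
    data.frame(strain = d$strain[1L], temperature_C = d$temperature_C[1L],
               replicate = d$replicate[1L], mu_per_day = f$mu,
               stderr = f$stderr, n_points = f$n_points,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$strain, out$temperature_C, out$replicate), ]
  rownames(out) <- NULL
  out
}

.check_cardinal <- function(tmin, topt, tmax, mu_opt) {
  if (any(!is.finite(c(tmin, topt, tmax, mu_opt))))
    stop("cardinal parameters must be finite")
  if (!(tmin < topt && topt < tmax))
    stop("cardinal temperatures must satisfy Tmin < Topt < Tmax")
  if (mu_opt < 0) stop("mu_opt must be non-negative")
}

#' CTMI growth rate at temperature T
#'
#' @param t temperature(s), degrees C
#' @param tmin,topt,tmax cardinal temperatures (Tmin < Topt < Tmax)
#' @param mu_opt optimal growth rate (per day), >= 0
#' @return mu_max(T) in per day; 0 outside (Tmin, Tmax).
#' @examples
#' ctmi_mu(20, tmin = 0, topt = 24, tmax = 28, mu_opt = 1)  # 0.8333...
#' @export
ctmi_mu <- function(t, tmin, topt, tmax, mu_opt) {
  .check_cardinal(tmin, topt, tmax, mu_opt)
  num <- (t - tmax) * (t - tmin)^2
  den <- (topt - tmin) * ((topt - tmin) * (t - topt) -
                            (topt - tmax) * (topt + tmin - 2 * t))
  mu <- mu_opt * num / den
  mu[t <= tmin | t >= tmax] <- 0
  mu
}

# RSS objective on the reparameterised scale theta = (Tmin, Topt, dmax,
# mu_opt) with Tmax = Topt + dmax; box bounds then imply Tmin < Topt < Tmax.
.ctmi_rss <- function(theta, temp, mu) {
  tmin <- theta[1L]; topt <- theta[2L]; tmax <- theta[2L] + theta[3L]
  num <- (temp - tmax) * (temp - tmin)^2
  den <- (topt - tmin) * ((topt - tmin) * (temp - topt) -
                            (topt - tmax) * (topt + tmin - 2 * temp))
  pred <- theta[4L] * num / den
  pred[temp <= tmin | temp >= tmax] <- 0
  rss <- sum((mu - pred)^2)
  if (!is.finite(rss)) 1e10 else rss
}

#' Fit the Cardinal Temperature Model with Inflection
#'
#' Least-squares fit of the CTMI to growth-rate observations at several
#' temperatures: minimizes the residual sum of squares over (Tmin, Topt,
#' Tmax, mu_opt) subject to Tmin < Topt < Tmax and mu_opt >= 0, using
#' L-BFGS-B from \code{n_starts} Latin-hypercube starting points; the best
#' residual sum of squares wins (ties to the first start). Replicate rates
#' at one temperature are averaged before fitting by default
#' (\code{fit_on = "mean"}); \code{fit_on = "replicates"} fits every point.
#'
#' Search bounds: Tmin in [-20, min observed T), Topt within the observed
#' range, Tmax in (Topt, max observed T + 10], mu_opt in (0, 2 max mu].
#' Data rarely constrain Tmin when no sub-zero growth is observed; Topt,
#' Tmax and mu_opt remain identifiable regardless.
#'
#' @param temperature temperatures (degrees C), or a data.frame with columns
#'   \code{temperature_C} and \code{mu_per_day}
#' @param mu observed growth rates (per day); ignored when
#'   \code{temperature} is a data.frame
#' @param fit_on "mean" (default) or "replicates"
#' @param n_starts number of multi-start points (default 20)
#' @param seed seed for the start design, for determinism (default 1)
#' @return object of class \code{ctmi} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{fitted},
#'   \code{residuals}, \code{plot}, \code{confint}.
#' @export
fit_ctmi <- function(temperature, mu = NULL, fit_on = c("mean", "replicates"),
                     n_starts = 20L, seed = 1L) {
  fit_on <- match.arg(fit_on)
  if (is.data.frame(temperature)) {
    mu <- temperature$mu_per_day
    temperature <- temperature$temperature_C
  }
  if (length(temperature) != length(mu)) stop("length mismatch")
  ok <- is.finite(temperature) & is.finite(mu)
  temperature <- temperature[ok]; mu <- mu[ok]
  raw <- data.frame(temperature_C = temperature, mu_per_day = mu)
  if (fit_on == "mean") {
    agg <- tapply(mu, temperature, mean)
    temperature <- as.numeric(names(agg))
    mu <- as.numeric(agg)
  }
  if (length(unique(temperature)) < 5L)
    stop("need rates at >= 5 distinct temperatures to fit the CTMI")
  if (all(mu <= 0))
    stop("all growth rates are zero; the thermal response is unfittable")

  t_lo <- min(temperature); t_hi <- max(temperature)
  lower <- c(-20, t_lo, 0.1, 1e-8)
  upper <- c(t_lo - 0.1, t_hi, t_hi + 10 - t_lo, 2 * max(mu))

  # stratified Latin-hypercube start design, deterministic under the seed
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  u <- vapply(1:4, function(j)
    (sample(n_starts) - stats::runif(n_starts)) / n_starts,
    numeric(n_starts))
  starts <- sweep(sweep(u, 2L, upper - lower, "*"), 2L, lower, "+")

  best <- NULL
  conv <- 0L
  for (i in seq_len(n_starts)) {
    res <- tryCatch(
      stats::optim(starts[i, ], .ctmi_rss, temp = temperature, mu = mu,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0L) conv <- conv + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("CTMI fit failed to converge from any start; check the rate data")

  th <- best$par
  cf <- c(Tmin = th[1L], Topt = th[2L], Tmax = th[2L] + th[3L],
          mu_opt = th[4L])
  structure(list(coefficients = cf, rss = best$value, data = raw,
                 fitted_data = data.frame(temperature_C = temperature,
                                          mu_per_day = mu),
                 fit_on = fit_on, n_starts = n_starts, seed = seed,
                 n_converged = conv,
                 bounds = list(lower = lower, upper = upper)),
            class = "ctmi")
}

#' @export
coef.ctmi <- function(object, ...) object$coefficients

#' @export
predict.ctmi <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$fitted_data$temperature_C
  else if (is.data.frame(newdata)) newdata$temperature_C else newdata
  cf <- object$coefficients
  ctmi_mu(t, cf[["Tmin"]], cf[["Topt"]], cf[["Tmax"]], cf[["mu_opt"]])
}

#' @export
fitted.ctmi <- function(object, ...) predict(object)

#' @export
residuals.ctmi <- function(object, ...)
  object$fitted_data$mu_per_day - fitted(object)

#' @export
print.ctmi <- function(x, ...) {
  cat("Cardinal Temperature Model with Inflection fit\n")
  print(round(x$coefficients, 3))
  cat(sprintf("RSS: %.5g on %d temperatures (%s)\n", x$rss,
              nrow(x$fitted_data), x$fit_on))
  invisible(x)
}

#' @export
summary.ctmi <- function(object, ...) {
  cat("CTMI thermal response fit\n\n")
  cat("Cardinal parameters:\n")
  print(round(object$coefficients, 3))
  cat(sprintf("\nRSS %.5g | %d fitted points (%s of %d observations)\n",
              object$rss, nrow(object$fitted_data), object$fit_on,
              nrow(object$data)))
  cat(sprintf("%d/%d starts converged (seed %d)\n", object$n_converged,
              object$n_starts, object$seed))
  d <- object$fitted_data
  cat(sprintf("Topt (measured, max observed mu): %.1f C; Tmax (measured, warmest growth): %.1f C\n",
              d$temperature_C[which.max(d$mu_per_day)],
              suppressWarnings(max(d$temperature_C[d$mu_per_day > 0]))))
  invisible(object)
}

#' @export
plot.ctmi <- function(x, ...) {
  d <- x$data
  grid <- seq(min(d$temperature_C) - 2, max(d$temperature_C) + 2,
              length.out = 200)
  plot(d$temperature_C, d$mu_per_day, xlab = "Temperature (°C)",
       ylab = expression(mu ~ (day^-1)), pch = 19, ...)
  lines(grid, predict(x, grid), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Bootstrap confidence intervals for CTMI parameters
#'
#' Nonparametric bootstrap: replicate rate observations are resampled with
#' replacement within each temperature, the model is refit to each resample
#' (warm-started from the point estimate), and percentile 2.5/97.5 bounds
#' are reported for Topt, Tmax and mu_opt (Tmin is reported too, but is
#' typically unconstrained by data lacking near-zero-growth cold
#' observations). Because resampling n points from their own empirical
#' distribution understates the noise variance by (n - 1)/n — severe for
#' triplicate cultures — resampled deviations from each temperature's mean
#' are inflated by sqrt(n/(n - 1)), the usual finite-sample variance
#' correction; without it the intervals are systematically narrow.
#'
#' Each refit searches from the point estimate plus \code{extra_starts}
#' Latin-hypercube starting points: with sparse temperature grids the RSS
#' surface can hold two basins (a broad thermal envelope and a near-vertical
#' decline squeezed between the two warmest growing temperatures), and
#' refits warm-started only at the point estimate never leave the basin the
#' point estimate sits in, understating the uncertainty.
#'
#' @param object a fitted \code{ctmi} object
#' @param B number of bootstrap replicates (default 1000)
#' @param seed RNG seed
#' @param level confidence level (default 0.95)
#' @param extra_starts additional multi-start points per refit (default 2)
#' @return matrix with rows Tmin/Topt/Tmax/mu_opt and columns lower/upper;
#'   attribute \code{"n_failed"} counts failed refits. Warns and returns
#'   NA bounds if more than half of the refits fail.
#' @export
ctmi_confidence_intervals <- function(object, B = 1000L, seed = 1L,
                                      level = 0.95, extra_starts = 2L) {
  if (!inherits(object, "ctmi")) stop("'object' must be a ctmi fit")
  if (!is.numeric(B) || B < 1L) stop("'B' must be a positive integer")
  d <- object$data
  by_temp <- split(seq_len(nrow(d)), d$temperature_C)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  cf <- object$coefficients
  start <- c(cf["Tmin"], cf["Topt"], cf["Tmax"] - cf["Topt"], cf["mu_opt"])
  lower <- object$bounds$lower; upper <- object$bounds$upper
  start <- pmin(pmax(start, lower), upper)
  starts <- matrix(start, nrow = 1L)
  if (extra_starts > 0L) {
    u <- vapply(1:4, function(j)
      (sample(extra_starts) - stats::runif(extra_starts)) / extra_starts,
      numeric(extra_starts))
    u <- matrix(u, ncol = 4L)
    starts <- rbind(starts,
                    sweep(sweep(u, 2L, upper - lower, "*"), 2L, lower, "+"))
  }

  boot <- matrix(NA_real_, nrow = B, ncol = 4L,
                 dimnames = list(NULL, c("Tmin", "Topt", "Tmax", "mu_opt")))
  failed <- 0L
  for (b in seq_len(B)) {
    db <- do.call(rbind, lapply(by_temp, function(i) {
      n_i <- length(i)
      draw <- d[i[sample.int(n_i, n_i, replace = TRUE)], ]
      if (n_i > 1L) {
        m <- mean(d$mu_per_day[i])
        draw$mu_per_day <- pmax(0, m + (draw$mu_per_day - m) *
                                  sqrt(n_i / (n_i - 1)))
      }
      draw
    }))
    if (object$fit_on == "mean") {
      agg <- tapply(db$mu_per_day, db$temperature_C, mean)
      temp <- as.numeric(names(agg)); mu <- as.numeric(agg)
    } else {
      temp <- db$temperature_C; mu <- db$mu_per_day
    }
    res <- NULL
    for (s in seq_len(nrow(starts))) {
      r1 <- tryCatch(
        stats::optim(starts[s, ], .ctmi_rss, temp = temp, mu = mu,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 500L)),
        error = function(e) NULL)
      if (!is.null(r1) && (is.null(res) || r1$value < res$value)) res <- r1
    }
    if (is.null(res)) { failed <- failed + 1L; next }
    boot[b, ] <- c(res$par[1L], res$par[2L], res$par[2L] + res$par[3L],
                   res$par[4L])
  }

  a <- (1 - level) / 2
  ci <- t(apply(boot, 2L, stats::quantile, probs = c(a, 1 - a),
                na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  if (failed > B / 2) {
    warning("more than half of the bootstrap refits failed; ",
            "confidence intervals unavailable")
    ci[] <- NA_real_
  }
  attr(ci, "n_failed") <- failed
  attr(ci, "level") <- level
  ci
}

#' @export
confint.ctmi <- function(object, parm, level = 0.95, B = 1000L,
                         seed = 1L, ...) {
  ci <- ctmi_confidence_intervals(object, B = B, seed = seed, level = level)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Thermal-preferenda report for several strains
#'
#' Fits the CTMI per strain and tabulates measured vs model cardinal
#' temperatures with bootstrap confidence bounds: Topt_measured is the
#' temperature of the largest observed mean rate, Tmax_measured the warmest
#' temperature with positive growth.
#'
#' @param rates data.frame \code{strain, temperature_C, mu_per_day}
#'   (replicate rows allowed)
#' @param B bootstrap replicates per strain (default 200)
#' @param seed RNG seed
#' @return data.frame, one row per strain.
#' @export
growth_fit_report <- function(rates, B = 200L, seed = 1L) {
  rows <- lapply(split(rates, rates$strain), function(d) {
    fit <- fit_ctmi(d)
    ci <- ctmi_confidence_intervals(fit, B = B, seed = seed)
    agg <- tapply(d$mu_per_day, d$temperature_C, mean)
    temps <- as.numeric(names(agg))
    cf <- coef(fit)
    data.frame(strain = d$strain[1L],
               Topt_measured = temps[which.max(agg)],
               Topt_model = cf[["Topt"]],
               Topt_lo = ci["Topt", "lower"], Topt_hi = ci["Topt", "upper"],
               Tmax_measured = suppressWarnings(max(temps[agg > 0])),
               Tmax_model = cf[["Tmax"]],
               Tmax_lo = ci["Tmax", "lower"], Tmax_hi = ci["Tmax", "upper"],
               mu_opt = cf[["mu_opt"]], rss = fit$rss,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
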