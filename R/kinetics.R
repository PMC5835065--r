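#' Construct a growth curve
#'
#' Time-stamped inorganic nitrogen concentrations for one bottle/replicate.
#'
#' @param time_h sampling times in hours, strictly increasing.
#' @param nh4_uM,no2_uM,no3_uM concentrations in micromolar (any subset may
#'   be supplied; omitted species are `NULL`).
#' @param replicate replicate identifier.
#' @param inoculation_time inoculation time in hours (default 0); lag
#'   durations are measured from this point.
#' @return data frame of class `growth_curve`.
#' @export
growth_curve <- function(time_h, nh4_uM = NULL, no2_uM = NULL, no3_uM = NULL,
                         replicate = "r1", inoculation_time = 0) {
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing")
  for (s in list(nh4_uM, no2_uM, no3_uM)) {
    if (!is.null(s)) {
      if (length(s) != length(time_h)) stop("species length must match times")
      if (any(s < 0)) stop("concentrations must be non-negative")
    }
  }
  df <- data.frame(time_h = time_h)
  if (!is.null(nh4_uM)) df$nh4_uM <- nh4_uM
  if (!is.null(no2_uM)) df$no2_uM <- no2_uM
  if (!is.null(no3_uM)) df$no3_uM <- no3_uM
  df$replicate <- replicate
  structure(df, class = c("growth_curve", "data.frame"),
            inoculation_time = inoculation_time)
}

#' Oxidation-product series for a nitrifier guild
#'
#' The growth proxy regressed against time is the accumulated oxidation
#' product: for ammonia oxidisers (AOB) the sum of nitrite and nitrate, for
#' nitrite oxidisers (NOB) nitrate alone.
#'
#' @param curve a [growth_curve()].
#' @param guild `"AOB"` or `"NOB"`.
#' @return numeric vector of product concentrations, one per time point.
#' @export
oxidation_product <- function(curve, guild = c("AOB", "NOB")) {
  guild <- match.arg(guild)
  need <- if (guild == "AOB") c("no2_uM", "no3_uM") else "no3_uM"
  missing <- setdiff(need, names(curve))
  if (length(missing) > 0) {
    stop("guild ", guild, " requires species: ",
         paste(missing, collapse = ", "))
  }
  out <- if (guild == "AOB") curve$no2_uM + curve$no3_uM else curve$no3_uM
  if (all(out == 0)) {
    warning("all-zero product series for guild ", guild,
            ": no exponential phase can exist")
  }
  out
}

# slope and R^2 of an OLS line, vectorised building block
ols_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  dx <- x - mx; dy <- y - my
  sxx <- sum(dx^2); syy <- sum(dy^2); sxy <- sum(dx * dy)
  slope <- sxy / sxx
  r2 <- if (syy == 0) 1 else sxy^2 / (sxx * syy)
  list(slope = slope, intercept = my - slope * mx, r2 = r2)
}

#' Select the exponential-phase regression window
#'
#' Searches all contiguous windows of at least `min_points` samples in which
#' every value is positive (zeros are treated as below detection and
#' excluded), and keeps the longest window whose log-linear regression has a
#' positive slope and a coefficient of determination of at least `r2_min`;
#' ties break towards the earliest start. This makes the published
#' window-acceptance rule (all accepted slopes with R-squared >= 0.99)
#' algorithmic.
#'
#' @param series positive product concentrations.
#' @param times sampling times in hours.
#' @param r2_min minimum R-squared for acceptance (default 0.99).
#' @param min_points minimum number of points per window (default 4).
#' @return list with `start_idx`, `end_idx`, `t_start`, `t_end`, `n_points`,
#'   `slope`, `r2`.
#' @export
select_window <- function(series, times, r2_min = 0.99, min_points = 4) {
  if (length(series) != length(times)) stop("series/times length mismatch")
  if (!(r2_min > 0 && r2_min <= 1)) stop("r2_min must lie in (0, 1]")
  if (min_points < 4) stop("min_points must be at least 4")
  n <- length(series)
  logy <- ifelse(series > 0, log(series), NA_real_)
  best <- NULL
  for (i in seq_len(n - min_points + 1L)) {
    if (is.na(logy[i])) next
    for (j in seq(i + min_points - 1L, n)) {
      if (anyNA(logy[i:j])) break  # window must be contiguous in positives
      fit <- ols_line(times[i:j], logy[i:j])
      if (fit$slope > 0 && fit$r2 >= r2_min) {
        len <- j - i + 1L
        if (is.null(best) || len > best$n_points) {
          best <- list(start_idx = i, end_idx = j, t_start = times[i],
                       t_end = times[j], n_points = len,
                       slope = fit$slope, r2 = fit$r2)
        }
      }
    }
  }
  if (is.null(best)) stop("no exponential phase detected")
  best
}

#' Growth rate, fit diagnostics and lag from a regression window
#'
#' The specific growth rate is the ordinary-least-squares slope of the
#' natural-log product series against time (hours) over the window, so the
#' slope is the rate in h^-1 directly. The lag duration is the time from
#' inoculation to the first point of the window.
#'
#' @param series,times as in [select_window()].
#' @param window a window from [select_window()].
#' @param inoculation_time inoculation time in hours (default 0).
#' @return object of class `growth_fit`: `mu` (h^-1), `r2`, `lag_h`,
#'   `n_points`, `window` (`t_start`, `t_end`), `intercept`.
#' @export
growth_rate <- function(series, times, window, inoculation_time = 0) {
  idx <- seq(window$start_idx, window$end_idx)
  y <- series[idx]
  if (any(y <= 0)) stop("non-positive values inside the regression window")
  fit <- ols_line(times[idx], log(y))
  if (fit$slope <= 0) stop("window slope is not positive")
  structure(list(
    mu = fit$slope, r2 = fit$r2,
    lag_h = window$t_start - inoculation_time,
    n_points = length(idx),
    window = c(t_start = window$t_start, t_end = window$t_end),
    intercept = fit$intercept
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Exponential-phase growth fit\n")
  cat(sprintf("  mu = %.5f h^-1  (R^2 = %.4f, %d points)\n",
              x$mu, x$r2, x$n_points))
  cat(sprintf("  window %.1f-%.1f h, lag = %.1f h\n",
              x$window["t_start"], x$window["t_end"], x$lag_h))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(mu = object$mu, lag_h = object$lag_h)
}

#' One-call growth estimation for a curve
#'
#' Convenience wrapper: product series via [oxidation_product()], window via
#' [select_window()], then [growth_rate()].
#'
#' @inheritParams oxidation_product
#' @inheritParams select_window
#' @return a `growth_fit`.
#' @export
estimate_growth <- function(curve, guild = c("AOB", "NOB"), r2_min = 0.99,
                            min_points = 4) {
  series <- oxidation_product(curve, guild)
  w <- select_window(series, curve$time_h, r2_min = r2_min,
                     min_points = min_points)
  growth_rate(series, curve$time_h, w,
              inoculation_time = attr(curve, "inoculation_time") %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Monod growth rate
#'
#' `mu = mu_max * S / (ks + S)`: the saturating dependence of the specific
#' growth rate on the limiting substrate concentration, with half-maximal
#' rate at `S = ks`.
#'
#' @param S substrate concentration(s), micromolar, non-negative.
#' @param mu_max maximum specific growth rate, h^-1, positive.
#' @param ks half-saturation constant, micromolar, positive.
#' @return growth rate(s) in h^-1.
#' @export
monod_mu <- function(S, mu_max, ks) {
  if (any(S < 0)) stop("S must be non-negative")
  if (mu_max <= 0) stop("mu_max must be positive")
  if (ks <= 0) stop("ks must be positive")
  mu_max * S / (ks + S)
}

#' Fit the Monod model to (substrate, rate) pairs
#'
#' Nonlinear least squares of `mu ~ mu_max * S / (ks + S)` by bounded
#' Levenberg-Marquardt. Initialisation: `mu_max` starts at the largest
#' observed rate, `ks` at the substrate concentration whose rate is nearest
#' half of that; both parameters are bounded positive. If the optimiser
#' fails to converge the best iterate is returned with `converged = FALSE`
#' (cultures that fit the model poorly must surface diagnostics, not fail
#' silently).
#'
#' @param S substrate concentrations, micromolar (at least 3 distinct).
#' @param mu observed growth rates, h^-1, non-negative.
#' @return object of class `monod_fit`: use [coef()], [predict()],
#'   [summary()] and [plot()] on it. Fields include `mu_max`, `ks`, `rss`,
#'   `converged`, `n_obs`, `data`.
#' @export
#' @examples
#' S <- c(50, 200, 500, 1000, 1500)
#' fit <- fit_monod(S, monod_mu(S, 0.028, 25.9))
#' coef(fit)
fit_monod <- function(S, mu) {
  if (length(S) != length(mu)) stop("S and mu must have equal length")
  if (length(unique(S)) < 3) stop("need at least 3 distinct S values")
  if (any(mu < 0)) stop("mu must be non-negative")
  if (all(mu == 0)) stop("all rates are zero: no kinetics to fit")

  mu_max0 <- max(mu)
  ks0 <- S[which.min(abs(mu - mu_max0 / 2))]
  if (ks0 <= 0) ks0 <- min(S[S > 0]) / 2
  dat <- data.frame(S = S, mu = mu)

  fit <- tryCatch(
    minpack.lm::nlsLM(mu ~ mu_max * S / (ks + S), data = dat,
                      start = list(mu_max = mu_max0, ks = ks0),
                      lower = c(mu_max = 1e-10, ks = 1e-10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (!is.null(fit)) {
    est <- coef(fit)
    converged <- isTRUE(fit$convInfo$isConv)
    rss <- sum(resid(fit)^2)
  } else {
    # fall back to bounded quasi-Newton on the same objective
    obj <- function(p) sum((mu - p[1] * S / (p[2] + S))^2)
    opt <- stats::optim(c(mu_max0, max(ks0, 1e-6)), obj,
                        method = "L-BFGS-B", lower = c(1e-10, 1e-10))
    est <- c(mu_max = opt$par[1], ks = opt$par[2])
    converged <- FALSE
    rss <- opt$value
  }
  structure(list(
    mu_max = unname(est["mu_max"]), ks = unname(est["ks"]),
    rss = rss, converged = converged, n_obs = length(S), data = dat
  ), class = "monod_fit")
}

#' @export
coef.monod_fit <- function(object, ...) {
  c(mu_max = object$mu_max, ks = object$ks)
}

#' @export
predict.monod_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$data$S else
    if (is.data.frame(newdata)) newdata$S else newdata
  monod_mu(S, object$mu_max, object$ks)
}

#' @export
print.monod_fit <- function(x, ...) {
  cat("Monod kinetics fit: mu = mu_max * S / (ks + S)\n")
  cat(sprintf("  mu_max = %.5f h^-1, ks = %.2f uM  (n = %d)\n",
              x$mu_max, x$ks, x$n_obs))
  cat(sprintf("  rss = %.3g, converged = %s\n", x$rss, x$converged))
  invisible(x)
}

#' @export
summary.monod_fit <- function(object, ...) {
  res <- object$data$mu - predict(object)
  structure(list(fit = object, residuals = res,
                 sigma = sqrt(object$rss / max(1, object$n_obs - 2))),
            class = "summary.monod_fit")
}

#' @export
print.summary.monod_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual sd = %.3g on %d observations\n",
              x$sigma, x$fit$n_obs))
  cat("  residuals:\n")
  print(summary(x$residuals))
  invisible(x)
}

#' @export
residuals.monod_fit <- function(object, ...) {
  object$data$mu - predict(object)
}

#' @export
plot.monod_fit <- function(x, ...) {
  S <- x$data$S
  grid <- seq(0, max(S) * 1.05, length.out = 200)
  plot(S, x$data$mu, xlab = "substrate (uM)", ylab = "mu (1/h)",
       main = "Monod fit", ...)
  graphics::lines(grid, monod_mu(grid, x$mu_max, x$ks))
  graphics::abline(v = x$ks, lty = 3)
  invisible(x)
}

#' Absolute quantification from a qPCR standard curve
#'
#' Fits the standard line `Ct = slope * log10(copies) + intercept` to
#' serially diluted standards, inverts unknown Ct values through it, and
#' reports the amplification efficiency `10^(-1/slope) - 1` (1.0 means
#' perfect doubling per cycle).
#'
#' @param standards data frame with columns `log10_copies` and `ct`
#'   (at least 3 standards spanning at least 2 log10 units).
#' @param unknowns Ct values to quantify (optional).
#' @return list with `copies` (numeric, one per unknown) and `curve`, an
#'   object of class `qpcr_curve` (`slope`, `intercept`, `efficiency`,
#'   `r2`).
#' @export
qpcr_quantify <- function(standards, unknowns = numeric(0)) {
  if (!all(c("log10_copies", "ct") %in% names(standards))) {
    stop("standards need columns log10_copies and ct")
  }
  if (nrow(standards) < 3) stop("need at least 3 standards")
  if (diff(range(standards$log10_copies)) < 2) {
    stop("standards must span at least 2 log10 units")
  }
  fit <- lm(ct ~ log10_copies, data = standards)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (slope >= 0) stop("positive standard-curve slope: inverted standards")
  sst <- sum((standards$ct - mean(standards$ct))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(resid(fit)^2) / sst
  curve <- structure(list(
    slope = slope, intercept = intercept,
    efficiency = 10^(-1 / slope) - 1, r2 = r2
  ), class = "qpcr_curve")
  copies <- 10^((unknowns - intercept) / slope)
  list(copies = copies, curve = curve)
}

#' @export
print.qpcr_curve <- function(x, ...) {
  cat("qPCR standard curve\n")
  cat(sprintf("  Ct = %.4f * log10(copies) + %.3f  (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r2))
  cat(sprintf("  amplification efficiency = %.1f%%\n", 100 * x$efficiency))
  invisible(x)
}
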