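# Growth and uptake kinetics from OD600 / substrate time series.

#' Fit the specific growth rate from an OD600 curve
#'
#' mu is the slope of a linear regression of ln(OD) on time over the
#' selected exponential window; DT = ln(2)/mu. The window is the
#' maximal-length sliding window (>= `min_points` samples above
#' `od_threshold`) whose ln-linear fit reaches `r2_threshold`.
#'
#' @param curve data.frame with columns `time_h`, `od600`.
#' @param od_threshold detection threshold below which points are ignored.
#' @param r2_threshold minimum r-squared for an acceptable window.
#' @param min_points minimum window length.
#' @param od_to_cdw strain-specific correlation factor
#'   (gCDW L^-1 per OD600 unit); default 0.4, a documented non-measured
#'   default.
#' @return a `c1_growth_fit`: `mu` (h^-1), `DT` (h), `window`,
#'   `r_squared`, `od_to_cdw`.
#' @export
fit_growth <- function(curve, od_threshold = 0.02, r2_threshold = 0.99,
                       min_points = 4L, od_to_cdw = 0.4) {
  stopifnot(all(c("time_h", "od600") %in% names(curve)))
  ok <- is.finite(curve$od600) & curve$od600 > od_threshold
  d <- curve[ok, , drop = FALSE]
  d <- d[order(d$time_h), , drop = FALSE]
  n <- nrow(d)
  if (n < min_points) stop("no exponential window: too few points above threshold")
  lno <- log(d$od600)
  best <- NULL
  for (len in seq(n, min_points)) {
    for (start in seq_len(n - len + 1L)) {
      idx <- start:(start + len - 1L)
      fit <- stats::lm.fit(cbind(1, d$time_h[idx]), lno[idx])
      slope <- fit$coefficients[2]
      ss_res <- sum(fit$residuals^2)
      ss_tot <- sum((lno[idx] - mean(lno[idx]))^2)
      r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
      if (slope > 0 && r2 >= r2_threshold) {
        best <- list(idx = idx, mu = unname(slope), r2 = r2)
        break
      }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) stop("no exponential window: no ln-linear stretch with r2 >= ",
                          r2_threshold)
  # Refine: corner points of the lag or stationary phase can sit inside the
  # maximal window while keeping r2 above threshold, biasing mu downward.
  # Trim an endpoint while its residual is an outlier against the interior
  # scatter (systematic curvature); pure-noise endpoints survive.
  win_fit <- function(idx) {
    fit <- stats::lm.fit(cbind(1, d$time_h[idx]), lno[idx])
    ss_tot <- sum((lno[idx] - mean(lno[idx]))^2)
    list(r2 = if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 0,
         mu = unname(fit$coefficients[2]), resid = fit$residuals)
  }
  idx <- best$idx
  repeat {
    if (length(idx) <= min_points) break
    cur <- win_fit(idx)
    k <- length(idx)
    s_int <- stats::sd(cur$resid[2:(k - 1)])
    if (!is.finite(s_int) || s_int < 1e-12) break
    za <- abs(cur$resid[1]) / s_int
    zb <- abs(cur$resid[k]) / s_int
    if (max(za, zb) < 2.2) break
    idx <- if (za >= zb) idx[-1] else idx[-k]
  }
  fin <- win_fit(idx)
  best <- list(idx = idx, mu = fin$mu, r2 = fin$r2)
  structure(list(mu = best$mu, DT = log(2) / best$mu,
                 window = c(d$time_h[best$idx[1]],
                            d$time_h[best$idx[length(best$idx)]]),
                 r_squared = best$r2, od_to_cdw = od_to_cdw,
                 n_points = length(best$idx)),
            class = "c1_growth_fit")
}

#' @export
print.c1_growth_fit <- function(x, ...) {
  cat(sprintf("mu = %.4g h^-1, DT = %.3g h (window %.4g-%.4g h, r2 = %.4f)\n",
              x$mu, x$DT, x$window[1], x$window[2], x$r_squared))
  invisible(x)
}

align_series <- function(biomass, substrate) {
  stopifnot(all(c("time_h") %in% names(biomass)),
            all(c("time_h", "mM") %in% names(substrate)))
  t_common <- intersect(biomass$time_h, substrate$time_h)
  if (length(t_common) < 2) stop("mismatched timestamps between series")
  b <- biomass[match(t_common, biomass$time_h), , drop = FALSE]
  s <- substrate[match(t_common, substrate$time_h), , drop = FALSE]
  ord <- order(t_common)
  list(time = sort(t_common), biomass = b[ord, ], substrate = s[ord, ])
}

#' Estimate a specific substrate consumption rate
#'
#' Implements q_S = (1/X) dS/dt two ways: per sampling interval (X is the
#' centred average biomass between the two sampling points) and as a
#' regression aggregate: mu divided by the slope of a linear regression of
#' biomass concentration on substrate concentration over the growth
#' window. The aggregate is the headline value; with q in
#' mmol gCDW^-1 h^-1, X in gCDW L^-1 and S in mM, no unit factor is needed
#' (1 mM = 1 mmol L^-1).
#'
#' @param biomass data.frame `time_h`, `od600` (or `gcdw_l`).
#' @param substrate data.frame `time_h`, `mM`.
#' @param od_to_cdw OD600 -> gCDW L^-1 factor (used when only `od600` is
#'   supplied).
#' @param growth_fit optional precomputed [fit_growth()] result.
#' @return a `c1_rate_estimate`: `q_s` (aggregate), `per_interval`
#'   (data.frame with q_s, X, delta_S, delta_t), `mu`, `Y_XS`.
#' @export
estimate_uptake <- function(biomass, substrate, od_to_cdw = 0.4,
                            growth_fit = NULL) {
  al <- align_series(biomass, substrate)
  X <- if ("gcdw_l" %in% names(al$biomass)) al$biomass$gcdw_l else
    al$biomass$od600 * od_to_cdw
  if (any(X <= 0)) stop("zero or negative biomass in series")
  S <- al$substrate$mM
  tt <- al$time
  k <- length(tt)
  Xbar <- (X[-1] + X[-k]) / 2
  dS <- S[-k] - S[-1]          # positive when consumed
  dt <- tt[-1] - tt[-k]
  per <- data.frame(t_start = tt[-k], t_end = tt[-1], X = Xbar,
                    delta_S = dS, delta_t = dt,
                    q_s = dS / dt / Xbar)
  if (is.null(growth_fit)) {
    growth_fit <- tryCatch(
      fit_growth(data.frame(time_h = tt, od600 = X / od_to_cdw),
                 od_to_cdw = od_to_cdw),
      error = function(e) NULL)
  }
  if (is.null(growth_fit)) {
    # no exponential window (e.g. constant biomass): fall back to the
    # time-weighted mean of the per-interval estimates
    q_agg <- sum(per$q_s * per$delta_t) / sum(per$delta_t)
    if (q_agg < 0) warning("substrate increasing over time: negative q_s reported")
    return(structure(list(q_s = q_agg, per_interval = per, mu = NA_real_,
                          Y_XS = NA_real_, window = c(NA_real_, NA_real_)),
                     class = "c1_rate_estimate"))
  }
  win <- growth_fit$window
  use <- tt >= win[1] & tt <= win[2]
  # extend to substrate-consuming samples adjacent to the window
  if (sum(use) < 3) use <- rep(TRUE, k)
  slope <- unname(stats::coef(stats::lm(X[use] ~ S[use]))[2])  # gCDW/L per mM
  q_agg <- -growth_fit$mu / slope
  if (q_agg < 0) warning("substrate increasing over time: negative q_s reported")
  structure(list(q_s = q_agg, per_interval = per, mu = growth_fit$mu,
                 Y_XS = growth_fit$mu / q_agg * 1000,
                 window = win),
            class = "c1_rate_estimate")
}

#' Estimate a biomass yield on substrate
#'
#' Y_X/S = delta X / delta S over the consumption phase, converted from mM
#' to mol L^-1 (factor 1000), in gCDW per mol of substrate.
#'
#' @inheritParams estimate_uptake
#' @return a `c1_yield_estimate`: `Y_XS` (gCDW mol^-1), `delta_X`,
#'   `delta_S`, `basis`.
#' @export
estimate_yield <- function(biomass, substrate, od_to_cdw = 0.4,
                           basis = "substrate") {
  al <- align_series(biomass, substrate)
  X <- if ("gcdw_l" %in% names(al$biomass)) al$biomass$gcdw_l else
    al$biomass$od600 * od_to_cdw
  S <- al$substrate$mM
  dS <- S[1] - min(S)                  # mM consumed
  i_end <- which.min(S)
  dX <- X[i_end] - X[1]
  if (dS <= 0) stop("zero substrate consumption: yield undefined")
  structure(list(Y_XS = max(dX, 0) / dS * 1000, delta_X = dX, delta_S = dS,
                 basis = basis),
            class = "c1_yield_estimate")
}
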