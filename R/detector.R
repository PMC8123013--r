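#' Detector configuration
#'
#' Parameters of the sampling-grid-independent QRS detector.  The detection
#' function (DF) is evaluated on its own regular grid (`df_step`),
#' independent of how the ECG itself is sampled.  At every DF instant two
#' pairs of regression lines ("triangle legs") are fitted over long
#' (`dt_long`) and short (`dt_short`) windows on each side; the apex angles
#' of the two triangles are multiplied and inverted into a probability-like
#' detection function.
#'
#' @param dt_long long-leg window length in ms
#' @param dt_short short-leg window length in ms
#' @param df_step DF sampling step in ms
#' @param kernel regression weighting window: `"gaussian"` (default) or
#'   `"flat"`
#' @param init_window span used to initialise the adaptive threshold (ms)
#' @param adapt_interval threshold adaptation interval (ms)
#' @param slope_estimator `"wls"` (weighted least squares, default) or
#'   `"eq7"` (the literal ratio-form kernel estimator; kept for comparison,
#'   it cannot recover the slope of an exact line on a symmetric window)
#' @param angle_mode `"legs"` (angle between the fitted legs, default) or
#'   `"ratio"` (arctangent of the slope ratio)
#' @param time_scale time constant (ms) converting normalized-amplitude
#'   slopes to dimensionless arguments before the arctangent
#' @param normalize divide each lead by its robust amplitude scale (median
#'   absolute deviation) before slope fitting, making detection invariant to
#'   common amplitude scaling
#' @param p_ceiling cap for the DF where both angles approach zero
#' @param update_trigger `"interval"`: update the threshold unconditionally
#'   every `adapt_interval`; `"maxima"`: additionally at strict 3-point local
#'   DF maxima
#' @export
detector_config <- function(dt_long = 61, dt_short = 20, df_step = 2,
                            kernel = c("gaussian", "flat"),
                            init_window = 2000, adapt_interval = 120,
                            slope_estimator = c("wls", "eq7"),
                            angle_mode = c("legs", "ratio"),
                            time_scale = 61, normalize = TRUE,
                            p_ceiling = 1e6,
                            update_trigger = c("interval", "maxima")) {
  stopifnot(dt_short < dt_long, df_step > 0)
  structure(list(dt_long = dt_long, dt_short = dt_short, df_step = df_step,
                 kernel = match.arg(kernel), init_window = init_window,
                 adapt_interval = adapt_interval,
                 slope_estimator = match.arg(slope_estimator),
                 angle_mode = match.arg(angle_mode),
                 time_scale = time_scale, normalize = normalize,
                 p_ceiling = p_ceiling,
                 update_trigger = match.arg(update_trigger)),
            class = "detector_config")
}

#' Kernel-weighted slope of a signal cloud in a time window
#'
#' Fits `y = m t` (plus intercept) to the samples falling in
#' `[window[1], window[2]]`, weighting by a window centred kernel.  Returns
#' `NA` (a flagged gap) when fewer than two samples fall in the window.
#'
#' @param nu an [nu_signal()]
#' @param lead lead index
#' @param window numeric `c(t_a, t_b)` in ms
#' @param kernel `"gaussian"` or `"flat"`
#' @param slope_estimator see [detector_config()]
#' @param anchor reference instant of the `"eq7"` estimator (defaults to the
#'   window end nearest the apex; unused for `"wls"`)
#' @return slope in amplitude units per ms
#' @export
fit_slope <- function(nu, lead = 1, window, kernel = "gaussian",
                      slope_estimator = "wls", anchor = NULL) {
  stopifnot(inherits(nu, "nu_signal"), length(window) == 2)
  ts <- nu$times
  i1 <- findInterval(window[1] - 1e-9, ts) + 1L
  i2 <- findInterval(window[2] + 1e-9, ts)
  if (i2 - i1 + 1L < 2L) return(NA_real_)
  tau <- ts[i1:i2]
  y <- as.numeric(nu$values[[lead]][i1:i2])
  w <- kernel_weights(tau, window, kernel)
  slope_kernel(tau, y, w, slope_estimator,
               anchor = if (is.null(anchor)) mean(window) else anchor)
}

kernel_weights <- function(tau, window, kernel) {
  if (kernel == "flat") return(rep(1, length(tau)))
  ctr <- mean(window)
  sigma <- (window[2] - window[1]) / 4
  exp(-((tau - ctr) / sigma)^2 / 2)
}

slope_kernel <- function(tau, y, w, slope_estimator, anchor) {
  if (slope_estimator == "eq7") {
    den <- sum(w * (tau - anchor))
    if (abs(den) < 1e-12) return(NA_real_)
    return(sum(w * (tau - anchor) * y) / den)
  }
  sw <- sum(w)
  tm <- sum(w * tau) / sw
  ym <- sum(w * y) / sw
  den <- sum(w * (tau - tm)^2)
  if (den < 1e-12) return(NA_real_)
  sum(w * (tau - tm) * (y - ym)) / den
}

#' Apex angle of two fitted triangle legs
#'
#' Default interpretation: the angle enclosed by the two legs,
#' `pi - |atan(m_plus) - atan(m_minus)|`, in `(0, pi]`: near `pi` on flat or
#' monotone stretches, small at a sharp peak where the legs fold back on
#' each other.  `mode = "ratio"` gives the literal arctangent of the slope
#' ratio.
#'
#' @param m_minus,m_plus leg slopes (dimensionless; normalize and scale
#'   before calling, see [detector_config()])
#' @param mode `"legs"` or `"ratio"`
#' @export
apex_angle <- function(m_minus, m_plus, mode = "legs") {
  if (mode == "ratio") return(atan(m_plus / m_minus))
  pi - abs(atan(m_plus) - atan(m_minus))
}

#' Detection function of a non-uniform ECG record
#'
#' Computes the regular-step detection function `p(t)`: per lead, apex
#' angles `L(t)` (long legs) and `M(t)` (short legs);
#' single lead `p = 1/(L M)`, multilead `p = 1 / sum_c (L_c M_c)^2`.
#' Leads are normalized by their robust amplitude scale and slopes by the
#' configured time constant before the arctangent.  Windows with fewer than
#' two samples carry the previous DF value forward.
#'
#' @param nu an [nu_signal()]
#' @param config a [detector_config()]
#' @return object of class `detection_function`: fields `grid` (ms), `p`,
#'   and after thresholding (see [detect_beats()]) `H`
#' @export
detection_function <- function(nu, config = detector_config()) {
  stopifnot(inherits(nu, "nu_signal"))
  dur <- signal_duration(nu)
  if (dur <= 2 * config$dt_long)
    stop("record shorter than twice the long window")
  t0 <- nu$times[1]
  grid <- seq(t0 + config$dt_long, t0 + dur - config$dt_long,
              by = config$df_step)
  ts <- nu$times
  nlead <- length(nu$values)
  angles_ok <- rep(TRUE, length(grid))
  lm_prod <- vector("list", nlead)
  for (lead in seq_len(nlead)) {
    y <- as.numeric(nu$values[[lead]])
    if (config$normalize) {
      sc <- stats::mad(y)
      if (sc <= 0) sc <- 1
      y <- (y - stats::median(y)) / sc
    }
    sL_m <- slope_sweep(ts, y, grid, config$dt_long, -1L, config)
    sL_p <- slope_sweep(ts, y, grid, config$dt_long, +1L, config)
    sM_m <- slope_sweep(ts, y, grid, config$dt_short, -1L, config)
    sM_p <- slope_sweep(ts, y, grid, config$dt_short, +1L, config)
    k <- config$time_scale
    L <- apex_angle(sL_m * k, sL_p * k, config$angle_mode)
    M <- apex_angle(sM_m * k, sM_p * k, config$angle_mode)
    lm <- L * M
    angles_ok <- angles_ok & !is.na(lm)
    lm_prod[[lead]] <- lm
  }
  p <- if (nlead == 1L) {
    1 / abs(lm_prod[[1]])
  } else {
    1 / Reduce(`+`, lapply(lm_prod, function(z) z^2))
  }
  p[!angles_ok] <- NA
  p <- pmin(p, config$p_ceiling)
  # gaps: carry the previous value forward
  if (anyNA(p)) {
    for (i in seq_along(p)) {
      if (is.na(p[i])) p[i] <- if (i > 1) p[i - 1] else 1 / pi^2
    }
  }
  structure(list(grid = grid, p = p, H = NULL, config = config),
            class = "detection_function")
}

# Sweep of kernel-weighted slopes over the DF grid; side = -1 fits the
# window [t - delta, t], side = +1 fits [t, t + delta].
slope_sweep <- function(ts, y, grid, delta, side, config) {
  n <- length(grid)
  out <- rep(NA_real_, n)
  a <- if (side < 0) grid - delta else grid
  b <- if (side < 0) grid else grid + delta
  i1 <- findInterval(a - 1e-9, ts) + 1L
  i2 <- findInterval(b + 1e-9, ts)
  gaussian <- config$kernel == "gaussian"
  sigma <- delta / 4
  eq7 <- config$slope_estimator == "eq7"
  for (k in seq_len(n)) {
    lo <- i1[k]; hi <- i2[k]
    if (hi - lo < 1L) next
    tau <- ts[lo:hi]
    yy <- y[lo:hi]
    ctr <- (a[k] + b[k]) / 2
    w <- if (gaussian) exp(-((tau - ctr) / sigma)^2 / 2) else rep(1, hi - lo + 1L)
    if (eq7) {
      d <- tau - grid[k]
      den <- sum(w * d)
      if (abs(den) > 1e-12) out[k] <- sum(w * d * yy) / den
    } else {
      sw <- sum(w)
      tm <- sum(w * tau) / sw
      ym <- sum(w * yy) / sw
      dt <- tau - tm
      den <- sum(w * dt * dt)
      if (den > 1e-12) out[k] <- sum(w * dt * (yy - ym)) / den
    }
  }
  out
}

#' One step of the adaptive threshold recursion
#'
#' `H = 0.9 H_prev + 0.1 (1/N) (sum of DF values above H_prev - sum of DF
#' values at or below H_prev)`, applied over the values of the last
#' adaptation interval.
#'
#' @param H_prev previous threshold value
#' @param values DF values in the adaptation interval
#' @param N divisor (defaults to `length(values)`)
#' @export
update_threshold <- function(H_prev, values, N = length(values)) {
  stopifnot(N >= 1)
  over <- values[values > H_prev]
  under <- values[values <= H_prev]
  0.9 * H_prev + 0.1 * (sum(over) - sum(under)) / N
}

#' Detect heartbeats in a non-uniform ECG record
#'
#' Thresholds the detection function adaptively.  The initial threshold is
#' taken from the first `init_window` of DF values (geometric midpoint of the
#' median and the maximum); afterwards the threshold is updated by
#' [update_threshold()] every `adapt_interval` (and additionally at strict
#' local DF maxima when configured).  One detection is emitted per upward
#' threshold crossing, timed at the DF maximum of the supra-threshold
#' excursion -- a unique per-beat landmark rather than a refined fiducial.
#'
#' @param nu an [nu_signal()]
#' @param config a [detector_config()]
#' @param df optionally a precomputed [detection_function()]
#' @return numeric vector of detection times (ms); the DF with its threshold
#'   trace is attached as attribute `"df"`
#' @export
detect_beats <- function(nu, config = detector_config(), df = NULL) {
  if (is.null(df)) df <- detection_function(nu, config)
  grid <- df$grid; p <- df$p
  n_init <- sum(grid - grid[1] < config$init_window)
  if (n_init < 2 || length(grid) <= n_init)
    stop("record shorter than the threshold initialisation window")
  if (diff(range(p)) < 1e-12) return(structure(numeric(0), df = df))
  p_init <- p[seq_len(n_init)]
  med <- stats::median(p_init)
  H0 <- sqrt(max(med, 1e-12) * max(max(p_init), 2 * med, 1e-9))
  per_upd <- max(1L, round(config$adapt_interval / config$df_step))
  H <- numeric(length(p))
  Hcur <- H0
  last_upd <- 0L
  maxima_mode <- config$update_trigger == "maxima"
  for (i in seq_along(p)) {
    due <- (i - last_upd) >= per_upd
    is_max <- maxima_mode && i > 2L &&
      p[i - 1] > p[i - 2] && p[i - 1] > p[i]
    if ((due || is_max) && i > 1L) {
      vals <- p[max(1L, i - per_upd):(i - 1L)]
      Hcur <- update_threshold(Hcur, vals)
      last_upd <- i
    }
    H[i] <- Hcur
  }
  up <- which(p[-1] > H[-1] & p[-length(p)] <= H[-length(p)]) + 1L
  det <- numeric(0)
  for (i in up) {
    j <- i
    while (j < length(p) && p[j] > H[j]) j <- j + 1L
    seg <- i:j
    det <- c(det, grid[seg[which.max(p[seg])]])
  }
  det <- unique(det)
  df$H <- H
  attr(det, "df") <- df
  det
}
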