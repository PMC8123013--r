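#' Standardized local bandwidth (SLB) profiles
#'
#' An SLB profile states, over one normalized beat cycle, the local sampling
#' frequency the arbitrary sampling model assigns to each phase of the
#' heartbeat.  The cycle coordinate runs from 0 (midpoint of the preceding RR
#' interval) to 1 (midpoint of the following one); five anchor fractions mark
#' the wave delimitation points (P-onset, P-end, QRS-onset, QRS-end, T-end).
#' Between knots the frequency is linear.  Projecting the profile onto a
#' concrete beat warps the cycle coordinate so the anchors coincide with the
#' beat's actual borders.
#'
#' The default template keeps the full source rate over the QRS, intermediate
#' rates over P and T, and the floor rate over iso-electric segments, with
#' short linear ramps at the transitions; the published perceptual relevance
#' profile it emulates is not itself public, and the whole chain is designed
#' to work with any profile within the declared frequency bounds.
#'
#' @param f_min,f_max frequency bounds in Hz (defaults 100 and 500)
#' @param f_p,f_t sampling frequency over the P and T waves (Hz)
#' @param anchors normalized cycle positions of the five border anchors
#' @param ramp normalized half-width of the linear transitions
#' @return an object of class `slb_profile` with fields `knots`
#'   (data frame `u`, `f`), `anchors`, `f_min`, `f_max`
#' @export
slb_profile <- function(f_min = 100, f_max = 500, f_p = 180, f_t = 130,
                        anchors = c(p_on = 0.241, p_end = 0.385,
                                    qrs_on = 0.443, qrs_end = 0.557,
                                    t_end = 0.900),
                        ramp = 0.014) {
  stopifnot(f_min > 0, f_max >= f_min, all(diff(anchors) > 0),
            anchors[1] > ramp, anchors[5] < 1 - ramp)
  clamp <- function(f) pmin(pmax(f, f_min), f_max)
  u <- c(0, anchors[["p_on"]] - ramp, anchors[["p_on"]], anchors[["p_end"]],
         anchors[["qrs_on"]], anchors[["qrs_end"]],
         anchors[["qrs_end"]] + ramp, anchors[["t_end"]],
         anchors[["t_end"]] + ramp, 1)
  f <- clamp(c(f_min, f_min, f_p, f_p, f_max, f_max, f_t, f_t, f_min, f_min))
  structure(list(knots = data.frame(u = u, f = f), anchors = anchors,
                 f_min = f_min, f_max = f_max),
            class = "slb_profile")
}

#' @export
print.slb_profile <- function(x, ...) {
  cat(sprintf("SLB profile: %g-%g Hz, %d knots, anchors at %s\n",
              x$f_min, x$f_max, nrow(x$knots),
              paste(sprintf("%.3f", x$anchors), collapse = " ")))
  invisible(x)
}

#' Evaluate an SLB template at normalized cycle positions
#' @param profile an [slb_profile()]
#' @param u positions in \[0, 1\]
#' @export
slb_template_at <- function(profile, u) {
  stats::approx(profile$knots$u, profile$knots$f, xout = pmin(pmax(u, 0), 1),
                rule = 2)$y
}

#' Read or write an SLB profile as JSON
#'
#' The JSON schema is `{f_min, f_max, anchors: [...5 fractions...],
#' segments: [{from, to, f_start, f_end}, ...]}` over the normalized cycle.
#' @param path file path
#' @export
read_slb_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- j$segments
  u <- c(seg$from, seg$to[nrow(seg)])
  f <- c(seg$f_start, seg$f_end[nrow(seg)])
  anchors <- stats::setNames(as.numeric(j$anchors),
                             c("p_on", "p_end", "qrs_on", "qrs_end", "t_end"))
  structure(list(knots = data.frame(u = u, f = f), anchors = anchors,
                 f_min = j$f_min, f_max = j$f_max),
            class = "slb_profile")
}

#' @rdname read_slb_json
#' @param profile an [slb_profile()]
#' @export
write_slb_json <- function(profile, path) {
  k <- profile$knots
  n <- nrow(k)
  jsonlite::write_json(
    list(f_min = profile$f_min, f_max = profile$f_max,
         anchors = as.numeric(profile$anchors),
         segments = data.frame(from = k$u[-n], to = k$u[-1],
                               f_start = k$f[-n], f_end = k$f[-1])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Project an SLB template onto one concrete beat
#'
#' Warps the normalized cycle so that the five anchors land on the beat's
#' actual wave borders; the segment covered runs from the midpoint of the
#' preceding RR interval to the midpoint of the following one.  The default
#' warp is piecewise linear between control points; `warp = "spline"` uses a
#' monotone cubic warp through the same control points (the three-step
#' scaling-transform variant).
#'
#' @param profile an [slb_profile()]
#' @param borders the beat's [wave_borders()] in absolute ms (P/T may be
#'   absent; absent anchors are interpolated between their neighbours)
#' @param rr_context numeric `c(prev_fiducial, this_fiducial, next_fiducial)`
#'   in ms
#' @param warp `"linear"` or `"spline"`
#' @return a `beat_slb`: data frame of knots `(t, f)` with strictly
#'   increasing `t`, frequencies within the profile bounds
#' @export
project_slb <- function(profile, borders, rr_context,
                        warp = c("linear", "spline")) {
  warp <- match.arg(warp)
  stopifnot(inherits(profile, "slb_profile"), length(rr_context) == 3)
  seg_start <- mean(rr_context[1:2])
  seg_end <- mean(rr_context[2:3])
  bt <- c(borders$p_on, borders$p_end, borders$qrs_on, borders$qrs_end,
          borders$t_end)
  ua <- as.numeric(profile$anchors)
  # absent P/T anchors: keep them at their template-proportional position
  # between the surrounding present control points
  ctrl_u <- c(0, ua, 1)
  ctrl_t <- c(seg_start, bt, seg_end)
  known <- !is.na(ctrl_t)
  ctrl_t[!known] <- stats::approx(ctrl_u[known], ctrl_t[known],
                                  xout = ctrl_u[!known])$y
  # waves may overrun the RR midpoints around premature beats; extend the
  # segment so the profile stays anchored (overlaps between adjacent beats
  # are resolved by slb_series_fun, which keeps the denser requirement)
  if (min(ctrl_t, na.rm = TRUE) < ctrl_t[1])
    ctrl_t[1] <- min(ctrl_t, na.rm = TRUE) - 1
  if (max(ctrl_t, na.rm = TRUE) > ctrl_t[length(ctrl_t)])
    ctrl_t[length(ctrl_t)] <- max(ctrl_t, na.rm = TRUE) + 1
  if (rr_context[2] < ctrl_t[1] || rr_context[2] > ctrl_t[length(ctrl_t)])
    stop("borders fall outside the RR context segment")
  if (any(diff(ctrl_t) <= 0))
    stop("borders are not ordered within the RR context segment")
  warp_fun <- if (warp == "linear") {
    function(u) stats::approx(ctrl_u, ctrl_t, xout = u, rule = 2)$y
  } else {
    stats::splinefun(ctrl_u, ctrl_t, method = "hyman")
  }
  if (warp == "linear") {
    u <- sort(unique(c(profile$knots$u, ctrl_u)))
    knots <- data.frame(t = warp_fun(u), f = slb_template_at(profile, u))
  } else {
    u <- sort(unique(c(profile$knots$u, ctrl_u,
                       seq(0, 1, length.out = 41))))
    knots <- data.frame(t = warp_fun(u), f = slb_template_at(profile, u))
  }
  keep <- c(TRUE, diff(knots$t) > 1e-9)
  knots <- knots[keep, , drop = FALSE]
  structure(list(knots = knots, f_min = profile$f_min, f_max = profile$f_max),
            class = "beat_slb")
}

#' Evaluate a projected beat SLB at absolute times
#' @param bslb a `beat_slb` from [project_slb()]
#' @param t times in ms
#' @export
beat_slb_at <- function(bslb, t) {
  stats::approx(bslb$knots$t, bslb$knots$f, xout = t, rule = 2)$y
}

#' Assemble a record-level local sampling frequency function
#'
#' Concatenates per-beat SLB projections, clipping each at the RR midpoints
#' (its own segment) and filling uncovered spans -- record edges and beats
#' without borders -- with `f_fill` (the full source rate, so rare or
#' unclassifiable beats lose nothing).
#'
#' @param slb_series list of `beat_slb`
#' @param duration record duration in ms
#' @param f_fill frequency for uncovered spans (Hz)
#' @return a function `f(t)` returning Hz at any vector of times
#' @export
slb_series_fun <- function(slb_series, duration, f_fill = 500) {
  slb_series <- Filter(Negate(is.null), slb_series)
  if (!length(slb_series)) return(function(t) rep(f_fill, length(t)))
  # evaluate every beat profile on a common fine grid; where profiles of
  # adjacent beats overlap (waves overrunning the RR midpoints) the denser
  # requirement wins
  grid <- seq(0, duration, by = 2)
  f <- rep(NA_real_, length(grid))
  for (b in slb_series) {
    lo <- b$knots$t[1]; hi <- b$knots$t[nrow(b$knots)]
    sel <- grid >= lo & grid <= hi
    if (!any(sel)) next
    fb <- stats::approx(b$knots$t, b$knots$f, xout = grid[sel])$y
    f[sel] <- pmax(f[sel], fb, na.rm = TRUE)
  }
  f[is.na(f)] <- f_fill
  function(t) stats::approx(grid, f, xout = t, rule = 2)$y
}
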