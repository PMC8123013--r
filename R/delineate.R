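#' Delineator configuration
#'
#' Thresholds and search windows of the P/QRS/T delineator.  Border
#' placement works on the slotted time-scale coefficients: significant
#' extrema are qualified against a fraction of the dominant extremum with an
#' analytic noise floor; borders are then located from the stable landmark
#' geometry (decay crossings for the QRS, zero-crossing spans for P, the
#' zero-crossing/side-lobe distance for T-end), linearly interpolated to
#' real-valued ms.  All constants were calibrated once on the synthetic
#' suite and frozen.
#'
#' @param qrs_scale,p_scale,t_scales dyadic scales used per wave
#' @param qrs_halfwin QRS search half-window around the detection point (ms)
#' @param p_win_rr P search window start as a fraction of the local RR
#'   before QRS onset
#' @param p_gap gap kept between the P window and QRS onset (ms)
#' @param t_start offset of the T window after QRS end (ms)
#' @param t_win_rr T window length as a fraction of the local RR
#' @param gq decay fraction of the outer QRS extrema locating onset/end
#' @param dq symmetric offset added outward to both QRS borders (ms)
#' @param kp_on,kp_end multiples of the P-lobe zero-crossing half-span
#'   locating P onset/end from the lobe centre
#' @param gt decay fraction of the dominant T extremum locating T-end
#' @param dt_t offset added to the T-end decay crossing (ms)
#' @param qual_qrs,qual_p,qual_t significance fractions of the dominant
#'   extremum when qualifying peaks
#' @param presence_snr dominant-extremum multiple of the coefficient noise
#'   floor required for a wave to count as present
#' @param rel_floor_p,rel_floor_t additional presence floors for P and T as
#'   fractions of the record-wide coefficient magnitude at their scale
#'   (rejecting residual tails of neighbouring complexes on clean signals)
#' @param qual_snr,cross_snr noise-floor multiples flooring the
#'   qualification and crossing levels
#' @export
delineator_config <- function(qrs_scale = 2, p_scale = 3, t_scales = c(4, 5),
                              qrs_halfwin = 110, p_win_rr = 0.35, p_gap = 24,
                              t_start = 80, t_win_rr = 0.6,
                              gq = 0.06, dq = -2.37,
                              kp_on = 2.30, kp_end = 2.13, gt = 0.30, dt_t = 66.5,
                              qual_qrs = 0.08, qual_p = 0.35, qual_t = 0.3,
                              presence_snr = 4, qual_snr = 3.5,
                              cross_snr = 2.5,
                              rel_floor_p = 0.006, rel_floor_t = 0.006) {
  structure(as.list(environment()), class = "delineator_config")
}

# slice one scale of a time_scale_grid to a window, 3-point smoothed
tsg_window <- function(tsg, scale, lo, hi) {
  s <- tsg$scales[[as.character(scale)]]
  if (is.null(s)) stop("scale ", scale, " not present in the transform")
  sel <- which(s$b >= lo & s$b <= hi)
  if (length(sel) < 3) return(NULL)
  cc <- s$c[sel]
  cc[is.na(cc)] <- 0
  n <- length(cc)
  sm <- cc
  sm[2:(n - 1)] <- 0.25 * cc[1:(n - 2)] + 0.5 * cc[2:(n - 1)] + 0.25 * cc[3:n]
  list(b = s$b[sel], c = sm, noise = s$noise * 0.61,
       cmax = if (is.finite(s$cmax)) s$cmax else 0)
}

# indices of interior extrema of a series
series_extrema <- function(c) {
  n <- length(c)
  if (n < 3) return(integer(0))
  d1 <- c[2:(n - 1)] - c[1:(n - 2)]
  d2 <- c[3:n] - c[2:(n - 1)]
  which(d1 * d2 <= 0 & d1 != 0) + 1L
}

# crossing of |c| below `level`, scanning outward from extremum i0
decay_crossing <- function(b, c, i0, level, dir) {
  ac <- abs(c)
  i <- i0
  while (i + dir >= 1 && i + dir <= length(c)) {
    if (ac[i + dir] < level && level <= ac[i]) {
      f <- (ac[i] - level) / (ac[i] - ac[i + dir])
      return(b[i] + f * (b[i + dir] - b[i]))
    }
    i <- i + dir
  }
  b[min(max(i, 1), length(b))]
}

# zero crossing scanning from index i in direction dir, NA if none
zero_crossing <- function(b, c, i, dir) {
  j <- i
  while (j + dir >= 1 && j + dir <= length(c)) {
    if (c[j] == 0) return(b[j])
    if (c[j] * c[j + dir] < 0) {
      f <- abs(c[j]) / (abs(c[j]) + abs(c[j + dir]))
      return(b[j] + f * (b[j + dir] - b[j]))
    }
    j <- j + dir
  }
  NA_real_
}

#' Delineate the QRS complex of one beat
#'
#' In the QRS scale of the transform, the pair of outermost significant
#' extrema of opposite polarity around the detection point brackets the
#' complex; onset and end are the outward decay crossings of the coefficient
#' magnitude, expressed as real-valued ms.
#'
#' @param tsg a [nuts_transform()] grid containing the QRS scale
#' @param detection_time beat detection point (ms)
#' @param config a [delineator_config()]
#' @return list `qrs_on`, `qrs_end` (ms), or `NULL` when no qualifying pair
#'   exists (flat or unqualified beat)
#' @export
delineate_qrs <- function(tsg, detection_time, config = delineator_config()) {
  w <- tsg_window(tsg, config$qrs_scale,
                  detection_time - config$qrs_halfwin,
                  detection_time + config$qrs_halfwin)
  if (is.null(w)) return(NULL)
  ex <- series_extrema(w$c)
  if (!length(ex)) return(NULL)
  dom <- ex[which.max(abs(w$c[ex]))]
  if (abs(w$c[dom]) < config$presence_snr * w$noise) return(NULL)
  sig <- ex[abs(w$c[ex]) >= pmax(config$qual_qrs * abs(w$c[dom]),
                                 config$qual_snr * w$noise)]
  if (length(sig) >= 2 && !any(sign(w$c[sig]) != sign(w$c[sig[1]])))
    sig <- sig # single-polarity complexes are still delineated
  A <- sig[1]; B <- sig[length(sig)]
  on <- decay_crossing(w$b, w$c, A,
                       max(config$gq * abs(w$c[A]), config$cross_snr * w$noise),
                       -1L) - config$dq
  end <- decay_crossing(w$b, w$c, B,
                        max(config$gq * abs(w$c[B]), config$cross_snr * w$noise),
                        +1L) + config$dq
  list(qrs_on = on, qrs_end = end)
}

#' Delineate the T wave of one beat
#'
#' Searches the window after QRS end in the first T scale; on failure the
#' next scale is tried.  The dominant interior extremum marks the T lobe;
#' the zero crossing following it and the next side-lobe extremum give the
#' T-end by the calibrated landmark geometry.  Qualification is
#' sign-agnostic, so inverted T waves delineate identically.
#'
#' @param tsg a [nuts_transform()] grid
#' @param qrs_end QRS end of the beat (ms)
#' @param local_rr local RR interval (ms)
#' @param config a [delineator_config()]
#' @return list `t_end`, `t_peak`, `present`
#' @export
delineate_t <- function(tsg, qrs_end, local_rr = 750,
                        config = delineator_config()) {
  for (a in config$t_scales) {
    # fallback scales sit farther from the T band and must show stronger
    # evidence before a wave is accepted
    floor_t <- config$rel_floor_t * 2^(match(a, config$t_scales) - 1)
    # the window reaches back towards the QRS so the T lobe forms an
    # interior extremum, but only extrema past t_start may dominate
    w <- tsg_window(tsg, a, qrs_end + config$t_start - 40,
                    qrs_end + config$t_win_rr * local_rr)
    if (is.null(w)) next
    ex <- series_extrema(w$c)
    ex <- ex[w$b[ex] >= qrs_end + config$t_start]
    if (!length(ex)) next
    dom <- ex[which.max(abs(w$c[ex]))]
    step <- w$b[2] - w$b[1]
    if (abs(w$c[dom]) < max(config$presence_snr * w$noise,
                            floor_t * w$cmax)) next
    if (w$b[dom] >= w$b[length(w$b)] - step) next # tail running into window edge
    tend <- decay_crossing(w$b, w$c, dom,
                           max(config$gt * abs(w$c[dom]),
                               config$cross_snr * w$noise), +1L) + config$dt_t
    return(list(t_end = tend, t_peak = w$b[dom], present = TRUE))
  }
  list(t_end = NA_real_, t_peak = NA_real_, present = FALSE)
}

#' Delineate the P wave of one beat
#'
#' Searches the window before QRS onset (scaled by the local RR) in the P
#' scale.  A present P wave shows a dominant interior extremum well clear of
#' the window edges; its flanking zero crossings give the lobe centre and
#' half-span, from which onset and end follow by the calibrated span
#' multipliers.
#'
#' @param tsg a [nuts_transform()] grid
#' @param qrs_on QRS onset of the beat (ms)
#' @param local_rr local RR interval (ms)
#' @param config a [delineator_config()]
#' @return list `p_on`, `p_end`, `present`
#' @export
delineate_p <- function(tsg, qrs_on, local_rr = 750,
                        config = delineator_config()) {
  absent <- list(p_on = NA_real_, p_end = NA_real_, present = FALSE)
  w <- tsg_window(tsg, config$p_scale, qrs_on - config$p_win_rr * local_rr,
                  qrs_on - config$p_gap)
  if (is.null(w)) return(absent)
  ex <- series_extrema(w$c)
  if (!length(ex)) return(absent)
  dom <- ex[which.max(abs(w$c[ex]))]
  step <- w$b[2] - w$b[1]
  if (abs(w$c[dom]) < max(config$presence_snr * w$noise,
                          config$rel_floor_p * w$cmax)) return(absent)
  if (w$b[dom] <= w$b[1] + step || w$b[dom] >= w$b[length(w$b)] - step)
    return(absent) # edge maxima are tails of neighbouring waves
  zl <- zero_crossing(w$b, w$c, dom, -1L)
  zr <- zero_crossing(w$b, w$c, dom, +1L)
  if (is.na(zl) || is.na(zr) || zr <= zl) return(absent)
  ctr <- (zl + zr) / 2
  half <- (zr - zl) / 2
  list(p_on = ctr - config$kp_on * half, p_end = ctr + config$kp_end * half,
       present = TRUE)
}

#' Delineate one beat
#'
#' Runs the QRS, T and P delineation of one beat on a precomputed transform.
#'
#' @param tsg a [nuts_transform()] grid with the configured scales
#' @param detection_time beat detection point (ms)
#' @param local_rr local RR interval (ms)
#' @param config a [delineator_config()]
#' @return a [wave_borders()] or `NULL` when the QRS cannot be delineated
#' @export
delineate_beat <- function(tsg, detection_time, local_rr = 750,
                           config = delineator_config()) {
  q <- delineate_qrs(tsg, detection_time, config)
  if (is.null(q)) return(NULL)
  tw <- delineate_t(tsg, q$qrs_end, local_rr, config)
  pw <- delineate_p(tsg, q$qrs_on, local_rr, config)
  p_on <- pw$p_on; p_end <- pw$p_end
  if (pw$present && (p_end > q$qrs_on)) { p_on <- NA_real_; p_end <- NA_real_ }
  t_end <- if (tw$present && tw$t_end > q$qrs_end) tw$t_end else NA_real_
  wave_borders(qrs_on = q$qrs_on, qrs_end = q$qrs_end,
               p_on = p_on, p_end = p_end, t_end = t_end)
}

#' Delineate all beats of a record
#'
#' Computes the per-lead transforms once, delineates every beat in every
#' requested lead and fuses the per-lead borders (mean of the leads where
#' the wave was found; a wave is present when any lead finds it).
#'
#' @param nu an [nu_signal()]
#' @param detections beat detection times (ms)
#' @param leads lead indices (default: all)
#' @param config a [delineator_config()]
#' @return a [borders_table()] (rows of `NA` for undelineated beats)
#' @export
delineate_record <- function(nu, detections, leads = NULL,
                             config = delineator_config()) {
  if (is.null(leads)) leads <- seq_along(nu$values)
  scales <- sort(unique(c(config$qrs_scale, config$p_scale, config$t_scales)))
  tsgs <- lapply(leads, function(l) nuts_transform(nu, l, scales = scales))
  n <- length(detections)
  rr <- if (n > 1) stats::median(diff(detections)) else 750
  fuse <- function(vals) {
    vals <- vals[!is.na(vals)]
    if (!length(vals)) NA_real_ else mean(vals)
  }
  borders <- vector("list", n)
  for (k in seq_len(n)) {
    local_rr <- if (n > 1) {
      iv <- c(if (k > 1) detections[k] - detections[k - 1],
              if (k < n) detections[k + 1] - detections[k])
      stats::median(iv)
    } else rr
    per_lead <- lapply(tsgs, function(tsg)
      delineate_beat(tsg, detections[k], local_rr, config))
    per_lead <- Filter(Negate(is.null), per_lead)
    if (!length(per_lead)) next
    g <- function(f) fuse(vapply(per_lead, function(b) b[[f]], numeric(1)))
    p_on <- g("p_on"); p_end <- g("p_end")
    if (is.na(p_on) || is.na(p_end) || p_on >= p_end) p_on <- p_end <- NA_real_
    qrs_on <- g("qrs_on"); qrs_end <- g("qrs_end")
    t_end <- g("t_end")
    if (!is.na(p_end) && p_end > qrs_on) { p_on <- NA_real_; p_end <- NA_real_ }
    if (!is.na(t_end) && t_end <= qrs_end) t_end <- NA_real_
    borders[[k]] <- tryCatch(
      wave_borders(qrs_on = qrs_on, qrs_end = qrs_end, p_on = p_on,
                   p_end = p_end, t_end = t_end),
      error = function(e) NULL)
  }
  borders_table(detections, borders)
}
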