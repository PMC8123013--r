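#' Project a uniform record onto an arbitrary non-uniform grid
#'
#' Emits sample instants by forward integration of the local sampling
#' interval, `t[k+1] = t[k] + 1000/f(t[k])`, where `f` is the record-level
#' local sampling frequency assembled from per-beat SLB projections.  Each
#' emitted value is the source signal -- low-pass filtered to a cutoff of
#' `0.45 * f(t)` when anti-aliasing is on and the local rate is below the
#' source rate -- interpolated with cubic splines at the emitted instant and
#' re-quantized.
#'
#' @param signal a [uniform_signal()]
#' @param slb_series list of `beat_slb` (one per beat, from
#'   [project_slb()]), or a single `beat_slb`, or `NULL` for a constant-rate
#'   grid at `f_fill`
#' @param antialias apply the adaptive anti-aliasing filter bank
#' @param f_fill rate for spans not covered by any beat profile (Hz)
#' @return an [nu_signal()] (`model = "nECG"`, or `"pECG"` when the grid is
#'   constant at the source rate)
#' @export
sample_nonuniform <- function(signal, slb_series = NULL, antialias = TRUE,
                              f_fill = 500) {
  stopifnot(inherits(signal, "uniform_signal"))
  dur <- signal_duration(signal)
  if (inherits(slb_series, "beat_slb")) slb_series <- list(slb_series)
  f_of_t <- slb_series_fun(slb_series, dur, f_fill = f_fill)
  # forward integration of the local interval
  t_max <- dur - 1000 / signal$fs
  times <- numeric(ceiling(dur * signal$fs / 1000) + 1L)
  k <- 1L; times[1] <- 0
  while (TRUE) {
    f_here <- f_of_t(times[k])
    if (f_here > signal$fs + 1e-9)
      stop(sprintf("local sampling frequency %.1f Hz exceeds the source rate %g Hz",
                   f_here, signal$fs))
    nxt <- times[k] + 1000 / f_here
    if (nxt > t_max + 1e-9) break
    k <- k + 1L
    times[k] <- nxt
  }
  times <- times[seq_len(k)]
  f_local <- f_of_t(times)
  t_src <- uniform_times(signal)
  values <- lapply(signal$values, function(v) {
    bank <- antialias_bank(v, signal$fs, antialias)
    pick <- bank$pick(f_local)
    out <- numeric(length(times))
    for (lev in unique(pick)) {
      sel <- pick == lev
      sf <- stats::splinefun(t_src, bank$filtered[[lev]], method = "fmm")
      out[sel] <- sf(times[sel])
    }
    round(out)
  })
  model <- if (length(slb_series) == 0 && f_fill == signal$fs) "pECG" else "nECG"
  nu_signal(times, values, gain = signal$gain,
            lead_names = signal$lead_names, model = model)
}

# Zero-phase Butterworth filter bank for adaptive anti-aliasing.  One
# filtered copy of the lead per cutoff level; level 1 is the unfiltered
# signal, used wherever the local rate reaches the source rate (nothing to
# remove there).  pick() maps local frequencies to the level whose design
# rate is nearest in log space.
antialias_bank <- function(v, fs, antialias, rates = c(100, 140, 200, 280, 400)) {
  rates <- rates[rates < fs]
  if (!antialias || !length(rates)) {
    return(list(filtered = list(as.numeric(v)),
                pick = function(f) rep(1L, length(f))))
  }
  filtered <- c(list(as.numeric(v)), lapply(rates, function(r) {
    bf <- signal::butter(4, (0.45 * r) / (fs / 2), type = "low")
    as.numeric(signal::filtfilt(bf, as.numeric(v)))
  }))
  list(
    filtered = filtered,
    pick = function(f) {
      idx <- integer(length(f))
      full <- f >= fs * (1 - 1e-9)
      idx[full] <- 1L
      if (any(!full)) {
        d <- abs(outer(log(f[!full]), log(rates), "-"))
        idx[!full] <- apply(d, 1, which.min) + 1L
      }
      idx
    })
}

#' Project a non-uniform record back to a uniform grid
#'
#' Cubic-spline interpolation of each lead at the regular target grid,
#' followed by adaptive anti-aliasing smoothing wherever the local density of
#' the non-uniform grid falls below the target rate.  Mirrors the inverse
#' projection the four-variant cross-check calls "uniformized" (uECG); edge
#' regions inherit the usual zero-phase filter transients.
#'
#' @param nu an [nu_signal()]
#' @param fs target sampling frequency in Hz
#' @param antialias apply density-matched smoothing
#' @return a [uniform_signal()] spanning the record
#' @export
uniformize <- function(nu, fs, antialias = TRUE) {
  stopifnot(inherits(nu, "nu_signal"))
  if (length(nu$times) < 4) stop("record too short to uniformize")
  t0 <- nu$times[1]
  n_new <- floor((nu$times[length(nu$times)] - t0) * fs / 1000) + 1
  t_new <- t0 + (seq_len(n_new) - 1) * 1000 / fs
  # local density of the source grid at the target instants
  iv <- diff(nu$times)
  mid <- nu$times[-length(nu$times)] + iv / 2
  f_loc <- stats::approx(mid, 1000 / iv, xout = t_new, rule = 2)$y
  values <- lapply(nu$values, function(v) {
    base <- stats::spline(nu$times, v, xout = t_new, method = "fmm")$y
    bank <- antialias_bank(base, fs, antialias)
    pick <- bank$pick(f_loc)
    out <- base
    for (lev in setdiff(unique(pick), 1L)) {
      sel <- pick == lev
      out[sel] <- bank$filtered[[lev]][sel]
    }
    round(out)
  })
  out <- uniform_signal(values, fs = fs, gain = nu$gain,
                        lead_names = nu$lead_names, t0 = t0)
  out$model <- "uECG"
  out
}

#' Compression ratio of a non-uniform representation
#'
#' Ratio of the uniform sample count to the non-uniform sample count over the
#' same span.
#'
#' @param uniform a [uniform_signal()]
#' @param nu an [nu_signal()]
#' @export
compression_ratio <- function(uniform, nu) {
  stopifnot(inherits(uniform, "uniform_signal"), inherits(nu, "nu_signal"))
  n_u <- length(uniform$values[[1]])
  n_n <- length(nu$times)
  if (n_u == 0 || n_n == 0) stop("cannot compute a compression ratio of an empty record")
  n_u / n_n
}
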