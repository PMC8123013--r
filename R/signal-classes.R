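#' Core signal containers
#'
#' `uniform_signal()` and `nu_signal()` are the two record containers used
#' throughout the package.  A uniform record holds per-lead integer-quantized
#' amplitude vectors on a regular grid declared by its sampling frequency; a
#' non-uniform record stores explicit real-valued sample instants (one shared
#' time grid for all leads) next to the quantized values.  Times are always
#' milliseconds from record start, amplitudes are integer counts scaled by
#' `gain` microvolts per least significant bit.
#'
#' @param values list of per-lead integer amplitude vectors (equal lengths)
#' @param fs sampling frequency in Hz (uniform records)
#' @param times strictly increasing sample instants in ms (non-uniform records)
#' @param gain quantization step in microvolts per LSB
#' @param lead_names character vector naming the leads
#' @param t0 record start time in ms
#' @param model optional name of the sampling model that produced the record
#'   (e.g. `"pECG"` for a pseudo-non-uniform constant-interval record)
#' @return an object of class `uniform_signal` or `nu_signal`
#' @export
uniform_signal <- function(values, fs, gain = 2.5, lead_names = NULL, t0 = 0) {
  if (!is.list(values)) values <- list(values)
  n <- unique(vapply(values, length, integer(1)))
  if (length(n) != 1L)
    stop("all leads must have the same length")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (gain <= 0) stop("gain must be positive")
  if (is.null(lead_names)) lead_names <- paste0("lead", seq_along(values))
  values <- lapply(values, function(v) as.integer(round(v)))
  structure(
    list(values = values, fs = fs, gain = gain,
         lead_names = lead_names, t0 = t0),
    class = "uniform_signal")
}

#' @rdname uniform_signal
#' @export
nu_signal <- function(times, values, gain = 2.5, lead_names = NULL,
                      model = NULL) {
  if (!is.list(values)) values <- list(values)
  n <- unique(vapply(values, length, integer(1)))
  if (length(n) != 1L)
    stop("all leads must have the same length")
  if (length(times) != n)
    stop("times and values must have the same length per lead")
  if (n > 1L && any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    stop(sprintf("times must be strictly increasing (violated at sample %d)",
                 bad))
  }
  if (gain <= 0) stop("gain must be positive")
  if (is.null(lead_names)) lead_names <- paste0("lead", seq_along(values))
  values <- lapply(values, function(v) as.integer(round(v)))
  structure(
    list(times = as.numeric(times), values = values, gain = gain,
         lead_names = lead_names, model = model),
    class = "nu_signal")
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("uniform ECG record: %d leads x %d samples @ %g Hz (%.1f s), gain %g uV/LSB\n",
              length(x$values), length(x$values[[1]]), x$fs,
              length(x$values[[1]]) / x$fs, x$gain))
  invisible(x)
}

#' @export
print.nu_signal <- function(x, ...) {
  n <- length(x$times)
  span <- if (n > 1) diff(range(x$times)) / 1000 else 0
  cat(sprintf("non-uniform ECG record: %d leads x %d samples over %.1f s, gain %g uV/LSB\n",
              length(x$values), n, span, x$gain))
  if (n > 2) {
    iv <- diff(x$times)
    cat(sprintf("  sample interval %.3f-%.3f ms%s\n", min(iv), max(iv),
                if (is_pseudo_nonuniform(x)) " (pseudo-non-uniform)" else ""))
  }
  invisible(x)
}

#' Sample times of a uniform record
#' @param x a `uniform_signal`
#' @return numeric vector of instants in ms
#' @export
uniform_times <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  x$t0 + (seq_along(x$values[[1]]) - 1) * 1000 / x$fs
}

#' Record duration in ms
#' @param x a `uniform_signal` or `nu_signal`
#' @export
signal_duration <- function(x) {
  if (inherits(x, "uniform_signal"))
    length(x$values[[1]]) * 1000 / x$fs
  else diff(range(x$times))
}

#' Detect a pseudo-non-uniform (constant-interval) record
#'
#' A uniform record stored in `{t, v}` form (the pECG variant) carries a
#' constant sample interval; such records are accepted everywhere a
#' non-uniform record is, and this predicate flags them.
#'
#' @param x an `nu_signal`
#' @param tol relative tolerance on interval constancy
#' @export
is_pseudo_nonuniform <- function(x, tol = 1e-9) {
  stopifnot(inherits(x, "nu_signal"))
  if (length(x$times) < 3) return(TRUE)
  iv <- diff(x$times)
  diff(range(iv)) <= tol * mean(iv)
}

#' Store a uniform record in non-uniform form (pECG)
#'
#' Attaches the constant-interval time grid to the samples, producing a
#' pseudo-non-uniform record suitable for the non-uniform processing chain.
#'
#' @param x a `uniform_signal`
#' @return an `nu_signal` with `model = "pECG"`
#' @export
as_pseudo_nonuniform <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  nu_signal(uniform_times(x), x$values, gain = x$gain,
            lead_names = x$lead_names, model = "pECG")
}

#' Beat annotation sets
#'
#' An annotation set is an ordered table of beat instants and single-character
#' beat labels.  The default vocabulary is the 14 MITDB beat symbols handled
#' by the interpretation chain plus `"?"` for unknown.
#'
#' @param times beat instants in ms (non-decreasing)
#' @param labels character labels, one per beat
#' @param vocabulary allowed labels
#' @export
annotation_set <- function(times, labels,
                           vocabulary = mitdb_labels()) {
  if (length(times) != length(labels))
    stop("times and labels must have equal length")
  if (length(times) > 1 && any(diff(times) < 0))
    stop("annotation times must be non-decreasing")
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), vocabulary)
  if (length(bad))
    stop("labels outside vocabulary: ", paste(bad, collapse = ", "))
  structure(list(times = as.numeric(times), labels = labels,
                 vocabulary = vocabulary),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation set: %d beats (%s)\n", length(x$times),
              paste(sprintf("%s=%d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = " ")))
  invisible(x)
}

#' The 14 MITDB beat labels handled by the chain
#'
#' Paced and pacemaker-fusion beats are outside the scope of the sampling
#' model and are not part of the vocabulary.
#' @param synthetic also include the synthetic generator's labels
#' @export
mitdb_labels <- function(synthetic = TRUE) {
  base <- c("N", "L", "R", "A", "j", "x", "a", "J", "e", "V", "!", "E", "F", "Q")
  if (synthetic) unique(c(base, "?")) else base
}

#' Wave border sets
#'
#' The five diagnostic wave delimitation points of one heartbeat, real-valued
#' in ms.  P and T waves may be absent; their fields are `NA` then.  When all
#' points are present they satisfy
#' `p_on < p_end <= qrs_on < qrs_end < t_end`.
#'
#' @param qrs_on,qrs_end QRS onset and end (ms), required
#' @param p_on,p_end P-wave onset and end, `NA` when absent
#' @param t_end T-wave end, `NA` when absent
#' @export
wave_borders <- function(qrs_on, qrs_end, p_on = NA_real_, p_end = NA_real_,
                         t_end = NA_real_) {
  has_p <- !is.na(p_on) && !is.na(p_end)
  if (!is.na(p_on) != !is.na(p_end))
    stop("p_on and p_end must both be present or both absent")
  ok <- qrs_on < qrs_end &&
    (!has_p || (p_on < p_end && p_end <= qrs_on)) &&
    (is.na(t_end) || t_end > qrs_end)
  if (!ok) stop("wave borders must satisfy p_on < p_end <= qrs_on < qrs_end < t_end")
  structure(list(p_on = as.numeric(p_on), p_end = as.numeric(p_end),
                 qrs_on = as.numeric(qrs_on), qrs_end = as.numeric(qrs_end),
                 t_end = as.numeric(t_end),
                 p_present = has_p, t_present = !is.na(t_end)),
            class = "wave_borders")
}

#' @export
print.wave_borders <- function(x, ...) {
  f <- function(v) if (is.na(v)) "-" else sprintf("%.2f", v)
  cat(sprintf("wave borders [ms]: P %s..%s  QRS %s..%s  T-end %s\n",
              f(x$p_on), f(x$p_end), f(x$qrs_on), f(x$qrs_end), f(x$t_end)))
  invisible(x)
}

#' Borders tables
#'
#' A borders table is a data frame with one row per beat: `beat_time_ms`,
#' `p_on`, `p_end`, `qrs_on`, `qrs_end`, `t_end` (absolute ms, `NA` for
#' absent waves).
#'
#' @param beat_times fiducial instants (ms)
#' @param borders list of `wave_borders`, absolute times
#' @export
borders_table <- function(beat_times, borders) {
  stopifnot(length(beat_times) == length(borders))
  g <- function(field) vapply(borders, function(b)
    if (is.null(b)) NA_real_ else b[[field]], numeric(1))
  data.frame(beat_time_ms = as.numeric(beat_times),
             p_on = g("p_on"), p_end = g("p_end"),
             qrs_on = g("qrs_on"), qrs_end = g("qrs_end"),
             t_end = g("t_end"))
}
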