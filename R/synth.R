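#' Beat morphologies for the synthetic generator
#'
#' A morphology is a sum of five Gaussian components (P, Q, R, S, T), each
#' with amplitude (uV), centre offset from the R centre (ms) and width
#' (Gaussian sigma, ms).  Ground-truth wave borders are defined at +-3 sigma
#' of the outermost contributing component, the fiducial point is the R
#' centre.  Absent components (e.g. the P wave of a ventricular ectopic) are
#' `NULL`.
#'
#' @param p,q,r,s,t numeric `c(amp, center, sigma)` or `NULL` for absent
#' @param label annotation label the morphology carries (`"N"`, `"V"`, ...)
#' @param name morphology name
#' @export
beat_morphology <- function(r, p = NULL, q = NULL, s = NULL, t = NULL,
                            label = "N", name = "custom") {
  comp <- list(P = p, Q = q, R = r, S = s, T = t)
  for (nm in names(comp)) {
    cc <- comp[[nm]]
    if (!is.null(cc)) {
      stopifnot(length(cc) == 3, cc[3] > 0)
      comp[[nm]] <- stats::setNames(as.numeric(cc), c("amp", "center", "sigma"))
    }
  }
  ctr <- vapply(comp[!vapply(comp, is.null, TRUE)], `[[`, numeric(1), "center")
  if (is.unsorted(ctr)) stop("component centres must be ordered P < Q < R < S < T")
  structure(list(components = comp, label = label, name = name),
            class = "beat_morphology")
}

#' Built-in morphology presets
#'
#' `NOR`: a normal sinus beat; `PVC`: a premature ventricular contraction
#' (wide QRS, no P, discordant T); `APC`: an atrial premature beat with an
#' inverted ectopic P and an RBBB-flavoured deep S wave.  Amplitudes and
#' widths are nominal adult surface-lead values.
#'
#' @param name one of `"NOR"`, `"PVC"`, `"APC"`
#' @export
morphology_preset <- function(name = c("NOR", "PVC", "APC")) {
  name <- match.arg(name)
  switch(name,
    NOR = beat_morphology(p = c(150, -140, 18), q = c(-100, -25, 6),
                          r = c(1000, 0, 9), s = c(-200, 22, 7),
                          t = c(350, 180, 40), label = "N", name = "NOR"),
    PVC = beat_morphology(r = c(1200, 0, 22), t = c(-400, 200, 45),
                          label = "V", name = "PVC"),
    APC = beat_morphology(p = c(-120, -150, 16), q = c(-60, -22, 6),
                          r = c(850, 0, 8), s = c(-450, 25, 9),
                          t = c(250, 170, 35), label = "A", name = "APC"))
}

#' Ground-truth borders of a morphology (relative to the fiducial)
#' @param morph a [beat_morphology()]
#' @export
morphology_borders <- function(morph) {
  cc <- morph$components
  edge <- function(x, side) if (is.null(x)) NA_real_ else x[["center"]] + side * 3 * x[["sigma"]]
  qrs_on <- if (!is.null(cc$Q)) edge(cc$Q, -1) else edge(cc$R, -1)
  qrs_end <- if (!is.null(cc$S)) edge(cc$S, +1) else edge(cc$R, +1)
  wave_borders(qrs_on = qrs_on, qrs_end = qrs_end,
               p_on = edge(cc$P, -1), p_end = edge(cc$P, +1),
               t_end = edge(cc$T, +1))
}

#' Generate one beat waveform with its ground truth
#'
#' @param morph a [beat_morphology()]
#' @param fs sampling frequency (Hz)
#' @param window numeric `c(from, to)` in ms around the fiducial
#' @param amp_scale multiplier applied to all component amplitudes
#' @return list with `t` (ms), `v` (uV), `borders` ([wave_borders()] relative
#'   to the fiducial, or `NULL` if the beat has zero amplitude everywhere)
#'   and `fiducial` (0)
#' @export
generate_beat <- function(morph, fs = 500, window = c(-400, 500),
                          amp_scale = 1) {
  t <- seq(window[1], window[2], by = 1000 / fs)
  v <- morphology_values(morph, t, amp_scale)
  borders <- if (all(v == 0)) NULL else morphology_borders(morph)
  list(t = t, v = v, borders = borders, fiducial = 0)
}

morphology_values <- function(morph, t, amp_scale = 1) {
  v <- numeric(length(t))
  for (cc in morph$components) {
    if (is.null(cc) || cc[["amp"]] == 0) next
    v <- v + amp_scale * cc[["amp"]] *
      exp(-0.5 * ((t - cc[["center"]]) / cc[["sigma"]])^2)
  }
  v
}

#' Record specification for the synthetic generator
#'
#' @param duration_s record length in seconds
#' @param fs sampling frequency (360 or 500 Hz)
#' @param n_leads number of leads
#' @param mean_rr mean RR interval (ms)
#' @param rr_jitter_sd standard deviation of RR jitter (ms)
#' @param mixture named beat-type probabilities over the preset names
#' @param snr_db signal-to-noise ratio of the additive white noise (dB);
#'   `Inf` disables noise
#' @param baseline_amp,baseline_freq baseline wander amplitude (uV) and
#'   frequency (Hz); 0 disables
#' @param amp_jitter_sd relative beat-to-beat amplitude variability
#' @param lead_scales per-lead amplitude multipliers
#' @param gain quantization step (uV/LSB)
#' @param seed RNG seed
#' @export
record_spec <- function(duration_s = 60, fs = 500, n_leads = 2,
                        mean_rr = 750, rr_jitter_sd = 25,
                        mixture = c(NOR = 1),
                        snr_db = 20, baseline_amp = 80, baseline_freq = 0.33,
                        amp_jitter_sd = 0.05,
                        lead_scales = NULL, gain = 2.5, seed = 1) {
  if (abs(sum(mixture) - 1) > 1e-9) stop("mixture probabilities must sum to 1")
  if (!fs %in% c(360, 500)) stop("fs must be 360 or 500 Hz")
  if (is.null(lead_scales)) lead_scales <- c(1, 0.65, 0.5)[seq_len(n_leads)]
  stopifnot(length(lead_scales) == n_leads)
  structure(list(duration_s = duration_s, fs = fs, n_leads = n_leads,
                 mean_rr = mean_rr, rr_jitter_sd = rr_jitter_sd,
                 mixture = mixture, snr_db = snr_db,
                 baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 amp_jitter_sd = amp_jitter_sd, lead_scales = lead_scales,
                 gain = gain, seed = seed),
            class = "record_spec")
}

#' Generate a synthetic multilead ECG record with ground truth
#'
#' Beats are placed at RR-jittered instants; morphologies are drawn from the
#' mixture; ventricular ectopics arrive early (x0.75 of the mean interval)
#' with a compensatory pause after.  Baseline wander and white noise are
#' added last -- all ground truth (beat instants, labels, wave borders) is
#' recorded from the clean waveform.  Fully deterministic for a given spec.
#'
#' @param spec a [record_spec()]
#' @return list with `signal` ([uniform_signal()]), `annotations`
#'   ([annotation_set()] at the fiducial instants), `borders` (absolute-time
#'   [borders_table()]) and `beats` (data frame: `time`, `label`, `type`)
#' @export
generate_record <- function(spec = record_spec()) {
  stopifnot(inherits(spec, "record_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  dur <- spec$duration_s * 1000
  types <- names(spec$mixture)
  # beat schedule
  fid <- numeric(0); kind <- character(0)
  t_cur <- 400
  while (TRUE) {
    ty <- sample(types, 1, prob = spec$mixture)
    rr <- spec$mean_rr
    if (length(kind)) {
      jit <- max(-3, min(3, stats::rnorm(1))) * spec$rr_jitter_sd
      rr <- spec$mean_rr + jit
      if (ty == "PVC") rr <- 0.75 * rr
      if (kind[length(kind)] == "PVC") rr <- 1.25 * rr
      t_cur <- fid[length(fid)] + rr
    }
    if (t_cur > dur - 500) break
    fid <- c(fid, t_cur); kind <- c(kind, ty)
  }
  n <- length(fid)
  t_grid <- (seq_len(round(dur * spec$fs / 1000)) - 1) * 1000 / spec$fs
  clean1 <- numeric(length(t_grid)) # lead-1 clean waveform in uV
  borders <- vector("list", n)
  labels <- character(n)
  amp_scales <- pmax(0.5, 1 + stats::rnorm(n, 0, spec$amp_jitter_sd))
  for (k in seq_len(n)) {
    m <- morphology_preset(kind[k])
    labels[k] <- m$label
    lo <- findInterval(fid[k] - 450, t_grid) + 1L
    hi <- findInterval(fid[k] + 550, t_grid)
    idx <- lo:hi
    clean1[idx] <- clean1[idx] +
      morphology_values(m, t_grid[idx] - fid[k], amp_scales[k])
    b <- morphology_borders(m)
    borders[[k]] <- wave_borders(
      qrs_on = fid[k] + b$qrs_on, qrs_end = fid[k] + b$qrs_end,
      p_on = fid[k] + b$p_on, p_end = fid[k] + b$p_end,
      t_end = fid[k] + b$t_end)
  }
  rms <- sqrt(mean(clean1^2))
  noise_sd <- if (is.finite(spec$snr_db)) rms * 10^(-spec$snr_db / 20) else 0
  values <- vector("list", spec$n_leads)
  for (lead in seq_len(spec$n_leads)) {
    v <- clean1 * spec$lead_scales[lead]
    if (spec$baseline_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      v <- v + spec$baseline_amp * spec$lead_scales[lead] *
        sin(2 * pi * spec$baseline_freq * t_grid / 1000 + phase)
    }
    if (noise_sd > 0)
      v <- v + stats::rnorm(length(v), 0, noise_sd * spec$lead_scales[lead])
    values[[lead]] <- round(v / spec$gain)
  }
  sig <- uniform_signal(values, fs = spec$fs, gain = spec$gain)
  list(signal = sig,
       annotations = annotation_set(fid, labels),
       borders = borders_table(fid, borders),
       beats = data.frame(time = fid, label = labels, type = kind,
                          stringsAsFactors = FALSE))
}
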