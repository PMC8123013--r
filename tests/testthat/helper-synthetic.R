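# Shared fixtures are generated in code and memoised for the test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# per-beat SLB projections from a generated record's ground-truth borders
make_slbs <- function(rec, profile = slb_profile()) {
  fid <- rec$beats$time
  n <- length(fid)
  lapply(seq_len(n), function(k) {
    b <- rec$borders[k, ]
    wb <- tryCatch(
      wave_borders(qrs_on = b$qrs_on, qrs_end = b$qrs_end,
                   p_on = b$p_on, p_end = b$p_end, t_end = b$t_end),
      error = function(e) NULL)
    if (is.null(wb)) return(NULL)
    rr <- c(if (k > 1) fid[k - 1] else fid[k] - 750, fid[k],
            if (k < n) fid[k + 1] else fid[k] + 750)
    project_slb(profile, wb, rr)
  })
}

# the 60 s detection-suite record (2 leads, SNR 20 dB) and its variants
detection_fixture <- function() {
  cached("det60", {
    rec <- generate_record(record_spec(duration_s = 60, seed = 42,
                                       mixture = c(NOR = 1)))
    list(rec = rec,
         pECG = as_pseudo_nonuniform(rec$signal),
         nECG = sample_nonuniform(rec$signal, make_slbs(rec)))
  })
}

# a short clean record for fast unit tests
short_fixture <- function() {
  cached("short20", {
    rec <- generate_record(record_spec(duration_s = 20, seed = 7,
                                       snr_db = 30, mixture = c(NOR = 1)))
    list(rec = rec, pECG = as_pseudo_nonuniform(rec$signal))
  })
}

# independent brute-force slotted estimator: explicit double sum over signal
# samples and atom taps through the slot_kernel primitive (signal samples
# outside the atom support cannot fall in any tap's slot, so restricting the
# outer sum to the support is an identity, not an approximation)
nuts_oracle <- function(nu, lead, scale, b, base_step = 2) {
  atom <- wavelet_atom(scale, b, base_step)
  in_support <- which(abs(nu$times - b) <= atom$support)
  ts <- nu$times[in_support]
  v <- as.numeric(nu$values[[lead]][in_support])
  num <- 0; cnt <- 0
  for (j in seq_along(atom$values)) {
    k <- slot_kernel(ts, atom$times[j], atom$spacing)
    num <- num + atom$values[j] * sum(v * k)
    cnt <- cnt + sum(k)
  }
  if (cnt < 2) return(NA_real_)
  num / cnt
}

# shift relative wave borders to an absolute fiducial
shift_borders <- function(wb, offset) {
  wave_borders(qrs_on = wb$qrs_on + offset, qrs_end = wb$qrs_end + offset,
               p_on = wb$p_on + offset, p_end = wb$p_end + offset,
               t_end = wb$t_end + offset)
}
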