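test_that("the slot kernel is a closed rectangular indicator", {
  expect_equal(slot_kernel(100, 100, 64), 1L)
  expect_equal(slot_kernel(133, 100, 64), 0L)
  expect_equal(slot_kernel(132, 100, 64), 1L) # boundary |t-b| = s/2 included
  expect_equal(slot_kernel(c(60, 68, 140), 100, 64), c(0L, 1L, 0L))
})

test_that("the atom derives from the Coiflet-5 filter bank", {
  expect_equal(sum(nuecg:::nuts_atom_values^2), 1, tolerance = 1e-12)
  expect_lt(abs(sum(nuecg:::nuts_atom_values)), 1e-12) # zero mean
  # cell averages of the cascade-refined mother wavelet reproduce the atom
  level <- 7
  psi <- coif5_wavefun(level)
  block <- 2^level
  # the periodized synthesis places psi at an arbitrary (sub-cell) shift,
  # and returns scaling-coefficient expansions rather than point samples
  # (a smoothing of about a quarter cell); scan offsets for the best match
  best <- 0
  for (off in seq(0, block - 1, by = 4)) {
    cells <- vapply(seq_len(30), function(k) {
      idx <- (off + (k - 1) * block + 1):min(off + k * block, length(psi))
      if (idx[1] > length(psi)) return(0)
      mean(psi[idx])
    }, numeric(1))
    nrm <- sqrt(sum(cells^2))
    if (nrm == 0) next
    cells <- cells / nrm
    for (sh in -3:3) {
      src <- seq_along(cells) - sh
      keep <- src >= 1 & src <= length(cells)
      cc <- abs(sum(cells[src[keep]] * nuecg:::nuts_atom_values[keep]))
      best <- max(best, cc)
    }
  }
  expect_gt(best, 0.995)
})

test_that("coefficients match the brute-force slotted double sum", {
  fx <- short_fixture()
  nu <- fx$pECG
  for (a in c(1, 3, 5)) {
    tsg <- nuts_transform(nu, 1, scales = a)
    s <- tsg$scales[[as.character(a)]]
    idx <- round(seq(5, length(s$b) - 5, length.out = 25))
    for (i in idx) {
      expect_equal(s$c[i], nuts_oracle(nu, 1, a, s$b[i]), tolerance = 1e-12)
    }
  }
  # and on a genuinely non-uniform grid
  set.seed(9)
  ts <- cumsum(runif(800, 2, 10))
  nu2 <- nu_signal(ts, list(round(300 * sin(2 * pi * ts / 400))))
  tsg <- nuts_transform(nu2, 1, scales = 2)
  s <- tsg$scales[["2"]]
  for (i in round(seq(10, length(s$b) - 10, length.out = 20)))
    expect_equal(s$c[i], nuts_oracle(nu2, 1, 2, s$b[i]), tolerance = 1e-12)
})

test_that("the slotted estimator is linear and kills DC", {
  t <- seq(0, 5000, by = 2)
  x <- round(200 * sin(2 * pi * t / 300))
  y <- round(150 * cos(2 * pi * t / 520))
  mk <- function(v) { n <- nu_signal(t, list(v)); n$values[[1]] <- v; n }
  ta <- nuts_transform(mk(x), 1, scales = 3)$scales[["3"]]
  tb <- nuts_transform(mk(y), 1, scales = 3)$scales[["3"]]
  tc <- nuts_transform(mk(x + y), 1, scales = 3)$scales[["3"]]
  expect_equal(tc$c, ta$c + tb$c, tolerance = 1e-10)
  # zero signal -> exactly zero; DC -> near-zero at every scale
  tz <- nuts_transform(mk(rep(0, length(t))), 1, scales = 2)$scales[["2"]]
  expect_true(all(tz$c == 0, na.rm = TRUE))
  dc <- nuts_transform(mk(rep(500, length(t))), 1, scales = 1:4)
  for (s in dc$scales) {
    interior <- s$count == max(s$count)
    expect_lt(max(abs(s$c[interior])), 500 * 1e-10)
  }
})

test_that("an embedded atom is recovered at its own shift", {
  a <- 3
  atom <- wavelet_atom(a, 2000)
  t <- seq(0, 4000, by = 2)
  v <- approx(atom$times, atom$values * 1000, xout = t, rule = 2, yleft = 0,
              yright = 0)$y
  v[t < min(atom$times) | t > max(atom$times)] <- 0
  nu <- nu_signal(t, list(v)); nu$values[[1]] <- v
  tsg <- nuts_transform(nu, 1, scales = a)
  s <- tsg$scales[[as.character(a)]]
  expect_equal(s$b[which.max(s$c)], 2000, tolerance = diff(s$b[1:2]) + 1e-9)
})

test_that("the orthogonal Coiflet-5 filter bank reconstructs losslessly", {
  set.seed(31)
  x <- rnorm(4096)
  w <- dwt_coif5(x, levels = 4)
  expect_lt(max(abs(idwt_coif5(w) - x)), 1e-8)
  # energy preservation (orthogonality)
  expect_equal(sum(x^2), sum(unlist(w)^2), tolerance = 1e-10)
})

test_that("flat records are flagged undelineated", {
  nu <- nu_signal(seq(0, 5000, by = 2), list(rep(0L, 2501)))
  tsg <- nuts_transform(nu, 1, scales = 2:5)
  expect_null(delineate_qrs(tsg, 2500))
  expect_null(delineate_beat(tsg, 2500))
})

test_that("a symmetric QRS delineates symmetrically about its centre", {
  t <- seq(0, 5000, by = 2)
  v <- round(1000 * exp(-0.5 * ((t - 2500) / 12)^2))
  nu <- nu_signal(t, list(v))
  tsg <- nuts_transform(nu, 1, scales = 2:5)
  q <- delineate_qrs(tsg, 2500)
  expect_false(is.null(q))
  expect_lt(abs((q$qrs_on - 2500) + (q$qrs_end - 2500)), 2)
})

test_that("generated beats delineate within the IEC-style tolerances", {
  rec <- cached("delin_rec", {
    generate_record(record_spec(duration_s = 30, seed = 301, snr_db = 30,
                                mixture = c(NOR = 0.7, APC = 0.3)))
  })
  nu <- cached("delin_nu", sample_nonuniform(rec$signal, make_slbs(rec)))
  det <- cached("delin_det", detect_beats(nu))
  tab <- cached("delin_tab", delineate_record(nu, det))
  e_on <- e_end <- c()
  for (k in seq_len(nrow(tab))) {
    j <- which.min(abs(rec$beats$time - tab$beat_time_ms[k]))
    if (abs(rec$beats$time[j] - tab$beat_time_ms[k]) > 25.6) next
    e_on <- c(e_on, tab$qrs_on[k] - rec$borders$qrs_on[j])
    e_end <- c(e_end, tab$qrs_end[k] - rec$borders$qrs_end[j])
  }
  expect_gt(length(e_on), 20)
  expect_lte(mean(abs(e_on)), 10)
  expect_lte(mean(abs(e_end)), 10)
  # ordering invariant wherever all borders are present
  full <- stats::complete.cases(tab)
  expect_true(all(tab$p_on[full] < tab$p_end[full]))
  expect_true(all(tab$p_end[full] <= tab$qrs_on[full]))
  expect_true(all(tab$qrs_on[full] < tab$qrs_end[full]))
  expect_true(all(tab$qrs_end[full] < tab$t_end[full]))
})

test_that("beats without a P or T wave report the wave absent", {
  # ventricular beat: wide QRS, no P
  t <- seq(0, 6000, by = 2)
  v <- round(1200 * exp(-0.5 * ((t - 3000) / 22)^2) -
             400 * exp(-0.5 * ((t - 3200) / 45)^2))
  nu <- nu_signal(t, list(v))
  tsg <- nuts_transform(nu, 1, scales = 2:5)
  q <- delineate_qrs(tsg, 3000)
  p <- delineate_p(tsg, q$qrs_on)
  expect_false(p$present)
  # inverted T still delineates (sign-agnostic)
  tw <- delineate_t(tsg, q$qrs_end)
  expect_true(tw$present)
  expect_lt(abs(tw$t_end - (3200 + 3 * 45)), 30)
  # beat generated without any T wave
  v2 <- round(1000 * exp(-0.5 * ((t - 3000) / 10)^2))
  nu2 <- nu_signal(t, list(v2))
  tsg2 <- nuts_transform(nu2, 1, scales = 2:5)
  q2 <- delineate_qrs(tsg2, 3000)
  expect_false(delineate_t(tsg2, q2$qrs_end)$present)
})
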