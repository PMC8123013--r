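wb_example <- wave_borders(qrs_on = -43, qrs_end = 43, p_on = -194,
                           p_end = -86, t_end = 300)

test_that("SLB projection honours anchors and warps as declared", {
  # constant template is invariant under any warp
  const <- slb_profile(f_min = 500, f_max = 500, f_p = 500, f_t = 500)
  b <- project_slb(const, shift_borders(wb_example, 1000),
                   rr_context = c(250, 1000, 1750))
  expect_true(all(b$knots$f == 500))

  prof <- slb_profile()
  b <- project_slb(prof, shift_borders(wb_example, 1000), c(250, 1000, 1750))
  # frequency at each actual border equals the template frequency there
  for (nm in names(prof$anchors)) {
    f_t <- slb_template_at(prof, prof$anchors[[nm]])
    expect_equal(beat_slb_at(b, 1000 + wb_example[[nm]]), f_t, tolerance = 1e-9)
  }
})

test_that("a stretched QRS stretches the projected profile curve alike", {
  prof <- slb_profile()
  b1 <- project_slb(prof, shift_borders(wb_example, 1000), c(250, 1000, 1750))
  wb2 <- wave_borders(qrs_on = -86, qrs_end = 86, p_on = -194, p_end = -100,
                      t_end = 300)
  b2 <- project_slb(prof, shift_borders(wb2, 1000), c(250, 1000, 1750))
  # hand-warped oracle: within the QRS the frequency-vs-time curve of the
  # stretched beat equals the original curve with time doubled about qrs
  # onset (piecewise-linear warp maps the span linearly)
  u <- seq(0.05, 0.95, by = 0.1)
  t1 <- 1000 - 43 + u * 86
  t2 <- 1000 - 86 + u * 172
  expect_equal(beat_slb_at(b2, t2), beat_slb_at(b1, t1), tolerance = 1e-9)
  # spline warp passes through the same anchors
  b3 <- project_slb(prof, shift_borders(wb2, 1000), c(250, 1000, 1750),
                    warp = "spline")
  expect_equal(beat_slb_at(b3, 1000 - 86), beat_slb_at(b2, 1000 - 86),
               tolerance = 1e-6)
})

test_that("identity sampling: constant source-rate grid reproduces the record", {
  fx <- short_fixture()
  pe <- sample_nonuniform(fx$rec$signal, NULL, antialias = FALSE, f_fill = 500)
  n <- length(pe$times)
  expect_identical(pe$values[[1]], fx$rec$signal$values[[1]][seq_len(n)])
  expect_equal(diff(pe$times), rep(2, n - 1))
  expect_identical(pe$model, "pECG")
})

test_that("constant low-rate sampling of DC yields the DC level at 10 ms", {
  dc <- uniform_signal(list(rep(100L, 2500)), fs = 500, gain = 1)
  nu <- sample_nonuniform(dc, NULL, antialias = FALSE, f_fill = 100)
  expect_true(all(nu$values[[1]] == 100L))
  expect_equal(unique(round(diff(nu$times), 9)), 10)
  expect_error(sample_nonuniform(dc, NULL, f_fill = 600), "exceeds")
})

test_that("the default profile compresses a normal-rhythm minute about 3x", {
  fx <- detection_fixture()
  cr <- compression_ratio(fx$rec$signal, fx$nECG)
  expect_gte(cr, 2.5)
  expect_lte(cr, 3.7)
  iv <- diff(fx$nECG$times)
  expect_gte(min(iv), 2 - 1e-9)
  expect_lte(max(iv), 10 + 1e-9)
})

test_that("uniformize returns original samples at knots of a pECG grid", {
  fx <- short_fixture()
  pe <- as_pseudo_nonuniform(fx$rec$signal)
  u <- uniformize(pe, 500, antialias = TRUE)
  n <- length(fx$rec$signal$values[[1]])
  interior <- seq(250, n - 250)
  expect_identical(u$values[[1]][interior], fx$rec$signal$values[[1]][interior])
  expect_error(uniformize(nu_signal(c(0, 1), list(c(1, 2))), 500), "short")
})

test_that("a band-limited tone survives the non-uniform round trip", {
  fs <- 500
  t <- (0:(10 * fs - 1)) * 1000 / fs
  tone <- uniform_signal(list(round(400 * sin(2 * pi * 10 * t / 1000))),
                         fs = fs, gain = 1)
  nu <- sample_nonuniform(tone, NULL, antialias = TRUE, f_fill = 150)
  back <- uniformize(nu, fs)
  n <- min(length(t), length(back$values[[1]]))
  interior <- seq(500, n - 500)
  expect_lt(prd(tone$values[[1]][interior], back$values[[1]][interior]), 1)
})

test_that("compression ratio is plain sample-count arithmetic", {
  u <- uniform_signal(list(rep(0L, 5000)), fs = 500)
  mk <- function(n) nu_signal(seq(0, 9998, length.out = n), list(rep(0L, n)))
  expect_equal(compression_ratio(u, mk(5000)), 1)
  expect_equal(compression_ratio(u, mk(1613)), 3.10, tolerance = 0.01)
  expect_error(compression_ratio(uniform_signal(list(integer(0)), 500), mk(10)),
               "empty")
})
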