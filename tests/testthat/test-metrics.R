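test_that("PRD identities and arithmetic", {
  x <- c(3, -4, 5, 1)
  expect_equal(prd(x, x), 0)
  expect_equal(prd(x, 2 * x), 100)
  expect_equal(prd(c(3, 4), c(3, 0)), 80)
  expect_error(prd(c(0, 0), c(1, 1)), "zero energy")
  expect_error(prd(1:3, 1:4), "same grid")
  # invariant to common amplitude scaling
  expect_equal(prd(10 * x, 10 * 2 * x), prd(x, 2 * x))
})

test_that("detection scoring implements the Se/PPV/Fd definitions", {
  truth <- seq(0, 9000, by = 1000)   # 10 beats
  pred <- c(truth[1:9] + 5, 4500.5)  # 9 hits and one double detection
  st <- detection_stats(pred, truth)
  expect_equal(st$TP, 9); expect_equal(st$FP, 1); expect_equal(st$FN, 1)
  expect_equal(st$Se, 90)
  expect_equal(st$PPV, 90)
  expect_equal(st$Fd, 2 / 11 * 100, tolerance = 1e-12)
  # empty prediction
  st0 <- detection_stats(numeric(0), truth)
  expect_equal(st0$Se, 0)
  expect_equal(st0$Fd, 100)
  # jittered truth within tolerance matches one-to-one
  set.seed(77)
  jit <- truth + runif(10, -10, 10)
  stj <- detection_stats(jit, truth)
  expect_equal(stj$TP, 10)
  expect_equal(stj$Fd, 0)
})

test_that("the 14-label AAMI projection is total and surjective", {
  expect_equal(map_mitdb_to_aami("L"), "N")
  expect_equal(map_mitdb_to_aami("J"), "S")
  expect_equal(map_mitdb_to_aami("!"), "V")
  lab14 <- mitdb_labels(synthetic = FALSE)
  classes <- map_mitdb_to_aami(lab14)
  expect_length(classes, 14)
  expect_setequal(unique(classes), c("N", "S", "V", "F", "Q"))
  expect_equal(sum(classes == "S"), 6)
  expect_error(map_mitdb_to_aami("P"), "unknown")
})

test_that("confusion matrices count majority-labelled clusters", {
  lab <- rep(c("N", "V"), c(90, 10))
  asg <- rep(c(1, 2), c(90, 10))
  cs <- confusion_stats(asg, lab)
  expect_equal(cs$accuracy, 100)
  expect_true(all(cs$matrix[row(cs$matrix) != col(cs$matrix)] == 0))
  asg2 <- asg; asg2[1] <- 2 # one N lands in the V cluster
  expect_equal(confusion_stats(asg2, lab)$accuracy, 99)
  expect_error(confusion_stats(NA, "N"), "no classified")
})

test_that("coarsening labels to AAMI classes can only merge errors", {
  set.seed(13)
  labs <- sample(mitdb_labels(synthetic = FALSE), 400, replace = TRUE)
  for (r in 1:5) {
    asg <- sample(1:6, 400, replace = TRUE)
    acc_fine <- confusion_stats(asg, labs)$accuracy
    acc_aami <- confusion_stats(asg, map_mitdb_to_aami(labs))$accuracy
    expect_gte(acc_aami, acc_fine)
  }
})

test_that("WDD identities, the printed-weight example and bounds", {
  fx <- short_fixture()
  rec <- fx$rec
  nu <- fx$pECG
  k <- 5
  wb <- shift_borders(
    wave_borders(qrs_on = rec$borders$qrs_on[k] - rec$beats$time[k],
                 qrs_end = rec$borders$qrs_end[k] - rec$beats$time[k],
                 p_on = rec$borders$p_on[k] - rec$beats$time[k],
                 p_end = rec$borders$p_end[k] - rec$beats$time[k],
                 t_end = rec$borders$t_end[k] - rec$beats$time[k]),
    rec$beats$time[k])
  beta <- extract_wdd_features(nu, 1, rec$beats$time[k], wb, rr_prev = 750)
  expect_length(unclass(beta), 18)
  expect_equal(wdd(beta, beta), 0)
  expect_equal(sum(nuecg:::wdd_weights), 29.1)
  # a single categorical mismatch on ST shape-class weight 3
  beta3 <- beta
  beta3$ST_shape <- if (identical(beta$ST_shape, "up")) "down" else "up"
  expect_equal(wdd(beta, beta3), 3 / 29.1 * 100, tolerance = 1e-9)
  # symmetry and bounds
  expect_equal(wdd(beta, beta3), wdd(beta3, beta))
  beta4 <- beta
  for (nm in names(beta4)) if (is.numeric(beta4[[nm]]))
    beta4[[nm]] <- -10 * beta4[[nm]] - 5
  w <- wdd(beta, beta4)
  expect_gte(w, 0); expect_lte(w, 100)
})

test_that("feature extraction tracks the generator's ground truth", {
  fx <- short_fixture()
  rec <- fx$rec
  k <- 4
  fid <- rec$beats$time[k]
  wb <- wave_borders(qrs_on = rec$borders$qrs_on[k],
                     qrs_end = rec$borders$qrs_end[k],
                     p_on = rec$borders$p_on[k], p_end = rec$borders$p_end[k],
                     t_end = rec$borders$t_end[k])
  f <- extract_wdd_features(fx$pECG, 1, fid, wb,
                            rr_prev = fid - rec$beats$time[k - 1])
  expect_equal(f$QRS_dur, wb$qrs_end - wb$qrs_on)
  expect_equal(f$RR_int, fid - rec$beats$time[k - 1])
  expect_equal(f$P_shape, "pos")
  expect_equal(f$T_shape, "pos")
  expect_gt(f$QRSp_amp, 800)  # ~1000 uV R wave
  expect_lt(f$QRSn_amp, -100) # S wave
  expect_true(f$Q_wave_exist)
  # a beat without P drops the P features
  wb2 <- wave_borders(qrs_on = wb$qrs_on, qrs_end = wb$qrs_end,
                      t_end = wb$t_end)
  f2 <- extract_wdd_features(fx$pECG, 1, fid, wb2, rr_prev = 750)
  expect_true(is.na(f2$P_dur) && is.na(f2$P_amp))
  expect_equal(f2$P_shape, "absent")
})
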