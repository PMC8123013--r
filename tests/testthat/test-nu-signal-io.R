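test_that("NU-CSV parsing, canonical writing and round trips", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("0.0,10", "2.5,12", "7.5,11"), f)
  x <- read_nu(f)
  expect_equal(x$times, c(0, 2.5, 7.5))
  expect_equal(x$values[[1]], c(10L, 12L, 11L))

  # canonical write: 6-decimal times, integer values
  y <- nu_signal(0, list(7))
  write_nu(y, f)
  expect_true(any(grepl("^0\\.000000,7$", readLines(f))))

  # write(read()) is byte-identical on canonical files
  z <- nu_signal(c(0, 2.125, 7.5), list(c(10, -12, 11)), gain = 2.5)
  write_nu(z, f)
  bytes1 <- readBin(f, "raw", file.info(f)$size)
  write_nu(read_nu(f), f)
  bytes2 <- readBin(f, "raw", file.info(f)$size)
  expect_identical(bytes1, bytes2)
  expect_equal(read_nu(f)$times, z$times, tolerance = 1e-9)

  # empty signal: header-only file
  write_nu(nu_signal(numeric(0), list(integer(0))), f)
  expect_true(all(grepl("^#", readLines(f))))
  expect_length(read_nu(f)$times, 0)
})

test_that("malformed NU files are rejected with the offending row", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("0,1", "5,2", "3,3"), f)
  expect_error(read_nu(f), "row 3")
  writeLines(c("# leads=a;b", "0,1", "2,2"), f)
  expect_error(read_nu(f), "leads")
})

test_that("constant-interval records are flagged pseudo-non-uniform", {
  x <- nu_signal(seq(0, 100, by = 2), list(rep(1L, 51)))
  expect_true(is_pseudo_nonuniform(x))
  y <- nu_signal(c(0, 2, 5, 9), list(rep(1L, 4)))
  expect_false(is_pseudo_nonuniform(y))
  u <- uniform_signal(list(1:10), fs = 500)
  p <- as_pseudo_nonuniform(u)
  expect_identical(p$model, "pECG")
  expect_equal(diff(p$times), rep(2, 9))
})

test_that("uniform CSV reading and spline resampling track a known tone", {
  fs <- 360
  t <- (0:(2 * fs - 1)) / fs
  v <- round(1000 * sin(2 * pi * 10 * t))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(lead1 = v), f, row.names = FALSE)
  x <- read_uniform(f, "csv", fs = fs)
  expect_equal(signal_duration(x), 2000)
  y <- resample_uniform(x, 500)
  t_new <- uniform_times(y) / 1000
  interior <- t_new > 0.1 & t_new < 1.9
  err <- abs(y$values[[1]][interior] - 1000 * sin(2 * pi * 10 * t_new[interior]))
  expect_lt(max(err), 2) # within quantization of the 1000-unit tone
  # annotation bookkeeping: a beat at source sample k maps to sample k*500/360
  k <- 180
  t_ms <- (k - 1) / fs * 1000
  expect_equal(t_ms * 500 / 1000 + 1, (k - 1) * 500 / 360 + 1, tolerance = 1e-9)
})

test_that("a synthetic WFDB record (formats 212 and 16) reads back", {
  dir <- tempfile(); dir.create(dir)
  v1 <- as.integer(round(500 * sin(2 * pi * (0:499) / 50)))
  v2 <- as.integer(round(250 * cos(2 * pi * (0:499) / 50)))
  # format 212 packing
  raw <- raw(0)
  for (i in seq_along(v1)) {
    a <- v1[i]; b <- v2[i]
    if (a < 0) a <- a + 4096L
    if (b < 0) b <- b + 4096L
    raw <- c(raw, as.raw(bitwAnd(a, 0xFF)),
             as.raw(bitwAnd(a %/% 256L, 0x0F) + 16L * bitwAnd(b %/% 256L, 0x0F)),
             as.raw(bitwAnd(b, 0xFF)))
  }
  writeBin(raw, file.path(dir, "rec.dat"))
  writeLines(c("rec 2 360 500",
               "rec.dat 212 200 11 0 0 0 0 MLII",
               "rec.dat 212 200 11 0 0 0 0 V1"), file.path(dir, "rec.hea"))
  x <- read_wfdb(file.path(dir, "rec.hea"))
  expect_equal(x$fs, 360)
  expect_equal(x$values[[1]], v1)
  expect_equal(x$values[[2]], v2)
  expect_equal(x$gain, 5) # 200 counts/mV -> 5 uV per count
  # format 16
  writeBin(as.integer(rbind(v1, v2)), file.path(dir, "r16.dat"), size = 2,
           endian = "little")
  writeLines(c("r16 2 360 500",
               "r16.dat 16 200 16 0 0 0 0 MLII",
               "r16.dat 16 200 16 0 0 0 0 V1"), file.path(dir, "r16.hea"))
  y <- read_wfdb(file.path(dir, "r16.hea"))
  expect_equal(y$values[[1]], v1)
})

test_that("annotation and border tables round-trip through CSV", {
  f <- tempfile(fileext = ".csv")
  ann <- annotation_set(c(100, 850, 1600), c("N", "V", "N"))
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_equal(back$times, ann$times)
  expect_equal(back$labels, ann$labels)
  expect_error(annotation_set(c(2, 1), c("N", "N")), "non-decreasing")
  expect_error(annotation_set(1, "Z"), "vocabulary")

  wb <- wave_borders(qrs_on = -40, qrs_end = 40, p_on = -190, p_end = -90,
                     t_end = 300)
  tab <- borders_table(1000, list(wb))
  write_borders(tab, f)
  back <- read_borders(f)
  expect_equal(back$qrs_on, -40)
  expect_error(wave_borders(qrs_on = 0, qrs_end = -1), "must satisfy")
  expect_error(wave_borders(qrs_on = 0, qrs_end = 10, p_on = -5, p_end = 2),
               "must satisfy")
})
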