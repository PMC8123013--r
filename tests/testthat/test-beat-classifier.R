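test_that("beat-graph extraction windows and node counts are exact", {
  nu <- nu_signal(seq(0, 2000, by = 2), list(seq(0, 2000, by = 2)))
  g <- extract_beat_graph(nu, 1, 1000, baseline_correct = FALSE)
  expect_equal(range(g$tau), c(-200, 400))
  expect_length(g$tau, 301) # 2 ms grid over [-200, 400], inclusive ends
  expect_true(any(g$tau == 0)) # the detection point aligns to tau = 0
  # sample at 1401 ms would be outside; at 805..1395 all included
  expect_true(all(g$tau + 1000 >= 800 & g$tau + 1000 <= 1400))
  # truncated by the record edge: flagged by NULL
  expect_null(extract_beat_graph(nu, 1, 100))
  expect_null(extract_beat_graph(nu, 1, 1950))
})

test_that("graph distance: identity, arithmetic oracle and symmetry", {
  grid <- seq(-200, 400, by = 4)
  ga <- structure(list(tau = grid, value = rep(100, length(grid))),
                  class = "beat_graph")
  gb <- structure(list(tau = grid, value = rep(110, length(grid))),
                  class = "beat_graph")
  expect_equal(graph_distance(ga, ga), 0)
  # constant offset on a shared J-point grid with unit weights:
  # s = 10 * J, distance = 10 * J / 105
  J <- length(grid)
  expect_equal(graph_distance(ga, gb, weighting = "flat"), 10 * J / 105,
               tolerance = 1e-12)
  # symmetry under the two-direction average
  set.seed(5)
  gc <- structure(list(tau = sort(runif(150, -200, 400)),
                       value = rnorm(150, 0, 50)), class = "beat_graph")
  gd <- structure(list(tau = sort(runif(90, -200, 400)),
                       value = rnorm(90, 0, 50)), class = "beat_graph")
  expect_equal(graph_distance(gc, gd), graph_distance(gd, gc))
  expect_gte(graph_distance(gc, gd), 0)
  # non-overlapping windows are an error
  ge <- structure(list(tau = 300:400, value = rep(1, 101)), class = "beat_graph")
  gf <- structure(list(tau = -200:-100, value = rep(1, 101)), class = "beat_graph")
  expect_error(graph_distance(ge, gf), "overlap")
})

test_that("the kernel grid is beat-independent with the declared densities", {
  g <- kernel_grid()
  expect_equal(min(diff(g)), 0.25) # 8x the 500 Hz signal density
  d <- diff(g)
  expect_equal(d[findInterval(60, g)], 1)
  expect_equal(d[findInterval(150, g)], 2)
  expect_equal(d[findInterval(300, g)], 4)
  # density decays monotonically with |tau|
  expect_true(all(diff(d[g[-length(g)] >= 0]) >= 0))
})

test_that("kernel updates keep running means of member beats", {
  mk <- function(val) structure(
    list(tau = seq(-200, 400, by = 2), value = rep(val, 301)),
    class = "beat_graph")
  k1 <- update_kernel(NULL, mk(100))
  expect_true(all(k1$value[k1$count > 0] == 100)) # founding beat is the kernel
  k2 <- update_kernel(k1, mk(100))
  expect_true(all(k2$value[k2$count > 0] == 100))
  k3 <- update_kernel(k1, mk(120))
  expect_true(all(abs(k3$value[k3$count > 0] - 110) < 1e-9))
  expect_equal(unique(k3$count[k3$count > 0]), 2L)
})

test_that("identical beats collapse to one class within two passes", {
  beat <- structure(list(tau = seq(-200, 400, by = 2),
                         value = 100 * exp(-(seq(-200, 400, by = 2))^2 / 800)),
                    class = "beat_graph")
  beats <- replicate(20, list(beat), simplify = FALSE)
  cl <- cluster_beats(beats)
  expect_equal(length(cl$kernels), 1L)
  expect_true(cl$converged)
  expect_lte(cl$n_pass, 2L)
  expect_true(all(cl$assignments == 1L))
})

test_that("assignments are invariant to common amplitude scaling", {
  fx <- short_fixture()
  det <- cached("short_det", detect_beats(fx$pECG))
  graphs <- record_beat_graphs(fx$pECG, det)
  cl1 <- cluster_beats(graphs)
  scaled <- fx$pECG
  scaled$values <- lapply(scaled$values, function(v) 3L * v)
  cl2 <- cluster_beats(record_beat_graphs(scaled, det))
  expect_equal(cl1$assignments, cl2$assignments)
})

test_that("termination assignments are a fixed point of nearest-kernel", {
  fx <- short_fixture()
  det <- cached("short_det", detect_beats(fx$pECG))
  graphs <- record_beat_graphs(fx$pECG, det)
  cl <- cluster_beats(graphs)
  expect_true(cl$converged)
  ok <- which(!is.na(cl$assignments))
  for (i in ok) {
    d <- vapply(cl$kernels, function(kern)
      sum(mapply(function(g, k) graph_distance(g, nuecg:::kernel_as_graph(k)),
                 graphs[[i]], kern)), numeric(1))
    expect_equal(which.min(d), cl$assignments[i])
  }
})
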