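test_that("fractional occupancy: degenerate cases and loop oracle", {
  idx <- rbind(c(1, 5), c(6, 10))
  g1 <- matrix(0, 10, 3); g1[, 1] <- 1
  expect_equal(fractional_occupancy(g1, idx),
               rbind(c(1, 0, 0), c(1, 0, 0)))
  gu <- matrix(1 / 3, 10, 3)
  expect_equal(fractional_occupancy(gu, idx)[1, ], rep(1 / 3, 3))
  set.seed(60)
  g <- matrix(runif(30), 10, 3); g <- g / rowSums(g)
  fo <- fractional_occupancy(g, idx, unit_of_segment = c(1, 2))
  expect_equal(fo[1, ], colMeans(g[1:5, ]))
  expect_equal(fo[2, ], colMeans(g[6:10, ]))
  # invariance to unit relabelling: same partition, different labels
  idx3 <- rbind(c(1, 4), c(5, 7), c(8, 10))
  foA <- fractional_occupancy(g, idx3, unit_of_segment = c(1, 2, 1))
  foB <- fractional_occupancy(g, idx3, unit_of_segment = c(7, 5, 7))
  expect_equal(foA, foB)
})

test_that("occupancy entropy: one-hot zero, uniform log K, known value", {
  expect_equal(fo_entropy(c(1, 0, 0)), 0)
  expect_equal(fo_entropy(c(0.5, 0.5)), log(2))
  expect_equal(fo_entropy(rep(1 / 5, 5)), log(5))
  expect_equal(fo_entropy(c(0.7, 0.2, 0.1)), 0.8018, tolerance = 1e-4)
  # maximal at uniform
  set.seed(61)
  for (i in 1:10) {
    p <- runif(4); p <- p / sum(p)
    expect_lte(fo_entropy(p), log(4) + 1e-12)
  }
})

test_that("dwell times follow run-length enumeration, NA when unvisited", {
  path <- c(1, 1, 2, 2, 2, 1)
  dt <- dwell_times(path, rbind(c(1, 6)), K = 3)
  expect_equal(dt[1, 1], 1.5)    # runs of length 2 and 1
  expect_equal(dt[1, 2], 3)
  expect_true(is.na(dt[1, 3]))
  # constant path: dwell equals the segment length
  expect_equal(dwell_times(rep(2, 7), rbind(c(1, 7)), K = 2)[1, 2], 7)
  # visits truncated at segment boundaries count separately
  dt2 <- dwell_times(rep(1, 10), rbind(c(1, 5), c(6, 10)), K = 1,
                     unit_of_segment = c(1, 1))
  expect_equal(dt2[1, 1], 5)
})

test_that("switching rate counts within-segment changes", {
  expect_equal(switching_rate(rep(1, 10), rbind(c(1, 10))), 0)
  expect_equal(switching_rate(rep(c(1, 2), 5), rbind(c(1, 10))), 1)
  expect_equal(switching_rate(c(1, 1, 2, 2, 2, 1), rbind(c(1, 6))), 0.4)
  # equals 1 - mean self-transition indicator on a decoded path
  set.seed(62)
  vp <- sample(1:3, 50, replace = TRUE)
  sr <- switching_rate(vp, rbind(c(1, 50)))
  expect_equal(sr, 1 - mean(vp[-1] == vp[-50]))
  expect_error(switching_rate(1L, rbind(c(1, 1))), "fewer than 2")
})

test_that("state-evoked response averages across trials and stays simplex", {
  set.seed(63)
  g <- matrix(runif(40 * 2), 40, 2); g <- g / rowSums(g)
  idx <- cbind(seq(1, 40, by = 10), seq(10, 40, by = 10))
  ev <- state_evoked_response(g, idx)
  # explicit-loop oracle
  ref <- (g[1:10, ] + g[11:20, ] + g[21:30, ] + g[31:40, ]) / 4
  expect_equal(ev, ref)
  expect_equal(rowSums(ev), rep(1, 10))
  expect_equal(state_evoked_response(g[1:10, ], rbind(c(1, 10))), g[1:10, ])
  expect_error(state_evoked_response(g, rbind(c(1, 10), c(11, 40))), "length")
})
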