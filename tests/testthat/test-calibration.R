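test_that("parameter bounds follow the per-class fractional rules", {
  b <- parameter_bounds()
  expect_equal(nrow(b), 16)
  ta_f <- b[b$param == "ta.F0m", ]
  expect_equal(c(ta_f$lower, ta_f$initial, ta_f$upper), c(635, 1270, 1905))
  sol_l <- b[b$param == "sol.lst", ]
  expect_equal(c(sol_l$lower, sol_l$upper), 0.268 * c(0.85, 1.15))
  expect_true(all(b$lower < b$initial & b$initial < b$upper))
})

test_that("binary encoding: endpoints, round-trip bound, midpoint", {
  b <- parameter_bounds()
  bits <- 12
  lo <- b$lower; names(lo) <- b$param
  hi <- b$upper; names(hi) <- b$param
  expect_equal(encode_params(lo, b, bits), rep(0L, 16 * bits))
  expect_equal(encode_params(hi, b, bits), rep(1L, 16 * bits))
  expect_equal(decode_params(rep(0L, 16 * bits), b, bits), lo)
  expect_equal(decode_params(rep(1L, 16 * bits), b, bits), hi)

  step <- (b$upper - b$lower) / (2^bits - 1)
  set.seed(11)
  for (i in 1:25) {
    p <- b$lower + runif(16) * (b$upper - b$lower)
    names(p) <- b$param
    p2 <- decode_params(encode_params(p, b, bits), b, bits)
    expect_true(all(abs(p2 - p) <= step + 1e-12))
  }

  mid <- (b$lower + b$upper) / 2
  names(mid) <- b$param
  mid2 <- decode_params(encode_params(mid, b, bits), b, bits)
  expect_true(all(abs(mid2 - mid) <= step))

  # out-of-bounds values are clamped before encoding
  over <- hi * 1.2
  expect_equal(decode_params(encode_params(over, b, bits), b, bits), hi)
})

test_that("objective: self-consistency, local-minimum property, order invariance", {
  tr1 <- quick_trial("dorsiflexion", seed = 21)
  tr2 <- quick_trial("plantarflexion", seed = 22)
  truth <- ankle_muscle_defaults("subject")
  obj0 <- calibration_objective(truth, list(tr1, tr2))
  expect_lt(obj0, 1e-10 * (sum(tr1$torque^2) + sum(tr2$torque^2)))

  # perturbing one parameter at a time strictly increases the objective
  v0 <- param_vector(truth)
  for (k in c(1, 4, 5, 9, 14)) {
    for (f in c(0.93, 1.07)) {
      v <- v0; v[k] <- v[k] * f
      expect_gt(calibration_objective(v, list(tr1, tr2)), obj0)
    }
  }

  expect_equal(calibration_objective(truth, list(tr1, tr2)),
               calibration_objective(truth, list(tr2, tr1)))
})

test_that("GA recovers a single free parameter against a grid-search oracle", {
  # noiseless so the objective floor is zero and the grid argmin is the
  # truth itself
  tr <- quick_trial("plantarflexion", seed = 23)
  truth <- param_vector(ankle_muscle_defaults("subject"))

  # all parameters pinned at truth except soleus F0m, which keeps its
  # calibration interval
  b <- parameter_bounds()
  pin <- b$param != "sol.F0m"
  b$lower[pin] <- truth[pin] * (1 - 1e-9)
  b$upper[pin] <- truth[pin] * (1 + 1e-9)
  b$initial[pin] <- truth[pin]

  bits <- 8
  step <- (b$upper - b$lower) / (2^bits - 1)

  # brute-force oracle: evaluate the objective on every codeword of the
  # free parameter
  codes <- 0:(2^bits - 1)
  grid <- b$lower[!pin] + codes / (2^bits - 1) * (b$upper - b$lower)[!pin]
  objs <- vapply(grid, function(x) {
    v <- truth; v["sol.F0m"] <- x
    calibration_objective(v, list(tr))
  }, 1.0)
  oracle_best <- grid[which.min(objs)]

  res <- run_ga(list(tr), bounds = b,
                ga = ga_config(population = 30, generations = 30,
                               bits_per_param = bits, seed = 17))
  expect_lt(abs(res$best_params[["sol.F0m"]] - oracle_best),
            2 * step[!pin] + 1e-9)

  # structural properties of the result
  expect_true(all(res$best_params >= b$lower & res$best_params <= b$upper))
  expect_true(all(diff(res$objective_trace) <= 0))
  expect_equal(res$seed, 17)

  # a different seed converges to the same oracle optimum
  res2 <- run_ga(list(tr), bounds = b,
                 ga = ga_config(population = 30, generations = 30,
                                bits_per_param = bits, seed = 99))
  expect_lt(abs(res2$best_params[["sol.F0m"]] - oracle_best),
            2 * step[!pin] + 1e-9)
  expect_false(identical(res$objective_trace, res2$objective_trace))
})

test_that("decoded populations always lie within bounds", {
  b <- parameter_bounds()
  set.seed(8)
  for (i in 1:50) {
    bs <- sample(0:1, 16 * 10, replace = TRUE)
    v <- decode_params(bs, b, 10)
    expect_true(all(v >= b$lower & v <= b$upper))
  }
})

test_that("calibration results serialize to structured text", {
  tr <- quick_trial("dorsiflexion", seed = 25, duration = 1, fs = 250)
  res <- run_ga(list(tr), ga = ga_config(population = 10, generations = 3,
                                         seed = 2))
  d <- tempfile()
  write_calibration_result(res, d)
  expect_true(file.exists(file.path(d, "calibrated_params.txt")))
  trace <- read.csv(file.path(d, "objective_trace.csv"))
  expect_equal(nrow(trace), 3)
  expect_true(all(diff(trace$best_objective) <= 0))
  p <- read_muscle_config(file.path(d, "calibrated_params.txt"))
  expect_equal(param_vector(p), res$best_params, tolerance = 1e-9)
  unlink(d, recursive = TRUE)
})
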