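test_that("zero-lag filter has unit DC gain, zero phase and stop-band rejection", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  spec <- filter_spec(cutoff = 5, order = 4, fs = fs)

  expect_equal(filter_offline(rep(2.5, 300), spec), rep(2.5, 300),
               tolerance = 1e-10)

  x <- sin(2 * pi * 1 * t)                    # pass-band
  y <- filter_offline(x, spec)
  mid <- 150:850
  expect_equal(max(abs(y[mid])) / max(abs(x[mid])), 1, tolerance = 0.01)
  cc <- stats::ccf(y[mid], x[mid], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)  # zero lag

  x20 <- sin(2 * pi * 20 * t)                 # 4 x cutoff
  expect_lt(max(abs(filter_offline(x20, spec)[mid])), 0.01)

  expect_error(filter_offline(rep(1, 10), spec), "too short")
  expect_error(filter_spec(cutoff = 60, fs = 100), "cutoff")
  expect_error(filter_spec(order = 3), "order")
})

test_that("streaming causal filter equals batch causal filtering bit-exactly", {
  spec <- filter_spec(mode = "CAUSAL")
  x <- withr::with_seed(1, matrix(rnorm(400 * 4), 400, 4))
  batch <- filter_causal(x, spec)
  st <- filter_state(spec, 4)
  stream <- matrix(NA_real_, 400, 4)
  for (i in seq_len(400)) {
    r <- filter_online_step(st, x[i, ])
    st <- r$state
    stream[i, ] <- r$y
  }
  expect_identical(unname(batch), stream)

  # zeros in, zeros out; constants converge to the constant (DC gain 1)
  st0 <- filter_state(spec, 1)
  for (i in 1:5) {
    r <- filter_online_step(st0, 0)
    st0 <- r$state
    expect_identical(r$y, 0)
  }
  const <- filter_causal(rep(4, 600), spec)
  expect_equal(tail(const, 1), 4, tolerance = 1e-6)

  expect_error(filter_online_step(filter_state(spec, 3), c(1, 2)), "mismatch")
})

test_that("min-max scaler maps the training range to [-1, 1] and inverts", {
  tr <- cbind(a = c(2, 3, 4), b = c(0, 5, 10))
  sc <- fit_scaler(tr)
  expect_equal(unname(sc$min), c(2, 0))
  expect_equal(unname(sc$max), c(4, 10))

  scaled <- apply_scaler(sc, tr)
  expect_equal(range(scaled[, "a"]), c(-1, 1))
  expect_equal(range(scaled[, "b"]), c(-1, 1))
  expect_equal(unname(scaled[2, ]), c(0, 0))         # midpoints to 0

  # out-of-range extrapolates linearly, no clipping: 5 under (2, 4) -> 2
  expect_equal(unname(apply_scaler(sc, cbind(a = 5, b = 5))[1, 1]), 2)

  x <- withr::with_seed(2, matrix(runif(60, -5, 15), 30, 2,
                                  dimnames = list(NULL, c("a", "b"))))
  expect_equal(invert_scaler(sc, apply_scaler(sc, x)), x, tolerance = 1e-12)

  expect_error(fit_scaler(cbind(a = c(1, 1), b = c(0, 2))), "constant")
  expect_error(apply_scaler(sc, matrix(0, 2, 3)), "dimension")
})

test_that("scaler serialization restores parameters exactly", {
  tr <- withr::with_seed(3, matrix(rnorm(40), 20, 2,
                                   dimnames = list(NULL, c("u", "v"))))
  sc <- fit_scaler(tr)
  f <- withr::local_tempfile(fileext = ".json")
  write_scaler(sc, f)
  back <- read_scaler(f)
  expect_identical(back$min, sc$min)
  expect_identical(back$max, sc$max)
})

test_that("sensor reduction keeps the documented channel subsets", {
  rec <- fixture_recording(seed = 12)
  full <- rec$channels
  expect_equal(ncol(full), 30)
  r3 <- reduce_sensors(full, "REDUCED_3")
  expect_equal(ncol(r3), 18)
  expect_false(any(grepl("wrist", colnames(r3))))
  c1 <- reduce_sensors(full, "CHEST_1")
  expect_equal(ncol(c1), 6)
  expect_true(all(grepl("^chest_", colnames(c1))))

  expect_identical(reduce_sensors(full, "FULL_5"), full)       # identity
  expect_identical(reduce_sensors(r3, "REDUCED_3"), r3)        # idempotent
  expect_identical(reduce_sensors(r3, "CHEST_1"), c1)          # nested
  expect_error(reduce_sensors(c1, "FULL_5"), "lacks channels")
})

test_that("windowing counts windows and labels each by its last sample", {
  m <- matrix(seq_len(330), 110, 3)
  expect_equal(dim(windowize(m[1:100, ], window_spec(100, 1))$x)[3], 1)
  expect_equal(dim(windowize(m, window_spec(100, 1))$x)[3], 11)
  expect_equal(dim(windowize(m, window_spec(50, 10))$x)[3], 7)
  expect_error(windowize(m[1:10, ], window_spec(100, 1)), "shorter")

  # window content is the trailing W samples
  w <- windowize(m, window_spec(100, 1))
  expect_equal(w$x[, , 11], m[11:110, ])

  # label-of-last-sample across a STAND -> LIFT transition
  act <- c(rep("STAND", 105), rep("INTERACT", 5))
  inter <- c(rep(NA_character_, 105), rep("LIFT", 5))
  w2 <- windowize(m, window_spec(100, 1), action = act, interaction = inter)
  # windows end at samples 100..110; sample 106 is the first INTERACT one
  expect_equal(w2$action[6], "STAND")
  expect_equal(w2$action[7], "INTERACT")
  expect_equal(w2$interaction[7], "LIFT")
})
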