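# Toy windows: class k = constant level k with a touch of noise, trivially
# separable, tiny geometry so training takes well under a second.
toy_windows <- function(n_per_class, levels, W = 10, F = 4, seed = 1) {
  withr::with_seed(seed, {
    n <- n_per_class * length(levels)
    x <- array(0, dim = c(W, F, n))
    y <- character(n)
    i <- 0
    for (k in seq_along(levels)) {
      for (j in seq_len(n_per_class)) {
        i <- i + 1
        x[, , i] <- levels[[k]]$level + matrix(rnorm(W * F, sd = 0.05), W, F)
        y[i] <- levels[[k]]$label
      }
    }
    list(x = x, y = y)
  })
}

toy_config <- function(seed = 1, epochs = 30) {
  model_config(recurrent_units = c(6, 4), dense_units = 4,
               window = window_spec(10, 1), batch_size = 16,
               max_epochs = epochs, patience = 10, seed = seed)
}

test_that("model builders enforce head sizes and feature widths", {
  har <- build_har_model(model_config(), 30)
  expect_equal(unlist(har$heads), c(action = 3, interaction = 2))
  expect_equal(har$sensor_config, "FULL_5")
  pay <- build_payload_model(model_config(), 6)
  expect_equal(unlist(pay$heads), c(payload = 3))
  expect_equal(pay$sensor_config, "CHEST_1")
  expect_error(build_har_model(model_config(), 7), "30, 18 or 6")
  expect_error(predict_model(har, array(0, c(10, 30, 1))), "untrained")
})

test_that("softmax heads emit normalized probabilities for any input", {
  toys <- toy_windows(6, list(list(label = "STAND", level = -1),
                              list(label = "WALK", level = 0),
                              list(label = "INTERACT", level = 1)),
                      W = 10, F = 6)
  m <- build_har_model(toy_config(epochs = 2), 6)
  m <- train_model(m, toys$x, action = toys$y,
                   interaction = ifelse(toys$y == "INTERACT", "LIFT", NA))
  pr <- predict_model(m, toys$x)
  expect_equal(dim(pr$action), c(18, 3))
  expect_equal(dim(pr$interaction), c(18, 2))
  expect_equal(rowSums(pr$action), rep(1, 18), tolerance = 1e-9)
  expect_equal(rowSums(pr$interaction), rep(1, 18), tolerance = 1e-9)
  expect_true(all(pr$action >= 0))
})

test_that("capacity sanity: separable toy data is learned to F1 = 1", {
  toys <- toy_windows(10, list(list(label = "5", level = -1),
                               list(label = "10", level = 0),
                               list(label = "15", level = 1)),
                      W = 10, F = 4)
  m <- build_payload_model(toy_config(), 30)
  expect_error(train_model(m, toys$x, payload = as.numeric(toys$y)),
               "feature width")
  m <- build_payload_model(toy_config(), 6)
  toys6 <- toy_windows(10, list(list(label = "5", level = -1),
                                list(label = "10", level = 0),
                                list(label = "15", level = 1)),
                       W = 10, F = 6)
  fit <- train_model(m, toys6$x, payload = as.numeric(toys6$y))
  pred <- classify(predict_model(fit, toys6$x)$payload)
  r <- score_labels(toys6$y, pred, as.character(PAYLOADS))
  expect_equal(r$weighted_f1, 1)
  # training loss decreased over the retained path
  h <- fit$history
  expect_lt(h$train_loss[fit$best_epoch], h$train_loss[1])
})

test_that("training is reproducible for a fixed seed and fails cleanly", {
  toys <- toy_windows(8, list(list(label = "5", level = -0.5),
                              list(label = "10", level = 0.2),
                              list(label = "15", level = 0.9)),
                      W = 10, F = 6, seed = 3)
  m <- build_payload_model(toy_config(seed = 7, epochs = 5), 6)
  f1 <- train_model(m, toys$x, payload = as.numeric(toys$y))
  f2 <- train_model(m, toys$x, payload = as.numeric(toys$y))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
  # a different seed changes initialization
  m2 <- build_payload_model(toy_config(seed = 8, epochs = 5), 6)
  f3 <- train_model(m2, toys$x, payload = as.numeric(toys$y))
  expect_false(identical(f1$weights, f3$weights))

  expect_error(train_model(m, toys$x[, , 0, drop = FALSE], payload = numeric(0)),
               "empty")
  only2 <- toys$y != "15"
  expect_error(train_model(m, toys$x[, , only2, drop = FALSE],
                           payload = as.numeric(toys$y[only2])),
               "entirely absent")
})

test_that("the interaction head is masked outside object interaction", {
  # non-INTERACT windows carry NA interaction labels; training must accept
  # them and the head must still learn the labeled subset
  toys <- toy_windows(10, list(list(label = "STAND", level = -1.5),
                               list(label = "WALK", level = -0.5),
                               list(label = "LIFT", level = 0.6),
                               list(label = "LOWER", level = 1.4)),
                      W = 10, F = 6, seed = 4)
  act <- ifelse(toys$y %in% c("LIFT", "LOWER"), "INTERACT", toys$y)
  inter <- ifelse(toys$y %in% c("LIFT", "LOWER"), toys$y, NA)
  m <- build_har_model(toy_config(epochs = 30), 6)
  fit <- train_model(m, toys$x, action = act, interaction = inter)
  pr <- predict_model(fit, toys$x)
  lab <- classify(pr$interaction[act == "INTERACT", , drop = FALSE])
  expect_equal(mean(lab == inter[act == "INTERACT"]), 1)
})

test_that("a trained subject suite respects the split contracts", {
  fx <- fixture_suite()
  suite <- fx$suite
  expect_s3_class(suite$har, "exohar_model")
  expect_s3_class(suite$payload, "exohar_model")
  expect_equal(suite$har$n_features, 30)
  # HAR training never touches D3 (its test set)
  expect_true(all(vapply(suite$splits$HAR$train,
                         function(s) s$rec$protocol_id == 2L &&
                           identical(s$rec$subject_id, fx$bundle$D2$subject_id),
                         logical(1))))
  # payload training uses both protocols
  protos <- vapply(suite$splits$PAYLOAD$train,
                   function(s) s$rec$protocol_id, integer(1))
  expect_setequal(unique(protos), c(1L, 2L))
})

test_that("model serialization restores predictions exactly", {
  fx <- fixture_suite()
  f <- withr::local_tempfile(fileext = ".json")
  write_model(fx$suite$payload, f)
  back <- read_model(f)
  expect_identical(back$weights, fx$suite$payload$weights)
  expect_identical(back$scaler$min, fx$suite$payload$scaler$min)
  x <- withr::with_seed(5, array(rnorm(100 * 30 * 3), c(100, 30, 3)))
  expect_identical(predict_model(back, x), predict_model(fx$suite$payload, x))
})
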