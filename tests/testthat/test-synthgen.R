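test_that("subject profiles are seed-deterministic, distinct and in range", {
  p1 <- make_subject_profile(0)
  p2 <- make_subject_profile(0)
  expect_identical(p1, p2)
  p3 <- make_subject_profile(1)
  expect_false(identical(p1[-1], p3[-1]))
  for (seed in c(0, 1, 17, 123456)) {
    p <- make_subject_profile(seed)
    expect_gt(p$lift_duration_base, 0)
    expect_gt(p$gait_frequency, 0)
    expect_gt(p$noise_sd_accel, 0)
    expect_gte(p$rep_variability_cv, 0)
    expect_lte(p$rep_variability_cv, 0.5)
  }
})

test_that("protocol-1 scripts emit the lift/lower cycle structure", {
  s <- script_protocol1(c(5, 10, 15), reps_per_payload = 10, pause = 10)
  expect_equal(sum(s$interaction == "LIFT", na.rm = TRUE), 30)
  expect_equal(sum(s$interaction == "LOWER", na.rm = TRUE), 30)
  expect_true(all(s$nominal_duration[s$action == "STAND"] == 10))
  # interaction/payload present iff INTERACT
  expect_true(all(is.na(s$interaction[s$action != "INTERACT"])))
  expect_true(all(!is.na(s$payload[s$action == "INTERACT"])))

  s1 <- script_protocol1(5, reps_per_payload = 1, pause = 2)
  expect_equal(sum(s1$interaction == "LIFT", na.rm = TRUE), 1)
  expect_equal(sum(s1$interaction == "LOWER", na.rm = TRUE), 1)
  expect_error(script_protocol1(numeric(0)), "non-empty")
})

test_that("protocol-2 scripts cover all actions with the documented sequence", {
  s <- script_protocol2(10, reps = 10)
  expect_equal(sum(s$interaction == "LIFT", na.rm = TRUE), 10)
  expect_equal(sum(s$interaction == "LOWER", na.rm = TRUE), 10)
  expect_setequal(unique(s$action), c("STAND", "WALK", "INTERACT"))

  s3 <- script_protocol2_multi(c(5, 10, 15), reps = 2)
  expect_equal(sum(s3$interaction == "LIFT", na.rm = TRUE), 6)
  expect_equal(length(unique(s3$rep)), 6)

  one <- script_protocol2(5, reps = 1)
  rec <- render_recording(make_subject_profile(1), one, seed = 1)
  expect_setequal(unique(rec$action), c("STAND", "WALK", "INTERACT"))
})

test_that("rendering is deterministic and honors the static limit", {
  p <- make_subject_profile(5)
  s <- script_protocol1(5, 1, pause = 2)
  r1 <- render_recording(p, s, seed = 9)
  r2 <- render_recording(p, s, seed = 9)
  expect_identical(r1, r2)
  expect_false(identical(r1$channels, render_recording(p, s, seed = 10)$channels))
  expect_equal(ncol(r1$channels), 30)

  # standing still, zero noise: chest accelerometer reads gravity on its
  # longitudinal axis, gyro silent
  stand <- structure(data.frame(action = "STAND", interaction = NA_character_,
                                payload = NA_real_, nominal_duration = 3,
                                rep = 1L),
                     class = c("exohar_script", "data.frame"),
                     protocol_id = 1L)
  rs <- render_recording(p, stand, seed = 1, noise_scale = 0)
  expect_equal(max(abs(rs$channels[, "chest_ax"] - 9.81)), 0, tolerance = 1e-12)
  expect_equal(max(abs(rs$channels[, "chest_gy"])), 0, tolerance = 1e-12)
})

test_that("payload slows the lift and the label track shows it", {
  p <- make_subject_profile(2)
  p$rep_variability_cv <- 0   # isolate the payload effect
  dur_of <- function(w) {
    s <- script_protocol1(w, 1, pause = 1)
    rec <- render_recording(p, s, seed = 1, noise_scale = 0)
    seg <- recording_segments(rec)
    seg$duration_s[!is.na(seg$interaction) & seg$interaction == "LIFT"]
  }
  expect_gt(dur_of(15), dur_of(5))
  expect_gt(dur_of(10), dur_of(5))
})

test_that("label track is total and transitions precede the kinematic peak", {
  rec <- fixture_recording(seed = 4)
  expect_true(all(rec$action %in% ACTIONS))
  ii <- rec$action == "INTERACT"
  expect_false(anyNA(rec$interaction[ii]))
  expect_false(anyNA(rec$payload[ii]))
  expect_true(all(is.na(rec$interaction[!ii])))
  expect_true(all(is.na(rec$payload[!ii])))

  seg <- recording_segments(rec)
  gy <- rec$channels[, "chest_gy"]
  for (i in which(!is.na(seg$interaction))) {
    idx <- seg$start[i]:seg$end[i]
    peak <- idx[which.max(abs(gy[idx]))]
    expect_gt(peak, seg$start[i])   # labeled onset precedes the peak
  }
})

test_that("payload classes separate by mean lift duration without noise", {
  p <- make_subject_profile(6)
  s <- script_protocol1(c(5, 15), reps_per_payload = 5, pause = 1)
  rec <- render_recording(p, s, seed = 2, noise_scale = 0)
  seg <- recording_segments(rec)
  lifts <- seg[!is.na(seg$interaction) & seg$interaction == "LIFT", ]
  d5 <- lifts$duration_s[lifts$payload == 5]
  d15 <- lifts$duration_s[lifts$payload == 15]
  thr <- (mean(d5) + mean(d15)) / 2
  expect_true(all(d5 < thr))       # a simple threshold separates perfectly
  expect_true(all(d15 > thr))
})

test_that("generate_study yields the experimental dataset design", {
  study <- generate_study(2, seed = 3, config = tiny_study_config())
  expect_length(study, 2)
  for (b in study) {
    expect_s3_class(b, "exohar_bundle")
    expect_equal(b$D1$protocol_id, 1L)
    expect_true(all(b$D2$payload[b$D2$action == "INTERACT"] == 10))
    seg3 <- recording_segments(b$D3)
    expect_equal(sum(seg3$interaction == "LIFT", na.rm = TRUE),
                 2 * 3)            # reps_d3 x 3 payloads
  }
  # reproducible
  study2 <- generate_study(2, seed = 3, config = tiny_study_config())
  expect_identical(study, study2)
})
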