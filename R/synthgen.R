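# Synthetic multi-IMU motion generator.
#
# Each body segment carrying a sensor is given a single pitch-angle trajectory
# phi(t) (degrees). The simulated 6-axis signals follow a reduced kinematic
# model: the gyroscope's y axis measures dphi/dt; the accelerometer measures
# the gravity vector projected through the pitch plus a tangential term
# proportional to the angular acceleration (scaled per placement), plus
# additive white Gaussian noise. This captures the features the classifiers
# rely on in real lifting data — trunk-flexion bells whose duration and
# amplitude depend on the handled load, gait oscillations of the thighs, and
# quiet standing — without claiming biomechanical fidelity.

GRAVITY <- 9.81

#' Draw a synthetic subject's kinematic profile
#'
#' Parameters are drawn uniformly from fixed documented ranges, emulating
#' inter-subject variability of task kinematics. Units: durations s, angles
#' deg, gait frequency Hz, noise SDs m/s^2 (accel) and deg/s (gyro);
#' `payload_slowing_coeff` and `payload_amplitude_coeff` are per-kg fractional
#' increases of lift duration and of segment acceleration amplitude;
#' `rep_variability_cv` is the coefficient of variation applied to durations
#' and amplitudes of every repetition.
#'
#' @param seed Non-negative integer; same seed, same profile.
#' @return A list of class `exohar_profile`.
#' @export
make_subject_profile <- function(seed) {
  stopifnot(is.numeric(seed), seed >= 0, seed == round(seed))
  withr::with_seed(as.integer(seed), {
    p <- list(
      subject_id = sprintf("S%04d", as.integer(seed) %% 10000L),
      lift_duration_base = runif(1, 1.0, 1.6),
      trunk_flexion_peak = runif(1, 40, 70),
      payload_slowing_coeff = runif(1, 0.04, 0.07),
      payload_amplitude_coeff = runif(1, 0.03, 0.05),
      gait_frequency = runif(1, 0.8, 1.1),
      noise_sd_accel = runif(1, 0.2, 0.4),
      noise_sd_gyro = runif(1, 2, 5),
      rep_variability_cv = runif(1, 0.04, 0.08))
    class(p) <- "exohar_profile"
    p
  })
}

PROFILE_RANGES <- list(
  lift_duration_base = c(1.0, 1.6), trunk_flexion_peak = c(40, 70),
  payload_slowing_coeff = c(0.04, 0.07), payload_amplitude_coeff = c(0.03, 0.05),
  gait_frequency = c(0.8, 1.1), noise_sd_accel = c(0.2, 0.4),
  noise_sd_gyro = c(2, 5), rep_variability_cv = c(0.04, 0.08))

#' @export
print.exohar_profile <- function(x, ...) {
  cat("<exohar_profile>", x$subject_id, "\n")
  for (nm in setdiff(names(x), "subject_id"))
    cat(sprintf("  %-24s %.4g\n", nm, x[[nm]]))
  invisible(x)
}

# ---- protocol scripts --------------------------------------------------------

script_segment <- function(action, duration, interaction = NA_character_,
                           payload = NA_real_, rep = NA_integer_) {
  data.frame(action = action, interaction = interaction, payload = payload,
             nominal_duration = duration, rep = rep, stringsAsFactors = FALSE)
}

#' Script the lift/lower protocol (protocol 1)
#'
#' For each payload and repetition: a standing pause, a lift (floor to desk),
#' another pause, a lower (desk to floor). With the defaults (three payloads,
#' 10 repetitions) this yields 30 lifting and 30 lowering segments.
#'
#' @param payloads Payload classes in kg (subset of [PAYLOADS]).
#' @param reps_per_payload Repetitions per payload (>= 1).
#' @param pause Standing pause in seconds between actions (default 10).
#' @param lift_duration Nominal interact-segment duration in seconds; the
#'   renderer rescales it per payload and repetition.
#' @return A data.frame of class `exohar_script`: one row per segment with
#'   columns action, interaction, payload, nominal_duration, rep.
#' @export
script_protocol1 <- function(payloads = PAYLOADS, reps_per_payload = 10,
                             pause = 10, lift_duration = 1.5) {
  if (length(payloads) == 0) stop("payload list must be non-empty")
  stopifnot(all(payloads %in% PAYLOADS), reps_per_payload >= 1, pause >= 0)
  segs <- list()
  for (w in payloads) for (r in seq_len(reps_per_payload)) {
    rep_id <- (match(w, payloads) - 1L) * reps_per_payload + r
    segs[[length(segs) + 1]] <- rbind(
      script_segment("STAND", pause, rep = rep_id),
      script_segment("INTERACT", lift_duration, "LIFT", w, rep_id),
      script_segment("STAND", pause, rep = rep_id),
      script_segment("INTERACT", lift_duration, "LOWER", w, rep_id))
  }
  out <- do.call(rbind, segs)
  structure(out, class = c("exohar_script", "data.frame"), protocol_id = 1L)
}

#' Script the stand/walk/manipulation protocol (protocol 2)
#'
#' Per repetition the fixed sequence STAND, WALK (approach), INTERACT/LIFT,
#' WALK (carry), INTERACT/LOWER, WALK (return). Carrying is labeled WALK:
#' the interaction vocabulary is reserved for the lift and lower events
#' themselves.
#'
#' @param payload Single payload class in kg.
#' @param reps Number of sequence repetitions (>= 1).
#' @param stand,walk Nominal durations (s) of the stand and walk segments.
#' @param lift_duration Nominal interact duration (s), rescaled by the renderer.
#' @return An `exohar_script` data.frame.
#' @export
script_protocol2 <- function(payload = 10, reps = 10, stand = 3, walk = 3,
                             lift_duration = 1.5) {
  stopifnot(length(payload) == 1, payload %in% PAYLOADS, reps >= 1)
  segs <- list()
  for (r in seq_len(reps)) {
    segs[[length(segs) + 1]] <- rbind(
      script_segment("STAND", stand, rep = r),
      script_segment("WALK", walk, rep = r),
      script_segment("INTERACT", lift_duration, "LIFT", payload, r),
      script_segment("WALK", walk, rep = r),
      script_segment("INTERACT", lift_duration, "LOWER", payload, r),
      script_segment("WALK", walk, rep = r))
  }
  out <- do.call(rbind, segs)
  structure(out, class = c("exohar_script", "data.frame"), protocol_id = 2L)
}

#' Concatenate protocol-2 scripts over several payloads
#'
#' Convenience for dataset D3: `reps` repetitions of protocol 2 for each
#' payload in turn, repetition indices running consecutively.
#'
#' @inheritParams script_protocol2
#' @param payloads Payload classes in kg.
#' @return An `exohar_script` data.frame.
#' @export
script_protocol2_multi <- function(payloads = PAYLOADS, reps = 2, stand = 3,
                                   walk = 3, lift_duration = 1.5) {
  parts <- lapply(seq_along(payloads), function(i) {
    s <- script_protocol2(payloads[i], reps, stand, walk, lift_duration)
    s$rep <- s$rep + (i - 1L) * reps
    s
  })
  out <- do.call(rbind, parts)
  structure(out, class = c("exohar_script", "data.frame"), protocol_id = 2L)
}

# ---- trajectory primitives ---------------------------------------------------

# Skewed raised-cosine bell on [0, 1]: rises over [0, s], falls over [s, 1];
# C1-continuous, zero value and slope at both ends.
bell <- function(u, s) {
  ifelse(u < s,
         0.5 * (1 - cos(pi * u / s)),
         0.5 * (1 + cos(pi * (u - s) / (1 - s))))
}

# Raised-cosine edge taper over the first/last `ramp` fraction of a segment.
edge_taper <- function(n, ramp_frac = 0.2) {
  u <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  r <- max(ramp_frac, 1e-9)
  w[u < r] <- 0.5 * (1 - cos(pi * u[u < r] / r))
  w[u > 1 - r] <- 0.5 * (1 - cos(pi * (1 - u[u > 1 - r]) / r))
  w
}

# Pitch trajectories (deg) for all 5 placements over one segment.
# Returns an n x 5 matrix ordered as PLACEMENTS.
segment_pitch <- function(action, interaction, payload, n, fs, profile,
                          amp_factor, phase0) {
  t <- seq_len(n) / fs
  u <- (seq_len(n) - 0.5) / n
  phi <- matrix(0, n, 5, dimnames = list(NULL, PLACEMENTS))
  if (action == "STAND" || n == 0) return(phi)
  if (action == "WALK") {
    f <- profile$gait_frequency
    tap <- edge_taper(n, 0.15)
    swing <- 20 * sin(2 * pi * f * t + phase0) * tap
    phi[, "left_thigh"] <- swing
    phi[, "right_thigh"] <- -swing
    phi[, "chest"] <- 2 * sin(4 * pi * f * t + phase0) * tap
    phi[, "left_wrist"] <- 8 * sin(2 * pi * f * t + phase0 + pi) * tap
    phi[, "right_wrist"] <- 8 * sin(2 * pi * f * t + phase0) * tap
    return(phi)
  }
  # INTERACT: trunk-flexion bell; lifts peak early, lowers peak late, and the
  # wrists rotate with opposite sign, so the two interaction types are
  # kinematically distinct even from the chest alone. On top of the bell, a
  # sustained counterbalance lean proportional to the held mass (the trunk
  # and arms offset the load for as long as it is in the hands), so the
  # payload is observable in any window inside the segment, not only at the
  # movement peak.
  skew <- if (interaction == "LIFT") 0.35 else 0.65
  wsign <- if (interaction == "LIFT") -1 else 1
  b <- bell(u, skew)
  amp <- profile$trunk_flexion_peak * amp_factor
  lean <- LEAN_DEG_PER_KG * payload * amp_factor * edge_taper(n, 0.15)
  phi[, "chest"] <- amp * b + lean
  phi[, "left_wrist"] <- wsign * 0.8 * amp * b + 2 * lean
  phi[, "right_wrist"] <- wsign * 0.8 * amp * b + 2 * lean
  phi[, "left_thigh"] <- 0.4 * amp * b
  phi[, "right_thigh"] <- 0.4 * amp * b
  phi
}

# Sustained trunk lean while supporting a load, deg per kg.
LEAN_DEG_PER_KG <- 0.6

# 6-axis signals from a pitch trajectory. kin_gain scales the tangential
# acceleration term (payload-amplitude modulation applies here).
imu_from_pitch <- function(phi_deg, fs, kin_gain) {
  n <- length(phi_deg)
  phi <- phi_deg * pi / 180
  dphi <- c(0, diff(phi)) * fs                 # rad/s
  ddphi <- c(0, diff(dphi)) * fs               # rad/s^2
  cbind(
    ax = GRAVITY * cos(phi),
    ay = rep(0, n),
    az = GRAVITY * sin(phi) + kin_gain * ddphi,
    gx = rep(0, n),
    gy = phi_deg * 0 + c(0, diff(phi_deg)) * fs,  # deg/s
    gz = rep(0, n))
}

# Tangential-lever gains (m) per placement: wrists move most, chest least.
KIN_GAIN <- c(chest = 0.25, left_wrist = 0.45, right_wrist = 0.45,
              left_thigh = 0.30, right_thigh = 0.30)

# ---- renderer ----------------------------------------------------------------

#' Render a protocol script into a labeled recording
#'
#' Every script segment is realized with a per-repetition duration/amplitude
#' jitter (`rep_variability_cv`). Interact segments use the skewed
#' trunk-flexion bell whose duration is
#' `lift_duration_base * (1 + payload_slowing_coeff * w)` and whose
#' acceleration amplitude scales as `(1 + payload_amplitude_coeff * w)` for a
#' payload of `w` kg. Walking uses tapered sinusoidal thigh/arm oscillation at
#' the subject's gait frequency. White Gaussian noise is added per channel.
#' Transitions are implicit in the smooth per-segment trajectories, which
#' start and end at rest inside each segment: every sample carries the label
#' of the segment it belongs to, so a transition is assigned to the
#' *subsequent* class and the labeled onset precedes the kinematic peak.
#'
#' @param profile An `exohar_profile`.
#' @param script An `exohar_script`.
#' @param fs Sampling rate in Hz (default 100).
#' @param seed Integer; rendering is deterministic given
#'   (profile, script, fs, seed).
#' @param noise_scale Multiplier on the profile's noise SDs (default 1);
#'   0 disables noise.
#' @return An `exohar_recording`.
#' @export
render_recording <- function(profile, script, fs = 100, seed = 0L,
                             noise_scale = 1) {
  stopifnot(inherits(profile, "exohar_profile"), inherits(script, "exohar_script"))
  if (fs <= 0) stop("fs must be positive")
  withr::with_seed(as.integer(seed), {
    nseg <- nrow(script)
    chan_list <- vector("list", nseg)
    act <- vector("list", nseg); intr <- vector("list", nseg)
    pay <- vector("list", nseg)
    cv <- profile$rep_variability_cv
    for (i in seq_len(nseg)) {
      sg <- script[i, ]
      jit_d <- max(0.5, 1 + cv * rnorm(1))
      jit_a <- max(0.5, 1 + cv * rnorm(1))
      if (sg$action == "INTERACT") {
        w <- sg$payload
        dur <- profile$lift_duration_base * (1 + profile$payload_slowing_coeff * w) * jit_d
        # heavier loads: deeper trunk flexion (gravity-projection cue visible
        # from the chest alone) and stronger tangential acceleration
        amp_factor <- (1 + 0.5 * profile$payload_amplitude_coeff * w) * jit_a
        kin_scale <- (1 + profile$payload_amplitude_coeff * w) * jit_a
      } else {
        dur <- sg$nominal_duration * if (sg$action == "WALK") jit_d else 1
        amp_factor <- jit_a
        kin_scale <- 1
      }
      n <- max(1L, as.integer(round(dur * fs)))
      phase0 <- runif(1, 0, 2 * pi)
      phi <- segment_pitch(sg$action, sg$interaction, sg$payload, n, fs,
                           profile, amp_factor, phase0)
      seg_chan <- matrix(0, n, 30, dimnames = list(NULL, channel_names()))
      for (p in PLACEMENTS) {
        sig <- imu_from_pitch(phi[, p], fs, KIN_GAIN[[p]] * kin_scale)
        seg_chan[, paste(p, AXES, sep = "_")] <- sig
      }
      chan_list[[i]] <- seg_chan
      act[[i]] <- rep(sg$action, n)
      intr[[i]] <- rep(sg$interaction, n)
      pay[[i]] <- rep(sg$payload, n)
    }
    channels <- do.call(rbind, chan_list)
    # additive sensor noise
    if (noise_scale > 0) {
      acc_cols <- grepl("_a[xyz]$", colnames(channels))
      noise <- matrix(rnorm(length(channels)), nrow(channels), ncol(channels))
      noise[, acc_cols] <- noise[, acc_cols] * profile$noise_sd_accel * noise_scale
      noise[, !acc_cols] <- noise[, !acc_cols] * profile$noise_sd_gyro * noise_scale
      channels <- channels + noise
    }
    labeled_recording(profile$subject_id, attr(script, "protocol_id"), fs,
                      channels,
                      unlist(act), unlist(intr), unlist(pay))
  })
}

# ---- study generation --------------------------------------------------------

#' Default study configuration
#'
#' Controls the generator at study scale: sampling rate, protocol-1 pause, the
#' protocol-2 stand/walk durations, payload set and repetition counts matching
#' the experimental design (D1: 10 reps x 3 payloads of protocol 1; D2: 10
#' reps of protocol 2 at 10 kg; D3: 2 reps x 3 payloads of protocol 2), and a
#' global noise multiplier (difficulty). `desk_scale = TRUE` shortens the
#' pauses and walks so that a full study renders and trains quickly on one
#' CPU; label structure and class counts are unchanged.
#'
#' @param fs Sampling rate (Hz).
#' @param pause Protocol-1 standing pause (s).
#' @param stand,walk Protocol-2 stand/walk durations (s).
#' @param reps_d1,reps_d2,reps_d3 Repetition counts.
#' @param payloads Payload class set (kg).
#' @param noise_scale Multiplier on profile noise SDs.
#' @param desk_scale If TRUE, override pause/stand/walk with short values
#'   (2 s) for fast runs.
#' @return A named list.
#' @export
study_config <- function(fs = 100, pause = 10, stand = 3, walk = 3,
                         reps_d1 = 10, reps_d2 = 10, reps_d3 = 2,
                         payloads = PAYLOADS, noise_scale = 1,
                         desk_scale = FALSE) {
  if (desk_scale) { pause <- 2; stand <- 2; walk <- 2 }
  list(fs = fs, pause = pause, stand = stand, walk = walk,
       reps_d1 = reps_d1, reps_d2 = reps_d2, reps_d3 = reps_d3,
       payloads = payloads, noise_scale = noise_scale)
}

# Seed-splitting: one study seed deterministically yields per-subject and
# per-dataset seeds, all < 2^31.
derive_seed <- function(seed, index, stream = 0L) {
  (as.numeric(seed) * 1000003 + index * 7919 + stream * 104729) %% 2147483647
}

#' Generate one subject's dataset bundle
#'
#' Renders D1 (protocol 1), D2 (protocol 2, 10 kg) and D3 (protocol 2, all
#' payloads) for the subject whose profile is drawn from `subject_seed`.
#'
#' @param subject_seed Integer seed for the subject profile.
#' @param config A [study_config()] list.
#' @return An `exohar_bundle`.
#' @export
generate_subject <- function(subject_seed, config = study_config()) {
  profile <- make_subject_profile(subject_seed)
  s1 <- script_protocol1(config$payloads, config$reps_d1, pause = config$pause)
  s2 <- script_protocol2(10, config$reps_d2, stand = config$stand, walk = config$walk)
  s3 <- script_protocol2_multi(config$payloads, config$reps_d3,
                               stand = config$stand, walk = config$walk)
  dataset_bundle(
    D1 = render_recording(profile, s1, config$fs, derive_seed(subject_seed, 1),
                          config$noise_scale),
    D2 = render_recording(profile, s2, config$fs, derive_seed(subject_seed, 2),
                          config$noise_scale),
    D3 = render_recording(profile, s3, config$fs, derive_seed(subject_seed, 3),
                          config$noise_scale))
}

#' Generate a full synthetic study
#'
#' @param n_subjects Number of subjects (the experimental cohort was 12).
#' @param seed Study seed; per-subject seeds are derived from it.
#' @param config A [study_config()] list.
#' @return A named list of `exohar_bundle`, one per subject.
#' @export
generate_study <- function(n_subjects = 12, seed = 0L, config = study_config()) {
  stopifnot(n_subjects >= 1)
  out <- lapply(seq_len(n_subjects), function(i)
    generate_subject(derive_seed(seed, i, stream = 9L), config))
  names(out) <- vapply(out, function(b) b$D1$subject_id, character(1))
  out
}
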