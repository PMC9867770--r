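# Gated two-model streaming cascade: each incoming 100-Hz sample is causally
# filtered, scaled with the offline-fit scaler, and pushed into a circular
# buffer of one window. Once the buffer is full the HAR network runs on every
# step; the interaction head is read and the payload network triggered only
# when the predicted action is object interaction.

#' Initialize the streaming state
#'
#' @param har_model,payload_model Trained `exohar_model`s sharing the same
#'   sensor configuration; the HAR model must carry its scaler.
#' @param fspec Causal [filter_spec()] (the online single-pass filter).
#' @return A list of class `exohar_stream` holding the per-channel causal
#'   filter state, the circular buffer, scalers and both models.
#' @export
stream_state <- function(har_model, payload_model,
                         fspec = filter_spec(mode = "CAUSAL")) {
  stopifnot(inherits(har_model, "exohar_model"),
            inherits(payload_model, "exohar_model"))
  if (har_model$sensor_config != payload_model$sensor_config)
    stop("models must share the sensor configuration")
  if (is.null(har_model$scaler) || is.null(payload_model$scaler))
    stop("models must carry their training scalers")
  W <- har_model$config$window$length
  Fh <- har_model$n_features
  structure(list(
    har = har_model, payload = payload_model,
    # the causal filter warm-starts at the steady state of the first sample
    # (set on the first step), so stream start injects no step transient
    filter = filter_state(fspec, Fh),
    # circular buffer of causally-filtered (unscaled) samples; row `head`
    # is the next slot to overwrite
    buffer = matrix(NA_real_, W, Fh),
    head = 1L, count = 0L, t = 0L, W = W, n_features = Fh),
    class = "exohar_stream")
}

#' Advance the stream by one raw sample
#'
#' Filters causally, scales, pushes into the buffer. During warm-up (fewer
#' than one full window seen) no prediction is emitted. Otherwise the HAR
#' model runs on the current window; if and only if the predicted action is
#' `INTERACT`, the interaction head is read and the payload model is run on
#' the same window.
#'
#' @param state An `exohar_stream`.
#' @param sample Raw numeric vector (one multichannel sample, model feature
#'   order).
#' @return A list `(state, prediction)`; `prediction` is `NULL` during
#'   warm-up, else a one-row data.frame (class `exohar_gated`) with the
#'   timestamp (s), action + probabilities, and interaction/payload fields
#'   that are `NA` unless the action is `INTERACT`.
#' @export
stream_step <- function(state, sample) {
  if (length(sample) != state$n_features) stop("sample width mismatch")
  fs <- state$filter$spec$fs
  if (state$t == 0L)
    state$filter <- filter_state(state$filter$spec, state$n_features,
                                 x0 = sample)
  st <- filter_online_step(state$filter, sample)
  state$filter <- st$state
  state$buffer[state$head, ] <- st$y
  state$head <- if (state$head == state$W) 1L else state$head + 1L
  state$count <- min(state$count + 1L, state$W)
  state$t <- state$t + 1L
  if (state$count < state$W)
    return(list(state = state, prediction = NULL))
  # unroll the circular buffer: oldest sample first
  ord <- c(seq(state$head, state$W), seq_len(state$head - 1L))
  if (state$head == 1L) ord <- seq_len(state$W)
  win <- state$buffer[ord, , drop = FALSE]
  colnames(win) <- state$har$scaler$features
  hwin <- apply_scaler(state$har$scaler, win)
  x <- array(hwin, dim = c(state$W, state$n_features, 1L))
  pr <- predict_model(state$har, x)
  act <- classify(pr$action)
  out <- data.frame(time_s = (state$t - 1L) / fs, action = act,
                    interaction = NA_character_, payload = NA_real_,
                    stringsAsFactors = FALSE)
  for (cl in ACTIONS) out[[paste0("p_action_", cl)]] <- pr$action[1, cl]
  for (cl in INTERACTIONS) out[[paste0("p_interaction_", cl)]] <- NA_real_
  for (cl in PAYLOADS) out[[paste0("p_payload_", cl)]] <- NA_real_
  if (act == "INTERACT") {
    out$interaction <- classify(pr$interaction)
    for (cl in INTERACTIONS)
      out[[paste0("p_interaction_", cl)]] <- pr$interaction[1, cl]
    # payload model scales the same filtered window with its own scaler
    pwin <- apply_scaler(state$payload$scaler, win)
    pp <- predict_model(state$payload,
                        array(pwin, dim = c(state$W, state$n_features, 1L)))
    out$payload <- as.numeric(classify(pp$payload))
    for (cl in PAYLOADS) out[[paste0("p_payload_", cl)]] <- pp$payload[1, as.character(cl)]
  }
  class(out) <- c("exohar_gated", "data.frame")
  list(state = state, prediction = out)
}

#' Replay a recording through the streaming cascade
#'
#' Deterministic offline simulation of the 100-Hz loop: every sample of the
#' recording is passed through [stream_step()]. The summary reports per-head
#' agreement with the ground-truth tracks (on samples where a prediction was
#' emitted and, for interaction/payload, where the truth is defined) and
#' per-step wall-clock latency quantiles, which are informational only.
#'
#' @param recording An `exohar_recording` matching the models' sensor
#'   configuration.
#' @param har_model,payload_model Trained models.
#' @param fspec Causal [filter_spec()].
#' @return A list: `predictions` (data.frame, one row per emitted step),
#'   `summary` (agreement rates and latency stats).
#' @export
replay <- function(recording, har_model, payload_model,
                   fspec = filter_spec(mode = "CAUSAL")) {
  rec <- recording
  ch <- reduce_sensors(rec$channels, har_model$sensor_config)
  state <- stream_state(har_model, payload_model, fspec)
  n <- nrow(ch)
  preds <- vector("list", n)
  lat <- numeric(n)
  for (i in seq_len(n)) {
    t0 <- proc.time()[["elapsed"]]
    st <- stream_step(state, ch[i, ])
    lat[i] <- proc.time()[["elapsed"]] - t0
    state <- st$state
    if (!is.null(st$prediction)) preds[[i]] <- cbind(st$prediction, sample = i)
  }
  preds <- do.call(rbind, preds)
  emitted <- preds$sample
  agree_action <- mean(preds$action == rec$action[emitted])
  gt_int <- rec$action[emitted] == "INTERACT" & preds$action == "INTERACT"
  agree_interaction <- if (any(gt_int))
    mean(preds$interaction[gt_int] == rec$interaction[emitted][gt_int]) else NA_real_
  agree_payload <- if (any(gt_int))
    mean(preds$payload[gt_int] == rec$payload[emitted][gt_int]) else NA_real_
  list(predictions = preds,
       summary = list(
         n_samples = n, n_emitted = nrow(preds),
         agreement_action = agree_action,
         agreement_interaction = agree_interaction,
         agreement_payload = agree_payload,
         latency_ms = unname(quantile(lat * 1000, c(0.5, 0.95)))))
}

#' Batch equivalent of the streaming cascade
#'
#' Causally filters and scales the whole recording at once, cuts stride-1
#' windows, runs the HAR model on all of them and the payload model on the
#' windows the HAR model gates as `INTERACT`. Produces the same label
#' sequence as [replay()]; used as its oracle and for fast evaluation.
#'
#' @inheritParams replay
#' @return A data.frame with one row per window (same columns as `replay()`'s
#'   predictions).
#' @export
batch_cascade <- function(recording, har_model, payload_model,
                          fspec = filter_spec(mode = "CAUSAL")) {
  ch <- reduce_sensors(recording$channels, har_model$sensor_config)
  filt <- filter_causal(ch, fspec, x0 = ch[1, ])
  W <- har_model$config$window$length
  wins_h <- windowize(apply_scaler(har_model$scaler, filt), window_spec(W, 1))
  pr <- predict_model(har_model, wins_h$x)
  act <- classify(pr$action)
  n <- length(act)
  out <- data.frame(time_s = (wins_h$last - 1) / fspec$fs, action = act,
                    interaction = NA_character_, payload = NA_real_,
                    stringsAsFactors = FALSE)
  for (cl in ACTIONS) out[[paste0("p_action_", cl)]] <- pr$action[, cl]
  for (cl in INTERACTIONS) out[[paste0("p_interaction_", cl)]] <- NA_real_
  for (cl in PAYLOADS) out[[paste0("p_payload_", cl)]] <- NA_real_
  gate <- which(act == "INTERACT")
  if (length(gate)) {
    out$interaction[gate] <- classify(pr$interaction[gate, , drop = FALSE])
    for (cl in INTERACTIONS)
      out[[paste0("p_interaction_", cl)]][gate] <- pr$interaction[gate, cl]
    wins_p <- windowize(apply_scaler(payload_model$scaler, filt), window_spec(W, 1))
    pp <- predict_model(payload_model, wins_p$x[, , gate, drop = FALSE])
    out$payload[gate] <- as.numeric(classify(pp$payload))
    for (cl in PAYLOADS)
      out[[paste0("p_payload_", cl)]][gate] <- pp$payload[, as.character(cl)]
  }
  out$sample <- wins_h$last
  out
}
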