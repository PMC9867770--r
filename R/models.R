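# Multi-output LSTM classifiers: a HAR network with a 3-class action head and
# a 2-class interaction head on a shared trunk, and a payload network with a
# single 3-class head. Trunk: two LSTM layers and one tanh dense layer; heads
# are softmax. Trained per subject with Adam on masked categorical
# cross-entropy, early-stopped on validation support-weighted F1.

#' Model configuration
#'
#' Defaults follow the reference architecture: recurrent layers of 100 and 50
#' units, a 20-unit dense layer, heads of 3 (action) + 2 (interaction) for
#' HAR and 3 (payload classes) for payload estimation. Optimizer: Adam,
#' learning rate 1e-3, batch 64, at most 50 epochs, early stopping patience 5
#' on validation weighted F1, validation = 10% of training windows.
#'
#' @param recurrent_units Integer vector of length 2.
#' @param dense_units Dense layer width.
#' @param window A [window_spec()] used to build training windows.
#' @param learning_rate,batch_size,max_epochs,patience Optimizer settings.
#' @param validation_fraction Fraction of training windows held out for early
#'   stopping.
#' @param clip Global gradient-norm clip.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return A list of class `exohar_model_config`.
#' @export
model_config <- function(recurrent_units = c(100, 50), dense_units = 20,
                         window = window_spec(100, 1),
                         learning_rate = 1e-3, batch_size = 64,
                         max_epochs = 50, patience = 5,
                         validation_fraction = 0.1, clip = 5, seed = 0L) {
  stopifnot(length(recurrent_units) == 2, all(recurrent_units >= 1),
            dense_units >= 1)
  structure(list(recurrent_units = as.integer(recurrent_units),
                 dense_units = as.integer(dense_units), window = window,
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 validation_fraction = validation_fraction, clip = clip,
                 seed = as.integer(seed)),
            class = "exohar_model_config")
}

#' Build an untrained model
#'
#' `build_har_model()` defines the multi-output HAR network (action head with
#' 3 units, interaction head with 2); `build_payload_model()` the payload
#' network (single 3-unit head over 5/10/15 kg). `n_features` must match a
#' sensor configuration (30, 18 or 6).
#'
#' @param config An `exohar_model_config`.
#' @param n_features Input feature width.
#' @return A list of class `exohar_model` (untrained: `weights = NULL`).
#' @export
build_har_model <- function(config = model_config(), n_features = 30) {
  new_model("HAR", heads = list(action = length(ACTIONS),
                                interaction = length(INTERACTIONS)),
            config, n_features)
}

#' @rdname build_har_model
#' @export
build_payload_model <- function(config = model_config(), n_features = 30) {
  new_model("PAYLOAD", heads = list(payload = length(PAYLOADS)),
            config, n_features)
}

new_model <- function(kind, heads, config, n_features) {
  if (!n_features %in% c(30L, 18L, 6L))
    stop("n_features must be 30, 18 or 6 (a sensor configuration width)")
  sensor_config <- c(`30` = "FULL_5", `18` = "REDUCED_3", `6` = "CHEST_1")[
    as.character(n_features)]
  structure(list(kind = kind, heads = heads, config = config,
                 n_features = as.integer(n_features),
                 sensor_config = unname(sensor_config),
                 weights = NULL, scaler = NULL, history = NULL),
            class = "exohar_model")
}

#' @export
print.exohar_model <- function(x, ...) {
  cat(sprintf("<exohar_model> %s, %s (%d features), heads: %s, %s\n",
              x$kind, x$sensor_config, x$n_features,
              paste(sprintf("%s=%d", names(x$heads), unlist(x$heads)),
                    collapse = " "),
              if (is.null(x$weights)) "untrained" else
                sprintf("trained (best epoch %d, val F1 %.3f)",
                        x$best_epoch, x$best_val_f1)))
  invisible(x)
}

# Encode label vectors to per-head integer targets (0 = masked out of the
# head's loss). The interaction head is masked on non-INTERACT windows.
encode_targets <- function(model, action = NULL, interaction = NULL,
                           payload = NULL) {
  n <- max(length(action), length(interaction), length(payload))
  Y <- matrix(0L, n, length(model$heads))
  colnames(Y) <- names(model$heads)
  for (h in names(model$heads)) {
    Y[, h] <- switch(h,
      action = match(action, ACTIONS),
      interaction = match(interaction, INTERACTIONS),
      payload = match(payload, PAYLOADS))
  }
  Y[is.na(Y)] <- 0L
  Y
}

#' Train a model on labeled windows
#'
#' Windows must already be scaled with a scaler fit on the training data only
#' (attach it as `scaler` so provenance travels with the model). Optimizes
#' masked categorical cross-entropy summed over heads; keeps the epoch with
#' the best validation weighted F1. Reproducible for a fixed seed.
#'
#' @param model An untrained `exohar_model`.
#' @param x Window array `W x F x N` (from [windowize()]).
#' @param action,interaction,payload Per-window label vectors as required by
#'   the model's heads.
#' @param scaler The `exohar_scaler` the windows were scaled with.
#' @param valid Optional list with elements `x`, `action`/`interaction`/
#'   `payload` used for early stopping; when absent, a fraction of the
#'   training windows (`validation_fraction`) is held out.
#' @return The trained `exohar_model` (weights, history, best epoch).
#' @export
train_model <- function(model, x, action = NULL, interaction = NULL,
                        payload = NULL, scaler = NULL, valid = NULL) {
  stopifnot(inherits(model, "exohar_model"))
  if (dim(x)[2] != model$n_features)
    stop("window feature width does not match the model configuration")
  Y <- encode_targets(model, action, interaction, payload)
  if (dim(x)[3] == 0 || nrow(Y) == 0) stop("empty training set")
  for (h in seq_along(model$heads)) {
    present <- sort(unique(Y[Y[, h] > 0, h]))
    if (!length(present))
      stop("head '", names(model$heads)[h], "' has no labeled training windows")
    if (names(model$heads)[h] != "interaction" &&
        length(present) < model$heads[[h]])
      stop("class entirely absent from training labels for head '",
           names(model$heads)[h], "'")
  }
  cfg <- model$config
  if (is.null(valid)) {
    n <- dim(x)[3]
    nv <- max(1L, floor(n * cfg$validation_fraction))
    vi <- withr::with_seed(cfg$seed, sample(n, nv))
    valid <- list(x = x[, , vi, drop = FALSE], Y = Y[vi, , drop = FALSE])
    x <- x[, , -vi, drop = FALSE]
    Y <- Y[-vi, , drop = FALSE]
  } else {
    valid$Y <- encode_targets(model, valid$action, valid$interaction,
                              valid$payload)
  }
  fit <- cpp_lstm_train(x, Y, valid$x, valid$Y,
                        head_sizes = unlist(model$heads),
                        units1 = cfg$recurrent_units[1],
                        units2 = cfg$recurrent_units[2],
                        dense_units = cfg$dense_units,
                        lr = cfg$learning_rate, batch_size = cfg$batch_size,
                        max_epochs = cfg$max_epochs, patience = cfg$patience,
                        clip = cfg$clip, seed = cfg$seed)
  model$weights <- fit$weights
  model$history <- fit$history
  model$best_epoch <- fit$best_epoch
  model$best_val_f1 <- fit$best_val_f1
  model$scaler <- scaler
  model
}

#' Predict class probabilities for windows
#'
#' @param model A trained `exohar_model`.
#' @param x Window array `W x F x N`.
#' @return Named list (one per head) of `N x C` probability matrices, columns
#'   named by class.
#' @export
predict_model <- function(model, x) {
  if (is.null(model$weights)) stop("model is untrained")
  if (dim(x)[2] != model$n_features)
    stop("window feature width does not match the model configuration")
  probs <- cpp_lstm_predict(model$weights, x)
  names(probs) <- names(model$heads)
  for (h in names(probs)) {
    colnames(probs[[h]]) <- switch(h, action = ACTIONS,
                                   interaction = INTERACTIONS,
                                   payload = as.character(PAYLOADS))
  }
  probs
}

#' Hard class labels from head probabilities
#'
#' Argmax with lowest-index preference on exact ties.
#'
#' @param probs A probability matrix from [predict_model()].
#' @return Character vector of class labels.
#' @export
classify <- function(probs) {
  colnames(probs)[max.col(probs, ties.method = "first")]
}

# ---- subject suite -----------------------------------------------------------

#' Preprocess one recording slice into scaled windows
#'
#' Zero-lag filters the slice's channels, reduces to the target sensor
#' configuration, applies the supplied scaler and cuts windows.
#' @noRd
slice_windows <- function(slice, sensor_config, scaler, fspec, wspec) {
  rec <- slice$rec
  rows <- slice$rows
  ch <- reduce_sensors(rec$channels[rows, , drop = FALSE], sensor_config)
  ch <- filter_offline(ch, fspec)
  ch <- apply_scaler(scaler, ch)
  windowize(ch, wspec, action = rec$action[rows],
            interaction = rec$interaction[rows], payload = rec$payload[rows])
}

# Concatenate windowize outputs.
bind_windows <- function(parts) {
  parts <- Filter(function(p) dim(p$x)[3] > 0, parts)
  x <- array(unlist(lapply(parts, `[[`, "x")),
             dim = c(dim(parts[[1]]$x)[1:2], sum(sapply(parts, function(p) dim(p$x)[3]))))
  out <- list(x = x)
  for (f in c("action", "interaction", "payload", "last"))
    if (!is.null(parts[[1]][[f]]))
      out[[f]] <- unlist(lapply(parts, `[[`, f), use.names = FALSE)
  out
}

# Raw (filtered, reduced, unscaled) channels of a list of slices, stacked --
# used to fit scalers on training data only.
stack_training_channels <- function(slices, sensor_config, fspec) {
  do.call(rbind, lapply(slices, function(s) {
    ch <- reduce_sensors(s$rec$channels[s$rows, , drop = FALSE], sensor_config)
    filter_offline(ch, fspec)
  }))
}

#' Train the HAR and payload models of one subject
#'
#' For each requested sensor configuration, builds the Table-1 splits
#' (HAR: train D2 / test D3; payload: train 90% D1 + 50% D3), fits a min-max
#' scaler per model on its training data only, and trains both networks.
#'
#' @param bundle An `exohar_bundle`.
#' @param configs Character vector of sensor configurations.
#' @param model_cfg An `exohar_model_config`.
#' @param fspec Zero-lag [filter_spec()] used offline.
#' @param train_stride Stride (samples) used to thin training windows;
#'   evaluation windows keep the spec's stride.
#' @param split_seed Seed for the repetition-wise splits.
#' @return Nested list: `result[[config]]$har`, `result[[config]]$payload`
#'   (trained models) and `result[[config]]$splits`.
#' @export
train_subject_suite <- function(bundle, configs = "FULL_5",
                                model_cfg = model_config(),
                                fspec = filter_spec(),
                                train_stride = 4, split_seed = 0L) {
  stopifnot(inherits(bundle, "exohar_bundle"))
  wtrain <- window_spec(model_cfg$window$length, train_stride)
  out <- list()
  for (cfg in configs) {
    splits <- list(HAR = make_splits(bundle, "HAR", seed = split_seed),
                   PAYLOAD = make_splits(bundle, "PAYLOAD", seed = split_seed))
    models <- list()
    for (kind in c("HAR", "PAYLOAD")) {
      tr <- splits[[kind]]$train
      # HAR trains on all of D2, delivered as one slice: cut it into
      # repetitions so validation can hold out whole repetitions
      if (kind == "HAR") tr <- rep_slices(tr)
      scaler <- fit_scaler(stack_training_channels(tr, cfg, fspec))
      held <- hold_out_slices(tr, model_cfg$validation_fraction,
                              seed = split_seed)
      mk_wins <- function(slices, kind) {
        wins <- bind_windows(lapply(slices, slice_windows, sensor_config = cfg,
                                    scaler = scaler, fspec = fspec,
                                    wspec = wtrain))
        if (kind == "PAYLOAD") {
          keep <- wins$action == "INTERACT"
          wins$x <- wins$x[, , keep, drop = FALSE]
          wins$action <- wins$action[keep]
          wins$interaction <- wins$interaction[keep]
          wins$payload <- wins$payload[keep]
        }
        wins
      }
      wins <- mk_wins(held$train, kind)
      valid <- mk_wins(held$valid, kind)
      model <- if (kind == "HAR")
        build_har_model(model_cfg, config_n_features(cfg))
      else build_payload_model(model_cfg, config_n_features(cfg))
      models[[tolower(kind)]] <- train_model(
        model, wins$x, action = wins$action, interaction = wins$interaction,
        payload = wins$payload, scaler = scaler, valid = valid)
    }
    out[[cfg]] <- list(har = models$har, payload = models$payload,
                       splits = splits)
  }
  out
}

# Explode whole-recording slices into one slice per repetition.
rep_slices <- function(slices) {
  do.call(c, lapply(slices, function(s) {
    rt <- repetition_track(s$rec)[s$rows]
    lapply(unique(rt), function(r) list(rec = s$rec, rows = s$rows[rt == r]))
  }))
}

# Hold out ~`fraction` of the slices (at least one; stratified by the
# slice's payload when defined) as a validation set for early stopping.
hold_out_slices <- function(slices, fraction, seed) {
  pl <- vapply(slices, function(s) {
    p <- unique(s$rec$payload[s$rows])
    p <- p[!is.na(p)]
    if (length(p)) p[1] else NA_real_
  }, numeric(1))
  withr::with_seed(seed, {
    vi <- integer(0)
    for (g in unique(pl)) {
      grp <- which(if (is.na(g)) is.na(pl) else !is.na(pl) & pl == g)
      k <- max(1L, round(length(grp) * fraction))
      vi <- c(vi, if (length(grp) == 1) grp else sample(grp, k))
    }
    list(train = slices[-vi], valid = slices[vi])
  })
}

# ---- model serialization -----------------------------------------------------

#' Save / load a trained model as structured text
#'
#' Weights are serialized as full-precision JSON together with a manifest
#' (kind, sensor configuration, heads, training seed, best epoch) and the
#' attached scaler, so the streaming pipeline reproduces offline predictions
#' exactly.
#'
#' @param model A trained `exohar_model`.
#' @param path File path (JSON).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "exohar_model"))
  obj <- list(
    kind = model$kind, heads = model$heads, n_features = model$n_features,
    sensor_config = model$sensor_config,
    config = unclass(model$config[c("recurrent_units", "dense_units",
                                    "learning_rate", "batch_size",
                                    "max_epochs", "patience", "clip", "seed")]),
    window = unclass(model$config$window),
    best_epoch = model$best_epoch, best_val_f1 = model$best_val_f1,
    weights = lapply(model$weights, function(w)
      list(nrow = nrow(w), ncol = ncol(w), data = as.numeric(w))),
    scaler = if (!is.null(model$scaler))
      list(min = model$scaler$min, max = model$scaler$max,
           features = model$scaler$features))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- model_config(recurrent_units = x$config$recurrent_units,
                      dense_units = x$config$dense_units,
                      window = window_spec(x$window$length, x$window$stride),
                      learning_rate = x$config$learning_rate,
                      batch_size = x$config$batch_size,
                      max_epochs = x$config$max_epochs,
                      patience = x$config$patience,
                      clip = x$config$clip, seed = x$config$seed)
  model <- new_model(x$kind, as.list(x$heads), cfg, x$n_features)
  model$weights <- lapply(x$weights, function(w)
    matrix(as.numeric(w$data), w$nrow, w$ncol))
  model$best_epoch <- x$best_epoch
  model$best_val_f1 <- x$best_val_f1
  if (!is.null(x$scaler))
    model$scaler <- structure(
      list(min = setNames(as.numeric(x$scaler$min), x$scaler$features),
           max = setNames(as.numeric(x$scaler$max), x$scaler$features),
           features = x$scaler$features),
      class = "exohar_scaler")
  model
}
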