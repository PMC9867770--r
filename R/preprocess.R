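# Signal conditioning: Butterworth low-pass (zero-lag offline, causal online),
# min-max amplitude scaling fit on training data only, sensor reduction, and
# sliding-window assembly for the sequence classifiers.

#' Butterworth low-pass filter specification
#'
#' The default matches the preprocessing used throughout the pipeline: 5 Hz
#' cutoff, 4th order, 100 Hz sampling. `ZERO_LAG` applies the design
#' forward-backward (zero phase, effectively squared magnitude response) and
#' is offline-only; `CAUSAL` is the single forward pass used in streaming.
#'
#' @param cutoff Cutoff frequency, Hz (0 < cutoff < fs/2).
#' @param order Filter order (even, positive); the per-pass design order.
#' @param fs Sampling rate, Hz.
#' @param mode `"ZERO_LAG"` or `"CAUSAL"`.
#' @return A list of class `exohar_filter` including the designed
#'   coefficients `b`, `a` (from [signal::butter()]).
#' @export
filter_spec <- function(cutoff = 5, order = 4, fs = 100,
                        mode = c("ZERO_LAG", "CAUSAL")) {
  mode <- match.arg(mode)
  if (!(cutoff > 0 && cutoff < fs / 2)) stop("cutoff must lie in (0, fs/2)")
  if (order <= 0 || order %% 2 != 0) stop("order must be even and positive")
  bf <- signal::butter(order, 2 * cutoff / fs, type = "low")
  structure(list(cutoff = cutoff, order = order, fs = fs, mode = mode,
                 b = as.numeric(bf$b), a = as.numeric(bf$a)),
            class = "exohar_filter")
}

# Steady-state state vector of the direct-form-II-transposed filter for a
# unit-amplitude constant input (so a constant signal passes with no
# transient). Solves (I - A^T) zi = B for the companion-form state update.
iir_steady_state <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  if (n == 1) return(numeric(0))
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1] / a[1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(diag(n - 1) - t(comp), B))
}

#' Zero-lag offline filtering
#'
#' Forward-backward application of the Butterworth design with odd-reflection
#' padding of length `3 * order` at both ends and steady-state initial
#' conditions, giving zero phase shift and exact unit DC gain.
#'
#' @param channels Numeric matrix (samples x channels) or vector.
#' @param spec An `exohar_filter` with `mode = "ZERO_LAG"`.
#' @return Filtered matrix of the same shape.
#' @export
filter_offline <- function(channels, spec = filter_spec()) {
  stopifnot(inherits(spec, "exohar_filter"))
  if (spec$mode != "ZERO_LAG") stop("filter_offline requires mode ZERO_LAG")
  vec_in <- is.null(dim(channels))
  x <- as.matrix(channels)
  pad <- 3L * spec$order
  if (nrow(x) <= pad) stop("sequence too short for edge padding")
  zi <- iir_steady_state(spec$b, spec$a)
  ext <- rbind(2 * matrix(x[1, ], pad, ncol(x), byrow = TRUE) - x[(pad + 1):2, , drop = FALSE],
               x,
               2 * matrix(x[nrow(x), ], pad, ncol(x), byrow = TRUE) -
                 x[(nrow(x) - 1):(nrow(x) - pad), , drop = FALSE])
  z0 <- outer(zi, ext[1, ])
  fwd <- cpp_iir_filter(spec$b, spec$a, ext, z0)$y
  rev1 <- fwd[nrow(fwd):1, , drop = FALSE]
  z0b <- outer(zi, rev1[1, ])
  bwd <- cpp_iir_filter(spec$b, spec$a, rev1, z0b)$y
  y <- bwd[nrow(bwd):1, , drop = FALSE][(pad + 1):(pad + nrow(x)), , drop = FALSE]
  colnames(y) <- colnames(x)
  if (vec_in) as.numeric(y) else y
}

#' Batch causal (single-pass) filtering
#'
#' One forward pass from zero initial state; identical, sample for sample, to
#' feeding the stream through [filter_online_step()].
#'
#' @inheritParams filter_offline
#' @param spec An `exohar_filter` (mode `CAUSAL`).
#' @param x0 Optional numeric vector (one value per channel): start the
#'   filter at the steady state for this input level instead of zero state,
#'   suppressing the artificial step transient at stream start. The gated
#'   streaming cascade warm-starts on the first sample.
#' @return Filtered matrix of the same shape.
#' @export
filter_causal <- function(channels, spec = filter_spec(mode = "CAUSAL"),
                          x0 = NULL) {
  vec_in <- is.null(dim(channels))
  x <- as.matrix(channels)
  ns <- max(length(spec$a), length(spec$b)) - 1L
  z0 <- if (is.null(x0)) matrix(0, ns, ncol(x))
        else outer(iir_steady_state(spec$b, spec$a), as.numeric(x0))
  y <- cpp_iir_filter(spec$b, spec$a, x, z0)$y
  colnames(y) <- colnames(x)
  if (vec_in) as.numeric(y) else y
}

#' Streaming causal filter: state initialization and one-sample step
#'
#' `filter_state()` creates the zeroed per-channel filter state;
#' `filter_online_step()` advances it by one multichannel sample and returns
#' the filtered sample. Uses the same C++ kernel as [filter_causal()], so a
#' sample-by-sample replay is bit-identical to batch causal filtering.
#'
#' @param spec An `exohar_filter`.
#' @param n_channels Number of channels in the stream.
#' @param x0 Optional per-channel input level for a steady-state warm start
#'   (see [filter_causal()]); default is zero state.
#' @return `filter_state()`: a list with the spec and state matrix.
#' @export
filter_state <- function(spec, n_channels, x0 = NULL) {
  ns <- max(length(spec$a), length(spec$b)) - 1L
  z <- if (is.null(x0)) matrix(0, ns, n_channels)
       else outer(iir_steady_state(spec$b, spec$a), as.numeric(x0))
  list(spec = spec, z = z)
}

#' @rdname filter_state
#' @param state A state list from `filter_state()`.
#' @param sample Numeric vector of length `n_channels`.
#' @return `filter_online_step()`: list `(state, y)` with the updated state
#'   and the filtered sample.
#' @export
filter_online_step <- function(state, sample) {
  if (length(sample) != ncol(state$z)) stop("sample dimensionality mismatch")
  res <- cpp_iir_filter(state$spec$b, state$spec$a,
                        matrix(sample, nrow = 1), state$z)
  state$z <- res$zf
  list(state = state, y = as.numeric(res$y))
}

# ---- min-max scaler ----------------------------------------------------------

#' Fit a min-max scaler on training data only
#'
#' Stores per-feature minima and maxima of the training matrix. The scaling
#' map is `x -> 2 * (x - min) / (max - min) - 1`, sending the training range
#' to `[-1, +1]`. Constant (degenerate) features are rejected.
#'
#' @param train Numeric matrix (samples x features), column-named.
#' @return A list of class `exohar_scaler` with `min`, `max`, `features`.
#' @export
fit_scaler <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop("need at least two samples to fit the scaler")
  mn <- apply(train, 2, min)
  mx <- apply(train, 2, max)
  if (any(mx <= mn)) stop("constant feature: ",
                          paste(colnames(train)[mx <= mn], collapse = ", "))
  structure(list(min = mn, max = mx, features = colnames(train)),
            class = "exohar_scaler")
}

#' Apply (or invert) a fitted scaler
#'
#' Linear map with no clipping: out-of-range test values extrapolate beyond
#' `[-1, 1]`. `invert_scaler()` is the exact inverse.
#'
#' @param params An `exohar_scaler`.
#' @param channels Matrix or vector with features matching the fit.
#' @return Scaled matrix of the same shape.
#' @export
apply_scaler <- function(params, channels) {
  stopifnot(inherits(params, "exohar_scaler"))
  vec_in <- is.null(dim(channels))
  x <- if (vec_in) matrix(channels, nrow = 1) else as.matrix(channels)
  if (ncol(x) != length(params$min)) stop("feature dimension mismatch")
  if (!is.null(colnames(x)) && !is.null(params$features) &&
      !identical(colnames(x), params$features))
    stop("feature order does not match the fitted scaler")
  y <- sweep(x, 2, params$min)
  y <- sweep(y, 2, (params$max - params$min) / 2, "/") - 1
  colnames(y) <- colnames(x)
  if (vec_in) as.numeric(y) else y
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(params, channels) {
  stopifnot(inherits(params, "exohar_scaler"))
  vec_in <- is.null(dim(channels))
  y <- if (vec_in) matrix(channels, nrow = 1) else as.matrix(channels)
  x <- sweep((y + 1) / 2, 2, params$max - params$min, "*")
  x <- sweep(x, 2, params$min, "+")
  colnames(x) <- colnames(y)
  if (vec_in) as.numeric(x) else x
}

#' Serialize / restore scaler and filter parameters
#'
#' Written as plain JSON so the streaming pipeline reuses offline-fit
#' parameters bit-exactly (doubles serialized at full precision).
#'
#' @param params An `exohar_scaler`.
#' @param path File path.
#' @export
write_scaler <- function(params, path) {
  jsonlite::write_json(list(min = params$min, max = params$max,
                            features = params$features),
                       path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(min = setNames(as.numeric(x$min), x$features),
                 max = setNames(as.numeric(x$max), x$features),
                 features = x$features),
            class = "exohar_scaler")
}

# ---- sensor reduction --------------------------------------------------------

#' Reduce a channel matrix to a smaller sensor configuration
#'
#' Keeps the columns of the target configuration in their canonical order:
#' `REDUCED_3` = chest + both thighs (18 features), `CHEST_1` = chest only
#' (6 features). Reducing to the matrix's own configuration is the identity;
#' the operation is idempotent.
#'
#' @param channels Column-named channel matrix (full or already reduced, as
#'   long as the target's columns are present).
#' @param config Target configuration tag.
#' @return The reduced matrix.
#' @export
reduce_sensors <- function(channels, config) {
  config <- match.arg(config, names(SENSOR_CONFIGS))
  want <- config_channels(config)
  missing <- setdiff(want, colnames(channels))
  if (length(missing))
    stop("input lacks channels required for ", config, ": ",
         paste(missing, collapse = ", "))
  channels[, want, drop = FALSE]
}

#' Reduce a whole recording to a sensor configuration
#'
#' @param rec An `exohar_recording`.
#' @param config Target configuration tag.
#' @return A new `exohar_recording` with the reduced channel set.
#' @export
reduce_recording <- function(rec, config) {
  labeled_recording(rec$subject_id, rec$protocol_id, rec$fs,
                    reduce_sensors(rec$channels, config),
                    rec$action, rec$interaction, rec$payload)
}

# ---- windowing ---------------------------------------------------------------

#' Sliding-window specification
#'
#' Windows of `length` samples at the given `stride`; each window is labeled
#' by its **last** sample (causal labeling: the window ending at time t is
#' paired with the activity at t, so a classifier can flag an action as soon
#' as it starts).
#'
#' @param length Window length in samples (default 100 = 1 s at 100 Hz).
#' @param stride Stride in samples (1 for per-sample evaluation; larger
#'   strides thin the training set).
#' @return A list of class `exohar_window`.
#' @export
window_spec <- function(length = 100, stride = 1) {
  stopifnot(length >= 1, stride >= 1)
  structure(list(length = as.integer(length), stride = as.integer(stride)),
            class = "exohar_window")
}

#' Cut a feature matrix into labeled windows
#'
#' @param matrix Numeric feature matrix (T x F), already filtered and scaled.
#' @param spec An `exohar_window`.
#' @param action,interaction,payload Optional label tracks of length T; each
#'   window receives its last sample's labels.
#' @return A list: `x` an array `W x F x N`; `last` the source row index of
#'   each window's final sample; plus `action`/`interaction`/`payload`
#'   vectors of length N when tracks were supplied.
#' @export
windowize <- function(matrix, spec = window_spec(), action = NULL,
                      interaction = NULL, payload = NULL) {
  m <- as.matrix(matrix)
  W <- spec$length
  if (nrow(m) < W) stop("sequence shorter than the window length")
  last <- seq(W, nrow(m), by = spec$stride)
  starts <- last - W + 1L
  idx <- as.vector(outer(0:(W - 1L), starts, "+"))
  arr <- aperm(array(m[idx, , drop = FALSE],
                     dim = c(W, length(starts), ncol(m))), c(1, 3, 2))
  out <- list(x = arr, last = last)
  if (!is.null(action)) out$action <- action[last]
  if (!is.null(interaction)) out$interaction <- interaction[last]
  if (!is.null(payload)) out$payload <- payload[last]
  out
}
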