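#' @useDynLib exohar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile runif rnorm sd setNames
#' @importFrom utils head tail
NULL

# ---- label vocabularies ------------------------------------------------------

#' Sensor placements, label vocabularies and sensor configurations
#'
#' The five inertial measurement units are worn on the chest (sternum), both
#' wrists and both thighs. Their fixed order defines the column order of every
#' channel matrix: for each placement, six channels
#' `ax, ay, az` (linear acceleration, m/s^2) and `gx, gy, gz` (angular
#' velocity, deg/s), giving 30 features for the full configuration.
#'
#' Actions are `STAND`, `WALK`, `INTERACT`; interactions (defined only while
#' the action is `INTERACT`) are `LIFT`, `LOWER`; payload classes are the
#' nominal box weights 5, 10 and 15 kg.
#'
#' @format Character (or numeric, for payloads) vectors of constants.
#' @name vocabulary
NULL

#' @rdname vocabulary
#' @export
PLACEMENTS <- c("chest", "left_wrist", "right_wrist", "left_thigh", "right_thigh")

#' @rdname vocabulary
#' @export
ACTIONS <- c("STAND", "WALK", "INTERACT")

#' @rdname vocabulary
#' @export
INTERACTIONS <- c("LIFT", "LOWER")

#' @rdname vocabulary
#' @export
PAYLOADS <- c(5, 10, 15)

AXES <- c("ax", "ay", "az", "gx", "gy", "gz")

#' @rdname vocabulary
#' @export
channel_names <- function(placements = PLACEMENTS) {
  as.vector(t(outer(placements, AXES, paste, sep = "_")))
}

# Sensor configurations: which placements each keeps.
SENSOR_CONFIGS <- list(
  FULL_5    = PLACEMENTS,
  REDUCED_3 = c("chest", "left_thigh", "right_thigh"),
  CHEST_1   = "chest"
)

#' Feature count and channel names of a sensor configuration
#'
#' `FULL_5` keeps all five IMUs (30 features), `REDUCED_3` drops the wrists
#' (18 features, a 40% reduction), `CHEST_1` keeps the sternum unit only
#' (6 features, an 80% reduction).
#'
#' @param config One of `"FULL_5"`, `"REDUCED_3"`, `"CHEST_1"`.
#' @return `config_channels()`: character vector of channel names;
#'   `config_n_features()`: integer feature count.
#' @export
config_channels <- function(config) {
  config <- match.arg(config, names(SENSOR_CONFIGS))
  channel_names(SENSOR_CONFIGS[[config]])
}

#' @rdname config_channels
#' @export
config_n_features <- function(config) length(config_channels(config))

# ---- LabeledRecording --------------------------------------------------------

#' Construct a labeled multi-IMU recording
#'
#' A recording is one continuous subject-session: a `T x F` channel matrix
#' (columns named per [channel_names()]), a sampling rate, and three per-sample
#' label tracks. The interaction and payload tracks are `NA` exactly where the
#' action is not `INTERACT`.
#'
#' @param subject_id Character scalar.
#' @param protocol_id 1 (lift/lower cycles) or 2 (stand/walk/manipulation).
#' @param fs Sampling rate in Hz.
#' @param channels Numeric matrix, `T` rows, columns named channels.
#' @param action Character vector of length `T`, values in [ACTIONS].
#' @param interaction Character vector of length `T`, `NA` outside INTERACT.
#' @param payload Numeric vector of length `T` (kg), `NA` outside INTERACT.
#' @return An object of class `exohar_recording`.
#' @export
labeled_recording <- function(subject_id, protocol_id, fs, channels,
                              action, interaction, payload) {
  rec <- structure(
    list(subject_id = as.character(subject_id),
         protocol_id = as.integer(protocol_id),
         fs = as.numeric(fs),
         channels = channels,
         action = as.character(action),
         interaction = as.character(interaction),
         payload = as.numeric(payload)),
    class = "exohar_recording")
  validate_recording(rec)
  rec
}

#' Validate a labeled recording's invariants
#'
#' Checks track lengths, label vocabularies, the iff-coupling between
#' `INTERACT` and the interaction/payload tracks, and the channel column set
#' (which must match one of the three sensor configurations). The matched
#' configuration is stored as `rec$config`.
#'
#' @param rec An `exohar_recording`.
#' @return The recording, invisibly, with `config` filled in.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "exohar_recording"))
  n <- nrow(rec$channels)
  if (length(rec$action) != n || length(rec$interaction) != n ||
      length(rec$payload) != n)
    stop("label tracks and channel matrix must have equal length")
  if (!rec$protocol_id %in% c(1L, 2L)) stop("protocol_id must be 1 or 2")
  if (!is.finite(rec$fs) || rec$fs <= 0) stop("fs must be positive")
  if (anyNA(rec$action) || !all(rec$action %in% ACTIONS))
    stop("unknown action label")
  ii <- rec$action == "INTERACT"
  if (anyNA(rec$interaction[ii]) || anyNA(rec$payload[ii]))
    stop("interaction/payload must be present on INTERACT samples")
  if (any(!is.na(rec$interaction[!ii])) || any(!is.na(rec$payload[!ii])))
    stop("interaction/payload label outside INTERACT span")
  if (!all(rec$interaction[ii] %in% INTERACTIONS))
    stop("unknown interaction label")
  if (!all(rec$payload[ii] %in% PAYLOADS))
    stop("unknown payload class")
  cfg <- NULL
  for (nm in names(SENSOR_CONFIGS))
    if (identical(colnames(rec$channels), config_channels(nm))) cfg <- nm
  if (is.null(cfg))
    stop("channel columns match no known sensor configuration")
  rec$config <- cfg
  invisible(rec)
}

#' @export
print.exohar_recording <- function(x, ...) {
  cat(sprintf(
    "<exohar_recording> subject %s, protocol %d, %.0f Hz, %d samples x %d channels (%s)\n",
    x$subject_id, x$protocol_id, x$fs, nrow(x$channels), ncol(x$channels),
    validate_recording(x)$config))
  tab <- table(factor(x$action, ACTIONS))
  cat("  actions:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' @export
length.exohar_recording <- function(x) nrow(x$channels)

# ---- CSV dialect -------------------------------------------------------------

#' Write a recording to CSV
#'
#' Dialect: UTF-8, '.' decimal separator, header
#' `time_s,<30 channel columns>,action,interaction,payload`; time in seconds
#' with 4 decimals, channels with 6 decimals; `NA` labels serialized as empty
#' fields. One file per (subject, protocol run). Round-trips exactly through
#' [read_recording()] at the written precision.
#'
#' @param rec An `exohar_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  n <- nrow(rec$channels)
  dt <- data.table::data.table(
    time_s = sprintf("%.4f", (seq_len(n) - 1) / rec$fs))
  for (cn in colnames(rec$channels))
    dt[[cn]] <- sprintf("%.6f", rec$channels[, cn])
  dt$action <- rec$action
  dt$interaction <- ifelse(is.na(rec$interaction), "", rec$interaction)
  dt$payload <- ifelse(is.na(rec$payload), "", format(rec$payload))
  hdr <- sprintf("# subject=%s protocol=%d fs=%g", rec$subject_id,
                 rec$protocol_id, rec$fs)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(dt), collapse = ","), con)
  writeLines(do.call(paste, c(as.list(dt), sep = ",")), con)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Parses the dialect written by [write_recording()], validates every
#' invariant, and tags the sensor configuration from the channel column set
#' (30 -> `FULL_5`, 18 -> `REDUCED_3`, 6 -> `CHEST_1`).
#'
#' @param path File path.
#' @return An `exohar_recording`.
#' @export
read_recording <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("^# subject=(\\S+) protocol=(\\d) fs=([0-9.]+)$", hdr))[[1]]
  if (length(m) != 4) stop("malformed header line: ", hdr)
  dt <- data.table::fread(path, skip = 1L, header = TRUE, sep = ",",
                          colClasses = list(character = c("action", "interaction", "payload")),
                          na.strings = NULL, fill = FALSE)
  need_tail <- c("action", "interaction", "payload")
  if (names(dt)[1] != "time_s" ||
      !identical(tail(names(dt), 3), need_tail))
    stop("malformed column header")
  ch_cols <- setdiff(names(dt), c("time_s", need_tail))
  chan <- as.matrix(dt[, ch_cols, with = FALSE])
  storage.mode(chan) <- "double"
  interaction <- dt$interaction
  interaction[interaction == ""] <- NA_character_
  payload <- suppressWarnings(as.numeric(ifelse(dt$payload == "", NA, dt$payload)))
  labeled_recording(m[2], as.integer(m[3]), as.numeric(m[4]), chan,
                    dt$action, interaction, payload)
}

# ---- segments and repetitions ------------------------------------------------

#' Maximal contiguous label segments of a recording
#'
#' Each row is one run of constant (action, interaction, payload) labels:
#' start/end sample (1-based, inclusive), the labels, and duration in seconds.
#'
#' @param rec An `exohar_recording`.
#' @return A data.frame.
#' @export
recording_segments <- function(rec) {
  key <- paste(rec$action, rec$interaction, rec$payload, sep = "\r")
  r <- rle(key)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(
    start = start, end = end,
    action = rec$action[start],
    interaction = rec$interaction[start],
    payload = rec$payload[start],
    duration_s = r$lengths / rec$fs,
    stringsAsFactors = FALSE)
}

#' Assign each sample to a task repetition
#'
#' Repetition boundaries are recovered from the label track so that splits can
#' be made at repetition granularity without extra metadata in the CSV.
#' Protocol 1: one repetition per lift/lower cycle, starting at the standing
#' pause that precedes each LIFT. Protocol 2: one repetition per
#' stand/walk/manipulation sequence, starting at each STAND onset.
#'
#' @param rec An `exohar_recording`.
#' @return Integer vector of length `T`: repetition index (1-based).
#' @export
repetition_track <- function(rec) {
  seg <- recording_segments(rec)
  n <- nrow(rec$channels)
  rep_id <- integer(n)
  if (rec$protocol_id == 1L) {
    lifts <- which(seg$action == "INTERACT" & seg$interaction == "LIFT")
    # cycle starts at the STAND pause immediately before each LIFT
    starts <- vapply(lifts, function(i) if (i > 1 && seg$action[i - 1] == "STAND")
      seg$start[i - 1] else seg$start[i], integer(1))
  } else {
    starts <- seg$start[seg$action == "STAND"]
  }
  starts <- sort(unique(c(1L, starts)))
  rep_id <- findInterval(seq_len(n), starts)
  rep_id
}

# ---- dataset bundle and splits -----------------------------------------------

#' Bundle the three datasets of one subject
#'
#' `D1` is a protocol-1 recording (lift/lower cycles, 10 repetitions per
#' payload by default), `D2` a protocol-2 recording at 10 kg, `D3` a
#' protocol-2 recording with 2 repetitions per payload.
#'
#' @param D1,D2,D3 `exohar_recording` objects.
#' @return An object of class `exohar_bundle`.
#' @export
dataset_bundle <- function(D1, D2, D3) {
  stopifnot(D1$protocol_id == 1L, D2$protocol_id == 2L, D3$protocol_id == 2L)
  if (!all(D2$payload[D2$action == "INTERACT"] == 10))
    stop("D2 payload must be uniformly 10 kg")
  structure(list(D1 = D1, D2 = D2, D3 = D3), class = "exohar_bundle")
}

#' Train/test splits per model kind
#'
#' `HAR`: train = 100% of D2, test = 100% of D3. `PAYLOAD`: train = 90% of D1
#' + 50% of D3, test = 10% of D1 + 50% of D3. Splits are made at repetition
#' granularity, stratified by payload class, fractions honored to the nearest
#' whole repetition (at least one test repetition per stratum when the test
#' fraction is nonzero). Train and test repetitions are disjoint and cover the
#' input.
#'
#' @param bundle An `exohar_bundle`.
#' @param model_kind `"HAR"` or `"PAYLOAD"`.
#' @param seed Integer seed controlling which repetitions land in the test set.
#' @return A list with elements `train` and `test`, each a list of *slices*:
#'   `list(rec = <recording>, rows = <integer sample indices>)`.
#' @export
make_splits <- function(bundle, model_kind = c("HAR", "PAYLOAD"), seed = 0L) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(bundle, "exohar_bundle"))
  if (model_kind == "HAR") {
    return(list(
      train = list(whole_slice(bundle$D2)),
      test  = list(whole_slice(bundle$D3))))
  }
  withr::with_seed(seed, {
    s1 <- split_recording_reps(bundle$D1, test_fraction = 0.10)
    s3 <- split_recording_reps(bundle$D3, test_fraction = 0.50)
    list(train = c(s1$train, s3$train), test = c(s1$test, s3$test))
  })
}

whole_slice <- function(rec) list(rec = rec, rows = seq_len(nrow(rec$channels)))

# Stratified (by payload) repetition-wise split of one recording.
# Consumes the ambient RNG stream (callers wrap in withr::with_seed).
split_recording_reps <- function(rec, test_fraction) {
  rep_id <- repetition_track(rec)
  reps <- sort(unique(rep_id))
  # payload of a repetition = payload of its INTERACT samples (unique by design)
  rep_payload <- vapply(reps, function(r) {
    p <- unique(rec$payload[rep_id == r & rec$action == "INTERACT"])
    if (length(p) == 0) NA_real_ else p[1]
  }, numeric(1))
  test_reps <- integer(0)
  for (p in sort(unique(rep_payload))) {
    grp <- reps[!is.na(rep_payload) & rep_payload == p]
    k <- round(length(grp) * test_fraction)
    if (test_fraction > 0) k <- max(1L, k)
    if (k > length(grp))
      stop("too few repetitions to honor the requested test fraction")
    picked <- if (length(grp) == 1) grp[seq_len(k)] else sample(grp, k)
    test_reps <- c(test_reps, picked)
  }
  train_reps <- setdiff(reps, test_reps)
  mk <- function(rr) lapply(rr, function(r) list(rec = rec, rows = which(rep_id == r)))
  list(train = mk(train_reps), test = mk(sort(test_reps)))
}
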