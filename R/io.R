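#' @title Trajectory log I/O
#' @description Read and write trajectory logs in the package's CSV schema:
#' `time_s, speed_mps, accel_mps2, dist_to_light_m, light_phase (G/Y/R),
#' hmi_active (0/1), approach_idx, lap_id, condition, subject_id`. Time must
#' be strictly increasing within each subject x lap.
#' @param path File path.
#' @return `read_trajectory_log`: the log data.frame.
#' @name trajectory_log_io
NULL

.log_columns <- c("time_s", "speed_mps", "accel_mps2", "dist_to_light_m",
                  "light_phase", "hmi_active", "approach_idx", "lap_id",
                  "condition", "subject_id")
.log_numeric <- c("time_s", "speed_mps", "accel_mps2", "dist_to_light_m")

validate_trajectory_log <- function(log, where = "trajectory log") {
  if (nrow(log) == 0L) stop(where, ": empty log")
  missing <- setdiff(.log_columns, names(log))
  if (length(missing))
    stop(where, ": missing column(s): ", paste(missing, collapse = ", "))
  for (col in .log_numeric) {
    bad <- which(!is.finite(log[[col]]))
    if (length(bad))
      stop(where, ": malformed numeric value in column '", col,
           "' at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }
  bad_phase <- which(!log$light_phase %in% c("G", "Y", "R"))
  if (length(bad_phase))
    stop(where, ": invalid light_phase at row(s) ",
         paste(utils::head(bad_phase, 5), collapse = ", "))
  key <- paste(log$subject_id, log$lap_id)
  for (k in unique(key)) {
    tt <- log$time_s[key == k]
    if (any(diff(tt) <= 0))
      stop(where, ": non-monotone time within subject x lap '", k, "'")
  }
  invisible(log)
}

#' @rdname trajectory_log_io
#' @export
read_trajectory_log <- function(path) {
  if (!file.exists(path)) stop("read_trajectory_log: no such file: ", path)
  log <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(light_phase = "character",
                                        subject_id = "character",
                                        condition = "character"))
  if (nrow(log) == 0L) stop("read_trajectory_log: empty log: ", path)
  validate_trajectory_log(log, where = path)
  log[, .log_columns]
}

#' @rdname trajectory_log_io
#' @param log Trajectory log data.frame.
#' @export
write_trajectory_log <- function(log, path) {
  validate_trajectory_log(log)
  utils::write.csv(log[, .log_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Extract pre-transition trajectory snippets
#'
#' One snippet per green-to-yellow transition with enough same-lap history:
#' the window covers the `window_T` steps strictly before the transition
#' instant (half-open; the final step is the last pre-transition step, still
#' green), so extraction is strictly causal. The driver's action at the
#' transition step (speed, accel) is attached as the decoder target.
#' Transitions with insufficient history are skipped and counted.
#'
#' @param log Trajectory log (one or many subjects/laps).
#' @param window_T Window length in steps (>= 2); default 100 (10 s at
#'   10 Hz).
#' @param channels Channel columns fed to the encoder; the phase column is
#'   expanded to a G/Y/R one-hot.
#' @return Object of class `snippet_set`: list with `snippets` (each a list
#'   with `subject_id`, `lap_id`, `approach_idx`, `channels` T x C matrix,
#'   `dt`, `anchor_time`, `action`), `channel_names`, `window_T`, and
#'   `n_skipped`.
#' @export
extract_snippets <- function(log, window_T = 100L,
                             channels = c("speed_mps", "accel_mps2",
                                          "dist_to_light_m", "light_phase",
                                          "hmi_active")) {
  if (window_T < 2L) stop("extract_snippets: window_T must be >= 2")
  validate_trajectory_log(log)
  chan_names <- unlist(lapply(channels, function(ch)
    if (ch == "light_phase") c("phase_G", "phase_Y", "phase_R") else ch))
  snippets <- list()
  n_skipped <- 0L
  key <- paste(log$subject_id, log$lap_id)
  for (k in unique(key)) {
    lap <- log[key == k, , drop = FALSE]
    dt <- stats::median(diff(lap$time_s))
    phase <- lap$light_phase
    anchors <- which(phase == "Y" & c("", phase[-length(phase)]) == "G")
    for (a in anchors) {
      if (a - window_T < 1L) { n_skipped <- n_skipped + 1L; next }
      rows <- lap[(a - window_T):(a - 1L), , drop = FALSE]
      mats <- lapply(channels, function(ch) {
        if (ch == "light_phase") {
          cbind(phase_G = as.numeric(rows$light_phase == "G"),
                phase_Y = as.numeric(rows$light_phase == "Y"),
                phase_R = as.numeric(rows$light_phase == "R"))
        } else matrix(as.numeric(rows[[ch]]), ncol = 1,
                      dimnames = list(NULL, ch))
      })
      ch_mat <- do.call(cbind, mats)
      snippets[[length(snippets) + 1L]] <- list(
        subject_id = lap$subject_id[1], lap_id = lap$lap_id[1],
        approach_idx = lap$approach_idx[a], channels = ch_mat, dt = dt,
        anchor_time = lap$time_s[a],
        action = c(speed = lap$speed_mps[a], accel = lap$accel_mps2[a]))
    }
  }
  structure(list(snippets = snippets, channel_names = chan_names,
                 window_T = as.integer(window_T), n_skipped = n_skipped),
            class = "snippet_set")
}

#' @export
print.snippet_set <- function(x, ...) {
  cat("snippet_set:", length(x$snippets), "snippets of", x$window_T,
      "steps x", length(x$channel_names), "channels (", x$n_skipped,
      "skipped )\n")
  invisible(x)
}

#' Standardize cognitive measures
#'
#' Batch-normalization convention: each measure is centered and scaled to
#' zero mean and unit SD over the training table, using the population SD
#' (divide by n). The fitted transform is returned for test-time reuse and
#' is exactly invertible.
#'
#' @param subject_table data.frame with `subject_id` and one column per
#'   measure.
#' @param measures Character vector of measure columns to standardize.
#' @return Object of class `factor_transform`: list with `measures`,
#'   `center`, `scale`, and `profiles` (standardized matrix, one row per
#'   subject, rownames = subject ids).
#' @export
standardize_factors <- function(subject_table,
                                measures = names(default_factor_specs())) {
  missing <- setdiff(measures, names(subject_table))
  if (length(missing))
    stop("standardize_factors: missing measure column(s): ",
         paste(missing, collapse = ", "))
  x <- as.matrix(subject_table[, measures, drop = FALSE])
  if (any(!is.finite(x))) stop("standardize_factors: non-finite measures")
  n <- nrow(x)
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2, center)^2))  # population sd
  if (any(scale <= 0))
    stop("standardize_factors: constant measure column(s): ",
         paste(measures[scale <= 0], collapse = ", "))
  profiles <- sweep(sweep(x, 2, center), 2, scale, `/`)
  rownames(profiles) <- subject_table$subject_id
  structure(list(measures = measures, center = center, scale = scale,
                 profiles = profiles),
            class = "factor_transform")
}

#' Apply / invert a stored standardization transform
#'
#' @param transform A `factor_transform` from [standardize_factors()].
#' @param subject_table data.frame with the transform's measure columns
#'   (`apply_factor_transform`), or a standardized matrix/vector
#'   (`invert_factor_transform`).
#' @return Standardized matrix, or raw-score matrix for the inverse.
#' @export
apply_factor_transform <- function(transform, subject_table) {
  x <- as.matrix(subject_table[, transform$measures, drop = FALSE])
  out <- sweep(sweep(x, 2, transform$center), 2, transform$scale, `/`)
  if ("subject_id" %in% names(subject_table))
    rownames(out) <- subject_table$subject_id
  out
}

#' @rdname apply_factor_transform
#' @param standardized Standardized matrix (columns in transform order).
#' @export
invert_factor_transform <- function(transform, standardized) {
  z <- matrix(standardized, ncol = length(transform$measures))
  sweep(sweep(z, 2, transform$scale, `*`), 2, transform$center, `+`)
}

#' Build the per-approach trial table
#'
#' One row per subject x lap x light approach. For approaches with a yellow
#' phase, `mean_yellow_speed` and `max_yellow_speed` are computed over the
#' steps where the phase is Y; approaches that stay green have
#' `had_yellow = FALSE` and `NA` speeds.
#'
#' @param log Trajectory log.
#' @return data.frame with `subject_id`, `lap_id`, `approach_idx`,
#'   `condition`, `hmi_present`, `had_yellow`, `mean_yellow_speed`,
#'   `max_yellow_speed`.
#' @export
build_trial_table <- function(log) {
  validate_trajectory_log(log)
  key <- interaction(log$subject_id, log$lap_id, log$approach_idx,
                     drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(seq_len(nrow(log)), key), function(idx) {
    g <- log[idx, , drop = FALSE]
    y <- g$light_phase == "Y"
    data.frame(
      subject_id = g$subject_id[1], lap_id = g$lap_id[1],
      approach_idx = g$approach_idx[1], condition = g$condition[1],
      hmi_present = !g$condition[1] %in% c("baseline", "practice"),
      had_yellow = any(y),
      mean_yellow_speed = if (any(y)) mean(g$speed_mps[y]) else NA_real_,
      max_yellow_speed = if (any(y)) max(g$speed_mps[y]) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$lap_id, out$approach_idx), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a snippet archive
#'
#' Plain-text counterpart of an NPZ archive: a long-format CSV of channel
#' values plus a JSON sidecar carrying subject ids, 0-based anchor indices,
#' actions, dt and channel names.
#'
#' @param snips A `snippet_set`.
#' @param dir Output directory (created if needed).
#' @return `write_snippet_archive`: the directory, invisibly;
#'   `read_snippet_archive`: a `snippet_set`.
#' @export
write_snippet_archive <- function(snips, dir) {
  stopifnot(inherits(snips, "snippet_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- lapply(seq_along(snips$snippets), function(i) {
    s <- snips$snippets[[i]]
    data.frame(snippet = i - 1L,                       # 0-based on disk
               step = rep(seq_len(nrow(s$channels)) - 1L,
                          ncol(s$channels)),
               channel = rep(colnames(s$channels), each = nrow(s$channels)),
               value = as.vector(s$channels))
  })
  utils::write.csv(do.call(rbind, tabs), file.path(dir, "snippets.csv"),
                   row.names = FALSE, quote = FALSE)
  meta <- list(
    window_T = snips$window_T, channel_names = snips$channel_names,
    n_skipped = snips$n_skipped,
    snippets = lapply(snips$snippets, function(s)
      list(subject_id = s$subject_id, lap_id = s$lap_id,
           approach_idx = s$approach_idx, dt = s$dt,
           anchor_time = s$anchor_time, action = as.list(s$action))))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_snippet_archive
#' @export
read_snippet_archive <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = FALSE)
  tab <- utils::read.csv(file.path(dir, "snippets.csv"),
                         stringsAsFactors = FALSE)
  chans <- unlist(meta$channel_names)
  snippets <- lapply(seq_along(meta$snippets), function(i) {
    m <- meta$snippets[[i]]
    sub <- tab[tab$snippet == i - 1L, , drop = FALSE]
    ch <- matrix(0, meta$window_T, length(chans),
                 dimnames = list(NULL, chans))
    for (cn in chans)
      ch[, cn] <- sub$value[sub$channel == cn][order(
        sub$step[sub$channel == cn])]
    list(subject_id = m$subject_id, lap_id = m$lap_id,
         approach_idx = m$approach_idx, channels = ch, dt = m$dt,
         anchor_time = m$anchor_time,
         action = c(speed = m$action$speed, accel = m$action$accel))
  })
  structure(list(snippets = snippets, channel_names = chans,
                 window_T = as.integer(meta$window_T),
                 n_skipped = as.integer(meta$n_skipped)),
            class = "snippet_set")
}
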