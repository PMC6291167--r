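## Plain-text interchange formats: tab-separated tables with documented
## headers plus JSON sidecars. Deliberately language-agnostic and
## diff-able; adequate at desk scale.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", na.strings = "",
                    stringsAsFactors = FALSE, ...)
}

#' Write / read a trial table
#'
#' Tab-separated, one row per trial, with header `phase, run, trial,
#' pair, side_left, choice, outcome, rt, t_fixation, t_options_on,
#' t_choice, t_feedback, t_options_off`. Missing outcome (transfer
#' phase) is encoded as an empty field.
#'
#' @param trials Trial data frame.
#' @param path File path.
#' @return `read_trials` returns the trial data frame.
#' @export
write_trials <- function(trials, path) {
  cols <- c("phase", "run", "trial", "pair", "side_left", "choice",
            "outcome", "rt", "t_fixation", "t_options_on", "t_choice",
            "t_feedback", "t_options_off")
  .write_tsv(trials[, cols], path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- .read_tsv(path, colClasses = list(pair = "character",
                                          choice = "character",
                                          side_left = "character"))
  need <- c("phase", "run", "trial", "pair", "choice", "rt")
  if (!all(need %in% names(df)))
    stop("malformed trial table, missing: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Write / read a pupil trace
#'
#' Tab-separated with header `time_s, diameter, run`. The sampling rate
#' is recovered from the time stamps on read; non-monotone time stamps
#' are rejected.
#'
#' @param ts A [pupil_ts()].
#' @param path File path.
#' @return `read_pupil` returns a `pupil_ts`.
#' @export
write_pupil <- function(ts, path) {
  .write_tsv(data.frame(time_s = ts$time, diameter = ts$diameter,
                        run = ts$run), path)
  invisible(path)
}

#' @rdname write_pupil
#' @export
read_pupil <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("time_s", "diameter", "run") %in% names(df)))
    stop("malformed pupil trace: expected columns time_s, diameter, run")
  if (is.unsorted(df$time_s))
    stop("pupil trace has non-monotone time stamps")
  fs <- 1 / stats::median(diff(df$time_s))
  pupil_ts(df$time_s, df$diameter, round(fs, 6), df$run)
}

#' Write / read event annotations
#'
#' Tab-separated with header `event_type, time_s, amplitude_deg`;
#' `event_type` is `blink_start`, `blink_end`, or `saccade` (only
#' saccades carry an amplitude). Proprietary eye-tracker formats are out
#' of scope; converters should emit this layout.
#'
#' @param blinks Data frame with `start`, `end` (seconds).
#' @param saccades Data frame with `time`, `amplitude`.
#' @param path File path.
#' @return `read_annotations` returns `list(blinks, saccades)`.
#' @export
write_annotations <- function(blinks, saccades, path) {
  rows <- rbind(
    if (nrow(blinks)) data.frame(event_type = "blink_start",
                                 time_s = blinks$start,
                                 amplitude_deg = NA_real_),
    if (nrow(blinks)) data.frame(event_type = "blink_end",
                                 time_s = blinks$end,
                                 amplitude_deg = NA_real_),
    if (nrow(saccades)) data.frame(event_type = "saccade",
                                   time_s = saccades$time,
                                   amplitude_deg = saccades$amplitude))
  if (is.null(rows))
    rows <- data.frame(event_type = character(0), time_s = numeric(0),
                       amplitude_deg = numeric(0))
  rows <- rows[order(rows$time_s), ]
  .write_tsv(rows, path)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("event_type", "time_s") %in% names(df)))
    stop("malformed annotation file")
  bs <- sort(df$time_s[df$event_type == "blink_start"])
  be <- sort(df$time_s[df$event_type == "blink_end"])
  if (length(bs) != length(be))
    stop("unbalanced blink_start/blink_end annotations")
  sac <- df[df$event_type == "saccade", ]
  list(blinks = data.frame(start = bs, end = be),
       saccades = data.frame(time = sac$time_s,
                             amplitude = sac$amplitude_deg))
}

#' Write / read posterior draws
#'
#' Long-format tab-separated table with header `chain, draw, quantity,
#' value`.
#'
#' @param fit An `hb_fit` object (or, for reading, a path).
#' @param path File path.
#' @return `read_draws` returns the long-format data frame.
#' @export
write_draws <- function(fit, path) {
  d <- fit$draws
  dims <- dim(d)
  long <- data.frame(
    chain = rep(rep(seq_len(dims[2]), each = dims[1]), dims[3]),
    draw = rep(seq_len(dims[1]), dims[2] * dims[3]),
    quantity = rep(dimnames(d)[[3]], each = dims[1] * dims[2]),
    value = as.vector(d))
  .write_tsv(long, path)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("chain", "draw", "quantity", "value") %in% names(df)))
    stop("malformed draws table")
  df
}

#' Write / read deconvolved response coefficients
#'
#' Tab-separated `regressor, lag_s, beta` plus a JSON sidecar
#' (`<path>.json`) holding the chosen penalty, the CV curve, and the
#' number of splits.
#'
#' @param result A `deconv_result`.
#' @param path File path of the TSV.
#' @return `read_betas` returns a data frame `regressor, lag, beta`
#'   with the sidecar (if present) attached as attribute `"meta"`.
#' @export
write_betas <- function(result, path) {
  .write_tsv(data.frame(regressor = result$betas$regressor,
                        lag_s = result$betas$lag,
                        beta = result$betas$beta), path)
  meta <- list(lambda_star = result$lambda_star,
               cv_scores = result$cv_scores, n_splits = result$n_splits,
               fs = result$fs)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_betas
#' @export
read_betas <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("regressor", "lag_s", "beta") %in% names(df)))
    stop("malformed beta table")
  out <- data.frame(regressor = df$regressor, lag = df$lag_s,
                    beta = df$beta)
  side <- paste0(path, ".json")
  if (file.exists(side)) attr(out, "meta") <- jsonlite::read_json(side)
  out
}

#' Write a cluster-test table
#'
#' Tab-separated `start_s, end_s, size, p`.
#'
#' @param test A `cluster_test` object.
#' @param path File path.
#' @export
write_clusters <- function(test, path) {
  .write_tsv(data.frame(start_s = test$clusters$start_s,
                        end_s = test$clusters$end_s,
                        size = test$clusters$size,
                        p = test$clusters$p_corrected), path)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' One directory per subject (`sub-01`, ...) with the trial table, raw
#' pupil traces, and annotation files for each phase, plus a top-level
#' `manifest.json` recording seeds, true parameters, and planted effect
#' sizes.
#'
#' @param cohort A [generate_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    d <- file.path(out_dir, sprintf("sub-%02d", s$subject))
    dir.create(d, showWarnings = FALSE)
    write_trials(s$trials, file.path(d, "trials.tsv"))
    write_pupil(s$learning_pupil$ts, file.path(d, "learning_pupil.tsv"))
    write_annotations(s$learning_pupil$blinks, s$learning_pupil$saccades,
                      file.path(d, "learning_annotations.tsv"))
    if (!is.null(s$transfer_pupil)) {
      write_pupil(s$transfer_pupil$ts, file.path(d, "transfer_pupil.tsv"))
      write_annotations(s$transfer_pupil$blinks, s$transfer_pupil$saccades,
                        file.path(d, "transfer_annotations.tsv"))
    }
  }
  jsonlite::write_json(cohort$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(out_dir)
}

#' Write / read a single-trial covariate trajectory
#'
#' Tab-separated per-trial table with header `trial, q_chosen,
#' q_unchosen, rpe, delta_value`, the interchange format between the
#' behavioral model and the deconvolution stage. Transfer-phase tables
#' (no prediction error) leave `rpe` empty.
#'
#' @param trajectory A [compute_trajectory()] or [transfer_values()]
#'   data frame.
#' @param path File path.
#' @return `read_trajectory` returns the data frame.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- data.frame(trial = trajectory$trial,
                   q_chosen = trajectory$q_chosen,
                   q_unchosen = trajectory$q_unchosen,
                   rpe = if (is.null(trajectory$rpe)) NA_real_ else trajectory$rpe,
                   delta_value = trajectory$delta_value)
  .write_tsv(df, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- .read_tsv(path)
  need <- c("trial", "q_chosen", "q_unchosen", "delta_value")
  if (!all(need %in% names(df)))
    stop("malformed trajectory table, missing: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}
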