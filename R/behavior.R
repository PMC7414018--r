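#' Trial scoring rule
#'
#' A sequence counts as correct when it is pressed in exactly the target
#' order and the total movement time -- the time between the first and the
#' last press -- is strictly shorter than `mt_threshold_s`.
#'
#' @param mt_threshold_s Movement-time cutoff in seconds (default 2.5).
#' @param sequence_length Number of presses per sequence (default 5).
#' @return A `scoring_rule` list.
#' @export
scoring_rule <- function(mt_threshold_s = 2.5, sequence_length = 5L) {
  stopifnot(mt_threshold_s > 0, sequence_length >= 1)
  structure(list(mt_threshold_s = mt_threshold_s,
                 sequence_length = as.integer(sequence_length)),
            class = "scoring_rule")
}

#' Score a single trial
#'
#' @param buttons Integer vector of pressed buttons, in press order.
#' @param times Numeric vector of press times (seconds), non-decreasing.
#' @param target Integer vector: the cued button sequence.
#' @param rule A [scoring_rule()].
#' @return A one-row tibble with `correct` (logical) and `movement_time_s`
#'   (last minus first press time; `NA` when the press count is wrong).
#'   A wrong press count scores incorrect rather than erroring: the
#'   accuracy denominator is all trials.
#' @examples
#' score_trial(1:5, c(0, 0.3, 0.6, 0.9, 1.2), 1:5) # correct, MT 1.2 s
#' @export
score_trial <- function(buttons, times, target, rule = scoring_rule()) {
  if (length(buttons) == 0 || length(buttons) != length(times)) {
    stop("`buttons` and `times` must be non-empty and of equal length")
  }
  if (anyNA(times) || anyNA(buttons)) {
    return(tibble::tibble(correct = FALSE, movement_time_s = NA_real_))
  }
  if (is.unsorted(times)) stop("press times must be non-decreasing")
  if (length(buttons) != rule$sequence_length) {
    return(tibble::tibble(correct = FALSE, movement_time_s = NA_real_))
  }
  mt <- times[length(times)] - times[1]
  ok <- all(buttons == target) && mt < rule$mt_threshold_s
  tibble::tibble(correct = ok, movement_time_s = mt)
}

#' Score every trial of a press log
#'
#' @param log A trial-log tibble as produced by [simulate_press_log()]
#'   (columns subject, run, trial, class, `press1..pressN`, `t1..tN`).
#' @param sequences Named list of target sequences indexed by class, as from
#'   [finger_sequences()].
#' @param rule A [scoring_rule()].
#' @return The log with `correct` and `movement_time_s` columns appended.
#' @export
score_press_log <- function(log, sequences = finger_sequences(),
                            rule = scoring_rule()) {
  stopifnot(nrow(log) > 0)
  np <- rule$sequence_length
  press_cols <- paste0("press", seq_len(np))
  time_cols <- paste0("t", seq_len(np))
  if (!all(c(press_cols, time_cols) %in% names(log))) {
    stop("log lacks press/time columns ",
         paste(setdiff(c(press_cols, time_cols), names(log)), collapse = ", "))
  }
  scored <- purrr::map_dfr(seq_len(nrow(log)), function(r) {
    score_trial(as.integer(log[r, press_cols]), as.numeric(log[r, time_cols]),
                sequences[[log$class[r]]], rule)
  })
  dplyr::bind_cols(log, scored)
}

#' Per-cell behavioural summary
#'
#' Accuracy (fraction of correct trials) and mean movement time over the
#' correct trials only, per subject x run x sequence class. Cells without
#' any correct trial get a missing movement time.
#'
#' @param log A trial log; scored with [score_press_log()] first if the
#'   `correct` column is absent.
#' @param sequences,rule Passed to [score_press_log()] when scoring is
#'   needed.
#' @return Tibble with subject, run, class, n_trials, accuracy, mean_mt_s.
#' @export
summarize_performance <- function(log, sequences = finger_sequences(),
                                  rule = scoring_rule()) {
  stopifnot(nrow(log) > 0)
  if (!"correct" %in% names(log)) {
    log <- score_press_log(log, sequences, rule)
  }
  out <- log |>
    dplyr::group_by(.data$subject, .data$run, .data$class) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      accuracy = mean(.data$correct),
      mean_mt_s = if (any(.data$correct)) {
        mean(.data$movement_time_s[.data$correct])
      } else NA_real_,
      .groups = "drop"
    )
  if (anyNA(out$mean_mt_s)) {
    warning(sum(is.na(out$mean_mt_s)),
            " cell(s) without correct trials: movement time missing")
  }
  out
}

#' Write / read a trial log as TSV
#' @param log Trial-log tibble.
#' @param path File path.
#' @return `path` (write) or the log tibble (read).
#' @export
write_press_log <- function(log, path) {
  write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_press_log
#' @export
read_press_log <- function(path) {
  tibble::as_tibble(read.delim(path, sep = "\t", check.names = FALSE))
}
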