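#' The four finger sequences, by complexity level
#'
#' Four 5-press sequences over buttons 1--5 (thumb to little finger),
#' graded by the number of direction changes and jumps: level 1 is the
#' simple ascending run; levels 2--4 add progressively more direction
#' inversions and non-adjacent transitions. `set = 2` gives the mirrored
#' versions (button `b -> 6 - b`).
#'
#' @param set 1 or 2 (mirrored).
#' @return Named list of four integer vectors (`seq1` .. `seq4`).
#' @export
finger_sequences <- function(set = 1) {
  base <- list(
    seq1 = c(1L, 2L, 3L, 4L, 5L),  # 0 changes, 0 jumps
    seq2 = c(2L, 4L, 5L, 3L, 1L),  # 1 change,  2 jumps
    seq3 = c(1L, 4L, 2L, 3L, 5L),  # 2 changes, 3 jumps
    seq4 = c(3L, 1L, 4L, 2L, 5L)   # 3 changes, 4 jumps
  )
  if (set == 1) base else lapply(base, function(s) 6L - s)
}

#' Learning-curve parameters for the press-log generator
#'
#' Expected movement time per run follows the saturating curve
#' `MT_r = mt_asymptote + (mt_initial - mt_asymptote) * exp(-r / tau_learn)`,
#' emulating improvement that plateaus over the late runs. The simple
#' sequence (class 1) is performed faster by `class1_advantage_s` seconds.
#'
#' @param mt_initial_s,mt_asymptote_s Initial and asymptotic expected
#'   movement times in seconds.
#' @param tau_learn Learning time constant in runs (> 0; smaller = faster
#'   saturation).
#' @param mt_sd_s Trial-to-trial movement-time SD in seconds.
#' @param error_prob Probability that a trial is performed in a wrong order;
#'   either a scalar or one value per run.
#' @param class1_advantage_s Speed advantage of sequence 1 in seconds.
#' @param trials_per_class 12 by default: 4 trial blocks per run, each with
#'   3 executions of the cued sequence.
#' @return A `learning_params` list.
#' @export
learning_params <- function(mt_initial_s = 1.8, mt_asymptote_s = 1.15,
                            tau_learn = 1.2, mt_sd_s = 0.15,
                            error_prob = c(0.15, 0.10, 0.07, 0.05, 0.05, 0.05),
                            class1_advantage_s = 0.12,
                            trials_per_class = 12L) {
  stopifnot(mt_initial_s > 0, mt_asymptote_s > 0, tau_learn > 0,
            mt_sd_s >= 0, all(error_prob >= 0), all(error_prob <= 1),
            class1_advantage_s >= 0, trials_per_class >= 1)
  structure(
    list(mt_initial_s = mt_initial_s, mt_asymptote_s = mt_asymptote_s,
         tau_learn = tau_learn, mt_sd_s = mt_sd_s, error_prob = error_prob,
         class1_advantage_s = class1_advantage_s,
         trials_per_class = as.integer(trials_per_class)),
    class = "learning_params"
  )
}

#' Expected movement time by run under the learning curve
#'
#' @param params A [learning_params()].
#' @param run Run number(s).
#' @param class Sequence class(es) (class 1 gets the speed advantage).
#' @return Expected movement time(s) in seconds.
#' @export
expected_movement_time <- function(params, run, class = 2L) {
  mt <- params$mt_asymptote_s +
    (params$mt_initial_s - params$mt_asymptote_s) * exp(-run / params$tau_learn)
  mt - ifelse(class == 1L, params$class1_advantage_s, 0)
}

#' Simulate a button-press trial log
#'
#' Each trial holds 5 press events (button, time). Correct trials press the
#' target sequence in order with total movement time drawn around the
#' learning-curve expectation; error trials press a randomly chosen
#' non-identity permutation of the target order. Press times are strictly
#' increasing within a trial.
#'
#' @param design A [synthetic_design()].
#' @param params A [learning_params()].
#' @param sequence_set 1 or 2, passed to [finger_sequences()].
#' @return Tibble with columns subject, run, trial, class,
#'   `press1..press5`, `t1..t5`.
#' @export
simulate_press_log <- function(design, params = learning_params(),
                               sequence_set = 1) {
  stopifnot(inherits(design, "synthetic_design"),
            inherits(params, "learning_params"))
  seqs <- finger_sequences(sequence_set)[seq_len(min(4, design$n_classes))]
  if (design$n_classes > 4) {
    stop("the task defines 4 sequence classes; n_classes > 4 is not supported")
  }
  err <- rep(params$error_prob, length.out = design$n_runs)

  with_stage_seed(design$seed, "presslog", {
    grid <- tidyr::expand_grid(
      subject = seq_len(design$n_subjects), run = seq_len(design$n_runs),
      class = seq_len(design$n_classes), rep = seq_len(params$trials_per_class)
    )
    rows <- purrr::pmap_dfr(grid, function(subject, run, class, rep) {
      target <- seqs[[class]]
      wrong <- runif(1) < err[run]
      buttons <- if (wrong) scramble_order(target) else target
      mt <- max(0.3, rnorm(1, expected_movement_time(params, run, class),
                           params$mt_sd_s))
      gaps <- runif(4, 0.5, 1.5)
      times <- 0.2 + c(0, cumsum(gaps / sum(gaps) * mt))
      tibble::tibble(
        subject = subject, run = run, rep = rep, class = class,
        !!!setNames(as.list(buttons), paste0("press", 1:5)),
        !!!setNames(as.list(times), paste0("t", 1:5))
      )
    })
    rows <- dplyr::arrange(rows, .data$subject, .data$run, .data$rep, .data$class)
    rows$trial <- stats::ave(rows$subject, rows$subject, rows$run,
                             FUN = seq_along)
    dplyr::select(rows, "subject", "run", "trial", "class",
                  dplyr::starts_with("press"), dplyr::starts_with("t"))
  })
}

# a permutation of the target that differs from the correct order
scramble_order <- function(target) {
  repeat {
    perm <- sample(length(target))
    if (any(target[perm] != target)) return(target[perm])
  }
}
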