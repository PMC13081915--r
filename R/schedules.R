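# Training-schedule state machines, framework-agnostic: an early-stopping
# monitor and a reduce-LR-on-plateau controller. Both are pure
# step functions over explicit state so traces can be verified exactly.

#' Early-stopping monitor
#'
#' Tracks the best validation metric seen; after `patience` consecutive
#' steps without an improvement greater than `min_delta`, the `stop`
#' flag is raised. The index of the best step (the checkpoint to
#' retain) is kept in `best_index`.
#'
#' @param patience Consecutive non-improving steps tolerated
#'   (default 7).
#' @param min_delta Minimum improvement that resets the counter
#'   (default 5e-4).
#' @param mode `"max"` when larger metric is better (validation
#'   accuracy; the default) or `"min"` (validation loss).
#' @return An `early_stop_state`.
#' @export
early_stop_state <- function(patience = 7, min_delta = 5e-4,
                             mode = c("max", "min")) {
  structure(
    list(patience = patience, min_delta = min_delta,
         mode = match.arg(mode), best = NULL, best_index = 0L,
         step = 0L, wait = 0L, stop = FALSE),
    class = "early_stop_state"
  )
}

#' Advance the early-stopping monitor by one validation step
#'
#' @param state An [early_stop_state()].
#' @param metric Finite validation metric for this step.
#' @return Updated state; check `$stop` and `$best_index`.
#' @export
early_stop_step <- function(state, metric) {
  if (!is.finite(metric)) stop("validation metric must be finite")
  state$step <- state$step + 1L
  improved <- if (is.null(state$best)) {
    TRUE
  } else if (state$mode == "max") {
    metric > state$best + state$min_delta
  } else {
    metric < state$best - state$min_delta
  }
  if (improved) {
    state$best <- metric
    state$best_index <- state$step
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) state$stop <- TRUE
  }
  state
}

#' Reduce-LR-on-plateau controller
#'
#' Halves (times `factor`) the learning rate when the monitored loss
#' has not improved for more than `patience` consecutive steps, never
#' dropping below `min_lr`; the wait counter resets after each
#' reduction.
#'
#' @param initial_lr Starting learning rate (default 1e-4).
#' @param patience Non-improving steps tolerated before a reduction
#'   (default 3).
#' @param factor Multiplicative LR decay in `(0, 1)` (default 0.5).
#' @param min_lr Floor on the learning rate (default 1e-6).
#' @return A `plateau_state`; the current LR is `$lr`.
#' @export
plateau_state <- function(initial_lr = 1e-4, patience = 3, factor = 0.5,
                          min_lr = 1e-6) {
  if (factor <= 0 || factor >= 1) stop("factor must lie in (0, 1)")
  structure(
    list(lr = initial_lr, patience = patience, factor = factor,
         min_lr = min_lr, best = NULL, wait = 0L, step = 0L),
    class = "plateau_state"
  )
}

#' Advance the plateau controller by one validation step
#'
#' @param state A [plateau_state()].
#' @param loss Finite validation loss for this step.
#' @return Updated state; `$lr` is the rate to use next.
#' @export
plateau_step <- function(state, loss) {
  if (!is.finite(loss)) stop("validation loss must be finite")
  state$step <- state$step + 1L
  if (is.null(state$best) || loss < state$best) {
    state$best <- loss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait > state$patience) {
      state$lr <- max(state$lr * state$factor, state$min_lr)
      state$wait <- 0L
    }
  }
  state
}

#' Full training schedule
#'
#' Bundles the optimizer and schedule hyper-parameters of the
#' classifier training protocol: early stopping (patience 7, minimum
#' improvement 5e-4), LR-on-plateau (patience 3, factor 0.5, floor
#' 1e-6), initial learning rate and weight decay.
#'
#' @param initial_lr Initial learning rate (default 1e-4).
#' @param weight_decay L2 penalty (default 1e-4).
#' @param early_patience,early_min_delta Early-stopping settings.
#' @param plateau_patience,plateau_factor,min_lr Plateau settings.
#' @param max_epochs Hard epoch cap for desk-scale training
#'   (default 300).
#' @return A `train_schedule` list.
#' @export
train_schedule <- function(initial_lr = 1e-4, weight_decay = 1e-4,
                           early_patience = 7, early_min_delta = 5e-4,
                           plateau_patience = 3, plateau_factor = 0.5,
                           min_lr = 1e-6, max_epochs = 300) {
  structure(
    list(initial_lr = initial_lr, weight_decay = weight_decay,
         early_patience = early_patience,
         early_min_delta = early_min_delta,
         plateau_patience = plateau_patience,
         plateau_factor = plateau_factor, min_lr = min_lr,
         max_epochs = max_epochs),
    class = "train_schedule"
  )
}
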