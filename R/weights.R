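#' Class weights for imbalanced classification losses
#'
#' Three frequency-based weighting schemes for a weighted
#' cross-entropy loss `L = sum_i w_i L_i` over `K` classes with counts
#' `n_i` and `N = sum n_i`:
#'
#' * `inverse`: `w_i = N / (K * n_i)` — satisfies
#'   `sum_i n_i w_i = N` exactly and gives unit weights when counts
#'   are equal.
#' * `sqrt_inverse`: `w_i = sqrt(N / (K * n_i))` — a milder
#'   re-weighting, the square root of the inverse weights.
#' * `effective_number`: `w_i = 1 / E_i` with
#'   `E_i = (1 - beta^n_i) / (1 - beta)`, the class-balanced
#'   effective-number-of-samples scheme; `beta` defaults to 0.9999.
#'
#' @param counts Positive per-class sample counts (named vector).
#' @param scheme One of `"inverse"`, `"sqrt_inverse"`,
#'   `"effective_number"`.
#' @param beta Effective-number decay, in `[0, 1)` (default 0.9999).
#' @param normalize Rescale so `mean(w) = 1` (default `FALSE`).
#' @return Numeric weight vector, named like `counts`.
#' @examples
#' class_weights(c(DO = 871, E = 264, ES = 799, G = 882, R = 263))
#' @export
class_weights <- function(counts,
                          scheme = c("inverse", "sqrt_inverse",
                                     "effective_number"),
                          beta = 0.9999, normalize = FALSE) {
  scheme <- match.arg(scheme)
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    bad <- which(!is.finite(counts) | counts <= 0)
    lab <- if (!is.null(names(counts))) names(counts)[bad] else bad
    stop("non-positive count for class ", paste(lab, collapse = ", "))
  }
  N <- sum(counts)
  K <- length(counts)
  w <- switch(scheme,
    inverse = N / (K * counts),
    sqrt_inverse = sqrt(N / (K * counts)),
    effective_number = {
      if (beta < 0 || beta >= 1) stop("beta must lie in [0, 1)")
      E <- (1 - beta^counts) / (1 - beta)
      1 / E
    })
  if (normalize) w <- w / mean(w)
  w
}

#' Focal loss
#'
#' `FL(p_t) = -alpha_t * (1 - p_t)^gamma * log(p_t)`, where `p_t` is
#' the predicted probability of the true class. The modulating factor
#' `(1 - p_t)^gamma` down-weights easy (high-`p_t`) examples; with
#' `gamma = 0` and `alpha_t = 1` it reduces to plain cross-entropy.
#'
#' @param p_t Predicted probability of the ground-truth class, in
#'   `(0, 1]`; vectorized.
#' @param alpha_t Class balancing factor in `(0, 1]` (default 0.25).
#' @param gamma Focusing parameter, `>= 0` (default 2).
#' @return Non-negative loss value(s); strictly decreasing in `p_t`.
#' @examples
#' focal_loss(0.5)            # 0.25 * 0.25 * log(2)
#' focal_loss(0.9, 1, 0)      # -log(0.9)
#' @export
focal_loss <- function(p_t, alpha_t = 0.25, gamma = 2) {
  if (any(p_t <= 0) || any(p_t > 1)) {
    stop("p_t must lie in (0, 1]")
  }
  if (alpha_t <= 0 || alpha_t > 1) stop("alpha_t must lie in (0, 1]")
  if (gamma < 0) stop("gamma must be non-negative")
  -alpha_t * (1 - p_t)^gamma * log(p_t)
}

#' Image-level oversampling duplication factor
#'
#' `k = max(1, round(N_maj * r / N_rare))` with half-up rounding, where
#' `N_maj` is the majority-class instance count, `N_rare` the total
#' rare-class instance count, and `r` the target ratio (default 0.5).
#'
#' @param n_majority Majority-class instance count.
#' @param n_rare Total rare-class instance count (> 0).
#' @param ratio Target ratio `r`.
#' @return Integer duplication factor `k >= 1`.
#' @export
duplication_factor <- function(n_majority, n_rare, ratio = 0.5) {
  if (n_rare <= 0) stop("no rare-class instances: N_rare must be positive")
  max(1L, as.integer(round_half_up(n_majority * ratio / n_rare)))
}
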