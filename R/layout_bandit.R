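#' Rally loss for the layout bandit
#'
#' The loss of rally i is `min(score, 10)/10 - 1`, where the score is the
#' number of paddle returns (bounces) in that rally; it lies in `[-1, 0]`
#' with 0 reached at ten or more returns.
#'
#' @param score integer rally score (number of hits), >= 0; vectorized.
#' @return loss in `[-1, 0]`.
#' @export
rally_loss <- function(score) {
  if (any(score < 0)) stop("rally score must be >= 0")
  pmin(score, 10) / 10 - 1
}

#' Initialize an EXP3 bandit over motor layouts
#'
#' The exponential-weight algorithm for exploration and exploitation
#' maintains one positive weight per arm (motor layout). Arms are drawn
#' from the exploration-mixed distribution
#' `p_i = (1 - gamma) w_i / sum(w) + gamma / K`, so every arm keeps at
#' least probability `gamma / K`.
#'
#' @param n_arms number of arms (default: the 5 layout presets).
#' @param gamma exploration rate in (0, 1].
#' @return an object of class `exp3_state`.
#' @export
exp3_init <- function(n_arms = 5L, gamma = 0.1) {
  stopifnot(n_arms >= 2L, gamma > 0, gamma <= 1)
  structure(list(weights = rep(1, n_arms), gamma = gamma,
                 n_arms = as.integer(n_arms)),
            class = "exp3_state")
}

#' Selection probabilities of the current EXP3 state
#' @param state an `exp3_state`.
#' @return numeric vector summing to 1, each element >= gamma / K.
#' @export
exp3_probs <- function(state) {
  (1 - state$gamma) * state$weights / sum(state$weights) +
    state$gamma / state$n_arms
}

#' Draw an arm from the EXP3 distribution
#'
#' @param state an `exp3_state`.
#' @param rng bandit substream ([rng_stream()]).
#' @return list with `arm` (1-based index) and `prob` (its probability).
#' @export
exp3_select <- function(state, rng) {
  p <- exp3_probs(state)
  arm <- rng_eval(rng, sample.int(state$n_arms, 1L, prob = p))
  list(arm = arm, prob = p[arm])
}

#' Update EXP3 weights after observing a rally loss
#'
#' The loss in `[-1, 0]` is mapped to a reward `r = loss + 1` in `[0, 1]`;
#' the importance-weighted estimate `r / p_arm` is applied to the chosen
#' arm only: `w_arm <- w_arm * exp(gamma * r / (p_arm * K))`. Weights are
#' renormalized when their sum grows large to avoid overflow.
#'
#' @param state an `exp3_state`.
#' @param arm 1-based index of the arm that was played.
#' @param loss observed loss in `[-1, 0]` (see [rally_loss()]).
#' @return updated `exp3_state`.
#' @export
exp3_update <- function(state, arm, loss) {
  if (loss < -1 || loss > 0) stop("loss must lie in [-1, 0]")
  p <- exp3_probs(state)
  r <- loss + 1
  state$weights[arm] <- state$weights[arm] *
    exp(state$gamma * (r / p[arm]) / state$n_arms)
  s <- sum(state$weights)
  if (s > 1e100) state$weights <- state$weights / s
  state
}
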