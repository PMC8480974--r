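#' Configuration of a transformed up-down staircase
#'
#' An n-down/1-up adaptive rule on stimulus onset asynchrony (SOA): after
#' `n_down` consecutive correct responses the SOA decreases by `step_down_ms`;
#' after a single incorrect response it increases by `step_up_ms`. The run
#' terminates after `termination_reversals` direction reversals and the
#' threshold is the mean SOA at the last `threshold_last_k` reversal points.
#' SOAs are clamped to \[`soa_floor_ms`, `soa_ceiling_ms`\].
#'
#' The temporal-order task uses 50 ms down / 5 ms up steps starting at
#' 1000 ms ([task1_config()]); the micropattern discrimination task uses
#' 20 ms down / 2 ms up, starting below the subject's order threshold
#' ([task2_config()]).
#'
#' @param initial_soa_ms starting SOA.
#' @param step_down_ms,step_up_ms fixed step sizes (ms), both > 0.
#' @param n_down consecutive-correct count triggering a decrease (default 3,
#'   tracking the 0.5^(1/3) = 79.4% correct level).
#' @param termination_reversals reversals after which the run stops.
#' @param threshold_last_k number of final reversal SOAs averaged into the
#'   threshold (must not exceed `termination_reversals`).
#' @param soa_floor_ms,soa_ceiling_ms presentable SOA limits.
#' @param max_trials safety cap guaranteeing termination for degenerate
#'   observers; a run hitting the cap is flagged non-converged.
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(initial_soa_ms = 1000, step_down_ms = 50,
                             step_up_ms = 5, n_down = 3L,
                             termination_reversals = 8L,
                             threshold_last_k = 5L,
                             soa_floor_ms = 2, soa_ceiling_ms = 1000,
                             max_trials = 1000L) {
  stopifnot(step_down_ms > 0, step_up_ms > 0, n_down >= 1,
            threshold_last_k <= termination_reversals,
            soa_floor_ms < soa_ceiling_ms,
            initial_soa_ms >= soa_floor_ms, initial_soa_ms <= soa_ceiling_ms,
            max_trials >= 1)
  structure(list(initial_soa_ms = initial_soa_ms,
                 step_down_ms = step_down_ms, step_up_ms = step_up_ms,
                 n_down = as.integer(n_down),
                 termination_reversals = as.integer(termination_reversals),
                 threshold_last_k = as.integer(threshold_last_k),
                 soa_floor_ms = soa_floor_ms, soa_ceiling_ms = soa_ceiling_ms,
                 max_trials = as.integer(max_trials)),
            class = "staircase_config")
}

#' @rdname staircase_config
#' @export
task1_config <- function(...) staircase_config(step_down_ms = 50, step_up_ms = 5, ...)

#' @rdname staircase_config
#' @param start_soa_ms starting SOA for the micropattern task, by convention
#'   the subject's temporal-order threshold from the first task.
#' @param ... overrides passed to [staircase_config()].
#' @export
task2_config <- function(start_soa_ms, ...)
  staircase_config(initial_soa_ms = start_soa_ms, step_down_ms = 20,
                   step_up_ms = 2, ...)

#' Simulated psychophysical observers
#'
#' `logistic_observer()` responds correctly with probability
#' `guess + (1 - guess - lapse) * plogis(slope * (log(soa) - log(midpoint)))`,
#' monotone non-decreasing in SOA. `constant_observer()` responds correctly
#' with a fixed probability regardless of SOA (degenerate cases: p = 1 or
#' p = 0 probe floor/ceiling behaviour).
#'
#' @param midpoint_ms SOA of half-way performance between guess and lapse
#'   asymptotes.
#' @param slope psychometric slope per natural-log ms.
#' @param guess_rate lower asymptote (0.5 for two-alternative judgments).
#' @param lapse_rate lapse probability at arbitrarily easy SOAs.
#' @return An observer object with a [p_correct()] method.
#' @export
logistic_observer <- function(midpoint_ms, slope = 8, guess_rate = 0.5,
                              lapse_rate = 0.02) {
  stopifnot(midpoint_ms > 0, slope > 0, guess_rate >= 0, guess_rate < 1,
            lapse_rate >= 0, guess_rate + lapse_rate < 1)
  structure(list(midpoint_ms = midpoint_ms, slope = slope,
                 guess_rate = guess_rate, lapse_rate = lapse_rate),
            class = c("logistic_observer", "observer"))
}

#' @rdname logistic_observer
#' @param p fixed probability of a correct response.
#' @export
constant_observer <- function(p) {
  stopifnot(p >= 0, p <= 1)
  structure(list(p = p), class = c("constant_observer", "observer"))
}

#' Probability of a correct response at a given SOA
#'
#' @param obs an observer.
#' @param soa_ms SOA in ms (vectorized).
#' @return Probability (ies) of a correct response.
#' @export
p_correct <- function(obs, soa_ms) UseMethod("p_correct")

#' @export
p_correct.logistic_observer <- function(obs, soa_ms) {
  obs$guess_rate + (1 - obs$guess_rate - obs$lapse_rate) *
    stats::plogis(obs$slope * (log(soa_ms) - log(obs$midpoint_ms)))
}

#' @export
p_correct.constant_observer <- function(obs, soa_ms) {
  rep(obs$p, length(soa_ms))
}

#' One step of the transformed up-down decision rule
#'
#' An incorrect response always triggers an SOA increase and resets the
#' consecutive-correct counter; a correct response that completes `n_down`
#' consecutive correct triggers a decrease (counter reset); any other
#' correct response holds the SOA and increments the counter.
#'
#' @param consecutive_correct current counter, in \[0, n_down - 1\].
#' @param response_correct logical, outcome of the current trial.
#' @param cfg a [staircase_config()].
#' @return List with `direction` ("down", "up" or "hold") and
#'   `consecutive_correct` (updated counter).
#' @export
update_state <- function(consecutive_correct, response_correct, cfg) {
  stopifnot(consecutive_correct >= 0, consecutive_correct < cfg$n_down)
  if (!response_correct) return(list(direction = "up", consecutive_correct = 0L))
  if (consecutive_correct + 1L >= cfg$n_down)
    return(list(direction = "down", consecutive_correct = 0L))
  list(direction = "hold", consecutive_correct = consecutive_correct + 1L)
}

#' Run one adaptive staircase on a simulated observer
#'
#' Each trial draws a Bernoulli response at the observer's `p_correct(SOA)`,
#' applies the up-down rule, and clamps moves to the SOA range. A reversal is
#' recorded when the realized movement direction changes sign relative to the
#' previous non-hold movement; moves fully absorbed by the floor/ceiling
#' clamp produce no realized movement and therefore never count as direction
#' changes. The run converges when `termination_reversals` reversals have
#' occurred; hitting `max_trials` first flags the run as non-converged with a
#' missing threshold.
#'
#' @param cfg a [staircase_config()].
#' @param obs an observer.
#' @param seed optional RNG seed making the run deterministic.
#' @return An object of class `staircase_result`: `trials` data.frame
#'   (index, soa_ms, correct, direction), `reversal_indices`,
#'   `reversal_soas_ms`, `threshold_ms` (NA when non-converged), `converged`.
#' @export
run_staircase <- function(cfg, obs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  soa <- cfg$initial_soa_ms
  cc <- 0L
  last_move <- 0
  rev_idx <- integer(0)
  rev_soa <- numeric(0)
  idx <- integer(cfg$max_trials)
  soas <- numeric(cfg$max_trials)
  corr <- logical(cfg$max_trials)
  dirs <- character(cfg$max_trials)
  n <- 0L
  while (length(rev_idx) < cfg$termination_reversals && n < cfg$max_trials) {
    n <- n + 1L
    p <- p_correct(obs, soa)
    correct <- stats::runif(1) < p
    st <- update_state(cc, correct, cfg)
    cc <- st$consecutive_correct
    idx[n] <- n; soas[n] <- soa; corr[n] <- correct; dirs[n] <- st$direction
    if (st$direction != "hold") {
      step <- if (st$direction == "down") -cfg$step_down_ms else cfg$step_up_ms
      new_soa <- min(cfg$soa_ceiling_ms, max(cfg$soa_floor_ms, soa + step))
      move <- new_soa - soa
      if (move != 0) {
        if (last_move != 0 && sign(move) != sign(last_move)) {
          rev_idx <- c(rev_idx, n)
          rev_soa <- c(rev_soa, soa)
        }
        last_move <- move
      }
      soa <- new_soa
    }
  }
  converged <- length(rev_idx) >= cfg$termination_reversals
  res <- structure(list(
    trials = data.frame(index = idx[seq_len(n)], soa_ms = soas[seq_len(n)],
                        correct = corr[seq_len(n)],
                        direction = dirs[seq_len(n)],
                        stringsAsFactors = FALSE),
    reversal_indices = rev_idx,
    reversal_soas_ms = rev_soa,
    converged = converged,
    config = cfg), class = "staircase_result")
  res$threshold_ms <- if (converged) compute_threshold(res, cfg) else NA_real_
  res
}

#' Threshold from a staircase run
#'
#' Arithmetic mean of the SOA at the final `threshold_last_k` reversal
#' points.
#'
#' @param result a `staircase_result`.
#' @param cfg the run's [staircase_config()] (defaults to the one stored in
#'   the result).
#' @return Threshold in ms.
#' @export
compute_threshold <- function(result, cfg = result$config) {
  k <- cfg$threshold_last_k
  r <- result$reversal_soas_ms
  if (length(r) < k)
    stop(sprintf("need at least %d reversals to estimate a threshold, got %d",
                 k, length(r)))
  mean(utils::tail(r, k))
}

#' Asymptotic percent-correct level of an n-down/1-up rule
#'
#' The transformed up-down rule equilibrates where the probability of an SOA
#' decrease equals that of an increase, i.e. p^n = 1/2, giving
#' p = 0.5^(1/n): 50% for 1-down, 70.7% for 2-down, 79.4% for the 3-down
#' rule used here.
#'
#' @param n_down the consecutive-correct rule parameter (>= 1).
#' @return Proportion correct tracked at equilibrium.
#' @export
convergence_level <- function(n_down) {
  if (n_down < 1) stop("n_down must be >= 1")
  0.5^(1 / n_down)
}

#' SOA at a target proportion correct
#'
#' Numerically inverts an observer's psychometric function on a log-SOA
#' grid refined by bisection; used to locate, e.g., the 79.4%-correct SOA.
#'
#' @param obs an observer.
#' @param p target probability correct (must be attainable).
#' @param lower,upper search bracket in ms.
#' @return SOA in ms.
#' @export
soa_at_level <- function(obs, p, lower = 0.1, upper = 10000) {
  f <- function(s) p_correct(obs, s) - p
  if (f(lower) > 0 || f(upper) < 0)
    stop("target level is not bracketed by the search range")
  stats::uniroot(f, c(lower, upper), tol = 1e-8)$root
}
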