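#' Discounted life years over a fixed remaining life expectancy
#'
#' Annual-cycle discounting with the first year undiscounted and a pro-rated
#' fractional final year:
#' \deqn{\sum_{t=1}^{\lceil le \rceil} w_t (1+r)^{-(t-1)}, \quad
#'       w_t = \min(1, le - (t-1)).}
#' At `rate = 0` this reduces to `le` exactly.
#'
#' @param le remaining life expectancy in years, >= 0.
#' @param rate annual discount rate, >= 0.
#' @return Discounted life years.
#' @examples
#' discounted_life_years(8.3, 0.015)
#' discounted_life_years(2, 0.04)  # 1 + 1/1.04
#' @export
discounted_life_years <- function(le, rate) {
  if (le < 0 || rate < 0) {
    stop("discounted_life_years: 'le' and 'rate' must be non-negative",
         call. = FALSE)
  }
  if (le == 0) return(0)
  tt <- seq_len(ceiling(le))
  w <- pmin(1, le - (tt - 1))
  sum(w * (1 + rate)^-(tt - 1))
}

#' Per-pathway cost stream
#'
#' @param test_cost diagnostic test cost at time zero (euros).
#' @param first_year_cost AMI treatment cost in year 1 (euros).
#' @param subsequent_annual_cost annual AMI cost in years 2..LE (euros).
#' @return An object of class `cost_stream`.
#' @export
cost_stream <- function(test_cost = 0, first_year_cost = 0,
                        subsequent_annual_cost = 0) {
  if (test_cost < 0 || first_year_cost < 0 || subsequent_annual_cost < 0) {
    stop("cost_stream: components must be non-negative", call. = FALSE)
  }
  structure(list(test_cost = test_cost,
                 first_year_cost = first_year_cost,
                 subsequent_annual_cost = subsequent_annual_cost),
            class = "cost_stream")
}

#' Discounted lifetime cost of a pathway
#'
#' Test costs accrue at time zero, undiscounted. The first-year treatment
#' cost accrues in year 1 (undiscounted under the year-1 convention). For
#' survivors the subsequent-year annual cost accrues over years 2 to the
#' (pro-rated) end of life expectancy, discounted at `rate`. In-hospital
#' deaths accrue the test and first-year costs only, independent of `le`.
#'
#' @param stream a [cost_stream()].
#' @param le remaining life expectancy of a survivor, years.
#' @param rate annual cost discount rate.
#' @param died_in_hospital logical flag.
#' @return Discounted euros.
#' @examples
#' discounted_lifetime_cost(cost_stream(0, 12446, 2092), 2, 0.04, FALSE)
#' @export
discounted_lifetime_cost <- function(stream, le, rate, died_in_hospital = FALSE) {
  stopifnot(inherits(stream, "cost_stream"))
  if (rate < 0) stop("discounted_lifetime_cost: negative rate", call. = FALSE)
  if (died_in_hospital) {
    return(stream$test_cost + stream$first_year_cost)
  }
  if (le < 0) stop("discounted_lifetime_cost: negative life expectancy", call. = FALSE)
  subsequent <- 0
  if (le > 1 && stream$subsequent_annual_cost > 0) {
    tt <- 2:ceiling(le)
    w <- pmin(1, le - (tt - 1))
    subsequent <- sum(w * stream$subsequent_annual_cost * (1 + rate)^-(tt - 1))
  }
  stream$test_cost + stream$first_year_cost + subsequent
}

#' Expected per-patient diagnostic test cost of a strategy
#'
#' Every patient receives the stage-1 test; stage-1 negatives who are
#' retested (the `continuing_symptoms` fraction, via the supplied pathway
#' probabilities' `n_tests` field) also receive the stage-2 test. With full
#' retesting this is `stage1_cost + P(stage-1 negative) * stage2_cost`.
#'
#' @param strategy a [strategy_spec()].
#' @param paths pathway data frame from [path_probabilities()].
#' @return Expected euros per patient.
#' @export
expected_test_cost <- function(strategy, paths) {
  p2 <- sum(paths$probability * paths$p_second_test)
  strategy$stage1_test_cost + p2 * strategy$stage2_test_cost
}

#' Quality adjustment of discounted life years
#'
#' @param ly discounted life years, >= 0.
#' @param utility post-AMI utility weight in \[0, 1\].
#' @return QALYs = `ly * utility`.
#' @export
qalys <- function(ly, utility) {
  if (any(ly < 0)) stop("qalys: negative life years", call. = FALSE)
  if (any(utility < 0 | utility > 1)) stop("qalys: utility outside [0, 1]", call. = FALSE)
  ly * utility
}
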