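#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: each iteration draws
#' every non-fixed parameter once from its fitted distribution (draws shared
#' across strategies within an iteration, parameters sampled independently),
#' re-evaluates the decision tree for all strategies, and records expected
#' cost, life years and QALYs. Draws whose joint values violate a probability
#' constraint (e.g. missed-case mortality above one) are rejected and
#' redrawn, with a cap to surface misconfiguration.
#'
#' @param params an `ami_parameters` set.
#' @param n_iter number of iterations (default 1000).
#' @param seed integer seed; the PSA is a pure function of
#'   `(params, n_iter, seed, settings)`.
#' @param settings a [cea_settings()] object.
#' @param keep_draws retain the sampled parameter values per iteration
#'   (default `TRUE`).
#' @param max_rejections cap on rejected draws before aborting.
#' @return An object of class `psa_result`: list with `n_iter`, `seed`,
#'   `strategies` (names), `cost`, `ly`, `qaly` (each an `n_iter` x strategy
#'   matrix), `draws` (matrix of sampled parameter values or `NULL`) and
#'   `n_rejected`.
#' @examples
#' psa <- run_psa(ami_parameters(), n_iter = 50, seed = 1)
#' colMeans(psa$qaly)
#' @export
run_psa <- function(params, n_iter = 1000L, seed = 1L,
                    settings = cea_settings(), keep_draws = TRUE,
                    max_rejections = 10000L) {
  stopifnot(n_iter >= 1)
  validate_parameter_set(params)
  strategies <- names(ami_strategies(params))
  ns <- length(strategies)
  cost <- ly <- qaly <- matrix(NA_real_, n_iter, ns,
                               dimnames = list(NULL, strategies))
  sampled_names <- names(params)[vapply(params, function(p) p$family != "fixed", TRUE)]
  draws <- if (keep_draws) {
    matrix(NA_real_, n_iter, length(sampled_names),
           dimnames = list(NULL, sampled_names))
  }
  n_rejected <- 0L
  set.seed(seed)
  for (i in seq_len(n_iter)) {
    repeat {
      draw <- sample_parameters(params)
      res <- tryCatch(evaluate_all(draw, settings), error = function(e) e)
      if (!inherits(res, "error")) break
      n_rejected <- n_rejected + 1L
      if (n_rejected > max_rejections) {
        stop("run_psa: more than ", max_rejections, " rejected draws; ",
             "check the parameter configuration (last error: ",
             conditionMessage(res), ")", call. = FALSE)
      }
    }
    if (keep_draws) {
      draws[i, ] <- vapply(sampled_names, function(nm) draw[[nm]]$value, 0)
    }
    cost[i, ] <- vapply(res, `[[`, 0, "expected_cost")
    ly[i, ] <- vapply(res, `[[`, 0, "expected_ly")
    qaly[i, ] <- vapply(res, `[[`, 0, "expected_qaly")
  }
  structure(list(n_iter = as.integer(n_iter), seed = as.integer(seed),
                 strategies = strategies, cost = cost, ly = ly, qaly = qaly,
                 draws = draws, n_rejected = n_rejected,
                 settings = settings),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("Probabilistic sensitivity analysis:", x$n_iter, "iterations, seed",
      x$seed, if (x$n_rejected) paste0("(", x$n_rejected, " draws rejected)"),
      "\n")
  print(psa_summary(x)$summary, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value, a strategy's acceptability is the
#' fraction of PSA iterations in which it attains the strictly highest net
#' monetary benefit; exact ties split their iteration's weight equally among
#' the tied strategies, so the probabilities sum to one at every grid point.
#'
#' @param psa a [run_psa()] result.
#' @param wtp_grid willingness-to-pay grid, euros per effect unit, >= 0
#'   (default 0 to 20000 in steps of 500).
#' @param effect_measure `"qaly"` (default) or `"ly"`.
#' @return An object of class `ceac_curve`: data frame with columns `wtp` and
#'   one acceptability column per strategy.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 20000, by = 500),
                 effect_measure = c("qaly", "ly")) {
  stopifnot(inherits(psa, "psa_result"))
  effect_measure <- match.arg(effect_measure)
  if (!length(wtp_grid) || any(wtp_grid < 0)) {
    stop("ceac: willingness-to-pay grid must be non-empty and non-negative",
         call. = FALSE)
  }
  if (!nrow(psa$cost)) stop("ceac: empty PSA result", call. = FALSE)
  eff <- psa[[effect_measure]]
  out <- matrix(0, length(wtp_grid), length(psa$strategies),
                dimnames = list(NULL, psa$strategies))
  for (k in seq_along(wtp_grid)) {
    b <- nmb(psa$cost, eff, wtp_grid[k])
    best <- apply(b, 1L, function(r) {
      w <- which(r == max(r))
      tabulate(w, nbins = length(r)) / length(w)
    })
    out[k, ] <- rowMeans(best)
  }
  structure(data.frame(wtp = wtp_grid, out, check.names = FALSE),
            class = c("ceac_curve", "data.frame"),
            effect_measure = effect_measure)
}

#' Summarise a PSA
#'
#' Per-strategy means and 2.5-97.5 percentile intervals of cost, life years
#' and QALYs, plus the pairwise incremental (delta cost, delta effect) cloud
#' for scatter plotting.
#'
#' @param psa a [run_psa()] result with at least two iterations.
#' @param effect_measure `"qaly"` (default) or `"ly"`.
#' @return List with `summary` (data frame) and `incremental` (data frame
#'   with one row per iteration and ordered strategy pair).
#' @export
psa_summary <- function(psa, effect_measure = c("qaly", "ly")) {
  stopifnot(inherits(psa, "psa_result"), psa$n_iter >= 2)
  effect_measure <- match.arg(effect_measure)
  qs <- function(m) apply(m, 2L, stats::quantile, probs = c(0.025, 0.975))
  cq <- qs(psa$cost); lq <- qs(psa$ly); qq <- qs(psa$qaly)
  summary <- data.frame(
    strategy = psa$strategies,
    mean_cost = colMeans(psa$cost), cost_lo = cq[1, ], cost_hi = cq[2, ],
    mean_ly = colMeans(psa$ly), ly_lo = lq[1, ], ly_hi = lq[2, ],
    mean_qaly = colMeans(psa$qaly), qaly_lo = qq[1, ], qaly_hi = qq[2, ],
    row.names = NULL
  )
  eff <- psa[[effect_measure]]
  ns <- length(psa$strategies)
  inc <- do.call(rbind, lapply(seq_len(ns - 1L), function(i) {
    do.call(rbind, lapply(seq(i + 1L, ns), function(j) {
      data.frame(
        comparison = paste(psa$strategies[j], "vs", psa$strategies[i]),
        iteration = seq_len(psa$n_iter),
        delta_cost = psa$cost[, j] - psa$cost[, i],
        delta_effect = eff[, j] - eff[, i],
        row.names = NULL
      )
    }))
  }))
  list(summary = summary, incremental = inc)
}
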