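#' Fit the AMI diagnostic cost-effectiveness model
#'
#' The package's front door. Evaluates the three-strategy decision tree at
#' the supplied parameters and returns a model object carrying the
#' per-strategy expected discounted costs, life years and QALYs together
#' with the incremental analysis. The usual verbs apply: `print` and
#' `summary` show the base case and incremental table, `coef` extracts the
#' parameter vector, `predict` re-evaluates under modified parameters,
#' `simulate` runs the probabilistic sensitivity analysis, and `plot` draws
#' the acceptability curves or the tornado diagram.
#'
#' @param params an `ami_parameters` set (default [ami_parameters()]).
#' @param settings structural conventions, a [cea_settings()] object.
#' @param effect_measure primary effect scale for the incremental table,
#'   `"qaly"` (default) or `"ly"`.
#' @return An object of class `cea_model` with components `params`,
#'   `settings`, `results` (list of `strategy_result`), `cea` (a
#'   `cea_table`) and `effect_measure`.
#' @examples
#' m <- cea_model()
#' summary(m)
#' coef(m)[c("prevalence", "utility_post_ami")]
#' @export
cea_model <- function(params = ami_parameters(), settings = cea_settings(),
                      effect_measure = c("qaly", "ly")) {
  effect_measure <- match.arg(effect_measure)
  validate_parameter_set(params)
  results <- evaluate_all(params, settings)
  structure(list(params = params, settings = settings, results = results,
                 cea = incremental_analysis(results, effect_measure),
                 effect_measure = effect_measure),
            class = "cea_model")
}

#' @export
print.cea_model <- function(x, ...) {
  cat("AMI diagnostic-strategy cost-effectiveness model\n")
  cat("Strategies evaluated at base-case parameters:\n")
  for (r in x$results) print(r)
  invisible(x)
}

#' @rdname cea_model
#' @param object,x a `cea_model`.
#' @param ... passed through (unused).
#' @export
summary.cea_model <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$cea)
  invisible(object$cea)
}

#' @rdname cea_model
#' @export
coef.cea_model <- function(object, ...) {
  vapply(object$params, `[[`, 0, "value")
}

#' @rdname cea_model
#' @param params replacement or partial update of the parameter set: either
#'   an `ami_parameters` object or a named list of point values.
#' @export
predict.cea_model <- function(object, params = NULL, ...) {
  ps <- object$params
  if (inherits(params, "ami_parameters")) {
    ps <- params
  } else if (!is.null(params)) {
    ps <- do.call(set_param_values, c(list(ps), params))
  }
  cea_model(ps, object$settings, object$effect_measure)
}

#' @rdname cea_model
#' @param nsim number of PSA iterations.
#' @param seed integer seed for the PSA.
#' @export
simulate.cea_model <- function(object, nsim = 1000L, seed = 1L, ...) {
  run_psa(object$params, n_iter = nsim, seed = seed,
          settings = object$settings)
}

#' @rdname cea_model
#' @param type `"ceac"` (acceptability curves, computed from a fresh PSA
#'   unless one is supplied via `psa`) or `"tornado"`.
#' @param psa optional precomputed [run_psa()] result for `type = "ceac"`.
#' @param n_iter,top_n PSA iterations / tornado rows when computed here.
#' @export
plot.cea_model <- function(x, type = c("ceac", "tornado"), psa = NULL,
                           n_iter = 1000L, seed = 1L, top_n = 10L, ...) {
  type <- match.arg(type)
  if (type == "ceac") {
    if (is.null(psa)) psa <- simulate(x, nsim = n_iter, seed = seed)
    curve <- ceac(psa)
    strategies <- setdiff(names(curve), "wtp")
    graphics::matplot(curve$wtp, as.matrix(curve[strategies]), type = "l",
                      lty = 1, lwd = 2, col = seq_along(strategies),
                      xlab = "Willingness to pay (EUR per QALY)",
                      ylab = "Probability cost-effective", ylim = c(0, 1), ...)
    graphics::legend("right", legend = strategies, lty = 1, lwd = 2,
                     col = seq_along(strategies), bty = "n")
  } else {
    rows <- tornado_rank(run_owsa(x$params, settings = x$settings), top_n)
    base_icer <- x$cea$comparisons$icer_qaly[
      x$cea$comparisons$comparison == "hsTnT vs cTnT"]
    ord <- rev(seq_len(nrow(rows)))
    graphics::plot(NA, xlim = range(c(rows$icer_at_low, rows$icer_at_high)),
                   ylim = c(0.5, nrow(rows) + 0.5), yaxt = "n",
                   xlab = "ICER (EUR per QALY)", ylab = "", ...)
    graphics::axis(2, at = seq_len(nrow(rows)), labels = rows$parameter[ord],
                   las = 1, cex.axis = 0.7)
    for (i in seq_len(nrow(rows))) {
      r <- rows[ord[i], ]
      graphics::segments(r$icer_at_low, i, r$icer_at_high, i, lwd = 8,
                         col = "steelblue")
    }
    graphics::abline(v = base_icer, lty = 2)
  }
  invisible(x)
}
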