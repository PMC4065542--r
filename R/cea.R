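#' Incremental cost-effectiveness ratio
#'
#' `delta_cost / delta_effect` on unrounded inputs. A zero effect difference
#' has no defined ICER and returns `NaN`.
#'
#' @param delta_cost cost difference in euros.
#' @param delta_effect effect difference (life years or QALYs).
#' @return Euros per effect unit, or `NaN` when `delta_effect == 0`.
#' @export
icer <- function(delta_cost, delta_effect) {
  ifelse(delta_effect == 0, NaN, delta_cost / delta_effect)
}

#' Net monetary benefit
#'
#' `wtp * effect - cost`. At willingness-to-pay `wtp`, a strategy with higher
#' NMB is preferred; for two strategies this reproduces the ICER decision
#' rule (adopt the costlier, more effective strategy iff `wtp` exceeds its
#' ICER).
#'
#' @param cost expected cost, euros.
#' @param effect expected effect (LY or QALY).
#' @param wtp willingness to pay, euros per effect unit, >= 0.
#' @return Euros.
#' @export
nmb <- function(cost, effect, wtp) {
  if (any(wtp < 0)) stop("nmb: willingness to pay must be non-negative", call. = FALSE)
  wtp * effect - cost
}

#' Incremental cost-effectiveness analysis
#'
#' Orders strategies by ascending expected cost, flags strong dominance
#' (costlier and no more effective than another strategy) and extended
#' dominance (bypassed on the cost-effectiveness frontier because a costlier
#' strategy has a lower incremental ratio), and reports pairwise incremental
#' rows: each non-reference strategy against the reference (lowest-cost)
#' strategy, plus each successive pair of non-reference strategies.
#'
#' @param results list of `strategy_result` objects (at least two, unique
#'   names), e.g. from [evaluate_all()].
#' @param effect_measure `"qaly"` (default) or `"ly"`.
#' @return An object of class `cea_table`: list with `strategies` (per-
#'   strategy costs/effects, dominance flags, frontier ICERs) and
#'   `comparisons` (pairwise increments and ICERs), plus `effect_measure`.
#' @examples
#' incremental_analysis(evaluate_all(ami_parameters()), "qaly")
#' @export
incremental_analysis <- function(results, effect_measure = c("qaly", "ly")) {
  effect_measure <- match.arg(effect_measure)
  if (length(results) < 2) {
    stop("incremental_analysis: need at least two strategies", call. = FALSE)
  }
  nm <- vapply(results, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("incremental_analysis: duplicate strategy names", call. = FALSE)
  }
  eff_field <- if (effect_measure == "qaly") "expected_qaly" else "expected_ly"
  df <- data.frame(
    strategy = nm,
    cost = vapply(results, `[[`, 0, "expected_cost"),
    ly = vapply(results, `[[`, 0, "expected_ly"),
    qaly = vapply(results, `[[`, 0, "expected_qaly"),
    row.names = NULL
  )
  df$effect <- df[[effect_measure]]
  df <- df[order(df$cost, df$effect, df$strategy), ]
  rownames(df) <- NULL

  # strong dominance: some other strategy costs no more and yields at least
  # as much effect, with at least one strict inequality
  n <- nrow(df)
  df$dominated <- vapply(seq_len(n), function(i) {
    any(df$cost <= df$cost[i] & df$effect >= df$effect[i] &
          (df$cost < df$cost[i] | df$effect > df$effect[i]))
  }, TRUE)

  # extended dominance on the remaining candidates: enforce non-decreasing
  # incremental ratios along the cost-ordered frontier
  df$ext_dominated <- FALSE
  repeat {
    idx <- which(!df$dominated & !df$ext_dominated)
    if (length(idx) < 3) break
    ic <- diff(df$cost[idx]) / diff(df$effect[idx])
    bad <- which(diff(ic) < 0)
    if (!length(bad)) break
    df$ext_dominated[idx[bad[1] + 1L]] <- TRUE
  }
  frontier <- which(!df$dominated & !df$ext_dominated)
  df$frontier_icer <- NA_real_
  if (length(frontier) > 1) {
    df$frontier_icer[frontier[-1]] <-
      diff(df$cost[frontier]) / diff(df$effect[frontier])
  }

  ref <- df$strategy[1]
  non_ref <- df$strategy[-1]
  pairs <- lapply(non_ref, function(s) c(s, ref))
  if (length(non_ref) > 1) {
    pairs <- c(pairs, lapply(seq_len(length(non_ref) - 1L),
                             function(i) c(non_ref[i + 1L], non_ref[i])))
  }
  comparisons <- do.call(rbind, lapply(pairs, function(pp) {
    a <- df[df$strategy == pp[1], ]; b <- df[df$strategy == pp[2], ]
    dc <- a$cost - b$cost
    dly <- a$ly - b$ly
    dq <- a$qaly - b$qaly
    de <- a$effect - b$effect
    data.frame(comparison = paste(pp[1], "vs", pp[2]),
               delta_cost = dc, delta_ly = dly, delta_qaly = dq,
               icer_ly = icer(dc, dly), icer_qaly = icer(dc, dq),
               icer = icer(dc, de),
               dominated = dc > 0 & de <= 0,
               row.names = NULL)
  }))

  structure(list(strategies = df, comparisons = comparisons,
                 reference = ref, effect_measure = effect_measure),
            class = "cea_table")
}

#' @export
print.cea_table <- function(x, ...) {
  cat("Incremental cost-effectiveness analysis (effect:",
      toupper(x$effect_measure), ")\n\n")
  s <- x$strategies
  s$status <- ifelse(s$dominated, "dominated",
                     ifelse(s$ext_dominated, "ext. dominated",
                            ifelse(s$strategy == x$reference,
                                   "Reference strategy",
                                   sprintf("ICER %.0f", s$frontier_icer))))
  print(s[, c("strategy", "cost", "ly", "qaly", "status")],
        row.names = FALSE, digits = 6)
  cat("\nPairwise increments:\n")
  print(x$comparisons[, c("comparison", "delta_cost", "delta_ly", "delta_qaly",
                          "icer_ly", "icer_qaly")],
        row.names = FALSE, digits = 5)
  invisible(x)
}

#' Serialize a CEA table to CSV
#'
#' Writes the per-strategy block (discounted cost, LY, QALY, dominance
#' status) followed by the pairwise incremental block (increments and ICERs
#' per LYG and per QALY) into one CSV with a `section` column.
#'
#' @param x a `cea_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cea_csv <- function(x, path) {
  stopifnot(inherits(x, "cea_table"))
  s <- x$strategies
  a <- data.frame(section = "strategy", name = s$strategy,
                  delta_cost = NA_real_, delta_ly = NA_real_,
                  delta_qaly = NA_real_, icer_ly = NA_real_,
                  icer_qaly = NA_real_, cost = s$cost, ly = s$ly, qaly = s$qaly,
                  status = ifelse(s$strategy == x$reference,
                                  "Reference strategy",
                                  ifelse(s$dominated, "dominated",
                                         ifelse(s$ext_dominated, "ext-dominated", ""))))
  cc <- x$comparisons
  b <- data.frame(section = "increment", name = cc$comparison,
                  delta_cost = cc$delta_cost, delta_ly = cc$delta_ly,
                  delta_qaly = cc$delta_qaly, icer_ly = cc$icer_ly,
                  icer_qaly = cc$icer_qaly,
                  cost = NA_real_, ly = NA_real_, qaly = NA_real_,
                  status = ifelse(cc$dominated, "dominated", ""))
  utils::write.csv(rbind(a, b), path, row.names = FALSE)
  invisible(path)
}
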