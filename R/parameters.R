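#' @title Model parameters
#' @name parameters
#' @description
#' The model's parameter inventory: unit test costs, AMI treatment costs,
#' utility, discount rates, prevalence, mortalities, life expectancy and the
#' two-stage diagnostic accuracies of the three strategies, each carried as a
#' point estimate with a (min, max) range and a sampling-distribution family.
NULL

# Canonical inventory: name, units, family. Order fixed; load/validation
# require exactly these names.
.param_inventory <- function() {
  inv <- list(
    cost_ctnt_test            = c("euros",       "beta_pert"),
    cost_hstnt_test           = c("euros",       "beta_pert"),
    cost_hfabp_marginal       = c("euros",       "beta_pert"),
    cost_ami_first_year       = c("euros",       "gamma"),
    cost_ami_subsequent_year  = c("euros",       "gamma"),
    utility_post_ami          = c("probability", "beta"),
    discount_rate_cost        = c("rate",        "fixed"),
    discount_rate_effect      = c("rate",        "fixed"),
    prevalence                = c("probability", "beta_pert"),
    mortality_ratio_missed    = c("ratio",       "beta_pert"),
    life_expectancy           = c("years",       "beta_pert"),
    mortality_early_ppci      = c("probability", "beta_pert"),
    mortality_delayed_ppci    = c("probability", "beta_pert"),
    mortality_procedural      = c("probability", "beta_pert"),
    se6_ctnt   = c("probability", "beta"),
    se12_ctnt  = c("probability", "beta"),
    sp6_ctnt   = c("probability", "beta"),
    sp12_ctnt  = c("probability", "beta"),
    se6_hstnt  = c("probability", "beta"),
    se12_hstnt = c("probability", "beta"),
    sp6_hstnt  = c("probability", "beta"),
    sp12_hstnt = c("probability", "beta"),
    se6_combo  = c("probability", "beta"),
    se12_combo = c("probability", "beta"),
    sp6_combo  = c("probability", "beta"),
    sp12_combo = c("probability", "beta")
  )
  data.frame(name = names(inv),
             units = vapply(inv, `[`, "", 1L),
             family = vapply(inv, `[`, "", 2L),
             row.names = NULL)
}

.required_param_names <- function() .param_inventory()$name

#' Construct a single model parameter
#'
#' @param name identifier (one of the canonical inventory names for use in a
#'   parameter set; free-form for standalone use).
#' @param value point estimate on the parameter's natural scale.
#' @param low,high range bounds on the natural scale; for `family = "fixed"`
#'   they default to `value`.
#' @param family sampling-distribution family: `"fixed"`, `"beta"`,
#'   `"beta_pert"` or `"gamma"`.
#' @param units one of `"euros"`, `"probability"`, `"years"`, `"ratio"`,
#'   `"rate"`; drives domain validation.
#' @return An object of class `ami_parameter`.
#' @export
ami_parameter <- function(name, value, low = value, high = value,
                          family = c("fixed", "beta", "beta_pert", "gamma"),
                          units = c("euros", "probability", "years", "ratio", "rate")) {
  family <- match.arg(family)
  units <- match.arg(units)
  p <- structure(list(name = as.character(name), value = as.numeric(value),
                      low = as.numeric(low), high = as.numeric(high),
                      family = family, units = units),
                 class = "ami_parameter")
  validate_parameter(p)
  p
}

validate_parameter <- function(p) {
  with(p, {
    if (!is.finite(value) || !is.finite(low) || !is.finite(high)) {
      stop("parameter '", name, "': non-finite value or range", call. = FALSE)
    }
    if (low > high) {
      stop("parameter '", name, "': low > high", call. = FALSE)
    }
    if (family != "fixed" && !(low < high)) {
      stop("parameter '", name, "': degenerate range requires family 'fixed'",
           call. = FALSE)
    }
    if (value < low || value > high) {
      stop("parameter '", name, "': value outside [low, high]", call. = FALSE)
    }
    switch(units,
      probability = if (low < 0 || high > 1) {
        stop("parameter '", name, "': probability outside [0, 1]", call. = FALSE)
      },
      euros = if (low < 0) {
        stop("parameter '", name, "': negative cost", call. = FALSE)
      },
      years = if (value <= 0 || low < 0) {
        stop("parameter '", name, "': life expectancy must be positive", call. = FALSE)
      },
      ratio = if (value <= 0 || low < 0) {
        stop("parameter '", name, "': ratio must be positive", call. = FALSE)
      },
      rate = if (low < 0) {
        stop("parameter '", name, "': negative rate", call. = FALSE)
      }
    )
  })
  invisible(p)
}

#' Default parameter set
#'
#' Returns the complete default parameter inventory: costs in 2012 euros,
#' event probabilities, two-stage diagnostic accuracies for the three
#' strategies, post-AMI utility and life expectancy, and annual discount
#' rates of 4% for costs and 1.5% for effects (the Dutch pharmacoeconomic
#' convention).
#'
#' Two values deserve note. The high-sensitive troponin T unit cost defaults
#' to EUR 21.50 (a micro-costed estimate consistent with the EUR 4.39
#' per-test increment over the conventional assay); its sampling range is
#' +/- 25% of that value, the convention used for all cost parameters. The
#' marginal cost of adding the H-FABP assay to the combination strategy is
#' not externally sourced; it is a placeholder of EUR 10.00 (range +/- 25%)
#' and is flagged as such in the shipped configuration file.
#'
#' @return An object of class `ami_parameters`: a named list of
#'   [ami_parameter()] objects covering the full inventory.
#' @examples
#' p <- ami_parameters()
#' p$prevalence$value            # 0.30
#' param_value(p, "se6_hstnt")   # 0.94
#' @seealso [load_parameters()], [sample_parameters()]
#' @export
ami_parameters <- function() {
  rows <- list(
    #                         value     low      high
    cost_ctnt_test           = c(17.11,  12.8,    21.4),
    cost_hstnt_test          = c(21.50,  16.125,  26.875),
    cost_hfabp_marginal      = c(10.00,   7.50,   12.50),
    cost_ami_first_year      = c(12446,  9334,    15557),
    cost_ami_subsequent_year = c(2092,   1569,    2615),
    utility_post_ami         = c(0.725,  0.544,   0.906),
    discount_rate_cost       = c(0.04,   0.04,    0.04),
    discount_rate_effect     = c(0.015,  0.015,   0.015),
    prevalence               = c(0.30,   0.23,    0.38),
    mortality_ratio_missed   = c(1.9,    1.43,    2.38),
    life_expectancy          = c(8.3,    6.23,    10.38),
    mortality_early_ppci     = c(0.062,  0.0468,  0.0780),
    mortality_delayed_ppci   = c(0.103,  0.077,   0.1288),
    mortality_procedural     = c(0.0072, 0.0054,  0.009),
    se6_ctnt   = c(0.44, 0.32, 0.56),
    se12_ctnt  = c(0.93, 0.85, 0.97),
    sp6_ctnt   = c(0.92, 0.88, 0.95),
    sp12_ctnt  = c(0.85, 0.76, 0.91),
    se6_hstnt  = c(0.94, 0.87, 0.98),
    se12_hstnt = c(0.95, 0.91, 0.98),
    sp6_hstnt  = c(0.52, 0.39, 0.65),
    sp12_hstnt = c(0.51, 0.40, 0.62),
    se6_combo  = c(0.97, 0.90, 0.99),
    se12_combo = c(0.97, 0.93, 0.99),
    sp6_combo  = c(0.39, 0.27, 0.51),
    sp12_combo = c(0.38, 0.27, 0.49)
  )
  inv <- .param_inventory()
  ps <- lapply(inv$name, function(nm) {
    v <- rows[[nm]]
    ami_parameter(nm, v[1], v[2], v[3],
                  family = inv$family[inv$name == nm],
                  units = inv$units[inv$name == nm])
  })
  names(ps) <- inv$name
  structure(ps, class = "ami_parameters")
}

#' @export
print.ami_parameters <- function(x, ...) {
  cat("AMI diagnostic model parameter set (", length(x), " parameters)\n", sep = "")
  df <- as.data.frame(x)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.ami_parameters <- function(x, ...) {
  data.frame(
    name = vapply(x, `[[`, "", "name"),
    value = vapply(x, `[[`, 0, "value"),
    low = vapply(x, `[[`, 0, "low"),
    high = vapply(x, `[[`, 0, "high"),
    family = vapply(x, `[[`, "", "family"),
    units = vapply(x, `[[`, "", "units"),
    row.names = NULL
  )
}

#' Extract a parameter's point value
#'
#' @param params an `ami_parameters` set.
#' @param name parameter name.
#' @return Numeric point estimate.
#' @export
param_value <- function(params, name) {
  if (!name %in% names(params)) {
    stop("unknown parameter '", name, "'", call. = FALSE)
  }
  params[[name]]$value
}

#' Return a parameter set with selected point values replaced
#'
#' Replaces point estimates only; ranges and families are kept, and range
#' bounds are widened to contain the new value if needed (so sensitivity
#' analyses restore cleanly).
#'
#' @param params an `ami_parameters` set.
#' @param ... `name = value` pairs.
#' @return Modified `ami_parameters` set.
#' @export
set_param_values <- function(params, ...) {
  upd <- list(...)
  for (nm in names(upd)) {
    if (!nm %in% names(params)) stop("unknown parameter '", nm, "'", call. = FALSE)
    p <- params[[nm]]
    p$value <- as.numeric(upd[[nm]])
    p$low <- min(p$low, p$value)
    p$high <- max(p$high, p$value)
    validate_parameter(p)
    params[[nm]] <- p
  }
  params
}

validate_parameter_set <- function(params) {
  req <- .required_param_names()
  nms <- names(params)
  missing <- setdiff(req, nms)
  if (length(missing)) {
    stop("parameter set incomplete; missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(nms, req)
  if (length(unknown)) {
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(nms)) stop("duplicate parameter names", call. = FALSE)
  for (p in params) validate_parameter(p)
  invisible(params)
}

#' Load a parameter set from a YAML or JSON configuration file
#'
#' The configuration is a mapping `parameters: {name: {value, low, high,
#' family, units}}`. All canonical parameter names must be present exactly
#' once; unknown names are rejected; every domain invariant (probabilities in
#' \[0,1\], non-negative costs, `low <= value <= high`) is checked. The file
#' shipped at `system.file("extdata", "params_table1.yaml", package =
#' "amicea")` reproduces the default set.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `ami_parameters` set.
#' @seealso [write_parameters()]
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$parameters)) {
    stop("config must contain a top-level 'parameters' mapping", call. = FALSE)
  }
  entries <- raw$parameters
  inv <- .param_inventory()
  req <- inv$name
  missing <- setdiff(req, names(entries))
  if (length(missing)) {
    stop("config missing required parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(entries), req)
  if (length(unknown)) {
    stop("config contains unknown parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ps <- lapply(req, function(nm) {
    e <- entries[[nm]]
    if (is.null(e$value)) {
      stop("config entry '", nm, "' lacks a 'value'", call. = FALSE)
    }
    fam <- if (is.null(e$family)) inv$family[inv$name == nm] else e$family
    un <- if (is.null(e$units)) inv$units[inv$name == nm] else e$units
    low <- if (is.null(e$low)) e$value else e$low
    high <- if (is.null(e$high)) e$value else e$high
    ami_parameter(nm, e$value, low, high, family = fam, units = un)
  })
  names(ps) <- req
  structure(validate_parameter_set(ps), class = "ami_parameters")
}

#' Write a parameter set to a YAML configuration file
#'
#' Round-trips with [load_parameters()].
#'
#' @param params an `ami_parameters` set.
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  entries <- lapply(params, function(p) {
    list(value = p$value, low = p$low, high = p$high,
         family = p$family, units = p$units)
  })
  yaml::write_yaml(list(parameters = entries), path)
  invisible(path)
}

#' Draw from a parameter's sampling distribution
#'
#' `fixed` parameters return the point value; `beta_pert` draws a Beta-PERT
#' variate on `[low, high]` with mode at the point value; `beta` draws from
#' the method-of-moments Beta fit (mean = point value, range read as a 95%
#' interval); `gamma` likewise from the moment-matched Gamma. Draws use R's
#' global random number generator, so `set.seed()` gives reproducibility.
#'
#' @param param an [ami_parameter()].
#' @param n number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_parameter <- function(param, n = 1L) {
  validate_parameter(param)
  switch(param$family,
    fixed = rep(param$value, n),
    beta_pert = {
      sh <- pert_shape(param$low, param$value, param$high)
      param$low + (param$high - param$low) * stats::rbeta(n, sh[["alpha"]], sh[["beta"]])
    },
    beta = {
      sh <- beta_from_mean_ci(param$value, param$low, param$high)
      stats::rbeta(n, sh[["alpha"]], sh[["beta"]])
    },
    gamma = {
      sh <- gamma_from_mean_range(param$value, param$low, param$high)
      stats::rgamma(n, shape = sh[["shape"]], scale = sh[["scale"]])
    },
    stop("unknown distribution family '", param$family, "'", call. = FALSE)
  )
}

#' Draw one joint parameter-set realisation
#'
#' Samples every non-fixed parameter once (independently) and returns a
#' parameter set whose point values are the draws. Ranges are widened where a
#' draw falls outside the printed range (possible for the unbounded Gamma
#' tails), keeping the set valid.
#'
#' @param params an `ami_parameters` set.
#' @return An `ami_parameters` set of sampled values.
#' @export
sample_parameters <- function(params) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (p$family == "fixed") next
    p$value <- sample_parameter(p, 1L)
    p$low <- min(p$low, p$value)
    p$high <- max(p$high, p$value)
    params[[nm]] <- p
  }
  params
}
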