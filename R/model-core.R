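#' Model parameters for the mass-density heaviness model
#'
#' Perceived heaviness is modelled as a weighted average of two Stevens
#' power-law estimates, one derived from the lifted object's mass and one
#' from its density:
#' \deqn{\hat h(m, \rho) = (1 - w_\rho)\, a m^x + w_\rho\, b \rho^y}
#' where \eqn{w_\rho} is the condition-specific weight of the density
#' estimate (the mass estimate implicitly receives \eqn{1 - w_\rho}).
#'
#' @param a,x Scale and exponent of the mass power law (both > 0).
#' @param b,y Scale and exponent of the density power law (both > 0).
#' @param weights Named numeric vector of density weights in \[0, 1\],
#'   one entry per experimental condition (e.g.
#'   `c(no_vision = 0, full = 0.29)`).
#'
#' @return An object of class `swi_params`.
#' @examples
#' exp1_aggregate_params()
#' model_params(a = 0.006, x = 1.06, b = 1.27, y = 0.537,
#'              weights = c(full = 0.29))
#' @export
model_params <- function(a, x, b, y, weights = numeric(0)) {
  for (nm in c("a", "x", "b", "y")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0) {
      stop("parameter '", nm, "' must be a single strictly positive number",
           call. = FALSE)
    }
  }
  weights <- unlist(weights)
  if (length(weights)) {
    if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
      stop("'weights' must be a named vector of condition weights",
           call. = FALSE)
    }
    if (any(!is.finite(weights)) || any(weights < 0) || any(weights > 1)) {
      stop("all density weights must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(a = a, x = x, b = b, y = y, weights = weights),
    class = "swi_params"
  )
}

#' @export
print.swi_params <- function(x, ...) {
  cat("<swi_params> mass: a =", format(x$a), ", x =", format(x$x),
      "| density: b =", format(x$b), ", y =", format(x$y), "\n")
  if (length(x$weights)) {
    cat("  density weights:",
        paste(names(x$weights), "=", format(x$weights), collapse = ", "),
        "\n")
  } else {
    cat("  density weights: none\n")
  }
  invisible(x)
}

#' Aggregate-fit parameter sets from the two magnitude-estimation experiments
#'
#' Convenience constructors holding the published aggregate fits: the
#' visual experiment (visibility manipulated; conditions `no_vision`,
#' `poor`, `medium`, `full`) and the haptic experiment (grip type
#' manipulated; conditions `string`, `precision`, `enclosure`). These are
#' the reference points around which the synthetic population is sampled.
#'
#' @return An `swi_params` object.
#' @export
exp1_aggregate_params <- function() {
  model_params(a = 0.006, x = 1.06, b = 1.27, y = 0.537,
               weights = c(no_vision = 0, poor = 0.14,
                           medium = 0.21, full = 0.29))
}

#' @rdname exp1_aggregate_params
#' @export
exp2_aggregate_params <- function() {
  model_params(a = 0.0014, x = 1.37, b = 1.08, y = 0.74,
               weights = c(string = 0, precision = 0.31, enclosure = 0.42))
}

#' Power-law heaviness estimates from mass and from density
#'
#' The mass estimate is \eqn{\hat h_m(m) = a m^x}; the density estimate is
#' \eqn{\hat h_\rho(\rho) = b \rho^y}. Outputs are dimensionless magnitudes
#' on the observer's free-modulus scale.
#'
#' @param m Mass in grams (> 0); vectorized.
#' @param rho Density in g/cm^3 (> 0); vectorized.
#' @param params An [model_params()] object.
#' @return Numeric vector of heaviness magnitudes.
#' @examples
#' mass_estimate(230, exp1_aggregate_params())   # about 1.91
#' density_estimate(0.39, exp1_aggregate_params())
#' @export
mass_estimate <- function(m, params) {
  stopifnot(inherits(params, "swi_params"))
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("mass must be strictly positive", call. = FALSE)
  }
  params$a * m^params$x
}

#' @rdname mass_estimate
#' @export
density_estimate <- function(rho, params) {
  stopifnot(inherits(params, "swi_params"))
  if (any(!is.finite(rho)) || any(rho <= 0)) {
    stop("density must be strictly positive", call. = FALSE)
  }
  params$b * rho^params$y
}

#' Combined heaviness percept
#'
#' Weighted average of the mass and density estimates with the
#' condition-specific density weight:
#' \eqn{\hat h = (1 - w_\rho) a m^x + w_\rho b \rho^y}.
#'
#' @inheritParams mass_estimate
#' @param condition Condition label; must be present in `params$weights`.
#' @return Numeric vector of combined heaviness magnitudes.
#' @examples
#' p <- exp2_aggregate_params()
#' combined_heaviness(200, 200 / 596, p, "precision")
#' @export
combined_heaviness <- function(m, rho, params, condition) {
  stopifnot(inherits(params, "swi_params"))
  w <- params$weights[condition]
  if (any(is.na(w))) {
    stop("condition(s) ",
         paste(unique(condition[is.na(w)]), collapse = ", "),
         " not found in params$weights", call. = FALSE)
  }
  w <- unname(w)
  (1 - w) * mass_estimate(m, params) + w * density_estimate(rho, params)
}

#' Cue reliabilities with optional error correlation
#'
#' A cue's reliability is the inverse variance of its estimate,
#' \eqn{r_i = \sigma_i^{-2}}. When the two estimates' noises are
#' correlated with coefficient \eqn{\varrho}, the optimal weight of cue 1
#' and the reliability of the integrated percept change accordingly.
#'
#' @param r1,r2 Reliabilities (> 0).
#' @param corr Error correlation \eqn{\varrho} in \[0, 1). Defaults to 0:
#'   the correlation is carried for completeness but never estimated from
#'   data in this package.
#' @return `cue_reliability()` returns an object of class
#'   `swi_reliability`.
#' @export
cue_reliability <- function(r1, r2, corr = 0) {
  if (!is.finite(r1) || !is.finite(r2) || r1 <= 0 || r2 <= 0) {
    stop("reliabilities must be strictly positive", call. = FALSE)
  }
  if (!is.finite(corr) || corr < 0 || corr >= 1) {
    stop("error correlation must lie in [0, 1)", call. = FALSE)
  }
  structure(list(r1 = r1, r2 = r2, corr = corr), class = "swi_reliability")
}

#' Optimal cue weights and integrated reliability
#'
#' `weight_uncorrelated()` is the classic relative-reliability weight
#' \eqn{w_1 = r_1 / (r_1 + r_2)}. `weight_correlated()` generalizes it to
#' correlated noise,
#' \deqn{w_1 = \frac{r_1 - \varrho\sqrt{r_1 r_2}}
#'                  {r_1 + r_2 - 2\varrho\sqrt{r_1 r_2}},}
#' which may legitimately leave \[0, 1\]; such values are returned as-is
#' with attribute `status = "outside_unit_interval"` so that pipelines can
#' reject them. `combined_reliability()` returns the reliability of the
#' integrated percept,
#' \eqn{r_{int} = (r_1 + r_2 - 2\varrho\sqrt{r_1 r_2}) / (1 - \varrho^2)},
#' which reduces to \eqn{r_1 + r_2} at \eqn{\varrho = 0}.
#'
#' @param r1,r2 Reliabilities (> 0).
#' @param cr An object from [cue_reliability()].
#' @return A single numeric weight or reliability.
#' @examples
#' weight_uncorrelated(3, 1)                         # 0.75
#' weight_correlated(cue_reliability(4, 1, 0.5))     # 1
#' combined_reliability(cue_reliability(4, 1, 0.5))  # 4
#' @export
weight_uncorrelated <- function(r1, r2) {
  if (!is.finite(r1) || !is.finite(r2) || r1 <= 0 || r2 <= 0) {
    stop("reliabilities must be strictly positive", call. = FALSE)
  }
  r1 / (r1 + r2)
}

#' @rdname weight_uncorrelated
#' @export
weight_correlated <- function(cr) {
  stopifnot(inherits(cr, "swi_reliability"))
  cross <- cr$corr * sqrt(cr$r1 * cr$r2)
  denom <- cr$r1 + cr$r2 - 2 * cross
  if (abs(denom) < .Machine$double.eps * (cr$r1 + cr$r2)) {
    stop("degenerate denominator in correlated-weight formula",
         call. = FALSE)
  }
  w <- (cr$r1 - cross) / denom
  status <- if (w < 0 || w > 1) "outside_unit_interval" else "ok"
  structure(w, status = status)
}

#' @rdname weight_uncorrelated
#' @export
combined_reliability <- function(cr) {
  stopifnot(inherits(cr, "swi_reliability"))
  (cr$r1 + cr$r2 - 2 * cr$corr * sqrt(cr$r1 * cr$r2)) / (1 - cr$corr^2)
}

#' Serialize and restore model parameters as JSON
#'
#' @param params An `swi_params` object.
#' @param path File path; for `params_to_json()` with `path = NULL` the
#'   JSON string is returned instead of written.
#' @return `params_to_json()` a JSON string (invisibly, if written);
#'   `params_from_json()` an `swi_params` object.
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "swi_params"))
  js <- jsonlite::toJSON(
    list(a = params$a, x = params$x, b = params$b, y = params$y,
         weights = as.list(params$weights)),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname params_to_json
#' @export
params_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  model_params(a = obj$a, x = obj$x, b = obj$b, y = obj$y,
               weights = unlist(obj$weights))
}
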