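#' Specification of a model fit
#'
#' Declares which of the model parameters (`a`, `x`, `b`, `y` and one
#' density weight `w_<condition>` per condition) are free and which are
#' fixed, together with the optimizer budget and seed. Every condition
#' present in the data must have its weight either free or fixed (a
#' typical fixture is fixing the weight of a string-lifting / blindfolded
#' condition to 0, since no density estimate can be formed there).
#'
#' @param conditions Character vector of condition labels in the data.
#' @param fixed Named list of fixed assignments, e.g.
#'   `list(w_no_vision = 0)`; may also fix `a`, `x`, `b`, `y`.
#' @param free Character vector of free parameter names; defaults to all
#'   of `a`, `x`, `b`, `y` plus every condition weight not in `fixed`.
#' @param iterations Total number of perturbation iterations (proposal
#'   rounds) across all restarts; the reference procedure uses 1000.
#' @param restarts Number of random restarts folded into the iteration
#'   budget.
#' @param seed Integer seed; fitting is fully reproducible from it.
#' @return An object of class `swi_fit_spec`.
#' @export
fit_spec <- function(conditions, fixed = list(), free = NULL,
                     iterations = 1000, restarts = 10, seed = 1L) {
  wnames <- paste0("w_", conditions)
  all_params <- c("a", "x", "b", "y", wnames)
  fixed <- unlist(fixed)
  if (length(fixed) && !all(names(fixed) %in% all_params)) {
    stop("unknown fixed parameter(s): ",
         paste(setdiff(names(fixed), all_params), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(free)) free <- setdiff(all_params, names(fixed))
  if (!all(free %in% all_params)) {
    stop("unknown free parameter(s): ",
         paste(setdiff(free, all_params), collapse = ", "), call. = FALSE)
  }
  uncovered <- setdiff(wnames, c(free, names(fixed)))
  if (length(uncovered)) {
    stop("condition weight(s) neither free nor fixed: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  structure(
    list(conditions = conditions, free = free, fixed = fixed,
         iterations = as.integer(iterations),
         restarts = as.integer(restarts), seed = as.integer(seed)),
    class = "swi_fit_spec"
  )
}

#' Squared-error sum of model predictions against observed scores
#'
#' @param params An [model_params()] object whose weights cover every
#'   condition in `data`.
#' @param data A tibble of aggregated scores with columns `condition`,
#'   `mass_g`, `density_g_cm3`, `score`.
#' @return Sum of squared (predicted - observed) over all cells.
#' @export
model_sse <- function(params, data) {
  pred <- combined_heaviness(data$mass_g, data$density_g_cm3, params,
                             data$condition)
  sum((pred - data$score)^2)
}

#' Fit the mass-density model by multi-start random perturbation
#'
#' Minimizes the squared error of model-predicted heaviness against
#' observed condition-mean scores. Each iteration proposes perturbed
#' copies of the current best parameter set -- perturbing one, two and
#' all free parameters -- and keeps a proposal only if it lowers the SSE
#' (greedy acceptance). Scale parameters (`a`, `b`) and exponents (`x`,
#' `y`) are perturbed multiplicatively on the log scale; weights are
#' perturbed additively and clipped to \[0, 1\]. The perturbation scale
#' decays geometrically from 0.5 to 0.01 over each restart's iterations.
#' Random restarts are folded into the total iteration budget, and the
#' overall best point is polished with a derivative-free simplex search.
#'
#' If `data` contains a `participant` column with several participants,
#' cells are first averaged over participants (arithmetic mean of
#' scores), matching an aggregate fit; pass per-participant slices to
#' obtain individual fits.
#'
#' When no free weight exists and all fixed weights are zero the density
#' power law never enters the predictions, so `b` and `y` are dropped
#' from the free set and reported in `$unidentified`.
#'
#' @param data Scores tibble with columns `condition`, `mass_g`,
#'   `density_g_cm3`, `score` (optionally `participant`).
#' @param spec An [fit_spec()] object.
#' @return An object of class `swi_fit`: a list with elements `params`
#'   (fitted [model_params()]), `sse`, `r_squared`, `trace` (best-so-far
#'   SSE per iteration, non-increasing), `seed`, `unidentified`, `data`
#'   (the aggregated cells used).
#' @export
fit_model <- function(data, spec) {
  stopifnot(inherits(spec, "swi_fit_spec"))
  data <- aggregate_scores(data)
  missing_cols <- setdiff(c("condition", "mass_g", "density_g_cm3", "score"),
                          names(data))
  if (length(missing_cols)) {
    stop("scores table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(unique(data$condition), spec$conditions)
  if (length(extra)) {
    stop("data contain condition(s) not covered by the fit spec: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (length(unique(data$mass_g)) < 2 ||
      length(unique(round(data$density_g_cm3, 10))) < 2) {
    stop("degenerate data: need at least 2 distinct masses and densities",
         call. = FALSE)
  }

  free <- spec$free
  fixed <- spec$fixed
  unidentified <- character(0)
  wfree <- grepl("^w_", free)
  if (!any(wfree) && all(fixed[grepl("^w_", names(fixed))] == 0)) {
    unidentified <- intersect(c("b", "y"), free)
    free <- setdiff(free, unidentified)
  }

  defaults <- c(a = 1, x = 1, b = 1, y = 1)
  wnames <- paste0("w_", spec$conditions)
  defaults[wnames] <- 0.2
  theta0 <- defaults
  theta0[names(fixed)] <- fixed

  # fast SSE path: avoids re-validating a params object on each of the
  # thousands of proposal evaluations (identical arithmetic to model_sse)
  w_idx <- match(paste0("w_", data$condition), names(theta0))
  m <- data$mass_g
  rho <- data$density_g_cm3
  score <- data$score
  obj <- function(theta) {
    w <- theta[w_idx]
    pred <- (1 - w) * theta[["a"]] * m^theta[["x"]] +
      w * theta[["b"]] * rho^theta[["y"]]
    sum((pred - score)^2)
  }

  res <- with_seed(spec$seed, {
    perturbation_search(theta0, free, obj, spec$iterations, spec$restarts)
  })
  # polish the best point of every restart: restarts land in different
  # basins and the global pre-polish leader is not always in the best one
  quick <- lapply(res$per_restart, polish_fit, free = free, obj = obj,
                  rounds = 1)
  vals <- vapply(quick, obj, numeric(1))
  top <- order(vals)[seq_len(min(3L, length(vals)))]
  polished <- lapply(quick[top], polish_fit, free = free, obj = obj)
  vals <- vapply(polished, obj, numeric(1))
  best <- polished[[which.min(vals)]]

  params <- theta_to_params(best, spec$conditions)
  sse <- obj(best)
  pred <- combined_heaviness(data$mass_g, data$density_g_cm3, params,
                             data$condition)
  structure(
    list(params = params, sse = sse,
         r_squared = variance_explained(pred, data$score),
         trace = cummin(res$trace),
         seed = spec$seed, spec = spec, unidentified = unidentified,
         data = data),
    class = "swi_fit"
  )
}

#' @export
print.swi_fit <- function(x, ...) {
  cat("<swi_fit> SSE =", format(x$sse, digits = 6),
      "| r^2 =", format(x$r_squared, digits = 4), "\n")
  print(x$params)
  if (length(x$unidentified)) {
    cat("  unidentified (left at default):",
        paste(x$unidentified, collapse = ", "), "\n")
  }
  invisible(x)
}

aggregate_scores <- function(data) {
  if ("participant" %in% names(data) &&
      length(unique(data$participant)) > 1) {
    data <- data |>
      dplyr::group_by(.data$condition, .data$mass_g,
                      .data$density_g_cm3) |>
      dplyr::summarise(score = mean(.data$score), .groups = "drop")
  }
  data
}

theta_to_params <- function(theta, conditions) {
  w <- theta[paste0("w_", conditions)]
  names(w) <- conditions
  model_params(a = unname(theta["a"]), x = unname(theta["x"]),
               b = unname(theta["b"]), y = unname(theta["y"]),
               weights = w)
}

perturb_theta <- function(theta, which_free, scale) {
  for (nm in which_free) {
    if (grepl("^w_", nm)) {
      theta[nm] <- min(1, max(0, theta[nm] + stats::rnorm(1, 0, scale)))
    } else {
      theta[nm] <- theta[nm] * exp(stats::rnorm(1, 0, scale))
    }
  }
  theta
}

random_start <- function(theta, free) {
  for (nm in free) {
    theta[nm] <- switch(
      substr(nm, 1, 1),
      a = exp(stats::rnorm(1, 0, 1.5)),
      b = exp(stats::rnorm(1, 0, 1)),
      x = exp(stats::rnorm(1, 0, 0.3)),
      y = exp(stats::rnorm(1, 0, 0.3)),
      w = stats::runif(1)
    )
  }
  theta
}

perturbation_search <- function(theta0, free, obj, iterations, restarts) {
  iters_per <- max(1L, iterations %/% max(1L, restarts))
  best_global <- theta0
  sse_global <- obj(theta0)
  trace <- numeric(0)
  per_restart <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    cur <- if (r == 1) theta0 else random_start(theta0, free)
    sse_cur <- obj(cur)
    if (sse_cur < sse_global) {
      best_global <- cur
      sse_global <- sse_cur
    }
    for (i in seq_len(iters_per)) {
      scale <- 0.5 * (0.01 / 0.5)^((i - 1) / max(1, iters_per - 1))
      for (k in c(1, 2, length(free))) {
        pick <- if (k >= length(free)) free else sample(free, k)
        cand <- perturb_theta(cur, pick, scale)
        sse_cand <- obj(cand)
        if (sse_cand < sse_cur) {
          cur <- cand
          sse_cur <- sse_cand
        }
      }
      if (sse_cur < sse_global) {
        best_global <- cur
        sse_global <- sse_cur
      }
      trace <- c(trace, sse_global)
    }
    per_restart[[r]] <- cur
  }
  list(best = best_global, trace = trace, per_restart = per_restart)
}

polish_fit <- function(theta, free, obj, rounds = 25) {
  if (!length(free)) return(theta)
  to_free <- function(th) {
    v <- th[free]
    lg <- !grepl("^w_", free)
    v[lg] <- log(v[lg])
    v
  }
  from_free <- function(v, base) {
    lg <- !grepl("^w_", free)
    v[lg] <- exp(v[lg])
    v[!lg] <- pmin(1, pmax(0, v[!lg]))
    base[free] <- v
    base
  }
  fn <- function(v) obj(from_free(v, theta))
  best <- theta
  best_val <- obj(theta)
  par <- to_free(theta)
  # restart the simplex until it stops improving: a single Nelder-Mead
  # run routinely stalls on the correlated (a, x) / (b, y) axes
  for (round in seq_len(rounds)) {
    opt <- stats::optim(par, fn, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-14))
    cand <- from_free(opt$par, best)
    val <- obj(cand)
    if (val < best_val - 1e-15 * (1 + best_val)) {
      improved <- best_val - val
      best <- cand
      best_val <- val
      par <- opt$par
      if (improved < 1e-10 * (1 + best_val)) break
    } else {
      break
    }
  }
  best
}

#' Proportion of variance explained
#'
#' \eqn{r^2 = 1 - \sum (obs - pred)^2 / \sum (obs - \bar{obs})^2},
#' computed on the matched value lists (for model fits: on aggregated
#' condition-mean scores).
#'
#' @param predicted,observed Equal-length numeric vectors (length >= 2);
#'   `observed` must not be constant.
#' @return A proportion in \eqn{(-\infty, 1]}.
#' @export
variance_explained <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 2) {
    stop("need two matched value lists of equal length >= 2", call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("observed values have zero total variance", call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Serialize a fit result to JSON
#'
#' @param fit An `swi_fit` object.
#' @param path Output path; with `path = NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "swi_fit"))
  js <- jsonlite::toJSON(
    list(a = fit$params$a, x = fit$params$x, b = fit$params$b,
         y = fit$params$y, weights = as.list(fit$params$weights),
         sse = fit$sse, r_squared = fit$r_squared, seed = fit$seed,
         unidentified = fit$unidentified),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# run code under a fixed RNG state without clobbering the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
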