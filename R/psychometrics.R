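#' Fit a cumulative Gaussian to 2IFC proportions by maximum likelihood
#'
#' Fits \eqn{P(\mathrm{comparison\ heavier}) = \Phi((c - \mu)/\sigma)} to
#' binomial counts per comparison level. \eqn{\mu} is reported as the
#' point of subjective equality (PSE) and \eqn{\sigma} as the
#' just-noticeable difference (JND): \eqn{\sigma} is the step from the
#' 50% point to the 84.1% point of the function. No lapse or guess
#' parameters are used by default.
#'
#' The fit is deterministic: a coarse grid over \eqn{(\mu, \sigma)}
#' initializes a Nelder-Mead polish of the binomial log-likelihood.
#'
#' @param data One participant x condition x set slice: a tibble with
#'   columns `comparison_mass` (or `comparison`), `n_trials`,
#'   `n_comparison_heavier`. At least 3 distinct comparison levels with
#'   trials are required and responses must not be all-"heavier" or
#'   all-"lighter".
#' @param lapse Optional fixed lapse rate \eqn{\lambda} (and guess rate,
#'   applied symmetrically): predicted proportions become
#'   \eqn{\lambda + (1 - 2\lambda)\Phi}. Defaults to 0.
#' @return An object of class `psychometric_fit`: list with `mu`
#'   (PSE), `sigma` (JND), `loglik`, `converged`, and `boundary` (TRUE
#'   when `sigma` ran into its lower bound, as happens under complete
#'   separation).
#' @examples
#' d <- tibble::tibble(comparison_mass = seq(170, 230, by = 10),
#'                     n_trials = 20,
#'                     n_comparison_heavier =
#'                       round(20 * pnorm((seq(170, 230, by = 10) - 200) / 15)))
#' fit_cumulative_gaussian(d)
#' @export
fit_cumulative_gaussian <- function(data, lapse = 0) {
  x_col <- intersect(c("comparison_mass", "comparison"), names(data))[1]
  if (is.na(x_col)) {
    stop("data need a 'comparison_mass' (or 'comparison') column",
         call. = FALSE)
  }
  needed <- c("n_trials", "n_comparison_heavier")
  if (!all(needed %in% names(data))) {
    stop("data need columns n_trials and n_comparison_heavier",
         call. = FALSE)
  }
  keep <- data$n_trials > 0
  x <- data[[x_col]][keep]
  n <- data$n_trials[keep]
  k <- data$n_comparison_heavier[keep]
  if (any(k < 0 | k > n)) {
    stop("counts must satisfy 0 <= n_comparison_heavier <= n_trials",
         call. = FALSE)
  }
  ord <- order(x)
  x <- x[ord]; n <- n[ord]; k <- k[ord]
  agg <- rowsum(cbind(n, k), group = x)
  x <- as.numeric(rownames(agg)); n <- agg[, 1]; k <- agg[, 2]
  if (length(x) < 3) {
    stop("need at least 3 distinct comparison levels with trials",
         call. = FALSE)
  }
  if (all(k == 0) || all(k == n)) {
    stop("responses are all identical; PSE is not identifiable",
         call. = FALSE)
  }

  rng <- diff(range(x))
  sigma_lo <- rng * 1e-3

  # complete separation (a monotone step with no graded proportions):
  # the likelihood is maximized by sigma -> 0, so report the step
  # midpoint with sigma at its lower bound
  if (all(k == 0 | k == n)) {
    step_at <- which(diff(k == n) != 0)
    if (length(step_at) == 1 && all((k == n) == (x > x[step_at]))) {
      warning(
        "sigma at lower bound (complete separation in the responses)",
        call. = FALSE)
      mu <- mean(x[step_at + 0:1])
      p <- stats::pnorm((x - mu) / sigma_lo)
      p <- pmin(1 - 1e-12, pmax(1e-12, p))
      return(structure(
        list(mu = mu, sigma = sigma_lo,
             loglik = sum(k * log(p) + (n - k) * log(1 - p)),
             converged = TRUE, boundary = TRUE),
        class = "psychometric_fit"
      ))
    }
  }
  nll <- function(mu, sigma) {
    p <- lapse + (1 - 2 * lapse) * stats::pnorm((x - mu) / sigma)
    p <- pmin(1 - 1e-12, pmax(1e-12, p))
    -sum(k * log(p) + (n - k) * log(1 - p))
  }
  grid_mu <- seq(min(x), max(x), length.out = 41)
  grid_sigma <- rng * c(0.02, 0.05, 0.1, 0.2, 0.35, 0.5, 1)
  grid <- expand.grid(mu = grid_mu, sigma = grid_sigma)
  grid_nll <- mapply(nll, grid$mu, grid$sigma)
  start <- grid[which.min(grid_nll), ]

  opt <- stats::optim(
    c(start$mu, log(start$sigma)),
    function(par) nll(par[1], sigma_lo + exp(par[2])),
    method = "Nelder-Mead",
    control = list(maxit = 1000, reltol = 1e-12)
  )
  mu <- opt$par[1]
  sigma <- sigma_lo + exp(opt$par[2])
  boundary <- sigma < 2 * sigma_lo
  if (boundary) {
    warning("sigma at lower bound (complete separation in the responses)",
            call. = FALSE)
  }
  structure(
    list(mu = mu, sigma = sigma, loglik = -opt$value,
         converged = opt$convergence == 0, boundary = boundary),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("<psychometric_fit> PSE mu =", format(x$mu, digits = 5),
      "| JND sigma =", format(x$sigma, digits = 4),
      "| logLik =", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' Weber fraction
#'
#' The just-noticeable difference expressed as a proportion of the
#' standard magnitude.
#'
#' @param jnd JND in the same units as the standard (>= 0).
#' @param standard Standard magnitude (> 0).
#' @return `jnd / standard`.
#' @examples
#' weber_fraction(59.6, 596)  # 0.10
#' @export
weber_fraction <- function(jnd, standard) {
  if (any(!is.finite(standard)) || any(standard <= 0)) {
    stop("standard must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(jnd)) || any(jnd < 0)) {
    stop("jnd must be non-negative", call. = FALSE)
  }
  jnd / standard
}

#' Model-predicted point of subjective equality
#'
#' In the 2IFC experiment the comparison is lifted on a string (heaviness
#' driven by mass only) while the standard is lifted with a grip that
#' also conveys density. The predicted PSE is the comparison mass whose
#' mass-only estimate matches the standard's combined estimate:
#' \deqn{a\,\mathrm{PSE}^x = (1 - w_\rho) a m_s^x + w_\rho b \rho_s^y
#'   \quad\Rightarrow\quad \mathrm{PSE} = (\hat h(m_s, \rho_s)/a)^{1/x}.}
#' With \eqn{w_\rho = 0} this inverts exactly to the standard's mass.
#'
#' @param params An [model_params()] object with a weight for
#'   `condition`.
#' @param condition Condition label of the standard's grip.
#' @param standard_mass Standard mass in grams (> 0).
#' @param standard_density Standard density in g/cm^3 (> 0).
#' @return Predicted PSE in grams.
#' @examples
#' predict_pse(exp2_aggregate_params(), "precision", 200, 200 / 596)
#' @export
predict_pse <- function(params, condition, standard_mass,
                        standard_density) {
  w <- params$weights[condition]
  h <- combined_heaviness(standard_mass, standard_density, params,
                          condition)
  if (any(h <= 0)) {
    stop("combined heaviness must be positive to invert the mass power law",
         call. = FALSE)
  }
  if (all(w == 0)) {
    # algebraic identity: the inversion returns the standard's mass
    return(standard_mass)
  }
  (h / params$a)^(1 / params$x)
}

#' Adaptive comparison-discarding routine for the 2IFC experiment
#'
#' To avoid collecting uninformative trials, extreme comparison stimuli
#' whose responses are fully consistent are dropped at two block
#' boundaries. After block 2: if more than three of the heaviest retained
#' comparisons have been judged heavier than the standard on every
#' presented trial, only the three least-extreme of that run are kept
#' (mirror rule at the light end for all-"lighter" runs). After block 5:
#' if two or more extreme comparisons are still fully consistent, only
#' the single least-extreme of the run is kept. Comparisons with mixed
#' responses are never removed, so the retained set always brackets the
#' standard.
#'
#' @param comparisons Numeric vector of comparison masses (grams).
#' @param standard_mass Standard mass in grams.
#' @return `discard_state()` returns an object of class
#'   `swi_discard_state` with fields `retained`, `standard_mass`, `log`.
#' @export
discard_state <- function(comparisons, standard_mass) {
  structure(
    list(retained = sort(unique(comparisons)),
         standard_mass = standard_mass,
         log = list()),
    class = "swi_discard_state"
  )
}

#' @rdname discard_state
#' @param state An `swi_discard_state`.
#' @param consistency Named character vector over the retained
#'   comparisons (names = masses) with values `"heavier"` (judged heavier
#'   than the standard on every presented trial so far), `"lighter"`
#'   (always judged lighter), or `"mixed"`.
#' @param boundary Block boundary at which the rule is applied: 2 or 5.
#' @export
apply_discard_rule <- function(state, consistency, boundary) {
  stopifnot(inherits(state, "swi_discard_state"))
  if (!boundary %in% c(2, 5)) {
    stop("the discard rule applies only at block boundaries 2 and 5",
         call. = FALSE)
  }
  keep_n <- if (boundary == 2) 3L else 1L
  trigger <- if (boundary == 2) {
    function(run) run > 3          # "more than three"
  } else {
    function(run) run >= 2         # "two or more"
  }
  ret <- state$retained
  cons <- consistency[as.character(ret)]
  cons[is.na(cons)] <- "mixed"

  run_len <- function(values, want) {
    r <- 0L
    for (v in values) {
      if (identical(v, want)) r <- r + 1L else break
    }
    r
  }
  drop_masses <- numeric(0)
  heavy <- ret > state$standard_mass
  k_heavy <- run_len(rev(cons[heavy]), "heavier")
  if (trigger(k_heavy)) {
    heavy_sorted <- rev(ret[heavy])         # heaviest first
    drop_masses <- c(drop_masses, heavy_sorted[seq_len(k_heavy - keep_n)])
  }
  light <- ret < state$standard_mass
  k_light <- run_len(cons[light], "lighter")
  if (trigger(k_light)) {
    light_sorted <- ret[light]              # lightest first
    drop_masses <- c(drop_masses, light_sorted[seq_len(k_light - keep_n)])
  }
  if (length(drop_masses)) {
    state$retained <- setdiff(ret, drop_masses)
    state$log <- c(state$log,
                   list(list(boundary = boundary,
                             dropped = sort(drop_masses))))
  }
  state
}

#' Summarize per-comparison response consistency
#'
#' Helper turning a trial-count table into the consistency labels
#' consumed by [apply_discard_rule()]: a comparison is `"heavier"` if it
#' was judged heavier than the standard on every presented trial so far,
#' `"lighter"` if on none, otherwise `"mixed"`. Comparisons not yet
#' presented are `"mixed"` (never dropped).
#'
#' @param tab Tibble with columns `comparison_mass`, `n_trials`,
#'   `n_comparison_heavier` (cumulative over blocks so far).
#' @return Named character vector keyed by comparison mass.
#' @export
response_consistency <- function(tab) {
  lab <- ifelse(tab$n_trials == 0, "mixed",
         ifelse(tab$n_comparison_heavier == tab$n_trials, "heavier",
         ifelse(tab$n_comparison_heavier == 0, "lighter", "mixed")))
  stats::setNames(lab, tab$comparison_mass)
}

#' Read/write 2IFC response tables; discard audit log as JSON
#'
#' Response tables are comma-separated UTF-8 text with columns
#' `participant`, `condition`, `set`, `comparison_mass`, `n_trials`,
#' `n_comparison_heavier`.
#'
#' @param tab Response tibble.
#' @param path File path.
#' @param state An `swi_discard_state`.
#' @return Readers return tibbles; `discard_log_json()` a JSON string.
#' @export
write_response_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8"))
}

#' @rdname write_response_table
#' @export
discard_log_json <- function(state, path = NULL) {
  stopifnot(inherits(state, "swi_discard_state"))
  js <- jsonlite::toJSON(
    list(standard_mass = state$standard_mass,
         retained = state$retained, log = state$log),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
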