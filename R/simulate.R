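#' Population specification for synthetic participants
#'
#' Describes the generative distribution of per-participant model
#' parameters and the two noise sources of the simulator. Power-law
#' parameters are log-normal around the aggregate-fit centers, truncated
#' to the ranges observed across individually fitted participants in the
#' visual experiment (`a` 0.0007--0.0271, `x` 0.75--1.51, `b` 0.59--2.1,
#' `y` 0.27--0.77); condition weights are normal around their aggregate
#' values, truncated to \[0, 1\] and to the printed individual ranges.
#' Magnitude-estimation noise is multiplicative log-normal with
#' coefficient of variation `noise_cv`; 2IFC decisions follow a Gaussian
#' difference model with standard deviation `sigma_d` on the internal
#' heaviness scale.
#'
#' @param center An [model_params()] object giving the population
#'   centers; defaults to the visual-experiment aggregate fit.
#' @param sdlog Named numeric: log-scale spreads of `a`, `x`, `b`, `y`.
#' @param weight_sd Standard deviation of the truncated-normal weight
#'   distributions (shared across conditions).
#' @param bounds Named list of length-2 numeric ranges for `a`, `x`,
#'   `b`, `y`; samples are drawn by rejection until inside.
#' @param weight_bounds Named list mapping condition to a length-2 range
#'   (defaults to \[0, 1\] per condition; conditions with center weight 0
#'   are held exactly at 0).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   magnitude-estimate noise (>= 0).
#' @param sigma_d 2IFC decision noise on the heaviness scale (> 0).
#' @return An object of class `swi_population_spec`.
#' @export
population_spec <- function(center = exp1_aggregate_params(),
                            sdlog = c(a = 0.5, x = 0.12, b = 0.2,
                                      y = 0.2),
                            weight_sd = 0.08,
                            bounds = list(a = c(0.0007, 0.0271),
                                          x = c(0.75, 1.51),
                                          b = c(0.59, 2.1),
                                          y = c(0.27, 0.77)),
                            weight_bounds = NULL,
                            noise_cv = 0.1,
                            sigma_d = 0.2) {
  stopifnot(inherits(center, "swi_params"))
  if (!is.numeric(noise_cv) || noise_cv < 0) {
    stop("noise_cv must be >= 0", call. = FALSE)
  }
  if (!is.numeric(sigma_d) || sigma_d <= 0) {
    stop("sigma_d must be > 0", call. = FALSE)
  }
  if (is.null(weight_bounds)) {
    weight_bounds <- lapply(center$weights, function(w) c(0, 1))
  }
  for (nm in c("a", "x", "b", "y")) {
    rng <- bounds[[nm]]
    cen <- center[[nm]]
    if (!is.null(rng) && (cen < rng[1] || cen > rng[2])) {
      stop("center for '", nm, "' lies outside its bounds", call. = FALSE)
    }
  }
  structure(
    list(center = center, sdlog = sdlog, weight_sd = weight_sd,
         bounds = bounds, weight_bounds = weight_bounds,
         noise_cv = noise_cv, sigma_d = sigma_d),
    class = "swi_population_spec"
  )
}

# truncated draw helpers (rejection sampling; reproducible under seed)
rlnorm_trunc <- function(center, sdlog, rng) {
  if (sdlog == 0) return(center)
  repeat {
    v <- center * exp(stats::rnorm(1, 0, sdlog))
    if (is.null(rng) || (v >= rng[1] && v <= rng[2])) return(v)
  }
}

rnorm_trunc <- function(center, sd, rng) {
  if (sd == 0) return(center)
  repeat {
    v <- stats::rnorm(1, center, sd)
    if (v >= rng[1] && v <= rng[2]) return(v)
  }
}

#' Sample synthetic participants
#'
#' Draws `n` per-participant parameter sets from a population
#' specification. Conditions whose center weight is 0 (no density
#' information available, e.g. blindfolded string lifting) keep weight 0
#' for every participant.
#'
#' @param spec An [population_spec()] object.
#' @param n Number of participants (>= 1).
#' @param seed Integer seed; the draw is reproducible from it.
#' @return A list of [model_params()] objects; also carries a tibble of
#'   the sampled values as attribute `"table"`.
#' @export
sample_participants <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "swi_population_spec"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  cen <- spec$center
  out <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      a <- rlnorm_trunc(cen$a, spec$sdlog[["a"]], spec$bounds[["a"]])
      x <- rlnorm_trunc(cen$x, spec$sdlog[["x"]], spec$bounds[["x"]])
      b <- rlnorm_trunc(cen$b, spec$sdlog[["b"]], spec$bounds[["b"]])
      y <- rlnorm_trunc(cen$y, spec$sdlog[["y"]], spec$bounds[["y"]])
      w <- vapply(names(cen$weights), function(cond) {
        w0 <- cen$weights[[cond]]
        if (w0 == 0) return(0)
        rng <- spec$weight_bounds[[cond]]
        rnorm_trunc(w0, spec$weight_sd, c(max(0, rng[1]), min(1, rng[2])))
      }, numeric(1))
      model_params(a = a, x = x, b = b, y = y, weights = w)
    })
  })
  tab <- dplyr::bind_rows(lapply(seq_along(out), function(i) {
    p <- out[[i]]
    tibble::tibble(participant = i, a = p$a, x = p$x, b = p$b, y = p$y,
                   !!!as.list(stats::setNames(p$weights,
                                              paste0("w_",
                                                     names(p$weights)))))
  }))
  attr(out, "table") <- tab
  out
}

#' Trial layouts of the two magnitude-estimation experiments
#'
#' `exp1_design()`: visibility experiment; all 18 stimuli in the
#' `no_vision` and `full` conditions, the 8 inferential-statistics
#' stimuli in `poor` and `medium`, 6 blocks per condition (312 trials
#' per participant). `exp2_design()`: grip-type experiment; 10 stimuli
#' (60/140/230 g of the small and big sets plus the 55/139/165/198 g
#' equal-density cans) in each of `string`, `precision`, `enclosure`,
#' 6 blocks (180 trials per participant).
#'
#' @return A tibble with one row per trial slot: columns `condition`,
#'   `set`, `mass_g`, `volume_cm3`, `density_g_cm3`, `block`.
#' @export
exp1_design <- function() {
  sets <- build_standard_sets()
  all18 <- dplyr::filter(sets, .data$set %in%
                           c("small", "big", "equal_density"))
  sub8 <- dplyr::filter(all18,
                        (.data$set %in% c("small", "big") &
                           .data$mass_g %in% c(60, 140, 230)) |
                          (.data$set == "equal_density" &
                             .data$mass_g %in% c(55, 139)))
  blocks <- function(stims, condition) {
    tidyr::crossing(block = 1:6,
                    stims[, c("set", "mass_g", "volume_cm3",
                              "density_g_cm3")]) |>
      dplyr::mutate(condition = condition)
  }
  dplyr::bind_rows(
    blocks(all18, "no_vision"), blocks(sub8, "poor"),
    blocks(sub8, "medium"), blocks(all18, "full")
  ) |>
    dplyr::select("condition", "set", "mass_g", "volume_cm3",
                  "density_g_cm3", "block")
}

#' @rdname exp1_design
#' @export
exp2_design <- function() {
  sets <- build_standard_sets()
  stims <- dplyr::filter(sets,
                         (.data$set %in% c("small", "big") &
                            .data$mass_g %in% c(60, 140, 230)) |
                           .data$set == "equal_density" &
                           .data$mass_g %in% c(55, 139, 165, 198))
  blocks <- function(condition) {
    tidyr::crossing(block = 1:6,
                    stims[, c("set", "mass_g", "volume_cm3",
                              "density_g_cm3")]) |>
      dplyr::mutate(condition = condition)
  }
  dplyr::bind_rows(blocks("string"), blocks("precision"),
                   blocks("enclosure")) |>
    dplyr::select("condition", "set", "mass_g", "volume_cm3",
                  "density_g_cm3", "block")
}

#' Simulate a magnitude-estimation dataset
#'
#' For every participant and design trial, the reported estimate is the
#' model-predicted combined heaviness multiplied by log-normal noise
#' with coefficient of variation `spec$noise_cv` (the multiplicative
#' form is what a geometric-mean analysis assumes; an additive option
#' exists for robustness checks).
#'
#' @param participants List of [model_params()] from
#'   [sample_participants()], or a single `swi_params` object.
#' @param design A design tibble from [exp1_design()] / [exp2_design()].
#' @param spec An [population_spec()] (only its noise fields are used).
#' @param seed Integer seed.
#' @param noise One of `"multiplicative"` (default) or `"additive"`.
#' @return A list of class `swi_simulated`: `data` (estimate table with
#'   a `trial` index per participant), `truth` (list of generating
#'   parameter sets), `seed`.
#' @export
simulate_magnitude_dataset <- function(participants, design,
                                       spec = population_spec(),
                                       seed = 1L,
                                       noise = c("multiplicative",
                                                 "additive")) {
  noise <- match.arg(noise)
  if (inherits(participants, "swi_params")) {
    participants <- list(participants)
  }
  cv <- spec$noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  rows <- with_seed(seed, {
    lapply(seq_along(participants), function(i) {
      p <- participants[[i]]
      missing_cond <- setdiff(unique(design$condition), names(p$weights))
      if (length(missing_cond)) {
        stop("participant ", i, " has no weight for condition(s): ",
             paste(missing_cond, collapse = ", "), call. = FALSE)
      }
      mu <- combined_heaviness(design$mass_g, design$density_g_cm3, p,
                               design$condition)
      est <- if (cv == 0) {
        mu
      } else if (noise == "multiplicative") {
        # median-1 noise: unbiased on the log scale, which is the scale
        # the geometric-mean pipeline averages on
        mu * stats::rlnorm(length(mu), meanlog = 0, sdlog = sdlog)
      } else {
        pmax(1e-6, mu + stats::rnorm(length(mu), 0, cv * mean(mu)))
      }
      tibble::tibble(participant = i, condition = design$condition,
                     set = design$set, mass_g = design$mass_g,
                     density_g_cm3 = design$density_g_cm3,
                     trial = design$block, estimate = est)
    })
  })
  structure(
    list(data = dplyr::bind_rows(rows), truth = participants,
         seed = seed),
    class = "swi_simulated"
  )
}

#' Simulate a 2IFC heaviness-discrimination dataset
#'
#' Each trial pairs the standard (lifted with the condition's grip, so
#' its percept combines mass and density) against a comparison lifted on
#' a string (mass-only percept). The comparison is reported heavier with
#' probability \eqn{\Phi((\hat h_m(c) - \hat h(m_s, \rho_s)) / \sigma_d)}.
#' With `discard = TRUE` the adaptive discarding routine is applied at
#' the block-2 and block-5 boundaries, as in the lab procedure.
#'
#' @param params An [model_params()] object for the simulated
#'   participant.
#' @param standard_mass,standard_density Standard stimulus properties.
#' @param comparison_masses Numeric vector of comparison masses (grams).
#' @param condition Grip condition of the standard.
#' @param blocks Number of blocks; each block presents every retained
#'   comparison once.
#' @param sigma_d Decision noise; defaults to the population spec
#'   default.
#' @param discard Apply the adaptive discard routine (default FALSE).
#' @param seed Integer seed.
#' @return A list of class `swi_simulated_2ifc`: `data` (response table
#'   with columns `comparison_mass`, `n_trials`, `n_comparison_heavier`),
#'   `state` (final `swi_discard_state`, when `discard = TRUE`),
#'   `truth` (params, standard, sigma_d), `seed`.
#' @export
simulate_2ifc_dataset <- function(params, standard_mass, standard_density,
                                  comparison_masses, condition,
                                  blocks = 10, sigma_d = 0.2,
                                  discard = FALSE, seed = 1L) {
  stopifnot(inherits(params, "swi_params"))
  if (blocks < 1) stop("blocks must be >= 1", call. = FALSE)
  h_std <- combined_heaviness(standard_mass, standard_density, params,
                              condition)
  comparison_masses <- sort(unique(comparison_masses))
  p_heavier <- stats::pnorm(
    (mass_estimate(comparison_masses, params) - h_std) / sigma_d
  )
  names(p_heavier) <- comparison_masses

  counts <- tibble::tibble(
    comparison_mass = comparison_masses,
    n_trials = 0L, n_comparison_heavier = 0L
  )
  state <- discard_state(comparison_masses, standard_mass)

  with_seed(seed, {
    if (!discard) {
      # no adaptivity: the block structure is exchangeable, draw in bulk
      counts$n_trials <- as.integer(blocks)
      counts$n_comparison_heavier <-
        stats::rbinom(nrow(counts), blocks, p_heavier)
    } else {
      for (b in seq_len(blocks)) {
        idx <- counts$comparison_mass %in% state$retained
        resp <- stats::rbinom(sum(idx), 1,
                              p_heavier[as.character(
                                counts$comparison_mass[idx])])
        counts$n_trials[idx] <- counts$n_trials[idx] + 1L
        counts$n_comparison_heavier[idx] <-
          counts$n_comparison_heavier[idx] + resp
        if (b %in% c(2, 5)) {
          state <- apply_discard_rule(state,
                                      response_consistency(counts), b)
        }
      }
    }
  })
  structure(
    list(data = counts, state = if (discard) state else NULL,
         truth = list(params = params, standard_mass = standard_mass,
                      standard_density = standard_density,
                      condition = condition, sigma_d = sigma_d),
         seed = seed),
    class = "swi_simulated_2ifc"
  )
}
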