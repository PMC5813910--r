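#' Geometric-mean standardization of free-modulus magnitude estimates
#'
#' In free-modulus magnitude estimation each participant chooses their own
#' numerical scale, so raw estimates are only comparable within a
#' participant. Standardization divides every estimate by the
#' participant's geometric mean over *all* of their estimates, after which
#' each participant's overall geometric mean equals 1.
#'
#' @param raw A tibble with columns `participant`, `condition`, `set`,
#'   `mass_g`, `trial`, `estimate` (all estimates > 0).
#' @return The same tibble with `estimate` rescaled; attribute
#'   `standardized` set to `TRUE`. Standardizing an already standardized
#'   table is a no-op (idempotence).
#' @examples
#' tab <- tibble::tibble(participant = 1, condition = "full", set = "big",
#'                       mass_g = c(60, 140, 230), trial = 1,
#'                       estimate = c(1, 10, 100))
#' standardize_estimates(tab)$estimate  # 0.1 1 10
#' @export
standardize_estimates <- function(raw) {
  check_estimate_table(raw)
  bad <- which(!is.finite(raw$estimate) | raw$estimate <= 0)
  if (length(bad)) {
    stop("estimates must be strictly positive; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out <- raw |>
    dplyr::group_by(.data$participant) |>
    dplyr::mutate(estimate = .data$estimate /
                    exp(mean(log(.data$estimate)))) |>
    dplyr::ungroup()
  attr(out, "standardized") <- TRUE
  out
}

check_estimate_table <- function(tab) {
  needed <- c("participant", "condition", "set", "mass_g", "trial",
              "estimate")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("estimate table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(tab)
}

#' Per-cell heaviness scores
#'
#' Collapses repeated standardized estimates into one score per
#' participant x condition x set x mass cell by taking the geometric mean
#' of the cell's estimates. The 230 g big-set cell is duplicated into the
#' equal-density set, which it belongs to by density (0.39 g/cm^3).
#'
#' @param standardized A standardized estimate table
#'   (see [standardize_estimates()]).
#' @return A tibble with columns `participant`, `condition`, `set`,
#'   `mass_g`, `score` (plus `density_g_cm3` when the input carries it,
#'   as simulated tables do).
#' @export
condition_scores <- function(standardized) {
  check_estimate_table(standardized)
  if (!isTRUE(attr(standardized, "standardized"))) {
    stop("estimates must be standardized first; see standardize_estimates()",
         call. = FALSE)
  }
  keys <- c("participant", "condition", "set", "mass_g",
            intersect("density_g_cm3", names(standardized)))
  scores <- standardized |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(score = exp(mean(log(.data$estimate))),
                     .groups = "drop")
  # the heaviest big-set can doubles as an equal-density member
  dup <- scores |>
    dplyr::filter(.data$set == "big", .data$mass_g == 230) |>
    dplyr::mutate(set = "equal_density")
  dup <- dplyr::anti_join(
    dup, scores,
    by = c("participant", "condition", "set", "mass_g")
  )
  dplyr::bind_rows(scores, dup) |>
    dplyr::arrange(.data$participant, .data$condition, .data$set,
                   .data$mass_g)
}

#' Participant-mean score differences between two density sets
#'
#' Matches cells of two stimulus sets on condition and mass (applying the
#' 55 g -> 60 g and 139 g -> 140 g equal-density aliases), computes the
#' within-participant score difference `setA - setB`, and averages over
#' participants within each grouping cell.
#'
#' @param scores A [condition_scores()] tibble.
#' @param setA,setB Set labels to difference (A minus B).
#' @param by Grouping columns for the output means; defaults to
#'   `c("condition", "mass_g")`.
#' @return A tibble of grouping columns plus `diff` (mean over
#'   participants) and `n` (participants contributing).
#' @export
set_differences <- function(scores, setA, setB,
                            by = c("condition", "mass_g")) {
  alias <- function(d) {
    d$mass_g[d$set == "equal_density" & d$mass_g == 55] <- 60
    d$mass_g[d$set == "equal_density" & d$mass_g == 139] <- 140
    d
  }
  a <- alias(dplyr::filter(scores, .data$set == setA))
  b <- alias(dplyr::filter(scores, .data$set == setB))
  joined <- dplyr::inner_join(
    a, b,
    by = c("participant", "condition", "mass_g"),
    suffix = c("_a", "_b")
  )
  if (!nrow(joined)) {
    stop("no matched cells between sets '", setA, "' and '", setB, "'",
         call. = FALSE)
  }
  joined |>
    dplyr::mutate(diff = .data$score_a - .data$score_b) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(diff = mean(.data$diff),
                     n = dplyr::n(), .groups = "drop")
}

#' Linear trend contrast over ordered levels
#'
#' Inner product of a value vector with centered, integer-spaced linear
#' contrast weights: `(-1, 0, 1)` for 3 levels, `(-3, -1, 1, 3)` for 4,
#' and so on. Used to quantify monotone trends of set differences over
#' ordered visibility / grip-type or mass levels.
#'
#' @param values Numeric vector (one value per ordered level, >= 3
#'   levels), or a matrix with one row per participant and one column per
#'   level.
#' @return For a vector, the contrast value. For a matrix, a list with
#'   per-participant contrasts (`by_participant`) and their `mean`.
#' @examples
#' linear_trend_contrast(c(0.04, 0.35, 0.49, 0.58))  # 1.76
#' @export
linear_trend_contrast <- function(values) {
  if (is.matrix(values)) {
    k <- ncol(values)
    w <- contrast_weights(k)
    per <- drop(values %*% w)
    return(list(by_participant = per, mean = mean(per)))
  }
  k <- length(values)
  w <- contrast_weights(k)
  sum(values * w)
}

contrast_weights <- function(k) {
  if (k < 3) {
    stop("a linear contrast needs at least 3 ordered levels", call. = FALSE)
  }
  w <- seq_len(k) - (k + 1) / 2
  if (k %% 2 == 0) w <- 2 * w  # keep weights integer for even k
  w
}

#' Read/write magnitude-estimation tables as delimited text
#'
#' Comma-separated, UTF-8, header row, `.` decimal separator. The
#' estimate-table schema is `participant, condition, set, mass_g, trial,
#' estimate`; the scores schema is `participant, condition, set, mass_g,
#' score`.
#'
#' @param tab A tibble to write.
#' @param path File path.
#' @return `read_estimate_table()` / `read_scores()` return tibbles.
#' @export
write_estimate_table <- function(tab, path) {
  check_estimate_table(tab)
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_estimate_table
#' @export
read_estimate_table <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8"))
  check_estimate_table(tab)
  tab
}

#' @rdname write_estimate_table
#' @export
write_scores <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_estimate_table
#' @export
read_scores <- function(path) {
  tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8"))
}
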