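#' Stimulus registry for the heaviness and size-discrimination experiments
#'
#' Builds the full set of stimulus tables used across the three
#' experiments:
#' \describe{
#'   \item{`small`}{6 high-density cans, constant volume 31.8 cm^3, masses
#'     60--230 g.}
#'   \item{`big`}{6 low-density cans, constant volume 596 cm^3, same six
#'     masses.}
#'   \item{`equal_density`}{6 cans at constant density 0.39 g/cm^3, masses
#'     55--198 g; the 230 g big-set can shares this density and is pooled
#'     with this set at analysis time.}
#'   \item{`exp3_small` / `exp3_big`}{2IFC comparison series around the
#'     200 g standard (11 masses 170--230 g; the big series adds 60, 100
#'     and 140 g comparisons).}
#'   \item{`sizedisc_small` / `sizedisc_big`}{size-discrimination volume
#'     series at 80--120% of the 31.8 / 596 cm^3 standards.}
#' }
#'
#' The canonical small-set volume is 31.8 cm^3 (its rounded value 32 cm^3
#' also appears in print); densities are always stored as `mass / volume`
#' and printed densities are treated as rounded display values. The 55 g
#' and 139 g equal-density cans carry `mass_matched_g` aliases 60 and
#' 140 g so they can be joined against the equal-mass members of the two
#' volume sets.
#'
#' @return A tibble with columns `set`, `label`, `mass_g`, `volume_cm3`,
#'   `density_g_cm3`, `mass_matched_g`, `is_standard`.
#' @examples
#' sets <- build_standard_sets()
#' subset(sets, set == "big" & mass_g == 230)$density_g_cm3  # ~0.386
#' @export
build_standard_sets <- function() {
  heav_masses <- c(60, 100, 140, 170, 200, 230)
  v_small <- 31.8
  v_big <- 596
  eq_masses <- c(55, 85, 112, 139, 165, 198)
  eq_density <- 0.39

  small <- stimulus_rows("small", heav_masses, volume = v_small)
  big <- stimulus_rows("big", heav_masses, volume = v_big)
  equal <- stimulus_rows("equal_density", eq_masses,
                         volume = eq_masses / eq_density)

  exp3_small_masses <- c(170, 180, 186, 194, 198, 200, 202, 206, 214,
                         220, 230)
  exp3_big_masses <- c(60, 100, 140, exp3_small_masses)
  exp3_small <- stimulus_rows("exp3_small", exp3_small_masses,
                              volume = v_small, standard_mass = 200)
  exp3_big <- stimulus_rows("exp3_big", exp3_big_masses,
                            volume = v_big, standard_mass = 200)

  sd_small <- sizedisc_rows("sizedisc_small", v_small)
  sd_big <- sizedisc_rows("sizedisc_big", v_big)

  out <- dplyr::bind_rows(small, big, equal, exp3_small, exp3_big,
                          sd_small, sd_big)
  # analysis-join aliases for the two off-mass equal-density cans
  out$mass_matched_g <- out$mass_g
  out$mass_matched_g[out$set == "equal_density" & out$mass_g == 55] <- 60
  out$mass_matched_g[out$set == "equal_density" & out$mass_g == 139] <- 140
  out
}

stimulus_rows <- function(set, masses, volume, standard_mass = NA_real_) {
  tibble::tibble(
    set = set,
    label = paste0(set, "_", masses, "g"),
    mass_g = masses,
    volume_cm3 = rep_len(volume, length(masses)),
    density_g_cm3 = masses / rep_len(volume, length(masses)),
    is_standard = !is.na(standard_mass) & masses == standard_mass
  )
}

sizedisc_rows <- function(set, standard_volume) {
  vols <- c(standard_volume, comparison_volumes(standard_volume))
  # nominal mass 200 g for all size-task cylinders: volume is the
  # manipulated dimension, mass is irrelevant to the size judgment
  tibble::tibble(
    set = set,
    label = paste0(set, "_", format(vols, trim = TRUE), "cm3"),
    mass_g = 200,
    volume_cm3 = vols,
    density_g_cm3 = 200 / vols,
    is_standard = vols == standard_volume
  )
}

#' Comparison volumes for the size-discrimination task
#'
#' The comparisons vary in 5% steps from 80% to 120% of the standard's
#' volume, excluding 100%.
#'
#' @param standard_volume Standard volume in cm^3 (> 0).
#' @return Ascending numeric vector of 8 volumes.
#' @examples
#' comparison_volumes(31.8)  # 25.44 ... 38.16
#' @export
comparison_volumes <- function(standard_volume) {
  if (!is.numeric(standard_volume) || length(standard_volume) != 1L ||
      !is.finite(standard_volume) || standard_volume <= 0) {
    stop("standard volume must be a single positive number", call. = FALSE)
  }
  standard_volume * c(80, 85, 90, 95, 105, 110, 115, 120) / 100
}

#' Read/write the stimulus registry as delimited text or JSON
#'
#' @param sets Tibble from [build_standard_sets()] (or a subset).
#' @param path Output/input file path. `write_stimulus_sets()` writes
#'   a UTF-8 comma-separated file with a header row; the JSON variants
#'   serialize the registry grouped by set name.
#' @return `read_stimulus_sets()` returns the registry tibble.
#' @export
write_stimulus_sets <- function(sets, path) {
  utils::write.csv(sets, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_stimulus_sets
#' @export
read_stimulus_sets <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  tibble::as_tibble(df)
}

#' @rdname write_stimulus_sets
#' @export
stimulus_registry_json <- function(sets, path = NULL) {
  reg <- lapply(split(sets, sets$set), function(d) {
    d$set <- NULL
    d
  })
  js <- jsonlite::toJSON(reg, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
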