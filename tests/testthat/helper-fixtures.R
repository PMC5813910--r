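# shared fixtures, all built in code

exp1_conditions <- c("no_vision", "poor", "medium", "full")
exp2_conditions <- c("string", "precision", "enclosure")

# unique design cells with noiseless model-generated aggregate scores
noiseless_aggregate <- function(design, params) {
  cells <- unique(design[, c("condition", "set", "mass_g",
                             "density_g_cm3")])
  cells$score <- combined_heaviness(cells$mass_g, cells$density_g_cm3,
                                    params, cells$condition)
  cells
}

# small hand-rolled estimate table: 2 participants x 2 conditions
tiny_estimate_table <- function() {
  tibble::tibble(
    participant = rep(c(1, 2), each = 6),
    condition = rep(c("no_vision", "full"), times = 6),
    set = "big",
    mass_g = rep(c(60, 140, 230), each = 2, times = 2),
    trial = rep(1:2, each = 6) * 0 + rep(1:2, times = 6),
    estimate = c(2, 8, 1, 10, 5, 5, 0.4, 0.9, 1.6, 2, 3, 7)
  )
}

# degenerate population: every participant equals the aggregate fit
point_population <- function(center = exp1_aggregate_params(),
                             noise_cv = 0.1) {
  population_spec(center = center,
                  sdlog = c(a = 0, x = 0, b = 0, y = 0),
                  weight_sd = 0, noise_cv = noise_cv)
}
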