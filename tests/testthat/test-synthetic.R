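test_that("experiment layouts have the published trial counts", {
  d1 <- exp1_design()
  expect_equal(nrow(d1), 312)
  # 18 stimuli x 6 blocks in the two full-information conditions,
  # 8 x 6 in the two restricted ones
  counts <- table(d1$condition)
  expect_equal(as.vector(counts[c("no_vision", "full")]), c(108L, 108L))
  expect_equal(as.vector(counts[c("poor", "medium")]), c(48L, 48L))

  d2 <- exp2_design()
  expect_equal(nrow(d2), 180)
  expect_equal(as.vector(table(d2$condition)), rep(60L, 3))
  expect_equal(length(unique(paste(d2$set, d2$mass_g))), 10)
})

test_that("participant sampling is reproducible and respects bounds", {
  spec <- population_spec()
  p1 <- sample_participants(spec, 15, seed = 9)
  p2 <- sample_participants(spec, 15, seed = 9)
  expect_identical(attr(p1, "table"), attr(p2, "table"))

  tab <- attr(sample_participants(spec, 200, seed = 1), "table")
  expect_true(all(tab$a >= 0.0007 & tab$a <= 0.0271))
  expect_true(all(tab$x >= 0.75 & tab$x <= 1.51))
  expect_true(all(tab$b >= 0.59 & tab$b <= 2.1))
  expect_true(all(tab$y >= 0.27 & tab$y <= 0.77))
  expect_true(all(tab$w_full >= 0 & tab$w_full <= 1))
  # no-information condition stays at exactly zero weight
  expect_true(all(tab$w_no_vision == 0))

  # zero spread collapses to the center
  pt <- sample_participants(point_population(), 5, seed = 2)
  for (p in pt) expect_equal(p$a, exp1_aggregate_params()$a)

  # medians near the centers at large n
  big <- attr(sample_participants(spec, 1000, seed = 3), "table")
  cen <- exp1_aggregate_params()
  expect_lt(abs(median(big$x) / cen$x - 1), 0.05)
  expect_lt(abs(median(big$y) / cen$y - 1), 0.05)
  expect_lt(abs(median(big$w_full) - cen$weights[["full"]]), 0.05)
})

test_that("magnitude simulation matches the design and noise model", {
  spec <- point_population(noise_cv = 0)
  parts <- sample_participants(spec, 2, seed = 1)
  sim <- simulate_magnitude_dataset(parts, exp1_design(), spec, seed = 1)
  per_part <- table(sim$data$participant)
  expect_equal(as.vector(per_part), c(312L, 312L))
  # noiseless limit: every trial equals the model prediction
  pred <- combined_heaviness(sim$data$mass_g, sim$data$density_g_cm3,
                             parts[[1]], sim$data$condition)
  expect_equal(sim$data$estimate, pred, tolerance = 1e-12)

  spec2 <- point_population(center = exp2_aggregate_params(),
                            noise_cv = 0)
  parts2 <- sample_participants(spec2, 2, seed = 1)
  sim2 <- simulate_magnitude_dataset(parts2, exp2_design(), spec2,
                                     seed = 1)
  expect_equal(as.vector(table(sim2$data$participant)), c(180L, 180L))

  # same seed, byte-identical output; different seed differs (with noise)
  specn <- point_population(center = exp2_aggregate_params(),
                            noise_cv = 0.1)
  a <- simulate_magnitude_dataset(parts2, exp2_design(), specn, seed = 5)
  b <- simulate_magnitude_dataset(parts2, exp2_design(), specn, seed = 5)
  expect_identical(a$data, b$data)
  c2 <- simulate_magnitude_dataset(parts2, exp2_design(), specn, seed = 6)
  expect_false(identical(a$data, c2$data))

  # truth travels with the data
  expect_identical(sim$truth, parts)

  # a condition without a participant weight is an error
  bad <- model_params(1, 1, 1, 1, weights = c(full = 0.2))
  expect_error(simulate_magnitude_dataset(list(bad), exp1_design(), spec),
               "no weight for condition")
})

test_that("noise realizations have roughly the requested CV", {
  spec <- point_population(noise_cv = 0.1)
  parts <- sample_participants(spec, 1, seed = 1)
  sim <- simulate_magnitude_dataset(parts, exp1_design(), spec, seed = 8)
  pred <- combined_heaviness(sim$data$mass_g, sim$data$density_g_cm3,
                             parts[[1]], sim$data$condition)
  ratio <- sim$data$estimate / pred
  expect_lt(abs(sd(log(ratio)) / sqrt(log(1 + 0.1^2)) - 1), 0.2)
})

test_that("2IFC simulation has the published trial-count bounds", {
  p <- exp2_aggregate_params()
  sets <- build_standard_sets()
  total <- 0
  for (grip in c("precision", "enclosure")) {
    for (setname in c("exp3_small", "exp3_big")) {
      s <- sets[sets$set == setname, ]
      std <- s[s$is_standard, ]
      comps <- s$mass_g[!s$is_standard]
      sim <- simulate_2ifc_dataset(p, std$mass_g, std$density_g_cm3,
                                   comps, grip, blocks = 10,
                                   discard = FALSE, seed = 4)
      total <- total + sum(sim$data$n_trials)
    }
  }
  # full grid: 2 grips x (10 + 13 comparisons) x 10 blocks
  expect_equal(total, 460)
})

test_that("discarding only reduces trials for extreme comparisons", {
  p <- exp2_aggregate_params()
  sets <- build_standard_sets()
  s <- sets[sets$set == "exp3_big", ]
  comps <- s$mass_g[!s$is_standard]
  sim <- simulate_2ifc_dataset(p, 200, 200 / 596, comps, "precision",
                               blocks = 10, sigma_d = 0.05,
                               discard = TRUE, seed = 4)
  expect_true(sum(sim$data$n_trials) <= 13 * 10)
  # dropped comparisons keep their partial counts
  expect_true(all(sim$data$n_trials >= 2))
  # every dropped mass is more extreme than every kept mass on its side
  kept <- sim$state$retained
  dropped <- setdiff(comps, kept)
  expect_gt(length(dropped), 0)  # sigma_d = 0.05 forces near-steps
  for (d in dropped[dropped > 200]) {
    expect_true(all(kept[kept > 200] < d))
  }
  for (d in dropped[dropped < 200]) {
    expect_true(all(kept[kept < 200] > d))
  }
})

test_that("simulated response rates follow the decision model", {
  p <- exp2_aggregate_params()
  pse <- predict_pse(p, "precision", 200, 200 / 596)
  # a comparison placed exactly at the predicted PSE is judged heavier
  # about half of the time
  sim <- simulate_2ifc_dataset(p, 200, 200 / 596, pse, "precision",
                               blocks = 4000, sigma_d = 0.2, seed = 12)
  prop <- sim$data$n_comparison_heavier / sim$data$n_trials
  expect_lt(abs(prop - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("pipeline closure: simulate, standardize, score, fit", {
  truth <- exp1_aggregate_params()
  spec <- point_population(noise_cv = 0)
  parts <- sample_participants(spec, 3, seed = 1)
  sim <- simulate_magnitude_dataset(parts, exp1_design(), spec, seed = 1)
  sc <- condition_scores(standardize_estimates(sim$data))
  fit <- fit_model(sc, fit_spec(exp1_conditions,
                                fixed = list(w_no_vision = 0),
                                seed = 1))
  # standardization rescales the shared magnitude scale, so a and b are
  # recovered up to a common factor; exponents and weights are absolute
  expect_gte(fit$r_squared, 0.999)
  expect_lt(abs(fit$params$x / truth$x - 1), 0.01)
  expect_lt(abs(fit$params$y / truth$y - 1), 0.01)
  expect_equal(fit$params$weights[exp1_conditions],
               truth$weights[exp1_conditions], tolerance = 0.01)
  expect_lt(abs(fit$params$a / fit$params$b -
                  truth$a / truth$b) / (truth$a / truth$b), 0.01)
})
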