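make_2ifc_counts <- function(mu, sigma, n_per, masses = seq(170, 230,
                                                            by = 6),
                             seed = NULL) {
  p <- pnorm((masses - mu) / sigma)
  k <- if (is.null(seed)) {
    round(n_per * p)
  } else {
    withr::with_seed(seed, rbinom(length(masses), n_per, p))
  }
  tibble::tibble(comparison_mass = masses, n_trials = n_per,
                 n_comparison_heavier = k)
}

test_that("cumulative Gaussian fit recovers generating PSE and JND", {
  d <- make_2ifc_counts(200, 15, 1000, seed = 21)
  fit <- fit_cumulative_gaussian(d)
  expect_true(fit$converged)
  expect_lt(abs(fit$mu - 200), 1)
  expect_lt(abs(fit$sigma - 15), 1.5)

  # agreement with an independent probit-regression oracle
  glm_fit <- glm(cbind(n_comparison_heavier,
                       n_trials - n_comparison_heavier) ~ comparison_mass,
                 family = binomial("probit"), data = d)
  mu_glm <- -coef(glm_fit)[1] / coef(glm_fit)[2]
  sigma_glm <- 1 / coef(glm_fit)[2]
  expect_equal(fit$mu, unname(mu_glm), tolerance = 1e-3)
  expect_equal(fit$sigma, unname(sigma_glm), tolerance = 1e-3)
})

test_that("symmetric proportions give the symmetric PSE", {
  masses <- c(180, 190, 200, 210, 220)
  d <- tibble::tibble(comparison_mass = masses, n_trials = 100,
                      n_comparison_heavier = c(5, 25, 50, 75, 95))
  fit <- fit_cumulative_gaussian(d)
  expect_equal(fit$mu, 200, tolerance = 1e-6)
  # the 84.1% point sits one JND above the PSE
  p_at_jnd <- pnorm((fit$mu + fit$sigma - fit$mu) / fit$sigma)
  expect_equal(p_at_jnd, 0.841, tolerance = 1e-3)
})

test_that("psychometric fit ignores empty rows and row order", {
  d <- make_2ifc_counts(195, 12, 500, seed = 3)
  base <- fit_cumulative_gaussian(d)
  shuffled <- d[rev(seq_len(nrow(d))), ]
  with_empty <- dplyr::bind_rows(
    shuffled,
    tibble::tibble(comparison_mass = c(100, 300), n_trials = 0L,
                   n_comparison_heavier = 0L)
  )
  alt <- fit_cumulative_gaussian(with_empty)
  expect_equal(alt$mu, base$mu, tolerance = 1e-9)
  expect_equal(alt$sigma, base$sigma, tolerance = 1e-9)
})

test_that("degenerate response patterns are rejected or flagged", {
  masses <- seq(170, 230, by = 10)
  all_heavy <- tibble::tibble(comparison_mass = masses, n_trials = 10,
                              n_comparison_heavier = 10)
  expect_error(fit_cumulative_gaussian(all_heavy), "not identifiable")

  step <- tibble::tibble(comparison_mass = masses, n_trials = 10,
                         n_comparison_heavier = c(0, 0, 0, 10, 10, 10,
                                                  10))
  expect_warning(fit <- fit_cumulative_gaussian(step), "lower bound")
  expect_true(fit$boundary)
})

test_that("weber fractions reproduce the printed size-task values", {
  expect_equal(weber_fraction(5.72, 31.8), 0.18, tolerance = 0.005)
  expect_equal(weber_fraction(59.6, 596), 0.10, tolerance = 1e-12)
  expect_equal(weber_fraction(0, 10), 0)
  expect_error(weber_fraction(1, 0), "positive")
})

test_that("PSE prediction inverts the mass power law", {
  # zero density weight: the PSE is the standard's mass, exactly
  p0 <- model_params(0.0014, 1.37, 1.08, 0.74, weights = c(string = 0))
  expect_identical(predict_pse(p0, "string", 200, 0.3356), 200)
  p_arb <- model_params(2.7, 0.9, 0.4, 1.8, weights = c(c = 0))
  expect_equal(predict_pse(p_arb, "c", 123.4, 5), 123.4,
               tolerance = 1e-12)

  # printed haptic-experiment aggregate parameters, precision grip
  p <- exp2_aggregate_params()
  pse <- predict_pse(p, "precision", 200, 200 / 596)
  expect_equal(pse, 164.49, tolerance = 1e-2)
  expect_lt(abs(pse - 165) / 165, 0.01)
  # enclosure weight pushes the PSE further down
  p42 <- model_params(p$a, p$x, p$b, p$y, weights = c(g = 0.42))
  expect_equal(predict_pse(p42, "g", 200, 200 / 596), 151.1,
               tolerance = 0.1)
})

test_that("predicted PSE increases with standard density", {
  p <- exp2_aggregate_params()
  rhos <- seq(0.1, 7, length.out = 25)
  pses <- sapply(rhos, function(r) predict_pse(p, "enclosure", 200, r))
  expect_true(all(diff(pses) > 0))
})

test_that("discard rule drops only long fully-consistent extreme runs", {
  comps <- c(170, 180, 186, 194, 198, 202, 206, 214, 220, 230)
  st <- discard_state(comps, 200)

  # heaviest four all-consistent, fifth not: drop exactly the heaviest
  cons <- setNames(rep("mixed", 10), comps)
  cons[c("230", "220", "214", "206")] <- "heavier"
  out <- apply_discard_rule(st, cons, 2)
  expect_setequal(setdiff(comps, out$retained), 230)

  # only three consistent: below the "more than three" threshold
  cons2 <- setNames(rep("mixed", 10), comps)
  cons2[c("230", "220", "214")] <- "heavier"
  expect_equal(apply_discard_rule(st, cons2, 2)$retained, sort(comps))

  # after block 5, two or more consistent: keep the least-extreme one
  cons3 <- setNames(rep("mixed", 10), comps)
  cons3[c("230", "220", "214")] <- "heavier"
  out5 <- apply_discard_rule(st, cons3, 5)
  expect_setequal(setdiff(comps, out5$retained), c(230, 220))

  # mirrored at the light end
  cons4 <- setNames(rep("mixed", 10), comps)
  cons4[c("170", "180", "186", "194")] <- "lighter"
  outl <- apply_discard_rule(st, cons4, 2)
  expect_setequal(setdiff(comps, outl$retained), 170)

  # a gap in the run does not trigger: run must be contiguous from the
  # extreme
  cons5 <- setNames(rep("mixed", 10), comps)
  cons5[c("230", "214", "206", "202")] <- "heavier"
  expect_equal(apply_discard_rule(st, cons5, 2)$retained, sort(comps))

  expect_error(apply_discard_rule(st, cons, 3), "boundaries 2 and 5")
})

test_that("discard rule never removes mixed comparisons and only shrinks", {
  comps <- c(170, 180, 186, 194, 198, 202, 206, 214, 220, 230)
  set.seed(42)
  for (i in 1:50) {
    st <- discard_state(comps, 200)
    cons <- setNames(sample(c("heavier", "lighter", "mixed"), 10,
                            replace = TRUE), comps)
    st2 <- apply_discard_rule(st, cons, 2)
    expect_true(all(st2$retained %in% st$retained))
    dropped <- setdiff(st$retained, st2$retained)
    expect_false(any(cons[as.character(dropped)] == "mixed"))
    st5 <- apply_discard_rule(st2, cons, 5)
    expect_true(all(st5$retained %in% st2$retained))
  }
})

test_that("discard audit log records removals as JSON", {
  comps <- c(170, 180, 186, 194, 198, 202, 206, 214, 220, 230)
  st <- discard_state(comps, 200)
  cons <- setNames(rep("mixed", 10), comps)
  cons[c("230", "220", "214", "206", "202")] <- "heavier"
  st <- apply_discard_rule(st, cons, 2)
  js <- jsonlite::fromJSON(discard_log_json(st))
  expect_equal(js$log$boundary, 2)
  expect_setequal(unlist(js$log$dropped), c(220, 230))
})
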