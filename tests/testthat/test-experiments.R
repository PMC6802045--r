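test_that("the factorial enumerator crosses all factors with per-replicate seeds", {
  d <- build_design()
  ex <- d[d$experiment_id > 0L, ]
  expect_equal(length(unique(ex$experiment_id)), 120L)
  expect_equal(nrow(ex), 3840L)
  expect_equal(sum(d$experiment_id == 0L), 32L)
  expect_false(anyDuplicated(d$seed) > 0)
  expect_true(all(d$seed >= 0 & d$seed < 2^31))
  d2 <- build_design(functions = "linear", landscape_levels = 0.1,
                     cell_levels = 0.5, replicates = 2L, controls = 0L)
  d2 <- d2[d2$experiment_id > 0L, ]
  expect_equal(nrow(d2), 2L)
  expect_false(d2$seed[1] == d2$seed[2])
  expect_error(build_design(functions = c("linear", "linear")), "duplicate")
  expect_error(build_design(functions = character(0)), "non-empty")
})

test_that("outcome metrics follow their definitions", {
  s <- data.frame(tick = 1:300, adult_f_start = 50, starv_f = 0)
  s$starv_f[250] <- 1
  run <- structure(list(series = s, final_population = 77L,
                        mean_territory_km2 = 328 * 0.0625,
                        final_territory_cells = rep(328L, 10),
                        morans_i = 0.9),
                   class = "run_record")
  oc <- compute_outcomes(run)
  expect_equal(oc$starvation_rate, 1 / (50 * 100))
  expect_equal(oc$territory_km2, 20.5)
  expect_equal(oc$population, 77L)
  # no starvation at all
  s$starv_f <- 0
  run$series <- s
  expect_equal(compute_outcomes(run)$starvation_rate, 0)
  expect_error(compute_outcomes(list()), "run_record")
})

test_that("a toy suite runs, resumes idempotently and tolerates failures", {
  g <- make_circle_landscape(120, 4.84)
  cfg <- sim_config(landscape = g, burn_in = 15L, horizon_post = 15L,
                    n_females = 5L, n_males = 3L)
  d <- build_design(functions = "linear", landscape_levels = c(0.1, 0.25),
                    cell_levels = 1, replicates = 2L, base_seed = 3L,
                    controls = 2L)
  cache_dir <- file.path(tempdir(), "suite-toy")
  out1 <- run_experiment_suite(d, cfg, out_dir = cache_dir)
  expect_equal(nrow(out1), 6L)
  expect_true(all(!is.na(out1$population)))
  # Moran's I shared within each experiment from replicate 1
  for (e in unique(out1$experiment_id[out1$experiment_id > 0]))
    expect_length(unique(out1$morans_i[out1$experiment_id == e]), 1L)
  out2 <- run_experiment_suite(d, cfg, out_dir = cache_dir)
  expect_equal(out1$population, out2$population)
  expect_equal(out1$territory_km2, out2$territory_km2)
  # an invalid row fails alone, recorded as missing plus a failure report
  bad <- d
  bad$fun[3] <- "bogus"
  out3 <- run_experiment_suite(bad, cfg)
  expect_equal(sum(is.na(out3$population)), 1L)
  expect_length(attr(out3, "failures"), 1L)
})

test_that("the gamma GLM stage recovers known coefficients", {
  set.seed(31)
  d <- build_design(replicates = 32L)
  land25 <- d$landscape_fraction == 0.25
  cell25 <- d$cell_fraction == 0.25
  mu_t <- exp(log(20.51) + 0.15 * land25 + 0.04 * cell25)
  shape <- 60
  d$territory_km2 <- rgamma(nrow(d), shape = shape, rate = shape / mu_t)
  mu_p <- exp(log(156) - 0.31 * land25 - 0.14 * cell25)
  d$population <- rnbinom(nrow(d), size = 60, mu = mu_p)
  d$morans_i <- rgamma(nrow(d), shape = shape, rate = shape / 0.8)
  d$starvation_rate <- 0.003
  m <- fit_outcome_models(d)
  tt <- m$territory
  est <- tt$estimate[tt$term == "landscape_25"]
  se <- tt$se[tt$term == "landscape_25"]
  expect_lt(abs(est - 0.15), 2 * se)
  est_c <- tt$estimate[tt$term == "cell_25"]
  expect_lt(abs(est_c - 0.04), 2 * tt$se[tt$term == "cell_25"])
  pp <- m$population
  expect_lt(abs(pp$estimate[pp$term == "landscape_25"] + 0.31),
            2 * pp$se[pp$term == "landscape_25"])
  expect_lt(abs(pp$estimate[pp$term == "cell_25"] + 0.14),
            2 * pp$se[pp$term == "cell_25"])
  # the control level ties the three factors: the landscape-5% and
  # random-function columns are the linearly dependent ones dropped
  dropped <- tt$term[tt$dropped]
  expect_setequal(dropped, c("landscape_5", "random"))
})

test_that("degenerate and helper cases behave", {
  d <- build_design(functions = c("linear", "random"),
                    landscape_levels = c(0.1, 0.25), cell_levels = c(0.5, 1),
                    replicates = 4L, controls = 4L)
  d$territory_km2 <- 20.51
  d$population <- rep(c(149L, 150L, 151L), length.out = nrow(d))
  d$morans_i <- 0.8
  d$starvation_rate <- 0
  m <- suppressWarnings(fit_outcome_models(d))
  tt <- m$territory
  expect_equal(tt$estimate[tt$term == "(Intercept)"], log(20.51),
               tolerance = 1e-6)
  others <- tt$estimate[tt$term != "(Intercept)" & !tt$dropped]
  expect_true(all(abs(others) < 1e-6))
  expect_equal(exp_effect(20.51, 0.04), 20.51 * exp(0.04))
  expect_equal(round(exp_effect(20.51, 0.04), 2), 21.35)
  expect_error(model_coef(tt, "nope"), "no term")
})

test_that("Moran's-I-as-covariate models use rows with a defined statistic", {
  set.seed(8)
  d <- build_design(replicates = 8L, controls = 8L)
  d$morans_i <- ifelse(d$experiment_id == 0L, NA,
                       0.9 - 0.3 * d$cell_fraction + rnorm(nrow(d), 0, 0.02))
  mu <- exp(log(20) + 0.1 * d$morans_i)
  mu[is.na(mu)] <- 20
  d$territory_km2 <- rgamma(nrow(d), 80, rate = 80 / mu)
  d$population <- rnbinom(nrow(d), size = 50,
                          mu = ifelse(is.na(d$morans_i), 150,
                                      exp(log(150) - 0.2 * d$morans_i)))
  d$starvation_rate <- 0
  m <- fit_outcome_models(d)
  tvm <- m$territory_vs_morans
  expect_true("morans_i" %in% tvm$term)
  expect_gt(tvm$estimate[tvm$term == "morans_i"], 0)
  pvm <- m$population_vs_morans
  expect_lt(pvm$estimate[pvm$term == "morans_i"], 0)
})
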