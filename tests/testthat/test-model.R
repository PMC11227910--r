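# one simulated plot reused across model tests (3 censuses for interval
# bookkeeping checks)
local_sim <- local({
  cfg <- sim_config(n_adults = 1500, n_species_adult = 40,
                    n_species_seedling = 25, n_species_liana = 2,
                    n_seedlings_init = 400, n_recruits_year = 30,
                    census_years = 2020:2022, n_null = 49)
  sim <- simulate_plot(cfg, seed = 21)
  dmat <- patristic_matrix(sim$phylogeny)
  idx <- indices_table(sim$plot, dmat, n_null = 49, seed = 5)
  list(sim = sim, dmat = dmat, idx = idx)
})

test_that("build_dataset standardizes covariates and tracks eligibility", {
  sim <- local_sim$sim
  ds <- build_dataset(sim$plot, local_sim$idx, sim$pca$scores,
                      interval = c(2020, 2021), variant = "apd")
  num <- c("height", "s_con", "a_con", "s_index", "a_index", "light",
           "pca1", "pca2", "pca3")
  for (v in num) {
    expect_lt(abs(mean(ds$data[[v]])), 1e-10)
    expect_lt(abs(stats::sd(ds$data[[v]]) - 1), 1e-10)
  }
  expect_true(all(ds$data$outcome %in% 0:1))
  expect_equal(nrow(ds$constants), 9)

  # only seedlings alive at interval start enter; lianas never focal
  st0 <- sim$plot$seedlings$status_2020
  dead_or_unrecruited <- sim$plot$seedlings$tag[is.na(st0) | st0 != "A"]
  expect_length(intersect(ds$data$tag, dead_or_unrecruited), 0)
  expect_length(intersect(unique(ds$data$species),
                          sim$plot$non_focal_species), 0)

  # absorbing death: dead in 2021 stays an 0 outcome over (2020, 2022)
  ds2 <- build_dataset(sim$plot, local_sim$idx, sim$pca$scores,
                       interval = c(2020, 2022), variant = "apd")
  died_y1 <- sim$plot$seedlings$tag[!is.na(st0) & st0 == "A" &
                                    sim$plot$seedlings$status_2021 == "D"]
  common <- intersect(died_y1, ds2$data$tag)
  expect_gt(length(common), 0)
  expect_true(all(ds2$data$outcome[match(common, ds2$data$tag)] == 0))

  expect_error(build_dataset(sim$plot, local_sim$idx, sim$pca$scores,
                             interval = c(2021, 2020)), "invalid interval")
})

test_that("fit_glmm returns a complete fit with lme4 AIC bookkeeping", {
  sim <- local_sim$sim
  ds <- build_dataset(sim$plot, local_sim$idx, sim$pca$scores,
                      interval = c(2020, 2021), variant = "apd")
  fit <- fit_glmm(ds)
  expect_s3_class(fit, "model_fit")
  expect_false(fit$separation)
  expect_equal(nrow(fit$coefficients), 10)  # intercept + 9 slopes
  # AIC counts intercept + 9 slopes + 2 variance components: k = 12
  expect_equal(fit$aic, 2 * 12 - 2 * fit$loglik)
  expect_true(all(c("quadrat", "species") %in% names(fit$varcomp)))
  expect_true(fit$r2_conditional >= 0 && fit$r2_conditional <= 1)
  expect_equal(fit$n_obs, nrow(ds$data))
})

test_that("model fits serialize to JSON and CSV", {
  sim <- local_sim$sim
  ds <- build_dataset(sim$plot, local_sim$idx, sim$pca$scores,
                      interval = c(2020, 2021), variant = "totpd")
  fit <- fit_glmm(ds)
  dir <- withr::local_tempdir()
  write_model_fit(fit, file.path(dir, "fit.json"),
                  coef_csv = file.path(dir, "coef.csv"))
  j <- jsonlite::read_json(file.path(dir, "fit.json"))
  expect_equal(j$aic, fit$aic)
  expect_equal(j$varcomp$quadrat, unname(fit$varcomp["quadrat"]))
  cc <- utils::read.csv(file.path(dir, "coef.csv"))
  expect_equal(cc$estimate, fit$coefficients$estimate)
})

test_that("complete separation is flagged, not raised", {
  sim <- local_sim$sim
  ds <- build_dataset(sim$plot, local_sim$idx, sim$pca$scores,
                      interval = c(2020, 2021), variant = "apd")
  ds$data$outcome <- 1L
  fit <- fit_glmm(ds)
  expect_true(fit$separation)
  expect_true(is.na(fit$aic))
})

test_that("conditional R2 evaluates its closed form", {
  expect_equal(conditional_r2(list(var_fixed = 1,
                                   varcomp = c(quadrat = 0.25, species = 0.25))),
               1.5 / (1.5 + pi^2 / 3))
  expect_equal(conditional_r2(list(var_fixed = 0,
                                   varcomp = c(quadrat = 0, species = 0))), 0)
  r_lo <- conditional_r2(list(var_fixed = 0.5, varcomp = c(0.1, 0.1)))
  r_hi <- conditional_r2(list(var_fixed = 0.5, varcomp = c(0.5, 0.1)))
  expect_gt(r_hi, r_lo)
})

test_that("effect classification follows the significance bands", {
  expect_equal(classify_effect(0.03, 0.4)[c("class", "sign")],
               list(class = "significant", sign = "positive"))
  expect_equal(classify_effect(0.07, -0.2)$class, "marginal")
  expect_equal(classify_effect(0.5, 0.1)$class, "none")
  expect_equal(classify_effect(0.02, 0.3)$interpretation,
               "phylogenetic negative density dependence")
  expect_equal(classify_effect(0.02, -0.3)$interpretation,
               "phylogenetic positive density dependence")
  expect_error(classify_effect(1.2, 0), "p must be")
})

test_that("adding a truly predictive covariate usually lowers AIC", {
  # fixed-effect-only logistic world; majority criterion over replicates
  set.seed(31)
  wins <- 0L
  for (r in 1:20) {
    n <- 400
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.3 + 0.8 * x))
    with_x <- stats::AIC(stats::glm(y ~ x, family = binomial()))
    without <- stats::AIC(stats::glm(y ~ 1, family = binomial()))
    wins <- wins + (with_x < without)
  }
  expect_gt(wins, 10)
})

test_that("permuted outcomes rarely produce |z| > 1.96", {
  sim <- local_sim$sim
  ds <- build_dataset(sim$plot, local_sim$idx, sim$pca$scores,
                      interval = c(2020, 2021), variant = "apd")
  set.seed(17)
  zs <- c()
  for (r in 1:5) {
    dsp <- ds
    dsp$data$outcome <- sample(dsp$data$outcome)
    fit <- fit_glmm(dsp)
    zs <- c(zs, abs(fit$coefficients$z[-1]))  # slopes only
  }
  expect_gte(mean(zs < 1.96), 0.9)
})
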