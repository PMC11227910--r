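test_that("simulation is deterministic given the seed", {
  cfg <- fast_sim_config()
  s1 <- simulate_plot(cfg, seed = 4)
  s2 <- simulate_plot(cfg, seed = 4)
  expect_identical(s1$plot$adults, s2$plot$adults)
  expect_identical(s1$plot$seedlings, s2$plot$seedlings)
  expect_identical(s1$plot$habitat, s2$plot$habitat)
  expect_identical(ape::write.tree(s1$phylogeny), ape::write.tree(s2$phylogeny))
  expect_identical(s1$truth$p_survive, s2$truth$p_survive)
  s3 <- simulate_plot(cfg, seed = 5)
  expect_false(identical(s1$plot$seedlings, s3$plot$seedlings))
})

test_that("census eligibility rules are enforced at generation", {
  sim <- simulate_plot(fast_sim_config(), seed = 4)
  expect_true(all(sim$plot$adults$dbh >= 1))
  h0 <- sim$plot$seedlings$height_2020
  expect_true(all(h0[!is.na(h0)] >= 20))
  expect_true(all(sim$plot$seedlings$species %in% sim$phylogeny$tip.label))
})

test_that("survival rates follow the logistic intercept in the null world", {
  beta0_null <- fast_sim_config(
    beta0 = 0, sigma_q = 0, sigma_s = 0,
    beta = c(height = 0, s_con = 0, a_con = 0, s_index = 0, a_index = 0,
             light = 0, pca1 = 0, pca2 = 0, pca3 = 0))
  sim <- simulate_plot(beta0_null, seed = 9)
  s0 <- sim$plot$seedlings$status_2020
  st <- sim$plot$seedlings$status_2021[!is.na(s0) & s0 == "A"]
  rate <- mean(st == "A")
  n <- length(st)
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / n))

  high <- fast_sim_config(
    beta0 = 4, sigma_q = 0, sigma_s = 0,
    beta = c(height = 0, s_con = 0, a_con = 0, s_index = 0, a_index = 0,
             light = 0, pca1 = 0, pca2 = 0, pca3 = 0))
  sim2 <- simulate_plot(high, seed = 9)
  s02 <- sim2$plot$seedlings$status_2020
  st2 <- sim2$plot$seedlings$status_2021[!is.na(s02) & s02 == "A"]
  expect_lt(abs(mean(st2 == "A") - plogis(4)),
            3 * sqrt(plogis(4) * (1 - plogis(4)) / length(st2)) + 0.005)
})

test_that("latent habitat factors surface in the PCA", {
  sim <- simulate_plot(fast_sim_config(), seed = 13)
  vf <- sim$pca$variance_fraction
  # soil variables are 3-factor mixtures: the leading 3 components must
  # concentrate at least half of the 13-variable variance
  expect_gt(sum(vf[1:3]), 0.5)
})

test_that("dispersal couples seedling composition to local adult density", {
  sim <- simulate_plot(fast_sim_config(n_seedlings_init = 600), seed = 14)
  p <- sim$plot
  st <- p$seedlings$status_2020
  alive <- !is.na(st) & st == "A"
  qd <- p$quadrats
  # per-quadrat mean S_con vs conspecific adult count within 20 m
  scon_q <- acon_q <- numeric(nrow(qd))
  for (q in seq_len(nrow(qd))) {
    rows <- which(alive & p$seedlings$quadrat_id == qd$quadrat_id[q])
    if (!length(rows)) { scon_q[q] <- NA; next }
    scon_q[q] <- mean(vapply(p$seedlings$tag[rows], function(tg)
      s_con(p, tg, 2020), numeric(1)))
    d <- sqrt((p$adults$x - qd$center_x[q])^2 + (p$adults$y - qd$center_y[q])^2)
    acon_q[q] <- mean(vapply(rows, function(i)
      sum(d <= 20 & p$adults$species == p$seedlings$species[i]), numeric(1)))
  }
  keep <- !is.na(scon_q)
  expect_gt(stats::cor(scon_q[keep], acon_q[keep], method = "spearman"), 0)
})

test_that("configs are validated and written simulations round-trip", {
  expect_error(sim_config(n_species_adult = 0), "> 0")
  expect_error(sim_config(sigma_q = -1), ">= 0")
  expect_error(sim_config(n_species_seedling = 200), "subset")
  expect_error(sim_config(beta = c(height = 1)), "beta must name")

  sim <- simulate_plot(fast_sim_config(), seed = 4)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir,
    c("adults.csv", "seedlings.csv", "quadrats.csv", "habitat.csv",
      "tree.nwk", "truth.json")))))
  p2 <- read_plot(file.path(dir, "adults.csv"), file.path(dir, "seedlings.csv"),
                  file.path(dir, "quadrats.csv"), file.path(dir, "habitat.csv"))
  expect_equal(nrow(p2$seedlings), nrow(sim$plot$seedlings))
  tr <- read_newick(file.path(dir, "tree.nwk"))
  expect_equal(sort(tr$tip.label), sort(sim$phylogeny$tip.label))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$beta$s_index, sim$truth$beta[["s_index"]])
})

test_that("covariate_effect_check summarizes recovery over replicates", {
  cfg <- fast_sim_config()
  rec <- covariate_effect_check(cfg, n_reps = 2, seed = 100)
  expect_true(all(c("term", "true", "bias", "rmse", "coverage",
                    "rejection_rate") %in% names(rec$summary)))
  expect_equal(nrow(rec$summary), 10)
  expect_equal(rec$summary$true[rec$summary$term == "s_index"], 0.5)
  expect_error(covariate_effect_check(cfg, n_reps = 1), "n_reps")
})
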