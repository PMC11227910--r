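#' Configuration for the synthetic forest-plot generator
#'
#' Defaults emulate the study system: a 200 x 200 m plot on a 10 x 10 grid
#' of 20 x 20 m subplots with one 2 x 2 m seedling quadrat each; ~10,500
#' adult stems of 95 species with a log-series abundance distribution and
#' Thomas-cluster spatial aggregation; ~900 focal seedlings of a 56-species
#' subset recruited at >= 20 cm height; four annual censuses; smooth
#' spatially structured habitat (elevation trend + bumps, 10 soil variables
#' as linear mixtures of 3 latent spatial factors, lognormal canopy
#' openness). Survival follows a logit-linear model on the same
#' standardized covariates the analysis uses, with quadrat and species
#' random intercepts.
#'
#' @param extent plot extent (m). @param subplot_m subplot side (m).
#' @param n_species_adult,n_species_seedling,n_species_liana species pool
#'   sizes; seedling and liana pools are subsets of the adult pool and
#'   liana species are never focal.
#' @param n_adults adult stems. @param n_seedlings_init seedlings tagged at
#'   the first census. @param n_recruits_year expected new recruits per
#'   later census (Poisson).
#' @param census_years census years. @param tree_depth root-to-tip depth
#'   the pure-birth tree is scaled to (Myr).
#' @param logseries_p log-series parameter of the adult species-abundance
#'   distribution.
#' @param cluster_size,cluster_sd Thomas process mean stems per cluster and
#'   cluster spread (m).
#' @param dbh_meanlog,dbh_sdlog adult dbh is `1 + lognormal` (cm).
#' @param dispersal_scale exponential dispersal kernel scale (m) coupling
#'   seedling species composition to local adult density.
#' @param soil_noise_sd residual SD of each soil variable around its
#'   3-factor loading structure (factors have SD 1).
#' @param beta0 intercept of the survival model (logit scale; 2.2 gives
#'   ~90% annual survival, matching the observed cohort attrition).
#' @param beta named coefficients on the standardized covariates
#'   (`height`, `s_con`, `a_con`, `s_index`, `a_index`, `light`, `pca1`,
#'   `pca2`, `pca3`).
#' @param sigma_q,sigma_s SDs of the quadrat and species random
#'   intercepts.
#' @param variant phylogenetic index the generator (and hence the
#'   correctly-specified model) uses.
#' @param n_null shuffles used when the generator computes SES covariates.
#' @param radius_m adult neighborhood radius (m).
#' @return a `sim_config` list.
#' @export
sim_config <- function(extent = c(200, 200), subplot_m = 20,
                       n_species_adult = 95, n_species_seedling = 56,
                       n_species_liana = 4,
                       n_adults = 10546, n_seedlings_init = 900,
                       n_recruits_year = 80,
                       census_years = 2020:2023, tree_depth = 200,
                       logseries_p = 0.99,
                       cluster_size = 25, cluster_sd = 15,
                       dbh_meanlog = log(3), dbh_sdlog = 1,
                       dispersal_scale = 10, soil_noise_sd = 0.6,
                       beta0 = 2.2,
                       beta = c(height = 0, s_con = 0, a_con = 0,
                                s_index = 0.5, a_index = 0, light = 0.3,
                                pca1 = 0, pca2 = -0.2, pca3 = 0),
                       sigma_q = 0.5, sigma_s = 0.5,
                       variant = "apd", n_null = 999, radius_m = 20) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_species_adult, cfg$n_species_seedling, cfg$n_adults,
              cfg$n_seedlings_init, cfg$n_null)
  if (any(counts <= 0)) stop("config counts must be > 0")
  if (cfg$n_species_seedling > cfg$n_species_adult)
    stop("seedling species pool must be a subset of the adult pool")
  if (cfg$sigma_q < 0 || cfg$sigma_s < 0) stop("sigma must be >= 0")
  need <- c("height", "s_con", "a_con", "s_index", "a_index", "light",
            "pca1", "pca2", "pca3")
  if (!all(need %in% names(cfg$beta)))
    stop("beta must name all of: ", paste(need, collapse = ", "))
  structure(cfg, class = "sim_config")
}

# log-series random weights by inversion of P(K = k) = -p^k / (k log(1-p))
rlogseries <- function(n, p) {
  u <- stats::runif(n)
  k <- integer(n)
  for (i in seq_len(n)) {
    cum <- 0; kk <- 0
    repeat {
      kk <- kk + 1
      cum <- cum - p^kk / (kk * log(1 - p))
      if (u[i] <= cum || kk > 1e6) break
    }
    k[i] <- kk
  }
  k
}

# smooth random surface: linear trend + Gaussian bumps
.random_surface <- function(extent, n_bumps = 12, amp = 1, scale = 40,
                            trend = c(0, 0)) {
  cx <- stats::runif(n_bumps, 0, extent[1])
  cy <- stats::runif(n_bumps, 0, extent[2])
  a <- stats::rnorm(n_bumps, 0, amp)
  function(x, y) {
    z <- trend[1] * x / extent[1] + trend[2] * y / extent[2]
    for (b in seq_len(n_bumps))
      z <- z + a[b] * exp(-((x - cx[b])^2 + (y - cy[b])^2) / (2 * scale^2))
    z
  }
}

# reflect coordinates into [0, hi]
.reflect <- function(x, hi) {
  x <- abs(x)
  x <- hi - abs(hi - x %% (2 * hi))
  pmin(pmax(x, 0), hi)
}

#' Simulate a complete synthetic plot with known ground truth
#'
#' Generates the phylogeny, adult stem map, quadrat/habitat tables and a
#' multi-census seedling table whose survival outcomes are drawn from the
#' logit-linear model in `config`, using the package's own covariate
#' pipeline (neighborhoods, SES indices, PCA, standardization) so the
#' fitted analysis model is correctly specified. Death is absorbing;
#' annual survival draws are independent Bernoulli steps, so multi-year
#' outcomes are their products. Deterministic given `seed`; null
#' permutations inside index computation use a separate stream derived
#' from `seed` so data generation and index nulls are independently
#' reproducible.
#'
#' @param config a [sim_config()]. @param seed integer master seed.
#' @return list with `plot` (a [plot_dataset()] incl. habitat +
#'   topography), `phylogeny` (`phylo`), `truth` (betas, random-effect
#'   draws, per seedling-year survival probabilities and `index_seed`,
#'   the master seed of the index null streams), `pca`, and `indices` —
#'   the exact [indices_table()] the survival generator consumed
#'   (recomputable via `seed = truth$index_seed` with the same `n_null`).
#' @export
simulate_plot <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  ext <- config$extent
  nsp <- config$n_species_adult
  species <- sprintf("sp%03d", seq_len(nsp))

  tr <- ape::rphylo(nsp, birth = 1, death = 0)
  tr$tip.label <- sample(species)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * config$tree_depth / depth

  seedling_pool <- sort(sample(species, config$n_species_seedling))
  lianas <- sort(sample(species, config$n_species_liana))

  # adults: log-series abundances, Thomas-clustered positions
  w <- rlogseries(nsp, config$logseries_p)
  n_i <- as.vector(stats::rmultinom(1, config$n_adults, w / sum(w)))
  n_i <- pmax(n_i, 1L)
  ax <- ay <- numeric(0); asp <- character(0)
  for (s in seq_len(nsp)) {
    n_par <- max(1L, stats::rpois(1, n_i[s] / config$cluster_size))
    px <- stats::runif(n_par, 0, ext[1]); py <- stats::runif(n_par, 0, ext[2])
    pick <- sample.int(n_par, n_i[s], replace = TRUE)
    ax <- c(ax, .reflect(px[pick] + stats::rnorm(n_i[s], 0, config$cluster_sd), ext[1]))
    ay <- c(ay, .reflect(py[pick] + stats::rnorm(n_i[s], 0, config$cluster_sd), ext[2]))
    asp <- c(asp, rep(species[s], n_i[s]))
  }
  n_ad <- length(asp)
  adults <- data.frame(tag = sprintf("A%05d", seq_len(n_ad)), species = asp,
                       x = ax, y = ay,
                       dbh = 1 + stats::rlnorm(n_ad, config$dbh_meanlog,
                                               config$dbh_sdlog))

  # quadrats on the subplot grid, habitat surfaces
  n_side <- ext / config$subplot_m
  g <- expand.grid(subplot_col = seq_len(n_side[1]) - 1L,
                   subplot_row = seq_len(n_side[2]) - 1L)
  ctr <- quadrat_center(g$subplot_row, g$subplot_col,
                        subplot_m = config$subplot_m,
                        n_rows = n_side[2], n_cols = n_side[1])
  elev_f <- .random_surface(ext, n_bumps = 10, amp = 8, scale = 50,
                            trend = c(120, 25))  # high east, low west
  half <- 1  # quadrat half-side, m
  corner_dx <- c(-half, half, half, -half)
  corner_dy <- c(-half, -half, half, half)
  elev_c <- sapply(1:4, function(k)
    2135 + elev_f(ctr[, 1] + corner_dx[k], ctr[, 2] + corner_dy[k]) +
      stats::rnorm(nrow(g), 0, 0.3))
  quadrats <- data.frame(quadrat_id = sprintf("Q%03d", seq_len(nrow(g))),
                         subplot_row = g$subplot_row,
                         subplot_col = g$subplot_col,
                         center_x = ctr[, 1], center_y = ctr[, 2])
  quadrats[paste0("elev_c", 1:4)] <- elev_c

  # soil: 10 variables as mixtures of 3 latent smooth factors + noise
  fac <- sapply(1:3, function(f) {
    sf <- .random_surface(ext, n_bumps = 8, amp = 1, scale = 45)
    z <- sf(ctr[, 1], ctr[, 2]); as.vector(scale(z))
  })
  L <- matrix(stats::runif(30, 0.4, 1) * sample(c(-1, 1), 30, TRUE), 10, 3)
  soil_mean <- c(ph = 4.8, ec = 120, c = 45, ap = 12, ak = 95, tn = 3.2,
                 tp = 0.5, tk = 14, soil_temp = 14, soil_moist = 32)
  soil_scale <- c(0.4, 30, 12, 4, 25, 0.8, 0.12, 3, 1.5, 7)
  soil <- sapply(1:10, function(j) {
    z <- fac %*% L[j, ] + stats::rnorm(nrow(g), 0, config$soil_noise_sd)
    soil_mean[j] + soil_scale[j] * as.vector(scale(z))
  })
  colnames(soil) <- SOIL_VARS
  habitat <- data.frame(quadrat_id = quadrats$quadrat_id, soil,
                        gli = stats::rlnorm(nrow(g), log(8), 0.4))

  # seedling placement: species drawn from dispersal-weighted local adults
  qw <- vapply(seq_len(nrow(g)), function(q) {
    d <- sqrt((adults$x - ctr[q, 1])^2 + (adults$y - ctr[q, 2])^2)
    sum(exp(-d / config$dispersal_scale))
  }, numeric(1))
  qw <- qw + mean(qw)  # background so every quadrat can receive seedlings
  # quadrat x species dispersal-weight matrix, computed once
  spw <- t(vapply(seq_len(nrow(g)), function(q) {
    d <- sqrt((adults$x - ctr[q, 1])^2 + (adults$y - ctr[q, 2])^2)
    keep <- d < 4 * config$radius_m & adults$species %in% seedling_pool
    wv <- tapply(exp(-d[keep] / config$dispersal_scale),
                 adults$species[keep], sum)
    w <- stats::setNames(rep(0.2, length(seedling_pool)), seedling_pool)
    w[names(wv)] <- w[names(wv)] + wv
    w
  }, numeric(length(seedling_pool))))
  place <- function(n) {
    q <- sample.int(nrow(g), n, replace = TRUE, prob = qw)
    sp <- vapply(q, function(qi)
      sample(seedling_pool, 1, prob = spw[qi, ]), character(1))
    data.frame(quadrat_id = quadrats$quadrat_id[q], species = sp)
  }

  yrs <- config$census_years
  init <- place(config$n_seedlings_init)
  n0 <- nrow(init)
  seedlings <- data.frame(tag = sprintf("S%05d", seq_len(n0)),
                          quadrat_id = init$quadrat_id,
                          species = init$species)
  for (y in yrs) {
    seedlings[[paste0("status_", y)]] <- NA_character_
    seedlings[[paste0("height_", y)]] <- NA_real_
  }
  seedlings[[paste0("status_", yrs[1])]] <- "A"
  seedlings[[paste0("height_", yrs[1])]] <- 20 + stats::rlnorm(n0, log(15), 0.7)

  u_q <- stats::setNames(stats::rnorm(nrow(g), 0, config$sigma_q),
                         quadrats$quadrat_id)
  v_s <- stats::setNames(stats::rnorm(nsp, 0, config$sigma_s), species)

  # interim datasets carry only the censuses simulated so far, so the
  # "status at every census after recruitment" invariant holds throughout
  mk_plot <- function(upto) {
    p <- plot_dataset(adults, seedlings, quadrats, habitat,
                      census_years = yrs[seq_len(upto)], extent = ext,
                      species_pool = tr$tip.label,
                      non_focal_species = lianas)
    add_topography(p)
  }
  plt <- mk_plot(1L)
  pca <- habitat_pca(plt$habitat)

  idx_seed <- .stream_seed(seed, "index-null-stream")
  idx_all <- list()
  truth_p <- list()
  bnames <- c("height", "s_con", "a_con", "s_index", "a_index", "light",
              "pca1", "pca2", "pca3")
  beta <- config$beta[bnames]

  for (step in seq_len(length(yrs) - 1L)) {
    y0 <- yrs[step]; y1 <- yrs[step + 1L]
    rng_state <- .Random.seed
    idx <- indices_table(plt, patristic_matrix(tr), years = y0,
                         n_null = config$n_null, radius_m = config$radius_m,
                         seed = idx_seed)
    idx_all[[length(idx_all) + 1L]] <- idx
    # index nulls live on their own streams; restore the generator stream
    assign(".Random.seed", rng_state, envir = globalenv())

    cov <- .assemble_covariates(plt, idx, pca$scores, y0,
                                variant = config$variant,
                                radius_m = config$radius_m)
    X <- as.matrix(cov[, bnames])
    cc <- stats::complete.cases(X)
    Xs <- X
    for (j in seq_len(ncol(X))) {
      m <- mean(X[cc, j]); s <- stats::sd(X[cc, j])
      Xs[, j] <- (X[, j] - m) / (if (!is.na(s) && s > 0) s else 1)
    }
    Xs[is.na(Xs)] <- 0  # rows the analysis will drop: covariate term off
    eta <- config$beta0 + as.vector(Xs %*% beta) +
      u_q[cov$quadrat_id] + v_s[cov$species]
    p_surv <- stats::plogis(eta)
    i <- match(cov$tag, seedlings$tag)
    alive <- stats::rbinom(length(p_surv), 1, p_surv) == 1
    seedlings[[paste0("status_", y1)]][i] <- ifelse(alive, "A", "D")
    hj <- paste0("height_", y1)
    h0 <- seedlings[[paste0("height_", y0)]][i]
    seedlings[[hj]][i[alive]] <-
      h0[alive] * exp(stats::rnorm(sum(alive), 0.08, 0.03))
    truth_p[[length(truth_p) + 1L]] <-
      data.frame(tag = cov$tag, year = y0, p_survive = p_surv,
                 complete = cc)

    # liana (non-focal) seedlings survive on intercept + random effects
    st0 <- seedlings[[paste0("status_", y0)]]
    nf <- which(!is.na(st0) & st0 == "A" & !(seedlings$tag %in% cov$tag))
    if (length(nf)) {
      pn <- stats::plogis(config$beta0 + u_q[seedlings$quadrat_id[nf]] +
                          v_s[seedlings$species[nf]])
      al <- stats::rbinom(length(nf), 1, pn) == 1
      seedlings[[paste0("status_", y1)]][nf] <- ifelse(al, "A", "D")
      seedlings[[hj]][nf[al]] <-
        seedlings[[paste0("height_", y0)]][nf[al]] *
        exp(stats::rnorm(sum(al), 0.08, 0.03))
    }
    # death is absorbing
    dead <- which(!is.na(st0) & st0 == "D")
    seedlings[[paste0("status_", y1)]][dead] <- "D"

    # new recruits enter at y1
    n_new <- stats::rpois(1, config$n_recruits_year)
    if (n_new > 0) {
      newp <- place(n_new)
      add <- seedlings[0, ]
      add[seq_len(n_new), c("tag", "quadrat_id", "species")] <-
        data.frame(sprintf("S%05d", nrow(seedlings) + seq_len(n_new)),
                   newp$quadrat_id, newp$species)
      add[[paste0("status_", y1)]] <- "A"
      add[[hj]] <- 20 + stats::rlnorm(n_new, log(15), 0.7)
      seedlings <- rbind(seedlings, add)
    }
    plt <- mk_plot(step + 1L)
  }

  truth <- list(beta0 = config$beta0, beta = beta,
                sigma_q = config$sigma_q, sigma_s = config$sigma_s,
                u_quadrat = u_q, v_species = v_s,
                p_survive = do.call(rbind, truth_p),
                variant = config$variant, seed = seed,
                index_seed = idx_seed)
  # `indices` are the exact covariate tables the survival generator used;
  # analyzing with them (or recomputing with seed = index_seed and the
  # same n_null) keeps the fitted model correctly specified
  list(plot = plt, phylogeny = tr, truth = truth, pca = pca,
       indices = do.call(rbind, idx_all))
}

# covariate assembly shared by build_dataset() and the generator
.assemble_covariates <- function(plot, idx, pca, y0, variant, radius_m = 20,
                                 d_floor = 0.1) {
  icol <- INDEX_VARIANTS[[variant]]
  sl <- plot$seedlings
  st0 <- seedling_status(plot, y0)
  focal <- which(!is.na(st0) & st0 == "A" &
                 !(sl$species %in% plot$non_focal_species))
  qd <- plot$quadrats

  # S_con: alive conspecifics in the quadrat, grouped once
  alive <- which(!is.na(st0) & st0 == "A")
  grp <- paste(sl$quadrat_id[alive], sl$species[alive], sep = "\r")
  cnt <- table(grp)
  scon <- as.numeric(cnt[paste(sl$quadrat_id[focal], sl$species[focal],
                               sep = "\r")]) - 1

  # A_con: one evaluation per unique (quadrat, species) pair, from
  # precomputed per-quadrat adult neighborhoods
  ad <- plot$adults
  near <- lapply(seq_len(nrow(qd)), function(q) {
    d <- sqrt((ad$x - qd$center_x[q])^2 + (ad$y - qd$center_y[q])^2)
    keep <- d <= radius_m
    list(species = ad$species[keep],
         w = pi * (ad$dbh[keep] / 2)^2 / pmax(d[keep], d_floor))
  })
  names(near) <- qd$quadrat_id
  pk <- paste(sl$quadrat_id[focal], sl$species[focal], sep = "\r")
  fu <- which(!duplicated(pk))
  acon_u <- vapply(fu, function(j) {
    nb <- near[[sl$quadrat_id[focal[j]]]]
    sum(nb$w[nb$species == sl$species[focal[j]]])
  }, numeric(1))
  acon <- acon_u[match(pk, pk[fu])]
  iy <- idx[idx$year == y0, ]
  is_s <- iy$layer == "seedling"
  s_idx <- iy[is_s, icol][match(sl$tag[focal], iy$tag[is_s])]
  a_idx <- iy[!is_s, icol][match(sl$tag[focal], iy$tag[!is_s])]
  hab <- plot$habitat
  gli <- hab$gli[match(sl$quadrat_id[focal], hab$quadrat_id)]
  pc <- pca[match(sl$quadrat_id[focal], pca$quadrat_id), ]
  data.frame(tag = sl$tag[focal], species = sl$species[focal],
             quadrat_id = sl$quadrat_id[focal],
             height = log(seedling_height(plot, y0)[focal]),
             s_con = scon, a_con = acon, s_index = s_idx, a_index = a_idx,
             light = gli, pca1 = pc$pca1, pca2 = pc$pca2, pca3 = pc$pca3)
}

#' Write a simulation to disk as plain-text files
#'
#' Writes the io tables (`adults.csv`, `seedlings.csv`, `quadrats.csv`,
#' `habitat.csv`), the phylogeny (`tree.nwk`) and the ground truth
#' (`truth.json`).
#'
#' @param sim result of [simulate_plot()]. @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  write_plot(sim$plot, dir)
  ape::write.tree(sim$phylogeny, file.path(dir, "tree.nwk"))
  tr <- sim$truth
  tr$u_quadrat <- as.list(tr$u_quadrat)
  tr$v_species <- as.list(tr$v_species)
  tr$beta <- as.list(tr$beta)
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Parameter-recovery report over replicate simulations
#'
#' Simulates `n_reps` datasets from `config`, runs the full pipeline
#' (indices, PCA, standardized dataset, GLMM) on the first census interval
#' of each, and summarizes recovery of every fixed-effect coefficient:
#' bias, RMSE, empirical 95% Wald CI coverage, sign recovery and Wald
#' rejection rate. Failed fits are counted, not fatal.
#'
#' @param config a [sim_config()]. @param n_reps replicates (>= 2).
#' @param seed master seed; replicate r uses `seed + r`.
#' @return list: `summary` (per-coefficient data.frame), `estimates`
#'   (per-rep coefficient table), `n_failed`.
#' @export
covariate_effect_check <- function(config = sim_config(), n_reps = 10,
                                   seed = 1L) {
  if (n_reps < 2) stop("n_reps must be >= 2")
  est <- list(); n_failed <- 0L
  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      sim <- simulate_plot(config, seed = seed + r)
      # analyze with the generator's own index tables: the model is then
      # exactly correctly specified (same covariate-construction code AND
      # same null draws)
      ds <- build_dataset(sim$plot, sim$indices, sim$pca$scores,
                          interval = config$census_years[1:2],
                          variant = config$variant,
                          radius_m = config$radius_m)
      fit_glmm(ds)
    }, error = function(e) e)
    if (!inherits(res, "model_fit") || res$separation ||
        is.null(res$coefficients)) {
      n_failed <- n_failed + 1L
      next
    }
    co <- res$coefficients
    co$rep <- r
    est[[length(est) + 1L]] <- co
  }
  if (!length(est)) stop("all replicate fits failed")
  est <- do.call(rbind, est)
  truth <- c("(Intercept)" = config$beta0, config$beta)
  terms <- unique(est$term)
  summ <- do.call(rbind, lapply(terms, function(tm) {
    e <- est[est$term == tm, ]
    tv <- unname(truth[tm])
    data.frame(term = tm, true = tv, mean_estimate = mean(e$estimate),
               bias = mean(e$estimate) - tv,
               rmse = sqrt(mean((e$estimate - tv)^2)),
               coverage = mean(abs(e$estimate - tv) <= 1.96 * e$se),
               sign_recovery = if (tv != 0) mean(sign(e$estimate) == sign(tv))
                               else NA_real_,
               rejection_rate = mean(e$p < 0.05))
  }))
  list(summary = summ, estimates = est, n_failed = n_failed)
}
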