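# Shared fixtures and independent oracles, built in code at test time.

# --- toy plot ---------------------------------------------------------------

# 2x2 subplot grid (40 x 40 m plot), 4 quadrats, 3 species, hand-placed
# stems; small enough to verify every neighborhood count by eye.
toy_plot <- function(extent = c(40, 40)) {
  quadrats <- data.frame(
    quadrat_id = c("Q1", "Q2", "Q3", "Q4"),
    subplot_row = c(0, 0, 1, 1), subplot_col = c(0, 1, 0, 1),
    elev_c1 = 10, elev_c2 = 10, elev_c3 = 10, elev_c4 = 10)
  adults <- data.frame(
    tag = paste0("A", 1:5),
    species = c("alpha", "alpha", "beta", "gamma", "beta"),
    x = c(15, 12, 18, 30, 39), y = c(15, 17, 13, 35, 2),
    dbh = c(10, 20, 5, 8, 12))
  seedlings <- data.frame(
    tag = paste0("S", 1:6),
    quadrat_id = c("Q1", "Q1", "Q1", "Q1", "Q2", "Q3"),
    species = c("alpha", "alpha", "alpha", "beta", "gamma", "beta"),
    status_2020 = c("A", "A", "A", "A", "A", "A"),
    height_2020 = c(25, 30, 40, 22, 50, 33),
    status_2021 = c("A", "D", "A", "A", "A", "D"),
    height_2021 = c(27, NA, 44, 23, 55, NA),
    stringsAsFactors = FALSE)
  habitat <- data.frame(
    quadrat_id = quadrats$quadrat_id,
    ph = c(4.5, 4.8, 5.0, 4.2), ec = c(100, 120, 90, 110),
    c = c(40, 42, 39, 45), ap = c(10, 12, 9, 11),
    ak = c(90, 85, 100, 95), tn = c(3, 3.2, 2.9, 3.1),
    tp = c(0.5, 0.6, 0.4, 0.55), tk = c(14, 13, 15, 14.5),
    soil_temp = c(13, 14, 13.5, 14.2), soil_moist = c(30, 35, 28, 33),
    gli = c(8, 10, 7, 12))
  plot_dataset(adults, seedlings, quadrats, habitat,
               census_years = c(2020, 2021), extent = extent)
}

# small simulation config: one census interval, modest pool, cheap nulls
fast_sim_config <- function(...) {
  args <- list(n_adults = 1500, n_species_adult = 40, n_species_seedling = 25,
               n_species_liana = 2, n_seedlings_init = 400,
               n_recruits_year = 30, census_years = 2020:2021, n_null = 49)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# --- independent oracles ----------------------------------------------------

# naive loops over the profile, no vectorization shared with the package
oracle_totpd <- function(profile, dmat, focal) {
  if (!length(profile)) return(NA_real_)
  tot <- 0
  for (sp in names(profile)) tot <- tot + dmat[focal, sp] * profile[[sp]]
  tot
}
oracle_avepd <- function(profile, dmat, focal) {
  if (!length(profile)) return(NA_real_)
  oracle_totpd(profile, dmat, focal) / sum(profile)
}
oracle_minpd <- function(profile, dmat, focal) {
  if (!length(profile)) return(NA_real_)
  m <- Inf
  for (sp in names(profile)) m <- min(m, dmat[focal, sp])
  m
}

# patristic distances as shortest paths on the tree graph (igraph)
oracle_patristic <- function(phy) {
  g <- igraph::graph_from_edgelist(apply(phy$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- phy$edge.length
  n <- ape::Ntip(phy)
  d <- igraph::distances(g, v = as.character(1:n), to = as.character(1:n))
  dimnames(d) <- list(phy$tip.label, phy$tip.label)
  d
}

# exhaustive taxa-shuffle null distribution of AVEPd and MINPd for a
# profile: enumerate every permutation of the full label pool
oracle_null_distribution <- function(profile, dmat, focal) {
  labs <- rownames(dmat)
  perms <- all_permutations(length(labs))
  w <- as.numeric(profile)
  f <- match(focal, labs); j <- match(names(profile), labs)
  ave <- numeric(nrow(perms)); mn <- numeric(nrow(perms))
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    x <- dmat[p[f], p[j]]
    ave[r] <- sum(x * w) / sum(w)
    mn[r] <- min(x)
  }
  list(ave = ave, min = mn)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    m <- cbind(k, sub + (sub >= k))
    out <- rbind(out, m)
  }
  out
}

# random (tree, profile) instance for oracle-equivalence checks
random_instance <- function(n_tips = sample(5:30, 1)) {
  phy <- ape::rtree(n_tips)
  dmat <- patristic_matrix(phy)
  focal <- sample(phy$tip.label, 1)
  pool <- setdiff(phy$tip.label, focal)
  k <- sample.int(min(8, length(pool)), 1)
  profile <- stats::setNames(sample.int(5, k, replace = TRUE),
                             sample(pool, k))
  list(dmat = dmat, focal = focal, profile = profile)
}
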