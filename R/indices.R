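#' Total phylogenetic distance to heterospecific neighbors (TOTPd)
#'
#' `TOTPd = sum_i X_i * abundance_i`, where `X_i` is the patristic distance
#' between species i and the focal species and `abundance_i` the number of
#' neighbors of species i. Units: branch-length units x individuals.
#'
#' @param profile named integer vector of per-species neighbor counts
#'   (heterospecifics only, as from [neighbor_profiles()]).
#' @param dmat patristic distance matrix. @param focal focal species label.
#' @return numeric; `NA` for an empty profile.
#' @export
totpd <- function(profile, dmat, focal) {
  if (!length(profile)) return(NA_real_)
  x <- .profile_dist(profile, dmat, focal)
  sum(x * profile)
}

#' Abundance-weighted mean phylogenetic distance (AVEPd)
#'
#' `AVEPd = sum_i X_i * abundance_i / sum_i abundance_i`; equals TOTPd when
#' total abundance is 1. Units: branch-length units.
#' @inheritParams totpd
#' @return numeric; `NA` for an empty profile.
#' @export
avepd <- function(profile, dmat, focal) {
  if (!length(profile)) return(NA_real_)
  x <- .profile_dist(profile, dmat, focal)
  sum(x * profile) / sum(profile)
}

#' Nearest-taxon phylogenetic distance (MINPd)
#'
#' Minimum patristic distance between the focal species and any
#' heterospecific neighbor species in the profile.
#' @inheritParams totpd
#' @return numeric; `NA` for an empty profile.
#' @export
minpd <- function(profile, dmat, focal) {
  if (!length(profile)) return(NA_real_)
  min(.profile_dist(profile, dmat, focal))
}

.profile_dist <- function(profile, dmat, focal) {
  labs <- rownames(dmat)
  f <- match(focal, labs)
  j <- match(names(profile), labs)
  if (is.na(f)) stop("species missing from distance matrix: ", focal)
  if (anyNA(j))
    stop("species missing from distance matrix: ",
         paste(names(profile)[is.na(j)], collapse = ", "))
  dmat[f, j]
}

#' Standardized effect sizes APd' and NTPd' under the taxa-shuffle null
#'
#' Shuffling species labels on the phylogeny `n_null` times yields null
#' distributions of AVEPd and MINPd for the focal's neighbor profile
#' (abundance structure and the focal's slot held fixed, all tips of the
#' supplied tree participating in the shuffle). Then
#' `APd' = (AVEPd - mean(AVEPd_null)) / SD(AVEPd_null)` and
#' `NTPd' = (MINPd - mean(MINPd_null)) / SD(MINPd_null)`, with the sample
#' (n-1) SD over the `n_null` draws; the observed value is not added to the
#' null distribution. Values > 0 mean neighbors are less related to the
#' focal than expected under the null.
#'
#' Both statistics are evaluated on the same permutation draws (paired
#' nulls). Only the permuted identities of the focal and the profile
#' species matter, so each draw samples `length(profile) + 1` distinct
#' labels from the pool rather than materializing a full permutation —
#' distributionally identical and much cheaper.
#'
#' @inheritParams totpd
#' @param n_null number of label shuffles (default 999; must be >= 2).
#' @return list with `apd_prime`, `ntpd_prime`, `null_mean_ave`,
#'   `null_sd_ave`, `null_mean_min`, `null_sd_min`, `n_null`. SES values
#'   are `NA` when the null SD is 0 (e.g. a star tree) or the profile is
#'   empty. Uses the current RNG stream; seed before calling for
#'   reproducibility.
#' @export
ses_indices <- function(profile, dmat, focal, n_null = 999) {
  if (n_null < 2) stop("n_null must be >= 2")
  empty <- list(apd_prime = NA_real_, ntpd_prime = NA_real_,
                null_mean_ave = NA_real_, null_sd_ave = NA_real_,
                null_mean_min = NA_real_, null_sd_min = NA_real_,
                n_null = as.integer(n_null))
  if (!length(profile)) return(empty)
  x <- .profile_dist(profile, dmat, focal)
  w <- as.numeric(profile)
  obs_ave <- sum(x * w) / sum(w)
  obs_min <- min(x)

  S <- nrow(dmat)
  k <- length(profile) + 1L
  # k x n_null matrix of sampled label slots: row 1 = focal's image
  idx <- vapply(seq_len(n_null), function(b) sample.int(S, k), integer(k))
  f_img <- idx[1L, ]
  nb_img <- idx[-1L, , drop = FALSE]
  # d[f_img[b], nb_img[r, b]] via linear indexing
  lin <- (nb_img - 1L) * S + rep(f_img, each = k - 1L)
  vals <- matrix(dmat[lin], nrow = k - 1L)
  null_ave <- colSums(vals * w) / sum(w)
  null_min <- vals[1L, ]
  if (k > 2L) for (r in 2:(k - 1L)) null_min <- pmin(null_min, vals[r, ])

  m_a <- mean(null_ave); s_a <- stats::sd(null_ave)
  m_m <- mean(null_min); s_m <- stats::sd(null_min)
  list(apd_prime = if (s_a > 0) (obs_ave - m_a) / s_a else NA_real_,
       ntpd_prime = if (s_m > 0) (obs_min - m_m) / s_m else NA_real_,
       null_mean_ave = m_a, null_sd_ave = s_a,
       null_mean_min = m_m, null_sd_min = s_m,
       n_null = as.integer(n_null))
}

#' All four phylogenetic indices for one focal seedling
#'
#' Computes TOTPd, AVEPd, MINPd, APd' and NTPd' for the seedling-layer and
#' adult-layer neighbor profiles of a focal seedling at one census.
#'
#' @inheritParams neighbor_profiles
#' @param dmat patristic distance matrix of the plot species pool.
#' @param n_null shuffles for the SES null. @param seed optional integer;
#'   when given, each layer's null draws are seeded deterministically from
#'   it (see [indices_table()]).
#' @return list with elements `seedling` and `adult`, each a one-row
#'   data.frame of index values and null diagnostics.
#' @export
index_set <- function(plot, dmat, tag, year, n_null = 999, radius_m = 20,
                      seed = NULL) {
  prof <- neighbor_profiles(plot, tag, year, radius_m = radius_m)
  focal <- attr(prof, "focal_species")
  out <- lapply(c(seedling = "seedling", adult = "adult"), function(layer) {
    p <- prof[[layer]]
    if (!is.null(seed))
      set.seed(.stream_seed(seed, paste(layer, year, focal,
                                        attr(prof, "quadrat_id"))))
    s <- ses_indices(p, dmat, focal, n_null = n_null)
    data.frame(totpd = totpd(p, dmat, focal), avepd = avepd(p, dmat, focal),
               minpd = minpd(p, dmat, focal), apd_prime = s$apd_prime,
               ntpd_prime = s$ntpd_prime, null_mean_ave = s$null_mean_ave,
               null_sd_ave = s$null_sd_ave, null_mean_min = s$null_mean_min,
               null_sd_min = s$null_sd_min, n_null = s$n_null)
  })
  out
}

# deterministic 31-bit stream seed from a master seed and a string key
.stream_seed <- function(master, key) {
  h <- as.double(master %% 2147483647L)
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Phylogenetic index table for all focal seedlings
#'
#' Evaluates [index_set()] for every alive focal seedling at each requested
#' census, one row per (tag, year, layer). Seedlings of species flagged
#' `non_focal_species` in the plot (lianas) are skipped as focals but still
#' count as neighbors. Results are cached per unique (layer, year, focal
#' species, quadrat) profile — all conspecific focals in a quadrat share
#' identical profiles, index values and null draws. Null streams are seeded
#' deterministically from `seed` and the cache key, so the table is
#' reproducible and independent of evaluation order.
#'
#' @inheritParams index_set
#' @param years census years to evaluate (default: all but the last).
#' @return data.frame: tag, year, layer, totpd, avepd, minpd, apd_prime,
#'   ntpd_prime, null diagnostics, n_null.
#' @export
indices_table <- function(plot, dmat, years = NULL, n_null = 999,
                          radius_m = 20, seed = 1L) {
  if (is.null(years))
    years <- utils::head(plot$census_years, -1L)
  sl <- plot$seedlings
  qd <- plot$quadrats

  # per-quadrat adult neighborhoods, static across censuses
  ad <- plot$adults
  adult_counts <- lapply(seq_len(nrow(qd)), function(qi) {
    d <- sqrt((ad$x - qd$center_x[qi])^2 + (ad$y - qd$center_y[qi])^2)
    table_counts(ad$species[d <= radius_m])
  })
  names(adult_counts) <- qd$quadrat_id

  # enumerate all (focal, year, layer) rows up front
  tag <- year <- layer <- sp <- qid <- list()
  seed_counts <- list()
  for (yr in as.character(years)) {
    st <- seedling_status(plot, as.integer(yr))
    alive <- which(!is.na(st) & st == "A" &
                   !(sl$species %in% plot$non_focal_species))
    if (!length(alive)) next
    st_all <- which(!is.na(st) & st == "A")
    seed_counts[[yr]] <- tapply(sl$species[st_all], sl$quadrat_id[st_all],
                                table_counts, simplify = FALSE)
    for (ly in c("seedling", "adult")) {
      tag[[length(tag) + 1L]] <- sl$tag[alive]
      year[[length(year) + 1L]] <- rep(as.integer(yr), length(alive))
      layer[[length(layer) + 1L]] <- rep(ly, length(alive))
      sp[[length(sp) + 1L]] <- sl$species[alive]
      qid[[length(qid) + 1L]] <- sl$quadrat_id[alive]
    }
  }
  if (!length(tag)) stop("no alive focal seedlings in the requested years")
  out <- data.frame(tag = unlist(tag), year = unlist(year),
                    layer = unlist(layer))
  sp <- unlist(sp); qid <- unlist(qid)

  # one evaluation per unique (layer, year, species, quadrat) profile;
  # conspecific focals in a quadrat share values and null draws
  key <- paste(out$layer, out$year, sp, qid, sep = "\r")
  first <- which(!duplicated(key))
  vals <- matrix(NA_real_, length(first), 10,
                 dimnames = list(NULL, c("totpd", "avepd", "minpd",
                   "apd_prime", "ntpd_prime", "null_mean_ave", "null_sd_ave",
                   "null_mean_min", "null_sd_min", "n_null")))
  for (u in seq_along(first)) {
    i <- first[u]
    p <- if (out$layer[i] == "seedling")
      seed_counts[[as.character(out$year[i])]][[qid[i]]]
    else adult_counts[[qid[i]]]
    prof <- p[setdiff(names(p), sp[i])]   # heterospecifics only
    set.seed(.stream_seed(seed, key[i]))
    s <- ses_indices(prof, dmat, sp[i], n_null = n_null)
    vals[u, ] <- c(totpd(prof, dmat, sp[i]), avepd(prof, dmat, sp[i]),
                   minpd(prof, dmat, sp[i]), s$apd_prime, s$ntpd_prime,
                   s$null_mean_ave, s$null_sd_ave, s$null_mean_min,
                   s$null_sd_min, s$n_null)
  }
  out <- cbind(out, as.data.frame(vals[match(key, key[first]), ,
                                       drop = FALSE]))
  out$n_null <- as.integer(out$n_null)
  rownames(out) <- NULL
  out
}
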