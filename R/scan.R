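#' Temporal analysis design from the census years
#'
#' Enumerates all (start, end) census intervals, grouped by span in years.
#' For the default four annual censuses this yields three 1-year, two
#' 2-year and one 3-year interval.
#'
#' @param census_years strictly increasing integer vector.
#' @param spans interval spans (years) to include.
#' @return data.frame: start, end, span.
#' @export
temporal_design <- function(census_years, spans = NULL) {
  yrs <- sort(unique(as.integer(census_years)))
  g <- expand.grid(start = yrs, end = yrs)
  g <- g[g$end > g$start, ]
  g$span <- g$end - g$start
  if (!is.null(spans)) g <- g[g$span %in% spans, ]
  g <- g[order(g$span, g$start), ]
  rownames(g) <- NULL
  g
}

#' Standard spatial analysis windows
#'
#' 1 ha = 100 x 100 m, 2 ha = 200 x 100 m, 4 ha = 200 x 200 m, anchored at
#' the plot origin (south-west corner) by default.
#'
#' @param labels subset of `c("1ha", "2ha", "4ha")`.
#' @param anchor numeric length-2 SW corner of the windows.
#' @return named list of windows, each `list(xlim =, ylim =)`.
#' @export
spatial_windows <- function(labels = c("1ha", "2ha", "4ha"),
                            anchor = c(0, 0)) {
  all <- list(
    "1ha" = list(xlim = anchor[1] + c(0, 100), ylim = anchor[2] + c(0, 100)),
    "2ha" = list(xlim = anchor[1] + c(0, 200), ylim = anchor[2] + c(0, 100)),
    "4ha" = list(xlim = anchor[1] + c(0, 200), ylim = anchor[2] + c(0, 200)))
  all[match.arg(labels, names(all), several.ok = TRUE)]
}

#' Restrict a plot dataset to a spatial window
#'
#' Emulates a smaller plot: focal quadrats AND the neighbor pools (adults,
#' seedlings) are truncated to the window, so density and index covariates
#' recomputed afterwards see only the windowed pool. With
#' `truncate_neighbors = FALSE` only the focal quadrats are subset and the
#' full-plot neighbor pools are kept.
#'
#' @param plot a [plot_dataset()]. @param window `list(xlim, ylim)`.
#' @param truncate_neighbors logical, see above.
#' @return a `plot_dataset` restricted to the window.
#' @export
spatial_subset <- function(plot, window, truncate_neighbors = TRUE) {
  qd <- plot$quadrats
  in_w <- qd$center_x >= window$xlim[1] & qd$center_x <= window$xlim[2] &
          qd$center_y >= window$ylim[1] & qd$center_y <= window$ylim[2]
  if (!any(in_w)) stop("window contains no quadrat")
  out <- plot
  out$quadrats <- qd[in_w, , drop = FALSE]
  keep_s <- plot$seedlings$quadrat_id %in% out$quadrats$quadrat_id
  out$seedlings <- plot$seedlings[keep_s, , drop = FALSE]
  if (truncate_neighbors) {
    ad <- plot$adults
    keep_a <- ad$x >= window$xlim[1] & ad$x <= window$xlim[2] &
              ad$y >= window$ylim[1] & ad$y <= window$ylim[2]
    out$adults <- ad[keep_a, , drop = FALSE]
  }
  if (!is.null(plot$habitat))
    out$habitat <- plot$habitat[plot$habitat$quadrat_id %in%
                                out$quadrats$quadrat_id, , drop = FALSE]
  out
}

#' Factorial scan over index variants, temporal and spatial scales
#'
#' For every (spatial window, census interval, index variant) cell:
#' truncate the plot to the window, recompute neighborhoods and
#' phylogenetic indices within the truncated pool, build the standardized
#' survival dataset, and fit the binomial mixed model. PCA scores are
#' computed once from the full-plot habitat table and subset per window.
#' AIC comparison (delta AIC <= 2 validity rule) is per (window, interval)
#' candidate set across the four variants. Cells whose fit fails are
#' recorded with `NA` and the scan continues. Deterministic given `seed`.
#'
#' @param plot a [plot_dataset()] carrying habitat data.
#' @param dmat patristic distance matrix of the species pool.
#' @param windows named list from [spatial_windows()].
#' @param spans interval spans to analyze (default `1:3`).
#' @param variants index variants (default all four).
#' @param n_null null shuffles for SES indices. @param radius_m adult
#'   neighborhood radius. @param d_floor distance floor for [a_con()].
#' @param seed master seed for the null streams.
#' @param out_dir when given, writes `comparison.csv` and `effects.csv`.
#' @return list: `comparison` (one row per cell: window, start, end, span,
#'   variant, aic, r2_conditional, delta_aic, valid, best, n_obs,
#'   converged), `effects` (long coefficient table with significance
#'   classes), `fits` (nested list of `model_fit`s).
#' @export
run_scan <- function(plot, dmat, windows = spatial_windows(),
                     spans = 1:3,
                     variants = c("totpd", "avepd", "apd", "ntpd"),
                     n_null = 999, radius_m = 20, d_floor = 0.1, seed = 1L,
                     out_dir = NULL) {
  if (is.null(plot$habitat)) stop("plot has no habitat table")
  pca <- habitat_pca(plot$habitat)
  design <- temporal_design(plot$census_years, spans = spans)
  comp <- list(); eff <- list(); fits <- list()

  for (wl in names(windows)) {
    sub <- spatial_subset(plot, windows[[wl]])
    idx <- indices_table(sub, dmat, n_null = n_null, radius_m = radius_m,
                         seed = seed)
    for (r in seq_len(nrow(design))) {
      interval <- c(design$start[r], design$end[r])
      cell_fits <- list()
      for (v in variants) {
        res <- tryCatch({
          ds <- build_dataset(sub, idx, pca$scores, interval, variant = v,
                              radius_m = radius_m, d_floor = d_floor)
          fit_glmm(ds)
        }, error = function(e) e)
        cell_fits[[v]] <- res
        ok <- inherits(res, "model_fit") && !res$separation
        comp[[length(comp) + 1L]] <- data.frame(
          window = wl, start = interval[1], end = interval[2],
          span = design$span[r], variant = v,
          aic = if (ok) res$aic else NA_real_,
          r2_conditional = if (ok) res$r2_conditional else NA_real_,
          n_obs = if (inherits(res, "model_fit")) res$n_obs else NA_integer_,
          converged = if (ok) res$converged else FALSE)
        if (ok) {
          cl <- t(vapply(seq_len(nrow(res$coefficients)), function(i)
            unlist(classify_effect(res$coefficients$p[i],
                                   res$coefficients$estimate[i])[c("class", "sign")]),
            character(2)))
          eff[[length(eff) + 1L]] <- data.frame(
            window = wl, start = interval[1], end = interval[2],
            variant = v, res$coefficients,
            class = cl[, 1], sign = cl[, 2])
        }
      }
      fits[[paste(wl, interval[1], interval[2], sep = "_")]] <- cell_fits
    }
  }
  comparison <- do.call(rbind, comp)
  if (all(is.na(comparison$aic))) stop("all scan cells failed")
  # delta AIC within each (window, interval) candidate set
  comparison$delta_aic <- NA_real_
  comparison$valid <- NA
  comparison$best <- NA
  for (key in unique(paste(comparison$window, comparison$start,
                           comparison$end))) {
    rows <- paste(comparison$window, comparison$start, comparison$end) == key
    if (all(is.na(comparison$aic[rows]))) next
    da <- delta_aic(comparison$aic[rows])
    comparison$delta_aic[rows] <- da$delta_aic
    comparison$valid[rows] <- da$valid
    comparison$best[rows] <- da$best
  }
  effects <- if (length(eff)) do.call(rbind, eff) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(effects, file.path(out_dir, "effects.csv"),
                     row.names = FALSE)
  }
  list(comparison = comparison, effects = effects, fits = fits)
}
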