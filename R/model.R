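INDEX_VARIANTS <- c(totpd = "totpd", avepd = "avepd",
                    apd = "apd_prime", ntpd = "ntpd_prime")

#' Build a standardized survival dataset for one model cell
#'
#' Assembles one analysis row per focal seedling alive at the interval
#' start census, with outcome 1 if still alive at the interval end and 0 if
#' dead (death is absorbing). Covariates are taken at the interval start:
#' log-transformed height, S_con, A_con, the chosen phylogenetic index for
#' the seedling and adult neighbor layers, canopy openness (gli), and PCA
#' scores 1-3. All continuous covariates are centered by their mean and
#' divided by 1 SD, with constants computed from this dataset's own rows.
#' Rows with any missing covariate (empty neighbor layer, null SD of 0,
#' missing height) are dropped and counted.
#'
#' @param plot a [plot_dataset()] (after [add_topography()] if PCA scores
#'   are derived from it).
#' @param idx index table from [indices_table()].
#' @param pca PCA score table (`quadrat_id`, `pca1..pca3`) from
#'   [habitat_pca()].
#' @param interval length-2 integer `(start_year, end_year)`.
#' @param variant one of `"totpd"`, `"avepd"`, `"apd"`, `"ntpd"`.
#' @param radius_m,d_floor passed to [a_con()].
#' @return object of class `survival_dataset`: list with `data` (model
#'   frame), `constants` (per-covariate mean/sd), `n_dropped`, `interval`,
#'   `variant`.
#' @export
build_dataset <- function(plot, idx, pca, interval,
                          variant = c("totpd", "avepd", "apd", "ntpd"),
                          radius_m = 20, d_floor = 0.1) {
  variant <- match.arg(variant)
  y0 <- interval[1]; y1 <- interval[2]
  if (!all(c(y0, y1) %in% plot$census_years) || y1 <= y0)
    stop("invalid interval (", y0, ", ", y1, ")")
  st0 <- seedling_status(plot, y0)
  if (!any(!is.na(st0) & st0 == "A" &
           !(plot$seedlings$species %in% plot$non_focal_species)))
    stop("no focal seedlings alive at ", y0)

  df <- .assemble_covariates(plot, idx, pca, y0, variant = variant,
                             radius_m = radius_m, d_floor = d_floor)
  st1 <- seedling_status(plot, y1)
  df$outcome <- as.integer(st1[match(df$tag, plot$seedlings$tag)] == "A")

  num <- c("height", "s_con", "a_con", "s_index", "a_index",
           "light", "pca1", "pca2", "pca3")
  keep <- stats::complete.cases(df[, c("outcome", num)])
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (!nrow(df))
    stop("empty dataset for interval (", y0, ", ", y1, "), variant ", variant)

  constants <- data.frame(covariate = num,
                          mean = vapply(df[num], mean, numeric(1)),
                          sd = vapply(df[num], stats::sd, numeric(1)))
  for (v in num) {
    s <- constants$sd[constants$covariate == v]
    df[[v]] <- (df[[v]] - constants$mean[constants$covariate == v]) /
      (if (s > 0) s else 1)
  }
  structure(list(data = df, constants = constants, n_dropped = n_dropped,
                 interval = c(y0, y1), variant = variant),
            class = "survival_dataset")
}

#' Fit the binomial mixed survival model
#'
#' Logit-link Bernoulli GLMM with the nine standardized fixed effects
#' (height, S_con, A_con, seedling- and adult-layer phylogenetic index,
#' light, PCA1-3) and crossed random intercepts for quadrat and species,
#' fitted by maximum likelihood with the Laplace approximation
#' ([lme4::glmer()]). Wald z tests per coefficient. AIC counts the
#' intercept, 9 slopes and 2 variance components (k = 12). Complete
#' separation (all outcomes identical) and non-convergence are flagged on
#' the returned fit rather than raised.
#'
#' @param dataset a [build_dataset()] result.
#' @param force_zero_re fit with both random-intercept variances
#'   constrained to zero (theta fixed at 0 in the Laplace deviance, fixed
#'   effects optimized by BFGS). In this degenerate limit the integrated
#'   likelihood reduces to the plain logistic likelihood, which the tests
#'   cross-check against an independent IRLS fit. AIC then counts only the
#'   fixed effects.
#' @return object of class `model_fit`: list with `coefficients`
#'   (data.frame term/estimate/se/z/p), `varcomp` (quadrat, species
#'   intercept variances), `loglik`, `aic`, `r2_conditional`, `n_obs`,
#'   `converged`, `separation`, `variant`, `interval`, and the underlying
#'   `fit` object.
#' @export
fit_glmm <- function(dataset, force_zero_re = FALSE) {
  df <- dataset$data
  base <- list(coefficients = NULL, varcomp = c(quadrat = NA_real_,
               species = NA_real_), loglik = NA_real_, aic = NA_real_,
               r2_conditional = NA_real_, n_obs = nrow(df),
               converged = FALSE, separation = FALSE,
               variant = dataset$variant, interval = dataset$interval,
               fit = NULL)
  if (length(unique(df$outcome)) < 2L) {
    base$separation <- TRUE
    return(structure(base, class = "model_fit"))
  }
  if (length(unique(df$quadrat_id)) < 2L || length(unique(df$species)) < 2L)
    stop("need >= 2 quadrats and >= 2 species")
  form <- outcome ~ height + s_con + a_con + s_index + a_index +
    light + pca1 + pca2 + pca3 + (1 | quadrat_id) + (1 | species)
  if (force_zero_re) {
    gf <- lme4::glFormula(form, data = df, family = stats::binomial())
    devfun <- do.call(lme4::mkGlmerDevfun, gf)
    devfun <- lme4::updateGlmerDevfun(devfun, gf$reTrms)
    p <- ncol(gf$X)
    n_theta <- length(gf$reTrms$theta)
    fn <- function(beta) devfun(c(rep(0, n_theta), beta))
    opt <- stats::optim(rep(0, p), fn, method = "BFGS", hessian = TRUE,
                        control = list(maxit = 500, reltol = 1e-12))
    se <- sqrt(diag(solve(opt$hessian / 2)))
    z <- opt$par / se
    out <- base
    out$coefficients <- data.frame(term = colnames(gf$X),
                                   estimate = opt$par, se = se, z = z,
                                   p = 2 * stats::pnorm(-abs(z)))
    out$varcomp <- c(quadrat = 0, species = 0)
    out$loglik <- -opt$value / 2
    out$aic <- 2 * p - 2 * out$loglik
    out$converged <- opt$convergence == 0
    eta <- as.vector(gf$X %*% opt$par)
    out$r2_conditional <- conditional_r2(
      list(var_fixed = stats::var(eta) * (length(eta) - 1) / length(eta),
           varcomp = out$varcomp))
    return(structure(out, class = "model_fit"))
  }
  warned <- FALSE
  fit <- withCallingHandlers(
    lme4::glmer(form, data = df, family = stats::binomial(),
                control = lme4::glmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  co <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                   z = sm[, 3], p = sm[, 4], row.names = NULL)
  vc <- lme4::VarCorr(fit)
  varcomp <- c(quadrat = as.numeric(vc$quadrat_id),
               species = as.numeric(vc$species))
  out <- base
  out$coefficients <- co
  out$varcomp <- varcomp
  out$loglik <- as.numeric(stats::logLik(fit))
  out$aic <- stats::AIC(fit)
  out$n_obs <- nrow(df)
  out$converged <- !warned
  out$fit <- fit
  out <- structure(out, class = "model_fit")
  out$r2_conditional <- conditional_r2(out)
  out
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit> variant=", x$variant, " interval=",
      paste(x$interval, collapse = "-"), " n=", x$n_obs, "\n", sep = "")
  if (x$separation) { cat("  flagged: complete separation\n"); return(invisible(x)) }
  cat("  AIC=", round(x$aic, 2), "  logLik=", round(x$loglik, 2),
      "  condR2=", round(x$r2_conditional, 3),
      if (!x$converged) "  [convergence flagged]", "\n", sep = "")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Conditional R-squared of a logit-link mixed model
#'
#' Variance explained by fixed plus random effects:
#' `(var_f + var_q + var_s) / (var_f + var_q + var_s + pi^2/3)`, where
#' `var_f` is the variance of the fixed-effect linear predictor over the
#' data rows, `var_q`/`var_s` the random-intercept variances, and
#' `pi^2/3` the logistic distribution-specific residual variance.
#'
#' @param fit a `model_fit` (with its underlying `lme4` fit), or a list
#'   with elements `var_fixed` and `varcomp` for direct evaluation.
#' @return fraction in [0, 1].
#' @export
conditional_r2 <- function(fit) {
  if (!is.null(fit$fit)) {
    eta <- as.numeric(lme4::getME(fit$fit, "X") %*% lme4::fixef(fit$fit))
    var_f <- stats::var(eta) * (length(eta) - 1) / length(eta)
  } else {
    var_f <- fit$var_fixed
  }
  vr <- sum(fit$varcomp)
  (var_f + vr) / (var_f + vr + pi^2 / 3)
}

#' Classify a coefficient's effect from its Wald p-value and sign
#'
#' `p < .05` is significant, `.05 <= p < .1` marginally significant,
#' otherwise none. Positive estimates indicate positive effects on
#' seedling survival; for a phylogenetic index a positive coefficient is
#' read as phylogenetic negative density dependence (survival rises as
#' neighbors become less related).
#'
#' @param p p-value in [0, 1]. @param estimate coefficient estimate.
#' @return list `class` ("significant", "marginal", "none"), `sign`
#'   ("positive"/"negative"/"zero"), `interpretation` for index terms.
#' @export
classify_effect <- function(p, estimate) {
  if (is.na(p) || p < 0 || p > 1) stop("p must be in [0, 1]")
  cls <- if (p < 0.05) "significant" else if (p < 0.1) "marginal" else "none"
  sgn <- if (estimate > 0) "positive" else if (estimate < 0) "negative" else "zero"
  interp <- if (sgn == "positive") "phylogenetic negative density dependence"
            else if (sgn == "negative") "phylogenetic positive density dependence"
            else "none"
  list(class = cls, sign = sgn, interpretation = interp)
}

#' Write a model fit to JSON (and optionally the coefficient table to CSV)
#'
#' Serializes the fit summary — variant, interval, coefficient table,
#' variance components, log-likelihood, AIC, conditional R-squared,
#' convergence flags, n — without the underlying lme4 object.
#'
#' @param fit a `model_fit`. @param path output `.json` path.
#' @param coef_csv optional path for the coefficient table as CSV.
#' @return invisibly, `path`.
#' @export
write_model_fit <- function(fit, path, coef_csv = NULL) {
  stopifnot(inherits(fit, "model_fit"))
  out <- fit[c("variant", "interval", "coefficients", "varcomp", "loglik",
               "aic", "r2_conditional", "n_obs", "converged", "separation")]
  out$varcomp <- as.list(out$varcomp)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  if (!is.null(coef_csv))
    utils::write.csv(fit$coefficients, coef_csv, row.names = FALSE)
  invisible(path)
}

#' AIC differences relative to the best candidate
#'
#' `delta_i = AIC_i - min(AIC)`; models with `delta <= 2` are judged
#' equally valid, and the minimum-AIC model is best (ties broken by input
#' order).
#'
#' @param aic numeric vector of AIC values.
#' @return data.frame: aic, delta_aic, valid, best.
#' @export
delta_aic <- function(aic) {
  delta <- aic - min(aic, na.rm = TRUE)
  best <- rep(FALSE, length(aic))
  best[which.min(aic)] <- TRUE
  data.frame(aic = aic, delta_aic = delta, valid = delta <= 2, best = best)
}
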