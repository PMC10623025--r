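#' Fit the fixed-effect model for a trait and report least-squares means
#'
#' Fits the trait's model (period + season, the AFC covariate where the
#' template uses it, and sire) by
#' ordinary least squares, reports partial (Type III) F tests for every term
#' and population-marginal least-squares means (other factors averaged over
#' their levels, covariate held at its mean). Significance codes follow the
#' herd-book convention: `***` p<0.01, `**` p<0.05, `*` not significant.
#'
#' @param spec A [model_spec()].
#' @param records Coded phenotype records (see [code_fixed_effects()]).
#' @param lsmeans Compute least-squares means (default `TRUE`; turn off for
#'   speed in simulation loops where only the F tests are needed).
#' @return List of class `lsml_fit`: `anova` (data.frame of term, df, F, p,
#'   code), `lsmeans` (per-factor data.frame of level, lsmean, se), `lsm`
#'   (overall least-squares mean and its SE), `sigma2_e`, `fit` (the `lm`).
#' @export
fit_fixed_model <- function(spec, records, lsmeans = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  df <- data.frame(
    y = records[[spec$trait]],
    period = records[[paste0("period_", spec$period_basis)]],
    season = records[[paste0("season_", spec$season_basis)]],
    sire = factor(records$sire_code)
  )
  if (spec$afc_covariate) df$afc <- records$afc
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df$period <- drop_empty_levels(df$period)
  df$season <- drop_empty_levels(df$season)
  df$sire <- drop_empty_levels(df$sire)
  terms <- c(if (nlevels(df$period) > 1) "period",
             if (nlevels(df$season) > 1) "season",
             if (spec$afc_covariate) "afc",
             if (nlevels(df$sire) > 1) "sire")
  fml <- stats::reformulate(terms, response = "y")
  # sum-to-zero contrasts so that Type III marginal tests are well defined
  ctr <- stats::setNames(
    rep(list("contr.sum"), sum(terms %in% c("period", "season", "sire"))),
    terms[terms %in% c("period", "season", "sire")])
  fit <- stats::lm(fml, data = df, contrasts = ctr)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; confounded terms: ",
         paste(unique(bad), collapse = ", "))
  }
  a3 <- car::Anova(fit, type = 3)
  keep <- !rownames(a3) %in% c("(Intercept)", "Residuals")
  an <- data.frame(
    term = rownames(a3)[keep],
    df = a3$Df[keep],
    F = a3$`F value`[keep],
    p = a3$`Pr(>F)`[keep],
    stringsAsFactors = FALSE
  )
  an$code <- ifelse(an$p < 0.01, "***", ifelse(an$p < 0.05, "**", "*"))
  out <- list(anova = an,
              sigma2_e = stats::sigma(fit)^2,
              n = nrow(df), fit = fit, trait = spec$trait)
  if (lsmeans) {
    lsm <- list()
    for (f in intersect(c("period", "season", "sire"), terms)) {
      em <- as.data.frame(emmeans::emmeans(fit, f))
      lsm[[f]] <- data.frame(level = as.character(em[[1]]),
                             lsmean = em$emmean, se = em$SE,
                             stringsAsFactors = FALSE)
    }
    ov <- as.data.frame(emmeans::emmeans(fit, ~1))
    out$lsmeans <- lsm
    out$lsm <- c(lsmean = ov$emmean[1], se = ov$SE[1])
  }
  class(out) <- "lsml_fit"
  out
}

#' @export
print.lsml_fit <- function(x, ...) {
  cat("Least-squares analysis of", toupper(x$trait),
      " (n =", x$n, ")\n")
  if (!is.null(x$lsm))
    cat(sprintf("Overall LSM = %.2f +/- %.2f\n", x$lsm["lsmean"],
                x$lsm["se"]))
  print(x$anova, row.names = FALSE)
  cat("Codes: *** p<0.01, ** p<0.05, * non-significant\n")
  invisible(x)
}

# projection helper: fitted values of the column space of M
proj_fitted <- function(qrM, v) qr.fitted(qrM, v)

#' Sire and residual (co)variance components by Henderson's Method III
#'
#' Treats the sire term as random in the trait model and equates the
#' reduction in sums of squares `R(sire | fixed)` and the full-model
#' residual to their expectations. For a trait pair the analogous
#' cross-product forms on the common records yield sire and residual
#' covariances. Negative sire components are truncated to zero for derived
#' statistics, with the raw value retained.
#'
#' @param spec A [model_spec()] (its fixed terms are used; `random` is
#'   forced to sire).
#' @param records Coded phenotype records.
#' @param trait2 Optional second trait name for covariance components.
#' @return List of class `h3_components`: `sigma2_s`, `sigma2_e`, raw
#'   values, `k` (effective progeny-group size), `n_sires`, `n`, and for a
#'   pair `cov_s`, `cov_e`.
#' @export
henderson3_components <- function(spec, records, trait2 = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  y1 <- records[[spec$trait]]
  y2 <- if (!is.null(trait2)) records[[trait2]] else NULL
  per <- records[[paste0("period_", spec$period_basis)]]
  sea <- records[[paste0("season_", spec$season_basis)]]
  cov <- if (spec$afc_covariate) records$afc else NULL
  sire <- records$sire_code
  ok <- !is.na(y1) & !is.na(per) & !is.na(sea) & !is.na(sire)
  if (!is.null(cov)) ok <- ok & !is.na(cov)
  if (!is.null(y2)) ok <- ok & !is.na(y2)
  y1 <- y1[ok]; per <- factor(per[ok]); sea <- factor(sea[ok])
  sire <- factor(sire[ok])
  if (!is.null(cov)) cov <- cov[ok]
  if (!is.null(y2)) y2 <- y2[ok]
  N <- length(y1)
  s <- nlevels(sire)
  if (s < 2) stop("need at least 2 sires with records")
  if (min(table(sire)) < 1) stop("empty sire group")

  X <- matrix(1, N, 1)
  if (nlevels(per) > 1) X <- cbind(X, stats::model.matrix(~per)[, -1])
  if (nlevels(sea) > 1) X <- cbind(X, stats::model.matrix(~sea)[, -1])
  if (!is.null(cov)) X <- cbind(X, cov - mean(cov))
  Zs <- stats::model.matrix(~ sire - 1)
  W <- cbind(X, Zs)
  qrX <- qr(X); qrW <- qr(W)
  rX <- qrX$rank; rW <- qrW$rank
  dfs <- rW - rX
  # residual quadratic / cross-product forms
  e1 <- y1 - proj_fitted(qrW, y1)
  sse1 <- sum(e1^2)
  sigma2_e <- sse1 / (N - rW)
  # R(sire | fixed) and its sire-variance expectation coefficient
  r1 <- sum(proj_fitted(qrW, y1)^2) - sum(proj_fitted(qrX, y1)^2)
  trZQZ <- sum(proj_fitted(qrW, Zs)^2) - sum(proj_fitted(qrX, Zs)^2)
  sigma2_s_raw <- (r1 - dfs * sigma2_e) / trZQZ
  out <- list(
    sigma2_s = max(0, sigma2_s_raw),
    sigma2_e = sigma2_e,
    sigma2_s_raw = sigma2_s_raw,
    truncated = sigma2_s_raw < 0,
    n = N, n_sires = s,
    k = (N - sum(table(sire)^2) / N) / (s - 1),
    df_sire = dfs, coef_sire = trZQZ
  )
  if (!is.null(y2)) {
    e2 <- y2 - proj_fitted(qrW, y2)
    cov_e <- sum(e1 * e2) / (N - rW)
    r12 <- sum(proj_fitted(qrW, y1) * proj_fitted(qrW, y2)) -
           sum(proj_fitted(qrX, y1) * proj_fitted(qrX, y2))
    out$cov_e <- cov_e
    out$cov_s <- (r12 - dfs * cov_e) / trZQZ
    # second trait's own components on the common records
    sse2 <- sum(e2^2)
    out$sigma2_e2 <- sse2 / (N - rW)
    r2 <- sum(proj_fitted(qrW, y2)^2) - sum(proj_fitted(qrX, y2)^2)
    out$sigma2_s2_raw <- (r2 - dfs * out$sigma2_e2) / trZQZ
    out$sigma2_s2 <- max(0, out$sigma2_s2_raw)
  }
  class(out) <- "h3_components"
  out
}

#' Paternal half-sib heritability with Swiger's standard error
#'
#' `h2 = 4 t` with intraclass correlation `t = sigma2_s / (sigma2_s +
#' sigma2_e)`; `SE(h2) = 4 SE(t)` from Swiger's large-sample formula with
#' `s` sire groups, `N` records and effective progeny-group size `k`.
#'
#' @param sigma2_s,sigma2_e Sire and residual variance components.
#' @param k Effective progeny-group size.
#' @param s Number of sire groups.
#' @param N Total record count.
#' @return List of class `phs_estimate`: `h2` (raw), `h2_reported`
#'   (truncated into \[0,1\]), `se_h2`, `t`, `se_t`, `k`, `s`, `N`.
#' @export
phs_heritability <- function(sigma2_s, sigma2_e, k, s, N) {
  tot <- sigma2_s + sigma2_e
  if (tot <= 0) stop("total variance must be positive")
  t <- sigma2_s / tot
  var_t <- 2 * (N - 1) * (1 - t)^2 * (1 + (k - 1) * t)^2 /
    (k^2 * (N - s) * (s - 1))
  est <- list(h2 = 4 * t,
              h2_reported = min(1, max(0, 4 * t)),
              se_h2 = 4 * sqrt(var_t),
              t = t, se_t = sqrt(var_t), k = k, s = s, N = N)
  class(est) <- "phs_estimate"
  est
}

#' @export
print.phs_estimate <- function(x, ...) {
  cat(sprintf("Paternal half-sib h2 = %.3f +/- %.3f (t = %.3f, %d sires, N = %d)\n",
              x$h2_reported, x$se_h2, x$t, x$s, x$N))
  invisible(x)
}

#' Sire-component genetic and phenotypic correlations for trait pairs
#'
#' From pairwise Method III component sets on common records:
#' `r_g = cov_s / sqrt(sigma2_s_x * sigma2_s_y)` and
#' `r_p = (cov_s + cov_e) / sqrt(sigma2_p_x * sigma2_p_y)`. A pair with a
#' non-positive sire variance in either trait yields `NA` for `r_g` with
#' the reason recorded. Values outside \[-1, 1\] (possible with Method III)
#' are clipped for reporting with the raw value retained.
#'
#' @param spec_list Named list of [model_spec()]s, one per trait.
#' @param records Coded phenotype records.
#' @return List of class `phs_correlations` with matrices `r_g`, `r_p`
#'   (clipped), `r_g_raw`, `r_p_raw` and a character matrix `note`.
#' @export
phs_correlations <- function(spec_list, records) {
  traits <- names(spec_list)
  t_n <- length(traits)
  rg <- rp <- matrix(NA_real_, t_n, t_n, dimnames = list(traits, traits))
  note <- matrix("", t_n, t_n, dimnames = list(traits, traits))
  diag(rg) <- diag(rp) <- 1
  for (i in seq_len(t_n - 1)) for (j in (i + 1):t_n) {
    comp <- tryCatch(
      henderson3_components(spec_list[[i]], records, trait2 = traits[j]),
      error = function(e) NULL)
    if (is.null(comp)) { note[i, j] <- note[j, i] <- "inestimable"; next }
    if (comp$sigma2_s_raw <= 0 || comp$sigma2_s2_raw <= 0) {
      note[i, j] <- note[j, i] <- "zero sire variance"
    } else {
      rg[i, j] <- rg[j, i] <-
        comp$cov_s / sqrt(comp$sigma2_s_raw * comp$sigma2_s2_raw)
    }
    p1 <- comp$sigma2_s_raw + comp$sigma2_e
    p2 <- comp$sigma2_s2_raw + comp$sigma2_e2
    if (p1 > 0 && p2 > 0)
      rp[i, j] <- rp[j, i] <- (comp$cov_s + comp$cov_e) / sqrt(p1 * p2)
  }
  out <- list(r_g_raw = rg, r_p_raw = rp,
              r_g = pmin(pmax(rg, -1), 1), r_p = pmin(pmax(rp, -1), 1),
              note = note)
  class(out) <- "phs_correlations"
  out
}
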