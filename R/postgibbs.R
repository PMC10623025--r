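#' Shortest (highest posterior density) credible interval
#'
#' Among all windows of `ceiling(coverage * N)` consecutive order
#' statistics, returns the shortest; ties go to the lowest lower bound.
#'
#' @param samples Numeric vector of stored draws.
#' @param coverage Fraction of samples the interval must contain (0.95).
#' @return Named vector `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, coverage = 0.95) {
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
  n <- length(samples)
  m <- ceiling(coverage * n)
  if (m < 2) stop("too few samples for the requested coverage")
  s <- sort(samples)
  widths <- s[m:n] - s[seq_len(n - m + 1)]
  i <- which.min(widths) # which.min returns the first (lowest lower bound)
  c(lower = s[i], upper = s[i + m - 1])
}

#' Effective sample size by Geyer's initial monotone sequence
#'
#' `ESS = N / (1 + 2 sum rho_k)` with the autocorrelation sum truncated
#' where the sums of adjacent autocovariance pairs stop being positive and
#' forced monotone non-increasing. Capped at `N`. A zero-variance chain
#' returns `N` with a warning.
#'
#' @param samples Numeric chain (>= 10 draws).
#' @return Effective sample size (scalar).
#' @export
effective_sample_size <- function(samples) {
  n <- length(samples)
  if (n < 10) stop("need at least 10 samples")
  v <- stats::var(samples)
  if (v == 0) {
    warning("zero-variance chain: effective size set to N")
    return(n)
  }
  max_lag <- min(n - 1L, as.integer(ceiling(10 * sqrt(n))))
  ac <- stats::acf(samples, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  # initial positive sequence of paired sums Gamma_m = rho_{2m} + rho_{2m+1}
  n_pairs <- (max_lag + 1) %/% 2
  big_gamma <- numeric(0)
  for (m in seq_len(n_pairs)) {
    g <- ac[2 * m - 1] + if (2 * m <= max_lag + 1) ac[2 * m] else 0
    if (g <= 0) break
    big_gamma <- c(big_gamma, g)
  }
  if (length(big_gamma)) big_gamma <- cummin(big_gamma)
  tau <- -1 + 2 * sum(big_gamma) # = 1 + 2 sum_{k>=1} rho_k (Gamma_1 holds rho_0)
  tau <- max(tau, 1 / n)
  min(n, n / tau)
}

#' Geweke stationarity diagnostic
#'
#' z-test of equal means between an early window (first `frac_a`) and a
#' late window (last `frac_b`) of the chain, with the variance of each
#' window mean estimated by batch means (about sqrt(n) batches).
#'
#' @param samples Numeric chain.
#' @param frac_a Early-window fraction (default 0.10).
#' @param frac_b Late-window fraction (default 0.50).
#' @return z statistic (scalar).
#' @export
geweke_z <- function(samples, frac_a = 0.10, frac_b = 0.50) {
  n <- length(samples)
  a <- samples[seq_len(floor(frac_a * n))]
  b <- samples[(n - floor(frac_b * n) + 1):n]
  if (length(a) < 10 || length(b) < 10)
    stop("Geweke windows must each contain at least 10 samples")
  # overlapping batch means estimate of the spectral density at zero
  bm_var <- function(x) {
    nx <- length(x)
    bs <- max(2L, floor(sqrt(nx)))
    cs <- c(0, cumsum(x))
    means <- (cs[(bs + 1):(nx + 1)] - cs[1:(nx - bs + 1)]) / bs
    nb <- length(means)
    bs * sum((means - mean(x))^2) / nb
  }
  (mean(a) - mean(b)) /
    sqrt(bm_var(a) / length(a) + bm_var(b) / length(b))
}

#' Monte-Carlo error of a posterior mean
#'
#' The SD-scaled convention: `MCE = SD / sqrt(ESS)`.
#'
#' @param sd Posterior standard deviation.
#' @param ess Effective sample size.
#' @return Monte-Carlo error.
#' @export
mc_error <- function(sd, ess) sd / sqrt(ess)

# Freedman-Diaconis histogram modal-bin midpoint
fd_mode <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(x[1])
  iqr <- stats::IQR(x)
  h <- if (iqr > 0) 2 * iqr / length(x)^(1 / 3) else diff(r) / 30
  nb <- min(10000L, max(1L, ceiling(diff(r) / h)))
  br <- seq(r[1], r[2], length.out = nb + 1)
  hist <- graphics::hist(x, breaks = br, include.lowest = TRUE,
                         plot = FALSE)
  hist$mids[which.max(hist$counts)]
}

#' Posterior summary of a scalar chain
#'
#' Mean, mode (Freedman-Diaconis histogram modal-bin midpoint), median, SD
#' (denominator N-1), shortest 95% HPD interval, Geyer effective sample
#' size, Monte-Carlo error `SD / sqrt(ESS)` and the Geweke z statistic.
#'
#' @param samples Numeric chain (>= 10 stored draws).
#' @param coverage HPD coverage (default 0.95).
#' @return One-row data.frame with columns `mean, mode, median, sd,
#'   hpd_lower, hpd_upper, ess, mce, geweke_z`.
#' @export
summarize_chain <- function(samples, coverage = 0.95) {
  if (length(samples) < 10) stop("need at least 10 stored samples")
  sd_s <- stats::sd(samples)
  if (sd_s == 0) {
    hpd <- c(lower = samples[1], upper = samples[1])
    ess <- suppressWarnings(effective_sample_size(samples))
    z <- NA_real_
  } else {
    hpd <- hpd_interval(samples, coverage)
    ess <- effective_sample_size(samples)
    z <- tryCatch(geweke_z(samples), error = function(e) NA_real_)
  }
  data.frame(mean = mean(samples), mode = fd_mode(samples),
             median = stats::median(samples), sd = sd_s,
             hpd_lower = hpd[["lower"]], hpd_upper = hpd[["upper"]],
             ess = ess, mce = mc_error(sd_s, ess), geweke_z = z)
}

#' Derived genetic parameters from stored covariance draws
#'
#' For every stored draw computes, per trait, `h2 = s2_g / (s2_g + s2_e)`
#' and `s2_p = s2_g + s2_e`, and per trait pair the genetic correlation
#' `r_g = cov_g / sqrt(s2_g_x s2_g_y)` and the phenotypic correlation from
#' `P0 = G0 + R0`. Draws whose G0 or R0 is not positive definite are
#' excluded and counted. Summaries come from [summarize_chain()]; the `mce`
#' column is the convention behind the reported "+/-" of posterior means,
#' and the posterior `sd` column is also given so either convention can be
#' read.
#'
#' @param result A `gibbs_result` from [run_chain()].
#' @return List of class `derived_parameters`: `chains` (data.frame, one
#'   column per derived parameter, one row per retained draw), `summary`
#'   (one row per parameter, Table-style columns), `n_excluded`.
#' @export
derive_parameters <- function(result) {
  traits <- result$traits
  t_n <- length(traits)
  n_s <- nrow(result$G)
  keep <- rep(TRUE, n_s)
  cols <- list()
  # draws on the PSD boundary (e.g. perfectly correlated traits) are kept;
  # only indefinite draws are excluded
  is_pd <- function(M) {
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    all(ev > -1e-8 * max(abs(ev)))
  }
  G_arr <- array(0, c(t_n, t_n, n_s))
  R_arr <- array(0, c(t_n, t_n, n_s))
  for (i in seq_len(n_s)) {
    G <- unpack_symmetric(result$G[i, ], t_n)
    R <- unpack_symmetric(result$R[i, ], t_n)
    if (!is_pd(G) || !is_pd(R)) keep[i] <- FALSE
    G_arr[, , i] <- G
    R_arr[, , i] <- R
  }
  G_arr <- G_arr[, , keep, drop = FALSE]
  R_arr <- R_arr[, , keep, drop = FALSE]
  m <- sum(keep)
  for (k in seq_len(t_n)) {
    g <- G_arr[k, k, ]; e <- R_arr[k, k, ]
    cols[[paste0("s2_g_", traits[k])]] <- g
    cols[[paste0("s2_e_", traits[k])]] <- e
    cols[[paste0("s2_p_", traits[k])]] <- g + e
    cols[[paste0("h2_", traits[k])]] <- g / (g + e)
  }
  if (t_n > 1) {
    for (i in 2:t_n) for (j in seq_len(i - 1)) {
      gij <- G_arr[i, j, ]
      pij <- G_arr[i, j, ] + R_arr[i, j, ]
      cols[[paste0("rg_", traits[i], "_", traits[j])]] <-
        gij / sqrt(G_arr[i, i, ] * G_arr[j, j, ])
      cols[[paste0("rp_", traits[i], "_", traits[j])]] <-
        pij / sqrt((G_arr[i, i, ] + R_arr[i, i, ]) *
                   (G_arr[j, j, ] + R_arr[j, j, ]))
    }
  }
  chains <- as.data.frame(cols)
  summ <- NULL
  if (nrow(chains) >= 10) {
    summ <- do.call(rbind, lapply(names(chains), function(p) {
      s <- summarize_chain(chains[[p]])
      cbind(parameter = p, s)
    }))
    rownames(summ) <- NULL
  } else {
    warning("fewer than 10 retained draws: summaries omitted")
  }
  structure(list(chains = chains, summary = summ,
                 n_excluded = n_s - m, traits = traits),
            class = "derived_parameters")
}

#' @export
print.derived_parameters <- function(x, ...) {
  cat("Posterior summaries (", nrow(x$chains), " draws",
      if (x$n_excluded) paste0(", ", x$n_excluded, " non-PD draws excluded"),
      "):\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Posterior summary table for the raw (co)variance chains
#'
#' One row per stored (co)variance element of G0 and R0, in the standard
#' column order `parameter, mean, mode, median, sd, hpd_lower, hpd_upper,
#' ess, mce, geweke_z`.
#'
#' @param result A `gibbs_result`.
#' @return Data.frame.
#' @export
posterior_summary_table <- function(result) {
  M <- cbind(result$G, result$R)
  out <- do.call(rbind, lapply(colnames(M), function(p) {
    cbind(parameter = p, summarize_chain(M[, p]))
  }))
  rownames(out) <- NULL
  out
}
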