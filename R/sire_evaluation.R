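#' Solve Henderson's mixed-model equations
#'
#' Builds and solves
#' `[X'X/s2e, X'Z/s2e; Z'X/s2e, Z'Z/s2e + K/s2g] [b; u] = [X'y; Z'y]/s2e`
#' for a univariate model, where `K` is the random-effect precision
#' structure (A-inverse for the animal model, identity for the sire model).
#' The solver is Jacobi-preconditioned conjugate gradient at relative
#' tolerance 1e-10, with a sparse direct solve fallback for systems up to
#' 2000 random levels.
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix (full rank).
#' @param z Integer vector mapping each record to a random-effect level
#'   (1..q).
#' @param q Number of random levels (defaults to `max(z)`; pass the
#'   pedigree size for the animal model).
#' @param K Precision structure of the random effect (sparse symmetric;
#'   default identity).
#' @param sigma2_u,sigma2_e Variance components (both > 0).
#' @return List with `beta`, `u` (length q), `lambda`, `converged`,
#'   `solver`.
#' @export
solve_mme <- function(y, X, z, sigma2_u, sigma2_e, q = max(z), K = NULL) {
  if (sigma2_u <= 0 || sigma2_e <= 0)
    stop("variance components must be positive definite")
  n <- length(y)
  p <- ncol(X)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = z, x = 1, dims = c(n, q))
  if (is.null(K)) K <- Matrix::Diagonal(q)
  lambda <- sigma2_e / sigma2_u
  X <- Matrix::Matrix(X, sparse = TRUE)
  C <- rbind(
    cbind(Matrix::crossprod(X), Matrix::crossprod(X, Z)),
    cbind(Matrix::crossprod(Z, X), Matrix::crossprod(Z) + lambda * K)
  )
  rhs <- c(as.vector(Matrix::crossprod(X, y)),
           as.vector(Matrix::crossprod(Z, y)))
  sol <- pcg_solve(C, rhs)
  if (!sol$converged) {
    if (q <= 2000) {
      sol <- list(x = as.vector(Matrix::solve(C, rhs)), converged = TRUE,
                  solver = "direct")
    } else {
      stop("mixed-model equations solver did not converge")
    }
  }
  list(beta = sol$x[seq_len(p)], u = sol$x[p + seq_len(q)],
       lambda = lambda, converged = sol$converged,
       solver = if (is.null(sol$solver)) "pcg" else sol$solver)
}

# Jacobi-preconditioned conjugate gradient on a sparse symmetric system
pcg_solve <- function(C, b, tol = 1e-12, maxit = 20000) {
  d <- Matrix::diag(C)
  d[d == 0] <- 1
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  b_norm <- sqrt(sum(b^2))
  if (b_norm == 0) return(list(x = x, converged = TRUE))
  for (i in seq_len(maxit)) {
    Cp <- as.vector(C %*% p)
    alpha <- rz / sum(p * Cp)
    x <- x + alpha * p
    r <- r - alpha * Cp
    if (sqrt(sum(r^2)) / b_norm < tol)
      return(list(x = x, converged = TRUE, iterations = i))
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, converged = FALSE, iterations = maxit)
}

#' BLUP sire evaluation by either route
#'
#' Frequentist route: sire-model BLUP with the intraclass variance ratio
#' from the half-sib heritability, `lambda = (4 - h2) / h2`, EBV = 2 x sire
#' solution. Bayesian route: animal-model BLUP with the posterior-mean
#' genetic and residual variances and the pedigree A-inverse; a sire's EBV
#' is its own animal solution.
#'
#' @param spec A [model_spec()].
#' @param records Coded phenotype records (`animal_code`, `sire_code`).
#' @param method `"sire_model"` or `"animal_model"`.
#' @param h2 Half-sib heritability (sire-model route).
#' @param sigma2_g,sigma2_e Variance components (animal-model route).
#' @param Ainv Sparse A-inverse over the full pedigree (animal-model route).
#' @param min_progeny Only sires with more than this many recorded progeny
#'   are evaluated (default 3).
#' @return Data.frame of class `sire_evaluation`: `sire_code`, `ebv`,
#'   `n_progeny`, `rank` (1 = best, ties broken by sire code).
#' @export
evaluate_sires <- function(spec, records,
                           method = c("sire_model", "animal_model"),
                           h2 = NULL, sigma2_g = NULL, sigma2_e = NULL,
                           Ainv = NULL, min_progeny = 3) {
  method <- match.arg(method)
  if (method == "sire_model")
    records <- records[!is.na(records$sire_code), , drop = FALSE]
  d <- build_design(spec, records)
  sires <- records$sire_code[d$rows]
  if (method == "sire_model") {
    if (is.null(h2) || h2 <= 0 || h2 > 1)
      stop("sire-model route needs h2 in (0, 1]")
    sire_levels <- sort(unique(sires))
    zi <- match(sires, sire_levels)
    lambda <- (4 - h2) / h2
    sol <- solve_mme(d$y, d$X, zi, sigma2_u = 1, sigma2_e = lambda,
                     q = length(sire_levels))
    ebv <- 2 * sol$u
    tab <- data.frame(sire_code = sire_levels, ebv = ebv)
  } else {
    if (is.null(sigma2_g) || is.null(sigma2_e) || is.null(Ainv))
      stop("animal-model route needs sigma2_g, sigma2_e and Ainv")
    sol <- solve_mme(d$y, d$X, d$z, sigma2_u = sigma2_g,
                     sigma2_e = sigma2_e, q = nrow(Ainv), K = Ainv)
    sire_levels <- sort(unique(sires))
    tab <- data.frame(sire_code = sire_levels, ebv = sol$u[sire_levels])
  }
  cnt <- table(sires)
  tab$n_progeny <- as.integer(cnt[as.character(tab$sire_code)])
  tab <- tab[tab$n_progeny > min_progeny, , drop = FALSE]
  ord <- order(-tab$ebv, tab$sire_code)
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("sire_evaluation", "data.frame")
  attr(tab, "method") <- method
  tab
}

#' Spearman rank comparison of two sire rankings
#'
#' `r` is the Spearman correlation (average ranks on ties),
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, with a
#' two-sided verdict at alpha = 0.05. Perfect agreement (`|r| = 1`) flags
#' `t` as unbounded and the verdict significant.
#'
#' @param ranks_a,ranks_b Equal-length numeric vectors (ranks or scores;
#'   Spearman ranks internally), `n >= 3`.
#' @return List of class `rank_comparison`: `r`, `t`, `df`, `p`,
#'   `verdict`, `n`.
#' @export
spearman_t <- function(ranks_a, ranks_b) {
  n <- length(ranks_a)
  if (length(ranks_b) != n) stop("rank vectors must have equal length")
  if (n < 3) stop("need at least 3 sires")
  r <- stats::cor(ranks_a, ranks_b, method = "spearman")
  out <- spearman_t_stat(r, n)
  class(out) <- "rank_comparison"
  out
}

#' t statistic for a Spearman rank correlation
#'
#' @param r Rank correlation.
#' @param n Number of paired ranks.
#' @return List with `r`, `t`, `df = n - 2`, `p`, `verdict`.
#' @export
spearman_t_stat <- function(r, n) {
  df <- n - 2
  if (abs(r) >= 1) {
    return(list(r = r, t = Inf * sign(r), df = df, p = 0,
                verdict = "significant", unbounded = TRUE, n = n))
  }
  t <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df)
  list(r = r, t = t, df = df, p = p,
       verdict = if (p < 0.05) "significant" else "non-significant",
       unbounded = FALSE, n = n)
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf("Spearman r = %.3f, t = %s, df = %d: %s\n",
              x$r, if (is.finite(x$t)) sprintf("%.2f", x$t) else "unbounded",
              x$df, x$verdict))
  invisible(x)
}

#' Compare sire rankings from the two evaluation routes
#'
#' @param eval_a,eval_b `sire_evaluation` tables for the same trait; only
#'   sires present in both are compared.
#' @return A `rank_comparison` (see [spearman_t()]).
#' @export
compare_sire_rankings <- function(eval_a, eval_b) {
  common <- intersect(eval_a$sire_code, eval_b$sire_code)
  if (length(common) < 3) stop("fewer than 3 sires evaluated by both routes")
  a <- eval_a$ebv[match(common, eval_a$sire_code)]
  b <- eval_b$ebv[match(common, eval_b$sire_code)]
  spearman_t(a, b)
}
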