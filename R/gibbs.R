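#' Gibbs chain configuration
#'
#' @param total Total iterations (default 30000).
#' @param burn_in Discarded initial iterations (default 1000).
#' @param thin Storage interval: every `thin`-th post-burn-in draw is kept
#'   (default 10).
#' @return List of class `chain_config` with `n_stored =
#'   floor((total - burn_in) / thin)`.
#' @export
chain_config <- function(total = 30000, burn_in = 1000, thin = 10) {
  if (burn_in >= total) stop("burn_in must be smaller than total")
  if (thin < 1) stop("thinning interval must be >= 1")
  structure(list(total = as.integer(total), burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 n_stored = (as.integer(total) - as.integer(burn_in)) %/%
                   as.integer(thin)),
            class = "chain_config")
}

#' @export
print.chain_config <- function(x, ...) {
  cat(sprintf("Gibbs chain: %d iterations, %d burn-in, thin %d -> %d stored\n",
              x$total, x$burn_in, x$thin, x$n_stored))
  invisible(x)
}

#' Inverse-Wishart prior for a covariance matrix
#'
#' Default is weakly informative: `nu = t + 2` degrees of freedom and scale
#' `(nu - t - 1) * diag(half the phenotypic variances)`, so the prior mean
#' sits at half the observed phenotypic (co)variance. `flat = TRUE` selects
#' the improper flat prior (zero scale, `nu = -(t + 1)`); the posterior is
#' then proper only when the data dominate, and a warning is issued.
#'
#' @param pheno_var Numeric vector of phenotypic variances, one per trait.
#' @param nu Degrees of freedom (default `t + 2`).
#' @param scale Scale matrix (default as above).
#' @param flat Use the flat prior.
#' @return List of class `prior_spec` with elements `S` and `nu`.
#' @export
prior_spec <- function(pheno_var, nu = NULL, scale = NULL, flat = FALSE) {
  t_n <- length(pheno_var)
  if (flat) {
    warning("flat prior selected: posterior is improper unless the data ",
            "carry enough information")
    return(structure(list(S = matrix(0, t_n, t_n), nu = -(t_n + 1),
                          flat = TRUE), class = "prior_spec"))
  }
  if (is.null(nu)) nu <- t_n + 2
  if (nu < t_n + 1) stop("proper prior requires nu >= t + 1")
  if (is.null(scale)) scale <- (nu - t_n - 1) * diag(pheno_var / 2, t_n)
  structure(list(S = scale, nu = nu, flat = FALSE), class = "prior_spec")
}

#' Draw from an inverse-Wishart distribution
#'
#' Density proportional to
#' `|W|^{-(dof + t + 1)/2} exp(-tr(scale W^{-1}) / 2)`, with mean
#' `scale / (dof - t - 1)` for `dof > t + 1`.
#'
#' @param scale Symmetric positive-definite scale matrix.
#' @param dof Degrees of freedom, `> t - 1`.
#' @param n Number of draws.
#' @return A matrix for `n = 1`, else an array `t x t x n`.
#' @export
sample_inv_wishart <- function(scale, dof, n = 1) {
  scale <- as.matrix(scale)
  t_n <- nrow(scale)
  if (dof <= t_n - 1) stop("dof must exceed t - 1")
  ev <- eigen(scale, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("scale matrix must be positive definite")
  W <- stats::rWishart(n, df = dof, Sigma = solve(scale))
  out <- array(apply(W, 3, solve), dim = dim(W))
  if (n == 1) out[, , 1] else out
}

lower_tri_names <- function(traits, prefix) {
  t_n <- length(traits)
  nm <- character(0)
  for (r in seq_len(t_n)) for (cc in seq_len(r))
    nm <- c(nm, paste(prefix, traits[r], traits[cc], sep = "_"))
  nm
}

#' Unpack a lower-triangle row into a symmetric matrix
#' @param v Numeric vector of length t(t+1)/2, row-major lower triangle.
#' @param t_n Matrix dimension.
#' @return Symmetric t x t matrix.
#' @export
unpack_symmetric <- function(v, t_n) {
  M <- matrix(0, t_n, t_n)
  c <- 1
  for (r in seq_len(t_n)) for (cc in seq_len(r)) {
    M[r, cc] <- M[cc, r] <- v[c]
    c <- c + 1
  }
  M
}

#' Run the Gibbs sampler for a single- or multi-trait animal model
#'
#' Complete-case records for the trait set are assembled, each trait gets
#' its fixed-effect design from its model template, and the chain samples
#' location effects (single-site Gauss-Seidel sweep) and the genetic and
#' residual covariance matrices (inverse-Wishart full conditionals).
#' Starting values for both matrices are half the phenotypic covariance of
#' the trait set. Identical seeds give bit-identical chains.
#'
#' @param specs A [model_spec()] or list of them (one per trait, animal
#'   random effect).
#' @param records Coded phenotype records with `animal_code`.
#' @param Ainv Sparse A-inverse from [build_A_inverse()] (dimension = full
#'   pedigree).
#' @param config A [chain_config()].
#' @param prior A [prior_spec()]; default built from the data.
#' @param seed Random seed (integer); `NULL` leaves the RNG state alone.
#' @param fix_variances Keep G0 and R0 at their starting values and sample
#'   only location effects (for solver cross-checks).
#' @param G0_start,R0_start Optional starting covariance matrices.
#' @param overflow_mult Abort if a sampled variance exceeds this multiple of
#'   its starting value (default 1e12).
#' @return Object of class `gibbs_result`: matrices `G`, `R` (one stored
#'   draw per row, row-major lower triangle), `traits`, `config`, posterior
#'   running means of location effects (`beta_mean`, `u_mean`), `n_records`.
#' @export
run_chain <- function(specs, records, Ainv, config = chain_config(),
                      prior = NULL, seed = NULL, fix_variances = FALSE,
                      G0_start = NULL, R0_start = NULL,
                      overflow_mult = 1e12) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  traits <- vapply(specs, function(s) s$trait, character(1))
  t_n <- length(traits)
  # common complete-case rows across the trait set
  designs <- lapply(specs, build_design, records = records)
  rows <- Reduce(intersect, lapply(designs, `[[`, "rows"))
  if (length(rows) < 2) stop("too few complete-case records for trait set")
  sub <- records[rows, , drop = FALSE]
  designs <- lapply(specs, build_design, records = sub)
  y <- vapply(designs, `[[`, numeric(nrow(sub)), "y")
  y <- matrix(y, ncol = t_n)
  Xl <- lapply(designs, `[[`, "X")
  anim <- designs[[1]]$z
  P <- stats::cov(y)
  if (is.null(G0_start)) G0_start <- P / 2
  if (is.null(R0_start)) R0_start <- P / 2
  if (is.null(prior)) prior <- prior_spec(diag(P))
  if (!is.null(seed)) set.seed(seed)
  res <- gibbs_chain_cpp(y, Xl, as.integer(anim),
                         methods::as(methods::as(Ainv, "generalMatrix"),
                                     "CsparseMatrix"),
                         as.matrix(G0_start), as.matrix(R0_start),
                         as.matrix(prior$S), prior$nu,
                         as.matrix(prior$S), prior$nu,
                         config$total, config$burn_in, config$thin,
                         fix_variances, overflow_mult)
  colnames(res$G) <- lower_tri_names(traits, "g")
  colnames(res$R) <- lower_tri_names(traits, "r")
  structure(list(G = res$G, R = res$R, iteration = drop(res$iteration),
                 traits = traits, config = config,
                 beta_mean = res$beta_mean, u_mean = res$u_mean,
                 n_records = nrow(y), n_stored = res$n_stored,
                 G0_start = G0_start, R0_start = R0_start,
                 prior = prior, seed = seed),
            class = "gibbs_result")
}

#' @export
print.gibbs_result <- function(x, ...) {
  cat(sprintf("Gibbs chain for %s: %d stored draws (%d records)\n",
              paste(toupper(x$traits), collapse = " + "),
              x$n_stored, x$n_records))
  invisible(x)
}
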