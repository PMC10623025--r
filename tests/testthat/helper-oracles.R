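# Independent oracles and small fixture builders used across the suite.

# Recursive-kinship oracle (memoised): f(i,j) coefficients of coancestry,
# independent of the tabular pass used by the package.
kinship_oracle <- function(rped) {
  q <- nrow(rped)
  s <- rped$sire_code
  d <- rped$dam_code
  memo <- matrix(NA_real_, q, q)
  f <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (!is.na(memo[i, j])) return(memo[i, j])
    val <- if (i == j) {
      0.5 * (1 + f(s[i], d[i]))
    } else {
      a <- max(i, j); b <- min(i, j) # codes are parent-before-offspring
      0.5 * (f(s[a], b) + f(d[a], b))
    }
    memo[i, j] <<- memo[j, i] <<- val
    val
  }
  A <- matrix(0, q, q)
  for (i in seq_len(q)) for (j in seq_len(i)) A[i, j] <- A[j, i] <- 2 * f(i, j)
  A
}

# Random multi-generation pedigree with sexed animals (acyclic by
# construction); returns the raw record data.frame.
random_pedigree <- function(q, seed, p_known = 0.7) {
  set.seed(seed)
  sex <- sample(c("M", "F"), q, replace = TRUE)
  sex[1:2] <- c("M", "F")
  sire <- dam <- rep(NA_character_, q)
  for (i in 3:q) {
    males <- which(sex[seq_len(i - 1)] == "M")
    females <- which(sex[seq_len(i - 1)] == "F")
    if (length(males) && stats::runif(1) < p_known)
      sire[i] <- paste0("X", males[sample.int(length(males), 1)])
    if (length(females) && stats::runif(1) < p_known)
      dam[i] <- paste0("X", females[sample.int(length(females), 1)])
  }
  data.frame(animal = paste0("X", seq_len(q)), sire = sire, dam = dam,
             stringsAsFactors = FALSE)
}

# Brute-force shortest interval containing >= coverage * N samples,
# enumerating every pair of order statistics (not a window scan).
brute_hpd <- function(samples, coverage = 0.95) {
  s <- sort(samples)
  n <- length(s)
  m <- ceiling(coverage * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 >= m && (s[j] - s[i]) < (best[2] - best[1])) {
        best <- c(s[i], s[j])
      }
    }
  }
  best
}

# Minimal coded record set for generic variance-component simulations:
# constant fixed-effect classes so only the intercept enters the model.
half_sib_records <- function(n_sires, n_progeny, sigma2_s, sigma2_e,
                             mu = 10) {
  n <- n_sires * n_progeny
  sire <- rep(seq_len(n_sires), each = n_progeny)
  u <- stats::rnorm(n_sires, 0, sqrt(sigma2_s))
  y <- mu + u[sire] + stats::rnorm(n, 0, sqrt(sigma2_e))
  data.frame(
    afc = y,
    sire_code = sire,
    animal_code = seq_len(n),
    period_birth = factor(1), season_birth = factor("winter"),
    period_calving = factor(1), season_calving = factor("winter")
  )
}

# Coded records with real factor structure but no genetic signal.
null_records <- function(n, n_sires = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    afc = stats::rnorm(n),
    sire_code = sample(seq_len(n_sires), n, replace = TRUE),
    animal_code = seq_len(n),
    period_birth = factor(sample(1:3, n, replace = TRUE), levels = 1:3),
    season_birth = factor(sample(c("summer", "rainy", "autumn", "winter"),
                                 n, replace = TRUE),
                          levels = c("summer", "rainy", "autumn", "winter")),
    period_calving = factor(sample(1:3, n, replace = TRUE), levels = 1:3),
    season_calving = factor(sample(c("summer", "rainy", "autumn", "winter"),
                                   n, replace = TRUE),
                            levels = c("summer", "rainy", "autumn", "winter"))
  )
}

# Two-point sample with a prescribed mean and (n-1)-denominator SD.
two_point_sample <- function(mean, sd) {
  c(mean - sd / sqrt(2), mean + sd / sqrt(2))
}
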