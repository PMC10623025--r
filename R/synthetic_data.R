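#' Default trait means and dispersions for the emulated herd
#'
#' Per-trait means and phenotypic SDs on the scale of a zebu dairy herd
#' (AFC about 1228 d, first-lactation milk yield about 1765 kg, ...), used
#' as generator defaults.
#'
#' @return Data.frame with `trait`, `mean`, `sd`, `min`, `max`.
#' @export
default_trait_scales <- function() {
  data.frame(
    trait = c("afc", "fsp", "flmy", "flfy", "flsnfy", "ltmy", "pl", "hl"),
    mean = c(1227.73, 148.37, 1765.44, 2701.79, 1482.38,
             5374.76, 1292.72, 2555.11),
    sd = c(179.45, 94.21, 697.26, 409.36, 269.02, 3119.39, 639.90, 655.63),
    min = c(879, 41, 506, 2029.83, 952.05, 701, 492, 1650),
    max = c(1554, 374, 3149.1, 3579.81, 2012.39, 13433.6, 3010, 4233),
    stringsAsFactors = FALSE
  )
}

# Genetic and residual variances per trait (posterior-mean magnitudes of
# the emulated herd) and the correlation structure used to fill G0 and R0.
default_variances <- function() {
  data.frame(
    trait = c("afc", "fsp", "flmy", "flfy", "flsnfy", "ltmy", "pl", "hl"),
    sigma2_g = c(21689, 10175, 2589900, 2831800, 811450,
                 2956500, 276470, 247420),
    sigma2_e = c(14045, 7089.9, 1864000, 1870800, 533640,
                 9230900, 378520, 412820),
    stringsAsFactors = FALSE
  )
}

default_genetic_correlations <- function() {
  tr <- c("afc", "fsp", "flmy", "flfy", "flsnfy", "ltmy", "pl", "hl")
  R <- diag(8)
  dimnames(R) <- list(tr, tr)
  set_r <- function(a, b, v) {
    R[a, b] <<- v; R[b, a] <<- v
  }
  set_r("afc", "fsp", 0.32); set_r("afc", "flmy", 0.68)
  set_r("afc", "flfy", 0.80); set_r("afc", "flsnfy", 0.85)
  set_r("afc", "pl", -0.59); set_r("afc", "hl", -0.59)
  set_r("fsp", "flmy", 0.59); set_r("fsp", "flfy", 0.65)
  set_r("fsp", "flsnfy", 0.63); set_r("fsp", "pl", -0.38)
  set_r("fsp", "hl", -0.34)
  set_r("flmy", "flfy", 0.92); set_r("flmy", "flsnfy", 0.93)
  set_r("flmy", "pl", 0.13); set_r("flmy", "hl", 0.23)
  set_r("flfy", "flsnfy", 0.99); set_r("flfy", "pl", 0.33)
  set_r("flfy", "hl", 0.25)
  set_r("flsnfy", "pl", 0.35); set_r("flsnfy", "hl", 0.26)
  set_r("pl", "hl", 0.95)
  # lifetime milk yield: correlations from the half-sib track (the
  # multi-trait chain dropped this trait), zero where inestimable
  set_r("ltmy", "afc", -0.0566); set_r("ltmy", "fsp", -0.3640)
  set_r("ltmy", "flmy", 0.1423); set_r("ltmy", "flfy", -0.0134)
  set_r("ltmy", "flsnfy", -0.0037)
  R
}

default_phenotypic_correlations <- function() {
  tr <- c("afc", "fsp", "flmy", "flfy", "flsnfy", "ltmy", "pl", "hl")
  R <- diag(8)
  dimnames(R) <- list(tr, tr)
  set_r <- function(a, b, v) {
    R[a, b] <<- v; R[b, a] <<- v
  }
  set_r("afc", "fsp", 0.46); set_r("afc", "flmy", 0.77)
  set_r("afc", "flfy", 0.85); set_r("afc", "flsnfy", 0.87)
  set_r("afc", "pl", -0.33); set_r("afc", "hl", -0.21)
  set_r("fsp", "flmy", 0.54); set_r("fsp", "flfy", 0.64)
  set_r("fsp", "flsnfy", 0.64); set_r("fsp", "pl", -0.16)
  set_r("fsp", "hl", -0.04)
  set_r("flmy", "flfy", 0.92); set_r("flmy", "flsnfy", 0.93)
  set_r("flmy", "pl", 0.19); set_r("flmy", "hl", 0.25)
  set_r("flfy", "flsnfy", 0.99); set_r("flfy", "pl", 0.23)
  set_r("flfy", "hl", 0.23)
  set_r("flsnfy", "pl", 0.24); set_r("flsnfy", "hl", 0.23)
  set_r("pl", "hl", 0.96)
  set_r("ltmy", "afc", -0.0466); set_r("ltmy", "fsp", -0.3821)
  set_r("ltmy", "flmy", 0.6580); set_r("ltmy", "flfy", 0.0202)
  set_r("ltmy", "flsnfy", -0.0443)
  R
}

# Project a symmetric matrix to positive definiteness while preserving a
# target diagonal: alternate eigenvalue clipping with diagonal rescaling.
project_pd <- function(M, target_diag = diag(M)) {
  M <- (M + t(M)) / 2
  for (i in 1:100) {
    e <- eigen(M, symmetric = TRUE)
    if (min(e$values) > 1e-8 * max(e$values)) break
    vals <- pmax(e$values, 1e-4 * max(e$values))
    M <- e$vectors %*% (vals * t(e$vectors))
    s <- sqrt(target_diag / diag(M))
    M <- M * outer(s, s)
  }
  (M + t(M)) / 2
}

cor_to_cov <- function(R, v) {
  s <- sqrt(v)
  project_pd(R * outer(s, s), target_diag = v)
}

#' Simulation parameters for a synthetic herd
#'
#' Defaults emulate a zebu dairy herd of about 964 recorded cows born over
#' three decades: 8 founder sires, 482 founder dams, one recorded daughter
#' per dam, trait scales from [default_trait_scales()], and genetic/residual
#' covariance matrices assembled from the default variance magnitudes and
#' correlation structure (projected to the nearest positive-definite
#' matrix). Fixed-effect magnitudes are moderate: season effects of about
#' 0.25 phenotypic SD, a linear period trend of about 0.1 SD per period,
#' and an AFC covariate slope of 0.1 trait-SD per AFC-SD.
#'
#' @param traits Trait subset to simulate (default all eight).
#' @param n_sires,n_dams Founder counts.
#' @param progeny_per_mating Recorded progeny per mating (>= 1).
#' @param n_generations Number of descendant generations (>= 1).
#' @param G0,R0 True genetic / residual covariance matrices (trait order =
#'   `traits`).
#' @param means Named trait means.
#' @param season_effect,period_trend,afc_slope Fixed-effect magnitudes as
#'   fractions of the phenotypic SD (see details above).
#' @param birth_year_range Founder-cohort birth years.
#' @param seed Seed recorded in the parameter set (used by the simulators).
#' @return List of class `sim_params`.
#' @export
sim_params <- function(traits = default_trait_scales()$trait,
                       n_sires = 8, n_dams = 482,
                       progeny_per_mating = 1, n_generations = 1,
                       G0 = NULL, R0 = NULL, means = NULL,
                       season_effect = 0.25, period_trend = 0.10,
                       afc_slope = 0.10,
                       birth_year_range = c(1986, 2014),
                       seed = 1L) {
  sc <- default_trait_scales()
  sc <- sc[match(traits, sc$trait), ]
  vv <- default_variances()
  vv <- vv[match(traits, vv$trait), ]
  if (is.null(G0) && is.null(R0)) {
    G0 <- cor_to_cov(default_genetic_correlations()[traits, traits,
                                                    drop = FALSE],
                     vv$sigma2_g)
    # residual covariance from phenotypic minus genetic covariance
    P <- cor_to_cov(default_phenotypic_correlations()[traits, traits,
                                                      drop = FALSE],
                    vv$sigma2_g + vv$sigma2_e)
    R0 <- project_pd(P - G0, target_diag = vv$sigma2_e)
    # rescale each trait so the total variance matches the descriptive
    # phenotypic SD while keeping heritabilities and correlations; the
    # posterior-scale variance magnitudes and the descriptive dispersion
    # are not mutually consistent for the production traits, and the
    # generator follows the descriptive scale
    D <- diag(sc$sd / sqrt(vv$sigma2_g + vv$sigma2_e),
              nrow = length(traits))
    G0 <- D %*% G0 %*% D
    R0 <- D %*% R0 %*% D
    dimnames(G0) <- dimnames(R0) <- list(traits, traits)
  } else if (is.null(G0) || is.null(R0)) {
    stop("supply both G0 and R0, or neither")
  }
  if (is.null(means)) means <- stats::setNames(sc$mean, traits)
  ev_g <- eigen(G0, symmetric = TRUE, only.values = TRUE)$values
  ev_r <- eigen(R0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_g) <= 0 || min(ev_r) <= 0)
    stop("G0 and R0 must be positive definite")
  h2 <- diag(G0) / (diag(G0) + diag(R0))
  if (any(h2 <= 0 | h2 >= 1)) stop("implied heritabilities must be in (0,1)")
  structure(list(traits = traits, n_sires = n_sires, n_dams = n_dams,
                 progeny_per_mating = progeny_per_mating,
                 n_generations = n_generations,
                 G0 = G0, R0 = R0, means = means,
                 pheno_sd = sqrt(diag(G0) + diag(R0)),
                 season_effect = season_effect,
                 period_trend = period_trend, afc_slope = afc_slope,
                 birth_year_range = birth_year_range, seed = seed),
            class = "sim_params")
}

#' Simulate a pedigree
#'
#' Founder sires and dams, then `n_generations` rounds of random mating
#' (each dam of the current generation is mated to a random current sire;
#' each mating produces `progeny_per_mating` offspring). In intermediate
#' generations half the offspring are male and join the sire pool;
#' final-generation offspring are all female. Output is
#' parent-before-offspring and reproducible by seed.
#'
#' @param params A [sim_params()].
#' @return Data.frame with `animal`, `sire`, `dam` (character; `NA` =
#'   unknown) and `sex` ("M"/"F"), founders first.
#' @export
simulate_pedigree <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  sires <- paste0("S", seq_len(params$n_sires))
  dams <- paste0("D", seq_len(params$n_dams))
  ped <- data.frame(
    animal = c(sires, dams),
    sire = NA_character_, dam = NA_character_,
    sex = c(rep("M", params$n_sires), rep("F", params$n_dams)),
    generation = 0L, stringsAsFactors = FALSE
  )
  cur_sires <- sires
  cur_dams <- dams
  counter <- 0L
  for (g in seq_len(params$n_generations)) {
    mate_sire <- sample(cur_sires, length(cur_dams), replace = TRUE)
    npm <- params$progeny_per_mating
    off <- data.frame(
      animal = paste0("A", counter + seq_len(length(cur_dams) * npm)),
      sire = rep(mate_sire, each = npm),
      dam = rep(cur_dams, each = npm),
      stringsAsFactors = FALSE)
    counter <- counter + nrow(off)
    last <- g == params$n_generations
    n_off <- nrow(off)
    sex <- if (last) rep("F", n_off)
           else sample(rep(c("M", "F"), length.out = n_off))
    off$sex <- sex
    off$generation <- g
    ped <- rbind(ped, off)
    cur_sires <- off$animal[off$sex == "M"]
    cur_dams <- off$animal[off$sex == "F"]
    if (!last && (!length(cur_sires) || !length(cur_dams)))
      stop("intermediate generation produced no animals of one sex")
  }
  ped
}

#' Simulate multi-trait phenotypes on a pedigree
#'
#' Generative version of the animal model `y = Xb + Zu + e`: founders draw
#' breeding values `u ~ N(0, G0)`; non-founders get `0.5 (u_s + u_d)` plus
#' Mendelian sampling noise `N(0, 0.5 G0)` (non-inbred approximation).
#' Birth dates are uniform over the configured cohort range, first calving
#' follows the animal's own simulated AFC, season and period classes come
#' from the herd calendar rules, and every trait except AFC receives the
#' centered AFC covariate term. Phenotypes are recorded for all females.
#'
#' @param ped Pedigree from [simulate_pedigree()].
#' @param params The same [sim_params()].
#' @return List of class `sim_herd`: `phenotypes` (coded records, one row
#'   per recorded cow, with `animal_code` and `sire_code`), `pedigree`
#'   (the `renum_ped`), `true_bv` (q x t matrix of true breeding values),
#'   `params`.
#' @export
simulate_phenotypes <- function(ped, params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 1L)
  traits <- params$traits
  t_n <- length(traits)
  rped <- renumber_pedigree(ped[c("animal", "sire", "dam")])
  q <- nrow(rped)
  Lg <- chol(params$G0)
  u <- matrix(0, q, t_n)
  for (i in seq_len(q)) {
    s <- rped$sire_code[i]; d <- rped$dam_code[i]
    if (s == 0 && d == 0) {
      u[i, ] <- drop(crossprod(Lg, stats::rnorm(t_n)))
    } else {
      pa <- (if (s > 0) u[s, ] else 0) + (if (d > 0) u[d, ] else 0)
      n_known <- (s > 0) + (d > 0)
      msv <- 1 - 0.25 * n_known # Mendelian sampling variance multiplier
      u[i, ] <- pa / 2 + sqrt(msv) * drop(crossprod(Lg, stats::rnorm(t_n)))
    }
  }
  rownames(u) <- rped$id
  colnames(u) <- traits

  sex <- ped$sex[match(rped$id, ped$animal)]
  rec <- which(sex == "F")
  n <- length(rec)
  birth_year <- sample(seq(params$birth_year_range[1],
                           params$birth_year_range[2]), n, replace = TRUE)
  birth_month <- sample(1:12, n, replace = TRUE)

  Lr <- chol(params$R0)
  e <- matrix(stats::rnorm(n * t_n), n, t_n) %*% Lr
  season_b <- assign_season(birth_month)
  # season effects: fixed per-level offsets scaled by phenotypic SD
  sea_lev <- c(0.5, -0.5, 1, -1) * params$season_effect
  per_b <- assign_period(birth_year, 1986, n_periods = 7)

  Y <- matrix(NA_real_, n, t_n, dimnames = list(NULL, traits))
  afc_idx <- match("afc", traits)
  u_rec <- u[rec, , drop = FALSE]
  # AFC first: its own model uses birth period/season and no covariate
  if (!is.na(afc_idx)) {
    k <- afc_idx
    sd_k <- params$pheno_sd[k]
    Y[, k] <- params$means[k] +
      params$period_trend * sd_k * (per_b - mean(per_b)) +
      sea_lev[as.integer(season_b)] * sd_k +
      u_rec[, k] + e[, k]
    afc <- Y[, k]
  } else {
    afc <- stats::rnorm(n, 1228, 179) # covariate still needed by templates
  }
  # calving date = birth date + AFC (days)
  doy <- (birth_year - 1900) * 365.25 + (birth_month - 0.5) * 30.44 + afc
  calving_year <- pmax(1990L, as.integer(1900 + doy %/% 365.25))
  calving_month <- pmin(12L, pmax(1L, as.integer(ceiling(
    (doy %% 365.25) / 30.44))))
  season_c <- assign_season(calving_month)
  per_c <- assign_period(calving_year, 1990, n_periods = 6)
  afc_dev <- (afc - mean(afc)) / stats::sd(afc)
  for (k in seq_len(t_n)) {
    if (!is.na(afc_idx) && k == afc_idx) next
    sd_k <- params$pheno_sd[k]
    Y[, k] <- params$means[k] +
      params$period_trend * sd_k * (per_c - mean(per_c)) +
      sea_lev[as.integer(season_c)] * sd_k +
      params$afc_slope * sd_k * afc_dev +
      u_rec[, k] + e[, k]
  }

  phen <- data.frame(
    animal = rped$id[rec],
    animal_code = rped$code[rec],
    sire_code = ifelse(rped$sire_code[rec] == 0L, NA_integer_,
                       rped$sire_code[rec]),
    birth_year = birth_year, birth_month = birth_month,
    calving_year = calving_year, calving_month = calving_month,
    stringsAsFactors = FALSE
  )
  phen$afc <- afc
  for (k in seq_len(t_n)) phen[[traits[k]]] <- Y[, k]
  phen <- code_fixed_effects(phen)
  structure(list(phenotypes = phen, pedigree = rped, true_bv = u,
                 params = params),
            class = "sim_herd")
}

#' @export
print.sim_herd <- function(x, ...) {
  cat(sprintf("Synthetic herd: %d recorded cows, %d pedigree animals, traits: %s\n",
              nrow(x$phenotypes), nrow(x$pedigree),
              paste(toupper(x$params$traits), collapse = ", ")))
  invisible(x)
}

#' Simulate a complete herd in one call
#'
#' @param params A [sim_params()].
#' @return A `sim_herd` (see [simulate_phenotypes()]).
#' @export
simulate_herd <- function(params = sim_params()) {
  ped <- simulate_pedigree(params)
  simulate_phenotypes(ped, params)
}

#' Descriptive statistics per trait
#'
#' @param records Phenotype data.frame.
#' @param traits Trait columns to summarise (default: all registry traits
#'   present).
#' @return Data.frame with `trait`, `n`, `mean`, `se`, `cv` (percent,
#'   `100 sd/mean`), `sd`, `min`, `max`; all-missing traits give NA rows.
#' @export
descriptive_statistics <- function(records,
                                   traits = intersect(trait_registry()$trait,
                                                      names(records))) {
  out <- lapply(traits, function(tr) {
    x <- records[[tr]]
    x <- x[!is.na(x)]
    if (length(x) < 2)
      return(data.frame(trait = tr, n = length(x), mean = NA, se = NA,
                        cv = NA, sd = NA, min = NA, max = NA))
    data.frame(trait = tr, n = length(x), mean = mean(x),
               se = stats::sd(x) / sqrt(length(x)),
               cv = 100 * stats::sd(x) / mean(x), sd = stats::sd(x),
               min = min(x), max = max(x))
  })
  do.call(rbind, out)
}
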