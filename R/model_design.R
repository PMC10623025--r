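#' Season classes
#'
#' The herd calendar partitions the year into four seasons: summer
#' (April-June), rainy (July-September), autumn (October-November) and
#' winter (December-March).
#'
#' @param month Integer month(s) in 1..12.
#' @return Factor with levels `summer`, `rainy`, `autumn`, `winter`.
#' @export
assign_season <- function(month) {
  month <- as.integer(month)
  if (any(is.na(month)) || any(month < 1L | month > 12L))
    stop("month must be in 1..12")
  lev <- c("summer", "rainy", "autumn", "winter")
  out <- character(length(month))
  out[month %in% 4:6]  <- "summer"
  out[month %in% 7:9]  <- "rainy"
  out[month %in% 10:11] <- "autumn"
  out[month %in% c(12L, 1L, 2L, 3L)] <- "winter"
  factor(out, levels = lev)
}

#' Period classes from calendar years
#'
#' Groups years into consecutive classes of `width` years starting at
#' `base_year`; the final class absorbs any overhang so that the mapping is
#' total on `[base_year, Inf)` (the last period may be short or long).
#'
#' @param year Integer year(s).
#' @param base_year First year of period 1.
#' @param n_periods Number of period classes.
#' @param width Years per period (default 5).
#' @return Integer period class in `1..n_periods`.
#' @export
assign_period <- function(year, base_year, n_periods, width = 5) {
  year <- as.integer(year)
  if (any(is.na(year))) stop("year must be numeric")
  if (any(year < base_year))
    stop("year ", min(year), " precedes base year ", base_year)
  pmin((year - base_year) %/% width + 1L, as.integer(n_periods))
}

#' Sturges class count
#'
#' Number of equal-width classes for binning a continuous covariate,
#' `k = round(1 + 3.322 log10(n))`.
#'
#' @param n Number of observations (>= 1).
#' @return Integer class count.
#' @export
sturges_class_count <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be >= 1")
  as.integer(round(1 + 3.322 * log10(n)))
}

#' Equal-width Sturges classes of a covariate
#'
#' @param x Numeric vector.
#' @param k Class count; default [sturges_class_count()] of `length(x)`.
#' @return Integer class labels in `1..k` (constant input collapses to 1).
#' @export
sturges_classes <- function(x, k = sturges_class_count(length(x))) {
  r <- range(x, na.rm = TRUE)
  if (diff(r) == 0) return(rep(1L, length(x)))
  br <- seq(r[1], r[2], length.out = k + 1)
  as.integer(cut(x, breaks = br, include.lowest = TRUE, labels = FALSE))
}

#' Standardising edit filters for lactation records
#'
#' Drops records failing any of the herd-book screening thresholds:
#' lactation length below 100 days, first-lactation milk yield below 500 kg,
#' fat percentage below 3.5. All comparisons are strict (`<`), so records at
#' a threshold are retained. A rule is only applied when its column is
#' present and non-missing.
#'
#' @param records Data.frame; columns `ll` (lactation length, d), `flmy`
#'   (milk yield, kg) and `fat_pct` (fat %) trigger the respective rules.
#' @param min_ll,min_my,min_fat Thresholds (defaults 100 d, 500 kg, 3.5%).
#' @return The surviving records, with an `"exclusions"` attribute counting
#'   drops per rule. Warns if no record survives.
#' @export
apply_edit_filters <- function(records, min_ll = 100, min_my = 500,
                               min_fat = 3.5) {
  n <- nrow(records)
  bad_ll <- if ("ll" %in% names(records))
    !is.na(records$ll) & records$ll < min_ll else rep(FALSE, n)
  bad_my <- if ("flmy" %in% names(records))
    !is.na(records$flmy) & records$flmy < min_my else rep(FALSE, n)
  bad_fat <- if ("fat_pct" %in% names(records))
    !is.na(records$fat_pct) & records$fat_pct < min_fat else rep(FALSE, n)
  keep <- !(bad_ll | bad_my | bad_fat)
  out <- records[keep, , drop = FALSE]
  if (!nrow(out)) warning("all records removed by edit filters")
  attr(out, "exclusions") <- c(
    lactation_length = sum(bad_ll),
    milk_yield = sum(bad_my),
    fat_percent = sum(bad_fat),
    retained = sum(keep)
  )
  out
}

#' Trait registry
#'
#' The eight analysed traits with units and the fixed-effect template each
#' trait uses. Age at first calving (AFC) is modelled on period and season
#' of birth and never carries itself as a covariate; all other traits use
#' period and season of calving with AFC as a linear covariate.
#'
#' @return Data.frame with columns `trait`, `unit`, `period_basis`,
#'   `n_periods`, `season_basis`, `afc_covariate`.
#' @export
trait_registry <- function() {
  traits <- c("afc", "fsp", "flmy", "flfy", "flsnfy", "ltmy", "pl", "hl")
  data.frame(
    trait = traits,
    unit = c("d", "d", "kg", "kg", "kg", "kg", "d", "d"),
    period_basis = ifelse(traits == "afc", "birth", "calving"),
    n_periods = ifelse(traits == "afc", 7L, 6L),
    season_basis = ifelse(traits == "afc", "birth", "calving"),
    afc_covariate = traits != "afc",
    stringsAsFactors = FALSE
  )
}

#' Model specification for one trait
#'
#' @param trait Trait name (see [trait_registry()]).
#' @param random `"animal"` (pedigree-structured) or `"sire"`.
#' @return List of class `model_spec` with the response, fixed terms and
#'   random term for the trait's model.
#' @export
model_spec <- function(trait, random = c("animal", "sire")) {
  random <- match.arg(random)
  reg <- trait_registry()
  row <- reg[reg$trait == trait, ]
  if (!nrow(row)) stop("unknown trait: ", trait)
  structure(list(
    trait = trait,
    period_basis = row$period_basis,
    n_periods = row$n_periods,
    season_basis = row$season_basis,
    afc_covariate = row$afc_covariate,
    random = random
  ), class = "model_spec")
}

#' Attach fixed-effect codings to phenotype records
#'
#' Computes season and period classes (both bases) and the centered AFC
#' covariate from the raw date columns, using the herd calendar rules.
#'
#' @param records Phenotype data.frame with columns `birth_year`,
#'   `birth_month`, `calving_year`, `calving_month`, `afc` and trait
#'   columns.
#' @param base_birth_year,base_calving_year First years of the birth and
#'   calving period scales.
#' @return `records` with added factor columns `season_birth`,
#'   `season_calving`, `period_birth`, `period_calving` and numeric
#'   `afc_class` (Sturges classes of AFC, for reporting).
#' @export
code_fixed_effects <- function(records, base_birth_year = 1986,
                               base_calving_year = 1990) {
  records$season_birth <- assign_season(records$birth_month)
  records$season_calving <- assign_season(records$calving_month)
  records$period_birth <- factor(
    assign_period(records$birth_year, base_birth_year, n_periods = 7),
    levels = 1:7)
  records$period_calving <- factor(
    assign_period(records$calving_year, base_calving_year, n_periods = 6),
    levels = 1:6)
  if ("afc" %in% names(records) && any(!is.na(records$afc)))
    records$afc_class <- sturges_classes(
      records$afc, sturges_class_count(sum(!is.na(records$afc))))
  records
}

drop_empty_levels <- function(f) factor(f)

#' Build the design for a trait's mixed model
#'
#' Assembles `y`, the fixed-effect matrix `X` (set-to-zero constraint on the
#' last observed level of each factor, covariate centered) and the random
#' mapping `z` (pedigree animal codes or sire codes per record). Records
#' missing the response or any model term are dropped; for multi-trait sets
#' use the intersection of complete cases first.
#'
#' @param spec A [model_spec()].
#' @param records Coded phenotype records (see [code_fixed_effects()]) with
#'   `animal_code` and `sire_code` columns.
#' @return List with `y`, `X`, `z` (integer codes, one per row), `rows`
#'   (row indices of `records` used) and `levels` bookkeeping.
#' @export
build_design <- function(spec, records) {
  stopifnot(inherits(spec, "model_spec"))
  y <- records[[spec$trait]]
  per <- records[[paste0("period_", spec$period_basis)]]
  sea <- records[[paste0("season_", spec$season_basis)]]
  cov <- if (spec$afc_covariate) records$afc else NULL
  ok <- !is.na(y) & !is.na(per) & !is.na(sea)
  if (spec$afc_covariate) ok <- ok & !is.na(cov)
  rows <- which(ok)
  if (!length(rows)) stop("no usable records for trait ", spec$trait)
  per <- drop_empty_levels(per[rows])
  sea <- drop_empty_levels(sea[rows])
  X <- cbind(intercept = rep(1, length(rows)))
  lev <- list()
  for (nm in c("period", "season")) {
    f <- if (nm == "period") per else sea
    lev[[nm]] <- levels(f)
    if (nlevels(f) > 1) {
      # set-to-zero on the last level: dummies for levels 1..k-1
      M <- stats::model.matrix(
        ~ f, contrasts.arg = list(f = stats::contr.treatment(
          nlevels(f), base = nlevels(f))))[, -1, drop = FALSE]
      colnames(M) <- paste0(nm, levels(f)[-nlevels(f)])
      X <- cbind(X, M)
    }
  }
  if (spec$afc_covariate) {
    cv <- cov[rows]
    X <- cbind(X, afc_cov = cv - mean(cv))
    lev$afc_mean <- mean(cv)
  }
  if (qr(X)$rank < ncol(X))
    stop("design matrix rank deficient after constraint (confounded terms)")
  z <- if (spec$random == "animal") records$animal_code[rows]
       else records$sire_code[rows]
  list(y = y[rows], X = X, z = as.integer(z), rows = rows, levels = lev)
}
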