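#' Write / read phenotype records
#'
#' Plain CSV, one row per cow, with the declared header. Round-trips the
#' output of [simulate_phenotypes()] losslessly up to numeric printing.
#'
#' @param records Phenotype data.frame.
#' @param path Output path.
#' @export
write_phenotypes <- function(records, path) {
  drop <- intersect(c("season_birth", "season_calving", "period_birth",
                      "period_calving", "afc_class"), names(records))
  utils::write.csv(records[setdiff(names(records), drop)], path,
                   row.names = FALSE, quote = FALSE)
}

#' @rdname write_phenotypes
#' @return `read_phenotypes` returns the records with fixed-effect codings
#'   re-attached via [code_fixed_effects()].
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  code_fixed_effects(df)
}

#' Write a pedigree CSV
#'
#' @param ped Data.frame with `animal`, `sire`, `dam`.
#' @param path Output path.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped[c("animal", "sire", "dam")]
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write / read stored Gibbs samples
#'
#' Plain-text table, one row per stored draw, one column per (co)variance
#' element in row-major lower-triangle order for G0 then R0, with a
#' `#`-prefixed header naming the columns.
#'
#' @param result A `gibbs_result`.
#' @param path Output path.
#' @export
write_chain_samples <- function(result, path) {
  M <- cbind(iteration = result$iteration, result$G, result$R)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(colnames(M), collapse = " ")), con)
  utils::write.table(M, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

#' @rdname write_chain_samples
#' @return `read_chain_samples` returns a data.frame with the named
#'   columns.
#' @export
read_chain_samples <- function(path) {
  header <- sub("^#\\s*", "", readLines(path, n = 1))
  cols <- strsplit(header, "\\s+")[[1]]
  df <- utils::read.table(path, comment.char = "#")
  names(df) <- cols
  df
}

#' Write a posterior summary table
#'
#' CSV with columns exactly
#' `parameter,mean,mode,median,sd,hpd_lower,hpd_upper,ess,mce,geweke_z`.
#'
#' @param summary Data.frame as produced by [posterior_summary_table()] or
#'   `derive_parameters()$summary`.
#' @param path Output path.
#' @export
write_summary_table <- function(summary, path) {
  cols <- c("parameter", "mean", "mode", "median", "sd", "hpd_lower",
            "hpd_upper", "ess", "mce", "geweke_z")
  utils::write.csv(summary[cols], path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_summary_table
#' @export
read_summary_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a minimal TOML run configuration
#'
#' Supports the flat dialect used by the pipeline: `[section]` headers,
#' `key = value` pairs with quoted strings, numbers, booleans and
#' single-line arrays, `#` comments. Section keys are flattened to
#' `section.key`.
#'
#' @param path Path to the TOML file.
#' @return Named list of values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- ""
  parse_val <- function(v) {
    v <- trimws(v)
    if (grepl("^\\[.*\\]$", v)) {
      items <- strsplit(gsub("^\\[|\\]$", "", v), ",")[[1]]
      return(unlist(lapply(items, parse_val)))
    }
    if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
    if (v %in% c("true", "false")) return(v == "true")
    num <- suppressWarnings(as.numeric(gsub("_", "", v)))
    if (!is.na(num)) return(num)
    v
  }
  for (ln in lines) {
    if (grepl("^\\[[^]]+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      if (nzchar(section)) key <- paste(section, key, sep = ".")
      out[[key]] <- parse_val(paste(kv[-1], collapse = "="))
    } else {
      stop("cannot parse config line: ", ln)
    }
  }
  out
}
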