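#' Read a pedigree file
#'
#' Reads a pedigree CSV with columns `animal,sire,dam`. An empty field, `0`
#' or `NA` marks an unknown parent. The header is required.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with character columns `animal`, `sire`, `dam`
#'   (`NA` = unknown parent).
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        strip.white = TRUE, na.strings = c("", "0", "NA"))
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree file must have columns 'animal,sire,dam'")
  df[need]
}

#' Renumber a pedigree with parents before offspring
#'
#' Assigns consecutive integer codes 1..q to every animal appearing in the
#' pedigree (including animals referenced only as parents, which are added
#' with unknown parents) such that every parent's code is strictly smaller
#' than its offspring's code. Ties in the topological order are broken by
#' first appearance in the input, so the output is deterministic for a fixed
#' record ordering.
#'
#' @param records Data.frame with columns `animal`, `sire`, `dam`
#'   (character; `NA` or `"0"` = unknown).
#' @return An object of class `renum_ped`: a data.frame with columns
#'   `code`, `sire_code`, `dam_code` (0 = unknown) and `id` (original
#'   identifier), rows ordered by `code`.
#' @export
renumber_pedigree <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("animal", "sire", "dam")) {
    v <- as.character(records[[col]])
    v[!is.na(v) & (v == "" | v == "0")] <- NA_character_
    records[[col]] <- v
  }
  if (anyNA(records$animal) || any(records$animal == ""))
    stop("animal identifiers must be non-empty")
  if (anyDuplicated(records$animal)) {
    dup <- records$animal[duplicated(records$animal)][1]
    stop("duplicate animal record: ", dup)
  }
  self <- records$animal == records$sire | records$animal == records$dam
  if (any(self, na.rm = TRUE))
    stop("animal listed as its own parent: ",
         records$animal[which(self)[1]])
  sires <- unique(stats::na.omit(records$sire))
  dams  <- unique(stats::na.omit(records$dam))
  both <- intersect(sires, dams)
  if (length(both))
    stop("identifier used as both sire and dam: ", both[1])

  ids <- unique(c(records$animal,
                  stats::na.omit(c(rbind(records$sire, records$dam)))))
  # first-appearance order over the full id universe
  ids <- ids[order(match(ids, c(records$animal, records$sire, records$dam)))]
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  sire_of <- dam_of <- rep(NA_integer_, n)
  ri <- idx[records$animal]
  sire_of[ri] <- ifelse(is.na(records$sire), NA, idx[records$sire])
  dam_of[ri]  <- ifelse(is.na(records$dam),  NA, idx[records$dam])

  # Kahn topological sort, ties broken by first-appearance index
  indeg <- (!is.na(sire_of)) + (!is.na(dam_of))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire_of[i], dam_of[i]))
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  avail <- which(indeg == 0L)
  order_out <- integer(0)
  while (length(avail)) {
    i <- avail[which.min(avail)]
    avail <- setdiff(avail, i)
    order_out <- c(order_out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) avail <- c(avail, ch)
    }
  }
  if (length(order_out) < n) {
    on_cycle <- setdiff(seq_len(n), order_out)
    stop("pedigree cycle detected involving animal: ", ids[on_cycle[1]])
  }
  code <- integer(n)
  code[order_out] <- seq_len(n)
  out <- data.frame(
    code = seq_len(n),
    sire_code = 0L, dam_code = 0L,
    id = ids[order(code)],
    stringsAsFactors = FALSE
  )
  sc <- sire_of[order(code)]
  dc <- dam_of[order(code)]
  out$sire_code <- ifelse(is.na(sc), 0L, code[sc])
  out$dam_code  <- ifelse(is.na(dc), 0L, code[dc])
  class(out) <- c("renum_ped", "data.frame")
  out
}

#' @export
print.renum_ped <- function(x, ...) {
  cat("Renumbered pedigree:", nrow(x), "animals,",
      sum(x$sire_code == 0 & x$dam_code == 0), "founders\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Map original identifiers to pedigree codes
#'
#' @param ped A `renum_ped` object.
#' @param ids Character vector of original identifiers.
#' @return Integer codes; error if any identifier is absent.
#' @export
pedigree_codes <- function(ped, ids) {
  m <- match(as.character(ids), ped$id)
  if (anyNA(m)) stop("identifier(s) not in pedigree: ",
                     paste(utils::head(ids[is.na(m)], 3), collapse = ", "))
  ped$code[m]
}

#' Numerator relationship matrix by the tabular method
#'
#' Builds the additive (numerator) relationship matrix A for a renumbered
#' pedigree: `a(i,i) = 1 + 0.5 a(s_i, d_i)` and
#' `a(i,j) = 0.5 (a(j, s_i) + a(j, d_i))` for `j < i`, with unknown parents
#' contributing zero. The diagonal is `1 + F_i` with `F_i` the inbreeding
#' coefficient of animal i.
#'
#' @param ped A `renum_ped` object.
#' @return Dense symmetric q x q matrix with the original identifiers as
#'   dimnames.
#' @export
build_relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "renum_ped"))
  q <- nrow(ped)
  A <- matrix(0, q, q)
  s <- ped$sire_code
  d <- ped$dam_code
  for (i in seq_len(q)) {
    si <- s[i]; di <- d[i]
    A[i, i] <- 1 + if (si > 0 && di > 0) 0.5 * A[si, di] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (si > 0) A[j, si] else 0) +
                    (if (di > 0) A[j, di] else 0))
      A[j, i] <- A[i, j] <- aij
    }
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Inbreeding coefficients from the pedigree
#'
#' @param ped A `renum_ped` object.
#' @return Numeric vector F (diagonal of A minus one), named by identifier.
#' @export
inbreeding_coefficients <- function(ped) {
  diag(build_relationship_matrix(ped)) - 1
}

#' Inverse of the numerator relationship matrix by Henderson's rules
#'
#' Builds A-inverse directly, without inverting A. For animal i with parents
#' s and d, add `delta_i` to (i,i), `-delta_i/2` to (i,s) and (i,d), and
#' `delta_i/4` to (s,s), (d,d) and (s,d)+(d,s). With inbreeding accounted,
#' `delta_i = 1 / (0.5 - 0.25 (F_s + F_d))` (a missing parent contributes
#' F = -1, reproducing the 4/3 and 1 rules); without, `delta_i` is 2, 4/3 or
#' 1 by the number of known parents.
#'
#' @param ped A `renum_ped` object.
#' @param account_inbreeding Use pedigree inbreeding when forming the
#'   Mendelian sampling variances (default `TRUE`).
#' @return Sparse symmetric matrix (`Matrix::dsCMatrix`) with attribute
#'   `"account_inbreeding"` recording the flag.
#' @export
build_A_inverse <- function(ped, account_inbreeding = TRUE) {
  stopifnot(inherits(ped, "renum_ped"))
  q <- nrow(ped)
  s <- ped$sire_code
  d <- ped$dam_code
  Fc <- if (account_inbreeding) inbreeding_coefficients(ped) else rep(0, q)
  ii <- jj <- integer(0)
  xx <- numeric(0)
  push <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(q)) {
    si <- s[i]; di <- d[i]
    Fs <- if (si > 0) Fc[si] else -1
    Fd <- if (di > 0) Fc[di] else -1
    delta <- 1 / (0.5 - 0.25 * (Fs + Fd))
    push(i, i, delta)
    for (p in c(si, di)) {
      if (p > 0) {
        push(i, p, -delta / 2); push(p, i, -delta / 2)
        push(p, p, delta / 4)
      }
    }
    if (si > 0 && di > 0) {
      push(si, di, delta / 4); push(di, si, delta / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(q, q),
                               dimnames = list(ped$id, ped$id))
  Ainv <- Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2)
  attr(Ainv, "account_inbreeding") <- account_inbreeding
  Ainv
}
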