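#' Effective number of records
#'
#' For an animal with `n` repeated records and a permanent-environment
#' correlation between them, the information content of the `n` records is
#' `n (1 + lambda) / (n + lambda)` with `lambda = sigma_e2 / sigma_pe2`.
#' It equals 1 for a single record and approaches `1 + lambda` as `n` grows:
#' repeated records never count as fully independent observations because
#' they share the animal's permanent environment.
#'
#' @param n integer number of records, >= 1 (vectorised).
#' @param lam lambda = residual variance / permanent-environment variance,
#'   >= 0. `lam = 0` means records are perfectly repeatable beyond the
#'   residual, so extra parities add no information (n_eff = 1).
#' @return n_eff, same length as `n`.
#' @export
effective_records <- function(n, lam) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(n != floor(n))) stop("n must be a whole number of records")
  if (length(lam) != 1 || is.na(lam) || lam < 0) stop("lam must be a single value >= 0")
  if (is.infinite(lam)) return(as.numeric(n))  # no permanent environment: records independent
  n * (1 + lam) / (n + lam)
}

#' Collapse per-parity yield deviations into one weighted record per animal
#'
#' Repeated-record samplers here take a single phenotype per animal: the
#' arithmetic mean of that animal's parity yield deviations, weighted in the
#' residual by the effective number of records. The residual variance of
#' animal i is `sigma_e2 / n_eff_i`, i.e. the diagonal of the D matrix is
#' `1 / n_eff`.
#'
#' @param records data.frame with columns `animal_id`, `parity`, `value`
#'   (one row per parity yield deviation).
#' @param lam lambda = sigma_e2 / sigma_pe2 for the trait (a configuration
#'   input, typically taken from the routine evaluation that produced the
#'   yield deviations).
#' @return data.frame with one row per animal, ordered by `animal_id`:
#'   columns `animal_id`, `y` (mean yield deviation), `n_records`, `n_eff`,
#'   `weight` (= 1/n_eff, the D diagonal entry).
#' @export
collapse_parities <- function(records, lam) {
  req <- c("animal_id", "parity", "value")
  if (!all(req %in% names(records)))
    stop("records must have columns animal_id, parity, value")
  if (nrow(records) == 0) stop("no records")
  if (any(records$parity < 1 | records$parity != floor(records$parity)))
    stop("parity must be a positive integer")
  key <- paste(records$animal_id, records$parity, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate (animal, parity) pair: (", d$animal_id, ", ", d$parity, ")")
  }
  ids <- as.character(records$animal_id)
  y <- tapply(records$value, ids, mean)
  n <- tapply(records$value, ids, length)
  out <- data.frame(animal_id = sort(unique(ids)), stringsAsFactors = FALSE)
  out$y <- as.numeric(y[out$animal_id])
  out$n_records <- as.integer(n[out$animal_id])
  out$n_eff <- effective_records(out$n_records, lam)
  out$weight <- 1 / out$n_eff
  rownames(out) <- NULL
  out
}

#' Residual weight matrix diagonal
#'
#' Returns the diagonal of D, the residual weight matrix: entry i is
#' `1 / n_eff_i`, so the residual variance of animal i is
#' `d_ii * sigma_e2`. Order follows the input rows (the phenotyped-animal
#' order the fitters use).
#'
#' @param phenos data.frame from [collapse_parities()] (needs column
#'   `n_eff`), or a numeric vector of n_eff values.
#' @return Named numeric vector of D diagonal entries.
#' @export
build_residual_weights <- function(phenos) {
  n_eff <- if (is.data.frame(phenos)) phenos$n_eff else phenos
  if (any(n_eff <= 0)) stop("n_eff must be positive")
  d <- 1 / n_eff
  if (is.data.frame(phenos)) names(d) <- phenos$animal_id
  d
}

#' Read a per-parity phenotype table
#'
#' TSV with columns `animal_id`, `parity`, `value`; one file per trait.
#' @param path input path.
#' @return data.frame of parity records.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  req <- c("animal_id", "parity", "value")
  if (!all(req %in% names(df)))
    stop("phenotype file must have columns animal_id, parity, value")
  df$animal_id <- as.character(df$animal_id)
  df
}

#' Write collapsed phenotypes as TSV
#' @param phenos data.frame from [collapse_parities()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenos, path) {
  data.table::fwrite(phenos, path, sep = "\t")
  invisible(path)
}
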