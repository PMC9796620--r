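#' Split animals into reference and validation sets by age
#'
#' Mimics a breeding-program forward validation: the youngest animals'
#' phenotypes are masked for fitting and kept for scoring. The
#' `n_validation` animals with the largest birth keys form the validation
#' set; ties at the cut are broken by animal id (lexicographically last ids
#' go to validation), which makes the split deterministic.
#'
#' @param phenos data.frame with an `animal_id` column (typically from
#'   [collapse_parities()]).
#' @param birth_order named numeric vector: ordering key per animal (larger
#'   = younger, e.g. birth date as a number). Names must cover all
#'   phenotyped animals.
#' @param n_validation number of validation animals, < total.
#' @return list with character vectors `reference` and `validation`.
#' @export
split_reference_validation <- function(phenos, birth_order, n_validation) {
  ids <- as.character(phenos$animal_id)
  if (n_validation >= length(ids)) stop("n_validation must be < total animals")
  if (n_validation < 1) stop("n_validation must be >= 1")
  if (length(setdiff(ids, names(birth_order))))
    stop("birth_order missing for some animals")
  key <- birth_order[ids]
  ord <- order(key, ids)  # ties broken by id
  validation <- ids[ord][(length(ids) - n_validation + 1):length(ids)]
  list(reference = sort(setdiff(ids, validation)),
       validation = sort(validation))
}

#' Prediction accuracy on the validation set
#'
#' `r_pred = cor(GEBV, YD) / sqrt(h2)`: the correlation with the (noisy)
#' yield deviation understates the correlation with the true breeding
#' value by a factor sqrt(h2), so dividing by sqrt(h2) rescales it to the
#' accuracy of predicting genetic merit. Small-sample estimates can exceed
#' 1 and are not clipped.
#'
#' @param gebv,yd paired per-animal vectors (length >= 3).
#' @param h2 heritability of the trait, in (0, 1\].
#' @return Scalar accuracy.
#' @export
prediction_accuracy <- function(gebv, yd, h2) {
  if (length(gebv) != length(yd)) stop("gebv and yd must be paired")
  if (length(gebv) < 3) stop("need >= 3 validation animals")
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  if (stats::sd(gebv) == 0 || stats::sd(yd) == 0)
    stop("zero variance in gebv or yd")
  stats::cor(gebv, yd) / sqrt(h2)
}

#' Dispersion bias: regression of phenotype on GEBV
#'
#' Ordinary least squares of `yd = a + b * gebv`. A slope b = 1 means the
#' GEBVs are correctly dispersed; b < 1 means their variance is inflated
#' (over-dispersed predictions), b > 1 deflated.
#'
#' @param gebv,yd paired per-animal vectors (length >= 3).
#' @return Named vector `c(intercept_a, slope_b)`.
#' @export
regression_bias <- function(gebv, yd) {
  if (length(gebv) != length(yd)) stop("gebv and yd must be paired")
  if (length(gebv) < 3) stop("need >= 3 animals")
  if (stats::sd(gebv) == 0) stop("zero variance in gebv")
  fit <- stats::lm(yd ~ gebv)
  c(intercept_a = unname(stats::coef(fit)[1]),
    slope_b = unname(stats::coef(fit)[2]))
}

#' Bootstrap standard error of the prediction accuracy
#'
#' Nonparametric bootstrap over validation animals: resample animals with
#' replacement, recompute [prediction_accuracy()], report the standard
#' deviation over resamples. Degenerate resamples (zero variance in either
#' vector) are redrawn and counted.
#'
#' @inheritParams prediction_accuracy
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed random seed for the resampling.
#' @return Scalar SE, with attribute `n_redrawn` (degenerate resamples).
#' @export
accuracy_se <- function(gebv, yd, h2, n_boot = 1000, seed = 1) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (length(gebv) != length(yd)) stop("gebv and yd must be paired")
  n <- length(gebv)
  set.seed(seed)
  acc <- numeric(n_boot)
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(gebv[idx]) > 0 && stats::sd(yd[idx]) > 0) break
      redrawn <- redrawn + 1L
      if (redrawn > 100L * n_boot) stop("data too degenerate to bootstrap")
    }
    acc[b] <- stats::cor(gebv[idx], yd[idx]) / sqrt(h2)
  }
  structure(stats::sd(acc), n_redrawn = redrawn)
}

#' Validation report for one fitted method
#'
#' Scores a fit on the validation animals: accuracy, its bootstrap SE, and
#' the dispersion-bias regression. Scoring uses the collapsed weighted-mean
#' yield deviations (the same `y` the fit would have used had the animals
#' not been masked).
#'
#' @param result a `fit_result`.
#' @param phenos collapsed phenotypes (must include the validation animals).
#' @param validation_ids animals to score on.
#' @param h2 trait heritability.
#' @param trait trait label for the report row.
#' @param spec the `prior_spec` used for the fit (for the Fr and q columns).
#' @param n_boot,seed bootstrap settings for the SE.
#' @return One-row data.frame: trait, method, Fr, q, accuracy, se,
#'   intercept_a, slope_b, n_validation.
#' @export
validation_report <- function(result, phenos, validation_ids, h2,
                              trait = "trait", spec = NULL,
                              n_boot = 1000, seed = 1) {
  idx <- match(validation_ids, phenos$animal_id)
  if (anyNA(idx)) stop("validation animals missing from phenotypes")
  yd <- phenos$y[idx]
  gebv <- result$gebv[validation_ids]
  if (anyNA(gebv)) stop("validation animals missing from fit")
  ab <- regression_bias(gebv, yd)
  data.frame(trait = trait, method = result$method,
             Fr = if (is.null(spec)) NA_real_ else spec$Fr,
             q = if (is.null(spec)) NA_real_ else spec$q,
             accuracy = prediction_accuracy(gebv, yd, h2),
             se = as.numeric(accuracy_se(gebv, yd, h2, n_boot, seed)),
             intercept_a = ab[["intercept_a"]],
             slope_b = ab[["slope_b"]],
             n_validation = length(validation_ids),
             stringsAsFactors = FALSE)
}
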