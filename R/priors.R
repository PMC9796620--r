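#' Prior inclusion probability for BayesC
#'
#' Under the assumption that a single fitted SNP explains a fraction `Fr` of
#' the total genetic variance, the expected number of SNPs in the model is
#' `1/Fr` and the per-SNP prior inclusion probability is
#' `pi_c = (1/Fr) / n_loci`.
#'
#' @param Fr fraction of total genetic variance per fitted SNP, in (0, 1\].
#' @param n_loci number of SNPs in the panel.
#' @return pi_c in (0, 1\].
#' @export
pi_bayesc <- function(Fr, n_loci) {
  if (Fr <= 0 || Fr > 1) stop("Fr must lie in (0, 1]")
  if (n_loci < 1) stop("n_loci must be >= 1")
  pi <- (1 / Fr) / n_loci
  if (pi > 1 + 1e-12)
    stop("pi = ", signif(pi, 4), " > 1: 1/Fr exceeds the number of loci; ",
         "the (Fr, n_loci) configuration is inconsistent")
  min(pi, 1)
}

#' Prior inclusion probability for BayesGC
#'
#' BayesGC assigns only a fraction `q` of the genetic variance to the
#' variable-selection (marker) term, so the expected number of fitted SNPs
#' shrinks proportionally: `pi_gc = q * pi_c`.
#'
#' @param q fraction of total genetic variance given to the marker term,
#'   in (0, 1\].
#' @inheritParams pi_bayesc
#' @return pi_gc in (0, 1\].
#' @export
pi_bayesgc <- function(q, Fr, n_loci) {
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
  q * pi_bayesc(Fr, n_loci)
}

#' Per-SNP effect variance
#'
#' A fitted SNP is assumed to explain `Fr * sigma_u2` of genetic variance.
#' An average SNP carries `HETbar = 2 sum(p(1-p))/Nloci` of genotypic
#' variance per unit effect variance, so the prior effect variance is
#' `sigma_m2 = Fr * sigma_u2 / HETbar`. The same value is used by BayesC
#' and BayesGC at a given `Fr`.
#'
#' @param Fr fraction of total genetic variance per fitted SNP.
#' @param sigma_u2 total genetic variance of the trait.
#' @param het_bar average expected heterozygosity of the panel
#'   (see [average_heterozygosity()]).
#' @return sigma_m2 in trait-variance units.
#' @export
sigma_m2 <- function(Fr, sigma_u2, het_bar) {
  if (het_bar <= 0) stop("het_bar must be positive")
  if (Fr <= 0) stop("Fr must be positive")
  if (sigma_u2 < 0) stop("sigma_u2 must be >= 0")
  Fr * sigma_u2 / het_bar
}

#' Polygenic variance under the q-partition
#'
#' The genetic variance not assigned to the marker term is carried by the
#' polygenic effect: `sigma_pol2 = (1 - q) * sigma_u2`.
#'
#' @param q fraction of total genetic variance given to the marker term,
#'   in \[0, 1\].
#' @param sigma_u2 total genetic variance.
#' @return sigma_pol2.
#' @export
sigma_pol2 <- function(q, sigma_u2) {
  if (q < 0 || q > 1) stop("q must lie in [0, 1]")
  if (sigma_u2 < 0) stop("sigma_u2 must be >= 0")
  (1 - q) * sigma_u2
}

#' Narrow-sense heritability from variance components
#'
#' `h2 = sigma_u2 / (sigma_u2 + sigma_e2)` on the collapsed-record scale.
#'
#' @param sigma_u2 total genetic variance.
#' @param sigma_e2 residual variance.
#' @return h2 in \[0, 1\].
#' @export
heritability <- function(sigma_u2, sigma_e2) {
  if (sigma_u2 < 0 || sigma_e2 < 0) stop("variances must be >= 0")
  tot <- sigma_u2 + sigma_e2
  if (tot <= 0) stop("total variance is zero")
  sigma_u2 / tot
}

#' Assemble the full prior specification for a fitting method
#'
#' Combines the partitioning formulas into the prior set a sampler needs.
#' For `gblup`, `q = 0` (all variance polygenic, no marker term). For
#' `bayesc`, `q = 1` (all variance on markers). For `bayesgc` both terms are
#' active. The resulting spec satisfies the variance-accounting identity
#' `sigma_pol2 + pi * n_loci * het_bar * sigma_m2 = sigma_u2`.
#'
#' @param method one of `"gblup"`, `"bayesc"`, `"bayesgc"`.
#' @param sigma_u2,sigma_e2 variance components for the trait (configuration
#'   inputs, typically from a pedigree-based REML analysis).
#' @param Fr fraction of genetic variance per fitted SNP (marker methods).
#' @param q marker-term fraction of genetic variance (bayesgc; forced to 1
#'   for bayesc and 0 for gblup).
#' @param het_bar average heterozygosity of the fitted panel.
#' @param n_loci number of SNPs in the fitted panel.
#' @return An object of class `prior_spec`: list with `method`, `Fr`, `q`,
#'   `pi`, `sigma_m2`, `sigma_pol2`, `sigma_u2`, `sigma_e2`, `het_bar`,
#'   `n_loci`.
#' @export
make_prior_spec <- function(method = c("gblup", "bayesc", "bayesgc"),
                            sigma_u2, sigma_e2, Fr = NULL, q = NULL,
                            het_bar = NULL, n_loci = NULL) {
  method <- match.arg(method)
  if (sigma_e2 <= 0) stop("sigma_e2 must be positive")
  if (method == "gblup") {
    spec <- list(method = method, Fr = NA_real_, q = 0, pi = 0,
                 sigma_m2 = 0, sigma_pol2 = sigma_u2,
                 sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                 het_bar = if (is.null(het_bar)) NA_real_ else het_bar,
                 n_loci = if (is.null(n_loci)) NA_integer_ else n_loci)
    return(structure(spec, class = "prior_spec"))
  }
  if (is.null(Fr) || is.null(het_bar) || is.null(n_loci))
    stop(method, " needs Fr, het_bar and n_loci")
  if (method == "bayesc") {
    if (!is.null(q) && q != 1) stop("bayesc fixes q = 1")
    q <- 1
  } else {
    if (is.null(q)) stop("bayesgc needs q")
    if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
  }
  pi <- if (method == "bayesc") pi_bayesc(Fr, n_loci) else pi_bayesgc(q, Fr, n_loci)
  spec <- list(method = method, Fr = Fr, q = q, pi = pi,
               sigma_m2 = sigma_m2(Fr, sigma_u2, het_bar),
               sigma_pol2 = sigma_pol2(q, sigma_u2),
               sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
               het_bar = het_bar, n_loci = as.integer(n_loci))
  structure(spec, class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("prior_spec [%s]", x$method))
  if (x$method != "gblup")
    cat(sprintf(" Fr=%s q=%.2f pi=%.3g sigma_m2=%.4g", format(x$Fr), x$q,
                x$pi, x$sigma_m2))
  cat(sprintf("\n  sigma_u2=%.4g sigma_e2=%.4g sigma_pol2=%.4g h2=%.3f\n",
              x$sigma_u2, x$sigma_e2, x$sigma_pol2,
              heritability(x$sigma_u2, x$sigma_e2)))
  invisible(x)
}

#' Grid of prior inclusion probabilities over Fr and method
#'
#' Convenience table of pi values for BayesC and BayesGC at a set of Fr
#' values and marker-variance fractions q, for a given panel size.
#'
#' @param n_loci panel SNP count.
#' @param Fr_values vector of Fr fractions.
#' @param q_values vector of q fractions for the BayesGC columns.
#' @return data.frame: one row per Fr, one column per BayesGC q plus a
#'   BayesC column.
#' @export
pi_grid <- function(n_loci,
                    Fr_values = c(1/100, 1/500, 1/1000, 1/5000, 1/10000),
                    q_values = c(0.1, 0.5, 0.9)) {
  out <- data.frame(Fr = Fr_values)
  for (q in q_values) {
    out[[sprintf("BayesGC_%d", round(100 * q))]] <-
      vapply(Fr_values, function(f) pi_bayesgc(q, f, n_loci), numeric(1))
  }
  out$BayesC <- vapply(Fr_values, function(f) pi_bayesc(f, n_loci), numeric(1))
  out
}
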