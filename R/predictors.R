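#' MCMC configuration
#'
#' @param n_cycles total Gibbs cycles per chain.
#' @param n_burnin burn-in cycles discarded before accumulating posterior
#'   summaries.
#' @param n_chains number of independent chains; chain c is seeded with
#'   `seed + c`.
#' @param seed base random seed.
#' @param recompute_every full residual recomputation interval (cycles), to
#'   bound incremental-update drift.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_cycles = 20000, n_burnin = 4000, n_chains = 2,
                        seed = 1, recompute_every = 1000) {
  if (n_burnin >= n_cycles) stop("n_burnin must be < n_cycles")
  if (n_chains < 1) stop("n_chains must be >= 1")
  structure(list(n_cycles = as.integer(n_cycles),
                 n_burnin = as.integer(n_burnin),
                 n_chains = as.integer(n_chains),
                 seed = as.integer(seed),
                 recompute_every = as.integer(recompute_every)),
            class = "mcmc_config")
}

# Align phenotypes to the animal order used by a fitter. Animals listed in
# predict_ids keep weight 0: they never enter the likelihood, but their
# GEBVs are still computed. Returns y (0 where unobserved) and the residual
# precision weights w = n_eff (0 = masked).
align_phenotypes <- function(phenos, animal_ids, predict_ids = NULL) {
  stopifnot(is.data.frame(phenos), all(c("animal_id", "y") %in% names(phenos)))
  if (!"n_eff" %in% names(phenos)) phenos$n_eff <- 1
  missing_ids <- setdiff(phenos$animal_id, animal_ids)
  if (length(missing_ids))
    stop("phenotyped animals absent from genotype data: ",
         paste(utils::head(missing_ids, 3), collapse = ", "))
  if (length(predict_ids) && length(setdiff(predict_ids, animal_ids)))
    stop("predict_ids contains animals absent from genotype data")
  y <- stats::setNames(numeric(length(animal_ids)), animal_ids)
  w <- stats::setNames(numeric(length(animal_ids)), animal_ids)
  y[phenos$animal_id] <- phenos$y
  w[phenos$animal_id] <- phenos$n_eff
  w[intersect(predict_ids, phenos$animal_id)] <- 0
  if (all(w == 0)) stop("no animals with non-zero likelihood weight")
  list(y = unname(y), w = unname(w))
}

new_fit_result <- function(method, animal_ids, per_chain_gebv, mu_mean,
                           polygenic_mean = NULL, snp_ids = NULL,
                           snp_effect_mean = NULL, snp_inclusion_prob = NULL,
                           max_residual_drift = NA_real_, mcmc = NULL) {
  gebv <- rowMeans(per_chain_gebv)
  names(gebv) <- animal_ids
  structure(list(method = method, animal_ids = animal_ids, gebv = gebv,
                 per_chain_gebv = per_chain_gebv, mu_mean = mu_mean,
                 polygenic_mean = polygenic_mean, snp_ids = snp_ids,
                 snp_effect_mean = snp_effect_mean,
                 snp_inclusion_prob = snp_inclusion_prob,
                 max_residual_drift = max_residual_drift, mcmc = mcmc),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result [%s]: %d animals, %d chain(s)\n", x$method,
              length(x$gebv), ncol(x$per_chain_gebv)))
  cat(sprintf("  mu = %.4g, sd(GEBV) = %.4g\n", x$mu_mean, stats::sd(x$gebv)))
  if (!is.null(x$snp_inclusion_prob))
    cat(sprintf("  mean SNPs in model: %.1f of %d\n",
                sum(x$snp_inclusion_prob), length(x$snp_inclusion_prob)))
  invisible(x)
}

#' GBLUP: mixed-model prediction with a genomic relationship matrix
#'
#' Solves the mixed-model equations for `y = 1 mu + u + e` with
#' `u ~ N(0, G sigma_u2)` and `e ~ N(0, D sigma_e2)`, where D is diagonal
#' with entries 1/n_eff (heterogeneous residual for collapsed repeated
#' records). All animals of the GRM enter the system; animals without
#' phenotypes (or listed in `predict_ids`) carry zero residual information,
#' so their solutions are the conditional means given the phenotyped
#' animals. GEBV = u-hat; the intercept is excluded.
#'
#' @param phenos data.frame with columns `animal_id`, `y`, and optionally
#'   `n_eff` (default 1), as produced by [collapse_parities()].
#' @param grm a `grm` from [build_grm()] covering all animals.
#' @param spec a `prior_spec` supplying `sigma_u2` and `sigma_e2`.
#' @param predict_ids animals whose phenotypes (if present) are masked;
#'   they are predicted from relationships only.
#' @param ridge diagonal ridge added to G before inversion (G built from
#'   fewer SNPs than animals is singular).
#' @return A `fit_result` with deterministic `gebv` (one "chain").
#' @export
fit_gblup <- function(phenos, grm, spec, predict_ids = NULL, ridge = 1e-6) {
  stopifnot(inherits(grm, "grm"))
  if (spec$sigma_u2 <= 0) stop("sigma_u2 must be positive for GBLUP")
  al <- align_phenotypes(phenos, grm$animal_ids, predict_ids)
  n <- length(grm$animal_ids)
  k <- spec$sigma_e2 / spec$sigma_u2
  Ginv <- tryCatch(chol2inv(chol(grm$matrix + diag(ridge, n))),
                   error = function(e)
                     stop("G + ridge is not positive definite: ",
                          conditionMessage(e)))
  W <- al$w
  C <- rbind(c(sum(W), W), cbind(W, diag(W, n) + k * Ginv))
  rhs <- c(sum(W * al$y), W * al$y)
  sol <- tryCatch(solve(C, rhs),
                  error = function(e) stop("singular mixed-model equations: ",
                                           conditionMessage(e)))
  u <- sol[-1]
  new_fit_result("gblup", grm$animal_ids,
                 per_chain_gebv = matrix(unname(u), ncol = 1),
                 mu_mean = unname(sol[1]), polygenic_mean = unname(u))
}

# shared driver for the two Gibbs samplers
run_gibbs <- function(method, phenos, panel, spec, mcmc, predict_ids,
                      grm = NULL, ridge = 1e-6) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(mcmc, "mcmc_config"))
  if (spec$sigma_m2 <= 0) stop("sigma_m2 must be positive")
  if (spec$sigma_e2 <= 0) stop("sigma_e2 must be positive")
  if (spec$pi <= 0 || spec$pi > 1) stop("pi must lie in (0, 1]")
  al <- align_phenotypes(phenos, panel$animal_ids, predict_ids)
  X <- sweep(panel$dosages, 2, 2 * panel$allele_freqs, "-")
  n <- nrow(X)

  L <- matrix(0, 0, 0)
  if (method == "bayesgc" && spec$sigma_pol2 > 0) {
    stopifnot(inherits(grm, "grm"))
    if (!setequal(grm$animal_ids, panel$animal_ids))
      stop("GRM and genotype panel cover different animal sets")
    idx <- match(panel$animal_ids, grm$animal_ids)
    G <- grm$matrix[idx, idx]
    Ginv <- chol2inv(chol(G + diag(ridge, n)))
    P <- Ginv / spec$sigma_pol2 + diag(al$w / spec$sigma_e2, n)
    L <- t(chol(P))
  }

  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + ch)
    chains[[ch]] <- gibbs_core(X, al$y, al$w, spec$sigma_e2, spec$sigma_m2,
                               spec$pi, L, mcmc$n_cycles, mcmc$n_burnin,
                               mcmc$recompute_every)
  }
  per_chain <- vapply(chains, `[[`, numeric(n), "gebv")
  avg <- function(f) Reduce(`+`, lapply(chains, `[[`, f)) / length(chains)
  new_fit_result(method, panel$animal_ids, per_chain_gebv = per_chain,
                 mu_mean = avg("mu_mean"),
                 polygenic_mean = stats::setNames(as.numeric(avg("polygenic_mean")),
                                                  panel$animal_ids),
                 snp_ids = panel$snp_ids,
                 snp_effect_mean = stats::setNames(as.numeric(avg("snp_effect_mean")),
                                                   panel$snp_ids),
                 snp_inclusion_prob = stats::setNames(as.numeric(avg("snp_inclusion_prob")),
                                                      panel$snp_ids),
                 max_residual_drift = max(vapply(chains, `[[`, numeric(1),
                                                 "max_residual_drift")),
                 mcmc = mcmc)
}

#' BayesC: Bayesian variable-selection regression on SNPs
#'
#' Single-site Gibbs sampler for `y = 1 mu + sum_i I_i x_i s_i + e` with
#' `I_i ~ Bern(pi)`, `s_i | I_i=1 ~ N(0, sigma_m2)`, `e ~ N(0, D sigma_e2)`.
#' Each cycle samples the intercept, then every SNP's indicator from its
#' Bernoulli full conditional with the effect integrated out, then the
#' effect given inclusion. All variance parameters are fixed constants from
#' the prior spec; they are not updated. GEBV is the posterior mean of the
#' summed marker effects (intercept excluded), averaged over chains.
#'
#' @inheritParams fit_gblup
#' @param panel [genotype_panel] over all animals (dosages are centred by
#'   `2p` internally).
#' @param spec `prior_spec` with `method = "bayesc"`.
#' @param mcmc an [mcmc_config()].
#' @return A `fit_result` with per-chain GEBVs, posterior SNP inclusion
#'   probabilities and effect means.
#' @export
gibbs_bayesc <- function(phenos, panel, spec, mcmc = mcmc_config(),
                         predict_ids = NULL) {
  if (spec$method != "bayesc") stop("spec$method must be 'bayesc'")
  run_gibbs("bayesc", phenos, panel, spec, mcmc, predict_ids)
}

#' BayesGC: joint polygenic and variable-selection prediction
#'
#' Fits GBLUP and BayesC simultaneously:
#' `y = 1 mu + u + sum_i I_i x_i s_i + e` with `u ~ N(0, G sigma_pol2)`.
#' The marker term is sampled as in [gibbs_bayesc()]; the polygenic vector
#' is drawn each cycle from its multivariate-normal full conditional using a
#' Cholesky factor of its (cycle-invariant) precision. GEBV is the
#' posterior mean of `u + sum_i I_i x_i s_i`.
#'
#' @inheritParams gibbs_bayesc
#' @param grm a `grm` over the same animals as `panel`.
#' @param spec `prior_spec` with `method = "bayesgc"`; `sigma_pol2 = 0`
#'   (q = 1) drops the polygenic term and the model reduces to BayesC.
#' @param ridge diagonal ridge added to G before inversion.
#' @return A `fit_result`.
#' @export
gibbs_bayesgc <- function(phenos, panel, grm, spec, mcmc = mcmc_config(),
                          predict_ids = NULL, ridge = 1e-6) {
  if (spec$method != "bayesgc") stop("spec$method must be 'bayesgc'")
  run_gibbs("bayesgc", phenos, panel, spec, mcmc, predict_ids, grm = grm,
            ridge = ridge)
}

#' Two-chain convergence diagnostic
#'
#' Pearson correlation between per-chain posterior-mean GEBVs. With more
#' than two chains the minimum pairwise correlation is reported. Chains
#' whose GEBVs correlate above the threshold are taken as converged.
#'
#' @param result a `fit_result` with at least two chains.
#' @param threshold convergence threshold on the correlation.
#' @return list with `ebv_chain_correlation` and logical `converged`.
#' @export
diagnose_chains <- function(result, threshold = 0.9999) {
  stopifnot(inherits(result, "fit_result"))
  C <- ncol(result$per_chain_gebv)
  if (C < 2) stop("chain diagnostics need >= 2 chains")
  cm <- stats::cor(result$per_chain_gebv)
  rho <- min(cm[upper.tri(cm)])
  list(ebv_chain_correlation = rho, converged = rho >= threshold)
}

#' Write per-animal GEBVs as TSV
#' @param result a `fit_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gebv <- function(result, path) {
  df <- data.frame(animal_id = result$animal_ids, gebv = unname(result$gebv))
  if (!is.null(result$polygenic_mean))
    df$polygenic_mean <- unname(result$polygenic_mean)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Write per-SNP posterior summaries as TSV
#' @param result a `fit_result` from a marker sampler.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_summary <- function(result, path) {
  if (is.null(result$snp_ids)) stop("no SNP summaries in this fit")
  data.table::fwrite(
    data.frame(snp_id = result$snp_ids,
               inclusion_prob = unname(result$snp_inclusion_prob),
               effect_mean = unname(result$snp_effect_mean)),
    path, sep = "\t")
  invisible(path)
}
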