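#' Simulation configuration
#'
#' Defines a synthetic population with the statistical structure the
#' analysis assumes: allele frequencies from a Beta distribution, genotypes
#' in Hardy-Weinberg proportions (optionally with first-order Markov LD
#' along the SNP order), an additive trait with a few discrete QTL plus a
#' polygenic tail, and 1-6 repeated parity records per animal sharing a
#' permanent-environment effect.
#'
#' @param n_animals number of animals.
#' @param n_snps number of SNPs.
#' @param maf_dist length-2 Beta shape parameters for allele frequencies.
#' @param n_qtl number of discrete large-effect QTL.
#' @param qtl_var_fraction fraction of the genetic variance carried by the
#'   discrete QTL; the remainder is spread over all other SNPs as a
#'   polygenic tail of tiny effects.
#' @param h2 target heritability sigma_u2 / (sigma_u2 + sigma_e2).
#' @param sigma_u2 total genetic variance (trait scale).
#' @param sigma_pe2_ratio sigma_pe2 / sigma_e2; lambda = 1 / ratio. 0 means
#'   no permanent environment (lambda infinite, n_eff = n).
#' @param parities_per_animal length-2 integer range; each animal's number
#'   of parity records is uniform on it (capped at 6).
#' @param n_validation number of youngest animals held out for validation
#'   (default: the youngest 10%).
#' @param qtl_effect_dist `"equal"` (default): every QTL carries the same
#'   variance share `qtl_var_fraction/n_qtl`, with random sign; `"normal"`:
#'   QTL effects are drawn normal and jointly rescaled, so individual shares
#'   vary.
#' @param ld_rho AR(1) correlation of the latent Gaussians used to generate
#'   haplotypes; 0 (default) gives linkage equilibrium, values near 1 give
#'   strong adjacent-marker LD. The realised adjacent-allele r is roughly
#'   (2/pi) asin(ld_rho) for intermediate frequencies.
#' @param seed base random seed; all generator randomness derives from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_animals = 2000, n_snps = 5000, maf_dist = c(2, 2),
                       n_qtl = 3, qtl_var_fraction = 0.3, h2 = 0.3,
                       sigma_u2 = 1, sigma_pe2_ratio = 0.2,
                       parities_per_animal = c(1, 6),
                       n_validation = round(0.1 * n_animals),
                       ld_rho = 0, qtl_effect_dist = c("equal", "normal"),
                       seed = 42) {
  qtl_effect_dist <- match.arg(qtl_effect_dist)
  stopifnot(n_animals >= 2, n_snps >= 1, length(maf_dist) == 2,
            all(maf_dist > 0), n_qtl >= 0, n_qtl <= n_snps,
            qtl_var_fraction >= 0, qtl_var_fraction <= 1,
            h2 > 0, h2 < 1, sigma_u2 > 0, sigma_pe2_ratio >= 0,
            length(parities_per_animal) == 2,
            parities_per_animal[1] >= 1, parities_per_animal[2] <= 6,
            parities_per_animal[1] <= parities_per_animal[2],
            n_validation >= 0, n_validation < n_animals,
            ld_rho >= 0, ld_rho < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a genotype panel
#'
#' Allele frequencies are drawn from `Beta(maf_dist)`; genotypes are
#' `Binomial(2, p)` per animal under Hardy-Weinberg equilibrium. With
#' `ld_rho > 0`, two haplotypes per animal are generated by thresholding
#' AR(1) latent Gaussians, which induces first-order LD along the SNP order
#' while preserving the marginal frequencies. Animal ids are in birth
#' order: larger index = younger animal.
#'
#' @param config a [sim_config()].
#' @return A [genotype_panel].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_animals
  m <- config$n_snps
  p <- stats::rbeta(m, config$maf_dist[1], config$maf_dist[2])
  if (config$ld_rho == 0) {
    M <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
  } else {
    rho <- config$ld_rho
    thr <- stats::qnorm(p)
    hap <- function() {
      Z <- matrix(stats::rnorm(n * m), n, m)
      for (j in 2:m) Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * Z[, j]
      sweep(Z, 2, thr, "<") + 0
    }
    M <- hap() + hap()
  }
  genotype_panel(M,
                 animal_ids = sprintf("A%05d", seq_len(n)),
                 snp_ids = sprintf("S%05d", seq_len(m)))
}

#' Simulate repeated-parity phenotypes for a panel
#'
#' True breeding values are `tbv = Xc beta` with centred genotypes: `n_qtl`
#' discrete QTL carry `qtl_var_fraction` of sigma_u2 (effects scaled so
#' `sum 2p(1-p) beta^2` hits the target exactly) and the remaining variance
#' is spread over all other SNPs as a polygenic tail. Each animal gets a
#' permanent-environment deviate shared by its records, and each parity
#' record is `tbv + pe + residual`. This emulates yield deviations already
#' adjusted for fixed effects, so no fixed-effect structure is simulated.
#'
#' @param panel a [genotype_panel] from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return list with `records` (data.frame animal_id, parity, value) and
#'   `truth` (class `sim_truth`: tbv, qtl_ids, qtl_effects, realized_h2 and
#'   the variance components incl. `lambda = sigma_e2 / sigma_pe2`).
#' @export
simulate_trait <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  if (config$qtl_var_fraction > 0 && config$n_qtl == 0)
    stop("qtl_var_fraction > 0 requires n_qtl > 0")
  set.seed(config$seed + 1L)
  n <- length(panel$animal_ids)
  m <- length(panel$snp_ids)
  p <- panel$allele_freqs
  sigma_u2 <- config$sigma_u2
  sigma_e2 <- sigma_u2 * (1 - config$h2) / config$h2
  sigma_pe2 <- config$sigma_pe2_ratio * sigma_e2
  lambda <- if (sigma_pe2 > 0) sigma_e2 / sigma_pe2 else Inf

  het <- 2 * p * (1 - p)
  beta <- numeric(m)
  qtl_idx <- integer(0)
  if (config$n_qtl > 0 && config$qtl_var_fraction > 0) {
    eligible <- which(pmin(p, 1 - p) > 0.05)
    if (length(eligible) < config$n_qtl) eligible <- which(het > 0)
    qtl_idx <- sort(sample(eligible, config$n_qtl))
    if (config$qtl_effect_dist == "equal") {
      # every QTL carries the same variance share, with random sign
      share <- config$qtl_var_fraction * sigma_u2 / config$n_qtl
      b <- sample(c(-1, 1), config$n_qtl, replace = TRUE) *
        sqrt(share / het[qtl_idx])
    } else {
      b <- stats::rnorm(config$n_qtl)
      b <- b * sqrt(config$qtl_var_fraction * sigma_u2 / sum(het[qtl_idx] * b^2))
    }
    beta[qtl_idx] <- b
  }
  tail_frac <- 1 - config$qtl_var_fraction
  if (tail_frac > 0) {
    tail_idx <- setdiff(which(het > 0), qtl_idx)
    if (length(tail_idx) == 0) stop("no polymorphic SNPs for the polygenic tail")
    bt <- stats::rnorm(length(tail_idx))
    bt <- bt * sqrt(tail_frac * sigma_u2 / sum(het[tail_idx] * bt^2))
    beta[tail_idx] <- bt
  }
  Xc <- sweep(panel$dosages, 2, 2 * p, "-")
  tbv <- as.numeric(Xc %*% beta)
  names(tbv) <- panel$animal_ids

  par_range <- seq(config$parities_per_animal[1], config$parities_per_animal[2])
  n_par <- if (length(par_range) == 1) rep(par_range, n) else
    sample(par_range, n, replace = TRUE)
  pe <- stats::rnorm(n, 0, sqrt(sigma_pe2))
  idx <- rep(seq_len(n), n_par)
  records <- data.frame(
    animal_id = panel$animal_ids[idx],
    parity = sequence(n_par),
    value = tbv[idx] + pe[idx] + stats::rnorm(length(idx), 0, sqrt(sigma_e2)),
    stringsAsFactors = FALSE)

  truth <- structure(list(
    tbv = tbv,
    qtl_ids = panel$snp_ids[qtl_idx],
    qtl_effects = beta[qtl_idx],
    realized_h2 = stats::var(tbv) / (stats::var(tbv) + sigma_e2),
    sigma_u2 = sigma_u2, sigma_e2 = sigma_e2, sigma_pe2 = sigma_pe2,
    lambda = lambda, h2_target = config$h2), class = "sim_truth")
  list(records = records, truth = truth)
}

#' Ready-made study fixtures
#'
#' Bundles a simulated panel, parity records, collapsed phenotypes, a
#' youngest-animals split and the generating truth at two scales:
#' `tiny` (50 animals x 20 SNPs) for fast unit tests and `desk`
#' (2000 x 5000) with litter-size-like variance components
#' (sigma_u2 = 1.049, sigma_e2 ~ 4.49, h2 ~ 0.19) and a youngest-10%
#' validation split. With `dir` set, the bundle is also written in the
#' formats the pipeline reads (dosage TSV, phenotype TSV, truth and QTL
#' TSVs, config YAML).
#'
#' @param scale `"tiny"` or `"desk"`.
#' @param seed base seed passed to the generator.
#' @param dir optional directory to write the fixture files into.
#' @param ... overrides forwarded to [sim_config()].
#' @return list: `config`, `panel`, `records`, `phenos`, `split`, `truth`,
#'   and (when written) `paths`.
#' @export
make_study_fixture <- function(scale = c("tiny", "desk"), seed = 42,
                               dir = NULL, ...) {
  scale <- match.arg(scale)
  base <- if (scale == "tiny") {
    list(n_animals = 50, n_snps = 20, n_qtl = 2, qtl_var_fraction = 0.3,
         h2 = 0.3, sigma_u2 = 1, sigma_pe2_ratio = 0.25,
         parities_per_animal = c(1, 3), n_validation = 5, seed = seed)
  } else {
    list(n_animals = 2000, n_snps = 5000, n_qtl = 3, qtl_var_fraction = 0.3,
         h2 = 0.1894, sigma_u2 = 1.049, sigma_pe2_ratio = 0.2,
         parities_per_animal = c(1, 6), n_validation = 200, seed = seed)
  }
  over <- list(...)
  base[names(over)] <- over
  config <- do.call(sim_config, base)
  panel <- simulate_genotypes(config)
  sim <- simulate_trait(panel, config)
  lam <- if (is.infinite(sim$truth$lambda)) 1e6 else sim$truth$lambda
  phenos <- collapse_parities(sim$records, lam)
  birth_order <- stats::setNames(seq_along(panel$animal_ids), panel$animal_ids)
  split <- split_reference_validation(phenos, birth_order, config$n_validation)
  out <- list(config = config, panel = panel, records = sim$records,
              phenos = phenos, split = split, truth = sim$truth,
              birth_order = birth_order)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      genotypes = file.path(dir, "genotypes.tsv"),
      phenotypes = file.path(dir, "phenotypes.tsv"),
      truth = file.path(dir, "truth.tsv"),
      qtl = file.path(dir, "qtl.tsv"),
      config = file.path(dir, "config.yaml"))
    write_genotypes(panel, paths$genotypes)
    data.table::fwrite(sim$records, paths$phenotypes, sep = "\t")
    data.table::fwrite(data.frame(animal_id = names(sim$truth$tbv),
                                  tbv = unname(sim$truth$tbv)),
                       paths$truth, sep = "\t")
    data.table::fwrite(data.frame(snp_id = sim$truth$qtl_ids,
                                  effect = sim$truth$qtl_effects),
                       paths$qtl, sep = "\t")
    yaml::write_yaml(list(
      trait = list(name = paste0(scale, "_trait"),
                   sigma_u2 = sim$truth$sigma_u2,
                   sigma_e2 = sim$truth$sigma_e2,
                   lambda = lam),
      n_validation = config$n_validation,
      seed = config$seed), paths$config)
    out$paths <- paths
  }
  out
}
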