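test_that("GBLUP matches a GLS closed-form oracle on a small system", {
  panel <- hwe_panel(5, 50, seed = 21)
  grm <- build_grm(panel)
  set.seed(22)
  y <- rnorm(5)
  spec <- make_prior_spec("gblup", sigma_u2 = 0.8, sigma_e2 = 1.5)
  ridge <- 1e-6
  fit <- fit_gblup(pheno_frame(panel, y), grm, spec, ridge = ridge)
  oracle <- gls_blup(grm$matrix + diag(ridge, 5), rep(1, 5), y, 0.8, 1.5)
  expect_equal(unname(fit$gebv), oracle$u, tolerance = 1e-8)
  expect_equal(fit$mu_mean, oracle$mu, tolerance = 1e-8)
  # residuals satisfy the normal equations: 1'W r = 0 at the solution
  r <- y - fit$mu_mean - unname(fit$gebv)
  expect_lt(abs(sum(r)), 1e-8)
})

test_that("GBLUP with heterogeneous residual weights matches the oracle", {
  panel <- hwe_panel(8, 60, seed = 31)
  grm <- build_grm(panel)
  set.seed(32)
  n_eff <- effective_records(sample(1:6, 8, replace = TRUE), lam = 4)
  ph <- data.frame(animal_id = panel$animal_ids, y = rnorm(8), n_eff = n_eff)
  spec <- make_prior_spec("gblup", sigma_u2 = 1.2, sigma_e2 = 2.5)
  fit <- fit_gblup(ph, grm, spec, ridge = 1e-6)
  oracle <- gls_blup(grm$matrix + diag(1e-6, 8), 1 / n_eff, ph$y, 1.2, 2.5)
  expect_equal(unname(fit$gebv), oracle$u, tolerance = 1e-8)
})

test_that("GBLUP on a constant phenotype returns zero breeding values", {
  panel <- hwe_panel(10, 40, seed = 41)
  grm <- build_grm(panel)
  fit <- fit_gblup(pheno_frame(panel, rep(3.7, 10)), grm,
                   make_prior_spec("gblup", 1, 1))
  expect_lt(max(abs(fit$gebv)), 1e-6)
  expect_equal(fit$mu_mean, 3.7, tolerance = 1e-6)
})

test_that("GBLUP equals SNP-BLUP ridge regression mapped back to animals", {
  fx <- make_study_fixture("tiny")
  grm <- build_grm(fx$panel)
  spec <- make_prior_spec("gblup", sigma_u2 = 1, sigma_e2 = fx$truth$sigma_e2)
  fit <- fit_gblup(fx$phenos, grm, spec, predict_ids = fx$split$validation,
                   ridge = 1e-8)
  X <- sweep(fx$panel$dosages, 2, 2 * fx$panel$allele_freqs, "-")
  w <- stats::setNames(fx$phenos$n_eff, fx$phenos$animal_id)[fx$panel$animal_ids]
  w[fx$split$validation] <- 0
  y <- stats::setNames(fx$phenos$y, fx$phenos$animal_id)[fx$panel$animal_ids]
  y[is.na(y)] <- 0
  # per-SNP effect variance sigma_u2 / (2 sum p(1-p)) makes the two models
  # mathematically equivalent
  lambda <- fx$truth$sigma_e2 / (1 / grm$denominator)
  oracle <- ridge_mme(X, unname(y), unname(w), lambda)
  expect_lt(max(abs(unname(fit$gebv) - oracle$ghat)), 1e-6)
})

test_that("unphenotyped animals never enter the GBLUP likelihood", {
  panel <- hwe_panel(30, 80, seed = 51)
  set.seed(52)
  y <- rnorm(30)
  ph_all <- pheno_frame(panel, y)
  masked <- panel$animal_ids[26:30]
  spec <- make_prior_spec("gblup", 1, 1)
  fit_full <- fit_gblup(ph_all, build_grm(panel), spec, predict_ids = masked)
  # drop the masked animals from the system entirely (frequencies fixed to
  # the full panel's so both fits centre identically)
  sub <- genotype_panel(panel$dosages[1:25, ], allele_freqs = panel$allele_freqs)
  grm_sub <- build_grm(sub)
  grm_sub$denominator <- build_grm(panel)$denominator
  Z <- sweep(sub$dosages, 2, 2 * panel$allele_freqs, "-")
  grm_sub$matrix <- tcrossprod(Z) / build_grm(panel)$denominator
  fit_sub <- fit_gblup(ph_all[1:25, ], grm_sub, spec)
  expect_equal(unname(fit_full$gebv[1:25]), unname(fit_sub$gebv),
               tolerance = 1e-10)
})

test_that("BayesC with pi = 1 recovers the ridge posterior mean", {
  fx <- make_study_fixture("tiny")
  het <- average_heterozygosity(fx$panel)
  # Fr = 1/m makes pi = 1: every SNP is always in the model
  spec <- make_prior_spec("bayesc", sigma_u2 = 1, sigma_e2 = fx$truth$sigma_e2,
                          Fr = 1/20, het_bar = het, n_loci = 20)
  expect_equal(spec$pi, 1)
  mc <- mcmc_config(n_cycles = 20000, n_burnin = 4000, n_chains = 8, seed = 9)
  fit <- gibbs_bayesc(fx$phenos, fx$panel, spec, mc,
                      predict_ids = fx$split$validation)
  al <- bayesgc:::align_phenotypes(fx$phenos, fx$panel$animal_ids,
                                   fx$split$validation)
  X <- sweep(fx$panel$dosages, 2, 2 * fx$panel$allele_freqs, "-")
  oracle <- ridge_mme(X, al$y, al$w, fx$truth$sigma_e2 / spec$sigma_m2)
  mc_se <- apply(fit$per_chain_gebv, 1, sd) / sqrt(ncol(fit$per_chain_gebv))
  expect_within_mc_se(unname(fit$gebv) - oracle$ghat, mc_se, df = 7)
  expect_gt(cor(unname(fit$gebv), oracle$ghat), 0.999)
  expect_lt(fit$max_residual_drift, 1e-8)
})

test_that("BayesC finds no signal in a null phenotype", {
  panel <- hwe_panel(60, 30, seed = 61)
  het <- average_heterozygosity(panel)
  spec <- make_prior_spec("bayesc", sigma_u2 = 1, sigma_e2 = 1, Fr = 1/5,
                          het_bar = het, n_loci = 30)
  fit <- gibbs_bayesc(pheno_frame(panel, rep(0, 60)), panel, spec,
                      mcmc_config(4000, 1000, n_chains = 4, seed = 3))
  mc_se <- apply(fit$per_chain_gebv, 1, sd) / 2
  expect_within_mc_se(unname(fit$gebv), mc_se, df = 3)
  # inclusion stays near the prior when there is nothing to find
  expect_lt(mean(fit$snp_inclusion_prob), 3 * spec$pi)
})

test_that("BayesC posterior summaries are exchangeable under SNP permutation", {
  fx <- make_study_fixture("tiny")
  het <- average_heterozygosity(fx$panel)
  spec <- make_prior_spec("bayesc", sigma_u2 = 1, sigma_e2 = fx$truth$sigma_e2,
                          Fr = 1/4, het_bar = het, n_loci = 20)
  mc <- mcmc_config(8000, 2000, n_chains = 2, seed = 17)
  fit1 <- gibbs_bayesc(fx$phenos, fx$panel, spec, mc)
  set.seed(99)
  perm <- sample(20)
  panel_p <- genotype_panel(fx$panel$dosages[, perm],
                            snp_ids = fx$panel$snp_ids[perm])
  fit2 <- gibbs_bayesc(fx$phenos, panel_p, spec, mc)
  expect_gt(cor(fit1$gebv, fit2$gebv), 0.99)
  expect_gt(cor(fit1$snp_inclusion_prob[fx$panel$snp_ids[perm]],
                fit2$snp_inclusion_prob), 0.95)
})

test_that("BayesC concentrates inclusion around large simulated QTL", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- sim_config(n_animals = 400, n_snps = 500, n_qtl = 2,
                      qtl_var_fraction = 0.5, h2 = 0.5, sigma_pe2_ratio = 0,
                      parities_per_animal = c(1, 1), n_validation = 0,
                      seed = 1000 + s)
    panel <- simulate_genotypes(cfg)
    sim <- simulate_trait(panel, cfg)
    phenos <- collapse_parities(sim$records, Inf)
    het <- average_heterozygosity(panel)
    spec <- make_prior_spec("bayesc", sigma_u2 = 1,
                            sigma_e2 = sim$truth$sigma_e2, Fr = 1/4,
                            het_bar = het, n_loci = 500)
    fit <- gibbs_bayesc(phenos, panel, spec,
                        mcmc_config(3000, 600, n_chains = 1, seed = s))
    # windowed inclusion: top two +/-2-SNP windows flank the two QTL
    ip <- unname(fit$snp_inclusion_prob)
    win <- stats::filter(ip, rep(1, 5), sides = 2)
    win[is.na(win)] <- 0
    top1 <- which.max(win)
    win2 <- win; win2[max(1, top1 - 4):min(500, top1 + 4)] <- -1
    top2 <- which.max(win2)
    qtl <- match(sim$truth$qtl_ids, panel$snp_ids)
    ok <- all(vapply(qtl, function(q)
      min(abs(q - c(top1, top2))) <= 2, logical(1)))
    hits <- hits + ok
  }
  expect_gte(hits, 9L)
})

test_that("BayesGC with a suppressed marker term degenerates to GBLUP", {
  cfg <- sim_config(n_animals = 200, n_snps = 300, h2 = 0.3,
                    n_validation = 20, seed = 7)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_trait(panel, cfg)
  phenos <- collapse_parities(sim$records, sim$truth$lambda)
  grm <- build_grm(panel)
  het <- average_heterozygosity(panel)
  spec <- make_prior_spec("bayesgc", sigma_u2 = 1,
                          sigma_e2 = sim$truth$sigma_e2, Fr = 1/10, q = 0.5,
                          het_bar = het, n_loci = 300)
  sup <- spec; sup$pi <- 1e-9; sup$sigma_m2 <- 1e-12
  fit_gc <- gibbs_bayesgc(phenos, panel, grm, sup,
                          mcmc_config(10000, 2000, n_chains = 6, seed = 5))
  ref <- fit_gblup(phenos, grm,
                   make_prior_spec("gblup", spec$sigma_pol2, spec$sigma_e2))
  mc_se <- apply(fit_gc$per_chain_gebv, 1, sd) / sqrt(6)
  expect_within_mc_se(unname(fit_gc$gebv - ref$gebv), mc_se, df = 5, floor = 5e-3)
  expect_gt(cor(fit_gc$gebv, ref$gebv), 0.999)
})

test_that("chain diagnostics report agreement and disagreement", {
  fx <- make_study_fixture("tiny")
  het <- average_heterozygosity(fx$panel)
  spec <- make_prior_spec("bayesc", 1, fx$truth$sigma_e2, Fr = 1/4,
                          het_bar = het, n_loci = 20)
  fit <- gibbs_bayesc(fx$phenos, fx$panel, spec,
                      mcmc_config(2000, 400, n_chains = 2, seed = 1))
  # identical chains by construction
  same <- fit; same$per_chain_gebv <- fit$per_chain_gebv[, c(1, 1)]
  expect_equal(diagnose_chains(same, 0.9999)$ebv_chain_correlation, 1.0)
  neg <- fit; neg$per_chain_gebv[, 2] <- -neg$per_chain_gebv[, 1]
  d <- diagnose_chains(neg, 0.9999)
  expect_equal(d$ebv_chain_correlation, -1.0)
  expect_false(d$converged)
  one <- fit; one$per_chain_gebv <- fit$per_chain_gebv[, 1, drop = FALSE]
  expect_error(diagnose_chains(one), ">= 2 chains")
})

test_that("GEBV variance grows towards h2-consistent levels with reference size", {
  vars <- vapply(c(100, 400, 1600), function(n) {
    cfg <- sim_config(n_animals = n, n_snps = 500, n_qtl = 0,
                      qtl_var_fraction = 0, h2 = 0.3, sigma_pe2_ratio = 0,
                      parities_per_animal = c(1, 1), n_validation = 0,
                      seed = 77)
    panel <- simulate_genotypes(cfg)
    sim <- simulate_trait(panel, cfg)
    phenos <- collapse_parities(sim$records, Inf)
    fit <- fit_gblup(phenos, build_grm(panel),
                     make_prior_spec("gblup", 1, sim$truth$sigma_e2))
    stats::var(unname(fit$gebv))
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
  expect_lt(vars[3], 1.1)  # bounded by sigma_u2
})
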