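test_that("the generator is deterministic given a seed", {
  cfg <- sim_config(n_animals = 100, n_snps = 50, seed = 5)
  p1 <- simulate_genotypes(cfg); p2 <- simulate_genotypes(cfg)
  expect_identical(p1$dosages, p2$dosages)
  s1 <- simulate_trait(p1, cfg); s2 <- simulate_trait(p2, cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$tbv, s2$truth$tbv)
})

test_that("genotypes follow the configured allele-frequency spectrum", {
  # near-degenerate Beta concentrates p at 0.5: mean dosage ~ 1
  cfg <- sim_config(n_animals = 1000, n_snps = 50, maf_dist = c(1e5, 1e5),
                    seed = 8)
  panel <- simulate_genotypes(cfg)
  expect_gt(mean(panel$dosages), 0.95)
  expect_lt(mean(panel$dosages), 1.05)

  # a spectrum with mass below MAF 0.01 interacts with the filter as expected
  cfg2 <- sim_config(n_animals = 400, n_snps = 400, maf_dist = c(0.08, 1),
                     seed = 9)
  panel2 <- simulate_genotypes(cfg2)
  suppressMessages(filtered <- filter_maf(panel2, 0.01))
  expect_lt(length(filtered$snp_ids), length(panel2$snp_ids))
  maf <- pmin(filtered$allele_freqs, 1 - filtered$allele_freqs)
  expect_true(all(maf > 0.01))
})

test_that("LD mode induces adjacent-marker correlation", {
  cfg <- sim_config(n_animals = 800, n_snps = 200, ld_rho = 0.9, seed = 10)
  panel <- simulate_genotypes(cfg)
  adj <- vapply(1:199, function(j)
    suppressWarnings(cor(panel$dosages[, j], panel$dosages[, j + 1])),
    numeric(1))
  expect_gt(mean(adj, na.rm = TRUE), 0.4)
  cfg0 <- sim_config(n_animals = 800, n_snps = 200, ld_rho = 0, seed = 10)
  panel0 <- simulate_genotypes(cfg0)
  adj0 <- vapply(1:199, function(j)
    suppressWarnings(cor(panel0$dosages[, j], panel0$dosages[, j + 1])),
    numeric(1))
  expect_lt(abs(mean(adj0, na.rm = TRUE)), 0.05)
  # marginal frequencies are preserved by the thresholding construction
  expect_equal(mean(panel$allele_freqs), 0.5, tolerance = 0.05)
})

test_that("trait variance components are realised as configured", {
  cfg <- sim_config(n_animals = 2000, n_snps = 800, n_qtl = 3,
                    qtl_var_fraction = 0.3, h2 = 0.3, sigma_pe2_ratio = 0.25,
                    parities_per_animal = c(4, 6), seed = 12)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_trait(panel, cfg)
  tr <- sim$truth
  expect_equal(tr$sigma_e2, (1 - 0.3) / 0.3, tolerance = 1e-12)
  expect_equal(tr$lambda, 1 / 0.25)
  # QTL effects carry exactly the configured variance share
  p <- panel$allele_freqs[match(tr$qtl_ids, panel$snp_ids)]
  expect_equal(sum(2 * p * (1 - p) * tr$qtl_effects^2), 0.3, tolerance = 1e-12)
  # realised tbv variance near sigma_u2
  expect_equal(stats::var(tr$tbv), 1, tolerance = 0.1)
  # total phenotypic variance ~ sigma_u2 + sigma_pe2 + sigma_e2 (within 5%)
  total <- 1 + tr$sigma_pe2 + tr$sigma_e2
  expect_equal(stats::var(sim$records$value), total, tolerance = 0.05)
})

test_that("an ANOVA oracle recovers the target heritability", {
  # no permanent environment: the between-animal variance component is
  # purely genetic, so a one-way ANOVA identifies h2
  cfg <- sim_config(n_animals = 2000, n_snps = 500, h2 = 0.3,
                    sigma_pe2_ratio = 0, parities_per_animal = c(4, 6),
                    seed = 13)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_trait(panel, cfg)
  v <- sim$records$value
  g <- sim$records$animal_id
  N <- length(v); a <- length(unique(g))
  ni <- tapply(v, g, length)
  ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
  ssb <- sum(ni * (tapply(v, g, mean) - mean(v))^2)
  msw <- ssw / (N - a); msb <- ssb / (a - 1)
  k0 <- (N - sum(ni^2) / N) / (a - 1)  # unbalanced-design group size
  sigma_a2 <- (msb - msw) / k0
  h2_hat <- sigma_a2 / (sigma_a2 + msw)
  expect_gt(h2_hat, 0.25); expect_lt(h2_hat, 0.35)
})

test_that("no permanent environment means records differ only by residual", {
  cfg <- sim_config(n_animals = 500, n_snps = 100, h2 = 0.4,
                    sigma_pe2_ratio = 0, parities_per_animal = c(3, 3),
                    seed = 14)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_trait(panel, cfg)
  within_var <- mean(tapply(sim$records$value, sim$records$animal_id, var))
  expect_equal(within_var, sim$truth$sigma_e2, tolerance = 0.1)
  expect_true(is.infinite(sim$truth$lambda))
  # collapse with lambda -> Inf gives n_eff = n
  ph <- collapse_parities(sim$records, Inf)
  expect_equal(ph$n_eff, as.numeric(ph$n_records))
})

test_that("degenerate architecture configurations error", {
  cfg <- sim_config(n_animals = 50, n_snps = 20, n_qtl = 0,
                    qtl_var_fraction = 0.5, seed = 1)
  panel <- simulate_genotypes(cfg)
  expect_error(simulate_trait(panel, cfg), "n_qtl")
  # purely polygenic is fine
  cfg2 <- sim_config(n_animals = 50, n_snps = 20, n_qtl = 0,
                     qtl_var_fraction = 0, seed = 1)
  sim <- simulate_trait(simulate_genotypes(cfg2), cfg2)
  expect_equal(length(sim$truth$qtl_ids), 0L)
})

test_that("the tiny fixture round-trips through every I/O format", {
  dir <- tempfile("fixture_")
  fx <- make_study_fixture("tiny", dir = dir)
  panel <- read_genotypes(fx$paths$genotypes)
  expect_equal(panel$dosages, fx$panel$dosages)
  rec <- read_phenotypes(fx$paths$phenotypes)
  expect_equal(nrow(rec), nrow(fx$records))
  truth <- read.delim(fx$paths$truth)
  expect_equal(truth$tbv, unname(fx$truth$tbv))
  cfgy <- yaml::read_yaml(fx$paths$config)
  expect_equal(cfgy$trait$sigma_u2, 1)
  expect_equal(length(fx$split$validation), 5L)
})
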