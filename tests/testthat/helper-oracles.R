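# Independent linear-algebra oracles used across test files.

# Weighted ridge regression with an unpenalised intercept:
# minimises sum w_j (y_j - mu - x_j's)^2 + lambda * ||s||^2.
# This is the closed-form posterior mean of SNP-BLUP / BayesC-with-pi=1.
ridge_mme <- function(X, y, w, lambda) {
  m <- ncol(X)
  C <- rbind(c(sum(w), colSums(w * X)),
             cbind(colSums(w * X), crossprod(X, w * X) + diag(lambda, m)))
  sol <- solve(C, c(sum(w * y), crossprod(X, w * y)))
  list(mu = sol[1], s = sol[-1], ghat = as.numeric(X %*% sol[-1]))
}

# GLS/BLUP closed form, a different route than the mixed-model equations:
# V = Gt * sigma_u2 + D * sigma_e2; mu = (1'Vi1)^-1 1'Vi y;
# u = sigma_u2 * Gt * Vi * (y - mu).
gls_blup <- function(Gt, d_diag, y, sigma_u2, sigma_e2) {
  V <- Gt * sigma_u2 + diag(d_diag * sigma_e2)
  Vi <- solve(V)
  one <- rep(1, length(y))
  mu <- drop(crossprod(one, Vi %*% y) / crossprod(one, Vi %*% one))
  u <- drop(sigma_u2 * Gt %*% Vi %*% (y - mu))
  list(mu = mu, u = unname(u))
}

# small HWE panel with fixed seed
hwe_panel <- function(n, m, p = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(p)) p <- stats::runif(m, 0.1, 0.9)
  M <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
  genotype_panel(M)
}

# single-record phenotypes from a vector aligned to panel animals
pheno_frame <- function(panel, y) {
  data.frame(animal_id = panel$animal_ids, y = y, n_eff = 1,
             stringsAsFactors = FALSE)
}

# "within 3 Monte-Carlo standard errors": the SE is estimated from `df + 1`
# chains, so the 3-sigma criterion maps to the matching t quantile, and
# testing many animals at once is allowed for by requiring 95% within the
# bound and none beyond twice it.
expect_within_mc_se <- function(diff, se, df = Inf, floor = 1e-3) {
  z3 <- stats::qt(stats::pnorm(3), df)
  z <- abs(diff) / pmax(se, floor)
  testthat::expect_gte(mean(z < z3), 0.95)
  testthat::expect_lt(max(z), 2 * z3)
}
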