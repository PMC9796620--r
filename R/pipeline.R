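#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file path) with blocks:
#' \describe{
#'   \item{trait}{`name`, `sigma_u2`, `sigma_e2`, `lambda` (all required).}
#'   \item{data}{either `simulate:` (fields forwarded to [sim_config()]) or
#'     `files:` with `genotypes`, `phenotypes` and optional
#'     `format` ("matrix"/"vcf").}
#'   \item{grid}{`methods` (subset of gblup/bayesc/bayesgc), `Fr_values`,
#'     `q_values`. GBLUP ignores Fr and q; BayesC ignores q; BayesGC spans
#'     Fr x q — so the classic 1 + 5 + 15 design is one config.}
#'   \item{mcmc}{`n_cycles`, `n_burnin`, `n_chains`, `seed`.}
#'   \item{top level}{`maf_threshold` (default 0.01), `n_validation`,
#'     `seed`, `n_boot` (default 1000).}
#' }
#'
#' @param config named list or path to a YAML file.
#' @return The validated config list (with defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  missing <- character(0)
  need <- function(path, ok) if (!ok) missing <<- c(missing, path)
  need("trait", !is.null(config$trait))
  for (f in c("name", "sigma_u2", "sigma_e2", "lambda"))
    need(paste0("trait.", f), !is.null(config$trait[[f]]))
  need("data.simulate or data.files",
       !is.null(config$data$simulate) || !is.null(config$data$files))
  if (!is.null(config$data$files)) {
    for (f in c("genotypes", "phenotypes"))
      need(paste0("data.files.", f), !is.null(config$data$files[[f]]))
  }
  need("grid.methods", length(config$grid$methods) > 0)
  if (length(missing))
    stop("config schema error; missing: ", paste(missing, collapse = ", "))
  bad <- setdiff(config$grid$methods, c("gblup", "bayesc", "bayesgc"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (any(c("bayesc", "bayesgc") %in% config$grid$methods) &&
      length(config$grid$Fr_values) == 0)
    stop("config schema error; missing: grid.Fr_values")
  if ("bayesgc" %in% config$grid$methods &&
      length(config$grid$q_values) == 0)
    stop("config schema error; missing: grid.q_values")
  config$maf_threshold <- config$maf_threshold %||% 0.01
  config$seed <- config$seed %||% 1
  config$n_boot <- config$n_boot %||% 1000
  config$mcmc <- utils::modifyList(
    list(n_cycles = 20000, n_burnin = 4000, n_chains = 2, seed = config$seed),
    config$mcmc %||% list())
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full prediction pipeline
#'
#' simulate/load -> MAF filter -> collapse parities -> youngest-animal
#' split -> GRM -> fit every (method, Fr, q) combination of the grid ->
#' validation reports -> summary files. Deterministic given the config
#' seed.
#'
#' @param config config list or YAML path (see [validate_config()]).
#' @param out_dir directory for report files; created if absent.
#' @return list with `reports` (one row per grid combination), `best`
#'   (best row per trait), and `manifest` (config snapshot, seeds, file
#'   digests, per-stage wall times).
#' @export
run_pipeline <- function(config, out_dir = tempfile("bayesgc_run_")) {
  config <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  times <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  # --- data ---
  if (!is.null(config$data$simulate)) {
    sc <- do.call(sim_config, utils::modifyList(
      list(seed = config$seed), config$data$simulate))
    panel <- simulate_genotypes(sc)
    sim <- simulate_trait(panel, sc)
    records <- sim$records
    n_validation <- config$n_validation %||% sc$n_validation
  } else {
    panel <- read_genotypes(config$data$files$genotypes,
                            format = config$data$files$format %||% "matrix")
    records <- read_phenotypes(config$data$files$phenotypes)
    n_validation <- config$n_validation %||%
      stop("config schema error; missing: n_validation (required for file input)")
  }
  times["data"] <- tic() - t0; t0 <- tic()

  panel <- filter_maf(panel, config$maf_threshold)
  phenos <- collapse_parities(records, config$trait$lambda)
  bad_ids <- setdiff(phenos$animal_id, panel$animal_ids)
  if (length(bad_ids))
    stop("inconsistent animal ids: phenotyped but not genotyped: ",
         paste(utils::head(bad_ids, 3), collapse = ", "))
  birth_order <- stats::setNames(seq_along(panel$animal_ids),
                                 panel$animal_ids)
  split <- split_reference_validation(phenos, birth_order, n_validation)
  grm <- if (any(c("gblup", "bayesgc") %in% config$grid$methods))
    build_grm(panel) else NULL
  het <- average_heterozygosity(panel)
  h2 <- heritability(config$trait$sigma_u2, config$trait$sigma_e2)
  times["prepare"] <- tic() - t0; t0 <- tic()

  # --- normalized grid: gblup once, bayesc x Fr, bayesgc x Fr x q ---
  combos <- list()
  for (method in config$grid$methods) {
    if (method == "gblup") {
      combos[[length(combos) + 1L]] <- list(method = "gblup", Fr = NA, q = NA)
    } else if (method == "bayesc") {
      for (Fr in config$grid$Fr_values)
        combos[[length(combos) + 1L]] <- list(method = "bayesc", Fr = Fr, q = 1)
    } else {
      for (Fr in config$grid$Fr_values) for (q in config$grid$q_values)
        combos[[length(combos) + 1L]] <- list(method = "bayesgc", Fr = Fr, q = q)
    }
  }

  mcmc <- mcmc_config(n_cycles = config$mcmc$n_cycles,
                      n_burnin = config$mcmc$n_burnin,
                      n_chains = config$mcmc$n_chains,
                      seed = config$mcmc$seed)
  reports <- vector("list", length(combos))
  for (i in seq_along(combos)) {
    cb <- combos[[i]]
    spec <- if (cb$method == "gblup") {
      make_prior_spec("gblup", sigma_u2 = config$trait$sigma_u2,
                      sigma_e2 = config$trait$sigma_e2,
                      het_bar = het, n_loci = length(panel$snp_ids))
    } else {
      make_prior_spec(cb$method, sigma_u2 = config$trait$sigma_u2,
                      sigma_e2 = config$trait$sigma_e2, Fr = cb$Fr,
                      q = if (cb$method == "bayesc") 1 else cb$q,
                      het_bar = het, n_loci = length(panel$snp_ids))
    }
    fit <- switch(cb$method,
      gblup = fit_gblup(phenos, grm, spec, predict_ids = split$validation),
      bayesc = gibbs_bayesc(phenos, panel, spec, mcmc,
                            predict_ids = split$validation),
      bayesgc = gibbs_bayesgc(phenos, panel, grm, spec, mcmc,
                              predict_ids = split$validation))
    reports[[i]] <- validation_report(fit, phenos, split$validation, h2,
                                      trait = config$trait$name, spec = spec,
                                      n_boot = config$n_boot,
                                      seed = config$seed)
    message(sprintf("[%d/%d] %s Fr=%s q=%s accuracy=%.3f", i, length(combos),
                    cb$method, format(cb$Fr), format(cb$q),
                    reports[[i]]$accuracy))
  }
  reports <- do.call(rbind, reports)
  times["fit"] <- tic() - t0; t0 <- tic()

  out <- report_grid(reports, out_dir = out_dir)
  times["report"] <- tic() - t0

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(config = config, seed = config$seed,
                   version = as.character(utils::packageVersion("bayesgc")),
                   digests = as.list(tools::md5sum(files)),
                   wall_times = as.list(times))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  list(reports = out$reports, best = out$best, manifest = manifest,
       out_dir = out_dir)
}

#' Summarise a grid of validation reports
#'
#' Writes the long-format grid and extracts the best row per trait
#' (maximum accuracy; ties broken towards the smaller model, i.e. the
#' larger Fr, with GBLUP counted as the smallest model of all).
#'
#' @param reports data.frame of [validation_report()] rows.
#' @param out_dir optional directory; when given, writes
#'   `report_grid.tsv` and `report_best.tsv`.
#' @return list with `reports` and `best` data.frames.
#' @export
report_grid <- function(reports, out_dir = NULL) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 1)
  best <- do.call(rbind, lapply(split(reports, reports$trait), function(df) {
    k <- ifelse(is.na(df$Fr), 1, df$Fr)  # GBLUP = smallest model
    df[order(-df$accuracy, -k), ][1, ]
  }))
  rownames(best) <- NULL
  if (!is.null(out_dir)) {
    data.table::fwrite(reports, file.path(out_dir, "report_grid.tsv"),
                       sep = "\t")
    data.table::fwrite(best, file.path(out_dir, "report_best.tsv"),
                       sep = "\t")
  }
  list(reports = reports, best = best)
}
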