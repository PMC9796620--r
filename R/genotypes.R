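#' Construct a genotype panel
#'
#' A `genotype_panel` holds an animals-by-SNPs matrix of allele dosages
#' (counts of the counted allele, 0/1/2) together with per-SNP allele
#' frequencies. All downstream code (GRM construction, the samplers) centres
#' dosages by `2 * p_i`, so the frequencies stored here define the centring.
#'
#' @param dosages numeric matrix, animals in rows, SNPs in columns; values
#'   in \[0, 2\] (fractional values arise from mean-imputation of missing
#'   genotypes).
#' @param animal_ids character vector of row identifiers.
#' @param snp_ids character vector of column identifiers.
#' @param allele_freqs optional per-SNP frequency of the counted allele; when
#'   `NULL` it is computed as `colMeans(dosages) / 2`.
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosages`, `animal_ids`, `snp_ids`, `allele_freqs`.
#' @export
genotype_panel <- function(dosages, animal_ids = rownames(dosages),
                           snp_ids = colnames(dosages), allele_freqs = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(animal_ids)) animal_ids <- paste0("A", seq_len(nrow(dosages)))
  if (is.null(snp_ids)) snp_ids <- paste0("S", seq_len(ncol(dosages)))
  animal_ids <- as.character(animal_ids)
  snp_ids <- as.character(snp_ids)
  if (length(animal_ids) != nrow(dosages))
    stop("length(animal_ids) must equal nrow(dosages)")
  if (length(snp_ids) != ncol(dosages))
    stop("length(snp_ids) must equal ncol(dosages)")
  if (anyDuplicated(animal_ids)) stop("duplicate animal ids")
  if (anyNA(dosages)) stop("dosages must not contain NA; impute before construction")
  if (any(dosages < 0 | dosages > 2)) stop("dosages must lie in [0, 2]")
  if (is.null(allele_freqs)) {
    allele_freqs <- colMeans(dosages) / 2
  } else if (length(allele_freqs) != ncol(dosages)) {
    stop("length(allele_freqs) must equal ncol(dosages)")
  }
  dimnames(dosages) <- list(animal_ids, snp_ids)
  structure(list(dosages = dosages, animal_ids = animal_ids,
                 snp_ids = snp_ids, allele_freqs = unname(allele_freqs)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d animals x %d SNPs\n",
              length(x$animal_ids), length(x$snp_ids)))
  maf <- pmin(x$allele_freqs, 1 - x$allele_freqs)
  cat(sprintf("  MAF range: %.4f - %.4f; mean heterozygosity: %.4f\n",
              min(maf), max(maf), average_heterozygosity(x)))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Read genotypes from a dosage matrix TSV or a VCF
#'
#' The matrix format is a tab-separated file whose header row carries the SNP
#' ids and whose first column carries the animal ids; cells are allele
#' dosages 0/1/2 (`NA` allowed). VCF input (requires the vcfR package) takes
#' biallelic SNP records with a GT field; the dosage is the count of the ALT
#' allele. Multi-allelic records are skipped with a warning; missing
#' genotypes are imputed to the column mean `2 p_i` and the number of imputed
#' cells is reported via a message.
#'
#' @param path path to the input file.
#' @param format `"matrix"` (default) or `"vcf"`.
#' @return A [genotype_panel].
#' @export
read_genotypes <- function(path, format = c("matrix", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "matrix") {
    dt <- tryCatch(
      data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE),
      error = function(e) stop("unparseable dosage matrix '", path, "': ",
                               conditionMessage(e)))
    if (ncol(dt) < 2) stop("dosage matrix needs an id column plus >=1 SNP column")
    animal_ids <- as.character(dt[[1]])
    M <- as.matrix(dt[, -1, drop = FALSE])
    storage.mode(M) <- "double"
    bad <- which(!is.na(M) & (M < 0 | M > 2))
    if (length(bad))
      stop("format error: dosage outside [0,2] at data line ",
           ((bad[1] - 1L) %% nrow(M)) + 1L)
    snp_ids <- colnames(dt)[-1]
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("VCF input requires the 'vcfR' package")
    v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("unparseable VCF '", path, "': ",
                                           conditionMessage(e)))
    alt <- vcfR::getALT(v)
    multi <- grepl(",", alt) | is.na(alt) | alt == ""
    if (any(multi))
      warning(sum(multi), " non-biallelic VCF record(s) skipped")
    gt <- vcfR::extract.gt(v, element = "GT")[!multi, , drop = FALSE]
    if (nrow(gt) == 0) stop("no biallelic SNP records in ", path)
    # count ALT alleles in the GT string; "./." and friends become NA
    count_alt <- function(g) {
      al <- strsplit(g, "[/|]")
      vapply(al, function(a) {
        if (any(is.na(a)) || any(a == ".")) return(NA_real_)
        sum(a == "1")
      }, numeric(1))
    }
    M <- t(apply(gt, 1, count_alt))
    M <- t(M)  # animals x SNPs
    animal_ids <- colnames(gt)
    snp_ids <- rownames(gt)
    if (is.null(snp_ids) || anyDuplicated(snp_ids))
      snp_ids <- paste0("snp", seq_len(ncol(M)))
  }
  n_missing <- sum(is.na(M))
  if (n_missing > 0) {
    p <- colMeans(M, na.rm = TRUE) / 2
    for (j in which(colSums(is.na(M)) > 0)) {
      M[is.na(M[, j]), j] <- 2 * p[j]
    }
    message("imputed ", n_missing, " missing genotype(s) to 2p")
  }
  genotype_panel(M, animal_ids = animal_ids, snp_ids = snp_ids)
}

#' Write a genotype panel as a dosage matrix TSV
#'
#' @param panel a [genotype_panel].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path) {
  df <- data.frame(animal_id = panel$animal_ids, panel$dosages,
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Filter SNPs on minor allele frequency
#'
#' Retains SNPs with `min(p, 1 - p) > threshold` and recomputes allele
#' frequencies on the retained panel. The genotype panel used in the study
#' design this package emulates kept 429,403 SNPs at MAF > 0.01.
#'
#' @param panel a [genotype_panel].
#' @param threshold MAF threshold in \[0, 0.5); the comparison is strict.
#' @return A new [genotype_panel] with only the retained SNPs.
#' @export
filter_maf <- function(panel, threshold = 0.01) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (threshold < 0 || threshold >= 0.5)
    stop("threshold must lie in [0, 0.5)")
  maf <- pmin(panel$allele_freqs, 1 - panel$allele_freqs)
  keep <- maf > threshold
  if (!any(keep))
    stop("MAF filter at ", threshold, " removed every SNP (empty panel)")
  message(sum(keep), " of ", length(keep), " SNPs retained at MAF > ",
          threshold)
  genotype_panel(panel$dosages[, keep, drop = FALSE],
                 animal_ids = panel$animal_ids,
                 snp_ids = panel$snp_ids[keep])
}

#' Average expected heterozygosity of a panel
#'
#' Computes `HETbar = 2 * sum(p_i * (1 - p_i)) / Nloci`, the mean expected
#' heterozygosity over the SNP panel. This scalar converts the per-SNP
#' effect variance into genetic variance: a SNP with effect variance
#' sigma_m2 contributes `HETbar * sigma_m2` genetic variance on average.
#'
#' @param panel a [genotype_panel], or a numeric vector of allele
#'   frequencies.
#' @return Scalar in \[0, 0.5\].
#' @export
average_heterozygosity <- function(panel) {
  p <- if (inherits(panel, "genotype_panel")) panel$allele_freqs else panel
  if (length(p) < 1) stop("empty panel")
  mean(2 * p * (1 - p))
}

#' Build a VanRaden method-1 genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum(p_i (1 - p_i)))` where `Z` holds the centred dosages
#' `dosage - 2 p_i` (so homozygotes are `-2p` / `2 - 2p` and heterozygotes
#' `1 - 2p`). Frequencies come from the panel itself, i.e. from all animals
#' of the current run.
#'
#' @param panel a [genotype_panel] with at least 2 animals.
#' @return An object of class `grm`: list with `matrix` (symmetric,
#'   animals x animals), `animal_ids`, and `denominator` (`2 sum p(1-p)`).
#' @export
build_grm <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (length(panel$animal_ids) < 2) stop("need >= 2 animals for a GRM")
  p <- panel$allele_freqs
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all SNPs monomorphic: GRM denominator is 0")
  Z <- sweep(panel$dosages, 2, 2 * p, "-")
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(panel$animal_ids, panel$animal_ids)
  structure(list(matrix = G, animal_ids = panel$animal_ids,
                 denominator = denom),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d animals, denominator 2*sum(p(1-p)) = %.4f, mean diag = %.4f\n",
              length(x$animal_ids), x$denominator, mean(diag(x$matrix))))
  invisible(x)
}

#' Write a GRM as TSV for inspection
#' @param grm a `grm` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grm <- function(grm, path) {
  df <- data.frame(animal_id = grm$animal_ids, grm$matrix, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
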