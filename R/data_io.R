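# Containers and file interfaces for individual-level MR data.

#' Construct an `mrdata` object
#'
#' Bundles an N x p genotype dosage matrix (additive 0/1/2 coding, fractional
#' dosages allowed), a quantitative exposure and a quantitative or binary
#' outcome, with aligned sample identifiers.
#'
#' @param genotypes numeric matrix, samples in rows, SNPs in columns; values
#'   must lie in \[0, 2\] with no missing entries.
#' @param exposure numeric vector of length `nrow(genotypes)`.
#' @param outcome numeric vector of length `nrow(genotypes)`; if
#'   `outcome_binary` it must contain exactly the values 0 and 1.
#' @param sample_ids,snp_ids optional identifier vectors; defaults are taken
#'   from dimnames or generated.
#' @param outcome_binary logical flag; `NULL` (default) auto-detects a 0/1
#'   outcome.
#' @return An object of class `mrdata`.
#' @examples
#' g <- matrix(rbinom(40, 2, 0.3), 20, 2)
#' d <- mr_data(g, exposure = rnorm(20), outcome = rnorm(20))
#' d
#' @export
mr_data <- function(genotypes, exposure, outcome, sample_ids = NULL,
                    snp_ids = NULL, outcome_binary = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  exposure <- as.numeric(exposure)
  outcome <- as.numeric(outcome)
  n <- nrow(genotypes)
  p <- ncol(genotypes)

  if (p < 1L) stop("at least one SNP column is required")
  if (n < 4L) stop("at least 4 samples are required (minimum to split and fit)")
  if (length(exposure) != n || length(outcome) != n) {
    stop(sprintf(
      "genotypes (%d), exposure (%d) and outcome (%d) must share the same sample count",
      n, length(exposure), length(outcome)
    ))
  }
  if (anyNA(genotypes) || anyNA(exposure) || anyNA(outcome)) {
    stop(sprintf(
      "missing values are not allowed: %d in genotypes, %d in exposure, %d in outcome",
      sum(is.na(genotypes)), sum(is.na(exposure)), sum(is.na(outcome))
    ))
  }
  if (is.null(snp_ids)) snp_ids <- colnames(genotypes)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(p))
  if (is.null(sample_ids)) sample_ids <- rownames(genotypes)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  sample_ids <- as.character(sample_ids)
  snp_ids <- as.character(snp_ids)

  bad <- which(genotypes < 0 | genotypes > 2, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "dosage values outside [0, 2] in SNP(s): %s",
      paste(unique(snp_ids[bad[, 2L]]), collapse = ", ")
    ))
  }

  if (is.null(outcome_binary)) {
    outcome_binary <- all(outcome %in% c(0, 1)) && length(unique(outcome)) == 2L
  }
  if (outcome_binary &&
      !(all(outcome %in% c(0, 1)) && length(unique(outcome)) == 2L)) {
    stop("binary outcome must take exactly two values coded 0/1")
  }

  dimnames(genotypes) <- list(sample_ids, snp_ids)
  structure(
    list(
      genotypes = genotypes, exposure = exposure, outcome = outcome,
      outcome_binary = outcome_binary, sample_ids = sample_ids,
      snp_ids = snp_ids
    ),
    class = "mrdata"
  )
}

#' @export
print.mrdata <- function(x, ...) {
  cat(sprintf(
    "<mrdata> %d samples x %d SNPs, %s outcome\n",
    length(x$sample_ids), length(x$snp_ids),
    if (x$outcome_binary) "binary" else "quantitative"
  ))
  invisible(x)
}

#' @export
dim.mrdata <- function(x) dim(x$genotypes)

# Detect the field separator of a delimited text file from its header line.
#' @noRd
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
}

#' @noRd
read_delim_auto <- function(path) {
  read.table(path,
    header = TRUE, sep = detect_sep(path),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

#' Read individual-level MR data from files
#'
#' The genotype file is a delimited dosage matrix: samples in rows, SNPs in
#' columns, first column holding sample identifiers, header holding SNP
#' identifiers; tab or comma separation is auto-detected.  The phenotype file
#' is delimited with a sample-identifier first column and named phenotype
#' columns.  Samples are intersected by identifier and ordered identically.
#' PLINK binary genotypes are not read directly; recode them to an additive
#' dosage matrix first (e.g. `plink --recode A`).
#'
#' @param genotype_path path to the dosage matrix.
#' @param phenotype_path path to the phenotype table.
#' @param exposure_name,outcome_name column names in the phenotype table.
#' @param impute_missing if `TRUE`, missing dosages are replaced by the
#'   per-SNP mean; the default is to reject files with missing dosages.
#' @param outcome_binary see [mr_data()].
#' @return An [mr_data()] object.
#' @export
read_mrdata <- function(genotype_path, phenotype_path, exposure_name,
                        outcome_name, impute_missing = FALSE,
                        outcome_binary = NULL) {
  if (grepl("\\.bed$", genotype_path, ignore.case = TRUE)) {
    stop(
      "PLINK .bed input is not supported directly; export additive dosages ",
      "to a delimited matrix (e.g. 'plink --recode A') and pass that file"
    )
  }
  geno <- read_delim_auto(genotype_path)
  pheno <- read_delim_auto(phenotype_path)
  if (ncol(geno) < 2L) stop("genotype file must have an id column plus >=1 SNP column")
  for (nm in c(exposure_name, outcome_name)) {
    if (!nm %in% names(pheno)) {
      stop(sprintf("column '%s' not found in %s", nm, phenotype_path))
    }
  }

  gid <- as.character(geno[[1L]])
  pid <- as.character(pheno[[1L]])
  common <- intersect(gid, pid)
  if (length(common) == 0L) {
    stop(sprintf(
      "no samples shared between %s and %s", genotype_path, phenotype_path
    ))
  }
  geno <- geno[match(common, gid), , drop = FALSE]
  pheno <- pheno[match(common, pid), , drop = FALSE]

  g <- as.matrix(geno[, -1L, drop = FALSE])
  storage.mode(g) <- "double"
  if (anyNA(g)) {
    if (!impute_missing) {
      counts <- colSums(is.na(g))
      bad <- counts[counts > 0L]
      stop(sprintf(
        "missing dosages present (use impute_missing = TRUE to mean-impute): %s",
        paste(sprintf("%s=%d", names(bad), bad), collapse = ", ")
      ))
    }
    for (j in which(colSums(is.na(g)) > 0L)) {
      g[is.na(g[, j]), j] <- mean(g[, j], na.rm = TRUE)
    }
  }

  mr_data(
    genotypes = g,
    exposure = as.numeric(pheno[[exposure_name]]),
    outcome = as.numeric(pheno[[outcome_name]]),
    sample_ids = common,
    snp_ids = colnames(g),
    outcome_binary = outcome_binary
  )
}

#' Export an `mrdata` object to delimited text files
#'
#' Writes a genotype dosage matrix and a phenotype table in the dialect read
#' by [read_mrdata()]; the round trip is lossless at printed precision.
#'
#' @param data an [mr_data()] object.
#' @param genotype_path,phenotype_path output file paths.
#' @param digits significant digits used when printing numeric values.
#' @return Invisibly, the two paths.
#' @export
export_mrdata <- function(data, genotype_path, phenotype_path, digits = 15) {
  stopifnot(inherits(data, "mrdata"))
  gdf <- data.frame(sample_id = data$sample_ids, check.names = FALSE)
  gdf <- cbind(gdf, as.data.frame(signif(data$genotypes, digits)))
  write.table(gdf, genotype_path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  pdf <- data.frame(
    sample_id = data$sample_ids,
    exposure = signif(data$exposure, digits),
    outcome = signif(data$outcome, digits)
  )
  write.table(pdf, phenotype_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genotype_path, phenotype_path))
}

#' Write multi-split results (or a study table) to delimited text
#'
#' For a [mr_split()] result, writes one row per attempted split (estimate,
#' standard error, p-value, instrument counts, status) followed by a summary
#' row carrying the aggregated estimate and Cauchy-combined p-value.  Plain
#' data frames (e.g. study tables from [run_estimator_study()]) are written
#' as-is.  Output is bit-identical on re-run with the same input.
#'
#' @param result a `multisplit_result` or a data frame.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(result, path) {
  if (is.data.frame(result)) {
    if (nrow(result) == 0L) stop("refusing to write an empty results table")
    write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (!inherits(result, "multisplit_result")) {
    stop("result must be a multisplit_result or a data frame")
  }
  tab <- as.data.frame(result)
  summary_row <- data.frame(
    row_type = "summary", split = NA_integer_,
    estimate = result$beta_aggregated, se = NA_real_,
    pval = result$p_combined, n_major = NA_real_, n_weak = NA_real_,
    status = sprintf("%d/%d splits ok", result$n_success, result$n_splits)
  )
  out <- rbind(cbind(row_type = "split", tab), summary_row)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
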