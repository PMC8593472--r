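#' Read an additive-coded genotype matrix
#'
#' Supports two plain-text layouts: `"plink-raw"`, the PLINK additive
#' recoding (`--recode A`) with header
#' `FID IID PAT MAT SEX PHENOTYPE <snp>_<allele> ...` and genotype values
#' 0/1/2/NA, and `"matrix-tsv"`, a tab/whitespace table whose first column
#' is the sample ID and remaining columns are loci. Missing genotypes are
#' mean-imputed per locus (count reported by the returned object);
#' all-missing loci are dropped with a warning.
#'
#' @param path file path.
#' @param format `"plink-raw"` (default) or `"matrix-tsv"`.
#' @param impute forwarded to [snp_set()].
#' @param drop_monomorphic forwarded to [snp_set()] (default `FALSE` at
#'   ingestion; the test drops monomorphic loci per SNP set).
#' @return a [snp_set()] with an extra `ids` element (sample identifiers,
#'   in file order).
#' @export
read_genotypes <- function(path, format = c("plink-raw", "matrix-tsv"),
                           impute = TRUE, drop_monomorphic = FALSE) {
  format <- match.arg(format)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, check.names = FALSE,
                      na.strings = c("NA", "-9")),
    error = function(e)
      stop("cannot parse genotype file '", path, "': ",
           conditionMessage(e), call. = FALSE))
  if (format == "plink-raw") {
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (ncol(tab) < 7L || !identical(toupper(names(tab)[1:6]), meta))
      stop("'", path, "' does not look like a PLINK .raw file ",
           "(expected header FID IID PAT MAT SEX PHENOTYPE ...)",
           call. = FALSE)
    ids <- as.character(tab$IID)
    G <- as.matrix(tab[, -(1:6), drop = FALSE])
  } else {
    ids <- as.character(tab[[1L]])
    G <- as.matrix(tab[, -1L, drop = FALSE])
  }
  if (!is.numeric(G))
    stop("non-numeric genotype entries in '", path, "'", call. = FALSE)
  bad <- which(!(is.na(G) | (G >= 0 & G <= 2)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("genotype values outside [0, 2] in '", path, "' (first at data row ",
         bad[1L, 1L], ")", call. = FALSE)
  ss <- snp_set(G, impute = impute, drop_monomorphic = drop_monomorphic)
  ss$ids <- ids
  ss
}

#' Write a SNP set in PLINK additive text format
#'
#' Round-trip companion of [read_genotypes()] (format `"plink-raw"`).
#'
#' @param snpset a [snp_set()].
#' @param path output file path.
#' @param ids optional sample identifiers (default `indiv1..n` or the
#'   set's own `ids`).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(snpset, path, ids = NULL) {
  stopifnot(inherits(snpset, "snp_set"))
  ids <- ids %||% snpset$ids %||% paste0("indiv", seq_len(snpset$n))
  tab <- data.frame(FID = ids, IID = ids, PAT = 0L, MAT = 0L, SEX = 0L,
                    PHENOTYPE = -9L, check.names = FALSE)
  G <- snpset$G
  colnames(G) <- snpset$locus_ids
  utils::write.table(cbind(tab, G), path, sep = " ", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table and assemble the null design
#'
#' Expects a delimited table (header required) with a sample-ID column, the
#' phenotype, covariates, and one designated exposure column. Rows with any
#' missing phenotype, covariate, or exposure value are dropped; constant
#' covariates are dropped with a warning.
#'
#' @param path file path.
#' @param pheno_col phenotype column name.
#' @param env_col exposure column name.
#' @param covar_cols covariate column names (default: all remaining
#'   columns except ID, phenotype, exposure).
#' @param id_col sample-ID column name (default `"IID"`).
#' @return list with `ids`, `y`, `X` (covariate matrix or `NULL`), `E`.
#' @export
read_pheno_covar <- function(path, pheno_col = "y", env_col = "E",
                             covar_cols = NULL, id_col = "IID") {
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, check.names = FALSE),
    error = function(e)
      stop("cannot parse phenotype file '", path, "': ",
           conditionMessage(e), call. = FALSE))
  for (col in c(id_col, pheno_col, env_col))
    if (!col %in% names(tab))
      stop("column '", col, "' not found in '", path, "'", call. = FALSE)
  if (is.null(covar_cols))
    covar_cols <- setdiff(names(tab), c(id_col, pheno_col, env_col))
  keep <- stats::complete.cases(tab[, c(pheno_col, env_col, covar_cols),
                                    drop = FALSE])
  if (any(!keep))
    message(sum(!keep), " individual(s) dropped for missing values")
  tab <- tab[keep, , drop = FALSE]
  X <- NULL
  if (length(covar_cols) > 0L) {
    X <- as.matrix(tab[, covar_cols, drop = FALSE])
    const <- apply(X, 2L, function(x) diff(range(x)) == 0)
    if (any(const)) {
      warning("constant covariate(s) dropped: ",
              paste(covar_cols[const], collapse = ", "), call. = FALSE)
      X <- X[, !const, drop = FALSE]
    }
    if (ncol(X) == 0L) X <- NULL
  }
  list(ids = as.character(tab[[id_col]]),
       y = as.numeric(tab[[pheno_col]]),
       X = X,
       E = as.numeric(tab[[env_col]]))
}

#' Write a phenotype/covariate table
#'
#' Round-trip companion of [read_pheno_covar()].
#'
#' @param path output path.
#' @param ids,y,E,X the dataset pieces (covariates `X` optional).
#' @return `path`, invisibly.
#' @export
write_pheno_covar <- function(path, ids, y, E, X = NULL) {
  tab <- data.frame(IID = ids, y = y, check.names = FALSE)
  if (!is.null(X)) {
    X <- as.matrix(X)
    colnames(X) <- colnames(X) %||% paste0("X", seq_len(ncol(X)))
    tab <- cbind(tab, X)
  }
  tab$E <- E
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Align genotype and phenotype data by sample ID
#'
#' Intersects the two ID sets (order-independent) and returns the pieces
#' reordered to a common sample order.
#'
#' @param snpset a [snp_set()] carrying `ids`.
#' @param pheno the list returned by [read_pheno_covar()].
#' @return list with `snpset` (subset, same class), `y`, `E`, `X`, `ids`.
#' @export
align_samples <- function(snpset, pheno) {
  stopifnot(inherits(snpset, "snp_set"), !is.null(snpset$ids))
  common <- intersect(snpset$ids, pheno$ids)
  if (length(common) == 0L)
    stop("no overlapping sample IDs between genotype and phenotype data",
         call. = FALSE)
  common <- sort(common)
  gi <- match(common, snpset$ids)
  pi_ <- match(common, pheno$ids)
  ss <- suppressWarnings(snp_set(snpset$G[gi, , drop = FALSE],
                                 locus_ids = snpset$locus_ids,
                                 drop_monomorphic = FALSE))
  ss$ids <- common
  list(snpset = ss, y = pheno$y[pi_], E = pheno$E[pi_],
       X = if (is.null(pheno$X)) NULL else pheno$X[pi_, , drop = FALSE],
       ids = common)
}

#' Read a gene-range list
#'
#' Whitespace-delimited, four columns per line: chromosome, start, end,
#' gene symbol (the glist convention; coordinates 1-based, both ends
#' inclusive). No header.
#'
#' @param path file path.
#' @return data frame with `chrom`, `start`, `end`, `gene`.
#' @export
read_gene_ranges <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, header = FALSE,
                      col.names = c("chrom", "start", "end", "gene"),
                      colClasses = c("character", "integer", "integer",
                                     "character")),
    error = function(e)
      stop("cannot parse gene-range file '", path, "': ",
           conditionMessage(e), call. = FALSE))
  if (any(tab$start > tab$end))
    stop("gene range with start > end in '", path, "'", call. = FALSE)
  if (any(!nzchar(tab$gene)))
    stop("empty gene symbol in '", path, "'", call. = FALSE)
  tab[order(tab$chrom, tab$start), , drop = FALSE]
}

#' Gene-by-gene GxE scan
#'
#' Maps SNPs to genes by position (1-based, both ends inclusive, matching
#' chromosome), runs the set-based GxE test for every gene containing more
#' than one SNP, and reports the Bonferroni threshold
#' `0.05 / (number of genes tested)` alongside the per-gene results.
#'
#' @param snpset a [snp_set()] with all scanned SNPs.
#' @param positions data frame with columns `snp`, `chrom`, `pos` giving
#'   each locus's coordinates (see [read_snp_map()]).
#' @param ranges gene ranges from [read_gene_ranges()].
#' @param y,E,X phenotype, exposure, optional covariates (aligned to
#'   `snpset` rows).
#' @param ... forwarded to [gxe_test()] (engine, tolerances, ...).
#' @return a `"gxe_scan"`: list with `results` (one row per tested gene:
#'   `gene`, `chrom`, `n`, `L_snps`, `T`, `p_value`, `tau_hat`,
#'   `sigma_hat`, `em_iters`, `em_converged`, `p_method`), `n_tested`,
#'   `bonferroni` (= 0.05 / n_tested), and QC counters (`n_skipped_single`,
#'   `n_empty`).
#' @export
scan_genes <- function(snpset, positions, ranges, y, E, X = NULL, ...) {
  stopifnot(inherits(snpset, "snp_set"))
  req <- c("snp", "chrom", "pos")
  if (!all(req %in% names(positions)))
    stop("'positions' needs columns snp, chrom, pos", call. = FALSE)
  idx <- match(snpset$locus_ids, positions$snp)
  if (anyNA(idx))
    stop(sum(is.na(idx)), " locus(es) missing from 'positions'",
         call. = FALSE)
  chrom <- as.character(positions$chrom)[idx]
  pos <- as.numeric(positions$pos)[idx]
  rows <- vector("list", nrow(ranges))
  n_single <- 0L; n_empty <- 0L
  for (g in seq_len(nrow(ranges))) {
    sel <- which(chrom == ranges$chrom[g] &
                   pos >= ranges$start[g] & pos <= ranges$end[g])
    if (length(sel) == 0L) { n_empty <- n_empty + 1L; next }
    if (length(sel) == 1L) { n_single <- n_single + 1L; next }
    sub <- tryCatch(
      suppressWarnings(snp_set(snpset$G[, sel, drop = FALSE],
                               locus_ids = snpset$locus_ids[sel])),
      error = function(e) NULL)
    if (is.null(sub) || sub$L < 2L) { n_single <- n_single + 1L; next }
    fit <- gxe_test(y, E, sub, X = X, ...)
    rows[[g]] <- data.frame(
      gene = ranges$gene[g], chrom = ranges$chrom[g], n = fit$n,
      L_snps = fit$L, T = fit$T, p_value = fit$p_value,
      tau_hat = fit$vc$tau_hat, sigma_hat = fit$vc$sigma_hat,
      em_iters = fit$vc$n_iter, em_converged = fit$vc$converged,
      p_method = fit$method)
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  n_tested <- if (is.null(results)) 0L else nrow(results)
  if (n_tested == 0L)
    warning("no gene with more than one SNP was tested", call. = FALSE)
  structure(list(results = results, n_tested = n_tested,
                 bonferroni = if (n_tested > 0L) 0.05 / n_tested else NA_real_,
                 n_skipped_single = n_single, n_empty = n_empty),
            class = "gxe_scan")
}

#' Bonferroni threshold for a gene scan
#'
#' @param n_tests number of tests performed.
#' @param alpha family-wise level (default 0.05).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1L) stop("'n_tests' must be >= 1", call. = FALSE)
  alpha / n_tests
}

#' Read a SNP position map
#'
#' PLINK `.map` convention: four whitespace-delimited columns
#' (chromosome, SNP ID, genetic distance, base-pair position), no header.
#'
#' @param path file path.
#' @return data frame with `snp`, `chrom`, `pos`.
#' @export
read_snp_map <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, header = FALSE,
                      col.names = c("chrom", "snp", "cm", "pos"),
                      colClasses = c("character", "character", "numeric",
                                     "integer")),
    error = function(e)
      stop("cannot parse map file '", path, "': ", conditionMessage(e),
           call. = FALSE))
  tab[, c("snp", "chrom", "pos")]
}

#' Write scan results as a tab-delimited table
#'
#' @param scan a `"gxe_scan"` from [scan_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_results <- function(scan, path) {
  stopifnot(inherits(scan, "gxe_scan"))
  utils::write.table(scan$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.gxe_scan <- function(x, ...) {
  cat("Gene-based GxE scan:", x$n_tested, "gene(s) tested",
      "(", x$n_skipped_single, "skipped with <= 1 SNP )\n")
  cat("  Bonferroni threshold:", format(x$bonferroni, digits = 3), "\n")
  if (!is.null(x$results)) {
    top <- x$results[order(x$results$p_value), , drop = FALSE]
    print(utils::head(top, 5L), row.names = FALSE)
  }
  invisible(x)
}
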