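#' Consolidated null-model fixed-effect design
#'
#' Assembles the n x P design `X_tilde = [1 | X | E]` used throughout the
#' test: intercept first, covariates in the middle, the environmental
#' exposure as the last column. The exposure enters the null model as an
#' ordinary fixed effect; it also defines the interaction design
#' `diag(E) %*% G` tested against.
#'
#' @param E numeric exposure vector of length n (continuous or binary).
#' @param X optional numeric matrix (n x p) of covariates, without an
#'   intercept column.
#' @return an object of class `"null_design"`: list with `X_tilde`, `E`,
#'   `n`, `P`.
#' @export
null_design <- function(E, X = NULL) {
  E <- as.numeric(E)
  n <- length(E)
  if (!all(is.finite(E))) stop("'E' contains non-finite values", call. = FALSE)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("'X' and 'E' disagree on n", call. = FALSE)
    if (!all(is.finite(X))) stop("'X' contains non-finite values", call. = FALSE)
    Xt <- cbind(1, X, E)
    colnames(Xt) <- c("(Intercept)",
                      if (is.null(colnames(X))) paste0("X", seq_len(ncol(X)))
                      else colnames(X),
                      "E")
  } else {
    Xt <- cbind(1, E)
    colnames(Xt) <- c("(Intercept)", "E")
  }
  structure(list(X_tilde = Xt, E = E, n = n, P = ncol(Xt)),
            class = "null_design")
}

#' SNP-set genotype container
#'
#' Wraps an n x L additive genotype matrix (minor-allele counts, 0/1/2 for
#' raw data). Missing entries are mean-imputed per locus; monomorphic loci
#' (constant columns, which carry no testable signal and would make the
#' projected design collinear) are dropped with a warning.
#'
#' @param G numeric matrix, n individuals x L loci; `NA` allowed.
#' @param locus_ids optional character vector of L locus identifiers
#'   (defaults to column names, or `snp1..snpL`).
#' @param impute mean-impute missing entries per locus (default `TRUE`;
#'   with `FALSE`, missing entries are an error).
#' @param drop_monomorphic drop constant columns (default `TRUE`).
#' @return an object of class `"snp_set"`: list with `G` (complete numeric
#'   matrix), `maf` (column mean / 2), `locus_ids`, `n`, `L`, and QC
#'   counters `n_imputed`, `n_monomorphic`.
#' @export
snp_set <- function(G, locus_ids = NULL, impute = TRUE,
                    drop_monomorphic = TRUE) {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  if (is.null(locus_ids))
    locus_ids <- colnames(G) %||% paste0("snp", seq_len(ncol(G)))
  if (length(locus_ids) != ncol(G))
    stop("'locus_ids' length must equal ncol(G)", call. = FALSE)
  n_imputed <- 0L
  if (anyNA(G)) {
    if (!impute) stop("'G' contains missing genotypes and impute = FALSE",
                      call. = FALSE)
    all_na <- colSums(!is.na(G)) == 0L
    if (any(all_na)) {
      warning(sum(all_na), " all-missing locus(es) dropped", call. = FALSE)
      G <- G[, !all_na, drop = FALSE]
      locus_ids <- locus_ids[!all_na]
    }
    n_imputed <- sum(is.na(G))
    if (n_imputed > 0L) {
      mu <- colMeans(G, na.rm = TRUE)
      idx <- which(is.na(G), arr.ind = TRUE)
      G[idx] <- mu[idx[, 2L]]
    }
  }
  n_mono <- 0L
  if (drop_monomorphic && ncol(G) > 0L) {
    rng <- apply(G, 2L, function(x) diff(range(x)))
    mono <- rng == 0
    if (any(mono)) {
      n_mono <- sum(mono)
      warning(n_mono, " monomorphic locus(es) dropped: ",
              paste(utils::head(locus_ids[mono], 5L), collapse = ", "),
              if (n_mono > 5L) ", ..." else "", call. = FALSE)
      G <- G[, !mono, drop = FALSE]
      locus_ids <- locus_ids[!mono]
    }
  }
  if (ncol(G) < 1L)
    stop("SNP set is empty after quality control; the test is undefined",
         call. = FALSE)
  if (nrow(G) <= ncol(G))
    warning("n <= L: the test path assumes more individuals than loci",
            call. = FALSE)
  structure(list(G = G, maf = colMeans(G) / 2, locus_ids = locus_ids,
                 n = nrow(G), L = ncol(G),
                 n_imputed = n_imputed, n_monomorphic = n_mono),
            class = "snp_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.snp_set <- function(x, ...) {
  cat("SNP set:", x$n, "individuals x", x$L, "loci\n")
  cat("  MAF range:", format(min(x$maf), digits = 3), "-",
      format(max(x$maf), digits = 3), "\n")
  if (x$n_imputed > 0L) cat("  imputed entries:", x$n_imputed, "\n")
  if (x$n_monomorphic > 0L)
    cat("  monomorphic loci dropped:", x$n_monomorphic, "\n")
  invisible(x)
}
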