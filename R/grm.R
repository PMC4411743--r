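# SNP-derived relationship matrices.
#
# A_g uses the standard GREML estimator: for individuals j, k
#   A_jk = (1/m_jk) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))
# over loci i non-missing in both, with allele frequencies p_i estimated
# in-sample. The same formula is used on the diagonal, so E[A_jj] = 1 under
# Hardy-Weinberg equilibrium.
#
# The interaction matrix keeps A_g where a pair shares the environment and
# zeroes it where it does not (binary/categorical E); for a continuous
# exposure it is the Schur product A_g o z z' with z the standardised
# environment (the random-regression / reaction-norm form).

#' Compute the genetic relationship matrix from genotypes
#'
#' @param geno A [genotype_matrix()].
#' @param maf_min Minimum minor allele frequency; variants below it (and all
#'   monomorphic variants) are excluded before computing relationships.
#' @return A [new_grm()] of kind `"genetic"`, carrying per-pair SNP counts.
#' @export
compute_grm <- function(geno, maf_min = 0.01) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n <- nrow(geno$dosages)
  if (n < 2) stop("need at least 2 samples for a relationship matrix",
                  call. = FALSE)
  X <- geno$dosages
  all_missing <- rowSums(!is.na(X)) == 0
  if (any(all_missing))
    stop("sample(s) with all genotypes missing: ",
         paste(utils::head(geno$samples$iid[all_missing], 5), collapse = ", "),
         call. = FALSE)

  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  keep <- poly & pmin(p, 1 - p) >= maf_min
  if (!any(poly))
    stop("all variants are monomorphic; relationship matrix undefined",
         call. = FALSE)
  if (!any(keep))
    stop("no variants pass the MAF filter (maf_min = ", maf_min, ")",
         call. = FALSE)
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  m <- ncol(X)

  W <- sweep(X, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  has_missing <- anyNA(W)
  if (has_missing) {
    obs <- !is.na(W)
    W[!obs] <- 0
    counts <- tcrossprod(obs * 1)
    if (any(counts == 0))
      stop("pair(s) of individuals share no non-missing variant",
           call. = FALSE)
    A <- tcrossprod(W) / counts
  } else {
    counts <- m
    A <- tcrossprod(W) / m
  }
  new_grm(A, samples = geno$samples, n_snps = counts, kind = "genetic")
}

#' Build the gene-environment interaction relationship matrix
#'
#' For a binary or categorical environment the interaction matrix equals the
#' genetic relationship for pairs of individuals sharing the same
#' environment level and zero for pairs in different levels; the diagonal is
#' always retained (an individual shares its own environment). For a
#' continuous environment the matrix is `A * (z z')` elementwise, with `z`
#' the environment standardised to mean 0 and variance 1.
#'
#' @param grm A genetic [new_grm()].
#' @param env Environment tibble (`fid, iid, value`) as returned by
#'   [read_table_input()] or [simulate_cohort()]; ids must cover every GRM
#'   sample. Missing environment values are an error.
#' @param kind Environment type: `"binary"`, `"categorical"` or
#'   `"continuous"`. Defaults to the tibble's `kind` attribute when present.
#' @return A [new_grm()] of kind `"interaction"`.
#' @export
build_ge_matrix <- function(grm, env, kind = NULL) {
  stopifnot(inherits(grm, "gxe_grm"))
  if (is.null(kind)) kind <- attr(env, "kind")
  if (is.null(kind)) kind <- "binary"
  if (kind == "ordinal") kind <- "categorical"
  kind <- match.arg(kind, c("binary", "categorical", "continuous"))

  idx <- match_samples(env, grm$samples, what = "environment value")
  e <- env$value[idx]
  if (anyNA(e))
    stop("missing environment value for sample(s): ",
         paste(utils::head(grm$samples$iid[is.na(e)], 5), collapse = ", "),
         call. = FALSE)
  if (length(unique(e)) == 1L)
    stop("environment is constant; the interaction matrix would equal the ",
         "genetic relationship matrix", call. = FALSE)

  A <- grm$values
  if (kind == "continuous") {
    z <- drop(scale(e))
    V <- A * tcrossprod(z)
  } else {
    mask <- outer(e, e, "==") * 1
    diag(mask) <- 1
    V <- A * mask
  }
  new_grm(V, samples = grm$samples, n_snps = grm$n_snps, kind = "interaction")
}

# reorder/subset a GRM to the given sample indices
grm_subset <- function(grm, idx) {
  ns <- if (is.matrix(grm$n_snps)) grm$n_snps[idx, idx, drop = FALSE] else
    grm$n_snps
  new_grm(grm$values[idx, idx, drop = FALSE], grm$samples[idx, ], ns,
          kind = grm$kind)
}
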