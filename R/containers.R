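#' Construct a genotype matrix container
#'
#' Bundles an `n x m` allele-dosage matrix (counts of the A1 allele, values
#' 0/1/2 or `NA` for missing) with per-variant and per-sample metadata.
#' This is the in-memory form of a PLINK bed/bim/fam fileset and the input
#' to [compute_grps()] and [compute_grm()].
#'
#' @param dosages Integer/numeric matrix, individuals in rows, variants in
#'   columns; non-missing entries must be 0, 1 or 2.
#' @param variants Data frame with columns `id`, `chr`, `pos`, `a1`, `a2`
#'   (one row per matrix column). Variant ids must be unique.
#' @param samples Data frame with columns `fid`, `iid` (one row per matrix
#'   row).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants` (tibble, with a computed missing-aware `maf`
#'   column) and `samples` (tibble).
#' @examples
#' g <- genotype_matrix(
#'   matrix(c(0, 1, 2, 2), 2, 2),
#'   variants = data.frame(id = c("rs1", "rs2"), chr = "1", pos = c(100, 200),
#'                         a1 = c("A", "C"), a2 = c("G", "T")),
#'   samples = data.frame(fid = c("F1", "F2"), iid = c("I1", "I2"))
#' )
#' g
#' @export
genotype_matrix <- function(dosages, variants, samples) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  variants <- tibble::as_tibble(variants)
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("id", "chr", "pos", "a1", "a2") %in% names(variants)),
            all(c("fid", "iid") %in% names(samples)))
  if (nrow(variants) != ncol(dosages))
    stop("variants table has ", nrow(variants), " rows but dosage matrix has ",
         ncol(dosages), " columns", call. = FALSE)
  if (nrow(samples) != nrow(dosages))
    stop("samples table has ", nrow(samples), " rows but dosage matrix has ",
         nrow(dosages), " rows", call. = FALSE)
  if (anyDuplicated(variants$id))
    stop("duplicate variant id(s): ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "),
         call. = FALSE)
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad))
    stop("dosages must be 0, 1, 2 or NA; found ",
         paste(unique(dosages[bad])[1:min(3, sum(bad))], collapse = ", "),
         call. = FALSE)
  if (any(variants$a1 == variants$a2))
    stop("variant(s) with identical A1 and A2 alleles: ",
         paste(utils::head(variants$id[variants$a1 == variants$a2], 3),
               collapse = ", "), call. = FALSE)
  if (any(variants$pos < 0)) stop("negative base-pair position", call. = FALSE)
  p <- colMeans(dosages, na.rm = TRUE) / 2
  variants$maf <- pmin(p, 1 - p)
  dimnames(dosages) <- list(samples$iid, variants$id)
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosages), " individuals x ",
      ncol(x$dosages), " variants\n", sep = "")
  nm <- sum(is.na(x$dosages))
  cat("  missing dosages: ", nm, " (",
      format(100 * nm / length(x$dosages), digits = 3), "%)\n", sep = "")
  cat("  MAF range: ", paste(format(range(x$variants$maf), digits = 3),
                             collapse = " - "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Construct a relationship matrix container
#'
#' Holds a symmetric `n x n` relationship matrix together with sample ids,
#' the per-pair number of SNPs that entered each element, and a kind tag
#' distinguishing the genetic matrix (`A_g`) from a gene-environment
#' interaction matrix (`A_ge`).
#'
#' @param values Symmetric numeric matrix.
#' @param samples Data frame with columns `fid`, `iid`.
#' @param n_snps Per-pair SNP counts: a single integer (all pairs identical)
#'   or a symmetric integer matrix.
#' @param kind `"genetic"` or `"interaction"`.
#' @return An object of class `gxe_grm`.
#' @export
new_grm <- function(values, samples, n_snps, kind = c("genetic", "interaction")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("fid", "iid") %in% names(samples)))
  n <- nrow(values)
  if (ncol(values) != n) stop("relationship matrix must be square", call. = FALSE)
  if (nrow(samples) != n)
    stop("sample table rows (", nrow(samples), ") do not match matrix order (",
         n, ")", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-8 * max(1, max(abs(values))))
    stop("relationship matrix is not symmetric", call. = FALSE)
  values <- (values + t(values)) / 2
  dimnames(values) <- list(samples$iid, samples$iid)
  if (is.matrix(n_snps)) storage.mode(n_snps) <- "double"
  structure(list(values = values, samples = samples, n_snps = n_snps,
                 kind = kind),
            class = "gxe_grm")
}

#' @export
print.gxe_grm <- function(x, ...) {
  n <- nrow(x$values)
  cat("<gxe_grm> ", x$kind, " relationship matrix, ", n, " x ", n, "\n", sep = "")
  cat("  mean diagonal: ", format(mean(diag(x$values)), digits = 4),
      "; mean off-diagonal: ",
      format(mean(x$values[upper.tri(x$values)]), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
dim.gxe_grm <- function(x) dim(x$values)

# Resolve a FID/IID-keyed table against the sample order of a container.
# Returns integer indices into `samples` for each row of `tab`, erroring on
# ids that do not resolve. Join key is the (FID, IID) pair.
match_samples <- function(tab, samples, what = "record") {
  key <- paste(tab$fid, tab$iid, sep = "\r")
  ref <- paste(samples$fid, samples$iid, sep = "\r")
  idx <- match(ref, key)
  if (anyNA(idx)) {
    miss <- samples[is.na(idx), , drop = FALSE]
    stop("no ", what, " for sample(s): ",
         paste(utils::head(paste(miss$fid, miss$iid), 5), collapse = ", "),
         if (nrow(miss) > 5) " ..." else "", call. = FALSE)
  }
  idx
}
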