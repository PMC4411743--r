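# GCTA binary GRM persistence.
#
# Triplet layout: prefix.grm.bin holds the lower triangle including the
# diagonal as 4-byte little-endian floats, row-major over pairs
# (1,1), (2,1), (2,2), (3,1), ...; prefix.grm.N.bin holds the per-pair SNP
# counts in the same layout; prefix.grm.id holds FID<tab>IID per line.

#' Write a relationship matrix in GCTA binary format
#'
#' @param grm A [new_grm()] object.
#' @param prefix Output path prefix; writes `prefix.grm.bin`,
#'   `prefix.grm.N.bin` and `prefix.grm.id`.
#' @return `prefix`, invisibly.
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "gxe_grm"))
  n <- nrow(grm$values)
  lt <- lower.tri(grm$values, diag = TRUE)
  # row-major over pairs == column-major lower triangle of the transpose;
  # symmetric matrix so t() is a no-op and column order matches pair order
  vals <- t(grm$values)[upper.tri(grm$values, diag = TRUE)]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(vals), con, size = 4, endian = "little")
  close(con)

  nm <- grm$n_snps
  if (!is.matrix(nm)) nm <- matrix(nm, n, n)
  nvals <- t(nm)[upper.tri(nm, diag = TRUE)]
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(nvals), con, size = 4, endian = "little")
  close(con)

  utils::write.table(data.frame(grm$samples$fid, grm$samples$iid),
                     paste0(prefix, ".grm.id"),
                     quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a relationship matrix in GCTA binary format
#'
#' Exact inverse of [write_grm()] up to float32 storage precision.
#'
#' @param prefix Path prefix of the `.grm.bin` / `.grm.N.bin` / `.grm.id`
#'   triplet. `.grm.N.bin` is optional.
#' @param kind Tag for the returned object, `"genetic"` or `"interaction"`.
#' @return A [new_grm()] object.
#' @export
read_grm <- function(prefix, kind = c("genetic", "interaction")) {
  kind <- match.arg(kind)
  idp <- paste0(prefix, ".grm.id")
  binp <- paste0(prefix, ".grm.bin")
  for (p in c(idp, binp))
    if (!file.exists(p)) stop("missing GRM file: ", p, call. = FALSE)
  ids <- utils::read.table(idp, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  n <- nrow(ids)
  npairs <- n * (n + 1) / 2
  con <- file(binp, "rb")
  vals <- readBin(con, "numeric", n = npairs + 1, size = 4, endian = "little")
  close(con)
  if (length(vals) != npairs)
    stop(binp, ": triangle length ", length(vals), " inconsistent with ",
         n, " ids (expected ", npairs, " values)", call. = FALSE)

  A <- matrix(0, n, n)
  A[upper.tri(A, diag = TRUE)] <- vals
  A <- t(A)
  A[upper.tri(A)] <- t(A)[upper.tri(A)]

  np <- paste0(prefix, ".grm.N.bin")
  n_snps <- if (file.exists(np)) {
    con <- file(np, "rb")
    nvals <- readBin(con, "numeric", n = npairs, size = 4, endian = "little")
    close(con)
    N <- matrix(0, n, n)
    N[upper.tri(N, diag = TRUE)] <- nvals
    N <- t(N)
    N[upper.tri(N)] <- t(N)[upper.tri(N)]
    N
  } else NA_real_
  new_grm(A, samples = tibble::tibble(fid = ids[[1]], iid = ids[[2]]),
          n_snps = n_snps, kind = kind)
}
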