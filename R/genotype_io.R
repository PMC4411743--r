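# PLINK 1 binary fileset reader/writer.
#
# .bed layout: magic bytes 0x6c 0x1b, mode byte 0x01 (SNP-major), then
# ceiling(n/4) bytes per variant, four samples per byte, low bits first.
# 2-bit codes follow the PLINK 1.9 convention:
#   00 -> homozygous A1 (dosage 2)   01 -> missing
#   10 -> heterozygous  (dosage 1)   11 -> homozygous A2 (dosage 0)
# Dosages count the A1 allele (.bim column five), matching PLINK --score.

BED_MAGIC <- as.raw(c(0x6c, 0x1b))
BED_CODE_TO_DOSAGE <- c(2, NA, 1, 0)    # index by code + 1
BED_DOSAGE_TO_CODE <- c(3L, 2L, 0L)     # index by dosage + 1; NA handled apart

#' Read a PLINK bed/bim/fam fileset
#'
#' @param prefix Path prefix; `prefix.bed`, `prefix.bim` and `prefix.fam`
#'   must exist. Only SNP-major mode (the PLINK 1.9 default) is supported.
#' @return A [genotype_matrix()].
#' @seealso [write_plink()]
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing PLINK file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(fam) < 2) stop(".fam file needs at least FID and IID columns",
                          call. = FALSE)
  samples <- tibble::tibble(fid = fam[[1]], iid = fam[[2]])

  bim <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "character", "character"))
  variants <- tibble::tibble(id = bim[[2]], chr = bim[[1]], pos = bim[[4]],
                             a1 = bim[[5]], a2 = bim[[6]])

  n <- nrow(samples); m <- nrow(variants)
  bpv <- ceiling(n / 4)
  con <- file(paths[1], "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 3)
  if (length(hdr) < 3 || !identical(hdr[1:2], BED_MAGIC))
    stop(paths[1], ": not a PLINK .bed file (bad magic bytes)", call. = FALSE)
  if (hdr[3] == as.raw(0x00))
    stop(paths[1], ": sample-major .bed files are not supported", call. = FALSE)
  if (hdr[3] != as.raw(0x01))
    stop(paths[1], ": unknown .bed mode byte ", as.integer(hdr[3]),
         call. = FALSE)
  payload <- readBin(con, "raw", n = bpv * m)
  if (length(payload) != bpv * m)
    stop(paths[1], ": truncated (expected ", bpv * m, " data bytes, got ",
         length(payload), ")", call. = FALSE)

  bytes <- matrix(as.integer(payload), nrow = bpv, ncol = m)
  dos <- matrix(NA_real_, n, m)
  for (k in 0:3) {
    if (k + 1 > n) next
    ii <- seq.int(k + 1, n, by = 4)
    code <- bitwAnd(bitwShiftR(bytes[ceiling(ii / 4), , drop = FALSE], 2L * k), 3L)
    dos[ii, ] <- BED_CODE_TO_DOSAGE[code + 1L]
  }
  genotype_matrix(dos, variants, samples)
}

#' Write a PLINK bed/bim/fam fileset
#'
#' Writes SNP-major PLINK 1 binary files; `read_plink()` is its exact
#' inverse (bit-identical .bed on a re-write).
#'
#' @param geno A [genotype_matrix()].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n <- nrow(geno$dosages); m <- ncol(geno$dosages)
  bpv <- ceiling(n / 4)

  v <- geno$variants
  utils::write.table(
    data.frame(v$chr, v$id, 0, v$pos, v$a1, v$a2),
    paste0(prefix, ".bim"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  s <- geno$samples
  utils::write.table(
    data.frame(s$fid, s$iid, 0, 0, 0, -9),
    paste0(prefix, ".fam"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)

  dos <- geno$dosages
  bytes <- matrix(0L, bpv, m)
  for (k in 0:3) {
    if (k + 1 > n) next
    ii <- seq.int(k + 1, n, by = 4)
    d <- dos[ii, , drop = FALSE]
    code <- matrix(1L, nrow(d), m)           # 01 = missing
    ok <- !is.na(d)
    code[ok] <- BED_DOSAGE_TO_CODE[d[ok] + 1L]
    acc <- matrix(0L, bpv, m)
    acc[ceiling(ii / 4), ] <- bitwShiftL(code, 2L * k)
    bytes <- bytes + acc
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(BED_MAGIC, as.raw(0x01), as.raw(bytes)), con)
  invisible(prefix)
}

#' Read a delimited analysis table
#'
#' One reader for the whitespace/tab-delimited text inputs of the toolkit:
#' * `sumstats` - header row with columns `SNP`, `A1`, `A2` and `BETA` (or
#'   `OR`, log-transformed on input); returns discovery effect sizes.
#' * `phenotype` / `environment` - headerless `FID IID VALUE` rows; `NA`
#'   values are kept and flagged missing. Environments carry a declared
#'   `kind` (binary values must be 0/1).
#' * `partition` - columns `SNP` or `SNP PARTITION`, no header; returns
#'   variant-id sets for per-partition risk scores.
#'
#' The discovery summary-statistics layout is a convention of this package:
#' any table with those four columns (extra columns ignored) is accepted.
#'
#' @param path File path.
#' @param schema One of `"sumstats"`, `"phenotype"`, `"environment"`,
#'   `"partition"`.
#' @param kind For `environment`: declared type, one of `"binary"`,
#'   `"ordinal"`, `"continuous"`.
#' @return A tibble. Sumstats: `id, a1, a2, beta`. Phenotype/environment:
#'   `fid, iid, value` plus attributes `kind`. Partition: `id, partition`.
#' @export
read_table_input <- function(path,
                             schema = c("sumstats", "phenotype",
                                        "environment", "partition"),
                             kind = c("continuous", "binary", "ordinal")) {
  schema <- match.arg(schema)
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop(path, ": empty file", call. = FALSE)

  if (schema == "sumstats") {
    tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    if (length(tab) == 0 || nrow(tab) == 0) stop(path, ": empty file", call. = FALSE)
    names(tab) <- toupper(names(tab))
    need <- c("SNP", "A1", "A2")
    if (!all(need %in% names(tab)))
      stop(path, ": sumstats table needs columns SNP, A1, A2 and BETA or OR",
           call. = FALSE)
    if ("BETA" %in% names(tab)) {
      beta <- as.numeric(tab$BETA)
    } else if ("OR" %in% names(tab)) {
      or <- as.numeric(tab$OR)
      if (any(or <= 0, na.rm = TRUE))
        stop(path, ": OR column must be positive", call. = FALSE)
      beta <- log(or)
    } else {
      stop(path, ": sumstats table needs a BETA or OR column", call. = FALSE)
    }
    dup <- unique(tab$SNP[duplicated(tab$SNP)])
    if (length(dup))
      stop(path, ": duplicate variant id(s) in sumstats: ",
           paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
    bad <- which(!is.finite(beta))
    if (length(bad))
      stop(path, ": non-finite effect size at line(s) ",
           paste(utils::head(bad + 1, 5), collapse = ", "), call. = FALSE)
    return(tibble::tibble(id = as.character(tab$SNP),
                          a1 = toupper(as.character(tab$A1)),
                          a2 = toupper(as.character(tab$A2)),
                          beta = beta))
  }

  if (schema == "partition") {
    tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
    part <- if (ncol(tab) >= 2) tab[[2]] else "all"
    return(tibble::tibble(id = tab[[1]], partition = part))
  }

  # phenotype / environment: FID IID VALUE
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = character())
  if (ncol(tab) < 3)
    stop(path, ": expected FID IID VALUE rows", call. = FALSE)
  value <- suppressWarnings(as.numeric(tab[[3]]))
  not_na <- !(tab[[3]] %in% c("NA", "na", ".", "-9"))
  unparseable <- which(is.na(value) & not_na)
  if (length(unparseable))
    stop(path, ": unparseable value at line(s) ",
         paste(utils::head(unparseable, 5), collapse = ", "), call. = FALSE)
  value[!not_na] <- NA_real_
  out <- tibble::tibble(fid = tab[[1]], iid = tab[[2]], value = value)
  if (schema == "environment") {
    if (kind == "binary" && !all(value[!is.na(value)] %in% c(0, 1)))
      stop(path, ": environment declared binary but contains value(s) ",
           paste(utils::head(setdiff(unique(value[!is.na(value)]), c(0, 1)), 3),
                 collapse = ", "), call. = FALSE)
    attr(out, "kind") <- kind
  } else {
    attr(out, "kind") <- if (all(value[!is.na(value)] %in% c(0, 1)))
      "binary" else "continuous"
  }
  out
}
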