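# Genomic risk profile scores (GRPS).
#
# Two-step construction: discovery-sample effect sizes are matched to the
# target genotypes allele-by-allele, then each individual's score is the
# effect-weighted count of risk alleles averaged over the loci available
# for that individual.

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Match discovery effect alleles to target variant alleles
#'
#' For each variant id shared between the target genotypes and the
#' discovery summary statistics, resolves which target allele carries the
#' discovery effect: a direct match (effect allele is A1), a flip (effect
#' allele is A2, so the effect is negated to apply to the A1 dosage), a
#' strand-resolved match through base complements, or an exclusion
#' (incompatible alleles, or a strand-ambiguous A/T / C/G variant when
#' `drop_ambiguous` is set).
#'
#' @param geno Target [genotype_matrix()].
#' @param sumstats Discovery effects tibble (`id, a1, a2, beta`), `a1` the
#'   effect allele.
#' @param drop_ambiguous Exclude strand-ambiguous palindromic variants
#'   (default `TRUE`).
#' @return A tibble `id, beta_a1, action` of usable variants (`beta_a1` is
#'   the weight to apply to the A1 dosage), with an exclusion/match count
#'   report in attribute `"report"`.
#' @export
match_alleles <- function(geno, sumstats, drop_ambiguous = TRUE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (nrow(sumstats) == 0) stop("empty summary statistics", call. = FALSE)
  v <- geno$variants
  idx <- match(v$id, sumstats$id)
  shared <- which(!is.na(idx))
  ss <- sumstats[idx[shared], ]
  va1 <- toupper(v$a1[shared]); va2 <- toupper(v$a2[shared])
  ea <- toupper(ss$a1); oa <- toupper(ss$a2)

  ambiguous <- va2 == unname(COMPLEMENT[va1]) & !is.na(COMPLEMENT[va1])
  direct <- ea == va1 & oa == va2
  flip <- ea == va2 & oa == va1
  cea <- unname(COMPLEMENT[ea]); coa <- unname(COMPLEMENT[oa])
  strand_direct <- !direct & !flip & !is.na(cea) & cea == va1 & coa == va2
  strand_flip <- !direct & !flip & !is.na(cea) & cea == va2 & coa == va1

  action <- rep("mismatch", length(shared))
  action[direct] <- "direct"
  action[flip] <- "flip"
  action[strand_direct] <- "strand_direct"
  action[strand_flip] <- "strand_flip"
  if (drop_ambiguous) action[ambiguous] <- "ambiguous"

  used <- action %in% c("direct", "flip", "strand_direct", "strand_flip")
  beta <- ss$beta
  beta[action %in% c("flip", "strand_flip")] <-
    -beta[action %in% c("flip", "strand_flip")]

  report <- tibble::tibble(
    category = c("direct", "flip", "strand_direct", "strand_flip",
                 "ambiguous", "mismatch", "not_in_target"),
    n = c(sum(action == "direct"), sum(action == "flip"),
          sum(action == "strand_direct"), sum(action == "strand_flip"),
          sum(action == "ambiguous"), sum(action == "mismatch"),
          nrow(sumstats) - length(shared)))
  if (!any(used))
    stop("no variants could be matched between target and discovery ",
         "summary statistics", call. = FALSE)
  out <- tibble::tibble(id = v$id[shared][used], beta_a1 = beta[used],
                        action = action[used])
  attr(out, "report") <- report
  out
}

#' Compute genomic risk profile scores
#'
#' For each individual, the score is the sum of A1-dosage-weighted matched
#' effects over the loci with a non-missing genotype, divided by the number
#' of such loci (per-individual averaging). Scores can be computed within
#' SNP partitions (e.g. functional annotation or position classes) to give
#' one genetic term per partition in downstream interaction models.
#'
#' @param geno Target [genotype_matrix()].
#' @param matched Matched effects from [match_alleles()].
#' @param partitions Optional partition tibble (`id, partition`) from
#'   [read_table_input()]; default is a single partition `"all"` holding
#'   every matched variant.
#' @param standardize Also emit a z-standardised score column (default
#'   `TRUE`).
#' @param impute_missing Replace missing dosages by the variant mean dosage
#'   instead of dropping the locus for that individual (default `FALSE`).
#' @param discovery_ids Optional tibble (`fid, iid`) of discovery-sample
#'   ids; overlap with the target triggers a warning, because scoring
#'   individuals present in the discovery sample inflates association.
#' @return A tibble of class `grps_scores`: `fid, iid, partition, score,
#'   score_std, n_loci`.
#' @export
compute_grps <- function(geno, matched, partitions = NULL,
                         standardize = TRUE, impute_missing = FALSE,
                         discovery_ids = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (nrow(matched) == 0) stop("empty matched-effects table", call. = FALSE)
  if (!is.null(discovery_ids)) {
    ov <- intersect(paste(geno$samples$fid, geno$samples$iid),
                    paste(discovery_ids$fid, discovery_ids$iid))
    if (length(ov))
      warning(length(ov), " target individual(s) also appear in the ",
              "discovery sample; their scores overfit the discovery ",
              "weights and inflate association", call. = FALSE)
  }
  absent <- setdiff(matched$id, geno$variants$id)
  if (length(absent))
    stop("matched effect(s) reference variant(s) absent from the genotypes: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  if (is.null(partitions))
    partitions <- tibble::tibble(id = matched$id, partition = "all")
  unknown <- setdiff(partitions$id, matched$id)
  if (length(unknown) == nrow(partitions))
    stop("no partition variant is present in the matched effects",
         call. = FALSE)

  X <- geno$dosages
  if (impute_missing && anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    nas <- which(is.na(X), arr.ind = TRUE)
    X[nas] <- mu[nas[, 2]]
  }

  res <- lapply(split(partitions$id, partitions$partition), function(ids) {
    sel <- matched$id %in% ids
    if (!any(sel)) return(NULL)
    cols <- match(matched$id[sel], colnames(X))
    w <- matched$beta_a1[sel]
    Xp <- X[, cols, drop = FALSE]
    obs <- !is.na(Xp)
    Xp[!obs] <- 0
    num <- unname(drop(Xp %*% w))
    nloci <- unname(rowSums(obs))
    score <- ifelse(nloci > 0, num / nloci, NA_real_)
    list(score = score, n_loci = nloci)
  })
  res <- res[!vapply(res, is.null, TRUE)]

  out <- dplyr::bind_rows(lapply(names(res), function(pn) {
    sc <- res[[pn]]$score
    if (anyNA(sc))
      warning(sum(is.na(sc)), " individual(s) with zero non-missing loci ",
              "in partition '", pn, "'; score set missing", call. = FALSE)
    tibble::tibble(fid = geno$samples$fid, iid = geno$samples$iid,
                   partition = pn, score = sc,
                   score_std = if (standardize) drop(scale(sc)) else NA_real_,
                   n_loci = res[[pn]]$n_loci)
  }))
  class(out) <- c("grps_scores", class(out))
  out
}
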