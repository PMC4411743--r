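# Synthetic cohorts with known polygenic G, GxE and residual architecture.
#
# Generative model (liability scale):
#   y = g + ge + e_main*E + eps
# with g = Z beta (Z the column-standardised dosages) scaled to var sigma2_g,
# ge the interaction genetic value scaled to var sigma2_ge, eps gaussian
# scaled to sigma2_e. Binary traits threshold the liability at the quantile
# implied by the configured prevalence.
#
# Interaction architecture, binary/categorical E: the interaction genetic
# value is drawn independently per environment level (gamma^(k) per level),
# so cov(ge_i, ge_j) = sigma2_ge * A_ij for same-environment pairs and 0
# otherwise -- exactly the masked interaction relationship matrix the GREML
# model fits. For continuous E, ge = (Z gamma) * z_E with z_E standardised,
# matching A_ge = A o z z'. The "amplification" switch sets gamma
# proportional to beta (a pure scale effect, removable by transformation).

#' Simulate hard-call genotypes under Hardy-Weinberg equilibrium
#'
#' Variants are independent (no linkage disequilibrium); per-variant allele
#' frequencies are drawn uniformly in `maf_range` and dosages are the sum of
#' two independent allele draws.
#'
#' @param n Number of individuals.
#' @param m Number of variants.
#' @param maf_range Length-2 numeric in (0, 0.5], frequency range of the A1
#'   allele.
#' @param id_prefix Prefix for generated FID/IID values (`"<prefix>1"`, ...).
#' @param seed Optional integer seed (local to this call).
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5),
                               id_prefix = "per", seed = NULL) {
  stopifnot(n >= 1, m >= 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  p <- stats::runif(m, maf_range[1], maf_range[2])
  dos <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
  ids <- paste0(id_prefix, seq_len(n))
  genotype_matrix(
    dos,
    variants = tibble::tibble(id = paste0("snp", seq_len(m)), chr = "1",
                              pos = seq_len(m) * 1000, a1 = "A", a2 = "G"),
    samples = tibble::tibble(fid = ids, iid = ids))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# standardise dosage columns; monomorphic columns map to 0
standardise_dosages <- function(dos) {
  if (anyNA(dos)) {
    nobs <- colSums(!is.na(dos))
    mu <- colMeans(dos, na.rm = TRUE)
    ss <- colSums(dos^2, na.rm = TRUE) - nobs * mu^2
    sdv <- sqrt(ss / pmax(nobs - 1, 1))
  } else {
    n <- nrow(dos)
    mu <- colMeans(dos)
    sdv <- sqrt((colSums(dos^2) - n * mu^2) / (n - 1))
  }
  sdv[sdv == 0 | is.na(sdv)] <- Inf
  Z <- sweep(dos, 2, mu, "-")
  Z[is.na(Z)] <- 0
  sweep(Z, 2, sdv, "/")
}

# scale a vector to have exactly the target variance (0 -> zero vector);
# returns the scaled vector with the multiplier as attribute
scale_to_var <- function(x, v) {
  if (v == 0) return(structure(rep(0, length(x)), mult = 0))
  s <- stats::sd(x)
  if (s == 0) stop("cannot scale a constant component to positive variance",
                   call. = FALSE)
  structure(x * sqrt(v) / s, mult = sqrt(v) / s)
}

#' Simulate a cohort with known G, GxE and residual variance
#'
#' Forward simulation from the polygenic gene-environment interaction model:
#' every variant is causal with a normal effect on the standardised-dosage
#' scale, and each simulated component (genetic, interaction, residual) is
#' rescaled to hit its configured variance exactly in-sample, so estimator
#' bias can be measured against known truth.
#'
#' @param n,m,maf_range,seed As [simulate_genotypes()].
#' @param sigma2_g,sigma2_ge,sigma2_e Target variances of the genetic,
#'   interaction and residual components (liability/phenotype scale).
#' @param env Environment kind: `"binary"` or `"continuous"`.
#' @param env_prevalence Exposure probability for binary environments.
#' @param env_beta Fixed main effect of the environment on the phenotype
#'   (default 0; the random-effects model has no fixed environment term).
#' @param trait `"quantitative"` (liability observed directly) or
#'   `"binary"` (liability thresholded).
#' @param prevalence Disease prevalence for binary traits: the liability
#'   threshold is the `1 - prevalence` quantile of the population liability
#'   distribution.
#' @param interaction `"independent"` draws interaction effects independent
#'   of the main effects (per environment level for binary E);
#'   `"amplification"` makes the interaction value proportional to the
#'   genetic value (a pure scale effect).
#' @param case_fraction Optional ascertained case fraction for binary
#'   traits: controls are subsampled (cases all kept when possible) until
#'   cases make up this fraction of the returned cohort.
#' @param id_prefix FID/IID prefix; use distinct prefixes for discovery and
#'   target cohorts so the no-overlap rule is checkable.
#' @return An object of class `gxe_cohort`: list with `genotypes`
#'   ([genotype_matrix()]), `phenotype` and `environment` tibbles
#'   (`fid, iid, value`), `liability`, and `truth` (true effect sizes,
#'   per-component values and realised variances).
#' @export
simulate_cohort <- function(n, m, maf_range = c(0.05, 0.5),
                            sigma2_g = 0.3, sigma2_ge = 0.2, sigma2_e = 0.5,
                            env = c("binary", "continuous"),
                            env_prevalence = 0.5, env_beta = 0,
                            trait = c("quantitative", "binary"),
                            prevalence = 0.1,
                            interaction = c("independent", "amplification"),
                            case_fraction = NULL,
                            id_prefix = "per", seed = NULL) {
  env <- match.arg(env)
  trait <- match.arg(trait)
  interaction <- match.arg(interaction)
  stopifnot(sigma2_g >= 0, sigma2_ge >= 0, sigma2_e >= 0,
            env_prevalence > 0, env_prevalence < 1,
            prevalence > 0, prevalence < 1)
  total_var <- sigma2_g + sigma2_ge + sigma2_e
  if (total_var <= 0)
    stop("at least one variance component must be positive", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }

  geno <- simulate_genotypes(n, m, maf_range, id_prefix = id_prefix)
  Z <- standardise_dosages(geno$dosages)

  e <- if (env == "binary") stats::rbinom(n, 1L, env_prevalence) else
    stats::rnorm(n)
  if (env == "binary" && length(unique(e)) == 1L)
    e[1] <- 1L - e[1]  # guard degenerate tiny-n draws

  # main genetic component
  beta <- stats::rnorm(m)
  g_raw <- drop(Z %*% beta)
  g <- scale_to_var(g_raw, sigma2_g)
  beta <- beta * attr(g, "mult")

  # interaction component
  if (sigma2_ge > 0) {
    if (interaction == "amplification") {
      ef <- if (env == "binary") e - mean(e) else drop(scale(e))
      ge_raw <- g_raw * ef
      ge <- scale_to_var(ge_raw, sigma2_ge)
      gamma <- matrix(beta / attr(g, "mult") * attr(ge, "mult"), m, 1,
                      dimnames = list(NULL, "amplification"))
    } else if (env == "binary") {
      gamma <- matrix(stats::rnorm(2 * m), m, 2,
                      dimnames = list(NULL, c("env0", "env1")))
      U <- Z %*% gamma
      ge_raw <- ifelse(e == 1, U[, 2], U[, 1])
      ge <- scale_to_var(ge_raw, sigma2_ge)
      gamma <- gamma * attr(ge, "mult")
    } else {
      gamma <- matrix(stats::rnorm(m), m, 1, dimnames = list(NULL, "slope"))
      ze <- drop(scale(e))
      ge_raw <- drop(Z %*% gamma) * ze
      ge <- scale_to_var(ge_raw, sigma2_ge)
      gamma <- gamma * attr(ge, "mult")
    }
  } else {
    ge <- rep(0, n)
    gamma <- matrix(0, m, 1)
  }

  eps <- scale_to_var(stats::rnorm(n), sigma2_e)
  liability <- as.numeric(g) + as.numeric(ge) + as.numeric(eps) + env_beta * e

  if (trait == "binary") {
    thr <- stats::qnorm(1 - prevalence, mean = env_beta * mean(e),
                        sd = sqrt(total_var))
    y <- as.numeric(liability > thr)
  } else {
    thr <- NA_real_
    y <- liability
  }

  ids <- geno$samples
  keep <- seq_len(n)
  if (trait == "binary" && !is.null(case_fraction)) {
    stopifnot(case_fraction > 0, case_fraction < 1)
    cases <- which(y == 1); controls <- which(y == 0)
    n_ctrl <- min(length(controls),
                  round(length(cases) * (1 - case_fraction) / case_fraction))
    keep <- sort(c(cases, sample(controls, n_ctrl)))
    geno <- genotype_matrix(geno$dosages[keep, , drop = FALSE],
                            geno$variants[, c("id", "chr", "pos", "a1", "a2")],
                            ids[keep, ])
  }

  structure(list(
    genotypes = geno,
    phenotype = tibble::tibble(fid = ids$fid[keep], iid = ids$iid[keep],
                               value = y[keep]),
    environment = structure(
      tibble::tibble(fid = ids$fid[keep], iid = ids$iid[keep],
                     value = as.numeric(e)[keep]),
      kind = if (env == "binary") "binary" else "continuous"),
    liability = liability[keep],
    truth = list(
      beta = beta, gamma = gamma,
      g = as.numeric(g)[keep], ge = as.numeric(ge)[keep],
      eps = as.numeric(eps)[keep],
      sigma2 = c(g = sigma2_g, ge = sigma2_ge, e = sigma2_e),
      realised = c(g = stats::var(as.numeric(g)[keep]),
                   ge = stats::var(as.numeric(ge)[keep]),
                   e = stats::var(as.numeric(eps)[keep])),
      env_kind = env, env_beta = env_beta, trait = trait,
      prevalence = prevalence, threshold = thr,
      maf_range = maf_range, interaction = interaction)),
    class = "gxe_cohort")
}

#' @export
print.gxe_cohort <- function(x, ...) {
  cat("<gxe_cohort> ", nrow(x$phenotype), " individuals, ",
      ncol(x$genotypes$dosages), " variants (", x$truth$trait, " trait, ",
      x$truth$env_kind, " environment)\n", sep = "")
  cat("  target variances (g, ge, e): ",
      paste(format(x$truth$sigma2, digits = 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulate an independent discovery GWAS and return summary statistics
#'
#' Draws a fresh cohort sharing the target cohort's true per-variant effect
#' sizes, runs a marginal (one SNP at a time) regression of the discovery
#' phenotype on each dosage, and returns the estimated effects as a
#' discovery summary-statistics table keyed by the A1 allele. This is the
#' two-sample setting risk profiling requires: discovery weights estimated
#' in a sample disjoint from the target.
#'
#' @param cohort Target `gxe_cohort` (supplies true effects, variant
#'   metadata and the configuration to replicate).
#' @param n_discovery Discovery sample size.
#' @param id_prefix FID/IID prefix for the discovery cohort; must not
#'   collide with the target's ids (enforced).
#' @param seed Optional integer seed.
#' @return A tibble with columns `id, a1, a2, beta` (the `sumstats` schema
#'   of [read_table_input()]), with the discovery cohort attached as
#'   attribute `"cohort"`.
#' @export
simulate_discovery <- function(cohort, n_discovery, id_prefix = "disc",
                               seed = NULL) {
  stopifnot(inherits(cohort, "gxe_cohort"), n_discovery >= 3)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  tr <- cohort$truth
  m <- length(tr$beta)
  disc_geno <- simulate_genotypes(n_discovery, m, tr$maf_range,
                                  id_prefix = id_prefix)
  overlap <- intersect(paste(disc_geno$samples$fid, disc_geno$samples$iid),
                       paste(cohort$genotypes$samples$fid,
                             cohort$genotypes$samples$iid))
  if (length(overlap))
    stop("discovery sample overlaps the target sample (",
         length(overlap), " shared id(s), e.g. ", overlap[1],
         "); discovery weights must come from a disjoint sample",
         call. = FALSE)

  Z <- standardise_dosages(disc_geno$dosages)
  g <- drop(Z %*% tr$beta)
  e <- if (tr$env_kind == "binary")
    stats::rbinom(n_discovery, 1L, 0.5) else stats::rnorm(n_discovery)
  ge <- if (tr$sigma2["ge"] > 0) {
    if (ncol(tr$gamma) == 2 && tr$env_kind == "binary") {
      U <- Z %*% tr$gamma
      ifelse(e == 1, U[, 2], U[, 1])
    } else if (tr$env_kind == "binary") {
      drop(Z %*% tr$gamma[, 1]) * (e - mean(e))
    } else {
      drop(Z %*% tr$gamma[, 1]) * drop(scale(e))
    }
  } else 0
  y <- g + ge + stats::rnorm(n_discovery, sd = sqrt(tr$sigma2["e"])) +
    tr$env_beta * e
  if (tr$trait == "binary") y <- as.numeric(y > tr$threshold)

  # marginal per-SNP regression of y on dosage: beta_j = cov(y, x_j)/var(x_j)
  X <- disc_geno$dosages
  xc <- sweep(X, 2, colMeans(X))
  vx <- colSums(xc^2)
  vx[vx == 0] <- Inf
  beta_hat <- as.numeric(crossprod(xc, y - mean(y)) / vx)

  v <- disc_geno$variants
  out <- tibble::tibble(id = v$id, a1 = v$a1, a2 = v$a2, beta = beta_hat)
  attr(out, "cohort") <- structure(
    list(genotypes = disc_geno,
         phenotype = tibble::tibble(fid = disc_geno$samples$fid,
                                    iid = disc_geno$samples$iid, value = y),
         environment = structure(
           tibble::tibble(fid = disc_geno$samples$fid,
                          iid = disc_geno$samples$iid, value = as.numeric(e)),
           kind = tr$env_kind),
         liability = NULL, truth = tr),
    class = "gxe_cohort")
  out
}
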