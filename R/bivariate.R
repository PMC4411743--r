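# Bivariate (two-environment) GREML.
#
# The trait measured under each of two environment levels is treated as a
# separate trait; each individual is observed in exactly one environment, so
# the stacked covariance is
#   V = v_g1 B11 + v_g2 B22 + c_g12 B12 + v_e1 E1 + v_e2 E2
# where B11/B22 are the within-group blocks of the genetic relationship
# matrix, B12 its cross-group block, and E1/E2 group-diagonal residuals
# (no residual cross-covariance: the groups are disjoint individuals).
# The cross-environment genetic correlation is r_g = c_g12 / (s_g1 s_g2);
# r_g significantly below 1 indicates gene-environment interaction, and the
# constrained r_g = 1 fit uses the nonlinear coefficient map
# (v1, v2, e1, e2) -> (v1, v2, sqrt(v1 v2), e1, e2).

#' Fit the bivariate two-environment genetic model
#'
#' Fits the free model, the `r_g = 1` constrained model (the G-by-E null)
#' and the `r_g = 0` constrained model by AI-REML, and reports the genetic
#' correlation with likelihood-ratio tests against both constraints. The
#' `r_g = 1` test is the primary gene-environment interaction criterion;
#' it is unaffected by different trait scales or ascertainment in the two
#' environments, which is why it is preferred over comparing per-environment
#' heritabilities for disease traits.
#'
#' @param pheno Phenotype tibble (`fid, iid, value`).
#' @param env Binary environment tibble (`fid, iid, value`), exactly two
#'   observed levels; each individual belongs to one group.
#' @param grm Genetic [new_grm()] over all individuals (both groups).
#' @param covariates Optional covariate tibble (`fid, iid`, numeric columns).
#' @param min_group Minimum group size (default 50).
#' @param tol,max_iter Passed to the AI-REML engine.
#' @return An object of class `gxe_bivar`: `components` tibble, `rg`,
#'   `rg_se`, `loglik` tibble (model, loglik, converged), `lrt` tibble
#'   (tests against `r_g = 1` and `r_g = 0`), `n` per group.
#' @export
fit_bivariate <- function(pheno, env, grm, covariates = NULL,
                          min_group = 50L, tol = 1e-8, max_iter = 200L) {
  stopifnot(inherits(grm, "gxe_grm"))
  samples <- grm$samples
  e <- env$value[match_samples(env, samples, "environment value")]
  y <- pheno$value[match_samples(pheno, samples, "phenotype")]
  keep <- !is.na(e) & !is.na(y)
  idx <- which(keep)
  e <- e[idx]; y <- y[idx]
  A <- grm$values[idx, idx, drop = FALSE]
  samples <- samples[idx, ]

  lev <- sort(unique(e))
  if (length(lev) < 2)
    stop("environment has a single level; the bivariate model needs two ",
         "groups", call. = FALSE)
  if (length(lev) > 2)
    stop("bivariate model requires a binary environment; found ",
         length(lev), " levels", call. = FALSE)
  i1 <- e == lev[1]; i2 <- !i1
  if (sum(i1) < min_group || sum(i2) < min_group)
    stop("environment group sizes (", sum(i1), ", ", sum(i2),
         ") below the minimum of ", min_group, call. = FALSE)

  n <- length(y)
  d1 <- as.numeric(i1); d2 <- as.numeric(i2)
  M11 <- tcrossprod(d1); M22 <- tcrossprod(d2)
  B11 <- A * M11
  B22 <- A * M22
  B12 <- A * (1 - M11 - M22)
  E1 <- diag(d1); E2 <- diag(d2)
  structures <- list(g1 = B11, g2 = B22, g12 = B12, e1 = E1, e2 = E2)

  X <- cbind(mu1 = d1, mu2 = d2)
  if (!is.null(covariates)) {
    ci <- match_samples(covariates, samples, "covariate row")
    cv <- as.matrix(covariates[ci, setdiff(names(covariates), c("fid", "iid")),
                               drop = FALSE])
    X <- cbind(X, cv)
    cc <- stats::complete.cases(cv)
    if (!all(cc)) stop("missing covariate values for ", sum(!cc),
                       " individual(s)", call. = FALSE)
  }

  v1 <- stats::var(y[i1]); v2 <- stats::var(y[i2])
  init_free <- c(v1 / 2, v2 / 2, 0.25 * sqrt(v1 * v2), v1 / 2, v2 / 2)
  lower_free <- c(0, 0, -Inf, 0, 0)
  free <- ai_reml(y, X, structures, init = init_free, lower = lower_free,
                  tol = tol, max_iter = max_iter)

  map_rg1 <- list(
    q = 4L,
    coef = function(th) c(th[1], th[2], sqrt(th[1] * th[2]), th[3], th[4]),
    jac = function(th) {
      J <- matrix(0, 5, 4)
      J[1, 1] <- 1; J[2, 2] <- 1
      J[3, 1] <- 0.5 * sqrt(th[2] / th[1])
      J[3, 2] <- 0.5 * sqrt(th[1] / th[2])
      J[4, 3] <- 1; J[5, 4] <- 1
      J
    })
  # constrained fits warm-start from the free optimum (same maximum,
  # fewer iterations)
  init_c <- pmax(free$theta[-3], 1e-4 * stats::var(y))
  rg1 <- ai_reml(y, X, structures, init = init_c, par_map = map_rg1,
                 tol = tol, max_iter = max_iter)
  rg0 <- ai_reml(y, X, structures[-3], init = init_c, tol = tol,
                 max_iter = max_iter)

  th <- free$theta
  bnd <- free$at_boundary
  rg <- rg_se <- NA_real_
  if (!bnd[1] && !bnd[2]) {
    rg <- th[3] / sqrt(th[1] * th[2])
    rg <- max(-1, min(1, rg))
    Cov <- tryCatch(solve(free$AI), error = function(e) NULL)
    if (!is.null(Cov)) {
      gr <- c(-rg / (2 * th[1]), -rg / (2 * th[2]), 1 / sqrt(th[1] * th[2]))
      rg_se <- sqrt(max(0, drop(t(gr) %*% Cov[1:3, 1:3] %*% gr)))
    }
  } else {
    warning("genetic variance estimate at the zero boundary in ",
            "environment group ", paste(which(bnd[1:2]), collapse = " and "),
            "; genetic correlation undefined", call. = FALSE)
  }

  ll <- tibble::tibble(
    model = c("free", "rg1", "rg0"),
    loglik = c(free$loglik, rg1$loglik, rg0$loglik),
    converged = c(free$converged, rg1$converged, rg0$converged))
  lrt <- dplyr::bind_rows(
    dplyr::mutate(lrt_component(free, rg1, df = 1L, boundary = FALSE),
                  test = "rg_eq_1", .before = 1),
    dplyr::mutate(lrt_component(free, rg0, df = 1L, boundary = FALSE),
                  test = "rg_eq_0", .before = 1))

  comp <- tibble::tibble(
    component = c("g1", "g2", "g12", "e1", "e2"),
    estimate = th, se = free$se, at_boundary = bnd)
  h2 <- c(th[1] / (th[1] + th[4]), th[2] / (th[2] + th[5]))

  structure(list(
    components = comp, rg = rg, rg_se = rg_se, h2 = h2,
    loglik = ll, lrt = lrt,
    n = c(sum(i1), sum(i2)), levels = lev,
    fits = list(free = free, rg1 = rg1, rg0 = rg0)),
    class = "gxe_bivar")
}

#' @export
print.gxe_bivar <- function(x, ...) {
  cat("<gxe_bivar> n = (", paste(x$n, collapse = ", "), "), r_g = ",
      format(x$rg, digits = 4), " (SE ", format(x$rg_se, digits = 3), ")\n",
      sep = "")
  cat("  per-environment variance ratio: ",
      paste(format(x$h2, digits = 3), collapse = ", "), "\n", sep = "")
  print(x$lrt)
  invisible(x)
}
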