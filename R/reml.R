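# Restricted maximum likelihood for variance-component models
#   y = X b + sum_c u_c + eps,  u_c ~ N(0, sigma2_c A_c),  eps ~ N(0, sigma2_e I)
#
# Estimation is average-information (AI) REML with step-halving and an EM
# fallback when the AI proposal is not an ascent direction, variance
# components constrained non-negative by an active floor. The engine also
# accepts a nonlinear parametrisation (coefficients of the covariance
# structures as a smooth function of the parameters) which the bivariate
# genetic-correlation constraint r_g = 1 needs.

#' Assemble a variance-component model
#'
#' Aligns phenotype, optional environment main effect and covariates to the
#' sample order of the supplied relationship matrices and builds the fixed-
#' effects design. When an interaction matrix is fitted, always pass `env`:
#' the environment main effect then enters as a fixed effect, keeping it out
#' of the interaction variance component.
#'
#' @param pheno Phenotype tibble (`fid, iid, value`).
#' @param grms Named list of [new_grm()] objects (e.g.
#'   `list(g = a_g, ge = a_ge)`); all must share the same sample set. A
#'   residual identity component is always appended.
#' @param env Optional environment tibble; its value is added to the fixed
#'   effects.
#' @param covariates Optional tibble (`fid, iid`, then numeric columns) of
#'   additional fixed covariates.
#' @return An object of class `vc_model` with elements `y`, `X`,
#'   `structures` (named covariance matrices including `residual`),
#'   `samples`.
#' @export
vc_model <- function(pheno, grms, env = NULL, covariates = NULL) {
  stopifnot(is.list(grms), length(grms) >= 1,
            all(vapply(grms, inherits, TRUE, "gxe_grm")))
  if (is.null(names(grms)) || any(names(grms) == ""))
    names(grms) <- paste0("K", seq_along(grms))
  samples <- grms[[1]]$samples
  for (g in grms[-1])
    if (!identical(paste(g$samples$fid, g$samples$iid),
                   paste(samples$fid, samples$iid)))
      stop("relationship matrices have different sample sets/orders",
           call. = FALSE)

  y <- pheno$value[match_samples(pheno, samples, "phenotype")]
  keep <- !is.na(y)
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(env)) {
    e <- env$value[match_samples(env, samples, "environment value")]
    X <- cbind(X, env = e)
    keep <- keep & !is.na(e)
  }
  if (!is.null(covariates)) {
    ci <- match_samples(covariates, samples, "covariate row")
    cv <- as.matrix(covariates[ci, setdiff(names(covariates), c("fid", "iid")),
                               drop = FALSE])
    X <- cbind(X, cv)
    keep <- keep & stats::complete.cases(cv)
  }
  if (!all(keep)) {
    idx <- which(keep)
    y <- y[idx]; X <- X[idx, , drop = FALSE]
    grms <- lapply(grms, grm_subset, idx = idx)
    samples <- samples[idx, ]
  }
  if (qr(X)$rank < ncol(X))
    stop("fixed-effects design is rank deficient", call. = FALSE)
  structures <- c(lapply(grms, function(g) g$values),
                  list(residual = diag(length(y))))
  # aliasing guard: a component proportional to the identity duplicates the
  # residual and the pair is unidentifiable
  for (nm in names(structures)[-length(structures)]) {
    S <- structures[[nm]]
    offd <- S[upper.tri(S)]
    if (max(abs(offd)) < 1e-12 && stats::sd(diag(S)) < 1e-12 &&
        mean(diag(S)) > 1e-12)
      stop("component '", nm, "' is proportional to the identity and ",
           "cannot be separated from the residual variance", call. = FALSE)
  }
  structure(list(y = y, X = X, structures = structures, samples = samples),
            class = "vc_model")
}

#' Restricted log-likelihood of a variance-component model
#'
#' Evaluates
#' \eqn{-\tfrac12[(n-p)\log 2\pi + \log|V| + \log|X'V^{-1}X| + y'Py]}
#' at the supplied component values, with
#' \eqn{V = \sum_c \sigma^2_c A_c + \sigma^2_e I}.
#'
#' @param model A [vc_model()].
#' @param components Numeric vector of variance components, one per
#'   structure (residual last), or named to match the structure names.
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(model, components) {
  stopifnot(inherits(model, "vc_model"))
  k <- length(model$structures)
  if (length(components) != k)
    stop("expected ", k, " components (", paste(names(model$structures),
         collapse = ", "), ")", call. = FALSE)
  if (!is.null(names(components)) && all(names(model$structures) %in%
                                         names(components)))
    components <- components[names(model$structures)]
  ll <- reml_eval(model$y, model$X, model$structures, components)
  if (is.null(ll))
    stop("V is singular or not positive definite at the evaluated point ",
         "(smallest eigenvalue ",
         format(min(eigen(Reduce(`+`, Map(`*`, model$structures,
                                          components)),
                          symmetric = TRUE, only.values = TRUE)$values),
                digits = 3), ")", call. = FALSE)
  ll$ll
}

# One dense REML evaluation. Returns NULL if V is not PD, else a list with
# the log-likelihood and the pieces AI-REML reuses (P, Py).
reml_eval <- function(y, X, structures, coefs) {
  V <- Reduce(`+`, Map(`*`, structures, coefs))
  C <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(C)) return(NULL)
  n <- length(y); p <- ncol(X)
  Vi <- chol2inv(C)
  logdetV <- 2 * sum(log(diag(C)))
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  Cx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(Cx)) return(NULL)
  logdetX <- 2 * sum(log(diag(Cx)))
  P <- Vi - ViX %*% chol2inv(Cx) %*% t(ViX)
  Py <- drop(P %*% y)
  yPy <- sum(y * Py)
  ll <- -0.5 * ((n - p) * log(2 * pi) + logdetV + logdetX + yPy)
  list(ll = ll, P = P, Py = Py)
}

# Average-information REML. par_map: NULL for the identity parametrisation
# (one non-negative variance per structure), else list(coef = function(theta)
# -> structure coefficients, jac = function(theta) -> length(structures) x
# length(theta) Jacobian). lower: per-parameter lower bounds (on theta).
ai_reml <- function(y, X, structures, init = NULL, par_map = NULL,
                    lower = NULL, tol = 1e-8, max_iter = 200L) {
  k <- length(structures)
  vp <- stats::var(y)
  if (is.null(par_map)) {
    q <- k
    coef_fun <- identity
    jac_fun <- function(theta) diag(q)
  } else {
    coef_fun <- par_map$coef
    jac_fun <- par_map$jac
    q <- par_map$q
  }
  if (is.null(init)) init <- rep(vp / k, q)
  floor_v <- 1e-6 * vp
  if (is.null(lower)) lower <- rep(floor_v, q)
  lower[is.finite(lower) & lower == 0] <- floor_v

  clamp <- function(th) pmax(th, lower)
  theta <- clamp(init)
  ev <- reml_eval(y, X, structures, coef_fun(theta))
  if (is.null(ev)) {
    theta <- rep(vp / k, q)
    ev <- reml_eval(y, X, structures, coef_fun(theta))
    if (is.null(ev)) stop("could not find a positive-definite starting point",
                          call. = FALSE)
  }
  trace <- list()
  converged <- FALSE
  n <- length(y)
  grad <- rep(NA_real_, q); AI <- matrix(NA_real_, q, q)

  for (it in seq_len(max_iter)) {
    J <- jac_fun(theta)
    # derivative matrices dV/dtheta_j and AI/gradient pieces
    W <- matrix(0, n, q)     # Vdot_j %*% Py
    trPV <- numeric(q)
    for (j in seq_len(q)) {
      nzero <- which(abs(J[, j]) > 0)
      Vd_Py <- numeric(n); tr <- 0
      for (c in nzero) {
        Vd_Py <- Vd_Py + J[c, j] * drop(structures[[c]] %*% ev$Py)
        tr <- tr + J[c, j] * sum(ev$P * structures[[c]])
      }
      W[, j] <- Vd_Py
      trPV[j] <- tr
    }
    PW <- ev$P %*% W
    grad <- -0.5 * (trPV - colSums(W * ev$Py))
    AI <- 0.5 * crossprod(W, PW)
    trace[[it]] <- c(iter = it, ll = ev$ll, stats::setNames(theta,
                     paste0("theta", seq_len(q))))

    # active set: parameters pinned at their floor with the likelihood
    # pushing further down stay put this iteration
    at_floor <- theta <= lower * (1 + 1e-8)
    free <- !(at_floor & grad < 0)
    delta <- numeric(q)
    if (any(free)) {
      Af <- AI[free, free, drop = FALSE]
      delta[free] <- tryCatch(
        drop(solve(Af + diag(1e-10 * max(diag(Af)), sum(free)), grad[free])),
        error = function(e) grad[free] * pmax(theta[free], vp / q)^2 * 2 / n)
    }

    step <- 1
    improved <- FALSE
    full_step <- FALSE
    for (h in 1:12) {
      cand <- clamp(theta + step * delta)
      ev2 <- reml_eval(y, X, structures, coef_fun(cand))
      if (!is.null(ev2) && ev2$ll >= ev$ll - 1e-12) {
        improved <- TRUE
        full_step <- h == 1
        break
      }
      step <- step / 2
    }
    if (!improved) {
      # EM-style rescue (monotone for the identity parametrisation); if even
      # this cannot move the likelihood the optimum is reached to machine
      # precision
      cand <- clamp(theta + theta^2 * ifelse(free, grad, 0) * 2 / n)
      ev2 <- reml_eval(y, X, structures, coef_fun(cand))
      if (is.null(ev2) || ev2$ll < ev$ll + 1e-12) {
        converged <- TRUE
        break
      }
    }
    ll_old <- ev$ll
    theta <- cand
    ev <- ev2
    if (abs(ev$ll - ll_old) < tol * max(1, abs(ev$ll)) &&
        (full_step || abs(ev$ll - ll_old) < 1e-12 * max(1, abs(ev$ll)))) {
      converged <- TRUE
      break
    }
  }
  if (!converged && it >= max_iter)
    stop("AI-REML failed to converge in ", max_iter, " iterations; ",
         "last log-likelihoods: ",
         paste(format(utils::tail(vapply(trace, `[[`, 0, "ll"), 3),
                      digits = 10), collapse = ", "), call. = FALSE)

  se <- tryCatch(sqrt(diag(solve(AI))), error = function(e) rep(NA_real_, q))
  list(theta = theta, coefs = coef_fun(theta), se = se, AI = AI,
       loglik = ev$ll, gradient = grad, converged = converged,
       at_boundary = theta <= lower * (1 + 1e-6),
       trace = dplyr::bind_rows(lapply(trace, function(r)
         tibble::as_tibble(as.list(r)))),
       n = n)
}

#' Fit a univariate variance-component model by AI-REML
#'
#' Estimates the genetic, interaction and residual variances of
#' `y = Xb + g + ge + eps` (or any set of supplied relationship matrices)
#' with average-information REML, components constrained non-negative, and
#' standard errors from the inverse average-information matrix. Binary
#' disease phenotypes are analysed on the observed 0/1 scale.
#'
#' @param model A [vc_model()].
#' @param constrain Keep components non-negative (default). `FALSE` allows
#'   negative component estimates, useful for constructing unconstrained
#'   likelihood-ratio tests.
#' @param init Optional numeric vector of starting values, one per
#'   component; defaults to an equal split of the phenotypic variance.
#'   Starting values do not change the optimum, only the iteration count.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap; non-convergence is an error carrying the
#'   iteration trace.
#' @return An object of class `vc_fit`: `components` tibble (component,
#'   estimate, se, proportion, prop_se, at_boundary), `loglik`, `converged`,
#'   `trace`, `AI`, `n`, and the model.
#' @export
fit_univariate <- function(model, constrain = TRUE, tol = 1e-8,
                           max_iter = 200L, init = NULL) {
  stopifnot(inherits(model, "vc_model"))
  k <- length(model$structures)
  n <- length(model$y)
  if (n < k + ncol(model$X) + 10)
    stop("sample size (", n, ") too small for ", k, " variance components",
         call. = FALSE)
  lower <- if (constrain) NULL else rep(-Inf, k)
  res <- ai_reml(model$y, model$X, model$structures, init = init,
                 lower = lower, tol = tol, max_iter = max_iter)
  est <- res$theta
  tot <- sum(est)
  prop <- est / tot
  # delta-method SEs of the proportions from the AI covariance
  Cov <- tryCatch(solve(res$AI), error = function(e)
    matrix(NA_real_, k, k))
  prop_se <- vapply(seq_len(k), function(j) {
    gr <- -est[j] / tot^2 + ifelse(seq_len(k) == j, 1 / tot, 0)
    sqrt(max(0, drop(t(gr) %*% Cov %*% gr)))
  }, 0)
  structure(list(
    components = tibble::tibble(
      component = names(model$structures),
      estimate = est, se = res$se,
      proportion = prop, prop_se = prop_se,
      at_boundary = res$at_boundary),
    loglik = res$loglik, converged = res$converged, trace = res$trace,
    AI = res$AI, n = n, model = model, constrained = constrain),
    class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("<vc_fit> AI-REML, n = ", x$n, ", logL = ",
      format(x$loglik, digits = 8), "\n", sep = "")
  print(x$components)
  invisible(x)
}

#' Likelihood-ratio test between nested variance-component fits
#'
#' Statistic `2 (logL_full - logL_reduced)`, floored at zero. With
#' `boundary = TRUE` (the default, appropriate when a single variance
#' component is dropped and its null value lies on the boundary of the
#' parameter space) the reference distribution is the equal mixture
#' `0.5 chi^2_0 + 0.5 chi^2_1`; otherwise a chi-square with `df` degrees of
#' freedom.
#'
#' @param full,reduced `vc_fit` objects (or anything with `$loglik`);
#'   `reduced` must be nested in `full`.
#' @param df Degrees of freedom (parameters dropped); default 1.
#' @param boundary Use the boundary mixture null (default `TRUE`).
#' @return A one-row tibble: `statistic, df, p_value, boundary`.
#' @export
lrt_component <- function(full, reduced, df = 1L, boundary = TRUE) {
  llf <- full$loglik; llr <- reduced$loglik
  if (llr > llf + 1e-4 * max(1, abs(llf)))
    stop("reduced-model log-likelihood (", format(llr, digits = 10),
         ") exceeds the full model's (", format(llf, digits = 10),
         "); a fit has not converged", call. = FALSE)
  stat <- max(0, 2 * (llf - llr))
  p <- if (boundary && df == 1L) {
    0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE) +
      0.5 * (stat <= 0)
  } else {
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  tibble::tibble(statistic = stat, df = as.integer(df), p_value = p,
                 boundary = boundary && df == 1L)
}

#' Transform a phenotype to probe scale effects
#'
#' Interaction variance that disappears after a monotone transformation of
#' the phenotype is a scale effect rather than biological G-by-E; refitting
#' the model on a transformed phenotype and comparing the interaction
#' estimates side by side is the standard check.
#'
#' @param pheno Phenotype tibble (`fid, iid, value`).
#' @param method `"none"`, `"rank-inverse-normal"` (Blom offsets, ties
#'   averaged) or `"log"` (requires positive values).
#' @return The tibble with `value` transformed.
#' @export
transform_phenotype <- function(pheno,
                                method = c("none", "rank-inverse-normal",
                                           "log")) {
  method <- match.arg(method)
  y <- pheno$value
  ok <- !is.na(y)
  if (method == "log") {
    if (any(y[ok] <= 0))
      stop("log transform requires positive phenotype values", call. = FALSE)
    y[ok] <- log(y[ok])
  } else if (method == "rank-inverse-normal") {
    r <- rank(y[ok], ties.method = "average")
    y[ok] <- stats::qnorm((r - 3 / 8) / (sum(ok) + 1 / 4))
  }
  out <- pheno
  out$value <- y
  out
}
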