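# Risk-profiling interaction tests.
#
# The nested model sequence for a disease trait is
#   logit P(Y=1) = b0 + covariates                         (M0)
#                + b_E E                                   (M1)
#                + sum_p b_Gp G_p                          (M2)
#                + sum_p b_GEp (G_p x E)                   (M3)
# with one genetic and one interaction term per score partition; each step
# is tested against the previous by a likelihood-ratio test with degrees of
# freedom equal to the columns added. Significant G and E main effects
# already imply interaction on the observed disease scale; the product-term
# test addresses interaction on the underlying liability. Quantitative
# phenotypes use the analogous linear-model nesting with F tests.

#' Fit the nested GRPS-environment interaction models
#'
#' @param pheno Phenotype tibble (`fid, iid, value`); binary 0/1 values give
#'   logistic fits, anything else linear fits.
#' @param scores [compute_grps()] output (long tibble; one genetic term per
#'   partition).
#' @param env Environment tibble (`fid, iid, value`).
#' @param covariates Optional covariate tibble (`fid, iid`, numeric
#'   columns), always retained in every model.
#' @param use_std Build genetic and interaction terms from the standardised
#'   score column (default `TRUE`; the likelihood-ratio tests are invariant
#'   to this affine choice).
#' @return An object of class `gxe_profile`: `comparisons` tibble (term
#'   added, LRT/F statistic, df, p-value, Nagelkerke R-squared increment for
#'   logistic fits, Bonferroni-adjusted p for the interaction step),
#'   `coefficients` tibble of the full model, `loglik` per model, `n`,
#'   `family`, `firth` flag.
#' @export
fit_nested_models <- function(pheno, scores, env, covariates = NULL,
                              use_std = TRUE) {
  score_col <- if (use_std && !all(is.na(scores$score_std)))
    "score_std" else "score"
  wide <- tidyr::pivot_wider(
    dplyr::select(scores, "fid", "iid", "partition",
                  dplyr::all_of(c(value = score_col))),
    names_from = "partition", values_from = "value")
  parts <- setdiff(names(wide), c("fid", "iid"))

  dat <- dplyr::inner_join(wide, dplyr::rename(pheno, .y = "value"),
                           by = c("fid", "iid"))
  dat <- dplyr::inner_join(dat, dplyr::rename(env, .e = "value"),
                           by = c("fid", "iid"))
  if (!is.null(covariates))
    dat <- dplyr::inner_join(dat, covariates, by = c("fid", "iid"))
  dat <- dat[stats::complete.cases(dat), ]
  n <- nrow(dat)
  if (n < 10) stop("fewer than 10 complete cases", call. = FALSE)

  y <- dat$.y
  if (length(unique(y)) < 2) stop("phenotype is constant", call. = FALSE)
  e <- dat$.e
  if (length(unique(e)) < 2)
    stop("environment is constant; interaction model undefined",
         call. = FALSE)
  G <- as.matrix(dat[parts])
  const <- apply(G, 2, function(x) stats::sd(x) == 0)
  if (any(const))
    stop("constant score column(s): ", paste(parts[const], collapse = ", "),
         "; genetic and interaction terms inestimable", call. = FALSE)
  GE <- G * e
  colnames(G) <- paste0("grps_", parts)
  colnames(GE) <- paste0("grps_", parts, "_x_env")
  cv <- if (!is.null(covariates))
    as.matrix(dat[setdiff(names(covariates), c("fid", "iid"))]) else NULL

  binary <- all(y %in% c(0, 1))
  ones <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  designs <- list(
    base = cbind(ones, cv),
    env = cbind(ones, cv, env = e),
    grps = cbind(ones, cv, env = e, G),
    interaction = cbind(ones, cv, env = e, G, GE))
  n_par <- vapply(designs, ncol, 0L)
  if (n < 10 * n_par[["interaction"]])
    warning("complete cases (", n, ") fewer than 10 x ",
            n_par[["interaction"]], " model parameters", call. = FALSE)

  firth_used <- FALSE
  if (binary) {
    fits <- lapply(designs, function(d) fit_logistic(y, d))
    firth_used <- any(vapply(fits, `[[`, TRUE, "firth"))
    ll <- vapply(fits, `[[`, 0, "loglik")
    ll0 <- fit_logistic(y, ones)$loglik   # intercept-only, for Nagelkerke
    r2max <- 1 - exp(2 * ll0 / n)
    r2 <- (1 - exp(-2 * (ll - ll0) / n)) / r2max
    comparisons <- tibble::tibble(
      term = c("env", "grps", "grps_x_env"),
      statistic = pmax(0, 2 * diff(ll)),
      df = as.integer(diff(n_par)),
      p_value = stats::pchisq(pmax(0, 2 * diff(ll)), diff(n_par),
                              lower.tail = FALSE),
      r2_nagelkerke_increment = diff(r2))
  } else {
    fits <- lapply(designs, function(d) fit_gaussian(y, d))
    ll <- vapply(fits, `[[`, 0, "loglik")
    rss <- vapply(fits, `[[`, 0, "rss")
    df1 <- diff(n_par)
    df2 <- n - n_par[-1]
    fstat <- (-diff(rss) / df1) / (rss[-1] / df2)
    comparisons <- tibble::tibble(
      term = c("env", "grps", "grps_x_env"),
      statistic = fstat,
      df = as.integer(df1),
      df_resid = as.integer(df2),
      p_value = stats::pf(fstat, df1, df2, lower.tail = FALSE))
  }
  k_ge <- ncol(GE)
  comparisons$p_bonferroni <- ifelse(
    comparisons$term == "grps_x_env",
    pmin(1, comparisons$p_value * k_ge), NA_real_)

  structure(list(
    comparisons = comparisons,
    coefficients = fits$interaction$coefficients,
    loglik = tibble::tibble(model = names(designs), loglik = ll,
                            n_par = as.integer(n_par)),
    n = n, family = if (binary) "binomial" else "gaussian",
    firth = firth_used, partitions = parts),
    class = "gxe_profile")
}

#' @export
print.gxe_profile <- function(x, ...) {
  cat("<gxe_profile> ", x$family, " nested models, n = ", x$n,
      if (x$firth) " (Firth-penalised)" else "", "\n", sep = "")
  print(x$comparisons)
  invisible(x)
}

# Least-squares fit (design already includes the intercept column).
fit_gaussian <- function(y, X) {
  f <- stats::lm.fit(X, y)
  rss <- sum(f$residuals^2)
  n <- length(y)
  sigma2 <- rss / f$df.residual
  XtXi <- chol2inv(qr.R(f$qr))
  se <- sqrt(diag(XtXi) * sigma2)
  tstat <- f$coefficients / se
  list(coefficients = tibble::tibble(
    term = colnames(X), estimate = f$coefficients, std_error = se,
    statistic = tstat,
    p_value = 2 * stats::pt(-abs(tstat), f$df.residual)),
    loglik = -n / 2 * (log(2 * pi * rss / n) + 1),
    rss = rss)
}

# Logistic ML fit via glm.fit (iteratively reweighted least squares with
# step-halving), with a Firth-penalised fallback when separation is
# detected (fitted probabilities pinned at 0/1 or non-convergence).
fit_logistic <- function(y, X) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!sep && fit$converged) {
    mu <- fit$fitted.values
    w <- mu * (1 - mu)
    I <- crossprod(X * sqrt(w))
    se <- sqrt(diag(solve(I)))
    z <- fit$coefficients / se
    return(list(
      coefficients = tibble::tibble(
        term = colnames(X), estimate = fit$coefficients, std_error = se,
        statistic = z, p_value = 2 * stats::pnorm(-abs(z))),
      loglik = -fit$deviance / 2, firth = FALSE, converged = TRUE))
  }
  warning("separation detected; falling back to Firth-penalised logistic ",
          "regression", call. = FALSE)
  firth_logistic(y, X)
}

# Firth (1993) bias-reduced logistic regression: score adjusted by the hat
# values, penalised log-likelihood ll + 0.5 log|X'WX|.
firth_logistic <- function(y, X, max_iter = 100, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    I <- crossprod(X * sqrt(w))
    Ii <- solve(I)
    h <- rowSums((X %*% Ii) * (X * w))
    U <- drop(t(X) %*% (y - mu + h * (0.5 - mu)))
    delta <- drop(Ii %*% U)
    if (max(abs(delta)) > 5) delta <- delta * 5 / max(abs(delta))
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  I <- crossprod(X * sqrt(w))
  ll <- sum(y * eta - log1p(exp(eta))) +
    0.5 * as.numeric(determinant(I)$modulus)
  se <- sqrt(diag(solve(I)))
  z <- beta / se
  list(coefficients = tibble::tibble(
    term = colnames(X), estimate = beta, std_error = se, statistic = z,
    p_value = 2 * stats::pnorm(-abs(z))),
    loglik = ll, firth = TRUE, converged = TRUE)
}

#' Decile odds-ratio risk stratification
#'
#' Ranks individuals on a risk score, splits them into near-equal deciles
#' (ties broken by input order, so the split is deterministic) and reports
#' the odds of disease in each decile relative to the first, with Woolf
#' confidence intervals. Large top-versus-bottom decile odds ratios are the
#' standard display of polygenic risk stratification.
#'
#' @param pheno Binary phenotype tibble (`fid, iid, value`).
#' @param scores [compute_grps()] output or any tibble with `fid, iid,
#'   score` (optionally `partition`).
#' @param partition Partition to use when `scores` holds several (default:
#'   first).
#' @param n_groups Number of quantile groups (default 10).
#' @param conf_level Confidence level for the Woolf intervals.
#' @return A tibble of class `gxe_deciles`: `decile, n, cases, controls,
#'   odds, odds_ratio, ci_lower, ci_upper, degenerate` (flag for zero
#'   cells, where the odds ratio is 0 or infinite).
#' @export
decile_odds_ratios <- function(pheno, scores, partition = NULL,
                               n_groups = 10L, conf_level = 0.95) {
  if ("partition" %in% names(scores)) {
    if (is.null(partition)) partition <- scores$partition[1]
    scores <- scores[scores$partition == partition, ]
  }
  dat <- dplyr::inner_join(dplyr::rename(pheno, .y = "value"),
                           scores[c("fid", "iid", "score")],
                           by = c("fid", "iid"))
  dat <- dat[!is.na(dat$.y) & !is.na(dat$score), ]
  n <- nrow(dat)
  if (n < n_groups) stop("need at least ", n_groups, " individuals",
                         call. = FALSE)
  if (!all(dat$.y %in% c(0, 1)))
    stop("decile odds ratios require a binary 0/1 phenotype", call. = FALSE)

  ord <- order(dat$score, seq_len(n))
  sizes <- diff(round(seq(0, n, length.out = n_groups + 1)))
  grp <- integer(n)
  grp[ord] <- rep(seq_len(n_groups), sizes)

  tab <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(decile = grp, y = dat$.y), .data$decile),
    n = dplyr::n(), cases = sum(.data$y), controls = sum(1 - .data$y),
    .groups = "drop")
  tab$odds <- tab$cases / tab$controls
  a1 <- tab$cases[1]; b1 <- tab$controls[1]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  or <- tab$odds / tab$odds[1]
  se_log <- sqrt(1 / tab$cases + 1 / tab$controls + 1 / a1 + 1 / b1)
  degenerate <- tab$cases == 0 | tab$controls == 0 | a1 == 0 | b1 == 0
  out <- tibble::tibble(
    decile = tab$decile, n = tab$n, cases = tab$cases,
    controls = tab$controls, odds = tab$odds,
    odds_ratio = or,
    ci_lower = ifelse(degenerate, NA_real_, exp(log(or) - z * se_log)),
    ci_upper = ifelse(degenerate, NA_real_, exp(log(or) + z * se_log)),
    degenerate = degenerate)
  class(out) <- c("gxe_deciles", class(out))
  out
}
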