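# broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the full-model coefficients of a profile fit
#'
#' @param x A `gxe_profile` from [fit_nested_models()].
#' @param ... Unused.
#' @return Tibble of full-model coefficient estimates, standard errors and
#'   Wald p-values.
#' @method tidy gxe_profile
#' @export
tidy.gxe_profile <- function(x, ...) x$coefficients

#' One-row summary of a profile fit
#'
#' @param x A `gxe_profile`.
#' @param ... Unused.
#' @return Tibble with n, family, full-model log-likelihood and the
#'   interaction-step LRT.
#' @method glance gxe_profile
#' @export
glance.gxe_profile <- function(x, ...) {
  ge <- x$comparisons[x$comparisons$term == "grps_x_env", ]
  tibble::tibble(
    n = x$n, family = x$family,
    loglik_full = x$loglik$loglik[x$loglik$model == "interaction"],
    statistic_gxe = ge$statistic, p_value_gxe = ge$p_value,
    firth = x$firth)
}

#' Tidy variance-component estimates
#'
#' @param x A `vc_fit` from [fit_univariate()].
#' @param ... Unused.
#' @return The component tibble (estimate, SE, proportion of total
#'   variance, boundary flag).
#' @method tidy vc_fit
#' @export
tidy.vc_fit <- function(x, ...) x$components

#' One-row summary of a variance-component fit
#'
#' @param x A `vc_fit`.
#' @param ... Unused.
#' @return Tibble with n, REML log-likelihood, convergence flag and number
#'   of iterations.
#' @method glance vc_fit
#' @export
glance.vc_fit <- function(x, ...) {
  tibble::tibble(n = x$n, loglik = x$loglik, converged = x$converged,
                 iterations = nrow(x$trace))
}

#' Tidy bivariate model estimates
#'
#' @param x A `gxe_bivar` from [fit_bivariate()].
#' @param ... Unused.
#' @return Component tibble with the genetic correlation appended.
#' @method tidy gxe_bivar
#' @export
tidy.gxe_bivar <- function(x, ...) {
  dplyr::bind_rows(
    x$components,
    tibble::tibble(component = "rg", estimate = x$rg, se = x$rg_se,
                   at_boundary = FALSE))
}

#' One-row summary of a bivariate fit
#'
#' @param x A `gxe_bivar`.
#' @param ... Unused.
#' @return Tibble with group sizes, genetic correlation and the two
#'   constraint tests.
#' @method glance gxe_bivar
#' @export
glance.gxe_bivar <- function(x, ...) {
  tibble::tibble(
    n1 = x$n[1], n2 = x$n[2], rg = x$rg, rg_se = x$rg_se,
    loglik_free = x$loglik$loglik[1],
    p_rg_eq_1 = x$lrt$p_value[x$lrt$test == "rg_eq_1"],
    p_rg_eq_0 = x$lrt$p_value[x$lrt$test == "rg_eq_0"])
}
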