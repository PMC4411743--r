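# small ready-made variance-component fixture
reml_fixture <- function(n, m = 300, s2 = c(0.3, 0.2, 0.5), seed = 1) {
  coh <- simulate_cohort(n = n, m = m, sigma2_g = s2[1], sigma2_ge = s2[2],
                         sigma2_e = s2[3], seed = seed)
  A <- compute_grm(coh$genotypes)
  ge <- build_ge_matrix(A, coh$environment)
  model <- vc_model(coh$phenotype, list(g = A, ge = ge),
                    env = coh$environment)
  list(coh = coh, A = A, ge = ge, model = model)
}

test_that("restricted log-likelihood matches an independent dense oracle", {
  fx <- reml_fixture(50, seed = 41)
  for (comps in list(c(0.3, 0.2, 0.5), c(1, 0.01, 0.4), c(0.05, 0.9, 0.2))) {
    expect_equal(reml_loglik(fx$model, comps),
                 dense_reml_ll(fx$model$y, fx$model$X, fx$model$structures,
                               comps),
                 tolerance = 1e-8)
  }
})

test_that("log-likelihood is flat in the weight of a zero structure", {
  fx <- reml_fixture(40, seed = 42)
  zero <- new_grm(matrix(0, 40, 40), fx$A$samples, n_snps = 0,
                  kind = "genetic")
  m0 <- vc_model(fx$coh$phenotype, list(null = zero))
  expect_equal(reml_loglik(m0, c(0.1, 0.8)), reml_loglik(m0, c(5, 0.8)))
})

test_that("REML is invariant to phenotype translation, scales as c^2", {
  fx <- reml_fixture(120, seed = 43)
  f1 <- fit_univariate(fx$model)
  ph2 <- dplyr::mutate(fx$coh$phenotype, value = value + 7)
  m2 <- vc_model(ph2, list(g = fx$A, ge = fx$ge), env = fx$coh$environment)
  expect_equal(reml_loglik(m2, c(0.3, 0.2, 0.5)),
               reml_loglik(fx$model, c(0.3, 0.2, 0.5)), tolerance = 1e-8)

  ph3 <- dplyr::mutate(fx$coh$phenotype, value = value * 3)
  f3 <- fit_univariate(vc_model(ph3, list(g = fx$A, ge = fx$ge),
                                env = fx$coh$environment))
  expect_equal(f3$components$estimate, f1$components$estimate * 9,
               tolerance = 1e-4)
  expect_equal(f3$components$proportion, f1$components$proportion,
               tolerance = 1e-4)
  red1 <- fit_univariate(vc_model(fx$coh$phenotype, list(g = fx$A),
                                  env = fx$coh$environment))
  red3 <- fit_univariate(vc_model(ph3, list(g = fx$A),
                                  env = fx$coh$environment))
  expect_equal(lrt_component(f3, red3)$statistic,
               lrt_component(f1, red1)$statistic, tolerance = 1e-4)
})

test_that("AI-REML finds the optimum located by grid plus refinement", {
  fx <- reml_fixture(100, seed = 44)
  fit <- fit_univariate(fx$model)
  oracle <- grid_refine_reml(fx$model$y, fx$model$X, fx$model$structures)
  expect_lt(abs(fit$loglik - oracle$loglik), 1e-4)
})

test_that("identity components alias the residual and are rejected", {
  ids <- tibble::tibble(fid = sprintf("f%d", 1:60),
                        iid = sprintf("i%d", 1:60))
  eye <- new_grm(diag(60), ids, n_snps = 1, kind = "genetic")
  ph <- tibble::tibble(fid = ids$fid, iid = ids$iid, value = rnorm(60))
  expect_error(vc_model(ph, list(g = eye)), "identity")
})

test_that("sample alignment follows FID/IID pairs, not order", {
  fx <- reml_fixture(80, seed = 45)
  perm <- sample(80)
  ph <- fx$coh$phenotype[perm, ]
  en <- fx$coh$environment[perm, ]
  m2 <- vc_model(ph, list(g = fx$A, ge = fx$ge), env = en)
  expect_equal(m2$y, fx$model$y)
  expect_equal(m2$X, fx$model$X)
  ph_bad <- dplyr::mutate(ph, iid = paste0(iid, "zzz"))
  expect_error(vc_model(ph_bad, list(g = fx$A)), "no phenotype")
})

test_that("component LRT handles boundaries and reference distributions", {
  f <- list(loglik = -100)
  r <- list(loglik = -100)
  out <- lrt_component(f, r)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)

  out2 <- lrt_component(list(loglik = -98.08), list(loglik = -100),
                        boundary = FALSE)
  expect_equal(out2$statistic, 3.84)
  expect_equal(out2$p_value, pchisq(3.84, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(out2$p_value, 0.05, tolerance = 1e-3)

  # mixture null halves the tail probability
  out3 <- lrt_component(list(loglik = -98.08), list(loglik = -100),
                        boundary = TRUE)
  expect_equal(out3$p_value, out2$p_value / 2)

  expect_error(lrt_component(list(loglik = -100), list(loglik = -90)),
               "exceeds")
})

test_that("interaction variance is recovered and null fits stay near zero", {
  set.seed(46)
  est <- t(replicate(4, {
    fx <- reml_fixture(700, m = 700, s2 = c(0.3, 0.3, 0.4),
                       seed = sample.int(1e6, 1))
    fit_univariate(fx$model)$components$estimate
  }))
  expect_lt(max(abs(colMeans(est) - c(0.3, 0.3, 0.4))), 0.12)

  set.seed(47)
  null_est <- replicate(4, {
    fx <- reml_fixture(500, m = 500, s2 = c(0.4, 0, 0.6),
                       seed = sample.int(1e6, 1))
    fit_univariate(fx$model)$components$estimate[2]
  })
  expect_lt(mean(null_est), 0.08)
})

test_that("undersized models are refused", {
  fx <- reml_fixture(40, seed = 48)
  sub <- function(g) new_grm(g$values[1:12, 1:12], g$samples[1:12, ],
                             n_snps = g$n_snps, kind = g$kind)
  small <- sub(fx$A)
  small_ge <- sub(fx$ge)
  ph <- fx$coh$phenotype[1:12, ]
  en <- fx$coh$environment[1:12, ]
  expect_error(
    fit_univariate(vc_model(ph, list(g = small, ge = small_ge), env = en)),
    "too small")
})
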