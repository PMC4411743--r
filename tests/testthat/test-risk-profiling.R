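# builds a ready-made score/pheno/env triple without the genotype pipeline
sim_profile_data <- function(n, b_g = 0, b_e = 0, b_ge = 0, binary = TRUE,
                             parts = 1) {
  g <- matrix(rnorm(n * parts), n)
  e <- rbinom(n, 1, 0.5)
  eta <- -0.5 + b_g * rowSums(g) + b_e * e + b_ge * rowSums(g) * e
  y <- if (binary) rbinom(n, 1, plogis(eta)) else eta + rnorm(n)
  ids <- sprintf("p%d", seq_len(n))
  scores <- dplyr::bind_rows(lapply(seq_len(parts), function(k)
    tibble::tibble(fid = ids, iid = ids, partition = paste0("part", k),
                   score = g[, k], score_std = drop(scale(g[, k])),
                   n_loci = 100L)))
  list(pheno = tibble::tibble(fid = ids, iid = ids, value = y),
       env = tibble::tibble(fid = ids, iid = ids, value = e),
       scores = scores)
}

test_that("nested fits are monotone in likelihood with correct df", {
  set.seed(21)
  d <- sim_profile_data(500, b_g = 0.4, b_e = 0.5, b_ge = 0.3)
  fit <- fit_nested_models(d$pheno, d$scores, d$env)
  expect_equal(fit$comparisons$term, c("env", "grps", "grps_x_env"))
  expect_true(all(diff(fit$loglik$loglik) >= 0))
  expect_true(all(fit$comparisons$statistic >= 0))
  expect_equal(fit$comparisons$df, c(1L, 1L, 1L))
  expect_equal(fit$loglik$n_par, c(1L, 2L, 3L, 4L))
  # strong simulated signals are detected
  expect_lt(fit$comparisons$p_value[2], 0.01)

  # two partitions -> two columns added at the G and GxE steps
  d2 <- sim_profile_data(500, b_g = 0.3, parts = 2)
  fit2 <- fit_nested_models(d2$pheno, d2$scores, d2$env)
  expect_equal(fit2$comparisons$df, c(1L, 2L, 2L))
  ge <- fit2$comparisons[fit2$comparisons$term == "grps_x_env", ]
  expect_equal(ge$p_bonferroni, min(1, ge$p_value * 2))
})

test_that("interaction LRT is invariant to affine rescaling of score and E", {
  set.seed(22)
  d <- sim_profile_data(400, b_g = 0.3, b_e = 0.4, b_ge = 0.25)
  base <- fit_nested_models(d$pheno, d$scores, d$env, use_std = FALSE)
  d2 <- d
  d2$scores$score <- 3 * d2$scores$score - 1
  d2$env$value <- 5 * d2$env$value + 2
  refit <- fit_nested_models(d2$pheno, d2$scores, d2$env, use_std = FALSE)
  ge <- function(f) f$comparisons$statistic[f$comparisons$term == "grps_x_env"]
  expect_equal(ge(refit), ge(base), tolerance = 1e-6)

  # quantitative phenotype: same invariance for the F statistic
  set.seed(23)
  dq <- sim_profile_data(300, b_g = 0.3, b_ge = 0.2, binary = FALSE)
  fq <- fit_nested_models(dq$pheno, dq$scores, dq$env, use_std = FALSE)
  dq2 <- dq
  dq2$env$value <- -2 * dq2$env$value + 7
  fq2 <- fit_nested_models(dq2$pheno, dq2$scores, dq2$env, use_std = FALSE)
  expect_equal(ge(fq2), ge(fq), tolerance = 1e-6)
  expect_true(all(c("df_resid") %in% names(fq$comparisons)))
})

test_that("degenerate inputs are rejected with informative errors", {
  set.seed(24)
  d <- sim_profile_data(100)
  dbad <- d
  dbad$scores$score <- 1
  dbad$scores$score_std <- NA_real_
  expect_error(fit_nested_models(dbad$pheno, dbad$scores, dbad$env),
               "constant score")
  dbad2 <- d
  dbad2$env$value <- 1
  expect_error(fit_nested_models(d$pheno, d$scores, dbad2$env),
               "environment is constant")
  expect_warning(
    fit_nested_models(d$pheno[1:30, ], d$scores[1:30, ], d$env[1:30, ]),
    "10 x")
})

test_that("separation falls back to a finite Firth-penalised fit", {
  set.seed(25)
  n <- 80
  g <- rnorm(n)
  y <- as.numeric(g > 0)            # perfectly separated on the score
  ids <- sprintf("p%d", 1:n)
  sc <- tibble::tibble(fid = ids, iid = ids, partition = "all", score = g,
                       score_std = drop(scale(g)), n_loci = 10L)
  ph <- tibble::tibble(fid = ids, iid = ids, value = y)
  en <- tibble::tibble(fid = ids, iid = ids, value = rbinom(n, 1, 0.5))
  fit <- suppressWarnings(fit_nested_models(ph, sc, en))
  expect_true(fit$firth)
  expect_true(all(is.finite(fit$coefficients$estimate)))
  expect_true(all(is.finite(fit$loglik$loglik)))
})

test_that("decile odds ratios match hand-computed cross-ratios", {
  # n = 20, 2 per decile, fully hand-countable
  y <- c(0, 0, 0, 1, 0, 0, 0, 1, 0, 1, 0, 1, 1, 0, 1, 1, 0, 1, 1, 1)
  ids <- sprintf("p%d", 1:20)
  ph <- tibble::tibble(fid = ids, iid = ids, value = y)
  sc <- tibble::tibble(fid = ids, iid = ids, score = seq(0.1, 2, by = 0.1))
  d <- decile_odds_ratios(ph, sc)
  expect_equal(d$n, rep(2L, 10))
  expect_equal(d$cases, c(0, 1, 0, 1, 1, 1, 1, 2, 1, 2))
  # decile 2: odds (1/1); decile 1: odds (0/2) -> OR infinite, flagged
  expect_equal(d$odds[1], 0)
  expect_true(all(is.infinite(d$odds_ratio[-c(1, 3)])))
  expect_true(all(d$degenerate))

  # shift so decile 1 has a case: ORs become finite hand cross-ratios
  y2 <- c(1, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 1, 1, 0, 1, 1, 0, 1, 1, 1)
  ph2 <- tibble::tibble(fid = ids, iid = ids, value = y2)
  d2 <- decile_odds_ratios(ph2, sc)
  expect_equal(d2$odds_ratio[6], (1 / 1) / (1 / 1))
  expect_equal(d2$odds_ratio[10], (2 / 0) / (1 / 1))
  expect_false(d2$degenerate[6])
})

test_that("perfect separation on the score flags an infinite top decile", {
  set.seed(26)
  n <- 100
  sc_v <- rnorm(n)
  y <- as.numeric(sc_v > quantile(sc_v, 0.5))
  ids <- sprintf("p%d", 1:n)
  d <- decile_odds_ratios(tibble::tibble(fid = ids, iid = ids, value = y),
                          tibble::tibble(fid = ids, iid = ids, score = sc_v))
  expect_equal(d$cases[1], 0)
  expect_true(is.infinite(d$odds_ratio[10]))
  expect_true(d$degenerate[10])
})

test_that("null interaction p-values are approximately uniform", {
  set.seed(27)
  reps <- 300
  p <- replicate(reps, {
    d <- sim_profile_data(300, b_g = 0.3, b_e = 0.3, b_ge = 0)
    f <- fit_nested_models(d$pheno, d$scores, d$env)
    f$comparisons$p_value[3]
  })
  rej <- mean(p < 0.05)
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.10)
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
})

test_that("true interaction coefficients are recovered", {
  set.seed(28)
  ok <- replicate(20, {
    d <- sim_profile_data(1000, b_g = 0.2, b_e = 0.3, b_ge = 0.5)
    f <- fit_nested_models(d$pheno, d$scores, d$env, use_std = FALSE)
    co <- f$coefficients[grepl("_x_env", f$coefficients$term), ]
    abs(co$estimate - 0.5) < 3 * co$std_error
  })
  expect_gte(mean(ok), 0.9)
})

test_that("phenotype transforms behave as documented", {
  ids <- sprintf("p%d", 1:50)
  set.seed(29)
  y <- rgamma(50, 2)
  ph <- tibble::tibble(fid = ids, iid = ids, value = y)
  expect_equal(transform_phenotype(ph, "none"), ph)
  # rank-based transform is invariant to monotone transformation
  rin1 <- transform_phenotype(ph, "rank-inverse-normal")
  ph_log <- dplyr::mutate(ph, value = log(value))
  rin2 <- transform_phenotype(ph_log, "rank-inverse-normal")
  expect_equal(rin1$value, rin2$value)
  expect_equal(transform_phenotype(ph, "log")$value, log(y))
  ph_neg <- dplyr::mutate(ph, value = value - 5)
  expect_error(transform_phenotype(ph_neg, "log"), "positive")
  # near-normal input passes through almost unchanged
  z <- rnorm(2000)
  idz <- sprintf("q%d", 1:2000)
  phz <- tibble::tibble(fid = idz, iid = idz, value = z)
  expect_gt(cor(transform_phenotype(phz, "rank-inverse-normal")$value, z),
            0.99)
})
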