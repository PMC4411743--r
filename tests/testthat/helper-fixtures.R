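# Shared fixture builders. All fixtures are generated in code; file-based
# ones go into per-test temporary directories.

# tiny genotype container from a dosage matrix
tiny_geno <- function(dos, a1 = NULL, a2 = NULL) {
  dos <- as.matrix(dos)
  m <- ncol(dos); n <- nrow(dos)
  genotype_matrix(
    dos,
    variants = data.frame(id = paste0("rs", seq_len(m)), chr = "1",
                          pos = seq_len(m) * 100,
                          a1 = a1 %||% rep("A", m),
                          a2 = a2 %||% rep("G", m)),
    samples = data.frame(fid = paste0("f", seq_len(n)),
                         iid = paste0("i", seq_len(n))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write lines to a temp file, return path
tmp_lines <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# dense-algebra REML log-likelihood, deliberately independent of the
# package's Cholesky-based evaluation: explicit inverses and determinants
dense_reml_ll <- function(y, X, structures, comps) {
  V <- Reduce(`+`, Map(`*`, structures, comps))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  n <- length(y); p <- ncol(X)
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       t(y) %*% P %*% y))
}

# grid-plus-refinement maximiser of the dense REML likelihood over
# (sigma2_g, sigma2_ge, sigma2_e); independent of the AI-REML path
grid_refine_reml <- function(y, X, structures) {
  vp <- var(y)
  grid <- as.matrix(expand.grid(g = seq(0.05, 1.2, length.out = 6) * vp,
                                ge = seq(0.05, 1.2, length.out = 6) * vp,
                                e = seq(0.05, 1.2, length.out = 6) * vp))
  ll <- apply(grid, 1, function(th)
    tryCatch(dense_reml_ll(y, X, structures, th), error = function(e) -Inf))
  start <- grid[which.max(ll), ]
  opt <- optim(log(start), function(lth)
    -dense_reml_ll(y, X, structures, exp(lth)),
    method = "Nelder-Mead",
    control = list(maxit = 2000, reltol = 1e-12))
  list(par = exp(opt$par), loglik = -opt$value)
}
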