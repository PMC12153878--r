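# REML likelihood machinery for the single-random-intercept LMM.
#
# lme4 fits the model; the pieces lme4 alone does not provide --
# Satterthwaite denominator degrees of freedom, type-III F tests and
# estimated marginal means -- are computed here from the closed-form REML
# log-likelihood in the variance components (tau2, sigma2), exactly the
# construction lmerTest uses. Dimensions are tiny (a cow-period row per
# observation), so dense linear algebra is fine.

# -2 * REML log-likelihood (up to an additive constant) as a function of
# vp = c(tau2, sigma2); also returns vcov(beta) on request.
.reml_pieces <- function(y, X, Z, vp) {
  n <- length(y)
  V <- vp[2] * diag(n) + vp[1] * tcrossprod(Z)
  R <- chol(V)
  Vi <- chol2inv(R)
  XtViX <- crossprod(X, Vi %*% X)
  XtViy <- crossprod(X, Vi %*% y)
  beta <- solve(XtViX, XtViy)
  r <- y - X %*% beta
  neg2ll <- 2 * sum(log(diag(R))) +
    determinant(XtViX, logarithm = TRUE)$modulus[1] +
    drop(crossprod(r, Vi %*% r))
  list(neg2ll = neg2ll, vcov_beta = solve(XtViX), beta = drop(beta))
}

.fd_grad <- function(f, x, rel = 1e-4, floor = 1e-8) {
  h <- pmax(abs(x) * rel, floor)
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h[i]
    (f(x + e) - f(x - e)) / (2 * h[i])
  }, 0)
}

.fd_hess <- function(f, x, rel = 1e-4, floor = 1e-8) {
  k <- length(x)
  h <- pmax(abs(x) * rel, floor)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- numeric(k); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < k) for (j in (i + 1):k) {
      ej <- numeric(k); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) -
           f(x - ei + ej) + f(x - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

# Satterthwaite df for a single contrast L'beta:
#   df = 2 [Var(L'beta)]^2 / (g' A g)
# with g the gradient of Var(L'beta) in the variance components and
# A = 2 H^{-1} the asymptotic vcov of the REML variance-component
# estimates (H the Hessian of -2 logLik_REML).
.satterthwaite_df <- function(y, X, Z, vphat, L, A = NULL, fallback_df) {
  fvar <- function(vp) {
    vp <- pmax(vp, c(0, 1e-10))
    drop(t(L) %*% .reml_pieces(y, X, Z, vp)$vcov_beta %*% L)
  }
  if (is.null(A)) A <- .varpar_vcov(y, X, Z, vphat)
  if (is.null(A)) return(fallback_df)
  f0 <- fvar(vphat)
  g <- .fd_grad(fvar, vphat)
  denom <- drop(t(g) %*% A %*% g)
  if (!is.finite(denom) || denom <= 0) return(fallback_df)
  df <- 2 * f0^2 / denom
  if (!is.finite(df) || df <= 1) fallback_df else df
}

.varpar_vcov <- function(y, X, Z, vphat) {
  f <- function(vp) .reml_pieces(y, X, Z, pmax(vp, c(0, 1e-10)))$neg2ll
  H <- .fd_hess(f, vphat)
  A <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (!is.null(A) && any(!is.finite(A))) A <- NULL
  A
}

# Multi-df Satterthwaite F test for H0: L beta = 0 (L is q x p), following
# the eigen-decomposition combination rule used by lmerTest.
.satterthwaite_F <- function(y, X, Z, vphat, beta, vcov_beta, L,
                             fallback_df, A = NULL) {
  q <- nrow(L)
  M <- L %*% vcov_beta %*% t(L)
  eg <- eigen(M, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  q_eff <- sum(pos)
  P <- eg$vectors[, pos, drop = FALSE]
  d <- eg$values[pos]
  Lstar <- t(P) %*% L                          # orthogonalized contrasts
  tstat2 <- (drop(Lstar %*% beta))^2 / d
  Fval <- sum(tstat2) / q_eff
  if (is.null(A)) A <- .varpar_vcov(y, X, Z, vphat)
  nu <- vapply(seq_len(q_eff), function(i) {
    .satterthwaite_df(y, X, Z, vphat, drop(Lstar[i, ]), A = A,
                      fallback_df = fallback_df)
  }, 0)
  E <- sum(ifelse(nu > 2, nu / (nu - 2), Inf))
  df2 <- if (is.finite(E) && E > q_eff) 2 * E / (E - q_eff) else fallback_df
  pval <- stats::pf(Fval, q_eff, df2, lower.tail = FALSE)
  list(F = Fval, df1 = q_eff, df2 = df2, p = pval)
}

# Reference-grid L matrix: one row per level of `focus`, averaging the
# fixed-effect model matrix over the full factorial grid of the remaining
# factors (equal weights), i.e. classical estimated marginal means.
.emm_lmatrix <- function(formula_fixed, data, focus) {
  vars <- all.vars(formula_fixed)[-1]
  grid <- expand.grid(lapply(data[vars], levels),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (v in vars) {
    grid[[v]] <- factor(grid[[v]], levels = levels(data[[v]]))
    contrasts(grid[[v]]) <- contrasts(data[[v]])
  }
  mm <- stats::model.matrix(formula_fixed[-2], grid)
  lv <- levels(data[[focus]])
  L <- t(vapply(lv, function(g) colMeans(mm[grid[[focus]] == g, ,
                                            drop = FALSE]),
                numeric(ncol(mm))))
  rownames(L) <- lv
  L
}
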