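#' Robust z-score outlier screen
#'
#' z_i = (x_i - median) / (1.4826 * MAD). Values with |z| above the
#' threshold are flagged. A zero raw MAD draws a warning; points equal to
#' the median then score NaN (never flagged) while points off the median
#' score infinite and are flagged. Flagging is advisory: nothing is
#' removed automatically.
#'
#' @param values Numeric vector, length >= 3.
#' @param threshold Flagging threshold on |z| (default 3.5).
#' @return Logical vector of flags with attribute `z` (the scores).
#' @export
#' @examples
#' robust_z_outliers(c(1, 1, 1, 1, 100))
robust_z_outliers <- function(values, threshold = 3.5) {
  if (length(values) < 3L) stop("need >= 3 values", call. = FALSE)
  med <- stats::median(values)
  mad_raw <- stats::median(abs(values - med))
  if (mad_raw == 0) {
    # degenerate scale: points at the median get NaN scores (never
    # flagged); any point off the median is infinitely many MADs away
    warning("MAD is zero; z scores are degenerate", call. = FALSE)
  }
  z <- (values - med) / (1.4826 * mad_raw)
  out <- !is.na(z) & abs(z) > threshold
  attr(out, "z") <- z
  out
}

#' Chamber intake exclusion filter
#'
#' Cow-periods whose mean intake falls below 0.1 kg DM per kg metabolic
#' body weight are excluded from chamber analyses (the motivating trial
#' dropped one cow on this rule). The boundary is strict: exactly 0.1 is
#' retained.
#'
#' @param records Data frame with `cow_id`, `period`, `dmi_kg_d` and
#'   either `mbw_kg075` or `bw_kg`.
#' @param threshold kg DMI per kg^0.75 (default 0.1).
#' @return List with `retained` (the surviving rows) and `exclusions`
#'   (one row per dropped cow-period, with the measured ratio).
#' @export
exclusion_filter <- function(records, threshold = 0.1) {
  stopifnot(all(c("cow_id", "period", "dmi_kg_d") %in% names(records)))
  mbw <- if ("mbw_kg075" %in% names(records)) records$mbw_kg075
  else metabolic_bw(records$bw_kg)
  key <- interaction(records$cow_id, records$period, drop = TRUE)
  ratio <- tapply(records$dmi_kg_d / mbw, key, mean)
  drop_keys <- names(ratio)[ratio < threshold]
  excl <- do.call(rbind, lapply(drop_keys, function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(cow_id = parts[1], period = as.integer(parts[2]),
               dmi_per_mbw = as.numeric(ratio[k]),
               reason = sprintf("mean DMI/mBW %.4f < %.2f kg/kg^0.75",
                                ratio[k], threshold),
               stringsAsFactors = FALSE)
  }))
  if (is.null(excl)) {
    excl <- data.frame(cow_id = character(), period = integer(),
                       dmi_per_mbw = numeric(), reason = character())
  }
  list(retained = records[!(as.character(key) %in% drop_keys), ,
                          drop = FALSE],
       exclusions = excl)
}

#' Model specification for the crossover analysis
#'
#' @param response Column name of the response to analyse.
#' @param time Optional column name of a repeated-measures time factor;
#'   when given, time and group x time enter the fixed effects.
#' @param transformation `"auto"` applies the fallback ladder (see
#'   [fit_crossover_model()]); `"none"`, `"log2"` or `"gamma"` force a
#'   scale.
#' @param alpha Significance level (default 0.05); effects with
#'   `alpha <= p < trend` are labelled trends.
#' @param trend Trend threshold (default 0.10).
#' @param diag_alpha Level for the residual normality check driving the
#'   ladder (default 0.05).
#' @return A `model_spec` list.
#' @export
model_spec <- function(response, time = NULL,
                       transformation = c("auto", "none", "log2", "gamma"),
                       alpha = 0.05, trend = 0.10, diag_alpha = 0.05) {
  transformation <- match.arg(transformation)
  stopifnot(alpha > 0, alpha < 1, trend >= alpha)
  structure(list(response = response, time = time,
                 transformation = transformation, alpha = alpha,
                 trend = trend, diag_alpha = diag_alpha),
            class = "model_spec")
}

#' Fit the crossover mixed model with the fallback ladder
#'
#' Fits `response ~ group + period + sequence + block (+ time +
#' group:time) + (1 | cow)` by REML and applies, in order: (1) residual
#' normality check (Shapiro-Wilk at `diag_alpha`); if violated, log2
#' transformation; (2) if still violated, a gamma GLMM with log link;
#' (3) if the mixed model is singular, a fixed-effects-only linear model.
#' Heteroscedasticity is tested (Breusch-Pagan type) and flagged but never
#' triggers a fallback. The path taken is recorded.
#'
#' Inference: type-III F tests with Satterthwaite denominator df for the
#' LMM, Wald chi-square for the GLMM, classical F for the LM. Estimated
#' marginal means for the diet groups average the fixed-effect design over
#' the factorial reference grid; pairwise group contrasts are
#' Tukey-Kramer adjusted. EMMs from transformed fits are back-transformed.
#'
#' @param data Data frame with one row per cow-period (or cow-time) and
#'   columns `treatment` (or `group`), `period`, `sequence`, `block`,
#'   `cow_id` (or `cow`) plus the response.
#' @param spec A [model_spec()].
#' @return An object of class `crossover_fit`: `path`, `anova` (term,
#'   statistic, df, p), `emm`, `contrasts`, `diagnostics`, `spec`,
#'   and the underlying `model`.
#' @export
fit_crossover_model <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  d <- .prepare_model_frame(data, spec)
  y_raw <- d$y
  fixed_terms <- attr(d, "fixed_terms")
  f_fixed <- stats::reformulate(fixed_terms, response = "y")
  f_mixed <- stats::as.formula(
    paste("y ~", paste(c(fixed_terms, "(1 | cow)"), collapse = " + ")))

  trans <- "none"; path <- "lmm"
  flags <- character(0)
  fit <- .quiet_lmer(f_mixed, d)
  sw_p <- .shapiro_p(stats::resid(fit))

  want <- spec$transformation
  if (want == "log2" || (want == "auto" && sw_p < spec$diag_alpha)) {
    if (all(y_raw > 0)) {
      d$y <- log2(y_raw)
      fit <- .quiet_lmer(f_mixed, d)
      trans <- "log2"; path <- "lmm-log2"
      sw_p <- .shapiro_p(stats::resid(fit))
      if (want == "auto" && sw_p < spec$diag_alpha) want <- "gamma"
    } else flags <- c(flags, "nonpositive_values_transform_skipped")
  }
  if (want == "gamma") {
    if (all(y_raw > 0)) {
      d$y <- y_raw
      fit <- suppressWarnings(suppressMessages(
        lme4::glmer(f_mixed, data = d, family = stats::Gamma(link = "log"))
      ))
      trans <- "gamma"; path <- "glmm-gamma"
    } else flags <- c(flags, "nonpositive_values_gamma_skipped")
  }

  if (lme4::isSingular(fit, tol = 1e-4)) {
    if (trans == "gamma") {
      d$y <- log2(y_raw); trans <- "log2"
    }
    fit <- stats::lm(f_fixed, data = d)
    path <- "lm"
  }

  het_p <- .bp_het_p(fit, d)
  out <- .infer_crossover(fit, d, f_fixed, trans, path)
  out$diagnostics <- list(shapiro_p = sw_p, heteroscedasticity_p = het_p,
                          normality_violated = sw_p < spec$diag_alpha,
                          heteroscedastic = het_p < spec$diag_alpha,
                          flags = flags)
  out$spec <- spec
  class(out) <- "crossover_fit"
  out
}

.prepare_model_frame <- function(data, spec) {
  grp <- if ("group" %in% names(data)) "group" else "treatment"
  cow <- if ("cow" %in% names(data)) "cow" else "cow_id"
  need <- c(spec$response, grp, cow, "period", "sequence", "block",
            spec$time)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- data.frame(y = data[[spec$response]],
                  group = factor(data[[grp]]),
                  period = factor(data$period),
                  sequence = factor(data$sequence),
                  block = factor(data$block),
                  cow = factor(data[[cow]]))
  if (!is.null(spec$time)) d$time <- factor(data[[spec$time]])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nlevels(droplevels(d$group)) < 2L) {
    stop("both treatment levels must be present", call. = FALSE)
  }
  cows_per_seq <- tapply(d$cow, d$sequence,
                         function(x) length(unique(x)))
  if (any(cows_per_seq < 2)) {
    stop("need >= 2 cows per sequence", call. = FALSE)
  }
  cells <- table(d$group, d$period)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-estimable contrast: empty cell group=%s, period=%s",
      rownames(cells)[bad[1]], colnames(cells)[bad[2]]), call. = FALSE)
  }
  fixed <- c("group", "period", "sequence", "block")
  fixed <- fixed[vapply(fixed,
                        function(v) nlevels(droplevels(d[[v]])) > 1, TRUE)]
  for (v in c(fixed, if (!is.null(spec$time)) "time")) {
    d[[v]] <- droplevels(d[[v]])
    stats::contrasts(d[[v]]) <- stats::contr.sum(nlevels(d[[v]]))
  }
  if (!is.null(spec$time) && nlevels(d$time) > 1) {
    fixed <- c(fixed, "time", "group:time")
  }
  attr(d, "fixed_terms") <- fixed
  d
}

.quiet_lmer <- function(formula, data) {
  suppressWarnings(suppressMessages(
    lme4::lmer(formula, data = data, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))
  ))
}

.shapiro_p <- function(r) {
  r <- r[is.finite(r)]
  # numerically exact fits leave machine-noise residuals; calling them
  # non-normal would send a perfect model down the ladder
  if (length(r) < 3 || stats::sd(r) < 1e-8) return(1)
  stats::shapiro.test(r)$p.value
}

# Breusch-Pagan-type test: n * R^2 of squared residuals on fitted values
.bp_het_p <- function(fit, d) {
  r <- stats::resid(fit); f <- stats::fitted(fit)
  if (stats::sd(f) < 1e-10 || stats::sd(r) < 1e-10) return(1)
  aux <- stats::lm(I(r^2) ~ f)
  r2 <- suppressWarnings(summary(aux)$r.squared)
  stats::pchisq(length(r) * r2, df = 1, lower.tail = FALSE)
}

.infer_crossover <- function(fit, d, f_fixed, trans, path) {
  is_lm <- inherits(fit, "lm")
  is_glmm <- inherits(fit, "glmerMod") && !is_lm
  mm <- stats::model.matrix(f_fixed, d)
  if (is_lm) {
    beta <- stats::coef(fit)
    C <- stats::vcov(fit)
    fb_df <- stats::df.residual(fit)
  } else {
    beta <- lme4::fixef(fit)
    C <- as.matrix(stats::vcov(fit))
    fb_df <- nrow(mm) - ncol(mm)
  }
  vphat <- A <- Z <- NULL
  if (!is_lm && !is_glmm) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    vphat <- c(tau2 = vc$vcov[vc$grp == "cow"],
               sigma2 = vc$vcov[vc$grp == "Residual"])
    Z <- stats::model.matrix(~ 0 + cow, d)
    A <- .varpar_vcov(d$y, mm, Z, vphat)
  }

  terms_lab <- attr(stats::terms(f_fixed), "term.labels")
  asgn <- attr(mm, "assign")
  anova_tab <- do.call(rbind, lapply(seq_along(terms_lab), function(j) {
    idx <- which(asgn == j)
    L <- diag(ncol(mm))[idx, , drop = FALSE]
    if (!is_lm && !is_glmm) {
      ft <- .satterthwaite_F(d$y, mm, Z, vphat, beta, C, L, fb_df, A = A)
      data.frame(term = terms_lab[j], statistic = ft$F, df1 = ft$df1,
                 df2 = ft$df2, p = ft$p, stringsAsFactors = FALSE)
    } else {
      est <- drop(L %*% beta)
      M <- L %*% C %*% t(L)
      W <- drop(t(est) %*% solve(M, est))
      q <- nrow(L)
      if (is_glmm) {
        data.frame(term = terms_lab[j], statistic = W / q, df1 = q,
                   df2 = Inf,
                   p = stats::pchisq(W, q, lower.tail = FALSE),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(term = terms_lab[j], statistic = W / q, df1 = q,
                   df2 = fb_df,
                   p = stats::pf(W / q, q, fb_df, lower.tail = FALSE),
                   stringsAsFactors = FALSE)
      }
    }
  }))

  Lg <- .emm_lmatrix(f_fixed, d, "group")
  emm_lin <- drop(Lg %*% beta)
  emm_se <- sqrt(diag(Lg %*% C %*% t(Lg)))
  emm_df <- vapply(seq_len(nrow(Lg)), function(i) {
    if (!is_lm && !is_glmm) {
      .satterthwaite_df(d$y, mm, Z, vphat, drop(Lg[i, ]), A = A,
                        fallback_df = fb_df)
    } else if (is_glmm) Inf else fb_df
  }, 0)
  back <- switch(trans,
                 none = list(est = emm_lin, se = emm_se),
                 log2 = list(est = 2^emm_lin,
                             se = 2^emm_lin * log(2) * emm_se),
                 gamma = list(est = exp(emm_lin),
                              se = exp(emm_lin) * emm_se))
  emm <- data.frame(group = rownames(Lg), emm = back$est, se = back$se,
                    emm_link = emm_lin, se_link = emm_se, df = emm_df,
                    transformation = trans, stringsAsFactors = FALSE)

  lv <- rownames(Lg)
  pairs <- utils::combn(seq_along(lv), 2)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    Lc <- Lg[i, ] - Lg[j, ]
    est <- drop(Lc %*% beta)
    se <- sqrt(drop(t(Lc) %*% C %*% Lc))
    df <- if (!is_lm && !is_glmm) {
      .satterthwaite_df(d$y, mm, Z, vphat, Lc, A = A, fallback_df = fb_df)
    } else if (is_glmm) Inf else fb_df
    data.frame(contrast = paste(lv[i], "-", lv[j]), estimate = est,
               se = se, df = df, t = est / se, stringsAsFactors = FALSE)
  }))
  contrasts$p_tukey <- tukey_kramer(contrasts, n_means = length(lv))

  list(path = path, transformation = trans, anova = anova_tab,
       emm = emm, contrasts = contrasts, model = fit)
}

#' @export
print.crossover_fit <- function(x, ...) {
  cat(sprintf("<crossover_fit> response '%s', path: %s\n",
              x$spec$response, x$path))
  cat("\nEstimated marginal means:\n")
  print(x$emm[, c("group", "emm", "se", "df")], row.names = FALSE,
        digits = 4)
  cat("\nEffects:\n")
  print(transform(x$anova, p = signif(p, 3)), row.names = FALSE,
        digits = 4)
  cat("\nPairwise (Tukey-Kramer):\n")
  print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tukey-Kramer adjusted p-values
#'
#' Studentized-range adjustment for pairwise contrasts among `n_means`
#' groups, with Kramer's correction entering through each contrast's own
#' standard error and degrees of freedom. For two groups the adjusted
#' p-value equals the unadjusted t-test p-value.
#'
#' @param contrasts Data frame with columns `estimate`, `se`, `df` (or a
#'   precomputed `t`).
#' @param n_means Number of group means the pairs are drawn from.
#' @return Numeric vector of adjusted p-values.
#' @export
tukey_kramer <- function(contrasts, n_means) {
  stopifnot(n_means >= 2)
  tval <- if ("t" %in% names(contrasts)) contrasts$t
  else contrasts$estimate / contrasts$se
  df <- contrasts$df
  df[!is.finite(df)] <- 1e6 # normal limit
  stats::ptukey(sqrt(2) * abs(tval), nmeans = n_means, df = df,
                lower.tail = FALSE)
}

#' Sample size for equivalence by TOST (2x2 crossover, log scale)
#'
#' Sizes a two-treatment, two-period crossover to demonstrate equivalence
#' of a log-normal response. The within-subject log-scale SD is
#' sqrt(log(1 + CV^2)); the treatment-difference estimate has standard
#' error sigma_w * sqrt(2/n) with n - 2 degrees of freedom. Exact TOST
#' power is computed by integrating the joint rejection region over the
#' chi-square distribution of the variance estimate, and the smallest
#' even n with power >= 1 - beta is returned.
#'
#' @param cv Within-subject coefficient of variation (default 0.15).
#' @param theta0 True ratio of means (default 0.9).
#' @param limits Lower/upper equivalence limits (default c(0.75, 1.33)).
#' @param alpha One-sided type-I error of each test (default 0.05).
#' @param beta Type-II error; target power is 1 - beta (default 0.2).
#' @return Total number of subjects (even), with attribute
#'   `power` (the achieved power).
#' @export
#' @examples
#' tost_sample_size()
tost_sample_size <- function(cv = 0.15, theta0 = 0.9,
                             limits = c(0.75, 1.33),
                             alpha = 0.05, beta = 0.2) {
  stopifnot(cv > 0, theta0 > 0, limits[1] < limits[2],
            alpha > 0, alpha < 1, beta > 0, beta < 1)
  if (theta0 <= limits[1] || theta0 >= limits[2]) {
    stop("`theta0` on or outside the equivalence limits: ",
         "target power unreachable", call. = FALSE)
  }
  sw <- sqrt(log(1 + cv^2))
  target <- 1 - beta
  n <- 4L
  repeat {
    pw <- tost_power(n, cv = cv, theta0 = theta0, limits = limits,
                     alpha = alpha)
    if (pw >= target) break
    n <- n + 2L
    if (n > 10000L) stop("sample size search did not converge",
                         call. = FALSE)
  }
  structure(n, power = pw)
}

#' Exact TOST power for a 2x2 crossover at total size n
#'
#' @inheritParams tost_sample_size
#' @param n Total number of subjects (both sequences).
#' @return Power of the TOST procedure.
#' @export
tost_power <- function(n, cv = 0.15, theta0 = 0.9,
                       limits = c(0.75, 1.33), alpha = 0.05) {
  stopifnot(n >= 3)
  sw <- sqrt(log(1 + cv^2))
  se <- sw * sqrt(2 / n)
  df <- n - 2
  tcrit <- stats::qt(1 - alpha, df)
  lL <- log(limits[1]); lU <- log(limits[2]); l0 <- log(theta0)
  # reject iff lL + tcrit*se*s < dhat < lU - tcrit*se*s, s^2 ~ chi2_df/df
  f <- function(x) { # x = chi2 variate
    s <- sqrt(x / df)
    up <- stats::pnorm((lU - tcrit * se * s - l0) / se)
    lo <- stats::pnorm((lL + tcrit * se * s - l0) / se)
    pmax(up - lo, 0) * stats::dchisq(x, df)
  }
  stats::integrate(f, 0, stats::qchisq(1 - 1e-10, df))$value
}

#' Sample size for a two-sided t test
#'
#' Smallest per-group n whose two-sided t-test power (noncentral-t) meets
#' the target, for standardized effect size d.
#'
#' @param d Cohen's d (> 0).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Target power (default 0.8).
#' @param design `"two.sample"`, `"one.sample"` or `"paired"`.
#' @return n per group (per sample for one-sample/paired), with attribute
#'   `power`.
#' @export
#' @examples
#' t_power_n(1.0) # 17 per group
t_power_n <- function(d, alpha = 0.05, power = 0.8,
                      design = c("two.sample", "one.sample", "paired")) {
  design <- match.arg(design)
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  n <- 2L
  repeat {
    pw <- t_test_power(n, d, alpha, design)
    if (pw >= power) break
    n <- n + 1L
    if (n > 1e6) stop("sample size search did not converge", call. = FALSE)
  }
  structure(n, power = pw)
}

#' Power of the two-sided t test at size n
#'
#' @param n Per-group sample size.
#' @inheritParams t_power_n
#' @return Power.
#' @export
t_test_power <- function(n, d, alpha = 0.05,
                         design = c("two.sample", "one.sample", "paired")) {
  design <- match.arg(design)
  if (design == "two.sample") {
    df <- 2 * n - 2; ncp <- d * sqrt(n / 2)
  } else {
    df <- n - 1; ncp <- d * sqrt(n)
  }
  if (df < 1) return(0)
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
}
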