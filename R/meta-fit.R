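#' Multilevel weighted random-effects meta-analysis
#'
#' Fits the marginal meta-analytic model
#' \deqn{y_i = x_i'\beta + u_{study(i)} + (u_{obs(i)}) + e_i,}
#' where the sampling variances \eqn{Var(e_i) = v_i} are known (the inverse
#' weights of the meta-analysis), \eqn{u_{study} \sim N(0, \tau^2)} is a
#' case-study random intercept and, optionally, \eqn{u_{obs} \sim N(0,
#' \omega^2)} an observation-level component nested within studies.  Variance
#' components are estimated by restricted maximum likelihood (default) or
#' maximum likelihood, profiling \eqn{\beta} out with generalized least
#' squares; components are constrained nonnegative by optimizing on the
#' standard-deviation scale with a derivative-free method (golden-section for
#' one component, Nelder-Mead for two).
#'
#' The marginal covariance is block-diagonal by study, and each block is a
#' diagonal plus a rank-one matrix, so the likelihood is evaluated in O(n)
#' via the Sherman-Morrison identity; no n-by-n matrix is ever formed.
#'
#' @param data Data frame of effect sizes (one row per observation).
#' @param formula Fixed-effects formula, e.g. `z ~ driver` or
#'   `z ~ zB + intensity + study_type`.  Character moderators are coded with
#'   treatment contrasts, first level alphabetical.
#' @param variance Name of the column holding the known sampling variances
#'   (default `"var_z"`); must be strictly positive.
#' @param study Name of the case-study identifier column (default
#'   `"case_study_id"`).
#' @param obs Name of an observation identifier column to add a nested
#'   observation-level variance component (`~ 1 | study/obs`), or `NULL`
#'   (default) for a study-level component only.
#' @param method `"REML"` (default) or `"ML"`.
#' @param sigma2_fixed Optional fixed values for the variance components
#'   instead of estimating them: a single value (study component) or a
#'   length-2 vector `(study, observation)` when `obs` is given.  Setting
#'   all components to 0 gives the fixed-effect inverse-variance weighted
#'   model.
#' @param control List: `maxit` (default 500), `reltol` (default 1e-10).
#'
#' @return An object of class `meta_fit`: coefficients, standard errors,
#'   coefficient covariance, variance components (`sigma2`), log-likelihood,
#'   ML-based AIC, the moderator Wald test (`QM`, `QM_df`, `QM_p`), and a
#'   convergence flag.  Supports [tidy()], [glance()], `print()`.
#' @examples
#' d <- data.frame(z = c(0.2, 0.6), var_z = c(0.04, 0.01),
#'                 case_study_id = c("a", "b"))
#' fit_meta(d, z ~ 1)
#' @export
fit_meta <- function(data, formula, variance = "var_z",
                     study = "case_study_id", obs = NULL,
                     method = c("REML", "ML"), sigma2_fixed = NULL,
                     control = list()) {
  method <- match.arg(method)
  data <- as.data.frame(data)
  maxit <- control$maxit %||% 500L
  reltol <- control$reltol %||% 1e-10

  stopifnot(variance %in% names(data), study %in% names(data))
  chr <- vapply(data, is.character, logical(1))
  data[chr] <- lapply(data[chr], factor)  # alphabetical levels
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  X <- stats::model.matrix(formula, mf)
  y <- as.numeric(stats::model.response(mf))
  n <- length(y)
  p <- ncol(X)

  qr_x <- qr(X)
  if (qr_x$rank < p) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):p]]
    abort(sprintf("Fixed-effects design is rank deficient; aliased term(s): %s",
                  paste(aliased, collapse = ", ")),
          class = "befmeta_rank")
  }
  v <- as.numeric(data[[variance]])
  if (any(!is.finite(v)) || any(v <= 0)) {
    abort("Sampling variances must be finite and strictly positive.")
  }
  if (is.null(sigma2_fixed) && n < p + 2) {
    abort("Need at least p + 2 observations for p parameters.")
  }
  if (n < p) abort("More parameters than observations.")

  g <- as.integer(factor(data[[study]]))
  nested <- !is.null(obs)
  if (nested) {
    o <- data[[obs]]
    if (anyDuplicated(paste(g, o))) {
      abort("`obs` must identify rows uniquely within studies.")
    }
  }

  core <- .fit_meta_core(X, y, v, g, nested = nested, method = method,
                         maxit = maxit, reltol = reltol,
                         sigma2_fixed = sigma2_fixed)
  sigma2 <- core$sigma2
  beta <- core$beta
  names(beta) <- colnames(X)
  vc <- core$vcov
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc))

  fit <- structure(list(
    coefficients = beta, se = se, vcov = vc, sigma2 = sigma2,
    loglik = core$ll, loglik_ml = core$ll_ml, AIC_ML = core$aic_ml,
    k_params = core$k_params, method = method, converged = core$converged,
    n = n, p = p, n_studies = length(unique(g)),
    formula = formula, variance = variance, study = study, obs = obs,
    assign = attr(X, "assign"),
    term_labels = attr(terms(mf), "term.labels"),
    xlevels = stats::.getXlevels(terms(mf), mf),
    yname = deparse(formula[[2]])
  ), class = "meta_fit")
  qm <- tryCatch(wald_qm(fit), error = function(e) NULL)
  fit$QM <- qm$QM
  fit$QM_df <- qm$df
  fit$QM_p <- qm$p
  fit
}

# Optimization core shared by fit_meta() and the resampled-SEM fast path:
# estimates the variance components on precomputed design matrices.  Bounded,
# derivative-free: golden-section search for one component, Nelder-Mead on the
# SD scale for two.  Always also computes the ML log-likelihood (warm-started
# from the REML solution) so ML-based AICs are available for model comparison.
.fit_meta_core <- function(X, y, v, g, nested, method = "REML",
                           maxit = 500L, reltol = 1e-10,
                           sigma2_fixed = NULL, ml = TRUE, start = NULL) {
  p <- ncol(X)
  if (!is.null(sigma2_fixed)) {
    stopifnot(all(sigma2_fixed >= 0))
    s2 <- c(study = sigma2_fixed[1],
            observation = if (nested) sigma2_fixed[2] %||% 0)
    fin <- .meta_loglik(s2[["study"]], if (nested) s2[["observation"]] else 0,
                        X, y, v, g, reml = (method == "REML"))
    ll_ml <- .meta_loglik(s2[["study"]], if (nested) s2[["observation"]] else 0,
                          X, y, v, g, reml = FALSE)$ll
    return(list(beta = drop(fin$beta), vcov = fin$vcov, sigma2 = s2,
                ll = fin$ll, ll_ml = ll_ml, aic_ml = -2 * ll_ml + 2 * p,
                k_params = p, converged = TRUE))
  }
  ub_sd <- sqrt(max(10 * var(y), 10 * mean(v), 1e-3))
  M <- cbind(X, y)
  B <- max(g)
  gi <- as.integer(g)

  opt_components <- function(reml, start = NULL) {
    if (!nested) {
      op <- optimize(function(s) .meta_negll_cpp(s^2, 0, M, v, gi, B, reml),
                     interval = c(0, ub_sd), tol = 1e-9)
      list(sigma2 = c(study = op$minimum^2), converged = TRUE)
    } else {
      if (is.null(start)) {
        s0 <- sqrt(max(var(y) - mean(v), mean(v)) / 2)
        start <- c(s0, s0 / 2)
      }
      op <- optim(start, function(s)
        .meta_negll_cpp(s[1]^2, s[2]^2, M, v, gi, B, reml),
        method = "Nelder-Mead",
        control = list(maxit = maxit, reltol = reltol))
      list(sigma2 = c(study = op$par[1]^2, observation = op$par[2]^2),
           converged = op$convergence == 0)
    }
  }

  opt <- opt_components(method == "REML", start = start)
  if (!opt$converged) {
    abort(sprintf("Variance-component optimization did not converge (maxit %d).",
                  maxit), class = "befmeta_convergence")
  }
  sigma2 <- opt$sigma2
  fin <- .meta_loglik(sigma2[1], if (nested) sigma2[2] else 0, X, y, v, g,
                      reml = (method == "REML"))
  if (method == "ML") {
    ll_ml <- fin$ll
  } else if (ml) {
    opt_ml <- opt_components(FALSE, start = sqrt(pmax(sigma2, 1e-8)))
    s2m <- opt_ml$sigma2
    ll_ml <- .meta_loglik(s2m[1], if (nested) s2m[2] else 0, X, y, v, g,
                          reml = FALSE)$ll
  } else {
    ll_ml <- NA_real_
  }
  k_params <- p + length(sigma2)
  list(beta = drop(fin$beta), vcov = fin$vcov, sigma2 = sigma2,
       ll = fin$ll, ll_ml = ll_ml, aic_ml = -2 * ll_ml + 2 * k_params,
       k_params = k_params, converged = opt$converged)
}

# Profiled (restricted) log-likelihood of the multilevel meta-analytic model.
# V = diag(v + omega2) + tau2 * block-ones; everything reduces to per-study
# weighted sums (Sherman-Morrison / matrix determinant lemma).  M = cbind(X, y)
# may be passed precomputed to avoid rebuilding it in optimization loops.
.meta_loglik <- function(tau2, omega2, X, y, v, g, reml, M = NULL,
                         Ind = NULL) {
  a <- v + omega2
  w <- 1 / a
  if (is.null(M)) M <- cbind(X, y)
  if (is.null(Ind)) Ind <- group_indicator(g)
  p <- ncol(M) - 1L
  n <- length(y)
  Mw <- M * w
  S_all <- Ind %*% cbind(Mw, w)   # per-study sums of weighted columns
  S <- S_all[, seq_len(p + 1L), drop = FALSE]
  tb <- S_all[, p + 2L]
  cb <- tau2 / (1 + tau2 * tb)
  A <- crossprod(M, Mw) - crossprod(S, S * cb)  # [X'V⁻¹X X'V⁻¹y; . y'V⁻¹y]
  XtVX <- A[seq_len(p), seq_len(p), drop = FALSE]
  XtVy <- A[seq_len(p), p + 1L]
  ytVy <- A[p + 1L, p + 1L]
  ch <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  beta <- backsolve(ch, backsolve(ch, XtVy, transpose = TRUE))
  ytPy <- ytVy - sum(XtVy * beta)
  logdetV <- sum(log(a)) + sum(log1p(tau2 * tb))
  if (reml) {
    ll <- -0.5 * ((n - p) * log(2 * pi) + logdetV +
                    2 * sum(log(diag(ch))) + ytPy)
  } else {
    ll <- -0.5 * (n * log(2 * pi) + logdetV + ytPy)
  }
  list(ll = ll, beta = beta, vcov = chol2inv(ch))
}

group_indicator <- function(g) {
  B <- max(g)
  Ind <- matrix(0, B, length(g))
  Ind[cbind(g, seq_along(g))] <- 1
  Ind
}

#' Wald-type chi-square test of moderators (QM)
#'
#' Tests the selected coefficients jointly against zero:
#' \eqn{Q_M = b' V_b^{-1} b}, chi-square with df equal to the number of
#' coefficients tested.  By default all non-intercept coefficients are tested
#' (the omnibus moderator test of a meta-regression).
#'
#' @param fit A [fit_meta()] object.
#' @param terms Coefficient names or model term labels to test; default all
#'   non-intercept coefficients.
#' @return A list with `QM`, `df`, `p`.
#' @export
wald_qm <- function(fit, terms = NULL) {
  stopifnot(inherits(fit, "meta_fit"))
  cn <- names(fit$coefficients)
  if (is.null(terms)) {
    keep <- cn[cn != "(Intercept)"]
    if (!length(keep)) keep <- cn  # intercept-only model: test the intercept
  } else {
    keep <- unique(unlist(lapply(terms, function(tm) {
      if (tm %in% cn) return(tm)
      hit <- fit$term_labels == tm
      if (!any(hit)) abort(sprintf("Term '%s' not in the fit.", tm))
      cn[fit$assign == which(hit)]
    })))
  }
  b <- fit$coefficients[keep]
  Vb <- fit$vcov[keep, keep, drop = FALSE]
  qm <- tryCatch(drop(crossprod(b, solve(Vb, b))),
                 error = function(e) abort(
                   "Singular coefficient sub-covariance in Wald test."))
  list(QM = qm, df = length(b), p = pchisq(qm, df = length(b),
                                           lower.tail = FALSE))
}

#' Per-group grand mean effect sizes
#'
#' For a meta-analysis with a single categorical moderator (e.g.
#' `z ~ driver`), returns each group's mean effect with Wald normal 95%
#' confidence intervals and p-values against zero, computed as linear
#' combinations of the fitted coefficients (no refitting).
#'
#' @param fit A [fit_meta()] object whose fixed part is an intercept plus one
#'   categorical moderator (or intercept only).
#' @param level Confidence level (default 0.95).
#' @return A tibble with `group`, `estimate`, `se`, `ci_low`, `ci_high`, `p`.
#' @export
grand_means <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "meta_fit"))
  if (length(fit$term_labels) > 1) {
    abort("grand_means() needs a model with at most one (categorical) moderator.")
  }
  if (length(fit$term_labels) == 0) {
    L <- matrix(1, 1, 1)
    groups <- "overall"
  } else {
    lv <- fit$xlevels[[fit$term_labels]]
    if (is.null(lv)) abort("The single moderator must be categorical.")
    nd <- setNames(data.frame(factor(lv, levels = lv)), fit$term_labels)
    L <- stats::model.matrix(as.formula(paste("~", fit$term_labels)), nd)
    groups <- lv
  }
  est <- unname(drop(L %*% fit$coefficients))
  se <- unname(sqrt(diag(L %*% fit$vcov %*% t(L))))
  zc <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(group = groups, estimate = est, se = se,
                 ci_low = est - zc * se, ci_high = est + zc * se,
                 p = 2 * pnorm(-abs(est / se)))
}

#' Egger's regression test for funnel-plot asymmetry
#'
#' Regresses the standardized effect size \eqn{z_i / SE_i} on precision
#' \eqn{1 / SE_i}; a regression intercept different from zero indicates
#' funnel asymmetry consistent with publication bias.  The intercept is tested
#' with a t-test on k - 2 degrees of freedom.
#'
#' @param effects Data frame with effect column `z` and variance column
#'   `var_z` (at least 3 rows, SEs not all equal).
#' @return A one-row tibble: `intercept`, `se`, `t`, `df`, `p`, `k`.
#' @export
egger_test <- function(effects) {
  z <- effects$z
  se_i <- sqrt(effects$var_z)
  k <- length(z)
  if (k < 3) abort("Egger's regression needs at least 3 effects.")
  if (sd(se_i) == 0) abort("Egger's regression needs varying standard errors.")
  fit <- lm(I(z / se_i) ~ I(1 / se_i))
  sm <- summary(fit)$coefficients
  tibble::tibble(intercept = sm[1, 1], se = sm[1, 2], t = sm[1, 3],
                 df = k - 2, p = sm[1, 4], k = k)
}

#' Funnel-plot data
#'
#' Extracts the plotting-ready (effect, standard error, group) table used by
#' funnel diagnostics, with the environmental-change driver as the grouping
#' covariate when present.
#'
#' @param effects Effect-size data frame with `z` and `var_z`.
#' @return A tibble with `z`, `se`, `group`.
#' @export
funnel_data <- function(effects) {
  if (nrow(effects) == 0) abort("Empty effect-size table.")
  tibble::tibble(z = effects$z, se = sqrt(effects$var_z),
                 group = effects$driver %||% rep("all", nrow(effects)))
}

#' @export
print.meta_fit <- function(x, ...) {
  cat(sprintf("Multilevel meta-analysis (%s), %d obs in %d studies\n",
              x$method, x$n, x$n_studies))
  cat("Variance components:",
      paste(sprintf("%s = %.4f", names(x$sigma2), x$sigma2), collapse = ", "),
      "\n")
  print(tidy(x), ...)
  if (!is.null(x$QM)) {
    cat(sprintf("QM(df = %d) = %.3f, p = %.4g\n", x$QM_df, x$QM, x$QM_p))
  }
  invisible(x)
}
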