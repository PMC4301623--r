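#' Natural cubic spline basis for the time trend
#'
#' Basis for the smooth time adjustment `s(t, v)`: natural cubic splines with
#' `v` degrees of freedom, boundary knots at the range of the observed
#' periods, interior knots at equally spaced quantiles, and linear
#' extrapolation beyond the boundary. `v = 0` returns an empty basis (no time
#' adjustment); `v = 1` is rejected.
#'
#' @param t period values.
#' @param v degrees of freedom (0, or 2 and above).
#' @return matrix with `length(t)` rows and `v` columns.
#' @export
natural_spline_basis <- function(t, v) {
  v <- check_count(v, "v", min = 0L)
  if (v == 1L) stopf("v = 1 is not a valid spline dimension; use 0 or >= 2")
  t <- as.numeric(t)
  if (v == 0L) return(matrix(numeric(0), nrow = length(t), ncol = 0L))
  if (length(unique(t)) < 2L) stopf("time values are constant; no spline basis")
  if (length(unique(t)) < v + 1L)
    stopf("basis with v = %d is rank-deficient over %d distinct periods",
          v, length(unique(t)))
  B <- splines::ns(t, df = v)
  colnames(B) <- paste0("s", seq_len(v))
  B
}

panel_model_data <- function(panel, v, cluster_level) {
  need <- c("child_id", "sector", "group", "period", "x", "y")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols))
    stopf("panel is missing column(s): %s", paste(missing_cols, collapse = ", "))
  panel <- panel[!is.na(panel$x), , drop = FALSE]
  if (nrow(panel) == 0L) stopf("panel is empty")
  if (length(unique(panel$x)) < 2L)
    stopf("both exposure levels must be present for identifiability")
  if (!all(panel$y %in% c(0, 1))) stopf("y must be binary 0/1")
  d <- data.frame(
    y = as.integer(panel$y),
    x = as.numeric(panel$x),
    period = as.numeric(panel$period),
    cluster = factor(if (cluster_level == "sector") panel$sector else panel$group),
    child = factor(panel$child_id)
  )
  B <- natural_spline_basis(d$period, v)
  if (v > 0) d <- cbind(d, as.data.frame(unclass(B)))
  list(data = d, v = v, spline_cols = colnames(B))
}

#' Fit the stepped-wedge ALRI analysis model
#'
#' Maximum-likelihood (Laplace approximation) fit of the logistic
#' random-intercept model for a stepped-wedge outcome panel:
#' `logit p = alpha0 + b_cluster + c_child + s(t, v) + theta * x`, with
#' mean-zero normal random intercepts for cluster ("village") and child, a
#' natural cubic spline time adjustment with `v` degrees of freedom
#' ([natural_spline_basis()]) and the fixed stove-effect coefficient `theta`
#' of primary interest. A Wald z test of `theta = 0` is reported.
#'
#' Two Laplace engines are supported: `"glmmTMB"` (default; several-fold
#' faster on full-size panels) and `"glmer"` (lme4). Both maximize the same
#' Laplace-approximate marginal likelihood and agree closely; an independent
#' adaptive Gauss-Hermite audit fitter for small panels is available as
#' [fit_alri_glmm_agq()]. Non-convergence is flagged, never silently ignored.
#'
#' @param panel data frame with columns `child_id`, `sector`, `group`,
#'   `period`, `x`, `y` (as produced by [simulate_panel()] or
#'   [read_panel()]). Rows with `x = NA` (dropped transition periods) are
#'   excluded.
#' @param v spline degrees of freedom (default 8; 0 = no time adjustment).
#' @param cluster_level `"sector"` (default) or `"group"`: the level of the
#'   village random intercept and of robust-variance aggregation.
#' @param include_child_effect include the child random intercept
#'   (default TRUE).
#' @param engine `"glmmTMB"` or `"glmer"`.
#' @param alpha test size for confidence intervals (default 0.05).
#' @return object of class `"alri_fit"`; see [summary.alri_fit()]. Key
#'   elements: `theta_hat`, `se_model`, `se_robust` (filled by
#'   [robust_variance()]), `wald_z`, `p_value`, `alpha0_hat`, `spline_coefs`,
#'   `var_village_hat`, `var_child_hat`, `loglik`, `converged`, `n_obs`.
#' @export
fit_alri_glmm <- function(panel, v = 8, cluster_level = c("sector", "group"),
                          include_child_effect = TRUE,
                          engine = c("glmmTMB", "glmer"), alpha = 0.05) {
  cluster_level <- match.arg(cluster_level)
  engine <- match.arg(engine)
  alpha <- check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  md <- panel_model_data(panel, v, cluster_level)
  d <- md$data
  re_terms <- c("(1 | cluster)", if (include_child_effect) "(1 | child)")
  fml <- reformulate(c("x", md$spline_cols, re_terms), response = "y")

  warnings_seen <- character(0)
  fit <- withCallingHandlers(
    if (engine == "glmmTMB") {
      glmmTMB::glmmTMB(fml, data = d, family = binomial(),
                       control = glmmTMB::glmmTMBControl(profile = TRUE))
    } else {
      lme4::glmer(fml, data = d, family = binomial(),
                  control = lme4::glmerControl(calc.derivs = FALSE))
    },
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  if (engine == "glmmTMB") {
    beta <- glmmTMB::fixef(fit)$cond
    Vb <- as.matrix(vcov(fit)$cond)
    vc <- glmmTMB::VarCorr(fit)$cond
    var_village <- as.numeric(vc$cluster)
    var_child <- if (include_child_effect) as.numeric(vc$child) else NA_real_
    conv <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
    ll <- as.numeric(logLik(fit))
  } else {
    beta <- lme4::fixef(fit)
    Vb <- as.matrix(vcov(fit))
    vc <- lme4::VarCorr(fit)
    var_village <- as.numeric(vc$cluster)
    var_child <- if (include_child_effect) as.numeric(vc$child) else NA_real_
    conv <- length(fit@optinfo$conv$lme4$messages) == 0L
    ll <- as.numeric(logLik(fit))
  }
  se <- sqrt(diag(Vb))
  theta_hat <- unname(beta["x"])
  se_theta <- unname(se["x"])
  separated <- is.na(se_theta) || abs(theta_hat) > 8 || se_theta > 8
  converged <- conv && !separated
  z <- theta_hat / se_theta
  structure(list(
    theta_hat = theta_hat,
    se_model = se_theta,
    se_robust = NA_real_,
    robust_ratio = NA_real_,
    use_robust = FALSE,
    wald_z = z,
    p_value = 2 * pnorm(-abs(z)),
    alpha0_hat = unname(beta["(Intercept)"]),
    spline_coefs = beta[md$spline_cols],
    beta = beta,
    vcov_fixed = Vb,
    vcov_robust = NULL,
    var_village_hat = var_village,
    var_child_hat = var_child,
    loglik = ll,
    converged = converged,
    separated = separated,
    warnings = warnings_seen,
    n_obs = nrow(d),
    n_clusters = nlevels(d$cluster),
    v = md$v, cluster_level = cluster_level,
    include_child_effect = include_child_effect,
    engine = engine, alpha = alpha,
    model_data = d, spline_cols = md$spline_cols,
    engine_fit = fit
  ), class = "alri_fit")
}

#' @export
print.alri_fit <- function(x, ...) {
  cat(sprintf("Stepped-wedge logistic mixed model (%s, Laplace; v = %d, cluster = %s)\n",
              x$engine, x$v, x$cluster_level))
  ci <- confint(x)
  cat(sprintf("  theta (stove effect): %.4f  [%.4f, %.4f]  OR %.3f\n",
              x$theta_hat, ci[1], ci[2], exp(x$theta_hat)))
  cat(sprintf("  SE: %.4f (model-based)%s\n", x$se_model,
              if (!is.na(x$se_robust)) sprintf(", %.4f (robust, ratio %.2f)",
                                               x$se_robust, x$robust_ratio) else ""))
  cat(sprintf("  Wald z = %.3f, p = %.4g\n", x$wald_z, x$p_value))
  cat(sprintf("  variances: village %.4f, child %s\n", x$var_village_hat,
              if (is.na(x$var_child_hat)) "-" else sprintf("%.4f", x$var_child_hat)))
  cat(sprintf("  n = %d obs, %d clusters; logLik %.1f; %s\n", x$n_obs,
              x$n_clusters, x$loglik,
              if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}

#' @export
summary.alri_fit <- function(object, ...) {
  print(object)
  if (length(object$warnings))
    cat("Fitting warnings:\n", paste(" -", object$warnings, collapse = "\n"), "\n")
  invisible(object)
}

#' @export
coef.alri_fit <- function(object, ...) object$beta

#' @export
vcov.alri_fit <- function(object, robust = FALSE, ...) {
  if (robust) {
    if (is.null(object$vcov_robust))
      stopf("robust variance not computed; call robust_variance() first")
    object$vcov_robust
  } else object$vcov_fixed
}

#' Wald confidence interval for the stove effect
#'
#' @param object an `alri_fit`.
#' @param parm ignored (theta only).
#' @param level confidence level (defaults to `1 - alpha` of the fit).
#' @param robust use the cluster-robust SE (requires [robust_variance()]).
#' @param ... ignored.
#' @export
confint.alri_fit <- function(object, parm = "theta", level = NULL,
                             robust = FALSE, ...) {
  level <- level %||% (1 - object$alpha)
  se <- if (robust) {
    if (is.na(object$se_robust))
      stopf("robust variance not computed; call robust_variance() first")
    object$se_robust
  } else object$se_model
  zq <- qnorm(1 - (1 - level) / 2)
  c(lower = object$theta_hat - zq * se, upper = object$theta_hat + zq * se)
}

# ---- marginal likelihood by nested Gauss-Hermite quadrature ----------------

# Log marginal likelihood contribution of one cluster:
#   l_i = log int phi(b; sd_v) prod_j [ int phi(c; sd_c) prod_t f(y|eta+b+c) dc ] db
# Xi: fixed-effect design matrix rows of the cluster; child_idx: integer child
# index per row (1..n_children); quadrature nodes from gauss_hermite().
cluster_marginal_loglik <- function(beta, Xi, yi, child_idx, sd_v, sd_c, gh) {
  eta0 <- drop(Xi %*% beta)
  nb <- if (sd_v > 0) length(gh$nodes) else 1L
  nc <- if (sd_c > 0) length(gh$nodes) else 1L
  zb <- if (sd_v > 0) sqrt(2) * sd_v * gh$nodes else 0
  zc <- if (sd_c > 0) sqrt(2) * sd_c * gh$nodes else 0
  lwb <- if (sd_v > 0) log(gh$weights) - 0.5 * log(pi) else 0
  lwc <- if (sd_c > 0) log(gh$weights) - 0.5 * log(pi) else 0
  sgn <- 2 * yi - 1
  out <- numeric(nb)
  for (k in seq_len(nb)) {
    # obs x nc matrix of sgn * (eta0 + b + c); log f(y|eta) = log plogis(sgn*eta)
    E <- outer(sgn, zc) + sgn * (eta0 + zb[k])
    LL <- plogis(E, log.p = TRUE)
    S <- rowsum(LL, child_idx)            # children x nc
    S <- sweep(S, 2L, lwc, `+`)
    m <- apply(S, 1L, max)
    la <- m + log(rowSums(exp(S - m)))    # log A_j(b) per child
    out[k] <- lwb[k] + sum(la)
  }
  logsumexp(out)
}

# Per-cluster log-likelihood pieces for an alri_fit at given fixed effects.
fit_cluster_logliks <- function(fit, beta, nq = 12) {
  d <- fit$model_data
  X <- cbind(`(Intercept)` = 1, x = d$x,
             as.matrix(d[, fit$spline_cols, drop = FALSE]))
  X <- X[, names(fit$beta), drop = FALSE]
  sd_v <- sqrt(max(fit$var_village_hat, 0))
  sd_c <- if (fit$include_child_effect) sqrt(max(fit$var_child_hat, 0)) else 0
  gh <- gauss_hermite(nq)
  vapply(levels(d$cluster), function(lev) {
    idx <- which(d$cluster == lev)
    child_idx <- as.integer(factor(d$child[idx]))
    cluster_marginal_loglik(beta, X[idx, , drop = FALSE], d$y[idx],
                            child_idx, sd_v, sd_c, gh)
  }, numeric(1))
}

#' Cluster-robust (sandwich) variance for the stove effect
#'
#' Adds a cluster-level sandwich variance estimate to an [fit_alri_glmm()]
#' fit, as a check on the assumed within-child and within-village correlation
#' model. Scores are the per-cluster gradients of the marginal log-likelihood
#' (evaluated by nested Gauss-Hermite quadrature with the variance components
#' held at their estimates) with respect to the fixed effects, obtained by
#' central finite differences; the bread is the model-based fixed-effect
#' covariance. A small-sample factor `G/(G-1)` is applied. The conventional
#' decision rule is recorded: if the robust SE is appreciably larger than the
#' model-based SE (ratio above `use_threshold`), robust SEs should be used
#' for tests and intervals (`use_robust`).
#'
#' @param fit a converged `alri_fit`.
#' @param nq quadrature nodes per random-effect level (default 12).
#' @param fd_eps relative step for finite differences (default 1e-5).
#' @param use_threshold robust/model SE ratio above which `use_robust` is set
#'   (default 1.1).
#' @return the fit, with `se_robust`, `robust_ratio`, `use_robust`,
#'   `vcov_robust` and diagnostic `score_norm` (gradient norm at the MLE,
#'   near zero for a converged fit) filled in.
#' @export
robust_variance <- function(fit, nq = 12, fd_eps = 1e-5, use_threshold = 1.1) {
  stopifnot(inherits(fit, "alri_fit"))
  if (!fit$converged)
    stopf("robust variance requires a converged fit")
  G <- fit$n_clusters
  if (G < 2L) stopf("cluster-robust variance undefined with a single cluster")
  if (G < 10L) warnf("only %d clusters; the sandwich estimator may be unstable", G)
  beta <- fit$beta
  p <- length(beta)
  h <- fd_eps * pmax(abs(beta), 1)
  scores <- matrix(0, G, p, dimnames = list(NULL, names(beta)))
  for (j in seq_len(p)) {
    bp <- beta; bp[j] <- bp[j] + h[j]
    bm <- beta; bm[j] <- bm[j] - h[j]
    scores[, j] <- (fit_cluster_logliks(fit, bp, nq) -
                    fit_cluster_logliks(fit, bm, nq)) / (2 * h[j])
  }
  M <- crossprod(scores)
  B <- fit$vcov_fixed
  V <- B %*% M %*% B * G / (G - 1)
  dimnames(V) <- dimnames(B)
  fit$vcov_robust <- V
  fit$se_robust <- sqrt(V["x", "x"])
  fit$robust_ratio <- fit$se_robust / fit$se_model
  fit$use_robust <- fit$robust_ratio > use_threshold
  fit$score_norm <- sqrt(sum(colSums(scores)^2))
  fit
}

#' Adaptive Gauss-Hermite audit fit (small panels)
#'
#' Direct maximum-likelihood fit of the same two-level logistic
#' random-intercept model by maximizing the nested Gauss-Hermite
#' approximation of the marginal likelihood with `optim`. Exact within
#' quadrature error, it serves as an independent audit of the Laplace
#' engines on small panels; it is not intended for full-size panels.
#'
#' @inheritParams fit_alri_glmm
#' @param nq quadrature nodes per level (default 15).
#' @return list with `alpha0_hat`, `theta_hat`, `spline_coefs`,
#'   `var_village_hat`, `var_child_hat`, `loglik`, `converged`.
#' @export
fit_alri_glmm_agq <- function(panel, v = 0, cluster_level = c("sector", "group"),
                              include_child_effect = TRUE, nq = 15) {
  cluster_level <- match.arg(cluster_level)
  md <- panel_model_data(panel, v, cluster_level)
  d <- md$data
  X <- cbind(`(Intercept)` = 1, x = d$x,
             as.matrix(d[, md$spline_cols, drop = FALSE]))
  gh <- gauss_hermite(nq)
  clusters <- lapply(levels(d$cluster), function(lev) {
    idx <- which(d$cluster == lev)
    list(X = X[idx, , drop = FALSE], y = d$y[idx],
         child = as.integer(factor(d$child[idx])))
  })
  p <- ncol(X)
  negll <- function(par) {
    beta <- par[seq_len(p)]
    sd_v <- exp(par[p + 1L])
    sd_c <- if (include_child_effect) exp(par[p + 2L]) else 0
    -sum(vapply(clusters, function(cl)
      cluster_marginal_loglik(beta, cl$X, cl$y, cl$child, sd_v, sd_c, gh),
      numeric(1)))
  }
  start <- c(qlogis(max(mean(d$y), 1e-3)), rep(0, p - 1L),
             log(0.15), if (include_child_effect) log(0.3))
  opt <- optim(start, negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  beta <- opt$par[seq_len(p)]
  names(beta) <- colnames(X)
  list(alpha0_hat = unname(beta[1L]),
       theta_hat = unname(beta["x"]),
       spline_coefs = beta[md$spline_cols],
       var_village_hat = exp(2 * opt$par[p + 1L]),
       var_child_hat = if (include_child_effect) exp(2 * opt$par[p + 2L]) else NA_real_,
       loglik = -opt$value,
       converged = opt$convergence == 0)
}

#' Spline-sensitivity analysis for the stove effect
#'
#' Refits the analysis model over a range of spline dimensions `v` and
#' tabulates the stove-effect estimate and confidence interval for each, to
#' assess sensitivity of the primary result to the smoothness choice
#' (a priori `v = 8` with two years of monthly data; reasonable range 4-12).
#' Values of `v` whose basis would be rank-deficient over the observed
#' periods are omitted with a warning.
#'
#' @inheritParams fit_alri_glmm
#' @param v_list spline dimensions to fit (default `4:12`).
#' @return data frame of class `"v_sensitivity"`: one row per fitted `v` with
#'   `theta_hat`, `se_model`, `ci_lower`, `ci_upper`, `converged`, `loglik`.
#' @export
sensitivity_over_v <- function(panel, v_list = 4:12,
                               cluster_level = c("sector", "group"),
                               engine = c("glmmTMB", "glmer"), alpha = 0.05) {
  cluster_level <- match.arg(cluster_level)
  engine <- match.arg(engine)
  n_distinct <- length(unique(panel$period[!is.na(panel$x)]))
  rows <- lapply(v_list, function(v) {
    if (v != 0 && n_distinct < v + 1L) {
      warnf("v = %d omitted: basis rank-deficient over %d distinct periods",
            v, n_distinct)
      return(NULL)
    }
    f <- fit_alri_glmm(panel, v = v, cluster_level = cluster_level,
                       engine = engine, alpha = alpha)
    ci <- confint(f)
    data.frame(v = v, theta_hat = f$theta_hat, se_model = f$se_model,
               ci_lower = ci[1], ci_upper = ci[2],
               converged = f$converged, loglik = f$loglik)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("v_sensitivity", "data.frame")
  out
}

#' @export
print.v_sensitivity <- function(x, ...) {
  cat("Stove-effect sensitivity to spline dimension v\n")
  print.data.frame(cbind(x[1], round(as.data.frame(x[-1])[1:4], 4),
                         x[c("converged")]))
  invisible(x)
}

#' Birthweight treatment-effect model
#'
#' Fits the treatment effect on birthweight with sector (cluster) random
#' intercepts: a linear mixed model for continuous birthweight, or a logistic
#' mixed model for low birthweight (LBW, strictly below `lbw_cutoff` grams).
#' Model-based and cluster-robust standard errors are reported.
#'
#' @param bw data frame with columns `cluster`, `treated` (logical/0-1) and
#'   `weight` (grams), as from [simulate_birthweights()].
#' @param outcome `"continuous"` (grams) or `"lbw"` (log-odds of low
#'   birthweight).
#' @param lbw_cutoff low-birthweight threshold in grams (default 2500;
#'   strict `<`).
#' @return list with `effect`, `se_model`, `se_robust`, `icc_hat` (continuous
#'   only), `n`, `n_clusters`, `outcome`, `fit`.
#' @export
fit_birthweight <- function(bw, outcome = c("continuous", "lbw"),
                            lbw_cutoff = 2500) {
  outcome <- match.arg(outcome)
  need <- c("cluster", "treated", "weight")
  missing_cols <- setdiff(need, names(bw))
  if (length(missing_cols))
    stopf("bw is missing column(s): %s", paste(missing_cols, collapse = ", "))
  d <- data.frame(cluster = factor(bw$cluster),
                  treated = as.numeric(as.logical(bw$treated)),
                  weight = as.numeric(bw$weight))
  arms <- tapply(d$treated, d$cluster, mean)
  if (nlevels(d$cluster) < 4L || length(unique(round(arms))) < 2L)
    stopf("need at least 2 clusters per arm")
  if (outcome == "continuous") {
    fit <- lme4::lmer(weight ~ treated + (1 | cluster), data = d, REML = TRUE)
    Vr <- lmm_cluster_sandwich(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    tau2 <- vc$vcov[1L]; sig2 <- vc$vcov[vc$grp == "Residual"]
    list(effect = unname(lme4::fixef(fit)["treated"]),
         se_model = unname(sqrt(diag(as.matrix(vcov(fit)))["treated"])),
         se_robust = sqrt(Vr["treated", "treated"]),
         icc_hat = tau2 / (tau2 + sig2),
         n = nrow(d), n_clusters = nlevels(d$cluster),
         outcome = outcome, fit = fit)
  } else {
    d$lbw <- as.integer(d$weight < lbw_cutoff)
    fit <- lme4::glmer(lbw ~ treated + (1 | cluster), data = d,
                       family = binomial())
    # sandwich via the shared quadrature machinery: each birth is its own
    # "child" with a degenerate child effect
    beta <- lme4::fixef(fit)
    sd_v <- sqrt(as.numeric(lme4::VarCorr(fit)$cluster))
    gh <- gauss_hermite(15)
    X <- cbind(`(Intercept)` = 1, treated = d$treated)
    levs <- levels(d$cluster)
    sc <- function(b) vapply(levs, function(lev) {
      idx <- which(d$cluster == lev)
      cluster_marginal_loglik(b, X[idx, , drop = FALSE], d$lbw[idx],
                              seq_along(idx), sd_v, 0, gh)
    }, numeric(1))
    p <- length(beta)
    h <- 1e-5 * pmax(abs(beta), 1)
    S <- sapply(seq_len(p), function(j) {
      bp <- beta; bp[j] <- bp[j] + h[j]
      bm <- beta; bm[j] <- bm[j] - h[j]
      (sc(bp) - sc(bm)) / (2 * h[j])
    })
    G <- length(levs)
    B <- as.matrix(vcov(fit))
    V <- B %*% crossprod(S) %*% B * G / (G - 1)
    list(effect = unname(beta["treated"]),
         se_model = unname(sqrt(diag(B)[2L])),
         se_robust = sqrt(V[2L, 2L]),
         icc_hat = NA_real_,
         lbw_rate = mean(d$lbw),
         n = nrow(d), n_clusters = G,
         outcome = outcome, fit = fit)
  }
}
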