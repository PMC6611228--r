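# Linear-quadratic survival fitting. The response is y = -ln(SF), the
# model y = alpha*D + beta*D^2 + b_i + e with no fixed intercept and a
# random intercept b_i per replicate set (biological repeat), estimated
# by REML profiled over the variance ratio sigma_b^2 / sigma_e^2.

#' Surviving fraction of a clonogenic well
#'
#' Colonies per plated cell, normalised by the plating efficiency of
#' unirradiated controls. Zero-colony wells return 0; they cannot enter
#' a log-domain fit and are flagged by [prepare_survival_data()].
#'
#' @param colonies Colonies counted (vectorised).
#' @param plated Cells plated.
#' @param plating_efficiency Fraction of unirradiated cells forming
#'   colonies, in (0, 1].
#' @return Surviving fraction(s).
#' @examples
#' surviving_fraction(150, 5000, 0.6)  # 0.05
#' @export
surviving_fraction <- function(colonies, plated, plating_efficiency) {
  stopifnot(all(plating_efficiency > 0), all(plating_efficiency <= 1),
            all(plated > 0), all(colonies >= 0))
  (colonies / plated) / plating_efficiency
}

#' Plating efficiency of each replicate set
#'
#' Estimated from the 0 Gy control wells of the same replicate set, so
#' normalised survival averages one in the controls by construction.
#'
#' @param records Data frame with columns `dose_Gy`, `colonies`,
#'   `plated`, `replicate_set`.
#' @return Named numeric vector of plating efficiencies per set.
#' @export
plating_efficiency <- function(records) {
  ctrl <- records[records$dose_Gy == 0, ]
  if (nrow(ctrl) == 0L) stop("no 0 Gy control wells to estimate plating efficiency")
  pe <- c(tapply(ctrl$colonies / ctrl$plated, ctrl$replicate_set, mean))
  if (any(pe <= 0)) stop("a replicate set has zero colonies in all control wells")
  pe
}

#' Attach surviving fractions and the log-survival response
#'
#' Computes per-set plating efficiencies, surviving fractions and
#' y = -ln(SF); wells with non-positive SF are flagged `excluded` (they
#' have no log-domain response).
#'
#' @param records Data frame of assay wells with columns `dose_Gy`,
#'   `colonies`, `plated`, `replicate_set` (and any others, carried
#'   through).
#' @return The input with columns `pe`, `sf`, `y` and `excluded` added.
#' @export
prepare_survival_data <- function(records) {
  stopifnot(all(c("dose_Gy", "colonies", "plated", "replicate_set") %in%
                  names(records)))
  pe <- plating_efficiency(records)
  records$pe <- pe[as.character(records$replicate_set)]
  records$sf <- surviving_fraction(records$colonies, records$plated, records$pe)
  records$excluded <- records$sf <= 0
  records$y <- as.numeric(ifelse(records$excluded, NA_real_, -log(records$sf)))
  records
}

# REML criterion for y = X theta + Z b + e, random intercept per group,
# profiled over r = sigma_b^2 / sigma_e^2. Returns -2 * restricted
# log-likelihood up to a constant. Sizes here are tens of wells, so a
# dense V is simplest and exact.
.reml_crit <- function(r, y, X, group) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(n)
  for (g in split(seq_len(n), group)) V[g, g] <- V[g, g] + r
  cV <- chol(V)
  Vinv_X <- backsolve(cV, forwardsolve(t(cV), X))
  Vinv_y <- backsolve(cV, forwardsolve(t(cV), y))
  XtVX <- crossprod(X, Vinv_X)
  theta <- solve(XtVX, crossprod(X, Vinv_y))
  resid <- y - X %*% theta
  Vinv_r <- backsolve(cV, forwardsolve(t(cV), resid))
  rss <- drop(crossprod(resid, Vinv_r))
  crit <- 2 * sum(log(diag(cV))) + determinant(XtVX)$modulus +
    (n - p) * log(rss)
  list(crit = as.numeric(crit), theta = drop(theta), rss = rss,
       XtVX = XtVX)
}

#' Fit the linear-quadratic model to clonogenic assay data
#'
#' Fits \eqn{-\ln(SF) = \alpha D + \beta D^2 + b_i + \epsilon} by
#' restricted maximum likelihood, with a random intercept \eqn{b_i} per
#' replicate set. There is no fixed intercept, so the population survival
#' curve passes through SF(0) = 1 exactly. The variance ratio
#' \eqn{\sigma_b^2/\sigma_e^2} is profiled out and located by bounded
#' scalar search; a flat profile resolves to \eqn{\sigma_b = 0}. beta is
#' not constrained non-negative; `alpha_only = TRUE` refits with the
#' quadratic column dropped (beta fixed at 0).
#'
#' Wells with non-positive surviving fraction are excluded with a
#' warning. A single replicate set cannot support a random intercept; the
#' fit then degrades to fixed-effects least squares with a warning.
#'
#' @param records Data frame of assay wells (see
#'   [prepare_survival_data()]); typically one cell line x modality.
#' @param alpha_only Drop the quadratic term?
#' @return An object of class `lq_fit`: coefficients `alpha`, `beta`,
#'   their covariance matrix `vcov`, variance components `sigma_b` and
#'   `sigma_e`, Wald p-values, counts, and the excluded wells.
#' @examples
#' spec <- simulation_spec(alpha = 0.273, beta = 0.0189, seed = 1)
#' fit <- fit_lqm(simulate_clonogenic(spec))
#' fit$alpha
#' @export
fit_lqm <- function(records, alpha_only = FALSE) {
  dat <- prepare_survival_data(records)
  n_excluded <- sum(dat$excluded)
  if (n_excluded > 0) {
    warning(n_excluded, " well(s) with non-positive surviving fraction ",
            "excluded from the log-domain fit")
  }
  excluded <- dat[dat$excluded, , drop = FALSE]
  dat <- dat[!dat$excluded, , drop = FALSE]
  doses <- unique(dat$dose_Gy[dat$dose_Gy > 0])
  min_doses <- if (alpha_only) 1L else 2L
  if (length(doses) < min_doses) {
    stop("need at least ", min_doses, " distinct positive dose(s); ",
         "the design matrix is singular")
  }
  y <- dat$y
  X <- if (alpha_only) cbind(D = dat$dose_Gy) else
    cbind(D = dat$dose_Gy, D2 = dat$dose_Gy^2)
  group <- factor(dat$replicate_set)
  n_groups <- nlevels(group)

  if (n_groups < 2L) {
    warning("only one replicate set: the random intercept is inestimable; ",
            "falling back to fixed-effects least squares")
    r_hat <- 0
  } else {
    crit_fun <- function(u) .reml_crit(expm1(u), y, X, group)$crit
    opt <- stats::optimize(crit_fun, c(0, log1p(1e3)), tol = 1e-10)
    # a flat or boundary-preferring profile resolves toward sigma_b = 0
    r_hat <- if (crit_fun(0) <= opt$objective + 1e-8) 0 else expm1(opt$minimum)
  }

  sol <- .reml_crit(r_hat, y, X, group)
  n <- length(y)
  p <- ncol(X)
  sigma_e2 <- sol$rss / (n - p)
  vc <- sigma_e2 * solve(sol$XtVX)
  alpha <- unname(sol$theta[1])
  beta <- if (alpha_only) 0 else unname(sol$theta[2])
  vcov2 <- matrix(0, 2, 2, dimnames = list(c("alpha", "beta"),
                                           c("alpha", "beta")))
  vcov2[seq_len(p), seq_len(p)] <- vc

  se_alpha <- sqrt(vcov2[1, 1])
  se_beta <- if (alpha_only) NA_real_ else sqrt(vcov2[2, 2])
  structure(list(
    alpha = alpha, beta = beta, vcov = vcov2,
    var_alpha = vcov2[1, 1], var_beta = vcov2[2, 2],
    cov_alpha_beta = vcov2[1, 2],
    sigma_b = sqrt(r_hat * sigma_e2), sigma_e = sqrt(sigma_e2),
    wald_p_alpha = wald_test(alpha, se_alpha),
    wald_p_beta = if (alpha_only) NA_real_ else wald_test(beta, se_beta),
    n_obs = n, n_groups = n_groups, alpha_only = alpha_only,
    excluded = excluded
  ), class = "lq_fit")
}

#' @export
print.lq_fit <- function(x, ...) {
  cat("Linear-quadratic survival fit",
      if (x$alpha_only) "(alpha-only)" else "", "\n")
  cat(sprintf("  alpha = %.4g Gy^-1 (SE %.3g, Wald p = %.3g)\n",
              x$alpha, sqrt(x$var_alpha), x$wald_p_alpha))
  if (!x$alpha_only) {
    cat(sprintf("  beta  = %.4g Gy^-2 (SE %.3g, Wald p = %.3g)\n",
                x$beta, sqrt(x$var_beta), x$wald_p_beta))
  }
  cat(sprintf("  sigma_b = %.4g, sigma_e = %.4g, n = %d wells in %d sets\n",
              x$sigma_b, x$sigma_e, x$n_obs, x$n_groups))
  invisible(x)
}

#' Alpha/beta ratio with a delta-method standard error
#'
#' \deqn{SE = \sqrt{\frac{1}{\beta^2}var(\alpha)
#'   - \frac{2\alpha}{\beta^3}cov(\alpha,\beta)
#'   + \frac{\alpha^2}{\beta^4}var(\beta)}}
#' with a normal-approximation 95\% interval.
#'
#' @param fit An `lq_fit` object (beta must be estimated, not fixed).
#' @return A list of class `ratio_estimate` with `value`, `se`,
#'   `ci_low`, `ci_high`.
#' @export
alpha_beta_ratio <- function(fit) {
  stopifnot(inherits(fit, "lq_fit"))
  if (fit$alpha_only || fit$beta == 0) {
    stop("alpha/beta is undefined for an alpha-only fit (beta = 0)")
  }
  a <- fit$alpha
  b <- fit$beta
  se <- sqrt((1 / b^2) * fit$var_alpha -
               (2 * a / b^3) * fit$cov_alpha_beta +
               (a^2 / b^4) * fit$var_beta)
  value <- a / b
  structure(list(value = value, se = se,
                 ci_low = value - 1.96 * se, ci_high = value + 1.96 * se),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("alpha/beta = %.4g Gy (SE %.3g, 95%% CI %.4g to %.4g)\n",
              x$value, x$se, x$ci_low, x$ci_high))
  invisible(x)
}

#' Two-sided Wald test against zero
#'
#' @param estimate Point estimate.
#' @param se Standard error (non-negative).
#' @return Two-sided p-value.
#' @export
wald_test <- function(estimate, se) {
  stopifnot(se >= 0)
  if (se == 0) return(if (estimate == 0) 1 else 0)
  2 * stats::pnorm(-abs(estimate / se))
}
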