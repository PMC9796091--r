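# Trio variance-component model.
#
# Phenotype model: y = Xb + g_o + g_m + g_p + e, with the three genetic values
# correlated across individuals through the GRM role-blocks:
#   V = s2o A_oo + s2m A_mm + s2p A_pp + s_om (A_om + A_om') +
#       s_op (A_op + A_op') + s_mp (A_mp + A_mp') + s2e I.
# All specifications are linear in a 7-vector of coefficients
# (s2o, s2m, s2p, s_om, s_op, s_mp, s2e); each nested spec maps its free
# parameters onto that vector through a constant matrix M.

COMP7 <- c("sigma2_o", "sigma2_m", "sigma2_p", "sigma_om", "sigma_op",
           "sigma_mp", "sigma2_e")
# phenotypic-variance accounting: parent-offspring covariances count once,
# the mother-father covariance not at all
ACCT7 <- c(1, 1, 1, 1, 1, 0, 1)

#' Nested model specifications
#'
#' The four nested specifications of genetic effects on an offspring
#' phenotype:
#' \describe{
#'   \item{differential}{maternal and paternal indirect effects free:
#'     7 variance parameters (\eqn{\sigma_o^2, \sigma_m^2, \sigma_p^2,
#'     \sigma_{om}, \sigma_{op}, \sigma_{mp}, \sigma_\epsilon^2}).}
#'   \item{combined}{a single combined parental effect: maternal and paternal
#'     effects equal and perfectly correlated
#'     (\eqn{\sigma_m^2=\sigma_p^2=\sigma_{mp}}, here `sigma2_par`) and
#'     equally correlated with the direct effect
#'     (\eqn{\sigma_{om}=\sigma_{op}}, here `sigma_opar`); 4 parameters.}
#'   \item{no_parental}{direct genetic effects only (GRM-based heritability
#'     estimation); 2 parameters.}
#'   \item{null}{residual variance only; 1 parameter.}
#' }
#' Every specification additionally carries an intercept and a sex fixed
#' effect. Parameters are internally transformed (log-Cholesky of the implied
#' genetic covariance, log residual variance) so variances stay non-negative
#' and the genetic covariance positive semi-definite, with the boundary
#' reachable in the limit; implied effect correlations are thereby bounded in
#' \[-1, 1\].
#'
#' @param name one of `"differential"`, `"combined"`, `"no_parental"`,
#'   `"null"`.
#' @return object of class `vc_spec` with the parameter names, count, the
#'   linear map onto the 7 covariance coefficients, and the transform pair.
#' @export
vc_spec <- function(name = c("differential", "combined", "no_parental", "null")) {
  name <- match.arg(name)
  chol_psd <- function(S) {
    # Cholesky tolerant of a (near-)singular target, for start values only
    out <- tryCatch(t(chol(S)), error = function(e) NULL)
    if (is.null(out)) out <- t(chol(S + diag(1e-6 * max(diag(S), 1e-6), nrow(S))))
    out
  }
  spec <- switch(name,
    differential = list(
      par_names = COMP7, df = 7L,
      M = diag(7),
      trans_to_raw = function(t) {
        L <- matrix(0, 3, 3)
        diag(L) <- exp(t[c(1, 4, 6)])
        L[2, 1] <- t[2]; L[3, 1] <- t[3]; L[3, 2] <- t[5]
        S <- L %*% t(L)
        c(S[1, 1], S[2, 2], S[3, 3], S[1, 2], S[1, 3], S[2, 3], exp(2 * t[7]))
      },
      raw_to_trans = function(r) {
        S <- matrix(c(r[1], r[4], r[5], r[4], r[2], r[6], r[5], r[6], r[3]), 3, 3)
        L <- chol_psd(S)
        c(log(L[1, 1]), L[2, 1], L[3, 1], log(L[2, 2]), L[3, 2], log(L[3, 3]),
          0.5 * log(r[7]))
      }),
    combined = list(
      par_names = c("sigma2_o", "sigma2_par", "sigma_opar", "sigma2_e"), df = 4L,
      # coef7 = (s2o, tau, tau, gamma, gamma, tau, s2e) for raw (s2o, tau, gamma, s2e)
      M = matrix(c(1, 0, 0, 0,
                   0, 1, 0, 0,
                   0, 1, 0, 0,
                   0, 0, 1, 0,
                   0, 0, 1, 0,
                   0, 1, 0, 0,
                   0, 0, 0, 1), 7, 4, byrow = TRUE),
      trans_to_raw = function(t) {
        l11 <- exp(t[1]); l21 <- t[2]; l22 <- exp(t[3])
        c(l11^2, l21^2 + l22^2, l11 * l21, exp(2 * t[4]))
      },
      raw_to_trans = function(r) {
        S <- matrix(c(r[1], r[3], r[3], r[2]), 2, 2)
        L <- chol_psd(S)
        c(log(L[1, 1]), L[2, 1], log(L[2, 2]), 0.5 * log(r[4]))
      }),
    no_parental = list(
      par_names = c("sigma2_o", "sigma2_e"), df = 2L,
      M = matrix(c(1, 0,
                   0, 0,
                   0, 0,
                   0, 0,
                   0, 0,
                   0, 0,
                   0, 1), 7, 2, byrow = TRUE),
      trans_to_raw = function(t) exp(2 * t),
      raw_to_trans = function(r) 0.5 * log(r)),
    null = list(
      par_names = "sigma2_e", df = 1L,
      M = matrix(c(0, 0, 0, 0, 0, 0, 1), 7, 1),
      trans_to_raw = function(t) exp(2 * t),
      raw_to_trans = function(r) 0.5 * log(r)))
  structure(c(list(name = name), spec), class = "vc_spec")
}

# The seven N x N component matrices of the covariance model, built once per
# dataset and reused across likelihood evaluations.
vc_components <- function(grms) {
  stopifnot(inherits(grms, "grm_set"))
  list(grms$A_oo, grms$A_mm, grms$A_pp,
       grms$A_om + t(grms$A_om), grms$A_op + t(grms$A_op),
       grms$A_mp + t(grms$A_mp), diag(grms$n))
}

#' Build the trio phenotypic covariance matrix
#'
#' Assembles \eqn{V(\theta)} for a specification's raw parameter vector, with
#' the spec's equality constraints substituted (e.g. the combined spec weights
#' \eqn{A_{mm}+A_{pp}+A_{mp}+A_{mp}'} by the per-parent variance and
#' \eqn{A_{om}+A_{om}'+A_{op}+A_{op}'} by the per-parent covariance).
#'
#' @param grms a [trio_grm_blocks()] result.
#' @param theta raw parameter vector matching `spec$par_names`.
#' @param spec a [vc_spec()].
#' @return symmetric N x N covariance matrix.
#' @export
build_covariance <- function(grms, theta, spec) {
  if (length(theta) != length(spec$par_names))
    tv_stop("theta length does not match spec", "triovc_input_error")
  comps <- vc_components(grms)
  coef7 <- as.vector(spec$M %*% theta)
  V <- matrix(0, grms$n, grms$n)
  for (j in which(coef7 != 0)) V <- V + coef7[j] * comps[[j]]
  if (max(abs(V - t(V))) > 1e-8 * max(abs(V), 1))
    tv_stop("covariance matrix not symmetric", "triovc_internal_error")
  (V + t(V)) / 2
}

# Core evaluator. Returns -2 log profile likelihood (fixed effects profiled
# out by GLS); optionally the analytic gradient with respect to the spec's
# raw parameters. One Cholesky per call; the inverse is formed only when the
# gradient is requested.
vc_nll <- function(theta, y, X, comps, spec, gradient = FALSE) {
  coef7 <- as.vector(spec$M %*% theta)
  n <- length(y)
  V <- matrix(0, n, n)
  for (j in which(coef7 != 0)) V <- V + coef7[j] * comps[[j]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    val <- 1e10 + sum(theta^2)
    attr(val, "ok") <- FALSE
    if (gradient) attr(val, "gradient") <- rep(0, length(theta))
    return(val)
  }
  logdet <- 2 * sum(log(diag(ch)))
  u <- backsolve(ch, cbind(y, X), transpose = TRUE)   # L^{-1} [y X]
  uy <- u[, 1]; uX <- u[, -1, drop = FALSE]
  XtViX <- crossprod(uX)
  beta <- solve(XtViX, crossprod(uX, uy))
  ur <- uy - uX %*% beta
  quad <- sum(ur^2)
  val <- n * log(2 * pi) + logdet + quad
  attr(val, "ok") <- TRUE
  attr(val, "beta") <- drop(beta)
  attr(val, "XtViX") <- XtViX
  if (gradient) {
    Vi <- chol2inv(ch)
    r <- y - X %*% beta
    Vir <- Vi %*% r
    g7 <- numeric(7)
    for (j in which(rowSums(abs(spec$M)) > 0)) {
      Cj <- comps[[j]]
      # full-ML profile score: d(-2 pll)/dc_j = tr(V^{-1} C_j) - u' C_j u,
      # u = V^{-1} r (the beta-hat term vanishes by the envelope theorem)
      g7[j] <- sum(Vi * Cj) - sum(Vir * (Cj %*% Vir))
    }
    attr(val, "gradient") <- drop(t(spec$M) %*% g7)
  }
  val
}

#' -2 log profile likelihood of a trio variance-component model
#'
#' Evaluates \eqn{-2 \log} of the multivariate normal likelihood of `y` with
#' mean \eqn{X\hat\beta(\theta)} (generalized-least-squares profile of the
#' fixed effects) and covariance \eqn{V(\theta)}. When \eqn{V} is not positive
#' definite a large penalized value is returned with attribute `ok = FALSE`
#' so optimizers can recover.
#'
#' @param theta raw parameter vector for `spec`.
#' @param y phenotype vector (one entry per trio offspring).
#' @param X fixed-effect design matrix (intercept and sex).
#' @param grms a [trio_grm_blocks()] result.
#' @param spec a [vc_spec()].
#' @return numeric value with attributes `ok`, `beta` (the GLS fixed-effect
#'   estimates) and, via the internal fitting path, the analytic gradient.
#' @export
neg2_loglik <- function(theta, y, X, grms, spec) {
  vc_nll(theta, y, X, vc_components(grms), spec)
}

#' Fitting options
#'
#' @param rel_tol relative convergence tolerance on -2ll.
#' @param max_iter maximum optimizer iterations.
#' @param all_starts optimize from all three deterministic starts instead of
#'   screening them by objective value and optimizing from the best (the
#'   remaining starts are still used as fallbacks on non-convergence).
#' @param se compute delta-method standard errors from the observed
#'   information at the optimum.
#' @param extra_starts optional list of additional raw-scale start vectors
#'   (used by [fit_all_specs()] to warm-start each model from the optimum of
#'   the spec nested in it, which guarantees -2ll is monotone along the
#'   nesting chain).
#' @return list of options for [fit_vc()].
#' @export
fit_options <- function(rel_tol = 1e-8, max_iter = 500, all_starts = FALSE,
                        se = TRUE, extra_starts = NULL) {
  list(rel_tol = rel_tol, max_iter = max_iter, all_starts = all_starts,
       se = se, extra_starts = extra_starts)
}

# Three deterministic initializations on the raw scale, anchored at the ML
# residual variance of y after regressing on X: an equal split, a
# direct-heavy split and a residual-heavy split.
vc_starts <- function(spec, s2) {
  mk <- function(so, sm, sp, com, cop, cmp, se) {
    switch(spec$name,
           differential = c(so, sm, sp, com, cop, cmp, se) * s2,
           combined = c(so, (sm + sp) / 2, (com + cop) / 2, se) * s2,
           no_parental = c(so + sm + sp, se) * s2,
           null = se * s2)
  }
  list(equal = mk(1/6, 1/6, 1/6, 0, 0, 0, 0.5),
       direct = mk(0.6, 0.05, 0.05, 0, 0, 0, 0.3),
       residual = mk(0.05, 0.025, 0.025, 0, 0, 0, 0.9))
}

#' Fit a trio variance-component model by maximum likelihood
#'
#' Maximizes the Gaussian likelihood over the specification's variance
#' parameters with a quasi-Newton optimizer on transformed parameters
#' (log-Cholesky of the implied genetic covariance, log residual variance),
#' using the analytic score. Three deterministic initializations are
#' screened by objective value; optimization runs from the best and falls
#' back to the others if it fails to converge (set
#' `fit_options(all_starts = TRUE)` to optimize from every start). Standard
#' errors come from the inverse observed information at the optimum (central
#' finite differences of the analytic score on the raw scale); the fit is
#' standardized with [standardize_fit()] on success.
#'
#' @param spec a [vc_spec()] (or its name).
#' @param y complete phenotype vector (listwise deletion upstream).
#' @param X fixed-effect design matrix; default intercept-only; use
#'   `cbind(1, sex)` for the sex-adjusted model.
#' @param grms a [trio_grm_blocks()] result.
#' @param options a [fit_options()] list.
#' @return object of class `vc_fit`: raw `estimates`, `coef7` (the implied
#'   7-component vector), `fixed_effects`, `neg2_loglik`, `df`, `se`
#'   (raw-scale), `vcov_raw`, `standardized` (list `est`, `se`, `total`),
#'   `converged`, `n_trios`, `n_fixed`, `start_used`, `iterations`.
#' @export
fit_vc <- function(spec, y, X = NULL, grms = NULL, options = fit_options()) {
  if (is.character(spec)) spec <- vc_spec(spec)
  stopifnot(inherits(spec, "vc_spec"))
  if (is.null(X)) X <- matrix(1, length(y), 1)
  X <- as.matrix(X)
  if (anyNA(y) || anyNA(X))
    tv_stop("y and X must be complete (apply listwise deletion first)",
            "triovc_input_error")
  if (nrow(X) != length(y) || grms$n != length(y))
    tv_stop("y, X and grms sizes disagree", "triovc_input_error")
  comps <- vc_components(grms)
  s2 <- mean(lm.fit(X, y)$residuals^2)
  starts <- vc_starts(spec, s2)
  if (!is.null(options$extra_starts)) {
    extra <- options$extra_starts
    names(extra) <- paste0("extra", seq_along(extra))
    starts <- c(starts, extra)
  }

  cache <- new.env(parent = emptyenv())
  fn <- function(t) {
    if (!is.null(cache$t) && identical(t, cache$t)) return(cache$val)
    v <- vc_nll(spec$trans_to_raw(t), y, X, comps, spec)
    as.numeric(v)
  }
  gr <- function(t) {
    raw <- spec$trans_to_raw(t)
    v <- vc_nll(raw, y, X, comps, spec, gradient = TRUE)
    cache$t <- t; cache$val <- as.numeric(v)
    J <- num_jacobian(spec$trans_to_raw, t)
    drop(t(J) %*% attr(v, "gradient"))
  }

  t_starts <- lapply(starts, function(r) spec$raw_to_trans(pmax_raw(spec, r)))
  vals <- vapply(t_starts, fn, numeric(1))
  best <- NULL
  for (k in order(vals)) {
    res <- nlminb(t_starts[[k]], fn, gr,
                  control = list(rel.tol = options$rel_tol,
                                 iter.max = options$max_iter,
                                 eval.max = 4 * options$max_iter))
    res$start <- names(starts)[k]
    res$converged <- res$convergence == 0 && is.finite(res$objective) &&
      res$objective < 1e9
    if (is.null(best) || res$objective < best$objective - 1e-9 ||
        (res$converged && !best$converged && res$objective < best$objective + 1e-6))
      best <- res
    if (!options$all_starts && best$converged) break
  }
  theta_hat <- spec$trans_to_raw(best$par)
  names(theta_hat) <- spec$par_names
  at_opt <- vc_nll(theta_hat, y, X, comps, spec)
  coef7 <- as.vector(spec$M %*% theta_hat)
  names(coef7) <- COMP7
  se_raw <- rep(NA_real_, length(theta_hat)); vcov_raw <- NULL
  if (options$se && best$converged) {
    H <- obs_information(theta_hat, y, X, comps, spec)
    vcov_raw <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vcov_raw) && all(diag(vcov_raw) >= 0)) {
      se_raw <- sqrt(diag(vcov_raw))
    } else if (!is.null(vcov_raw)) {
      se_raw <- sqrt(pmax(diag(vcov_raw), 0))
      se_raw[diag(vcov_raw) < 0] <- NA_real_
    }
    if (!is.null(vcov_raw)) dimnames(vcov_raw) <- list(spec$par_names, spec$par_names)
    names(se_raw) <- spec$par_names
  }
  XtViX <- attr(at_opt, "XtViX")
  fit <- structure(list(
    spec = spec, estimates = theta_hat, coef7 = coef7,
    fixed_effects = setNames(attr(at_opt, "beta"),
                             colnames(X, do.NULL = FALSE, prefix = "x")),
    fixed_vcov = solve(XtViX),
    neg2_loglik = as.numeric(at_opt), df = spec$df,
    se = se_raw, vcov_raw = vcov_raw,
    standardized = NULL, converged = best$converged,
    n_trios = length(y), n_fixed = ncol(X),
    start_used = best$start, iterations = best$iterations,
    message = best$message), class = "vc_fit")
  if (fit$converged)
    fit <- tryCatch(standardize_fit(fit), error = function(e) fit)
  fit
}

# Keep start values strictly inside the parameter space.
pmax_raw <- function(spec, r) {
  eps <- 1e-8
  if (spec$name == "differential") {
    r[c(1, 2, 3, 7)] <- pmax(r[c(1, 2, 3, 7)], eps)
  } else if (spec$name == "combined") {
    r[c(1, 2, 4)] <- pmax(r[c(1, 2, 4)], eps)
  } else r <- pmax(r, eps)
  r
}

# Central finite-difference Jacobian of a vector map (used for the chain rule
# through the log-Cholesky transform; the map is cheap, so FD is exact enough
# at h ~ 1e-6).
num_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    hj <- h * max(abs(x[j]), 1)
    xp <- x; xp[j] <- xp[j] + hj
    xm <- x; xm[j] <- xm[j] - hj
    J[, j] <- (f(xp) - f(xm)) / (2 * hj)
  }
  J
}

# Observed information on the raw scale: central finite differences of the
# analytic score of the log-likelihood (= -score of -2ll / 2).
obs_information <- function(theta, y, X, comps, spec, h = 1e-5) {
  k <- length(theta)
  H <- matrix(NA_real_, k, k)
  for (j in seq_len(k)) {
    hj <- h * max(abs(theta[j]), 1e-3)
    tp <- theta; tp[j] <- tp[j] + hj
    tm <- theta; tm[j] <- tm[j] - hj
    gp <- attr(vc_nll(tp, y, X, comps, spec, gradient = TRUE), "gradient")
    gm <- attr(vc_nll(tm, y, X, comps, spec, gradient = TRUE), "gradient")
    H[, j] <- (gp - gm) / (2 * hj)
  }
  0.5 * (H + t(H)) / 2   # Hessian of -2ll, halved -> observed information
}

#' Standardize a fitted model
#'
#' Rescales the variance-component estimates so the model-implied total
#' phenotypic variance conditional on the fixed effects,
#' \eqn{\sigma_o^2+\sigma_m^2+\sigma_p^2+\sigma_{om}+\sigma_{op}+
#' \sigma_\epsilon^2}, equals one (\eqn{\sigma_{mp}} is excluded from the
#' accounting because unrelated mates contribute no covariance to the
#' phenotype). Standard errors are mapped by the delta method through the
#' rescaling.
#'
#' @param fit a converged [fit_vc()] result.
#' @return the fit with its `standardized` element filled (`est` and `se` are
#'   named 7-component vectors, `total` the raw model-implied variance).
#' @export
standardize_fit <- function(fit) {
  stopifnot(inherits(fit, "vc_fit"))
  if (!isTRUE(fit$converged))
    tv_stop("cannot standardize a non-converged fit", "triovc_input_error")
  total <- sum(fit$coef7 * ACCT7)
  if (!is.finite(total) || total <= 0)
    tv_stop("model-implied total variance is not positive (degenerate fit)",
            "triovc_input_error")
  std <- fit$coef7 / total
  se7 <- rep(NA_real_, 7)
  if (!is.null(fit$vcov_raw)) {
    a <- as.vector(t(ACCT7) %*% fit$spec$M)        # d total / d raw
    J <- fit$spec$M / total - outer(fit$coef7, a) / total^2
    se7 <- sqrt(pmax(diag(J %*% fit$vcov_raw %*% t(J)), 0))
  }
  names(std) <- names(se7) <- COMP7
  fit$standardized <- list(est = std, se = se7, total = total)
  fit
}

#' @export
print.vc_fit <- function(x, digits = 3, ...) {
  cat(sprintf("vc_fit: '%s' spec, %d trios, %s\n", x$spec$name, x$n_trios,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  -2 log lik: %.2f   (df = %d, start = %s)\n",
              x$neg2_loglik, x$df, x$start_used))
  est <- cbind(estimate = x$estimates, se = x$se)
  print(round(est, digits))
  if (!is.null(x$standardized)) {
    cat(sprintf("  standardized (total = %.3f):\n", x$standardized$total))
    print(round(rbind(est = x$standardized$est, se = x$standardized$se), digits))
  }
  invisible(x)
}

#' Fit all four nested specifications
#'
#' Models are fitted smallest first and each larger specification receives
#' the optimum of the model nested in it as an additional start (the nested
#' solution is a feasible point of the larger model), so the maximized
#' likelihood is monotone non-decreasing along the nesting chain by
#' construction.
#'
#' @inheritParams fit_vc
#' @param specs character vector of spec names (default all four; returned
#'   largest first).
#' @return named list of [fit_vc()] results, in the order of `specs`.
#' @export
fit_all_specs <- function(y, X = NULL, grms = NULL, options = fit_options(),
                          specs = c("differential", "combined", "no_parental",
                                    "null")) {
  specs <- match.arg(specs, c("differential", "combined", "no_parental",
                              "null"), several.ok = TRUE)
  chain <- SPEC_ORDER[SPEC_ORDER %in% specs]      # smallest first
  fits <- list()
  prev <- NULL
  for (s in chain) {
    opt <- options
    if (!is.null(prev))
      opt$extra_starts <- c(options$extra_starts,
                            list(embed_raw(prev$spec$name, s, prev$estimates)))
    fits[[s]] <- fit_vc(s, y = y, X = X, grms = grms, options = opt)
    prev <- fits[[s]]
  }
  fits[specs]
}

# Map the raw parameters of a nested spec into the parameter space of the
# spec directly above it in the chain (zero variances floored just inside
# the boundary by the start sanitizer).
embed_raw <- function(from, to, r) {
  r <- unname(r)
  emb <- function(a, b, x) switch(paste(a, b),
    "null no_parental" = c(0, x),
    "no_parental combined" = c(x[1], 0, 0, x[2]),
    "combined differential" = c(x[1], x[2], x[2], x[3], x[3], x[2], x[4]),
    NULL)
  i <- match(from, SPEC_ORDER); j <- match(to, SPEC_ORDER)
  while (i < j) {
    r <- emb(SPEC_ORDER[i], SPEC_ORDER[i + 1], r)
    i <- i + 1
  }
  r
}
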