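# Nested model comparison and variance decomposition.

#' Akaike information criterion for a trio variance-component fit
#'
#' Uses full-ML parameter counting: the fixed effects (intercept and sex,
#' `n_fixed = 2`) count as estimated parameters alongside the variance
#' parameters, so \eqn{AIC = -2ll + 2 (df + n_{fixed})}.
#'
#' @param fit a [fit_vc()] result, or a numeric \eqn{-2ll} value (then `df`
#'   must be given).
#' @param df number of variance parameters (taken from the fit when given).
#' @param n_fixed number of fixed-effect parameters (default 2).
#' @return the AIC value.
#' @export
aic <- function(fit, df = NULL, n_fixed = 2) {
  if (inherits(fit, "vc_fit")) {
    neg2ll <- fit$neg2_loglik
    df <- fit$df
    n_fixed <- fit$n_fixed
  } else {
    neg2ll <- as.numeric(fit)
    if (is.null(df)) tv_stop("df required when fit is numeric", "triovc_usage_error")
  }
  neg2ll + 2 * (df + n_fixed)
}

# nesting order, smallest model first
SPEC_ORDER <- c("null", "no_parental", "combined", "differential")
SPEC_DF <- c(null = 1L, no_parental = 2L, combined = 4L, differential = 7L)

#' Likelihood-ratio test between nested specifications
#'
#' The statistic is the difference in \eqn{-2ll} (floored at 0), referred to
#' a chi-square distribution with degrees of freedom equal to the difference
#' in variance-parameter counts. Some null hypotheses place variances on the
#' boundary of the parameter space, which makes the plain chi-square
#' reference conservative.
#'
#' @param nested,full [fit_vc()] results (or numeric \eqn{-2ll} values, in
#'   which case `df_nested`/`df_full` must be given); `nested` must be nested
#'   in `full`.
#' @param df_nested,df_full variance-parameter counts for numeric input.
#' @return list with `delta` (the statistic), `df_diff` and `p`.
#' @export
lrt <- function(nested, full, df_nested = NULL, df_full = NULL) {
  if (inherits(nested, "vc_fit")) {
    if (!inherits(full, "vc_fit"))
      tv_stop("nested and full must both be fits or both numeric", "triovc_usage_error")
    i1 <- match(nested$spec$name, SPEC_ORDER)
    i2 <- match(full$spec$name, SPEC_ORDER)
    if (is.na(i1) || is.na(i2) || i1 >= i2)
      tv_stop(sprintf("'%s' is not nested in '%s'", nested$spec$name,
                      full$spec$name), "triovc_usage_error")
    n2_nested <- nested$neg2_loglik; n2_full <- full$neg2_loglik
    df_nested <- nested$df; df_full <- full$df
  } else {
    n2_nested <- as.numeric(nested); n2_full <- as.numeric(full)
    if (is.null(df_nested) || is.null(df_full))
      tv_stop("df_nested and df_full required for numeric input", "triovc_usage_error")
    if (df_nested >= df_full)
      tv_stop("nested model must have fewer parameters", "triovc_usage_error")
  }
  delta <- max(n2_nested - n2_full, 0)
  df_diff <- df_full - df_nested
  p <- if (delta == 0) 1 else pchisq(delta, df = df_diff, lower.tail = FALSE)
  list(delta = delta, df_diff = df_diff, p = p)
}

#' Variance decomposition and gene-environment correlation
#'
#' Splits a standardized fit into the direct share \eqn{\sigma_o^2}, the
#' combined indirect share \eqn{\sigma_m^2+\sigma_p^2}, the covariance
#' contribution \eqn{\sigma_{om}+\sigma_{op}}, and the residual
#' \eqn{\sigma_\epsilon^2}; `explained` is \eqn{1-\sigma_\epsilon^2} and the
#' gene-environment correlation is
#' \deqn{r_{GE} = \frac{\sigma_{om}+\sigma_{op}}
#'   {\sqrt{\sigma_o^2\,(\sigma_m^2+\sigma_p^2)}},}
#' reported as `NA` when its denominator is zero. A negative correlation
#' means direct and indirect effects counteract each other and shrink the
#' phenotypic variance; a positive one inflates it.
#'
#' @param fit a standardized [fit_vc()] result, or a named vector/list with
#'   elements `sigma2_o`, `sigma2_m`, `sigma2_p`, `sigma_om`, `sigma_op`,
#'   `sigma2_e` (standardized scale).
#' @return object of class `vc_decomposition`: list with `direct`,
#'   `indirect`, `covariance`, `residual`, `explained`, `ge_correlation` and,
#'   for fits with a covariance matrix, delta-method `se` for each field.
#' @export
decompose_variance <- function(fit) {
  if (inherits(fit, "vc_fit")) {
    if (is.null(fit$standardized))
      tv_stop("fit must be standardized (see standardize_fit)", "triovc_usage_error")
    est <- fit$standardized$est
  } else {
    est <- unlist(fit)[COMP7[-6]]
    est[is.na(est)] <- 0
    names(est) <- COMP7[-6]
    est <- c(est[1:5], sigma_mp = 0, est[6])
    names(est) <- COMP7
  }
  direct <- est[["sigma2_o"]]
  indirect <- est[["sigma2_m"]] + est[["sigma2_p"]]
  covar <- est[["sigma_om"]] + est[["sigma_op"]]
  residual <- est[["sigma2_e"]]
  denom <- direct * indirect
  ge <- if (denom > 0) covar / sqrt(denom) else NA_real_
  out <- list(direct = direct, indirect = indirect, covariance = covar,
              residual = residual, explained = 1 - residual,
              ge_correlation = ge)
  if (inherits(fit, "vc_fit") && !is.null(fit$vcov_raw)) {
    # delta method through raw -> standardized -> decomposition
    g <- function(raw) {
      c7 <- as.vector(fit$spec$M %*% raw)
      tot <- sum(c7 * ACCT7)
      s <- c7 / tot
      dn <- s[1] * (s[2] + s[3])
      c(direct = s[1], indirect = s[2] + s[3], covariance = s[4] + s[5],
        residual = s[7], explained = 1 - s[7],
        ge_correlation = if (dn > 0) (s[4] + s[5]) / sqrt(dn) else NA_real_)
    }
    J <- tryCatch(num_jacobian(function(r) {
      v <- g(r); v[is.na(v)] <- 0; v
    }, fit$estimates), error = function(e) NULL)
    if (!is.null(J)) {
      se <- sqrt(pmax(diag(J %*% fit$vcov_raw %*% t(J)), 0))
      names(se) <- c("direct", "indirect", "covariance", "residual",
                     "explained", "ge_correlation")
      if (is.na(ge)) se["ge_correlation"] <- NA_real_
      out$se <- se
    }
  }
  structure(out, class = "vc_decomposition")
}

#' @export
print.vc_decomposition <- function(x, digits = 3, ...) {
  cat("variance decomposition (standardized scale)\n")
  v <- c(direct = x$direct, indirect = x$indirect, covariance = x$covariance,
         residual = x$residual, explained = x$explained,
         ge_correlation = x$ge_correlation)
  print(round(v, digits))
  invisible(x)
}

#' Model-comparison table across nested fits
#'
#' Builds a comparison of the four specifications for one or more subscales:
#' standardized estimates, \eqn{-2ll}, AIC, df, the sequential LRT p-value of
#' each model against the next-larger specification, and a best-model flag
#' (lowest AIC within subscale). Rows are ordered differential, combined,
#' no_parental, null.
#'
#' @param fits a named list of [fit_vc()] results for one subscale, or a
#'   named list of such lists (one per subscale).
#' @return data.frame of class `vc_model_table` with one row per
#'   subscale-specification; full precision (use [format_model_table()] for
#'   display rounding).
#' @export
model_table <- function(fits) {
  if (inherits(fits[[1]], "vc_fit")) fits <- list(phenotype = fits)
  rows <- list()
  for (sub in names(fits)) {
    fl <- fits[[sub]]
    nm <- vapply(fl, function(f) f$spec$name, character(1))
    if (anyDuplicated(nm))
      tv_stop("duplicate specifications for one subscale", "triovc_usage_error")
    if (length(fl) < 2)
      tv_stop("need at least two fits per subscale", "triovc_usage_error")
    names(fl) <- nm
    present <- intersect(rev(SPEC_ORDER), nm)   # differential first
    aics <- vapply(present, function(s) aic(fl[[s]]), numeric(1))
    for (s in present) {
      f <- fl[[s]]
      std <- if (!is.null(f$standardized)) f$standardized$est else
        setNames(rep(NA_real_, 7), COMP7)
      larger <- SPEC_ORDER[match(s, SPEC_ORDER) + 1]
      pval <- if (!is.na(larger) && larger %in% nm)
        lrt(f, fl[[larger]])$p else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        subscale = sub, model = s, t(std), neg2ll = f$neg2_loglik,
        aic = aics[[s]], df = f$df, p_value = pval,
        best = aics[[s]] == min(aics), converged = f$converged)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("vc_model_table", "data.frame")
  out
}

#' Round a model table for display
#'
#' Follows the reporting convention of the field: estimates to 3 decimals,
#' \eqn{-2ll} and AIC to 2, p-values to 2 (with values below .01 shown as
#' `<.01`).
#'
#' @param tab a [model_table()] result.
#' @return data.frame of formatted character columns.
#' @export
format_model_table <- function(tab) {
  fmt <- tab
  for (cl in COMP7) fmt[[cl]] <- ifelse(is.na(tab[[cl]]), "",
                                        sprintf("%.3f", tab[[cl]]))
  fmt$neg2ll <- sprintf("%.2f", tab$neg2ll)
  fmt$aic <- sprintf("%.2f", tab$aic)
  fmt$p_value <- ifelse(is.na(tab$p_value), "",
                        ifelse(tab$p_value < 0.005, "<.01",
                               sub("^0", "", sprintf("%.2f", tab$p_value))))
  fmt
}

#' Write a model table as TSV and Markdown
#'
#' @param tab a [model_table()] result.
#' @param prefix output path prefix; `<prefix>.tsv` (full precision) and
#'   `<prefix>.md` (display rounding) are written.
#' @return `prefix`, invisibly.
#' @export
write_model_table <- function(tab, prefix) {
  write.table(tab, paste0(prefix, ".tsv"), quote = FALSE, sep = "\t",
              row.names = FALSE)
  fmt <- format_model_table(tab)
  con <- file(paste0(prefix, ".md"), "w")
  on.exit(close(con))
  cols <- names(fmt)
  writeLines(paste("|", paste(cols, collapse = " | "), "|"), con)
  writeLines(paste("|", paste(rep("---", length(cols)), collapse = " | "), "|"), con)
  for (i in seq_len(nrow(fmt)))
    writeLines(paste("|", paste(unlist(fmt[i, ]), collapse = " | "), "|"), con)
  writeLines(c("", paste("LRT p-values use a plain chi-square reference at the",
                         "parameter-count difference; null hypotheses on the",
                         "variance boundary make this conservative.")), con)
  invisible(prefix)
}

#' Stacked-bar variance decomposition figure
#'
#' One stacked bar per subscale showing the standardized direct, indirect,
#' covariance and residual shares of the selected (or supplied) fits.
#' Negative covariance contributions plot below zero.
#'
#' @param decomps named list of [decompose_variance()] results (one per
#'   subscale).
#' @return a ggplot object.
#' @export
plot_decomposition <- function(decomps) {
  df <- do.call(rbind, lapply(names(decomps), function(nm) {
    d <- decomps[[nm]]
    data.frame(subscale = nm,
               component = factor(c("direct", "indirect", "covariance",
                                    "residual"),
                                  levels = c("residual", "covariance",
                                             "indirect", "direct")),
               share = c(d$direct, d$indirect, d$covariance, d$residual))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = subscale, y = share, fill = component)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(y = "share of standardized phenotypic variance", x = NULL) +
    ggplot2::theme_minimal()
}
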