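#' Model-implied covariance of the 3-node path model
#'
#' The model regresses one endogenous reporter (`endpoint`) on two correlated
#' exogenous regulators (`fac1`, `fac2`):
#' `endpoint = gamma11 * fac1 + gamma21 * fac2 + zeta`, with `zeta`
#' independent of both regulators. Its implied covariance matrix is
#' \deqn{\Sigma(\theta) = \begin{pmatrix} \Phi & \Phi\gamma \\
#'   \gamma'\Phi & \gamma'\Phi\gamma + \psi \end{pmatrix}}
#' with \eqn{\Phi} the 2x2 exogenous covariance and \eqn{\psi} the residual
#' variance.
#'
#' @param gamma11,gamma21 Path coefficients (endpoint units per regressor unit).
#' @param exo_cov Covariance of the two regulators.
#' @param var_fac1,var_fac2 Exogenous variances.
#' @param resid_var Residual variance of the endpoint.
#' @return A symmetric 3x3 matrix with dimnames `fac1`, `fac2`, `endpoint`.
#' @export
sem_implied_cov <- function(gamma11, gamma21, exo_cov,
                            var_fac1 = 1, var_fac2 = 1, resid_var = 1) {
  phi <- matrix(c(var_fac1, exo_cov, exo_cov, var_fac2), 2L, 2L)
  b <- c(gamma11, gamma21)
  sxy <- phi %*% b
  syy <- drop(t(b) %*% phi %*% b) + resid_var
  sigma <- rbind(cbind(phi, sxy), c(sxy, syy))
  dimnames(sigma) <- rep(list(c("fac1", "fac2", "endpoint")), 2L)
  sigma
}

# ML discrepancy between a sample covariance S and an implied covariance
# Sigma: F = log|Sigma| + tr(S Sigma^-1) - log|S| - p. Zero iff Sigma = S.
.ml_discrepancy <- function(S, Sigma) {
  p <- nrow(S)
  as.numeric(
    determinant(Sigma, logarithm = TRUE)$modulus +
      sum(diag(S %*% solve(Sigma))) -
      determinant(S, logarithm = TRUE)$modulus - p
  )
}

.param_names <- c("var_fac1", "var_fac2", "exo_cov",
                  "gamma11", "gamma21", "resid_var")

# Derivative of Sigma(theta) wrt one parameter, at (phi, b).
.dSigma <- function(param, phi, b) {
  d <- matrix(0, 3L, 3L)
  if (param %in% c("var_fac1", "var_fac2", "exo_cov")) {
    dphi <- switch(param,
      var_fac1 = matrix(c(1, 0, 0, 0), 2L, 2L),
      var_fac2 = matrix(c(0, 0, 0, 1), 2L, 2L),
      exo_cov  = matrix(c(0, 1, 1, 0), 2L, 2L)
    )
    d[1:2, 1:2] <- dphi
    dxy <- dphi %*% b
    d[1:2, 3L] <- dxy
    d[3L, 1:2] <- dxy
    d[3L, 3L] <- drop(t(b) %*% dphi %*% b)
  } else if (param %in% c("gamma11", "gamma21")) {
    db <- if (param == "gamma11") c(1, 0) else c(0, 1)
    dxy <- phi %*% db
    d[1:2, 3L] <- dxy
    d[3L, 1:2] <- dxy
    d[3L, 3L] <- 2 * drop(t(db) %*% phi %*% b)
  } else {
    d[3L, 3L] <- 1
  }
  d
}

#' Fit the 3-node path model by maximum likelihood
#'
#' Estimates the path model `endpoint = gamma11*fac1 + gamma21*fac2 + zeta`
#' from the sample covariance matrix (divisor n - 1) by minimising the ML
#' covariance-structure discrepancy
#' `F = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - 3`.
#' Any of the two paths and the exogenous covariance can be fixed to 0; the
#' joint-normal likelihood then factorises into the exogenous block and the
#' conditional regression of the endpoint on the free regressors, giving the
#' exact ML solution in closed form for every supported specification. The
#' test statistic is `T = (n-1) * F_min`; standard errors come from the
#' inverse expected information, with two-sided normal (Wald) p-values.
#' Covariance-only fitting: no mean structure is modelled.
#'
#' @param data A data frame of samples; three numeric columns are used.
#' @param fac1,fac2,endpoint Column names of the two exogenous regulators
#'   (T-scores and/or expression levels) and the endogenous reporter.
#' @param free_gamma11,free_gamma21 Whether each path is free (otherwise
#'   fixed to 0). At least one path must be free.
#' @param free_exo_cov Whether the exogenous covariance is free.
#' @return An object of class `sem3_fit` with estimates, standard errors,
#'   Wald tests, the chi-square statistic and fit indices (RMSEA with 90% CI,
#'   CFI, TLI, SRMR). Use [tidy()] / [glance()] / [autoplot()] on it.
#' @examples
#' d <- simulate_sem_dataset(gamma11 = 0.5, gamma21 = 0.3, exo_corr = 0.4,
#'                           resid_var = 0.5, n = 200, seed = 1)
#' fit <- fit_path_model(d)
#' glance(fit)
#' @export
fit_path_model <- function(data, fac1 = "fac1", fac2 = "fac2",
                           endpoint = "endpoint",
                           free_gamma11 = TRUE, free_gamma21 = TRUE,
                           free_exo_cov = TRUE) {
  vars <- c(fac1, fac2, endpoint)
  missing <- setdiff(vars, names(data))
  if (length(missing) > 0L) {
    abort(paste0("column(s) not in data: ", paste(missing, collapse = ", ")))
  }
  if (!free_gamma11 && !free_gamma21) {
    abort("at least one path (gamma11, gamma21) must be free")
  }
  X <- as.matrix(data[vars])
  if (!is.numeric(X) || anyNA(X) || any(!is.finite(X))) {
    abort("fac1/fac2/endpoint columns must be finite numeric")
  }
  n <- nrow(X)
  if (n < 4L) {
    abort("need at least 4 samples")
  }
  S <- stats::cov(X)
  if (!is.finite(determinant(S)$modulus) || det(S) <= 1e-12 * prod(diag(S))) {
    abort("sample covariance matrix is singular (collinear or constant inputs)")
  }

  # Closed-form ML: exogenous block from the marginal likelihood, paths and
  # residual variance from the conditional regression on the free regressors.
  phi <- S[1:2, 1:2]
  if (!free_exo_cov) phi <- diag(diag(phi))
  free_J <- which(c(free_gamma11, free_gamma21))
  b <- c(0, 0)
  b[free_J] <- unname(solve(S[free_J, free_J, drop = FALSE], S[free_J, 3L]))
  psi <- unname(S[3L, 3L] - drop(S[3L, free_J, drop = FALSE] %*% b[free_J]))

  Sigma <- sem_implied_cov(b[1L], b[2L], phi[1L, 2L],
                           phi[1L, 1L], phi[2L, 2L], psi)
  est <- c(var_fac1 = phi[1L, 1L], var_fac2 = phi[2L, 2L],
           exo_cov = phi[1L, 2L], gamma11 = b[1L], gamma21 = b[2L],
           resid_var = psi)
  free <- c(var_fac1 = TRUE, var_fac2 = TRUE, exo_cov = free_exo_cov,
            gamma11 = free_gamma11, gamma21 = free_gamma21, resid_var = TRUE)

  df_model <- 6L - sum(free)
  # the saturated solution reproduces S exactly, so its discrepancy is 0 by
  # construction; evaluate F only for over-identified models
  chisq <- if (df_model == 0L) 0
    else max((n - 1) * .ml_discrepancy(S, Sigma), 0)

  # expected information of the free parameters at the ML solution
  Sinv <- solve(Sigma)
  free_names <- .param_names[free]
  D <- lapply(free_names, .dSigma, phi = phi, b = b)
  k <- length(D)
  info <- matrix(0, k, k)
  for (i in seq_len(k)) {
    SDi <- Sinv %*% D[[i]]
    for (j in i:k) {
      info[i, j] <- info[j, i] <- (n - 1) / 2 * sum(SDi * t(Sinv %*% D[[j]]))
    }
  }
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, k, k))
  se <- z <- p <- stats::setNames(rep(NA_real_, 6L), .param_names)
  se[free_names] <- sqrt(pmax(diag(vc), 0))
  z[free_names] <- est[free_names] / se[free_names]
  p[free_names] <- 2 * pnorm(-abs(z[free_names]))

  bl <- baseline_model(S, n)
  idx <- fit_indices(chisq, df_model, bl$chisq, bl$df, n, S, Sigma)

  structure(
    list(
      estimates = est, free = free, se = se, z = z, p = p,
      S = S, Sigma = Sigma, n = n, vars = vars,
      chisq = chisq, df_model = df_model,
      baseline_chisq = bl$chisq, baseline_df = bl$df,
      rmsea = idx$rmsea, rmsea_ci90 = idx$rmsea_ci90,
      cfi = idx$cfi, tli = idx$tli, srmr = idx$srmr
    ),
    class = "sem3_fit"
  )
}

#' Independence (baseline) model fit
#'
#' Fits the null model in which all three variables are mutually uncorrelated
#' (implied covariance `diag(S)`, free variances only). Its chi-square anchors
#' the incremental fit indices CFI and TLI.
#'
#' @param S 3x3 sample covariance matrix (divisor n - 1).
#' @param n Sample count.
#' @return A list with `chisq` and `df` (always 3 for three variables).
#' @export
baseline_model <- function(S, n) {
  Sigma0 <- diag(diag(S))
  list(chisq = max((n - 1) * .ml_discrepancy(S, Sigma0), 0), df = 3L)
}

#' Global fit indices of a covariance-structure fit
#'
#' * RMSEA `= sqrt(max(T - df, 0) / (df (n-1)))` (0 when `df = 0`); values
#'   below 0.05 are conventionally read as close fit.
#' * CFI `= 1 - max(T - df, 0) / max(T_b - df_b, T - df, 0)`; 1 is perfect.
#' * TLI `= ((T_b/df_b) - (T/df)) / ((T_b/df_b) - 1)`; reported as 1 for a
#'   saturated model (`df = 0`), where the ratio form is undefined.
#' * SRMR: square root of the mean squared standardized residual over the six
#'   unique elements of `S - Sigma_hat` (diagonals included), each residual
#'   scaled by the product of the corresponding sample standard deviations;
#'   values below 0.08 are conventionally read as very good fit.
#'
#' @param chisq Model test statistic `T`.
#' @param df_model Model degrees of freedom.
#' @param chisq_b,df_b Baseline (independence) statistic and df.
#' @param n Sample count.
#' @param S Sample covariance.
#' @param Sigma_hat Model-implied covariance.
#' @param level Confidence level for the RMSEA interval.
#' @return List: `rmsea`, `rmsea_ci90`, `cfi`, `tli`, `srmr`.
#' @export
fit_indices <- function(chisq, df_model, chisq_b, df_b, n, S, Sigma_hat,
                        level = 0.90) {
  rmsea <- if (df_model > 0) {
    sqrt(max(chisq - df_model, 0) / (df_model * (n - 1)))
  } else 0
  denom <- max(chisq_b - df_b, chisq - df_model, 0)
  cfi <- if (denom > 0) 1 - max(chisq - df_model, 0) / denom else 1
  tli <- if (df_model > 0) {
    rb <- chisq_b / df_b
    if (abs(rb - 1) < .Machine$double.eps^0.5) 1
    else (rb - chisq / df_model) / (rb - 1)
  } else 1
  sdv <- sqrt(diag(S))
  res <- (S - Sigma_hat) / tcrossprod(sdv)
  srmr <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))
  list(
    rmsea = rmsea,
    rmsea_ci90 = rmsea_ci(chisq, df_model, n, level = level),
    cfi = cfi, tli = tli, srmr = srmr
  )
}

# Bisection for the noncentrality parameter lambda solving
# pchisq(q, df, ncp = lambda) = prob; the CDF is decreasing in lambda.
.invert_ncp <- function(q, df, prob, tol = 1e-8) {
  if (pchisq(q, df, ncp = 0) <= prob) return(0)
  lo <- 0
  hi <- 1
  while (pchisq(q, df, ncp = hi) > prob) {
    lo <- hi
    hi <- hi * 2
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pchisq(q, df, ncp = mid) > prob) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Confidence interval for the RMSEA
#'
#' Endpoints are `sqrt(lambda / (df (n-1)))` where `lambda` solves the
#' noncentral chi-square CDF equation `P(chisq_df(lambda) <= T)` equal to
#' `(1 + level)/2` (lower endpoint) and `(1 - level)/2` (upper endpoint),
#' found by bisection to 1e-8 and truncated at 0. For `df = 0` the interval
#' is (0, 0).
#'
#' @param chisq Model test statistic `T`.
#' @param df Model degrees of freedom.
#' @param n Sample count.
#' @param level Confidence level (default 0.90).
#' @return Numeric length-2 vector `c(lo, hi)`.
#' @export
rmsea_ci <- function(chisq, df, n, level = 0.90) {
  if (df <= 0) return(c(lo = 0, hi = 0))
  alpha <- (1 - level) / 2
  lam_lo <- .invert_ncp(chisq, df, 1 - alpha)
  lam_hi <- .invert_ncp(chisq, df, alpha)
  c(lo = sqrt(lam_lo / (df * (n - 1))), hi = sqrt(lam_hi / (df * (n - 1))))
}

#' @export
print.sem3_fit <- function(x, digits = 4, ...) {
  cat("3-node path model fit (ML, covariance structure)\n")
  cat(sprintf("  %s ~ %s + %s   (n = %d)\n",
              x$vars[3L], x$vars[1L], x$vars[2L], x$n))
  cat(sprintf("  chisq = %.*g on %d df;  baseline chisq = %.*g on %d df\n",
              digits, x$chisq, x$df_model, digits, x$baseline_chisq,
              x$baseline_df))
  cat(sprintf("  RMSEA = %.*g [90%% CI %.*g, %.*g]  CFI = %.*g  TLI = %.*g  SRMR = %.*g\n",
              digits, x$rmsea, digits, x$rmsea_ci90[1L], digits,
              x$rmsea_ci90[2L], digits, x$cfi, digits, x$tli, digits, x$srmr))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy the parameter table of a 3-node path model fit
#'
#' @param x A `sem3_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: SEM-syntax `term`,
#'   `estimate`, `std.error`, `statistic` (Wald z), `p.value`, the
#'   fully standardized `std.estimate`, and whether the parameter was `free`.
#' @export
tidy.sem3_fit <- function(x, ...) {
  v <- x$vars
  e <- x$estimates
  syy <- x$Sigma[3L, 3L]
  std <- c(
    var_fac1 = 1, var_fac2 = 1,
    exo_cov = unname(e["exo_cov"] / sqrt(e["var_fac1"] * e["var_fac2"])),
    gamma11 = unname(e["gamma11"] * sqrt(e["var_fac1"] / syy)),
    gamma21 = unname(e["gamma21"] * sqrt(e["var_fac2"] / syy)),
    resid_var = unname(e["resid_var"] / syy)
  )
  tibble::tibble(
    term = c(
      paste0(v[1L], " ~~ ", v[1L]),
      paste0(v[2L], " ~~ ", v[2L]),
      paste0(v[1L], " ~~ ", v[2L]),
      paste0(v[3L], " ~ ", v[1L]),
      paste0(v[3L], " ~ ", v[2L]),
      paste0(v[3L], " ~~ ", v[3L])
    ),
    parameter = .param_names,
    estimate = unname(e),
    std.error = unname(x$se),
    statistic = unname(x$z),
    p.value = unname(x$p),
    std.estimate = unname(std),
    free = unname(x$free)
  )
}

#' One-row summary of a 3-node path model fit
#'
#' @param x A `sem3_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the chi-square test, fit indices and sizes.
#' @export
glance.sem3_fit <- function(x, ...) {
  tibble::tibble(
    chisq = x$chisq, df = x$df_model, n = x$n,
    rmsea = x$rmsea, rmsea.lo = unname(x$rmsea_ci90[1L]),
    rmsea.hi = unname(x$rmsea_ci90[2L]),
    cfi = x$cfi, tli = x$tli, srmr = x$srmr,
    baseline.chisq = x$baseline_chisq, baseline.df = x$baseline_df,
    n.free = sum(x$free)
  )
}

#' Edge list of the path diagram for a fit
#'
#' @param fit A `sem3_fit`.
#' @return A tibble of diagram edges: `from`, `to`, `type` (`"path"` or
#'   `"covariance"`), `label`.
#' @export
path_diagram_edges <- function(fit) {
  v <- fit$vars
  lab <- function(par, sym) {
    p <- fit$p[par]
    stars <- if (is.na(p)) "" else if (p < 0.001) "***"
      else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
    sprintf("%s = %.3f%s", sym, fit$estimates[par], stars)
  }
  edges <- tibble::tibble(
    from = c(v[1L], v[2L], v[1L]),
    to = c(v[3L], v[3L], v[2L]),
    type = c("path", "path", "covariance"),
    parameter = c("gamma11", "gamma21", "exo_cov"),
    label = c(lab("gamma11", "γ11"), lab("gamma21", "γ21"),
              lab("exo_cov", "φ12"))
  )
  edges[fit$free[edges$parameter], ]
}

#' Plot a fitted 3-node path model
#'
#' Draws the two regulators on the left, the endpoint on the right, directed
#' edges for free paths labelled with estimates and Wald significance stars,
#' and a two-headed arc for a free exogenous covariance.
#'
#' @param object A `sem3_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sem3_fit <- function(object, ...) {
  v <- object$vars
  nodes <- tibble::tibble(
    name = v, x = c(0, 0, 2), y = c(1, -1, 0)
  )
  edges <- path_diagram_edges(object) |>
    dplyr::left_join(nodes, by = c(from = "name")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(nodes, by = c(to = "name")) |>
    dplyr::rename(x1 = "x", y1 = "y")
  paths <- edges[edges$type == "path", ]
  covs <- edges[edges$type == "covariance", ]
  gg <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = paths,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "inches")),
      linewidth = 0.6
    ) +
    ggplot2::geom_label(
      data = paths,
      ggplot2::aes(x = (.data$x0 + .data$x1) / 2,
                   y = (.data$y0 + .data$y1) / 2, label = .data$label),
      size = 3
    )
  if (nrow(covs) > 0L) {
    gg <- gg +
      ggplot2::geom_curve(
        data = covs,
        ggplot2::aes(x = .data$x0 - 0.15, y = .data$y0, xend = .data$x1 - 0.15,
                     yend = .data$y1),
        curvature = 0.5,
        arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "inches"),
                               ends = "both"),
        linewidth = 0.5, linetype = 2
      ) +
      ggplot2::geom_label(
        data = covs,
        ggplot2::aes(x = .data$x0 - 0.65, y = (.data$y0 + .data$y1) / 2,
                     label = .data$label),
        size = 3
      )
  }
  gg +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      fill = "grey90", label.padding = ggplot2::unit(0.35, "lines")
    ) +
    ggplot2::xlim(-1.2, 2.6) + ggplot2::ylim(-1.6, 1.6) +
    ggplot2::theme_void()
}

#' Save the path-model diagram to a file
#'
#' @param fit A `sem3_fit`.
#' @param path Output file; format from the extension (png or pdf).
#' @param width,height Size in inches.
#' @return `path`, invisibly.
#' @export
render_model_figure <- function(fit, path, width = 6, height = 4) {
  ggplot2::ggsave(path, plot = autoplot(fit), width = width, height = height,
                  dpi = 150)
  invisible(path)
}

#' Write all fit statistics of a `sem3_fit` as flat JSON
#'
#' @param fit A `sem3_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sem_report <- function(fit, path) {
  est <- as.list(fit$estimates)
  report <- c(
    est,
    stats::setNames(as.list(fit$se), paste0("se_", .param_names)),
    stats::setNames(as.list(fit$z), paste0("z_", .param_names)),
    stats::setNames(as.list(fit$p), paste0("p_", .param_names)),
    list(
      chisq = fit$chisq, df_model = fit$df_model, n = fit$n,
      baseline_chisq = fit$baseline_chisq, baseline_df = fit$baseline_df,
      rmsea = fit$rmsea,
      rmsea_ci90_lo = unname(fit$rmsea_ci90[1L]),
      rmsea_ci90_hi = unname(fit$rmsea_ci90[2L]),
      cfi = fit$cfi, tli = fit$tli, srmr = fit$srmr
    )
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
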