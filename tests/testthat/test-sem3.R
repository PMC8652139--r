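test_that("a near-noiseless single-path construction is recovered", {
  set.seed(51)
  fac1 <- rnorm(200)
  fac2 <- rnorm(200)
  d <- tibble::tibble(fac1 = fac1, fac2 = fac2,
                      endpoint = 0.5 * fac1 + rnorm(200, sd = 1e-5))
  fit <- fit_path_model(d)
  expect_equal(unname(fit$estimates["gamma11"]), 0.5, tolerance = 1e-4)
  expect_lt(abs(fit$estimates["gamma21"]), 1e-4)
  expect_lt(fit$estimates["resid_var"], 1e-8)
})

test_that("the saturated model reproduces S and equals the OLS oracle", {
  for (seed in 1:10) {
    d <- simulate_sem_dataset(runif(1, -1, 1), runif(1, -1, 1),
                              runif(1, -0.7, 0.7), runif(1, 0.2, 2),
                              n = 60, seed = seed)
    fit <- fit_path_model(d)
    ols <- stats::lm(endpoint ~ fac1 + fac2, data = d)
    expect_equal(unname(fit$estimates[c("gamma11", "gamma21")]),
                 unname(stats::coef(ols)[2:3]), tolerance = 1e-8)
    expect_equal(unname(fit$estimates["resid_var"]),
                 sum(stats::resid(ols)^2) / (nrow(d) - 1), tolerance = 1e-8)
    expect_equal(fit$Sigma, stats::cov(as.matrix(d)),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_lt(fit$chisq, 1e-8)
    expect_equal(fit$df_model, 0L)
  }
})

test_that("estimates at n = 10,000 sit within 3 SE of the generating values", {
  truth <- c(gamma11 = 0.5, gamma21 = 0.3)
  d <- simulate_sem_dataset(0.5, 0.3, 0.4, 0.5, n = 10000, seed = 99)
  fit <- fit_path_model(d)
  for (par in names(truth)) {
    expect_lt(abs(fit$estimates[par] - truth[par]), 3 * fit$se[par])
  }
  expect_lt(abs(fit$estimates["exo_cov"] - 0.4), 3 * fit$se["exo_cov"])
})

test_that("constrained closed-form fits agree with direct numeric minimisation", {
  d <- simulate_sem_dataset(0.5, 0.25, 0.4, 0.5, n = 300, seed = 7)
  S <- stats::cov(as.matrix(d))
  n <- nrow(d)

  # gamma21 fixed to 0
  fit <- fit_path_model(d, free_gamma21 = FALSE)
  expect_equal(fit$df_model, 1L)
  obj <- function(th) {
    Sig <- sem_implied_cov(th[4], 0, th[3], exp(th[1]), exp(th[2]),
                           exp(th[5]))
    if (det(Sig) <= 0) return(1e10)
    perturbsem:::.ml_discrepancy(S, Sig)
  }
  opt <- stats::nlminb(c(0, 0, 0.1, 0.1, 0), obj)
  expect_equal(fit$chisq, (n - 1) * opt$objective, tolerance = 1e-5)
  expect_equal(unname(fit$estimates["gamma11"]), opt$par[4],
               tolerance = 1e-4)
  expect_equal(unname(fit$estimates["resid_var"]), exp(opt$par[5]),
               tolerance = 1e-4)

  # exogenous covariance fixed to 0
  fit2 <- fit_path_model(d, free_exo_cov = FALSE)
  expect_equal(fit2$df_model, 1L)
  obj2 <- function(th) {
    Sig <- sem_implied_cov(th[3], th[4], 0, exp(th[1]), exp(th[2]),
                           exp(th[5]))
    perturbsem:::.ml_discrepancy(S, Sig)
  }
  opt2 <- stats::nlminb(c(0, 0, 0.1, 0.1, 0), obj2)
  expect_equal(fit2$chisq, (n - 1) * opt2$objective, tolerance = 1e-5)
  expect_equal(unname(fit2$estimates["gamma11"]), opt2$par[3],
               tolerance = 1e-4)
})

test_that("the baseline independence model matches a direct discrepancy evaluation", {
  d <- simulate_sem_dataset(0.4, 0.2, 0.3, 1, n = 150, seed = 8)
  S <- stats::cov(as.matrix(d))
  bl <- baseline_model(S, 150)
  expect_equal(bl$df, 3L)
  direct <- (150 - 1) *
    (log(det(diag(diag(S)))) + sum(diag(S %*% solve(diag(diag(S))))) -
       log(det(S)) - 3)
  expect_equal(bl$chisq, direct, tolerance = 1e-10)

  Sd <- diag(c(1.3, 0.7, 2.1))
  expect_lt(baseline_model(Sd, 100)$chisq, 1e-10)
})

test_that("fit indices follow their closed forms and degenerate conventions", {
  S <- diag(3)
  idx <- fit_indices(10, 4, 80, 3, 101, S, S)
  expect_equal(idx$rmsea, sqrt(6 / 400), tolerance = 1e-12)

  # T below df truncates at perfect fit
  idx0 <- fit_indices(2, 4, 80, 3, 101, S, S)
  expect_equal(idx0$rmsea, 0)
  expect_equal(idx0$cfi, 1)

  # saturated conventions
  idxs <- fit_indices(0, 0, 80, 3, 101, S, S)
  expect_equal(idxs$rmsea, 0)
  expect_equal(idxs$cfi, 1)
  expect_equal(idxs$tli, 1)
  expect_equal(idxs$srmr, 0)
  expect_equal(unname(idxs$rmsea_ci90), c(0, 0))
})

test_that("RMSEA interval endpoints invert the noncentral chi-square CDF", {
  cases <- list(c(T = 12, df = 4, n = 101), c(T = 30, df = 5, n = 51),
                c(T = 3, df = 2, n = 201))
  for (cs in cases) {
    ci <- rmsea_ci(cs["T"], cs["df"], cs["n"])
    point <- sqrt(max(cs["T"] - cs["df"], 0) / (cs["df"] * (cs["n"] - 1)))
    expect_lte(ci[1], point + 1e-12)
    expect_gte(ci[2], point - 1e-12)
    lam_hi <- ci[2]^2 * cs["df"] * (cs["n"] - 1)
    expect_equal(pchisq(cs["T"], cs["df"], ncp = lam_hi), 0.05,
                 tolerance = 1e-6, ignore_attr = TRUE)
    lam_lo <- ci[1]^2 * cs["df"] * (cs["n"] - 1)
    if (lam_lo > 0) {
      expect_equal(pchisq(cs["T"], cs["df"], ncp = lam_lo), 0.95,
                   tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
  expect_equal(unname(rmsea_ci(5, 0, 100)), c(0, 0))
})

test_that("fit indices are invariant to positive rescaling of the variables", {
  d <- simulate_sem_dataset(0.5, 0, 0.4, 0.5, n = 200, seed = 13)
  fit <- fit_path_model(d, free_gamma21 = FALSE)
  d2 <- dplyr::mutate(d, fac1 = fac1 * 3.2, fac2 = fac2 * 0.41,
                      endpoint = endpoint * 12)
  fit2 <- fit_path_model(d2, free_gamma21 = FALSE)
  expect_equal(fit2$chisq, fit$chisq, tolerance = 1e-6)
  expect_equal(fit2$rmsea, fit$rmsea, tolerance = 1e-6)
  expect_equal(fit2$cfi, fit$cfi, tolerance = 1e-6)
  expect_equal(fit2$tli, fit$tli, tolerance = 1e-6)
  expect_equal(fit2$srmr, fit$srmr, tolerance = 1e-6)
})

test_that("the chi-square of a correctly specified constrained model is chi2(1)", {
  stats <- vapply(1:500, function(s) {
    d <- simulate_sem_dataset(0.5, 0, 0.4, 0.5, n = 200, seed = 6000 + s)
    fit_path_model(d, free_gamma21 = FALSE)$chisq
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(stats, "pchisq", df = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate data are rejected with clear errors", {
  d <- tibble::tibble(fac1 = rnorm(50), fac2 = rnorm(50))
  d$endpoint <- d$fac1          # perfectly collinear
  expect_error(fit_path_model(d), "singular")
  expect_error(fit_path_model(d[1:3, ]), "at least 4")
  expect_error(
    fit_path_model(simulate_sem_dataset(n = 20, seed = 1),
                   free_gamma11 = FALSE, free_gamma21 = FALSE),
    "at least one path"
  )
})

test_that("tidy and glance expose the broom-style views of a fit", {
  d <- simulate_sem_dataset(0.5, 0.3, 0.4, 0.5, n = 120, seed = 3)
  fit <- fit_path_model(d)
  td <- tidy(fit)
  expect_equal(nrow(td), 6L)
  expect_true(all(c("term", "estimate", "std.error", "statistic", "p.value",
                    "std.estimate", "free") %in% names(td)))
  expect_true(all(td$free))
  # standardized paths are on the correlation scale
  expect_true(all(abs(td$std.estimate[td$parameter %in%
                                        c("gamma11", "gamma21")]) <= 1))
  gl <- glance(fit)
  expect_equal(gl$df, 0L)
  expect_equal(gl$cfi, 1)
  expect_equal(gl$n.free, 6L)

  fit2 <- fit_path_model(d, free_gamma21 = FALSE)
  td2 <- tidy(fit2)
  expect_equal(td2$estimate[td2$parameter == "gamma21"], 0)
  expect_false(td2$free[td2$parameter == "gamma21"])
  expect_true(is.na(td2$std.error[td2$parameter == "gamma21"]))
})

test_that("the path diagram carries one edge per free relation", {
  d <- simulate_sem_dataset(0.5, 0.3, 0.4, 0.5, n = 80, seed = 4)
  fit <- fit_path_model(d)
  edges <- path_diagram_edges(fit)
  expect_equal(sum(edges$type == "path"), 2L)
  expect_equal(sum(edges$type == "covariance"), 1L)

  fit2 <- fit_path_model(d, free_gamma21 = FALSE)
  edges2 <- path_diagram_edges(fit2)
  expect_equal(sum(edges2$type == "path"), 1L)
  expect_false("gamma21" %in% edges2$parameter)

  expect_s3_class(autoplot(fit), "ggplot")
  path <- withr::local_tempfile(fileext = ".png")
  render_model_figure(fit, path)
  expect_true(file.exists(path))
  expect_gt(file.size(path), 0)
})

test_that("the JSON report round-trips all fit statistics", {
  d <- simulate_sem_dataset(0.5, 0.3, 0.4, 0.5, n = 90, seed = 5)
  fit <- fit_path_model(d, free_gamma21 = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  write_sem_report(fit, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$gamma11, unname(fit$estimates["gamma11"]))
  expect_equal(rep$chisq, fit$chisq)
  expect_equal(rep$rmsea_ci90_lo, unname(fit$rmsea_ci90[1]))
  expect_equal(rep$srmr, fit$srmr)
  expect_null(rep$p_gamma21[[1]])    # fixed path has no Wald test
})
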