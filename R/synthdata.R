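#' Simulate an expression matrix with an embedded directional signature
#'
#' Each sample carries a latent regulator activity drawn standard normal.
#' Up-signature genes are shifted by `+effect_size * activity`, down-signature
#' genes by `-effect_size * activity`, and every value receives Gaussian noise
#' with standard deviation `noise_sd`; background genes are pure noise. With
#' standard-normal activities, `effect_size / noise_sd` is the only
#' signal-to-noise knob.
#'
#' @param n_samples Number of samples.
#' @param n_background Number of unrelated background genes.
#' @param n_up,n_down Signature arm sizes (each at least 2).
#' @param effect_size Mean shift per unit activity (expression units).
#' @param noise_sd Residual noise SD (> 0).
#' @param seed Integer seed; output is bitwise reproducible given it.
#' @param activities Optional numeric vector of per-sample activities to use
#'   instead of fresh standard-normal draws.
#' @return A list: `matrix` (gene-level [expression_matrix()]), `signature`
#'   ([gene_signature()]), `activities` (tibble `sample_id`, `activity`).
#' @export
simulate_expression <- function(n_samples = 50, n_background = 200,
                                n_up = 20, n_down = 20,
                                effect_size = 1, noise_sd = 1, seed = 1,
                                activities = NULL) {
  if (n_up < 2L || n_down < 2L) abort("signature arms need at least 2 genes")
  if (noise_sd <= 0) abort("noise_sd must be positive")
  if (effect_size < 0) abort("effect_size must be non-negative")
  set.seed(seed)
  if (is.null(activities)) {
    activities <- rnorm(n_samples)
  } else if (length(activities) != n_samples) {
    abort("`activities` must have one value per sample")
  }
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  up_genes <- sprintf("UPG%04d", seq_len(n_up))
  down_genes <- sprintf("DNG%04d", seq_len(n_down))
  bg_genes <- sprintf("BGG%04d", seq_len(n_background))
  genes <- c(up_genes, down_genes, bg_genes)
  shift <- c(rep(effect_size, n_up), rep(-effect_size, n_down),
             rep(0, n_background))
  vals <- outer(shift, activities) +
    matrix(rnorm(length(genes) * n_samples, sd = noise_sd),
           nrow = length(genes))
  df <- tibble::as_tibble(as.data.frame(vals))
  names(df) <- sample_ids
  df <- dplyr::bind_cols(tibble::tibble(feature_id = genes), df)
  list(
    matrix = expression_matrix(df, level = "gene"),
    signature = gene_signature(up = up_genes, down = down_genes,
                               species = "synthetic"),
    activities = tibble::tibble(sample_id = sample_ids, activity = activities)
  )
}

#' Simulate a three-variable dataset from the path model
#'
#' Draws (`fac1`, `fac2`) bivariate normal with unit variances and correlation
#' `exo_corr`, then sets
#' `endpoint = gamma11*fac1 + gamma21*fac2 + N(0, resid_var)`.
#' The population covariance equals
#' `sem_implied_cov(gamma11, gamma21, exo_corr, 1, 1, resid_var)`.
#'
#' @param gamma11,gamma21 True path coefficients.
#' @param exo_corr Correlation of the two regulators (|exo_corr| < 1).
#' @param resid_var Residual variance (> 0).
#' @param n Sample count (>= 4).
#' @param seed Integer seed.
#' @return A tibble with columns `fac1`, `fac2`, `endpoint`.
#' @export
simulate_sem_dataset <- function(gamma11 = 0.5, gamma21 = 0.3,
                                 exo_corr = 0.4, resid_var = 0.5,
                                 n = 500, seed = 1) {
  if (abs(exo_corr) >= 1) abort("|exo_corr| must be < 1")
  if (resid_var <= 0) abort("resid_var must be positive")
  if (n < 4L) abort("n must be at least 4")
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  fac1 <- z1
  fac2 <- exo_corr * z1 + sqrt(1 - exo_corr^2) * z2
  endpoint <- gamma11 * fac1 + gamma21 * fac2 +
    rnorm(n, sd = sqrt(resid_var))
  tibble::tibble(fac1 = fac1, fac2 = fac2, endpoint = endpoint)
}

#' Build an end-to-end fixture chaining signatures, T-scores and the path model
#'
#' Draws (`fac1`, `fac2`, `endpoint`) from the path model, embeds two
#' disjoint directional signatures into one expression matrix whose latent
#' activities are `fac1` and `fac2`, and adds a reporter gene whose expression
#' row is exactly the `endpoint` vector. Running the signature -> T-score ->
#' path-model workflow on the fixture should recover the generating
#' coefficients' signs.
#'
#' @inheritParams simulate_sem_dataset
#' @param n_up,n_down Arm sizes of each embedded signature.
#' @param n_background Background gene count.
#' @param effect_size,noise_sd Signature response strength and noise SD.
#' @param endpoint_gene Symbol used for the reporter row.
#' @param dir Optional directory; when given, the matrix, both signatures and
#'   the reporter symbol are also written as the package's TSV formats.
#' @return A list: `matrix`, `sig1`, `sig2`, `endpoint_gene`, `truth`
#'   (the tibble of generating `fac1`, `fac2`, `endpoint`), and `paths`
#'   (when `dir` was given).
#' @export
make_chained_truth <- function(gamma11 = 0.5, gamma21 = 0.3, exo_corr = 0.4,
                               resid_var = 0.5, n = 60,
                               n_up = 25, n_down = 25, n_background = 150,
                               effect_size = 2, noise_sd = 1,
                               endpoint_gene = "RPTR1", seed = 1,
                               dir = NULL) {
  truth <- simulate_sem_dataset(gamma11, gamma21, exo_corr, resid_var,
                                n = n, seed = seed)
  sim1 <- simulate_expression(
    n_samples = n, n_background = n_background, n_up = n_up, n_down = n_down,
    effect_size = effect_size, noise_sd = noise_sd, seed = seed + 1L,
    activities = truth$fac1
  )
  sim2 <- simulate_expression(
    n_samples = n, n_background = 0L, n_up = n_up, n_down = n_down,
    effect_size = effect_size, noise_sd = noise_sd, seed = seed + 2L,
    activities = truth$fac2
  )
  m2 <- sim2$matrix
  m2$feature_id <- paste0("B", m2$feature_id)
  sig2 <- gene_signature(up = paste0("B", sim2$signature$up),
                         down = paste0("B", sim2$signature$down),
                         species = "synthetic")
  reporter <- sim1$matrix[1L, ]
  reporter$feature_id <- endpoint_gene
  reporter[-1L] <- as.list(truth$endpoint)
  combined <- dplyr::bind_rows(
    tibble::as_tibble(sim1$matrix), tibble::as_tibble(m2),
    tibble::as_tibble(reporter)
  )
  out <- list(
    matrix = expression_matrix(combined, level = "gene"),
    sig1 = sim1$signature, sig2 = sig2,
    endpoint_gene = endpoint_gene, truth = truth
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      matrix = file.path(dir, "expression_matrix.tsv"),
      sig1 = file.path(dir, "signature1.tsv"),
      sig2 = file.path(dir, "signature2.tsv")
    )
    write_expression_matrix(out$matrix, paths$matrix)
    write_signature(out$sig1, paths$sig1)
    write_signature(out$sig2, paths$sig2)
    out$paths <- paths
  }
  out
}
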