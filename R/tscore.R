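#' T-score of one sample from up- and down-arm expression values
#'
#' The T-score summarises, within a single specimen, how strongly the
#' up-regulated arm of a regulator's signature exceeds the down-regulated arm:
#' `tscore = d * TINV(p, df)` where `p` is the two-tailed equal-variance
#' (pooled) two-sample t-test p-value comparing the two arms, `df = n_up +
#' n_down - 2`, `TINV(p, df)` is the positive t with `P(|T| > t) = p`, and
#' `d` is +1 when the up-arm mean exceeds the down-arm mean, otherwise -1
#' (at an exact tie the score is 0). This reconstruction is algebraically
#' identical to the signed pooled t statistic itself.
#'
#' @param up_values,down_values Numeric vectors of median-centered expression
#'   values for the up- and down-arm homologs in one sample; each needs at
#'   least 2 values and jointly non-zero pooled variance.
#' @return A one-row tibble: `tscore`, `pvalue`, `n_up`, `n_down`, `df`.
#' @export
tscore_sample <- function(up_values, down_values) {
  n_up <- length(up_values)
  n_down <- length(down_values)
  if (n_up < 2L || n_down < 2L) {
    abort("each direction needs at least 2 genes for the pooled t-test")
  }
  df <- n_up + n_down - 2L
  sp2 <- ((n_up - 1) * var(up_values) + (n_down - 1) * var(down_values)) / df
  if (!is.finite(sp2) || sp2 <= 0) {
    abort("zero pooled variance: up and down values are degenerate")
  }
  delta <- mean(up_values) - mean(down_values)
  tstat <- delta / sqrt(sp2 * (1 / n_up + 1 / n_down))
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  d <- if (delta > 0) 1 else if (delta < 0) -1 else 1
  tibble::tibble(
    tscore = d * qt(p / 2, df = df, lower.tail = FALSE),
    pvalue = p,
    n_up = n_up, n_down = n_down, df = df
  )
}

# Vectorised T-scores over the columns of a genes x samples numeric matrix.
# Identical to per-sample tscore_sample(); kept in matrix form because the
# elimination bootstrap recomputes this thousands of times.
.tscores_matrix <- function(vals, up_idx, down_idx, sample_ids) {
  n_up <- length(up_idx)
  n_down <- length(down_idx)
  df <- n_up + n_down - 2L
  up <- vals[up_idx, , drop = FALSE]
  dn <- vals[down_idx, , drop = FALSE]
  m_up <- colMeans(up)
  m_dn <- colMeans(dn)
  ss_up <- colSums(up^2) - n_up * m_up^2
  ss_dn <- colSums(dn^2) - n_down * m_dn^2
  sp2 <- (ss_up + ss_dn) / df
  bad <- which(!is.finite(sp2) | sp2 <= 0)
  if (length(bad) > 0L) {
    abort(paste0("zero pooled variance in sample '", sample_ids[bad[1L]], "'"))
  }
  delta <- m_up - m_dn
  tstat <- delta / sqrt(sp2 * (1 / n_up + 1 / n_down))
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  d <- ifelse(delta < 0, -1, 1)
  tibble::tibble(
    sample_id = sample_ids,
    tscore = unname(d * qt(p / 2, df = df, lower.tail = FALSE)),
    pvalue = unname(p),
    n_up = n_up, n_down = n_down, df = df
  )
}

#' Per-sample T-scores of a projected signature over a matrix
#'
#' Applies [tscore_sample()] column by column: for each sample, the centered
#' expression values of the up-arm homologs are tested against those of the
#' down-arm homologs. Raw per-sample p-values are reported alongside; no
#' multiple-testing correction is applied.
#'
#' @param x A gene-level, median-centered [expression_matrix()].
#' @param sig A `projected_signature` (from [project_signature()]) or a
#'   [gene_signature()] of the matrix's own species (projected through an
#'   identity map).
#' @return A tibble with one row per sample: `sample_id`, `tscore`, `pvalue`,
#'   `n_up`, `n_down`, `df`.
#' @export
compute_tscores <- function(x, sig) {
  if (inherits(sig, "gene_signature")) {
    sig <- project_signature(sig, x)
  }
  if (!inherits(sig, "projected_signature")) {
    abort("`sig` must be a gene_signature or projected_signature")
  }
  up_idx <- match(sig$up, x$feature_id)
  down_idx <- match(sig$down, x$feature_id)
  if (anyNA(up_idx) || anyNA(down_idx)) {
    abort("projected signature refers to genes absent from the matrix")
  }
  if (length(up_idx) < 2L || length(down_idx) < 2L) {
    abort("each signature direction needs at least 2 genes in the matrix")
  }
  vals <- as.matrix(x[-1L])
  .tscores_matrix(vals, up_idx, down_idx, colnames(vals))
}

#' Classify samples as showing regulator activity
#'
#' A sample whose T-score exceeds 0 shares the signature's expression pattern
#' and is called `active`; a score of exactly 0 is `inactive` (strict
#' inequality).
#'
#' @param tscore Numeric vector of T-scores.
#' @return A factor with levels `active`, `inactive`.
#' @export
classify_activity <- function(tscore) {
  factor(ifelse(tscore > 0, "active", "inactive"),
         levels = c("active", "inactive"))
}
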