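#' Perturb a projected signature by gene elimination
#'
#' Removes the designated genes from the signature. Under
#' `"without_replacement"` the signature simply shrinks. Under
#' `"with_replacement"` the same number of genes is drawn uniformly without
#' repetition from `pool` minus the current signature and added back, each
#' refill inheriting the direction (up/down) of the removed gene it replaces,
#' matched by removal order, so the signature keeps its original size.
#'
#' @param sig A `projected_signature`.
#' @param target_genes Character vector (or `gene_set`) of genes to remove;
#'   genes absent from the signature are ignored.
#' @param mode `"without_replacement"` or `"with_replacement"`.
#' @param pool Character vector of background genes for refill draws
#'   (required for `"with_replacement"`).
#' @return A perturbed `projected_signature`. Errors if a direction would be
#'   left with fewer than 2 genes, or if the usable pool is smaller than the
#'   number of removed genes.
#' @export
perturb_signature <- function(sig, target_genes,
                              mode = c("without_replacement",
                                       "with_replacement"),
                              pool = NULL) {
  mode <- match.arg(mode)
  if (inherits(target_genes, "gene_set")) target_genes <- target_genes$genes
  target_genes <- unique(as.character(target_genes))
  current <- c(sig$up, sig$down)
  removed <- target_genes[target_genes %in% current]
  up <- setdiff(sig$up, removed)
  down <- setdiff(sig$down, removed)
  if (mode == "with_replacement" && length(removed) > 0L) {
    if (is.null(pool)) abort("with_replacement needs a refill `pool`")
    usable <- setdiff(unique(as.character(pool)), current)
    if (length(usable) < length(removed)) {
      abort(paste0("pool too small: need ", length(removed),
                   " refill gene(s), have ", length(usable)))
    }
    refill <- sample(usable, length(removed))
    was_up <- removed %in% sig$up
    up <- c(up, refill[was_up])
    down <- c(down, refill[!was_up])
  }
  if (length(up) < 2L || length(down) < 2L) {
    abort(paste0("perturbation leaves ", length(up), " up / ", length(down),
                 " down gene(s); at least 2 per direction required"))
  }
  structure(
    list(up = up, down = down,
         dropped_up = sum(removed %in% sig$up),
         dropped_down = sum(removed %in% sig$down),
         n_conflict = 0L, species = sig$species),
    class = "projected_signature"
  )
}

.boot_statistics <- c("gamma11", "gamma21", "chisq", "rmsea", "cfi", "tli",
                      "srmr")

.extract_stat <- function(fit, statistic) {
  switch(statistic,
    gamma11 = unname(fit$estimates["gamma11"]),
    gamma21 = unname(fit$estimates["gamma21"]),
    chisq = fit$chisq, rmsea = fit$rmsea, cfi = fit$cfi,
    tli = fit$tli, srmr = fit$srmr
  )
}

#' Two-class elimination bootstrap of a signature through T-scores and the SEM
#'
#' Quantifies how much a designated subset of signature genes (e.g. a
#' downstream effector's own targets) matters to a path-model quantity.
#' The observed statistic removes exactly the target subset, recomputes the
#' perturbed regulator's per-sample T-scores and refits the saturated 3-node
#' model against the unchanged second regulator and endpoint. Null replicates
#' are built per mode:
#' * `"without_replacement"`: remove an equally sized random subset of
#'   non-target signature genes;
#' * `"with_replacement"`: remove the target subset and refill to the original
#'   size with random pool genes (direction-matched by removal order).
#' The empirical p-value is `max(count, 1) / B` where `count` is the number of
#' replicate statistics at least as extreme as the observed one under `tail`,
#' so it is floored at `1/B` (1,000 iterations can reach p = 0.001).
#'
#' @param x A gene-level, median-centered [expression_matrix()].
#' @param sig `projected_signature` of the perturbed regulator.
#' @param target_genes Genes to eliminate (character or `gene_set`); must
#'   intersect the signature.
#' @param fac2 Numeric vector: the second regulator's T-scores or expression,
#'   one value per sample of `x`.
#' @param endpoint Numeric vector: the reporter's expression per sample.
#' @param mode `"without_replacement"` or `"with_replacement"`.
#' @param pool Background genes for refill draws (`"with_replacement"` only);
#'   must be genes of `x`.
#' @param iterations Number of bootstrap replicates B (>= 1; 1,000
#'   recommended).
#' @param seed Master seed; one independent substream is derived per
#'   replicate index, so results do not depend on execution order.
#' @param statistic Path-model quantity tested (default `"gamma11"`, the
#'   perturbed regulator's path).
#' @param tail `"two_sided"` (|replicate| >= |observed|), `"lower"` or
#'   `"upper"`.
#' @return An `elimination_boot` object: `observed`, `replicates` (length B,
#'   `NA` for failed replicates), `pvalue`, and the run metadata. Replicates
#'   failing the model fit are excluded from the p-value (denominator = number
#'   of successful replicates); more than 5% failures is an error.
#' @export
run_bootstrap <- function(x, sig, target_genes, fac2, endpoint,
                          mode = c("without_replacement", "with_replacement"),
                          pool = NULL, iterations = 1000, seed = 1,
                          statistic = .boot_statistics,
                          tail = c("two_sided", "lower", "upper")) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  tail <- match.arg(tail)
  if (inherits(target_genes, "gene_set")) target_genes <- target_genes$genes
  target_genes <- unique(as.character(target_genes))
  B <- as.integer(iterations)
  if (B < 1L) abort("iterations must be >= 1")
  n_samples <- ncol(x) - 1L
  if (length(fac2) != n_samples || length(endpoint) != n_samples) {
    abort("fac2 and endpoint must have one value per sample of the matrix")
  }
  vals <- as.matrix(x[-1L])
  rownames(vals) <- x$feature_id
  current <- c(sig$up, sig$down)
  removed <- target_genes[target_genes %in% current]
  if (length(removed) == 0L) {
    abort("target_genes do not intersect the signature")
  }
  n_elim <- length(removed)

  stat_of <- function(psig) {
    ts <- .tscores_matrix(vals,
                          match(psig$up, rownames(vals)),
                          match(psig$down, rownames(vals)),
                          colnames(vals))
    d <- tibble::tibble(fac1 = ts$tscore, fac2 = fac2, endpoint = endpoint)
    .extract_stat(fit_path_model(d), statistic)
  }

  observed <- stat_of(perturb_signature(sig, removed, "without_replacement"))

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, B)
  non_target <- setdiff(current, removed)
  replicates <- rep(NA_real_, B)
  for (i in seq_len(B)) {
    set.seed(sub_seeds[i])
    replicates[i] <- tryCatch({
      psig <- if (mode == "without_replacement") {
        perturb_signature(sig, sample(non_target, n_elim),
                          "without_replacement")
      } else {
        perturb_signature(sig, removed, "with_replacement", pool = pool)
      }
      stat_of(psig)
    }, error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(replicates))
  if (n_failed > 0.05 * B) {
    abort(paste0(n_failed, " of ", B, " replicates failed (> 5%)"))
  }
  ok <- replicates[!is.na(replicates)]
  count <- switch(tail,
    two_sided = sum(abs(ok) >= abs(observed)),
    lower = sum(ok <= observed),
    upper = sum(ok >= observed)
  )
  structure(
    list(
      observed = observed, replicates = replicates,
      pvalue = max(count, 1L) / length(ok),
      mode = mode, seed = seed, B = B, n_failed = n_failed,
      statistic = statistic, tail = tail, n_eliminated = n_elim
    ),
    class = "elimination_boot"
  )
}

#' @export
print.elimination_boot <- function(x, ...) {
  cat(sprintf(
    "Elimination bootstrap (%s): %d gene(s) removed, B = %d, seed = %d\n",
    x$mode, x$n_eliminated, x$B, x$seed
  ))
  cat(sprintf("  statistic = %s, tail = %s\n", x$statistic, x$tail))
  cat(sprintf("  observed = %.5g;  empirical p = %.4g", x$observed, x$pvalue))
  if (x$n_failed > 0L) cat(sprintf("  (%d failed replicate(s))", x$n_failed))
  cat("\n")
  invisible(x)
}

#' Tidy the replicate distribution of an elimination bootstrap
#'
#' @param x An `elimination_boot`.
#' @param ... Unused.
#' @return A tibble with `replicate` index and the replicate statistic
#'   `value` (`NA` for failed replicates).
#' @export
tidy.elimination_boot <- function(x, ...) {
  tibble::tibble(replicate = seq_len(x$B), value = x$replicates)
}

#' One-row summary of an elimination bootstrap
#'
#' @param x An `elimination_boot`.
#' @param ... Unused.
#' @return A one-row tibble: observed statistic, empirical p-value and run
#'   metadata.
#' @export
glance.elimination_boot <- function(x, ...) {
  tibble::tibble(
    observed = x$observed, pvalue = x$pvalue, B = x$B,
    n.failed = x$n_failed, n.eliminated = x$n_eliminated,
    statistic = x$statistic, mode = x$mode, tail = x$tail, seed = x$seed
  )
}

#' Plot the null replicate distribution with the observed statistic
#'
#' @param object An `elimination_boot`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.elimination_boot <- function(object, bins = 30, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30",
                            na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = paste0("replicate ", object$statistic),
      y = "count",
      title = sprintf("Elimination bootstrap (%s), p = %.4g",
                      object$mode, object$pvalue)
    ) +
    ggplot2::theme_minimal()
}

#' Write a bootstrap result as JSON
#'
#' @param result An `elimination_boot`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bootstrap_result <- function(result, path) {
  jsonlite::write_json(
    list(
      observed = result$observed, pvalue = result$pvalue,
      mode = result$mode, statistic = result$statistic, tail = result$tail,
      B = result$B, seed = result$seed, n_failed = result$n_failed,
      n_eliminated = result$n_eliminated,
      replicates = result$replicates
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
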