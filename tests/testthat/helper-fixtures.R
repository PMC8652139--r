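# In-code fixtures shared across test files.

# genes x samples expression tibble with deterministic values
tiny_expr <- function(genes = c("G1", "G2", "G3"),
                      samples = c("S1", "S2"),
                      values = NULL, level = "gene", seed = 1) {
  if (is.null(values)) {
    set.seed(seed)
    values <- matrix(rnorm(length(genes) * length(samples)),
                     nrow = length(genes))
  }
  df <- tibble::as_tibble(as.data.frame(values))
  names(df) <- samples
  df <- dplyr::bind_cols(tibble::tibble(feature_id = genes), df)
  expression_matrix(df, level = level)
}

write_matrix_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# projected signature straight from up/down gene vectors
psig_of <- function(up, down) {
  structure(list(up = up, down = down, dropped_up = 0L, dropped_down = 0L,
                 n_conflict = 0L, species = "synthetic"),
            class = "projected_signature")
}

# pooled-variance two-sample t oracle via stats::t.test
pooled_t_oracle <- function(up, down) {
  ht <- stats::t.test(up, down, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}
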