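#' Collapse a probe-level matrix to gene level
#'
#' When several probes measure one gene, the probe with the highest sample
#' standard deviation (denominator n - 1) is kept to represent that gene; ties
#' go to the lexicographically first probe id. Probes without a map entry are
#' dropped with an informative message.
#'
#' @param x A probe-level [expression_matrix()].
#' @param probe_map Tibble with columns `source` (probe id) and `target`
#'   (gene symbol); every mapped probe must map to exactly one gene.
#' @return A gene-level `expr_mat` with one row per gene.
#' @export
collapse_probes <- function(x, probe_map) {
  if (expr_level(x) != "probe") {
    abort("collapse_probes() expects a probe-level matrix")
  }
  multi <- unique(probe_map$source[duplicated(probe_map$source)])
  if (length(multi) > 0L) {
    abort(paste0("probe(s) mapped to more than one gene: ",
                 paste(head(multi, 5L), collapse = ", ")))
  }
  vals <- as.matrix(x[-1L])
  row_sd <- apply(vals, 1L, sd)
  tab <- tibble::tibble(feature_id = x$feature_id,
                        .row = seq_len(nrow(x)), .sd = row_sd) |>
    dplyr::inner_join(probe_map, by = c(feature_id = "source"))
  n_dropped <- nrow(x) - nrow(tab)
  if (n_dropped > 0L) {
    inform(paste0("collapse_probes: dropped ", n_dropped,
                  " unmapped probe(s)"))
  }
  if (nrow(tab) == 0L) {
    abort("no probe maps to any gene")
  }
  keep <- tab |>
    dplyr::arrange(.data$target, dplyr::desc(.data$.sd), .data$feature_id) |>
    dplyr::distinct(.data$target, .keep_all = TRUE)
  out <- x[keep$.row, ]
  out$feature_id <- keep$target
  expression_matrix(out, level = "gene")
}

#' Median-center each feature across samples
#'
#' Subtracts the per-row median so each gene's values describe deviation from
#' its typical level across the cohort; the T-score compares these centered
#' values between the up and down arms of a signature. For an even sample
#' count the median is the mean of the two middle order statistics. The
#' operation is idempotent.
#'
#' @param x An [expression_matrix()] (probe or gene level).
#' @return `x` with every row median 0.
#' @export
median_center <- function(x) {
  vals <- as.matrix(x[-1L])
  centered <- vals - apply(vals, 1L, median)
  out <- x
  out[-1L] <- as.data.frame(centered)
  expression_matrix(out, level = expr_level(x))
}

#' Project a signature through an ortholog map onto a matrix
#'
#' Maps each direction of the signature through the ortholog table (identity
#' map if `map` is `NULL`, i.e. signature and matrix share a species), then
#' intersects with the genes present in the matrix. A homolog reachable from
#' both the up and the down arm is a direction conflict and is excluded from
#' both sets, keeping them disjoint.
#'
#' @param sig A [gene_signature()].
#' @param matrix A gene-level [expression_matrix()].
#' @param map Optional tibble with columns `source`, `target` (may be
#'   many-to-many).
#' @param fold_case Match symbols case-insensitively (HUGO human symbols are
#'   upper case where MGI mouse symbols are not).
#' @return A `projected_signature`: lists `up` and `down` of matrix genes,
#'   drop counts `dropped_up`/`dropped_down` (source genes contributing no
#'   homolog), and `n_conflict`.
#' @export
project_signature <- function(sig, matrix, map = NULL, fold_case = FALSE) {
  if (expr_level(matrix) != "gene") {
    abort("project_signature() needs a gene-level matrix; collapse probes first")
  }
  genes <- matrix$feature_id
  key <- if (fold_case) toupper else identity
  image_of <- function(src) {
    if (is.null(map)) {
      hom <- src
    } else {
      hom <- map$target[key(map$source) %in% key(src)]
    }
    unique(genes[key(genes) %in% key(hom)])
  }
  up <- image_of(sig$up)
  down <- image_of(sig$down)
  conflict <- intersect(up, down)
  up <- setdiff(up, conflict)
  down <- setdiff(down, conflict)
  if (length(up) + length(down) == 0L) {
    abort("signature has no homologs in matrix")
  }
  # a source gene is "dropped" if none of its homologs survived
  survives <- function(src, kept) {
    if (length(src) == 0L) return(logical(0))
    vapply(src, function(g) {
      hom <- if (is.null(map)) g else map$target[key(map$source) == key(g)]
      any(key(kept) %in% key(hom))
    }, logical(1))
  }
  structure(
    list(
      up = up, down = down,
      dropped_up = sum(!survives(sig$up, up)),
      dropped_down = sum(!survives(sig$down, down)),
      n_conflict = length(conflict),
      species = sig$species
    ),
    class = "projected_signature"
  )
}

#' @export
print.projected_signature <- function(x, ...) {
  cat(sprintf(
    "# Projected signature: %d up, %d down homolog(s) in matrix (dropped %d up, %d down; %d direction conflict(s))\n",
    length(x$up), length(x$down), x$dropped_up, x$dropped_down, x$n_conflict
  ))
  invisible(x)
}
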