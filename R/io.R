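#' Construct an expression matrix object
#'
#' An expression matrix is a tibble whose first column, `feature_id`, holds
#' probe or gene identifiers and whose remaining columns hold one numeric
#' expression profile per sample. The `level` attribute records whether rows
#' are probes (duplicate gene identity allowed once mapped) or genes (row ids
#' must be unique).
#'
#' @param df A data frame: first column character feature ids, remaining
#'   columns numeric sample values.
#' @param level `"gene"` or `"probe"`.
#' @return A tibble of class `expr_mat` with attribute `level`.
#' @export
expression_matrix <- function(df, level = c("gene", "probe")) {
  level <- match.arg(level)
  df <- tibble::as_tibble(df, .name_repair = "minimal")
  if (ncol(df) < 2L) {
    abort("expression matrix needs a feature id column plus at least one sample column")
  }
  sample_ids <- names(df)[-1L]
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate sample id(s): ", paste(unique(dup), collapse = ", ")))
  }
  names(df)[1L] <- "feature_id"
  df$feature_id <- trimws(as.character(df$feature_id))
  for (s in sample_ids) {
    if (!is.numeric(df[[s]])) {
      abort(paste0("sample column '", s, "' is not numeric"))
    }
    bad <- which(!is.finite(df[[s]]))
    if (length(bad) > 0L) {
      abort(paste0(
        "non-finite value in sample '", s, "' at row ", bad[1L],
        " (feature '", df$feature_id[bad[1L]], "')"
      ))
    }
  }
  if (level == "gene") {
    dupg <- df$feature_id[duplicated(df$feature_id)]
    if (length(dupg) > 0L) {
      abort(paste0(
        "duplicate gene id(s) at level = 'gene': ",
        paste(unique(dupg), collapse = ", ")
      ))
    }
  }
  structure(df, class = c("expr_mat", class(tibble::tibble())), level = level)
}

#' Expression level of an expression matrix
#' @param x An `expr_mat`.
#' @return `"gene"` or `"probe"`.
#' @export
expr_level <- function(x) attr(x, "level") %||% "gene"

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf(
    "# Expression matrix: %d %s-level feature(s) x %d sample(s)\n",
    nrow(x), expr_level(x), ncol(x) - 1L
  ))
  NextMethod()
}

.delim_char <- function(sep = c("tab", "comma")) {
  switch(match.arg(sep), tab = "\t", comma = ",")
}

#' Read an expression matrix from delimited text
#'
#' The file must have a header row of sample ids, a first column of feature
#' ids, and a fully numeric body. Any non-numeric or missing cell is a hard
#' error naming the offending row and column: downstream t-tests assume
#' complete columns.
#'
#' @param path Path to a tab- (default) or comma-separated text file.
#' @param level Row identity: `"gene"` (unique ids enforced) or `"probe"`.
#' @param sep Field separator dialect, `"tab"` or `"comma"`.
#' @return An [expression_matrix()] tibble.
#' @export
read_expression_matrix <- function(path, level = c("gene", "probe"),
                                   sep = c("tab", "comma")) {
  level <- match.arg(level)
  raw <- readr::read_delim(
    path,
    delim = .delim_char(sep),
    col_types = readr::cols(.default = readr::col_character()),
    name_repair = "minimal",
    progress = FALSE
  )
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    abort(paste0("'", path, "': empty or header-only expression matrix"))
  }
  sample_ids <- names(raw)[-1L]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup) > 0L) {
    abort(paste0("'", path, "': duplicated sample id(s) in header: ",
                 paste(dup, collapse = ", ")))
  }
  out <- raw[1L]
  for (s in sample_ids) {
    v <- suppressWarnings(as.numeric(raw[[s]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      abort(paste0(
        "'", path, "': non-numeric cell '", raw[[s]][bad[1L]],
        "' at data row ", bad[1L], " (feature '", raw[[1L]][bad[1L]],
        "'), column '", s, "'"
      ))
    }
    out[[s]] <- v
  }
  expression_matrix(out, level = level)
}

#' Write an expression matrix to delimited text
#' @param x An `expr_mat`.
#' @param path Output path.
#' @param sep `"tab"` or `"comma"`.
#' @return `x`, invisibly.
#' @export
write_expression_matrix <- function(x, path, sep = c("tab", "comma")) {
  readr::write_delim(tibble::as_tibble(x), path, delim = .delim_char(sep),
                     progress = FALSE)
  invisible(x)
}

#' Construct a directional gene signature
#'
#' A gene signature is the set of genes responding to perturbation of a
#' regulator in a model system, split by direction of change. Up- and
#' down-regulated sets must be disjoint and jointly non-empty.
#'
#' @param up,down Character vectors of gene symbols (whitespace trimmed,
#'   duplicates collapsed).
#' @param species Species tag for the symbols, e.g. `"human"` or `"mouse"`.
#' @return A `gene_signature` object.
#' @export
gene_signature <- function(up, down, species = "human") {
  up <- unique(trimws(as.character(up)))
  down <- unique(trimws(as.character(down)))
  up <- up[nzchar(up)]
  down <- down[nzchar(down)]
  both <- intersect(up, down)
  if (length(both) > 0L) {
    abort(paste0("gene(s) listed both up and down: ",
                 paste(both, collapse = ", ")))
  }
  if (length(up) + length(down) == 0L) {
    abort("signature is empty")
  }
  structure(list(up = up, down = down, species = species),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("# Gene signature (%s): %d up, %d down\n",
              x$species, length(x$up), length(x$down)))
  invisible(x)
}

#' Read a directional gene signature
#'
#' Expects two columns without a header: gene symbol, then direction
#' (`up`/`down`, case-insensitive).
#'
#' @inheritParams read_expression_matrix
#' @param species Species tag to attach.
#' @return A [gene_signature()].
#' @export
read_signature <- function(path, species = "human", sep = c("tab", "comma")) {
  tab <- .read_two_columns(path, sep, c("symbol", "direction"))
  dir <- tolower(trimws(tab$direction))
  bad <- which(!dir %in% c("up", "down"))
  if (length(bad) > 0L) {
    abort(paste0("'", path, "': unknown direction token '",
                 tab$direction[bad[1L]], "' at line ", bad[1L]))
  }
  gene_signature(up = tab$symbol[dir == "up"],
                 down = tab$symbol[dir == "down"],
                 species = species)
}

#' Write a gene signature
#' @param sig A [gene_signature()].
#' @param path Output path.
#' @param sep `"tab"` or `"comma"`.
#' @return `sig`, invisibly.
#' @export
write_signature <- function(sig, path, sep = c("tab", "comma")) {
  tab <- tibble::tibble(
    symbol = c(sig$up, sig$down),
    direction = rep(c("up", "down"), c(length(sig$up), length(sig$down)))
  )
  readr::write_delim(tab, path, delim = .delim_char(sep), col_names = FALSE,
                     progress = FALSE)
  invisible(sig)
}

# Two-column headerless reader shared by signature / ortholog-map input;
# malformed lines (wrong field count, empty field) error with line numbers.
.read_two_columns <- function(path, sep = c("tab", "comma"), col_names) {
  delim <- .delim_char(sep)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(paste0("'", path, "': empty file"))
  }
  tab <- suppressWarnings(readr::read_delim(
    I(lines),
    delim = delim, col_names = col_names,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  ))
  prob <- readr::problems(tab)
  if (nrow(prob) > 0L) {
    abort(paste0("'", path, "': malformed line ", prob$row[1L],
                 " (expected 2 fields)"))
  }
  bad <- which(is.na(tab[[1L]]) | is.na(tab[[2L]]) |
                 !nzchar(trimws(tab[[1L]])) | !nzchar(trimws(tab[[2L]])))
  if (length(bad) > 0L) {
    abort(paste0("'", path, "': malformed line ", bad[1L],
                 " (expected 2 fields)"))
  }
  tab[[1L]] <- trimws(tab[[1L]])
  tab[[2L]] <- trimws(tab[[2L]])
  tab
}

#' Read an ortholog/homolog mapping table
#'
#' Two columns without a header: source symbol (e.g. mouse), target symbol
#' (e.g. human). Many-to-many mappings are allowed; exact duplicate pairs are
#' collapsed.
#'
#' @inheritParams read_expression_matrix
#' @return A tibble with columns `source` and `target`.
#' @export
read_ortholog_map <- function(path, sep = c("tab", "comma")) {
  tab <- .read_two_columns(path, sep, c("source", "target"))
  dplyr::distinct(tab)
}

#' Write an ortholog mapping table
#' @param map Tibble with columns `source`, `target`.
#' @param path Output path.
#' @param sep `"tab"` or `"comma"`.
#' @return `map`, invisibly.
#' @export
write_ortholog_map <- function(map, path, sep = c("tab", "comma")) {
  readr::write_delim(map[c("source", "target")], path,
                     delim = .delim_char(sep), col_names = FALSE,
                     progress = FALSE)
  invisible(map)
}

#' Read a gene set
#'
#' One symbol per line; an optional first line of the form `#name` names the
#' set (default: the file name).
#'
#' @param path Path to the gene-set file.
#' @return A `gene_set`: list with `name` and a character vector `genes`.
#' @export
read_gene_set <- function(path) {
  lines <- trimws(readr::read_lines(path, progress = FALSE))
  lines <- lines[nzchar(lines)]
  name <- sub("\\.[^.]*$", "", basename(path))
  if (length(lines) > 0L && startsWith(lines[1L], "#")) {
    name <- trimws(sub("^#", "", lines[1L]))
    lines <- lines[-1L]
  }
  if (length(lines) == 0L) {
    abort(paste0("'", path, "': gene set is empty"))
  }
  structure(list(name = name, genes = unique(lines)), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("# Gene set '%s': %d gene(s)\n", x$name, length(x$genes)))
  invisible(x)
}

#' Write a T-score table
#'
#' Columns, in order: `sample_id`, `tscore`, `pvalue`, `n_up`, `n_down`, `df`.
#'
#' @param table A T-score tibble as returned by [compute_tscores()].
#' @param path Output path.
#' @param sep `"tab"` or `"comma"`.
#' @return `table`, invisibly.
#' @export
write_tscores <- function(table, path, sep = c("tab", "comma")) {
  if (nrow(table) == 0L) {
    abort("T-score table is empty")
  }
  cols <- c("sample_id", "tscore", "pvalue", "n_up", "n_down", "df")
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0L) {
    abort(paste0("T-score table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  readr::write_delim(table[cols], path, delim = .delim_char(sep),
                     progress = FALSE)
  invisible(table)
}

#' Read a T-score table written by [write_tscores()]
#' @param path Path to the file.
#' @param sep `"tab"` or `"comma"`.
#' @return A tibble with the T-score columns.
#' @export
read_tscores <- function(path, sep = c("tab", "comma")) {
  readr::read_delim(
    path,
    delim = .delim_char(sep),
    col_types = readr::cols(
      sample_id = readr::col_character(),
      tscore = readr::col_double(),
      pvalue = readr::col_double(),
      n_up = readr::col_integer(),
      n_down = readr::col_integer(),
      df = readr::col_integer()
    ),
    progress = FALSE
  )
}
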