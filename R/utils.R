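# internal helpers shared across modules

# first column is the row id (gene_id / antibody_id); remaining columns samples
tbl_to_matrix <- function(tbl, what = "matrix") {
  ids <- tbl[[1]]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate %s ids in %s: %s", names(tbl)[1], what,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "phosphosig_error_duplicate_ids")
  }
  m <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    abort(sprintf("non-numeric values in %s", what),
          class = "phosphosig_error_parse")
  }
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

matrix_to_tbl <- function(m, id_col) {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- tibble(!!id_col := rownames(m), !!!out)
  out
}

expr_scale <- function(expr) attr(expr, "scale", exact = TRUE)

set_expr_scale <- function(expr, scale) {
  attr(expr, "scale") <- scale
  expr
}

# log-CPM transform expression tibbles declared (or assumed) to be counts
ensure_log_scale <- function(expr) {
  sc <- expr_scale(expr)
  if (identical(sc, "counts")) log_cpm(expr) else expr
}

sample_ids_of <- function(tbl) names(tbl)[-1]

assert_positive_scalar <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("configuration error: `%s` must be a positive number", field),
          class = "phosphosig_error_config")
  }
}

assert_count_scalar <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != trunc(x)) {
    abort(sprintf("configuration error: `%s` must be an integer >= %d", field, min),
          class = "phosphosig_error_config")
  }
}

# doubles formatted to round-trip exactly through text
fmt_double <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

write_tsv_exact <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(function(col) is.double(col) && !is.integer(col)), fmt_double))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
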