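#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row whose first field names the id column and whose
#' remaining fields are sample ids, then one row per gene. Duplicate
#' sample columns, duplicate gene rows, ragged rows and non-numeric
#' cells are rejected with the offending line reported.
#'
#' @param path TSV file path.
#' @param scale Declared value scale: `"counts"`, `"log2"` or
#'   `"intensity"`. Recorded as the tibble's `scale` attribute and used
#'   by downstream steps (e.g. [score_cohort()] log-CPM-transforms
#'   counts before scoring).
#' @return A tibble with first column `gene_id` and one numeric column
#'   per sample.
#' @export
read_expression <- function(path, scale = c("counts", "log2", "intensity")) {
  scale <- match.arg(scale)
  tbl <- read_matrix_tsv(path, id_col = "gene_id")
  if (scale == "counts" && any(as.matrix(tbl[, -1]) < 0)) {
    abort("counts-scale matrix contains negative values",
          class = "phosphosig_error_parse")
  }
  set_expr_scale(tbl, scale)
}

#' Write an expression (or RPPA) matrix tibble to TSV
#'
#' Doubles are written with enough digits to round-trip exactly.
#'
#' @param matrix Tibble with an id first column and sample columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(matrix, path) {
  write_tsv_exact(matrix, path)
}

#' Read an antibody-by-sample RPPA matrix from TSV
#'
#' Same layout rules as [read_expression()]; the first column is
#' `antibody_id`. Values are assumed already normalized (RPPA
#' level-3-like): no re-normalization is applied here or by
#' [pathway_activity()].
#'
#' @param path TSV file path.
#' @return A tibble with first column `antibody_id` and sample columns.
#' @export
read_rppa <- function(path) {
  read_matrix_tsv(path, id_col = "antibody_id")
}

#' Read a clinical table (sample_id, age, bmi, optional group) from TSV
#'
#' @param path TSV file path.
#' @return A tibble with `sample_id`, numeric `age` and `bmi`, plus any
#'   further columns present.
#' @export
read_clinical <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("sample_id", "age", "bmi")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols)) {
    abort(sprintf("clinical table missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "phosphosig_error_parse")
  }
  if (anyDuplicated(tbl$sample_id)) {
    abort("clinical table has duplicate sample_id values",
          class = "phosphosig_error_parse")
  }
  bad_age <- !is.na(tbl$age) & tbl$age <= 0
  bad_bmi <- !is.na(tbl$bmi) & tbl$bmi <= 0
  if (any(bad_age) || any(bad_bmi)) {
    abort("clinical table contains non-positive age or bmi",
          class = "phosphosig_error_parse")
  }
  tbl
}

read_matrix_tsv <- function(path, id_col) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'", path), class = "phosphosig_error_io")
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples)) {
    abort(sprintf("parse error (%s, line 1): duplicate sample column(s): %s",
                  basename(path),
                  paste(unique(samples[duplicated(samples)]), collapse = ", ")),
          class = "phosphosig_error_parse")
  }
  tbl <- suppressWarnings(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      .default = readr::col_character())))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(sprintf("parse error (%s, line %d): %s", basename(path),
                  probs$row[1] + 1L, probs$expected[1]),
          class = "phosphosig_error_parse")
  }
  names(tbl)[1] <- id_col
  # strtod-based conversion: correctly rounded, unlike fast float parsers
  for (j in seq_along(tbl)[-1]) {
    v <- suppressWarnings(as.numeric(tbl[[j]]))
    bad <- which(is.na(v) & !is.na(tbl[[j]]))
    if (length(bad)) {
      abort(sprintf("parse error (%s, line %d): non-numeric value '%s' in column '%s'",
                    basename(path), bad[1] + 1L, tbl[[j]][bad[1]],
                    names(tbl)[j]),
            class = "phosphosig_error_parse")
    }
    tbl[[j]] <- v
  }
  if (anyDuplicated(tbl[[1]])) {
    abort(sprintf("duplicate %s rows in '%s'; collapse before reading",
                  id_col, basename(path)),
          class = "phosphosig_error_duplicate_ids")
  }
  m <- as.matrix(tbl[, -1, drop = FALSE])
  if (any(!is.finite(m))) {
    abort(sprintf("parse error (%s): missing or non-finite values present",
                  basename(path)),
          class = "phosphosig_error_parse")
  }
  tbl
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name TAB description TAB member...`.
#' Duplicate members within a line are removed with a warning; a line
#' with fewer than three fields, or with no members, is an error.
#'
#' @param path GMT file path.
#' @return A tibble with columns `name`, `description` and `genes`
#'   (list-column of character vectors); zero rows for an empty file.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'", path), class = "phosphosig_error_io")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(name = character(), description = character(),
                  genes = list()))
  }
  parsed <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      abort(sprintf("parse error (%s, line %d): expected at least 3 tab-separated fields",
                    basename(path), i),
            class = "phosphosig_error_parse")
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      abort(sprintf("parse error (%s, line %d): gene set '%s' has no members",
                    basename(path), i, fields[1]),
            class = "phosphosig_error_parse")
    }
    if (anyDuplicated(members)) {
      warn(sprintf("gene set '%s': %d duplicate member(s) removed",
                   fields[1], sum(duplicated(members))))
      members <- unique(members)
    }
    tibble(name = fields[1], description = fields[2], genes = list(members))
  })
  dplyr::bind_rows(parsed)
}

#' Write gene sets to a GMT file
#'
#' @param sets Tibble as returned by [read_gmt()] (`name`,
#'   `description`, list-column `genes`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(sets, function(name, description, genes, ...) {
    paste(c(name, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}
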