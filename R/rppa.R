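#' Built-in phospho-protein pathway definitions
#'
#' `akt_pathway()` comprises the five phospho antibodies used for the
#' PI3K/AKT activity score: Akt S473 and T308, GSK3 S9 and S21/S9, and
#' PRAS40 T246. `mtor_pathway()` extends it with total mTOR, 4EBP1
#' (S65, T37/T46, T70), RICTOR T3135 and S6 (S235/S236, S240/S244).
#' Antibody ids use the canonical `PROTEIN_pRESIDUE` form (see
#' [canonicalize_antibody()]).
#'
#' @return A tibble of class `"pathway_def"` with columns
#'   `antibody_id`, `protein`, `residue` and a `pathway` attribute
#'   holding the pathway name.
#' @export
#' @examples
#' akt_pathway()
akt_pathway <- function() {
  pathway_def("AKT", tibble(
    antibody_id = c("AKT_pS473", "AKT_pT308", "GSK3_pS9", "GSK3_pS21S9",
                    "PRAS40_pT246"),
    protein = c("AKT", "AKT", "GSK3", "GSK3", "PRAS40"),
    residue = c("S473", "T308", "S9", "S21/S9", "T246")))
}

#' @rdname akt_pathway
#' @export
mtor_pathway <- function() {
  extra <- tibble(
    antibody_id = c("MTOR", "4EBP1_pS65", "4EBP1_pT37T46", "4EBP1_pT70",
                    "RICTOR_pT3135", "S6_pS235S236", "S6_pS240S244"),
    protein = c("MTOR", "4EBP1", "4EBP1", "4EBP1", "RICTOR", "S6", "S6"),
    residue = c(NA, "S65", "T37/T46", "T70", "T3135", "S235/S236",
                "S240/S244"))
  pathway_def("MTOR", dplyr::bind_rows(akt_pathway(), extra))
}

#' Define a custom phospho-protein pathway
#'
#' @param name Pathway name.
#' @param targets Tibble with at least `antibody_id`; optional
#'   `protein` and `residue` columns.
#' @return A `"pathway_def"` tibble.
#' @export
pathway_def <- function(name, targets) {
  if (!"antibody_id" %in% names(targets) || nrow(targets) == 0) {
    abort("pathway definition needs a non-empty `antibody_id` column",
          class = "phosphosig_error_input")
  }
  if (anyDuplicated(targets$antibody_id)) {
    abort("pathway definition has duplicate antibody ids",
          class = "phosphosig_error_input")
  }
  out <- as_tibble(targets)
  attr(out, "pathway") <- name
  class(out) <- unique(c("pathway_def", class(out)))
  out
}

#' Canonicalize RPPA antibody identifiers
#'
#' RPPA platforms name antibodies inconsistently ("Akt_pS473",
#' "AKT pS473", "Akt (S473)"). This maps a vector of ids to the
#' canonical `PROTEIN_pRESIDUE` form: user aliases are applied first,
#' then spaces, parentheses, slashes and dashes are stripped, the
#' remainder upper-cased and the phospho marker restored to `_p`.
#'
#' @param x Character vector of antibody ids.
#' @param aliases Optional named character vector mapping platform ids
#'   to canonical ids, applied before normalization.
#' @return Character vector of canonical ids.
#' @export
#' @examples
#' canonicalize_antibody(c("Akt_pS473", "GSK3 pS21/S9"))
canonicalize_antibody <- function(x, aliases = NULL) {
  if (!is.null(aliases)) {
    hit <- x %in% names(aliases)
    x[hit] <- aliases[x[hit]]
  }
  out <- toupper(x)
  out <- gsub("[/-]", "", out)          # residue separators: S21/S9 -> S21S9
  out <- gsub("[ ()]+", "_", out)       # word separators become underscores
  out <- gsub("_+", "_", out)
  out <- gsub("^_|_$", "", out)
  sub("_P(?=[STY0-9])", "_p", out, perl = TRUE)
}

#' Sum-based pathway activity scores from an RPPA matrix
#'
#' Each sample's activity is the sum of its normalized phospho-protein
#' levels over the pathway's antibodies. Input values are used as-is
#' (RPPA level-3-like, already normalized). Antibody matching is exact
#' on canonicalized ids.
#'
#' @param rppa Antibody-by-sample tibble (first column `antibody_id`).
#' @param pathway A `"pathway_def"`, e.g. [akt_pathway()].
#' @param missing_policy `"strict"` (default): any pathway antibody
#'   absent from `rppa` is an error; `"lenient"`: absent antibodies are
#'   skipped with a warning and recorded in the coverage.
#' @param aliases Optional alias table passed to
#'   [canonicalize_antibody()] for the `rppa` row ids.
#' @return A tibble of class `"activity_scores"` with columns
#'   `sample_id`, `activity`; attributes `pathway`, `coverage`
#'   (fraction of pathway antibodies found) and `antibodies_used`.
#' @export
pathway_activity <- function(rppa, pathway,
                             missing_policy = c("strict", "lenient"),
                             aliases = NULL) {
  missing_policy <- match.arg(missing_policy)
  if (!inherits(pathway, "pathway_def")) {
    abort("`pathway` must be a pathway_def", class = "phosphosig_error_input")
  }
  m <- tbl_to_matrix(rppa, "RPPA matrix")
  canon_rows <- canonicalize_antibody(rownames(m), aliases = aliases)
  wanted <- canonicalize_antibody(pathway$antibody_id)
  found <- wanted[wanted %in% canon_rows]
  absent <- setdiff(wanted, canon_rows)
  if (length(found) == 0) {
    abort(sprintf("no pathway antibody present in the RPPA matrix; missing: %s",
                  paste(absent, collapse = ", ")),
          class = "phosphosig_error_missing_antibody")
  }
  if (length(absent) > 0) {
    if (missing_policy == "strict") {
      abort(sprintf("pathway antibod%s absent from the RPPA matrix: %s (use missing_policy = \"lenient\" to skip)",
                    if (length(absent) > 1) "ies" else "y",
                    paste(absent, collapse = ", ")),
            class = "phosphosig_error_missing_antibody")
    }
    warn(sprintf("pathway_activity: skipping absent antibod%s: %s",
                 if (length(absent) > 1) "ies" else "y",
                 paste(absent, collapse = ", ")))
  }
  sub <- m[match(found, canon_rows), , drop = FALSE]
  out <- tibble(sample_id = colnames(m), activity = unname(colSums(sub)))
  attr(out, "pathway") <- attr(pathway, "pathway")
  attr(out, "coverage") <- length(found) / length(wanted)
  attr(out, "antibodies_used") <- found
  class(out) <- c("activity_scores", class(out))
  out
}

#' Correlate an activity score vector with another per-sample quantity
#'
#' Computed over the intersection of sample ids; at least three shared
#' samples are required and both vectors must vary.
#'
#' @param a An `"activity_scores"` tibble (or any tibble with
#'   `sample_id` and a numeric second column), or a named numeric
#'   vector.
#' @param b Same accepted forms as `a`.
#' @param method `"pearson"` or `"spearman"`.
#' @return A one-row tibble: `estimate`, `p.value`, `n`, `method`.
#' @export
score_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  av <- as_named_scores(a)
  bv <- as_named_scores(b)
  shared <- intersect(names(av), names(bv))
  if (length(shared) < 3L) {
    abort(sprintf("score_correlation needs >= 3 shared samples (got %d)",
                  length(shared)),
          class = "phosphosig_error_input")
  }
  x <- av[shared]
  y <- bv[shared]
  if (sd(x) == 0 || sd(y) == 0) {
    abort("score_correlation: zero variance in one of the vectors",
          class = "phosphosig_error_input")
  }
  ct <- suppressWarnings(cor.test(x, y, method = method))
  tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
         n = length(shared), method = method)
}

as_named_scores <- function(x) {
  if (is.numeric(x)) {
    if (is.null(names(x))) {
      abort("numeric score vectors must be named by sample id",
            class = "phosphosig_error_input")
    }
    return(x)
  }
  if (is.data.frame(x)) {
    num_cols <- names(x)[vapply(x, is.numeric, logical(1))]
    if (!"sample_id" %in% names(x) || length(num_cols) == 0) {
      abort("score tables must have `sample_id` and a numeric column",
            class = "phosphosig_error_input")
    }
    return(setNames(x[[num_cols[1]]], x$sample_id))
  }
  abort("unsupported score input", class = "phosphosig_error_input")
}
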