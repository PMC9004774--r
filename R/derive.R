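#' Stratify samples into phospho-high and phospho-low classes
#'
#' Dichotomizes the continuous anchor antibody values at the q-th
#' quantile: samples strictly above the cut are labelled `high`, the
#' rest `low`. The default median split is the package's reading of
#' "phosphorylated vs non-phosphorylated" sample classes.
#'
#' @param rppa Antibody-by-sample tibble.
#' @param antibody Anchor antibody id (canonical form, see
#'   [canonicalize_antibody()]).
#' @param q Quantile in (0, 1); default 0.5.
#' @param aliases Optional alias table for the `rppa` row ids.
#' @return A tibble of class `"phospho_strata"` with columns
#'   `sample_id`, `value`, `label` (factor low/high); attributes
#'   `antibody`, `q`, `cut`.
#' @export
stratify_by_phospho <- function(rppa, antibody, q = 0.5, aliases = NULL) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    abort("`q` must lie strictly between 0 and 1",
          class = "phosphosig_error_input")
  }
  v <- anchor_values(rppa, antibody, aliases)
  if (max(v) == min(v)) {
    abort(sprintf("cannot stratify: all values of '%s' are identical", antibody),
          class = "phosphosig_error_degenerate")
  }
  cut <- unname(quantile(v, q))
  label <- factor(ifelse(v > cut, "high", "low"), levels = c("low", "high"))
  if (any(table(label) == 0)) {
    abort(sprintf("stratification at q = %g leaves an empty class", q),
          class = "phosphosig_error_degenerate")
  }
  out <- tibble(sample_id = names(v), value = unname(v), label = label)
  attr(out, "antibody") <- antibody
  attr(out, "q") <- q
  attr(out, "cut") <- cut
  class(out) <- c("phospho_strata", class(out))
  out
}

anchor_values <- function(rppa, antibody, aliases = NULL) {
  m <- tbl_to_matrix(rppa, "RPPA matrix")
  canon <- canonicalize_antibody(rownames(m), aliases = aliases)
  idx <- match(canonicalize_antibody(antibody), canon)
  if (is.na(idx)) {
    abort(sprintf("antibody '%s' not found in the RPPA matrix", antibody),
          class = "phosphosig_error_missing_antibody")
  }
  setNames(m[idx, ], colnames(m))
}

#' Differential expression between phospho-high and phospho-low samples
#'
#' Per-gene Welch two-sample t-test on log2 expression (counts are
#' log-CPM transformed first), `log2fc = mean(high) - mean(low)`, with
#' Benjamini-Hochberg adjustment across all tested genes. Genes with
#' zero variance in both classes get `p = 1` and are flagged.
#'
#' @param expr Gene-by-sample expression tibble; log2 scale, or counts
#'   (auto-transformed).
#' @param strata A [stratify_by_phospho()] result; only samples shared
#'   with `expr` are used, and each class needs at least two of them.
#' @return A tibble: `gene_id`, `log2fc`, `statistic`, `df`, `p.value`,
#'   `fdr`, `zero_variance`; attribute `anchor` echoes the
#'   stratification's antibody.
#' @export
differential_expression <- function(expr, strata) {
  if (!inherits(strata, "phospho_strata")) {
    abort("`strata` must come from stratify_by_phospho()",
          class = "phosphosig_error_input")
  }
  expr <- ensure_log_scale(expr)
  m <- tbl_to_matrix(expr, "expression matrix")
  shared <- intersect(colnames(m), strata$sample_id)
  lab <- setNames(as.character(strata$label), strata$sample_id)[shared]
  hi <- shared[lab == "high"]
  lo <- shared[lab == "low"]
  if (length(hi) < 2L || length(lo) < 2L) {
    abort(sprintf("each class needs >= 2 samples (high: %d, low: %d)",
                  length(hi), length(lo)),
          class = "phosphosig_error_input")
  }
  res <- welch_by_row(m[, hi, drop = FALSE], m[, lo, drop = FALSE])
  out <- tibble(gene_id = rownames(m), log2fc = res$log2fc,
                statistic = res$statistic, df = res$df, p.value = res$p,
                fdr = p.adjust(res$p, method = "BH"),
                zero_variance = res$zero_variance)
  attr(out, "anchor") <- attr(strata, "antibody")
  out
}

# vectorized Welch t over matrix rows: x = high class, y = low class
welch_by_row <- function(x, y) {
  nx <- ncol(x)
  ny <- ncol(y)
  mx <- rowMeans(x)
  my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  stat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(stat), df)
  degenerate <- vx == 0 & vy == 0
  stat[degenerate] <- 0
  df[degenerate] <- NA_real_
  p[degenerate] <- 1
  list(log2fc = unname(mx - my), statistic = unname(stat), df = unname(df),
       p = unname(p), zero_variance = unname(degenerate))
}

#' Correlate each gene's expression with the anchor phospho values
#'
#' Computed over the samples shared between the expression and RPPA
#' matrices. For `method = "spearman"` both sides are rank-transformed
#' first; p-values come from the t-transform of r on n - 2 degrees of
#' freedom. Zero-variance genes are flagged `excluded` with `NA`
#' estimates.
#'
#' @param expr Gene-by-sample expression tibble (counts are log-CPM
#'   transformed first).
#' @param rppa Antibody-by-sample tibble.
#' @param antibody Anchor antibody id.
#' @param method `"spearman"` (default, robust to the mixed scales of
#'   RNA-seq and RPPA) or `"pearson"`.
#' @param aliases Optional alias table for the `rppa` row ids.
#' @return A tibble: `gene_id`, `estimate`, `p.value`, `excluded`;
#'   attributes `anchor`, `method`.
#' @export
mrna_phospho_correlation <- function(expr, rppa, antibody,
                                     method = c("spearman", "pearson"),
                                     aliases = NULL) {
  method <- match.arg(method)
  expr <- ensure_log_scale(expr)
  m <- tbl_to_matrix(expr, "expression matrix")
  v <- anchor_values(rppa, antibody, aliases)
  shared <- intersect(colnames(m), names(v))
  if (length(shared) < 3L) {
    abort(sprintf("mrna_phospho_correlation needs >= 3 shared samples (got %d)",
                  length(shared)),
          class = "phosphosig_error_input")
  }
  m <- m[, shared, drop = FALSE]
  v <- v[shared]
  gene_ids <- rownames(m)
  if (sd(v) == 0) {
    abort(sprintf("anchor '%s' has zero variance over shared samples", antibody),
          class = "phosphosig_error_degenerate")
  }
  if (method == "spearman") {
    m <- matrix(t(apply(m, 1L, rank)), nrow = length(gene_ids))
    v <- rank(v)
  }
  n <- length(shared)
  mc <- m - rowMeans(m)
  vc <- v - mean(v)
  denom <- sqrt(rowSums(mc^2) * sum(vc^2))
  excluded <- denom == 0
  r <- ifelse(excluded, NA_real_, (mc %*% vc)[, 1] / denom)
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  out <- tibble(gene_id = gene_ids, estimate = unname(r),
                p.value = unname(p), excluded = unname(excluded))
  attr(out, "anchor") <- antibody
  attr(out, "method") <- method
  out
}

#' Assemble an up/down gene signature from DE and correlation filters
#'
#' A gene enters the up set when it is over-expressed in phospho-high
#' samples (`log2fc >= lfc_min`, `fdr <= fdr_max`) and positively
#' correlated with the anchor (`estimate > 0`, `p.value <= p_max`); the
#' down set mirrors this with negated thresholds. Genes whose DE
#' direction contradicts their correlation sign are excluded as
#' discordant and counted in the provenance.
#'
#' @param de A [differential_expression()] result.
#' @param corr An [mrna_phospho_correlation()] result over the same
#'   gene universe.
#' @param lfc_min Minimum absolute log2 fold change (default 1).
#' @param fdr_max Maximum BH-adjusted DE p (default 0.05).
#' @param p_max Maximum correlation p (default 0.05).
#' @param name Signature name used when exporting to GMT.
#' @param allow_empty Permit an empty up or down set (default FALSE:
#'   an empty set is an error, since the ratio-of-means score needs
#'   both). Useful for null-calibration studies.
#' @return An object of class `"gene_signature"`: list with character
#'   vectors `up` and `down` and a `provenance` list (anchor,
#'   thresholds, discordant count, universe size).
#' @export
assemble_signature <- function(de, corr, lfc_min = 1, fdr_max = 0.05,
                               p_max = 0.05, name = NULL,
                               allow_empty = FALSE) {
  if (!setequal(de$gene_id, corr$gene_id)) {
    abort("`de` and `corr` must cover the same gene universe",
          class = "phosphosig_error_input")
  }
  j <- dplyr::inner_join(
    dplyr::select(de, "gene_id", "log2fc", "fdr"),
    dplyr::select(corr, "gene_id", r = "estimate", p_corr = "p.value",
                  "excluded"),
    by = "gene_id") |>
    dplyr::filter(!.data$excluded, !is.na(.data$r))
  de_up <- j$log2fc >= lfc_min & j$fdr <= fdr_max
  de_dn <- j$log2fc <= -lfc_min & j$fdr <= fdr_max
  corr_ok <- j$p_corr <= p_max
  up <- j$gene_id[de_up & corr_ok & j$r > 0]
  down <- j$gene_id[de_dn & corr_ok & j$r < 0]
  n_discordant <- sum((de_up & corr_ok & j$r < 0) | (de_dn & corr_ok & j$r > 0))
  if (!allow_empty && (length(up) == 0 || length(down) == 0)) {
    empty <- if (length(up) == 0) "up" else "down"
    dir_pass <- if (empty == "up") de_up else de_dn
    near <- if (any(dir_pass)) {
      sprintf("smallest correlation p among DE-passing genes: %.3g",
              suppressWarnings(min(j$p_corr[dir_pass])))
    } else {
      fdr_dir <- if (empty == "up") j$fdr[j$log2fc >= lfc_min] else j$fdr[j$log2fc <= -lfc_min]
      if (length(fdr_dir)) {
        sprintf("smallest FDR among genes passing the fold-change cut: %.3g",
                min(fdr_dir))
      } else {
        sprintf("no gene reaches |log2fc| >= %g in that direction", lfc_min)
      }
    }
    abort(sprintf("signature %s set is empty (%s)", empty, near),
          class = "phosphosig_error_empty_signature")
  }
  structure(
    list(up = up, down = down,
         provenance = list(
           anchor = attr(de, "anchor") %||% attr(corr, "anchor"),
           lfc_min = lfc_min, fdr_max = fdr_max, p_max = p_max,
           correlation_method = attr(corr, "method"),
           n_discordant = n_discordant, n_genes_tested = nrow(j),
           name = name %||% paste0(attr(de, "anchor") %||% "SIG", "_SIGNATURE"))),
    class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s (anchor: %s)\n", x$provenance$name,
              x$provenance$anchor %||% "unknown"))
  cat(sprintf("  up: %d genes, down: %d genes, discordant excluded: %d\n",
              length(x$up), length(x$down), x$provenance$n_discordant))
  cat(sprintf("  thresholds: |log2FC| >= %g, FDR <= %g, corr p <= %g\n",
              x$provenance$lfc_min, x$provenance$fdr_max, x$provenance$p_max))
  invisible(x)
}

#' Derive a phospho-anchored signature in one call
#'
#' Convenience composition: stratify by the anchor antibody, test
#' differential expression, correlate genes with the anchor, assemble.
#'
#' @inheritParams stratify_by_phospho
#' @inheritParams mrna_phospho_correlation
#' @inheritParams assemble_signature
#' @param expr Gene-by-sample expression tibble.
#' @return A `"gene_signature"`.
#' @export
derive_signature <- function(expr, rppa, antibody, q = 0.5,
                             method = c("spearman", "pearson"),
                             lfc_min = 1, fdr_max = 0.05, p_max = 0.05,
                             name = NULL, allow_empty = FALSE,
                             aliases = NULL) {
  method <- match.arg(method)
  expr <- ensure_log_scale(expr)
  strata <- stratify_by_phospho(rppa, antibody, q = q, aliases = aliases)
  de <- differential_expression(expr, strata)
  corr <- mrna_phospho_correlation(expr, rppa, antibody, method = method,
                                   aliases = aliases)
  assemble_signature(de, corr, lfc_min = lfc_min, fdr_max = fdr_max,
                     p_max = p_max, name = name, allow_empty = allow_empty)
}

#' Export a signature as two GMT gene sets (NAME_UP / NAME_DOWN)
#'
#' @param signature A `"gene_signature"`.
#' @return A GMT tibble suitable for [write_gmt()].
#' @export
signature_to_gmt <- function(signature) {
  nm <- signature$provenance$name
  desc <- sprintf("anchor=%s;lfc_min=%g;fdr_max=%g;p_max=%g",
                  signature$provenance$anchor %||% "NA",
                  signature$provenance$lfc_min, signature$provenance$fdr_max,
                  signature$provenance$p_max)
  tibble(name = paste0(nm, c("_UP", "_DOWN")),
         description = desc,
         genes = list(signature$up, signature$down))
}

#' Build a signature object from explicit up/down gene sets
#'
#' Wraps user-supplied gene lists (e.g. published signatures read from
#' GMT) so they can be scored with [score_cohort()].
#'
#' @param up,down Character vectors of gene ids.
#' @param name Signature name.
#' @return A `"gene_signature"`.
#' @export
gene_signature <- function(up, down, name = "SIGNATURE") {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  if (length(up) == 0 || length(down) == 0) {
    abort("both up and down sets must be non-empty",
          class = "phosphosig_error_empty_signature")
  }
  if (length(intersect(up, down)) > 0) {
    abort("up and down sets overlap", class = "phosphosig_error_input")
  }
  structure(list(up = up, down = down,
                 provenance = list(anchor = NA_character_, lfc_min = NA_real_,
                                   fdr_max = NA_real_, p_max = NA_real_,
                                   n_discordant = 0L,
                                   n_genes_tested = NA_integer_, name = name)),
            class = "gene_signature")
}
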