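test_that("phospho stratification splits at the requested quantile", {
  rppa <- anchor_rppa(c(1, 2, 3, 4))
  st <- stratify_by_phospho(rppa, "AKT_pS473", q = 0.5)
  expect_identical(as.character(st$label), c("low", "low", "high", "high"))
  expect_equal(attr(st, "cut"), 2.5)
  st75 <- stratify_by_phospho(rppa, "AKT_pS473", q = 0.75)
  expect_identical(st75$sample_id[st75$label == "high"], "s004")
  expect_error(stratify_by_phospho(anchor_rppa(rep(2, 4)), "AKT_pS473"),
               class = "phosphosig_error_degenerate")
  expect_error(stratify_by_phospho(rppa, "AKT_pS473", q = 1),
               class = "phosphosig_error_input")
  expect_error(stratify_by_phospho(rppa, "NOT_THERE"),
               class = "phosphosig_error_missing_antibody")
})

test_that("phospho-high samples carry higher latent activity", {
  hits <- vapply(1:20, function(s) {
    co <- simulate_cohort(cohort_config(n_samples = 200, n_genes = 20,
                                        n_up = 2, n_down = 2, seed = 1000 + s))
    st <- stratify_by_phospho(co$rppa, "AKT_pS473")
    a <- setNames(co$truth$samples$latent_activity, co$truth$samples$sample_id)
    mean(a[st$sample_id[st$label == "high"]]) >
      mean(a[st$sample_id[st$label == "low"]])
  }, logical(1))
  expect_true(all(hits))
})

log2_expr <- function(values_by_gene, sample_ids) {
  dplyr::bind_cols(
    tibble::tibble(gene_id = names(values_by_gene)),
    tibble::as_tibble(do.call(rbind, values_by_gene),
                      .name_repair = ~sample_ids))
}

test_that("differential expression reproduces the Welch formulation", {
  sample_ids <- sprintf("s%03d", 1:6)
  strat <- structure(
    tibble::tibble(sample_id = sample_ids,
                   value = c(4, 4, 4, 1, 1, 1),
                   label = factor(rep(c("high", "low"), each = 3),
                                  levels = c("low", "high"))),
    antibody = "AKT_pS473", q = 0.5, cut = 2.5,
    class = c("phospho_strata", class(tibble::tibble())))
  expr <- log2_expr(list(gA = c(10, 10.1, 9.9, 6, 6.1, 5.9),
                         gB = c(7, 7, 7, 7, 7, 7),
                         gC = c(5, 6, 7, 6.5, 5.5, 6)),
                    sample_ids)
  de <- differential_expression(expr, strat)
  expect_equal(de$log2fc[de$gene_id == "gA"], 4.0, tolerance = 1e-12)
  oracle <- brute_welch(c(10, 10.1, 9.9), c(6, 6.1, 5.9))
  expect_equal(de$statistic[de$gene_id == "gA"], oracle$statistic,
               tolerance = 1e-10)
  expect_equal(de$p.value[de$gene_id == "gA"], oracle$p, tolerance = 1e-10)
  # flat gene: zero variance in both classes
  expect_equal(de$log2fc[de$gene_id == "gB"], 0)
  expect_equal(de$p.value[de$gene_id == "gB"], 1)
  expect_true(de$zero_variance[de$gene_id == "gB"])
  expect_true(all(de$fdr >= de$p.value - 1e-15))
  expect_identical(attr(de, "anchor"), "AKT_pS473")
})

test_that("vectorized Welch agrees with t.test across random instances", {
  withr::with_seed(4, {
    for (i in 1:50) {
      n1 <- sample(3:8, 1)
      n2 <- sample(3:8, 1)
      x <- rnorm(n1, mean = runif(1, -2, 2))
      y <- rnorm(n2, mean = runif(1, -2, 2))
      expr <- log2_expr(list(g1 = c(x, y), g2 = rnorm(n1 + n2)),
                        sprintf("s%03d", seq_len(n1 + n2)))
      strat <- structure(
        tibble::tibble(sample_id = sprintf("s%03d", seq_len(n1 + n2)),
                       value = c(rep(1, n1), rep(0, n2)),
                       label = factor(rep(c("high", "low"), c(n1, n2)),
                                      levels = c("low", "high"))),
        antibody = "X", class = c("phospho_strata", class(tibble::tibble())))
      de <- differential_expression(expr, strat)
      tt <- stats::t.test(x, y, var.equal = FALSE)
      expect_equal(de$statistic[1], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(de$df[1], unname(tt$parameter), tolerance = 1e-10)
      expect_equal(de$p.value[1], tt$p.value, tolerance = 1e-10)
    }
  })
})

test_that("differential expression requires two samples per class", {
  sample_ids <- sprintf("s%03d", 1:3)
  strat <- structure(
    tibble::tibble(sample_id = sample_ids, value = c(3, 1, 1),
                   label = factor(c("high", "low", "low"),
                                  levels = c("low", "high"))),
    class = c("phospho_strata", class(tibble::tibble())))
  expr <- log2_expr(list(g1 = c(1, 2, 3)), sample_ids)
  expect_error(differential_expression(expr, strat),
               class = "phosphosig_error_input")
})

test_that("gene-anchor correlation matches rank-based brute force", {
  v <- c(0.3, -1.2, 2.2, 0.9, -0.5, 1.4)
  rppa <- anchor_rppa(v)
  ids <- sprintf("s%03d", 1:6)
  expr <- log2_expr(list(copy = v + 5, neg = 5 - v,
                         other = c(2.5, 0.1, 1.7, -0.3, 0.8, 1.1) + 5),
                    ids)
  corr <- mrna_phospho_correlation(expr, rppa, "AKT_pS473")
  expect_equal(corr$estimate[corr$gene_id == "copy"], 1)
  expect_equal(corr$estimate[corr$gene_id == "neg"], -1)
  expect_equal(corr$estimate[corr$gene_id == "other"],
               brute_spearman(c(2.5, 0.1, 1.7, -0.3, 0.8, 1.1), v),
               tolerance = 1e-12)
  pear <- mrna_phospho_correlation(expr, rppa, "AKT_pS473",
                                   method = "pearson")
  expect_equal(pear$estimate[pear$gene_id == "other"],
               brute_pearson(c(2.5, 0.1, 1.7, -0.3, 0.8, 1.1), v),
               tolerance = 1e-12)
})

test_that("zero-variance genes are flagged and excluded from correlation", {
  rppa <- anchor_rppa(c(1, 2, 3, 4))
  expr <- log2_expr(list(flat = rep(3, 4), live = c(1, 2, 3, 4)),
                    sprintf("s%03d", 1:4))
  corr <- mrna_phospho_correlation(expr, rppa, "AKT_pS473")
  expect_true(corr$excluded[corr$gene_id == "flat"])
  expect_true(is.na(corr$estimate[corr$gene_id == "flat"]))
  expect_false(corr$excluded[corr$gene_id == "live"])
})

fake_de <- function(genes, log2fc, fdr) {
  structure(tibble::tibble(gene_id = genes, log2fc = log2fc,
                           statistic = 0, df = 1, p.value = fdr, fdr = fdr,
                           zero_variance = FALSE),
            anchor = "AKT_pS473")
}

fake_corr <- function(genes, r, p) {
  structure(tibble::tibble(gene_id = genes, estimate = r, p.value = p,
                           excluded = FALSE),
            anchor = "AKT_pS473", method = "spearman")
}

test_that("signature assembly applies the concordance filter", {
  genes <- c("gUp", "gDiscordant", "gDown", "gWeak", "gCorrOnly")
  de <- fake_de(genes, log2fc = c(2, 2, -2, 0.5, 0),
                fdr = c(0.01, 0.01, 0.01, 0.01, 0.9))
  corr <- fake_corr(genes, r = c(0.6, -0.6, -0.5, 0.7, 0.8),
                    p = c(0.001, 0.001, 0.02, 0.001, 0.001))
  sig <- assemble_signature(de, corr)
  expect_identical(sig$up, "gUp")
  expect_identical(sig$down, "gDown")
  expect_equal(sig$provenance$n_discordant, 1)
  expect_length(intersect(sig$up, sig$down), 0)
})

test_that("empty signature sets raise informative errors unless allowed", {
  genes <- c("g1", "g2")
  de <- fake_de(genes, log2fc = c(2, -2), fdr = c(0.01, 0.5))
  corr <- fake_corr(genes, r = c(0.5, -0.5), p = c(0.01, 0.3))
  expect_error(assemble_signature(de, corr), "down",
               class = "phosphosig_error_empty_signature")
  sig <- assemble_signature(de, corr, allow_empty = TRUE)
  expect_identical(sig$up, "g1")
  expect_length(sig$down, 0)
  expect_error(assemble_signature(de, fake_corr("g3", 0.5, 0.01)),
               class = "phosphosig_error_input")
})

test_that("tightening any threshold never grows the signature", {
  co <- small_cohort(seed = 6)
  expr <- log_cpm(co$expression)
  st <- stratify_by_phospho(co$rppa, "AKT_pS473")
  de <- differential_expression(expr, st)
  corr <- mrna_phospho_correlation(expr, co$rppa, "AKT_pS473")
  loose <- assemble_signature(de, corr, lfc_min = 0.5, fdr_max = 0.1,
                              p_max = 0.1, allow_empty = TRUE)
  for (args in list(list(lfc_min = 1), list(fdr_max = 0.01),
                    list(p_max = 0.01))) {
    tight <- do.call(assemble_signature,
                     c(list(de = de, corr = corr, allow_empty = TRUE),
                       utils::modifyList(list(lfc_min = 0.5, fdr_max = 0.1,
                                              p_max = 0.1), args)))
    expect_true(all(tight$up %in% loose$up))
    expect_true(all(tight$down %in% loose$down))
  }
})

test_that("planted memberships are recovered on a strong-effect cohort", {
  co <- simulate_cohort(cohort_config(n_samples = 200, n_genes = 500,
                                      n_up = 25, n_down = 25, beta = 1,
                                      seed = 91))
  sig <- derive_signature(co$expression, co$rppa, "AKT_pS473")
  truth <- co$truth$genes
  planted_up <- truth$gene_id[truth$membership == "up"]
  planted_down <- truth$gene_id[truth$membership == "down"]
  expect_gte(mean(planted_up %in% sig$up), 0.9)
  expect_gte(mean(planted_down %in% sig$down), 0.9)
  nulls <- truth$gene_id[truth$membership == "null"]
  expect_lte(mean(c(sig$up, sig$down) %in% nulls), 0.05)
})

test_that("under a null cohort the derivation recovers nothing above chance", {
  co <- simulate_cohort(cohort_config(n_samples = 100, n_genes = 500,
                                      n_up = 25, n_down = 25, beta = 0,
                                      seed = 13))
  sig <- derive_signature(co$expression, co$rppa, "AKT_pS473",
                          allow_empty = TRUE)
  expect_lte(length(sig$up) + length(sig$down), 5)
})
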