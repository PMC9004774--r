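# independent oracles used to cross-check the package's statistics;
# deliberately written as plain loops / enumeration, not shared with R/

# exhaustive two-sided rank-sum p: enumerate all C(n, n1) group labelings
# and count rank-sum deviations at least as extreme as observed
enum_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  n1 <- length(x)
  r <- rank(pooled)
  mu <- n1 * (n + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  labelings <- utils::combn(n, n1)
  sums <- apply(labelings, 2L, function(i) sum(r[i]))
  mean(abs(sums - mu) >= obs - 1e-9)
}

# brute-force Pearson r via the covariance formula
brute_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

brute_spearman <- function(x, y) brute_pearson(rank(x), rank(y))

# Welch t via scalar formulas, independent of the vectorized implementation
brute_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  stat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(statistic = stat, df = df,
       p = 2 * stats::pt(-abs(stat), df))
}

# quantile normalization by explicit sort-and-average (no ties assumed)
brute_quantile_normalize <- function(m) {
  target <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) out[, j] <- target[rank(m[, j])]
  out
}

rand_expr_tbl <- function(n_genes, n_samples, seed = 1, prefix = "g") {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples, mean = 8, sd = 2),
                nrow = n_genes,
                dimnames = list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n_samples))))
    dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                     tibble::as_tibble(abs(m), .name_repair = "minimal"))
  })
}

# tiny RPPA tibble with a single anchor row
anchor_rppa <- function(values, antibody = "AKT_pS473") {
  ids <- sprintf("s%03d", seq_along(values))
  tibble::tibble(antibody_id = antibody,
                 !!!stats::setNames(as.list(values), ids))
}

small_cohort <- function(seed = 42, ...) {
  simulate_cohort(cohort_config(n_samples = 60, n_genes = 300, n_up = 15,
                                n_down = 15, seed = seed, ...))
}

tbl_to_mat <- function(tbl) {
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl[[1]]
  storage.mode(m) <- "double"
  m
}
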