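#' Configuration for a simulated paired expression/RPPA cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The
#' simulator emulates the joint structure this package's analyses assume:
#' a per-sample latent phospho-protein activity drives both the RPPA
#' phospho-antibody readout and the up-/down-modulation of planted gene
#' sets in an RNA-seq count matrix, with an additive latent shift in the
#' obese BMI group.
#'
#' @param n_samples Number of samples.
#' @param n_genes Number of genes in the count matrix.
#' @param n_up,n_down Sizes of the planted up- and down-modulated gene sets.
#' @param beta Effect size: log2-scale expression shift per unit latent
#'   activity for planted genes (`+beta` for up, `-beta` for down).
#' @param sigma_a Standard deviation of the latent phospho activity.
#' @param delta_group Additive latent-activity shift for the obese group,
#'   in units of `sigma_a`.
#' @param frac_obese,frac_overweight Group proportions; the remainder is
#'   normal-weight. Group sizes are deterministic rounded counts.
#' @param frac_pre Proportion of samples drawn from the premenopausal age
#'   range.
#' @param age_range_pre,age_range_post Integer year ranges `c(lo, hi)` for
#'   pre- and postmenopausal ages.
#' @param mean_library_size Expected total counts per sample.
#' @param dispersion Negative-binomial overdispersion (variance
#'   `mu + dispersion * mu^2`); `0` gives Poisson counts.
#' @param rppa_noise_sd Measurement noise SD added to each activity-linked
#'   antibody.
#' @param n_decoys Number of pure-noise decoy antibodies appended to the
#'   RPPA matrix.
#' @param seed Integer RNG seed; the same seed reproduces the cohort
#'   bit-identically.
#'
#' @return A validated list of class `"cohort_config"`.
#' @seealso [simulate_cohort()]
#' @export
#' @examples
#' cohort_config(n_samples = 20, n_genes = 100, n_up = 5, n_down = 5)
cohort_config <- function(n_samples = 200L,
                          n_genes = 2000L,
                          n_up = 50L,
                          n_down = 50L,
                          beta = 1,
                          sigma_a = 1,
                          delta_group = 1,
                          frac_obese = 1 / 3,
                          frac_overweight = 1 / 3,
                          frac_pre = 0.5,
                          age_range_pre = c(30L, 48L),
                          age_range_post = c(49L, 75L),
                          mean_library_size = 1e6,
                          dispersion = 0.1,
                          rppa_noise_sd = 0.2,
                          n_decoys = 3L,
                          seed = 1L) {
  assert_count_scalar(n_samples, "n_samples", min = 2L)
  assert_count_scalar(n_genes, "n_genes")
  assert_count_scalar(n_up, "n_up", min = 0L)
  assert_count_scalar(n_down, "n_down", min = 0L)
  assert_count_scalar(n_decoys, "n_decoys", min = 0L)
  assert_count_scalar(seed, "seed", min = -.Machine$integer.max)
  if (n_up + n_down > n_genes) {
    abort("configuration error: `n_up` + `n_down` must not exceed `n_genes`",
          class = "phosphosig_error_config")
  }
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta)) {
    abort("configuration error: `beta` must be a number",
          class = "phosphosig_error_config")
  }
  assert_positive_scalar(sigma_a, "sigma_a")
  assert_positive_scalar(mean_library_size, "mean_library_size")
  assert_positive_scalar(rppa_noise_sd, "rppa_noise_sd")
  if (!is.numeric(dispersion) || length(dispersion) != 1L || dispersion < 0) {
    abort("configuration error: `dispersion` must be >= 0",
          class = "phosphosig_error_config")
  }
  if (!is.numeric(delta_group) || length(delta_group) != 1L || is.na(delta_group)) {
    abort("configuration error: `delta_group` must be a number",
          class = "phosphosig_error_config")
  }
  for (f in c("frac_obese", "frac_overweight", "frac_pre")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("configuration error: `%s` must be in [0, 1]", f),
            class = "phosphosig_error_config")
    }
  }
  if (frac_obese + frac_overweight > 1) {
    abort("configuration error: `frac_obese` + `frac_overweight` must be <= 1",
          class = "phosphosig_error_config")
  }
  for (f in c("age_range_pre", "age_range_post")) {
    r <- get(f)
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2]) {
      abort(sprintf("configuration error: `%s` must be c(lo, hi) with 0 < lo <= hi", f),
            class = "phosphosig_error_config")
    }
  }
  structure(
    list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
         n_up = as.integer(n_up), n_down = as.integer(n_down),
         beta = as.double(beta), sigma_a = as.double(sigma_a),
         delta_group = as.double(delta_group),
         frac_obese = as.double(frac_obese),
         frac_overweight = as.double(frac_overweight),
         frac_pre = as.double(frac_pre),
         age_range_pre = as.integer(age_range_pre),
         age_range_post = as.integer(age_range_post),
         mean_library_size = as.double(mean_library_size),
         dispersion = as.double(dispersion),
         rppa_noise_sd = as.double(rppa_noise_sd),
         n_decoys = as.integer(n_decoys),
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' Simulate a paired expression / RPPA / clinical cohort with ground truth
#'
#' Draws a per-sample latent phospho activity `a_i ~ N(shift_i, sigma_a)`
#' (where `shift_i = delta_group * sigma_a` for obese samples and 0
#' otherwise), exposes it through (a) the RPPA matrix — each AKT-pathway
#' phospho antibody measures `a_i` plus independent Gaussian noise, with
#' the designated anchor `AKT_pS473` first, plus pure-noise decoys — and
#' (b) the count matrix, where a planted gene's log2 mean is shifted by
#' `+/- beta * a_i`. Gene baselines are log-normal; counts are
#' negative-binomial with per-sample means rescaled to the expected
#' library size; BMI is uniform within each group's class interval and
#' age uniform within the pre-/postmenopausal ranges.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `"phospho_cohort"`: a list with elements
#'   `expression` (tibble, `gene_id` + one column per sample, raw counts,
#'   scale attribute `"counts"`), `rppa` (tibble, `antibody_id` + sample
#'   columns), `clinical` (tibble: `sample_id`, `age`, `bmi`, `group`)
#'   and `truth` (list: `samples` tibble with `sample_id`,
#'   `latent_activity`, `group`; `genes` tibble with `gene_id`,
#'   `membership` in up/down/null; the `config`).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_samples = 30, n_genes = 200,
#'                                         n_up = 10, n_down = 10, seed = 7))
#' dplyr::count(cohort$truth$genes, membership)
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created by cohort_config()",
          class = "phosphosig_error_config")
  }
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_samples
  g <- config$n_genes
  sample_ids <- sprintf("S%04d", seq_len(n))
  gene_ids <- sprintf("G%05d", seq_len(g))

  n_ob <- round(config$frac_obese * n)
  n_ow <- round(config$frac_overweight * n)
  n_nw <- n - n_ob - n_ow
  if (n_nw < 0) {
    abort("configuration error: rounded group sizes exceed `n_samples`",
          class = "phosphosig_error_config")
  }
  group <- rep(c("obese", "overweight", "normal-weight"), c(n_ob, n_ow, n_nw))

  shift <- ifelse(group == "obese", config$delta_group * config$sigma_a, 0)
  latent <- rnorm(n, mean = shift, sd = config$sigma_a)

  bmi_lo <- c(`normal-weight` = 18.5, overweight = 25, obese = 30)[group]
  bmi_hi <- c(`normal-weight` = 25, overweight = 30, obese = 45)[group]
  bmi <- runif(n, bmi_lo, bmi_hi)

  pre <- runif(n) < config$frac_pre
  age <- integer(n)
  rp <- config$age_range_pre
  rq <- config$age_range_post
  age[pre] <- sample(seq(rp[1], rp[2]), sum(pre), replace = TRUE)
  age[!pre] <- sample(seq(rq[1], rq[2]), sum(!pre), replace = TRUE)

  membership <- sample(rep(c("up", "down", "null"),
                           c(config$n_up, config$n_down,
                             g - config$n_up - config$n_down)))
  sgn <- c(up = 1, down = -1, null = 0)[membership]

  # log-normal baselines (normal on the log2 scale)
  baseline <- rnorm(g, mean = 0, sd = 1.5)
  log2_mu <- baseline + outer(sgn * config$beta, latent)   # genes x samples
  mu <- 2^log2_mu
  mu <- sweep(mu, 2, colSums(mu), "/") * config$mean_library_size
  counts <- if (config$dispersion > 0) {
    rnbinom(g * n, mu = mu, size = 1 / config$dispersion)
  } else {
    rpois(g * n, lambda = mu)
  }
  counts <- matrix(as.double(counts), nrow = g, ncol = n,
                   dimnames = list(gene_ids, sample_ids))

  targets <- akt_pathway()$antibody_id
  rppa <- matrix(rep(latent, each = length(targets)) +
                   rnorm(length(targets) * n, 0, config$rppa_noise_sd),
                 nrow = length(targets), ncol = n,
                 dimnames = list(targets, sample_ids))
  if (config$n_decoys > 0) {
    decoys <- matrix(rnorm(config$n_decoys * n), nrow = config$n_decoys,
                     dimnames = list(sprintf("NOISE%d", seq_len(config$n_decoys)),
                                     sample_ids))
    rppa <- rbind(rppa, decoys)
  }

  expression <- set_expr_scale(matrix_to_tbl(counts, "gene_id"), "counts")
  structure(
    list(
      expression = expression,
      rppa = matrix_to_tbl(rppa, "antibody_id"),
      clinical = tibble(sample_id = sample_ids, age = age, bmi = bmi,
                        group = group),
      truth = list(
        samples = tibble(sample_id = sample_ids, latent_activity = latent,
                         group = group),
        genes = tibble(gene_id = gene_ids, membership = membership),
        config = config)),
    class = "phospho_cohort")
}

#' @export
print.phospho_cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("<phospho_cohort> %d samples, %d genes (%d up / %d down planted), %d antibodies\n",
              cfg$n_samples, cfg$n_genes, cfg$n_up, cfg$n_down,
              nrow(x$rppa)))
  cat(sprintf("  beta = %g, sigma_a = %g, delta_group = %g, seed = %d\n",
              cfg$beta, cfg$sigma_a, cfg$delta_group, cfg$seed))
  invisible(x)
}

#' Write a simulated cohort to a directory of TSV files
#'
#' Writes `expression.tsv`, `rppa.tsv`, `clinical.tsv`,
#' `truth_samples.tsv`, `truth_genes.tsv` and a `manifest.json` echoing
#' the configuration. Numeric values are formatted so the files
#' round-trip losslessly through [read_cohort()] and the matrix readers.
#'
#' @param cohort A `"phospho_cohort"` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a tibble manifest of the written files.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "phospho_cohort")) {
    abort("`cohort` must be a phospho_cohort", class = "phosphosig_error_input")
  }
  if (!is.character(dir) || length(dir) != 1L || !nzchar(dir)) {
    abort("`dir` must be a non-empty directory path",
          class = "phosphosig_error_io")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(expression = "expression.tsv", rppa = "rppa.tsv",
             clinical = "clinical.tsv", truth_samples = "truth_samples.tsv",
             truth_genes = "truth_genes.tsv")
  write_tsv_exact(cohort$expression, file.path(dir, files["expression"]))
  write_tsv_exact(cohort$rppa, file.path(dir, files["rppa"]))
  write_tsv_exact(cohort$clinical, file.path(dir, files["clinical"]))
  write_tsv_exact(cohort$truth$samples, file.path(dir, files["truth_samples"]))
  write_tsv_exact(cohort$truth$genes, file.path(dir, files["truth_genes"]))
  manifest <- list(files = as.list(files),
                   config = unclass(cohort$truth$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(tibble(component = names(files), file = unname(files)))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files and `manifest.json`.
#' @return A `"phospho_cohort"` equal to the one written.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) {
    abort(sprintf("no manifest.json under '%s'", dir),
          class = "phosphosig_error_io")
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  cfg <- do.call(cohort_config, manifest$config)
  tsv <- function(f) readr::read_tsv(file.path(dir, f), show_col_types = FALSE,
                                     progress = FALSE)
  structure(
    list(
      expression = set_expr_scale(
        read_matrix_tsv(file.path(dir, manifest$files$expression), "gene_id"),
        "counts"),
      rppa = read_matrix_tsv(file.path(dir, manifest$files$rppa),
                             "antibody_id"),
      clinical = tsv(manifest$files$clinical),
      truth = list(samples = tsv(manifest$files$truth_samples),
                   genes = tsv(manifest$files$truth_genes),
                   config = cfg)),
    class = "phospho_cohort")
}
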