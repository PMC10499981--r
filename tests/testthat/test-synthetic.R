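small_cfg <- function(seed = 7, ...) {
  cohort_config(n_per_class = 5, n_proteins = 60, n_phospho = 40,
                mutation_rate = 20, seed = seed, ...)
}

test_that("identical configs generate bit-identical bundles", {
  b1 <- generate_cohort(small_cfg())
  b2 <- generate_cohort(small_cfg())
  expect_identical(b1, b2)
  b3 <- generate_cohort(small_cfg(seed = 8))
  expect_false(identical(b1$proteome$values, b3$proteome$values))
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_per_class = 1), "n_per_class >= 2")
  expect_error(cohort_config(effect_log2 = -1), "effect_log2")
  expect_error(cohort_config(hras_papilloma_prob = 1.2), "hras")
  expect_error(cohort_config(exposure_profiles = list(
    Normal = c(SBS1 = 0.5, SBS5 = 0.4)), classes = "Normal",
    n_per_class = 5), "sum to 1")
  cc <- small_cfg()
  cc$exposure_profiles$Normal <- c(BOGUS = 1)
  b <- generate_cohort(small_cfg())
  expect_error(generate_mutation_table(b$cohort, b$signatures, cc),
               "unknown signature")
})

test_that("a zero branch effect leaves panel proteins at the null", {
  cc <- cohort_config(n_per_class = c(LGPC = 40, CIS = 40),
                      classes = c("LGPC", "CIS"), n_proteins = 50,
                      n_phospho = 10, mutation_rate = 2,
                      effect_log2 = 0, seed = 5)
  b <- generate_cohort(cc)
  pap <- b$cohort$sample_id[b$cohort$latent_branch == "papillary"]
  cis <- b$cohort$sample_id[b$cohort$latent_branch == "cis"]
  obs <- log2(b$proteome$values)  # observed entries only (dropout is NA)
  diffs <- rowMeans(obs[b$truth$panel$protein, pap], na.rm = TRUE) -
    rowMeans(obs[b$truth$panel$protein, cis], na.rm = TRUE)
  expect_lt(max(abs(diffs)), 1)  # within noise at n = 40/40
  expect_lt(abs(mean(diffs)), 0.3)
})

test_that("the injected branch effect has the configured standardized size", {
  cc <- cohort_config(n_per_class = c(HGPC = 60, CIS = 60),
                      classes = c("HGPC", "CIS"), n_proteins = 60,
                      n_phospho = 10, mutation_rate = 2, seed = 9)
  b <- generate_cohort(cc)
  truth <- b$truth$panel
  pap <- b$cohort$latent_branch == "papillary"
  raw <- b$proteome$values
  smd <- vapply(seq_len(nrow(truth)), function(i) {
    x <- log2(raw[truth$protein[i], pap])
    y <- log2(raw[truth$protein[i], !pap])
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    (mean(x) - mean(y)) / sp
  }, 0)
  signed <- smd * ifelse(truth$direction == "up_puc", 1, -1)
  expect_gt(mean(signed), 1.3)
  expect_lt(mean(signed), 1.7)
})

test_that("dropout probability decreases with abundance", {
  b <- generate_cohort(cohort_config(n_per_class = 20, classes = c("Normal"),
                                     n_proteins = 200, n_phospho = 10,
                                     mutation_rate = 2, seed = 3))
  v <- b$proteome$values
  obs_log2 <- log2(v)
  miss_rate <- rowMeans(b$proteome$missing)
  mean_ab <- rowMeans(obs_log2, na.rm = TRUE)
  # deciles of abundance: dropout rate falls monotonically overall
  dec <- cut(mean_ab, quantile(mean_ab, seq(0, 1, 0.2)), include.lowest = TRUE)
  rates <- tapply(miss_rate, dec, mean)
  expect_lt(spearman(as.numeric(rates), seq_along(rates))$rho, 0)
  expect_lt(rates[length(rates)], rates[1])
})

test_that("papilloma HRAS hotspot frequency matches the configured 83%", {
  cc <- cohort_config(n_per_class = c(Papilloma = 1000),
                      classes = "Papilloma", n_proteins = 8, n_phospho = 8, panel_size = 2,
                      mutation_rate = 3, seed = 21)
  b <- generate_cohort(cc)
  hs <- b$mutations[b$mutations$hotspot %in% TRUE, ]
  frac <- nrow(hs) / 1000
  ci <- 0.83 + c(-1, 1) * qnorm(0.995) * sqrt(0.83 * 0.17 / 1000)
  expect_gte(frac, ci[1]); expect_lte(frac, ci[2])
  # Q61R share of hotspots near 0.8
  q61r <- mean(hs$protein_change == "Q61R")
  ciq <- 0.8 + c(-1, 1) * qnorm(0.995) * sqrt(0.8 * 0.2 / nrow(hs))
  expect_gte(q61r, ciq[1]); expect_lte(q61r, ciq[2])
})

test_that("mutation sampling follows the exposure-weighted mixture", {
  cc <- cohort_config(n_per_class = c(Papilloma = 3), classes = "Papilloma",
                      n_proteins = 8, n_phospho = 8, panel_size = 2, mutation_rate = 2000,
                      hras_papilloma_prob = 0, seed = 31)
  b <- generate_cohort(cc)
  mix <- drop(b$signatures[, c("SBS1", "SBS5")] %*% c(0.6, 0.4))
  catalog <- build_catalog(b$mutations, samples = b$cohort$sample_id)
  for (s in rownames(catalog)) {
    emp <- catalog[s, ] / sum(catalog[s, ])
    expect_lt(max(abs(emp - mix)), 0.03)
  }

  # zero rate gives an empty table and a zero catalog
  cc0 <- cohort_config(n_per_class = c(CIS = 3), classes = "CIS",
                       n_proteins = 8, n_phospho = 8, panel_size = 2, mutation_rate = 0,
                       seed = 1)
  b0 <- generate_cohort(cc0)
  expect_equal(nrow(b0$mutations), 0L)
  expect_true(all(build_catalog(b0$mutations,
                                samples = b0$cohort$sample_id) == 0))
})

test_that("survival generation recovers the configured hazard ratio", {
  cc <- cohort_config(n_per_class = c(Invasive = 4000), classes = "Invasive",
                      n_proteins = 5, n_phospho = 5, panel_size = 2, mutation_rate = 0,
                      invasive_cis_frac = 0.5, seed = 13)
  b <- generate_cohort(cc)
  x <- as.numeric(b$cohort$latent_branch == "cis")
  fit <- cox_univariate(b$cohort$survival_time, b$cohort$event, x)
  expect_gte(fit$hr, 0.85 * 2)
  expect_lte(fit$hr, 1.18 * 2)
})

test_that("bundle cross-references resolve and files round-trip", {
  b <- generate_cohort(small_cfg())
  expect_true(all(b$truth$panel$protein %in% rownames(b$proteome$values)))
  expect_true(all(b$truth$ddr_marker_ids %in% rownames(b$phospho$values)))
  expect_true(all(b$mutations$sample %in% b$cohort$sample_id))
  expect_true(all(b$segments$sample %in% b$cohort$sample_id))
  expect_true(all(b$cohort$survival_time > 0))
  inv <- b$cohort$histology_class == "Invasive"
  expect_true(all(!is.na(b$cohort$derived_label[inv])))
  expect_true(all(is.na(b$cohort$derived_label[!inv])))

  dir <- withr::local_tempdir()
  write_cohort_bundle(b, dir)
  rb <- read_cohort_bundle(dir)
  expect_equal(rb$proteome$values, b$proteome$values, tolerance = 1e-10)
  expect_equal(rb$cohort$histology_class, b$cohort$histology_class)
  expect_equal(rb$segments$start, b$segments$start)
  expect_equal(rb$signatures, b$signatures, tolerance = 1e-12)
  expect_equal(rb$gene_sets, b$gene_sets)
  expect_equal(unname(rb$truth$del8p12), unname(b$truth$del8p12))
})
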