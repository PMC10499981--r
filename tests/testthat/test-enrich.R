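make_profile <- function(n, seed = 1) {
  set.seed(seed)
  setNames(sort(rnorm(n), decreasing = TRUE) + 0, paste0("g", 1:n))
}

test_that("ES is positive for top-ranked sets and negative for bottom-ranked", {
  p <- setNames(10:1, paste0("g", 1:10))
  pa <- enrichment_params(min_overlap = 2)
  expect_gt(ssgsea_es(p, c("g1", "g2"), pa), 0)
  expect_lt(ssgsea_es(p, c("g9", "g10"), pa), 0)
})

test_that("ES equals the brute-force running-sum oracle", {
  set.seed(17)
  pa <- enrichment_params(min_overlap = 2)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    profile <- setNames(rnorm(n), paste0("g", sample.int(10 * n, n)))
    gs <- sample(names(profile), sample(2:min(8, n - 1), 1))
    expect_equal(ssgsea_es(profile, gs, pa),
                 oracle_ssgsea_es(profile, gs, weight = pa$weight),
                 tolerance = 1e-12)
  }
})

test_that("sets below the minimum overlap are skipped", {
  p <- make_profile(20)
  es <- ssgsea_es(p, names(p)[1:4], enrichment_params())  # overlap 4 < 5
  expect_true(is.na(es))
  expect_equal(attr(es, "skipped"), "min.overlap")
  expect_false(is.na(ssgsea_es(p, names(p)[1:5], enrichment_params())))
})

test_that("complement symmetry holds at weight zero", {
  p <- make_profile(25, seed = 2)
  pa <- enrichment_params(weight = 0, min_overlap = 2)
  s <- names(p)[c(3, 8, 15, 20)]
  expect_equal(ssgsea_es(p, s, pa), -ssgsea_es(p, setdiff(names(p), s), pa),
               tolerance = 1e-12)
})

test_that("rank normalization makes scores invariant to monotone transforms", {
  p <- make_profile(40, seed = 3)
  gs <- names(p)[c(1, 5, 9, 22, 31, 40)]
  pa <- enrichment_params()
  base <- ssgsea_es(p, gs, pa)
  expect_equal(ssgsea_es(p + 100, gs, pa), base, tolerance = 1e-12)
  expect_equal(ssgsea_es(exp(p), gs, pa), base, tolerance = 1e-12)
  expect_equal(ssgsea_es(p^3 + 2 * p, gs, pa), base, tolerance = 1e-12)
  # permuting the feature order changes nothing
  perm <- sample(length(p))
  expect_equal(ssgsea_es(p[perm], gs, pa), base, tolerance = 1e-12)
})

test_that("NES is deterministic, null-calibrated, and separates signal", {
  p <- make_profile(50, seed = 4)
  gs <- sample(names(p), 8)
  pa <- enrichment_params(n_permutations = 500, seed = 99)
  expect_equal(ssgsea_nes(p, gs, pa), ssgsea_nes(p, gs, pa))

  # null calibration: a random set is exchangeable with the size-matched
  # permutation sets, so the permutation rank of its ES is uniform
  set.seed(31)
  pa_small <- enrichment_params(n_permutations = 200, seed = 31,
                                min_overlap = 5)
  pvals <- vapply(1:100, function(i) {
    prof <- setNames(rnorm(40), paste0("g", 1:40))
    es <- ssgsea_es(prof, sample(names(prof), 6), pa_small)
    perm <- vapply(1:200, function(j)
      ssgsea_es(prof, sample(names(prof), 6), pa_small), 0)
    (1 + sum(perm >= es)) / 201
  }, 0)
  expect_gt(mean(pvals), 0.4)
  expect_lt(mean(pvals), 0.6)

  # exact top-k of a strictly decreasing profile scores above the null scale
  top <- setNames(40:1, paste0("g", 1:40))
  expect_gt(ssgsea_nes(top, paste0("g", 1:6),
                       enrichment_params(n_permutations = 500, seed = 7)), 1)
})

test_that("score_matrix detects an injected pathway effect", {
  set.seed(55)
  n <- 30
  v <- matrix(rnorm(100 * n, 5, 1), 100, n,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:n)))
  grp <- rep(c("a", "b"), each = n / 2)
  hit_set <- paste0("g", 1:10)
  v[hit_set, grp == "b"] <- v[hit_set, grp == "b"] + 2
  am <- abundance_matrix(v, "log2FOT", matrix(FALSE, 100, n,
                                              dimnames = dimnames(v)))
  sc <- score_matrix(am, list(HIT = hit_set, NULLSET = paste0("g", 50:60)),
                     enrichment_params(output = "ES"))
  w <- wilcoxon_rank_sum(sc["HIT", grp == "a"], sc["HIT", grp == "b"])
  expect_lt(w$p_value, 0.01)
  expect_gt(mean(sc["HIT", grp == "b"]), mean(sc["HIT", grp == "a"]))
})

test_that("DDR score is the mean of per-marker standardized values", {
  v <- rbind(m1 = c(1, 2, 3), m2 = c(10, 20, 30))
  colnames(v) <- paste0("s", 1:3)
  am <- abundance_matrix(v, "FOT", matrix(FALSE, 2, 3, dimnames = dimnames(v)))
  d <- ddr_score(am, c("m1", "m2"))
  expect_equal(unname(d$scores), c(-1, 0, 1))

  v2 <- rbind(m1 = c(1, 2, 3), m2 = c(3, 2, 1))
  colnames(v2) <- paste0("s", 1:3)
  am2 <- abundance_matrix(v2, "FOT", matrix(FALSE, 2, 3, dimnames = dimnames(v2)))
  expect_equal(unname(ddr_score(am2, c("m1", "m2"))$scores), c(0, 0, 0))

  # rescaling one marker does not move the score
  v3 <- v; v3["m2", ] <- v3["m2", ] * 100
  am3 <- abundance_matrix(v3, "FOT", matrix(FALSE, 2, 3, dimnames = dimnames(v)))
  expect_equal(ddr_score(am3, c("m1", "m2"))$scores, d$scores)

  # standardization invariants hold exactly
  set.seed(6)
  v4 <- matrix(rnorm(50), 5, 10,
               dimnames = list(paste0("m", 1:5), paste0("s", 1:10)))
  am4 <- abundance_matrix(v4, "FOT", matrix(FALSE, 5, 10, dimnames = dimnames(v4)))
  z <- t(scale(t(v4)))
  expect_equal(unname(rowMeans(z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(ddr_score(am4, paste0("m", 1:5))$scores),
               unname(colMeans(z)), tolerance = 1e-12)

  expect_error(ddr_score(am4, "absent"), "no DDR marker")
})

test_that("regulon activity enforces the minimum set size and tracks repression", {
  set.seed(77)
  n <- 60
  repressor <- rnorm(n)
  targets <- paste0("t", 1:10)
  v <- matrix(rnorm(80 * n, 5, 0.5), 80, n,
              dimnames = list(c(targets, paste0("g", 1:70)), paste0("s", 1:n)))
  v[targets, ] <- v[targets, ] - 1.2 * rep(repressor, each = 10)
  am <- abundance_matrix(v, "log2FOT", matrix(FALSE, 80, n,
                                              dimnames = dimnames(v)))
  act <- regulon_activity(am, list(AP1 = targets, SMALL = paste0("g", 1:9)),
                          params = enrichment_params(output = "ES"))
  expect_false("SMALL" %in% rownames(act))  # 9 targets -> skipped
  expect_true("AP1" %in% rownames(act))
  sp <- spearman(repressor, act["AP1", ])
  expect_lt(sp$rho, 0)
  expect_lt(sp$p_value, 0.05)
})
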