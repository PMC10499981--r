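test_that("catalog binning follows the pyrimidine-strand convention", {
  expect_equal(sbs_contexts()[1], "A[C>A]A")
  expect_equal(length(sbs_contexts()), 96L)

  m <- data.frame(sample = "s1", ref = "C", alt = "T",
                  flank5 = "A", flank3 = "A")
  cat1 <- build_catalog(m)
  expect_equal(unname(cat1["s1", "A[C>T]A"]), 1L)
  expect_equal(sum(cat1), 1L)

  # purine-strand record reverse-complements: T-G-C with G>A -> G[C>T]A
  m2 <- data.frame(sample = "s1", ref = "G", alt = "A",
                   flank5 = "T", flank3 = "C")
  cat2 <- build_catalog(m2)
  expect_equal(unname(cat2["s1", "G[C>T]A"]), 1L)

  empty <- build_catalog(data.frame(sample = character(0), ref = character(0),
                                    alt = character(0), flank5 = character(0),
                                    flank3 = character(0)),
                         samples = c("s1", "s2"))
  expect_true(all(empty == 0))
})

test_that("catalog counts accepted records and reports skips", {
  set.seed(8)
  n <- 200
  ctx <- sbs_contexts()
  cx <- sample(ctx, n, replace = TRUE)
  m <- data.frame(sample = sample(c("a", "b"), n, TRUE),
                  ref = substr(cx, 3, 3), alt = substr(cx, 5, 5),
                  flank5 = substr(cx, 1, 1), flank3 = substr(cx, 7, 7))
  bad <- data.frame(sample = "a", ref = c("AT", "N"), alt = c("A", "C"),
                    flank5 = "A", flank3 = "A")
  cat_all <- build_catalog(rbind(m, bad))
  expect_equal(sum(cat_all), n)
  expect_equal(attr(cat_all, "n_skipped"), 2L)

  # strand invariance: reverse-complementing every record changes nothing
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m_rc <- data.frame(sample = m$sample, ref = comp[m$ref], alt = comp[m$alt],
                     flank5 = comp[m$flank3], flank3 = comp[m$flank5])
  expect_equal(build_catalog(m_rc, samples = c("a", "b"))[, ],
               build_catalog(m, samples = c("a", "b"))[, ])
})

test_that("NMF recovers exact rank-1 structure and separated signatures", {
  sigs <- synthetic_signature_set()
  # rank-1: catalog proportional to one signature
  expos <- c(200, 500, 300, 800)
  V <- outer(expos, sigs[, "SBS13"])
  colnames(V) <- sbs_contexts(); rownames(V) <- paste0("s", 1:4)
  fit <- nmf_extract(V, k = 1, n_restarts = 3, seed = 5)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_gt(cosine(fit$signatures[, 1], sigs[, "SBS13"]), 1 - 1e-6)

  # determinism
  fit2 <- nmf_extract(V, k = 1, n_restarts = 3, seed = 5)
  expect_identical(fit, fit2)

  # objective is non-increasing across iterations
  expect_true(all(diff(fit$objective_trace) <=
                    1e-8 * pmax(1, abs(fit$objective_trace[-1]))))

  # two separated signatures from noisy counts
  set.seed(12)
  mix <- cbind(runif(100, 0, 1))
  W_true <- sigs[, c("SBS1", "SBS13")]
  lam <- t(W_true %*% rbind(c(mix), c(1 - mix))) * 2000
  catalog <- matrix(rpois(length(lam), lam), nrow = 100,
                    dimnames = list(paste0("s", 1:100), sbs_contexts()))
  fit3 <- nmf_extract(catalog, k = 2, n_restarts = 5, seed = 3)
  cs <- outer(1:2, 1:2, Vectorize(function(i, j)
    cosine(fit3$signatures[, i], W_true[, j])))
  best <- pmax(cs[1, ], cs[2, ])
  expect_true(all(best >= 0.95))

  expect_error(nmf_extract(catalog, k = 0), "out of bounds")
})

test_that("refitting recovers mixtures and applies the 0.08 weight filter", {
  sigs <- synthetic_signature_set()
  # exact single-signature catalog
  counts <- round(sigs[, "SBS30"] * 5000)
  r <- refit_signatures(counts, sigs)
  expect_equal(unname(r$weights["SBS30"]), 1, tolerance = 1e-6)
  expect_equal(r$dominant, "SBS30")

  # 0.6 / 0.4 mixture at 2000 mutations
  set.seed(14)
  mix <- 0.6 * sigs[, "SBS1"] + 0.4 * sigs[, "SBS13"]
  counts2 <- rmultinom(1, 2000, mix)[, 1]
  r2 <- refit_signatures(counts2, sigs)
  expect_equal(unname(r2$weights["SBS1"]), 0.6, tolerance = 0.05)
  expect_equal(unname(r2$weights["SBS13"]), 0.4, tolerance = 0.05)

  # a 0.05 true contribution is filtered out by the 0.08 threshold
  mix3 <- 0.55 * sigs[, "SBS1"] + 0.40 * sigs[, "SBS13"] +
    0.05 * sigs[, "SBS30"]
  counts3 <- round(mix3 * 1e5)
  r3 <- refit_signatures(counts3, sigs)
  expect_false("SBS30" %in% names(r3$weights))
  expect_equal(sum(r3$weights), 1, tolerance = 1e-9)

  # convex-hull catalog refits with ~zero residual
  hull <- 0.5 * sigs[, "SBS1"] + 0.5 * sigs[, "SBS5"]
  r4 <- refit_signatures(hull * 1e6, sigs)
  expect_lt(r4$residual, 1e-9)

  # raising the threshold never increases the retained count
  thr <- c(0.01, 0.05, 0.08, 0.2, 0.4)
  kept <- vapply(thr, function(t_)
    length(refit_signatures(counts2, sigs, threshold = t_)$weights), 0L)
  expect_true(all(diff(kept) <= 0))
})

test_that("dominant-signature assignment uses argmax with documented ties", {
  sigs <- synthetic_signature_set()
  r1 <- refit_signatures(round(sigs[, "SBS1"] * 0.7e4 + sigs[, "SBS5"] * 0.3e4),
                         sigs)
  expect_equal(r1$dominant, "SBS1")

  # exact tie between two separated signatures
  tie_counts <- round((0.5 * sigs[, "SBS1"] + 0.5 * sigs[, "SBS13"]) * 1e6)
  rt <- refit_signatures(tie_counts, sigs)
  expect_equal(rt$dominant, sort(names(rt$weights))[1])

  groups <- assign_signature_groups(
    list(s1 = r1, s2 = structure(list(weights = numeric(0), dominant = "none",
                                      unassigned = TRUE, tie = FALSE),
                                 class = "exposure_result")),
    classes = c(s1 = "CIS", s2 = "Normal"))
  expect_equal(groups$label, c("SBS1", "none"))
  expect_s3_class(attr(groups, "crosstab"), "table")
})

test_that("class-dependent exposure truth is recovered at the cohort level", {
  cc <- cohort_config(n_per_class = c(Papilloma = 30, CIS = 30),
                      classes = c("Papilloma", "CIS"),
                      n_proteins = 10, n_phospho = 10, panel_size = 2,
                      mutation_rate = 300, seed = 42)
  b <- generate_cohort(cc)
  catalog <- build_catalog(b$mutations, samples = b$cohort$sample_id)
  refits <- lapply(rownames(catalog), function(s)
    refit_signatures(catalog[s, ], b$signatures))
  names(refits) <- rownames(catalog)
  groups <- assign_signature_groups(
    refits, classes = setNames(b$cohort$histology_class, b$cohort$sample_id))
  ct <- attr(groups, "crosstab")
  # papilloma is SBS1-dominant (0.6 mixture), CIS SBS30-dominant (0.5)
  expect_gt(ct["Papilloma", "SBS1"] / 30, 0.8)
  expect_gt(ct["CIS", "SBS30"] / 30, 0.8)
})
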