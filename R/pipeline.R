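# End-to-end orchestration: generate or read a cohort, quantify, score,
# extract signatures and copy-number burden, build the differential panel,
# train the origin classifier, assign invasive samples, and compare the
# derived groups (pathways, metastasis, survival). One top-level seed
# deterministically derives the per-stage RNG streams.

#' Pipeline configuration
#'
#' @param mode "synthetic" (generate a cohort from `cohort`) or "files"
#'   (read a bundle directory written by [write_cohort_bundle()]).
#' @param cohort a [cohort_config()] (synthetic mode); its seed is overridden
#'   by a stream derived from `seed`.
#' @param path bundle directory (files mode).
#' @param enrichment an [enrichment_params()] block for pathway scoring.
#' @param panel_alpha,fold_bounds differential-panel thresholds.
#' @param panel_size maximal classifier panel size (default 18).
#' @param lambda ridge strength of the origin classifier (NULL: 1/n of the
#'   training set).
#' @param k_folds cross-validation folds.
#' @param train_fraction train share of the PUC/CIS samples.
#' @param signature_threshold refit weight filter (default 0.08).
#' @param cna_cutoff amplification/deletion call threshold (default 1).
#' @param band_genes named list mapping a CNA band to the gene ids whose
#'   proteins are screened for cis effects (synthetic mode fills this from
#'   the generator truth when NULL).
#' @param seed top-level integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            cohort = cohort_config(),
                            path = NULL,
                            enrichment = enrichment_params(n_permutations = 200L),
                            panel_alpha = 0.05,
                            fold_bounds = c(2, 0.5),
                            panel_size = 18L,
                            lambda = NULL,
                            k_folds = 10L,
                            train_fraction = 0.8,
                            signature_threshold = 0.08,
                            cna_cutoff = 1,
                            band_genes = NULL,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "files") {
    if (is.null(path)) stop("files mode needs a bundle path")
    if (!dir.exists(path)) stop("bundle directory does not exist: ", path)
    for (f in c("clinical.tsv", "proteome.tsv", "phospho.tsv",
                "mutations.maf.tsv", "segments.seg.tsv", "arms.tsv",
                "signatures.tsv", "gene_sets.gmt")) {
      fp <- file.path(path, f)
      if (!file.exists(fp)) stop("missing input file: ", fp)
    }
  }
  stopifnot(panel_alpha > 0, panel_alpha < 1, signature_threshold >= 0,
            signature_threshold < 1, train_fraction > 0, train_fraction < 1,
            k_folds >= 2)
  structure(list(mode = mode, cohort = cohort, path = path,
                 enrichment = enrichment, panel_alpha = panel_alpha,
                 fold_bounds = fold_bounds,
                 panel_size = as.integer(panel_size), lambda = lambda,
                 k_folds = as.integer(k_folds),
                 train_fraction = train_fraction,
                 signature_threshold = signature_threshold,
                 cna_cutoff = cna_cutoff, band_genes = band_genes,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Quantify peptide evidence into a FOT protein matrix
#'
#' Per run: peptide intensities are summed per protein, divided by the
#' theoretically observable peptide count (iBAQ), and FOT-normalized with the
#' 1e-5 floor. Proteins without evidence in a run are missing.
#'
#' @param peptides evidence data.frame (`run_id, peptide, protein,
#'   intensity`).
#' @param sequences named character vector of protein sequences (for the
#'   observable-peptide counts).
#' @return `abundance_matrix` on the FOT scale.
#' @export
quantify_evidence <- function(peptides, sequences) {
  n_obs <- vapply(sequences, count_observable_peptides, 0L)
  usable <- names(n_obs)[n_obs >= 1L]
  dropped <- setdiff(unique(peptides$protein), usable)
  if (length(dropped))
    warning(length(dropped),
            " protein(s) without observable peptides excluded")
  ev <- as.data.table(peptides)[protein %in% usable]
  sums <- ev[, list(total = sum(intensity)), by = c("run_id", "protein")]
  runs <- sort(unique(peptides$run_id))
  prot <- sort(usable)
  ib <- matrix(NA_real_, length(prot), length(runs),
               dimnames = list(prot, runs))
  ib[cbind(match(sums$protein, prot), match(sums$run_id, runs))] <-
    sums$total / n_obs[sums$protein]
  fot <- ib
  for (j in seq_len(ncol(fot))) {
    obs <- !is.na(ib[, j])
    fot[obs, j] <- normalize_fot(ib[obs, j])
  }
  abundance_matrix(fot, scale = "FOT", missing = is.na(ib))
}

#' Read a cohort bundle directory
#' @param dir directory written by [write_cohort_bundle()].
#' @return list with the same tabular elements as a generated bundle (no
#'   truth unless truth.json is present).
#' @export
read_cohort_bundle <- function(dir) {
  rd <- function(f, ...) read.table(file.path(dir, f), sep = "\t",
                                    header = TRUE, stringsAsFactors = FALSE,
                                    ...)
  out <- list(
    cohort = rd("clinical.tsv"),
    proteome = read_abundance_tsv(file.path(dir, "proteome.tsv")),
    phospho = read_abundance_tsv(file.path(dir, "phospho.tsv")),
    mutations = rd("mutations.maf.tsv"),
    segments = read_segments(file.path(dir, "segments.seg.tsv")),
    arms = rd("arms.tsv"),
    signatures = read_signatures_tsv(file.path(dir, "signatures.tsv")),
    gene_sets = read_gmt(file.path(dir, "gene_sets.gmt")))
  pep <- file.path(dir, "peptides.tsv")
  if (file.exists(pep)) out$peptides <- rd("peptides.tsv")
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    tr <- jsonlite::read_json(tj, simplifyVector = TRUE)
    tr$del8p12 <- unlist(tr$del8p12)
    tr$exposures <- as.matrix(tr$exposures)
    rownames(tr$exposures) <- names(tr$del8p12)
    out$truth <- tr
  }
  class(out) <- "cohort_bundle"
  out
}

#' Compare classifier-derived origin groups
#'
#' Fisher's exact test of metastasis against the derived label, Wilcoxon
#' tests of each pathway score between derived groups with BH adjustment, and
#' Kaplan-Meier / log-rank / univariate Cox on the derived label.
#'
#' @param origin_calls data.frame from [assign_origin()].
#' @param clinical cohort table with `sample_id`, `metastasis`,
#'   `survival_time`, `event`.
#' @param pathway_scores optional matrix sets x samples.
#' @return list with `fisher_metastasis`, `pathway_tests`, `km`, `logrank`,
#'   `cox`, or NULL (with a warning) when only one derived group is present.
#' @export
compare_derived_groups <- function(origin_calls, clinical,
                                   pathway_scores = NULL) {
  lbl <- origin_calls$label
  if (length(unique(lbl)) < 2L || min(table(lbl)) < 2L) {
    warning("single derived group; comparison skipped")
    return(NULL)
  }
  cl <- clinical[match(origin_calls$sample, clinical$sample_id), ]
  is_cis <- lbl == "CIS-derived"
  tb <- matrix(c(sum(cl$metastasis & is_cis), sum(!cl$metastasis & is_cis),
                 sum(cl$metastasis & !is_cis), sum(!cl$metastasis & !is_cis)),
               2, 2, byrow = TRUE)
  fish <- fisher_exact_2x2(tb)
  pw <- NULL
  if (!is.null(pathway_scores) && nrow(pathway_scores) > 0) {
    common <- intersect(colnames(pathway_scores), origin_calls$sample)
    isc <- is_cis[match(common, origin_calls$sample)]
    pvals <- apply(pathway_scores[, common, drop = FALSE], 1L, function(s)
      wilcoxon_rank_sum(s[isc], s[!isc])$p_value)
    pw <- data.frame(set = rownames(pathway_scores), p = pvals,
                     q = bh_adjust(pvals), row.names = NULL,
                     stringsAsFactors = FALSE)
  }
  km <- lapply(split(seq_along(lbl), lbl), function(i)
    km_estimate(cl$survival_time[i], cl$event[i]))
  lr <- logrank_test(cl$survival_time, cl$event, lbl)
  cox <- cox_univariate(cl$survival_time, cl$event, as.numeric(is_cis))
  list(fisher_metastasis = list(table = tb, p_value = fish$p_value,
                                odds_ratio = fish$odds_ratio),
       pathway_tests = pw, km = km, logrank = lr, cox = cox)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: cohort acquisition, label-free
#' quantification, differential panel, origin classifier (split / CV / test
#' evaluation / invasive assignment), pathway and DDR scoring, mutational
#' signatures, copy-number burden, and derived-group comparison. In synthetic
#' mode a truth-vs-estimate recovery table is added. Deterministic given
#' `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory: when given, [write_report()] is called.
#' @param stages subset of `c("quant", "panel", "classify", "enrich",
#'   "mutsig", "cna", "survival")`; the cohort stage always runs, and later
#'   stages silently skip when their dependencies were not run.
#' @return list of class `report_bundle`.
#' @export
run_pipeline <- function(config, outdir = NULL,
                         stages = c("quant", "panel", "classify", "enrich",
                                    "mutsig", "cna", "survival")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  report <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- cohort ---------------------------------------------------------
  bundle <- run_stage("cohort", {
    if (config$mode == "synthetic") {
      cc <- config$cohort
      cc$seed <- derive_seed(config$seed, "cohort")
      generate_cohort(cc)
    } else {
      read_cohort_bundle(config$path)
    }
  })
  report$cohort <- bundle$cohort
  band_genes <- config$band_genes
  if (is.null(band_genes) && !is.null(bundle$truth))
    band_genes <- list("8p12" = bundle$truth$cis_gene)

  # ---- quantification -------------------------------------------------
  prot_fot <- run_stage("quant", {
    if ("quant" %in% stages && !is.null(bundle$peptides) &&
        !is.null(bundle$protein_sequences)) {
      quantify_evidence(bundle$peptides, bundle$protein_sequences)
    } else {
      bundle$proteome
    }
  })
  prot_log2 <- run_stage("quant", filter_and_impute(prot_fot))
  ph_log2 <- run_stage("quant", filter_and_impute(bundle$phospho))
  report$proteome_log2 <- prot_log2

  cohort <- bundle$cohort
  is_puc <- cohort$histology_class %in% c("LGPC", "HGPC")
  is_cis <- cohort$histology_class == "CIS"
  is_inv <- cohort$histology_class == "Invasive"

  # ---- differential panel --------------------------------------------
  if ("panel" %in% stages) {
    report$panel <- run_stage("panel", {
      sel <- is_puc | is_cis
      labels <- factor(ifelse(is_puc[sel], "PUC", "CIS"),
                       levels = c("PUC", "CIS"))
      sub <- abundance_matrix(prot_log2$values[, cohort$sample_id[sel],
                                               drop = FALSE],
                              scale = "log2FOT",
                              missing = prot_log2$missing[, cohort$sample_id[sel],
                                                          drop = FALSE])
      differential_panel(sub, labels, alpha = config$panel_alpha,
                         fold_bounds = config$fold_bounds)
    })
    qual <- report$panel$table[report$panel$table$direction != "ns", ]
    qual <- qual[order(qual$q, qual$p, qual$feature), ]
    report$panel_features <- head(qual$feature, config$panel_size)
  }

  # ---- origin classifier ---------------------------------------------
  if ("classify" %in% stages && length(report$panel_features) >= 2L) {
    run_stage("classify", {
      sel <- which(is_puc | is_cis)
      X <- t(prot_log2$values[report$panel_features,
                              cohort$sample_id[sel], drop = FALSE])
      y <- factor(ifelse(is_puc[sel], "PUC", "CIS"),
                  levels = c("PUC", "CIS"))
      sp <- split_train_test(y, config$train_fraction,
                             seed = derive_seed(config$seed, "split"))
      report$split <- sp
      report$cv <- cross_validate(X[sp$train, , drop = FALSE], y[sp$train],
                                   k = config$k_folds,
                                   lambda = config$lambda,
                                   seed = derive_seed(config$seed, "cv"))
      model <- fit_margin_logistic(X[sp$train, , drop = FALSE], y[sp$train],
                                   lambda = config$lambda)
      report$model <- model
      report$test_eval <- evaluate_classifier(model,
                                               X[sp$test, , drop = FALSE],
                                               y[sp$test])
      Xi <- t(prot_log2$values[report$panel_features,
                               cohort$sample_id[is_inv], drop = FALSE])
      report$origin_calls <- assign_origin(model, Xi)
      invisible(NULL)
    })
  }

  # ---- pathway / DDR scoring -----------------------------------------
  if ("enrich" %in% stages) {
    run_stage("enrich", {
      params <- config$enrichment
      params$seed <- derive_seed(config$seed, "nes")
      report$pathway_scores <- score_matrix(prot_log2, bundle$gene_sets,
                                             params)
      ddr_markers <- bundle$gene_sets[["DDR_PHOSPHO"]]
      if (!is.null(ddr_markers) &&
          length(intersect(ddr_markers, rownames(ph_log2$values))) > 0)
        report$ddr <- ddr_score(ph_log2, ddr_markers)
      invisible(NULL)
    })
  }

  # ---- mutational signatures -----------------------------------------
  if ("mutsig" %in% stages) {
    run_stage("mutsig", {
      catalog <- build_catalog(bundle$mutations,
                               samples = cohort$sample_id)
      report$catalog <- catalog
      with_mut <- rownames(catalog)[rowSums(catalog) > 0]
      refits <- lapply(with_mut, function(s)
        refit_signatures(catalog[s, ], bundle$signatures,
                         threshold = config$signature_threshold))
      names(refits) <- with_mut
      report$exposures <- refits
      report$signature_groups <-
        assign_signature_groups(refits,
                                classes = setNames(cohort$histology_class,
                                                   cohort$sample_id))
      invisible(NULL)
    })
  }

  # ---- copy number ----------------------------------------------------
  if ("cna" %in% stages) {
    run_stage("cna", {
      burden <- arm_burden(bundle$segments, bundle$arms)
      report$arm_burden <- burden
      calls <- matrix(call_amp_del(burden, config$cna_cutoff),
                      nrow(burden), dimnames = dimnames(burden))
      report$cna_calls <- calls
      inv_s <- cohort$sample_id[is_inv]
      inv_s <- intersect(inv_s, rownames(calls))
      if (length(inv_s) >= 4L &&
          length(unique(cohort$metastasis[match(inv_s, cohort$sample_id)])) == 2L) {
        report$cna_group_test <- group_freq_test(
          calls[inv_s, , drop = FALSE],
          ifelse(cohort$metastasis[match(inv_s, cohort$sample_id)],
                 "metastatic", "non-metastatic"))
      }
      if (!is.null(band_genes)) {
        for (band in names(band_genes)) {
          genes <- intersect(band_genes[[band]], rownames(prot_log2$values))
          smp <- intersect(inv_s, colnames(prot_log2$values))
          if (length(genes) && band %in% colnames(burden) &&
              length(smp) >= 5L) {
            cna_m <- matrix(burden[smp, band], length(smp), length(genes),
                            dimnames = list(smp, genes))
            prot_m <- t(prot_log2$values[genes, smp, drop = FALSE])
            report$cis_effects <- cis_effect(cna_m, prot_m)
          }
        }
      }
      invisible(NULL)
    })
  }

  # ---- derived-group comparison --------------------------------------
  if ("survival" %in% stages && !is.null(report$origin_calls)) {
    report$derived_comparison <- run_stage("survival",
      compare_derived_groups(report$origin_calls, cohort,
                             report$pathway_scores))
  }

  # ---- recovery vs truth ---------------------------------------------
  if (!is.null(bundle$truth)) {
    report$recovery <- run_stage("recovery",
      .recovery_table(report, bundle$truth, bundle$signatures))
  }

  report$provenance <- list(
    seed = config$seed,
    mode = config$mode,
    package_version = as.character(utils::packageVersion("ucbranch")),
    config_json = as.character(jsonlite::toJSON(
      config[setdiff(names(config), c("cohort", "enrichment"))],
      auto_unbox = TRUE, digits = NA, null = "null")))
  class(report) <- "report_bundle"
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

# truth-vs-estimate recovery metrics for synthetic cohorts
.recovery_table <- function(report, truth, signatures) {
  out <- list()
  if (!is.null(report$panel)) {
    selected <- c(report$panel$up_a, report$panel$up_b)
    out$panel_recall <- mean(truth$panel$protein %in% selected)
  }
  if (!is.null(report$origin_calls)) {
    truth_lbl <- names(truth$del8p12)  # sample ids
    cohort_lbl <- report$cohort$derived_label[
      match(report$origin_calls$sample, report$cohort$sample_id)]
    out$origin_accuracy <- mean(report$origin_calls$label == cohort_lbl)
  }
  if (!is.null(report$exposures) && !is.null(truth$exposures)) {
    sig_ids <- colnames(signatures)
    errs <- vapply(names(report$exposures), function(s) {
      est <- setNames(numeric(length(sig_ids)), sig_ids)
      w <- report$exposures[[s]]$weights
      est[names(w)] <- w
      mean(abs(est - truth$exposures[s, sig_ids]))
    }, 0)
    out$exposure_mae <- mean(errs)
  }
  if (!is.null(report$cna_calls) && "8p12" %in% colnames(report$cna_calls)) {
    calls <- report$cna_calls[, "8p12"]
    truth_del <- truth$del8p12[names(calls)]
    out$del8p12_call_accuracy <-
      mean((calls == "del") == truth_del, na.rm = TRUE)
  }
  if (!is.null(report$derived_comparison)) {
    out$hr_estimate <- report$derived_comparison$cox$hr
    out$hr_true <- truth$hazard_ratio
    out$hr_rel_error <- abs(out$hr_estimate - truth$hazard_ratio) /
      truth$hazard_ratio
  }
  out
}

#' Write a report bundle as TSV/JSON files
#'
#' Plain-text, diffable outputs: panel table, pathway scores, exposures,
#' arm burdens and calls, origin calls, classifier model and evaluation,
#' survival fits, recovery table, and a provenance block.
#'
#' @param report a `report_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) write.table(format(df, digits = 12, trim = TRUE),
                                    file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wt(report$cohort, "cohort.tsv")
  if (!is.null(report$panel)) wt(report$panel$table, "panel.tsv")
  if (!is.null(report$pathway_scores)) {
    ps <- report$pathway_scores
    wt(data.frame(set = rownames(ps), ps, check.names = FALSE),
       "pathway_scores.tsv")
  }
  if (!is.null(report$ddr))
    wt(data.frame(sample = names(report$ddr$scores),
                  ddr_score = report$ddr$scores), "ddr_scores.tsv")
  if (!is.null(report$exposures)) {
    rows <- lapply(names(report$exposures), function(s) {
      w <- report$exposures[[s]]$weights
      if (length(w) == 0L) return(NULL)
      data.frame(sample = s, signature = names(w), weight = unname(w),
                 stringsAsFactors = FALSE)
    })
    wt(do.call(rbind, rows), "exposures.tsv")
  }
  if (!is.null(report$signature_groups))
    wt(report$signature_groups, "signature_groups.tsv")
  if (!is.null(report$arm_burden)) {
    ab <- report$arm_burden
    wt(data.frame(sample = rownames(ab), ab, check.names = FALSE),
       "arm_burden.tsv")
  }
  if (!is.null(report$cna_group_test)) wt(report$cna_group_test,
                                          "cna_group_test.tsv")
  if (!is.null(report$cis_effects)) wt(report$cis_effects, "cis_effects.tsv")
  if (!is.null(report$origin_calls)) wt(report$origin_calls,
                                        "origin_calls.tsv")
  if (!is.null(report$model))
    write_classifier_json(report$model, file.path(dir, "model.json"))
  js <- function(x, f) jsonlite::write_json(x, file.path(dir, f),
                                            auto_unbox = TRUE, digits = NA)
  if (!is.null(report$cv))
    js(unclass(report$cv)[c("confusion", "sensitivity", "specificity",
                            "accuracy", "auc", "fold_accuracy", "k")],
       "cv_eval.json")
  if (!is.null(report$test_eval))
    js(unclass(report$test_eval), "test_eval.json")
  if (!is.null(report$derived_comparison)) {
    dc <- report$derived_comparison
    js(list(fisher_metastasis_p = dc$fisher_metastasis$p_value,
            fisher_metastasis_or = dc$fisher_metastasis$odds_ratio,
            logrank_statistic = dc$logrank$statistic,
            logrank_p = dc$logrank$p_value,
            cox = unclass(dc$cox)), "derived_comparison.json")
    if (!is.null(dc$pathway_tests)) wt(dc$pathway_tests,
                                       "derived_pathway_tests.tsv")
  }
  if (!is.null(report$recovery)) js(report$recovery, "recovery.json")
  js(report$provenance, "provenance.json")
  invisible(dir)
}
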