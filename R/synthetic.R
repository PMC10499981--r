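# Seeded synthetic multi-omics cohort generator. It emulates the latent
# structure the downstream analysis assumes -- histology classes spanning
# normal through invasive disease, a papillary-vs-CIS branch effect on a
# protein panel, DDR-marker phospho elevation in CIS/invasive disease, HRAS
# hotspots in papilloma, class-dependent mutational-signature mixtures, an
# 8p12 deletion enriched in metastatic invasive samples with a cis protein
# effect, and proportional-hazards survival with a worse CIS-derived hazard.

.UC_CLASSES <- c("Normal", "Hyperplasia", "UPUMP", "Papilloma",
                 "LGPC", "HGPC", "CIS", "Invasive")

#' Synthetic reference SBS signature set
#'
#' Four deterministic, well-separated signatures over the 96 contexts, named
#' after the aetiologies they caricature: SBS1 (C>T at CpG, aging-like), SBS5
#' (flat, clock-like), SBS13 (C>G at TpC, APOBEC-like), SBS30 (C>T outside
#' CpG, base-excision-repair-like). Columns sum to 1. These are synthetic
#' stand-ins constructed for testing, not the COSMIC catalogs.
#'
#' @return 96 x 4 matrix of probability vectors.
#' @export
synthetic_signature_set <- function() {
  ctx <- sbs_contexts()
  sub <- sub(".*\\[(.*)\\].*", "\\1", ctx)
  f5 <- substr(ctx, 1, 1)
  f3 <- substr(ctx, 7, 7)
  mk <- function(core, core_mass = 0.92) {
    v <- rep((1 - core_mass) / (96 - sum(core)), 96)
    v[core] <- core_mass / sum(core)
    v
  }
  m <- cbind(
    SBS1 = mk(sub == "C>T" & f3 == "G"),
    SBS5 = rep(1 / 96, 96),
    SBS13 = mk(sub == "C>G" & f5 == "T"),
    SBS30 = mk(sub == "C>T" & f3 != "G"))
  rownames(m) <- ctx
  m
}

#' Synthetic genome arm definitions
#'
#' A reduced genome of eight arms on four chromosomes plus the 8p12 band as a
#' separately queryable interval. Coordinates are 0-based half-open.
#'
#' @param include_bands include the 8p12 band row (default TRUE).
#' @return data.frame arm/chrom/start/end.
#' @export
synthetic_arms <- function(include_bands = TRUE) {
  arms <- data.frame(
    arm = c("1p", "1q", "3p", "3q", "8p", "8q", "9p", "9q"),
    chrom = c("chr1", "chr1", "chr3", "chr3", "chr8", "chr8", "chr9", "chr9"),
    start = c(0, 1.2e8, 0, 9e7, 0, 4.5e7, 0, 4e7),
    end = c(1.2e8, 2.4e8, 9e7, 1.98e8, 4.5e7, 1.45e8, 4e7, 1.4e8),
    stringsAsFactors = FALSE)
  if (include_bands)
    arms <- rbind(arms, data.frame(arm = "8p12", chrom = "chr8",
                                   start = 3.0e7, end = 3.8e7))
  arms
}

.default_exposures <- function(classes) {
  prof <- list(
    Normal      = c(SBS1 = 0.2, SBS5 = 0.8),
    Hyperplasia = c(SBS1 = 0.3, SBS5 = 0.7),
    UPUMP       = c(SBS1 = 0.5, SBS5 = 0.5),
    Papilloma   = c(SBS1 = 0.6, SBS5 = 0.4),
    LGPC        = c(SBS1 = 0.6, SBS5 = 0.4),
    HGPC        = c(SBS5 = 0.4, SBS30 = 0.4, SBS13 = 0.2),
    CIS         = c(SBS5 = 0.3, SBS30 = 0.5, SBS13 = 0.2),
    Invasive    = c(SBS5 = 0.3, SBS30 = 0.5, SBS13 = 0.2))
  prof[classes]
}

#' Synthetic cohort configuration
#'
#' Holds every tunable of the generator. Defaults are the study conditions
#' the downstream recovery checks assume: a 1.5 log2 branch effect on the
#' panel at unit residual SD, an 83% HRAS-hotspot rate in papilloma with 80%
#' of hotspots being Q61R, a true CIS-derived hazard ratio of 2, and
#' class-dependent signature mixtures that make SBS1 dominate early lesions
#' and SBS30 late ones.
#'
#' @param n_per_class samples per histology class: a single count or a named
#'   vector over `classes` (every used class needs >= 2).
#' @param classes ordered histology labels to generate (subset of the eight
#'   defaults).
#' @param n_proteins protein feature count.
#' @param panel_size number of branch-discriminating panel proteins.
#' @param effect_log2 log2 shift of panel proteins between branches (>= 0).
#' @param noise_sd residual SD on the log2 scale.
#' @param dropout_midpoint,dropout_slope logistic missingness parameters:
#'   P(missing) = plogis(slope * (midpoint - log2_abundance)).
#' @param hras_papilloma_prob probability a papilloma carries an HRAS hotspot.
#' @param q61r_frac fraction of HRAS hotspots that are Q61R.
#' @param mutation_rate Poisson mean mutations per sample.
#' @param exposure_profiles per-class named mixture vectors over the
#'   signature set (each non-negative, summing to 1); NULL for the defaults.
#' @param cis_derived_hr true hazard ratio of CIS-derived vs PUC-derived.
#' @param censor_rate exponential censoring rate (per month).
#' @param n_phospho phosphoprotein feature count.
#' @param invasive_cis_frac fraction of invasive samples on the CIS branch.
#' @param seed integer seed; identical configs give bit-identical cohorts.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_class = 12L,
                          classes = .UC_CLASSES,
                          n_proteins = 300L,
                          panel_size = 20L,
                          effect_log2 = 1.5,
                          noise_sd = 1.0,
                          dropout_midpoint = 1.0,
                          dropout_slope = 1.0,
                          hras_papilloma_prob = 0.83,
                          q61r_frac = 0.8,
                          mutation_rate = 50,
                          exposure_profiles = NULL,
                          cis_derived_hr = 2.0,
                          censor_rate = 0.01,
                          n_phospho = 150L,
                          invasive_cis_frac = 0.4,
                          seed = 1L) {
  classes <- match.arg(classes, .UC_CLASSES, several.ok = TRUE)
  if (length(n_per_class) == 1L)
    n_per_class <- setNames(rep(as.integer(n_per_class), length(classes)),
                            classes)
  if (!all(classes %in% names(n_per_class)))
    stop("n_per_class must name every class")
  n_per_class <- n_per_class[classes]
  if (any(n_per_class < 2L))
    stop("configuration error: every class needs n_per_class >= 2")
  if (panel_size >= n_proteins)
    stop("panel_size must be smaller than n_proteins")
  if (effect_log2 < 0) stop("effect_log2 must be >= 0")
  if (hras_papilloma_prob < 0 || hras_papilloma_prob > 1)
    stop("hras_papilloma_prob must be in [0, 1]")
  if (q61r_frac < 0 || q61r_frac > 1) stop("q61r_frac must be in [0, 1]")
  if (is.null(exposure_profiles)) exposure_profiles <- .default_exposures(classes)
  for (cl in classes) {
    pr <- exposure_profiles[[cl]]
    if (is.null(pr)) stop("missing exposure profile for class ", cl)
    if (any(pr < 0) || abs(sum(pr) - 1) > 1e-8)
      stop("configuration error: exposure profile for ", cl,
           " must be non-negative and sum to 1")
  }
  structure(list(n_per_class = n_per_class, classes = classes,
                 n_proteins = as.integer(n_proteins),
                 panel_size = as.integer(panel_size),
                 effect_log2 = effect_log2, noise_sd = noise_sd,
                 dropout_midpoint = dropout_midpoint,
                 dropout_slope = dropout_slope,
                 hras_papilloma_prob = hras_papilloma_prob,
                 q61r_frac = q61r_frac, mutation_rate = mutation_rate,
                 exposure_profiles = exposure_profiles,
                 cis_derived_hr = cis_derived_hr, censor_rate = censor_rate,
                 n_phospho = as.integer(n_phospho),
                 invasive_cis_frac = invasive_cis_frac,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# encode an integer as an amino-acid prefix over letters that are neither
# cleavage sites (K/R) nor proline, guaranteeing peptide uniqueness
.aa_encode <- function(i, width = 4L) {
  letters17 <- strsplit("ACDEFGHILMNQSTVWY", "")[[1]]
  out <- character(width)
  for (p in seq_len(width)) {
    out[p] <- letters17[(i %% 17L) + 1L]
    i <- i %/% 17L
  }
  paste(out, collapse = "")
}

# tryptic protein sequences: each protein is a concatenation of peptides with
# a unique encoded prefix, random body (no K/R/P), and a K/R terminus, so the
# digestion recovers exactly the generating peptides
.make_proteins <- function(n_proteins, n_pep_range = c(3L, 5L)) {
  body_letters <- strsplit("ACDEFGHILMNQSTVWY", "")[[1]]
  n_pep <- sample(seq(n_pep_range[1], n_pep_range[2]),
                  n_proteins, replace = TRUE)
  pep_id <- 0L
  seqs <- character(n_proteins)
  peptides <- vector("list", n_proteins)
  for (p in seq_len(n_proteins)) {
    peps <- character(n_pep[p])
    for (j in seq_len(n_pep[p])) {
      pep_id <- pep_id + 1L
      body_len <- sample(3:8, 1L)
      body <- paste(sample(body_letters, body_len, replace = TRUE),
                    collapse = "")
      term <- sample(c("K", "R"), 1L)
      peps[j] <- paste0(.aa_encode(pep_id), body, term)
    }
    peptides[[p]] <- peps
    seqs[p] <- paste(peps, collapse = "")
  }
  list(sequences = seqs, peptides = peptides, n_observable = n_pep)
}

#' Generate a synthetic multi-omics cohort
#'
#' Draws a full bundle -- clinical table, peptide-level evidence, protein and
#' phosphoprotein abundance matrices, mutation table, segment table, gene
#' sets, and a ground-truth record -- with the latent structure described in
#' [cohort_config()]. Identical configurations produce bit-identical bundles.
#'
#' @param config a [cohort_config()] object.
#' @return list of class `cohort_bundle` with elements `cohort`, `truth`,
#'   `peptides`, `proteome` (FOT `abundance_matrix` with dropout), `phospho`,
#'   `mutations`, `segments`, `signatures`, `gene_sets`,
#'   `protein_sequences`, `arms`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  cls <- rep(config$classes, config$n_per_class)
  n <- length(cls)
  sample_id <- sprintf("S%04d", seq_len(n))

  branch <- ifelse(cls %in% c("Papilloma", "LGPC", "HGPC"), "papillary",
            ifelse(cls == "CIS", "cis", "none"))
  inv <- cls == "Invasive"
  branch[inv] <- ifelse(runif(sum(inv)) < config$invasive_cis_frac,
                        "cis", "papillary")
  derived <- rep(NA_character_, n)
  derived[inv] <- ifelse(branch[inv] == "cis", "CIS-derived", "PUC-derived")
  grade <- ifelse(cls %in% c("HGPC", "CIS", "Invasive"), "high", "low")
  metastasis <- rep(FALSE, n)
  metastasis[inv] <- runif(sum(inv)) <
    ifelse(branch[inv] == "cis", 0.55, 0.20)

  # ---- proteome truth -------------------------------------------------
  prot_id <- sprintf("P%04d", seq_len(config$n_proteins))
  panel_idx <- sample(config$n_proteins, config$panel_size)
  panel_dir <- rep(c(1, -1), length.out = config$panel_size)  # +1: up in PUC
  cis_gene <- prot_id[setdiff(seq_len(config$n_proteins), panel_idx)[1L]]
  mu <- rnorm(config$n_proteins, mean = 5, sd = 2)
  # the designated 8p12 gene sits at a well-quantified abundance so its
  # protein survives detection filtering cohort-wide
  mu[prot_id == cis_gene] <- 6
  true_log2 <- matrix(mu, config$n_proteins, n,
                      dimnames = list(prot_id, sample_id))
  b_sign <- ifelse(branch == "papillary", 0.5,
            ifelse(branch == "cis", -0.5, 0))
  true_log2[panel_idx, ] <- true_log2[panel_idx, ] +
    outer(panel_dir, b_sign) * config$effect_log2

  # 8p12 deletion truth, with a cis effect on one designated gene
  del8p12 <- rep(FALSE, n)
  del8p12[inv] <- runif(sum(inv)) < ifelse(metastasis[inv], 0.8, 0.1)
  del8p12[!inv] <- runif(sum(!inv)) < 0.02
  true_log2[cis_gene, del8p12] <- true_log2[cis_gene, del8p12] - 1.2

  noisy_log2 <- true_log2 +
    matrix(rnorm(length(true_log2), 0, config$noise_sd),
           nrow(true_log2), dimnames = dimnames(true_log2))
  p_miss <- plogis(config$dropout_slope *
                     (config$dropout_midpoint - noisy_log2))
  missing <- matrix(runif(length(p_miss)) < p_miss, nrow(p_miss),
                    dimnames = dimnames(p_miss))
  # keep every run quantifiable
  for (j in which(colSums(!missing) == 0)) missing[1L, j] <- FALSE

  intensity <- 2^noisy_log2 * 100
  fot <- matrix(NA_real_, nrow(intensity), n,
                dimnames = dimnames(intensity))
  for (j in seq_len(n)) {
    obs <- !missing[, j]
    fot[obs, j] <- normalize_fot(intensity[obs, j])
  }
  proteome <- abundance_matrix(fot, scale = "FOT", missing = missing)

  # ---- peptide evidence ----------------------------------------------
  prot <- .make_proteins(config$n_proteins)
  names(prot$sequences) <- prot_id
  run_shift <- rnorm(n, 0, 0.5)
  run_slope <- rnorm(n, 1, 0.01)
  pep_rt <- lapply(prot$peptides, function(p) runif(length(p), 5, 115))
  pep_w <- lapply(prot$peptides, function(p) {
    w <- rexp(length(p)); w / sum(w)
  })
  ev <- vector("list", n)
  for (j in seq_len(n)) {
    obs_p <- which(!missing[, j])
    npep <- prot$n_observable[obs_p]
    pep <- unlist(prot$peptides[obs_p], use.names = FALSE)
    prt <- rep(prot_id[obs_p], npep)
    base_int <- rep(intensity[obs_p, j], npep) * unlist(pep_w[obs_p])
    ints <- base_int * 2^rnorm(length(pep), 0, 0.2)
    rts <- run_shift[j] + run_slope[j] * unlist(pep_rt[obs_p]) +
      rnorm(length(pep), 0, 0.05)
    ev[[j]] <- data.frame(run_id = sample_id[j], peptide = pep,
                          protein = prt, intensity = ints,
                          rt = pmax(0.1, rts), observed = TRUE,
                          stringsAsFactors = FALSE)
  }
  peptides <- do.call(rbind, ev)

  # ---- phosphoproteome ------------------------------------------------
  ph_id <- sprintf("PH%04d", seq_len(config$n_phospho))
  ddr_idx <- sample(config$n_phospho, min(10L, config$n_phospho))
  mu_ph <- rnorm(config$n_phospho, 3, 2)
  ph_log2 <- matrix(mu_ph, config$n_phospho, n,
                    dimnames = list(ph_id, sample_id))
  ddr_up <- cls %in% c("CIS", "Invasive")
  ph_log2[ddr_idx, ddr_up] <- ph_log2[ddr_idx, ddr_up] + 1.0
  ph_log2 <- ph_log2 + matrix(rnorm(length(ph_log2), 0, config$noise_sd),
                              nrow(ph_log2))
  ph_miss <- matrix(runif(length(ph_log2)) <
                      plogis(config$dropout_slope *
                               (config$dropout_midpoint - ph_log2)),
                    nrow(ph_log2), dimnames = dimnames(ph_log2))
  ph_vals <- 2^ph_log2
  ph_vals[ph_miss] <- NA
  phospho <- abundance_matrix(ph_vals, scale = "FOT", missing = ph_miss)

  # ---- survival -------------------------------------------------------
  base_haz <- ifelse(inv, 0.02, 0.005)
  haz <- base_haz * ifelse(inv & branch == "cis", config$cis_derived_hr, 1)
  t_event <- rexp(n, haz)
  t_cens <- rexp(n, config$censor_rate)
  survival_time <- pmax(0.01, pmin(t_event, t_cens))
  event <- as.integer(t_event <= t_cens)

  cohort <- data.frame(sample_id = sample_id, histology_class = cls,
                       grade = grade, latent_branch = branch,
                       derived_label = derived, metastasis = metastasis,
                       survival_time = survival_time, event = event,
                       stringsAsFactors = FALSE)

  truth <- list(
    panel = data.frame(protein = prot_id[panel_idx],
                       direction = ifelse(panel_dir > 0, "up_puc", "up_cis"),
                       stringsAsFactors = FALSE),
    ddr_marker_ids = ph_id[ddr_idx],
    del8p12 = setNames(del8p12, sample_id),
    hazard_ratio = config$cis_derived_hr,
    cis_gene = cis_gene)

  # ---- mutations ------------------------------------------------------
  signatures <- synthetic_signature_set()
  mutations <- generate_mutation_table(cohort, signatures, config,
                                       .reseed = FALSE)
  truth$exposures <- attr(mutations, "true_exposures")

  # ---- segments -------------------------------------------------------
  arms <- synthetic_arms(include_bands = FALSE)
  seg <- vector("list", n)
  for (j in seq_len(n)) {
    rows <- vector("list", nrow(arms))
    for (a in seq_len(nrow(arms))) {
      nseg <- sample(1:3, 1L)
      bp <- sort(c(arms$start[a],
                   runif(nseg - 1L, arms$start[a], arms$end[a]),
                   arms$end[a]))
      rows[[a]] <- data.frame(sample = sample_id[j], chrom = arms$chrom[a],
                              start = bp[-length(bp)], end = bp[-1L],
                              log2_ratio = rnorm(nseg, 0, 0.15),
                              stringsAsFactors = FALSE)
    }
    sj <- do.call(rbind, rows)
    if (del8p12[j]) {
      # carve a deleted segment spanning the 8p12 band out of the 8p arm
      p8 <- sj$chrom == "chr8" & sj$start < 4.5e7
      keep <- sj[!p8, , drop = FALSE]
      flank_lr <- rnorm(2, 0, 0.15)
      del_rows <- data.frame(sample = sample_id[j], chrom = "chr8",
                             start = c(0, 2.9e7, 3.9e7),
                             end = c(2.9e7, 3.9e7, 4.5e7),
                             log2_ratio = c(flank_lr[1], -1.2, flank_lr[2]),
                             stringsAsFactors = FALSE)
      sj <- rbind(keep, del_rows)
    }
    seg[[j]] <- sj
  }
  segments <- do.call(rbind, seg)
  rownames(segments) <- NULL

  # ---- gene sets ------------------------------------------------------
  up_puc <- prot_id[panel_idx][panel_dir > 0]
  up_cis <- prot_id[panel_idx][panel_dir < 0]
  rnd <- function() sample(prot_id, min(15L, length(prot_id)))
  gene_sets <- list(BRANCH_UP_PUC = up_puc, BRANCH_UP_CIS = up_cis,
                    DDR_PHOSPHO = ph_id[ddr_idx],
                    RANDOM_A = rnd(), RANDOM_B = rnd(), RANDOM_C = rnd())

  structure(list(cohort = cohort, truth = truth, peptides = peptides,
                 proteome = proteome, phospho = phospho,
                 mutations = mutations, segments = segments,
                 signatures = signatures, gene_sets = gene_sets,
                 protein_sequences = prot$sequences,
                 arms = synthetic_arms(include_bands = TRUE),
                 config = config),
            class = "cohort_bundle")
}

#' Generate a synthetic mutation table for a cohort
#'
#' Each sample draws a Poisson number of substitutions i.i.d. from its
#' class's exposure-weighted signature mixture; each record carries ref, alt
#' and both flanking bases consistent with its sampled context (half the
#' records are emitted on the purine strand to exercise reverse-complement
#' handling). Papilloma samples additionally carry an HRAS hotspot record
#' with the configured probability (Q61R with probability `q61r_frac`, else
#' G13R).
#'
#' @param cohort cohort table (needs `sample_id`, `histology_class`).
#' @param signatures 96 x k matrix of signature probability vectors.
#' @param config a [cohort_config()].
#' @param .reseed reset the RNG from `config$seed` (TRUE when called
#'   standalone; [generate_cohort()] passes FALSE to keep one stream).
#' @return data.frame with columns sample, chrom, pos, gene, ref, alt,
#'   flank5, flank3, protein_change, hotspot; attribute `true_exposures`
#'   holds the per-sample mixture weights used.
#' @export
generate_mutation_table <- function(cohort, signatures, config,
                                    .reseed = TRUE) {
  if (.reseed) set.seed(config$seed)
  ctx <- sbs_contexts()
  sig_ids <- colnames(signatures)
  for (cl in unique(cohort$histology_class)) {
    pr <- config$exposure_profiles[[cl]]
    if (is.null(pr)) stop("missing exposure profile for class ", cl)
    if (!all(names(pr) %in% sig_ids))
      stop("exposure profile for ", cl, " references unknown signature: ",
           paste(setdiff(names(pr), sig_ids), collapse = ", "))
  }
  n <- nrow(cohort)
  true_exp <- matrix(0, n, length(sig_ids),
                     dimnames = list(cohort$sample_id, sig_ids))
  recs <- vector("list", n)
  comp <- .COMPLEMENT
  for (j in seq_len(n)) {
    pr <- config$exposure_profiles[[cohort$histology_class[j]]]
    true_exp[j, names(pr)] <- pr
    nm <- rpois(1L, config$mutation_rate)
    if (nm > 0L) {
      mix <- drop(signatures[, names(pr), drop = FALSE] %*% pr)
      ctx_i <- sample.int(96L, nm, replace = TRUE, prob = mix)
      cx <- ctx[ctx_i]
      ref <- substr(cx, 3, 3); alt <- substr(cx, 5, 5)
      f5 <- substr(cx, 1, 1); f3 <- substr(cx, 7, 7)
      flip <- runif(nm) < 0.5
      r2 <- ifelse(flip, comp[ref], ref)
      a2 <- ifelse(flip, comp[alt], alt)
      f5_2 <- ifelse(flip, comp[f3], f5)
      f3_2 <- ifelse(flip, comp[f5], f3)
      recs[[j]] <- data.frame(
        sample = cohort$sample_id[j], chrom = "chr1",
        pos = sort(sample.int(2.4e8, nm)), gene = NA_character_,
        ref = unname(r2), alt = unname(a2),
        flank5 = unname(f5_2), flank3 = unname(f3_2),
        protein_change = NA_character_, hotspot = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  mut <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  pap <- which(cohort$histology_class == "Papilloma")
  if (length(pap)) {
    carry <- pap[runif(length(pap)) < config$hras_papilloma_prob]
    if (length(carry)) {
      q61r <- runif(length(carry)) < config$q61r_frac
      hs <- data.frame(
        sample = cohort$sample_id[carry], chrom = "chr11", pos = 534286L,
        gene = "HRAS", ref = "A", alt = "G", flank5 = "C", flank3 = "A",
        protein_change = ifelse(q61r, "Q61R", "G13R"), hotspot = TRUE,
        stringsAsFactors = FALSE)
      mut <- rbind(mut, hs)
    }
  }
  if (is.null(mut))
    mut <- data.frame(sample = character(0), chrom = character(0),
                      pos = integer(0), gene = character(0),
                      ref = character(0), alt = character(0),
                      flank5 = character(0), flank3 = character(0),
                      protein_change = character(0), hotspot = logical(0),
                      stringsAsFactors = FALSE)
  rownames(mut) <- NULL
  attr(mut, "true_exposures") <- true_exp
  mut
}

#' Write a cohort bundle to a directory of plain-text files
#'
#' Emits peptides.tsv, proteome.tsv, phospho.tsv, clinical.tsv,
#' mutations.maf.tsv, segments.seg.tsv (0-based half-open), arms.tsv,
#' signatures.tsv, gene_sets.gmt, and truth.json.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wt(bundle$peptides, "peptides.tsv")
  write_abundance_tsv(bundle$proteome, file.path(dir, "proteome.tsv"))
  write_abundance_tsv(bundle$phospho, file.path(dir, "phospho.tsv"))
  wt(bundle$cohort, "clinical.tsv")
  wt(bundle$mutations, "mutations.maf.tsv")
  write_segments(bundle$segments, file.path(dir, "segments.seg.tsv"))
  wt(bundle$arms, "arms.tsv")
  sig <- data.frame(context = rownames(bundle$signatures),
                    bundle$signatures, check.names = FALSE)
  wt(sig, "signatures.tsv")
  write_gmt(bundle$gene_sets, file.path(dir, "gene_sets.gmt"))
  truth <- bundle$truth
  truth$exposures <- as.data.frame(truth$exposures)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
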