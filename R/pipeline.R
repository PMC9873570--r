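#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end run. All thresholds
#' are echoed into the run manifest. Unknown keys are rejected by
#' [run_pipeline()].
#'
#' @param sim A [sim_config()] for the synthetic cohort.
#' @param p_gws Discovery genome-wide significance (default 5e-8).
#' @param p_candidate Meta-analysis candidate threshold (default 5e-6).
#' @param p_meta_sig Meta-analysis significance (default 5e-9).
#' @param locus_window Locus merge / region half-width in bp
#'   (default 1.5e6).
#' @param finemap_W Fine-mapping prior effect variance (default 0.04).
#' @param finemap_L Maximum signals per region (default 5).
#' @param coverage Credible-set coverage (default 0.95).
#' @param purity_min Credible-set purity threshold (default 0.5).
#' @param compare_W,compare_rho Model-comparison prior variance and
#'   RISK/CAD prior correlation (defaults 0.04, 0.9).
#' @param support Posterior support threshold (default 0.6).
#' @param n_endpoints Endpoint-scan Bonferroni denominator
#'   (default 231).
#' @param concordance_null Null concordance probability for the
#'   direction sign test (default 0.5).
#' @param train_frac,auc_rounds PRS evaluation split fraction and
#'   number of AUC rounds (defaults 0.75, 100).
#' @param meta_split Fraction of the cohort forming the first
#'   pseudo-cohort of the meta-analysis (default 0.6).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            p_gws = 5e-8, p_candidate = 5e-6,
                            p_meta_sig = 5e-9, locus_window = 1.5e6,
                            finemap_W = 0.04, finemap_L = 5L,
                            coverage = 0.95, purity_min = 0.5,
                            compare_W = 0.04, compare_rho = 0.9,
                            support = 0.6, n_endpoints = 231L,
                            concordance_null = 0.5,
                            train_frac = 0.75, auc_rounds = 100L,
                            meta_split = 0.6) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Small demonstration configuration
#'
#' A scaled-down cohort (3,000 individuals, 400 variants, strong causal
#' effects) that exercises every stage in a few minutes on one CPU.
#'
#' @param seed Integer seed.
#' @return A `pipeline_config`.
#' @export
demo_config <- function(seed = 1L) {
  pipeline_config(
    sim = sim_config(n_individuals = 3000, n_variants = 400,
                     n_causal = c(lipid = 8, htn = 8, t2d = 8),
                     h2 = c(lipid = 0.4, htn = 0.4, t2d = 0.4),
                     maf_range = c(0.05, 0.5), seed = seed),
    auc_rounds = 100L)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.tsv <- function(d, dir, f) utils::write.table(
  as.data.frame(d), file.path(dir, f), sep = "\t", quote = FALSE,
  row.names = FALSE)

#' Run the full synthetic-registry analysis pipeline
#'
#' simulate -> phenotype -> scan -> loci -> meta -> finemap ->
#' compare -> annotate -> prs, writing per-stage TSVs, a parameter
#' manifest and a JSON summary under `out_dir`. All randomness flows
#' from `config$sim$seed`; a rerun with the same configuration
#' reproduces the outputs. A stage failure halts the run with the
#' failing stage named; earlier outputs remain on disk.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the main in-memory artifacts.
#' @export
run_pipeline <- function(config = demo_config(), out_dir = tempfile("medtraj_")) {
  known_keys <- names(formals(pipeline_config))
  extra <- setdiff(names(config), known_keys)
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- .stage("simulate", {
    s <- simulate_cohort(config$sim)
    .tsv(s$registry, out_dir, "registry.tsv")
    .tsv(s$persons, out_dir, "persons.tsv")
    .tsv(s$truth$causal, out_dir, "truth_causal.tsv")
    s
  })

  phen <- .stage("phenotype", {
    p <- derive_phenotypes(sim$registry, sim$persons, config$sim$window)
    .tsv(p, out_dir, "phenotypes.tsv")
    .tsv(summarize_cohort(p), out_dir, "cohort_summary.tsv")
    p
  })

  quant <- c(lipid = "purchases_lipid", htn = "purchases_htn",
             t2d = "purchases_t2d")
  covars <- .stage("scan", {
    el <- phen$eligible
    data.frame(age = phen$age_end[el], age2 = phen$age_end[el]^2,
               follow_up = phen$follow_up_years[el],
               sex = factor(sim$persons$sex[el]))
  })
  el <- phen$eligible
  G_el <- list(dosages = sim$genotypes$dosages[el, , drop = FALSE],
               variants = sim$genotypes$variants)
  class(G_el) <- "genotype_matrix"

  scans <- .stage("scan", {
    out <- lapply(names(quant), function(f) {
      cv <- covars
      cv$batch <- pool_small_batches(sim$persons$batch[el],
                                     phen[[quant[[f]]]][el])
      st <- run_scan(G_el, phen[[quant[[f]]]][el], cv, family = "linear")
      st$phenotype <- quant[[f]]
      st
    })
    names(out) <- names(quant)
    all <- do.call(rbind, lapply(out, as.data.frame))
    .tsv(all, out_dir, "sumstats.tsv")
    out
  })
  all_stats <- do.call(rbind, lapply(scans, as.data.frame))

  loci <- .stage("loci", {
    l <- define_loci(all_stats, config$p_gws, config$locus_window)
    .tsv(l, out_dir, "loci.tsv")
    l
  })
  candidates <- define_loci(all_stats, config$p_candidate,
                            config$locus_window)
  # downstream single-trait stages follow the best-supported phenotype
  target <- if (nrow(candidates))
    names(sort(table(candidates$lead_phenotype), decreasing = TRUE))[1L]
  else "purchases_lipid"
  target_f <- names(quant)[match(target, quant)]

  meta_res <- .stage("meta", {
    nA <- round(config$meta_split * sum(el))
    iA <- seq_len(nA); iB <- setdiff(seq_len(sum(el)), iA)
    subG <- function(i) {
      g <- list(dosages = G_el$dosages[i, , drop = FALSE],
                variants = sim$genotypes$variants)
      class(g) <- "genotype_matrix"; g
    }
    y <- phen[[target]][el]
    scan_half <- function(i) {
      cv <- covars[i, , drop = FALSE]
      run_scan(subG(i), y[i], cv, family = "linear")
    }
    cohA <- scan_half(iA); cohB <- scan_half(iB)
    harm <- harmonize_alleles(cohB, cohA)
    mt <- ivw_meta(list(A = cohA, B = harm$aligned))
    .tsv(mt, out_dir, "meta.tsv")
    cand_t <- candidates[candidates$lead_phenotype == target, ]
    sel <- select_and_declare(cand_t, mt, config$p_candidate,
                              config$p_meta_sig, config$p_gws)
    leads <- mt[mt$id %in% loci$lead_id, , drop = FALSE]
    conc <- if (nrow(leads)) concordance_test(leads$direction,
                                              config$concordance_null)
      else list(k = 0, n = 0, pval = NA)
    list(meta = mt, selected = sel, concordance = conc,
         cohorts = list(A = cohA, B = harm$aligned), split = list(A = iA, B = iB))
  })

  finemap_res <- .stage("finemap", {
    all_cs <- list()
    for (f in names(quant)) {
      lf <- loci[loci$lead_phenotype == quant[[f]], , drop = FALSE]
      regions <- build_regions(lf, scans[[f]], sim$genotypes,
                               config$locus_window, config$p_gws)
      for (ri in seq_along(regions)) {
        sets <- multi_signal_sets(regions[[ri]], L = config$finemap_L,
                                  W = config$finemap_W,
                                  coverage = config$coverage,
                                  purity_min = config$purity_min)
        for (cs in sets) {
          top <- cs$variants[1L, ]
          vt <- sim$genotypes$variants
          vm <- match(top$id, vt$id)
          enr <- flag_enrichment(vt$af_sample[vm], vt$af_reference[vm])
          all_cs[[length(all_cs) + 1L]] <- data.frame(
            phenotype = quant[[f]], region = ri, signal = cs$signal,
            cs_id = sprintf("%s_r%d_s%d", f, ri, cs$signal),
            chr = regions[[ri]]$chr, pos = top$pos, top_variant = top$id,
            n_variants = nrow(cs$variants), coverage = cs$coverage,
            purity = cs$purity, enriched = enr$enriched,
            fold = enr$fold, stringsAsFactors = FALSE)
        }
      }
    }
    cs_tab <- if (length(all_cs)) do.call(rbind, all_cs) else
      data.frame(phenotype = character(), cs_id = character(),
                 chr = integer(), pos = integer(), category = character())
    .tsv(cs_tab, out_dir, "credible_sets.tsv")
    cs_tab
  })

  compare_res <- .stage("compare", {
    # RISK proxy: scan of the true lipid liability; CAD proxy: scan of a
    # composite cardiometabolic liability (both emulate external GWAS)
    set.seed(config$sim$seed + 10L)
    cad_liab <- as.numeric(scale(0.4 * sim$persons$liab_lipid +
                                 0.4 * sim$persons$liab_htn +
                                 0.2 * sim$persons$liab_t2d)) +
      stats::rnorm(nrow(sim$persons), 0, 0.8)
    risk_stats <- run_scan(G_el, sim$persons[[paste0("liab_", target_f)]][el],
                           covars, family = "linear")
    cad_stats <- run_scan(G_el, cad_liab[el], covars, family = "linear")
    .tsv(risk_stats, out_dir, "risk_sumstats.tsv")
    .tsv(cad_stats, out_dir, "cad_sumstats.tsv")
    t_loci <- loci[loci$lead_phenotype == target, ]
    bc <- batch_compare(t_loci$lead_id, scans[[target_f]], risk_stats,
                        cad_stats, W = config$compare_W,
                        rho = config$compare_rho, support = config$support)
    .tsv(bc$results, out_dir, "model_comparison.tsv")
    c(bc, list(cad_stats = cad_stats))
  })

  annot_res <- .stage("annotate", {
    category_of <- c(purchases_lipid = "lipid", purchases_htn = "blood-pressure",
                     purchases_t2d = "glucose")
    cs_tab <- finemap_res
    if (nrow(cs_tab)) {
      cs_tab$category <- category_of[cs_tab$phenotype]
      truth <- sim$truth$causal
      vm <- match(truth$variant, sim$genotypes$variants$id)
      known <- data.frame(
        chr = sim$genotypes$variants$chr[vm],
        pos = sim$genotypes$variants$pos[vm],
        trait = truth$factor,
        trait_category = c(lipid = "lipid", htn = "blood-pressure",
                           t2d = "glucose")[truth$factor],
        p = 1e-20, stringsAsFactors = FALSE)
      known <- known[seq(1, nrow(known), by = 2), ]  # half the truth is "known"
      ann <- annotate_novelty(cs_tab, known, config$locus_window)
      .tsv(ann, out_dir, "novelty.tsv")
    } else ann <- cs_tab
    ep <- compare_res$cad_stats
    t_leads <- loci$lead_id[loci$lead_phenotype == target]
    ep_tab <- data.frame(id = character(), endpoint = character(),
                         p = numeric(), stringsAsFactors = FALSE)
    if (length(t_leads))
      ep_tab <- data.frame(id = t_leads, endpoint = "composite_cvd",
                           p = ep$pval[match(t_leads, ep$id)],
                           stringsAsFactors = FALSE)
    ep_tab <- ep_tab[!is.na(ep_tab$p), , drop = FALSE]
    hits <- endpoint_scan(ep_tab, config$n_endpoints)
    .tsv(hits, out_dir, "endpoint_hits.tsv")
    list(novelty = ann, endpoint_hits = hits)
  })

  prs_res <- .stage("prs", {
    # weights come from the candidate loci of the target phenotype,
    # estimated in pseudo-cohort A; evaluation is on held-out cohort B
    t_loci <- candidates[candidates$lead_phenotype == target, ]
    if (nrow(t_loci) == 0L) {
      list(available = FALSE)
    } else {
      cohA <- meta_res$cohorts$A
      wm <- match(t_loci$lead_id, cohA$id)
      ok <- !is.na(wm)
      weights <- data.frame(id = t_loci$lead_id[ok],
                            effect_allele = cohA$effect_allele[wm[ok]],
                            beta = cohA$beta[wm[ok]],
                            stringsAsFactors = FALSE)
      .tsv(weights, out_dir, "prs_weights.tsv")
      iB <- meta_res$split$B
      GB <- list(dosages = G_el$dosages[iB, , drop = FALSE],
                 variants = sim$genotypes$variants)
      class(GB) <- "genotype_matrix"
      scoreB <- prs_score(GB, weights)
      yq <- phen[[target]][el][iB]
      cvB <- covars[iB, , drop = FALSE]
      qa <- quantile_association(scoreB, inverse_normal_transform(yq), cvB)
      ever <- as.integer(yq > 0)
      f1 <- suppressWarnings(stats::glm(ever ~ scoreB, family = stats::binomial()))
      f0 <- suppressWarnings(stats::glm(ever ~ 1, family = stats::binomial()))
      r2 <- nagelkerke_r2(as.numeric(stats::logLik(f0)),
                          as.numeric(stats::logLik(f1)), length(ever))
      w2 <- weights; w2$beta <- rev(w2$beta)   # rival mis-specified score
      score2 <- prs_score(GB, w2)
      jt <- tryCatch(j_test(ever, NULL, score2, scoreB),
                     error = function(e) list(p_A_given_B = NA,
                                              p_B_given_A = NA))
      auc <- repeated_split_auc(scoreB, ever, covariates = NULL,
                                train_frac = config$train_frac,
                                rounds = config$auc_rounds,
                                seed = config$sim$seed + 20L)
      res <- list(available = TRUE, weights = weights, quantiles = qa,
                  nagelkerke = r2, j_test = jt, auc = auc)
      res
    }
  })

  summary <- list(
    n_individuals = nrow(sim$persons),
    n_variants = nrow(sim$genotypes$variants),
    n_purchases = nrow(sim$registry),
    n_loci = nrow(loci),
    n_candidate_loci = nrow(candidates),
    target_phenotype = target,
    n_meta_significant = sum(meta_res$selected$significant),
    concordance = meta_res$concordance,
    n_credible_sets = nrow(finemap_res),
    model_counts = as.list(compare_res$counts),
    n_novel = if (nrow(annot_res$novelty)) sum(annot_res$novelty$novel) else 0L,
    prs = if (isTRUE(prs_res$available))
      list(nagelkerke_r2 = prs_res$nagelkerke,
           mean_auc = prs_res$auc$mean_auc) else NULL)
  manifest <- list(
    package = "medtraj",
    package_version = as.character(utils::packageVersion("medtraj")),
    r_version = R.version.string,
    seed = config$sim$seed,
    parameters = config[setdiff(names(config), "sim")],
    sim_parameters = lapply(unclass(config$sim), function(x)
      if (inherits(x, "Date")) as.character(x) else x),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(sim = sim, phenotypes = phen, scans = scans, loci = loci,
                 candidates = candidates, meta = meta_res,
                 credible_sets = finemap_res, comparison = compare_res,
                 annotation = annot_res, prs = prs_res,
                 summary = summary, out_dir = out_dir))
}
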