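#' Simulation configuration
#'
#' Builds and validates the configuration driving the synthetic cohort:
#' genotypes with block-wise linkage disequilibrium, one latent liability
#' per risk factor (lipid, hypertension, type-2 diabetes), and a purchase
#' registry whose initiation, purchase intensity, switching and
#' discontinuation all depend on that liability through one shared
#' mechanism. Higher liability means earlier initiation, more purchases,
#' more medication changes and a lower probability of discontinuation, so
#' the registry reproduces the qualitative correlation structure the
#' downstream analyses assume.
#'
#' @param n_individuals Cohort size (default 20000).
#' @param n_variants Number of biallelic variants (default 2000).
#' @param n_causal Causal variants per risk factor (default 30).
#' @param maf_range Minor-allele-frequency range, within (0, 0.5].
#' @param h2 Liability heritability per risk factor, each in [0, 1].
#' @param ld_block_size Variants per LD block (default 20).
#' @param ld_rho Latent within-block correlation, in [0, 1).
#' @param n_chr Number of chromosomes the variants are spread over.
#' @param enrich_frac Fraction of variants whose reference-population
#'   frequency makes the minor allele at least twofold enriched in the
#'   study sample.
#' @param window Follow-up window (date pair).
#' @param init_hazard Baseline initiation hazard per year, one per factor.
#' @param init_slope Log-hazard increase per liability SD.
#' @param purchases_per_year Mean purchase rate after initiation.
#' @param rate_slope Log-rate increase per liability SD.
#' @param nb_size Negative-binomial overdispersion of yearly purchases.
#' @param disc_intercept,disc_slope Logistic model of fast
#'   discontinuation: `plogis(disc_intercept - disc_slope * liability)`.
#' @param p_simva_start Probability that a statin starter begins on
#'   simvastatin.
#' @param switch_intercept,switch_slope Logistic model of switching
#'   simvastatin to another statin (increasing in liability).
#' @param grp_intercept,grp_slope Logistic model of adding each further
#'   antihypertensive group (count = 1 + Binomial(4, p)).
#' @param secondline_intercept,secondline_slope Logistic model of using a
#'   second-line T2D agent.
#' @param insulin_intercept,insulin_slope Logistic model of progressing
#'   to insulin.
#' @param insulin_first_frac Fraction of T2D medication users whose
#'   insulin starts before oral treatment (exercises the exclusion rule).
#' @param frac_nonstatin_lipid Fraction of lipid purchases that are
#'   non-statin lipid modifiers.
#' @param seed Integer seed; the full simulated output is a pure function
#'   of the configuration including this seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 20000,
                       n_variants = 2000,
                       n_causal = c(lipid = 30, htn = 30, t2d = 30),
                       maf_range = c(0.01, 0.5),
                       h2 = c(lipid = 0.3, htn = 0.3, t2d = 0.3),
                       ld_block_size = 20,
                       ld_rho = 0.8,
                       n_chr = 2,
                       enrich_frac = 0.1,
                       window = default_window(),
                       init_hazard = c(lipid = 0.022, htn = 0.045, t2d = 0.008),
                       init_slope = 0.5,
                       purchases_per_year = 4,
                       rate_slope = 0.2,
                       nb_size = 2,
                       disc_intercept = stats::qlogis(0.10),
                       disc_slope = 0.5,
                       p_simva_start = 0.59,
                       switch_intercept = stats::qlogis(0.40),
                       switch_slope = 0.3,
                       grp_intercept = stats::qlogis(0.25),
                       grp_slope = 0.4,
                       secondline_intercept = stats::qlogis(0.45),
                       secondline_slope = 0.3,
                       insulin_intercept = stats::qlogis(0.20),
                       insulin_slope = 0.3,
                       insulin_first_frac = 0.03,
                       frac_nonstatin_lipid = 0.05,
                       seed = 1L) {
  factors <- c("lipid", "htn", "t2d")
  if (is.null(names(n_causal))) names(n_causal) <- factors
  if (is.null(names(h2))) names(h2) <- factors
  if (is.null(names(init_hazard))) names(init_hazard) <- factors
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_variants = as.integer(n_variants),
              n_causal = n_causal, maf_range = maf_range, h2 = h2,
              ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
              n_chr = as.integer(n_chr), enrich_frac = enrich_frac,
              window = .as_date(window),
              init_hazard = init_hazard, init_slope = init_slope,
              purchases_per_year = purchases_per_year,
              rate_slope = rate_slope, nb_size = nb_size,
              disc_intercept = disc_intercept, disc_slope = disc_slope,
              p_simva_start = p_simva_start,
              switch_intercept = switch_intercept,
              switch_slope = switch_slope,
              grp_intercept = grp_intercept, grp_slope = grp_slope,
              secondline_intercept = secondline_intercept,
              secondline_slope = secondline_slope,
              insulin_intercept = insulin_intercept,
              insulin_slope = insulin_slope,
              insulin_first_frac = insulin_first_frac,
              frac_nonstatin_lipid = frac_nonstatin_lipid,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @param config A `sim_config` list.
#' @export
validate_sim_config <- function(config) {
  with(config, {
    stopifnot(n_individuals >= 1, n_variants >= 1, ld_block_size >= 1)
    if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
      stop("maf_range must lie within (0, 0.5]")
    if (any(h2 < 0 | h2 > 1)) stop("h2 must lie in [0, 1]")
    if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
    if (any(init_hazard <= 0) || purchases_per_year <= 0 || nb_size <= 0)
      stop("rate parameters must be positive")
    if (any(h2 == 1 & n_causal == 0))
      stop("h2 = 1 requires at least one causal variant")
  })
  invisible(config)
}

#' Simulate genotype dosages with block LD
#'
#' Draws per-variant minor allele frequencies uniformly within
#' `maf_range`, then samples two haplotypes per person from a Gaussian
#' copula with compound-symmetric latent correlation `ld_rho` within each
#' block of `ld_block_size` consecutive variants (blocks independent; the
#' last block may be shorter). Dosages are the haplotype sums, so each
#' variant is marginally Binomial(2, maf). A reference-population
#' frequency is drawn per variant so that a fraction `enrich_frac` of
#' variants has its minor allele at least twofold enriched in the sample.
#'
#' @param config A [sim_config()].
#' @return List of class `genotype_matrix` with elements `dosages`
#'   (n_individuals x n_variants matrix) and `variants` (data frame:
#'   `chr`, `pos`, `ref`, `alt`, `maf`, `af_sample`, `af_reference`).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_individuals; m <- config$n_variants
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  thr <- stats::qnorm(maf)
  block <- rep(seq_len(ceiling(m / config$ld_block_size)),
               each = config$ld_block_size)[seq_len(m)]
  rho <- config$ld_rho

  dos <- matrix(0L, n, m)
  for (b in unique(block)) {
    j <- which(block == b)
    k <- length(j)
    for (h in 1:2) {
      z0 <- stats::rnorm(n)
      z <- sqrt(rho) * z0 + sqrt(1 - rho) *
        matrix(stats::rnorm(n * k), n, k)
      dos[, j] <- dos[, j] + (z < rep(thr[j], each = n))
    }
  }
  storage.mode(dos) <- "integer"

  # variant map: blocks laid out along n_chr chromosomes, positions increasing
  chr <- 1L + ((block - 1L) %% config$n_chr)
  pos <- integer(m)
  for (cc in unique(chr)) {
    j <- which(chr == cc)
    pos[j] <- cumsum(sample(2000:10000, length(j), replace = TRUE)) + 10000L
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  enriched <- stats::runif(m) < config$enrich_frac
  fold <- ifelse(enriched, stats::runif(m, 2.2, 6), stats::runif(m, 0.8, 1.25))
  af_reference <- pmin(maf / fold, 0.5)

  variants <- data.frame(
    chr = chr, pos = pos, ref = ref, alt = alt,
    maf = maf, af_sample = colMeans(dos) / 2,
    af_reference = af_reference, block = block,
    stringsAsFactors = FALSE)
  variants$id <- with(variants, paste(chr, pos, ref, alt, sep = ":"))
  colnames(dos) <- variants$id
  structure(list(dosages = dos, variants = variants),
            class = "genotype_matrix")
}

#' Simulate additive liabilities from genotypes
#'
#' For each risk factor, draws `n_causal` causal variants with normal
#' effects rescaled so the genetic component has variance `h2`, then adds
#' independent Gaussian noise of variance `1 - h2`. The realized causal
#' variants, effects and genetic components are returned so downstream
#' recovery tests have the truth available.
#'
#' @param genotypes A `genotype_matrix` from [simulate_genotypes()].
#' @param config A [sim_config()].
#' @return List with `liabilities` (n x 3 matrix, columns lipid/htn/t2d),
#'   `genetic` (same shape, the genetic components) and `truth` (data
#'   frame: `factor`, `variant`, `effect`).
#' @export
simulate_liabilities <- function(genotypes, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  n <- nrow(genotypes$dosages)
  factors <- names(config$h2)
  liab <- gen <- matrix(0, n, length(factors),
                        dimnames = list(NULL, factors))
  truth <- list()
  for (f in factors) {
    h2 <- config$h2[[f]]; nc <- config$n_causal[[f]]
    g <- numeric(n)
    eff <- numeric(0); idx <- integer(0)
    if (nc > 0 && h2 > 0) {
      idx <- sort(sample(config$n_variants, nc))
      eff <- stats::rnorm(nc)
      raw <- as.numeric(genotypes$dosages[, idx, drop = FALSE] %*% eff)
      s <- stats::sd(raw)
      if (s == 0) stop("causal variants carry no dosage variance")
      eff <- eff * sqrt(h2) / s
      g <- raw * sqrt(h2) / s
    }
    liab[, f] <- g + stats::rnorm(n, 0, sqrt(max(1 - h2, 0)))
    gen[, f] <- g
    if (length(idx))
      truth[[f]] <- data.frame(factor = f,
                               variant = genotypes$variants$id[idx],
                               effect = eff, stringsAsFactors = FALSE)
  }
  list(liabilities = liab, genetic = gen,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(factor = character(), variant = character(),
                    effect = numeric()))
}

# Person table with demographics and one batch label.
.simulate_persons <- function(config) {
  n <- config$n_individuals
  w <- config$window
  birth <- w[1] - round(stats::runif(n, 12, 80) * 365.25)
  death <- rep(as.Date(NA), n)
  dies <- stats::runif(n) < 0.12
  death[dies] <- w[1] + round(stats::runif(sum(dies), -3, 24) * 365.25)
  data.frame(person_id = sprintf("P%06d", seq_len(n)),
             sex = sample(c("female", "male"), n, replace = TRUE,
                          prob = c(0.55, 0.45)),
             birth_date = birth, death_date = death,
             batch = sample(paste0("b", 1:3), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# One factor's purchase stream for one person; returns a date vector.
.purchase_dates <- function(start, end, rate_per_year, nb_size) {
  if (start > end) return(as.Date(character()))
  years <- as.numeric(end - start) / 365.25
  n_events <- stats::rnbinom(1, size = nb_size * max(years, 0.25),
                             mu = rate_per_year * years)
  if (n_events == 0) return(start)
  sort(c(start, start + round(stats::runif(n_events, 1,
                                           max(as.numeric(end - start), 2)))))
}

#' Simulate an ATC-coded purchase registry
#'
#' For every person and risk factor: initiation time is exponential with
#' hazard `init_hazard * exp(init_slope * liability)` from the window
#' start; after initiation, purchases arrive at a negative-binomial
#' yearly rate increasing in liability until the person's end of
#' follow-up, unless the person fast-discontinues (one or two purchases,
#' probability logistic-decreasing in liability). Statin starters begin
#' on simvastatin with probability `p_simva_start` and switch to another
#' statin with probability logistic-increasing in liability;
#' antihypertensive purchases are spread over 1-5 of the five ATC groups
#' with the group count increasing in liability; T2D users start on a
#' metformin-like drug, may add a second-line agent, and may progress to
#' insulin, both with liability-dependent probabilities. All emitted
#' codes belong to the standard medication classes.
#'
#' @param persons Person table from the simulator, with liability columns
#'   `liab_lipid`, `liab_htn`, `liab_t2d` attached.
#' @param config A [sim_config()].
#' @return Data frame `person_id`, `date`, `atc` (one row per purchase).
#' @export
simulate_registry <- function(persons, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  w <- config$window
  eof <- .end_of_followup(persons, w)
  n <- nrow(persons)
  out <- vector("list", 3L * n)
  k <- 0L

  other_statins <- c("C10AA05", "C10AA03", "C10AA07")
  htn_codes <- c(C02 = "C02AC01", C03 = "C03AA03", C07 = "C07AB02",
                 C08 = "C08CA01", C09 = "C09AA05")
  secondline_codes <- c("A10BD07", "A10BH01", "A10BJ02", "A10BK01")

  for (f in c("lipid", "htn", "t2d")) {
    L <- persons[[paste0("liab_", f)]]
    if (is.null(L)) stop("persons table lacks liability column liab_", f)
    hazard <- config$init_hazard[[f]] * exp(config$init_slope * L)
    t_init <- stats::rexp(n, hazard)
    init_date <- w[1] + round(t_init * 365.25)
    rate <- config$purchases_per_year * exp(config$rate_slope * L)
    p_disc <- stats::plogis(config$disc_intercept - config$disc_slope * L)
    fast <- stats::runif(n) < p_disc

    for (i in seq_len(n)) {
      if (init_date[i] > eof[i]) next
      if (fast[i]) {
        nd <- sample(1:2, 1L)
        dates <- init_date[i] +
          c(0, round(stats::rexp(1, rate[i] / 365.25)))[seq_len(nd)]
        dates <- dates[dates <= eof[i]]
      } else {
        dates <- .purchase_dates(init_date[i], eof[i], rate[i], config$nb_size)
      }
      if (!length(dates)) next
      np <- length(dates)

      codes <- switch(f,
        lipid = {
          start_code <- if (stats::runif(1) < config$p_simva_start)
            "C10AA01" else sample(other_statins, 1L)
          cd <- rep(start_code, np)
          if (start_code == "C10AA01" && np >= 2 &&
              stats::runif(1) < stats::plogis(config$switch_intercept +
                                              config$switch_slope * L[i])) {
            sw_at <- sample(2:np, 1L)
            cd[sw_at:np] <- sample(other_statins, 1L)
          }
          nonstatin <- stats::runif(np) < config$frac_nonstatin_lipid
          # never replace the first purchase: keeps the starter well defined
          nonstatin[1] <- FALSE
          cd[nonstatin] <- "C10AB05"
          cd
        },
        htn = {
          ng <- 1L + stats::rbinom(1, 4, stats::plogis(config$grp_intercept +
                                                       config$grp_slope * L[i]))
          grps <- sample(names(htn_codes), ng)
          # cycle through the person's groups so all appear
          htn_codes[grps[1L + (seq_len(np) - 1L) %% ng]]
        },
        t2d = {
          cd <- rep("A10BA02", np)
          if (stats::runif(1) < stats::plogis(config$secondline_intercept +
                                              config$secondline_slope * L[i]) &&
              np >= 2) {
            jj <- sample(2:np, min(np - 1L, max(1L, np %/% 3L)))
            cd[jj] <- sample(secondline_codes, length(jj), replace = TRUE)
          }
          cd
        })
      out[[k <- k + 1L]] <- data.frame(person_id = persons$person_id[i],
                                       date = dates, atc = unname(codes),
                                       stringsAsFactors = FALSE)

      # insulin progression rides on the T2D stream
      if (f == "t2d") {
        p_ins <- stats::plogis(config$insulin_intercept +
                               config$insulin_slope * L[i])
        if (stats::runif(1) < p_ins) {
          if (stats::runif(1) < config$insulin_first_frac) {
            ins_start <- max(w[1], dates[1] - round(stats::runif(1, 180, 1000)))
          } else {
            ins_start <- dates[1] + round(stats::rexp(1, 1 / (5 * 365.25))) + 1
          }
          if (ins_start <= eof[i]) {
            ins_dates <- .purchase_dates(ins_start, eof[i], rate[i],
                                         config$nb_size)
            out[[k <- k + 1L]] <- data.frame(
              person_id = persons$person_id[i], date = ins_dates,
              atc = "A10AE04", stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (k == 0L)
    return(data.frame(person_id = character(), date = as.Date(character()),
                      atc = character(), stringsAsFactors = FALSE))
  reg <- do.call(rbind, out[seq_len(k)])
  reg <- reg[reg$date >= w[1] & reg$date <= w[2], , drop = FALSE]
  reg <- reg[order(reg$person_id, reg$date, reg$atc), , drop = FALSE]
  rownames(reg) <- NULL
  reg
}

#' Simulate a full synthetic cohort
#'
#' Chains [simulate_genotypes()], [simulate_liabilities()], a person
#' table and [simulate_registry()] under one seed. The returned object
#' carries the generative truth (causal variants, effects, liabilities)
#' for parameter-recovery tests.
#'
#' @param config A [sim_config()].
#' @return List of class `medtraj_sim` with `genotypes`, `persons`
#'   (including liability columns), `registry`, `truth`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  geno <- simulate_genotypes(config)
  lia <- simulate_liabilities(geno, config)
  set.seed(config$seed + 3L)
  persons <- .simulate_persons(config)
  persons$liab_lipid <- lia$liabilities[, "lipid"]
  persons$liab_htn <- lia$liabilities[, "htn"]
  persons$liab_t2d <- lia$liabilities[, "t2d"]
  registry <- simulate_registry(persons, config)
  structure(list(genotypes = geno, persons = persons, registry = registry,
                 truth = list(causal = lia$truth, genetic = lia$genetic,
                              liabilities = lia$liabilities),
                 config = config),
            class = "medtraj_sim")
}

#' @export
print.medtraj_sim <- function(x, ...) {
  cat("Synthetic medication-use cohort\n")
  cat("  individuals:", nrow(x$persons),
      " variants:", nrow(x$genotypes$variants),
      " purchases:", nrow(x$registry), "\n")
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' Registry, persons, truth tables and the dosage matrix are written as
#' TSV under `dir`.
#'
#' @param sim A `medtraj_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wr(sim$registry, "registry.tsv")
  wr(sim$persons, "persons.tsv")
  wr(sim$genotypes$variants, "variants.tsv")
  wr(as.data.frame(sim$genotypes$dosages), "dosages.tsv")
  wr(sim$truth$causal, "truth_causal.tsv")
  invisible(dir)
}
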