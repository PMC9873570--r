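cfg_small <- function(...) sim_config(n_individuals = 500, n_variants = 60,
                                      n_causal = c(lipid = 4, htn = 4, t2d = 4),
                                      maf_range = c(0.05, 0.5), seed = 42, ...)

test_that("configuration invariants are enforced", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(h2 = c(lipid = 1.2, htn = 0.3, t2d = 0.3)), "h2")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(init_hazard = c(lipid = -1, htn = 1, t2d = 1)),
               "positive")
  expect_error(sim_config(h2 = c(lipid = 1, htn = 0, t2d = 0),
                          n_causal = c(lipid = 0, htn = 1, t2d = 1)),
               "causal")
})

test_that("genotypes are deterministic, match their MAF, and honor ld_rho = 0", {
  cfg <- cfg_small()
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$variants, g2$variants)

  # allele frequency accuracy at fixed maf: 10,000 people, sampling bound
  cfg2 <- sim_config(n_individuals = 10000, n_variants = 6,
                     maf_range = c(0.3, 0.3), ld_rho = 0, seed = 5)
  g <- simulate_genotypes(cfg2)
  expect_true(all(abs(g$variants$af_sample - 0.3) <
                    3 * sqrt(0.3 * 0.7 / (2 * 10000))))

  # independence across variants when ld_rho = 0
  cfg3 <- sim_config(n_individuals = 5000, n_variants = 12,
                     maf_range = c(0.2, 0.4), ld_rho = 0, seed = 6)
  g3 <- simulate_genotypes(cfg3)
  cc <- cor(g3$dosages)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)

  # positions strictly increasing within chromosome
  v <- g1$variants
  for (ch in unique(v$chr))
    expect_true(all(diff(v$pos[v$chr == ch]) > 0))
})

test_that("within-block LD is positive and blocks are independent", {
  cfg <- sim_config(n_individuals = 3000, n_variants = 40,
                    ld_block_size = 10, ld_rho = 0.8,
                    maf_range = c(0.2, 0.4), n_chr = 1, seed = 9)
  g <- simulate_genotypes(cfg)
  cc <- cor(g$dosages)
  b <- g$variants$block
  within <- cc[outer(b, b, "==") & upper.tri(cc)]
  across <- cc[outer(b, b, "!=") & upper.tri(cc)]
  expect_gt(mean(within), 0.3)
  expect_lt(mean(abs(across)), 0.06)
})

test_that("liability heritability is realized and truth is exported", {
  cfg <- sim_config(n_individuals = 10000, n_variants = 100,
                    n_causal = c(lipid = 20, htn = 20, t2d = 20),
                    h2 = c(lipid = 0.5, htn = 0, t2d = 0.5),
                    maf_range = c(0.1, 0.5), seed = 11)
  g <- simulate_genotypes(cfg)
  lia <- simulate_liabilities(g, cfg)

  # R^2 of liability on the true genetic score ~ h2
  r2 <- summary(lm(lia$liabilities[, "lipid"] ~ lia$genetic[, "lipid"]))$r.squared
  expect_lt(abs(r2 - 0.5), 0.03)

  # h2 = 0: liability carries no detectable genotype signal
  f <- lm(lia$liabilities[, "htn"] ~ rowSums(g$dosages))
  expect_gt(summary(f)$coefficients[2, 4], 0.001)

  expect_setequal(unique(lia$truth$factor), c("lipid", "t2d"))
  expect_true(all(lia$truth$variant %in% g$variants$id))

  # identical genotypes + same seed => identical genetic component
  lia2 <- simulate_liabilities(g, cfg)
  expect_identical(lia$genetic, lia2$genetic)
})

test_that("registry emits only Table-1 class codes, in-window dates, deterministically", {
  sim <- simulate_cohort(cfg_small())
  reg <- sim$registry
  prefixes <- c("C10", "C02", "C03", "C07", "C08", "C09", "A10B", "A10A")
  ok <- rowSums(sapply(prefixes, function(p) startsWith(reg$atc, p))) > 0
  expect_true(all(ok))
  expect_true(all(reg$date >= as.Date("1995-01-01") &
                    reg$date <= as.Date("2018-12-31")))
  sim2 <- simulate_cohort(cfg_small())
  expect_identical(sim$registry, sim2$registry)
  expect_identical(sim$truth$causal, sim2$truth$causal)

  expect_equal(nrow(simulate_registry(sim$persons[0, ], sim$config)), 0)
})

test_that("liability drives purchases up, discontinuation down, initiation earlier", {
  cfg <- sim_config(n_individuals = 20000, n_variants = 20,
                    n_causal = c(lipid = 4, htn = 4, t2d = 4),
                    maf_range = c(0.1, 0.5), seed = 13)
  sim <- simulate_cohort(cfg)
  phen <- derive_phenotypes(sim$registry, sim$persons)

  # total purchases vs discontinuation indicator: negative correlation
  use <- phen$statin_disc != "excluded"
  disc <- as.integer(phen$statin_disc[use] == "case")
  expect_lt(suppressWarnings(
    cor(phen$purchases_lipid[use], disc, method = "spearman",
        use = "complete.obs")), 0)

  # purchases and medication changes positively correlated
  users <- !is.na(phen$purchases_htn) & phen$htn_groups > 0
  expect_gt(cor(phen$purchases_htn[users], phen$htn_groups[users],
                method = "spearman"), 0)

  # top vs bottom liability decile: earlier mean initiation
  L <- sim$persons$liab_lipid
  first_lip <- aggregate(date ~ person_id,
                         data = sim$registry[startsWith(sim$registry$atc, "C10"), ],
                         FUN = min)
  m <- match(sim$persons$person_id, first_lip$person_id)
  init_year <- as.numeric(format(first_lip$date[m], "%Y"))
  dec <- cut(L, quantile(L, c(0, 0.1, 0.9, 1)), include.lowest = TRUE,
             labels = c("bottom", "mid", "top"))
  gap <- mean(init_year[dec == "bottom"], na.rm = TRUE) -
    mean(init_year[dec == "top"], na.rm = TRUE)
  expect_gt(gap, 0)
})

test_that("zero initiation slope removes the liability-initiation gradient", {
  cfg <- sim_config(n_individuals = 8000, n_variants = 20,
                    n_causal = c(lipid = 4, htn = 4, t2d = 4),
                    init_slope = 0, maf_range = c(0.1, 0.5), seed = 17)
  sim <- simulate_cohort(cfg)
  L <- sim$persons$liab_lipid
  lip <- sim$registry[startsWith(sim$registry$atc, "C10"), ]
  first_lip <- aggregate(date ~ person_id, data = lip, FUN = min)
  m <- match(sim$persons$person_id, first_lip$person_id)
  init_t <- as.numeric(first_lip$date[m])
  dec <- cut(L, quantile(L, seq(0, 1, 0.1)), include.lowest = TRUE,
             labels = FALSE)
  means <- tapply(init_t, dec, mean, na.rm = TRUE)
  # decile means stay within a Monte-Carlo band of the overall mean
  pooled_sd <- sd(init_t, na.rm = TRUE)
  n_per <- tapply(!is.na(init_t), dec, sum)
  expect_true(all(abs(means - mean(init_t, na.rm = TRUE)) <
                    4 * pooled_sd / sqrt(n_per)))
})
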