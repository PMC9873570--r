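test_that("region construction merges overlapping lead windows", {
  loci <- data.frame(locus_id = 1:2, chr = 1, start = c(10e6, 12.5e6),
                     end = c(10e6, 12.5e6), lead_id = c("a", "b"),
                     lead_pos = c(10e6, 12.5e6), lead_pval = c(1e-9, 1e-10),
                     lead_phenotype = "p", n_variants = 1)
  stats <- data.frame(id = c("a", "b"), chr = 1, pos = c(10e6, 12.5e6),
                      beta = 0.3, se = 0.05, pval = 1e-9)
  dos <- matrix(rbinom(200, 2, 0.3), 100, 2, dimnames = list(NULL, c("a", "b")))
  geno <- structure(list(dosages = dos,
                         variants = data.frame(id = c("a", "b"))),
                    class = "genotype_matrix")
  # leads at 10.0 and 12.5 Mb overlap at 11.0-11.5 Mb -> one region
  r <- build_regions(loci, stats, geno)
  expect_length(r, 1L)
  expect_equal(r[[1]]$start, 8.5e6)
  expect_equal(r[[1]]$end, 14e6)

  # leads 4 Mb apart -> two regions
  loci2 <- loci; loci2$lead_pos <- c(10e6, 14e6)
  expect_length(build_regions(loci2, stats, geno), 2L)

  # single lead near the chromosome start is clipped at 1
  loci3 <- loci[1, ]; loci3$lead_pos <- 5e5
  r3 <- build_regions(loci3, stats, geno)
  expect_equal(r3[[1]]$start, 1)
  expect_equal(r3[[1]]$end, 2e6)

  # sub-threshold leads are not fine-mapped
  loci4 <- loci; loci4$lead_pval <- c(1e-7, 1e-7)
  expect_length(build_regions(loci4, stats, geno), 0L)
})

test_that("Wakefield log ABF matches the closed form and its limits", {
  # z = 5, se = 0.1, W = 0.04: 0.5 ln(0.2) + 12.5 * 0.8 = 9.195
  expect_equal(wakefield_abf(0.5, 0.1, 0.04),
               0.5 * log(0.2) + 12.5 * (0.04 / 0.05), tolerance = 1e-12)
  expect_equal(wakefield_abf(0.5, 0.1, 0.04), 9.195, tolerance = 1e-3)
  # z = 0: ABF < 1 (evidence for the null)
  expect_lt(wakefield_abf(0, 0.1, 0.04, log = FALSE), 1)
  # W -> 0: ABF -> 1 for any z
  expect_equal(wakefield_abf(0.8, 0.1, 1e-12, log = FALSE), 1,
               tolerance = 1e-6)
  expect_error(wakefield_abf(0.1, -1, 0.04), "positive")
  expect_error(wakefield_abf(0.1, 0.1, 0), "positive")
  # huge z does not overflow in log space
  expect_true(is.finite(wakefield_abf(10, 0.01, 0.04)))
})

test_that("single-signal credible set normalizes, orders and filters by purity", {
  rs <- simulate_region(n = 1000, m = 25, rho = 0.85, b = 0.5, seed = 3)
  cs <- credible_set(rs$region)
  expect_equal(sum(cs$variants$posterior), cs$coverage, tolerance = 1e-12)
  expect_equal(cs$variants$cumulative,
               cumsum(cs$variants$posterior), tolerance = 1e-12)
  expect_gte(cs$coverage, 0.95)
  expect_true(all(diff(cs$variants$posterior) <= 1e-12))
  expect_true(cs$purity >= 0 && cs$purity <= 1)
  # causal variant is the top or among the set in a high-LD block
  expect_true(rs$region$stats$id[rs$causal] %in% cs$variants$id)

  # two identical z in perfect LD: both enter, position breaks the tie
  st <- data.frame(id = c("v2", "v1"), chr = 1, pos = c(2000, 1000),
                   beta = c(0.5, 0.5), se = 0.1)
  reg <- list(chr = 1, start = 1, end = 3000, stats = st,
              ld = matrix(1, 2, 2))
  cs2 <- credible_set(reg)
  expect_equal(cs2$variants$id, c("v1", "v2"))  # tie -> ascending position
  expect_equal(cs2$purity, 1)

  # flat region: posteriors equal, set flagged low resolution
  stf <- data.frame(id = paste0("f", 1:20), chr = 1, pos = 1:20 * 100,
                    beta = 0, se = 0.1)
  regf <- list(chr = 1, start = 1, end = 2100, stats = stf,
               ld = diag(20))
  csf <- credible_set(regf)
  expect_true(csf$low_resolution)
  expect_equal(nrow(csf$variants), 19)  # ceil(0.95 * 20)
})

test_that("reporting rule trims listings of large sets to posterior >= 0.01", {
  st <- data.frame(id = paste0("v", 1:36), chr = 1, pos = 1:36 * 100,
                   beta = c(0.5, rep(0.42, 5), rep(0.33, 30)), se = 0.1)
  reg <- list(chr = 1, start = 1, end = 3700, stats = st,
              ld = matrix(0.9, 36, 36))
  cs <- credible_set(reg)
  expect_gt(nrow(cs$variants), 10)
  expect_true(all(cs$variants$posterior[cs$variants$reported] >= 0.01))
  expect_true(any(!cs$variants$reported))
})

test_that("multi-signal fit reduces to one set at L = 1 and finds two planted signals", {
  rs <- simulate_region(n = 1500, m = 20, rho = 0.7, b = 0.5, seed = 5)
  s1 <- multi_signal_sets(rs$region, L = 1)
  cs <- credible_set(rs$region)
  expect_length(s1, 1L)
  expect_equal(s1[[1]]$variants$id, cs$variants$id)
  expect_equal(s1[[1]]$variants$posterior, cs$variants$posterior,
               tolerance = 1e-10)

  # null region -> zero sets
  stf <- data.frame(id = paste0("n", 1:15), chr = 1, pos = 1:15 * 100,
                    beta = rnorm(15, 0, 0.01), se = 0.1)
  regn <- list(chr = 1, start = 1, end = 1600, stats = stf, ld = diag(15))
  expect_length(multi_signal_sets(regn), 0L)

  # two independent planted signals in two LD blocks
  set.seed(6)
  n <- 2000
  mk_block <- function(m, rho) {
    z0 <- rnorm(n)
    d <- matrix(0L, n, m)
    for (h in 1:2) {
      z <- sqrt(rho) * rnorm(n) + sqrt(1 - rho) * matrix(rnorm(n * m), n, m)
      d <- d + (z < qnorm(0.3))
    }
    d
  }
  hits <- 0L
  for (rep in 1:10) {
    d1 <- mk_block(10, 0.7); d2 <- mk_block(10, 0.7)
    dos <- cbind(d1, d2)
    colnames(dos) <- sprintf("1:%d:A:G", 1:20 * 1000)
    c1 <- 3L; c2 <- 14L
    y <- 0.45 * dos[, c1] + 0.45 * dos[, c2] + rnorm(n)
    beta <- se <- numeric(20)
    for (j in 1:20) {
      f <- .lm.fit(cbind(1, dos[, j]), y)
      rss <- sum(f$residuals^2)
      gss <- sum((dos[, j] - mean(dos[, j]))^2)
      beta[j] <- f$coefficients[2]
      se[j] <- sqrt(rss / (n - 2) / gss)
    }
    st <- data.frame(id = colnames(dos), chr = 1, pos = 1:20 * 1000,
                     beta = beta, se = se)
    ld <- suppressWarnings(cor(dos)); ld[is.na(ld)] <- 0; diag(ld) <- 1
    reg <- list(chr = 1, start = 1, end = 21000, stats = st, ld = ld)
    sets <- multi_signal_sets(reg, L = 5)
    ids <- lapply(sets, function(s) s$variants$id)
    found1 <- any(vapply(ids, function(v) st$id[c1] %in% v, logical(1)))
    found2 <- any(vapply(ids, function(v) st$id[c2] %in% v, logical(1)))
    if (length(sets) == 2L && found1 && found2) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("enrichment flag orients to the minor allele", {
  e1 <- flag_enrichment(0.04, 0.01)
  expect_equal(e1$fold, 4)
  expect_true(e1$enriched)
  e2 <- flag_enrichment(0.3, 0.3)
  expect_false(e2$enriched)
  # af 0.96 -> minor allele 0.04 against reference minor 0.01 (0.99 major)
  e3 <- flag_enrichment(0.96, 0.99)
  expect_equal(e3$fold, 4, tolerance = 1e-12)
  expect_true(e3$enriched)
  e4 <- flag_enrichment(0.04, 0)
  expect_true(is.infinite(e4$fold) && e4$enriched)
})
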