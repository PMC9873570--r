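#' Build fine-mapping regions around genome-wide significant leads
#'
#' Places a window of `±window` bp around each locus lead whose P value
#' passes `p_gws`, merges overlapping windows on the same chromosome
#' into one region, and attaches the member variants' association
#' statistics and their pairwise dosage correlation (LD) matrix.
#'
#' @param loci Loci table from [define_loci()].
#' @param stats `assoc_stats` for all variants of the scanned phenotype.
#' @param genotypes `genotype_matrix` (source of the LD matrix).
#' @param window Half-width in bp (default 1.5e6, i.e. 3 Mb regions).
#' @param p_gws Lead threshold for fine-mapping (default 5e-8).
#' @return List of regions, each a list with `chr`, `start`, `end`,
#'   `stats` (member `assoc_stats`), `ld` (correlation matrix).
#' @export
build_regions <- function(loci, stats, genotypes, window = 1.5e6,
                          p_gws = 5e-8) {
  keep <- loci$lead_pval < p_gws
  loci <- loci[keep, , drop = FALSE]
  if (nrow(loci) == 0L) return(list())
  iv <- data.frame(chr = loci$chr,
                   start = pmax(loci$lead_pos - window, 1),
                   end = loci$lead_pos + window)
  iv <- iv[order(iv$chr, iv$start), ]
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1L) for (i in 2:nrow(iv)) {
    last <- nrow(merged)
    if (iv$chr[i] == merged$chr[last] && iv$start[i] <= merged$end[last]) {
      merged$end[last] <- max(merged$end[last], iv$end[i])
    } else merged <- rbind(merged, iv[i, ])
  }
  lapply(seq_len(nrow(merged)), function(i) {
    sel <- stats$chr == merged$chr[i] &
      stats$pos >= merged$start[i] & stats$pos <= merged$end[i]
    st <- stats[sel, , drop = FALSE]
    st <- st[order(st$pos), ]
    dos <- genotypes$dosages[, st$id, drop = FALSE]
    ld <- suppressWarnings(stats::cor(dos))
    ld[is.na(ld)] <- 0
    diag(ld) <- 1
    list(chr = merged$chr[i], start = merged$start[i], end = merged$end[i],
         stats = st, ld = ld)
  })
}

#' Wakefield approximate Bayes factor
#'
#' `ABF = sqrt(se^2 / (se^2 + W)) * exp(z^2 W / (2 (se^2 + W)))` with
#' `z = beta/se`, comparing a normal prior of variance `W` on the effect
#' against the point null. Computed and returned in log space for
#' overflow safety; values above 1 (log above 0) favor a non-zero
#' effect.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), positive.
#' @param W Prior effect variance (default 0.04, prior SD 0.2).
#' @param log Return the natural log (default TRUE).
#' @return Numeric vector of (log) approximate Bayes factors.
#' @examples
#' wakefield_abf(0.5, 0.1, W = 0.04) # log ABF ~ 9.195
#' @export
wakefield_abf <- function(beta, se, W = 0.04, log = TRUE) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(W <= 0)) stop("prior variance W must be positive")
  z <- beta / se
  labf <- 0.5 * base::log(se^2 / (se^2 + W)) +
    z^2 / 2 * W / (se^2 + W)
  if (log) labf else exp(labf)
}

.logsumexp <- function(x) {
  m <- max(x)
  m + base::log(sum(exp(x - m)))
}

# Minimum absolute pairwise LD among a credible set's members.
.purity <- function(ld, idx) {
  if (length(idx) <= 1L) return(1)
  sub <- abs(ld[idx, idx])
  min(sub[lower.tri(sub)])
}

.make_cs <- function(st, alpha, ld, coverage, purity_min, W, signal = 1L) {
  ord <- order(-alpha, st$pos)
  cum <- cumsum(alpha[ord])
  size <- which(cum >= coverage)[1L]
  if (is.na(size)) size <- length(ord)
  idx <- ord[seq_len(size)]
  vars <- data.frame(id = st$id[idx], pos = st$pos[idx],
                     posterior = alpha[idx], cumulative = cum[seq_len(size)],
                     stringsAsFactors = FALSE)
  vars$reported <- if (nrow(vars) > 10L) vars$posterior >= 0.01 else TRUE
  pur <- .purity(ld, idx)
  structure(list(signal = signal, variants = vars,
                 coverage = cum[size], purity = pur,
                 pass_purity = pur >= purity_min,
                 lead = st$id[ord[1L]],
                 low_resolution = length(unique(round(alpha, 12))) == 1L,
                 W = W),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("95%% credible set (signal %d): %d variants, coverage %.3f, purity %.2f%s\n",
              x$signal, nrow(x$variants), x$coverage, x$purity,
              if (x$pass_purity) "" else " [fails purity]"))
  invisible(x)
}

#' Single-signal 95% credible set
#'
#' Computes per-variant approximate Bayes factors, normalizes them over
#' the region under a uniform causal prior, and takes the smallest set
#' of variants (sorted by posterior, ties broken by position) whose
#' cumulative posterior reaches `coverage`. The set's purity is the
#' minimum absolute pairwise LD among its members; sets below
#' `purity_min` are marked as failing the purity filter. For sets over
#' ten variants the emitted listing flags only variants with posterior
#' at least 0.01 (`reported` column); the full set is retained.
#'
#' @param region A region from [build_regions()].
#' @param coverage Target cumulative posterior (default 0.95).
#' @param W Prior effect variance (default 0.04).
#' @param purity_min Minimum absolute pairwise correlation (default 0.5,
#'   i.e. r^2 >= 0.25).
#' @return A `credible_set` object.
#' @export
credible_set <- function(region, coverage = 0.95, W = 0.04,
                         purity_min = 0.5) {
  st <- region$stats
  labf <- wakefield_abf(st$beta, st$se, W)
  alpha <- exp(labf - .logsumexp(labf))
  .make_cs(st, alpha, region$ld, coverage, purity_min, W)
}

#' Multi-signal credible sets by iterative single-effect regression
#'
#' Fits up to `L` single effects to the region's z-scores: each effect
#' is a Bayesian single-effect regression on the residual z-scores after
#' regressing out (through the LD matrix) the posterior-mean
#' contributions of the other effects, cycled until the maximum change
#' in any posterior falls below `tol`. Effects whose average Bayes
#' factor does not beat the null (effect log BF <= 0) are dropped.
#' Surviving effects yield one credible set each, subject to the same
#' coverage and purity rules as [credible_set()].
#'
#' @inheritParams credible_set
#' @param L Maximum number of signals (default 5).
#' @param tol Convergence tolerance on posterior change (default 1e-3).
#' @param max_iter Iteration cap (default 100).
#' @param keep_failing_purity Keep sets failing the purity filter
#'   (default FALSE).
#' @return List of `credible_set` objects (possibly empty).
#' @export
multi_signal_sets <- function(region, L = 5L, W = 0.04, coverage = 0.95,
                              purity_min = 0.5, tol = 1e-3,
                              max_iter = 100L,
                              keep_failing_purity = FALSE) {
  stopifnot(L >= 1L)
  st <- region$stats
  p <- nrow(st)
  if (p == 0L) return(list())
  z <- st$beta / st$se
  R <- (region$ld + t(region$ld)) / 2
  omega <- W / st$se^2          # prior effect variance on the z scale

  alpha <- matrix(1 / p, L, p)
  mu <- matrix(0, L, p)
  lbf_eff <- rep(-Inf, L)
  for (iter in seq_len(max_iter)) {
    max_delta <- 0
    for (l in seq_len(L)) {
      other <- colSums((alpha * mu)[-l, , drop = FALSE])
      r <- z - as.numeric(R %*% other)
      labf <- 0.5 * base::log(1 / (1 + omega)) +
        r^2 / 2 * omega / (1 + omega)
      a_new <- exp(labf - .logsumexp(labf))
      max_delta <- max(max_delta, max(abs(a_new - alpha[l, ])))
      alpha[l, ] <- a_new
      mu[l, ] <- r * omega / (1 + omega)
      lbf_eff[l] <- .logsumexp(labf) - base::log(p)
    }
    if (max_delta < tol) break
  }
  keep <- which(lbf_eff > 0)
  sets <- lapply(seq_along(keep), function(i) {
    .make_cs(st, alpha[keep[i], ], region$ld, coverage, purity_min, W,
             signal = i)
  })
  if (!keep_failing_purity)
    sets <- Filter(function(cs) cs$pass_purity, sets)
  # de-duplicate effects that converged onto the same lead variant
  if (length(sets) > 1L) {
    leads <- vapply(sets, `[[`, character(1), "lead")
    sets <- sets[!duplicated(leads)]
  }
  sets
}

#' Flag Finnish-style allele-frequency enrichment
#'
#' Orients both frequencies to the sample's minor allele, computes the
#' enrichment fold `maf_sample / maf_reference`, and flags variants
#' whose fold exceeds `fold` (default 2). A zero reference frequency
#' yields an infinite fold and a flag.
#'
#' @param af_fin Sample (e.g. Finnish) allele frequency in [0, 1].
#' @param af_ref Reference-population frequency of the same allele.
#' @param fold Enrichment threshold (default 2).
#' @return Data frame `maf_fin`, `maf_ref`, `fold`, `enriched`.
#' @export
flag_enrichment <- function(af_fin, af_ref, fold = 2) {
  stopifnot(all(af_fin >= 0 & af_fin <= 1), all(af_ref >= 0 & af_ref <= 1))
  flip <- af_fin > 0.5
  maf_fin <- ifelse(flip, 1 - af_fin, af_fin)
  maf_ref <- ifelse(flip, 1 - af_ref, af_ref)
  f <- ifelse(maf_ref == 0, Inf, maf_fin / maf_ref)
  data.frame(maf_fin = maf_fin, maf_ref = maf_ref, fold = f,
             enriched = f > fold)
}
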