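#' Rank-based inverse normal transformation
#'
#' Maps values to standard normal quantiles through their ranks:
#' `qnorm((rank - c) / (n - 2c + 1))` with the Blom offset `c = 3/8` by
#' default. Ties receive the average rank, so tied observations map to
#' the same quantile.
#'
#' @param values Numeric vector (at least two finite values).
#' @param offset Rank offset `c` (default 3/8).
#' @return Transformed numeric vector (NA preserved).
#' @examples
#' inverse_normal_transform(c(1, 2, 3))
#' @export
inverse_normal_transform <- function(values, offset = 3/8) {
  ok <- is.finite(values)
  if (sum(ok) < 2L) stop("need at least two finite values")
  x <- values[ok]
  if (max(x) == min(x)) stop("all values identical; transform undefined")
  n <- length(x)
  r <- rank(x, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

# Pool genotyping batches with fewer than `min_count` cases or controls
# into the reference level; for quantitative outcomes the threshold is on
# the total batch size.
#' Pool small genotyping batches
#'
#' Batch indicators are only informative when a batch holds enough cases
#' and controls; smaller batches are collapsed into the reference level.
#'
#' @param batch Factor or character vector of batch labels.
#' @param outcome Outcome vector; when binary (two levels), each retained
#'   batch needs `min_count` observations in both classes.
#' @param min_count Minimum per-class (or total) count (default 10).
#' @return Factor with small batches set to "pooled".
#' @export
pool_small_batches <- function(batch, outcome, min_count = 10) {
  batch <- as.character(batch)
  binary <- length(unique(stats::na.omit(outcome))) == 2L
  keep <- vapply(unique(batch), function(b) {
    o <- outcome[batch == b]
    if (binary) min(table(factor(o, levels = unique(stats::na.omit(outcome))))) >= min_count
    else length(o) >= min_count
  }, logical(1))
  batch[!batch %in% names(keep)[keep]] <- "pooled"
  factor(batch)
}

.covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1,
                                         dimnames = list(NULL, "intercept")))
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  X
}

.geno_parts <- function(genotypes) {
  if (inherits(genotypes, "genotype_matrix"))
    list(dos = genotypes$dosages, variants = genotypes$variants)
  else if (is.matrix(genotypes))
    list(dos = genotypes,
         variants = data.frame(id = colnames(genotypes) %||%
                                 paste0("v", seq_len(ncol(genotypes)))))
  else stop("genotypes must be a genotype_matrix or a dosage matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-variant association scan
#'
#' Fits, for every variant, `outcome ~ dosage + covariates`: linear
#' regression on the inverse-normal transformed outcome for quantitative
#' phenotypes, logistic regression for binary ones. Returns Wald effect
#' estimates, standard errors, z and two-sided normal-approximation P
#' values. Monomorphic variants and variants below the minor-allele
#' frequency thresholds are omitted with a reason; for quantitative
#' scans the MAF < 0.005 filter guards against rare-variant artefacts of
#' the rank transformation, while binary scans apply only the global
#' 1e-4 floor.
#'
#' @param genotypes `genotype_matrix` or dosage matrix (columns named by
#'   variant id).
#' @param phenotype Numeric outcome; for `family = "logistic"` it must be
#'   0/1 (or a case/control/excluded status factor, excluded set to NA).
#' @param covariates Optional data frame of covariates.
#' @param family `"linear"` or `"logistic"`.
#' @param int Apply [inverse_normal_transform()] first (linear only;
#'   default TRUE).
#' @param maf_min Quantitative-scan MAF threshold (default 0.005).
#' @param maf_floor Global MAF sanity floor (default 1e-4).
#' @return Data frame of class `assoc_stats` with columns `id`, `chr`,
#'   `pos`, `ref`, `alt`, `effect_allele`, `af`, `beta`, `se`, `z`,
#'   `pval`, `n` (and `n_cases`, `n_controls` for logistic). Variants
#'   omitted by a filter are recorded in `attr(, "dropped")`.
#' @export
run_scan <- function(genotypes, phenotype, covariates = NULL,
                     family = c("linear", "logistic"), int = TRUE,
                     maf_min = 0.005, maf_floor = 1e-4) {
  family <- match.arg(family)
  gp <- .geno_parts(genotypes)
  y <- phenotype
  if (is.factor(y)) {
    y <- c(case = 1, control = 0, excluded = NA)[as.character(y)]
  }
  keep_i <- !is.na(y)
  if (!is.null(covariates))
    keep_i <- keep_i & stats::complete.cases(as.data.frame(covariates))
  y <- y[keep_i]
  G <- gp$dos[keep_i, , drop = FALSE]
  covariates <- if (is.null(covariates)) NULL else
    as.data.frame(covariates)[keep_i, , drop = FALSE]
  n <- length(y)

  af <- colMeans(G) / 2
  maf <- pmin(af, 1 - af)
  v <- apply(G, 2, stats::var)
  reason <- rep(NA_character_, ncol(G))
  reason[v == 0] <- "monomorphic"
  reason[is.na(reason) & maf < maf_floor] <- "maf_below_floor"
  if (family == "linear")
    reason[is.na(reason) & maf < maf_min] <- "maf_below_quant_threshold"

  if (family == "linear") {
    if (int) y <- inverse_normal_transform(y)
    X <- .covariate_matrix(covariates, n)
    qrX <- qr(X)
    yres <- qr.resid(qrX, y)
    Gres <- qr.resid(qrX, G)
    gss <- colSums(Gres^2)
    beta <- colSums(Gres * yres) / gss
    rss <- sum(yres^2) - beta^2 * gss
    df <- n - ncol(X) - 1L
    se <- sqrt(rss / df / gss)
    ncase <- ncontrol <- NULL
  } else {
    if (!all(y %in% c(0, 1))) stop("logistic family needs a 0/1 outcome")
    X <- .covariate_matrix(covariates, n)
    beta <- se <- rep(NA_real_, ncol(G))
    for (j in which(is.na(reason))) {
      fit <- tryCatch(
        suppressWarnings(stats::glm.fit(cbind(X, g = G[, j]), y,
                                        family = stats::binomial())),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        reason[j] <- "nonconvergence"; next
      }
      cf <- fit$coefficients["g"]
      # Wald se from the final IRLS weights
      W <- fit$weights
      XtWX <- crossprod(cbind(X, g = G[, j]) * sqrt(W))
      cov <- tryCatch(solve(XtWX), error = function(e) NULL)
      if (is.null(cov)) { reason[j] <- "singular_fit"; next }
      s <- sqrt(cov["g", "g"])
      if (!is.finite(cf) || !is.finite(s) || abs(cf) > 15 || s > 100) {
        reason[j] <- "separation"; next
      }
      beta[j] <- cf; se[j] <- s
    }
    ncase <- sum(y == 1); ncontrol <- sum(y == 0)
  }

  ok <- is.na(reason)
  vt <- gp$variants
  out <- data.frame(id = vt$id[ok],
                    chr = if ("chr" %in% names(vt)) vt$chr[ok] else 1L,
                    pos = if ("pos" %in% names(vt)) vt$pos[ok] else
                      which(ok),
                    ref = if ("ref" %in% names(vt)) vt$ref[ok] else "N",
                    alt = if ("alt" %in% names(vt)) vt$alt[ok] else "N",
                    effect_allele = if ("alt" %in% names(vt)) vt$alt[ok] else "N",
                    af = af[ok], beta = beta[ok], se = se[ok],
                    stringsAsFactors = FALSE)
  out$z <- out$beta / out$se
  out$pval <- 2 * stats::pnorm(-abs(out$z))
  out$n <- n
  if (family == "logistic") {
    out$n_cases <- ncase; out$n_controls <- ncontrol
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(id = vt$id[!ok],
                                     reason = reason[!ok],
                                     stringsAsFactors = FALSE)
  class(out) <- c("assoc_stats", class(out))
  out
}

#' Merge genome-wide significant variants into loci
#'
#' Takes every variant with `pval < p_gws` in any analysis and merges
#' significant variants lying within `window` base pairs of each other
#' (transitive closure along the chromosome) into one locus. The locus
#' lead is the variant with the smallest P over all analyses; ties are
#' broken by phenotype name and then position for a deterministic result.
#'
#' @param stats `assoc_stats` data frame (rows may cover several
#'   phenotypes; include a `phenotype` column to track the leading
#'   analysis).
#' @param p_gws Significance threshold (default 5e-8).
#' @param window Merge distance in bp (default 1.5e6).
#' @return Data frame of loci: `locus_id`, `chr`, `start`, `end`,
#'   `lead_id`, `lead_pos`, `lead_pval`, `lead_phenotype`, `n_variants`;
#'   member variant ids are kept in `attr(, "members")`.
#' @export
define_loci <- function(stats, p_gws = 5e-8, window = 1.5e6) {
  if (!"phenotype" %in% names(stats)) stats$phenotype <- "trait"
  sig <- stats[stats$pval < p_gws, , drop = FALSE]
  if (nrow(sig) == 0L) {
    out <- data.frame(locus_id = integer(), chr = integer(),
                      start = integer(), end = integer(),
                      lead_id = character(), lead_pos = integer(),
                      lead_pval = numeric(), lead_phenotype = character(),
                      n_variants = integer())
    attr(out, "members") <- data.frame(locus_id = integer(),
                                       id = character())
    return(out)
  }
  # collapse to unique positions keeping each variant's best analysis
  sig <- sig[order(sig$pval, sig$phenotype, sig$pos), ]
  best <- sig[!duplicated(sig$id), ]
  best <- best[order(best$chr, best$pos), ]
  newloc <- c(TRUE, diff(best$pos) > window | diff(as.integer(
    factor(best$chr))) != 0)
  locus <- cumsum(newloc)

  rows <- lapply(split(seq_len(nrow(best)), locus), function(i) {
    b <- best[i, ]
    lead <- b[order(b$pval, b$phenotype, b$pos)[1L], ]
    data.frame(chr = lead$chr, start = min(b$pos), end = max(b$pos),
               lead_id = lead$id, lead_pos = lead$pos,
               lead_pval = lead$pval, lead_phenotype = lead$phenotype,
               n_variants = nrow(b), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chr, out$start), ]
  out <- cbind(locus_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  members <- data.frame(locus_id = locus[order(best$chr, best$pos)],
                        id = best$id, stringsAsFactors = FALSE)
  members$locus_id <- match(members$locus_id, unique(members$locus_id))
  attr(out, "members") <- members
  out
}

#' Genotype-by-modifier interaction scan
#'
#' For each lead variant, refits the association model with the modifier
#' dichotomized at its sample median (`dummy = modifier > median`) and a
#' `dosage x dummy` interaction term, keeping the continuous modifier and
#' all original covariates as main effects. Reports the Wald P of the
#' interaction coefficient and a Bonferroni flag at `0.05 / n_variants`.
#'
#' @param genotypes Dosage matrix restricted to the lead variants.
#' @param phenotype Outcome (INT-transformed counts or 0/1).
#' @param covariates Data frame of covariates; must contain the modifier
#'   column.
#' @param modifier Name of the covariate to dichotomize (e.g. `"age"`).
#' @param family `"linear"` or `"logistic"`.
#' @param alpha Family-wise level before Bonferroni division.
#' @return Data frame `id`, `beta_int`, `se_int`, `pval_int`,
#'   `significant`.
#' @export
interaction_scan <- function(genotypes, phenotype, covariates, modifier,
                             family = c("linear", "logistic"),
                             alpha = 0.05) {
  family <- match.arg(family)
  gp <- .geno_parts(genotypes)
  covariates <- as.data.frame(covariates)
  if (!modifier %in% names(covariates))
    stop("modifier '", modifier, "' not among covariates")
  mod <- covariates[[modifier]]
  med <- stats::median(mod, na.rm = TRUE)
  dummy <- as.numeric(mod > med)
  if (length(unique(dummy)) < 2L)
    stop("median split of '", modifier, "' produces an empty stratum")

  m <- ncol(gp$dos)
  thr <- alpha / m
  res <- data.frame(id = gp$variants$id, beta_int = NA_real_,
                    se_int = NA_real_, pval_int = NA_real_,
                    stringsAsFactors = FALSE)
  dat0 <- cbind(data.frame(.y = phenotype, .dummy = dummy), covariates)
  for (j in seq_len(m)) {
    dat0$.g <- gp$dos[, j]
    fit <- if (family == "linear")
      stats::lm(.y ~ . + .g:.dummy, data = dat0)
    else
      suppressWarnings(stats::glm(.y ~ . + .g:.dummy, data = dat0,
                                  family = stats::binomial()))
    cf <- summary(fit)$coefficients
    row <- grep("^\\.g:\\.dummy$|^\\.dummy:\\.g$", rownames(cf))
    if (length(row) == 1L) {
      res$beta_int[j] <- cf[row, 1]
      res$se_int[j] <- cf[row, 2]
      res$pval_int[j] <- 2 * stats::pnorm(-abs(cf[row, 1] / cf[row, 2]))
    }
  }
  res$significant <- !is.na(res$pval_int) & res$pval_int < thr
  attr(res, "threshold") <- thr
  res
}

#' Benjamini-Hochberg adjusted P values
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]).
#'
#' @param p Vector of P values in (0, 1].
#' @return Adjusted P values in the input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.na(p) & (p <= 0 | p > 1))) stop("p values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}
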