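#' Weighted-sum polygenic score
#'
#' `score = sum_j beta_j * dosage_j(effect allele)`. Weights whose
#' effect allele is the variant's reference allele contribute through
#' the reflected dosage `2 - dosage`.
#'
#' @param genotypes `genotype_matrix` (or dosage matrix whose columns
#'   are variant ids; then every effect allele is taken as counted).
#' @param weights Data frame `id`, `effect_allele`, `beta`.
#' @param on_missing `"error"` (default) or `"drop"` for weights whose
#'   variant is absent from the genotypes.
#' @return Numeric score per person.
#' @export
prs_score <- function(genotypes, weights, on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  gp <- .geno_parts(genotypes)
  stopifnot(all(c("id", "beta") %in% names(weights)))
  if (any(!is.finite(weights$beta))) stop("weights must be finite")
  m <- match(weights$id, colnames(gp$dos))
  if (anyNA(m)) {
    if (on_missing == "error")
      stop("weights refer to variants absent from the genotypes: ",
           paste(utils::head(weights$id[is.na(m)], 5L), collapse = ", "))
    weights <- weights[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  if (nrow(weights) == 0L) return(rep(0, nrow(gp$dos)))
  D <- gp$dos[, m, drop = FALSE]
  if ("effect_allele" %in% names(weights) && "alt" %in% names(gp$variants)) {
    vm <- match(weights$id, gp$variants$id)
    ea <- weights$effect_allele
    is_alt <- ea == gp$variants$alt[vm]
    is_ref <- ea == gp$variants$ref[vm]
    if (any(!is_alt & !is_ref))
      stop("effect allele not resolvable for: ",
           paste(weights$id[!is_alt & !is_ref], collapse = ", "))
    D[, is_ref] <- 2 - D[, is_ref, drop = FALSE]
  }
  as.numeric(D %*% weights$beta)
}

.is_binary <- function(y) all(stats::na.omit(y) %in% c(0, 1))

.fit_family <- function(y) if (.is_binary(y)) stats::binomial() else
  stats::gaussian()

# coefficient, 95% CI and separation flag for one model term
.term_ci <- function(fit, term, logistic) {
  cf <- summary(fit)$coefficients
  if (!term %in% rownames(cf))
    return(data.frame(estimate = NA, lo = NA, hi = NA, separated = TRUE))
  b <- cf[term, 1]; s <- cf[term, 2]
  sep <- !is.finite(b) || !is.finite(s) || abs(b) > 15 || s > 100
  est <- c(b, b - 1.96 * s, b + 1.96 * s)
  if (logistic) est <- exp(est)
  data.frame(estimate = est[1], lo = est[2], hi = est[3], separated = sep)
}

#' Quantile-bin association of a polygenic score with an outcome
#'
#' Splits scores into quantile bins, regresses the outcome on the bin
#' factor plus covariates (linear for quantitative outcomes, logistic
#' for binary), and reports each bin's estimate against the reference
#' bin with a 95% CI, plus the two standard contrasts: top versus
#' bottom decile, and top 1% versus the middle quintile (40-60%).
#'
#' @param scores Numeric polygenic scores.
#' @param outcome Outcome vector (0/1 for logistic).
#' @param covariates Optional covariate data frame.
#' @param bins Number of quantile bins for the per-bin profile
#'   (default 10).
#' @param reference Reference bin index (default 1, the bottom bin).
#' @return List with `bin_estimates` (per-bin estimate/CI),
#'   `top_vs_bottom` and `top1_vs_mid` contrast rows (odds ratios for
#'   binary outcomes), and `family`.
#' @export
quantile_association <- function(scores, outcome, covariates = NULL,
                                 bins = 10, reference = 1) {
  fam <- .fit_family(outcome)
  logistic <- fam$family == "binomial"
  qs <- stats::quantile(scores, probs = seq(0, 1, length.out = bins + 1))
  bin <- cut(scores, unique(qs), include.lowest = TRUE, labels = FALSE)
  bin <- stats::relevel(factor(bin), ref = as.character(reference))

  dat <- data.frame(.y = outcome, .bin = bin)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  fit <- suppressWarnings(stats::glm(.y ~ ., data = dat, family = fam))
  ests <- do.call(rbind, lapply(setdiff(levels(bin), as.character(reference)),
    function(b) cbind(bin = as.integer(b),
                      .term_ci(fit, paste0(".bin", b), logistic))))
  ref_row <- data.frame(bin = reference, estimate = if (logistic) 1 else 0,
                        lo = NA, hi = NA, separated = FALSE)
  ests <- rbind(ref_row, ests)
  ests <- ests[order(ests$bin), ]
  rownames(ests) <- NULL

  contrast <- function(sel_hi, sel_lo) {
    use <- sel_hi | sel_lo
    dat2 <- data.frame(.y = outcome[use], .g = as.numeric(sel_hi[use]))
    if (!is.null(covariates))
      dat2 <- cbind(dat2, as.data.frame(covariates)[use, , drop = FALSE])
    f2 <- suppressWarnings(stats::glm(.y ~ ., data = dat2, family = fam))
    .term_ci(f2, ".g", logistic)
  }
  dec <- .score_quantile_group(scores, 10)
  pct <- .score_quantile_group(scores, 100)
  top_bottom <- contrast(dec == 10, dec == 1)
  top1_mid <- contrast(pct == 100, pct > 40 & pct <= 60)
  list(bin_estimates = ests, top_vs_bottom = top_bottom,
       top1_vs_mid = top1_mid,
       family = fam$family)
}

.score_quantile_group <- function(scores, k) {
  qs <- unique(stats::quantile(scores, probs = seq(0, 1, length.out = k + 1)))
  cut(scores, qs, include.lowest = TRUE, labels = FALSE) *
    (k / (length(qs) - 1))
}

#' Nagelkerke pseudo-R-squared
#'
#' `R2 = (1 - exp(2 (l0 - l1) / n)) / (1 - exp(2 l0 / n))`, the
#' Cox-Snell ratio rescaled to a 0-1 range, from the log-likelihoods of
#' a null and a nesting model.
#'
#' @param ll0 Log-likelihood of the null model.
#' @param ll1 Log-likelihood of the full model (must be >= `ll0`).
#' @param n Sample size.
#' @return Pseudo-R-squared in [0, 1].
#' @export
nagelkerke_r2 <- function(ll0, ll1, n) {
  if (ll1 < ll0 - 1e-8)
    stop("full-model log-likelihood below the null; models are not nested")
  (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
}

#' Davidson-MacKinnon J-test of two non-nested score models
#'
#' Fits the outcome on each score (plus covariates), then inserts each
#' model's fitted values as an extra regressor into the rival model and
#' reports the Wald P of that coefficient. A small P for
#' `p_A_given_B` means model A's specification is rejected in favor of
#' information carried by B.
#'
#' @param outcome Outcome vector.
#' @param covariates Optional covariate data frame.
#' @param scoreA,scoreB The two competing scores.
#' @return List `p_A_given_B`, `p_B_given_A`.
#' @export
j_test <- function(outcome, covariates = NULL, scoreA, scoreB) {
  if (stats::sd(scoreA) == 0 || stats::sd(scoreB) == 0 ||
      abs(stats::cor(scoreA, scoreB)) > 1 - 1e-10)
    stop("scores are collinear; the J-test is undefined")
  fam <- .fit_family(outcome)
  base_dat <- if (is.null(covariates)) data.frame(.y = outcome) else
    cbind(data.frame(.y = outcome), as.data.frame(covariates))
  fit_on <- function(score, extra = NULL) {
    d <- cbind(base_dat, .s = score)
    if (!is.null(extra)) d$.f <- extra
    suppressWarnings(stats::glm(.y ~ ., data = d, family = fam))
  }
  fitA <- fit_on(scoreA); fitB <- fit_on(scoreB)
  pval_of <- function(fit) {
    cf <- summary(fit)$coefficients
    2 * stats::pnorm(-abs(cf[".f", 1] / cf[".f", 2]))
  }
  list(p_A_given_B = pval_of(fit_on(scoreA, stats::fitted(fitB))),
       p_B_given_A = pval_of(fit_on(scoreB, stats::fitted(fitA))))
}

#' Repeated train/validation split AUC
#'
#' Repeatedly splits the data into a training fraction and a validation
#' remainder, fits a logistic model of the outcome on the score (plus
#' covariates) in training, and measures the area under the ROC curve
#' of the validation predictions. Rounds whose validation split lacks a
#' class are redrawn (and counted) so exactly `rounds` valid rounds
#' enter the mean.
#'
#' @param scores Numeric score.
#' @param outcome Binary outcome (0/1).
#' @param covariates Optional covariate data frame.
#' @param train_frac Training fraction (default 0.75).
#' @param rounds Number of rounds (default 100).
#' @param seed Integer seed for the splits.
#' @return List `mean_auc`, `sd_auc`, `aucs`, `n_redraws`.
#' @export
repeated_split_auc <- function(scores, outcome, covariates = NULL,
                               train_frac = 0.75, rounds = 100,
                               seed = 1L) {
  stopifnot(.is_binary(outcome), length(scores) == length(outcome))
  set.seed(seed)
  n <- length(outcome)
  dat <- data.frame(.y = outcome, .s = scores)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  aucs <- numeric(rounds)
  redraws <- 0L
  for (r in seq_len(rounds)) {
    repeat {
      tr <- sample(n, round(train_frac * n))
      if (length(unique(outcome[-tr])) == 2L &&
          length(unique(outcome[tr])) == 2L) break
      redraws <- redraws + 1L
    }
    fit <- suppressWarnings(stats::glm(.y ~ ., data = dat[tr, ],
                                       family = stats::binomial()))
    pred <- stats::predict(fit, newdata = dat[-tr, ], type = "response")
    aucs[r] <- as.numeric(pROC::auc(pROC::roc(outcome[-tr], pred,
                                              quiet = TRUE,
                                              direction = "<")))
  }
  list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs), aucs = aucs,
       n_redraws = redraws)
}
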