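#' Bayesian comparison of cross-trait effect models
#'
#' For a medication-use lead variant with summary statistics for the
#' matching risk factor (RISK) and coronary artery disease (CAD), four
#' hypotheses about where the variant acts are compared: MED ONLY (no
#' effect on RISK or CAD), RISK only, CAD only, and CAD+RISK (a shared,
#' highly correlated effect on both). The medication-use effect itself
#' is taken as established and common to all four models. Each model's
#' approximate Bayes factor is a bivariate normal Bayes factor on the
#' (RISK, CAD) z-scores: a trait that is "on" carries a normal effect
#' prior of variance `W`, an "off" trait a point mass at zero, and in
#' CAD+RISK the two effects have prior correlation `rho`. Posterior
#' model probabilities follow from a uniform model prior; a model is
#' supported when its posterior reaches `support`.
#'
#' @param med,risk,cad Lists (or one-row data frames) with `beta` and
#'   `se` for the variant in each summary-statistic set.
#' @param W Prior effect variance for "on" traits (default 0.04).
#' @param rho Prior correlation of the RISK and CAD effects in the
#'   shared model (default 0.9; values near 1 approximate a fixed
#'   common effect).
#' @param support Posterior threshold to declare a supported model
#'   (default 0.6).
#' @return List with `labf` (named log ABFs), `posterior` (named,
#'   sums to 1), `supported` (model name or `NA`), `pip_cad`
#'   (posterior(CAD) + posterior(CAD+RISK)).
#' @export
compare_models <- function(med, risk, cad, W = 0.04, rho = 0.9,
                           support = 0.6) {
  for (s in list(med, risk, cad))
    if (is.null(s$beta) || is.null(s$se) || is.na(s$beta) || is.na(s$se))
      stop("compare_models needs beta and se for med, risk and cad")
  if (rho <= -1 || rho >= 1) stop("rho must lie in (-1, 1)")
  z <- c(risk = risk$beta / risk$se, cad = cad$beta / cad$se)
  w <- c(risk = W / risk$se^2, cad = W / cad$se^2)  # prior variance, z scale

  ldmvn <- function(z, S) {
    # bivariate normal log density at z with covariance S
    det <- S[1, 1] * S[2, 2] - S[1, 2]^2
    q <- (S[2, 2] * z[1]^2 - 2 * S[1, 2] * z[1] * z[2] +
            S[1, 1] * z[2]^2) / det
    -base::log(2 * pi) - 0.5 * base::log(det) - 0.5 * q
  }
  I2 <- diag(2)
  prior <- list(
    MED_ONLY = matrix(0, 2, 2),
    RISK = diag(c(w["risk"], 0)),
    CAD = diag(c(0, w["cad"])),
    CAD_RISK = matrix(c(w["risk"], rho * sqrt(w["risk"] * w["cad"]),
                        rho * sqrt(w["risk"] * w["cad"]), w["cad"]), 2, 2))
  null_ld <- ldmvn(z, I2)
  labf <- vapply(prior, function(S) ldmvn(z, I2 + S) - null_ld, numeric(1))
  post <- exp(labf - .logsumexp(labf))
  supported <- if (max(post) >= support) names(post)[which.max(post)]
    else NA_character_
  list(labf = labf, posterior = post, supported = supported,
       pip_cad = unname(post["CAD"] + post["CAD_RISK"]),
       W = W, rho = rho)
}

#' Run the model comparison over a set of lead variants
#'
#' Matches each lead variant into the three summary-statistic tables by
#' variant id, skips variants missing from any table (with a reason),
#' and tabulates how many variants each model supports.
#'
#' @param lead_ids Character vector of variant ids.
#' @param med_stats,risk_stats,cad_stats `assoc_stats`-dialect data
#'   frames (columns `id`, `beta`, `se`).
#' @inheritParams compare_models
#' @return List with `results` (one row per tested variant: posteriors,
#'   supported model, CAD PIP), `skipped` (ids and reasons) and
#'   `counts` (supported-model tally, `none` for unsupported).
#' @export
batch_compare <- function(lead_ids, med_stats, risk_stats, cad_stats,
                          W = 0.04, rho = 0.9, support = 0.6) {
  rows <- list(); skipped <- list()
  for (id in lead_ids) {
    hit <- function(d) {
      i <- match(id, d$id)
      if (is.na(i)) NULL else list(beta = d$beta[i], se = d$se[i])
    }
    m <- hit(med_stats); r <- hit(risk_stats); cc <- hit(cad_stats)
    missing_in <- c("med", "risk", "cad")[vapply(list(m, r, cc), is.null,
                                                 logical(1))]
    if (length(missing_in)) {
      skipped[[id]] <- paste("absent from", paste(missing_in, collapse = "+"))
      next
    }
    res <- compare_models(m, r, cc, W = W, rho = rho, support = support)
    rows[[id]] <- data.frame(id = id, t(res$posterior),
                             supported = res$supported %||% NA_character_,
                             pip_cad = res$pip_cad,
                             stringsAsFactors = FALSE)
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), MED_ONLY = numeric(), RISK = numeric(),
               CAD = numeric(), CAD_RISK = numeric(),
               supported = character(), pip_cad = numeric())
  rownames(results) <- NULL
  tally <- table(factor(ifelse(is.na(results$supported), "none",
                               results$supported),
                        levels = c("MED_ONLY", "RISK", "CAD", "CAD_RISK",
                                   "none")))
  list(results = results,
       skipped = data.frame(id = names(skipped),
                            reason = unlist(skipped) %||% character(),
                            stringsAsFactors = FALSE),
       counts = tally)
}
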