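#' Harmonize cohort summary statistics to a reference allele coding
#'
#' Variants are keyed `chr:pos`. A cohort record whose ref/alt pair is
#' swapped relative to the reference cohort has its effect negated and
#' its allele frequency reflected; records with incompatible allele
#' pairs at the same position, or positions absent from the reference,
#' are dropped and counted.
#'
#' @param stats Cohort `assoc_stats` data frame.
#' @param reference Reference `assoc_stats` (defines allele orientation).
#' @return List with `aligned` (harmonized stats) and `dropped`
#'   (positions with reasons).
#' @export
harmonize_alleles <- function(stats, reference) {
  key <- function(d) paste(d$chr, d$pos, sep = ":")
  m <- match(key(stats), key(reference))
  dropped <- data.frame(id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  unmatched <- is.na(m)
  if (any(unmatched))
    dropped <- rbind(dropped, data.frame(id = stats$id[unmatched],
                                         reason = "not_in_reference"))
  s <- stats[!unmatched, , drop = FALSE]
  r <- reference[m[!unmatched], , drop = FALSE]
  same <- s$ref == r$ref & s$alt == r$alt
  swapped <- s$ref == r$alt & s$alt == r$ref
  bad <- !same & !swapped
  if (any(bad))
    dropped <- rbind(dropped, data.frame(id = s$id[bad],
                                         reason = "allele_mismatch"))
  if (any(swapped)) {
    i <- which(swapped)
    s$beta[i] <- -s$beta[i]
    s$z[i] <- -s$z[i]
    s$af[i] <- 1 - s$af[i]
    tmp <- s$ref[i]; s$ref[i] <- s$alt[i]; s$alt[i] <- tmp
    s$effect_allele[i] <- s$alt[i]
    s$id[i] <- r$id[i]
  }
  list(aligned = s[!bad, , drop = FALSE], dropped = dropped)
}

#' Inverse-variance weighted fixed-effect meta-analysis
#'
#' Pools allele-harmonized per-cohort estimates by precision:
#' `beta = sum(b_i / se_i^2) / sum(1 / se_i^2)`,
#' `se = sqrt(1 / sum(1 / se_i^2))`, with a two-sided normal P from
#' `z = beta / se`. Variants present in fewer than `min_cohorts` cohorts
#' are carried through un-pooled (single-cohort estimate) and flagged.
#'
#' @param cohorts Named list of harmonized `assoc_stats` data frames.
#' @param min_cohorts Minimum cohorts for a pooled estimate (default 2).
#' @return Data frame with `id`, `chr`, `pos`, `beta`, `se`, `z`,
#'   `pval`, `n_cohorts`, `direction` (one `+`/`-`/`?` per cohort) and
#'   `pooled` flag.
#' @export
ivw_meta <- function(cohorts, min_cohorts = 2L) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1L)
  for (d in cohorts) if (any(d$se <= 0, na.rm = TRUE))
    stop("non-positive standard error in cohort statistics")
  ids <- unique(unlist(lapply(cohorts, `[[`, "id")))
  K <- length(cohorts)
  B <- SE <- matrix(NA_real_, length(ids), K)
  for (k in seq_len(K)) {
    m <- match(cohorts[[k]]$id, ids)
    B[m, k] <- cohorts[[k]]$beta
    SE[m, k] <- cohorts[[k]]$se
  }
  W <- 1 / SE^2
  W[is.na(W)] <- 0
  Bz <- B; Bz[is.na(Bz)] <- 0
  wsum <- rowSums(W)
  beta <- rowSums(Bz * W) / wsum
  se <- sqrt(1 / wsum)
  z <- beta / se
  direction <- apply(B, 1, function(b)
    paste(ifelse(is.na(b), "?", ifelse(b >= 0, "+", "-")), collapse = ""))
  n_coh <- rowSums(!is.na(B))

  first <- cohorts[[1L]]
  fm <- match(ids, first$id)
  out <- data.frame(id = ids,
                    chr = first$chr[fm], pos = first$pos[fm],
                    beta = beta, se = se, z = z,
                    pval = 2 * stats::pnorm(-abs(z)),
                    n_cohorts = n_coh, direction = direction,
                    pooled = n_coh >= min_cohorts,
                    stringsAsFactors = FALSE)
  # fill positions for variants absent from the first cohort
  for (k in seq_len(K)[-1L]) {
    nafill <- is.na(out$chr)
    if (!any(nafill)) break
    m <- match(ids[nafill], cohorts[[k]]$id)
    out$chr[nafill] <- cohorts[[k]]$chr[m]
    out$pos[nafill] <- cohorts[[k]]$pos[m]
  }
  rownames(out) <- NULL
  out
}

#' Candidate selection and declaration of meta-analysis significance
#'
#' Discovery loci are formed at the candidate threshold (lead
#' `P < 5e-6`); a locus is declared significant when its lead variant
#' meets the stricter meta-analysis threshold `P < 5e-9`. Loci whose
#' meta P is significant while the discovery lead was below genome-wide
#' significance (`P >= 5e-8`) are flagged as rescued by the
#' meta-analysis.
#'
#' @param discovery_loci Loci from [define_loci()] run at
#'   `p_gws = p_candidate`.
#' @param meta Meta-analysis results from [ivw_meta()].
#' @param p_candidate Candidate threshold (default 5e-6).
#' @param p_meta_sig Meta-analysis significance threshold (default 5e-9).
#' @param p_gws Discovery genome-wide threshold (default 5e-8).
#' @return The loci table with `meta_pval`, `significant`,
#'   `meta_rescued` columns.
#' @export
select_and_declare <- function(discovery_loci, meta,
                               p_candidate = 5e-6, p_meta_sig = 5e-9,
                               p_gws = 5e-8) {
  out <- discovery_loci
  m <- match(out$lead_id, meta$id)
  out$meta_pval <- meta$pval[m]
  out$significant <- !is.na(out$meta_pval) & out$meta_pval < p_meta_sig
  out$meta_rescued <- out$significant & out$lead_pval >= p_gws
  out
}

#' Exact binomial test of cross-cohort direction concordance
#'
#' Given per-variant direction strings (one `+`/`-` per cohort), counts
#' variants whose direction agrees in every cohort and returns the exact
#' one-sided binomial tail probability `P(X >= k | n, null_p)`. The null
#' concordance probability is analysis-specific and must be supplied.
#'
#' @param directions Character vector of direction strings (e.g.
#'   `"++-"`); strings containing `?` (missing cohorts) are ignored.
#' @param null_p Null probability of full concordance, in (0, 1).
#' @return List with `k`, `n`, `pval`.
#' @export
concordance_test <- function(directions, null_p) {
  if (length(null_p) != 1L || null_p <= 0 || null_p >= 1)
    stop("null_p must be a single probability in (0, 1)")
  use <- !grepl("?", directions, fixed = TRUE)
  d <- directions[use]
  n <- length(d)
  k <- sum(vapply(strsplit(d, ""), function(ch) length(unique(ch)) == 1L,
                  logical(1)))
  if (k > n) stop("concordant count exceeds total")
  p <- stats::pbinom(k - 1L, n, null_p, lower.tail = FALSE)
  list(k = k, n = n, pval = p)
}
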