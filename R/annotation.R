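#' Novelty annotation of credible sets against a known-association table
#'
#' A credible set is non-novel when the local table of known
#' associations holds, within `window` bp of the set's top variant
#' (window closed on both ends), a genome-wide significant association
#' whose trait category matches the medication class's indication
#' (lipid medication - `lipid`, antihypertensives - `blood-pressure`,
#' T2D medication - `glucose`). Independently, the presence of any
#' in-window cardiovascular-disease (`CVD`) association is reported.
#'
#' @param cs_table Data frame, one row per credible set: `cs_id`, `chr`,
#'   `pos` (top variant position), `category` (indication category of
#'   the medication class).
#' @param known Known-association table: `chr`, `pos`, `trait`,
#'   `trait_category`, `p`.
#' @param window Half-width in bp (default 1.5e6).
#' @param p_known Significance required of a known association
#'   (default 5e-8).
#' @return `cs_table` with `novel` and `cvd_in_window` columns.
#' @export
annotate_novelty <- function(cs_table, known, window = 1.5e6,
                             p_known = 5e-8) {
  if (nrow(known) == 0L) {
    warning("known-association table is empty; every credible set is novel")
    cs_table$novel <- TRUE
    cs_table$cvd_in_window <- FALSE
    return(cs_table)
  }
  if (any(known$p <= 0 | known$p > 1)) stop("known p values must lie in (0, 1]")
  kn <- known[known$p < p_known, , drop = FALSE]
  cs_table$novel <- vapply(seq_len(nrow(cs_table)), function(i) {
    hit <- kn$chr == cs_table$chr[i] &
      abs(kn$pos - cs_table$pos[i]) <= window &
      kn$trait_category == cs_table$category[i]
    !any(hit)
  }, logical(1))
  cs_table$cvd_in_window <- vapply(seq_len(nrow(cs_table)), function(i) {
    any(kn$chr == cs_table$chr[i] &
          abs(kn$pos - cs_table$pos[i]) <= window &
          kn$trait_category == "CVD")
  }, logical(1))
  cs_table
}

#' Bonferroni endpoint scan over lead variants
#'
#' Flags variant-endpoint pairs whose P value passes `0.05 /
#' n_endpoints`, the Bonferroni level for the number of endpoints
#' considered.
#'
#' @param endpoint_table Data frame `id`, `endpoint`, `p`.
#' @param n_endpoints Number of endpoints tested (positive).
#' @param alpha Family-wise level (default 0.05).
#' @return The significant rows, with the threshold in
#'   `attr(, "threshold")`.
#' @export
endpoint_scan <- function(endpoint_table, n_endpoints, alpha = 0.05) {
  if (length(n_endpoints) != 1L || n_endpoints <= 0)
    stop("n_endpoints must be a positive count")
  thr <- alpha / n_endpoints
  hits <- endpoint_table[endpoint_table$p < thr, , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "threshold") <- thr
  hits
}
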