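#' Read and write the package's TSV dialects
#'
#' Summary statistics travel as TSV with columns `chr`, `pos`, `ref`,
#' `alt`, `effect_allele`, `af`, `beta`, `se`, `pval`, `n` (plus
#' `n_cases`, `n_controls` for binary traits); registries as
#' `person_id`, `date`, `atc`.
#'
#' @param path File path.
#' @name io
NULL

#' @rdname io
#' @export
read_sumstats <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chr", "pos", "ref", "alt", "beta", "se")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("summary statistics missing columns: ",
                         paste(miss, collapse = ", "))
  if (!"id" %in% names(d))
    d$id <- paste(d$chr, d$pos, d$ref, d$alt, sep = ":")
  if (!"z" %in% names(d)) d$z <- d$beta / d$se
  if (!"pval" %in% names(d)) d$pval <- 2 * stats::pnorm(-abs(d$z))
  class(d) <- c("assoc_stats", class(d))
  d
}

#' @rdname io
#' @param stats An `assoc_stats` data frame.
#' @export
write_sumstats <- function(stats, path) {
  utils::write.table(as.data.frame(stats), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_registry <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_registry(d)
}

#' @rdname io
#' @export
read_persons <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"person_id" %in% names(d)) stop("persons table needs person_id")
  d
}
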