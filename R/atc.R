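#' ATC code pattern
#'
#' A named set of ATC prefixes defining a drug class. Matching is uppercase
#' prefix matching on the code string: a registry code matches the pattern
#' when it starts with at least one include prefix and with no exclude
#' prefix. No ATC hierarchy table is needed; the WHO ATC system is itself
#' prefix-structured (C10 = lipid modifiers, C10AA = statins, C10AA01 =
#' simvastatin).
#'
#' @param name Label for the pattern (used in diagnostics and output).
#' @param include Character vector of ATC prefixes selecting the class.
#' @param exclude Character vector of ATC prefixes removed from the class.
#' @return An object of class `atc_pattern`.
#' @examples
#' statins <- atc_pattern("statin", "C10AA")
#' atc_match(c("C10AA01", "C03AA04"), statins)
#' @export
atc_pattern <- function(name, include, exclude = character()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(include), length(include) >= 1L,
            is.character(exclude))
  include <- toupper(include)
  exclude <- toupper(exclude)
  if (length(intersect(include, exclude)) > 0L)
    stop("include and exclude prefixes must be disjoint")
  structure(list(name = name, include = include, exclude = exclude),
            class = "atc_pattern")
}

#' @export
print.atc_pattern <- function(x, ...) {
  cat("ATC pattern '", x$name, "': ", paste(x$include, collapse = ", "), sep = "")
  if (length(x$exclude))
    cat(" excluding ", paste(x$exclude, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Match ATC codes against a pattern
#'
#' @param codes Character vector of ATC codes.
#' @param pattern An [atc_pattern()].
#' @return Logical vector, one element per code.
#' @export
atc_match <- function(codes, pattern) {
  stopifnot(inherits(pattern, "atc_pattern"))
  codes <- toupper(as.character(codes))
  hit <- .prefix_any(codes, pattern$include)
  if (length(pattern$exclude))
    hit <- hit & !.prefix_any(codes, pattern$exclude)
  hit
}

.prefix_any <- function(codes, prefixes) {
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

#' Standard medication class patterns
#'
#' The ATC class definitions used throughout the package: lipid-modifying
#' agents (C10), statins (C10AA) with simvastatin (C10AA01) singled out,
#' the five antihypertensive groups (C02, C03, C07, C08, C09),
#' non-insulin blood-glucose-lowering drugs (A10B), second-line
#' type-2-diabetes agents (combinations A10BD, DPP-4 inhibitors A10BH,
#' GLP-1 analogues A10BJ, SGLT2 inhibitors A10BK) and insulins (A10A).
#'
#' @return Named list of [atc_pattern()] objects.
#' @export
medication_patterns <- function() {
  list(
    lipid        = atc_pattern("lipid", "C10"),
    statin       = atc_pattern("statin", "C10AA"),
    simvastatin  = atc_pattern("simvastatin", "C10AA01"),
    other_statin = atc_pattern("other_statin", "C10AA", exclude = "C10AA01"),
    htn          = atc_pattern("htn", c("C02", "C03", "C07", "C08", "C09")),
    t2d          = atc_pattern("t2d", "A10B"),
    t2d_secondline = atc_pattern("t2d_secondline",
                                 c("A10BD", "A10BH", "A10BJ", "A10BK")),
    insulin      = atc_pattern("insulin", "A10A")
  )
}

#' The five antihypertensive ATC groups
#' @return Character vector of the five top-level prefixes.
#' @export
htn_groups <- function() c("C02", "C03", "C07", "C08", "C09")
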