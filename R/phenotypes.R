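#' @title Medication-use phenotypes from a purchase registry
#' @description Derivation of the twelve medication-use phenotypes: three
#'   quantitative purchase counts (lipid, hypertension, type-2-diabetes
#'   medications) and nine binary trajectory patterns (statin switching,
#'   fast discontinuation of statins and of antihypertensives, four
#'   antihypertensive combination-breadth thresholds, second-line T2D
#'   agents, progression to insulin).
#' @name phenotypes
NULL

#' Default follow-up window of the purchase registry
#' @return Date vector of length 2 (1995-01-01 to 2018-12-31).
#' @export
default_window <- function() as.Date(c("1995-01-01", "2018-12-31"))

.as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(as.character(x))
}

#' Validate a purchase registry against a person table
#'
#' Checks required columns, coerces dates, and rejects registry rows whose
#' person is absent from the person table.
#'
#' @param registry Data frame with columns `person_id`, `date`, `atc`.
#' @param persons Optional data frame with column `person_id` (plus
#'   `birth_date`, `death_date`, `sex` where the caller needs them).
#' @return The registry with `date` as `Date`, invisibly checked.
#' @export
validate_registry <- function(registry, persons = NULL) {
  need <- c("person_id", "date", "atc")
  miss <- setdiff(need, names(registry))
  if (length(miss))
    stop("registry is missing columns: ", paste(miss, collapse = ", "))
  registry$date <- .as_date(registry$date)
  if (anyNA(registry$date)) stop("registry contains unparseable dates")
  if (!is.null(persons)) {
    unknown <- setdiff(unique(registry$person_id), persons$person_id)
    if (length(unknown))
      stop("registry refers to person_id absent from the person table: ",
           paste(utils::head(unknown, 5L), collapse = ", "),
           if (length(unknown) > 5L) " ..." else "")
  }
  registry
}

# Per-person end of follow-up: death censors the registry window.
.end_of_followup <- function(persons, window) {
  end <- rep(window[2], nrow(persons))
  if ("death_date" %in% names(persons)) {
    dd <- .as_date(persons$death_date)
    has <- !is.na(dd)
    end[has] <- pmin(end[has], dd[has])
  }
  end
}

# Alive at window start; used as the universe for binary phenotypes.
.alive_at_start <- function(persons, window) {
  if (!"death_date" %in% names(persons)) return(rep(TRUE, nrow(persons)))
  dd <- .as_date(persons$death_date)
  is.na(dd) | dd >= window[1]
}

#' Count drug purchases per person
#'
#' Counts registry rows matching an ATC pattern for every eligible person.
#' Each row is one dispensed purchase; several purchases on one day count
#' separately. Persons who were dead or younger than 10 years at the start
#' of the follow-up window are excluded (their count is `NA` and
#' `eligible` is `FALSE`); all other non-purchasers are kept with count 0.
#'
#' @param registry Purchase registry (`person_id`, `date`, `atc`).
#' @param pattern An [atc_pattern()].
#' @param persons Person table with `person_id`, `birth_date` and
#'   optionally `death_date`.
#' @param window Date vector of length 2; defaults to [default_window()].
#' @return Data frame with `person_id`, `count`, `eligible`.
#' @export
count_purchases <- function(registry, pattern, persons,
                            window = default_window()) {
  window <- .as_date(window)
  registry <- validate_registry(registry, persons)
  birth <- .as_date(persons$birth_date)
  age_at_start <- as.numeric(window[1] - birth) / 365.25
  eligible <- .alive_at_start(persons, window) & age_at_start >= 10

  keep <- atc_match(registry$atc, pattern) &
    registry$date >= window[1] & registry$date <= window[2]
  tab <- table(factor(registry$person_id[keep], levels = persons$person_id))
  out <- data.frame(person_id = persons$person_id,
                    count = as.integer(tab),
                    eligible = eligible,
                    stringsAsFactors = FALSE)
  out$count[!eligible] <- NA_integer_
  out
}

# First purchase date per person for rows selected by `sel`.
.first_date <- function(registry, sel) {
  r <- registry[sel, , drop = FALSE]
  if (nrow(r) == 0L)
    return(data.frame(person_id = character(), first = as.Date(character())))
  agg <- stats::aggregate(r["date"], by = r["person_id"], FUN = min)
  names(agg)[2] <- "first"
  agg
}

.status_factor <- function(x) factor(x, levels = c("case", "control", "excluded"))

#' Statin switching status
#'
#' Among statin users (any C10AA purchase): persons whose first statin
#' purchase is simvastatin (C10AA01) are cases if they later purchase a
#' different statin, controls if they never do. Persons starting on a
#' non-simvastatin statin are excluded, as are ambiguous starters whose
#' first statin day carries two different statin molecules. Never-users
#' are excluded.
#'
#' @param registry Purchase registry.
#' @param persons Person table; statuses are reported for each of its rows.
#' @param window Follow-up window.
#' @return Data frame `person_id`, `status` (case/control/excluded).
#' @export
derive_statin_switch <- function(registry, persons,
                                 window = default_window()) {
  window <- .as_date(window)
  registry <- validate_registry(registry, persons)
  registry <- registry[registry$date >= window[1] & registry$date <= window[2], ]
  alive <- .alive_at_start(persons, window)

  is_statin <- atc_match(registry$atc, atc_pattern("statin", "C10AA"))
  is_simva <- atc_match(registry$atc, atc_pattern("simva", "C10AA01"))
  st <- registry[is_statin, , drop = FALSE]
  st$simva <- is_simva[is_statin]

  status <- rep("excluded", nrow(persons))
  if (nrow(st) > 0L) {
    first <- .first_date(st, rep(TRUE, nrow(st)))
    idx <- match(st$person_id, first$person_id)
    on_first_day <- st$date == first$first[idx]
    # ambiguous starter: both a simvastatin and a non-simvastatin row on day 1
    amb <- tapply(st$simva[on_first_day], st$person_id[on_first_day],
                  function(s) any(s) && any(!s))
    starts_simva <- tapply(st$simva[on_first_day], st$person_id[on_first_day], all)
    later_other <- tapply(!st$simva[!on_first_day],
                          factor(st$person_id[!on_first_day],
                                 levels = names(starts_simva)),
                          any)
    later_other[is.na(later_other)] <- FALSE

    ids <- names(starts_simva)
    st_status <- ifelse(amb[ids], "excluded",
                 ifelse(!starts_simva[ids], "excluded",
                 ifelse(later_other[ids], "case", "control")))
    m <- match(ids, persons$person_id)
    status[m] <- st_status
  }
  status[!alive] <- "excluded"
  data.frame(person_id = persons$person_id,
             status = .status_factor(status), stringsAsFactors = FALSE)
}

#' Fast treatment discontinuation status
#'
#' Among users of a drug class: cases made only one or two purchases and
#' their last purchase lies more than 365 days before their end of
#' follow-up (death date or window end, whichever is earlier). Users with
#' one or two purchases but insufficient purchase-free follow-up are
#' excluded (they may still be discontinuing); users with three or more
#' purchases are controls. Never-users are excluded.
#'
#' @inheritParams derive_statin_switch
#' @param pattern An [atc_pattern()] defining the drug class.
#' @return Data frame `person_id`, `status`.
#' @export
derive_fast_discontinuation <- function(registry, pattern, persons,
                                        window = default_window()) {
  window <- .as_date(window)
  registry <- validate_registry(registry, persons)
  registry <- registry[registry$date >= window[1] & registry$date <= window[2], ]
  alive <- .alive_at_start(persons, window)
  eof <- .end_of_followup(persons, window)

  sel <- atc_match(registry$atc, pattern)
  r <- registry[sel, , drop = FALSE]
  status <- rep("excluded", nrow(persons))
  if (nrow(r) > 0L) {
    n_purch <- tapply(r$date, r$person_id, length)
    last <- tapply(r$date, r$person_id, max)
    ids <- names(n_purch)
    m <- match(ids, persons$person_id)
    free_days <- as.numeric(eof[m]) - as.numeric(last)
    st <- ifelse(n_purch >= 3, "control",
          ifelse(free_days > 365, "case", "excluded"))
    status[m] <- st
  }
  status[!alive] <- "excluded"
  data.frame(person_id = persons$person_id,
             status = .status_factor(status), stringsAsFactors = FALSE)
}

#' Antihypertensive combination breadth
#'
#' Counts, per person, the distinct antihypertensive ATC groups (C02, C03,
#' C07, C08, C09) purchased at least once during follow-up, and derives
#' the four threshold phenotypes: more than one, more than two, more than
#' three, and all five groups used. Controls are users below the
#' case-defining threshold; never-users are excluded. Rows outside the
#' five groups are ignored.
#'
#' @inheritParams derive_statin_switch
#' @return Data frame `person_id`, `n_groups`, `htn_gt1`, `htn_gt2`,
#'   `htn_gt3`, `htn_all5`.
#' @export
derive_antihypertensive_groups <- function(registry, persons,
                                           window = default_window()) {
  window <- .as_date(window)
  registry <- validate_registry(registry, persons)
  registry <- registry[registry$date >= window[1] & registry$date <= window[2], ]
  alive <- .alive_at_start(persons, window)

  grp <- rep(NA_character_, nrow(registry))
  for (g in htn_groups()) grp[startsWith(toupper(registry$atc), g)] <- g
  r <- registry[!is.na(grp), , drop = FALSE]
  r$grp <- grp[!is.na(grp)]

  n_groups <- integer(nrow(persons))
  if (nrow(r) > 0L) {
    ng <- tapply(r$grp, r$person_id, function(g) length(unique(g)))
    m <- match(names(ng), persons$person_id)
    n_groups[m] <- as.integer(ng)
  }
  user <- n_groups > 0L & alive

  thr_status <- function(thr, eq = FALSE) {
    st <- rep("excluded", nrow(persons))
    is_case <- if (eq) n_groups == thr else n_groups > thr
    st[user & is_case] <- "case"
    st[user & !is_case] <- "control"
    .status_factor(st)
  }
  data.frame(person_id = persons$person_id,
             n_groups = ifelse(alive, n_groups, NA_integer_),
             htn_gt1 = thr_status(1), htn_gt2 = thr_status(2),
             htn_gt3 = thr_status(3), htn_all5 = thr_status(5, eq = TRUE),
             stringsAsFactors = FALSE)
}

#' Type-2-diabetes treatment progression
#'
#' Among users of non-insulin glucose-lowering drugs (any A10B purchase):
#' second-line cases purchased a combination product (A10BD), DPP-4
#' inhibitor (A10BH), GLP-1 analogue (A10BJ) or SGLT2 inhibitor (A10BK);
#' other users are controls. Insulin-progression cases made their first
#' insulin (A10A) purchase strictly after their first A10B purchase;
#' users whose insulin precedes or ties the first A10B purchase are
#' excluded from that phenotype; users who never purchase insulin are
#' controls. Never-users of A10B are excluded from both.
#'
#' @inheritParams derive_statin_switch
#' @return Data frame `person_id`, `t2d_secondline`, `t2d_insulin`.
#' @export
derive_t2d_progression <- function(registry, persons,
                                   window = default_window()) {
  window <- .as_date(window)
  registry <- validate_registry(registry, persons)
  registry <- registry[registry$date >= window[1] & registry$date <= window[2], ]
  alive <- .alive_at_start(persons, window)
  pats <- medication_patterns()

  is_t2d <- atc_match(registry$atc, pats$t2d)
  is_second <- atc_match(registry$atc, pats$t2d_secondline)
  is_ins <- atc_match(registry$atc, pats$insulin)

  sl <- rep("excluded", nrow(persons))
  ins <- rep("excluded", nrow(persons))

  t2d_first <- .first_date(registry, is_t2d)
  if (nrow(t2d_first) > 0L) {
    m <- match(t2d_first$person_id, persons$person_id)
    has_second <- tapply(rep(TRUE, sum(is_second)),
                         factor(registry$person_id[is_second],
                                levels = t2d_first$person_id), any)
    has_second[is.na(has_second)] <- FALSE
    sl[m] <- ifelse(has_second, "case", "control")

    ins_first <- .first_date(registry, is_ins)
    fi <- ins_first$first[match(t2d_first$person_id, ins_first$person_id)]
    ins[m] <- ifelse(is.na(fi), "control",
               ifelse(fi > t2d_first$first, "case", "excluded"))
  }
  sl[!alive] <- "excluded"
  ins[!alive] <- "excluded"
  data.frame(person_id = persons$person_id,
             t2d_secondline = .status_factor(sl),
             t2d_insulin = .status_factor(ins), stringsAsFactors = FALSE)
}

#' Derive all twelve medication-use phenotypes
#'
#' Runs every derivation and assembles one row per person: the three
#' quantitative purchase counts (NA for persons ineligible for the
#' quantitative analyses), the nine binary statuses, and the covariates
#' age at end of follow-up, follow-up years and sex (carried through from
#' the person table when present).
#'
#' @inheritParams derive_statin_switch
#' @return A `phenotype_table` data frame.
#' @export
derive_phenotypes <- function(registry, persons, window = default_window()) {
  window <- .as_date(window)
  registry <- validate_registry(registry, persons)
  pats <- medication_patterns()

  lipid <- count_purchases(registry, pats$lipid, persons, window)
  htn <- count_purchases(registry, pats$htn, persons, window)
  t2d <- count_purchases(registry, pats$t2d, persons, window)

  sw <- derive_statin_switch(registry, persons, window)
  sd <- derive_fast_discontinuation(registry, pats$statin, persons, window)
  hg <- derive_antihypertensive_groups(registry, persons, window)
  hd <- derive_fast_discontinuation(registry, pats$htn, persons, window)
  tp <- derive_t2d_progression(registry, persons, window)

  eof <- .end_of_followup(persons, window)
  birth <- .as_date(persons$birth_date)
  fy <- pmax(as.numeric(eof - window[1]) / 365.25, 0)
  age_end <- as.numeric(eof - birth) / 365.25

  out <- data.frame(
    person_id = persons$person_id,
    eligible = lipid$eligible,
    purchases_lipid = lipid$count,
    purchases_htn = htn$count,
    purchases_t2d = t2d$count,
    statin_switch = sw$status,
    statin_disc = sd$status,
    htn_groups = hg$n_groups,
    htn_gt1 = hg$htn_gt1, htn_gt2 = hg$htn_gt2,
    htn_gt3 = hg$htn_gt3, htn_all5 = hg$htn_all5,
    htn_disc = hd$status,
    t2d_secondline = tp$t2d_secondline,
    t2d_insulin = tp$t2d_insulin,
    age_end = age_end,
    follow_up_years = fy,
    stringsAsFactors = FALSE)
  if ("sex" %in% names(persons)) out$sex <- persons$sex
  class(out) <- c("phenotype_table", class(out))
  out
}

.binary_phenotypes <- c("statin_switch", "statin_disc", "htn_gt1", "htn_gt2",
                        "htn_gt3", "htn_all5", "htn_disc",
                        "t2d_secondline", "t2d_insulin")
.count_phenotypes <- c("purchases_lipid", "purchases_htn", "purchases_t2d")

#' Cohort summary of the derived phenotypes
#'
#' One row per phenotype: sample size, cases, controls, excluded and the
#' case percentage among users (cases / (cases + controls) * 100), rounded
#' to one decimal. For quantitative phenotypes the row reports the number
#' of eligible participants and of participants with at least one
#' purchase.
#'
#' @param phen A `phenotype_table` from [derive_phenotypes()].
#' @param digits Decimal places for the percentage (default 1).
#' @return Data frame with columns `phenotype`, `n`, `cases`, `controls`,
#'   `excluded`, `pct_cases`.
#' @export
summarize_cohort <- function(phen, digits = 1) {
  rows <- lapply(.count_phenotypes, function(p) {
    x <- phen[[p]]
    data.frame(phenotype = p, n = sum(!is.na(x)),
               cases = sum(x > 0, na.rm = TRUE), controls = NA_integer_,
               excluded = sum(is.na(x)), pct_cases = NA_real_)
  })
  rows2 <- lapply(.binary_phenotypes, function(p) {
    s <- phen[[p]]
    ca <- sum(s == "case"); co <- sum(s == "control")
    data.frame(phenotype = p, n = ca + co, cases = ca, controls = co,
               excluded = sum(s == "excluded"),
               pct_cases = case_percentage(ca, ca + co, digits))
  })
  out <- do.call(rbind, c(rows, rows2))
  rownames(out) <- NULL
  out
}

#' Case percentage with reporting precision
#'
#' @param cases Number of cases.
#' @param universe Number of cases plus controls.
#' @param digits Decimal places (default 1).
#' @return `100 * cases / universe` rounded; `NA` when the universe is
#'   empty.
#' @examples
#' case_percentage(19228, 45134) # 42.6
#' @export
case_percentage <- function(cases, universe, digits = 1) {
  if (any(universe == 0)) {
    out <- rep(NA_real_, length(cases))
    ok <- universe > 0
    out[ok] <- round(100 * cases[ok] / universe[ok], digits)
    return(out)
  }
  round(100 * cases / universe, digits)
}
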