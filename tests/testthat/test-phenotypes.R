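test_that("ATC matching is prefix-based with excludes", {
  p <- atc_pattern("statin_not_simva", "C10AA", exclude = "C10AA01")
  expect_equal(atc_match(c("C10AA01", "C10AA05", "C03AA03"), p),
               c(FALSE, TRUE, FALSE))
  expect_error(atc_pattern("bad", "C10", exclude = "C10"), "disjoint")
})

test_that("purchase counting applies the age/death eligibility rules", {
  persons <- toy_persons(c("a", "b", "c"),
                         birth = c("1950-01-01", "1990-06-01", "1950-01-01"),
                         death = c(NA, NA, "1994-06-01"))
  reg <- toy_registry(
    list("a", "1996-01-01", "C10AA01"), list("a", "1997-01-01", "C10AA01"),
    list("a", "1998-01-01", "C10AA01"), list("a", "1998-02-01", "C03AA03"),
    list("b", "2005-01-01", "C10AA01"))
  cnt <- count_purchases(reg, atc_pattern("lipid", "C10"), persons)
  expect_equal(cnt$count[cnt$person_id == "a"], 3L)
  # born 1990-06-01: age 4.6 on 1995-01-01 -> excluded from quantitative
  expect_true(is.na(cnt$count[cnt$person_id == "b"]))
  expect_false(cnt$eligible[cnt$person_id == "b"])
  # dead before follow-up start -> excluded
  expect_true(is.na(cnt$count[cnt$person_id == "c"]))
  # unknown person in registry rejected
  bad <- toy_registry(list("zz", "2000-01-01", "C10AA01"))
  expect_error(count_purchases(bad, atc_pattern("lipid", "C10"), persons),
               "absent")
})

test_that("statin switching follows the starter/switcher definition", {
  persons <- toy_persons(c("sw", "ctrl", "other", "tie", "never"))
  reg <- toy_registry(
    list("sw", "1996-03-01", "C10AA01"), list("sw", "1997-01-10", "C10AA05"),
    list("ctrl", "1996-03-01", "C10AA01"), list("ctrl", "1997-01-10", "C10AA01"),
    list("ctrl", "1998-01-10", "C10AA01"), list("ctrl", "1999-01-10", "C10AA01"),
    list("ctrl", "2000-01-10", "C10AA01"),
    list("other", "1996-03-01", "C10AA05"), list("other", "1997-01-10", "C10AA01"),
    list("tie", "1996-03-01", "C10AA01"), list("tie", "1996-03-01", "C10AA05"),
    list("never", "1996-03-01", "C03AA03"))
  st <- derive_statin_switch(reg, persons)
  s <- function(id) as.character(st$status[st$person_id == id])
  expect_equal(s("sw"), "case")
  expect_equal(s("ctrl"), "control")
  expect_equal(s("other"), "excluded")  # non-simvastatin starter
  expect_equal(s("tie"), "excluded")    # ambiguous first day
  expect_equal(s("never"), "excluded")  # never purchased a statin
})

test_that("fast discontinuation needs 1-2 purchases and a year free of purchases", {
  persons <- toy_persons(c("case", "late", "ctrl", "dead"),
                         death = c(NA, NA, NA, "2001-06-01"))
  statin <- atc_pattern("statin", "C10AA")
  reg <- toy_registry(
    list("case", "1999-01-01", "C10AA01"), list("case", "2000-01-01", "C10AA01"),
    list("late", "2018-10-01", "C10AA01"),
    list("ctrl", "1999-01-01", "C10AA01"), list("ctrl", "2000-01-01", "C10AA01"),
    list("ctrl", "2001-01-01", "C10AA01"),
    list("dead", "2001-01-01", "C10AA01"))
  st <- derive_fast_discontinuation(reg, statin, persons)
  s <- function(id) as.character(st$status[st$person_id == id])
  expect_equal(s("case"), "case")
  expect_equal(s("late"), "excluded")  # < 1 year purchase-free follow-up
  expect_equal(s("ctrl"), "control")   # >= 3 purchases
  # death censors the end of follow-up: last purchase 2001-01-01,
  # death 2001-06-01 -> only ~5 months free -> excluded
  expect_equal(s("dead"), "excluded")
})

test_that("antihypertensive thresholds partition users and nest", {
  persons <- toy_persons(c("two", "five", "one", "none"))
  reg <- toy_registry(
    list("two", "2000-01-01", "C03AA03"), list("two", "2001-01-01", "C09AA05"),
    list("five", "2000-01-01", "C02AC01"), list("five", "2000-02-01", "C03AA03"),
    list("five", "2000-03-01", "C07AB02"), list("five", "2000-04-01", "C08CA01"),
    list("five", "2000-05-01", "C09AA05"),
    list("one", "2000-01-01", "C03AA03"),
    list("none", "2000-01-01", "C10AA01"))
  hg <- derive_antihypertensive_groups(reg, persons)
  two <- hg[hg$person_id == "two", ]
  expect_equal(two$n_groups, 2L)
  expect_equal(as.character(unlist(two[c("htn_gt1", "htn_gt2", "htn_gt3",
                                         "htn_all5")])),
               c("case", "control", "control", "control"))
  five <- hg[hg$person_id == "five", ]
  expect_equal(as.character(unlist(five[c("htn_gt1", "htn_gt2", "htn_gt3",
                                          "htn_all5")])),
               rep("case", 4))
  expect_equal(as.character(hg$htn_gt1[hg$person_id == "none"]), "excluded")
})

test_that("T2D progression handles second-line and insulin ordering", {
  persons <- toy_persons(c("sl", "ins", "insfirst", "plain"))
  reg <- toy_registry(
    list("sl", "2005-01-01", "A10BA02"), list("sl", "2015-01-01", "A10BK03"),
    list("ins", "2003-01-01", "A10BA02"), list("ins", "2010-01-01", "A10AE04"),
    list("insfirst", "2001-01-01", "A10AE04"), list("insfirst", "2003-01-01", "A10BA02"),
    list("plain", "2005-01-01", "A10BA02"))
  tp <- derive_t2d_progression(reg, persons)
  g <- function(id, col) as.character(tp[[col]][tp$person_id == id])
  expect_equal(g("sl", "t2d_secondline"), "case")
  expect_equal(g("ins", "t2d_insulin"), "case")
  expect_equal(g("insfirst", "t2d_insulin"), "excluded")
  expect_equal(g("plain", "t2d_secondline"), "control")
  expect_equal(g("plain", "t2d_insulin"), "control")
})

test_that("derivations equal the brute-force oracle on random registries", {
  ids <- sprintf("p%02d", 1:25)
  persons <- toy_persons(ids)
  persons$death_date[3] <- as.Date("2006-05-01")
  persons$birth_date[4] <- as.Date("1991-01-01")
  for (seed in c(101, 202)) {
    reg <- random_registry(300, ids, seed)
    got <- derive_phenotypes(reg, persons)
    want <- oracle_phenotypes(reg, persons)
    for (col in c("purchases_lipid", "purchases_htn", "purchases_t2d"))
      expect_equal(got[[col]], want[[col]], ignore_attr = TRUE)
    for (col in c("statin_switch", "statin_disc", "htn_gt1", "htn_gt2",
                  "htn_gt3", "htn_all5", "htn_disc", "t2d_secondline",
                  "t2d_insulin"))
      expect_equal(as.character(got[[col]]), want[[col]],
                   info = paste(col, seed))
  }
})

test_that("binary statuses partition and are order-invariant", {
  ids <- sprintf("q%02d", 1:20)
  persons <- toy_persons(ids)
  reg <- random_registry(250, ids, 7)
  phen <- derive_phenotypes(reg, persons)
  for (col in c("statin_switch", "htn_gt1", "htn_all5", "t2d_insulin")) {
    tab <- table(phen[[col]])
    expect_equal(sum(tab), nrow(persons))
  }
  # nesting of the antihypertensive thresholds
  expect_true(all(which(phen$htn_all5 == "case") %in%
                    which(phen$htn_gt3 == "case")))
  expect_true(all(which(phen$htn_gt3 == "case") %in%
                    which(phen$htn_gt2 == "case")))
  expect_true(all(which(phen$htn_gt2 == "case") %in%
                    which(phen$htn_gt1 == "case")))
  # shuffling registry rows changes nothing
  phen2 <- derive_phenotypes(reg[sample(nrow(reg)), ], persons)
  expect_equal(phen, phen2)
})

test_that("cohort summary computes case percentages at reporting precision", {
  expect_equal(case_percentage(19228, 45134), 42.6)
  expect_equal(case_percentage(0, 100), 0)
  expect_true(is.na(case_percentage(0, 0)))
  ids <- sprintf("s%02d", 1:15)
  persons <- toy_persons(ids)
  phen <- derive_phenotypes(random_registry(200, ids, 3), persons)
  sm <- summarize_cohort(phen)
  expect_equal(nrow(sm), 12L)
  bin <- sm[!is.na(sm$cases) & !is.na(sm$controls), ]
  expect_true(all(bin$n == bin$cases + bin$controls))
})
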