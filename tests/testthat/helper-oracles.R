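# Independent brute-force re-derivation of the twelve phenotypes, written
# as straight per-person loops from the verbal definitions. Deliberately
# naive: no shared code with the package internals.

oracle_phenotypes <- function(registry, persons,
                              window = as.Date(c("1995-01-01", "2018-12-31"))) {
  registry$date <- as.Date(registry$date)
  persons$birth_date <- as.Date(persons$birth_date)
  dd <- if ("death_date" %in% names(persons))
    as.Date(persons$death_date) else rep(as.Date(NA), nrow(persons))
  out <- list()
  for (i in seq_len(nrow(persons))) {
    pid <- persons$person_id[i]
    r <- registry[registry$person_id == pid &
                    registry$date >= window[1] & registry$date <= window[2], ]
    r <- r[order(r$date), ]
    alive <- is.na(dd[i]) || dd[i] >= window[1]
    age0 <- as.numeric(window[1] - persons$birth_date[i]) / 365.25
    eligible <- alive && age0 >= 10
    eof <- min(window[2], dd[i], na.rm = TRUE)

    cnt <- function(prefixes) {
      if (!eligible) return(NA_integer_)
      sum(sapply(r$atc, function(a) any(startsWith(a, prefixes))))
    }
    statin <- r[startsWith(r$atc, "C10AA"), ]
    sw <- "excluded"
    if (alive && nrow(statin) > 0) {
      d1 <- min(statin$date)
      first <- statin[statin$date == d1, ]
      if (any(first$atc == "C10AA01") && any(first$atc != "C10AA01")) {
        sw <- "excluded"
      } else if (all(first$atc == "C10AA01")) {
        later <- statin[statin$date > d1 & statin$atc != "C10AA01", ]
        sw <- if (nrow(later) > 0) "case" else "control"
      }
    }
    disc <- function(prefixes) {
      rr <- r[sapply(r$atc, function(a) any(startsWith(a, prefixes))), ]
      if (!alive || nrow(rr) == 0) return("excluded")
      if (nrow(rr) >= 3) return("control")
      if (as.numeric(eof - max(rr$date)) > 365) "case" else "excluded"
    }
    groups <- c("C02", "C03", "C07", "C08", "C09")
    used <- groups[sapply(groups, function(g) any(startsWith(r$atc, g)))]
    ng <- length(used)
    thr <- function(k, eq = FALSE) {
      if (!alive || ng == 0) return("excluded")
      hit <- if (eq) ng == k else ng > k
      if (hit) "case" else "control"
    }
    t2d <- r[startsWith(r$atc, "A10B"), ]
    sl <- ins <- "excluded"
    if (alive && nrow(t2d) > 0) {
      second <- sapply(t2d$atc, function(a)
        any(startsWith(a, c("A10BD", "A10BH", "A10BJ", "A10BK"))))
      sl <- if (any(second)) "case" else "control"
      insrows <- r[startsWith(r$atc, "A10A") & !startsWith(r$atc, "A10B"), ]
      if (nrow(insrows) == 0) ins <- "control"
      else if (min(insrows$date) > min(t2d$date)) ins <- "case"
      else ins <- "excluded"
    }
    out[[i]] <- data.frame(
      person_id = pid,
      purchases_lipid = cnt("C10"), purchases_htn = cnt(groups),
      purchases_t2d = cnt("A10B"),
      statin_switch = sw, statin_disc = disc("C10AA"),
      htn_gt1 = thr(1), htn_gt2 = thr(2), htn_gt3 = thr(3),
      htn_all5 = thr(5, eq = TRUE), htn_disc = disc(groups),
      t2d_secondline = sl, t2d_insulin = ins,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Toy registry / person builders --------------------------------------------

toy_persons <- function(ids, birth = "1950-01-01", death = NA) {
  data.frame(person_id = ids,
             sex = "female",
             birth_date = as.Date(rep(birth, length.out = length(ids))),
             death_date = as.Date(rep(death, length.out = length(ids))),
             stringsAsFactors = FALSE)
}

toy_registry <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(x)
    data.frame(person_id = x[[1]], date = as.Date(x[[2]]), atc = x[[3]],
               stringsAsFactors = FALSE)))
}

# random registry with codes drawn from the Table-1 classes
random_registry <- function(n_rows, ids, seed) {
  set.seed(seed)
  codes <- c("C10AA01", "C10AA05", "C10AB05", "C02AC01", "C03AA03",
             "C07AB02", "C08CA01", "C09AA05", "A10BA02", "A10BD07",
             "A10BH01", "A10BK01", "A10AE04")
  data.frame(person_id = sample(ids, n_rows, replace = TRUE),
             date = as.Date("1995-01-01") +
               sample.int(8500, n_rows, replace = TRUE),
             atc = sample(codes, n_rows, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Small LD-block region with one planted causal variant; returns the region
# list build_regions() would produce plus the causal index.
simulate_region <- function(n = 800, m = 30, rho = 0.8, maf = 0.3,
                            b = 0.4, seed = 1) {
  set.seed(seed)
  thr <- qnorm(maf)
  dos <- matrix(0L, n, m)
  for (h in 1:2) {
    z0 <- rnorm(n)
    z <- sqrt(rho) * z0 + sqrt(1 - rho) * matrix(rnorm(n * m), n, m)
    dos <- dos + (z < thr)
  }
  colnames(dos) <- sprintf("1:%d:A:G", seq_len(m) * 1000L)
  causal <- sample(m, 1)
  y <- b * dos[, causal] + rnorm(n)
  beta <- se <- numeric(m)
  for (j in 1:m) {
    f <- lm(y ~ dos[, j])
    beta[j] <- coef(f)[2]
    se[j] <- summary(f)$coefficients[2, 2]
  }
  st <- data.frame(id = colnames(dos), chr = 1L, pos = seq_len(m) * 1000L,
                   ref = "A", alt = "G", beta = beta, se = se,
                   stringsAsFactors = FALSE)
  st$z <- st$beta / st$se
  st$pval <- 2 * pnorm(-abs(st$z))
  ld <- suppressWarnings(cor(dos)); ld[is.na(ld)] <- 0; diag(ld) <- 1
  list(region = list(chr = 1L, start = 1L, end = m * 1000L,
                     stats = st, ld = ld),
       causal = causal, dosages = dos)
}
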