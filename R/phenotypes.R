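## Fertility phenotypes of risk matings: classification of matings into
## risk1 / risk2 / non-risk and carrier-sire groups, the three phenotypes
## (insemination success, stillbirth rate, juvenile mortality), and the
## two-proportion contrasts.

#' Classify matings into risk categories for one region
#'
#' Categories follow the carrier logic of risk-mating analysis:
#' * `risk1`: carrier sire x genotyped carrier dam (heterozygous or
#'   homozygous status);
#' * `risk2`: carrier sire x ungenotyped dam whose sire (the maternal
#'   grandsire) is a carrier; a genotyped non-carrier dam excludes the mating
#'   even when the grandsire is carrier, and a genotyped carrier dam belongs
#'   to risk1 only;
#' * `non-risk`: non-carrier sire with the same dam groups (carrier dam, or
#'   ungenotyped dam with carrier maternal grandsire);
#' * `none`: everything else.
#'
#' Independently, each mating gets a sire-level group (`carrier-sire`,
#' `non-carrier-sire`, `unknown-sire`); matings whose sire has unknown status
#' are excluded from all contrasts.
#'
#' @param matings data.frame with `sire_id`, `dam_id`, `date`.
#' @param carrier_status data.frame with `animal_id`, `status` in
#'   `c("non-carrier", "carrier", "homozygous", "unknown")`.
#' @param pedigree data.frame with `animal_id`, `sire_id`, `dam_id` (used for
#'   the maternal grandsire).
#' @return `matings` with added `risk_category` and `sire_group` columns.
#' @export
classify_matings <- function(matings, carrier_status, pedigree) {
  status_of <- function(ids) {
    s <- carrier_status$status[match(ids, carrier_status$animal_id)]
    s[is.na(s)] <- "unknown"
    s
  }
  is_carrier <- function(s) s %in% c("carrier", "homozygous")

  sire_s <- status_of(matings$sire_id)
  dam_s <- status_of(matings$dam_id)
  mgs <- pedigree$sire_id[match(matings$dam_id, pedigree$animal_id)]
  mgs_s <- status_of(mgs)

  sire_group <- ifelse(sire_s == "unknown", "unknown-sire",
                       ifelse(is_carrier(sire_s), "carrier-sire",
                              "non-carrier-sire"))

  dam_risk <- ifelse(is_carrier(dam_s), "dam",
                     ifelse(dam_s == "unknown" & is_carrier(mgs_s), "mgs",
                            "none"))
  risk <- rep("none", nrow(matings))
  risk[sire_group == "carrier-sire" & dam_risk == "dam"] <- "risk1"
  risk[sire_group == "carrier-sire" & dam_risk == "mgs"] <- "risk2"
  risk[sire_group == "non-carrier-sire" & dam_risk != "none"] <- "non-risk"
  risk[sire_group == "unknown-sire"] <- "excluded"

  matings$risk_category <- risk
  matings$sire_group <- sire_group
  matings
}

#' Collapse re-matings and measure insemination success
#'
#' Matings of the same sire-dam pair within `remating_window` days of the
#' previous mating in the chain are collapsed into one insemination event
#' that keeps the first date (chains are transitive). An event succeeds iff
#' at least one foal of the dam is attributable to it: the foal's birth lies
#' `gestation[1]`-`gestation[2]` days after the event date, and a foal is
#' attributed to the latest such event of its dam.
#'
#' @param matings data.frame with `sire_id`, `dam_id`, `date` (numeric days).
#' @param foals data.frame with `foal_id`, `dam_id`, `birth_date`.
#' @param remating_window collapse window in days (re-mating at day 11 is a
#'   separate event).
#' @param gestation attribution interval in days around a 340-day gestation.
#' @return list with `successes`, `n` (number of events) and the per-event
#'   data.frame `events` (sire_id, dam_id, date, success).
#' @export
insemination_success <- function(matings, foals, remating_window = 10,
                                 gestation = c(300, 400)) {
  if (!nrow(matings))
    return(list(successes = 0L, n = 0L,
                events = data.frame(sire_id = character(),
                                    dam_id = character(), date = numeric(),
                                    success = logical())))
  o <- order(matings$sire_id, matings$dam_id, matings$date)
  m <- matings[o, , drop = FALSE]
  pair <- paste(m$sire_id, m$dam_id, sep = "\r")
  new_event <- c(TRUE, pair[-1] != pair[-nrow(m)] |
                   diff(m$date) > remating_window)
  event_id <- cumsum(new_event)
  events <- m[new_event, c("sire_id", "dam_id", "date"), drop = FALSE]
  rownames(events) <- NULL

  events$success <- FALSE
  if (nrow(foals)) {
    ev_by_dam <- split(seq_len(nrow(events)), events$dam_id)
    for (i in seq_len(nrow(foals))) {
      cand <- ev_by_dam[[foals$dam_id[i]]]
      if (is.null(cand)) next
      lag <- foals$birth_date[i] - events$date[cand]
      ok <- cand[lag >= gestation[1] & lag <= gestation[2]]
      if (length(ok))
        events$success[ok[which.max(events$date[ok])]] <- TRUE
    }
  }
  list(successes = sum(events$success), n = nrow(events), events = events)
}

#' Stillbirth rate
#'
#' A foal counts as stillborn when its dead-at-birth flag is set or its death
#' date equals its birth date; the denominator is all foals.
#'
#' @param foals data.frame with `birth_date`, `dead_at_birth`, `death_date`.
#' @return list with `stillbirths` and `n`.
#' @export
stillbirth_rate <- function(foals) {
  sb <- foals$dead_at_birth == 1 |
    (!is.na(foals$death_date) & foals$death_date == foals$birth_date)
  list(stillbirths = sum(sb), n = nrow(foals))
}

#' Juvenile mortality
#'
#' A foal counts when it died within 365 days of birth; day-0 deaths
#' (stillbirths) are included, since every case of death counts. The
#' denominator is all foals.
#'
#' @param foals data.frame with `birth_date`, `dead_at_birth`, `death_date`.
#' @return list with `deaths` and `n`.
#' @export
juvenile_mortality <- function(foals) {
  dd <- ifelse(foals$dead_at_birth == 1 & is.na(foals$death_date),
               foals$birth_date, foals$death_date)
  dead <- !is.na(dd) & dd - foals$birth_date <= 365
  list(deaths = sum(dead), n = nrow(foals))
}

#' Two-proportion z-test (pooled variance, two-tailed)
#'
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with `p` the pooled
#' proportion; `p-value = 2 * pnorm(-|z|)`. When the pooled variance is zero
#' (all failures or all successes in both groups) the p-value is 1 by
#' convention.
#'
#' @param x1,n1 successes and size of group 1.
#' @param x2,n2 successes and size of group 2.
#' @return list with `z` and `p_value`.
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  p_pool <- (x1 + x2) / (n1 + n2)
  v <- p_pool * (1 - p_pool) * (1 / n1 + 1 / n2)
  if (v == 0) return(list(z = 0, p_value = 1))
  z <- (x1 / n1 - x2 / n2) / sqrt(v)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Relative difference between two rates, in percent
#'
#' `(rate_ref - rate_cmp) / rate_ref * 100`: e.g. a reference insemination
#' success of 76.4% and a comparison of 47.2% is a 38.2% relative reduction.
#'
#' @param rate_ref reference rate (> 0).
#' @param rate_cmp comparison rate.
#' @return relative difference in percent.
#' @export
relative_difference <- function(rate_ref, rate_cmp) {
  if (any(rate_ref <= 0)) stop("rate_ref must be > 0")
  (rate_ref - rate_cmp) / rate_ref * 100
}

#' Expected insemination-success reduction for carrier-sire matings
#'
#' Under full embryonic lethality, a carrier sire mated to a random dam loses
#' `0.5 * 0.5 * carrier_freq` of conceptions: the dam is a carrier with the
#' population carrier frequency and a carrier-by-carrier conception is
#' homozygous with probability 1/4.
#'
#' @param carrier_freq population carrier frequency in [0, 1].
#' @return expected relative reduction in percent.
#' @export
expected_sire_reduction <- function(carrier_freq) {
  stopifnot(all(carrier_freq >= 0 & carrier_freq <= 1))
  0.25 * carrier_freq * 100
}

#' Compare semen-quality parameters between carrier and non-carrier sires
#'
#' Two-sided Wilcoxon rank-sum test per parameter with a Bonferroni
#' correction across parameters; medians and interquartile ranges are
#' reported per group. A parameter with an empty group is skipped with a
#' warning.
#'
#' @param values named list (one element per parameter) of numeric vectors,
#'   one value per sire, aligned with `carrier_flags`.
#' @param carrier_flags logical vector, `TRUE` for carrier sires.
#' @return data.frame with per-parameter group medians, IQRs, raw and
#'   Bonferroni-adjusted p-values.
#' @export
compare_semen_quality <- function(values, carrier_flags) {
  stopifnot(is.list(values), length(values) >= 1)
  rows <- lapply(names(values), function(par) {
    v <- values[[par]]
    stopifnot(length(v) == length(carrier_flags))
    keep <- !is.na(v)
    car <- v[keep & carrier_flags]
    non <- v[keep & !carrier_flags]
    if (!length(car) || !length(non)) {
      warning("parameter '", par, "' skipped: one group is empty")
      return(NULL)
    }
    wt <- stats::wilcox.test(car, non, exact = NULL)
    data.frame(
      parameter = par,
      median_carrier = stats::median(car),
      iqr_carrier = stats::IQR(car),
      median_noncarrier = stats::median(non),
      iqr_noncarrier = stats::IQR(non),
      p_value = wt$p.value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no parameter had both groups populated")
  out$p_adj <- pmin(1, out$p_value * nrow(out))
  rownames(out) <- NULL
  out
}

#' Phenotype contrasts per mating category for one region
#'
#' Computes, for each category (risk1, risk2, non-risk, carrier-sire,
#' non-carrier-sire), the three phenotypes, and contrasts risk1 and risk2
#' against non-risk and carrier-sire against non-carrier-sire with the
#' two-proportion z-test and the relative difference in percent.
#'
#' @param matings classified matings from [classify_matings()].
#' @param foals foal records.
#' @param remating_window,gestation passed to [insemination_success()].
#' @return list with `categories` (per-category counts and rates) and
#'   `contrasts` (per phenotype and comparison: rates, relative difference,
#'   z, p).
#' @export
mating_category_table <- function(matings, foals, remating_window = 10,
                                  gestation = c(300, 400)) {
  stopifnot(all(c("risk_category", "sire_group") %in% names(matings)))
  groups <- list(
    risk1 = matings$risk_category == "risk1",
    risk2 = matings$risk_category == "risk2",
    `non-risk` = matings$risk_category == "non-risk",
    `carrier-sire` = matings$sire_group == "carrier-sire",
    `non-carrier-sire` = matings$sire_group == "non-carrier-sire"
  )
  per_group <- lapply(names(groups), function(gname) {
    sub <- matings[groups[[gname]], , drop = FALSE]
    ins <- insemination_success(sub, foals, remating_window, gestation)
    ## foals of this group: attributable to a successful event
    ev <- ins$events[ins$events$success, , drop = FALSE]
    fsub <- foals[paste(foals$sire_id, foals$dam_id) %in%
                    paste(ev$sire_id, ev$dam_id) &
                    foals$dam_id %in% ev$dam_id, , drop = FALSE]
    ## keep only foals whose birth matches an event of the group
    if (nrow(fsub)) {
      keep <- vapply(seq_len(nrow(fsub)), function(i) {
        lag <- fsub$birth_date[i] -
          ev$date[ev$dam_id == fsub$dam_id[i] & ev$sire_id == fsub$sire_id[i]]
        any(lag >= gestation[1] & lag <= gestation[2])
      }, logical(1))
      fsub <- fsub[keep, , drop = FALSE]
    }
    sb <- stillbirth_rate(fsub)
    jm <- juvenile_mortality(fsub)
    data.frame(
      category = gname,
      n_matings = ins$n, n_success = ins$successes,
      insemination_success = if (ins$n) ins$successes / ins$n else NA_real_,
      n_foals = sb$n, n_stillbirths = sb$stillbirths,
      stillbirth_rate = if (sb$n) sb$stillbirths / sb$n else NA_real_,
      n_juvenile_deaths = jm$deaths,
      juvenile_mortality = if (jm$n) jm$deaths / jm$n else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  categories <- do.call(rbind, per_group)

  comparisons <- list(
    c("risk1", "non-risk"), c("risk2", "non-risk"),
    c("carrier-sire", "non-carrier-sire")
  )
  phenos <- list(
    insemination_success = c("n_success", "n_matings"),
    stillbirth_rate = c("n_stillbirths", "n_foals"),
    juvenile_mortality = c("n_juvenile_deaths", "n_foals")
  )
  rows <- list()
  for (cmp in comparisons) {
    a <- categories[categories$category == cmp[1], ]
    b <- categories[categories$category == cmp[2], ]
    for (ph in names(phenos)) {
      xa <- a[[phenos[[ph]][1]]]; na <- a[[phenos[[ph]][2]]]
      xb <- b[[phenos[[ph]][1]]]; nb <- b[[phenos[[ph]][2]]]
      if (!na || !nb) next
      zt <- two_proportion_ztest(xa, na, xb, nb)
      ## for success the reference is the non-risk/non-carrier group; for the
      ## mortality phenotypes the comparison group rate is reported relative
      ## to the same reference
      ref <- xb / nb; val <- xa / na
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste(cmp[1], "vs", cmp[2]),
        phenotype = ph,
        rate_cmp = val, rate_ref = ref,
        delta_rel_pct = if (ref > 0) relative_difference(ref, val) else NA_real_,
        z = zt$z, p_value = zt$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  contrasts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(comparison = character(), phenotype = character(),
               rate_cmp = numeric(), rate_ref = numeric(),
               delta_rel_pct = numeric(), z = numeric(), p_value = numeric())
  list(categories = categories, contrasts = contrasts)
}
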