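# Resident-parent contribution inference. A parentage slot left NONE after
# assignment against the complete anadromous candidate pool is read as a
# resident parent (the trap samples all ascending anadromous spawners, so
# an absent parent was not anadromous). Offspring are classified AA / RA /
# AR / RR by the life-history origin of father x mother.

#' Classify offspring by parental life-history origin
#'
#' Unassigned mothers/fathers are treated as resident. Categories: `AA`
#' both parents anadromous, `RA` resident father x anadromous mother, `AR`
#' anadromous father x resident mother, `RR` both resident. Wilson 95%
#' intervals accompany the category percentages, and within each sex the
#' anadromous-vs-resident contribution is compared to a 1:1 split with a
#' two-sided binomial test.
#'
#' @param parentage A `parentage_result` (or tibble with `id`, `mother`,
#'   `father`).
#' @param conf Confidence level for the Wilson intervals.
#' @return A `contribution_summary` list: `categories` (tibble with counts,
#'   percentages, CI bounds), `by_sex` (anadromous/resident counts per
#'   parental sex with binomial p), `percent_at_least_one_resident`,
#'   `percent_mixed_female_anadromous` (share of mixed matings that pair an
#'   anadromous mother with a resident father), `n`.
#' @export
classify_parental_origin <- function(parentage, conf = 0.95) {
  if (nrow(parentage) == 0) stop("empty offspring set")
  mother_res <- is.na(parentage$mother)
  father_res <- is.na(parentage$father)
  category <- dplyr::case_when(
    !father_res & !mother_res ~ "AA",
    father_res & !mother_res ~ "RA",
    !father_res & mother_res ~ "AR",
    TRUE ~ "RR"
  )
  n <- length(category)
  cats <- c("AA", "RA", "AR", "RR")
  counts <- vapply(cats, function(cc) sum(category == cc), integer(1))
  ci <- t(vapply(counts, wilson_ci, numeric(2), n = n, conf = conf))
  categories <- tibble::tibble(
    category = cats, count = unname(counts),
    percent = 100 * unname(counts) / n,
    ci_lo = 100 * unname(ci[, 1]), ci_hi = 100 * unname(ci[, 2])
  )
  n_mixed <- counts["RA"] + counts["AR"]
  by_sex <- tibble::tibble(
    parent_sex = c("female", "male"),
    anadromous = c(sum(!mother_res), sum(!father_res)),
    resident = c(sum(mother_res), sum(father_res))
  )
  by_sex$percent_anadromous <- 100 * by_sex$anadromous / n
  by_sex$binom_p <- vapply(seq_len(2), function(i) {
    stats::binom.test(by_sex$anadromous[i], n, p = 0.5)$p.value
  }, numeric(1))

  structure(list(
    categories = categories,
    by_sex = by_sex,
    percent_at_least_one_resident =
      unname(100 * (counts["RA"] + counts["AR"] + counts["RR"]) / n),
    percent_mixed_female_anadromous =
      if (n_mixed > 0) unname(100 * counts["RA"] / n_mixed) else NA_real_,
    n = n
  ), class = "contribution_summary")
}

#' @export
print.contribution_summary <- function(x, ...) {
  cat("<contribution_summary> n =", x$n, "\n")
  for (i in seq_len(nrow(x$categories))) {
    cat(sprintf("  %s: %5.1f%% (%.1f-%.1f)\n", x$categories$category[i],
                x$categories$percent[i], x$categories$ci_lo[i],
                x$categories$ci_hi[i]))
  }
  cat(sprintf("  >=1 resident parent: %.1f%%; mixed matings with anadromous mother: %.1f%%\n",
              x$percent_at_least_one_resident, x$percent_mixed_female_anadromous))
  invisible(x)
}

#' Validate final-year parents against earlier capture years
#'
#' Parents assigned to an offspring cohort that could not result from the
#' final monitored spawning season should, if genuinely parents, also have
#' ascended in an earlier year. For each assigned parent whose capture
#' years include `final_year`, the predicate passes iff it also has a
#' capture year before `final_year`.
#'
#' @param parentage A `parentage_result`.
#' @param meta Captures tibble covering the candidate parents.
#' @param final_year The last adult monitoring year.
#' @return Tibble: `parent`, `sex_role` (mother/father), `years` (list),
#'   `passes`.
#' @export
validate_final_year_parents <- function(parentage, meta, final_year) {
  assigned <- dplyr::bind_rows(
    tibble::tibble(parent = parentage$mother, sex_role = "mother"),
    tibble::tibble(parent = parentage$father, sex_role = "father")
  )
  assigned <- dplyr::distinct(dplyr::filter(assigned, !is.na(.data$parent)))
  yrs <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(meta, .data$id %in% assigned$parent), .data$id),
    years = list(sort(unique(.data$year))), .groups = "drop")
  out <- dplyr::left_join(assigned, yrs, by = c(parent = "id"))
  out <- dplyr::filter(out, purrr::map_lgl(.data$years, ~ final_year %in% .x))
  out$passes <- purrr::map_lgl(out$years, ~ any(.x < final_year))
  out
}

#' Census trend by ordinary least squares
#'
#' Regresses per-year counts on year and reports the slope, F statistic,
#' adjusted R-squared and p-value.
#'
#' @param counts Tibble with columns `year` and `count` (>= 3 years).
#' @return One-row tibble: `slope`, `f_statistic`, `df1`, `df2`,
#'   `adj_r_squared`, `p`.
#' @export
census_trend <- function(counts) {
  stopifnot(all(c("year", "count") %in% names(counts)), nrow(counts) >= 3)
  if (all(counts$count == counts$count[1])) {
    return(tibble::tibble(slope = 0, f_statistic = 0, df1 = 1,
                          df2 = nrow(counts) - 2, adj_r_squared = 0, p = 1))
  }
  fit <- stats::lm(count ~ year, data = counts)
  sm <- summary(fit)
  f <- sm$fstatistic
  tibble::tibble(
    slope = unname(stats::coef(fit)["year"]),
    f_statistic = unname(f[1]), df1 = unname(f[2]), df2 = unname(f[3]),
    adj_r_squared = sm$adj.r.squared,
    p = stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
  )
}

#' Chi-squared tests on yearly sex ratios
#'
#' Two complementary views of a female-biased run: `gof_sum` sums per-year
#' goodness-of-fit chi-squared statistics against a 1:1 ratio (df = number
#' of years); `contingency` is the year x sex heterogeneity test
#' (df = years - 1). Both are computed; `mode` selects the headline row.
#'
#' @param counts Tibble with columns `year`, `females`, `males`.
#' @param mode `"gof_sum"` or `"contingency"`.
#' @return Tibble with one row per computed test: `test`, `chisq`, `df`,
#'   `p`, `headline`. Years with zero total are excluded.
#' @export
sex_ratio_test <- function(counts, mode = c("gof_sum", "contingency")) {
  mode <- match.arg(mode)
  stopifnot(all(c("year", "females", "males") %in% names(counts)))
  keep <- counts$females + counts$males > 0
  counts <- counts[keep, ]
  f <- counts$females; m <- counts$males
  tot <- f + m
  gof <- sum((f - tot / 2)^2 / (tot / 2) + (m - tot / 2)^2 / (tot / 2))
  gof_df <- nrow(counts)
  res <- tibble::tibble(
    test = "gof_sum", chisq = gof, df = gof_df,
    p = stats::pchisq(gof, gof_df, lower.tail = FALSE)
  )
  if (nrow(counts) > 1) {
    ct <- suppressWarnings(stats::chisq.test(cbind(f, m), correct = FALSE))
    res <- dplyr::bind_rows(res, tibble::tibble(
      test = "contingency", chisq = unname(ct$statistic),
      df = unname(ct$parameter), p = ct$p.value))
  }
  res$headline <- res$test == mode
  res
}
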