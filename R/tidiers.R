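# broom-style accessors for the package's result objects

#' @export
tidy.ne_estimate <- function(x, ...) {
  tibble::tibble(
    term = c("ne", "r2_mean", "r2_expected", "r2_drift"),
    estimate = c(x$ne_point, x$r2_mean, x$r2_expected, x$r2_drift),
    conf.low = c(x$ci_low, NA, NA, NA),
    conf.high = c(x$ci_high, NA, NA, NA)
  )
}

#' @export
glance.ne_estimate <- function(x, ...) {
  tibble::as_tibble(x)[, c("ne_point", "ci_low", "ci_high", "harmonic_mean_s",
                           "n_locus_pairs", "n_comparisons")]
}

#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(term = "mantel_r", estimate = x$r, p.value = x$p,
                 conf.low = x$boot_lo, conf.high = x$boot_hi)
}

#' @export
glance.mantel_result <- function(x, ...) {
  tibble::as_tibble(x)[, c("r", "p", "n", "n_perm", "pct_fullsib",
                           "pct_halfsib", "pct_unrelated")]
}

#' @export
tidy.contribution_summary <- function(x, ...) {
  dplyr::rename(x$categories, term = "category", estimate = "percent",
                conf.low = "ci_lo", conf.high = "ci_hi")
}

#' @export
glance.contribution_summary <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    percent_at_least_one_resident = x$percent_at_least_one_resident,
    percent_two_resident = x$categories$percent[x$categories$category == "RR"],
    percent_mixed_female_anadromous = x$percent_mixed_female_anadromous
  )
}

#' @export
tidy.sibship_partition <- function(x, ...) x$families

#' @export
glance.sibship_partition <- function(x, ...) {
  sz <- table(x$families$family)
  tibble::tibble(
    n_individuals = nrow(x$families),
    n_families = length(sz),
    n_nonsingleton_families = sum(sz > 1),
    mean_family_size = mean(sz),
    max_family_size = max(sz),
    n_fullsib_dyads = sum(choose(sz, 2)),
    n_halfsib_dyads = nrow(x$halfsib_pairs)
  )
}

#' @export
tidy.parentage_result <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.parentage_result <- function(x, ...) {
  tibble::tibble(
    n_offspring = nrow(x),
    n_mother_assigned = sum(!is.na(x$mother)),
    n_father_assigned = sum(!is.na(x$father)),
    n_unique_mothers = dplyr::n_distinct(x$mother, na.rm = TRUE),
    n_unique_fathers = dplyr::n_distinct(x$father, na.rm = TRUE)
  )
}
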