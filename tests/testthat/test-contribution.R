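parentage_from_counts <- function(n_aa, n_ra, n_ar, n_rr) {
  # RA = resident father x anadromous mother; AR = the reverse
  n <- n_aa + n_ra + n_ar + n_rr
  tibble::tibble(
    id = sprintf("S%04d", seq_len(n)),
    mother = c(sprintf("M%04d", seq_len(n_aa + n_ra)), rep(NA, n_ar + n_rr)),
    father = c(sprintf("F%04d", seq_len(n_aa)), rep(NA, n_ra),
               sprintf("F9%03d", seq_len(n_ar)), rep(NA, n_rr))
  )
}

test_that("fully assigned offspring are all AA with no resident share", {
  cs <- classify_parental_origin(parentage_from_counts(40, 0, 0, 0))
  expect_equal(cs$categories$percent[cs$categories$category == "AA"], 100)
  expect_equal(cs$percent_at_least_one_resident, 0)
  expect_error(classify_parental_origin(parentage_from_counts(0, 0, 0, 0)),
               "empty")
})

test_that("category counts always partition the offspring set", {
  set.seed(55)
  for (rep in 1:20) {
    k <- as.integer(rmultinom(1, 200, runif(4)))
    cs <- classify_parental_origin(parentage_from_counts(k[1], k[2], k[3], k[4]))
    expect_equal(sum(cs$categories$count), 200)
    expect_equal(sum(cs$categories$percent), 100)
    expect_equal(cs$percent_at_least_one_resident,
                 100 * sum(k[2:4]) / 200)
    if (k[2] + k[3] > 0)
      expect_equal(cs$percent_mixed_female_anadromous,
                   100 * k[2] / (k[2] + k[3]))
  }
})

test_that("published-style category structure reproduces the derived shares", {
  # categories at 30% / 42% / 4% / 24% of an 851-smolt run imply 70%
  # with at least one resident parent and 91% of mixed matings pairing
  # an anadromous mother with a resident father
  counts <- utils::read.csv(system.file("extdata", "parental_origin_counts.csv",
                                        package = "smoltkin"))
  cs <- classify_parental_origin(parentage_from_counts(
    counts$count[counts$category == "AA"], counts$count[counts$category == "RA"],
    counts$count[counts$category == "AR"], counts$count[counts$category == "RR"]))
  expect_equal(cs$n, 851)
  expect_equal(round(cs$percent_at_least_one_resident), 70)
  expect_equal(round(cs$percent_mixed_female_anadromous), 91)
  expect_lt(cs$by_sex$binom_p[cs$by_sex$parent_sex == "male"], 0.001)
})

test_that("simulated resident rates are recovered through the full chain", {
  pop <- small_study_pop(seed = 23, noise = FALSE, n_families = 60)
  smolts <- smolt_geno_of(pop)
  adults <- dplyr::filter(pop$parents, .data$life_history == "anadromous")
  res <- assign_parentage(smolts, adult_geno_of(pop), adults, eps = 1e-4)
  cs <- classify_parental_origin(res)
  tr <- pop$truth
  true_pct <- 100 * mean(tr$mother_life_history == "resident" |
                           tr$father_life_history == "resident")
  expect_lt(abs(cs$percent_at_least_one_resident - true_pct), 5)
  true_rr <- 100 * mean(tr$mother_life_history == "resident" &
                          tr$father_life_history == "resident")
  expect_lt(abs(cs$categories$percent[cs$categories$category == "RR"] - true_rr), 5)
})

test_that("removing parents from the pool only moves offspring toward resident", {
  pop <- small_study_pop(seed = 24, noise = FALSE, n_families = 40)
  smolts <- smolt_geno_of(pop)
  adults <- dplyr::filter(pop$parents, .data$life_history == "anadromous")
  full <- classify_parental_origin(
    assign_parentage(smolts, adult_geno_of(pop), adults, eps = 1e-4))
  set.seed(66)
  drop <- sample(adults$id, nrow(adults) %/% 3)
  reduced_pool <- dplyr::filter(adults, !(.data$id %in% drop))
  reduced <- classify_parental_origin(
    assign_parentage(smolts,
                     dplyr::filter(adult_geno_of(pop), !(.data$id %in% drop)),
                     reduced_pool, eps = 1e-4))
  expect_gte(reduced$percent_at_least_one_resident,
             full$percent_at_least_one_resident)
})

test_that("final-year validation passes returners and flags one-off parents", {
  meta <- tibble::tibble(
    id = c("P1", "P1", "P2", "P3", "P3"),
    capture_date = as.Date(c("2014-08-01", "2016-08-10", "2016-08-05",
                             "2013-08-01", "2015-08-01")),
    trap = "upstream", sex = "female", stage = "anadromous_adult",
    year = c(2014L, 2016L, 2016L, 2013L, 2015L)
  )
  parentage <- tibble::tibble(id = c("S1", "S2", "S3"),
                              mother = c("P1", "P2", "P3"),
                              father = NA_character_)
  v <- validate_final_year_parents(parentage, meta, final_year = 2016)
  expect_setequal(v$parent, c("P1", "P2"))   # P3 never seen in 2016
  expect_true(v$passes[v$parent == "P1"])
  expect_false(v$passes[v$parent == "P2"])
})

test_that("final-year validation flags exactly injected violations at scale", {
  pop <- small_study_pop(seed = 26, noise = FALSE, n_families = 40)
  smolts <- smolt_geno_of(pop)
  adults <- dplyr::filter(pop$parents, .data$life_history == "anadromous")
  res <- assign_parentage(smolts, adult_geno_of(pop), adults, eps = 1e-4)
  meta <- pop$meta
  # every simulated parent spawned in 2012-2014; graft a 2016-only capture
  # history onto some assigned parents to inject violations
  assigned <- stats::na.omit(unique(c(res$mother, res$father)))
  inject <- utils::head(sort(assigned), 3)
  meta2 <- dplyr::filter(meta, !(.data$id %in% inject))
  meta2 <- dplyr::bind_rows(meta2, tibble::tibble(
    id = inject, capture_date = as.Date("2016-08-15"), trap = "upstream",
    sex = "female", stage = "anadromous_adult", year = 2016L))
  v <- validate_final_year_parents(res, meta2, final_year = 2016)
  expect_setequal(v$parent[!v$passes], inject)
})

test_that("census trend matches an independent least-squares evaluation", {
  up <- tibble::tibble(year = 2006:2016, count = 10 + 3 * (0:10))
  tr <- census_trend(up)
  expect_gt(tr$slope, 0)
  expect_lt(tr$p, 1e-10)

  flat <- tibble::tibble(year = 2006:2016, count = rep(42, 11))
  tr0 <- census_trend(flat)
  expect_equal(tr0$slope, 0)
  expect_equal(tr0$f_statistic, 0)

  set.seed(77)
  base <- c(86, 37, 89, 82, 28, 73, 56, 41, 60, 99, 89)
  for (rep in 1:11) {
    cnt <- tibble::tibble(year = 2006:2016, count = sample(base))
    tr <- census_trend(cnt)
    # independent route: normal equations
    X <- cbind(1, cnt$year)
    beta <- solve(crossprod(X), crossprod(X, cnt$count))
    res2 <- cnt$count - X %*% beta
    rss <- sum(res2^2)
    tss <- sum((cnt$count - mean(cnt$count))^2)
    f <- (tss - rss) / (rss / 9)
    expect_equal(tr$slope, beta[2], tolerance = 1e-8)
    expect_equal(tr$f_statistic, f, tolerance = 1e-8)
    expect_equal(tr$adj_r_squared, 1 - (rss / 9) / (tss / 10), tolerance = 1e-8)
  }
})

test_that("sex-ratio tests implement both chi-squared modes", {
  even <- tibble::tibble(year = 2016, females = 50, males = 50)
  res <- sex_ratio_test(even)
  expect_equal(res$chisq[res$test == "gof_sum"], 0)

  skew <- tibble::tibble(year = 2016, females = 30, males = 10)
  res <- sex_ratio_test(skew)
  expect_equal(res$chisq[res$test == "gof_sum"], 10)   # (10^2+10^2)/20
  expect_equal(res$df[res$test == "gof_sum"], 1)

  multi <- tibble::tibble(year = 2006:2016,
                          females = c(49, 22, 48, 55, 16, 35, 29, 20, 34, 52, 51),
                          males = c(34, 12, 31, 26, 9, 28, 24, 19, 24, 44, 36))
  res <- sex_ratio_test(multi, mode = "contingency")
  expect_equal(res$df[res$test == "gof_sum"], 11)
  expect_equal(res$df[res$test == "contingency"], 10)
  expect_true(res$headline[res$test == "contingency"])

  # size under equal ratios
  set.seed(88)
  rej <- replicate(300, {
    f <- rbinom(11, 60, 0.5)
    r <- sex_ratio_test(tibble::tibble(year = 2006:2016, females = f,
                                       males = 60 - f))
    r$p[r$test == "gof_sum"] <= 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.04)
})
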