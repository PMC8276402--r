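toy_partition <- function(families, halfsibs = NULL) {
  ids <- names(families)
  structure(list(
    families = tibble::tibble(id = ids, family = unname(unlist(families))),
    halfsib_pairs = if (is.null(halfsibs))
      tibble::tibble(id_a = character(), id_b = character()) else halfsibs,
    run_comembership = list(), seeds = integer()
  ), class = "sibship_partition")
}

test_that("kinship distances use the 1 / 0.75 / 0.5 coding and drop loners", {
  # all singletons: nothing retained
  part <- toy_partition(c(A = 1, B = 2, C = 3))
  M <- kinship_distance_matrix(part)
  expect_equal(nrow(M), 0)
  expect_setequal(attr(M, "dropped"), c("A", "B", "C"))

  # one FS pair plus a third linked by a half-sib edge to one of them
  part <- toy_partition(c(A = 1, B = 1, C = 2),
                        halfsibs = tibble::tibble(id_a = "A", id_b = "C"))
  M <- kinship_distance_matrix(part)
  expect_equal(sort(rownames(M)), c("A", "B", "C"))
  expect_equal(M["A", "B"], 0.5)
  expect_equal(M["A", "C"], 0.75)
  expect_equal(M["B", "C"], 1)
  expect_equal(diag(M), c(A = 0, B = 0, C = 0))
})

test_that("timing distances respect the unit definitions", {
  meta <- tibble::tibble(
    id = c("A", "B", "C"),
    capture_date = as.Date(c("2017-06-01", "2017-06-01", "2017-06-08")),
    trap = "downstream", sex = "unknown", stage = "smolt", year = 2017L
  )
  M <- timing_distance_matrix(meta, unit = "days")
  expect_equal(M["A", "B"], 0)
  expect_equal(M["A", "C"], 7)

  # week index is floor(day-of-year / 7)
  dates <- as.Date("2017-01-01") + c(0, 6, 7, 13, 14, 100, 140, 200, 250, 300)
  meta10 <- tibble::tibble(id = paste0("I", 1:10), capture_date = dates,
                           trap = "downstream", sex = "unknown",
                           stage = "smolt", year = 2017L)
  Mw <- timing_distance_matrix(meta10, unit = "weeks")
  doy <- as.integer(strftime(dates, "%j"))
  expect_equal(unname(Mw), abs(outer(doy %/% 7L, doy %/% 7L, "-")),
               ignore_attr = TRUE)
})

test_that("mantel r is 1 against itself and invariant to joint reordering", {
  set.seed(91)
  n <- 12
  D <- as.matrix(stats::dist(stats::runif(n)))
  dimnames(D) <- list(paste0("I", 1:n), paste0("I", 1:n))
  res <- mantel_test(D, D, n_perm = 99, n_boot = 0, seed = 1)
  expect_equal(res$r, 1)

  B <- as.matrix(stats::dist(stats::rnorm(n)))
  dimnames(B) <- dimnames(D)
  r1 <- mantel_test(D, B, n_perm = 99, n_boot = 0, seed = 1)$r
  p <- sample(n)
  r2 <- mantel_test(D[p, p], B[p, p], n_perm = 99, n_boot = 0, seed = 1)$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("sampled permutation p agrees with exact enumeration on small n", {
  set.seed(92)
  for (rep in 1:3) {
    n <- 5
    A <- as.matrix(stats::dist(stats::runif(n)))
    B <- as.matrix(stats::dist(stats::runif(n)))
    dimnames(A) <- dimnames(B) <- list(paste0("I", 1:n), paste0("I", 1:n))
    exact <- mantel_test(A, B, exact = TRUE, n_boot = 0)
    samp <- mantel_test(A, B, n_perm = 10000, n_boot = 0, seed = rep)
    se <- sqrt(exact$p * (1 - exact$p) / 10000)
    expect_lt(abs(samp$p - exact$p), 3 * se + 1e-4)
  }
  A9 <- as.matrix(stats::dist(1:9))
  dimnames(A9) <- list(paste0("I", 1:9), paste0("I", 1:9))
  expect_error(mantel_test(A9, A9, exact = TRUE), "n <= 7")
})

test_that("mantel r agrees with an independent implementation", {
  set.seed(93)
  n <- 20
  A <- as.matrix(stats::dist(stats::runif(n)))
  B <- as.matrix(stats::dist(0.4 * stats::runif(n) + 0.6 * A[1, ]))
  dimnames(A) <- dimnames(B) <- list(paste0("I", 1:n), paste0("I", 1:n))
  mine <- mantel_test(A, B, n_perm = 999, n_boot = 0, seed = 3)
  ref <- vegan::mantel(A, B, permutations = 999)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-10)
  expect_lt(abs(mine$p - ref$signif), 0.05)
})

test_that("degenerate matrices are signalled", {
  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_error(mantel_test(Z, Z), "zero-variance")
  A <- as.matrix(stats::dist(1:2))
  dimnames(A) <- list(c("a", "b"), c("a", "b"))
  expect_error(mantel_test(A, A), "at least 3")
  B <- matrix(0, 4, 4, dimnames = list(letters[5:8], letters[5:8]))
  expect_error(mantel_test(Z, B), "identical id dimnames")
})

test_that("family-correlated timing produces positive r that grows with the signal", {
  mean_r <- vapply(c(0, 6, 14), function(fsd) {
    rs <- vapply(1:25, function(s) {
      co <- timing_cohort(1000 * fsd + s, n_fam = 14, mean_size = 3,
                          family_date_sd = fsd, within_sd = 4)
      mk <- kinship_distance_matrix(co$partition)
      if (nrow(mk) < 3) return(NA_real_)
      mt <- timing_distance_matrix(co$meta, ids = rownames(mk), unit = "days")
      mantel_test(mk, mt[rownames(mk), rownames(mk)],
                  n_perm = 2, n_boot = 0, seed = s)$r
    }, numeric(1))
    mean(rs, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
  expect_gt(mean_r[3], 0.2)
})

test_that("the permutation test holds its size under the null", {
  # timing independent of kinship; moderate replicate count here, the
  # full calibration lives in the acceptance suite
  rej <- vapply(1:120, function(s) {
    co <- timing_cohort(s, n_fam = 12, mean_size = 3, family_date_sd = 0)
    mk <- kinship_distance_matrix(co$partition)
    if (nrow(mk) < 3) return(NA)
    mt <- timing_distance_matrix(co$meta, ids = rownames(mk), unit = "days")
    mantel_test(mk, mt[rownames(mk), rownames(mk)],
                n_perm = 499, n_boot = 0, seed = s)$p <= 0.05
  }, logical(1))
  rate <- mean(rej, na.rm = TRUE)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.11)
})

test_that("the wrapper ties the partition and metadata together", {
  pop <- small_study_pop(seed = 25, n_families = 25)
  smolts <- smolt_geno_of(pop)
  part <- reconstruct_sibships(smolts, eps = 0.01, seed = 4)
  res <- kin_timing_mantel(part, pop$meta, ids = unique(smolts$id),
                           unit = "days", year = 2017,
                           n_perm = 999, n_boot = 99, seed = 5)
  expect_true(res$r > -1 && res$r < 1)
  expect_true(res$p > 0 && res$p <= 1)
  expect_equal(res$pct_fullsib + res$pct_halfsib + res$pct_unrelated, 100)
})
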