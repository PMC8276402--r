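test_that("noise-free offspring are Mendelian-consistent with their parents", {
  pop <- small_study_pop(seed = 2, noise = FALSE, n_families = 20)
  pm <- dplyr::rename(pop$parents_geno, pa1 = "a1", pa2 = "a2")
  for (role in c("mother", "father")) {
    joined <- dplyr::inner_join(
      dplyr::mutate(smolt_geno_of(pop),
                    parent = pop$truth[[role]][match(.data$id, pop$truth$id)]),
      pm, by = c(parent = "id", "locus")
    )
    shares <- joined$a1 == joined$pa1 | joined$a1 == joined$pa2 |
      joined$a2 == joined$pa1 | joined$a2 == joined$pa2
    expect_true(all(shares))
  }
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_anadromous = rep(10, 11), n_resident_females = 10,
                    n_resident_males = 25, n_families = 10)
  p1 <- simulate_population(cfg, seed = 42)
  p2 <- simulate_population(cfg, seed = 42)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$meta, p2$meta)
  expect_identical(p1$truth, p2$truth)
  p3 <- simulate_population(cfg, seed = 43)
  expect_false(identical(p1$genotypes, p3$genotypes))
})

test_that("Mendelian transmission reproduces parental allele frequencies", {
  # law-of-large-numbers oracle: conditional on the realised parents and
  # family sizes, the expected offspring frequency of each allele is the
  # mean parental dosage, and deviations are pure segregation noise
  cfg <- sim_config(n_loci = 6, n_anadromous = rep(60, 3), years = 2012:2014,
                    n_resident_females = 50, n_resident_males = 120,
                    n_families = 1200, offspring_mean = 5,
                    offspring_dispersion = 5,
                    error_rate = 0, dropout_rate = 0, missing_rate = 0)
  pop <- simulate_population(cfg, seed = 9)
  n_off <- nrow(pop$truth)
  expect_gt(n_off, 3000)
  obs <- allele_freqs(smolt_geno_of(pop))
  pg <- dplyr::inner_join(
    pop$parents_geno,
    dplyr::count(tidyr::pivot_longer(pop$truth[, c("mother", "father")],
                                     dplyr::everything(), values_to = "id"),
                 .data$id, name = "weight"),
    by = "id")
  expected <- dplyr::summarise(
    tidyr::pivot_longer(pg, c("a1", "a2"), values_to = "allele"),
    w = sum(.data$weight), .by = c("locus", "allele"))
  expected <- dplyr::mutate(expected, freq_exp = .data$w / sum(.data$w),
                            .by = "locus")
  cmp <- dplyr::inner_join(obs, expected, by = c("locus", "allele"))
  # per-copy transmission variance <= 1/4; 2*n_off copies per locus
  se <- 1 / (2 * sqrt(2 * n_off))
  expect_true(all(abs(cmp$freq - cmp$freq_exp) < 3 * se + 1e-9))
  # and the parental pool itself sits near the founder frequencies
  cmp2 <- dplyr::inner_join(expected, pop$founder_freqs,
                            by = c("locus", "allele"))
  expect_lt(mean(abs(cmp2$freq_exp - cmp2$freq)), 0.02)
})

test_that("genotyping noise behaves per rates and degenerate cases", {
  g <- sim_families(5, 4, founder_freqs_fixture(6, 6), seed = 1)$geno

  expect_equal(apply_genotyping_noise(g, 0, 0, 0, seed = 1), g,
               ignore_attr = TRUE)

  # single-allele registry: miscalls can only reproduce the same allele
  mono <- toy_geno(list(A = list(L1 = c(1, 1)), B = list(L1 = c(1, 1))))
  noised <- apply_genotyping_noise(mono, error_rate = 1, seed = 2,
                                   registry = list(L1 = 1L))
  expect_equal(noised$a1, mono$a1)
  expect_equal(noised$a2, mono$a2)

  # realized miscall fraction within 3 SE of the nominal rate
  big <- sim_families(50, 20, founder_freqs_fixture(18, 8), seed = 3)$geno
  eps <- 0.01
  nz <- apply_genotyping_noise(big, error_rate = eps, seed = 4)
  n_calls <- 2 * nrow(big)
  # a miscall hits a different allele with prob (K-1)/K = 7/8
  expected <- eps * 7 / 8
  changed <- nrow(attr(nz, "noise_log"))
  se <- sqrt(expected * (1 - expected) * n_calls)
  expect_lt(abs(changed - expected * n_calls), 3 * se)
})

test_that("truth export round-trips and matches the simulated counts", {
  pop <- small_study_pop(seed = 4, n_families = 10)
  f <- withr::local_tempfile(fileext = ".json")
  export_truth(pop, f)
  back <- read_truth(f)
  expect_equal(back$seed, pop$seed)
  expect_equal(nrow(back$offspring), nrow(pop$truth))
  expect_equal(back$offspring$mother, pop$truth$mother)
  expect_equal(back$offspring$smolt_date, pop$truth$smolt_date)
  expect_equal(nrow(back$parents), nrow(pop$parents))
})

test_that("family sizes are overdispersed and can reach the configured tail", {
  cfg <- sim_config(n_anadromous = rep(40, 11), n_resident_females = 60,
                    n_resident_males = 150, n_families = 317)
  pop <- simulate_population(cfg, seed = 12)
  sizes <- as.integer(table(pop$truth$family))
  expect_gt(var(sizes), mean(sizes))   # overdispersed vs Poisson
  expect_gt(max(sizes), 15)
  expect_gte(min(sizes), 1)
})

test_that("anadromous sex ratio and smolt dates follow the configuration", {
  cfg <- sim_config(n_anadromous = rep(60, 11), n_resident_females = 60,
                    n_resident_males = 150, n_families = 150)
  pop <- simulate_population(cfg, seed = 6)
  adults <- dplyr::distinct(
    dplyr::filter(pop$meta, .data$stage == "anadromous_adult"),
    .data$id, .data$sex)
  fr <- mean(adults$sex == "female")
  expect_lt(abs(fr - 0.6), 3 * sqrt(0.6 * 0.4 / nrow(adults)))

  # same-family smolts migrate closer together than unrelated smolts
  tr <- pop$truth
  doy <- as.integer(strftime(tr$smolt_date, "%j"))
  fam <- tr$family
  n <- nrow(tr)
  dd <- abs(outer(doy, doy, "-"))
  same <- outer(fam, fam, "==")
  ut <- upper.tri(dd)
  expect_lt(mean(dd[same & ut]), mean(dd[!same & ut]))
})

test_that("impossible mating draws raise an error", {
  cfg <- sim_config(n_anadromous = rep(4, 3), years = 2012:2014,
                    n_resident_females = 0, n_resident_males = 5,
                    p_mother_resident = 1, n_families = 5)
  expect_error(simulate_population(cfg, seed = 1), "no candidate female")
})
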