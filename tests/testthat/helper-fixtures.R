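# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so the suite is deterministic.

# long genotype tibble from a list of id -> list(locus -> c(a1, a2))
toy_geno <- function(calls, loci = NULL) {
  rows <- purrr::imap_dfr(calls, function(gl, id) {
    purrr::imap_dfr(gl, function(al, locus) {
      tibble::tibble(id = id, locus = locus,
                     a1 = al[1], a2 = al[2])
    })
  })
  if (!is.null(loci)) rows$locus <- factor(rows$locus, levels = loci)
  as_geno(rows)
}

# equal or Dirichlet founder frequencies
founder_freqs_fixture <- function(n_loci, k, conc = NULL, seed = 1) {
  loci <- sprintf("L%02d", seq_len(n_loci))
  if (is.null(conc)) {
    fr <- matrix(1 / k, n_loci, k)
  } else {
    set.seed(seed)
    fr <- matrix(stats::rgamma(n_loci * k, conc), n_loci)
    fr <- fr / rowSums(fr)
  }
  tibble::tibble(locus = rep(loci, each = k),
                 allele = rep(seq_len(k), n_loci),
                 freq = as.vector(t(fr)))
}

# full-sib families with unrelated parents drawn from `freqs`
sim_families <- function(n_fam, fam_size, freqs, seed = 1) {
  set.seed(seed)
  fb <- split(stats::setNames(freqs$freq, freqs$allele), freqs$locus)
  loci <- names(fb)
  L <- length(loci)
  draw_parent <- function() {
    t(vapply(fb, function(p) sample(as.integer(names(p)), 2, TRUE, prob = p),
             integer(2)))
  }
  rows <- list()
  truth <- list()
  for (f in seq_len(n_fam)) {
    M <- draw_parent(); P <- draw_parent()
    for (k in seq_len(fam_size)) {
      id <- sprintf("F%02dI%02d", f, k)
      a1 <- ifelse(stats::runif(L) < 0.5, M[, 1], M[, 2])
      a2 <- ifelse(stats::runif(L) < 0.5, P[, 1], P[, 2])
      rows[[length(rows) + 1]] <- tibble::tibble(id = id, locus = loci,
                                                 a1 = a1, a2 = a2)
      truth[[length(truth) + 1]] <- tibble::tibble(id = id, family = f)
    }
  }
  list(geno = as_geno(dplyr::bind_rows(rows)),
       truth = dplyr::bind_rows(truth))
}

# HWE sample of n diploids at one locus
hwe_sample <- function(n, p, seed = 1) {
  set.seed(seed)
  al <- as.integer(names(p))
  tibble::tibble(
    id = sprintf("I%04d", seq_len(n)), locus = "L01",
    a1 = sample(al, n, TRUE, prob = p),
    a2 = sample(al, n, TRUE, prob = p)
  ) |> as_geno()
}

# Wright-Fisher population: N diploids, unlinked loci, `gens` generations
# of random mating from an equifrequent founder pool; returns all N
wf_population <- function(seed, N = 50, n_loci = 18, k = 10, gens = 8) {
  set.seed(seed)
  a1 <- matrix(sample(k, N * n_loci, TRUE), N, n_loci)
  a2 <- matrix(sample(k, N * n_loci, TRUE), N, n_loci)
  for (g in seq_len(gens)) {
    mo <- sample(N, N, TRUE)
    fa <- sample(N, N, TRUE)
    u1 <- matrix(stats::runif(N * n_loci) < 0.5, N, n_loci)
    u2 <- matrix(stats::runif(N * n_loci) < 0.5, N, n_loci)
    na1 <- ifelse(u1, a1[mo, ], a2[mo, ])
    na2 <- ifelse(u2, a1[fa, ], a2[fa, ])
    a1 <- na1; a2 <- na2
  }
  loci <- sprintf("L%02d", seq_len(n_loci))
  as_geno(tibble::tibble(
    id = rep(sprintf("I%03d", seq_len(N)), n_loci),
    locus = rep(loci, each = N),
    a1 = as.vector(a1), a2 = as.vector(a2)
  ))
}

# family-structured cohort without genotypes: a sibship partition plus
# migration dates, for exercising the Mantel machinery against known
# timing structure. family_date_sd = 0 makes timing independent of kinship.
timing_cohort <- function(seed, n_fam = 12, mean_size = 3,
                          family_date_sd = 0, within_sd = 4) {
  set.seed(seed)
  sizes <- 1 + stats::rpois(n_fam, mean_size - 1)
  fam <- rep(seq_len(n_fam), sizes)
  n <- length(fam)
  ids <- sprintf("I%03d", seq_len(n))
  fmean <- stats::rnorm(n_fam, 130, family_date_sd)
  doy <- round(fmean[fam] + stats::rnorm(n, 0, within_sd))
  part <- structure(list(
    families = tibble::tibble(id = ids, family = fam),
    halfsib_pairs = tibble::tibble(id_a = character(), id_b = character()),
    run_comembership = list(), seeds = integer()
  ), class = "sibship_partition")
  meta <- tibble::tibble(
    id = ids,
    capture_date = as.Date(doy - 1, origin = "2017-01-01"),
    trap = "downstream", sex = "unknown", stage = "smolt", year = 2017L
  )
  list(partition = part, meta = meta, n = n)
}

# small simulated monitoring population used across integration tests
small_study_pop <- function(seed = 7, noise = TRUE, n_families = 60) {
  cfg <- sim_config(
    n_anadromous = c(20, 15, 20, 20, 10, 15, 15, 12, 15, 25, 20),
    n_resident_females = 40, n_resident_males = 100,
    n_families = n_families,
    error_rate = if (noise) 0.01 else 0,
    dropout_rate = if (noise) 0.01 else 0,
    missing_rate = if (noise) 0.002 else 0
  )
  simulate_population(cfg, seed = seed)
}

smolt_ids_of <- function(pop) pop$truth$id

smolt_geno_of <- function(pop) {
  dplyr::filter(pop$genotypes, .data$id %in% pop$truth$id)
}

adult_geno_of <- function(pop) {
  dplyr::filter(pop$genotypes, !.data$id %in% pop$truth$id)
}

# pairwise co-membership comparison of two partitions over the same ids
partition_agreement <- function(fam_inferred, fam_true) {
  n <- length(fam_inferred)
  ut <- upper.tri(matrix(0, n, n))
  same_i <- outer(fam_inferred, fam_inferred, "==")[ut]
  same_t <- outer(fam_true, fam_true, "==")[ut]
  list(
    comembership_error = mean(same_i != same_t),
    fs_recovery = if (any(same_t)) sum(same_i & same_t) / sum(same_t) else NA,
    false_merge = if (any(!same_t)) mean(same_i[!same_t]) else NA
  )
}
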