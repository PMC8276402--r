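#' Simulation configuration for a partially migratory population
#'
#' Defaults describe a small coastal sea-trout system monitored with full
#' up- and downstream trapping: ~18 unlinked microsatellite loci with ~8
#' effective alleles, 25-96 anadromous ascenders per year over 11 years with
#' a ~1.5:1 female bias, a male-biased resident pool contributing fathers to
#' two thirds of the smolt run, overdispersed full-sib family sizes (mean
#' ~2.7, occasional families in the dozens), smolt ages 2-4, family-
#' correlated outmigration dates, and a 1% per-allele genotyping error rate.
#'
#' @param n_loci Number of unlinked loci.
#' @param alleles_per_locus Number of founder alleles per locus.
#' @param founder_concentration Symmetric Dirichlet parameter for founder
#'   allele frequencies (larger = more even frequencies).
#' @param years Calendar years of the adult ascent monitoring.
#' @param n_anadromous Total ascenders per year (recycled/truncated to
#'   `length(years)`).
#' @param prop_female_anadromous Proportion of female ascenders.
#' @param n_resident_females,n_resident_males Resident (unsampled) pool.
#' @param p_mother_resident,p_father_resident Probability that an
#'   offspring's mother/father is resident rather than anadromous.
#' @param n_families Number of mating-pair draws producing the smolt cohort.
#' @param offspring_mean,offspring_dispersion Negative-binomial mean and
#'   size for offspring per pair, zero-truncated. The defaults give a
#'   zero-truncated mean of ~2.7 sampled offspring per family with a
#'   heavy tail (family sizes from 1 into the dozens).
#' @param smolt_age_probs Named probabilities over smolt ages 2-4.
#' @param smolt_year Year of the sampled smolt run.
#' @param smolt_run_midpoint,family_date_sd,within_family_date_sd Day-of-year
#'   midpoint of the smolt run and between/within-family date SDs (days).
#' @param adult_run_midpoint,adult_date_sd Day-of-year midpoint and SD of
#'   the adult ascent dates.
#' @param p_return_again Probability an anadromous adult re-ascends in a
#'   later year.
#' @param p_female_smolt Probability a smolt is female.
#' @param error_rate,dropout_rate,missing_rate Per-allele miscall, per-
#'   heterozygote allelic dropout, and per-call missingness probabilities.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_loci = 18,
                       alleles_per_locus = 10,
                       founder_concentration = 3,
                       years = 2006:2016,
                       n_anadromous = c(85, 34, 79, 81, 25, 63, 53, 39, 58, 96, 87),
                       prop_female_anadromous = 0.6,
                       n_resident_females = 150,
                       n_resident_males = 400,
                       p_mother_resident = 0.28,
                       p_father_resident = 0.66,
                       n_families = 317,
                       offspring_mean = 0.95,
                       offspring_dispersion = 0.3,
                       smolt_age_probs = c("2" = 0.40, "3" = 0.45, "4" = 0.15),
                       smolt_year = 2017,
                       smolt_run_midpoint = 121,
                       family_date_sd = 8,
                       within_family_date_sd = 4,
                       adult_run_midpoint = 227,
                       adult_date_sd = 25,
                       p_return_again = 0.16,
                       p_female_smolt = 0.68,
                       error_rate = 0.01,
                       dropout_rate = 0.01,
                       missing_rate = 0.002) {
  cfg <- as.list(environment())
  probs <- c(cfg$p_mother_resident, cfg$p_father_resident, cfg$p_return_again,
             cfg$p_female_smolt, cfg$prop_female_anadromous,
             cfg$error_rate, cfg$dropout_rate, cfg$missing_rate)
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$n_loci >= 1, cfg$alleles_per_locus >= 1,
            cfg$family_date_sd >= 0, cfg$within_family_date_sd >= 0,
            abs(sum(cfg$smolt_age_probs) - 1) < 1e-8)
  cfg$n_anadromous <- rep_len(cfg$n_anadromous, length(cfg$years))
  structure(cfg, class = "sim_config")
}

# HWE genotype draws for n founders at the configured frequencies
draw_founder_geno <- function(ids, freqs_by_locus) {
  loci <- names(freqs_by_locus)
  n <- length(ids)
  purrr::map_dfr(loci, function(l) {
    p <- freqs_by_locus[[l]]
    al <- as.integer(names(p))
    tibble::tibble(
      id = ids, locus = l,
      a1 = sample(al, n, replace = TRUE, prob = p),
      a2 = sample(al, n, replace = TRUE, prob = p)
    )
  })
}

#' Forward-simulate a partially migratory population with known pedigree
#'
#' Produces a ground-truthed synthetic analogue of a trap-monitoring
#' dataset: anadromous adults with (possibly repeated) upstream capture
#' dates, one sampled smolt cohort with family-correlated downstream dates,
#' Mendelian genotypes, sdY-style genetic sexes, and configurable
#' genotyping noise. Resident parents exist in the truth but are absent
#' from the sampled dataset, which is what makes resident contribution
#' inferable only through parentage gaps.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the run is fully deterministic given it.
#' @return A `sim_population` list with elements `genotypes` (sampled,
#'   noised genotype table: adults + smolts), `meta` (captures tibble),
#'   `truth` (per-offspring pedigree tibble), `parents` (roster of all true
#'   parents incl. residents), `parents_geno` (their pre-noise genotypes),
#'   `founder_freqs`, `noise_log`, `config`, `seed`.
#' @export
simulate_population <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cfg <- config
  loci <- sprintf("L%02d", seq_len(cfg$n_loci))

  g <- matrix(stats::rgamma(cfg$n_loci * cfg$alleles_per_locus,
                            shape = cfg$founder_concentration),
              nrow = cfg$n_loci)
  founder_freqs <- tibble::tibble(
    locus = rep(loci, each = cfg$alleles_per_locus),
    allele = rep(seq_len(cfg$alleles_per_locus), cfg$n_loci),
    freq = as.vector(t(g / rowSums(g)))
  )
  fb <- freq_list(founder_freqs)

  # --- anadromous adults: per-year totals = new ascenders + returners
  adults <- tibble::tibble(id = character(), sex = character(),
                           first_year = integer())
  ascents <- tibble::tibble(id = character(), year = integer())
  pending <- tibble::tibble(id = character(), year = integer())
  serial <- 0L
  for (k in seq_along(cfg$years)) {
    y <- cfg$years[k]
    back <- dplyr::filter(pending, .data$year == y)
    pending <- dplyr::filter(pending, .data$year != y)
    n_new <- max(0L, cfg$n_anadromous[k] - nrow(back))
    new_ids <- sprintf("A%04d", serial + seq_len(n_new))
    serial <- serial + n_new
    nf <- round(n_new * cfg$prop_female_anadromous)
    sexes <- sample(c(rep("female", nf), rep("male", n_new - nf)))
    adults <- dplyr::bind_rows(adults,
      tibble::tibble(id = new_ids, sex = sexes, first_year = y))
    yr_asc <- tibble::tibble(id = c(back$id, new_ids), year = y)
    ascents <- dplyr::bind_rows(ascents, yr_asc)
    ret <- yr_asc$id[stats::runif(nrow(yr_asc)) < cfg$p_return_again]
    if (length(ret)) {
      gap <- sample(1:2, length(ret), replace = TRUE)
      nxt <- tibble::tibble(id = ret, year = y + gap)
      pending <- dplyr::bind_rows(pending, dplyr::filter(nxt, .data$year <= max(cfg$years)))
    }
  }

  residents <- tibble::tibble(
    id = sprintf("R%04d", seq_len(cfg$n_resident_females + cfg$n_resident_males)),
    sex = c(rep("female", cfg$n_resident_females), rep("male", cfg$n_resident_males)),
    first_year = NA_integer_
  )
  parents <- dplyr::bind_rows(
    dplyr::mutate(adults, life_history = "anadromous"),
    dplyr::mutate(residents, life_history = "resident")
  )
  parents_geno <- as_geno(dplyr::mutate(
    draw_founder_geno(parents$id, fb), locus = factor(.data$locus, levels = loci)))

  # --- families (offspring-centric parent draws, NB offspring counts)
  ages <- as.integer(sample(names(cfg$smolt_age_probs), cfg$n_families,
                            replace = TRUE, prob = cfg$smolt_age_probs))
  spawn_year <- cfg$smolt_year - 1L - ages
  pick_parent <- function(sy, sex, p_res) {
    if (stats::runif(1) < p_res) {
      pool <- residents$id[residents$sex == sex]
    } else {
      asc_y <- ascents$id[ascents$year == sy]
      pool <- asc_y[adults$sex[match(asc_y, adults$id)] == sex]
    }
    if (!length(pool)) stop("no candidate ", sex, " parents for spawning year ", sy)
    sample(pool, 1)
  }
  mothers <- vapply(spawn_year, pick_parent, character(1),
                    sex = "female", p_res = cfg$p_mother_resident)
  fathers <- vapply(spawn_year, pick_parent, character(1),
                    sex = "male", p_res = cfg$p_father_resident)
  n_off <- stats::rnbinom(cfg$n_families, mu = cfg$offspring_mean,
                          size = cfg$offspring_dispersion)
  while (any(n_off == 0))
    n_off[n_off == 0] <- stats::rnbinom(sum(n_off == 0), mu = cfg$offspring_mean,
                                        size = cfg$offspring_dispersion)

  fam <- tibble::tibble(mother = mothers, father = fathers,
                        spawn_year = spawn_year, age = ages, n = n_off)
  # identical parent pairs are one full-sib family
  fam <- dplyr::mutate(fam, family = paste(.data$mother, .data$father, sep = "x"))

  truth <- tidyr::uncount(fam, .data$n)
  n_smolt <- nrow(truth)
  truth$id <- sprintf("S%04d", seq_len(n_smolt))
  truth$hatch_year <- truth$spawn_year + 1L
  truth$mother_life_history <- ifelse(grepl("^R", truth$mother), "resident", "anadromous")
  truth$father_life_history <- ifelse(grepl("^R", truth$father), "resident", "anadromous")

  fam_mean <- stats::rnorm(dplyr::n_distinct(truth$family),
                           cfg$smolt_run_midpoint, cfg$family_date_sd)
  names(fam_mean) <- unique(truth$family)
  doy <- round(unname(fam_mean[truth$family]) +
                 stats::rnorm(n_smolt, 0, cfg$within_family_date_sd))
  doy <- pmin(pmax(doy, 32), 365)
  truth$smolt_date <- as.Date(doy - 1, origin = paste0(cfg$smolt_year, "-01-01"))
  truth$sex <- ifelse(stats::runif(n_smolt) < cfg$p_female_smolt, "female", "male")
  truth <- dplyr::select(truth, "id", "mother", "father", "mother_life_history",
                         "father_life_history", "family", "hatch_year", "age",
                         "smolt_date", "sex")

  # --- Mendelian transmission (vectorised over offspring x loci)
  pm <- geno_matrices(parents_geno)
  mi <- match(truth$mother, pm$ids)
  fi <- match(truth$father, pm$ids)
  pick <- function(a1m, a2m, idx) {
    u <- matrix(stats::runif(length(idx) * length(loci)) < 0.5,
                length(idx), length(loci))
    ifelse(u, a1m[idx, , drop = FALSE], a2m[idx, , drop = FALSE])
  }
  off_a1 <- pick(pm$a1, pm$a2, mi)
  off_a2 <- pick(pm$a1, pm$a2, fi)
  smolt_geno <- tibble::tibble(
    id = rep(truth$id, times = cfg$n_loci),
    locus = rep(loci, each = n_smolt),
    a1 = as.vector(off_a1),
    a2 = as.vector(off_a2)
  )

  adult_geno <- dplyr::filter(parents_geno, .data$id %in% adults$id)
  sampled <- as_geno(dplyr::mutate(
    dplyr::bind_rows(
      tibble::tibble(id = adult_geno$id, locus = as.character(adult_geno$locus),
                     a1 = adult_geno$a1, a2 = adult_geno$a2),
      smolt_geno
    ),
    locus = factor(.data$locus, levels = loci)
  ))
  sampled <- apply_genotyping_noise(sampled, cfg$error_rate, cfg$dropout_rate,
                                    cfg$missing_rate,
                                    seed = derive_seed(seed, "noise"))

  # --- capture metadata
  asc <- dplyr::mutate(ascents,
    capture_date = as.Date(
      pmin(pmax(round(cfg$adult_run_midpoint +
                        stats::rnorm(nrow(ascents), 0, cfg$adult_date_sd)), 32), 360) - 1,
      origin = paste0(.data$year, "-01-01")),
    trap = "upstream", stage = "anadromous_adult",
    sex = adults$sex[match(.data$id, adults$id)]
  )
  meta <- dplyr::bind_rows(
    dplyr::select(asc, "id", "capture_date", "trap", "sex", "stage", "year"),
    tibble::tibble(id = truth$id, capture_date = truth$smolt_date,
                   trap = "downstream", sex = truth$sex, stage = "smolt",
                   year = cfg$smolt_year)
  )
  meta$year <- as.integer(meta$year)
  meta <- dplyr::arrange(meta, .data$id, .data$capture_date)

  structure(list(
    genotypes = sampled,
    meta = meta,
    truth = truth,
    parents = parents,
    parents_geno = parents_geno,
    founder_freqs = founder_freqs,
    noise_log = attr(sampled, "noise_log"),
    config = cfg,
    seed = seed
  ), class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("<sim_population>\n",
      " adults sampled:  ", sum(grepl("^A", unique(x$genotypes$id))), "\n",
      " smolts sampled:  ", nrow(x$truth), "\n",
      " full-sib families:", dplyr::n_distinct(x$truth$family), "\n",
      " loci:            ", length(geno_loci(x$genotypes)), "\n",
      " seed:            ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Apply genotyping noise to a genotype table
#'
#' Each allele call is independently miscalled to a uniformly random
#' registry allele with probability `error_rate`; each heterozygous call
#' then drops to a homozygote for one of its alleles with probability
#' `dropout_rate`; each locus call is finally set missing with probability
#' `missing_rate`.
#'
#' @param geno Genotype table.
#' @param error_rate,dropout_rate,missing_rate Probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @param registry Optional named list of allowed allele codes per locus;
#'   defaults to the alleles observed in `geno`.
#' @return The noised genotype table, with a `noise_log` attribute listing
#'   affected (`id`, `locus`, `type`) rows.
#' @export
apply_genotyping_noise <- function(geno, error_rate = 0.01, dropout_rate = 0,
                                   missing_rate = 0, seed = 1, registry = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 1, dropout_rate >= 0,
            dropout_rate <= 1, missing_rate >= 0, missing_rate <= 1)
  set.seed(seed)
  out <- geno
  if (is.null(registry)) {
    fr <- allele_freqs(geno)
    registry <- split(fr$allele, fr$locus)
  }
  lidx <- as.integer(out$locus)
  reg <- registry[geno_loci(out)]
  logs <- list()
  ok <- !is.na(out$a1)

  if (error_rate > 0) {
    for (col in c("a1", "a2")) {
      hit <- ok & stats::runif(nrow(out)) < error_rate
      if (any(hit)) {
        new <- vapply(lidx[hit], function(l) {
          r <- reg[[l]]
          r[sample.int(length(r), 1)]
        }, numeric(1))
        changed <- new != out[[col]][hit]
        out[[col]][hit] <- as.integer(new)
        logs[[length(logs) + 1]] <- tibble::tibble(
          id = out$id[hit][changed], locus = as.character(out$locus[hit][changed]),
          type = "miscall")
      }
    }
    lo <- pmin(out$a1, out$a2); hi <- pmax(out$a1, out$a2)
    out$a1 <- lo; out$a2 <- hi
  }
  if (dropout_rate > 0) {
    het <- ok & !is.na(out$a1) & out$a1 != out$a2
    hit <- het & stats::runif(nrow(out)) < dropout_rate
    if (any(hit)) {
      keep_first <- stats::runif(sum(hit)) < 0.5
      kept <- ifelse(keep_first, out$a1[hit], out$a2[hit])
      out$a1[hit] <- kept
      out$a2[hit] <- kept
      logs[[length(logs) + 1]] <- tibble::tibble(
        id = out$id[hit], locus = as.character(out$locus[hit]), type = "dropout")
    }
  }
  if (missing_rate > 0) {
    hit <- ok & stats::runif(nrow(out)) < missing_rate
    if (any(hit)) {
      out$a1[hit] <- NA_integer_
      out$a2[hit] <- NA_integer_
      logs[[length(logs) + 1]] <- tibble::tibble(
        id = out$id[hit], locus = as.character(out$locus[hit]), type = "missing")
    }
  }
  attr(out, "noise_log") <- if (length(logs)) dplyr::bind_rows(logs) else
    tibble::tibble(id = character(), locus = character(), type = character())
  out
}

#' Export simulator ground truth as JSON
#'
#' @param pop A `sim_population`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_truth <- function(pop, path) {
  obj <- list(
    seed = pop$seed,
    offspring = dplyr::mutate(pop$truth, smolt_date = format(.data$smolt_date, "%Y-%m-%d")),
    parents = pop$parents
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read simulator ground truth back from JSON
#' @param path Path written by [export_truth()].
#' @return List with `seed`, `offspring`, `parents` tibbles.
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  off <- tibble::as_tibble(obj$offspring)
  if (nrow(off)) off$smolt_date <- as.Date(off$smolt_date)
  par <- tibble::as_tibble(obj$parents)
  if (nrow(par) && !is.integer(par$first_year))
    par$first_year <- as.integer(par$first_year)
  list(seed = obj$seed, offspring = off, parents = par)
}
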