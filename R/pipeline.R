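#' Run the full monitoring analysis pipeline
#'
#' Orchestrates the stages in order: identity matching (collapse repeat
#' captures), per-sample diversity summaries, LD effective population
#' size, sibship reconstruction, kinship-versus-timing Mantel tests
#' (per adult ascent year in weeks, smolt cohort in days), parentage
#' against the year-windowed anadromous candidate pool, resident-
#' contribution classification with final-year validation, and
#' census-trend / sex-ratio statistics. A stage failure halts the run with
#' the stage name; results of completed stages are retained.
#'
#' @param geno Genotype table (per-capture records).
#' @param meta Captures tibble.
#' @param smolt_year Year of the smolt cohort.
#' @param candidate_window_start First ascent year admitted to the
#'   candidate parent pool.
#' @param final_year Last adult monitoring year (validation predicate).
#' @param exclude_loci_ne Loci excluded from Ne estimation (e.g. markers
#'   linked to immune loci under diversifying selection) but used for
#'   sibship reconstruction.
#' @param stages Character vector of stages to run, a subset of
#'   `c("match", "diversity", "ne", "kinship", "mantel", "parentage",
#'   "contribution", "census")`. Stages whose prerequisites are toggled
#'   off are marked skipped.
#' @param eps,pcrit,llr_threshold,min_lod,n_perm,n_boot Stage parameters.
#' @param min_adults_mantel Minimum retained adults for a yearly Mantel
#'   test.
#' @param seed Master seed; every stochastic stage derives its own.
#' @param out_dir If non-`NULL`, per-stage CSVs and a JSON run manifest
#'   are written there.
#' @return A `smolt_pipeline` list with one element per stage plus
#'   `manifest`.
#' @export
run_pipeline <- function(geno, meta, smolt_year,
                         candidate_window_start, final_year = NULL,
                         exclude_loci_ne = NULL,
                         stages = c("match", "diversity", "ne", "kinship",
                                    "mantel", "parentage", "contribution",
                                    "census"),
                         eps = 0.01, pcrit = 0.05, llr_threshold = 3,
                         min_lod = 5, n_perm = 10000, n_boot = 1000,
                         min_adults_mantel = 5, seed = 1, out_dir = NULL) {
  if (is.null(final_year)) final_year <- smolt_year - 1
  res <- list()
  run_stage <- function(name, deps, fun) {
    if (!name %in% stages || any(vapply(deps, function(d)
      is.null(res[[d]]) || identical(res[[d]], "skipped"), logical(1)))) {
      res[[name]] <<- "skipped"
      return(invisible())
    }
    res[[name]] <<- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  run_stage("match", character(), function() {
    rep <- find_matches(geno, meta)
    list(report = rep, error_rates = estimate_error_rates(rep, geno))
  })
  cg <- if (!identical(res$match, "skipped")) res$match$report$genotypes else geno
  cm <- if (!identical(res$match, "skipped")) res$match$report$meta else meta

  adult_meta <- dplyr::filter(cm, .data$stage == "anadromous_adult")
  smolt_ids <- unique(dplyr::filter(cm, .data$stage == "smolt")$id)
  adult_years <- sort(unique(adult_meta$year))
  year_ids <- lapply(adult_years, function(y)
    unique(adult_meta$id[adult_meta$year == y]))
  names(year_ids) <- adult_years

  sample_sets <- c(
    stats::setNames(year_ids, paste0("adults_", adult_years)),
    list(smolts = smolt_ids)
  )

  run_stage("diversity", "match", function() {
    purrr::imap_dfr(sample_sets, function(ids, nm) {
      sub <- dplyr::filter(cg, .data$id %in% ids)
      ind <- join_metadata(sub, cm, policy = "intersect")
      ind$sample_label <- nm
      dplyr::mutate(
        diversity_summary(sub, ind, group = "sample_label",
                          seed = derive_seed(seed, paste0("div", nm))),
        sample = nm)
    })
  })

  run_stage("ne", "match", function() {
    purrr::imap_dfr(sample_sets, function(ids, nm) {
      sub <- dplyr::filter(cg, .data$id %in% ids)
      est <- tryCatch(
        estimate_ne(sub, pcrit = pcrit, exclude_loci = exclude_loci_ne),
        error = function(e) NULL)
      if (is.null(est)) return(tibble::tibble(sample = nm, ne_point = NA_real_))
      class(est) <- c("tbl_df", "tbl", "data.frame")
      dplyr::mutate(est, sample = nm, .before = 1)
    })
  })

  run_stage("kinship", "match", function() {
    list(
      smolts = reconstruct_sibships(
        dplyr::filter(cg, .data$id %in% smolt_ids), eps = eps,
        seed = derive_seed(seed, "sib_smolt")),
      adults = reconstruct_sibships(
        dplyr::filter(cg, .data$id %in% unique(adult_meta$id)), eps = eps,
        seed = derive_seed(seed, "sib_adult"))
    )
  })

  run_stage("mantel", c("match", "kinship"), function() {
    rows <- list()
    for (y in adult_years) {
      ids <- year_ids[[as.character(y)]]
      mk <- kinship_distance_matrix(res$kinship$adults, ids)
      if (nrow(mk) < min_adults_mantel) {
        rows[[paste0("adults_", y)]] <- tibble::tibble(
          sample = paste0("adults_", y), n = nrow(mk), r = NA_real_, p = NA_real_)
        next
      }
      mt <- timing_distance_matrix(cm, ids = rownames(mk), unit = "weeks", year = y)
      ok <- intersect(rownames(mk), rownames(mt))
      rows[[paste0("adults_", y)]] <- dplyr::mutate(
        mantel_test(mk[ok, ok], mt[ok, ok], n_perm = n_perm, n_boot = n_boot,
                    seed = derive_seed(seed, paste0("mantel", y))),
        sample = paste0("adults_", y), .before = 1)
    }
    mk <- kinship_distance_matrix(res$kinship$smolts, smolt_ids)
    if (nrow(mk) >= 3) {
      mt <- timing_distance_matrix(cm, ids = rownames(mk), unit = "days",
                                   year = smolt_year)
      ok <- intersect(rownames(mk), rownames(mt))
      rows$smolts <- dplyr::mutate(
        mantel_test(mk[ok, ok], mt[ok, ok], n_perm = n_perm, n_boot = n_boot,
                    seed = derive_seed(seed, "mantelsmolt")),
        sample = "smolts", .before = 1)
    }
    dplyr::bind_rows(rows)
  })

  run_stage("parentage", "match", function() {
    cand_ids <- unique(adult_meta$id[adult_meta$year >= candidate_window_start])
    cands <- dplyr::distinct(
      dplyr::select(dplyr::filter(cm, .data$id %in% cand_ids), "id", "sex"))
    assign_parentage(
      dplyr::filter(cg, .data$id %in% smolt_ids),
      dplyr::filter(cg, .data$id %in% cand_ids),
      cands, eps = eps, min_lod = min_lod)
  })

  run_stage("contribution", "parentage", function() {
    list(
      summary = classify_parental_origin(res$parentage),
      final_year_validation = validate_final_year_parents(res$parentage, cm,
                                                          final_year)
    )
  })

  run_stage("census", "match", function() {
    counts <- dplyr::count(adult_meta, .data$year, name = "count")
    sexes <- dplyr::summarise(
      dplyr::group_by(dplyr::distinct(adult_meta, .data$id, .data$year,
                                      .data$sex), .data$year),
      females = sum(.data$sex == "female"), males = sum(.data$sex == "male"),
      .groups = "drop")
    list(trend = census_trend(counts),
         sex_ratio = sex_ratio_test(sexes),
         counts = dplyr::left_join(counts, sexes, by = "year"))
  })

  res$manifest <- list(
    package_version = as.character(utils::packageVersion("smoltkin")),
    seed = seed,
    parameters = list(smolt_year = smolt_year,
                      candidate_window_start = candidate_window_start,
                      final_year = final_year, eps = eps, pcrit = pcrit,
                      llr_threshold = llr_threshold, min_lod = min_lod,
                      n_perm = n_perm, n_boot = n_boot,
                      exclude_loci_ne = exclude_loci_ne),
    stages_run = stages
  )
  class(res) <- "smolt_pipeline"
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
  if (!identical(res$diversity, "skipped")) w(res$diversity, "diversity.csv")
  if (!identical(res$ne, "skipped")) w(res$ne, "ne.csv")
  if (!identical(res$mantel, "skipped")) w(res$mantel, "mantel.csv")
  if (!identical(res$parentage, "skipped")) w(res$parentage, "parentage.csv")
  if (is.list(res$contribution)) {
    w(res$contribution$summary$categories, "contribution_categories.csv")
    w(res$contribution$summary$by_sex, "contribution_by_sex.csv")
  }
  if (is.list(res$census)) w(res$census$counts, "census.csv")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.smolt_pipeline <- function(x, ...) {
  cat("<smolt_pipeline>\n")
  for (nm in setdiff(names(x), "manifest")) {
    status <- if (identical(x[[nm]], "skipped")) "skipped" else "done"
    cat(sprintf("  %-13s %s\n", nm, status))
  }
  invisible(x)
}

#' Write deterministic synthetic fixture datasets to disk
#'
#' `tiny` is a 3-family, 6-locus toy for examples; `demo` is a
#' monitoring-scale cohort (reduced sample sizes, same structure as the
#' default simulator conditions). Files: `genotypes.gen` (Genepop),
#' `metadata.csv`, `truth.json`.
#'
#' @param size `"tiny"` or `"demo"`.
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Invisible named vector of the file paths.
#' @export
make_fixtures <- function(size = c("tiny", "demo"), dir, seed = 42) {
  size <- match.arg(size)
  cfg <- if (size == "tiny") {
    sim_config(n_loci = 6, alleles_per_locus = 6, years = 2012:2016,
               n_anadromous = rep(8, 5), n_resident_females = 5,
               n_resident_males = 10, n_families = 3,
               offspring_mean = 4, missing_rate = 0)
  } else {
    sim_config(n_anadromous = c(30, 20, 30, 30, 15, 25, 25, 20, 25, 35, 30),
               n_resident_females = 60, n_resident_males = 150,
               n_families = 120)
  }
  pop <- simulate_population(cfg, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, "genotypes.gen"),
    metadata = file.path(dir, "metadata.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_genepop(pop$genotypes, paths["genotypes"],
                title = paste("smoltkin", size, "fixture, seed", seed))
  write_metadata(pop$meta, paths["metadata"])
  export_truth(pop, paths["truth"])
  invisible(paths)
}
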