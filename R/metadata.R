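#' Read a per-individual capture metadata table
#'
#' Reads a delimited text file (CSV by default) with one row per capture
#' event. Required columns: `id`, `capture_date` (ISO 8601 `YYYY-MM-DD`),
#' `trap` (`upstream`/`downstream`), `sex` (`female`/`male`/`unknown`),
#' `stage` (`smolt`/`anadromous_adult`). Extra columns are preserved.
#' Multiple rows with the same `id` form that individual's capture history.
#'
#' @param path Path to the file.
#' @param sep Field separator.
#' @return Captures tibble, one row per capture, with an added `year`
#'   column. Rows are sorted by id and date.
#' @export
read_metadata <- function(path, sep = ",") {
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
  req <- c("id", "capture_date", "trap", "sex", "stage")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata is missing required column(s): ",
                         paste(miss, collapse = ", "))
  d <- as.Date(df$capture_date, format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(df$capture_date) & nzchar(df$capture_date))
  if (length(bad)) stop("unparsable capture_date at row ", bad[1],
                        ": '", df$capture_date[bad[1]], "'")
  if (anyNA(d)) stop("missing capture_date at row ", which(is.na(d))[1])
  bad_trap <- setdiff(unique(df$trap), c("upstream", "downstream"))
  if (length(bad_trap)) stop("unknown trap value(s): ", paste(bad_trap, collapse = ", "))
  bad_sex <- setdiff(unique(df$sex), c("female", "male", "unknown"))
  if (length(bad_sex)) stop("unknown sex value(s): ", paste(bad_sex, collapse = ", "))
  bad_stage <- setdiff(unique(df$stage), c("smolt", "anadromous_adult"))
  if (length(bad_stage)) stop("unknown stage value(s): ", paste(bad_stage, collapse = ", "))
  out <- tibble::as_tibble(df)
  out$id <- as.character(out$id)
  out$capture_date <- d
  out$year <- as.integer(format(d, "%Y"))
  conf <- dplyr::filter(
    dplyr::summarise(dplyr::group_by(out, .data$id),
                     n_stage = dplyr::n_distinct(.data$stage)),
    .data$n_stage > 1
  )
  if (nrow(conf)) stop("conflicting stage for id(s): ",
                       paste(utils::head(conf$id, 5), collapse = ", "))
  smolt_up <- out$stage == "smolt" & out$trap == "upstream"
  if (any(smolt_up)) stop("smolt records must have downstream captures only (id ",
                          out$id[which(smolt_up)[1]], ")")
  dplyr::arrange(out, .data$id, .data$capture_date)
}

#' Write a captures metadata table
#' @param meta Captures tibble (see [read_metadata()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  df <- as.data.frame(dplyr::select(meta, -dplyr::any_of("year")))
  df$capture_date <- format(df$capture_date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Join genotypes with capture metadata into per-individual records
#'
#' Validates that genotype and metadata ids agree (per `policy`) and
#' summarises each individual's capture history.
#'
#' @param geno Genotype table.
#' @param meta Captures tibble.
#' @param policy `"geno_in_meta"` requires every genotyped id to have
#'   metadata; `"meta_in_geno"` the reverse; `"intersect"` keeps the common
#'   ids and reports the rest.
#' @return Tibble with one row per individual: `id`, `sex`, `stage`,
#'   `n_captures`, `first_year`, `last_year`, `years` (list column),
#'   `primary_date` (earliest capture). Unmatched ids are attached as
#'   attribute `"unmatched"`.
#' @export
join_metadata <- function(geno, meta,
                          policy = c("geno_in_meta", "meta_in_geno", "intersect")) {
  policy <- match.arg(policy)
  gids <- unique(geno$id)
  mids <- unique(meta$id)
  only_g <- setdiff(gids, mids)
  only_m <- setdiff(mids, gids)
  if (policy == "geno_in_meta" && length(only_g))
    stop("genotyped id(s) without metadata: ", paste(utils::head(only_g, 5), collapse = ", "))
  if (policy == "meta_in_geno" && length(only_m))
    stop("metadata id(s) without genotypes: ", paste(utils::head(only_m, 5), collapse = ", "))
  keep <- intersect(gids, mids)
  ind <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(meta, .data$id %in% keep), .data$id),
    sex = .data$sex[1],
    stage = .data$stage[1],
    n_captures = dplyr::n(),
    first_year = min(.data$year),
    last_year = max(.data$year),
    years = list(sort(unique(.data$year))),
    primary_date = min(.data$capture_date),
    .groups = "drop"
  )
  attr(ind, "unmatched") <- list(genotypes_only = only_g, metadata_only = only_m)
  ind
}

#' Trap-sampling bookkeeping summary
#'
#' From per-sample trap tallies, computes the number of genotyped records
#' (catches minus fish without tissue minus non-target species) and the
#' number of genotyped individuals (additionally collapsing within-year
#' recaptures), mirroring the bookkeeping of a trap-monitoring study.
#'
#' @param counts Tibble with columns `sample` (label), `catches`,
#'   `no_tissue`, `non_target`, `within_year_recaptures`.
#' @return The input with added `genotyped_records` and
#'   `genotyped_individuals` columns.
#' @export
summarize_sampling <- function(counts) {
  req <- c("sample", "catches", "no_tissue", "non_target", "within_year_recaptures")
  miss <- setdiff(req, names(counts))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  dplyr::mutate(
    tibble::as_tibble(counts),
    genotyped_records = .data$catches - .data$no_tissue - .data$non_target,
    genotyped_individuals = .data$genotyped_records - .data$within_year_recaptures
  )
}
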