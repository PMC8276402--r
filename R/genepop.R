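#' Read a Genepop-format genotype file
#'
#' Parses the classic Genepop text dialect: a title line, locus names (one
#' per line and/or comma-separated), `Pop` separators, then one line per
#' individual of the form `id , 0102 0304 ...` with concatenated 2- or
#' 3-digit allele codes where `00`/`000` codes a missing allele. Pop blocks
#' are concatenated into one dataset; the block label (the id of the last
#' individual in common usage, here the 1-based block index) is kept in a
#' `pop` column. A call with one missing allele is treated as a fully
#' missing locus.
#'
#' @param path Path to the Genepop file.
#' @param allele_digits 2, 3, or `NULL` to auto-detect from token width.
#' @return Genotype table (see [as_geno()]) with an extra `pop` column and a
#'   `title` attribute carrying the file's title line.
#' @export
read_genepop <- function(path, allele_digits = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 2) stop("Genepop file too short: no locus lines found")
  title <- lines[1]
  body <- lines[-1]
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!any(is_pop)) stop("Genepop file has no 'Pop' line")
  first_pop <- which(is_pop)[1]
  locus_lines <- body[seq_len(first_pop - 1)]
  loci <- unlist(strsplit(locus_lines, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0) stop("Genepop file declares no loci")
  if (anyDuplicated(loci)) stop("duplicate locus names: ",
                                paste(unique(loci[duplicated(loci)]), collapse = ", "))

  data_idx <- which(!is_pop)
  data_idx <- data_idx[data_idx > first_pop]
  pop_of <- findInterval(data_idx, which(is_pop))

  recs <- vector("list", length(data_idx))
  for (k in seq_along(data_idx)) {
    ln <- body[data_idx[k]]
    line_no <- data_idx[k] + 1L  # account for title line
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) stop("malformed individual line ", line_no,
                                ": no ',' separator")
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != length(loci))
      stop("line ", line_no, ": expected ", length(loci),
           " genotype tokens, found ", length(toks))
    if (!all(grepl("^[0-9]+$", toks)))
      stop("line ", line_no, ": non-numeric genotype token")
    w <- unique(nchar(toks))
    if (length(w) != 1 || !(w %in% c(4L, 6L)))
      stop("line ", line_no, ": genotype tokens must be uniformly 4 or 6 digits wide")
    d <- w / 2L
    if (!is.null(allele_digits) && d != allele_digits)
      stop("line ", line_no, ": token width ", w, " inconsistent with allele_digits=",
           allele_digits)
    recs[[k]] <- tibble::tibble(
      id = id,
      pop = pop_of[k],
      locus = loci,
      a1 = as.integer(substr(toks, 1, d)),
      a2 = as.integer(substr(toks, d + 1, w))
    )
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  rec_ids <- vapply(recs, function(r) r$id[1], character(1))
  if (anyDuplicated(rec_ids))
    stop("duplicate individual id: ", rec_ids[duplicated(rec_ids)][1])
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) {
    out <- tibble::tibble(id = character(), pop = integer(),
                          locus = character(), a1 = integer(), a2 = integer())
  }
  out$locus <- factor(out$locus, levels = loci)
  out <- as_geno(out)
  attr(out, "title") <- title
  out
}

#' Write a genotype table to a Genepop-format file
#'
#' Inverse of [read_genepop()]: output is re-readable with call-level
#' equality. All individuals are written into a single `Pop` block (the
#' package analyses one population; grouping comes from metadata).
#'
#' @param geno Genotype table.
#' @param path Output path.
#' @param allele_digits 2 or 3; allele codes must fit the width.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(geno, path, allele_digits = 2,
                          title = "smoltkin genotype export") {
  stopifnot(allele_digits %in% c(2, 3))
  loci <- geno_loci(geno)
  mx <- suppressWarnings(max(geno$a1, geno$a2, na.rm = TRUE))
  if (is.finite(mx) && mx >= 10^allele_digits)
    stop("allele code ", mx, " not representable with allele_digits=", allele_digits)
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = allele_digits, flag = "0")
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(title, loci, "Pop"), con)
  if (nrow(geno)) {
    m <- geno_matrices(geno)
    for (i in seq_along(m$ids)) {
      toks <- paste0(fmt(m$a1[i, ]), fmt(m$a2[i, ]))
      writeLines(paste0(m$ids[i], " , ", paste(toks, collapse = " ")), con)
    }
  }
  invisible(path)
}
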