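# Central data shape: a genotype table is a long tibble with columns
#   id    - individual/record identifier (character)
#   locus - factor whose levels carry the locus order of the dataset
#   a1,a2 - integer allele codes with a1 <= a2, both NA when the call is missing
# All user-facing functions take this table first and return tibbles.

#' Normalise a genotype table
#'
#' Coerces a data frame with columns `id`, `locus`, `a1`, `a2` into the
#' canonical long genotype table used throughout the package: `locus` becomes
#' a factor (levels in first-appearance order unless already a factor),
#' alleles are stored low-high, and half-missing calls (one allele `NA` or 0)
#' are set fully missing because downstream likelihoods require complete
#' diploid calls.
#'
#' @param df Data frame with columns `id`, `locus`, `a1`, `a2`.
#' @return A tibble with the canonical column types.
#' @export
as_geno <- function(df) {
  stopifnot(all(c("id", "locus", "a1", "a2") %in% names(df)))
  out <- tibble::as_tibble(df)
  if (!is.factor(out$locus)) out$locus <- factor(out$locus, levels = unique(out$locus))
  out$id <- as.character(out$id)
  a1 <- as.integer(out$a1)
  a2 <- as.integer(out$a2)
  a1[!is.na(a1) & a1 == 0L] <- NA_integer_
  a2[!is.na(a2) & a2 == 0L] <- NA_integer_
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA_integer_
  a2[half] <- NA_integer_
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  out$a1 <- lo
  out$a2 <- hi
  out
}

#' Locus names of a genotype table
#' @param geno Genotype table (see [as_geno()]).
#' @return Character vector of loci in dataset order.
#' @export
geno_loci <- function(geno) levels(geno$locus)

# Wide allele matrices (individuals x loci), NA = missing. Used by the
# numeric kernels (matching, LD, likelihood lookups).
geno_matrices <- function(geno) {
  ids <- unique(geno$id)
  loci <- geno_loci(geno)
  a1 <- matrix(NA_integer_, length(ids), length(loci), dimnames = list(ids, loci))
  a2 <- a1
  i <- match(geno$id, ids)
  j <- as.integer(geno$locus)
  a1[cbind(i, j)] <- geno$a1
  a2[cbind(i, j)] <- geno$a2
  list(a1 = a1, a2 = a2, ids = ids, loci = loci)
}

#' Sample allele frequencies per locus
#'
#' @param geno Genotype table.
#' @return Tibble with `locus`, `allele`, `count`, `freq` (frequencies among
#'   non-missing gene copies at that locus).
#' @export
allele_freqs <- function(geno) {
  long <- tidyr::pivot_longer(
    dplyr::filter(geno, !is.na(.data$a1)),
    c("a1", "a2"), values_to = "allele"
  )
  dplyr::ungroup(dplyr::mutate(
    dplyr::count(long, .data$locus, .data$allele, name = "count"),
    freq = .data$count / sum(.data$count),
    .by = "locus"
  ))
}

# frequency list: named numeric vectors per locus (names = allele codes)
freq_list <- function(freqs) {
  split(stats::setNames(freqs$freq, freqs$allele), freqs$locus)
}

# Deterministic sub-seed derivation so one master seed governs every
# stochastic stage without re-using streams. Kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((abs(seed) * 48271 + h * 9973 + 12345) %% 2147483629)
}

# day-of-year from a Date; weeks are floor(doy / 7) for locale-free
# reproducibility (documented choice, not ISO weeks)
day_of_year <- function(date) as.integer(strftime(date, "%j"))
week_index <- function(date) day_of_year(date) %/% 7L

# Wilson score interval for a binomial proportion (used for the
# parental-origin error bars)
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}
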