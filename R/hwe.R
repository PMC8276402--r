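# Hardy-Weinberg exact tests. Two routes to the same conditional
# distribution of genotype arrays given allele counts:
#   * full enumeration via the Levene distribution of the heterozygote
#     count (exact, 2 alleles);
#   * a Markov-chain Monte Carlo walk over genotype arrays (any number of
#     alleles), the classic two-genotype allele-switch chain.
# Both use the probability-ordering criterion: p = total probability of
# arrays no more probable than the observed one.

# exact two-allele path: enumerate the heterozygote count n_AB
hwe_enumerate_2 <- function(a1, a2) {
  al <- sort(unique(c(a1, a2)))
  stopifnot(length(al) == 2)
  n <- length(a1)
  nA <- sum(a1 == al[1]) + sum(a2 == al[1])
  nB <- 2 * n - nA
  obs_het <- sum(a1 != a2)
  support <- seq(nA %% 2, min(nA, nB), by = 2)
  logp <- vapply(support, function(nab) {
    naa <- (nA - nab) / 2
    nbb <- (nB - nab) / 2
    lfactorial(n) - lfactorial(naa) - lfactorial(nab) - lfactorial(nbb) +
      nab * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  }, numeric(1))
  p_obs <- logp[match(obs_het, support)]
  sum(exp(logp[logp <= p_obs + 1e-9]))
}

#' Hardy-Weinberg exact test per locus
#'
#' Estimates the exact-test p-value by a Markov chain over genotype arrays
#' with fixed allele counts; for loci with two alleles and up to
#' `enum_max_n` individuals the full-enumeration p-value is returned
#' instead (and the chain, if forced, agrees with it to Monte Carlo error).
#' Monomorphic loci are reported with `NA`.
#'
#' @param geno Genotype table.
#' @param dememorisation,batches,iter_per_batch Chain parameters; defaults
#'   are a 10^7-step chain after 10^4 burn-in steps.
#' @param seed Integer seed.
#' @param method `"auto"` (enumeration where available), `"mc"`, or
#'   `"enum"` (errors where enumeration is unavailable).
#' @param enum_max_n Largest sample size for the enumeration path.
#' @return Tibble: `locus`, `n`, `n_alleles`, `p`, `mc_se` (`NA` for the
#'   enumeration path), `method`.
#' @export
hwe_exact <- function(geno, dememorisation = 10000, batches = 1000,
                      iter_per_batch = 10000, seed = 1,
                      method = c("auto", "mc", "enum"), enum_max_n = 100) {
  method <- match.arg(method)
  loci <- geno_loci(geno)
  rows <- vector("list", length(loci))
  for (li in seq_along(loci)) {
    d <- geno[geno$locus == loci[li] & !is.na(geno$a1), ]
    n <- nrow(d)
    al <- sort(unique(c(d$a1, d$a2)))
    k <- length(al)
    if (n < 2 || k < 2) {
      rows[[li]] <- tibble::tibble(locus = loci[li], n = n, n_alleles = k,
                                   p = NA_real_, mc_se = NA_real_,
                                   method = "undefined")
      next
    }
    use_enum <- (method == "enum") ||
      (method == "auto" && k == 2 && n <= enum_max_n)
    if (use_enum && k != 2)
      stop("enumeration path only available for 2 alleles (locus ", loci[li], ")")
    if (use_enum) {
      p <- hwe_enumerate_2(d$a1, d$a2)
      rows[[li]] <- tibble::tibble(locus = loci[li], n = n, n_alleles = k,
                                   p = p, mc_se = NA_real_, method = "enumeration")
    } else {
      set.seed(derive_seed(seed, paste0("hwe", loci[li])))
      res <- hwe_mc_cpp(match(d$a1, al), match(d$a2, al), k,
                        dememorisation, batches, iter_per_batch)
      rows[[li]] <- tibble::tibble(locus = loci[li], n = n, n_alleles = k,
                                   p = res[1], mc_se = res[2], method = "mc")
    }
  }
  dplyr::bind_rows(rows)
}
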