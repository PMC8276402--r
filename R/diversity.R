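#' Per-locus heterozygosity and inbreeding coefficient
#'
#' Observed heterozygosity is the fraction of heterozygotes among
#' individuals with non-missing calls; expected heterozygosity is the
#' unbiased (small-sample corrected) estimator
#' `H_E = 2n/(2n-1) * (1 - sum p_i^2)`; the inbreeding coefficient is
#' `F_IS = 1 - H_O/H_E` (0 where `H_E = 0`).
#'
#' @param geno Genotype table.
#' @return Tibble with one row per locus: `locus`, `n` (non-missing
#'   individuals), `n_alleles`, `h_obs`, `h_exp`, `f_is`. Loci with all
#'   calls missing are returned with `NA` statistics.
#' @export
locus_stats <- function(geno) {
  per_locus <- function(d) {
    ok <- !is.na(d$a1)
    n <- sum(ok)
    if (n == 0) {
      return(tibble::tibble(n = 0L, n_alleles = 0L, h_obs = NA_real_,
                            h_exp = NA_real_, f_is = NA_real_))
    }
    al <- c(d$a1[ok], d$a2[ok])
    p <- as.numeric(table(al)) / (2 * n)
    h_obs <- mean(d$a1[ok] != d$a2[ok])
    h_exp <- if (n >= 1) (2 * n / (2 * n - 1)) * (1 - sum(p^2)) else NA_real_
    f_is <- if (!is.na(h_exp) && h_exp > 0) 1 - h_obs / h_exp else 0
    tibble::tibble(n = n, n_alleles = length(unique(al)),
                   h_obs = h_obs, h_exp = h_exp, f_is = f_is)
  }
  dplyr::reframe(dplyr::group_by(geno, .data$locus), per_locus(dplyr::pick(dplyr::everything())))
}

#' Rarefied allelic richness at a locus
#'
#' Expected number of distinct alleles in a random draw of `g` gene copies:
#' `A_r = sum_i [1 - choose(N - N_i, g) / choose(N, g)]` with `N` total
#' copies and `N_i` copies of allele `i`.
#'
#' @param allele_counts Integer vector of allele copy counts at the locus.
#' @param g Number of gene copies to rarefy to (`2 <= g <= N`).
#' @return Rarefied richness (equals the observed allele count at `g = N`).
#' @export
allelic_richness <- function(allele_counts, g) {
  allele_counts <- allele_counts[allele_counts > 0]
  N <- sum(allele_counts)
  if (g < 2) stop("g must be at least 2")
  if (g > N) stop("g (", g, ") exceeds total gene copies (", N, ")")
  sum(1 - exp(lchoose(N - allele_counts, g) - lchoose(N, g)))
}

#' Benjamini-Hochberg step-up false discovery rate control
#'
#' Rejects all hypotheses with p-value at or below `p_(k*)`, where
#' `k* = max{k : p_(k) <= k * alpha / m}`.
#'
#' @param pvals Numeric p-values in `[0, 1]` (`NA`s are never rejected and
#'   do not count toward `m`).
#' @param alpha Target FDR level.
#' @return Logical vector parallel to `pvals`: `TRUE` = rejected.
#' @export
fdr_bh <- function(pvals, alpha = 0.05) {
  out <- rep(FALSE, length(pvals))
  ok <- which(!is.na(pvals))
  if (!length(ok)) return(out)
  p <- pvals[ok]
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  o <- order(p)
  below <- which(p[o] <= seq_len(m) * alpha / m)
  if (length(below)) out[ok[o[seq_len(max(below))]]] <- TRUE
  out
}

#' Per-sample diversity summary
#'
#' Computes, for each sample (e.g. year x stage), the classic monitoring
#' summary: sample size, sex ratio, total alleles, rarefied allelic
#' richness, mean observed/unbiased expected heterozygosity and F_IS with
#' percentile-bootstrap intervals over loci, and the number of
#' Hardy-Weinberg deviations after Benjamini-Hochberg correction.
#'
#' @param geno Genotype table (collapsed to unique individuals).
#' @param individuals Tibble from [join_metadata()] (needs `id`, `sex`, and
#'   the grouping columns referenced by `group`).
#' @param group Column names of `individuals` defining samples (default
#'   `c("stage", "first_year")`).
#' @param g Gene copies for rarefaction; default: smallest per-sample,
#'   per-locus non-missing gene-copy count across the dataset.
#' @param n_boot Bootstrap replicates over loci for the mean +/- CI.
#' @param hwe_chain Chain parameters passed to [hwe_exact()].
#' @param alpha FDR level for counting Hardy-Weinberg deviations.
#' @param seed Integer seed (bootstrap and Markov chains).
#' @return A `diversity_summary` tibble: one row per sample with columns
#'   `n`, `sex_ratio_f_m`, `n_alleles`, `allelic_richness`, `h_obs`,
#'   `h_obs_lo`, `h_obs_hi`, `h_exp`, `h_exp_lo`, `h_exp_hi`, `f_is`,
#'   `f_is_lo`, `f_is_hi`, `n_hwe_deviations`, `n_loci_tested`. Per-locus
#'   Hardy-Weinberg p-values are attached as attribute `"hwe"`.
#' @export
diversity_summary <- function(geno, individuals,
                              group = c("stage", "first_year"),
                              g = NULL, n_boot = 999,
                              hwe_chain = list(dememorisation = 2000,
                                               batches = 100,
                                               iter_per_batch = 2000),
                              alpha = 0.05, seed = 1) {
  stopifnot(all(group %in% names(individuals)))
  ind <- dplyr::filter(individuals, .data$id %in% unique(geno$id))
  ind$.sample <- do.call(paste, c(ind[group], sep = "/"))
  samples <- split(ind, ind$.sample)

  if (is.null(g)) {
    gmin <- Inf
    for (s in samples) {
      sub <- dplyr::filter(geno, .data$id %in% s$id, !is.na(.data$a1))
      cnt <- dplyr::count(sub, .data$locus, .drop = TRUE)
      if (nrow(cnt)) gmin <- min(gmin, 2 * min(cnt$n))
    }
    g <- max(2, gmin)
  }

  rows <- list()
  hwe_all <- list()
  for (nm in names(samples)) {
    s <- samples[[nm]]
    sub <- dplyr::filter(geno, .data$id %in% s$id)
    ls <- locus_stats(sub)
    fr <- allele_freqs(sub)
    ar <- dplyr::summarise(
      dplyr::group_by(fr, .data$locus),
      ar = allelic_richness(.data$count, g = g), .groups = "drop")
    hwe <- hwe_exact(sub, dememorisation = hwe_chain$dememorisation,
                     batches = hwe_chain$batches,
                     iter_per_batch = hwe_chain$iter_per_batch,
                     seed = derive_seed(seed, paste0("hwe", nm)))
    hwe_all[[nm]] <- dplyr::mutate(hwe, sample = nm, .before = 1)
    rej <- fdr_bh(hwe$p, alpha = alpha)

    boot_ci <- function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(c(NA_real_, NA_real_))
      set.seed(derive_seed(seed, paste0("boot", nm, length(x), signif(mean(x), 6))))
      bs <- replicate(n_boot, mean(sample(x, replace = TRUE)))
      stats::quantile(bs, c(0.025, 0.975), names = FALSE)
    }
    ho_ci <- boot_ci(ls$h_obs); he_ci <- boot_ci(ls$h_exp); fis_ci <- boot_ci(ls$f_is)
    nf <- sum(s$sex == "female"); nm_ <- sum(s$sex == "male")
    rows[[nm]] <- tibble::tibble(
      sample = nm,
      n = nrow(s),
      sex_ratio_f_m = if (nm_ > 0) nf / nm_ else NA_real_,
      n_alleles = sum(ls$n_alleles),
      allelic_richness = mean(ar$ar),
      h_obs = mean(ls$h_obs, na.rm = TRUE),
      h_obs_lo = ho_ci[1], h_obs_hi = ho_ci[2],
      h_exp = mean(ls$h_exp, na.rm = TRUE),
      h_exp_lo = he_ci[1], h_exp_hi = he_ci[2],
      f_is = mean(ls$f_is, na.rm = TRUE),
      f_is_lo = fis_ci[1], f_is_hi = fis_ci[2],
      n_hwe_deviations = sum(rej, na.rm = TRUE),
      n_loci_tested = sum(!is.na(hwe$p))
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "hwe") <- dplyr::bind_rows(hwe_all)
  attr(out, "g") <- g
  class(out) <- c("diversity_summary", class(out))
  out
}
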