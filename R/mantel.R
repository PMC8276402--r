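# Kinship-versus-migration-timing Mantel machinery. The kinship distance
# codes dyads as 0.5 (full sibs), 0.75 (half sibs), 1 (otherwise);
# individuals without any sib in the sample are dropped before matrix
# construction so the test is not diluted by all-unrelated rows.

#' Relationship-coded distance matrix from a sibship partition
#'
#' @param partition A `sibship_partition`.
#' @param ids Individuals to consider (default: all in the partition).
#' @return Symmetric matrix with entries 0.5 (same full-sib family), 0.75
#'   (consensus half-sib pair), 1 (otherwise), 0 diagonal, over the
#'   individuals that have at least one full- or half-sib among `ids`;
#'   dropped ids are in attribute `"dropped"`.
#' @export
kinship_distance_matrix <- function(partition, ids = NULL) {
  fams <- partition$families
  if (is.null(ids)) ids <- fams$id
  miss <- setdiff(ids, fams$id)
  if (length(miss)) stop("ids not covered by the partition: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  fams <- dplyr::filter(fams, .data$id %in% ids)
  hs <- dplyr::filter(partition$halfsib_pairs,
                      .data$id_a %in% ids & .data$id_b %in% ids)
  fam_of <- stats::setNames(fams$family, fams$id)
  has_fs <- fams$id %in% fams$id[duplicated(fams$family) |
                                   duplicated(fams$family, fromLast = TRUE)]
  has_hs <- fams$id %in% c(hs$id_a, hs$id_b)
  retained <- fams$id[has_fs | has_hs]
  M <- matrix(1, length(retained), length(retained),
              dimnames = list(retained, retained))
  if (length(retained)) {
    same_fam <- outer(fam_of[retained], fam_of[retained], "==")
    M[same_fam] <- 0.5
    hs2 <- dplyr::filter(hs, .data$id_a %in% retained & .data$id_b %in% retained)
    if (nrow(hs2)) {
      M[cbind(hs2$id_a, hs2$id_b)] <- 0.75
      M[cbind(hs2$id_b, hs2$id_a)] <- 0.75
    }
    diag(M) <- 0
  }
  attr(M, "dropped") <- setdiff(ids, retained)
  M
}

#' Migration-timing distance matrix
#'
#' @param meta Captures tibble.
#' @param ids Individuals to include; each needs one primary capture date
#'   (the earliest within `year`, if given).
#' @param unit `"days"` (absolute day-of-year difference) or `"weeks"`
#'   (difference of `floor(day-of-year / 7)` week indices).
#' @param year Restrict captures to this year before taking the primary
#'   date.
#' @return Symmetric distance matrix over the ids with dates; ids lacking a
#'   date are dropped and listed in attribute `"dropped"`.
#' @export
timing_distance_matrix <- function(meta, ids = NULL,
                                   unit = c("days", "weeks"), year = NULL) {
  unit <- match.arg(unit)
  m <- meta
  if (!is.null(year)) m <- dplyr::filter(m, .data$year == !!year)
  if (!is.null(ids)) m <- dplyr::filter(m, .data$id %in% ids) else ids <- unique(m$id)
  prim <- dplyr::summarise(dplyr::group_by(m, .data$id),
                           date = min(.data$capture_date), .groups = "drop")
  dropped <- setdiff(ids, prim$id)
  prim <- prim[match(intersect(ids, prim$id), prim$id), ]
  t_val <- switch(unit,
                  days = day_of_year(prim$date),
                  weeks = week_index(prim$date))
  M <- abs(outer(t_val, t_val, "-"))
  dimnames(M) <- list(prim$id, prim$id)
  attr(M, "dropped") <- dropped
  M
}

# all permutations of 1..n (n small) for the exact enumeration path
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1
      v <- integer(n)
      v[i] <- n
      v[-i] <- s
      out[[k]] <- v
    }
  }
  out
}

lower_vec <- function(M) M[lower.tri(M)]

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with significance
#' from joint row/column permutations of the second matrix. The p-value
#' uses the add-one estimator `(count + 1) / (n_perm + 1)` (upper tail by
#' default: the working hypothesis is that kin migrate together, giving a
#' positive correlation of the two distances). A percentile bootstrap over
#' individuals gives a CI for r (reported, not used for significance). For
#' `exact = TRUE` and up to 7 individuals, all `n!` orderings are
#' enumerated instead and the p-value is the exact tail fraction.
#'
#' @param m_a,m_b Symmetric distance matrices with identical id dimnames
#'   (reordered automatically if needed).
#' @param n_perm Number of permutations.
#' @param n_boot Bootstrap resamples (0 disables).
#' @param seed Integer seed.
#' @param tail `"upper"` or `"two"`.
#' @param exact Use full enumeration (requires `n <= 7`).
#' @return A `mantel_result` tibble: `r`, `p`, `n`, `n_perm`, `boot_lo`,
#'   `boot_hi`, `pct_fullsib`, `pct_halfsib`, `pct_unrelated` (dyad
#'   percentages of `m_a`'s codes, `NA` when `m_a` is not relationship-
#'   coded), `tail`, `exact`.
#' @export
mantel_test <- function(m_a, m_b, n_perm = 10000, n_boot = 1000, seed = 1,
                        tail = c("upper", "two"), exact = FALSE) {
  tail <- match.arg(tail)
  ids <- rownames(m_a)
  if (is.null(ids) || is.null(rownames(m_b)) ||
      !setequal(ids, rownames(m_b)))
    stop("matrices must carry identical id dimnames")
  m_b <- m_b[ids, ids]
  n <- nrow(m_a)
  if (n < 3) stop("need at least 3 retained individuals, have ", n)
  a <- lower_vec(m_a)
  b <- lower_vec(m_b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance lower triangle; Mantel r undefined")
  r_obs <- stats::cor(a, b)

  if (exact) {
    if (n > 7) stop("exact enumeration limited to n <= 7")
    rs <- vapply(all_perms(n), function(p) {
      stats::cor(a, lower_vec(m_b[p, p]))
    }, numeric(1))
    p_val <- if (tail == "upper") mean(rs >= r_obs - 1e-12) else
      mean(abs(rs) >= abs(r_obs) - 1e-12)
    n_used <- length(rs)
  } else {
    set.seed(derive_seed(seed, "mantelperm"))
    rs <- mantel_perm_cpp(m_a, m_b, as.integer(n_perm))
    hits <- if (tail == "upper") sum(rs >= r_obs - 1e-12) else
      sum(abs(rs) >= abs(r_obs) - 1e-12)
    p_val <- (hits + 1) / (n_perm + 1)
    n_used <- n_perm
  }

  boot_lo <- boot_hi <- NA_real_
  if (n_boot > 0) {
    set.seed(derive_seed(seed, "mantelboot"))
    rb <- vapply(seq_len(n_boot), function(k) {
      ix <- sample.int(n, replace = TRUE)
      keep <- outer(ix, ix, "!=")[lower.tri(m_a)]
      av <- lower_vec(m_a[ix, ix])[keep]
      bv <- lower_vec(m_b[ix, ix])[keep]
      if (length(av) < 3 || stats::sd(av) == 0 || stats::sd(bv) == 0) return(NA_real_)
      stats::cor(av, bv)
    }, numeric(1))
    qs <- stats::quantile(rb, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    boot_lo <- qs[1]; boot_hi <- qs[2]
  }

  codes <- sort(unique(a))
  coded <- all(codes %in% c(0.5, 0.75, 1))
  out <- tibble::tibble(
    r = r_obs, p = p_val, n = n, n_perm = n_used,
    boot_lo = boot_lo, boot_hi = boot_hi,
    pct_fullsib = if (coded) 100 * mean(a == 0.5) else NA_real_,
    pct_halfsib = if (coded) 100 * mean(a == 0.75) else NA_real_,
    pct_unrelated = if (coded) 100 * mean(a == 1) else NA_real_,
    tail = tail, exact = exact
  )
  class(out) <- c("mantel_result", class(out))
  out
}

#' Kinship-versus-timing Mantel test for one sample
#'
#' Convenience wrapper: builds the relationship-coded and timing distance
#' matrices for one sample and runs [mantel_test()].
#'
#' @param partition A `sibship_partition` covering the sample.
#' @param meta Captures tibble.
#' @param ids Sample individuals.
#' @param unit `"days"` (smolts) or `"weeks"` (adult ascents).
#' @param year Restrict captures to this year.
#' @inheritParams mantel_test
#' @return A `mantel_result` (see [mantel_test()]).
#' @export
kin_timing_mantel <- function(partition, meta, ids = NULL,
                              unit = c("days", "weeks"), year = NULL,
                              n_perm = 10000, n_boot = 1000, seed = 1,
                              tail = c("upper", "two")) {
  unit <- match.arg(unit)
  tail <- match.arg(tail)
  mk <- kinship_distance_matrix(partition, ids)
  if (nrow(mk) < 3) stop("fewer than 3 individuals with kin in the sample")
  mt <- timing_distance_matrix(meta, ids = rownames(mk), unit = unit, year = year)
  common <- intersect(rownames(mk), rownames(mt))
  mantel_test(mk[common, common], mt[common, common],
              n_perm = n_perm, n_boot = n_boot, seed = seed, tail = tail)
}
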