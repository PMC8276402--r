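# Parentage assignment against a candidate pool. Per offspring and
# candidate the parent-offspring LOD is log10 L(PO)/L(UNRELATED) summed
# over mutually non-missing loci (same likelihood model as the dyad
# classifier); Mendelian mismatches are loci where the pair shares no
# allele. The caller applies the candidacy window (e.g. ascent years
# compatible with the offspring's hatch window).

#' Assign parentage from year-windowed candidate pools
#'
#' For each offspring the mother is the female candidate maximising the
#' parent-offspring LOD, subject to at most `max_mendel_mismatch`
#' Mendelian-mismatch loci, LOD at least `min_lod`, and at least
#' `min_comparable_loci` comparable loci; fathers likewise among males.
#' When both parents are assigned the trio must be jointly Mendelian
#' consistent at all but `max_mendel_mismatch` loci, otherwise the
#' lower-LOD parent is dropped. Candidates with unknown sex are excluded
#' and reported.
#'
#' @param offspring_geno Genotype table of the offspring sample.
#' @param candidate_geno Genotype table of the candidate parents.
#' @param candidates Tibble with `id` and `sex` for the candidates.
#' @param freqs Allele frequencies; default computed from both tables
#'   combined (fixed input frequencies, not updated during assignment).
#' @param eps Per-allele miscall probability.
#' @param max_mendel_mismatch Tolerated exclusion loci (default 1).
#' @param min_lod Minimum LOD (log10) for an assignment (default 5).
#' @param min_comparable_loci Minimum shared non-missing loci (default 10).
#' @return A `parentage_result` tibble, one row per offspring: `id`,
#'   `mother`, `father` (`NA` = no assignment), `mother_lod`, `father_lod`,
#'   `mother_mismatch`, `father_mismatch`, `trio_mismatch`,
#'   `dropped_parent`. Excluded unknown-sex candidates are in attribute
#'   `"excluded_candidates"`.
#' @export
assign_parentage <- function(offspring_geno, candidate_geno, candidates,
                             freqs = NULL, eps = 0.01,
                             max_mendel_mismatch = 1, min_lod = 5,
                             min_comparable_loci = 10) {
  stopifnot(all(c("id", "sex") %in% names(candidates)))
  unknown <- candidates$id[!candidates$sex %in% c("female", "male")]
  candidates <- dplyr::filter(candidates, .data$sex %in% c("female", "male"))
  cand_ids <- intersect(unique(candidate_geno$id), candidates$id)
  candidate_geno <- dplyr::filter(candidate_geno, .data$id %in% cand_ids)
  if (is.null(freqs)) {
    freqs <- allele_freqs(dplyr::bind_rows(
      offspring_geno,
      dplyr::mutate(candidate_geno, locus = factor(as.character(.data$locus),
                                                   levels = geno_loci(offspring_geno)))
    ))
  }
  tables <- build_dyad_tables(freqs, eps)
  Oo <- obs_index_matrix(offspring_geno, tables)
  Oc <- obs_index_matrix(candidate_geno, tables)
  no <- nrow(Oo); nc <- nrow(Oc)
  loci <- colnames(Oo)

  mo <- geno_matrices(offspring_geno)
  mc <- geno_matrices(candidate_geno)

  lod <- matrix(0, no, nc, dimnames = list(rownames(Oo), rownames(Oc)))
  mism <- matrix(0L, no, nc, dimnames = dimnames(lod))
  comp <- matrix(0L, no, nc, dimnames = dimnames(lod))
  for (l in seq_along(loci)) {
    tab <- tables[[loci[l]]]
    oi <- Oo[, l]; oj <- Oc[, l]
    ok <- outer(!is.na(oi), !is.na(oj), "&")
    comp <- comp + ok
    A1 <- tab$A[[2]]; A0 <- tab$A[[1]]
    contrib <- matrix(0, no, nc)
    pr <- which(ok, arr.ind = TRUE)
    if (nrow(pr)) {
      contrib[pr] <- log10(A1[cbind(oi[pr[, 1]], oj[pr[, 2]])]) -
        log10(A0[cbind(oi[pr[, 1]], oj[pr[, 2]])])
      lod <- lod + contrib
      share <- outer(mo$a1[, l], mc$a1[, l], "==") |
        outer(mo$a1[, l], mc$a2[, l], "==") |
        outer(mo$a2[, l], mc$a1[, l], "==") |
        outer(mo$a2[, l], mc$a2[, l], "==")
      mism <- mism + (ok & !share)
    }
  }

  sex <- candidates$sex[match(rownames(Oc), candidates$id)]
  pick_parent <- function(i, which_sex) {
    elig <- sex == which_sex & mism[i, ] <= max_mendel_mismatch &
      lod[i, ] >= min_lod & comp[i, ] >= min_comparable_loci
    if (!any(elig)) return(list(id = NA_character_, lod = NA_real_, mm = NA_integer_))
    j <- which(elig)[which.max(lod[i, elig])]
    list(id = rownames(Oc)[j], lod = lod[i, j], mm = mism[i, j])
  }

  trio_mismatches <- function(i, mj, fj) {
    x1 <- mo$a1[i, ]; x2 <- mo$a2[i, ]
    m1 <- mc$a1[mj, ]; m2 <- mc$a2[mj, ]
    f1 <- mc$a1[fj, ]; f2 <- mc$a2[fj, ]
    ok <- !is.na(x1) & !is.na(m1) & !is.na(f1)
    from_m1 <- (x1 == m1 | x1 == m2)
    from_m2 <- (x2 == m1 | x2 == m2)
    from_f1 <- (x1 == f1 | x1 == f2)
    from_f2 <- (x2 == f1 | x2 == f2)
    consistent <- (from_m1 & from_f2) | (from_m2 & from_f1)
    sum(ok & !consistent)
  }

  rows <- vector("list", no)
  for (i in seq_len(no)) {
    m <- pick_parent(i, "female")
    f <- pick_parent(i, "male")
    trio <- NA_integer_
    dropped <- NA_character_
    if (!is.na(m$id) && !is.na(f$id)) {
      trio <- trio_mismatches(i, match(m$id, rownames(Oc)), match(f$id, rownames(Oc)))
      if (trio > max_mendel_mismatch) {
        if (m$lod < f$lod) {
          dropped <- m$id
          m <- list(id = NA_character_, lod = NA_real_, mm = NA_integer_)
        } else {
          dropped <- f$id
          f <- list(id = NA_character_, lod = NA_real_, mm = NA_integer_)
        }
      }
    }
    rows[[i]] <- tibble::tibble(
      id = rownames(Oo)[i],
      mother = m$id, father = f$id,
      mother_lod = m$lod, father_lod = f$lod,
      mother_mismatch = m$mm, father_mismatch = f$mm,
      trio_mismatch = trio, dropped_parent = dropped
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "excluded_candidates") <- unknown
  class(out) <- c("parentage_result", class(out))
  out
}
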