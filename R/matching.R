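# Repeat-capture collapsing by multilocus genotype matching. Pairs are
# linked when they mismatch at no more than `max_mismatch` of their
# mutually non-missing loci; clusters are connected components of the link
# graph (components, not cliques: A-B and B-C may chain with A-C at
# 2 mismatches, mirroring common "matches" implementations).

# per-locus genotype codes (a1 * big + a2), NA for missing
geno_codes <- function(geno) {
  m <- geno_matrices(geno)
  list(code = m$a1 * 10000L + m$a2, a1 = m$a1, a2 = m$a2,
       ids = m$ids, loci = m$loci)
}

# tiny union-find for connected components
components_from_edges <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ri <- find(edges[k, 1]); rj <- find(edges[k, 2])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Collapse repeated captures by genotype matching
#'
#' Compares all record pairs over mutually non-missing loci, links pairs
#' with at most `max_mismatch` mismatching loci, and merges connected
#' components into single individuals whose capture history is the union of
#' member captures. Pairs sharing fewer than `min_shared_loci` comparable
#' loci are flagged uncomparable and never linked.
#'
#' @param geno Genotype table (one row-set per capture record).
#' @param meta Optional captures tibble; if supplied, the collapsed capture
#'   history and return counts are computed.
#' @param max_mismatch Maximum mismatching loci for a link (default 1).
#' @param min_shared_loci Minimum mutually non-missing loci for a pair to be
#'   comparable (default 10).
#' @return A `match_report` list: `clusters` (tibble `record_id`,
#'   `individual_id`), `pairs` (linked/uncomparable pairs with mismatch
#'   counts), `genotypes` (collapsed genotype table, consensus = member
#'   record with fewest missing loci), `meta` (collapsed captures, if `meta`
#'   given), `returns` (per-individual upstream return counts and year
#'   spans, if `meta` given).
#' @export
find_matches <- function(geno, meta = NULL, max_mismatch = 1,
                         min_shared_loci = 10) {
  gc <- geno_codes(geno)
  n <- length(gc$ids)
  if (n == 0) stop("empty dataset")
  L <- length(gc$loci)
  mism <- matrix(0L, n, n)
  shared <- matrix(0L, n, n)
  for (l in seq_len(L)) {
    v <- gc$code[, l]
    okv <- !is.na(v)
    both <- outer(okv, okv, "&")
    shared <- shared + both
    neq <- both & outer(v, v, "!=")
    neq[is.na(neq)] <- FALSE
    mism <- mism + neq
  }
  iu <- which(upper.tri(mism), arr.ind = TRUE)
  comparable <- shared[iu] >= min_shared_loci
  linked <- comparable & mism[iu] <= max_mismatch
  near <- linked | (mism[iu] <= max_mismatch + 2)  # keep context rows only
  pairs <- tibble::tibble(
    idA = gc$ids[iu[, 1]], idB = gc$ids[iu[, 2]],
    mismatches = mism[iu], shared_loci = shared[iu],
    comparable = comparable, linked = linked
  )[near | !comparable, ]

  comp <- components_from_edges(n, iu[linked, , drop = FALSE])
  # individual id = first member record id
  first_member <- tapply(seq_len(n), comp, min)
  ind_id <- gc$ids[first_member[comp]]
  clusters <- tibble::tibble(record_id = gc$ids, individual_id = ind_id)

  n_missing <- rowSums(is.na(gc$code))
  rep_rec <- vapply(split(seq_len(n), comp), function(ix) ix[which.min(n_missing[ix])],
                    integer(1))
  keep_ids <- gc$ids[rep_rec]
  collapsed <- dplyr::filter(geno, .data$id %in% keep_ids)
  relabel <- stats::setNames(ind_id[rep_rec], keep_ids)
  collapsed$id <- unname(relabel[collapsed$id])

  out <- list(clusters = clusters, pairs = pairs, genotypes = collapsed,
              max_mismatch = max_mismatch, min_shared_loci = min_shared_loci)
  if (!is.null(meta)) {
    m2 <- dplyr::filter(meta, .data$id %in% gc$ids)
    m2$id <- clusters$individual_id[match(m2$id, clusters$record_id)]
    m2 <- dplyr::distinct(dplyr::arrange(m2, .data$id, .data$capture_date))
    out$meta <- m2
    ups <- dplyr::filter(m2, .data$trap == "upstream")
    out$returns <- dplyr::summarise(
      dplyr::group_by(ups, .data$id),
      n_returns = dplyr::n(),
      n_years = dplyr::n_distinct(.data$year),
      year_span = max(.data$year) - min(.data$year),
      .groups = "drop"
    )
  }
  structure(out, class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  n_rec <- nrow(x$clusters)
  n_ind <- dplyr::n_distinct(x$clusters$individual_id)
  cat("<match_report> ", n_rec, " records -> ", n_ind, " individuals (",
      sum(x$pairs$linked), " linked pairs)\n", sep = "")
  invisible(x)
}

#' Flag records carrying alleles outside a species registry
#'
#' An individual is flagged when it carries out-of-registry alleles at `k`
#' or more loci, the signature of a non-target species amplified with the
#' same markers.
#'
#' @param geno Genotype table.
#' @param registry Named list: allowed allele codes per locus (must cover
#'   all loci in `geno`).
#' @param k Minimum number of offending loci (default 2).
#' @return Tibble `id`, `n_alien_loci` for flagged individuals.
#' @export
flag_non_target <- function(geno, registry, k = 2) {
  loci <- geno_loci(geno)
  miss <- setdiff(loci, names(registry))
  if (length(miss)) stop("registry does not cover loci: ", paste(miss, collapse = ", "))
  alien <- dplyr::mutate(
    dplyr::filter(geno, !is.na(.data$a1)),
    alien = !purrr::map2_lgl(
      .data$a1, as.character(.data$locus), ~ .x %in% registry[[.y]]) |
      !purrr::map2_lgl(.data$a2, as.character(.data$locus), ~ .x %in% registry[[.y]])
  )
  counts <- dplyr::summarise(dplyr::group_by(alien, .data$id),
                             n_alien_loci = sum(.data$alien), .groups = "drop")
  dplyr::filter(counts, .data$n_alien_loci >= k)
}

#' Estimate genotyping error and dropout rates from recaptures
#'
#' Uses clusters of repeat captures of the same individual: the per-allele
#' miscall rate is the fraction of mismatching allele calls among all
#' comparable allele calls between cluster members, and the dropout rate is
#' the fraction of discordant calls that are heterozygote vs
#' homozygote-subset discordances (e.g. 1/2 against 1/1).
#'
#' @param report A `match_report`.
#' @param geno The original (pre-collapse) genotype table.
#' @return One-row tibble: `error_rate`, `dropout_rate`, `n_compared_calls`,
#'   `n_discordant_calls`; rates are `NA` when no recaptures exist.
#' @export
estimate_error_rates <- function(report, geno) {
  cl <- report$clusters
  multi <- dplyr::filter(dplyr::add_count(cl, .data$individual_id), .data$n > 1)
  if (nrow(multi) == 0) {
    return(tibble::tibble(error_rate = NA_real_, dropout_rate = NA_real_,
                          n_compared_calls = 0L, n_discordant_calls = 0L))
  }
  gc <- geno_codes(geno)
  allele_mism <- 0L
  total_alleles <- 0L
  discord <- 0L
  dropout_like <- 0L
  for (ind in unique(multi$individual_id)) {
    members <- match(multi$record_id[multi$individual_id == ind], gc$ids)
    prs <- utils::combn(members, 2)
    for (c2 in seq_len(ncol(prs))) {
      i <- prs[1, c2]; j <- prs[2, c2]
      ok <- !is.na(gc$code[i, ]) & !is.na(gc$code[j, ])
      total_alleles <- total_alleles + 2L * sum(ok)
      for (l in which(ok)) {
        gi <- c(gc$a1[i, l], gc$a2[i, l])
        gj <- c(gc$a1[j, l], gc$a2[j, l])
        if (identical(gi, gj)) next
        discord <- discord + 1L
        # multiset intersection size -> 1 or 2 differing alleles
        tmp <- gj
        inter <- 0L
        for (a in gi) {
          hit <- match(a, tmp)
          if (!is.na(hit)) { inter <- inter + 1L; tmp <- tmp[-hit] }
        }
        allele_mism <- allele_mism + (2L - inter)
        het_i <- gi[1] != gi[2]
        het_j <- gj[1] != gj[2]
        if (xor(het_i, het_j)) {
          hom <- if (het_i) gj else gi
          het <- if (het_i) gi else gj
          if (hom[1] %in% het) dropout_like <- dropout_like + 1L
        }
      }
    }
  }
  tibble::tibble(
    error_rate = allele_mism / total_alleles,
    dropout_rate = if (discord > 0) dropout_like / discord else NA_real_,
    n_compared_calls = total_alleles %/% 2L,
    n_discordant_calls = discord
  )
}
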