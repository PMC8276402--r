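# Pairwise relationship likelihoods for unordered diploid genotypes.
# Categories are parameterised by IBD coefficients (k0, k1, k2):
#   UNRELATED (1,0,0), HALFSIB (1/2,1/2,0), FULLSIB (1/4,1/2,1/4),
#   PARENT_OFFSPRING (0,1,0).
# Per locus the dyad likelihood is sum_m k_m P(g1,g2 | m IBD alleles),
# with observed genotypes linked to true genotypes by a per-allele miscall
# model: observed = true with probability 1-eps, otherwise uniform on the
# locus registry. Everything is precomputed as per-locus lookup tables over
# unordered genotype pairs, so scoring any number of dyads is just matrix
# indexing.

KIN_CATEGORIES <- c("UNRELATED", "HALFSIB", "FULLSIB", "PARENT_OFFSPRING")

kin_k_coefs <- function(category) {
  switch(category,
         UNRELATED = c(1, 0, 0),
         HALFSIB = c(0.5, 0.5, 0),
         FULLSIB = c(0.25, 0.5, 0.25),
         PARENT_OFFSPRING = c(0, 1, 0),
         stop("unknown category: ", category))
}

# per-locus lookup tables: obs-pair likelihood matrices for m = 0,1,2 IBD
# alleles, genotype indexing helpers
build_locus_tables <- function(p, eps) {
  al <- as.integer(names(p))
  p <- as.numeric(p) / sum(p)
  K <- length(al)
  idx <- which(upper.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
  G <- nrow(idx)              # unordered genotypes (i <= j as allele indices)
  g1 <- idx[, 1]; g2 <- idx[, 2]
  gprob <- ifelse(g1 == g2, p[g1]^2, 2 * p[g1] * p[g2])
  # genotype index lookup from a pair of allele codes
  gidx <- matrix(NA_integer_, K, K)
  gidx[cbind(g1, g2)] <- seq_len(G)
  gidx[cbind(g2, g1)] <- seq_len(G)

  # one-IBD transition: from genotype t1, share one allele (1/2 each),
  # draw the other from the frequencies
  T1 <- matrix(0, G, G)
  for (t in seq_len(G)) {
    for (shared in unique(c(g1[t], g2[t]))) {
      w <- if (g1[t] == g2[t]) 1 else 0.5
      for (x in seq_len(K)) {
        tgt <- gidx[shared, x]
        T1[t, tgt] <- T1[t, tgt] + w * p[x]
      }
    }
  }
  J0 <- outer(gprob, gprob)
  J1 <- gprob * T1                      # P(t1) * P(t2 | 1 IBD)
  J2 <- diag(gprob)

  # emission: P(observed unordered genotype | true unordered genotype)
  e <- (1 - eps) * diag(K) + eps / K    # e[o, t] per allele
  M <- matrix(0, G, G)
  for (o in seq_len(G)) {
    o1 <- g1[o]; o2 <- g2[o]
    if (o1 == o2) {
      M[o, ] <- e[o1, g1] * e[o1, g2]
    } else {
      M[o, ] <- e[o1, g1] * e[o2, g2] + e[o2, g1] * e[o1, g2]
    }
  }
  A <- list(M %*% J0 %*% t(M), M %*% J1 %*% t(M), M %*% J2 %*% t(M))
  list(alleles = al, gidx = gidx, A = A, gprob = gprob)
}

build_dyad_tables <- function(freqs, eps) {
  fb <- freq_list(freqs)
  lapply(fb, build_locus_tables, eps = eps)
}

# observed genotype index matrix (individuals x loci), NA = missing or
# allele outside the frequency registry
obs_index_matrix <- function(geno, tables) {
  m <- geno_matrices(geno)
  out <- matrix(NA_integer_, length(m$ids), length(m$loci),
                dimnames = list(m$ids, m$loci))
  for (l in seq_along(m$loci)) {
    tab <- tables[[m$loci[l]]]
    if (is.null(tab)) next
    i1 <- match(m$a1[, l], tab$alleles)
    i2 <- match(m$a2[, l], tab$alleles)
    ok <- !is.na(i1) & !is.na(i2)
    out[ok, l] <- tab$gidx[cbind(i1[ok], i2[ok])]
  }
  out
}

#' Log-likelihood of a dyad under a relationship category
#'
#' @param geno Genotype table containing both individuals.
#' @param id1,id2 Individual ids.
#' @param freqs Allele frequency tibble ([allele_freqs()] format); defaults
#'   to frequencies computed from `geno`.
#' @param eps Per-allele miscall probability.
#' @param category One of `"UNRELATED"`, `"HALFSIB"`, `"FULLSIB"`,
#'   `"PARENT_OFFSPRING"`.
#' @param min_comparable_loci Minimum mutually non-missing loci.
#' @return Natural-log likelihood (may be `-Inf`, e.g. a Mendelian
#'   exclusion under `eps = 0`).
#' @export
dyad_loglik <- function(geno, id1, id2, freqs = NULL, eps = 0.01,
                        category = "FULLSIB", min_comparable_loci = 1) {
  stopifnot(category %in% KIN_CATEGORIES)
  if (is.null(freqs)) freqs <- allele_freqs(geno)
  if (eps == 0) {
    obs <- unique(c(geno$a1, geno$a2))
    reg <- unique(freqs$allele)
    if (any(!stats::na.omit(obs) %in% reg))
      stop("allele absent from frequency table with eps = 0")
  }
  tables <- build_dyad_tables(freqs, eps)
  O <- obs_index_matrix(dplyr::filter(geno, .data$id %in% c(id1, id2)), tables)
  o1 <- O[id1, ]; o2 <- O[id2, ]
  ok <- which(!is.na(o1) & !is.na(o2))
  if (length(ok) < min_comparable_loci)
    stop("only ", length(ok), " comparable loci; need ", min_comparable_loci)
  k <- kin_k_coefs(category)
  ll <- 0
  loci <- colnames(O)
  for (l in ok) {
    A <- tables[[loci[l]]]$A
    lik <- k[1] * A[[1]][o1[l], o2[l]] + k[2] * A[[2]][o1[l], o2[l]] +
      k[3] * A[[3]][o1[l], o2[l]]
    ll <- ll + log(lik)
  }
  ll
}

# all-pairs category log-likelihood computation shared by classify_dyads
# and reconstruct_sibships; returns matrices of summed log-likelihoods
dyad_loglik_all <- function(geno, freqs, eps, ids = NULL) {
  tables <- build_dyad_tables(freqs, eps)
  O <- obs_index_matrix(geno, tables)
  if (!is.null(ids)) O <- O[ids, , drop = FALSE]
  n <- nrow(O)
  pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  np <- nrow(pair)
  ll <- list(UNRELATED = numeric(np), HALFSIB = numeric(np),
             FULLSIB = numeric(np), PARENT_OFFSPRING = numeric(np))
  comp <- integer(np)
  loci <- colnames(O)
  ks <- lapply(KIN_CATEGORIES, kin_k_coefs)
  names(ks) <- KIN_CATEGORIES
  for (l in seq_along(loci)) {
    o <- O[, l]
    oi <- o[pair[, 1]]
    oj <- o[pair[, 2]]
    ok <- !is.na(oi) & !is.na(oj)
    if (!any(ok)) next
    comp <- comp + ok
    A <- tables[[loci[l]]]$A
    a0 <- A[[1]][cbind(oi[ok], oj[ok])]
    a1 <- A[[2]][cbind(oi[ok], oj[ok])]
    a2 <- A[[3]][cbind(oi[ok], oj[ok])]
    for (cat in KIN_CATEGORIES) {
      k <- ks[[cat]]
      ll[[cat]][ok] <- ll[[cat]][ok] + log(k[1] * a0 + k[2] * a1 + k[3] * a2)
    }
  }
  # identical observed genotypes at every comparable locus (possible twin
  # or unnoticed duplicate: FS / PO / recapture are then indistinguishable)
  identical_pair <- rep(TRUE, np)
  for (l in seq_along(loci)) {
    o <- O[, l]
    oi <- o[pair[, 1]]; oj <- o[pair[, 2]]
    ok <- !is.na(oi) & !is.na(oj)
    identical_pair[ok & oi != oj] <- FALSE
  }
  list(ids = rownames(O), pair = pair, comp = comp, ll = ll,
       identical_pair = identical_pair)
}

#' Classify all dyads in a sample by relationship likelihood
#'
#' Scores every within-sample pair under the four relationship categories;
#' the best non-unrelated category is retained when its log-likelihood
#' ratio against UNRELATED reaches `llr_threshold`, otherwise the pair is
#' called UNRELATED. FULLSIB and PARENT_OFFSPRING are genotypically
#' near-indistinguishable for a single pair; dyads whose top two
#' non-unrelated categories fall within `ambiguity_margin` log units are
#' flagged.
#'
#' @param geno Genotype table (one sample).
#' @param freqs Allele frequencies; default computed from `geno`.
#' @param eps Per-allele miscall probability.
#' @param llr_threshold Retention threshold for the best-vs-unrelated
#'   log-likelihood ratio (natural log).
#' @param min_comparable_loci Pairs with fewer mutually non-missing loci
#'   are marked `UNCOMPARABLE` and never linked.
#' @param ambiguity_margin Log-units margin for the ambiguity flag.
#' @param categories Candidate categories to consider besides UNRELATED.
#'   Capture metadata can rule categories out a priori: within one smolt
#'   cohort no dyad can be parent and offspring, so cohort analyses pass
#'   `c("HALFSIB", "FULLSIB")`.
#' @return Tibble: `id_a`, `id_b`, `n_comparable`, the four category
#'   log-likelihoods (`ll_*`), `best`, `llr`, `ambiguous`.
#' @export
classify_dyads <- function(geno, freqs = NULL, eps = 0.01, llr_threshold = 3,
                           min_comparable_loci = 10, ambiguity_margin = 2,
                           categories = c("HALFSIB", "FULLSIB",
                                          "PARENT_OFFSPRING")) {
  stopifnot(all(categories %in% KIN_CATEGORIES), length(categories) >= 1)
  if (is.null(freqs)) freqs <- allele_freqs(geno)
  d <- dyad_loglik_all(geno, freqs, eps)
  lls <- do.call(cbind, d$ll)
  rel <- lls[, categories, drop = FALSE] - lls[, "UNRELATED"]
  best_rel <- colnames(rel)[max.col(rel, ties.method = "first")]
  best_llr <- rel[cbind(seq_len(nrow(rel)), max.col(rel, ties.method = "first"))]
  best <- ifelse(best_llr >= llr_threshold, best_rel, "UNRELATED")
  llr <- pmax(best_llr, 0)
  second <- if (ncol(rel) >= 2) {
    apply(rel, 1, function(x) sort(x, decreasing = TRUE)[2])
  } else {
    rep(-Inf, nrow(rel))
  }
  ambiguous <- best != "UNRELATED" &
    ((best_llr - second) < ambiguity_margin | d$identical_pair)
  uncomp <- d$comp < min_comparable_loci
  best[uncomp] <- "UNCOMPARABLE"
  llr[uncomp] <- NA_real_
  tibble::tibble(
    id_a = d$ids[d$pair[, 1]], id_b = d$ids[d$pair[, 2]],
    n_comparable = d$comp,
    ll_unrelated = lls[, "UNRELATED"], ll_halfsib = lls[, "HALFSIB"],
    ll_fullsib = lls[, "FULLSIB"], ll_po = lls[, "PARENT_OFFSPRING"],
    best = best, llr = llr, ambiguous = ambiguous & !uncomp
  )
}

# one greedy agglomeration run over the full-sib LLR matrix
greedy_partition_run <- function(W, seed) {
  set.seed(seed)
  n <- nrow(W)
  G <- W                      # cluster-level gain matrix
  diag(G) <- -Inf
  member <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  repeat {
    pos <- which(G > 0 & outer(active, active), arr.ind = TRUE)
    pos <- pos[pos[, 1] < pos[, 2], , drop = FALSE]
    if (!nrow(pos)) break
    pick <- pos[sample.int(nrow(pos), 1), ]
    i <- pick[1]; j <- pick[2]
    member[[i]] <- c(member[[i]], member[[j]])
    member[[j]] <- integer()
    active[j] <- FALSE
    G[i, ] <- G[i, ] + G[j, ]
    G[, i] <- G[, i] + G[, j]
    G[i, i] <- -Inf
    G[j, ] <- -Inf
    G[, j] <- -Inf
  }
  cl <- integer(n)
  fam <- 0L
  for (i in which(active)) {
    fam <- fam + 1L
    cl[member[[i]]] <- fam
  }
  refine_partition(W, cl)
}

# local search: move single individuals between families (or out to a new
# singleton) while the summed within-family FS-vs-unrelated log-likelihood
# improves; repairs early lock-ins of the greedy agglomeration
refine_partition <- function(W, cl, max_passes = 20) {
  n <- length(cl)
  for (pass in seq_len(max_passes)) {
    moved <- FALSE
    for (i in sample.int(n)) {
      sums <- rowsum(W[, i], cl)            # per-cluster sum of W[i, members]
      cur <- sums[as.character(cl[i]), 1]   # own cluster (W[i,i] = 0)
      cand <- c(sums[, 1], 0)               # 0 = leave as a new singleton
      names(cand)[length(cand)] <- max(cl) + 1L
      best <- which.max(cand)
      if (names(cand)[best] != as.character(cl[i]) && cand[best] > cur + 1e-9) {
        cl[i] <- as.integer(names(cand)[best])
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  match(cl, unique(cl))
}

# half-sib links between the families of one run: positive summed HS LLR
halfsib_links_run <- function(Whs, cl) {
  fams <- sort(unique(cl))
  links <- list()
  for (a in seq_along(fams)) {
    for (b in seq_len(a - 1)) {
      ia <- which(cl == fams[a]); ib <- which(cl == fams[b])
      if (sum(Whs[ia, ib]) > 0) links[[length(links) + 1]] <- c(fams[b], fams[a])
    }
  }
  if (length(links)) do.call(rbind, links) else matrix(integer(), 0, 2)
}

#' Reconstruct full-sib families and half-sib links by consensus
#'
#' Runs a randomized greedy agglomeration `n_runs` times: clusters are
#' merged into full-sib families whenever the merge improves the summed
#' full-sib-vs-unrelated log-likelihood of within-family pairs, with the
#' merge order randomized by each run's seed; half-sib links between
#' families are added on the same criterion with the half-sib likelihood.
#' Only co-memberships and half-sib pairs present in every run are kept
#' (the intersection of equivalence relations is itself one, so the
#' consensus is a valid partition).
#'
#' @param geno Genotype table (one sample).
#' @param freqs Allele frequencies; default computed from `geno`.
#' @param eps Per-allele miscall probability.
#' @param n_runs Number of randomized runs (default 3).
#' @param seed Master seed; run seeds derive from it.
#' @param min_comparable_loci Pairs below this are never linked.
#' @return A `sibship_partition`: `families` (tibble `id`, `family`),
#'   `halfsib_pairs` (tibble `id_a`, `id_b`, consensus half-sib dyads
#'   between different families), `run_comembership` (list of per-run
#'   family vectors, for reliability checks), `seeds`.
#' @export
reconstruct_sibships <- function(geno, freqs = NULL, eps = 0.01, n_runs = 3,
                                 seed = 1, min_comparable_loci = 10) {
  if (is.null(freqs)) freqs <- allele_freqs(geno)
  d <- dyad_loglik_all(geno, freqs, eps)
  n <- length(d$ids)
  W <- matrix(0, n, n)
  Whs <- matrix(0, n, n)
  usable <- d$comp >= min_comparable_loci
  ij <- d$pair[usable, , drop = FALSE]
  W[ij] <- (d$ll$FULLSIB - d$ll$UNRELATED)[usable]
  W[ij[, c(2, 1), drop = FALSE]] <- W[ij]
  Whs[ij] <- (d$ll$HALFSIB - d$ll$UNRELATED)[usable]
  Whs[ij[, c(2, 1), drop = FALSE]] <- Whs[ij]

  seeds <- vapply(seq_len(n_runs), function(r) derive_seed(seed, paste0("sib", r)),
                  integer(1))
  runs <- lapply(seeds, function(s) greedy_partition_run(W, s))
  hs_runs <- lapply(runs, function(cl) {
    lk <- halfsib_links_run(Whs, cl)
    if (!nrow(lk)) return(matrix(integer(), 0, 2))
    prs <- list()
    for (r in seq_len(nrow(lk))) {
      ia <- which(cl == lk[r, 1]); ib <- which(cl == lk[r, 2])
      eg <- expand.grid(ia, ib)
      prs[[r]] <- cbind(pmin(eg[, 1], eg[, 2]), pmax(eg[, 1], eg[, 2]))
    }
    do.call(rbind, prs)
  })

  # consensus co-membership
  key <- function(m) if (nrow(m)) paste(m[, 1], m[, 2]) else character()
  co_keys <- lapply(runs, function(cl) {
    same <- outer(cl, cl, "==")
    ij2 <- which(same & upper.tri(same), arr.ind = TRUE)
    paste(ij2[, 1], ij2[, 2])
  })
  co_cons <- Reduce(intersect, co_keys)
  edges <- if (length(co_cons)) {
    do.call(rbind, lapply(strsplit(co_cons, " "), as.integer))
  } else matrix(integer(), 0, 2)
  fam <- components_from_edges(n, edges)

  hs_cons <- Reduce(intersect, lapply(hs_runs, key))
  hs_edges <- if (length(hs_cons)) {
    do.call(rbind, lapply(strsplit(hs_cons, " "), as.integer))
  } else matrix(integer(), 0, 2)
  # never within one consensus family
  if (nrow(hs_edges)) {
    keep <- fam[hs_edges[, 1]] != fam[hs_edges[, 2]]
    hs_edges <- hs_edges[keep, , drop = FALSE]
  }

  structure(list(
    families = tibble::tibble(id = d$ids, family = fam),
    halfsib_pairs = tibble::tibble(id_a = d$ids[hs_edges[, 1]],
                                   id_b = d$ids[hs_edges[, 2]]),
    run_comembership = runs,
    seeds = seeds
  ), class = "sibship_partition")
}

#' @export
print.sibship_partition <- function(x, ...) {
  sz <- table(x$families$family)
  cat("<sibship_partition> ", length(sz), " families over ",
      nrow(x$families), " individuals (largest ", max(sz), "); ",
      nrow(x$halfsib_pairs), " consensus half-sib dyads\n", sep = "")
  invisible(x)
}

#' Full-sib dyads implied by a sibship partition
#' @param partition A `sibship_partition`.
#' @return Tibble `id_a`, `id_b` of co-membered pairs.
#' @export
fullsib_dyads <- function(partition) {
  fams <- split(partition$families$id, partition$families$family)
  prs <- purrr::map_dfr(fams[lengths(fams) > 1], function(ids) {
    cb <- utils::combn(sort(ids), 2)
    tibble::tibble(id_a = cb[1, ], id_b = cb[2, ])
  })
  if (nrow(prs) == 0) tibble::tibble(id_a = character(), id_b = character()) else prs
}
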