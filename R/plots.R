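# ggplot2 views of the main result types

#' @export
autoplot.contribution_summary <- function(object, ...) {
  d <- object$categories
  d$category <- factor(d$category, levels = c("AA", "RA", "AR", "RR"),
                       labels = c("both anadromous",
                                  "resident father x anadromous mother",
                                  "anadromous father x resident mother",
                                  "both resident"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "% of smolts",
                  title = "Parental origin of the smolt run") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' @export
autoplot.ne_estimate <- function(object, ...) {
  d <- tibble::as_tibble(object)
  cap <- function(v, hi) pmin(v, hi)
  hi <- max(d$ne_point[is.finite(d$ne_point)], 100) * 3
  ggplot2::ggplot(d, ggplot2::aes(x = 1, y = cap(.data$ne_point, hi))) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = cap(.data$ci_low, hi),
                                          ymax = cap(.data$ci_high, hi))) +
    ggplot2::labs(x = NULL, y = "Ne (LD method)",
                  title = "Effective population size") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Per-sample diversity overview plot
#'
#' @param summary A `diversity_summary` tibble.
#' @return A ggplot object showing mean expected heterozygosity with its
#'   bootstrap interval per sample.
#' @export
plot_diversity <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$sample, y = .data$h_exp)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$h_exp_lo,
                                          ymax = .data$h_exp_hi)) +
    ggplot2::labs(x = NULL, y = expression(H[E]),
                  title = "Unbiased expected heterozygosity by sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Timing-by-kinship diagnostic plot for one sample
#'
#' Shows migration dates of individuals grouped into their full-sib
#' families (families of one are pooled as "singletons").
#'
#' @param partition A `sibship_partition`.
#' @param meta Captures tibble.
#' @param year Restrict to this capture year.
#' @return A ggplot object.
#' @export
plot_family_timing <- function(partition, meta, year = NULL) {
  m <- meta
  if (!is.null(year)) m <- dplyr::filter(m, .data$year == !!year)
  prim <- dplyr::summarise(dplyr::group_by(m, .data$id),
                           date = min(.data$capture_date), .groups = "drop")
  d <- dplyr::inner_join(partition$families, prim, by = "id")
  sz <- table(d$family)
  d$fam_label <- ifelse(sz[as.character(d$family)] > 1,
                        paste0("F", d$family), "singletons")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fam_label, y = .data$date)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::labs(x = "full-sib family", y = "migration date",
                  title = "Migration timing by family") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
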