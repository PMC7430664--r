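#' Plot per-position information content of phase profiles
#'
#' Bar chart of information content (bits) across the 35 motif positions,
#' faceted by phase; the conserved-signature positions stand out as tall
#' bars in a single phase.
#'
#' @param object A `ppr_phase_profiles` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ppr_phase_profiles <- function(object, ...) {
  ggplot2::ggplot(
    object$info,
    ggplot2::aes(x = .data$position, y = .data$ic)
  ) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::facet_wrap(~ .data$phase, ncol = 1) +
    ggplot2::labs(
      x = "motif position",
      y = "information content (bits)",
      title = paste0("Phase-stratified PPR conservation: ", object$protein_id)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a binding profile as a weight heatmap
#'
#' @param object A `ppr_binding_profile` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ppr_binding_profile <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$position, y = .data$base, fill = .data$weight)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(
      x = "target position (5' to 3')", y = NULL, fill = "weight",
      title = paste0("PPR binding profile: ", object$protein_id)
    ) +
    ggplot2::theme_minimal()
}

#' Plot log-odds scan scores along a sequence
#'
#' @param scores A scan tibble from [scan_rna()].
#' @return A ggplot object with the best window highlighted.
#' @export
plot_scan_scores <- function(scores) {
  stopifnot(all(c("seq_id", "start", "score", "is_best") %in% names(scores)))
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$start, y = .data$score)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(
      data = dplyr::filter(scores, .data$is_best),
      colour = "firebrick", size = 2
    ) +
    ggplot2::facet_wrap(~ .data$seq_id, scales = "free_x") +
    ggplot2::labs(x = "window start (nt)", y = "log-odds score (bits)") +
    ggplot2::theme_minimal()
}

#' Plot motif loci and repeat tracts along a sequence
#'
#' @param loci A loci tibble (from [find_motif_loci()]); may be empty.
#' @param tracts Optional repeat-tract tibble (from [find_repeat_tracts()]).
#' @param seq_len Optional sequence length to fix the x axis.
#' @return A ggplot object.
#' @export
plot_motif_map <- function(loci, tracts = NULL, seq_len = NULL) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(loci)))
  layers <- list()
  dat <- mutate(loci, feature = "motif locus")
  if (!is.null(tracts) && nrow(tracts)) {
    dat <- bind_rows(
      dat,
      tracts |>
        select("seq_id", "start", "end") |>
        mutate(feature = "repeat tract")
    )
  }
  p <- ggplot2::ggplot(
    dat,
    ggplot2::aes(xmin = .data$start, xmax = .data$end,
                 ymin = as.numeric(factor(.data$feature)) - 0.35,
                 ymax = as.numeric(factor(.data$feature)) + 0.35,
                 fill = .data$feature)
  ) +
    ggplot2::geom_rect() +
    ggplot2::facet_wrap(~ .data$seq_id, ncol = 1) +
    ggplot2::scale_y_continuous(
      breaks = seq_along(unique(dat$feature)),
      labels = sort(unique(dat$feature))
    ) +
    ggplot2::labs(x = "position (nt)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(seq_len)) {
    p <- p + ggplot2::xlim(1, seq_len)
  }
  p
}
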