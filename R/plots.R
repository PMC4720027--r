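#' Plot per-feature growth curves
#'
#' Nucleus counts over days, one line per feature, coloured by growth class
#' when present; counts are shown on a log scale since the fitted model is
#' exponential.
#'
#' @param data Count records (`well`, `grid_row`, `grid_col`, `day`,
#'   `nucleus_count`), optionally joined to a classification, or the output
#'   of [classify_growth()] (its list columns are unnested).
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(data) {
  if ("days" %in% names(data)) {
    data <- tidyr::unnest(
      dplyr::select(data, dplyr::any_of(c("well", "grid_row", "grid_col",
                                          "growth_class", "days", "counts"))),
      c("days", "counts")) |>
      dplyr::rename(day = "days", nucleus_count = "counts")
  }
  data <- dplyr::mutate(
    data, feature = interaction(.data$well, .data$grid_row, .data$grid_col))
  aes_col <- if ("growth_class" %in% names(data)) {
    ggplot2::aes(x = .data$day, y = pmax(.data$nucleus_count, 0.5),
                 group = .data$feature, colour = .data$growth_class)
  } else {
    ggplot2::aes(x = .data$day, y = pmax(.data$nucleus_count, 0.5),
                 group = .data$feature)
  }
  ggplot2::ggplot(data, aes_col) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Day", y = "Nuclei per feature (log scale)",
                  colour = "Growth class") +
    ggplot2::theme_minimal()
}

#' Plot a per-base wild-type match profile
#'
#' Match frequency along the amplicon with masked primer positions greyed
#' out and the expected cut site(s) marked; the dip localises the indel
#' spectrum, expected 3-4 nt upstream of the PAM.
#'
#' @param profile Tibble from [per_base_profile()].
#' @param cut_sites Optional integer cut-site coordinates to mark.
#' @return A ggplot object.
#' @export
plot_per_base_profile <- function(profile, cut_sites = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$position, y = .data$match_freq,
                                    colour = .data$masked)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "grey70")) +
    ggplot2::labs(x = "Reference position (0-based)",
                  y = "Fraction of reads matching wild type",
                  colour = "Primer-masked") +
    ggplot2::theme_minimal()
  if (!is.null(cut_sites)) {
    p <- p + ggplot2::geom_vline(xintercept = cut_sites, linetype = "dashed",
                                 colour = "red")
  }
  p
}

#' Plot an edit summary as stacked fractions
#'
#' @param summary One-row tibble from [summarize_edits()] (or several rows,
#'   one per amplicon, with an optional `name` column).
#' @return A ggplot object.
#' @export
plot_edit_summary <- function(summary) {
  if (!"name" %in% names(summary)) {
    summary$name <- paste0("amplicon_", seq_len(nrow(summary)))
  }
  long <- summary |>
    dplyr::mutate(frac_indel_other = .data$frac_indel - .data$frac_inframe) |>
    dplyr::select("name", wild_type = "frac_wt",
                  `in-frame indel` = "frac_inframe",
                  `frameshift indel` = "frac_indel_other") |>
    tidyr::pivot_longer(-"name", names_to = "class", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$name, y = .data$fraction,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Fraction of reads", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot methods
#'
#' `autoplot()` dispatches to the matching `plot_*()` function:
#' segmentations render the label image, screen runs render their growth
#' curves by class.
#'
#' @param object A `segmentation` or `screen_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.segmentation <- function(object, ...) {
  lab <- object$label_image
  df <- tibble(
    x = as.vector(row(lab)), y = as.vector(col(lab)),
    label = factor(as.vector(lab))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$label)) +
    ggplot2::geom_raster(show.legend = FALSE) +
    ggplot2::scale_fill_manual(
      values = c("0" = "black",
                 setNames(grDevices::hcl.colors(
                   max(1, object$nucleus_count), "Spectral"),
                   as.character(seq_len(max(1, object$nucleus_count)))))) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @rdname autoplot.segmentation
#' @export
autoplot.screen_run <- function(object, ...) {
  plot_growth_curves(object$classified)
}

#' @export
ggplot2::autoplot
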