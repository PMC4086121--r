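# Visual analyses of a prediction run: per-sequence basic-residue
# graphics (di/tribasic motifs in red, single basics in green) and
# feature-distribution histograms in standard-deviation units.

#' Sequence graphic of basic-residue motifs
#'
#' Draws the sequence as a horizontal baseline proportional to its length
#' with red marks spanning dibasic/tribasic motifs and green marks at
#' single basic residues, annotated with motif counts and density
#' (motifs per 100 aa).
#'
#' @param sequence A one-row tibble with `id` and `residues`, or a
#'   residue string.
#' @param id Identifier used in the title when `sequence` is a string.
#' @return A ggplot object.
#' @export
#' @examples
#' plot_sequence_motifs("MAKKAARRGALLKAAGKKRA", id = "demo")
plot_sequence_motifs <- function(sequence, id = "sequence") {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1L)
    id <- sequence$id[1]
    residues <- sequence$residues[1]
  } else {
    residues <- sequence
  }
  m <- find_basic_sites(residues)
  marks <- motif_table(tibble::tibble(id = id, residues = residues))
  density <- 100 * (m$n_dibasic + m$n_tribasic) / m$length
  subtitle <- sprintf(
    "%d aa | %d dibasic + %d tribasic motifs (%.2f per 100 aa), %d single basic",
    m$length, m$n_dibasic, m$n_tribasic, density, m$n_single
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = tibble::tibble(x = 0.5, xend = m$length + 0.5),
      ggplot2::aes(x = .data$x, xend = .data$xend, y = 0, yend = 0),
      linewidth = 1.2, colour = "grey30"
    )
  if (nrow(marks) > 0) {
    marks <- marks |>
      dplyr::mutate(
        fill = ifelse(.data$motif_class == "single", "single basic",
                      "di/tribasic motif")
      )
    p <- p + ggplot2::geom_rect(
      data = marks,
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                   ymin = -0.35, ymax = 0.35, fill = .data$fill)
    )
  }
  p +
    ggplot2::scale_fill_manual(
      values = c("di/tribasic motif" = "red3", "single basic" = "green4"),
      name = NULL
    ) +
    ggplot2::scale_y_continuous(limits = c(-1, 1), breaks = NULL) +
    ggplot2::labs(title = id, subtitle = subtitle,
                  x = "residue position", y = NULL) +
    ggplot2::theme_minimal()
}

#' Render a sequence motif graphic as an SVG document
#'
#' Writes a standalone, well-formed SVG: a baseline scaled to the
#' sequence length, red rectangles over dibasic/tribasic motif spans,
#' green rectangles at single basic residues, and a text annotation with
#' the motif counts and density.
#'
#' @inheritParams plot_sequence_motifs
#' @param path Output `.svg` path.
#' @param width,height Canvas size in pixels.
#' @return `path`, invisibly.
#' @export
render_sequence_svg <- function(sequence, path, id = "sequence",
                                width = 800, height = 120) {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1L)
    id <- sequence$id[1]
    residues <- sequence$residues[1]
  } else {
    residues <- sequence
  }
  m <- find_basic_sites(residues)
  marks <- motif_table(tibble::tibble(id = id, residues = residues))
  density <- 100 * (m$n_dibasic + m$n_tribasic) / m$length
  margin <- 40
  xscale <- (width - 2 * margin) / m$length
  y0 <- height / 2
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  lines <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'),
            width, height, width, height),
    sprintf('<title>%s</title>', esc(id)),
    sprintf(paste0('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" ',
                   'stroke="#444444" stroke-width="3"/>'),
            margin, y0, margin + m$length * xscale, y0)
  )
  if (nrow(marks) > 0) {
    colour <- ifelse(marks$motif_class == "single", "#1a9641", "#d7191c")
    lines <- c(lines, sprintf(
      paste0('<rect x="%.2f" y="%.2f" width="%.2f" height="24" ',
             'fill="%s"><desc>%s %d-%d</desc></rect>'),
      margin + (marks$start - 1) * xscale, y0 - 12,
      pmax((marks$end - marks$start + 1) * xscale, 1), colour,
      marks$motif_class, marks$start, marks$end
    ))
  }
  lines <- c(
    lines,
    sprintf(paste0('<text x="%.2f" y="%.2f" font-size="12" ',
                   'font-family="sans-serif">%s: %d aa, %d dibasic + %d ',
                   'tribasic motifs (%.2f per 100 aa), %d single basic',
                   '</text>'),
            margin, height - 12, esc(id), m$length, m$n_dibasic,
            m$n_tribasic, density, m$n_single),
    "</svg>"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Rescale two feature distributions to standard-deviation units
#'
#' Centers both sets on the pooled mean and scales each set by its own
#' standard deviation, yielding the "Feature Units" axis of the feature
#' histogram. Errors if either set has zero variance, naming the set.
#'
#' @param pos_values,neg_values Numeric feature values of the positive
#'   and negative sets.
#' @param query_value Optional value of a query sequence (rescaled with
#'   the positive set's SD).
#' @return A list with tibble `data` (`value`, `set`) and
#'   `query` (rescaled query value or `NA`).
#' @export
normalize_feature_units <- function(pos_values, neg_values,
                                    query_value = NULL) {
  stopifnot(length(pos_values) > 0, length(neg_values) > 0)
  sd_pos <- stats::sd(pos_values)
  sd_neg <- stats::sd(neg_values)
  if (is.na(sd_pos) || sd_pos == 0) {
    stop("positive set has zero variance; cannot rescale", call. = FALSE)
  }
  if (is.na(sd_neg) || sd_neg == 0) {
    stop("negative set has zero variance; cannot rescale", call. = FALSE)
  }
  center <- mean(c(pos_values, neg_values))
  data <- dplyr::bind_rows(
    tibble::tibble(value = (pos_values - center) / sd_pos, set = "positive"),
    tibble::tibble(value = (neg_values - center) / sd_neg, set = "negative")
  )
  query <- if (is.null(query_value)) NA_real_ else {
    (query_value - center) / sd_pos
  }
  list(data = data, query = query)
}

#' Feature histogram of positive vs negative sets
#'
#' Overlaid distributions of one feature over the positive (green) and
#' negative (red) sets, rescaled to standard-deviation units about the
#' pooled mean ("Feature Units"); an optional query sequence is drawn as
#' a dashed vertical marker.
#'
#' @param feature_name Feature to display (must exist in both tables, or
#'   pass raw vectors via `pos_values`/`neg_values`).
#' @param pos_features,neg_features Feature tibbles from
#'   [extract_features()].
#' @param query_value Optional raw feature value of a query sequence.
#' @param bins Histogram bin count (default Sturges' rule).
#' @return A ggplot object.
#' @export
plot_feature_histogram <- function(feature_name, pos_features, neg_features,
                                   query_value = NULL, bins = NULL) {
  stopifnot(feature_name %in% names(pos_features),
            feature_name %in% names(neg_features))
  nf <- normalize_feature_units(pos_features[[feature_name]],
                                neg_features[[feature_name]],
                                query_value)
  if (is.null(bins)) {
    bins <- max(1L, grDevices::nclass.Sturges(nf$data$value))
  }
  p <- ggplot2::ggplot(nf$data,
                       ggplot2::aes(x = .data$value, fill = .data$set)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.55,
                            position = "identity") +
    ggplot2::scale_fill_manual(
      values = c(positive = "green4", negative = "red3"), name = NULL
    ) +
    ggplot2::labs(x = "Feature Units (SD about pooled mean)", y = "count",
                  title = feature_name) +
    ggplot2::theme_minimal()
  if (!is.na(nf$query)) {
    p <- p + ggplot2::geom_vline(xintercept = nf$query, linetype = "dashed",
                                 linewidth = 0.8)
  }
  p
}

#' Autoplot methods for package result objects
#'
#' `autoplot.npp_run()` shows the classifier-agreement distribution of a
#' run (the pie-chart summary, as a bar chart); `autoplot.nppred_bundle()`
#' shows per-model cross-validation metrics.
#'
#' @param object An `npp_run` or `nppred_bundle`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.npp_run <- function(object, ...) {
  ggplot2::ggplot(object$agreement,
                  ggplot2::aes(x = factor(.data$n_models_agreeing),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "models calling positive", y = "sequences",
                  title = "Classifier agreement") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.npp_run
#' @export
autoplot.nppred_bundle <- function(object, ...) {
  long <- tidyr::pivot_longer(object$cv_metrics, -"model",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fold-averaged value",
                  title = "Cross-validation metrics") +
    ggplot2::theme_minimal()
}
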