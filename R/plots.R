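#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_line geom_col
#'   geom_point geom_tile labs scale_y_log10 facet_wrap theme_minimal
#'   after_stat
NULL

#' Histogram of junction lengths with the fitted mixture overlaid
#'
#' @param object A [fit_length_mixture()] result.
#' @param lengths The lengths the model was fitted to (the fit does not
#'   retain them).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.length_mixture <- function(object, lengths, ...) {
  grid <- seq(0, max(lengths), by = 1)
  dens <- mixture_densities(object, grid)
  df <- tibble(
    length = rep(grid, 3),
    density = c(dens[, 1], dens[, 2], rowSums(dens)),
    component = rep(c("short", "long", "mixture"), each = length(grid))
  )
  ggplot(tibble(length = lengths), aes(x = .data$length)) +
    geom_histogram(aes(y = after_stat(.data$density)),
      binwidth = 1, fill = "grey80", colour = "grey60"
    ) +
    geom_line(
      data = df,
      aes(y = .data$density, colour = .data$component)
    ) +
    labs(
      x = "junction length (nt, excluding RS)", y = "density",
      title = sprintf(
        "two-component fit (%s): means %.1f / %.1f nt",
        object$family, object$means[1], object$means[2]
      )
    ) +
    theme_minimal()
}

#' Rank-abundance (clonal distribution) plot
#'
#' Unique clonotypes ranked by descending frequency, frequency on a log
#' scale - the standard view of clonal expansion structure.
#'
#' @param table A clonotype table ([aggregate_clonotypes()]); multiple
#'   samples are faceted.
#' @return A ggplot.
#' @export
plot_rank_abundance <- function(table) {
  df <- table |>
    group_by(.data$sample_id) |>
    arrange(dplyr::desc(.data$freq), .by_group = TRUE) |>
    mutate(rank = dplyr::row_number()) |>
    ungroup()
  ggplot(df, aes(x = .data$rank, y = .data$freq)) +
    geom_point(size = 0.6, alpha = 0.6) +
    scale_y_log10() +
    facet_wrap(~sample_id) +
    labs(x = "clonotype rank", y = "frequency") +
    theme_minimal()
}

#' Junction length distribution by class
#'
#' @param table A clonotype table with `klass`.
#' @param weighted Weight by clonotype count.
#' @return A ggplot.
#' @export
plot_length_distribution <- function(table, weighted = FALSE) {
  df <- mutate(table,
    length = nchar(.data$junction),
    w = if (weighted) .data$count else 1
  )
  ggplot(df, aes(x = .data$length, weight = .data$w, fill = .data$klass)) +
    geom_histogram(binwidth = 1, position = "stack") +
    labs(x = "junction length (nt, excluding RS)", y = "clonotypes") +
    theme_minimal()
}

#' Heat-map view of a position frequency matrix
#'
#' @param object A `dd_pfm` from [position_frequency_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dd_pfm <- function(object, ...) {
  df <- tibble(
    base = rep(rownames(object), ncol(object)),
    position = rep(seq_len(ncol(object)), each = nrow(object)),
    freq = as.vector(object)
  )
  ggplot(df, aes(x = .data$position, y = .data$base, fill = .data$freq)) +
    geom_tile() +
    labs(x = "position", y = NULL, fill = "frequency") +
    theme_minimal()
}
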