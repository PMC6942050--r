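# ggplot2 displays for the main result types.

#' Plot a windowed identity profile
#'
#' One line per query along the reference, with the per-window mean across
#' queries overlaid in black.
#'
#' @param object a `dj_identity_profile` from [window_identity()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot dj_identity_profile
#' @export
autoplot.dj_identity_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$window_start + df$window_end) / 2
  mn <- profile_mean(object)
  mn$mid <- (mn$window_start + mn$window_end) / 2
  ggplot2::ggplot(df, ggplot2::aes(.data$mid / 1000, .data$identity)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$query_id), na.rm = TRUE) +
    ggplot2::geom_line(
      data = mn, ggplot2::aes(y = .data$mean_identity),
      colour = "black", linewidth = 1, na.rm = TRUE
    ) +
    ggplot2::labs(
      x = sprintf("position on %s (kb)", attr(object, "reference_id")),
      y = sprintf("identity (%%, %s)", attr(object, "mode")),
      colour = "query"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a marker presence matrix
#'
#' Tile plot of marker carriage per chromosome; missing entries are grey.
#'
#' @param object a `dj_marker_matrix`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot dj_marker_matrix
#' @export
autoplot.dj_marker_matrix <- function(object, ...) {
  df <- tidy(object)
  df$state <- factor(
    ifelse(is.na(df$present), "missing", ifelse(df$present == 1, "carrier", "absent")),
    levels = c("carrier", "absent", "missing")
  )
  ggplot2::ggplot(df, ggplot2::aes(
    factor(.data$marker_id, levels = object$markers$marker_id),
    .data$chromosome
  )) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$state), colour = "white") +
    ggplot2::scale_fill_manual(
      values = c(carrier = "#b2182b", absent = "#f7f7f7", missing = "grey70")
    ) +
    ggplot2::labs(x = "marker", y = "chromosome", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a distance matrix
#'
#' @param object a `dj_dist`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot dj_dist
#' @export
autoplot.dj_dist <- function(object, ...) {
  ids <- rownames(object)
  df <- as_tibble(as.data.frame.table(unclass(object), stringsAsFactors = FALSE))
  names(df) <- c("a", "b", "distance")
  ggplot2::ggplot(df, ggplot2::aes(
    factor(.data$a, ids), factor(.data$b, ids),
    fill = .data$distance
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "subs/site") +
    ggplot2::theme_minimal()
}
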