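#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a TIM fit into one row per query
#'
#' @param x A `tim_fit` from [tim_infer()] or [proto_infer()].
#' @param ... Unused.
#' @return Tibble with `query`, `predicted`, `max_posterior`, and one
#'   `p_<k>` column per class.
#' @export
tidy.tim_fit <- function(x, ...) {
  P <- x$posterior$P
  out <- tibble::tibble(query = seq_len(nrow(P)),
                        predicted = x$predicted,
                        max_posterior = apply(P, 1, max))
  for (k in seq_len(ncol(P))) out[[paste0("p_", k)]] <- P[, k]
  out
}

#' One-row summary of a TIM fit
#'
#' @inheritParams tidy.tim_fit
#' @return Tibble with `n_query`, `n_way`, `n_iters`, `final_loss`,
#'   `mutual_information`, `marginal_entropy`.
#' @export
glance.tim_fit <- function(x, ...) {
  phat <- x$posterior$marginal
  tibble::tibble(
    n_query = nrow(x$posterior$P),
    n_way = ncol(x$posterior$P),
    n_iters = x$n_iters,
    final_loss = if (length(x$trace)) tail(x$trace, 1) else NA_real_,
    mutual_information = mutual_information(x$posterior),
    marginal_entropy = -sum(xlogx(phat))
  )
}

#' Tidy a match result into its matched pairs
#'
#' @param x A `match_result` from [match_events()].
#' @param ... Unused.
#' @return Tibble of matched `(gt, pred, iou)` pairs.
#' @export
tidy.match_result <- function(x, ...) x$pairs

#' One-row summary of a match result
#'
#' @inheritParams tidy.match_result
#' @return Tibble with counts plus precision/recall/F-score.
#' @export
glance.match_result <- function(x, ...) {
  precision_recall_fscore(x$tp, x$fp, x$fn)
}

#' @export
tidy.sed_eval <- function(x, ...) x$by_file

#' @export
glance.sed_eval <- function(x, ...) x$pooled

#' Plot a spectrogram
#'
#' @param object A `spectrogram`.
#' @param ... Unused.
#' @return A ggplot raster of time x Mel band.
#' @export
autoplot.spectrogram <- function(object, ...) {
  df <- tidyr::expand_grid(
    frame = seq_len(nrow(object$values)),
    band = seq_len(ncol(object$values))
  )
  df$time_s <- object$start_time_s + (df$frame - 1) * object$frame_hop_s
  df$value <- as.vector(t(object$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$band,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "energy") +
    ggplot2::labs(x = "time (s)", y = "Mel band")
}

#' Plot a TIM loss trace
#'
#' @param object A `tim_fit`.
#' @param ... Unused.
#' @return A ggplot line of loss vs iteration (iteration 0 = at the
#'   prototype initialization).
#' @export
autoplot.tim_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$trace) - 1L,
                       loss = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "TIM iteration", y = "loss")
}

#' Plot predicted and annotated events on a shared timeline
#'
#' @param gt Annotation tibble (with `status`).
#' @param pred Prediction tibble (with `score`).
#' @return A ggplot of event segments by source.
#' @export
plot_events <- function(gt, pred) {
  gg <- dplyr::bind_rows(
    dplyr::mutate(gt, source = paste0("annotated (", .data$status, ")")),
    dplyr::mutate(pred, source = "predicted")
  )
  ggplot2::ggplot(gg, ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s,
                                   y = .data$source, yend = .data$source)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$onset_s, xend = .data$offset_s),
                          linewidth = 4) +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
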