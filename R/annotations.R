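#' Build an event table
#'
#' Events are tibbles with columns `onset_s`, `offset_s`, `label`, and
#' either `status` (annotations: `"POS"`, `"NEG"`, `"UNK"`) or `score`
#' (predictions). All functions in the package accept and return this
#' shape.
#'
#' @param onset_s,offset_s Event boundaries in seconds (`onset_s <
#'   offset_s`).
#' @param label Class label per event.
#' @param status Annotation status per event, or `NULL`.
#' @param score Prediction score per event in \[0, 1\], or `NULL`.
#' @param audiofilename Optional source file name per event.
#' @return A tibble, one row per event, sorted by onset.
#' @export
event_table <- function(onset_s, offset_s, label = "event", status = NULL,
                        score = NULL, audiofilename = NULL) {
  tb <- tibble::tibble(onset_s = as.numeric(onset_s),
                       offset_s = as.numeric(offset_s),
                       label = rep_len(as.character(label), length(onset_s)))
  if (!is.null(audiofilename)) {
    tb <- dplyr::mutate(tb,
      audiofilename = rep_len(as.character(audiofilename), nrow(tb)),
      .before = 1)
  }
  if (!is.null(status)) tb$status <- rep_len(as.character(status), nrow(tb))
  if (!is.null(score)) tb$score <- rep_len(as.numeric(score), nrow(tb))
  validate_events(tb)
  dplyr::arrange(tb, .data$onset_s)
}

validate_events <- function(tb) {
  if (nrow(tb) == 0) return(invisible(tb))
  bad <- tb$onset_s < 0 | tb$offset_s <= tb$onset_s |
    !is.finite(tb$onset_s) | !is.finite(tb$offset_s)
  if (any(bad)) {
    abort(sprintf("%d event(s) violate 0 <= onset < offset", sum(bad)))
  }
  if ("status" %in% names(tb) &&
      !all(tb$status %in% c("POS", "NEG", "UNK"))) {
    abort("event status must be POS, NEG or UNK")
  }
  invisible(tb)
}

#' Read a DCASE-style annotation CSV
#'
#' Expects the dialect `Audiofilename,Starttime,Endtime,<CLASS>...` with
#' one column per class holding `POS` / `NEG` / `UNK`. Each annotated
#' segment becomes one event row per class whose value is kept.
#'
#' @param path CSV path.
#' @param keep Statuses to retain (default `POS` and `UNK`; add `"NEG"`
#'   to keep confirmed-absence rows).
#' @return Event tibble with `audiofilename`, `onset_s`, `offset_s`,
#'   `label`, `status`.
#' @export
read_annotations <- function(path, keep = c("POS", "UNK")) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("Audiofilename", "Starttime", "Endtime")
  if (!all(need %in% names(raw))) {
    abort(sprintf("%s: missing required column(s) %s", path,
                  paste(setdiff(need, names(raw)), collapse = ", ")))
  }
  cls_cols <- setdiff(names(raw), need)
  if (!length(cls_cols)) abort(sprintf("%s: no class columns", path))
  long <- tidyr::pivot_longer(raw, cols = dplyr::all_of(cls_cols),
                              names_to = "label", values_to = "status")
  out <- long |>
    dplyr::filter(.data$status %in% keep) |>
    dplyr::transmute(audiofilename = as.character(.data$Audiofilename),
                     onset_s = as.numeric(.data$Starttime),
                     offset_s = as.numeric(.data$Endtime),
                     label = .data$label, status = .data$status) |>
    dplyr::arrange(.data$onset_s)
  validate_events(out)
  out
}

#' Write a DCASE-style annotation CSV
#'
#' One row per event; the event's class column carries its status and all
#' other class columns are filled with `NEG`. Times are written with six
#' decimals.
#'
#' @param events Event tibble with `audiofilename`, `onset_s`,
#'   `offset_s`, `label`, `status`.
#' @param path Output CSV path.
#' @param classes Class columns to emit (default: the labels present).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path, classes = NULL) {
  validate_events(events)
  classes <- classes %||% sort(unique(events$label))
  wide <- tibble::tibble(
    Audiofilename = events$audiofilename,
    Starttime = sprintf("%.6f", events$onset_s),
    Endtime = sprintf("%.6f", events$offset_s)
  )
  for (cl in classes) {
    wide[[cl]] <- ifelse(events$label == cl, events$status, "NEG")
  }
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read / write a predictions CSV
#'
#' Dialect: `Audiofilename,Starttime,Endtime,Score`.
#'
#' @param path CSV path.
#' @return Event tibble with `score`.
#' @export
read_predictions <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tibble::tibble(audiofilename = as.character(raw$Audiofilename),
                 onset_s = as.numeric(raw$Starttime),
                 offset_s = as.numeric(raw$Endtime),
                 label = "event",
                 score = as.numeric(raw$Score))
}

#' @rdname read_predictions
#' @param predictions Event tibble with `audiofilename` and `score`.
#' @export
write_predictions <- function(predictions, path) {
  out <- tibble::tibble(
    Audiofilename = predictions$audiofilename,
    Starttime = sprintf("%.6f", predictions$onset_s),
    Endtime = sprintf("%.6f", predictions$offset_s),
    Score = sprintf("%.6f", predictions$score)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
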