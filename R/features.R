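# Image-level feature assembly and table IO.

# The fourteen tortuosity metrics plus the two curvature summaries that are
# aggregated per image.
METRIC_COLUMNS <- c("arc", "chord", "dm", "df", "td",
                    paste0("tau", 1:7), "soam", "icm",
                    "sd_avc", "n_avc")

#' Aggregate segment records into per-image features
#'
#' For each image, computes the segment count and the average, minimum and
#' maximum of every tortuosity metric and curvature summary over that
#' image's segments. Values flagged degenerate (e.g. ratio metrics of a
#' zero-chord segment, stored as `NA`) are excluded from the aggregates; if
#' every value of a metric is flagged, its aggregates are `NA`.
#'
#' @param records Segment-level tibble from [segment_metrics()].
#' @param image_id Optional: restrict to one image (errors if that image has
#'   no segments).
#' @return Tibble with one row per image: `image_id`, `n_segments`, and
#'   `<metric>_avg`, `<metric>_min`, `<metric>_max` for each of the 16
#'   metrics.
#' @export
aggregate_image_features <- function(records, image_id = NULL) {
  if (!is.null(image_id)) {
    records <- dplyr::filter(records, .data$image_id %in% !!image_id)
    if (nrow(records) == 0) {
      abort(paste0("no segments for image: ", paste(image_id, collapse = ", ")))
    }
  }
  if (nrow(records) == 0) abort("no segment records to aggregate")
  safe <- function(f) function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else f(x)
  }
  records |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(
      n_segments = dplyr::n(),
      dplyr::across(dplyr::all_of(METRIC_COLUMNS),
                    list(avg = safe(mean), min = safe(min), max = safe(max)),
                    .names = "{.col}_{.fn}"),
      .groups = "drop"
    )
}

#' Join severity labels onto an image feature table
#'
#' Inner-joins grades (1 = normal, 2 = mild, 3 = moderate, 4 = severe) onto
#' image rows by `image_id`. Duplicate labels are an error; with
#' `strict = TRUE` (default) unlabeled images are too, otherwise they are
#' dropped with a warning.
#'
#' @param images Image feature tibble from [aggregate_image_features()].
#' @param labels Tibble with columns `image_id`, `grade` (integers 1-4).
#' @param strict Error on unlabeled images?
#' @return Labeled tibble with a `grade` column (ordered factor 1 < 2 < 3 < 4).
#' @export
join_labels <- function(images, labels, strict = TRUE) {
  stopifnot(all(c("image_id", "grade") %in% names(labels)))
  if (!all(labels$grade %in% 1:4)) abort("grades must be integers 1..4")
  dup <- labels$image_id[duplicated(labels$image_id)]
  if (length(dup)) {
    abort(paste0("duplicate labels for image(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  missing <- setdiff(images$image_id, labels$image_id)
  if (length(missing)) {
    msg <- paste0("unlabeled image(s): ", paste(missing, collapse = ", "))
    if (strict) abort(msg) else warn(msg)
  }
  dplyr::inner_join(images, labels, by = "image_id") |>
    dplyr::mutate(grade = factor(.data$grade, levels = 1:4, ordered = TRUE))
}

#' Write the segment-level feature CSV
#'
#' Column layout mirrors the canonical per-segment report: image, segment,
#' artery/vein flag (pass-through, blank when absent), Arc, Chord, DM, SOAM,
#' ICMn, ICMb, SDavc, Navc, Tau1..Tau7. `ICMb` duplicates `ICMn` unless the
#' records carry a configured variant.
#'
#' @param records Segment-level tibble from [segment_metrics()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segment_features <- function(records, path) {
  av <- if ("av" %in% names(records)) records$av else ""
  out <- tibble(
    image = records$image_id, segment = records$segment_id, av = av,
    arc = records$arc, chord = records$chord, dm = records$dm,
    soam = records$soam, icm_n = records$icm,
    icm_b = if ("icm_b" %in% names(records)) records$icm_b else records$icm,
    sd_avc = records$sd_avc, n_avc = records$n_avc,
    tau1 = records$tau1, tau2 = records$tau2, tau3 = records$tau3,
    tau4 = records$tau4, tau5 = records$tau5, tau6 = records$tau6,
    tau7 = records$tau7
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write / read the image-level feature CSV
#'
#' Plain UTF-8 CSV with header, `.` decimal separator and empty fields for
#' flagged (missing) aggregates; numeric values round-trip exactly.
#'
#' @param images Image feature tibble.
#' @param path CSV path.
#' @return `path` (write) or the tibble (read).
#' @export
write_image_features <- function(images, path) {
  readr::write_csv(images, path, na = "")
  invisible(path)
}

#' @rdname write_image_features
#' @export
read_image_features <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(image_id = readr::col_character(),
                                          .default = readr::col_double()))
}

#' Read / write severity labels
#'
#' @param labels Tibble with `image_id`, `grade`.
#' @param path CSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_labels <- function(labels, path) {
  readr::write_csv(labels[, c("image_id", "grade")], path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(image_id = readr::col_character(),
                                          grade = readr::col_integer()))
}
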