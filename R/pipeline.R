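# End-to-end wrappers: mask files -> feature CSVs, and feature row -> grade.

#' Pipeline configuration
#'
#' Collects every tunable of the preprocessing and metric stages with its
#' default, so a run can log (and reproduce) its resolved configuration.
#' Unknown keys are rejected.
#'
#' @param ... Overrides for: `min_segment_points` (5), `max_spur_length`
#'   (5), `junction_radius` (2), `step` (1), `smooth_sigma` (3),
#'   `eps_kappa` (0.02), `pixel_spacing` (1), `seed` (1).
#' @return Named list of resolved settings.
#' @export
pipeline_config <- function(...) {
  defaults <- list(min_segment_points = 5, max_spur_length = 5,
                   junction_radius = 2, step = 1, smooth_sigma = 3,
                   eps_kappa = 0.02, pixel_spacing = 1, seed = 1L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown pipeline config key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defaults, overrides)
}

#' Run the tortuosity measurement pipeline over vessel masks
#'
#' For each mask file: read, skeletonize, prune spurs, extract ordered
#' segments, compute the fourteen tortuosity metrics per segment, and
#' aggregate per-image features. Unreadable or empty inputs are reported
#' and skipped; the batch continues.
#'
#' @param mask_paths Character vector of PNG/TIFF mask files (the file base
#'   name becomes the `image_id`).
#' @param out_dir Optional directory; when given,
#'   `segment_features.csv` and `image_features.csv` are written there.
#' @param config A [pipeline_config()].
#' @return List: `segments` (segment-level records), `images` (image-level
#'   features), `log` (per-file tibble: segment counts, discarded pixels,
#'   errors), `failed` (character vector of failed inputs).
#' @export
run_metrics <- function(mask_paths, out_dir = NULL,
                        config = pipeline_config()) {
  logs <- list()
  records <- list()
  failed <- character(0)
  for (path in mask_paths) {
    image_id <- tools::file_path_sans_ext(basename(path))
    res <- tryCatch({
      mask <- read_mask(path)
      skel <- prune_spurs(skeletonize(mask), config$max_spur_length)
      segs <- extract_segments(skel, image_id = image_id,
                               min_segment_points = config$min_segment_points,
                               junction_radius = config$junction_radius)
      if (nrow(segs) == 0) abort("no segments extracted")
      acct <- attr(segs, "accounting")
      rec <- segment_metrics(segs, step = config$step,
                             smooth_sigma = config$smooth_sigma,
                             eps_kappa = config$eps_kappa,
                             pixel_spacing = config$pixel_spacing)
      list(rec = rec,
           log = tibble(image_id = image_id, path = path,
                        n_segments = dplyr::n_distinct(rec$segment_id),
                        n_skeleton_px = acct$n_skeleton,
                        n_discarded_px = acct$n_discarded,
                        error = NA_character_))
    }, error = function(e) {
      list(rec = NULL,
           log = tibble(image_id = image_id, path = path,
                        n_segments = 0L, n_skeleton_px = NA_integer_,
                        n_discarded_px = NA_integer_,
                        error = conditionMessage(e)))
    })
    logs[[length(logs) + 1]] <- res$log
    if (is.null(res$rec)) failed <- c(failed, path) else {
      records[[length(records) + 1]] <- res$rec
    }
  }
  if (!length(records)) abort("no mask produced any segment")
  segments <- dplyr::bind_rows(records)
  images <- aggregate_image_features(segments)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_segment_features(segments, file.path(out_dir, "segment_features.csv"))
    write_image_features(images, file.path(out_dir, "image_features.csv"))
  }
  list(segments = segments, images = images,
       log = dplyr::bind_rows(logs), failed = failed)
}

#' Grade a single image's features
#'
#' @param features One-row image feature tibble (or several rows, one per
#'   image).
#' @param model A `severity_model` (see [fit_severity()],
#'   [load_severity_model()]).
#' @return Tibble: `image_id` (if present), `grade`, `p1`..`p4`
#'   (probabilities summing to 1).
#' @export
run_grade <- function(features, model) {
  pred <- predict_severity(model, features)
  if ("image_id" %in% names(features)) {
    pred <- dplyr::bind_cols(tibble(image_id = features$image_id), pred)
  }
  pred
}
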