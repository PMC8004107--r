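run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s': %s", name, conditionMessage(e)),
          class = "brainfish_stage_error")
  })
}

#' Run configuration for the smFISH counting workflow
#'
#' Validates and normalizes the configuration consumed by
#' [run_smfish_count()]. Either build it programmatically or load a YAML
#' file with the same field names.
#'
#' @param input an [mc_stack], or a path to a TIFF readable by
#'   [read_stack()].
#' @param channel_names channel labels (required when `input` is a path).
#' @param smfish_channel,label_channel channel labels for the smFISH and
#'   membrane-label data; `label_channel = NULL` counts against M1 only.
#' @param calib_channels `NULL`, or `c(ref, moving)` calibration channel
#'   labels; when given, the chromatic shift estimated between them is
#'   applied to the smFISH channel before detection.
#' @param substack `NULL`, or `list(center_z, n_slices)`.
#' @param detection a [detection_params].
#' @param mask `list(name, vertices)` — the drawn compartment polygon
#'   (matrix of `(y, x)` vertices, or a list of per-slice matrices).
#' @param max_width width cutoff for [filter_by_width()].
#' @param sample_id identifier carried into the outputs.
#' @param seed RNG seed recorded in the provenance (the counting workflow
#'   itself is deterministic; the seed matters when the input is a
#'   rendered scene).
#' @param out_dir `NULL`, or a directory to write spot tables, counts and
#'   the provenance record into.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input, channel_names = NULL,
                       smfish_channel = "smFISH", label_channel = NULL,
                       calib_channels = NULL, substack = NULL,
                       detection = detection_params(), mask = NULL,
                       max_width = 5, sample_id = "sample", seed = 1L,
                       out_dir = NULL) {
  if (is.character(input)) {
    if (!file.exists(input)) {
      abort(sprintf("input file '%s' does not exist", input),
            class = "brainfish_config_error")
    }
    if (is.null(channel_names)) {
      abort("channel_names is required when input is a file path",
            class = "brainfish_config_error")
    }
  } else if (!inherits(input, "mc_stack")) {
    abort("input must be an mc_stack or a file path", class = "brainfish_config_error")
  }
  stopifnot(inherits(detection, "detection_params"))
  structure(
    list(input = input, channel_names = channel_names,
         smfish_channel = smfish_channel, label_channel = label_channel,
         calib_channels = calib_channels, substack = substack,
         detection = detection, mask = mask, max_width = max_width,
         sample_id = sample_id, seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' End-to-end smFISH counting
#'
#' Orchestrates (optional) chromatic-shift correction, substack selection,
#' GLRT detection with FDR control, MLE spot refinement, width filtering
#' and compartment assignment, and emits count tables plus a provenance
#' record sufficient to re-run the analysis bit-identically.
#'
#' The stage order is fixed; any stage error aborts with a stage-labeled
#' diagnostic.
#'
#' @param config a [run_config].
#' @return A list of class `bf_run`: `counts` (tibble: sample,
#'   compartment, n_detected, n_kept, n_colocalized), `spots` (fit tibble
#'   with `colocalized`), `mask` (the [compartment_mask]), `provenance`.
#' @export
run_smfish_count <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stack <- run_stage("load", {
    if (is.character(config$input)) {
      read_stack(config$input, config$channel_names)
    } else config$input
  })
  img <- run_stage("extract", get_channel(stack, config$smfish_channel))
  label <- if (!is.null(config$label_channel)) {
    run_stage("extract", get_channel(stack, config$label_channel))
  } else NULL
  if (!is.null(config$calib_channels)) {
    shift <- run_stage("align", {
      estimate_chromatic_shift(get_channel(stack, config$calib_channels[1]),
                               get_channel(stack, config$calib_channels[2]))
    })
    img <- run_stage("align", apply_transform(img, affine_invert(shift)))
  } else {
    shift <- NULL
  }
  if (!is.null(config$substack)) {
    img <- run_stage("substack",
                     select_substack(img, config$substack$center_z,
                                     config$substack$n_slices))
    if (!is.null(label)) {
      label <- run_stage("substack",
                         select_substack(label, config$substack$center_z,
                                         config$substack$n_slices))
    }
  }
  detections <- run_stage("detect", detect_spots(img, config$detection))
  fits <- run_stage("fit", fit_spots(img, detections, config$detection))
  kept <- run_stage("filter", filter_by_width(fits, config$max_width))
  mask <- run_stage("mask", {
    if (is.null(config$mask)) {
      stop("no compartment mask configured", call. = FALSE)
    }
    build_compartment_mask(dim(img), config$mask$vertices,
                           label_channel = label,
                           name = config$mask$name %||% "compartment")
  })
  assigned <- run_stage("assign", assign_spots(kept, mask))
  counts <- tibble(
    sample = config$sample_id,
    compartment = mask$name,
    n_detected = nrow(detections),
    n_kept = nrow(kept),
    n_colocalized = sum(assigned$colocalized)
  )
  provenance <- list(
    package_version = as.character(utils::packageVersion("brainfish")),
    sample_id = config$sample_id,
    seed = config$seed,
    detection = unclass(config$detection),
    max_width = config$max_width,
    substack = config$substack,
    smfish_channel = config$smfish_channel,
    label_channel = config$label_channel,
    chromatic_shift = if (is.null(shift)) NULL else
      list(matrix = as.vector(t(shift$matrix)), translation = shift$translation)
  )
  out <- structure(
    list(counts = counts, spots = assigned, mask = mask, provenance = provenance),
    class = "bf_run"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(assigned, file.path(config$out_dir, "spots.csv"), row.names = FALSE)
    utils::write.csv(counts, file.path(config$out_dir, "counts.csv"), row.names = FALSE)
    jsonlite::write_json(provenance, file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' @export
print.bf_run <- function(x, ...) {
  cat("<bf_run>\n")
  print(x$counts)
  invisible(x)
}

#' Tidy cross-sample report
#'
#' Collates result tables into one long tibble with one row per
#' (sample, compartment, metric), in a deterministic order, optionally
#' written as CSV (byte-identical for identical inputs).
#'
#' @param results a `bf_run`, a tibble, or a list of either. Tibbles must
#'   carry `sample` and `compartment` columns; all other numeric columns
#'   become metrics.
#' @param path optional CSV output path.
#' @return Long tibble `sample, compartment, metric, value`.
#' @export
run_report <- function(results, path = NULL) {
  if (inherits(results, "bf_run") || is.data.frame(results)) {
    results <- list(results)
  }
  if (length(results) == 0L) {
    abort("run_report needs at least one result table", class = "brainfish_config_error")
  }
  tabs <- lapply(results, function(r) {
    if (inherits(r, "bf_run")) r$counts else as_tibble(r)
  })
  long <- bind_rows(lapply(tabs, function(tb) {
    stopifnot(all(c("sample", "compartment") %in% names(tb)))
    num <- names(tb)[vapply(tb, is.numeric, logical(1))]
    tidyr::pivot_longer(tb[, c("sample", "compartment", num)],
                        cols = dplyr::all_of(num),
                        names_to = "metric", values_to = "value")
  }))
  long <- arrange(long, .data$sample, .data$compartment, .data$metric)
  if (!is.null(path)) {
    utils::write.csv(as.data.frame(long), path, row.names = FALSE)
  }
  long
}
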