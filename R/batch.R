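#' Batch directionality analysis over a directory of images
#'
#' Analyzes every readable TIFF/PNG under `image_dir` (recursively) with
#' [analyze_image()]. Images are grouped into series by their subdirectory
#' (files at the top level form series `"."`); per-series summaries give the
#' mean and range of eccentricity and angular SD. A file that fails to
#' analyze is recorded in the `errors` table and does not abort the batch.
#'
#' @param image_dir Directory containing at least one readable image.
#' @param config An [analysis_config()].
#' @return A `batch_result` list: `results` (one row per image, in the
#'   column order of [as.data.frame.alignment_result()] plus `series`),
#'   `summary` (per-series mean/min/max of eccentricity and sigma),
#'   `errors` (file, stage/message).
#' @export
run_batch <- function(image_dir, config = analysis_config()) {
  image_dir <- sub("/+$", "", image_dir)
  if (!dir.exists(image_dir))
    stop_fibralign(sprintf("directory not found: %s", image_dir),
                   "fibralign_input_error")
  files <- list.files(image_dir, pattern = "\\.(tif|tiff|png)$",
                      recursive = TRUE, ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0)
    stop_fibralign(sprintf("no TIFF/PNG images under %s", image_dir),
                   "fibralign_input_error")
  files <- sort(files)
  series <- dirname(substring(files, nchar(image_dir) + 2))
  rows <- list(); errs <- list()
  for (i in seq_along(files)) {
    res <- tryCatch(analyze_image(files[i], config), error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(
        file = files[i], message = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      df <- as.data.frame(res)
      df$series <- series[i]
      df$file <- files[i]
      rows[[length(rows) + 1L]] <- df
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source_id = character(0))
  summary <- if (length(rows)) {
    agg <- lapply(split(results, results$series), function(d) {
      data.frame(series = d$series[1], n_images = nrow(d),
                 eps_mean = mean(d$eccentricity),
                 eps_min = min(d$eccentricity),
                 eps_max = max(d$eccentricity),
                 sigma_mean = mean(d$sigma_deg),
                 sigma_min = min(d$sigma_deg),
                 sigma_max = max(d$sigma_deg),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(agg, list(make.row.names = FALSE)))
  } else data.frame(series = character(0))
  errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(file = character(0), message = character(0))
  structure(list(results = results, summary = summary, errors = errors,
                 config = config),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result> %d image(s) analyzed, %d series, %d error(s)\n",
              nrow(x$results), nrow(x$summary), nrow(x$errors)))
  if (nrow(x$summary)) print(x$summary)
  if (nrow(x$errors)) {
    cat("errors:\n"); print(x$errors)
  }
  invisible(x)
}

#' Write batch outputs to disk
#'
#' Writes the per-image table as CSV, one JSON record per image, and the
#' per-series summary CSV.
#'
#' @param batch A `batch_result`.
#' @param csv_path Path for the per-image CSV (optional).
#' @param json_dir Directory for per-image JSON records (optional).
#' @param summary_path Path for the per-series summary CSV (optional).
#' @return Invisibly, `batch`.
#' @export
write_batch <- function(batch, csv_path = NULL, json_dir = NULL,
                        summary_path = NULL) {
  stopifnot(inherits(batch, "batch_result"))
  if (!is.null(csv_path))
    utils::write.csv(batch$results, csv_path, row.names = FALSE)
  if (!is.null(summary_path))
    utils::write.csv(batch$summary, summary_path, row.names = FALSE)
  if (!is.null(json_dir) && nrow(batch$results)) {
    dir.create(json_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(batch$results))) {
      rec <- as.list(batch$results[i, setdiff(names(batch$results), "file")])
      jsonlite::write_json(
        rec, file.path(json_dir, paste0(
          tools::file_path_sans_ext(batch$results$source_id[i]), ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(batch)
}
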