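#' Load and validate an experiment manifest
#'
#' The manifest is the tabular data model of a grouped imaging experiment:
#' one row per image with its ROI, group label (e.g. NT, ITGa6-KD),
#' treatment label (e.g. untreated, 5Gy, 20Gy), replicate id, channel list
#' and flags marking the control group and the untreated arm. CSV and YAML
#' (list-of-records under a `records` key) are accepted.
#'
#' Required columns: `image`, `roi`, `group`, `treatment`, `replicate`,
#' `channels` (semicolon-separated channel names), `control` (logical),
#' `untreated` (logical).
#'
#' @param path Manifest file (`.csv`, `.yaml`/`.yml`).
#' @param check_files Verify that referenced image/ROI files exist relative
#'   to the manifest's directory (default `TRUE`).
#' @return A tibble of class `experiment_manifest` with attributes
#'   `control_group` and `dir`.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) abort(sprintf("Manifest not found: %s", path))
  m <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    recs <- recs$records %||% recs
    dplyr::bind_rows(lapply(recs, tibble::as_tibble))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  required <- c("image", "roi", "group", "treatment", "replicate",
                "channels", "control", "untreated")
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    abort(sprintf("Manifest missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  m$control <- as.logical(m$control)
  m$untreated <- as.logical(m$untreated)
  ctrl <- unique(m$group[m$control])
  if (length(ctrl) == 0L) abort("Manifest designates no control group.")
  if (length(ctrl) > 1L) {
    abort(sprintf("Multiple control groups flagged: %s.", paste(ctrl, collapse = ", ")))
  }
  dup <- duplicated(m[, c("group", "treatment", "replicate")])
  if (any(dup)) {
    d <- m[dup, ][1, ]
    abort(sprintf("Duplicate replicate id: group '%s', treatment '%s', replicate %s.",
                  d$group, d$treatment, d$replicate))
  }
  dir <- dirname(path)
  if (check_files) {
    for (col in c("image", "roi")) {
      full <- ifelse(file.exists(m[[col]]), m[[col]], file.path(dir, m[[col]]))
      bad <- !file.exists(full)
      if (any(bad)) {
        abort(sprintf("Dangling %s path(s) in manifest: %s.", col,
                      paste(utils::head(m[[col]][bad], 3L), collapse = ", ")))
      }
    }
  }
  out <- tibble::as_tibble(m)
  attr(out, "control_group") <- ctrl
  attr(out, "dir") <- dir
  class(out) <- c("experiment_manifest", class(out))
  out
}

#' Channel names of a manifest record
#'
#' @param record One row of an `experiment_manifest`.
#' @return Character vector of channel names.
#' @export
manifest_channels <- function(record) {
  strsplit(record$channels, ";", fixed = TRUE)[[1]]
}
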