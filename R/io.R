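#' Write trajectories to delimited text
#'
#' Persists a localization tibble as CSV with the canonical schema
#' (`trajectory_id`, `geometry`, `frame`, `t_s`, `x_um`, `y_um`, `z_um`;
#' `geometry` defaults to `"planar"` and `z_um` to empty for 2D data).
#' All values are in um and seconds. When `config` is supplied (or
#' attached to `x` as an attribute) a JSON sidecar `<path>.json` records
#' it alongside the seed for full reproducibility.
#'
#' @param x Localization tibble.
#' @param path Output CSV path.
#' @param config Optional [simulation_config()] or [fixture_spec()]
#'   written to the sidecar.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(x, path, config = NULL) {
  check_trajectory_cols(x, c("trajectory_id", "frame", "t_s", "x_um", "y_um"))
  out <- tibble::tibble(
    trajectory_id = x$trajectory_id,
    geometry = if ("geometry" %in% names(x)) x$geometry else "planar",
    frame = x$frame,
    t_s = x$t_s,
    x_um = x$x_um,
    y_um = x$y_um,
    z_um = if ("z_um" %in% names(x)) x$z_um else NA_real_
  )
  readr::write_csv(out, path, na = "")
  config <- config %||% attr(x, "config")
  if (!is.null(config)) {
    jsonlite::write_json(
      list(format = "tubediff trajectories",
           version = as.character(utils::packageVersion("tubediff")),
           config = unclass(config)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Read trajectories from delimited text
#'
#' Reads the canonical CSV trajectory schema back into a localization
#' tibble. Unknown columns are rejected (a schema mismatch usually means
#' wrong units or a foreign format), malformed rows are reported with
#' their line numbers, rows are re-sorted by frame within each trajectory
#' (with a warning if the file was shuffled), and duplicate frames within
#' a trajectory are an error.
#'
#' @param path CSV path, as written by [write_trajectories()].
#' @return A localization tibble; if a JSON sidecar exists its parsed
#'   contents are attached as attribute `sidecar`.
#' @export
read_trajectories <- function(path) {
  schema <- c("trajectory_id", "geometry", "frame", "t_s", "x_um", "y_um",
              "z_um")
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  unknown <- setdiff(hdr, schema)
  if (length(unknown) > 0) {
    abort(paste0("Unknown column(s) in trajectory file: ",
                 paste(unknown, collapse = ", "), "."))
  }
  missing <- setdiff(setdiff(schema, c("geometry", "z_um")), hdr)
  if (length(missing) > 0) {
    abort(paste0("Trajectory file is missing required column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  parsers <- list(
    trajectory_id = readr::col_character(),
    geometry = readr::col_character(),
    frame = readr::col_integer(),
    t_s = readr::col_double(),
    x_um = readr::col_double(),
    y_um = readr::col_double(),
    z_um = readr::col_double()
  )
  x <- readr::read_csv(
    path, show_col_types = FALSE,
    col_types = do.call(readr::cols, parsers[intersect(schema, hdr)])
  )
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    abort(paste0(
      "Malformed trajectory file: ",
      paste(sprintf("row %d (%s)", prob$row, prob$expected), collapse = "; ")
    ))
  }
  keys <- intersect(c("trajectory_id", "geometry"), names(x))
  dup <- x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(dup = anyDuplicated(.data$frame) > 0, .groups = "drop")
  if (any(dup$dup)) {
    abort("Duplicate frame indices within a trajectory; frames must be unique per trajectory.")
  }
  sorted <- x |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "frame"))))
  if (!identical(sorted$frame, x$frame) ||
      !identical(sorted$trajectory_id, x$trajectory_id)) {
    warn("Trajectory rows were not ordered by frame; re-sorting per trajectory.")
  }
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    attr(sorted, "sidecar") <- jsonlite::fromJSON(sidecar_path)
  }
  sorted
}
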