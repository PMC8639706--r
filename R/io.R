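#' Read and write bottle tables
#'
#' Bottle tables are delimited text with one row per bottle and the DO time
#' series either long (one row per reading, columns `bottle_id`, `t_hours`,
#' `DO_nM`, optional `censored`, with per-bottle metadata repeated on every
#' row) or wide (one row per bottle with reading columns named
#' `DO_nM_<hours>h`, e.g. `DO_nM_12h`). Both dialects parse to the same
#' canonical form: one row per bottle with a nested `do_series` tibble.
#' `write_bottles()` always writes the long (tidy) dialect; unknown atomic
#' columns round-trip unchanged, list-columns other than `do_series` are
#' dropped with a message. Lines starting with `#` are header comments
#' (used to record the pipeline config hash) and are ignored on read.
#'
#' @param path file path.
#' @param data a bottle tibble as returned by [simulate_experiment()] or
#'   [read_bottles()].
#' @param config_hash optional hash string recorded as a header comment.
#' @return `read_bottles()`: a tibble with one row per bottle and a nested
#'   `do_series` list-column. `write_bottles()`: `path`, invisibly.
#' @export
read_bottles <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  wide_cols <- grep("^DO_nM_[0-9.]+h$", names(raw), value = TRUE)
  if (length(wide_cols) > 0) {
    raw <- tidyr::pivot_longer(raw, dplyr::all_of(wide_cols),
                               names_to = "t_hours", values_to = "DO_nM",
                               names_pattern = "^DO_nM_([0-9.]+)h$",
                               names_transform = as.numeric)
    raw <- dplyr::arrange(raw, .data$bottle_id, .data$t_hours)
  }
  missing <- setdiff(c("bottle_id", "t_hours", "DO_nM"), names(raw))
  if (length(missing) > 0) {
    abort(sprintf("bottle table %s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  series_cols <- intersect(c("t_hours", "DO_nM", "censored"), names(raw))
  meta_cols <- setdiff(names(raw), setdiff(series_cols, "t_hours"))
  # t_hours appears both as a reading time and as the per-bottle endpoint
  # time; the endpoint time is restored as the last reading time per bottle
  nested <- raw |>
    dplyr::group_by(.data$bottle_id) |>
    tidyr::nest(do_series = dplyr::all_of(series_cols)) |>
    dplyr::ungroup()
  meta <- raw |>
    dplyr::select(dplyr::all_of(setdiff(meta_cols, "t_hours"))) |>
    dplyr::distinct(.data$bottle_id, .keep_all = TRUE)
  out <- dplyr::left_join(meta, nested[, c("bottle_id", "do_series")],
                          by = "bottle_id")
  out$t_hours <- vapply(out$do_series, function(s) max(s$t_hours), numeric(1))
  out
}

#' @rdname read_bottles
#' @export
write_bottles <- function(data, path, config_hash = NULL) {
  .need_cols(data, c("bottle_id", "do_series"), "write_bottles")
  drop <- names(data)[vapply(data, is.list, logical(1))]
  drop <- setdiff(drop, "do_series")
  if (length(drop) > 0) {
    inform(sprintf("write_bottles: dropping list column(s): %s",
                   paste(drop, collapse = ", ")))
    data <- data[, setdiff(names(data), drop)]
  }
  long <- data |>
    dplyr::select(-dplyr::any_of("t_hours")) |>
    tidyr::unnest("do_series")
  header <- c("# nitroxr bottle table (long format)",
              if (!is.null(config_hash)) paste0("# config_hash: ", config_hash))
  readr::write_lines(header, path)
  readr::write_csv(long, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read and write depth-profile tables
#'
#' Profile tables are flat delimited text with one row per depth: required
#' columns `station`, `depth_m`, `DO_nM`; typical optional columns `NO2_nM`,
#' `chl_mg_m3`, `delta15N`, `delta18O` and per-depth rates. Unknown columns
#' round-trip unchanged; `#` header comments are ignored on read.
#'
#' @param path file path.
#' @param data a profile tibble.
#' @param config_hash optional hash string recorded as a header comment.
#' @return `read_profiles()`: a tibble. `write_profiles()`: `path`,
#'   invisibly.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  missing <- setdiff(c("station", "depth_m", "DO_nM"), names(out))
  if (length(missing) > 0) {
    abort(sprintf("profile table %s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  out
}

#' @rdname read_profiles
#' @export
write_profiles <- function(data, path, config_hash = NULL) {
  .need_cols(data, c("station", "depth_m", "DO_nM"), "write_profiles")
  keep <- !vapply(data, is.list, logical(1))
  if (any(!keep)) {
    inform(sprintf("write_profiles: dropping list column(s): %s",
                   paste(names(data)[!keep], collapse = ", ")))
  }
  header <- c("# nitroxr profile table",
              if (!is.null(config_hash)) paste0("# config_hash: ", config_hash))
  readr::write_lines(header, path)
  readr::write_csv(data[, keep], path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Apply substitute-bottle directives
#'
#' A bottle row whose `substitute_for` column names another bottle id
#' replaces that bottle's measurements (a data-curation directive for, e.g.,
#' swapping in a previous day's cast at an equivalent depth when a bottle
#' misbehaves). The substitute row takes over the target's identity; the
#' original target row is dropped and the event is logged.
#'
#' @param bottles a bottle tibble with an optional `substitute_for` column.
#' @return the bottle tibble with substitutions applied.
#' @export
apply_substitutions <- function(bottles) {
  if (!"substitute_for" %in% names(bottles)) return(bottles)
  sub_idx <- which(!is.na(bottles$substitute_for) & bottles$substitute_for != "")
  if (length(sub_idx) == 0) return(dplyr::select(bottles, -"substitute_for"))
  drop_idx <- integer(0)
  for (i in sub_idx) {
    target <- bottles$substitute_for[i]
    hit <- which(bottles$bottle_id == target)
    hit <- setdiff(hit, sub_idx)
    if (length(hit) == 0) {
      abort(sprintf("substitute_for names unknown bottle: %s", target))
    }
    inform(sprintf("substituting bottle %s for %s", bottles$bottle_id[i],
                   target))
    drop_idx <- c(drop_idx, hit)
    bottles$bottle_id[i] <- target
  }
  if (length(drop_idx) > 0) {
    bottles <- bottles[-drop_idx, , drop = FALSE]
  }
  dplyr::select(bottles, -"substitute_for")
}
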