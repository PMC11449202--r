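#' Read a fix table
#'
#' Reads a localization CSV with columns `tag_id`, `time` (ISO-8601 UTC or
#' epoch seconds; accepted as `t` too), `x`, `y`, `var_x`, `var_y`,
#' `cov_xy`. Rows with missing coordinates are dropped, duplicate
#' `(tag_id, t)` rows deduplicated, and the table sorted by tag and time;
#' dropped-row counts are reported as messages. Lines starting with `#` are
#' metadata comments.
#'
#' @param path CSV path.
#' @return a fix tibble.
#' @export
read_fixes <- function(path) {
  df <- read_table_csv(path)
  if ("time" %in% names(df) && !("t" %in% names(df))) {
    names(df)[names(df) == "time"] <- "t"
  }
  require_columns(df, c("tag_id", "t", "x", "y", "var_x", "var_y", "cov_xy"),
                  path)
  if (is.character(df$t)) {
    df$t <- as.numeric(as.POSIXct(df$t, tz = "UTC"))
  } else if (inherits(df$t, "POSIXt")) {
    df$t <- as.numeric(df$t)
  }
  bad <- !is.finite(df$x) | !is.finite(df$y) | !is.finite(df$t)
  if (any(bad)) {
    message("read_fixes: dropped ", sum(bad), " row(s) with missing ",
            "coordinates or time")
    df <- df[!bad, , drop = FALSE]
  }
  df <- df[order(df$tag_id, df$t), , drop = FALSE]
  dup <- duplicated(df[, c("tag_id", "t")])
  if (any(dup)) {
    message("read_fixes: deduplicated ", sum(dup), " repeated (tag, t) row(s)")
    df <- df[!dup, , drop = FALSE]
  }
  as_tibble(df)
}

#' Read a tree table
#'
#' Columns: `tree_id, x, y, species, predictability, is_focal`.
#'
#' @param path CSV path.
#' @return a tree tibble.
#' @export
read_trees <- function(path) {
  df <- read_table_csv(path)
  require_columns(df, c("tree_id", "x", "y", "species", "predictability",
                        "is_focal"), path)
  df$is_focal <- as.logical(df$is_focal)
  as_tibble(df)
}

#' Read a visit table
#'
#' Columns: `bat_id, night_index, tree_id, t_start, t_end, duration,
#' flyover` (extra columns are kept).
#'
#' @param path CSV path.
#' @return a visit tibble.
#' @export
read_visits <- function(path) {
  df <- read_table_csv(path)
  require_columns(df, c("bat_id", "night_index", "tree_id"), path)
  if ("flyover" %in% names(df)) df$flyover <- as.logical(df$flyover)
  as_tibble(df)
}

#' Read a manipulation manifest
#'
#' Columns: `bat_id, roost, role, night` with role in
#' \{"manipulated", "naive"\}.
#'
#' @param path CSV path.
#' @return a manifest tibble.
#' @export
read_manifest <- function(path) {
  df <- read_table_csv(path)
  require_columns(df, c("bat_id", "roost", "role", "night"), path)
  bad <- setdiff(unique(df$role), c("manipulated", "naive"))
  if (length(bad)) {
    stop("schema error in ", path, ": unknown role(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  as_tibble(df)
}

#' Read a tracking roster
#'
#' Columns: `bat_id, start_night, end_night` (optional `roost`).
#'
#' @param path CSV path.
#' @return a roster tibble.
#' @export
read_roster <- function(path) {
  df <- read_table_csv(path)
  require_columns(df, c("bat_id", "start_night", "end_night"), path)
  as_tibble(df)
}

read_table_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as.data.frame(readr::read_csv(path, comment = "#", show_col_types = FALSE,
                                progress = FALSE))
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Write a table as CSV with metadata header
#'
#' Writes `# key: value` comment lines (e.g. seed and config hash)
#' followed by the CSV body; the package readers skip such comments.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param meta named list of metadata scalars.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, format(meta[[k]])), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
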