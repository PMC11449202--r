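#' Quality- and speed-filter raw fixes
#'
#' Two-stage pre-processing of localization fixes, applied per tag:
#' first drop fixes whose localization covariance matrix has a larger
#' eigenvalue above `quality_var_max` (poorly constrained solutions), then
#' make a single forward pass dropping any fix whose incoming speed --
#' computed against the last retained fix -- exceeds `speed_max` (default
#' 20 m/s, well above sustained fruit-bat flight). The arriving fix is
#' removed, not both endpoints, so the pass is causal. Input order is
#' preserved.
#'
#' @param fixes fix tibble (`tag_id, t, x, y, var_x, var_y, cov_xy`),
#'   sorted by tag and time.
#' @param params a [segmenter_params()].
#' @return the filtered fix tibble.
#' @export
filter_fixes <- function(fixes, params = segmenter_params()) {
  if (nrow(fixes) == 0) return(fixes)
  check_sorted(fixes)
  eig <- cov_max_eigenvalue(fixes$var_x, fixes$var_y, fixes$cov_xy)
  fixes <- fixes[is.na(eig) | eig <= params$quality_var_max, , drop = FALSE]
  if (nrow(fixes) == 0) return(fixes)
  keep <- unlist(lapply(
    split(seq_len(nrow(fixes)), fixes$tag_id),
    function(idx) idx[speed_pass_keep(fixes$t[idx], fixes$x[idx],
                                      fixes$y[idx], params$speed_max)]
  ), use.names = FALSE)
  fixes[sort(keep), , drop = FALSE]
}

check_sorted <- function(fixes) {
  ord <- order(fixes$tag_id, fixes$t)
  if (!identical(ord, seq_len(nrow(fixes)))) {
    stop("fixes must be sorted by (tag_id, t); use read_fixes() to ingest",
         call. = FALSE)
  }
  invisible(fixes)
}

# larger eigenvalue of the 2x2 covariance [[vx, cxy], [cxy, vy]]
cov_max_eigenvalue <- function(vx, vy, cxy) {
  ((vx + vy) + sqrt((vx - vy)^2 + 4 * cxy^2)) / 2
}

# forward single pass: a fix survives if its speed relative to the last
# retained fix is <= vmax; returns logical keep vector
speed_pass_keep <- function(t, x, y, vmax) {
  n <- length(t)
  keep <- logical(n)
  if (n == 0) return(keep)
  keep[1] <- TRUE
  last <- 1
  for (i in seq_len(n)[-1]) {
    dt <- t[i] - t[last]
    d <- sqrt((x[i] - x[last])^2 + (y[i] - y[last])^2)
    if (dt > 0 && d / dt <= vmax) {
      keep[i] <- TRUE
      last <- i
    }
  }
  keep
}
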