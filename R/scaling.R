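#' Fit a per-variable min-max scaler
#'
#' Maps each variable linearly from its observed data range
#' \[`n_min`, `n_max`\] onto the target range \[`m_min`, `m_max`\]
#' (default \[-1, 1\], the operating range of the tansig hidden layer):
#' \deqn{m = (m_{max}-m_{min})(x - n_{min})/(n_{max}-n_{min}) + m_{min}}
#'
#' Input ranges are taken over all records of the table; response ranges over
#' the non-missing observations. A constant column cannot be scaled and is an
#' error.
#'
#' @param table a `disinfection_table`.
#' @param m_range length-2 target range, default `c(-1, 1)`.
#' @return a `minmax_scaler`: data frame with columns `variable`, `n_min`,
#'   `n_max`, `m_min`, `m_max` and one row per variable
#'   (`naocl`, `h2o2`, `hgcl2`, `time`, `de`, `nde`).
#' @export
fit_scaler <- function(table, m_range = c(-1, 1)) {
  stopifnot(inherits(table, "disinfection_table"))
  if (m_range[2] <= m_range[1]) stop("target range must have m_max > m_min")
  x <- treatment_matrix(table)
  ranges <- data.frame(
    variable = c(.var_ids, "de", "nde"),
    n_min = c(apply(x, 2, min),
              min(table$de_actual, na.rm = TRUE),
              min(table$nde_actual, na.rm = TRUE)),
    n_max = c(apply(x, 2, max),
              max(table$de_actual, na.rm = TRUE),
              max(table$nde_actual, na.rm = TRUE)),
    m_min = m_range[1], m_max = m_range[2],
    stringsAsFactors = FALSE
  )
  new_scaler(ranges)
}

new_scaler <- function(ranges) {
  degenerate <- ranges$n_max <= ranges$n_min
  if (any(degenerate)) {
    stop("degenerate range (n_max <= n_min) for variable(s): ",
         paste(ranges$variable[degenerate], collapse = ", "))
  }
  rownames(ranges) <- ranges$variable
  structure(ranges, class = c("minmax_scaler", "data.frame"))
}

scaler_row <- function(scaler, var) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  i <- match(var, scaler$variable)
  if (is.na(i)) stop("unknown scaler variable: ", var)
  scaler[i, ]
}

#' Normalize a raw value onto the scaler's target range
#'
#' Linear map with no clipping: values outside the fitted data range
#' extrapolate beyond the target range.
#'
#' @param x numeric vector of raw values.
#' @param scaler a `minmax_scaler`.
#' @param var variable id (`"naocl"`, `"h2o2"`, `"hgcl2"`, `"time"`, `"de"`,
#'   `"nde"`).
#' @return numeric vector on the target (normalized) scale.
#' @export
normalize <- function(x, scaler, var) {
  p <- scaler_row(scaler, var)
  (p$m_max - p$m_min) * (x - p$n_min) / (p$n_max - p$n_min) + p$m_min
}

#' Map a normalized value back to raw units
#'
#' Exact inverse of [normalize()], again without clipping: a network output
#' beyond the target range maps to a raw value beyond the fitted data range
#' (e.g. a predicted disinfection efficiency above 100\%).
#'
#' @inheritParams normalize
#' @param m numeric vector on the normalized scale.
#' @return numeric vector in raw units.
#' @export
denormalize <- function(m, scaler, var) {
  p <- scaler_row(scaler, var)
  (m - p$m_min) * (p$n_max - p$n_min) / (p$m_max - p$m_min) + p$n_min
}

# normalize the 4 protocol columns of a treatment matrix
normalize_inputs <- function(x, scaler) {
  out <- x
  for (v in .var_ids) out[, v] <- normalize(x[, v], scaler, v)
  out
}

#' Read / write min-max scaler ranges as structured text
#'
#' One line per variable: `variable n_min n_max m_min m_max`, `#` comments
#' allowed. This is the format of the packaged frozen scaler
#' (`published_scaler()`).
#'
#' @param path text file path.
#' @return `read_scaler` returns a `minmax_scaler`; `write_scaler` its path,
#'   invisibly.
#' @export
read_scaler <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("variable", "n_min", "n_max",
                                         "m_min", "m_max"),
                           stringsAsFactors = FALSE)
  new_scaler(tab)
}

#' @rdname read_scaler
#' @param scaler a `minmax_scaler`.
#' @export
write_scaler <- function(scaler, path) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  lines <- c("# min-max scaler ranges",
             "# columns: variable n_min n_max m_min m_max",
             sprintf("%s %.17g %.17g %.17g %.17g", scaler$variable,
                     scaler$n_min, scaler$n_max, scaler$m_min, scaler$m_max))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.minmax_scaler <- function(x, ...) {
  cat("min-max scaler:\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
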