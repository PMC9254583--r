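# canonical column order for a disinfection experiment table
.predictor_cols <- c("naocl_pct", "h2o2_pct", "hgcl2_pct", "time_min")
.response_cols <- c("de_actual", "nde_actual")
.model_cols <- c("de_pred", "nde_pred", "de_resid", "nde_resid")
.required_cols <- c("code", .predictor_cols, .response_cols)

# short variable ids used by the scaler and the optimizer
.var_ids <- c("naocl", "h2o2", "hgcl2", "time")

#' Construct and validate a disinfection experiment table
#'
#' An experiment table holds one row per disinfection treatment: a code, the
#' four protocol variables (NaOCl \% w/v, H2O2 \%, HgCl2 \%, immersion time in
#' minutes) and the two observed responses, disinfection efficiency (DE, the
#' percentage of contamination-free cultures) and negative disinfection effect
#' (NDE, the percentage of contamination-free cultures showing phytotoxic
#' damage). Model columns (`de_pred`, `nde_pred`, `de_resid`, `nde_resid`) are
#' optional and unconstrained in range, since an unclipped network may predict
#' outside \[0, 100\].
#'
#' Observed responses may be missing (`NA`): NDE is only defined on
#' contamination-free cultures, so a fully contaminated control has no NDE.
#'
#' @param df data frame with columns `code`, `naocl_pct`, `h2o2_pct`,
#'   `hgcl2_pct`, `time_min`, `de_actual`, `nde_actual` and optionally the
#'   four model columns.
#' @param provenance free-text description of where the rows came from.
#' @return a validated `disinfection_table` (a data frame subclass).
#' @export
disinfection_table <- function(df, provenance = "") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.required_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  keep <- intersect(c(.required_cols, .model_cols), names(df))
  df <- df[, keep, drop = FALSE]
  df$code <- as.character(df$code)
  for (col in setdiff(keep, "code")) df[[col]] <- as.numeric(df[[col]])
  validate_table(df)
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("disinfection_table", "data.frame"))
}

validate_table <- function(df) {
  if (nrow(df) == 0) stop("experiment table has no rows")
  if (anyDuplicated(df$code)) {
    stop("duplicate treatment code(s): ",
         paste(unique(df$code[duplicated(df$code)]), collapse = ", "))
  }
  for (col in .predictor_cols) {
    x <- df[[col]]
    if (any(!is.finite(x))) stop("non-finite value in predictor column ", col)
    if (any(x < 0)) stop("negative value in predictor column ", col)
  }
  if (any(df$time_min <= 0)) stop("immersion time must be positive")
  for (col in .response_cols) {
    x <- df[[col]]
    bad <- !is.na(x) & (x < 0 | x > 100)
    if (any(bad)) {
      stop("observed response outside [0, 100] in column ", col,
           " (row ", which(bad)[1], ")")
    }
  }
  invisible(df)
}

#' Read a disinfection experiment table from CSV
#'
#' Expects the canonical comma-separated schema
#' `code,naocl_pct,h2o2_pct,hgcl2_pct,time_min,de_actual,nde_actual` with the
#' optional model columns `de_pred,nde_pred,de_resid,nde_resid`. Empty cells
#' become missing values, never zero. A cell that is neither empty nor a
#' number is a parse error naming the offending row and column.
#'
#' @param path path to a CSV file.
#' @param provenance recorded on the returned table; defaults to the path.
#' @return a `disinfection_table`.
#' @export
load_table <- function(path, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, strip.white = TRUE)
  if (nrow(raw) == 0) stop("no data rows in ", path)
  num_cols <- intersect(c(.predictor_cols, .response_cols, .model_cols),
                        names(raw))
  for (col in num_cols) {
    cell <- raw[[col]]
    val <- suppressWarnings(as.numeric(cell))
    bad <- is.na(val) & !(cell == "" | is.na(cell) | toupper(cell) == "NA")
    if (any(bad)) {
      stop(sprintf("malformed numeric cell '%s' at row %d, column %s",
                   cell[which(bad)[1]], which(bad)[1], col))
    }
    raw[[col]] <- val
  }
  disinfection_table(raw, provenance = provenance)
}

#' Write a disinfection experiment table to CSV
#'
#' Missing responses are written as empty cells so that
#' `load_table(write_table(t))` round-trips losslessly.
#'
#' @param table a `disinfection_table`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_table <- function(table, path) {
  stopifnot(inherits(table, "disinfection_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}

#' Split an experiment table into training / validation / test sets
#'
#' Draws a random partition of the row indices with subset sizes equal to the
#' rounded fractions (the remainder goes to the test set), reproducible for a
#' fixed seed. The global random-number state is left untouched.
#'
#' @param table a `disinfection_table`.
#' @param fractions three proportions summing to 1 (train, validation, test).
#' @param seed integer seed; required, there is no hidden default.
#' @return a `data_split` list with `train_idx`, `val_idx`, `test_idx`, `seed`.
#' @export
split_table <- function(table, fractions = c(0.70, 0.15, 0.15), seed) {
  stopifnot(inherits(table, "disinfection_table"))
  if (missing(seed)) stop("an explicit seed is required")
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three non-negative proportions summing to 1")
  }
  n <- nrow(table)
  if (n < 3) stop("need at least 3 records to split")
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  if (n_train + n_val > n) n_val <- n - n_train
  perm <- with_seed(seed, sample.int(n))
  split <- list(train_idx = sort(perm[seq_len(n_train)]),
                val_idx = sort(perm[n_train + seq_len(n_val)]),
                test_idx = sort(perm[setdiff(seq_len(n), seq_len(n_train + n_val))]),
                seed = as.integer(seed))
  class(split) <- "data_split"
  split
}

# run expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 4-column matrix of protocol variables in canonical order
treatment_matrix <- function(table) {
  x <- as.matrix(as.data.frame(table)[, .predictor_cols])
  colnames(x) <- .var_ids
  x
}

#' @export
print.disinfection_table <- function(x, ...) {
  cat(sprintf("disinfection experiment table: %d treatments (%s)\n",
              nrow(x), attr(x, "provenance")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("data split (seed %d): %d train / %d validation / %d test\n",
              x$seed, length(x$train_idx), length(x$val_idx),
              length(x$test_idx)))
  invisible(x)
}
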