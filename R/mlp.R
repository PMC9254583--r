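#' Hyperbolic tangent sigmoid activation
#'
#' `tansig(x) = 2 / (1 + exp(-2 x)) - 1`, the hidden-layer activation of the
#' network: odd, strictly increasing, saturating at -1 and 1.
#'
#' @param x numeric vector.
#' @return numeric vector in (-1, 1).
#' @export
tansig <- function(x) 2 / (1 + exp(-2 * x)) - 1

#' Construct a 4-H-2 multilayer perceptron parameter set
#'
#' A single-hidden-layer feed-forward network with tansig hidden units and
#' linear (purelin) outputs, mapping the four normalized protocol variables to
#' normalized disinfection efficiency (DE) and negative disinfection effect
#' (NDE). Hidden unit `i` is the row `w1[i, ]` with bias `b1[i]`, and feeds
#' the outputs through `w2_de[i]` and `w2_nde[i]`.
#'
#' @param w1 hidden weight matrix, `hidden_size` x 4.
#' @param b1 hidden bias vector, length `hidden_size`.
#' @param w2_de,w2_nde output weight vectors, length `hidden_size`.
#' @param b2_de,b2_nde scalar output biases.
#' @return an `mlp_params` object.
#' @export
mlp_params <- function(w1, b1, w2_de, w2_nde, b2_de, b2_nde) {
  w1 <- as.matrix(w1)
  h <- nrow(w1)
  if (ncol(w1) != 4) stop("w1 must have 4 columns (one per protocol variable)")
  if (length(b1) != h) stop("b1 length must equal nrow(w1)")
  if (length(w2_de) != h || length(w2_nde) != h) {
    stop("output weight vectors must have one entry per hidden unit")
  }
  if (length(b2_de) != 1 || length(b2_nde) != 1) {
    stop("output biases must be scalars")
  }
  p <- list(w1 = unname(w1), b1 = as.numeric(b1),
            w2_de = as.numeric(w2_de), w2_nde = as.numeric(w2_nde),
            b2_de = as.numeric(b2_de), b2_nde = as.numeric(b2_nde),
            hidden_size = h)
  if (!all(vapply(p[1:6], function(v) all(is.finite(v)), logical(1)))) {
    stop("all network parameters must be finite")
  }
  structure(p, class = "mlp_params")
}

#' Forward pass in the normalized domain
#'
#' Computes `purelin(w2 %*% tansig(w1 %*% x + b1) + b2)` for each input row
#' and both outputs; purelin is the identity.
#'
#' @param xn normalized inputs: length-4 vector or n x 4 matrix.
#' @param params an `mlp_params` object.
#' @return n x 2 matrix with columns `de` and `nde` (normalized scale).
#' @export
mlp_forward <- function(xn, params) {
  stopifnot(inherits(params, "mlp_params"))
  if (is.null(dim(xn))) xn <- matrix(xn, nrow = 1)
  if (ncol(xn) != 4) stop("inputs must have 4 columns")
  h <- tansig(xn %*% t(params$w1) +
                matrix(params$b1, nrow(xn), params$hidden_size, byrow = TRUE))
  cbind(de = as.vector(h %*% params$w2_de) + params$b2_de,
        nde = as.vector(h %*% params$w2_nde) + params$b2_nde)
}

#' Predict disinfection outcomes in raw units
#'
#' Normalizes the protocol variables, runs the forward pass and maps the two
#' outputs back to percent. Predictions are not clipped: values outside
#' \[0, 100\] are returned as-is, mirroring how the fitted model behaves at
#' the edge of its calibration range.
#'
#' @param newdata a `disinfection_table`, a data frame with the predictor
#'   columns (`naocl_pct`, `h2o2_pct`, `hgcl2_pct`, `time_min`), or an
#'   n x 4 matrix / length-4 vector in that variable order.
#' @param params an `mlp_params` object.
#' @param scaler a `minmax_scaler` covering the four inputs and both outputs.
#' @return data frame with columns `de_pred` and `nde_pred` (percent).
#' @export
predict_treatments <- function(newdata, params, scaler) {
  if (is.data.frame(newdata)) {
    x <- as.matrix(as.data.frame(newdata)[, .predictor_cols])
  } else if (is.null(dim(newdata))) {
    x <- matrix(newdata, nrow = 1)
  } else {
    x <- as.matrix(newdata)
  }
  if (ncol(x) != 4) stop("newdata must supply the 4 protocol variables")
  colnames(x) <- .var_ids
  yn <- mlp_forward(normalize_inputs(x, scaler), params)
  data.frame(de_pred = denormalize(yn[, "de"], scaler, "de"),
             nde_pred = denormalize(yn[, "nde"], scaler, "nde"))
}

#' Read / write MLP parameters as structured text
#'
#' Labeled-section format: a `hidden_size:` line followed by `[w1]`, `[b1]`,
#' `[w2_de]`, `[w2_nde]`, `[b2_de]`, `[b2_nde]` blocks of whitespace-separated
#' numbers at full precision. The packaged published weights use this format,
#' and user-trained models round-trip through the same pair.
#'
#' @param path text file path.
#' @return `read_mlp_params` returns an `mlp_params`; `write_mlp_params`
#'   returns the path, invisibly.
#' @export
read_mlp_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  hs_line <- grep("^hidden_size:", lines, value = TRUE)
  if (length(hs_line) != 1) stop("corrupt parameter file: need one hidden_size line")
  hidden_size <- as.integer(sub("^hidden_size:\\s*", "", hs_line))
  sections <- list()
  current <- NULL
  for (ln in lines) {
    if (grepl("^hidden_size:", ln)) next
    if (grepl("^\\[.+\\]$", ln)) {
      current <- gsub("\\[|\\]", "", ln)
      sections[[current]] <- numeric(0)
    } else {
      if (is.null(current)) stop("corrupt parameter file: values before any section")
      vals <- as.numeric(strsplit(ln, "\\s+")[[1]])
      if (anyNA(vals)) stop("corrupt parameter file: non-numeric value in [", current, "]")
      sections[[current]] <- c(sections[[current]], vals)
    }
  }
  need <- c("w1", "b1", "w2_de", "w2_nde", "b2_de", "b2_nde")
  if (!all(need %in% names(sections))) {
    stop("corrupt parameter file: missing section(s) ",
         paste(setdiff(need, names(sections)), collapse = ", "))
  }
  if (length(sections$w1) != hidden_size * 4) {
    stop("corrupt parameter file: w1 has ", length(sections$w1),
         " entries, expected ", hidden_size * 4)
  }
  mlp_params(matrix(sections$w1, nrow = hidden_size, ncol = 4, byrow = TRUE),
             sections$b1, sections$w2_de, sections$w2_nde,
             sections$b2_de, sections$b2_nde)
}

#' @rdname read_mlp_params
#' @param params an `mlp_params` object.
#' @export
write_mlp_params <- function(params, path) {
  stopifnot(inherits(params, "mlp_params"))
  fmt <- function(v) sprintf("%.17g", v)
  lines <- c(
    "# 4-H-2 multilayer perceptron parameters (tansig hidden layer, linear outputs)",
    sprintf("hidden_size: %d", params$hidden_size),
    "[w1]", apply(params$w1, 1, function(r) paste(fmt(r), collapse = " ")),
    "[b1]", fmt(params$b1),
    "[w2_de]", fmt(params$w2_de),
    "[w2_nde]", fmt(params$w2_nde),
    "[b2_de]", fmt(params$b2_de),
    "[b2_nde]", fmt(params$b2_nde))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.mlp_params <- function(x, ...) {
  cat(sprintf("4-%d-2 MLP (tansig hidden layer, linear outputs), %d parameters\n",
              x$hidden_size, x$hidden_size * 4 + x$hidden_size * 3 + 2))
  invisible(x)
}
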