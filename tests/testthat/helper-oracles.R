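# independent oracles used across the suite; deliberately naive

# forward pass as explicit double loops over hidden units and inputs
naive_forward <- function(xn, p) {
  out <- matrix(NA_real_, nrow(xn), 2)
  for (r in seq_len(nrow(xn))) {
    hidden <- numeric(p$hidden_size)
    for (i in seq_len(p$hidden_size)) {
      acc <- p$b1[i]
      for (j in 1:4) acc <- acc + p$w1[i, j] * xn[r, j]
      hidden[i] <- 2 / (1 + exp(-2 * acc)) - 1
    }
    de <- p$b2_de
    nde <- p$b2_nde
    for (i in seq_len(p$hidden_size)) {
      de <- de + p$w2_de[i] * hidden[i]
      nde <- nde + p$w2_nde[i] * hidden[i]
    }
    out[r, ] <- c(de, nde)
  }
  out
}

# rank-1 membership by exhaustive pairwise domination checks
brute_front <- function(obj) {
  n <- nrow(obj)
  vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) {
      j != i && dominates(obj[j, ], obj[i, ])
    }, logical(1)))
  }, logical(1))
}

# random parameter set for a 4-h-2 network
random_mlp <- function(h, seed) {
  set.seed(seed)
  mlp_params(w1 = matrix(rnorm(h * 4), h, 4), b1 = rnorm(h),
             w2_de = rnorm(h), w2_nde = rnorm(h),
             b2_de = rnorm(1), b2_nde = rnorm(1))
}

# random valid experiment table, some responses missing
random_table <- function(n, seed) {
  set.seed(seed)
  df <- data.frame(
    code = sprintf("R%d", seq_len(n)),
    naocl_pct = round(runif(n, 0, 1.3), 3),
    h2o2_pct = round(runif(n, 0, 12), 3),
    hgcl2_pct = round(runif(n, 0, 0.2), 4),
    time_min = round(runif(n, 5, 30), 2),
    de_actual = round(runif(n, 0, 100), 2),
    nde_actual = round(runif(n, 0, 100), 2))
  df$nde_actual[sample.int(n, 1)] <- NA
  df
}
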