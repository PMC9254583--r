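# noise-free table generated by a known 4-h-2 teacher network, for network
# recovery tests; weights scaled so raw responses stay inside (0, 100)
teacher_table <- function(n, seed, scaler = published_scaler()) {
  set.seed(seed)
  h <- 10
  teacher <- mlp_params(matrix(rnorm(h * 4, sd = 0.6), h, 4),
                        rnorm(h, sd = 0.4), rnorm(h, sd = 0.25),
                        rnorm(h, sd = 0.25), 0, 0)
  b <- default_bounds()
  x <- sapply(1:4, function(j) runif(n, b[j, 1], b[j, 2]))
  pred <- predict_treatments(x, teacher, scaler)
  tab <- disinfection_table(data.frame(
    code = sprintf("S%d", seq_len(n)),
    naocl_pct = x[, 1], h2o2_pct = x[, 2], hgcl2_pct = x[, 3],
    time_min = x[, 4],
    de_actual = pred$de_pred, nde_actual = pred$nde_pred),
    provenance = "teacher network")
  list(teacher = teacher, table = tab)
}
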