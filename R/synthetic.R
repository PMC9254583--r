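#' Ground-truth dose-response surface parameters
#'
#' The synthetic generator emulates the qualitative structure of a
#' surface-disinfection experiment with a mechanistic surface, deliberately
#' outside the MLP model family. Each chemical's effective exposure is
#' `e = dose * t / (t + time_half)` (dose intensified by immersion time with
#' saturation). Disinfection acts by independent action across chemicals,
#' each with a Hill kill curve: `kill = e^hill / (e^hill + ec50^hill)` and
#' `DE = 100 (1 - prod(1 - kill))`. Phytotoxicity is a single saturating
#' Hill response to the toxicity-weighted total exposure:
#' `NDE = 100 s^ph / (s^ph + phytotox_ec50^ph)` with
#' `s = sum(tox_weight * e)`.
#'
#' Defaults are calibrated once to the per-chemical response ranges observed
#' in the study system over its tested dose and time grids: NaOCl
#' (0.54-1.26 \% w/v, 10-30 min) kills 27-77\% with negligible phytotoxicity,
#' H2O2 (5.25-12.25 \%, 10-30 min) kills 66-100\% with moderate
#' phytotoxicity, and HgCl2 (0.05-0.2 \%, 5-15 min) is by far the most
#' potent per unit dose and the dominant source of damage. The HgCl2 kill
#' curve is kept smoother (lower Hill slope) than the near-total kill the
#' real assay shows at its lowest dose, so the surface stays learnable by a
#' moderate-size network; the potency ordering is preserved.
#'
#' @param ec50 per-chemical half-kill effective exposure (NaOCl, H2O2, HgCl2;
#'   same units as dose).
#' @param hill per-chemical Hill slopes (> 0).
#' @param time_half minutes to half of the asymptotic exposure.
#' @param tox_weight per-chemical phytotoxicity weight (per unit exposure).
#' @param phytotox_ec50,phytotox_hill parameters of the toxicity response.
#' @param noise_sd observation noise, percentage points.
#' @return a `surface_params` list.
#' @export
surface_params <- function(ec50 = c(naocl = 0.54, h2o2 = 1.7, hgcl2 = 0.01),
                           hill = c(naocl = 1.5, h2o2 = 1.5, hgcl2 = 1.2),
                           time_half = c(naocl = 10, h2o2 = 10, hgcl2 = 5),
                           tox_weight = c(naocl = 0.35, h2o2 = 0.10,
                                          hgcl2 = 18),
                           phytotox_ec50 = 1, phytotox_hill = 2,
                           noise_sd = 5) {
  stopifnot(all(ec50 > 0), all(hill > 0), all(time_half > 0),
            all(tox_weight >= 0), phytotox_ec50 > 0, phytotox_hill > 0,
            noise_sd >= 0)
  structure(list(ec50 = ec50, hill = hill, time_half = time_half,
                 tox_weight = tox_weight, phytotox_ec50 = phytotox_ec50,
                 phytotox_hill = phytotox_hill, noise_sd = noise_sd),
            class = "surface_params")
}

#' Evaluate the true dose-response surface
#'
#' @param x length-4 vector or n x 4 matrix of protocol variables
#'   (NaOCl, H2O2, HgCl2, time), or a `disinfection_table`.
#' @param sp a `surface_params`.
#' @return data frame with `de_true` and `nde_true`, both in \[0, 100\].
#' @export
true_surface <- function(x, sp) {
  stopifnot(inherits(sp, "surface_params"))
  if (is.data.frame(x)) x <- treatment_matrix(disinfection_table(x))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  t_min <- x[, 4]
  surv <- rep(1, nrow(x))
  tox <- rep(0, nrow(x))
  for (c_i in 1:3) {
    e <- x[, c_i] * t_min / (t_min + sp$time_half[c_i])
    kill <- e^sp$hill[c_i] / (e^sp$hill[c_i] + sp$ec50[c_i]^sp$hill[c_i])
    kill[e == 0] <- 0
    surv <- surv * (1 - kill)
    tox <- tox + sp$tox_weight[c_i] * e
  }
  nde <- tox^sp$phytotox_hill /
    (tox^sp$phytotox_hill + sp$phytotox_ec50^sp$phytotox_hill)
  nde[tox == 0] <- 0
  data.frame(de_true = 100 * (1 - surv), nde_true = 100 * nde)
}

#' Generate a synthetic disinfection experiment table
#'
#' Treatments are drawn from the protocol box (uniformly at random or as the
#' leading rows of a full-factorial grid) and responses are the true surface
#' plus Gaussian noise, truncated to \[0, 100\] — observed percentages are
#' bounded even though the underlying model is not.
#'
#' @param n number of treatments.
#' @param sp a `surface_params`.
#' @param design `"random"` or `"grid"`.
#' @param seed integer seed; required.
#' @param bounds protocol box, default [default_bounds()].
#' @return a `disinfection_table` with columns matching the packaged study
#'   table.
#' @export
generate_table <- function(n, sp, design = c("random", "grid"), seed,
                           bounds = default_bounds()) {
  stopifnot(inherits(sp, "surface_params"), n >= 1)
  if (missing(seed)) stop("an explicit seed is required")
  design <- match.arg(design)
  with_seed(seed, {
    if (design == "random") {
      x <- sapply(1:4, function(j) stats::runif(n, bounds[j, 1], bounds[j, 2]))
    } else {
      k <- ceiling(n^(1 / 4))
      levels <- lapply(1:4, function(j) seq(bounds[j, 1], bounds[j, 2],
                                            length.out = max(k, 2)))
      x <- as.matrix(expand.grid(levels))[seq_len(n), , drop = FALSE]
    }
    truth <- true_surface(x, sp)
    de <- truth$de_true + stats::rnorm(n, sd = sp$noise_sd)
    nde <- truth$nde_true + stats::rnorm(n, sd = sp$noise_sd)
    disinfection_table(
      data.frame(code = sprintf("S%d", seq_len(n)),
                 naocl_pct = x[, 1], h2o2_pct = x[, 2], hgcl2_pct = x[, 3],
                 time_min = x[, 4],
                 de_actual = pmin(pmax(de, 0), 100),
                 nde_actual = pmin(pmax(nde, 0), 100)),
      provenance = sprintf("synthetic %s design (n=%d, seed %d)",
                           design, n, seed))
  })
}
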