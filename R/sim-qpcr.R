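#' Simulate qPCR amplification curves
#'
#' Fluorescence follows `baseline + plateau * x / (plateau + x)` with
#' `x = q0 * efficiency^cycle` — exponential growth with logistic clipping
#' at the plateau — plus Gaussian noise. The true (fractional) Ct is the
#' cycle at which the exponential-phase signal crosses `threshold`:
#' `Ct = log(threshold / q0) / log(efficiency)`, so halving `q0` at
#' efficiency 2 raises Ct by exactly one cycle.
#'
#' @param q0 numeric vector of true initial quantities (arbitrary units).
#' @param efficiency per-cycle amplification factor(s) in `(1, 2]`.
#' @param n_cycles number of cycles (`>= 30`).
#' @param noise Gaussian noise SD on the fluorescence scale.
#' @param seed RNG seed.
#' @param baseline,plateau,threshold curve constants.
#' @return list with `curves` (list of per-cycle fluorescence vectors named
#'   `well1`, ...) and `truth` (data.frame well / q0 / efficiency /
#'   true_ct).
#' @export
simulate_qpcr_curves <- function(q0, efficiency = 2, n_cycles = 40L,
                                 noise = 0, seed = 1L,
                                 baseline = 0.05, plateau = 10,
                                 threshold = 0.1) {
  stopifnot(all(efficiency > 1), all(efficiency <= 2), n_cycles >= 30L)
  set.seed(seed)
  efficiency <- rep_len(efficiency, length(q0))
  curves <- list()
  truth <- data.frame(well = character(), q0 = numeric(),
                      efficiency = numeric(), true_ct = numeric(),
                      stringsAsFactors = FALSE)
  for (i in seq_along(q0)) {
    x <- q0[i] * efficiency[i]^seq_len(n_cycles)
    f <- baseline + plateau * x / (plateau + x)
    if (noise > 0) f <- f + rnorm(n_cycles, 0, noise)
    well <- sprintf("well%d", i)
    curves[[well]] <- f
    truth <- rbind(truth, data.frame(
      well = well, q0 = q0[i], efficiency = efficiency[i],
      true_ct = log(threshold / q0[i]) / log(efficiency[i]),
      stringsAsFactors = FALSE))
  }
  list(curves = curves, truth = truth)
}
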