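## Radial spectral density of the chromatin process and quadrature helpers.
##
## The realizable process (see process_acf) is defined through its radial
## spectrum Phi(q) = (1 / (2 pi^2 q)) int_0^Inf r B(r) sin(q r) dr.
## A small negative residue (clip mass < ~10% near d_b = 3, < 1% over most
## of the range) is clipped to zero; the clipped spectrum defines the
## process that both the field synthesiser and the analytic Sigma map use,
## so the forward and inverse routes stay mutually consistent.

## Composite trapezoid weights for an arbitrary ordered grid.
.trapz_weights <- function(x) {
  dx <- diff(x)
  c(dx / 2, 0) + c(0, dx / 2)
}

#' Radial spectral density of the chromatin process
#'
#' Computes the 3-D isotropic spectral density of the smooth process
#' autocorrelation ([process_acf()]) by a sine-transform quadrature, clips
#' any negative residue, and returns an interpolating function `Phi(q)`
#' (q in rad/nm) valid on (0, 0.7] rad/nm, together with the clipped
#' negative-mass fraction.
#'
#' @param model A `cspws_acf` model.
#' @return A list with elements `phi` (function of q), `neg_fraction`, and
#'   `q_max`.
#' @export
process_spectrum <- function(model) {
  rmax <- model$r_max_nm
  r <- c(seq(0.25, 60, by = 0.25),
         seq(60.5, 400, by = 0.5),
         seq(401, rmax * 3 + 2000, by = 1))
  wr <- .trapz_weights(r)
  rbw <- r * process_acf(model, r) * wr
  qg <- c(seq(1e-5, 2e-3, by = 5e-5),
          exp(seq(log(2.1e-3), log(0.7), length.out = 500)))
  p <- as.numeric(sin(outer(qg, r)) %*% rbw) / (2 * pi^2 * qg)
  neg <- p < 0
  neg_fraction <- if (any(neg)) {
    sum(abs(p[neg]) * qg[neg]^2) / sum(abs(p) * qg^2)
  } else 0
  p[neg] <- 0
  f <- stats::splinefun(qg, p, method = "monoH.FC")
  phi <- function(q) {
    q <- pmin(pmax(q, qg[1]), qg[length(qg)])
    pmax(f(q), 0)
  }
  list(phi = phi, neg_fraction = neg_fraction, q_max = qg[length(qg)])
}
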