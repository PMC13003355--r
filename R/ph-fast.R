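# Vectorized charge-balance machinery.
#
# solve_ph() is the reference scalar solver (Brent + residual polish); the
# absorber re-solves the liquor pH in every stage at every RHS evaluation,
# so a bisection solver vectorized over stages is used there. Both solve the
# same charge balance; agreement is asserted in the test suite.

# mean species charge per mole of total, vectorized over pH
.mean_charge_vec <- function(pKa, charge0, pH) {
  n <- length(pKa)
  wsum <- rep(1, length(pH))
  csum <- rep(charge0, length(pH))
  lw <- rep(0, length(pH))
  for (j in seq_len(n)) {
    lw <- lw + (pH - pKa[j])
    w <- 10^lw
    wsum <- wsum + w
    csum <- csum + w * (charge0 - j)
  }
  csum / wsum
}

# fraction of the fully protonated (neutral, gas-exchanging) state
.alpha0_vec <- function(pKa, pH) {
  wsum <- rep(1, length(pH))
  lw <- rep(0, length(pH))
  for (j in seq_along(pKa)) {
    lw <- lw + (pH - pKa[j])
    wsum <- wsum + 10^lw
  }
  1 / wsum
}

# charge residual, vectorized over pH (and over per-system total vectors)
.residual_vec <- function(totals_list, systems, sc, sa, pH, pKw = 14) {
  res <- sc - sa + 10^(-pH) - 10^(pH - pKw)
  for (nm in names(totals_list)) {
    s <- systems[[nm]]
    res <- res + totals_list[[nm]] * .mean_charge_vec(s$pKa, s$charge0, pH)
  }
  res
}

# bisection on [0, 14], 54 iterations (interval width 14/2^54 ~ 8e-16)
.solve_ph_vec <- function(totals_list, systems, sc, sa) {
  m <- max(c(1L, lengths(totals_list), length(sc), length(sa)))
  lo <- rep(0, m)
  hi <- rep(14, m)
  flo <- .residual_vec(totals_list, systems, sc, sa, lo)
  fhi <- .residual_vec(totals_list, systems, sc, sa, hi)
  if (any(sign(flo) == sign(fhi))) {
    stop("degenerate input: charge balance has no root in pH [0, 14]")
  }
  for (it in 1:54) {
    mid <- 0.5 * (lo + hi)
    fm <- .residual_vec(totals_list, systems, sc, sa, mid)
    take <- fm > 0 # residual decreasing in pH: root above mid
    lo[take] <- mid[take]
    hi[!take] <- mid[!take]
  }
  0.5 * (lo + hi)
}
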