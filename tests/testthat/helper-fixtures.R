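# Shared fixtures: small games and graphs built in code.

vd_3_1 <- function(d = 3) volunteers_dilemma(B = 3, C = 1, d = d)

random_game <- function(d) {
  multiplayer_game(a = runif(d, -2, 2), b = runif(d, -2, 2))
}

# Brute-force oracle for sigma_rule_lhs: explicit loop over j, no vector ops.
lhs_bruteforce <- function(sigma, a, b) {
  d <- length(sigma)
  tot <- 0
  for (j in 0:(d - 1)) tot <- tot + sigma[j + 1] * (a[j + 1] - b[d - j])
  tot
}

# Bisection on B/C for the sigma-rule threshold of a one-parameter game
# family (C fixed at 1), independent of the closed-form threshold functions.
bc_threshold_bisect <- function(sc, maker, lo = 1e-3, hi = 1e3, tol = 1e-11) {
  f <- function(bc) sigma_rule_lhs(sc, maker(B = bc, C = 1, d = sc$d))
  stopifnot(f(lo) < 0, f(hi) > 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
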