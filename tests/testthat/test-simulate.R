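test_that("focal payoffs count A-neighbors in a single self-centered game", {
  g <- make_ring(6, 2)
  vd <- vd_3_1()
  all_a <- rep(1L, 6)
  expect_equal(focal_payoff(1, all_a, vd, g), vd$a[3])      # a[k]
  # A-vertex with one A and one B neighbor
  st <- c(1L, 1L, 0L, 0L, 0L, 0L)
  expect_equal(focal_payoff(1, st, vd, g), vd$a[2])
  # B-vertex flanked by two A players gets b[2] = 3
  st2 <- c(1L, 0L, 1L, 0L, 0L, 0L)
  expect_equal(focal_payoff(2, st2, vd, g), 3)
  expect_error(focal_payoff(1, all_a, volunteers_dilemma(3, 1, 4), g),
               "group-size mismatch")
})

test_that("a death-Birth step copies a neighbor and fixes monomorphic states", {
  g <- make_ring(8, 2)
  vd <- vd_3_1()
  mono <- rep(1L, 8)
  set.seed(3)
  expect_equal(db_step(mono, vd, g, w = 0.1), mono)
  for (i in 1:50) {
    st <- as.integer(runif(8) < 0.5)
    new <- db_step(st, vd, g, w = 0.1)
    ch <- which(new != st)
    expect_lte(length(ch), 1)
    if (length(ch) == 1) expect_true(new[ch] %in% st[g$adj[ch, ]])
  }
})

test_that("replacement probabilities follow relative fitness 1 - w + w payoff", {
  # cycle of 4, single A at vertex 1, focal deaths at vertex 2 compete
  # neighbor 1 (A, zero A co-players) against neighbor 3 (B, zero A co-players)
  g <- make_ring(4, 2)
  vd <- vd_3_1()
  w <- 0.5
  fA <- 1 - w + w * vd$a[1]
  fB <- 1 - w + w * vd$b[1]
  p_flip <- (1 / 4) * fA / (fA + fB)  # P(vertex 2 dies and adopts A)
  st <- c(1L, 0L, 0L, 0L)
  set.seed(17)
  n <- 2e4
  flips <- sum(vapply(seq_len(n),
                      function(i) db_step(st, vd, g, w)[2] == 1L, logical(1)))
  expect_lt(abs(flips / n - p_flip), 3 * sqrt(p_flip * (1 - p_flip) / n))
})

test_that("fitness positivity is enforced up front", {
  g <- make_ring(6, 2)
  harsh <- multiplayer_game(a = c(-30, -30, -30), b = c(0, 1, 1))
  expect_error(fixation_probability(g, harsh, w = 0.5, runs = 10, seed = 1),
               "positivity")
  expect_error(db_step(rep(0L, 6), harsh, g, w = 0.5), "positivity")
})

test_that("Monte Carlo fixation is seeded, deterministic and neutral at 1/N", {
  g <- make_ring(10, 2)
  vd <- vd_3_1()
  e1 <- fixation_probability(g, vd, w = 0.01, runs = 4000, seed = 99)
  e2 <- fixation_probability(g, vd, w = 0.01, runs = 4000, seed = 99)
  expect_identical(e1$fixations, e2$fixations)
  expect_equal(e1$stderr, sqrt(e1$rho * (1 - e1$rho) / e1$runs))

  for (g0 in list(make_ring(8, 2), make_random_regular(8, 3, seed = 4))) {
    game0 <- multiplayer_game(rep(0, g0$k + 1), rep(0, g0$k + 1))
    e <- fixation_probability(g0, game0, w = 0, runs = 3e4, seed = 5)
    expect_lt(abs(e$rho - 1 / g0$N), 3 * sqrt((1 / g0$N) * (1 - 1 / g0$N) / e$runs))
  }

  # strongly favored mutant fixes more often than the disfavored one
  g3 <- make_ring(8, 2)
  big <- multiplayer_game(a = rep(3, 3), b = rep(0, 3))
  ea <- fixation_probability(g3, big, w = 0.2, runs = 4000, seed = 6, mutant = "A")
  eb <- fixation_probability(g3, big, w = 0.2, runs = 4000, seed = 6, mutant = "B")
  expect_gt(ea$rho, eb$rho)
})

test_that("exact chain solves neutral drift to 1/N and fixes the boundaries", {
  vd <- vd_3_1()
  g6 <- make_ring(6, 2)
  res <- exact_fixation(g6, vd, w = 0)
  expect_equal(res$rho_A, 1 / 6, tolerance = 1e-12)
  expect_equal(res$rho_B, 1 / 6, tolerance = 1e-12)
  expect_equal(res$prob_A_fixation[2^6], 1)   # all-A
  expect_equal(res$prob_A_fixation[1], 0)     # all-B
  expect_true(all(res$prob_A_fixation >= -1e-12 &
                    res$prob_A_fixation <= 1 + 1e-12))

  k4 <- make_random_regular(4, 3, seed = 1)
  expect_equal(exact_fixation(k4, volunteers_dilemma(3, 1, 4), w = 0)$rho_A,
               1 / 4, tolerance = 1e-12)
  r8 <- make_ring(8, 4)
  expect_equal(exact_fixation(r8, volunteers_dilemma(3, 1, 5), w = 0)$rho_A,
               1 / 8, tolerance = 1e-12)
})

test_that("Monte Carlo estimates agree with the exact chain under selection", {
  g <- make_ring(10, 2)
  vd <- vd_3_1()
  ex <- exact_fixation(g, vd, w = 0.01)
  for (m in c("A", "B")) {
    est <- fixation_probability(g, vd, w = 0.01, runs = 2e4, seed = 31,
                                mutant = m)
    truth <- if (m == "A") ex$rho_A else ex$rho_B
    expect_lt(abs(est$rho - truth), 3 * est$stderr + 1e-12)
  }
})

test_that("exact sign change converges to the weak-selection cycle threshold", {
  # on the cycle the coefficients are exact, so as w -> 0 the B/C where
  # rho_A = rho_B approaches 2(N-2)/(N-3); the bracket tightens with w
  g <- make_ring(10, 2)
  thr <- critical_bc_vd(cycle_coefficients(10))   # 16/7
  diff_at <- function(bc, w) {
    ex <- exact_fixation(g, volunteers_dilemma(bc, 1, 3), w)
    ex$rho_A - ex$rho_B
  }
  for (w in c(0.01, 0.005)) {
    expect_lt(diff_at(thr - 0.15, w), 0)
    expect_gt(diff_at(thr + 0.15, w), 0)
  }
})

test_that("benefit-to-cost sweeps track the exact chain", {
  g <- make_ring(10, 2)
  sw <- sweep_bc(g, "vd", bc_grid = c(1.5, 3.5), C = 1, w = 0.01,
                 runs = 5000, seed = 12)
  expect_equal(sw$diff, sw$rho_A - sw$rho_B)
  for (i in seq_len(nrow(sw))) {
    ex <- exact_fixation(g, volunteers_dilemma(sw$bc[i], 1, 3), w = 0.01)
    se <- sqrt(sw$stderr_A[i]^2 + sw$stderr_B[i]^2)
    expect_lt(abs(sw$diff[i] - (ex$rho_A - ex$rho_B)), 4 * se)
  }
  # neutral sweep: both fixation probabilities sit at 1/N
  sw0 <- sweep_bc(g, "vd", bc_grid = c(2, 3), C = 1, w = 0, runs = 5000,
                  seed = 13)
  expect_true(all(abs(sw0$rho_A - 0.1) < 4 * sw0$stderr_A))
  expect_true(all(abs(sw0$rho_B - 0.1) < 4 * sw0$stderr_B))
})
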