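test_that("sigma-rule lhs equals the brute-force sum and the cycle boundary rule", {
  set.seed(11)
  for (d in c(2, 3, 6)) {
    sc <- wellmixed_coefficients(20, d)
    g <- random_game(d)
    expect_equal(sigma_rule_lhs(sc, g), lhs_bruteforce(sc$sigma, g$a, g$b),
                 tolerance = 1e-14)
  }
  # large cycle: lhs = (a1 + a2 - b1 - b0)/2
  a <- c(0.4, -1, 2); b <- c(0.2, 0.9, -3)
  expect_equal(sigma_rule_lhs(cycle_coefficients(Inf), multiplayer_game(a, b)),
               (a[2] + a[3] - b[2] - b[1]) / 2)
  # zero game
  expect_equal(sigma_rule_lhs(cycle_coefficients(10),
                              multiplayer_game(rep(0, 3), rep(0, 3))), 0)
  expect_error(sigma_rule_lhs(cycle_coefficients(10), random_game(4)),
               "mismatch")
})

test_that("a strictly dominated strategy can be favored on the cycle", {
  g <- multiplayer_game(a = c(0, 0, 5), b = c(1, 1, 1))
  v <- is_favored(cycle_coefficients(Inf), g)
  expect_equal(v$lhs, 3 / 2)
  expect_true(v$favored)
  # a_j < b_j for every j, yet the large-cycle sigma rule still holds
  # because mutual cooperation pays enough (a_2 > b_0 + b_1 - a_1)
  dom <- multiplayer_game(a = c(0, 0, 5.5), b = c(1, 1, 6))
  expect_true(all(dom$a < dom$b))
  expect_true(is_favored(cycle_coefficients(Inf), dom)$favored)
})

test_that("verdicts flag the selection boundary and respect the VD threshold", {
  sc <- cycle_coefficients(Inf)
  expect_true(is_favored(sc, volunteers_dilemma(3, 1, 3))$favored)
  expect_false(is_favored(sc, volunteers_dilemma(1.5, 1, 3))$favored)
  at <- is_favored(sc, volunteers_dilemma(2, 1, 3))
  expect_false(at$favored)
  expect_true(at$boundary)
  gl <- glance(at)
  expect_equal(gl$lhs, 0)
  expect_true(gl$boundary)
})

test_that("sigma-rule lhs is linear in the payoffs (superposition)", {
  set.seed(5)
  sc <- regular_graph_coefficients(4)
  for (i in 1:20) {
    g1 <- random_game(5); g2 <- random_game(5)
    lam <- runif(1, -2, 2)
    mix <- multiplayer_game(g1$a + lam * g2$a, g1$b + lam * g2$b)
    expect_equal(sigma_rule_lhs(sc, mix),
                 sigma_rule_lhs(sc, g1) + lam * sigma_rule_lhs(sc, g2),
                 tolerance = 1e-12)
  }
})

test_that("strategy swap negates the lhs under symmetric coefficients", {
  set.seed(9)
  sc <- wellmixed_coefficients(Inf, 4)   # uniform
  for (i in 1:10) {
    g <- random_game(4)
    expect_equal(sigma_rule_lhs(sc, swap_strategies(g)),
                 -sigma_rule_lhs(sc, g), tolerance = 1e-14)
  }
})

test_that("volunteer's dilemma thresholds match closed forms and bisection", {
  expect_equal(critical_bc_vd(cycle_coefficients(Inf)), 2)
  expect_equal(critical_bc_vd_cs(cycle_coefficients(Inf)), 5 / 6)
  expect_equal(critical_bc_vd(wellmixed_coefficients(Inf, 4)), 4)   # k + 1
  expect_equal(critical_bc_vd_cs(wellmixed_coefficients(Inf, 3)), 11 / 6)
  for (N in c(5, 10, 100)) {
    sc <- cycle_coefficients(N)
    expect_equal(critical_bc_vd(sc), 2 * (N - 2) / (N - 3), tolerance = 1e-12)
    expect_equal(critical_bc_vd_cs(sc), (5 * N - 6) / (6 * (N - 3)),
                 tolerance = 1e-12)
  }
  # independent bisection oracle on the game constructors themselves
  for (sc in list(cycle_coefficients(12), regular_graph_coefficients(3),
                  wellmixed_coefficients(30, 4))) {
    expect_equal(bc_threshold_bisect(sc, volunteers_dilemma),
                 critical_bc_vd(sc), tolerance = 1e-9)
    expect_equal(bc_threshold_bisect(sc, vd_cost_sharing),
                 critical_bc_vd_cs(sc), tolerance = 1e-9)
  }
})

test_that("exact rational thresholds equal the closed-form fractions", {
  for (N in 4:1000) {
    sc <- cycle_coefficients(N)
    t1 <- critical_bc_vd(sc, exact = TRUE)
    t2 <- critical_bc_vd_cs(sc, exact = TRUE)
    r1 <- graphgames:::rat(2 * (N - 2), N - 3)
    r2 <- graphgames:::rat(5 * N - 6, 6 * (N - 3))
    expect_true(graphgames:::rat_eq(t1, r1))
    expect_true(graphgames:::rat_eq(t2, r2))
  }
  # degenerate: last coefficient zero means an infinite threshold
  sc0 <- normalize_coefficients(c(1, 1, 0))
  expect_identical(critical_bc_vd(sc0), Inf)
  expect_identical(critical_bc_vd_cs(sc0), Inf)
})

test_that("pairwise and linear reductions agree with the full sigma rule", {
  set.seed(2024)
  for (i in 1:300) {
    k <- sample(3:12, 1)
    p <- runif(4, -2, 2)
    full <- is_favored(regular_graph_coefficients(k),
                       game_from_pairwise(p[1], p[2], p[3], p[4], k))$favored
    expect_equal(pairwise_condition(p[1], p[2], p[3], p[4], k), full)

    q <- runif(3, -2, 2)
    fullL <- is_favored(regular_graph_coefficients(k),
                        linear_game(q[1], q[2], q[3], k))$favored
    expect_equal(linear_condition(q[1], q[2], q[3], k), fullL)
  }
  # donation game: favored iff B/C > k
  k <- 5
  expect_true(pairwise_condition(5.1 - 1, -1, 5.1, 0, k))
  expect_false(pairwise_condition(4.9 - 1, -1, 4.9, 0, k))
  # symmetric game sits on the boundary
  expect_false(pairwise_condition(1, 2, 2, 1, k))
  # linear game: D = 0 recovers B/C > k; large k needs D > 2C
  expect_true(linear_condition(5.1, 1, 0, 5))
  expect_false(linear_condition(4.9, 1, 0, 5))
  expect_true(linear_condition(0, 1, 2.1, 1000))
  expect_false(linear_condition(0, 1, 1.9, 1000))
})

test_that("sign changes are counted with zeros skipped", {
  expect_equal(sign_changes(c(-1, -2, 3, 4)), list(count = 1L, pattern = "-+"))
  expect_equal(sign_changes(c(1, -1, 1)), list(count = 2L, pattern = "+-+"))
  expect_equal(sign_changes(c(0, -1, 0, 2)), list(count = 1L, pattern = "-+"))
  expect_error(sign_changes(c(0, 0, 0)), "all entries")
})

test_that("containment order: graphs dominate the well-mixed baseline", {
  expect_equal(containment_compare(regular_graph_coefficients(5),
                                   wellmixed_coefficients(Inf, 6)),
               "a_contains_b")
  sc <- cycle_coefficients(10)
  expect_equal(containment_compare(sc, sc), "incomparable_by_this_test")
  expect_equal(containment_compare(cycle_coefficients(8),
                                   cycle_overlapping_coefficients(8)),
               "a_contains_b")
  expect_equal(containment_compare(wellmixed_coefficients(Inf, 6),
                                   regular_graph_coefficients(5)),
               "b_contains_a")
  scan <- containment_scan(3, 10)
  expect_equal(nrow(scan), 8)
  expect_true(all(scan$sign_change_count == 1 & scan$pattern == "-+"))
})
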