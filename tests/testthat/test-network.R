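# Connectivity construction, layer updates, and the fixed-point solver.

test_that("sigmoid midpoint and closed-form layer values", {
  expect_equal(sigmoid(-0.6, 3, -0.6), 0.5)
  expect_equal(sigmoid(-0.45, 4.5, -0.45), 0.5)
  expect_equal(sigmoid(0, 3, -0.6), 0.97340301, tolerance = 1e-6)
  expect_equal(sigmoid(-1, 3, -0.6), 0.08317270, tolerance = 1e-6)
  expect_equal(sigmoid(-1, 4.5, -0.45), 0.007033587, tolerance = 1e-6)
  expect_equal(sigmoid(0, 4.5, -0.45), 0.98287597, tolerance = 1e-6)
  x <- seq(-2, 2, by = 0.1)
  expect_true(all(diff(sigmoid(x, 4.5, -0.45)) > 0))
})

test_that("weight matrices have the required signs, fan-ins and scales", {
  m <- urchin_model(n_prc = 10, n_onr = 50)
  w <- m$weights
  expect_true(all(w$W_rp@x <= 0))
  expect_true(all(w$W_or@x <= 0))
  expect_true(all(w$W_rr@x >= 0))
  expect_true(all(w$W_oo@x >= 0))
  # every eONR group has exactly onr_fanin_k inhibitory afferents
  or_fanin <- Matrix::rowSums(w$W_or != 0)
  expect_true(all(or_fanin == 3))
  expect_true(all(abs(w$W_or@x) == 1 / sqrt(3)))
  # interior RN groups: 3 feedforward (1/sqrt(3)) and 2 lateral afferents
  rp_fanin <- Matrix::rowSums(w$W_rp != 0)
  expect_equal(sum(rp_fanin == 3), 5 * 8) # interior cells
  expect_equal(sum(rp_fanin == 2), 5 * 2) # ambulacrum edges
  rr_fanin <- Matrix::rowSums(w$W_rr != 0)
  expect_equal(sum(rr_fanin == 2), 5 * 8)
  # no self-connections on the diagonal
  expect_true(all(Matrix::diag(w$W_rr) == 0))
  expect_true(all(Matrix::diag(w$W_oo) == 0))
  # lateral RN links never cross ambulacrum boundaries
  s <- Matrix::summary(w$W_rr)
  expect_true(all(((s$i - 1) %/% 10) == ((s$j - 1) %/% 10)))
})

test_that("layer updates reproduce closed-form operating points", {
  m <- urchin_model()
  n <- 500
  # dark, no lateral input: RN at the spontaneous rate S(0)
  r <- rn_update(rep(0, n), rep(0, n), m)
  expect_equal(as.vector(r), rep(0.9734030, n), tolerance = 1e-6)
  # maximal photoreceptor drive, no lateral: S(-1)
  r <- rn_update(rep(1, n), rep(0, n), m)
  expect_equal(as.vector(r), rep(0.0831727, n), tolerance = 1e-6)
  # fully active RN silences eONR: S(-1); fully silent RN disinhibits: S(0)
  r <- onr_update(rep(1, n), rep(0, 500), m)
  expect_equal(as.vector(r), rep(0.007033587, 500), tolerance = 1e-6)
  r <- onr_update(rep(0, n), rep(0, 500), m)
  expect_equal(as.vector(r), rep(0.9828760, 500), tolerance = 1e-6)
})

test_that("update monotonicity follows the sign structure", {
  m <- urchin_model()
  set.seed(8)
  prc <- runif(500, 0, 0.8); rn <- runif(500, 0, 1)
  base_rn <- as.vector(rn_update(prc, rn, m))
  prc2 <- prc; prc2[250] <- prc2[250] + 0.1
  more_light <- as.vector(rn_update(prc2, rn, m))
  expect_lt(more_light[250], base_rn[250])  # light inhibits RN
  base_onr <- as.vector(onr_update(rn, rep(0.3, 500), m))
  rn2 <- rn; rn2[100] <- rn2[100] + 0.2
  expect_true(all(as.vector(onr_update(rn2, rep(0.3, 500), m)) <= base_onr))
  lat2 <- as.vector(onr_update(rn, rep(0.5, 500), m))
  expect_true(all(lat2 >= base_onr))        # lateral ONR input excites
})

test_that("control steady state is five-fold symmetric and bounded", {
  m <- default_model()
  st <- solve_steady_state(m, make_stimulus("control"))
  expect_true(st$converged)
  expect_lte(st$iterations, 600)
  for (tab in list(st$prc, st$rn, st$onr)) {
    expect_true(all(tab$rate >= 0 & tab$rate <= 1))
  }
  # RN activity identical across ambulacra; eONR 5-fold symmetric
  rnm <- matrix(st$rn$rate, ncol = 5)
  expect_lt(max(apply(rnm, 1, function(x) diff(range(x)))), 1e-9)
  onrm <- matrix(st$onr$rate, ncol = 5)
  expect_lt(max(apply(onrm, 1, function(x) diff(range(x)))), 1e-9)
})

test_that("fixed point is independent of initialization", {
  m <- default_model()
  s <- make_stimulus("dog", 69)
  st0 <- solve_steady_state(m, s, animal_pose(0, 0, 36), init = "zero")
  st1 <- solve_steady_state(m, s, animal_pose(0, 0, 36), init = "rmax")
  expect_true(st0$converged && st1$converged)
  expect_lt(max(abs(st0$rn$rate - st1$rn$rate)), 1e-4)
  expect_lt(max(abs(st0$onr$rate - st1$onr$rate)), 1e-4)
})

test_that("72-degree rotation permutes the steady state by one ambulacrum", {
  m <- default_model()
  s <- make_stimulus("dog", 69)
  a <- solve_steady_state(m, s, animal_pose(0, 0, 10))
  b <- solve_steady_state(m, s, animal_pose(0, 0, 82))
  # at psi + 72 each ambulacrum sees what its successor saw at psi
  rn_a <- matrix(a$rn$rate, ncol = 5); rn_b <- matrix(b$rn$rate, ncol = 5)
  expect_equal(rn_b[, 1:4], rn_a[, 2:5], tolerance = 1e-6)
  onr_a <- a$onr$rate; onr_b <- b$onr$rate
  expect_equal(onr_b, onr_a[c(101:500, 1:100)], tolerance = 1e-6)
})

test_that("steady state converges for all families and orientations", {
  m <- default_model()
  psi <- seq(0, 359, by = 5)
  for (family in c("bar", "dog", "flanked_bar", "morlet", "haar",
                   "hermitian")) {
    pv <- population_vectors(m, make_stimulus(family, 69), psi = psi)
    expect_true(all(pv$converged), label = family)
    expect_lte(max(pv$iterations), 600)
  }
})

test_that("disinhibition chain: light within an ambulacrum raises nearby eONR", {
  m <- default_model()
  # a thin white probe inside ambulacrum 1's span vs near-darkness
  st_dark <- solve_steady_state(m, make_stimulus("control",
                                                 background_grey = 0.001))
  stim <- make_stimulus("control", background_grey = 0.001)
  f0 <- attr(stim, "ink_fun")
  attr(stim, "ink_fun") <- function(phi) {
    ifelse(abs(((phi + 180) %% 360) - 180) <= 3, 0, f0(phi))
  }
  st_lit <- solve_steady_state(m, stim)
  near <- which(abs(((m$onr_pos + 180) %% 360) - 180) <= 10)
  expect_true(all(st_lit$onr$rate[near] >= st_dark$onr$rate[near] - 1e-9))
  expect_gt(max(st_lit$onr$rate[near] - st_dark$onr$rate[near]), 1e-4)
})
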