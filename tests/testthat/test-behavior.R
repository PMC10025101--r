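# Movement models and circular statistics.

test_that("circular mean vector matches direct evaluation", {
  cm <- circular_mean(c(0, 0, 90))
  expect_equal(cm$length, 0.7453560, tolerance = 1e-6)
  expect_equal(cm$direction_deg, 26.5650512, tolerance = 1e-6)
  expect_equal(circular_mean(rep(90, 5))$r_y, 1)
  expect_equal(circular_mean(c(0, 90, 180, 270))$length, 0, tolerance = 1e-12)
  expect_error(circular_mean(numeric(0)), "non-empty")
})

test_that("Rayleigh test: exact grid, full concentration, frozen series value", {
  expect_equal(rayleigh_test(seq(0, 350, by = 10))$p_value, 1)
  expect_lt(rayleigh_test(rep(33, 20))$p_value, 1e-6)
  # n = 100 with Rbar exactly 0.2: 20 aligned + 80 on a uniform grid
  b <- c(rep(0, 20), seq(0, 356.4, by = 4.5))
  rt <- rayleigh_test(b)
  expect_equal(rt$r_bar, 0.2, tolerance = 1e-12)
  expect_equal(rt$p_value, 0.017945866, tolerance = 1e-6)
  expect_error(rayleigh_test(c(1, 2, 3)), "at least 4")
})

test_that("V test: aligned, uniform, and opposed samples", {
  vt <- v_test(rep(0, 25), 0)
  expect_equal(vt$u, sqrt(50), tolerance = 1e-12)
  expect_lt(vt$p_value, 1e-11)
  expect_equal(v_test(seq(0, 350, by = 10), 0)$p_value, 0.5, tolerance = 1e-9)
  expect_gt(v_test(rep(180, 25), 0)$p_value, 1 - 1e-11)
})

test_that("analytic circular tests agree with a Monte-Carlo null oracle", {
  set.seed(99)
  bearings <- (rnorm(20, 20, 70)) %% 360
  obs_r <- circular_mean(bearings)$length
  obs_v <- v_test(bearings, 0)$v
  n_mc <- 20000
  null_r <- numeric(n_mc); null_v <- numeric(n_mc)
  for (i in seq_len(n_mc)) {
    u <- runif(20, 0, 360)
    cx <- mean(cos(u * pi / 180)); cy <- mean(sin(u * pi / 180))
    null_r[i] <- sqrt(cx^2 + cy^2)
    null_v[i] <- cx # Rbar * cos(mean - 0)
  }
  p_r_mc <- mean(null_r >= obs_r)
  p_v_mc <- mean(null_v >= obs_v)
  expect_lt(abs(rayleigh_test(bearings)$p_value - p_r_mc), 0.015)
  expect_lt(abs(v_test(bearings, 0)$p_value - p_v_mc), 0.02)
})

test_that("static endpoints: uniform below threshold, Gaussian above", {
  set.seed(1)
  draws <- static_endpoint(0, 0, theta_p = 5, n = 10000)
  # chi-square uniformity over 36 bins at alpha = 0.01
  counts <- table(cut(draws, seq(0, 360, by = 10)))
  chi2 <- sum((counts - 10000 / 36)^2 / (10000 / 36))
  expect_lt(chi2, qchisq(0.99, 35))
  # |v| = theta_p + 2: wrapped Gaussian, s.d. 0.5 rad = 28.65 deg
  draws <- static_endpoint(7, 90, theta_p = 5, n = 20000)
  expect_equal(circ_sd_deg(draws), 28.6479, tolerance = 1.5)
  expect_equal(circular_mean(draws)$direction_deg, 90, tolerance = 2)
  # very long vectors concentrate sharply at the capped s.d. (1 rad max)
  draws <- static_endpoint(1e6, 180, theta_p = 5, n = 5000)
  expect_lt(circ_sd_deg(draws), 1)
})

test_that("step direction: persistence, capture, and peri-threshold mixing", {
  set.seed(2)
  # subthreshold: q ~ 0, steps stay within ~10 deg of the previous heading
  d <- replicate(3000, step_direction(0, 0, phi_pre = 200, theta_p = 5))
  expect_equal(circular_mean(d)$direction_deg, 200, tolerance = 1)
  expect_equal(circ_sd_deg(d), 10, tolerance = 0.7)
  # strong vector: q ~ 1 with narrow sigma_1 -> captured by the stimulus
  d <- replicate(2000, step_direction(25, 40, phi_pre = 200, theta_p = 5))
  expect_equal(circular_mean(d)$direction_deg, 40, tolerance = 0.2)
  expect_lt(circ_sd_deg(d), 1)
  # peri-threshold: mixture components equally likely (q = 1/2); sigma_1
  # is 10/(v - theta) > 360 -> uniform component + persistence component
  d <- replicate(4000, step_direction(5, 0, phi_pre = 180, theta_p = 5))
  frac_near_pre <- mean(abs(((d - 180 + 180) %% 360) - 180) < 30)
  # half the draws from p2 (all within 30 deg) + uniform share of p1
  expect_equal(frac_near_pre, 0.5 + 0.5 * 60 / 360, tolerance = 0.04)
})

test_that("forced-persistence trajectory is a straight radial 8-step line", {
  m <- with_preferred_directions(urchin_model(sigma_2 = 0),
                                 pref = default_model()$pref)
  set.seed(7)
  tr <- simulate_trajectory(m, make_stimulus("control"), psi0 = 120)
  # q(v ~ 0) ~ 0 so every step follows the previous heading exactly;
  # 8 steps of 0.1 R reach the 0.75 R stopping radius
  expect_equal(nrow(tr), 8)
  expect_equal(length(unique(round(tr$heading_deg, 9))), 1)
  radii <- sqrt(tr$x^2 + tr$y^2)
  expect_equal(radii, seq(0.1, 0.8, by = 0.1), tolerance = 1e-12)
  expect_equal(attr(tr, "final_bearing"), tr$heading_deg[1],
               tolerance = 1e-9)
})

test_that("cohorts are reproducible and single subjects give |r_f| = 1", {
  m <- default_model()
  s <- make_stimulus("control")
  c1 <- run_cohort(m, s, n_subjects = 20, n_replicates = 2, seed = 5)
  c2 <- run_cohort(m, s, n_subjects = 20, n_replicates = 2, seed = 5)
  expect_identical(c1$bearings, c2$bearings)
  c3 <- run_cohort(m, s, n_subjects = 20, n_replicates = 2, seed = 6)
  expect_false(identical(c1$bearings, c3$bearings))
  c_one <- run_cohort(m, s, n_subjects = 1, seed = 3)
  expect_equal(c_one$stats$r_f_length, 1)
})

test_that("static and dynamic cohorts agree in aggregate", {
  m <- default_model()
  reps <- 6; n <- 25
  for (fam in list(c("dog", "69"), c("control", NA))) {
    s <- if (is.na(fam[2])) make_stimulus("control") else
      make_stimulus(fam[1], as.numeric(fam[2]))
    st <- run_cohort(m, s, n_subjects = n, n_replicates = reps,
                     mode = "static", seed = 21)
    dy <- run_cohort(m, s, n_subjects = n, n_replicates = reps,
                     mode = "dynamic", seed = 22)
    # mean resultant lengths statistically indistinguishable
    tt <- t.test(st$stats$r_f_length, dy$stats$r_f_length)
    expect_gt(tt$p.value, 0.001)
    expect_lt(abs(mean(st$stats$r_f_length) - mean(dy$stats$r_f_length)),
              0.2)
  }
})

test_that("endpoint-sampler robustness: wider Gaussians keep conclusions", {
  # widening the above-threshold endpoint s.d. by 5x or 10x must not change
  # which stimuli give significant taxis
  m <- default_model()
  pv <- pv_table("dog", 69)
  for (widen in c(1, 5, 10)) {
    set.seed(31)
    ps <- replicate(40, {
      psi0 <- sample(0:359, 100, replace = TRUE)
      bearing <- vapply(psi0, function(ps) {
        row <- pv[pv$psi == ps, ]
        if (row$length <= 5) runif(1, 0, 360) else
          (rnorm(1, row$bearing_deg,
                 pmin(widen / (row$length - 5), 1) * 180 / pi)) %% 360
      }, numeric(1))
      v_test(bearing, 0)$p_value
    })
    expect_lt(mean(ps), 0.1)
  }
})
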