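# Photoreceptor angular sensitivity and response quadrature.

test_that("angular sensitivity peaks at 1 and halves at +/- delta_rho/2", {
  expect_equal(angular_sensitivity(0, 30, 0), 1)
  expect_equal(angular_sensitivity(0, 30, c(-15, 15)), c(0.5, 0.5))
  # a = 2 cos(15 deg) - 1
  a <- 2 * cos(15 * pi / 180) - 1
  expect_equal(a, 0.9318516526, tolerance = 1e-9)
  # vanishes exactly outside the rectification support
  support <- acos(a) * 180 / pi
  expect_equal(angular_sensitivity(0, 30, support + 0.01), 0)
  expect_gt(angular_sensitivity(0, 30, support - 0.01), 0)
  # circular wrap-around of the difference
  expect_equal(angular_sensitivity(350, 30, 5),
               angular_sensitivity(0, 30, 15))
  expect_error(angular_sensitivity(0, 180, 0), "delta_rho")
})

test_that("FWHM of the sensitivity curve equals delta_rho", {
  for (dr in c(20, 30, 60, 120)) {
    half <- uniroot(function(x) angular_sensitivity(0, dr, x) - 0.5,
                    c(0, dr))$root
    expect_equal(2 * half, dr, tolerance = 1e-6)
  }
})

test_that("ambulacrum envelope FWHM is the effective acceptance angle", {
  for (par in list(c(30, 15), c(20, 10), c(40, 5))) {
    arr <- build_prc_array(n_prc = 100, delta = par[2], delta_rho = par[1])
    phi <- seq(-90, 90, by = 0.01)
    env <- prc_envelope(arr, 1, phi)
    expect_equal(max(env), 1)
    crossings <- range(phi[env >= 0.5])
    expect_equal(diff(crossings), par[1] + 2 * par[2], tolerance = 0.05)
  }
})

test_that("layout: five bands of n cells centred 72 deg apart", {
  arr <- build_prc_array()
  expect_equal(nrow(arr), 500)
  amb2 <- arr$center_deg[arr$ambulacrum == 2]
  expect_equal(range(amb2), c(57, 87))
  amb1 <- arr$center_deg[arr$ambulacrum == 1]
  expect_equal(sort(abs(((amb1 + 180) %% 360) - 180))[c(1, 100)], c(0.3 / 2, 15),
               tolerance = 0.011)
  expect_error(build_prc_array(delta = 36), "delta")
  arr20 <- build_prc_array(delta = 20)
  expect_equal(range(((arr20$center_deg[arr20$ambulacrum == 1] + 180) %% 360) - 180),
               c(-20, 20))
})

test_that("randomized acceptance angles are reproducible and well placed", {
  a1 <- build_prc_array(delta_rho_range = c(20, 40), seed = 11)
  a2 <- build_prc_array(delta_rho_range = c(20, 40), seed = 11)
  expect_identical(a1$delta_rho, a2$delta_rho)
  a3 <- build_prc_array(delta_rho_range = c(20, 40), seed = 12)
  expect_false(identical(a1$delta_rho, a3$delta_rho))
  # mean within 3 s.e. of the uniform mean 30
  se <- sqrt((40 - 20)^2 / 12 / nrow(a1))
  expect_lt(abs(mean(a1$delta_rho) - 30), 3 * se)
})

test_that("response to uniform and dark profiles is exact", {
  arr <- build_prc_array()
  grid <- seq(0, 359.5, by = 0.5)
  uniform <- tibble::tibble(angle_deg = grid, intensity = rep(0.37, 720))
  r <- prc_response(arr, uniform, r_max = 1)$response
  expect_equal(r, rep(0.37, 500), tolerance = 1e-12)
  dark <- tibble::tibble(angle_deg = grid, intensity = rep(0, 720))
  expect_equal(prc_response(arr, dark)$response, rep(0, 500))
})

test_that("response is linear in the profile", {
  arr <- build_prc_array(n_prc = 20)
  grid <- seq(0, 359.5, by = 0.5)
  set.seed(3)
  x1 <- runif(720); x2 <- runif(720)
  p <- function(v) tibble::tibble(angle_deg = grid, intensity = v)
  r1 <- prc_response(arr, p(x1))$response
  r2 <- prc_response(arr, p(x2))$response
  r12 <- prc_response(arr, p(0.4 * x1 + 0.6 * x2))$response
  expect_equal(r12, 0.4 * r1 + 0.6 * r2, tolerance = 1e-10)
})

test_that("narrow-bar response matches a fine-grid quadrature oracle", {
  arr <- build_prc_array()
  cell <- which(arr$ambulacrum == 1 & arr$cell == 50)
  ctr <- arr$center_deg[cell]
  grid <- seq(0, 359.5, by = 0.5)
  bar <- as.numeric(abs(((grid - ctr + 180) %% 360) - 180) <= 1)
  prof <- tibble::tibble(angle_deg = grid, intensity = bar)
  got <- prc_response(arr, prof)$response[cell]
  # oracle: direct quadrature of the rectified cosine at 0.01 deg
  fine <- seq(0, 359.99, by = 0.01)
  f <- angular_sensitivity(ctr, 30, fine)
  x <- as.numeric(abs(((fine - ctr + 180) %% 360) - 180) <= 1)
  # match the coarse sampling of the bar edges: oracle on the same stimulus
  # support as sampled on the coarse grid
  expected_fine <- sum(f * x) / sum(f)
  expect_equal(got, expected_fine, tolerance = 1e-3)
})

test_that("rotating the profile by 72 deg advances one ambulacrum", {
  arr <- build_prc_array()
  grid <- seq(0, 359.5, by = 0.5)
  s <- make_stimulus("dog", 69)
  x <- ink_to_intensity_profile(s)
  shift <- 72 / 0.5
  x72 <- x[((seq_along(x) - 1 + shift) %% length(x)) + 1]
  r <- prc_response(arr, tibble::tibble(angle_deg = grid, intensity = x))
  r72 <- prc_response(arr, tibble::tibble(angle_deg = grid, intensity = x72))
  for (k in 1:4) {
    expect_equal(r72$response[r72$ambulacrum == k],
                 r$response[r$ambulacrum == k + 1], tolerance = 1e-10)
  }
})
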