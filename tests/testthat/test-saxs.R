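test_that("SEC frame reduction subtracts buffer and propagates sigma", {
  q <- seq(0.01, 0.3, by = 0.01)
  mk <- function(I) scattering_curve(q, I, rep(0.5, length(q)))
  # identical sample and buffer -> zero curve with positive sigma
  frames <- c(replicate(4, mk(rep(10, length(q))), simplify = FALSE),
              replicate(4, mk(rep(10, length(q))), simplify = FALSE))
  red <- reduce_sec_frames(frames, 1:4, 5:8)
  expect_equal(red$I, rep(0, length(q)))
  expect_true(all(red$sigma > 0))
  expect_equal(red$sigma, rep(sqrt(2 * 0.25 / 4), length(q)))
  # planted constant offset
  frames2 <- c(replicate(3, mk(rep(10, length(q))), simplify = FALSE),
               replicate(3, mk(rep(10 + 7, length(q))), simplify = FALSE))
  red2 <- reduce_sec_frames(frames2, 1:3, 4:6)
  expect_equal(red2$I, rep(7, length(q)))
  # disjointness and grid checks
  expect_error(reduce_sec_frames(frames, 1:4, 4:8), "overlap")
  frames3 <- frames
  frames3[[2]] <- scattering_curve(q + 0.001, rep(10, length(q)), 0.5)
  expect_error(reduce_sec_frames(frames3, 1:4, 5:8), "common q grid")
})

test_that("reduced noisy sphere frames recover the noiseless curve within 3 sigma", {
  sec <- gen_sec_frames("sphere", list(R = 50), n_sample = 10, n_buffer = 10,
                        seed = 21)
  red <- reduce_sec_frames(sec$frames, sec$buffer_ids, sec$sample_ids)
  z <- abs(red$I - sec$truth_curve$I) / red$sigma
  expect_gte(mean(z <= 3), 0.95)
  elu <- attr(red, "elution")
  expect_equal(nrow(elu), 20)
  # sample frames carry more total intensity than buffer frames
  expect_gt(min(elu$total[sec$sample_ids]), max(elu$total[sec$buffer_ids]))
})

test_that("Guinier fit is exact on a pure Gaussian and accurate on a sphere", {
  q <- default_q
  I <- 100 * exp(-q^2 * 30^2 / 3)
  g <- guinier_fit(scattering_curve(q, I, 0.01 * I))
  expect_equal(g$Rg, 30, tolerance = 1e-6)
  expect_equal(g$I0, 100, tolerance = 1e-6)
  expect_lte(g$qRg_range[2], 1.3)
  # analytic sphere R = 50: Rg within 2% of R sqrt(3/5)
  sph <- gen_curve("sphere", list(R = 50), noise_rel = 0)
  gs <- guinier_fit(sph$curve)
  expect_equal(gs$Rg, 50 * sqrt(3 / 5), tolerance = 0.02)
  # rising low-q cannot yield an Rg
  bad <- scattering_curve(q, 10 + q^2 * 100, rep(0.1, length(q)))
  gb <- guinier_fit(bad)
  expect_equal(gb$status, "failed")
  expect_null(gb$Rg)
})

test_that("Guinier recovery is unbiased over noisy replicates", {
  q <- default_q
  I <- 100 * exp(-q^2 * 30^2 / 3)
  rgs <- vapply(1:100, function(s) {
    set.seed(s)
    In <- I + rnorm(length(q), 0, 0.01 * I)
    guinier_fit(scattering_curve(q, In, 0.01 * I))$Rg
  }, numeric(1))
  expect_equal(mean(rgs), 30, tolerance = 0.005)
})

test_that("pr_ift recovers a planted two-point distance and the sphere p(r)", {
  q <- default_q
  # two point scatterers at distance d: I = 2(1 + sinc(qd))
  d <- 37
  I <- 2 * (1 + sin(q * d) / (q * d))
  cur <- scattering_curve(q, I, rep(0.002, length(q)))
  pr <- pr_ift(cur, dmax = 60, alpha = 1e-6, n_grid = 61)
  expect_equal(pr$r[which.max(pr$p)], d, tolerance = 1.5)  # within a bin
  # analytic sphere p(r), Pearson r > 0.99
  sph <- gen_curve("sphere", list(R = 50), noise_rel = 0.01, seed = 5)
  pr2 <- pr_ift(sph$curve, dmax = 100)
  expect_gt(cor(pr2$p, sphere_pr(pr2$r, 50)), 0.99)
  expect_true(all(pr2$p >= 0))
  expect_equal(pr2$p[1], 0)
  expect_equal(pr2$p[length(pr2$p)], 0)
  expect_error(pr_ift(sph$curve, 100, alpha = -1), "alpha")
})

test_that("I0 reconstructed from 4 pi integral of p(r) matches Guinier I0", {
  sph <- gen_curve("sphere", list(R = 50), noise_rel = 0)
  pr <- pr_ift(sph$curve, dmax = 100)
  g <- guinier_fit(sph$curve)
  dr <- pr$r[2] - pr$r[1]
  i0_pr <- 4 * pi * sum(pr$p) * dr
  expect_equal(i0_pr, g$I0, tolerance = 0.05)
})

test_that("estimate_dmax recovers sphere and dumbbell sizes from the scan rule", {
  sph <- gen_curve("sphere", list(R = 50), noise_rel = 0.01, seed = 2)
  es <- estimate_dmax(sph$curve, seq(60, 140, by = 5))
  expect_equal(es$status, "ok")
  expect_equal(es$dmax, 100, tolerance = 5.01)
  db <- gen_curve("dumbbell", list(R = 20, d = 80), noise_rel = 0.01, seed = 2)
  ed <- estimate_dmax(db$curve, seq(80, 160, by = 5))
  expect_equal(ed$dmax, 120, tolerance = 10.01)
  # round trip via a structure: dmax within one bin of the coordinate Dmax
  m <- make_fixture_structure("two_domain", n_res = 60, radius = 15, seed = 6)
  truth <- max_pairwise_distance(m)
  cur <- gen_curve("structure", list(model = m), noise_rel = 0.01, seed = 6)
  grid <- seq(ceiling(truth * 0.5 / 5) * 5, ceiling(truth * 1.5 / 5) * 5, 5)
  er <- estimate_dmax(cur$curve, grid)
  expect_equal(er$dmax, truth, tolerance = 7.5)
})

test_that("dimensionless Kratky transform has the Guinier-model closed form", {
  q <- default_q
  cur <- scattering_curve(q, 100 * exp(-q^2 * 30^2 / 3), 1)
  k <- dimensionless_kratky(cur, 30, 100)
  expect_equal(k$y, k$x^2 * exp(-k$x^2 / 3), tolerance = 1e-12)
  pk <- which.max(k$y)
  dx <- diff(k$x[1:2])
  expect_equal(k$x[pk], sqrt(3), tolerance = dx * 1.01)
  expect_equal(k$y[pk], 3 / exp(1), tolerance = 1e-3)
  # scale invariance
  cur2 <- scattering_curve(q, 5 * cur$I, 1)
  k2 <- dimensionless_kratky(cur2, 30, 500)
  expect_equal(k2$y, k$y)
})

test_that("Vc molecular weight matches its closed-form oracle and both calibrations behave", {
  # closed-form oracle: exact sphere integrals with the same constants
  vc_oracle <- function(R, qmax = 0.3) {
    f <- function(q) q * (3 * (sin(q * R) - q * R * cos(q * R)) / (q * R)^3)^2
    1 / stats::integrate(f, 0, qmax, subdivisions = 2000)$value
  }
  R <- 36
  mw_oracle <- (vc_oracle(R)^2 / (R * sqrt(3 / 5)) / 0.1231) / 1000
  cur <- gen_curve("sphere", list(R = R), noise_rel = 0.01, seed = 4)$curve
  g <- guinier_fit(cur)
  est <- mw_from_curve(cur, g)
  expect_equal(est$mw_kda, mw_oracle, tolerance = 0.05)
  expect_equal(est$method, "volume_of_correlation_power_law")
  # homogeneity: joint doubling of I and I0 leaves the relative estimate fixed
  cur2 <- scattering_curve(cur$q, 2 * cur$I, 2 * cur$sigma)
  g2 <- guinier_fit(cur2)
  est2 <- mw_from_curve(cur2, g2)
  expect_equal(est2$mw_kda, est$mw_kda, tolerance = 1e-6)
  # ... but doubles it under absolute-I0 calibration
  abs1 <- mw_from_curve(cur, g, calibration = "absolute", i0_per_kda = 1)
  abs2 <- mw_from_curve(cur2, g2, calibration = "absolute", i0_per_kda = 1)
  expect_equal(abs2$mw_kda / abs1$mw_kda, 2, tolerance = 1e-6)
})

test_that("pr_from_structure tallies pairwise distances like the brute force", {
  two <- point_model(rbind(c(0, 0, 0), c(10, 0, 0)))
  pr <- pr_from_structure(two, bin_width = 2)
  expect_equal(pr$dmax, 10)
  expect_equal(sum(pr$p > 0), 1)
  expect_equal(pr$r[pr$p > 0], 9)  # centre of the bin containing 10
  set.seed(13)
  xyz <- matrix(rnorm(300, sd = 15), ncol = 3)
  m <- point_model(xyz)
  pr2 <- pr_from_structure(m, bin_width = 2)
  d <- numeric(0)
  for (i in 1:99) for (j in (i + 1):100)
    d <- c(d, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
  h <- hist(d, breaks = seq(0, max(d) + 2, by = 2), plot = FALSE)
  expect_equal(pr2$p, h$density)
  expect_equal(pr2$dmax, max(d))
})

test_that("Debye curve matches one- and two-bead closed forms and the q->0 limit", {
  q <- default_q
  one <- point_model(matrix(0, 1, 3))
  expect_equal(debye_curve(one, q, f = 2)$I, rep(4, length(q)),
               tolerance = 1e-9)
  two <- point_model(rbind(c(0, 0, 0), c(12, 0, 0)))
  expect_equal(debye_curve(two, q, f = 1.5)$I,
               2 * 1.5^2 * (1 + sin(q * 12) / (q * 12)), tolerance = 1e-9)
  m <- make_fixture_structure("cloud", n_res = 30, seed = 8)
  qq <- c(1e-8, q)
  I <- debye_curve(m, qq, f = 0.7)$I
  expect_equal(I[1], (30 * 0.7)^2, tolerance = 1e-6)
})

test_that("multi-state fit identifies an exact candidate and recovers mixtures", {
  q <- default_q
  c1 <- gen_curve("sphere", list(R = 30), noise_rel = 0)$curve
  c2 <- gen_curve("sphere", list(R = 60), noise_rel = 0)$curve
  c3 <- gen_curve("dumbbell", list(R = 15, d = 60), noise_rel = 0)$curve
  # experiment equals candidate 2 exactly
  f <- multi_state_fit(scattering_curve(q, c2$I, 0.01 * c2$I),
                       list(c1, c2, c3), max_states = 3)
  expect_equal(f$states, 2)
  expect_equal(f$weights, 1)
  expect_lt(f$chi2, 1e-6)
  # 60/40 noisy mixture
  I_mix <- 0.6 * c1$I + 0.4 * c2$I
  set.seed(77)
  sig <- 0.01 * I_mix
  mix <- scattering_curve(q, I_mix + rnorm(length(q), 0, sig), sig)
  f2 <- multi_state_fit(mix, list(c1, c2, c3), max_states = 3)
  expect_setequal(f2$states, c(1, 2))
  w1 <- f2$weights[match(1, f2$states)]
  expect_equal(w1, 0.6, tolerance = 0.05)
  expect_equal(sum(f2$weights), 1, tolerance = 1e-9)
  # chi2 non-increasing in the allowed state count
  expect_true(all(diff(f2$by_size$chi2) <= 1e-9))
  # clamping
  expect_warning(multi_state_fit(mix, list(c1, c2), max_states = 5),
                 "clamped")
})

test_that("2-candidate weights agree with a dense simplex grid search", {
  q <- default_q
  c1 <- gen_curve("sphere", list(R = 30), noise_rel = 0)$curve
  c2 <- gen_curve("sphere", list(R = 60), noise_rel = 0)$curve
  I_mix <- 0.35 * c1$I + 0.65 * c2$I
  set.seed(5)
  sig <- 0.02 * I_mix
  mix <- scattering_curve(q, I_mix + rnorm(length(q), 0, sig), sig)
  f <- multi_state_fit(mix, list(c1, c2), max_states = 2)
  # oracle: grid over w in [0,1] step 0.01 with per-w optimal scale
  chi_at <- function(w) {
    model <- w * c1$I + (1 - w) * c2$I
    cc <- sum(mix$I * model / sig^2) / sum(model^2 / sig^2)
    sum((mix$I - cc * model)^2 / sig^2) / (length(q) - 1)
  }
  ws <- seq(0, 1, by = 0.01)
  w_star <- ws[which.min(vapply(ws, chi_at, numeric(1)))]
  expect_equal(f$weights[match(1, f$states)], w_star, tolerance = 0.01)
})

test_that("curve IO round-trips and flags probable 1/nm units", {
  cur <- gen_curve("sphere", list(R = 50), noise_rel = 0.01, seed = 3)$curve
  path <- withr::local_tempfile(fileext = ".dat")
  write_saxs_curve(cur, path)
  back <- read_saxs_curve(path)
  expect_equal(back$q, cur$q, tolerance = 1e-8)
  expect_equal(back$I, cur$I, tolerance = 1e-6)
  expect_equal(back$sigma, cur$sigma, tolerance = 1e-6)
  expect_warning(scattering_curve(seq(0.05, 3, by = 0.05),
                                  rep(1, 60), rep(0.1, 60)), "nm")
})
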