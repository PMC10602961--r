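test_that("vorticity of canonical fields matches analytic curls", {
  # rigid rotation: curl = 2 Omega (linear field, WLS gradients exact)
  Om <- 5
  f <- box_field(function(p) c(-Om * p[2], Om * p[1], 0))
  z <- vorticity(f, 1)
  expect_equal(max(abs(z[, 3] - 2 * Om)), 0, tolerance = 1e-9)
  expect_equal(max(abs(z[, 1:2])), 0, tolerance = 1e-9)

  # uniform flow: curl 0
  fu <- box_field(function(p) c(1, 0, 0))
  expect_lt(max(abs(vorticity(fu, 1))), 1e-10)

  # simple shear u = (k y, 0, 0): curl_z = -k, exact for a linear profile
  k <- 3
  fs <- box_field(function(p) c(k * p[2], 0, 0))
  expect_equal(vorticity(fs, 1)[, 3], rep(-k, nrow(fs$points)), tolerance = 1e-9)
})

test_that("kinetic energy density is the volume-weighted half-rho-V-squared", {
  f <- box_field(function(p) c(0.1, 0, 0))
  expect_equal(kinetic_energy(f, 1, region = "sac"), 0.5 * 1055 * 0.01,
               tolerance = 1e-12)
  f0 <- box_field(function(p) c(0, 0, 0))
  expect_equal(kinetic_energy(f0, 1, region = "sac"), 0)
})

test_that("Poiseuille kinetic energy approaches the 4/3 profile factor", {
  ph <- make_phantom(phantom_spec("poiseuille", nr = 16, ntheta = 24, nz = 4,
                                  nt = 3))
  # oracle: radial quadrature of (2 Vbar (1 - r^2/R^2))^2 over the disc
  R <- 0.002; Vb <- 0.25
  r <- seq(0, R, length.out = 4001)
  oracle <- 0.5 * 1055 * pracma::trapz(r, (2 * Vb * (1 - r^2 / R^2))^2 * 2 * pi * r) /
    (pi * R^2)
  expect_equal(oracle, 0.5 * 1055 * (4 / 3) * Vb^2, tolerance = 1e-6)
  expect_equal(kinetic_energy(ph$field, 1, region = c("sac", "parent")),
               oracle, tolerance = 0.02)
})

test_that("kinetic-energy ratio tracks the squared speed ratio", {
  ph <- make_phantom(phantom_spec("sac_on_pipe", speed_ratio = 0.5))
  expect_equal(ker(ph$field), 0.25, tolerance = 1e-9)
  ph2 <- make_phantom(phantom_spec("sac_on_pipe", speed_ratio = 1))
  expect_equal(ker(ph2$field), 1, tolerance = 1e-9)
})

test_that("OVI is zero for steady flow and one half for exact reversal", {
  steady <- make_phantom(phantom_spec("poiseuille", nt = 5))
  expect_equal(ovi(steady$field, region = c("sac", "parent")), 0,
               tolerance = 1e-12)
  rev <- make_phantom(phantom_spec("pulsatile_poiseuille", mean_speed = 0,
                                   amplitude = 0.3, nt = 17))
  expect_equal(ovi(rev$field, region = c("sac", "parent")), 0.5,
               tolerance = 1e-12)
})

test_that("OVI of an offset sinusoid matches dense quadrature and fades with offset", {
  # single 'cell' time series: u(t) = (c + sin(2 pi t), 0, 0)
  one_cell_field <- function(c0, nt = 201) {
    pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    cells <- tibble::tibble(volume = 1, region = "sac", points = list(1:4))
    surf <- tibble::tibble(area = 1, region = "sac", cx = 0, cy = 0, cz = -1,
                           nx = 0, ny = 0, nz = 1)
    times <- seq(0, 1, length.out = nt)
    vel <- lapply(times, function(t) {
      matrix(rep(c(c0 + sin(2 * pi * t), 0, 0), each = 4), 4, 3)
    })
    field_series(pts, cells, surf, times, vel,
                 wss = lapply(times, function(t) matrix(0, 1, 3)))
  }
  for (c0 in c(0.2, 1.5, 10)) {
    t <- seq(0, 1, length.out = 20001)
    f <- c0 + sin(2 * pi * t)
    oracle <- 0.5 * (1 - abs(pracma::trapz(t, f)) / pracma::trapz(t, abs(f)))
    expect_equal(ovi(one_cell_field(c0), region = "sac"), oracle,
                 tolerance = 2e-3)
  }
  # large steady offset drives OVI to zero
  expect_lt(ovi(one_cell_field(10), region = "sac"), 1e-3)
})

test_that("TAWSS averages the WSS magnitude over the cycle", {
  mk <- function(wss_fun, nt = 101) {
    pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    cells <- tibble::tibble(volume = 1, region = "sac", points = list(1:4))
    surf <- tibble::tibble(area = c(1, 3), region = "sac",
                           cx = c(0, 1), cy = 0, cz = -1,
                           nx = 0, ny = 0, nz = 1)
    times <- seq(0, 1, length.out = nt)
    vel <- lapply(times, function(t) matrix(0, 4, 3))
    wss <- lapply(times, function(t) cbind(wss_fun(t), 0, 0))
    field_series(pts, cells, surf, times, vel, wss)
  }
  # constant magnitude
  expect_equal(tawss(mk(function(t) c(2, 2)), region = "sac"), 2,
               tolerance = 1e-12)
  # |sin| scaled so the cycle mean is 1 (mean of |sin| is 2/pi)
  f <- mk(function(t) rep(abs(sin(2 * pi * t)) * pi / 2, 2))
  expect_equal(tawss(f, region = "sac"), 1, tolerance = 0.01)
  # area weighting: cells at 1 Pa (area 1) and 5 Pa (area 3)
  f2 <- mk(function(t) c(1, 5))
  expect_equal(tawss(f2, region = "sac"), (1 * 1 + 3 * 5) / 4, tolerance = 1e-12)
})

test_that("steady Poiseuille wall shear matches the 4 mu V / R closed form", {
  ph <- make_phantom(phantom_spec("poiseuille"))
  expect_equal(tawss(ph$field, region = c("sac", "parent")), 2.0,
               tolerance = 1e-9) # 4 * 0.004 * 0.25 / 0.002
})

test_that("low shear area reproduces the hand-computed threshold example", {
  # parent: equal-area cells at 2 and 4 Pa (mean 3, SD 1, boundary 2);
  # sac: equal areas at 1 and 5 Pa -> half the area below the boundary
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  cells <- tibble::tibble(volume = 1, region = "sac", points = list(1:4))
  surf <- tibble::tibble(area = rep(1, 4), region = c("parent", "parent", "sac", "sac"),
                         cx = 0, cy = 0, cz = -1, nx = 0, ny = 0, nz = 1)
  times <- c(0, 1)
  vel <- lapply(times, function(t) matrix(0, 4, 3))
  wss <- lapply(times, function(t) cbind(c(2, 4, 1, 5), 0, 0))
  f <- field_series(pts, cells, surf, times, vel, wss)
  expect_equal(lsa(f), 0.5)
  # extremes
  wss_hi <- lapply(times, function(t) cbind(c(2, 4, 9, 9), 0, 0))
  expect_equal(lsa(field_series(pts, cells, surf, times, vel, wss_hi)), 0)
  wss_lo <- lapply(times, function(t) cbind(c(2, 4, 0.1, 0.2), 0, 0))
  expect_equal(lsa(field_series(pts, cells, surf, times, vel, wss_lo)), 1)
  # normalized TAWSS on the same construction: sac mean 3 / parent mean 3
  expect_equal(ntawss(f), 1, tolerance = 1e-12)
})

test_that("nTAWSS is the sac-to-parent TAWSS ratio", {
  ph <- make_phantom(phantom_spec("sac_on_pipe", wss_ratio = 0.25))
  expect_equal(ntawss(ph$field), 0.25, tolerance = 1e-9)
})

test_that("wall shear derived from velocity is exact for linear profiles", {
  # linear shear above a z = 0 wall: u = (k z, 0, 0), tau = mu k
  k <- 7
  f <- box_field(function(p) c(k * p[3], 0, 0))
  f <- wss_from_velocity(f)
  expect_equal(f$wss[[1]][1, 1], f$mu * k, tolerance = 1e-12)
  # uniform flow parallel to the wall has no normal gradient: zero WSS
  f0 <- box_field(function(p) c(1, 0, 0))
  f0 <- wss_from_velocity(f0)
  expect_lt(max(abs(f0$wss[[1]])), 1e-12)
})

test_that("wall shear from a Poiseuille velocity field approaches 4 mu V / R", {
  ph <- make_phantom(phantom_spec("poiseuille", nr = 12, ntheta = 24, nz = 4,
                                  nt = 3))
  fld <- ph$field
  fld$wss <- NULL
  fld <- wss_from_velocity(fld)
  expect_equal(tawss(fld, region = c("sac", "parent")), 2.0, tolerance = 0.05)
})

test_that("the metrics report composes the suite and scales correctly", {
  ph <- make_phantom(phantom_spec("poiseuille"))
  rep1 <- metrics_report(ph$field)
  expect_equal(rep1$OVI, 0, tolerance = 1e-12)
  expect_equal(rep1$KER, 1, tolerance = 1e-9)
  expect_equal(rep1$nTAWSS, 1, tolerance = 1e-9)
  expect_true(rep1$LSA %in% c(0, 1))
  # doubling rho doubles KE and leaves KER unchanged
  spec2 <- phantom_spec("poiseuille", rho = 2110)
  rep2 <- metrics_report(make_phantom(spec2)$field)
  expect_equal(rep2$KE / rep1$KE, 2, tolerance = 1e-9)
  expect_equal(rep2$KER, rep1$KER, tolerance = 1e-9)
  # tidy/glance accessors
  expect_equal(nrow(tidy(rep1)), 8)
  expect_equal(glance(rep1)$TAWSS, rep1$TAWSS)
})

test_that("volume metrics are invariant under rigid rotation of geometry and field", {
  ph <- make_phantom(phantom_spec("poiseuille", nr = 6, ntheta = 12, nz = 4, nt = 3))
  f <- ph$field
  th <- 0.7
  Q <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  srot <- f$surface
  cc <- as.matrix(f$surface[, c("cx", "cy", "cz")]) %*% t(Q)
  nn <- as.matrix(f$surface[, c("nx", "ny", "nz")]) %*% t(Q)
  srot[, c("cx", "cy", "cz")] <- cc
  srot[, c("nx", "ny", "nz")] <- nn
  g <- field_series(f$points %*% t(Q), f$cells, srot, f$times,
                    lapply(f$velocity, function(v) v %*% t(Q)),
                    lapply(f$wss, function(w) w %*% t(Q)),
                    rho = f$rho, mu = f$mu)
  for (fun in list(ker, ntawss)) {
    expect_equal(fun(g), fun(f), tolerance = 1e-9)
  }
  expect_equal(tawss(g, region = "sac"), tawss(f, region = "sac"),
               tolerance = 1e-9)
  expect_equal(kinetic_energy(g, 1), kinetic_energy(f, 1), tolerance = 1e-9)
})
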