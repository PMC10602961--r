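test_that("Murray split reproduces symmetry and the square law", {
  expect_equal(murray_split(c(a = 1, b = 1), n = 2)$fraction, c(0.5, 0.5))
  expect_equal(murray_split(c(a = 1, b = 2), n = 2)$fraction, c(0.2, 0.8))
  expect_error(murray_split(numeric(0)), "empty")
  expect_error(murray_split(c(a = -1, b = 1)), "positive")
})

test_that("cube-law fractions follow from square-law fractions via inferred diameters", {
  # diameters inferred as sqrt of the published square-law fractions
  f2 <- c(o1 = 0.236, o2 = 0.182, o3 = 0.581)
  res <- murray_split(sqrt(f2), n = 3)
  expect_equal(round(res$fraction[3], 3), 0.697)
  expect_equal(round(res$fraction[1], 3), 0.181)
})

test_that("hierarchical split equals global Murray at a single junction", {
  tr <- make_tree(c(0.5, 1)) # diameters 1 and 2
  bc4 <- bifurcation_split(tr)
  expect_equal(bc4$fraction, c(0.2, 0.8), tolerance = 1e-9)
  bc2 <- murray_split(c(o1 = 1, o2 = 2), n = 2)
  expect_equal(bc4$fraction, bc2$fraction, tolerance = 1e-9)
})

test_that("two-level tree splits multiply along the path and differ from global Murray", {
  tr <- two_level_tree()
  bc4 <- bifurcation_split(tr)
  expect_equal(bc4$fraction[match(c("A1", "A2", "B"), bc4$outlet)],
               c(0.4, 0.4, 0.2), tolerance = 1e-6)
  # global Murray on the equal leaf diameters gives thirds: not equivalent
  bc2 <- murray_split(c(A1 = 1, A2 = 1, B = 1), n = 2)
  expect_equal(bc2$fraction, rep(1 / 3, 3))
  expect_gt(max(abs(bc4$fraction[match(c("A1", "A2", "B"), bc4$outlet)] -
                    bc2$fraction)), 0.05)
})

test_that("area split matches squared-diameter split for circular sections", {
  tr <- make_tree(c(0.7, 1, 1.4))
  expect_equal(area_split(tr, n_rays = 720)$fraction,
               bifurcation_split(tr, n_rays = 720)$fraction, tolerance = 1e-4)
})

test_that("elliptical sections split by true area", {
  # ellipse semi-axes (2, 1) vs circle r = 1 at one junction: areas 2pi vs pi
  th <- 2 * pi * (0:255) / 256
  ell <- cbind(2 * cos(th), sin(th), 0)
  seg <- tibble::tibble(
    parent = c("inlet", "j", "j"),
    child = c("j", "e", "c"),
    length = c(10, 10, 10),
    radius = c(1.5, NA, 1),
    section = list(NULL,
                   cross_section(c(0, 0, 0), c(0, 0, 1), ell),
                   circle_section(1, n = 256))
  )
  res <- area_split(vessel_tree(seg), n_rays = 720)
  expect_equal(res$fraction[res$outlet == "e"], 2 / 3, tolerance = 1e-3)
  expect_equal(res$fraction[res$outlet == "c"], 1 / 3, tolerance = 1e-3)
})

test_that("uniform dilation of all boundaries leaves area-split fractions unchanged", {
  base <- make_tree(c(0.8, 1.1, 1.6))
  spec <- ensemble_spec(base, n_members = 2, radius_noise_sd = 0,
                        factor_range = c(1.1, 1.1), roughness_amp = 0, seed = 7)
  ens <- make_ensemble(spec)
  f0 <- area_split(ens[[1]], n_rays = 128)$fraction
  f1 <- area_split(ens[[2]], n_rays = 128)$fraction
  expect_equal(f1, f0, tolerance = 1e-9)
  # but the member's equivalent diameters scale by the dilation factor
  a0 <- polygon_area_raytrace(ens[[1]]$segments$section[[2]], 256)
  a1 <- polygon_area_raytrace(ens[[2]]$segments$section[[2]], 256)
  expect_equal(equivalent_diameter(a1) / equivalent_diameter(a0), 1.1,
               tolerance = 1e-9)
})

test_that("zero-pressure network splits by Poiseuille conductance", {
  # symmetric Y
  expect_equal(zero_pressure_network_split(make_tree(c(1, 1)))$fraction,
               c(0.5, 0.5), tolerance = 1e-12)
  # radii 1 vs 2, equal lengths: G ~ R^4 gives 1:16
  seg <- tibble::tibble(parent = c("inlet", "j", "j"), child = c("j", "a", "b"),
                        length = c(10, 10, 10), radius = c(2, 1, 2))
  res <- zero_pressure_network_split(vessel_tree(seg))
  expect_equal(res$fraction, c(1 / 17, 16 / 17), tolerance = 1e-12)
})

test_that("three-outlet network agrees with an independent dense linear solve", {
  seg <- tibble::tibble(
    parent = c("inlet", "j1", "j1", "j2", "j2"),
    child = c("j1", "o1", "j2", "o2", "o3"),
    length = c(12, 7, 9, 5, 11),
    radius = c(1.6, 0.8, 1.2, 0.7, 1.0)
  )
  tr <- vessel_tree(seg)
  res <- zero_pressure_network_split(tr)

  # oracle: assemble the full nodal admittance system independently
  mu <- 0.004
  G <- pi * seg$radius^4 / (8 * mu * seg$length)
  nodes <- c("inlet", "j1", "j2", "o1", "o2", "o3")
  Y <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(seg))) {
    p <- seg$parent[k]; ch <- seg$child[k]
    Y[p, p] <- Y[p, p] + G[k]; Y[ch, ch] <- Y[ch, ch] + G[k]
    Y[p, ch] <- Y[p, ch] - G[k]; Y[ch, p] <- Y[ch, p] - G[k]
  }
  free <- c("inlet", "j1", "j2")
  rhs <- c(1, 0, 0)
  p_free <- solve(Y[free, free], rhs)
  q <- c(G[2] * p_free["j1"], G[4] * p_free["j2"], G[5] * p_free["j2"])
  expect_equal(res$fraction, as.numeric(q / sum(q)), tolerance = 1e-10)
})

test_that("all five strategies conserve flow and coincide on symmetric circular trees", {
  tr <- make_tree(c(1, 1))
  all5 <- compute_all_splits(tr)
  sums <- dplyr::summarise(dplyr::group_by(all5, method),
                           s = sum(fraction), .groups = "drop")
  expect_equal(sums$s, rep(1, 5), tolerance = 1e-9)
  expect_equal(all5$fraction, rep(0.5, 10), tolerance = 1e-6)
})

test_that("circular sections make the area and squared-diameter columns agree", {
  tr <- make_tree(c(0.6, 1, 1.3, 0.9))
  all5 <- compute_all_splits(tr, n_rays = 256)
  bc4 <- all5$fraction[all5$method == "bc4"]
  bc5 <- all5$fraction[all5$method == "bc5"]
  expect_equal(bc5, bc4, tolerance = 1e-4)
})

test_that("splits are permutation-equivariant and monotone in diameter", {
  d <- c(a = 0.9, b = 1.4, c = 2.1)
  f <- murray_split(d, n = 3)
  fp <- murray_split(d[c(3, 1, 2)], n = 3)
  expect_equal(fp$fraction[match(names(d), fp$outlet)], f$fraction)
  # enlarging one outlet strictly increases its fraction
  for (n in c(2, 3)) {
    f1 <- murray_split(c(a = 1, b = 1.5), n = n)$fraction[1]
    f2 <- murray_split(c(a = 1.2, b = 1.5), n = n)$fraction[1]
    expect_gt(f2, f1)
  }
})

test_that("random trees conserve flow and bc4 equals bc2 at one junction", {
  set.seed(42)
  for (rep in 1:25) {
    k <- sample(2:5, 1)
    radii <- stats::runif(k, 0.4, 2)
    tr <- make_tree(radii, section_points = 64)
    for (res in list(bifurcation_split(tr), area_split(tr, n_rays = 64),
                     zero_pressure_network_split(tr))) {
      expect_equal(sum(res$fraction), 1, tolerance = 1e-9)
      expect_true(all(res$fraction >= 0))
    }
  }
  # one-junction trees: hierarchical and global square law are identical
  for (rep in 1:10) {
    radii <- stats::runif(2, 0.4, 2)
    tr <- make_tree(radii, section_points = 64)
    bc4 <- bifurcation_split(tr)
    bc2 <- murray_split(stats::setNames(2 * radii, tr$outlets), n = 2)
    expect_equal(bc4$fraction, bc2$fraction, tolerance = 1e-4)
  }
})
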