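#' Synthetic vessel trees, segmentation ensembles and flow phantoms
#'
#' Everything the analysis pipeline consumes can be generated here: small
#' bifurcating vessel trees with circular cross-sections, "segmentation
#' ensembles" that perturb those trees the way independent manual lumen
#' segmentations of one vessel differ (global over/under-segmentation,
#' radius noise, smooth boundary roughness), and analytic pulsatile flow
#' phantoms whose metric values are known in closed form. The phantoms stand
#' in for 3D CFD fields, which this package deliberately does not compute.
#'
#' @name synthetic_data
NULL

#' Deterministic bifurcating vessel tree with given outlet radii
#'
#' Builds a binary tree whose leaves carry circular cross-sections with the
#' requested radii; internal segment radii follow the Murray-type closure
#' `r_parent^3 = sum(r_child^3)`. Segment lengths are ten radii, a typical
#' branch length-to-caliber ratio. The outlet order matches the order of
#' `radii`.
#'
#' @param radii Outlet radii (mm), length >= 2.
#' @param length_factor Segment length as a multiple of its radius.
#' @param section_points Vertices per circular boundary polyline.
#' @return A [vessel_tree()].
#' @examples
#' make_tree(c(1, 2, 3))
#' @export
make_tree <- function(radii, length_factor = 10, section_points = 96) {
  if (length(radii) < 2) stop("make_tree: need at least 2 outlet radii")
  if (any(radii <= 0)) stop("make_tree: radii must be positive")
  counter <- new.env(parent = emptyenv())
  counter$j <- 0L
  segs <- list()
  # returns the node id and closure radius of the subtree over radii[lo..hi]
  build <- function(lo, hi) {
    if (lo == hi) {
      return(list(id = sprintf("o%d", lo), radius = radii[lo]))
    }
    counter$j <- counter$j + 1L
    id <- sprintf("j%d", counter$j)
    mid <- (lo + hi) %/% 2
    left <- build(lo, mid)
    right <- build(mid + 1, hi)
    for (ch in list(left, right)) {
      segs[[length(segs) + 1L]] <<- tibble::tibble(
        parent = id, child = ch$id,
        length = length_factor * ch$radius, radius = ch$radius,
        section = list(circle_section(ch$radius, n = section_points))
      )
    }
    list(id = id, radius = (left$radius^3 + right$radius^3)^(1 / 3))
  }
  top <- build(1, length(radii))
  trunk <- tibble::tibble(
    parent = "inlet", child = top$id,
    length = length_factor * top$radius, radius = top$radius,
    section = list(circle_section(top$radius, n = section_points))
  )
  seg <- dplyr::bind_rows(c(list(trunk), segs))
  # order rows so outlets appear in the order of `radii`
  seg <- seg[order(match(seg$child, c(top$id, sprintf("o%d", seq_along(radii)))),
                   na.last = FALSE), ]
  vessel_tree(seg)
}

#' Segmentation-ensemble specification
#'
#' @param base A [vessel_tree()], the unperturbed reference lumen.
#' @param n_members Number of ensemble members (member 1 is the base).
#' @param radius_noise_sd Relative SD of the per-segment radius jitter.
#' @param factor_range Multiplicative over/under-segmentation factor range;
#'   each member draws one global scale uniformly from it.
#' @param roughness_amp Relative amplitude of the smooth radial boundary
#'   roughness (low-order Fourier modes 2-6, the "uneven spots" of manual
#'   segmentations).
#' @param seed Integer seed; the ensemble is a single reproducible stream.
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(base, n_members = 10, radius_noise_sd = 0.03,
                          factor_range = c(0.92, 1.1), roughness_amp = 0.02,
                          seed = 1) {
  stopifnot(inherits(base, "vessel_tree"), n_members >= 1,
            radius_noise_sd >= 0, roughness_amp >= 0,
            length(factor_range) == 2, all(factor_range > 0))
  structure(
    list(base = base, n_members = as.integer(n_members),
         radius_noise_sd = radius_noise_sd,
         factor_range = sort(factor_range),
         roughness_amp = roughness_amp, seed = as.integer(seed)),
    class = "ensemble_spec"
  )
}

# perturb one cross-section: global scale, radius factor, Fourier roughness
.perturb_section <- function(sec, scale, rough_amp) {
  b2 <- .section_local_2d(sec)
  th <- atan2(b2[, 2], b2[, 1])
  r <- sqrt(rowSums(b2^2))
  modes <- 2:6
  a <- stats::rnorm(length(modes), 0, rough_amp / sqrt(2 * length(modes)))
  b <- stats::rnorm(length(modes), 0, rough_amp / sqrt(2 * length(modes)))
  bump <- as.numeric(cos(outer(th, modes)) %*% a + sin(outer(th, modes)) %*% b)
  r_new <- r * scale * (1 + bump)
  basis <- .plane_basis(sec$normal)
  pts <- outer(r_new * cos(th), basis$e1) + outer(r_new * sin(th), basis$e2)
  cross_section(sec$anchor, sec$normal,
                sweep(pts, 2, sec$anchor, `+`),
                planar_tol = sec$planar_tol * max(scale, 1) + 1e-9)
}

#' Generate a segmentation ensemble
#'
#' Returns `n_members` perturbed copies of the base tree. Member 1 is the
#' unperturbed base. Each further member draws a global over/under-
#' segmentation factor from `factor_range`, a per-segment radius factor
#' `(1 + N(0, radius_noise_sd))`, and smooth radial roughness on every
#' boundary polyline. Deterministic for a fixed seed.
#'
#' @param spec An [ensemble_spec()].
#' @return A list of [vessel_tree()] objects, length `n_members`.
#' @export
make_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  members <- vector("list", spec$n_members)
  members[[1]] <- spec$base
  if (spec$n_members >= 2) {
    for (m in 2:spec$n_members) {
      tr <- spec$base
      scale <- stats::runif(1, spec$factor_range[1], spec$factor_range[2])
      seg <- tr$segments
      for (k in seq_len(nrow(seg))) {
        rf <- 1 + stats::rnorm(1, 0, spec$radius_noise_sd)
        rf <- max(rf, 0.2) # keep lumens open
        if (!is.na(seg$radius[k])) seg$radius[k] <- seg$radius[k] * scale * rf
        if (!is.null(seg$section[[k]])) {
          seg$section[[k]] <- .perturb_section(seg$section[[k]], scale * rf,
                                               spec$roughness_amp)
        }
      }
      tr$segments <- seg
      members[[m]] <- tr
    }
  }
  members
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Analytic flow-phantom specification
#'
#' @param kind One of `"poiseuille"`, `"rigid_rotation"`,
#'   `"pulsatile_poiseuille"`, `"sac_on_pipe"`.
#' @param radius Pipe radius (m), default 0.002 (a 4 mm artery).
#' @param length Pipe length (m).
#' @param mean_speed Bulk (cross-section mean) speed V-bar (m/s).
#' @param omega Rotation rate (1/s), rigid-rotation kind only.
#' @param amplitude Pulsatile amplitude of V-bar(t) (m/s).
#' @param period Cycle period T (s).
#' @param speed_ratio Sac-to-parent speed ratio (sac_on_pipe).
#' @param wss_ratio Sac-to-parent WSS ratio (sac_on_pipe).
#' @param nr,ntheta,nz Radial, azimuthal, axial mesh resolution.
#' @param nt Time samples per cycle (inclusive of both ends).
#' @param rho,mu Blood density (kg/m^3) and viscosity (Pa s).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(kind = c("poiseuille", "rigid_rotation",
                                  "pulsatile_poiseuille", "sac_on_pipe"),
                         radius = 0.002, length = 0.02, mean_speed = 0.25,
                         omega = 5, amplitude = 0.25, period = 1,
                         speed_ratio = 0.5, wss_ratio = 0.5,
                         nr = 8, ntheta = 16, nz = 8, nt = 17,
                         rho = 1055, mu = 0.004) {
  kind <- match.arg(kind)
  stopifnot(radius > 0, length > 0, period > 0, nr >= 3, ntheta >= 8, nz >= 2)
  if (kind %in% c("pulsatile_poiseuille") && nt < 8) {
    stop("phantom_spec: pulsatile kinds need >= 8 time samples")
  }
  if (nt < 2) stop("phantom_spec: need >= 2 time samples")
  structure(
    list(kind = kind, radius = radius, length = length,
         mean_speed = mean_speed, omega = omega, amplitude = amplitude,
         period = period, speed_ratio = speed_ratio, wss_ratio = wss_ratio,
         nr = as.integer(nr), ntheta = as.integer(ntheta),
         nz = as.integer(nz), nt = as.integer(nt), rho = rho, mu = mu),
    class = "phantom_spec"
  )
}

# Structured cylindrical tube mesh stored as unstructured cells.
# Regions: z < length/2 -> "parent", z >= length/2 -> "sac" (mirrored halves).
.tube_mesh <- function(R, L, nr, ntheta, nz, split_regions = TRUE) {
  dz <- L / nz
  zs <- seq(0, L, length.out = nz + 1)
  th <- 2 * pi * (seq_len(ntheta) - 1) / ntheta
  rs <- R * (0:nr) / nr
  # axis point per z level, then rings of nr x ntheta points
  coords <- matrix(0, (nz + 1) * (1 + nr * ntheta), 3)
  idx <- array(0L, dim = c(nr + 1, ntheta, nz + 1))
  p <- 0L
  axis_id <- integer(nz + 1)
  for (k in 0:nz) {
    p <- p + 1L; coords[p, ] <- c(0, 0, zs[k + 1]); axis_id[k + 1] <- p
    for (i in 1:nr) for (j in 1:ntheta) {
      p <- p + 1L
      coords[p, ] <- c(rs[i + 1] * cos(th[j]), rs[i + 1] * sin(th[j]), zs[k + 1])
      idx[i + 1, j, k + 1] <- p
    }
  }
  cells <- vector("list", nz * nr * ntheta)
  vol <- numeric(length(cells)); creg <- character(length(cells))
  c_ <- 0L
  for (k in 1:nz) for (i in 1:nr) for (j in 1:ntheta) {
    jn <- j %% ntheta + 1
    ids <- if (i == 1) {
      c(axis_id[k], axis_id[k + 1],
        idx[2, j, k], idx[2, jn, k], idx[2, j, k + 1], idx[2, jn, k + 1])
    } else {
      c(idx[i, j, k], idx[i, jn, k], idx[i + 1, j, k], idx[i + 1, jn, k],
        idx[i, j, k + 1], idx[i, jn, k + 1], idx[i + 1, j, k + 1], idx[i + 1, jn, k + 1])
    }
    c_ <- c_ + 1L
    cells[[c_]] <- ids
    vol[c_] <- pi * (rs[i + 1]^2 - rs[i]^2) / ntheta * dz
    zc <- (zs[k] + zs[k + 1]) / 2
    creg[c_] <- if (!split_regions || zc >= L / 2) "sac" else "parent"
  }
  # wall cells at r = R
  nsurf <- nz * ntheta
  sarea <- numeric(nsurf); sreg <- character(nsurf)
  sc <- matrix(0, nsurf, 3); sn <- matrix(0, nsurf, 3)
  s <- 0L
  dth <- 2 * pi / ntheta
  for (k in 1:nz) for (j in 1:ntheta) {
    s <- s + 1L
    thc <- th[j] + dth / 2
    zc <- (zs[k] + zs[k + 1]) / 2
    sc[s, ] <- c(R * cos(thc), R * sin(thc), zc)
    sn[s, ] <- c(-cos(thc), -sin(thc), 0)
    sarea[s] <- R * dth * dz
    sreg[s] <- if (!split_regions || zc >= L / 2) "sac" else "parent"
  }
  list(
    points = coords[seq_len(p), , drop = FALSE],
    cells = tibble::tibble(volume = vol, region = creg, points = cells),
    surface = tibble::tibble(area = sarea, region = sreg,
                             cx = sc[, 1], cy = sc[, 2], cz = sc[, 3],
                             nx = sn[, 1], ny = sn[, 2], nz = sn[, 3])
  )
}

# Spherical sac mesh (radial shells x angles), offset from the pipe.
.sphere_mesh <- function(Rs, center, nr, ntheta, nphi) {
  rs <- Rs * (0:nr) / nr
  th <- 2 * pi * (seq_len(ntheta) - 1) / ntheta
  ph <- pi * (0:nphi) / nphi
  # centre + radial shells (points duplicate at the poles; the gradient
  # operators drop zero-distance neighbors, so this is harmless)
  npts <- 1 + nr * ntheta * (nphi + 1)
  pts <- matrix(0, npts, 3)
  pts[1, ] <- center
  p <- 1L
  idx <- array(0L, dim = c(nr + 1, ntheta, nphi + 1))
  for (i in 1:nr) for (j in 1:ntheta) for (k in 0:nphi) {
    p <- p + 1L
    pts[p, ] <- center + rs[i + 1] * c(sin(ph[k + 1]) * cos(th[j]),
                                       sin(ph[k + 1]) * sin(th[j]),
                                       cos(ph[k + 1]))
    idx[i + 1, j, k + 1] <- p
  }
  cells <- list(); vol <- numeric(); c_ <- 0L
  for (i in 1:nr) for (j in 1:ntheta) for (k in 1:nphi) {
    jn <- j %% ntheta + 1
    inner <- if (i == 1) 1L else c(idx[i, j, k], idx[i, jn, k],
                                   idx[i, j, k + 1], idx[i, jn, k + 1])
    ids <- unique(c(inner, idx[i + 1, j, k], idx[i + 1, jn, k],
                    idx[i + 1, j, k + 1], idx[i + 1, jn, k + 1]))
    c_ <- c_ + 1L
    cells[[c_]] <- ids
    vol[c_] <- (rs[i + 1]^3 - rs[i]^3) / 3 * (2 * pi / ntheta) *
      (cos(ph[k]) - cos(ph[k + 1]))
  }
  # surface patches on the outer shell
  sarea <- numeric(); sc <- list(); sn <- list(); s <- 0L
  for (j in 1:ntheta) for (k in 1:nphi) {
    s <- s + 1L
    thc <- th[j] + pi / ntheta
    phc <- (ph[k] + ph[k + 1]) / 2
    dirn <- c(sin(phc) * cos(thc), sin(phc) * sin(thc), cos(phc))
    sc[[s]] <- center + Rs * dirn
    sn[[s]] <- -dirn
    sarea[s] <- Rs^2 * (2 * pi / ntheta) * (cos(ph[k]) - cos(ph[k + 1]))
  }
  scm <- do.call(rbind, sc); snm <- do.call(rbind, sn)
  list(
    points = pts,
    cells = tibble::tibble(volume = vol, region = "sac", points = cells),
    surface = tibble::tibble(area = sarea, region = "sac",
                             cx = scm[, 1], cy = scm[, 2], cz = scm[, 3],
                             nx = snm[, 1], ny = snm[, 2], nz = snm[, 3])
  )
}

# closed-form OVI of a 1D signal c + a sin(2 pi t / T) by dense quadrature
.ovi_1d <- function(c0, a, period, n = 20001) {
  t <- seq(0, period, length.out = n)
  f <- c0 + a * sin(2 * pi * t / period)
  num <- abs(pracma::trapz(t, f))
  den <- pracma::trapz(t, abs(f))
  if (den == 0) 0 else 0.5 * (1 - num / den)
}

#' Generate an analytic flow phantom with known metric values
#'
#' Builds a small structured mesh, samples an exactly known velocity (and
#' analytic WSS) field on it, and returns the field together with a
#' prescription record of the closed-form metric values the field should
#' produce:
#'
#' * `poiseuille` — steady parabolic pipe flow, axial bulk speed V-bar;
#'   prescribed TAWSS `4 mu Vbar / R`, OVI 0, KER 1 and nTAWSS 1 (the sac
#'   and parent regions are mirrored halves of the pipe).
#' * `rigid_rotation` — solid-body rotation at rate Omega; prescribed
#'   vorticity `2 Omega`, zero WSS.
#' * `pulsatile_poiseuille` — parabolic profile scaled by
#'   `Vbar(t) = mean_speed + amplitude sin(2 pi t / T)`; with zero mean the
#'   flow reverses exactly and OVI is 0.5.
#' * `sac_on_pipe` — plug-flow pipe (parent) with a spherical sac whose
#'   uniform speed is `speed_ratio` times the parent speed and whose wall
#'   WSS is `wss_ratio` times the parent value; prescribed
#'   `KER = speed_ratio^2`, `nTAWSS = wss_ratio`.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom` with elements `field` (a
#'   [field_series()], regions `"sac"` and `"parent"`) and `prescription`
#'   (one-row tibble of closed-form metric values; `NA` where the kind does
#'   not pin the metric down).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  R <- spec$radius; L <- spec$length; Vb <- spec$mean_speed
  times <- seq(0, spec$period, length.out = spec$nt)
  presc <- tibble::tibble(mean_V = NA_real_, mean_vorticity = NA_real_,
                          KE = NA_real_, KER = NA_real_, OVI = NA_real_,
                          TAWSS = NA_real_, nTAWSS = NA_real_, LSA = NA_real_)
  if (spec$kind == "sac_on_pipe") {
    pipe <- .tube_mesh(R, L, spec$nr, spec$ntheta, spec$nz, split_regions = FALSE)
    pipe$cells$region <- "parent"
    pipe$surface$region <- "parent"
    sac <- .sphere_mesh(R, c(0, 3 * R, L / 2), max(3, spec$nr %/% 2),
                        spec$ntheta, max(4, spec$nz %/% 2))
    off <- nrow(pipe$points)
    sac$cells$points <- lapply(sac$cells$points, function(x) x + off)
    points <- rbind(pipe$points, sac$points)
    cells <- dplyr::bind_rows(pipe$cells, sac$cells)
    surface <- dplyr::bind_rows(pipe$surface, sac$surface)
    vsac <- spec$speed_ratio * Vb
    vel <- lapply(times, function(t) {
      v <- matrix(0, nrow(points), 3)
      v[seq_len(off), 3] <- Vb           # plug flow in the pipe
      v[(off + 1):nrow(points), 3] <- vsac # uniform sac speed
      v
    })
    tau_p <- 4 * spec$mu * Vb / R
    wss <- lapply(times, function(t) {
      w <- matrix(0, nrow(surface), 3)
      w[surface$region == "parent", 3] <- -tau_p
      w[surface$region == "sac", 3] <- -spec$wss_ratio * tau_p
      w
    })
    field <- field_series(points, cells, surface, times, vel, wss,
                          rho = spec$rho, mu = spec$mu)
    presc$mean_V <- vsac
    presc$KE <- 0.5 * spec$rho * vsac^2
    presc$KER <- spec$speed_ratio^2
    presc$OVI <- 0
    presc$TAWSS <- spec$wss_ratio * tau_p
    presc$nTAWSS <- spec$wss_ratio
    presc$LSA <- if (spec$wss_ratio < 1) 1 else 0
    presc$mean_vorticity <- 0
    return(structure(list(field = field, prescription = presc, spec = spec),
                     class = "phantom"))
  }
  mesh <- .tube_mesh(R, L, spec$nr, spec$ntheta, spec$nz)
  r2 <- mesh$points[, 1]^2 + mesh$points[, 2]^2
  if (spec$kind == "poiseuille") {
    prof <- 2 * Vb * (1 - r2 / R^2)
    vel <- lapply(times, function(t) cbind(0, 0, prof))
    tau <- 4 * spec$mu * Vb / R
    wss <- lapply(times, function(t) {
      w <- matrix(0, nrow(mesh$surface), 3); w[, 3] <- -tau; w
    })
    presc$mean_V <- Vb
    presc$mean_vorticity <- 8 * Vb / (3 * R)
    presc$KE <- 0.5 * spec$rho * (4 / 3) * Vb^2
    presc$KER <- 1; presc$OVI <- 0
    presc$TAWSS <- tau; presc$nTAWSS <- 1
  } else if (spec$kind == "rigid_rotation") {
    Om <- spec$omega
    vel <- lapply(times, function(t) {
      cbind(-Om * mesh$points[, 2], Om * mesh$points[, 1], 0)
    })
    wss <- lapply(times, function(t) matrix(0, nrow(mesh$surface), 3))
    presc$mean_V <- Om * 2 * R / 3
    presc$mean_vorticity <- 2 * Om
    presc$KE <- 0.5 * spec$rho * Om^2 * R^2 / 2
    presc$KER <- 1; presc$OVI <- 0; presc$TAWSS <- 0
  } else { # pulsatile_poiseuille
    prof <- 2 * (1 - r2 / R^2)
    vbar_t <- Vb + spec$amplitude * sin(2 * pi * times / spec$period)
    vel <- lapply(vbar_t, function(vb) cbind(0, 0, prof * vb))
    wss <- lapply(vbar_t, function(vb) {
      w <- matrix(0, nrow(mesh$surface), 3)
      w[, 3] <- -4 * spec$mu * vb / R
      w
    })
    o <- .ovi_1d(Vb, spec$amplitude, spec$period)
    presc$OVI <- o
    presc$KER <- 1
    t_dense <- seq(0, spec$period, length.out = 20001)
    f <- Vb + spec$amplitude * sin(2 * pi * t_dense / spec$period)
    presc$mean_V <- pracma::trapz(t_dense, abs(f)) / spec$period
    presc$TAWSS <- 4 * spec$mu / R * pracma::trapz(t_dense, abs(f)) / spec$period
    presc$nTAWSS <- 1
  }
  field <- field_series(mesh$points, mesh$cells, mesh$surface, times, vel, wss,
                        rho = spec$rho, mu = spec$mu)
  structure(list(field = field, prescription = presc, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> kind '%s'\n", x$spec$kind))
  print(x$field)
  cat("prescription:\n")
  print(as.data.frame(x$prescription))
  invisible(x)
}
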