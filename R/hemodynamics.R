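#' Aneurysmal flow and shear metrics
#'
#' The metric suite evaluated on a [field_series()]: vorticity, kinetic
#' energy and the sac-to-parent kinetic-energy ratio, the oscillatory
#' velocity index, time-averaged wall shear stress and its normalized and
#' low-shear-area derivatives. Volume quantities are evaluated at cell
#' centres (mean of the cell's point samples) and averaged with volume
#' weights; surface quantities are area-weighted. Temporal means use the
#' trapezoidal rule over the supplied cycle.
#'
#' @name hemodynamics
NULL

# Per-point weighted-least-squares gradient operators, cached on the field.
# For point i with neighbors j (points sharing a cell), the operator P_i maps
# neighbor differences (f_j - f_i) to the gradient. A quadratic fit is used
# where the neighborhood supports it (exact gradients for quadratic fields,
# e.g. a parabolic pipe profile); sparse neighborhoods fall back to a linear
# fit, which is still exact for linear fields.
.gradient_ops <- function(field) {
  cache <- field$cache
  if (!is.null(cache$grad_ops)) return(cache$grad_ops)
  n <- nrow(field$points)
  nbr <- vector("list", n)
  for (k in seq_len(nrow(field$cells))) {
    ids <- field$cells$points[[k]]
    for (i in ids) nbr[[i]] <- c(nbr[[i]], ids)
  }
  ops <- vector("list", n)
  scale2 <- sum(apply(field$points, 2, stats::var))
  tol2 <- 1e-24 * max(scale2, 1e-30)
  for (i in seq_len(n)) {
    js <- setdiff(unique(nbr[[i]]), i)
    if (length(js) >= 1) {
      A0 <- sweep(field$points[js, , drop = FALSE], 2, field$points[i, ])
      js <- js[rowSums(A0^2) > tol2] # drop coincident (duplicated) points
    }
    if (length(js) < 3) {
      stop(sprintf("degenerate neighborhood at point %d (%d neighbors)", i, length(js)))
    }
    A <- sweep(field$points[js, , drop = FALSE], 2, field$points[i, ])
    d <- sqrt(rowSums(A^2))
    h <- mean(d) # local length scale, conditions the quadratic columns
    S <- A / h
    w <- 1 / d
    P <- NULL
    if (length(js) >= 12) {
      X <- cbind(S, S[, 1]^2, S[, 2]^2, S[, 3]^2,
                 S[, 1] * S[, 2], S[, 1] * S[, 3], S[, 2] * S[, 3])
      Xw <- X * w
      M <- crossprod(Xw)
      if (rcond(M) > 1e-10) {
        P <- solve(M, t(Xw * w))[1:3, , drop = FALSE] / h
      }
    }
    if (is.null(P)) {
      Aw <- S * w
      M <- crossprod(Aw)
      if (rcond(M) < 1e-12) {
        stop(sprintf("degenerate (near-coplanar) neighborhood at point %d", i))
      }
      P <- solve(M, t(Aw * w)) / h
    }
    ops[[i]] <- list(js = js, P = P)
  }
  cache$grad_ops <- ops
  ops
}

#' Vorticity field at one time sample
#'
#' Computes the curl of the velocity field at every mesh point,
#' `(zeta_x, zeta_y, zeta_z) = (dw/dy - dv/dz, du/dz - dw/dx, dv/dx - du/dy)`,
#' using weighted least-squares gradient reconstruction over point
#' neighborhoods (inverse-distance weights; exact for linear velocity
#' fields, so a rigid rotation with rate Omega yields exactly 2 Omega).
#'
#' @param field A [field_series()].
#' @param t_index Time sample index.
#' @return N x 3 matrix of vorticity vectors (1/s).
#' @export
vorticity <- function(field, t_index = 1) {
  stopifnot(inherits(field, "field_series"))
  ops <- .gradient_ops(field)
  v <- field$velocity[[t_index]]
  out <- matrix(0, nrow(field$points), 3)
  for (i in seq_along(ops)) {
    o <- ops[[i]]
    dv <- sweep(v[o$js, , drop = FALSE], 2, v[i, ])
    J <- o$P %*% dv # J[a, b] = d v_b / d x_a
    out[i, ] <- c(J[2, 3] - J[3, 2], J[3, 1] - J[1, 3], J[1, 2] - J[2, 1])
  }
  out
}

# volume-weighted mean over region cells of a per-cell scalar
.vol_mean <- function(field, region_idx, cell_values) {
  w <- field$cells$volume[region_idx]
  sum(w * cell_values[region_idx]) / sum(w)
}

#' Volume-averaged kinetic energy density in a region
#'
#' `KE = 1/2 rho V^2`, evaluated per cell from the cell-averaged velocity
#' and volume-averaged over the region (J/m^3).
#'
#' @param field A [field_series()].
#' @param t_index Time sample index.
#' @param region Region label(s) of the volume cells, default `"sac"`.
#' @return Scalar kinetic energy density (J/m^3).
#' @export
kinetic_energy <- function(field, t_index = 1, region = "sac") {
  idx <- .region_cells(field, region)
  cv <- .cell_velocity(field, t_index)
  ke <- 0.5 * field$rho * rowSums(cv^2)
  .vol_mean(field, idx, ke)
}

#' Kinetic-energy ratio between sac and parent vessel
#'
#' Cycle-averaged kinetic energy in the aneurysm sac divided by the
#' cycle-averaged kinetic energy in the parent vessel; dimensionless.
#'
#' @param field A [field_series()].
#' @param sac,parent Region labels.
#' @return Scalar KER.
#' @export
ker <- function(field, sac = "sac", parent = "parent") {
  nt <- length(field$times)
  ke_s <- vapply(seq_len(nt), kinetic_energy, numeric(1),
                 field = field, region = sac)
  ke_p <- vapply(seq_len(nt), kinetic_energy, numeric(1),
                 field = field, region = parent)
  denom <- .time_mean(field$times, ke_p)
  if (denom <= 0) stop("ker: parent-vessel kinetic energy is zero")
  .time_mean(field$times, ke_s) / denom
}

#' Oscillatory velocity index of a region
#'
#' Per cell, `OVI = 1/2 (1 - |mean velocity vector| / mean speed)` with the
#' temporal means taken by the trapezoidal rule over one cycle; the region
#' value is the volume-weighted mean. OVI is 0 for steady flow and reaches
#' 0.5 when the velocity reverses so that the vector integral cancels; the
#' bound arises from vector cancellation, no clamping is applied. Cells with
#' identically zero velocity over the cycle take OVI = 0 (trivially steady).
#'
#' @param field A [field_series()].
#' @param region Region label(s), default `"sac"`.
#' @return Scalar OVI in \[0, 0.5\].
#' @export
ovi <- function(field, region = "sac") {
  idx <- .region_cells(field, region)
  nt <- length(field$times)
  cvs <- lapply(seq_len(nt), .cell_velocity, field = field)
  nc <- nrow(field$cells)
  comp <- vapply(1:3, function(a) {
    m <- matrix(vapply(cvs, function(cv) cv[, a], numeric(nc)), nrow = nc)
    apply(m, 1, function(row) pracma::trapz(field$times, row))
  }, numeric(nc))
  comp <- matrix(comp, nrow = nc)
  num <- sqrt(rowSums(comp^2))
  spd <- matrix(vapply(cvs, function(cv) sqrt(rowSums(cv^2)), numeric(nc)),
                nrow = nc)
  den <- apply(spd, 1, function(row) pracma::trapz(field$times, row))
  o <- ifelse(den > 0, 0.5 * (1 - num / den), 0)
  .vol_mean(field, idx, o)
}

# per-surface-cell TAWSS (Pa): (1/T) int |WSS| dt by trapezoid
.tawss_cells <- function(field) {
  if (is.null(field$wss)) {
    stop("no WSS on this field series; supply wss or run wss_from_velocity()")
  }
  mag <- vapply(field$wss, function(m) sqrt(rowSums(m^2)),
                numeric(nrow(field$surface)))
  if (nrow(field$surface) == 1) mag <- matrix(mag, nrow = 1)
  apply(mag, 1, function(row) .time_mean(field$times, row))
}

#' Time-averaged wall shear stress
#'
#' Per wall cell, the cycle mean of the wall-shear-stress magnitude
#' (trapezoidal rule); with a region label, the area-weighted region mean.
#'
#' @param field A [field_series()] carrying WSS.
#' @param region Region label(s); `NULL` returns the per-cell tibble.
#' @return Scalar TAWSS (Pa), or a tibble (`cell`, `region`, `area`,
#'   `tawss`) when `region` is `NULL`.
#' @export
tawss <- function(field, region = "sac") {
  tc <- .tawss_cells(field)
  if (is.null(region)) {
    return(tibble::tibble(
      cell = seq_len(nrow(field$surface)),
      region = field$surface$region,
      area = field$surface$area,
      tawss = tc
    ))
  }
  idx <- .region_surface(field, region)
  w <- field$surface$area[idx]
  sum(w * tc[idx]) / sum(w)
}

#' Low shear area of the aneurysm sac
#'
#' Fraction of the sac wall area exposed to TAWSS below the parent-vessel
#' threshold `mean(TAWSS_parent) - SD(TAWSS_parent)`, both area-weighted
#' (the SD in its population form, consistent with the weighted mean).
#'
#' @param field A [field_series()] carrying WSS.
#' @param sac,parent Surface region labels.
#' @return Scalar LSA in \[0, 1\].
#' @export
lsa <- function(field, sac = "sac", parent = "parent") {
  tc <- .tawss_cells(field)
  pidx <- .region_surface(field, parent)
  sidx <- .region_surface(field, sac)
  wp <- field$surface$area[pidx]
  m <- sum(wp * tc[pidx]) / sum(wp)
  s <- sqrt(sum(wp * (tc[pidx] - m)^2) / sum(wp))
  boundary <- m - s
  ws <- field$surface$area[sidx]
  sum(ws[tc[sidx] < boundary]) / sum(ws)
}

#' Normalized TAWSS
#'
#' Area-weighted sac TAWSS divided by area-weighted parent-vessel TAWSS.
#'
#' @inheritParams lsa
#' @return Scalar nTAWSS (dimensionless).
#' @export
ntawss <- function(field, sac = "sac", parent = "parent") {
  denom <- tawss(field, region = parent)
  if (denom <= 0) stop("ntawss: parent-vessel TAWSS is zero")
  tawss(field, region = sac) / denom
}

#' Derive wall shear stress from the velocity field
#'
#' For each wall cell, fits the tangential velocity of the nearest mesh
#' points against their distance `d` along the cell's inward normal and
#' takes `tau = mu * (d u_t / d n)` as the slope (one-sided, since only
#' interior points exist). The fit is exact for linear near-wall profiles,
#' gives zero for a gradient-free uniform field, and approaches the
#' Poiseuille closed form `4 mu Vbar / R` on pipe meshes as the near-wall
#' resolution grows.
#'
#' @param field A [field_series()].
#' @param region Restrict to these surface regions (`NULL` = all).
#' @param k_neighbors Number of nearest points used in each fit.
#' @return The field with its `wss` slot filled (cells outside `region`
#'   get zero).
#' @export
wss_from_velocity <- function(field, region = NULL, k_neighbors = 8) {
  stopifnot(inherits(field, "field_series"))
  surf <- field$surface
  sel <- if (is.null(region)) seq_len(nrow(surf)) else .region_surface(field, region)
  nrm <- as.matrix(surf[, c("nx", "ny", "nz")])
  ctr <- as.matrix(surf[, c("cx", "cy", "cz")])
  ops <- vector("list", nrow(surf))
  for (k in sel) {
    rel <- sweep(field$points, 2, ctr[k, ])
    d <- as.numeric(rel %*% nrm[k, ])
    dist <- sqrt(rowSums(rel^2))
    cand <- order(dist)[seq_len(min(k_neighbors, length(dist)))]
    if (diff(range(d[cand])) < 1e-12 * max(dist[cand], 1e-30)) {
      cand <- seq_along(d) # flat neighborhood: widen to all points
    }
    if (diff(range(d[cand])) <= 0) {
      stop(sprintf("wall cell %d has no interior point along its normal", k))
    }
    # slope operator of the simple linear regression u_t ~ a + b d
    dd <- d[cand] - mean(d[cand])
    ops[[k]] <- list(js = cand, w = dd / sum(dd^2))
  }
  wss <- lapply(seq_along(field$times), function(t) {
    out <- matrix(0, nrow(surf), 3)
    v <- field$velocity[[t]]
    for (k in sel) {
      o <- ops[[k]]
      slope <- as.numeric(o$w %*% v[o$js, , drop = FALSE]) # d u / d n
      ut <- slope - sum(slope * nrm[k, ]) * nrm[k, ]
      out[k, ] <- field$mu * ut
    }
    out
  })
  field$wss <- wss
  field
}

#' Assemble the full per-aneurysm metrics report
#'
#' Computes the cycle means of sac velocity magnitude, vorticity magnitude
#' and kinetic energy, the sac-to-parent kinetic-energy ratio, the
#' oscillatory velocity index, and the shear metrics TAWSS, nTAWSS and LSA.
#' Volume metrics are volume-weighted over the sac cells; shear metrics are
#' area-weighted over the sac wall. If the field carries no WSS it is
#' derived from the velocity via [wss_from_velocity()].
#'
#' @param field A [field_series()].
#' @param sac,parent Region labels used for both volume and surface cells.
#' @return A one-row `metrics_report` tibble with columns `mean_V` (m/s),
#'   `mean_vorticity` (1/s), `KE` (J/m^3), `KER`, `OVI`, `TAWSS` (Pa),
#'   `nTAWSS`, `LSA`.
#' @export
metrics_report <- function(field, sac = "sac", parent = "parent") {
  stopifnot(inherits(field, "field_series"))
  if (is.null(field$wss)) field <- wss_from_velocity(field)
  nt <- length(field$times)
  idx <- .region_cells(field, sac)
  speed_t <- vapply(seq_len(nt), function(t) {
    cv <- .cell_velocity(field, t)
    .vol_mean(field, idx, sqrt(rowSums(cv^2)))
  }, numeric(1))
  vort_t <- vapply(seq_len(nt), function(t) {
    zmag <- sqrt(rowSums(vorticity(field, t)^2))
    cz <- rowsum(zmag[field$cache$cell_idx], field$cache$cell_grp) / field$cache$cell_n
    .vol_mean(field, idx, cz[, 1])
  }, numeric(1))
  ke_t <- vapply(seq_len(nt), kinetic_energy, numeric(1),
                 field = field, region = sac)
  parent_tawss <- tawss(field, region = parent)
  out <- tibble::tibble(
    mean_V = .time_mean(field$times, speed_t),
    mean_vorticity = .time_mean(field$times, vort_t),
    KE = .time_mean(field$times, ke_t),
    KER = ker(field, sac, parent),
    OVI = ovi(field, sac),
    TAWSS = tawss(field, region = sac),
    nTAWSS = if (parent_tawss > 0) tawss(field, region = sac) / parent_tawss else NA_real_,
    LSA = lsa(field, sac, parent)
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' Tidy a metrics report into long parameter/value form
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `value`.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(unclass(x)),
                      dplyr::everything(),
                      names_to = "parameter", values_to = "value")
}

#' @rdname tidy.metrics_report
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) tibble::as_tibble(unclass(x))
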