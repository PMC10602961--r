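#' Time-resolved velocity / wall-shear-stress field on a labeled mesh
#'
#' Container for one cardiac cycle of a flow solution sampled on an
#' unstructured mesh. Velocity is point-centred; wall shear stress and the
#' region labels are cell-centred, the way solver exports naturally store
#' them. All physics is SI: metres, seconds, Pascal, kg/m^3.
#'
#' @param points Numeric N x 3 matrix of point coordinates (m).
#' @param cells Data frame of volume cells with columns `volume` (m^3),
#'   `region` (character label, e.g. `"sac"`, `"parent"`), and `points`
#'   (list column of integer point indices).
#' @param surface Data frame of wall cells with columns `area` (m^2),
#'   `region`, `cx`, `cy`, `cz` (cell centre, m) and `nx`, `ny`, `nz`
#'   (unit normal pointing into the lumen).
#' @param times Strictly increasing sample times (s) spanning one cycle.
#' @param velocity List (one entry per time) of N x 3 velocity matrices (m/s).
#' @param wss Optional list (one entry per time) of M x 3 wall-shear-stress
#'   matrices (Pa) on the surface cells; `NULL` if WSS is to be derived from
#'   the velocity field ([wss_from_velocity()]).
#' @param rho Blood density (kg/m^3), default 1055.
#' @param mu Dynamic viscosity (Pa s), default 0.004.
#' @return An object of class `field_series`.
#' @export
field_series <- function(points, cells, surface, times, velocity, wss = NULL,
                         rho = 1055, mu = 0.004) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  cells <- tibble::as_tibble(cells)
  surface <- tibble::as_tibble(surface)
  stopifnot(all(c("volume", "region", "points") %in% names(cells)))
  stopifnot(all(c("area", "region", "cx", "cy", "cz", "nx", "ny", "nz") %in% names(surface)))
  times <- as.numeric(times)
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("field_series: need >= 2 strictly increasing time samples")
  }
  if (length(velocity) != length(times)) {
    stop("field_series: one velocity matrix per time sample required")
  }
  for (k in seq_along(velocity)) {
    velocity[[k]] <- as.matrix(velocity[[k]])
    if (nrow(velocity[[k]]) != nrow(points) || ncol(velocity[[k]]) != 3) {
      stop(sprintf("field_series: velocity[[%d]] is not N x 3", k))
    }
    if (any(!is.finite(velocity[[k]]))) {
      stop(sprintf("field_series: non-finite velocity at time index %d", k))
    }
  }
  if (!is.null(wss)) {
    if (length(wss) != length(times)) {
      stop("field_series: one wss matrix per time sample required")
    }
    wss <- lapply(wss, function(m) {
      m <- as.matrix(m)
      if (nrow(m) != nrow(surface) || ncol(m) != 3) {
        stop("field_series: wss matrices must be M x 3 over the surface cells")
      }
      m
    })
  }
  if (any(cells$volume <= 0)) stop("field_series: non-positive cell volume")
  if (any(surface$area <= 0)) stop("field_series: non-positive surface cell area")
  structure(
    list(points = points, cells = cells, surface = surface, times = times,
         velocity = velocity, wss = wss, rho = rho, mu = mu,
         cache = new.env(parent = emptyenv())),
    class = "field_series"
  )
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf(
    "<field_series> %d points, %d cells, %d wall cells, %d time samples over %.3g s%s\n",
    nrow(x$points), nrow(x$cells), nrow(x$surface), length(x$times),
    diff(range(x$times)), if (is.null(x$wss)) " (no WSS)" else ""
  ))
  cat(sprintf("  regions: %s\n",
              paste(sort(unique(c(x$cells$region, x$surface$region))), collapse = ", ")))
  invisible(x)
}

.region_cells <- function(field, region) {
  idx <- which(field$cells$region %in% region)
  if (length(idx) == 0) stop(sprintf("no volume cells in region '%s'",
                                     paste(region, collapse = ",")))
  idx
}

.region_surface <- function(field, region) {
  idx <- which(field$surface$region %in% region)
  if (length(idx) == 0) stop(sprintf("no surface cells in region '%s'",
                                     paste(region, collapse = ",")))
  idx
}

# cell-averaged velocity (C x 3) at one time index; cached index structure
.cell_velocity <- function(field, t_index) {
  cache <- field$cache
  if (is.null(cache$cell_idx)) {
    cache$cell_idx <- unlist(field$cells$points, use.names = FALSE)
    cache$cell_grp <- rep(seq_len(nrow(field$cells)),
                          lengths(field$cells$points))
    cache$cell_n <- lengths(field$cells$points)
  }
  v <- field$velocity[[t_index]]
  rowsum(v[cache$cell_idx, , drop = FALSE], cache$cell_grp) / cache$cell_n
}

# temporal mean over the supplied cycle: (1/T) * trapz
.time_mean <- function(times, values) {
  pracma::trapz(times, values) / (times[length(times)] - times[1])
}
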