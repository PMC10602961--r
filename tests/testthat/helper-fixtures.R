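# Small geometry and field builders shared across tests.

# two-level asymmetric tree: root -> A (D = 2) and B (D = 1);
# A -> A1 (D = 1), A2 (D = 1). Hand split: A1 = A2 = 0.4, B = 0.2.
two_level_tree <- function(section_points = 256) {
  seg <- tibble::tibble(
    parent = c("inlet", "j1", "j1", "A", "A"),
    child = c("j1", "A", "B", "A1", "A2"),
    length = c(10, 10, 10, 5, 5),
    radius = c(1.2, 1, 0.5, 0.5, 0.5),
    section = list(
      circle_section(1.2, n = section_points),
      circle_section(1, n = section_points),
      circle_section(0.5, n = section_points),
      circle_section(0.5, n = section_points),
      circle_section(0.5, n = section_points)
    )
  )
  vessel_tree(seg)
}

# tiny Cartesian box mesh with an analytic velocity field; used for
# gradient/vorticity tests where the field is a function of (x, y, z)
box_field <- function(velocity_fun, n = 4, times = c(0, 1), L = 1) {
  xs <- seq(0, L, length.out = n + 1)
  # expand.grid varies x fastest, matching the first array dimension below
  pts <- as.matrix(expand.grid(x = xs, y = xs, z = xs)[, c("x", "y", "z")])
  idx <- array(seq_len(nrow(pts)), dim = c(n + 1, n + 1, n + 1))
  cells <- list(); c_ <- 0L
  for (k in 1:n) for (j in 1:n) for (i in 1:n) {
    c_ <- c_ + 1L
    cells[[c_]] <- c(idx[i, j, k], idx[i + 1, j, k], idx[i, j + 1, k],
                     idx[i + 1, j + 1, k], idx[i, j, k + 1], idx[i + 1, j, k + 1],
                     idx[i, j + 1, k + 1], idx[i + 1, j + 1, k + 1])
  }
  vol <- rep((L / n)^3, length(cells))
  cell_tbl <- tibble::tibble(volume = vol, region = "sac", points = cells)
  surf <- tibble::tibble(area = 1, region = "sac",
                         cx = L / 2, cy = L / 2, cz = 0,
                         nx = 0, ny = 0, nz = 1)
  vel <- lapply(times, function(t) t(apply(pts, 1, velocity_fun)))
  field_series(pts, cell_tbl, surf, times, vel,
               wss = lapply(times, function(t) matrix(0, 1, 3)))
}
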