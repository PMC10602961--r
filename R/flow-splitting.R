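#' Flow-splitting strategies for vessel outlets
#'
#' Five strategies assign each outlet its fraction of the total outflow:
#'
#' * **bc1** — surrogate for the zero-pressure condition: a 0D Poiseuille
#'   resistance network is solved with unit inflow and zero pressure at every
#'   outlet ([zero_pressure_network_split()]). This is a lumped-parameter
#'   stand-in for the outflow a 3D solve with constant outlet pressure would
#'   produce; it is not a splitting rule imposed a priori.
#' * **bc2 / bc3** — Murray's law applied globally to the outlet diameters
#'   with exponents n = 2 and n = 3 ([murray_split()]).
#' * **bc4** — Murray's law with n = 2 applied locally at every bifurcation
#'   using circular (equivalent) diameters ([bifurcation_split()]).
#' * **bc5** — the same hierarchical traversal, with each local split
#'   proportional to the raytraced anatomical cross-section area
#'   ([area_split()]). Because it carries the most geometric information,
#'   bc5 is the usual reference in comparisons.
#'
#' All functions return a **split result**: a tibble with columns `method`,
#' `outlet`, `fraction`, fractions summing to one.
#'
#' @name flow_splitting
NULL

.new_split_result <- function(method, outlets, fractions) {
  out <- tibble::tibble(
    method = method,
    outlet = as.character(outlets),
    fraction = as.numeric(fractions)
  )
  class(out) <- c("split_result", class(out))
  out
}

#' Murray-law flow split over outlet diameters
#'
#' Assigns outlet fractions proportional to the n-th power of outlet
#' diameter: `fraction_i = D_i^n / sum_j D_j^n`. This is the normalized form
#' of the proportionality between vessel flow rate and diameter; n = 2 and
#' n = 3 are the conventional square and cube laws.
#'
#' @param diameters Named positive numeric vector of outlet diameters (mm);
#'   names are outlet ids.
#' @param n Positive exponent (2 or 3 in common use).
#' @param method Label stored in the result; defaults to `"bc2"`/`"bc3"` for
#'   n = 2/3 and `"murray"` otherwise.
#' @return A split-result tibble (`method`, `outlet`, `fraction`).
#' @examples
#' murray_split(c(a = 1, b = 2), n = 2)
#' @export
murray_split <- function(diameters, n = 2, method = NULL) {
  if (length(diameters) == 0) stop("murray_split: empty diameter set")
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    stop("murray_split: all diameters must be positive and finite")
  }
  if (!is.numeric(n) || n <= 0) stop("murray_split: exponent n must be positive")
  ids <- names(diameters)
  if (is.null(ids)) ids <- paste0("o", seq_along(diameters))
  if (is.null(method)) {
    method <- if (n == 2) "bc2" else if (n == 3) "bc3" else "murray"
  }
  w <- as.numeric(diameters)^n
  .new_split_result(method, ids, w / sum(w))
}

# Shared hierarchical traversal: at each junction, split the incoming
# fraction among children proportionally to weight_fun(child); an outlet's
# global fraction is the product of local fractions along its root path.
# Single-child junctions pass the fraction through unchanged.
.hierarchical_split <- function(tree, weight_fun, method) {
  viol <- validate_tree(tree)
  if (length(viol)) {
    stop(sprintf("invalid vessel tree: %s", paste(viol, collapse = "; ")))
  }
  frac <- stats::setNames(numeric(length(tree$outlets)), tree$outlets)
  recurse <- function(node, f) {
    kids <- .children_of(tree, node)
    if (length(kids) == 0) {
      frac[[node]] <<- f
      return(invisible())
    }
    if (length(kids) == 1) {
      recurse(kids, f)
      return(invisible())
    }
    w <- vapply(kids, weight_fun, numeric(1))
    if (any(!is.finite(w)) || any(w <= 0)) {
      stop(sprintf("non-positive local weight at junction '%s'", node))
    }
    w <- w / sum(w)
    for (i in seq_along(kids)) recurse(kids[i], f * w[i])
    invisible()
  }
  recurse(tree$inlet, 1)
  .new_split_result(method, tree$outlets, frac[tree$outlets])
}

#' Hierarchical per-bifurcation Murray split (circular cross-sections)
#'
#' Applies the square (or general exponent) diameter law locally at each
#' branch junction: among the children of a junction, local fractions are
#' proportional to `D^exponent`; an outlet's global fraction is the product
#' of the local fractions along its root-to-outlet path. Junctions with more
#' than two children split jointly in proportion to all children's
#' `D^exponent` at once.
#'
#' @param tree A [vessel_tree()]; every child segment at every junction needs
#'   a diameter (radius or cross-section).
#' @param exponent Local law exponent, default 2.
#' @param n_rays Rays used when a segment's diameter must be derived from an
#'   anatomical cross-section.
#' @return A split-result tibble with method `"bc4"` (or `"bc4_n<exponent>"`).
#' @examples
#' bifurcation_split(make_tree(c(1, 2)))
#' @export
bifurcation_split <- function(tree, exponent = 2, n_rays = 64) {
  method <- if (exponent == 2) "bc4" else sprintf("bc4_n%g", exponent)
  .hierarchical_split(
    tree,
    function(child) .segment_diameter(tree, child, n_rays)^exponent,
    method
  )
}

#' Hierarchical split on raytraced anatomical cross-section areas
#'
#' Same traversal as [bifurcation_split()], but each local split is
#' proportional to the true luminal area of the child segment's
#' cross-section, estimated by [polygon_area_raytrace()] (`Q1/Q2 = A1/A2`).
#' Segments carrying only a circular radius contribute `pi r^2` exactly.
#'
#' @inheritParams bifurcation_split
#' @return A split-result tibble with method `"bc5"`.
#' @export
area_split <- function(tree, n_rays = 64) {
  .hierarchical_split(
    tree,
    function(child) .segment_area(tree, child, n_rays),
    "bc5"
  )
}

#' Blood and network properties for the 0D resistance surrogate
#'
#' @param viscosity Dynamic viscosity (Pa s); default 0.004, the Newtonian
#'   blood value.
#' @param density Density (kg/m^3); default 1055. Unused by the resistance
#'   network (Poiseuille flow splits are density-free) but carried for
#'   completeness.
#' @return A `network_properties` list.
#' @export
network_properties <- function(viscosity = 0.004, density = 1055) {
  stopifnot(viscosity > 0, density > 0)
  structure(list(viscosity = viscosity, density = density),
            class = "network_properties")
}

#' Zero-pressure outflow surrogate: 0D Poiseuille resistance network
#'
#' Emulates the flow split a constant-pressure (zero-pressure) outlet
#' condition produces, without a 3D solve: each segment becomes a Poiseuille
#' conductance `G = pi R^4 / (8 mu L)`, a unit inflow is injected at the
#' inlet, all outlets are held at pressure zero, and the linear nodal system
#' is solved for the internal pressures. Outlet fractions are the flows
#' through the outlet segments. This is a lumped surrogate: it reproduces
#' the character of a zero-pressure condition (flows governed by resistance
#' to ground), not any particular 3D result.
#'
#' @param tree A [vessel_tree()] with positive lengths and radii on all
#'   segments (radii fall back to section equivalent radii).
#' @param props A [network_properties()].
#' @param n_rays Rays for section-derived radii.
#' @return A split-result tibble with method `"bc1"`.
#' @examples
#' zero_pressure_network_split(make_tree(c(1, 1)))
#' @export
zero_pressure_network_split <- function(tree, props = network_properties(),
                                        n_rays = 64) {
  viol <- validate_tree(tree)
  if (length(viol)) {
    stop(sprintf("invalid vessel tree: %s", paste(viol, collapse = "; ")))
  }
  seg <- tree$segments
  radii <- vapply(seg$child, function(ch) .segment_diameter(tree, ch, n_rays) / 2,
                  numeric(1))
  if (any(radii <= 0)) {
    stop(sprintf("zero or negative radius on segment into '%s': singular network",
                 paste(seg$child[radii <= 0], collapse = ", ")))
  }
  # conductances; mm and Pa s — units cancel in the fractions
  G <- pi * radii^4 / (8 * props$viscosity * seg$length)
  free <- setdiff(tree$nodes, tree$outlets) # unknown pressures
  idx <- stats::setNames(seq_along(free), free)
  A <- matrix(0, length(free), length(free))
  b <- numeric(length(free))
  b[idx[[tree$inlet]]] <- 1 # unit inflow
  for (k in seq_len(nrow(seg))) {
    p <- seg$parent[k]; c_ <- seg$child[k]; g <- G[k]
    A[idx[[p]], idx[[p]]] <- A[idx[[p]], idx[[p]]] + g
    if (c_ %in% free) {
      A[idx[[c_]], idx[[c_]]] <- A[idx[[c_]], idx[[c_]]] + g
      A[idx[[p]], idx[[c_]]] <- A[idx[[p]], idx[[c_]]] - g
      A[idx[[c_]], idx[[p]]] <- A[idx[[c_]], idx[[p]]] - g
    }
  }
  pressures <- tryCatch(solve(A, b), error = function(e) {
    stop(sprintf("singular 0D network: %s", conditionMessage(e)))
  })
  names(pressures) <- free
  flows <- vapply(tree$outlets, function(o) {
    k <- match(o, seg$child)
    G[k] * pressures[[seg$parent[k]]] # outlet pressure is 0
  }, numeric(1))
  .new_split_result("bc1", tree$outlets, flows / sum(flows))
}

#' Compute all five flow-splitting strategies for one tree
#'
#' Runs bc1 (0D zero-pressure surrogate), bc2/bc3 (global Murray on outlet
#' equivalent diameters), bc4 (hierarchical squared-diameter) and bc5
#' (hierarchical raytraced area) and stacks the results in the tree's stable
#' outlet order.
#'
#' @inheritParams zero_pressure_network_split
#' @return A split-result tibble with one row per (method, outlet).
#' @examples
#' compute_all_splits(make_tree(c(1, 1.5, 2)))
#' @export
compute_all_splits <- function(tree, props = network_properties(), n_rays = 64) {
  outlet_d <- vapply(tree$outlets, function(o) .segment_diameter(tree, o, n_rays),
                     numeric(1))
  res <- dplyr::bind_rows(
    zero_pressure_network_split(tree, props, n_rays),
    murray_split(outlet_d, n = 2, method = "bc2"),
    murray_split(outlet_d, n = 3, method = "bc3"),
    bifurcation_split(tree, exponent = 2, n_rays = n_rays),
    area_split(tree, n_rays = n_rays)
  )
  class(res) <- c("split_result", class(tibble::tibble()))
  res
}

#' Plot outlet flow fractions per method
#'
#' @param object A split-result tibble (from any splitting function or
#'   [compute_all_splits()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot split_result
#' @export
autoplot.split_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$outlet, levels = unique(.data$outlet)),
    y = .data$fraction, fill = .data$method
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::labs(x = "outlet", y = "flow fraction", fill = "method") +
    ggplot2::theme_minimal()
}
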