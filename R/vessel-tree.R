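#' Vessel tree
#'
#' A rooted directed tree of vessel segments with one inlet and at least two
#' outlets. Each segment (directed parent -> child edge) carries a length
#' (mm) and either a circular radius (mm) or a full [cross_section()]; the
#' child node names the segment. Outlets are ordered by first appearance in
#' `segments`, matching the stable "Outlet 1..k" ordering used when tabulating
#' splitting values.
#'
#' @param segments A data frame with columns `parent`, `child` (character
#'   node ids), `length` (mm), and either `radius` (mm, `NA` allowed when a
#'   section is given) and/or `section` (list column of `cross_section`
#'   objects or `NULL`).
#' @param node_types Optional named character vector declaring node types
#'   (`"inlet"`, `"junction"`, `"outlet"`); by default types are derived from
#'   the topology. Declared types that contradict the topology are reported
#'   by [validate_tree()].
#' @return An object of class `vessel_tree`.
#' @examples
#' tr <- make_tree(c(1, 1))
#' validate_tree(tr)
#' @export
vessel_tree <- function(segments, node_types = NULL) {
  segments <- tibble::as_tibble(segments)
  if (!all(c("parent", "child", "length") %in% names(segments))) {
    stop("vessel_tree: segments needs columns parent, child, length")
  }
  if (!"radius" %in% names(segments)) segments$radius <- NA_real_
  if (!"section" %in% names(segments)) {
    segments$section <- vector("list", nrow(segments))
  }
  segments$parent <- as.character(segments$parent)
  segments$child <- as.character(segments$child)
  nodes <- unique(c(segments$parent, segments$child))
  roots <- setdiff(segments$parent, segments$child)
  leaves <- setdiff(segments$child, segments$parent)
  outlets <- segments$child[segments$child %in% leaves]
  outlets <- outlets[!duplicated(outlets)]
  structure(
    list(
      segments = segments,
      nodes = nodes,
      inlet = if (length(roots) == 1) roots else NA_character_,
      outlets = outlets,
      node_types = node_types
    ),
    class = "vessel_tree"
  )
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf(
    "<vessel_tree> %d segments, inlet '%s', %d outlets (%s)\n",
    nrow(x$segments), x$inlet, length(x$outlets),
    paste(x$outlets, collapse = ", ")
  ))
  invisible(x)
}

#' Diagnose vessel-tree invariant violations
#'
#' Checks that the graph is a tree with exactly one inlet, that every leaf is
#' an outlet, that there are at least two outlets, and that any declared node
#' types agree with the topology. Diagnostic only: returns a character vector
#' of human-readable violations, empty when the tree is valid.
#'
#' @param tree A [vessel_tree()].
#' @return Character vector of violations (length 0 when valid).
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "vessel_tree"))
  seg <- tree$segments
  out <- character()
  roots <- setdiff(seg$parent, seg$child)
  if (length(roots) != 1) {
    out <- c(out, sprintf(
      "expected exactly one inlet, found %d (%s)",
      length(roots), paste(roots, collapse = ", ")
    ))
  }
  dup <- seg$child[duplicated(seg$child)]
  if (length(dup)) {
    out <- c(out, sprintf("node(s) %s have more than one parent: not a tree",
                          paste(unique(dup), collapse = ", ")))
  }
  # cycle check: iteratively strip leaves
  edges <- seg[, c("parent", "child")]
  repeat {
    leaf <- setdiff(edges$child, edges$parent)
    keep <- !(edges$child %in% leaf)
    if (all(keep)) break
    edges <- edges[keep, , drop = FALSE]
  }
  if (nrow(edges) > 0) {
    out <- c(out, sprintf("cycle detected involving node(s): %s",
                          paste(unique(edges$child), collapse = ", ")))
  }
  leaves <- setdiff(seg$child, seg$parent)
  if (length(leaves) < 2) {
    out <- c(out, sprintf("tree has %d outlet(s); need >= 2", length(leaves)))
  }
  if (!is.null(tree$node_types)) {
    for (nd in names(tree$node_types)) {
      ty <- tree$node_types[[nd]]
      is_leaf <- nd %in% leaves
      is_root <- nd %in% roots
      derived <- if (is_root) "inlet" else if (is_leaf) "outlet" else "junction"
      if (!nd %in% tree$nodes) {
        out <- c(out, sprintf("declared node '%s' does not appear in any segment", nd))
      } else if (ty != derived) {
        out <- c(out, sprintf("node '%s' declared '%s' but topology makes it a %s",
                              nd, ty, derived))
      }
    }
  }
  bad_len <- which(!is.finite(seg$length) | seg$length <= 0)
  if (length(bad_len)) {
    out <- c(out, sprintf("segment(s) into %s have non-positive length",
                          paste(seg$child[bad_len], collapse = ", ")))
  }
  out
}

# Representative diameter (mm) of the segment ending at `child`:
# raytraced equivalent diameter when a section is attached, else 2 * radius.
.segment_diameter <- function(tree, child, n_rays = 64) {
  i <- match(child, tree$segments$child)
  if (is.na(i)) stop(sprintf("no segment ends at node '%s'", child))
  sec <- tree$segments$section[[i]]
  if (!is.null(sec)) {
    return(equivalent_diameter(polygon_area_raytrace(sec, n_rays)))
  }
  r <- tree$segments$radius[i]
  if (is.na(r) || r <= 0) {
    stop(sprintf("segment into '%s' carries neither a cross-section nor a positive radius", child))
  }
  2 * r
}

.segment_area <- function(tree, child, n_rays = 64) {
  i <- match(child, tree$segments$child)
  if (is.na(i)) stop(sprintf("no segment ends at node '%s'", child))
  sec <- tree$segments$section[[i]]
  if (is.null(sec)) {
    r <- tree$segments$radius[i]
    if (is.na(r) || r <= 0) {
      stop(sprintf("segment into '%s' has no cross-section and no positive radius", child))
    }
    return(pi * r^2)
  }
  tryCatch(
    polygon_area_raytrace(sec, n_rays),
    error = function(e) stop(sprintf("invalid cross-section on segment into '%s': %s",
                                     child, conditionMessage(e)))
  )
}

.children_of <- function(tree, node) {
  tree$segments$child[tree$segments$parent == node]
}

#' @rdname tidy.vessel_tree
#' @method glance vessel_tree
#' @export
glance.vessel_tree <- function(x, ...) {
  tibble::tibble(
    n_segments = nrow(x$segments),
    n_outlets = length(x$outlets),
    n_junctions = length(setdiff(unique(x$segments$parent), x$inlet)),
    valid = length(validate_tree(x)) == 0
  )
}

#' Tidy a vessel tree into its segment table
#'
#' `tidy()` returns one row per segment with derived diameters; `glance()`
#' returns a one-row topology summary.
#'
#' @param x A [vessel_tree()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy vessel_tree
#' @export
tidy.vessel_tree <- function(x, ...) {
  seg <- x$segments
  dplyr::mutate(
    seg[, c("parent", "child", "length", "radius")],
    has_section = !purrr::map_lgl(seg$section, is.null),
    is_outlet = seg$child %in% x$outlets
  )
}
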