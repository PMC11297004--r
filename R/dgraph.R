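#' Superbasin analysis at discretised energy levels
#'
#' At each threshold `E_ref + k * delta_e` the minima with energy at or
#' below the threshold are partitioned by union-find, joining two minima
#' whenever a transition state at or below the threshold links them. The
#' resulting hierarchy of superbasins is the disconnectivity-graph
#' structure: branches merge at the first discrete level at which a
#' transition path entirely below that level exists.
#'
#' @param ktn a [ktn_new()] database with at least one minimum.
#' @param delta_e level spacing in kcal/mol (> 0); 1 kcal/mol by default.
#' @param e_ref reference energy for the level grid; defaults to the
#'   global-minimum energy.
#' @return object of class `superbasin_tree`: `levels` (threshold energies),
#'   `nodes` (per-node: id, level index, member minimum ids, parent id,
#'   children ids), `min_energies`, `delta_e`, `e_ref`.
#' @export
build_superbasins <- function(ktn, delta_e = 1.0, e_ref = NULL) {
  stopifnot(delta_e > 0)
  e <- ktn_min_energies(ktn)
  if (!length(e))
    return(structure(list(levels = numeric(), nodes = list(),
                          min_energies = numeric(), delta_e = delta_e,
                          e_ref = NA_real_),
                     class = "superbasin_tree"))
  if (is.null(e_ref)) e_ref <- min(e)
  ed <- ktn_edges(ktn)
  top <- max(c(e, ed$energy))
  k_max <- ceiling((top - e_ref) / delta_e + 1e-9) + 1L
  levels <- e_ref + delta_e * seq_len(k_max)

  n <- length(e)
  nodes <- list()
  # previous level: map minimum id -> node id
  prev_node_of <- rep(NA_integer_, n)
  for (li in seq_along(levels)) {
    L <- levels[li]
    present <- which(e <= L)
    if (!length(present)) next
    parent <- seq_len(n)
    findr <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    sel <- ed$energy <= L
    for (k in which(sel)) {
      a <- ed$minus[k]; b <- ed$plus[k]
      if (e[a] <= L && e[b] <= L) {
        ra <- findr(a); rb <- findr(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
    roots <- vapply(present, findr, integer(1))
    comp_node_of <- rep(NA_integer_, n)
    for (r in unique(roots)) {
      members <- present[roots == r]
      id <- length(nodes) + 1L
      nodes[[id]] <- list(id = id, level = li, members = members,
                          parent = NA_integer_, children = integer())
      comp_node_of[members] <- id
    }
    # link children from the previous level
    for (m in which(!is.na(prev_node_of))) {
      child <- prev_node_of[m]
      par <- comp_node_of[m]
      if (is.na(nodes[[child]]$parent)) {
        nodes[[child]]$parent <- par
        nodes[[par]]$children <- c(nodes[[par]]$children, child)
      }
    }
    for (id in seq_along(nodes)) nodes[[id]]$children <- unique(nodes[[id]]$children)
    prev_node_of <- comp_node_of
  }
  structure(list(levels = levels, nodes = nodes, min_energies = e,
                 delta_e = delta_e, e_ref = e_ref),
            class = "superbasin_tree")
}

#' @export
print.superbasin_tree <- function(x, ...) {
  nl <- length(x$levels)
  roots <- sum(vapply(x$nodes, function(n) is.na(n$parent) && n$level == nl, logical(1)))
  cat(sprintf("<superbasin_tree: %d minima, %d levels (spacing %g), %d top-level component(s)>\n",
              length(x$min_energies), nl, x$delta_e, roots))
  invisible(x)
}

unreachable_error <- function(a, b) {
  structure(class = c("pelkit_unreachable", "error", "condition"),
            list(message = sprintf("minima %d and %d are not connected by any transition-state path", a, b),
                 call = NULL))
}

#' Minimax barrier between two minima
#'
#' The lowest, over all transition-state paths joining the two minima, of
#' the highest transition-state energy along the path (the widest-path /
#' continuous-limit superbasin merge energy). Computed with a Dijkstra
#' variant that relaxes the running path maximum instead of a sum. By
#' convention the barrier from a minimum to itself is its own energy.
#'
#' @param ktn a [ktn_new()] database.
#' @param min_a_id,min_b_id minimum ids.
#' @return the merge energy in kcal/mol; signals an unreachable condition
#'   when no path exists.
#' @export
minimax_barrier <- function(ktn, min_a_id, min_b_id) {
  e <- ktn_min_energies(ktn)
  stopifnot(min_a_id >= 1, min_a_id <= length(e), min_b_id >= 1, min_b_id <= length(e))
  if (min_a_id == min_b_id) return(e[min_a_id])
  ed <- ktn_edges(ktn)
  n <- length(e)
  # adjacency with the cheapest TS per pair
  best <- matrix(Inf, n, n)
  for (k in seq_len(nrow(ed))) {
    a <- ed$minus[k]; b <- ed$plus[k]
    if (ed$energy[k] < best[a, b]) best[a, b] <- best[b, a] <- ed$energy[k]
  }
  dist <- rep(Inf, n)
  dist[min_a_id] <- -Inf
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    cand <- which(!done)
    u <- cand[which.min(dist[cand])]
    if (!is.finite(dist[u]) && dist[u] > 0) break
    done[u] <- TRUE
    if (u == min_b_id) break
    nd <- pmax(dist[u], best[u, ])
    upd <- which(!done & nd < dist)
    dist[upd] <- nd[upd]
  }
  if (!is.finite(dist[min_b_id]) && dist[min_b_id] > 0)
    stop(unreachable_error(min_a_id, min_b_id))
  dist[min_b_id]
}

#' Barrier matrix between a set of minima
#'
#' @param ktn a [ktn_new()] database.
#' @param ids minimum ids (default all).
#' @return symmetric matrix of minimax barriers (`NA` for unreachable
#'   pairs), diagonal the minima's own energies.
#' @export
barrier_matrix <- function(ktn, ids = seq_along(ktn$minima)) {
  n <- length(ids)
  M <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { M[i, j] <- ktn$minima[[ids[i]]]$energy; next }
    M[i, j] <- tryCatch(minimax_barrier(ktn, ids[i], ids[j]),
                        error = function(e) NA_real_)
  }
  M
}

#' Identify funnels in a superbasin tree
#'
#' A funnel is a subtree whose lowest member lies at least `min_depth` below
#' the level at which the subtree merges with any lower-energy subtree.
#' Funnels are returned sorted by their lowest energy and labelled "A",
#' "B", "C", ... — label "A" is always the global-minimum funnel.
#'
#' @param tree a [build_superbasins()] result.
#' @param min_depth minimum depth (kcal/mol) for a merged subtree to count
#'   as a separate funnel; the level spacing times five is a common
#'   heuristic.
#' @return list of `basin` objects (`label`, `members`, `lowest_id`,
#'   `lowest_energy`).
#' @export
identify_funnels <- function(tree, min_depth = 5 * tree$delta_e) {
  e <- tree$min_energies
  if (!length(e)) return(list())
  nl <- length(tree$levels)
  roots <- Filter(function(n) is.na(n$parent), tree$nodes)

  walk <- function(node) {
    # returns list(open = members of the funnel containing the subtree's
    # lowest minimum, closed = list of completed funnels below this node)
    kids <- node$children
    if (!length(kids)) {
      return(list(open = node$members, closed = list()))
    }
    parts <- lapply(kids, function(cid) walk(tree$nodes[[cid]]))
    # minima can first appear at this level without a child node
    seen <- unlist(lapply(parts, function(p) c(p$open, unlist(p$closed))))
    newcomers <- setdiff(node$members, seen)
    lows <- vapply(parts, function(p) min(e[p$open]), numeric(1))
    main <- which.min(lows)
    open <- parts[[main]]$open
    closed <- parts[[main]]$closed
    merge_level <- tree$levels[node$level]
    for (k in seq_along(parts)) {
      if (k == main) next
      depth <- merge_level - min(e[parts[[k]]$open])
      if (depth >= min_depth) {
        closed <- c(closed, list(parts[[k]]$open), parts[[k]]$closed)
      } else {
        open <- c(open, parts[[k]]$open)
        closed <- c(closed, parts[[k]]$closed)
      }
    }
    open <- c(open, newcomers)
    list(open = open, closed = closed)
  }

  funnels <- list()
  for (r in roots) {
    res <- walk(r)
    funnels <- c(funnels, list(res$open), res$closed)
  }
  lows <- vapply(funnels, function(m) min(e[m]), numeric(1))
  funnels <- funnels[order(lows)]
  out <- vector("list", length(funnels))
  for (k in seq_along(funnels)) {
    mem <- sort(unique(funnels[[k]]))
    li <- mem[which.min(e[mem])]
    out[[k]] <- structure(list(label = make_basin_label(k), members = mem,
                               lowest_id = as.integer(li), lowest_energy = e[li]),
                          class = "basin")
  }
  out
}

make_basin_label <- function(k) {
  if (k <= 26) LETTERS[k] else paste0(LETTERS[((k - 1) %/% 26)], LETTERS[((k - 1) %% 26) + 1])
}

#' @export
print.basin <- function(x, ...) {
  cat(sprintf("<basin %s: %d minima, lowest #%d at %.4f kcal/mol>\n",
              x$label, length(x$members), x$lowest_id, x$lowest_energy))
  invisible(x)
}

#' Render a disconnectivity graph
#'
#' The vertical axis is energy; every minimum is a branch terminating at its
#' own energy, and branches merge at the discrete level where a transition
#' path entirely below that level first exists. Children at each merge are
#' ordered left to right by decreasing subtree size, ties broken by lowest
#' energy then smallest member id, which makes the layout deterministic and
#' crossing-free. Returns the drawing as an SVG string plus a JSON document
#' of node positions.
#'
#' @param tree a [build_superbasins()] result.
#' @param layout_config list of options: `width`, `height` (pixels),
#'   `e_min`, `e_max` (shared energy-axis range, defaults to the tree's own
#'   range), `highlight` (list of basins from [identify_funnels()] to shade),
#'   `margin`.
#' @return object of class `disconnectivity_drawing` with elements `svg`
#'   (character), `json` (character), `segments` and `leaves` (data frames).
#' @export
render_disconnectivity <- function(tree, layout_config = list()) {
  cfg <- utils::modifyList(list(width = 480, height = 640, margin = 40,
                                e_min = NULL, e_max = NULL, highlight = list()),
                           layout_config)
  e <- tree$min_energies
  stopifnot(length(e) > 0)
  nl <- length(tree$levels)
  roots <- which(vapply(tree$nodes, function(n) is.na(n$parent), logical(1)))

  # horizontal order: recursive, children sorted by (size desc, lowest energy,
  # smallest member id)
  leaf_order <- integer()
  x_of_node <- numeric(length(tree$nodes))
  assign_x <- function(nid) {
    node <- tree$nodes[[nid]]
    kids <- node$children
    seen_below <- unlist(lapply(kids, function(cid) tree$nodes[[cid]]$members))
    newcomers <- setdiff(node$members, seen_below)
    if (length(kids)) {
      key <- vapply(kids, function(cid) {
        m <- tree$nodes[[cid]]$members
        c(-length(m), min(e[m]), min(m))
      }, numeric(3))
      kids <- kids[order(key[1, ], key[2, ], key[3, ])]
      for (cid in kids) assign_x(cid)
    }
    for (m in sort(newcomers)) leaf_order <<- c(leaf_order, m)
    invisible(NULL)
  }
  for (r in roots) assign_x(r)
  leaf_x <- stats::setNames(seq_along(leaf_order), leaf_order)
  node_x <- function(nid) mean(leaf_x[as.character(tree$nodes[[nid]]$members)])
  for (nid in seq_along(tree$nodes)) x_of_node[nid] <- node_x(nid)

  # segments: vertical branch pieces between levels, plus leaf stems down to
  # each minimum's energy
  seg <- list()
  for (nid in seq_along(tree$nodes)) {
    node <- tree$nodes[[nid]]
    y_top <- tree$levels[node$level]
    if (!is.na(node$parent)) {
      seg[[length(seg) + 1L]] <- data.frame(
        x0 = x_of_node[nid], y0 = y_top,
        x1 = x_of_node[node$parent], y1 = tree$levels[tree$nodes[[node$parent]]$level],
        kind = "merge")
    }
    kids_members <- unlist(lapply(node$children, function(cid) tree$nodes[[cid]]$members))
    for (m in setdiff(node$members, kids_members)) {
      seg[[length(seg) + 1L]] <- data.frame(
        x0 = leaf_x[as.character(m)], y0 = e[m],
        x1 = x_of_node[nid], y1 = y_top, kind = "leaf")
    }
  }
  segments <- do.call(rbind, seg)
  leaves <- data.frame(minimum = leaf_order,
                       x = as.numeric(leaf_x[as.character(leaf_order)]),
                       y = e[leaf_order])

  e_min <- cfg$e_min %||% min(e)
  e_max <- cfg$e_max %||% max(tree$levels)
  W <- cfg$width; H <- cfg$height; mar <- cfg$margin
  sx <- function(x) mar + (x - 0.5) / max(1, length(leaf_order)) * (W - 2 * mar)
  sy <- function(y) H - mar - (y - e_min) / max(1e-12, e_max - e_min) * (H - 2 * mar)

  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
                   W, H, W, H),
           sprintf('<!-- energy axis: %.6g to %.6g kcal/mol -->', e_min, e_max))
  for (hb in cfg$highlight) {
    xs <- sx(leaf_x[as.character(hb$members)])
    svg <- c(svg, sprintf('<rect x="%.1f" y="%.1f" width="%.1f" height="%.1f" fill="gold" opacity="0.35"><title>basin %s</title></rect>',
                          min(xs) - 6, sy(e_max), max(xs) - min(xs) + 12,
                          sy(e_min) - sy(e_max), hb$label))
  }
  for (k in seq_len(nrow(segments))) {
    svg <- c(svg, sprintf('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="black" stroke-width="1"/>',
                          sx(segments$x0[k]), sy(segments$y0[k]),
                          sx(segments$x1[k]), sy(segments$y1[k])))
  }
  svg <- c(svg, '</svg>')

  json <- jsonlite::toJSON(list(
    e_ref = tree$e_ref, delta_e = tree$delta_e,
    energy_range = c(e_min, e_max),
    levels = tree$levels,
    leaves = leaves,
    nodes = lapply(seq_along(tree$nodes), function(nid) {
      n <- tree$nodes[[nid]]
      list(id = n$id, level = n$level, level_energy = tree$levels[n$level],
           x = x_of_node[nid], members = n$members, parent = n$parent)
    })), auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  structure(list(svg = paste(svg, collapse = "\n"), json = as.character(json),
                 segments = segments, leaves = leaves,
                 energy_range = c(e_min, e_max)),
            class = "disconnectivity_drawing")
}

#' @export
print.disconnectivity_drawing <- function(x, ...) {
  cat(sprintf("<disconnectivity_drawing: %d leaves, energy range [%.4g, %.4g]>\n",
              nrow(x$leaves), x$energy_range[1], x$energy_range[2]))
  invisible(x)
}

#' @export
plot.disconnectivity_drawing <- function(x, ...) {
  graphics::plot(NA, xlim = range(c(x$segments$x0, x$segments$x1)) + c(-0.5, 0.5),
                 ylim = x$energy_range, xlab = "", ylab = "energy (kcal/mol)",
                 xaxt = "n", ...)
  graphics::segments(x$segments$x0, x$segments$y0, x$segments$x1, x$segments$y1)
  invisible(x)
}

#' Parse the JSON emitted by [render_disconnectivity()] back into its tree
#' topology (node ids, levels, membership, parenthood); used to verify
#' round-tripping of drawings.
#'
#' @param json character scalar.
#' @return list with `levels` and `nodes`.
#' @export
parse_disconnectivity_json <- function(json) {
  raw <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE, simplifyVector = TRUE)
  list(levels = as.numeric(raw$levels),
       nodes = lapply(raw$nodes, function(n)
         list(id = n$id, level = n$level, members = sort(as.integer(unlist(n$members))),
              parent = if (is.null(n$parent)) NA_integer_ else as.integer(n$parent))))
}
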