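procrustes_align <- function(Y, target) {
  # orthogonal Procrustes with scaling: align Y to target
  X <- target
  if (nrow(X) < 2) return(X)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  ssY <- sum(Yc^2)
  if (ssY < 1e-12) return(sweep(Yc, 2, cx, `+`))
  sv <- svd(crossprod(Yc, Xc))
  R <- sv$u %*% t(sv$v)
  s <- sum(sv$d) / ssY
  sweep(s * Yc %*% R, 2, cx, `+`)
}

#' Shared force-directed layout averaged over several networks
#'
#' Runs the Fruchterman-Reingold algorithm per network with edge weights
#' `|selected partial correlation|`, aligns every layout to the first by
#' Procrustes rotation/reflection/scaling (naive averaging of independently
#' rotated force-directed layouts is meaningless), and returns the
#' node-wise mean — one layout shared by all networks to ease visual
#' comparison. Deterministic at a fixed seed.
#'
#' @param estimates list of [select_edges()] results on one node set.
#' @param seed integer seed.
#' @return matrix of node coordinates (nodes x 2).
#' @export
fr_layout_averaged <- function(estimates, seed) {
  if (!length(estimates)) stop("need at least one network estimate")
  nodes <- estimates[[1]]$nodes
  if (!length(nodes)) stop("empty node set")
  for (e in estimates) check_same_nodes(estimates[[1]], e)
  layouts <- lapply(estimates, function(e) {
    W <- abs(e$selected_partials)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    set.seed(seed)
    co <- igraph::layout_with_fr(g, weights = if (igraph::ecount(g))
      igraph::E(g)$weight else NULL)
    co
  })
  ref <- layouts[[1]]
  aligned <- lapply(layouts, procrustes_align, target = ref)
  co <- Reduce(`+`, aligned) / length(aligned)
  dimnames(co) <- list(nodes, c("x", "y"))
  co
}

svg_num <- function(x) formatC(x, format = "f", digits = 2)

#' Render a selected network as an SVG figure
#'
#' Draws only CI-selected edges: blue for positive partial correlations,
#' red for negative, stroke width proportional to magnitude. The SVG is
#' generated directly as text (no graphics device needed) and records the
#' drawn edge count in a `data-edges` attribute.
#'
#' @param estimate a [select_edges()] result.
#' @param layout coordinates from [fr_layout_averaged()] covering the node
#'   set.
#' @param path output `.svg` path.
#' @return `path`, invisibly.
#' @export
render_network_figure <- function(estimate, layout, path) {
  nodes <- estimate$nodes
  if (!all(nodes %in% rownames(layout)))
    stop("layout does not cover the node set")
  co <- layout[nodes, , drop = FALSE]
  # map into a 600x600 viewport with a margin
  rng <- apply(co, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-9)
  xy <- cbind(60 + 480 * (co[, 1] - rng[1, 1]) / span[1],
              60 + 480 * (co[, 2] - rng[1, 2]) / span[2])
  ed <- edge_index(nodes)
  sel <- estimate$adjacency[cbind(ed$i, ed$j)]
  lines <- character(0)
  for (k in which(sel)) {
    w <- estimate$selected_partials[ed$i[k], ed$j[k]]
    lines <- c(lines, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s" stroke-opacity="0.8"/>',
      svg_num(xy[ed$i[k], 1]), svg_num(xy[ed$i[k], 2]),
      svg_num(xy[ed$j[k], 1]), svg_num(xy[ed$j[k], 2]),
      if (w > 0) "#2166ac" else "#b2182b", svg_num(15 * abs(w))))
  }
  circles <- sprintf(
    '<circle cx="%s" cy="%s" r="18" fill="#f7f7f7" stroke="#333333"/>\n<text x="%s" y="%s" font-size="9" text-anchor="middle" dominant-baseline="middle">%s</text>',
    svg_num(xy[, 1]), svg_num(xy[, 2]), svg_num(xy[, 1]), svg_num(xy[, 2]),
    nodes)
  svg <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" viewBox="0 0 600 600" data-edges="%d">',
    sum(sel)),
    lines, circles, "</svg>")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(svg, con)
  invisible(path)
}
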