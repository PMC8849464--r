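#' Build a conductance graph from a resistance raster
#'
#' Every valid (non-nodata) cell becomes a node; neighbouring cells are joined
#' by a resistor whose resistance is the mean of the two cell resistances,
#' scaled by `sqrt(2)` for diagonal neighbours; edge conductance is the
#' reciprocal. 8-neighbour connectivity by default.
#'
#' @param resistance a `raster_surface` of resistances (values >= small positive).
#' @param connectivity 4 or 8.
#' @return an object of class `conductance_graph`: edge table (`a`, `b`,
#'   `conductance`), node-to-cell lookup, and the raster geometry.
#' @export
build_conductance_graph <- function(resistance, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  v <- resistance$values
  if (any(v[!is.na(v)] <= 0)) stop("resistances must be positive")
  nr <- nrow(v); nc <- ncol(v)
  valid <- !is.na(v)
  if (sum(valid) < 2) stop("need at least 2 valid cells")
  node_of_cell <- matrix(NA_integer_, nr, nc)
  node_of_cell[valid] <- seq_len(sum(valid))
  cells <- which(valid, arr.ind = TRUE)

  offs <- list(c(0, 1), c(1, 0))
  if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
  ea <- integer(0); eb <- integer(0); er <- numeric(0)
  for (off in offs) {
    r1 <- seq_len(nr - max(off[1], 0)) + max(-off[1], 0) * 0
    rows <- seq_len(nr); cols <- seq_len(nc)
    rA <- rows[rows + off[1] >= 1 & rows + off[1] <= nr]
    cA <- cols[cols + off[2] >= 1 & cols + off[2] <= nc]
    A <- node_of_cell[rA, cA, drop = FALSE]
    B <- node_of_cell[rA + off[1], cA + off[2], drop = FALSE]
    vA <- v[rA, cA, drop = FALSE]
    vB <- v[rA + off[1], cA + off[2], drop = FALSE]
    keep <- !is.na(A) & !is.na(B)
    res <- (vA[keep] + vB[keep]) / 2
    if (all(off != 0) && sum(abs(off)) == 2) res <- res * sqrt(2)
    ea <- c(ea, A[keep]); eb <- c(eb, B[keep]); er <- c(er, res)
  }
  structure(list(edges = data.frame(a = ea, b = eb, resistance = er,
                                    conductance = 1 / er),
                 n_nodes = sum(valid), cells = cells,
                 node_of_cell = node_of_cell,
                 cell_size = resistance$cell_size, origin = resistance$origin,
                 dim = c(nr, nc)),
            class = "conductance_graph")
}

#' @export
print.conductance_graph <- function(x, ...) {
  cat(sprintf("conductance_graph: %d nodes, %d edges\n",
              x$n_nodes, nrow(x$edges)))
  invisible(x)
}

## sparse weighted graph Laplacian
graph_laplacian <- function(graph) {
  e <- graph$edges
  n <- graph$n_nodes
  A <- Matrix::sparseMatrix(i = c(e$a, e$b), j = c(e$b, e$a),
                            x = c(e$conductance, e$conductance),
                            dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(A)) - A
}

## connected-component labels via sparse BFS on the adjacency structure
graph_component_of <- function(graph) {
  n <- graph$n_nodes
  e <- graph$edges
  adj_i <- c(e$a, e$b); adj_j <- c(e$b, e$a)
  ord <- order(adj_i)
  adj_i <- adj_i[ord]; adj_j <- adj_j[ord]
  starts <- c(match(seq_len(n), adj_i), length(adj_i) + 1L)
  starts <- cummin_fill(starts)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      lo <- starts[u]; hi <- starts[u + 1L] - 1L
      if (hi >= lo) {
        nb <- adj_j[lo:hi]
        new <- nb[comp[nb] == 0L]
        if (length(new)) {
          comp[new] <- cur
          stack <- c(stack, new)
        }
      }
    }
  }
  comp
}

## fill NA run-starts so starts is non-decreasing (isolated nodes)
cummin_fill <- function(starts) {
  for (k in rev(seq_along(starts))) {
    if (is.na(starts[k])) starts[k] <- starts[k + 1L]
  }
  starts
}

#' Map site coordinates to graph nodes
#'
#' Each site is snapped to the nearest valid raster cell centre.
#'
#' @param graph a `conductance_graph`.
#' @param sites data.frame with `site_id`, `x`, `y` (projected metres).
#' @return integer vector of node ids named by site.
#' @export
site_nodes <- function(graph, sites) {
  rc <- cbind(
    row = pmin(pmax(graph$dim[1] - ceiling((sites$y - graph$origin[2]) / graph$cell_size) + 1L, 1L), graph$dim[1]),
    col = pmin(pmax(ceiling((sites$x - graph$origin[1]) / graph$cell_size), 1L), graph$dim[2]))
  nodes <- graph$node_of_cell[rc]
  if (anyNA(nodes)) {
    # snap to nearest valid cell
    cx <- graph$origin[1] + (graph$cells[, "col"] - 0.5) * graph$cell_size
    cy <- graph$origin[2] + (graph$dim[1] - graph$cells[, "row"] + 0.5) * graph$cell_size
    for (k in which(is.na(nodes))) {
      nodes[k] <- which.min((cx - sites$x[k])^2 + (cy - sites$y[k])^2)
    }
  }
  stats::setNames(as.integer(nodes), as.character(sites$site_id))
}

## grounded-Laplacian solve machinery shared by commute and current solvers.
## Returns potentials matrix X (n x n_focal): column k solves L x = e_focal[k]
## with `ground` (last focal node) fixed at potential 0.
solve_focal_potentials <- function(graph, focal) {
  comp <- graph_component_of(graph)
  if (length(unique(comp[focal])) > 1 || any(comp[focal] != comp[focal[1]])) {
    bad <- focal[comp[focal] != comp[focal][1]]
    stop("focal nodes fall in disconnected components: ",
         paste(bad, collapse = ", "))
  }
  keep <- which(comp == comp[focal[1]])
  if (length(keep) < graph$n_nodes) {
    # restrict to the focal component
    remap <- integer(graph$n_nodes); remap[keep] <- seq_along(keep)
    e <- graph$edges
    sel <- comp[e$a] == comp[focal[1]]
    graph <- structure(list(edges = data.frame(a = remap[e$a[sel]],
                                               b = remap[e$b[sel]],
                                               resistance = e$resistance[sel],
                                               conductance = e$conductance[sel]),
                            n_nodes = length(keep)),
                       class = "conductance_graph")
    focal_local <- remap[focal]
  } else {
    focal_local <- focal
    keep <- seq_len(graph$n_nodes)
  }
  L <- graph_laplacian(graph)
  ground <- focal_local[length(focal_local)]
  idx <- setdiff(seq_len(graph$n_nodes), ground)
  Lg <- L[idx, idx, drop = FALSE]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lg), LDL = FALSE, perm = TRUE)
  rhs <- Matrix::sparseMatrix(
    i = match(focal_local[-length(focal_local)], idx),
    j = seq_len(length(focal_local) - 1L),
    x = 1, dims = c(length(idx), length(focal_local) - 1L))
  Xg <- as.matrix(Matrix::solve(ch, rhs, system = "A"))
  # reinsert the grounded row, and a zero column for the ground node itself
  X <- matrix(0, graph$n_nodes, length(focal_local))
  X[idx, seq_len(ncol(Xg))] <- Xg
  list(X = X, focal_local = focal_local, ground_pos = length(focal_local),
       keep = keep, graph_local = graph)
}

#' Commute-time effective distances between focal nodes
#'
#' The random-walk commute time between nodes i and j is
#' `C(i, j) = vol(G) * R_eff(i, j)`, with `vol(G)` the sum of weighted node
#' degrees and `R_eff` the effective electrical resistance obtained from the
#' graph-Laplacian (pseudo)inverse.
#'
#' @param graph a `conductance_graph`.
#' @param focal_nodes integer node ids (e.g. from [site_nodes()]).
#' @param labels labels for the returned matrix (defaults to node ids).
#' @return a `dist_matrix` of kind `"effective"` with attribute
#'   `"r_eff"` (the effective-resistance matrix) and `"volume"`.
#' @export
commute_distance <- function(graph, focal_nodes, labels = NULL) {
  if (is.null(labels)) labels <- names(focal_nodes)
  if (is.null(labels)) labels <- as.character(focal_nodes)
  sol <- solve_focal_potentials(graph, focal_nodes)
  X <- sol$X
  f <- sol$focal_local
  m <- length(f)
  # Xf[k, l] = potential at focal k when unit current enters focal l, exits ground
  Xf <- X[f, , drop = FALSE]
  reff <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      reff[i, j] <- Xf[i, i] + Xf[j, j] - Xf[i, j] - Xf[j, i]
    }
  }
  vol <- 2 * sum(sol$graph_local$edges$conductance)
  out <- dist_matrix(vol * reff, labels, kind = "effective")
  attr(out, "r_eff") <- dist_matrix(reff, labels, kind = "effective")
  attr(out, "volume") <- vol
  out
}

#' Circuit-theory current-density map
#'
#' For every unordered pair of focal sites, one unit of current is injected at
#' the source and extracted at the sink; the Laplacian system is solved for
#' node potentials, per-edge currents are computed, and each cell accumulates
#' half the sum of absolute currents on its incident edges (so a pure
#' pass-through cell carries the current that traverses it). Cell currents are
#' summed over all pairs.
#'
#' @param resistance a `raster_surface` of resistances.
#' @param focal_sites data.frame with `site_id`, `x`, `y`.
#' @param connectivity 4 or 8.
#' @return list with `map` (a `raster_surface` of summed current), `r_eff`
#'   (a `dist_matrix` of per-pair effective resistances), and
#'   `max_kirchhoff_violation` (largest net current at any non-focal node).
#' @export
current_map <- function(resistance, focal_sites, connectivity = 8) {
  graph <- build_conductance_graph(resistance, connectivity)
  focal <- site_nodes(graph, focal_sites)
  sol <- solve_focal_potentials(graph, focal)
  X <- sol$X
  f <- sol$focal_local
  m <- length(f)
  g <- sol$graph_local
  e <- g$edges
  L <- graph_laplacian(g)
  acc <- numeric(g$n_nodes)
  reff <- matrix(0, m, m)
  max_viol <- 0
  for (i in seq_len(m - 1)) {
    for (j in seq((i + 1), m)) {
      v <- X[, i] - X[, j]
      reff[i, j] <- reff[j, i] <- v[f[i]] - v[f[j]]
      iedge <- e$conductance * (v[e$a] - v[e$b])
      flow <- abs(iedge)
      node_cur <- 0.5 * (rowsum_vec(e$a, flow, g$n_nodes) +
                         rowsum_vec(e$b, flow, g$n_nodes))
      # focal endpoints carry the full injected current, not through-flow
      node_cur[f[c(i, j)]] <- 2 * node_cur[f[c(i, j)]]
      acc <- acc + node_cur
      net <- as.numeric(L %*% v)
      net[f[c(i, j)]] <- 0
      max_viol <- max(max_viol, max(abs(net)))
    }
  }
  vals <- matrix(NA_real_, graph$dim[1], graph$dim[2])
  full_acc <- rep(NA_real_, graph$n_nodes)
  full_acc[sol$keep] <- acc
  vals[graph$cells] <- full_acc
  map <- raster_surface(vals, graph$cell_size, graph$origin, kind = "continuous")
  labels <- names(focal)
  list(map = map,
       r_eff = dist_matrix(reff, labels, kind = "effective"),
       max_kirchhoff_violation = max_viol)
}

## sum `x` into bins given by integer index `idx` of length-n output
rowsum_vec <- function(idx, x, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
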