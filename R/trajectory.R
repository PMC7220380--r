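#' Minimum spanning tree over cluster centroids
#'
#' Computes per-cluster centroids in the reduced space and Kruskal's MST
#' over all centroid pairs under Euclidean distance, with deterministic
#' tie-breaking by (edge length, smaller cluster-id pair).
#'
#' @param coords cells x dims reduced-space coordinates (PCs by
#'   default in this workflow).
#' @param clusters cluster id per cell.
#' @return a `lineage_tree` list: `centroids` (clusters x dims),
#'   `edges` (data frame `from`, `to`, `length`), unrooted.
#' @export
build_mst <- function(coords, clusters) {
  coords <- as.matrix(coords)
  cl <- sort(unique(as.character(clusters)))
  if (length(cl) < 2) stop("need >= 2 clusters for a lineage tree")
  cent <- t(vapply(cl, function(k)
    colMeans(coords[clusters == k, , drop = FALSE]), numeric(ncol(coords))))
  pairs <- utils::combn(length(cl), 2)
  len <- sqrt(colSums((t(cent)[, pairs[1, ], drop = FALSE] -
                       t(cent)[, pairs[2, ], drop = FALSE])^2))
  ord <- order(len, cl[pairs[1, ]], cl[pairs[2, ]])
  # Kruskal with union-find
  parent <- seq_along(cl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- data.frame(from = character(0), to = character(0),
                      length = numeric(0), stringsAsFactors = FALSE)
  for (e in ord) {
    a <- find(pairs[1, e]); b <- find(pairs[2, e])
    if (a != b) {
      parent[a] <- b
      edges <- rbind(edges, data.frame(
        from = cl[pairs[1, e]], to = cl[pairs[2, e]], length = len[e],
        stringsAsFactors = FALSE))
    }
    if (nrow(edges) == length(cl) - 1) break
  }
  structure(list(centroids = cent, edges = edges, root = NULL,
                 lineages = NULL), class = "lineage_tree")
}

tree_adjacency <- function(tree) {
  cl <- rownames(tree$centroids)
  adj <- stats::setNames(vector("list", length(cl)), cl)
  for (i in seq_len(nrow(tree$edges))) {
    a <- tree$edges$from[i]; b <- tree$edges$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Root the lineage tree and enumerate root-to-leaf lineages
#'
#' @param tree unrooted [build_mst()] result.
#' @param root_cluster the root cluster id (the progenitor population
#'   the trajectory starts from).
#' @return the tree with `root` and `lineages` (named list of ordered
#'   cluster paths, one per leaf, leaves in lexicographic order) and
#'   `branch_points` (nodes of degree >= 3).
#' @export
extract_lineages <- function(tree, root_cluster) {
  root_cluster <- as.character(root_cluster)
  cl <- rownames(tree$centroids)
  if (!root_cluster %in% cl) stop("root cluster not in tree: ", root_cluster)
  adj <- tree_adjacency(tree)
  deg <- lengths(adj)
  leaves <- sort(names(deg)[deg == 1 & names(deg) != root_cluster])
  # DFS paths root -> each leaf
  path_to <- function(target) {
    stack <- list(root_cluster)
    seen <- stats::setNames(rep(FALSE, length(cl)), cl)
    parent <- stats::setNames(rep(NA_character_, length(cl)), cl)
    seen[root_cluster] <- TRUE
    q <- root_cluster
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (!seen[w]) {
        seen[w] <- TRUE; parent[w] <- v; q <- c(q, w)
      }
    }
    path <- target
    while (!is.na(parent[path[1]])) path <- c(unname(parent[path[1]]), path)
    path
  }
  lineages <- lapply(leaves, path_to)
  names(lineages) <- paste0("lineage_", leaves)
  tree$root <- root_cluster
  tree$lineages <- lineages
  tree$branch_points <- names(deg)[deg >= 3]
  tree
}

# orthogonal projection of points onto segment a->b; returns the clamped
# position t in [0,1] and squared distance
project_segment <- function(P, a, b) {
  d <- b - a
  L2 <- sum(d^2)
  t <- if (L2 == 0) rep(0, nrow(P)) else
    pmin(1, pmax(0, as.numeric((P - matrix(a, nrow(P), length(a),
                                           byrow = TRUE)) %*% d) / L2))
  proj <- matrix(a, nrow(P), length(a), byrow = TRUE) + outer(t, d)
  list(t = t, dist2 = rowSums((P - proj)^2))
}

#' Pseudotime and branch assignment along a rooted lineage tree
#'
#' Each cell is orthogonally projected onto the nearest segment of the
#' piecewise-linear centroid path of a lineage containing its cluster;
#' pseudotime is the arc length from the root centroid to the projection
#' point. Cells whose cluster lies on the shared trunk (on every
#' lineage) get branch id `"trunk"`; cells past the branch point get
#' their lineage id.
#'
#' @param coords cells x dims reduced-space coordinates.
#' @param clusters cluster id per cell.
#' @param tree rooted tree from [extract_lineages()].
#' @return data frame: `cell_id`, `cluster`, `pseudotime`, `branch`,
#'   `segment` (index of the projection segment on its lineage).
#' @export
assign_pseudotime <- function(coords, clusters, tree) {
  if (is.null(tree$root)) stop("tree is unrooted; call extract_lineages")
  coords <- as.matrix(coords)
  clusters <- as.character(clusters)
  shared <- Reduce(intersect, tree$lineages)
  n <- nrow(coords)
  pt <- rep(NA_real_, n); br <- rep(NA_character_, n)
  seg_id <- rep(NA_integer_, n)
  for (ln in names(tree$lineages)) {
    path <- tree$lineages[[ln]]
    cent <- tree$centroids[path, , drop = FALSE]
    seg_len <- sqrt(rowSums((cent[-1, , drop = FALSE] -
                             cent[-nrow(cent), , drop = FALSE])^2))
    arc0 <- c(0, cumsum(seg_len))
    cells <- which(clusters %in% path & is.na(pt))
    # trunk cells are shared between lineages; assign them on the first
    # lineage (the shared prefix path is identical across lineages)
    if (!length(cells)) next
    best_d2 <- rep(Inf, length(cells))
    best_pt <- rep(0, length(cells)); best_seg <- rep(1L, length(cells))
    for (s in seq_along(seg_len)) {
      pr <- project_segment(coords[cells, , drop = FALSE],
                            cent[s, ], cent[s + 1, ])
      upd <- pr$dist2 < best_d2
      best_d2[upd] <- pr$dist2[upd]
      best_pt[upd] <- arc0[s] + pr$t[upd] * seg_len[s]
      best_seg[upd] <- s
    }
    pt[cells] <- best_pt
    seg_id[cells] <- best_seg
    br[cells] <- ifelse(clusters[cells] %in% shared, "trunk", ln)
  }
  if (anyNA(pt)) stop("cell in a cluster absent from every lineage")
  data.frame(cell_id = rownames(coords), cluster = clusters,
             pseudotime = pt, branch = br, segment = seg_id,
             stringsAsFactors = FALSE, row.names = NULL)
}
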