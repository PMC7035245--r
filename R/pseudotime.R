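# Negative-binomial log-likelihood machinery for the ordering-gene and
# branch-node tests. Model: y_i ~ NB(mu_i, size = 1/phi) with
# mu_i = s_i * exp(b_{g(i)}), s_i the cell's total count (offset), group
# means fitted by 1-D root finding; dispersion phi by method of moments
# (floor 1e-8), shared between null and alternative fits.

nb_fit_group <- function(y, s, phi) {
  # MLE of b in mu = s * exp(b) for fixed phi: solve sum (y - mu)/(1 + phi mu) = 0
  if (sum(y) == 0) return(-30)
  b0 <- log(sum(y) / sum(s))
  f <- function(b) {
    mu <- s * exp(b)
    sum((y - mu) / (1 + phi * mu))
  }
  lo <- b0 - 8; hi <- b0 + 8
  if (f(lo) < 0) return(lo)
  if (f(hi) > 0) return(hi)
  uniroot(f, c(lo, hi), tol = 1e-9)$root
}

nb_loglik <- function(y, mu, phi) {
  sum(dnbinom(y, mu = pmax(mu, 1e-12), size = 1 / max(phi, 1e-8), log = TRUE))
}

#' Negative-binomial likelihood-ratio test for group-dependent expression
#'
#' Tests a per-group-mean NB model (with log total-count offset) against an
#' intercept-only null; dispersion is estimated once by method of moments
#' under the group model and shared between fits.
#'
#' @param y Integer counts per cell.
#' @param group Factor/character group label per cell.
#' @param totals Per-cell total counts used as the offset.
#' @return List: p (chi-square, df = groups - 1), statistic, df, dispersion.
#' @export
nb_lrt <- function(y, group, totals) {
  group <- factor(group)
  s <- totals / mean(totals)
  # method-of-moments dispersion around the group means
  mu_g <- vapply(split(seq_along(y), group),
                 function(i) sum(y[i]) / sum(s[i]), numeric(1))
  mu_hat <- s * mu_g[as.integer(group)]
  phi <- max(1e-8, sum((y - mu_hat)^2 - mu_hat) / sum(mu_hat^2))
  b_alt <- vapply(levels(group), function(g) {
    i <- group == g
    nb_fit_group(y[i], s[i], phi)
  }, numeric(1))
  b_null <- nb_fit_group(y, s, phi)
  ll_alt <- nb_loglik(y, s * exp(b_alt[as.integer(group)]), phi)
  ll_null <- nb_loglik(y, s * exp(b_null), phi)
  stat <- max(0, 2 * (ll_alt - ll_null))
  df <- nlevels(group) - 1
  list(p = pchisq(stat, df, lower.tail = FALSE), statistic = stat, df = df,
       dispersion = phi)
}

#' Ordering-gene configuration
#'
#' @param n_ordering_genes Genes retained for trajectory ordering (default
#'   780).
#' @param exclude_patterns Regular expressions removed from the ranked list
#'   (ribosomal RPL*/RPS* and mitochondrial MT-* by default).
#' @param de_universe_min_cells Genes must be detected in at least this many
#'   cells to be tested.
#' @return A `conecod_ordering_config` list.
#' @export
ordering_config <- function(n_ordering_genes = 780,
                            exclude_patterns = c("^RP[LS]", "^MT-"),
                            de_universe_min_cells = 10) {
  assert_that(n_ordering_genes >= 2, "n_ordering_genes must be >= 2")
  structure(list(n_ordering_genes = n_ordering_genes,
                 exclude_patterns = exclude_patterns,
                 de_universe_min_cells = de_universe_min_cells),
            class = "conecod_ordering_config")
}

#' Semi-supervised label assignment for ordering-gene selection
#'
#' Labels each cell rod, cone or undifferentiated from raw marker detection
#' (rod marker present = rod; cone marker present = cone; both or neither =
#' undifferentiated), the semi-supervision used upstream of ordering-gene
#' selection.
#'
#' @param counts Raw genes x cells matrix.
#' @param rod_marker,cone_marker Marker gene ids (NR2E3 and ARR3 by default).
#' @param min_count Minimum raw count to call a marker detected.
#' @return Character vector per cell: "rod", "cone" or "undifferentiated".
#' @export
coarse_type_labels <- function(counts, rod_marker = "NR2E3",
                               cone_marker = "ARR3", min_count = 1) {
  counts <- check_counts(counts)
  rod <- if (rod_marker %in% rownames(counts))
    counts[rod_marker, ] >= min_count else rep(FALSE, ncol(counts))
  cone <- if (cone_marker %in% rownames(counts))
    counts[cone_marker, ] >= min_count else rep(FALSE, ncol(counts))
  ifelse(rod & !cone, "rod", ifelse(cone & !rod, "cone", "undifferentiated"))
}

#' Select trajectory ordering genes by a semi-supervised NB test
#'
#' Per-gene NB likelihood-ratio test of expression against the supervision
#' groups (e.g. age x coarse type), ranking genes by p-value; ribosomal and
#' mitochondrial genes are removed from the ranking and the top
#' `n_ordering_genes` are returned.
#'
#' @param counts Raw genes x cells matrix.
#' @param labels Group label per cell (factor or character); groups with
#'   fewer than 2 cells are dropped with a warning.
#' @param config An [ordering_config()].
#' @return Character vector of ordering genes (ranked), with the full test
#'   table in attribute `table`.
#' @export
select_ordering_genes <- function(counts, labels, config = ordering_config()) {
  counts <- check_counts(counts)
  labels <- factor(labels)
  small <- names(which(table(labels) < 2))
  if (length(small)) {
    warn(paste("dropping groups with < 2 cells:", paste(small, collapse = ", ")))
    keep <- !labels %in% small
    counts <- counts[, keep, drop = FALSE]
    labels <- droplevels(labels[keep])
  }
  assert_that(nlevels(labels) >= 2, "need at least 2 supervision groups")
  totals <- Matrix::colSums(counts)
  universe <- rownames(counts)[
    Matrix::rowSums(counts > 0) >= config$de_universe_min_cells]
  dense <- as.matrix(counts[universe, , drop = FALSE])
  p <- vapply(seq_along(universe), function(i)
    nb_lrt(dense[i, ], labels, totals)$p, numeric(1))
  tab <- tibble(gene = universe, p = p) |> arrange(.data$p, .data$gene)
  excl <- Reduce(`|`, lapply(config$exclude_patterns, grepl, x = tab$gene))
  tab <- tab[!excl, ]
  structure(head(tab$gene, config$n_ordering_genes), table = tab)
}

#' Build a branch-aware centroid-MST pseudotime
#'
#' PCA (10 components) on the ordering genes, k-means centroids, a minimum
#' spanning tree over centroid Euclidean distances, and geodesic pseudotime
#' from a root centroid. A cell's pseudotime is its centroid's path distance
#' to the root plus the cell's projection along the incident tree edge.
#' States are the tree segments between branch nodes; branches are labeled
#' downstream of the first node of degree >= 3 on paths from the root.
#'
#' @param norm Normalized genes x cells matrix.
#' @param ordering_genes Genes defining the trajectory space.
#' @param n_centroids Number of k-means centroids (>= 3; default 12).
#' @param root Centroid id to root at, or `NULL` to pick the centroid with
#'   the lowest mean maturity-marker expression.
#' @param maturity_genes Markers of mature photoreceptors used for default
#'   root selection.
#' @param seed Seed for k-means.
#' @return A `conecod_trajectory` object: `cells` tibble (barcode,
#'   pseudotime, centroid, state, branch), `centroids`, `edges`, `mst`
#'   (igraph), `root`, `branch_node`.
#' @export
build_trajectory <- function(norm, ordering_genes, n_centroids = 12,
                             root = NULL,
                             maturity_genes = c("NR2E3", "SAG", "RHO", "GNAT1",
                                                "ARR3", "OPN1SW", "OPN1MW"),
                             seed = 1L) {
  assert_that(n_centroids >= 3, "n_centroids must be >= 3")
  ordering_genes <- intersect(ordering_genes, rownames(norm))
  emb <- pca_embed(norm, ordering_genes, 10)
  set.seed(seed)
  km <- suppressWarnings(kmeans(emb, centers = min(n_centroids, nrow(emb)),
                                nstart = 10, iter.max = 100))
  centers <- km$centers[sort(unique(km$cluster)), , drop = FALSE]
  ids <- seq_len(nrow(centers))
  rownames(centers) <- ids
  d <- as.matrix(dist(centers))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  deg_all <- igraph::degree(mst)
  mat <- intersect(maturity_genes, rownames(norm))
  maturity <- if (length(mat) > 0) {
    vapply(ids, function(k)
      mean(Matrix::rowMeans(norm[mat, km$cluster == k, drop = FALSE])),
      numeric(1))
  } else NULL
  if (is.null(root)) {
    assert_that(!is.null(maturity),
                "no maturity gene present; give an explicit root")
    # root at a leaf of the tree: the immature end of the trajectory, not a
    # mid-path or junction centroid
    leaves <- ids[deg_all[as.character(ids)] == 1]
    root <- leaves[which.min(maturity[leaves])]
  }
  root <- as.integer(root)
  dist_root <- igraph::distances(mst, v = as.character(root))[1, ]
  dist_root <- dist_root[as.character(ids)]
  # parent of each centroid on its path to the root
  parent <- rep(NA_integer_, length(ids))
  for (k in ids) {
    if (k == root) next
    path <- igraph::shortest_paths(mst, from = as.character(k),
                                   to = as.character(root))$vpath[[1]]
    parent[k] <- as.integer(igraph::as_ids(path)[2])
  }
  # branch labeling: among junction centroids (degree >= 3), find the one
  # where two substantial downstream subtrees both look like maturing fates.
  # Candidate subtrees must hold >= 10% of cells (noisy trunk side-stubs stay
  # labeled trunk); with maturity markers available the junction maximizing
  # the smaller subtree's mean maturity wins (the split into the two mature
  # fates), otherwise the junction with the largest second subtree.
  deg <- deg_all
  cluster_sizes <- tabulate(km$cluster, nbins = length(ids))
  n_cells_all <- sum(cluster_sizes)
  junctions <- setdiff(ids[deg[as.character(ids)] >= 3], root)
  branch_node <- NA_integer_
  best_score <- -Inf
  best_subtrees <- NULL
  for (j in junctions) {
    cut <- igraph::delete_vertices(mst, as.character(j))
    comp <- igraph::components(cut)$membership
    root_comp <- comp[as.character(root)]
    subtrees <- lapply(setdiff(unique(comp), root_comp), function(cmp)
      as.integer(names(comp)[comp == cmp]))
    if (length(subtrees) < 2) next
    sizes <- vapply(subtrees, function(m) sum(cluster_sizes[m]), numeric(1))
    eligible <- sizes >= 0.1 * n_cells_all
    if (sum(eligible) < 2) next
    subtrees <- subtrees[eligible]; sizes <- sizes[eligible]
    if (!is.null(maturity)) {
      mat_sub <- vapply(subtrees, function(m)
        sum(maturity[m] * cluster_sizes[m]) / sum(cluster_sizes[m]),
        numeric(1))
      pick <- order(mat_sub, decreasing = TRUE)[1:2]
      score <- min(mat_sub[pick])
    } else {
      pick <- order(sizes, decreasing = TRUE)[1:2]
      score <- min(sizes[pick])
    }
    if (score > best_score) {
      best_score <- score
      branch_node <- j
      best_subtrees <- subtrees[pick]
    }
  }
  branch <- rep("trunk", length(ids))
  if (!is.na(branch_node)) {
    branch[best_subtrees[[1]]] <- "branch_1"
    branch[best_subtrees[[2]]] <- "branch_2"
  }
  # states: contiguous tree segments delimited by branch nodes and the root
  state <- assign_states(mst, ids, root, deg)
  # per-cell pseudotime: centroid distance + projection on incident edge
  pt <- numeric(nrow(emb))
  for (k in ids) {
    cells_k <- which(km$cluster == k)
    if (length(cells_k) == 0) next
    if (k == root) {
      nbr <- as.integer(igraph::as_ids(igraph::neighbors(mst, as.character(k))))
      u <- centers[as.character(nbr[1]), ] - centers[as.character(k), ]
    } else {
      u <- centers[as.character(k), ] - centers[as.character(parent[k]), ]
    }
    u <- u / sqrt(sum(u^2))
    proj <- as.numeric((emb[cells_k, , drop = FALSE] -
                          matrix(centers[as.character(k), ],
                                 nrow = length(cells_k),
                                 ncol = ncol(centers), byrow = TRUE)) %*% u)
    pt[cells_k] <- pmax(0, dist_root[k] + proj)
  }
  edges <- igraph::as_data_frame(mst, "edges")
  cells <- tibble(
    barcode = colnames(norm),
    pseudotime = pt,
    centroid = as.integer(km$cluster),
    state = state[km$cluster],
    branch = branch[km$cluster]
  )
  structure(list(cells = cells, centroids = centers,
                 edges = as_tibble(edges), mst = mst, root = root,
                 branch_node = branch_node,
                 centroid_pseudotime = dist_root,
                 embedding = emb),
            class = "conecod_trajectory")
}

# Segment the MST into states: edges grouped into maximal root-directed paths
# broken at branch points.
assign_states <- function(mst, ids, root, deg) {
  state <- rep(NA_integer_, length(ids))
  state[root] <- 1L
  next_state <- 1L
  # BFS from root; a child starts a new state when its parent is a branch
  # point (degree >= 3) or is the root with degree >= 2
  bfs <- igraph::bfs(mst, root = as.character(root), father = TRUE)
  ord <- as.integer(igraph::as_ids(bfs$order))
  fathers <- as.integer(igraph::as_ids(bfs$father))
  names(fathers) <- igraph::as_ids(igraph::V(mst))
  for (k in ord) {
    if (k == root) next
    f <- fathers[as.character(k)]
    if (is.na(state[f]) || deg[as.character(f)] >= 3 || f == root) {
      next_state <- next_state + 1L
      state[k] <- next_state
    } else {
      state[k] <- state[f]
    }
  }
  state
}

#' @export
print.conecod_trajectory <- function(x, ...) {
  cat(sprintf("Centroid-MST trajectory: %d cells, %d centroids, root %d\n",
              nrow(x$cells), nrow(x$centroids), x$root))
  if (!is.na(x$branch_node))
    cat(sprintf("  branch node: centroid %d; branches: %s\n", x$branch_node,
                paste(setdiff(unique(x$cells$branch), "trunk"), collapse = ", ")))
  cat(sprintf("  pseudotime range: %.2f - %.2f\n",
              min(x$cells$pseudotime), max(x$cells$pseudotime)))
  invisible(x)
}

#' Branch-node differential expression
#'
#' Per-gene NB likelihood-ratio test of a branch indicator (with log-total
#' offset) between the cells of two branches, with Benjamini-Hochberg
#' q-values; returns all tested genes plus the top `top_n` non-ribosomal
#' genes for heatmap export.
#'
#' @param counts Raw genes x cells matrix.
#' @param trajectory A [build_trajectory()] result.
#' @param branch_a,branch_b Branch labels (or state ids given as integers) of
#'   the two branches.
#' @param top_n Size of the non-ribosomal heatmap set.
#' @param de_universe_min_cells Universe prefilter as in DE.
#' @return Tibble: gene, mean_a, mean_b, p, q, top; heatmap genes in
#'   attribute `heatmap_genes`.
#' @export
branch_de <- function(counts, trajectory, branch_a, branch_b, top_n = 100,
                      de_universe_min_cells = 10) {
  counts <- check_counts(counts)
  cells <- trajectory$cells
  pick <- function(b) {
    if (is.numeric(b)) cells$barcode[cells$state %in% b]
    else cells$barcode[cells$branch %in% b]
  }
  a <- pick(branch_a); b <- pick(branch_b)
  if (length(a) == 0 || length(b) == 0)
    stop_conecod("empty branch", class = "conecod_validation_error")
  sub <- counts[, c(a, b), drop = FALSE]
  grp <- factor(rep(c("A", "B"), c(length(a), length(b))))
  totals <- Matrix::colSums(sub)
  universe <- rownames(sub)[Matrix::rowSums(sub > 0) >= de_universe_min_cells]
  dense <- as.matrix(sub[universe, , drop = FALSE])
  sf <- totals / mean(totals)
  res <- purrr::map_dfr(seq_along(universe), function(i) {
    y <- dense[i, ]
    tibble(gene = universe[i],
           mean_a = mean(y[grp == "A"] / sf[grp == "A"]),
           mean_b = mean(y[grp == "B"] / sf[grp == "B"]),
           p = nb_lrt(y, grp, totals)$p)
  })
  res <- res |> mutate(q = p.adjust(.data$p, "BH")) |>
    arrange(.data$p, .data$gene)
  heat <- res |> filter(!is_ribosomal(.data$gene)) |> head(top_n)
  res |>
    mutate(top = .data$gene %in% heat$gene) |>
    structure(heatmap_genes = heat$gene)
}
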