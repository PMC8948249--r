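# Dispersion-based gene selection, PCA embedding, Louvain clustering on a
# k-NN graph, centroid-MST principal-tree pseudotime, and Moran's I
# spatial-autocorrelation differential expression with permutation p-values.

#' Select highly dispersed genes
#'
#' Estimates a per-gene NB-style overdispersion `(var - mean) / mean^2` on
#' normalized expression and fits the technical mean-dispersion trend
#' `b0 + b1 / mean` on the trimmed baseline (the lower half of dispersions,
#' which under a shared technical dispersion is free of structured genes).
#' A gene is selected when its dispersion exceeds the trend by more than the
#' `dispersion_quantile` quantile of the baseline's absolute scatter around
#' the trend. Deterministic; raising the quantile never enlarges the
#' selection.
#'
#' @param norm A `NormalizedMatrix` (or `CountMatrix`).
#' @param min_mean Minimum mean expression for eligibility.
#' @param dispersion_quantile Quantile of the trend scatter used as the
#'   selection margin, in [0, 1).
#' @return Character vector of selected gene symbols.
#' @export
select_genes_by_dispersion <- function(norm, min_mean = 0.05,
                                       dispersion_quantile = 0.75) {
  if (dispersion_quantile < 0 || dispersion_quantile >= 1)
    stop("dispersion_quantile must be in [0, 1)")
  m <- Matrix::rowMeans(norm)
  ex2 <- Matrix::rowMeans(norm^2)
  v <- (ex2 - m^2) * ncol(norm) / max(1, ncol(norm) - 1)
  disp <- ifelse(m > 0, (v - m) / m^2, -Inf)
  eligible <- which(m >= min_mean & v > 0 & is.finite(disp) & disp > 0)
  if (!length(eligible)) {
    warning("no eligible genes for dispersion selection")
    return(character())
  }
  d <- disp[eligible]
  inv_m <- 1 / m[eligible]
  baseline <- d <= stats::quantile(d, 0.5, names = FALSE, type = 7)
  if (sum(baseline) >= 10) {
    fit <- tryCatch(MASS::rlm(d[baseline] ~ inv_m[baseline], maxit = 100),
                    error = function(e)
                      stats::lm(d[baseline] ~ inv_m[baseline]))
    b <- stats::coef(fit)
    trend <- pmax(b[1] + b[2] * inv_m, 0)
    scatter <- abs(d[baseline] - trend[baseline])
  } else {
    trend <- rep(stats::median(d[baseline]), length(d))
    scatter <- abs(d[baseline] - trend[1])
  }
  margin <- stats::quantile(scatter, dispersion_quantile, names = FALSE,
                            type = 7)
  sel <- eligible[d > trend + margin]
  genes <- rownames(norm)[sort(sel)]
  if (length(genes) < 10)
    warning("fewer than 10 genes selected by dispersion")
  genes
}

#' Embed cells by principal components
#'
#' log1p-transforms the normalized expression of the selected genes and
#' projects cells onto the top principal components. Deterministic (PCA
#' signs are fixed so the largest-magnitude loading of each component is
#' positive); the seed is part of the interface for pluggable embeddings.
#'
#' @param norm A `NormalizedMatrix`.
#' @param selected_genes Genes to embed on (default: all).
#' @param n_pcs Number of components (must be <= min(dims)).
#' @param seed Unused by PCA; kept for interface stability.
#' @return Matrix cells x n_pcs with attribute `variance_explained`.
#' @export
embed_cells <- function(norm, selected_genes = rownames(norm), n_pcs = 10,
                        seed = 1L) {
  selected_genes <- intersect(selected_genes, rownames(norm))
  x <- t(as.matrix(log1p(norm[selected_genes, , drop = FALSE])))
  if (n_pcs > min(dim(x)))
    stop("n_pcs = ", n_pcs, " exceeds min(dim) = ", min(dim(x)))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  coords <- sweep(pc$x, 2, flip, `*`)
  rownames(coords) <- colnames(norm)
  attr(coords, "variance_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[
    seq_len(ncol(coords))]
  coords
}

#' Symmetric k-nearest-neighbor graph over an embedding
#'
#' Binary weights, symmetrized by union, zero diagonal; the substrate for
#' Moran's I spatial-correlation tests.
#'
#' @param embedding Matrix cells x dims.
#' @param k Number of neighbors (default 15; must be < n cells).
#' @return Object of class `neighbor_graph`: list with `w` (sparse symmetric
#'   0/1 matrix), `W` (sum of weights) and `n`.
#' @export
knn_graph <- function(embedding, k = 15) {
  n <- nrow(embedding)
  if (k >= n) stop("k_neighbors must be smaller than the number of cells")
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  idx <- apply(d, 1, function(row) order(row)[seq_len(k)])
  i <- rep(seq_len(n), each = k)
  j <- as.integer(idx)
  w <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  w <- methods::as((w + Matrix::t(w)) > 0, "dMatrix") * 1
  w <- methods::as(w, "CsparseMatrix")
  Matrix::diag(w) <- 0
  w <- Matrix::drop0(w)
  dimnames(w) <- list(rownames(embedding), rownames(embedding))
  structure(list(w = w, W = sum(w), n = n), class = "neighbor_graph")
}

#' Construct a neighbor graph from an explicit weight matrix
#' @param w Symmetric non-negative weight matrix with zero diagonal.
#' @export
neighbor_graph <- function(w) {
  w <- methods::as(methods::as(w, "generalMatrix"), "CsparseMatrix")
  if (!Matrix::isSymmetric(w)) stop("weights must be symmetric")
  if (any(Matrix::diag(w) != 0)) stop("diagonal weights must be zero")
  if (length(w@x) && any(w@x < 0)) stop("weights must be non-negative")
  if (any(Matrix::rowSums(w != 0) == 0))
    stop("every cell needs at least one neighbor")
  structure(list(w = w, W = sum(w), n = nrow(w)), class = "neighbor_graph")
}

#' Louvain clustering of cells
#'
#' Community detection on the k-NN graph of the embedding. Because a k-NN
#' graph discards distance scale, Louvain partitions even a single
#' unstructured blob; communities that are not separated in the embedding
#' (centroid distance below `merge_factor` times the sum of their RMS radii)
#' are therefore merged afterwards. Labels are integers ordered by
#' descending cluster size (label 1 = largest).
#'
#' @param embedding Matrix cells x dims.
#' @param k_neighbors Neighbors for the graph (default 15).
#' @param resolution Louvain resolution (default 1).
#' @param seed RNG seed (Louvain is randomized).
#' @param merge_factor Separation threshold for the merge step (0 disables).
#'   Adjacent tiles of a single Gaussian cluster sit at centroid-distance /
#'   radius-sum ratios up to about 1.6, while genuinely distinct populations
#'   exceed 2, hence the 1.75 default.
#' @return Named integer vector of cluster labels.
#' @export
cluster_cells <- function(embedding, k_neighbors = 15, resolution = 1,
                          seed = 1L, merge_factor = 1.75) {
  if (nrow(embedding) < 3) stop("need at least 3 cells to cluster")
  g <- knn_graph(embedding, k = min(k_neighbors, nrow(embedding) - 1))
  ig <- igraph::graph_from_adjacency_matrix(g$w, mode = "undirected",
                                            weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(ig, resolution = resolution)
  raw <- as.integer(igraph::membership(comm))
  raw <- merge_unseparated(embedding, raw, merge_factor)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  stats::setNames(as.integer(relabel[as.character(raw)]),
                  rownames(embedding))
}

# Iteratively merge cluster pairs whose centroids are closer than
# merge_factor * (rms radius_i + rms radius_j).
merge_unseparated <- function(embedding, labels, merge_factor) {
  if (merge_factor <= 0) return(labels)
  repeat {
    labs <- sort(unique(labels))
    if (length(labs) < 2) return(labels)
    cents <- t(vapply(labs, function(k)
      colMeans(embedding[labels == k, , drop = FALSE]),
      numeric(ncol(embedding))))
    radii <- vapply(seq_along(labs), function(i) {
      x <- embedding[labels == labs[i], , drop = FALSE]
      sqrt(mean(rowSums(sweep(x, 2, cents[i, ])^2)))
    }, numeric(1))
    d <- as.matrix(stats::dist(cents))
    lim <- outer(radii, radii, `+`) * merge_factor
    ratio <- d / lim
    diag(ratio) <- Inf
    if (min(ratio) >= 1) return(labels)
    ij <- which(ratio == min(ratio), arr.ind = TRUE)[1, ]
    labels[labels == labs[ij[2]]] <- labs[ij[1]]
  }
}

#' Principal-tree pseudotime
#'
#' Learns a SimplePPT-style principal tree: a minimum-spanning tree over
#' centroids (k-means by default, or the centroids of supplied cluster
#' labels), projects every cell onto its nearest tree segment, and takes
#' pseudotime as the geodesic distance along the tree from the root cell's
#' projection, rescaled to [0, 1]. The root is the cell given by
#' `root_barcode`, or the cell maximizing `root_score` (e.g. an arterial-EC
#' gene-set score).
#'
#' @param embedding Matrix cells x dims.
#' @param root_score Per-cell numeric; the maximizing cell roots the tree.
#' @param root_barcode Explicit root (overrides `root_score`).
#' @param clusters Optional integer labels whose centroids form the tree
#'   nodes; default: k-means centroids.
#' @param n_centers Number of k-means centroids when `clusters` is NULL.
#' @param seed Seed for k-means.
#' @return List of class `trajectory_result`: `pseudotime` (named, in
#'   [0, 1], root = 0), `root`, `tree` (igraph), `centroids`.
#' @export
learn_pseudotime <- function(embedding, root_score = NULL,
                             root_barcode = NULL, clusters = NULL,
                             n_centers = 10, seed = 1L) {
  n <- nrow(embedding)
  if (is.null(root_barcode)) {
    if (is.null(root_score))
      stop("supply root_score or root_barcode")
    if (length(root_score) != n) stop("root_score must have one value per cell")
    root_barcode <- rownames(embedding)[which.max(root_score)]
  }
  if (!root_barcode %in% rownames(embedding))
    stop("root barcode not found: ", root_barcode)
  # normalize the coordinate scale so pseudotime is exactly invariant to
  # uniform scaling of the embedding
  scale0 <- sqrt(mean(embedding^2))
  if (scale0 > 0) embedding <- embedding / scale0
  if (is.null(clusters)) {
    set.seed(seed)
    n_centers <- min(n_centers, n)
    km <- stats::kmeans(embedding, centers = n_centers, nstart = 5,
                        iter.max = 100)
    centroids <- km$centers
  } else {
    if (length(clusters) != n) stop("need one cluster label per cell")
    centroids <- do.call(rbind, lapply(split(seq_len(n), clusters),
                                       function(i)
                                         colMeans(embedding[i, , drop = FALSE])))
  }
  k <- nrow(centroids)
  if (k < 2) {
    pt <- stats::setNames(rep(0, n), rownames(embedding))
    return(structure(list(pseudotime = pt, root = root_barcode,
                          tree = NULL, centroids = centroids),
                     class = "trajectory_result"))
  }
  dc <- as.matrix(stats::dist(centroids))
  ig <- igraph::graph_from_adjacency_matrix(dc, mode = "undirected",
                                            weighted = TRUE)
  tree <- igraph::mst(ig)
  edges <- igraph::as_edgelist(tree, names = FALSE)
  # project each cell to its nearest segment
  proj <- project_to_segments(embedding, centroids, edges)
  # geodesic node distances along the tree
  nd <- igraph::distances(tree, weights = igraph::E(tree)$weight)
  # arc length between each projection and the root cell's projection
  ri <- which(rownames(embedding) == root_barcode)
  pt <- point_to_point_geodesic(proj, nd, edges, ri)
  mx <- max(pt)
  pt <- if (mx > 0) pt / mx else pt
  structure(list(pseudotime = stats::setNames(pt, rownames(embedding)),
                 root = root_barcode, tree = tree, centroids = centroids),
            class = "trajectory_result")
}

# For each cell: nearest tree segment (edge index), projection parameter t
# (fraction of the way from endpoint a to b, clamped to [0,1] at interior
# nodes but unclamped past leaves so terminal segments extend outward), and
# segment length.
project_to_segments <- function(embedding, centroids, edges) {
  n <- nrow(embedding)
  ne <- nrow(edges)
  deg <- tabulate(as.integer(edges), nbins = nrow(centroids))
  best_d2 <- rep(Inf, n)
  out <- data.frame(edge = integer(n), t = numeric(n), len = numeric(n))
  for (e in seq_len(ne)) {
    a <- centroids[edges[e, 1], ]; b <- centroids[edges[e, 2], ]
    ab <- b - a
    len2 <- sum(ab^2)
    diff <- sweep(embedding, 2, a)
    tt <- if (len2 > 0) as.numeric(diff %*% ab) / len2 else rep(0, n)
    lo <- if (deg[edges[e, 1]] == 1) -Inf else 0
    hi <- if (deg[edges[e, 2]] == 1) Inf else 1
    tt <- pmin(hi, pmax(lo, tt))
    px <- outer(tt, ab)
    d2 <- rowSums((diff - px)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    out$edge[upd] <- e
    out$t[upd] <- tt[upd]
    out$len[upd] <- sqrt(len2)
  }
  out
}

# Geodesic distance along the tree between every cell's projection point and
# the root cell's projection point.
point_to_point_geodesic <- function(proj, nd, edges, root_idx) {
  rp <- proj[root_idx, ]
  ra <- edges[rp$edge, 1]; rb <- edges[rp$edge, 2]
  rda <- abs(rp$t) * rp$len        # root point to endpoint a of its edge
  rdb <- abs(1 - rp$t) * rp$len    # root point to endpoint b
  n <- nrow(proj)
  d <- numeric(n)
  for (i in seq_len(n)) {
    p <- proj[i, ]
    if (p$edge == rp$edge) {
      d[i] <- abs(p$t - rp$t) * p$len
      next
    }
    a <- edges[p$edge, 1]; b <- edges[p$edge, 2]
    da <- abs(p$t) * p$len; db <- abs(1 - p$t) * p$len
    d[i] <- min(da + nd[a, ra] + rda, da + nd[a, rb] + rdb,
                db + nd[b, ra] + rda, db + nd[b, rb] + rdb)
  }
  d
}

#' Moran's I spatial autocorrelation
#'
#' `I = (N / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' computed exactly on the neighbor graph.
#'
#' @param values Per-cell numeric vector (not all equal).
#' @param graph A `neighbor_graph`.
#' @return The statistic (scalar).
#' @export
morans_i <- function(values, graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  if (length(values) != graph$n)
    stop("need one value per cell")
  xc <- values - mean(values)
  ss <- sum(xc^2)
  if (ss == 0) stop("zero variance: Moran's I is undefined for a constant vector")
  num <- as.numeric(xc %*% (graph$w %*% xc))
  (graph$n / graph$W) * num / ss
}

# Moran's I for many genes at once: rows of X are gene expression vectors.
morans_i_rows <- function(X, graph) {
  xc <- X - rowMeans(X)
  ss <- rowSums(xc^2)
  num <- rowSums((xc %*% graph$w) * xc)
  ifelse(ss > 0, (graph$n / graph$W) * num / ss, NA_real_)
}

#' Benjamini-Hochberg adjusted q-values
#' @param p Numeric p-values.
#' @return q-values (monotone step-up).
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Differential expression over the trajectory (Moran's I permutation test)
#'
#' Tests genes detected in more than `min_detect_frac` of cells (strict >)
#' for spatial autocorrelation of log1p normalized expression on the cell
#' neighbor graph. P-values are upper-tail permutation p-values (a common
#' column permutation per iteration), adjusted by Benjamini-Hochberg;
#' direction is the sign of the Spearman correlation with pseudotime.
#'
#' @param counts A `CountMatrix` (detection fractions).
#' @param norm The matching `NormalizedMatrix`.
#' @param graph A `neighbor_graph` over the same cells.
#' @param pseudotime Per-cell pseudotime (for the direction sign).
#' @param min_detect_frac Detection fraction threshold (strict >).
#' @param q_max Significance cutoff on the BH q-value.
#' @param n_permutations Number of permutations (>= 100).
#' @param seed Permutation seed.
#' @return data.frame: gene, morans_i, p_value, q_value, detected_fraction,
#'   direction ("early" for decreasing, "late" for increasing, "ns"),
#'   significant.
#' @export
trajectory_de <- function(counts, norm, graph, pseudotime,
                          min_detect_frac = 0.05, q_max = 0.01,
                          n_permutations = 999, seed = 1L) {
  if (n_permutations < 100)
    stop("n_permutations must be at least 100")
  stopifnot(inherits(graph, "neighbor_graph"), graph$n == ncol(counts))
  det_frac <- Matrix::rowMeans(counts >= 1)
  keep <- which(det_frac > min_detect_frac)
  if (!length(keep))
    stop("no gene passes the detection-fraction filter")
  X <- as.matrix(log1p(norm[keep, , drop = FALSE]))
  variable <- apply(X, 1, function(x) stats::var(x) > 0)
  X <- X[variable, , drop = FALSE]
  keep <- keep[variable]
  obs <- morans_i_rows(X, graph)
  set.seed(seed)
  exceed <- rep(0L, nrow(X))
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(ncol(X))
    exceed <- exceed + (morans_i_rows(X[, perm, drop = FALSE], graph) >=
                          obs - 1e-12)
  }
  p <- (1 + exceed) / (n_permutations + 1)
  q <- bh_adjust(p)
  rho <- suppressWarnings(apply(X, 1, function(x)
    stats::cor(x, pseudotime, method = "spearman")))
  sig <- q < q_max
  data.frame(gene = rownames(norm)[keep],
             morans_i = as.numeric(obs),
             p_value = p, q_value = q,
             detected_fraction = as.numeric(det_frac[keep]),
             direction = ifelse(!sig | is.na(rho), "ns",
                                ifelse(rho > 0, "late", "early")),
             significant = sig,
             stringsAsFactors = FALSE)
}

#' Cluster marker genes by Moran's I and specificity
#'
#' `specificity(g, k) = mean_norm(g, k) / sum_k' mean_norm(g, k')`; a gene
#' marks the cluster where its specificity is maximal iff its Moran's I on
#' the cell graph is >= `morans_min` and that specificity is > `specificity_min`.
#'
#' @param counts A `CountMatrix`.
#' @param norm The matching `NormalizedMatrix`.
#' @param graph A `neighbor_graph` over the same cells.
#' @param clusters Integer labels, >= 2 non-empty clusters.
#' @param morans_min Moran's I threshold (default 0.25).
#' @param specificity_min Specificity threshold, strict > (default 0.75).
#' @return data.frame: gene, cluster (of max specificity), morans_i,
#'   specificity, is_marker.
#' @export
cluster_markers <- function(counts, norm, graph, clusters,
                            morans_min = 0.25, specificity_min = 0.75) {
  if (length(clusters) != ncol(norm)) stop("need one cluster label per cell")
  labs <- if (is.factor(clusters)) levels(clusters) else
    sort(unique(clusters))
  if (length(labs) < 2) stop("need at least 2 clusters")
  if (any(table(factor(clusters, levels = labs)) == 0))
    stop("empty cluster: ",
         paste(labs[table(factor(clusters, levels = labs)) == 0],
               collapse = ", "))
  means <- vapply(labs, function(k)
    Matrix::rowMeans(norm[, clusters == k, drop = FALSE]),
    numeric(nrow(norm)))
  tot <- rowSums(means)
  spec <- means / ifelse(tot > 0, tot, NA_real_)
  best <- max.col(replace(spec, is.na(spec), -Inf), ties.method = "first")
  X <- as.matrix(log1p(norm))
  variable <- apply(X, 1, function(x) stats::var(x) > 0)
  mi <- rep(NA_real_, nrow(norm))
  mi[variable] <- morans_i_rows(X[variable, , drop = FALSE], graph)
  best_spec <- spec[cbind(seq_len(nrow(spec)), best)]
  data.frame(gene = rownames(norm),
             cluster = labs[best],
             morans_i = mi,
             specificity = as.numeric(best_spec),
             is_marker = !is.na(mi) & !is.na(best_spec) &
               mi >= morans_min & best_spec > specificity_min,
             stringsAsFactors = FALSE)
}

#' Pseudotime-enrichment category of a gene
#'
#' For a gene that varies significantly over pseudotime within the masked
#' cells, splits those cells at their median pseudotime and categorizes the
#' gene as "early" (mean normalized expression higher in the early half,
#' e.g. enriched in HE over pre-HSC) or "late"; non-significant genes are
#' "ns".
#'
#' @param gene Gene symbol.
#' @param norm A `NormalizedMatrix`.
#' @param pseudotime Per-cell pseudotime.
#' @param cell_mask Logical or index mask (>= 10 cells).
#' @param significant Whether the gene passed [trajectory_de()] within the
#'   masked cells.
#' @return "early", "late" or "ns".
#' @export
pseudotime_enrichment <- function(gene, norm, pseudotime, cell_mask,
                                  significant = TRUE) {
  idx <- if (is.logical(cell_mask)) which(cell_mask) else cell_mask
  if (length(idx) < 10) stop("cell mask must cover at least 10 cells")
  if (!significant) return("ns")
  if (!gene %in% rownames(norm)) stop("gene not in matrix: ", gene)
  x <- as.numeric(norm[gene, idx])
  pt <- pseudotime[idx]
  early <- pt <= stats::median(pt)
  if (mean(x[early]) > mean(x[!early])) "early" else "late"
}
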