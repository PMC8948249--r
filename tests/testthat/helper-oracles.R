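# Independent oracles used across the suite. Each is coded naively (loops,
# enumeration) and must stay independent of the package implementation it
# checks.

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Moran's I by the naive double loop over all (i, j) pairs
naive_morans_i <- function(x, w) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      num <- num + w[i, j] * (x[i] - xb) * (x[j] - xb)
  (n / sum(w)) * num / sum((x - xb)^2)
}

# Benjamini-Hochberg step-up coded from the definition
bh_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# random connected symmetric 0/1 adjacency on n nodes (ring + extra edges)
random_graph_adjacency <- function(n, extra = n) {
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    w[i, j] <- w[j, i] <- 1
  }
  for (k in seq_len(extra)) {
    ij <- sample(n, 2)
    w[ij[1], ij[2]] <- w[ij[2], ij[1]] <- 1
  }
  diag(w) <- 0
  w
}

# boolean marker-rule predicate coded directly from the rule definition
rule_oracle <- function(det, rule) {
  all_ok <- if (length(rule$required_all))
    all(det[rule$required_all]) else TRUE
  any_ok <- if (length(rule$required_any))
    any(det[rule$required_any]) else TRUE
  forb_ok <- if (length(rule$forbidden))
    !any(det[rule$forbidden]) else TRUE
  all_ok && any_ok && forb_ok
}

# small dense CountMatrix from a base matrix
cm_from <- function(m, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(cells)) cells <- paste0("c", seq_len(ncol(m)))
  count_matrix(m, gene_symbols = genes, barcodes = cells)
}

# a small fast simulation configuration for unit tests
small_sim_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_genes = 150L, n_cells_per_type = 40L,
               niche_n_cells = 60L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
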