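# fixtures and independent oracles shared across the suite

zs <- function(v) (v - mean(v)) / sd(v)

# noiseless 60-point sample of each canonical shape, standardized
canonical_cloud <- function(type, n = 60, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- seq(-1, 1, length.out = n)
  xe <- seq(0, 3, length.out = n)
  xl <- seq(0.1, 3, length.out = n)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  base <- switch(type,
    LIN_POS = cbind(zs(x), zs(x)),
    LIN_NEG = cbind(zs(x), zs(-x)),
    EXP_POS = cbind(zs(xe), zs(exp(xe))),
    EXP_NEG = cbind(zs(xe), zs(-exp(xe))),
    LOG_POS = cbind(zs(xl), zs(log(xl))),
    LOG_NEG = cbind(zs(xl), zs(-log(xl))),
    QUAD_POS = cbind(zs(x), zs(x^2)),
    QUAD_NEG = cbind(zs(x), zs(-x^2)),
    CUBIC_POS = cbind(zs(x), zs(x^3)),
    CUBIC_NEG = cbind(zs(x), zs(-x^3)),
    SIDE_QUAD_POS = cbind(zs(x^2), zs(x)),
    SIDE_QUAD_NEG = cbind(zs(-x^2), zs(x)),
    CLOSED = cbind(zs(cos(th)), zs(sin(th))),
    stop("unknown canonical type: ", type))
  if (noise_sd > 0)
    base <- cbind(zs(base[, 1] + rnorm(n, 0, noise_sd)),
                  zs(base[, 2] + rnorm(n, 0, noise_sd)))
  base
}

# the ten shapes named by the canonical function list (plus ln x)
CANONICAL10 <- c("LIN_POS", "LIN_NEG", "EXP_POS", "EXP_NEG", "LOG_POS",
                 "LOG_NEG", "QUAD_POS", "QUAD_NEG", "CUBIC_POS", "CLOSED")

# independent oracle: squared distances to a polyline by brute force over
# a dense resampling of every segment
brute_dist2_polyline <- function(points, P, per_seg = 200) {
  dense <- do.call(rbind, lapply(seq_len(nrow(P) - 1), function(i) {
    t <- seq(0, 1, length.out = per_seg)
    cbind(P[i, 1] + t * (P[i + 1, 1] - P[i, 1]),
          P[i, 2] + t * (P[i + 1, 2] - P[i, 2]))
  }))
  vapply(seq_len(nrow(points)), function(j) {
    min((dense[, 1] - points[j, 1])^2 + (dense[, 2] - points[j, 2])^2)
  }, numeric(1))
}

# independent oracle: all maximal cliques of size >= min_size by exhaustive
# subset enumeration (n <= 12)
brute_max_cliques <- function(adj_mat, min_size = 3) {
  n <- nrow(adj_mat)
  stopifnot(n <= 14)
  subsets <- lapply(seq_len(2^n - 1), function(mask) which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0))
  is_clique <- vapply(subsets, function(s) {
    if (length(s) < 2) return(TRUE)
    all(adj_mat[t(combn(s, 2))] == 1)
  }, logical(1))
  cl <- subsets[is_clique]
  maximal <- vapply(seq_along(cl), function(i) {
    s <- cl[[i]]
    ext <- setdiff(seq_len(n), s)
    !any(vapply(ext, function(v) all(adj_mat[v, s] == 1), logical(1)))
  }, logical(1))
  out <- cl[maximal & lengths(cl) >= min_size]
  out[order(vapply(out, paste, character(1), collapse = ","))]
}

# independent oracle: exhaustive permutation search for an isomorphic and
# linear bijection between two labelled cliques
brute_match <- function(genes_a, genes_b, coex_pairs, types) {
  if (length(genes_a) != length(genes_b)) return(NULL)
  coex_key <- apply(coex_pairs, 1, function(r) paste(sort(r), collapse = "|"))
  ok_coex <- function(u, v) paste(sort(c(u, v)), collapse = "|") %in% coex_key
  otype <- function(u, v) {
    key <- paste(sort(c(u, v)), collapse = "|")
    t <- types[[key]]
    if (is.null(t)) return(NA_character_)
    if (u < v) t else transpose_type(t)
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  k <- length(genes_a)
  for (p in perms(genes_b)) {
    valid <- all(vapply(seq_len(k), function(i) ok_coex(genes_a[i], p[i]),
                        logical(1)))
    if (valid && k >= 2) {
      prs <- combn(k, 2)
      valid <- all(vapply(seq_len(ncol(prs)), function(q) {
        i <- prs[1, q]; j <- prs[2, q]
        t1 <- otype(genes_a[i], genes_a[j])
        t2 <- otype(p[i], p[j])
        !is.na(t1) && !is.na(t2) && t1 == t2
      }, logical(1)))
    }
    if (valid) return(stats::setNames(p, genes_a))
  }
  NULL
}

# a small hand-built relationship table
toy_table <- function() {
  data.frame(
    gene_a = c("A1", "A1", "B1", "A2"),
    gene_b = c("A2", "B1", "B2", "B2"),
    f = c(0.01, 0.02, 0.015, 0.03),
    n_curvature_points = c(0L, 1L, 0L, 1L),
    curve_type = c("LIN_POS", "EXP_POS", "LIN_POS", "EXP_POS"),
    relation_class = c("linear", "nonlinear", "linear", "nonlinear"),
    stringsAsFactors = FALSE)
}

# study-condition synthetic dataset: 3 modules x 10 genes + 20 background
study_spec <- function(seed = 7) {
  network_spec(
    n_samples = 60,
    modules = list(
      list(n_genes = 10, noise_sd = 0.05, transform = "identity"),
      list(n_genes = 10, noise_sd = 0.05, transform = "exp"),
      list(n_genes = 10, noise_sd = 0.05, transform = "neg_log")),
    background_genes = 20, seed = seed)
}

# the full pipeline on the study dataset, computed once per test session
.e2e_cache <- new.env(parent = emptyenv())
e2e_result <- function(seed = 7) {
  key <- as.character(seed)
  if (is.null(.e2e_cache[[key]])) {
    ds <- gen_network_dataset(study_spec(seed))
    scan <- scan_all(ds$matrix)
    nets <- suppressWarnings(discover_networks(scan$table))
    .e2e_cache[[key]] <- list(ds = ds, scan = scan, nets = nets)
  }
  .e2e_cache[[key]]
}
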