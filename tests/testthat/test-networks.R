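# build a relationship table that plants k mutually matched transversal
# cliques over `n_mod` modules of `per_mod` genes: within-module pairs are
# linear, cross-module pairs nonlinear with a fixed type per module pair
planted_table <- function(n_mod = 3, per_mod = 4,
                          types = c("EXP_POS", "LOG_NEG", "QUAD_POS")) {
  genes <- unlist(lapply(seq_len(n_mod), function(m)
    sprintf("M%d_G%02d", m, seq_len(per_mod))))
  mod <- rep(seq_len(n_mod), each = per_mod)
  names(mod) <- genes
  pr <- t(combn(genes, 2))
  ma <- mod[pr[, 1]]; mb <- mod[pr[, 2]]
  tmap <- matrix(NA_character_, n_mod, n_mod)
  tmap[lower.tri(tmap)] <- types[seq_len(choose(n_mod, 2))]
  tmap <- t(tmap)
  data.frame(
    gene_a = pr[, 1], gene_b = pr[, 2],
    f = 0.01 + seq_len(nrow(pr)) * 1e-4,
    n_curvature_points = ifelse(ma == mb, 0L, 1L),
    curve_type = ifelse(ma == mb, "LIN_POS", tmap[cbind(pmin(ma, mb), pmax(ma, mb))]),
    relation_class = ifelse(ma == mb, "linear", "nonlinear"),
    stringsAsFactors = FALSE)
}

test_that("graphs split accepted pairs by class with disjoint edge sets", {
  tab <- toy_table()
  g <- build_graphs(tab)
  expect_equal(igraph::ecount(g$coexpression), 2)
  expect_equal(igraph::ecount(g$nonlinear), 2)
  e_co <- apply(igraph::as_edgelist(g$coexpression), 1,
                function(r) paste(sort(r), collapse = "|"))
  e_nl <- apply(igraph::as_edgelist(g$nonlinear), 1,
                function(r) paste(sort(r), collapse = "|"))
  expect_length(intersect(e_co, e_nl), 0)
  # empty table gives two empty graphs
  g0 <- build_graphs(toy_table()[0, ])
  expect_equal(igraph::ecount(g0$coexpression), 0)
  expect_equal(igraph::ecount(g0$nonlinear), 0)
})

test_that("maximal-clique enumeration matches brute-force subset search", {
  for (r in 1:30) {
    set.seed(4000 + r)
    n <- 12
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- rbinom(choose(n, 2), 1, 0.5)
    adj <- adj + t(adj)
    names <- sprintf("G%02d", seq_len(n))
    dimnames(adj) <- list(names, names)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    tab <- data.frame(gene_a = character(0), gene_b = character(0),
                      f = numeric(0), n_curvature_points = integer(0),
                      curve_type = character(0),
                      relation_class = character(0))
    got <- enumerate_gene_cliques(g, tab, min_size = 3, max_cliques = 5000)
    got_sets <- lapply(got, function(cl) match(cl$genes, names))
    want_sets <- brute_max_cliques(adj, min_size = 3)
    expect_equal(length(got_sets), length(want_sets))
    expect_setequal(vapply(got_sets, paste, character(1), collapse = ","),
                    vapply(want_sets, paste, character(1), collapse = ","))
  }
})

test_that("clique annotation carries canonical edge types and the cap warns", {
  tab <- planted_table()
  g <- build_graphs(tab)
  cl <- enumerate_gene_cliques(g$nonlinear, tab)
  expect_true(all(lengths(lapply(cl, `[[`, "genes")) == 3))
  c1 <- cl[[1]]
  expect_identical(unname(c1$edge_types[["M1_G01|M2_G01"]]), "EXP_POS")
  expect_warning(enumerate_gene_cliques(g$nonlinear, tab, max_cliques = 5),
                 "clique cap")
  # an edgeless graph yields no cliques
  g0 <- igraph::make_empty_graph(5, directed = FALSE)
  expect_length(enumerate_gene_cliques(g0, tab), 0)
})

test_that("isomorphic matching agrees with exhaustive permutation search", {
  pool <- c("EXP_POS", "EXP_NEG", "LOG_NEG", "QUAD_POS", "COMPLEX")
  n_found <- 0
  for (r in 1:50) {
    set.seed(7000 + r)
    k <- sample(3:6, 1)
    a <- sprintf("A%02d", seq_len(k))
    b <- sprintf("B%02d", seq_len(k))
    # random types on each clique's edges; half the time copy them so a
    # valid bijection is likely
    ta <- apply(combn(a, 2), 2, function(p) sample(pool, 1))
    copy <- r %% 2 == 0
    perm <- sample(k)
    tb <- if (copy) ta else apply(combn(b, 2), 2, function(p) sample(pool, 1))
    types <- c(stats::setNames(ta, apply(combn(a, 2), 2, paste, collapse = "|")))
    prb <- combn(b[perm], 2)
    keyb <- apply(prb, 2, function(p) paste(sort(p), collapse = "|"))
    valb <- vapply(seq_along(keyb), function(i) {
      if (prb[1, i] < prb[2, i]) tb[i] else transpose_type(tb[i])
    }, character(1))
    types <- c(types, stats::setNames(valb, keyb))
    # random sparse coexpression plus (when copying) the planted bijection
    coex <- cbind(sample(a, k, replace = TRUE), sample(b, k, replace = TRUE))
    if (copy) coex <- rbind(coex, cbind(a, b[perm]))
    coex <- unique(coex)
    g_co <- igraph::graph_from_data_frame(
      as.data.frame(coex), directed = FALSE,
      vertices = data.frame(name = c(a, b)))
    c1 <- structure(list(genes = a, edge_types = types), class = "GeneClique")
    c2 <- structure(list(genes = b, edge_types = types), class = "GeneClique")
    got <- match_isomorphic_pair(c1, c2, g_co, types)
    want <- brute_match(a, b, coex, as.list(types))
    expect_identical(is.null(got), is.null(want))
    if (!is.null(got)) {
      n_found <- n_found + 1
      # the returned bijection itself must be valid under the oracle's rules
      coex_key <- apply(coex, 1, function(x) paste(sort(x), collapse = "|"))
      for (i in seq_len(k))
        expect_true(paste(sort(c(a[i], got[[a[i]]])), collapse = "|") %in% coex_key)
    }
  }
  expect_gt(n_found, 5)  # the planted half must actually exercise matches
})

test_that("size mismatch and type mismatch block the bijection", {
  types <- c("A1|A2" = "EXP_POS", "A1|A3" = "EXP_POS", "A2|A3" = "EXP_POS",
             "B1|B2" = "EXP_POS", "B1|B3" = "EXP_POS", "B2|B3" = "LOG_NEG")
  coex <- data.frame(from = c("A1", "A2", "A3"), to = c("B1", "B2", "B3"))
  g_co <- igraph::graph_from_data_frame(coex, directed = FALSE,
    vertices = data.frame(name = c(paste0("A", 1:3), paste0("B", 1:3))))
  c3 <- structure(list(genes = paste0("A", 1:3), edge_types = types),
                  class = "GeneClique")
  c3b <- structure(list(genes = paste0("B", 1:3), edge_types = types),
                   class = "GeneClique")
  c4 <- structure(list(genes = paste0("B", 1:4), edge_types = types),
                  class = "GeneClique")
  expect_null(match_isomorphic_pair(c3, c4, g_co, types))
  # one mismatching internal type kills every candidate bijection
  expect_null(match_isomorphic_pair(c3, c3b, g_co, types))
  # fixing the type restores the unique bijection
  types2 <- types
  types2[["B2|B3"]] <- "EXP_POS"
  got <- match_isomorphic_pair(c3, c3b, g_co, types2)
  expect_identical(got, c(A1 = "B1", A2 = "B2", A3 = "B3"))
})

test_that("planted transversal cliques assemble into one complete network", {
  tab <- planted_table(n_mod = 3, per_mod = 4)
  nets <- discover_networks(tab)
  expect_length(nets, 1)
  net <- nets[[1]]
  expect_equal(net$n_sets, 3)
  # complete graph over the sets
  expect_equal(nrow(net$intergroup), choose(net$n_sets, 2))
  # orbits are the planted modules
  for (s in net$sets) {
    mods <- unique(substr(s$skeleton, 1, 2))
    expect_length(mods, 1)
  }
  expect_identical(net$signature, "3:EXP_POS,LOG_NEG,QUAD_POS")
  # every set pair carries the planted type
  ig <- net$intergroup
  expect_setequal(ig$curve_type, c("EXP_POS", "LOG_NEG", "QUAD_POS"))
})

test_that("fewer than min_cliques matched cliques yield no network", {
  # only two transversal cliques available: 2 genes per module
  tab <- planted_table(n_mod = 3, per_mod = 2)
  g <- build_graphs(tab)
  cl <- enumerate_gene_cliques(g$nonlinear, tab)
  cg <- build_clique_graph(cl, g$coexpression, tab)
  expect_length(cliques_of_cliques(cl, cg, min_cliques = 3), 0)
  nets2 <- cliques_of_cliques(cl, cg, min_cliques = 2)
  expect_gt(length(nets2), 0)
})

test_that("network signatures group by set count and type multiset", {
  tab <- planted_table()
  net <- discover_networks(tab)[[1]]
  expect_identical(network_signature(net), net$signature)
  # the signature is a multiset key: row order of the intergroup table is
  # irrelevant
  net_perm <- net
  net_perm$intergroup <- net$intergroup[c(3, 1, 2), ]
  expect_identical(network_signature(net_perm), net$signature)
  # distinct planted type patterns give distinct keys
  tab2 <- planted_table(types = c("EXP_POS", "EXP_POS", "EXP_POS"))
  net2 <- discover_networks(tab2)[[1]]
  expect_identical(net2$signature, "3:EXP_POS,EXP_POS,EXP_POS")
  expect_false(identical(net$signature, net2$signature))
})

test_that("halos collect coexpressed genes ordered by f with best anchors", {
  res <- e2e_result()
  expect_length(res$nets, 1)
  net <- res$nets[[1]]
  tab <- res$scan$table
  for (s in net$sets) {
    halo <- s$halo
    if (nrow(halo) < 2) next
    expect_true(all(diff(halo$f) >= 0))
    # anchors are skeleton genes and the f is the recorded linear f
    expect_true(all(halo$anchor %in% s$skeleton))
    for (i in seq_len(nrow(halo))) {
      key <- sort(c(halo$gene[i], halo$anchor[i]))
      row <- tab[tab$gene_a == key[1] & tab$gene_b == key[2], ]
      expect_identical(row$relation_class, "linear")
      expect_equal(row$f, halo$f[i])
      # the anchor is the strongest (lowest-f) linear link into the skeleton
      links <- tab[tab$relation_class == "linear" &
                   (tab$gene_a == halo$gene[i] | tab$gene_b == halo$gene[i]), ]
      partners <- ifelse(links$gene_a == halo$gene[i], links$gene_b,
                         links$gene_a)
      expect_equal(halo$f[i], min(links$f[partners %in% s$skeleton]))
    }
  }
  # no halo genes when there are no linear neighbours
  tab_nl <- planted_table()
  tab_nl$relation_class[tab_nl$relation_class == "linear"] <- "rejected"
  g <- build_graphs(tab_nl)
  cl <- enumerate_gene_cliques(g$nonlinear, tab_nl)
  cg <- build_clique_graph(cl, g$coexpression, tab_nl)
  expect_length(cliques_of_cliques(cl, cg), 0)  # no coexpression, no match
})

test_that("gene-centric queries order both lists by correlation strength", {
  tab <- toy_table()
  q <- query_gene(tab, "A1")
  expect_length(q, 1)
  expect_identical(q[[1]]$partner, "B1")
  expect_identical(q[[1]]$curve_type, "EXP_POS")
  expect_match(q[[1]]$dependence, "activation")
  expect_identical(q[[1]]$gene_coexpressed$gene, "A2")
  expect_identical(q[[1]]$partner_coexpressed$gene, "B2")
  # orientation: B1 sees the transposed type
  qb <- query_gene(tab, "B1")
  expect_identical(qb[[1]]$curve_type, transpose_type("EXP_POS"))
  # no nonlinear partner -> empty list; unknown gene -> error
  expect_length(query_gene(tab, "B2"), 1)  # B2-A2 nonlinear
  tab2 <- tab[tab$relation_class == "linear", ]
  expect_length(query_gene(tab2, "A1"), 0)
  expect_error(query_gene(tab, "ZZ"), "unknown gene")
  # ordering equals an independent re-sort by f on the study data
  res <- e2e_result()
  gene <- res$nets[[1]]$sets[[1]]$skeleton[1]
  q <- query_gene(res$scan$table, gene)
  fs <- vapply(q, `[[`, numeric(1), "f")
  expect_identical(fs, sort(fs))
})

test_that("emitted networks are complete graphs over their sets", {
  res <- e2e_result()
  for (net in res$nets) {
    expect_equal(nrow(net$intergroup), choose(net$n_sets, 2))
    expect_setequal(paste(net$intergroup$set_a, net$intergroup$set_b),
                    apply(combn(net$n_sets, 2), 2, paste, collapse = " "))
  }
})
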