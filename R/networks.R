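#' Build coexpression and nonlinear relationship graphs
#'
#' The coexpression graph holds the accepted linear pairs; the nonlinear
#' graph holds the accepted nonlinear pairs, edge-labelled with their curve
#' type (canonical orientation: lexicographically smaller gene on x).
#' Rejected pairs contribute no edges, so the two edge sets are disjoint.
#'
#' @param table a scan table ([scan_all()]`$table` or [read_relationships()]).
#' @return list with igraph objects `coexpression` and `nonlinear`.
#' @export
build_graphs <- function(table) {
  genes <- sort(unique(c(table$gene_a, table$gene_b)), method = "radix")
  lin <- table[table$relation_class == "linear", , drop = FALSE]
  nl <- table[table$relation_class == "nonlinear", , drop = FALSE]
  g_co <- igraph::graph_from_data_frame(
    lin[, c("gene_a", "gene_b", "f", "curve_type")],
    directed = FALSE, vertices = data.frame(name = genes))
  g_nl <- igraph::graph_from_data_frame(
    nl[, c("gene_a", "gene_b", "f", "curve_type")],
    directed = FALSE, vertices = data.frame(name = genes))
  list(coexpression = g_co, nonlinear = g_nl)
}

# curve type of (u, v) read with u on the x axis, from the canonical store
.oriented_type <- function(types, u, v) {
  key <- if (u < v) paste(u, v, sep = "|") else paste(v, u, sep = "|")
  t <- types[[key]]
  if (is.null(t) || is.na(t)) return(NA_character_)
  if (u < v) t else transpose_type(t)
}

# named vector "a|b" -> curve_type for accepted pairs of a class
.type_lookup <- function(table, class = "nonlinear") {
  sel <- table$relation_class == class
  stats::setNames(table$curve_type[sel],
                  paste(table$gene_a[sel], table$gene_b[sel], sep = "|"))
}

# named vector "a|b" -> f
.f_lookup <- function(table, class) {
  sel <- table$relation_class == class
  stats::setNames(table$f[sel],
                  paste(table$gene_a[sel], table$gene_b[sel], sep = "|"))
}

# adjacency as named list of sorted character vectors
.adjacency_list <- function(graph) {
  nms <- igraph::V(graph)$name
  al <- igraph::as_adj_list(graph)
  stats::setNames(lapply(al, function(v) sort(nms[as.integer(v)], method = "radix")),
                  nms)
}

#' Enumerate gene cliques of the nonlinear graph
#'
#' Maximal cliques with at least `min_size` genes (default 3, the minimum
#' for a clique of nonlinear relationships), each annotated with the curve
#' type of every internal edge. Output is deterministic: cliques are sorted
#' by their gene ids; at most `max_cliques` are kept (with a warning when
#' truncated).
#'
#' @param nonlinear_graph igraph from [build_graphs()].
#' @param table the scan table (source of edge types).
#' @param min_size minimum clique size (default 3).
#' @param max_cliques cap on the number of cliques kept (default 400).
#' @return list of `GeneClique` objects: `genes` (sorted), `edge_types`
#'   (named "a|b" -> type, canonical orientation).
#' @export
enumerate_gene_cliques <- function(nonlinear_graph, table, min_size = 3,
                                   max_cliques = 400) {
  cl <- igraph::max_cliques(nonlinear_graph, min = min_size)
  nms <- igraph::V(nonlinear_graph)$name
  cliques <- lapply(cl, function(v) sort(nms[as.integer(v)], method = "radix"))
  if (!length(cliques)) return(list())
  keys <- vapply(cliques, paste, character(1), collapse = "|")
  cliques <- cliques[order(keys, method = "radix")]
  if (length(cliques) > max_cliques) {
    warning(sprintf("clique cap: keeping %d of %d gene cliques",
                    max_cliques, length(cliques)), call. = FALSE)
    cliques <- cliques[seq_len(max_cliques)]
  }
  types <- .type_lookup(table, "nonlinear")
  lapply(cliques, function(g) {
    pr <- utils::combn(g, 2)
    et <- stats::setNames(types[paste(pr[1, ], pr[2, ], sep = "|")],
                          paste(pr[1, ], pr[2, ], sep = "|"))
    structure(list(genes = g, edge_types = et), class = "GeneClique")
  })
}

#' Match two gene cliques into an isomorphic and linear pair
#'
#' Searches for a bijection mapping every gene of `c1` to a distinct gene of
#' `c2` such that (a) each gene is coexpressed (accepted linear pair) with
#' its image and (b) every internal edge of `c1` carries the same curve type
#' as the corresponding edge of `c2`, after orientation normalization.
#' Backtracking over candidates in gene-id order returns the first valid
#' bijection, so the result is deterministic.
#'
#' @param c1,c2 `GeneClique` objects (equal size, disjoint gene sets;
#'   otherwise no match).
#' @param coex_adj coexpression adjacency from `.adjacency_list`, or an
#'   igraph (converted internally).
#' @param types canonical nonlinear type lookup (named "a|b" vector); if
#'   missing, taken from the cliques' own `edge_types`.
#' @return named character vector (names = genes of c1, values = matched
#'   genes of c2) or `NULL`.
#' @export
match_isomorphic_pair <- function(c1, c2, coex_adj, types = NULL) {
  if (igraph::is_igraph(coex_adj)) coex_adj <- .adjacency_list(coex_adj)
  a <- c1$genes; b <- c2$genes
  if (length(a) != length(b)) return(NULL)
  if (length(intersect(a, b))) return(NULL)
  if (is.null(types)) types <- c(c1$edge_types, c2$edge_types)
  k <- length(a)
  assign <- character(k)
  used <- character(0)
  ok_pair <- function(i, cand) {
    if (i == 1) return(TRUE)
    for (j in seq_len(i - 1)) {
      t1 <- .oriented_type(types, a[j], a[i])
      t2 <- .oriented_type(types, assign[j], cand)
      if (is.na(t1) || is.na(t2) || t1 != t2) return(FALSE)
    }
    TRUE
  }
  bt <- function(i) {
    if (i > k) return(TRUE)
    cands <- setdiff(intersect(coex_adj[[a[i]]], b), used)
    for (cand in cands) {
      if (ok_pair(i, cand)) {
        assign[i] <<- cand
        used <<- c(used, cand)
        if (bt(i + 1)) return(TRUE)
        used <<- setdiff(used, cand)
      }
    }
    FALSE
  }
  if (bt(1L)) stats::setNames(assign, a) else NULL
}

#' Build the clique-level graph of isomorphic and linear clique pairs
#'
#' Vertices are gene cliques; an edge links two cliques admitting an
#' isomorphic-and-linear bijection ([match_isomorphic_pair()]). To bound the
#' quadratic matching stage each clique contributes at most `max_partners`
#' edges (candidate pairs are visited in deterministic clique order).
#'
#' @param cliques list of `GeneClique` from [enumerate_gene_cliques()].
#' @param coexpression_graph igraph of accepted linear pairs.
#' @param table the scan table.
#' @param max_partners per-clique cap on matched partners (default 20).
#' @return list with `edges` (two-column integer matrix of clique indices)
#'   and `bijections` (list of named character vectors, parallel to rows).
#' @export
build_clique_graph <- function(cliques, coexpression_graph, table,
                               max_partners = 20) {
  nc <- length(cliques)
  adj <- .adjacency_list(coexpression_graph)
  types <- .type_lookup(table, "nonlinear")
  deg <- integer(nc)
  edges <- list()
  bijections <- list()
  if (nc >= 2) {
    sizes <- lengths(lapply(cliques, `[[`, "genes"))
    for (i in seq_len(nc - 1)) {
      if (deg[i] >= max_partners) next
      gi <- cliques[[i]]$genes
      # genes coexpressed with any gene of clique i, for a quick disjointness
      # and reachability screen
      reach <- unique(unlist(adj[gi], use.names = FALSE))
      for (j in seq.int(i + 1, nc)) {
        if (deg[i] >= max_partners) break
        if (deg[j] >= max_partners) next
        if (sizes[j] != sizes[i]) next
        gj <- cliques[[j]]$genes
        if (!all(gj %in% reach)) next
        bij <- match_isomorphic_pair(cliques[[i]], cliques[[j]], adj, types)
        if (!is.null(bij)) {
          edges[[length(edges) + 1]] <- c(i, j)
          bijections[[length(bijections) + 1]] <- bij
          deg[i] <- deg[i] + 1L
          deg[j] <- deg[j] + 1L
        }
      }
    }
  }
  list(edges = if (length(edges)) do.call(rbind, edges)
               else matrix(integer(0), 0, 2),
       bijections = bijections)
}

# minimal union-find over character ids
.uf_new <- function() new.env(parent = emptyenv())
.uf_find <- function(uf, x) {
  r <- x
  while (!is.null(p <- uf[[r]]) && p != r) r <- p
  r
}
.uf_union <- function(uf, x, y) {
  if (is.null(uf[[x]])) uf[[x]] <- x
  if (is.null(uf[[y]])) uf[[y]] <- y
  rx <- .uf_find(uf, x); ry <- .uf_find(uf, y)
  if (rx != ry) uf[[max(rx, ry)]] <- min(rx, ry)
}

#' Assemble cliques of cliques into skeleton networks
#'
#' Enumerates maximal cliques (at least `min_cliques` vertices) of the
#' clique-level graph. Each such clique of cliques is resolved into a
#' skeleton network: the bijections along its edges group genes into orbits,
#' and each orbit -- one gene per member clique, all pairwise coexpressed --
#' is the skeleton of one set of coexpressed genes. The curve type between
#' two sets is the unique type (after orientation normalization) among the
#' member cliques' corresponding edges. Networks whose orbits are
#' inconsistent (an orbit holding two genes of one clique) or whose
#' intergroup type is not unique are discarded with a warning.
#'
#' @param cliques list of `GeneClique`.
#' @param clique_graph result of [build_clique_graph()].
#' @param min_sets minimum number of coexpressed sets, i.e. member-clique
#'   size (default 3).
#' @param min_cliques minimum member cliques = skeleton genes per set
#'   (default 3).
#' @param max_networks cap on enumerated cliques of cliques (default 2000).
#' @return list of `SkeletonNetwork` objects: `sets` (list of
#'   `list(skeleton, halo)`), `intergroup` (data.frame `set_a`, `set_b`,
#'   `curve_type`), `signature`, `n_sets`, `member_cliques`.
#' @export
cliques_of_cliques <- function(cliques, clique_graph, min_sets = 3,
                               min_cliques = 3, max_networks = 2000) {
  ed <- clique_graph$edges
  if (nrow(ed) == 0) return(list())
  g <- igraph::graph_from_edgelist(matrix(as.character(ed), ncol = 2),
                                   directed = FALSE)
  cc <- igraph::max_cliques(g, min = min_cliques)
  nms <- igraph::V(g)$name
  members <- lapply(cc, function(v) sort(as.integer(nms[as.integer(v)])))
  if (!length(members)) return(list())
  keys <- vapply(members, paste, character(1), collapse = "|")
  members <- members[order(keys, method = "radix")]
  if (length(members) > max_networks) {
    warning(sprintf("network cap: resolving %d of %d cliques of cliques",
                    max_networks, length(members)), call. = FALSE)
    members <- members[seq_len(max_networks)]
  }
  ekey <- paste(ed[, 1], ed[, 2], sep = "|")
  types <- do.call(c, lapply(cliques, `[[`, "edge_types"))
  types <- types[!duplicated(names(types))]

  nets <- list()
  n_dropped <- 0L
  for (mem in members) {
    if (length(unique(lengths(lapply(cliques[mem], `[[`, "genes")))) != 1) next
    s <- length(cliques[[mem[1]]]$genes)
    if (s < min_sets) next
    uf <- .uf_new()
    for (ci in mem) for (gg in cliques[[ci]]$genes)
      if (is.null(uf[[gg]])) uf[[gg]] <- gg
    prs <- utils::combn(mem, 2)
    ok <- TRUE
    for (p in seq_len(ncol(prs))) {
      e <- which(ekey == paste(prs[1, p], prs[2, p], sep = "|"))
      if (!length(e)) { ok <- FALSE; break }
      bij <- clique_graph$bijections[[e[1]]]
      for (gg in names(bij)) .uf_union(uf, gg, bij[[gg]])
    }
    if (!ok) { n_dropped <- n_dropped + 1L; next }
    all_genes <- sort(unique(unlist(lapply(cliques[mem], `[[`, "genes"))),
                      method = "radix")
    roots <- vapply(all_genes, function(gg) .uf_find(uf, gg), character(1))
    orbits <- split(all_genes, roots)
    # each orbit must hold exactly one gene of every member clique
    if (length(orbits) != s) { n_dropped <- n_dropped + 1L; next }
    consistent <- all(vapply(orbits, function(orb) {
      all(vapply(mem, function(ci)
        sum(cliques[[ci]]$genes %in% orb) == 1L, logical(1)))
    }, logical(1)))
    if (!consistent) { n_dropped <- n_dropped + 1L; next }

    orbits <- orbits[order(vapply(orbits, min, character(1)), method = "radix")]
    names(orbits) <- NULL
    # intergroup type per set pair, must be unique across member cliques
    sp <- utils::combn(length(orbits), 2)
    ig <- vector("list", ncol(sp))
    ok <- TRUE
    for (p in seq_len(ncol(sp))) {
      S <- orbits[[sp[1, p]]]; T <- orbits[[sp[2, p]]]
      tt <- character(0)
      for (ci in mem) {
        u <- intersect(cliques[[ci]]$genes, S)
        v <- intersect(cliques[[ci]]$genes, T)
        tt <- c(tt, .oriented_type(types, u, v))
      }
      tt <- unique(tt)
      if (length(tt) != 1 || is.na(tt)) { ok <- FALSE; break }
      ig[[p]] <- data.frame(set_a = sp[1, p], set_b = sp[2, p],
                            curve_type = tt, stringsAsFactors = FALSE)
    }
    if (!ok) { n_dropped <- n_dropped + 1L; next }
    net <- structure(list(
      sets = lapply(orbits, function(orb)
        list(skeleton = orb,
             halo = data.frame(gene = character(0), f = numeric(0),
                               anchor = character(0),
                               stringsAsFactors = FALSE))),
      intergroup = do.call(rbind, ig),
      n_sets = length(orbits),
      member_cliques = mem), class = "SkeletonNetwork")
    net$signature <- network_signature(net)
    nets[[length(nets) + 1]] <- net
  }
  if (n_dropped > 0)
    warning(sprintf("%d clique(s) of cliques discarded (inconsistent orbits or curve types)",
                    n_dropped), call. = FALSE)
  nets
}

#' Signature of a skeleton network
#'
#' Networks are classified by the number of sets and the sorted multiset of
#' intergroup curve types; the signature is invariant under relabelling of
#' the sets.
#'
#' @param net a `SkeletonNetwork`.
#' @return a string key, e.g. `"3:EXP_POS,LOG_NEG,LOG_NEG"`.
#' @export
network_signature <- function(net) {
  paste0(net$n_sets, ":",
         paste(sort(net$intergroup$curve_type, method = "radix"),
               collapse = ","))
}

#' Merge redundant skeleton networks
#'
#' Cliques of cliques are highly redundant views of the same underlying
#' structure: many different triples of gene cliques describe the same sets
#' of coexpressed genes. Networks with identical signature whose aligned
#' sets are mutually coexpressed (share a gene or an accepted linear pair)
#' are merged by taking the union of the aligned skeletons; the alignment
#' must be one-to-one and preserve intergroup curve types, otherwise the
#' networks stay separate.
#'
#' @param nets list of `SkeletonNetwork`.
#' @param coexpression_graph igraph of accepted linear pairs.
#' @return list of merged `SkeletonNetwork` objects, deterministically
#'   ordered by their smallest gene id.
#' @export
consolidate_networks <- function(nets, coexpression_graph) {
  if (length(nets) <= 1) return(nets)
  adj <- .adjacency_list(coexpression_graph)
  linked <- function(A, B) {
    # same coexpressed set: shared gene or any linear edge across
    length(intersect(A, B)) > 0 ||
      length(intersect(unique(unlist(adj[A], use.names = FALSE)), B)) > 0
  }
  merged <- list()
  for (net in nets) {
    placed <- FALSE
    for (mi in seq_along(merged)) {
      M <- merged[[mi]]
      if (M$signature != net$signature || M$n_sets != net$n_sets) next
      # align each set of `net` to a set of M
      mp <- integer(net$n_sets)
      ok <- TRUE
      for (si in seq_len(net$n_sets)) {
        hits <- which(vapply(M$sets, function(ms)
          linked(ms$skeleton, net$sets[[si]]$skeleton), logical(1)))
        if (length(hits) != 1) { ok <- FALSE; break }
        mp[si] <- hits
      }
      if (!ok || anyDuplicated(mp)) next
      # intergroup types must agree under the alignment
      tM <- .intergroup_map(M)
      agree <- TRUE
      for (p in seq_len(nrow(net$intergroup))) {
        a <- mp[net$intergroup$set_a[p]]; b <- mp[net$intergroup$set_b[p]]
        key <- paste(min(a, b), max(a, b), sep = "|")
        tt <- net$intergroup$curve_type[p]
        # orientation of the merged pair follows its own set order
        if (a > b) tt <- transpose_type(tt)
        if (tM[[key]] != tt) { agree <- FALSE; break }
      }
      if (!agree) next
      for (si in seq_len(net$n_sets)) {
        M$sets[[mp[si]]]$skeleton <-
          sort(union(M$sets[[mp[si]]]$skeleton, net$sets[[si]]$skeleton),
               method = "radix")
      }
      M$member_cliques <- sort(unique(c(M$member_cliques, net$member_cliques)))
      merged[[mi]] <- M
      placed <- TRUE
      break
    }
    if (!placed) merged[[length(merged) + 1]] <- net
  }
  ord <- order(vapply(merged, function(n)
    min(unlist(lapply(n$sets, `[[`, "skeleton"))), character(1)),
    method = "radix")
  merged[ord]
}

.intergroup_map <- function(net) {
  stats::setNames(as.list(net$intergroup$curve_type),
                  paste(net$intergroup$set_a, net$intergroup$set_b, sep = "|"))
}

#' Attach coexpressed halos to a skeleton network
#'
#' The halo of a set is every gene linearly linked (accepted coexpression)
#' to at least one skeleton gene of the set and not itself part of any
#' skeleton of the network. Each halo gene carries its strongest anchor
#' (the skeleton gene with the lowest f) and halos are ordered by f
#' ascending, strongest coexpression first.
#'
#' @param net a `SkeletonNetwork`.
#' @param coexpression_graph igraph of accepted linear pairs.
#' @param table the scan table (source of f values).
#' @return the network with `halo` data.frames filled in.
#' @export
attach_halo <- function(net, coexpression_graph, table) {
  adj <- .adjacency_list(coexpression_graph)
  fs <- .f_lookup(table, "linear")
  all_skel <- unlist(lapply(net$sets, `[[`, "skeleton"))
  for (si in seq_along(net$sets)) {
    skel <- net$sets[[si]]$skeleton
    cand <- setdiff(sort(unique(unlist(adj[skel], use.names = FALSE)),
                         method = "radix"), all_skel)
    if (!length(cand)) next
    halo <- do.call(rbind, lapply(cand, function(gg) {
      anchors <- intersect(adj[[gg]], skel)
      key <- ifelse(gg < anchors, paste(gg, anchors, sep = "|"),
                    paste(anchors, gg, sep = "|"))
      fv <- fs[key]
      best <- which.min(fv)
      data.frame(gene = gg, f = unname(fv[best]), anchor = anchors[best],
                 stringsAsFactors = FALSE)
    }))
    halo <- halo[order(halo$f, halo$gene, method = "radix"), , drop = FALSE]
    rownames(halo) <- NULL
    net$sets[[si]]$halo <- halo
  }
  net
}

#' @export
print.SkeletonNetwork <- function(x, ...) {
  cat(sprintf("SkeletonNetwork: %d sets, signature %s\n", x$n_sets, x$signature))
  for (i in seq_along(x$sets))
    cat(sprintf("  set %d: skeleton {%s} + %d halo gene(s)\n", i,
                paste(x$sets[[i]]$skeleton, collapse = ", "),
                nrow(x$sets[[i]]$halo)))
  invisible(x)
}

#' Gene-centric query of the relationship table
#'
#' For a gene of interest, one entry per accepted nonlinear partner (ordered
#' by f ascending): the partner, the curve type read with the query gene on
#' the x axis, its dependence semantics, the genes coexpressed with the
#' query gene and the genes coexpressed with the partner (both ordered by f
#' ascending).
#'
#' @param table the scan table.
#' @param gene gene id.
#' @return list of entries (`partner`, `f`, `curve_type`, `dependence`,
#'   `gene_coexpressed`, `partner_coexpressed`); empty list when the gene
#'   has no accepted nonlinear partner.
#' @export
query_gene <- function(table, gene) {
  if (!gene %in% c(table$gene_a, table$gene_b))
    stop("unknown gene: ", gene, call. = FALSE)
  coex_of <- function(g) {
    sel <- table$relation_class == "linear" &
      (table$gene_a == g | table$gene_b == g)
    partners <- ifelse(table$gene_a[sel] == g, table$gene_b[sel],
                       table$gene_a[sel])
    ord <- order(table$f[sel], partners, method = "radix")
    data.frame(gene = partners[ord], f = table$f[sel][ord],
               stringsAsFactors = FALSE)
  }
  sel <- table$relation_class == "nonlinear" &
    (table$gene_a == gene | table$gene_b == gene)
  if (!any(sel)) return(list())
  partners <- ifelse(table$gene_a[sel] == gene, table$gene_b[sel],
                     table$gene_a[sel])
  # type stored with gene_a on x; flip when the query gene is gene_b
  ctype <- ifelse(table$gene_a[sel] == gene, table$curve_type[sel],
                  transpose_type(table$curve_type[sel]))
  fv <- table$f[sel]
  ord <- order(fv, partners, method = "radix")
  mine <- coex_of(gene)
  lapply(ord, function(i) {
    list(partner = partners[i], f = fv[i], curve_type = ctype[i],
         dependence = dependence_label(ctype[i]),
         gene_coexpressed = mine,
         partner_coexpressed = coex_of(partners[i]))
  })
}

#' Run the full network-discovery pipeline
#'
#' Scan table in, consolidated skeleton networks with halos out:
#' [build_graphs()], [enumerate_gene_cliques()], [build_clique_graph()],
#' [cliques_of_cliques()], [consolidate_networks()], [attach_halo()].
#'
#' @param table the scan table.
#' @param min_clique minimum gene-clique size (default 3).
#' @param min_sets minimum number of coexpressed sets per network
#'   (default 3).
#' @param min_cliques minimum member cliques per network (default 3).
#' @param max_cliques,max_partners,max_networks combinatorial caps, see the
#'   stage functions.
#' @return list of `SkeletonNetwork` with halos attached.
#' @export
discover_networks <- function(table, min_clique = 3, min_sets = 3,
                              min_cliques = 3, max_cliques = 400,
                              max_partners = 20, max_networks = 2000) {
  graphs <- build_graphs(table)
  # a gene with no accepted coexpression partner can never be matched into
  # an isomorphic clique pair, so dropping it before clique enumeration
  # loses no network and keeps uncorrelated genes from absorbing the
  # maximal cliques
  deg <- igraph::degree(graphs$coexpression)
  iso <- names(deg)[deg == 0]
  nl <- igraph::delete_vertices(graphs$nonlinear,
                                intersect(iso, igraph::V(graphs$nonlinear)$name))
  cliques <- enumerate_gene_cliques(nl, table,
                                    min_size = min_clique,
                                    max_cliques = max_cliques)
  if (!length(cliques)) return(list())
  cg <- build_clique_graph(cliques, graphs$coexpression, table,
                           max_partners = max_partners)
  nets <- cliques_of_cliques(cliques, cg, min_sets = min_sets,
                             min_cliques = min_cliques,
                             max_networks = max_networks)
  nets <- consolidate_networks(nets, graphs$coexpression)
  lapply(nets, attach_halo, coexpression_graph = graphs$coexpression,
         table = table)
}
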