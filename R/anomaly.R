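#' Anomaly-zone boundary function a(x)
#'
#' For a species-tree internal branch of length `x` (coalescent units) with a
#' descendant internal branch of length `y`, the pair lies in the anomaly
#' zone -- where the most probable gene-tree topology differs from the
#' species-tree topology -- iff `y < a(x)`, with
#' \deqn{a(x) = \log\left[\frac{2}{3} +
#'   \frac{3 e^{2x} - 2}{18\,(e^{3x} - e^{2x})}\right].}
#' The function is strictly decreasing on (0, Inf), diverges as x -> 0+, and
#' tends to log(2/3) < 0 as x -> Inf, so long parent branches admit no
#' anomalous descendant. Evaluated in the numerically stable form
#' `log(2/3 + (3 - 2 exp(-2x)) / (18 (exp(x) - 1)))`, which avoids overflow
#' for large x.
#'
#' @param x Parent internal branch length(s) in coalescent units, > 0.
#' @return a(x), same length as `x` (natural log scale).
#' @examples
#' anomaly_boundary(0.1)  # ~ 0.3267
#' @export
anomaly_boundary <- function(x) {
  if (any(x <= 0)) stop("a(x) requires x > 0 (singular at 0)")
  log(2 / 3 + (3 - 2 * exp(-2 * x)) / (18 * (exp(x) - 1)))
}

#' Scan a species tree for internal-branch pairs in the anomaly zone
#'
#' Enumerates every (parent internal branch, child internal branch)
#' adjacency of the species tree, evaluates [anomaly_boundary()] at the
#' parent length x, and flags the pair when the child length y < a(x).
#' Terminal branches never participate. The tree is treated as unrooted for
#' adjacency: with a binary root, the two root-incident edges count as a
#' single branch whose length is their sum, matching the convention of
#' quartet-based species-tree methods whose coalescent-unit lengths are
#' defined on the unrooted topology. Parent lengths above 30 coalescent
#' units short-circuit to `in_zone = FALSE` (a(x) is already negative
#' there).
#'
#' @param species Rooted `phylo` with internal branch lengths in coalescent
#'   units.
#' @return A tibble with columns `parent_id`, `child_id`, `x`, `y`,
#'   `a_of_x`, `in_zone`. Branch ids match [extract_bipartitions()] on the
#'   same tree. Empty when the tree has no two adjacent internal branches.
#' @export
detect_anomaly_pairs <- function(species) {
  adj <- .internal_branch_adjacency(species)
  records <- adj$records
  pairs <- adj$pairs
  if (!nrow(pairs)) {
    return(tibble::tibble(parent_id = character(), child_id = character(),
                          x = numeric(), y = numeric(), a_of_x = numeric(),
                          in_zone = logical()))
  }
  x <- records$length[match(pairs$parent_id, records$branch_id)]
  y <- records$length[match(pairs$child_id, records$branch_id)]
  if (any(is.na(x)) || any(is.na(y))) {
    bad <- unique(c(pairs$parent_id[is.na(x)], pairs$child_id[is.na(y)]))
    stop("missing coalescent-unit length on internal branch(es): ",
         paste(bad, collapse = ", "))
  }
  a_of_x <- ifelse(x > 30, log(2 / 3), anomaly_boundary(pmin(x, 30)))
  tibble::tibble(parent_id = pairs$parent_id, child_id = pairs$child_id,
                 x = x, y = y, a_of_x = a_of_x, in_zone = y < a_of_x)
}

# Internal: branch records plus the parent->child adjacencies between
# internal branches of the unrooted topology. Each unrooted internal branch
# is identified by the branch_id assigned by extract_bipartitions().
.internal_branch_adjacency <- function(species) {
  stopifnot(inherits(species, "phylo"))
  if (!ape::is.rooted(species)) stop("species tree must be rooted")
  records <- extract_bipartitions(species)
  tr <- stats::reorder(species, "cladewise")
  ntip <- length(tr$tip.label)
  edge <- tr$edge
  root <- ntip + 1L
  root_children <- edge[edge[, 1L] == root, 2L]
  merge_root <- length(root_children) == 2L
  # map internal edges (by child node) to branch ids via the split key
  taxa <- tr$tip.label
  below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- taxa[i]
  po <- stats::reorder(species, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    below[[po[i, 1L]]] <- c(below[[po[i, 1L]]], below[[po[i, 2L]]])
  }
  node_key <- function(v) {
    s <- sort(below[[v]])
    comp <- sort(setdiff(taxa, s))
    k1 <- paste(s, collapse = ","); k2 <- paste(comp, collapse = ",")
    if (k1 < k2) paste(k1, k2, sep = "|") else paste(k2, k1, sep = "|")
  }
  internal_nodes <- which(vapply(seq_len(ntip + tr$Nnode), function(v) {
    v > ntip && length(below[[v]]) >= 2L &&
      ntip - length(below[[v]]) >= 2L
  }, logical(1)))
  id_of_node <- stats::setNames(rep(NA_character_, ntip + tr$Nnode), NULL)
  for (v in internal_nodes) {
    id_of_node[v] <- records$branch_id[match(node_key(v), records$key)]
  }
  # lower endpoints of each branch: the child node(s) from which further
  # internal branches descend
  lower_nodes <- split(internal_nodes, id_of_node[internal_nodes])
  if (merge_root) {
    rb <- id_of_node[root_children]
    rb <- unique(rb[!is.na(rb)])
    if (length(rb) == 1L) {
      # merged root branch: both root children are its lower endpoints
      lower_nodes[[rb]] <- unique(c(lower_nodes[[rb]],
                                    root_children[root_children > ntip]))
    }
  }
  out <- list()
  k <- 0L
  for (pid in names(lower_nodes)) {
    for (v in lower_nodes[[pid]]) {
      kids <- edge[edge[, 1L] == v, 2L]
      for (ch in kids) {
        cid <- id_of_node[ch]
        if (is.na(cid) || identical(cid, pid)) next
        k <- k + 1L
        out[[k]] <- tibble::tibble(parent_id = pid, child_id = cid)
      }
    }
  }
  pairs <- if (k) dplyr::bind_rows(out) else
    tibble::tibble(parent_id = character(), child_id = character())
  pairs <- dplyr::distinct(pairs)
  # branch -> incident nodes of the unrooted topology (for adjacency
  # clustering): a normal branch touches its child node and parent node; the
  # merged root branch touches both root children (and the root, shared by
  # nothing else when the root is binary)
  parent_of <- stats::setNames(rep(NA_integer_, ntip + tr$Nnode), NULL)
  parent_of[edge[, 2L]] <- edge[, 1L]
  incident <- lapply(stats::setNames(records$branch_id, records$branch_id),
                     function(bid) {
    vs <- internal_nodes[!is.na(id_of_node[internal_nodes]) &
                           id_of_node[internal_nodes] == bid]
    unique(c(vs, parent_of[vs]))
  })
  list(records = records, pairs = pairs, incident = incident)
}

#' Cluster consecutive anomalous internodes
#'
#' Takes the internal branches appearing in `in_zone` pairs and partitions
#' them into maximal connected components under tree adjacency (two internal
#' branches are adjacent when they share a node of the unrooted topology).
#' Clusters are numbered deterministically by the preorder position of their
#' first branch.
#'
#' @param pairs Output of [detect_anomaly_pairs()].
#' @param species The same species tree the pairs were computed from.
#' @return A tibble with columns `branch_id`, `cluster`; empty when no pair
#'   is in the zone.
#' @export
cluster_anomaly_internodes <- function(pairs, species) {
  inz <- pairs[pairs$in_zone, , drop = FALSE]
  if (!nrow(inz)) {
    return(tibble::tibble(branch_id = character(), cluster = integer()))
  }
  adj <- .internal_branch_adjacency(species)
  members <- unique(c(inz$parent_id, inz$child_id))
  # connect member branches through shared tree nodes (bipartite projection)
  inc <- adj$incident[members]
  edges <- dplyr::bind_rows(lapply(members, function(bid) {
    tibble::tibble(from = bid, to = paste0("node#", inc[[bid]]))
  }))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = unique(c(members, edges$to))
  )
  comp <- igraph::components(g)
  memb <- comp$membership[members]
  pre <- adj$records$preorder[match(members, adj$records$branch_id)]
  first_pre <- tapply(pre, memb, min)
  renum <- rank(first_pre, ties.method = "first")
  tibble::tibble(branch_id = members,
                 cluster = as.integer(renum[as.character(memb)])) |>
    dplyr::arrange(.data$cluster, .data$branch_id)
}
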