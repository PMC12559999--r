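# Shared fixtures and independent oracles for the test suite.

# Caterpillar species tree with the given internode lengths (coalescent
# units), shallowest first; tips are contemporaneous.
make_caterpillar <- function(lens, tip_prefix = "t") {
  n <- length(lens) + 2
  tips <- sprintf("%s%02d", tip_prefix, seq_len(n + 1))
  nwk <- paste0("(", tips[1], ":1,", tips[2], ":1)")
  depth <- 1
  for (i in seq_along(lens)) {
    depth <- depth + lens[i]
    nwk <- paste0("(", nwk, ":", lens[i], ",", tips[i + 2], ":", depth, ")")
  }
  depth <- depth + 2
  nwk <- paste0("(", nwk, ":2,", tips[n + 1], ":", depth, ");")
  parse_newick(nwk, unit = "coalescent")
}

# Independent split enumeration built on phangorn::Descendants (a different
# code path from the package's own traversal): every internal edge's tip set
# with the support of its child node.
oracle_edge_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  edges <- tree$edge[tree$edge[, 2L] > ntip, 2L, drop = TRUE]
  out <- lapply(edges, function(v) {
    tips <- tree$tip.label[phangorn::Descendants(tree, v, "tips")[[1L]]]
    s <- sup[v - ntip]
    list(side = tips, support = if (is.na(s)) 0 else s)
  })
  # drop trivial splits (complement < 2 taxa); root-redundant splits are kept
  Filter(function(x) length(x$side) >= 2 &&
           ntip - length(x$side) >= 2, out)
}

# Independent conflict classifier: restrict the species split to the shared
# taxa and score it against the gene tree's edge splits enumerated with
# phangorn; display and incompatibility re-derived from first principles.
oracle_classify <- function(gene, side_a, side_b, threshold) {
  g <- intersect(gene$tip.label, c(side_a, side_b))
  a <- sort(intersect(side_a, g))
  b <- sort(intersect(side_b, g))
  if (length(a) < 2 || length(b) < 2) return("missing")
  setequal2 <- function(x, y) length(x) == length(y) && all(sort(x) == sort(y))
  disp <- -Inf; conf <- -Inf
  for (sp in oracle_edge_splits(gene)) {
    s <- intersect(sp$side, g)
    sc <- setdiff(g, s)
    if (length(s) < 2 || length(sc) < 2) next
    if (setequal2(s, a) || setequal2(s, b)) {
      disp <- max(disp, sp$support)
    } else if (length(intersect(s, a)) && length(intersect(s, b)) &&
               length(intersect(sc, a)) && length(intersect(sc, b))) {
      conf <- max(conf, sp$support)
    }
  }
  if (is.finite(disp)) {
    if (disp >= threshold) "strong_support" else "weak_support"
  } else if (is.finite(conf)) {
    if (conf >= threshold) "strong_conflict" else "weak_conflict"
  } else "weak_conflict"
}

# Quartet topology of one gene tree on 4 sorted taxa by explicit restriction
# with ape::keep.tip: returns 1, 2 or 3 for the pairing of the first taxon
# (with the 2nd, 3rd, 4th), or NA when missing/unresolved.
oracle_quartet_topology <- function(gene, q) {
  if (!all(q %in% gene$tip.label)) return(NA_integer_)
  sub <- ape::unroot(ape::keep.tip(gene, q))
  if (sub$Nnode < 2) return(NA_integer_)     # star quartet
  ntip <- 4L
  # cherries: tips sharing a parent node
  par <- sub$edge[match(seq_len(ntip), sub$edge[, 2L]), 1L]
  mate <- which(par == par[match(q[1L], sub$tip.label)])
  mate_lab <- sub$tip.label[setdiff(mate, match(q[1L], sub$tip.label))]
  if (length(mate_lab) != 1L) return(NA_integer_)
  match(mate_lab, q) - 1L
}

# Does any unrooted binary tree on the taxon set display both splits?
# Exhaustive search over phangorn::allTrees (4-6 taxa only).
oracle_compatible <- function(b1, b2) {
  taxa <- sort(c(b1$side_a, b1$side_b))
  all_trees <- phangorn::allTrees(length(taxa), rooted = FALSE,
                                  tip.label = taxa)
  displays <- function(tr, side) {
    any(vapply(oracle_edge_splits(tr), function(sp) {
      setequal(sp$side, side) || setequal(setdiff(taxa, sp$side), side)
    }, logical(1)))
  }
  any(vapply(all_trees, function(tr) {
    displays(tr, b1$side_a) && displays(tr, b2$side_a)
  }, logical(1)))
}

# Closed-form OLS of y on log(x).
oracle_ols_loglinear <- function(xs, ys) {
  u <- log(xs)
  slope <- sum((u - mean(u)) * (ys - mean(ys))) / sum((u - mean(u))^2)
  intercept <- mean(ys) - slope * mean(u)
  list(slope = slope, intercept = intercept)
}

# Direct per-pair summation of the NANUQ distance from a results tibble.
oracle_nanuq <- function(results, taxa, star_w = 0.5, hyb_w = 0.5) {
  D <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  for (i in seq_len(nrow(results))) {
    q <- c(results$t1[i], results$t2[i], results$t3[i], results$t4[i])
    cl <- results$classification[i]
    pairs <- t(utils::combn(q, 2L))
    if (cl == "treelike") {
      cherry <- switch(results$topology[i],
                       "t1t2|t3t4" = list(c(q[1], q[2]), c(q[3], q[4])),
                       "t1t3|t2t4" = list(c(q[1], q[3]), c(q[2], q[4])),
                       "t1t4|t2t3" = list(c(q[1], q[4]), c(q[2], q[3])))
      for (k in seq_len(nrow(pairs))) {
        p <- pairs[k, ]
        w <- if (setequal(p, cherry[[1]]) || setequal(p, cherry[[2]])) 0 else 1
        D[p[1], p[2]] <- D[p[1], p[2]] + w
        D[p[2], p[1]] <- D[p[2], p[1]] + w
      }
    } else {
      w <- if (cl == "starlike") star_w else hyb_w
      for (k in seq_len(nrow(pairs))) {
        p <- pairs[k, ]
        D[p[1], p[2]] <- D[p[1], p[2]] + w
        D[p[2], p[1]] <- D[p[2], p[1]] + w
      }
    }
  }
  D
}

# Printed partner-sharing summary (section 3.6 OTUs): raw pair counts.
table1_counts <- function() {
  tibble::tibble(
    otu_pair = c("V and XLII", "3.6a and XLII", "3.6a and V",
                 "XLII and XLII", "V and V", "3.6a and 3.6a"),
    total_pairs = c(18078, 4554, 17292, 2346, 34191, 2145),
    cooccurring_pairs = c(107, 24, 169, 35, 499, 31),
    noncooccurring_pairs = c(17971, 4530, 17123, 2311, 33692, 2114),
    cooccurring_sharing = c(26, 2, 50, 9, 120, 18),
    noncooccurring_sharing = c(1561, 430, 4207, 367, 6251, 718),
    pct_cooccurring = c(24.29, 8.33, 29.58, 25.71, 24.04, 58.06),
    pct_noncooccurring = c(8.68, 9.49, 24.56, 15.88, 18.55, 33.96)
  )
}
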