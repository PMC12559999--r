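#' Parse a newick string into an annotated phylogenetic tree
#'
#' Thin wrapper around [ape::read.tree()] that validates the tree, interprets
#' numeric internal-node labels as branch support values, and records the unit
#' of the branch lengths. Supports are kept on the 0--100 scale used by
#' ultrafast-bootstrap software; inputs that look like proportions (all
#' supports in \[0, 1\]) are rescaled to 0--100 with a warning.
#'
#' @param text A single newick statement ending in ";". Quoted labels are
#'   allowed and square-bracket comments are ignored (ape's dialect).
#' @param unit Unit of the branch lengths: one of `"coalescent"`,
#'   `"time_My"`, `"subs_per_site"` or `"none"`.
#' @return An object of class `phylo` with a `length_unit` attribute.
#'   Supports, where present, live in `node.label` (numeric strings).
#' @examples
#' tr <- parse_newick("((A:1,B:1)90:0.5,C:1.5);", unit = "coalescent")
#' branch_supports(tr)
#' @export
parse_newick <- function(text, unit = c("none", "coalescent", "time_My",
                                        "subs_per_site")) {
  unit <- match.arg(unit)
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text) || !endsWith(text, ";")) {
    stop("newick text must be a single statement ending in ';'")
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop(sprintf("unbalanced parentheses in newick text (%d '(' vs %d ')')",
                 n_open, n_close))
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("newick parse error: ape could not read the statement")
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup)) {
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0, na.rm = TRUE)) {
    stop("negative branch length(s) in newick text")
  }
  tr <- .normalise_supports(tr)
  attr(tr, "length_unit") <- unit
  tr
}

# Rescale proportion-scale supports to 0-100 and validate the range.
.normalise_supports <- function(tr) {
  if (is.null(tr$node.label)) return(tr)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  num <- !is.na(sup)
  if (!any(num)) return(tr)
  if (all(sup[num] >= 0 & sup[num] <= 1)) {
    warning("supports look like proportions in [0, 1]; rescaling to 0-100")
    sup[num] <- sup[num] * 100
    tr$node.label[num] <- as.character(sup[num])
  }
  if (any(sup[num] < 0 | sup[num] > 100)) {
    stop("branch supports must lie in [0, 100]")
  }
  tr
}

#' Numeric branch supports of a tree
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of length `tree$Nnode` (NA where absent or
#'   non-numeric).
#' @export
branch_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Serialise a tree to newick
#'
#' Round-trips with [parse_newick()]: topology, branch lengths (to printed
#' precision) and supports are preserved.
#'
#' @param tree A `phylo` object with at least one tip.
#' @return A newick string ending in ";".
#' @export
write_newick <- function(tree) {
  if (is.null(tree) || !inherits(tree, "phylo") || length(tree$tip.label) == 0) {
    stop("cannot serialise an empty tree")
  }
  ape::write.tree(tree)
}

#' Read a set of gene trees (one newick per line)
#'
#' @param path Path to a file with one newick statement per line.
#' @inheritParams parse_newick
#' @return A list of `phylo` objects.
#' @export
read_gene_trees <- function(path, unit = "none") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, parse_newick, unit = unit)
}

#' Construct a bipartition (unrooted split) of a taxon set
#'
#' @param side_a,side_b Disjoint, non-empty character vectors whose union is
#'   the taxon set the split lives on.
#' @return An object of class `bipartition` with sorted sides, the
#'   lexicographically smaller side first, and a canonical `key`.
#' @export
bipartition <- function(side_a, side_b) {
  side_a <- sort(unique(as.character(side_a)))
  side_b <- sort(unique(as.character(side_b)))
  if (!length(side_a) || !length(side_b)) stop("bipartition sides must be non-empty")
  if (length(intersect(side_a, side_b))) {
    stop("bipartition sides must be disjoint: ",
         paste(intersect(side_a, side_b), collapse = ", "))
  }
  ka <- paste(side_a, collapse = ",")
  kb <- paste(side_b, collapse = ",")
  if (kb < ka) {
    tmp <- side_a; side_a <- side_b; side_b <- tmp
    tmp <- ka; ka <- kb; kb <- tmp
  }
  structure(list(side_a = side_a, side_b = side_b,
                 key = paste(ka, kb, sep = "|")),
            class = "bipartition")
}

#' @export
print.bipartition <- function(x, ...) {
  cat("<bipartition> {", paste(x$side_a, collapse = ","), "} | {",
      paste(x$side_b, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Is a bipartition informative?
#'
#' A split is informative when both sides contain at least two taxa.
#' @param b A `bipartition`.
#' @return Logical scalar.
#' @export
is_informative <- function(b) {
  length(b$side_a) >= 2 && length(b$side_b) >= 2
}

#' Test compatibility of two bipartitions over the same taxon set
#'
#' Two splits are compatible (a tree can display both) iff at least one of
#' the four pairwise side intersections is empty.
#'
#' @param b1,b2 `bipartition` objects over the same taxon set.
#' @return Logical scalar.
#' @export
bipartitions_compatible <- function(b1, b2) {
  t1 <- sort(c(b1$side_a, b1$side_b))
  t2 <- sort(c(b2$side_a, b2$side_b))
  if (!identical(t1, t2)) {
    stop("bipartitions are over different taxon sets")
  }
  !length(intersect(b1$side_a, b2$side_a)) ||
    !length(intersect(b1$side_a, b2$side_b)) ||
    !length(intersect(b1$side_b, b2$side_a)) ||
    !length(intersect(b1$side_b, b2$side_b))
}

# Internal: splits of a tree viewed as unrooted, with per-split support and
# branch length. The two edges incident to a binary root map to one split;
# their lengths are summed and the larger available support kept.
# Returns a list with: sides (list of tip-label vectors, the child side),
# support, length, preorder (first edge index realising the split).
.tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  out <- list(sides = list(), support = numeric(), length = numeric(),
              preorder = integer())
  if (ntip < 4) return(out)
  tree <- stats::reorder(tree, "cladewise")
  edge <- tree$edge
  sup <- branch_supports(tree)
  root <- ntip + 1L
  # tips below each node
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (i in rev(seq_len(nrow(edge)))) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  root_children <- edge[edge[, 1L] == root, 2L]
  merge_root <- length(root_children) == 2L
  seen <- character()
  for (i in seq_len(nrow(edge))) {
    ch <- edge[i, 2L]
    if (ch <= ntip) next                     # terminal edge
    side <- below[[ch]]
    if (length(side) < 2L || ntip - length(side) < 2L) next
    key <- paste(sort(side), collapse = ",")
    ckey <- paste(sort(setdiff(tree$tip.label, side)), collapse = ",")
    canon <- if (key < ckey) key else ckey
    len <- if (is.null(tree$edge.length)) NA_real_ else tree$edge.length[i]
    spt <- sup[ch - ntip]
    if (merge_root && edge[i, 1L] == root) {
      # the complementary root edge describes the same unrooted split
      other <- setdiff(root_children, ch)
      if (length(other) == 1L && other > ntip && !is.null(tree$edge.length)) {
        j <- which(edge[, 2L] == other)
        len <- len + tree$edge.length[j]
        both <- c(spt, sup[other - ntip])
        spt <- if (all(is.na(both))) NA_real_ else max(both, na.rm = TRUE)
      }
    }
    if (canon %in% seen) next
    seen <- c(seen, canon)
    out$sides <- c(out$sides, list(side))
    out$support <- c(out$support, spt)
    out$length <- c(out$length, len)
    out$preorder <- c(out$preorder, i)
  }
  out
}

#' Extract the informative bipartitions (branch records) of a tree
#'
#' The tree is treated as unrooted: with a binary root the two root-incident
#' edges collapse to one branch whose length is their sum. One record is
#' returned per internal branch; a fully resolved unrooted tree on n tips
#' yields exactly n - 3 records.
#'
#' @param tree A `phylo` object.
#' @return A tibble with columns `branch_id`, `bipartition` (list column of
#'   [bipartition()] objects), `key`, `length`, `support`, `unit` and
#'   `preorder` (position of the branch in a preorder edge traversal).
#'   Empty for trees with fewer than 4 tips.
#' @export
extract_bipartitions <- function(tree) {
  sp <- .tree_splits(tree)
  unit <- attr(tree, "length_unit") %||% "none"
  if (!length(sp$sides)) {
    return(tibble::tibble(branch_id = character(), bipartition = list(),
                          key = character(), length = numeric(),
                          support = numeric(), unit = character(),
                          preorder = integer()))
  }
  taxa <- tree$tip.label
  bips <- lapply(sp$sides, function(s) bipartition(s, setdiff(taxa, s)))
  keys <- vapply(bips, function(b) b$key, character(1))
  ord <- order(sp$preorder)
  tibble::tibble(
    branch_id = paste0("b", seq_along(keys)),
    bipartition = bips, key = keys,
    length = sp$length, support = sp$support,
    unit = unit, preorder = sp$preorder
  )[ord, ] |>
    dplyr::mutate(branch_id = paste0("b", dplyr::row_number()))
}

#' Restrict a tree to a subset of taxa
#'
#' Returns the induced subtree: degree-2 nodes created by the pruning are
#' suppressed with their incident branch lengths summed, so tip-to-tip path
#' lengths among retained taxa are preserved. Supports of suppressed nodes
#' are discarded.
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of tip labels to keep (subset of the tree's
#'   tips, at least one).
#' @return A `phylo` object carrying over the `length_unit` attribute.
#' @export
restrict_tree <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown)) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  }
  if (!length(taxa)) stop("need at least one taxon to keep")
  out <- ape::keep.tip(tree, taxa)
  attr(out, "length_unit") <- attr(tree, "length_unit")
  out
}

#' Flag and filter loci by single-nucleotide-variant (SNV) content
#'
#' Screens per-genome, per-locus SNV summaries for traces of strain
#' heterogeneity. A (genome, locus) sequence is flagged when the maximum
#' non-consensus allele frequency at its SNVs reaches `freq_threshold`;
#' flagged sequences are excluded. A genome is dropped entirely when its
#' flagged fraction (over the loci it has rows for) is strictly greater
#' than `taxon_fraction`.
#'
#' @param snv A data frame with columns `genome`, `locus`, `snv_count`
#'   (non-negative integer) and `max_freq` (in \[0, 1\]); one row per
#'   (genome, locus).
#' @param freq_threshold Non-consensus allele frequency at or above which a
#'   sequence is flagged (default 0.1).
#' @param taxon_fraction Flagged fraction above which (strictly) a genome is
#'   dropped (default 0.2).
#' @return A list with `kept` (tibble of genome/locus pairs that survive),
#'   `flagged` (tibble of excluded pairs) and `dropped_genomes` (character).
#' @export
filter_snv_sequences <- function(snv, freq_threshold = 0.1,
                                 taxon_fraction = 0.2) {
  snv <- tibble::as_tibble(snv)
  req <- c("genome", "locus", "snv_count", "max_freq")
  if (!all(req %in% names(snv))) {
    stop("snv table needs columns: ", paste(req, collapse = ", "))
  }
  if (any(snv$max_freq < 0 | snv$max_freq > 1, na.rm = TRUE)) {
    stop("max_freq values must lie in [0, 1]")
  }
  if (anyDuplicated(snv[c("genome", "locus")])) {
    stop("snv table must have one row per (genome, locus)")
  }
  snv <- dplyr::mutate(snv, flagged = .data$snv_count > 0 &
                         .data$max_freq >= freq_threshold)
  per_genome <- snv |>
    dplyr::group_by(.data$genome) |>
    dplyr::summarise(frac_flagged = mean(.data$flagged), .groups = "drop")
  dropped <- per_genome$genome[per_genome$frac_flagged > taxon_fraction]
  kept <- snv |>
    dplyr::filter(!.data$flagged, !(.data$genome %in% dropped)) |>
    dplyr::select("genome", "locus")
  flagged <- snv |>
    dplyr::filter(.data$flagged) |>
    dplyr::select("genome", "locus")
  list(kept = kept, flagged = flagged,
       dropped_genomes = as.character(dropped))
}

#' Default analysis thresholds
#'
#' Bundles the thresholds used across the package: the strong-support cutoff
#' on the 0--100 bootstrap scale, the quartet-test levels, the ANI species
#' threshold, the regression significance level, and the SNV filtering rule.
#'
#' @param support_threshold Strong-support cutoff, 0--100 (default 95).
#' @param alpha_t3 Level of the T3 quartet test (default 1e-6).
#' @param beta_star Level of the star quartet test (default 0.1).
#' @param ani_threshold ANI clustering threshold in percent (default 95).
#' @param regression_alpha Significance level for conflict regressions
#'   (default 0.01).
#' @param snv_freq_threshold See [filter_snv_sequences()] (default 0.1).
#' @param snv_taxon_fraction See [filter_snv_sequences()] (default 0.2).
#' @param seed Integer seed recorded for downstream simulation calls.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(support_threshold = 95, alpha_t3 = 1e-6,
                            beta_star = 0.1, ani_threshold = 95,
                            regression_alpha = 0.01,
                            snv_freq_threshold = 0.1,
                            snv_taxon_fraction = 0.2, seed = 1L) {
  stopifnot(support_threshold >= 0, support_threshold <= 100,
            alpha_t3 > 0, alpha_t3 < 1, beta_star > 0, beta_star < 1,
            ani_threshold > 0, ani_threshold <= 100,
            regression_alpha > 0, regression_alpha < 1,
            snv_freq_threshold >= 0, snv_freq_threshold <= 1,
            snv_taxon_fraction >= 0, snv_taxon_fraction <= 1)
  structure(list(support_threshold = support_threshold, alpha_t3 = alpha_t3,
                 beta_star = beta_star, ani_threshold = ani_threshold,
                 regression_alpha = regression_alpha,
                 snv_freq_threshold = snv_freq_threshold,
                 snv_taxon_fraction = snv_taxon_fraction,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
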