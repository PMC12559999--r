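#' Read a FastANI-style pairwise ANI table
#'
#' Expects tab-separated columns query, reference, ANI (percent), fragments
#' mapped, fragments total, with or without a header line.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `query`, `reference`, `ani`,
#'   `frag_mapped`, `frag_total`.
#' @export
read_ani_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("query", first, ignore.case = TRUE)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("ANI table needs at least 3 columns")
  names(df)[1:3] <- c("query", "reference", "ani")
  if (ncol(df) >= 5L) names(df)[4:5] <- c("frag_mapped", "frag_total")
  tibble::as_tibble(df)
}

#' Symmetrize a pairwise ANI table into a matrix
#'
#' Upstream ANI tools report slightly different values in the two
#' directions of a pair. The symmetrized entry is the mean of the two
#' directions when both are present, or the single value otherwise (with a
#' warning counting one-direction pairs). Reciprocal asymmetries larger than
#' 1 percentage point also trigger a warning but are averaged. The diagonal
#' is 100; pairs absent in both directions are `NA`.
#'
#' @param table A data frame with columns `query`, `reference`, `ani`
#'   (percent in (0, 100\]).
#' @return A symmetric numeric matrix with genome labels as dimnames.
#' @export
symmetrize_ani <- function(table) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("query", "reference", "ani") %in% names(table)))
  if (any(table$ani <= 0 | table$ani > 100, na.rm = TRUE)) {
    stop("ANI values must lie in (0, 100]")
  }
  labs <- sort(unique(c(table$query, table$reference)))
  M <- matrix(NA_real_, length(labs), length(labs),
              dimnames = list(labs, labs))
  Cnt <- matrix(0L, length(labs), length(labs))
  for (r in seq_len(nrow(table))) {
    i <- match(table$query[r], labs)
    j <- match(table$reference[r], labs)
    if (i == j) next
    M[i, j] <- table$ani[r]
    Cnt[i, j] <- 1L
  }
  up_i <- which(upper.tri(M), arr.ind = TRUE)
  one_dir <- 0L
  big_asym <- 0L
  for (k in seq_len(nrow(up_i))) {
    i <- up_i[k, 1L]; j <- up_i[k, 2L]
    a <- M[i, j]; b <- M[j, i]
    if (Cnt[i, j] + Cnt[j, i] == 0L) next
    if (Cnt[i, j] == 0L || Cnt[j, i] == 0L) {
      one_dir <- one_dir + 1L
      v <- if (Cnt[i, j]) a else b
    } else {
      if (abs(a - b) > 1) big_asym <- big_asym + 1L
      v <- (a + b) / 2
    }
    M[i, j] <- M[j, i] <- v
  }
  diag(M) <- 100
  if (one_dir) warning(one_dir, " pair(s) present in one direction only")
  if (big_asym) {
    warning(big_asym,
            " pair(s) with reciprocal ANI asymmetry > 1 percentage point (averaged)")
  }
  M
}

#' Cluster genomes at an ANI threshold
#'
#' Single-linkage (default): clusters are the connected components of the
#' graph with an edge wherever symmetrized ANI >= threshold, so any chain of
#' above-threshold pairs merges. Complete linkage is available as an
#' alternative (hierarchical clustering on 100 - ANI cut at the threshold).
#' Clusters are numbered deterministically by their smallest member label.
#'
#' @param matrix Symmetric ANI matrix (output of [symmetrize_ani()]).
#' @param threshold ANI threshold in percent (default 95, the conventional
#'   bacterial species boundary).
#' @param linkage `"single"` (default) or `"complete"`.
#' @return A tibble of class `ani_clusters` with columns `genome`,
#'   `cluster` and a `threshold` attribute.
#' @export
cluster_genomes <- function(matrix, threshold = 95,
                            linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  labs <- rownames(matrix)
  stopifnot(!is.null(labs), isSymmetric(unname(matrix)))
  if (linkage == "single") {
    A <- !is.na(matrix) & matrix >= threshold
    diag(A) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    memb <- igraph::components(g)$membership
  } else {
    d <- 100 - matrix
    d[is.na(d)] <- 100
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    memb <- stats::cutree(hc, h = 100 - threshold + 1e-9)
    names(memb) <- labs
  }
  # deterministic numbering by smallest member label
  first <- tapply(labs, memb[labs], min)
  renum <- stats::setNames(rank(first, ties.method = "first"), names(first))
  out <- tibble::tibble(genome = labs,
                        cluster = as.integer(renum[as.character(memb[labs])]))
  attr(out, "threshold") <- threshold
  class(out) <- c("ani_clusters", class(out))
  out
}

#' Detect empty intervals (gaps) in a set of pairwise ANI values
#'
#' Finds the maximal open intervals inside \[min(values), max(values)\] that
#' contain no observed value and are at least `min_width` wide. Values
#' closer together than `resolution` are treated as contiguous coverage, so
#' `resolution` sets the granularity of the search grid.
#'
#' @param values Numeric vector of pairwise ANI percents (>= 2 values).
#' @param min_width Minimum gap width in percentage points (default 0.5,
#'   must be > 0).
#' @param resolution Search granularity in percentage points (default 0.1).
#' @return A tibble with columns `lower`, `upper`, `width`, sorted by
#'   `lower`; zero rows when the values are dense.
#' @export
detect_ani_gaps <- function(values, min_width = 0.5, resolution = 0.1) {
  if (min_width <= 0) stop("min_width must be > 0")
  values <- sort(unique(values[is.finite(values)]))
  if (length(values) < 2L) stop("need at least 2 ANI values")
  d <- diff(values)
  gap <- d >= pmax(min_width, resolution)
  tibble::tibble(lower = values[which(gap)],
                 upper = values[which(gap) + 1L]) |>
    dplyr::mutate(width = .data$upper - .data$lower) |>
    dplyr::arrange(.data$lower)
}

#' Long-format ANI table ordered along a phylogeny
#'
#' Lays out the symmetrized pairwise ANI values with focal genomes in the
#' order the tree's tips are drawn (preorder traversal), the layout used for
#' per-genome ANI dot plots along a phylogeny.
#'
#' @param tree A `phylo` whose tips are (a subset of) the matrix labels.
#' @param matrix Symmetric ANI matrix.
#' @return A tibble with columns `focal` (factor in tip order), `partner`,
#'   `ani`; one row per ordered pair, n(n-1) rows for n tips.
#' @export
tree_ordered_ani_table <- function(tree, matrix) {
  missing_tips <- setdiff(tree$tip.label, rownames(matrix))
  if (length(missing_tips)) {
    stop("tip(s) absent from the ANI matrix: ",
         paste(missing_tips, collapse = ", "))
  }
  tr <- stats::reorder(tree, "cladewise")
  ntip <- length(tr$tip.label)
  tip_order <- tr$tip.label[tr$edge[tr$edge[, 2L] <= ntip, 2L]]
  grid <- expand.grid(focal = tip_order, partner = tip_order,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$focal != grid$partner, ]
  tibble::tibble(
    focal = factor(grid$focal, levels = tip_order),
    partner = grid$partner,
    ani = matrix[cbind(grid$focal, grid$partner)]
  ) |>
    dplyr::arrange(.data$focal)
}
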