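#' Classify one gene tree against one species-tree bipartition
#'
#' The species-tree split is restricted to the taxa shared with the gene
#' tree. If either restricted side has fewer than two taxa the gene tree is
#' `missing` for that branch. Otherwise, if the gene tree displays the
#' restricted split, the outcome is `strong_support` when the gene tree's
#' support for it reaches `threshold` and `weak_support` otherwise; if it
#' does not, the outcome is `strong_conflict` when any gene-tree split
#' incompatible with the restricted split has support at or above
#' `threshold`, and `weak_conflict` otherwise. Absent supports count as 0.
#'
#' @param gene A `phylo` gene tree (tips not in the species taxon set are
#'   ignored).
#' @param branch A single [bipartition()] over the species taxon set, or a
#'   one-row slice of [extract_bipartitions()] output.
#' @param threshold Strong-support cutoff on the 0--100 scale (default 95).
#' @return One of `"strong_support"`, `"weak_support"`, `"strong_conflict"`,
#'   `"weak_conflict"`, `"missing"`.
#' @export
classify_gene_tree_vs_branch <- function(gene, branch, threshold = 95) {
  if (is.data.frame(branch)) {
    stopifnot(nrow(branch) == 1L)
    branch <- branch$bipartition[[1L]]
  }
  stopifnot(inherits(branch, "bipartition"))
  gs <- .tree_splits(gene)
  .classify_splits(gs, gene$tip.label, branch, threshold)
}

# Core classification on precomputed gene-tree splits.
.classify_splits <- function(gene_splits, gene_tips, branch, threshold) {
  g <- intersect(gene_tips, c(branch$side_a, branch$side_b))
  a <- intersect(branch$side_a, g)
  b <- intersect(branch$side_b, g)
  if (length(a) < 2L || length(b) < 2L) return("missing")
  key_a <- paste(sort(a), collapse = ",")
  best_display <- -Inf
  best_conflict <- -Inf
  displayed <- FALSE
  for (i in seq_along(gene_splits$sides)) {
    s <- intersect(gene_splits$sides[[i]], g)
    if (length(s) < 2L || length(g) - length(s) < 2L) next
    sup <- gene_splits$support[i]
    if (is.na(sup)) sup <- 0
    # compare restricted gene split {s, g \ s} with {a, b}; s subset of g
    ia <- length(intersect(s, a))
    ib <- length(intersect(s, b))
    if ((ia == length(a) && ib == 0L) || (ib == length(b) && ia == 0L)) {
      displayed <- TRUE
      best_display <- max(best_display, sup)
    } else if (ia > 0L && ib > 0L &&
               length(a) - ia > 0L && length(b) - ib > 0L) {
      # all four pairwise side intersections non-empty => incompatible splits
      best_conflict <- max(best_conflict, sup)
    }
  }
  if (displayed) {
    if (best_display >= threshold) "strong_support" else "weak_support"
  } else if (is.finite(best_conflict)) {
    if (best_conflict >= threshold) "strong_conflict" else "weak_conflict"
  } else {
    # no informative restricted split conflicts or matches: the gene tree is
    # unresolved with respect to this branch
    "weak_conflict"
  }
}

#' Tally gene-tree conflict per species-tree branch
#'
#' Scores every gene tree against every internal branch of the species tree
#' with [classify_gene_tree_vs_branch()] and counts the five categories.
#'
#' @param species Species tree (`phylo`, >= 4 tips).
#' @param genes List of gene trees (`phylo` or `multiPhylo`).
#' @param threshold Strong-support cutoff on the 0--100 scale (default 95).
#' @return A tibble of class `conflict_tally` with one row per species-tree
#'   internal branch: `branch_id`, `key`, `length`, the five category
#'   counts, and `n_genes`. The five counts sum to `n_genes` in every row.
#' @export
tally_conflicts <- function(species, genes, threshold = 95) {
  stopifnot(length(species$tip.label) >= 4L, length(genes) >= 1L)
  records <- extract_bipartitions(species)
  cats <- c("strong_support", "weak_support", "strong_conflict",
            "weak_conflict", "missing")
  counts <- matrix(0L, nrow(records), length(cats),
                   dimnames = list(records$branch_id, cats))
  for (g in genes) {
    gs <- .tree_splits(g)
    for (r in seq_len(nrow(records))) {
      cl <- .classify_splits(gs, g$tip.label, records$bipartition[[r]],
                             threshold)
      counts[r, cl] <- counts[r, cl] + 1L
    }
  }
  out <- dplyr::bind_cols(
    records[c("branch_id", "key", "length", "support")],
    tibble::as_tibble(counts)
  )
  out$n_genes <- length(genes)
  class(out) <- c("conflict_tally", class(out))
  out
}

#' Conflict proportions per branch
#'
#' Converts a [tally_conflicts()] table to percentages. With
#' `include_missing = TRUE` (the five-way pie-chart convention) the
#' denominator is all gene trees; with `FALSE` (the regression convention)
#' only scored gene trees count.
#'
#' @param tally A `conflict_tally`.
#' @param include_missing Keep the missing category in the denominator
#'   (default TRUE).
#' @return A tibble with per-branch percentage columns `pct_*`.
#' @export
conflict_proportions <- function(tally, include_missing = TRUE) {
  cats <- c("strong_support", "weak_support", "strong_conflict",
            "weak_conflict", "missing")
  denom <- if (include_missing) tally$n_genes else
    tally$n_genes - tally$missing
  out <- tally[c("branch_id", "key", "length")]
  for (cat in cats) {
    if (!include_missing && cat == "missing") next
    out[[paste0("pct_", cat)]] <- 100 * tally[[cat]] / denom
  }
  tibble::as_tibble(out)
}

#' Ordinary least squares of a branch statistic on log branch length
#'
#' Fits `y ~ log(x)` by OLS and tests the null hypothesis of zero slope with
#' a two-sided t-test. Natural logarithm; the base only rescales the slope
#' and leaves the p-value unchanged.
#'
#' @param xs Positive branch lengths (any time unit).
#' @param ys Percentages (or any per-branch statistic), same length as `xs`,
#'   length >= 3.
#' @param response Name of the response for reporting (default "y").
#' @return An object of class `loglinear_fit`: list with `response`,
#'   `slope`, `intercept`, `p_slope`, `r_squared`, `n` and the underlying
#'   `lm` fit. Supports [generics::tidy()] and [generics::glance()].
#' @export
fit_loglinear <- function(xs, ys, response = "y") {
  if (any(xs <= 0)) stop("all branch lengths must be > 0 (got non-positive x)")
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  if (length(xs) < 3L) stop("need at least 3 points")
  fit <- stats::lm(ys ~ log(xs))
  if (stats::var(ys) == 0) {
    # constant response: slope exactly 0, no evidence against the null
    return(structure(list(response = response, slope = 0,
                          intercept = ys[1L], p_slope = 1, r_squared = 0,
                          n = length(xs), fit = fit),
                     class = "loglinear_fit"))
  }
  sm <- summary(fit)
  co <- stats::coef(sm)
  p_slope <- if (nrow(co) >= 2L && !is.na(co[2L, 2L]) && co[2L, 2L] > 0) {
    co[2L, 4L]
  } else 1
  structure(list(response = response,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 p_slope = unname(p_slope),
                 r_squared = sm$r.squared,
                 n = length(xs), fit = fit),
            class = "loglinear_fit")
}

#' @export
print.loglinear_fit <- function(x, ...) {
  cat(sprintf("<loglinear_fit> %s ~ log(x): slope %.4g (p = %.3g), r2 %.3f, n = %d\n",
              x$response, x$slope, x$p_slope, x$r_squared, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy loglinear_fit
#' @export
tidy.loglinear_fit <- function(x, ...) {
  co <- stats::coef(summary(x$fit))
  tibble::tibble(term = c("(Intercept)", "log(x)"),
                 estimate = co[, 1L], std.error = co[, 2L],
                 statistic = co[, 3L], p.value = co[, 4L])
}

#' @method glance loglinear_fit
#' @export
glance.loglinear_fit <- function(x, ...) {
  tibble::tibble(response = x$response, slope = x$slope,
                 intercept = x$intercept, p_slope = x$p_slope,
                 r.squared = x$r_squared, n = x$n)
}

#' Regress conflict percentages on log internode length
#'
#' Convenience wrapper: computes percentages from a tally (missing category
#' excluded from the denominator) and fits one log-linear model per
#' category. Branches without a positive length are dropped with a message.
#'
#' @param tally A [tally_conflicts()] result whose branches carry lengths.
#' @param lengths Optional named vector of branch lengths (names =
#'   `branch_id`) overriding the lengths stored in the tally, e.g. when
#'   regressing on time rather than coalescent units.
#' @return A tibble with one row per category: the [glance()] of each fit,
#'   plus a `fits` list column of `loglinear_fit` objects.
#' @export
conflict_regressions <- function(tally, lengths = NULL) {
  props <- conflict_proportions(tally, include_missing = FALSE)
  len <- props$length
  if (!is.null(lengths)) len <- unname(lengths[props$branch_id])
  ok <- !is.na(len) & len > 0
  if (!all(ok)) {
    message(sum(!ok), " branch(es) without positive length dropped from regression")
  }
  cats <- c("strong_support", "weak_support", "strong_conflict",
            "weak_conflict")
  fits <- lapply(cats, function(cat) {
    fit_loglinear(len[ok], props[[paste0("pct_", cat)]][ok], response = cat)
  })
  dplyr::bind_rows(lapply(fits, glance)) |>
    dplyr::mutate(fits = fits)
}
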