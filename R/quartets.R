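#' Count quartet topologies across a set of gene trees
#'
#' For each 4-taxon subset of `taxa`, every gene tree containing all four
#' taxa contributes one count to the resolved topology it displays after
#' restriction to those taxa; gene trees missing any of the four, or
#' unresolved on them, contribute nothing to the three counts (unresolved
#' trees are tallied separately). Quartets are keyed canonically by the
#' sorted taxon labels: `n1` counts the topology pairing the first taxon
#' with the second (t1t2 | t3t4), `n2` with the third, `n3` with the fourth.
#'
#' @param genes List of gene trees (`phylo` or `multiPhylo`).
#' @param taxa Character vector of at least four taxon labels.
#' @param max_quartets Exhaustive enumeration up to this many 4-subsets
#'   (default 500000); beyond it, a seeded uniform sample of this size is
#'   scored instead.
#' @param seed Seed for the subsample (only used when sampling kicks in).
#' @return A tibble with columns `t1`..`t4` (sorted taxa), `n1`, `n2`, `n3`,
#'   `n_unresolved` and `n` (= n1 + n2 + n3).
#' @export
count_quartet_topologies <- function(genes, taxa, max_quartets = 500000L,
                                     seed = 1L) {
  taxa <- sort(unique(as.character(taxa)))
  if (length(taxa) < 4L) stop("need at least four taxa")
  quartets <- utils::combn(taxa, 4L)
  if (ncol(quartets) > max_quartets) {
    set.seed(as.integer(seed))
    quartets <- quartets[, sample.int(ncol(quartets), max_quartets),
                         drop = FALSE]
    quartets <- quartets[, order(quartets[1L, ], quartets[2L, ],
                                 quartets[3L, ], quartets[4L, ]),
                         drop = FALSE]
  }
  nq <- ncol(quartets)
  counts <- matrix(0L, nq, 4L)   # n1, n2, n3, unresolved
  for (g in genes) {
    present <- quartets[1L, ] %in% g$tip.label &
      quartets[2L, ] %in% g$tip.label &
      quartets[3L, ] %in% g$tip.label &
      quartets[4L, ] %in% g$tip.label
    if (!any(present)) next
    sp <- .tree_splits(g)
    if (!length(sp$sides)) {
      counts[present, 4L] <- counts[present, 4L] + 1L
      next
    }
    # membership matrix: splits x tips
    M <- vapply(sp$sides, function(s) g$tip.label %in% s,
                logical(length(g$tip.label)))
    rownames(M) <- g$tip.label
    idx <- which(present)
    m1 <- M[quartets[1L, idx], , drop = FALSE]
    m2 <- M[quartets[2L, idx], , drop = FALSE]
    m3 <- M[quartets[3L, idx], , drop = FALSE]
    m4 <- M[quartets[4L, idx], , drop = FALSE]
    d12 <- (m1 == m2) & (m3 == m4) & (m1 != m3)
    d13 <- (m1 == m3) & (m2 == m4) & (m1 != m2)
    d14 <- (m1 == m4) & (m2 == m3) & (m1 != m2)
    topo1 <- rowSums(d12) > 0
    topo2 <- rowSums(d13) > 0
    topo3 <- rowSums(d14) > 0
    counts[idx[topo1], 1L] <- counts[idx[topo1], 1L] + 1L
    counts[idx[topo2], 2L] <- counts[idx[topo2], 2L] + 1L
    counts[idx[topo3], 3L] <- counts[idx[topo3], 3L] + 1L
    unres <- !(topo1 | topo2 | topo3)
    counts[idx[unres], 4L] <- counts[idx[unres], 4L] + 1L
  }
  tibble::tibble(t1 = quartets[1L, ], t2 = quartets[2L, ],
                 t3 = quartets[3L, ], t4 = quartets[4L, ],
                 n1 = counts[, 1L], n2 = counts[, 2L], n3 = counts[, 3L],
                 n_unresolved = counts[, 4L],
                 n = counts[, 1L] + counts[, 2L] + counts[, 3L])
}

#' Star (polytomy) test for a quartet
#'
#' Likelihood-ratio test of the null hypothesis that the three resolved
#' quartet topology probabilities are all 1/3 (a hard polytomy / star
#' quartet) against the unrestricted multinomial. The statistic is
#' 2 * sum(n_i log(3 n_i / n)), with zero counts contributing 0, referred to
#' a chi-squared distribution with 2 degrees of freedom.
#'
#' @param counts Numeric vector of the three topology counts (or a one-row
#'   quartet record with columns n1, n2, n3).
#' @return A list with `statistic` and `p.value` (`NA` when n = 0).
#' @export
star_test <- function(counts) {
  counts <- .quartet_counts(counts)
  n <- sum(counts)
  if (n == 0) return(list(statistic = NA_real_, p.value = NA_real_))
  terms <- ifelse(counts > 0, counts * log(3 * counts / n), 0)
  stat <- 2 * sum(terms)
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 2, lower.tail = FALSE))
}

.quartet_counts <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot(nrow(counts) == 1L)
    counts <- c(counts$n1, counts$n2, counts$n3)
  }
  stopifnot(length(counts) == 3L, all(counts >= 0))
  as.numeric(counts)
}

# MLE of (p1, p2, p3) under the T3 model {max coordinate >= 1/3, other two
# equal} and the resulting LR statistic.
.t3_stat <- function(counts) {
  n <- sum(counts)
  m <- max(counts)
  p_major <- max(m / n, 1 / 3)
  p_minor <- (1 - p_major) / 2
  phat <- rep(p_minor, 3L)
  phat[which.max(counts)] <- p_major
  terms <- ifelse(counts > 0, counts * log(counts / (n * phat)), 0)
  list(statistic = 2 * sum(terms), p_major = p_major)
}

#' T3 test: does a quartet fit some resolved species tree under the MSC?
#'
#' Tests the null hypothesis that the quartet topology counts arose from a
#' species quartet tree of unspecified topology under the multispecies
#' coalescent: the model T3 with one topology probability >= 1/3 and the two
#' minor probabilities equal. The maximum-likelihood estimate under T3 sets
#' the major probability to max(m/n, 1/3) (m the largest count) with equal
#' minors; the likelihood-ratio statistic 2 * sum(n_i log(n_i / (n p_i)))
#' is referred to a chi-squared distribution with 1 degree of freedom.
#' Near the simplex centre (|p_major - 1/3| < 2/sqrt(n)) the chi-squared
#' approximation is unreliable, so a parametric bootstrap p-value is used
#' there by default (and can be forced or disabled).
#'
#' @inheritParams star_test
#' @param bootstrap `"auto"` (bootstrap near the centre), `"never"`, or
#'   `"always"`.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap.
#' @return A list with `statistic`, `p.value`, `p_major` and `method`
#'   (`"chisq"` or `"bootstrap"`); `NA`s when n = 0.
#' @export
t3_test <- function(counts, bootstrap = c("auto", "never", "always"),
                    n_boot = 2000L, seed = 1L) {
  bootstrap <- match.arg(bootstrap)
  counts <- .quartet_counts(counts)
  n <- sum(counts)
  if (n == 0) {
    return(list(statistic = NA_real_, p.value = NA_real_,
                p_major = NA_real_, method = "none"))
  }
  ts <- .t3_stat(counts)
  near_centre <- abs(ts$p_major - 1 / 3) < 2 / sqrt(n)
  use_boot <- bootstrap == "always" || (bootstrap == "auto" && near_centre)
  if (!use_boot) {
    return(list(statistic = ts$statistic,
                p.value = stats::pchisq(ts$statistic, df = 1,
                                        lower.tail = FALSE),
                p_major = ts$p_major, method = "chisq"))
  }
  set.seed(as.integer(seed))
  p0 <- rep((1 - ts$p_major) / 2, 3L)
  p0[which.max(counts)] <- ts$p_major
  reps <- stats::rmultinom(n_boot, n, p0)
  stat_boot <- apply(reps, 2L, function(x) .t3_stat(x)$statistic)
  pval <- (1 + sum(stat_boot >= ts$statistic - 1e-12)) / (n_boot + 1)
  list(statistic = ts$statistic, p.value = pval,
       p_major = ts$p_major, method = "bootstrap")
}

#' Classify quartets as tree-like, star-like or reticulate
#'
#' Applies the NANUQ decision rule to each quartet record: reticulate when
#' the T3 test rejects at level `alpha` (the counts fit no species quartet
#' tree under the MSC); otherwise star-like when the star test fails to
#' reject at level `beta` (p_star >= beta); otherwise tree-like, with the
#' resolved topology taken as the argmax count (ties are classified
#' star-like). A summary reports the class fractions at the requested levels
#' and across a sensitivity grid of alpha values.
#'
#' @param records Output of [count_quartet_topologies()] (columns t1..t4,
#'   n1, n2, n3).
#' @param alpha Level of the T3 test (default 1e-6).
#' @param beta Level of the star test (default 0.1).
#' @param alpha_grid Additional alpha levels for the sensitivity summary
#'   (default 1e-2, 1e-3, 1e-5, 1e-6).
#' @param ... Passed on to [t3_test()] (e.g. `bootstrap`, `seed`).
#' @return A list of class `quartet_classification` with `results` (the
#'   records plus `p_star`, `p_t3`, `classification`, `topology`) and
#'   `summary` (fractions per class at each alpha level).
#' @export
classify_quartets <- function(records, alpha = 1e-6, beta = 0.1,
                              alpha_grid = c(1e-2, 1e-3, 1e-5, 1e-6), ...) {
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1)
  n_rec <- nrow(records)
  p_star <- p_t3 <- numeric(n_rec)
  for (i in seq_len(n_rec)) {
    cts <- c(records$n1[i], records$n2[i], records$n3[i])
    p_star[i] <- star_test(cts)$p.value
    p_t3[i] <- t3_test(cts, ...)$p.value
  }
  classify_at <- function(a) {
    cl <- character(n_rec)
    for (i in seq_len(n_rec)) {
      cts <- c(records$n1[i], records$n2[i], records$n3[i])
      if (is.na(p_t3[i])) {
        cl[i] <- NA_character_
      } else if (p_t3[i] < a) {
        cl[i] <- "reticulate"
      } else if (p_star[i] >= beta) {
        cl[i] <- "starlike"
      } else if (sum(cts == max(cts)) > 1L) {
        cl[i] <- "starlike"
      } else {
        cl[i] <- "treelike"
      }
    }
    cl
  }
  cl <- classify_at(alpha)
  topo <- ifelse(cl == "treelike",
                 c("t1t2|t3t4", "t1t3|t2t4", "t1t4|t2t3")[
                   max.col(cbind(records$n1, records$n2, records$n3),
                           ties.method = "first")],
                 NA_character_)
  results <- dplyr::mutate(tibble::as_tibble(records),
                           p_star = p_star, p_t3 = p_t3,
                           classification = cl, topology = topo)
  levels_all <- sort(unique(c(alpha, alpha_grid)))
  summary <- dplyr::bind_rows(lapply(levels_all, function(a) {
    cla <- classify_at(a)
    tibble::tibble(alpha = a, beta = beta,
                   frac_treelike = mean(cla == "treelike", na.rm = TRUE),
                   frac_starlike = mean(cla == "starlike", na.rm = TRUE),
                   frac_reticulate = mean(cla == "reticulate", na.rm = TRUE))
  }))
  structure(list(results = results, summary = summary,
                 alpha = alpha, beta = beta),
            class = "quartet_classification")
}

#' @export
print.quartet_classification <- function(x, ...) {
  cat(sprintf("<quartet_classification> %d quartets, alpha = %g, beta = %g\n",
              nrow(x$results), x$alpha, x$beta))
  print(x$summary)
  invisible(x)
}

#' @method tidy quartet_classification
#' @export
tidy.quartet_classification <- function(x, ...) x$results

#' @method glance quartet_classification
#' @export
glance.quartet_classification <- function(x, ...) {
  x$summary[x$summary$alpha == x$alpha, ]
}

#' NANUQ quartet distance matrix
#'
#' Converts per-quartet classifications into an inter-taxon distance whose
#' splits graph (computed by external splits-network software) reveals
#' network-like evolution. For a tree-like quartet resolved as ab|cd the
#' quartet contributes 0 to the pairs on the same cherry and 1 to the four
#' separated pairs; star-like and reticulate quartets contribute
#' `star_weight` and `hybrid_weight` to all six pairs (an approximation of
#' the published NANUQ weighting; both default to 1/2 and are configurable).
#'
#' @param classification A [classify_quartets()] result (or its `results`
#'   tibble).
#' @param taxa Character vector of taxa the matrix is over (default: all
#'   taxa appearing in the results).
#' @param star_weight,hybrid_weight Per-pair weight of star-like and
#'   reticulate quartets (default 0.5 each).
#' @return A symmetric numeric matrix with zero diagonal and taxa as
#'   dimnames. A warning reports quartets missing relative to
#'   choose(length(taxa), 4).
#' @export
nanuq_distance_matrix <- function(classification, taxa = NULL,
                                  star_weight = 0.5, hybrid_weight = 0.5) {
  res <- if (inherits(classification, "quartet_classification")) {
    classification$results
  } else {
    tibble::as_tibble(classification)
  }
  if (is.null(taxa)) {
    taxa <- sort(unique(c(res$t1, res$t2, res$t3, res$t4)))
  }
  n_expected <- choose(length(taxa), 4L)
  if (nrow(res) < n_expected) {
    warning(n_expected - nrow(res), " quartet(s) unscored; ",
            "distance matrix computed from the available quartets")
  }
  D <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  add <- function(x, y, w) {
    D[x, y] <<- D[x, y] + w
    D[y, x] <<- D[y, x] + w
  }
  for (i in seq_len(nrow(res))) {
    q <- c(res$t1[i], res$t2[i], res$t3[i], res$t4[i])
    cl <- res$classification[i]
    if (is.na(cl)) next
    if (cl == "treelike") {
      mate <- switch(res$topology[i],
                     "t1t2|t3t4" = c(2L, 1L, 4L, 3L),
                     "t1t3|t2t4" = c(3L, 4L, 1L, 2L),
                     "t1t4|t2t3" = c(4L, 3L, 2L, 1L))
      for (x in 1:3) for (y in (x + 1):4) {
        add(q[x], q[y], if (mate[x] == y) 0 else 1)
      }
    } else {
      w <- if (cl == "starlike") star_weight else hybrid_weight
      for (x in 1:3) for (y in (x + 1):4) add(q[x], q[y], w)
    }
  }
  D
}

#' Write a distance matrix as a nexus DISTANCES block
#'
#' Lower-triangular nexus format consumable by splits-network viewers.
#'
#' @param D Symmetric matrix with taxon dimnames (e.g. from
#'   [nanuq_distance_matrix()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_nanuq_nexus <- function(D, path) {
  taxa <- rownames(D)
  n <- length(taxa)
  lines <- c("#NEXUS", "",
             "BEGIN TAXA;",
             sprintf("  DIMENSIONS NTAX=%d;", n),
             "  TAXLABELS",
             paste0("    ", taxa),
             "  ;", "END;", "",
             "BEGIN DISTANCES;",
             sprintf("  DIMENSIONS NTAX=%d;", n),
             "  FORMAT TRIANGLE=LOWER DIAGONAL LABELS=LEFT;",
             "  MATRIX")
  for (i in seq_len(n)) {
    row <- paste(sprintf("%.6g", D[i, seq_len(i)]), collapse = " ")
    lines <- c(lines, paste0("    ", taxa[i], " ", row))
  }
  lines <- c(lines, "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}
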