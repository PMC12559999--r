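#' Expected quartet concordance factors under the multispecies coalescent
#'
#' For a species quartet with internal branch length `t` (coalescent units),
#' the gene-tree quartet topology matching the species tree has probability
#' 1 - (2/3) exp(-t) and each of the two discordant topologies has
#' probability (1/3) exp(-t).
#'
#' @param t Internal branch length in coalescent units (vectorised, >= 0).
#' @return A tibble with columns `t`, `cf_major`, `cf_minor1`, `cf_minor2`;
#'   rows sum to 1 across the three concordance factors.
#' @examples
#' expected_quartet_cf(c(0, 1))
#' @export
expected_quartet_cf <- function(t) {
  if (any(t < 0)) stop("branch length t must be >= 0")
  minor <- exp(-t) / 3
  tibble::tibble(t = t, cf_major = 1 - 2 * minor,
                 cf_minor1 = minor, cf_minor2 = minor)
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Draws `n_loci` gene trees on a rooted species tree with branch lengths in
#' coalescent units, sampling one haploid lineage per tip. Within each
#' species-tree branch of length t, the lineages present coalesce pairwise at
#' rate 1 per pair until the branch is exhausted; lineages remaining at the
#' root coalesce in the ancestral population with unlimited time. Population
#' sizes are absorbed into the coalescent-unit branch lengths (no separate Ne
#' parameter). Gene-tree branch lengths are retained in coalescent units.
#'
#' @param species Rooted `phylo` with all internal branch lengths present
#'   (coalescent units). Missing terminal branch lengths are treated as 0.
#' @param n_loci Number of gene trees to simulate.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A `multiPhylo` list of rooted gene trees with a `topology_key`
#'   attribute: the canonical rooted topology string of each gene tree
#'   (see [topology_key()]), useful for tallying topology frequencies.
#' @export
simulate_gene_trees <- function(species, n_loci, seed = 1L) {
  stopifnot(inherits(species, "phylo"), n_loci >= 1)
  if (!ape::is.rooted(species)) stop("species tree must be rooted")
  ntip <- length(species$tip.label)
  tr <- stats::reorder(species, "postorder")
  edge <- tr$edge
  el <- tr$edge.length
  if (is.null(el)) stop("species tree has no branch lengths")
  term <- edge[, 2L] <= ntip
  if (any(is.na(el[!term]))) {
    bad <- edge[!term & is.na(el), 2L]
    stop("missing coalescent-unit length on internal branch above node(s): ",
         paste(bad, collapse = ", "))
  }
  el[term & is.na(el)] <- 0
  # node ages: tips anchored by depth from root
  el0 <- el
  depth <- numeric(ntip + tr$Nnode)
  pre <- stats::reorder(species, "cladewise")
  pel <- pre$edge.length
  pel[is.na(pel)] <- 0
  for (i in seq_len(nrow(pre$edge))) {
    depth[pre$edge[i, 2L]] <- depth[pre$edge[i, 1L]] + pel[i]
  }
  age <- max(depth) - depth
  root <- ntip + 1L
  set.seed(as.integer(seed))
  fmt <- function(x) sprintf("%.8g", x)
  newick <- character(n_loci)
  topo <- character(n_loci)
  for (locus in seq_len(n_loci)) {
    # pending lineages per species node: parallel vectors
    pend_str <- vector("list", ntip + tr$Nnode)   # newick fragments
    pend_key <- vector("list", ntip + tr$Nnode)   # canonical topology keys
    pend_age <- vector("list", ntip + tr$Nnode)
    for (i in seq_len(ntip)) {
      pend_str[[i]] <- tr$tip.label[i]
      pend_key[[i]] <- tr$tip.label[i]
      pend_age[[i]] <- age[i]
    }
    run_coal <- function(strs, keys, ages, a0, tmax) {
      elapsed <- 0
      k <- length(strs)
      while (k >= 2L) {
        rate <- k * (k - 1) / 2
        dt <- stats::rexp(1L) / rate
        if (elapsed + dt > tmax) break
        elapsed <- elapsed + dt
        pair <- sample.int(k, 2L)
        i <- pair[1L]; j <- pair[2L]
        anew <- a0 + elapsed
        s <- paste0("(", strs[i], ":", fmt(anew - ages[i]), ",",
                    strs[j], ":", fmt(anew - ages[j]), ")")
        kk <- sort(c(keys[i], keys[j]))
        knew <- paste0("(", kk[1L], ",", kk[2L], ")")
        strs <- c(strs[-pair], s)
        keys <- c(keys[-pair], knew)
        ages <- c(ages[-pair], anew)
        k <- k - 1L
      }
      list(strs = strs, keys = keys, ages = ages)
    }
    for (i in seq_len(nrow(edge))) {
      v <- edge[i, 2L]; p <- edge[i, 1L]
      res <- run_coal(unlist(pend_str[[v]]), unlist(pend_key[[v]]),
                      unlist(pend_age[[v]]), age[v], el0[i])
      pend_str[[p]] <- c(pend_str[[p]], res$strs)
      pend_key[[p]] <- c(pend_key[[p]], res$keys)
      pend_age[[p]] <- c(pend_age[[p]], res$ages)
    }
    res <- run_coal(unlist(pend_str[[root]]), unlist(pend_key[[root]]),
                    unlist(pend_age[[root]]), age[root], Inf)
    newick[locus] <- paste0(res$strs, ";")
    topo[locus] <- res$keys
  }
  trees <- ape::read.tree(text = paste(newick, collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- structure(list(trees),
                                                   class = "multiPhylo")
  attr(trees, "topology_key") <- topo
  attr(trees, "length_unit") <- "coalescent"
  attr(trees, "seed") <- as.integer(seed)
  trees
}

#' Canonical topology key of a rooted or unrooted tree
#'
#' For `rooted = TRUE`, a canonical newick-like string with children sorted
#' lexicographically, so two trees share a key iff they have the same rooted
#' topology. For `rooted = FALSE`, the sorted set of canonical split keys.
#'
#' @param tree A `phylo` object.
#' @param rooted Compare as rooted (default) or as unrooted topologies.
#' @return A character scalar.
#' @export
topology_key <- function(tree, rooted = TRUE) {
  if (!rooted) {
    bp <- extract_bipartitions(tree)
    return(paste(sort(bp$key), collapse = ";"))
  }
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  rec <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    paste0("(", paste(sort(vapply(kids[[as.character(v)]], rec,
                                  character(1))), collapse = ","), ")")
  }
  rec(ntip + 1L)
}

#' Tabulate gene-tree topology frequencies
#'
#' @param trees A `multiPhylo` (topology keys are taken from the
#'   `topology_key` attribute when present, otherwise computed).
#' @param rooted Passed to [topology_key()] when keys must be computed.
#' @return A tibble with columns `topology`, `n`, `freq`, sorted by
#'   decreasing frequency.
#' @export
topology_freq <- function(trees, rooted = TRUE) {
  keys <- attr(trees, "topology_key")
  if (is.null(keys) || !rooted) {
    keys <- vapply(trees, topology_key, character(1), rooted = rooted)
  }
  tb <- sort(table(keys), decreasing = TRUE)
  tibble::tibble(topology = names(tb), n = as.integer(tb),
                 freq = as.integer(tb) / length(keys))
}

#' Gene-tree estimation-error model
#'
#' Parameters of the topology-error and pseudo-support model applied by
#' [apply_estimation_error()]. The probability that an internal branch is hit
#' by a random nearest-neighbour interchange (NNI) is
#' `base_nni_prob * exp(-length / length_scale)`: short branches are
#' perturbed more often, mimicking the difficulty of estimating short
#' internodes from finite alignments. Pseudo-supports have mean
#' `100 * (1 - exp(-length / support_scale))` (multiplied by
#' `perturb_factor` on branches involved in an NNI) plus Gaussian noise,
#' truncated to \[0, 100\]: long internodes saturate near 100 while short
#' ones are weakly supported.
#'
#' @param base_nni_prob NNI probability at zero branch length (default 0.5).
#' @param length_scale Coalescent-unit scale of the error decay (default
#'   0.3, so estimation error is concentrated on very short internodes).
#' @param support_scale Coalescent-unit scale of support saturation: expected
#'   support is 63 at this branch length (default 0.4).
#' @param support_sd Gaussian noise of the pseudo-support (default 10).
#' @param perturb_factor Multiplier on the expected support of branches
#'   involved in an NNI (default 0.4).
#' @return A list of class `error_model`.
#' @export
error_model <- function(base_nni_prob = 0.5, length_scale = 0.3,
                        support_scale = 0.4, support_sd = 10,
                        perturb_factor = 0.4) {
  stopifnot(base_nni_prob >= 0, base_nni_prob <= 1, length_scale > 0,
            support_scale > 0, support_sd >= 0,
            perturb_factor >= 0, perturb_factor <= 1)
  structure(list(base_nni_prob = base_nni_prob, length_scale = length_scale,
                 support_scale = support_scale, support_sd = support_sd,
                 perturb_factor = perturb_factor), class = "error_model")
}

#' Apply topology-estimation error and pseudo-supports to a gene tree
#'
#' Each internal branch is independently subjected to a random
#' nearest-neighbour interchange with probability given by the
#' [error_model()], choosing uniformly between the two alternative
#' configurations; every internal node is then assigned a pseudo-support in
#' \[0, 100\], lower in expectation for short and for perturbed branches.
#'
#' @param tree A resolved rooted `phylo` with branch lengths (coalescent
#'   units).
#' @param model An [error_model()].
#' @param seed Integer seed.
#' @return A `phylo` with (possibly) perturbed topology and numeric
#'   `node.label` supports.
#' @export
apply_estimation_error <- function(tree, model = error_model(), seed = 1L) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "error_model"))
  set.seed(as.integer(seed))
  tr <- stats::reorder(tree, "cladewise")
  ntip <- length(tr$tip.label)
  edge <- tr$edge
  el <- tr$edge.length
  if (is.null(el)) el <- rep(0, nrow(edge))
  root <- ntip + 1L
  internal <- which(edge[, 2L] > ntip)
  orig_len <- stats::setNames(rep(NA_real_, ntip + tr$Nnode), NULL)
  orig_len[edge[, 2L]] <- el
  perturbed_nodes <- integer()
  for (i in internal) {
    v <- edge[i, 2L]; u <- edge[i, 1L]
    p_nni <- model$base_nni_prob * exp(-el[i] / model$length_scale)
    if (stats::runif(1L) >= p_nni) next
    ch_u <- setdiff(edge[edge[, 1L] == u, 2L], v)
    ch_v <- edge[edge[, 1L] == v, 2L]
    if (!length(ch_u) || length(ch_v) < 2L) next
    cu <- if (length(ch_u) == 1L) ch_u else sample(ch_u, 1L)
    cv <- sample(ch_v, 1L)
    edge[edge[, 2L] == cu, 1L] <- v
    edge[edge[, 2L] == cv, 1L] <- u
    perturbed_nodes <- c(perturbed_nodes, v, u)
  }
  tr$edge <- edge
  # pseudo-supports per internal node (root gets NA)
  sup <- rep(NA_real_, tr$Nnode)
  for (nd in (ntip + 1L):(ntip + tr$Nnode)) {
    if (nd == root) next
    len <- orig_len[nd]
    if (is.na(len)) len <- 0
    mean_sup <- 100 * (1 - exp(-len / model$support_scale))
    if (nd %in% perturbed_nodes) mean_sup <- mean_sup * model$perturb_factor
    s <- stats::rnorm(1L, mean_sup, model$support_sd)
    sup[nd - ntip] <- min(100, max(0, s))
  }
  tr$node.label <- ifelse(is.na(sup), "", sprintf("%.4g", sup))
  attr(tr, "order") <- NULL   # edge matrix was rewritten; force a real reorder
  tr <- stats::reorder(tr, "cladewise")
  attr(tr, "length_unit") <- attr(tree, "length_unit")
  tr
}

#' Parameters for the synthetic ANI-table generator
#'
#' @param anchors A data frame with columns `time` (pairwise divergence time,
#'   millions of years, increasing) and `ani` (expected average nucleotide
#'   identity, percent, strictly decreasing in time). Expected ANI for a pair
#'   is linearly interpolated between anchors.
#' @param noise_sd Gaussian noise on each emitted ANI value (percentage
#'   points, default 0.3).
#' @param gap Optional length-2 numeric: an open percent interval to be left
#'   empty; simulated values landing inside are redrawn (default none).
#' @param asym_sd Extra noise distinguishing the (query, reference) and
#'   (reference, query) directions (default 0.05).
#' @return A list of class `ani_sim_params`.
#' @export
ani_sim_params <- function(anchors = data.frame(
                             time = c(0, 25, 100, 300, 600, 1000),
                             ani = c(100, 97.5, 93, 84, 78, 74)),
                           noise_sd = 0.3, gap = NULL, asym_sd = 0.05) {
  stopifnot(is.data.frame(anchors), all(c("time", "ani") %in% names(anchors)),
            !is.unsorted(anchors$time), all(diff(anchors$ani) < 0),
            all(anchors$ani > 0 & anchors$ani <= 100), noise_sd >= 0)
  if (!is.null(gap)) stopifnot(length(gap) == 2L, gap[1] < gap[2])
  structure(list(anchors = anchors, noise_sd = noise_sd, gap = gap,
                 asym_sd = asym_sd), class = "ani_sim_params")
}

#' Simulate a pairwise ANI table on an ultrametric dated tree
#'
#' Expected ANI for each genome pair is a monotone decreasing map of the
#' pair's divergence time; Gaussian noise is added, values are truncated at
#' 100, and values landing inside the imposed gap interval are redrawn.
#' Both (query, reference) directions are emitted with a small asymmetry, in
#' FastANI-style long format.
#'
#' @param tree Ultrametric `phylo` with branch lengths in millions of years.
#' @param params An [ani_sim_params()].
#' @param seed Integer seed.
#' @return A tibble with columns `query`, `reference`, `ani`,
#'   `frag_mapped`, `frag_total`.
#' @export
simulate_ani_table <- function(tree, params = ani_sim_params(), seed = 1L) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "ani_sim_params"))
  if (!ape::is.ultrametric(tree, tol = 1e-6)) {
    stop("tree must be ultrametric (divergence times)")
  }
  set.seed(as.integer(seed))
  dmat <- ape::cophenetic.phylo(tree) / 2   # pairwise divergence time
  labs <- rownames(dmat)
  draw <- function(mu) {
    repeat {
      v <- min(100, stats::rnorm(1L, mu, params$noise_sd))
      if (is.null(params$gap) ||
          !(v > params$gap[1] && v < params$gap[2])) return(v)
    }
  }
  rows <- list()
  k <- 0L
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (i == j) next
      mu <- stats::approx(params$anchors$time, params$anchors$ani,
                          xout = dmat[i, j], rule = 2)$y
      k <- k + 1L
      rows[[k]] <- c(mu = draw(mu + stats::rnorm(1L, 0, params$asym_sd)))
    }
  }
  idx <- which(outer(seq_along(labs), seq_along(labs), "!="), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  ani <- vapply(rows, unname, numeric(1))
  total <- 1000L
  tibble::tibble(query = labs[idx[, 1L]], reference = labs[idx[, 2L]],
                 ani = ani, frag_mapped = as.integer(round(total * ani / 100)),
                 frag_total = total)
}

#' Parameters for the synthetic specimen-table generator
#'
#' @param n_sites Number of collection sites.
#' @param otu_counts Named integer vector: number of specimens per
#'   cyanobacterial OTU.
#' @param partner_pools Named list (one entry per OTU) of fungal partner
#'   labels available to that OTU; pools may overlap between OTUs.
#' @param sharing_elevation Excess probability (>= 0, capped at 1) that a
#'   specimen adopts the fungal partner of a co-occurring specimen, mimicking
#'   vertical transmission of the symbiont within sites. 0 makes partner
#'   choice independent of co-occurrence.
#' @return A list of class `specimen_sim_params`.
#' @export
specimen_sim_params <- function(n_sites, otu_counts, partner_pools,
                                sharing_elevation = 0) {
  stopifnot(n_sites >= 1, length(otu_counts) >= 1,
            !is.null(names(otu_counts)), all(otu_counts >= 1),
            sharing_elevation >= 0)
  if (!all(names(otu_counts) %in% names(partner_pools))) {
    stop("every OTU needs a partner pool")
  }
  if (any(lengths(partner_pools[names(otu_counts)]) == 0)) {
    stop("empty partner pool for OTU: ",
         paste(names(otu_counts)[lengths(partner_pools[names(otu_counts)]) == 0],
               collapse = ", "))
  }
  structure(list(n_sites = n_sites, otu_counts = otu_counts,
                 partner_pools = partner_pools,
                 sharing_elevation = min(1, sharing_elevation)),
            class = "specimen_sim_params")
}

#' Simulate a specimen table with tunable local partner sharing
#'
#' Specimens are placed uniformly across sites. Each specimen draws a fungal
#' partner uniformly from its OTU's pool, except that with probability
#' `sharing_elevation` it instead copies the partner of a random co-occurring
#' specimen already placed at its site (when one with a compatible partner
#' exists). With `sharing_elevation = 0`, partner sharing between two
#' specimens is independent of whether they co-occur.
#'
#' @param params A [specimen_sim_params()].
#' @param seed Integer seed.
#' @return A tibble with columns `specimen`, `site`, `otu`, `partner`.
#' @export
simulate_specimen_table <- function(params, seed = 1L) {
  stopifnot(inherits(params, "specimen_sim_params"))
  set.seed(as.integer(seed))
  otu <- rep(names(params$otu_counts), params$otu_counts)
  n <- length(otu)
  otu <- sample(otu)                       # random placement order
  site <- paste0("site", sample.int(params$n_sites, n, replace = TRUE))
  partner <- character(n)
  for (i in seq_len(n)) {
    pool <- params$partner_pools[[otu[i]]]
    partner[i] <- sample(pool, 1L)
    if (params$sharing_elevation > 0 && i > 1L &&
        stats::runif(1L) < params$sharing_elevation) {
      prev <- which(site[seq_len(i - 1L)] == site[i] &
                      partner[seq_len(i - 1L)] %in% pool)
      if (length(prev)) {
        donor <- if (length(prev) == 1L) prev else sample(prev, 1L)
        partner[i] <- partner[donor]
      }
    }
  }
  tibble::tibble(specimen = sprintf("sp%04d", seq_len(n)),
                 site = site, otu = otu, partner = partner)
}
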