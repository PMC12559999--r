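test_that("expected quartet concordance factors follow the MSC closed form", {
  cf0 <- expected_quartet_cf(0)
  expect_equal(unlist(cf0[, -1]), c(cf_major = 1 / 3, cf_minor1 = 1 / 3,
                                    cf_minor2 = 1 / 3))
  cf_inf <- expected_quartet_cf(50)
  expect_equal(cf_inf$cf_major, 1, tolerance = 1e-12)
  cf1 <- expected_quartet_cf(1)
  expect_equal(cf1$cf_major, 1 - (2 / 3) * exp(-1))
  expect_equal(cf1$cf_minor1, exp(-1) / 3)
  expect_equal(cf1$cf_major + cf1$cf_minor1 + cf1$cf_minor2, 1)
  expect_error(expected_quartet_cf(-0.1), ">= 0")
})

test_that("long internal branches yield fully concordant gene trees", {
  sp <- parse_newick("((A:25,B:25):25,(C:50,D:50):25);", unit = "coalescent")
  sims <- simulate_gene_trees(sp, 40, seed = 5)
  tf <- topology_freq(sims)
  expect_equal(nrow(tf), 1L)
  expect_equal(tf$topology, topology_key(sp))
})

test_that("quartet discordance frequency matches (1/3)exp(-t) at t = 1", {
  # unrooted internal edge length 1 (= 0.5 + 0.5 across the root)
  sp <- parse_newick("((A:1,B:1):0.5,(C:1,D:1):0.5);", unit = "coalescent")
  n_loci <- 4000
  sims <- simulate_gene_trees(sp, n_loci, seed = 7)
  q <- count_quartet_topologies(sims, c("A", "B", "C", "D"))
  p_minor <- exp(-1) / 3
  mc_se <- sqrt(p_minor * (1 - p_minor) / n_loci)
  expect_lt(abs(q$n2 / q$n - p_minor), 3 * mc_se)
  expect_lt(abs(q$n3 / q$n - p_minor), 3 * mc_se)
  expect_equal(q$n, n_loci)
})

test_that("a fixed seed reproduces the simulation byte for byte", {
  sp <- make_caterpillar(c(0.2, 0.5))
  s1 <- simulate_gene_trees(sp, 25, seed = 99)
  s2 <- simulate_gene_trees(sp, 25, seed = 99)
  expect_identical(lapply(s1, write_newick), lapply(s2, write_newick))
  expect_identical(attr(s1, "topology_key"), attr(s2, "topology_key"))
  s3 <- simulate_gene_trees(sp, 25, seed = 100)
  expect_false(identical(attr(s1, "topology_key"), attr(s3, "topology_key")))
})

test_that("each simulated gene tree is a full binary coalescent tree", {
  sp <- make_caterpillar(c(0.1, 0.3, 0.8))
  sims <- simulate_gene_trees(sp, 30, seed = 3)
  for (g in sims) {
    expect_equal(g$Nnode, length(g$tip.label) - 1L)  # n - 1 coalescences
    expect_true(all(g$edge.length >= 0))
  }
  expect_setequal(sims[[1]]$tip.label, sp$tip.label)
})

test_that("missing internal branch lengths stop the simulator", {
  sp <- parse_newick("((A:1,B:1),(C:2,D:2):5);", unit = "coalescent")
  expect_error(simulate_gene_trees(sp, 5, seed = 1), "missing coalescent")
})

test_that("estimation error leaves topology unchanged at zero NNI rate", {
  sp <- make_caterpillar(c(0.2, 0.5, 1))
  sims <- simulate_gene_trees(sp, 20, seed = 13)
  for (i in 1:5) {
    e <- apply_estimation_error(sims[[i]],
                                error_model(base_nni_prob = 0),
                                seed = i)
    expect_identical(topology_key(e), attr(sims, "topology_key")[i])
    sup <- branch_supports(e)
    expect_true(all(stats::na.omit(sup) >= 0 & stats::na.omit(sup) <= 100))
  }
})

test_that("shorter internodes raise the rate of weakly supported conflict", {
  n_loci <- 250
  run <- function(len) {
    sp <- make_caterpillar(rep(len, 3))
    sims <- simulate_gene_trees(sp, n_loci, seed = 31)
    err <- lapply(seq_along(sims), function(i) {
      apply_estimation_error(sims[[i]], error_model(), seed = 5000 + i)
    })
    tal <- tally_conflicts(sp, err, threshold = 95)
    sum(tal$weak_conflict) / (nrow(tal) * n_loci)
  }
  expect_gt(run(0.05), run(2.0))
})

test_that("synthetic ANI respects monotonicity, the gap and asymmetry bounds", {
  tr <- ape::read.tree(text = "((g1:10,g2:10):390,((g3:20,g4:20):40,g5:60):340);")
  ani <- simulate_ani_table(tr, ani_sim_params(gap = c(85, 87)), seed = 3)
  expect_equal(nrow(ani), 5 * 4)
  expect_true(all(ani$ani <= 100))
  expect_false(any(ani$ani > 85 & ani$ani < 87))     # imposed gap left empty
  M <- symmetrize_ani(ani)
  # deeper divergence -> lower expected ANI
  expect_gt(M["g1", "g2"], M["g3", "g4"])
  expect_gt(M["g3", "g4"], M["g3", "g5"])
  expect_gt(M["g3", "g5"], M["g1", "g3"])
  expect_error(simulate_ani_table(ape::rtree(5), ani_sim_params(), seed = 1),
               "ultrametric")
})

test_that("specimen generator respects counts and the null sharing property", {
  pools <- list(V = paste0("f", 1:5), X = paste0("f", 1:5))
  p0 <- specimen_sim_params(n_sites = 15, otu_counts = c(V = 120, X = 80),
                            partner_pools = pools, sharing_elevation = 0)
  spec <- simulate_specimen_table(p0, seed = 4)
  expect_equal(unname(table(spec$otu)[c("V", "X")]), c(120L, 80L),
               ignore_attr = TRUE)
  expect_identical(spec, simulate_specimen_table(p0, seed = 4))

  # elevation 0: sharing independent of co-occurrence (>= 10,000 pairs)
  tab <- partner_sharing_table(spec, "V:X")
  expect_gte(tab$total_pairs, 9600)
  p_share <- 1 / 5
  se <- sqrt(p_share * (1 - p_share) / tab$cooccurring_pairs)
  expect_lt(abs(tab$pct_cooccurring_sharing_exact -
                  tab$pct_noncooccurring_sharing_exact) / 100, 3 * se)

  expect_error(specimen_sim_params(5, c(V = 3), list(V = character(0))),
               "empty partner pool")
})

test_that("positive sharing elevation raises co-occurring partner sharing", {
  pools <- list(V = paste0("f", 1:6), X = paste0("f", 1:6))
  p1 <- specimen_sim_params(n_sites = 12, otu_counts = c(V = 150, X = 150),
                            partner_pools = pools, sharing_elevation = 0.6)
  spec <- simulate_specimen_table(p1, seed = 8)
  tab <- partner_sharing_table(spec, c("V:X", "V:V"))
  expect_true(all(tab$pct_cooccurring_sharing_exact >
                    tab$pct_noncooccurring_sharing_exact))
})
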