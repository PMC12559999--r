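test_that("quartet counts follow displayed topologies and missing taxa", {
  g <- parse_newick("((a,b),(c,d));")
  q <- count_quartet_topologies(list(g, g, g), c("a", "b", "c", "d"))
  expect_equal(c(q$n1, q$n2, q$n3, q$n), c(3, 0, 0, 3))

  gmiss <- parse_newick("((a,b),c);")
  q2 <- count_quartet_topologies(list(g, gmiss), c("a", "b", "c", "d"))
  expect_equal(q2$n, 1)

  gstar <- parse_newick("(a,b,c,d);")
  q3 <- count_quartet_topologies(list(gstar), c("a", "b", "c", "d"))
  expect_equal(q3$n, 0)
  expect_equal(q3$n_unresolved, 1)

  # concordance factors sum to 1 whenever n > 0
  set.seed(9)
  genes <- lapply(1:10, function(i) ape::rtree(6, tip.label = letters[1:6]))
  qq <- count_quartet_topologies(genes, letters[1:6])
  expect_equal((qq$n1 + qq$n2 + qq$n3) / qq$n, rep(1, nrow(qq)))
  # canonical keying: taxon input order does not matter
  qq2 <- count_quartet_topologies(genes, rev(letters[1:6]))
  expect_equal(qq, qq2)
})

test_that("fast counting equals brute-force per-tree restriction (8 taxa)", {
  set.seed(17)
  taxa <- letters[1:8]
  genes <- lapply(1:20, function(i) {
    g <- ape::rtree(8, tip.label = taxa)
    if (i %% 4 == 0) g <- ape::drop.tip(g, sample(taxa, 1))
    g
  })
  fast <- count_quartet_topologies(genes, taxa)
  expect_equal(nrow(fast), choose(8, 4))
  for (r in seq_len(nrow(fast))) {
    q <- c(fast$t1[r], fast$t2[r], fast$t3[r], fast$t4[r])
    topo <- vapply(genes, oracle_quartet_topology, integer(1), q = q)
    expect_equal(c(fast$n1[r], fast$n2[r], fast$n3[r]),
                 c(sum(topo == 1, na.rm = TRUE), sum(topo == 2, na.rm = TRUE),
                   sum(topo == 3, na.rm = TRUE)),
                 info = paste(q, collapse = ","))
  }
})

test_that("the star test matches its likelihood-ratio formula", {
  s1 <- star_test(c(100, 100, 100))
  expect_equal(s1$statistic, 0)
  expect_equal(s1$p.value, 1)

  s2 <- star_test(c(300, 0, 0))
  expect_equal(s2$statistic, 2 * 300 * log(3))
  expect_lt(s2$p.value, 1e-100)

  s3 <- star_test(c(40, 30, 30))
  stat <- 2 * (40 * log(3 * 40 / 100) + 30 * log(3 * 30 / 100) +
                 30 * log(3 * 30 / 100))
  expect_equal(s3$statistic, stat)
  expect_equal(s3$p.value, pchisq(stat, 2, lower.tail = FALSE))

  expect_true(is.na(star_test(c(0, 0, 0))$p.value))
})

test_that("the T3 statistic vanishes inside the model", {
  expect_equal(t3_test(c(50, 25, 25))$statistic, 0)
  expect_equal(t3_test(c(50, 25, 25))$p.value, 1)
  expect_equal(t3_test(c(100, 100, 100))$statistic, 0)  # centre is in T3
  expect_equal(t3_test(c(100, 100, 100))$p.value, 1)
  t <- t3_test(c(40, 40, 20))
  expect_gt(t$statistic, 0)
  expect_true(is.na(t3_test(c(0, 0, 0))$p.value))
})

test_that("chi-squared T3 p-values agree with the bootstrap away from centre", {
  cases <- list(c(150, 80, 70), c(200, 60, 40), c(180, 70, 50),
                c(120, 100, 80))
  for (cts in cases) {
    pc <- t3_test(cts, bootstrap = "never")$p.value
    pb <- t3_test(cts, bootstrap = "always", n_boot = 10000, seed = 42)$p.value
    expect_lt(abs(pc - pb), 0.02)
  }
})

test_that("T3 p-values are close to uniform under interior null sampling", {
  set.seed(55)
  n_loci <- 300
  p <- expected_quartet_cf(0.8)
  probs <- c(p$cf_major, p$cf_minor1, p$cf_minor2)
  pvals <- replicate(400, {
    t3_test(as.vector(rmultinom(1, n_loci, probs)), bootstrap = "never")$p.value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the NANUQ decision rule classifies canonical cases", {
  recs <- tibble::tibble(
    t1 = "a", t2 = "b", t3 = "c", t4 = "d",
    n1 = c(600L, 340L), n2 = c(200L, 330L), n3 = c(200L, 330L),
    n_unresolved = 0L, n = c(1000L, 1000L)
  )
  cl <- classify_quartets(recs, alpha = 1e-6, beta = 0.1)
  expect_equal(cl$results$classification, c("treelike", "starlike"))
  expect_equal(cl$results$topology, c("t1t2|t3t4", NA))
  expect_true(all(c(1e-2, 1e-3, 1e-5, 1e-6) %in% cl$summary$alpha))
  # argmax ties go to starlike
  tie <- tibble::tibble(t1 = "a", t2 = "b", t3 = "c", t4 = "d",
                        n1 = 80L, n2 = 80L, n3 = 20L,
                        n_unresolved = 0L, n = 180L)
  clt <- classify_quartets(tie, alpha = 1e-12, beta = 1e-8)
  expect_equal(clt$results$classification, "starlike")
})

test_that("NANUQ distances match definitional and brute-force sums", {
  one <- tibble::tibble(t1 = "a", t2 = "b", t3 = "c", t4 = "d",
                        n1 = 50L, n2 = 0L, n3 = 0L, n_unresolved = 0L,
                        n = 50L, p_star = 0, p_t3 = 1,
                        classification = "treelike", topology = "t1t2|t3t4")
  D <- nanuq_distance_matrix(one)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["c", "d"], 0)
  expect_equal(D["a", "c"], 1)
  expect_equal(D["b", "d"], 1)
  expect_true(isSymmetric(D))
  expect_equal(diag(D), setNames(rep(0, 4), letters[1:4]))

  # 5 taxa, tree-consistent quartets: equals brute-force over all 5 quartets
  sp <- parse_newick("(((a:8,b:8):8,c:16):8,(d:16,e:16):8);",
                     unit = "coalescent")
  genes <- simulate_gene_trees(sp, 150, seed = 12)
  recs <- count_quartet_topologies(genes, sp$tip.label)
  cl <- classify_quartets(recs, alpha = 1e-6, beta = 0.1)
  D2 <- nanuq_distance_matrix(cl)
  D2_oracle <- oracle_nanuq(cl$results, sort(sp$tip.label))
  expect_equal(D2, D2_oracle)

  # all-starlike input: constant off-diagonal 1/2 per shared quartet
  star <- dplyr::mutate(cl$results, classification = "starlike",
                        topology = NA_character_)
  D3 <- nanuq_distance_matrix(star)
  off <- D3[upper.tri(D3)]
  expect_true(all(off == 0.5 * choose(3, 2)))   # each pair in 3 of 5 quartets
})

test_that("missing quartets trigger a warning but still yield a matrix", {
  one <- tibble::tibble(t1 = "a", t2 = "b", t3 = "c", t4 = "d",
                        n1 = 10L, n2 = 0L, n3 = 0L, n_unresolved = 0L,
                        n = 10L, p_star = 0, p_t3 = 1,
                        classification = "treelike", topology = "t1t2|t3t4")
  expect_warning(D <- nanuq_distance_matrix(one, taxa = letters[1:5]),
                 "unscored")
  expect_equal(dim(D), c(5L, 5L))
})

test_that("nexus export is well-formed and lower-triangular", {
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  path <- withr::local_tempfile(fileext = ".nex")
  write_nanuq_nexus(D, path)
  lines <- readLines(path)
  expect_equal(lines[1], "#NEXUS")
  expect_true(any(grepl("BEGIN DISTANCES;", lines)))
  expect_true(any(grepl("TRIANGLE=LOWER", lines)))
  expect_true(any(grepl("^    z 2 3 0$", lines)))
})
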