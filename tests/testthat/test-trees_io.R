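test_that("newick parsing attaches lengths, supports and units", {
  tr <- parse_newick("((A:1,B:1):0.5,C:1.5);", unit = "coalescent")
  expect_s3_class(tr, "phylo")
  expect_equal(attr(tr, "length_unit"), "coalescent")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(sort(tr$edge.length), c(0.5, 1, 1, 1.5))

  tr2 <- parse_newick("((A,B)95:0.2,(C,D)80:0.1);")
  expect_equal(sort(branch_supports(tr2)), c(80, 95))
})

test_that("malformed newick is rejected with informative errors", {
  expect_error(parse_newick("((A,B);"), "unbalanced")
  expect_error(parse_newick("((A,B),(A,C));"), "duplicate")
  expect_error(parse_newick("((A,B),C)"), "ending in ';'")
})

test_that("proportion-scale supports are rescaled to 0-100 with a warning", {
  expect_warning(tr <- parse_newick("((A,B)0.97:0.2,(C,D)0.8:0.1);"),
                 "rescaling")
  expect_equal(sort(branch_supports(tr)), c(80, 97))
})

test_that("newick round trip preserves topology, lengths and supports", {
  texts <- c("((A:1,B:1)90:0.5,C:1.5);",
             "((A,B),(C,(D,E)));",
             "(((a:0.1,b:0.2)75:0.3,c:0.4)99:0.5,(d:0.6,e:0.7)50:0.8,f:1);")
  for (txt in texts) {
    t1 <- parse_newick(txt)
    t2 <- parse_newick(write_newick(t1))
    expect_equal(topology_key(t1, rooted = FALSE),
                 topology_key(t2, rooted = FALSE))
    expect_equal(sort(t1$edge.length), sort(t2$edge.length))
    expect_equal(sort(branch_supports(t1)), sort(branch_supports(t2)))
  }
  expect_error(write_newick(NULL), "empty")
})

test_that("bipartition extraction yields n - 3 records on resolved trees", {
  expect_equal(nrow(extract_bipartitions(parse_newick("((A,B),(C,D));"))), 1L)
  expect_equal(extract_bipartitions(parse_newick("((A,B),(C,D));"))$key,
               "A,B|C,D")
  cat5 <- parse_newick("((((A,B),C),D),E);")
  expect_equal(nrow(extract_bipartitions(cat5)), 2L)
  star5 <- parse_newick("(A,B,C,D,E);")
  expect_equal(nrow(extract_bipartitions(star5)), 0L)
  expect_equal(nrow(extract_bipartitions(parse_newick("((A,B),C);"))), 0L)
  set.seed(42)
  for (n in c(6, 9, 14)) {
    tr <- ape::rtree(n)
    expect_equal(nrow(extract_bipartitions(tr)), n - 3L)
  }
})

test_that("tree restriction sums suppressed branch lengths", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  r <- restrict_tree(tr, c("A", "C", "D"))
  d <- ape::cophenetic.phylo(r)
  full <- ape::cophenetic.phylo(tr)
  expect_equal(d[c("A", "C", "D"), c("A", "C", "D")],
               full[c("A", "C", "D"), c("A", "C", "D")])
  # property: path lengths among retained taxa preserved on random trees
  set.seed(7)
  for (rep in 1:5) {
    tr <- ape::rtree(10)
    keep <- sample(tr$tip.label, 5)
    r <- restrict_tree(tr, keep)
    expect_equal(ape::cophenetic.phylo(r)[keep, keep],
                 ape::cophenetic.phylo(tr)[keep, keep])
  }
  tr <- parse_newick("((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  expect_error(restrict_tree(tr, c("A", "Z")), "Z")
  expect_identical(topology_key(restrict_tree(tr, tr$tip.label),
                                rooted = FALSE),
                   topology_key(tr, rooted = FALSE))
  expect_equal(nrow(extract_bipartitions(restrict_tree(tr, c("A", "B")))), 0L)
})

test_that("split compatibility matches exhaustive tree search", {
  b_ab <- bipartition(c("A", "B"), c("C", "D"))
  b_ac <- bipartition(c("A", "C"), c("B", "D"))
  expect_true(bipartitions_compatible(b_ab, b_ab))
  expect_false(bipartitions_compatible(b_ab, b_ac))
  b1 <- bipartition(c("A", "B"), c("C", "D", "E"))
  b2 <- bipartition(c("A", "B", "C"), c("D", "E"))
  expect_true(bipartitions_compatible(b1, b2))
  expect_error(bipartitions_compatible(b_ab, b1), "different taxon sets")

  skip_if_not_installed("phangorn")
  set.seed(11)
  taxa5 <- LETTERS[1:5]
  taxa6 <- LETTERS[1:6]
  cases <- list()
  rand_bip <- function(taxa) {
    k <- sample(2:(length(taxa) - 2), 1)
    s <- sample(taxa, k)
    bipartition(s, setdiff(taxa, s))
  }
  for (i in 1:12) cases[[i]] <- list(rand_bip(taxa5), rand_bip(taxa5))
  for (i in 13:24) cases[[i]] <- list(rand_bip(taxa6), rand_bip(taxa6))
  for (cs in cases) {
    expect_equal(bipartitions_compatible(cs[[1]], cs[[2]]),
                 oracle_compatible(cs[[1]], cs[[2]]),
                 info = paste(cs[[1]]$key, "vs", cs[[2]]$key))
  }
})

test_that("SNV filtering drops flagged sequences and outlier genomes", {
  snv <- tibble::tibble(
    genome = c(rep("g1", 10), rep("g2", 100), rep("g3", 100)),
    locus = c(sprintf("L%03d", 1:10), sprintf("L%03d", 1:100),
              sprintf("L%03d", 1:100)),
    snv_count = 1,
    max_freq = c(c(0.05, 0.15, rep(0.01, 8)),        # g1: only L002 flagged
                 c(rep(0.2, 21), rep(0.01, 79)),     # g2: 21/100 flagged
                 c(rep(0.2, 20), rep(0.01, 80)))     # g3: 20/100 flagged
  )
  res <- filter_snv_sequences(snv, freq_threshold = 0.1,
                              taxon_fraction = 0.2)
  expect_true(any(res$kept$genome == "g1" & res$kept$locus == "L001"))
  expect_false(any(res$kept$genome == "g1" & res$kept$locus == "L002"))
  expect_equal(res$dropped_genomes, "g2")          # strictly > 20% flagged
  expect_true("g3" %in% res$kept$genome)           # exactly 20% is kept
  expect_error(filter_snv_sequences(dplyr::mutate(snv, max_freq = 2)),
               "\\[0, 1\\]")
})

test_that("loci without SNVs are never flagged regardless of frequency", {
  snv <- tibble::tibble(genome = "g", locus = sprintf("L%02d", 1:10),
                        snv_count = c(0, 2, rep(0, 8)),
                        max_freq = c(0.9, 0.9, rep(0.9, 8)))
  res <- filter_snv_sequences(snv)
  expect_setequal(res$kept$locus, sprintf("L%02d", c(1, 3:10)))
  expect_equal(res$flagged$locus, "L02")
})
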