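test_that("parse_newick reads valid trees and rejects malformed input", {
  tr <- parse_newick("((A:1.0,B:2.0):0.5,C:3.0):0.0;")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(nrow(tr$edge), 4L)

  expect_error(parse_newick("(A:1,B:2"), "unbalanced|semicolon|';'")
  expect_error(parse_newick("((A:1,A:2):1,C:1);"), "duplicate tip")
  expect_error(parse_newick("((A:1,B:-2):0.5,C:3);"), "negative branch length")
  expect_error(parse_newick("((A:1,B:2):0.5,C:3);", file = "x.nwk"),
               "exactly one")
})

test_that("missing branch lengths are zeroed with a warning, or rejected", {
  expect_warning(tr <- parse_newick("((A:1,B),C:3);"), "branch length")
  expect_equal(sum(tr$edge.length), 4)
  expect_true(all(tr$edge.length >= 0))
  expect_error(parse_newick("((A:1,B),C:3);", missing_lengths = "error"),
               "branch length")
})

test_that("parsed trees round-trip through write_newick", {
  txts <- c("((A:1,B:2)ab:0.5,C:3)r;",
            "((A:1,B:2,C:1):0.5,(D:2,E:1):1);")   # polytomy kept
  for (txt in txts) {
    tr <- parse_newick(txt)
    tr2 <- parse_newick(write_newick(tr))
    expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
    expect_equal(sort(tr2$edge.length), sort(tr$edge.length))
  }
})

test_that("mrca_node finds ancestors, tips are their own MRCA", {
  tr <- parse_newick("((A:1,B:2):0.5,C:3);")
  rt <- setdiff(tr$edge[, 1], tr$edge[, 2])
  expect_equal(mrca_node(tr, c("A", "C")), rt)
  ab <- mrca_node(tr, c("A", "B"))
  expect_true(ab > length(tr$tip.label) && ab != rt)
  expect_equal(mrca_node(tr, "A"), which(tr$tip.label == "A"))
  expect_error(mrca_node(tr, c("A", "Z")), "not in tree: Z")
})

test_that("cumulative branch length matches hand-enumerated edge sums", {
  tr <- parse_newick("((A:1,B:2):0.5,C:3);")
  expect_equal(cumulative_branch_length(tr, c("A", "B")), 3.0)
  expect_equal(cumulative_branch_length(tr, c("A", "B", "C")), 6.5)
  expect_equal(cumulative_branch_length(tr, "A"), 0.0)
  # non-monophyletic set: error by default, MRCA subtree under force_mrca
  expect_error(cumulative_branch_length(tr, c("A", "C")),
               "not monophyletic.*B")
  expect_warning(v <- cumulative_branch_length(tr, c("A", "C"),
                                               force_mrca = TRUE))
  expect_equal(v, 6.5)
})

test_that("normalized CBL is CBL per sequence and guards its domain", {
  expect_equal(normalized_cbl(3.0, 2), 1.5)
  expect_equal(normalized_cbl(0.0, 5), 0.0)
  expect_equal(normalized_cbl(6.5, 3), 6.5 / 3)
  expect_error(normalized_cbl(3.0, 0), "n_seqs")
  expect_error(normalized_cbl(-1, 2), "nonnegative")
})

test_that("cumulative patristic distance adds the root-to-clade path", {
  tr <- parse_newick("((A:1,B:2):0.5,C:3);")
  expect_equal(cumulative_patristic_distance(tr, c("A", "B")), 3.5)
  expect_equal(cumulative_patristic_distance(tr, c("A", "B", "C")), 6.5)
  tr2 <- parse_newick("(((A:1,B:1):1,C:1):2,D:1);")
  expect_equal(cumulative_patristic_distance(tr2, c("A", "B")), 5.0)
  # exclusive-stem convention drops the MRCA's own subtending edge
  expect_equal(cumulative_patristic_distance(tr, c("A", "B"),
                                             include_stem = FALSE), 3.0)
  expect_equal(cumulative_patristic_distance(tr2, c("A", "B"),
                                             include_stem = FALSE), 4.0)
})

test_that("clade_stats_table computes per-clade records in stable order", {
  tr <- parse_newick("(((g1:1,g2:2):1,g3:4):0.5,((g4:1,g5:1):2,g6:3):1.5);")
  asn <- data.frame(gene_id = paste0("g", 1:6),
                    clade_id = rep(c("beta", "alpha"), each = 3))
  st <- clade_stats_table(tr, asn)
  expect_equal(st$clade_id, c("alpha", "beta"))   # deterministic order
  expect_equal(st$n_seqs, c(3L, 3L))
  expect_equal(st$cbl[st$clade_id == "beta"], 1 + 2 + 1 + 4)
  expect_equal(st$cbl[st$clade_id == "alpha"], 1 + 1 + 2 + 3)
  expect_equal(st$cpd[st$clade_id == "beta"], 8 + 0.5)
  expect_equal(st$cpd[st$clade_id == "alpha"], 7 + 1.5)
  expect_equal(st$normalized_cbl * st$n_seqs, st$cbl)
  expect_true(all(st$monophyletic))
  # against the independent enumeration oracle
  expect_equal(st$cbl[1], oracle_cbl(tr, paste0("g", 4:6)))
  expect_equal(st$cbl[2], oracle_cbl(tr, paste0("g", 1:3)))

  one <- clade_stats_table(tr, data.frame(gene_id = paste0("g", 1:6),
                                          clade_id = "all"))
  expect_equal(one$cpd, one$cbl)                  # MRCA is the root
  expect_error(clade_stats_table(tr, asn[-2, ]), "missing.*g2")
})

test_that("CBL and CPD agree with enumeration oracles on random trees", {
  set.seed(71)
  for (rep in 1:40) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n)
    internal <- (n + 2):(n + tr$Nnode)   # skip the root: stem-path nonzero
    if (!length(internal)) next
    v <- sample(internal, 1)
    tips <- ape::extract.clade(tr, v)$tip.label
    cbl <- cumulative_branch_length(tr, tips)
    expect_equal(cbl, oracle_cbl(tr, tips))
    cpd <- cumulative_patristic_distance(tr, tips)
    expect_equal(cpd - cbl, oracle_root_path(tr, tips))
    expect_gte(cpd, cbl)
  }
})

test_that("clade statistics scale linearly with branch lengths", {
  set.seed(72)
  for (rep in 1:20) {
    tr <- ape::rtree(8)
    v <- sample(10:(8 + tr$Nnode), 1)
    tips <- ape::extract.clade(tr, v)$tip.label
    s <- stats::runif(1, 0.1, 10)
    tr2 <- tr
    tr2$edge.length <- tr$edge.length * s
    expect_equal(cumulative_branch_length(tr2, tips),
                 s * cumulative_branch_length(tr, tips))
    expect_equal(cumulative_patristic_distance(tr2, tips),
                 s * cumulative_patristic_distance(tr, tips))
  }
})

test_that("CBL is additive over child subtrees plus their stems", {
  set.seed(73)
  for (rep in 1:20) {
    tr <- ape::rtree(10)
    ntip <- length(tr$tip.label)
    v <- sample((ntip + 1):(ntip + tr$Nnode), 1)
    kids <- tr$edge[tr$edge[, 1] == v, 2]
    parent_tips <- if (v == ntip + 1) tr$tip.label else
      ape::extract.clade(tr, v)$tip.label
    total <- 0
    for (k in kids) {
      ktips <- if (k <= ntip) tr$tip.label[k] else
        ape::extract.clade(tr, k)$tip.label
      stem <- tr$edge.length[tr$edge[, 2] == k]
      total <- total + cumulative_branch_length(tr, ktips) + stem
    }
    expect_equal(cumulative_branch_length(tr, parent_tips), total)
  }
})
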