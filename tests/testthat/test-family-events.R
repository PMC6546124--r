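toy_gene_tables <- function() {
  list(
    gene_species = data.frame(
      gene_id = c("g1", "g2", "g3", "g4"),
      species_id = c("sp1", "sp2", "sp1", "sp2"),
      pseudogene = c(0L, 0L, 0L, 0L), stringsAsFactors = FALSE),
    clade_assignment = data.frame(
      gene_id = c("g1", "g2", "g3", "g4"),
      clade_id = c("c1", "c1", "c2", "c2"), stringsAsFactors = FALSE))
}

test_that("build_copy_matrix tabulates copies and pseudogenes", {
  tt <- toy_gene_tables()
  mat <- build_copy_matrix(tt$gene_species, tt$clade_assignment)
  expect_s3_class(mat, "copy_matrix")
  expect_equal(unname(mat$counts), matrix(1L, 2, 2))
  expect_equal(sum(mat$pseudo_counts), 0L)

  tt$gene_species$pseudogene[3] <- 1L   # g3 flagged: moves matrices
  mat2 <- build_copy_matrix(tt$gene_species, tt$clade_assignment)
  expect_equal(mat2$counts["c2", "sp1"], 0L)
  expect_equal(mat2$pseudo_counts["c2", "sp1"], 1L)

  expect_error(build_copy_matrix(tt$gene_species, tt$clade_assignment[-1, ]),
               "missing clade for: g1")
})

test_that("stability calls require one copy in every species", {
  far <- load_far_fixture()
  calls <- classify_stability(far$matrix)
  expect_equal(sum(calls$status == "stable"), 12L)
  expect_equal(sum(calls$status == "unstable"), 6L)
  # a clade absent from an entire subgenus is unstable
  g <- calls[calls$clade_id == "CG13091", ]
  expect_equal(g$status, "unstable")
  expect_setequal(strsplit(g$missing_species, ",")[[1]],
                  c("Dmoj", "Dvir", "Dgri"))
  # a clade whose only copy in one species is a pseudogene stays unstable
  p <- calls[calls$clade_id == "CG10097", ]
  expect_equal(p$status, "unstable")
  expect_true("Dsec" %in% strsplit(p$missing_species, ",")[[1]])
})

test_that("counting pseudogenes as presence can flip a call", {
  counts <- matrix(c(1L, 0L), 1, 2, dimnames = list("c1", c("sp1", "sp2")))
  pseudo <- matrix(c(0L, 1L), 1, 2, dimnames = list("c1", c("sp1", "sp2")))
  mat <- copy_matrix(counts, pseudo)
  expect_equal(classify_stability(mat)$status, "unstable")
  expect_equal(classify_stability(mat, count_pseudogenes = TRUE)$status,
               "stable")
})

test_that("stability is invariant to copy-number magnitude", {
  set.seed(81)
  for (rep in 1:10) {
    counts <- matrix(rpois(24, 1.2), 4, 6,
                     dimnames = list(paste0("c", 1:4), paste0("s", 1:6)))
    counts[, 1] <- pmax(counts[, 1], 1L)   # keep every clade nonempty
    storage.mode(counts) <- "integer"
    mat <- copy_matrix(counts)
    flat <- copy_matrix(matrix(as.integer(counts >= 1L), 4, 6,
                               dimnames = dimnames(counts)))
    expect_equal(classify_stability(mat), classify_stability(flat))
  }
})

test_that("Dollo reconstruction recovers the published loss narratives", {
  far <- load_far_fixture()
  ev <- dollo_reconstruct(far$matrix, far$species_tree)
  et <- events_table(ev)

  # clades present everywhere originate at the root with zero losses
  expect_true(all(et$n_losses[et$clade_id %in% c("CG1443", "CG10096")] == 0L))
  expect_equal(et$origin[et$clade_id == "CG1443"], "root")

  # GJ13738: subgenus Drosophila + willistoni group -> one loss on the edge
  # subtending the Sophophora clade that excludes D. willistoni
  gj <- et[et$clade_id == "GJ13738", ]
  expect_equal(gj$n_losses, 1L)
  expect_equal(gj$losses, "melobscura")
  expect_equal(gj$origin, "root")

  # ancestral CG14893-lineage pattern: Sophophora + D. virilis -> two
  # independent terminal losses (D. mojavensis, D. grimshawi)
  cg <- et[et$clade_id == "CG17560", ]
  expect_equal(cg$n_losses, 2L)
  expect_setequal(strsplit(cg$losses, ",")[[1]], c("Dmoj", "Dgri"))

  # pseudogene does not count as presence: CG10097 lost in Dsec and Dana
  p <- et[et$clade_id == "CG10097", ]
  expect_equal(p$n_losses, 2L)
  expect_setequal(strsplit(p$losses, ",")[[1]], c("Dsec", "Dana"))
})

test_that("Dollo origin can be forced to the root", {
  far <- load_far_fixture()
  ev <- dollo_reconstruct(far$matrix, far$species_tree)
  expect_equal(events_table(ev)[events_table(ev)$clade_id == "CG13091",
                                c("origin", "n_losses")],
               data.frame(origin = "Sophophora", n_losses = 0L,
                          row.names = 13L))
  ev2 <- dollo_reconstruct(far$matrix, far$species_tree,
                           origin_at_root = "CG13091")
  et2 <- events_table(ev2)
  row <- et2[et2$clade_id == "CG13091", ]
  expect_equal(row$origin, "root")
  expect_equal(row$n_losses, 1L)
  expect_equal(row$losses, "DrosophilaSubg")
})

test_that("a clade with zero presence cannot be reconstructed", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  counts <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L), 2, 3, byrow = TRUE,
                   dimnames = list(c("ok", "gone"), c("A", "B", "C")))
  pseudo <- counts * 0L
  pseudo["gone", "A"] <- 1L   # keeps the matrix valid but is not presence
  expect_error(dollo_reconstruct(copy_matrix(counts, pseudo), tr),
               "zero presence.*gone")
})

test_that("Dollo equals exhaustive minimal loss placement (small trees)", {
  set.seed(82)
  trees <- c(lapply(c(4, 5, 6), ape::rtree),
             list(parse_newick("((A:1,B:1,C:1):1,(D:1,E:1):1);")))
  for (tr in trees) {
    n <- length(tr$tip.label)
    for (pat in 1:(2^n - 1)) {
      present <- tr$tip.label[bitwAnd(bitwShiftR(pat, 0:(n - 1)), 1L) == 1L]
      ev <- dollo_reconstruct(pattern_matrix(tr, present), tr)
      expect_equal(ev[["cl"]]$n_losses, oracle_dollo_losses(tr, present),
                   info = paste("pattern", pat, "on",
                                paste(tr$tip.label, collapse = "")))
      # minimality: no loss edge ancestral to another loss of the same clade
      losses <- ev[["cl"]]$losses
      if (length(losses) > 1) {
        for (v in losses) {
          below <- bdfam:::subtree_nodes(tr, v)
          expect_length(intersect(setdiff(below, v), losses), 0)
        }
      }
    }
  }
})

test_that("ancestral repertoires count clades present at a node", {
  tr <- parse_newick("((A:1,B:1)ab:1,C:2)r;")
  counts <- matrix(c(1L, 1L, 1L,
                     1L, 1L, 0L,
                     1L, 1L, 1L), 3, 3, byrow = TRUE,
                   dimnames = list(c("c1", "c2", "c3"), c("A", "B", "C")))
  ev <- dollo_reconstruct(copy_matrix(counts), tr)
  expect_equal(ancestral_repertoire(ev, "r"), 2L)    # c2 originates below
  expect_equal(ancestral_repertoire(ev, "ab"), 3L)
  expect_equal(ancestral_repertoire(ev, "C"), 2L)
  expect_error(ancestral_repertoire(ev, "nope"), "not found")

  tab <- ancestral_repertoire_table(ev)
  expect_equal(nrow(tab), 5L)
  # root count equals the number of root-origin clades
  expect_equal(tab$repertoire_size[tab$node_label == "r"],
               sum(vapply(ev, function(e) e$origin_label == "r", TRUE)))
  # brute recount from the presence flags themselves
  for (i in seq_len(nrow(tab))) {
    v <- bdfam:::resolve_node(tr, tab$node_label[i])
    expect_equal(tab$repertoire_size[i],
                 sum(vapply(ev, function(e) e$presence[v], TRUE)))
  }
})

test_that("repertoire lower bound subtracts lineage-specific duplicates", {
  expect_equal(repertoire_lower_bound(18, 3), 15L)
  expect_equal(repertoire_lower_bound(7, 0), 7L)
  expect_equal(repertoire_lower_bound(5, 5), 0L)
  expect_error(repertoire_lower_bound(3, 4), "exceed")
  expect_error(repertoire_lower_bound(-1, 0), "nonnegative")
})

test_that("lethality tally reproduces the knockdown proportions", {
  far <- load_far_fixture()
  tal <- lethality_tally(far$rnai)
  expect_equal(tal$prop_lethal[tal$stability == "stable"], 0.75)
  expect_equal(tal$prop_lethal[tal$stability == "unstable"], 0.20)
  expect_equal(tal$n, c(12L, 5L))
  expect_error(lethality_tally(data.frame(stability = "stable")), "lacks")
  expect_error(lethality_tally(data.frame(stability = "odd",
                                          rnai_phenotype = "Lethal")),
               "stable/unstable")
})
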