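# Independent oracles used by the property tests. These deliberately avoid
# the package's own traversal code: tip sets come from ape::extract.clade,
# path lengths from ape::nodepath, and Dollo loss counts from exhaustive
# enumeration over loss-edge subsets.

# tip labels below every node, as a list indexed by node number
oracle_tipsets <- function(tr) {
  ntip <- length(tr$tip.label)
  lapply(seq_len(ntip + tr$Nnode), function(v) {
    if (v <= ntip) tr$tip.label[v] else ape::extract.clade(tr, v)$tip.label
  })
}

# brute-force CBL: sum over explicitly enumerated edges whose child-side tip
# set is inside the clade, minus nothing (the stem edge's child IS the MRCA
# and is excluded by the child != mrca condition)
oracle_cbl <- function(tr, clade_tips) {
  ts <- oracle_tipsets(tr)
  mrca <- which(vapply(ts, function(d) setequal(d, clade_tips), TRUE))[1L]
  keep <- vapply(seq_len(nrow(tr$edge)), function(i) {
    child <- tr$edge[i, 2L]
    all(ts[[child]] %in% clade_tips) && child != mrca
  }, TRUE)
  sum(tr$edge.length[keep])
}

# root-to-MRCA path length (stem edge of the MRCA included), via nodepath
oracle_root_path <- function(tr, clade_tips) {
  ts <- oracle_tipsets(tr)
  mrca <- which(vapply(ts, function(d) setequal(d, clade_tips), TRUE))[1L]
  rt <- setdiff(tr$edge[, 1L], tr$edge[, 2L])[1L]
  if (mrca == rt) return(0)
  path <- ape::nodepath(tr, rt, mrca)
  tot <- 0
  for (i in seq_len(length(path) - 1L)) {
    e <- which(tr$edge[, 1L] == path[i] & tr$edge[, 2L] == path[i + 1L])
    tot <- tot + tr$edge.length[e]
  }
  tot
}

# minimum number of losses over ALL single-origin + loss-edge placements
# consistent with the tip presence pattern (exhaustive enumeration; trees
# must be small). Bitmask representation of tip sets for speed.
oracle_dollo_losses <- function(tr, present_tips) {
  ntip <- length(tr$tip.label)
  ts <- oracle_tipsets(tr)
  mask <- vapply(ts, function(d)
    sum(bitwShiftL(1L, match(d, tr$tip.label) - 1L)), integer(1L))
  pres_mask <- sum(bitwShiftL(1L, match(present_tips, tr$tip.label) - 1L))
  origins <- which(vapply(seq_along(mask), function(v)
    bitwAnd(pres_mask, mask[v]) == pres_mask, TRUE))
  best <- Inf
  for (o in origins) {
    inside <- setdiff(which(bitwAnd(mask, mask[o]) == mask), o)
    k <- length(inside)
    for (sub in 0:(2^k - 1)) {
      S <- inside[bitwAnd(bitwShiftR(sub, seq_len(k) - 1L), 1L) == 1L]
      if (length(S) >= best) next
      lost <- Reduce(bitwOr, mask[S], 0L)
      if (bitwAnd(mask[o], bitwNot(lost)) == pres_mask)
        best <- min(best, length(S))
    }
  }
  best
}

# single-row copy matrix for a presence pattern over a species tree
pattern_matrix <- function(tr, present_tips, clade_id = "cl") {
  counts <- matrix(as.integer(tr$tip.label %in% present_tips), nrow = 1L,
                   dimnames = list(clade_id, tr$tip.label))
  copy_matrix(counts)
}

# expand a copy_matrix into per-gene tables (one synthetic gene id per copy)
matrix_to_gene_tables <- function(mat) {
  rows <- list()
  for (cl in rownames(mat$counts)) {
    for (sp in colnames(mat$counts)) {
      n <- mat$counts[cl, sp]
      np <- mat$pseudo_counts[cl, sp]
      if (n + np == 0L) next
      ids <- paste0(cl, "_", sp, "_", seq_len(n + np))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = ids, species_id = sp, clade_id = cl,
        pseudogene = rep(c(0L, 1L), c(n, np)), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  list(gene_species = df[, c("gene_id", "species_id", "pseudogene")],
       clade_assignment = df[, c("gene_id", "clade_id")])
}

# write the packaged clade matrix out as per-gene pipeline input TSVs
fixture_run_inputs <- function(dir) {
  far <- load_far_fixture()
  tabs <- matrix_to_gene_tables(far$matrix)
  gs <- file.path(dir, "gene_species.tsv")
  ca <- file.path(dir, "clades.tsv")
  write.table(tabs$gene_species, gs, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(tabs$clade_assignment, ca, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(far = far, gene_species = gs, clade_assignment = ca,
       species_tree = fixture_path("drosophila12.nwk"))
}

# per-clade branch statistics for a simulated family (one gene tree per
# clade, every tip of a tree belongs to that clade)
family_clade_stats <- function(fam) {
  rows <- lapply(names(fam$gene_trees), function(cl) {
    gt <- fam$gene_trees[[cl]]
    asn <- stats::setNames(rep(cl, length(gt$tip.label)), gt$tip.label)
    clade_stats_table(gt, asn)
  })
  do.call(rbind, rows)
}
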