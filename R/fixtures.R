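# Packaged example data: a 12-species fly tree and an 18-clade fatty
# acyl-CoA reductase (FAR) presence/pseudogene matrix encoding the published
# distribution statements for that family, plus the branch-site selection
# test table and the knockdown phenotype table.

#' Path to a packaged data file
#'
#' @param name File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return Absolute path (or character vector of file names).
#' @export
fixture_path <- function(name = NULL) {
  if (is.null(name))
    return(dir(system.file("extdata", package = "bdfam")))
  system.file("extdata", name, package = "bdfam", mustWork = TRUE)
}

#' Load the packaged FAR gene-family example
#'
#' The example encodes, over the 12 classic *Drosophila* genomes, the
#' published content of the fatty acyl-CoA reductase family: 12 stable
#' clades present in every genome (with the 8-copy *CG10096* expansion in
#' *D. virilis*), the unstable *CG13091*/*CG10097* clades (including the
#' *D. sechellia* pseudogene and the *D. ananassae* absence), the
#' *CG14893*/*CG17560*/*CG17562* clades, and *GJ13738* (restricted to the
#' subgenus *Drosophila* plus *D. willistoni*). Three clades are annotated
#' as lineage-specific duplication products. Also included: the six-row
#' branch-site selection-test table and the per-gene RNAi lethality table.
#'
#' @return List with `species_tree` (`phylo`), `matrix` (a `copy_matrix`),
#'   `clade_info` (data frame: `clade_id`, `lineage_specific_duplicate`),
#'   `rnai` (data frame) and `lrt_table` (data frame).
#' @examples
#' far <- load_far_fixture()
#' table(classify_stability(far$matrix)$status)
#' @export
load_far_fixture <- function() {
  tr <- parse_newick(file = fixture_path("drosophila12.nwk"))
  long <- read_tsv_checked(fixture_path("far_clades.tsv"),
                           c("clade_id", "species_id", "count",
                             "pseudo_count", "lineage_specific_duplicate"))
  clades <- unique(long$clade_id)
  species <- sort(tr$tip.label)
  shape <- function(col) {
    m <- matrix(0L, length(clades), length(species),
                dimnames = list(clades, species))
    m[cbind(long$clade_id, long$species_id)] <- as.integer(long[[col]])
    m
  }
  mat <- copy_matrix(shape("count"), shape("pseudo_count"))
  info <- unique(long[, c("clade_id", "lineage_specific_duplicate")])
  rownames(info) <- NULL
  list(species_tree = tr, matrix = mat, clade_info = info,
       rnai = read_tsv_checked(fixture_path("far_rnai.tsv"),
                               c("clade_id", "stability", "rnai_phenotype")),
       lrt_table = read_lrt_table(fixture_path("far_lrt.tsv")))
}
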