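# End-to-end orchestration: branch statistics -> content classification ->
# Dollo events -> selection-test post-processing, with TSV/JSON outputs.

# accept either a ready object or a path plus reader
input_or_path <- function(x, reader, what) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x))
      stop("[", what, "] input file not found: ", x, call. = FALSE)
    return(reader(x))
  }
  x
}

#' Validate pipeline inputs without computing
#'
#' Cross-checks the input files of [run_pipeline()] — tip coverage of the
#' assignment tables, agreement of species sets, orphan genes — and returns
#' machine-readable findings instead of raising errors.
#'
#' @inheritParams run_pipeline
#' @return Data frame with columns `severity` (`"error"`/`"warning"`),
#'   `message`, `location`; zero rows when everything is consistent.
#' @export
validate_inputs <- function(gene_tree = NULL, species_tree = NULL,
                            gene_species = NULL, clade_assignment = NULL,
                            lrt_table = NULL) {
  findings <- list()
  note <- function(severity, message, location)
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, message = message, location = location,
      stringsAsFactors = FALSE)
  grab <- function(x, reader, what) {
    if (is.character(x) && length(x) == 1L && !file.exists(x)) {
      note("error", paste0("file not found: ", x), what)
      return(NULL)
    }
    tryCatch(input_or_path(x, reader, what),
             error = function(e) {
               note("error", conditionMessage(e), what)
               NULL
             }, warning = function(w) {
               suppressWarnings(input_or_path(x, reader, what))
             })
  }
  gt <- grab(gene_tree, function(p) parse_newick(file = p), "gene_tree")
  st <- grab(species_tree, function(p) parse_newick(file = p), "species_tree")
  gs <- grab(gene_species, read_gene_species_map, "gene_species")
  ca <- grab(clade_assignment, read_clade_assignment, "clade_assignment")
  lt <- grab(lrt_table, read_lrt_table, "lrt_table")

  if (!is.null(gs) && !is.null(st)) {
    extra <- setdiff(unique(gs$species_id), st$tip.label)
    if (length(extra))
      note("error", paste0("species in gene map absent from species tree: ",
                           paste(extra, collapse = ", ")), "gene_species")
  }
  if (!is.null(gt) && !is.null(gs)) {
    orphan <- setdiff(gt$tip.label, gs$gene_id)
    if (length(orphan))
      note("error", paste0("gene tree tip(s) missing from gene map: ",
                           paste(orphan, collapse = ", ")), "gene_tree")
  }
  if (!is.null(gt) && !is.null(ca)) {
    orphan <- setdiff(gt$tip.label, ca$gene_id)
    if (length(orphan))
      note("error", paste0("gene tree tip(s) missing from clade assignment: ",
                           paste(orphan, collapse = ", ")), "gene_tree")
  }
  if (!is.null(gs) && !is.null(ca)) {
    a <- setdiff(gs$gene_id, ca$gene_id)
    b <- setdiff(ca$gene_id, gs$gene_id)
    if (length(a))
      note("error", paste0("gene(s) without clade assignment: ",
                           paste(a, collapse = ", ")), "clade_assignment")
    if (length(b))
      note("error", paste0("assigned gene(s) missing from gene map: ",
                           paste(b, collapse = ", ")), "gene_species")
  }
  if (!length(findings))
    return(data.frame(severity = character(), message = character(),
                      location = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, findings)
  rownames(out) <- NULL
  out
}

#' Run the full birth-and-death analysis pipeline
#'
#' Executes, in order: per-clade branch statistics on the gene tree,
#' copy-number matrix construction, stable/unstable classification, Dollo
#' gain/loss reconstruction with ancestral repertoire sizes, the
#' stable-vs-unstable group comparison, and selection-test post-processing.
#' Each stage's table is written as TSV next to a `report.json` that gathers
#' all results. Stages whose inputs are not supplied (e.g. no gene tree, no
#' selection-test table) are skipped.
#'
#' @param species_tree Rooted species tree: `phylo` or Newick file path.
#'   Required.
#' @param gene_species Gene-to-species map: data frame or TSV path. Required.
#' @param clade_assignment Gene-to-clade table: data frame or TSV path.
#'   Required.
#' @param gene_tree Optional gene tree (`phylo` or Newick path) for branch
#'   statistics and the group comparison.
#' @param lrt_table Optional selection-test table (data frame or TSV path).
#' @param clade_info Optional data frame with `clade_id` and logical
#'   `lineage_specific_duplicate`; enables the ancestral repertoire lower
#'   bound.
#' @param out_dir Output directory; created if needed. While a run is in
#'   progress a `.partial` marker file sits in it and is removed on success.
#' @param metric Metric for the group comparison (default `"cbl"`).
#' @param flavor t-test flavor (default `"student_pooled"`).
#' @param count_pseudogenes Count pseudogenes as presence (default `FALSE`).
#' @param force_mrca Tolerate non-monophyletic clades in branch statistics.
#' @param include_stem Stem-edge convention for patristic distances.
#' @param origin_at_root Clade ids whose Dollo origin is forced to the root.
#' @return The report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(species_tree, gene_species, clade_assignment,
                         gene_tree = NULL, lrt_table = NULL,
                         clade_info = NULL, out_dir,
                         metric = c("cbl", "normalized_cbl", "cpd"),
                         flavor = c("student_pooled", "welch"),
                         count_pseudogenes = FALSE, force_mrca = FALSE,
                         include_stem = TRUE,
                         origin_at_root = character()) {
  metric <- match.arg(metric)
  flavor <- match.arg(flavor)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, ".partial")
  file.create(marker)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  st <- stage("species_tree",
              input_or_path(species_tree, function(p) parse_newick(file = p),
                            "species_tree"))
  gs <- stage("gene_species",
              input_or_path(gene_species, read_gene_species_map,
                            "gene_species"))
  ca <- stage("clade_assignment",
              input_or_path(clade_assignment, read_clade_assignment,
                            "clade_assignment"))
  gt <- stage("gene_tree",
              input_or_path(gene_tree, function(p) parse_newick(file = p),
                            "gene_tree"))
  lt <- stage("lrt_table", input_or_path(lrt_table, read_lrt_table,
                                         "lrt_table"))

  report <- list()
  cstats <- NULL
  if (!is.null(gt)) {
    cstats <- stage("treestats",
                    clade_stats_table(gt, ca, force_mrca = force_mrca,
                                      include_stem = include_stem))
    write_tsv(cstats, file.path(out_dir, "clade_stats.tsv"))
    report$clade_stats <- cstats
  }
  mat <- stage("copy_matrix",
               build_copy_matrix(gs, ca, species = sort(st$tip.label)))
  calls <- stage("stability", classify_stability(mat, count_pseudogenes))
  write_tsv(calls, file.path(out_dir, "stability.tsv"))
  report$stability <- calls
  report$n_stable <- sum(calls$status == "stable")
  report$n_unstable <- sum(calls$status == "unstable")

  events <- stage("dollo",
                  dollo_reconstruct(mat, st,
                                    count_pseudogenes = count_pseudogenes,
                                    origin_at_root = origin_at_root))
  ev_tab <- events_table(events)
  write_tsv(ev_tab, file.path(out_dir, "events.tsv"))
  report$events <- ev_tab
  anc <- ancestral_repertoire_table(events)
  write_tsv(anc, file.path(out_dir, "ancestral_counts.tsv"))
  report$ancestral_counts <- anc

  if (!is.null(clade_info)) {
    report$repertoire_lower_bound <- stage("repertoire_bound", {
      if (!all(c("clade_id", "lineage_specific_duplicate") %in%
               names(clade_info)))
        stop("clade_info needs columns clade_id, lineage_specific_duplicate")
      repertoire_lower_bound(nrow(clade_info),
                             sum(clade_info$lineage_specific_duplicate))
    })
  }

  if (!is.null(cstats)) {
    cmp <- stage("compare_groups",
                 compare_groups(cstats, calls, metric = metric,
                                flavor = flavor))
    report$group_comparison <- unclass(cmp)
  }
  if (!is.null(lt)) {
    lres <- stage("selstats", process_lrt_table(lt))
    write_tsv(lres, file.path(out_dir, "lrt_results.tsv"))
    report$lrt <- lres
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  file.remove(marker)
  invisible(report)
}
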