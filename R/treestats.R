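# Per-clade branch-length statistics on phylograms.
#
# Trees are ape "phylo" objects throughout. A "clade" is a set of tip labels;
# statistics are taken over the subtree spanned by their most recent common
# ancestor (MRCA).

#' Parse a Newick tree with validation
#'
#' Reads a single rooted Newick statement into an [ape::read.tree()] `phylo`
#' object and enforces the invariants the downstream statistics rely on:
#' unique, nonempty tip labels and nonnegative branch lengths. Edges with no
#' branch length in the input are set to 0 (with a warning) by default, which
#' tolerates published trees whose root or outgroup edges lack lengths.
#'
#' @param text Newick string terminated by `;`. Exactly one of `text`/`file`.
#' @param file Path to a file containing a single Newick statement.
#' @param missing_lengths Either `"zero"` (default: replace missing branch
#'   lengths by 0 with a warning) or `"error"`.
#' @return A `phylo` object.
#' @examples
#' tr <- parse_newick("((A:1.0,B:2.0):0.5,C:3.0);")
#' @export
parse_newick <- function(text = NULL, file = NULL,
                         missing_lengths = c("zero", "error")) {
  missing_lengths <- match.arg(missing_lengths)
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'", call. = FALSE)
  if (!is.null(file)) {
    if (!file.exists(file))
      stop("tree file not found: ", file, call. = FALSE)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  if (!grepl(";", text, fixed = TRUE))
    stop("Newick parse error: no terminating ';' in input", call. = FALSE)
  # balance check up front so the error can name the problem
  opens <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  closes <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (opens != closes)
    stop("Newick parse error: unbalanced parentheses (", opens, " '(' vs ",
         closes, " ')')", call. = FALSE)
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE))
  if (is.null(tr))
    stop("Newick parse error: input could not be read as a tree", call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L)
      stop("Newick parse error: expected a single tree, found ", length(tr),
           call. = FALSE)
    tr <- tr[[1L]]
  }
  validate_phylo(tr, missing_lengths = missing_lengths)
}

#' Validate a phylo object against the package's tree invariants
#'
#' @param tr A `phylo` object.
#' @param missing_lengths `"zero"` or `"error"`, see [parse_newick()].
#' @return The (possibly repaired) `phylo` object, invisibly usable downstream.
#' @export
validate_phylo <- function(tr, missing_lengths = c("zero", "error")) {
  missing_lengths <- match.arg(missing_lengths)
  if (!inherits(tr, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  bad <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(bad))
    stop("duplicate tip label(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(tr$tip.label)))
    stop("empty tip label(s) present", call. = FALSE)
  if (is.null(tr$edge.length)) {
    if (missing_lengths == "error")
      stop("tree has no branch lengths", call. = FALSE)
    warning("tree has no branch lengths; all set to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  miss <- !is.finite(tr$edge.length)
  if (any(miss)) {
    if (missing_lengths == "error")
      stop(sum(miss), " edge(s) lack a branch length", call. = FALSE)
    warning(sum(miss), " edge(s) lack a branch length; set to 0")
    tr$edge.length[miss] <- 0
  }
  if (any(tr$edge.length < 0)) {
    i <- which(tr$edge.length < 0)[1L]
    stop("negative branch length (", tr$edge.length[i],
         ") on edge to node ", tr$edge[i, 2L], call. = FALSE)
  }
  tr
}

#' Serialize a tree to Newick
#'
#' @param tr A `phylo` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
write_newick <- function(tr, file = NULL) {
  s <- ape::write.tree(tr)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

# node number of the root
root_node <- function(tr) {
  setdiff(tr$edge[, 1L], tr$edge[, 2L])[1L]
}

# tip labels -> node numbers, with a clear error for unknown labels
tip_numbers <- function(tr, tips) {
  idx <- match(tips, tr$tip.label)
  if (anyNA(idx))
    stop("tip label(s) not in tree: ",
         paste(tips[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

#' Most recent common ancestor of a set of tips
#'
#' @param tr A `phylo` object.
#' @param tips Character vector of tip labels (length >= 1). A single tip is
#'   its own MRCA.
#' @return Node number (tip numbers are `1..Ntip`, internal nodes follow).
#' @export
mrca_node <- function(tr, tips) {
  tips <- unique(tips)
  idx <- tip_numbers(tr, tips)
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tr, idx)
}

# all node numbers in the subtree rooted at `node` (including `node`)
subtree_nodes <- function(tr, node) {
  n_tip <- length(tr$tip.label)
  if (node <= n_tip) return(node)
  # edge matrix is not guaranteed preordered; iterate to closure
  out <- node
  repeat {
    kids <- tr$edge[tr$edge[, 1L] %in% out, 2L]
    new <- setdiff(kids, out)
    if (!length(new)) break
    out <- c(out, new)
  }
  out
}

# indices into edge matrix of edges strictly inside the subtree at `node`
subtree_edges <- function(tr, node) {
  which(tr$edge[, 1L] %in% subtree_nodes(tr, node))
}

#' Cumulative branch length (CBL) of a clade
#'
#' Sum of all branch lengths within a clade: every terminal and internal edge
#' below the clade's MRCA. The MRCA's own subtending (stem) edge is not within
#' the clade and is excluded. A single-tip clade has CBL 0.
#'
#' @param tr A `phylo` object.
#' @param clade_tips Character vector of member tip labels.
#' @param force_mrca If the tips are not monophyletic, `FALSE` (default)
#'   errors; `TRUE` computes over the full MRCA subtree with a warning.
#' @return Nonnegative number.
#' @examples
#' tr <- parse_newick("((A:1,B:2):0.5,C:3);")
#' cumulative_branch_length(tr, c("A", "B"))   # 3
#' @export
cumulative_branch_length <- function(tr, clade_tips, force_mrca = FALSE) {
  node <- clade_check(tr, clade_tips, force_mrca)$mrca
  sum(tr$edge.length[subtree_edges(tr, node)])
}

# monophyly check shared by the clade statistics; returns mrca + flag
clade_check <- function(tr, clade_tips, force_mrca = FALSE) {
  clade_tips <- unique(clade_tips)
  node <- mrca_node(tr, clade_tips)
  below <- subtree_nodes(tr, node)
  members <- tr$tip.label[below[below <= length(tr$tip.label)]]
  extra <- setdiff(members, clade_tips)
  mono <- length(extra) == 0L
  if (!mono) {
    if (!force_mrca)
      stop("clade is not monophyletic; MRCA subtree also contains: ",
           paste(extra, collapse = ", "),
           " (use force_mrca = TRUE to compute over the full subtree)",
           call. = FALSE)
    warning("clade not monophyletic; computing over full MRCA subtree (",
            length(extra), " extra tip(s))")
  }
  list(mrca = node, monophyletic = mono)
}

#' Normalized cumulative branch length
#'
#' CBL divided by the number of member sequences, removing the trivial
#' dependence of CBL on clade size.
#'
#' @param cbl Nonnegative cumulative branch length.
#' @param n_seqs Number of sequences in the clade (>= 1).
#' @return `cbl / n_seqs`.
#' @export
normalized_cbl <- function(cbl, n_seqs) {
  if (any(n_seqs < 1)) stop("n_seqs must be >= 1", call. = FALSE)
  if (any(cbl < 0)) stop("cbl must be nonnegative", call. = FALSE)
  cbl / n_seqs
}

#' Cumulative patristic distance of a clade
#'
#' CBL plus the branch lengths on the path from the tree root down to the node
#' supporting the clade. By default the path includes the MRCA's subtending
#' (stem) edge; `include_stem = FALSE` gives the exclusive convention. When
#' the MRCA is the root the value equals the CBL under either convention.
#'
#' @inheritParams cumulative_branch_length
#' @param include_stem Include the MRCA's stem edge in the root path
#'   (default `TRUE`).
#' @return Nonnegative number, always `>=` the clade's CBL.
#' @examples
#' tr <- parse_newick("((A:1,B:2):0.5,C:3);")
#' cumulative_patristic_distance(tr, c("A", "B"))   # 3.5
#' @export
cumulative_patristic_distance <- function(tr, clade_tips, force_mrca = FALSE,
                                          include_stem = TRUE) {
  node <- clade_check(tr, clade_tips, force_mrca)$mrca
  cbl <- sum(tr$edge.length[subtree_edges(tr, node)])
  cbl + root_path_length(tr, node, include_stem)
}

# summed branch lengths from the root to `node` (stem edge of `node`
# included when include_stem)
root_path_length <- function(tr, node, include_stem = TRUE) {
  rt <- root_node(tr)
  if (node == rt) return(0)
  total <- 0
  cur <- node
  while (cur != rt) {
    e <- which(tr$edge[, 2L] == cur)
    total <- total + tr$edge.length[e]
    cur <- tr$edge[e, 1L]
  }
  if (!include_stem) {
    e <- which(tr$edge[, 2L] == node)
    total <- total - tr$edge.length[e]
  }
  total
}

#' Per-clade branch-length statistics table
#'
#' Computes, for every clade in an assignment, the number of member sequences,
#' cumulative branch length (CBL), normalized CBL and cumulative patristic
#' distance, in deterministic order by clade id.
#'
#' @param tr Gene tree (`phylo`).
#' @param clade_assignment Data frame with columns `gene_id`, `clade_id`
#'   covering every tip of `tr`, or a named character vector
#'   (names = gene ids, values = clade ids).
#' @param force_mrca Passed to the per-clade statistics; non-monophyletic
#'   clades error unless `TRUE`.
#' @param include_stem Stem-edge convention for the patristic distance.
#' @return Data frame with columns `clade_id`, `n_seqs`, `cbl`,
#'   `normalized_cbl`, `cpd`, `monophyletic`.
#' @export
clade_stats_table <- function(tr, clade_assignment, force_mrca = FALSE,
                              include_stem = TRUE) {
  map <- as_clade_map(clade_assignment)
  missing <- setdiff(tr$tip.label, names(map))
  if (length(missing))
    stop("tip(s) missing from clade assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  map <- map[tr$tip.label]
  clades <- sort(unique(unname(map)))
  rows <- lapply(clades, function(cl) {
    tips <- names(map)[map == cl]
    chk <- clade_check(tr, tips, force_mrca)
    cbl <- sum(tr$edge.length[subtree_edges(tr, chk$mrca)])
    cpd <- cbl + root_path_length(tr, chk$mrca, include_stem)
    data.frame(clade_id = cl, n_seqs = length(tips), cbl = cbl,
               normalized_cbl = cbl / length(tips), cpd = cpd,
               monophyletic = chk$monophyletic, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

as_clade_map <- function(clade_assignment) {
  if (is.data.frame(clade_assignment)) {
    need <- c("gene_id", "clade_id")
    if (!all(need %in% names(clade_assignment)))
      stop("clade assignment needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    stats::setNames(as.character(clade_assignment$clade_id),
                    as.character(clade_assignment$gene_id))
  } else if (!is.null(names(clade_assignment))) {
    stats::setNames(as.character(clade_assignment), names(clade_assignment))
  } else {
    stop("clade assignment must be a data frame or named vector", call. = FALSE)
  }
}

#' Read a two-column gene-to-clade assignment TSV
#'
#' @param path TSV with header columns `gene_id`, `clade_id`.
#' @return Data frame.
#' @export
read_clade_assignment <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "clade_id"))
  df$gene_id <- as.character(df$gene_id)
  df$clade_id <- as.character(df$clade_id)
  df
}

#' Read a gene-to-species map TSV
#'
#' @param path TSV with header columns `gene_id`, `species_id` and optional
#'   `pseudogene` (0/1); a missing pseudogene column is filled with 0.
#' @return Data frame with columns `gene_id`, `species_id`, `pseudogene`.
#' @export
read_gene_species_map <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "species_id"))
  df$gene_id <- as.character(df$gene_id)
  df$species_id <- as.character(df$species_id)
  if (is.null(df$pseudogene)) df$pseudogene <- 0L
  if (!all(df$pseudogene %in% c(0L, 1L)))
    stop("pseudogene column must be 0/1 in ", path, call. = FALSE)
  df$pseudogene <- as.integer(df$pseudogene)
  df
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, " lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
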