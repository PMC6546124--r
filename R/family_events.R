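# Gene-family content analysis: clade x species copy-number matrices,
# stable/unstable classification, Dollo gain/loss reconstruction on a rooted
# species tree, and ancestral repertoire sizes.

#' Build a clade x species copy-number matrix
#'
#' Tabulates functional gene copies and pseudogene copies per clade and
#' species from a gene-to-species map and a gene-to-clade assignment. The two
#' tables must describe exactly the same set of genes.
#'
#' @param gene_species Data frame with columns `gene_id`, `species_id` and
#'   optional `pseudogene` (0/1, default 0). See [read_gene_species_map()].
#' @param clade_assignment Data frame with columns `gene_id`, `clade_id`.
#' @param species Optional character vector fixing the species set (and column
#'   order), e.g. the tip labels of a species tree; species without genes get
#'   zero columns. Defaults to the species seen in `gene_species`.
#' @return A `copy_matrix`: list with integer matrices `counts` and
#'   `pseudo_counts` (clades x species, dimnames set).
#' @export
build_copy_matrix <- function(gene_species, clade_assignment, species = NULL) {
  gs <- gene_species
  ca <- clade_assignment
  if (is.null(gs$pseudogene)) gs$pseudogene <- 0L
  orphan_gs <- setdiff(gs$gene_id, ca$gene_id)
  orphan_ca <- setdiff(ca$gene_id, gs$gene_id)
  if (length(orphan_gs) || length(orphan_ca))
    stop("gene tables disagree; missing clade for: ",
         paste(orphan_gs, collapse = ", "),
         if (length(orphan_ca)) paste0("; missing species for: ",
                                       paste(orphan_ca, collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(gs$gene_id) || anyDuplicated(ca$gene_id))
    stop("each gene must appear exactly once per table", call. = FALSE)
  m <- merge(gs, ca, by = "gene_id")
  clades <- sort(unique(as.character(m$clade_id)))
  if (is.null(species)) {
    species <- sort(unique(as.character(m$species_id)))
  } else {
    extra <- setdiff(m$species_id, species)
    if (length(extra))
      stop("species in gene map but not in supplied species set: ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  dims <- list(clades, species)
  tab <- function(sub) {
    mat <- matrix(0L, length(clades), length(species), dimnames = dims)
    if (nrow(sub)) {
      tt <- table(factor(sub$clade_id, clades), factor(sub$species_id, species))
      mat[] <- as.integer(tt)
    }
    mat
  }
  out <- list(counts = tab(m[m$pseudogene == 0L, ]),
              pseudo_counts = tab(m[m$pseudogene == 1L, ]))
  class(out) <- "copy_matrix"
  validate_copy_matrix(out)
}

#' Construct a copy_matrix directly from count matrices
#'
#' @param counts Integer matrix, clades x species, functional copies.
#' @param pseudo_counts Optional matching matrix of pseudogene copies
#'   (default all zero).
#' @return A `copy_matrix`.
#' @export
copy_matrix <- function(counts, pseudo_counts = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(pseudo_counts)) {
    pseudo_counts <- counts
    pseudo_counts[] <- 0L
  } else {
    pseudo_counts <- as.matrix(pseudo_counts)
    storage.mode(pseudo_counts) <- "integer"
  }
  out <- list(counts = counts, pseudo_counts = pseudo_counts)
  class(out) <- "copy_matrix"
  validate_copy_matrix(out)
}

validate_copy_matrix <- function(x) {
  stopifnot(inherits(x, "copy_matrix"))
  if (!identical(dim(x$counts), dim(x$pseudo_counts)) ||
      !identical(dimnames(x$counts), dimnames(x$pseudo_counts)))
    stop("counts and pseudo_counts must have identical dimnames", call. = FALSE)
  if (is.null(rownames(x$counts)) || is.null(colnames(x$counts)))
    stop("copy matrix needs clade rownames and species colnames", call. = FALSE)
  if (any(x$counts < 0) || any(x$pseudo_counts < 0))
    stop("copy numbers must be nonnegative", call. = FALSE)
  tot <- x$counts + x$pseudo_counts
  empty <- rownames(tot)[rowSums(tot) == 0L]
  if (length(empty))
    stop("clade(s) with no gene in any species: ",
         paste(empty, collapse = ", "), call. = FALSE)
  x
}

#' @export
print.copy_matrix <- function(x, ...) {
  cat("copy_matrix:", nrow(x$counts), "clades x", ncol(x$counts), "species;",
      sum(x$counts), "genes,", sum(x$pseudo_counts), "pseudogenes\n")
  invisible(x)
}

#' Classify clades as phylogenetically stable or unstable
#'
#' A clade is stable when it keeps at least one copy in every species;
#' otherwise it is unstable, with the species lacking a copy listed.
#' Pseudogenes do not count as presence unless `count_pseudogenes = TRUE`:
#' a pseudogenized copy is evidence of loss in progress, not of a retained
#' functional gene.
#'
#' @param mat A `copy_matrix`.
#' @param count_pseudogenes Count pseudogene copies as presence
#'   (default `FALSE`).
#' @return Data frame with columns `clade_id`, `status`
#'   (`"stable"`/`"unstable"`), `n_species_present`, `missing_species`
#'   (comma-separated, `""` for stable clades).
#' @export
classify_stability <- function(mat, count_pseudogenes = FALSE) {
  validate_copy_matrix(mat)
  eff <- mat$counts
  if (count_pseudogenes) eff <- eff + mat$pseudo_counts
  present <- eff >= 1L
  n_present <- rowSums(present)
  missing <- apply(present, 1L, function(r)
    paste(colnames(eff)[!r], collapse = ","))
  data.frame(clade_id = rownames(eff),
             status = ifelse(n_present == ncol(eff), "stable", "unstable"),
             n_species_present = as.integer(n_present),
             missing_species = unname(missing),
             stringsAsFactors = FALSE)
}

# display label for a node: tip label, internal node label, or "node<k>"
node_label <- function(tr, node) {
  n_tip <- length(tr$tip.label)
  vapply(node, function(v) {
    if (v <= n_tip) return(tr$tip.label[v])
    lab <- if (!is.null(tr$node.label)) tr$node.label[v - n_tip] else ""
    if (is.na(lab) || !nzchar(lab)) paste0("node", v) else lab
  }, character(1L))
}

# resolve a node given as number or label
resolve_node <- function(tr, node) {
  if (is.numeric(node)) {
    node <- as.integer(node)
    if (node < 1L || node > length(tr$tip.label) + tr$Nnode)
      stop("node number out of range: ", node, call. = FALSE)
    return(node)
  }
  i <- match(node, tr$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tr$node.label)) {
    j <- match(node, tr$node.label)
    if (!is.na(j)) return(length(tr$tip.label) + j)
  }
  stop("node not found in tree: ", node, call. = FALSE)
}

#' Dollo reconstruction of gain and loss events on a species tree
#'
#' Under Dollo parsimony each clade originates exactly once — at the most
#' recent common ancestor of the species that still carry it — and can only
#' be lost thereafter. Losses are placed on the minimal set of edges below
#' the origin whose subtrees contain exactly the absent species: the roots of
#' the maximal all-absent subtrees. This decomposition is unique, so no
#' tie-breaking is needed.
#'
#' @param mat A `copy_matrix` whose species match the species-tree tips.
#' @param species_tree Rooted `phylo`; polytomies allowed.
#' @param count_pseudogenes Treat pseudogene copies as presence
#'   (default `FALSE`).
#' @param origin_at_root Character vector of clade ids forced to originate at
#'   the tree root even if their presence pattern would allow a later origin
#'   (useful when outgroup evidence places the gain deeper than the extant
#'   distribution implies).
#' @return An object of class `dollo_events`: a list with one record per
#'   clade (`clade_id`, `origin` node number, `origin_label`, `losses` node
#'   numbers of lost-subtree roots, `loss_labels`, `n_losses`, `presence`
#'   logical vector over all tree nodes) plus the species tree as attribute.
#' @export
dollo_reconstruct <- function(mat, species_tree, count_pseudogenes = FALSE,
                              origin_at_root = character()) {
  validate_copy_matrix(mat)
  tr <- validate_phylo(species_tree)
  sp <- colnames(mat$counts)
  if (!setequal(sp, tr$tip.label))
    stop("species-tree tips and matrix species differ: tree-only {",
         paste(setdiff(tr$tip.label, sp), collapse = ","), "}, matrix-only {",
         paste(setdiff(sp, tr$tip.label), collapse = ","), "}", call. = FALSE)
  eff <- mat$counts
  if (count_pseudogenes) eff <- eff + mat$pseudo_counts
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  rt <- root_node(tr)
  post <- ape::reorder.phylo(tr, "postorder")$edge
  parent_of <- integer(n_node)
  parent_of[post[, 2L]] <- post[, 1L]

  events <- lapply(rownames(eff), function(cl) {
    present_sp <- sp[eff[cl, ] >= 1L]
    if (!length(present_sp))
      stop("clade has zero presence, cannot place an origin: ", cl,
           call. = FALSE)
    origin <- if (cl %in% origin_at_root) rt else mrca_node(tr, present_sp)
    present_tip <- tr$tip.label %in% present_sp
    # postorder pass: is every tip below this node absent? (child edges are
    # visited before their parent edge, so one array suffices)
    all_absent <- logical(n_node)
    all_absent[seq_len(n_tip)] <- !present_tip
    all_absent[(n_tip + 1L):n_node] <- TRUE
    for (i in seq_len(nrow(post))) {
      all_absent[post[i, 1L]] <- all_absent[post[i, 1L]] &&
        all_absent[post[i, 2L]]
    }
    in_sub <- logical(n_node)
    in_sub[subtree_nodes(tr, origin)] <- TRUE
    # loss edges subtend the maximal all-absent subtrees below the origin
    cand <- setdiff(which(in_sub & all_absent), origin)
    losses <- cand[!all_absent[parent_of[cand]]]
    # presence flag: within origin subtree and not inside a lost subtree
    lost <- logical(n_node)
    for (v in losses) lost[subtree_nodes(tr, v)] <- TRUE
    presence <- in_sub & !lost
    list(clade_id = cl, origin = origin,
         origin_label = node_label(tr, origin),
         losses = losses, loss_labels = node_label(tr, losses),
         n_losses = length(losses), presence = presence)
  })
  names(events) <- rownames(eff)
  structure(events, class = "dollo_events", species_tree = tr)
}

#' @export
print.dollo_events <- function(x, ...) {
  cat("dollo_events:", length(x), "clades,",
      sum(vapply(x, `[[`, 0L, "n_losses")), "loss events\n")
  invisible(x)
}

#' Summarize Dollo events as a table
#'
#' @param events A `dollo_events` object.
#' @return Data frame with columns `clade_id`, `origin`, `losses`
#'   (comma-separated labels of lost-subtree roots), `n_losses`.
#' @export
events_table <- function(events) {
  stopifnot(inherits(events, "dollo_events"))
  data.frame(
    clade_id = vapply(events, `[[`, "", "clade_id"),
    origin = vapply(events, `[[`, "", "origin_label"),
    losses = vapply(events, function(e) paste(e$loss_labels, collapse = ","), ""),
    n_losses = vapply(events, `[[`, 0L, "n_losses"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Ancestral repertoire size at a species-tree node
#'
#' Number of clades reconstructed as present at a node: those whose origin is
#' at or above the node and which were not lost on the path down to it.
#'
#' @param events A `dollo_events` object from [dollo_reconstruct()].
#' @param node Node number, tip label, or internal node label of the species
#'   tree the events were reconstructed on.
#' @return Integer count.
#' @export
ancestral_repertoire <- function(events, node) {
  stopifnot(inherits(events, "dollo_events"))
  tr <- attr(events, "species_tree")
  v <- resolve_node(tr, node)
  sum(vapply(events, function(e) e$presence[v], logical(1L)))
}

#' Repertoire sizes at every node of the species tree
#'
#' @param events A `dollo_events` object.
#' @return Data frame with columns `node_label`, `repertoire_size`, one row
#'   per tree node (tips first).
#' @export
ancestral_repertoire_table <- function(events) {
  stopifnot(inherits(events, "dollo_events"))
  tr <- attr(events, "species_tree")
  nodes <- seq_len(length(tr$tip.label) + tr$Nnode)
  data.frame(node_label = node_label(tr, nodes),
             repertoire_size = vapply(nodes, function(v)
               ancestral_repertoire(events, v), integer(1L)),
             stringsAsFactors = FALSE)
}

#' Lower bound on the ancestral gene repertoire
#'
#' With `n_clades` extant clades of which `n_lineage_specific_duplicates`
#' arose through duplications confined to a single species group (each such
#' duplication adding one excess clade), the family's last common ancestor
#' must have carried at least `n_clades - n_lineage_specific_duplicates`
#' genes.
#'
#' @param n_clades Total number of clades (nonnegative integer).
#' @param n_lineage_specific_duplicates Number of clades annotated as
#'   lineage-specific duplication products, `<= n_clades`.
#' @return Integer lower bound.
#' @examples
#' repertoire_lower_bound(18, 3)   # 15
#' @export
repertoire_lower_bound <- function(n_clades, n_lineage_specific_duplicates) {
  if (n_clades < 0 || n_lineage_specific_duplicates < 0)
    stop("counts must be nonnegative", call. = FALSE)
  if (n_lineage_specific_duplicates > n_clades)
    stop("lineage-specific duplicate clades (", n_lineage_specific_duplicates,
         ") exceed total clades (", n_clades, ")", call. = FALSE)
  as.integer(n_clades) - as.integer(n_lineage_specific_duplicates)
}

#' Tally knockdown lethality by stability class
#'
#' Summarizes a per-gene phenotype table (e.g. ubiquitous RNAi knockdown
#' outcomes) by phylogenetic stability class, giving the number and
#' proportion of genes whose loss is lethal in each class.
#'
#' @param rnai Data frame with columns `stability`
#'   (`"stable"`/`"unstable"`) and `rnai_phenotype` (`"Lethal"`/`"Viable"`,
#'   case-insensitive).
#' @return Data frame with columns `stability`, `n`, `n_lethal`,
#'   `prop_lethal`, ordered stable first.
#' @export
lethality_tally <- function(rnai) {
  need <- c("stability", "rnai_phenotype")
  miss <- setdiff(need, names(rnai))
  if (length(miss))
    stop("table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  stab <- tolower(rnai$stability)
  phen <- tolower(rnai$rnai_phenotype)
  if (!all(stab %in% c("stable", "unstable")))
    stop("stability must be stable/unstable", call. = FALSE)
  if (!all(phen %in% c("lethal", "viable")))
    stop("rnai_phenotype must be Lethal/Viable", call. = FALSE)
  classes <- intersect(c("stable", "unstable"), unique(stab))
  out <- do.call(rbind, lapply(classes, function(cl) {
    n <- sum(stab == cl)
    nl <- sum(stab == cl & phen == "lethal")
    data.frame(stability = cl, n = n, n_lethal = nl, prop_lethal = nl / n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
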