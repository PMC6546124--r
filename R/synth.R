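# Seeded duplication-loss simulator. Each clade starts as a single gene
# lineage at the species-tree root; along every species-tree edge each extant
# lineage evolves under a linear birth-death process (duplication rate
# lambda, loss rate mu per unit time) simulated event by event, and at every
# speciation node each lineage is copied into all daughter edges. Gene-tree
# branch lengths are elapsed time multiplied by a per-class substitution-rate
# multiplier, so "unstable" clades can be made both lossier and
# faster-evolving than "stable" ones.

#' Simulation configuration for the duplication-loss generator
#'
#' Defaults emulate a 12-species fly-like data set: 12 stable clades that
#' neither duplicate nor get lost, and 6 unstable clades with equal
#' duplication and loss rates and a doubled substitution rate.
#'
#' @param species_tree Rooted `phylo` with positive branch lengths in time
#'   units. Defaults to the packaged 12-species tree.
#' @param n_stable,n_unstable Number of clades per class.
#' @param stable,unstable Per-class parameter lists with elements `dup_rate`,
#'   `loss_rate` (events per lineage per unit time) and `rate_multiplier`
#'   (substitutions/site per unit time on gene-tree branches).
#' @param pseudogene_prob Probability that a loss on a terminal edge leaves a
#'   detectable pseudogene (a flagged tip truncated at the loss time) instead
#'   of disappearing without trace. Losses on internal edges are always
#'   silent: a pseudogene can only be observed in a sequenced extant genome.
#' @param seed Integer seed; mandatory, every simulation is reproducible.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(species_tree = NULL,
                              n_stable = 12L, n_unstable = 6L,
                              stable = list(dup_rate = 0, loss_rate = 0,
                                            rate_multiplier = 1),
                              unstable = list(dup_rate = 0.05, loss_rate = 0.05,
                                              rate_multiplier = 2),
                              pseudogene_prob = 0.1,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (is.null(species_tree))
    species_tree <- parse_newick(file = fixture_path("drosophila12.nwk"))
  species_tree <- validate_phylo(species_tree)
  if (any(species_tree$edge.length <= 0))
    stop("species-tree branch lengths must be positive", call. = FALSE)
  for (cls in list(stable, unstable)) {
    stopifnot(cls$dup_rate >= 0, cls$loss_rate >= 0, cls$rate_multiplier > 0)
  }
  stopifnot(n_stable >= 0, n_unstable >= 0, n_stable + n_unstable >= 1,
            pseudogene_prob >= 0, pseudogene_prob <= 1)
  structure(list(species_tree = species_tree,
                 n_stable = as.integer(n_stable),
                 n_unstable = as.integer(n_unstable),
                 stable = stable, unstable = unstable,
                 pseudogene_prob = pseudogene_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# one gene lineage entering the species-tree edge that leads to `sp_child`,
# with `t_left` time units remaining on that edge. Returns a nested-list gene
# subtree (NULL if the lineage leaves no trace). `st` is the per-clade
# simulation state environment.
sim_lineage <- function(st, sp_child, t_left, blen = 0) {
  tr <- st$tree
  repeat {
    total <- st$dup_rate + st$loss_rate
    dt <- if (total > 0) stats::rexp(1L, total) else Inf
    if (dt >= t_left) break
    blen <- blen + dt * st$r
    t_left <- t_left - dt
    ei <- st$edge_index[sp_child]
    if (stats::runif(1L) < st$dup_rate / total) {        # duplication
      st$n_dup[ei] <- st$n_dup[ei] + 1L
      left <- sim_lineage(st, sp_child, t_left, 0)
      right <- sim_lineage(st, sp_child, t_left, 0)
      kids <- Filter(Negate(is.null), list(left, right))
      if (length(kids) == 2L)
        return(list(children = kids, blen = blen))
      if (length(kids) == 1L) {
        kids[[1L]]$blen <- kids[[1L]]$blen + blen
        return(kids[[1L]])
      }
      return(NULL)
    } else {                                             # loss
      st$n_loss[ei] <- st$n_loss[ei] + 1L
      if (sp_child <= st$n_tip && stats::runif(1L) < st$pg_prob)
        return(list(species = tr$tip.label[sp_child], blen = blen,
                    pseudo = TRUE))
      return(NULL)
    }
  }
  blen <- blen + t_left * st$r
  if (sp_child <= st$n_tip)
    return(list(species = tr$tip.label[sp_child], blen = blen,
                pseudo = FALSE))
  # speciation: the lineage is copied into every daughter edge
  dedges <- which(tr$edge[, 1L] == sp_child)
  kids <- list()
  for (e in dedges) {
    k <- sim_lineage(st, tr$edge[e, 2L], tr$edge.length[e], 0)
    if (!is.null(k)) kids <- c(kids, list(k))
  }
  if (!length(kids)) return(NULL)
  if (length(kids) == 1L) {
    kids[[1L]]$blen <- kids[[1L]]$blen + blen
    return(kids[[1L]])
  }
  list(children = kids, blen = blen)
}

# simulate one clade; returns list(tree = nested list or NULL, n_dup, n_loss)
sim_clade <- function(tr, dup_rate, loss_rate, r, pg_prob, clade_seed) {
  set.seed(clade_seed)
  st <- new.env(parent = emptyenv())
  st$tree <- tr
  st$n_tip <- length(tr$tip.label)
  st$dup_rate <- dup_rate
  st$loss_rate <- loss_rate
  st$r <- r
  st$pg_prob <- pg_prob
  st$edge_index <- integer(st$n_tip + tr$Nnode)
  st$edge_index[tr$edge[, 2L]] <- seq_len(nrow(tr$edge))
  st$n_dup <- integer(nrow(tr$edge))
  st$n_loss <- integer(nrow(tr$edge))
  rt <- root_node(tr)
  dedges <- which(tr$edge[, 1L] == rt)
  kids <- list()
  for (e in dedges) {
    k <- sim_lineage(st, tr$edge[e, 2L], tr$edge.length[e], 0)
    if (!is.null(k)) kids <- c(kids, list(k))
  }
  g <- if (!length(kids)) NULL
  else if (length(kids) == 1L) kids[[1L]]
  else list(children = kids, blen = 0)
  list(tree = g, n_dup = st$n_dup, n_loss = st$n_loss)
}

# assign tip labels <clade>_<species>_<k> in-place; returns list(tree, tips)
# where tips is a data.frame(gene_id, species_id, pseudogene)
label_gene_tree <- function(g, clade_id) {
  counter <- new.env(parent = emptyenv())
  rows <- list()
  walk <- function(node) {
    if (!is.null(node$species)) {
      k <- (get0(node$species, counter, ifnotfound = 0L)) + 1L
      assign(node$species, k, counter)
      lab <- paste0(clade_id, "_", node$species, "_", k)
      rows[[length(rows) + 1L]] <<- data.frame(
        gene_id = lab, species_id = node$species,
        pseudogene = as.integer(node$pseudo), stringsAsFactors = FALSE)
      node$label <- lab
      return(node)
    }
    node$children <- lapply(node$children, walk)
    node
  }
  g <- walk(g)
  list(tree = g, tips = do.call(rbind, rows))
}

# nested-list gene tree -> Newick string
gene_tree_newick <- function(g) {
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)
  rec <- function(node) {
    if (!is.null(node$species))
      return(paste0(node$label, ":", fmt(node$blen)))
    paste0("(", paste(vapply(node$children, rec, ""), collapse = ","),
           "):", fmt(node$blen))
  }
  if (!is.null(g$species))                       # single surviving copy
    paste0("(", g$label, ":", fmt(g$blen), ");")
  else
    paste0(rec(g), ";")
}

#' Simulate a gene family along a species tree
#'
#' Runs the duplication-loss process of [simulation_config()] for every
#' clade. A single global seed drives one independent child stream per
#' clade, so enlarging the clade set never perturbs the clades already
#' simulated.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return A `sim_family`: list with `gene_trees` (named list of `phylo`,
#'   surviving clades only), `matrix` (a `copy_matrix` over all species),
#'   `gene_species` and `clade_assignment` data frames, `truth`
#'   (`clade_id`, `class`, `extinct`), `events_true` (per species-tree edge:
#'   `clade_id`, `edge_child`, `n_dup`, `n_loss`) and the `config`.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tr <- config$species_tree
  classes <- c(rep("stable", config$n_stable),
               rep("unstable", config$n_unstable))
  width <- max(2L, nchar(length(classes)))
  clade_ids <- sprintf("%s%0*d", ifelse(classes == "stable", "S", "U"),
                       width, seq_along(classes))
  set.seed(config$seed)
  clade_seeds <- vapply(seq_along(classes), function(i)
    sample.int(.Machine$integer.max, 1L), integer(1L))

  gene_trees <- list()
  gs_rows <- list()
  ev_rows <- list()
  extinct <- logical(length(classes))
  edge_child <- node_label(tr, tr$edge[, 2L])
  for (i in seq_along(classes)) {
    par <- config[[classes[i]]]
    res <- sim_clade(tr, par$dup_rate, par$loss_rate, par$rate_multiplier,
                     config$pseudogene_prob, clade_seeds[i])
    nz <- which(res$n_dup + res$n_loss > 0L)
    if (length(nz))
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        clade_id = clade_ids[i], edge_child = edge_child[nz],
        n_dup = res$n_dup[nz], n_loss = res$n_loss[nz],
        stringsAsFactors = FALSE)
    if (is.null(res$tree)) {
      extinct[i] <- TRUE
      next
    }
    lab <- label_gene_tree(res$tree, clade_ids[i])
    gene_trees[[clade_ids[i]]] <-
      ape::read.tree(text = gene_tree_newick(lab$tree))
    gs_rows[[length(gs_rows) + 1L]] <- lab$tips
  }
  gene_species <- if (length(gs_rows)) do.call(rbind, gs_rows) else
    data.frame(gene_id = character(), species_id = character(),
               pseudogene = integer(), stringsAsFactors = FALSE)
  rownames(gene_species) <- NULL
  clade_assignment <- data.frame(
    gene_id = gene_species$gene_id,
    clade_id = sub("_.*$", "", gene_species$gene_id),
    stringsAsFactors = FALSE)
  mat <- if (nrow(gene_species))
    build_copy_matrix(gene_species, clade_assignment,
                      species = sort(tr$tip.label))
  else NULL
  structure(list(gene_trees = gene_trees, matrix = mat,
                 gene_species = gene_species,
                 clade_assignment = clade_assignment,
                 truth = data.frame(clade_id = clade_ids, class = classes,
                                    extinct = extinct,
                                    stringsAsFactors = FALSE),
                 events_true = if (length(ev_rows)) do.call(rbind, ev_rows)
                 else data.frame(clade_id = character(),
                                 edge_child = character(),
                                 n_dup = integer(), n_loss = integer(),
                                 stringsAsFactors = FALSE),
                 config = config),
            class = "sim_family")
}

#' @export
print.sim_family <- function(x, ...) {
  cat("sim_family:", nrow(x$truth), "clades (",
      sum(x$truth$extinct), "extinct ),",
      nrow(x$gene_species), "genes, seed", x$config$seed, "\n")
  invisible(x)
}

#' Write a simulated family to disk
#'
#' Emits one Newick file per surviving clade plus `gene_species.tsv`,
#' `clades.tsv`, `truth.tsv`, `events_true.tsv` and a JSON manifest holding
#' the configuration and seed. Output is byte-identical for identical
#' configurations.
#'
#' @param family A `sim_family`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_family <- function(family, out_dir) {
  stopifnot(inherits(family, "sim_family"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  tree_files <- character(0)
  for (cl in names(family$gene_trees)) {
    f <- file.path(out_dir, paste0("genetree_", cl, ".nwk"))
    write_newick(family$gene_trees[[cl]], f)
    tree_files <- c(tree_files, basename(f))
  }
  write_tsv(family$gene_species, file.path(out_dir, "gene_species.tsv"))
  write_tsv(family$clade_assignment, file.path(out_dir, "clades.tsv"))
  write_tsv(family$truth, file.path(out_dir, "truth.tsv"))
  write_tsv(family$events_true, file.path(out_dir, "events_true.tsv"))
  cfg <- family$config
  manifest <- list(
    seed = cfg$seed,
    n_stable = cfg$n_stable, n_unstable = cfg$n_unstable,
    stable = cfg$stable, unstable = cfg$unstable,
    pseudogene_prob = cfg$pseudogene_prob,
    species_tree = write_newick(cfg$species_tree),
    gene_tree_files = as.list(tree_files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Reload a simulated family's tables from disk
#'
#' @param dir Directory written by [write_family()].
#' @return List with `gene_species`, `clade_assignment`, `truth`, `matrix`
#'   (a `copy_matrix`), `species_tree` and `gene_trees`.
#' @export
read_family <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  tr <- parse_newick(text = manifest$species_tree)
  gs <- read_gene_species_map(file.path(dir, "gene_species.tsv"))
  ca <- read_clade_assignment(file.path(dir, "clades.tsv"))
  truth <- read_tsv_checked(file.path(dir, "truth.tsv"),
                            c("clade_id", "class", "extinct"))
  trees <- lapply(manifest$gene_tree_files, function(f)
    parse_newick(file = file.path(dir, f)))
  names(trees) <- sub("^genetree_(.*)\\.nwk$", "\\1",
                      unlist(manifest$gene_tree_files))
  list(gene_species = gs, clade_assignment = ca, truth = truth,
       matrix = build_copy_matrix(gs, ca, species = sort(tr$tip.label)),
       species_tree = tr, gene_trees = trees)
}
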