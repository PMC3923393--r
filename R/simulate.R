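#' Species tree of the 18 study organisms
#'
#' A rooted, ultrametric (depth 1) tree over short organism tags for the
#' 18 eukaryotes profiled by the pipeline: metazoans and their
#' unicellular relatives (choanoflagellates, filastereans,
#' ichthyosporeans), fungi, the apusozoan Thecamonas trahens and the
#' amoebozoan Dictyostelium discoideum.  Branch lengths follow Grafen's
#' node-height rule; the topology reflects the consensus eukaryote
#' phylogeny at the resolution the simulator needs.
#'
#' @return `phylo` tree with 18 tips.
#' @export
default_species_tree <- function() {
  holozoa <- "(((((((((Hsa,Cin),Bfl),Spu),Dme),Nve),Tad),Aqe),(Mbr,Sro)),(Cow,Sar))"
  fungi <- "(((Sce,Spo),Cci),Spn)"
  txt <- paste0("(((", holozoa, ",", fungi, "),Ttr),Ddi);")
  ape::compute.brlen(ape::read.tree(text = txt), method = "Grafen")
}

#' Simulation configuration
#'
#' Defines the conditions a synthetic gene-family benchmark emulates: K
#' founder subfamilies at the root of a species tree, each evolving by
#' gene duplication and loss along its branches; clade supports that
#' increase with subtending branch length; and pairwise E-values that
#' decay with patristic distance, plus log-scale noise.
#'
#' @param species_tree `phylo` or Newick text; default the 18-organism
#'   tree of [default_species_tree()].
#' @param founders subfamily labels of the K founder lineages; default
#'   the eight CDK subfamily labels.
#' @param dup_rate,loss_rate duplication / loss rates per unit branch
#'   length; defaults 0.2 and 0.1.
#' @param stem_length branch length separating each founder from the
#'   gene-family root, i.e. how long subfamilies evolved apart before
#'   the species radiation; default 1 (one species-tree depth).
#' @param support_sharpness kappa: an internal edge of length l receives
#'   support `100 * (1 - exp(-kappa * l))` before noise; default 20
#'   (edges of length 0.12 reach ~90).
#' @param support_noise_sd additive Gaussian noise on the support
#'   percentage; default 3.
#' @param evalue_slope beta: `log10 E = -beta * exp(-d / tau)` for a
#'   query--reference pair at patristic distance d; default 50 (a
#'   zero-distance pair scores 1e-50).
#' @param evalue_scale tau, the distance scale of E-value decay;
#'   default 1.
#' @param evalue_noise_sd Gaussian noise on `log10 E`; default 0.5.
#' @param reference_organism organism whose surviving copy anchors each
#'   subfamily (the role human proteins play in the real analysis);
#'   default the first species-tree tip.
#' @param seed integer seed; stages draw from `seed`, `seed + 1`,
#'   `seed + 2`, `seed + 3` (tree, supports, E-values, sequences) so
#'   each stage is reproducible in isolation.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(species_tree = default_species_tree(),
                              founders = c("CDK1", "CDK4/6", "CDK5",
                                           "CDK7", "CDK8/19", "CDK9",
                                           "CDK10/11", "CDK20"),
                              dup_rate = 0.2, loss_rate = 0.1,
                              stem_length = 1,
                              support_sharpness = 20,
                              support_noise_sd = 3,
                              evalue_slope = 50, evalue_scale = 1,
                              evalue_noise_sd = 0.5,
                              reference_organism = NULL,
                              seed = 1L) {
  if (is.character(species_tree))
    species_tree <- read_newick(species_tree)
  stopifnot(inherits(species_tree, "phylo"),
            !is.null(species_tree$edge.length),
            length(founders) >= 1,
            dup_rate >= 0, loss_rate >= 0, stem_length >= 0,
            support_sharpness > 0, support_noise_sd >= 0,
            evalue_slope > 0, evalue_scale > 0, evalue_noise_sd >= 0)
  if (anyDuplicated(founders)) stop("duplicate founder label")
  if (is.null(reference_organism))
    reference_organism <- species_tree$tip.label[1]
  if (!reference_organism %in% species_tree$tip.label)
    stop("reference organism not a species-tree tip: ", reference_organism)
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0 || seed > 2^31 - 10)
    stop("seed must be an integer in [0, 2^31 - 10]")
  structure(list(species_tree = species_tree, founders = founders,
                 dup_rate = dup_rate, loss_rate = loss_rate,
                 stem_length = stem_length,
                 support_sharpness = support_sharpness,
                 support_noise_sd = support_noise_sd,
                 evalue_slope = evalue_slope, evalue_scale = evalue_scale,
                 evalue_noise_sd = evalue_noise_sd,
                 reference_organism = reference_organism, seed = seed),
            class = "sim_config")
}

# birth--death evolution of one gene lineage along the species tree.
# sp: list(children[[node]], lengths[node], tip_label[node]); node ids as
# in the phylo edge matrix.  Returns NULL (extinct) or a nested list with
# $edge (length back to the lineage's origin point), $org for leaves,
# $children for internal nodes.
evolve_branch <- function(sp, node, remaining, lam, mu) {
  rate <- lam + mu
  t <- if (rate > 0) stats::rexp(1, rate) else Inf
  if (t < remaining) {
    if (stats::runif(1) < lam / rate) {      # duplication
      a <- evolve_branch(sp, node, remaining - t, lam, mu)
      b <- evolve_branch(sp, node, remaining - t, lam, mu)
      if (is.null(a) && is.null(b)) return(NULL)
      if (is.null(a)) { b$edge <- b$edge + t; return(b) }
      if (is.null(b)) { a$edge <- a$edge + t; return(a) }
      return(list(edge = t, children = list(a, b)))
    }
    return(NULL)                              # loss
  }
  kids <- sp$children[[node]]
  if (!length(kids))                          # species-tree tip reached
    return(list(edge = remaining, org = sp$tip_label[node]))
  subs <- list()
  for (k in kids) {
    s <- evolve_branch(sp, k, sp$lengths[k], lam, mu)
    if (!is.null(s)) subs[[length(subs) + 1]] <- s
  }
  if (!length(subs)) return(NULL)
  if (length(subs) == 1) {
    subs[[1]]$edge <- subs[[1]]$edge + remaining
    return(subs[[1]])
  }
  list(edge = remaining, children = subs)
}

# assign "{org}|{subfamily}|{serial}" labels in traversal order,
# mutating the gene-subtree in place via an environment counter
label_gene_tree <- function(gt, subfamily, env) {
  if (!is.null(gt$org)) {
    key <- gt$org
    env$counts[[key]] <- (env$counts[[key]] %||% 0L) + 1L
    gt$label <- paste(gt$org, subfamily, env$counts[[key]], sep = "|")
    env$leaves <- rbind(env$leaves,
                        data.frame(accession = gt$label, organism = gt$org,
                                   subfamily = subfamily,
                                   stringsAsFactors = FALSE))
    return(gt)
  }
  gt$children <- lapply(gt$children, label_gene_tree, subfamily, env)
  gt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gene_subtree_newick <- function(gt) {
  if (!is.null(gt$org))
    return(sprintf("%s:%.10g", gt$label, gt$edge))
  sprintf("(%s):%.10g",
          paste(vapply(gt$children, gene_subtree_newick, ""),
                collapse = ","),
          gt$edge)
}

#' Simulate a gene-family tree with known truth
#'
#' Runs, for every founder subfamily, an independent birth--death
#' process along the species tree (a duplication bifurcates a lineage
#' within a branch; a loss terminates it; surviving lineages are carried
#' through speciations into both descendant branches), then joins the
#' surviving founder subtrees at a root over stems of
#' `stem_length`.  Leaves are named `"{org}|{subfamily}|{serial}"`.  One
#' surviving copy per subfamily in the reference organism is designated
#' the subfamily's reference leaf.
#'
#' @param config a [simulation_config()].
#' @return list with `tree` (`phylo`, no supports yet), `truth`
#'   (data.frame `accession`, `organism`, `subfamily`, `is_reference`)
#'   and `config`.  A founder whose lineages all die out is simply
#'   absent from tree and truth.
#' @export
simulate_gene_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tr <- config$species_tree
  ntip <- ape::Ntip(tr)
  nn <- ntip + tr$Nnode
  children <- vector("list", nn)
  for (k in seq_len(nrow(tr$edge)))
    children[[tr$edge[k, 1]]] <- c(children[[tr$edge[k, 1]]], tr$edge[k, 2])
  lengths <- numeric(nn)
  lengths[tr$edge[, 2]] <- tr$edge.length
  tip_label <- c(tr$tip.label, rep(NA_character_, tr$Nnode))
  sp <- list(children = children, lengths = lengths, tip_label = tip_label)
  root <- tree_root(tr)

  env <- new.env()
  env$leaves <- data.frame(accession = character(0), organism = character(0),
                           subfamily = character(0),
                           stringsAsFactors = FALSE)
  subtrees <- character(0)
  for (f in config$founders) {
    env$counts <- list()
    gt <- evolve_branch(sp, root, 0, config$dup_rate, config$loss_rate)
    if (is.null(gt)) next                     # founder went extinct
    gt <- label_gene_tree(gt, f, env)
    gt$edge <- gt$edge + config$stem_length
    subtrees <- c(subtrees, gene_subtree_newick(gt))
  }
  if (!length(subtrees))
    stop("every founder lineage went extinct; lower loss_rate")
  txt <- if (length(subtrees) == 1) {
    paste0("(", subtrees, ");")
  } else {
    paste0("(", paste(subtrees, collapse = ","), ");")
  }
  tree <- read_newick(txt)
  truth <- env$leaves
  # reference leaf: first surviving copy in the reference organism
  truth$is_reference <- FALSE
  for (f in unique(truth$subfamily)) {
    cand <- which(truth$subfamily == f &
                    truth$organism == config$reference_organism)
    if (length(cand)) truth$is_reference[cand[1]] <- TRUE
  }
  rownames(truth) <- NULL
  list(tree = tree, truth = truth, config = config)
}

#' Emulate bootstrap supports from branch lengths
#'
#' Each internal edge of length `l` receives support
#' `clamp(round(100 * (1 - exp(-kappa * l)) + eps), 0, 100)` with
#' `eps ~ Normal(0, support_noise_sd)`: long edges are confidently
#' recovered, short edges poorly, as bootstrap resampling behaves.  The
#' root carries no support.  Missing branch lengths are treated as 0.
#'
#' @param tree `phylo` tree.
#' @param config a [simulation_config()]; uses `support_sharpness`,
#'   `support_noise_sd` and `seed + 1`.
#' @return the tree with `node.label` supports on the
#'   bootstrap-percentage scale.
#' @export
emulate_supports <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ntip <- ape::Ntip(tree)
  root <- tree_root(tree)
  len <- stem_lengths(tree)
  labs <- character(tree$Nnode)
  internal <- ntip + seq_len(tree$Nnode)
  eps <- stats::rnorm(tree$Nnode, 0, config$support_noise_sd)
  for (i in seq_along(internal)) {
    node <- internal[i]
    if (node == root) { labs[i] <- ""; next }
    l <- len[node]
    if (is.na(l)) l <- 0
    s <- round(100 * (1 - exp(-config$support_sharpness * l)) + eps[i])
    labs[i] <- as.character(min(100, max(0, s)))
  }
  tree$node.label <- labs
  attr(tree, "support_scale") <- "bootstrap_percent"
  tree
}

#' Emulate similarity-search E-values from patristic distances
#'
#' For every (query, reference) leaf pair at patristic distance `d`,
#' `log10 E = -beta * exp(-d / tau) + eps`, `eps ~ Normal(0,
#' evalue_noise_sd)`: identical sequences score `1e-beta`, distant ones
#' decay toward no signal.  Values are floored at `log10 E = -180`
#' (search-engine underflow) and pairs weaker than `log10 E = -2` are
#' omitted, as a real search would report no hit.
#'
#' @param tree gene tree (`phylo` with branch lengths).
#' @param truth truth table from [simulate_gene_tree()]; its reference
#'   leaves are the hit subjects.
#' @param config a [simulation_config()]; uses the `evalue_*` fields and
#'   `seed + 2`.
#' @return 12-column hit data.frame as from [read_hit_table()], queries
#'   being all non-reference leaves.
#' @export
emulate_evalues <- function(tree, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  refs <- truth$accession[truth$is_reference]
  queries <- setdiff(tree$tip.label, refs)
  if (!length(refs) || !length(queries))
    return(read_hit_table_empty())
  D <- ape::dist.nodes(tree)
  tipidx <- stats::setNames(seq_along(tree$tip.label), tree$tip.label)
  pairs <- expand.grid(query = queries, subject = refs,
                       stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  d <- D[cbind(tipidx[pairs$query], tipidx[pairs$subject])]
  log10e <- -config$evalue_slope * exp(-d / config$evalue_scale) +
    stats::rnorm(nrow(pairs), 0, config$evalue_noise_sd)
  log10e <- pmax(log10e, -180)
  keep <- log10e <= -2
  pairs <- pairs[keep, , drop = FALSE]
  log10e <- log10e[keep]
  d <- d[keep]
  data.frame(query = pairs$query, subject = pairs$subject,
             pident = round(pmin(100, 100 * exp(-d / 2)), 1),
             length = 100, mismatch = 0, gapopen = 0,
             qstart = 1, qend = 100, sstart = 1, send = 100,
             evalue = 10^log10e,
             bitscore = round(30 - 1.8 * log10e, 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

read_hit_table_empty <- function() {
  data.frame(query = character(0), subject = character(0),
             pident = numeric(0), length = numeric(0),
             mismatch = numeric(0), gapopen = numeric(0),
             qstart = numeric(0), qend = numeric(0), sstart = numeric(0),
             send = numeric(0), evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

#' Toy sequences along a gene tree
#'
#' A deliberately simple Poisson substitution process over the 20-letter
#' amino-acid alphabet, sufficient for smoke-testing sequence plumbing
#' (isoform selection, FASTA round trips), not for realism.
#'
#' @param tree gene tree (`phylo`).
#' @param config a [simulation_config()]; uses `seed + 3`.
#' @param root_length sequence length; default 200.
#' @param subst_rate substitutions per site per unit branch length;
#'   default 0.5.
#' @return protein record data.frame, one row per leaf.
#' @export
simulate_sequences <- function(tree, config, root_length = 200,
                               subst_rate = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ntip <- ape::Ntip(tree)
  root <- tree_root(tree)
  nn <- ntip + tree$Nnode
  seqs <- vector("list", nn)
  seqs[[root]] <- sample(aa, root_length, replace = TRUE)
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  elen <- tree$edge.length %||% rep(0, nrow(ord))
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1]; chl <- tree$edge[k, 2]
    s <- seqs[[par]]
    nsub <- stats::rpois(1, subst_rate * elen[k] * root_length)
    if (nsub > 0) {
      pos <- sample.int(root_length, min(nsub, root_length))
      s[pos] <- sample(aa, length(pos), replace = TRUE)
    }
    seqs[[chl]] <- s
  }
  protein_records(tree$tip.label,
                  vapply(seqs[seq_len(ntip)], paste, "", collapse = ""),
                  organism = leaf_organism(tree$tip.label))
}

#' Truth presence/absence matrix of a simulation
#'
#' @param truth truth table from [simulate_gene_tree()].
#' @param config the generating [simulation_config()].
#' @return logical matrix organisms x founders (all species-tree tips
#'   and all founders, including extinct ones, which show as absent).
#' @export
truth_presence <- function(truth, config) {
  orgs <- config$species_tree$tip.label
  m <- matrix(FALSE, length(orgs), length(config$founders),
              dimnames = list(orgs, config$founders))
  for (i in seq_len(nrow(truth)))
    m[truth$organism[i], truth$subfamily[i]] <- TRUE
  m
}
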