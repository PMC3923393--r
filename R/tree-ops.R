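#' Put clade supports on the bootstrap-percentage scale
#'
#' Trees annotated with Bayesian posterior probabilities (0--1) are
#' rescaled to 0--100 so a single support threshold applies everywhere;
#' bootstrap-percentage trees pass through unchanged.  Values outside the
#' declared range are an error.
#'
#' @param tree `phylo` with a `support_scale` attribute (see
#'   [read_newick()]); a missing attribute is taken as
#'   `"bootstrap_percent"`.
#' @return the tree with supports in 0--100 and `support_scale` set to
#'   `"bootstrap_percent"`.
#' @export
normalize_support <- function(tree) {
  scale <- attr(tree, "support_scale")
  if (is.null(scale)) scale <- "bootstrap_percent"
  s <- node_supports(tree)
  ok <- !is.na(s)
  if (identical(scale, "posterior_unit")) {
    if (any(s[ok] < 0 | s[ok] > 1))
      stop("posterior support outside [0, 1]: ",
           paste(s[ok][s[ok] < 0 | s[ok] > 1], collapse = ", "))
    s[ok] <- s[ok] * 100
    lab <- ifelse(is.na(s), "", formatC(s, format = "g", digits = 6))
    tree$node.label <- lab
  } else if (identical(scale, "bootstrap_percent")) {
    if (any(s[ok] < 0 | s[ok] > 100))
      stop("bootstrap support outside [0, 100]: ",
           paste(s[ok][s[ok] < 0 | s[ok] > 100], collapse = ", "))
  } else {
    stop("unknown support scale: ", scale)
  }
  attr(tree, "support_scale") <- "bootstrap_percent"
  tree
}

#' Root a gene tree at an outgroup
#'
#' Roots on the edge separating the outgroup leaves from the rest when
#' that bipartition exists.  Internal labels are treated as edge
#' (bipartition) supports, so rooting never changes which bipartition a
#' support value describes.  When the outgroup is not monophyletic the
#' tree is rooted on the edge whose outgroup side contains the most
#' outgroup leaves (ties broken by the smallest clade), with a warning.
#'
#' @param tree `phylo` tree.
#' @param outgroup_labels character vector of outgroup leaf labels; at
#'   least one must be present in the tree.
#' @return rooted `phylo` tree.
#' @export
root_at_outgroup <- function(tree, outgroup_labels) {
  og <- intersect(outgroup_labels, tree$tip.label)
  if (!length(og))
    stop("no outgroup label present in tree: ",
         paste(outgroup_labels, collapse = ", "))
  if (length(og) == length(tree$tip.label))
    stop("outgroup contains every leaf; rooting is undefined")
  scale <- attr(tree, "support_scale")
  ut <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  rooted <- tryCatch(
    ape::root(ut, outgroup = og, resolve.root = TRUE, edgelabel = TRUE),
    error = function(e) NULL)
  if (is.null(rooted)) {
    # outgroup not monophyletic: pick the clade maximising the number of
    # outgroup leaves it contains, ties broken by smallest clade size
    sets <- clade_tip_sets(ut)
    root <- tree_root(ut)
    ntip <- ape::Ntip(ut)
    cand <- setdiff(seq_along(sets), root)
    n_og <- vapply(sets[cand], function(s) length(intersect(s, og)), 0L)
    size <- lengths(sets[cand])
    # never root on a clade spanning all outgroups *and* all other tips
    best <- cand[order(-n_og, size)][1]
    warning("outgroup not monophyletic; rooting on the edge with ",
            n_og[match(best, cand)], "/", length(og),
            " outgroup leaves on the outgroup side")
    rooted <- if (best > ntip) {
      ape::root(ut, node = best, resolve.root = TRUE, edgelabel = TRUE)
    } else {
      ape::root(ut, outgroup = ut$tip.label[best], resolve.root = TRUE,
                edgelabel = TRUE)
    }
  }
  attr(rooted, "support_scale") <- scale
  rooted
}

#' First ancestor of a query containing a reference leaf
#'
#' Walks from the query leaf toward the root and returns the first
#' ancestral node whose clade contains at least one reference leaf.  This
#' operationalises the "clusters with a subfamily" judgement: the
#' subfamilies represented among the reference leaves of that clade, and
#' the clade's support, drive the assignment rule in [assign_by_tree()].
#'
#' @param tree rooted `phylo` tree.
#' @param query leaf label.
#' @param reference_map named character vector mapping reference leaf
#'   labels to subfamily labels.
#' @return list with `node` (internal node number), `tips` (leaf labels
#'   of the clade), `subfamilies` (sorted unique subfamily labels among
#'   the clade's references) and `support` (numeric, `NA` when the node
#'   carries none).
#' @export
first_reference_ancestor <- function(tree, query, reference_map) {
  tip <- match(query, tree$tip.label)
  if (is.na(tip)) stop("query not in tree: ", query)
  refs <- intersect(names(reference_map), tree$tip.label)
  if (!length(refs)) stop("no reference leaf present in tree")
  parents <- tree_parents(tree)
  sets <- clade_tip_sets(tree)
  supp <- node_supports(tree)
  ntip <- ape::Ntip(tree)
  node <- parents[tip]
  while (node != 0L) {
    hit <- intersect(sets[[node]], refs)
    if (length(hit)) {
      return(list(node = node, tips = sets[[node]],
                  subfamilies = sort(unique(unname(reference_map[hit]))),
                  support = unname(supp[as.character(node)])))
    }
    node <- parents[node]
  }
  stop("no reference-containing ancestor found for ", query)
}

#' Test whether a leaf set forms a clade
#'
#' Returns whether `leafset` is exactly the leaf set of some node (or,
#' for unrooted use, the complement of one), together with the support of
#' the corresponding edge.  Singleton leaf sets are monophyletic by
#' convention with absent support.
#'
#' @param tree `phylo` tree.
#' @param leafset character vector of leaf labels (non-empty, all in the
#'   tree).
#' @return list with `monophyletic` (logical) and `support` (numeric or
#'   `NA`).
#' @export
is_monophyletic <- function(tree, leafset) {
  if (!length(leafset)) stop("empty leaf set")
  leafset <- unique(leafset)
  if (!all(leafset %in% tree$tip.label))
    stop("leaf not in tree: ",
         paste(setdiff(leafset, tree$tip.label), collapse = ", "))
  if (length(leafset) == 1)
    return(list(monophyletic = TRUE, support = NA_real_))
  sets <- clade_tip_sets(tree)
  supp <- node_supports(tree)
  ntip <- ape::Ntip(tree)
  all_tips <- tree$tip.label
  target <- sort(leafset)
  comp <- sort(setdiff(all_tips, leafset))
  for (node in (ntip + 1):(ntip + tree$Nnode)) {
    s <- sort(sets[[node]])
    if (identical(s, target) || (length(comp) && identical(s, comp)))
      return(list(monophyletic = TRUE,
                  support = unname(supp[as.character(node)])))
  }
  list(monophyletic = FALSE, support = NA_real_)
}
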