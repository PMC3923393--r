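#' Read a single-tree Newick string or file
#'
#' Internal node labels are interpreted as clade supports when numeric
#' (the usual RAxML / PhyloBayes convention of writing supports on the
#' child-side node of an edge).  The declared `support_scale` is attached
#' as an attribute and consumed by [normalize_support()].
#'
#' @param x Newick text (containing `;`) or a file path.
#' @param support_scale `"bootstrap_percent"` (0--100) or
#'   `"posterior_unit"` (0--1).
#' @return an `ape::phylo` tree with a `support_scale` attribute.
#' @export
read_newick <- function(x, support_scale = c("bootstrap_percent",
                                             "posterior_unit")) {
  support_scale <- match.arg(support_scale)
  txt <- if (length(x) == 1 && !grepl(";", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    paste(x, collapse = "")
  }
  txt <- trimws(txt)
  # balanced-parenthesis check with position reporting
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced ')' at position ", i, " in Newick input")
    }
  }
  if (depth != 0L)
    stop("unbalanced '(' in Newick input (", depth, " unclosed)")
  # bare single-leaf tree, e.g. "A;" -- ape cannot parse it
  if (grepl("^[^();,]+;?$", txt)) {
    lab <- sub(";$", "", txt)
    tree <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                           tip.label = lab, Nnode = 1L),
                      class = "phylo", order = "cladewise")
    attr(tree, "support_scale") <- support_scale
    return(tree)
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("could not parse Newick input")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(unique(dup), collapse = ", "))
  attr(tree, "support_scale") <- support_scale
  tree
}

#' Write a tree as Newick
#'
#' Supports (stored in `node.label`) are emitted as internal labels;
#' branch lengths are written with 6 significant digits.
#'
#' @param tree `phylo` tree.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- if (ape::Ntip(tree) == 1) {
    paste0(tree$tip.label, ";")
  } else {
    ape::write.tree(tree, digits = 6)
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Numeric clade supports of internal nodes
#'
#' @param tree `phylo` tree.
#' @return numeric vector of length `Nnode`, `NA` where no numeric label
#'   is present; names are internal node numbers.
#' @export
node_supports <- function(tree) {
  n <- tree$Nnode
  lab <- tree$node.label
  v <- if (is.null(lab)) rep(NA_real_, n) else
    suppressWarnings(as.numeric(lab))
  names(v) <- as.character(ape::Ntip(tree) + seq_len(n))
  v
}

# ---- small internal tree helpers (edge-matrix based) ----

# parent of each node (0 for root)
tree_parents <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  p <- integer(n)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

tree_root <- function(tree) {
  setdiff(tree$edge[, 1], tree$edge[, 2])[1]
}

# tip labels under each node: list indexed by node number
clade_tip_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  # postorder: process edges so children come before parents
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(ord))) {
    par <- ord[k, 1]; chl <- ord[k, 2]
    sets[[par]] <- c(sets[[par]], sets[[chl]])
  }
  sets
}

# branch length leading to each node (NA for root / absent)
stem_lengths <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  len <- rep(NA_real_, n)
  if (!is.null(tree$edge.length))
    len[tree$edge[, 2]] <- tree$edge.length
  len
}
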