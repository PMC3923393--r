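# Independent brute-force oracles and fixture builders.  These
# deliberately avoid the package's own tree-walking code paths: clade
# enumeration goes through ape::prop.part, RBH through an all-pairs scan.

# random gene tree with numeric supports and n tips labelled t1..tn
random_support_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
  tr$node.label <- c("", as.character(sample(0:100, tr$Nnode - 1,
                                             replace = TRUE)))
  attr(tr, "support_scale") <- "bootstrap_percent"
  tr
}

# all clades of a rooted tree as a list of tip-label sets, node numbers
# as names (via ape::prop.part, independent of the package's traversal)
oracle_clades <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  ntip <- ape::Ntip(tree)
  out <- lapply(pp, function(idx) labs[idx])
  names(out) <- as.character(ntip + seq_along(out))
  out
}

# brute-force tree rule: enumerate every clade containing the query and
# at least one reference; the smallest such clade is the first
# reference-containing ancestor
oracle_assign_by_tree <- function(tree, query, refmap, min_support = 50) {
  clades <- oracle_clades(tree)
  supp <- suppressWarnings(as.numeric(tree$node.label))
  names(supp) <- names(clades)
  cand <- Filter(function(nm) {
    s <- clades[[nm]]
    query %in% s && length(intersect(s, names(refmap))) > 0
  }, names(clades))
  sizes <- lengths(clades[cand])
  nm <- cand[which.min(sizes)]
  refs <- intersect(clades[[nm]], names(refmap))
  subs <- sort(unique(unname(refmap[refs])))
  s <- supp[[nm]]
  if (is.na(s)) s <- 0
  if (length(subs) == 1 && s > min_support)
    list(subfamily = subs, support = s)
  else
    NULL
}

# brute-force all-pairs reciprocal-best-hit scan
oracle_rbh_excluded <- function(accessions, forward, reverse,
                                exclusion_refs) {
  best_of <- function(hits, q) {
    h <- hits[hits$query == q, , drop = FALSE]
    if (!nrow(h)) return(NA_character_)
    h <- h[order(h$evalue, -h$bitscore, h$subject, method = "radix"), ]
    h$subject[1]
  }
  out <- character(0)
  for (a in accessions) {
    b <- best_of(forward, a)
    if (!is.na(b) && b %in% exclusion_refs &&
        identical(best_of(reverse, b), a))
      out <- c(out, a)
  }
  out
}

# minimal hit table from (query, subject, evalue[, bitscore]) triples
hit_df <- function(query, subject, evalue, bitscore = 100) {
  data.frame(query = query, subject = subject,
             pident = 90, length = 100, mismatch = 1, gapopen = 0,
             qstart = 1, qend = 100, sstart = 1, send = 100,
             evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

# tiny reference set: subfamilies S1..Sk anchored by r1..rk
toy_refset <- function(k = 2, outgroups = character(0)) {
  subf <- stats::setNames(lapply(seq_len(k), function(i) paste0("r", i)),
                          paste0("S", seq_len(k)))
  reference_set("toy", subf, outgroups = outgroups)
}

# four-tip ultrametric species tree used by scaled-down simulations
small_species_tree <- function() {
  read_newick("(((A:0.4,B:0.4):0.3,C:0.7):0.3,D:1);")
}

# independent single-lineage birth-death simulator: number of surviving
# descendants after time T (used as Monte-Carlo oracle for expected
# family size, which is e^{(lambda-mu)T} per species-tree tip path)
oracle_bd_survivors <- function(lambda, mu, T) {
  n_alive <- 0L
  sim <- function(remaining) {
    rate <- lambda + mu
    t <- if (rate > 0) stats::rexp(1, rate) else Inf
    if (t >= remaining) {
      n_alive <<- n_alive + 1L
    } else if (stats::runif(1) < lambda / rate) {
      sim(remaining - t)
      sim(remaining - t)
    }
  }
  sim(T)
  n_alive
}
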