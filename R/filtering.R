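#' Filtering parameters
#'
#' @param required_domain domain name a candidate must carry
#'   (e.g. `"Cyclin_N"`, Pfam PF00134).
#' @param domain_max_evalue maximum domain E-value accepted; the HMM
#'   search threshold, default `1e-4`.  The comparison is `<=` (closed
#'   boundary, robust to floating point).
#' @param max_gap_fraction alignment columns with a gap fraction above
#'   this are trimmed; default 0.5.
#' @return list of validated parameters.
#' @export
filter_params <- function(required_domain = "Cyclin_N",
                          domain_max_evalue = 1e-4,
                          max_gap_fraction = 0.5) {
  stopifnot(is.character(required_domain), length(required_domain) == 1,
            domain_max_evalue > 0,
            max_gap_fraction >= 0, max_gap_fraction <= 1)
  list(required_domain = required_domain,
       domain_max_evalue = domain_max_evalue,
       max_gap_fraction = max_gap_fraction)
}

#' Keep only the longest isoform per gene
#'
#' Retains, for each `gene_id`, the single longest protein; length ties
#' are broken by the lexicographically smallest accession so the result
#' is deterministic.  Output rows are sorted by (organism, gene_id).
#'
#' @param records protein record data.frame.
#' @return subset of `records`, one row per gene.
#' @export
select_longest_isoform <- function(records) {
  if (nrow(records) == 0) return(records)
  if (anyNA(records$gene_id)) stop("records lack gene_id")
  keep <- unlist(lapply(split(seq_len(nrow(records)), records$gene_id),
                        function(idx) {
    len <- records$length[idx]
    top <- idx[len == max(len)]
    top[order(records$accession[top], method = "radix")][1]
  }), use.names = FALSE)
  out <- records[keep, , drop = FALSE]
  out <- out[order(out$organism, out$gene_id, method = "radix",
                   na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition records by presence of a required domain
#'
#' A protein is kept when it carries at least one hit to
#' `params$required_domain` at E-value `<= params$domain_max_evalue`
#' (proteins lacking the domain are discarded, as are those whose only
#' hits exceed the threshold).  The two parts are an exact partition of
#' the input.
#'
#' @param records protein record data.frame.
#' @param domain_hits domain hit data.frame ([read_domain_table()]); may
#'   cover a superset of `records`.
#' @param params [filter_params()].
#' @return list with elements `kept` and `discarded`.
#' @export
filter_by_domain <- function(records, domain_hits, params = filter_params()) {
  ok <- domain_hits$domain == params$required_domain &
    domain_hits$evalue <= params$domain_max_evalue
  good <- unique(domain_hits$protein[ok])
  sel <- records$accession %in% good
  list(kept = records[sel, , drop = FALSE],
       discarded = records[!sel, , drop = FALSE])
}

# best partner per query: minimum E-value, ties by max bitscore then
# lexicographic subject
best_hit_map <- function(hits) {
  if (nrow(hits) == 0) return(character(0))
  o <- order(hits$query, hits$evalue, -hits$bitscore, hits$subject,
             method = "radix")
  h <- hits[o, ]
  first <- !duplicated(h$query)
  stats::setNames(h$subject[first], h$query[first])
}

#' Exclude records that are reciprocal best hits of excluded references
#'
#' Implements reciprocal-BLAST removal of non-family proteins that carry
#' the family domain (the CABLES1 / CNTD1 / CNTD2 situation for
#' cyclins): a record is excluded exactly when it and a member of
#' `exclusion_refs` are mutual minimum-E-value best partners across the
#' forward (query set against reference proteome) and reverse tables.
#'
#' @param records protein record data.frame.
#' @param forward_hits hits of the query set against the reference
#'   proteome.
#' @param reverse_hits hits of the reference proteome against the query
#'   set; required (RBH is undecidable without it).
#' @param exclusion_refs accessions of the non-family reference proteins.
#' @return list with elements `kept` and `excluded` (exact partition).
#' @export
exclude_by_rbh <- function(records, forward_hits, reverse_hits,
                           exclusion_refs) {
  if (missing(reverse_hits) || is.null(reverse_hits))
    stop("reverse hit table is required: reciprocal best hits are ",
         "undecidable without it")
  excl <- logical(nrow(records))
  if (length(exclusion_refs) && nrow(forward_hits)) {
    fwd <- best_hit_map(forward_hits)
    rev <- best_hit_map(reverse_hits)
    best <- fwd[records$accession]
    excl <- !is.na(best) & best %in% exclusion_refs &
      !is.na(rev[ifelse(is.na(best), "", best)]) &
      rev[ifelse(is.na(best), "", best)] == records$accession
  }
  list(kept = records[!excl, , drop = FALSE],
       excluded = records[excl, , drop = FALSE])
}

#' Screen candidates with a guide tree of family and non-family kinases
#'
#' Reproduces the preliminary clustering screen that separates true
#' family members from related kinases (e.g. CDK candidates versus MAP
#' kinases): each query is kept when its first reference-containing
#' ancestor in the guide tree contains only family references, and
#' discarded when it contains only non-family references.  A mixed
#' ancestor keeps the query with a warning -- inclusion errs toward the
#' downstream classifier, which can still reject it.
#'
#' @param guide_tree rooted `phylo` containing the queries and both
#'   reference groups.
#' @param queries leaf labels to screen.
#' @param family_refs,nonfamily_refs leaf labels of the two reference
#'   groups.
#' @return list with `kept`, `discarded` and `ambiguous` (subset of
#'   `kept`) character vectors.
#' @export
screen_by_family_cluster <- function(guide_tree, queries, family_refs,
                                     nonfamily_refs) {
  missing_q <- setdiff(queries, guide_tree$tip.label)
  if (length(missing_q))
    stop("query absent from guide tree: ", paste(missing_q, collapse = ", "))
  refmap <- c(stats::setNames(rep("family", length(family_refs)), family_refs),
              stats::setNames(rep("nonfamily", length(nonfamily_refs)),
                              nonfamily_refs))
  kept <- character(0); discarded <- character(0); ambiguous <- character(0)
  for (q in queries) {
    anc <- first_reference_ancestor(guide_tree, q, refmap)
    grp <- anc$subfamilies
    if (identical(grp, "family")) {
      kept <- c(kept, q)
    } else if (identical(grp, "nonfamily")) {
      discarded <- c(discarded, q)
    } else {
      kept <- c(kept, q)
      ambiguous <- c(ambiguous, q)
    }
  }
  if (length(ambiguous))
    warning("ambiguous family clustering (kept): ",
            paste(ambiguous, collapse = ", "))
  list(kept = kept, discarded = discarded, ambiguous = ambiguous)
}

#' Trim gappy alignment columns
#'
#' Stands in for the removal of poorly aligned positions before tree
#' inference: retains exactly the columns whose gap fraction (characters
#' `-` or `.`) is at most `max_gap_fraction`.  The retained original
#' column indices are attached as the `column_map` attribute
#' (new position `i` came from old position `column_map[i]`, 1-based).
#'
#' @param alignment named character vector of equal-length gapped
#'   sequences.
#' @param params [filter_params()]; only `max_gap_fraction` is used.
#' @return trimmed alignment (same names, same order) with a
#'   `column_map` attribute.
#' @export
trim_alignment <- function(alignment, params = filter_params()) {
  if (!length(alignment)) stop("empty alignment")
  ncols <- unique(nchar(alignment))
  if (length(ncols) != 1)
    stop("alignment rows have unequal lengths")
  m <- do.call(rbind, strsplit(alignment, ""))
  gapfrac <- colMeans(m == "-" | m == ".")
  keep <- which(gapfrac <= params$max_gap_fraction)
  if (!length(keep))
    stop("no columns retained at max_gap_fraction = ",
         params$max_gap_fraction, "; raise the threshold")
  out <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  names(out) <- names(alignment)
  attr(out, "column_map") <- keep
  out
}
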