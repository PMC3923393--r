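#' Classification parameters
#'
#' @param min_support minimum clade support (bootstrap-percentage scale)
#'   a query's subfamily clade must *exceed* for a tree-based
#'   assignment; default 50.  The comparison is strict (`>`), matching
#'   the "greater than 50% bootstrap support" rule.
#' @param margin the five-orders E-value ratio: a query is assigned by
#'   similarity when its best subfamily E-value is at most
#'   `margin` times the next-best subfamily's; default `1e-5`
#'   (inclusive comparison).
#' @param evalue_floor E-values of 0 (search-engine underflow) are
#'   floored here before ratios are formed; default `1e-180`.
#' @param solo_hit_ceiling when a query hits references of only one
#'   subfamily there is no next-best E-value; the single subfamily is
#'   accepted only below this absolute E-value; default `1e-10`.
#' @return list of validated parameters.
#' @export
classify_params <- function(min_support = 50, margin = 1e-5,
                            evalue_floor = 1e-180,
                            solo_hit_ceiling = 1e-10) {
  stopifnot(min_support >= 0, min_support <= 100,
            margin > 0, margin < 1, evalue_floor > 0,
            solo_hit_ceiling > 0)
  list(min_support = min_support, margin = margin,
       evalue_floor = evalue_floor, solo_hit_ceiling = solo_hit_ceiling)
}

assignment_row <- function(query, organism = NA_character_,
                           subfamily = "unclassified", clade = NA_character_,
                           evidence = "unclassified", statistic = NA_real_,
                           notes = "") {
  data.frame(query = query, organism = organism, subfamily = subfamily,
             clade = clade, evidence = evidence, statistic = statistic,
             notes = notes, stringsAsFactors = FALSE)
}

#' Tree-based subfamily assignment of one query
#'
#' A query is assigned to subfamily S when its first
#' reference-containing ancestor ([first_reference_ancestor()]) contains
#' references of S only and that clade's support exceeds
#' `params$min_support`.  A mixed-subfamily ancestor or insufficient
#' support yields no assignment (`NULL`), to be resolved by the
#' five-orders fallback.  A clade without a support value is treated as
#' support 0 and therefore never passes.
#'
#' @param tree rooted, support-normalized `phylo` tree containing
#'   `query`.
#' @param query leaf label.
#' @param refset a [reference_set()].
#' @param params [classify_params()].
#' @return one-row assignment data.frame, or `NULL`.
#' @export
assign_by_tree <- function(tree, query, refset,
                           params = classify_params()) {
  anc <- first_reference_ancestor(tree, query, ref_accessions(refset))
  supp <- if (is.na(anc$support)) 0 else anc$support
  if (length(anc$subfamilies) == 1 && supp > params$min_support) {
    assignment_row(query, subfamily = anc$subfamilies,
                   evidence = "tree", statistic = supp)
  } else {
    NULL
  }
}

#' Minimum E-value per subfamily for one query
#'
#' Collapses a hit table to the per-subfamily minimum E-value against
#' that subfamily's reference accessions, flooring zero / underflowed
#' E-values at `evalue_floor`.  Subfamilies without any hit are omitted.
#'
#' @param query query accession.
#' @param hits hit data.frame ([read_hit_table()]).
#' @param refset a [reference_set()].
#' @param evalue_floor see [classify_params()].
#' @return named numeric vector (subfamily -> min E-value), sorted
#'   ascending; empty when the query hits no reference.
#' @export
subfamily_evalue_profile <- function(query, hits, refset,
                                     evalue_floor = 1e-180) {
  refmap <- ref_accessions(refset)
  sel <- hits$query == query & hits$subject %in% names(refmap)
  if (!any(sel)) return(stats::setNames(numeric(0), character(0)))
  ev <- pmax(hits$evalue[sel], evalue_floor)
  subf <- unname(refmap[hits$subject[sel]])
  prof <- vapply(split(ev, subf), min, 0)
  sort(prof)
}

#' Five-orders E-value margin assignment
#'
#' With best subfamily E-value `E1` and next-best `E2`, the best
#' subfamily is accepted when `E1 <= margin * E2` (at least five orders
#' of magnitude smaller at the default margin; inclusive at the
#' boundary).  A profile covering a single subfamily is accepted only
#' when `E1 <= solo_hit_ceiling`.  The reported statistic is the ratio
#' `E1 / E2` (or `E1` itself in the solo case, noted as such).
#'
#' @param profile named numeric vector from
#'   [subfamily_evalue_profile()].
#' @param params [classify_params()].
#' @return one-row assignment data.frame, or `NULL`.
#' @export
assign_by_five_orders <- function(profile, params = classify_params()) {
  if (!length(profile)) return(NULL)
  profile <- sort(profile)
  if (length(profile) == 1) {
    if (profile[1] <= params$solo_hit_ceiling)
      return(assignment_row(NA_character_, subfamily = names(profile)[1],
                            evidence = "five_orders",
                            statistic = unname(profile[1]),
                            notes = "single-subfamily profile"))
    return(NULL)
  }
  e1 <- profile[1]; e2 <- profile[2]
  if (e1 <= params$margin * e2)
    return(assignment_row(NA_character_, subfamily = names(profile)[1],
                          evidence = "five_orders",
                          statistic = unname(e1 / e2)))
  NULL
}

#' Within-subfamily clade assignment
#'
#' After a query is assigned to a subfamily with more than one clade
#' (e.g. CDK9 versus CDK12/13 inside the CDK9 subfamily), the tree rule
#' is re-run at clade level on the subtree spanned by that subfamily's
#' references plus the query.  No clade passing the rule leaves the
#' query at subfamily level only (`NA`), mirroring proteins placed in a
#' subfamily but in none of its clades.
#'
#' @param tree rooted `phylo` containing the query and at least one of
#'   the subfamily's references.
#' @param query leaf label.
#' @param subfamily subfamily label the query is already assigned to.
#' @param refset a [reference_set()].
#' @param params [classify_params()].
#' @return clade label, or `NA_character_`.
#' @export
assign_clade <- function(tree, query, subfamily, refset,
                         params = classify_params()) {
  cmap <- clade_map(refset, subfamily)
  clades <- unique(unname(cmap))
  if (length(clades) == 1) return(clades)
  refs_here <- intersect(names(cmap), tree$tip.label)
  if (!length(refs_here)) return(NA_character_)
  sub <- ape::keep.tip(tree, c(refs_here, query))
  anc <- first_reference_ancestor(sub, query, cmap)
  supp <- if (is.na(anc$support)) 0 else anc$support
  if (length(anc$subfamilies) == 1 && supp > params$min_support)
    anc$subfamilies
  else
    NA_character_
}

# organism tag from a leaf label: prefix before the first '|' (synthetic
# naming) or, failing that, before the first '-' (figure-style labels)
leaf_organism <- function(labels) {
  out <- rep(NA_character_, length(labels))
  bar <- grepl("|", labels, fixed = TRUE)
  out[bar] <- sub("\\|.*$", "", labels[bar])
  dash <- !bar & grepl("-", labels, fixed = TRUE)
  out[dash] <- sub("-.*$", "", labels[dash])
  out
}

#' Classify queries into subfamilies
#'
#' The full decision procedure, one assignment per query:
#' 1. *Tree evidence.*  [assign_by_tree()] is attempted on every tree
#'    containing the query.  If passing trees agree on one subfamily the
#'    highest-support assignment wins; if they conflict the conflict is
#'    noted and the query falls through to similarity evidence.
#' 2. *Five-orders evidence.*  [subfamily_evalue_profile()] +
#'    [assign_by_five_orders()] on the hit table.
#' 3. Otherwise the query is designated `"unclassified"`.
#'
#' Tree-assigned queries in a multi-clade subfamily are further placed
#' at clade level with [assign_clade()]; single-clade subfamilies
#' receive their clade label directly.
#'
#' @param trees a `phylo` or list of rooted, support-normalized `phylo`
#'   trees.
#' @param hits hit data.frame ([read_hit_table()]), or `NULL`.
#' @param refset a [reference_set()].
#' @param params [classify_params()].
#' @param queries leaf labels / accessions to classify; defaults to all
#'   tree leaves and hit queries that are neither references nor
#'   outgroups.
#' @param organisms optional named character vector (query -> organism);
#'   defaults to parsing the label prefix.
#' @return data.frame with columns `query`, `organism`, `subfamily`,
#'   `clade`, `evidence` (`tree` / `five_orders` / `unclassified`),
#'   `statistic` and `notes`.
#' @export
classify <- function(trees, hits = NULL, refset,
                     params = classify_params(), queries = NULL,
                     organisms = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  refmap <- ref_accessions(refset)
  known <- c(names(refmap), refset$outgroups)
  if (is.null(queries)) {
    leaves <- unique(unlist(lapply(trees, `[[`, "tip.label")))
    hq <- if (!is.null(hits)) unique(hits$query) else character(0)
    queries <- setdiff(union(leaves, hq), known)
  }
  in_tree <- lapply(trees, function(tr) queries %in% tr$tip.label)
  covered <- Reduce(`|`, in_tree, rep(FALSE, length(queries)))
  if (!is.null(hits)) covered <- covered | queries %in% hits$query
  if (any(!covered))
    stop("query in no tree and no hit table: ",
         paste(queries[!covered], collapse = ", "))

  multi_clade <- vapply(names(refset$subfamilies),
                        function(s) length(refset$subfamilies[[s]]) > 1,
                        TRUE)
  rows <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    q <- queries[i]
    cand <- list()
    for (k in seq_along(trees)) {
      if (!q %in% trees[[k]]$tip.label) next
      a <- assign_by_tree(trees[[k]], q, refset, params)
      if (!is.null(a)) { a$tree_index <- k; cand[[length(cand) + 1]] <- a }
    }
    note <- ""
    row <- NULL
    if (length(cand)) {
      subs <- vapply(cand, `[[`, "", "subfamily")
      if (length(unique(subs)) == 1) {
        best <- cand[[which.max(vapply(cand, `[[`, 0, "statistic"))]]
        tr <- trees[[best$tree_index]]
        cl <- if (multi_clade[[best$subfamily]]) {
          assign_clade(tr, q, best$subfamily, refset, params)
        } else {
          names(refset$subfamilies[[best$subfamily]])[1]
        }
        row <- assignment_row(q, subfamily = best$subfamily, clade = cl,
                              evidence = "tree",
                              statistic = best$statistic)
      } else {
        note <- paste0("conflicting tree assignments: ",
                       paste(sort(unique(subs)), collapse = " vs "),
                       "; fell back to similarity")
      }
    }
    if (is.null(row) && !is.null(hits)) {
      prof <- subfamily_evalue_profile(q, hits, refset,
                                       params$evalue_floor)
      a <- assign_by_five_orders(prof, params)
      if (!is.null(a)) {
        a$query <- q
        if (!multi_clade[[a$subfamily]])
          a$clade <- names(refset$subfamilies[[a$subfamily]])[1]
        if (nzchar(note))
          a$notes <- paste(note, a$notes, sep = "; ")
        row <- a
      }
    }
    if (is.null(row)) row <- assignment_row(q, notes = note)
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$organism <- if (!is.null(organisms)) {
    unname(organisms[out$query])
  } else {
    leaf_organism(out$query)
  }
  attr(out, "params") <- params
  out
}

#' Write assignments as TSV and/or JSON
#'
#' @param assignments data.frame from [classify()].
#' @param path output file; extension `.json` selects JSON (with a
#'   provenance block carrying the parameters), anything else TSV.
#' @export
write_assignments <- function(assignments, path) {
  if (grepl("\\.json$", path)) {
    obj <- list(params = attr(assignments, "params"),
                assignments = assignments)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
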