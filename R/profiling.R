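#' Per-organism record counts
#'
#' Summarises a curated family collection as the number of proteins per
#' organism, the per-organism distribution reported for a family across
#' the study organisms.
#'
#' @param records protein record data.frame.
#' @param organism_order optional organism ordering; organisms absent
#'   from `records` get a zero count.
#' @return named numeric vector of counts ending in a `total` element.
#' @export
count_by_organism <- function(records, organism_order = NULL) {
  tab <- table(factor(records$organism,
                      levels = if (is.null(organism_order))
                        sort(unique(records$organism)) else organism_order))
  counts <- stats::setNames(as.numeric(tab), names(tab))
  c(counts, total = sum(counts))
}

#' Build an organism-by-subfamily presence/absence profile
#'
#' Collects the non-unclassified assignments into a matrix of member
#' accessions per (organism, subfamily) cell; presence is a non-empty
#' cell (the binary dot of a phylogenetic profile).  Unclassified
#' queries are kept in a side table.
#'
#' @param assignments data.frame from [classify()].
#' @param refset a [reference_set()]; supplies subfamily order and
#'   group tags.
#' @param organism_order optional row order; defaults to sorted
#'   organisms seen in `assignments`.
#' @return object of class `profile_matrix`: list with `organisms`,
#'   `subfamilies`, `groups`, `members` (list-matrix of accession
#'   vectors) and `unclassified` (data.frame).
#' @export
build_profile <- function(assignments, refset, organism_order = NULL) {
  subf <- names(refset$subfamilies)
  assigned <- assignments[assignments$subfamily != "unclassified", ,
                          drop = FALSE]
  bad <- setdiff(unique(assigned$subfamily), subf)
  if (length(bad))
    stop("assignment names subfamily absent from reference set: ",
         paste(bad, collapse = ", "))
  orgs <- if (is.null(organism_order))
    sort(unique(assignments$organism), na.last = TRUE) else organism_order
  members <- matrix(vector("list", length(orgs) * length(subf)),
                    nrow = length(orgs), ncol = length(subf),
                    dimnames = list(orgs, subf))
  if (nrow(assigned)) {
    assigned <- assigned[order(assigned$query, method = "radix"), ,
                         drop = FALSE]
    for (i in seq_len(nrow(assigned))) {
      o <- assigned$organism[i]; s <- assigned$subfamily[i]
      if (!o %in% orgs)
        stop("assignment organism '", o, "' not in organism order")
      members[[o, s]] <- c(members[[o, s]], assigned$query[i])
    }
  }
  structure(list(organisms = orgs, subfamilies = subf,
                 groups = refset$groups, members = members,
                 unclassified = assignments[
                   assignments$subfamily == "unclassified", , drop = FALSE]),
            class = "profile_matrix")
}

#' Presence/absence matrix of a profile
#'
#' @param profile a `profile_matrix`.
#' @return logical matrix organisms x subfamilies.
#' @export
presence_matrix <- function(profile) {
  m <- matrix(vapply(profile$members, function(x) length(x) > 0, TRUE),
              nrow = length(profile$organisms),
              dimnames = list(profile$organisms, profile$subfamilies))
  m
}

#' @export
print.profile_matrix <- function(x, ...) {
  p <- presence_matrix(x)
  cat("Phylogenetic profile: ", nrow(p), " organisms x ", ncol(p),
      " subfamilies; ", sum(p), " presences, ",
      nrow(x$unclassified), " unclassified\n", sep = "")
  print(ifelse(p, "*", "-"), quote = FALSE)
  invisible(x)
}

#' Write a profile as TSV or JSON
#'
#' TSV: one row per organism, one column per subfamily, cells are
#' semicolon-joined member accessions with `-` marking absence (never an
#' empty string).  JSON mirrors the full structure including group tags
#' and the unclassified table, and round-trips through
#' [read_profile_json()].
#'
#' @param profile a `profile_matrix`.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @export
write_profile <- function(profile, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    cells <- apply(profile$members, c(1, 2), function(x)
      if (length(x[[1]])) paste(x[[1]], collapse = ";") else "-")
    df <- data.frame(organism = profile$organisms, cells,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    cells <- lapply(seq_along(profile$organisms), function(i)
      stats::setNames(lapply(seq_along(profile$subfamilies), function(j)
        as.list(profile$members[[i, j]])), profile$subfamilies))
    names(cells) <- profile$organisms
    obj <- list(organisms = as.list(profile$organisms),
                subfamilies = as.list(profile$subfamilies),
                groups = as.list(profile$groups),
                members = cells,
                unclassified = profile$unclassified)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a JSON profile written by [write_profile()]
#'
#' @param path JSON file.
#' @return a `profile_matrix`.
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path)
  orgs <- unlist(obj$organisms)
  subf <- unlist(obj$subfamilies)
  members <- matrix(vector("list", length(orgs) * length(subf)),
                    nrow = length(orgs), dimnames = list(orgs, subf))
  for (o in orgs) for (s in subf) {
    v <- unlist(obj$members[[o]][[s]])
    if (!is.null(v)) members[[o, s]] <- as.character(v)
  }
  uncl <- obj$unclassified
  uncl_df <- if (length(uncl)) {
    do.call(rbind, lapply(uncl, function(r)
      as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                    stringsAsFactors = FALSE)))
  } else {
    data.frame(query = character(0), organism = character(0),
               subfamily = character(0), clade = character(0),
               evidence = character(0), statistic = numeric(0),
               notes = character(0), stringsAsFactors = FALSE)
  }
  groups <- if (length(obj$groups)) unlist(obj$groups) else NULL
  structure(list(organisms = orgs, subfamilies = subf, groups = groups,
                 members = members, unclassified = uncl_df),
            class = "profile_matrix")
}

#' Plain-text summary report of counts
#'
#' @param assignments data.frame from [classify()].
#' @param profile a `profile_matrix`.
#' @return character vector of report lines.
#' @export
profile_report <- function(assignments, profile) {
  p <- presence_matrix(profile)
  n_mem <- matrix(vapply(profile$members, length, 0L), nrow = nrow(p))
  c(sprintf("queries classified: %d (%d unclassified)",
            nrow(assignments), nrow(profile$unclassified)),
    "",
    "per organism:",
    sprintf("  %-12s %3d proteins, %2d subfamilies present",
            profile$organisms, rowSums(n_mem), rowSums(p)),
    "",
    "per subfamily:",
    sprintf("  %-14s %3d members in %2d organisms",
            profile$subfamilies, colSums(n_mem), colSums(p)))
}
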