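#' Construct a reference set
#'
#' A reference set defines the classification taxonomy of a protein
#' family: an ordered list of subfamilies, each divided into one or more
#' clades anchored by reference accessions (human proteins in the
#' shipped CDK and cyclin sets), plus the outgroup accessions used to
#' root gene trees.  Every reference accession must appear in exactly one
#' clade of one subfamily.
#'
#' @param family family name, e.g. `"CDK"`.
#' @param subfamilies named list: subfamily label -> named list of
#'   clades, each a character vector of reference accessions.  A
#'   subfamily given directly as a character vector is treated as a
#'   single clade carrying the subfamily's own label.
#' @param outgroups character vector of outgroup accessions.
#' @param groups optional named character vector tagging subfamilies
#'   with a group (e.g. cyclin `"B-like"` / `"Y-like"` / `"C-like"`).
#' @return object of class `reference_set`.
#' @export
reference_set <- function(family, subfamilies, outgroups = character(0),
                          groups = NULL) {
  stopifnot(is.character(family), length(family) == 1,
            is.list(subfamilies), length(subfamilies) >= 1)
  if (is.null(names(subfamilies)) || any(!nzchar(names(subfamilies))))
    stop("subfamilies must be named")
  if (anyDuplicated(names(subfamilies)))
    stop("duplicate subfamily label")
  labels <- names(subfamilies)
  subfamilies <- lapply(seq_along(subfamilies), function(i) {
    s <- subfamilies[[i]]
    if (is.character(s)) s <- stats::setNames(list(s), labels[i])
    if (is.null(names(s)) || any(!nzchar(names(s))))
      stop("clades of subfamily '", labels[i], "' must be named")
    lapply(s, as.character)
  })
  names(subfamilies) <- labels
  acc <- unlist(subfamilies, use.names = FALSE)
  if (anyDuplicated(acc))
    stop("reference accession in more than one clade: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  structure(list(family = family, subfamilies = subfamilies,
                 outgroups = as.character(outgroups), groups = groups),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("Reference set '", x$family, "': ", length(x$subfamilies),
      " subfamilies, ", length(ref_accessions(x)), " reference proteins, ",
      length(x$outgroups), " outgroups\n", sep = "")
  for (s in names(x$subfamilies)) {
    cl <- x$subfamilies[[s]]
    cat("  ", s, ": ", paste(sprintf("%s (%s)", names(cl),
        vapply(cl, function(a) paste(a, collapse = ","), "")),
        collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Reference accession to subfamily map
#'
#' @param refset a [reference_set()].
#' @return named character vector: accession -> subfamily label.
#' @export
ref_accessions <- function(refset) {
  out <- character(0)
  for (s in names(refset$subfamilies)) {
    acc <- unlist(refset$subfamilies[[s]], use.names = FALSE)
    out <- c(out, stats::setNames(rep(s, length(acc)), acc))
  }
  out
}

#' Reference accession to clade map for one subfamily
#'
#' @param refset a [reference_set()].
#' @param subfamily subfamily label.
#' @return named character vector: accession -> clade label.
#' @export
clade_map <- function(refset, subfamily) {
  cl <- refset$subfamilies[[subfamily]]
  if (is.null(cl)) stop("unknown subfamily: ", subfamily)
  out <- character(0)
  for (k in names(cl))
    out <- c(out, stats::setNames(rep(k, length(cl[[k]])), cl[[k]]))
  out
}

#' Read / write a reference set as YAML
#'
#' The on-disk format mirrors the structure: `family`, `subfamilies`
#' (label -> clade -> accessions), `outgroups`, optional `groups`.
#'
#' @param path YAML file.
#' @return a [reference_set()].
#' @export
read_reference_set <- function(path) {
  y <- yaml::read_yaml(path)
  groups <- if (!is.null(y$groups)) unlist(y$groups) else NULL
  reference_set(y$family,
                lapply(y$subfamilies, function(s)
                  lapply(s, function(cl) as.character(unlist(cl)))),
                outgroups = as.character(unlist(y$outgroups)),
                groups = groups)
}

#' @rdname read_reference_set
#' @param refset a [reference_set()].
#' @export
write_reference_set <- function(refset, path) {
  y <- list(family = refset$family,
            subfamilies = refset$subfamilies,
            outgroups = as.list(refset$outgroups))
  if (!is.null(refset$groups)) y$groups <- as.list(refset$groups)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' The CDK reference taxonomy
#'
#' Eight subfamilies anchored by the human CDKs: CDK1 (clades CDK1 and
#' CDK2/3), CDK4/6, CDK5 (clades CDK5, CDK16/17/18 and CDK14/15), CDK7,
#' CDK8/19, CDK9 (clades CDK9 and CDK12/13), CDK10/11 (clades CDK10 and
#' CDK11) and CDK20.  Outgroups are the human non-CDK kinases GSK3alpha,
#' MAK and CDKL1.
#'
#' @return a [reference_set()].
#' @export
cdk_reference_set <- function() {
  reference_set(
    "CDK",
    list(
      "CDK1" = list("CDK1" = "Hsa-CDK1",
                    "CDK2/3" = c("Hsa-CDK2", "Hsa-CDK3")),
      "CDK4/6" = c("Hsa-CDK4", "Hsa-CDK6"),
      "CDK5" = list("CDK5" = "Hsa-CDK5",
                    "CDK16/17/18" = c("Hsa-CDK16", "Hsa-CDK17", "Hsa-CDK18"),
                    "CDK14/15" = c("Hsa-CDK14", "Hsa-CDK15")),
      "CDK7" = "Hsa-CDK7",
      "CDK8/19" = c("Hsa-CDK8", "Hsa-CDK19"),
      "CDK9" = list("CDK9" = "Hsa-CDK9",
                    "CDK12/13" = c("Hsa-CDK12", "Hsa-CDK13")),
      "CDK10/11" = list("CDK10" = "Hsa-CDK10",
                        "CDK11" = c("Hsa-CDK11A", "Hsa-CDK11B")),
      "CDK20" = "Hsa-CDK20"
    ),
    outgroups = c("Hsa-GSK3alpha", "Hsa-MAK", "Hsa-CDKL1")
  )
}

#' The cyclin reference taxonomy
#'
#' Sixteen metazoan subfamilies (anchored by human cyclins) plus the
#' three fungus-specific subfamilies CLB, CLN and PCL (anchored by
#' budding-yeast proteins), each tagged with its group: cyclin B-like
#' (B, A, D, E, J, F, G, I, O, CLB, CLN), cyclin Y-like (Y, PCL) and
#' cyclin C-like (C, H, L, K, T, Fam58).  Outgroups are human CABLES1
#' and CABLES2.
#'
#' @return a [reference_set()].
#' @export
cyclin_reference_set <- function() {
  subf <- list(
    "cyclin B" = c("Hsa-CCNB1", "Hsa-CCNB2", "Hsa-CCNB3"),
    "cyclin A" = c("Hsa-CCNA1", "Hsa-CCNA2"),
    "cyclin D" = c("Hsa-CCND1", "Hsa-CCND2", "Hsa-CCND3"),
    "cyclin E" = c("Hsa-CCNE1", "Hsa-CCNE2"),
    "cyclin J" = "Hsa-CCNJ",
    "cyclin F" = "Hsa-CCNF",
    "cyclin G" = c("Hsa-CCNG1", "Hsa-CCNG2"),
    "cyclin I" = "Hsa-CCNI",
    "cyclin O" = "Hsa-CCNO",
    "CLB" = c("Sce-CLB1", "Sce-CLB2", "Sce-CLB5"),
    "CLN" = c("Sce-CLN1", "Sce-CLN2"),
    "cyclin Y" = "Hsa-CCNY",
    "PCL" = c("Sce-PCL1", "Sce-PHO80"),
    "cyclin C" = "Hsa-CCNC",
    "cyclin H" = "Hsa-CCNH",
    "cyclin L" = c("Hsa-CCNL1", "Hsa-CCNL2"),
    "cyclin K" = "Hsa-CCNK",
    "cyclin T" = c("Hsa-CCNT1", "Hsa-CCNT2"),
    "Fam58" = "Hsa-FAM58A"
  )
  groups <- c(
    "cyclin B" = "B-like", "cyclin A" = "B-like", "cyclin D" = "B-like",
    "cyclin E" = "B-like", "cyclin J" = "B-like", "cyclin F" = "B-like",
    "cyclin G" = "B-like", "cyclin I" = "B-like", "cyclin O" = "B-like",
    "CLB" = "B-like", "CLN" = "B-like",
    "cyclin Y" = "Y-like", "PCL" = "Y-like",
    "cyclin C" = "C-like", "cyclin H" = "C-like", "cyclin L" = "C-like",
    "cyclin K" = "C-like", "cyclin T" = "C-like", "Fam58" = "C-like"
  )
  reference_set("cyclin", subf,
                outgroups = c("Hsa-CABLES1", "Hsa-CABLES2"),
                groups = groups)
}
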