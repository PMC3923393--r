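#' Construct a table of protein records
#'
#' The package represents a protein collection as a plain `data.frame`
#' with columns `accession`, `organism`, `gene_id`, `sequence` and
#' `length`.  `gene_id` groups alternative isoforms of the same gene and
#' defaults to the accession; `organism` is a short species tag
#' (e.g. `"Hsa"`).
#'
#' @param accession character vector of unique, non-empty identifiers.
#' @param sequence amino-acid sequences (non-empty); uppercased, any
#'   terminal `*` stop character stripped.
#' @param organism species tags, recycled; `NA` allowed.
#' @param gene_id gene identifiers, recycled; defaults to `accession`.
#' @return data.frame with one row per protein.
#' @export
protein_records <- function(accession, sequence, organism = NA_character_,
                            gene_id = accession) {
  accession <- as.character(accession)
  sequence <- toupper(as.character(sequence))
  sequence <- sub("\\*+$", "", sequence)
  if (length(sequence) == 1 && length(accession) > 1)
    sequence <- rep_len(sequence, length(accession))
  if (length(accession) != length(sequence))
    stop("'accession' and 'sequence' must have the same length")
  if (any(!nzchar(accession)) || anyNA(accession))
    stop("accessions must be non-empty")
  dup <- accession[duplicated(accession)]
  if (length(dup))
    stop("duplicate accession(s): ", paste(unique(dup), collapse = ", "))
  if (length(accession) && any(!nzchar(sequence)))
    stop("empty sequence for: ",
         paste(accession[!nzchar(sequence)], collapse = ", "))
  data.frame(
    accession = accession,
    organism = rep_len(as.character(organism), length(accession)),
    gene_id = rep_len(as.character(gene_id), length(accession)),
    sequence = sequence,
    length = nchar(sequence),
    stringsAsFactors = FALSE
  )
}

# Parse "ACC key=value key=value" FASTA headers.
parse_fasta_header <- function(headers, default_organism = NA_character_) {
  acc <- sub("\\s.*$", "", headers)
  org <- rep_len(as.character(default_organism), length(headers))
  gid <- acc
  get_tag <- function(h, tag) {
    m <- regmatches(h, regexec(paste0("(?:^|\\s)", tag, "=([^\\s]+)"), h,
                               perl = TRUE))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  o <- get_tag(headers, "organism")
  g <- get_tag(headers, "gene")
  org[!is.na(o)] <- o[!is.na(o)]
  gid[!is.na(g)] <- g[!is.na(g)]
  list(accession = acc, organism = org, gene_id = gid)
}

#' Read a protein FASTA file
#'
#' Headers carry the accession as the first whitespace-delimited token;
#' optional `organism=` and `gene=` key=value tokens supply the species
#' tag and the isoform-grouping gene identifier.  When absent, the
#' organism falls back to `default_organism` and the gene id to the
#' accession.  Sequences are uppercased and a terminal `*` is stripped.
#'
#' @param path FASTA file.
#' @param default_organism organism tag used when the header carries none.
#' @return protein record data.frame (see [protein_records()]); an empty
#'   file yields zero rows with a warning.
#' @export
read_fasta <- function(path, default_organism = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(raw)))) {
    warning("empty FASTA file: ", path)
    return(protein_records(character(0), character(0)))
  }
  x <- Biostrings::readAAStringSet(path)
  h <- parse_fasta_header(names(x), default_organism)
  dup <- h$accession[duplicated(h$accession)]
  if (length(dup))
    stop("duplicate accession(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  protein_records(h$accession, as.character(x),
                  organism = h$organism, gene_id = h$gene_id)
}

#' Write protein records as FASTA
#'
#' Emits standard 60-column-wrapped FASTA; organism and gene id are
#' re-emitted as `organism=`/`gene=` header tokens when informative (a
#' gene id equal to the accession is omitted).
#'
#' @param records protein record data.frame.
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  if (nrow(records) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  hdr <- records$accession
  has_org <- !is.na(records$organism) & nzchar(records$organism)
  hdr[has_org] <- paste0(hdr[has_org], " organism=", records$organism[has_org])
  has_gid <- !is.na(records$gene_id) & records$gene_id != records$accession
  hdr[has_gid] <- paste0(hdr[has_gid], " gene=", records$gene_id[has_gid])
  x <- Biostrings::AAStringSet(records$sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}
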