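#' Published per-organism CDK and cyclin counts
#'
#' The distribution of curated CDK and cyclin proteins across the 18
#' study organisms, as published (columns `species`, `tag`, `phylum`,
#' `cdk`, `cyclin`).  The CDK column sums to 172 and the cyclin column
#' to 226.  Also supplies the canonical organism ordering used by
#' profiles.
#'
#' @return data.frame with 18 rows.
#' @export
organism_table <- function() {
  path <- system.file("extdata", "organism_table.tsv",
                      package = "cdkcyclin", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
}

#' Synthetic stand-in for a curated family collection
#'
#' Builds a protein collection with a prescribed number of records per
#' organism (dummy 50-residue sequences, accessions
#' `"{tag}-{family}-{i}"`).  This is a synthetic stand-in for a curated
#' family FASTA whose real sequences are not redistributed here; it
#' carries the collection's *structure* (per-organism membership) so
#' counting and profiling machinery can be exercised against published
#' distributions.
#'
#' @param counts named integer vector: organism tag -> record count.
#' @param family family tag used in accessions; default `"CDK"`.
#' @return protein record data.frame.
#' @export
synthetic_family_records <- function(counts, family = "CDK") {
  tags <- rep(names(counts), counts)
  serial <- unlist(lapply(counts, seq_len), use.names = FALSE)
  if (!length(tags))
    return(protein_records(character(0), character(0)))
  protein_records(
    accession = paste(tags, family, serial, sep = "-"),
    sequence = strrep("ACDEFGHIKL", 5),
    organism = tags)
}
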