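#' Read a 12-column BLAST tabular hit file
#'
#' Parses the standard tab-separated BLAST tabular dialect (`qseqid
#' sseqid pident length mismatch gapopen qstart qend sstart send evalue
#' bitscore`).  Lines starting with `#` are ignored.  Multiple HSPs per
#' (query, subject) pair are retained; consumers take the minimum E-value
#' per pair as the canonical score.
#'
#' @param path tab-separated file.
#' @return data.frame with columns `query`, `subject`, `pident`,
#'   `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore`.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (!length(idx)) {
    out <- as.data.frame(stats::setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 10)), cols))
    return(out)
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 12))
    stop(sprintf("line %d of %s: expected 12 tab-separated columns, found %d",
                 idx[which(nfield != 12)[1]], path,
                 nfield[which(nfield != 12)[1]]))
  m <- matrix(unlist(parts), ncol = 12, byrow = TRUE)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop(sprintf("line %d of %s: unparsable %s '%s'",
                   idx[which(is.na(v))[1]], path, what,
                   m[which(is.na(v))[1], j]))
    v
  }
  out <- data.frame(query = m[, 1], subject = m[, 2],
                    pident = num(3, "pident"), length = num(4, "length"),
                    mismatch = num(5, "mismatch"), gapopen = num(6, "gapopen"),
                    qstart = num(7, "qstart"), qend = num(8, "qend"),
                    sstart = num(9, "sstart"), send = num(10, "send"),
                    evalue = num(11, "evalue"), bitscore = num(12, "bitscore"),
                    stringsAsFactors = FALSE)
  if (any(out$evalue < 0))
    stop("negative E-value in ", path)
  out
}

#' Write hits as 12-column BLAST tabular
#'
#' @param hits data.frame as returned by [read_hit_table()].
#' @param path output file.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  stopifnot(all(cols %in% names(hits)))
  df <- hits[, cols]
  df$evalue <- formatC(df$evalue, format = "g", digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a domain-annotation table
#'
#' Tab-separated columns `protein`, `domain`, `evalue`, `start`, `end`
#' (1-based inclusive residue coordinates, the Pfam/SMART convention).  A
#' header line naming the columns is tolerated and skipped.
#'
#' @param path tab-separated file.
#' @return data.frame of domain hits.
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  if (length(idx) && identical(strsplit(lines[idx[1]], "\t")[[1]][1:2],
                               c("protein", "domain")))
    idx <- idx[-1]
  empty <- data.frame(protein = character(0), domain = character(0),
                      evalue = numeric(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (!length(idx)) return(empty)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 5))
    stop(sprintf("line %d of %s: expected 5 tab-separated columns, found %d",
                 idx[which(nfield != 5)[1]], path,
                 nfield[which(nfield != 5)[1]]))
  m <- matrix(unlist(parts), ncol = 5, byrow = TRUE)
  ev <- suppressWarnings(as.numeric(m[, 3]))
  st <- suppressWarnings(as.integer(m[, 4]))
  en <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(ev) || anyNA(st) || anyNA(en))
    stop("unparsable numeric field in ", path)
  bad <- which(st > en | st < 1)
  if (length(bad))
    stop(sprintf("line %d of %s: invalid coordinates start=%d end=%d",
                 idx[bad[1]], path, st[bad[1]], en[bad[1]]))
  if (any(ev < 0)) stop("negative E-value in ", path)
  data.frame(protein = m[, 1], domain = m[, 2], evalue = ev,
             start = st, end = en, stringsAsFactors = FALSE)
}

#' Write a domain-annotation table
#'
#' @param domains data.frame as returned by [read_domain_table()].
#' @param path output file.
#' @export
write_domain_table <- function(domains, path) {
  utils::write.table(
    domains[, c("protein", "domain", "evalue", "start", "end")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
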