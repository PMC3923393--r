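#' Write a complete synthetic benchmark bundle
#'
#' Runs [simulate_gene_tree()], [emulate_supports()] and
#' [emulate_evalues()], derives a [reference_set()] from the designated
#' reference leaves (one single-clade subfamily per founder), and writes
#' everything in the formats the pipeline reads:
#'
#' * `gene_tree.nwk` -- Newick with bootstrap-percent supports
#' * `hits.tsv` -- 12-column BLAST tabular
#' * `refset.yaml` -- the reference set
#' * `truth.tsv` -- leaf, organism, true subfamily, reference flag
#' * `sequences.fasta` -- optional toy sequences
#' * `manifest.json` -- file list with MD5 digests, the configuration
#'   and the seed
#'
#' Identical configurations (including seed) produce byte-identical
#' bundles.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @param sequences also emit toy sequences; default `FALSE`.
#' @return invisibly, a list with the in-memory objects (`tree`,
#'   `truth`, `hits`, `refset`, `config`, `files`).
#' @export
make_benchmark <- function(config, dir, sequences = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_gene_tree(config)
  tree <- emulate_supports(sim$tree, config)
  hits <- emulate_evalues(tree, sim$truth, config)
  refset <- benchmark_reference_set(sim$truth, config)

  files <- c(tree = "gene_tree.nwk", hits = "hits.tsv",
             refset = "refset.yaml", truth = "truth.tsv")
  write_newick(tree, file.path(dir, files["tree"]))
  write_hit_table(hits, file.path(dir, files["hits"]))
  write_reference_set(refset, file.path(dir, files["refset"]))
  utils::write.table(sim$truth, file.path(dir, files["truth"]),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (sequences) {
    files <- c(files, sequences = "sequences.fasta")
    write_fasta(simulate_sequences(tree, config),
                file.path(dir, files["sequences"]))
  }
  manifest <- list(
    files = lapply(stats::setNames(as.character(files), names(files)),
                   function(f) list(
                     name = f,
                     md5 = unname(tools::md5sum(file.path(dir, f))))),
    config = config_as_list(config),
    seed = config$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(tree = tree, truth = sim$truth, hits = hits,
                 refset = refset, config = config, files = files))
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$species_tree <- write_newick(config$species_tree)
  out
}

# one subfamily per founder, anchored by its reference leaf
benchmark_reference_set <- function(truth, config) {
  refs <- truth[truth$is_reference, , drop = FALSE]
  subf <- stats::setNames(as.list(refs$accession), refs$subfamily)
  reference_set(family = "synthetic", subfamilies = subf)
}

#' Read a benchmark bundle from disk
#'
#' @param dir directory written by [make_benchmark()].
#' @return list with `tree`, `hits`, `refset`, `truth`, `manifest`.
#' @export
read_benchmark <- function(dir) {
  tree <- read_newick(file.path(dir, "gene_tree.nwk"))
  tree <- normalize_support(tree)
  list(tree = tree,
       hits = read_hit_table(file.path(dir, "hits.tsv")),
       refset = read_reference_set(file.path(dir, "refset.yaml")),
       truth = utils::read.table(file.path(dir, "truth.tsv"),
                                 header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE),
       manifest = jsonlite::read_json(file.path(dir, "manifest.json")))
}

#' Score assignments against a simulation truth table
#'
#' Recovery is the percentage of non-reference truth leaves whose
#' assigned subfamily equals the true one (an unclassified query counts
#' as a miss).
#'
#' @param assignments data.frame from [classify()].
#' @param truth truth table from [simulate_gene_tree()].
#' @return list with `recovery` (percent), `n_queries`, `n_correct`,
#'   and `by_evidence` (correct/total per evidence type).
#' @export
score_classification <- function(assignments, truth) {
  q <- truth[!truth$is_reference, , drop = FALSE]
  m <- match(q$accession, assignments$query)
  if (anyNA(m))
    stop("truth leaves missing from assignments: ",
         paste(q$accession[is.na(m)], collapse = ", "))
  got <- assignments$subfamily[m]
  correct <- got == q$subfamily
  ev <- assignments$evidence[m]
  by_ev <- t(vapply(split(correct, ev),
                    function(x) c(correct = sum(x), total = length(x)),
                    c(correct = 0, total = 0)))
  list(recovery = 100 * mean(correct), n_queries = nrow(q),
       n_correct = sum(correct), by_evidence = by_ev)
}

#' Simulate, classify and score in one step
#'
#' @param config a [simulation_config()].
#' @param params [classify_params()].
#' @return list with `score` (from [score_classification()]),
#'   `assignments`, `truth`, `profile` and `truth_presence`.
#' @export
run_benchmark <- function(config, params = classify_params()) {
  sim <- simulate_gene_tree(config)
  tree <- emulate_supports(sim$tree, config)
  tree <- normalize_support(tree)
  hits <- emulate_evalues(tree, sim$truth, config)
  refset <- benchmark_reference_set(sim$truth, config)
  asg <- classify(tree, hits, refset, params = params)
  # the reference anchors are family members by definition and belong in
  # the presence profile alongside the classified queries
  refmap <- ref_accessions(refset)
  ref_rows <- assignment_row(names(refmap),
                             organism = leaf_organism(names(refmap)),
                             subfamily = unname(refmap),
                             evidence = "reference",
                             statistic = NA_real_,
                             notes = "reference anchor")
  profile <- build_profile(rbind(asg, ref_rows), refset,
                           organism_order = config$species_tree$tip.label)
  list(score = score_classification(asg, sim$truth),
       assignments = asg, truth = sim$truth, profile = profile,
       truth_presence = truth_presence(sim$truth, config))
}
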