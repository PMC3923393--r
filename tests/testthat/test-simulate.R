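test_that("no-event limit: gene tree per founder mirrors the species tree", {
  cfg <- simulation_config(species_tree = small_species_tree(),
                           founders = c("F1", "F2"),
                           dup_rate = 0, loss_rate = 0, seed = 1)
  sim <- simulate_gene_tree(cfg)
  # exactly one copy per founder per species
  expect_equal(nrow(sim$truth), 2 * 4)
  expect_equal(unname(table(sim$truth$subfamily)), c(4L, 4L),
               ignore_attr = TRUE)
  expect_setequal(unique(sim$truth$organism), c("A", "B", "C", "D"))
  # per-founder topology congruent with the species tree
  for (f in c("F1", "F2")) {
    leaves <- sim$truth$accession[sim$truth$subfamily == f]
    expect_true(is_monophyletic(sim$tree, leaves)$monophyletic)
    sub <- ape::keep.tip(sim$tree, leaves)
    sub$tip.label <- sub("\\|.*$", "", sub$tip.label)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(sub),
                                           ape::unroot(cfg$species_tree))),
                 0)
  }
  # reference: first surviving copy in the reference organism (tip A)
  refs <- sim$truth[sim$truth$is_reference, ]
  expect_equal(refs$organism, c("A", "A"))
  expect_equal(sort(refs$subfamily), c("F1", "F2"))
})

test_that("duplication-only simulation never shrinks a family", {
  cfg <- simulation_config(species_tree = small_species_tree(),
                           founders = "F1", dup_rate = 0.8,
                           loss_rate = 0, seed = 9)
  sim <- simulate_gene_tree(cfg)
  expect_gte(nrow(sim$truth), 4)         # >= one copy per species
  expect_setequal(unique(sim$truth$organism), c("A", "B", "C", "D"))
})

test_that("mean family size matches the birth-death expectation", {
  # ultrametric depth-1 tree with 4 tips: E[leaves] = 4 * e^(lambda-mu)
  lam <- 0.3; mu <- 0.1
  n_rep <- 400
  sizes <- vapply(seq_len(n_rep), function(i) {
    cfg <- simulation_config(species_tree = small_species_tree(),
                             founders = "F1", dup_rate = lam,
                             loss_rate = mu, seed = 10000 + i)
    sim <- tryCatch(simulate_gene_tree(cfg), error = function(e) NULL)
    if (is.null(sim)) 0 else nrow(sim$truth)
  }, 0)
  expected <- 4 * exp(lam - mu)
  se <- stats::sd(sizes) / sqrt(n_rep)
  expect_lt(abs(mean(sizes) - expected), 4 * se + 0.05)

  # independent Monte-Carlo oracle: per-tip survivor count after time 1
  set.seed(99)
  oracle <- 4 * mean(vapply(seq_len(4000), function(i)
    oracle_bd_survivors(lam, mu, 1), 0L))
  expect_lt(abs(mean(sizes) - oracle),
            4 * sqrt(se^2 + (stats::sd(sizes) / sqrt(4000))^2) + 0.1)
})

test_that("support emulation follows branch lengths and clamps", {
  tr <- read_newick("(((A:0.5,B:0.5):0.00001,C:1):1,D:2);")
  # huge sharpness, no noise -> every non-root internal edge at 100
  cfg <- simulation_config(species_tree = small_species_tree(),
                           support_sharpness = 1e6,
                           support_noise_sd = 0, seed = 2)
  out <- emulate_supports(tr, cfg)
  s <- node_supports(out)
  expect_equal(unname(s[!is.na(s)]), c(100, 100))

  # near-zero branch, no noise -> support ~ 0
  cfg0 <- simulation_config(species_tree = small_species_tree(),
                            support_sharpness = 1e-9,
                            support_noise_sd = 0, seed = 2)
  out0 <- emulate_supports(tr, cfg0)
  s0 <- node_supports(out0)
  expect_equal(unname(s0[!is.na(s0)]), c(0, 0))

  # determinism under a fixed seed
  cfgn <- simulation_config(species_tree = small_species_tree(),
                            support_noise_sd = 10, seed = 31)
  expect_identical(emulate_supports(tr, cfgn)$node.label,
                   emulate_supports(tr, cfgn)$node.label)
})

test_that("emulated E-values decay with patristic distance", {
  cfg <- simulation_config(species_tree = small_species_tree(),
                           founders = c("F1", "F2"),
                           dup_rate = 0, loss_rate = 0,
                           evalue_slope = 50, evalue_scale = 1,
                           evalue_noise_sd = 0, seed = 4)
  sim <- simulate_gene_tree(cfg)
  hits <- emulate_evalues(sim$tree, sim$truth, cfg)
  expect_gt(nrow(hits), 0)
  D <- ape::dist.nodes(sim$tree)
  idx <- stats::setNames(seq_along(sim$tree$tip.label),
                         sim$tree$tip.label)
  d <- D[cbind(idx[hits$query], idx[hits$subject])]
  # noise-free: log10 E strictly increasing in distance
  o <- order(d)
  expect_true(all(diff(log10(hits$evalue)[o]) >= -1e-9))
  # no hit weaker than the reporting cutoff
  expect_true(all(log10(hits$evalue) <= -2 + 1e-12))

  # within-subfamily hits are stronger than between-subfamily hits,
  # checked against exhaustive pair enumeration of the truth table
  subf_q <- sim$truth$subfamily[match(hits$query, sim$truth$accession)]
  subf_s <- sim$truth$subfamily[match(hits$subject, sim$truth$accession)]
  within <- log10(hits$evalue[subf_q == subf_s])
  between <- log10(hits$evalue[subf_q != subf_s])
  expect_gt(length(within), 0)
  if (length(between) > 0)
    expect_lt(mean(within), mean(between))
  # every within-subfamily (query, reference) pair appears
  refs <- sim$truth$accession[sim$truth$is_reference]
  queries <- setdiff(sim$tree$tip.label, refs)
  n_within_expected <- sum(outer(
    sim$truth$subfamily[match(queries, sim$truth$accession)],
    sim$truth$subfamily[match(refs, sim$truth$accession)], "=="))
  expect_equal(length(within), n_within_expected)
})

test_that("benchmark bundles are deterministic and self-consistent", {
  cfg <- simulation_config(species_tree = small_species_tree(),
                           founders = c("F1", "F2"), seed = 8)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- make_benchmark(cfg, d1)
  b2 <- make_benchmark(cfg, d2)
  for (f in b1$files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # truth conservation: every surviving lineage appears exactly once
  expect_equal(anyDuplicated(b1$truth$accession), 0L)
  expect_setequal(b1$truth$accession, b1$tree$tip.label)
  # bundle reads back and classifies
  bundle <- read_benchmark(d1)
  expect_equal(sort(bundle$tree$tip.label), sort(b1$tree$tip.label))
  expect_equal(bundle$refset$family, "synthetic")
  asg <- classify(bundle$tree, bundle$hits, bundle$refset)
  expect_equal(nrow(asg), sum(!bundle$truth$is_reference))
})

test_that("toy sequences are reproducible and well-formed", {
  cfg <- simulation_config(species_tree = small_species_tree(),
                           founders = "F1", seed = 12)
  sim <- simulate_gene_tree(cfg)
  s1 <- simulate_sequences(sim$tree, cfg)
  s2 <- simulate_sequences(sim$tree, cfg)
  expect_identical(s1, s2)
  expect_equal(s1$length, rep(200L, nrow(s1)))
  expect_setequal(s1$accession, sim$tree$tip.label)
})

test_that("zero-loss simulations give an all-present truth matrix", {
  cfg <- simulation_config(species_tree = small_species_tree(),
                           founders = c("F1", "F2"), dup_rate = 0.3,
                           loss_rate = 0, seed = 21)
  sim <- simulate_gene_tree(cfg)
  tp <- truth_presence(sim$truth, cfg)
  expect_true(all(tp))
})

test_that("recovery is non-increasing in support noise", {
  # baseline supports are saturated (sharpness 1e4), so noise can only
  # push clades below the threshold; the displaced queries fall to the
  # similarity rule, which fails for distant organisms.  Same seeds at
  # every noise level (common random numbers).
  recov <- vapply(c(0, 15, 40), function(sn) {
    mean(vapply(1:8, function(seed) {
      cfg <- simulation_config(dup_rate = 0.2, loss_rate = 0,
                               support_sharpness = 1e4,
                               support_noise_sd = sn,
                               evalue_noise_sd = 0, seed = seed)
      run_benchmark(cfg)$score$recovery
    }, 0))
  }, 0)
  expect_equal(recov[1], 100)
  expect_true(all(diff(recov) <= 0))
})
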