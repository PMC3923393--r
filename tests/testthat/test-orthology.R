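test_that("tree rule: single-subfamily clade above the support threshold", {
  rs <- toy_refset(2)
  tr <- read_newick("((q:1,r1:1)90:1,(r2:1,o:1)70:1);")
  a <- assign_by_tree(tr, "q", rs)
  expect_equal(a$subfamily, "S1")
  expect_equal(a$evidence, "tree")
  expect_equal(a$statistic, 90)

  # insufficient support
  lo <- read_newick("((q:1,r1:1)40:1,(r2:1,o:1)70:1);")
  expect_null(assign_by_tree(lo, "q", rs))

  # the threshold is strict: exactly 50 fails
  at50 <- read_newick("((q:1,r1:1)50:1,(r2:1,o:1)70:1);")
  expect_null(assign_by_tree(at50, "q", rs))

  # mixed-subfamily first ancestor fails the tree rule
  mixed <- read_newick("((q:1,(r1:1,r2:1)80:1)95:1,o:1);")
  expect_null(assign_by_tree(mixed, "q", rs))

  # a clade without support is treated as support 0
  nosupp <- read_newick("((q:1,r1:1):1,(r2:1,o:1):1);")
  expect_null(assign_by_tree(nosupp, "q", rs))
})

test_that("tree rule agrees with brute-force clade enumeration", {
  n_agree <- 0L
  for (seed in 1:60) {
    tr <- random_support_tree(sample(5:12, 1), seed + 500)
    tips <- tr$tip.label
    refs <- sample(tips, sample(2:4, 1))
    query <- sample(setdiff(tips, refs), 1)
    refmap <- stats::setNames(sample(c("S1", "S2"), length(refs), TRUE),
                              refs)
    rs <- reference_set("toy", lapply(
      stats::setNames(c("S1", "S2"), c("S1", "S2")),
      function(s) names(refmap)[refmap == s]))
    got <- assign_by_tree(tr, query, rs)
    want <- oracle_assign_by_tree(tr, query, refmap)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$subfamily, want$subfamily)
      expect_equal(got$statistic, want$support)
    }
    n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, 60L)
})

test_that("subfamily E-value profiles take per-subfamily minima with floor", {
  rs <- reference_set("toy", list(S1 = c("r1", "r1b"), S2 = "r2"))
  hits <- hit_df(c("q", "q", "q"), c("r1", "r1b", "r2"),
                 c(1e-30, 1e-12, 1e-7))
  prof <- subfamily_evalue_profile("q", hits, rs)
  expect_equal(prof, c(S1 = 1e-30, S2 = 1e-7))

  # zero E-value (underflow) is floored
  h0 <- hit_df("q", "r1", 0)
  expect_equal(subfamily_evalue_profile("q", h0, rs), c(S1 = 1e-180))

  # no reference hits -> empty profile
  expect_length(subfamily_evalue_profile("zz", hits, rs), 0)
})

test_that("five-orders rule: ratio criterion with inclusive boundary", {
  expect_equal(assign_by_five_orders(c(S1 = 1e-15, S2 = 1e-7))$subfamily,
               "S1")                               # ratio 1e-8
  expect_null(assign_by_five_orders(c(S1 = 1e-10, S2 = 1e-6)))  # 1e-4
  # exactly five orders passes (inclusive)
  a <- assign_by_five_orders(c(S1 = 1e-12, S2 = 1e-7))
  expect_equal(a$subfamily, "S1")
  expect_equal(a$statistic, 1e-5, tolerance = 1e-10)
  # single-subfamily profile: absolute ceiling applies
  solo <- assign_by_five_orders(c(S1 = 1e-12))
  expect_equal(solo$subfamily, "S1")
  expect_match(solo$notes, "single-subfamily")
  expect_null(assign_by_five_orders(c(S1 = 1e-6)))  # above ceiling
  expect_null(assign_by_five_orders(stats::setNames(numeric(0),
                                                    character(0))))
})

test_that("five-orders decisions are invariant under global rescaling", {
  set.seed(77)
  n_same <- 0L
  for (rep in 1:200) {
    k <- sample(2:5, 1)
    prof <- stats::setNames(10^-stats::runif(k, 3, 100),
                            paste0("S", seq_len(k)))
    a <- assign_by_five_orders(prof)
    cc <- 10^-stats::runif(1, 0, 40)     # c in (0, 1]
    b <- assign_by_five_orders(prof * cc)
    same <- (is.null(a) && is.null(b)) ||
      (!is.null(a) && !is.null(b) && a$subfamily == b$subfamily)
    n_same <- n_same + same
  }
  expect_equal(n_same, 200L)
})

test_that("classify chains tree, five-orders and unclassified evidence", {
  rs <- toy_refset(2)
  hits <- hit_df(c("q", "q"), c("r1", "r2"), c(1e-20, 1e-5))

  # strong tree signal wins regardless of E-values
  tr <- read_newick("((q:1,r1:1)90:1,(r2:1,o:1)70:1);")
  a <- classify(tr, hits, rs, queries = "q")
  expect_equal(a$evidence, "tree")
  expect_equal(a$subfamily, "S1")

  # weak tree -> five-orders fallback (ratio 1e-15)
  lo <- read_newick("((q:1,r1:1)40:1,(r2:1,o:1)70:1);")
  b <- classify(lo, hits, rs, queries = "q")
  expect_equal(b$evidence, "five_orders")
  expect_equal(b$subfamily, "S1")

  # weak tree and weak margin -> unclassified
  weak <- hit_df(c("q", "q"), c("r1", "r2"), c(1e-8, 1e-6))
  c_ <- classify(lo, weak, rs, queries = "q")
  expect_equal(c_$evidence, "unclassified")
  expect_equal(c_$subfamily, "unclassified")

  # a query nowhere to be found is an error naming it
  expect_error(classify(lo, hits, rs, queries = c("q", "ghost")),
               "ghost")
})

test_that("conflicting tree assignments fall back to similarity", {
  rs <- toy_refset(2)
  t1 <- read_newick("((q:1,r1:1)90:1,(r2:1,o:1)70:1);")
  t2 <- read_newick("((q:1,r2:1)80:1,(r1:1,o:1)70:1);")
  hits <- hit_df(c("q", "q"), c("r1", "r2"), c(1e-40, 1e-6))
  a <- classify(list(t1, t2), hits, rs, queries = "q")
  expect_equal(a$evidence, "five_orders")
  expect_match(a$notes, "conflict")

  # agreeing trees: highest support wins, evidence stays tree
  t3 <- read_newick("((q:1,r1:1)60:1,(r2:1,o:1)70:1);")
  b <- classify(list(t1, t3), hits, rs, queries = "q")
  expect_equal(b$evidence, "tree")
  expect_equal(b$statistic, 90)
})

test_that("clade-level assignment reruns the rule inside the subfamily", {
  rs <- reference_set("CDKtoy", list(
    CDK9 = list("CDK9" = "hCDK9", "CDK12/13" = c("hCDK12", "hCDK13"))))
  # query inside the CDK12/13 reference clade with support 85
  tr <- read_newick(
    "(((q:1,(hCDK12:1,hCDK13:1)90:1)85:1,hCDK9:1)95:1,o:1);")
  expect_equal(assign_clade(tr, "q", "CDK9", rs), "CDK12/13")

  # query attaching below the clades' common stem -> subfamily only
  tr2 <- read_newick(
    "((q:1,((hCDK12:1,hCDK13:1)90:1,hCDK9:1)80:1)95:1,o:1);")
  expect_true(is.na(assign_clade(tr2, "q", "CDK9", rs)))

  # single-clade subfamily is trivial
  rs1 <- reference_set("toy", list(S1 = "r1"))
  expect_equal(assign_clade(tr, "q", "S1", rs1), "S1")
})

test_that("classification emits exactly one assignment per query", {
  cfg <- simulation_config(species_tree = small_species_tree(),
                           founders = c("F1", "F2", "F3"), seed = 3)
  bm <- run_benchmark(cfg)
  expect_equal(anyDuplicated(bm$assignments$query), 0L)
  expect_setequal(bm$assignments$query,
                  bm$truth$accession[!bm$truth$is_reference])
  expect_true(all(bm$assignments$evidence %in%
                    c("tree", "five_orders", "unclassified")))
  # evidence/subfamily consistency
  uncl <- bm$assignments$evidence == "unclassified"
  expect_equal(bm$assignments$subfamily == "unclassified", uncl)
  expect_true(all(!is.na(bm$assignments$statistic[!uncl])))
})

test_that("assignments serialise to TSV and JSON", {
  rs <- toy_refset(2)
  tr <- read_newick("((q:1,r1:1)90:1,(r2:1,o:1)70:1);")
  a <- classify(tr, NULL, rs, queries = "q")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_assignments(a, tsv)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(back$subfamily, a$subfamily)
  write_assignments(a, jsn)
  obj <- jsonlite::read_json(jsn)
  expect_equal(obj$assignments[[1]]$subfamily, "S1")
  expect_equal(obj$params$min_support, 50)
})

test_that("recovery degrades as the support threshold rises", {
  # with informative supports every query passes the tree rule; raising
  # min_support pushes queries onto the similarity fallback, which
  # cannot rescue the most distant organisms, so recovery can only drop
  means <- vapply(c(50, 80, 100), function(ms) {
    mean(vapply(1:6, function(seed) {
      cfg <- simulation_config(dup_rate = 0.2, loss_rate = 0,
                               support_sharpness = 20,
                               support_noise_sd = 0,
                               evalue_noise_sd = 0, seed = seed)
      run_benchmark(cfg,
                    classify_params(min_support = ms))$score$recovery
    }, 0))
  }, 0)
  expect_true(all(diff(means) <= 0))
  expect_lt(means[3], means[1])
})
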