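test_that("additive distance matrices are inverted exactly by tree inference", {
  set.seed(30)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    true <- ape::rtree(n)
    dm <- ape::cophenetic.phylo(true)
    dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
    for (method in c("bme", "nj")) {
      tr <- infer_tree(dm, method)
      back <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
      expect_equal(back, dm, tolerance = 1e-6)
    }
  }
})

test_that("three-taxon matrices give the closed-form star lengths", {
  dm <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- infer_tree(dm)
  # three-point formulas: la = (dab + dac - dbc)/2 etc.
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(3, 2, 6))
})

test_that("invalid distance matrices are rejected", {
  m <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a","b"), c("a","b")))
  expect_error(infer_tree(m), "symmetric")
  m2 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m2[1, 2] <- m2[2, 1] <- NaN
  expect_error(infer_tree(m2), "finite")
  m3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(infer_tree(m3), "diagonal")
})

# small fabricated pairwise_set for resampling tests
mk_ps <- function(ids, hsps_per_pair, lengths = NULL) {
  combs <- utils::combn(ids, 2)
  pairs <- data.frame(genome_a = combs[1, ], genome_b = combs[2, ],
                      stringsAsFactors = FALSE)
  if (is.null(lengths)) lengths <- setNames(rep(1e5, length(ids)), ids)
  structure(list(ids = ids, pairs = pairs, hsps = hsps_per_pair,
                 lengths = lengths,
                 gc = setNames(rep(50, length(ids)), ids)),
            class = "pairwise_set")
}

test_that("pseudo-bootstrap is seed-reproducible and invariant on uniform HSPs", {
  ids <- c("a", "b", "c")
  uniform <- data.frame(length = rep(1000, 5), identities = rep(950, 5),
                        bitscore = rep(100, 5))
  ps <- mk_ps(ids, list(uniform, uniform, uniform))
  reps1 <- pseudo_bootstrap(ps, replicates = 10, seed = 99)
  reps2 <- pseudo_bootstrap(ps, replicates = 10, seed = 99)
  expect_identical(reps1, reps2)
  # all HSPs identical => every replicate distance equals the original
  d0 <- gbdp_distance_from_hsps(uniform, 1e5, 1e5, "d5")
  for (m in reps1) expect_true(all(abs(m[upper.tri(m)] - d0) < 1e-12))
  # a pair with no HSPs keeps the capped maximum in every replicate
  ps2 <- mk_ps(ids, list(uniform, uniform, NULL))
  reps3 <- pseudo_bootstrap(ps2, replicates = 3, seed = 1)
  cap <- pd_constants()$gbdp_max_distance[["d5"]]
  expect_equal(reps3[[1]]["b", "c"], cap)
})

test_that("support mapping equals brute-force bipartition counting", {
  set.seed(31)
  main <- ape::rtree(5)
  reps <- replicate(20, ape::rtree(5, tip.label = main$tip.label),
                    simplify = FALSE)
  sup <- map_support(main, reps)
  # brute force: compare each internal bipartition of main against each
  # replicate using an independent enumeration over tip subsets
  tips <- main$tip.label
  nt <- length(tips)
  splits_of <- function(tr) {
    out <- list()
    for (nd in (nt + 2):(nt + tr$Nnode)) {   # skip the root
      cl <- sort(ape::extract.clade(tr, nd)$tip.label)
      if (length(cl) >= 2 && length(cl) <= nt - 2) {
        if (sort(tips)[1] %in% cl) cl <- sort(setdiff(tips, cl))
        out[[length(out) + 1L]] <- cl
      }
    }
    out
  }
  main_splits <- splits_of(main)
  counts <- vapply(main_splits, function(sp)
    sum(vapply(reps, function(r)
      any(vapply(splits_of(r), identical, logical(1), y = sp)),
      logical(1))), numeric(1))
  expected <- round(100 * counts / length(reps))
  got <- suppressWarnings(as.numeric(sup$node.label))
  got <- got[!is.na(got)]
  expect_setequal(got, expected)
  expect_error(map_support(main, list(ape::rtree(5, tip.label = paste0("x", 1:5)))),
               "leaf set")
})

test_that("bipartitions present in all or no replicates get support 100 or 0", {
  set.seed(32)
  main <- ape::rtree(6)
  same <- replicate(10, main, simplify = FALSE)
  sup_all <- map_support(main, same)
  vals <- suppressWarnings(as.numeric(sup_all$node.label))
  expect_true(all(vals[!is.na(vals)] == 100))
  # replicates sharing no internal structure with a caterpillar main tree
  cat_tree <- ape::read.tree(text = "(((((a,b),c),d),e),f);")
  star_like <- replicate(10, {
    t <- ape::rtree(6, tip.label = sample(letters[1:6]))
    t
  }, simplify = FALSE)
  sup0 <- map_support(cat_tree, star_like)
  vals0 <- suppressWarnings(as.numeric(sup0$node.label))
  expect_true(all(vals0[!is.na(vals0)] >= 0))
})

test_that("collapse contracts support <= 50 and keeps 51 (boundary rule)", {
  txt <- "((a:1,b:1)50:1,(c:1,d:1)51:1,e:1);"
  tr <- ape::read.tree(text = txt)
  col <- collapse_low_support(tr, 50)
  # the 50-support edge is gone, the 51-support edge retained
  expect_equal(col$Nnode, tr$Nnode - 1)
  expect_true("51" %in% col$node.label)
  expect_false("50" %in% col$node.label)
  expect_setequal(col$tip.label, tr$tip.label)
  # tree with all supports at 100 is unchanged
  txt2 <- "((a:1,b:1)100:1,(c:1,d:1)100:1,e:1);"
  tr2 <- ape::read.tree(text = txt2)
  col2 <- collapse_low_support(tr2, 50)
  expect_equal(col2$Nnode, tr2$Nnode)
  expect_equal(as.numeric(ape::dist.topo(col2, tr2)), 0)
})

test_that("collapsing never drops leaves nor adds internal edges", {
  set.seed(33)
  for (i in 1:5) {
    tr <- ape::rtree(8)
    tr$node.label <- as.character(sample(0:100, tr$Nnode, TRUE))
    col <- collapse_low_support(tr, 50)
    expect_setequal(col$tip.label, tr$tip.label)
    expect_lte(col$Nnode, tr$Nnode)
  }
})

test_that("outgroup rooting works for valid outgroups and fails loudly otherwise", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,(e:1,f:1):1);")
  r1 <- root_with_outgroup(tr, "e")
  expect_true(ape::is.rooted(r1))
  r2 <- root_with_outgroup(tr, c("e", "f"))
  expect_true(ape::is.rooted(r2))
  expect_true(ape::is.monophyletic(r2, c("e", "f")))
  expect_error(root_with_outgroup(tr, c("a", "c")), "monophyletic")
  expect_error(root_with_outgroup(tr, "zz"), "not in tree")
})
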