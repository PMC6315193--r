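test_that("genome fragmentation follows the window and keep rules", {
  set.seed(20)
  g <- mk_genome("a", rand_seq(5100))
  expect_length(fragment_genome(g), 5)
  expect_true(all(nchar(fragment_genome(g)) == 1020))

  g2 <- mk_genome("b", rand_seq(5200))
  fr2 <- fragment_genome(g2)
  expect_length(fr2, 6)                      # 5 full + one 100-base trailer
  expect_equal(unname(nchar(fr2)), c(rep(1020, 5), 100))

  g3 <- mk_genome("c", rand_seq(5199))
  expect_length(fragment_genome(g3), 5)      # 99-base trailer discarded
  expect_length(fragment_genome(mk_genome("d", rand_seq(99))), 0)
})

test_that("POCP is exact integer arithmetic from the printed formula", {
  expect_identical(compute_pocp(list(count = 1000), list(count = 500), 300),
                   40)
  expect_identical(compute_pocp(list(count = 7), list(count = 7), 0), 0)
  expect_identical(compute_pocp(list(count = 12), list(count = 12), 12), 100)
  expect_error(compute_pocp(list(count = 10), list(count = 5), 6),
               "consistency")
})

test_that("ANI is 100 for identical genomes and absent for unrelated ones", {
  set.seed(21)
  g <- mk_genome("a", rand_seq(12000))
  self <- compute_ani(g, genome_record("b", g$contigs))
  expect_equal(self$ani, 100)
  r1 <- mk_genome("r1", rand_seq(12000))
  r2 <- mk_genome("r2", rand_seq(12000))
  expect_true(is.na(compute_ani(r1, r2)$ani))
})

test_that("ANI recovers the realized substitution fraction (mutation-log oracle)", {
  set.seed(22)
  anc <- rand_seq(30000)
  mut <- mutate_seq(anc, 0.02)
  realized <- string_divergence(anc, mut$seq)
  a <- mk_genome("a", anc); b <- mk_genome("b", mut$seq)
  ani <- compute_ani(a, b)
  expect_lt(abs(ani$ani - 100 * (1 - realized)), 0.3)
  # symmetric by construction, exactly
  expect_identical(compute_ani(a, b)$ani, compute_ani(b, a)$ani)
})

test_that("ANI is invariant under contig order and robust to 50% incompleteness", {
  set.seed(23)
  c1 <- rand_seq(6000); c2 <- rand_seq(6000)
  g12 <- genome_record("a", c(x = c1, y = c2))
  g21 <- genome_record("b", c(y = c2, x = c1))
  expect_equal(compute_ani(g12, g21)$ani, 100)
  # clonal pair, one genome halved: ANI moves by < 1 point
  full <- genome_record("full", c(x = c1, y = c2))
  half <- genome_record("half", c(x = c1))
  expect_lt(abs(compute_ani(full, half)$ani - 100), 1)
})

test_that("AAI and ortholog count recover planted proteome divergence", {
  set.seed(24)
  pool <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")
  genes <- replicate(40, paste(sample(pool, 250, TRUE), collapse = ""))
  mut_aa <- function(s, f) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < f)
    if (length(hit)) {
      idx <- match(ch[hit], pool)
      ch[hit] <- pool[((idx - 1L + sample.int(19L, length(hit), TRUE))
                       %% 20L) + 1L]
    }
    paste(ch, collapse = "")
  }
  evolved <- vapply(genes, mut_aa, "", f = 0.20)
  realized_id <- mean(vapply(seq_along(genes), function(i)
    1 - string_divergence(genes[i], evolved[i]), numeric(1)))
  pa <- mk_proteome("A", setNames(genes, paste0("a", seq_along(genes))))
  pb <- mk_proteome("B", setNames(evolved, paste0("b", seq_along(genes))))
  res <- compute_aai(pa, pb)
  expect_equal(res$orthologs, 40)
  expect_lt(abs(res$aai - 100 * realized_id), 1.0)
  # zero-homology proteomes: AAI absent with zero orthologs
  r1 <- mk_proteome("r1", setNames(
    replicate(10, paste(sample(pool, 250, TRUE), collapse = "")),
    paste0("x", 1:10)))
  r2 <- mk_proteome("r2", setNames(
    replicate(10, paste(sample(pool, 250, TRUE), collapse = "")),
    paste0("y", 1:10)))
  none <- compute_aai(r1, r2)
  expect_true(is.na(none$aai))
  expect_equal(none$orthologs, 0)
})

test_that("whole-genome distance is zero at self, symmetric, capped without HSPs", {
  set.seed(25)
  g <- mk_genome("a", rand_seq(20000))
  expect_equal(gbdp_distance(g, g), 0)
  b <- mk_genome("b", mutate_seq(g$contigs[[1]], 0.05)$seq)
  expect_identical(gbdp_distance(g, b), gbdp_distance(b, g))
  r <- mk_genome("r", rand_seq(20000))
  d <- gbdp_distance(g, r)
  expect_equal(as.numeric(d), pd_constants()$gbdp_max_distance[["d5"]])
  expect_true(isTRUE(attr(d, "capped")))
})

test_that("greedy trimming never double-counts aligned columns", {
  set.seed(26)
  core <- rand_seq(4000)
  # a genome with a duplicated segment produces overlapping subject HSPs
  dup <- paste0(core, substr(core, 1001, 3000))
  a <- mk_genome("a", core)
  b <- mk_genome("b", dup)
  hs <- gbdp_hsps(a, b)
  expect_gt(nrow(hs), 0)
  expect_lte(sum(hs$length), a$total_length + 60)
  expect_true(all(hs$identities <= hs$length))
})

test_that("distance ladder is strictly monotone and dDDH strictly decreasing", {
  set.seed(27)
  anc <- rand_seq(30000)
  g0 <- mk_genome("anc", anc)
  ani <- c(); d5 <- c()
  for (f in c(0.01, 0.05, 0.10)) {
    gm <- mk_genome(paste0("f", f), mutate_seq(anc, f)$seq)
    ani <- c(ani, compute_ani(g0, gm)$ani)
    d5 <- c(d5, as.numeric(gbdp_distance(g0, gm)))
  }
  expect_true(all(diff(ani) < 0))
  expect_true(all(diff(d5) > 0))
  dd <- distance_to_dddh(c(0, 0.01, 0.05, 0.1, 0.3))
  expect_true(all(diff(dd) < 0))
  expect_gt(dd[1], 99)
  expect_true(all(dd > 0 & dd < 100))
})

test_that("all_pairwise covers every unordered pair with symmetric matrices", {
  set.seed(28)
  anc <- rand_seq(8000)
  genomes <- list(mk_genome("g1", anc),
                  mk_genome("g2", mutate_seq(anc, 0.02)$seq),
                  mk_genome("g3", mutate_seq(anc, 0.10)$seq))
  ps <- all_pairwise(genomes)
  expect_equal(nrow(ps$pairs), 3)
  for (idx in c("ani", "dddh", "gbdp_d5", "gc_diff")) {
    m <- index_matrix(ps, idx)
    expect_identical(m, t(m))
  }
  expect_true(all(diag(index_matrix(ps, "ani")) == 100))
  expect_true(all(diag(index_matrix(ps, "gbdp_d5")) == 0))
  # failures never abort the batch: an all-N genome records NA gc_diff
  genomes4 <- c(genomes, list(mk_genome("g4", strrep("N", 8000))))
  expect_warning(ps4 <- all_pairwise(genomes4), NA)
  expect_equal(nrow(ps4$pairs), 6)
})

test_that("index matrices and pair table are written as TSV artifacts", {
  set.seed(29)
  anc <- rand_seq(6000)
  genomes <- list(mk_genome("g1", anc),
                  mk_genome("g2", mutate_seq(anc, 0.03)$seq))
  ps <- all_pairwise(genomes)
  dir <- tempfile()
  write_index_matrices(ps, dir)
  expect_true(all(file.exists(file.path(
    dir, c("ani.tsv", "dddh.tsv", "gbdp_dist.tsv", "gc.tsv",
           "pairs.tsv")))))
  m <- read.delim(file.path(dir, "ani.tsv"), check.names = FALSE)
  expect_equal(m$id, c("g1", "g2"))
})
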