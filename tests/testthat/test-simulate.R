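test_that("ancestor simulation hits the G+C target and is seed-deterministic", {
  g <- simulate_ancestor(1e5, gc_target = 50, seed = 5)
  expect_lt(abs(gc_content(g) - 50), 0.5)
  g0 <- simulate_ancestor(2000, gc_target = 0, seed = 5)
  expect_true(grepl("^[AT]+$", g0$contigs[[1]]))
  g1 <- simulate_ancestor(5000, gc_target = 64, seed = 9)
  g2 <- simulate_ancestor(5000, gc_target = 64, seed = 9)
  expect_identical(g1$contigs, g2$contigs)
  expect_lt(abs(gc_content(g1) - 64), 2)
})

test_that("evolution without mutation pressure is the identity", {
  g <- simulate_ancestor(3000, seed = 6)
  e <- evolve_genome(g, sub_fraction = 0, indel_rate = 0, seed = 1)
  expect_identical(unname(e$contigs), unname(g$contigs))
  expect_equal(nrow(attr(e, "mutation_log")), 0)
  expect_equal(attr(e, "realized_sub_fraction"), 0)
})

test_that("realized substitution fraction concentrates around the target", {
  g <- simulate_ancestor(1e5, seed = 7)
  e <- evolve_genome(g, sub_fraction = 0.05, indel_rate = 0, seed = 2)
  realized <- attr(e, "realized_sub_fraction")
  expect_lt(abs(realized - 0.05), 0.003)
  # the log agrees with a direct sequence comparison
  direct <- string_divergence(g$contigs[[1]], e$contigs[[1]])
  expect_equal(realized, direct)
})

test_that("indel events change length and are logged", {
  g <- simulate_ancestor(20000, seed = 8)
  e <- evolve_genome(g, sub_fraction = 0, indel_rate = 1e-3,
                     mean_indel_len = 3, seed = 3)
  log <- attr(e, "mutation_log")
  expect_gt(nrow(log), 0)
  expect_true(all(log$type %in% c("ins", "del")))
  delta <- sum(log$len[log$type == "ins"]) - sum(log$len[log$type == "del"])
  expect_equal(e$total_length, g$total_length + delta)
})

test_that("clade sets have the planted structure and bookkeeping", {
  p <- sim_params(seed = 11, n_genera = 2L, species_per_genus = 2L,
                  genomes_per_species = 2L, genome_length = 10000L,
                  n_genes = 40L)
  sim <- simulate_clade_set(p)
  expect_length(sim$genomes, 8)
  expect_length(sim$proteomes, 8)
  expect_equal(unname(table(sim$truth$genus_partition)), c(4L, 4L),
               ignore_attr = TRUE)
  expect_equal(sort(unname(table(sim$truth$species_partition))),
               rep(2L, 4), ignore_attr = TRUE)
  expect_setequal(sim$truth$true_tree$tip.label, names(sim$genomes))
  # same seed reproduces the set exactly
  sim2 <- simulate_clade_set(p)
  expect_identical(sim$genomes$G1S1R1$contigs, sim2$genomes$G1S1R1$contigs)
})

test_that("tier divergences order as planted", {
  sim <- simulate_clade_set(sim_params(seed = 12, genome_length = 20000L,
                                       n_genes = 50L))
  same_sp <- realized_divergence(sim$truth, "G1S1R1", "G1S1R2")
  same_ge <- realized_divergence(sim$truth, "G1S1R1", "G1S2R1")
  diff_ge <- realized_divergence(sim$truth, "G1S1R1", "G2S1R1")
  expect_lt(same_sp, 0.02)
  expect_gt(same_ge, same_sp)
  expect_gt(diff_ge, same_ge)
  # within-species pairs stay in ANI same-species territory
  expect_gt(100 * (1 - same_sp), 98)
})

test_that("truth oracle gives exact self values and the POCP formula", {
  sim <- simulate_clade_set(sim_params(seed = 13, genome_length = 10000L,
                                       n_genes = 40L))
  ids <- names(sim$genomes)
  ti <- truth_index(sim$truth, ids[1], ids[1])
  expect_equal(ti$expected_ani, 100)
  expect_equal(ti$expected_aai, 100)
  expect_equal(ti$expected_pocp, 100)
  # cross pair: POCP from the construction's S, T1, T2
  t12 <- truth_index(sim$truth, ids[1], ids[3])
  S <- length(intersect(sim$truth$gene_sets[[ids[1]]],
                        sim$truth$gene_sets[[ids[3]]]))
  T1 <- length(sim$truth$gene_sets[[ids[1]]])
  T2 <- length(sim$truth$gene_sets[[ids[3]]])
  expect_identical(t12$expected_pocp, 200 * S / (T1 + T2))
})

test_that("pipeline estimators match the truth oracle on a small clade set", {
  sim <- simulate_clade_set(sim_params(seed = 14, genome_length = 20000L,
                                       n_genes = 60L, indel_rate = 0))
  a <- "G1S1R1"; b <- "G1S2R1"
  ti <- truth_index(sim$truth, a, b)
  ani <- compute_ani(sim$genomes[[a]], sim$genomes[[b]])
  expect_lt(abs(ani$ani - ti$expected_ani), 0.5)
  aai <- compute_aai(sim$proteomes[[a]], sim$proteomes[[b]])
  expect_lt(abs(aai$aai - ti$expected_aai), 1.0)
  S <- length(intersect(sim$truth$gene_sets[[a]], sim$truth$gene_sets[[b]]))
  expect_equal(aai$orthologs, S)
  pocp <- compute_pocp(sim$proteomes[[a]], sim$proteomes[[b]],
                       aai$orthologs)
  expect_identical(pocp, ti$expected_pocp)
})

test_that("clade sets round-trip to disk with sample sheet and truth files", {
  sim <- simulate_clade_set(sim_params(seed = 15, genome_length = 5000L,
                                       n_genes = 20L))
  dir <- tempfile()
  write_clade_set(sim, dir)
  expect_true(file.exists(file.path(dir, "samples.tsv")))
  expect_true(file.exists(file.path(dir, "true_tree.nwk")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_equal(nrow(sheet), 12)
  g <- read_genome_fasta(sheet$genome_path[1], id = sheet$id[1])
  expect_identical(unname(g$contigs),
                   unname(sim$genomes[[sheet$id[1]]]$contigs))
})
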