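# build a pairs data frame from named per-pair index values
mk_pairs <- function(ids, set = list()) {
  combs <- utils::combn(ids, 2)
  df <- data.frame(genome_a = combs[1, ], genome_b = combs[2, ],
                   ani = 60, aai = 50, dddh = 1, gc_diff = 5,
                   stringsAsFactors = FALSE)
  for (key in names(set)) {
    ab <- strsplit(key, "~")[[1]]
    i <- which((df$genome_a == ab[1] & df$genome_b == ab[2]) |
               (df$genome_a == ab[2] & df$genome_b == ab[1]))
    for (col in names(set[[key]])) df[[col]][i] <- set[[key]][[col]]
  }
  df
}

test_that("monophyly test agrees with exhaustive clade enumeration", {
  set.seed(40)
  for (rep in 1:10) {
    tr <- ape::rtree(6)
    tips <- tr$tip.label
    for (size in 1:6) {
      subsets <- utils::combn(tips, size, simplify = FALSE)
      for (ss in subsets) {
        expect_equal(is_monophyletic(tr, ss), oracle_monophyletic(tr, ss),
                     info = paste(ss, collapse = ","))
      }
    }
  }
  tr <- ape::rtree(6)
  expect_true(is_monophyletic(tr, tr$tip.label[1]))
  expect_true(is_monophyletic(tr, tr$tip.label))
  expect_error(is_monophyletic(tr, "missing_tip"), "unknown")
})

test_that("species clustering applies the dDDH AND ANI AND G+C conjunction", {
  tr <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,(e:1,f:1):2);")
  pairs <- mk_pairs(letters[1:6], list(
    # strong same-species signal: merged
    "a~b" = list(dddh = 89, ani = 99, gc_diff = 0.2),
    # borderline ANI but failing dDDH: stays split (the conjunction)
    "c~d" = list(dddh = 63, ani = 96, gc_diff = 0.2),
    # passing dDDH but failing ANI: stays split
    "e~f" = list(dddh = 78, ani = 61, gc_diff = 0.2)))
  cl <- infer_species_clusters(tr, pairs)
  members <- lapply(cl, `[[`, "members")
  expect_true(list(c("a", "b")) %in% members ||
              any(vapply(members, identical, logical(1), c("a", "b"))))
  expect_false(any(vapply(members, identical, logical(1), c("c", "d"))))
  expect_false(any(vapply(members, identical, logical(1), c("e", "f"))))
  # every genome in exactly one cluster
  expect_setequal(unlist(members), letters[1:6])
  expect_equal(anyDuplicated(unlist(members)), 0)
})

test_that("species clustering enforces monophyly and G+C agreement", {
  # a and d pass indexes but are not monophyletic: both stay singletons
  tr <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,e:3);")
  pairs <- mk_pairs(letters[1:5],
                    list("a~d" = list(dddh = 95, ani = 99, gc_diff = 0.1)))
  cl <- infer_species_clusters(tr, pairs)
  expect_true(all(lengths(lapply(cl, `[[`, "members")) == 1))
  # G+C difference of 1.0 or more blocks an otherwise passing pair
  pairs2 <- mk_pairs(letters[1:5],
                     list("a~b" = list(dddh = 95, ani = 99, gc_diff = 1.0)))
  cl2 <- infer_species_clusters(tr, pairs2)
  expect_true(all(lengths(lapply(cl2, `[[`, "members")) == 1))
})

test_that("genus clustering finds maximal monophyletic clades above the AAI floor", {
  tr <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,((d:1,e:1):1,f:1):1);")
  pairs <- mk_pairs(letters[1:6])
  within <- list(aai = 85); between <- list(aai = 65)
  for (p in c("a~b", "a~c", "b~c", "d~e", "d~f", "e~f"))
    pairs <- local({ i <- p; mk <- pairs
      ab <- strsplit(i, "~")[[1]]
      j <- which((mk$genome_a == ab[1] & mk$genome_b == ab[2]) |
                 (mk$genome_a == ab[2] & mk$genome_b == ab[1]))
      mk$aai[j] <- 85; mk })
  cl <- infer_genus_clusters(tr, pairs)
  members <- lapply(cl, `[[`, "members")
  expect_setequal(members, list(c("a", "b", "c"), c("d", "e", "f")))
  # raising the within-clade AAI by a pair below threshold splits that clade
  pairs$aai[pairs$genome_a == "a" & pairs$genome_b == "b"] <- 69
  cl2 <- infer_genus_clusters(tr, pairs)
  members2 <- lapply(cl2, `[[`, "members")
  expect_false(any(vapply(members2, function(m) "a" %in% m && "b" %in% m,
                          logical(1))))
})

test_that("genomes without AAI become flagged singletons in genus clustering", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,x:1):1);")
  pairs <- mk_pairs(c("a", "b", "c", "x"))
  pairs$aai <- 85
  pairs$aai[pairs$genome_a == "x" | pairs$genome_b == "x"] <- NA
  cl <- infer_genus_clusters(tr, pairs)
  singles <- Filter(function(c) identical(c$members, "x"), cl)
  expect_length(singles, 1)
  expect_true("no_aai" %in% singles[[1]]$flags)
})

test_that("the species partition refines the genus partition", {
  set.seed(41)
  sim <- simulate_clade_set(sim_params(seed = 41, genome_length = 20000L,
                                       n_genes = 80L))
  ps <- all_pairwise(sim$genomes, sim$proteomes)
  tree <- phangorn::midpoint(infer_tree(index_matrix(ps, "gbdp_d5")))
  ge <- infer_genus_clusters(tree, ps)
  sp <- infer_species_clusters(tree, ps, genus_clusters = ge)
  ge_members <- lapply(ge, `[[`, "members")
  ids <- names(sim$genomes)
  expect_setequal(unlist(ge_members), ids)
  for (s in sp) {
    inside <- vapply(ge_members, function(g) all(s$members %in% g),
                     logical(1))
    expect_equal(sum(inside), 1)
    expect_true(is_monophyletic(tree, s$members))
  }
})

test_that("name resolution follows page, date and type-species priority", {
  md <- read.delim(system.file("extdata", "nomenclature_examples.tsv",
                               package = "phylodelim"),
                   stringsAsFactors = FALSE)
  # same publication: priority by page order
  cl <- resolve_names(list(
    list(rank = "species", members = c("marinus_T", "whittenburyi_T"),
         monophyletic = TRUE, resolved_name = NA, name_basis = "unchanged",
         synonyms = list(), flags = character())), md)
  expect_equal(cl[[1]]$resolved_name, "Methylobacter marinus")
  expect_equal(cl[[1]]$name_basis, "page_order")
  syn <- cl[[1]]$synonyms[[1]]
  expect_equal(unname(syn["junior_name"]), "Methylobacter whittenburyi")
  acts <- attr(cl, "actions")
  expect_equal(acts$action[acts$genome_id == "whittenburyi_T"],
               "synonymized")
  expect_equal(acts$action[acts$genome_id == "marinus_T"], "unchanged")

  # earlier publication date wins
  cl2 <- resolve_names(list(
    list(rank = "species", members = c("methanica_T", "denitrificans_T"),
         monophyletic = TRUE, resolved_name = NA, name_basis = "unchanged",
         synonyms = list(), flags = character())), md)
  expect_equal(cl2[[1]]$resolved_name, "Methylomonas methanica")
  expect_equal(cl2[[1]]$name_basis, "publication_date")

  # type species retained regardless of later date
  cl3 <- resolve_names(list(
    list(rank = "genus", members = c("agile_T", "album_T"),
         monophyletic = TRUE, resolved_name = NA, name_basis = "unchanged",
         synonyms = list(), flags = character())), md)
  expect_equal(cl3[[1]]$resolved_name, "Methylomicrobium agile")
  expect_equal(cl3[[1]]$name_basis, "type_species_priority")
})

test_that("MAG-only clusters get placeholders and unordered ties are flagged", {
  md <- read.delim(system.file("extdata", "nomenclature_examples.tsv",
                               package = "phylodelim"),
                   stringsAsFactors = FALSE)
  cl <- resolve_names(list(
    list(rank = "species", members = c("mag_1", "mag_2"),
         monophyletic = TRUE, resolved_name = NA, name_basis = "unchanged",
         synonyms = list(), flags = character())), md)
  expect_equal(cl[[1]]$name_basis, "placeholder_mag")
  expect_match(cl[[1]]$resolved_name, "unnamed species")
  expect_length(cl[[1]]$synonyms, 0)

  cl2 <- resolve_names(list(
    list(rank = "species", members = c("noyear_a", "noyear_b"),
         monophyletic = TRUE, resolved_name = NA, name_basis = "unchanged",
         synonyms = list(), flags = character())), md)
  expect_equal(cl2[[1]]$name_basis, "unresolved")
  expect_true("priority_unresolved" %in% cl2[[1]]$flags)
})

test_that("name resolution is idempotent when the name already has priority", {
  md <- data.frame(id = c("x1", "x2"), name = c("Alpha one", "Alpha one"),
                   is_type_species = FALSE, validly_published = TRUE,
                   publication_year = c(1990, 1990), page_rank = c(1, 1),
                   stringsAsFactors = FALSE)
  cl <- resolve_names(list(
    list(rank = "species", members = c("x1", "x2"), monophyletic = TRUE,
         resolved_name = NA, name_basis = "unchanged",
         synonyms = list(), flags = character())), md)
  expect_equal(cl[[1]]$resolved_name, "Alpha one")
  acts <- attr(cl, "actions")
  expect_true(all(acts$action == "unchanged"))
})

test_that("phyly classification distinguishes mono-, para- and polyphyly", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  labs <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  rep1 <- detect_phyly_problems(tr, labs)
  expect_true(all(rep1$status == "monophyletic"))

  tr2 <- ape::read.tree(text = "((a1:1,(a2:1,b1:1):1):1,b2:1);")
  labs2 <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  rep2 <- detect_phyly_problems(tr2, labs2)
  expect_false(rep2$status[rep2$label == "A"] == "monophyletic")
  expect_equal(rep2$status[rep2$label == "B"], "polyphyletic")

  # an unnamed genome nested inside a label's span gives paraphyly
  tr3 <- ape::read.tree(text = "((a1:1,(a2:1,m1:1):1):1,b1:1);")
  labs3 <- c(a1 = "A", a2 = "A", m1 = NA, b1 = "B")
  rep3 <- detect_phyly_problems(tr3, labs3)
  expect_equal(rep3$status[rep3$label == "A"], "paraphyletic")
})

test_that("phyly classification matches a brute-force checker on random labeled trees", {
  set.seed(42)
  brute <- function(tree, labs) {
    out <- list()
    for (lb in unique(labs[!is.na(labs)])) {
      members <- names(labs)[!is.na(labs) & labs == lb]
      if (length(members) < 2) next
      clades <- enumerate_clades(tree)
      mono <- any(vapply(clades, function(cl)
        identical(sort(cl), sort(members)), logical(1)))
      if (mono) { out[[lb]] <- "monophyletic"; next }
      mrca <- ape::getMRCA(tree, members)
      inside <- sort(ape::extract.clade(tree, mrca)$tip.label)
      foreign <- setdiff(inside, members)
      named_foreign <- foreign[!is.na(labs[foreign])]
      single_entry <- length(foreign) == 1 ||
        any(vapply(clades, function(cl)
          identical(sort(cl), sort(foreign)), logical(1)))
      out[[lb]] <- if (length(named_foreign) == 0 || single_entry)
        "paraphyletic" else "polyphyletic"
    }
    out
  }
  for (rep in 1:10) {
    tr <- ape::rtree(8)
    labs <- setNames(sample(c("A", "A", "A", "B", "B", "B", "C", NA)),
                     tr$tip.label)
    got <- detect_phyly_problems(tr, labs)
    want <- brute(tr, labs)
    for (lb in names(want))
      expect_equal(got$status[got$label == lb], want[[lb]], info = lb)
  }
})

test_that("new genomes are classified against reference clusters", {
  set.seed(43)
  anc <- rand_seq(15000)
  ga <- mk_genome("refA", anc)
  gb <- mk_genome("refB", mutate_seq(anc, 0.20)$seq)
  state <- list(
    genomes = list(refA = ga, refB = gb),
    proteomes = NULL,
    species_clusters = list(
      list(rank = "species", members = "refA"),
      list(rank = "species", members = "refB")),
    genus_clusters = list(
      list(rank = "genus", members = c("refA", "refB"))),
    thresholds = delimitation_thresholds())
  # identical query lands in refA's species cluster
  q <- genome_record("query", ga$contigs)
  res <- classify_new_genome(q, state)
  expect_equal(res$verdict, "assigned_species")
  expect_equal(res$species_cluster, 1)
  # strongly diverged query is a novel lineage
  q2 <- mk_genome("far", mutate_seq(anc, 0.10)$seq)
  res2 <- classify_new_genome(q2, state)
  expect_false(res2$verdict == "assigned_species")
})
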