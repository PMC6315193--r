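#' Synthetic genome sets with planted taxonomy
#'
#' Generates nucleotide genomes and proteomes descending from a known
#' genus/species tree with controlled substitution and indel divergence,
#' controlled G+C and controlled gene sharing, together with a complete
#' truth object (tree, partitions, homology maps) so every pipeline stage
#' can be validated against known answers. Substitution fractions are
#' per-branch realized targets, not rates: the truth oracle recomputes the
#' realized divergence of every pair directly from the simulated homology
#' maps, so recovery tests are exact.
#'
#' @name synthetic_data
NULL

NT_BASES <- c("A", "C", "G", "T")
AA_BASES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V")

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulation parameters
#'
#' The defaults define the package's standard desk-scale clade set: 3
#' genera of 2 species of 2 genomes (12 genomes), 100-kb genomes at 50
#' percent G+C, nucleotide divergence tiers of 1 / 15 / 25 percent
#' (within species / within genus / between genera), amino-acid divergence
#' tiers of 1 / 15 / 40 percent, a light indel process, and 500 genes of
#' 300 residues with 90 percent gene sharing within genera.
#'
#' @param seed Integer seed; all simulation randomness flows from it.
#' @param n_genera,species_per_genus,genomes_per_species Clade structure.
#' @param genome_length Bases per genome (ancestor length).
#' @param gc_target Percent G+C of the ancestor.
#' @param within_species_sub,within_genus_sub,between_genus_sub Pairwise
#'   nucleotide substitution targets per tier (fractions; must increase).
#' @param indel_rate Per-site Poisson rate of indel events per branch.
#' @param mean_indel_len Mean indel length (geometric).
#' @param n_genes,gene_length Proteome size.
#' @param shared_gene_fraction_within_genus Expected fraction of genes
#'   shared by two genomes of the same genus.
#' @param protein_sub_within_species,protein_sub_within_genus,protein_sub_between_genus
#'   Amino-acid substitution targets per tier.
#' @return Named list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_genera = 3L, species_per_genus = 2L,
                       genomes_per_species = 2L,
                       genome_length = 100000L, gc_target = 50,
                       within_species_sub = 0.01,
                       within_genus_sub = 0.15,
                       between_genus_sub = 0.25,
                       indel_rate = 3e-5, mean_indel_len = 3,
                       n_genes = 500L, gene_length = 300L,
                       shared_gene_fraction_within_genus = 0.9,
                       protein_sub_within_species = 0.01,
                       protein_sub_within_genus = 0.15,
                       protein_sub_between_genus = 0.40) {
  p <- as.list(environment())
  stopifnot(p$within_species_sub < p$within_genus_sub,
            p$within_genus_sub < p$between_genus_sub,
            p$protein_sub_within_species < p$protein_sub_within_genus,
            p$protein_sub_within_genus <= p$protein_sub_between_genus,
            p$gc_target >= 0, p$gc_target <= 100)
  structure(p, class = c("sim_params", "list"))
}

#' Simulate an ancestral genome
#'
#' I.i.d. bases with `P(G) = P(C) = gc_target / 200` and the remainder
#' split equally between A and T.
#'
#' @param length Genome length in bases.
#' @param gc_target Percent G+C.
#' @param seed Integer seed.
#' @param id Genome id for the returned record.
#' @return A `genome_record` with one contig.
#' @export
simulate_ancestor <- function(length, gc_target = 50, seed = 1L,
                              id = "ancestor") {
  stopifnot(length > 0)
  chars <- with_seed(seed, {
    p_gc <- gc_target / 200
    p_at <- (100 - gc_target) / 200
    sample(NT_BASES, length, replace = TRUE,
           prob = c(p_at, p_gc, p_gc, p_at))
  })
  genome_record(id, paste(chars, collapse = ""))
}

# core mutation step on a character vector plus root-coordinate map
evolve_chars <- function(chars, map, sub_fraction, indel_rate,
                         mean_indel_len, alphabet = NT_BASES) {
  L <- length(chars)
  log_sub <- NULL
  if (sub_fraction > 0 && L > 0) {
    hit <- which(runif(L) < sub_fraction)
    if (length(hit)) {
      idx <- match(chars[hit], alphabet)
      # unmapped symbols (ambiguity codes) are left untouched
      ok <- !is.na(idx)
      hit <- hit[ok]; idx <- idx[ok]
      k <- length(alphabet)
      off <- sample.int(k - 1L, length(hit), replace = TRUE)
      new <- alphabet[((idx - 1L + off) %% k) + 1L]
      log_sub <- data.frame(type = "sub", pos = map[hit],
                            ref = chars[hit], alt = new, len = 1L,
                            stringsAsFactors = FALSE)
      chars[hit] <- new
    }
  }
  log_ind <- NULL
  if (indel_rate > 0 && L > 0) {
    n_ev <- rpois(1L, indel_rate * L)
    if (n_ev > 0) {
      rows <- vector("list", n_ev)
      for (e in seq_len(n_ev)) {
        len <- rgeom(1L, 1 / mean_indel_len) + 1L
        insert <- runif(1) < 0.5
        Lc <- length(chars)
        if (Lc == 0L) break
        pos <- sample.int(Lc, 1L)
        if (insert) {
          ins <- sample(alphabet, len, replace = TRUE)
          chars <- append(chars, ins, after = pos)
          map <- append(map, rep(NA_integer_, len), after = pos)
          rows[[e]] <- data.frame(type = "ins", pos = map[pos],
                                  ref = "", alt = paste(ins, collapse = ""),
                                  len = len, stringsAsFactors = FALSE)
        } else {
          del <- pos:min(Lc, pos + len - 1L)
          rows[[e]] <- data.frame(type = "del", pos = map[pos],
                                  ref = paste(chars[del], collapse = ""),
                                  alt = "", len = length(del),
                                  stringsAsFactors = FALSE)
          chars <- chars[-del]
          map <- map[-del]
        }
      }
      log_ind <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    }
  }
  list(chars = chars, map = map,
       log = rbind(log_sub, log_ind))
}

#' Evolve a genome by substitutions and indels
#'
#' Each site is substituted independently with probability `sub_fraction`
#' to a uniformly chosen different base; indel events arrive as a Poisson
#' process with geometric lengths. Every event is recorded in the mutation
#' log; the realized substitution fraction is attached as an attribute.
#'
#' @param genome A `genome_record` (multi-contig supported; contigs evolve
#'   independently).
#' @param sub_fraction Per-site substitution probability.
#' @param indel_rate Per-site indel event rate.
#' @param mean_indel_len Mean indel length.
#' @param seed Integer seed.
#' @param id Id for the evolved record.
#' @return A `genome_record` with attributes `mutation_log` (data frame)
#'   and `realized_sub_fraction`.
#' @export
evolve_genome <- function(genome, sub_fraction, indel_rate = 0,
                          mean_indel_len = 3, seed = 1L,
                          id = paste0(genome$id, "_evolved")) {
  stopifnot(sub_fraction >= 0, sub_fraction <= 1)
  res <- with_seed(seed, {
    contigs <- character(length(genome$contigs))
    logs <- list()
    n_sub <- 0; n_sites <- 0
    for (ci in seq_along(genome$contigs)) {
      chars <- strsplit(genome$contigs[[ci]], "")[[1]]
      ev <- evolve_chars(chars, seq_along(chars), sub_fraction,
                         indel_rate, mean_indel_len)
      contigs[ci] <- paste(ev$chars, collapse = "")
      if (!is.null(ev$log)) logs[[length(logs) + 1L]] <- ev$log
      if (!is.null(ev$log))
        n_sub <- n_sub + sum(ev$log$type == "sub")
      n_sites <- n_sites + length(chars)
    }
    list(contigs = contigs, log = if (length(logs)) do.call(rbind, logs)
         else data.frame(type = character(), pos = integer(),
                         ref = character(), alt = character(),
                         len = integer(), stringsAsFactors = FALSE),
         realized = n_sub / n_sites)
  })
  names(res$contigs) <- names(genome$contigs)
  g <- genome_record(id, res$contigs, genome$metadata)
  attr(g, "mutation_log") <- res$log
  attr(g, "realized_sub_fraction") <- res$realized
  g
}

# caterpillar genus backbone: (((g1,g2):eps,g3):eps,...); each genus stem
# then carries the between-genus tier divergence
genus_backbone_newick <- function(ids, stem, eps) {
  node <- sprintf("%s:%g", ids[1], stem)
  if (length(ids) == 1) return(node)
  node <- sprintf("(%s,%s:%g)", node, ids[2], stem)
  if (length(ids) > 2) {
    for (i in 3:length(ids))
      node <- sprintf("(%s:%g,%s:%g)", node, eps, ids[i], stem)
  }
  node
}

#' Simulate a clade set with planted genus/species taxonomy
#'
#' An ancestor genome (and proteome) is evolved down a genus/species/genome
#' tree whose branch lengths realize the tier divergences of `params`:
#' two genomes of one species differ by about `within_species_sub`, two
#' species of one genus by about `within_genus_sub`, and two genera by
#' about `between_genus_sub` (plus a small backbone increment when more
#' than two genera are simulated). Proteins evolve along the same tree
#' under the protein tiers without indels; each genome independently
#' retains each gene with probability
#' `sqrt(shared_gene_fraction_within_genus)` so two genomes share about
#' the requested fraction.
#'
#' @param params A [sim_params()] object.
#' @return List with `genomes` (named list of `genome_record`),
#'   `proteomes` (named list of `proteome_record`) and `truth` (class
#'   `sim_truth`): `true_tree` (phylo), `genus_partition`,
#'   `species_partition` (named character vectors), `maps` (per-genome
#'   root-coordinate maps), `seqs` (per-genome character vectors),
#'   `prot_seqs`, `gene_sets`, `params`.
#' @export
simulate_clade_set <- function(params = sim_params()) {
  p <- params
  with_seed(p$seed, {
    # ---- tier branch lengths (realized-substitution targets) ----
    b_genome  <- p$within_species_sub / 2
    b_species <- (p$within_genus_sub - p$within_species_sub) / 2
    b_genus   <- (p$between_genus_sub - p$within_genus_sub) / 2
    eps <- if (p$n_genera > 2) 0.01 else 0
    pb_genome  <- p$protein_sub_within_species / 2
    pb_species <- (p$protein_sub_within_genus -
                     p$protein_sub_within_species) / 2
    pb_genus   <- (p$protein_sub_between_genus -
                     p$protein_sub_within_genus) / 2

    anc_chars <- {
      p_gc <- p$gc_target / 200
      p_at <- (100 - p$gc_target) / 200
      sample(NT_BASES, p$genome_length, replace = TRUE,
             prob = c(p_at, p_gc, p_gc, p_at))
    }
    anc_prot <- sample(AA_BASES, p$n_genes * p$gene_length, replace = TRUE)

    genus_ids <- paste0("G", seq_len(p$n_genera))
    genomes <- list(); proteomes <- list()
    maps <- list(); seqs <- list(); prot_seqs <- list(); gene_sets <- list()
    genus_part <- character(); species_part <- character()
    tip_bl <- character()   # newick pieces per genus

    retain_p <- sqrt(p$shared_gene_fraction_within_genus)

    # caterpillar backbone: genera 1 and 2 attach at the first backbone
    # node; each further genus attaches after an extra eps of divergence
    backbone <- list(chars = anc_chars, map = seq_along(anc_chars))
    backbone_prot <- list(chars = anc_prot, map = seq_along(anc_prot))

    for (gi in seq_len(p$n_genera)) {
      if (gi > 2 && eps > 0) {
        backbone <- evolve_chars(backbone$chars, backbone$map, eps,
                                 p$indel_rate, p$mean_indel_len)
        backbone_prot <- evolve_chars(backbone_prot$chars,
                                      backbone_prot$map, eps, 0, 0,
                                      AA_BASES)
      }
      g_ev <- evolve_chars(backbone$chars, backbone$map, b_genus,
                           p$indel_rate, p$mean_indel_len)
      g_prot <- evolve_chars(backbone_prot$chars,
                             seq_along(backbone_prot$chars), pb_genus,
                             0, 0, AA_BASES)
      sp_pieces <- character()
      for (si in seq_len(p$species_per_genus)) {
        s_ev <- evolve_chars(g_ev$chars, g_ev$map, b_species,
                             p$indel_rate, p$mean_indel_len)
        s_prot <- evolve_chars(g_prot$chars, seq_along(anc_prot),
                               pb_species, 0, 0, AA_BASES)
        rep_pieces <- character()
        for (ri in seq_len(p$genomes_per_species)) {
          id <- sprintf("G%dS%dR%d", gi, si, ri)
          r_ev <- evolve_chars(s_ev$chars, s_ev$map, b_genome,
                               p$indel_rate, p$mean_indel_len)
          r_prot <- evolve_chars(s_prot$chars, seq_along(anc_prot),
                                 pb_genome, 0, 0, AA_BASES)
          seqs[[id]] <- r_ev$chars
          maps[[id]] <- r_ev$map
          genomes[[id]] <- genome_record(
            id, paste(r_ev$chars, collapse = ""))
          keep <- which(runif(p$n_genes) < retain_p)
          gene_sets[[id]] <- keep
          prot_mat <- matrix(r_prot$chars, nrow = p$gene_length)
          prots <- apply(prot_mat[, keep, drop = FALSE], 2, paste,
                         collapse = "")
          names(prots) <- paste0(id, "_g", keep)
          prot_seqs[[id]] <- prot_mat
          proteomes[[id]] <- proteome_record(id, prots)
          genus_part[id] <- genus_ids[gi]
          species_part[id] <- sprintf("G%dS%d", gi, si)
          rep_pieces <- c(rep_pieces, sprintf("%s:%g", id, b_genome))
        }
        sp_pieces <- c(sp_pieces,
                       sprintf("(%s):%g", paste(rep_pieces, collapse = ","),
                               b_species))
      }
      tip_bl <- c(tip_bl, sprintf("(%s)", paste(sp_pieces, collapse = ",")))
    }
    nwk <- paste0(genus_backbone_newick(tip_bl, b_genus, eps), ";")
    true_tree <- ape::collapse.singles(ape::read.tree(text = nwk))

    truth <- structure(
      list(true_tree = true_tree,
           genus_partition = genus_part,
           species_partition = species_part,
           maps = maps, seqs = seqs, prot_seqs = prot_seqs,
           gene_sets = gene_sets, params = p),
      class = "sim_truth")
    list(genomes = genomes, proteomes = proteomes, truth = truth)
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>", length(x$maps), "genomes,",
      length(unique(x$species_partition)), "species,",
      length(unique(x$genus_partition)), "genera\n")
  invisible(x)
}

#' Realized pairwise nucleotide divergence from the simulation truth
#'
#' Compares the two genomes at sites tracked to the same ancestral
#' coordinate (insertions excluded); no alignment involved.
#'
#' @param truth A `sim_truth`.
#' @param a,b Genome ids.
#' @return Fraction of differing homologous sites.
#' @export
realized_divergence <- function(truth, a, b) {
  ma <- truth$maps[[a]]; mb <- truth$maps[[b]]
  sa <- truth$seqs[[a]]; sb <- truth$seqs[[b]]
  ia <- which(!is.na(ma))
  pos_b <- match(ma[ia], mb[!is.na(mb)])
  ib_all <- which(!is.na(mb))
  ok <- !is.na(pos_b)
  mean(sa[ia[ok]] != sb[ib_all[pos_b[ok]]])
}

#' Expected similarity indexes for a simulated pair (oracle)
#'
#' Computed directly from the simulation bookkeeping: expected ANI from the
#' realized substitution fraction at homologous sites, expected AAI from
#' the realized amino-acid identity of shared genes, expected POCP from
#' the retained gene sets. No alignment is involved, so these values are an
#' independent oracle for the estimators.
#'
#' @param truth A `sim_truth`.
#' @param a,b Genome ids.
#' @return List with `expected_ani`, `expected_aai`, `expected_pocp`.
#' @export
truth_index <- function(truth, a, b) {
  div <- realized_divergence(truth, a, b)
  shared <- intersect(truth$gene_sets[[a]], truth$gene_sets[[b]])
  aai <- if (length(shared)) {
    pa <- truth$prot_seqs[[a]][, shared, drop = FALSE]
    pb <- truth$prot_seqs[[b]][, shared, drop = FALSE]
    100 * mean(pa == pb)
  } else NA_real_
  t1 <- length(truth$gene_sets[[a]]); t2 <- length(truth$gene_sets[[b]])
  list(expected_ani = 100 * (1 - div),
       expected_aai = aai,
       expected_pocp = 200 * length(shared) / (t1 + t2))
}

#' Write a simulated clade set to disk
#'
#' FASTA genomes and proteomes, a sample sheet, the true tree (Newick) and
#' a truth summary (JSON) into `dir`.
#'
#' @param sim Result of [simulate_clade_set()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_clade_set <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(sim$genomes)
  gpaths <- file.path(dir, paste0(ids, ".fna"))
  ppaths <- file.path(dir, paste0(ids, ".faa"))
  for (i in seq_along(ids)) {
    write_fasta(sim$genomes[[i]], gpaths[i])
    write_fasta(sim$proteomes[[i]], ppaths[i])
  }
  sheet <- data.frame(id = ids, genome_path = gpaths,
                      proteome_path = ppaths,
                      name = "", is_type_strain = FALSE,
                      is_type_species = FALSE, validly_published = FALSE,
                      publication_year = NA_integer_,
                      page_rank = NA_integer_, is_mag = TRUE,
                      input_genus = unname(
                        sim$truth$genus_partition[ids]),
                      stringsAsFactors = FALSE)
  write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$truth$true_tree, file.path(dir, "true_tree.nwk"))
  jsonlite::write_json(
    list(genus_partition = as.list(sim$truth$genus_partition),
         species_partition = as.list(sim$truth$species_partition),
         params = unclass(sim$truth$params)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
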