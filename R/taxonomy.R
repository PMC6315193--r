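#' Monophyly-constrained genus and species delimitation
#'
#' Turns a rooted genome phylogeny plus pairwise similarity indexes into
#' genus and species clusters under threshold-and-monophyly rules, resolves
#' cluster names by nomenclature priority, and reports paraphyly/polyphyly
#' of the input classification.
#'
#' @name taxonomy_delimitation
NULL

#' Delimitation thresholds
#'
#' Defaults follow common genome-taxonomy practice: genus lower bound of
#' 71 percent AAI (the 50 percent POCP boundary is computed as a diagnostic
#' but never used for delimitation), species bounds of 70 percent dDDH and
#' 95 percent ANI jointly, and a maximum same-species G+C difference of one
#' percentage point.
#'
#' @param aai_genus_min,pocp_genus_min,dddh_species_min,ani_species_min
#'   Percent thresholds.
#' @param gc_diff_species_max Percentage points.
#' @return Named list of thresholds.
#' @export
delimitation_thresholds <- function(aai_genus_min = 71,
                                    pocp_genus_min = 50,
                                    dddh_species_min = 70,
                                    ani_species_min = 95,
                                    gc_diff_species_max = 1.0) {
  th <- list(aai_genus_min = aai_genus_min, pocp_genus_min = pocp_genus_min,
             dddh_species_min = dddh_species_min,
             ani_species_min = ani_species_min,
             gc_diff_species_max = gc_diff_species_max)
  stopifnot(all(unlist(th) >= 0), all(unlist(th) <= 100))
  th
}

#' Is a set of taxa monophyletic?
#'
#' TRUE iff the taxa form a clade of the rooted tree (all descendants of a
#' single node and nothing else). Singletons are clades.
#'
#' @param tree Rooted `phylo`.
#' @param taxa Character vector of tip labels.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, taxa) {
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("unknown taxon id(s): ", paste(unknown, collapse = ", "))
  if (length(taxa) <= 1) return(TRUE)
  if (length(taxa) == length(tree$tip.label)) return(TRUE)
  ape::is.monophyletic(tree, taxa)
}

clade_tips <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

# matrices of the species/genus edge criteria, keyed by genome id
comparison_matrices <- function(comparisons) {
  if (inherits(comparisons, "pairwise_set")) {
    list(ani = index_matrix(comparisons, "ani"),
         aai = index_matrix(comparisons, "aai"),
         dddh = index_matrix(comparisons, "dddh"),
         gc_diff = index_matrix(comparisons, "gc_diff"))
  } else if (is.data.frame(comparisons)) {
    ids <- sort(unique(c(comparisons$genome_a, comparisons$genome_b)))
    mk <- function(col, diag_val) {
      m <- matrix(NA_real_, length(ids), length(ids),
                  dimnames = list(ids, ids))
      diag(m) <- diag_val
      for (i in seq_len(nrow(comparisons))) {
        a <- comparisons$genome_a[i]; b <- comparisons$genome_b[i]
        v <- if (col %in% names(comparisons)) comparisons[[col]][i]
             else NA_real_
        m[a, b] <- m[b, a] <- v
      }
      m
    }
    list(ani = mk("ani", 100), aai = mk("aai", 100),
         dddh = mk("dddh", 100), gc_diff = mk("gc_diff", 0))
  } else stop("comparisons must be a pairwise_set or a pairs data frame")
}

# all unordered pairs within `members` satisfy pred(matrix value)
all_pairs_pass <- function(members, mat, pass) {
  if (length(members) < 2) return(TRUE)
  sub <- mat[members, members, drop = FALSE]
  vals <- sub[upper.tri(sub)]
  !anyNA(vals) && all(pass(vals))
}

# Top-down maximal-clade clustering: starting from `node`, accept the clade
# if every leaf pair inside passes; otherwise recurse into children. Leaves
# that never join a passing clade become singletons.
topdown_clusters <- function(tree, node, pass_fun) {
  tips <- clade_tips(tree, node)
  if (pass_fun(tips)) return(list(tips))
  nt <- length(tree$tip.label)
  if (node <= nt) return(list(tips))
  children <- tree$edge[tree$edge[, 1] == node, 2]
  out <- list()
  for (ch in children) out <- c(out, topdown_clusters(tree, ch, pass_fun))
  out
}

new_cluster <- function(rank, members, monophyletic = TRUE, flags = character()) {
  list(rank = rank, members = members, monophyletic = monophyletic,
       resolved_name = NA_character_, name_basis = "unchanged",
       synonyms = list(), flags = flags)
}

#' Infer genus-level clusters
#'
#' Maximal monophyletic clades in which every leaf pair has AAI at or above
#' the genus threshold, chosen greedily from the root down (so clusters are
#' as inclusive as possible without violating monophyly or the minimum
#' pairwise AAI); clusters are clades by construction, so paraphyly is never
#' created. Genomes lacking AAI values (no proteome) become flagged
#' singletons.
#'
#' @param tree Rooted `phylo` over the genome ids (outgroup removed).
#' @param comparisons A `pairwise_set` or pairs data frame.
#' @param thresholds [delimitation_thresholds()].
#' @return List of genus `TaxonCluster`s (rank, members, monophyletic,
#'   naming fields).
#' @export
infer_genus_clusters <- function(tree, comparisons,
                                 thresholds = delimitation_thresholds()) {
  mats <- comparison_matrices(comparisons)
  root <- length(tree$tip.label) + 1L
  pass <- function(members)
    all_pairs_pass(members, mats$aai,
                   function(v) v >= thresholds$aai_genus_min)
  groups <- topdown_clusters(tree, root, pass)
  lapply(groups, function(g) {
    flags <- character()
    if (length(g) == 1 && all(is.na(mats$aai[g, setdiff(rownames(mats$aai),
                                                        g)])))
      flags <- "no_aai"
    new_cluster("genus", sort(g), flags = flags)
  })
}

#' Infer species-level clusters
#'
#' A pair is a same-species candidate iff dDDH, ANI and the G+C difference
#' all pass (`dddh >= dddh_species_min` AND `ani >= ani_species_min` AND
#' `gc_diff < gc_diff_species_max`; absent values fail). Clusters are the
#' maximal monophyletic clades in which every internal pair passes
#' (complete linkage, which prevents threshold chaining); every genome ends
#' up in exactly one cluster. When genus clusters are supplied, species
#' clusters are sought within each genus clade so the species partition
#' refines the genus partition.
#'
#' @inheritParams infer_genus_clusters
#' @param genus_clusters Optional list from [infer_genus_clusters()].
#' @return List of species `TaxonCluster`s.
#' @export
infer_species_clusters <- function(tree, comparisons,
                                   thresholds = delimitation_thresholds(),
                                   genus_clusters = NULL) {
  mats <- comparison_matrices(comparisons)
  pass <- function(members) {
    all_pairs_pass(members, mats$dddh,
                   function(v) v >= thresholds$dddh_species_min) &&
    all_pairs_pass(members, mats$ani,
                   function(v) v >= thresholds$ani_species_min) &&
    all_pairs_pass(members, mats$gc_diff,
                   function(v) v < thresholds$gc_diff_species_max)
  }
  start_nodes <- if (is.null(genus_clusters)) {
    length(tree$tip.label) + 1L
  } else {
    vapply(genus_clusters, function(cl) {
      if (length(cl$members) == 1)
        match(cl$members, tree$tip.label)
      else ape::getMRCA(tree, cl$members)
    }, integer(1))
  }
  groups <- list()
  for (nd in start_nodes)
    groups <- c(groups, topdown_clusters(tree, nd, pass))
  lapply(groups, function(g) new_cluster("species", sort(g)))
}

#' Resolve cluster names by nomenclature priority
#'
#' Within a cluster containing two or more named members the retained name
#' is chosen by (1) type-species status, then (2) validly published over
#' effectively published, then (3) earlier publication year, then (4) lower
#' page rank (order of appearance within one publication); the losing names
#' are recorded as later heterotypic synonyms. Clusters whose members are
#' all unnamed (metagenome-assembled genomes) receive a placeholder name.
#' Members whose input name disagrees with the resolved name are reported
#' as reclassifications. If two contenders cannot be ordered (both missing
#' a year), the cluster is flagged unresolved rather than guessed.
#'
#' @param clusters List of `TaxonCluster`s.
#' @param metadata Data frame with columns `id`, `name`, and optionally
#'   `is_type_species`, `is_type_strain`, `validly_published`,
#'   `publication_year`, `page_rank`, `is_mag`.
#' @return The clusters with `resolved_name`, `name_basis` and `synonyms`
#'   filled in, plus a per-genome `action` attribute table
#'   (`attr(x, "actions")`).
#' @export
resolve_names <- function(clusters, metadata) {
  md <- metadata
  rownames(md) <- md$id
  col <- function(id, colname, default) {
    if (!id %in% rownames(md) || !colname %in% names(md))
      return(default)
    v <- md[id, colname]
    if (is.null(v) || is.na(v)) default else v
  }
  actions <- data.frame(genome_id = character(), cluster = integer(),
                        input_name = character(), resolved_name = character(),
                        action = character(), stringsAsFactors = FALSE)
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    members <- cl$members
    named <- members[vapply(members, function(m)
      nzchar(col(m, "name", "")), logical(1))]
    if (length(named) == 0) {
      cl$resolved_name <- paste0("unnamed ", cl$rank, " cluster ", ci)
      cl$name_basis <- "placeholder_mag"
    } else {
      cand <- data.frame(
        id = named,
        name = vapply(named, function(m) as.character(col(m, "name", "")),
                      ""),
        type_species = vapply(named, function(m)
          isTRUE(col(m, "is_type_species", FALSE)), logical(1)),
        valid = vapply(named, function(m)
          isTRUE(col(m, "validly_published", TRUE)), logical(1)),
        year = vapply(named, function(m)
          as.numeric(col(m, "publication_year", NA_real_)), numeric(1)),
        page = vapply(named, function(m)
          as.numeric(col(m, "page_rank", NA_real_)), numeric(1)),
        stringsAsFactors = FALSE)
      # one row per distinct name (best representative per name)
      cand <- cand[!duplicated(cand$name), , drop = FALSE]
      if (nrow(cand) == 1) {
        cl$resolved_name <- cand$name
        cl$name_basis <- "unchanged"
      } else {
        ord <- order(!cand$type_species, !cand$valid,
                     cand$year, cand$page, cand$name)
        top <- cand[ord[1], ]; second <- cand[ord[2], ]
        tie_unordered <- !top$type_species && !second$type_species &&
          top$valid == second$valid &&
          is.na(top$year) && is.na(second$year)
        if (tie_unordered) {
          cl$resolved_name <- NA_character_
          cl$name_basis <- "unresolved"
          cl$flags <- union(cl$flags, "priority_unresolved")
        } else {
          cl$resolved_name <- top$name
          cl$name_basis <- if (top$type_species) {
            "type_species_priority"
          } else if (!is.na(top$year) && !is.na(second$year) &&
                     top$year != second$year) {
            "publication_date"
          } else {
            "page_order"
          }
          juniors <- setdiff(cand$name, top$name)
          cl$synonyms <- lapply(juniors, function(j)
            c(junior_name = j, senior_name = top$name))
        }
      }
    }
    for (m in members) {
      input <- as.character(col(m, "name", ""))
      act <- if (cl$name_basis == "placeholder_mag") "placeholder"
        else if (!nzchar(input)) "placeholder"
        else if (is.na(cl$resolved_name)) "unresolved"
        else if (identical(input, cl$resolved_name)) "unchanged"
        else if (input %in% vapply(cl$synonyms, `[[`, "", "junior_name"))
          "synonymized"
        else "reclassified"
      actions <- rbind(actions, data.frame(
        genome_id = m, cluster = ci, input_name = input,
        resolved_name = cl$resolved_name, action = act,
        stringsAsFactors = FALSE))
    }
    clusters[[ci]] <- cl
  }
  attr(clusters, "actions") <- actions
  clusters
}

#' Classify input genus labels as mono-, para- or polyphyletic
#'
#' For each label carried by at least two leaves: monophyletic if the
#' labeled leaves form a clade; otherwise the label splits into k >= 2
#' maximal same-label clades. If no *named* foreign leaf sits inside the
#' labeled leaves' most recent common ancestor, or the foreign leaves enter
#' through a single nested clade, the label is paraphyletic; if its pieces
#' attach at two or more independent points among other named labels, it is
#' polyphyletic.
#'
#' @param tree Rooted `phylo`.
#' @param name_assignments Named character vector: tip label -> input genus
#'   (NA or "" for unnamed genomes).
#' @return Data frame with `label`, `n`, `status`, `n_pieces`.
#' @export
detect_phyly_problems <- function(tree, name_assignments) {
  labs <- name_assignments[tree$tip.label]
  names(labs) <- tree$tip.label
  out <- data.frame(label = character(), n = integer(), status = character(),
                    n_pieces = integer(), stringsAsFactors = FALSE)
  for (lb in unique(labs[!is.na(labs) & nzchar(labs)])) {
    members <- names(labs)[!is.na(labs) & labs == lb]
    if (length(members) < 2) next
    if (is_monophyletic(tree, members)) {
      out <- rbind(out, data.frame(label = lb, n = length(members),
                                   status = "monophyletic", n_pieces = 1L))
      next
    }
    mrca <- ape::getMRCA(tree, members)
    inside <- clade_tips(tree, mrca)
    foreign <- setdiff(inside, members)
    foreign_named <- foreign[!is.na(labs[foreign]) & nzchar(labs[foreign])]
    pieces <- count_label_pieces(tree, members)
    single_entry <- length(foreign) > 0 &&
      (length(foreign) == 1 || is_monophyletic(tree, foreign))
    status <- if (length(foreign_named) == 0 || single_entry)
      "paraphyletic" else "polyphyletic"
    out <- rbind(out, data.frame(label = lb, n = length(members),
                                 status = status, n_pieces = pieces))
  }
  out
}

# number of maximal clades consisting solely of `members`
count_label_pieces <- function(tree, members) {
  nt <- length(tree$tip.label)
  in_set <- tree$tip.label %in% members
  # a node is "pure" iff all children are pure; fixed-point iteration keeps
  # this independent of any node-numbering convention
  pure <- c(in_set, rep(FALSE, tree$Nnode))
  repeat {
    changed <- FALSE
    for (nd in (nt + 1):(nt + tree$Nnode)) {
      ch <- tree$edge[tree$edge[, 1] == nd, 2]
      val <- all(pure[ch])
      if (val != pure[nd]) { pure[nd] <- val; changed <- TRUE }
    }
    if (!changed) break
  }
  parent_of <- function(nd) tree$edge[tree$edge[, 2] == nd, 1]
  maximal <- 0L
  for (nd in which(pure)) {
    p <- parent_of(nd)
    if (length(p) == 0 || !pure[p]) maximal <- maximal + 1L
  }
  maximal
}

#' Classify a new genome against a finished pipeline run
#'
#' The query is compared to one representative per cluster (the
#' alphabetically first member): ANI and dDDH against species
#' representatives, AAI against genus representatives. It is assigned to
#' the best species cluster whose representative passes the species
#' thresholds; failing that, to the best genus cluster passing the AAI
#' threshold ("novel species"); failing both it is reported as a novel
#' genus within the dataset.
#'
#' @param query A `genome_record`.
#' @param state List with `genomes`, `proteomes`, `species_clusters`,
#'   `genus_clusters`, `thresholds` (see [run_pipeline()] output).
#' @param query_proteome Optional `proteome_record` for the query.
#' @return List with `verdict`, `species_cluster`, `genus_cluster` and the
#'   per-representative index table.
#' @export
classify_new_genome <- function(query, state, query_proteome = NULL) {
  th <- state$thresholds
  reps_sp <- vapply(state$species_clusters, function(cl) cl$members[1], "")
  rows <- lapply(seq_along(reps_sp), function(i) {
    ref <- state$genomes[[reps_sp[i]]]
    ani <- compute_ani(query, ref)$ani
    hs <- gbdp_hsps(query, ref)
    d4 <- as.numeric(gbdp_distance_from_hsps(hs, query$total_length,
                                             ref$total_length, "d4"))
    gcd <- tryCatch(gc_difference(query, ref), error = function(e) NA_real_)
    data.frame(cluster = i, representative = reps_sp[i], ani = ani,
               dddh = distance_to_dddh(d4), gc_diff = gcd,
               stringsAsFactors = FALSE)
  })
  sp_tab <- do.call(rbind, rows)
  pass_sp <- !is.na(sp_tab$ani) & sp_tab$ani >= th$ani_species_min &
    sp_tab$dddh >= th$dddh_species_min &
    !is.na(sp_tab$gc_diff) & sp_tab$gc_diff < th$gc_diff_species_max
  ge_tab <- NULL
  if (any(pass_sp)) {
    best <- which.max(ifelse(pass_sp, sp_tab$dddh, -Inf))
    sp_cl <- state$species_clusters[[best]]
    ge <- which(vapply(state$genus_clusters, function(cl)
      sp_cl$members[1] %in% cl$members, logical(1)))
    return(list(verdict = "assigned_species", species_cluster = best,
                genus_cluster = ge[1], species_indexes = sp_tab,
                genus_indexes = ge_tab))
  }
  verdict <- "novel_genus_within_dataset"
  ge_best <- NA_integer_
  if (!is.null(query_proteome) && !is.null(state$proteomes)) {
    reps_ge <- vapply(state$genus_clusters, function(cl) cl$members[1], "")
    ge_rows <- lapply(seq_along(reps_ge), function(i) {
      pr <- state$proteomes[[reps_ge[i]]]
      aai <- if (is.null(pr)) NA_real_
             else compute_aai(query_proteome, pr)$aai
      data.frame(cluster = i, representative = reps_ge[i], aai = aai,
                 stringsAsFactors = FALSE)
    })
    ge_tab <- do.call(rbind, ge_rows)
    pass_ge <- !is.na(ge_tab$aai) & ge_tab$aai >= th$aai_genus_min
    if (any(pass_ge)) {
      verdict <- "novel_species"
      ge_best <- which.max(ifelse(pass_ge, ge_tab$aai, -Inf))
    }
  }
  list(verdict = verdict, species_cluster = NA_integer_,
       genus_cluster = ge_best, species_indexes = sp_tab,
       genus_indexes = ge_tab)
}

#' Tabulate clusters as a per-genome data frame
#'
#' @param genus_clusters,species_clusters Cluster lists.
#' @return Data frame with `genome_id`, `genus_cluster`, `species_cluster`,
#'   `monophyletic`, `resolved_name`, `name_basis`.
#' @export
clusters_table <- function(genus_clusters, species_clusters) {
  rows <- list()
  for (si in seq_along(species_clusters)) {
    sp <- species_clusters[[si]]
    for (m in sp$members) {
      gi <- which(vapply(genus_clusters, function(cl) m %in% cl$members,
                         logical(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = m, genus_cluster = gi[1], species_cluster = si,
        monophyletic = sp$monophyletic,
        resolved_name = sp$resolved_name,
        name_basis = sp$name_basis, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df[order(df$genome_id), , drop = FALSE]
}
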