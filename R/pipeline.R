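#' End-to-end pipeline: indexes, tree, delimitation, report
#'
#' Orchestrates the full analysis over a sample sheet of genomes and
#' proteomes, with per-step manifests (input checksums) so unchanged steps
#' are skipped on rerun, a run log, and plain TSV/Newick artifacts.
#'
#' @name cli_pipeline
NULL

#' Pipeline configuration
#'
#' Defaults reproduce the standard settings: 1020-bp ANI fragments,
#' E-value filters 1e-8 (whole-genome distances) and 1e-5 (proteome
#' search), 100 pseudo-bootstrap replicates, and delimitation thresholds
#' 71 (AAI) / 70 (dDDH) / 95 (ANI) / 1.0 (G+C difference).
#'
#' @param sample_sheet Path to the sample sheet TSV
#'   ([read_sample_sheet()]).
#' @param output_dir Output directory.
#' @param thresholds [delimitation_thresholds()].
#' @param replicates Pseudo-bootstrap replicates (default 100).
#' @param seed Integer seed (all pipeline randomness flows from it).
#' @param outgroup Character vector of outgroup genome ids (may be empty:
#'   the tree is then left unrooted and midpoint-free, and delimitation
#'   uses the tree as read).
#' @param steps Subset of `c("indexes", "tree", "delimit", "report")`.
#' @param tree_method `"bme"` or `"nj"`.
#' @param fragment_length ANI fragment size.
#' @param collapse_support Collapse tree edges with support at or below
#'   this value before delimitation (`NA` to disable; default 50).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(sample_sheet, output_dir,
                            thresholds = delimitation_thresholds(),
                            replicates = 100L, seed = 1L,
                            outgroup = character(),
                            steps = c("indexes", "tree", "delimit",
                                      "report"),
                            tree_method = "bme",
                            fragment_length = 1020L,
                            collapse_support = NA) {
  steps <- match.arg(steps, several.ok = TRUE)
  structure(list(sample_sheet = sample_sheet, output_dir = output_dir,
                 thresholds = thresholds, replicates = as.integer(replicates),
                 seed = as.integer(seed), outgroup = outgroup,
                 steps = steps, tree_method = tree_method,
                 fragment_length = as.integer(fragment_length),
                 collapse_support = collapse_support),
            class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat YAML mapping of the [pipeline_config()] fields; `overrides` (e.g.
#' parsed command-line options) win over the file. The effective
#' configuration is written to the output directory by [run_pipeline()].
#'
#' @param path YAML file.
#' @param overrides Named list of fields replacing the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw <- modifyList(raw, overrides)
  th <- do.call(delimitation_thresholds,
                raw$thresholds %||% list())
  raw$thresholds <- NULL
  do.call(pipeline_config, c(raw, list(thresholds = th)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pd_log <- function(run_dir, level, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " [", level, "] ",
                paste0(..., collapse = ""))
  message(msg)
  logf <- file.path(run_dir, "run.log")
  cat(msg, "\n", file = logf, append = TRUE)
}

step_manifest_path <- function(dir, step) {
  file.path(dir, paste0(".manifest_", step, ".json"))
}

manifest_current <- function(dir, step, inputs, params) {
  mf <- step_manifest_path(dir, step)
  if (!file.exists(mf)) return(FALSE)
  old <- tryCatch(jsonlite::read_json(mf), error = function(e) NULL)
  if (is.null(old)) return(FALSE)
  new <- manifest_payload(inputs, params)
  identical(unlist(old$checksums), unlist(new$checksums)) &&
    identical(old$params, new$params)
}

manifest_payload <- function(inputs, params) {
  sums <- as.list(tools::md5sum(inputs[file.exists(inputs)]))
  list(checksums = sums,
       params = as.character(jsonlite::toJSON(params, auto_unbox = TRUE,
                                              na = "null", digits = NA)))
}

write_manifest <- function(dir, step, inputs, params) {
  jsonlite::write_json(manifest_payload(inputs, params),
                       step_manifest_path(dir, step), auto_unbox = TRUE)
}

load_samples <- function(config) {
  sheet <- read_sample_sheet(config$sample_sheet)
  genomes <- list(); proteomes <- list()
  for (i in seq_len(nrow(sheet))) {
    id <- sheet$id[i]
    genomes[[id]] <- read_genome_fasta(sheet$genome_path[i], id = id,
                                       metadata = sheet[i, , drop = FALSE])
    pp <- if ("proteome_path" %in% names(sheet)) sheet$proteome_path[i]
          else NA
    if (!is.na(pp) && nzchar(pp) && file.exists(pp))
      proteomes[[id]] <- read_proteome_fasta(pp, id)
  }
  list(sheet = sheet, genomes = genomes, proteomes = proteomes)
}

hsps_to_long <- function(ps) {
  rows <- list()
  for (i in seq_len(nrow(ps$pairs))) {
    hs <- ps$hsps[[i]]
    if (is.null(hs) || nrow(hs) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      genome_a = ps$pairs$genome_a[i], genome_b = ps$pairs$genome_b[i],
      length = hs$length, identities = hs$identities,
      bitscore = hs$bitscore, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(genome_a = character(), genome_b = character(),
                      length = integer(), identities = integer(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

long_to_ps <- function(long, pairs, lengths, gc, ids) {
  hsps <- vector("list", nrow(pairs))
  names(hsps) <- pair_key(pairs$genome_a, pairs$genome_b)
  key_long <- pair_key(long$genome_a, long$genome_b)
  for (i in seq_len(nrow(pairs))) {
    k <- pair_key(pairs$genome_a[i], pairs$genome_b[i])
    sub <- long[key_long == k, , drop = FALSE]
    hsps[[i]] <- sub[, c("length", "identities", "bitscore"), drop = FALSE]
  }
  structure(list(ids = ids, pairs = pairs, hsps = hsps,
                 lengths = lengths, gc = gc),
            class = "pairwise_set")
}

#' Run the pipeline
#'
#' Executes the requested steps in order (`indexes`, `tree`, `delimit`,
#' `report`). Each step writes its artifacts plus a manifest with input
#' checksums; rerunning with unchanged inputs skips completed steps. A
#' pair or index failure is logged and recorded as absent, never fatal.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the loaded `genomes`, `proteomes`,
#'   `pairwise` set, `tree`, `genus_clusters`, `species_clusters`,
#'   `thresholds` and artifact paths.
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- config$output_dir
  yaml::write_yaml(list(
    sample_sheet = config$sample_sheet, output_dir = config$output_dir,
    thresholds = config$thresholds, replicates = config$replicates,
    seed = config$seed, outgroup = as.list(config$outgroup),
    steps = as.list(config$steps), tree_method = config$tree_method,
    fragment_length = config$fragment_length,
    collapse_support = config$collapse_support),
    file.path(out, "effective_config.yaml"))
  samples <- load_samples(config)
  state <- list(genomes = samples$genomes, proteomes = samples$proteomes,
                thresholds = config$thresholds, output_dir = out)
  input_files <- c(config$sample_sheet, samples$sheet$genome_path,
                   if ("proteome_path" %in% names(samples$sheet))
                     samples$sheet$proteome_path)
  base_params <- list(seed = config$seed,
                      fragment_length = config$fragment_length)

  # ---- indexes -------------------------------------------------------
  if ("indexes" %in% config$steps) {
    if (manifest_current(out, "indexes", input_files, base_params) &&
        file.exists(file.path(out, "pairs.tsv"))) {
      pd_log(out, "INFO", "indexes: up to date, skipping")
    } else {
      pd_log(out, "INFO", "indexes: computing all pairwise indexes for ",
             length(samples$genomes), " genomes")
      ps <- all_pairwise(samples$genomes,
                         if (length(samples$proteomes)) samples$proteomes
                         else NULL)
      write_index_matrices(ps, out)
      write.table(hsps_to_long(ps), file.path(out, "hsps.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_manifest(out, "indexes", input_files, base_params)
      pd_log(out, "INFO", "indexes: done (", nrow(ps$pairs), " pairs)")
    }
  }

  # reload pairwise set (also when the step was skipped)
  pairs_path <- file.path(out, "pairs.tsv")
  if (file.exists(pairs_path)) {
    pairs <- read.delim(pairs_path, stringsAsFactors = FALSE)
    long <- read.delim(file.path(out, "hsps.tsv"),
                       stringsAsFactors = FALSE)
    lens <- vapply(samples$genomes, `[[`, numeric(1), "total_length")
    gc <- vapply(samples$genomes,
                 function(g) tryCatch(gc_content(g),
                                      error = function(e) NA_real_),
                 numeric(1))
    state$pairwise <- long_to_ps(long, pairs, lens, gc,
                                 names(samples$genomes))
  }

  # ---- tree ----------------------------------------------------------
  tree_path <- file.path(out, "tree.nwk")
  if ("tree" %in% config$steps) {
    tp <- c(base_params, list(replicates = config$replicates,
                              method = config$tree_method))
    if (manifest_current(out, "tree", c(input_files, pairs_path), tp) &&
        file.exists(tree_path)) {
      pd_log(out, "INFO", "tree: up to date, skipping")
    } else {
      pd_log(out, "INFO", "tree: inferring ", config$tree_method,
             " tree with ", config$replicates, " pseudo-bootstrap ",
             "replicates (seed ", config$seed, ")")
      ps <- state$pairwise
      dm <- index_matrix(ps, "gbdp_d5")
      write_phylip_dist(dm, file.path(out, "gbdp_dist.phylip"))
      tree <- infer_tree(dm, config$tree_method)
      reps <- pseudo_bootstrap(ps, config$replicates, config$seed)
      rep_trees <- lapply(reps, infer_tree, method = config$tree_method)
      tree <- map_support(tree, rep_trees)
      # delimitation needs a rooted tree: outgroup rooting when an
      # outgroup is configured, midpoint rooting otherwise
      tree <- if (length(config$outgroup)) {
        root_with_outgroup(tree, config$outgroup)
      } else {
        phangorn::midpoint(tree, node.labels = "support")
      }
      ape::write.tree(tree, tree_path)
      write_manifest(out, "tree", c(input_files, pairs_path), tp)
      pd_log(out, "INFO", "tree: written to ", tree_path)
    }
  }
  if (file.exists(tree_path)) state$tree <- ape::read.tree(tree_path)

  # ---- delimit -------------------------------------------------------
  if ("delimit" %in% config$steps) {
    dp <- c(base_params, list(thresholds = config$thresholds,
                              collapse = config$collapse_support))
    if (manifest_current(out, "delimit", c(pairs_path, tree_path), dp) &&
        file.exists(file.path(out, "clusters.tsv"))) {
      pd_log(out, "INFO", "delimit: up to date, skipping")
    } else {
      pd_log(out, "INFO", "delimit: thresholds AAI>=",
             config$thresholds$aai_genus_min, " dDDH>=",
             config$thresholds$dddh_species_min, " ANI>=",
             config$thresholds$ani_species_min, " dGC<",
             config$thresholds$gc_diff_species_max)
      tree <- state$tree
      if (!is.na(config$collapse_support) &&
          !is.null(tree$node.label))
        tree <- collapse_low_support(tree, config$collapse_support)
      work_tree <- if (length(config$outgroup))
        ape::drop.tip(tree, config$outgroup) else tree
      genus_cl <- infer_genus_clusters(work_tree, state$pairwise,
                                       config$thresholds)
      species_cl <- infer_species_clusters(work_tree, state$pairwise,
                                           config$thresholds, genus_cl)
      md <- samples$sheet
      genus_cl <- resolve_names(genus_cl, md)
      species_cl <- resolve_names(species_cl, md)
      state$genus_clusters <- genus_cl
      state$species_clusters <- species_cl
      ct <- clusters_table(genus_cl, species_cl)
      acts <- attr(species_cl, "actions")
      ct$action <- acts$action[match(ct$genome_id, acts$genome_id)]
      write.table(ct, file.path(out, "clusters.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      if ("input_genus" %in% names(md)) {
        labels <- setNames(md$input_genus, md$id)
        phyly <- detect_phyly_problems(work_tree, labels)
        write.table(phyly, file.path(out, "phyly_report.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      }
      write_manifest(out, "delimit", c(pairs_path, tree_path), dp)
      pd_log(out, "INFO", "delimit: ", length(genus_cl), " genus and ",
             length(species_cl), " species clusters")
    }
  }
  if (is.null(state$genus_clusters) &&
      file.exists(file.path(out, "clusters.tsv"))) {
    ct <- read.delim(file.path(out, "clusters.tsv"),
                     stringsAsFactors = FALSE)
    state$clusters_table <- ct
    state$genus_clusters <- lapply(sort(unique(ct$genus_cluster)),
      function(g) list(rank = "genus",
                       members = sort(ct$genome_id[ct$genus_cluster == g])))
    state$species_clusters <- lapply(sort(unique(ct$species_cluster)),
      function(s) list(rank = "species",
                       members = sort(ct$genome_id[ct$species_cluster == s])))
  }

  # ---- report --------------------------------------------------------
  if ("report" %in% config$steps) {
    rp <- file.path(out, "report.md")
    pipeline_report(out, rp)
    pd_log(out, "INFO", "report: written to ", rp)
  }
  invisible(state)
}

#' Write a human-readable run summary
#'
#' Markdown summary of cluster memberships, per-cluster index ranges,
#' phyly problems and reclassification actions, mirroring a
#' before/after reclassification table.
#'
#' @param run_dir Pipeline output directory (delimitation complete).
#' @param path Output file (default `report.md` inside `run_dir`).
#' @return `path`, invisibly.
#' @export
pipeline_report <- function(run_dir, path = file.path(run_dir,
                                                      "report.md")) {
  ct_path <- file.path(run_dir, "clusters.tsv")
  if (!file.exists(ct_path)) stop("delimitation artifacts not found in ",
                                  run_dir)
  ct <- read.delim(ct_path, stringsAsFactors = FALSE)
  pairs <- read.delim(file.path(run_dir, "pairs.tsv"),
                      stringsAsFactors = FALSE)
  lines <- c("# Taxonomic delimitation report", "")
  lines <- c(lines, paste0("Genomes: ", nrow(ct),
                           "; genus clusters: ",
                           length(unique(ct$genus_cluster)),
                           "; species clusters: ",
                           length(unique(ct$species_cluster))), "")
  range_str <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return("-")
    sprintf("%.1f-%.1f", min(v), max(v))
  }
  lines <- c(lines, "## Genus clusters", "")
  for (g in sort(unique(ct$genus_cluster))) {
    members <- ct$genome_id[ct$genus_cluster == g]
    sub <- pairs[pairs$genome_a %in% members & pairs$genome_b %in% members, ]
    lines <- c(lines, paste0("- genus cluster ", g, " (n=",
                             length(members), "): ",
                             paste(members, collapse = ", "),
                             "  [AAI ", range_str(sub$aai), "]"))
  }
  lines <- c(lines, "", "## Species clusters", "")
  for (s in sort(unique(ct$species_cluster))) {
    members <- ct$genome_id[ct$species_cluster == s]
    sub <- pairs[pairs$genome_a %in% members & pairs$genome_b %in% members, ]
    nm <- unique(ct$resolved_name[ct$species_cluster == s])
    lines <- c(lines, paste0("- species cluster ", s, " (n=",
                             length(members), ", name: ", nm[1], "): ",
                             paste(members, collapse = ", "),
                             "  [dDDH ", range_str(sub$dddh),
                             "; ANI ", range_str(sub$ani), "]"))
  }
  phyly_path <- file.path(run_dir, "phyly_report.tsv")
  if (file.exists(phyly_path)) {
    ph <- read.delim(phyly_path, stringsAsFactors = FALSE)
    lines <- c(lines, "", "## Phyly of input genus labels", "")
    if (nrow(ph))
      lines <- c(lines, sprintf("- %s (n=%d): %s (%d piece%s)", ph$label,
                                ph$n, ph$status, ph$n_pieces,
                                ifelse(ph$n_pieces > 1, "s", "")))
    else lines <- c(lines, "- no multi-genome input labels")
  }
  if ("action" %in% names(ct)) {
    lines <- c(lines, "", "## Reclassification actions", "")
    lines <- c(lines, sprintf("- %s: %s%s", ct$genome_id, ct$action,
                              ifelse(ct$action %in%
                                       c("reclassified", "synonymized"),
                                     paste0(" -> ", ct$resolved_name), "")))
  }
  writeLines(lines, path)
  invisible(path)
}
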