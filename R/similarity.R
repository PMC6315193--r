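#' Pairwise genome similarity indexes
#'
#' Fragment-based average nucleotide identity (ANI), average amino acid
#' identity (AAI) over reciprocal best hits, percentage of conserved
#' proteins (POCP), genome-BLAST-style intergenomic distances with
#' greedy-with-trimming HSP selection, and the digital DDH transform.
#'
#' @name similarity_indexes
NULL

CONTIG_SPACER <- strrep("N", 60)

concat_contigs <- function(genome) {
  paste(genome$contigs, collapse = CONTIG_SPACER)
}

#' Cut a genome into consecutive fragments
#'
#' Each contig is cut into non-overlapping windows of `fragment_length`
#' bases; the trailing window of each contig is kept only if it is at least
#' 100 bases long (a fixed rule so fragment counts are deterministic).
#'
#' @param genome A `genome_record`.
#' @param fragment_length Window size in bases (default 1020).
#' @return Named character vector of fragments, labeled `contig:offset`.
#' @export
fragment_genome <- function(genome, fragment_length = 1020L) {
  stopifnot(inherits(genome, "genome_record"), fragment_length > 0)
  out <- character(0)
  for (ci in seq_along(genome$contigs)) {
    s <- genome$contigs[[ci]]
    L <- nchar(s)
    if (L < 100L) next
    starts <- seq.int(1L, L, by = fragment_length)
    ends <- pmin(starts + fragment_length - 1L, L)
    keep <- (ends - starts + 1L) >= pmin(fragment_length, 100L)
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) next
    frs <- substring(s, starts, ends)
    names(frs) <- paste0(names(genome$contigs)[ci], ":", starts - 1L)
    out <- c(out, frs)
  }
  out
}

#' One-directional fragment-based ANI
#'
#' The query genome is cut into fragments ([fragment_genome()]); each
#' fragment's best HSP against the reference is retained iff its identity is
#' at least `min_identity` percent and its aligned length at least
#' `min_coverage` of the fragment length. The value is the mean percent
#' identity over retained fragments.
#'
#' @param query,reference `genome_record` objects.
#' @param params Nucleotide [align_params()]; the ANI preset uses an E-value
#'   cutoff of 1e-15 with the identity/coverage retention rules doing the
#'   real filtering.
#' @param fragment_length Fragment size (default 1020).
#' @param min_identity,min_coverage Retention rules (default 30 percent,
#'   0.70).
#' @return List with `ani` (percent, or `NA` if no fragment was retained)
#'   and `fragments_used`.
#' @export
ani_one_direction <- function(query, reference,
                              params = align_params("nucleotide",
                                                    evalue_cutoff = 1e-15,
                                                    min_seed_hits = 2L),
                              fragment_length = 1020L,
                              min_identity = 30, min_coverage = 0.70) {
  frs <- fragment_genome(query, fragment_length)
  if (!length(frs)) return(list(ani = NA_real_, fragments_used = 0L))
  hits <- cpp_best_hits_batch(unname(frs), concat_contigs(reference),
                              unclass(params))
  found <- hits[, 1] == 1
  len <- hits[, 2]; idn <- hits[, 3]
  pid <- ifelse(found & len > 0, 100 * idn / len, NA_real_)
  keep <- found & !is.na(pid) & pid >= min_identity &
    len >= min_coverage * nchar(frs)
  if (!any(keep)) return(list(ani = NA_real_, fragments_used = 0L))
  list(ani = mean(pid[keep]), fragments_used = sum(keep))
}

#' Average nucleotide identity (two-way)
#'
#' Mean of the two one-directional values (query and reference reversed),
#' symmetric by construction.
#'
#' @inheritParams ani_one_direction
#' @param a,b `genome_record` objects.
#' @return List with `ani` (percent or `NA`), `fragments_used` (sum of both
#'   directions).
#' @export
compute_ani <- function(a, b,
                        params = align_params("nucleotide",
                                              evalue_cutoff = 1e-15,
                                                    min_seed_hits = 2L),
                        fragment_length = 1020L) {
  # canonical orientation so compute_ani(a, b) == compute_ani(b, a) exactly
  if (a$id > b$id) { tmp <- a; a <- b; b <- tmp }
  d1 <- ani_one_direction(a, b, params, fragment_length)
  d2 <- ani_one_direction(b, a, params, fragment_length)
  if (is.na(d1$ani) || is.na(d2$ani))
    return(list(ani = NA_real_, fragments_used = 0L))
  list(ani = mean(c(d1$ani, d2$ani)),
       fragments_used = d1$fragments_used + d2$fragments_used)
}

#' Average amino acid identity between two proteomes
#'
#' Mean percent identity over reciprocal best hits (E-value at most 1e-5,
#' identity at least 30 percent, aligned length at least 70 percent of the
#' shorter protein). The ortholog count is the shared-gene count `S`
#' consumed by [compute_pocp()].
#'
#' @param a,b `proteome_record` objects.
#' @param params Protein-mode [align_params()].
#' @return List with `aai` (percent or `NA`) and `orthologs` (count).
#' @export
compute_aai <- function(a, b, params = align_params("protein")) {
  rbh <- reciprocal_best_hits(a, b, params)
  if (nrow(rbh) == 0L) return(list(aai = NA_real_, orthologs = 0L))
  list(aai = mean(rbh$percent_identity), orthologs = nrow(rbh))
}

#' Percentage of conserved proteins
#'
#' Exactly `(2 * S) / (T1 + T2) * 100` with `S` the shared-ortholog count
#' and `T1`, `T2` the two proteome sizes.
#'
#' @param a,b `proteome_record` objects (only their counts are used).
#' @param shared Ortholog count `S`, usually from [compute_aai()].
#' @return POCP percentage.
#' @export
compute_pocp <- function(a, b, shared) {
  t1 <- a$count; t2 <- b$count
  stopifnot(t1 > 0, t2 > 0)
  if (shared > min(t1, t2))
    stop("internal consistency error: shared orthologs (", shared,
         ") exceed the smaller proteome (", min(t1, t2), ")")
  200 * shared / (t1 + t2)
}

# Greedy-with-trimming reduction of an HSP set to a non-overlapping set.
# HSPs are taken in descending bitscore order; a candidate overlapping
# already-accepted regions (on query or subject) is trimmed to its
# non-covered columns when the overlap is at most half its length and
# dropped otherwise. Identities are scaled proportionally.
greedy_trim_hsps <- function(hsps) {
  if (nrow(hsps) == 0L) return(hsps)
  ord <- order(-hsps$bitscore, hsps$q_start, hsps$s_start)
  hsps <- hsps[ord, , drop = FALSE]
  covered_len <- function(iv, lo, hi) {
    if (!nrow(iv)) return(0L)
    o <- pmin(iv$hi, hi) - pmax(iv$lo, lo)
    sum(pmax(o, 0L))
  }
  qiv <- data.frame(lo = integer(), hi = integer())
  siv <- data.frame(lo = integer(), hi = integer())
  keep <- logical(nrow(hsps))
  newlen <- hsps$length
  newid <- hsps$identities
  for (i in seq_len(nrow(hsps))) {
    covq <- covered_len(qiv, hsps$q_start[i], hsps$q_end[i])
    covs <- covered_len(siv, hsps$s_start[i], hsps$s_end[i])
    ov <- max(covq, covs)
    if (ov == 0L) {
      keep[i] <- TRUE
    } else if (ov <= hsps$length[i] / 2) {
      frac <- (hsps$length[i] - ov) / hsps$length[i]
      newlen[i] <- hsps$length[i] - ov
      newid[i] <- round(hsps$identities[i] * frac)
      keep[i] <- newlen[i] > 0L
    }
    if (keep[i]) {
      qiv <- rbind(qiv, data.frame(lo = hsps$q_start[i], hi = hsps$q_end[i]))
      siv <- rbind(siv, data.frame(lo = hsps$s_start[i], hi = hsps$s_end[i]))
    }
  }
  hsps$length <- newlen
  hsps$identities <- newid
  hsps[keep, , drop = FALSE]
}

#' Whole-genome HSP set for distance computation
#'
#' Aligns the two genomes (contigs concatenated with an N spacer, both
#' subject strands), filters at the whole-genome E-value cutoff and reduces
#' the HSPs to a non-overlapping set by greedy selection in descending score
#' with trimming of partial overlaps. The pair is aligned in a canonical
#' orientation (lexicographically smaller id as query) so the result is
#' symmetric by construction.
#'
#' @param a,b `genome_record` objects.
#' @param params Nucleotide [align_params()] (default E-value cutoff 1e-8).
#' @return Data frame of retained HSPs (`length`, `identities`, ...).
#' @export
gbdp_hsps <- function(a, b,
                      params = align_params("nucleotide",
                                            min_seed_hits = 2L)) {
  if (a$id > b$id) { tmp <- a; a <- b; b <- tmp }
  hsps <- local_align(concat_contigs(a), concat_contigs(b), params)
  greedy_trim_hsps(hsps)
}

#' Intergenomic distance from a retained HSP set
#'
#' With `I` the total identities, `H` the total aligned columns over the
#' retained HSPs and `L1`, `L2` the genome lengths:
#' `d0 = 1 - 2H/(L1+L2)` (coverage), `d4 = 1 - I/H` (identity; the
#' "formula 2" distance feeding digital DDH), `d5 = -log(I/H)`
#' (log-transformed identity; used for tree branch lengths) and
#' `d6 = 1 - 2I/(L1+L2)`. An empty HSP set yields the configured maximum
#' for the formula, flagged via the `"capped"` attribute.
#'
#' @param hsps Data frame from [gbdp_hsps()] (or a resample of it).
#' @param l1,l2 Total genome lengths in bases.
#' @param formula One of `"d0"`, `"d4"`, `"d5"`, `"d6"`.
#' @return Nonnegative distance (scalar).
#' @export
gbdp_distance_from_hsps <- function(hsps, l1, l2, formula = "d5") {
  formula <- match.arg(formula, c("d0", "d4", "d5", "d6"))
  cap <- pd_constants()$gbdp_max_distance[[formula]]
  if (is.null(hsps) || nrow(hsps) == 0L)
    return(structure(cap, capped = TRUE))
  I <- sum(hsps$identities); H <- sum(hsps$length)
  if (H == 0L || I == 0L) return(structure(cap, capped = TRUE))
  d <- switch(formula,
    d0 = max(0, 1 - 2 * H / (l1 + l2)),
    d4 = max(0, 1 - I / H),
    d5 = -log(min(1, I / H)),
    d6 = max(0, 1 - 2 * I / (l1 + l2)))
  min(d, cap)
}

#' Intergenomic distance between two genomes
#'
#' Convenience wrapper: [gbdp_hsps()] followed by
#' [gbdp_distance_from_hsps()]. Zero for self-comparison, symmetric.
#'
#' @inheritParams gbdp_hsps
#' @param formula Distance formula (default `"d5"`).
#' @return Nonnegative distance.
#' @export
gbdp_distance <- function(a, b, params = align_params("nucleotide"),
                          formula = "d5") {
  gbdp_distance_from_hsps(gbdp_hsps(a, b, params),
                          a$total_length, b$total_length, formula)
}

#' Digital DNA-DNA hybridization from an intergenomic distance
#'
#' Logistic transform of the identity-based ("formula 2", `d4`) distance
#' into a DDH-analog percentage, strictly monotone decreasing in the
#' distance with range (0, 100). Coefficients live in [pd_constants()];
#' see that help page for the calibration and its provenance.
#'
#' @param d Nonnegative `d4` distance(s).
#' @return dDDH percentage(s).
#' @export
distance_to_dddh <- function(d) {
  stopifnot(all(d >= 0))
  glm <- pd_constants()$dddh_glm
  100 / (1 + exp(glm$a + glm$b * d))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' All pairwise similarity indexes for a genome set
#'
#' Computes every unordered pair's ANI, AAI, POCP, intergenomic distances
#' (`d5` for trees, `d4` for digital DDH), dDDH and G+C difference. A
#' pair's failure is recorded as `NA` for the affected indexes and never
#' aborts the batch. Genomes without a proteome get `NA` AAI/POCP.
#'
#' @param genomes Named list of `genome_record`s (names = ids).
#' @param proteomes Named list of `proteome_record`s (may be missing
#'   entries), or `NULL`.
#' @param nt_params,aa_params,ani_params Alignment presets.
#' @param verbose Print progress.
#' @return A `pairwise_set`: list with `ids`, `pairs` (long-format data
#'   frame), `hsps` (retained HSP sets per pair, for pseudo-bootstrap),
#'   `lengths`, `gc`.
#' @export
all_pairwise <- function(genomes, proteomes = NULL,
                         nt_params = align_params("nucleotide"),
                         aa_params = align_params("protein"),
                         ani_params = align_params("nucleotide",
                                                   evalue_cutoff = 1e-15,
                                                    min_seed_hits = 2L),
                         verbose = FALSE) {
  stopifnot(length(genomes) >= 2)
  ids <- vapply(genomes, `[[`, "", "id")
  names(genomes) <- ids
  gc <- vapply(genomes, function(g) tryCatch(gc_content(g),
                                             error = function(e) NA_real_),
               numeric(1))
  lens <- vapply(genomes, `[[`, numeric(1), "total_length")
  combs <- utils::combn(ids, 2)
  n <- ncol(combs)
  pairs <- data.frame(
    genome_a = combs[1, ], genome_b = combs[2, ],
    ani = NA_real_, ani_fragments_used = 0L,
    aai = NA_real_, aai_orthologs = 0L, pocp = NA_real_,
    gbdp_d5 = NA_real_, gbdp_d4 = NA_real_, dddh = NA_real_,
    gc_diff = NA_real_, stringsAsFactors = FALSE)
  hsp_store <- vector("list", n)
  names(hsp_store) <- pair_key(combs[1, ], combs[2, ])
  for (i in seq_len(n)) {
    ga <- genomes[[combs[1, i]]]; gb <- genomes[[combs[2, i]]]
    if (verbose) message("pair ", ga$id, " vs ", gb$id)
    res <- tryCatch({
      hsps <- gbdp_hsps(ga, gb, nt_params)
      d5 <- gbdp_distance_from_hsps(hsps, ga$total_length, gb$total_length,
                                    "d5")
      d4 <- gbdp_distance_from_hsps(hsps, ga$total_length, gb$total_length,
                                    "d4")
      ani <- compute_ani(ga, gb, ani_params)
      list(hsps = hsps, d5 = as.numeric(d5), d4 = as.numeric(d4), ani = ani)
    }, error = function(e) {
      warning("pair ", ga$id, "/", gb$id, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      hsp_store[[i]] <- res$hsps
      pairs$gbdp_d5[i] <- res$d5
      pairs$gbdp_d4[i] <- res$d4
      pairs$dddh[i] <- distance_to_dddh(res$d4)
      pairs$ani[i] <- res$ani$ani
      pairs$ani_fragments_used[i] <- res$ani$fragments_used
    }
    if (!is.null(proteomes) &&
        !is.null(proteomes[[ga$id]]) && !is.null(proteomes[[gb$id]])) {
      aai <- tryCatch(compute_aai(proteomes[[ga$id]], proteomes[[gb$id]],
                                  aa_params),
                      error = function(e) list(aai = NA_real_,
                                               orthologs = 0L))
      pairs$aai[i] <- aai$aai
      pairs$aai_orthologs[i] <- aai$orthologs
      if (aai$orthologs >= 0)
        pairs$pocp[i] <- tryCatch(
          compute_pocp(proteomes[[ga$id]], proteomes[[gb$id]],
                       aai$orthologs),
          error = function(e) NA_real_)
    }
    pairs$gc_diff[i] <- abs(gc[[ga$id]] - gc[[gb$id]])
  }
  structure(list(ids = unname(ids), pairs = pairs, hsps = hsp_store,
                 lengths = lens, gc = gc),
            class = "pairwise_set")
}

#' @export
print.pairwise_set <- function(x, ...) {
  cat("<pairwise_set>", length(x$ids), "genomes,", nrow(x$pairs),
      "pairs\n")
  invisible(x)
}

#' Extract a symmetric index matrix from a pairwise set
#'
#' The diagonal is fixed to the self-comparison value of the index (100 for
#' the percent identities and POCP, 0 for distances and G+C difference).
#'
#' @param ps A `pairwise_set`.
#' @param index One of `"ani"`, `"aai"`, `"pocp"`, `"dddh"`, `"gbdp_d5"`,
#'   `"gbdp_d4"`, `"gc_diff"`.
#' @return Symmetric numeric matrix with genome ids as dimnames.
#' @export
index_matrix <- function(ps, index = "ani") {
  stopifnot(inherits(ps, "pairwise_set"))
  index <- match.arg(index, c("ani", "aai", "pocp", "dddh", "gbdp_d5",
                              "gbdp_d4", "gc_diff"))
  ids <- ps$ids
  diag_val <- if (index %in% c("gbdp_d5", "gbdp_d4", "gc_diff")) 0 else 100
  m <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  diag(m) <- diag_val
  for (i in seq_len(nrow(ps$pairs))) {
    a <- ps$pairs$genome_a[i]; b <- ps$pairs$genome_b[i]
    m[a, b] <- m[b, a] <- ps$pairs[[index]][i]
  }
  m
}

#' Write one TSV matrix per index plus the long-format pair table
#'
#' @param ps A `pairwise_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_index_matrices <- function(ps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(ani = "ani.tsv", aai = "aai.tsv", pocp = "pocp.tsv",
             dddh = "dddh.tsv", gbdp_d5 = "gbdp_dist.tsv",
             gc_diff = "gc_diff.tsv")
  for (idx in names(files)) {
    m <- index_matrix(ps, idx)
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    write.table(df, file.path(dir, files[[idx]]), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  gcdf <- data.frame(id = names(ps$gc), gc = round(ps$gc, 1))
  write.table(gcdf, file.path(dir, "gc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ps$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
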