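#' Local alignment parameters
#'
#' Builds the parameter set consumed by the seed-and-extend alignment engine.
#' Two presets freeze the settings used throughout the pipeline:
#'
#' * `"nucleotide"`: k = 11 exact seeding, match +1 / mismatch -2, gap
#'   open 5 / extend 2 (legacy BLASTN-style scoring), x-drop 30, E-value
#'   cutoff 1e-8 (the whole-genome distance filter).
#' * `"protein"`: k = 4 two-hit same-diagonal seeding, BLOSUM62, gap
#'   open 11 / extend 1, x-drop 40, E-value cutoff 1e-5 (the proteome
#'   search filter).
#'
#' Karlin-Altschul constants placing raw scores on a bit scale live in
#' [pd_constants()]. Any field can be overridden through `...`.
#'
#' @param mode `"nucleotide"` or `"protein"`.
#' @param ... Named overrides of individual fields (`kmer_size`,
#'   `min_seed_hits`, `x_drop`, `match`, `mismatch`, `gap_open`,
#'   `gap_extend`, `evalue_cutoff`).
#' @return A named list of class `align_params`.
#' @export
align_params <- function(mode = c("nucleotide", "protein"), ...) {
  mode <- match.arg(mode)
  ka <- pd_constants()$karlin[[mode]]
  base <- if (mode == "nucleotide") {
    list(mode = "nucleotide", kmer_size = 11L, min_seed_hits = 1L,
         x_drop = 30L, match = 1L, mismatch = -2L,
         gap_open = 5L, gap_extend = 2L, evalue_cutoff = 1e-8,
         protein_matrix = NA_character_)
  } else {
    list(mode = "protein", kmer_size = 4L, min_seed_hits = 3L,
         x_drop = 40L, match = 1L, mismatch = -2L,
         gap_open = 11L, gap_extend = 1L, evalue_cutoff = 1e-5,
         protein_matrix = "BLOSUM62")
  }
  base$lambda <- ka$lambda
  base$karlin_k <- ka$K
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown align_params field(s): ",
                        paste(bad, collapse = ", "))
  p <- modifyList(base, over)
  stopifnot(p$evalue_cutoff > 0,
            p$kmer_size >= if (mode == "nucleotide") 4L else 2L)
  structure(p, class = c("align_params", "list"))
}

#' Local alignment of two sequences into HSPs
#'
#' Seed-and-extend local alignment. Both subject strands are searched in
#' nucleotide mode; minus-strand HSPs carry forward-strand subject
#' coordinates plus a strand flag. HSPs failing the E-value cutoff are
#' removed; the result is sorted by descending bitscore with deterministic
#' `(q_start, s_start)` tie-breaking.
#'
#' @param query,subject Character scalars (sequences).
#' @param params An [align_params()] object.
#' @return Data frame of HSPs with 0-based half-open coordinates
#'   (`q_start`, `q_end`, `s_start`, `s_end`), `strand`, `length`,
#'   `identities`, `score`, `bitscore`, `evalue`.
#' @export
local_align <- function(query, subject, params = align_params()) {
  stopifnot(is.character(query), is.character(subject),
            nzchar(query), nzchar(subject))
  df <- cpp_align_pair(query, subject, unclass(params))
  df
}

#' Karlin-Altschul style expectation value
#'
#' `E = m * n * 2^(-bitscore)`: monotone decreasing in the bitscore, linear
#' in each sequence length.
#'
#' @param bitscore Alignment score in bits.
#' @param query_len,subject_len Sequence lengths.
#' @return Expected number of chance alignments at this score.
#' @export
evalue <- function(bitscore, query_len, subject_len) {
  stopifnot(query_len > 0, subject_len > 0)
  as.numeric(query_len) * as.numeric(subject_len) * 2^(-bitscore)
}

#' Reciprocal best hits between two proteomes
#'
#' A pair `(a, b)` is reported iff `b` is `a`'s best-scoring hit and `a` is
#' `b`'s, and the alignment passes the E-value cutoff, the identity floor and
#' the coverage floor (aligned columns relative to the shorter protein).
#' Each protein appears at most once.
#'
#' @param prot_a,prot_b `proteome_record` objects.
#' @param params A protein-mode [align_params()].
#' @param min_identity Minimum percent identity (default 30).
#' @param min_coverage Minimum aligned length as a fraction of the shorter
#'   protein (default 0.70).
#' @return Data frame with `protein_a`, `protein_b`, `percent_identity`,
#'   `length`, `bitscore`, `evalue`.
#' @export
reciprocal_best_hits <- function(prot_a, prot_b,
                                 params = align_params("protein"),
                                 min_identity = 30, min_coverage = 0.70) {
  stopifnot(inherits(prot_a, "proteome_record"),
            inherits(prot_b, "proteome_record"),
            prot_a$count > 0, prot_b$count > 0)
  hits <- cpp_proteome_search(unname(prot_a$proteins),
                              unname(prot_b$proteins), unclass(params))
  empty <- data.frame(protein_a = character(), protein_b = character(),
                      percent_identity = numeric(), length = integer(),
                      bitscore = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  hits$a <- hits$a + 1L   # to 1-based indexes
  hits$b <- hits$b + 1L
  # deterministic best hit per side: bitscore desc, then partner index asc
  ord <- order(-hits$bitscore, hits$a, hits$b)
  hits <- hits[ord, , drop = FALSE]
  best_ab <- hits[!duplicated(hits$a), c("a", "b")]
  best_ba <- hits[!duplicated(hits$b), c("a", "b")]
  mutual <- merge(best_ab, best_ba, by = c("a", "b"))
  if (nrow(mutual) == 0L) return(empty)
  key <- paste(hits$a, hits$b)
  rows <- hits[match(paste(mutual$a, mutual$b), key), , drop = FALSE]
  len_a <- nchar(prot_a$proteins)[rows$a]
  len_b <- nchar(prot_b$proteins)[rows$b]
  pid <- 100 * rows$identities / rows$length
  keep <- rows$evalue <= params$evalue_cutoff &
    pid >= min_identity &
    rows$length >= min_coverage * pmin(len_a, len_b)
  rows <- rows[keep, , drop = FALSE]
  pid <- pid[keep]
  out <- data.frame(
    protein_a = names(prot_a$proteins)[rows$a],
    protein_b = names(prot_b$proteins)[rows$b],
    percent_identity = pid,
    length = rows$length,
    bitscore = rows$bitscore,
    evalue = rows$evalue,
    stringsAsFactors = FALSE)
  out[order(out$protein_a), , drop = FALSE]
}

#' Write HSPs in a BLAST outfmt-6-like TSV
#'
#' Coordinates in this dump (and only here) are 1-based inclusive, matching
#' the de-facto tabular standard.
#'
#' @param hsps Data frame from [local_align()].
#' @param query_id,subject_id Sequence identifiers for the first two columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hsps_tsv <- function(hsps, query_id, subject_id, path) {
  out <- data.frame(
    qseqid = query_id, sseqid = subject_id,
    pident = round(100 * hsps$identities / hsps$length, 2),
    length = hsps$length,
    mismatch = hsps$length - hsps$identities,
    gapopen = NA_integer_,
    qstart = hsps$q_start + 1L, qend = hsps$q_end,
    sstart = ifelse(hsps$strand == "+", hsps$s_start + 1L, hsps$s_end),
    send   = ifelse(hsps$strand == "+", hsps$s_end, hsps$s_start + 1L),
    evalue = hsps$evalue, bitscore = round(hsps$bitscore, 1))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
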