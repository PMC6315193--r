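#' Genome and proteome input/output
#'
#' Readers for nucleotide assemblies and protein sets, the sample sheet that
#' names them, and basic base-composition statistics. Genome identifiers come
#' from the sample sheet (or an explicit `id` argument), never from FASTA
#' headers, because strain names routinely contain characters that are unsafe
#' as identifiers.
#'
#' @name genome_io
NULL

IUPAC_NT <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V")
AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Read a nucleotide genome assembly from FASTA
#'
#' Contigs are kept in file order and case-folded to uppercase. The genome id
#' is taken from `id` when supplied, otherwise from the first header token.
#'
#' @param path Path to a (possibly multi-contig) nucleotide FASTA file.
#' @param id Genome identifier; defaults to the first token of the first
#'   header.
#' @param metadata Optional single-row data frame of strain metadata
#'   (see [read_sample_sheet()]).
#' @return A `genome_record`: list with `id`, `contigs` (named character
#'   vector), `total_length` and `metadata`.
#' @export
read_genome_fasta <- function(path, id = NULL, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in ", path,
                                           ": ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  contigs <- toupper(as.character(set))
  if (any(nchar(contigs) == 0L))
    stop("FASTA format error: record without sequence in ", path)
  names(contigs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  bad <- vapply(contigs, function(s) {
    chars <- unique(strsplit(s, "")[[1]])
    any(!chars %in% IUPAC_NT)
  }, logical(1))
  if (any(bad))
    stop("non-nucleotide characters beyond IUPAC codes in record(s): ",
         paste(names(contigs)[bad], collapse = ", "))
  genome_record(if (is.null(id)) names(contigs)[1] else id, contigs, metadata)
}

#' Construct a genome record from in-memory contigs
#'
#' @param id Unique genome identifier.
#' @param contigs Character vector of uppercase nucleotide sequences.
#' @param metadata Optional metadata row.
#' @return A `genome_record`.
#' @export
genome_record <- function(id, contigs, metadata = NULL) {
  stopifnot(is.character(id), nzchar(id), length(id) == 1L)
  contigs <- setNames(as.character(contigs), names(contigs))
  if (is.null(names(contigs)) || anyNA(names(contigs)))
    names(contigs) <- paste0(id, "_ctg", seq_along(contigs))
  structure(
    list(id = id, contigs = contigs,
         total_length = sum(nchar(contigs)), metadata = metadata),
    class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record>", x$id, "-", length(x$contigs), "contig(s),",
      x$total_length, "bp\n")
  invisible(x)
}

#' Read a proteome (amino-acid FASTA)
#'
#' Trailing stop symbols (`*`) are stripped; a file whose residues are all
#' A/C/G/T is accepted with a warning (such proteins are legal, if unusual).
#'
#' @param path Path to an amino-acid FASTA file.
#' @param genome_id Identifier of the genome the proteins belong to.
#' @return A `proteome_record`: list with `genome_id`, `proteins` (named
#'   character vector) and `count`.
#' @export
read_proteome_fasta <- function(path, genome_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in ", path,
                                           ": ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA format error: no protein records in ", path)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)
  if (any(nchar(seqs) == 0L))
    stop("FASTA format error: empty protein sequence in ", path)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  nt_only <- all(grepl("^[ACGT]+$", seqs))
  if (nt_only && any(nchar(seqs) > 50L))
    warning("proteome ", path, " looks nucleotide-only (ACGT residues); ",
            "accepting as amino acids")
  proteome_record(genome_id, seqs)
}

#' Construct a proteome record from in-memory sequences
#'
#' @param genome_id Identifier of the owning genome.
#' @param proteins Named character vector of amino-acid sequences.
#' @return A `proteome_record`.
#' @export
proteome_record <- function(genome_id, proteins) {
  proteins <- setNames(as.character(proteins), names(proteins))
  if (is.null(names(proteins)))
    names(proteins) <- paste0(genome_id, "_p", seq_along(proteins))
  if (any(nchar(proteins) == 0L)) stop("empty protein sequence")
  structure(list(genome_id = genome_id, proteins = proteins,
                 count = length(proteins)),
            class = "proteome_record")
}

#' @export
print.proteome_record <- function(x, ...) {
  cat("<proteome_record>", x$genome_id, "-", x$count, "proteins\n")
  invisible(x)
}

#' Write contigs or proteins to FASTA
#'
#' @param record A `genome_record` or `proteome_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(record, path) {
  seqs <- if (inherits(record, "genome_record")) record$contigs
          else record$proteins
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read the sample sheet naming genomes, proteomes and metadata
#'
#' Tab-separated with a header row. Required columns: `id`, `genome_path`.
#' Optional: `proteome_path`, `name`, `is_type_strain`, `is_type_species`,
#' `validly_published`, `publication_year`, `page_rank`, `is_mag`,
#' `input_genus`. `page_rank` (order of appearance within one publication)
#' is only meaningful when `publication_year` is present.
#'
#' @param path Path to the TSV sample sheet.
#' @return A data frame with one row per genome, ids unique.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("id", "genome_path")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("sample sheet missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("duplicate genome ids in sample sheet: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  for (col in c("is_type_strain", "is_type_species", "validly_published",
                "is_mag"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  if ("page_rank" %in% names(df) && "publication_year" %in% names(df)) {
    bad <- !is.na(df$page_rank) & is.na(df$publication_year)
    if (any(bad))
      stop("page_rank without publication_year for: ",
           paste(df$id[bad], collapse = ", "))
  }
  df
}

#' G+C content of a genome (mol%)
#'
#' Computed as `100 * (G + C) / (A + C + G + T)`. Ambiguity codes (including
#' N) are excluded from both numerator and denominator, keeping the statistic
#' a pure base-composition measure.
#'
#' @param genome A `genome_record`.
#' @return G+C percentage (numeric scalar).
#' @export
gc_content <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(genome$contigs),
    baseOnly = TRUE))
  acgt <- counts[c("A", "C", "G", "T")]
  denom <- sum(acgt)
  if (denom == 0)
    stop("G+C undefined: genome ", genome$id,
         " has no unambiguous A/C/G/T bases")
  unname(100 * (acgt[["G"]] + acgt[["C"]]) / denom)
}

#' Absolute difference in G+C content between two genomes
#'
#' @param a,b `genome_record` objects.
#' @return Difference in percentage points (symmetric, nonnegative).
#' @export
gc_difference <- function(a, b) {
  abs(gc_content(a) - gc_content(b))
}
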