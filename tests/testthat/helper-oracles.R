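# Shared fixtures and independent oracles for the test suite.
# Everything here is deliberately implemented without the package's
# alignment engine so it can serve as an independent cross-check.

NT <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(NT, n, replace = TRUE), collapse = "")

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# substitute a fraction of sites to a different base; returns the mutated
# string and the true mismatch count (the oracle)
mutate_seq <- function(s, frac) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < frac)
  if (length(hit)) {
    idx <- match(ch[hit], NT)
    ch[hit] <- NT[((idx - 1L + sample.int(3L, length(hit),
                                          replace = TRUE)) %% 4L) + 1L]
  }
  list(seq = paste(ch, collapse = ""), n_sub = length(hit))
}

# realized per-site difference of two equal-length strings
string_divergence <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  mean(ca != cb)
}

# Smith-Waterman local alignment oracle (Biostrings), nucleotide +1/-2 5/2
sw_oracle <- function(q, s) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(q, s, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = 5, gapExtension = 2)
}

# Rand index of two labelings over the same elements
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  unname(agree / choose(n, 2))
}

# all clades (tip-label sets) of a rooted tree, by exhaustive enumeration
enumerate_clades <- function(tree) {
  nt <- length(tree$tip.label)
  out <- lapply(seq_len(nt), function(i) tree$tip.label[i])
  for (nd in (nt + 1):(nt + tree$Nnode))
    out[[length(out) + 1L]] <-
      sort(ape::extract.clade(tree, nd)$tip.label)
  out
}

oracle_monophyletic <- function(tree, taxa) {
  taxa <- sort(taxa)
  if (length(taxa) <= 1) return(TRUE)
  any(vapply(enumerate_clades(tree),
             function(cl) identical(sort(cl), taxa), logical(1)))
}

# small genome/proteome builders
mk_genome <- function(id, ...) genome_record(id, c(...))

mk_proteome <- function(id, seqs) proteome_record(id, seqs)

write_tmp_fasta <- function(seqs, headers = names(seqs)) {
  path <- tempfile(fileext = ".fa")
  lines <- character(0)
  for (i in seq_along(seqs))
    lines <- c(lines, paste0(">", headers[i]), seqs[i])
  writeLines(lines, path)
  path
}
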