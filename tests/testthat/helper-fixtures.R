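# hand-built fixtures shared across test files

# minimal locus where every rearrangement is productive when lambda = 0:
# one segment per class, ATG at position 1, alanine codons everywhere else,
# all segment lengths multiples of 3
productive_locus <- function() {
  structure(
    data.frame(
      name = c("TRAV1", "TRAJ1", "TRAC", "TRBV1", "TRBD1",
               "TRBJ1-1", "TRBJ2-1", "TRBC1", "TRBC2"),
      chain = c("alpha", "alpha", "alpha", rep("beta", 6)),
      segtype = c("V", "J", "C", "V", "D", "J", "J", "C", "C"),
      cassette = c("none", "none", "none", "none", "none",
                   "1", "2", "1", "2"),
      sequence = c(
        "ATGGCCGCCGCA",   # V alpha: ATG + Ala x3
        "GCAGCTGCA",      # J alpha
        "GCAGCTGCA",      # C alpha
        "ATGGCCGCCGCA",   # V beta
        "GCCGCA",         # D beta (6 nt)
        "GCAGCTGCA",      # J cassette 1
        "GCTGCAGCT",      # J cassette 2
        "GCAGCTGCA",      # C cassette 1
        "GCAGCAGCA"       # C cassette 2
      ),
      stringsAsFactors = FALSE
    ),
    class = c("germline_locus", "data.frame")
  )
}

# locus whose V segments contain no ATG: no rearrangement can be productive
atg_free_locus <- function() {
  loc <- productive_locus()
  loc$sequence[loc$segtype == "V"] <- "CCAGCCGCCGCA"
  loc
}

# dense counts matrix with names, wrapped into a cell_matrix
named_counts <- function(counts, ...) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("c%02d", seq_len(ncol(counts)))
  }
  cell_matrix(counts, ...)
}

# brute-force ORF oracle used against is_productive(): scans every ATG in
# the V portion and translates with Biostrings
oracle_productive <- function(sequence, v_len) {
  n <- nchar(sequence)
  v_part <- substr(sequence, 1, v_len)
  hits <- gregexpr("ATG", v_part, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(FALSE)
  for (p in hits) {
    if (p + 2 > v_len) next
    span <- n - p + 1
    if (span < 3 || span %% 3 != 0) next
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(sequence, p, n))
    ))
    body <- substr(aa, 1, nchar(aa) - 1) # final codon may be a stop
    if (!grepl("*", body, fixed = TRUE)) return(TRUE)
  }
  FALSE
}
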