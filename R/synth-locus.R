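#' Specification of a parametric germline TCR locus
#'
#' Describes a synthetic two-chain T cell receptor locus used as substrate by
#' the V(D)J rearrangement simulator. The real murine locus is replaced by a
#' parametric emulation: segments are random nucleotide strings, except that a
#' start codon is planted near the 5' end of a configurable fraction of V
#' segments. Planting the ATG (rather than relying on chance occurrences)
#' makes the per-attempt productive probability steerable through the segment
#' lengths.
#'
#' The beta chain carries two J/C cassettes mirroring the murine TRBJ1-TRBC1
#' and TRBJ2-TRBC2 arrangement: J segments are split between cassettes and
#' each cassette owns one constant segment. The alpha chain has no D segments
#' and a single constant region.
#'
#' @param n_v,n_j Named integer vectors `c(alpha = , beta = )`: number of V
#'   and J segments per chain. Beta J segments are split as evenly as
#'   possible between the two cassettes; both cassettes must be non-empty.
#' @param n_d Number of beta-chain D segments (alpha has none); must be >= 1.
#' @param len_v,len_d,len_j,len_c Length ranges (nt), each `c(min, max)`;
#'   segment lengths are drawn uniformly from the range.
#' @param base_probs Per-position composition over A, C, G, T.
#' @param atg_frac Fraction of V segments carrying a planted ATG; incidental
#'   start codons are scrubbed from all V segments first, so exactly this
#'   fraction of V segments can seed an open reading frame.
#' @param atg_offset 1-based position of the planted ATG within the V segment.
#' @param seed Integer seed; fixes all randomness of [gen_germline_locus()].
#' @return An object of class `locus_spec`.
#' @seealso [gen_germline_locus()]
#' @export
locus_spec <- function(n_v = c(alpha = 20L, beta = 20L),
                       n_d = 2L,
                       n_j = c(alpha = 12L, beta = 12L),
                       len_v = c(45L, 57L),
                       len_d = c(10L, 16L),
                       len_j = c(15L, 21L),
                       len_c = c(24L, 33L),
                       base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       atg_frac = 1,
                       atg_offset = 1L,
                       seed = 1L) {
  spec <- list(
    n_v = n_v, n_d = as.integer(n_d), n_j = n_j,
    len_v = len_v, len_d = len_d, len_j = len_j, len_c = len_c,
    base_probs = base_probs / sum(base_probs),
    atg_frac = atg_frac, atg_offset = as.integer(atg_offset),
    seed = as.integer(seed)
  )
  class(spec) <- "locus_spec"
  validate_locus_spec(spec)
  spec
}

validate_locus_spec <- function(spec) {
  for (nm in c("alpha", "beta")) {
    if (is.na(spec$n_v[nm]) || spec$n_v[nm] < 1L) {
      stopf("locus_spec: need >= 1 V segment for chain '%s'", nm)
    }
    if (is.na(spec$n_j[nm]) || spec$n_j[nm] < 1L) {
      stopf("locus_spec: need >= 1 J segment for chain '%s'", nm)
    }
  }
  if (spec$n_d < 1L) stopf("locus_spec: beta chain needs >= 1 D segment")
  if (spec$n_j["beta"] < 2L) {
    stopf("locus_spec: beta needs >= 2 J segments so both cassettes are non-empty")
  }
  for (fld in c("len_v", "len_d", "len_j", "len_c")) {
    rng <- spec[[fld]]
    if (length(rng) != 2L || any(rng < 1L) || rng[2] < rng[1]) {
      stopf("locus_spec: '%s' must be c(min, max) with 1 <= min <= max", fld)
    }
  }
  if (spec$atg_frac < 0 || spec$atg_frac > 1) {
    stopf("locus_spec: 'atg_frac' must lie in [0, 1]")
  }
  if (spec$atg_offset < 1L || spec$atg_offset + 2L > spec$len_v[1]) {
    stopf("locus_spec: planted ATG (offset %d) must fit inside the shortest V segment",
          spec$atg_offset)
  }
  if (any(spec$base_probs < 0) || abs(sum(spec$base_probs) - 1) > 1e-8) {
    stopf("locus_spec: 'base_probs' must be non-negative and sum to 1")
  }
  invisible(spec)
}

#' Generate a synthetic germline locus
#'
#' Draws random V/(D)/J/C segment sequences for both TCR chains according to
#' a [locus_spec()]. Beta-chain J and C segments are partitioned into the two
#' cassettes; alpha segments carry cassette `"none"`. Output is deterministic
#' for a fixed `spec$seed`.
#'
#' @param spec A [locus_spec()].
#' @return An object of class `germline_locus`: a data.frame with columns
#'   `name`, `chain`, `segtype`, `cassette`, `sequence`.
#' @examples
#' loc <- gen_germline_locus(locus_spec(seed = 7))
#' table(loc$chain, loc$segtype)
#' @export
gen_germline_locus <- function(spec) {
  if (!inherits(spec, "locus_spec")) stopf("'spec' must be a locus_spec")
  validate_locus_spec(spec)
  with_seed(spec$seed, {
    rows <- list()
    for (chain in c("alpha", "beta")) {
      nv <- spec$n_v[[chain]]
      nj <- spec$n_j[[chain]]
      v_len <- sample(spec$len_v[1]:spec$len_v[2], nv, replace = TRUE)
      v_seq <- random_nt(v_len, spec$base_probs)
      # scrub chance start codons so atg_frac exactly controls which V
      # segments can seed an open reading frame (ATG -> ACG cannot create a
      # new ATG, so one pass suffices)
      v_seq <- gsub("ATG", "ACG", v_seq, fixed = TRUE)
      has_atg <- seq_len(nv) <= round(spec$atg_frac * nv)
      v_seq[has_atg] <- plant_atg(v_seq[has_atg], spec$atg_offset)
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("TR%sV%d", toupper(substr(chain, 1, 1)), seq_len(nv)),
        chain = chain, segtype = "V", cassette = "none",
        sequence = v_seq, stringsAsFactors = FALSE
      )
      if (chain == "beta") {
        d_len <- sample(spec$len_d[1]:spec$len_d[2], spec$n_d, replace = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          name = sprintf("TRBD%d", seq_len(spec$n_d)),
          chain = chain, segtype = "D", cassette = "none",
          sequence = random_nt(d_len, spec$base_probs), stringsAsFactors = FALSE
        )
      }
      j_len <- sample(spec$len_j[1]:spec$len_j[2], nj, replace = TRUE)
      j_seq <- random_nt(j_len, spec$base_probs)
      if (chain == "beta") {
        # split J segments between the two cassettes, each with its own C
        cass <- rep(c("1", "2"), length.out = nj)
        j_name <- unlist(lapply(c("1", "2"), function(cc) {
          sprintf("TRBJ%s-%d", cc, seq_len(sum(cass == cc)))
        }))
        j_ord <- order(cass)
        rows[[length(rows) + 1L]] <- data.frame(
          name = j_name, chain = chain, segtype = "J",
          cassette = sort(cass), sequence = j_seq[j_ord],
          stringsAsFactors = FALSE
        )
        c_len <- sample(spec$len_c[1]:spec$len_c[2], 2L, replace = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          name = c("TRBC1", "TRBC2"), chain = chain, segtype = "C",
          cassette = c("1", "2"),
          sequence = scrub_end_frame_stops(random_nt(c_len, spec$base_probs)),
          stringsAsFactors = FALSE
        )
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          name = sprintf("TRAJ%d", seq_len(nj)), chain = chain, segtype = "J",
          cassette = "none", sequence = j_seq, stringsAsFactors = FALSE
        )
        c_len <- sample(spec$len_c[1]:spec$len_c[2], 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          name = "TRAC", chain = chain, segtype = "C", cassette = "none",
          sequence = scrub_end_frame_stops(random_nt(c_len, spec$base_probs)),
          stringsAsFactors = FALSE
        )
      }
    }
    locus <- do.call(rbind, rows)
    rownames(locus) <- NULL
    class(locus) <- c("germline_locus", "data.frame")
    validate_locus(locus)
    locus
  })
}

# Remove stop codons from the reading frame anchored at the 3' end of a
# segment. Constant segments are always read in this frame (any complete ORF
# ends at the sequence end), and a real constant region is coding, so a stop
# there would sterilise the locus. T -> C flips turn TAA/TAG/TGA into
# CAA/CAG/CGA without touching other frames' codon boundaries.
scrub_end_frame_stops <- function(seqs) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    starts <- rev(seq.int(n - 2L, 1L, by = -3L))
    codons <- substring(s, starts, starts + 2L)
    bad <- codons %in% STOP_CODONS
    for (p in starts[bad]) substr(s, p, p) <- "C"
    s
  }, character(1L), USE.NAMES = FALSE)
}

plant_atg <- function(seqs, offset) {
  vapply(seqs, function(s) {
    paste0(substr(s, 1L, offset - 1L), "ATG",
           substr(s, offset + 3L, nchar(s)))
  }, character(1L), USE.NAMES = FALSE)
}

validate_locus <- function(locus) {
  req <- c("name", "chain", "segtype", "cassette", "sequence")
  if (!all(req %in% names(locus))) {
    stopf("germline locus must have columns %s", paste(req, collapse = ", "))
  }
  if (anyDuplicated(locus$name)) stopf("segment names must be unique")
  if (any(nchar(locus$sequence) == 0L)) stopf("segment sequences must be non-empty")
  check_acgt(locus$sequence, "germline segment")
  beta_j <- locus$cassette[locus$chain == "beta" & locus$segtype %in% c("J", "C")]
  if (!all(c("1", "2") %in% beta_j)) {
    stopf("beta chain must have non-empty J/C cassettes 1 and 2")
  }
  if (any(locus$cassette[locus$chain == "alpha"] != "none")) {
    stopf("alpha segments cannot carry a cassette label")
  }
  invisible(locus)
}

#' Read or write a germline locus as FASTA
#'
#' Headers follow the convention `name|chain|segtype|cassette`.
#'
#' @param locus A `germline_locus` data.frame.
#' @param path File path.
#' @return `write_locus_fasta()` returns `path` invisibly;
#'   `read_locus_fasta()` returns a `germline_locus`.
#' @export
write_locus_fasta <- function(locus, path) {
  validate_locus(locus)
  seqs <- Biostrings::DNAStringSet(locus$sequence)
  names(seqs) <- paste(locus$name, locus$chain, locus$segtype, locus$cassette,
                       sep = "|")
  Biostrings::writeXStringSet(seqs, filepath = path, width = 80L)
  invisible(path)
}

#' @rdname write_locus_fasta
#' @export
read_locus_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    stopf("FASTA headers must follow 'name|chain|segtype|cassette'")
  }
  locus <- data.frame(
    name = vapply(parts, `[`, "", 1L),
    chain = vapply(parts, `[`, "", 2L),
    segtype = vapply(parts, `[`, "", 3L),
    cassette = vapply(parts, `[`, "", 4L),
    sequence = as.character(seqs),
    stringsAsFactors = FALSE
  )
  rownames(locus) <- NULL
  class(locus) <- c("germline_locus", "data.frame")
  validate_locus(locus)
  locus
}
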