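#' @section Rearrangement model:
#' A thymocyte first rearranges its beta chain: on each allele the first
#' attempt draws a J (and matching C) segment from cassette 1, and a failed
#' attempt is followed by a second attempt on cassette 2; up to two alleles
#' are tried (at most four beta attempts). Under allelic exclusion the alpha
#' chain is rearranged only once a productive beta chain exists, with one
#' attempt per allele (at most two). V and D segments are drawn uniformly;
#' untemplated nucleotides are inserted at every junction (beta: V-D and
#' VD-J; alpha: V-J) with i.i.d. Poisson(lambda) lengths and uniform base
#' identity. An attempt is productive when an ATG inside the V segment opens
#' a reading frame that tiles the assembled sequence exactly (length from the
#' ATG divisible by three) with no in-frame stop codon before the final codon
#' of the constant segment.
#' @name tcr_rearrangement
#' @keywords internal
NULL

# ---- locus preprocessing ----------------------------------------------------

# Index a germline locus into per-chain segment tables once, so the simulator
# avoids repeated data.frame subsetting. ATG positions per V segment are
# precomputed: productivity scanning only ever starts at those offsets.
index_locus <- function(locus) {
  validate_locus(locus)
  grab <- function(chain, segtype, cassette = NULL) {
    keep <- locus$chain == chain & locus$segtype == segtype
    if (!is.null(cassette)) keep <- keep & locus$cassette == cassette
    list(name = locus$name[keep], seq = locus$sequence[keep],
         len = nchar(locus$sequence[keep]))
  }
  atg_positions <- function(seqs) {
    lapply(seqs, function(s) {
      hits <- gregexpr("ATG", s, fixed = TRUE)[[1]]
      if (hits[1] == -1L) integer(0) else as.integer(hits)
    })
  }
  alpha <- list(
    V = grab("alpha", "V"), J = grab("alpha", "J"), C = grab("alpha", "C")
  )
  beta <- list(
    V = grab("beta", "V"), D = grab("beta", "D"),
    J1 = grab("beta", "J", "1"), J2 = grab("beta", "J", "2"),
    C1 = grab("beta", "C", "1"), C2 = grab("beta", "C", "2")
  )
  if (length(alpha$V$name) == 0L || length(alpha$J$name) == 0L ||
      length(alpha$C$name) == 0L) {
    stopf("locus lacks alpha V, J or C segments")
  }
  if (length(beta$V$name) == 0L || length(beta$D$name) == 0L ||
      length(beta$J1$name) == 0L || length(beta$J2$name) == 0L ||
      length(beta$C1$name) != 1L || length(beta$C2$name) != 1L) {
    stopf("locus lacks beta V/D segments or a complete J/C cassette pair")
  }
  alpha$V$atg <- atg_positions(alpha$V$seq)
  beta$V$atg <- atg_positions(beta$V$seq)
  list(alpha = alpha, beta = beta)
}

# ---- productivity -----------------------------------------------------------

# Position of the 5'-most ATG inside the V portion that opens a stop-free
# reading frame tiling the sequence exactly; NA if none. `atg` may carry the
# precomputed ATG positions of the V segment.
find_orf_start <- function(sequence, v_len, atg = NULL) {
  n <- nchar(sequence)
  if (is.null(atg)) {
    v_part <- substr(sequence, 1L, v_len)
    hits <- gregexpr("ATG", v_part, fixed = TRUE)[[1]]
    atg <- if (hits[1] == -1L) integer(0) else as.integer(hits)
  }
  for (p in atg) {
    if (p + 2L > v_len) next                     # ATG must lie inside V
    span <- n - p + 1L
    if (span < 3L || span %% 3L != 0L) next      # frame must tile to the end
    if (span > 3L) {
      starts <- seq.int(p, n - 5L, by = 3L)      # all codons but the final one
      codons <- substring(sequence, starts, starts + 2L)
      if (any(codons %in% STOP_CODONS)) next
    }
    return(p)
  }
  NA_integer_
}

#' Test whether a rearranged chain is productive
#'
#' A rearrangement is productive when some ATG within the V segment opens a
#' complete open reading frame: the frame tiles the assembled sequence
#' exactly through the end of the constant segment and contains no in-frame
#' stop codon before the final codon.
#'
#' @param attempt_sequence Assembled nucleotide sequence (V...C), which must
#'   begin with `v_sequence`.
#' @param v_sequence The V segment the attempt used.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_productive("ATGAAATAAGGG", "ATGAAA") # stop codon in frame -> FALSE
#' is_productive("ATGAAACCCGGG", "ATGAAA") # TRUE
#' @export
is_productive <- function(attempt_sequence, v_sequence) {
  check_acgt(attempt_sequence, "attempt sequence")
  check_acgt(v_sequence, "V sequence")
  if (substr(attempt_sequence, 1L, nchar(v_sequence)) != v_sequence) {
    stopf("attempt sequence must begin with the V segment")
  }
  !is.na(find_orf_start(attempt_sequence, nchar(v_sequence)))
}

# ---- batch attempt simulation ----------------------------------------------

# Simulate `m` independent rearrangement attempts of one chain/cassette.
# Returns a data.frame with segment choices, insertion lengths and sequences,
# the assembled sequence, the ORF start and the productive flag. Uses the
# current RNG stream.
sim_attempt_batch <- function(chain, idx, m, lambda, cassette = NA_character_) {
  tabs <- if (chain == "beta") idx$beta else idx$alpha
  vi <- sample.int(length(tabs$V$name), m, replace = TRUE)
  if (chain == "beta") {
    J <- if (cassette == "1") tabs$J1 else tabs$J2
    Cseg <- if (cassette == "1") tabs$C1 else tabs$C2
    di <- sample.int(length(tabs$D$name), m, replace = TRUE)
    ji <- sample.int(length(J$name), m, replace = TRUE)
    ins1 <- rpois(m, lambda)
    ins2 <- rpois(m, lambda)
    ins1_seq <- random_nt(ins1)
    ins2_seq <- random_nt(ins2)
    seqs <- paste0(tabs$V$seq[vi], ins1_seq, tabs$D$seq[di], ins2_seq,
                   J$seq[ji], Cseg$seq[1])
    out <- data.frame(
      chain = chain, cassette = cassette,
      v = tabs$V$name[vi], d = tabs$D$name[di], j = J$name[ji],
      c = Cseg$name[1], ins1 = ins1, ins2 = ins2,
      stringsAsFactors = FALSE
    )
    out$ins1_seq <- ins1_seq
    out$ins2_seq <- ins2_seq
    out$d_seq <- tabs$D$seq[di]
    out$j_seq <- J$seq[ji]
  } else {
    ji <- sample.int(length(tabs$J$name), m, replace = TRUE)
    ins1 <- rpois(m, lambda)
    ins1_seq <- random_nt(ins1)
    seqs <- paste0(tabs$V$seq[vi], ins1_seq, tabs$J$seq[ji], tabs$C$seq[1])
    out <- data.frame(
      chain = chain, cassette = NA_character_,
      v = tabs$V$name[vi], d = NA_character_, j = tabs$J$name[ji],
      c = tabs$C$name[1], ins1 = ins1, ins2 = NA_integer_,
      stringsAsFactors = FALSE
    )
    out$ins1_seq <- ins1_seq
    out$ins2_seq <- NA_character_
    out$d_seq <- NA_character_
    out$j_seq <- tabs$J$seq[ji]
  }
  v_len <- tabs$V$len[vi]
  orf <- integer(m)
  for (i in seq_len(m)) {
    orf[i] <- find_orf_start(seqs[i], v_len[i], atg = tabs$V$atg[[vi[i]]])
  }
  out$v_len <- v_len
  out$sequence <- seqs
  out$orf_start <- orf
  out$productive <- !is.na(orf)
  out
}

#' Simulate a single rearrangement attempt
#'
#' Draws one V(D)J rearrangement for the requested chain: segments are
#' sampled uniformly (beta J/C from the cassette dictated by
#' `attempt_index`), junction insertions are Poisson(`lambda`) nucleotides
#' with uniform base identity, and productivity is determined by
#' [is_productive()]. Uses the session RNG; seed upstream for
#' reproducibility.
#'
#' @param chain `"alpha"` or `"beta"`.
#' @param locus A `germline_locus`.
#' @param attempt_index For beta, 1 selects cassette 1 (TRBJ1/TRBC1) and 2
#'   selects cassette 2; ignored for alpha.
#' @param allele Allele being rearranged (1 or 2), recorded in the output.
#' @param lambda Mean of the Poisson insertion-length distribution per
#'   junction (default 4).
#' @return An object of class `chain_attempt`: a one-row data.frame with the
#'   segment names, insertion lengths and sequences, the assembled
#'   nucleotide sequence, the open-reading-frame start (`orf_start`, NA when
#'   unproductive) and the `productive` flag.
#' @export
rearrange_chain <- function(chain = c("beta", "alpha"), locus,
                            attempt_index = 1L, allele = 1L, lambda = 4) {
  chain <- match.arg(chain)
  idx <- index_locus(locus)
  cassette <- if (chain == "beta") as.character(attempt_index) else NA_character_
  if (chain == "beta" && !cassette %in% c("1", "2")) {
    stopf("beta 'attempt_index' must be 1 or 2 (one per J/C cassette)")
  }
  out <- sim_attempt_batch(chain, idx, 1L, lambda, cassette)
  out$allele <- as.integer(allele)
  out$attempt_index <- as.integer(attempt_index)
  class(out) <- c("chain_attempt", "data.frame")
  out
}

# ---- thymocyte and repertoire ----------------------------------------------

# Vectorised simulation of n thymocytes; returns the long attempts table.
# Beta attempt order: (allele 1, cassette 1), (allele 1, cassette 2),
# (allele 2, cassette 1), (allele 2, cassette 2); alpha: allele 1 then 2.
sim_thymocyte_batch <- function(idx, n, lambda) {
  plan_beta <- data.frame(allele = c(1L, 1L, 2L, 2L),
                          cassette = c("1", "2", "1", "2"),
                          attempt_index = c(1L, 2L, 1L, 2L))
  attempts <- list()
  alive <- seq_len(n)           # thymocytes without a productive beta chain
  beta_ok <- logical(n)
  for (r in seq_len(4L)) {
    if (length(alive) == 0L) break
    batch <- sim_attempt_batch("beta", idx, length(alive), lambda,
                               plan_beta$cassette[r])
    batch$thymocyte <- alive
    batch$allele <- plan_beta$allele[r]
    batch$attempt_index <- plan_beta$attempt_index[r]
    attempts[[length(attempts) + 1L]] <- batch
    beta_ok[alive[batch$productive]] <- TRUE
    alive <- alive[!batch$productive]
  }
  alpha_alive <- which(beta_ok)  # allelic exclusion: alpha only after beta
  for (r in seq_len(2L)) {
    if (length(alpha_alive) == 0L) break
    batch <- sim_attempt_batch("alpha", idx, length(alpha_alive), lambda)
    batch$thymocyte <- alpha_alive
    batch$allele <- r
    batch$attempt_index <- 1L
    attempts[[length(attempts) + 1L]] <- batch
    alpha_alive <- alpha_alive[!batch$productive]
  }
  att <- do.call(rbind, attempts)
  att[order(att$thymocyte, att$chain, att$allele, att$attempt_index), ,
      drop = FALSE]
}

#' Simulate one thymocyte's sequential chain rearrangements
#'
#' Runs the full rearrangement program for a single thymocyte (see
#' `?tcr_rearrangement`): up to four beta attempts over two alleles and two
#' cassettes, then - only if a productive beta chain was made - up to two
#' alpha attempts. Uses the session RNG.
#'
#' @inheritParams rearrange_chain
#' @param flank_nt CDR3 window flank passed to [clonotype()].
#' @return An object of class `thymocyte`: a list with the `attempts`
#'   data.frame, logical `productive_pair`, clonotype strings
#'   (`clonotype_alpha`, `clonotype_beta`, NA when absent) and
#'   `total_inserted_nt` summed over all attempted junctions.
#' @export
simulate_thymocyte <- function(locus, lambda = 4, flank_nt = 9L) {
  idx <- index_locus(locus)
  att <- sim_thymocyte_batch(idx, 1L, lambda)
  build_thymocyte(att, flank_nt)
}

build_thymocyte <- function(att, flank_nt) {
  beta <- att[att$chain == "beta", , drop = FALSE]
  alpha <- att[att$chain == "alpha", , drop = FALSE]
  beta_hit <- which(beta$productive)[1]
  alpha_hit <- which(alpha$productive)[1]
  pair <- !is.na(beta_hit) && !is.na(alpha_hit)
  thy <- list(
    attempts = att,
    productive_pair = pair,
    clonotype_beta = if (!is.na(beta_hit)) {
      clonotype(beta[beta_hit, , drop = FALSE], flank_nt)
    } else NA_character_,
    clonotype_alpha = if (!is.na(alpha_hit)) {
      clonotype(alpha[alpha_hit, , drop = FALSE], flank_nt)
    } else NA_character_,
    total_inserted_nt = sum(att$ins1, att$ins2, na.rm = TRUE)
  )
  class(thy) <- "thymocyte"
  thy
}

#' @export
print.thymocyte <- function(x, ...) {
  cat(sprintf("<thymocyte> %d attempts, productive pair: %s\n",
              nrow(x$attempts), x$productive_pair))
  if (x$productive_pair) {
    cat(sprintf("  beta CDR3: %s | alpha CDR3: %s\n",
                x$clonotype_beta, x$clonotype_alpha))
  }
  invisible(x)
}

#' Simulate a thymocyte repertoire
#'
#' Repeatedly runs the thymocyte rearrangement program. In `mode =
#' "attempts"` exactly `n` thymocytes are simulated; in `mode = "productive"`
#' simulation continues until `n` thymocytes with a productive alpha/beta
#' pair have been generated (or `max_attempts` thymocytes have been tried,
#' guarding against loci on which productive pairs are impossible).
#'
#' @inheritParams rearrange_chain
#' @param n Number of thymocytes (or productive pairs) to simulate; >= 1.
#' @param mode `"attempts"` or `"productive"`.
#' @param seed Integer seed; the whole repertoire is reproducible from it.
#' @param flank_nt CDR3 window flank passed to [clonotype()].
#' @param max_attempts Attempt ceiling for `mode = "productive"`.
#' @param keep_sequences Keep assembled nucleotide sequences in the attempts
#'   table (off by default; they dominate memory at repertoire scale).
#' @return An object of class `repertoire`: a list with `thymocytes` (one
#'   row per thymocyte: productive flags per chain, clonotypes, attempt
#'   counts, inserted nucleotides), `attempts` (long per-attempt table),
#'   `n_attempted` and `seed`.
#' @examples
#' rep <- simulate_repertoire(gen_germline_locus(locus_spec(seed = 1)),
#'                            n = 200, seed = 42)
#' summary(rep)
#' @export
simulate_repertoire <- function(locus, n, mode = c("attempts", "productive"),
                                seed = 1L, lambda = 4, flank_nt = 9L,
                                max_attempts = 100 * n + 10000,
                                keep_sequences = FALSE) {
  mode <- match.arg(mode)
  check_scalar_number(n, "n", min = 1)
  idx <- index_locus(locus)
  with_seed(seed, {
    if (mode == "attempts") {
      att <- sim_thymocyte_batch(idx, n, lambda)
      n_attempted <- n
    } else {
      chunks <- list()
      got <- 0L
      n_attempted <- 0L
      offset <- 0L
      while (got < n) {
        m <- min(max(n, 1000L), max_attempts - n_attempted)
        if (m <= 0L) {
          stopf(paste0("mode='productive' exceeded max_attempts=%d with only ",
                       "%d productive pairs (is the locus ATG-free?)"),
                max_attempts, got)
        }
        att <- sim_thymocyte_batch(idx, m, lambda)
        att$thymocyte <- att$thymocyte + offset
        chunks[[length(chunks) + 1L]] <- att
        n_attempted <- n_attempted + m
        offset <- offset + m
        got <- got + n_productive_pairs(att)
      }
      att <- do.call(rbind, chunks)
    }
    rep <- assemble_repertoire(att, n_attempted, seed, flank_nt,
                               keep_sequences)
    if (mode == "productive") {
      keep <- rep$thymocytes$thymocyte[rep$thymocytes$productive_pair][seq_len(n)]
      # retain every attempted thymocyte up to (and including) the n-th
      # productive one, preserving attempt statistics
      cutoff <- max(keep)
      rep$thymocytes <- rep$thymocytes[rep$thymocytes$thymocyte <= cutoff, ,
                                       drop = FALSE]
      rep$attempts <- rep$attempts[rep$attempts$thymocyte <= cutoff, ,
                                   drop = FALSE]
      rep$n_attempted <- cutoff
    }
    rep
  })
}

n_productive_pairs <- function(att) {
  beta_ok <- unique(att$thymocyte[att$chain == "beta" & att$productive])
  alpha_ok <- unique(att$thymocyte[att$chain == "alpha" & att$productive])
  length(intersect(beta_ok, alpha_ok))
}

assemble_repertoire <- function(att, n_attempted, seed, flank_nt,
                                keep_sequences) {
  is_beta <- att$chain == "beta"
  hit_beta <- att[is_beta & att$productive, , drop = FALSE]
  hit_alpha <- att[!is_beta & att$productive, , drop = FALSE]
  # clonotypes of the productive attempt of each chain (at most one by
  # construction: rearrangement stops at the first productive attempt)
  clono <- function(hits) {
    if (nrow(hits) == 0L) return(setNames(character(0), integer(0)))
    out <- character(nrow(hits))
    seqv <- hits$sequence; vl <- hits$v_len; orf <- hits$orf_start
    i1 <- hits$ins1; i2 <- hits$ins2; dv <- hits$d_seq
    fl <- as.integer(flank_nt)
    for (i in seq_len(nrow(hits))) {
      out[i] <- clonotype_core(seqv[i], vl[i], orf[i], i1[i], i2[i], dv[i], fl)
    }
    setNames(out, hits$thymocyte)
  }
  cb <- clono(hit_beta)
  ca <- clono(hit_alpha)
  ids <- seq_len(n_attempted)
  ins_tot <- tapply(rowSums(cbind(att$ins1, att$ins2), na.rm = TRUE),
                    factor(att$thymocyte, levels = ids), sum)
  thy <- data.frame(
    thymocyte = ids,
    beta_productive = ids %in% hit_beta$thymocyte,
    alpha_productive = ids %in% hit_alpha$thymocyte,
    n_beta_attempts = as.integer(table(factor(att$thymocyte[is_beta],
                                              levels = ids))),
    n_alpha_attempts = as.integer(table(factor(att$thymocyte[!is_beta],
                                               levels = ids))),
    clonotype_beta = unname(cb[as.character(ids)]),
    clonotype_alpha = unname(ca[as.character(ids)]),
    total_inserted_nt = as.integer(ins_tot),
    stringsAsFactors = FALSE
  )
  thy$productive_pair <- thy$beta_productive & thy$alpha_productive
  if (!keep_sequences) {
    att$sequence <- NULL
    att$ins1_seq <- NULL
    att$ins2_seq <- NULL
    att$d_seq <- NULL
    att$j_seq <- NULL
  }
  rownames(att) <- NULL
  out <- list(thymocytes = thy, attempts = att, n_attempted = n_attempted,
              seed = seed)
  class(out) <- "repertoire"
  out
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("<repertoire> %d thymocytes attempted, %d productive pairs\n",
              x$n_attempted, sum(x$thymocytes$productive_pair)))
  invisible(x)
}

#' Summarise a simulated repertoire
#'
#' @param object A `repertoire`.
#' @param ... Unused.
#' @return A list with the fraction of thymocytes with a valid beta chain
#'   (`beta_valid`, denominator: all thymocytes), the fraction with a valid
#'   alpha chain among those that reached alpha rearrangement
#'   (`alpha_valid`), the unconditional productive-pair fraction
#'   (`pair_valid`), and mean inserted nucleotides per beta attempt
#'   (`mean_beta_insertions`, both junctions).
#' @export
summary.repertoire <- function(object, ...) {
  thy <- object$thymocytes
  att <- object$attempts
  beta_att <- att[att$chain == "beta", , drop = FALSE]
  reached_alpha <- thy$beta_productive
  out <- list(
    n_attempted = object$n_attempted,
    beta_valid = mean(thy$beta_productive),
    alpha_valid = if (any(reached_alpha)) {
      mean(thy$alpha_productive[reached_alpha])
    } else NA_real_,
    pair_valid = mean(thy$productive_pair),
    mean_beta_insertions = mean(beta_att$ins1 + beta_att$ins2)
  )
  class(out) <- "summary.repertoire"
  out
}

#' @export
print.summary.repertoire <- function(x, ...) {
  cat(sprintf(
    paste0("Thymocytes attempted: %d\n",
           "  valid beta chain   : %.1f%% of thymocytes\n",
           "  valid alpha chain  : %.1f%% of those reaching alpha\n",
           "  productive pair    : %.1f%% of thymocytes\n",
           "  beta insertions    : %.2f nt per attempt (two junctions)\n"),
    x$n_attempted, 100 * x$beta_valid, 100 * x$alpha_valid,
    100 * x$pair_valid, x$mean_beta_insertions))
  invisible(x)
}

# ---- clonotypes -------------------------------------------------------------

translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# scalar clonotype worker on plain vectors (fast path for repertoire assembly)
clonotype_core <- function(sequence, v_len, orf, ins1, ins2, d_seq, flank_nt) {
  n <- nchar(sequence)
  mid <- ins1
  if (!is.na(ins2)) mid <- mid + nchar(d_seq) + ins2
  a <- max(v_len - flank_nt + 1L, orf)
  b <- min(v_len + mid + flank_nt, n)
  # codons of the ORF overlapping [a, b]
  i1 <- max(1L, (a - orf) %/% 3L + 1L)
  i2 <- min((n - orf + 1L) %/% 3L, (b - orf) %/% 3L + 1L)
  starts <- orf + 3L * (seq.int(i1, i2) - 1L)
  translate_codons(substring(sequence, starts, starts + 2L))
}

#' CDR3-like clonotype of a productive rearrangement
#'
#' Translates, in the productive reading frame, the codons overlapping the
#' junction window: the last `flank_nt` nucleotides of the V segment, all
#' inserted nucleotides (and the D segment for beta chains), and the first
#' `flank_nt` nucleotides of the J segment. Two rearrangements using the
#' same segments and insertions therefore share a clonotype.
#'
#' @param attempt A productive `chain_attempt` (or one row of a repertoire
#'   attempts table that retained sequences).
#' @param flank_nt Number of V and J nucleotides flanking the junction
#'   (default 9).
#' @return Amino-acid string.
#' @export
clonotype <- function(attempt, flank_nt = 9L) {
  if (!isTRUE(attempt$productive[1])) {
    stopf("clonotype() is defined only for productive attempts")
  }
  if (is.null(attempt$sequence) || is.na(attempt$sequence[1])) {
    stopf("attempt must carry its assembled sequence (keep_sequences = TRUE)")
  }
  clonotype_core(attempt$sequence[1], attempt$v_len[1], attempt$orf_start[1],
                 attempt$ins1[1], attempt$ins2[1], attempt$d_seq[1],
                 as.integer(flank_nt))
}

# ---- saturation statistics --------------------------------------------------

#' Sub-sampling saturation statistics of a repertoire
#'
#' For each subsample size and random replicate, draws productive thymocytes
#' without replacement and computes (i) V/(D)/J segment usage proportions per
#' chain and (ii) the Shannon entropy (bits by default) of the CDR3
#' clonotype distributions. Used to judge how many cells a TCR-sequencing
#' experiment must capture before diversity estimates saturate.
#'
#' @param repertoire A [simulate_repertoire()] result.
#' @param sizes Subsample sizes; each must not exceed the number of
#'   productive pairs.
#' @param n_seeds Number of random subsample replicates per size.
#' @param seed Seed for the subsampling RNG.
#' @param base Entropy logarithm base (2 = bits).
#' @return An object of class `saturation_table`: a list with `usage`
#'   (size, seed, chain, segtype, segment, proportion) and `entropy`
#'   (size, seed, chain, entropy).
#' @export
saturation_stats <- function(repertoire, sizes, n_seeds = 10L, seed = 1L,
                             base = 2) {
  thy <- repertoire$thymocytes
  att <- repertoire$attempts
  prod_ids <- thy$thymocyte[thy$productive_pair]
  if (length(prod_ids) == 0L) stopf("repertoire has no productive pairs")
  if (any(sizes > length(prod_ids))) {
    stopf("subsample size exceeds the %d productive pairs available",
          length(prod_ids))
  }
  if (any(sizes < 1)) stopf("subsample sizes must be >= 1")
  hit <- att[att$productive, , drop = FALSE]
  hit <- hit[hit$thymocyte %in% prod_ids, , drop = FALSE]
  usage_rows <- list()
  entropy_rows <- list()
  with_seed(seed, {
    for (size in sizes) {
      for (s in seq_len(n_seeds)) {
        ids <- sample(prod_ids, size)
        sub <- hit[hit$thymocyte %in% ids, , drop = FALSE]
        for (ch in c("alpha", "beta")) {
          chs <- sub[sub$chain == ch, , drop = FALSE]
          segtypes <- if (ch == "beta") c("v", "d", "j") else c("v", "j")
          for (st in segtypes) {
            tab <- table(chs[[st]])
            usage_rows[[length(usage_rows) + 1L]] <- data.frame(
              size = size, seed = s, chain = ch, segtype = toupper(st),
              segment = names(tab),
              proportion = as.numeric(tab) / sum(tab),
              stringsAsFactors = FALSE
            )
          }
          clon <- if (ch == "beta") thy$clonotype_beta else thy$clonotype_alpha
          clon <- clon[match(ids, thy$thymocyte)]
          entropy_rows[[length(entropy_rows) + 1L]] <- data.frame(
            size = size, seed = s, chain = ch,
            entropy = shannon_entropy(clon, base = base)
          )
        }
      }
    }
  })
  out <- list(usage = do.call(rbind, usage_rows),
              entropy = do.call(rbind, entropy_rows))
  class(out) <- "saturation_table"
  out
}

#' @export
print.saturation_table <- function(x, ...) {
  cat(sprintf("<saturation_table> sizes: %s; %d entropy rows\n",
              paste(sort(unique(x$entropy$size)), collapse = ", "),
              nrow(x$entropy)))
  invisible(x)
}
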