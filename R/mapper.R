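#' Quality-trim paired reads with a sliding window
#'
#' Scans 5'->3' with a window of `window` bases; at the first window whose
#' mean quality drops below `q_threshold` the read is cut at the first
#' individual base inside that window that is itself below the threshold
#' (so a high-quality prefix of the failing window is kept). Pairs in which
#' either trimmed mate is shorter than `min_length` are dropped whole.
#'
#' @param reads A `read_set` data.frame (see [read_fastq_pair()]).
#' @param window Window width (>= 1).
#' @param q_threshold Mean-quality threshold (phred).
#' @param min_length Minimum surviving read length.
#' @return A trimmed `read_set`; the number of dropped pairs is in
#'   attribute `n_dropped`.
#' @export
trim_reads <- function(reads, window = 4L, q_threshold = 15L,
                       min_length = 36L) {
  stopifnot(window >= 1L)
  cut_of <- local({
    memo <- new.env(parent = emptyenv())
    function(qual) {
      hit <- memo[[qual]]
      if (!is.null(hit)) return(hit)
      q <- utf8ToInt(qual) - 33L
      n <- length(q)
      keep <- n
      if (n >= window) {
        cs <- cumsum(c(0L, q))
        means <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) /
          window
        bad <- which(means < q_threshold)
        if (length(bad) > 0L) {
          i <- bad[1L]
          low <- which(q[i:n] < q_threshold)
          keep <- if (length(low) > 0L) i + low[1L] - 2L else n
        }
      }
      memo[[qual]] <- keep
      keep
    }
  })
  k1 <- vapply(reads$qual1, cut_of, integer(1L), USE.NAMES = FALSE)
  k2 <- vapply(reads$qual2, cut_of, integer(1L), USE.NAMES = FALSE)
  ok <- k1 >= min_length & k2 >= min_length
  out <- reads[ok, , drop = FALSE]
  out$seq1 <- substr(out$seq1, 1L, k1[ok])
  out$qual1 <- substr(out$qual1, 1L, k1[ok])
  out$seq2 <- substr(out$seq2, 1L, k2[ok])
  out$qual2 <- substr(out$qual2, 1L, k2[ok])
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Build an exact-match k-mer index over a reference set
#'
#' Every genome is indexed on both strands; circular genomes are indexed on
#' sequence + prefix(k-1) so k-mers spanning the origin are found. Each
#' k-mer maps to all its (genome, position, strand) hits.
#'
#' @param references List of [genome_record] with unique ids.
#' @param k K-mer size (default 31); must not exceed the shortest genome.
#' @return A `kmer_index` object.
#' @export
build_index <- function(references, k = 31L) {
  ids <- vapply(references, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  if (k > min(vapply(references, `[[`, 1L, "length"))) {
    stop("k exceeds the shortest genome")
  }
  env <- new.env(parent = emptyenv(), size = 2L^18L)
  pad <- 512L
  padded_seqs <- character(length(references))
  for (gi in seq_along(references)) {
    g <- references[[gi]]
    padded_seqs[gi] <- padded_sequence(g, pad)
    idx_pad <- padded_sequence(g, k - 1L)
    np <- nchar(idx_pad) - k + 1L
    kmers <- substring(idx_pad, seq_len(np), seq_len(np) + k - 1L)
    for (p in seq_len(np)) {
      km <- kmers[p]
      env[[km]] <- rbind(env[[km]], c(gi, p))
    }
  }
  structure(list(env = env, k = k, references = references, ids = ids,
                 padded = padded_seqs, pad = pad),
            class = "kmer_index")
}

#' Look up a k-mer in the index
#'
#' @param index A `kmer_index`.
#' @param kmer K-mer string of the index's k.
#' @return data.frame `genome_id`, `pos` (1-based start of the match on the
#'   top strand), `strand` (`"+"` for a top-strand match of `kmer`, `"-"`
#'   where the reverse strand carries it).
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(nchar(kmer) == index$k)
  fwd <- index$env[[kmer]]
  rc <- index$env[[revcomp(kmer)]]
  rows <- list()
  if (!is.null(fwd)) {
    rows[[1L]] <- data.frame(genome_id = index$ids[fwd[, 1L]],
                             pos = fwd[, 2L], strand = "+",
                             stringsAsFactors = FALSE)
  }
  if (!is.null(rc)) {
    rows[[2L]] <- data.frame(genome_id = index$ids[rc[, 1L]],
                             pos = rc[, 2L], strand = "-",
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(genome_id = character(0), pos = integer(0),
                      strand = character(0)))
  }
  do.call(rbind, rows)
}

# Hamming distance between equal-length strings.
hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# Global-in-read, free-ends-in-window edit alignment with traceback.
# Returns list(score, ref_from, ref_to (1-based in window), ops), where ops
# is a data.frame(type M/D/I, ref_off (0-based offset in window; for I the
# offset of the base the insertion follows), base).
align_in_window <- function(read, window) {
  n <- nchar(read); m <- nchar(window)
  r <- utf8ToInt(read); w <- utf8ToInt(window)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  # bitmask of optimal moves: 1 diagonal, 2 up (insertion), 4 left (del)
  P <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    sub <- D[i, 1:m] + (r[i] != w)
    up <- D[i, 2:(m + 1L)] + 1L
    base <- pmin(sub, up)
    # left (window-base deletion) closes under unit costs via a running
    # minimum: row[j] = min(base[j], min_{j' <= j}(base[j'] + j - j'))
    row <- pmin(base, cummin(c(D[i + 1L, 1L], base) - 0:m)[1:m] + 1:m)
    D[i + 1L, 2:(m + 1L)] <- row
    P[i + 1L, 2:(m + 1L)] <- (row == sub) + 2L * (row == up)
  }
  # the left-move flag needs the finished row: left is optimal at (i, j)
  # when D[i, j-1] + 1 == D[i, j]
  P[, 2:(m + 1L)] <- P[, 2:(m + 1L)] +
    4L * (D[, 1:m, drop = FALSE] + 1L == D[, 2:(m + 1L), drop = FALSE])
  ends <- D[n + 1L, ]
  j <- which.min(ends) - 1L   # 0-based window column of alignment end
  score <- ends[j + 1L]
  # traceback; on ties prefer continuing the current gap so indels stay
  # contiguous, then the diagonal
  ops <- list(); i <- n; jj <- j; prev <- 0L
  while (i > 0L) {
    mask <- if (jj == 0L) 2L else P[i + 1L, jj + 1L]
    move <- if (prev == 4L && bitwAnd(mask, 4L) > 0L) 4L
            else if (prev == 2L && bitwAnd(mask, 2L) > 0L) 2L
            else if (bitwAnd(mask, 1L) > 0L) 1L
            else if (bitwAnd(mask, 4L) > 0L) 4L
            else 2L
    if (move == 1L) {
      ops[[length(ops) + 1L]] <- c("M", jj, substr(read, i, i))
      i <- i - 1L; jj <- jj - 1L
    } else if (move == 2L) {
      ops[[length(ops) + 1L]] <- c("I", jj, substr(read, i, i))
      i <- i - 1L
    } else {
      ops[[length(ops) + 1L]] <- c("D", jj, "")
      jj <- jj - 1L
    }
    prev <- move
  }
  ops <- ops[rev(seq_along(ops))]
  opdf <- data.frame(type = vapply(ops, `[`, "", 1L),
                     ref_off = as.integer(vapply(ops, `[`, "", 2L)),
                     base = vapply(ops, `[`, "", 3L),
                     stringsAsFactors = FALSE)
  list(score = score, ref_from = jj + 1L, ref_to = j, ops = opdf)
}

# One mate against one candidate locus. Fast paths: exact/Hamming, then
# windowed (banded) DP. Returns NULL or an alignment record. Positions are
# reported un-wrapped (may exceed L on circular genomes; reduce mod L when
# needed) so that start <= end always holds.
align_candidate <- function(seq, index, gi, cand_start, band, max_mm) {
  n <- nchar(seq)
  genome <- index$references[[gi]]
  L <- genome$length
  padded <- index$padded[gi]
  circular <- genome$topology == "circular"
  start <- if (circular) ((cand_start - 1L) %% L) + 1L else cand_start
  if (start >= 1L && start + n - 1L <= nchar(padded)) {
    ref_exact <- substr(padded, start, start + n - 1L)
    hd <- hamming(seq, ref_exact)
    if (hd <= max(1L, as.integer(0.04 * n))) {
      if (hd > max_mm) return(NULL)
      return(list(start = start, score = hd, end = start + n - 1L,
                  ops = NULL))   # NULL ops = pure match/mismatch run
    }
  }
  wfrom <- max(1L, start - band)
  wto <- min(nchar(padded), start + n - 1L + band)
  if (wto - wfrom + 1L < n - band) return(NULL)
  window <- substr(padded, wfrom, wto)
  al <- align_in_window(seq, window)
  if (al$score > max_mm) return(NULL)
  astart <- wfrom + al$ref_from - 1L
  aend <- wfrom + al$ref_to - 1L
  if (nrow(al$ops) > 0L) al$ops$ref_pos <- wfrom + al$ops$ref_off - 1L
  list(start = astart, score = al$score, end = aend, ops = al$ops)
}

# Candidate start positions for one mate from seed k-mers.
seed_candidates <- function(seq, index, band) {
  n <- nchar(seq); k <- index$k
  if (n < k) return(NULL)
  offs <- unique(c(1L, max(1L, (n - k) %/% 2L + 1L), n - k + 1L))
  cands <- list()
  for (o in offs) {
    km <- substr(seq, o, o + k - 1L)
    hit <- index$env[[km]]
    if (!is.null(hit)) {
      cands[[length(cands) + 1L]] <-
        cbind(hit[, 1L], hit[, 2L] - o + 1L, 1L)
    }
    rkm <- revcomp(km)
    hit <- index$env[[rkm]]
    if (!is.null(hit)) {
      # read revcomp aligns forward: offset of rc(km) within rc(read)
      ro <- n - (o + k - 1L) + 1L
      cands[[length(cands) + 1L]] <-
        cbind(hit[, 1L], hit[, 2L] - ro + 1L, 2L)
    }
  }
  if (length(cands) == 0L) return(NULL)
  m <- unique(do.call(rbind, cands))
  # cluster starts within the band (per genome/strand), keep the smallest
  o <- order(m[, 1L], m[, 3L], m[, 2L])
  m <- m[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(m))
  if (nrow(m) > 1L) {
    for (i in 2:nrow(m)) {
      if (m[i, 1L] == m[i - 1L, 1L] && m[i, 3L] == m[i - 1L, 3L] &&
          abs(m[i, 2L] - m[i - 1L, 2L]) <= band && keep[i - 1L]) {
        keep[i] <- FALSE
      }
    }
  }
  m[keep, , drop = FALSE]
}

best_mate_alignments <- function(seq, index, band, max_mm) {
  cands <- seed_candidates(seq, index, band)
  if (is.null(cands)) return(NULL)
  out <- list()
  for (i in seq_len(nrow(cands))) {
    s <- if (cands[i, 3L] == 1L) seq else revcomp(seq)
    al <- align_candidate(s, index, cands[i, 1L], cands[i, 2L], band, max_mm)
    if (is.null(al)) next
    al$genome <- cands[i, 1L]
    al$strand <- if (cands[i, 3L] == 1L) "+" else "-"
    al$aseq <- s
    out[[length(out) + 1L]] <- al
  }
  if (length(out) == 0L) return(NULL)
  out
}

#' Assign a read pair to one genome of the double reference and align it
#'
#' Each mate is seeded with its k-mers, candidate loci are extended by a
#' banded alignment (unit costs; the band bounds the start shift), and the
#' pair is assigned to the genome holding the best total pair score under
#' proper (opposite-strand) orientation within `max_insert`. When the best
#' scores on two genomes tie within 1 the pair is
#' `ambiguous_between_genomes` and is excluded from the pileup; ties
#' between loci inside the winning genome give
#' `ambiguous_within_genome`.
#'
#' @param seq1,seq2 Mate sequences (trimmed).
#' @param index A `kmer_index` (see [build_index()]).
#' @param max_mismatch_rate Maximum edits per base tolerated per mate.
#' @param band Banded-alignment half-width (default 8).
#' @param max_insert Maximum insert size for a proper pair.
#' @return `NULL` when unmapped, else list with `genome_id`, `uniqueness`,
#'   `score` and per-mate records (`start`, `end`, `strand`, `score`,
#'   `ops`).
#' @export
assign_and_align <- function(seq1, seq2, index, max_mismatch_rate = 0.1,
                             band = 8L, max_insert = 2000L) {
  mm1 <- as.integer(max_mismatch_rate * nchar(seq1))
  mm2 <- as.integer(max_mismatch_rate * nchar(seq2))
  a1 <- best_mate_alignments(seq1, index, band, mm1)
  a2 <- best_mate_alignments(seq2, index, band, mm2)
  if (is.null(a1) || is.null(a2)) return(NULL)
  best <- NULL
  per_genome_best <- rep(NA_integer_, length(index$references))
  n_best_loci <- 0L
  for (x in a1) for (y in a2) {
    if (x$genome != y$genome) next
    if (x$strand == y$strand) next
    L <- index$references[[x$genome]]$length
    d <- abs(x$start - y$start)
    d <- min(d, L - d)
    if (d > max_insert) next
    sc <- x$score + y$score
    g <- x$genome
    if (is.na(per_genome_best[g]) || sc < per_genome_best[g]) {
      per_genome_best[g] <- sc
    }
    if (is.null(best) || sc < best$score) {
      best <- list(genome = g, score = sc, r1 = x, r2 = y)
      n_best_loci <- 1L
    } else if (sc == best$score &&
               (g != best$genome || x$start != best$r1$start)) {
      n_best_loci <- n_best_loci + 1L
    }
  }
  if (is.null(best)) return(NULL)
  others <- per_genome_best[-best$genome]
  between <- any(!is.na(others) & others - best$score <= 1L)
  uniqueness <- if (between) "ambiguous_between_genomes"
                else if (n_best_loci > 1L) "ambiguous_within_genome"
                else "unique"
  list(genome_id = index$ids[best$genome], uniqueness = uniqueness,
       score = best$score,
       r1 = best$r1[c("start", "end", "strand", "score", "ops", "aseq")],
       r2 = best$r2[c("start", "end", "strand", "score", "ops", "aseq")])
}

#' Map all pairs of a read set
#'
#' Thin loop over [assign_and_align()] that also keeps the read-fate
#' ledger: assigned + ambiguous + unmapped equals the number of input
#' pairs.
#'
#' @param reads Trimmed `read_set`.
#' @param index A `kmer_index`.
#' @inheritParams assign_and_align
#' @return List with `alignments` (per pair; `NULL` for unmapped) and
#'   `fate` (named counts: unique, ambiguous_within_genome,
#'   ambiguous_between_genomes, unmapped).
#' @export
map_reads <- function(reads, index, max_mismatch_rate = 0.1, band = 8L,
                      max_insert = 2000L) {
  n <- nrow(reads)
  out <- vector("list", n)
  fate <- c(unique = 0L, ambiguous_within_genome = 0L,
            ambiguous_between_genomes = 0L, unmapped = 0L)
  for (i in seq_len(n)) {
    al <- assign_and_align(reads$seq1[i], reads$seq2[i], index,
                           max_mismatch_rate, band, max_insert)
    if (is.null(al)) {
      fate["unmapped"] <- fate["unmapped"] + 1L
    } else {
      fate[al$uniqueness] <- fate[al$uniqueness] + 1L
      al$id <- reads$id[i]
      out[[i]] <- al
    }
  }
  list(alignments = out, fate = fate)
}
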