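BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)
DEL_CODE <- 6L

# Shift an anchored indel left to its canonical (left-aligned) position,
# so planted and called indels share one representation.
left_normalize_indel <- function(seq, pos, ref, alt) {
  if (nchar(ref) > nchar(alt)) {           # deletion of k bases after pos
    k <- nchar(ref) - 1L
    while (pos > 1L &&
           substr(seq, pos, pos) == substr(seq, pos + k, pos + k)) {
      pos <- pos - 1L
    }
    list(pos = pos, ref = substr(seq, pos, pos + k),
         alt = substr(seq, pos, pos))
  } else {                                  # insertion of x after pos
    x <- substr(alt, 2L, nchar(alt))
    k <- nchar(x)
    while (pos > 1L &&
           substr(x, k, k) == substr(seq, pos, pos)) {
      x <- paste0(substr(seq, pos, pos), substr(x, 1L, k - 1L))
      pos <- pos - 1L
    }
    a <- substr(seq, pos, pos)
    list(pos = pos, ref = a, alt = paste0(a, x))
  }
}

# Per-mate record extraction: positions/codes of matched columns, deleted
# reference positions, insertions (anchor, sequence).
mate_columns <- function(mate) {
  if (is.null(mate$ops)) {
    list(pos = seq.int(mate$start, mate$end),
         code = unname(BASE_CODE[strsplit(mate$aseq, "", fixed = TRUE)[[1L]]]),
         del = integer(0), del_events = NULL, ins = NULL,
         span = c(mate$start, mate$end))
  } else {
    ops <- mate$ops
    mrows <- ops$type == "M"
    irows <- which(ops$type == "I")
    ins <- NULL
    if (length(irows) > 0L) {
      by_anchor <- split(ops$base[irows], ops$ref_pos[irows])
      ins <- data.frame(pos = as.integer(names(by_anchor)),
                        seq = vapply(by_anchor, paste, "", collapse = ""),
                        stringsAsFactors = FALSE)
    }
    del_pos <- ops$ref_pos[ops$type == "D"]
    del_events <- NULL
    if (length(del_pos) > 0L) {
      runs <- split(del_pos, cumsum(c(1L, diff(del_pos) != 1L)))
      del_events <- data.frame(
        pos = vapply(runs, function(r) r[1L] - 1L, integer(1L)),
        len = lengths(runs), row.names = NULL)
    }
    list(pos = ops$ref_pos[mrows],
         code = unname(BASE_CODE[ops$base[mrows]]),
         del = del_pos, del_events = del_events, ins = ins,
         span = c(mate$start, mate$end))
  }
}

#' Pile up assigned alignments and call haploid consensus variants
#'
#' Organelle samples are treated as homoplasmic: a variant is emitted when
#' the top non-reference allele at a column reaches `min_fraction` of a
#' depth of at least `min_depth`; columns whose top non-reference allele
#' stays below the fraction are flagged mixed and never genotyped. Indels
#' are called from gap runs with VCF anchoring and left-normalized. Columns
#' inside microsatellite tracts are unreliable, so tract length is instead
#' genotyped as the mode over reads that fully span the tract plus 5 bp
#' flanks; a whole-unit difference is emitted as an `ssr_length` variant.
#' Pairs ambiguous between genomes are excluded from the pileup (as are
#' within-genome ambiguous placements).
#'
#' @param mapped Output of [map_reads()].
#' @param references List of [genome_record].
#' @param sample_id Sample name for the genotype column.
#' @param min_depth Minimum depth to call (default 10).
#' @param min_fraction Minimum top-allele fraction (default 0.8).
#' @param mask_ambiguous Exclude `ambiguous_between_genomes` pairs
#'   (default `TRUE`).
#' @param ssr_loci Optional data.frame from [detect_ssr_loci()] (with a
#'   `genome_id` column); computed from the references when `NULL`.
#' @return List with `variants` (single-sample [variant_set]), `no_call`
#'   (data.frame of 1-based closed intervals below `min_depth`), `mixed`
#'   (positions failing the consensus fraction), `coverage` (per-genome
#'   mean/median depth) and `fate` (read-pair counts).
#' @export
pileup_and_call <- function(mapped, references, sample_id = "sample",
                            min_depth = 10L, min_fraction = 0.8,
                            mask_ambiguous = TRUE, ssr_loci = NULL) {
  ids <- vapply(references, `[[`, "", "id")
  if (is.null(ssr_loci)) {
    ssr_loci <- do.call(rbind, lapply(references, function(g) {
      s <- detect_ssr_loci(g)
      if (nrow(s) > 0L) cbind(genome_id = g$id, s) else NULL
    }))
  }
  keep_class <- "unique"
  if (!mask_ambiguous) keep_class <- c(keep_class,
                                       "ambiguous_between_genomes")
  mates <- stats::setNames(vector("list", length(ids)), ids)
  for (gid in ids) mates[[gid]] <- list()
  for (al in mapped$alignments) {
    if (is.null(al) || !(al$uniqueness %in% keep_class)) next
    mates[[al$genome_id]] <-
      c(mates[[al$genome_id]],
        list(mate_columns(al$r1), mate_columns(al$r2)))
  }
  var_rows <- list(); no_call <- list(); mixed <- list(); coverage <- list()
  for (gid in ids) {
    g <- references[[which(ids == gid)]]
    L <- g$length
    ms <- mates[[gid]]
    pos_all <- unlist(lapply(ms, `[[`, "pos"), use.names = FALSE)
    code_all <- unlist(lapply(ms, `[[`, "code"), use.names = FALSE)
    if (length(pos_all) > 0L) pos_all <- ((pos_all - 1L) %% L) + 1L
    cnt <- matrix(tabulate((pos_all - 1L) * 6L + code_all, nbins = 6L * L),
                  nrow = 6L)
    del_pos <- unlist(lapply(ms, `[[`, "del"), use.names = FALSE)
    if (length(del_pos) > 0L) {
      del_pos <- ((del_pos - 1L) %% L) + 1L
      cnt[DEL_CODE, ] <- tabulate(del_pos, nbins = L)
    }
    depth <- colSums(cnt)
    ref_code <- unname(BASE_CODE[strsplit(g$sequence, "", fixed = TRUE)[[1L]]])
    my_ssr <- if (!is.null(ssr_loci)) {
      ssr_loci[ssr_loci$genome_id == gid, , drop = FALSE]
    } else NULL
    in_ssr <- rep(FALSE, L)
    if (!is.null(my_ssr) && nrow(my_ssr) > 0L) {
      for (s in seq_len(nrow(my_ssr))) {
        in_ssr[max(1L, my_ssr$start[s] - 1L):min(L, my_ssr$end[s] + 1L)] <-
          TRUE
      }
    }
    callable <- depth >= min_depth
    top_code <- max.col(t(cnt[1:4, , drop = FALSE]), ties.method = "first")
    top_n <- cnt[cbind(top_code, seq_len(L))]
    frac <- top_n / pmax(depth, 1L)
    is_snp <- callable & !in_ssr & top_code != ref_code &
      frac >= min_fraction
    is_mixed <- callable & !in_ssr & top_code != ref_code &
      frac < min_fraction & frac >= 0.2
    for (p in which(is_snp)) {
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        genome_id = gid, pos = p, ref = names(BASE_CODE)[ref_code[p]],
        alt = names(BASE_CODE)[top_code[p]], var_class = "snp",
        stringsAsFactors = FALSE)
    }
    if (any(is_mixed)) {
      mixed[[length(mixed) + 1L]] <- data.frame(
        genome_id = gid, pos = which(is_mixed), stringsAsFactors = FALSE)
    }
    # indel events: each mate's gap runs, left-normalized so equivalent
    # placements collapse to one canonical record, then consensus-called
    # against the depth at the (normalized) anchor column
    events <- list()
    for (mc in ms) {
      if (!is.null(mc$del_events)) {
        for (ei in seq_len(nrow(mc$del_events))) {
          anchor <- ((mc$del_events$pos[ei] - 1L) %% L) + 1L
          len <- mc$del_events$len[ei]
          if (anchor < 1L || anchor + len > L) next
          nv <- left_normalize_indel(g$sequence, anchor,
                                     substr(g$sequence, anchor,
                                            anchor + len),
                                     substr(g$sequence, anchor, anchor))
          events[[length(events) + 1L]] <-
            data.frame(pos = nv$pos, ref = nv$ref, alt = nv$alt,
                       var_class = "deletion", stringsAsFactors = FALSE)
        }
      }
      if (!is.null(mc$ins)) {
        for (ei in seq_len(nrow(mc$ins))) {
          p <- ((mc$ins$pos[ei] - 1L) %% L) + 1L
          a <- substr(g$sequence, p, p)
          nv <- left_normalize_indel(g$sequence, p, a,
                                     paste0(a, mc$ins$seq[ei]))
          events[[length(events) + 1L]] <-
            data.frame(pos = nv$pos, ref = nv$ref, alt = nv$alt,
                       var_class = "insertion", stringsAsFactors = FALSE)
        }
      }
    }
    if (length(events) > 0L) {
      ev <- do.call(rbind, events)
      key <- paste(ev$pos, ev$ref, ev$alt, ev$var_class)
      freq <- table(key)
      ev <- ev[!duplicated(key), , drop = FALSE]
      ev$n <- as.integer(freq[key[!duplicated(key)]])
      ev <- ev[order(ev$pos, -ev$n), , drop = FALSE]
      spans <- if (length(ms) > 0L) {
        t(vapply(ms, `[[`, integer(2L), "span"))
      } else matrix(integer(0), 0L, 2L)
      for (ii in seq_len(nrow(ev))) {
        p <- ev$pos[ii]
        if (!callable[p] || in_ssr[p]) next
        # consensus over mates that span the event with a k+6 bp flank: a
        # mate ending at or just past the anchor cannot exhibit the indel
        # (under unit costs a short mismatched tail is cheaper than a gap)
        # and must not dilute the fraction
        k <- max(nchar(ev$ref[ii]), nchar(ev$alt[ii])) - 1L
        lo <- p - 2L; hi <- p + k + (k + 6L)
        spanning <- sum((spans[, 1L] <= lo & spans[, 2L] >= hi) |
                          (spans[, 1L] <= lo + L & spans[, 2L] >= hi + L))
        if (spanning < min_depth) next
        if (ev$n[ii] / spanning < min_fraction) next
        var_rows[[length(var_rows) + 1L]] <- ev[ii, c("pos", "ref", "alt",
                                                      "var_class")] |>
          cbind(genome_id = gid)
      }
    }
    # SSR tract length from spanning reads
    if (!is.null(my_ssr) && nrow(my_ssr) > 0L && length(ms) > 0L) {
      spans <- t(vapply(ms, `[[`, integer(2L), "span"))
      for (s in seq_len(nrow(my_ssr))) {
        tr <- my_ssr[s, ]
        ref_len <- tr$end - tr$start + 1L
        covering <- which(spans[, 1L] <= tr$start - 5L &
                            spans[, 2L] >= tr$end + 5L)
        if (length(covering) < min_depth) next
        obs <- vapply(covering, function(ci) {
          mc <- ms[[ci]]
          n <- sum(mc$pos >= tr$start & mc$pos <= tr$end)
          if (!is.null(mc$ins)) {
            inside <- mc$ins$pos >= tr$start - 1L & mc$ins$pos <= tr$end
            n <- n + sum(nchar(mc$ins$seq[inside]))
          }
          n
        }, integer(1L))
        tab_l <- table(obs)
        mode_len <- as.integer(names(tab_l)[which.max(tab_l)])
        if (max(tab_l) / length(obs) < min_fraction) next
        diff <- mode_len - ref_len
        if (diff == 0L) next
        anchor <- tr$start - 1L
        anchor_b <- substr(g$sequence, anchor, anchor)
        if (diff < 0L) {
          ref <- substr(g$sequence, anchor, anchor - diff)
          alt <- anchor_b
        } else {
          unit <- substr(g$sequence, tr$start, tr$start + tr$period - 1L)
          ins <- substr(strrep(unit, diff %/% tr$period + 1L), 1L, diff)
          ref <- anchor_b
          alt <- paste0(anchor_b, ins)
        }
        cls <- if (diff %% tr$period == 0L) "ssr_length"
               else if (diff < 0L) "deletion" else "insertion"
        var_rows[[length(var_rows) + 1L]] <- data.frame(
          genome_id = gid, pos = anchor, ref = ref, alt = alt,
          var_class = cls, stringsAsFactors = FALSE)
      }
    }
    # no-call intervals
    if (any(!callable)) {
      runs <- rle(!callable)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (ri in which(runs$values)) {
        no_call[[length(no_call) + 1L]] <- data.frame(
          genome_id = gid, start = starts[ri], end = ends[ri],
          stringsAsFactors = FALSE)
      }
    }
    coverage[[length(coverage) + 1L]] <- data.frame(
      genome_id = gid, mean_depth = mean(depth),
      median_depth = stats::median(depth), stringsAsFactors = FALSE)
  }
  tab <- if (length(var_rows)) do.call(rbind, var_rows) else
    data.frame(genome_id = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               var_class = character(0), stringsAsFactors = FALSE)
  o <- order(tab$genome_id, tab$pos)
  tab <- tab[o, , drop = FALSE]
  gt <- matrix(1L, nrow = nrow(tab), ncol = 1L,
               dimnames = list(NULL, sample_id))
  list(variants = variant_set(tab, gt),
       no_call = if (length(no_call)) do.call(rbind, no_call) else NULL,
       mixed = if (length(mixed)) do.call(rbind, mixed) else NULL,
       coverage = do.call(rbind, coverage),
       fate = mapped$fate)
}

#' Call one sample end to end (trim, map, pile up)
#'
#' @param reads A raw `read_set`.
#' @param references Reference genomes.
#' @param index Optional prebuilt [build_index()] result.
#' @param sample_id Sample name.
#' @param trim_params,map_params,call_params Parameter lists forwarded to
#'   [trim_reads()], [map_reads()], [pileup_and_call()].
#' @return As [pileup_and_call()].
#' @export
call_sample <- function(reads, references, index = NULL,
                        sample_id = "sample", trim_params = list(),
                        map_params = list(), call_params = list()) {
  if (is.null(index)) index <- build_index(references)
  trimmed <- do.call(trim_reads, c(list(reads), trim_params))
  mapped <- do.call(map_reads, c(list(trimmed, index), map_params))
  do.call(pileup_and_call,
          c(list(mapped, references, sample_id = sample_id), call_params))
}
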