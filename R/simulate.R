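# Derive a stage-specific RNG seed from a global seed and a stage name,
# keeping the result inside 32-bit integer range.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

NON_STOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

# Map a 1-based coding-strand CDS offset to its genomic coordinate.
coding_to_genomic <- function(gene, off) {
  rest <- off
  for (e in seq_len(nrow(gene$exons))) {
    ex <- gene$exons[e, ]
    len <- ex[2L] - ex[1L] + 1L
    if (rest <= len) {
      return(if (gene$strand == "+") ex[1L] + rest - 1L else ex[2L] - rest + 1L)
    }
    rest <- rest - len
  }
  stop("offset beyond CDS")
}

#' Generate a toy chloroplast + mitochondrial reference pair
#'
#' Builds a circular chloroplast-like replicon carrying `n_genes` CDSs
#' (at least one with an intron and at least one on the minus strand, named
#' after classic plastid loci), microsatellite tracts, and a segment copied
#' verbatim into a larger circular mitochondrial-like replicon — the
#' cross-homology that makes some reads ambiguous between organelles.
#' Deterministic for a fixed seed.
#'
#' @param config List overriding any of: `cp_length` (>= 5000), `mt_length`
#'   (>= cp_length), `n_genes`, `n_introns`, `ssr_spec` (list of
#'   `list(motif, units)`), `shared_segment_length`.
#' @param seed Integer seed.
#' @return List with `references` (cp then mt [genome_record]),
#'   `gene_models`, `ssr_loci` (data.frame with `genome_id`), `shared`
#'   (data.frame of the homologous segment on both genomes) and `config`.
#' @export
generate_references <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(list(
    cp_length = 6000L, mt_length = 9000L, n_genes = 6L, n_introns = 1L,
    ssr_spec = list(list(motif = "A", units = 12L),
                    list(motif = "AT", units = 6L)),
    shared_segment_length = 400L), config)
  stopifnot(cfg$cp_length >= 5000L, cfg$mt_length >= cfg$cp_length,
            cfg$shared_segment_length >= 0L)
  withr::with_seed(stage_seed(seed, "refs"), {
    cp <- strsplit(random_dna(cfg$cp_length), "")[[1L]]
    gene_names <- c("matK_like", "infA_like", "ndhA_like", "ndhK_like",
                    "ndhG_like", "rpoC1_like", "rpoA_like", "psaA_like",
                    "atpA_like", "ndhD_like")
    if (cfg$n_genes > length(gene_names)) {
      gene_names <- c(gene_names,
                      paste0("orf", seq_len(cfg$n_genes - length(gene_names))))
    }
    models <- list()
    cursor <- 301L
    tail_reserve <- cfg$shared_segment_length + 400L
    for (i in seq_len(cfg$n_genes)) {
      n_codons <- sample(60:110, 1L)
      cds_len <- 3L * n_codons
      intron_len <- if (i <= cfg$n_introns) sample(80:120, 1L) else 0L
      span <- cds_len + intron_len
      if (cursor + span > cfg$cp_length - tail_reserve) {
        stop("gene layout infeasible at the given cp_length")
      }
      strand <- if (i %% 2L == 0L) "-" else "+"
      codons <- c("ATG", sample(NON_STOP_CODONS, n_codons - 2L,
                                replace = TRUE), "TAA")
      # guarantee plantable codons: an editable Ser (TCA) and a silent
      # third-position C site (GGC)
      codons[10L] <- "TCA"; codons[11L] <- "GGC"
      cds <- paste(codons, collapse = "")
      if (intron_len > 0L) {
        l1 <- 3L * (n_codons %/% 2L) + 1L  # junction inside a codon
        exons <- rbind(c(cursor, cursor + l1 - 1L),
                       c(cursor + l1 + intron_len, cursor + span - 1L))
        intron <- strsplit(paste0("GT", random_dna(intron_len - 4L), "AG"),
                           "")[[1L]]
        if (strand == "+") {
          cp[exons[1L, 1L]:exons[1L, 2L]] <-
            strsplit(substr(cds, 1L, l1), "")[[1L]]
          cp[exons[2L, 1L]:exons[2L, 2L]] <-
            strsplit(substr(cds, l1 + 1L, cds_len), "")[[1L]]
        } else {
          l2 <- cds_len - l1
          cp[exons[1L, 1L]:exons[1L, 2L]] <-
            strsplit(revcomp(substr(cds, l2 + 1L, cds_len)), "")[[1L]]
          cp[exons[2L, 1L]:exons[2L, 2L]] <-
            strsplit(revcomp(substr(cds, 1L, l2)), "")[[1L]]
        }
        cp[(exons[1L, 2L] + 1L):(exons[2L, 1L] - 1L)] <- intron
      } else {
        exons <- rbind(c(cursor, cursor + cds_len - 1L))
        seq_in <- if (strand == "+") cds else revcomp(cds)
        cp[cursor:(cursor + cds_len - 1L)] <- strsplit(seq_in, "")[[1L]]
      }
      models[[i]] <- gene_model(gene_names[i], "cp_ref", strand, exons)
      cursor <- cursor + span + sample(150:250, 1L)
    }
    # SSR tracts after the genes, with non-motif flanks so tracts are
    # maximal and unambiguous
    ssr <- list()
    cursor <- cursor + 60L
    for (ts in cfg$ssr_spec) {
      tract <- strrep(ts$motif, ts$units)
      tl <- nchar(tract)
      if (cursor + tl + 2L > cfg$cp_length - tail_reserve) {
        stop("gene layout infeasible: no room for SSR tracts")
      }
      flank <- setdiff(c("C", "G"), strsplit(ts$motif, "")[[1L]])
      cp[cursor - 1L] <- flank[1L]
      cp[cursor + tl] <- flank[length(flank)]
      cp[cursor:(cursor + tl - 1L)] <- strsplit(tract, "")[[1L]]
      ssr[[length(ssr) + 1L]] <- data.frame(
        genome_id = "cp_ref", start = cursor, end = cursor + tl - 1L,
        motif = ts$motif, period = nchar(ts$motif), n_units = ts$units,
        stringsAsFactors = FALSE)
      cursor <- cursor + tl + 40L
    }
    mt <- strsplit(random_dna(cfg$mt_length), "")[[1L]]
    shared <- NULL
    if (cfg$shared_segment_length > 0L) {
      src_start <- cfg$cp_length - cfg$shared_segment_length - 49L
      dst_start <- 2001L
      seg <- cp[src_start:(src_start + cfg$shared_segment_length - 1L)]
      mt[dst_start:(dst_start + cfg$shared_segment_length - 1L)] <- seg
      shared <- data.frame(
        genome_id = c("cp_ref", "mt_ref"),
        start = c(src_start, dst_start),
        end = c(src_start, dst_start) + cfg$shared_segment_length - 1L,
        stringsAsFactors = FALSE)
    }
    refs <- list(
      genome_record("cp_ref", paste(cp, collapse = ""), "circular",
                    "chloroplast"),
      genome_record("mt_ref", paste(mt, collapse = ""), "circular",
                    "mitochondrion"))
    list(references = refs, gene_models = models,
         ssr_loci = if (length(ssr)) do.call(rbind, ssr) else NULL,
         shared = shared, config = cfg)
  })
}

# ---- haplotype planting -------------------------------------------------

# Positions within `margin` of any interval in `zones` are forbidden.
position_allowed <- function(pos, width, zones, margin = 10L) {
  if (is.null(zones) || nrow(zones) == 0L) return(TRUE)
  !any(pos + width - 1L + margin >= zones$start & pos - margin <= zones$end)
}

#' Plant plasmotype-defining haplotypes onto a toy reference pair
#'
#' Assigns each of `n_samples` samples a chloroplast type (1..`k_cp`) and a
#' mitochondrial type (1..`k_mt`) and plants the type-defining variants as
#' a nested chain (type t carries variants 2..t), which makes the true type
#' tree a caterpillar with the all-reference type 1 — the first sample —
#' as outgroup. Chain characters cycle through the requested categories
#' (synonymous / nonsynonymous / Ser-to-Leu editable / intronic /
#' intergenic SNPs, an anchored deletion, an SSR whole-unit change whose
#' genotype vector is congruent with an existing chain character so typing
#' is unaffected by SSR exclusion). Optionally one parallel character (same
#' derived allele in the two non-adjacent types 2 and `k_cp`) and one
#' reverse character (derived on the deepest three types, reverted in the
#' middle one) are added with known ground truth.
#'
#' @param refs Output of [generate_references()].
#' @param k_cp,k_mt Number of cp / mt types (>= 1, `k_mt <= k_cp`).
#' @param n_samples Panel size (>= `k_cp`).
#' @param homoplasy Character vector subset of `c("parallel", "reverse")`
#'   (each needs `k_cp >= 5`).
#' @param seed Integer seed.
#' @return A `panel_truth` object: `references`, `gene_models`, `ssr_loci`,
#'   `shared`, `samples`, `variants` ([variant_set] with genotypes),
#'   `variant_info` (category per variant), `cp_type_of`, `mt_type_of`,
#'   `outgroup`, `homoplasy_plan`.
#' @export
plant_haplotypes <- function(refs, k_cp = 8L, k_mt = 5L, n_samples = 15L,
                             homoplasy = c("parallel", "reverse"),
                             seed = 1L) {
  stopifnot(k_cp >= 1L, k_mt >= 1L, k_mt <= k_cp, n_samples >= k_cp)
  if (length(homoplasy) > 0L && k_cp < 5L) {
    stop("homoplasy planting needs k_cp >= 5")
  }
  cp <- refs$references[[1L]]; mt <- refs$references[[2L]]
  samples <- sprintf("S%02d", seq_len(n_samples))
  cp_type <- ((seq_len(n_samples) - 1L) %% k_cp) + 1L
  mt_type <- ((cp_type - 1L) %% k_mt) + 1L
  zones <- rbind(
    if (!is.null(refs$shared)) refs$shared[c("start", "end", "genome_id")],
    if (!is.null(refs$ssr_loci)) refs$ssr_loci[c("start", "end", "genome_id")],
    data.frame(start = c(1L, 1L), end = c(60L, 60L),
               genome_id = c("cp_ref", "mt_ref")))
  used <- zones
  claim <- function(genome_id, pos, width = 1L) {
    used <<- rbind(used, data.frame(start = pos, end = pos + width - 1L,
                                    genome_id = genome_id))
  }
  allowed <- function(genome_id, pos, width = 1L, margin = 50L) {
    z <- used[used$genome_id == genome_id, , drop = FALSE]
    pos > 60L && position_allowed(pos, width, z, margin)
  }

  withr::with_seed(stage_seed(seed, "plant"), {
    vars <- list()
    add_var <- function(genome_id, pos, ref, alt, var_class, category,
                        carriers_cp = NULL, carriers_mt = NULL) {
      gt <- if (!is.null(carriers_cp)) as.integer(cp_type %in% carriers_cp)
            else as.integer(mt_type %in% carriers_mt)
      vars[[length(vars) + 1L]] <<- list(
        row = data.frame(genome_id = genome_id, pos = pos, ref = ref,
                         alt = alt, var_class = var_class,
                         stringsAsFactors = FALSE),
        gt = gt, category = category)
      claim(genome_id, pos, max(nchar(ref), 1L))
    }
    transition <- c(A = "G", G = "A", C = "T", T = "C")

    # --- reusable site finders on the cp genome -------------------------
    find_codon_site <- function(kind) {
      genes <- if (kind == "ser_leu") {
        Filter(function(m) m$strand == "-", refs$gene_models)
      } else refs$gene_models
      for (g in genes) {
        cds <- gene_cds_sequence(g, cp)
        for (ci in seq_len(nchar(cds) %/% 3L)) {
          codon <- substr(cds, 3L * ci - 2L, 3L * ci)
          hit <- switch(kind,
            ser_leu = if (codon %in% c("TCA", "TCG")) {
              list(off = 3L * (ci - 1L) + 2L, coding_alt = "T")
            },
            syn = if (ci > 1L && substr(codon, 3L, 3L) == "C") {
              mut <- codon; substr(mut, 3L, 3L) <- "T"
              aa1 <- translate_codon(codon, ci); aa2 <- translate_codon(mut, ci)
              if (identical(aa1, aa2)) list(off = 3L * ci, coding_alt = "T")
            },
            nonsyn = {
              b <- substr(codon, 1L, 1L)
              alt_b <- transition[[b]]
              mut <- codon; substr(mut, 1L, 1L) <- alt_b
              aa1 <- translate_codon(codon, ci); aa2 <- translate_codon(mut, ci)
              if (ci > 1L && !identical(aa1, aa2) && aa2 != "*" &&
                  !is.na(aa1)) {
                list(off = 3L * (ci - 1L) + 1L, coding_alt = alt_b)
              }
            })
          if (is.null(hit)) next
          gpos <- coding_to_genomic(g, hit$off)
          coding_ref <- substr(cds, hit$off, hit$off)
          ref_b <- if (g$strand == "-") revcomp(coding_ref) else coding_ref
          alt_b <- if (g$strand == "-") revcomp(hit$coding_alt) else
            hit$coding_alt
          if (allowed("cp_ref", gpos)) {
            return(list(pos = gpos, ref = ref_b, alt = alt_b))
          }
        }
      }
      stop("requested variant count exceeds available codon sites (", kind,
           ")")
    }
    find_intron_site <- function() {
      for (g in refs$gene_models) {
        if (nrow(g$exons) < 2L) next
        ex <- g$exons[order(g$exons[, 1L]), ]
        mid <- (ex[1L, 2L] + ex[2L, 1L]) %/% 2L
        for (p in mid + 0:20) {
          if (allowed("cp_ref", p)) {
            b <- substr(cp$sequence, p, p)
            return(list(pos = p, ref = b, alt = transition[[b]]))
          }
        }
      }
      stop("no intron available for an intronic variant")
    }
    intergenic_pool <- function(genome, gene_models) {
      covered <- rep(FALSE, genome$length)
      for (g in gene_models) {
        sp <- gene_span(g); covered[sp[1L]:sp[2L]] <- TRUE
      }
      which(!covered)
    }
    cp_pool <- intergenic_pool(cp, refs$gene_models)
    mt_pool <- intergenic_pool(mt, list())
    draw_intergenic <- function(genome, pool, width = 1L, margin = 50L) {
      pool <- pool[pool > 60L & pool < genome$length - 60L]
      for (try_ in seq_len(500L)) {
        p <- sample(pool, 1L)
        if (!allowed(genome$id, p, width, margin)) next
        return(p)
      }
      stop("could not place an intergenic variant")
    }

    # --- cp chain characters (define the k_cp types) --------------------
    chain_categories <- rep(c("nonsyn_ser_leu", "syn", "intron",
                              "intergenic", "indel", "nonsyn", "intergenic"),
                            length.out = max(k_cp - 1L, 0L))
    for (t in seq_len(k_cp)[-1L]) {
      cat_ <- chain_categories[t - 1L]
      carriers <- t:k_cp
      if (cat_ == "nonsyn_ser_leu") {
        s <- find_codon_site("ser_leu")
        add_var("cp_ref", s$pos, s$ref, s$alt, "snp", cat_, carriers)
      } else if (cat_ == "syn") {
        s <- find_codon_site("syn")
        add_var("cp_ref", s$pos, s$ref, s$alt, "snp", cat_, carriers)
      } else if (cat_ == "nonsyn") {
        s <- find_codon_site("nonsyn")
        add_var("cp_ref", s$pos, s$ref, s$alt, "snp", cat_, carriers)
      } else if (cat_ == "intron") {
        s <- find_intron_site()
        add_var("cp_ref", s$pos, s$ref, s$alt, "snp", cat_, carriers)
      } else if (cat_ == "indel") {
        repeat {
          p <- draw_intergenic(cp, cp_pool, width = 5L)
          del <- substr(cp$sequence, p + 1L, p + 4L)
          nxt <- substr(cp$sequence, p + 5L, p + 8L)
          prv <- substr(cp$sequence, max(1L, p - 3L), p)
          if (del != nxt && substr(del, 4L, 4L) != substr(prv, 4L, 4L)) break
        }
        add_var("cp_ref", p, substr(cp$sequence, p, p + 4L),
                substr(cp$sequence, p, p), "deletion", cat_, carriers)
      } else {
        p <- draw_intergenic(cp, cp_pool)
        b <- substr(cp$sequence, p, p)
        add_var("cp_ref", p, b, transition[[b]], "snp", cat_, carriers)
      }
    }
    # --- SSR whole-unit change, congruent with the deepest chain split --
    if (!is.null(refs$ssr_loci) && k_cp >= 2L) {
      tr <- refs$ssr_loci[refs$ssr_loci$period == 2L, , drop = FALSE]
      if (nrow(tr) == 0L) tr <- refs$ssr_loci
      tr <- tr[1L, ]
      anchor <- tr$start - 1L
      unit <- substr(cp$sequence, tr$start, tr$start + tr$period - 1L)
      add_var("cp_ref", anchor,
              paste0(substr(cp$sequence, anchor, anchor), unit),
              substr(cp$sequence, anchor, anchor),
              "ssr_length", "ssr", carriers_cp = k_cp:k_cp)
    }
    # --- homoplastic cp characters --------------------------------------
    plan <- character(0)
    if ("parallel" %in% homoplasy) {
      p <- draw_intergenic(cp, cp_pool)
      b <- substr(cp$sequence, p, p)
      add_var("cp_ref", p, b, transition[[b]], "snp", "parallel",
              carriers_cp = c(2L, k_cp))
    }
    if ("reverse" %in% homoplasy) {
      p <- draw_intergenic(cp, cp_pool)
      b <- substr(cp$sequence, p, p)
      add_var("cp_ref", p, b, transition[[b]], "snp", "reverse",
              carriers_cp = setdiff((k_cp - 2L):k_cp, k_cp - 1L))
      # a reversal makes the clade it sits in ambiguous unless the true
      # split it contradicts is supported by more than one clean
      # character; reinforce that split so the planted tree is the unique
      # parsimony optimum and the reversal has identifiable ground truth
      p2 <- draw_intergenic(cp, cp_pool)
      b2 <- substr(cp$sequence, p2, p2)
      add_var("cp_ref", p2, b2, transition[[b2]], "snp", "support",
              carriers_cp = (k_cp - 1L):k_cp)
    }
    # --- mt chain: SNPs plus one insertion ------------------------------
    if (k_mt >= 2L) {
      for (t in 2:k_mt) {
        if (t == k_mt) {  # the deepest mt character is an insertion
          repeat {
            p <- draw_intergenic(mt, mt_pool, width = 5L)
            ins <- "CTAG"
            # anchor must not allow a left shift of the inserted unit
            if (substr(mt$sequence, p + 1L, p + 4L) != ins &&
                substr(mt$sequence, p, p) != "G") break
          }
          add_var("mt_ref", p, substr(mt$sequence, p, p),
                  paste0(substr(mt$sequence, p, p), ins), "insertion",
                  "mt_chain", carriers_mt = t:k_mt)
        } else {
          p <- draw_intergenic(mt, mt_pool)
          b <- substr(mt$sequence, p, p)
          add_var("mt_ref", p, b, transition[[b]], "snp", "mt_chain",
                  carriers_mt = t:k_mt)
        }
      }
    }

    tab <- do.call(rbind, lapply(vars, `[[`, "row"))
    if (is.null(tab)) {
      tab <- data.frame(genome_id = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        var_class = character(0), stringsAsFactors = FALSE)
      gts <- matrix(integer(0), nrow = 0L, ncol = length(samples))
    } else {
      gts <- do.call(rbind, lapply(vars, `[[`, "gt"))
    }
    colnames(gts) <- samples
    cat_v <- vapply(vars, `[[`, "", "category")
    o <- order(tab$genome_id, tab$pos)
    vs <- variant_set(tab[o, , drop = FALSE], gts[o, , drop = FALSE])
    keys <- variant_keys(vs)
    plan <- ifelse(cat_v[o] == "parallel", "parallel",
                   ifelse(cat_v[o] == "reverse", "reverse", "clean"))
    names(plan) <- keys
    structure(list(references = refs$references,
                   gene_models = refs$gene_models,
                   ssr_loci = refs$ssr_loci, shared = refs$shared,
                   samples = samples, variants = vs,
                   variant_info = data.frame(key = keys,
                                             category = cat_v[o],
                                             stringsAsFactors = FALSE),
                   cp_type_of = stats::setNames(cp_type, samples),
                   mt_type_of = stats::setNames(mt_type, samples),
                   outgroup = samples[1L],
                   homoplasy_plan = plan, seed = seed),
              class = "panel_truth")
  })
}

#' @export
print.panel_truth <- function(x, ...) {
  cat(sprintf(
    "<panel_truth> %d samples, %d cp types, %d mt types, %d variants\n",
    length(x$samples), length(unique(x$cp_type_of)),
    length(unique(x$mt_type_of)), n_variants(x$variants)))
  invisible(x)
}

#' Mutated organelle genomes of one panel sample
#'
#' @param panel A `panel_truth`.
#' @param sample Sample id.
#' @return Named list of [genome_record] (with `map` attributes from
#'   [apply_variants()]).
#' @export
sample_genomes <- function(panel, sample) {
  out <- list()
  for (g in panel$references) {
    mine <- panel$variants$table$genome_id == g$id
    alleles <- ifelse(mine, panel$variants$genotypes[, sample], 0L)
    ap <- apply_variants(g, panel$variants, alleles)
    out[[g$id]] <- ap$genome
    attr(out[[g$id]], "map") <- ap$map
  }
  out
}

#' Simulate paired-end reads from a mixed organelle preparation
#'
#' Fragments are drawn uniformly on each replicon (wrapping across the
#' origin of circular genomes), with normally distributed lengths;
#' expected per-genome coverage is `depth * cp_fraction` for the
#' chloroplast and `depth * (1 - cp_fraction)` for the others (split by
#' length). Substitution errors are i.i.d. at `error_rate`; qualities are
#' constant Q37 with an optional linear decay to Q15 over the last 20% of
#' cycles. Byte-identical output for a fixed seed.
#'
#' @param genomes Named list of [genome_record] (one sample's genomes).
#' @param depth Total fold coverage.
#' @param read_length Read length before trimming.
#' @param fragment_mean,fragment_sd Fragment-length distribution
#'   (`fragment_mean` must be >= `read_length`).
#' @param error_rate Per-base substitution error rate in [0, 0.05].
#' @param cp_fraction Chloroplast mixture weight in (0, 1).
#' @param seed Integer seed.
#' @param sample_id Used as the read-id prefix.
#' @param quality_tail Apply the decaying-quality tail (default `TRUE`).
#' @return List with `reads` (a `read_set`) and `truth` (data.frame `id`,
#'   `genome_id`, `start` 1-based on the given genome, `strand`,
#'   `fragment_length`).
#' @export
simulate_reads <- function(genomes, depth = 50, read_length = 150L,
                           fragment_mean = 350, fragment_sd = 30,
                           error_rate = 0.002, cp_fraction = 0.5,
                           seed = 1L, sample_id = "S",
                           quality_tail = TRUE) {
  stopifnot(cp_fraction > 0, cp_fraction < 1,
            error_rate >= 0, error_rate <= 0.05)
  if (fragment_mean < read_length) stop("fragment_mean < read_length")
  is_cp <- vapply(genomes, function(g) g$molecule_class == "chloroplast",
                  logical(1L))
  lens <- vapply(genomes, `[[`, 1L, "length")
  cov <- numeric(length(genomes))
  cov[is_cp] <- depth * cp_fraction * lens[is_cp] / sum(lens[is_cp])
  if (any(!is_cp)) {
    cov[!is_cp] <- depth * (1 - cp_fraction) * lens[!is_cp] / sum(lens[!is_cp])
  }
  qual_int <- rep(37L, read_length)
  if (quality_tail) {
    i0 <- ceiling(0.8 * read_length)
    tail_idx <- i0:read_length
    qual_int[tail_idx] <- round(37 - (37 - 15) * (tail_idx - i0) /
                                  (read_length - i0))
  }
  qual_str <- intToUtf8(qual_int + 33L)
  bases <- c("A", "C", "G", "T")
  withr::with_seed(stage_seed(seed, paste0("reads_", sample_id)), {
    all_reads <- list(); all_truth <- list()
    for (gi in seq_along(genomes)) {
      g <- genomes[[gi]]
      L <- g$length
      n_pairs <- max(1L, as.integer(round(cov[gi] * L / (2 * read_length))))
      starts <- sample.int(L, n_pairs, replace = TRUE)
      flen <- pmax(read_length,
                   as.integer(round(stats::rnorm(n_pairs, fragment_mean,
                                                 fragment_sd))))
      padded <- paste0(g$sequence, substr(g$sequence, 1L, max(flen)))
      frag <- substring(padded, starts, starts + flen - 1L)
      r1 <- substr(frag, 1L, read_length)
      r2 <- revcomp(substr(frag, flen - read_length + 1L, flen))
      orient <- sample(c("+", "-"), n_pairs, replace = TRUE)
      flip <- orient == "-"
      tmp <- r1[flip]; r1[flip] <- r2[flip]; r2[flip] <- tmp
      # substitution errors
      n_err <- stats::rbinom(2L * n_pairs, read_length, error_rate)
      if (any(n_err > 0L)) {
        reads2 <- c(r1, r2)
        for (ri in which(n_err > 0L)) {
          ppos <- sample.int(read_length, n_err[ri])
          for (p in ppos) {
            old <- substr(reads2[ri], p, p)
            substr(reads2[ri], p, p) <- sample(setdiff(bases, old), 1L)
          }
        }
        r1 <- reads2[seq_len(n_pairs)]
        r2 <- reads2[n_pairs + seq_len(n_pairs)]
      }
      ids <- sprintf("%s_%s_p%05d", sample_id, g$id, seq_len(n_pairs))
      all_reads[[gi]] <- data.frame(
        id = ids, seq1 = r1, qual1 = qual_str, seq2 = r2, qual2 = qual_str,
        stringsAsFactors = FALSE)
      all_truth[[gi]] <- data.frame(
        id = ids, genome_id = g$id, start = starts, strand = orient,
        fragment_length = flen, stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, all_reads)
    structure(list(reads = structure(reads,
                                     class = c("read_set", "data.frame")),
                   truth = do.call(rbind, all_truth)),
              class = "sim_reads")
  })
}

#' The packaged fixture panel
#'
#' 15 samples, 8 chloroplast types, 5 mitochondrial types (8 plasmotypes),
#' one planted parallel and one planted reverse chloroplast character —
#' the shape of a small alloplasmic-line collection typed by both
#' organelles.
#'
#' @param seed Panel seed (default 20200202).
#' @return A `panel_truth`.
#' @export
table2_panel <- function(seed = 20200202L) {
  refs <- generate_references(seed = seed)
  plant_haplotypes(refs, k_cp = 8L, k_mt = 5L, n_samples = 15L,
                   homoplasy = c("parallel", "reverse"), seed = seed)
}
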