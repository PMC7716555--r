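AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              "*" = "Ter")

# Plastid genes use the bacterial/plastid code (NCBI table 11). A valid
# initiator codon at position 1 translates as Met; any other first codon
# translates by straight lookup.
translate_codon <- function(codon, codon_index = 2L) {
  if (grepl("N", codon)) return(NA_character_)
  code <- Biostrings::getGeneticCode("11")
  aa <- unname(code[codon])
  if (codon_index == 1L &&
      codon %in% c("ATG", attr(code, "alt_init_codons"))) {
    aa <- "M"
  }
  aa
}

#' Express a variant's alleles on the coding strand of a gene
#'
#' Alleles are reverse-complemented iff the gene is on the minus strand;
#' applying the transformation twice returns the genomic alleles.
#'
#' @param ref,alt Genomic alleles.
#' @param gene A [gene_model] overlapping the variant.
#' @param pos Variant position (must fall within the gene span).
#' @return Character vector `c(coding_ref, coding_alt)`.
#' @export
normalize_to_coding_strand <- function(ref, alt, gene, pos) {
  span <- gene_span(gene)
  if (pos < span[1L] || pos > span[2L]) {
    stop("variant at ", pos, " outside gene ", gene$gene_id)
  }
  if (gene$strand == "-") c(revcomp(ref), revcomp(alt)) else c(ref, alt)
}

# 1-based offset of genomic `pos` within the exon-concatenated CDS, or NA.
cds_offset <- function(gene, pos) {
  off <- 0L
  for (e in seq_len(nrow(gene$exons))) {
    ex <- gene$exons[e, ]
    if (pos >= ex[1L] && pos <= ex[2L]) {
      within <- if (gene$strand == "+") pos - ex[1L] + 1L else ex[2L] - pos + 1L
      return(off + within)
    }
    off <- off + ex[2L] - ex[1L] + 1L
  }
  NA_integer_
}

find_gene <- function(gene_models, genome_id, pos) {
  for (m in gene_models) {
    if (m$genome_id != genome_id) next
    span <- gene_span(m)
    if (pos >= span[1L] && pos <= span[2L]) return(m)
  }
  NULL
}

#' Annotate variants against gene models
#'
#' Each variant is classified as exonic, intronic (within a gene span but
#' outside its exons) or intergenic. For exonic SNPs in a CDS the codon
#' index (1-based), within-codon position (1/2/3), coding-strand alleles,
#' amino-acid change and an HGVS p. string are computed on the
#' exon-concatenated coding sequence — codons may straddle exon junctions.
#' Synonymous changes are written `p.Xaa<n>=`. Indels are annotated
#' region-only.
#'
#' @param vs A [variant_set].
#' @param gene_models List of [gene_model].
#' @param genomes List of [genome_record] (the reference set).
#' @return data.frame of class `variant_annotation` with one row per
#'   variant: `genome_id`, `pos`, `ref`, `alt`, `var_class`, `region`,
#'   `gene_id`, `coding_ref`, `coding_alt`, `codon_index`, `codon_pos`,
#'   `aa_ref`, `aa_alt`, `synonymous`, `hgvs_p`.
#' @export
annotate_variants <- function(vs, gene_models, genomes) {
  gmap <- stats::setNames(genomes, vapply(genomes, `[[`, "", "id"))
  tab <- vs$table
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    v <- tab[i, ]
    genome <- gmap[[v$genome_id]]
    if (is.null(genome)) stop("unknown genome ", v$genome_id)
    if (substr(genome$sequence, v$pos, v$pos + nchar(v$ref) - 1L) != v$ref) {
      stop("reference/annotation inconsistency at ", v$genome_id, ":",
           v$pos)
    }
    gene <- find_gene(gene_models, v$genome_id, v$pos)
    row <- data.frame(v, region = "intergenic", gene_id = NA_character_,
                      coding_ref = NA_character_, coding_alt = NA_character_,
                      codon_index = NA_integer_, codon_pos = NA_integer_,
                      aa_ref = NA_character_, aa_alt = NA_character_,
                      synonymous = NA, hgvs_p = NA_character_,
                      stringsAsFactors = FALSE)
    if (!is.null(gene)) {
      row$gene_id <- gene$gene_id
      off <- cds_offset(gene, v$pos)
      row$region <- if (is.na(off)) "intron" else "exon"
      if (!is.na(off) && v$var_class == "snp" && gene$is_cds) {
        cod <- normalize_to_coding_strand(v$ref, v$alt, gene, v$pos)
        ci <- ((off - 1L) %/% 3L) + 1L
        cp <- ((off - 1L) %% 3L) + 1L
        cds <- gene_cds_sequence(gene, genome)
        codon <- substr(cds, 3L * (ci - 1L) + 1L, 3L * ci)
        if (substr(codon, cp, cp) != cod[1L]) {
          stop("reference/annotation inconsistency in CDS of ",
               gene$gene_id, " at ", v$pos)
        }
        mut <- codon
        substr(mut, cp, cp) <- cod[2L]
        aa_ref <- translate_codon(codon, ci)
        aa_alt <- translate_codon(mut, ci)
        syn <- identical(aa_ref, aa_alt)
        row$coding_ref <- cod[1L]; row$coding_alt <- cod[2L]
        row$codon_index <- ci; row$codon_pos <- cp
        row$aa_ref <- AA_THREE[[aa_ref]]; row$aa_alt <- AA_THREE[[aa_alt]]
        row$synonymous <- syn
        row$hgvs_p <- if (syn) paste0("p.", AA_THREE[[aa_ref]], ci, "=")
                      else paste0("p.", AA_THREE[[aa_ref]], ci,
                                  AA_THREE[[aa_alt]])
      }
    }
    out[[i]] <- row
  }
  res <- if (length(out)) do.call(rbind, out) else NULL
  class(res) <- c("variant_annotation", "data.frame")
  res
}

#' Detect microsatellite (SSR) tracts in a genome
#'
#' Maximal runs of 1-, 2- and 3-bp motifs with at least `min_mono`,
#' `min_di`, `min_tri` unit repeats respectively. Motifs that are
#' repetitions of a shorter unit are reported at the shorter period only.
#'
#' @param genome A [genome_record].
#' @param min_mono,min_di,min_tri Minimum unit counts (all >= 2).
#' @return data.frame `start`, `end`, `motif`, `period`, `n_units`.
#' @export
detect_ssr_loci <- function(genome, min_mono = 8L, min_di = 5L,
                            min_tri = 4L) {
  stopifnot(min_mono >= 2L, min_di >= 2L, min_tri >= 2L)
  seq <- genome$sequence
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  hits <- list()
  mins <- c(min_mono, min_di, min_tri)
  for (p in 1:3) {
    if (L <= p) next
    # a tandem run of period p is a maximal stretch of seq[i] == seq[i+p]
    same <- chars[seq_len(L - p)] == chars[(p + 1L):L]
    r <- rle(same)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run_len <- r$lengths[k] + p       # total bases incl. partial unit
      n_units <- run_len %/% p
      if (n_units < mins[p]) next
      start <- starts[k]
      motif <- substr(seq, start, start + p - 1L)
      if (p == 2L && substr(motif, 1L, 1L) == substr(motif, 2L, 2L)) next
      if (p == 3L && length(unique(strsplit(motif, "")[[1L]])) == 1L) next
      end <- start + n_units * p - 1L   # trim partial trailing unit
      hits[[length(hits) + 1L]] <-
        data.frame(start = start, end = end, motif = motif, period = p,
                   n_units = n_units, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), period = integer(0),
                      n_units = integer(0)))
  }
  res <- do.call(rbind, hits)
  res[order(res$start, res$period), , drop = FALSE]
}

# Is `x` a whole number of (possibly rotated) units of `motif`?
is_whole_units <- function(x, motif) {
  p <- nchar(motif)
  if (nchar(x) == 0L || nchar(x) %% p != 0L) return(FALSE)
  rots <- vapply(seq_len(p), function(r) {
    paste0(substr(motif, r, p), substr(motif, 1L, r - 1L))
  }, character(1L))
  any(vapply(rots, function(rt) {
    identical(x, strrep(rt, nchar(x) %/% p))
  }, logical(1L)))
}

#' Reclassify indels inside SSR tracts as SSR-length variants
#'
#' An insertion or deletion becomes `ssr_length` iff its changed bases are a
#' whole number of units of the motif of a tract containing the edit.
#'
#' @param vs A [variant_set].
#' @param ssr_intervals Output of [detect_ssr_loci()].
#' @return The variant set with updated `var_class`.
#' @export
classify_ssr <- function(vs, ssr_intervals) {
  tab <- vs$table
  for (i in seq_len(nrow(tab))) {
    if (!tab$var_class[i] %in% c("insertion", "deletion")) next
    changed <- if (nchar(tab$alt[i]) > nchar(tab$ref[i])) {
      substr(tab$alt[i], 2L, nchar(tab$alt[i]))
    } else {
      substr(tab$ref[i], 2L, nchar(tab$ref[i]))
    }
    lo <- tab$pos[i] + 1L
    hi <- tab$pos[i] + nchar(tab$ref[i]) - 1L
    for (s in seq_len(nrow(ssr_intervals))) {
      tr <- ssr_intervals[s, ]
      inside <- lo >= tr$start - 1L && max(hi, lo) <= tr$end + 1L
      if (inside && is_whole_units(changed, tr$motif)) {
        tab$var_class[i] <- "ssr_length"
        break
      }
    }
  }
  vs$table <- tab
  vs
}
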