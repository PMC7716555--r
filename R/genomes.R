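#' Replicon sequence record
#'
#' A `genome_record` is the unit of the "double reference": one named
#' replicon with explicit topology and molecule class. Organelle genomes are
#' typically circular-mapping; topology matters for read simulation, k-mer
#' indexing and restriction scans, all of which wrap across the origin for
#' circular records.
#'
#' @param id Single non-empty string, unique within a reference set.
#' @param sequence DNA string. Lower case and U are normalized (U->T,
#'   upper-cased); any residue outside A/C/G/T/N becomes N and is counted in
#'   the `n_masked` attribute.
#' @param topology `"circular"` or `"linear"`.
#' @param molecule_class `"chloroplast"`, `"mitochondrion"` or
#'   `"nuclear_decoy"`.
#' @return An object of class `genome_record` with fields `id`, `sequence`,
#'   `topology`, `molecule_class` and `length`.
#' @export
genome_record <- function(id, sequence,
                          topology = c("linear", "circular"),
                          molecule_class = c("chloroplast", "mitochondrion",
                                             "nuclear_decoy")) {
  topology <- match.arg(topology)
  molecule_class <- match.arg(molecule_class)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_dna(sequence)
  if (nchar(sequence$seq) == 0L) {
    stop("genome_record '", id, "': empty sequence")
  }
  structure(
    list(id = id, sequence = sequence$seq, topology = topology,
         molecule_class = molecule_class, length = nchar(sequence$seq),
         n_masked = sequence$n_masked),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %s, %s\n",
              x$id, x$length, x$topology, x$molecule_class))
  invisible(x)
}

# Uppercase, U->T, anything else -> N (with count). Returns list(seq, n_masked).
normalize_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- chartr("u", "T", toupper(x))
  s <- chartr("U", "T", s)
  bad <- gsub("[ACGTN]", "", s)
  n_masked <- nchar(bad)
  if (n_masked > 0L) {
    s <- gsub("[^ACGTN]", "N", s)
    warning(n_masked, " non-ACGTN residue(s) masked to N")
  }
  list(seq = s, n_masked = n_masked)
}

#' Reverse complement of a DNA string
#'
#' Plain-character complement including IUPAC ambiguity codes; used for
#' minus-strand allele normalization and read orientation.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNRYSWKMBDHV", "TGCANYRSWMKVHDB", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Extract subsequence honoring circular topology; 1-based inclusive,
# end may exceed length for circular records (wraps).
genome_subseq <- function(genome, start, end) {
  L <- genome$length
  if (genome$topology == "circular") {
    # work on coordinates mod L
    idx <- ((seq.int(start, end) - 1L) %% L) + 1L
    paste(strsplit(genome$sequence, "", fixed = TRUE)[[1L]][idx],
          collapse = "")
  } else {
    stopifnot(start >= 1L, end <= L)
    substr(genome$sequence, start, end)
  }
}

# Doubled representation for circular scans: sequence + prefix of (k-1).
padded_sequence <- function(genome, overhang) {
  if (genome$topology == "circular" && overhang > 0L) {
    paste0(genome$sequence, substr(genome$sequence, 1L, overhang))
  } else {
    genome$sequence
  }
}

#' Stranded, possibly multi-exon gene model
#'
#' Exons are stored in genomic 1-based inclusive coordinates, ordered 5'->3'
#' on the coding strand (ascending for `+` genes, descending for `-` genes).
#' The concatenated exon sequence of a CDS must be a multiple of 3.
#'
#' @param gene_id,genome_id Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end), one row per exon.
#' @param is_cds Logical; CDS models are translated by the annotator.
#' @return A `gene_model` object.
#' @export
gene_model <- function(gene_id, genome_id, strand, exons, is_cds = TRUE) {
  stopifnot(strand %in% c("+", "-"), is.matrix(exons), ncol(exons) == 2L)
  storage.mode(exons) <- "integer"
  if (any(exons[, 2L] < exons[, 1L])) {
    stop("gene ", gene_id, ": exon end < start")
  }
  o <- order(exons[, 1L])
  sorted <- exons[o, , drop = FALSE]
  if (nrow(sorted) > 1L &&
      any(sorted[-1L, 1L] <= sorted[-nrow(sorted), 2L])) {
    stop("gene ", gene_id, ": overlapping exons")
  }
  # coding-strand order
  exons <- if (strand == "+") sorted else sorted[rev(seq_len(nrow(sorted))), ,
                                                 drop = FALSE]
  len <- sum(exons[, 2L] - exons[, 1L] + 1L)
  if (is_cds && len %% 3L != 0L) {
    stop("gene ", gene_id, ": CDS length ", len, " not a multiple of 3")
  }
  structure(list(gene_id = gene_id, genome_id = genome_id, strand = strand,
                 exons = exons, is_cds = is_cds, cds_length = len),
            class = "gene_model")
}

gene_span <- function(gene) range(gene$exons)

# Spliced coding-strand sequence of the model on `genome`.
gene_cds_sequence <- function(gene, genome) {
  parts <- apply(gene$exons, 1L, function(ex) {
    s <- substr(genome$sequence, ex[1L], ex[2L])
    if (gene$strand == "-") revcomp(s) else s
  })
  paste(parts, collapse = "")
}
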