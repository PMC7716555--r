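#' Parse reference sequences from FASTA or GenBank-style flat text
#'
#' External coordinates throughout the package are 1-based inclusive; this
#' is the single entry point where sequences are normalized (upper case,
#' U->T, non-ACGTN masked to N).
#'
#' FASTA headers may carry bracketed tokens after the id:
#' `[circular]` / `[linear]` for topology and `[chloroplast]` /
#' `[mitochondrion]` / `[nuclear_decoy]` for the molecule class. Defaults
#' are linear and chloroplast. The GenBank-lite reader takes the topology
#' from the LOCUS line and the molecule class from DEFINITION keywords.
#'
#' @param text Character: a single string with newlines, a character vector
#'   of lines, or the path of an existing file.
#' @param format `"fasta"` or `"genbank_lite"`.
#' @return List of [genome_record] objects.
#' @seealso [parse_genbank_lite()] for feature-table access.
#' @export
parse_sequences <- function(text, format = c("fasta", "genbank_lite")) {
  format <- match.arg(format)
  lines <- as_text_lines(text)
  if (format == "fasta") {
    parse_fasta_lines(lines)
  } else {
    parse_genbank_lite(lines)$genomes
  }
}

as_text_lines <- function(text) {
  stopifnot(is.character(text))
  if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
      file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
}

parse_fasta_lines <- function(lines) {
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("FASTA parse error at line 1: no '>' header")
  pre <- setdiff(which(nzchar(trimws(lines))), seq(hdr[1L], length(lines)))
  if (length(pre) > 0L) {
    stop("FASTA parse error at line ", min(pre), ": sequence before header")
  }
  bounds <- c(hdr, length(lines) + 1L)
  out <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    header <- sub("^>", "", lines[hdr[i]])
    toks <- strsplit(trimws(header), "[[:space:]]+")[[1L]]
    if (length(toks) == 0L || !nzchar(toks[1L])) {
      stop("FASTA parse error at line ", hdr[i], ": empty record id")
    }
    id <- toks[1L]
    lower <- tolower(toks)
    topology <- if ("[circular]" %in% lower) "circular" else "linear"
    mol <- "chloroplast"
    if ("[mitochondrion]" %in% lower) mol <- "mitochondrion"
    if ("[nuclear_decoy]" %in% lower) mol <- "nuclear_decoy"
    body <- lines[seq.int(hdr[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[!grepl("^>", body)]
    seq <- paste(gsub("[[:space:]]", "", body), collapse = "")
    if (!nzchar(seq)) {
      stop("FASTA parse error at line ", hdr[i], ": empty sequence for '",
           id, "'")
    }
    out[[i]] <- genome_record(id, seq, topology, mol)
  }
  ids <- vapply(out, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate record id: ",
                               ids[duplicated(ids)][1L])
  out
}

#' Write genome records as wrapped FASTA
#'
#' Headers carry the bracketed topology/molecule tokens understood by
#' [parse_sequences()], so write-then-parse is an identity.
#'
#' @param genomes List of [genome_record].
#' @param file Optional path; when `NULL` the lines are returned invisibly
#'   only.
#' @param width Wrap width (default 60 columns).
#' @return Character vector of FASTA lines, invisibly.
#' @export
write_fasta <- function(genomes, file = NULL, width = 60L) {
  lines <- unlist(lapply(genomes, function(g) {
    toks <- c(g$id,
              if (g$topology == "circular") "[circular]",
              if (g$molecule_class != "chloroplast")
                paste0("[", g$molecule_class, "]"))
    starts <- seq.int(1L, g$length, by = width)
    c(paste0(">", paste(toks, collapse = " ")),
      substring(g$sequence, starts, pmin(starts + width - 1L, g$length)))
  }), use.names = FALSE)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Parse a GenBank-lite flat file (LOCUS topology + CDS features)
#'
#' Reads only what organelle ingest needs: the LOCUS topology word, the
#' DEFINITION molecule keywords, `gene`/`CDS` features with plain or
#' `complement(join(...))` locations (same strand, non-wrapping segments),
#' and the ORIGIN sequence block. Everything else is ignored.
#'
#' @param text As in [parse_sequences()].
#' @return List with `genomes` (list of [genome_record]) and `gene_models`
#'   (list of [gene_model], one per CDS feature).
#' @export
parse_genbank_lite <- function(text) {
  lines <- as_text_lines(text)
  rec_starts <- grep("^LOCUS", lines)
  if (length(rec_starts) == 0L) stop("GenBank parse error at line 1: no LOCUS")
  rec_ends <- grep("^//", lines)
  genomes <- list(); models <- list()
  for (r in seq_along(rec_starts)) {
    from <- rec_starts[r]
    to <- rec_ends[rec_ends > from][1L]
    if (is.na(to)) stop("GenBank parse error at line ", from,
                        ": record without terminating //")
    rec <- lines[from:to]
    loc <- strsplit(trimws(rec[1L]), "[[:space:]]+")[[1L]]
    if (length(loc) < 2L) stop("GenBank parse error at line ", from,
                               ": malformed LOCUS line")
    id <- loc[2L]
    topology <- if (any(tolower(loc) == "circular")) "circular" else "linear"
    def <- paste(rec[grep("^DEFINITION|^  ", rec)], collapse = " ")
    mol <- if (grepl("mitochond", def, ignore.case = TRUE))
      "mitochondrion" else "chloroplast"
    ori <- grep("^ORIGIN", rec)
    if (length(ori) == 0L) stop("GenBank parse error at line ", from,
                                ": no ORIGIN block for '", id, "'")
    seq_lines <- rec[seq.int(ori[1L] + 1L, length(rec) - 1L)]
    seq <- paste(gsub("[^A-Za-z]", "", seq_lines), collapse = "")
    if (!nzchar(seq)) stop("GenBank parse error at line ", from + ori[1L],
                           ": empty ORIGIN for '", id, "'")
    genomes[[length(genomes) + 1L]] <- genome_record(id, seq, topology, mol)
    models <- c(models, parse_genbank_cds(rec, id))
  }
  ids <- vapply(genomes, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate LOCUS id: ",
                               ids[duplicated(ids)][1L])
  list(genomes = genomes, gene_models = models)
}

# CDS features of one GenBank record -> gene_model list.
parse_genbank_cds <- function(rec, genome_id) {
  feat_at <- grep("^ {1,8}[A-Za-z'_0-9]+ {2,}", rec)
  cds <- integer(0)
  for (i in feat_at) {
    key <- strsplit(trimws(rec[i]), "[[:space:]]+")[[1L]][1L]
    if (identical(key, "CDS")) cds <- c(cds, i)
  }
  out <- list()
  for (i in cds) {
    # location may continue over lines until a /qualifier or next feature
    locstr <- sub("^ +CDS +", "", rec[i])
    j <- i + 1L
    while (j <= length(rec) && !grepl("^ +/", rec[j]) &&
           !(j %in% feat_at) && !grepl("^[A-Z]", rec[j])) {
      locstr <- paste0(locstr, trimws(rec[j])); j <- j + 1L
    }
    # gene name from following qualifiers
    gene <- NA_character_
    k <- j
    while (k <= length(rec) && !(k %in% feat_at) && !grepl("^[A-Z]", rec[k])) {
      m <- regmatches(rec[k], regexec('^ +/(gene|locus_tag)="([^"]+)"',
                                      rec[k]))[[1L]]
      if (length(m) == 3L && (is.na(gene) || m[2L] == "gene")) gene <- m[3L]
      k <- k + 1L
    }
    loc <- parse_feature_location(locstr)
    if (is.null(loc)) next  # trans-spliced / wrapping: out of scope
    gid <- if (is.na(gene)) paste0("CDS_", loc$exons[1L, 1L]) else gene
    mdl <- try(gene_model(gid, genome_id, loc$strand, loc$exons,
                          is_cds = TRUE), silent = TRUE)
    if (!inherits(mdl, "try-error")) out[[length(out) + 1L]] <- mdl
  }
  out
}

# "complement(join(a..b,c..d))" etc. -> list(strand, exons) or NULL.
parse_feature_location <- function(s) {
  s <- gsub("[<>]", "", gsub("[[:space:]]", "", s))
  strand <- "+"
  if (grepl("^complement\\(", s)) {
    strand <- "-"
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  if (grepl("complement", s)) return(NULL)  # mixed strands unsupported
  s <- sub("^join\\((.*)\\)$", "\\1", s)
  if (grepl("[()]", s)) return(NULL)
  parts <- strsplit(s, ",", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^([0-9]+)\\.\\.([0-9]+)$", parts))
  if (any(lengths(m) != 3L)) {
    m1 <- regmatches(parts, regexec("^([0-9]+)$", parts))
    if (all(lengths(m1) == 2L)) {
      ex <- cbind(as.integer(vapply(m1, `[[`, "", 2L)),
                  as.integer(vapply(m1, `[[`, "", 2L)))
      return(list(strand = strand, exons = ex))
    }
    return(NULL)
  }
  ex <- cbind(as.integer(vapply(m, `[[`, "", 2L)),
              as.integer(vapply(m, `[[`, "", 3L)))
  if (any(ex[, 1L] > ex[, 2L])) return(NULL)  # origin-wrapping
  list(strand = strand, exons = ex)
}

#' Parse gene models from GFF3
#'
#' CDS lines sharing a `Parent` are merged into one multi-exon model with
#' exons ordered 5'->3' on the coding strand. 1-based inclusive GFF3
#' coordinates are preserved unchanged.
#'
#' @param text GFF3 text or a file path.
#' @return List of [gene_model].
#' @export
parse_gene_models <- function(text) {
  lines <- as_text_lines(text)
  path <- tempfile(fileext = ".gff3")
  on.exit(unlink(path))
  writeLines(lines, path)
  g <- rtracklayer::readGFF(path)
  g <- g[g$type == "CDS", , drop = FALSE]
  if (nrow(g) == 0L) return(list())
  parent <- vapply(seq_len(nrow(g)), function(i) {
    p <- g$Parent[[i]]
    if (length(p) >= 1L) p[[1L]]
    else if (!is.null(g$ID) && !is.na(g$ID[i])) g$ID[i]
    else paste0("cds_", g$start[i])
  }, character(1L))
  out <- lapply(split(seq_len(nrow(g)), parent), function(idx) {
    strand <- unique(as.character(g$strand[idx]))
    if (length(strand) != 1L || !strand %in% c("+", "-")) {
      stop("gene ", parent[idx[1L]], ": CDS strand missing or inconsistent")
    }
    gene_model(gene_id = parent[idx[1L]],
               genome_id = as.character(g$seqid[idx[1L]]),
               strand = strand,
               exons = cbind(g$start[idx], g$end[idx]),
               is_cds = TRUE)
  })
  unname(out[order(vapply(out, function(m) m$exons[1L, 1L], integer(1L)))])
}

#' Write gene models as GFF3
#'
#' @param gene_models List of [gene_model].
#' @param file Optional output path.
#' @return GFF3 lines, invisibly.
#' @export
write_gff3 <- function(gene_models, file = NULL) {
  lines <- "##gff-version 3"
  for (m in gene_models) {
    span <- gene_span(m)
    lines <- c(lines,
               paste(m$genome_id, "plastotyper", "gene", span[1L], span[2L],
                     ".", m$strand, ".", paste0("ID=", m$gene_id, "_gene"),
                     sep = "\t"))
    ex <- m$exons[order(m$exons[, 1L]), , drop = FALSE]
    for (e in seq_len(nrow(ex))) {
      lines <- c(lines,
                 paste(m$genome_id, "plastotyper", "CDS", ex[e, 1L],
                       ex[e, 2L], ".", m$strand, ".",
                       paste0("ID=", m$gene_id, "_cds;Parent=", m$gene_id),
                       sep = "\t"))
    }
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Write a variant set as VCF v4.2 (haploid GT dialect)
#'
#' Organelle consensus genotypes are effectively haploid, so calls are
#' written as bare "0"/"1". The variant class survives the round trip in an
#' INFO tag `VC`. One `##contig` line is written per genome.
#'
#' @param vs A [variant_set], positions sorted within each genome.
#' @param references Optional list of [genome_record] supplying contig
#'   lengths (and the contig-line order).
#' @param file Optional output path.
#' @param samples Optional ordered sample ids; must match the genotype
#'   columns of `vs` (a genotype for a sample not listed here is an error).
#' @return VCF lines, invisibly.
#' @export
write_vcf <- function(vs, references = NULL, file = NULL, samples = NULL) {
  tab <- vs$table
  for (gid in unique(tab$genome_id)) {
    p <- tab$pos[tab$genome_id == gid]
    if (is.unsorted(p)) stop("variants for ", gid, " are not sorted by pos")
  }
  if (is.null(samples)) {
    samples <- variant_samples(vs)
  } else {
    unknown <- setdiff(variant_samples(vs), samples)
    if (length(unknown) > 0L) {
      stop("genotype for unknown sample: ", paste(unknown, collapse = ", "))
    }
    if (!setequal(samples, variant_samples(vs))) {
      stop("samples without genotypes: ",
           paste(setdiff(samples, variant_samples(vs)), collapse = ", "))
    }
    vs$genotypes <- vs$genotypes[, samples, drop = FALSE]
  }
  contigs <- if (!is.null(references)) {
    vapply(references, function(g)
      sprintf("##contig=<ID=%s,length=%d>", g$id, g$length), character(1L))
  } else {
    sprintf("##contig=<ID=%s>", unique(tab$genome_id))
  }
  header <- c("##fileformat=VCFv4.2",
              contigs,
              "##INFO=<ID=VC,Number=1,Type=String,Description=\"Variant class\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  if (nrow(tab) == 0L) {
    lines <- header
  } else {
    body <- paste(tab$genome_id, tab$pos, ".", tab$ref, tab$alt, ".", ".",
                  paste0("VC=", tab$var_class), "GT",
                  sep = "\t")
    if (length(samples) > 0L) {
      gt <- apply(vs$genotypes, 1L, function(row) paste(row, collapse = "\t"))
      body <- paste(body, gt, sep = "\t")
    }
    lines <- c(header, body)
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read a VCF into a variant set
#'
#' Accepts the dialect emitted by [write_vcf()] plus plain haploid or
#' homozygous-diploid GT calls from other tools. Multi-allelic records are
#' split into biallelic rows.
#'
#' @param text VCF text or a file path.
#' @return A [variant_set].
#' @export
read_vcf <- function(text) {
  lines <- as_text_lines(text)
  chrom <- grep("^#CHROM", lines)
  if (length(chrom) != 1L) stop("VCF parse error: missing #CHROM header")
  cols <- strsplit(lines[chrom], "\t", fixed = TRUE)[[1L]]
  samples <- if (length(cols) > 9L) cols[-(1:9)] else character(0)
  body <- lines[-seq_len(chrom)]
  body <- body[nzchar(body)]
  rows <- list(); gts <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    alts <- strsplit(f[5L], ",", fixed = TRUE)[[1L]]
    vc <- sub("^.*VC=([a-z_]+).*$", "\\1", f[8L])
    has_vc <- grepl("VC=", f[8L], fixed = TRUE)
    raw_gt <- if (length(samples) > 0L) f[-(1:9)] else character(0)
    allele <- as.integer(sub("^([0-9.]+)([/|].*)?$", "\\1", raw_gt))
    for (ai in seq_along(alts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = f[1L], pos = as.integer(f[2L]), ref = f[4L],
        alt = alts[ai],
        var_class = if (has_vc && length(alts) == 1L) vc
                    else infer_var_class(f[4L], alts[ai]),
        stringsAsFactors = FALSE)
      gts[[length(gts) + 1L]] <- as.integer(allele == ai)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genome_id = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               var_class = character(0), stringsAsFactors = FALSE)
  gm <- if (length(gts)) do.call(rbind, gts) else
    matrix(integer(0), nrow = 0L, ncol = length(samples))
  if (length(samples) > 0L || ncol(gm) == length(samples)) {
    colnames(gm) <- samples
  }
  variant_set(tab, gm)
}

#' Read a paired FASTQ file pair
#'
#' @param r1,r2 Paths to the mate-1 and mate-2 FASTQ files (phred+33).
#' @return A `read_set`: data.frame with columns `id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`.
#' @export
read_fastq_pair <- function(r1, r2) {
  rd <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    data.frame(id = sub("[[:space:]].*$", "", names(x)),
               seq = as.character(x),
               qual = as.character(S4Vectors::mcols(x)$qualities),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  a <- rd(r1); b <- rd(r2)
  stopifnot(identical(a$id, b$id))
  structure(data.frame(id = a$id, seq1 = a$seq, qual1 = a$qual,
                       seq2 = b$seq, qual2 = b$qual,
                       stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

#' Write a read set as a FASTQ pair
#'
#' @param reads A `read_set` data.frame (see [read_fastq_pair()]).
#' @param r1,r2 Output paths.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pair <- function(reads, r1, r2) {
  emit <- function(seqs, quals, ids, path) {
    writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  }
  emit(reads$seq1, reads$qual1, reads$id, r1)
  emit(reads$seq2, reads$qual2, reads$id, r2)
  invisible(c(r1, r2))
}
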