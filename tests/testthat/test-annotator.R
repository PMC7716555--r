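one_gene_fixture <- function(cds, strand = "+", flank = 30L, seed = 55L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  left <- paste(sample(bases, flank, TRUE), collapse = "")
  right <- paste(sample(bases, flank, TRUE), collapse = "")
  body <- if (strand == "+") cds else revcomp(cds)
  g <- genome_record("toy", paste0(left, body, right), "linear")
  m <- gene_model("g1", "toy", strand,
                  rbind(c(flank + 1L, flank + nchar(cds))))
  list(genome = g, gene = m, offset = flank)
}

test_that("coding-strand normalization is strand-aware and involutive", {
  fx <- one_gene_fixture("ATGTCATAA", strand = "+")
  expect_equal(normalize_to_coding_strand("G", "A", fx$gene, fx$offset + 2L),
               c("G", "A"))
  fxm <- one_gene_fixture("ATGTCATAA", strand = "-")
  cod <- normalize_to_coding_strand("G", "A", fxm$gene, fxm$offset + 2L)
  expect_equal(cod, c("C", "T"))
  # involution: applying twice returns the genomic alleles
  expect_equal(normalize_to_coding_strand(cod[1L], cod[2L], fxm$gene,
                                          fxm$offset + 2L), c("G", "A"))
  expect_error(normalize_to_coding_strand("A", "G", fx$gene, 1L),
               "outside gene")
})

test_that("Ser->Leu at codon position 2 annotates as forced by the code", {
  fx <- one_gene_fixture("TCA")   # single Ser codon gene
  vs <- variant_set(data.frame(genome_id = "toy", pos = fx$offset + 2L,
                               ref = "C", alt = "T", var_class = "snp"))
  a <- annotate_variants(vs, list(fx$gene), list(fx$genome))
  expect_equal(a$region, "exon")
  expect_equal(a$codon_index, 1L)
  expect_equal(a$codon_pos, 2L)
  expect_equal(a$hgvs_p, "p.Ser1Leu")
  expect_false(a$synonymous)
})

test_that("a synonymous third-position change writes the '=' form", {
  # 213 codons; codon 213 is GGA; A>G at its third position -> GGG (Gly)
  set.seed(9)
  mids <- sample(plastotyper:::NON_STOP_CODONS[
    !plastotyper:::NON_STOP_CODONS %in% "ATG"], 211L, TRUE)
  cds <- paste0("ATG", paste(mids, collapse = ""), "GGA")
  fx <- one_gene_fixture(cds)
  pos <- fx$offset + 3L * 213L
  vs <- variant_set(data.frame(genome_id = "toy", pos = pos, ref = "A",
                               alt = "G", var_class = "snp"))
  a <- annotate_variants(vs, list(fx$gene), list(fx$genome))
  expect_equal(a$codon_index, 213L)
  expect_equal(a$codon_pos, 3L)
  expect_equal(a$hgvs_p, "p.Gly213=")
  expect_true(a$synonymous)
})

test_that("intronic and intergenic variants carry no codon fields", {
  refs <- generate_references(seed = 4L)
  intron_gene <- Filter(function(m) nrow(m$exons) > 1L,
                        refs$gene_models)[[1L]]
  ex <- intron_gene$exons[order(intron_gene$exons[, 1L]), ]
  ipos <- ex[1L, 2L] + 5L
  g <- refs$references[[1L]]
  b <- substr(g$sequence, ipos, ipos)
  vs <- variant_set(data.frame(
    genome_id = "cp_ref", pos = c(10L, ipos),
    ref = c(substr(g$sequence, 10L, 10L), b),
    alt = c(setdiff(c("A", "C"), substr(g$sequence, 10L, 10L))[1L],
            setdiff(c("A", "C"), b)[1L]),
    var_class = "snp"))
  a <- annotate_variants(vs, refs$gene_models, refs$references)
  expect_equal(a$region, c("intergenic", "intron"))
  expect_true(all(is.na(a$codon_index)))
  expect_equal(a$gene_id[2L], intron_gene$gene_id)
})

test_that("ref mismatches raise the reference/annotation error", {
  fx <- one_gene_fixture("ATGTAA")
  wrong <- setdiff(c("A", "C", "G", "T"),
                   substr(fx$genome$sequence, 3L, 3L))[1L]
  vs <- variant_set(data.frame(genome_id = "toy", pos = 3L, ref = wrong,
                               alt = "T", var_class = "snp"))
  expect_error(annotate_variants(vs, list(fx$gene), list(fx$genome)),
               "reference/annotation inconsistency")
})

test_that("whole-protein translation confirms every exonic annotation", {
  refs <- generate_references(seed = 12L)
  g <- refs$references[[1L]]
  set.seed(12)
  checked <- 0L
  for (gene in refs$gene_models[1:3]) {
    cds <- gene_cds_sequence(gene, g)
    n_cod <- nchar(cds) %/% 3L
    offs <- sample.int(nchar(cds), 25L)
    for (off in offs) {
      gpos <- plastotyper:::coding_to_genomic(gene, off)
      ref_b <- substr(g$sequence, gpos, gpos)
      alt_b <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1L)
      vs <- variant_set(data.frame(genome_id = "cp_ref", pos = gpos,
                                   ref = ref_b, alt = alt_b,
                                   var_class = "snp"))
      a <- annotate_variants(vs, refs$gene_models, refs$references)
      if (a$gene_id != gene$gene_id) next  # landed in an overlapping model
      # independent oracle: translate the whole mutated CDS
      coding_alt <- if (gene$strand == "-") revcomp(alt_b) else alt_b
      mut_cds <- cds
      substr(mut_cds, off, off) <- coding_alt
      tr <- function(s) {
        as.character(Biostrings::translate(
          Biostrings::DNAString(s),
          genetic.code = Biostrings::getGeneticCode("11"),
          no.init.codon = FALSE, if.fuzzy.codon = "X"))
      }
      p0 <- tr(cds); p1 <- tr(mut_cds)
      d <- which(strsplit(p0, "")[[1L]] != strsplit(p1, "")[[1L]])
      if (a$synonymous) {
        expect_length(d, 0L)
      } else {
        expect_equal(d, a$codon_index)
      }
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 50L)
})

test_that("codon positions are uniform over all CDS sites", {
  refs <- generate_references(seed = 6L)
  gene <- refs$gene_models[[1L]]
  cps <- vapply(seq_len(gene$cds_length), function(off) {
    ((off - 1L) %% 3L) + 1L
  }, integer(1L))
  expect_equal(unname(table(cps)), rep(gene$cds_length / 3L, 3L),
               ignore_attr = TRUE)
})

test_that("annotation is invariant under a whole-fixture strand flip", {
  fx <- one_gene_fixture("ATGTCACTGGGATAA", strand = "+")
  pos <- fx$offset + 5L   # codon 2 position 2 (the Ser TCA)
  vs <- variant_set(data.frame(genome_id = "toy", pos = pos, ref = "C",
                               alt = "T", var_class = "snp"))
  a1 <- annotate_variants(vs, list(fx$gene), list(fx$genome))
  # reverse-complement everything
  L <- fx$genome$length
  flip_g <- genome_record("toy", revcomp(fx$genome$sequence), "linear")
  flip_gene <- gene_model("g1", "toy", "-",
                          rbind(c(L - fx$gene$exons[1L, 2L] + 1L,
                                  L - fx$gene$exons[1L, 1L] + 1L)))
  flip_vs <- variant_set(data.frame(genome_id = "toy", pos = L - pos + 1L,
                                    ref = revcomp("C"), alt = revcomp("T"),
                                    var_class = "snp"))
  a2 <- annotate_variants(flip_vs, list(flip_gene), list(flip_g))
  expect_equal(a2$hgvs_p, a1$hgvs_p)
  expect_equal(a2$codon_index, a1$codon_index)
  expect_equal(a2$codon_pos, a1$codon_pos)
})

test_that("SSR detection matches the brute-force maximal-run oracle", {
  g0 <- genome_record("t", "AAAAAAAA", "linear")
  s0 <- detect_ssr_loci(g0, min_mono = 8L)
  expect_equal(nrow(s0), 1L)
  expect_equal(c(s0$start, s0$end), c(1L, 8L))

  set.seed(77)
  for (rep_ in 1:6) {
    seq <- paste(sample(c("A", "C", "G", "T"), 10000L, TRUE,
                        prob = c(0.35, 0.15, 0.15, 0.35)),
                 collapse = "")
    g <- genome_record("r", seq, "linear")
    mine <- detect_ssr_loci(g)
    oracle <- oracle_ssr(seq)
    expect_equal(mine[c("start", "end", "period", "n_units")], oracle,
                 ignore_attr = TRUE)
  }
})

test_that("whole-unit indels inside tracts reclassify as ssr_length", {
  seq <- paste0(strrep("G", 10L), "C", strrep("AT", 6L), "G",
                strrep("C", 10L))
  g <- genome_record("t", seq, "linear")
  ssr <- detect_ssr_loci(g, min_mono = 8L, min_di = 5L)
  anchor <- 11L  # the C before the tract
  vs <- variant_set(data.frame(
    genome_id = "t", pos = c(anchor, anchor),
    ref = c(paste0("C", "AT"), paste0("C", "ATA")),
    alt = c("C", "C"), var_class = "deletion"))
  out <- classify_ssr(vs, ssr)
  expect_equal(out$table$var_class, c("ssr_length", "deletion"))
})
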