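test_that("FASTA parsing normalizes case, topology tokens and U->T", {
  g <- parse_sequences(">x [circular]\nacgu", "fasta")[[1L]]
  expect_s3_class(g, "genome_record")
  expect_equal(g$id, "x")
  expect_equal(g$sequence, "ACGT")
  expect_equal(g$topology, "circular")

  expect_error(parse_sequences(">x\n\n>y\nACGT", "fasta"), "empty sequence")
  expect_error(parse_sequences("ACGT\n>x\nACGT", "fasta"), "line 1")
  expect_error(parse_sequences(">a\nAC\n>a\nGT", "fasta"), "duplicate")
})

test_that("FASTA write/parse round-trips wrapped multi-record files", {
  set.seed(7)
  gs <- list(
    genome_record("alpha", paste(sample(c("A", "C", "G", "T"), 175, TRUE),
                                 collapse = ""), "circular", "chloroplast"),
    genome_record("beta", paste(sample(c("A", "C", "G", "T"), 61, TRUE),
                                collapse = ""), "linear", "mitochondrion"))
  lines <- write_fasta(gs, width = 60L)
  expect_true(all(nchar(lines[!grepl("^>", lines)]) <= 60L))
  back <- parse_sequences(paste(lines, collapse = "\n"), "fasta")
  expect_equal(back, gs)
  # cross-check the writer against the Bioconductor FASTA reader
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_fasta(gs, tmp)
  bs <- Biostrings::readDNAStringSet(tmp)
  expect_equal(unname(as.character(bs)),
               vapply(gs, `[[`, "", "sequence"))
})

test_that("GenBank-lite reads LOCUS topology, ORIGIN and CDS join()", {
  gb <- c("LOCUS       toy        24 bp    DNA     circular PLN",
          "DEFINITION  toy chloroplast genome.",
          "FEATURES             Location/Qualifiers",
          "     CDS             complement(join(2..7,10..15))",
          "                     /gene=\"ndhA\"",
          "ORIGIN",
          "        1 acgtacgtac gtacgtacgt acgt",
          "//")
  p <- parse_genbank_lite(gb)
  g <- p$genomes[[1L]]
  expect_equal(g$id, "toy")
  expect_equal(g$topology, "circular")
  expect_equal(g$length, 24L)
  expect_equal(g$sequence, "ACGTACGTACGTACGTACGTACGT")
  m <- p$gene_models[[1L]]
  expect_equal(m$gene_id, "ndhA")
  expect_equal(m$strand, "-")
  # exons 5'->3' on the coding strand: genomic-right exon first
  expect_equal(unname(m$exons), rbind(c(10L, 15L), c(2L, 7L)))
  expect_equal(m$cds_length, 12L)
  expect_error(parse_genbank_lite("LOCUS x 4 bp\nORIGIN\n 1 acgt"),
               "terminating //")
})

test_that("GFF3 gene models merge CDS segments and validate frame", {
  gff <- c("##gff-version 3",
           "chr\tsrc\tgene\t11\t19\t.\t+\t.\tID=gA",
           "chr\tsrc\tCDS\t11\t19\t.\t+\t0\tID=cA;Parent=gA")
  m <- parse_gene_models(gff)
  expect_length(m, 1L)
  expect_equal(unname(m[[1L]]$exons), rbind(c(11L, 19L)))

  bad <- c("##gff-version 3",
           "chr\tsrc\tCDS\t100\t150\t.\t-\t0\tParent=ndhA_like",
           "chr\tsrc\tCDS\t300\t349\t.\t-\t0\tParent=ndhA_like")
  expect_error(parse_gene_models(bad), "ndhA_like")

  # two-exon minus-strand CDS, total length 99 -> 33 codons
  ok <- c("##gff-version 3",
          "chr\tsrc\tCDS\t100\t150\t.\t-\t0\tParent=gB",
          "chr\tsrc\tCDS\t300\t347\t.\t-\t0\tParent=gB")
  m2 <- parse_gene_models(ok)[[1L]]
  expect_equal(m2$cds_length, 99L)
  expect_equal(unname(m2$exons), rbind(c(300L, 347L), c(100L, 150L)))
  # independent translation-length check on a random genome
  g <- random_genome(400, "linear", seed = 42)
  cds <- gene_cds_sequence(m2, g)
  aa <- Biostrings::translate(Biostrings::DNAString(cds),
                              genetic.code = Biostrings::getGeneticCode("11"),
                              no.init.codon = TRUE)
  expect_equal(length(aa), 33L)
})

test_that("GFF3 write/parse preserves coordinates exactly", {
  set.seed(11)
  for (rep_ in 1:5) {
    n <- sample(1:4, 1L)
    models <- lapply(seq_len(n), function(i) {
      s <- 100L * i + sample.int(50L, 1L)
      w1 <- 3L * sample(4:20, 1L)
      gene_model(paste0("g", i), "chr", sample(c("+", "-"), 1L),
                 rbind(c(s, s + w1 - 1L)))
    })
    back <- parse_gene_models(paste(write_gff3(models), collapse = "\n"))
    for (i in seq_len(n)) {
      expect_equal(back[[i]]$exons, models[[i]]$exons)
      expect_equal(back[[i]]$strand, models[[i]]$strand)
    }
  }
})

test_that("VCF writer/reader round-trip the haploid GT dialect", {
  empty <- variant_set(data.frame(genome_id = character(0), pos = integer(0),
                                  ref = character(0), alt = character(0),
                                  var_class = character(0)))
  lines <- write_vcf(empty)
  expect_true(all(grepl("^#", lines)))
  expect_equal(n_variants(read_vcf(lines)), 0L)

  vs <- variant_set(
    data.frame(genome_id = "NC_test", pos = c(100L, 33315L),
               ref = c("A", "G"), alt = c("AT", "A"),
               var_class = c("insertion", "snp")),
    matrix(c(0L, 0L, 1L, 1L), 2L, 2L, dimnames = list(NULL, c("s1", "s2"))))
  lines <- write_vcf(vs)
  snp_line <- grep("\t33315\t", lines, value = TRUE)
  expect_match(snp_line, "33315\t.\tG\tA\t.\t.\tVC=snp\tGT\t0\t1",
               fixed = TRUE)
  back <- read_vcf(lines)
  expect_equal(back$table, vs$table, ignore_attr = TRUE)
  expect_equal(back$genotypes, vs$genotypes)
  expect_equal(back$table$var_class[1L], "insertion")

  # contract errors
  unsorted <- variant_set(data.frame(genome_id = "c", pos = c(20L, 10L),
                                     ref = c("A", "C"), alt = c("G", "T"),
                                     var_class = "snp"))
  expect_error(write_vcf(unsorted), "not sorted")
  expect_error(write_vcf(vs, samples = c("s1", "zz")), "unknown sample")
})

test_that("random variant sets survive VCF round trips unchanged", {
  set.seed(23)
  bases <- c("A", "C", "G", "T")
  for (rep_ in 1:10) {
    n <- sample(1:12, 1L)
    pos <- sort(sample.int(5000L, n))
    ref <- sample(bases, n, TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    cls <- rep("snp", n)
    ins <- which(stats::runif(n) < 0.3)
    if (length(ins) > 0L) {
      alt[ins] <- paste0(ref[ins],
                         vapply(ins, function(i)
                           paste(sample(bases, sample(1:4, 1L), TRUE),
                                 collapse = ""), ""))
      cls[ins] <- "insertion"
    }
    nsamp <- sample(1:4, 1L)
    gt <- matrix(rbinom(n * nsamp, 1L, 0.5), n, nsamp,
                 dimnames = list(NULL, paste0("s", seq_len(nsamp))))
    vs <- variant_set(data.frame(genome_id = "chr", pos = pos, ref = ref,
                                 alt = alt, var_class = cls), gt)
    back <- read_vcf(write_vcf(vs))
    expect_equal(back$table, vs$table, ignore_attr = TRUE)
    expect_equal(back$genotypes, vs$genotypes)
  }
})

test_that("our VCF output agrees with an independent VCF parser", {
  skip_if_not_installed("vcfR")
  vs <- variant_set(
    data.frame(genome_id = "cp", pos = c(5L, 9L), ref = c("G", "A"),
               alt = c("A", "AT"), var_class = c("snp", "insertion")),
    matrix(c(1L, 0L, 0L, 1L), 2L, 2L, dimnames = list(NULL, c("a", "b"))))
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vs, file = tmp)
  v <- suppressWarnings(vcfR::read.vcfR(tmp, verbose = FALSE))
  expect_equal(as.integer(vcfR::getPOS(v)), c(5L, 9L))
  expect_equal(vcfR::getREF(v), c("G", "A"))
  expect_equal(vcfR::getALT(v), c("A", "AT"))
  gt <- vcfR::extract.gt(v)
  expect_equal(unname(gt[, "a"]), c("1", "0"))
})

test_that("FASTQ pairs round-trip through files", {
  rs <- structure(data.frame(
    id = c("p1", "p2"), seq1 = c("ACGT", "GGCC"), qual1 = c("IIII", "!!!!"),
    seq2 = c("TTAA", "CCGG"), qual2 = c("IIII", "IIII"),
    stringsAsFactors = FALSE), class = c("read_set", "data.frame"))
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq_pair(rs, f1, f2)
  back <- read_fastq_pair(f1, f2)
  expect_equal(as.data.frame(back), as.data.frame(rs))
})
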