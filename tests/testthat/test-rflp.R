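test_that("site scanning honors topology and the worked examples", {
  ecoRI <- rflp_panel()$EcoRI
  lin <- scan_sites(genome_record("l", "AGAATTCA", "linear"), ecoRI)
  expect_equal(lin$sites, 2L)
  expect_equal(lin$fragments, c(1L, 7L))

  circ <- scan_sites(genome_record("c", "AATTCG", "circular"), ecoRI)
  expect_equal(circ$sites, 6L)       # wraps across the origin
  expect_equal(circ$fragments, 6L)

  none <- scan_sites(genome_record("n", "AAAACCCC", "linear"), ecoRI)
  expect_equal(none$n_sites, 0L)
  expect_equal(none$fragments, 8L)   # linear: sites + 1 fragments

  expect_error(restriction_enzyme("bad", "GGQTCC"), "IUPAC")
  expect_error(restriction_enzyme("tiny", "GGA"), "shorter")
})

test_that("N never matches and IUPAC degeneracy does", {
  e <- restriction_enzyme("toy", "GANTC")
  g <- genome_record("g", "TTGACTCAANNNNN", "linear")
  d <- scan_sites(g, e)
  expect_equal(d$sites, 3L)
  # a non-palindromic site is found on the reverse strand too
  np <- restriction_enzyme("np", "GGTCTC")   # BsaI-like
  g2 <- genome_record("h", paste0("AAA", revcomp("GGTCTC"), "AAA"),
                      "linear")
  expect_equal(scan_sites(g2, np)$n_sites, 1L)
})

test_that("Dam-overlapping sites are reported for sensitive enzymes", {
  bcl <- rflp_panel()$BclI
  # TGATCA contains GATC -> always Dam-overlapped
  g <- genome_record("g", "AATGATCAAA", "linear")
  d <- scan_sites(g, bcl)
  expect_equal(d$sites, 3L)
  expect_equal(d$dam_overlapped, 3L)
  # BamHI is not Dam-sensitive: no flag computed
  bam <- rflp_panel()$BamHI
  d2 <- scan_sites(genome_record("g", "AAGGATCCTT", "linear"), bam)
  expect_length(d2$dam_overlapped, 0L)
})

test_that("scanning equals the regex oracle on random circular genomes", {
  set.seed(61)
  enzymes <- c(rflp_panel(),
               list(bsai = restriction_enzyme("BsaI", "GGTCTC"),
                    hinfi = restriction_enzyme("HinfI", "GANTC")))
  for (rep_ in 1:500) {
    L <- sample(60:400, 1L)
    topo <- sample(c("circular", "linear"), 1L)
    g <- genome_record(
      "r", paste(sample(c("A", "C", "G", "T"), L, TRUE,
                        prob = c(0.3, 0.2, 0.2, 0.3)), collapse = ""), topo)
    e <- enzymes[[sample(length(enzymes), 1L)]]
    d <- scan_sites(g, e)
    expect_identical(d$sites, oracle_scan(g, e))
    # conservation invariants
    expect_equal(sum(d$fragments), L)
    if (topo == "circular") {
      expect_equal(length(d$fragments), max(d$n_sites, 1L))
    } else {
      expect_equal(length(d$fragments), d$n_sites + 1L)
    }
  }
})

test_that("variant application edits, maps coordinates and validates", {
  g <- genome_record("g", "AAACCCGGGTTT", "linear")
  empty <- variant_set(data.frame(genome_id = character(0),
                                  pos = integer(0), ref = character(0),
                                  alt = character(0),
                                  var_class = character(0)))
  expect_equal(apply_variants(g, empty)$genome$sequence, g$sequence)

  vs <- variant_set(data.frame(
    genome_id = "g", pos = c(2L, 7L), ref = c("AAC", "G"),
    alt = c("A", "T"), var_class = c("deletion", "snp")))
  ap <- apply_variants(g, vs)
  expect_equal(ap$genome$sequence, "AACCTGGTTT")
  # a deletion before a position shifts its mapped coordinate by -2
  expect_equal(map_to_new(ap$map, 10L), 8L)
  expect_equal(map_to_old(ap$map, 8L), 10L)
  expect_equal(map_to_new(ap$map, 1L), 1L)

  bad <- variant_set(data.frame(genome_id = "g", pos = 1L, ref = "T",
                                alt = "G", var_class = "snp"))
  expect_error(apply_variants(g, bad), "reference mismatch")
  over <- variant_set(data.frame(
    genome_id = "g", pos = c(2L, 3L), ref = c("AAC", "AC"),
    alt = c("A", "A"), var_class = "deletion"))
  expect_error(apply_variants(g, over), "overlapping")
})

test_that("gained sites are attributed to the variant that created them", {
  # GGATCC site completed by a SNP: reference carries GGATAC
  seq <- paste0(strrep("T", 30L), "GGATAC", strrep("C", 30L))
  g <- genome_record("g", seq, "linear")
  vs <- variant_set(
    data.frame(genome_id = "g", pos = 35L, ref = "A", alt = "C",
               var_class = "snp"),
    matrix(c(1L, 0L), 1L, 2L, dimnames = list(NULL, c("mut", "wt"))))
  res <- digest_compare(g, vs, enzymes = rflp_panel()["BamHI"])
  expect_equal(res$counts$n_sites[res$counts$sample == "mut"], 1L)
  expect_equal(res$counts$n_sites[res$counts$sample == "wt"], 0L)
  ev <- res$events
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$change, "gain")
  expect_equal(ev$variant, "g:35A>C")
  # gained + lost counts equal the symmetric difference of site sets
  ref_sites <- res$reference$BamHI$sites
  mut_sites <- res$samples$mut$BamHI$sites
  expect_equal(sum(ev$change == "gain") + sum(ev$change == "loss"),
               length(union(setdiff(ref_sites, mut_sites),
                            setdiff(mut_sites, ref_sites))))
})

test_that("samples whose variants miss all site windows digest like the reference", {
  panel <- fix_panel()
  cp <- panel$references[[1L]]
  res <- digest_compare(cp, panel$variants)
  ref_counts <- vapply(res$reference, `[[`, 1L, "n_sites")
  # every (sample, enzyme) count differs from the reference only where an
  # attribution event exists
  for (i in seq_len(nrow(res$counts))) {
    row <- res$counts[i, ]
    has_event <- !is.null(res$events) &&
      any(res$events$sample == row$sample & res$events$enzyme == row$enzyme)
    if (!has_event) {
      expect_equal(row$n_sites, unname(ref_counts[row$enzyme]))
    }
  }
})

test_that("RFLP grouping is coarser than or equal to sequence-level typing", {
  panel <- fix_panel()
  cp <- panel$references[[1L]]
  res <- digest_compare(cp, panel$variants)
  groups <- rflp_group(res$samples)
  ty <- assign_types(build_matrix(panel$variants, panel$references))
  merged <- merge(groups, ty$table, by = "sample")
  # identical digests -> one group; every cp type maps into exactly one
  # RFLP group (NGS types refine RFLP groups)
  for (t in unique(merged$cp_type)) {
    expect_length(unique(merged$rflp_group[merged$cp_type == t]), 1L)
  }
  expect_lte(length(unique(merged$rflp_group)),
             length(unique(merged$cp_type)))
  # and here strictly coarser: some group holds two or more cp types
  expect_gt(max(table(unique(merged[c("cp_type", "rflp_group")])$rflp_group)),
            1L)
})

test_that("gel-resolution tolerance only ever merges groups", {
  panel <- fix_panel()
  cp <- panel$references[[1L]]
  res <- digest_compare(cp, panel$variants)
  exact <- rflp_group(res$samples, tolerance = 0L)
  for (tol in c(10L, 50L, 200L)) {
    coarse <- rflp_group(res$samples, tolerance = tol)
    # samples identical at tolerance 0 stay identical at any tolerance
    for (g in unique(exact$rflp_group)) {
      members <- exact$sample[exact$rflp_group == g]
      expect_length(unique(coarse$rflp_group[coarse$sample %in% members]),
                    1L)
    }
    expect_lte(length(unique(coarse$rflp_group)),
               length(unique(exact$rflp_group)))
  }
})
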