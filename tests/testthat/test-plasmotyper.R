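two_sample_sets <- function(tables) {
  # helper: named list of single-sample variant_sets from plain tables
  out <- list()
  for (s in names(tables)) {
    tab <- tables[[s]]
    gt <- matrix(1L, nrow(tab), 1L, dimnames = list(NULL, s))
    out[[s]] <- variant_set(tab, gt)
  }
  out
}

test_that("the character matrix is the union of per-sample variant sets", {
  refs <- generate_references(seed = 10L)$references
  snp <- function(pos, ref, alt, cls = "snp", genome = "cp_ref") {
    data.frame(genome_id = genome, pos = pos, ref = ref, alt = alt,
               var_class = cls, stringsAsFactors = FALSE)
  }
  g <- refs[[1L]]$sequence
  b <- function(p) substr(g, p, p)
  alt_of <- function(p) setdiff(c("A", "C", "G", "T"), b(p))[1L]
  sets <- two_sample_sets(list(
    a = rbind(snp(100L, b(100L), alt_of(100L))),
    b = rbind(snp(100L, b(100L), alt_of(100L))),
    c = snp(200L, paste0(b(200L), "AT"), b(200L), cls = "ssr_length")))
  m <- build_matrix(sets, refs, exclude_ssr = FALSE)
  expect_equal(nrow(m$characters), 2L)
  # two identical samples: zero segregating characters between them
  expect_equal(m$states["a", ], m$states["b", ])
  # exclude_ssr drops exactly the ssr characters
  m2 <- build_matrix(sets, refs, exclude_ssr = TRUE)
  expect_equal(setdiff(m$characters$key, m2$characters$key),
               m$characters$key[m$characters$var_class == "ssr_length"])
  # unknown reference -> error
  bad <- two_sample_sets(list(z = snp(5L, "A", "C", genome = "other")))
  expect_error(build_matrix(bad, refs), "unknown reference")
})

test_that("fixture characters equal the planted non-SSR variants", {
  panel <- fix_panel()
  m <- build_matrix(panel$variants, panel$references,
                    outgroup = panel$outgroup)
  planted <- panel$variants$table
  expect_equal(nrow(m$characters),
               sum(planted$var_class != "ssr_length"))
  m_all <- build_matrix(panel$variants, panel$references,
                        exclude_ssr = FALSE)
  expect_equal(nrow(m_all$characters), nrow(planted))
})

test_that("type assignment is a partition with first-appearance labels", {
  panel <- fix_panel()
  m <- build_matrix(panel$variants, panel$references)
  ty <- assign_types(m)
  expect_equal(ty$n_cp_types, 8L)
  expect_equal(ty$n_mt_types, 5L)
  expect_equal(ty$n_plasmotypes, 8L)
  expect_equal(ty$table$cp_type[1L], "I")
  # partition equality with the planted truth (label-free)
  expect_identical(partition_canon(ty$table$sample, ty$table$cp_type),
                   partition_canon(panel$samples, panel$cp_type_of))
  expect_identical(partition_canon(ty$table$sample, ty$table$mt_type),
                   partition_canon(panel$samples, panel$mt_type_of))
  # one sample with a private variant becomes its own type
  vs <- panel$variants
  extra <- data.frame(genome_id = "cp_ref", pos = 70L,
                      ref = substr(panel$references[[1L]]$sequence, 70L, 70L),
                      alt = "A", var_class = "snp")
  if (extra$ref == "A") extra$alt <- "G"
  vs$table <- rbind(vs$table, extra)
  gt_extra <- matrix(0L, 1L, length(panel$samples),
                     dimnames = list(NULL, panel$samples))
  gt_extra[1L, "S09"] <- 1L   # S09 was type I with S01
  vs$genotypes <- rbind(vs$genotypes, gt_extra)
  ty2 <- assign_types(build_matrix(vs, panel$references))
  expect_equal(ty2$n_cp_types, 9L)
  expect_equal(sum(ty2$table$cp_type == ty2$table$cp_type[
    ty2$table$sample == "S09"]), 1L)
})

test_that("Fitch length matches brute-force Sankoff on random instances", {
  m0 <- list(samples = c("a", "b"),
             characters = data.frame(key = "k1"),
             states = matrix(c(0L, 1L), 2L, 1L,
                             dimnames = list(c("a", "b"), "k1")),
             outgroup = "a")
  class(m0) <- "character_matrix"
  tr <- ape::read.tree(text = "(a,b);")
  expect_equal(fitch_length(tr, m0)$total, 1L)

  set.seed(41)
  for (rep_ in 1:12) {
    n <- 6L
    labs <- paste0("t", 1:n)
    tr <- ape::rtree(n, tip.label = sample(labs))
    nchar_ <- sample(3:6, 1L)
    st <- matrix(sample(0:2, n * nchar_, TRUE), n, nchar_,
                 dimnames = list(labs, paste0("c", seq_len(nchar_))))
    m <- list(samples = labs,
              characters = data.frame(key = colnames(st)),
              states = st, outgroup = labs[1L])
    class(m) <- "character_matrix"
    fl <- fitch_length(tr, m)
    oracle <- sum(vapply(seq_len(nchar_), function(k) {
      oracle_sankoff(tr, st[, k])
    }, numeric(1L)))
    expect_equal(fl$total, oracle)
    # and agrees with phangorn's independent implementation
    dat <- phangorn::phyDat(matrix(as.character(st), n,
                                   dimnames = dimnames(st)),
                            type = "USER", levels = c("0", "1", "2"))
    expect_equal(fl$total,
                 as.integer(phangorn::parsimony(tr, dat,
                                                method = "fitch")))
  }
  expect_error(fitch_length(ape::read.tree(text = "(x,y,z);"), m0),
               "match")
})

test_that("homoplasy-free matrices attain the perfect-phylogeny bound", {
  panel <- fix_panel()
  m <- build_matrix(panel$variants, panel$references,
                    molecule_filter = "chloroplast",
                    outgroup = panel$outgroup)
  clean_keys <- names(panel$homoplasy_plan)[panel$homoplasy_plan == "clean"]
  m_clean <- plastotyper:::matrix_subset_chars(
    m, m$characters$key %in% clean_keys)
  clad <- search_tree(m_clean)
  bound <- sum(apply(m_clean$states, 2L, function(x) length(unique(x)) - 1L))
  expect_equal(clad$length, bound)
})

test_that("a single split forces the quartet and duplicates add nothing", {
  sets <- list(A = 0L, B = 0L, C = 1L, D = 1L)
  st <- matrix(unlist(sets), 4L, 1L, dimnames = list(names(sets), "k"))
  m <- list(samples = names(sets), characters = data.frame(key = "k"),
            states = st, outgroup = "A")
  class(m) <- "character_matrix"
  clad <- search_tree(m)
  expect_equal(clad$length, 1L)
  splits <- ape::prop.part(clad$tree)
  expect_true(any(vapply(splits, function(s) {
    setequal(clad$tree$tip.label[s], c("C", "D"))
  }, logical(1L))))

  # duplicate samples sit as zero-length cherries, length unchanged
  st2 <- rbind(st, E = 1L)
  m2 <- list(samples = rownames(st2), characters = data.frame(key = "k"),
             states = st2, outgroup = "A")
  class(m2) <- "character_matrix"
  clad2 <- search_tree(m2)
  expect_equal(clad2$length, 1L)
  expect_true(all(c("D", "E") %in% clad2$tree$tip.label))
})

test_that("the searched tree attains the exhaustive minimum (fixture)", {
  panel <- fix_panel()
  m <- build_matrix(panel$variants, panel$references,
                    molecule_filter = "chloroplast",
                    outgroup = panel$outgroup)
  clad <- search_tree(m)
  # independent oracle: phangorn parsimony over every topology on the
  # type-collapsed matrix
  key <- apply(m$states, 1L, paste, collapse = ",")
  reps <- m$samples[!duplicated(key)]
  st <- m$states[reps, , drop = FALSE]
  dat <- phangorn::phyDat(matrix(as.character(st), nrow(st),
                                 dimnames = dimnames(st)),
                          type = "USER", levels = c("0", "1"))
  trees <- phangorn::allTrees(length(reps), tip.label = reps)
  mins <- min(vapply(trees, function(t) {
    as.integer(phangorn::parsimony(t, dat, method = "fitch"))
  }, integer(1L)))
  expect_equal(clad$length, mins)
})

test_that("stepwise addition + NNI recovers clean trees beyond 8 leaves", {
  # 10 distinct types, nested chain characters (homoplasy-free)
  n <- 10L
  labs <- sprintf("T%02d", 1:n)
  st <- sapply(2:n, function(t) as.integer(seq_len(n) >= t))
  # two characters per split so the optimum is unique
  st <- cbind(st, st)
  dimnames(st) <- list(labs, paste0("c", seq_len(ncol(st))))
  m <- list(samples = labs,
            characters = data.frame(key = colnames(st)),
            states = st, outgroup = labs[1L])
  class(m) <- "character_matrix"
  clad <- search_tree(m)
  expect_equal(clad$length, 2L * (n - 1L))
  expect_true(all(clad$homoplasy$clean))
})

test_that("rooting on the outgroup never changes the parsimony length", {
  panel <- fix_panel()
  m <- build_matrix(panel$variants, panel$references,
                    molecule_filter = "chloroplast",
                    outgroup = panel$outgroup)
  clad <- search_tree(m)
  unrooted <- ape::unroot(clad$tree)
  expect_equal(fitch_length(unrooted, m)$total, clad$length)
})

test_that("planted parallel and reverse characters are classified as such", {
  panel <- fix_panel()
  m <- build_matrix(panel$variants, panel$references,
                    molecule_filter = "chloroplast",
                    outgroup = panel$outgroup)
  clad <- search_tree(m)
  hp <- clad$homoplasy
  plan <- panel$homoplasy_plan[hp$key]
  expect_equal(hp$class[plan == "parallel"], "parallel")
  expect_equal(hp$class[plan == "reverse"], "reverse")
  expect_true(all(hp$class[plan == "clean"] == "clean"))
  # clean characters have exactly one placement per derived state
  for (k in hp$key[hp$clean]) {
    pl <- clad$placements[clad$placements$key == k, ]
    expect_equal(nrow(pl), hp$n_states[hp$key == k] - 1L)
  }
  # total length equals the sum of per-character changes
  expect_equal(clad$length, sum(hp$n_changes))
})
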