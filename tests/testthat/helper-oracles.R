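# Shared fixtures (computed once per session) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

fix_panel <- function() {
  if (is.null(.fixture_cache$panel)) .fixture_cache$panel <- table2_panel()
  .fixture_cache$panel
}

fix_pipeline <- function() {
  if (is.null(.fixture_cache$pipeline)) {
    .fixture_cache$pipeline <- run_pipeline(seed = 20200202L, quiet = TRUE)
  }
  .fixture_cache$pipeline
}

random_genome <- function(len, topology = "circular", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome_record(paste0("g", sample.int(1e6, 1L)),
                paste(sample(c("A", "C", "G", "T"), len, TRUE),
                      collapse = ""), topology)
}

# --- IUPAC site-scan oracle: plain regex over the (doubled) sequence -----
IUPAC_REGEX <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                 S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
                 B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
                 N = "[ACGT]")

site_regex <- function(site) {
  paste(IUPAC_REGEX[strsplit(site, "")[[1L]]], collapse = "")
}

oracle_scan <- function(genome, enzyme) {
  slen <- nchar(enzyme$site)
  seq <- if (genome$topology == "circular") {
    paste0(genome$sequence, substr(genome$sequence, 1L, slen - 1L))
  } else genome$sequence
  find <- function(site) {
    pat <- paste0("(?=", site_regex(site), ")")
    m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m)
  }
  hits <- find(enzyme$site)
  if (enzyme$site != revcomp(enzyme$site)) {
    hits <- c(hits, find(revcomp(enzyme$site)))
  }
  hits <- ((hits - 1L) %% genome$length) + 1L
  if (genome$topology == "linear") {
    hits <- hits[hits + slen - 1L <= genome$length]
  }
  sort(unique(hits))
}

# --- Sankoff small-parsimony oracle (unit costs, recursive DP) ----------
oracle_sankoff <- function(tree, states) {
  # tree: rooted/unrooted ape phylo; states: named integer vector per tip
  lv <- sort(unique(states))
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  cost <- matrix(Inf, nrow = nn, ncol = length(lv))
  for (i in seq_len(ntip)) {
    cost[i, match(states[tree$tip.label[i]], lv)] <- 0
  }
  po <- unique(stats::reorder(tree, "postorder")$edge[, 1L])
  for (node in po) {
    for (s in seq_along(lv)) {
      tot <- 0
      for (ch in kids[[as.character(node)]]) {
        tot <- tot + min(cost[ch, ] + (seq_along(lv) != s))
      }
      cost[node, s] <- tot
    }
  }
  root <- ntip + 1L
  min(cost[root, ])
}

# --- plain full-DP edit alignment oracle (no vectorization tricks) ------
oracle_edit_score <- function(read, window) {
  n <- nchar(read); m <- nchar(window)
  r <- strsplit(read, "")[[1L]]; w <- strsplit(window, "")[[1L]]
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  for (i in 1:n) for (j in 1:m) {
    D[i + 1L, j + 1L] <- min(D[i, j] + (r[i] != w[j]),
                             D[i, j + 1L] + 1L,
                             D[i + 1L, j] + 1L)
  }
  min(D[n + 1L, ])
}

# --- brute-force maximal-run SSR oracle ---------------------------------
oracle_ssr <- function(seq, min_units = c(8L, 5L, 4L)) {
  chars <- strsplit(seq, "")[[1L]]
  L <- length(chars)
  out <- list()
  for (p in 1:3) {
    i <- 1L
    while (i + p <= L + 1L) {
      motif <- chars[i:(i + p - 1L)]
      # extend
      j <- i + p
      while (j + p - 1L <= L &&
             all(chars[j:(j + p - 1L)] == motif)) j <- j + p
      n_units <- (j - i) %/% p
      # maximality on the left: the run cannot be shifted one base left
      full <- !(i > 1L && chars[i - 1L] == chars[i + p - 1L])
      prim <- !(p == 2L && motif[1L] == motif[2L]) &&
        !(p == 3L && length(unique(motif)) == 1L)
      if (full && prim && n_units >= min_units[p]) {
        out[[length(out) + 1L]] <- data.frame(
          start = i, end = i + n_units * p - 1L, period = p,
          n_units = n_units)
      }
      i <- i + 1L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      period = integer(0), n_units = integer(0)))
  }
  res <- unique(do.call(rbind, out))
  res[order(res$start, res$period), , drop = FALSE]
}

# canonical partition representation for label-free comparison
partition_canon <- function(members, labels) {
  unname(sort(vapply(split(members, labels), function(g) {
    paste(sort(g), collapse = ",")
  }, character(1L))))
}
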