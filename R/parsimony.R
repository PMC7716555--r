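# Internal Fitch machinery. Character states (small non-negative integers)
# are encoded as bits so per-node state sets are single integers and all
# characters are processed simultaneously as integer vectors.

state_bits <- function(states) {
  r <- bitwShiftL(1L, as.integer(states))
  if (is.matrix(states)) {
    dim(r) <- dim(states)
    dimnames(r) <- dimnames(states)
  }
  r
}

lowest_bit <- function(x) bitwAnd(x, -x)

bit_to_state <- function(b) as.integer(round(log2(b)))

#' Fitch small-parsimony length of a tree
#'
#' Unit-cost Fitch count per character, summed over characters; equal to
#' Sankoff parsimony with a unit cost matrix. The tree may be rooted or
#' unrooted and may contain multifurcations whose members share identical
#' states (as produced by duplicate-sample cherries); the count is exact on
#' binary trees.
#'
#' @param tree An `ape` "phylo" whose tip labels are exactly the matrix
#'   samples.
#' @param m A `character_matrix` (see [build_matrix()]).
#' @return List with `total` (integer) and `per_character` (named integer
#'   vector of minimal change counts).
#' @export
fitch_length <- function(tree, m) {
  if (!setequal(tree$tip.label, m$samples)) {
    stop("tree leaves do not match matrix samples")
  }
  nchar_ <- nrow(m$characters)
  if (nchar_ == 0L) {
    return(list(total = 0L,
                per_character = stats::setNames(integer(0), character(0))))
  }
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  sets <- matrix(0L, nrow = ntip + nnode, ncol = nchar_)
  sets[seq_len(ntip), ] <- state_bits(m$states[tr$tip.label, , drop = FALSE])
  changes <- integer(nchar_)
  touched <- logical(ntip + nnode)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    cs <- sets[ch, ]
    if (!touched[p]) {
      sets[p, ] <- cs
      touched[p] <- TRUE
    } else {
      inter <- bitwAnd(sets[p, ], cs)
      empty <- inter == 0L
      changes <- changes + empty
      sets[p, ] <- ifelse(empty, bitwOr(sets[p, ], cs), inter)
    }
  }
  list(total = sum(changes),
       per_character = stats::setNames(changes, m$characters$key))
}

# ---- nested-list tree representation used by the search ----------------
# leaf = label string; internal node = list of >= 2 children; the top-level
# node of an unrooted tree has 3 children.

nested_newick <- function(node) {
  if (is.character(node)) return(node)
  paste0("(", paste(vapply(node, nested_newick, character(1L)),
                    collapse = ","), ")")
}

nested_canonical <- function(node) {
  if (is.character(node)) return(node)
  kids <- sort(vapply(node, nested_canonical, character(1L)))
  paste0("(", paste(kids, collapse = ","), ")")
}

# Fitch on the nested representation (sequential pairwise combine, which is
# exact for binary trees rooted at the top-level multifurcation).
fitch_nested <- function(node, bits) {
  if (is.character(node)) {
    return(list(set = bits[node, ], changes = 0L))
  }
  acc <- NULL; changes <- 0L
  for (child in node) {
    r <- fitch_nested(child, bits)
    changes <- changes + r$changes
    if (is.null(acc)) {
      acc <- r$set
    } else {
      inter <- bitwAnd(acc, r$set)
      empty <- inter == 0L
      changes <- changes + sum(empty)
      acc <- ifelse(empty, bitwOr(acc, r$set), inter)
    }
  }
  list(set = acc, changes = changes)
}

# All ways to insert `leaf` on an edge below `node` (top-level trifurcation
# counts its three child edges).
nested_insertions <- function(node, leaf) {
  out <- list()
  for (i in seq_along(node)) {
    child <- node[[i]]
    mod <- node
    mod[[i]] <- list(child, leaf)
    out[[length(out) + 1L]] <- mod
    if (is.list(child)) {
      for (sub in nested_insertions(child, leaf)) {
        mod2 <- node
        mod2[[i]] <- sub
        out[[length(out) + 1L]] <- mod2
      }
    }
  }
  out
}

# Exhaustive enumeration of unrooted binary topologies ((2n-5)!! trees).
enumerate_topologies <- function(labels) {
  stopifnot(length(labels) >= 3L)
  trees <- list(list(labels[1L], labels[2L], labels[3L]))
  for (lab in labels[-(1:3)]) {
    trees <- unlist(lapply(trees, nested_insertions, leaf = lab),
                    recursive = FALSE)
  }
  trees
}

#' Maximum-parsimony tree search with outgroup rooting
#'
#' Identical state vectors are collapsed first (duplicate samples re-attach
#' afterwards as zero-change cherries, leaving the length unchanged). With
#' at most 8 distinct vectors every unrooted topology is scored
#' exhaustively; larger problems use stepwise addition in input order
#' followed by nearest-neighbour-interchange hill climbing (at most
#' `max_nni` accepted rearrangements). Among equally parsimonious trees the
#' lexicographically smallest canonical newick wins, so the search is
#' deterministic. The tree is finally rooted on the branch leading to the
#' outgroup(s).
#'
#' @param m A `character_matrix` with a non-empty `outgroup`.
#' @param max_nni NNI iteration cap.
#' @return A `cladogram`: list with `tree` (rooted "phylo"), `newick`,
#'   `length` (parsimony changes), `per_character`, `homoplasy`
#'   (see [classify_homoplasy()]), `duplicates` (map of collapsed
#'   samples).
#' @export
search_tree <- function(m, max_nni = 200L) {
  if (length(m$samples) < 3L) stop("need at least 3 samples")
  if (length(m$outgroup) == 0L) stop("no outgroup in matrix")
  if (!all(m$outgroup %in% m$samples)) stop("outgroup absent from matrix")
  key <- apply(m$states, 1L, paste, collapse = ",")
  reps <- m$samples[!duplicated(key)]
  groups <- split(m$samples, match(key, unique(key)))
  names(groups) <- reps
  bits <- state_bits(m$states[reps, , drop = FALSE])
  rownames(bits) <- reps
  d <- length(reps)

  if (d <= 2L) {
    nw <- if (d == 1L) {
      paste0("(", paste(m$samples, collapse = ","), ");")
    } else {
      paste0("(", paste(vapply(groups, function(g)
        if (length(g) == 1L) g else
          paste0("(", paste(g, collapse = ","), ")"), character(1L)),
        collapse = ","), ");")
    }
    # groups already expanded into the newick: pass singleton groups only
    return(finish_cladogram(nw, m,
                            stats::setNames(as.list(unlist(groups)),
                                            unlist(groups))))
  }

  if (d <= 8L) {
    cands <- enumerate_topologies(reps)
    lens <- vapply(cands, function(tr) fitch_nested(tr, bits)$changes,
                   integer(1L))
    best <- which(lens == min(lens))
    if (length(best) > 1L) {
      canon <- vapply(cands[best], nested_canonical, character(1L))
      best <- best[order(canon)[1L]]
    }
    nw <- paste0(nested_newick(cands[[best[1L]]]), ";")
  } else {
    cur <- list(reps[1L], reps[2L], reps[3L])
    for (lab in reps[-(1:3)]) {
      cands <- nested_insertions(cur, lab)
      lens <- vapply(cands, function(tr) fitch_nested(tr, bits)$changes,
                     integer(1L))
      best <- which(lens == min(lens))
      if (length(best) > 1L) {
        canon <- vapply(cands[best], nested_canonical, character(1L))
        best <- best[order(canon)[1L]]
      }
      cur <- cands[[best[1L]]]
    }
    sub_m <- m
    sub_m$samples <- reps
    sub_m$states <- m$states[reps, , drop = FALSE]
    phy <- ape::read.tree(text = paste0(nested_newick(cur), ";"))
    cur_len <- fitch_length(phy, sub_m)$total
    for (it in seq_len(max_nni)) {
      nbrs <- phangorn::nni(phy)
      nlens <- vapply(nbrs, function(t) fitch_length(t, sub_m)$total,
                      integer(1L))
      if (min(nlens) >= cur_len) break
      phy <- nbrs[[which.min(nlens)]]
      cur_len <- min(nlens)
    }
    nw <- ape::write.tree(phy)
  }
  finish_cladogram(nw, m, groups)
}

# Expand duplicate groups into cherries, root on the outgroup, classify.
finish_cladogram <- function(nw, m, groups) {
  for (rep_ in names(groups)) {
    g <- groups[[rep_]]
    if (length(g) > 1L) {
      repl <- paste0("(", paste(g, collapse = ","), ")")
      nw <- gsub(paste0("(?<=[(,])", rep_, "(?=[,)])"), repl, nw,
                 perl = TRUE)
    }
  }
  phy <- ape::read.tree(text = nw)
  og <- intersect(m$outgroup, phy$tip.label)
  rooted <- if (length(og) > 0L) {
    r <- try(ape::root(phy, outgroup = og, resolve.root = TRUE),
             silent = TRUE)
    if (inherits(r, "try-error")) {
      ape::root(phy, outgroup = og[1L], resolve.root = TRUE)
    } else r
  } else phy
  fl <- fitch_length(rooted, m)
  hp <- classify_homoplasy(rooted, m)
  structure(list(tree = rooted, newick = ape::write.tree(rooted),
                 length = fl$total, per_character = fl$per_character,
                 homoplasy = hp$classes, placements = hp$placements,
                 duplicates = groups),
            class = "cladogram")
}

#' @export
print.cladogram <- function(x, ...) {
  cat(sprintf("<cladogram> %d leaves, parsimony length %d\n",
              length(x$tree$tip.label), x$length))
  if (!is.null(x$homoplasy) && nrow(x$homoplasy) > 0L) {
    n_par <- sum(x$homoplasy$parallel); n_rev <- sum(x$homoplasy$reverse)
    cat(sprintf("  homoplasy: %d parallel (>), %d reverse (!)\n",
                n_par, n_rev))
  }
  invisible(x)
}

#' Map character changes onto a rooted cladogram and classify homoplasy
#'
#' Ancestral states are reconstructed by a Fitch down-pass followed by a
#' final pass resolving ties toward the parent's state (the root toward the
#' outgroup's state). A character is `clean` when its number of changes
#' equals its number of observed states minus one; otherwise it is
#' `parallel` when some derived state arises on two or more branches and/or
#' `reverse` when a change re-enters a state that is ancestral on the path
#' to the root (both flags can be set; such "!"/">" marks are the classic
#' cladogram annotations for reversals and parallelisms).
#'
#' @param tree Rooted "phylo" over the matrix samples.
#' @param m A `character_matrix`.
#' @return List with `classes` (data.frame `key`, `n_changes`, `n_states`,
#'   `clean`, `parallel`, `reverse`, `class`) and `placements` (data.frame
#'   `key`, `parent`, `child`, `child_label`, `from_state`, `to_state`).
#' @export
classify_homoplasy <- function(tree, m) {
  if (!setequal(tree$tip.label, m$samples)) {
    stop("tree leaves do not match matrix samples")
  }
  nch <- nrow(m$characters)
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  root <- ntip + 1L
  sets <- matrix(0L, nrow = ntip + nnode, ncol = nch)
  if (nch > 0L) {
    sets[seq_len(ntip), ] <-
      state_bits(m$states[tr$tip.label, , drop = FALSE])
  }
  touched <- logical(ntip + nnode)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    cs <- sets[ch, ]
    if (!touched[p]) {
      sets[p, ] <- cs; touched[p] <- TRUE
    } else {
      inter <- bitwAnd(sets[p, ], cs)
      sets[p, ] <- ifelse(inter == 0L, bitwOr(sets[p, ], cs), inter)
    }
  }
  # final pass
  final <- matrix(0L, nrow = ntip + nnode, ncol = nch)
  og_tip <- match(intersect(m$outgroup, tr$tip.label)[1L], tr$tip.label)
  for (k in seq_len(nch)) {
    rs <- sets[root, k]
    pref <- if (!is.na(og_tip)) bitwAnd(rs, sets[og_tip, k]) else 0L
    final[root, k] <- if (pref != 0L) lowest_bit(pref) else lowest_bit(rs)
  }
  # preorder = reverse postorder edge order
  for (e in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    keep <- bitwAnd(sets[ch, ], final[p, ])
    final[ch, ] <- ifelse(keep != 0L, final[p, ], lowest_bit(sets[ch, ]))
  }
  parent_of <- integer(ntip + nnode)
  parent_of[tr$edge[, 2L]] <- tr$edge[, 1L]
  classes <- list(); placements <- list()
  for (k in seq_len(nch)) {
    chg_e <- which(final[tr$edge[, 1L], k] != final[tr$edge[, 2L], k])
    n_changes <- length(chg_e)
    n_states <- length(unique(m$states[, k]))
    to_states <- bit_to_state(final[tr$edge[chg_e, 2L], k])
    from_states <- bit_to_state(final[tr$edge[chg_e, 1L], k])
    parallel <- any(table(to_states) >= 2L)
    reverse <- FALSE
    for (j in seq_along(chg_e)) {
      node <- tr$edge[chg_e[j], 1L]
      b <- final[tr$edge[chg_e[j], 2L], k]
      while (node != root) {
        node <- parent_of[node]
        if (final[node, k] == b) { reverse <- TRUE; break }
      }
      if (reverse) break
    }
    clean <- n_changes == n_states - 1L
    classes[[k]] <- data.frame(
      key = m$characters$key[k], n_changes = n_changes,
      n_states = n_states, clean = clean, parallel = parallel,
      reverse = reverse,
      class = if (clean) "clean" else if (parallel && reverse) "both"
              else if (parallel) "parallel" else if (reverse) "reverse"
              else "clean",
      stringsAsFactors = FALSE)
    if (n_changes > 0L) {
      child_nodes <- tr$edge[chg_e, 2L]
      placements[[k]] <- data.frame(
        key = m$characters$key[k],
        parent = tr$edge[chg_e, 1L], child = child_nodes,
        child_label = ifelse(child_nodes <= ntip,
                             tr$tip.label[child_nodes],
                             paste0("node", child_nodes)),
        from_state = from_states, to_state = to_states,
        stringsAsFactors = FALSE)
    }
  }
  list(classes = if (length(classes)) do.call(rbind, classes) else
         data.frame(key = character(0), n_changes = integer(0),
                    n_states = integer(0), clean = logical(0),
                    parallel = logical(0), reverse = logical(0),
                    class = character(0)),
       placements = if (length(placements)) do.call(rbind, placements)
         else NULL)
}
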