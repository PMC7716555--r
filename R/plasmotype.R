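#' Build the sample x variant character matrix
#'
#' The union of variant loci across samples becomes the character list;
#' each sample's state at a character is its allele index (0 = reference).
#' SSR-length characters are excluded by default, matching the practice of
#' building organelle cladograms from SNPs and indels but not
#' microsatellites.
#'
#' @param x Either a multi-sample [variant_set] or a named list (sample id
#'   -> [variant_set]) to be unioned; in the list form each set's genotype
#'   column for that sample is used (a set without genotype columns is
#'   taken as all-alternate for that sample).
#' @param references List of [genome_record]; all samples must be called
#'   against this same reference set.
#' @param molecule_filter Molecule classes to keep
#'   (default chloroplast + mitochondrion).
#' @param exclude_ssr Drop `ssr_length` characters (default `TRUE`).
#' @param outgroup Character vector of sample ids used later for rooting.
#' @return A `character_matrix`: list with `samples`, `characters`
#'   (data.frame `key`, `genome_id`, `pos`, `ref`, `alt`, `var_class`,
#'   `molecule_class`), `states` (samples x characters integer matrix) and
#'   `outgroup`.
#' @export
build_matrix <- function(x, references,
                         molecule_filter = c("chloroplast", "mitochondrion"),
                         exclude_ssr = TRUE, outgroup = character(0)) {
  ref_ids <- vapply(references, `[[`, "", "id")
  mol_of <- stats::setNames(vapply(references, `[[`, "", "molecule_class"),
                            ref_ids)
  if (inherits(x, "variant_set")) {
    sets <- lapply(variant_samples(x), function(s) {
      variant_set(x$table, x$genotypes[, s, drop = FALSE])
    })
    names(sets) <- variant_samples(x)
  } else {
    sets <- x
  }
  stopifnot(length(sets) > 0L, !is.null(names(sets)))
  samples <- names(sets)
  rows <- list()
  for (s in samples) {
    vs <- sets[[s]]
    bad <- setdiff(unique(vs$table$genome_id), ref_ids)
    if (length(bad) > 0L) {
      stop("sample ", s, " called against unknown reference: ",
           paste(bad, collapse = ", "))
    }
    allele <- if (ncol(vs$genotypes) == 0L) rep(1L, n_variants(vs))
              else as.integer(vs$genotypes[, intersect(colnames(vs$genotypes),
                                                       s)[1L]])
    keep <- allele > 0L
    if (any(keep)) {
      rows[[s]] <- cbind(vs$table[keep, , drop = FALSE],
                         sample = s, allele = allele[keep])
    }
  }
  all_rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genome_id = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               var_class = character(0), sample = character(0),
               allele = integer(0))
  chars <- unique(all_rows[c("genome_id", "pos", "ref", "alt", "var_class")])
  chars$molecule_class <- unname(mol_of[chars$genome_id])
  chars <- chars[chars$molecule_class %in% molecule_filter, , drop = FALSE]
  if (exclude_ssr) chars <- chars[chars$var_class != "ssr_length", ,
                                  drop = FALSE]
  chars <- chars[order(chars$genome_id, chars$pos, chars$alt), ,
                 drop = FALSE]
  chars$key <- paste(chars$genome_id, chars$pos, chars$ref, chars$alt,
                     sep = ":")
  rownames(chars) <- NULL
  states <- matrix(0L, nrow = length(samples), ncol = nrow(chars),
                   dimnames = list(samples, chars$key))
  if (nrow(all_rows) > 0L && nrow(chars) > 0L) {
    key_all <- paste(all_rows$genome_id, all_rows$pos, all_rows$ref,
                     all_rows$alt, sep = ":")
    hit <- match(key_all, chars$key)
    ok <- !is.na(hit)
    states[cbind(match(all_rows$sample[ok], samples), hit[ok])] <-
      all_rows$allele[ok]
  }
  stopifnot(all(outgroup %in% samples))
  structure(list(samples = samples, characters = chars, states = states,
                 outgroup = outgroup),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("<character_matrix> %d sample(s) x %d character(s)\n",
              length(x$samples), nrow(x$characters)))
  invisible(x)
}

matrix_subset_chars <- function(m, keep) {
  m$characters <- m$characters[keep, , drop = FALSE]
  m$states <- m$states[, keep, drop = FALSE]
  m
}

#' Assign chloroplast/mitochondrial DNA types and plasmotypes
#'
#' The cpDNA type of a sample is the equivalence class of its state vector
#' over chloroplast characters (likewise mtDNA over mitochondrial
#' characters); the plasmotype is the (cp type, mt type) pair. Labels are
#' Roman numerals in order of first appearance, so relabeling is
#' deterministic for a fixed sample order; comparisons across runs should
#' be partition-based, not label-based.
#'
#' @param m A `character_matrix`.
#' @return List with `table` (data.frame `sample`, `cp_type`, `mt_type`,
#'   `plasmotype`), `n_cp_types`, `n_mt_types`, `n_plasmotypes`.
#' @export
assign_types <- function(m) {
  part_labels <- function(cols) {
    sub <- m$states[, cols, drop = FALSE]
    key <- apply(sub, 1L, paste, collapse = ",")
    as.character(as.roman(match(key, unique(key))))
  }
  cp <- part_labels(m$characters$molecule_class == "chloroplast")
  mt <- part_labels(m$characters$molecule_class == "mitochondrion")
  plas <- paste0(cp, "/", mt)
  tab <- data.frame(sample = m$samples, cp_type = cp, mt_type = mt,
                    plasmotype = plas, stringsAsFactors = FALSE)
  list(table = tab,
       n_cp_types = length(unique(cp)),
       n_mt_types = length(unique(mt)),
       n_plasmotypes = length(unique(plas)))
}
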