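#' Haploid variant set
#'
#' Container for reference edits with per-sample haploid genotypes, the
#' common currency between the caller, the annotator, the typing matrix and
#' the in silico digest. Coordinates are 1-based; `pos` is the first
#' reference base affected. Insertions and deletions use VCF anchoring:
#' `ref` and `alt` share their first base. `ssr_length` marks indels that
#' are whole-unit changes of a microsatellite tract.
#'
#' @param table data.frame with columns `genome_id`, `pos`, `ref`, `alt`,
#'   `var_class` (one of snp, insertion, deletion, ssr_length).
#' @param genotypes Integer matrix, variants x samples, allele index
#'   (0 = reference, 1 = alternate). May have zero columns.
#' @return A `variant_set` object.
#' @export
variant_set <- function(table, genotypes = NULL) {
  req <- c("genome_id", "pos", "ref", "alt", "var_class")
  stopifnot(is.data.frame(table), all(req %in% names(table)))
  table <- as.data.frame(table[req], stringsAsFactors = FALSE)
  table$pos <- as.integer(table$pos)
  n <- nrow(table)
  if (is.null(genotypes)) {
    genotypes <- matrix(integer(0), nrow = n, ncol = 0L)
  }
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != n) stop("genotypes rows != number of variants")
  validate_variant_rows(table)
  structure(list(table = table, genotypes = genotypes),
            class = "variant_set")
}

validate_variant_rows <- function(tab) {
  ok_class <- tab$var_class %in% c("snp", "insertion", "deletion",
                                   "ssr_length")
  if (!all(ok_class)) stop("unknown var_class: ",
                           paste(unique(tab$var_class[!ok_class]),
                                 collapse = ", "))
  snp <- tab$var_class == "snp"
  if (any(snp & (nchar(tab$ref) != 1L | nchar(tab$alt) != 1L |
                 tab$ref == tab$alt))) {
    stop("snp rows must have single differing ref/alt bases")
  }
  ind <- !snp
  if (any(ind & substr(tab$ref, 1L, 1L) != substr(tab$alt, 1L, 1L))) {
    stop("indel rows must share their first (anchor) base")
  }
  invisible(TRUE)
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d variant(s), %d sample(s)\n",
              nrow(x$table), ncol(x$genotypes)))
  invisible(x)
}

n_variants <- function(vs) nrow(vs$table)

variant_samples <- function(vs) colnames(vs$genotypes)

# Stable key for set comparisons.
variant_keys <- function(vs) {
  with(vs$table, paste(genome_id, pos, ref, alt, sep = ":"))
}

# Subset rows of a variant_set.
variant_subset <- function(vs, idx) {
  variant_set(vs$table[idx, , drop = FALSE],
              vs$genotypes[idx, , drop = FALSE])
}

# Infer var_class from ref/alt shapes (used when no explicit tag is given).
infer_var_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snp",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}
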