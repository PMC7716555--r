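#' Restriction enzyme definition
#'
#' @param name Enzyme name.
#' @param site IUPAC recognition sequence, length >= 4.
#' @param dam_sensitive Is digestion blocked by Dam methylation (GATC)?
#' @return A `restriction_enzyme` object.
#' @export
restriction_enzyme <- function(name, site, dam_sensitive = FALSE) {
  site <- toupper(site)
  if (nchar(site) < 4L) stop("recognition site shorter than 4 bp")
  if (grepl("[^ACGTRYSWKMBDHVN]", site)) {
    stop("invalid IUPAC character in site '", site, "'")
  }
  structure(list(name = name, site = site,
                 dam_sensitive = isTRUE(dam_sensitive)),
            class = "restriction_enzyme")
}

#' The four-enzyme panel used for historical barley cpDNA RFLP work
#'
#' BamHI, BclI, EcoRI and HindIII; BclI is Dam-sensitive. All four sites are
#' palindromic.
#'
#' @return Named list of [restriction_enzyme].
#' @export
rflp_panel <- function() {
  list(BamHI = restriction_enzyme("BamHI", "GGATCC"),
       BclI = restriction_enzyme("BclI", "TGATCA", dam_sensitive = TRUE),
       EcoRI = restriction_enzyme("EcoRI", "GAATTC"),
       HindIII = restriction_enzyme("HindIII", "AAGCTT"))
}

iupac_palindromic <- function(site) identical(site, revcomp(site))

# IUPAC match starts of `site` on the plain string `seq` (top strand only).
iupac_match_starts <- function(site, seq) {
  if (nchar(seq) < nchar(site)) return(integer(0))
  Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(site), Biostrings::DNAString(seq),
    fixed = "subject"))
}

#' Scan a genome for restriction sites and compute the digest
#'
#' Positions are the 1-based start of the top-strand match of the
#' recognition sequence. Circular genomes are scanned on
#' sequence + prefix(site length - 1) with positions reduced modulo the
#' length, so origin-spanning sites are found. Palindromic sites are counted
#' once; for non-palindromic enzymes the reverse strand is scanned too and
#' reported at top-strand coordinates. `N` never matches. Fragments are
#' obtained by cutting at site starts: a circular genome with s >= 1 sites
#' yields s fragments summing to the genome length; a linear genome yields
#' s + 1 fragments.
#'
#' @param genome A [genome_record].
#' @param enzyme A [restriction_enzyme].
#' @return A `digest_result`: list with `genome_id`, `enzyme`, `sites`
#'   (sorted positions), `n_sites`, `fragments` (lengths), `dam_overlapped`
#'   (subset of `sites` sharing >= 4 bp with a GATC occurrence, computed
#'   only for Dam-sensitive enzymes).
#' @export
scan_sites <- function(genome, enzyme) {
  stopifnot(inherits(genome, "genome_record"),
            inherits(enzyme, "restriction_enzyme"))
  slen <- nchar(enzyme$site)
  L <- genome$length
  padded <- padded_sequence(genome, slen - 1L)
  starts <- iupac_match_starts(enzyme$site, padded)
  if (!iupac_palindromic(enzyme$site)) {
    rc <- iupac_match_starts(revcomp(enzyme$site), padded)
    starts <- c(starts, rc)
  }
  starts <- sort(unique(((starts - 1L) %% L) + 1L))
  if (genome$topology == "linear") starts <- starts[starts + slen - 1L <= L]
  dam <- integer(0)
  if (enzyme$dam_sensitive && length(starts) > 0L) {
    gatc <- iupac_match_starts("GATC", padded_sequence(genome, 3L))
    gatc <- sort(unique(((gatc - 1L) %% L) + 1L))
    if (length(gatc) > 0L) {
      ov <- vapply(starts, function(s) {
        any(pmin(s + slen - 1L, gatc + 3L) - pmax(s, gatc) + 1L >= 4L) ||
          (genome$topology == "circular" &&
             any(pmin(s + slen - 1L, gatc + L + 3L) -
                   pmax(s, gatc + L) + 1L >= 4L))
      }, logical(1L))
      dam <- starts[ov]
    }
  }
  fragments <- if (genome$topology == "circular") {
    # an uncut circle is one full-length (circular) molecule
    if (length(starts) <= 1L) L
    else c(diff(starts), L - starts[length(starts)] + starts[1L])
  } else {
    c(starts, L + 1L) - c(1L, starts)
  }
  structure(list(genome_id = genome$id, enzyme = enzyme$name,
                 sites = starts, n_sites = length(starts),
                 fragments = as.integer(fragments),
                 dam_overlapped = dam),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("<digest> %s x %s: %d site(s)\n", x$genome_id, x$enzyme,
              x$n_sites))
  invisible(x)
}

#' Apply variants to a reference, producing a mutated genome
#'
#' Edits are applied in descending-position order so earlier coordinates
#' stay valid. Returns the mutated record together with an old->new
#' coordinate map for reporting positions of the mutated genome back in
#' reference coordinates.
#'
#' @param genome A [genome_record].
#' @param vs A [variant_set] restricted to this genome.
#' @param alleles Integer vector (one per variant row): allele to apply
#'   (0 = reference, 1 = alternate). Defaults to all-1.
#' @return List with `genome` (mutated [genome_record]), `map` (data.frame
#'   `old_pos`, `shift`: new = old + shift for positions at/after
#'   `old_pos`), and helpers are provided by [map_to_new()] / [map_to_old()].
#' @export
apply_variants <- function(genome, vs, alleles = NULL) {
  mine <- vs$table$genome_id == genome$id
  if (is.null(alleles)) alleles <- rep(1L, nrow(vs$table))
  stopifnot(length(alleles) == nrow(vs$table))
  tab <- vs$table[mine & alleles == 1L, , drop = FALSE]
  tab <- tab[order(tab$pos), , drop = FALSE]
  if (nrow(tab) > 1L) {
    ends <- tab$pos + nchar(tab$ref) - 1L
    if (any(tab$pos[-1L] <= ends[-nrow(tab)])) stop("overlapping variants")
  }
  seq <- genome$sequence
  shifts <- integer(nrow(tab))
  for (i in rev(seq_len(nrow(tab)))) {
    p <- tab$pos[i]; ref <- tab$ref[i]; alt <- tab$alt[i]
    if (substr(seq, p, p + nchar(ref) - 1L) != ref) {
      stop("reference mismatch at ", genome$id, ":", p, " (expected ", ref,
           ", found ", substr(seq, p, p + nchar(ref) - 1L), ")")
    }
    seq <- paste0(substr(seq, 1L, p - 1L), alt,
                  substr(seq, p + nchar(ref), nchar(seq)))
    shifts[i] <- nchar(alt) - nchar(ref)
  }
  map <- data.frame(old_pos = tab$pos + nchar(tab$ref),
                    shift = cumsum(shifts))
  mut <- genome_record(genome$id, seq, genome$topology,
                       genome$molecule_class)
  list(genome = mut, map = map)
}

#' Map a reference coordinate to the mutated genome
#' @param map The `map` element returned by [apply_variants()].
#' @param pos Integer vector of reference positions.
#' @return Integer vector of positions on the mutated genome.
#' @export
map_to_new <- function(map, pos) {
  if (nrow(map) == 0L) return(as.integer(pos))
  idx <- findInterval(pos, map$old_pos)
  as.integer(pos + c(0L, map$shift)[idx + 1L])
}

#' Map a mutated-genome coordinate back to the reference
#' @param map The `map` element returned by [apply_variants()].
#' @param pos Integer vector of positions on the mutated genome.
#' @return Integer vector of reference positions (positions inside an
#'   inserted segment map to the anchor base).
#' @export
map_to_old <- function(map, pos) {
  if (nrow(map) == 0L) return(as.integer(pos))
  new_breaks <- map$old_pos + map$shift
  idx <- findInterval(pos, new_breaks)
  as.integer(pos - c(0L, map$shift)[idx + 1L])
}

#' Digest every sample's mutated genome and attribute site gains/losses
#'
#' For each sample the variants it carries (allele 1) are applied to the
#' reference, each enzyme is scanned, and gained/lost sites relative to the
#' reference digest are attributed to the variant whose edited window
#' overlaps the site (or `"multiple"`). Gained-site positions are reported
#' in reference coordinates via the coordinate map.
#'
#' @param genome Reference [genome_record].
#' @param vs A [variant_set] with per-sample genotypes.
#' @param enzymes List of [restriction_enzyme] (default [rflp_panel()]).
#' @return List with `reference` (digests per enzyme), `samples` (per sample
#'   per enzyme `digest_result`), `counts` (data.frame sample x enzyme site
#'   counts), and `events` (data.frame of gains/losses with attribution).
#' @export
digest_compare <- function(genome, vs, enzymes = rflp_panel()) {
  ref_dig <- lapply(enzymes, scan_sites, genome = genome)
  names(ref_dig) <- vapply(enzymes, `[[`, "", "name")
  samples <- variant_samples(vs)
  res <- list(); counts <- list(); events <- list()
  mine <- vs$table$genome_id == genome$id
  for (s in samples) {
    alleles <- ifelse(mine, vs$genotypes[, s], 0L)
    ap <- apply_variants(genome, vs, alleles)
    tab <- vs$table[alleles == 1L, , drop = FALSE]
    per_enzyme <- lapply(enzymes, scan_sites, genome = ap$genome)
    names(per_enzyme) <- names(ref_dig)
    res[[s]] <- per_enzyme
    for (en in names(ref_dig)) {
      dig <- per_enzyme[[en]]
      slen <- nchar(enzymes[[which(names(ref_dig) == en)]]$site)
      sample_sites_ref_coord <- map_to_old(ap$map, dig$sites)
      gained <- setdiff(sample_sites_ref_coord, ref_dig[[en]]$sites)
      lost <- setdiff(ref_dig[[en]]$sites, sample_sites_ref_coord)
      counts[[length(counts) + 1L]] <-
        data.frame(sample = s, enzyme = en, n_sites = dig$n_sites,
                   stringsAsFactors = FALSE)
      chg <- rbind(
        if (length(gained)) data.frame(pos = gained, change = "gain"),
        if (length(lost)) data.frame(pos = lost, change = "loss"))
      if (!is.null(chg)) for (ci in seq_len(nrow(chg))) {
        site_lo <- chg$pos[ci]; site_hi <- chg$pos[ci] + slen - 1L
        hit <- which(tab$pos + pmax(nchar(tab$ref), nchar(tab$alt)) - 1L >=
                       site_lo &
                     tab$pos <= site_hi)
        attrib <- if (length(hit) == 1L)
          paste0(tab$genome_id[hit], ":", tab$pos[hit], tab$ref[hit], ">",
                 tab$alt[hit])
          else if (length(hit) > 1L) "multiple" else "unattributed"
        events[[length(events) + 1L]] <-
          data.frame(sample = s, enzyme = en, pos = chg$pos[ci],
                     change = chg$change, variant = attrib,
                     dam_overlapped = chg$pos[ci] %in% dig$dam_overlapped,
                     stringsAsFactors = FALSE)
      }
    }
  }
  list(reference = ref_dig,
       samples = res,
       counts = if (length(counts)) do.call(rbind, counts) else NULL,
       events = if (length(events)) do.call(rbind, events) else NULL)
}

#' Group samples into RFLP patterns
#'
#' Samples with identical fragment-length multisets across the enzyme panel
#' fall in one group — the in silico analogue of indistinguishable gel
#' patterns. A gel-resolution tolerance merges fragments differing by less
#' than `tolerance` bp (binning); `0` means exact comparison. Groups are
#' labeled by Roman numerals in order of first appearance.
#'
#' @param sample_digests The `samples` element of [digest_compare()].
#' @param tolerance Non-negative integer, bp.
#' @return data.frame `sample`, `rflp_group`.
#' @export
rflp_group <- function(sample_digests, tolerance = 0L) {
  stopifnot(tolerance >= 0L)
  key_of <- function(digs) {
    paste(vapply(names(digs), function(en) {
      fr <- sort(digs[[en]]$fragments)
      if (tolerance > 0L) fr <- fr %/% as.integer(tolerance)
      paste0(en, "=", paste(fr, collapse = ","))
    }, character(1L)), collapse = ";")
  }
  keys <- vapply(sample_digests, key_of, character(1L))
  labels <- as.roman(match(keys, unique(keys)))
  data.frame(sample = names(sample_digests),
             rflp_group = as.character(labels),
             stringsAsFactors = FALSE, row.names = NULL)
}
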