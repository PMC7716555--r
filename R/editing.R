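#' Common plastid C-to-U editing conversions
#'
#' The amino-acid conversions most frequently produced by angiosperm
#' plastid editing; configurable in [screen_editing_candidates()].
#' @return Character vector of `"Xaa>Yaa"` strings.
#' @export
common_editing_conversions <- function() {
  c("Ser>Leu", "Ser>Phe", "Pro>Leu", "Pro>Ser", "His>Tyr", "Thr>Ile",
    "Arg>Trp", "Ala>Val")
}

#' Screen annotated SNPs for plastid RNA-editing-site geometry
#'
#' Plastid editing is overwhelmingly a C-to-U conversion at the mRNA level,
#' preferentially at second codon positions, with Ser-to-Leu the most
#' common amino-acid change. A DNA polymorphism whose two alleles are C and
#' T on the coding strand therefore mimics an edited/unedited pair: the
#' T-bearing allele needs no correction, the C-bearing allele could be
#' corrected by the editing machinery.
#'
#' Eligibility requires an exonic SNP whose coding-strand alleles are
#' \{C, T\}. The reported `conversion` is always read in the editing
#' direction, from the C-bearing to the T-bearing codon. Tiers:
#' \describe{
#'   \item{1}{second codon position and Ser>Leu;}
#'   \item{2}{second codon position or a conversion in `common_set`;}
#'   \item{3}{any other eligible site, including synonymous ones.}
#' }
#' Exonic transitions that cannot be written as C>T on the coding strand
#' (coding G/A pairs) are returned with `tier = "not_candidate"` and
#' `atypical = TRUE`; with `allow_reverse = TRUE` coding \{G, A\} pairs are
#' additionally screened as putative reverse (U-to-C) events, conversion
#' read from the G-bearing to the A-bearing codon.
#'
#' @param annotations A `variant_annotation` data.frame
#'   (see [annotate_variants()]); only exonic SNP rows are screened.
#' @param common_set Conversion strings counted as common.
#' @param allow_reverse Also screen coding G/A pairs (default `FALSE`).
#' @return data.frame of class `editing_screen`: variant columns plus
#'   `is_ct_coding`, `codon_pos2`, `conversion`, `common_conversion`,
#'   `tier` (`"1"`, `"2"`, `"3"`, `"not_candidate"`), `atypical`; sorted by
#'   tier then position. Deterministic: no randomness is involved.
#' @export
screen_editing_candidates <- function(annotations,
                                      common_set = common_editing_conversions(),
                                      allow_reverse = FALSE) {
  a <- annotations[annotations$region == "exon" &
                     annotations$var_class == "snp" &
                     !is.na(annotations$codon_index), , drop = FALSE]
  n <- nrow(a)
  is_ct <- codon2 <- common <- atypical <- logical(n)
  conv <- character(n)
  tier <- rep("not_candidate", n)
  for (i in seq_len(n)) {
    alleles <- c(a$coding_ref[i], a$coding_alt[i])
    aas <- c(a$aa_ref[i], a$aa_alt[i])
    is_ct[i] <- setequal(alleles, c("C", "T"))
    is_ga <- setequal(alleles, c("G", "A"))
    transition <- is_ct[i] || is_ga
    codon2[i] <- a$codon_pos[i] == 2L
    eligible <- is_ct[i] || (allow_reverse && is_ga)
    atypical[i] <- !is_ct[i] && transition
    if (!eligible) {
      conv[i] <- ""
      next
    }
    # read the conversion in the editing direction: C->T (or G->A when
    # screening reverse events)
    from <- if (is_ct[i]) "C" else "G"
    o <- if (alleles[1L] == from) 1:2 else 2:1
    conv[i] <- if (aas[o[1L]] == aas[o[2L]]) "silent"
               else paste0(aas[o[1L]], ">", aas[o[2L]])
    common[i] <- conv[i] %in% common_set
    tier[i] <- if (codon2[i] && conv[i] == "Ser>Leu") "1"
               else if (codon2[i] || common[i]) "2"
               else "3"
  }
  res <- data.frame(a[c("genome_id", "pos", "ref", "alt", "gene_id",
                        "codon_index", "codon_pos", "hgvs_p")],
                    is_ct_coding = is_ct, codon_pos2 = codon2,
                    conversion = conv, common_conversion = common,
                    tier = tier, atypical = atypical,
                    stringsAsFactors = FALSE)
  ord <- order(match(res$tier, c("1", "2", "3", "not_candidate")), res$pos)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("editing_screen", "data.frame")
  res
}
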