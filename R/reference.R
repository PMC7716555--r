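#' Locate a local copy of the barley chloroplast reference (NC_008590)
#'
#' Several checks (the literature restriction-site counts, the infA/matK/ndhK
#' annotations) are defined on the public Hordeum vulgare chloroplast
#' genome NC_008590, which is not redistributed with the package. This
#' helper returns the path where a user-supplied copy is looked up:
#' the `plastotyper.reference_dir` option if set, else
#' `inst/extdata`/`extdata` of the installed package. Expected files are
#' `NC_008590.fasta` (the header should carry the `[circular]` token) and
#' optionally `NC_008590.gb` (GenBank flat file, for gene models) or
#' `NC_008590.gff3`.
#'
#' @param filename File to resolve (default the FASTA).
#' @return Full path (which may not exist; see [hv_reference_available()]).
#' @export
hv_reference_path <- function(filename = "NC_008590.fasta") {
  dir <- getOption("plastotyper.reference_dir",
                   system.file("extdata", package = "plastotyper"))
  file.path(dir, filename)
}

#' Is the real chloroplast reference available locally?
#' @return `TRUE` when the FASTA resolved by [hv_reference_path()] exists.
#' @export
hv_reference_available <- function() {
  file.exists(hv_reference_path())
}

#' Load the barley chloroplast reference and its gene models
#'
#' Reads the user-supplied NC_008590 files (see [hv_reference_path()]).
#' The annotation release used is whatever feature table was supplied;
#' its provenance is reported in the returned `source` fields.
#'
#' @return List with `genome` ([genome_record], forced circular),
#'   `gene_models` (possibly empty) and `source` (file paths used).
#' @export
load_hv_reference <- function() {
  fa <- hv_reference_path()
  if (!file.exists(fa)) {
    stop("NC_008590.fasta not found at ", fa,
         "; supply the public reference (see ?hv_reference_path)")
  }
  gb <- hv_reference_path("NC_008590.gb")
  gff <- hv_reference_path("NC_008590.gff3")
  if (file.exists(gb)) {
    parsed <- parse_genbank_lite(gb)
    genome <- parsed$genomes[[1L]]
    models <- parsed$gene_models
    src <- gb
  } else {
    genome <- parse_sequences(fa, "fasta")[[1L]]
    models <- if (file.exists(gff)) parse_gene_models(gff) else list()
    src <- if (file.exists(gff)) c(fa, gff) else fa
  }
  # organelle replicons are circular regardless of header tokens
  genome <- genome_record(genome$id, genome$sequence, "circular",
                          "chloroplast")
  list(genome = genome, gene_models = models, source = src)
}
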