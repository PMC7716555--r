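#' Default pipeline configuration
#'
#' All stage parameters with their defaults; any entry can be overridden
#' via the `config` argument of [run_pipeline()]. Unknown keys are
#' rejected before any stage runs.
#'
#' @return Nested named list of stage parameter defaults.
#' @export
default_config <- function() {
  list(
    panel = list(k_cp = 8L, k_mt = 5L, n_samples = 15L,
                 homoplasy = c("parallel", "reverse")),
    references = list(cp_length = 6000L, mt_length = 9000L, n_genes = 6L,
                      n_introns = 1L,
                      ssr_spec = list(list(motif = "A", units = 12L),
                                      list(motif = "AT", units = 6L)),
                      shared_segment_length = 400L),
    reads = list(depth = 50, read_length = 150L, fragment_mean = 350,
                 fragment_sd = 30, error_rate = 0.002, cp_fraction = 0.5,
                 quality_tail = TRUE),
    trim = list(window = 4L, q_threshold = 15L, min_length = 36L),
    map = list(max_mismatch_rate = 0.1, band = 8L, max_insert = 2000L),
    call = list(min_depth = 10L, min_fraction = 0.8,
                mask_ambiguous = TRUE),
    typing = list(exclude_ssr = TRUE),
    digest = list(tolerance = 0L)
  )
}

merge_config <- function(config) {
  def <- default_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad) > 0L) stop("unknown config section: ",
                             paste(bad, collapse = ", "))
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
    if (length(bad) > 0L) {
      stop("unknown config key in '", sec, "': ",
           paste(bad, collapse = ", "))
    }
    def[[sec]] <- utils::modifyList(def[[sec]], config[[sec]])
  }
  def
}

#' Run the whole plasmotyping pipeline on a simulated panel
#'
#' Simulate (references, planted haplotypes, mixed-organelle reads), then
#' per sample trim / assign to the double reference / call haploid
#' variants, then annotate, screen editing candidates, assign cp/mt types
#' and plasmotypes, build the outgroup-rooted maximum-parsimony cladogram
#' with homoplasy marks, and run the variant-aware in silico digest with
#' RFLP grouping. All outputs are pure functions of `(config, seed)`; the
#' returned `manifest` records both.
#'
#' @param config Nested list overriding [default_config()] entries.
#' @param seed Global seed; each stage derives its own stream from it.
#' @param out_dir Optional directory: when given, FASTA/GFF3/FASTQ/VCF/
#'   TSV/newick/JSON result files are written there.
#' @param quiet Suppress progress messages.
#' @return List with `panel`, `calls` (per sample), `panel_calls`
#'   (combined [variant_set]), `annotations`, `editing`, `matrix`, `types`,
#'   `cladogram`, `digest`, `rflp_groups`, `comparison` (RFLP group vs cp
#'   type), `metrics` (precision/recall against the planted truth) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = list(), seed = 1L, out_dir = NULL,
                         quiet = FALSE) {
  cfg <- merge_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  say("stage=simulate seed=%d", seed)
  refs <- generate_references(cfg$references, seed = seed)
  panel <- do.call(plant_haplotypes,
                   c(list(refs), cfg$panel, list(seed = seed)))
  index <- build_index(panel$references)
  ssr_tab <- do.call(rbind, lapply(panel$references, function(g) {
    s <- detect_ssr_loci(g)
    if (nrow(s) > 0L) cbind(genome_id = g$id, s) else NULL
  }))
  calls <- list()
  for (s in panel$samples) {
    gs <- sample_genomes(panel, s)
    sim <- do.call(simulate_reads,
                   c(list(gs), cfg$reads,
                     list(seed = seed, sample_id = s)))
    trimmed <- do.call(trim_reads, c(list(sim$reads), cfg$trim))
    mapped <- do.call(map_reads, c(list(trimmed, index), cfg$map))
    calls[[s]] <- do.call(pileup_and_call,
                          c(list(mapped, panel$references, sample_id = s),
                            cfg$call, list(ssr_loci = ssr_tab)))
    say("stage=call sample=%s pairs=%d variants=%d", s,
        sum(calls[[s]]$fate), n_variants(calls[[s]]$variants))
  }
  panel_calls <- combine_sample_calls(lapply(calls, `[[`, "variants"),
                                      panel$samples)
  annotations <- annotate_variants(panel_calls, panel$gene_models,
                                   panel$references)
  editing <- screen_editing_candidates(annotations)
  m <- build_matrix(panel_calls, panel$references,
                    exclude_ssr = cfg$typing$exclude_ssr,
                    outgroup = panel$outgroup)
  types <- assign_types(m)
  # the cladogram is built from the chloroplast characters (the cp-genome
  # tree); mt characters cross-cut it and only enter the typing table
  m_cp <- build_matrix(panel_calls, panel$references,
                       molecule_filter = "chloroplast",
                       exclude_ssr = cfg$typing$exclude_ssr,
                       outgroup = panel$outgroup)
  clad <- search_tree(m_cp)
  dig <- digest_compare(panel$references[[1L]], panel_calls)
  groups <- rflp_group(dig$samples, tolerance = cfg$digest$tolerance)
  comparison <- merge(types$table[c("sample", "cp_type")], groups,
                      by = "sample")
  metrics <- planted_recovery_metrics(panel, calls)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("plastotyper")),
                   seed = seed, config = cfg, timestamp = format(Sys.time()))
  res <- list(panel = panel, calls = calls, panel_calls = panel_calls,
              annotations = annotations, editing = editing, matrix = m,
              types = types, cladogram = clad, digest = dig,
              rflp_groups = groups, comparison = comparison,
              metrics = metrics, manifest = manifest)
  if (!is.null(out_dir)) write_report_bundle(res, out_dir)
  res
}

# Union the per-sample call sets into one multi-sample variant_set.
combine_sample_calls <- function(vs_list, samples) {
  keys <- unique(unlist(lapply(vs_list, variant_keys)))
  tabs <- do.call(rbind, lapply(vs_list, `[[`, "table"))
  tabs <- tabs[!duplicated(paste(tabs$genome_id, tabs$pos, tabs$ref,
                                 tabs$alt, sep = ":")), , drop = FALSE]
  tabs <- tabs[order(tabs$genome_id, tabs$pos), , drop = FALSE]
  key_o <- paste(tabs$genome_id, tabs$pos, tabs$ref, tabs$alt, sep = ":")
  gt <- matrix(0L, nrow = nrow(tabs), ncol = length(samples),
               dimnames = list(NULL, samples))
  for (s in samples) {
    vk <- variant_keys(vs_list[[s]])
    gt[match(vk, key_o), s] <- vs_list[[s]]$genotypes[, 1L]
  }
  variant_set(tabs, gt)
}

# Precision/recall of called variants against the planted truth,
# per sample, pooled over the panel.
planted_recovery_metrics <- function(panel, calls,
                                     classes = c("snp", "insertion",
                                                 "deletion")) {
  truth_tab <- panel$variants$table
  tp <- fp <- fn <- 0L
  tp_ssr <- fn_ssr <- 0L
  for (s in panel$samples) {
    tkeep <- panel$variants$genotypes[, s] == 1L
    tkeys <- variant_keys(panel$variants)[tkeep]
    tclass <- truth_tab$var_class[tkeep]
    called <- calls[[s]]$variants
    ckeys <- variant_keys(called)
    cclass <- called$table$var_class
    t_main <- tkeys[tclass %in% classes]
    c_main <- ckeys[cclass %in% classes]
    tp <- tp + length(intersect(t_main, c_main))
    fp <- fp + length(setdiff(c_main, t_main))
    fn <- fn + length(setdiff(t_main, c_main))
    t_ssr <- tkeys[tclass == "ssr_length"]
    c_ssr <- ckeys[cclass == "ssr_length"]
    tp_ssr <- tp_ssr + length(intersect(t_ssr, c_ssr))
    fn_ssr <- fn_ssr + length(setdiff(t_ssr, c_ssr))
  }
  list(precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
       tp = tp, fp = fp, fn = fn,
       ssr_recall = if (tp_ssr + fn_ssr > 0L) tp_ssr / (tp_ssr + fn_ssr)
                    else NA_real_)
}

# Write the text report bundle of one pipeline run.
write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(res$panel$references, file.path(out_dir, "references.fasta"))
  write_gff3(res$panel$gene_models, file.path(out_dir, "genes.gff3"))
  write_vcf(res$panel_calls, res$panel$references,
            file.path(out_dir, "panel_calls.vcf"))
  utils::write.table(res$annotations,
                     file.path(out_dir, "variant_annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$editing,
                     file.path(out_dir, "editing_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$types$table,
                     file.path(out_dir, "plasmotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(res$cladogram$newick, file.path(out_dir, "cladogram.nwk"))
  utils::write.table(res$cladogram$homoplasy,
                     file.path(out_dir, "homoplasy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$digest$counts,
                     file.path(out_dir, "digest_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(merge(res$rflp_groups, res$types$table,
                           by = "sample"),
                     file.path(out_dir, "rflp_vs_ngs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  no_call <- do.call(rbind, lapply(names(res$calls), function(s) {
    nc <- res$calls[[s]]$no_call
    if (is.null(nc)) return(NULL)
    cbind(sample = s, nc)
  }))
  if (!is.null(no_call)) {
    bed <- data.frame(chrom = no_call$genome_id,
                      start = no_call$start - 1L,  # BED 0-based half-open
                      end = no_call$end, name = no_call$sample)
    utils::write.table(bed, file.path(out_dir, "no_call.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(out_dir)
}
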