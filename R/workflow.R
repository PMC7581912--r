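#' Default run configuration
#'
#' Stage configurations with the workflow's canonical defaults: 120-base
#' capture probes, 5000-base gap criterion, 25-mer binning probes,
#' 16 = 8+8 boundary markers with up to 3 mismatches, LG fraction 0.75.
#'
#' @param seed integer seed propagated to all stochastic stages.
#' @return object of class `RunConfig`.
#' @export
run_config <- function(seed = 1) {
  structure(list(
    sim = sim_config(seed = seed),
    design = design_config(),
    bin = bin_config(),
    annotation = annotation_config(),
    eval = eval_config(),
    seed = as.integer(seed),
    paths = list()
  ), class = "RunConfig")
}

config_constructors <- function() {
  list(sim = sim_config, design = design_config, bin = bin_config,
       annotation = annotation_config, eval = eval_config)
}

#' Load a run configuration from a YAML file
#'
#' Missing sections and fields fall back to the package defaults; unknown
#' sections or fields are an error (listing them), so typos never silently
#' change a run.
#'
#' @param path YAML file, or `NULL`/empty file for all defaults.
#' @return a `RunConfig`.
#' @export
load_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  ctors <- config_constructors()
  known_top <- c(names(ctors), "seed", "paths")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  seed <- if (!is.null(raw$seed)) as.integer(raw$seed) else 1L
  cfg <- run_config(seed = seed)
  for (section in names(ctors)) {
    over <- raw[[section]]
    if (is.null(over)) next
    ctor <- ctors[[section]]
    allowed <- names(formals(ctor))
    unknown <- setdiff(names(over), allowed)
    if (length(unknown) > 0) {
      stop("unknown config key(s) in '", section, "': ",
           paste(unknown, collapse = ", "))
    }
    args <- lapply(over, function(v) if (length(v) > 1) unlist(v) else v)
    if (section == "sim" && is.null(args$seed)) args$seed <- seed
    cfg[[section]] <- do.call(ctor, args)
  }
  if (!is.null(raw$paths)) cfg$paths <- raw$paths
  cfg
}

stage_manifest <- function(name, params, paths) {
  paths <- unlist(paths)
  hashes <- tools::md5sum(paths[file.exists(paths)])
  list(stage = name, params = params,
       outputs = as.list(hashes))
}

#' Run the full workflow on synthetic data
#'
#' simulate -> design -> bin -> (assemble) -> annotate -> evaluate. The
#' assembly step is an external hook: when `assemble_cmd` is given it is
#' invoked once per bin directory (with `{bins}` and `{out}` placeholders);
#' by default the bypass is used, cutting each simulated haplotype at
#' truth intergenic midpoints into error-free haplotigs so the downstream
#' stages run without an assembler. Every stage writes its outputs plus a
#' manifest of parameters and output md5 hashes; re-running with the same
#' config and seed reproduces byte-identical outputs.
#'
#' @param config a `RunConfig` (see [run_config()], [load_run_config()]).
#' @param out_dir run directory (created).
#' @param assemble_cmd optional external assembler command template.
#' @return list with the in-memory stage results (`sim`, `panel`,
#'   `binning`, `haplotigs`, `annotation`, `report`) and `manifest`.
#' @export
run_workflow <- function(config, out_dir, assemble_cmd = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  for (p in unlist(config$paths)) {
    if (!file.exists(p)) stop("missing input path: ", p)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    res
  }

  # simulate
  sim <- run_stage("simulate", function() simulate_diploid(config$sim))
  hseqs <- hap_seqs(sim$haplotypes)
  reads <- run_stage("simulate", function() {
    simulate_reads(sim$haplotypes, config$sim)
  })
  hap_fa <- file.path(out_dir, "haplotypes.fasta")
  write_fasta(hseqs, hap_fa)
  reads_fq <- file.path(out_dir, "reads.fastq")
  truth_tsv <- file.path(out_dir, "read_truth.tsv")
  write_reads_fastq(reads, reads_fq, truth_tsv)
  truth_gff <- file.path(out_dir, "feature_truth.gff3")
  write_gff3(unlist(lapply(sim$haplotypes, `[[`, "features"),
                    recursive = FALSE), truth_gff)
  repeats_bed <- file.path(out_dir, "repeats.bed")
  rep_df <- do.call(rbind, lapply(sim$haplotypes, function(h) {
    if (nrow(h$repeats) == 0) return(NULL)
    data.frame(chrom = h$name, start = h$repeats$start, end = h$repeats$end)
  }))
  write.table(rep_df, repeats_bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  manifest$simulate <- stage_manifest("simulate", unclass(config$sim),
                                      c(hap_fa, reads_fq, truth_tsv,
                                        truth_gff, repeats_bed))

  # design
  refs <- lapply(sim$haplotypes, function(h) {
    masked_reference(h$name, h$sequence, h$repeats)
  })
  panel <- run_stage("design", function() {
    cands <- enumerate_candidates(refs, config$design)
    greedy_select(cands, refs, config$design)
  })
  panel_fa <- file.path(out_dir, "panel.fasta")
  panel_bed <- file.path(out_dir, "panel_hits.bed")
  write_panel(panel, panel_fa, panel_bed)
  gaps <- coverage_gaps(panel, refs)
  gap_tsv <- file.path(out_dir, "panel_gaps.tsv")
  gap_df <- do.call(rbind, lapply(names(gaps), function(rid) {
    data.frame(ref_id = rid, max_gap = gaps[[rid]]$max_gap,
               mean_gap = gaps[[rid]]$mean_gap)
  }))
  write.table(gap_df, gap_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$design <- stage_manifest("design", unclass(config$design),
                                    c(panel_fa, panel_bed, gap_tsv))

  # bin
  catalog <- derive_locus_catalog(sim$haplotypes, config$bin)
  panel_index <- build_kmer_index(panel_sequences(panel), config$bin)
  on_off <- run_stage("bin", function() {
    classify_on_target(reads, panel_index, config$bin)
  })
  binning <- run_stage("bin", function() {
    bin_by_locus(on_off$on, catalog, config$bin)
  })
  bin_dir <- file.path(out_dir, "bins")
  bin_paths <- write_bins(binning, bin_dir, on_off)
  manifest$bin <- stage_manifest("bin", unclass(config$bin), bin_paths)

  # assemble (external hook) or truth-breakpoint bypass
  if (!is.null(assemble_cmd)) {
    asm_out <- file.path(out_dir, "assembly.fasta")
    cmd <- gsub("{bins}", bin_dir, gsub("{out}", asm_out,
                                        assemble_cmd, fixed = TRUE),
                fixed = TRUE)
    status <- system(cmd)
    if (status != 0) stop("stage 'assemble' failed: exit status ", status)
    haplotigs <- read_fasta(asm_out)
  } else {
    haplotigs <- unlist(lapply(sim$haplotypes, function(h) {
      fragment_haplotigs(h$sequence, truth_breakpoints(h),
                         prefix = paste0(h$name, "_htg"))
    }))
  }
  htg_fa <- file.path(out_dir, "haplotigs.fasta")
  write_fasta(haplotigs, htg_fa)
  manifest$assemble <- stage_manifest("assemble",
                                      list(external = !is.null(assemble_cmd)),
                                      htg_fa)

  # annotate
  patterns <- learn_locus_patterns(sim$haplotypes, panel, config$annotation)
  markers <- build_boundary_markers(sim$haplotypes, config$annotation)
  ann <- run_stage("annotate", function() {
    annotate_haplotigs(haplotigs, panel, patterns, markers,
                       config$annotation, catalog = catalog)
  })
  tbl_path <- file.path(out_dir, "annotation.tbl")
  gff_path <- file.path(out_dir, "annotation.gff3")
  write_tbl(ann, tbl_path)
  write_gff3(ann, gff_path)
  manifest$annotate <- stage_manifest("annotate", unclass(config$annotation),
                                      c(tbl_path, gff_path))

  # evaluate
  ref_lengths <- nchar(hseqs)
  records <- align_exact(haplotigs, hseqs)
  paf_path <- file.path(out_dir, "alignments.paf")
  write_paf(records, paf_path, ref_lengths)
  report <- run_stage("evaluate", function() {
    evaluate_assembly(records, ref_lengths, config$eval)
  })
  write_eval_report(report, file.path(out_dir, "evaluation.tsv"),
                    file.path(out_dir, "evaluation.json"))
  manifest$evaluate <- stage_manifest("evaluate", unclass(config$eval),
                                      c(paf_path,
                                        file.path(out_dir, "evaluation.tsv"),
                                        file.path(out_dir, "evaluation.json")))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(sim = sim, panel = panel, binning = binning,
                 haplotigs = haplotigs, annotation = ann, report = report,
                 manifest = manifest))
}

#' Panel size: homologous versus unrelated loci
#'
#' Builds two single-haplotype design instances of equal structure — one
#' whose three loci descend from one shared master-block family
#' (homologous), one whose loci come from three independent families
#' (unrelated) — designs a panel on each, and returns the panel sizes.
#' Probe hits are counted with a small substitution tolerance, reflecting
#' that hybridization capture (and cross-locus homology) tolerates a few
#' mismatches over a 120-base probe.
#'
#' @param seed integer seed (paired: both instances use it).
#' @param n_genes loci per instance (default 3).
#' @param allow_mismatches design-time hit tolerance (default 4).
#' @param max_gap gap criterion (default 5000).
#' @return named numeric vector `c(homologous = ..., unrelated = ...)`.
#' @export
panel_size_experiment <- function(seed, n_genes = 3, allow_mismatches = 4,
                                  max_gap = 5000) {
  dcfg <- design_config(allow_mismatches = allow_mismatches,
                        max_gap = max_gap)
  build_instance <- function(templates, locus_order, hap_seed) {
    spec <- haplotype_spec("ref", locus_order)
    hap <- simulate_haplotype(spec, templates, seed = hap_seed)
    masked_reference(hap$name, hap$sequence, hap$repeats)
  }
  # homologous: one template family
  hom_cfg <- sim_config(n_loci = n_genes + 1, seed = seed)
  hom_tpl <- build_locus_templates(hom_cfg)
  genes <- setdiff(names(hom_tpl), "IGR")
  hom_ref <- build_instance(hom_tpl, genes, hap_seed = seed + 11L)
  # unrelated: one gene template from each of n_genes independent families
  unrel_tpl <- list()
  for (i in seq_len(n_genes)) {
    tpl_i <- build_locus_templates(sim_config(n_loci = 2,
                                              seed = seed + 1000L * i))
    t <- tpl_i[["G1"]]
    t$locus_name <- paste0("U", i)
    unrel_tpl[[paste0("U", i)]] <- t
  }
  unrel_ref <- build_instance(unrel_tpl, names(unrel_tpl),
                              hap_seed = seed + 11L)
  size_of <- function(ref) {
    cands <- enumerate_candidates(list(ref), dcfg)
    panel <- greedy_select(cands, list(ref), dcfg)
    length(panel$probes)
  }
  c(homologous = size_of(hom_ref), unrelated = size_of(unrel_ref))
}
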