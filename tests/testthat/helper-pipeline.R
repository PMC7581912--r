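# End-to-end closure harness shared by the annotation/evaluation tests and
# the acceptance suite: simulate a diploid pair, design a panel, learn
# patterns and markers from the (self-annotated) references, break each
# haplotype at truth intergenic midpoints into error-free haplotigs,
# annotate, and evaluate against the haplotypes.
pipeline_closure <- function(seed, n_loci = 4) {
  cfg <- sim_config(n_loci = n_loci, seed = seed)
  sim <- simulate_diploid(cfg)
  refs <- sim_refs(sim)
  dcfg <- design_config()
  panel <- greedy_select(enumerate_candidates(refs, dcfg), refs, dcfg)
  acfg <- annotation_config()
  patterns <- learn_locus_patterns(sim$haplotypes, panel, acfg)
  markers <- build_boundary_markers(sim$haplotypes, acfg)
  catalog <- derive_locus_catalog(sim$haplotypes, bin_config())

  elements_exact <- TRUE
  locus_order_exact <- TRUE
  haplotigs_all <- character(0)
  for (hap in sim$haplotypes) {
    htgs <- fragment_haplotigs(hap$sequence, truth_breakpoints(hap),
                               prefix = paste0(hap$name, "_htg"))
    haplotigs_all <- c(haplotigs_all, htgs)
    offsets <- cumsum(c(0, nchar(htgs)))[seq_along(htgs)]
    names(offsets) <- names(htgs)
    ann <- annotate_haplotigs(htgs, panel, patterns, markers, acfg,
                              catalog = catalog)
    got_order <- vapply(ann, `[[`, character(1), "locus_name")
    want_order <- vapply(hap$features, `[[`, character(1), "locus_name")
    locus_order_exact <- locus_order_exact && identical(got_order, want_order)
    for (tf in hap$features) {
      inside <- offsets <= tf$start & offsets + nchar(htgs) >= tf$end
      containing <- names(offsets)[inside][1]
      cand <- Filter(function(a) {
        a$haplotig_id == containing && a$locus_name == tf$locus_name
      }, ann)
      ok <- FALSE
      if (length(cand) == 1) {
        a <- cand[[1]]
        te <- tf$elements
        te$start <- te$start - offsets[[containing]]
        te$end <- te$end - offsets[[containing]]
        keep <- grepl("^exon|^intron", te$label)
        ae <- a$elements[grepl("^exon|^intron", a$elements$label), ,
                         drop = FALSE]
        te <- te[keep, c("label", "start", "end"), drop = FALSE]
        rownames(te) <- NULL
        rownames(ae) <- NULL
        ok <- isTRUE(all.equal(te, ae[, c("label", "start", "end")],
                               check.attributes = FALSE))
      }
      elements_exact <- elements_exact && ok
    }
  }
  ref_seqs <- vapply(sim$haplotypes, `[[`, character(1), "sequence")
  names(ref_seqs) <- names(sim$haplotypes)
  records <- align_exact(haplotigs_all, ref_seqs)
  report <- evaluate_assembly(records, nchar(ref_seqs), eval_config())
  list(sim = sim, panel = panel, report = report,
       elements_exact = elements_exact,
       locus_order_exact = locus_order_exact)
}

# a minimal annotated "reference" with one two-element feature whose
# junction is flanked by known 8-base half-sites
two_element_ref <- function(left_tail = "ACACGTGG", right_head = "GTGAGTCC",
                            locus = "L", seed = 71) {
  el1 <- paste0(substring(random_seq(60, seed), 1, 52), left_tail)
  el2 <- paste0(right_head, substring(random_seq(60, seed + 1), 1, 52))
  structure(list(
    name = "ref", sequence = paste0(el1, el2),
    features = list(list(haplotig_id = "ref", locus_name = locus,
                         start = 0L, end = 120L, strand = "+",
                         elements = data.frame(
                           label = c("exon2", "intron2"),
                           start = c(0L, 60L), end = c(60L, 120L)),
                         allele_name = NA_character_)),
    repeats = data.frame(start = integer(0), end = integer(0))
  ), class = "SimHaplotype")
}
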