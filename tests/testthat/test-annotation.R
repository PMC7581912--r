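test_that("boundary markers take 8 bases from each flanking element", {
  cfg <- annotation_config()
  ref <- two_element_ref()
  mk <- build_boundary_markers(ref, cfg)
  expect_equal(nrow(mk), 1)
  expect_identical(mk$marker, "ACACGTGGGTGAGTCC")
  expect_identical(mk$left_half, "ACACGTGG")
  expect_identical(mk$right_half, "GTGAGTCC")
  expect_equal(nchar(mk$marker), 16)
  # an element shorter than 8 bases yields no marker, with a warning
  short <- two_element_ref()
  short$features[[1]]$elements <- data.frame(
    label = c("exon2", "intron2"), start = c(0L, 5L), end = c(5L, 120L))
  expect_warning(mk2 <- build_boundary_markers(short, cfg), "skipped")
  expect_equal(nrow(mk2), 0)
})

test_that("marker halves re-concatenate and self-annotation recovers truth
           junctions exactly", {
  cfg <- annotation_config()
  sim <- small_sim(seed = 17, n_loci = 3)
  mk <- build_boundary_markers(sim$haplotypes, cfg)
  expect_true(all(nchar(mk$marker) == 16))
  expect_identical(paste0(mk$left_half, mk$right_half), mk$marker)
  # scan each source feature with its own markers: every truth junction
  # must come back at its exact position
  for (hap in sim$haplotypes) {
    for (f in hap$features) {
      lm <- mk[mk$locus_name == f$locus_name, , drop = FALSE]
      if (nrow(lm) == 0) next
      fseq <- substring(hap$sequence, f$start + 1, f$end)
      jn <- scan_boundaries(fseq, lm, cfg, offset = f$start)
      truth_pos <- f$elements$end[-nrow(f$elements)]
      expect_true(all(jn$found))
      expect_equal(jn$pos, truth_pos)
    }
  }
})

test_that("boundary scanning escalates mismatch tolerance minimally", {
  cfg <- annotation_config()
  marker <- "ACACGTGGGTGAGTCC"
  base <- random_seq(2000, seed = 73)
  site <- 1000L  # 0-based marker start
  seq0 <- paste0(substring(base, 1, site), marker,
                 substring(base, site + 17, 2000))
  mk <- data.frame(locus_name = "L", junction_index = 1L,
                   left_element = "exon2", right_element = "intron2",
                   marker = marker, left_half = "ACACGTGG",
                   right_half = "GTGAGTCC", ambiguous = FALSE)
  mutate_at <- function(s, k) {
    # substitute k distinct marker bases (positions spread over the marker)
    pos <- site + c(1, 4, 7, 10, 13, 16)[seq_len(k)]
    for (p in pos) {
      old <- substring(s, p, p)
      substring(s, p, p) <- if (old == "A") "C" else "A"
    }
    s
  }
  for (k in 0:3) {
    s <- mutate_at(seq0, k)
    # precondition: the mutated site is the only candidate window
    expect_identical(oracle_scan(marker, s, 3), site)
    jn <- scan_boundaries(s, mk, cfg)
    expect_true(jn$found)
    expect_equal(jn$pos, site + 8L)
    expect_equal(jn$mismatches, k)  # minimal escalation
  }
  s4 <- mutate_at(seq0, 4)
  expect_length(oracle_scan(marker, s4, 3), 0)
  jn4 <- scan_boundaries(s4, mk, cfg)
  expect_false(jn4$found)
  # recovered-junction sets are nested across thresholds
  s2 <- mutate_at(seq0, 2)
  found_at <- vapply(0:3, function(t) {
    c2 <- annotation_config(max_marker_mismatches = t)
    scan_boundaries(s2, mk, c2)$found
  }, logical(1))
  expect_identical(found_at, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("marker hits equal an exhaustive Hamming-window scan", {
  cfg <- annotation_config()
  sim <- small_sim(seed = 19, n_loci = 3)
  hap <- sim$haplotypes[[1]]
  mk <- build_boundary_markers(sim$haplotypes, cfg)
  f <- hap$features[[1]]
  lm <- mk[mk$locus_name == f$locus_name, , drop = FALSE]
  fseq <- substring(hap$sequence, f$start + 1, f$end)
  jn <- scan_boundaries(fseq, lm, cfg)
  prev <- -1
  for (i in seq_len(nrow(jn))) {
    variants <- lm[lm$junction_index == jn$junction_index[i], ]
    want <- integer(0)
    t_min <- NA_integer_
    for (t in 0:3) {
      want <- sort(unique(unlist(lapply(variants$marker, oracle_scan,
                                        subject = fseq, max_mm = t))))
      want <- want[want + 8 > prev]
      if (length(want) > 0) {
        t_min <- t
        break
      }
    }
    expect_equal(jn$mismatches[i], t_min)
    expect_equal(jn$pos[i], want[1] + 8L)
    prev <- want[1] + 8L
  }
})

test_that("probe signatures match construction and a naive scan", {
  cfg <- annotation_config()
  probes <- c(A = random_seq(120, seed = 75), B = random_seq(120, seed = 76))
  htg <- paste0(probes[["A"]], random_seq(1000, 77), probes[["B"]])
  sig <- align_probes(probes, htg, cfg)
  expect_identical(sig$label, c("A", "B"))
  expect_true(all(sig$strand == "+"))
  # reverse complement: same labels, reversed order, flipped strands
  sig_rc <- align_probes(probes, oracle_revcomp(htg), cfg)
  expect_identical(sig_rc$label, c("B", "A"))
  expect_true(all(sig_rc$strand == "-"))
  # oracle equivalence with mismatch tolerance on a larger haplotig
  sim <- small_sim(seed = 23, n_loci = 3)
  hap <- sim$haplotypes[[2]]
  refs <- sim_refs(sim)
  dcfg <- design_config()
  panel <- greedy_select(enumerate_candidates(refs, dcfg), refs, dcfg)
  sig2 <- align_probes(panel, hap$sequence, cfg)
  pseqs <- panel_sequences(panel)
  for (lab in unique(sig2$label)) {
    got <- sig2$start[sig2$label == lab & sig2$strand == "+"]
    want <- oracle_scan(pseqs[[lab]], hap$sequence,
                        cfg$probe_align_mismatches)
    expect_equal(got, want)
  }
})

test_that("orientation canonicalization flips reverse haplotigs and is an
           involution", {
  cfg <- annotation_config()
  probes <- c(A = random_seq(120, seed = 81), B = random_seq(120, seed = 82))
  fwd <- paste0(random_seq(200, 83), probes[["A"]], random_seq(500, 84),
                probes[["B"]], random_seq(200, 85))
  o1 <- orient_haplotig(fwd, probes, cfg)
  expect_false(o1$flipped)
  expect_identical(o1$sequence, fwd)
  o2 <- orient_haplotig(oracle_revcomp(fwd), probes, cfg)
  expect_true(o2$flipped)
  expect_identical(o2$sequence, fwd)
  o3 <- orient_haplotig(o2$sequence, probes, cfg)
  expect_identical(o3$sequence, o1$sequence)
  # strand tie keeps the input orientation with a warning
  tie <- paste0(probes[["A"]], random_seq(300, 86),
                oracle_revcomp(probes[["B"]]))
  expect_warning(ot <- orient_haplotig(tie, probes, cfg), "tie")
  expect_identical(ot$sequence, tie)
})

test_that("segmentation tokenizes repeated patterns with absent optional
           probes", {
  plabels <- c("P4", "P3", "P12", "P10", "P2", "P7", "P13")
  patterns <- structure(list(LOC = data.frame(
    label = plabels, optional = plabels == "P10")), class = "LocusPatterns")
  mk_sig <- function(labels) {
    starts <- seq(0, by = 400, length.out = length(labels))
    data.frame(label = labels, strand = "+", start = starts,
               end = starts + 120, mismatches = 0L, stringsAsFactors = FALSE)
  }
  htg <- random_seq(3 * 7 * 400 + 500, seed = 87)
  # one full pattern -> one feature spanning the haplotig
  seg1 <- segment_loci(mk_sig(plabels), patterns, htg)
  expect_length(seg1$features, 1)
  expect_equal(seg1$features[[1]]$start, 0)
  expect_equal(seg1$features[[1]]$end, nchar(htg))
  # pattern three times, the optional probe absent in the middle copy
  labels3 <- c(plabels, setdiff(plabels, "P10"), plabels)
  seg3 <- segment_loci(mk_sig(labels3), patterns, htg)
  expect_length(seg3$features, 3)
  expect_true(all(vapply(seg3$features, `[[`, character(1),
                         "locus_name") == "LOC"))
  # features tile the haplotig in order
  starts <- vapply(seg3$features, `[[`, integer(1), "start")
  ends <- vapply(seg3$features, `[[`, integer(1), "end")
  expect_equal(starts[-1], ends[-3])
  # a foreign label is reported unassigned, not an error
  seg_u <- segment_loci(mk_sig(c("ZZZ", plabels)), patterns, htg)
  expect_equal(seg_u$unassigned$label, "ZZZ")
  expect_length(seg_u$features, 1)
})

test_that("error-free haplotigs annotate to truth and mirror under reverse
           complement", {
  res <- pipeline_closure(seed = 29)
  expect_true(res$locus_order_exact)
  expect_true(res$elements_exact)

  # mirror property on a whole haplotype
  sim <- res$sim
  refs <- sim_refs(sim)
  dcfg <- design_config()
  panel <- res$panel
  acfg <- annotation_config()
  patterns <- learn_locus_patterns(sim$haplotypes, panel, acfg)
  markers <- build_boundary_markers(sim$haplotypes, acfg)
  catalog <- derive_locus_catalog(sim$haplotypes, bin_config())
  hap <- sim$haplotypes[[2]]
  L <- nchar(hap$sequence)
  fwd <- annotate_haplotigs(c(h = hap$sequence), panel, patterns, markers,
                            acfg, catalog = catalog)
  rev <- annotate_haplotigs(c(h = oracle_revcomp(hap$sequence)), panel,
                            patterns, markers, acfg, catalog = catalog)
  expect_length(rev, length(fwd))
  # canonicalization flips the reverse-complemented haplotig back, so
  # features come out in the same (gene) order; their input-frame
  # coordinates are mirrored
  for (i in seq_along(fwd)) {
    f <- fwd[[i]]
    r <- rev[[i]]
    expect_identical(r$locus_name, f$locus_name)
    expect_identical(r$strand, "-")
    expect_equal(r$start, L - f$end)
    expect_equal(r$end, L - f$start)
    expect_equal(r$elements$start, L - f$elements$end)
    expect_identical(r$elements$label, f$elements$label)
  }
  # empty haplotig set -> empty annotation
  expect_length(annotate_haplotigs(stats::setNames(character(0),
                                                   character(0)),
                                   panel, patterns, markers, acfg), 0)
})

test_that("allele naming distinguishes full, cDNA-only and novel alleles", {
  cfg <- annotation_config()
  sim <- small_sim(seed = 31, n_loci = 3)
  refs <- sim_refs(sim)
  dcfg <- design_config()
  panel <- greedy_select(enumerate_candidates(refs, dcfg), refs, dcfg)
  patterns <- learn_locus_patterns(sim$haplotypes, panel, cfg)
  markers <- build_boundary_markers(sim$haplotypes, cfg)
  catalog <- derive_locus_catalog(sim$haplotypes, bin_config())
  hap <- sim$haplotypes[[1]]
  haplotigs <- c(h = hap$sequence)
  ann <- annotate_haplotigs(haplotigs, panel, patterns, markers, cfg,
                            catalog = catalog)
  f <- ann[[1]]
  full_seq <- substring(hap$sequence, f$start + 1, f$end)

  # exact library allele -> full-level name
  lib <- c("G1*001" = full_seq)
  named <- name_alleles(list(f), lib, markers, cfg, haplotigs)
  expect_identical(named[[1]]$allele_name, "G1*001")
  expect_identical(named[[1]]$allele_level, "full")

  # one intronic substitution in the library allele -> cDNA-level match
  intron <- f$elements[f$elements$label == "intron2", ]
  p <- floor((intron$start + intron$end) / 2) - f$start
  lib2_seq <- full_seq
  substring(lib2_seq, p, p) <- if (substring(lib2_seq, p, p) == "A") "C"
                               else "A"
  named2 <- name_alleles(list(f), c("G1*002" = lib2_seq), markers, cfg,
                         haplotigs)
  expect_identical(named2[[1]]$allele_name, "G1*002")
  expect_identical(named2[[1]]$allele_level, "cdna")

  # empty library -> NEW; absent locus -> warning, unnamed
  named3 <- name_alleles(list(f), character(0), markers, cfg, haplotigs)
  expect_identical(named3[[1]]$allele_name, "NEW")
  expect_warning(
    named4 <- name_alleles(list(f), c("G2*001" = full_seq), markers, cfg,
                           haplotigs),
    "no library alleles")
  expect_true(is.na(named4[[1]]$allele_name))
})

test_that("tbl and GFF3 outputs use 1-based inclusive coordinates and
           round-trip", {
  feat <- list(list(haplotig_id = "h1", locus_name = "G1", start = 10L,
                    end = 20L, strand = "+",
                    elements = data.frame(label = c("exon1", "intron1"),
                                          start = c(10L, 14L),
                                          end = c(14L, 20L)),
                    allele_name = "G1*001"))
  tbl <- tempfile(fileext = ".tbl")
  write_tbl(feat, tbl)
  lines <- readLines(tbl)
  expect_identical(lines[1], ">Feature h1")
  expect_identical(lines[2], "11\t20\tgene")  # [10,20) -> 11..20
  back <- read_tbl(tbl)
  expect_length(back, 1)
  expect_equal(back[[1]]$start, 10)
  expect_equal(back[[1]]$end, 20)
  expect_identical(back[[1]]$locus_name, "G1")
  expect_identical(back[[1]]$allele_name, "G1*001")
  expect_identical(back[[1]]$elements$label, c("exon1", "intron1"))
  expect_equal(back[[1]]$elements$start, c(10, 14))

  gff <- tempfile(fileext = ".gff3")
  write_gff3(feat, gff)
  gback <- read_gff3_features(gff)
  expect_length(gback, 1)
  expect_equal(gback[[1]]$start, 10)
  expect_equal(gback[[1]]$end, 20)
  expect_identical(gback[[1]]$elements$label, c("exon1", "intron1"))

  # the GFF3 parses with an independent reader and keeps conventions
  skip_if_not_installed("rtracklayer")
  gr <- rtracklayer::import(gff)
  expect_setequal(as.character(gr$type), c("gene", "exon", "intron"))
  gene <- gr[gr$type == "gene"]
  expect_equal(BiocGenerics::start(gene), 11)
  expect_equal(BiocGenerics::end(gene), 20)

  # minus-strand features print reversed tbl coordinates
  featm <- feat
  featm[[1]]$strand <- "-"
  tbl2 <- tempfile()
  write_tbl(featm, tbl2)
  expect_identical(readLines(tbl2)[2], "20\t11\tgene")
  backm <- read_tbl(tbl2)
  expect_identical(backm[[1]]$strand, "-")
  expect_equal(backm[[1]]$start, 10)
})
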