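#' Simulation configuration
#'
#' Parameters for the synthetic homologous-haplotype generator. The defaults
#' emulate the statistical structure of the human KIR region at desk scale:
#' a family of loci whose alleles are 85--98\% identical, built from
#' alternating conserved and variable blocks with interspersed repeat
#' elements, an inverted-repeat intergenic "hotspot" locus, diploid
#' haplotypes of ordered loci, and reads drawn from 2--8 kb fragments at a
#' low substitution error rate.
#'
#' @param n_loci number of locus templates. When `n_loci >= 3` the last
#'   template is the exon-free intergenic hotspot (`IGR`); the others are
#'   gene templates with three exons.
#' @param fragment_len_range numeric length-2, min/max read fragment length
#'   in bases (default 2000--8000, the capture size-selection window).
#' @param error_rate per-base substitution error rate for simulated reads
#'   (default 0.001; must be in [0, 0.1)).
#' @param depth target mean read coverage per haplotype.
#' @param identity_range numeric length-2: range of pairwise identity between
#'   locus templates. Per-template divergence is drawn uniformly from
#'   `1 - identity_range`, applied fully to variable blocks and at 1/10 the
#'   rate to conserved and repeat blocks.
#' @param allele_divergence per-base substitution rate applied to variable
#'   blocks when a template is instantiated as an allele on a haplotype
#'   (conserved/repeat blocks again at 1/10 this rate).
#' @param spacer_len_range intergenic spacer length range between loci.
#' @param flank_len random flank length added at both haplotype ends.
#' @param seed integer RNG seed; every simulator output is byte-identical
#'   for a fixed seed.
#' @return an object of class `SimConfig`.
#' @export
sim_config <- function(n_loci = 4,
                       fragment_len_range = c(2000, 8000),
                       error_rate = 0.001,
                       depth = 30,
                       identity_range = c(0.85, 0.98),
                       allele_divergence = 0.002,
                       spacer_len_range = c(800, 1500),
                       flank_len = 500,
                       seed = 1) {
  if (!is.numeric(n_loci) || n_loci < 2) {
    stop("invalid SimConfig: n_loci must be >= 2")
  }
  if (error_rate < 0 || error_rate >= 0.1) {
    stop("invalid SimConfig: error_rate must be in [0, 0.1)")
  }
  if (length(fragment_len_range) != 2L ||
      fragment_len_range[1] >= fragment_len_range[2]) {
    stop("invalid SimConfig: fragment_len_range must be (min, max) with min < max")
  }
  if (depth <= 0) stop("invalid SimConfig: depth must be > 0")
  if (length(identity_range) != 2L || identity_range[1] > identity_range[2] ||
      identity_range[1] < 0.5 || identity_range[2] > 1) {
    stop("invalid SimConfig: identity_range must be within [0.5, 1]")
  }
  structure(list(
    n_loci = as.integer(n_loci),
    fragment_len_range = as.numeric(fragment_len_range),
    error_rate = error_rate,
    depth = depth,
    identity_range = as.numeric(identity_range),
    allele_divergence = allele_divergence,
    spacer_len_range = as.numeric(spacer_len_range),
    flank_len = as.integer(flank_len),
    seed = as.integer(seed)
  ), class = "SimConfig")
}

# Block layouts. Gene loci alternate variable (UTRs, exons) and conserved
# (introns) blocks with one Alu-like repeat inside intron 1; the hotspot
# locus is intergenic filler dominated by L1-like repeats carrying three
# Alu-like elements, two of them in opposite orientations.
gene_slots <- function() {
  data.frame(
    slot = c("u5", "ex1", "in1a", "alu1", "in1b", "ex2", "in2", "ex3", "u3"),
    kind = c("variable", "variable", "conserved", "repeat", "conserved",
             "variable", "conserved", "variable", "variable"),
    len = c(300L, 300L, 700L, 300L, 500L, 300L, 900L, 300L, 300L),
    stringsAsFactors = FALSE
  )
}

hotspot_slots <- function() {
  data.frame(
    slot = c("hfL", "hvar", "l1a", "aluF", "l1b", "aluR", "l1c", "aluF2", "hfR"),
    kind = c("conserved", "variable", "repeat", "repeat", "repeat", "repeat",
             "repeat", "repeat", "conserved"),
    len = c(500L, 300L, 700L, 300L, 500L, 300L, 400L, 300L, 500L),
    stringsAsFactors = FALSE
  )
}

gene_elements <- function() {
  # labels over the gene slot layout; intron1 spans in1a+alu1+in1b
  data.frame(
    label = c("utr5", "exon1", "intron1", "exon2", "intron2", "exon3", "utr3"),
    start = c(0L, 300L, 600L, 2100L, 2400L, 3300L, 3600L),
    end   = c(300L, 600L, 2100L, 2400L, 3300L, 3600L, 3900L),
    stringsAsFactors = FALSE
  )
}

# master block sequences shared by all templates in one simulation
build_masters <- function() {
  g <- gene_slots()
  h <- hotspot_slots()
  masters <- list()
  for (i in seq_len(nrow(g))) masters[[g$slot[i]]] <- random_dna(g$len[i])
  alu <- masters[["alu1"]]
  for (i in seq_len(nrow(h))) {
    s <- h$slot[i]
    masters[[s]] <- switch(s,
      aluF = alu,
      aluR = revcomp(alu),
      aluF2 = random_dna(h$len[i]),
      random_dna(h$len[i]))
  }
  masters
}

new_locus_template <- function(locus_name, slots, masters, divergence,
                               is_hotspot = FALSE) {
  seqs <- character(nrow(slots))
  for (i in seq_len(nrow(slots))) {
    rate <- if (slots$kind[i] == "variable") divergence else divergence / 10
    seqs[i] <- mutate_seq(masters[[slots$slot[i]]], rate)
  }
  ends <- cumsum(slots$len)
  starts <- ends - slots$len
  blocks <- data.frame(slot = slots$slot, kind = slots$kind,
                       start = starts, end = ends, sequence = seqs,
                       stringsAsFactors = FALSE)
  total <- sum(slots$len)
  if (is_hotspot) {
    exons <- data.frame(start = integer(0), end = integer(0))
    elements <- data.frame(label = locus_name, start = 0L, end = total,
                           stringsAsFactors = FALSE)
  } else {
    elements <- gene_elements()
    exons <- elements[grepl("^exon", elements$label), c("start", "end")]
    rownames(exons) <- NULL
  }
  rep_idx <- blocks$kind == "repeat"
  structure(list(
    locus_name = locus_name,
    blocks = blocks,
    sequence = paste(seqs, collapse = ""),
    exon_intervals = exons,
    elements = elements,
    repeat_intervals = data.frame(start = blocks$start[rep_idx],
                                  end = blocks$end[rep_idx]),
    is_hotspot = is_hotspot
  ), class = "LocusTemplate")
}

#' Build a family of homologous locus templates
#'
#' Generates `cfg$n_loci` locus templates derived from one shared set of
#' master blocks, so any two templates are homologous: variable blocks
#' (UTRs and exons) diverge at a per-template rate drawn from
#' `1 - cfg$identity_range`, conserved blocks (introns) and repeat elements
#' at one tenth of that rate. When `n_loci >= 3` the last template is the
#' intergenic inverted-repeat hotspot (`IGR`), which carries no exons; all
#' gene templates carry three exons separated by introns.
#'
#' @param cfg a [sim_config()] object.
#' @return a named list of `LocusTemplate` objects.
#' @export
build_locus_templates <- function(cfg) {
  if (!inherits(cfg, "SimConfig")) stop("cfg must be a SimConfig")
  with_seed(cfg$seed, {
    masters <- build_masters()
    div_range <- sort(1 - cfg$identity_range)
    n_genes <- if (cfg$n_loci >= 3L) cfg$n_loci - 1L else cfg$n_loci
    templates <- list()
    for (i in seq_len(n_genes)) {
      d <- runif(1, div_range[1], div_range[2])
      nm <- paste0("G", i)
      templates[[nm]] <- new_locus_template(nm, gene_slots(), masters, d)
    }
    if (cfg$n_loci >= 3L) {
      d <- runif(1, div_range[1], div_range[2])
      templates[["IGR"]] <- new_locus_template("IGR", hotspot_slots(),
                                               masters, d, is_hotspot = TRUE)
    }
    templates
  })
}

#' Haplotype structure specification
#'
#' @param name haplotype name, e.g. `"cA01~tA01"`.
#' @param locus_order ordered character vector of locus names.
#' @param hotspot_index optional position of the intergenic hotspot in
#'   `locus_order`.
#' @return an object of class `HaplotypeSpec`.
#' @export
haplotype_spec <- function(name, locus_order, hotspot_index = NA_integer_) {
  if (length(locus_order) == 0L) stop("locus_order must be non-empty")
  if (!is.na(hotspot_index) &&
      (hotspot_index < 1L || hotspot_index > length(locus_order))) {
    stop("hotspot_index out of range")
  }
  structure(list(name = name, locus_order = locus_order,
                 hotspot_index = as.integer(hotspot_index)),
            class = "HaplotypeSpec")
}

#' Default diploid haplotype structures for a template set
#'
#' Builds two haplotype specs emulating common structural variation: both
#' share the hotspot position, and the second haplotype lacks one gene
#' (a gene-content difference, as between A- and B-family haplotypes).
#'
#' @param templates output of [build_locus_templates()].
#' @return list of two `HaplotypeSpec` objects.
#' @export
default_haplotype_specs <- function(templates) {
  nms <- names(templates)
  genes <- setdiff(nms, "IGR")
  if ("IGR" %in% nms) {
    mid <- ceiling(length(genes) / 2)
    order1 <- append(genes, "IGR", after = mid)
    genes2 <- if (length(genes) >= 2) genes[-2] else genes
    mid2 <- ceiling(length(genes2) / 2)
    order2 <- append(genes2, "IGR", after = mid2)
    list(haplotype_spec("hapA", order1, which(order1 == "IGR")),
         haplotype_spec("hapB", order2, which(order2 == "IGR")))
  } else {
    order2 <- if (length(genes) >= 2) genes[-2] else genes
    list(haplotype_spec("hapA", genes), haplotype_spec("hapB", order2))
  }
}

#' Simulate one haplotype sequence with full ground truth
#'
#' Concatenates mutated copies of the locus templates in `spec$locus_order`,
#' separated by random intergenic spacers and flanked by random sequence.
#' Allelic variation is i.i.d. substitution at `allele_divergence` in
#' variable blocks and a tenth of that in conserved/repeat blocks.
#'
#' @param spec a [haplotype_spec()].
#' @param templates named list of `LocusTemplate`s covering all loci in the
#'   spec.
#' @param seed integer seed; output is byte-identical for a fixed seed.
#' @param allele_divergence substitution rate for allelic variation.
#' @param spacer_len_range intergenic spacer length range.
#' @param flank_len flanking sequence length.
#' @return object of class `SimHaplotype`: list with `name`, `sequence`,
#'   `features` (list of feature records with locus interval, strand, and
#'   element table in haplotype coordinates, 0-based half-open) and
#'   `repeats` (data.frame of repeat intervals).
#' @export
simulate_haplotype <- function(spec, templates, seed,
                               allele_divergence = 0.002,
                               spacer_len_range = c(800, 1500),
                               flank_len = 500) {
  missing_loci <- setdiff(spec$locus_order, names(templates))
  if (length(missing_loci) > 0) {
    stop("unknown locus name(s): ", paste(missing_loci, collapse = ", "))
  }
  with_seed(seed, {
    parts <- character(0)
    pos <- 0L
    features <- list()
    repeats <- list()
    add_part <- function(s) {
      parts[[length(parts) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }
    add_part(random_dna(flank_len))
    for (i in seq_along(spec$locus_order)) {
      nm <- spec$locus_order[i]
      tpl <- templates[[nm]]
      block_seqs <- character(nrow(tpl$blocks))
      for (b in seq_len(nrow(tpl$blocks))) {
        rate <- if (tpl$blocks$kind[b] == "variable") allele_divergence
                else allele_divergence / 10
        block_seqs[b] <- mutate_seq(tpl$blocks$sequence[b], rate)
      }
      allele <- paste(block_seqs, collapse = "")
      off <- pos
      features[[length(features) + 1L]] <- list(
        haplotig_id = spec$name,
        locus_name = nm,
        start = off,
        end = off + nchar(allele),
        strand = "+",
        elements = data.frame(label = tpl$elements$label,
                              start = tpl$elements$start + off,
                              end = tpl$elements$end + off,
                              stringsAsFactors = FALSE),
        allele_name = NA_character_
      )
      if (nrow(tpl$repeat_intervals) > 0) {
        repeats[[length(repeats) + 1L]] <-
          data.frame(start = tpl$repeat_intervals$start + off,
                     end = tpl$repeat_intervals$end + off)
      }
      add_part(allele)
      if (i < length(spec$locus_order)) {
        add_part(random_dna(as.integer(round(
          runif(1, spacer_len_range[1], spacer_len_range[2])))))
      }
    }
    add_part(random_dna(flank_len))
    structure(list(
      name = spec$name,
      sequence = paste(parts, collapse = ""),
      features = features,
      repeats = if (length(repeats)) do.call(rbind, repeats)
                else data.frame(start = integer(0), end = integer(0))
    ), class = "SimHaplotype")
  })
}

#' Simulate a diploid pair of haplotypes
#'
#' Convenience wrapper: builds templates from `cfg`, derives the two default
#' haplotype structures and simulates both haplotype sequences.
#'
#' @param cfg a [sim_config()].
#' @return list with `templates`, `specs` and `haplotypes` (list of two
#'   `SimHaplotype`s named by haplotype).
#' @export
simulate_diploid <- function(cfg) {
  templates <- build_locus_templates(cfg)
  specs <- default_haplotype_specs(templates)
  haps <- lapply(seq_along(specs), function(i) {
    simulate_haplotype(specs[[i]], templates, seed = cfg$seed + 7919L * i,
                       allele_divergence = cfg$allele_divergence,
                       spacer_len_range = cfg$spacer_len_range,
                       flank_len = cfg$flank_len)
  })
  names(haps) <- vapply(haps, `[[`, character(1), "name")
  list(templates = templates, specs = specs, haplotypes = haps)
}

hap_seqs <- function(haplotypes) {
  if (inherits(haplotypes, "SimHaplotype")) haplotypes <- list(haplotypes)
  if (is.list(haplotypes) && all(vapply(haplotypes, inherits, logical(1),
                                        "SimHaplotype"))) {
    out <- vapply(haplotypes, `[[`, character(1), "sequence")
    names(out) <- vapply(haplotypes, `[[`, character(1), "name")
    return(out)
  }
  stopifnot(is.character(haplotypes), !is.null(names(haplotypes)))
  haplotypes
}

#' Simulate CCS-like reads from haplotypes
#'
#' Draws fragments uniformly over each haplotype with lengths uniform in
#' `cfg$fragment_len_range`, until the target `cfg$depth` mean coverage is
#' reached, then applies i.i.d. substitution errors at `cfg$error_rate`.
#' Reads are emitted in the forward orientation of their origin haplotype
#' and each read records its origin interval (0-based half-open).
#'
#' @param haplotypes named character vector of haplotype sequences, or a
#'   list of `SimHaplotype` objects.
#' @param cfg a [sim_config()].
#' @return object of class `SimReads`: data.frame with columns `read_id`,
#'   `origin`, `start`, `end`, `sequence`.
#' @export
simulate_reads <- function(haplotypes, cfg) {
  seqs <- hap_seqs(haplotypes)
  if (length(seqs) == 0L || any(nchar(seqs) == 0L)) {
    stop("haplotypes must be non-empty")
  }
  fmin <- cfg$fragment_len_range[1]
  fmax <- cfg$fragment_len_range[2]
  bad <- nchar(seqs) < fmin
  if (any(bad)) {
    stop("degenerate input: haplotype(s) shorter than the minimum fragment ",
         "length: ", paste(names(seqs)[bad], collapse = ", "))
  }
  with_seed(cfg$seed + 104729L, {
    all_reads <- list()
    for (h in names(seqs)) {
      L <- nchar(seqs[[h]])
      hi <- min(fmax, L)
      target <- cfg$depth * L
      mean_len <- (fmin + hi) / 2
      lens <- integer(0)
      while (sum(lens) < target) {
        n_more <- max(1L, ceiling((target - sum(lens)) / mean_len))
        lens <- c(lens, as.integer(floor(runif(n_more, fmin, hi + 1))))
      }
      lens <- lens[seq_len(which(cumsum(lens) >= target)[1])]
      starts <- as.integer(floor(runif(length(lens)) * (L - lens + 1)))
      frags <- substring(seqs[[h]], starts + 1L, starts + lens)
      if (cfg$error_rate > 0) {
        frags <- vapply(frags, mutate_seq, character(1),
                        rate = cfg$error_rate, USE.NAMES = FALSE)
      }
      all_reads[[h]] <- data.frame(
        read_id = sprintf("%s_read%05d", h, seq_along(lens)),
        origin = h, start = starts, end = starts + lens,
        sequence = frags, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, all_reads)
    rownames(out) <- NULL
    class(out) <- c("SimReads", "data.frame")
    out
  })
}

#' Break a haplotype into haplotigs at given breakpoints
#'
#' Utility to produce pre-broken "assembled" haplotigs with known truth, so
#' annotation and evaluation can be exercised without an assembler. The
#' concatenation of the returned pieces equals the input sequence.
#'
#' @param sequence haplotype sequence (character scalar).
#' @param breakpoints strictly increasing integer positions in
#'   `(0, nchar(sequence))` (0-based) at which to cut.
#' @param prefix name prefix for the pieces.
#' @return named character vector of haplotig sequences.
#' @export
fragment_haplotigs <- function(sequence, breakpoints, prefix = "htg") {
  L <- nchar(sequence)
  breakpoints <- as.integer(breakpoints)
  if (length(breakpoints) > 0) {
    if (is.unsorted(breakpoints, strictly = TRUE)) {
      stop("breakpoints must be strictly increasing")
    }
    if (any(breakpoints <= 0L) || any(breakpoints >= L)) {
      stop("breakpoints must lie strictly inside the sequence")
    }
  }
  bounds <- c(0L, breakpoints, L)
  pieces <- substring(sequence, bounds[-length(bounds)] + 1L, bounds[-1L])
  names(pieces) <- sprintf("%s_%02d", prefix, seq_along(pieces))
  pieces
}

#' Intergenic midpoints of a simulated haplotype
#'
#' Positions halfway between consecutive locus features; convenient
#' truth-derived breakpoints that never cut a feature.
#'
#' @param hap a `SimHaplotype`.
#' @return integer vector of 0-based positions.
#' @export
truth_breakpoints <- function(hap) {
  f <- hap$features
  if (length(f) < 2L) return(integer(0))
  ends <- vapply(f, `[[`, numeric(1), "end")
  starts <- vapply(f, `[[`, numeric(1), "start")
  as.integer(floor((ends[-length(ends)] + starts[-1L]) / 2))
}

#' Write simulated reads as FASTQ plus a truth sidecar
#'
#' @param reads a `SimReads` data.frame.
#' @param fastq_path output FASTQ path.
#' @param truth_path optional path for a tab-separated truth table with
#'   columns read_id, haplotype, start, end.
#' @return `fastq_path`, invisibly.
#' @export
write_reads_fastq <- function(reads, fastq_path, truth_path = NULL) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  quals <- Biostrings::BStringSet(vapply(nchar(reads$sequence), function(n) {
    paste(rep("I", n), collapse = "")
  }, character(1)))
  Biostrings::writeXStringSet(seqs, filepath = fastq_path, format = "fastq",
                              qualities = quals)
  if (!is.null(truth_path)) {
    write.table(reads[, c("read_id", "origin", "start", "end")],
                truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fastq_path)
}

#' Read a FASTQ file to a named character vector
#' @param path FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Flatten feature records to a data.frame
#' @param features list of feature records (as in `SimHaplotype$features` or
#'   returned by [annotate_haplotigs()]).
#' @return data.frame with one row per feature.
#' @export
features_to_df <- function(features) {
  if (length(features) == 0L) {
    return(data.frame(haplotig_id = character(0), locus_name = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), allele_name = character(0)))
  }
  do.call(rbind, lapply(features, function(f) {
    data.frame(haplotig_id = f$haplotig_id, locus_name = f$locus_name,
               start = f$start, end = f$end, strand = f$strand,
               allele_name = if (is.null(f$allele_name)) NA_character_
                             else f$allele_name,
               stringsAsFactors = FALSE)
  }))
}
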