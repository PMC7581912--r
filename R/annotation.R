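#' Annotation configuration
#'
#' @param marker_length boundary-marker length in bases (default 16).
#' @param half_length bases contributed by each flanking element (default 8;
#'   `marker_length` must equal `2 * half_length`).
#' @param max_marker_mismatches maximum substitutions tolerated when
#'   scanning for a boundary marker (default 3; the scan escalates
#'   0, 1, 2, 3 and stops at the first threshold with a consistent hit).
#' @param probe_align_mismatches substitutions tolerated when aligning
#'   capture probes to haplotigs for signatures (default 3 over a 120-base
#'   probe, since assembled haplotigs carry real allelic variation).
#' @return object of class `AnnotationConfig`.
#' @export
annotation_config <- function(marker_length = 16, half_length = 8,
                              max_marker_mismatches = 3,
                              probe_align_mismatches = 3) {
  if (marker_length != 2 * half_length) {
    stop("marker_length must equal 2 * half_length")
  }
  if (max_marker_mismatches < 0 || max_marker_mismatches >= half_length) {
    stop("max_marker_mismatches must be in [0, half_length)")
  }
  structure(list(marker_length = as.integer(marker_length),
                 half_length = as.integer(half_length),
                 max_marker_mismatches = as.integer(max_marker_mismatches),
                 probe_align_mismatches = as.integer(probe_align_mismatches)),
            class = "AnnotationConfig")
}

coerce_panel <- function(panel) {
  if (inherits(panel, "ProbePanel")) return(panel_sequences(panel))
  stopifnot(is.character(panel), !is.null(names(panel)))
  panel
}

#' Align capture probes to a haplotig
#'
#' Finds every occurrence of every probe on either strand of the haplotig
#' at up to `cfg$probe_align_mismatches` substitutions, returning the
#' ordered probe signature.
#'
#' @param panel `ProbePanel` or named character vector of probe sequences.
#' @param haplotig DNA string.
#' @param cfg an [annotation_config()].
#' @return data.frame signature with columns `label`, `strand`, `start`,
#'   `end` (0-based half-open), `mismatches`, sorted by position.
#' @export
align_probes <- function(panel, haplotig, cfg) {
  probes <- coerce_panel(panel)
  subject <- Biostrings::DNAString(haplotig)
  rows <- list()
  for (i in seq_along(probes)) {
    plen <- nchar(probes[[i]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") probes[[i]] else revcomp(probes[[i]])
      starts <- match_starts(pat, subject, cfg$probe_align_mismatches)
      if (length(starts) == 0) next
      mm <- vapply(starts, function(s) {
        hamming(substring(haplotig, s + 1L, s + plen), pat)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        label = names(probes)[i], strand = strand, start = starts,
        end = starts + plen, mismatches = as.integer(mm),
        stringsAsFactors = FALSE)
    }
  }
  sig <- if (length(rows)) do.call(rbind, rows)
         else data.frame(label = character(0), strand = character(0),
                         start = integer(0), end = integer(0),
                         mismatches = integer(0))
  sig <- sig[order(sig$start, sig$label), , drop = FALSE]
  rownames(sig) <- NULL
  sig
}

#' Canonicalize haplotig orientation from its probe signature
#'
#' The loci of a homologous gene cluster share one transcriptional
#' orientation, so a haplotig whose probe hits are mostly on the reverse
#' strand is reverse-complemented (and its signature recomputed) before
#' pattern matching. A strand tie keeps the input orientation with a
#' warning.
#'
#' @param haplotig DNA string.
#' @param panel probes as in [align_probes()].
#' @param cfg an [annotation_config()].
#' @param signature optional precomputed signature of `haplotig`.
#' @return list with `sequence`, `signature`, and `flipped` flag.
#' @export
orient_haplotig <- function(haplotig, panel, cfg, signature = NULL) {
  if (is.null(signature)) signature <- align_probes(panel, haplotig, cfg)
  n_rev <- sum(signature$strand == "-")
  n_fwd <- sum(signature$strand == "+")
  if (nrow(signature) > 0 && n_rev == n_fwd) {
    warning("strand tie in probe signature; keeping input orientation")
  }
  if (n_rev > n_fwd) {
    flipped_seq <- revcomp(haplotig)
    list(sequence = flipped_seq,
         signature = align_probes(panel, flipped_seq, cfg),
         flipped = TRUE)
  } else {
    list(sequence = haplotig, signature = signature, flipped = FALSE)
  }
}

#' Learn per-locus probe patterns from annotated references
#'
#' Aligns the panel to each reference haplotype and collects, for every
#' truth locus occurrence, the ordered probe labels falling inside it. The
#' longest occurrence per locus becomes the canonical pattern; labels
#' absent from at least one occurrence are flagged optional (homologous
#' loci share most probes, so a probe may fail to align in some copies).
#'
#' @param haplotypes list of `SimHaplotype`s (sequence + feature truth).
#' @param panel probes as in [align_probes()].
#' @param cfg an [annotation_config()].
#' @return object of class `LocusPatterns`: named list of data.frames with
#'   columns `label`, `optional`.
#' @export
learn_locus_patterns <- function(haplotypes, panel, cfg) {
  if (inherits(haplotypes, "SimHaplotype")) haplotypes <- list(haplotypes)
  occ <- list()
  for (hap in haplotypes) {
    sig <- align_probes(panel, hap$sequence, cfg)
    for (f in hap$features) {
      inside <- sig$label[sig$start >= f$start & sig$end <= f$end]
      occ[[f$locus_name]] <- c(occ[[f$locus_name]], list(inside))
    }
  }
  patterns <- lapply(occ, function(runs) {
    canonical <- runs[[which.max(vapply(runs, length, integer(1)))]]
    optional <- vapply(canonical, function(lab) {
      any(!vapply(runs, function(r) lab %in% r, logical(1)))
    }, logical(1))
    data.frame(label = canonical, optional = optional,
               stringsAsFactors = FALSE)
  })
  patterns <- patterns[vapply(patterns, nrow, integer(1)) > 0]
  structure(patterns, class = "LocusPatterns")
}

#' Write / read locus patterns as TSV
#'
#' Columns: locus, position, label, optional — so real patterns can be
#' supplied from outside.
#'
#' @param patterns a `LocusPatterns` object.
#' @param path TSV path.
#' @return `path` (write) or a `LocusPatterns` (read).
#' @export
write_patterns_tsv <- function(patterns, path) {
  df <- do.call(rbind, lapply(names(patterns), function(nm) {
    p <- patterns[[nm]]
    data.frame(locus = nm, position = seq_len(nrow(p)), label = p$label,
               optional = p$optional, stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patterns_tsv
#' @export
read_patterns_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$locus), function(d) {
    d <- d[order(d$position), ]
    data.frame(label = d$label, optional = as.logical(d$optional),
               stringsAsFactors = FALSE)
  })
  structure(out, class = "LocusPatterns")
}

# longest run of signature labels (starting at i) that forms an ordered
# subsequence of the pattern labels; returns the number consumed
match_pattern_at <- function(labels, i, pattern_labels) {
  t <- i
  j <- 1L
  n <- length(labels)
  m <- length(pattern_labels)
  while (t <= n && j <= m) {
    hit <- which(pattern_labels[j:m] == labels[t])
    if (length(hit) == 0) break
    j <- j + hit[1]
    t <- t + 1L
  }
  t - i
}

#' Segment a probe signature into locus features
#'
#' Tokenizes the probe-label sequence greedily left to right: at each
#' position the locus pattern consuming the longest run of labels (as an
#' ordered subsequence, so absent/optional probes are tolerated) claims a
#' token. Feature intervals extend from the midpoint between a token and
#' its predecessor's last probe to the midpoint before the next token's
#' first probe; terminal features extend to the haplotig ends. When
#' homologous loci share identical probe patterns the tokenization fixes
#' only the boundaries; if a `catalog` of locus-specific k-mers is given,
#' each feature's locus is then re-identified by a k-mer vote over its
#' interval.
#'
#' @param signature probe signature from [align_probes()] (canonical
#'   orientation).
#' @param patterns a `LocusPatterns` object.
#' @param haplotig the haplotig sequence the signature was computed on.
#' @param catalog optional `LocusCatalog` for locus identification.
#' @param bin_cfg [bin_config()] used for the catalog vote (defaults to the
#'   catalog's k).
#' @return list with `features` (list of records: `locus_name`, `start`,
#'   `end`, `rows` signature subset) and `unassigned` (signature rows
#'   claimed by no pattern).
#' @export
segment_loci <- function(signature, patterns, haplotig, catalog = NULL,
                         bin_cfg = NULL) {
  L <- nchar(haplotig)
  labels <- signature$label
  n <- length(labels)
  tokens <- list()
  unassigned <- integer(0)
  i <- 1L
  while (i <= n) {
    best_len <- 0L
    best_locus <- NA_character_
    for (nm in names(patterns)) {
      len <- match_pattern_at(labels, i, patterns[[nm]]$label)
      if (len > best_len) {
        best_len <- len
        best_locus <- nm
      }
    }
    if (best_len == 0L) {
      unassigned <- c(unassigned, i)
      i <- i + 1L
    } else {
      tokens[[length(tokens) + 1L]] <- list(locus = best_locus,
                                            rows = i:(i + best_len - 1L))
      i <- i + best_len
    }
  }
  if (length(tokens) == 0L) {
    return(list(features = list(), unassigned = signature[unassigned, ,
                                                          drop = FALSE]))
  }
  first_start <- vapply(tokens, function(tk) signature$start[tk$rows[1]],
                        numeric(1))
  last_end <- vapply(tokens, function(tk) {
    signature$end[tk$rows[length(tk$rows)]]
  }, numeric(1))
  k <- length(tokens)
  bounds <- c(0, if (k > 1) floor((last_end[-k] + first_start[-1]) / 2), L)
  features <- lapply(seq_len(k), function(t) {
    list(locus_name = tokens[[t]]$locus,
         start = as.integer(bounds[t]), end = as.integer(bounds[t + 1]),
         rows = signature[tokens[[t]]$rows, , drop = FALSE])
  })
  if (!is.null(catalog)) {
    if (is.null(bin_cfg)) bin_cfg <- bin_config(k = catalog$k)
    index <- if (inherits(catalog, "KmerIndex")) catalog
             else catalog_index(catalog, bin_cfg)
    features <- lapply(features, function(f) {
      sseq <- substring(haplotig, f$start + 1L, f$end)
      km <- unique(seq_kmers(sseq, index$k, canonical = index$both_strands))
      idx <- match(km, index$kmers)
      idx <- idx[!is.na(idx)]
      if (length(idx) > 0) {
        tab <- sort(table(unlist(index$groups[idx])), decreasing = TRUE)
        f$locus_name <- names(tab)[1]
      }
      f
    })
  }
  list(features = features, unassigned = signature[unassigned, , drop = FALSE])
}

#' Build boundary markers from annotated references
#'
#' For every junction between adjacent elements of every locus occurrence,
#' concatenates the last `half_length` bases of the left element with the
#' first `half_length` bases of the right element into a
#' `marker_length`-base boundary marker. Markers recurring at different
#' junctions of the same locus are flagged ambiguous; elements shorter than
#' `half_length` are skipped with a warning.
#'
#' @param haplotypes list of `SimHaplotype`s carrying element-level truth.
#' @param cfg an [annotation_config()].
#' @return data.frame of class `BoundaryMarkers` with columns `locus_name`,
#'   `junction_index`, `left_element`, `right_element`, `marker`,
#'   `left_half`, `right_half`, `ambiguous`.
#' @export
build_boundary_markers <- function(haplotypes, cfg) {
  if (inherits(haplotypes, "SimHaplotype")) haplotypes <- list(haplotypes)
  h <- cfg$half_length
  rows <- list()
  for (hap in haplotypes) {
    for (f in hap$features) {
      el <- f$elements
      if (nrow(el) < 2) next
      for (j in seq_len(nrow(el) - 1L)) {
        if (el$end[j] - el$start[j] < h || el$end[j + 1] - el$start[j + 1] < h) {
          warning("element shorter than ", h, " bases at ", f$locus_name,
                  " junction ", j, "; marker skipped")
          next
        }
        jpos <- el$end[j]  # == el$start[j + 1]
        left <- substring(hap$sequence, jpos - h + 1L, jpos)
        right <- substring(hap$sequence, jpos + 1L, jpos + h)
        rows[[length(rows) + 1L]] <- data.frame(
          locus_name = f$locus_name, junction_index = j,
          left_element = el$label[j], right_element = el$label[j + 1],
          marker = paste0(left, right), left_half = left, right_half = right,
          stringsAsFactors = FALSE)
      }
    }
  }
  mk <- unique(do.call(rbind, c(rows, list(data.frame(
    locus_name = character(0), junction_index = integer(0),
    left_element = character(0), right_element = character(0),
    marker = character(0), left_half = character(0),
    right_half = character(0))))))
  # ambiguous: same locus+marker seen at more than one junction index
  tab <- unique(mk[, c("locus_name", "marker", "junction_index")])
  dup <- duplicated(paste(tab$locus_name, tab$marker)) |
         duplicated(paste(tab$locus_name, tab$marker), fromLast = TRUE)
  amb <- unique(paste(tab$locus_name, tab$marker)[dup])
  mk$ambiguous <- paste(mk$locus_name, mk$marker) %in% amb
  rownames(mk) <- NULL
  class(mk) <- c("BoundaryMarkers", "data.frame")
  mk
}

#' Write / read boundary markers as TSV
#' @param markers a `BoundaryMarkers` data.frame.
#' @param path TSV path.
#' @return `path` (write) or a `BoundaryMarkers` (read).
#' @export
write_markers_tsv <- function(markers, path) {
  write.table(markers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers_tsv
#' @export
read_markers_tsv <- function(path) {
  mk <- read.delim(path, stringsAsFactors = FALSE)
  class(mk) <- c("BoundaryMarkers", "data.frame")
  mk
}

#' Scan a feature sequence for element boundaries
#'
#' For each expected junction of the locus, in element order, scans for its
#' marker(s) at mismatch threshold 0, escalating to 1, 2, then
#' `cfg$max_marker_mismatches` only if no hit was found — minimal
#' escalation. The junction position is the marker start plus
#' `half_length`. Among multiple hits at the accepted threshold the
#' leftmost position strictly after the previous junction is taken;
#' junctions with no consistent hit are reported as not found.
#'
#' @param feature_seq DNA string of one locus feature.
#' @param markers `BoundaryMarkers` rows for this locus.
#' @param cfg an [annotation_config()].
#' @param offset added to reported positions (to lift feature-local
#'   coordinates to haplotig coordinates).
#' @return data.frame with columns `junction_index`, `left_element`,
#'   `right_element`, `pos` (0-based junction position), `mismatches`,
#'   `found`.
#' @export
scan_boundaries <- function(feature_seq, markers, cfg, offset = 0L) {
  subject <- Biostrings::DNAString(feature_seq)
  jidx <- sort(unique(markers$junction_index))
  prev <- -1L
  out <- list()
  for (j in jidx) {
    variants <- markers[markers$junction_index == j, , drop = FALSE]
    pos <- NA_integer_
    mm <- NA_integer_
    for (t in 0:cfg$max_marker_mismatches) {
      starts <- sort(unique(unlist(lapply(variants$marker, match_starts,
                                          subject = subject, max_mm = t))))
      jpos <- starts + cfg$half_length
      jpos <- jpos[jpos > prev]
      if (length(jpos) > 0) {
        pos <- jpos[1]
        mm <- t
        break
      }
    }
    found <- !is.na(pos)
    out[[length(out) + 1L]] <- data.frame(
      junction_index = j,
      left_element = variants$left_element[1],
      right_element = variants$right_element[1],
      pos = if (found) as.integer(pos + offset) else NA_integer_,
      mismatches = mm, found = found, stringsAsFactors = FALSE)
    if (found) prev <- pos
  }
  res <- do.call(rbind, c(out, list(data.frame(
    junction_index = integer(0), left_element = character(0),
    right_element = character(0), pos = integer(0),
    mismatches = integer(0), found = logical(0)))))
  rownames(res) <- NULL
  res
}

elements_from_junctions <- function(junctions, locus_name, fstart, fend) {
  found <- junctions[junctions$found, , drop = FALSE]
  if (nrow(found) == 0) {
    return(data.frame(label = locus_name, start = fstart, end = fend,
                      stringsAsFactors = FALSE))
  }
  labels <- c(found$left_element[1], found$right_element)
  bounds <- c(fstart, found$pos, fend)
  data.frame(label = labels, start = as.integer(bounds[-length(bounds)]),
             end = as.integer(bounds[-1]), stringsAsFactors = FALSE)
}

mirror_elements <- function(el, L) {
  out <- data.frame(label = el$label, start = L - el$end, end = L - el$start,
                    stringsAsFactors = FALSE)
  out
}

#' Annotate assembled haplotigs
#'
#' Full composition of the annotation stage: align the capture probes,
#' canonicalize orientation, segment the signature into locus features,
#' then place element boundaries within each feature by marker scanning.
#' Coordinates are reported in the frame of the input haplotig; features on
#' a reverse-complemented haplotig get strand `"-"` with mirrored
#' intervals, elements kept in gene order.
#'
#' @param haplotigs named character vector of haplotig sequences.
#' @param panel probes as in [align_probes()].
#' @param patterns a `LocusPatterns` object.
#' @param markers a `BoundaryMarkers` data.frame.
#' @param cfg an [annotation_config()].
#' @param catalog optional `LocusCatalog` for locus identification (see
#'   [segment_loci()]).
#' @return list of feature records: `haplotig_id`, `locus_name`, `start`,
#'   `end`, `strand`, `elements` (label/start/end table tiling the
#'   feature), `complete` (all junctions found), `allele_name` (NA until
#'   [name_alleles()]).
#' @export
annotate_haplotigs <- function(haplotigs, panel, patterns, markers, cfg,
                               catalog = NULL) {
  if (!is.null(catalog) && !inherits(catalog, "KmerIndex")) {
    catalog <- catalog_index(catalog, bin_config(k = catalog$k))
  }
  out <- list()
  for (hid in names(haplotigs)) {
    seq_in <- haplotigs[[hid]]
    L <- nchar(seq_in)
    sig <- align_probes(panel, seq_in, cfg)
    if (nrow(sig) == 0) next
    ori <- orient_haplotig(seq_in, panel, cfg, signature = sig)
    seg <- segment_loci(ori$signature, patterns, ori$sequence,
                        catalog = catalog)
    for (f in seg$features) {
      lm <- markers[markers$locus_name == f$locus_name, , drop = FALSE]
      fseq <- substring(ori$sequence, f$start + 1L, f$end)
      junctions <- if (nrow(lm) > 0) {
        scan_boundaries(fseq, lm, cfg, offset = f$start)
      } else {
        data.frame(junction_index = integer(0), left_element = character(0),
                   right_element = character(0), pos = integer(0),
                   mismatches = integer(0), found = logical(0))
      }
      el <- elements_from_junctions(junctions, f$locus_name, f$start, f$end)
      rec <- list(haplotig_id = hid, locus_name = f$locus_name,
                  start = f$start, end = f$end, strand = "+",
                  elements = el,
                  complete = nrow(junctions) == 0 || all(junctions$found),
                  junctions = junctions,
                  allele_name = NA_character_)
      if (ori$flipped) {
        rec$strand <- "-"
        tmp <- rec$start
        rec$start <- L - rec$end
        rec$end <- L - tmp
        rec$elements <- mirror_elements(el, L)
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  out
}

# canonical-orientation (gene-strand) sequence of a feature
feature_gene_seq <- function(feature, haplotig) {
  s <- substring(haplotig, feature$start + 1L, feature$end)
  if (feature$strand == "-") revcomp(s) else s
}

# spliced exonic sequence of a feature, in gene orientation
feature_spliced_seq <- function(feature, haplotig) {
  el <- feature$elements[grepl("^exon", feature$elements$label), ,
                         drop = FALSE]
  if (nrow(el) == 0) return("")
  pieces <- substring(haplotig, el$start + 1L, el$end)
  if (feature$strand == "-") {
    # elements are stored in gene order; on the minus strand their input-
    # frame coordinates descend, each piece must be reverse-complemented
    pieces <- revcomp(pieces)
  }
  paste(pieces, collapse = "")
}

#' Name feature alleles against an allele library
#'
#' Library sequences must be named `locus*allele` (e.g. `G1*001`). A
#' feature whose full gene-orientation sequence equals a library allele of
#' its locus gets that allele's name at full-gene level; otherwise, if its
#' spliced exonic sequence equals the library allele's spliced sequence
#' (the library allele is spliced by scanning the same boundary markers),
#' the name is assigned at cDNA level; otherwise the feature is `NEW`.
#'
#' @param features feature records from [annotate_haplotigs()].
#' @param library named character vector of allele sequences.
#' @param markers `BoundaryMarkers` (to splice library alleles).
#' @param cfg an [annotation_config()].
#' @param haplotigs the named haplotig sequences the features refer to.
#' @return the features, with `allele_name` and `allele_level`
#'   (`"full"`, `"cdna"` or `"none"`) filled in.
#' @export
name_alleles <- function(features, library, markers, cfg, haplotigs) {
  lib_locus <- sub("\\*.*$", "", names(library))
  lib_spliced <- rep(NA_character_, length(library))
  spliced_lib <- function(i) {
    if (!is.na(lib_spliced[i])) return(lib_spliced[i])
    lm <- markers[markers$locus_name == lib_locus[i], , drop = FALSE]
    s <- ""
    if (nrow(lm) > 0) {
      jn <- scan_boundaries(library[[i]], lm, cfg)
      el <- elements_from_junctions(jn, lib_locus[i], 0L,
                                    nchar(library[[i]]))
      ex <- el[grepl("^exon", el$label), , drop = FALSE]
      if (nrow(ex) > 0) {
        s <- paste(substring(library[[i]], ex$start + 1L, ex$end),
                   collapse = "")
      }
    }
    lib_spliced[i] <<- s
    s
  }
  lapply(features, function(f) {
    cand <- which(lib_locus == f$locus_name)
    if (length(cand) == 0) {
      if (length(library) > 0) {
        warning("no library alleles for locus ", f$locus_name,
                "; feature left unnamed")
        f$allele_name <- NA_character_
        f$allele_level <- "none"
      } else {
        f$allele_name <- "NEW"
        f$allele_level <- "none"
      }
      return(f)
    }
    full <- feature_gene_seq(f, haplotigs[[f$haplotig_id]])
    hit <- cand[unname(library[cand]) == full]
    if (length(hit) > 0) {
      f$allele_name <- names(library)[hit[1]]
      f$allele_level <- "full"
      return(f)
    }
    spl <- feature_spliced_seq(f, haplotigs[[f$haplotig_id]])
    if (nzchar(spl)) {
      hit <- cand[vapply(cand, function(i) spliced_lib(i) == spl, logical(1))]
      if (length(hit) > 0) {
        f$allele_name <- names(library)[hit[1]]
        f$allele_level <- "cdna"
        return(f)
      }
    }
    f$allele_name <- "NEW"
    f$allele_level <- "none"
    f
  })
}

tbl_feature_key <- function(label) {
  if (grepl("^exon", label)) return("exon")
  if (grepl("^intron", label)) return("intron")
  if (label == "utr5") return("5'UTR")
  if (label == "utr3") return("3'UTR")
  "misc_feature"
}

fmt_coords <- function(start, end, strand) {
  # 0-based half-open -> 1-based inclusive; minus strand prints end first
  if (strand == "-") paste0(end, "\t", start + 1L)
  else paste0(start + 1L, "\t", end)
}

#' Write feature annotations in GenBank tbl format
#'
#' One `>Feature <haplotig>` block per haplotig; each locus feature emits a
#' `gene` row (with `gene` and, when named, `allele` qualifiers) followed
#' by one row per element, with 1-based inclusive coordinates (reversed on
#' the minus strand).
#'
#' @param features feature records from [annotate_haplotigs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tbl <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  by_htg <- split(features, vapply(features, `[[`, character(1),
                                   "haplotig_id"))
  for (hid in names(by_htg)) {
    writeLines(paste0(">Feature ", hid), con)
    for (f in by_htg[[hid]]) {
      writeLines(paste0(fmt_coords(f$start, f$end, f$strand), "\tgene"), con)
      writeLines(paste0("\t\t\tgene\t", f$locus_name), con)
      if (!is.na(f$allele_name)) {
        writeLines(paste0("\t\t\tallele\t", f$allele_name), con)
      }
      el <- f$elements
      for (i in seq_len(nrow(el))) {
        writeLines(paste0(fmt_coords(el$start[i], el$end[i], f$strand), "\t",
                          tbl_feature_key(el$label[i])), con)
        writeLines(paste0("\t\t\tnote\t", el$label[i]), con)
      }
    }
  }
  invisible(path)
}

#' Parse a tbl file written by [write_tbl()]
#'
#' @param path tbl path.
#' @return list of feature records (`haplotig_id`, `locus_name`, `start`,
#'   `end`, `strand`, `elements`, `allele_name`) with 0-based half-open
#'   coordinates.
#' @export
read_tbl <- function(path) {
  lines <- readLines(path)
  features <- list()
  cur_htg <- NULL
  cur <- NULL
  flush_cur <- function() {
    if (!is.null(cur)) features[[length(features) + 1L]] <<- cur
    cur <<- NULL
  }
  for (ln in lines) {
    if (startsWith(ln, ">Feature")) {
      flush_cur()
      cur_htg <- sub("^>Feature\\s+", "", ln)
      next
    }
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) >= 3 && nzchar(fields[1])) {
      a <- as.integer(fields[1])
      b <- as.integer(fields[2])
      strand <- if (a <= b) "+" else "-"
      start <- min(a, b) - 1L
      end <- max(a, b)
      if (fields[3] == "gene") {
        flush_cur()
        cur <- list(haplotig_id = cur_htg, locus_name = NA_character_,
                    start = start, end = end, strand = strand,
                    elements = data.frame(label = character(0),
                                          start = integer(0),
                                          end = integer(0)),
                    allele_name = NA_character_)
      } else {
        cur$elements <- rbind(cur$elements,
                              data.frame(label = NA_character_, start = start,
                                         end = end, stringsAsFactors = FALSE))
      }
    } else if (length(fields) == 5) {
      key <- fields[4]
      val <- fields[5]
      if (key == "gene") cur$locus_name <- val
      if (key == "allele") cur$allele_name <- val
      if (key == "note") cur$elements$label[nrow(cur$elements)] <- val
    }
  }
  flush_cur()
  features
}

gff3_type <- function(label) {
  if (grepl("^exon", label)) return("exon")
  if (grepl("^intron", label)) return("intron")
  if (label == "utr5") return("five_prime_UTR")
  if (label == "utr3") return("three_prime_UTR")
  "region"
}

#' Write feature annotations as GFF3
#'
#' Emits one `gene` record per feature with `exon` / `intron` / UTR
#' children carrying `Parent` attributes, 1-based inclusive coordinates.
#'
#' @param features feature records from [annotate_haplotigs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(features)) {
    f <- features[[i]]
    gid <- sprintf("gene%04d", i)
    attrs <- paste0("ID=", gid, ";Name=", f$locus_name,
                    ";locus=", f$locus_name)
    if (!is.na(f$allele_name)) attrs <- paste0(attrs, ";allele=",
                                               f$allele_name)
    writeLines(paste(f$haplotig_id, "haplocap", "gene", f$start + 1L, f$end,
                     ".", f$strand, ".", attrs, sep = "\t"), con)
    el <- f$elements
    for (j in seq_len(nrow(el))) {
      cattrs <- paste0("ID=", gid, ".", j, ";Parent=", gid,
                       ";Name=", el$label[j])
      writeLines(paste(f$haplotig_id, "haplocap", gff3_type(el$label[j]),
                       el$start[j] + 1L, el$end[j], ".", f$strand, ".",
                       cattrs, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Parse a GFF3 file written by [write_gff3()]
#'
#' @param path GFF3 path.
#' @return list of feature records with 0-based half-open coordinates.
#' @export
read_gff3_features <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    if (length(m) == 0) return(NA_character_)
    sub(paste0("^;?", key, "="), "", m)
  }
  features <- list()
  by_id <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    type <- fields[3]
    start <- as.integer(fields[4]) - 1L
    end <- as.integer(fields[5])
    attrs <- fields[9]
    if (type == "gene") {
      id <- get_attr(attrs, "ID")
      by_id[[id]] <- list(haplotig_id = fields[1],
                          locus_name = get_attr(attrs, "locus"),
                          start = start, end = end, strand = fields[7],
                          elements = data.frame(label = character(0),
                                                start = integer(0),
                                                end = integer(0)),
                          allele_name = get_attr(attrs, "allele"))
    } else {
      parent <- get_attr(attrs, "Parent")
      by_id[[parent]]$elements <- rbind(
        by_id[[parent]]$elements,
        data.frame(label = get_attr(attrs, "Name"), start = start, end = end,
                   stringsAsFactors = FALSE))
    }
  }
  unname(by_id)
}
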