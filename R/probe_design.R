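#' Masked reference haplotype
#'
#' A reference sequence plus its repeat-element intervals (e.g. from
#' RepeatMasker), the substrate for capture-probe design. Intervals are
#' normalized: sorted and merged if overlapping.
#'
#' @param ref_id reference label.
#' @param sequence DNA string.
#' @param repeat_intervals data.frame with 0-based half-open `start`, `end`
#'   columns (may be empty).
#' @return object of class `MaskedReference`.
#' @export
masked_reference <- function(ref_id, sequence,
                             repeat_intervals = data.frame(start = integer(0),
                                                           end = integer(0))) {
  L <- nchar(sequence)
  if (nrow(repeat_intervals) > 0) {
    check_intervals(repeat_intervals$start, repeat_intervals$end, L,
                    "repeat interval")
    ir <- IRanges::reduce(IRanges::IRanges(repeat_intervals$start + 1L,
                                           repeat_intervals$end))
    repeat_intervals <- data.frame(start = BiocGenerics::start(ir) - 1L,
                                   end = BiocGenerics::end(ir))
  }
  structure(list(ref_id = ref_id, sequence = sequence,
                 repeat_intervals = repeat_intervals),
            class = "MaskedReference")
}

#' Probe design configuration
#'
#' @param probe_length capture probe length in bases (default 120).
#' @param stride candidate window step in bases (default `probe_length`,
#'   i.e. non-overlapping tiling).
#' @param max_gap stopping criterion: selection ends when every reference's
#'   largest inter-hit distance is below this (default 5000 bases, the
#'   expected captured fragment length scale).
#' @param allow_mismatches substitutions tolerated when counting probe hits
#'   during design (default 0, exact matching).
#' @param max_panel optional cap on panel size.
#' @return object of class `DesignConfig`.
#' @export
design_config <- function(probe_length = 120, stride = probe_length,
                          max_gap = 5000, allow_mismatches = 0,
                          max_panel = Inf) {
  if (probe_length <= 0) stop("probe_length must be > 0")
  if (max_gap <= probe_length) stop("max_gap must exceed probe_length")
  if (stride <= 0) stop("stride must be > 0")
  structure(list(probe_length = as.integer(probe_length),
                 stride = as.integer(stride),
                 max_gap = as.numeric(max_gap),
                 allow_mismatches = as.integer(allow_mismatches),
                 max_panel = max_panel),
            class = "DesignConfig")
}

mask_ranges <- function(ref) {
  if (nrow(ref$repeat_intervals) == 0) return(IRanges::IRanges())
  IRanges::IRanges(ref$repeat_intervals$start + 1L, ref$repeat_intervals$end)
}

#' Enumerate candidate probe windows
#'
#' Takes windows of `probe_length` at fixed `stride` from position 0 of each
#' reference, dropping any window that contains a non-ACGT base or overlaps
#' a repeat interval by any base. A terminal window flush with the reference
#' end is added only when the end would otherwise sit more than
#' `max_gap / 2` beyond the last regular window. Candidates are
#' deduplicated by sequence.
#'
#' @param refs list of [masked_reference()] objects.
#' @param cfg a [design_config()].
#' @return character vector of candidate probe sequences (sorted, unique).
#' @export
enumerate_candidates <- function(refs, cfg) {
  if (length(refs) == 0L) stop("refs must be non-empty")
  out <- character(0)
  for (ref in refs) {
    L <- nchar(ref$sequence)
    if (L < cfg$probe_length) next
    starts <- seq.int(0L, L - cfg$probe_length, by = cfg$stride)
    last_end <- starts[length(starts)] + cfg$probe_length
    if (L - last_end > cfg$max_gap / 2) {
      starts <- c(starts, L - cfg$probe_length)
    }
    wins <- substring(ref$sequence, starts + 1L, starts + cfg$probe_length)
    keep <- !grepl("[^ACGT]", wins)
    mask <- mask_ranges(ref)
    if (length(mask) > 0) {
      wr <- IRanges::IRanges(starts + 1L, starts + cfg$probe_length)
      keep <- keep & !IRanges::overlapsAny(wr, mask)
    }
    if (!any(keep) && length(mask) > 0) {
      warning("reference ", ref$ref_id, " yields no candidates (fully masked)")
    }
    out <- c(out, wins[keep])
  }
  sort(unique(out))
}

#' Count repeat-free hits of a candidate probe on references
#'
#' Finds every position on either strand of every reference where the
#' candidate matches with at most `allow_mismatches` substitutions; hits
#' whose interval overlaps a repeat interval by any base are discarded.
#'
#' @param candidate probe sequence.
#' @param refs list of [masked_reference()] objects.
#' @param allow_mismatches substitution tolerance.
#' @return data.frame with columns `ref_id`, `start`, `end` (0-based
#'   half-open), `strand`, `mismatches`.
#' @export
count_hits <- function(candidate, refs, allow_mismatches = 0) {
  plen <- nchar(candidate)
  rows <- list()
  for (ref in refs) {
    subject <- Biostrings::DNAString(ref$sequence)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") candidate else revcomp(candidate)
      starts <- match_starts(pat, subject, allow_mismatches)
      if (length(starts) == 0) next
      mm <- vapply(starts, function(s) {
        hamming(substring(ref$sequence, s + 1L, s + plen), pat)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        ref_id = ref$ref_id, start = starts, end = starts + plen,
        strand = strand, mismatches = as.integer(mm),
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows)
          else data.frame(ref_id = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          mismatches = integer(0))
  drop_masked_hits(hits, refs)
}

drop_masked_hits <- function(hits, refs) {
  if (nrow(hits) == 0) return(hits)
  keep <- rep(TRUE, nrow(hits))
  for (ref in refs) {
    mask <- mask_ranges(ref)
    if (length(mask) == 0) next
    idx <- hits$ref_id == ref$ref_id
    if (!any(idx)) next
    hr <- IRanges::IRanges(hits$start[idx] + 1L, hits$end[idx])
    keep[idx] <- !IRanges::overlapsAny(hr, mask)
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Score all candidates at once; exact matching uses a PDict pass per
# reference/strand, mismatch-tolerant matching falls back to per-candidate
# scans. Returns a list of hit data.frames parallel to `candidates`.
score_candidates <- function(candidates, refs, cfg) {
  if (cfg$allow_mismatches > 0) {
    return(lapply(candidates, count_hits, refs = refs,
                  allow_mismatches = cfg$allow_mismatches))
  }
  plen <- cfg$probe_length
  hit_rows <- vector("list", length(candidates))
  add <- function(i, df) {
    hit_rows[[i]] <<- if (is.null(hit_rows[[i]])) df else rbind(hit_rows[[i]], df)
  }
  fwd <- Biostrings::DNAStringSet(candidates)
  rev <- Biostrings::reverseComplement(fwd)
  pd_fwd <- Biostrings::PDict(fwd)
  pd_rev <- Biostrings::PDict(rev)
  for (ref in refs) {
    subject <- Biostrings::DNAString(ref$sequence)
    for (strand in c("+", "-")) {
      pd <- if (strand == "+") pd_fwd else pd_rev
      m <- Biostrings::matchPDict(pd, subject)
      for (i in seq_along(candidates)) {
        st <- BiocGenerics::start(m[[i]])
        if (length(st) == 0) next
        add(i, data.frame(ref_id = ref$ref_id, start = sort(st) - 1L,
                          end = sort(st) - 1L + plen, strand = strand,
                          mismatches = 0L, stringsAsFactors = FALSE))
      }
    }
  }
  lapply(hit_rows, function(df) {
    if (is.null(df)) {
      df <- data.frame(ref_id = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       mismatches = integer(0))
    }
    drop_masked_hits(df, refs)
  })
}

max_gap_from_midpoints <- function(midpoints, ref_length) {
  if (length(midpoints) == 0) return(ref_length)
  m <- sort(midpoints)
  max(c(m[1], diff(m), ref_length - m[length(m)]))
}

#' Greedy capture-probe panel selection
#'
#' Scores every candidate by its repeat-free hit count over the references
#' and adds probes in descending hit-count order (ties broken by probe
#' sequence, then by first hit position) until the largest distance between
#' consecutive hit midpoints — including the distances to both reference
#' ends — falls below `cfg$max_gap` on every reference, or candidates are
#' exhausted. This exploits homology: one probe hitting conserved blocks of
#' several loci covers them all.
#'
#' @param candidates character vector of candidate probe sequences (see
#'   [enumerate_candidates()]).
#' @param refs list of [masked_reference()] objects.
#' @param cfg a [design_config()].
#' @return object of class `ProbePanel`: list with `probes` (list of
#'   `probe_id`/`sequence`/`hits` in selection order), `max_gap_per_ref`,
#'   `satisfied` flag, `cfg`, and a `gap_report` when the criterion could
#'   not be met.
#' @export
greedy_select <- function(candidates, refs, cfg) {
  if (length(candidates) == 0L) {
    stop("design infeasible: empty candidate list")
  }
  hits_list <- score_candidates(candidates, refs, cfg)
  counts <- vapply(hits_list, nrow, integer(1))
  first_pos <- vapply(hits_list, function(h) {
    if (nrow(h) == 0) Inf else min(h$start)
  }, numeric(1))
  keep <- counts > 0
  ord <- order(-counts[keep], candidates[keep], first_pos[keep])
  pool_seq <- candidates[keep][ord]
  pool_hits <- hits_list[keep][ord]

  ref_lengths <- vapply(refs, function(r) nchar(r$sequence), numeric(1))
  names(ref_lengths) <- vapply(refs, `[[`, character(1), "ref_id")
  midpoints <- lapply(ref_lengths, function(...) numeric(0))

  cur_max_gap <- function() {
    vapply(names(ref_lengths), function(rid) {
      max_gap_from_midpoints(midpoints[[rid]], ref_lengths[[rid]])
    }, numeric(1))
  }

  probes <- list()
  i <- 0L
  while (any(cur_max_gap() >= cfg$max_gap) &&
         i < length(pool_seq) && length(probes) < cfg$max_panel) {
    i <- i + 1L
    h <- pool_hits[[i]]
    probes[[length(probes) + 1L]] <- list(
      probe_id = sprintf("P%03d", length(probes) + 1L),
      sequence = pool_seq[i],
      hits = h)
    for (rid in unique(h$ref_id)) {
      hh <- h[h$ref_id == rid, , drop = FALSE]
      midpoints[[rid]] <- c(midpoints[[rid]], (hh$start + hh$end) / 2)
    }
  }
  mg <- cur_max_gap()
  satisfied <- all(mg < cfg$max_gap)
  panel <- structure(list(probes = probes, max_gap_per_ref = mg,
                          satisfied = satisfied, cfg = cfg),
                     class = "ProbePanel")
  if (!satisfied) {
    panel$gap_report <- coverage_gaps(panel, refs)
    warning("gap criterion not met on: ",
            paste(names(mg)[mg >= cfg$max_gap], collapse = ", "))
  }
  panel
}

#' Extract probe sequences / hit table from a panel
#' @param panel a `ProbePanel`.
#' @return `panel_sequences`: named character vector (names = probe ids);
#'   `panel_hits`: data.frame of all hits with a `probe_id` column.
#' @export
panel_sequences <- function(panel) {
  out <- vapply(panel$probes, `[[`, character(1), "sequence")
  names(out) <- vapply(panel$probes, `[[`, character(1), "probe_id")
  out
}

#' @rdname panel_sequences
#' @export
panel_hits <- function(panel) {
  if (length(panel$probes) == 0) {
    return(data.frame(probe_id = character(0), ref_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  do.call(rbind, lapply(panel$probes, function(p) {
    if (nrow(p$hits) == 0) return(NULL)
    cbind(probe_id = p$probe_id, p$hits, stringsAsFactors = FALSE)
  }))
}

#' Coverage gaps of a probe panel over references
#'
#' Recomputes, from the panel's hit coordinates, the gap structure on every
#' reference: distances between consecutive hit midpoints, including the
#' distances from the reference start to the first midpoint and from the
#' last midpoint to the reference end.
#'
#' @param panel a `ProbePanel`.
#' @param refs list of [masked_reference()] objects.
#' @return named list per reference: `gaps` data.frame (`start`, `end`,
#'   `width`, between consecutive midpoints / ends), `max_gap`, and
#'   `mean_gap` (the mean inter-hit distance).
#' @export
coverage_gaps <- function(panel, refs) {
  hits <- panel_hits(panel)
  out <- list()
  for (ref in refs) {
    L <- nchar(ref$sequence)
    h <- hits[hits$ref_id == ref$ref_id, , drop = FALSE]
    mids <- sort((h$start + h$end) / 2)
    bounds <- c(0, mids, L)
    gaps <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
    gaps$width <- gaps$end - gaps$start
    out[[ref$ref_id]] <- list(gaps = gaps, max_gap = max(gaps$width),
                              mean_gap = mean(gaps$width))
  }
  out
}

#' Write a probe panel to FASTA and BED
#'
#' Emits the probe sequences as FASTA and all their reference hits as a
#' 6-column BED (0-based half-open, name = probe id, score = mismatches).
#'
#' @param panel a `ProbePanel`.
#' @param fasta_path output FASTA path.
#' @param bed_path output BED path.
#' @return invisibly, a list of the two paths.
#' @export
write_panel <- function(panel, fasta_path, bed_path) {
  seqs <- panel_sequences(panel)
  if (length(seqs) > 0) {
    write_fasta(seqs, fasta_path)
  } else {
    file.create(fasta_path)
  }
  hits <- panel_hits(panel)
  bed <- data.frame(chrom = hits$ref_id, start = hits$start, end = hits$end,
                    name = hits$probe_id, score = hits$mismatches,
                    strand = hits$strand)
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(list(fasta = fasta_path, bed = bed_path))
}

#' Read a probe panel FASTA back to a named character vector
#' @param fasta_path panel FASTA written by [write_panel()].
#' @return named character vector of probe sequences.
#' @export
read_panel_fasta <- function(fasta_path) {
  if (file.size(fasta_path) == 0) return(stats::setNames(character(0), character(0)))
  read_fasta(fasta_path)
}
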