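#' Evaluation configuration
#'
#' @param lg_fraction reference fraction for the LG metric (default 0.75,
#'   i.e. LG75: haplotigs needed to phase 75\% of a haplotype).
#' @param min_alignment_length drop alignment records spanning fewer
#'   reference bases than this (default 0).
#' @return object of class `EvalConfig`.
#' @export
eval_config <- function(lg_fraction = 0.75, min_alignment_length = 0) {
  if (lg_fraction <= 0 || lg_fraction > 1) {
    stop("lg_fraction must be in (0, 1]")
  }
  structure(list(lg_fraction = lg_fraction,
                 min_alignment_length = as.numeric(min_alignment_length)),
            class = "EvalConfig")
}

empty_records <- function() {
  data.frame(query_id = character(0), query_length = integer(0),
             target_id = character(0), target_start = integer(0),
             target_end = integer(0), strand = character(0),
             matches = integer(0), aligned_columns = integer(0),
             stringsAsFactors = FALSE)
}

parse_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_records())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) {
      stop("malformed PAF line ", i, ": expected >= 12 fields, got ",
           length(f))
    }
    nums <- suppressWarnings(as.numeric(f[c(2, 3, 4, 8, 9, 10, 11)]))
    if (any(is.na(nums))) stop("malformed PAF line ", i,
                               ": non-numeric coordinate field")
    data.frame(query_id = f[1], query_length = as.integer(nums[1]),
               target_id = f[6], target_start = as.integer(nums[4]),
               target_end = as.integer(nums[5]), strand = f[5],
               matches = as.integer(nums[6]),
               aligned_columns = as.integer(nums[7]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

parse_sam <- function(path) {
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "flag"),
                                         tag = "NM"))
  if (length(ga) == 0) return(empty_records())
  ops <- GenomicAlignments::cigarOpTable(GenomicAlignments::cigar(ga))
  m_cols <- ops[, "M"] + ops[, "="] + ops[, "X"]
  i_cols <- ops[, "I"]
  d_cols <- ops[, "D"]
  nm <- S4Vectors::mcols(ga)$NM
  nm[is.na(nm)] <- 0L
  mismatches <- pmax(nm - i_cols - d_cols, 0L)
  strand <- ifelse(bitwAnd(S4Vectors::mcols(ga)$flag, 16L) > 0L, "-", "+")
  data.frame(query_id = S4Vectors::mcols(ga)$qname,
             query_length = GenomicAlignments::qwidth(ga),
             target_id = as.character(GenomicAlignments::seqnames(ga)),
             target_start = BiocGenerics::start(ga) - 1L,
             target_end = BiocGenerics::end(ga),
             strand = strand,
             matches = as.integer(m_cols - mismatches),
             aligned_columns = as.integer(m_cols + i_cols + d_cols),
             stringsAsFactors = FALSE)
}

#' Parse haplotig-to-reference alignments from PAF or SAM
#'
#' Match counts come from format-native fields: PAF column 10 (residue
#' matches) and column 11 (alignment block length); for SAM they are
#' derived from the CIGAR and the NM tag (matches = aligned M columns minus
#' substitutions; aligned columns include insertion and deletion columns).
#'
#' @param path alignment file.
#' @param format `"paf"` or `"sam"`.
#' @param cfg optional [eval_config()] whose `min_alignment_length` filters
#'   records by reference span.
#' @return data.frame of alignment records with columns `query_id`,
#'   `query_length`, `target_id`, `target_start`, `target_end` (0-based
#'   half-open), `strand`, `matches`, `aligned_columns`.
#' @export
parse_alignments <- function(path, format = c("paf", "sam"), cfg = NULL) {
  format <- match.arg(format)
  rec <- switch(format, paf = parse_paf(path), sam = parse_sam(path))
  bad <- rec$matches > rec$aligned_columns
  if (any(bad)) stop("invalid record: matches exceed aligned columns")
  if (!is.null(cfg) && cfg$min_alignment_length > 0) {
    rec <- rec[rec$target_end - rec$target_start >= cfg$min_alignment_length,
               , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

target_ranges <- function(records) {
  IRanges::IRanges(records$target_start + 1L, records$target_end)
}

#' Phased coverage of a reference by alignment records
#'
#' 100 times the fraction of the reference covered by the union of the
#' records' target intervals (overlaps are never double-counted).
#'
#' @param records alignment records for one reference.
#' @param ref_length reference length in bases.
#' @return coverage percent in [0, 100].
#' @export
reference_coverage <- function(records, ref_length) {
  if (ref_length <= 0) stop("ref_length must be > 0")
  if (nrow(records) == 0) return(0)
  covered <- sum(BiocGenerics::width(IRanges::reduce(target_ranges(records))))
  100 * covered / ref_length
}

#' Concordance of alignment records
#'
#' 100 times total matches over total aligned columns (matches, mismatches
#' and gap columns), pooled over all records. Empty input yields `NA`
#' (undefined) rather than 0.
#'
#' @param records alignment records.
#' @return concordance percent, or `NA_real_` for empty input.
#' @export
concordance <- function(records) {
  if (nrow(records) == 0) return(NA_real_)
  100 * sum(records$matches) / sum(records$aligned_columns)
}

#' LG metric: haplotigs needed to phase a reference fraction
#'
#' Haplotigs are ranked by total aligned reference span (descending, ties
#' by query id); their target-interval unions are accumulated in that
#' order, and the LG value is the number of haplotigs at which the union
#' first reaches `cfg$lg_fraction` of the reference length. `NA` if the
#' fraction is never reached.
#'
#' @param records alignment records for one reference.
#' @param ref_length reference length in bases.
#' @param cfg an [eval_config()].
#' @return integer count, or `NA_integer_` if unreachable.
#' @export
lg_metric <- function(records, ref_length, cfg = eval_config()) {
  if (nrow(records) == 0) return(NA_integer_)
  spans <- vapply(split(records, records$query_id), function(r) {
    sum(BiocGenerics::width(IRanges::reduce(target_ranges(r))))
  }, numeric(1))
  ord <- names(spans)[order(-spans, names(spans))]
  needed <- cfg$lg_fraction * ref_length
  acc <- IRanges::IRanges()
  for (i in seq_along(ord)) {
    r <- records[records$query_id == ord[i], , drop = FALSE]
    acc <- IRanges::reduce(c(acc, target_ranges(r)))
    if (sum(BiocGenerics::width(acc)) >= needed) return(i)
  }
  NA_integer_
}

#' Evaluate a haplotig set against reference haplotypes
#'
#' Computes, per reference and pooled, the phased coverage, concordance
#' and LG metric from an alignment record table.
#'
#' @param records alignment records (see [parse_alignments()] or
#'   [align_exact()]).
#' @param ref_lengths named numeric vector of reference lengths.
#' @param cfg an [eval_config()].
#' @return object of class `EvalReport`: list with `per_ref` (data.frame
#'   with `ref_id`, `ref_length`, `coverage_percent`, `concordance_percent`,
#'   `lg_value`, `n_haplotigs`) and `overall` (length-weighted mean
#'   coverage, pooled concordance, mean LG).
#' @export
evaluate_assembly <- function(records, ref_lengths, cfg = eval_config()) {
  per <- do.call(rbind, lapply(names(ref_lengths), function(rid) {
    r <- records[records$target_id == rid, , drop = FALSE]
    data.frame(ref_id = rid, ref_length = ref_lengths[[rid]],
               coverage_percent = reference_coverage(r, ref_lengths[[rid]]),
               concordance_percent = concordance(r),
               lg_value = lg_metric(r, ref_lengths[[rid]], cfg),
               n_haplotigs = length(unique(r$query_id)),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  overall <- list(
    coverage_percent = sum(per$coverage_percent * per$ref_length) /
      sum(per$ref_length),
    concordance_percent = concordance(
      records[records$target_id %in% names(ref_lengths), , drop = FALSE]),
    mean_lg = mean(per$lg_value))
  structure(list(per_ref = per, overall = overall, cfg = cfg),
            class = "EvalReport")
}

#' Write an evaluation report as TSV and JSON
#' @param report an `EvalReport`.
#' @param tsv_path per-reference table output path (optional).
#' @param json_path JSON output path (optional).
#' @return the report, invisibly.
#' @export
write_eval_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    write.table(report$per_ref, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(per_ref = report$per_ref,
                              overall = report$overall),
                         json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(report)
}

#' Exact-substring aligner for fixture tests
#'
#' A deliberately trivial aligner: each haplotig is located on each
#' reference by exact matching on either strand, yielding perfect
#' alignment records. Intended for testing the evaluation stage with
#' haplotigs that are exact fragments of the references; real data should
#' be aligned with an external aligner and read via [parse_alignments()].
#'
#' @param haplotigs named character vector.
#' @param refs named character vector of reference sequences.
#' @return alignment record data.frame (see [parse_alignments()]).
#' @export
align_exact <- function(haplotigs, refs) {
  rows <- list()
  for (q in names(haplotigs)) {
    qlen <- nchar(haplotigs[[q]])
    for (t in names(refs)) {
      subject <- Biostrings::DNAString(refs[[t]])
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") haplotigs[[q]] else revcomp(haplotigs[[q]])
        starts <- match_starts(pat, subject, 0L)
        if (length(starts) == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = q, query_length = qlen, target_id = t,
          target_start = starts, target_end = starts + qlen,
          strand = strand, matches = qlen, aligned_columns = qlen,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_records()
  rownames(out) <- NULL
  out
}

#' Write alignment records as PAF
#' @param records alignment record data.frame.
#' @param path output PAF path.
#' @param ref_lengths named vector of target lengths (for PAF column 7).
#' @return `path`, invisibly.
#' @export
write_paf <- function(records, path, ref_lengths) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    paste(r$query_id, r$query_length, 0L, r$query_length, r$strand,
          r$target_id, ref_lengths[[r$target_id]], r$target_start,
          r$target_end, r$matches, r$aligned_columns, 60L, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
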