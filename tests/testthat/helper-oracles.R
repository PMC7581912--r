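# Independent brute-force oracles, deliberately written without reusing the
# package's search machinery.

oracle_hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# every 0-based start where pattern matches subject with <= max_mm
# substitutions, by explicit window enumeration
oracle_scan <- function(pattern, subject, max_mm = 0) {
  plen <- nchar(pattern)
  n <- nchar(subject)
  if (n < plen) return(integer(0))
  starts <- 0:(n - plen)
  wins <- substring(subject, starts + 1, starts + plen)
  starts[vapply(wins, oracle_hamming, numeric(1), b = pattern) <= max_mm]
}

# probe hits on masked references: both strands, mask exclusion by any-base
# overlap
oracle_probe_hits <- function(candidate, refs, max_mm = 0) {
  rows <- list()
  for (ref in refs) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") candidate else oracle_revcomp(candidate)
      for (s in oracle_scan(pat, ref$sequence, max_mm)) {
        e <- s + nchar(candidate)
        masked <- FALSE
        if (nrow(ref$repeat_intervals) > 0) {
          masked <- any(ref$repeat_intervals$start < e &
                        ref$repeat_intervals$end > s)
        }
        if (!masked) {
          rows[[length(rows) + 1]] <- data.frame(
            ref_id = ref$ref_id, start = s, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(ref_id = character(0), start = integer(0),
                      strand = character(0)))
  }
  df <- do.call(rbind, rows)
  df[order(df$ref_id, df$start, df$strand), , drop = FALSE]
}

# all k-mers of a read, both orientations, plain character sets
oracle_read_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, 1:(n - k + 1), k:n)
  unique(c(km, vapply(km, oracle_revcomp, character(1), USE.NAMES = FALSE)))
}

# on-target decision by direct set intersection of read and probe k-mers
oracle_on_target <- function(read_seq, probe_kmer_set, k, min_shared = 1) {
  shared <- intersect(oracle_read_kmers(read_seq, k), probe_kmer_set)
  # count distinct sites, not orientations: collapse to canonical form
  canon <- vapply(shared, function(x) {
    rc <- oracle_revcomp(x)
    if (x <= rc) x else rc
  }, character(1), USE.NAMES = FALSE)
  length(unique(canon)) >= min_shared
}

# covered length of [0, L) under a set of 0-based half-open intervals,
# via an explicit base-occupancy vector
oracle_union_len <- function(starts, ends, L) {
  occ <- logical(L)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) occ[(starts[i] + 1):ends[i]] <- TRUE
  }
  sum(occ)
}

# LG by explicit cumulative occupancy, haplotigs ranked by their own union
# span (ties by name)
oracle_lg <- function(records, ref_length, fraction) {
  spans <- vapply(split(records, records$query_id), function(r) {
    oracle_union_len(r$target_start, r$target_end, ref_length)
  }, numeric(1))
  ord <- names(spans)[order(-spans, names(spans))]
  occ <- logical(ref_length)
  for (i in seq_along(ord)) {
    r <- records[records$query_id == ord[i], , drop = FALSE]
    for (j in seq_len(nrow(r))) {
      if (r$target_end[j] > r$target_start[j]) {
        occ[(r$target_start[j] + 1):r$target_end[j]] <- TRUE
      }
    }
    if (sum(occ) >= fraction * ref_length) return(i)
  }
  NA_integer_
}

# percent identity of a global pairwise alignment (Biostrings as the
# independent alignment engine)
oracle_global_pid <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global")
  Biostrings::pid(aln)
}

# small shared fixtures -------------------------------------------------

small_sim <- function(seed = 3, n_loci = 4) {
  simulate_diploid(sim_config(n_loci = n_loci, seed = seed))
}

sim_refs <- function(sim) {
  lapply(sim$haplotypes, function(h) {
    masked_reference(h$name, h$sequence, h$repeats)
  })
}

random_seq <- function(n, seed) {
  haplocap:::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  })
}
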