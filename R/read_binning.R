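#' Read-binning configuration
#'
#' @param k k-mer length for probe matching (default 25, the gene-probe
#'   length).
#' @param both_strands match k-mers on both strands via canonical form
#'   (default TRUE).
#' @param min_shared_kmers minimum distinct shared k-mers for a read to be
#'   classified/binned (default 1: any hit counts).
#' @return object of class `BinConfig`.
#' @export
bin_config <- function(k = 25, both_strands = TRUE, min_shared_kmers = 1) {
  if (k <= 0) stop("k must be > 0")
  if (min_shared_kmers < 1) stop("min_shared_kmers must be >= 1")
  structure(list(k = as.integer(k), both_strands = isTRUE(both_strands),
                 min_shared_kmers = as.integer(min_shared_kmers)),
            class = "BinConfig")
}

# all k-mers of a sequence (0-based windows), optionally canonicalized
seq_kmers <- function(seq, k, canonical = TRUE) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  km <- km[!grepl("[^ACGT]", km)]
  if (canonical && length(km) > 0) {
    rc <- revcomp(km)
    km <- ifelse(km <= rc, km, rc)
  }
  km
}

#' Build a k-mer index from probe or catalog sequences
#'
#' Indexes every length-`k` window of every input sequence under its
#' canonical form (the lexicographic minimum of the k-mer and its reverse
#' complement, when `cfg$both_strands`), mapping it to the names of the
#' sequences it occurs in.
#'
#' @param seqs named character vector: capture probes (names = probe ids)
#'   or per-locus probe sets (names = locus names; duplicate names pool).
#' @param cfg a [bin_config()].
#' @return object of class `KmerIndex`: list with `k`, `both_strands`,
#'   `kmers` (character vector of indexed canonical k-mers) and `groups`
#'   (list of name sets parallel to `kmers`).
#' @export
build_kmer_index <- function(seqs, cfg) {
  if (length(seqs) == 0L) stop("seqs must be non-empty")
  if (any(nchar(seqs) < cfg$k)) {
    stop("sequence(s) shorter than k = ", cfg$k)
  }
  rows <- lapply(seq_along(seqs), function(i) {
    km <- unique(seq_kmers(seqs[[i]], cfg$k, canonical = cfg$both_strands))
    if (length(km) == 0) return(NULL)
    data.frame(kmer = km, name = names(seqs)[i], stringsAsFactors = FALSE)
  })
  df <- unique(do.call(rbind, rows))
  groups <- split(df$name, df$kmer)
  structure(list(k = cfg$k, both_strands = cfg$both_strands,
                 kmers = names(groups), groups = unname(groups)),
            class = "KmerIndex")
}

# number of distinct indexed k-mers shared by one read
shared_kmer_names <- function(read_seq, index) {
  km <- unique(seq_kmers(read_seq, index$k, canonical = index$both_strands))
  idx <- match(km, index$kmers)
  idx <- idx[!is.na(idx)]
  list(n = length(idx), names = unique(unlist(index$groups[idx])))
}

coerce_reads <- function(reads) {
  if (is.data.frame(reads)) {
    stats::setNames(reads$sequence, reads$read_id)
  } else {
    stopifnot(is.character(reads))
    if (is.null(names(reads))) names(reads) <- sprintf("read%05d", seq_along(reads))
    reads
  }
}

#' Classify reads as on- or off-target
#'
#' A read is on-target iff it shares at least `cfg$min_shared_kmers`
#' distinct indexed k-mers with the capture-probe panel, on either strand.
#' The partition is exhaustive and disjoint.
#'
#' @param reads named character vector of read sequences, or a `SimReads`
#'   data.frame.
#' @param index `KmerIndex` built from the capture-probe panel.
#' @param cfg a [bin_config()].
#' @return list with `on` and `off`: named character vectors of read
#'   sequences.
#' @export
classify_on_target <- function(reads, index, cfg) {
  seqs <- coerce_reads(reads)
  if (length(seqs) == 0L) {
    empty <- stats::setNames(character(0), character(0))
    return(list(on = empty, off = empty))
  }
  shared <- vapply(seqs, function(s) shared_kmer_names(s, index)$n, integer(1))
  on <- shared >= cfg$min_shared_kmers
  list(on = seqs[on], off = seqs[!on])
}

#' Derive a per-locus k-mer probe catalog from annotated references
#'
#' Collects, for every locus, the canonical k-mers of all its occurrences
#' on the reference haplotypes, and retains only the k-mers unique to one
#' locus. These locus-specific k-mers play the role of the short gene
#' probes used for in-silico binning.
#'
#' @param haplotypes list of `SimHaplotype`s (or any objects with
#'   `sequence` and `features` truth).
#' @param cfg a [bin_config()].
#' @return object of class `LocusCatalog`: list with `k` and `loci`, a
#'   named list of k-mer character vectors.
#' @export
derive_locus_catalog <- function(haplotypes, cfg) {
  if (inherits(haplotypes, "SimHaplotype")) haplotypes <- list(haplotypes)
  per_locus <- list()
  for (hap in haplotypes) {
    for (f in hap$features) {
      s <- substring(hap$sequence, f$start + 1L, f$end)
      km <- unique(seq_kmers(s, cfg$k, canonical = cfg$both_strands))
      per_locus[[f$locus_name]] <- unique(c(per_locus[[f$locus_name]], km))
    }
  }
  all_km <- unlist(per_locus, use.names = FALSE)
  dup <- unique(all_km[duplicated(all_km)])
  loci <- lapply(per_locus, function(km) setdiff(km, dup))
  structure(list(k = cfg$k, loci = loci), class = "LocusCatalog")
}

#' Build a k-mer index from a locus catalog
#'
#' Fast path for catalogs whose entries are already k-mers: canonicalizes
#' them in one pass and aggregates loci per k-mer.
#'
#' @param catalog a `LocusCatalog`.
#' @param cfg a [bin_config()].
#' @return a `KmerIndex`.
#' @export
catalog_index <- function(catalog, cfg) {
  kmers <- unlist(catalog$loci, use.names = FALSE)
  if (length(kmers) == 0L) stop("catalog has no locus-specific k-mers")
  groups <- rep(names(catalog$loci), lengths(catalog$loci))
  if (cfg$both_strands) {
    rc <- revcomp(kmers)
    swap <- rc < kmers
    kmers[swap] <- rc[swap]
  }
  gl <- split(groups, kmers)
  structure(list(k = catalog$k, both_strands = cfg$both_strands,
                 kmers = names(gl), groups = unname(lapply(gl, unique))),
            class = "KmerIndex")
}

#' Bin on-target reads per locus
#'
#' Assigns each read to every locus with which it shares at least
#' `cfg$min_shared_kmers` distinct catalog k-mers (multi-assignment: a read
#' spanning a locus junction lands in both bins, preserving
#' junction-spanning evidence for per-bin assembly). Reads matching no
#' locus go to `unbinned`.
#'
#' @param on_reads named character vector of on-target read sequences.
#' @param catalog a `LocusCatalog` (or a prebuilt `KmerIndex` over locus
#'   k-mers).
#' @param cfg a [bin_config()].
#' @return list with `bins` (named list locus -> named character vector of
#'   reads) and `unbinned` (named character vector).
#' @export
bin_by_locus <- function(on_reads, catalog, cfg) {
  index <- if (inherits(catalog, "KmerIndex")) catalog
           else catalog_index(catalog, cfg)
  locus_names <- sort(unique(unlist(index$groups)))
  bins <- stats::setNames(
    replicate(length(locus_names), character(0), simplify = FALSE),
    locus_names)
  unbinned <- character(0)
  for (rid in names(on_reads)) {
    km <- unique(seq_kmers(on_reads[[rid]], index$k,
                           canonical = index$both_strands))
    idx <- match(km, index$kmers)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) {
      unbinned[rid] <- on_reads[[rid]]
      next
    }
    tab <- table(unlist(index$groups[idx]))
    matched <- names(tab)[tab >= cfg$min_shared_kmers]
    if (length(matched) == 0) {
      unbinned[rid] <- on_reads[[rid]]
    } else {
      for (loc in matched) bins[[loc]][rid] <- on_reads[[rid]]
    }
  }
  list(bins = bins, unbinned = unbinned)
}

#' Write read bins to per-locus FASTQ files
#'
#' @param binning output of [bin_by_locus()].
#' @param on_off optional output of [classify_on_target()]; when given,
#'   `ontarget.fastq` and `offtarget.fastq` are written too.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named vector of written paths.
#' @export
write_bins <- function(binning, out_dir, on_off = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_one <- function(seqs, path) {
    if (length(seqs) == 0) {
      file.create(path)
      return(path)
    }
    df <- data.frame(read_id = names(seqs), sequence = unname(seqs),
                     stringsAsFactors = FALSE)
    set <- Biostrings::DNAStringSet(df$sequence)
    names(set) <- df$read_id
    quals <- Biostrings::BStringSet(vapply(nchar(df$sequence), function(n) {
      paste(rep("I", n), collapse = "")
    }, character(1)))
    Biostrings::writeXStringSet(set, filepath = path, format = "fastq",
                                qualities = quals)
    path
  }
  paths <- c()
  for (loc in names(binning$bins)) {
    p <- file.path(out_dir, paste0("bin_", loc, ".fastq"))
    paths[paste0("bin_", loc)] <- write_one(binning$bins[[loc]], p)
  }
  paths["unbinned"] <- write_one(binning$unbinned,
                                 file.path(out_dir, "unbinned.fastq"))
  if (!is.null(on_off)) {
    paths["ontarget"] <- write_one(on_off$on,
                                   file.path(out_dir, "ontarget.fastq"))
    paths["offtarget"] <- write_one(on_off$off,
                                    file.path(out_dir, "offtarget.fastq"))
  }
  invisible(paths)
}

#' Write / read a locus k-mer catalog as two-column TSV
#'
#' Column 1 is the locus name, column 2 the k-mer, so externally published
#' probe sets can be supplied in place of a derived catalog.
#'
#' @param catalog a `LocusCatalog`.
#' @param path TSV path.
#' @return `path` (write) or a `LocusCatalog` (read).
#' @export
write_catalog_tsv <- function(catalog, path) {
  df <- do.call(rbind, lapply(names(catalog$loci), function(nm) {
    if (length(catalog$loci[[nm]]) == 0) return(NULL)
    data.frame(locus = nm, kmer = catalog$loci[[nm]], stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog_tsv
#' @export
read_catalog_tsv <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("locus", "kmer"),
                   stringsAsFactors = FALSE)
  k <- unique(nchar(df$kmer))
  if (length(k) != 1) stop("catalog k-mers must have a single length")
  structure(list(k = k, loci = split(df$kmer, df$locus)),
            class = "LocusCatalog")
}
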