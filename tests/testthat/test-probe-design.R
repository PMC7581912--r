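test_that("candidate enumeration tiles the reference and applies filters", {
  ref <- masked_reference("r", random_seq(1000, seed = 1))
  cfg <- design_config(probe_length = 120, stride = 120)
  cands <- enumerate_candidates(list(ref), cfg)
  expect_length(cands, 8)  # starts 0..840 step 120, no ragged window
  expect_setequal(cands, substring(ref$sequence, seq(0, 840, 120) + 1,
                                   seq(0, 840, 120) + 120))

  # fully masked reference yields no candidates, with a warning
  mref <- masked_reference("m", ref$sequence,
                           data.frame(start = 0, end = 1000))
  expect_warning(c2 <- enumerate_candidates(list(mref), cfg), "fully masked")
  expect_length(c2, 0)

  # windows containing non-ACGT bases are excluded
  s <- ref$sequence
  substr(s, 50, 50) <- "N"
  nref <- masked_reference("n", s)
  expect_length(enumerate_candidates(list(nref), cfg), 7)

  # a terminal flush window is added when the end would sit > max_gap/2
  # beyond the last stride window
  tref <- masked_reference("t", random_seq(9000, seed = 2))
  tcfg <- design_config(probe_length = 120, stride = 1000, max_gap = 1000)
  tc <- enumerate_candidates(list(tref), tcfg)
  expect_true(substring(tref$sequence, 9000 - 119, 9000) %in% tc)
})

test_that("hit counting agrees with a naive two-strand masked scan", {
  probe <- random_seq(120, seed = 3)
  filler <- function(n, s) random_seq(n, s)
  # three forward occurrences
  ref1 <- masked_reference("a", paste0(filler(200, 4), probe, filler(300, 5),
                                       probe, filler(150, 6), probe,
                                       filler(200, 7)))
  h <- count_hits(probe, list(ref1))
  expect_equal(nrow(h), 3)
  expect_true(all(h$strand == "+"))

  # one forward and one reverse-complement occurrence -> opposite strands
  ref2 <- masked_reference("b", paste0(filler(200, 8), probe, filler(300, 9),
                                       oracle_revcomp(probe), filler(100, 10)))
  h2 <- count_hits(probe, list(ref2))
  expect_equal(nrow(h2), 2)
  expect_setequal(h2$strand, c("+", "-"))

  # an occurrence inside a masked interval is discarded
  ref3 <- masked_reference("c", paste0(filler(200, 11), probe, filler(100, 12)),
                           data.frame(start = 150, end = 350))
  expect_equal(nrow(count_hits(probe, list(ref3))), 0)

  # full equivalence with the oracle, including with mismatch tolerance
  for (mm in c(0, 1, 2)) {
    got <- count_hits(probe, list(ref1, ref2, ref3), allow_mismatches = mm)
    got <- got[order(got$ref_id, got$start, got$strand), ]
    want <- oracle_probe_hits(probe, list(ref1, ref2, ref3), max_mm = mm)
    expect_equal(got$ref_id, want$ref_id)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
  }
})

test_that("greedy selection follows hit-count order and the gap criterion", {
  # a reference shorter than max_gap needs no probes at all
  short <- masked_reference("s", random_seq(400, seed = 14))
  cfg <- design_config(max_gap = 5000)
  p0 <- greedy_select("ACGT", list(short), design_config(probe_length = 4,
                                                         max_gap = 5000))
  expect_length(p0$probes, 0)
  expect_true(p0$satisfied)
  expect_error(greedy_select(character(0), list(short), cfg), "infeasible")

  # hand-built instance: candidate A hits 5x, B 3x, C 1x; A+B meet the gap
  # criterion, A alone does not -> panel must be exactly (A, B) in order
  A <- random_seq(120, seed = 15)
  B <- random_seq(120, seed = 16)
  C <- random_seq(120, seed = 17)
  pieces <- c(A, random_seq(380, 18), A, random_seq(380, 19), A,
              random_seq(380, 20), B, random_seq(700, 21), B,
              random_seq(700, 22), A, random_seq(380, 23), A,
              random_seq(60, 24), B, random_seq(60, 25), C,
              random_seq(180, 26))
  ref <- masked_reference("toy", paste(pieces, collapse = ""))
  tcfg <- design_config(max_gap = 2000)
  panel <- greedy_select(c(B, C, A), list(ref), tcfg)
  expect_identical(unname(panel_sequences(panel)), c(A, B))
  expect_true(panel$satisfied)
})

test_that("max gap is non-increasing along the selection order and matches
           an independent recomputation", {
  sim <- small_sim(seed = 6)
  refs <- sim_refs(sim)
  cfg <- design_config()
  cands <- enumerate_candidates(refs, cfg)
  panel <- greedy_select(cands, refs, cfg)
  expect_true(panel$satisfied)

  # independent recomputation of the per-ref max gap from hit midpoints
  hits <- panel_hits(panel)
  recompute <- function(upto) {
    sel <- hits[hits$probe_id %in% sprintf("P%03d", seq_len(upto)), ]
    vapply(refs, function(r) {
      m <- sort((sel$start[sel$ref_id == r$ref_id] +
                 sel$end[sel$ref_id == r$ref_id]) / 2)
      L <- nchar(r$sequence)
      if (length(m) == 0) return(L)
      max(c(m[1], diff(m), L - m[length(m)]))
    }, numeric(1))
  }
  expect_equal(unname(recompute(length(panel$probes))),
               unname(panel$max_gap_per_ref))
  expect_true(all(panel$max_gap_per_ref < cfg$max_gap))
  gaps_along <- vapply(seq_along(panel$probes),
                       function(k) max(recompute(k)), numeric(1))
  expect_true(all(diff(gaps_along) <= 0))

  # soundness: every selected hit re-verifies and avoids repeats
  for (p in panel$probes) {
    for (i in seq_len(nrow(p$hits))) {
      h <- p$hits[i, ]
      ref <- refs[[h$ref_id]]
      win <- substring(ref$sequence, h$start + 1, h$end)
      pat <- if (h$strand == "+") p$sequence else oracle_revcomp(p$sequence)
      expect_identical(win, pat)
      if (nrow(ref$repeat_intervals) > 0) {
        expect_false(any(ref$repeat_intervals$start < h$end &
                         ref$repeat_intervals$end > h$start))
      }
    }
  }
})

test_that("coverage gap arithmetic matches hand-computed values", {
  ref <- masked_reference("r", random_seq(400, seed = 27))
  fake_panel <- structure(list(probes = list(list(
    probe_id = "P001", sequence = "NA",
    hits = data.frame(ref_id = "r", start = c(40, 240), end = c(160, 360),
                      strand = "+", mismatches = 0L)))), class = "ProbePanel")
  g <- coverage_gaps(fake_panel, list(ref))$r
  expect_equal(g$gaps$width, c(100, 200, 100))
  expect_equal(g$max_gap, 200)
  expect_equal(g$mean_gap, sum(g$gaps$width) / nrow(g$gaps))

  empty_panel <- structure(list(probes = list()), class = "ProbePanel")
  g0 <- coverage_gaps(empty_panel, list(ref))$r
  expect_equal(nrow(g0$gaps), 1)
  expect_equal(g0$max_gap, 400)
})

test_that("panel FASTA/BED round-trips and hits re-verify", {
  sim <- small_sim(seed = 9, n_loci = 3)
  refs <- sim_refs(sim)
  cfg <- design_config()
  panel <- greedy_select(enumerate_candidates(refs, cfg), refs, cfg)
  fa <- tempfile(fileext = ".fasta")
  bed <- tempfile(fileext = ".bed")
  write_panel(panel, fa, bed)
  expect_identical(read_panel_fasta(fa), panel_sequences(panel))
  bd <- read.delim(bed, header = FALSE,
                   col.names = c("ref", "start", "end", "name", "score",
                                 "strand"))
  seqs <- panel_sequences(panel)
  for (i in seq_len(nrow(bd))) {
    win <- substring(refs[[bd$ref[i]]]$sequence, bd$start[i] + 1, bd$end[i])
    pat <- if (bd$strand[i] == "+") seqs[[bd$name[i]]]
           else oracle_revcomp(seqs[[bd$name[i]]])
    expect_identical(win, pat)
  }
  # empty panel -> empty but valid files
  empty_panel <- structure(list(probes = list()), class = "ProbePanel")
  fa0 <- tempfile(); bed0 <- tempfile()
  write_panel(empty_panel, fa0, bed0)
  expect_length(read_panel_fasta(fa0), 0)
})
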