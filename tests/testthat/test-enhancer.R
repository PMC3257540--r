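test_that("sliding identity handles perfect, absent and gapped conservation", {
  ident <- function(L) paste(rep("A", L), collapse = "")
  p1 <- alignment_pair(ident(150), ident(150))
  prof <- sliding_identity(p1, 100)
  expect_equal(prof$identity, rep(100, 51))
  expect_equal(prof$pos, 1:51)

  p2 <- alignment_pair(ident(120), paste(rep("-", 120), collapse = ""))
  expect_equal(sliding_identity(p2, 100)$identity, rep(0, 21))

  expect_error(sliding_identity(alignment_pair("ACGT", "ACGT"), 100),
               "longer")

  # insertions in the partner (reference gaps) are skipped entirely
  ref <- "AC-GTAC"     # 6 reference bases
  par <- "ACCGTAC"
  prof3 <- sliding_identity(alignment_pair(ref, par), 3)
  expect_equal(prof3$identity, rep(100, 4))
})

test_that("windowed identity equals brute-force counting on random alignments", {
  set.seed(8)
  for (i in 1:100) {
    L <- sample(40:80, 1)
    chars <- c("A", "C", "G", "T", "-", "N")
    ref <- paste(sample(chars, L, replace = TRUE,
                        prob = c(.22, .22, .22, .22, .06, .06)),
                 collapse = "")
    par <- paste(sample(chars, L, replace = TRUE,
                        prob = c(.22, .22, .22, .22, .06, .06)),
                 collapse = "")
    nref <- nchar(gsub("-", "", ref))
    w <- 10
    if (nref < w) next
    prof <- sliding_identity(alignment_pair(ref, par), w)
    expect_equal(prof$identity, oracle_window_identity(ref, par, w))
  }
})

test_that("conserved elements are the union of qualifying windows", {
  ident <- function(L) paste(rep("G", L), collapse = "")
  prof <- sliding_identity(alignment_pair(ident(250), ident(250)), 100)
  el <- call_conserved(prof)
  expect_equal(nrow(el), 1)
  expect_equal(c(el$start, el$end), c(1, 250))
  expect_equal(el$mean_identity, 100)

  # strictly-greater threshold: a profile at exactly 80 yields nothing
  fake <- structure(data.frame(pos = 1:50, identity = rep(80, 50)),
                    class = c("conservation_profile", "data.frame"),
                    window_bp = 100L, ref_length = 149L)
  expect_equal(nrow(call_conserved(fake, 80, 100)), 0)

  # deterministic, disjoint and sorted on a noisy profile
  set.seed(9)
  fake2 <- structure(data.frame(pos = 1:400,
                                identity = runif(400, 60, 100)),
                     class = c("conservation_profile", "data.frame"),
                     window_bp = 20L, ref_length = 419L)
  a <- call_conserved(fake2, 80, 20)
  b <- call_conserved(fake2, 80, 20)
  expect_identical(a, b)
  if (nrow(a) > 1) {
    expect_true(all(diff(a$start) > 0))
    expect_true(all(a$start[-1] > a$end[-nrow(a)] + 1))
  }
  expect_equal(a$width, a$end - a$start + 1)
})

test_that("planted conserved blocks are recovered across seeds", {
  for (seed in 1:20) {
    g <- generate_alignment(2000, 0.5,
                            planted_blocks = list(list(500, 150, 0.95)),
                            seed = seed)
    prof <- sliding_identity(g$pair, 100)
    el <- call_conserved(prof, 80, 100)
    expect_equal(nrow(el), 1)
    expect_lte(abs(el$start - 500), 100)
    expect_lte(abs(el$end - 649), 100)
  }
})

test_that("motif scanning matches exhaustive enumeration", {
  # the motif itself: a single forward hit at position 1
  hits <- motif_scan("TCACACCT", max_mismatch = 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$position, 1)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0)

  set.seed(10)
  for (i in 1:10) {
    seqc <- paste(sample(c("A", "C", "G", "T", "N"), 500, replace = TRUE,
                         prob = c(.24, .24, .24, .24, .04)),
                  collapse = "")
    got <- motif_scan(seqc, "TCACACCT", max_mismatch = 2)
    want <- oracle_motif_hits(seqc, "TCACACCT", 2)
    expect_equal(got[, c("position", "strand", "mismatches")], want,
                 ignore_attr = TRUE)
  }

  # a motif longer than the sequence yields no hits, not an error
  expect_equal(nrow(motif_scan("ACG", "TCACACCT")), 0)
  expect_error(motif_scan("AC-GT"), "ungapped")
})

test_that("motif hits are monotone in the mismatch allowance and strand-symmetric", {
  set.seed(11)
  seqc <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                collapse = "")
  counts <- vapply(0:3, function(k)
    nrow(motif_scan(seqc, max_mismatch = k)), numeric(1))
  expect_true(all(diff(counts) >= 0))

  fwd <- motif_scan(seqc, max_mismatch = 2)
  rc <- motif_scan(revcomp_chr(seqc), max_mismatch = 2)
  m <- 8L
  mirrored <- sort(600 - (fwd$position + m - 1) + 1)
  expect_equal(sort(rc$position), mirrored)
  # strands swap under reverse complementation
  expect_equal(sum(fwd$strand == "+"), sum(rc$strand == "-"))
})

test_that("upstream fragments use TSS-relative closed coordinates", {
  expect_equal(extract_upstream("AAACCC", 4, -3, -1), "AAA")
  expect_equal(nchar(extract_upstream("AAACCC", 4, -2, -2)), 1)
  expect_error(extract_upstream("AAACCC", 4, -3, 0), "negative")
  expect_error(extract_upstream("AAACCC", 4, -5, -1), "outside")
  # the enhancer-fragment coordinate convention: length = to - from + 1
  s <- paste(rep("A", 5000), collapse = "")
  expect_equal(nchar(extract_upstream(s, 4000, -3462, -3045)),
               3462 - 3045 + 1)
})

test_that("aligned FASTA round-trips and malformed input names the line", {
  g <- generate_alignment(200, 0.8, seed = 12)
  path <- file.path(withr::local_tempdir(), "pair.fa")
  write_alignment_fasta(g$pair, path)
  back <- read_alignment_fasta(path)
  expect_equal(back$reference, g$pair$reference)
  expect_equal(back$partner, g$pair$partner)

  bad <- file.path(withr::local_tempdir(), "bad.fa")
  writeLines(c("ACGT", ">a", "ACGT"), bad)
  expect_error(read_alignment_fasta(bad), "line 1")
  writeLines(c(">a", "ACGT", ">b", "ACGT", ">c", "AC"), bad)
  expect_error(read_alignment_fasta(bad), "found 3")
  writeLines(c(">a", "ACGTACGT", ">b", "ACG"), bad)
  expect_error(read_alignment_fasta(bad), "differ in aligned length")
})
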