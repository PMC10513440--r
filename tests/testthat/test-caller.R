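make_read <- function(ref, junction, flip = FALSE) {
  a5 <- rs_genomic(gene_rs(ref_gene(ref, "TRBD1"), "five_prime"))
  a3 <- rs_genomic(gene_rs(ref_gene(ref, "TRBD2"), "three_prime"))
  read <- paste0(ref$flank5, a5, junction, a3, ref$flank3)
  if (flip) ddloop:::revcomp(read) else read
}

test_that("junction extraction recovers constructed junctions on both strands", {
  ref <- ref_fixture()
  out <- extract_junctions(make_read(ref, "GGTAC"), ref)
  expect_identical(out$junction, "GGTAC")
  expect_identical(out$status, "called")
  expect_identical(out$strand, "fwd")
  expect_identical(out$mismatches, 0L)

  # reverse-strand read comes back in the forward convention
  rev <- extract_junctions(make_read(ref, "GGTAC", flip = TRUE), ref)
  expect_identical(rev$junction, "GGTAC")
  expect_identical(rev$strand, "rev")

  # empty junction (perfect signal joint on the chromosome)
  expect_identical(extract_junctions(make_read(ref, ""), ref)$junction, "")
})

test_that("anchor mismatch budget is honoured", {
  ref <- ref_fixture()
  read <- make_read(ref, "GGTAC")
  # flip one base inside the 5' anchor (it starts right after the 60 nt flank)
  pos <- 65L
  base <- substr(read, pos, pos)
  sub <- chartr("ACGT", "GTAC", base)
  mut <- paste0(substr(read, 1, pos - 1), sub, substring(read, pos + 1))
  hit <- extract_junctions(mut, ref, max_mismatch = 1)
  expect_identical(hit$junction, "GGTAC")
  expect_identical(hit$mismatches, 1L)
  expect_identical(extract_junctions(mut, ref, max_mismatch = 0)$status, "no_anchor")
})

test_that("reads without or with inverted anchors are structural no-calls", {
  ref <- ref_fixture()
  set.seed(5)
  noise <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  expect_identical(extract_junctions(noise, ref)$status, "no_anchor")

  a5 <- rs_genomic(gene_rs(ref_gene(ref, "TRBD1"), "five_prime"))
  a3 <- rs_genomic(gene_rs(ref_gene(ref, "TRBD2"), "three_prime"))
  inverted <- paste0(ref$flank5, a3, "GGTAC", a5, ref$flank3)
  expect_identical(extract_junctions(inverted, ref)$status, "inverted")
})

test_that("decomposition matches the worked examples", {
  ref <- ref_fixture()
  d1 <- ref_gene(ref, "TRBD1")$coding_seq
  d2 <- ref_gene(ref, "TRBD2", "*01")$coding_seq

  # untrimmed concatenation: everything is germline
  full <- decompose_junctions(paste0(d1, d2), ref)
  expect_equal(full$d1_match, nchar(d1))
  expect_equal(full$d2_match, nchar(d2))
  expect_identical(full$insert_seq, "")

  ex <- decompose_junctions("GGGACAGGTCTACTAGCGGGGGGG", ref)
  expect_equal(ex$d1_match, 8L)
  expect_identical(ex$insert_seq, "TCT")
  expect_equal(ex$d2_match, 13L)

  # perfect signal joint and pure insert
  expect_equal(
    unlist(decompose_junctions("", ref)[, c("d1_match", "d2_match")]),
    c(d1_match = 0L, d2_match = 0L)
  )
  pure <- decompose_junctions("TTTT", ref)
  expect_equal(pure$d1_match, 0L)
  expect_identical(pure$insert_seq, "TTTT")
  expect_equal(pure$d2_match, 0L)
})

test_that("greedy decomposition equals the brute-force maximizer on 1000 junctions", {
  ref <- ref_fixture()
  d1 <- ref_gene(ref, "TRBD1")$coding_seq
  d2s <- ref_gene(ref, "TRBD2", allele = NULL)
  d2_codings <- setNames(as.list(d2s$coding_seq), d2s$allele)

  set.seed(7)
  # a mix of pure-random junctions and realistic trimmed-germline junctions
  rand <- random_junctions(500)
  ev <- sample_dd_events(500, sim_params(), ref)
  junctions <- c(rand, ev$chrom_junction)

  got <- decompose_junctions(junctions, ref)
  for (i in seq_along(junctions)) {
    want <- oracle_decompose(junctions[i], d1, d2_codings)
    expect_equal(got$d1_match[i], want$d1_match, info = junctions[i])
    expect_identical(got$insert_seq[i], want$insert_seq, info = junctions[i])
    expect_equal(got$d2_match[i], want$d2_match, info = junctions[i])
    expect_identical(got$d2_allele[i], want$d2_allele, info = junctions[i])
  }
  # conservation holds on every call
  expect_equal(
    got$d1_match + nchar(got$insert_seq) + got$d2_match,
    nchar(junctions)
  )
})

test_that("decomposition recovers simulated truth up to germline absorption", {
  ref <- ref_fixture()
  d1 <- ref_gene(ref, "TRBD1")$coding_seq
  d2s <- ref_gene(ref, "TRBD2", allele = NULL)
  len1 <- nchar(d1)

  set.seed(8)
  ev <- sample_dd_events(800, sim_params(), ref, pathway = "coding_joint")
  dec <- decompose_junctions(ev$chrom_junction, ref)
  # germline-compatible insert bases are absorbed, so the called match is an
  # upper bound on the true retained length
  expect_true(all(dec$d1_match >= len1 - ev$d1_trim3))

  # with insert edges constrained so that neither D2 allele can absorb them,
  # recovery is exact
  d2_cod <- d2s$coding_seq[match(ev$d2_allele, d2s$allele)]
  keep <- nchar(ev$insert_seq) >= 2 & ev$d1_trim3 >= 1 & ev$d2_trim5 >= 1
  ev2 <- ev[keep, ]
  d2_cod <- d2_cod[keep]
  common_suffix_len <- function(a, b) {
    n <- 0L
    la <- nchar(a)
    lb <- nchar(b)
    while (n < min(la, lb) &&
      substr(a, la - n, la - n) == substr(b, lb - n, lb - n)) {
      n <- n + 1L
    }
    n
  }
  ret1 <- len1 - ev2$d1_trim3
  left_next <- substring(d1, ret1 + 1, ret1 + 1) # base absorption would need
  ins2 <- character(nrow(ev2))
  for (i in seq_len(nrow(ev2))) {
    d2part <- substring(d2_cod[i], ev2$d2_trim5[i] + 1)
    # the base that would extend each allele's suffix match by one
    ext <- vapply(d2s$coding_seq, function(cod) {
      s <- common_suffix_len(d2part, cod)
      if (s >= nchar(cod)) "" else substr(cod, nchar(cod) - s, nchar(cod) - s)
    }, character(1))
    first <- setdiff(c("A", "C", "G", "T"), left_next[i])[1]
    last <- setdiff(c("A", "C", "G", "T"), ext)[1]
    ins <- ev2$insert_seq[i]
    ins2[i] <- paste0(first, substr(ins, 2, nchar(ins) - 1), last)
  }
  junc2 <- paste0(
    substring(d1, 1, ret1), ins2,
    substring(d2_cod, ev2$d2_trim5 + 1)
  )
  dec2 <- decompose_junctions(junc2, ref)
  expect_equal(dec2$d1_match, ret1)
  expect_equal(dec2$d2_match, nchar(d2_cod) - ev2$d2_trim5)
  expect_identical(dec2$insert_seq, unname(ins2))
})

test_that("classification applies the conservative two-sided threshold", {
  expect_identical(as.character(classify_calls(12, 16, 7)), "long")
  expect_identical(as.character(classify_calls(0, 0, 7)), "short")
  expect_identical(as.character(classify_calls(9, 3, 7)), "ambiguous")
  # lenient mode
  expect_identical(as.character(classify_calls(9, 3, 3)), "long")
  expect_error(classify_calls(1, 1, 0), class = "ddloop_parameter_error")
})

test_that("the caller has a zero no-call rate on error-free simulated reads", {
  ref <- ref_fixture()
  p <- sim_params(n_events = 400L, seed = 12L, error_rate = 0, both_strands = TRUE)
  fq <- tempfile(fileext = ".fastq")
  truth <- simulate_dd_reads(p, ref, fq)
  calls <- call_junctions(fq, ref)
  expect_identical(unique(calls$status), "called")
  idx <- as.integer(sub("^dd\\|event=([0-9]+)\\|.*$", "\\1", calls$read_id))
  expect_identical(calls$junction, truth$chrom_junction[idx])
  expect_true(all(c("fwd", "rev") %in% calls$strand))
  # conservation on every call
  expect_equal(
    calls$d1_match + nchar(calls$insert_seq) + calls$d2_match,
    nchar(calls$junction)
  )
})
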