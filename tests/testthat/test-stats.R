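fake_calls <- function(junctions, ref) {
  dec <- decompose_junctions(junctions, ref)
  tibble::tibble(
    read_id = sprintf("r%d", seq_along(junctions)),
    junction = dec$junction,
    d1_match = dec$d1_match,
    insert_seq = dec$insert_seq,
    d2_match = dec$d2_match,
    d2_allele = dec$d2_allele,
    klass = classify_calls(dec$d1_match, dec$d2_match),
    status = "called"
  )
}

test_that("clonotype aggregation merges junctions and normalizes frequencies", {
  ref <- ref_fixture()
  calls <- fake_calls(c("GGTAC", "GGTAC", "GGTAC", "TTTT"), ref)
  tab <- aggregate_clonotypes(calls, sample_id = "A")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$count[tab$junction == "GGTAC"], 3L)
  expect_equal(sum(tab$freq), 1, tolerance = 1e-9)
  expect_identical(unique(tab$sample_id), "A")

  # empty input: empty table, not an error
  empty <- aggregate_clonotypes(fake_calls(character(), ref))
  expect_equal(nrow(empty), 0L)

  # corrupted input with two decompositions for one junction is refused
  bad <- calls
  bad$d1_match[1] <- bad$d1_match[1] + 1L
  expect_error(aggregate_clonotypes(bad), class = "ddloop_consistency_error")
})

test_that("diversity normalization converts DNA mass to cells", {
  expect_equal(diversity_per_cells(n_unique = 1000, input_dna_ng = 600), 1000)
  expect_equal(diversity_per_cells(n_unique = 500, input_dna_ng = 300), 1000)
  expect_equal(diversity_per_cells(n_unique = 0, input_dna_ng = 600), 0)
  expect_error(diversity_per_cells(n_unique = 10, input_dna_ng = 0),
    class = "ddloop_parameter_error"
  )
})

test_that("indel summaries follow the decomposition arithmetic", {
  ref <- ref_fixture()
  # one long clonotype (d1 = 8, insert TCT, d2 = 13) and one perfect signal joint
  tab <- aggregate_clonotypes(
    fake_calls(c("GGGACAGGTCTACTAGCGGGGGGG", ""), ref),
    sample_id = "A"
  )
  st <- indel_stats(tab, ref)
  long_del <- st[st$klass == "long" & st$metric == "deletions", ]
  expect_equal(long_del$mean, (12 - 8) + (16 - 13))
  long_ins <- st[st$klass == "long" & st$metric == "insert_len", ]
  expect_equal(long_ins$mean, 3)
  short_ins <- st[st$klass == "short" & st$metric == "insert_len", ]
  expect_equal(short_ins$mean, 0)
  # deletions are undefined for the short class: no row at all
  expect_equal(nrow(st[st$klass == "short" & st$metric == "deletions", ]), 0L)
  # absent classes simply yield no rows, never an error
  expect_false("ambiguous" %in% st$klass)
})

test_that("Mann-Whitney exact mode matches the worked enumerations", {
  r1 <- mann_whitney_u(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(r1$u, 0)
  expect_equal(r1$p_value, 1 / 3, tolerance = 1e-9)

  r2 <- mann_whitney_u(c(1, 3), c(2, 4), mode = "exact")
  expect_equal(r2$u, 1)
  expect_equal(r2$p_value, 2 / 3, tolerance = 1e-9)

  # identical samples: no evidence against the null
  r3 <- mann_whitney_u(c(5, 6, 7), c(5, 6, 7), mode = "exact")
  expect_gte(r3$p_value, 0.99)

  expect_error(mann_whitney_u(numeric(), 1:3), class = "ddloop_parameter_error")
  expect_error(mann_whitney_u(1:15, 1:15, mode = "exact"),
    class = "ddloop_parameter_error"
  )
})

test_that("exact mode equals brute-force enumeration for all n1 + n2 <= 8", {
  set.seed(9)
  for (n1 in 1:4) {
    for (n2 in 1:4) {
      # include ties by drawing from a small integer support
      x <- sample(1:4, n1, replace = TRUE)
      y <- sample(1:4, n2, replace = TRUE)
      want <- oracle_mwu(x, y)
      got <- mann_whitney_u(x, y, mode = "exact")
      expect_equal(got$u, want$u, info = sprintf("n1=%d n2=%d", n1, n2))
      expect_equal(got$p_value, want$p, tolerance = 1e-9,
        info = sprintf("n1=%d n2=%d", n1, n2)
      )
    }
  }
})

test_that("the normal approximation tracks the reference implementation", {
  set.seed(10)
  x <- rpois(60, 6)
  y <- rpois(80, 7)
  got <- mann_whitney_u(x, y, mode = "normal_approx")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$u, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("publicity counts clonotypes shared by two or more samples", {
  ref <- ref_fixture()
  mk <- function(junctions, id) aggregate_clonotypes(fake_calls(junctions, ref), id)
  a <- mk(c("GGTAC", "TTTT"), "A")
  b <- mk(c("TTTT", "ACACA"), "B")
  res <- publicity(list(a, b))
  expect_equal(glance(res)$n_unique_pooled, 3L)
  expect_equal(glance(res)$n_public, 1L)
  expect_equal(glance(res)$public_fraction, 1 / 3)

  # identical samples share everything; disjoint samples share nothing
  expect_equal(glance(publicity(list(a, mk(c("GGTAC", "TTTT"), "B"))))$public_fraction, 1)
  expect_equal(glance(publicity(list(a, mk("ACACA", "B"))))$public_fraction, 0)
  expect_error(publicity(list(a)), class = "ddloop_parameter_error")

  # invariant to sample order and to per-sample count scaling
  res_rev <- publicity(list(b, a))
  expect_equal(glance(res_rev)$public_fraction, glance(res)$public_fraction)
  a_scaled <- mk(rep(c("GGTAC", "TTTT"), c(7, 13)), "A")
  expect_equal(
    glance(publicity(list(a_scaled, b)))$public_fraction,
    glance(res)$public_fraction
  )

  # per-class resolution
  byc <- publicity(list(a, b), by_class = TRUE)
  expect_true("klass" %in% names(glance(byc)))
})

test_that("position frequency matrices follow the padding rules", {
  pfm <- position_frequency_matrix(c("AC", "AG"))
  expect_equal(unname(pfm["A", 1]), 1)
  expect_equal(unname(pfm["C", 2]), 0.5)
  expect_equal(unname(pfm["G", 2]), 0.5)

  one <- position_frequency_matrix("ACGT")
  expect_equal(diag(one[c("A", "C", "G", "T"), ]), rep(1, 4), ignore_attr = TRUE)

  ragged <- position_frequency_matrix(c("A", "ACG"))
  expect_equal(ncol(ragged), 3L)
  expect_equal(attr(ragged, "support"), c(2L, 1L, 1L))
  expect_equal(unname(ragged["C", 2]), 1)

  right <- position_frequency_matrix(c("A", "ACG"), align = "right")
  expect_equal(attr(right, "support"), c(1L, 1L, 2L))

  # every column of any PFM sums to 1
  set.seed(11)
  rand <- random_junctions(200, max_len = 15)
  rand <- rand[nzchar(rand)]
  p <- position_frequency_matrix(rand)
  expect_equal(colSums(p), rep(1, ncol(p)), tolerance = 1e-9, ignore_attr = TRUE)
})
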