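d2_set <- function(ref) build_motif_set(ref_gene(ref, "TRBD2", allele = NULL), 7)
d1_set <- function(ref) build_motif_set(ref_gene(ref, "TRBD1", allele = NULL), 7)

test_that("motif flagging is a per-set presence test with a conjunction rule", {
  ref <- ref_fixture()
  tab <- tibble::tibble(junction = c(
    "AAATTGACTAGCTTAAA", # D2 motif present
    "AAAATTTTCCCCGGAA", # nothing
    "ggactagTTTT" # lower case D2 motif
  ))
  det <- detect_motif_fraction(tab, d2_set(ref))
  expect_identical(tidy(det)$flagged, c(TRUE, FALSE, TRUE))
  expect_equal(glance(det)$fraction, 2 / 3)

  # rows with no motifs anywhere: fraction 0
  none <- detect_motif_fraction(tibble::tibble(junction = rep("ACACACAC", 5)), d2_set(ref))
  expect_equal(glance(none)$fraction, 0)

  # conjunction: a D2 motif without a D1 motif must not flag in V-D-D-J mode
  vtab <- tibble::tibble(cdr3_nt = c(
    "TGTGCCGGACTAGCTTT", # D2 only
    "TGTGGACAGGGACTAGCTTT" # D1 + D2
  ))
  both <- detect_motif_fraction(vtab, list(d1_set(ref), d2_set(ref)))
  expect_identical(tidy(both)$flagged, c(FALSE, TRUE))

  expect_error(
    detect_motif_fraction(tab, structure(list(k = 7, motifs = character(), source_gene = "X"),
      class = "motif_set"
    )),
    class = "ddloop_parameter_error"
  )
})

test_that("flagging is invariant to case and row order", {
  ref <- ref_fixture()
  set.seed(12)
  tab <- simulate_junction_table("d1_j2", 300, 0.5, sim_params(), ref, seed = 41)
  det1 <- detect_motif_fraction(tab, d2_set(ref))
  lower <- tab
  lower$junction <- tolower(lower$junction)
  det2 <- detect_motif_fraction(lower, d2_set(ref))
  expect_identical(tidy(det1)$flagged, tidy(det2)$flagged)
  perm <- sample(nrow(tab))
  det3 <- detect_motif_fraction(tab[perm, ], d2_set(ref))
  expect_identical(tidy(det3)$flagged, tidy(det1)$flagged[perm])
  expect_equal(glance(det3)$fraction, glance(det1)$fraction)
})

test_that("detector sensitivity and false-positive rate are calibrated", {
  ref <- ref_fixture()
  p <- sim_params()

  # sensitivity on planted D2 segments
  tab <- simulate_junction_table("d1_j2", 8000, 0.5, p, ref, seed = 42)
  det <- detect_motif_fraction(tab, d2_set(ref))
  sens <- mean(tidy(det)$flagged[tab$spiked])
  expect_gte(sens, 0.99)

  # false positives on pure-random strings match the analytic rate within
  # 3 binomial sigmas
  set.seed(43)
  w <- 30L
  n <- 20000L
  rand <- vapply(
    seq_len(n),
    function(i) paste(sample(c("A", "C", "G", "T"), w, TRUE), collapse = ""),
    character(1)
  )
  detr <- detect_motif_fraction(tibble::tibble(junction = rand), d2_set(ref))
  p_exp <- exact_motif_hit_prob(TRBD2_MOTIFS_7, w)
  sigma <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(glance(detr)$fraction - p_exp), 3 * sigma)
  # the quick independence formula is an upper bound on the exact value
  expect_lte(p_exp, analytic_motif_fp(w, 7, 7))

  # unplanted simulated rows: germline context contributes no hits, so the
  # full-window analytic rate is an upper bound for the observed rate
  fp <- mean(tidy(det)$flagged[!tab$spiked])
  w_max <- max(nchar(tab$junction[!tab$spiked]))
  bound <- analytic_motif_fp(w_max, 7, 7)
  expect_lte(fp, bound + 3 * sqrt(bound * (1 - bound) / sum(!tab$spiked)))

  # v_d_j2 mode with the D1+D2 conjunction
  vtab <- simulate_junction_table("v_d_j2", 4000, 0.3, p, ref, seed = 44)
  detv <- detect_motif_fraction(vtab, list(d1_set(ref), d2_set(ref)))
  expect_gte(mean(tidy(detv)$flagged[vtab$spiked]), 0.99)
  expect_lte(mean(tidy(detv)$flagged[!vtab$spiked]), 0.01)
})

test_that("window masking excludes terminal codons from the search", {
  ref <- ref_fixture()
  tab <- tibble::tibble(cdr3_nt = paste0("GGACTAGCA", "TTTTTTTTTT", "AGACTAGCG"))
  hit <- detect_motif_fraction(tab, d2_set(ref))
  expect_true(tidy(hit)$flagged)
  masked <- detect_motif_fraction(tab, d2_set(ref), window_trim = c(9, 9))
  expect_false(tidy(masked)$flagged)
})

test_that("J usage is counted per gene and per cluster", {
  tab <- tibble::tibble(j_gene = c(rep("TRBJ2-1", 3), "TRBJ1-1"))
  by_gene <- j_usage(tab)
  expect_equal(sum(by_gene$freq), 1)
  expect_equal(by_gene$freq[by_gene$j_gene == "TRBJ2-1"], 0.75)
  by_cluster <- j_usage(tab, level = "cluster")
  expect_equal(by_cluster$freq[by_cluster$cluster == "J2"], 0.75)
  expect_equal(by_cluster$freq[by_cluster$cluster == "J1"], 0.25)
  expect_equal(j_usage(tibble::tibble(j_gene = "TRBJ2-7"))$freq, 1)
  expect_equal(nrow(j_usage(tibble::tibble(j_gene = character()))), 0L)
})

test_that("signal-joint calling recovers planted circle inserts exactly", {
  ref <- ref_fixture()
  primers <- ref$primers[tolower(ref$primers$species) == "human", ]
  rs_d2_5 <- rs_genomic(gene_rs(ref_gene(ref, "TRBD2"), "five_prime"))
  rs_d1_3 <- rs_genomic(gene_rs(ref_gene(ref, "TRBD1"), "three_prime"))
  mk_circle <- function(insert) {
    paste0(primers$dir_seq, rs_d2_5, insert, rs_d1_3, ddloop:::revcomp(primers$rev_seq))
  }

  perfect <- call_signal_joints(mk_circle(""), ref)
  expect_identical(perfect$status, "called")
  expect_true(perfect$perfect)
  expect_identical(perfect$insert_seq, "")

  gg <- call_signal_joints(mk_circle("GG"), ref)
  expect_identical(gg$insert_seq, "GG")
  expect_false(gg$perfect)

  # reverse strand normalization
  revd <- call_signal_joints(ddloop:::revcomp(mk_circle("GG")), ref)
  expect_identical(revd$insert_seq, "GG")
  expect_identical(revd$strand, "rev")

  set.seed(13)
  noise <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  expect_identical(call_signal_joints(noise, ref)$status, "no_anchor")

  # end to end on the simulator's excision-circle output at zero error rate
  p <- sim_params(n_events = 300L, seed = 14L, error_rate = 0)
  fq <- tempfile(fileext = ".fastq")
  truth <- simulate_signal_joint_reads(p, ref, fq)
  calls <- call_signal_joints(fq, ref)
  expect_identical(unique(calls$status), "called")
  expect_identical(calls$insert_seq, truth$insert_seq)
  expect_identical(calls$perfect, truth$perfect)
  smry <- summarize_signal_joints(calls)
  expect_identical(smry$consensus_insert, "") # the precise joint dominates
  expect_equal(smry$perfect_fraction, mean(truth$perfect))
})
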