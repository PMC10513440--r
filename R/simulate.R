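#' Simulation parameters for D-D recombination
#'
#' The defaults describe the standard study conditions used throughout the
#' package: an even split between the two legal D1-D2 synapses, memoryless
#' (geometric) exonucleolytic trimming of coding ends with mean 5 nt per end,
#' Poisson(6) nontemplated inserts at coding joints, and a zero-inflated
#' insert law at signal joints (38% precise joints, otherwise 1 + geometric
#' with non-zero mean 9.677 nt, for a marginal mean of 6 nt).
#'
#' @param p_signal Probability that an event resolves through the
#'   signal-joint synapse (5'D1-RS with 3'D2-RS), leaving the D regions on
#'   the excision circle. The complementary coding-joint synapse (3'D1-RS
#'   with 5'D2-RS) keeps the D1-D2 coding joint on the chromosome.
#' @param trim_mean Mean of the geometric per-end trimming applied to the D1
#'   3' end and D2 5' end of coding joints; draws are capped (not resampled)
#'   at the coding length.
#' @param coding_insert [dist_spec()] for nontemplated insert length at
#'   coding joints.
#' @param signal_insert [dist_spec()] for insert length at signal joints.
#' @param insert_base_weights Base composition of inserts over A, C, G, T.
#' @param n_events Number of recombination events to simulate.
#' @param clone_size_alpha Exponent of the discrete power law (truncated at
#'   `n_events`) used for clone sizes. The default `NA` disables clonal
#'   expansion (every event is emitted once): junction-length and
#'   decomposition analyses describe recombination biology, and read
#'   multiplicity would confound them with clonal expansion. Set an
#'   exponent (e.g. 2.5) for rank-abundance and publicity work, where the
#'   skew itself is the object of study.
#' @param error_rate Per-base substitution error rate applied to emitted
#'   reads; must lie in `[0, 0.1]`.
#' @param seed Integer seed; mandatory for reproducible read simulation.
#' @param both_strands Emit half of the reads reverse-complemented.
#' @return A `sim_params` object.
#' @export
sim_params <- function(p_signal = 0.5,
                       trim_mean = 5,
                       coding_insert = dist_spec("poisson", mean = 6),
                       signal_insert = dist_spec("zi_geometric",
                         zero_prob = 0.38, mean_nonzero = 9.677
                       ),
                       insert_base_weights = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       n_events = 20000L,
                       clone_size_alpha = NA,
                       error_rate = 0,
                       seed = NULL,
                       both_strands = FALSE) {
  if (p_signal < 0 || p_signal > 1) {
    dd_abort("p_signal must lie in [0, 1]", "ddloop_parameter_error")
  }
  if (trim_mean < 0) dd_abort("trim_mean must be >= 0", "ddloop_parameter_error")
  if (error_rate < 0 || error_rate > 0.1) {
    dd_abort("error_rate must lie in [0, 0.1]", "ddloop_parameter_error")
  }
  w <- insert_base_weights / sum(insert_base_weights)
  if (length(w) != 4 || any(w < 0)) {
    dd_abort("insert_base_weights must be 4 non-negative weights", "ddloop_parameter_error")
  }
  stopifnot(inherits(coding_insert, "dd_dist"), inherits(signal_insert, "dd_dist"))
  structure(
    list(
      p_signal = p_signal, trim_mean = trim_mean,
      coding_insert = coding_insert, signal_insert = signal_insert,
      insert_base_weights = w, n_events = as.integer(n_events),
      clone_size_alpha = clone_size_alpha, error_rate = error_rate,
      seed = seed, both_strands = isTRUE(both_strands)
    ),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<sim_params: n_events %d, p_signal %.2f, trim_mean %.1f,\n",
      "  coding insert mean %.2f, signal insert mean %.2f,\n",
      "  clone alpha %s, error rate %g, seed %s>\n"
    ),
    x$n_events, x$p_signal, x$trim_mean,
    dist_mean(x$coding_insert), dist_mean(x$signal_insert),
    format(x$clone_size_alpha), x$error_rate,
    if (is.null(x$seed)) "unset" else x$seed
  ))
  invisible(x)
}

## geometric on {0,1,...} with the given mean, capped at cap
rtrim <- function(n, mean, cap) {
  if (mean == 0) {
    return(rep(0L, n))
  }
  pmin(rgeom(n, 1 / (mean + 1)), cap)
}

#' Sample D-D recombination events
#'
#' Draws recombination events between TRBD1 and TRBD2 under the two-synapse
#' model. A coding-joint event trims the D1 3' end and the D2 5' end, adds a
#' nontemplated insert between the remnants, and leaves that coding joint on
#' the chromosome (the reciprocal RS-RS signal joint departs on the excision
#' circle). A signal-joint event fuses the 5'D1-RS to the 3'D2-RS on the
#' chromosome, with an optional insert between the heptamers, and excises
#' the intact D1-D2 coding material onto the circle. Both synapses are
#' checked against the 12/23 rule before use.
#'
#' @param n Number of events.
#' @param params A [sim_params()] object.
#' @param ref A `dd_reference`.
#' @param pathway Force all events down one pathway (`"coding_joint"` or
#'   `"signal_joint"`); default samples by `params$p_signal`.
#' @param seed Optional seed (defaults to no reseeding so callers control
#'   the stream).
#' @return A tibble with one row per event: `event_id`, `pathway`,
#'   `d2_allele`, `d1_trim3`, `d2_trim5`, `insert_seq`, `chrom_junction`,
#'   `circle_junction`.
#' @export
sample_dd_events <- function(n, params = sim_params(), ref = dd_example_reference(),
                             pathway = NULL, seed = NULL) {
  set_seed_if(seed)
  d1 <- ref_gene(ref, "TRBD1")
  d2s <- ref_gene(ref, "TRBD2", allele = NULL)

  ## both legal synapses must satisfy the 12/23 rule
  check_synapse(gene_rs(d1, "three_prime"), gene_rs(d2s[1, ], "five_prime"))
  check_synapse(gene_rs(d1, "five_prime"), gene_rs(d2s[1, ], "three_prime"))

  if (is.null(pathway)) {
    pw <- ifelse(runif(n) < params$p_signal, "signal_joint", "coding_joint")
  } else {
    pw <- rep(match.arg(pathway, c("coding_joint", "signal_joint")), n)
  }
  allele_idx <- sample.int(nrow(d2s), n, replace = TRUE)
  d2_allele <- d2s$allele[allele_idx]
  d2_coding <- d2s$coding_seq[allele_idx]
  len1 <- nchar(d1$coding_seq)
  len2 <- nchar(d2_coding)

  is_cj <- pw == "coding_joint"
  d1_trim3 <- integer(n)
  d2_trim5 <- integer(n)
  d1_trim3[is_cj] <- rtrim(sum(is_cj), params$trim_mean, len1)
  d2_trim5[is_cj] <- rtrim(sum(is_cj), params$trim_mean, len2[is_cj])

  ins_len <- integer(n)
  ins_len[is_cj] <- dist_sample(params$coding_insert, sum(is_cj))
  ins_len[!is_cj] <- dist_sample(params$signal_insert, sum(!is_cj))
  insert_seq <- random_dna(ins_len, params$insert_base_weights)

  d1_part <- substr(rep(d1$coding_seq, n), 1L, len1 - d1_trim3)
  d2_part <- substring(d2_coding, d2_trim5 + 1L)

  chrom <- ifelse(is_cj, paste0(d1_part, insert_seq, d2_part), insert_seq)
  circle <- ifelse(is_cj, "", paste0(d1$coding_seq, d2_coding))

  tibble(
    event_id = seq_len(n),
    pathway = pw,
    d2_allele = d2_allele,
    d1_trim3 = d1_trim3,
    d2_trim5 = d2_trim5,
    insert_seq = insert_seq,
    chrom_junction = chrom,
    circle_junction = circle
  )
}

## clone sizes from a discrete power law P(k) ~ k^-alpha, k = 1..kmax
rclone_sizes <- function(n, alpha, kmax) {
  if (is.null(alpha) || is.na(alpha)) {
    return(rep(1L, n))
  }
  kmax <- max(1L, as.integer(kmax))
  k <- seq_len(kmax)
  sample(k, n, replace = TRUE, prob = k^(-alpha))
}

## substitution errors: each base flips to a different base with prob rate
add_substitutions <- function(seqs, rate) {
  if (rate <= 0) {
    return(seqs)
  }
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (!length(hit)) {
      return(s)
    }
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

write_fastq <- function(seqs, ids, path) {
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  quals <- Biostrings::BStringSet(strrep("?", nchar(seqs))) # constant Q30
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Simulate the chromosomal D-D amplicon library
#'
#' Renders each recombination event as the amplicon captured by primers in
#' the genomic flanks: `flank5 + 5'D1-RS + junction + 3'D2-RS + flank3`,
#' where `junction` is the chromosomal inter-RS sequence of the event. Read
#' multiplicities follow a truncated discrete power law over clone sizes,
#' substitution errors are applied at `params$error_rate`, and reads are
#' written as Phred+33 FASTQ (constant Q30). With the same seed the output
#' file is byte-identical across runs.
#'
#' @param params [sim_params()]; `params$seed` must be set.
#' @param ref A `dd_reference`.
#' @param fastq_out Output FASTQ path.
#' @param sample_id Sample label attached to the truth records.
#' @return Invisibly, the truth tibble: the event table of
#'   [sample_dd_events()] plus `clone_count` and `sample_id`.
#' @export
simulate_dd_reads <- function(params, ref = dd_example_reference(),
                              fastq_out, sample_id = "sim") {
  if (is.null(params$seed)) {
    dd_abort("params$seed must be set for read simulation", "ddloop_parameter_error")
  }
  set_seed_if(params$seed)
  events <- sample_dd_events(params$n_events, params, ref)
  events$clone_count <- rclone_sizes(nrow(events), params$clone_size_alpha, params$n_events)
  events$sample_id <- sample_id

  a5 <- rs_genomic(gene_rs(ref_gene(ref, "TRBD1"), "five_prime"))
  a3 <- rs_genomic(gene_rs(ref_gene(ref, "TRBD2"), "three_prime"))
  amplicon <- paste0(ref$flank5, a5, events$chrom_junction, a3, ref$flank3)

  idx <- rep.int(seq_len(nrow(events)), events$clone_count)
  reads <- amplicon[idx]
  copy <- sequence(events$clone_count)
  ids <- sprintf("dd|event=%d|copy=%d", events$event_id[idx], copy)
  if (params$both_strands) {
    flip <- seq_along(reads) %% 2L == 0L
    reads[flip] <- revcomp(reads[flip])
  }
  reads <- add_substitutions(reads, params$error_rate)
  write_fastq(reads, ids, fastq_out)
  invisible(events)
}

#' Simulate the excision-circle signal-joint amplicon
#'
#' Coding-joint events place a 5'D2-RS - 3'D1-RS signal joint on the
#' excision circle; the bundled primer pair (direct primer upstream of the
#' 5'D2-RS, reverse primer downstream of the 3'D1-RS) amplifies across that
#' joint. Each read is rendered as
#' `dir_primer + 5'D2-RS + insert + 3'D1-RS + revcomp(rev_primer)`, the
#' insert drawn from the signal-joint insert law (`params$signal_insert`),
#' so most joints are precise and the remainder carry a few nontemplated
#' nucleotides.
#'
#' @inheritParams simulate_dd_reads
#' @param n Number of circle reads; defaults to `params$n_events`.
#' @return Invisibly, a truth tibble (`read_id`, `insert_seq`, `perfect`).
#' @export
simulate_signal_joint_reads <- function(params, ref = dd_example_reference(),
                                        fastq_out, n = params$n_events) {
  if (is.null(params$seed)) {
    dd_abort("params$seed must be set for read simulation", "ddloop_parameter_error")
  }
  set_seed_if(params$seed)
  primers <- dplyr::filter(ref$primers, tolower(.data$species) == "human")
  if (nrow(primers) == 0) {
    dd_abort("reference carries no human primer pair", "ddloop_validation_error")
  }
  d1 <- ref_gene(ref, "TRBD1")
  d2 <- ref_gene(ref, "TRBD2")
  check_synapse(gene_rs(d2, "five_prime"), gene_rs(d1, "three_prime"))
  rs_d2_5 <- rs_genomic(gene_rs(d2, "five_prime"))
  rs_d1_3 <- rs_genomic(gene_rs(d1, "three_prime"))

  ins_len <- dist_sample(params$signal_insert, n)
  inserts <- random_dna(ins_len, params$insert_base_weights)
  reads <- paste0(primers$dir_seq[1], rs_d2_5, inserts, rs_d1_3, revcomp(primers$rev_seq[1]))
  reads <- add_substitutions(reads, params$error_rate)
  ids <- sprintf("sj|event=%d", seq_len(n))
  write_fastq(reads, ids, fastq_out)
  invisible(tibble(read_id = ids, insert_seq = inserts, perfect = ins_len == 0L))
}

## contiguous substring of a D coding region guaranteed to span at least one
## window from the gene's conservative motif set (so planted rows are
## detectable by construction)
plant_d_segment <- function(n, coding, motifs, k = 7L) {
  if (n == 0) {
    return(character())
  }
  len <- nchar(coding)
  starts0 <- unlist(lapply(motifs, function(m) {
    hits <- gregexpr(m, coding, fixed = TRUE)[[1]]
    hits[hits > 0] - 1L
  }))
  if (!length(starts0)) {
    dd_abort("no motif of the set occurs in the coding region", "ddloop_parameter_error")
  }
  m <- sample(rep(starts0, 2L), n, replace = TRUE) # motif window start (0-based)
  lo <- vapply(m, function(s) sample.int(s + 1L, 1L) - 1L, integer(1)) # 0..m
  hi <- vapply(m, function(s) {
    if (s + k - 1L >= len - 1L) len - 1L else sample(seq(s + k - 1L, len - 1L), 1L)
  }, integer(1))
  substring(rep(coding, n), lo + 1L, hi + 1L)
}

has_inframe_stop <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s)
    if (n < 3) {
      return(FALSE)
    }
    codons <- substring(s, seq(1, n - 2, by = 3), seq(3, n, by = 3))
    any(codons %in% c("TAA", "TAG", "TGA"))
  }, logical(1), USE.NAMES = FALSE)
}

#' Simulate junction/CDR3 tables with planted D motifs
#'
#' Generates partial D1-J2 junction tables or productive CDR3-like V-D-J2
#' tables in which a controlled fraction of rows carry a planted TRBD2 (and,
#' for `v_d_j2`, TRBD1) remnant, for testing the conservative k-mer
#' detectors against known truth. Planted segments are contiguous substrings
#' of the coding region drawn to span at least one conservative motif
#' window; remnants confined to the low-complexity 3' tail would be real but
#' undetectable by design, and are a biological miss rate rather than a
#' detector property.
#'
#' @param kind `"d1_j2"` (junction = trimmed D1 + insert(s) + J2-proximal
#'   context) or `"v_d_j2"` (in-frame, stop-free CDR3-like strings).
#' @param n Number of rows.
#' @param spike_fraction Probability that a row carries the planted
#'   segment(s).
#' @param params [sim_params()] (insert laws, trimming, clone sizes).
#' @param ref A `dd_reference`.
#' @param seed Optional seed.
#' @return A tibble with `junction` (or `cdr3_nt`), `count`, `j_gene` and the
#'   truth flag `spiked`.
#' @export
simulate_junction_table <- function(kind = c("d1_j2", "v_d_j2"), n,
                                    spike_fraction = 0.2,
                                    params = sim_params(),
                                    ref = dd_example_reference(),
                                    seed = params$seed) {
  kind <- match.arg(kind)
  if (spike_fraction < 0 || spike_fraction > 1) {
    dd_abort("spike_fraction must lie in [0, 1]", "ddloop_parameter_error")
  }
  set_seed_if(seed)
  d1 <- ref_gene(ref, "TRBD1")
  d2s <- ref_gene(ref, "TRBD2", allele = NULL)
  j2 <- filter(ref$genes, grepl("^TRBJ2", .data$name))
  if (nrow(j2) == 0) dd_abort("reference carries no TRBJ2 genes", "ddloop_validation_error")

  spiked <- runif(n) < spike_fraction
  len1 <- nchar(d1$coding_seq)
  jpick <- sample.int(nrow(j2), n, replace = TRUE)

  if (kind == "d1_j2") {
    t1 <- rtrim(n, params$trim_mean, len1)
    d1_part <- substr(rep(d1$coding_seq, n), 1L, len1 - t1)
    jtrim <- rtrim(n, params$trim_mean, 12L)
    j_part <- substring(j2$coding_seq[jpick], jtrim + 1L)
    j_part <- substr(j_part, 1L, 18L) # J2-proximal context only
    ins1 <- random_dna(dist_sample(params$coding_insert, n), params$insert_base_weights)
    d2_motifs <- build_motif_set(d2s, 7L)$motifs
    seg <- character(n)
    seg[spiked] <- plant_d_segment(sum(spiked), d2s$coding_seq[1], d2_motifs)
    ins2 <- rep("", n)
    ins2[spiked] <- random_dna(
      dist_sample(params$coding_insert, sum(spiked)),
      params$insert_base_weights
    )
    junction <- ifelse(spiked,
      paste0(d1_part, ins1, seg, ins2, j_part),
      paste0(d1_part, ins1, j_part)
    )
    out <- tibble(
      junction = junction,
      count = rclone_sizes(n, params$clone_size_alpha, n),
      j_gene = j2$name[jpick],
      spiked = spiked
    )
    return(out)
  }

  ## v_d_j2: CDR3-like strings, in frame and stop-free
  d1_motifs <- build_motif_set(d1, 7L)$motifs
  d2_motifs <- build_motif_set(d2s, 7L)$motifs
  build_rows <- function(idx) {
    m <- length(idx)
    if (m == 0) {
      return(character())
    }
    vctx <- paste0("TGTGCCAGC", random_dna(sample(3:9, m, TRUE), params$insert_base_weights))
    jctx <- substr(j2$coding_seq[jpick[idx]], 4L, 18L)
    core <- character(m)
    sp <- spiked[idx]
    if (any(sp)) {
      segs1 <- plant_d_segment(sum(sp), d1$coding_seq, d1_motifs)
      segs2 <- plant_d_segment(sum(sp), d2s$coding_seq[1], d2_motifs)
      mid <- random_dna(dist_sample(params$coding_insert, sum(sp)), params$insert_base_weights)
      core[sp] <- paste0(segs1, mid, segs2)
    }
    if (any(!sp)) {
      core[!sp] <- random_dna(10L + dist_sample(params$coding_insert, sum(!sp)),
        params$insert_base_weights)
    }
    s <- paste0(vctx, core, jctx)
    pad <- (3L - nchar(s) %% 3L) %% 3L
    ## pad with T: no stop codon ends in T, so padding cannot create one
    paste0(s, strrep("T", pad))
  }
  idx <- seq_len(n)
  cdr3 <- build_rows(idx)
  ## re-draw rows with an in-frame stop; planted segments never contain one,
  ## so redrawing cannot bias the truth flags
  for (i in 1:25) {
    bad <- which(has_inframe_stop(cdr3))
    if (!length(bad)) break
    cdr3[bad] <- build_rows(bad)
  }
  tibble(
    cdr3_nt = cdr3,
    count = rclone_sizes(n, params$clone_size_alpha, n),
    j_gene = j2$name[jpick],
    spiked = spiked
  )
}
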