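## Anchor machinery -----------------------------------------------------------

## Mismatch budget: 1 mismatch tolerated per 20 anchor bases, rounded down.
anchor_budget <- function(anchor, max_mismatch = NULL) {
  if (!is.null(max_mismatch)) {
    return(as.integer(max_mismatch))
  }
  nchar(anchor) %/% 20L
}

## Locate `anchor` in each read (DNAStringSet); returns a list of IRanges-like
## start/end integer matrices, first hit per read (NA when absent).
locate_anchor <- function(reads, anchor, budget, take = c("first", "last")) {
  take <- match.arg(take)
  m <- Biostrings::vmatchPattern(anchor, reads, max.mismatch = budget, fixed = TRUE)
  nh <- S4Vectors::elementNROWS(m)
  starts <- rep(NA_integer_, length(reads))
  ends <- rep(NA_integer_, length(reads))
  hit <- nh > 0
  if (any(hit)) {
    st <- IRanges::start(m)[hit]
    en <- IRanges::end(m)[hit]
    pickfn <- if (take == "first") function(v) v[1] else function(v) v[length(v)]
    starts[hit] <- vapply(st, pickfn, integer(1))
    ends[hit] <- vapply(en, pickfn, integer(1))
  }
  list(start = starts, end = ends, n = nh)
}

## vectorized over reads: Hamming distance between the anchor and the read
## segment starting at `starts`
count_mismatches <- function(reads, starts, anchor) {
  k <- nchar(anchor)
  obs <- substr(reads, starts, starts + k - 1L)
  mm <- integer(length(obs))
  for (i in seq_len(k)) {
    mm <- mm + (substr(obs, i, i) != substr(anchor, i, i))
  }
  mm
}

## Core two-anchor extraction: returns tibble(junction, strand, status,
## mismatches). Junction = bases strictly between end(left anchor) and
## start(right anchor), reported in forward convention.
extract_between_anchors <- function(seqs, left_anchor, right_anchor,
                                    left_budget, right_budget) {
  n <- length(seqs)
  out <- tibble(
    junction = NA_character_,
    strand = NA_character_,
    status = "no_anchor",
    mismatches = NA_integer_
  )[rep(1, max(n, 1)), ]
  if (n == 0) {
    return(out[0, ])
  }
  todo <- seq_len(n)
  seqs_now <- seqs
  for (strand in c("fwd", "rev")) {
    if (!length(todo)) break
    reads <- Biostrings::DNAStringSet(seqs_now[todo])
    l <- locate_anchor(reads, left_anchor, left_budget, take = "first")
    r <- locate_anchor(reads, right_anchor, right_budget, take = "last")
    found <- !is.na(l$start) & !is.na(r$start)
    ok <- found & (l$end < r$start)
    inverted <- found & !ok
    idx_ok <- todo[ok]
    if (length(idx_ok)) {
      out$junction[idx_ok] <- substr(seqs_now[idx_ok], l$end[ok] + 1L, r$start[ok] - 1L)
      out$strand[idx_ok] <- strand
      out$status[idx_ok] <- "called"
      out$mismatches[idx_ok] <-
        count_mismatches(seqs_now[idx_ok], l$start[ok], left_anchor) +
        count_mismatches(seqs_now[idx_ok], r$start[ok], right_anchor)
    }
    out$status[todo[inverted]] <- "inverted"
    ## only reads with no full anchor pair on this strand are retried
    todo <- todo[!found]
    if (strand == "fwd" && length(todo)) {
      seqs_now[todo] <- revcomp(seqs_now[todo])
    }
  }
  out
}

#' Extract D-D junctions from reads by RS anchoring
#'
#' Locates the full 5'D1-RS (nonamer-spacer-heptamer) and 3'D2-RS
#' (heptamer-spacer-nonamer) in each read, on either strand, and returns the
#' sequence strictly between the two coding-proximal heptamer edges - the
#' junction, excluding both RS. Reads matching the reverse strand are
#' reported in forward orientation. Reads lacking either anchor within the
#' mismatch budget are no-calls (`status = "no_anchor"`); reads with both
#' anchors in inverted order are structural no-calls (`status = "inverted"`).
#'
#' @param seqs Character vector of read sequences (or a `DNAStringSet`).
#' @param ref A `dd_reference`.
#' @param max_mismatch Per-anchor mismatch budget; default 1 per 20 anchor
#'   bases, rounded down.
#' @return A tibble with columns `junction`, `strand`, `status`,
#'   `mismatches`.
#' @examples
#' ref <- dd_example_reference()
#' a5 <- rs_genomic(gene_rs(ref_gene(ref, "TRBD1"), "five_prime"))
#' a3 <- rs_genomic(gene_rs(ref_gene(ref, "TRBD2"), "three_prime"))
#' read <- paste0(ref$flank5, a5, "GGTAC", a3, ref$flank3)
#' extract_junctions(read, ref)$junction
#' @export
extract_junctions <- function(seqs, ref, max_mismatch = NULL) {
  seqs <- canon_seq(as.character(seqs))
  a5 <- rs_genomic(gene_rs(ref_gene(ref, "TRBD1"), "five_prime"))
  a3 <- rs_genomic(gene_rs(ref_gene(ref, "TRBD2"), "three_prime"))
  extract_between_anchors(
    seqs, a5, a3,
    anchor_budget(a5, max_mismatch), anchor_budget(a3, max_mismatch)
  )
}

## longest common prefix length of each junction with `coding`
prefix_match_len <- function(junctions, coding) {
  lenc <- nchar(coding)
  p <- integer(length(junctions))
  alive <- rep(TRUE, length(junctions))
  for (i in seq_len(lenc)) {
    ch <- substr(coding, i, i)
    alive <- alive & nchar(junctions) >= i & substr(junctions, i, i) == ch
    if (!any(alive)) break
    p[alive] <- i
  }
  p
}

## longest common suffix length, capped at `cap` per element
suffix_match_len <- function(junctions, coding, cap) {
  lenc <- nchar(coding)
  lj <- nchar(junctions)
  s <- integer(length(junctions))
  alive <- rep(TRUE, length(junctions))
  for (i in seq_len(lenc)) {
    ch <- substr(coding, lenc - i + 1L, lenc - i + 1L)
    alive <- alive & cap >= i & lj >= i &
      substr(junctions, lj - i + 1L, lj - i + 1L) == ch
    if (!any(alive)) break
    s[alive] <- i
  }
  s
}

#' Decompose a junction into germline D1 / insert / germline D2
#'
#' Maximal germline matching: `d1_match` is the longest prefix of the
#' junction identical to the TRBD1 coding region; within the remainder,
#' `d2_match` is the longest junction suffix identical to a TRBD2 allele
#' coding suffix (the allele with the longest match wins, ties broken toward
#' `*01`); everything in between is the nontemplated insert. The
#' decomposition always satisfies
#' `d1_match + nchar(insert_seq) + d2_match == nchar(junction)`. Insert
#' bases that happen to match adjacent germline are absorbed into the
#' germline matches - the caller reports retained germline length, which is
#' an upper bound on the true (unobservable) retained length.
#'
#' @param junctions Character vector of inter-RS junction sequences (may
#'   include empty strings - perfect signal joints).
#' @param ref A `dd_reference`.
#' @return A tibble with `junction`, `d1_match`, `insert_seq`, `d2_match`,
#'   `d2_allele`.
#' @examples
#' decompose_junctions("GGGACAGGTCTACTAGCGGGGGGG", dd_example_reference())
#' @export
decompose_junctions <- function(junctions, ref) {
  junctions <- canon_seq(junctions)
  assert_dna(junctions, "junctions")
  d1 <- ref_gene(ref, "TRBD1")
  d2s <- arrange(ref_gene(ref, "TRBD2", allele = NULL), .data$allele)

  p <- prefix_match_len(junctions, d1$coding_seq)
  rem <- nchar(junctions) - p
  best_s <- integer(length(junctions))
  best_allele <- rep(d2s$allele[1], length(junctions))
  for (i in seq_len(nrow(d2s))) {
    s <- suffix_match_len(junctions, d2s$coding_seq[i], cap = rem)
    better <- s > best_s
    best_s[better] <- s[better]
    best_allele[better] <- d2s$allele[i]
  }
  tibble(
    junction = junctions,
    d1_match = p,
    insert_seq = substr(junctions, p + 1L, nchar(junctions) - best_s),
    d2_match = best_s,
    d2_allele = best_allele
  )
}

#' Classify junction calls as short or long
#'
#' A rearrangement is `long` when both D regions are identifiable (at least
#' `min_germline` retained nucleotides on each side), `short` when neither
#' is, and `ambiguous` otherwise. The default `min_germline = 7` is the most
#' conservative criterion (7-mers of D1 and D2); `min_germline = 3` gives a
#' lenient classification.
#'
#' @param d1_match,d2_match Retained germline lengths from
#'   [decompose_junctions()].
#' @param min_germline Minimum identifiable germline length per side.
#' @return Factor with levels `short`, `long`, `ambiguous`.
#' @export
classify_calls <- function(d1_match, d2_match, min_germline = 7L) {
  if (min_germline < 1) {
    dd_abort("min_germline must be >= 1", "ddloop_parameter_error")
  }
  out <- ifelse(
    d1_match >= min_germline & d2_match >= min_germline, "long",
    ifelse(d1_match < min_germline & d2_match < min_germline, "short", "ambiguous")
  )
  factor(out, levels = c("short", "long", "ambiguous"))
}

#' Call D-D junctions from a FASTQ file
#'
#' End-to-end caller: reads the amplicon FASTQ, extracts the inter-RS
#' junction of each read by RS-anchor matching, decomposes it into
#' D1-match / insert / D2-match by maximal germline matching, and classifies
#' each call as short or long. Substitution errors inside a junction are
#' carried through (indels are not modelled); errors inside an anchor are
#' absorbed up to the mismatch budget.
#'
#' @param fastq Path to a FASTQ file, or a character vector of read
#'   sequences.
#' @param ref A `dd_reference`.
#' @param max_mismatch Per-anchor mismatch budget (default: 1 per 20 anchor
#'   bases).
#' @param min_germline Classification threshold, see [classify_calls()].
#' @return A tibble with one row per read: `read_id`, `junction`,
#'   `d1_match`, `insert_seq`, `d2_match`, `d2_allele`, `klass`, `strand`,
#'   `status`, `mismatches`. Rows that failed extraction keep their `status`
#'   and have `NA` elsewhere.
#' @export
call_junctions <- function(fastq, ref = dd_example_reference(),
                           max_mismatch = NULL, min_germline = 7L) {
  if (length(fastq) == 1 && file.exists(fastq)) {
    dna <- Biostrings::readDNAStringSet(fastq, format = "fastq")
    ids <- sub("\\s.*$", "", names(dna))
    seqs <- as.character(dna)
  } else {
    seqs <- canon_seq(fastq)
    ids <- names(fastq) %||% sprintf("read%d", seq_along(seqs))
  }
  ext <- extract_junctions(seqs, ref, max_mismatch)
  called <- ext$status == "called"
  dec <- decompose_junctions(ext$junction[called], ref)
  out <- tibble(
    read_id = ids,
    junction = ext$junction,
    d1_match = NA_integer_,
    insert_seq = NA_character_,
    d2_match = NA_integer_,
    d2_allele = NA_character_,
    klass = factor(NA, levels = c("short", "long", "ambiguous")),
    strand = ext$strand,
    status = ext$status,
    mismatches = ext$mismatches
  )
  out$d1_match[called] <- dec$d1_match
  out$insert_seq[called] <- dec$insert_seq
  out$d2_match[called] <- dec$d2_match
  out$d2_allele[called] <- dec$d2_allele
  out$klass[called] <- classify_calls(dec$d1_match, dec$d2_match, min_germline)
  out
}
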