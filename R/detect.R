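#' Detect D-region motifs in junction or CDR3 tables
#'
#' Conservative presence/absence detection: a row is flagged when every
#' required motif set has at least one of its k-mers occurring (overlapping
#' matches allowed, case-insensitive) inside the search window. With the
#' TRBD2 set on a D1-J2 table this estimates the D1-D2-J2 fraction of the
#' partial D-J2 repertoire; with both the TRBD1 and TRBD2 sets on a
#' productive CDR3 table it estimates the V-D1-D2-J2 fraction.
#'
#' @param table Tibble with a junction column (`junction` or `cdr3_nt`;
#'   override with `column`), optionally `count` for weighted fractions.
#' @param motif_sets A `motif_set` or list of them; a row must hit every
#'   set.
#' @param column Name of the sequence column; default: `junction` if
#'   present, else `cdr3_nt`.
#' @param window_trim Integer pair: bases to exclude from the start and end
#'   of each sequence before searching (e.g. `c(9, 9)` masks three codons at
#'   each CDR3 terminus). Default `c(0, 0)`: the full string is searched.
#' @param weighted Compute the flagged fraction over `count`-weighted rows.
#' @return A `dd_detection`: `glance()` returns `n_rows`, `n_flagged`,
#'   `fraction`; `tidy()` the per-row flags with per-set first-hit
#'   positions (1-based, relative to the untrimmed string; `NA` = no hit).
#' @examples
#' ref <- dd_example_reference()
#' ms <- build_motif_set(ref_gene(ref, "TRBD2", allele = NULL), 7)
#' tab <- tibble::tibble(junction = c("AAAGACTAGCAAA", "AAAATTTTCCCC"))
#' glance(detect_motif_fraction(tab, ms))
#' @export
detect_motif_fraction <- function(table, motif_sets, column = NULL,
                                  window_trim = c(0L, 0L), weighted = FALSE) {
  if (inherits(motif_sets, "motif_set")) {
    motif_sets <- list(motif_sets)
  }
  if (!length(motif_sets) || any(!vapply(motif_sets, inherits, TRUE, "motif_set"))) {
    dd_abort("motif_sets must be one or more motif_set objects", "ddloop_parameter_error")
  }
  if (any(vapply(motif_sets, function(m) length(m$motifs) == 0, TRUE))) {
    dd_abort("empty motif set", "ddloop_parameter_error")
  }
  column <- column %||% intersect(c("junction", "cdr3_nt"), names(table))[1]
  if (is.na(column) || is.null(column) || !column %in% names(table)) {
    dd_abort("table carries no junction/cdr3_nt column", "ddloop_format_error")
  }
  seqs <- canon_seq(table[[column]])
  lo <- window_trim[1]
  hi <- window_trim[2]
  win <- substr(seqs, lo + 1L, nchar(seqs) - hi)

  set_names <- vapply(motif_sets, function(m) m$source_gene, character(1))
  set_names <- make.unique(set_names)
  hits <- lapply(motif_sets, function(ms) {
    first_hit <- rep(NA_integer_, length(win))
    for (motif in ms$motifs) {
      pos <- stringr::str_locate(win, stringr::fixed(motif))[, "start"]
      better <- !is.na(pos) & (is.na(first_hit) | pos < first_hit)
      first_hit[better] <- pos[better]
    }
    first_hit + lo # back to untrimmed coordinates
  })
  hit_mat <- do.call(cbind, hits)
  flagged <- rowSums(!is.na(hit_mat)) == length(motif_sets)

  w <- if (weighted && "count" %in% names(table)) table[["count"]] else rep(1, length(win))
  rows <- tibble(row = seq_along(win), flagged = flagged)
  for (i in seq_along(motif_sets)) {
    rows[[paste0("hit_", set_names[i])]] <- hit_mat[, i]
  }
  structure(
    list(
      summary = tibble(
        n_rows = length(win),
        n_flagged = sum(flagged),
        fraction = sum(flagged * w) / sum(w),
        weighted = weighted,
        motif_sets_used = paste(set_names, collapse = "+")
      ),
      rows = rows
    ),
    class = "dd_detection"
  )
}

#' @export
print.dd_detection <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<dd_detection [%s]: %d rows, %.0f flagged (fraction %.4g)>\n",
    s$motif_sets_used, s$n_rows, s$n_flagged, s$fraction
  ))
  invisible(x)
}

#' @rdname detect_motif_fraction
#' @param x A `dd_detection` object.
#' @param ... Unused.
#' @export
tidy.dd_detection <- function(x, ...) x$rows

#' @rdname detect_motif_fraction
#' @export
glance.dd_detection <- function(x, ...) x$summary

#' J gene usage
#'
#' Frequency of each J gene (or of the J1 vs J2 cluster) among table rows.
#' Cluster membership is parsed from the gene name (`TRBJ1-*` vs `TRBJ2-*`).
#'
#' @param table Tibble with a `j_gene` column; optional `count` weights.
#' @param level `"gene"` or `"cluster"`.
#' @param weighted Weight by `count`.
#' @return Tibble (`j_gene` or `cluster`, `n`, `freq`) with frequencies
#'   summing to 1; empty input gives an empty tibble.
#' @export
j_usage <- function(table, level = c("gene", "cluster"), weighted = FALSE) {
  level <- match.arg(level)
  if (nrow(table) == 0) {
    out <- tibble(key = character(), n = numeric(), freq = numeric())
    names(out)[1] <- if (level == "gene") "j_gene" else "cluster"
    return(out)
  }
  w <- if (weighted && "count" %in% names(table)) table$count else rep(1, nrow(table))
  key <- if (level == "gene") {
    table$j_gene
  } else {
    ifelse(grepl("J1", table$j_gene), "J1", "J2")
  }
  out <- summarise(
    group_by(tibble(key = key, w = w), .data$key),
    n = sum(.data$w), .groups = "drop"
  )
  out$freq <- out$n / sum(out$n)
  colname <- if (level == "gene") "j_gene" else "cluster"
  names(out)[1] <- colname
  arrange(out, .data[[colname]])
}

#' Call 5'D2-RS - 3'D1-RS signal joints in excision-circle reads
#'
#' The excision circle produced by the coding-joint pathway carries the two
#' recombination signals fused head-to-head (heptamer to heptamer). This
#' locates the full 5'D2-RS (nonamer-spacer-heptamer) and 3'D1-RS
#' (heptamer-spacer-nonamer) in that orientation on either strand and
#' reports the bases strictly between the two heptamers: empty for the
#' canonical precise signal joint (`perfect = TRUE`), a few nontemplated
#' nucleotides for secondary joints. Reads lacking either anchor, or with
#' the anchors in a non-head-to-head arrangement, are no-calls.
#'
#' @param fastq Path to a FASTQ, or a character vector of read sequences.
#' @param ref A `dd_reference`.
#' @param max_mismatch Per-anchor mismatch budget (default 1 per 20 anchor
#'   bases, rounded down).
#' @return Tibble: `read_id`, `insert_seq`, `perfect`, `strand`, `status`,
#'   `mismatches`.
#' @export
call_signal_joints <- function(fastq, ref = dd_example_reference(),
                               max_mismatch = NULL) {
  if (length(fastq) == 1 && file.exists(fastq)) {
    dna <- Biostrings::readDNAStringSet(fastq, format = "fastq")
    ids <- sub("\\s.*$", "", names(dna))
    seqs <- as.character(dna)
  } else {
    seqs <- canon_seq(fastq)
    ids <- names(fastq) %||% sprintf("read%d", seq_along(seqs))
  }
  a5 <- rs_genomic(gene_rs(ref_gene(ref, "TRBD2"), "five_prime")) # ends in heptamer
  a3 <- rs_genomic(gene_rs(ref_gene(ref, "TRBD1"), "three_prime")) # starts with heptamer
  ext <- extract_between_anchors(
    seqs, a5, a3,
    anchor_budget(a5, max_mismatch), anchor_budget(a3, max_mismatch)
  )
  tibble(
    read_id = ids,
    insert_seq = ext$junction,
    perfect = !is.na(ext$junction) & !nzchar(ext$junction),
    strand = ext$strand,
    status = ext$status,
    mismatches = ext$mismatches
  )
}

#' Summarize signal-joint calls
#'
#' Read-level calls condensed to the consensus view capillary sequencing
#' would give: the majority insert sequence plus the fraction of precise
#' joints.
#'
#' @param calls Output of [call_signal_joints()].
#' @return One-row tibble: `n_called`, `n_perfect`, `perfect_fraction`,
#'   `consensus_insert` (majority insert among called reads).
#' @export
summarize_signal_joints <- function(calls) {
  called <- filter(calls, .data$status == "called")
  if (nrow(called) == 0) {
    return(tibble(
      n_called = 0L, n_perfect = 0L,
      perfect_fraction = NA_real_, consensus_insert = NA_character_
    ))
  }
  tab <- sort(table(called$insert_seq), decreasing = TRUE)
  tibble(
    n_called = nrow(called),
    n_perfect = sum(called$perfect),
    perfect_fraction = mean(called$perfect),
    consensus_insert = names(tab)[1]
  )
}
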