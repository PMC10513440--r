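#' Aggregate junction calls into a clonotype table
#'
#' Merges identical junction sequences from one sample into clonotypes with
#' summed counts and within-sample frequencies. Decomposition fields are
#' carried over; since decomposition is a deterministic function of the
#' junction sequence, conflicting annotations for the same junction indicate
#' corrupted input and raise an internal-consistency error.
#'
#' @param calls Per-read calls from [call_junctions()] (rows with
#'   `status != "called"` are dropped), or any tibble with `junction`,
#'   `d1_match`, `insert_seq`, `d2_match`, `klass` columns and optionally a
#'   `count` column of per-row multiplicities.
#' @param sample_id Sample label for the resulting table.
#' @return A clonotype tibble: `junction`, `count`, `freq`, `klass`,
#'   `d1_match`, `insert_len`, `d2_match`, `sample_id`, sorted by descending
#'   count. `freq` sums to 1 per sample.
#' @export
aggregate_clonotypes <- function(calls, sample_id = "S1") {
  if ("status" %in% names(calls)) {
    calls <- filter(calls, .data$status == "called")
  }
  if (nrow(calls) == 0) {
    return(tibble(
      junction = character(), count = integer(), freq = numeric(),
      klass = factor(character(), levels = c("short", "long", "ambiguous")),
      d1_match = integer(), insert_len = integer(), d2_match = integer(),
      sample_id = character()
    ))
  }
  if (!"count" %in% names(calls)) {
    calls$count <- 1L
  }
  consist <- summarise(group_by(calls, .data$junction),
    n_dec = n_distinct(.data$d1_match, .data$insert_seq, .data$d2_match),
    .groups = "drop"
  )
  if (any(consist$n_dec > 1)) {
    dd_abort(
      sprintf(
        "conflicting decompositions for junction '%s'",
        consist$junction[consist$n_dec > 1][1]
      ),
      "ddloop_consistency_error"
    )
  }
  out <- summarise(
    group_by(calls, .data$junction),
    count = sum(.data$count),
    klass = .data$klass[1],
    d1_match = .data$d1_match[1],
    insert_len = nchar(.data$insert_seq[1]),
    d2_match = .data$d2_match[1],
    .groups = "drop"
  )
  out <- arrange(out, dplyr::desc(.data$count), .data$junction)
  out$freq <- out$count / sum(out$count)
  out$sample_id <- sample_id
  select(
    out, "junction", "count", "freq", "klass",
    "d1_match", "insert_len", "d2_match", "sample_id"
  )
}

#' Clonal diversity per 100,000 cells
#'
#' Normalizes the number of unique clonotypes to cell input, converting DNA
#' mass to cell count at `pg_per_cell` picograms of genomic DNA per diploid
#' cell (6 pg by default, so 600 ng of input corresponds to ~100,000 cells).
#'
#' @param table A clonotype table ([aggregate_clonotypes()]); alternatively
#'   pass `n_unique` directly.
#' @param input_dna_ng Input DNA mass in nanograms (> 0).
#' @param pg_per_cell Genomic DNA mass per cell, pg.
#' @param n_unique Number of unique clonotypes; defaults to `nrow(table)`.
#' @return Unique clonotypes per 100,000 cells.
#' @examples
#' diversity_per_cells(n_unique = 1000, input_dna_ng = 600)
#' @export
diversity_per_cells <- function(table = NULL, input_dna_ng, pg_per_cell = 6,
                                n_unique = NULL) {
  if (input_dna_ng <= 0 || pg_per_cell <= 0) {
    dd_abort("input_dna_ng and pg_per_cell must be positive", "ddloop_parameter_error")
  }
  n_unique <- n_unique %||% nrow(table)
  cells <- input_dna_ng * 1000 / pg_per_cell
  n_unique * 1e5 / cells
}

#' Insertion and deletion statistics per junction class
#'
#' For each short/long/ambiguous class, summarizes the nontemplated insert
#' length and the number of germline nucleotides deleted,
#' `len(D1) + len(D2) - d1_match - d2_match`. Deletions are only defined
#' where germline is identifiable, i.e. for the `long` class; for other
#' classes they are reported as missing.
#'
#' @param table Clonotype table with `klass`, `insert_len`, `d1_match`,
#'   `d2_match` and (for deletions) `d2_allele` resolution via `ref`.
#' @param ref A `dd_reference` (for germline coding lengths).
#' @param weighted Weight rows by clonotype `count` instead of counting each
#'   clonotype once.
#' @return A tibble with one row per class and metric (`insert_len`,
#'   `deletions`): n, mean, median, and a normal-theory 95% CI for the mean.
#' @export
indel_stats <- function(table, ref = dd_example_reference(), weighted = FALSE) {
  len1 <- nchar(ref_gene(ref, "TRBD1")$coding_seq)
  len2 <- max(nchar(ref_gene(ref, "TRBD2", allele = NULL)$coding_seq))
  tab <- mutate(table,
    deletions = ifelse(.data$klass == "long",
      len1 + len2 - .data$d1_match - .data$d2_match, NA_real_
    ),
    .w = if (weighted && "count" %in% names(table)) .data$count else 1
  )
  long <- tidyr::pivot_longer(
    select(tab, "klass", "insert_len", "deletions", ".w"),
    c("insert_len", "deletions"),
    names_to = "metric", values_to = "value"
  )
  long <- filter(long, !is.na(.data$value))
  out <- summarise(
    group_by(long, .data$klass, .data$metric),
    n = sum(.data$.w),
    mean = sum(.data$value * .data$.w) / sum(.data$.w),
    median = median(rep(.data$value, .data$.w)),
    se = sqrt(wvar(.data$value, .data$.w) / sum(.data$.w)),
    .groups = "drop"
  )
  mutate(out,
    ci_lo = .data$mean - 1.96 * .data$se,
    ci_hi = .data$mean + 1.96 * .data$se,
    se = NULL
  )
}

wvar <- function(x, w) {
  m <- sum(x * w) / sum(w)
  sum(w * (x - m)^2) / max(sum(w) - 1, 1)
}

#' Two-sided Mann-Whitney U test
#'
#' U counts the pairs `(x_i, y_j)` with `x_i > y_j`, plus 0.5 per tie. In
#' exact mode the null distribution of U is obtained by full enumeration of
#' all assignments of the pooled values to the two groups; the two-sided p
#' doubles the smaller one-sided tail (capped at 1). The normal
#' approximation applies a tie correction to the variance and a 0.5
#' continuity correction.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param mode `"auto"` (exact when `n1 + n2 <= 20`), `"exact"` or
#'   `"normal_approx"`.
#' @return A one-row tibble: `u`, `p_value`, `method`, `n1`, `n2`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4), mode = "exact")
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) {
    dd_abort("both samples must be non-empty", "ddloop_parameter_error")
  }
  n1 <- length(x)
  n2 <- length(y)
  if (mode == "auto") {
    mode <- if (n1 + n2 <= 20) "exact" else "normal_approx"
  }
  if (mode == "exact" && n1 + n2 > 20) {
    dd_abort("exact mode is limited to n1 + n2 <= 20", "ddloop_parameter_error")
  }
  pooled <- c(x, y)
  r <- rank(pooled) # midranks handle ties
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (mode == "exact") {
    sets <- combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p_lo <- mean(u_all <= u_obs + eps)
    p_hi <- mean(u_all >= u_obs - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    mu <- n1 * n2 / 2
    if (sigma2 <= 0) {
      p <- 1
    } else {
      cc <- if (u_obs == mu) 0 else 0.5
      z <- (u_obs - mu - sign(u_obs - mu) * cc) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  tibble(u = u_obs, p_value = p, method = mode, n1 = n1, n2 = n2)
}

#' Clonotype publicity across samples
#'
#' A clonotype is public when its junction sequence occurs in two or more
#' samples. The public fraction is the number of public clonotypes over the
#' pooled number of unique clonotypes (presence-based: invariant to sample
#' order and per-sample count scaling).
#'
#' @param tables A clonotype table carrying >= 2 distinct `sample_id`s, or a
#'   list of per-sample tables to be combined.
#' @param by_class Compute separately per junction class.
#' @return A `dd_publicity` object; `glance()` gives the summary row(s)
#'   (`n_samples`, `n_unique_pooled`, `n_public`, `public_fraction`),
#'   `tidy()` the per-clonotype occurrence counts.
#' @export
publicity <- function(tables, by_class = FALSE) {
  tab <- if (is.data.frame(tables)) tables else bind_rows(tables)
  if (n_distinct(tab$sample_id) < 2) {
    dd_abort("publicity needs at least 2 samples", "ddloop_parameter_error")
  }
  grp <- if (by_class) c("klass", "junction") else "junction"
  occ <- summarise(
    group_by(tab, across(dplyr::all_of(grp))),
    n_samples_present = n_distinct(.data$sample_id),
    .groups = "drop"
  )
  sgrp <- if (by_class) "klass" else character()
  summ <- summarise(
    group_by(occ, across(dplyr::all_of(sgrp))),
    n_unique_pooled = n(),
    n_public = sum(.data$n_samples_present >= 2),
    public_fraction = .data$n_public / .data$n_unique_pooled,
    .groups = "drop"
  )
  summ$n_samples <- n_distinct(tab$sample_id)
  structure(
    list(summary = summ, occurrences = occ, by_class = by_class),
    class = "dd_publicity"
  )
}

#' @export
print.dd_publicity <- function(x, ...) {
  cat(sprintf("<dd_publicity over %d samples>\n", x$summary$n_samples[1]))
  print(x$summary)
  invisible(x)
}

#' @rdname publicity
#' @param x A `dd_publicity` object.
#' @param ... Unused.
#' @export
tidy.dd_publicity <- function(x, ...) x$occurrences

#' @rdname publicity
#' @export
glance.dd_publicity <- function(x, ...) x$summary

#' Position frequency matrix of junction sequences
#'
#' Aligns sequences at their left or right edge, pads with a gap symbol, and
#' computes per-position base frequencies over the non-gap entries (each
#' column sums to 1).
#'
#' @param junctions Non-empty character vector of DNA strings.
#' @param align `"left"` or `"right"`.
#' @return A `dd_pfm`: numeric matrix with rows A, C, G, T and one column
#'   per position; attribute `support` gives the non-gap count per column.
#' @examples
#' position_frequency_matrix(c("AC", "AG"))
#' @export
position_frequency_matrix <- function(junctions, align = c("left", "right")) {
  align <- match.arg(align)
  junctions <- canon_seq(junctions)
  if (length(junctions) == 0) {
    dd_abort("need at least one sequence", "ddloop_parameter_error")
  }
  assert_dna(junctions, "junctions")
  width <- max(nchar(junctions))
  pad <- strrep("-", width - nchar(junctions))
  padded <- if (align == "left") paste0(junctions, pad) else paste0(pad, junctions)
  chars <- matrix(unlist(strsplit(padded, "", fixed = TRUE)),
    nrow = length(padded), byrow = TRUE
  )
  counts <- vapply(
    seq_len(width),
    function(j) tabulate(factor(chars[, j], levels = DNA_BASES), 4L),
    integer(4)
  )
  rownames(counts) <- DNA_BASES
  support <- colSums(counts)
  freq <- sweep(counts, 2, pmax(support, 1L), "/")
  structure(freq,
    support = support, align = align,
    class = c("dd_pfm", "matrix", "array")
  )
}
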