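#' The conservative TRBD2 7-mer motif list
#'
#' The seven D2-specific 7-mers used for conservative detection of a D2
#' remnant inside D1-J2 junctions and CDR3 sequences. They are exactly the
#' k-mers derived from the two TRBD2 alleles by [build_motif_set()] under the
#' default exclusion rules.
#'
#' @format Character vector of seven 7-nt strings (upper case).
#' @export
TRBD2_MOTIFS_7 <- c(
  "GGACTAG", "GACTAGC", "ACTAGCG", "CTAGCGG",
  "TAGCGGG", "AGCGGGG", "AGCGGGA"
)

#' Exclusion rules for conservative motif derivation
#'
#' Controls which k-length windows of a D coding region are considered
#' gene-specific enough to act as detection motifs:
#'
#' * `drop_first`: drop the window starting at coding position 0. The D gene
#'   5' termini are shared across D genes (TRBD1 and TRBD2 both begin
#'   `GGGAC`), so the first window is not discriminative.
#' * `max_start`: latest allowed 0-based window start (default `k - 1`, set
#'   when the rules are applied). Windows beyond it lie in the 3'-terminal
#'   tail, which is low-complexity (poly-G in TRBD2) and is the part most
#'   often destroyed by exonucleolytic trimming.
#' * `max_homopolymer`: drop windows containing a homopolymer run longer
#'   than this (default 4).
#' * `literal`: an explicit motif list; when supplied it overrides
#'   derivation entirely.
#'
#' @param drop_first Drop the position-0 window?
#' @param max_start Latest allowed window start (0-based); `NULL` means
#'   `k - 1`.
#' @param max_homopolymer Longest tolerated homopolymer run inside a motif.
#' @param literal Optional literal motif list overriding derivation.
#' @return A list of class `motif_rules`.
#' @export
motif_exclude_rules <- function(drop_first = TRUE, max_start = NULL,
                                max_homopolymer = 4L, literal = NULL) {
  structure(
    list(
      drop_first = isTRUE(drop_first),
      max_start = max_start,
      max_homopolymer = as.integer(max_homopolymer),
      literal = if (!is.null(literal)) canon_seq(literal)
    ),
    class = "motif_rules"
  )
}

#' Build a conservative k-mer motif set from gene alleles
#'
#' Takes the union of all k-length windows of the coding regions of the
#' supplied alleles of one gene, then removes windows judged non-specific by
#' the exclusion rules. With the bundled human TRBD2 alleles, `k = 7` and the
#' default rules, the result is exactly [TRBD2_MOTIFS_7].
#'
#' @param gene_alleles Tibble of gene records (rows of `ref$genes`, all with
#'   the same `name`), e.g. `ref_gene(ref, "TRBD2", allele = NULL)`.
#' @param k Motif length.
#' @param exclude A [motif_exclude_rules()] object.
#' @return A `motif_set`: list with `k`, `motifs` (upper-case character
#'   vector) and `source_gene`.
#' @examples
#' ref <- dd_example_reference()
#' ms <- build_motif_set(ref_gene(ref, "TRBD2", allele = NULL), k = 7)
#' sort(ms$motifs)
#' @export
build_motif_set <- function(gene_alleles, k = 7L, exclude = motif_exclude_rules()) {
  stopifnot(inherits(exclude, "motif_rules"))
  k <- as.integer(k)
  if (k < 1) dd_abort("k must be >= 1", "ddloop_parameter_error")
  gene <- unique(gene_alleles$name)
  if (length(gene) != 1) {
    dd_abort("all alleles must belong to one gene", "ddloop_parameter_error")
  }
  if (!is.null(exclude$literal)) {
    motifs <- unique(exclude$literal)
    if (any(nchar(motifs) != k)) {
      dd_abort("literal motifs must all have length k", "ddloop_validation_error")
    }
    return(new_motif_set(k, motifs, gene))
  }
  max_start <- exclude$max_start %||% (k - 1L)
  motifs <- character()
  for (coding in gene_alleles$coding_seq) {
    km <- seq_kmers(canon_seq(coding), k)
    if (length(km) == 0) next
    start0 <- seq_along(km) - 1L
    keep <- rep(TRUE, length(km))
    if (exclude$drop_first) keep <- keep & start0 > 0L
    keep <- keep & start0 <= max_start
    keep <- keep & max_homopolymer_run(km) <= exclude$max_homopolymer
    motifs <- c(motifs, km[keep])
  }
  motifs <- unique(motifs)
  if (length(motifs) == 0) {
    dd_abort(
      sprintf("no %d-mers derivable from %s coding regions", k, gene),
      "ddloop_empty_set_error"
    )
  }
  new_motif_set(k, motifs, gene)
}

new_motif_set <- function(k, motifs, source_gene) {
  structure(
    list(k = as.integer(k), motifs = canon_seq(motifs), source_gene = source_gene),
    class = "motif_set"
  )
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf(
    "<motif_set %s: %d x %d-mers: %s>\n",
    x$source_gene, length(x$motifs), x$k,
    paste(tolower(sort(x$motifs)), collapse = ", ")
  ))
  invisible(x)
}
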