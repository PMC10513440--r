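#' Recombination signal (RS) objects
#'
#' An RS flanks every rearranging V, D or J gene: a conserved heptamer and
#' nonamer separated by a spacer of 12 or 23 nucleotides (the spacer length
#' defines the 12-RS / 23-RS classes). The RAG complex only synapses one
#' 12-RS with one 23-RS (the 12/23 rule), which is what makes the D1-D2 pair
#' a legal recombination substrate.
#'
#' @param heptamer 7-nt conserved heptamer.
#' @param spacer Spacer sequence; its length (12 or 23) is the spacer class.
#' @param nonamer 9-nt conserved nonamer.
#' @param side Which side of the coding region the signal flanks:
#'   `"five_prime"` or `"three_prime"`.
#' @return An `rs_signal` object.
#' @examples
#' rs_signal("CACTGTG", "TGAGTCACTTCA", "GGTTTTTGT", side = "five_prime")
#' @export
rs_signal <- function(heptamer, spacer, nonamer,
                      side = c("five_prime", "three_prime")) {
  side <- match.arg(side)
  heptamer <- canon_seq(heptamer)
  spacer <- canon_seq(spacer)
  nonamer <- canon_seq(nonamer)
  assert_dna(c(heptamer, spacer, nonamer), "RS sequences")
  if (nchar(heptamer) != 7) {
    dd_abort("RS heptamer must be 7 nt", "ddloop_validation_error")
  }
  if (nchar(nonamer) != 9) {
    dd_abort("RS nonamer must be 9 nt", "ddloop_validation_error")
  }
  if (!nchar(spacer) %in% c(12L, 23L)) {
    dd_abort(
      sprintf(
        "RS spacer must be 12 or 23 nt (its length is the spacer class); got %d",
        nchar(spacer)
      ),
      "ddloop_validation_error"
    )
  }
  structure(
    list(
      heptamer = heptamer, spacer = spacer, nonamer = nonamer,
      spacer_class = nchar(spacer), side = side
    ),
    class = "rs_signal"
  )
}

#' @export
print.rs_signal <- function(x, ...) {
  cat(sprintf(
    "<rs_signal %d-RS (%s): %s / %s / %s>\n",
    x$spacer_class, x$side, x$heptamer, x$spacer, x$nonamer
  ))
  invisible(x)
}

#' Assemble an RS as it appears on the genomic top strand
#'
#' The heptamer always abuts the coding region: a 5' signal reads
#' nonamer-spacer-heptamer (then coding), a 3' signal reads (coding then)
#' heptamer-spacer-nonamer.
#'
#' @param rs An [rs_signal()].
#' @return A single DNA string.
#' @export
rs_genomic <- function(rs) {
  stopifnot(inherits(rs, "rs_signal"))
  if (rs$side == "five_prime") {
    paste0(rs$nonamer, rs$spacer, rs$heptamer)
  } else {
    paste0(rs$heptamer, rs$spacer, rs$nonamer)
  }
}

#' Check a pair of recombination signals against the 12/23 rule
#'
#' Recombination proceeds only between signals of different spacer classes.
#'
#' @param a,b [rs_signal()] objects.
#' @return `TRUE` iff one signal is a 12-RS and the other a 23-RS.
#' @examples
#' a <- rs_signal("CACAGTG", strrep("A", 23), "ACAAAAACC", "three_prime")
#' b <- rs_signal("CACTGTG", strrep("A", 12), "GGTTTTTGT", "five_prime")
#' validate_12_23(a, b)
#' @export
validate_12_23 <- function(a, b) {
  stopifnot(inherits(a, "rs_signal"), inherits(b, "rs_signal"))
  setequal(c(a$spacer_class, b$spacer_class), c(12L, 23L))
}

## Internal guard used by the simulator: forming a synapse from two
## same-class signals is a mechanistic impossibility and is treated as a
## programming error, not a no-op.
check_synapse <- function(a, b) {
  if (!validate_12_23(a, b)) {
    dd_abort(
      sprintf(
        "12/23 rule violation: cannot synapse a %d-RS with a %d-RS",
        a$spacer_class, b$spacer_class
      ),
      "ddloop_12_23_error"
    )
  }
  invisible(TRUE)
}

#' Load a germline D/J reference bundle
#'
#' Reads a tab-separated gene table (one row per gene allele with coding
#' region and RS element sequences) plus a FASTA of the two genomic flanks
#' that carry the amplification primer sites, and validates the locus
#' geometry: D genes must carry a 12-RS at their 5' end and a 23-RS at their
#' 3' end, J genes a 5' 12-RS.
#'
#' The bundled human fixture (see [dd_example_reference()]) uses the IMGT
#' coding sequences for TRBD1 (`GGGACAGGGGGC`) and the two TRBD2 alleles
#' (`GGGACTAGCGGGGGGG`, `GGGACTAGCGGGAGGG`); RS spacers, J coding regions and
#' flanks are synthetic stand-ins (consensus heptamer/nonamer), which is why
#' the fixture files are named `*_synthetic`.
#'
#' @param genes_path Path to the gene TSV (columns `species`, `name`,
#'   `allele`, `coding_seq`, `rs5_heptamer`, `rs5_spacer`, `rs5_nonamer`,
#'   `rs3_heptamer`, `rs3_spacer`, `rs3_nonamer`; RS columns may be empty
#'   where a gene lacks that signal).
#' @param flanks_path Path to a FASTA with records `flank5` (upstream of the
#'   5'D1-RS, containing the forward primer site) and `flank3` (downstream of
#'   the 3'D2-RS, containing the reverse primer site).
#' @param primers_path Optional path to a signal-joint primer table (see
#'   [read_primer_table()]).
#' @param species Restrict to one species (default: keep all rows).
#' @return A `dd_reference` object: a list with a `genes` tibble, `flank5`,
#'   `flank3` and a `primers` tibble.
#' @export
read_trb_reference <- function(genes_path, flanks_path, primers_path = NULL,
                               species = NULL) {
  tab <- utils::read.delim(genes_path,
    sep = "\t", header = TRUE,
    colClasses = "character", check.names = FALSE,
    na.strings = NULL
  )
  required <- c(
    "species", "name", "allele", "coding_seq",
    "rs5_heptamer", "rs5_spacer", "rs5_nonamer",
    "rs3_heptamer", "rs3_spacer", "rs3_nonamer"
  )
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    dd_abort(
      sprintf("reference table lacks column(s): %s", paste(missing_cols, collapse = ", ")),
      "ddloop_format_error"
    )
  }
  genes <- as_tibble(tab[required])
  genes <- mutate(genes, across(dplyr::everything(), canon_seq))
  if (!is.null(species)) {
    sp <- toupper(species)
    genes <- filter(genes, .data$species == sp)
  }
  key <- paste(genes$species, genes$name, genes$allele)
  if (anyDuplicated(key)) {
    dd_abort(
      sprintf(
        "duplicate gene record: %s", key[duplicated(key)][1]
      ),
      "ddloop_duplicate_record_error"
    )
  }

  flanks <- Biostrings::readDNAStringSet(flanks_path)
  fnames <- sub("\\s.*$", "", names(flanks))
  if (!all(c("flank5", "flank3") %in% fnames)) {
    dd_abort("flank FASTA must contain records 'flank5' and 'flank3'", "ddloop_format_error")
  }
  flank5 <- canon_seq(as.character(flanks[[match("flank5", fnames)]]))
  flank3 <- canon_seq(as.character(flanks[[match("flank3", fnames)]]))

  primers <- if (!is.null(primers_path)) {
    read_primer_table(primers_path)
  } else {
    tibble(species = character(), dir_seq = character(), rev_seq = character())
  }

  ref <- structure(
    list(genes = genes, flank5 = flank5, flank3 = flank3, primers = primers),
    class = "dd_reference"
  )
  validate_dd_reference(ref)
}

validate_dd_reference <- function(ref) {
  genes <- ref$genes
  assert_dna(genes$coding_seq, "coding_seq", allow_empty = FALSE)
  assert_dna(c(ref$flank5, ref$flank3), "flanks", allow_empty = FALSE)
  is_d <- grepl("D[0-9]+$", genes$name)
  is_j <- grepl("J[0-9]", genes$name)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    has5 <- nzchar(g$rs5_heptamer)
    has3 <- nzchar(g$rs3_heptamer)
    if (is_d[i] && !(has5 && has3)) {
      dd_abort(sprintf("D gene %s must carry both a 5' and a 3' RS", g$name),
        "ddloop_validation_error")
    }
    if (is_j[i] && !has5) {
      dd_abort(sprintf("J gene %s must carry a 5' RS", g$name),
        "ddloop_validation_error")
    }
    if (has5) {
      rs <- rs_signal(g$rs5_heptamer, g$rs5_spacer, g$rs5_nonamer, "five_prime")
      if (rs$spacer_class != 12L) {
        dd_abort(sprintf("%s 5' RS must be a 12-RS", g$name), "ddloop_validation_error")
      }
    }
    if (has3) {
      rs <- rs_signal(g$rs3_heptamer, g$rs3_spacer, g$rs3_nonamer, "three_prime")
      if (is_d[i] && rs$spacer_class != 23L) {
        dd_abort(sprintf("%s 3' RS must be a 23-RS", g$name), "ddloop_validation_error")
      }
    }
  }
  for (need in c("TRBD1", "TRBD2")) {
    if (!need %in% genes$name) {
      dd_abort(sprintf("reference must contain %s", need), "ddloop_validation_error")
    }
  }
  ref
}

#' The bundled human reference
#'
#' Convenience loader for the reference bundle shipped with the package.
#'
#' @return A `dd_reference`.
#' @examples
#' ref <- dd_example_reference()
#' ref_gene(ref, "TRBD2", "*01")$coding_seq
#' @export
dd_example_reference <- function() {
  read_trb_reference(
    system.file("extdata", "trb_genes_synthetic.tsv", package = "ddloop"),
    system.file("extdata", "trb_flanks_synthetic.fasta", package = "ddloop"),
    system.file("extdata", "signal_joint_primers.tsv", package = "ddloop")
  )
}

#' Look up a gene (allele) in a reference
#'
#' @param ref A `dd_reference`.
#' @param name Gene name, e.g. `"TRBD1"`.
#' @param allele Allele label, e.g. `"*01"`; `NULL` returns all alleles of
#'   the gene (as a tibble); otherwise a single-row record.
#' @return A one-row tibble (with `allele`) or all alleles of the gene.
#' @export
ref_gene <- function(ref, name, allele = "*01") {
  stopifnot(inherits(ref, "dd_reference"))
  rows <- filter(ref$genes, .data$name == !!toupper(name))
  if (nrow(rows) == 0) {
    dd_abort(sprintf("gene %s not in reference", name), "ddloop_validation_error")
  }
  if (is.null(allele)) {
    return(rows)
  }
  hit <- filter(rows, .data$allele == !!allele)
  if (nrow(hit) == 0) {
    dd_abort(sprintf("allele %s%s not in reference", name, allele), "ddloop_validation_error")
  }
  hit
}

## RS accessors working off a one-row gene record.
gene_rs <- function(gene_row, side = c("five_prime", "three_prime")) {
  side <- match.arg(side)
  if (side == "five_prime") {
    rs_signal(gene_row$rs5_heptamer, gene_row$rs5_spacer, gene_row$rs5_nonamer, side)
  } else {
    rs_signal(gene_row$rs3_heptamer, gene_row$rs3_spacer, gene_row$rs3_nonamer, side)
  }
}

#' @export
print.dd_reference <- function(x, ...) {
  cat(sprintf(
    "<dd_reference: %d gene alleles (%s), flanks %d/%d nt, %d primer rows>\n",
    nrow(x$genes), paste(unique(x$genes$name), collapse = ", "),
    nchar(x$flank5), nchar(x$flank3), nrow(x$primers)
  ))
  invisible(x)
}
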