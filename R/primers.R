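#' Read a signal-joint primer table
#'
#' Parses the primer table used for excised signal-joint detection: one row
#' per species with the direct primer (annealing upstream of the TRB 5'D2-RS)
#' and the reverse primer (downstream of the 3'D1-RS). Primer strings may be
#' decorated as printed (`5'-ACGT...-3'`, with either a straight or a
#' typographic apostrophe); decorations are stripped and sequences
#' upper-cased.
#'
#' @param path Tab-separated file with columns `Species`,
#'   `Dir primer sequence`, `Length`, `Rev primer sequence`, `Length`.
#' @return A tibble with columns `species`, `dir_seq`, `rev_seq`.
#' @examples
#' p <- read_primer_table(
#'   system.file("extdata", "signal_joint_primers.tsv", package = "ddloop")
#' )
#' nchar(p$dir_seq)
#' @export
read_primer_table <- function(path) {
  tab <- utils::read.delim(path,
    sep = "\t", header = TRUE, check.names = FALSE,
    colClasses = "character", fileEncoding = "UTF-8"
  )
  cols <- names(tab)
  sp_col <- grep("^species$", cols, ignore.case = TRUE)
  dir_col <- grep("^dir", cols, ignore.case = TRUE)
  rev_col <- grep("^rev", cols, ignore.case = TRUE)
  if (!length(sp_col) || !length(dir_col) || !length(rev_col)) {
    dd_abort("primer table needs Species, Dir and Rev primer columns",
      "ddloop_format_error")
  }
  strip <- function(x) {
    x <- gsub("^\\s*5['’]-", "", x)
    x <- gsub("-3['’]\\s*$", "", x)
    canon_seq(x)
  }
  out <- tibble(
    species = trimws(tab[[sp_col[1]]]),
    dir_seq = strip(tab[[dir_col[1]]]),
    rev_seq = strip(tab[[rev_col[1]]])
  )
  assert_dna(c(out$dir_seq, out$rev_seq), "primer sequences", allow_empty = FALSE)
  out
}

#' Serialize a primer tibble back to the printed table layout
#'
#' Writes the five-column layout (`Species`, `Dir primer sequence`, `Length`,
#' `Rev primer sequence`, `Length`) with `5'-...-3'` decorations restored, so
#' parse + write round-trips the bundled table.
#'
#' @param primers Tibble from [read_primer_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_primer_table <- function(primers, path) {
  deco <- function(x) paste0("5’-", x, "-3’")
  lines <- c(
    paste(c("Species", "Dir primer sequence", "Length", "Rev primer sequence", "Length"),
      collapse = "\t"
    ),
    paste(primers$species, deco(primers$dir_seq), nchar(primers$dir_seq),
      deco(primers$rev_seq), nchar(primers$rev_seq),
      sep = "\t"
    )
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE, sep = "\n")
  invisible(path)
}
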