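# Toy transcript models: the coding context the consequence caller works in.

#' Construct a transcript model
#'
#' A transcript model carries the coding context needed to call protein-level
#' consequences of SNVs: strand-aware CDS intervals on a chromosome and the
#' spliced coding sequence. Intervals are 1-based closed and listed in
#' translation order (descending genomic coordinates on the minus strand).
#'
#' @param transcript_id,gene Identifiers.
#' @param chrom Chromosome label the CDS lives on.
#' @param strand `"+"` or `"-"`.
#' @param cds_intervals Tibble/data frame with `start`, `end` (1-based closed),
#'   in translation order.
#' @param cds_sequence Spliced coding sequence (including the stop codon), read
#'   5'→3' on the coding strand.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene, chrom, strand, cds_intervals,
                             cds_sequence) {
  cds_intervals <- as_tibble(cds_intervals)
  stopifnot(all(c("start", "end") %in% names(cds_intervals)),
            strand %in% c("+", "-"))
  if (any(cds_intervals$end < cds_intervals$start))
    abort("cds interval with end < start")
  span <- sum(cds_intervals$end - cds_intervals$start + 1L)
  if (span != nchar(cds_sequence))
    abort(sprintf("interval span (%d) != cds length (%d)", span, nchar(cds_sequence)))
  if (nchar(cds_sequence) %% 3L != 0L)
    abort("cds length not divisible by 3")
  structure(
    list(transcript_id = transcript_id, gene = gene, chrom = as.character(chrom),
         strand = strand, cds_intervals = cds_intervals,
         cds_sequence = toupper(cds_sequence),
         peptide = translate_cds(cds_sequence)),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s strand %s, CDS %d nt, peptide %d aa\n",
              x$transcript_id, x$gene, x$chrom,
              paste(sprintf("%d-%d", x$cds_intervals$start, x$cds_intervals$end),
                    collapse = ","),
              x$strand, nchar(x$cds_sequence), nchar(x$peptide)))
  invisible(x)
}

# 0-based offset into the spliced CDS of a genomic position, or NA when the
# position falls outside every interval. Strand-aware.
cds_offset <- function(model, pos) {
  iv <- model$cds_intervals
  cum <- c(0L, cumsum(iv$end - iv$start + 1L))
  for (i in seq_len(nrow(iv))) {
    if (pos >= iv$start[i] && pos <= iv$end[i]) {
      within <- if (model$strand == "+") pos - iv$start[i] else iv$end[i] - pos
      return(cum[i] + within)
    }
  }
  NA_integer_
}
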