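# Transcript <-> curated-protein reconciliation. Genome annotation moves under
# the pipeline's feet: transcript translations and curated protein sequences
# disagree surprisingly often, and only variants on perfectly cross-referenced
# transcripts proceed to structural work. Everything else is reported and, by
# default, stops the case so the analyst can patch the inputs.

XREF_STATUSES <- c("PERFECT", "LEN_MATCH_SEQ_MISMATCH", "LEN_MISMATCH", "NO_XREF")

#' Classify a transcript/curated sequence pair
#'
#' Pure function of the two peptides: no curated sequence gives `NO_XREF`;
#' identical sequences `PERFECT`; equal length with any mismatch
#' `LEN_MATCH_SEQ_MISMATCH`; different lengths `LEN_MISMATCH`. Vectorised.
#'
#' @param transcript_peptide Character vector of transcript translations.
#' @param curated_peptide Character vector of curated sequences; `NA` = no
#'   cross-reference.
#' @return Character vector of statuses.
#' @export
classify_xref <- function(transcript_peptide, curated_peptide) {
  case_when(
    is.na(curated_peptide) ~ "NO_XREF",
    transcript_peptide == curated_peptide ~ "PERFECT",
    nchar(transcript_peptide) == nchar(curated_peptide) ~ "LEN_MATCH_SEQ_MISMATCH",
    TRUE ~ "LEN_MISMATCH"
  )
}

#' Filter a case to variants on perfectly cross-referenced transcripts
#'
#' Variants whose transcript has status `PERFECT` in the cross-reference
#' catalog are retained; all others are rejected with the status as reason
#' (transcripts absent from the catalog count as `NO_XREF`). Conservation
#' holds: every input variant lands in exactly one of the two outputs.
#'
#' @param case A `vus_case`.
#' @param xrefs Tibble `transcript_id`, `transcript_peptide`,
#'   `curated_peptide` (and optionally a precomputed `status`).
#' @return List with `retained` (a `vus_case`) and `rejected` (tibble of
#'   variant rows plus `reason`).
#' @export
filter_curated <- function(case, xrefs) {
  stopifnot(inherits(case, "vus_case"))
  xrefs <- as_tibble(xrefs)
  if (!"status" %in% names(xrefs)) {
    xrefs <- xrefs %>%
      mutate(status = classify_xref(.data$transcript_peptide, .data$curated_peptide))
  }
  v <- case$variants %>%
    left_join(xrefs %>% select("transcript_id", "status"), by = "transcript_id") %>%
    mutate(status = coalesce(.data$status, "NO_XREF"))
  retained <- v %>% filter(.data$status == "PERFECT") %>% select(-"status")
  rejected <- v %>% filter(.data$status != "PERFECT") %>% rename(reason = "status")
  list(retained = new_case(case$case_id, retained), rejected = rejected)
}

#' Check a variant's reference residue against a peptide
#'
#' Guard used before every downstream stage: the claimed reference amino acid
#' must sit at the claimed 1-based position of the peptide.
#'
#' @param position 1-based residue index (vectorised).
#' @param ref_aa Claimed one-letter reference residue.
#' @param peptide Peptide sequence (scalar or vector).
#' @return Tibble with `status` (`ok`, `mismatch`, `out_of_range`) and
#'   `found` (the residue actually at that position, `NA` if out of range).
#' @export
validate_reference_residue <- function(position, ref_aa, peptide) {
  n <- max(length(position), length(ref_aa), length(peptide))
  position <- rep_len(as.integer(position), n)
  ref_aa <- rep_len(ref_aa, n)
  peptide <- rep_len(peptide, n)
  found <- ifelse(position >= 1L & position <= nchar(peptide),
                  substr(peptide, position, position), NA_character_)
  tibble(
    position = position, ref_aa = ref_aa, found = found,
    status = case_when(
      is.na(found) ~ "out_of_range",
      found == ref_aa ~ "ok",
      TRUE ~ "mismatch"
    )
  )
}

# Map a residue position from one peptide onto another. Fast path: when the
# two peptides agree on their first `pos` residues the mapping is the
# identity (gap-free coordinate check). Otherwise a global pairwise alignment
# (BLOSUM62, gap opening 10, gap extension 0.5) is walked; the position maps
# only if its alignment column pairs two residues (no gap) and the target
# residue equals `ref_aa`.
map_position_between_peptides <- function(pos, ref_aa, from_pep, to_pep) {
  fail <- function(reason) list(position = NA_integer_, reason = reason)
  if (pos > nchar(from_pep) || substr(from_pep, pos, pos) != ref_aa)
    return(fail("reference residue absent on source peptide"))
  if (nchar(to_pep) >= pos &&
      substr(to_pep, 1L, pos) == substr(from_pep, 1L, pos)) {
    return(list(position = pos, reason = NA_character_))
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(from_pep), Biostrings::AAString(to_pep),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  a1 <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  a2 <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  i1 <- cumsum(a1 != "-")
  col <- match(pos, i1)
  if (is.na(col) || a2[col] == "-")
    return(fail("position falls in an alignment gap"))
  if (a2[col] != ref_aa)
    return(fail(sprintf("aligned residue is %s, not %s", a2[col], ref_aa)))
  list(position = cumsum(a2 != "-")[col], reason = NA_character_)
}

#' Expand a variant across a gene's curated splice isoforms
#'
#' Curated non-canonical isoforms carry `-N` suffixed identifiers. The variant
#' (given on the canonical isoform) is re-addressed on every isoform whose
#' peptide carries the reference residue at a mappable position: a gap-free
#' coordinate check first, then global pairwise alignment. Isoforms where the
#' residue is absent or falls in a gap are skipped with a reason.
#'
#' @param variant One-row tibble/list with `position`, `ref_aa`, `alt_aa` and
#'   identifier columns.
#' @param isoforms Tibble `isoform_id`, `peptide`, `is_canonical` — exactly
#'   one canonical row.
#' @return List with `variants` (tibble, one row per mapped isoform, canonical
#'   first) and `skipped` (tibble `isoform_id`, `reason`).
#' @export
expand_isoforms <- function(variant, isoforms) {
  isoforms <- as_tibble(isoforms)
  stopifnot(sum(isoforms$is_canonical) == 1L,
            !anyDuplicated(isoforms$isoform_id))
  canon <- isoforms %>% filter(.data$is_canonical)
  ordered <- bind_rows(canon, isoforms %>% filter(!.data$is_canonical) %>%
                         arrange(isoform_suffix(.data$isoform_id)))
  hits <- map(seq_len(nrow(ordered)), function(i) {
    iso <- ordered[i, ]
    m <- map_position_between_peptides(variant$position, variant$ref_aa,
                                       canon$peptide, iso$peptide)
    tibble(isoform_id = iso$isoform_id, position = m$position,
           reason = m$reason, is_canonical = iso$is_canonical)
  }) %>% list_rbind()
  skipped <- hits %>% filter(is.na(.data$position)) %>%
    select("isoform_id", "reason")
  mapped <- hits %>% filter(!is.na(.data$position))
  if (nrow(mapped) == 0L) {
    abort(sprintf("variant %s maps to no isoform",
                  format_aa_change(variant$ref_aa, variant$position,
                                   variant$alt_aa)),
          class = "vus3d_isoform_disconnect")
  }
  out <- mapped %>%
    mutate(gene = variant$gene %||% NA_character_,
           transcript_id = variant$transcript_id %||% NA_character_,
           protein_id = .data$isoform_id,
           ref_aa = variant$ref_aa, alt_aa = variant$alt_aa,
           inheritance = variant$inheritance %||% "unknown") %>%
    select("gene", "protein_id", "transcript_id", "position", "ref_aa",
           "alt_aa", "inheritance", "is_canonical")
  list(variants = out, skipped = skipped)
}

# "-N" suffix as a sort key; the unsuffixed (or "-1") identifier is canonical.
isoform_suffix <- function(id) {
  out <- rep(1L, length(id))
  m <- grepl("-[0-9]+$", id)
  out[m] <- as.integer(sub("^.*-([0-9]+)$", "\\1", id[m]))
  out
}

#' Build the halt report for unprocessable variants
#'
#' Mirrors the stop-and-let-the-user-patch flow: when any variant cannot be
#' carried forward (no curated cross-reference, sequence disagreement, no
#' isoform mapping) a machine-readable report is produced, grouped by reason
#' class, and the case is marked stopped unless `force = TRUE`, in which case
#' the retained subset proceeds.
#'
#' @param case The original `vus_case`.
#' @param rejections Tibble of rejected variant rows with a `reason` column.
#' @param force Continue with the retained subset instead of stopping?
#' @return Object of class `halt_report` (list: `case_id`, `stopped`,
#'   `by_reason`, `entries`), or `NULL` when there are no rejections.
#' @export
halt_on_disconnect <- function(case, rejections, force = FALSE) {
  if (is.null(rejections) || nrow(rejections) == 0L) return(NULL)
  structure(list(
    case_id = case$case_id,
    stopped = !force,
    by_reason = rejections %>% count(.data$reason, name = "n_variants") %>%
      arrange(.data$reason),
    entries = as_tibble(rejections)
  ), class = "halt_report")
}

#' @export
print.halt_report <- function(x, ...) {
  cat(sprintf("<halt_report> case %s: %d unprocessable variant(s)%s\n",
              x$case_id, nrow(x$entries),
              if (x$stopped) " — pipeline stopped" else " — forced to continue"))
  print(x$by_reason, ...)
  invisible(x)
}

#' Read the cross-reference catalog
#'
#' CSV `transcript_id,protein_id,transcript_peptide,curated_peptide` (empty
#' curated_peptide = no cross-reference); the status column is derived.
#'
#' @param path CSV path.
#' @return Tibble with a computed `status` column.
#' @export
read_xref_catalog <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(.default = readr::col_character())) %>%
    mutate(curated_peptide = ifelse(.data$curated_peptide == "", NA_character_,
                                    .data$curated_peptide),
           status = classify_xref(.data$transcript_peptide, .data$curated_peptide))
}

#' Read an isoform FASTA into an isoform table
#'
#' Headers are protein identifiers, non-canonical ones `-N` suffixed;
#' the unsuffixed (or `-1`) entry is canonical.
#'
#' @param path FASTA path.
#' @return Tibble `protein_id` (base id), `isoform_id`, `peptide`,
#'   `is_canonical`.
#' @export
read_isoform_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- names(seqs)
  tibble(
    isoform_id = ids,
    protein_id = sub("-[0-9]+$", "", ids),
    peptide = as.character(seqs),
    is_canonical = !grepl("-[0-9]+$", ids) | grepl("-1$", ids)
  )
}
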