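# Case ingest: VCF SNVs, consequence calling against toy transcript models,
# and the canonical case CSV (the pipeline-ready flat file every later stage
# consumes).

#' Parse SNVs from a VCF file
#'
#' Reads a VCF and returns one genomic variant per SNV alternate allele.
#' Multi-allelic records are split; records whose REF or ALT is not a single
#' A/C/G/T base (indels, MNVs, symbolic alleles) are returned in a separate
#' `skipped` table with a reason. Parental inheritance is read from an
#' `INH=` INFO key when present, defaulting to `"unknown"`.
#'
#' @param path Path to a VCF file.
#' @return List with `variants` (tibble: `chrom`, `pos`, `ref`, `alt`,
#'   `inheritance`) and `skipped` (tibble: same coordinates plus `reason`).
#' @export
parse_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(sprintf("malformed VCF '%s': %s", path, conditionMessage(e)))
  )
  fix <- as_tibble(as.data.frame(vcfR::getFIX(vcf, getINFO = TRUE),
                                 stringsAsFactors = FALSE))
  if (nrow(fix) == 0L) {
    return(list(variants = empty_genomic_variants(), skipped = empty_skipped()))
  }
  pos_num <- suppressWarnings(as.integer(fix$POS))
  bad <- which(is.na(pos_num) | pos_num < 1L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed VCF '%s': non-positive or non-numeric POS at data row %d",
                  path, bad[1]))
  }
  inh <- extract_inheritance(fix$INFO)

  rows <- pmap(list(fix$CHROM, pos_num, toupper(fix$REF), toupper(fix$ALT), inh),
               function(chrom, pos, ref, alt, inheritance) {
    alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
    map(alts, function(a) {
      reason <- snv_skip_reason(ref, a)
      tibble(chrom = chrom, pos = pos, ref = ref, alt = a,
             inheritance = inheritance, reason = reason)
    }) %>% list_rbind()
  }) %>% list_rbind()

  list(
    variants = rows %>% filter(is.na(.data$reason)) %>% select(-"reason"),
    skipped  = rows %>% filter(!is.na(.data$reason)) %>% select(-"inheritance")
  )
}

empty_genomic_variants <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), inheritance = character())
}
empty_skipped <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), reason = character())
}

snv_skip_reason <- function(ref, alt) {
  if (!is_snv_allele(ref) && !is_snv_allele(alt)) return("not an SNV (ref and alt)")
  if (!is_snv_allele(ref)) return("not an SNV (multi-base or symbolic ref)")
  if (!is_snv_allele(alt)) return("not an SNV (multi-base or symbolic alt)")
  if (ref == alt) return("ref == alt")
  NA_character_
}

extract_inheritance <- function(info) {
  m <- regmatches(info, regexec("(?:^|;)INH=([A-Za-z_]+)", info))
  out <- map_chr(m, ~ if (length(.x) == 2L) .x[2] else NA_character_)
  ifelse(is.na(out) | !(out %in% INHERITANCE_LEVELS), "unknown", out)
}

#' Call the protein-level consequence of one SNV on one transcript
#'
#' Locates the genomic position inside the transcript's CDS intervals
#' (strand-aware; minus-strand alleles are complemented), retranslates the
#' mutated codon with the standard genetic code and classifies the change.
#' Positions outside every CDS interval are `non_coding` (splice and UTR
#' effects are deliberately out of scope).
#'
#' @param v One-row tibble or list with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `inheritance`.
#' @param model A [transcript_model()].
#' @return Tibble with one row: `class` (one of `missense`, `synonymous`,
#'   `nonsense`, `stop_lost`, `non_coding`) plus, for coding classes, the
#'   protein change (`position`, `ref_aa`, `alt_aa`) and identifiers.
#' @export
annotate_consequence <- function(v, model) {
  stopifnot(inherits(model, "transcript_model"))
  base_row <- tibble(
    chrom = as.character(v$chrom), pos = as.integer(v$pos),
    ref = v$ref, alt = v$alt,
    inheritance = if (!is.null(v$inheritance)) v$inheritance else "unknown",
    gene = model$gene, transcript_id = model$transcript_id,
    class = NA_character_, position = NA_integer_,
    ref_aa = NA_character_, alt_aa = NA_character_
  )
  if (!identical(as.character(v$chrom), model$chrom)) {
    base_row$class <- "non_coding"
    return(base_row)
  }
  off <- cds_offset(model, as.integer(v$pos))
  if (is.na(off)) {
    base_row$class <- "non_coding"
    return(base_row)
  }
  coding_ref <- if (model$strand == "+") v$ref else comp_base(v$ref)
  coding_alt <- if (model$strand == "+") v$alt else comp_base(v$alt)
  have <- substr(model$cds_sequence, off + 1L, off + 1L)
  if (have != coding_ref) {
    abort(sprintf(
      "reference mismatch at %s:%d on %s: VCF ref %s (coding-strand %s) vs CDS base %s",
      v$chrom, v$pos, model$transcript_id, v$ref, coding_ref, have),
      class = "vus3d_ref_mismatch")
  }
  codon_i <- off %/% 3L
  frame <- off %% 3L
  codon <- substr(model$cds_sequence, codon_i * 3L + 1L, codon_i * 3L + 3L)
  mutated <- codon
  substr(mutated, frame + 1L, frame + 1L) <- coding_alt
  aa_ref <- unname(Biostrings::GENETIC_CODE[codon])
  aa_alt <- unname(Biostrings::GENETIC_CODE[mutated])
  cls <- if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "nonsense"
    else if (aa_ref == "*") "stop_lost"
    else "missense"
  base_row$class <- cls
  if (cls %in% c("missense", "synonymous", "nonsense", "stop_lost")) {
    base_row$position <- codon_i + 1L
    base_row$ref_aa <- aa_ref
    base_row$alt_aa <- aa_alt
  }
  base_row
}

#' Annotate a table of SNVs against a set of transcript models
#'
#' Each variant is tested against every transcript; one row is returned per
#' variant x transcript whose chromosome matches (including `non_coding` calls),
#' so a variant hitting overlapping transcripts yields several rows.
#'
#' @param variants Tibble from [parse_vcf()].
#' @param transcripts List of [transcript_model()] objects.
#' @return Tibble of consequence rows (see [annotate_consequence()]).
#' @export
annotate_case <- function(variants, transcripts) {
  stopifnot(is.data.frame(variants))
  if (nrow(variants) == 0L) {
    return(annotate_consequence(
      list(chrom = "0", pos = 1L, ref = "A", alt = "C"),
      transcripts[[1]])[0, ])
  }
  out <- map(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    hit <- keep(transcripts, ~ .x$chrom == as.character(v$chrom))
    if (length(hit) == 0L) return(NULL)
    map(hit, ~ annotate_consequence(v, .x)) %>% list_rbind()
  })
  list_rbind(compact(out))
}

# ---- the canonical case object -------------------------------------------

CASE_CSV_COLUMNS <- c("gene", "transcript_id", "protein_id", "aa_change",
                      "inheritance", "provenance")

new_case <- function(case_id, variants) {
  stopifnot(nzchar(case_id))
  structure(list(case_id = case_id, variants = as_tibble(variants)),
            class = "vus_case")
}

#' Build a case from annotated consequences
#'
#' Keeps missense rows only (nonsense/stop-lost/synonymous calls have no
#' downstream structural work), attaches protein identifiers via the
#' transcript-to-protein map, and de-duplicates on
#' (protein_id, position, ref_aa, alt_aa) keeping the first occurrence.
#'
#' @param case_id Non-empty case label.
#' @param consequences Tibble from [annotate_case()].
#' @param protein_map Tibble `transcript_id`, `protein_id`.
#' @return A `vus_case`; duplicate rows dropped are recorded in
#'   `attr(, "duplicates")`.
#' @export
case_from_consequences <- function(case_id, consequences, protein_map) {
  v <- consequences %>%
    filter(.data$class == "missense") %>%
    left_join(protein_map, by = "transcript_id") %>%
    mutate(protein_id = coalesce(.data$protein_id, .data$transcript_id),
           provenance = "genomic") %>%
    select("gene", "protein_id", "transcript_id", "position",
           "ref_aa", "alt_aa", "inheritance", "provenance")
  dedup_case(new_case(case_id, v))
}

dedup_case <- function(case) {
  key <- with(case$variants,
              paste(protein_id, position, ref_aa, alt_aa, sep = "\r"))
  dup <- duplicated(key)
  if (any(dup)) {
    inform(sprintf("case %s: dropped %d duplicate variant row(s)",
                   case$case_id, sum(dup)))
  }
  out <- new_case(case$case_id, case$variants[!dup, ])
  attr(out, "duplicates") <- case$variants[dup, ]
  out
}

#' @export
print.vus_case <- function(x, ...) {
  cat(sprintf("<vus_case> %s: %d variant(s) on %d protein(s)\n",
              x$case_id, nrow(x$variants), n_distinct(x$variants$protein_id)))
  print(x$variants, ...)
  invisible(x)
}

#' @describeIn case_from_consequences Tidy a case into its variant tibble.
#' @param x A `vus_case`.
#' @param ... Unused.
#' @export
tidy.vus_case <- function(x, ...) x$variants

#' Read the case CSV dialect
#'
#' The pipeline-ready flat file: columns
#' `gene,transcript_id,protein_id,aa_change,inheritance` (plus an optional
#' `provenance` column), comma-delimited, UTF-8. The amino-acid change is
#' accepted in compact form (`C282Y`) or as split columns
#' `ref_aa`,`position`,`alt_aa`. Unknown or empty inheritance defaults to
#' `"unknown"`. Rows whose change string does not parse are excluded and
#' reported in `attr(, "row_errors")`; the rest of the case still loads.
#'
#' @param path CSV path.
#' @param case_id Case label; defaults to the file stem.
#' @return A `vus_case`.
#' @export
parse_case_csv <- function(path, case_id = NULL) {
  if (!file.exists(path)) abort(sprintf("case CSV not found: %s", path))
  case_id <- case_id %||% sub("\\.csv$", "", basename(path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!"gene" %in% names(raw)) abort("case CSV must carry a header with a 'gene' column")
  n <- nrow(raw)
  get_col <- function(nm, default = NA_character_) {
    if (nm %in% names(raw)) raw[[nm]] else rep(default, n)
  }
  if ("aa_change" %in% names(raw)) {
    parsed <- parse_aa_change(get_col("aa_change"))
  } else if (all(c("ref_aa", "position", "alt_aa") %in% names(raw))) {
    parsed <- tibble(ref_aa = raw$ref_aa,
                     position = suppressWarnings(as.integer(raw$position)),
                     alt_aa = raw$alt_aa) %>%
      mutate(ok = .data$ref_aa %in% AA_ALPHABET & .data$alt_aa %in% AA_ALPHABET &
               !is.na(.data$position) & .data$position >= 1L &
               .data$ref_aa != .data$alt_aa)
  } else {
    abort("case CSV needs an 'aa_change' column or ref_aa/position/alt_aa columns")
  }
  inheritance <- get_col("inheritance")
  inheritance[is.na(inheritance) |
                !(inheritance %in% INHERITANCE_LEVELS)] <- "unknown"
  v <- tibble(
    gene = get_col("gene"),
    protein_id = coalesce(get_col("protein_id"), get_col("transcript_id")),
    transcript_id = get_col("transcript_id"),
    position = parsed$position, ref_aa = parsed$ref_aa, alt_aa = parsed$alt_aa,
    inheritance = inheritance,
    provenance = coalesce(get_col("provenance"), "proteomic"),
    .row = seq_len(n), .ok = parsed$ok
  )
  errors <- v %>% filter(!.data$.ok) %>%
    transmute(row = .data$.row,
              reason = "unparseable amino-acid change")
  if (nrow(errors) > 0L) {
    warn(sprintf("case CSV %s: %d row(s) excluded (unparseable amino-acid change)",
                 basename(path), nrow(errors)))
  }
  out <- dedup_case(new_case(case_id, v %>% filter(.data$.ok) %>%
                               select(-".row", -".ok")))
  attr(out, "row_errors") <- errors
  out
}

#' Write the case CSV dialect
#'
#' Fixed column order `gene,transcript_id,protein_id,aa_change,inheritance,`
#' `provenance`; the emitted file re-parses to an equal case (round-trip
#' identity), whatever mix of genomic- and protein-provenance variants it
#' holds.
#'
#' @param case A `vus_case`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_case_csv <- function(case, path) {
  stopifnot(inherits(case, "vus_case"))
  v <- case$variants
  out <- tibble(
    gene = v$gene, transcript_id = v$transcript_id, protein_id = v$protein_id,
    aa_change = format_aa_change(v$ref_aa, v$position, v$alt_aa),
    inheritance = v$inheritance, provenance = v$provenance
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Import a pre-annotated consequence table
#'
#' Drop-in path for real annotation output: a CSV with at least
#' `transcript_id,position,ref_aa,alt_aa` (optionally `gene`, `protein_id`,
#' `inheritance`). All rows are treated as missense protein variants.
#'
#' @param path CSV path.
#' @param case_id Case label.
#' @return A `vus_case`.
#' @export
parse_annotated_csv <- function(path, case_id = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("transcript_id", "position", "ref_aa", "alt_aa")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L)
    abort(sprintf("pre-annotated table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  case_id <- case_id %||% sub("\\.csv$", "", basename(path))
  v <- tibble(
    gene = if ("gene" %in% names(raw)) as.character(raw$gene) else raw$transcript_id,
    protein_id = if ("protein_id" %in% names(raw)) as.character(raw$protein_id)
                 else raw$transcript_id,
    transcript_id = as.character(raw$transcript_id),
    position = as.integer(raw$position),
    ref_aa = as.character(raw$ref_aa), alt_aa = as.character(raw$alt_aa),
    inheritance = if ("inheritance" %in% names(raw))
      ifelse(raw$inheritance %in% INHERITANCE_LEVELS, raw$inheritance, "unknown")
      else "unknown",
    provenance = "pre_annotated"
  )
  dedup_case(new_case(case_id, v))
}
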