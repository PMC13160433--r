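# Precomputed per-residue score ingestion. Substitution scores (AlphaMissense
# style) key on (protein, position, alt residue); constraint scores (ConSurf/
# Rate4Site or COSMIS style) key on (protein, position). Values are looked up
# exactly and never imputed: an absent value is reported absent.

#' Load a precomputed score table
#'
#' Tab- or comma-delimited (sniffed from the first line), columns
#' `protein_id,position[,alt_aa],value`. The declared keying decides whether
#' `alt_aa` is part of the key (`"alt"`) or ignored (`"position"`). Duplicate
#' keys are an error naming the key; rows failing key validation (missing
#' fields, non-positive positions, non-numeric values) are dropped and counted
#' in `attr(, "n_invalid")`.
#'
#' @param path Table path.
#' @param keying `"alt"` (substitution scores) or `"position"` (constraint
#'   scores).
#' @param score_name Name the values are reported under; defaults to the file
#'   stem.
#' @return A `score_table` tibble with attributes `score_name`, `keying`,
#'   `provenance`.
#' @export
load_score_table <- function(path, keying = c("alt", "position"),
                             score_name = NULL) {
  keying <- match.arg(keying)
  if (!file.exists(path)) abort(sprintf("score table not found: %s", path))
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  need <- c("protein_id", "position", "value",
            if (keying == "alt") "alt_aa")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L)
    abort(sprintf("score table %s lacks column(s): %s", basename(path),
                  paste(missing_cols, collapse = ", ")))
  tbl <- tibble(
    protein_id = raw$protein_id,
    position = suppressWarnings(as.integer(raw$position)),
    alt_aa = if (keying == "alt") raw$alt_aa else NA_character_,
    value = suppressWarnings(as.numeric(raw$value))
  )
  valid <- !is.na(tbl$protein_id) & !is.na(tbl$position) & tbl$position >= 1L &
    !is.na(tbl$value) & (keying == "position" | tbl$alt_aa %in% AA_ALPHABET)
  n_invalid <- sum(!valid)
  if (n_invalid > 0L)
    warn(sprintf("score table %s: %d invalid row(s) dropped",
                 basename(path), n_invalid))
  tbl <- tbl[valid, ]
  key <- if (keying == "alt")
    paste(tbl$protein_id, tbl$position, tbl$alt_aa) else
    paste(tbl$protein_id, tbl$position)
  if (anyDuplicated(key)) {
    abort(sprintf("score table %s: duplicate key '%s'", basename(path),
                  key[duplicated(key)][1]))
  }
  out <- structure(tbl, class = c("score_table", class(tbl)))
  attr(out, "score_name") <- score_name %||%
    sub("\\.(tsv|csv|txt)$", "", basename(path))
  attr(out, "keying") <- keying
  attr(out, "provenance") <- basename(path)
  attr(out, "n_invalid") <- n_invalid
  out
}

#' Resolve precomputed scores for variants
#'
#' Exact-key lookup of each variant in each table; absent values are reported
#' as `NA`, never imputed. Precomputations cover canonical sequences only, so
#' an isoform-suffixed protein id misses by default; `canonical_fallback =
#' TRUE` retries the unsuffixed id and marks the provenance accordingly.
#'
#' @param variants Tibble with `protein_id`, `position` and (for
#'   substitution tables) `alt_aa`.
#' @param tables List of `score_table`s from [load_score_table()].
#' @param canonical_fallback Retry isoform-suffixed ids with the canonical id?
#' @return Tibble: variant key columns x `score_name`, `value`, `provenance`
#'   (long form, one row per variant per table).
#' @export
lookup_scores <- function(variants, tables, canonical_fallback = FALSE) {
  variants <- as_tibble(variants)
  map(tables, function(tb) {
    keying <- attr(tb, "keying")
    nm <- attr(tb, "score_name")
    lookup_one <- function(pid, pos, alt) {
      hit <- tb[tb$protein_id == pid & tb$position == pos &
                  (keying == "position" | tb$alt_aa == alt), , drop = FALSE]
      if (nrow(hit) == 1L) hit$value else NA_real_
    }
    res <- map_dbl(seq_len(nrow(variants)), function(i) {
      lookup_one(variants$protein_id[i], variants$position[i],
                 variants$alt_aa[i] %||% NA_character_)
    })
    prov <- rep(attr(tb, "provenance"), nrow(variants))
    if (canonical_fallback) {
      for (i in which(is.na(res))) {
        base_id <- sub("-[0-9]+$", "", variants$protein_id[i])
        if (base_id != variants$protein_id[i]) {
          v2 <- lookup_one(base_id, variants$position[i],
                           variants$alt_aa[i] %||% NA_character_)
          if (!is.na(v2)) {
            res[i] <- v2
            prov[i] <- paste0(prov[i], " (canonical fallback)")
          }
        }
      }
    }
    variants %>%
      select(any_of(c("protein_id", "position", "alt_aa"))) %>%
      mutate(score_name = nm, value = res, provenance = prov)
  }) %>% list_rbind()
}
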