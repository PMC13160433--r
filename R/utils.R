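# Shared helpers: genetic code, sequence utilities, path sanitisation, hashing.

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

INHERITANCE_LEVELS <- c("maternal", "paternal", "de_novo", "unknown")

#' Translate a coding DNA sequence to one-letter amino acids
#'
#' Standard genetic code only. Stop codons translate to `*`; a single trailing
#' stop is removed when `strip_stop = TRUE`.
#'
#' @param dna Character scalar of A/C/G/T, length divisible by 3.
#' @param strip_stop Drop a trailing `*`?
#' @return Character scalar peptide.
#' @export
translate_cds <- function(dna, strip_stop = TRUE) {
  stopifnot(is.character(dna), length(dna) == 1L)
  n <- nchar(dna)
  if (n %% 3L != 0L) abort("coding sequence length must be divisible by 3")
  codons <- substring(dna, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) abort("coding sequence contains a non-ACGT codon")
  pep <- paste(aa, collapse = "")
  if (strip_stop) pep <- sub("\\*$", "", pep)
  pep
}

#' Reverse-complement a DNA string
#' @param dna Character scalar over A/C/G/T.
#' @return Character scalar.
#' @export
revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

is_snv_allele <- function(x) grepl("^[ACGT]$", x)

#' Sanitise a string for use as a path component
#'
#' Replaces every character outside `[A-Za-z0-9._-]` with `_`. Used for all
#' identifiers entering the case directory hierarchy.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
sanitize_path_component <- function(x) {
  out <- gsub("[^A-Za-z0-9._-]", "_", x)
  out[out == "" | is.na(out)] <- "_"
  out
}

# 32-bit FNV-1a over UTF-8 bytes, in double arithmetic (exact below 2^53).
# The xor touches only the low 16 bits of the state, so split hi/lo words.
hash_string <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 2^16
    hi <- h %/% 2^16
    lo <- bitwXor(as.integer(lo), b)
    h <- (hi * 2^16 + lo) * 16777619
    h <- h %% 2^32
  }
  h
}

#' Deterministic pseudo-score in [0, 1] from a string key
#'
#' FNV-1a hash mapped to the unit interval; the basis of the stub executors'
#' reproducible outputs.
#'
#' @param key Character scalar.
#' @return Numeric scalar in \[0, 1).
#' @export
hash_unit <- function(key) hash_string(key) / 2^32

#' Generate a version-4 UUID from R's RNG
#'
#' Draws 16 bytes from the current RNG stream, sets the version/variant bits
#' and formats 8-4-4-4-12. Deterministic under a fixed seed, which is what the
#' planner's byte-identity guarantees rely on.
#'
#' @return Character scalar UUID.
#' @export
make_guid <- function() {
  bytes <- sample.int(256L, 16L, replace = TRUE) - 1L
  bytes[7L] <- bitwOr(bitwAnd(bytes[7L], 15L), 64L)   # version 4
  bytes[9L] <- bitwOr(bitwAnd(bytes[9L], 63L), 128L)  # variant 10xx
  hex <- sprintf("%02x", bytes)
  paste0(paste(hex[1:4], collapse = ""), "-", paste(hex[5:6], collapse = ""), "-",
         paste(hex[7:8], collapse = ""), "-", paste(hex[9:10], collapse = ""), "-",
         paste(hex[11:16], collapse = ""))
}

#' Format an amino-acid change in compact HGVS-like form
#' @param ref_aa,position,alt_aa Vectors of equal length.
#' @return Character vector like `"C282Y"`.
#' @export
format_aa_change <- function(ref_aa, position, alt_aa) {
  paste0(ref_aa, position, alt_aa)
}

#' Parse a compact amino-acid change string
#'
#' @param x Character vector like `"C282Y"`.
#' @return Tibble with `ref_aa`, `position`, `alt_aa`; a row of `NA`s where the
#'   string does not parse.
#' @export
parse_aa_change <- function(x) {
  m <- regmatches(x, regexec("^([A-Z])([0-9]+)([A-Z])$", x))
  tibble(
    ref_aa   = map_chr(m, ~ if (length(.x) == 4L) .x[2] else NA_character_),
    position = map_int(m, ~ if (length(.x) == 4L) as.integer(.x[3]) else NA_integer_),
    alt_aa   = map_chr(m, ~ if (length(.x) == 4L) .x[4] else NA_character_)
  ) %>%
    mutate(ok = !is.na(.data$ref_aa) & !is.na(.data$alt_aa) &
             .data$ref_aa %in% AA_ALPHABET & .data$alt_aa %in% AA_ALPHABET &
             .data$ref_aa != .data$alt_aa & .data$position >= 1L)
}

write_lines_utf8 <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
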