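# Shared builders for the test-suite. Everything is generated in code; no
# binary fixtures.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
  library(purrr)
})

# plus-strand toy transcript: CDS "ATGGCTTAA" (Met-Ala-stop) at chr1:101-109
toy_plus_model <- function() {
  transcript_model("Tplus", "TOY", "chr1", "+",
                   tibble(start = 101L, end = 109L), "ATGGCTTAA")
}

# the mirrored minus-strand transcript: same CDS, genomic sequence reverse-
# complemented onto chr1m:201-209
toy_minus_model <- function() {
  transcript_model("Tminus", "TOY", "chr1m", "-",
                   tibble(start = 201L, end = 209L), "ATGGCTTAA")
}

write_vcf_lines <- function(records, path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=INH,Number=1,Type=String,Description=\"Parental inheritance\">",
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO"), collapse = "\t")),
    records), path)
  path
}

random_case <- function(n, case_id = "rand") {
  genes <- sprintf("G%02d", sample.int(20, n, replace = TRUE))
  ref <- sample(vus3d:::AA_ALPHABET, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(vus3d:::AA_ALPHABET, r), 1),
                character(1))
  v <- tibble(
    gene = genes,
    protein_id = paste0("P", sprintf("%05d", sample.int(99999, n))),
    transcript_id = paste0("T", sprintf("%05d", sample.int(99999, n))),
    position = sample.int(500, n, replace = TRUE),
    ref_aa = ref, alt_aa = unname(alt),
    inheritance = sample(vus3d:::INHERITANCE_LEVELS, n, replace = TRUE),
    provenance = sample(c("genomic", "proteomic"), n, replace = TRUE)
  )
  v <- v[!duplicated(paste(v$protein_id, v$position, v$ref_aa, v$alt_aa)), ]
  vus3d:::new_case(case_id, v)
}

# random transcript model for consequence-oracle sweeps
random_model <- function(id) {
  len <- sample(10:60, 1)
  pep <- paste0("M", paste(sample(vus3d:::AA_ALPHABET, len - 1, replace = TRUE),
                           collapse = ""))
  cds <- vus3d:::back_translate(pep)
  strand <- sample(c("+", "-"), 1)
  n <- nchar(cds)
  gstart <- sample(100:2000, 1)
  if (runif(1) < 0.5) {
    iv <- tibble(start = gstart, end = gstart + n - 1L)
  } else {
    cut <- sample(seq(1L, n - 1L), 1)
    iv <- bind_rows(tibble(start = gstart, end = gstart + cut - 1L),
                    tibble(start = gstart + cut + 37L,
                           end = gstart + cut + 37L + (n - cut) - 1L))
  }
  if (strand == "-") iv <- iv[rev(seq_len(nrow(iv))), ]
  transcript_model(paste0("TR", id), paste0("GR", id), paste0("c", id),
                   strand, iv, cds)
}

# random structure-selection instance: candidates + alignments over a peptide
# of length `len`, residue maps as single full-interval segments
random_selection_instance <- function(n_cand, len = 100) {
  rows <- map(seq_len(n_cand), function(i) {
    source <- sample(vus3d:::STRUCT_SOURCES, 1)
    method <- if (source == "PDB") sample(c("xray", "cryoem", "nmr"), 1) else "model"
    quality <- if (method == "model") round(runif(1, 40, 99), 2) else
      round(runif(1, 1.2, 4.5), 2)
    cov_len <- sample(10:len, 1)
    cov_start <- sample.int(len - cov_len + 1L, 1)
    list(
      cand = tibble(protein_id = "P1", structure_id = sprintf("S%02d", i),
                    source = source, method = method, quality = quality,
                    oligomeric_state = sample(1:2, 1),
                    coords_path = NA_character_),
      align = tibble(structure_id = sprintf("S%02d", i), chain = "A",
                     seg_start_transcript = cov_start, seg_start_residue = 1L,
                     seg_length = cov_len))
  })
  list(candidates = map(rows, "cand") %>% list_rbind(),
       alignments = map(rows, "align") %>% list_rbind(),
       position = sample.int(len, 1))
}

# exhaustive oracle: best total utility over all ordered subsets of size <= k
brute_force_selection <- function(candidates, alignments, position, max_k) {
  ids <- candidates$structure_id
  cov_index <- vus3d:::coverage_index(alignments)
  best <- 0
  best_set <- character()
  for (k in seq_len(min(max_k, length(ids)))) {
    subsets <- utils::combn(ids, k, simplify = FALSE)
    for (s in subsets) {
      if (!selection_feasible(s, candidates, alignments, position,
                              cov_index = cov_index)) next
      perms <- if (length(s) == 1L) list(s) else {
        idx <- gtools_permutations(length(s))
        lapply(seq_len(nrow(idx)), function(r) s[idx[r, ]])
      }
      for (p in perms) {
        u <- selection_sequence_utility(p, candidates, alignments, position,
                                        cov_index = cov_index)
        if (u > best) { best <- u; best_set <- p }
      }
    }
  }
  list(utility = best, set = best_set)
}

# all permutations of 1..n as a matrix (n <= 3 in practice)
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- gtools_permutations(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow = nrow(sub))))
  }
  unname(out)
}

# helix-based labeled-site configuration for clustering tests
random_site_config <- function(n_res = 80, n_path = 6, n_ben = 6) {
  co <- vus3d:::helix_coords(n_res) %>%
    mutate(chain = "A", residue = seq_len(n_res))
  idx <- sample.int(n_res, n_path + n_ben)
  sites <- co[idx, ] %>%
    mutate(label = rep(c("pathogenic", "benign"), c(n_path, n_ben)))
  qi <- sample(setdiff(seq_len(n_res), idx), 1)
  list(coords = co,
       sites = sites %>% select(chain, residue, label, x, y, z),
       query = list(chain = "A", residue = co$residue[qi],
                    x = co$x[qi], y = co$y[qi], z = co$z[qi]))
}

swap_labels <- function(sites) {
  sites %>% mutate(label = ifelse(label == "pathogenic", "benign", "pathogenic"))
}

# small ready-to-run case bundle: transcriptome, case, structures, sites
mini_bundle <- function(seed = 11, n_genes = 3, n_missense = 3, dir = NULL) {
  spec <- fixture_spec(seed = seed, n_genes = n_genes, n_missense = n_missense,
                       xref_class_mix = c(PERFECT = 1, LEN_MATCH_SEQ_MISMATCH = 0,
                                          LEN_MISMATCH = 0, NO_XREF = 0))
  tx <- make_transcriptome(spec)
  dir <- dir %||% withr::local_tempdir(.local_envir = parent.frame())
  cs <- make_case(spec, tx, dir)
  pv <- parse_vcf(cs$vcf)
  ann <- annotate_case(pv$variants, tx$transcripts)
  case <- case_from_consequences("demo", ann, tx$protein_map)
  structs <- map(seq_len(nrow(tx$isoforms)), function(i)
    make_structures(spec, tx$isoforms$isoform_id[i], tx$isoforms$peptide[i],
                    file.path(dir, "pdb")))
  structures <- list(catalog = map(structs, "catalog") %>% list_rbind(),
                     alignments = map(structs, "alignments") %>% list_rbind())
  sites_dir <- file.path(dir, "sites")
  dir.create(sites_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(structures$catalog))) {
    co <- read_calpha(structures$catalog$coords_path[i])
    pl <- tryCatch(plant_clusters(
      co, list(n_pathogenic = 5, n_benign = 5, cluster_radius = 10,
               separation = 15),
      seed = 100 + i, structure_id = structures$catalog$structure_id[i]),
      error = function(e) NULL)
    if (!is.null(pl))
      readr::write_csv(pl$sites, file.path(
        sites_dir, paste0(structures$catalog$structure_id[i], ".csv")))
  }
  list(spec = spec, tx = tx, case = case, case_files = cs,
       structures = structures, sites_dir = sites_dir, dir = dir)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
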