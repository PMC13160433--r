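# Synthetic-fixture generation. Everything the pipeline consumes can be
# generated offline with controlled properties: toy transcriptomes with a
# planted mix of transcript/curated-sequence discrepancy classes, ideal-helix
# structures of known coverage, quality and multimericity, spatially planted
# pathogenic/benign site clusters with a ground-truth sidecar, and
# VCF + expected-case + score-table bundles whose expectations come from a
# full-sequence translation oracle independent of the consequence caller.

#' Specification for fixture generation
#'
#' Defaults define the standing study conditions of the test-suite. The
#' cross-reference class mix echoes the proportions observed between genome
#' annotation releases and curated proteomes (the perfect class dominating,
#' a substantial no-cross-reference class, and small same-length-mismatch /
#' length-mismatch classes); cluster geometry defaults give a tight (8 A)
#' pathogenic cluster well separated (20 A) from benign sites on helices of
#' 60-120 residues.
#'
#' @param seed Integer master seed; identical spec + seed gives identical
#'   fixture bytes.
#' @param n_genes Number of toy genes.
#' @param isoforms_per_gene Curated isoforms per gene (1 = canonical only).
#' @param xref_class_mix Named proportions over
#'   `PERFECT, LEN_MATCH_SEQ_MISMATCH, LEN_MISMATCH, NO_XREF`; must sum to 1.
#'   Planted counts are exact (largest-remainder rounding).
#' @param peptide_length Length-2 range of peptide lengths.
#' @param structures_per_protein Candidate structures generated per protein.
#' @param cluster_geometry List `n_pathogenic`, `n_benign`, `cluster_radius`
#'   (A), `separation` (A); `separation = 0` is the null geometry (both
#'   labels placed uniformly).
#' @param n_missense Missense SNVs the generated case should contain.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1,
                         n_genes = 6,
                         isoforms_per_gene = 2,
                         xref_class_mix = c(PERFECT = 0.83,
                                            LEN_MATCH_SEQ_MISMATCH = 0.02,
                                            LEN_MISMATCH = 0.01,
                                            NO_XREF = 0.14),
                         peptide_length = c(60, 120),
                         structures_per_protein = 3,
                         cluster_geometry = list(n_pathogenic = 8, n_benign = 8,
                                                 cluster_radius = 8,
                                                 separation = 20),
                         n_missense = 5) {
  stopifnot(abs(sum(xref_class_mix) - 1) < 1e-9, n_genes >= 1,
            all(xref_class_mix >= 0),
            setequal(names(xref_class_mix), XREF_STATUSES))
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 isoforms_per_gene = as.integer(isoforms_per_gene),
                 xref_class_mix = xref_class_mix,
                 peptide_length = as.integer(peptide_length),
                 structures_per_protein = as.integer(structures_per_protein),
                 cluster_geometry = cluster_geometry,
                 n_missense = as.integer(n_missense)),
            class = "fixture_spec")
}

# Exact planted counts from proportions (largest remainder).
planted_counts <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0L) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

random_peptide <- function(len) {
  paste0("M", paste(sample(AA_ALPHABET, len - 1L, replace = TRUE), collapse = ""))
}

CODONS_BY_AA <- split(names(Biostrings::GENETIC_CODE),
                      unname(Biostrings::GENETIC_CODE))

back_translate <- function(peptide) {
  aas <- strsplit(peptide, "")[[1]]
  codons <- map_chr(aas, ~ sample(CODONS_BY_AA[[.x]], 1L))
  paste0(paste(codons, collapse = ""), sample(CODONS_BY_AA[["*"]], 1L))
}

#' Generate a toy transcriptome with a planted discrepancy-class mix
#'
#' One transcript per gene on its own chromosome, alternating strands, and
#' alternating single- and two-exon CDS layouts to exercise interval
#' arithmetic. Cross-reference classes are planted exactly per the spec's
#' mix: `PERFECT` records copy the transcript translation; same-length
#' mismatches substitute one residue; length mismatches drop the last
#' residue; `NO_XREF` records carry no curated sequence. Non-canonical `-N`
#' isoforms alternate between a C-terminal extension and an internal
#' deletion of the canonical peptide.
#'
#' @param spec A [fixture_spec()].
#' @return List: `transcripts` (named list of [transcript_model()]),
#'   `xref` (catalog tibble with `planted_status`), `isoforms` (tibble),
#'   `protein_map` (tibble `transcript_id`, `protein_id`).
#' @export
make_transcriptome <- function(spec) {
  with_seed(spec$seed, {
    classes <- rep(XREF_STATUSES,
                   planted_counts(spec$xref_class_mix[XREF_STATUSES],
                                  spec$n_genes))
    classes <- sample(classes)
    out <- map(seq_len(spec$n_genes), function(g) {
      gene <- sprintf("GENE%02d", g)
      tid <- sprintf("T%03d", g)
      pid <- sprintf("P%05d", g)
      len <- sample(seq(spec$peptide_length[1], spec$peptide_length[2]), 1L)
      pep <- random_peptide(len)
      cds <- back_translate(pep)
      strand <- if (g %% 2L == 1L) "+" else "-"
      chrom <- paste0("chr", g)
      n <- nchar(cds)
      gstart <- 1000L
      if (g %% 3L == 0L) {
        iv <- tibble(start = gstart, end = gstart + n - 1L)
      } else {
        # two exons with a 50 nt intron; split off frame boundaries on purpose
        cut <- (n %/% 2L) + 1L
        e1 <- tibble(start = gstart, end = gstart + cut - 1L)
        e2 <- tibble(start = gstart + cut + 50L, end = gstart + cut + 50L + (n - cut) - 1L)
        iv <- bind_rows(e1, e2)
      }
      if (strand == "-") iv <- iv[rev(seq_len(nrow(iv))), ]
      model <- transcript_model(tid, gene, chrom, strand, iv, cds)
      cls <- classes[g]
      curated <- switch(cls,
        PERFECT = pep,
        LEN_MATCH_SEQ_MISMATCH = {
          p <- sample(2:len, 1L)
          cur <- pep
          substr(cur, p, p) <- sample(setdiff(AA_ALPHABET, substr(pep, p, p)), 1L)
          cur
        },
        LEN_MISMATCH = substr(pep, 1L, len - 1L),
        NO_XREF = NA_character_)
      isoforms <- tibble(protein_id = pid, isoform_id = pid, peptide = pep,
                         is_canonical = TRUE)
      if (spec$isoforms_per_gene >= 2L) {
        extra <- map(2:spec$isoforms_per_gene, function(k) {
          iso_pep <- if (k %% 2L == 0L) {
            paste0(pep, paste(rep("GS", 5L), collapse = ""))
          } else {
            # internal deletion of 10 residues around the middle
            mid <- len %/% 2L
            paste0(substr(pep, 1L, mid - 5L), substr(pep, mid + 6L, len))
          }
          tibble(protein_id = pid, isoform_id = paste0(pid, "-", k),
                 peptide = iso_pep, is_canonical = FALSE)
        }) %>% list_rbind()
        isoforms <- bind_rows(isoforms, extra)
      }
      list(model = model,
           xref = tibble(transcript_id = tid, protein_id = pid,
                         transcript_peptide = pep, curated_peptide = curated,
                         planted_status = cls),
           isoforms = isoforms)
    })
    transcripts <- map(out, "model")
    names(transcripts) <- map_chr(transcripts, "transcript_id")
    xref <- map(out, "xref") %>% list_rbind()
    list(transcripts = transcripts, xref = xref,
         isoforms = map(out, "isoforms") %>% list_rbind(),
         protein_map = xref %>% select("transcript_id", "protein_id"))
  })
}

#' Write transcriptome fixture files
#' @param tx [make_transcriptome()] output.
#' @param dir Output directory.
#' @return Invisible list of written paths (`xref`, `fasta`).
#' @export
write_transcriptome <- function(tx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xref_path <- file.path(dir, "xref_catalog.csv")
  readr::write_csv(tx$xref %>% select(-"planted_status") %>%
                     mutate(curated_peptide = ifelse(is.na(.data$curated_peptide),
                                                     "", .data$curated_peptide)),
                   xref_path, progress = FALSE)
  fasta_path <- file.path(dir, "isoforms.fasta")
  seqs <- Biostrings::AAStringSet(setNames(tx$isoforms$peptide,
                                           tx$isoforms$isoform_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(list(xref = xref_path, fasta = fasta_path))
}

# Ideal alpha-helix C-alpha trace: 1.5 A rise and 100 deg turn per residue on
# a 2.3 A radius. Geometry only has to support distances and coverage, not
# realistic folds.
helix_coords <- function(n, origin = c(0, 0, 0)) {
  i <- seq_len(n)
  theta <- i * 100 * pi / 180
  tibble(x = origin[1] + 2.3 * cos(theta),
         y = origin[2] + 2.3 * sin(theta),
         z = origin[3] + 1.5 * i)
}

#' Generate synthetic structures and catalogs for one protein
#'
#' Each structure is an ideal-helix C-alpha trace over a random coverage
#' interval of the peptide, with source/method/quality and oligomeric state
#' drawn per structure: experimental entries get a resolution in 1.5-3.5 A,
#' models a confidence in 50-95; about a third are homodimers (second
#' protomer translated 30 A in x). AlphaFold-style entries cover the full
#' peptide. Structure residues are numbered from 1 within each chain; every
#' other structure's alignment is split into two segments around a 3-residue
#' unmapped gap to exercise segment arithmetic.
#'
#' @param spec A [fixture_spec()].
#' @param protein_id Protein the structures model.
#' @param peptide Peptide sequence (its length bounds coverage).
#' @param dir Directory PDB files are written into.
#' @param seed Seed for this protein's draws (default derives from the spec
#'   seed and the protein id).
#' @return List `catalog` (structure catalog tibble), `alignments` (segment
#'   tibble), `paths` (PDB paths).
#' @export
make_structures <- function(spec, protein_id, peptide, dir,
                            seed = spec$seed + hash_string(protein_id) %% 10000L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  len <- nchar(peptide)
  with_seed(seed, {
    out <- map(seq_len(spec$structures_per_protein), function(s) {
      sid <- sprintf("%s_S%02d", protein_id, s)
      source <- sample(STRUCT_SOURCES, 1L,
                       prob = c(0.4, 0.2, 0.2, 0.2))
      method <- if (source == "PDB") sample(c("xray", "cryoem", "nmr"), 1L,
                                            prob = c(0.6, 0.3, 0.1)) else "model"
      quality <- if (method == "model") round(runif(1, 50, 95), 2) else
        round(runif(1, 1.5, 3.5), 2)
      olig <- sample(1:2, 1L, prob = c(0.7, 0.3))
      if (source == "ALPHAFOLD") {
        cov_start <- 1L; cov_end <- len
      } else {
        cov_len <- sample(seq(min(30L, len), len), 1L)
        cov_start <- sample(seq_len(len - cov_len + 1L), 1L)
        cov_end <- cov_start + cov_len - 1L
      }
      n_res <- cov_end - cov_start + 1L
      chains <- LETTERS[seq_len(olig)]
      coords <- map(seq_along(chains), function(ci) {
        helix_coords(n_res, origin = c(30 * (ci - 1L), 0, 0)) %>%
          mutate(chain = chains[ci], residue = seq_len(n_res))
      }) %>% list_rbind()
      pdb_path <- file.path(dir, paste0(sid, ".pdb"))
      resid_codes <- c(A="ALA",C="CYS",D="ASP",E="GLU",F="PHE",G="GLY",H="HIS",
                       I="ILE",K="LYS",L="LEU",M="MET",N="ASN",P="PRO",Q="GLN",
                       R="ARG",S="SER",T="THR",V="VAL",W="TRP",Y="TYR")
      aa_seq <- strsplit(substr(peptide, cov_start, cov_end), "")[[1]]
      bio3d::write.pdb(file = pdb_path,
                       xyz = as.numeric(t(as.matrix(coords[, c("x", "y", "z")]))),
                       resno = coords$residue,
                       chain = coords$chain,
                       resid = rep(resid_codes[aa_seq], length(chains)),
                       elety = rep("CA", nrow(coords)),
                       o = rep(1, nrow(coords)),
                       b = rep(0, nrow(coords)))
      split_seg <- s %% 2L == 0L && n_res >= 20L
      aligns <- map(chains, function(ch) {
        if (split_seg) {
          half <- n_res %/% 2L
          tibble(structure_id = sid, chain = ch,
                 seg_start_transcript = c(cov_start, cov_start + half + 3L),
                 seg_start_residue = c(1L, half + 4L),
                 seg_length = c(half, n_res - half - 3L))
        } else {
          tibble(structure_id = sid, chain = ch,
                 seg_start_transcript = cov_start,
                 seg_start_residue = 1L, seg_length = n_res)
        }
      }) %>% list_rbind()
      list(catalog = tibble(protein_id = protein_id, structure_id = sid,
                            source = source, method = method, quality = quality,
                            oligomeric_state = olig, coords_path = pdb_path),
           alignments = aligns)
    })
    list(catalog = map(out, "catalog") %>% list_rbind(),
         alignments = map(out, "alignments") %>% list_rbind(),
         paths = map_chr(out, ~ .x$catalog$coords_path))
  })
}

#' Plant labeled spatial clusters on a structure
#'
#' Picks a cluster centre among the chain-A residues, places pathogenic sites
#' within `cluster_radius` of it and benign sites at `>= separation` from it.
#' `separation = 0` is the null geometry: both labels are drawn uniformly
#' (without replacement) over all residues. A ground-truth sidecar records
#' the centre and memberships. Unsatisfiable geometry errors with the
#' achievable separations.
#'
#' @param coords C-alpha tibble (see [read_calpha()]); chain A is used.
#' @param geometry List `n_pathogenic`, `n_benign`, `cluster_radius`,
#'   `separation` (Angstrom).
#' @param seed Integer seed.
#' @param structure_id Recorded in the site table.
#' @return List `sites` (tibble `structure_id,chain,residue,label`), `truth`
#'   (list `center_residue`, `geometry`).
#' @export
plant_clusters <- function(coords, geometry, seed, structure_id = "planted") {
  ca <- as_tibble(coords) %>% filter(.data$chain == "A")
  n_need <- geometry$n_pathogenic + geometry$n_benign
  if (nrow(ca) < n_need + 1L)
    abort(sprintf("structure has %d residues; %d needed", nrow(ca), n_need + 1L))
  with_seed(seed, {
    if (geometry$separation == 0) {
      idx <- sample.int(nrow(ca), n_need)
      sites <- ca[idx, ] %>%
        mutate(label = rep(c("pathogenic", "benign"),
                           c(geometry$n_pathogenic, geometry$n_benign)))
      center <- NA_integer_
    } else {
      center_i <- sample.int(nrow(ca), 1L)
      d <- sqrt((ca$x - ca$x[center_i])^2 + (ca$y - ca$y[center_i])^2 +
                  (ca$z - ca$z[center_i])^2)
      path_pool <- which(d <= geometry$cluster_radius)
      ben_pool <- which(d >= geometry$separation)
      if (length(path_pool) < geometry$n_pathogenic ||
          length(ben_pool) < geometry$n_benign) {
        abort(sprintf(
          paste0("cluster geometry unsatisfiable: %d residues within %.1f A, ",
                 "%d at >= %.1f A; achievable separations up to %.1f A"),
          length(path_pool), geometry$cluster_radius,
          length(ben_pool), geometry$separation, max(d)))
      }
      sites <- bind_rows(
        ca[sample(path_pool, geometry$n_pathogenic), ] %>%
          mutate(label = "pathogenic"),
        ca[sample(ben_pool, geometry$n_benign), ] %>% mutate(label = "benign"))
      center <- ca$residue[center_i]
    }
    list(sites = sites %>%
           transmute(structure_id = structure_id, chain = .data$chain,
                     residue = .data$residue, label = .data$label),
         truth = list(center_residue = center, geometry = geometry))
  })
}

#' Full-sequence translation oracle for SNV consequences
#'
#' Independent route to the consequence of an SNV: mutate the spliced CDS
#' string at the variant's offset and translate the reference and mutated
#' sequences end-to-end with `Biostrings::translate()`, then diff the two
#' peptides. Used to compute expected values for the consequence caller; it
#' never shares the caller's codon arithmetic.
#'
#' @param v List/row with `chrom`, `pos`, `ref`, `alt`.
#' @param model A [transcript_model()].
#' @return List `class` and, for coding classes, `position`, `ref_aa`,
#'   `alt_aa`.
#' @export
oracle_consequence <- function(v, model) {
  if (!identical(as.character(v$chrom), model$chrom))
    return(list(class = "non_coding"))
  off <- cds_offset(model, as.integer(v$pos))
  if (is.na(off)) return(list(class = "non_coding"))
  coding_alt <- if (model$strand == "+") v$alt else comp_base(v$alt)
  mutated <- model$cds_sequence
  substr(mutated, off + 1L, off + 1L) <- coding_alt
  pep_ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(model$cds_sequence), if.fuzzy.codon = "error",
    no.init.codon = TRUE))
  pep_alt <- as.character(Biostrings::translate(
    Biostrings::DNAString(mutated), if.fuzzy.codon = "error",
    no.init.codon = TRUE))
  if (pep_ref == pep_alt) return(list(class = "synonymous",
                                      position = off %/% 3L + 1L,
                                      ref_aa = substr(pep_ref, off %/% 3L + 1L,
                                                      off %/% 3L + 1L),
                                      alt_aa = substr(pep_alt, off %/% 3L + 1L,
                                                      off %/% 3L + 1L)))
  diffpos <- which(strsplit(pep_ref, "")[[1]] != strsplit(pep_alt, "")[[1]])[1]
  a_ref <- substr(pep_ref, diffpos, diffpos)
  a_alt <- substr(pep_alt, diffpos, diffpos)
  cls <- if (a_alt == "*") "nonsense" else if (a_ref == "*") "stop_lost"
    else "missense"
  list(class = cls, position = diffpos, ref_aa = a_ref, alt_aa = a_alt)
}

# Genomic base (as read on the plus strand of the toy genome) at a CDS
# position of a model.
genomic_base <- function(model, pos) {
  off <- cds_offset(model, pos)
  if (is.na(off)) return(NA_character_)
  b <- substr(model$cds_sequence, off + 1L, off + 1L)
  if (model$strand == "+") b else comp_base(b)
}

#' Generate a case bundle: VCF, expected case table, score tables
#'
#' Samples SNVs inside the CDS of perfectly cross-referenced transcripts
#' until the requested missense count is reached (rejection sampling against
#' [oracle_consequence()], never against the consequence caller under test),
#' writes a minimal VCF with inheritance in the `INH` INFO key, the expected
#' pipeline-ready case table derived from the oracle, and planted
#' substitution- and constraint-score tables covering every expected variant.
#'
#' @param spec A [fixture_spec()].
#' @param tx [make_transcriptome()] output.
#' @param dir Output directory.
#' @return List `vcf` (path), `expected` (tibble), `score_tables` (paths),
#'   `planted_scores` (tibble of planted values).
#' @export
make_case <- function(spec, tx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  perfect <- tx$xref %>% filter(.data$planted_status == "PERFECT")
  if (nrow(perfect) == 0L) abort("no perfectly cross-referenced transcript to draw from")
  with_seed(spec$seed + 1L, {
    rows <- list(); expected <- list()
    guard <- 0L
    while (length(expected) < spec$n_missense && guard < 10000L) {
      guard <- guard + 1L
      tid <- sample(perfect$transcript_id, 1L)
      model <- tx$transcripts[[tid]]
      n_aa <- nchar(model$peptide)
      cds_pos <- sample.int(n_aa * 3L, 1L)  # skip the stop codon
      # genomic position of this cds offset
      gpos <- cds_to_genomic(model, cds_pos)
      ref <- genomic_base(model, gpos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      cons <- oracle_consequence(list(chrom = model$chrom, pos = gpos,
                                      ref = ref, alt = alt), model)
      if (cons$class != "missense") next
      inh <- sample(INHERITANCE_LEVELS, 1L)
      key <- paste(tid, cons$position, cons$ref_aa, cons$alt_aa)
      if (key %in% map_chr(expected, "key")) next
      rows[[length(rows) + 1L]] <-
        sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tINH=%s",
                model$chrom, gpos, ref, alt, inh)
      expected[[length(expected) + 1L]] <- list(
        key = key,
        row = tibble(gene = model$gene,
                     protein_id = perfect$protein_id[perfect$transcript_id == tid],
                     transcript_id = tid,
                     position = cons$position, ref_aa = cons$ref_aa,
                     alt_aa = cons$alt_aa, inheritance = inh,
                     provenance = "genomic"))
    }
    if (length(expected) < spec$n_missense)
      abort("could not reach the requested missense count")
    expected_tbl <- map(expected, "row") %>% list_rbind()
    vcf_path <- file.path(dir, "case.vcf")
    write_lines_utf8(c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=INH,Number=1,Type=String,Description=\"Parental inheritance\">",
      paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                          "FILTER", "INFO"), collapse = "\t")),
      unlist(rows)), vcf_path)
    # planted score tables: substitution-keyed and position-keyed
    sub_tbl <- expected_tbl %>%
      transmute(protein_id = .data$protein_id, position = .data$position,
                alt_aa = .data$alt_aa, value = round(runif(n()), 4))
    con_tbl <- expected_tbl %>%
      distinct(.data$protein_id, .data$position) %>%
      mutate(value = round(runif(n(), -2, 2), 4))
    sub_path <- file.path(dir, "substitution_scores.tsv")
    con_path <- file.path(dir, "constraint_scores.tsv")
    readr::write_tsv(sub_tbl, sub_path, progress = FALSE)
    readr::write_tsv(con_tbl, con_path, progress = FALSE)
    list(vcf = vcf_path, expected = expected_tbl,
         score_tables = c(substitution = sub_path, constraint = con_path),
         planted_scores = list(substitution = sub_tbl, constraint = con_tbl))
  })
}

# Genomic coordinate of the k-th CDS base (1-based, translation order).
cds_to_genomic <- function(model, k) {
  iv <- model$cds_intervals
  lens <- iv$end - iv$start + 1L
  cum <- c(0L, cumsum(lens))
  i <- findInterval(k - 1L, cum, rightmost.closed = FALSE)
  within <- k - 1L - cum[i]
  if (model$strand == "+") iv$start[i] + within else iv$end[i] - within
}
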