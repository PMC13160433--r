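test_that("VCF parsing splits multi-allelic SNVs and skips non-SNVs", {
  path <- write_vcf_lines(c(
    "1\t1000\t.\tA\tG\t.\tPASS\t.",
    "1\t1000\t.\tA\tG,T\t.\tPASS\tINH=maternal",
    "1\t1000\t.\tAT\tA\t.\tPASS\t.",
    "2\t50\t.\tC\t<DEL>\t.\tPASS\t."
  ), withr::local_tempfile(fileext = ".vcf"))
  out <- parse_vcf(path)
  expect_equal(nrow(out$variants), 3L)
  expect_equal(out$variants$alt[1:3], c("G", "G", "T"))
  expect_equal(out$variants$inheritance, c("unknown", "maternal", "maternal"))
  expect_equal(nrow(out$skipped), 2L)
  expect_match(out$skipped$reason[1], "ref")
})

test_that("missing VCF and malformed positions raise informative errors", {
  expect_error(parse_vcf(file.path(tempdir(), "nope.vcf")), "not found")
  bad <- write_vcf_lines("1\t-5\t.\tA\tG\t.\tPASS\t.",
                         withr::local_tempfile(fileext = ".vcf"))
  expect_error(parse_vcf(bad), "row 1")
})

test_that("consequence calling matches hand-translated toy examples", {
  m <- toy_plus_model()
  # codon 2 GCT -> GTT: Ala -> Val
  mis <- annotate_consequence(list(chrom = "chr1", pos = 105, ref = "C", alt = "T"), m)
  expect_equal(mis$class, "missense")
  expect_equal(mis$position, 2L)
  expect_equal(mis$ref_aa, "A")
  expect_equal(mis$alt_aa, "V")
  # GCT -> GCC is silent
  syn <- annotate_consequence(list(chrom = "chr1", pos = 106, ref = "T", alt = "C"), m)
  expect_equal(syn$class, "synonymous")
  # upstream of the CDS
  nc <- annotate_consequence(list(chrom = "chr1", pos = 100, ref = "G", alt = "A"), m)
  expect_equal(nc$class, "non_coding")
  # destroying the stop codon
  sl <- annotate_consequence(list(chrom = "chr1", pos = 108, ref = "A", alt = "C"), m)
  expect_equal(sl$class, "stop_lost")
  # wrong claimed reference base
  expect_error(
    annotate_consequence(list(chrom = "chr1", pos = 105, ref = "A", alt = "T"), m),
    class = "vus3d_ref_mismatch")
})

test_that("minus-strand transcripts give the complemented, identical consequence", {
  mp <- toy_plus_model()
  mm <- toy_minus_model()
  # CDS offset 4 (the Ala codon's middle base): genomic 105 on plus,
  # 205 on the mirrored minus transcript (201 + (9 - 5)); alleles complemented
  plus <- annotate_consequence(list(chrom = "chr1", pos = 105, ref = "C", alt = "T"), mp)
  minus <- annotate_consequence(list(chrom = "chr1m", pos = 205, ref = "G", alt = "A"), mm)
  expect_equal(minus$class, plus$class)
  expect_equal(minus$position, plus$position)
  expect_equal(minus$ref_aa, plus$ref_aa)
  expect_equal(minus$alt_aa, plus$alt_aa)
})

test_that("consequence caller agrees with the full-sequence translation oracle", {
  set.seed(42)
  models <- lapply(1:30, random_model)
  n_checked <- 0L
  for (m in models) {
    n <- nchar(m$cds_sequence)
    for (rep in 1:10) {
      k <- sample.int(n, 1)
      gpos <- vus3d:::cds_to_genomic(m, k)
      ref <- vus3d:::genomic_base(m, gpos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      v <- list(chrom = m$chrom, pos = gpos, ref = ref, alt = alt)
      got <- annotate_consequence(v, m)
      want <- oracle_consequence(v, m)
      expect_equal(got$class, want$class)
      if (want$class %in% c("missense", "nonsense", "stop_lost")) {
        expect_equal(got$position, want$position)
        expect_equal(got$ref_aa, want$ref_aa)
        expect_equal(got$alt_aa, want$alt_aa)
      }
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 300L)
})

test_that("case CSV accepts compact and split change forms with row-level errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,transcript_id,protein_id,aa_change,inheritance",
               "HFE,T1,P1,C282Y,maternal",
               "HFE,T1,P1,H63D,",
               "BAD,T2,P2,282CY,paternal"), path)
  case <- suppressWarnings(parse_case_csv(path, case_id = "k"))
  expect_equal(nrow(case$variants), 2L)
  expect_equal(case$variants$position[1], 282L)
  expect_equal(case$variants$ref_aa[1], "C")
  expect_equal(case$variants$alt_aa[1], "Y")
  expect_equal(case$variants$inheritance[2], "unknown")
  errs <- attr(case, "row_errors")
  expect_equal(nrow(errs), 1L)
  expect_equal(errs$row, 3L)

  split_path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,transcript_id,protein_id,ref_aa,position,alt_aa",
               "HFE,T1,P1,C,282,Y"), split_path)
  case2 <- parse_case_csv(split_path, case_id = "k2")
  expect_equal(case2$variants$position, 282L)
})

test_that("case CSV round-trips exactly for randomized cases", {
  set.seed(7)
  for (i in 1:100) {
    case <- random_case(sample(0:8, 1), case_id = sprintf("case%03d", i))
    path <- tempfile(fileext = ".csv")
    write_case_csv(case, path)
    back <- parse_case_csv(path, case_id = case$case_id)
    expect_identical(back$case_id, case$case_id)
    expect_equal(as.data.frame(back$variants), as.data.frame(case$variants))
    unlink(path)
  }
})

test_that("an empty case writes a header-only file that re-parses empty", {
  case <- random_case(0, case_id = "empty")
  path <- withr::local_tempfile(fileext = ".csv")
  write_case_csv(case, path)
  expect_length(readLines(path), 1L)
  back <- parse_case_csv(path, case_id = "empty")
  expect_equal(nrow(back$variants), 0L)
})

test_that("duplicated variants are dropped keeping the first occurrence", {
  v <- tibble(gene = "G", protein_id = "P1", transcript_id = c("Ta", "Tb"),
              position = 5L, ref_aa = "A", alt_aa = "V",
              inheritance = c("maternal", "paternal"),
              provenance = "proteomic")
  case <- suppressMessages(vus3d:::dedup_case(vus3d:::new_case("d", v)))
  expect_equal(nrow(case$variants), 1L)
  expect_equal(case$variants$inheritance, "maternal")
  expect_equal(nrow(attr(case, "duplicates")), 1L)
})

test_that("pre-annotated consequence tables import as proteomic cases", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("transcript_id,position,ref_aa,alt_aa,gene",
               "T9,12,L,P,GENE9"), path)
  case <- parse_annotated_csv(path, case_id = "pre")
  expect_equal(case$variants$protein_id, "T9")
  expect_equal(case$variants$provenance, "pre_annotated")
})
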