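fake_results <- function(values, states = rep("complete", length(values)),
                         metric = "ddg", calc = "ddg_cartesian") {
  tibble(job_id = sprintf("job_%04d", seq_along(values)),
         calc_type = calc, gene = "G1", protein_id = "P1", position = 10L,
         ref_aa = "A", alt_aa = "V",
         structure_id = sprintf("S%d", seq_along(values)),
         workdir = "w", status_dir = "s", state = states,
         metric = ifelse(is.na(values), NA_character_, metric),
         value = values, qualifier = "")
}

test_that("range aggregation spans structures and counts missing results", {
  agg <- aggregate_ranges(fake_results(c(1.2, 3.4, 2.2)))
  expect_equal(agg$min, 1.2)
  expect_equal(agg$max, 3.4)
  expect_equal(agg$n_structures, 3L)
  expect_equal(agg$n_missing, 0L)
  # single structure: degenerate range
  agg1 <- aggregate_ranges(fake_results(2.5))
  expect_equal(c(agg1$min, agg1$max), c(2.5, 2.5))
  # one failed job of three: counted missing, never coerced to zero
  agg2 <- aggregate_ranges(fake_results(c(1.2, NA, 2.2),
                                        states = c("complete", "failed",
                                                   "complete")))
  expect_equal(agg2$n_structures, 2L)
  expect_equal(agg2$n_missing, 1L)
  expect_equal(agg2$min, 1.2)
})

test_that("isoform child rows order canonical first then by numeric suffix", {
  rows <- tibble(gene = "G", protein_id = c("P1-3", "P1", "P1-2"),
                 position = 5L, ref_aa = "A", alt_aa = "V")
  out <- expand_isoform_rows(rows)
  expect_equal(out$protein_id, c("P1", "P1-2", "P1-3"))
  expect_equal(out$is_canonical, c(TRUE, FALSE, FALSE))
  expect_equal(out$display_order, 1:3)
})

test_that("report rendering is idempotent, sound, and row-conserving", {
  bundle <- mini_bundle(seed = 11)
  score_tables <- list(
    list(path = unname(bundle$case_files$score_tables["substitution"]),
         keying = "alt", score_name = "substitution_score"),
    list(path = unname(bundle$case_files$score_tables["constraint"]),
         keying = "position", score_name = "constraint_score"))
  clock <- function() as.POSIXct("2026-01-01 00:00:00", tz = "UTC")
  res <- run_pipeline(bundle$case, bundle$tx, bundle$structures,
                      file.path(bundle$dir, "out"), seed = 5,
                      sites_dir = bundle$sites_dir,
                      score_tables = score_tables, n_perm = 99,
                      clock = clock)
  expect_false(res$stopped)
  out1 <- file.path(bundle$dir, "render1")
  out2 <- file.path(bundle$dir, "render2")
  r1 <- render_case_report(res$expanded, res$plan, out1)
  r2 <- render_case_report(res$expanded, res$plan, out2)
  expect_identical(readLines(r1$html), readLines(r2$html))
  expect_identical(readLines(r1$csv), readLines(r2$csv))

  # the CSV twin re-parses to the same ranges the renderer used
  back <- readr::read_csv(r1$csv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(r1$ranges))
  expect_equal(back$min, r1$ranges$min)

  # row conservation: one variant-rows block per expanded isoform variant
  per_variant <- r1$ranges %>%
    distinct(gene, protein_id, position, ref_aa, alt_aa)
  expect_equal(nrow(per_variant), nrow(res$expanded$variants))

  # range soundness: every contributing result value inside its range
  results <- collect_results(res$plan)
  for (k in seq_len(nrow(r1$ranges))) {
    rr <- r1$ranges[k, ]
    if (is.na(rr$metric)) next
    vals <- results %>%
      filter(protein_id == rr$protein_id, position == rr$position,
             alt_aa == rr$alt_aa, calc_type == rr$calc_type,
             !is.na(metric), metric == rr$metric, is.finite(value)) %>%
      pull(value)
    expect_true(all(vals >= rr$min - 1e-12 & vals <= rr$max + 1e-12))
  }
})

test_that("a zero-variant case still renders a valid page and empty tables", {
  case <- random_case(0, "empty")
  out <- withr::local_tempdir()
  r <- render_case_report(case, NULL, out)
  expect_true(file.exists(r$html))
  expect_equal(nrow(r$ranges), 0L)
  expect_equal(nrow(readr::read_csv(r$csv, show_col_types = FALSE,
                                    col_types = readr::cols())), 0L)
})

test_that("summary flags honour thresholds and digenic symmetry", {
  case <- vus3d:::new_case("s", tibble(
    gene = c("G1", "G2"), protein_id = c("P1", "P2"),
    transcript_id = c("T1", "T2"), position = c(10L, 20L),
    ref_aa = "A", alt_aa = "V", inheritance = "unknown",
    provenance = "proteomic"))
  results <- bind_rows(
    fake_results(0.01, metric = "pathprox_pvalue", calc = "pathprox"),
    tibble(job_id = "job_9999", calc_type = "digenic_pair", gene = "G1+G2",
           protein_id = NA_character_, position = NA_integer_,
           ref_aa = NA_character_, alt_aa = NA_character_,
           structure_id = NA_character_, workdir = "w", status_dir = "s",
           state = "complete", metric = "digenic_score", value = 0.9,
           qualifier = ""))
  ranges <- aggregate_ranges(results)
  tbl <- vus3d:::case_summary_table(case, ranges, results, report_thresholds())
  expect_equal(nrow(tbl), 2L)
  expect_equal(tbl$clustering_flag[tbl$protein_id == "P1"], "yes")
  expect_equal(tbl$clustering_flag[tbl$protein_id == "P2"], "")
  # digenic partner tag is symmetric
  expect_equal(tbl$digenic_partners, c("G2", "G1"))
  # all-absent variant still gets a row with blank flags
  expect_equal(tbl$destabilizing_flag, c("", ""))
  expect_equal(tbl$recommendation, c("", ""))
})

test_that("domain track SVG and transcript report render deterministically", {
  domains <- tibble(protein_id = "P1", start = c(10L, 60L), end = c(40L, 90L),
                    name = c("kinase", "SH2"))
  out <- withr::local_tempdir()
  p1 <- write_domain_track_svg(domains, 100L, 25L, file.path(out, "a.svg"))
  p2 <- write_domain_track_svg(domains, 100L, 25L, file.path(out, "b.svg"))
  expect_identical(readLines(p1), readLines(p2))
  expect_match(paste(readLines(p1), collapse = ""), "polygon")

  sel <- select_structures(
    tibble(protein_id = "P1", structure_id = "S1", source = "PDB",
           method = "xray", quality = 2, oligomeric_state = 1L,
           coords_path = NA_character_),
    tibble(structure_id = "S1", chain = "A", seg_start_transcript = 1L,
           seg_start_residue = 1L, seg_length = 100L), 25L)
  html <- render_transcript_report("P1", 100L, 25L, sel,
                                   collect_results(NULL), domains, out)
  expect_true(file.exists(html))
  expect_match(paste(readLines(html), collapse = ""), "Structure summary")
})
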