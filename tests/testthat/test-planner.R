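plan_fixture_case <- function(n_var = 1, genes = "G1") {
  v <- tibble(gene = rep(genes, length.out = n_var),
              protein_id = sprintf("P%d", seq_len(n_var)),
              transcript_id = sprintf("T%d", seq_len(n_var)),
              position = 10L + seq_len(n_var), ref_aa = "A", alt_aa = "V",
              inheritance = "unknown", provenance = "proteomic")
  vus3d:::new_case("plan_case", v)
}

two_structure_selection <- function() {
  cand <- tibble(protein_id = "P1", structure_id = c("X1", "AF1"),
                 source = c("PDB", "ALPHAFOLD"), method = c("xray", "model"),
                 quality = c(1.8, 90), oligomeric_state = 1L,
                 coords_path = NA_character_)
  al <- tibble(structure_id = c("X1", "AF1"), chain = "A",
               seg_start_transcript = 1L, seg_start_residue = 1L,
               seg_length = 100L)
  select_structures(cand, al, 11L, max_k = 6L)
}

test_that("planning crosses variants, structures, calcs and enumerates gene pairs", {
  case <- plan_fixture_case(1)
  sel <- list()
  sel[[vus3d:::variant_key(case$variants[1, ])]] <- two_structure_selection()
  dir <- withr::local_tempdir()
  plan <- plan_case(case, sel, c("ddg_cartesian", "pathprox", "ptm_site"),
                    dir, guid = "fixed-guid")
  expect_equal(sum(plan$calc_type %in% c("ddg_cartesian", "pathprox")), 4L)
  expect_equal(sum(plan$calc_type == "ptm_site"), 1L)
  expect_true(file.exists(file.path(attr(plan, "root"), "workplan.csv")))

  case3 <- plan_fixture_case(3, genes = c("G1", "G2", "G3"))
  sel3 <- setNames(
    lapply(1:3, function(i) two_structure_selection()),
    vapply(1:3, function(i) vus3d:::variant_key(case3$variants[i, ]), ""))
  plan3 <- plan_case(case3, sel3, c("ptm_site", "digenic_pair"),
                     withr::local_tempdir(), guid = "g")
  expect_equal(sum(plan3$calc_type == "digenic_pair"), 3L)  # C(3,2)
  plan1 <- plan_case(case, sel, c("ptm_site", "digenic_pair"),
                     withr::local_tempdir(), guid = "g")
  expect_equal(sum(plan1$calc_type == "digenic_pair"), 0L)
})

test_that("workplan schema is fixed and scheduler-independent", {
  case <- plan_fixture_case(1)
  sel <- list()
  sel[[vus3d:::variant_key(case$variants[1, ])]] <- two_structure_selection()
  plan <- plan_case(case, sel, c("pathprox", "ptm_site"),
                    withr::local_tempdir(), guid = "g")
  expect_identical(names(plan), vus3d:::WORKPLAN_COLUMNS)
  forbidden <- c("slurm", "partition", "queue", "node", "account", "walltime")
  expect_false(any(forbidden %in% tolower(names(plan))))
})

test_that("path construction is injective and sanitises hostile identifiers", {
  p1 <- build_paths("C1", "g", "T1", "PDB_1ABC", "pathprox", tempdir())
  expect_match(p1$workdir, "C1_g/T1/PDB_1ABC/pathprox/work$")
  p2 <- build_paths("C1", "g", "T1", "PDB_1ABC", "ddg_monomer", tempdir())
  expect_false(identical(p1$workdir, p2$workdir))
  p3 <- build_paths("C1", "g", "T1", "PDB/1ABC", "pathprox", tempdir())
  expect_false(grepl("PDB/1ABC", p3$workdir, fixed = TRUE))
  expect_match(p3$workdir, "PDB_1ABC")
})

test_that("status files append monotonically and read back tolerantly", {
  sd <- withr::local_tempdir()
  clock <- function() as.POSIXct("2026-01-02 03:04:05", tz = "UTC")
  expect_equal(read_status(sd)$state, "planned")  # empty dir: implicit
  write_status(sd, "submitted", "queued", clock)
  write_status(sd, "running", "", clock)
  write_status(sd, "complete", "", clock)
  st <- read_status(sd)
  expect_equal(st$state, "complete")
  expect_equal(nrow(st$history), 3L)
  expect_error(write_status(sd, "running", clock = clock), "backward")
  # failures surface their detail verbatim
  sd2 <- withr::local_tempdir()
  write_status(sd2, "failed", "executor exploded: chain Z missing", clock)
  expect_equal(read_status(sd2)$detail, "executor exploded: chain Z missing")
  # partial files are ignored with a warning, never fatal
  writeLines("gar", file.path(sd2, "099_garbage.status"))
  expect_warning(st2 <- read_status(sd2), "partial")
  expect_equal(st2$state, "failed")
  expect_equal(read_status(file.path(sd2, "missing"))$state, "unknown")
})

test_that("local runs complete stubs, isolate failures, and conserve rows", {
  bundle <- mini_bundle(seed = 11)
  clock <- function() as.POSIXct("2026-01-01 00:00:00", tz = "UTC")
  sel <- list()
  for (i in seq_len(nrow(bundle$case$variants))) {
    vr <- bundle$case$variants[i, ]
    sel[[vus3d:::variant_key(vr)]] <- select_structures(
      load_candidates(vr$protein_id, bundle$structures$catalog,
                      check_files = FALSE),
      bundle$structures$alignments, vr$position, max_k = 2L)
  }
  plan <- plan_case(bundle$case, sel,
                    c("ddg_monomer", "ppi_surface", "ptm_site", "digenic_pair"),
                    withr::local_tempdir(), guid = "g1")
  st <- run_local(plan, default_executors(seed = 3), clock = clock)
  expect_equal(nrow(st), nrow(plan))
  expect_true(all(st$state == "complete"))
  result_files <- file.path(plan$workdir, "result.csv")
  expect_true(all(file.exists(result_files)))
  expect_equal(nrow(plan), sum(st$state == "complete") + sum(st$state == "failed"))

  # a raising executor fails exactly its own rows
  reg <- default_executors(seed = 3)
  reg$ppi_surface <- function(row, params, workdir) stop("boom")
  plan2 <- plan_case(bundle$case, sel,
                     c("ddg_monomer", "ppi_surface", "ptm_site"),
                     withr::local_tempdir(), guid = "g2")
  st2 <- run_local(plan2, reg, clock = clock)
  expect_true(all(st2$state[plan2$calc_type == "ppi_surface"] == "failed"))
  expect_true(all(st2$state[plan2$calc_type != "ppi_surface"] == "complete"))
  expect_match(st2$detail[st2$state == "failed"][1], "boom")

  # reruns under the same seed are byte-identical
  plan3 <- plan_case(bundle$case, sel,
                     c("ddg_monomer", "ppi_surface", "ptm_site"),
                     withr::local_tempdir(), guid = "g3")
  run_local(plan3, default_executors(seed = 3), clock = clock)
  for (k in seq_len(nrow(plan2))) {
    if (plan2$calc_type[k] == "ppi_surface") next
    expect_identical(readLines(file.path(plan3$workdir[k], "result.csv")),
                     readLines(file.path(plan2$workdir[k], "result.csv")))
  }
})

test_that("the relax cache invokes produce once per distinct key", {
  cache <- withr::local_tempdir()
  calls <- 0L
  produce <- function(path) { calls <<- calls + 1L; writeLines("artifact", path) }
  p1 <- ddg_cache(cache, "S1", "A", "cartesian", list(), produce)
  p2 <- ddg_cache(cache, "S1", "A", "cartesian", list(), produce)
  expect_identical(p1, p2)
  expect_equal(calls, 1L)
  ddg_cache(cache, "S1", "A", "monomer", list(), produce)
  expect_equal(calls, 2L)
  # cleared cache recomputes
  unlink(p1)
  ddg_cache(cache, "S1", "A", "cartesian", list(), produce)
  expect_equal(calls, 3L)
  # corrupt (empty) entries are recomputed with a warning
  writeLines(character(), p1)
  expect_warning(ddg_cache(cache, "S1", "A", "cartesian", list(), produce),
                 "corrupt")
  expect_equal(calls, 4L)
})
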