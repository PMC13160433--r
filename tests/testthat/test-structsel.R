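one_candidate <- function(id = "S1", source = "PDB", method = "xray",
                          quality = 1.8, olig = 1L) {
  tibble(protein_id = "P1", structure_id = id, source = source,
         method = method, quality = quality,
         oligomeric_state = as.integer(olig), coords_path = NA_character_)
}
full_align <- function(id, start = 1L, len = 100L, chain = "A") {
  tibble(structure_id = id, chain = chain, seg_start_transcript = start,
         seg_start_residue = 1L, seg_length = len)
}

test_that("marginal utility evaluates the additive formula at the defaults", {
  cand <- one_candidate()                       # 1.8 A X-ray, monomer
  al <- full_align("S1", 10L, 41L)              # covers 10..50
  u <- candidate_utility(cand, 25L, cand[0, ], al)
  # coverage 4 + new method 1 + quality 1 (res <= 2 A) + no multimer - no overlap
  expect_equal(u$utility, 6)
  expect_true(u$covers)
  expect_setequal(u$reasons, c("coverage", "technique_diversity", "quality"))
})

test_that("redundancy strictly lowers a duplicate's marginal utility", {
  cand <- one_candidate("S1")
  dup <- one_candidate("S2")
  al <- bind_rows(full_align("S1", 10L, 41L), full_align("S2", 10L, 41L))
  u1 <- candidate_utility(cand, 25L, cand[0, ], al)
  u2 <- candidate_utility(dup, 25L, cand, al)   # S1 already selected
  expect_lt(u2$utility, u1$utility)
  expect_equal(u1$utility - u2$utility,
               selection_weights()$red + selection_weights()$div)
})

test_that("a homodimer outscores an identical monomer by the multimer weight", {
  mono <- one_candidate("S1")
  dimer <- one_candidate("S2", olig = 2L)
  al <- bind_rows(full_align("S1", 10L, 41L), full_align("S2", 10L, 41L))
  u_m <- candidate_utility(mono, 25L, mono[0, ], al)
  u_d <- candidate_utility(dimer, 25L, mono[0, ], al)
  expect_equal(u_d$utility - u_m$utility, selection_weights()$mult)
})

test_that("residue mapping is exact segment arithmetic with protomer fan-out", {
  al <- full_align("S1", 10L, 41L)
  hit <- map_residue(25L, al)
  expect_equal(hit$chain, "A")
  expect_equal(hit$residue, 16L)   # 1 + (25 - 10)
  expect_equal(nrow(map_residue(5L, al)), 0L)
  dimer <- bind_rows(full_align("S1", 10L, 41L, "A"),
                     full_align("S1", 10L, 41L, "B"))
  expect_equal(nrow(map_residue(25L, dimer)), 2L)
  # duplicate mapping within a chain is rejected
  bad <- bind_rows(full_align("S1", 10L, 41L), full_align("S1", 30L, 41L))
  expect_error(residue_map(bad, "S1"), "twice")
})

test_that("selection keeps covering structures and collapses duplicates", {
  cand <- one_candidate("S1")
  al <- full_align("S1", 10L, 41L)
  sel <- select_structures(cand, al, 25L)
  expect_equal(sel$selected$structure_id, "S1")
  # byte-identical duplicate: exactly one retained
  both <- bind_rows(one_candidate("S1"), one_candidate("S1dup"))
  al2 <- bind_rows(full_align("S1", 10L, 41L), full_align("S1dup", 10L, 41L))
  sel2 <- select_structures(both, al2, 25L, max_k = 6L)
  expect_equal(nrow(sel2$selected), 1L)
  # empty candidate set yields the no-coverage note
  sel3 <- select_structures(cand[0, ], al, 25L)
  expect_equal(nrow(sel3$selected), 0L)
  expect_equal(sel3$note, "no structural coverage")
})

test_that("AlphaFold candidates attach only to canonical isoforms", {
  catalog <- bind_rows(
    one_candidate("X1", "PDB", "xray", 2.0),
    one_candidate("AF1", "ALPHAFOLD", "model", 90))
  expect_equal(nrow(load_candidates("P1", catalog, check_files = FALSE)), 2L)
  expect_equal(load_candidates("P1-2", catalog, check_files = FALSE)$structure_id,
               "X1")
})

test_that("selection is deterministic and matches the subset oracle", {
  set.seed(99)
  worse_than_optimal <- 0L
  for (i in 1:50) {
    inst <- random_selection_instance(sample(2:8, 1))
    max_k <- sample(1:3, 1)
    sel <- select_structures(inst$candidates, inst$alignments, inst$position,
                             max_k = max_k)
    sel_again <- select_structures(inst$candidates, inst$alignments,
                                   inst$position, max_k = max_k)
    expect_identical(sel$selected, sel_again$selected)
    opt <- brute_force_selection(inst$candidates, inst$alignments,
                                 inst$position, max_k)
    expect_gte(sel$total_utility, (1 - exp(-1)) * opt$utility - 1e-9)
    if (!setequal(sel$selected$structure_id, opt$set))
      worse_than_optimal <- worse_than_optimal + 1L
    # coverage guarantee
    covering <- vapply(inst$candidates$structure_id, function(id)
      inst$position %in% vus3d:::covered_positions(
        residue_map(inst$alignments, id)), logical(1))
    if (any(covering))
      expect_true(any(sel$selected$covers_variant))
  }
  # the greedy heuristic may deviate from the optimum, but the bound held above
  expect_lte(worse_than_optimal, 50L)
})

test_that("fixture residue maps invert onto the emitted coordinates", {
  spec <- fixture_spec(seed = 5)
  dir <- withr::local_tempdir()
  st <- make_structures(spec, "P00001", strrep("A", 80), dir)
  for (i in seq_len(nrow(st$catalog))) {
    sid <- st$catalog$structure_id[i]
    rmap <- residue_map(st$alignments, sid)
    ca <- read_calpha(st$catalog$coords_path[i])
    for (pos in vus3d:::covered_positions(rmap)) {
      hits <- map_residue(pos, rmap)
      expect_gt(nrow(hits), 0L)
      joined <- dplyr::inner_join(hits, ca, by = c("chain", "residue"))
      expect_equal(nrow(joined), nrow(hits))
      # inverse: structure residue -> transcript position -> same residue
      for (j in seq_len(nrow(hits))) {
        seg <- rmap %>%
          filter(chain == hits$chain[j],
                 seg_start_residue <= hits$residue[j],
                 hits$residue[j] < seg_start_residue + seg_length)
        back <- seg$seg_start_transcript +
          (hits$residue[j] - seg$seg_start_residue)
        expect_equal(back, pos)
      }
    }
  }
})
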