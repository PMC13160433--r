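# End-to-end orchestration: case -> curated-transcript filter -> isoform
# expansion -> structure selection -> workplan -> local execution -> reports.
# Every stage is also callable on its own; this wrapper wires the default
# desk-scale path used by the examples, the test-suite and the acceptance
# runs.

#' Run the full pipeline on a case
#'
#' Filters the case to perfectly cross-referenced transcripts (stopping with
#' a halt report unless `force = TRUE` when any variant is unprocessable),
#' expands variants over curated isoforms, selects structures per variant,
#' plans the work tree under a GUID-isolated case root, executes everything
#' with the default executor registry (native spatial clustering, stubs for
#' the licensed/ML calculators, exact score-table lookups) and renders the
#' case-wide report plus the draft case summary.
#'
#' @param case A `vus_case`.
#' @param tx Transcriptome bundle as from [make_transcriptome()] (fields
#'   `xref`, `isoforms`).
#' @param structures List with `catalog` and `alignments` tibbles and the
#'   catalog's `coords_path`s resolvable from the working directory.
#' @param out_dir Directory the case tree is created under.
#' @param seed Integer seed driving the GUID, the stub scores and the
#'   permutation tests.
#' @param enabled_calcs Calculation types to plan.
#' @param sites_dir Directory of per-structure labeled-site CSVs for the
#'   clustering stage (`NULL` disables it even if enabled).
#' @param score_tables List of `list(path=, keying=, score_name=)` entries
#'   for the score-lookup stage.
#' @param n_perm Permutations per clustering test.
#' @param max_k Maximum structures retained per variant.
#' @param force Proceed with the retained subset when variants are rejected?
#' @param guid Case GUID; derived from `seed` when `NULL`.
#' @param clock Injectable time source for the status protocol.
#' @return List: `halt` (halt report or `NULL`), `stopped` (logical),
#'   `retained`, `rejected`, `expanded` (isoform-expanded variants), `plan`,
#'   `statuses`, `selections`, `report` (paths), `root`.
#' @export
run_pipeline <- function(case, tx, structures, out_dir, seed = 1,
                         enabled_calcs = c("ddg_monomer", "ddg_cartesian",
                                           "pathprox", "ppi_surface",
                                           "ptm_site", "digenic_pair",
                                           "score_lookup"),
                         sites_dir = NULL, score_tables = list(),
                         n_perm = 199, max_k = 6L, force = FALSE,
                         guid = NULL, clock = Sys.time) {
  flt <- filter_curated(case, tx$xref)
  halt <- halt_on_disconnect(case, flt$rejected, force = force)
  if (!is.null(halt) && halt$stopped) {
    return(list(halt = halt, stopped = TRUE, retained = flt$retained,
                rejected = flt$rejected, expanded = NULL, plan = NULL,
                statuses = NULL, selections = NULL, report = NULL,
                root = NULL))
  }
  # isoform expansion + reference-residue validation
  v <- flt$retained$variants
  expanded <- map(seq_len(nrow(v)), function(i) {
    vr <- v[i, ]
    isoset <- tx$isoforms %>% filter(.data$protein_id == vr$protein_id) %>%
      select("isoform_id", "peptide", "is_canonical")
    if (nrow(isoset) == 0L)
      isoset <- tibble(isoform_id = vr$protein_id,
                       peptide = strrep("X", vr$position),
                       is_canonical = TRUE)
    ex <- expand_isoforms(vr, isoset)
    peps <- tx$isoforms$peptide[match(ex$variants$protein_id,
                                      tx$isoforms$isoform_id)]
    ok <- validate_reference_residue(ex$variants$position,
                                     ex$variants$ref_aa, peps)
    ex$variants[ok$status == "ok" | is.na(peps), ] %>%
      mutate(provenance = vr$provenance)
  }) %>% list_rbind()
  exp_case <- new_case(case$case_id, expanded %>% select(-"is_canonical"))

  # structure selection per expanded variant
  selections <- list()
  for (i in seq_len(nrow(exp_case$variants))) {
    vr <- exp_case$variants[i, ]
    cands <- load_candidates(vr$protein_id, structures$catalog,
                             check_files = TRUE)
    selections[[variant_key(vr)]] <-
      select_structures(cands, structures$alignments, vr$position,
                        max_k = max_k)
  }

  if (is.null(guid)) guid <- with_seed(seed, make_guid())
  alignment_path <- file.path(out_dir, "alignments.csv")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(structures$alignments, alignment_path, progress = FALSE)
  catalog_path <- file.path(out_dir, "structure_catalog.csv")
  readr::write_csv(structures$catalog, catalog_path, progress = FALSE)
  parameters <- list(
    pathprox = list(catalog_path = catalog_path,
                    alignment_path = alignment_path,
                    sites_dir = sites_dir, n_perm = n_perm, seed = seed),
    score_lookup = list(tables = score_tables)
  )
  if (is.null(sites_dir)) enabled_calcs <- setdiff(enabled_calcs, "pathprox")
  if (length(score_tables) == 0L)
    enabled_calcs <- setdiff(enabled_calcs, "score_lookup")
  plan <- plan_case(exp_case, selections, enabled_calcs, out_dir, guid,
                    parameters = parameters)
  statuses <- run_local(plan, default_executors(seed = seed), clock = clock)
  root <- attr(plan, "root")
  report <- render_case_report(exp_case, plan, file.path(root, "report"))
  list(halt = halt, stopped = FALSE, retained = flt$retained,
       rejected = flt$rejected, expanded = exp_case, plan = plan,
       statuses = statuses, selections = selections, report = report,
       root = root)
}
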