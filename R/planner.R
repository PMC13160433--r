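# Work planning and local execution. Planning is architecture-independent:
# the workplan is a flat table of calculations (variant x structure x
# calculation type, plus sequence-level and gene-pair jobs) with no scheduler
# concepts. Each job owns a work directory and a sibling status directory
# inside a GUID-isolated case tree; jobs communicate progress through
# append-only timestamped status files. Executors are pluggable; licensed/ML
# calculators ship as deterministic stubs, the clustering statistic runs
# natively.

CALC_TYPES <- c("ddg_monomer", "ddg_cartesian", "pathprox", "ppi_surface",
                "ptm_site", "digenic_pair", "score_lookup")
STRUCTURAL_CALCS <- c("ddg_monomer", "ddg_cartesian", "pathprox", "ppi_surface")
SEQUENCE_CALCS <- c("ptm_site", "score_lookup")
JOB_STATES <- c(planned = 1L, submitted = 2L, running = 3L,
                complete = 4L, failed = 4L)

WORKPLAN_COLUMNS <- c("job_id", "calc_type", "gene", "protein_id", "position",
                      "ref_aa", "alt_aa", "structure_id", "parameters_json",
                      "workdir", "status_dir")

variant_key <- function(v) {
  paste0(v$protein_id, ":", format_aa_change(v$ref_aa, v$position, v$alt_aa))
}

#' Build the job paths for one workplan entry
#'
#' Deterministic, injective path construction: the case root is
#' `<base>/<case_id>_<guid>/`, and each job lives under
#' `root/<transcript>/<structure type and id>/<calc type>/work` with a sibling
#' `status` directory. All components are sanitised to `[A-Za-z0-9._-]`;
#' a collision after sanitisation is an error, never a silent overwrite.
#'
#' @param case_id Case label.
#' @param guid Case GUID (see [make_guid()]).
#' @param transcript,structure,calc_type Path components; use `"sequence"` as
#'   the structure component of sequence-level jobs.
#' @param base_dir Directory the case root is created under.
#' @return List `root`, `workdir`, `status_dir`.
#' @export
build_paths <- function(case_id, guid, transcript, structure, calc_type,
                        base_dir = ".") {
  stopifnot(nzchar(case_id), nzchar(guid), nzchar(transcript),
            nzchar(structure), nzchar(calc_type))
  root <- file.path(base_dir, paste0(sanitize_path_component(case_id), "_",
                                     sanitize_path_component(guid)))
  job <- file.path(root, sanitize_path_component(transcript),
                   sanitize_path_component(structure),
                   sanitize_path_component(calc_type))
  list(root = root, workdir = file.path(job, "work"),
       status_dir = file.path(job, "status"))
}

#' Plan all calculations for a case
#'
#' Emits one row per retained variant x selected structure x enabled
#' structural calculation, one sequence-level row per variant x enabled
#' sequence calculation, and one row per unordered pair of distinct genes for
#' the digenic screen. Rows carry only calculation-level fields; nothing
#' scheduler- or host-specific. The combined `workplan.csv` is written at the
#' case root and a per-transcript `workplan.csv` into each variant
#' subdirectory. Job directories (work + status) are created.
#'
#' A collision of two jobs onto one sanitised path is an error.
#'
#' @param case Retained `vus_case`.
#' @param selections Named list of [select_structures()] results, keyed by
#'   `protein_id:change` (see the `variant_key` attribute of the output).
#' @param enabled_calcs Subset of
#'   `ddg_monomer, ddg_cartesian, pathprox, ppi_surface, ptm_site,`
#'   `digenic_pair, score_lookup`.
#' @param base_dir Directory to build the case tree under.
#' @param guid Case GUID; injected so planning itself is fully deterministic.
#' @param parameters Named list of per-calc-type parameter lists, serialised
#'   into `parameters_json`.
#' @return Workplan tibble (columns
#'   `job_id,calc_type,gene,protein_id,position,ref_aa,alt_aa,structure_id,`
#'   `parameters_json,workdir,status_dir`), with the case root in
#'   `attr(, "root")`.
#' @export
plan_case <- function(case, selections, enabled_calcs, base_dir, guid,
                      parameters = list()) {
  stopifnot(inherits(case, "vus_case"), length(enabled_calcs) > 0L)
  bad <- setdiff(enabled_calcs, CALC_TYPES)
  if (length(bad) > 0L)
    abort(sprintf("unknown calc type(s): %s", paste(bad, collapse = ", ")))
  v <- case$variants
  params_json <- function(calc) {
    jsonlite::toJSON(parameters[[calc]] %||% setNames(list(), character()),
                     auto_unbox = TRUE)
  }
  rows <- list()
  add_row <- function(calc, vr, structure_id, transcript, structure_part) {
    p <- build_paths(case$case_id, guid, transcript, structure_part, calc,
                     base_dir)
    rows[[length(rows) + 1L]] <<- tibble(
      calc_type = calc,
      gene = vr$gene %||% NA_character_,
      protein_id = vr$protein_id %||% NA_character_,
      position = vr$position %||% NA_integer_,
      ref_aa = vr$ref_aa %||% NA_character_,
      alt_aa = vr$alt_aa %||% NA_character_,
      structure_id = structure_id,
      parameters_json = as.character(params_json(calc)),
      workdir = p$workdir, status_dir = p$status_dir)
  }
  for (i in seq_len(nrow(v))) {
    vr <- v[i, ]
    # one subdirectory per variant: transcript plus isoform and change keep
    # two variants of one transcript (or one variant on two isoforms) apart
    transcript <- paste(vr$transcript_id %||% vr$protein_id, vr$protein_id,
                        format_aa_change(vr$ref_aa, vr$position, vr$alt_aa),
                        sep = "_")
    sel <- selections[[variant_key(vr)]]
    sel_tbl <- if (is.null(sel)) tibble() else sel$selected
    for (calc in intersect(enabled_calcs, STRUCTURAL_CALCS)) {
      for (j in seq_len(nrow(sel_tbl))) {
        s <- sel_tbl[j, ]
        add_row(calc, vr, s$structure_id, transcript,
                paste0(s$source, "_", s$structure_id))
      }
    }
    for (calc in intersect(enabled_calcs, SEQUENCE_CALCS)) {
      add_row(calc, vr, NA_character_, transcript, "sequence")
    }
  }
  if ("digenic_pair" %in% enabled_calcs) {
    genes <- sort(unique(v$gene))
    if (length(genes) >= 2L) {
      pairs <- utils::combn(genes, 2L)
      for (k in seq_len(ncol(pairs))) {
        g1 <- pairs[1, k]; g2 <- pairs[2, k]
        add_row("digenic_pair",
                list(gene = paste0(g1, "+", g2), protein_id = NA_character_,
                     position = NA_integer_, ref_aa = NA_character_,
                     alt_aa = NA_character_),
                NA_character_, "digenic", paste0(g1, "__", g2))
      }
    }
  }
  plan <- list_rbind(rows)
  if (nrow(plan) == 0L)
    abort("empty workplan: no variants and no enabled calculations apply")
  plan <- plan %>% mutate(job_id = sprintf("job_%04d", row_number()),
                          .before = 1)
  if (anyDuplicated(plan$workdir))
    abort("path collision after sanitisation; rename the colliding identifiers")
  root <- build_paths(case$case_id, guid, "x", "x", "x", base_dir)$root
  for (d in c(plan$workdir, plan$status_dir))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(plan, file.path(root, "workplan.csv"), progress = FALSE)
  for (tr in unique(dirname(dirname(dirname(plan$workdir))))) {
    sub <- plan %>% filter(dirname(dirname(dirname(.data$workdir))) == tr)
    readr::write_csv(sub, file.path(tr, "workplan.csv"), progress = FALSE)
  }
  attr(plan, "root") <- root
  plan
}

# ---- status protocol ------------------------------------------------------

#' Record a job status transition
#'
#' Appends one file `NNN_<state>.status` to the status directory (three lines:
#' state, ISO-8601 timestamp, free-text detail). Transitions are monotone
#' along planned -> submitted -> running -> complete|failed; a backward
#' transition is refused.
#'
#' @param status_dir Status directory (must exist).
#' @param state One of `planned, submitted, running, complete, failed`.
#' @param detail Free text.
#' @param clock Function returning the current time; injectable for
#'   reproducible runs.
#' @return The status file path, invisibly.
#' @export
write_status <- function(status_dir, state, detail = "", clock = Sys.time) {
  stopifnot(dir.exists(status_dir), state %in% names(JOB_STATES))
  cur <- read_status(status_dir)
  if (JOB_STATES[[state]] < JOB_STATES[[cur$state]] ||
      (JOB_STATES[[cur$state]] == 4L && state != cur$state))
    abort(sprintf("backward status transition %s -> %s refused",
                  cur$state, state))
  n <- nrow(cur$history) + 1L
  path <- file.path(status_dir, sprintf("%03d_%s.status", n, state))
  stamp <- format(clock(), "%Y-%m-%dT%H:%M:%S%z")
  write_lines_utf8(c(state, stamp, detail), path)
  invisible(path)
}

#' Reconstruct a job's status from its status directory
#'
#' Returns the latest state and the full transition history. An empty (or
#' missing) directory reads as the implicit `planned` state; partially written
#' or unparseable files are ignored with a warning, and an unreadable
#' directory reports state `unknown` rather than failing, so a monitor never
#' crashes on an in-flight job.
#'
#' @param status_dir Status directory.
#' @return List `state`, `detail`, `history` (tibble `seq`, `state`,
#'   `timestamp`, `detail`).
#' @export
read_status <- function(status_dir) {
  empty <- tibble(seq = integer(), state = character(),
                  timestamp = character(), detail = character())
  if (!dir.exists(status_dir))
    return(list(state = "unknown", detail = "status directory unreadable",
                history = empty))
  files <- sort(list.files(status_dir, pattern = "\\.status$", full.names = TRUE))
  hist <- map(files, function(f) {
    lines <- tryCatch(readLines(f, warn = FALSE), error = function(e) character())
    if (length(lines) < 2L || !(lines[1] %in% names(JOB_STATES))) {
      warn(sprintf("ignoring partial status file %s", basename(f)))
      return(NULL)
    }
    tibble(seq = as.integer(sub("_.*$", "", basename(f))),
           state = lines[1], timestamp = lines[2],
           detail = if (length(lines) >= 3L) paste(lines[-(1:2)], collapse = "\n")
                    else "")
  }) %>% compact() %>% list_rbind()
  if (is.null(hist) || nrow(hist) == 0L)
    return(list(state = "planned", detail = "", history = empty))
  last <- hist[nrow(hist), ]
  list(state = last$state, detail = last$detail, history = hist)
}

# ---- relax-artifact cache -------------------------------------------------

#' Cache keyed relaxed-structure artifacts
#'
#' Stability calculations run in two parts; the expensive structure-relaxation
#' step depends only on (structure, chain, protocol, parameters) and is stored
#' in a repository so equal keys never recompute. The first call with a key
#' invokes `produce(path)`; later calls with an equal key return the stored
#' path without invoking it. A corrupt (empty) entry is recomputed with a
#' warning.
#'
#' @param cache_dir Repository directory (created if needed).
#' @param structure_id,chain,relax_protocol_tag Key fields.
#' @param params Named list folded into the key via a stable hash.
#' @param produce Function of one argument (the artifact path) that writes it.
#' @return The artifact path.
#' @export
ddg_cache <- function(cache_dir, structure_id, chain, relax_protocol_tag,
                      params = list(), produce) {
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  phash <- sprintf("h%.0f", hash_string(
    paste(names(params), unlist(params), sep = "=", collapse = ";")))
  key <- sanitize_path_component(
    paste(structure_id, chain, relax_protocol_tag, phash, sep = "__"))
  path <- file.path(cache_dir, paste0(key, ".relax"))
  if (file.exists(path)) {
    if (file.size(path) > 0L) return(path)
    warn(sprintf("corrupt cache entry %s; recomputing", basename(path)))
  }
  produce(path)
  if (!file.exists(path)) abort("produce() did not write the cache artifact")
  path
}

# ---- executors ------------------------------------------------------------

stub_score <- function(row, seed, metric, lo, hi) {
  key <- paste("stub", metric, row$calc_type, row$gene, row$protein_id,
               row$position, row$ref_aa, row$alt_aa, row$structure_id, seed,
               sep = "|")
  lo + (hi - lo) * hash_unit(key)
}

write_result <- function(workdir, metric, value, qualifier = "") {
  readr::write_csv(tibble(metric = metric, value = value, qualifier = qualifier),
                   file.path(workdir, "result.csv"), progress = FALSE)
}

#' Default executor registry
#'
#' One executor per calculation type. The clustering statistic runs natively
#' (`pathprox`); the stability, interface, PTM and digenic executors are
#' deterministic stubs emitting seeded pseudo-scores in documented ranges
#' (stability in \[-1, 7\] energy units, probabilities in \[0, 1\]) so
#' end-to-end runs, range aggregation and reports are fully reproducible.
#' `score_lookup` resolves precomputed score tables from its parameters.
#' Each executor receives `(row, params, workdir)` and writes
#' `workdir/result.csv` with columns `metric,value,qualifier`.
#'
#' @param seed Integer seed folded into every stub score.
#' @param cache_dir Relax-artifact repository for the stability stubs
#'   (`NULL` = a `ddg_repo` sibling of each workdir's case root).
#' @return Named list of executor functions.
#' @export
default_executors <- function(seed = 1, cache_dir = NULL) {
  ddg_exec <- function(row, params, workdir) {
    repo <- cache_dir %||% params$cache_dir %||% file.path(workdir, "..", "..", "..", "..", "ddg_repo")
    ddg_cache(repo, row$structure_id, params$chain %||% "A",
              sub("ddg_", "", row$calc_type),
              params[intersect("protocol", names(params))],
              produce = function(p) write_lines_utf8(
                sprintf("relaxed %s", row$structure_id), p))
    write_result(workdir, "ddg",
                 round(stub_score(row, seed, "ddg", -1, 7), 4), "stub")
  }
  list(
    ddg_monomer = ddg_exec,
    ddg_cartesian = ddg_exec,
    ppi_surface = function(row, params, workdir)
      write_result(workdir, "ppi_prob",
                   round(stub_score(row, seed, "ppi", 0, 1), 4), "stub"),
    ptm_site = function(row, params, workdir)
      write_result(workdir, "ptm_prob",
                   round(stub_score(row, seed, "ptm", 0, 1), 4), "stub"),
    digenic_pair = function(row, params, workdir)
      write_result(workdir, "digenic_score",
                   round(stub_score(row, seed, "digenic", 0, 1), 4), "stub"),
    score_lookup = function(row, params, workdir) {
      tables <- map(params$tables, ~ load_score_table(.x$path, .x$keying,
                                                      .x$score_name))
      hits <- lookup_scores(tibble(protein_id = row$protein_id,
                                   position = row$position,
                                   alt_aa = row$alt_aa), tables,
                            canonical_fallback = isTRUE(params$canonical_fallback))
      found <- hits %>% filter(!is.na(.data$value))
      readr::write_csv(
        tibble(metric = found$score_name,
               value = found$value,
               qualifier = found$provenance),
        file.path(workdir, "result.csv"), progress = FALSE)
    },
    pathprox = function(row, params, workdir) {
      coords_path <- params$coords_path %||% {
        cat_tbl <- read_structure_catalog(params$catalog_path)
        hit <- cat_tbl[cat_tbl$structure_id == row$structure_id, ]
        if (nrow(hit) == 0L)
          abort(sprintf("structure %s not in catalog", row$structure_id))
        hit$coords_path[1]
      }
      sites_path <- params$sites_path %||%
        file.path(params$sites_dir, paste0(row$structure_id, ".csv"))
      coords <- read_calpha(coords_path)
      rmap <- read_alignment_catalog(params$alignment_path) %>%
        filter(.data$structure_id == row$structure_id)
      sites <- readr::read_csv(sites_path, show_col_types = FALSE,
                               progress = FALSE)
      res <- pathprox_variant(coords, rmap, row$position, sites,
                              n_perm = params$n_perm %||% 999,
                              seed = (params$seed %||% seed) +
                                hash_string(row$job_id) %% 10000L,
                              kernel = params$kernel %||% "inverse")
      write_result(workdir, c("pathprox_score", "pathprox_pvalue"),
                   c(res$score, res$p_value),
                   c("", sprintf("n_perm=%d", as.integer(params$n_perm %||% 999))))
      readr::write_csv(res$per_chain,
                       file.path(workdir, "per_chain.csv"), progress = FALSE)
    }
  )
}

#' Execute a workplan locally
#'
#' Runs every row through its registered executor, driving the status
#' protocol (submitted -> running -> complete|failed). An executor exception
#' fails exactly that row — the captured condition message lands in the
#' status detail — and leaves the remaining jobs untouched. With the default
#' stub registry and a fixed seed and clock, two runs are byte-identical.
#'
#' @param plan Workplan tibble from [plan_case()].
#' @param registry Executor registry; see [default_executors()].
#' @param clock Injectable time source for status timestamps.
#' @return Tibble `job_id`, `state`, `detail`.
#' @export
run_local <- function(plan, registry = default_executors(), clock = Sys.time) {
  missing <- setdiff(unique(plan$calc_type), names(registry))
  if (length(missing) > 0L)
    abort(sprintf("no executor registered for: %s", paste(missing, collapse = ", ")))
  out <- map(seq_len(nrow(plan)), function(i) {
    row <- plan[i, ]
    params <- jsonlite::fromJSON(row$parameters_json, simplifyVector = FALSE)
    write_status(row$status_dir, "submitted", row$job_id, clock)
    write_status(row$status_dir, "running", "", clock)
    res <- tryCatch({
      registry[[row$calc_type]](row, params, row$workdir)
      write_status(row$status_dir, "complete", "", clock)
      tibble(job_id = row$job_id, state = "complete", detail = "")
    }, error = function(e) {
      write_status(row$status_dir, "failed", conditionMessage(e), clock)
      tibble(job_id = row$job_id, state = "failed",
             detail = conditionMessage(e))
    })
    res
  })
  list_rbind(out)
}

#' Collect job results and statuses for a workplan
#'
#' Reads each job's `result.csv` (one row per metric) and its latest status.
#' Jobs without a parseable result contribute status-only rows with `NA`
#' metric.
#'
#' @param plan Workplan tibble.
#' @return Tibble: workplan fields plus `state`, `metric`, `value`,
#'   `qualifier`.
#' @export
collect_results <- function(plan) {
  if (is.null(plan) || nrow(plan) == 0L) {
    return(tibble(job_id = character(), calc_type = character(),
                  gene = character(), protein_id = character(),
                  position = integer(), ref_aa = character(),
                  alt_aa = character(), structure_id = character(),
                  workdir = character(), status_dir = character(),
                  state = character(), metric = character(),
                  value = double(), qualifier = character()))
  }
  map(seq_len(nrow(plan)), function(i) {
    row <- plan[i, ]
    st <- read_status(row$status_dir)
    rf <- file.path(row$workdir, "result.csv")
    base <- row %>% select(-"parameters_json") %>% mutate(state = st$state)
    if (file.exists(rf)) {
      res <- tryCatch(
        readr::read_csv(rf, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          metric = readr::col_character(),
                          value = readr::col_double(),
                          qualifier = readr::col_character())),
        error = function(e) NULL)
      if (!is.null(res) && nrow(res) > 0L)
        return(tidyr::crossing(base, res))
    }
    base %>% mutate(metric = NA_character_, value = NA_real_,
                    qualifier = NA_character_)
  }) %>% list_rbind()
}
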