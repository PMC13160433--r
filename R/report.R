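# Case reporting: value-range aggregation across structures and isoforms, the
# case-wide landing report (HTML + a machine-readable CSV twin), transcript
# reports with a domain track, and the clinician-facing case summary
# spreadsheet. Rendering is idempotent from the current result files: it can
# run mid-pipeline (pending cells) and re-run after completion without
# changing schema.

#' Default report flag thresholds
#'
#' `ddg_flag`: stability change (energy units) at or above which a variant is
#' flagged destabilising; `p_flag`: clustering p-value at or below which the
#' spatial-clustering flag is set; `prob_flag`: probability cut for
#' interface/PTM/digenic stub calls.
#' @return Named list.
#' @export
report_thresholds <- function() list(ddg_flag = 2, p_flag = 0.05, prob_flag = 0.5)

#' Aggregate job results into per-variant value ranges
#'
#' Ranges arise because several structures (and isoforms) are considered per
#' variant: for each variant and metric the displayed value is `[min, max]`
#' over the contributing result files, with `n_structures` the count of
#' contributing values and `n_missing` the jobs of that calculation that
#' produced none (failed or non-numeric; never coerced to 0).
#'
#' @param results Tibble from [collect_results()].
#' @return Tibble `gene`, `protein_id`, `position`, `ref_aa`, `alt_aa`,
#'   `calc_type`, `metric`, `min`, `max`, `n_structures`, `n_missing`.
#' @export
aggregate_ranges <- function(results) {
  empty <- tibble(gene = character(), protein_id = character(),
                  position = integer(), ref_aa = character(),
                  alt_aa = character(), calc_type = character(),
                  metric = character(), min = double(), max = double(),
                  n_structures = integer(), n_missing = integer())
  if (nrow(results) == 0L) return(empty)
  per_group <- results %>%
    filter(.data$calc_type != "digenic_pair") %>%
    group_by(.data$gene, .data$protein_id, .data$position, .data$ref_aa,
             .data$alt_aa, .data$calc_type)
  groups <- per_group %>% group_split()
  out <- map(groups, function(g) {
    jobs <- unique(g$job_id)
    metrics <- unique(g$metric[!is.na(g$metric) & is.finite(g$value)])
    if (length(metrics) == 0L) {
      return(g %>% distinct(.data$gene, .data$protein_id, .data$position,
                            .data$ref_aa, .data$alt_aa, .data$calc_type) %>%
               mutate(metric = NA_character_, min = NA_real_, max = NA_real_,
                      n_structures = 0L, n_missing = length(jobs)))
    }
    map(metrics, function(m) {
      vals <- g$value[!is.na(g$metric) & g$metric == m & is.finite(g$value)]
      with_val <- unique(g$job_id[!is.na(g$metric) & g$metric == m &
                                    is.finite(g$value)])
      g %>% distinct(.data$gene, .data$protein_id, .data$position,
                     .data$ref_aa, .data$alt_aa, .data$calc_type) %>%
        mutate(metric = m, min = min(vals), max = max(vals),
               n_structures = length(with_val),
               n_missing = length(jobs) - length(with_val))
    }) %>% list_rbind()
  }) %>% list_rbind()
  if (is.null(out) || nrow(out) == 0L) return(empty)
  ungroup(out)
}

#' Order isoform child rows for display
#'
#' One child row per impacted isoform of a variant, the canonical isoform
#' first and `-N` suffixed isoforms in increasing numeric order.
#'
#' @param rows Tibble with a `protein_id` column (isoform-suffixed ids).
#' @return The same tibble, reordered, with `is_canonical` and `display_order`
#'   columns.
#' @export
expand_isoform_rows <- function(rows) {
  rows %>%
    mutate(is_canonical = isoform_suffix(.data$protein_id) == 1L,
           .suffix = isoform_suffix(.data$protein_id)) %>%
    arrange(.data$gene, .data$ref_aa, .data$position, .data$alt_aa,
            desc(.data$is_canonical), .data$.suffix, .data$protein_id) %>%
    mutate(display_order = row_number()) %>%
    select(-".suffix")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df) {
  if (nrow(df) == 0L)
    return("<p class='pending'>No rows.</p>")
  fmt <- function(x) {
    out <- ifelse(is.na(x), "pending",
                  ifelse(is.numeric(x), format(x, digits = 6, trim = TRUE),
                         as.character(x)))
    html_escape(out)
  }
  cells <- map(df, fmt)
  head_row <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                    collapse = ""), "</tr>")
  body <- map_chr(seq_len(nrow(df)), function(i) {
    paste0("<tr>", paste0("<td>", map_chr(cells, ~ .x[i]), "</td>",
                          collapse = ""), "</tr>")
  })
  paste0("<table>", head_row, paste(body, collapse = "\n"), "</table>")
}

#' Render the case-wide landing report
#'
#' One summary row per retained variant with expandable per-isoform child
#' rows, the digenic screen section, and a per-job status block. The HTML and
#' its machine-readable CSV twin are derived from the same aggregated table
#' (single source of truth); rendering twice from unchanged result files is
#' byte-identical, and a mid-run render shows missing cells as pending
#' without changing the schema.
#'
#' @param case Retained `vus_case`.
#' @param plan Workplan tibble.
#' @param out_dir Output directory.
#' @param thresholds See [report_thresholds()].
#' @return Invisible list: `html`, `csv`, `ranges`, `summary_csv`.
#' @export
render_case_report <- function(case, plan, out_dir,
                               thresholds = report_thresholds()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- collect_results(plan)
  ranges <- aggregate_ranges(results) %>%
    expand_isoform_rows()
  statuses <- results %>%
    distinct(.data$job_id, .data$calc_type, .data$gene, .data$protein_id,
             .data$state)
  digenic <- results %>%
    filter(.data$calc_type == "digenic_pair", !is.na(.data$metric)) %>%
    select("gene", "metric", "value", "state")
  summary_tbl <- case_summary_table(case, ranges, results, thresholds)

  csv_path <- file.path(out_dir, "report.csv")
  readr::write_csv(ranges, csv_path, progress = FALSE)
  summary_path <- file.path(out_dir, "case_summary.csv")
  readr::write_csv(summary_tbl, summary_path, progress = FALSE)

  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    sprintf("<title>Case %s</title>", html_escape(case$case_id)),
    "<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:3px 6px}.pending{color:#888}</style>",
    "</head><body>",
    sprintf("<h1>Case report: %s</h1>", html_escape(case$case_id)),
    sprintf("<p>%d retained variant(s); %d planned job(s).</p>",
            nrow(case$variants), if (is.null(plan)) 0L else nrow(plan)),
    "<h2>Per-variant calculated value ranges</h2>",
    "<p>Ranges arise because multiple structures (and isoforms) are considered per variant.</p>",
    html_table(ranges %>% select("display_order", "gene", "protein_id",
                                 "position", "ref_aa", "alt_aa",
                                 "is_canonical", "calc_type", "metric",
                                 "min", "max", "n_structures", "n_missing")),
    "<h2>Digenic analysis</h2>",
    html_table(digenic),
    "<h2>Case summary (draft)</h2>",
    html_table(summary_tbl),
    "<h2>Job status</h2>",
    html_table(statuses),
    "</body></html>")
  html_path <- file.path(out_dir, "report.html")
  write_lines_utf8(html, html_path)
  invisible(list(html = html_path, csv = csv_path, summary_csv = summary_path,
                 ranges = ranges))
}

case_summary_table <- function(case, ranges, results, thresholds) {
  v <- case$variants
  digenic <- results %>%
    filter(.data$calc_type == "digenic_pair",
           !is.na(.data$value),
           .data$value >= thresholds$prob_flag)
  partners_of <- function(g) {
    pairs <- strsplit(digenic$gene, "+", fixed = TRUE)
    hits <- keep(pairs, ~ g %in% .x)
    paste(sort(unique(unlist(map(hits, ~ setdiff(.x, g))))), collapse = ";")
  }
  flag_for <- function(vr, metric, cmp, cut) {
    r <- ranges %>% filter(.data$protein_id == vr$protein_id,
                           .data$position == vr$position,
                           .data$ref_aa == vr$ref_aa,
                           .data$alt_aa == vr$alt_aa,
                           !is.na(.data$metric), .data$metric == metric)
    if (nrow(r) == 0L) return("")
    hit <- if (cmp == "ge") any(r$max >= cut, na.rm = TRUE)
           else any(r$min <= cut, na.rm = TRUE)
    if (isTRUE(hit)) "yes" else ""
  }
  map(seq_len(nrow(v)), function(i) {
    vr <- v[i, ]
    tibble(
      gene = vr$gene,
      variant = format_aa_change(vr$ref_aa, vr$position, vr$alt_aa),
      protein_id = vr$protein_id,
      inheritance = vr$inheritance,
      destabilizing_flag = flag_for(vr, "ddg", "ge", thresholds$ddg_flag),
      clustering_flag = flag_for(vr, "pathprox_pvalue", "le", thresholds$p_flag),
      interface_flag = flag_for(vr, "ppi_prob", "ge", thresholds$prob_flag),
      ptm_flag = flag_for(vr, "ptm_prob", "ge", thresholds$prob_flag),
      digenic_partners = partners_of(vr$gene),
      recommendation = ""
    )
  }) %>% list_rbind()
}

#' Draft the clinician-facing case summary spreadsheet
#'
#' One line per variant: gene, variant, high-level flags (destabilising
#' stability change, significant spatial clustering, interface/PTM hits,
#' digenic partners) and a free-text recommendation column left blank for the
#' analyst.
#'
#' @param case Retained `vus_case`.
#' @param plan Workplan tibble (results are read from its workdirs).
#' @param path Output CSV path.
#' @param thresholds See [report_thresholds()].
#' @return The summary tibble, invisibly.
#' @export
draft_case_summary <- function(case, plan, path,
                               thresholds = report_thresholds()) {
  results <- collect_results(plan)
  ranges <- aggregate_ranges(results)
  tbl <- case_summary_table(case, ranges, results, thresholds)
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(tbl)
}

#' Read a domain-interval track
#' @param path BED-like TSV `protein_id,start,end,name` (1-based closed).
#' @return Typed tibble.
#' @export
read_domain_track <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    protein_id = readr::col_character(),
                    start = readr::col_integer(),
                    end = readr::col_integer(),
                    name = readr::col_character()))
}

#' Write a static SVG domain track with the variant position marked
#'
#' Domains as boxes along the sequence axis, the variant as a diamond above —
#' the static replacement for an interactive viewer session. Hand-assembled
#' SVG, byte-deterministic.
#'
#' @param domains Tibble from [read_domain_track()] (one protein).
#' @param peptide_length Protein length in residues.
#' @param variant_position Residue to mark.
#' @param path Output `.svg` path.
#' @return `path`, invisibly.
#' @export
write_domain_track_svg <- function(domains, peptide_length, variant_position,
                                   path) {
  w <- 640; h <- 80; pad <- 20
  sx <- function(pos) pad + (pos - 1) / max(peptide_length - 1, 1) * (w - 2 * pad)
  boxes <- map_chr(seq_len(nrow(domains)), function(i) {
    d <- domains[i, ]
    sprintf(paste0("<rect x='%.1f' y='40' width='%.1f' height='20' ",
                   "fill='#7aa' stroke='#357'/>",
                   "<text x='%.1f' y='75' font-size='10' text-anchor='middle'>%s</text>"),
            sx(d$start), sx(d$end) - sx(d$start), (sx(d$start) + sx(d$end)) / 2,
            html_escape(d$name))
  })
  vx <- sx(variant_position)
  svg <- c(
    sprintf("<svg xmlns='http://www.w3.org/2000/svg' width='%d' height='%d'>", w, h),
    sprintf("<line x1='%.1f' y1='50' x2='%.1f' y2='50' stroke='#333'/>",
            sx(1), sx(peptide_length)),
    boxes,
    sprintf("<polygon points='%.1f,22 %.1f,32 %.1f,42 %.1f,32' fill='#e6399b'/>",
            vx, vx + 6, vx, vx - 6),
    sprintf("<text x='%.1f' y='16' font-size='10' text-anchor='middle'>%d</text>",
            vx, variant_position),
    "</svg>")
  write_lines_utf8(svg, path)
  invisible(path)
}

#' Render a per-transcript report
#'
#' Domain track (SVG), structure summary table (every selected structure
#' exactly once), and per-structure result blocks.
#'
#' @param protein_id Protein/isoform identifier.
#' @param peptide_length Protein length.
#' @param variant_position Variant residue.
#' @param selection A [select_structures()] result.
#' @param results Tibble from [collect_results()] filtered to this protein.
#' @param domains Domain tibble for this protein.
#' @param out_dir Output directory.
#' @return Invisible path of the HTML file.
#' @export
render_transcript_report <- function(protein_id, peptide_length,
                                     variant_position, selection, results,
                                     domains, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sanitize_path_component(protein_id)
  svg_path <- file.path(out_dir, paste0(stem, "_domains.svg"))
  write_domain_track_svg(domains, peptide_length, variant_position, svg_path)
  sel <- selection$selected
  blocks <- map_chr(seq_len(nrow(sel)), function(i) {
    s <- sel[i, ]
    block <- results %>%
      filter(!is.na(.data$structure_id), .data$structure_id == s$structure_id,
             !is.na(.data$metric)) %>%
      select("calc_type", "metric", "value", "qualifier", "state")
    paste0(sprintf("<h3 id='%s'>%s (%s, %s)</h3>", html_escape(s$structure_id),
                   html_escape(s$structure_id), html_escape(s$source),
                   html_escape(s$method)),
           html_table(block))
  })
  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    sprintf("<title>%s</title>", html_escape(protein_id)),
    "<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:3px 6px}</style>",
    "</head><body>",
    sprintf("<h1>Transcript report: %s</h1>", html_escape(protein_id)),
    sprintf("<img src='%s' alt='domain track'/>", basename(svg_path)),
    "<h2>Structure summary</h2>",
    html_table(sel %>% select("structure_id", "source", "method", "quality",
                              "oligomeric_state", "covers_variant",
                              "marginal_utility", "reasons")),
    blocks,
    "</body></html>")
  path <- file.path(out_dir, paste0(stem, ".html"))
  write_lines_utf8(html, path)
  invisible(path)
}
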