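# Spatial clustering of pathogenic variation. The statistic asks whether a
# query residue sits closer, in 3D, to the constellation of pathogenic-labeled
# sites than to the benign-labeled ones: score = mean kernel proximity to
# pathogenic C-alpha atoms minus mean kernel proximity to benign ones, with a
# permutation null that relocates both labeled sets uniformly over the mapped
# residues of the chain ("randomly placed" sites).

#' Read C-alpha coordinates from a PDB file
#' @param path PDB file.
#' @return Tibble `chain`, `residue`, `insertion_code`, `x`, `y`, `z`.
#' @export
read_calpha <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  ca <- pdb$atom[pdb$atom$elety == "CA", ]
  tibble(
    chain = as.character(ca$chain),
    residue = as.integer(ca$resno),
    insertion_code = ifelse(is.na(ca$insert), "", as.character(ca$insert)),
    x = ca$x, y = ca$y, z = ca$z
  )
}

kernel_fun <- function(kernel = c("inverse", "exponential"), scale = 8) {
  kernel <- match.arg(kernel)
  switch(kernel,
         inverse = function(d) 1 / (1 + d),
         exponential = function(d) exp(-d / scale))
}

#' Kernel proximity of a query point to a set of sites
#'
#' Mean over sites of `K(d)` with `K(d) = 1/(1+d)` by default (`d` the
#' Euclidean C-alpha distance in Angstrom); an exponential kernel
#' `exp(-d/scale)` is available. Exclusion of the query's own residue is the
#' caller's responsibility (see [pathprox_score()]).
#'
#' @param query Numeric length-3 coordinate.
#' @param coords Numeric matrix, one site per row (3 columns).
#' @param kernel `"inverse"` (default) or `"exponential"`.
#' @param scale Length scale of the exponential kernel, Angstrom.
#' @return Numeric scalar.
#' @export
proximity <- function(query, coords, kernel = "inverse", scale = 8) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (nrow(coords) == 0L)
    abort("proximity is undefined for an empty site set",
          class = "vus3d_empty_sites")
  d <- sqrt(colSums((t(coords) - as.numeric(query))^2))
  mean(kernel_fun(kernel, scale)(d))
}

site_matrix <- function(sites) cbind(sites$x, sites$y, sites$z)

# Drop any site on the query's own residue (leave-one-out).
drop_self <- function(sites, query_chain, query_residue) {
  if (is.null(query_chain) || is.null(query_residue)) return(sites)
  sites %>% filter(!(.data$chain == query_chain & .data$residue == query_residue))
}

#' Clustering score of a query against labeled sites
#'
#' `score = proximity(query, pathogenic) - proximity(query, benign)`;
#' positive values mean the query fits the pathogenic constellation better.
#' Antisymmetric under a label swap by construction. Sites on the query's own
#' residue are excluded (leave-one-out).
#'
#' @param query List/one-row tibble with `x`, `y`, `z` and optionally `chain`,
#'   `residue` for the leave-one-out rule.
#' @param sites Tibble `chain`, `residue`, `label` (`pathogenic`/`benign`),
#'   `x`, `y`, `z`.
#' @param kernel,scale See [proximity()].
#' @return Numeric scalar.
#' @export
pathprox_score <- function(query, sites, kernel = "inverse", scale = 8) {
  sites <- drop_self(as_tibble(sites), query$chain %||% NULL,
                     query$residue %||% NULL) %>%
    distinct(.data$chain, .data$residue, .data$label, .keep_all = TRUE)
  q <- c(query$x, query$y, query$z)
  path <- sites %>% filter(.data$label == "pathogenic")
  ben <- sites %>% filter(.data$label == "benign")
  proximity(q, site_matrix(path), kernel, scale) -
    proximity(q, site_matrix(ben), kernel, scale)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Permutation test for spatial clustering of a query variant
#'
#' The null relocates the pathogenic and benign site sets onto residues drawn
#' uniformly without replacement from the eligible residues (all mapped
#' residues of the chain, the query's own residue excluded), recomputing the
#' score each draw. `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so p is
#' never exactly zero. Fully reproducible under a fixed seed.
#'
#' When one label class is missing the result is flagged one-sided and the
#' p-value suppressed; when too few eligible residues remain the test is
#' skipped with a recorded reason.
#'
#' @param query As in [pathprox_score()].
#' @param sites Labeled site tibble.
#' @param eligible Tibble `chain`, `residue`, `x`, `y`, `z` of eligible
#'   residues.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @param kernel,scale See [proximity()].
#' @return Object of class `pathprox_result`.
#' @export
permutation_test <- function(query, sites, eligible, n_perm = 999, seed = 1,
                             kernel = "inverse", scale = 8) {
  stopifnot(n_perm >= 99)
  sites <- drop_self(as_tibble(sites), query$chain %||% NULL,
                     query$residue %||% NULL) %>%
    distinct(.data$chain, .data$residue, .data$label, .keep_all = TRUE)
  n_path <- sum(sites$label == "pathogenic")
  n_ben <- sum(sites$label == "benign")
  res <- structure(list(
    score = NA_real_, p_value = NA_real_, n_permutations = as.integer(n_perm),
    n_pathogenic = n_path, n_benign = n_ben, seed = as.integer(seed),
    kernel = kernel, one_sided = FALSE, skipped = NA_character_,
    null_scores = numeric()
  ), class = "pathprox_result")
  if (n_path == 0L || n_ben == 0L) {
    res$one_sided <- TRUE
    res$skipped <- "one label class missing; p-value suppressed"
    if (n_path + n_ben > 0L) {
      q <- c(query$x, query$y, query$z)
      res$score <- proximity(q, site_matrix(sites), kernel, scale) *
        (if (n_path > 0L) 1 else -1)
    }
    return(res)
  }
  res$score <- pathprox_score(query, sites, kernel, scale)
  pool <- drop_self(as_tibble(eligible), query$chain %||% NULL,
                    query$residue %||% NULL)
  if (nrow(pool) <= n_path + n_ben) {
    res$skipped <- sprintf("only %d eligible residues for %d sites",
                           nrow(pool), n_path + n_ben)
    return(res)
  }
  K <- kernel_fun(kernel, scale)(
    sqrt((pool$x - query$x)^2 + (pool$y - query$y)^2 + (pool$z - query$z)^2))
  null_scores <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(nrow(pool), n_path + n_ben)
      mean(K[idx[seq_len(n_path)]]) - mean(K[idx[(n_path + 1L):(n_path + n_ben)]])
    }, numeric(1))
  })
  res$null_scores <- null_scores
  res$p_value <- (1 + sum(null_scores >= res$score)) / (1 + n_perm)
  res
}

#' @export
print.pathprox_result <- function(x, ...) {
  cat(sprintf("<pathprox_result> score %.4f, p = %s (%d perms, %dP/%dB sites, seed %d)%s\n",
              x$score,
              ifelse(is.na(x$p_value), "NA", format(x$p_value, digits = 4)),
              x$n_permutations, x$n_pathogenic, x$n_benign, x$seed,
              if (!is.na(x$skipped)) paste0(" [", x$skipped, "]") else ""))
  invisible(x)
}

#' @describeIn permutation_test Tidy the result into a one-row tibble.
#' @param x A `pathprox_result`.
#' @param ... Unused.
#' @export
tidy.pathprox_result <- function(x, ...) {
  tibble(score = x$score, p_value = x$p_value,
         n_permutations = x$n_permutations,
         n_pathogenic = x$n_pathogenic, n_benign = x$n_benign,
         seed = x$seed, one_sided = x$one_sided, skipped = x$skipped)
}

#' @describeIn permutation_test One-row test summary (alias of `tidy`).
#' @export
glance.pathprox_result <- function(x, ...) tidy(x)

#' Per-residue clustering score track
#'
#' Evaluates the clustering score at every mapped residue's C-alpha, for
#' backbone colouring (low to high). Each residue's own sites are excluded
#' from its proximity terms.
#'
#' @param sites Labeled site tibble (see [pathprox_score()]).
#' @param residues Tibble `chain`, `residue`, `x`, `y`, `z` of residues to
#'   score (e.g. [read_calpha()] output).
#' @param kernel,scale See [proximity()].
#' @return Tibble `chain`, `residue`, `score`.
#' @export
per_residue_scores <- function(sites, residues, kernel = "inverse", scale = 8) {
  residues <- as_tibble(residues)
  residues %>%
    mutate(score = map_dbl(seq_len(nrow(residues)), function(i) {
      q <- residues[i, ]
      pathprox_score(list(chain = q$chain, residue = q$residue,
                          x = q$x, y = q$y, z = q$z),
                     sites, kernel, scale)
    })) %>%
    select("chain", "residue", "score")
}

#' Read a labeled-site table
#' @param path CSV `structure_id,chain,residue,label`.
#' @return Typed tibble.
#' @export
read_site_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    structure_id = readr::col_character(),
                    chain = readr::col_character(),
                    residue = readr::col_integer(),
                    label = readr::col_character()))
}

#' Run the clustering test for a variant on one structure
#'
#' Maps the variant position through the residue map, attaches coordinates,
#' replicates the labeled sites across protomer chains, evaluates the query
#' on each chain carrying it, and reports the minimum p-value with per-chain
#' detail retained.
#'
#' @param coords C-alpha tibble from [read_calpha()].
#' @param rmap Residue-map segments from [residue_map()].
#' @param position Variant position (transcript coordinates).
#' @param sites Tibble `residue`, `label` (structure residue numbering; chain
#'   column, if present, is ignored — sites are replicated per protomer).
#' @param n_perm,seed,kernel,scale See [permutation_test()].
#' @return List with `p_value` (min over chains), `score` (of the min-p
#'   chain), `per_chain` (tibble of per-chain results).
#' @export
pathprox_variant <- function(coords, rmap, position, sites, n_perm = 999,
                             seed = 1, kernel = "inverse", scale = 8) {
  addr <- map_residue(position, rmap)
  if (nrow(addr) == 0L)
    return(list(p_value = NA_real_, score = NA_real_,
                per_chain = tibble(), note = "variant position unmapped"))
  chains <- addr$chain
  per_chain <- map(seq_along(chains), function(i) {
    ch <- chains[i]
    ch_coords <- coords %>% filter(.data$chain == ch)
    mapped <- covered_positions(rmap %>% filter(.data$chain == ch))
    # eligible = mapped residues of this chain present in the coordinates
    addr_tbl <- map(mapped, ~ map_residue(.x, rmap %>% filter(.data$chain == ch))) %>%
      list_rbind()
    eligible <- addr_tbl %>%
      inner_join(ch_coords, by = c("chain", "residue"))
    ch_sites <- as_tibble(sites) %>%
      select(any_of(c("residue", "label"))) %>%
      mutate(chain = ch) %>%
      inner_join(ch_coords, by = c("chain", "residue"))
    qrow <- ch_coords %>% filter(.data$residue == addr$residue[i])
    if (nrow(qrow) == 0L) return(NULL)
    r <- permutation_test(
      list(chain = ch, residue = qrow$residue[1],
           x = qrow$x[1], y = qrow$y[1], z = qrow$z[1]),
      ch_sites, eligible, n_perm = n_perm, seed = seed + i - 1L,
      kernel = kernel, scale = scale)
    tidy(r) %>% mutate(chain = ch, .before = 1)
  }) %>% compact() %>% list_rbind()
  if (nrow(per_chain) == 0L || all(is.na(per_chain$p_value)))
    return(list(p_value = NA_real_,
                score = if (nrow(per_chain) > 0L) per_chain$score[1] else NA_real_,
                per_chain = per_chain, note = "no testable chain"))
  best <- which.min(per_chain$p_value)
  list(p_value = per_chain$p_value[best], score = per_chain$score[best],
       per_chain = per_chain, note = NA_character_)
}
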