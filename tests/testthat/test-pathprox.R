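test_that("kernel proximity matches hand-computed values", {
  expect_equal(proximity(c(0, 0, 0), matrix(c(0, 0, 0), ncol = 3)), 1.0)
  expect_equal(proximity(c(0, 0, 0), matrix(c(1, 0, 0), ncol = 3)), 0.5)
  # sites at 1 A and 3 A: mean(1/2, 1/4)
  expect_equal(proximity(c(0, 0, 0),
                         rbind(c(1, 0, 0), c(0, 3, 0))), 0.375)
  expect_error(proximity(c(0, 0, 0), matrix(numeric(), ncol = 3)),
               class = "vus3d_empty_sites")
})

test_that("a mirror-symmetric configuration scores exactly zero", {
  sites <- tibble(chain = "A", residue = c(10L, 20L),
                  label = c("pathogenic", "benign"),
                  x = c(5, -5), y = 0, z = 0)
  q <- list(chain = "A", residue = 1L, x = 0, y = 0, z = 0)
  expect_equal(pathprox_score(q, sites), 0)
})

test_that("scores are antisymmetric under label swap and rigid-motion invariant", {
  set.seed(31)
  for (i in 1:100) {
    cfg <- random_site_config()
    s <- pathprox_score(cfg$query, cfg$sites)
    expect_identical(pathprox_score(cfg$query, swap_labels(cfg$sites)), -s)
    # random rotation (QR of a gaussian matrix) + translation
    qr_m <- qr.Q(qr(matrix(rnorm(9), 3)))
    shift <- rnorm(3, sd = 20)
    rot <- function(df) {
      m <- as.matrix(df[, c("x", "y", "z")]) %*% t(qr_m)
      df$x <- m[, 1] + shift[1]; df$y <- m[, 2] + shift[2]
      df$z <- m[, 3] + shift[3]; df
    }
    sites_r <- rot(cfg$sites)
    q_m <- c(cfg$query$x, cfg$query$y, cfg$query$z) %*% t(qr_m)
    q_r <- list(chain = "A", residue = cfg$query$residue,
                x = q_m[1] + shift[1], y = q_m[2] + shift[2],
                z = q_m[3] + shift[3])
    expect_lt(abs(pathprox_score(q_r, sites_r) - s), 1e-9)
  }
})

test_that("a query inside a tight pathogenic cluster scores positive", {
  sites <- tibble(chain = "A", residue = 1:6,
                  label = rep(c("pathogenic", "benign"), each = 3),
                  x = c(1, -1, 0, 25, 26, 27), y = c(0, 0, 1, 0, 0, 0), z = 0)
  q <- list(chain = "A", residue = 99L, x = 0, y = 0, z = 0)
  expect_gt(pathprox_score(q, sites), 0)
})

test_that("the permutation test is reproducible and honours the +1 convention", {
  n_res <- 100
  co <- vus3d:::helix_coords(n_res) %>%
    mutate(chain = "A", residue = seq_len(n_res))
  # pathogenic sites hug the query; benign sites sit at the far end
  sites <- bind_rows(
    co[48:52, ] %>% mutate(label = "pathogenic"),
    co[c(1:2, 96:98), ] %>% mutate(label = "benign"))
  q <- list(chain = "A", residue = 50L, x = co$x[50], y = co$y[50], z = co$z[50])
  r1 <- permutation_test(q, sites, co, n_perm = 99, seed = 4)
  r2 <- permutation_test(q, sites, co, n_perm = 99, seed = 4)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(r1$null_scores, r2$null_scores)
  expect_equal(r1$p_value,
               (1 + sum(r1$null_scores >= r1$score)) / (1 + 99))
  # observed beats every null draw here: p is exactly 1/100
  expect_equal(sum(r1$null_scores >= r1$score), 0L)
  expect_equal(r1$p_value, 1 / 100)
  expect_gt(r1$score, 0)
})

test_that("degenerate inputs are flagged, not silently scored", {
  co <- vus3d:::helix_coords(30) %>% mutate(chain = "A", residue = 1:30)
  one_label <- co[1:4, ] %>% mutate(label = "pathogenic")
  q <- list(chain = "A", residue = 20L, x = co$x[20], y = co$y[20], z = co$z[20])
  r <- permutation_test(q, one_label, co, n_perm = 99, seed = 1)
  expect_true(r$one_sided)
  expect_true(is.na(r$p_value))
  # too few eligible residues
  q25 <- list(chain = "A", residue = 25L, x = co$x[25], y = co$y[25],
              z = co$z[25])
  sites <- co[1:20, ] %>% mutate(label = rep(c("pathogenic", "benign"), 10))
  r2 <- permutation_test(q25, sites, co[1:20, ], n_perm = 99, seed = 1)
  expect_match(r2$skipped, "eligible")
  expect_true(is.na(r2$p_value))
})

test_that("per-residue tracks are total, leave-one-out, and label-antisymmetric", {
  cfg <- withr::with_seed(8, random_site_config(n_res = 40))
  track <- per_residue_scores(cfg$sites, cfg$coords)
  expect_equal(nrow(track), 40L)
  expect_true(all(is.finite(track$score)))
  swapped <- per_residue_scores(swap_labels(cfg$sites), cfg$coords)
  expect_equal(swapped$score, -track$score)
  # a residue carrying a pathogenic site is scored from the *other* sites
  ps <- cfg$sites[cfg$sites$label == "pathogenic", ][1, ]
  others <- cfg$sites[!(cfg$sites$residue == ps$residue), ]
  manual <- pathprox_score(list(chain = ps$chain, residue = ps$residue,
                                x = ps$x, y = ps$y, z = ps$z), others)
  expect_equal(track$score[track$residue == ps$residue], manual)
})

test_that("planted clusters get more significant with wider separation", {
  # queries sit at the cluster edge (8-14 A from the centre along the helix
  # axis) so power is not saturated and the separation effect is visible
  seps <- c(6, 15, 30)
  med_p <- vapply(seps, function(sep) {
    ps <- vapply(1:30, function(r) {
      n_res <- 80
      co <- vus3d:::helix_coords(n_res) %>%
        mutate(chain = "A", residue = seq_len(n_res))
      pl <- tryCatch(plant_clusters(
        co, list(n_pathogenic = 4, n_benign = 10, cluster_radius = 8,
                 separation = sep), seed = 7000 * sep + r),
        error = function(e) NULL)
      if (is.null(pl)) return(NA_real_)
      sites <- pl$sites %>% inner_join(co, by = c("chain", "residue"))
      center <- pl$truth$center_residue
      dz <- abs(co$z - co$z[center])
      free <- setdiff(co$residue[dz >= 8 & dz <= 14], sites$residue)
      if (length(free) == 0L) return(NA_real_)
      qi <- free[1]
      q <- list(chain = "A", residue = qi, x = co$x[qi], y = co$y[qi],
                z = co$z[qi])
      permutation_test(q, sites, co, n_perm = 99, seed = r)$p_value
    }, numeric(1))
    median(ps, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_p) <= 0))
  expect_lt(med_p[3], med_p[1])
})

test_that("multimer evaluation replicates sites per protomer and takes min p", {
  n_res <- 60
  co <- bind_rows(
    vus3d:::helix_coords(n_res) %>% mutate(chain = "A", residue = seq_len(n_res)),
    vus3d:::helix_coords(n_res, origin = c(30, 0, 0)) %>%
      mutate(chain = "B", residue = seq_len(n_res)))
  rmap <- tibble(structure_id = "D1", chain = c("A", "B"),
                 seg_start_transcript = 10L, seg_start_residue = 1L,
                 seg_length = n_res)
  sites <- tibble(residue = c(5L, 6L, 7L, 40L, 45L, 50L),
                  label = rep(c("pathogenic", "benign"), each = 3))
  res <- pathprox_variant(co, rmap, 15L, sites, n_perm = 99, seed = 2)
  expect_equal(nrow(res$per_chain), 2L)
  expect_setequal(res$per_chain$chain, c("A", "B"))
  expect_equal(res$p_value, min(res$per_chain$p_value))
})
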