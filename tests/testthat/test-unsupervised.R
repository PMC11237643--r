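test_that("two well-separated blobs cluster at k = 2 with high silhouette", {
  n_half <- 20
  withr::with_seed(12, {
    a <- matrix(rnorm(n_half * 10, 100, 5), nrow = n_half)
    b <- matrix(rnorm(n_half * 10, 2000, 50), nrow = n_half)
  })
  tab <- make_attr_table(rbind(a, b), normalized = TRUE)
  sol <- cluster_samples(tab, k_range = 2:6, seed = 1)
  expect_identical(sol$k, 2L)
  expect_gt(max(sol$diagnostics$silhouette), 0.7)
  # blob membership is recovered exactly
  expect_length(unique(sol$assignment[1:n_half]), 1)
  expect_length(unique(sol$assignment[(n_half + 1):(2 * n_half)]), 1)
})

test_that("degenerate clustering inputs fail loudly", {
  flat <- make_attr_table(matrix(5, nrow = 6, ncol = 4), normalized = TRUE)
  expect_error(cluster_samples(flat, k_range = 2:3), "constant|identical")
  tab <- make_attr_table(matrix(runif(24), 6), normalized = TRUE)
  expect_error(cluster_samples(tab, k_range = 2:10), "k_range")
})

test_that("cluster assignment is invariant to sample order", {
  withr::with_seed(14, m <- rbind(matrix(rnorm(50, 10, 1), 5),
                                  matrix(rnorm(50, 500, 10), 5)))
  tab <- make_attr_table(m, normalized = TRUE)
  sol1 <- cluster_samples(tab, k_range = 2:4, seed = 3)
  perm <- c(7, 2, 9, 1, 10, 4, 3, 8, 5, 6)
  tab2 <- attr_table(tibble::as_tibble(tab)[perm, ], "KO", normalized = TRUE)
  sol2 <- cluster_samples(tab2, k_range = 2:4, seed = 3)
  expect_identical(sol1$k, sol2$k)
  expect_identical(sol1$assignment[sort(names(sol1$assignment))],
                   sol2$assignment[sort(names(sol2$assignment))])
})

test_that("per-cluster regressions find a planted total-abundance gradient", {
  n <- 30
  withr::with_seed(15, {
    soc <- runif(n, 10, 300)
    m <- cbind(driver = 2 * soc + rnorm(n, 0, 5),
               matrix(50, nrow = n, ncol = 5))
  })
  tab <- make_attr_table(m, normalized = TRUE,
                         attrs = c("driver", sprintf("C%d", 1:5)))
  env <- env_table(data.frame(sample = tab$sample, soc = soc,
                              cec = rep(20, n)))
  sol <- fake_solution(setNames(rep(1L, n), tab$sample))
  prof <- suppressMessages(profile_clusters(sol, tab, env, alpha = 0.05))
  soc_row <- dplyr::filter(prof$regressions, .data$factor == "soc")
  expect_true(soc_row$significant)
  expect_gt(soc_row$slope, 0)
  expect_gt(soc_row$r_squared, 0.9)
  # constant factor is skipped, not significant
  cec_row <- dplyr::filter(prof$regressions, .data$factor == "cec")
  expect_true(is.na(cec_row$p_value))
  expect_false(cec_row$significant)
  expect_lte(prof$summary$n_significant, 6)
})

test_that("tiny clusters are unusable rather than significant", {
  n <- 12
  withr::with_seed(16, {
    soc <- runif(n, 10, 300)
    m <- matrix(runif(n * 4, 10, 100), nrow = n)
  })
  tab <- make_attr_table(m, normalized = TRUE)
  env <- env_table(data.frame(sample = tab$sample, soc = soc))
  asg <- setNames(c(rep(1L, 10), 2L, 2L), tab$sample)
  prof <- suppressMessages(profile_clusters(fake_solution(asg), tab, env))
  expect_false(prof$summary$usable[prof$summary$cluster == 2])
  expect_identical(prof$summary$n_significant[prof$summary$cluster == 2], 0L)
})

test_that("cluster selection maximizes significant correlations, R2 breaks ties", {
  mk_profiles <- function(summary_tbl) {
    structure(list(regressions = tibble::tibble(), summary = summary_tbl,
                   alpha = 0.05),
              class = "fp_cluster_profiles")
  }
  s <- tibble::tibble(cluster = 1:3, n_samples = c(50, 40, 30),
                      usable = TRUE, n_significant = c(5L, 2L, 0L),
                      mean_r2_significant = c(0.5, 0.6, 0))
  expect_identical(suppressMessages(select_cluster(mk_profiles(s))), 1L)

  tie <- tibble::tibble(cluster = 1:2, n_samples = c(50, 40), usable = TRUE,
                        n_significant = c(5L, 5L),
                        mean_r2_significant = c(0.4, 0.6))
  expect_identical(suppressMessages(select_cluster(mk_profiles(tie))), 2L)

  single <- tibble::tibble(cluster = 1L, n_samples = 50, usable = TRUE,
                           n_significant = 1L, mean_r2_significant = 0.2)
  expect_identical(suppressMessages(select_cluster(mk_profiles(single))), 1L)

  none <- tibble::tibble(cluster = 1L, n_samples = 2, usable = FALSE,
                         n_significant = 0L, mean_r2_significant = 0)
  expect_error(suppressMessages(select_cluster(mk_profiles(none))), "usable")
})

test_that("cluster fingerprints cut dominant-abundance and high-CV heads", {
  n <- 10
  withr::with_seed(18, {
    noise <- matrix(runif(n * 20, 40, 60), nrow = n)
    big1 <- runif(n, 4000, 6000)
    big2 <- runif(n, 4000, 6000)
    swing1 <- rep(c(0, 90), length.out = n)   # high CV
    swing2 <- rep(c(90, 0), length.out = n)
    flat <- rep(50, n)                        # CV exactly 0
  })
  m <- cbind(noise, big1 = big1, big2 = big2, swing1 = swing1,
             swing2 = swing2, flat = flat)
  tab <- make_attr_table(m, normalized = TRUE,
                         attrs = c(sprintf("N%02d", 1:20), "big1", "big2",
                                   "swing1", "swing2", "flat"))
  sol <- fake_solution(setNames(rep(1L, n), tab$sample))
  fp <- extract_cluster_fingerprint(tab, sol, 1L)
  expect_setequal(fp$abundant_members$attribute_id, c("big1", "big2"))
  expect_setequal(fp$variable_members$attribute_id, c("swing1", "swing2"))
  expect_false("flat" %in% fp$variable_members$attribute_id)

  # invariant to attribute column order
  perm <- c(1, sample(2:ncol(tab)))
  tab2 <- attr_table(tibble::as_tibble(tab)[, perm], "KO", normalized = TRUE)
  fp2 <- extract_cluster_fingerprint(tab2, sol, 1L)
  expect_setequal(fp2$abundant_members$attribute_id,
                  fp$abundant_members$attribute_id)
  expect_setequal(fp2$variable_members$attribute_id,
                  fp$variable_members$attribute_id)
})

test_that("the full unsupervised pipeline recovers the fertile cluster", {
  sim <- generate_fertile_scenario(generator_spec(n_samples = 150L,
                                                  n_background = 200L),
                                   seed = 19)
  norm <- normalize_table(sim$table)
  res <- suppressMessages(fp_unsupervised(norm, sim$env, seed = 19))
  sel <- names(res$clusters$assignment)[
    res$clusters$assignment == res$selected_cluster]
  truth <- sim$truth$fertile_cluster_samples
  overlap <- length(intersect(sel, truth)) / length(union(sel, truth))
  expect_gt(overlap, 0.9)
  expect_true(res$informative)
  members <- unique(c(res$fingerprint$abundant_members$attribute_id,
                      res$fingerprint$variable_members$attribute_id))
  # this scenario is scaled down from the reference conditions (fewer samples
  # and background attributes), so a single planted straggler may fall just
  # below the abundance cut when a background attribute interleaves
  containment <- mean(sim$truth$fertile_fingerprint %in% members)
  expect_gte(containment, 0.9)
})
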