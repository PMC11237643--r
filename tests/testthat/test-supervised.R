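test_that("extreme splits take the outer deciles deterministically", {
  env <- env_table(data.frame(sample = sprintf("x%03d", 1:100), soc = 1:100))
  sp <- split_extremes(env, "soc", 0.10)
  expect_identical(sp$low_ids, sprintf("x%03d", 1:10))
  expect_identical(sp$high_ids, sprintf("x%03d", 100:91))
  expect_length(intersect(sp$low_ids, sp$high_ids), 0)

  # floor rule: 25 usable samples -> 2 per group
  env25 <- env_table(data.frame(sample = sprintf("y%02d", 1:25), soc = 1:25))
  sp25 <- split_extremes(env25, "soc", 0.10)
  expect_length(sp25$low_ids, 2)
  expect_length(sp25$high_ids, 2)

  # missing factor values are excluded before ranking
  env_na <- env_table(data.frame(sample = sprintf("z%03d", 1:30),
                                 soc = c(rep(NA, 5), 1:25)))
  expect_identical(split_extremes(env_na, "soc")$n_used, 25L)

  expect_error(split_extremes(env_table(data.frame(sample = sprintf("w%02d", 1:30),
                                                   soc = rep(1, 30))), "soc"),
               "no variation")
  expect_error(split_extremes(env25, "ph"), "not in metadata")
})

test_that("a perfectly separating attribute is ranked first", {
  n <- 40
  ids <- sprintf("p%02d", seq_len(n))
  grp <- rep(c("low", "high"), each = n / 2)
  for (seed in 1:5) {
    withr::with_seed(100 + seed, {
      m <- matrix(runif(n * 50, 0, 100), nrow = n)
      m <- cbind(m, signal = ifelse(grp == "high", 90, 10) + runif(n))
    })
    tab <- make_attr_table(m, normalized = TRUE, samples = ids,
                           attrs = c(sprintf("N%02d", 1:50), "signal"))
    prof <- rank_importance(tab, setNames(grp, ids), seed = seed, n_trees = 200)
    expect_identical(prof$attribute_id[1], "signal")
  }
})

test_that("permuted labels leave importances centred on zero", {
  n <- 40
  meds <- vapply(1:3, function(seed) {
    withr::with_seed(200 + seed, {
      m <- matrix(runif(n * 50, 0, 100), nrow = n)
      grp <- sample(rep(c("a", "b"), each = n / 2))
    })
    tab <- make_attr_table(m, normalized = TRUE)
    prof <- rank_importance(tab, setNames(grp, tab$sample),
                            seed = seed, n_trees = 200)
    median(prof$importance)
  }, numeric(1))
  # importances are z-scores; a null median should stay within the noise scale
  expect_lt(abs(mean(meds)), 1)
})

test_that("a duplicated informative attribute shares top ranks", {
  n <- 40
  grp <- rep(c("low", "high"), each = n / 2)
  withr::with_seed(77, {
    m <- matrix(runif(n * 50, 0, 100), nrow = n)
    sig <- ifelse(grp == "high", 80, 20) + rnorm(n, 0, 5)
  })
  m <- cbind(m, sig1 = sig, sig2 = sig)
  tab <- make_attr_table(m, normalized = TRUE,
                         attrs = c(sprintf("N%02d", 1:50), "sig1", "sig2"))
  prof <- rank_importance(tab, setNames(grp, tab$sample), seed = 1,
                          n_trees = 300)
  noise_q90 <- quantile(prof$importance[grepl("^N", prof$attribute_id)], 0.9)
  expect_gt(prof$importance[prof$attribute_id == "sig1"], noise_q90)
  expect_gt(prof$importance[prof$attribute_id == "sig2"], noise_q90)
})

test_that("importance ranking is reproducible under a fixed seed", {
  sim <- generate(generator_spec(n_samples = 60L, n_background = 40L,
                                 n_planted_per_direction = 5L), seed = 4)
  tab <- normalize_table(sim$table)
  sp <- split_extremes(sim$env, "ph", 0.10)
  p1 <- rank_importance(tab, sp, seed = 9, n_trees = 200)
  p2 <- rank_importance(tab, sp, seed = 9, n_trees = 200)
  expect_identical(p1$attribute_id, p2$attribute_id)
  expect_identical(p1$importance, p2$importance)
})

test_that("planted attributes land in the signed fingerprint with correct sign", {
  cfg <- fp_config(supervised = list(n_trees = 300))
  sim <- generate(generator_spec(n_samples = 150L, n_background = 80L,
                                 n_planted_per_direction = 10L), seed = 21)
  norm <- normalize_table(sim$table)
  fp <- fingerprint_context(norm, sim$env, factor = "ph", config = cfg,
                            seed = 21)
  up_found <- intersect(fp$high_members$attribute_id, sim$truth$planted_up)
  dn_found <- intersect(fp$low_members$attribute_id, sim$truth$planted_down)
  expect_gte(length(up_found) + length(dn_found), 16)  # >= 80% of 20
  expect_true(all(fp$high_members$slope > 0))
  expect_true(all(fp$low_members$slope < 0))
  # no member sits in both directions
  expect_length(intersect(fp$high_members$attribute_id,
                          fp$low_members$attribute_id), 0)
})

test_that("zero-variance attributes are never fingerprint members", {
  withr::with_seed(31, {
    n <- 40
    ph <- seq(4.5, 8, length.out = n)
    m <- cbind(
      up1 = 50 + 20 * ph + rnorm(n),
      dn1 = 200 - 20 * ph + rnorm(n),
      flat = rep(5, n),
      matrix(runif(n * 10, 0, 10), nrow = n)
    )
  })
  tab <- make_attr_table(m, normalized = TRUE,
                         attrs = c("up1", "dn1", "flat", sprintf("N%02d", 1:10)))
  env <- env_table(data.frame(sample = tab$sample, ph = ph))
  fp <- suppressWarnings(
    fingerprint_context(tab, env, factor = "ph",
                        config = fp_config(supervised = list(n_trees = 200,
                                                             fraction = 0.25)),
                        seed = 2)
  )
  members <- c(fp$high_members$attribute_id, fp$low_members$attribute_id)
  expect_false("flat" %in% members)
  expect_true("up1" %in% fp$high_members$attribute_id)
  expect_true("dn1" %in% fp$low_members$attribute_id)
})

test_that("negating the factor swaps high and low members exactly", {
  sim <- generate(generator_spec(n_samples = 120L, n_background = 60L,
                                 n_planted_per_direction = 8L,
                                 planted_factor = "soc"), seed = 13)
  norm <- normalize_table(sim$table)
  cfg <- fp_config(supervised = list(n_trees = 300))
  fp_pos <- fingerprint_context(norm, sim$env, factor = "soc", config = cfg,
                                seed = 13)
  env_neg <- sim$env
  env_neg$soc <- -env_neg$soc
  fp_neg <- fingerprint_context(norm, env_neg, factor = "soc", config = cfg,
                                seed = 13)
  expect_identical(sort(fp_pos$high_members$attribute_id),
                   sort(fp_neg$low_members$attribute_id))
  expect_identical(sort(fp_pos$low_members$attribute_id),
                   sort(fp_neg$high_members$attribute_id))
})

test_that("one-vs-rest biome fingerprinting signs members by indicator slope", {
  spec <- generator_spec(n_samples = 120L, n_background = 60L,
                         n_planted_per_direction = 0L,
                         biome_scheme = list(n_biomes = 3L, n_planted = 8L,
                                             effect_size = 2))
  sim <- generate(spec, seed = 17)
  norm <- normalize_table(sim$table)
  fp <- fingerprint_context(norm, sim$env, biome = "biome_1",
                            config = fp_config(supervised = list(n_trees = 300)),
                            seed = 17)
  expect_identical(fp$context_type, "biome")
  found <- intersect(fp$high_members$attribute_id, sim$truth$biome_planted)
  expect_gte(length(found), 6)  # >= 75% of the 8 planted, positively signed
})
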