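test_that("generation is deterministic under a fixed seed", {
  spec <- generator_spec(n_samples = 40L, n_background = 30L,
                         n_planted_per_direction = 5L)
  a <- generate(spec, seed = 5)
  b <- generate(spec, seed = 5)
  expect_identical(attr_matrix(a$table), attr_matrix(b$table))
  expect_identical(tibble::as_tibble(a$env), tibble::as_tibble(b$env))
  c <- generate(spec, seed = 6)
  expect_false(identical(attr_matrix(a$table), attr_matrix(c$table)))
})

test_that("factors stay inside their configured ranges", {
  sim <- generate(generator_spec(n_samples = 100L, n_background = 20L,
                                 n_planted_per_direction = 0L), seed = 2)
  rngs <- generator_spec()$factor_ranges
  for (f in names(rngs)) {
    expect_gte(min(sim$env[[f]]), rngs[[f]][1])
    expect_lte(max(sim$env[[f]]), rngs[[f]][2])
  }
  expect_true(all(sim$env$biome %in% sprintf("biome_%d", 1:4)))
})

test_that("null generator produces slopes centred on zero", {
  spec <- generator_spec(n_samples = 150L, n_background = 60L,
                         n_planted_per_direction = 10L, effect_size = 0)
  sim <- generate(spec, seed = 3)
  m <- attr_matrix(sim$table)
  cpm <- sweep(m, 1, rowSums(m), "/") * 1e6
  u <- (sim$env$ph - 4.4) / (8.3 - 4.4)
  slopes <- apply(log1p(cpm), 2, function(y) coef(lm(y ~ u))[2])
  expect_lt(abs(mean(slopes)), 0.1)
})

test_that("doubling the library-size location doubles expected totals", {
  base <- generator_spec(n_samples = 80L, n_background = 50L,
                         n_planted_per_direction = 0L,
                         library_size = list(location = 1e5, sdlog = 0.4))
  dbl <- generator_spec(n_samples = 80L, n_background = 50L,
                        n_planted_per_direction = 0L,
                        library_size = list(location = 2e5, sdlog = 0.4))
  t1 <- mean(rowSums(attr_matrix(generate(base, seed = 4)$table)))
  t2 <- mean(rowSums(attr_matrix(generate(dbl, seed = 4)$table)))
  expect_equal(t2 / t1, 2, tolerance = 0.05)
})

test_that("planted log-abundance slopes match the generator's closed form", {
  spec <- generator_spec(n_samples = 500L, n_background = 200L,
                         n_planted_per_direction = 20L, effect_size = 2)
  sim <- generate(spec, seed = 8)
  m <- attr_matrix(sim$table)
  frac <- sweep(m, 1, rowSums(m), "/")
  u <- (sim$env$ph - 4.4) / (8.3 - 4.4)
  slope_of <- function(ids) {
    mean(vapply(ids, function(j) {
      y <- frac[, j]
      ok <- y > 0
      unname(coef(lm(log(y[ok]) ~ u[ok]))[2])
    }, numeric(1)))
  }
  expect_equal(slope_of(sim$truth$planted_up), 2, tolerance = 0.15 * 2)
  expect_equal(slope_of(sim$truth$planted_down), -2, tolerance = 0.15 * 2)
})

test_that("fertile scenario plants the coordinated factor pattern", {
  spec <- generator_spec(n_samples = 200L, n_background = 100L)
  sim <- generate_fertile_scenario(spec, seed = 9)
  fert <- sim$truth$fertile_cluster_samples
  expect_length(fert, 50)  # fraction 0.25 of 200
  expect_length(sim$truth$fertile_fingerprint, 25)

  e <- dplyr::filter(tibble::as_tibble(sim$env), .data$sample %in% fert)
  # coordinated rise of SOC/N/CEC against fall of bulk density/clay
  expect_gt(cor(e$soc, e$nitrogen), 0.8)
  expect_gt(cor(e$soc, e$cec), 0.8)
  expect_lt(cor(e$soc, e$bulk_density), -0.8)
  expect_lt(cor(e$soc, e$clay), -0.8)

  # fertile-set abundance rises along the gradient within the subset
  m <- attr_matrix(sim$table)
  share <- rowSums(m[fert, sim$truth$fertile_fingerprint]) / rowSums(m[fert, ])
  expect_gt(cor(share, e$soc[match(fert, e$sample)]), 0.5)

  expect_error(
    generate_fertile_scenario(
      generator_spec(cluster_scheme = list(fraction = 0.8, n_attributes = 5,
                                           boost_base = 1, boost_gradient = 1,
                                           baseline_shift = 1)),
      seed = 1),
    "fraction"
  )
})

test_that("generated tables pass validity checks and survive the filters", {
  sim <- generate(generator_spec(n_samples = 60L, n_background = 80L,
                                 n_planted_per_direction = 5L), seed = 10)
  expect_s3_class(sim$table, "fp_attr_tbl")
  expect_s3_class(sim$env, "fp_env_tbl")
  norm <- normalize_table(sim$table)
  # at the default sequencing depth no sample or attribute is lost
  expect_identical(dim(attr_matrix(norm)), c(60L, 90L))
})
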