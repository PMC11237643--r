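# In-code fixtures, deterministic by construction.

make_attr_table <- function(m, type = "KO", normalized = FALSE,
                            samples = NULL, attrs = NULL) {
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(attrs)) attrs <- sprintf("A%03d", seq_len(ncol(m)))
  dimnames(m) <- list(samples, attrs)
  df <- data.frame(sample = samples, m, check.names = FALSE)
  attr_table(df, attribute_type = type, normalized = normalized)
}

# the fixed 4 x 20 count matrix used for TMM oracle equivalence
fixture_tmm_matrix <- function(seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(rpois(80, lambda = rep(c(50, 120, 80, 200), each = 20)),
                nrow = 4, byrow = TRUE)
    m[1, 1:3] <- 0          # pairwise zero exclusion must kick in
    m[2, 5] <- 900          # an outlying ratio for the trim to remove
    m
  })
}

tiny_env <- function(n = 6, samples = sprintf("s%02d", seq_len(n))) {
  env_table(data.frame(
    sample = samples,
    ph = seq(4.5, 8, length.out = n),
    soc = seq(10, 300, length.out = n),
    bulk_density = seq(1.5, 0.3, length.out = n),
    biome = rep(c("forest", "tundra"), length.out = n)
  ))
}

# minimal stand-in cluster solution (only `assignment` is consumed downstream)
fake_solution <- function(assignment) {
  structure(
    list(k = length(unique(assignment)), assignment = assignment,
         diagnostics = tibble::tibble(k = length(unique(assignment)),
                                      total_within_ss = NA_real_,
                                      silhouette = NA_real_, chosen = TRUE),
         seed = 0L),
    class = "fp_clusters"
  )
}
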