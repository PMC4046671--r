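test_that("data reduction removes low-signal then high-variability genes", {
  vals <- rbind(
    g_low = rep(100, 9),              # mean < 128: low-signal bucket
    g_ok = rep(500, 9),               # kept
    g_var = c(500, 500, 500, 10, 1500, 500, 500, 500, 500) # high replicate CV
  )
  colnames(vals) <- as.vector(outer(c("F", "V", "Ht"), 1:3,
                                    function(s, r) paste("P", s, r, sep = "_")))
  em <- ExpressionMatrix(vals)
  red <- reduce_dataset(em, "P", mean_floor = 128, cv_threshold = 0.5)
  expect_equal(red$report$genes_in, 3)
  expect_equal(red$report$genes_removed_low_signal, 1)
  expect_equal(red$report$genes_removed_variability, 1)
  expect_equal(red$report$genes_out, 1)
  expect_equal(red$matrix$genes$gene_id, "g_ok")

  # filters off: output equals input
  off <- reduce_dataset(em, "P", mean_floor = 0, cv_threshold = Inf)
  expect_equal(off$matrix$values, em$values)
  expect_equal(off$report$genes_out, 3)
  expect_error(reduce_dataset(em, "H"), "absent")
})

test_that("reduction counts reconcile on simulated data", {
  sim <- simulate_dataset(sim_params(n_genes = 2000, noise_cv = 0.2, seed = 31))
  red <- reduce_dataset(sim$matrix, "P")
  rep <- red$report
  expect_equal(rep$genes_out,
               rep$genes_in - rep$genes_removed_low_signal -
                 rep$genes_removed_variability)
  expect_equal(nrow(red$matrix$values), rep$genes_out)
  expect_true(all(rowMeans(red$matrix$values) >= 128))
})

test_that("the mixture fit recovers exact coefficients from noiseless data", {
  v <- c(100, 200, 400); ht <- c(50, 300, 10)
  f <- 0.92 * v + 0.08 * ht
  expect_equal(f, c(96, 208, 368.8))
  fit <- fit_mixture(v, ht, f, method = "ols")
  expect_equal(fit$a, 0.92, tolerance = 1e-10)
  expect_equal(fit$b, 0.08, tolerance = 1e-10)
  expect_equal(fit$sse, 0, tolerance = 1e-15)

  gfit <- fit_mixture(v, ht, f, method = "grid")
  expect_true(abs(gfit$a - fit$a) <= 0.001 + 1e-12)
  expect_true(abs(gfit$b - fit$b) <= 0.001 + 1e-12)

  tfit <- fit_mixture(v, ht, f, method = "tls")
  expect_equal(tfit$a, 0.92, tolerance = 1e-8)
  expect_equal(tfit$b, 0.08, tolerance = 1e-8)

  # coefficients are unconstrained in sign
  f_neg <- 1.05 * v - 0.04 * ht
  fit_neg <- fit_mixture(v, ht, f_neg, method = "ols")
  expect_equal(fit_neg$a, 1.05, tolerance = 1e-10)
  expect_equal(fit_neg$b, -0.04, tolerance = 1e-10)

  expect_error(fit_mixture(v, 2 * v, f, method = "ols"), "collinear")
  expect_error(fit_mixture(numeric(0), numeric(0), numeric(0)), "empty")
})

test_that("grid search agrees with a brute-force lattice oracle", {
  set.seed(13)
  v <- rlnorm(50, 6, 1); ht <- rlnorm(50, 6, 1)
  f <- 0.9 * v + 0.1 * ht + rnorm(50, 0, 20)
  a_seq <- seq(0.8, 1.0, by = 0.005)
  b_seq <- seq(0.0, 0.2, by = 0.005)
  norm2 <- v^2 + ht^2 + f^2
  best <- c(NA, NA); best_sse <- Inf
  for (a in a_seq) for (b in b_seq) {     # brute-force loop over the lattice
    sse <- sum((f - a * v - b * ht)^2 / norm2)
    if (sse < best_sse) { best_sse <- sse; best <- c(a, b) }
  }
  fit <- fit_mixture(v, ht, f, method = "grid",
                     grid_a = c(0.8, 1.0), grid_b = c(0, 0.2),
                     grid_step = 0.005)
  expect_equal(c(fit$a, fit$b), best, tolerance = 1e-12)
  expect_equal(fit$sse, best_sse, tolerance = 1e-12)
})

test_that("weighted residuals match the defining formula and ordering", {
  # hand-evaluated record: V = Ht = 100, F = 200, a = 0.92, b = 0.08
  fit <- list(a = 0.92, b = 0.08)
  rec <- weighted_residuals(fit, 100, 100, 200, gene_ids = "g1")
  expect_equal(rec$f_calc, 100)
  expect_equal(rec$vector_norm, sqrt(60000))
  expect_equal(rec$r, 100 / sqrt(60000), tolerance = 1e-12)
  expect_equal(rec$r, 0.4082483, tolerance = 1e-6)

  # exact-fit gene has r = 0; F below prediction gives r < 0
  rec2 <- weighted_residuals(fit, c(100, 100), c(50, 50), c(96, 50),
                             gene_ids = c("gA", "gB"))
  expect_equal(rec2$r[1], 0)
  expect_true(rec2$r[2] < 0)

  # residual identity r * norm + f_calc = f on random triples
  set.seed(2)
  v <- rlnorm(200, 5, 1); ht <- rlnorm(200, 5, 1); f <- rlnorm(200, 5, 1)
  rec3 <- weighted_residuals(fit, v, ht, f)
  expect_equal(rec3$r * rec3$vector_norm + rec3$f_calc, rec3$f_mean,
               tolerance = 1e-12)
  # ranks: |r| non-increasing with rank
  ord <- order(rec3$rank)
  expect_true(all(diff(abs(rec3$r[ord])) <= 1e-15))

  expect_warning(weighted_residuals(fit, c(0, 1), c(0, 1), c(0, 1),
                                    gene_ids = c("zero", "one")),
                 "zero")
})

test_that("outlier ranking respects direction, ties and k", {
  rec <- data.frame(
    gene_id = c("gB", "gA", "gC", "gD"),
    f_mean = 1, v_mean = 1, ht_mean = 1, f_calc = 1, vector_norm = 1,
    r = c(0.5, 0.5, -0.7, 0.1),
    rank = NA_integer_, stringsAsFactors = FALSE
  )
  top <- rank_outliers(rec, 4, "both")
  expect_equal(top$gene_id, c("gC", "gA", "gB", "gD"))  # tie gA < gB
  expect_equal(top$rank, 1:4)
  expect_equal(rank_outliers(rec, 2, "f_high")$gene_id, c("gA", "gB"))
  expect_equal(rank_outliers(rec, 1, "f_low")$gene_id, "gC")
  expect_equal(nrow(rank_outliers(rec, 0, "both")), 0L)
  expect_error(rank_outliers(rec, -1, "both"), "k")
  expect_error(rank_outliers(rec, 5, "both"), "k")
})

test_that("degraded transcripts surface as top f_high outliers", {
  hits <- sapply(1:10, function(s) {
    sim <- simulate_dataset(sim_params(
      n_genes = 1000, noise_cv = 0.1, degraded_gene_count = 5,
      degradation_factor = 0.1, seed = 200 + s))
    m <- condition_means(sim$matrix, "P")
    fit <- fit_mixture(m$v_mean, m$ht_mean, m$f_mean, method = "tls")
    wr <- weighted_residuals(fit, m$v_mean, m$ht_mean, m$f_mean,
                             gene_ids = m$gene_id)
    top <- rank_outliers(wr, 8, "f_high")$gene_id
    all(sim$truth$degraded_genes %in% top)
  })
  expect_true(mean(hits) >= 0.9)
})

test_that("degradation severity never demotes a gene's outlier rank", {
  rank_of <- sapply(c(0.8, 0.4, 0.1), function(delta) {
    sim <- simulate_dataset(sim_params(
      n_genes = 500, noise_cv = 0.05, degraded_gene_count = 1,
      degradation_factor = delta, seed = 55))
    m <- condition_means(sim$matrix, "P")
    fit <- fit_mixture(m$v_mean, m$ht_mean, m$f_mean, method = "tls")
    wr <- weighted_residuals(fit, m$v_mean, m$ht_mean, m$f_mean,
                             gene_ids = m$gene_id)
    wr$rank[wr$gene_id == sim$truth$degraded_genes]
  })
  expect_true(all(diff(rank_of) <= 0))
})

test_that("bootstrap intervals contain the point estimate and cover the truth", {
  sim <- simulate_dataset(sim_params(n_genes = 800, noise_cv = 0.1, seed = 9))
  m <- condition_means(sim$matrix, "P")
  fit <- fit_mixture(m$v_mean, m$ht_mean, m$f_mean, method = "ols",
                     n_boot = 200, seed = 17)
  expect_true(fit$bootstrap_ci_a[1] <= fit$a && fit$a <= fit$bootstrap_ci_a[2])
  expect_true(fit$bootstrap_ci_b[1] <= fit$b && fit$b <= fit$bootstrap_ci_b[2])
  # seeded: same call reproduces the intervals
  fit2 <- fit_mixture(m$v_mean, m$ht_mean, m$f_mean, method = "ols",
                      n_boot = 200, seed = 17)
  expect_identical(fit$bootstrap_ci_b, fit2$bootstrap_ci_b)

  # coverage: 95% percentile intervals cover the true b in 90-99% of runs
  covered <- sapply(1:120, function(s) {
    sm <- simulate_dataset(sim_params(n_genes = 600, noise_cv = 0.15,
                                      seed = 3000 + s))
    mm <- condition_means(sm$matrix, "P")
    ft <- fit_mixture(mm$v_mean, mm$ht_mean, mm$f_mean, method = "ols",
                      n_boot = 300, seed = s)
    ft$bootstrap_ci_b[1] <= 0.08 && 0.08 <= ft$bootstrap_ci_b[2]
  })
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})
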