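test_that("sample keys follow the {condition}_{type}_{replicate} convention", {
  k <- parse_sample_key("P_V_1")
  expect_equal(k$condition, "P")
  expect_equal(k$sample_type, "V")
  expect_equal(k$replicate, 1L)
  expect_equal(sample_key("M", "Ht", 2), "M_Ht_2")
  expect_error(parse_sample_key("X_V_1"), "unparseable")
  expect_error(parse_sample_key("P_V"), "unparseable")
})

test_that("the container enforces its invariants", {
  vals <- matrix(c(1, 2, 3, 4), 2, 2,
                 dimnames = list(c("g1", "g2"), c("P_V_1", "P_V_2")))
  em <- ExpressionMatrix(vals)
  expect_equal(dim(em), c(2L, 2L))

  bad <- vals; rownames(bad) <- c("g1", "g1")
  expect_error(ExpressionMatrix(bad), "duplicate gene ids")
  bad <- vals; bad[1, 1] <- -1
  expect_error(ExpressionMatrix(bad), "non-negative")
  bad <- vals; bad[2, 2] <- NA
  expect_error(ExpressionMatrix(bad), "finite")
})

test_that("expression tables round-trip exactly through TSV", {
  sim <- simulate_dataset(sim_params(n_genes = 10, conditions = c("P", "M", "H"),
                                     seed = 3))
  em <- sim$matrix
  expect_equal(ncol(em$values), 27)  # 3 conditions x 3 types x 3 replicates
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(em, path)
  back <- read_expression_table(path)
  expect_equal(back$genes, em$genes)
  expect_equal(back$samples, em$samples)
  expect_equal(back$values, em$values, tolerance = 1e-12)

  # second write is byte-identical (column order preserved)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("degenerate and malformed tables are rejected with named context", {
  em0 <- toy_matrix(n_genes = 2)[integer(0), ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(em0, path)
  back <- read_expression_table(path)
  expect_equal(nrow(back$values), 0L)

  tab <- data.frame(gene_id = c("Ava_1", "Ava_1"), product = "p",
                    category = "Other", P_V_1 = c(1, 2), P_V_2 = c(3, 4),
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_table(path), "Ava_1")

  tab$gene_id <- c("Ava_1", "Ava_2"); tab$P_V_1[2] <- -5
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_table(path), "negative value")
})

test_that("quantile normalization equalizes distributions and matches the oracle", {
  # two-column toy: (1,3) and (2,4) -> both (1.5, 3.5)
  m <- matrix(c(1, 3, 2, 4), 2, 2,
              dimnames = list(c("g1", "g2"), c("P_V_1", "P_V_2")))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(1.5, 3.5))
  expect_equal(unname(out[, 2]), c(1.5, 3.5))

  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rlnorm(300, 5, 1), 50, 6,
                dimnames = list(sprintf("g%d", 1:50), sprintf("P_V_%d", 1:6)))
    out <- quantile_normalize(m)
    expect_equal(out, qn_oracle(m), tolerance = 1e-12)
    # defining property: all columns share the same multiset of values
    sorted <- apply(out, 2, sort)
    expect_true(max(abs(sorted - sorted[, 1])) < 1e-12)
    # rank order preserved within columns
    for (j in 1:6) expect_equal(order(out[, j]), order(m[, j]))
    # idempotence
    expect_equal(quantile_normalize(out), out, tolerance = 1e-12)
  }

  # already-identical columns are a fixed point
  m_id <- matrix(c(1, 5, 9, 1, 5, 9), 3, 2,
                 dimnames = list(NULL, c("a", "b")))
  expect_equal(quantile_normalize(m_id), m_id)
  expect_error(quantile_normalize(m_id[, 1, drop = FALSE]), "at least 2")
})

test_that("correlation matrices are symmetric with the expected toy values", {
  vals <- cbind(P_V_1 = c(1, 2, 3), P_V_2 = c(1, 2, 3) * -2 + 10,
                P_V_3 = c(1, 3, 2))
  rownames(vals) <- c("g1", "g2", "g3")
  em <- ExpressionMatrix(vals)

  r2 <- correlation_matrix(em, "r2")
  expect_equal(r2, t(r2))
  expect_equal(unname(diag(r2)), rep(1, 3))
  # a column and its negative-slope affine image still give R^2 = 1
  expect_equal(r2["P_V_1", "P_V_2"], 1)

  rho <- correlation_matrix(em, "spearman")
  # ranks (1,2,3) vs (1,3,2): rho = 1 - 6*2/(3*8) = 0.5
  expect_equal(rho["P_V_1", "P_V_3"], 0.5)

  const <- ExpressionMatrix(cbind(P_V_1 = c(1, 1, 1), P_V_2 = c(1, 2, 3)) |>
                              `rownames<-`(c("g1", "g2", "g3")))
  expect_error(correlation_matrix(const), "P_V_1")
})

test_that("replicate R^2 is high within groups of a low-noise simulation", {
  sim <- simulate_dataset(sim_params(n_genes = 500, noise_cv = 0.05, seed = 11))
  r2 <- correlation_matrix(sim$matrix, "r2")
  s <- sim$matrix$samples
  for (st in c("F", "V", "Ht")) {
    keys <- s$key[s$sample_type == st]
    within <- r2[keys, keys][upper.tri(diag(length(keys)))]
    expect_true(all(within > 0.95))
  }
})

test_that("GEO series-matrix text is parsed with feature and sample mapping", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "!Series_title\t\"demo\"",
    "!series_matrix_table_begin",
    paste("ID_REF", "GSM1", "GSM2", sep = "\t"),
    paste("FEAT_1", "10.5", "11", sep = "\t"),
    paste("FEAT_2", "20", "21", sep = "\t"),
    paste("FEAT_3", "5", "6", sep = "\t"),
    "!series_matrix_table_end"
  ), path)
  em <- read_geo_series_matrix(
    path,
    id_map = c(FEAT_1 = "Ava_0001", FEAT_2 = "Ava_0002"),
    sample_map = c(GSM1 = "P_V_1", GSM2 = "P_V_2")
  )
  expect_equal(em$genes$gene_id, c("Ava_0001", "Ava_0002"))
  expect_equal(unname(em$values["Ava_0002", ]), c(20, 21))
  expect_error(read_geo_series_matrix(path, sample_map = c(GSM1 = "P_V_1")),
               "GSM2")
})
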