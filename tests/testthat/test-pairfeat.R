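test_that("binary, categorical and continuous pair features match the worked examples", {
  expect_identical(binary_pair_feature(1, 0), 1L)
  expect_identical(binary_pair_feature(0, 0), 0L)
  expect_identical(binary_pair_feature(1, 1), 2L)
  expect_error(binary_pair_feature(2, 0), "0/1")

  ov <- categorical_overlap(c("DNA binding", "signal transduction"),
                            c("signal transduction", "protein binding"))
  expect_equal(ov$n_overlap, 1)
  expect_equal(ov$n_union, 3)
  expect_equal(ov$pct_overlap, 100 / 3)
  expect_equal(categorical_overlap(c("a", "b"), c("b", "a")),
               list(n_overlap = 2L, n_union = 2L, pct_overlap = 100))
  expect_equal(categorical_overlap(c("a", "b"), c("c", "d", "e"))$pct_overlap, 0)
  expect_equal(categorical_overlap(character(0), character(0))$pct_overlap, 0)

  cf <- continuous_pair_features(10, 9)
  expect_equal(unlist(cf), c(diff = 1, avg = 9.5, max = 10, min = 9, total = 19))
  expect_equal(unlist(continuous_pair_features(3, 3)),
               c(diff = 0, avg = 3, max = 3, min = 3, total = 6))
  expect_equal(unlist(continuous_pair_features(0, 5)),
               c(diff = 5, avg = 2.5, max = 5, min = 0, total = 5))
  # symmetric in the pair order
  expect_equal(continuous_pair_features(2, 7), continuous_pair_features(7, 2))
})

test_that("quartile binning matches a sort-and-slice oracle and freezes breaks", {
  expect_identical(as.integer(quartile_bin(1:8)), rep(1:4, each = 2L))
  expect_warning(b <- quartile_bin(c(5, 5, 5, 5)), "distinct")
  expect_identical(as.integer(b), rep(1L, 4))
  expect_error(quartile_bin(c(1, 2, 3)), "4 non-missing")

  set.seed(11)
  x <- rnorm(200)
  bins <- quartile_bin(x)
  # oracle: sort and slice into four equal chunks (no ties in rnorm draws)
  oracle <- findInterval(rank(x), c(1, 51, 101, 151))
  expect_identical(as.integer(bins), oracle)
  # ties on a boundary take the lower bin
  xb <- c(1, 2, 2, 3, 4, 5, 6, 7)
  q <- unname(quantile(xb, 0.25))
  expect_true(all(as.integer(quartile_bin(xb))[xb == q] == 1))
  # frozen breaks reproduce training bins on shifted data
  newx <- x + 100
  expect_true(all(quartile_bin(newx, breaks = attr(bins, "breaks")) == 4))
  # idempotent under a monotone transform: bins of x and x^2 agree (x >= 0)
  xp <- abs(x)
  expect_identical(as.integer(quartile_bin(xp)), as.integer(quartile_bin(xp^2)))
})

test_that("column transforms implement the zero policies and skip negatives", {
  expect_equal(as.numeric(transform_column(3, "square")), 9)
  expect_equal(as.numeric(transform_column(c(1, 100), "log10")), c(0, 2))
  # zero policy: replace 0 by the smallest positive value before inversion
  r <- transform_column(c(0, 2, 4), "reciprocal")
  expect_equal(as.numeric(r), c(0.5, 0.5, 0.25))
  expect_equal(attr(r, "delta"), 2)
  # log10 of a column containing zero: shift by the smallest positive value
  l <- transform_column(c(0, 1, 10), "log10")
  expect_equal(as.numeric(l), log10(c(0, 1, 10) + 1))
  expect_warning(out <- transform_column(c(-1, 2), "log10"), "negative")
  expect_null(out)
  expect_warning(out2 <- transform_column(c(-1, 2), "reciprocal"), "negative")
  expect_null(out2)
})

test_that("engineered column counts follow the scheme formula for random schemas", {
  set.seed(21)
  for (rep in 1:5) {
    nb <- sample(0:3, 1); nc <- sample(1:3, 1); ncat <- sample(0:2, 1)
    schema <- data.frame(
      name = c(sprintf("b%d", seq_len(nb)), sprintf("c%d", seq_len(nc)),
               sprintf("k%d", seq_len(ncat))),
      data_type = c(rep("binary", nb), rep("continuous", nc),
                    rep("categorical", ncat)),
      category = "expression"
    )
    n_genes <- 40
    genes <- data.frame(gene = paste0("g", 1:n_genes))
    for (f in schema$name[schema$data_type == "binary"]) genes[[f]] <- rbinom(n_genes, 1, 0.5)
    for (f in schema$name[schema$data_type == "continuous"]) genes[[f]] <- rlnorm(n_genes)
    for (f in schema$name[schema$data_type == "categorical"]) {
      genes[[f]] <- replicate(n_genes, paste(sample(letters[1:6], 3), collapse = ";"))
    }
    pairs <- data.frame(pair_id = paste0("p", 1:20),
                        gene_a = genes$gene[1:20], gene_b = genes$gene[21:40])
    mt <- build_pair_matrix(genes, schema, pairs, scheme = "MT")
    expect_equal(ncol(mt$features), 4 * nb + 25 * nc + 15 * ncat)
    nt <- build_pair_matrix(genes, schema, pairs, scheme = "NT")
    expect_equal(ncol(nt$features), 1 * nb + 5 * nc + 3 * ncat)
    # metadata resolves every column uniquely to (base, aggregation, transform)
    expect_identical(sort(mt$metadata$column), sort(colnames(mt$features)))
    expect_false(anyDuplicated(mt$metadata$column) > 0)
    expect_true(all(mt$metadata$base %in% schema$name))
  }
})

test_that("pair features are symmetric under gene order swap", {
  pf1 <- build_pair_matrix(tiny_genes(), tiny_schema(), tiny_pairs(), scheme = "MT")
  swapped <- tiny_pairs()
  names(swapped)[2:3] <- c("gene_b", "gene_a")
  pf2 <- build_pair_matrix(tiny_genes(), tiny_schema(), swapped, scheme = "MT")
  expect_equal(pf1$features, pf2$features)
})

test_that("unknown gene ids are reported by name", {
  pairs <- tiny_pairs()
  pairs$gene_b[2] <- "gX"
  expect_error(build_pair_matrix(tiny_genes(), tiny_schema(), pairs), "gX")
})

test_that("PCA features match an eigendecomposition oracle", {
  # diagonal covariance with variances 4 and 1: PC1 explains 0.8
  set.seed(5)
  x <- cbind(a = rnorm(4000, sd = 2), b = rnorm(4000, sd = 1))
  p <- pca_features(x, n_components = 2)
  expect_equal(p$explained[1], 0.8, tolerance = 0.03)
  # scores orthogonal
  expect_equal(abs(cor(p$scores[, 1], p$scores[, 2])), 0, tolerance = 1e-10)
  # scores reproduce the covariance eigendecomposition up to sign
  set.seed(6)
  m <- matrix(rnorm(60), nrow = 10, ncol = 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  p2 <- pca_features(m, n_components = 5)
  eig <- eigen(cov(m))
  centered <- scale(m, scale = FALSE)
  for (k in 1:5) {
    oracle_scores <- as.numeric(centered %*% eig$vectors[, k])
    expect_equal(abs(cor(p2$scores[, k], oracle_scores)), 1, tolerance = 1e-8)
  }
  expect_true(all(diff(p2$explained) <= 1e-12))
  expect_error(pca_features(m, n_components = 7), "rank")
})

test_that("the recipe freezes imputation, bins and PCs for new pairs", {
  set.seed(31)
  b <- generate_benchmark(syn_config(n_pairs = 60, emission_noise = 0), seed = 31)
  train_pairs <- b$pairs[1:45, ]
  new_pairs <- b$pairs[46:60, ]
  pf <- build_pair_matrix(b$genes, b$schema, train_pairs, scheme = "MT", n_pcs = 3)
  pf_new <- build_pair_matrix(b$genes, b$schema, new_pairs, recipe = pf)
  expect_identical(colnames(pf_new$features), colnames(pf$features))
  # frozen constants: rebuilding the training pairs is bit-identical
  pf_re <- build_pair_matrix(b$genes, b$schema, train_pairs, recipe = pf)
  expect_equal(pf_re$features, pf$features)
  # bin columns on new data use training boundaries (values stay in 1..4)
  bin_cols <- pf$metadata$column[pf$metadata$transform == "quartile_bin"]
  expect_true(all(as.matrix(pf_new$features[, bin_cols]) %in% 1:4))
  # a training-set quantile, not a new-data quantile, decides the bins
  col <- pf$metadata$column[pf$metadata$transform == "quartile_bin"][1]
  idcol <- sub("quartile_bin", "identity", col)
  brk <- pf$recipe$constants[[col]]$breaks
  expect_identical(
    as.integer(pf_new$features[[col]]),
    as.integer(quartile_bin(pf_new$features[[idcol]], breaks = brk))
  )
})
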