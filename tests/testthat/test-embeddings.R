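test_that("CBOW covers observed k-mers only and reports the missing ones", {
  v <- build_vocabulary(4)
  # one repeated sentence of 4 distinct tokens: ACGT, CGTA, GTAC, TACG
  corpus <- rep("ACGTACG", 50)
  expect_message(
    E <- train_word2vec_embeddings(corpus, v, window = 2, dim = 16, epochs = 1,
                                   seed = 3),
    "252 of 256")
  expect_setequal(rownames(E), c("ACGT", "CGTA", "GTAC", "TACG"))
  expect_length(attr(E, "missing_kmers"), 252)
  expect_equal(ncol(E), 16)
})

test_that("CBOW defaults produce 768-dimensional vectors", {
  v <- build_vocabulary(4)
  E <- suppressMessages(train_word2vec_embeddings(rep("ACGTACGTAC", 30), v,
                                                  epochs = 1, seed = 1))
  expect_equal(ncol(E), 768)
  expect_identical(attr(E, "source"), "word2vec")
})

test_that("tokens in interchangeable contexts get similar CBOW vectors", {
  v1 <- build_vocabulary(1)
  # A and T both appear only in the frame C _ G
  corpus <- rep(c("CAG", "CTG", "CCG", "CGG"), times = c(200, 200, 50, 50))
  E <- unclass(train_word2vec_embeddings(corpus, v1, window = 1, dim = 8,
                                         epochs = 10, seed = 7))
  cs <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  pairs <- utils::combn(rownames(E), 2)
  allcos <- apply(pairs, 2, function(p) cs(E[p[1], ], E[p[2], ]))
  expect_gt(cs(E["A", ], E["T", ]), stats::median(allcos))
})

test_that("CBOW training is deterministic under a fixed seed", {
  v <- build_vocabulary(2)
  corpus <- c("ACGTTGCAAC", "TTGCACGTGT")
  E1 <- suppressMessages(train_word2vec_embeddings(corpus, v, window = 2,
                                                   dim = 8, epochs = 2, seed = 5))
  E2 <- suppressMessages(train_word2vec_embeddings(corpus, v, window = 2,
                                                   dim = 8, epochs = 2, seed = 5))
  expect_identical(E1, E2)
  expect_error(train_word2vec_embeddings(character(), v),
               class = "dnalm_data_error")
})

test_that("model embeddings drop special tokens and keep vocabulary order", {
  v <- build_vocabulary(4)
  E <- extract_model_embeddings(uniform_stub_model(v))
  expect_equal(nrow(E), 256)
  expect_identical(rownames(E), v$kmers)
  expect_identical(attr(E, "source"), "model")

  m <- tiny_model()
  Em <- extract_model_embeddings(m)
  expect_equal(dim(Em), c(256, 8))
  m2 <- suppressMessages(train_reference_mlm(
    tiny_corpus(), tiny_spec(),
    training_config(learning_rate = 1e-3, steps = 10L, batch_size = 8L,
                    classifier_dropout = 0), seed = 13))
  expect_identical(unclass(Em), unclass(extract_model_embeddings(m2)))

  v5 <- build_vocabulary(5)
  expect_error(extract_model_embeddings(uniform_stub_model(v), v5),
               class = "dnalm_contract_error")
})

test_that("embedding TSV serialization round-trips bit-exactly", {
  v <- build_vocabulary(2)
  E <- extract_model_embeddings(uniform_stub_model(v))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_embedding_tsv(E, path)
  back <- read_embedding_tsv(path, k = 2)
  expect_equal(unclass(back)[, ], unclass(E)[, ])
})

test_that("MEV equals the leading covariance eigenvalue fraction", {
  # rank-1: all rows on one line
  set.seed(9)
  dir <- rnorm(10)
  E1 <- outer(seq(-2, 2, length.out = 20), dir)
  expect_equal(compute_mev(E1)$mev, 1.0, tolerance = 1e-12)
  # 4 corners of a square: equal eigenvalues
  E2 <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  expect_equal(compute_mev(E2)$mev, 0.5, tolerance = 1e-12)
  # Gaussian matrix vs independent eigendecomposition oracle
  G <- matrix(rnorm(256 * 768), 256, 768)
  mg <- compute_mev(G)
  expect_equal(mg$mev, mev_oracle(G), tolerance = 1e-8)
  expect_gt(mg$mev, 1 / 768)
  expect_lt(mg$mev, 0.05)
  expect_equal(mg$mev, mg$eigenvalues[1] / sum(mg$eigenvalues))

  expect_error(compute_mev(matrix(1, 5, 3)),
               class = "dnalm_degenerate_error")
  expect_error(compute_mev(matrix(1, 1, 3)),
               class = "dnalm_parameter_error")
})

test_that("MEV is invariant to rotation and translation of the embedding", {
  set.seed(21)
  E <- matrix(rnorm(60 * 12), 60, 12)
  base <- compute_mev(E)$mev
  for (i in 1:5) {
    Q <- qr.Q(qr(matrix(rnorm(144), 12, 12)))
    shift <- matrix(rnorm(12), 60, 12, byrow = TRUE)
    expect_equal(compute_mev(E %*% Q)$mev, base, tolerance = 1e-8)
    expect_equal(compute_mev(E + shift)$mev, base, tolerance = 1e-8)
  }
})

test_that("R/Y annotation extracts the central n-mer and partitions the vocabulary", {
  a <- ry_annotation("ACGT", 2)
  expect_identical(a$central, "CG")
  expect_identical(a$ry_pattern, "YR")
  b <- ry_annotation("AACGTT", 4)
  expect_identical(b$central, "ACGT")
  expect_identical(b$ry_pattern, "RYRY")
  expect_error(ry_annotation("ACGT", 3), class = "dnalm_parameter_error")

  for (k in 4:6) {
    v <- build_vocabulary(k)
    cw <- k - 2L
    ann <- ry_annotation(v$kmers, cw)
    grp <- table(ann$central)
    expect_length(grp, 4^cw)
    expect_true(all(grp == 4^(k - cw)))
    expect_length(unique(ann$ry_pattern), 2^cw)
  }
  # 256 4-mers fall into 16 central-dimer groups
  ann4 <- ry_annotation(build_vocabulary(4)$kmers, 2)
  expect_length(unique(ann4$central), 16)
})

test_that("UMAP projection preserves well-separated clusters and is deterministic", {
  set.seed(33)
  centers <- matrix(rnorm(4 * 768, sd = 10), 4, 768)
  X <- centers[rep(1:4, each = 50), ] + matrix(rnorm(200 * 768), 200, 768)
  rownames(X) <- vapply(1:200, function(i) random_dna(4), character(1))
  E <- dnalmprobe:::new_embedding_matrix(X, k = 4, source = "model")
  proj <- umap_project(E, n_neighbors = 10, seed = 42)
  expect_equal(nrow(proj), 200)
  sil <- cluster::silhouette(rep(1:4, each = 50),
                             stats::dist(cbind(proj$x, proj$y)))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  proj2 <- umap_project(E, n_neighbors = 10, seed = 42)
  expect_identical(proj, proj2)
  expect_error(umap_project(E[1:5, ], n_neighbors = 10),
               class = "dnalm_parameter_error")
})

test_that("model and Word2Vec matrices flow through the same MEV comparison", {
  m <- tiny_model()
  Em <- extract_model_embeddings(m)
  corpus <- tiny_corpus()
  Ew <- suppressMessages(train_word2vec_embeddings(corpus, m$vocab, window = 3,
                                                   dim = 8, epochs = 1, seed = 2))
  cmp <- suppressMessages(compare_mev(Em, Ew))
  expect_identical(cmp$source, c("model", "word2vec"))
  expect_true(all(cmp$mev > 0 & cmp$mev < 1))
  expect_equal(cmp$n_tokens[1], cmp$n_tokens[2])
})
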