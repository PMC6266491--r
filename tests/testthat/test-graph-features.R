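test_that("graph encoding is deterministic and matches the 2-node hand enumeration", {
  p <- graph_params(radius = 0, distance = 1, hash_dim = 32768)
  e1 <- encode_graph_features("AC", p)
  e2 <- encode_graph_features("AC", p)
  expect_equal(e1, e2)
  # pairs on the path A-C: (A,A,d=0), (C,C,d=0), (A,C,d=1)
  hA <- hash_string("0|A||", p$hash_seed)
  hC <- hash_string("0|C||", p$hash_seed)
  want <- sort(c(oracle_pair_id(0, 0, hA, hA, p$hash_dim),
                 oracle_pair_id(0, 0, hC, hC, p$hash_dim),
                 oracle_pair_id(0, 1, hA, hC, p$hash_dim)))
  expect_equal(e1$id, want)
  expect_equal(e1$count, rep(1, 3))
})

test_that("short sequences match the explicit neighborhood-pair enumeration oracle", {
  withr::local_seed(12)
  p <- graph_params(radius = 2, distance = 3, hash_dim = 4096)
  for (len in 1:8) {
    for (rep in 1:5) {
      s <- rand_seq(len)
      got <- encode_graph_features(s, p)
      want <- oracle_graph_features(s, p)
      expect_equal(got$id, want$id)
      expect_equal(got$count, want$count)
    }
  }
})

test_that("the encoding is shift-covariant and reverse-symmetric", {
  withr::local_seed(13)
  p <- graph_params(radius = 2, distance = 4, hash_dim = 8192)
  for (rep in 1:5) {
    s <- rand_seq(40)
    super <- paste0(rand_seq(15), s, rand_seq(15))
    sub <- encode_graph_features(s, p)
    sup <- encode_graph_features(super, p)
    m <- match(sub$id, sup$id)
    expect_false(anyNA(m))
    expect_true(all(sup$count[m] >= sub$count))

    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(encode_graph_features(rev_s, p), sub)
  }
})

test_that("graph-feature ranking selects the requested number and respects ties", {
  withr::local_seed(14)
  pool <- vapply(rep(150, 40), rand_seq, character(1))
  p <- graph_params(hash_dim = 2048)
  gi <- rank_graph_features(pool[1:20], pool[21:40], p, top_k = 101, seed = 2)
  expect_length(gi$selected_ids, 101)
  expect_false(anyDuplicated(gi$selected_ids) > 0)
  expect_true(all(gi$selected_ids < p$hash_dim))
  expect_true(all(diff(gi$importance) <= 1e-12))
  expect_error(rank_graph_features(pool[1:2], pool[3:4],
                                   graph_params(hash_dim = 2048),
                                   top_k = 10000, seed = 1),
               "nonzero")
})

test_that("a planted motif drives its neighborhood features into the top ranks", {
  withr::local_seed(15)
  motif <- "GGTAGG"
  pos <- vapply(1:60, function(i) {
    s <- rand_seq(120)
    at <- sample(1:(120 - 6), 3)
    for (a in at) substr(s, a, a + 5) <- motif
    s
  }, character(1))
  neg <- vapply(rep(120, 60), rand_seq, character(1))
  p <- graph_params(radius = 1, distance = 2, hash_dim = 2048)
  gi <- rank_graph_features(pos, neg, p, top_k = 50, seed = 3)
  motif_ids <- encode_graph_features(motif, p)$id
  expect_true(length(intersect(gi$selected_ids[1:10], motif_ids)) >= 1)

  # with no signal, selected features should not dominate the rest
  null_gi <- rank_graph_features(vapply(rep(120, 60), rand_seq, character(1)),
                                 vapply(rep(120, 60), rand_seq, character(1)),
                                 p, top_k = 50, seed = 4)
  top10_share <- function(g) mean(g$importance[1:10])
  expect_gt(top10_share(gi) / top10_share(null_gi), 2)
})

test_that("ranking is reproducible and round-trips through JSON", {
  withr::local_seed(16)
  pool <- vapply(rep(100, 30), rand_seq, character(1))
  p <- graph_params(hash_dim = 1024)
  g1 <- rank_graph_features(pool[1:15], pool[16:30], p, top_k = 20, seed = 9)
  g2 <- rank_graph_features(pool[1:15], pool[16:30], p, top_k = 20, seed = 9)
  expect_identical(g1, g2)
  f <- withr::local_tempfile(fileext = ".json")
  write_graph_index(g1, f)
  g3 <- read_graph_index(f)
  expect_equal(g3$selected_ids, g1$selected_ids)
  expect_equal(g3$importance, g1$importance)
  expect_equal(unclass(g3$params), unclass(g1$params))
})
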