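test_that("pairwise identity matches hand arithmetic and the offset oracle", {
  s <- "ACGUACGUACGUACGUACGUA"
  expect_equal(pairwise_identity(s, s)$identity, 1.0)
  expect_equal(pairwise_identity(s, s)$mismatches, 0)

  s2 <- s
  substr(s2, 11, 11) <- "C"
  pid <- pairwise_identity(s, s2)
  expect_equal(pid$identity, 20 / 21)
  expect_equal(pid$mismatches, 1)

  set.seed(81)
  for (i in 1:25) {
    a <- rand_seq(sample(18:25, 1))
    b <- if (i %% 2) rand_seq(sample(18:25, 1)) else
      paste0(rand_seq(2), substr(a, 1, nchar(a) - 2))
    pid <- pairwise_identity(a, b)
    want <- oracle_offset_identity(a, b)
    expect_equal(pid$identity, unname(want["identity"]))
    expect_equal(pid$mismatches, unname(want["mismatches"]))
  }
})

test_that("family clustering is the components closure of the identity rule", {
  set.seed(82)
  seqs <- c(a = rand_seq(21), b = rand_seq(21), c = rand_seq(22))
  fam <- cluster_families(seqs)
  expect_equal(unname(fam$sizes), c(1L, 1L, 1L))

  # three sequences pairwise satisfying the rule form one family
  base <- rand_seq(21)
  trio <- c(x = base, y = base, z = base)
  fam <- cluster_families(trio)
  expect_equal(length(fam$families), 1)
  expect_equal(unname(fam$sizes), 3L)

  # random sets against a DFS components oracle
  for (rep in 1:5) {
    n <- 8
    seqs <- character(n)
    base <- rand_seq(21)
    for (i in 1:n) {
      seqs[i] <- if (i %% 3 == 0) base else rand_seq(21)
    }
    names(seqs) <- sprintf("m%02d", 1:n)
    fam <- cluster_families(seqs)
    edges <- matrix(integer(0), ncol = 2)
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        o <- oracle_offset_identity(seqs[i], seqs[j])
        if (o["identity"] >= 0.98 && o["mismatches"] <= 2) {
          edges <- rbind(edges, c(i, j))
        }
      }
    }
    comp <- oracle_components(n, edges)
    # same partition?
    got <- fam$membership$family_id[match(names(seqs), fam$membership$id)]
    expect_equal(length(unique(got)), length(unique(comp)))
    expect_true(all(tapply(got, comp, function(x) length(unique(x))) == 1))
  }

  # order invariance
  perm <- sample(length(seqs))
  fam2 <- cluster_families(seqs[perm])
  m1 <- fam$membership[order(fam$membership$id), ]
  m2 <- fam2$membership[order(fam2$membership$id), ]
  expect_equal(m1$family_id, m2$family_id)
})

test_that("family size table satisfies its accounting identities", {
  seqs <- c(a = rand_seq(21), b = rand_seq(21), c = rand_seq(21),
            d = rand_seq(21), e = rand_seq(21))
  fam <- cluster_families(seqs)
  tab <- family_size_table(fam)
  expect_equal(tab$size, 1L)
  expect_equal(tab$n_families, 5L)

  fam <- cluster_families(c(a = "ACGUACGUACGUACGUACGUA",
                            b = "ACGUACGUACGUACGUACGUA",
                            c = rand_seq(25)))
  tab <- family_size_table(fam)
  expect_equal(tab$n_families[tab$size == 2], 1L)
  expect_equal(tab$n_families[tab$size == 1], 1L)
  expect_equal(sum(tab$size * tab$n_families), 3)
})

test_that("neighbor joining recovers additive trees", {
  # 3 taxa: unique topology, closed-form branch lengths
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
  # closed form: la = (dab + dac - dbc)/2 etc.
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))

  expect_error(nj_tree(d[1:2, 1:2]), "3 taxa")

  # additive matrices from random trees, 5-8 taxa
  set.seed(83)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    tr0 <- ape::rtree(n, br = function(k) runif(k, 0.2, 1))
    tr0 <- ape::unroot(tr0)
    dm <- ape::cophenetic.phylo(tr0)
    rec <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(rec), tr0), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap support is 100 for a split carried by every column", {
  # two clearly separated pairs: every informative column supports ab|cd
  seqs <- c(a = "AAAAAAAAAAAAAAAAAAAAA",
            b = "AAAAAAAAAAAAAAAAAAAGA",
            c = "CCCCCCCCCCCCCCCCCCCCC",
            d = "CCCCCCCCCCCCCCCCCCCGC")
  bs <- bootstrap_support(seqs, replicates = 50, seed = 9)
  expect_true(all(bs$support[!is.na(bs$support)] >= 0))
  expect_true(any(bs$support == 100))
  # determinism under the same seed
  bs2 <- bootstrap_support(seqs, replicates = 50, seed = 9)
  expect_equal(bs$support, bs2$support)
})

test_that("distance matrix is a valid metric input", {
  seqs <- c(a = rand_seq(21), b = rand_seq(22), c = rand_seq(21))
  d <- mirna_distance_matrix(seqs)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))
  expect_true(all(d >= 0))
})
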