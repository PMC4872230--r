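test_that("folding handles forced structures", {
  f <- fold_mfe("AAAAAAAAAAAA")
  expect_equal(f$structure, strrep(".", 12))
  expect_equal(f$mfe, 0)

  f <- fold_mfe("GGGGAAAACCCC")
  expect_equal(f$structure, "((((....))))")
  expect_lt(f$mfe, 0)

  expect_error(fold_mfe("ACGUXACGUACGU"), "non-RNA")
  expect_error(fold_mfe("ACGUA"), "10 to 1000")
})

test_that("folding is deterministic and never positive", {
  set.seed(61)
  for (i in 1:20) {
    s <- rand_seq(sample(15:40, 1))
    f1 <- fold_mfe(s)
    f2 <- fold_mfe(s)
    expect_identical(f1$structure, f2$structure)
    expect_identical(f1$mfe, f2$mfe)
    expect_lte(f1$mfe, 0)
  }
})

test_that("DP minimum equals exhaustive enumeration on short sequences", {
  model <- default_energy_model()
  set.seed(62)
  for (i in 1:60) {
    s <- rand_seq(sample(10:18, 1), prob = c(0.2, 0.3, 0.3, 0.2))
    expect_equal(fold_mfe(s, model)$mfe, oracle_brute_mfe(s, model),
                 tolerance = 1e-6, label = s)
  }
})

test_that("unit model reduces folding to Nussinov maximum matching", {
  um <- unit_energy_model()
  set.seed(63)
  for (i in 1:30) {
    s <- rand_seq(30)
    expect_equal(-fold_mfe(s, um)$mfe, oracle_nussinov(s), label = s)
  }
})

test_that("stem-loop detection counts terminal hairpin loops", {
  hp <- paste0("GGCGGCGGCGGCGGCGGCGGC", "AACAACAAAC",
               rc("GGCGGCGGCGGCGGCGGCGGC"))
  f <- fold_mfe(hp)
  sl <- is_stem_loop(f)
  expect_true(sl$is_stem_loop)
  expect_equal(sl$hairpin_span[1], min(which(f$pairing > 0)))

  # two independent hairpins -> not a stem-loop
  one <- paste0("GGGCGGGC", "AAACAA", rc("GGGCGGGC"))
  two <- paste0(one, "AAAA", one)
  f2 <- fold_mfe(two)
  expect_false(is_stem_loop(f2)$is_stem_loop)

  # unpaired fold
  expect_false(is_stem_loop(fold_mfe("AAAAAAAAAAAA"))$is_stem_loop)

  # agrees with a direct dot-bracket scan on random sequences
  set.seed(64)
  for (i in 1:30) {
    f <- fold_mfe(rand_seq(sample(20:60, 1)))
    n_loops <- length(gregexpr("\\(\\.*\\)", f$structure)[[1]])
    if (gregexpr("\\(\\.*\\)", f$structure)[[1]][1] == -1) n_loops <- 0
    expect_equal(is_stem_loop(f)$is_stem_loop, n_loops == 1)
  }
})

test_that("duplex metrics recover planted geometry", {
  # perfect duplex, no overhangs
  m <- "UGGAGCUCCAAUCAUUCCAAUG"
  hp <- paste0(m, "AACAACAAAC", rc(m))
  f <- fold_mfe(hp)
  dup <- extract_duplex(f, c(1, nchar(m)),
                        c(nchar(m) + 11, nchar(hp)))
  expect_equal(dup$overhang_5p, 0L)
  expect_equal(dup$overhang_3p, 0L)
  expect_equal(dup$max_bulge, 0L)
  expect_equal(dup$paired_fraction, 1)
  expect_equal(dup$mature_arm, "5p")

  # canonical 2-nt 3' overhangs: trim the declared spans' partners
  # by extending each span 2 nt past its pairing partner range
  hp2 <- paste0("UU", m, "AACAACAAAC", rc(m), "AA")
  f2 <- fold_mfe(hp2)
  mature_span <- c(3, nchar(m) + 4)          # mature + 2 unpaired at 3' end
  star_span <- c(nchar(m) + 13, nchar(hp2))  # star + 2 unpaired at 3' end
  dup2 <- extract_duplex(f2, mature_span, star_span)
  expect_equal(dup2$overhang_5p, 2L)
  expect_equal(dup2$overhang_3p, 2L)
  expect_equal(dup2$max_bulge, 0L)

  expect_error(extract_duplex(f, c(1, 22), c(20, 40)), "overlap")
})

test_that("planted interior bulges of size 1..6 are measured exactly", {
  m <- "GCAGCAGCUAGCAGCAGCAGCA"
  for (b in 1:6) {
    # insert b unpaired As into the star arm interior
    star <- rc(m)
    star_bulged <- paste0(substr(star, 1, 10), strrep("A", b),
                          substr(star, 11, nchar(star)))
    hp <- paste0(m, "AACAACAAAC", star_bulged)
    f <- fold_mfe(hp)
    sl <- is_stem_loop(f)
    expect_true(sl$is_stem_loop, label = paste("bulge", b))
    dup <- extract_duplex(f, c(1, nchar(m)),
                          c(nchar(m) + 11, nchar(hp)))
    expect_equal(dup$max_bulge, b, label = paste("bulge", b))
    expect_gte(dup$loop_count_in_duplex, 1)
  }
})

test_that("duplex hybridization energy follows the stack table", {
  model <- default_energy_model()
  m <- "UGGAGCUCCAAUCAUUCCAAU"
  expect_lt(duplex_energy(m, rc(m), model), -18)

  # all-mismatch: pair every base with itself (A:A, C:C, ... never pair)
  s <- "ACGUACGUACGU"
  anti <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(duplex_energy(s, anti, model), 0)

  # manual stack-sum oracle on 12-nt duplexes
  set.seed(65)
  for (i in 1:20) {
    a <- rand_seq(12)
    b <- rand_seq(12)
    got <- duplex_energy(a, b, model)
    av <- strsplit(a, "")[[1]]
    bv <- rev(strsplit(b, "")[[1]])
    pt <- vapply(1:12, function(k) {
      p <- oracle_ptype(av[k], bv[k])
      if (is.na(p)) NA_integer_ else p
    }, integer(1))
    want <- 0
    for (k in 1:11) {
      if (!is.na(pt[k]) && !is.na(pt[k + 1])) {
        want <- want + model$stack[pt[k], pt[k + 1]]
      }
    }
    expect_equal(got, want, tolerance = 1e-9)
  }

  expect_error(duplex_energy("ACGUACGUACG", "ACGU"), "equal length")
})

test_that("hairpin rule checker applies all four criteria", {
  m <- "UGGAGCUCCAAUCAUUCCAAUG"
  hp <- paste0(m, "AACAACAAAC", rc(m))
  chk <- check_hairpin_candidate(hp, c(1, nchar(m)))
  expect_true(chk$pass)
  expect_true(chk$mfe_ok)
  expect_lte(chk$fold$mfe, -18)

  # 5-nt interior bulge violates the bulge rule
  star <- rc(m)
  star5 <- paste0(substr(star, 1, 10), strrep("A", 5),
                  substr(star, 11, nchar(star)))
  hp5 <- paste0(m, "AACAACAAAC", star5)
  chk5 <- check_hairpin_candidate(hp5, c(1, nchar(m)))
  expect_false(chk5$bulge_ok)
  expect_false(chk5$pass)

  # the MFE bound is inclusive ("no more than"): a precursor exactly at
  # the threshold passes, one just above it fails
  mfe <- chk$fold$mfe
  expect_true(check_hairpin_candidate(hp, c(1, nchar(m)),
                                      max_mfe = mfe)$pass)
  expect_false(check_hairpin_candidate(hp, c(1, nchar(m)),
                                       max_mfe = mfe - 0.1)$pass)
})
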