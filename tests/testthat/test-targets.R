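make_transcript <- function(site, flank = 30) {
  set.seed(nchar(site))
  paste0(rand_seq(flank), site, rand_seq(flank))
}

test_that("perfect complement windows are accepted as cleavage sites", {
  m <- c(mir1 = "UGGAGCUCCAAUCAUUCCAAU")
  tx <- c(t1 = make_transcript(rc(m[[1]])))
  sites <- scan_targets(m, tx)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$total_mismatches, 0)
  expect_equal(sites$mode, "cleavage")
  expect_lt(sites$duplex_mfe, -18)
  expect_equal(substr(tx[[1]], sites$start, sites$end), rc(m[[1]]))
})

test_that("positional rules reject central and excess mismatches", {
  m <- c(mir1 = "UGGAGCUCCAAUCAUUCCAAU")
  L <- nchar(m[[1]])
  site <- rc(m[[1]])
  mutate_at <- function(site, mir_pos) {
    sp <- L - mir_pos + 1
    ch <- strsplit(site, "")[[1]]
    base <- substr(m[[1]], mir_pos, mir_pos)
    partner <- c(A = "U", C = "G", G = "C", U = "A")[[base]]
    wob <- c(G = "U", U = "G", A = "x", C = "x")[[base]]
    ch[sp] <- setdiff(c("A", "C", "G", "U"), c(partner, wob))[1]
    paste(ch, collapse = "")
  }
  # single mismatch at miRNA position 10: rejected
  tx <- c(t1 = make_transcript(mutate_at(site, 10)))
  expect_equal(nrow(scan_targets(m, tx)), 0)
  # ... and also rejected by the relaxed scan (rule i, positions 10-11)
  expect_equal(nrow(scan_targets(m, tx, relaxed = TRUE)), 0)

  # five scattered mismatches: rejected even outside the seed
  s5 <- site
  for (p in c(13, 15, 17, 19, 21)) s5 <- mutate_at(s5, p)
  expect_equal(nrow(scan_targets(m, c(t1 = make_transcript(s5)))), 0)

  # mismatch at position 9 passes the relaxed scan only, as
  # translational inhibition
  s9 <- mutate_at(site, 9)
  tx9 <- c(t1 = make_transcript(s9))
  expect_equal(nrow(scan_targets(m, tx9)), 0)
  rel <- scan_targets(m, tx9, relaxed = TRUE)
  expect_equal(nrow(rel), 1)
  expect_equal(rel$mode, "translational_inhibition")

  # mismatch at position 5 only: cleavage
  s5b <- mutate_at(site, 5)
  rel5 <- scan_targets(m, c(t1 = make_transcript(s5b)), relaxed = TRUE)
  expect_equal(nrow(rel5), 1)
  expect_equal(rel5$mode, "cleavage")
})

test_that("transcripts shorter than the miRNA yield no sites and no error", {
  m <- c(mir1 = "UGGAGCUCCAAUCAUUCCAAU")
  expect_equal(nrow(scan_targets(m, c(t = "ACGUACGU"))), 0)
})

test_that("scan agrees with the direct rule evaluator on all single and double mismatch placements", {
  model <- default_energy_model()
  m <- "UGGAGCUCCAAUCAUUCCAAU"
  L <- nchar(m)
  site0 <- rc(m)
  mutate_at <- function(site, mir_pos) {
    sp <- L - mir_pos + 1
    ch <- strsplit(site, "")[[1]]
    base <- substr(m, mir_pos, mir_pos)
    partner <- c(A = "U", C = "G", G = "C", U = "A")[[base]]
    wob <- c(G = "U", U = "G", A = "x", C = "x")[[base]]
    ch[sp] <- setdiff(c("A", "C", "G", "U"), c(partner, wob))[1]
    paste(ch, collapse = "")
  }
  cases <- list(site0)
  for (p in 1:L) cases[[length(cases) + 1]] <- mutate_at(site0, p)
  for (p in 1:(L - 1)) {
    for (q in (p + 1):L) {
      cases[[length(cases) + 1]] <- mutate_at(mutate_at(site0, p), q)
    }
  }
  mirnas <- c(q = m)
  got <- logical(length(cases))
  want <- logical(length(cases))
  for (i in seq_along(cases)) {
    site <- cases[[i]]
    got[i] <- nrow(scan_targets(mirnas, c(t = site), model = model)) == 1
    want[i] <- oracle_target_rules(m, site, duplex_energy(m, site, model))
  }
  expect_equal(got, want)
  expect_gt(sum(want), 0)
  expect_lt(sum(want), length(cases))
})

test_that("tightening thresholds never adds sites", {
  set.seed(91)
  m <- c(mir1 = rand_seq(21))
  txs <- setNames(replicate(5, make_transcript(rc(m[[1]]))),
                  paste0("t", 1:5))
  # introduce scattered noise copies
  txs <- c(txs, setNames(replicate(5, rand_seq(120)), paste0("n", 1:5)))
  loose <- target_rules_default()
  tight <- loose
  tight$max_mismatches <- 0L
  n_loose <- nrow(scan_targets(m, txs, rules = loose))
  n_tight <- nrow(scan_targets(m, txs, rules = tight))
  expect_lte(n_tight, n_loose)
  tight2 <- loose
  tight2$max_energy <- -60
  expect_lte(nrow(scan_targets(m, txs, rules = tight2)), n_loose)
})

test_that("target summary uses distinct-count semantics", {
  sites <- data.frame(
    mirna_id = c("m1", "m1"), transcript_id = c("g1", "g2"),
    start = 1L, end = 21L, profile = "M", total_mismatches = 0L,
    duplex_mfe = -30, mode = "cleavage", stringsAsFactors = FALSE)
  ts <- target_summary(sites)
  expect_equal(unlist(ts[ts$group == "total", 2:5], use.names = FALSE),
               c(1, 2, 2, 2))

  set.seed(92)
  sites <- data.frame(
    mirna_id = sample(paste0("m", 1:6), 40, TRUE),
    transcript_id = sample(paste0("g", 1:10), 40, TRUE),
    start = 1L, end = 21L, profile = "M", total_mismatches = 0L,
    duplex_mfe = -30, mode = "cleavage", stringsAsFactors = FALSE)
  ts <- target_summary(sites)
  tot <- ts[ts$group == "total", ]
  expect_equal(tot$n_sites, 40)
  expect_equal(tot$n_genes, length(unique(sites$transcript_id)))
  expect_equal(tot$n_pairs,
               nrow(unique(sites[, c("mirna_id", "transcript_id")])))
  expect_gte(tot$n_pairs, tot$n_genes)
  expect_gte(tot$n_sites, tot$n_pairs)
})
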