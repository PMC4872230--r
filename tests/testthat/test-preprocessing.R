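make_reads <- function(seqs, qual = NULL) {
  data.frame(id = sprintf("r%d", seq_along(seqs)), seq = seqs,
             qual = if (is.null(qual)) strrep("I", nchar(seqs)) else qual,
             stringsAsFactors = FALSE)
}

AD3 <- "UCGUAUGCCGUCUUCUGCUUG"

test_that("filter assigns each read to exactly one category in fixed order", {
  res <- filter_clean_reads(make_reads(character(0)))
  expect_true(all(res$report$reads == 0))

  # a 17-nt insert with adapters present is shorter_than_min, not polyA
  ins <- "ACGCACGCACGCACGCA"
  rd <- make_reads(paste0(ins, AD3))
  res <- filter_clean_reads(rd)
  rep <- res$report
  expect_equal(rep$reads[rep$type == "shorter_than_min"], 1)
  expect_equal(rep$reads[rep$type == "polya"], 0)

  # low quality wins over everything else
  rd <- make_reads(paste0(ins, AD3))
  rd$qual <- paste0("#", substr(rd$qual, 2, nchar(rd$qual)))
  rep <- filter_clean_reads(rd)$report
  expect_equal(rep$reads[rep$type == "shorter_than_min"], 0)
  expect_equal(rep$reads[rep$type == "high_quality"], 0)

  # clean read comes back trimmed
  ins <- "GCUAGCUAGCUAGCUAGCUAGC"
  res <- filter_clean_reads(make_reads(paste0(ins, AD3)))
  expect_equal(res$clean$seq, ins)
  expect_equal(res$report$reads[res$report$type == "clean"], 1)
})

test_that("filter accounting balances on simulated defect reads", {
  cfg <- mini_sim_config(seed = 21L)
  gen <- generate_genome(cfg)
  rs <- simulate_reads(cfg, gen)
  res <- filter_clean_reads(rs$reads, adapter3 = cfg$adapter3,
                            adapter5 = cfg$adapter5)
  rep <- res$report
  n <- function(t) rep$reads[rep$type == t]
  # accounting invariant
  expect_equal(n("clean"),
               n("high_quality") - n("adapter3_null") - n("insert_null") -
                 n("adapter5_contaminant") - n("shorter_than_min") -
                 n("polya"))
  # generator-as-oracle: planted category counts are recovered exactly
  truth <- table(rs$category)
  expect_equal(n("clean"), unname(truth[["clean"]]))
  for (cat in c("adapter3_null", "insert_null", "adapter5_contaminant",
                "shorter_than_min", "polya")) {
    expect_equal(n(cat), unname(truth[[cat]]), label = cat)
  }
  expect_equal(n("total_reads") - n("high_quality"),
               unname(truth[["low_quality"]]))
})

test_that("genome mapping reports every exact occurrence on both strands", {
  genome <- c(chr1 = "AACCGGUUACGUACGUUGCAUGCAUGGCAUCGAAUUCCGGAACCGGUU")
  tag <- substr(genome[[1]], 5, 24)
  hits <- map_to_genome(tag, genome)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 5L)
  expect_equal(hits$strand, "+")

  anti <- rc(substr(genome[[1]], 11, 30))
  hits <- map_to_genome(anti, genome)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 11L)
  expect_equal(hits$strand, "-")

  expect_error(map_to_genome("ACGU", genome), "shorter")
})

test_that("mapping equals a sliding-window oracle on random instances", {
  set.seed(31)
  genome <- c(c1 = rand_seq(4000), c2 = rand_seq(3000))
  # half the tags are genuine substrings, half random
  tags <- character(120)
  for (i in 1:60) {
    ch <- sample(1:2, 1)
    st <- sample(nchar(genome[[ch]]) - 19, 1)
    s <- substr(genome[[ch]], st, st + 19)
    tags[i] <- if (i %% 2) s else rc(s)
  }
  for (i in 61:120) tags[i] <- rand_seq(20)
  tags <- unique(tags)
  hits <- map_to_genome(tags, genome)
  # brute-force scan oracle
  oracle <- list()
  for (tg in tags) {
    for (ch in names(genome)) {
      g <- genome[[ch]]
      for (st in seq_len(nchar(g) - nchar(tg) + 1)) {
        w <- substr(g, st, st + nchar(tg) - 1)
        if (w == tg) {
          oracle[[length(oracle) + 1]] <- c(tg, ch, st, "+")
        }
        if (w == rc(tg)) {
          oracle[[length(oracle) + 1]] <- c(tg, ch, st, "-")
        }
      }
    }
  }
  om <- do.call(rbind, oracle)
  okey <- sort(unique(paste(om[, 1], om[, 2], om[, 3], om[, 4])))
  hkey <- sort(paste(hits$seq, hits$chrom, hits$start, hits$strand))
  expect_equal(hkey, okey)
})

test_that("annotation follows the fixed priority order", {
  tags <- collapse_reads(c("ACGUACGUACGUACGUAC"))
  refs <- list(known_miRNA = c(k1 = "GGACGUACGUACGUACGUACGG"),
               rRNA = c(r1 = "ACGUACGUACGUACGUACAAAA"))
  ann <- annotate_tags(tags, refs)
  expect_equal(ann$annotation, "known_miRNA")

  ann <- annotate_tags(tags, list(tRNA = c(t1 = "AACGUACGUACGUACGUACA")))
  expect_equal(ann$annotation, "tRNA")

  # genomic context: inside an intron, matching no reference
  genome <- c(chr1 = rand_seq(200))
  tag <- substr(genome[[1]], 60, 79)
  tags <- collapse_reads(tag)
  hits <- map_to_genome(tags, genome)
  regions <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 50, 101), c(49, 100, 200)),
    strand = c("+", "+", "*"))
  regions$region_kind <- c("exon", "intron", "intergenic")
  ann <- annotate_tags(tags, list(), hits, regions)
  expect_equal(ann$annotation, "intron")
})

test_that("length distribution matches a tally oracle", {
  tags <- collapse_reads(rep(rand_seq(22), 3))
  ld <- length_distribution(tags)
  expect_equal(ld$unique_percent, 100)
  expect_equal(ld$total_percent, 100)

  tags <- data.frame(seq = c(rand_seq(21), rand_seq(22)),
                     count = c(10L, 30L),
                     annotation = "unannotated", stringsAsFactors = FALSE)
  ld <- length_distribution(tags)
  expect_equal(ld$unique_percent, c(50, 50))
  expect_equal(ld$total_percent, c(25, 75))

  set.seed(41)
  tags <- collapse_reads(replicate(500, rand_seq(sample(18:25, 1))))
  tags$annotation <- sample(c("unannotated", "rRNA"), nrow(tags), TRUE)
  ld <- length_distribution(tags, exclude = "rRNA")
  keep <- tags[tags$annotation != "rRNA", ]
  expect_equal(sum(ld$unique_count), nrow(keep))
  expect_equal(sum(ld$total_count), sum(keep$count))
  expect_equal(sum(ld$unique_percent), 100, tolerance = 1e-9)
  expect_equal(ld$total_count[ld$length == 20],
               sum(keep$count[nchar(keep$seq) == 20]))
})

test_that("first-nucleotide bias and positional frequencies sum to one", {
  fb <- first_nucleotide_bias(c("UAGCUAGCUAGCUAGCUA", "UGGCAUGCAUGCAUGCAU"))
  expect_equal(fb$U[fb$length == 18], 1)

  fb <- first_nucleotide_bias(c("GAGCUAGCUAGCUAGCUA", "UGGCAUGCAUGCAUGCAU"))
  expect_equal(fb$G, 0.5)
  expect_equal(fb$U, 0.5)

  set.seed(51)
  seqs <- replicate(50, rand_seq(sample(18:23, 1)))
  nf <- nucleotide_frequencies(seqs)
  expect_true(all(abs(rowSums(nf[, c("A", "C", "G", "U")]) - 1) < 1e-9))
  # position 3 tally oracle
  b3 <- substr(seqs, 3, 3)
  expect_equal(nf$A[3], mean(b3 == "A"))
})

test_that("report arithmetic honours the accounting invariants", {
  rep <- clean_filter_report(1000, 100, 10, 20, 30, 40, 0)
  r <- function(t) rep$reads[rep$type == t]
  expect_equal(r("high_quality"), 900)
  expect_equal(r("clean"), 800)
  expect_equal(rep$percent[rep$type == "clean"],
               round(100 * 800 / 900, 2))
  mp <- mapping_report(50, 200, 500, 1000)
  expect_equal(mp$unique_percent[2], 25)
  expect_equal(mp$total_percent[2], 50)
  expect_error(mapping_report(300, 200, 1, 2))
})
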