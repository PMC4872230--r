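#' Simulation configuration
#'
#' Study conditions for the synthetic small-RNA experiment: a random
#' genome with annotated gene models, planted pre-miRNA hairpins
#' (constructively designed to satisfy the precursor rules, verified at
#' generation time), log-normally expressed mature reads peaking at
#' 21-22 nt, decoy t/r/sn/snoRNA fragments, uniform degradation noise,
#' adapter-defect reads exercising every clean-filter category, ESTs
#' carrying homologs of reference matures, transcripts with planted
#' complementary target sites, and gene-to-GO/KO maps with one
#' deliberately over-represented term.
#'
#' @param seed Master seed; every downstream draw is fixed by it.
#' @param ... Overrides for any default listed below.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 7L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # genome
    n_chromosomes = 2L,
    chromosome_length = 25000L,
    genes_per_chromosome = 5L,
    exon_len = 300L, intron_len = 500L, intergenic_gap = 1500L,
    # hairpins
    n_novel_hairpins = 20L,
    n_known_hairpins = 8L,
    mature_lengths = c(20L, 21L, 22L, 23L),
    mature_length_probs = c(0.15, 0.35, 0.35, 0.15),
    loop_length_range = c(8L, 12L),
    # reads
    total_reads = 50000L,
    expression_meanlog = 6.5, expression_sdlog = 1.0,
    degradation_fraction = 0.2,
    decoy_fraction = 0.3,
    degradation_length_range = c(18L, 28L),
    read_length = 50L,
    adapter3 = "UCGUAUGCCGUCUUCUGCUUG",
    adapter5 = "GUUCAGAGUUCUACAGUCCGACGAUC",
    defect_fractions = c(low_quality = 0.01, adapter3_null = 0.01,
                         insert_null = 0.005, adapter5_contaminant = 0.005,
                         shorter_than_min = 0.01, polya = 0.002),
    # decoy ncRNA references
    n_decoys_per_class = 3L,
    decoy_length = c(rRNA = 120L, tRNA = 75L, snRNA = 100L, snoRNA = 90L),
    # ESTs and reference matures
    n_extra_reference_matures = 6L,
    n_ests = 30L, est_length = 400L, n_est_conserved = 2L,
    est_homolog_mismatches = 1L,
    # transcripts, targets, annotation maps
    n_transcript_genes = 60L, transcript_length = 300L,
    n_target_genes = 20L,
    n_relaxed_only_sites = 3L,
    n_go_terms = 15L, n_ko_terms = 10L,
    go_terms_per_gene = c(2L, 4L),
    planted_term_rate_target = 0.9,
    planted_term_rate_background = 0.05)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

rand_rna <- function(n, alphabet = c("A", "C", "G", "U"),
                     prob = rep(0.25, length(alphabet))) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# insert must be trimmed back exactly by the clean filter: the adapter
# must be located at the insert/adapter junction and nowhere earlier
insert_is_clean <- function(insert, cfg) {
  if (nchar(insert) == 0) return(FALSE)
  a_frac <- (nchar(insert) -
               nchar(gsub("A", "", insert, fixed = TRUE))) / nchar(insert)
  if (a_frac >= 0.8) return(FALSE)
  read <- substr(paste0(insert, cfg$adapter3), 1, cfg$read_length)
  locate_adapter_cpp(read, cfg$adapter3, 6L, 1L) == nchar(insert)
}

design_hairpin <- function(cfg, model) {
  repeat {
    L <- sample(cfg$mature_lengths, 1, prob = cfg$mature_length_probs)
    mature <- rand_rna(L)
    if (!insert_is_clean(mature, cfg)) next
    loop <- rand_rna(sample(cfg$loop_length_range[1]:cfg$loop_length_range[2],
                            1), alphabet = c("A", "C"))
    arm <- sample(c("5p", "3p"), 1)
    if (arm == "5p") {
      pre <- paste0(mature, loop, revcomp_rna(mature))
      mspan <- c(1L, L)
    } else {
      pre <- paste0(revcomp_rna(mature), loop, mature)
      mspan <- c(nchar(pre) - L + 1L, nchar(pre))
    }
    chk <- check_hairpin_candidate(pre, mspan, model = model)
    if (chk$pass) {
      return(list(mature = mature, precursor = pre, arm = arm,
                  mature_offset = mspan[1] - 1L, mfe = chk$fold$mfe))
    }
  }
}

#' Generate the synthetic genome, region annotation and planted truth
#'
#' Random chromosomes carry regularly spaced two-exon gene models
#' (alternating strands); the rest is intergenic. Pre-miRNA hairpins
#' (mature + A/C loop + reverse complement of the mature) are planted
#' at non-overlapping intergenic and intronic positions on random
#' strands. Each planted precursor is re-verified against the discovery
#' rules, including its genomic flanks, so recovery failures indicate a
#' pipeline defect rather than an unlucky draw.
#'
#' @param cfg A `sim_config`.
#' @param model Energy model used for generation-time verification.
#' @return A list: `genome` (named RNA character vector), `regions`
#'   (`GRanges`), `hairpins` (truth data.frame), `known_refs` and
#'   `extra_refs` (named reference mature sets), `decoys` (list of
#'   named vectors per ncRNA class).
#' @export
generate_genome <- function(cfg, model = default_energy_model()) {
  set.seed(cfg$seed)
  chroms <- paste0("contig", seq_len(cfg$n_chromosomes))
  genome <- vapply(chroms, function(ch) rand_rna(cfg$chromosome_length),
                   character(1))

  # gene models and region annotation
  reg <- list()
  free <- list()  # intervals available for hairpin planting
  for (ci in seq_along(chroms)) {
    pos <- 1L
    glen <- 2L * cfg$exon_len + cfg$intron_len
    for (g in seq_len(cfg$genes_per_chromosome)) {
      gap_end <- pos + cfg$intergenic_gap - 1L
      reg[[length(reg) + 1]] <- data.frame(
        chrom = chroms[ci], start = pos, end = gap_end,
        kind = "intergenic", strand = "*")
      free[[length(free) + 1]] <- c(ci, pos, gap_end)
      gs <- gap_end + 1L
      strand <- if (g %% 2 == 0) "-" else "+"
      e1 <- c(gs, gs + cfg$exon_len - 1L)
      it <- c(e1[2] + 1L, e1[2] + cfg$intron_len)
      e2 <- c(it[2] + 1L, it[2] + cfg$exon_len)
      reg[[length(reg) + 1]] <- data.frame(
        chrom = chroms[ci], start = e1[1], end = e1[2],
        kind = "exon", strand = strand)
      reg[[length(reg) + 1]] <- data.frame(
        chrom = chroms[ci], start = it[1], end = it[2],
        kind = "intron", strand = strand)
      free[[length(free) + 1]] <- c(ci, it[1], it[2])
      reg[[length(reg) + 1]] <- data.frame(
        chrom = chroms[ci], start = e2[1], end = e2[2],
        kind = "exon", strand = strand)
      pos <- e2[2] + 1L
    }
    if (pos <= cfg$chromosome_length) {
      reg[[length(reg) + 1]] <- data.frame(
        chrom = chroms[ci], start = pos, end = cfg$chromosome_length,
        kind = "intergenic", strand = "*")
      free[[length(free) + 1]] <- c(ci, pos, cfg$chromosome_length)
    }
  }
  reg <- do.call(rbind, reg)
  regions <- GenomicRanges::GRanges(
    reg$chrom, IRanges::IRanges(reg$start, reg$end), strand = reg$strand)
  regions$region_kind <- reg$kind

  # plant hairpins
  n_total <- cfg$n_novel_hairpins + cfg$n_known_hairpins
  occupied <- list()
  truth <- list()
  check <- function(win, mspan) check_hairpin_candidate(win, mspan,
                                                        model = model)
  for (hi in seq_len(n_total)) {
    repeat {
      hp <- design_hairpin(cfg, model)
      plen <- nchar(hp$precursor)
      # pick a free interval with clearance for the flank sweep
      slot <- free[[sample(length(free), 1)]]
      lo <- slot[2] + 160L
      hi_end <- slot[3] - 160L - plen
      if (hi_end <= lo) next
      start <- sample(lo:hi_end, 1)
      end <- start + plen - 1L
      ci <- slot[1]
      # keep planted hairpins out of each other's widest flank window
      clash <- any(vapply(occupied, function(o) {
        o[1] == ci && start <= o[3] + 350L && end >= o[2] - 350L
      }, logical(1)))
      if (clash) next
      strand <- sample(c("+", "-"), 1)
      planted <- if (strand == "+") hp$precursor else
        revcomp_rna(hp$precursor)
      g <- genome[[ci]]
      genome[[ci]] <- paste0(substr(g, 1, start - 1L), planted,
                             substr(g, end + 1L, nchar(g)))
      # mature genome span (plus-strand coordinates)
      if (strand == "+") {
        ms <- start + hp$mature_offset
      } else {
        ms <- end - hp$mature_offset - nchar(hp$mature) + 1L
      }
      me <- ms + nchar(hp$mature) - 1L
      # verify recoverability in genomic context (flanks included)
      best <- best_precursor_window(genome[[ci]], ms, me, strand,
                                    c(20L, 60L, 100L, 150L), check)
      if (is.null(best)) {
        # undo insertion and redraw
        genome[[ci]] <- g
        next
      }
      occupied[[length(occupied) + 1]] <- c(ci, start, end)
      origin <- if (hi <= cfg$n_novel_hairpins) "novel" else "known"
      truth[[length(truth) + 1]] <- data.frame(
        name = sprintf("%s-hp-%d", origin, hi),
        origin = origin, chrom = names(genome)[ci],
        precursor_start = start, precursor_end = end,
        mature_start = ms, mature_end = me,
        strand = strand, arm = hp$arm,
        mature_seq = hp$mature, precursor_seq = hp$precursor,
        mfe = hp$mfe, stringsAsFactors = FALSE)
      break
    }
  }
  truth <- do.call(rbind, truth)

  known <- truth$mature_seq[truth$origin == "known"]
  names(known) <- paste0("ref-", truth$name[truth$origin == "known"])
  extra <- character(cfg$n_extra_reference_matures)
  for (i in seq_along(extra)) {
    repeat {
      s <- rand_rna(sample(cfg$mature_lengths, 1,
                           prob = cfg$mature_length_probs))
      if (insert_is_clean(s, cfg)) { extra[i] <- s; break }
    }
  }
  names(extra) <- sprintf("ref-extra-%d", seq_along(extra))

  decoys <- list()
  for (cl in names(cfg$decoy_length)) {
    dl <- cfg$decoy_length[[cl]]
    decoys[[cl]] <- vapply(seq_len(cfg$n_decoys_per_class),
                           function(i) rand_rna(dl), character(1))
    names(decoys[[cl]]) <- sprintf("%s-%d", cl,
                                   seq_len(cfg$n_decoys_per_class))
  }

  list(genome = genome, regions = regions, hairpins = truth,
       known_refs = known, extra_refs = extra, decoys = decoys)
}

#' Simulate a raw small-RNA read set
#'
#' Mature reads are drawn with log-normal copy counts from the planted
#' hairpins; decoy ncRNA fragments and uniform degradation fragments
#' are added at the configured proportions; the 3' adapter is appended
#' and reads truncated to the read length; and a configured count of
#' reads per defect class exercises every clean-filter removal
#' category. Every insert is screened at generation time so that
#' adapter trimming recovers it exactly; the returned `category` truth
#' therefore matches the clean-filter report one-to-one.
#'
#' @param cfg A `sim_config`.
#' @param gen Output of [generate_genome()].
#' @return A list: `reads` (data.frame `id`, `seq`, `qual`),
#'   `category` (truth filter category per read), `insert` (the true
#'   insert), `source` (mature/decoy/degradation/defect class).
#' @export
simulate_reads <- function(cfg, gen) {
  set.seed(cfg$seed + 1L)
  hp <- gen$hairpins
  counts <- pmax(1L, as.integer(round(stats::rlnorm(
    nrow(hp), cfg$expression_meanlog, cfg$expression_sdlog))))
  mature_fraction <- 1 - cfg$degradation_fraction - cfg$decoy_fraction
  scale <- (cfg$total_reads * mature_fraction) / sum(counts)
  counts <- pmax(1L, as.integer(round(counts * scale)))
  inserts <- rep(hp$mature_seq, counts)
  source <- rep("mature", length(inserts))

  n_decoy <- as.integer(round(cfg$total_reads * cfg$decoy_fraction))
  all_decoys <- unlist(gen$decoys, use.names = FALSE)
  dec <- character(n_decoy)
  i <- 1L
  while (i <= n_decoy) {
    ref <- sample(all_decoys, 1)
    L <- sample(18:24, 1)
    st <- sample(nchar(ref) - L + 1L, 1)
    frag <- substr(ref, st, st + L - 1L)
    if (!insert_is_clean(frag, cfg)) next
    dec[i] <- frag
    i <- i + 1L
  }
  inserts <- c(inserts, dec)
  source <- c(source, rep("decoy", n_decoy))

  n_deg <- as.integer(round(cfg$total_reads * cfg$degradation_fraction))
  deg <- character(n_deg)
  i <- 1L
  while (i <= n_deg) {
    ch <- sample(names(gen$genome), 1)
    L <- sample(cfg$degradation_length_range[1]:cfg$degradation_length_range[2], 1)
    st <- sample(nchar(gen$genome[[ch]]) - L + 1L, 1)
    frag <- substr(gen$genome[[ch]], st, st + L - 1L)
    if (sample(c(TRUE, FALSE), 1)) frag <- revcomp_rna(frag)
    if (!insert_is_clean(frag, cfg)) next
    deg[i] <- frag
    i <- i + 1L
  }
  inserts <- c(inserts, deg)
  source <- c(source, rep("degradation", n_deg))
  category <- rep("clean", length(inserts))

  make_read <- function(ins) {
    substr(paste0(ins, cfg$adapter3), 1, cfg$read_length)
  }
  seqs <- vapply(inserts, make_read, character(1), USE.NAMES = FALSE)
  quals <- strrep("I", nchar(seqs))

  # defect reads, one category each
  df <- cfg$defect_fractions
  n_def <- as.integer(round(cfg$total_reads * df))
  names(n_def) <- names(df)
  cg_tail <- function(n) rand_rna(n, alphabet = c("C", "G"))
  add <- function(s, cat, src) {
    seqs <<- c(seqs, s)
    quals <<- c(quals, strrep("I", nchar(s)))
    inserts <<- c(inserts, NA_character_)
    category <<- c(category, rep(cat, length(s)))
    source <<- c(source, rep(src, length(s)))
  }
  base_insert <- function() {
    repeat {
      s <- rand_rna(21)
      if (insert_is_clean(s, cfg)) return(s)
    }
  }
  if (n_def[["low_quality"]] > 0) {
    s <- vapply(seq_len(n_def[["low_quality"]]),
                function(i) make_read(base_insert()), character(1))
    add(s, "low_quality", "defect")
    n <- length(seqs)
    sel <- (n - n_def[["low_quality"]] + 1L):n
    quals[sel] <- paste0("#", substr(quals[sel], 2, nchar(quals[sel])))
  }
  if (n_def[["adapter3_null"]] > 0) {
    s <- vapply(seq_len(n_def[["adapter3_null"]]), function(i) {
      substr(paste0(base_insert(), cg_tail(40)), 1, cfg$read_length)
    }, character(1))
    add(s, "adapter3_null", "defect")
  }
  if (n_def[["insert_null"]] > 0) {
    s <- vapply(seq_len(n_def[["insert_null"]]), function(i) {
      substr(paste0(cfg$adapter3, cg_tail(40)), 1, cfg$read_length)
    }, character(1))
    add(s, "insert_null", "defect")
  }
  if (n_def[["adapter5_contaminant"]] > 0) {
    s <- vapply(seq_len(n_def[["adapter5_contaminant"]]), function(i) {
      make_read(paste0(substr(cfg$adapter5, 1, 10), base_insert()))
    }, character(1))
    add(s, "adapter5_contaminant", "defect")
  }
  if (n_def[["shorter_than_min"]] > 0) {
    s <- vapply(seq_len(n_def[["shorter_than_min"]]), function(i) {
      repeat {
        ins <- rand_rna(sample(10:17, 1))
        if (insert_is_clean(ins, cfg)) return(make_read(ins))
      }
    }, character(1))
    add(s, "shorter_than_min", "defect")
  }
  if (n_def[["polya"]] > 0) {
    s <- rep(make_read(strrep("A", 22)), n_def[["polya"]])
    add(s, "polya", "defect")
  }

  ord <- sample(length(seqs))
  data.frame(id = sprintf("read%06d", seq_along(ord)),
             seq = seqs[ord], qual = quals[ord],
             stringsAsFactors = FALSE) -> reads
  list(reads = reads, category = category[ord], insert = inserts[ord],
       source = source[ord])
}

mutate_bases <- function(seq, n) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), n)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# a site base that neither Watson-Crick pairs nor wobbles with `base`
non_pairing_base <- function(base) {
  partner <- c(A = "U", C = "G", G = "C", U = "A")[[base]]
  wobble <- c(G = "U", U = "G", A = "", C = "")[[base]]
  sample(setdiff(c("A", "C", "G", "U"), c(partner, wobble)), 1)
}

#' Simulate ESTs, transcripts and annotation maps
#'
#' A configured number of ESTs embed hairpin contexts whose mature arm
#' is a near-copy (configured mismatch count) of an unexpressed
#' reference mature, emulating conserved miRNAs discoverable from EST
#' homology. Transcripts carry planted perfect-complement target sites
#' of planted matures on designated target genes, plus a few
#' relaxed-only sites holding a single mismatch at miRNA position 9
#' (translational-inhibition geometry). Gene-to-GO and gene-to-KO maps
#' assign one designated term to target genes at an elevated rate so
#' that enrichment analysis should rank it first.
#'
#' @param cfg A `sim_config`.
#' @param gen Output of [generate_genome()].
#' @param model Energy model for generation-time verification.
#' @return A list: `ests`, `est_truth`, `transcripts`, `target_truth`,
#'   `go_map`, `go_ontology`, `ko_map`, `planted_go_term`,
#'   `planted_ko_term`, `target_genes`.
#' @export
simulate_ests_and_annotations <- function(cfg, gen,
                                          model = default_energy_model()) {
  set.seed(cfg$seed + 2L)
  ests <- vapply(seq_len(cfg$n_ests), function(i) rand_rna(cfg$est_length),
                 character(1))
  names(ests) <- sprintf("est%03d", seq_len(cfg$n_ests))
  est_truth <- list()
  check <- function(win, mspan) {
    res <- check_hairpin_candidate(win, mspan, model = model,
                                   max_overhang = .Machine$integer.max,
                                   max_bulge = .Machine$integer.max,
                                   max_mfe = Inf)
    res$pass <- isTRUE(res$stem_loop) && !is.null(res$star_span) &&
      sum(res$fold$pairing[mspan[1]:mspan[2]] == 0) <= 3
    res
  }
  host <- sample(cfg$n_ests, cfg$n_est_conserved)
  for (k in seq_len(cfg$n_est_conserved)) {
    ref <- gen$extra_refs[[k]]
    repeat {
      mut <- mutate_bases(ref, cfg$est_homolog_mismatches)
      if (!insert_is_clean(mut, cfg)) next
      loop <- rand_rna(10, alphabet = c("A", "C"))
      pre <- paste0(mut, loop, revcomp_rna(mut))
      est <- ests[[host[k]]]
      pos <- sample(seq(50L, cfg$est_length - nchar(pre) - 50L), 1)
      cand <- paste0(substr(est, 1, pos - 1L), pre,
                     substr(est, pos + nchar(pre), nchar(est)))
      ms <- pos; me <- pos + nchar(mut) - 1L
      best <- best_precursor_window(cand, ms, me, "+",
                                    c(20L, 60L, 100L, 150L), check)
      if (is.null(best)) next
      ests[[host[k]]] <- cand
      est_truth[[k]] <- data.frame(
        est = names(ests)[host[k]], reference = names(gen$extra_refs)[k],
        mature_seq = mut, start = ms, end = me,
        stringsAsFactors = FALSE)
      break
    }
  }
  est_truth <- if (length(est_truth)) do.call(rbind, est_truth) else
    data.frame(est = character(0), reference = character(0),
               mature_seq = character(0), start = integer(0),
               end = integer(0))

  # transcripts with planted target sites
  genes <- sprintf("g%03d", seq_len(cfg$n_transcript_genes))
  transcripts <- vapply(genes, function(g) rand_rna(cfg$transcript_length),
                        character(1))
  target_genes <- genes[sample(cfg$n_transcript_genes, cfg$n_target_genes)]
  matures <- gen$hairpins$mature_seq
  names(matures) <- gen$hairpins$name
  tt <- list()
  for (i in seq_along(target_genes)) {
    g <- target_genes[i]
    mi <- sample(length(matures), 1)
    m <- matures[[mi]]
    site <- revcomp_rna(m)
    relaxed_only <- i <= cfg$n_relaxed_only_sites
    if (relaxed_only) {
      # single mismatch facing miRNA position 9
      sp <- nchar(m) - 9L + 1L
      ch <- strsplit(site, "")[[1]]
      ch[sp] <- non_pairing_base(substr(m, 9, 9))
      site <- paste(ch, collapse = "")
    }
    pos <- sample(seq(20L, cfg$transcript_length - nchar(site) - 20L), 1)
    tx <- transcripts[[g]]
    transcripts[[g]] <- paste0(substr(tx, 1, pos - 1L), site,
                               substr(tx, pos + nchar(site), nchar(tx)))
    tt[[i]] <- data.frame(gene = g, mirna = names(matures)[mi],
                          mature_seq = m, start = pos,
                          end = pos + nchar(site) - 1L,
                          kind = if (relaxed_only) "relaxed_only"
                                 else "perfect",
                          stringsAsFactors = FALSE)
  }
  target_truth <- do.call(rbind, tt)

  go_terms <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
  planted_go <- go_terms[1]
  go_ontology <- stats::setNames(
    rep(c("BP", "CC", "MF"), length.out = cfg$n_go_terms), go_terms)
  rows <- list()
  for (g in genes) {
    k <- sample(cfg$go_terms_per_gene[1]:cfg$go_terms_per_gene[2], 1)
    terms <- sample(go_terms[-1], k)
    rate <- if (g %in% target_genes) cfg$planted_term_rate_target
            else cfg$planted_term_rate_background
    if (stats::runif(1) < rate) terms <- c(planted_go, terms)
    rows[[length(rows) + 1]] <- data.frame(gene = g, term = terms,
                                           stringsAsFactors = FALSE)
  }
  go_map <- do.call(rbind, rows)

  ko_terms <- sprintf("K%05d", seq_len(cfg$n_ko_terms))
  planted_ko <- ko_terms[1]
  rows <- list()
  for (g in genes) {
    terms <- sample(ko_terms[-1], 2)
    rate <- if (g %in% target_genes) cfg$planted_term_rate_target
            else cfg$planted_term_rate_background
    if (stats::runif(1) < rate) terms <- c(planted_ko, terms)
    rows[[length(rows) + 1]] <- data.frame(gene = g, term = terms,
                                           stringsAsFactors = FALSE)
  }
  ko_map <- do.call(rbind, rows)

  list(ests = ests, est_truth = est_truth, transcripts = transcripts,
       target_truth = target_truth, target_genes = target_genes,
       go_map = go_map, go_ontology = go_ontology, ko_map = ko_map,
       planted_go_term = planted_go, planted_ko_term = planted_ko)
}

#' Generate the full synthetic study
#'
#' Runs [generate_genome()], [simulate_reads()] and
#' [simulate_ests_and_annotations()] under one configuration. Fully
#' reproducible: the same config (seed included) yields byte-identical
#' outputs.
#'
#' @param cfg A `sim_config`.
#' @param model Energy model for generation-time checks.
#' @return A list bundling all three components plus the config.
#' @export
simulate_study <- function(cfg = simulation_config(),
                           model = default_energy_model()) {
  gen <- generate_genome(cfg, model)
  reads <- simulate_reads(cfg, gen)
  est <- simulate_ests_and_annotations(cfg, gen, model)
  c(list(config = cfg), gen, reads, est)
}

#' Write a simulated study to disk
#'
#' Emits genome.fa, regions.gff3, reads.fq, ests.fa, transcripts.fa,
#' the ncRNA/known-miRNA reference FASTA files, go.tsv / ko.tsv and the
#' truth tables under `truth/`.
#'
#' @param sim Output of [simulate_study()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  write_fasta(sim$genome, file.path(outdir, "genome.fa"), "dna")
  write_gff_regions(sim$regions, file.path(outdir, "regions.gff3"))
  write_fastq(sim$reads, file.path(outdir, "reads.fq"))
  write_fasta(sim$ests, file.path(outdir, "ests.fa"), "dna")
  write_fasta(sim$transcripts, file.path(outdir, "transcripts.fa"), "dna")
  write_fasta(c(sim$known_refs, sim$extra_refs),
              file.path(outdir, "known_mirnas.fa"))
  for (cl in names(sim$decoys)) {
    write_fasta(sim$decoys[[cl]],
                file.path(outdir, paste0(tolower(cl), ".fa")))
  }
  write_annotation_map(sim$go_map, file.path(outdir, "go.tsv"))
  write_annotation_map(sim$ko_map, file.path(outdir, "ko.tsv"))
  utils::write.table(sim$hairpins, file.path(outdir, "truth", "hairpins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$target_truth,
                     file.path(outdir, "truth", "targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$est_truth,
                     file.path(outdir, "truth", "est_mirnas.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
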