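#' Filter raw reads into clean reads with per-category accounting
#'
#' Applies the five removal categories, each read being assigned to
#' exactly one category, tested in fixed order: low quality, 3' adapter
#' null, insert null, 5' adapter contaminant, shorter than `min_len`,
#' poly(A). Reads surviving all filters are returned adapter-trimmed as
#' clean reads. "Low quality" means any base call below `min_quality`
#' (Phred) or more than `max_n` ambiguous bases. The 3' adapter is
#' located by the best ungapped suffix-prefix overlap of at least
#' `min_overlap` nt with at most `adapter_mismatch` mismatches; no such
#' overlap is a "3' adapter null" and an overlap at position one (empty
#' insert) an "insert null". A read whose insert starts with at least 8
#' nt of the 5' adapter is a 5' adapter contaminant. Poly(A): at least
#' `polya_frac` A after trimming.
#'
#' @param reads data.frame from [read_fastq()] (`id`, `seq`, `qual`).
#' @param min_len Minimum insert length kept (nt).
#' @param adapter3,adapter5 Adapter sequences (any case, T or U).
#' @param min_quality Phred floor defining a low-quality base.
#' @param max_n Maximum number of N bases tolerated.
#' @param polya_frac Fraction of A defining a poly(A) read.
#' @param min_overlap,adapter_mismatch 3' adapter overlap parameters.
#' @param quality_offset ASCII offset of the quality encoding (33).
#' @return A list: `clean` (data.frame of trimmed clean reads) and
#'   `report`, the [clean_filter_report()] of category counts.
#' @export
filter_clean_reads <- function(reads, min_len = 18L,
                               adapter3 = "UCGUAUGCCGUCUUCUGCUUG",
                               adapter5 = "GUUCAGAGUUCUACAGUCCGACGAUC",
                               min_quality = 10L, max_n = 1L,
                               polya_frac = 0.8,
                               min_overlap = 6L, adapter_mismatch = 1L,
                               quality_offset = 33L) {
  n0 <- nrow(reads)
  if (n0 == 0) {
    rep0 <- clean_filter_report(total_reads = 0, low_quality = 0,
                                adapter3_null = 0, insert_null = 0,
                                adapter5_contaminant = 0,
                                shorter_than_min = 0, polya = 0)
    return(list(clean = reads, report = rep0))
  }
  adapter3 <- rna_norm(adapter3, "3' adapter")
  adapter5 <- rna_norm(adapter5, "5' adapter")
  seqs <- toupper(reads$seq)

  min_q_char <- vapply(reads$qual, function(q) {
    if (nchar(q) == 0) return(0L)
    min(utf8ToInt(q))
  }, integer(1), USE.NAMES = FALSE) - quality_offset
  n_count <- nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE))
  low_q <- min_q_char < min_quality | n_count > max_n

  status <- rep("clean", n0)
  status[low_q] <- "low_quality"
  live <- !low_q

  ins_len <- rep(-1L, n0)
  if (any(live)) {
    ins_len[live] <- locate_adapter_cpp(seqs[live], adapter3,
                                        as.integer(min_overlap),
                                        as.integer(adapter_mismatch))
  }
  status[live & ins_len < 0] <- "adapter3_null"
  live <- live & ins_len >= 0
  status[live & ins_len == 0] <- "insert_null"
  live <- live & ins_len > 0

  insert <- seqs
  insert[live] <- substr(seqs[live], 1, ins_len[live])

  pref <- substr(adapter5, 1, 8)
  contam <- live & nchar(insert) >= 8 & startsWith(insert, pref)
  status[contam] <- "adapter5_contaminant"
  live <- live & !contam

  short <- live & nchar(insert) < min_len
  status[short] <- "shorter_than_min"
  live <- live & !short

  a_frac <- (nchar(insert) - nchar(gsub("A", "", insert, fixed = TRUE))) /
    pmax(nchar(insert), 1)
  polya <- live & a_frac >= polya_frac
  status[polya] <- "polya"
  live <- live & !polya

  clean <- reads[live, , drop = FALSE]
  clean$seq <- insert[live]
  clean$qual <- substr(clean$qual, 1, nchar(clean$seq))
  rownames(clean) <- NULL

  report <- clean_filter_report(
    total_reads = n0,
    low_quality = sum(status == "low_quality"),
    adapter3_null = sum(status == "adapter3_null"),
    insert_null = sum(status == "insert_null"),
    adapter5_contaminant = sum(status == "adapter5_contaminant"),
    shorter_than_min = sum(status == "shorter_than_min"),
    polya = sum(status == "polya"))
  list(clean = clean, report = report)
}

#' Clean-read filtering report
#'
#' Assembles the clean-read accounting table from category counts: the
#' clean-read count is the high-quality count minus the five removal
#' categories, and every percentage is taken against the high-quality
#' count, rounded half-up to two decimals.
#'
#' @param total_reads Raw read count (high quality + low quality).
#' @param low_quality,adapter3_null,insert_null,adapter5_contaminant,shorter_than_min,polya
#'   Per-category removed read counts.
#' @return A data.frame of class `clean_filter_report` with columns
#'   `type`, `reads`, `percent`.
#' @export
#' @examples
#' clean_filter_report(11643105, 41335, 751, 7634, 11613, 337810, 112)
clean_filter_report <- function(total_reads, low_quality,
                                adapter3_null, insert_null,
                                adapter5_contaminant, shorter_than_min,
                                polya) {
  high_quality <- total_reads - low_quality
  clean <- high_quality - (adapter3_null + insert_null +
                           adapter5_contaminant + shorter_than_min + polya)
  types <- c("total_reads", "high_quality", "adapter3_null", "insert_null",
             "adapter5_contaminant", "shorter_than_min", "polya", "clean")
  reads <- c(total_reads, high_quality, adapter3_null, insert_null,
             adapter5_contaminant, shorter_than_min, polya, clean)
  percent <- c(NA, 100,
               vapply(reads[3:8], pct, numeric(1), den = high_quality))
  out <- data.frame(type = types, reads = reads, percent = percent,
                    stringsAsFactors = FALSE)
  class(out) <- c("clean_filter_report", class(out))
  out
}

#' Map tags to a genome by exact matching on both strands
#'
#' Every exact occurrence of each tag, sense and antisense (reverse
#' complement), is reported. Matching runs through Biostrings
#' dictionary matching with tags grouped by width.
#'
#' @param tags A `small_read_tags` data.frame (or character vector of
#'   tag sequences).
#' @param genome Named character vector of chromosome sequences (DNA or
#'   RNA alphabet).
#' @param min_len Tags shorter than this raise an error.
#' @return data.frame with columns `seq`, `chrom`, `start`, `end`,
#'   `strand` (1-based closed coordinates on the plus strand).
#' @export
map_to_genome <- function(tags, genome, min_len = 18L) {
  seqs <- if (is.data.frame(tags)) tags$seq else tags
  if (length(seqs) == 0) {
    return(data.frame(seq = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  if (any(nchar(seqs) < min_len)) {
    stop("tags shorter than the index width (", min_len, " nt) cannot be mapped")
  }
  gen <- Biostrings::DNAStringSet(dna_norm(genome))
  dna <- dna_norm(seqs)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(dna)))
  res <- list()
  for (w in unique(nchar(dna))) {
    sel <- which(nchar(dna) == w)
    # sense queries and antisense queries share one dictionary scan
    queries <- c(dna[sel], rc[sel])
    qstrand <- rep(c("+", "-"), each = length(sel))
    qseq <- rep(seqs[sel], 2)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(queries))
    for (ch in names(gen)) {
      m <- Biostrings::matchPDict(pd, gen[[ch]])
      cnt <- lengths(m)
      if (sum(cnt) == 0) next
      qi <- rep(seq_along(queries), cnt)
      st <- unlist(lapply(m, BiocGenerics::start), use.names = FALSE)
      res[[length(res) + 1]] <- data.frame(
        seq = qseq[qi], chrom = ch, start = st, end = st + w - 1L,
        strand = qstrand[qi], stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) {
    return(data.frame(seq = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$seq, out$chrom, out$start, out$strand), , drop = FALSE]
  out <- out[!duplicated(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome mapping report
#'
#' The unique-versus-total mapping accounting: a tag counts once in the
#' unique columns no matter how many loci it hits, and contributes its
#' copy count to the total columns. Percentages are taken against the
#' respective totals, rounded half-up to two decimals.
#'
#' @param unique_mapped,unique_total Mapped / all unique tag counts.
#' @param total_mapped,total_total Mapped / all read (copy) counts.
#' @return data.frame of class `mapping_report`.
#' @export
#' @examples
#' mapping_report(153264, 3017665, 4925432, 11243850)
mapping_report <- function(unique_mapped, unique_total,
                           total_mapped, total_total) {
  stopifnot(unique_mapped <= unique_total, total_mapped <= total_total)
  out <- data.frame(
    type = c("total", "mapped"),
    unique_reads = c(unique_total, unique_mapped),
    unique_percent = c(100, pct(unique_mapped, unique_total)),
    total_reads = c(total_total, total_mapped),
    total_percent = c(100, pct(total_mapped, total_total)),
    stringsAsFactors = FALSE)
  class(out) <- c("mapping_report", class(out))
  out
}

#' Summarize genome mapping of a tag set
#'
#' @param tags `small_read_tags` data.frame.
#' @param hits Hit table from [map_to_genome()].
#' @return A list: `report` ([mapping_report()]) and `by_chromosome`,
#'   per-chromosome per-strand tag and read counts.
#' @export
summarize_mapping <- function(tags, hits) {
  mapped <- tags$seq %in% hits$seq
  rep <- mapping_report(sum(mapped), nrow(tags),
                        sum(tags$count[mapped]), sum(tags$count))
  by_chrom <- if (nrow(hits)) {
    cnt <- tags$count[match(hits$seq, tags$seq)]
    stats::aggregate(cbind(tag_hits = 1, read_count = cnt),
                     by = list(chrom = hits$chrom, strand = hits$strand),
                     FUN = sum)
  } else {
    data.frame(chrom = character(0), strand = character(0),
               tag_hits = numeric(0), read_count = numeric(0))
  }
  list(report = rep, by_chromosome = by_chrom)
}

annotation_categories <- c("known_miRNA", "rRNA", "tRNA", "snRNA", "snoRNA",
                           "repeat", "exon_sense", "exon_antisense",
                           "intron", "intergenic", "unannotated")

#' Annotate tags against ncRNA references and genomic regions
#'
#' Assigns exactly one category per tag by fixed priority: known miRNA,
#' then rRNA, tRNA, snRNA, snoRNA and repeat references (a tag matches a
#' reference set when it is a substring of any of its sequences), then
#' genomic context of its mapped loci (exon sense, exon antisense,
#' intron, intergenic), else unannotated. A multi-locus tag takes the
#' highest-priority genomic label among its loci.
#'
#' @param tags `small_read_tags` data.frame.
#' @param references Named list of reference sequence vectors; recognized
#'   names: `known_miRNA`, `rRNA`, `tRNA`, `snRNA`, `snoRNA`, `repeat`.
#'   Missing or empty sets are skipped.
#' @param hits Hit table from [map_to_genome()].
#' @param regions `GRanges` from [read_gff_regions()].
#' @return `tags` with the `annotation` column filled in.
#' @export
annotate_tags <- function(tags, references = list(), hits = NULL,
                          regions = NULL) {
  ann <- rep("unannotated", nrow(tags))
  assigned <- rep(FALSE, nrow(tags))
  for (class_name in c("known_miRNA", "rRNA", "tRNA", "snRNA", "snoRNA",
                       "repeat")) {
    refs <- references[[class_name]]
    if (is.null(refs) || length(refs) == 0) next
    haystack <- paste(rna_norm(unname(refs), class_name), collapse = "\n")
    todo <- which(!assigned)
    hit <- vapply(tags$seq[todo], grepl, logical(1), x = haystack,
                  fixed = TRUE, USE.NAMES = FALSE)
    ann[todo[hit]] <- class_name
    assigned[todo[hit]] <- TRUE
  }
  if (!is.null(hits) && nrow(hits) > 0 && !is.null(regions) &&
      length(regions) > 0 && any(!assigned)) {
    todo <- which(!assigned)
    sub <- hits[hits$seq %in% tags$seq[todo], , drop = FALSE]
    if (nrow(sub) > 0) {
      gr <- GenomicRanges::GRanges(
        sub$chrom, IRanges::IRanges(sub$start, sub$end), strand = sub$strand)
      ov <- GenomicRanges::findOverlaps(gr, regions, ignore.strand = TRUE)
      if (length(ov) > 0) {
        hi <- S4Vectors::queryHits(ov)
        ri <- S4Vectors::subjectHits(ov)
        kind <- regions$region_kind[ri]
        rstrand <- as.character(GenomicRanges::strand(regions))[ri]
        hstrand <- sub$strand[hi]
        label <- ifelse(kind == "exon",
                        ifelse(rstrand == "*" | hstrand == rstrand,
                               "exon_sense", "exon_antisense"),
                        kind)
        prio <- match(label, annotation_categories)
        best <- tapply(prio, sub$seq[hi], min)
        lab <- annotation_categories[best]
        idx <- match(names(best), tags$seq)
        ann[idx] <- lab
      }
    }
  }
  tags$annotation <- ann
  tags
}

#' Length distribution of tags
#'
#' Per-length percentages of unique tags and of total read copies,
#' optionally excluding annotation categories (for example the
#' t/r/sn/snoRNA decoys before plotting a read-length profile).
#'
#' @param tags Annotated `small_read_tags`.
#' @param exclude Annotation categories to drop before tallying.
#' @return data.frame `length`, `unique_count`, `unique_percent`,
#'   `total_count`, `total_percent`.
#' @export
length_distribution <- function(tags,
                                exclude = c("rRNA", "tRNA", "snRNA",
                                            "snoRNA")) {
  keep <- !(tags$annotation %in% exclude)
  sub <- tags[keep, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(data.frame(length = integer(0), unique_count = integer(0),
                      unique_percent = numeric(0), total_count = integer(0),
                      total_percent = numeric(0)))
  }
  len <- nchar(sub$seq)
  uc <- tapply(rep(1L, nrow(sub)), len, sum)
  tc <- tapply(sub$count, len, sum)
  data.frame(length = as.integer(names(uc)),
             unique_count = as.integer(uc),
             unique_percent = 100 * as.integer(uc) / sum(uc),
             total_count = as.integer(tc),
             total_percent = 100 * as.integer(tc) / sum(tc))
}

#' First-nucleotide bias per sequence length
#'
#' @param seqs Character vector of miRNA sequences.
#' @return data.frame with `length` and frequency columns A, C, G, U
#'   summing to 1 within each length.
#' @export
first_nucleotide_bias <- function(seqs) {
  seqs <- rna_norm(seqs)
  len <- nchar(seqs)
  first <- substr(seqs, 1, 1)
  tab <- table(factor(len), factor(first, levels = c("A", "C", "G", "U")))
  freq <- prop.table(tab, margin = 1)
  out <- data.frame(length = as.integer(rownames(tab)),
                    as.data.frame.matrix(freq))
  rownames(out) <- NULL
  out
}

#' Per-position nucleotide frequencies
#'
#' @param seqs Character vector of miRNA sequences.
#' @return data.frame with `position` and frequency columns A, C, G, U;
#'   frequencies at each position sum to 1 over the sequences long
#'   enough to reach it.
#' @export
nucleotide_frequencies <- function(seqs) {
  seqs <- rna_norm(seqs)
  maxlen <- max(nchar(seqs))
  rows <- lapply(seq_len(maxlen), function(p) {
    b <- substr(seqs[nchar(seqs) >= p], p, p)
    tab <- prop.table(table(factor(b, levels = c("A", "C", "G", "U"))))
    data.frame(position = p, A = tab[["A"]], C = tab[["C"]],
               G = tab[["G"]], U = tab[["U"]])
  })
  do.call(rbind, rows)
}
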