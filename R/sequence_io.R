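#' Read a FASTQ file
#'
#' Plain four-line-record FASTQ reader with per-record validation.
#' Sequences are normalized to the RNA alphabet (T read as U); qualities
#' are returned verbatim. Malformed records (missing '@'/'+' markers,
#' sequence/quality length disagreement, truncated final record) raise an
#' error naming the offending record and line.
#'
#' @param path FASTQ file path.
#' @return A data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  if (n %% 4 != 0) {
    stop("truncated FASTQ record at line ", 4 * (n %/% 4) + 1, " of ", path)
  }
  idx <- seq(1, n, by = 4)
  heads <- lines[idx]
  seqs <- lines[idx + 1]
  plus <- lines[idx + 2]
  quals <- lines[idx + 3]
  bad <- !startsWith(heads, "@")
  if (any(bad)) {
    stop("malformed FASTQ header at line ", idx[which(bad)[1]])
  }
  bad <- !startsWith(plus, "+")
  if (any(bad)) {
    stop("malformed FASTQ separator at line ", idx[which(bad)[1]] + 2)
  }
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "sequence/quality length mismatch in record '%s' (line %d)",
      sub("^@", "", heads[i]), idx[i]))
  }
  data.frame(id = sub("^@", "", sub("\\s.*$", "", heads)),
             seq = chartr("Tt", "Uu", toupper(seqs)),
             qual = quals, stringsAsFactors = FALSE)
}

#' Collapse reads into unique tags
#'
#' Tallies identical sequences into one tag each, the "unique reads"
#' versus "total reads" distinction the report tables are built on. The
#' total tag count always equals the number of input reads. Tags are
#' ordered by descending count, ties broken by sequence.
#'
#' @param seqs Character vector of (clean) read sequences, or a
#'   data.frame with a `seq` column as returned by [read_fastq()].
#' @return A data.frame of class `small_read_tags` with columns `seq`,
#'   `count`, `annotation` (initialized to "unannotated").
#' @export
collapse_reads <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  if (length(seqs) == 0) {
    out <- data.frame(seq = character(0), count = integer(0),
                      annotation = character(0), stringsAsFactors = FALSE)
    class(out) <- c("small_read_tags", class(out))
    return(out)
  }
  tab <- table(seqs)
  out <- data.frame(seq = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out$annotation <- "unannotated"
  class(out) <- c("small_read_tags", class(out))
  out
}

#' Read a FASTA file into a named character vector of RNA sequences
#'
#' Thin wrapper over [Biostrings::readBStringSet()]; sequences come back
#' as plain character strings in the internal RNA alphabet.
#'
#' @param path FASTA file path.
#' @param alphabet "rna" (default, T read as U) or "dna".
#' @return Named character vector.
#' @export
read_fasta <- function(path, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  x <- as.character(ss)
  names(x) <- sub("\\s.*$", "", names(ss))
  x <- toupper(x)
  if (alphabet == "rna") chartr("T", "U", x) else chartr("U", "T", x)
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param alphabet "rna" writes U, "dna" back-transposes U to T.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, alphabet = c("rna", "dna"), width = 70L) {
  alphabet <- match.arg(alphabet)
  x <- if (alphabet == "dna") chartr("U", "T", seqs) else chartr("T", "U", seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read genomic region annotation from GFF3
#'
#' Reads exon/intron/intergenic region annotation into a
#' [GenomicRanges::GRanges] with a `region_kind` metadata column. Any
#' feature type other than exon, intron or intergenic is an error.
#'
#' @param path GFF3 file path.
#' @return A `GRanges` of regions (1-based closed coordinates, the
#'   GFF3/Bioconductor convention).
#' @export
read_gff_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(GenomicRanges::GRanges(region_kind = character(0)))
  }
  f <- strsplit(lines, "\t")
  if (any(lengths(f) < 8)) stop("malformed GFF3 line: fewer than 8 fields")
  kind <- vapply(f, `[[`, "", 3)
  bad <- !(kind %in% c("exon", "intron", "intergenic"))
  if (any(bad)) {
    stop("unknown region kind in GFF3: ", kind[which(bad)[1]])
  }
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(f, `[[`, "", 1),
    ranges = IRanges::IRanges(
      start = as.integer(vapply(f, `[[`, "", 4)),
      end = as.integer(vapply(f, `[[`, "", 5))),
    strand = vapply(f, function(x) {
      s <- x[[7]]
      if (s %in% c("+", "-")) s else "*"
    }, ""))
  gr$region_kind <- kind
  gr
}

#' Write a region set back to GFF3
#'
#' @param regions A `GRanges` with a `region_kind` column.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @export
write_gff_regions <- function(regions, path, source = "mirseed") {
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t.",
                   as.character(GenomicRanges::seqnames(regions)),
                   source,
                   regions$region_kind,
                   GenomicRanges::start(regions),
                   GenomicRanges::end(regions),
                   as.character(GenomicRanges::strand(regions)))
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a two-column gene-to-term annotation map
#'
#' Tab-separated, one (gene, term) pair per line. Duplicate pairs are
#' dropped with a warning so repeated reads are idempotent.
#'
#' @param path TSV path.
#' @return A data.frame with columns `gene` and `term`.
#' @export
read_annotation_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("gene", "term"),
                           colClasses = "character", quote = "")
  dup <- duplicated(tab)
  if (any(dup)) {
    warning(sum(dup), " duplicate gene-term pairs dropped from ", path)
    tab <- tab[!dup, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Write a gene-to-term annotation map
#' @param map data.frame with columns `gene`, `term`.
#' @param path Output path.
#' @export
write_annotation_map <- function(map, path) {
  utils::write.table(map[, c("gene", "term")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a FASTQ file
#' @param reads data.frame with `id`, `seq`, `qual` columns.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(rbind(paste0("@", reads$id),
                   chartr("U", "T", reads$seq),
                   "+",
                   reads$qual), con)
  invisible(path)
}
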