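empty_mirna_records <- function() {
  data.frame(id = character(0), mature_seq = character(0),
             star_seq = character(0), precursor_seq = character(0),
             origin = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             arm = character(0), mfe = numeric(0),
             expression_count = integer(0), family_id = character(0),
             stringsAsFactors = FALSE)
}

# Excise candidate precursor windows around a mature locus on one
# chromosome/EST and return the best (lowest-MFE) window passing
# `check`. Extensions are swept over ext_set on each side.
best_precursor_window <- function(chromseq, start, end, strand,
                                  ext_set, check) {
  clen <- nchar(chromseq)
  best <- NULL
  tried <- list()
  for (a in ext_set) {
    for (b in ext_set) {
      ws <- max(1L, start - a)
      we <- min(clen, end + b)
      key <- paste(ws, we)
      if (!is.null(tried[[key]])) next
      tried[[key]] <- TRUE
      win <- substr(chromseq, ws, we)
      if (strand == "-") {
        win <- revcomp_rna(win)
        m1 <- we - end + 1L
      } else {
        m1 <- start - ws + 1L
      }
      m2 <- m1 + (end - start)
      res <- check(win, c(m1, m2))
      if (isTRUE(res$pass)) {
        if (is.null(best) || res$fold$mfe < best$res$fold$mfe) {
          best <- list(res = res, window = win, mature_span = c(m1, m2),
                       win_start = ws, win_end = we)
        }
      }
    }
  }
  best
}

#' Call novel miRNAs from unannotated small-RNA tags
#'
#' Candidate tags (expressed at or above `min_count`, 18-25 nt, mapped
#' to exon-antisense, intron or intergenic space) are tested at each of
#' their genomic loci: precursor windows extending the tag by each pair
#' of flank lengths in `ext_set` are excised on the tag strand, folded,
#' and the candidate accepted when a window satisfies all four precursor
#' rules (single stem-loop; mature/star duplex overhangs at most
#' `max_overhang` nt; no loop or bulge over `max_bulge` nt inside the
#' duplex; fold MFE at or below `max_mfe` kcal/mol). The lowest-MFE
#' passing window becomes the reported precursor. One record is emitted
#' per accepted (tag, locus).
#'
#' @param tags Annotated `small_read_tags`.
#' @param hits Hit table from [map_to_genome()].
#' @param genome Named character vector of chromosome sequences.
#' @param model Energy model for folding.
#' @param min_count Minimum tag copy count for a candidate.
#' @param ext_set Flank extensions (nt) swept on each side of the tag.
#' @param max_overhang,max_bulge,max_mfe Precursor rule thresholds.
#' @param categories Annotation categories eligible for novel calls.
#' @return A `mirna_records` data.frame (one row per call).
#' @export
call_novel_mirnas <- function(tags, hits, genome,
                              model = default_energy_model(),
                              min_count = 5L,
                              ext_set = c(20L, 60L, 100L, 150L),
                              max_overhang = 2L, max_bulge = 4L,
                              max_mfe = -18,
                              categories = c("exon_antisense", "intron",
                                             "intergenic")) {
  gseq <- rna_norm(unname(genome))
  names(gseq) <- names(genome)
  cand <- tags[tags$annotation %in% categories &
                 tags$count >= min_count &
                 nchar(tags$seq) >= 18 & nchar(tags$seq) <= 25, ,
               drop = FALSE]
  out <- empty_mirna_records()
  if (nrow(cand) == 0) return(out)
  check <- function(win, mspan) {
    check_hairpin_candidate(win, mspan, model = model,
                            max_overhang = max_overhang,
                            max_bulge = max_bulge, max_mfe = max_mfe)
  }
  k <- 0L
  for (i in seq_len(nrow(cand))) {
    tag <- cand$seq[i]
    loci <- hits[hits$seq == tag, , drop = FALSE]
    for (j in seq_len(nrow(loci))) {
      best <- best_precursor_window(gseq[[loci$chrom[j]]],
                                    loci$start[j], loci$end[j],
                                    loci$strand[j], ext_set, check)
      if (is.null(best)) next
      k <- k + 1L
      span <- best$res$star_span
      star <- substr(best$window, span[1], span[2])
      out <- rbind(out, data.frame(
        id = sprintf("novel-mir-%d", k),
        mature_seq = tag,
        star_seq = star,
        precursor_seq = best$window,
        origin = "sequencing_novel",
        chrom = loci$chrom[j], start = loci$start[j], end = loci$end[j],
        strand = loci$strand[j],
        arm = best$res$duplex$mature_arm,
        mfe = best$res$fold$mfe,
        expression_count = cand$count[i],
        family_id = NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Collect known miRNAs from annotated tags
#'
#' A tag matching a known miRNA reference is counted by database
#' identity alone, without re-folding: one record per reference miRNA
#' with at least one supporting tag, carrying the summed tag counts.
#'
#' @param tags Annotated `small_read_tags` (category `known_miRNA`).
#' @param known_refs Named character vector of reference mature miRNAs.
#' @return A `mirna_records` data.frame with origin `sequencing_known`.
#' @export
known_mirna_records <- function(tags, known_refs) {
  out <- empty_mirna_records()
  kt <- tags[tags$annotation == "known_miRNA", , drop = FALSE]
  if (nrow(kt) == 0 || length(known_refs) == 0) return(out)
  refs <- rna_norm(unname(known_refs))
  names(refs) <- names(known_refs)
  for (i in seq_along(refs)) {
    sup <- vapply(kt$seq, grepl, logical(1), x = refs[[i]], fixed = TRUE,
                  USE.NAMES = FALSE)
    if (!any(sup)) next
    out <- rbind(out, data.frame(
      id = names(refs)[i], mature_seq = refs[[i]], star_seq = NA_character_,
      precursor_seq = NA_character_, origin = "sequencing_known",
      chrom = NA_character_, start = NA_integer_, end = NA_integer_,
      strand = NA_character_, arm = NA_character_, mfe = NA_real_,
      expression_count = sum(kt$count[sup]), family_id = NA_character_,
      stringsAsFactors = FALSE))
  }
  out
}

#' Identify conserved miRNAs from EST homology
#'
#' Scans each EST (both strands) against each reference mature miRNA
#' for ungapped windows with at most `max_mismatch` sequence mismatches
#' (G:U does not rescue an identity mismatch). A matching window of
#' mature length 18-25 nt becomes a candidate; its EST context is folded
#' over the same flank sweep as novel discovery and the candidate is
#' accepted when the context forms a single stem-loop whose star arm
#' leaves at most `max_star_mismatch` mature positions unpaired, and the
#' window matches no sequence in `exclusion_sets` (rRNA/tRNA and other
#' non-miRNA references).
#'
#' @param ests Named character vector of EST sequences.
#' @param reference_matures Named character vector of reference matures.
#' @param exclusion_sets List of reference sequence vectors a candidate
#'   must not match (substring test).
#' @param model Energy model.
#' @param max_mismatch Maximum sequence mismatches to the reference.
#' @param max_star_mismatch Maximum unpaired mature positions in the
#'   folded precursor duplex.
#' @param len_range Allowed mature length range.
#' @param ext_set Flank sweep for the precursor context.
#' @return A `mirna_records` data.frame with origin `est_conserved`.
#' @export
call_conserved_from_ests <- function(ests, reference_matures,
                                     exclusion_sets = list(),
                                     model = default_energy_model(),
                                     max_mismatch = 3L,
                                     max_star_mismatch = 3L,
                                     len_range = c(18L, 25L),
                                     ext_set = c(20L, 60L, 100L, 150L)) {
  out <- empty_mirna_records()
  if (length(ests) == 0 || length(reference_matures) == 0) return(out)
  ests_rna <- rna_norm(unname(ests))
  names(ests_rna) <- names(ests)
  refs <- rna_norm(unname(reference_matures))
  names(refs) <- names(reference_matures)
  refs <- refs[nchar(refs) >= len_range[1] & nchar(refs) <= len_range[2]]
  excl <- paste(unlist(lapply(exclusion_sets, rna_norm)), collapse = "\n")
  check <- function(win, mspan) {
    res <- check_hairpin_candidate(win, mspan, model = model,
                                   max_overhang = .Machine$integer.max,
                                   max_bulge = .Machine$integer.max,
                                   max_mfe = Inf)
    if (!res$stem_loop || is.null(res$star_span)) {
      res$pass <- FALSE
      return(res)
    }
    unpaired <- sum(res$fold$pairing[mspan[1]:mspan[2]] == 0)
    res$pass <- unpaired <= max_star_mismatch
    res
  }
  seen <- character(0)
  for (ref_i in seq_along(refs)) {
    ref <- refs[[ref_i]]
    L <- nchar(ref)
    probe <- encode_rna(revcomp_rna(ref))  # identity scan via complement scan
    for (est_i in seq_along(ests_rna)) {
      for (strand in c("+", "-")) {
        est <- ests_rna[[est_i]]
        if (strand == "-") est <- revcomp_rna(est)
        if (nchar(est) < L) next
        sc <- scan_windows_cpp(probe, encode_rna(est),
                               unname(model$stack), model$pair_bonus,
                               as.integer(max_mismatch))
        for (w in sc$start) {
          window_seq <- substr(est, w, w + L - 1L)
          key <- paste(names(ests_rna)[est_i], strand, w)
          if (key %in% seen) next
          if (nchar(excl) > 0 && grepl(window_seq, excl, fixed = TRUE)) next
          best <- best_precursor_window(est, w, w + L - 1L, "+",
                                        ext_set, check)
          if (is.null(best)) next
          seen <- c(seen, key)
          span <- best$res$star_span
          out <- rbind(out, data.frame(
            id = sprintf("est-%s-%s", names(refs)[ref_i],
                         names(ests_rna)[est_i]),
            mature_seq = window_seq,
            star_seq = substr(best$window, span[1], span[2]),
            precursor_seq = best$window,
            origin = "est_conserved",
            chrom = names(ests_rna)[est_i],
            start = w, end = w + L - 1L, strand = strand,
            arm = best$res$duplex$mature_arm,
            mfe = best$res$fold$mfe,
            expression_count = NA_integer_,
            family_id = NA_character_,
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  # one call per mature sequence; keep the lowest-MFE context
  if (nrow(out) > 1) {
    out <- out[order(out$mature_seq, out$mfe), , drop = FALSE]
    out <- out[!duplicated(out$mature_seq), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Summarize a miRNA call set
#'
#' @param records A `mirna_records` data.frame (rows may come from any
#'   mix of [call_novel_mirnas()], [known_mirna_records()] and
#'   [call_conserved_from_ests()]).
#' @return A list: `by_origin` (counts per origin), `total`,
#'   `conserved` (sequencing-known plus EST-conserved), and
#'   `length_histogram` of mature lengths.
#' @export
summarize_discovery <- function(records) {
  origins <- c("sequencing_known", "est_conserved", "sequencing_novel")
  by_origin <- vapply(origins, function(o) sum(records$origin == o),
                      integer(1))
  lens <- table(nchar(records$mature_seq))
  list(by_origin = by_origin,
       total = nrow(records),
       conserved = unname(by_origin["sequencing_known"] +
                            by_origin["est_conserved"]),
       length_histogram = data.frame(
         length = as.integer(names(lens)),
         count = as.integer(lens)))
}
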