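target_rules_default <- function() {
  list(max_mismatches = 4L,      # rule i, whole duplex
       max_mm_1_9 = 1L,          # rule i, positions 1-9
       perfect_10_11 = TRUE,     # rule i, positions 10-11
       perfect_8_12 = TRUE,      # rule iii, central perfect duplex
       max_overhang = 1L,        # rule v
       max_energy = -18,         # rule vi, strict inequality
       gu_counts_as_half_mismatch = FALSE)
}

# profile: character vector over miRNA positions 1..L, values
# "M" (Watson-Crick), "G" (G:U wobble), "m" (mismatch)
profile_mismatch_weight <- function(prof, gu_half) {
  ifelse(prof == "M", 0, ifelse(prof == "G" & gu_half, 0.5, 1))
}

evaluate_target_rules <- function(prof, energy, rules, relaxed = FALSE) {
  w <- profile_mismatch_weight(prof, rules$gu_counts_as_half_mismatch)
  L <- length(prof)
  ok <- sum(w) <= rules$max_mismatches &&
    sum(w[1:min(9, L)]) <= rules$max_mm_1_9
  if (ok && rules$perfect_10_11 && L >= 11) {
    ok <- all(prof[10:11] == "M")
  }
  if (ok && !relaxed && rules$perfect_8_12 && L >= 12) {
    ok <- all(prof[8:12] == "M")
  }
  # rule v: the ungapped site window equals the miRNA length, so no
  # terminal nucleotide is left unaligned and the overhang bound holds
  # by construction (kept configurable for non-flush scanners)
  ok && energy < rules$max_energy
}

#' Scan transcripts for miRNA target sites
#'
#' Ungapped antiparallel scan of one miRNA against a transcript set
#' (sense orientation). Every window of miRNA length is evaluated
#' against the positional rules: at most 4 weighted mismatches overall
#' and at most 1 in positions 1-9; positions 10-11 perfectly matched;
#' a perfect duplex across positions 8-12; no insertions or deletions
#' (enforced by the gap-free scan); terminal overhangs of at most 1 nt
#' (0 by construction here); and hybridization energy below -18
#' kcal/mol. G:U wobble counts as a full mismatch for the positional
#' rules (or half with `gu_counts_as_half_mismatch`) while still
#' contributing pairing energy. Positions are numbered from the miRNA
#' 5' end.
#'
#' With `relaxed = TRUE` the central-perfection rule (positions 8-12) is
#' dropped; the relaxed scan is the substrate for translational
#' inhibition classification.
#'
#' @param mirnas Named character vector of mature miRNA sequences (or a
#'   `mirna_records` data.frame).
#' @param transcripts Named character vector of transcript sequences.
#' @param model Energy model for the duplex energy.
#' @param rules Rule thresholds, see `target_rules_default()` values in
#'   the description.
#' @param relaxed Drop the central-perfection rule.
#' @return data.frame of class `target_sites`: `mirna_id`,
#'   `transcript_id`, `start`, `end` (site span on the transcript),
#'   `profile` (per-position M/G/m string over miRNA positions 1..L),
#'   `total_mismatches`, `duplex_mfe`, `mode`.
#' @export
scan_targets <- function(mirnas, transcripts,
                         model = default_energy_model(),
                         rules = target_rules_default(),
                         relaxed = FALSE) {
  if (is.data.frame(mirnas)) {
    mi <- mirnas$mature_seq
    names(mi) <- mirnas$id
  } else {
    mi <- mirnas
    if (is.null(names(mi))) names(mi) <- paste0("mir", seq_along(mi))
  }
  mi <- rna_norm(mi)
  tx <- rna_norm(unname(transcripts))
  names(tx) <- names(transcripts)
  stack <- unname(model$stack)
  prefilter <- max(rules$max_mismatches + 2L, 6L)
  res <- list()
  for (i in seq_along(mi)) {
    mcode <- encode_rna(mi[[i]])
    for (j in seq_along(tx)) {
      if (nchar(tx[[j]]) < length(mcode)) next
      sc <- scan_windows_cpp(mcode, encode_rna(tx[[j]]), stack,
                             model$pair_bonus, as.integer(prefilter))
      if (length(sc$start) == 0) next
      for (k in seq_along(sc$start)) {
        prof <- strsplit(sc$profile[k], "")[[1]]
        if (!evaluate_target_rules(prof, sc$energy[k], rules, relaxed)) next
        res[[length(res) + 1]] <- data.frame(
          mirna_id = names(mi)[i],
          transcript_id = names(tx)[j],
          start = sc$start[k],
          end = sc$start[k] + length(mcode) - 1L,
          profile = sc$profile[k],
          total_mismatches = sum(prof != "M"),
          duplex_mfe = sc$energy[k],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(mirna_id = character(0), transcript_id = character(0),
               start = integer(0), end = integer(0), profile = character(0),
               total_mismatches = integer(0), duplex_mfe = numeric(0),
               stringsAsFactors = FALSE)
  out$mode <- vapply(out$profile, classify_mode, character(1),
                     USE.NAMES = FALSE)
  class(out) <- c("target_sites", class(out))
  out
}

#' Classify the regulation mode of a target site
#'
#' Translational inhibition is called when the central complementary
#' region of the miRNA (positions 9-11 from the 5' end) holds at least
#' one non-Watson-Crick column; otherwise the site is a cleavage site.
#' Run on relaxed-scan sites: the strict rule set forbids central
#' mismatches, so strict sites are cleavage by construction.
#'
#' @param profile Per-position profile string (M/G/m) over miRNA
#'   positions, or a one-row `target_sites` entry's `profile`.
#' @return "cleavage" or "translational_inhibition".
#' @export
classify_mode <- function(profile) {
  prof <- strsplit(profile, "")[[1]]
  hi <- min(11L, length(prof))
  if (hi >= 9L && any(prof[9:hi] != "M")) "translational_inhibition"
  else "cleavage"
}

#' Summarize predicted target sites
#'
#' Distinct-count accounting of a site table: miRNAs with at least one
#' site, distinct target genes, distinct miRNA::gene pairs, and total
#' site count, overall and per origin group when provided.
#'
#' @param sites A `target_sites` data.frame.
#' @param origins Optional named character vector mirna_id -> origin
#'   group (e.g. "conserved" / "novel") to add per-group rows.
#' @return data.frame with columns `group`, `n_mirnas`, `n_genes`,
#'   `n_pairs`, `n_sites`.
#' @export
target_summary <- function(sites, origins = NULL) {
  count_block <- function(s, label) {
    data.frame(group = label,
               n_mirnas = length(unique(s$mirna_id)),
               n_genes = length(unique(s$transcript_id)),
               n_pairs = nrow(unique(s[, c("mirna_id", "transcript_id")])),
               n_sites = nrow(s),
               stringsAsFactors = FALSE)
  }
  out <- list()
  if (!is.null(origins)) {
    for (g in unique(origins[sites$mirna_id])) {
      sel <- origins[sites$mirna_id] == g
      out[[length(out) + 1]] <- count_block(sites[sel, , drop = FALSE], g)
    }
  }
  out[[length(out) + 1]] <- count_block(sites, "total")
  do.call(rbind, out)
}
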