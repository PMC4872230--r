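#' Fold an RNA sequence into its minimum-free-energy secondary structure
#'
#' Dynamic-programming minimization over nested (pseudoknot-free)
#' structures under a nearest-neighbor energy model. Helices must hold at
#' least `model$min_helix` stacked pairs (lone pairs are disallowed by
#' default), hairpin loops at least `model$min_hairpin` unpaired bases,
#' and G:U wobbles pair. The empty structure scores 0, so the reported
#' MFE is never positive. Ties are broken deterministically by a fixed
#' traceback order, so identical input always yields the identical
#' structure string.
#'
#' @param sequence RNA string over A/C/G/U (T is accepted and read as U).
#' @param model An `rna_energy_model`, by default [default_energy_model()].
#' @return A list of class `fold_result`: `sequence`, `structure`
#'   (dot-bracket), `mfe` (kcal/mol, <= 0), and `pairing` (integer vector,
#'   1-based partner per position, 0 = unpaired).
#' @export
#' @examples
#' fold_mfe("GGGGAAAACCCC")
fold_mfe <- function(sequence, model = default_energy_model()) {
  sequence <- rna_norm(sequence)
  n <- nchar(sequence)
  if (n < 10 || n > 1000) {
    stop("fold_mfe expects sequences of 10 to 1000 nt, got ", n)
  }
  res <- fold_mfe_cpp(encode_rna(sequence), model_params(model))
  structure(list(sequence = sequence,
                 structure = res$structure,
                 mfe = res$mfe,
                 pairing = res$pairing),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "\n", sep = "")
  cat(sprintf("MFE: %.2f kcal/mol\n", x$mfe))
  invisible(x)
}

#' Test whether a fold is a single stem-loop
#'
#' A precursor qualifies as a "perfect stem-loop" when its MFE structure
#' contains exactly one terminal hairpin loop: no multibranch loop and no
#' second independent hairpin. Bulges and internal loops along the stem
#' are permitted (they are judged separately by the duplex rules).
#'
#' @param fold A `fold_result`.
#' @return A list: `is_stem_loop` (logical) and `hairpin_span`, the
#'   1-based range from the first to the last paired base (NULL when the
#'   structure has no pairs or more than one hairpin).
#' @export
is_stem_loop <- function(fold) {
  stopifnot(inherits(fold, "fold_result"))
  db <- fold$structure
  hits <- gregexpr("\\(\\.*\\)", db)[[1]]
  n_hairpins <- if (hits[1] == -1) 0L else length(hits)
  if (n_hairpins != 1L) {
    return(list(is_stem_loop = FALSE, hairpin_span = NULL))
  }
  paired <- which(fold$pairing > 0)
  list(is_stem_loop = TRUE, hairpin_span = c(min(paired), max(paired)))
}

#' Duplex geometry of a miRNA/miRNA* pair inside a folded precursor
#'
#' Measures the geometry the precursor rules are stated on: terminal
#' overhangs at the two duplex ends and unpaired runs (bulges/internal
#' loops) interior to the duplex. An overhang at one duplex end is the
#' longest run of terminal bases on either strand without a partner on
#' the other strand; `overhang_5p` refers to the mature 5' end of the
#' duplex, `overhang_3p` to the mature 3' end.
#'
#' @param fold A `fold_result` for the precursor.
#' @param mature_span Integer c(start, end), 1-based, of the mature arm.
#' @param star_span Integer c(start, end) of the star arm. Must not
#'   overlap the mature span.
#' @return A list of class `duplex_metrics`: `mature_arm` ("5p"/"3p"),
#'   `overhang_5p`, `overhang_3p`, `max_bulge`, `loop_count_in_duplex`,
#'   `paired_fraction`.
#' @export
extract_duplex <- function(fold, mature_span, star_span) {
  stopifnot(inherits(fold, "fold_result"))
  m1 <- mature_span[1]; m2 <- mature_span[2]
  s1 <- star_span[1]; s2 <- star_span[2]
  if (max(m1, s1) <= min(m2, s2)) stop("mature and star spans overlap")
  pr <- fold$pairing
  mpos <- m1:m2
  spos <- s1:s2
  m_in <- pr[mpos] >= s1 & pr[mpos] <= s2   # mature bases paired into star
  s_in <- pr[spos] >= m1 & pr[spos] <= m2
  n_m <- sum(m_in); n_s <- sum(s_in)
  if (n_m == 0L || n_s == 0L) {
    return(structure(list(mature_arm = if (m1 < s1) "5p" else "3p",
                          overhang_5p = length(mpos), overhang_3p = length(mpos),
                          max_bulge = 0L, loop_count_in_duplex = 0L,
                          paired_fraction = 0),
                     class = "duplex_metrics"))
  }
  fm <- mpos[which(m_in)[1]]; lm <- mpos[rev(which(m_in))[1]]
  fs <- spos[which(s_in)[1]]; ls <- spos[rev(which(s_in))[1]]
  # in either orientation the mature 5' end faces the star 3' end
  overhang_5p <- max(fm - m1, s2 - ls)
  overhang_3p <- max(m2 - lm, fs - s1)
  runs <- function(flags) {
    r <- rle(flags)
    r$lengths[!r$values]
  }
  interior_m <- m_in[mpos >= fm & mpos <= lm]
  interior_s <- s_in[spos >= fs & spos <= ls]
  bulges <- c(runs(interior_m), runs(interior_s))
  structure(list(
    mature_arm = if (m1 < s1) "5p" else "3p",
    overhang_5p = as.integer(overhang_5p),
    overhang_3p = as.integer(overhang_3p),
    max_bulge = if (length(bulges)) as.integer(max(bulges)) else 0L,
    loop_count_in_duplex = length(bulges),
    paired_fraction = (n_m + n_s) / (length(mpos) + length(spos))
  ), class = "duplex_metrics")
}

#' Hybridization energy of an ungapped miRNA:target duplex
#'
#' Scores the antiparallel, gap-free duplex between a miRNA and an
#' equal-length target site under the same nearest-neighbor stack table
#' as [fold_mfe()]: adjacent paired columns contribute their stacking
#' energy, G:U wobbles pair, and unpaired (mismatch) columns contribute
#' nothing, so an all-mismatch alignment scores 0.
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param target_site Target-site sequence, 5' to 3', same length.
#' @param model An `rna_energy_model`.
#' @return Energy in kcal/mol (<= 0 under the default table).
#' @export
duplex_energy <- function(mirna, target_site, model = default_energy_model()) {
  mirna <- rna_norm(mirna, "miRNA")
  target_site <- rna_norm(target_site, "target site")
  if (nchar(mirna) != nchar(target_site)) {
    stop("miRNA and target site must have equal length for an ungapped duplex")
  }
  duplex_energy_cpp(encode_rna(mirna), encode_rna(target_site),
                    unname(model$stack), model$pair_bonus)
}

#' Evaluate a candidate precursor against the hairpin rules
#'
#' Applies the four precursor criteria used for novel miRNA calls:
#' (i) the window folds into a single stem-loop; (ii) the mature/star
#' duplex has terminal overhangs of at most `max_overhang` nt; (iii) no
#' unpaired run larger than `max_bulge` nt lies inside the duplex; and
#' (iv) the fold MFE is at or below `max_mfe` kcal/mol. The star arm is
#' derived computationally as the pairing-partner range of the mature
#' positions; an observed star read is not required.
#'
#' @param window Precursor window sequence (RNA).
#' @param mature_span 1-based span of the mature sequence inside `window`.
#' @param model Energy model.
#' @param max_overhang,max_bulge,max_mfe Rule thresholds (nt, nt, kcal/mol).
#' @return A list: `pass` plus per-criterion flags, the `fold`, the
#'   derived `star_span`, and the `duplex` metrics (NULL when no star
#'   arm exists).
#' @export
check_hairpin_candidate <- function(window, mature_span,
                                    model = default_energy_model(),
                                    max_overhang = 2L, max_bulge = 4L,
                                    max_mfe = -18) {
  fold <- fold_mfe(window, model)
  sl <- is_stem_loop(fold)
  out <- list(pass = FALSE, stem_loop = sl$is_stem_loop,
              overhang_ok = FALSE, bulge_ok = FALSE,
              mfe_ok = fold$mfe <= max_mfe,
              fold = fold, star_span = NULL, duplex = NULL)
  if (!sl$is_stem_loop) return(out)
  m1 <- mature_span[1]; m2 <- mature_span[2]
  partners <- fold$pairing[m1:m2]
  partners <- partners[partners > 0]
  # the star arm must lie entirely on one side of the mature
  if (length(partners) == 0L ||
      !(all(partners > m2) || all(partners < m1))) {
    return(out)
  }
  star_span <- c(min(partners), max(partners))
  dup <- extract_duplex(fold, mature_span, star_span)
  out$star_span <- star_span
  out$duplex <- dup
  out$overhang_ok <- dup$overhang_5p <= max_overhang &&
    dup$overhang_3p <= max_overhang
  out$bulge_ok <- dup$max_bulge <= max_bulge
  out$pass <- out$stem_loop && out$overhang_ok && out$bulge_ok && out$mfe_ok
  out
}
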