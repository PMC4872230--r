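#' Run the full analysis pipeline on a simulated study
#'
#' Chains every stage on in-memory simulation output: clean-read
#' filtering, tag collapsing, exact genome mapping, annotation triage,
#' novel and known miRNA calling, EST-homology conserved miRNA calling,
#' family clustering, strict and relaxed target scans, GO/KEGG
#' enrichment of the predicted target genes, and network construction.
#' Novel calls are deduplicated to one record per mature sequence
#' (lowest precursor MFE) before summarization.
#'
#' @param sim Output of [simulate_study()].
#' @param model Energy model.
#' @param min_count Minimum tag count for novel calls.
#' @return A list with each stage's output: `filter`, `tags`, `hits`,
#'   `mapping`, `mirnas` (combined records), `discovery_summary`,
#'   `families`, `sites_strict`, `sites_relaxed`, `target_summary`,
#'   `go_enrichment`, `kegg_enrichment`, `network`, `network_stats`.
#' @export
run_synthetic_pipeline <- function(sim, model = default_energy_model(),
                                   min_count = 5L) {
  filt <- filter_clean_reads(sim$reads,
                             adapter3 = sim$config$adapter3,
                             adapter5 = sim$config$adapter5)
  tags <- collapse_reads(filt$clean)
  hits <- map_to_genome(tags, sim$genome)
  refs <- c(list(known_miRNA = c(sim$known_refs, sim$extra_refs)),
            sim$decoys)
  tags <- annotate_tags(tags, refs, hits, sim$regions)
  mapping <- summarize_mapping(tags, hits)

  novel <- call_novel_mirnas(tags, hits, sim$genome, model = model,
                             min_count = min_count)
  if (nrow(novel) > 1) {
    novel <- novel[order(novel$mature_seq, novel$mfe), , drop = FALSE]
    novel_all <- novel
    novel <- novel[!duplicated(novel$mature_seq), , drop = FALSE]
  } else {
    novel_all <- novel
  }
  known <- known_mirna_records(tags, sim$known_refs)
  est <- call_conserved_from_ests(
    sim$ests, c(sim$known_refs, sim$extra_refs),
    exclusion_sets = sim$decoys, model = model)
  mirnas <- rbind(known, est, novel)
  fams <- if (nrow(mirnas) >= 1) cluster_families(mirnas) else NULL
  if (!is.null(fams)) {
    mirnas$family_id <- fams$membership$family_id[
      match(mirnas$id, fams$membership$id)]
  }

  sites_strict <- scan_targets(mirnas, sim$transcripts, model = model)
  sites_relaxed <- scan_targets(mirnas, sim$transcripts, model = model,
                                relaxed = TRUE)
  origin_group <- stats::setNames(
    ifelse(mirnas$origin == "sequencing_novel", "novel", "conserved"),
    mirnas$id)
  tsum <- target_summary(sites_strict, origin_group)

  candidates <- unique(c(sites_strict$transcript_id,
                         sites_relaxed$transcript_id))
  go_candidates <- intersect(candidates, unique(sim$go_map$gene))
  go_enr <- enrich(sim$go_map, go_candidates, method = "bonferroni")
  ko_candidates <- intersect(candidates, unique(sim$ko_map$gene))
  ko_enr <- enrich(sim$ko_map, ko_candidates, method = "BH")

  net <- build_network(sites_relaxed)
  list(filter = filt$report, tags = tags, hits = hits, mapping = mapping,
       mirnas = mirnas,
       novel_all_loci = novel_all,
       discovery_summary = summarize_discovery(mirnas),
       families = fams,
       sites_strict = sites_strict, sites_relaxed = sites_relaxed,
       target_summary = tsum,
       go_enrichment = go_enr, kegg_enrichment = ko_enr,
       network = net, network_stats = network_stats(net))
}

#' Evaluate pipeline calls against planted truth
#'
#' Sensitivity: fraction of planted novel hairpins recovered by a novel
#' call with the same mature sequence overlapping the planted precursor
#' locus. Precision: fraction of novel calls (all loci) overlapping any
#' planted precursor with a matching mature sequence.
#'
#' @param pipeline Output of [run_synthetic_pipeline()].
#' @param sim The simulation it ran on.
#' @return A list: `sensitivity`, `precision`, `n_planted`, `n_called`.
#' @export
evaluate_discovery <- function(pipeline, sim) {
  truth <- sim$hairpins
  calls <- pipeline$novel_all_loci
  planted_novel <- truth[truth$origin == "novel", , drop = FALSE]
  hit_truth <- vapply(seq_len(nrow(planted_novel)), function(i) {
    any(calls$mature_seq == planted_novel$mature_seq[i] &
          calls$chrom == planted_novel$chrom[i] &
          calls$start <= planted_novel$precursor_end[i] &
          calls$end >= planted_novel$precursor_start[i])
  }, logical(1))
  call_true <- vapply(seq_len(nrow(calls)), function(i) {
    any(truth$mature_seq == calls$mature_seq[i] &
          truth$chrom == calls$chrom[i] &
          truth$precursor_start <= calls$end[i] &
          truth$precursor_end >= calls$start[i])
  }, logical(1))
  list(sensitivity = mean(hit_truth),
       precision = if (nrow(calls)) mean(call_true) else NA_real_,
       n_planted = nrow(planted_novel),
       n_called = nrow(calls))
}
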