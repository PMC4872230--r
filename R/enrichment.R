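#' Hypergeometric upper-tail probability for term enrichment
#'
#' P(X >= m) where X counts term-annotated genes among n candidates
#' drawn without replacement from N annotated background genes of which
#' M carry the term. The boundary is inclusive, so m = 0 gives 1.
#'
#' @param N Annotated background genes.
#' @param M Background genes assigned to the term.
#' @param n Candidate genes (within N).
#' @param m Candidate genes assigned to the term.
#' @return Upper-tail probability.
#' @export
#' @examples
#' hypergeom_upper_tail(N = 10, M = 4, n = 5, m = 3)
hypergeom_upper_tail <- function(N, M, n, m) {
  if (any(c(N, M, n, m) < 0) || M > N || n > N || m > min(n, M)) {
    stop("invalid hypergeometric configuration: need 0 <= m <= min(n, M), M <= N, n <= N")
  }
  stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Term enrichment of a candidate gene set
#'
#' Hypergeometric upper-tail test per term, restricted to terms with at
#' least one candidate gene, with Bonferroni (family-wise) or
#' Benjamini-Hochberg (FDR) correction over the tested terms. The
#' background N is the number of genes carrying at least one annotation
#' in the supplied map.
#'
#' @param map Annotation map data.frame (`gene`, `term`), as from
#'   [read_annotation_map()].
#' @param candidates Character vector of candidate gene ids; must be a
#'   subset of the annotated background.
#' @param method "bonferroni" or "BH".
#' @param alpha Significance level on the adjusted p-value.
#' @return data.frame of class `enrichment_result`, one row per tested
#'   term: `term`, `N`, `n`, `M`, `m`, `p_raw`, `p_adjusted`,
#'   `significant`, sorted by adjusted then raw p then term.
#' @export
enrich <- function(map, candidates, method = c("bonferroni", "BH"),
                   alpha = 0.05) {
  method <- match.arg(method)
  background <- unique(map$gene)
  N <- length(background)
  missing <- setdiff(candidates, background)
  if (length(missing) > 0) {
    stop("candidate genes missing from the annotated background: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  candidates <- unique(candidates)
  n <- length(candidates)
  terms <- split(unique(map)[, "gene"], unique(map)[, "term"])
  rows <- lapply(names(terms), function(tm) {
    genes <- unique(terms[[tm]])
    m <- sum(candidates %in% genes)
    if (m == 0) return(NULL)  # untestable; excluded from the correction
    data.frame(term = tm, N = N, n = n, M = length(genes), m = m,
               p_raw = hypergeom_upper_tail(N, length(genes), n, m),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(term = character(0), N = integer(0), n = integer(0),
                      M = integer(0), m = integer(0), p_raw = numeric(0),
                      p_adjusted = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", class(out))
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = method)
  out$significant <- out$p_adjusted <= alpha
  out <- out[order(out$p_adjusted, out$p_raw, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Classify genes into GO categories
#'
#' Counts how many of the given genes carry at least one term in each
#' ontology category (biological process, cellular component, molecular
#' function). A gene with terms in several categories counts once in
#' each.
#'
#' @param map Annotation map data.frame (`gene`, `term`).
#' @param ontology Named character vector term -> category
#'   ("BP", "CC" or "MF").
#' @param genes Genes to classify (default: all genes in the map).
#' @return data.frame `category`, `n_genes`.
#' @export
classify_go <- function(map, ontology, genes = unique(map$gene)) {
  cats <- c("BP", "CC", "MF")
  sub <- map[map$gene %in% genes, , drop = FALSE]
  sub$category <- unname(ontology[sub$term])
  counts <- vapply(cats, function(cc) {
    length(unique(sub$gene[!is.na(sub$category) & sub$category == cc]))
  }, integer(1))
  data.frame(category = cats, n_genes = counts, stringsAsFactors = FALSE)
}

#' Validation-rate percentage
#'
#' The detected-over-tested success rate as a percentage, rounded
#' half-up to one decimal (the convention of the validation summary:
#' 3 of 4 gives 75, 18 of 19 gives 94.7).
#'
#' @param detected Number of positives.
#' @param tested Number assayed.
#' @return Percentage.
#' @export
validation_rate <- function(detected, tested) {
  stopifnot(tested > 0, detected >= 0, detected <= tested)
  round_half_up(100 * detected / tested, 1)
}
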