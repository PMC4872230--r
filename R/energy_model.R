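#' RNA nearest-neighbor energy models
#'
#' The folding engine evaluates secondary structures under a simplified
#' nearest-neighbor model: Watson-Crick and G:U stacks contribute the
#' tabulated stacking free energies, while hairpin, bulge, internal and
#' multibranch loops pay length-dependent penalties. All values are in
#' kcal/mol. The whole model travels as a plain list, so an alternative
#' parameterization (or a trivial per-pair scoring scheme) can be plugged
#' into every structure-based rule.
#'
#' @param stack_file Path to a TSV stacking-energy table with pair types
#'   AU, UA, CG, GC, GU, UG as both row and column labels. Rows are the
#'   outer (closing) pair, columns the next pair inward.
#' @return A list of class `rna_energy_model` holding the 6x6 stack
#'   matrix, loop penalty coefficients, the per-pair bonus, and the
#'   structural constraints (`min_helix`, `min_hairpin`, `max_internal`).
#' @details Default loop penalties: hairpin `5.0 + 0.3 * (len - 3)`,
#'   bulge `3.0 + 0.5 * len`, internal `2.0 + 0.4 * len`, multibranch
#'   `4.6 + 0.9 * branches + 0.1 * unpaired`. Lone pairs are disallowed
#'   (`min_helix = 2`), hairpin loops hold at least 3 nt, and internal
#'   loops are capped at 30 unpaired nt.
#' @export
#' @examples
#' mod <- default_energy_model()
#' fold_mfe("GGGGAAAACCCC", mod)$mfe
default_energy_model <- function(stack_file = NULL) {
  if (is.null(stack_file)) {
    stack_file <- system.file("extdata", "stack_energies.tsv",
                              package = "mirseed", mustWork = TRUE)
  }
  tab <- utils::read.table(stack_file, header = TRUE, sep = "\t",
                           row.names = 1, check.names = FALSE)
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  if (!identical(rownames(tab), pairs) || !identical(colnames(tab), pairs)) {
    stop("stack table must have rows/columns AU, UA, CG, GC, GU, UG in order")
  }
  structure(list(
    stack = as.matrix(tab),
    hairpin_a = 5.0, hairpin_b = 0.3,
    bulge_a = 3.0, bulge_b = 0.5,
    internal_a = 2.0, internal_b = 0.4,
    ml_init = 4.6, ml_branch = 0.9, ml_unpaired = 0.1,
    pair_bonus = 0.0,
    min_helix = 2L, min_hairpin = 3L, max_internal = 30L
  ), class = "rna_energy_model")
}

#' Unit-score energy model
#'
#' A degenerate model scoring -1 per base pair with no stacking terms, no
#' loop penalties and lone pairs allowed. Under this model the minimum
#' "energy" equals minus the maximum number of nested pairs, i.e. folding
#' reduces to Nussinov base-pair maximization (with the same minimum
#' hairpin loop of 3 nt). Used to cross-check the dynamic program.
#'
#' @return An `rna_energy_model` list.
#' @export
unit_energy_model <- function() {
  structure(list(
    stack = matrix(0, 6, 6, dimnames = list(
      c("AU", "UA", "CG", "GC", "GU", "UG"),
      c("AU", "UA", "CG", "GC", "GU", "UG"))),
    hairpin_a = 0, hairpin_b = 0,
    bulge_a = 0, bulge_b = 0,
    internal_a = 0, internal_b = 0,
    ml_init = 0, ml_branch = 0, ml_unpaired = 0,
    pair_bonus = -1.0,
    min_helix = 1L, min_hairpin = 3L, max_internal = 30L
  ), class = "rna_energy_model")
}

# internal: model list -> the flat parameter list the C++ engine expects
model_params <- function(model) {
  stopifnot(inherits(model, "rna_energy_model"))
  list(stack = unname(model$stack),
       hairpin_a = model$hairpin_a, hairpin_b = model$hairpin_b,
       bulge_a = model$bulge_a, bulge_b = model$bulge_b,
       internal_a = model$internal_a, internal_b = model$internal_b,
       ml_init = model$ml_init, ml_branch = model$ml_branch,
       ml_unpaired = model$ml_unpaired,
       pair_bonus = model$pair_bonus,
       min_helix = model$min_helix, min_hairpin = model$min_hairpin,
       max_internal = model$max_internal)
}
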