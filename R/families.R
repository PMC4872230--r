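#' Pairwise identity between two miRNA sequences
#'
#' Global end-free ungapped alignment: every relative offset of the two
#' sequences is scanned, the offset maximizing the number of matching
#' columns wins (ties broken toward the longer overlap, then the smaller
#' shift). Identity is matches over aligned columns; mismatches are the
#' non-matching aligned columns.
#'
#' @param a,b RNA sequences.
#' @return A list: `identity`, `mismatches`, `matches`, `aligned`.
#' @export
#' @examples
#' pairwise_identity("ACGUACGUACGUACGUACGUA", "ACGUACGUACGUACGUACGUA")
pairwise_identity <- function(a, b) {
  a <- strsplit(rna_norm(a), "")[[1]]
  b <- strsplit(rna_norm(b), "")[[1]]
  la <- length(a); lb <- length(b)
  best <- list(matches = -1L, aligned = 0L)
  for (off in seq(-(lb - 1L), la - 1L)) {
    ia <- max(1L, 1L + off):min(la, lb + off)
    ib <- ia - off
    m <- sum(a[ia] == b[ib])
    al <- length(ia)
    if (m > best$matches || (m == best$matches && al > best$aligned)) {
      best <- list(matches = m, aligned = al)
    }
  }
  list(identity = best$matches / best$aligned,
       mismatches = best$aligned - best$matches,
       matches = best$matches,
       aligned = best$aligned)
}

#' Cluster miRNAs into families
#'
#' Two miRNAs belong together when their best ungapped alignment reaches
#' at least `min_identity` identity with at most `max_mismatches`
#' mismatching columns; families are the connected components of this
#' relation (single linkage). Family ids are the lexicographically
#' smallest member id, so the partition is independent of input order.
#'
#' @param mirnas A `mirna_records` data.frame, or a named character
#'   vector of mature sequences.
#' @param min_identity Identity threshold (fraction).
#' @param max_mismatches Mismatch-count threshold.
#' @return A list of class `family_assignment`: `membership` (data.frame
#'   `id`, `seq`, `family_id`), `families` (list of member ids),
#'   `sizes`.
#' @export
cluster_families <- function(mirnas, min_identity = 0.98,
                             max_mismatches = 2L) {
  if (is.data.frame(mirnas)) {
    ids <- mirnas$id
    seqs <- mirnas$mature_seq
  } else {
    ids <- names(mirnas)
    if (is.null(ids)) ids <- paste0("mir", seq_along(mirnas))
    seqs <- unname(mirnas)
  }
  seqs <- rna_norm(seqs)
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        pi <- find(i); pj <- find(j)
        if (pi == pj) next
        pid <- pairwise_identity(seqs[i], seqs[j])
        if (pid$identity >= min_identity &&
            pid$mismatches <= max_mismatches) {
          parent[pj] <- pi
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  fam_of <- character(n)
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    fam_of[members] <- min(ids[members])
  }
  membership <- data.frame(id = ids, seq = seqs, family_id = fam_of,
                           stringsAsFactors = FALSE)
  fams <- split(membership$id, membership$family_id)
  structure(list(membership = membership,
                 families = fams,
                 sizes = lengths(fams)),
            class = "family_assignment")
}

#' Family-size summary table
#'
#' Tallies families by member count, with the share of all families that
#' each (size, origin composition) accounts for.
#'
#' @param assignment A `family_assignment`.
#' @param origins Optional named character vector id -> origin, used to
#'   split the percentage columns into conserved and novel families (a
#'   family counts as novel when all members are sequencing-novel).
#' @return data.frame `size`, `n_families`, and optionally
#'   `percent_conserved`, `percent_novel` (of all families, 2 decimals).
#' @export
family_size_table <- function(assignment, origins = NULL) {
  sizes <- assignment$sizes
  tab <- table(sizes)
  out <- data.frame(size = as.integer(names(tab)),
                    n_families = as.integer(tab))
  if (!is.null(origins)) {
    is_novel <- vapply(assignment$families, function(m) {
      all(origins[m] == "sequencing_novel")
    }, logical(1))
    nf <- length(sizes)
    out$percent_conserved <- vapply(out$size, function(s) {
      pct(sum(sizes == s & !is_novel), nf)
    }, numeric(1))
    out$percent_novel <- vapply(out$size, function(s) {
      pct(sum(sizes == s & is_novel), nf)
    }, numeric(1))
  }
  out
}

#' Pairwise p-distance matrix from mature sequences
#'
#' Distance is 1 - identity of the offset-optimal ungapped alignment of
#' [pairwise_identity()].
#'
#' @param seqs Named character vector of sequences.
#' @return Square symmetric numeric matrix with zero diagonal.
#' @export
mirna_distance_matrix <- function(seqs) {
  n <- length(seqs)
  labels <- names(seqs)
  if (is.null(labels)) labels <- paste0("mir", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- 1 - pairwise_identity(seqs[i], seqs[j])$identity
      }
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (Q-criterion agglomeration with the
#' standard branch-length formulas, as implemented in the ape package).
#' Requires at least three taxa.
#'
#' @param d Square symmetric distance matrix (or `dist`).
#' @param labels Optional tip labels overriding the matrix dimnames.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d, labels = NULL) {
  m <- as.matrix(d)
  if (nrow(m) < 3) stop("neighbor joining requires at least 3 taxa")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  ape::nj(stats::as.dist(m))
}

# pad sequences right with '-' into a character matrix
pad_alignment <- function(seqs) {
  L <- max(nchar(seqs))
  mat <- matrix("-", length(seqs), L)
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "")[[1]]
    mat[i, seq_along(ch)] <- ch
  }
  rownames(mat) <- names(seqs)
  mat
}

p_distance_from_columns <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        ok <- mat[i, ] != "-" & mat[j, ] != "-"
        d[i, j] <- d[j, i] <-
          if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else 1
      }
    }
  }
  d
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the reference NJ tree from a padded alignment of the input
#' sequences, then resamples alignment columns with replacement
#' `replicates` times, rebuilds the tree on each resample, and reports
#' for every internal edge of the reference tree the percentage of
#' replicate trees containing the same split. Seed-deterministic.
#'
#' @param seqs Named character vector of (mature) sequences, n >= 4.
#' @param replicates Number of bootstrap resamples.
#' @param seed Integer seed controlling the resampling.
#' @return A list: `tree` (reference `phylo` with `node.label` set to
#'   support percentages) and `support` (numeric vector per internal
#'   node).
#' @export
bootstrap_support <- function(seqs, replicates = 1000L, seed = 1L) {
  mat <- pad_alignment(rna_norm(seqs))
  if (nrow(mat) < 4) stop("bootstrap support needs at least 4 sequences")
  ref <- nj_tree(p_distance_from_columns(mat))
  set.seed(seed)
  L <- ncol(mat)
  reps <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    reps[[r]] <- nj_tree(p_distance_from_columns(mat[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / replicates
  ref$node.label <- round_half_up(support, 0)
  list(tree = ref, support = support)
}
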