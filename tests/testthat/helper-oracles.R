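# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

ORACLE_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")

oracle_ptype <- function(a, b) match(paste0(a, b), ORACLE_PAIRS)

oracle_can_pair <- function(a, b) !is.na(oracle_ptype(a, b))

rand_seq <- function(n, alphabet = c("A", "C", "G", "U"),
                     prob = rep(1 / length(alphabet), length(alphabet))) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

rc <- function(s) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# --- exhaustive secondary-structure enumeration -------------------------

# all nested pairings (2 x k matrices) with hairpin loops >= 3
enum_structures <- function(x) {
  rec <- function(i, j) {
    if (j - i < 4) return(list(matrix(integer(0), nrow = 2)))
    out <- rec(i + 1, j)
    for (k in (i + 4):j) {
      if (oracle_can_pair(x[i], x[k])) {
        inner <- rec(i + 1, k - 1)
        after <- if (k < j) rec(k + 1, j) else
          list(matrix(integer(0), nrow = 2))
        for (a in inner) for (b in after) {
          out[[length(out) + 1]] <- cbind(c(i, k), a, b)
        }
      }
    }
    out
  }
  rec(1, length(x))
}

# loop-decomposition energy of one structure; NA when a helix is shorter
# than min_helix
oracle_struct_energy <- function(x, pm, model) {
  if (ncol(pm) == 0) return(0)
  partner <- integer(length(x))
  partner[pm[1, ]] <- pm[2, ]
  partner[pm[2, ]] <- pm[1, ]
  if (model$min_helix >= 2) {
    for (cc in seq_len(ncol(pm))) {
      i <- pm[1, cc]; j <- pm[2, cc]
      stacked_in <- i + 1 < j - 1 && partner[i + 1] == j - 1
      stacked_out <- i > 1 && j < length(x) && partner[i - 1] == j + 1
      if (!(stacked_in || stacked_out)) return(NA_real_)
    }
  }
  e <- model$pair_bonus * ncol(pm)
  for (cc in seq_len(ncol(pm))) {
    i <- pm[1, cc]; j <- pm[2, cc]
    kids <- list(); p <- i + 1; unp <- 0L
    while (p < j) {
      if (partner[p] > p) {
        kids[[length(kids) + 1]] <- c(p, partner[p])
        p <- partner[p] + 1L
      } else {
        unp <- unp + 1L
        p <- p + 1L
      }
    }
    nk <- length(kids)
    if (nk == 0) {
      e <- e + model$hairpin_a + model$hairpin_b * (j - i - 1 - 3)
    } else if (nk == 1) {
      k <- kids[[1]]
      l1 <- k[1] - i - 1; l2 <- j - k[2] - 1
      if (l1 + l2 == 0) {
        e <- e + model$stack[oracle_ptype(x[i], x[j]),
                             oracle_ptype(x[k[1]], x[k[2]])]
      } else if (l1 == 0 || l2 == 0) {
        e <- e + model$bulge_a + model$bulge_b * (l1 + l2)
      } else {
        e <- e + model$internal_a + model$internal_b * (l1 + l2)
      }
    } else {
      e <- e + model$ml_init + model$ml_branch * (nk + 1) +
        model$ml_unpaired * unp
    }
  }
  e
}

oracle_brute_mfe <- function(s, model) {
  x <- strsplit(s, "")[[1]]
  es <- vapply(enum_structures(x), function(pm) {
    oracle_struct_energy(x, pm, model)
  }, numeric(1))
  min(c(0, es), na.rm = TRUE)
}

# --- Nussinov maximum matching -----------------------------------------

oracle_nussinov <- function(s) {
  x <- strsplit(s, "")[[1]]
  n <- length(x)
  D <- matrix(0L, n, n)
  for (l in 5:n) {
    for (i in 1:(n - l + 1)) {
      j <- i + l - 1
      best <- D[i, j - 1]
      for (k in i:(j - 4)) {
        if (oracle_can_pair(x[k], x[j])) {
          v <- (if (k > i) D[i, k - 1] else 0L) +
            (if (j - k >= 5) D[k + 1, j - 1] else 0L) + 1L
          if (v > best) best <- v
        }
      }
      D[i, j] <- best
    }
  }
  D[1, n]
}

# --- target positional rules, evaluated directly -----------------------

# site and mirna both 5'->3'; returns TRUE when the window passes the
# strict rule set under the given duplex energy
oracle_target_rules <- function(mirna, site, energy) {
  m <- strsplit(mirna, "")[[1]]
  s <- rev(strsplit(site, "")[[1]])  # s[k] faces miRNA position k
  L <- length(m)
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  match_ <- wc[m] == s
  mm <- !match_
  sum(mm) <= 4 &&
    sum(mm[1:9]) <= 1 &&
    !any(mm[10:11]) &&
    !any(mm[8:12]) &&
    energy < -18
}

# --- hypergeometric upper tail by subset enumeration -------------------

oracle_hyper_upper <- function(N, M, n, m) {
  if (n == 0) return(as.numeric(m == 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= M) >= m)
}

# --- Benjamini-Hochberg step-up, directly ------------------------------

oracle_bh_significant <- function(p, alpha = 0.05) {
  o <- order(p)
  ps <- p[o]
  mtot <- length(p)
  k <- which(ps <= seq_len(mtot) / mtot * alpha)
  sig <- logical(mtot)
  if (length(k)) sig[o[seq_len(max(k))]] <- TRUE
  sig
}

# --- best-offset ungapped identity -------------------------------------

oracle_offset_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best_m <- -1L; best_al <- 0L
  for (off in -(length(bv) - 1):(length(av) - 1)) {
    ia <- max(1, 1 + off):min(length(av), length(bv) + off)
    ib <- ia - off
    m <- sum(av[ia] == bv[ib])
    if (m > best_m || (m == best_m && length(ia) > best_al)) {
      best_m <- m; best_al <- length(ia)
    }
  }
  c(identity = best_m / best_al, mismatches = best_al - best_m)
}

# --- connected components by depth-first search ------------------------

oracle_components <- function(n, edges) {
  comp <- integer(n)
  cur <- 0L
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[v] != 0) next
      comp[v] <- cur
      stack <- c(stack, adj[[v]])
    }
  }
  comp
}

# small shared fixture: a simulation scaled down for unit tests
mini_sim_config <- function(seed = 11L) {
  simulation_config(
    seed = seed,
    n_chromosomes = 1L, chromosome_length = 12000L,
    genes_per_chromosome = 2L,
    n_novel_hairpins = 6L, n_known_hairpins = 2L,
    total_reads = 4000L,
    n_ests = 8L, est_length = 300L, n_est_conserved = 1L,
    n_extra_reference_matures = 3L,
    n_transcript_genes = 20L, n_target_genes = 8L,
    n_relaxed_only_sites = 2L)
}
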