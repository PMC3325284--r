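# Independent brute-force oracles and fixture builders. These deliberately
# share no code with the package internals: plain loops, recomputed from
# definitions.

BASES <- c("A", "C", "G", "T")

# Random aligned sequences with optional gaps and ambiguity characters.
random_alignment <- function(n, L, seed, gap_prob = 0, amb_prob = 0,
                             genus = "Rand") {
  set.seed(seed)
  M <- matrix(sample(BASES, n * L, replace = TRUE), nrow = n)
  if (gap_prob > 0) {
    M[matrix(runif(n * L) < gap_prob, nrow = n)] <- "-"
  }
  if (amb_prob > 0) {
    amb <- matrix(runif(n * L) < amb_prob, nrow = n)
    M[amb] <- sample(c("N", "R", "Y"), sum(amb), replace = TRUE)
  }
  # no gap-only columns (keep coordinates stable)
  allgap <- colSums(M == "-") == n
  if (any(allgap)) M[1L, allgap] <- "A"
  seqs <- apply(M, 1L, paste, collapse = "")
  names(seqs) <- paste0("s", seq_len(n))
  genus_alignment(seqs, genus)
}

# Per-window statistics recomputed from the definitions, column by column.
oracle_window_stats <- function(aln, start, end, policy = "complete") {
  M <- aln$seq
  n <- nrow(M)
  is_b <- function(ch) ch %in% BASES
  cols <- start:end
  retained <- if (policy == "complete") {
    keep <- logical(length(cols))
    for (k in seq_along(cols)) keep[k] <- all(is_b(M[, cols[k]]))
    cols[keep]
  } else cols
  S <- 0L
  for (cc in retained) {
    chars <- M[, cc]
    states <- unique(chars[is_b(chars)])
    if (length(states) >= 2L) S <- S + 1L
  }
  pairs <- utils::combn(n, 2L)
  if (policy == "complete") {
    if (length(retained) == 0L) {
      pi <- NA_real_
    } else {
      d <- 0L
      for (p in seq_len(ncol(pairs))) {
        for (cc in retained) {
          if (M[pairs[1L, p], cc] != M[pairs[2L, p], cc]) d <- d + 1L
        }
      }
      pi <- d / (ncol(pairs) * length(retained))
    }
  } else {
    tot <- 0
    used <- 0L
    for (p in seq_len(ncol(pairs))) {
      d <- 0L; Lp <- 0L
      for (cc in cols) {
        a <- M[pairs[1L, p], cc]; b <- M[pairs[2L, p], cc]
        if (is_b(a) && is_b(b)) {
          Lp <- Lp + 1L
          if (a != b) d <- d + 1L
        }
      }
      if (Lp > 0L) { tot <- tot + d / Lp; used <- used + 1L }
    }
    pi <- if (used == 0L) NA_real_ else tot / used
  }
  # indel events: maximal gap runs, deduplicated, assigned by start column
  runs <- list()
  for (i in seq_len(n)) {
    in_run <- FALSE; rs <- 0L
    for (cc in seq_len(ncol(M))) {
      if (M[i, cc] == "-" && !in_run) { in_run <- TRUE; rs <- cc }
      if (M[i, cc] != "-" && in_run) {
        runs[[length(runs) + 1L]] <- c(rs, cc - 1L); in_run <- FALSE
      }
    }
    if (in_run) runs[[length(runs) + 1L]] <- c(rs, ncol(M))
  }
  runs <- unique(runs)
  ind <- sum(vapply(runs, function(r) r[1L] >= start && r[1L] <= end, TRUE))
  list(S = S, L_retained = length(retained), pi = pi, indel_events = ind)
}

# Minimum number of changes for one tree by exhaustive internal-state
# labeling, per column; gaps and non-ACGT characters are wildcards (their
# leaf edge can always be made change-free).
oracle_parsimony <- function(tree, M) {
  tr <- ape::root(ape::unroot(tree), outgroup = tree$tip.label[1L],
                  resolve.root = TRUE)
  edge <- tr$edge
  ntip <- length(tr$tip.label)
  internal <- sort(unique(edge[, 1L]))
  leaf_state <- function(ch) if (ch %in% BASES) match(ch, BASES) else 0L
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  total <- 0L
  Mo <- M[tr$tip.label, , drop = FALSE]
  for (col in seq_len(ncol(Mo))) {
    costs <- integer(nrow(grid))
    for (r in seq_len(nrow(edge))) {
      par <- grid[, match(edge[r, 1L], internal)]
      ch_node <- edge[r, 2L]
      if (ch_node <= ntip) {
        st <- leaf_state(Mo[ch_node, col])
        if (st > 0L) costs <- costs + (par != st)
      } else {
        costs <- costs + (par != grid[, match(ch_node, internal)])
      }
    }
    total <- total + min(costs)
  }
  total
}

# Evolve sequences down a given tree with per-edge substitution
# probability p (uniform replacement), for parsimony/NJ recovery tests.
sim_matrix_on_tree <- function(tree, L, p, seed) {
  set.seed(seed)
  tr <- ape::root(ape::unroot(tree), outgroup = tree$tip.label[1L],
                  resolve.root = TRUE)
  edge <- tr$edge
  ntip <- length(tr$tip.label)
  root <- setdiff(edge[, 1L], edge[, 2L])
  seqs <- vector("list", max(edge))
  seqs[[root]] <- sample(BASES, L, replace = TRUE)
  # preorder: parents before children
  remaining <- seq_len(nrow(edge))
  done <- root
  while (length(remaining)) {
    ready <- remaining[edge[remaining, 1L] %in% done]
    for (r in ready) {
      par <- seqs[[edge[r, 1L]]]
      mut <- runif(L) < p
      ch <- par
      if (any(mut)) ch[mut] <- sample(BASES, sum(mut), replace = TRUE)
      seqs[[edge[r, 2L]]] <- ch
      done <- c(done, edge[r, 2L])
    }
    remaining <- setdiff(remaining, ready)
  }
  M <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(M) <- tr$tip.label
  M
}

# Simulate a genus and separate its declared inversions (the standard
# pre-scan treatment).
sim_separated <- function(cfg, genus_label = "SimGenus") {
  sim <- suppressMessages(simulate_genus(cfg, genus_label))
  sim$alignment <- apply_inversions(sim$alignment,
                                    sim$truth$inversion_declarations)
  sim
}

intervals_overlap <- function(s1, e1, s2, e2) {
  pmin(e1, e2) - pmax(s1, s2) >= 0
}

ungapped_string_oracle <- function(s) gsub("-", "", s, fixed = TRUE)
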