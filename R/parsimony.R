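# Case-study evaluation engine: exact Fitch parsimony over exhaustively
# enumerated unrooted topologies, neighbor joining on uncorrected
# p-distances, bootstrap majority-rule consensus, and a resolution metric
# (how many of the n-3 possible internal edges a consensus recovers).
#
# Scale: desk-size species groups (4-9 taxa). At that size every unrooted
# binary topology - (2n-5)!! of them - can be scored exactly, which beats
# emulating a heuristic search. Gaps and ambiguity codes are treated as
# missing data (wildcard states), the conventional default.

# --- character matrices -----------------------------------------------------

#' Read an aligned FASTA file as a character matrix
#'
#' @param path Aligned FASTA; all records must have equal length.
#' @return Character matrix, taxa in rows (rownames = record ids).
#' @export
read_character_matrix <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  lens <- nchar(seqs)
  if (any(lens != lens[1L])) stop("records differ in aligned length")
  M <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(M) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  M
}

# Bitmask encoding: A=1, C=2, G=4, T=8; gap/ambiguity/anything else is the
# full state set (missing data contributes no changes).
encode_states <- function(M) {
  code <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  out <- matrix(15L, nrow(M), ncol(M))
  for (b in names(code)) out[M == b] <- code[[b]]
  rownames(out) <- rownames(M)
  out
}

# Site-pattern compression: unique columns plus multiplicities.
compress_patterns <- function(enc) {
  key <- apply(enc, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  pat_id <- match(key, key[first])
  list(patterns = enc[, first, drop = FALSE],
       id = pat_id, weights = tabulate(pat_id, nbins = sum(first)))
}

# --- topology enumeration ---------------------------------------------------

# All rooted binary trees over `labels` as nested two-element lists
# (a leaf is its integer label), built by stepwise leaf insertion on
# every edge; yields (2m-3)!! trees on m labels, in deterministic order.
insert_leaf <- function(tree, leaf) {
  res <- list(list(tree, leaf))
  if (is.list(tree)) {
    for (side in 1:2) {
      for (s in insert_leaf(tree[[side]], leaf)) {
        t2 <- tree
        t2[[side]] <- s
        res[[length(res) + 1L]] <- t2
      }
    }
  }
  res
}

enum_rooted <- function(labels) {
  trees <- list(labels[1L])
  for (k in seq_along(labels)[-1L]) {
    trees <- unlist(lapply(trees, insert_leaf, leaf = labels[k]),
                    recursive = FALSE)
  }
  trees
}

# Flatten a nested tree to a postorder child table. Children are coded as
# negative leaf labels or positive internal row indices; rows appear
# after both their subtrees (postorder).
flatten_tree <- function(tree) {
  children <- list()
  rec <- function(node) {
    if (!is.list(node)) return(-node)
    a <- rec(node[[1L]])
    b <- rec(node[[2L]])
    children[[length(children) + 1L]] <<- c(a, b)
    length(children)
  }
  root <- rec(tree)
  list(children = do.call(rbind, children), root = root)
}

# An unrooted n-taxon binary topology is represented internally as a
# rooted binary tree over leaves 2..n; leaf 1 hangs off that tree's root.
# The set carries, per topology: the flat child table, the nontrivial
# splits (bitmasks over taxa, canonical side excluding taxon 1), and a
# Newick string.
topology_set <- function(taxa) {
  n <- length(taxa)
  if (n < 4L) stop("tree enumeration needs at least 4 taxa")
  if (n > 9L) {
    stop("exhaustive enumeration is limited to 9 taxa ((2n-5)!! growth); ",
         "use a heuristic search tool beyond that")
  }
  trees <- enum_rooted(2:n)
  flats <- lapply(trees, flatten_tree)
  bit <- 2^(seq_len(n) - 1L)
  splits <- lapply(flats, function(fl) {
    nint <- nrow(fl$children)
    masks <- numeric(nint)
    for (r in seq_len(nint)) {
      m <- 0
      for (ch in fl$children[r, ]) {
        m <- m + if (ch < 0L) bit[-ch] else masks[ch]
      }
      masks[r] <- m
    }
    masks[-fl$root]
  })
  nwk <- function(node) {
    if (!is.list(node)) return(taxa[node])
    paste0("(", nwk(node[[1L]]), ",", nwk(node[[2L]]), ")")
  }
  newicks <- vapply(trees, function(tr) {
    paste0("(", taxa[1L], ",", nwk(tr[[1L]]), ",", nwk(tr[[2L]]), ");")
  }, "")
  list(taxa = taxa, flats = flats, splits = splits, newicks = newicks)
}

#' Enumerate all unrooted binary topologies over a taxon set
#'
#' @param taxa Character vector of 4 to 9 taxon labels.
#' @return A `multiPhylo` of all (2n-5)!! unrooted binary topologies, in
#'   a deterministic order.
#' @export
enumerate_topologies <- function(taxa) {
  tset <- topology_set(taxa)
  ape::read.tree(text = paste(tset$newicks, collapse = "\n"))
}

# Fitch score of one internal topology for a pattern matrix (taxa x P
# bitmasks) with pattern weights w. Vectorized across patterns.
fitch_flat <- function(flat, states, w) {
  nint <- nrow(flat$children)
  node_state <- vector("list", nint)
  cost <- numeric(ncol(states))
  getst <- function(code) {
    if (code < 0L) states[-code, ] else node_state[[code]]
  }
  for (r in seq_len(nint)) {
    a <- getst(flat$children[r, 1L])
    b <- getst(flat$children[r, 2L])
    inter <- bitwAnd(a, b)
    z <- inter == 0L
    if (any(z)) inter[z] <- bitwOr(a, b)[z]
    cost <- cost + z
    node_state[[r]] <- inter
  }
  z <- bitwAnd(node_state[[flat$root]], states[1L, ]) == 0L
  sum(w * (cost + z))
}

#' Fitch small-parsimony score of a tree
#'
#' Minimum number of state changes the matrix requires on the given
#' unrooted binary topology, summed over columns. Gap and ambiguity
#' characters are wildcards (full state set), so they never force a
#' change. The score is invariant to where the tree is rooted.
#'
#' @param tree A binary `phylo` tree (rooted or unrooted) whose tip
#'   labels match the matrix rows.
#' @param matrix Character matrix (taxa x sites) as from
#'   [read_character_matrix].
#' @return Integer parsimony score.
#' @export
fitch_score <- function(tree, matrix) {
  if (!setequal(tree$tip.label, rownames(matrix))) {
    stop("tree tips and matrix taxa differ")
  }
  tr <- ape::root(ape::unroot(tree), outgroup = tree$tip.label[1L],
                  resolve.root = TRUE)
  if (!ape::is.binary(tr)) stop("fitch_score requires a binary tree")
  enc <- encode_states(matrix)
  cp <- compress_patterns(enc)
  states <- cp$patterns[tr$tip.label, , drop = FALSE]
  edge <- stats::reorder(tr, "postorder")$edge
  n <- length(tr$tip.label)
  node_state <- vector("list", max(edge))
  for (i in seq_len(n)) node_state[[i]] <- states[i, ]
  cost <- numeric(ncol(states))
  internal_order <- unique(edge[, 1L])
  for (nd in internal_order) {
    ch <- edge[edge[, 1L] == nd, 2L]
    a <- node_state[[ch[1L]]]
    b <- node_state[[ch[2L]]]
    inter <- bitwAnd(a, b)
    z <- inter == 0L
    if (any(z)) inter[z] <- bitwOr(a, b)[z]
    cost <- cost + z
    node_state[[nd]] <- inter
  }
  as.integer(sum(cp$weights * cost))
}

#' Exhaustive maximum parsimony
#'
#' Scores every unrooted binary topology and returns the minimum score
#' with all co-optimal trees.
#'
#' @param matrix Character matrix (4-9 taxa).
#' @return List with `score` (best Fitch score), `trees` (`multiPhylo` of
#'   all optima), `n_topologies` (number enumerated) and `scores` (all
#'   scores, in enumeration order).
#' @export
exhaustive_mp <- function(matrix) {
  taxa <- rownames(matrix)
  if (length(taxa) < 4L) stop("maximum parsimony needs at least 4 taxa")
  tset <- topology_set(taxa)
  cp <- compress_patterns(encode_states(matrix))
  scores <- vapply(tset$flats, fitch_flat, 0, states = cp$patterns,
                   w = cp$weights)
  best <- min(scores)
  opt <- which(scores == best)
  trees <- ape::read.tree(text = paste(tset$newicks[opt], collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- c(trees)  # always multiPhylo
  list(score = as.integer(best), trees = trees,
       n_topologies = length(tset$flats), scores = as.integer(scores))
}

# --- distances and neighbor joining ----------------------------------------

#' Uncorrected p-distance matrix with pairwise deletion
#'
#' @param matrix Character matrix.
#' @return Symmetric numeric matrix of proportions of differing sites,
#'   each pair compared over the sites where both sequences carry an
#'   unambiguous base.
#' @export
p_distance <- function(matrix) {
  n <- nrow(matrix)
  ok <- matrix %in% DNA_BASES
  dim(ok) <- dim(matrix)
  D <- matrix(0, n, n, dimnames = list(rownames(matrix), rownames(matrix)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- ok[i, ] & ok[j, ]
      if (!any(both)) {
        stop("sequences '", rownames(matrix)[i], "' and '",
             rownames(matrix)[j], "' share no comparable sites")
      }
      D[i, j] <- D[j, i] <- sum(matrix[i, both] != matrix[j, both]) /
        sum(both)
    }
  }
  D
}

# Neighbor joining from a distance matrix; deterministic tie-breaking:
# pairs are scanned in row order (input taxa first, agglomerated nodes
# appended) and the first strict minimum of the Q criterion wins.
nj_from_dist <- function(D, labels) {
  frag <- labels
  m <- length(labels)
  fmt <- function(x) sprintf("%.10g", x)
  while (m > 3L) {
    r <- rowSums(D)
    best <- c(NA_integer_, NA_integer_)
    bestq <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        if (q < bestq) {
          bestq <- q
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    d_iu <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    d_ju <- D[i, j] - d_iu
    new_frag <- paste0("(", frag[i], ":", fmt(d_iu), ",", frag[j], ":",
                       fmt(d_ju), ")")
    d_new <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], d_new[keep]),
               c(d_new[keep], 0))
    frag <- c(frag[keep], new_frag)
    m <- m - 1L
  }
  x1 <- (D[1L, 2L] + D[1L, 3L] - D[2L, 3L]) / 2
  x2 <- (D[1L, 2L] + D[2L, 3L] - D[1L, 3L]) / 2
  x3 <- (D[1L, 3L] + D[2L, 3L] - D[1L, 2L]) / 2
  nwk <- paste0("(", frag[1L], ":", fmt(x1), ",", frag[2L], ":", fmt(x2),
                ",", frag[3L], ":", fmt(x3), ");")
  ape::read.tree(text = nwk)
}

#' Neighbor-joining tree on p-distances
#'
#' Standard neighbor joining on the uncorrected p-distance matrix
#' (divergences at the scale this package targets are far below
#' saturation, so a model correction would not change the topology).
#' Tie-breaking in the Q-criterion scan is deterministic (first pair in
#' row order); negative branch-length estimates are kept as computed.
#'
#' @param matrix Character matrix with at least 4 taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(matrix) {
  if (nrow(matrix) < 4L) stop("neighbor joining needs at least 4 taxa")
  nj_from_dist(p_distance(matrix), rownames(matrix))
}

# --- bootstrap consensus ----------------------------------------------------

# Nontrivial splits of an unrooted phylo as taxa bitmasks, canonical side
# excluding taxa[1].
phylo_splits <- function(tree, taxa) {
  n <- length(taxa)
  bit <- 2^(match(tree$tip.label, taxa) - 1L)
  full <- sum(2^(seq_len(n) - 1L))
  edge <- stats::reorder(ape::unroot(tree), "postorder")$edge
  masks <- numeric(max(edge))
  masks[seq_along(tree$tip.label)] <- bit
  for (r in seq_len(nrow(edge))) {
    masks[edge[r, 1L]] <- masks[edge[r, 1L]] + masks[edge[r, 2L]]
  }
  internal <- unique(edge[, 2L][edge[, 2L] > length(tree$tip.label)])
  out <- masks[internal]
  out <- vapply(out, function(m) {
    if (bitwAnd(m, 1) == 1) full - m else m   # canonical: exclude taxon 1
  }, 0)
  sz <- vapply(out, function(m) sum(bitwAnd(m, 2^(seq_len(n) - 1L)) > 0), 0)
  unique(out[sz >= 2 & sz <= n - 2])
}

mask_members <- function(mask, n) which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)

# Build a majority-rule consensus phylo from compatible splits (all
# exclude taxon 1, so each is a clade of the tree rooted at taxon 1).
consensus_from_splits <- function(taxa, masks, support) {
  n <- length(taxa)
  if (length(masks) == 0L) {
    return(ape::read.tree(text = paste0("(", paste(taxa, collapse = ","),
                                        ");")))
  }
  sizes <- vapply(masks, function(m) length(mask_members(m, n)), 0)
  ord <- order(-sizes)
  masks <- masks[ord]; support <- support[ord]; sizes <- sizes[ord]
  contains <- function(a, b) bitwAnd(a, b) == b && a != b
  nwk_cluster <- function(ci) {
    members <- mask_members(masks[ci], n)
    child_cl <- integer()
    covered <- 0
    for (cj in seq_along(masks)) {
      if (contains(masks[ci], masks[cj]) &&
          !any(vapply(child_cl, function(k) contains(masks[k], masks[cj]),
                      TRUE))) {
        child_cl <- c(child_cl, cj)
        covered <- covered + masks[cj]
      }
    }
    loose <- members[bitwAnd(covered, 2^(members - 1L)) == 0]
    parts <- c(vapply(child_cl, nwk_cluster, ""), taxa[loose])
    paste0("(", paste(parts, collapse = ","), ")", support[ci])
  }
  top <- integer()
  for (ci in seq_along(masks)) {
    if (!any(vapply(top, function(k) contains(masks[k], masks[ci]), TRUE))) {
      top <- c(top, ci)
    }
  }
  covered <- sum(masks[top])
  loose <- setdiff(2:n, mask_members(covered, n))
  parts <- c(taxa[1L], vapply(top, nwk_cluster, ""), taxa[loose])
  ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
}

#' Bootstrap majority-rule consensus tree
#'
#' Resamples alignment columns with replacement, builds a tree per
#' replicate with the chosen method, and returns the majority-rule (>50
#' percent) consensus with split support percentages as node labels. For
#' maximum parsimony, replicates with several co-optimal trees credit
#' each tied tree's splits fractionally (1/number of ties), which keeps
#' the procedure deterministic and unbiased.
#'
#' @param matrix Character matrix (4-9 taxa for `"mp"`).
#' @param method `"mp"` (exhaustive maximum parsimony) or `"nj"`.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return An unrooted `phylo` consensus; node labels carry support
#'   percentages, and attribute `"splits"` is a data frame of every split
#'   seen with its support.
#' @export
bootstrap_consensus <- function(matrix, method = c("mp", "nj"),
                                replicates = 1000L, seed = 1L) {
  method <- match.arg(method)
  if (!is_count(replicates) || replicates < 1L) {
    stop("replicates must be a positive integer")
  }
  taxa <- rownames(matrix)
  n <- length(taxa)
  L <- ncol(matrix)
  set.seed(seed)
  acc <- new.env(parent = emptyenv())
  add_split <- function(mask, wt) {
    key <- as.character(mask)
    prev <- if (exists(key, envir = acc, inherits = FALSE)) {
      get(key, envir = acc)
    } else 0
    assign(key, prev + wt, envir = acc)
  }
  if (method == "mp") {
    tset <- topology_set(taxa)
    cp <- compress_patterns(encode_states(matrix[taxa, , drop = FALSE]))
    for (b in seq_len(replicates)) {
      w <- tabulate(cp$id[sample.int(L, L, replace = TRUE)],
                    nbins = length(cp$weights))
      scores <- vapply(tset$flats, fitch_flat, 0, states = cp$patterns,
                       w = w)
      ties <- which(scores == min(scores))
      wt <- 1 / length(ties)
      for (t in ties) for (m in tset$splits[[t]]) add_split(m, wt)
    }
  } else {
    ok <- matrix %in% DNA_BASES
    dim(ok) <- dim(matrix)
    pairs <- utils::combn(n, 2L)
    valid_p <- t(apply(pairs, 2L, function(p) ok[p[1L], ] & ok[p[2L], ]))
    diff_p <- t(apply(pairs, 2L, function(p) {
      ok[p[1L], ] & ok[p[2L], ] & (matrix[p[1L], ] != matrix[p[2L], ])
    }))
    for (b in seq_len(replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      num <- rowSums(diff_p[, cols, drop = FALSE])
      den <- rowSums(valid_p[, cols, drop = FALSE])
      if (any(den == 0)) {
        stop("a bootstrap replicate left a pair with no comparable sites")
      }
      D <- matrix(0, n, n)
      for (p in seq_len(ncol(pairs))) {
        D[pairs[1L, p], pairs[2L, p]] <- num[p] / den[p]
        D[pairs[2L, p], pairs[1L, p]] <- num[p] / den[p]
      }
      tr <- nj_from_dist(D, taxa)
      # an internal branch of length <= 0 carries no signal: collapse it
      # before counting splits (zero-variation data then yields a star)
      tr <- ape::di2multi(tr, tol = 1e-10)
      for (m in phylo_splits(tr, taxa)) add_split(m, 1)
    }
  }
  keys <- ls(acc)
  freq <- vapply(keys, function(k) 100 * acc[[k]] / replicates, 0)
  maj <- freq > 50
  cons <- consensus_from_splits(taxa, as.numeric(keys[maj]),
                                round(freq[maj], 1))
  split_taxa <- vapply(as.numeric(keys), function(m) {
    paste(taxa[mask_members(m, n)], collapse = ",")
  }, "")
  attr(cons, "splits") <- data.frame(split = split_taxa,
                                     support = round(unname(freq), 2))[
                                       order(-freq), , drop = FALSE]
  attr(cons, "replicates") <- replicates
  cons
}

#' Resolution of a consensus tree
#'
#' A set of taxa is "solved" when the consensus is fully bifurcating:
#' all n-3 possible internal edges are present.
#'
#' @param consensus A `phylo` tree (typically from
#'   [bootstrap_consensus]).
#' @param outgroup Optional outgroup label, recorded in the result.
#' @return List with `resolved_edges`, `max_edges` (= n-3) and
#'   `fully_resolved`.
#' @export
resolution <- function(consensus, outgroup = NULL) {
  tr <- if (ape::is.rooted(consensus)) ape::unroot(consensus) else consensus
  n <- length(tr$tip.label)
  resolved <- tr$Nnode - 1L
  list(resolved_edges = as.integer(resolved), max_edges = n - 3L,
       fully_resolved = resolved == n - 3L,
       outgroup = outgroup)
}
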