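# Independent oracles and small generators used across the suite.

# Brute-force per-edge classification of a community's branch set: walk
# parent pointers from each tip to the root and collect edge indices.
# Deliberately independent of the PD-difference identities used by
# branch_partition().
oracle_branch_set <- function(tree, tips) {
  nmax <- max(tree$edge)
  parent <- integer(nmax)
  eidx <- integer(nmax)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  eidx[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  edges <- integer(0)
  for (v in match(tips, tree$tip.label)) {
    while (v != root) {
      edges <- c(edges, eidx[v])
      v <- parent[v]
    }
  }
  unique(edges)
}

oracle_partition <- function(tree, tips_j, tips_k) {
  ej <- oracle_branch_set(tree, tips_j)
  ek <- oracle_branch_set(tree, tips_k)
  w <- tree$edge.length
  c(a = sum(w[intersect(ej, ek)]),
    b = sum(w[setdiff(ej, ek)]),
    c = sum(w[setdiff(ek, ej)]))
}

oracle_pd <- function(tree, tips) sum(tree$edge.length[oracle_branch_set(tree, tips)])

# Closed-form nestedness components (the published closed forms; the
# implementation uses subtraction instead).
closed_beta_sne <- function(a, b, c) {
  mn <- pmin(b, c); mx <- pmax(b, c)
  ifelse(mx == mn, 0, (mx - mn) / (2 * a + mn + mx) * a / (a + mn))
}
closed_beta_jne <- function(a, b, c) {
  mn <- pmin(b, c); mx <- pmax(b, c)
  ifelse(mx == mn, 0, (mx - mn) / (a + b + c) * a / (a + 2 * mn))
}

# Random tree with branch lengths, and a random non-empty tip subset.
random_tree <- function(n) {
  tr <- ape::rtree(n)  # random splitting; fine as a test-case generator
  tr$edge.length <- round(stats::runif(nrow(tr$edge), 0, 3), 3)
  tr
}

random_tipset <- function(tree, min_size = 1) {
  n <- length(tree$tip.label)
  sample(tree$tip.label, sample(min_size:n, 1))
}

# Random binary community table with non-empty sites.
random_comm <- function(n_sites, species) {
  m <- matrix(rbinom(n_sites * length(species), 1, 0.4),
              n_sites, length(species),
              dimnames = list(paste0("site", seq_len(n_sites)), species))
  empty <- rowSums(m) == 0
  m[cbind(which(empty), sample(length(species), sum(empty), replace = TRUE))] <- 1L
  m
}

table1_printed <- function() {
  # the nine printed rows of the six-community worked example:
  # a, b, c are branch lengths; six index values per row
  read.table(text = "
pair a b c phylosor phylosor.turn phylosor.pd unifrac unifrac.turn unifrac.pd
A-B 5 1 1 0.166 0.166 0     0.286 0.286 0
A-C 5 1 4 0.333 0.166 0.167 0.500 0.286 0.214
A-D 5 1 5 0.375 0.166 0.209 0.545 0.286 0.259
A-E 5 1 7 0.444 0.166 0.278 0.615 0.286 0.329
A-F 5 1 8 0.474 0.166 0.308 0.643 0.286 0.357
B-C 6 0 3 0.200 0     0.200 0.333 0     0.333
B-D 6 0 4 0.250 0     0.250 0.400 0     0.400
B-E 6 0 6 0.333 0     0.333 0.500 0     0.500
B-F 6 0 7 0.368 0     0.368 0.538 0     0.538
", header = TRUE, stringsAsFactors = FALSE)
}

# The printed table mixes 3-decimal rounding and truncation (e.g. 0.166
# for 1/6, and components computed from already-rounded values), so agree
# to one unit in the last printed place (absolute, not relative).
PRINTED_TOL <- 1e-3 + 1e-9

expect_printed <- function(actual, printed, tol = PRINTED_TOL) {
  expect_true(all(abs(actual - printed) <= tol),
              label = paste0("max |", deparse(substitute(actual)), " - printed| = ",
                             format(max(abs(actual - printed)))))
}
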