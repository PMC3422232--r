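# Rooted-tree plumbing: newick I/O, validation, Faith's PD and the shared /
# unique branch-length partition for a pair of communities.
#
# Trees are ordinary ape "phylo" objects throughout; every function here
# validates what it relies on (single root, complete non-negative edge
# lengths, unique non-empty tip labels).

#' Parse a newick string into a validated rooted phylogeny
#'
#' Strict parser for a single rooted newick tree. Every edge must carry an
#' explicit branch length unless `missing_lengths = "zero"`, in which case
#' absent lengths are substituted with 0 (silent defaults corrupt
#' phylogenetic-diversity sums, so substitution is opt-in). A basal
#' multifurcation (the common unrooted dialect) is accepted and treated as
#' rooted at the listed basal node, with a warning.
#'
#' @param text A character scalar holding one newick tree, terminated by `;`.
#' @param missing_lengths `"error"` (default) to reject edges without a
#'   length, `"zero"` to substitute 0.
#' @return An object of class `"phylo"` with complete `edge.length`.
#' @seealso [write_newick()], [faith_pd()], [branch_partition()]
#' @examples
#' tr <- parse_newick("((s1:1,s2:1):1,(s3:1,s4:1):1);")
#' sum(tr$edge.length)  # 6
#' @export
parse_newick <- function(text, missing_lengths = c("error", "zero")) {
  missing_lengths <- match.arg(missing_lengths)
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("'text' must be a single non-empty newick string", call. = FALSE)
  if (!grepl(";", text, fixed = TRUE))
    stop("newick parse error: no terminating ';' found", call. = FALSE)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L)
      stop("expected exactly one newick tree, found ", length(tree), call. = FALSE)
    tree <- tree[[1L]]
  }
  if (!inherits(tree, "phylo"))
    stop("newick parse error: input did not yield a tree", call. = FALSE)
  validate_phylogeny(tree, missing_lengths = missing_lengths)
}

#' Serialize a rooted phylogeny to newick
#'
#' The emitted string re-parses (via [parse_newick()]) to a tree with
#' identical topology, tip labels and branch lengths; zero-length edges are
#' preserved as `0`.
#'
#' @param tree A `"phylo"` object.
#' @param path Optional file path; when given the string is also written to
#'   disk.
#' @return The newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  tree <- validate_phylogeny(tree)
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Validate a rooted phylogeny
#'
#' Checks the invariants every computation in this package relies on:
#' a `"phylo"` tree with a single designated root, finite non-negative
#' branch lengths on all edges, and unique non-empty tip labels.
#'
#' @inheritParams write_newick
#' @param missing_lengths How to treat absent branch lengths; see
#'   [parse_newick()].
#' @return The validated (possibly length-completed) tree, invisibly usable.
#' @export
validate_phylogeny <- function(tree, missing_lengths = c("error", "zero")) {
  missing_lengths <- match.arg(missing_lengths)
  if (!inherits(tree, "phylo"))
    stop("'tree' must be an object of class \"phylo\"", call. = FALSE)
  n <- length(tree$tip.label)
  if (n < 1L) stop("tree has no tips", call. = FALSE)
  if (anyNA(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("tip labels must be non-empty", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  ne <- nrow(tree$edge)
  if (is.null(tree$edge.length)) {
    if (missing_lengths == "error")
      stop("tree has no branch lengths (use missing_lengths = \"zero\" to substitute 0)",
           call. = FALSE)
    tree$edge.length <- rep(0, ne)
  }
  if (anyNA(tree$edge.length)) {
    if (missing_lengths == "error")
      stop(sum(is.na(tree$edge.length)),
           " edge(s) lack a branch length (use missing_lengths = \"zero\" to substitute 0)",
           call. = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(!is.finite(tree$edge.length)))
    stop("branch lengths must be finite", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("branch lengths must be non-negative", call. = FALSE)
  if (ne > 0L) {
    # exactly one root: one node that never appears as a child
    child <- tree$edge[, 2L]
    if (anyDuplicated(child))
      stop("not a tree: some node has more than one parent", call. = FALSE)
    roots <- setdiff(tree$edge[, 1L], child)
    if (length(roots) != 1L)
      stop("tree must have exactly one root", call. = FALSE)
    if (n > 2L && !ape::is.rooted(tree))
      warning("tree has a basal multifurcation; treating it as rooted at the listed basal node")
  }
  tree
}

#' Total branch length of a tree
#'
#' Equals [faith_pd()] of the full tip set.
#'
#' @inheritParams write_newick
#' @return Sum of all branch lengths.
#' @export
total_branch_length <- function(tree) {
  tree <- validate_phylogeny(tree)
  sum(tree$edge.length)
}

# Edge/tip incidence of a tree, the workhorse behind the pairwise drivers
# and the simulators. Returns, in postorder edge order:
#   inc  - logical [n_edge x n_tip]; inc[e, t] is TRUE iff tip t descends
#          from (or is) the child node of edge e, i.e. edge e lies on the
#          root-to-tip path of t
#   w    - branch lengths
#   tips - tip labels (column order of inc)
edge_tip_incidence <- function(tree) {
  n <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  ne <- nrow(tr$edge)
  below <- matrix(FALSE, max(tr$edge), n)
  below[cbind(seq_len(n), seq_len(n))] <- TRUE
  for (i in seq_len(ne)) {
    p <- tr$edge[i, 1L]
    below[p, ] <- below[p, ] | below[tr$edge[i, 2L], ]
  }
  list(inc = below[tr$edge[, 2L], , drop = FALSE],
       w = tr$edge.length,
       tips = tr$tip.label)
}

# Resolve/validate a tip set against a tree.
resolve_tips <- function(tree, tips, prune_missing = FALSE, arg = "tips") {
  tips <- unique(as.character(tips))
  if (length(tips) == 0L)
    stop("'", arg, "' must contain at least one tip label", call. = FALSE)
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown) > 0L) {
    if (!prune_missing)
      stop("tip(s) not on the tree: ", paste(unknown, collapse = ", "),
           " (set prune_missing = TRUE to drop them)", call. = FALSE)
    message("dropping ", length(unknown), " label(s) not found on the tree")
    tips <- setdiff(tips, unknown)
  }
  if (length(tips) == 0L)
    stop("'", arg, "' has no members left on the tree", call. = FALSE)
  tips
}

#' Faith's phylogenetic diversity of a community
#'
#' Sum of the lengths of every branch lying on a path from the root of
#' `tree` to any tip in `tips` (root-inclusive convention: a community's
#' branch set includes basal/stem edges down to the root, so the PD of the
#' full tip set equals the total tree length). Duplicate labels in `tips`
#' collapse silently; a tip set is a set.
#'
#' @inheritParams write_newick
#' @param tips Character vector of tip labels (the community's species).
#' @param prune_missing Drop labels absent from the tree (with a message)
#'   instead of raising an error.
#' @return Non-negative numeric scalar.
#' @examples
#' tr <- parse_newick(
#'   "(((t1:1,t2:1):1,(t3:1,t4:1):1):1,((t5:1,t6:1):1,(t7:1,t8:1):1):1);")
#' faith_pd(tr, c("t1", "t2", "t3", "t4"))  # 7
#' @export
faith_pd <- function(tree, tips, prune_missing = FALSE) {
  tree <- validate_phylogeny(tree)
  tips <- resolve_tips(tree, tips, prune_missing = prune_missing)
  .faith_pd_fast(tree, tips)
}

# PD without re-validation, for internal loops.
.faith_pd_fast <- function(tree, tips) {
  tr <- ape::reorder.phylo(tree, "postorder")
  keep <- logical(max(tr$edge))
  keep[match(tips, tr$tip.label)] <- TRUE
  e <- tr$edge
  for (i in seq_len(nrow(e)))
    if (keep[e[i, 2L]]) keep[e[i, 1L]] <- TRUE
  sum(tr$edge.length[keep[e[, 2L]]])
}

#' Shared and unique branch lengths for a pair of communities
#'
#' Partitions the branch length spanned by two communities on a rooted
#' regional tree into `a` (shared by both), `b` (unique to the first) and
#' `c` (unique to the second), using the phylogenetic-diversity identities
#' `a = PD(j) + PD(k) - PD(j U k)`, `b = PD(j U k) - PD(k)`,
#' `c = PD(j U k) - PD(j)`. A branch belongs to a community's branch set
#' iff it lies on a root-to-tip path of that community, so the identities
#' coincide with a direct per-branch classification.
#'
#' @inheritParams faith_pd
#' @param tips_j,tips_k Character vectors of tip labels for the two
#'   communities; both must be non-empty.
#' @return Named numeric vector `c(a =, b =, c =)`, all non-negative, with
#'   `a + b + c` equal to the PD of the union.
#' @examples
#' tr <- parse_newick(
#'   "(((t1:1,t2:1):1,(t3:1,t4:1):1):1,((t5:1,t6:1):1,(t7:1,t8:1):1):1);")
#' branch_partition(tr, paste0("t", 1:4), paste0("t", 5:8))  # a=0 b=7 c=7
#' @export
branch_partition <- function(tree, tips_j, tips_k, prune_missing = FALSE) {
  tree <- validate_phylogeny(tree)
  tips_j <- resolve_tips(tree, tips_j, prune_missing, arg = "tips_j")
  tips_k <- resolve_tips(tree, tips_k, prune_missing, arg = "tips_k")
  pd_j <- .faith_pd_fast(tree, tips_j)
  pd_k <- .faith_pd_fast(tree, tips_k)
  pd_u <- .faith_pd_fast(tree, union(tips_j, tips_k))
  out <- c(a = pd_j + pd_k - pd_u, b = pd_u - pd_k, c = pd_u - pd_j)
  # guard against floating-point dust on the non-negativity invariant
  out[out < 0 & out > -1e-9] <- 0
  out
}
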