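# The six compositional indices (Sorensen and Jaccard families) and their
# branch-length analogues (PhyloSor and UniFrac), plus pairwise-matrix
# drivers over a site-by-species incidence table.
#
# All indices are functions of a partition (a, b, c): shared, unique-to-
# first, unique-to-second -- species counts for compositional beta
# diversity (CBD), branch lengths for phylogenetic beta diversity (PBD).
#
#   Sorensen family: total    = (b + c) / (2a + b + c)
#                    turnover = min(b,c) / (a + min(b,c))     [Simpson]
#   Jaccard family:  total    = (b + c) / (a + b + c)
#                    turnover = 2 min(b,c) / (a + 2 min(b,c))
#
# The third component (nestedness for CBD, phylogenetic-diversity
# difference for PBD) is computed by subtraction, total - turnover, which
# makes additivity exact in floating point; the closed forms serve as test
# oracles only.

# Vectorized core. Returns data.frame(total, turnover, diff).
decompose_partition <- function(a, b, c, family = c("sorensen", "jaccard")) {
  family <- match.arg(family)
  if (!(length(a) == length(b) && length(b) == length(c)))
    stop("'a', 'b' and 'c' must have equal length", call. = FALSE)
  if (anyNA(a) || anyNA(b) || anyNA(c))
    stop("'a', 'b', 'c' must not contain NA", call. = FALSE)
  if (any(a < 0 | b < 0 | c < 0))
    stop("'a', 'b', 'c' must be non-negative", call. = FALSE)
  if (any(a + b + c == 0))
    stop("undefined index: a + b + c must be positive", call. = FALSE)
  m <- pmin(b, c)
  if (family == "sorensen") {
    total <- (b + c) / (2 * a + b + c)
    turnover <- ifelse(m == 0, 0, m / (a + m))
  } else {
    total <- (b + c) / (a + b + c)
    turnover <- ifelse(m == 0, 0, 2 * m / (a + 2 * m))
  }
  data.frame(total = total, turnover = turnover, diff = total - turnover)
}

# Accept either (a, b, c) scalars/vectors or a single c(a=,b=,c=) vector
# (as returned by branch_partition()).
unpack_abc <- function(a, b, c) {
  if (is.null(b) && is.null(c)) {
    if (is.list(a)) a <- unlist(a)
    if (length(a) != 3L)
      stop("when 'b' and 'c' are missing, 'a' must be a length-3 (a, b, c) vector",
           call. = FALSE)
    return(list(a = a[[1L]], b = a[[2L]], c = a[[3L]]))
  }
  list(a = a, b = b, c = c)
}

#' Sorensen dissimilarity partitioned into turnover and nestedness
#'
#' Additive decomposition of the pairwise Sorensen dissimilarity
#' `beta.sor` into the Simpson turnover component `beta.sim` (species
#' replacement independent of richness differences) and the
#' nestedness-resultant component `beta.sne = beta.sor - beta.sim`.
#'
#' @param a,b,c Species counts: shared, unique to the first site, unique to
#'   the second site. Vectors of equal length, or a single `c(a, b, c)`
#'   vector in `a`.
#' @return A data.frame with columns `beta.sor`, `beta.sim`, `beta.sne`,
#'   one row per input partition. All values lie in `[0, 1]` and
#'   `beta.sor = beta.sim + beta.sne` exactly.
#' @examples
#' sorensen_decomposition(5, 1, 1)  # 1/6, 1/6, 0
#' @export
sorensen_decomposition <- function(a, b = NULL, c = NULL) {
  p <- unpack_abc(a, b, c)
  d <- decompose_partition(p$a, p$b, p$c, "sorensen")
  data.frame(beta.sor = d$total, beta.sim = d$turnover, beta.sne = d$diff)
}

#' Jaccard dissimilarity partitioned into turnover and nestedness
#'
#' Additive decomposition of the pairwise Jaccard dissimilarity `beta.jac`
#' into its turnover component `beta.jtu` and nestedness-resultant
#' component `beta.jne = beta.jac - beta.jtu`.
#'
#' @inheritParams sorensen_decomposition
#' @return A data.frame with columns `beta.jac`, `beta.jtu`, `beta.jne`.
#' @examples
#' jaccard_decomposition(5, 1, 4)  # 0.5, 2/7, rest
#' @export
jaccard_decomposition <- function(a, b = NULL, c = NULL) {
  p <- unpack_abc(a, b, c)
  d <- decompose_partition(p$a, p$b, p$c, "jaccard")
  data.frame(beta.jac = d$total, beta.jtu = d$turnover, beta.jne = d$diff)
}

#' PhyloSor dissimilarity partitioned into turnover and PD components
#'
#' Applies the Sorensen-family formulas to the branch-length partition of
#' two communities on a rooted tree: `phylosor` is the fraction of summed
#' community branch length not shared (shared length double-weighted in the
#' denominator, which is the sum of the two communities' phylogenetic
#' diversities); `phylosor.turn` is the 'true' lineage-turnover component
#' (the turnover expected if both communities had equal PD); and
#' `phylosor.pd = phylosor - phylosor.turn` is the part driven by the
#' phylogenetic diversity difference between the communities.
#'
#' @param a,b,c Branch lengths: shared, unique to the first community,
#'   unique to the second (e.g. from [branch_partition()], which can be
#'   passed directly as `a`).
#' @return A data.frame with columns `phylosor`, `phylosor.turn`,
#'   `phylosor.pd`.
#' @examples
#' phylosor_decomposition(5, 1, 8)
#' @export
phylosor_decomposition <- function(a, b = NULL, c = NULL) {
  p <- unpack_abc(a, b, c)
  d <- decompose_partition(p$a, p$b, p$c, "sorensen")
  data.frame(phylosor = d$total, phylosor.turn = d$turnover, phylosor.pd = d$diff)
}

#' UniFrac dissimilarity partitioned into turnover and PD components
#'
#' Applies the Jaccard-family formulas to the branch-length partition:
#' `unifrac` is the fraction of the total branch length linking all species
#' in both communities that is unique to either one; `unifrac.turn` is the
#' lineage-turnover component and `unifrac.pd = unifrac - unifrac.turn`
#' the phylogenetic-diversity-difference component.
#'
#' @inheritParams phylosor_decomposition
#' @return A data.frame with columns `unifrac`, `unifrac.turn`,
#'   `unifrac.pd`.
#' @examples
#' unifrac_decomposition(5, 1, 5)
#' @export
unifrac_decomposition <- function(a, b = NULL, c = NULL) {
  p <- unpack_abc(a, b, c)
  d <- decompose_partition(p$a, p$b, p$c, "jaccard")
  data.frame(unifrac = d$total, unifrac.turn = d$turnover, unifrac.pd = d$diff)
}

# --- community tables ------------------------------------------------------

# Coerce a sites-by-species table to a binary incidence matrix with
# informative errors; abundances collapse to presence with a notice.
as_incidence_matrix <- function(comm) {
  if (is.data.frame(comm)) comm <- as.matrix(comm)
  if (!is.matrix(comm) || !is.numeric(comm))
    stop("community table must be a numeric sites-by-species matrix", call. = FALSE)
  if (is.null(rownames(comm)))
    rownames(comm) <- paste0("site", seq_len(nrow(comm)))
  if (is.null(colnames(comm)))
    stop("community table must have species names as column names", call. = FALSE)
  if (anyDuplicated(rownames(comm)))
    stop("duplicate site names in community table", call. = FALSE)
  if (anyDuplicated(colnames(comm)))
    stop("duplicate species names in community table", call. = FALSE)
  if (anyNA(comm)) stop("community table contains NA cells", call. = FALSE)
  if (any(comm < 0)) stop("community table contains negative cells", call. = FALSE)
  if (any(comm > 1))
    message("non-binary cells found; collapsing abundances to presence/absence")
  (comm > 0) + 0L
}

pair_index <- function(n) {
  # unordered pairs i < j as a 2-column matrix
  if (n < 2L) stop("need at least two sites for pairwise comparisons", call. = FALSE)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

# Assemble the long-format result from per-pair (a, b, c) vectors.
# Pairs flagged in 'bad' (any empty site involved) get NA index values.
pairwise_table <- function(sites, pairs, a, b, c, family, bad = NULL) {
  if (is.null(bad)) bad <- a + b + c == 0
  fam_rows <- lapply(family, function(f) {
    d <- data.frame(total = rep(NA_real_, length(a)),
                    turnover = rep(NA_real_, length(a)),
                    diff = rep(NA_real_, length(a)))
    if (any(!bad))
      d[!bad, ] <- decompose_partition(a[!bad], b[!bad], c[!bad], f)
    data.frame(site_i = sites[pairs[, 1L]], site_j = sites[pairs[, 2L]],
               family = f, a = a, b = b, c = c,
               total = d$total, turnover = d$turnover, pd_component = d$diff,
               row.names = NULL)
  })
  out <- do.call(rbind, fam_rows)
  rownames(out) <- NULL
  out
}

resolve_family <- function(family) {
  family <- match.arg(family, c("both", "sorensen", "jaccard"))
  if (family == "both") c("sorensen", "jaccard") else family
}

#' Pairwise phylogenetic beta diversity decomposition over a community table
#'
#' For every unordered pair of sites, computes the branch-length partition
#' on the rooted tree and the requested index decompositions. The Sorensen
#' family gives PhyloSor and its components, the Jaccard family UniFrac.
#'
#' Sites with no species present yield `NA` index values (with a warning)
#' rather than failing the whole matrix; species in the table but absent
#' from the tree are an error unless `prune_missing = TRUE`.
#'
#' @inheritParams faith_pd
#' @param comm Sites-by-species incidence matrix (or data.frame); rownames
#'   are site names, colnames species names. Abundances collapse to
#'   presence/absence with a notice.
#' @param family `"sorensen"` (PhyloSor), `"jaccard"` (UniFrac) or
#'   `"both"`.
#' @return Long-format data.frame with one row per pair per family:
#'   `site_i`, `site_j`, `family`, the branch partition `a`, `b`, `c`, and
#'   `total`, `turnover`, `pd_component`.
#' @examples
#' ex <- pbd_example("pd_gradient")
#' head(pairwise_pbd(ex$tree, ex$comm, family = "sorensen"))
#' @export
pairwise_pbd <- function(tree, comm, family = c("both", "sorensen", "jaccard"),
                         prune_missing = FALSE) {
  family <- resolve_family(family)
  tree <- validate_phylogeny(tree)
  comm <- as_incidence_matrix(comm)
  missing_sp <- setdiff(colnames(comm), tree$tip.label)
  if (length(missing_sp) > 0L) {
    if (!prune_missing)
      stop(length(missing_sp), " species in the table are not tips of the tree: ",
           paste(utils::head(missing_sp, 5L), collapse = ", "),
           if (length(missing_sp) > 5L) ", ..." else "",
           " (set prune_missing = TRUE to drop them)", call. = FALSE)
    message("pruning ", length(missing_sp), " species absent from the tree")
    comm <- comm[, setdiff(colnames(comm), missing_sp), drop = FALSE]
  }
  empty <- rowSums(comm) == 0
  if (any(empty))
    warning("empty site(s) ", paste(rownames(comm)[empty], collapse = ", "),
            "; emitting NA for their pairs")
  et <- edge_tip_incidence(tree)
  pbd_pairs_core(comm, et$inc, et$w, match(colnames(comm), et$tips), family)
}

# Fast path shared with the null model: no validation, mapping given.
# tip_idx maps table columns to columns of inc.
pbd_pairs_core <- function(comm, inc, w, tip_idx, family) {
  sp_inc <- inc[, tip_idx, drop = FALSE]           # edges x species
  se <- (comm %*% t(sp_inc)) > 0                   # sites x edges
  storage.mode(se) <- "double"
  pd <- drop(se %*% w)
  shared <- se %*% (w * t(se))                     # sites x sites
  pairs <- pair_index(nrow(comm))
  a <- shared[pairs]
  b <- pd[pairs[, 1L]] - a
  c_ <- pd[pairs[, 2L]] - a
  empty <- rowSums(comm) == 0
  bad <- empty[pairs[, 1L]] | empty[pairs[, 2L]]
  pairwise_table(rownames(comm), pairs, a, b, c_, family, bad = bad)
}

#' Pairwise compositional beta diversity decomposition over a community table
#'
#' Species-count analogue of [pairwise_pbd()]: for every unordered pair of
#' sites, decomposes Sorensen and/or Jaccard dissimilarity into turnover
#' and nestedness-resultant components. In the output the `pd_component`
#' column holds the nestedness component (the naming is shared with the
#' phylogenetic driver so the two tables stack).
#'
#' @inheritParams pairwise_pbd
#' @return Long-format data.frame as in [pairwise_pbd()], with `a`, `b`,
#'   `c` as species counts.
#' @examples
#' comm <- rbind(s1 = c(1, 1, 0), s2 = c(0, 1, 1))
#' colnames(comm) <- c("x", "y", "z")
#' pairwise_cbd(comm, family = "sorensen")
#' @export
pairwise_cbd <- function(comm, family = c("both", "sorensen", "jaccard")) {
  family <- resolve_family(family)
  comm <- as_incidence_matrix(comm)
  m <- comm
  storage.mode(m) <- "double"
  shared <- m %*% t(m)
  rich <- rowSums(m)
  pairs <- pair_index(nrow(m))
  a <- shared[pairs]
  b <- rich[pairs[, 1L]] - a
  c_ <- rich[pairs[, 2L]] - a
  empty <- rich == 0
  if (any(empty))
    warning("empty site(s) ", paste(rownames(m)[empty], collapse = ", "),
            "; emitting NA for their pairs")
  bad <- empty[pairs[, 1L]] | empty[pairs[, 2L]]
  pairwise_table(rownames(m), pairs, a, b, c_, family, bad = bad)
}
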