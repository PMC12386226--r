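#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei agglomeration (via \pkg{ape}); exact on additive
#' distances.  Negative branch lengths, which NJ can produce on non-additive
#' input, are clamped to zero with a message.
#'
#' @param d square symmetric labelled distance matrix (>= 3 taxa).
#' @return An unrooted `"phylo"` tree whose tips are the matrix labels.
#' @export
nj_tree <- function(d) {
  .check_distance(d)
  if (nrow(d) < 3) stop("need at least 3 labels for a tree")
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message("clamped ", sum(neg), " negative NJ branch length(s) to 0")
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Bootstrap support for NJ tree bipartitions
#'
#' Loci are resampled with replacement; each replicate genotype matrix gives
#' an IBS distance matrix and an NJ tree.  Support for an internal edge of
#' the full-data tree is the percentage of replicate trees containing the
#' same bipartition.  Supports are attached as internal `node.label`s.
#'
#' @param g a `"geno"` object.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed optional integer seed for reproducible resampling.
#' @return The full-data NJ `"phylo"` tree with `node.label` holding percent
#'   support (root node label is `NA`).
#' @export
bootstrap_support <- function(g, n_reps = 100, seed = NULL) {
  stopifnot(n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  tr <- nj_tree(ibs_distance(g))
  L <- ncol(g$dosages)
  bp <- ape::prop.part(tr)
  counts <- numeric(length(bp))
  for (b in seq_len(n_reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    gb <- subset_geno(g, loci = idx)
    trb <- nj_tree(ibs_distance(gb))
    hits <- ape::prop.clades(tr, trb, rooted = FALSE)
    hits[is.na(hits)] <- 0  # bipartition absent from the replicate
    counts <- counts + hits
  }
  supp <- 100 * counts / n_reps
  supp[1] <- NA  # root pseudo-node of an unrooted tree
  tr$node.label <- supp
  tr
}

#' Cut a tree into heterotic groups
#'
#' Removes the `k - 1` longest internal edges of the tree (ties broken by
#' edge order); the connected components of the remaining graph define the
#' groups.  For `k = 2` the component with the higher restorer fraction is
#' labelled `"I"` and the other `"II"`; on a tie the larger component is
#' `"II"`, and if sizes also tie the component holding the lexicographically
#' smallest tip label is `"II"`.  For `k > 2` components are labelled with
#' roman numerals in the same restorer-fraction order.
#'
#' @param tree a `"phylo"` tree.
#' @param k number of groups (2 <= k <= number of leaves).
#' @param meta optional sample metadata data.frame (columns `sample_id`,
#'   `line_type`) used for the restorer-fraction labelling rule and the
#'   composition table.
#' @return A list of class `"group_assignment"`: `groups` (named character
#'   vector tip -> label), `composition` (label x line_type count table),
#'   `k`, `cut_edges` (indices of removed edges).
#' @export
assign_groups <- function(tree, k = 2, meta = NULL) {
  n_tip <- length(tree$tip.label)
  if (k < 2) stop("k must be >= 2")
  if (k > n_tip) stop("k larger than number of leaves")
  edge <- tree$edge
  internal <- edge[, 2] > n_tip
  int_idx <- which(internal)
  if (length(int_idx) < k - 1)
    stop("tree has fewer than k - 1 internal edges")
  ord <- int_idx[order(-tree$edge.length[int_idx], int_idx)]
  cut <- ord[seq_len(k - 1)]
  comp <- .components_after_cut(tree, cut)
  tips <- comp[seq_len(n_tip)]
  if (length(unique(tips)) != k)
    stop("cutting produced an empty (leafless) group; reduce k")
  labels <- .label_components(tree$tip.label, tips, meta)
  groups <- labels[as.character(tips)]
  names(groups) <- tree$tip.label
  lt <- .line_types(tree$tip.label, meta)
  composition <- table(group = groups, line_type = lt)
  structure(list(groups = groups, composition = composition, k = k,
                 cut_edges = cut), class = "group_assignment")
}

.components_after_cut <- function(tree, cut) {
  n_node <- max(tree$edge)
  keep <- setdiff(seq_len(nrow(tree$edge)), cut)
  parent <- tree$edge[keep, 1]; child <- tree$edge[keep, 2]
  comp <- seq_len(n_node)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (e in seq_along(parent)) {
    a <- find(parent[e]); b <- find(child[e])
    if (a != b) comp[b] <- a
  }
  vapply(seq_len(n_node), find, 0L)
}

.line_types <- function(tips, meta) {
  if (is.null(meta)) return(rep("unknown", length(tips)))
  lt <- as.character(meta$line_type[match(tips, meta$sample_id)])
  lt[is.na(lt)] <- "unknown"
  lt
}

.label_components <- function(tips, comp_of_tip, meta) {
  ids <- unique(comp_of_tip)
  lt <- .line_types(tips, meta)
  restorer_frac <- vapply(ids, function(id)
    mean(lt[comp_of_tip == id] == "restorer"), 0)
  size <- vapply(ids, function(id) sum(comp_of_tip == id), 0L)
  min_label <- vapply(ids, function(id)
    min(tips[comp_of_tip == id]), "")
  # group I = highest restorer fraction; ties -> larger component is II
  # (smaller first); remaining ties -> the component holding the smallest
  # tip label is II (so it sorts last)
  ord <- order(-restorer_frac, size, -xtfrm(min_label))
  roman <- as.character(utils::as.roman(seq_along(ids)))
  stats::setNames(roman, as.character(ids[ord]))
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("Heterotic group assignment (k =", x$k, ")\n")
  print(x$composition)
  invisible(x)
}

#' Split one heterotic group into subgroups
#'
#' Applies the same longest-internal-edge cutting to the subtree spanned by
#' the members of `group`, yielding labels like `"I-1"`, `"I-2"`, ...
#' (numbered in decreasing subgroup size, ties by smallest member label).
#'
#' @param tree the full `"phylo"` tree.
#' @param assignment a `"group_assignment"` from [assign_groups()].
#' @param group group label to split (e.g. `"I"`).
#' @param k_sub number of subgroups.
#' @return Named character vector member -> subgroup label.
#' @export
assign_subgroups <- function(tree, assignment, group = "I", k_sub = 2) {
  members <- names(assignment$groups)[assignment$groups == group]
  if (length(members) < max(3, k_sub))
    stop("group too small to split")
  sub <- ape::keep.tip(tree, members)
  a <- assign_groups(sub, k = k_sub, meta = NULL)
  comp <- a$groups
  sizes <- sort(table(comp), decreasing = TRUE)
  new <- stats::setNames(paste0(group, "-", seq_along(sizes)), names(sizes))
  out <- new[comp]
  names(out) <- names(comp)
  out
}

#' Write a tree in newick format
#'
#' @param tree a `"phylo"` tree (node labels, e.g. bootstrap supports, are
#'   preserved).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
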