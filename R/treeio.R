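#' @importFrom ape read.tree read.nexus write.tree keep.tip is.rooted
#'   node.depth.edgelength vcv.phylo Ntip reorder.phylo
NULL

# ---- validation ------------------------------------------------------------

#' Validate a single phylogeny for use in signal analyses
#'
#' Checks that `tree` is a rooted `phylo` object with unique tip labels and
#' non-negative branch lengths. Called by every user-facing entry point.
#'
#' @param tree an [ape::phylo] object.
#' @return `tree`, invisibly, if valid; otherwise an error.
#' @keywords internal
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("expected a 'phylo' object")
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stopf("negative branch lengths")
  if (anyDuplicated(tree$tip.label))
    stopf("duplicate tip labels: %s",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                collapse = ", "))
  if (!ape::is.rooted(tree)) stopf("tree is unrooted; a rooted tree is required")
  invisible(tree)
}

#' Construct a tree sample
#'
#' Bundles an ordered collection of trees on a shared tip set into a
#' `multiPhylo` object carrying provenance (run labels and per-run counts).
#'
#' @param trees a list of `phylo` objects or a `multiPhylo`.
#' @param provenance optional data frame with columns `run`, `n`.
#' @return a `multiPhylo` with a `provenance` attribute.
#' @export
tree_sample <- function(trees, provenance = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0L) stopf("tree sample must contain at least one tree")
  lapply(trees, validate_tree)
  tips <- sort(trees[[1L]]$tip.label)
  same <- vapply(trees, function(t) identical(sort(t$tip.label), tips), TRUE)
  if (!all(same))
    stopf("trees %s do not share the tip set of tree 1",
          paste(which(!same), collapse = ", "))
  class(trees) <- "multiPhylo"
  attr(trees, "provenance") <- provenance %||%
    data.frame(run = "run1", n = length(trees))
  trees
}

# ---- parsing ---------------------------------------------------------------

#' Parse a Newick or Nexus document into a tree sample
#'
#' Accepts either plain Newick (one tree per line) or a Nexus document with a
#' `TREES` block, optionally with a translate table. Square-bracket comments
#' (e.g. posterior annotations) are ignored. Branch lengths are preserved as
#' written.
#'
#' @param text character: the document, either as a single string or a vector
#'   of lines.
#' @param run character run label recorded in the sample's provenance.
#' @return a `multiPhylo` tree sample (see [tree_sample()]).
#' @examples
#' ts <- parse_trees("((A:1,B:1):1,C:2);")
#' length(ts)
#' @export
parse_trees <- function(text, run = "run1") {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  nonblank <- text[nzchar(trimws(text))]
  if (length(nonblank) == 0L) stopf("empty tree document")
  if (grepl("^\\s*#nexus", nonblank[1L], ignore.case = TRUE)) {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(text, tf)
    trees <- tryCatch(ape::read.nexus(tf),
                      error = function(e) stopf("Nexus parse error: %s",
                                                conditionMessage(e)))
    if (inherits(trees, "phylo")) trees <- list(trees)
    return(tree_sample(trees, data.frame(run = run, n = length(trees))))
  }
  trees <- vector("list", 0L)
  for (i in seq_along(text)) {
    line <- strip_newick_comments(text[i])
    if (!nzchar(trimws(line))) next
    no <- nchar(gsub("[^(]", "", line))
    nc <- nchar(gsub("[^)]", "", line))
    if (no != nc)
      stopf("parse error at line %d: unbalanced parentheses (%d open, %d close)",
            i, no, nc)
    tr <- tryCatch(ape::read.tree(text = line), error = function(e) NULL,
                   warning = function(w) NULL)
    if (is.null(tr) || !inherits(tr, "phylo"))
      stopf("parse error at line %d: malformed Newick", i)
    tryCatch(validate_tree(tr),
             error = function(e) stopf("line %d: %s", i, conditionMessage(e)))
    trees[[length(trees) + 1L]] <- tr
  }
  if (length(trees) == 0L) stopf("no trees found in document")
  tree_sample(trees, data.frame(run = run, n = length(trees)))
}

# drop [...] comment blocks (non-nested, the form written by BEAST/MrBayes)
strip_newick_comments <- function(line) gsub("\\[[^]]*\\]", "", line)

#' Write a tree sample to Newick text
#'
#' One tree per line, branch lengths at full precision so that
#' `parse_trees(write_trees(x))` round-trips topology and branch lengths.
#'
#' @param trees a `phylo` or `multiPhylo`.
#' @param path optional file path; if `NULL` the Newick lines are returned.
#' @return character vector of Newick strings (invisibly when `path` given).
#' @export
write_trees <- function(trees, path = NULL) {
  txt <- ape::write.tree(trees, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# ---- ultrametricity --------------------------------------------------------

#' Depth of every node from the root
#' @keywords internal
node_depths <- function(tree) ape::node.depth.edgelength(tree)

#' Check that a tree is ultrametric
#'
#' A tree is taken as ultrametric when every root-to-tip path length equals
#' the tree height within relative tolerance `rel_tol`.
#'
#' @param tree a rooted `phylo` with branch lengths and at least 2 tips.
#' @param rel_tol relative tolerance (default `1e-6`).
#' @return list with `ultrametric` (logical) and `max_deviation` (the largest
#'   relative tip-depth deviation from the tree height).
#' @export
check_ultrametric <- function(tree, rel_tol = 1e-6) {
  validate_tree(tree)
  if (ape::Ntip(tree) < 2L) stopf("tree must have at least 2 tips")
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  h <- max(d)
  dev <- if (h > 0) max(abs(d - h)) / h else 0
  list(ultrametric = dev <= rel_tol, max_deviation = dev)
}

#' @keywords internal
assert_ultrametric <- function(tree, rel_tol = 1e-6) {
  chk <- check_ultrametric(tree, rel_tol)
  if (!chk$ultrametric)
    stopf("tree is not ultrametric (max relative tip-depth deviation %.3g)",
          chk$max_deviation)
  invisible(tree)
}

# ---- covariance ------------------------------------------------------------

#' Phylogenetic variance-covariance matrix of a tree
#'
#' `C[i, j]` is the root-to-MRCA path length shared by tips i and j (the tip
#' covariance implied by Brownian motion on the tree); `C[i, i]` is the depth
#' of tip i.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param label_order optional character vector, a permutation of the tip
#'   labels fixing the row/column order.
#' @return a symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
tree_to_covariance <- function(tree, label_order = NULL) {
  validate_tree(tree)
  C <- ape::vcv.phylo(tree)
  if (!is.null(label_order)) {
    missing <- setdiff(label_order, rownames(C))
    if (length(missing))
      stopf("unknown tip labels: %s", paste(missing, collapse = ", "))
    if (length(label_order) != nrow(C) || anyDuplicated(label_order))
      stopf("label_order must be a permutation of the tip labels")
    C <- C[label_order, label_order, drop = FALSE]
  }
  C
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged: `lambda = 1` keeps the full tree structure, `lambda = 0` gives
#' the star (independent-tips) covariance.
#'
#' @param C phylogenetic covariance matrix.
#' @param lambda real in `[0, 1]`.
#' @return transformed covariance matrix.
#' @export
lambda_transform_cov <- function(C, lambda) {
  check_lambda(lambda)
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stopf("lambda must be a single value in [0, 1]")
  invisible(lambda)
}

#' Pagel's lambda transform of an ultrametric tree
#'
#' Multiplies internal branch lengths by `lambda` and stretches each terminal
#' branch so every tip keeps its original depth. The result is ultrametric
#' and its covariance equals [lambda_transform_cov()] of the input's
#' covariance.
#'
#' @param tree a rooted ultrametric `phylo`.
#' @param lambda real in `[0, 1]`.
#' @return the transformed `phylo`.
#' @export
lambda_transform_tree <- function(tree, lambda) {
  check_lambda(lambda)
  validate_tree(tree)
  ntip <- ape::Ntip(tree)
  depth <- node_depths(tree)
  newdepth <- depth * lambda
  newdepth[seq_len(ntip)] <- depth[seq_len(ntip)] # tips keep their depth
  out <- tree
  out$edge.length <- newdepth[tree$edge[, 2L]] - newdepth[tree$edge[, 1L]]
  out
}

# ---- pruning, burn-in, subsampling ----------------------------------------

#' Restrict a tree to a subset of tips
#'
#' Returns the induced subtree on `keep`: degree-2 internal nodes are
#' suppressed with their branch lengths summed, so all pairwise MRCA depths
#' among retained tips (and hence ultrametricity) are preserved.
#'
#' @param tree a rooted `phylo`.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned `phylo`.
#' @export
prune_tips <- function(tree, keep) {
  validate_tree(tree)
  keep <- unique(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stopf("unknown tip labels: %s", paste(missing, collapse = ", "))
  if (length(keep) < 2L) stopf("at least 2 tips must be kept")
  ape::keep.tip(tree, keep)
}

#' Remove burn-in from MCMC runs and combine them
#'
#' Drops the first `burnin_count` trees from each run and concatenates the
#' remainder in run order, mirroring standard post-MCMC bookkeeping.
#'
#' @param runs list of tree samples (`multiPhylo`), one per independent run.
#' @param burnin_count number of leading trees to discard from each run.
#' @return a combined `multiPhylo` tree sample with per-run provenance.
#' @export
burnin_and_combine <- function(runs, burnin_count) {
  if (!length(runs)) stopf("no runs supplied")
  if (burnin_count < 0) stopf("burnin_count must be non-negative")
  kept <- vector("list", 0L)
  prov <- vector("list", length(runs))
  for (r in seq_along(runs)) {
    run <- unclass(runs[[r]])
    if (burnin_count >= length(run))
      stopf("burn-in (%d) is not smaller than run %d length (%d)",
            burnin_count, r, length(run))
    keep <- run[seq.int(burnin_count + 1L, length(run))]
    kept <- c(kept, keep)
    prov[[r]] <- data.frame(run = paste0("run", r), n = length(keep))
  }
  tree_sample(kept, do.call(rbind, prov))
}

#' Randomly subsample a tree sample without replacement
#'
#' @param sample a `multiPhylo` tree sample.
#' @param n number of trees to draw.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return a `multiPhylo` of `n` trees.
#' @export
subsample_trees <- function(sample, n, seed) {
  trees <- unclass(sample)
  if (n <= 0 || n > length(trees))
    stopf("n must be in 1..%d (got %d)", length(trees), n)
  idx <- with_seed(seed, sample.int(length(trees), n))
  tree_sample(trees[idx],
              data.frame(run = "subsample", n = n))
}
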