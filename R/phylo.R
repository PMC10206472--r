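#' Parse a Newick string into a validated phylogeny
#'
#' Wraps [ape::read.tree()] with structural validation: the tree must have
#' at least two leaves, unique non-empty tip labels, and (if present)
#' non-negative branch lengths. Unlabeled internal nodes and polytomies are
#' permitted and preserved.
#'
#' @param text A Newick string (one tree, terminated by `;`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):0.5,C:1.5);")
#' tr$tip.label
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse failed: no tree found", call. = FALSE)
  validate_phylogeny(tree)
  tree
}

# Light lexical scan so malformed input is reported with a character offset
# (ape's parser aborts without one).
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed Newick: unmatched ')' at character %d", i),
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' at end of string", depth),
         call. = FALSE)
  semi <- regexpr(";", text, fixed = TRUE)
  if (semi < 0L)
    stop(sprintf("malformed Newick: missing ';' terminator (string length %d)",
                 nchar(text)), call. = FALSE)
  invisible(TRUE)
}

#' Read a phylogeny from a Newick file
#'
#' @param file Path to a file containing a single Newick tree.
#' @return A validated `phylo` object.
#' @export
read_phylogeny <- function(file) {
  if (!file.exists(file)) stop("tree file not found: ", file, call. = FALSE)
  parse_newick(paste(readLines(file, warn = FALSE), collapse = ""))
}

#' Write a phylogeny to Newick
#'
#' Branch lengths are written with 6 significant digits.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  validate_phylogeny(tree)
  txt <- ape::write.tree(tree, digits = 6)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Validate a phylogeny
#'
#' Checks the invariants required by downstream covariance construction:
#' at least two leaves, unique non-empty tip labels, and non-negative
#' branch lengths when branch lengths are present.
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  n <- length(tree$tip.label)
  if (n < 2L) stop("tree must have at least 2 leaves", call. = FALSE)
  if (anyNA(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("all leaves must carry non-empty labels", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (!is.null(tree$edge.length)) {
    if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
      stop("branch lengths must be non-negative and non-missing",
           call. = FALSE)
  }
  invisible(tree)
}

#' Assign branch lengths by Grafen's method
#'
#' For topologies lacking branch lengths: each internal node is placed at
#' height (number of descendant leaves - 1)/(n - 1), producing an
#' ultrametric tree of unit height. Trees without branch lengths are never
#' silently defaulted elsewhere in the package; this assignment is always
#' an explicit user request.
#'
#' @param tree A `phylo` object (branch lengths, if any, are discarded).
#' @return An ultrametric `phylo` with unit root-to-tip height.
#' @export
grafen_branch_lengths <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  out <- ape::compute.brlen(tree, method = "Grafen", power = 1)
  validate_phylogeny(out)
  out
}

#' Phylogenetic covariance matrices from a tree
#'
#' Computes the Brownian-motion covariance `C` (shared root-to-MRCA path
#' length between each pair of species) on the tree pruned to
#' `taxa`, together with its standardized form `A = C / max(diag(C))`.
#' The standardization makes the species-level variance component of the
#' mixed model carry trait units and keeps heritability scale-free; for an
#' ultrametric tree `diag(A)` is identically 1.
#'
#' @param tree A `phylo` object with branch lengths. Trees without branch
#'   lengths are rejected; call [grafen_branch_lengths()] first if desired.
#' @param taxa Optional character vector of species to retain (a subset of
#'   the tree's tip labels). Default: all tips.
#' @return An object of class `phylo_cov`: a list with `species`
#'   (row/column order), `C`, and `A`.
#' @export
#' @examples
#' pc <- phylo_covariance(parse_newick("((A:1,B:1):0.5,C:1.5);"))
#' pc$C["A", "B"]  # 0.5 shared path
phylo_covariance <- function(tree, taxa = NULL) {
  validate_phylogeny(tree)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; apply grafen_branch_lengths() ",
         "explicitly if an arbitrary ultrametric scaling is acceptable",
         call. = FALSE)
  C <- ape::vcv(tree)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, tree$tip.label)
    if (length(missing))
      stop("taxa not in tree: ", paste(missing, collapse = ", "),
           call. = FALSE)
    if (length(taxa) < 2L)
      stop("need at least 2 taxa for a covariance matrix", call. = FALSE)
    # subset of the full-tree covariance: root-to-tip depths (diagonal) are
    # preserved, unlike pruning-then-vcv, which would re-root at the MRCA
    taxa <- unique(taxa)
    C <- C[taxa, taxa, drop = FALSE]
  }
  dmax <- max(diag(C))
  if (dmax <= 0)
    stop("degenerate tree: zero total depth (all branch lengths 0)",
         call. = FALSE)
  A <- C / dmax
  structure(list(species = rownames(C), C = C, A = A), class = "phylo_cov")
}

#' @export
print.phylo_cov <- function(x, ...) {
  cat("Phylogenetic covariance over", length(x$species), "species\n")
  cat("  max root-to-tip depth:", format(max(diag(x$C))), "\n")
  cat("  ultrametric:", isTRUE(all.equal(diag(x$A), rep(1, nrow(x$A)),
                                         check.attributes = FALSE)), "\n")
  invisible(x)
}
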