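# Tree plumbing for the comparative analyses: Newick I/O, the Brownian-motion
# covariance implied by a rooted tree with branch lengths, and Felsenstein's
# phylogenetically independent contrasts. Trees are ape "phylo" objects
# throughout; every operation here requires branch lengths on all edges.

#' Read a Newick tree with mandatory branch lengths
#'
#' Parses a Newick string (or a file containing one) into an [ape] `"phylo"`
#' object. Branch lengths are required on every edge because everything
#' downstream (independent contrasts, Brownian covariance, phylogenetic GLS)
#' needs them; a tree without lengths is rejected rather than silently
#' assigned unit branches.
#'
#' @param x A Newick string (must contain `(` and terminate with `;`), or the
#'   path to a text file holding one.
#' @return An object of class `"phylo"` with `edge.length` set and unique tip
#'   labels.
#' @seealso [write_newick()], [is_binary_tree()]
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  text <- if (grepl("(", x, fixed = TRUE)) x else
    paste(readLines(x, warn = FALSE), collapse = "")
  .check_newick_syntax(text)
  tree <- tryCatch(ape::read.tree(text = text),
                   warning = function(w) NULL, error = function(e) NULL)
  if (is.null(tree) || inherits(tree, "multiPhylo"))
    stop("malformed Newick string (ape could not parse a single tree)")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree is missing branch lengths; independent contrasts and ",
         "Brownian covariance require a length on every edge")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

# Cheap structural pre-scan so parse failures come with a character offset,
# which ape's parser does not report.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at end of string ",
         "(character ", length(chars), ")")
  if (!grepl(";\\s*$", text))
    stop("malformed Newick: no terminating ';' at character ", nchar(text))
  invisible(TRUE)
}

#' Write a tree in Newick format
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; with the default `""` the Newick string is
#'   returned invisibly-printed rather than written.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = "") {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = file)
}

#' Is a tree rooted and strictly bifurcating?
#'
#' Contrast computation requires every internal node to have exactly two
#' daughters; polytomies must be resolved by the caller (e.g. with
#' [ape::multi2di()]) because any automatic zero-length resolution would
#' change every downstream statistic.
#'
#' @param tree A `"phylo"` object.
#' @return `TRUE` iff the tree is rooted and fully binary.
#' @export
is_binary_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::is.rooted(tree) && ape::is.binary(tree)
}

#' Brownian-motion covariance matrix of a tree
#'
#' Under Brownian trait evolution the covariance of tip values is
#' proportional to shared history: `C[i, j]` is the branch length from the
#' root down to the most recent common ancestor of tips `i` and `j`, and the
#' diagonal holds root-to-tip distances. This is the correlation structure
#' phylogenetic GLS assumes.
#'
#' @param tree A rooted `"phylo"` object with branch lengths.
#' @param tip_order Permutation of `tree$tip.label` giving the row/column
#'   order of the result.
#' @return A symmetric positive semi-definite `n x n` matrix with `dimnames`
#'   set to `tip_order`.
#' @examples
#' brownian_covariance(read_newick("((A:1,B:1):1,C:2);"), c("A", "B", "C"))
#' @export
brownian_covariance <- function(tree, tip_order = tree$tip.label) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  # the tree is treated as rooted at its root node; star phylogenies
  # (a basal multifurcation) are legitimate here even though contrast
  # computation would reject them
  unknown <- setdiff(tip_order, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (length(tip_order) != length(tree$tip.label) ||
      anyDuplicated(tip_order))
    stop("'tip_order' must be a permutation of the tree's tip labels")
  depth <- ape::node.depth.edgelength(tree)    # root-to-node path lengths
  m <- ape::mrca(tree)                         # tip x tip MRCA node ids
  C <- matrix(depth[m], nrow = nrow(m), dimnames = dimnames(m))
  C[tip_order, tip_order, drop = FALSE]
}

#' Phylogenetically independent contrasts (Felsenstein pruning)
#'
#' Transforms `n` tip values into `n - 1` standardized contrasts by the
#' pruning recursion: at an internal node with daughter values `x1, x2` and
#' (adjusted) daughter branch lengths `v1, v2`, the contrast is
#' `(x1 - x2) / sqrt(v1 + v2)`, the ancestral value is the
#' precision-weighted mean `(x1/v1 + x2/v2) / (1/v1 + 1/v2)`, and the node's
#' own parent branch is lengthened by `v1 * v2 / (v1 + v2)`. Under Brownian
#' motion the contrasts are i.i.d. with mean zero, which is what licenses
#' ordinary (through-origin) regression on them.
#'
#' Contrasts are returned in postorder (daughters before parents), named by
#' internal node number; the sign of each contrast is fixed by the daughter
#' order stored in the tree, so results are reproducible for a given input
#' Newick.
#'
#' @param tree A rooted, strictly bifurcating `"phylo"` object with strictly
#'   positive branch lengths on all paths used.
#' @param x Named numeric vector of tip values covering every tip label.
#' @return Numeric vector of `n - 1` contrasts named by internal node id,
#'   with attributes `ancestral` (the node value estimates) and
#'   `adjusted_length` (each internal node's parent branch after pruning
#'   adjustment).
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' pic_contrasts(tr, c(A = 3, B = 1, C = 2))
#' @export
pic_contrasts <- function(tree, x) {
  stopifnot(inherits(tree, "phylo"), is.numeric(x))
  n <- length(tree$tip.label)
  if (n < 2L) stop("need at least 2 tips")
  if (!is_binary_tree(tree))
    stop("tree contains a polytomy or is unrooted; resolve it first ",
         "(e.g. ape::multi2di) -- contrasts are only defined on rooted ",
         "strictly bifurcating trees")
  if (is.null(names(x))) stop("'x' must be named by species")
  missing_tips <- setdiff(tree$tip.label, names(x))
  if (length(missing_tips))
    stop("trait values missing for tip(s): ",
         paste(missing_tips, collapse = ", "))
  x <- x[tree$tip.label]
  if (anyNA(x)) stop("trait vector contains NA")

  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  nnode <- tree$Nnode
  blen <- numeric(n + nnode)
  blen[edge[, 2L]] <- po$edge.length
  val <- c(unname(x), rep(NA_real_, nnode))
  extra <- numeric(n + nnode)     # pruning elongation of each node's branch
  contrast <- numeric(nnode)
  adj_len <- numeric(nnode)
  node_seq <- unique(edge[, 1L])  # postorder: daughters precede parents

  for (k in seq_along(node_seq)) {
    nd <- node_seq[k]
    ch <- edge[edge[, 1L] == nd, 2L]
    if (length(ch) != 2L)
      stop("polytomy at node ", nd, "; resolve the tree before computing ",
           "contrasts")
    v1 <- blen[ch[1L]] + extra[ch[1L]]
    v2 <- blen[ch[2L]] + extra[ch[2L]]
    if (v1 <= 0 || v2 <= 0)
      stop("non-positive (adjusted) branch length at node ", nd,
           "; contrasts are undefined with zero-length branches")
    i <- nd - n
    contrast[i] <- (val[ch[1L]] - val[ch[2L]]) / sqrt(v1 + v2)
    val[nd] <- (val[ch[1L]] / v1 + val[ch[2L]] / v2) / (1 / v1 + 1 / v2)
    extra[nd] <- v1 * v2 / (v1 + v2)
    adj_len[i] <- blen[nd] + extra[nd]
  }

  ord <- node_seq - n
  out <- contrast[ord]
  names(out) <- node_seq
  anc <- val[node_seq]
  names(anc) <- node_seq
  al <- adj_len[ord]
  names(al) <- node_seq
  attr(out, "ancestral") <- anc
  attr(out, "adjusted_length") <- al
  out
}

# Intersect a set of named vectors (and a tree) on shared species; drops
# non-shared species with a warning, errors on an empty intersection.
.join_species <- function(tree, vectors, min_n = 2L) {
  common <- tree$tip.label
  for (v in vectors) common <- intersect(common, names(v))
  dropped <- setdiff(
    unique(c(tree$tip.label, unlist(lapply(vectors, names)))), common)
  if (length(common) < min_n)
    stop("fewer than ", min_n,
         " species shared between tree and trait tables")
  if (length(dropped))
    warning("dropping ", length(dropped),
            " species absent from tree or traits: ",
            paste(head(dropped, 8L), collapse = ", "),
            if (length(dropped) > 8L) ", ..." else "")
  tr <- if (length(common) < length(tree$tip.label))
    ape::drop.tip(tree, setdiff(tree$tip.label, common)) else tree
  list(tree = tr, species = tr$tip.label,
       vectors = lapply(vectors, function(v) v[tr$tip.label]))
}
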