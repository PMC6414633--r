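#' Parse a phylogenetic tree from newick or nexus text
#'
#' Reads a rooted phylogeny from a newick string, a nexus TREES block, or a
#' file in either format, and validates it for downstream comparative
#' analyses: tip labels must be unique and nonempty, and any branch lengths
#' present must be nonnegative.
#'
#' @param text A newick string (ending in \code{;}), nexus text containing a
#'   TREES block, or a path to a file holding either.
#' @return An object of class \code{"phylo"} (see \pkg{ape}).
#' @examples
#' tr <- parse_tree("((A:1,B:1):1,C:2);")
#' tip_depths(tr)
#' @export
parse_tree <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  is_file <- !grepl("[();]", text) && file.exists(text)
  raw <- if (is_file) paste(readLines(text, warn = FALSE), collapse = "\n") else text
  tr <- if (grepl("#NEXUS", raw, ignore.case = TRUE)) {
    if (is_file) ape::read.nexus(text) else {
      tf <- tempfile(fileext = ".nex")
      on.exit(unlink(tf), add = TRUE)
      writeLines(raw, tf)
      ape::read.nexus(tf)
    }
  } else {
    ape::read.tree(text = raw)
  }
  if (is.null(tr)) {
    stop("malformed tree string: could not parse newick near position 1")
  }
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  validate_phylo(tr)
  tr
}

#' Serialize a phylogeny to newick text
#'
#' @param tree A \code{"phylo"} object.
#' @param path Optional file path; if \code{NULL} the newick string is
#'   returned.
#' @return The newick string (invisibly when written to a file).
#' @export
write_tree <- function(tree, path = NULL) {
  validate_phylo(tree)
  if (is.null(path)) {
    ape::write.tree(tree)
  } else {
    ape::write.tree(tree, file = path)
    invisible(ape::write.tree(tree))
  }
}

# Validation shared by the readers and the covariance builders.
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("validation error: empty tip label(s)")
  dup <- labs[duplicated(labs)]
  if (length(dup)) {
    stop("validation error: duplicate tip labels: ", paste(unique(dup), collapse = ", "))
  }
  if (!is.null(tree$edge.length)) {
    if (anyNA(tree$edge.length)) stop("validation error: NA branch length")
    if (any(tree$edge.length < 0)) stop("validation error: negative branch length")
    term <- tree$edge[, 2] <= length(labs)
    if (any(tree$edge.length[term] == 0)) {
      warning("zero-length terminal branch(es); covariance remains PSD")
    }
  }
  invisible(tree)
}

#' Root-to-tip path lengths
#'
#' @param tree A rooted \code{"phylo"} with branch lengths.
#' @return Named numeric vector of tip depths.
#' @export
tip_depths <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  stats::setNames(depths[seq_along(tree$tip.label)], tree$tip.label)
}

#' Assign arbitrary ultrametric branch lengths (Pagel's method)
#'
#' Composite phylogenies assembled from supertrees usually lack meaningful
#' branch lengths. This scheme assigns every internal edge length 1 and then
#' stretches each terminal edge so that all tips sit at the same depth (the
#' maximum number of edges on any root-to-tip path), yielding an arbitrary
#' but time-proportional ultrametric tree.
#'
#' @param tree A rooted \code{"phylo"}; existing branch lengths are ignored.
#' @return A \code{"phylo"} with ultrametric branch lengths.
#' @examples
#' tr <- pagel_branch_lengths(parse_tree("((A,B),C);"))
#' tip_depths(tr)  # all 2
#' @export
pagel_branch_lengths <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  n_tip <- length(tree$tip.label)
  tree$edge.length <- rep(1, nrow(tree$edge))
  # depth in edge counts of every node, then stretch terminals to max depth
  depth <- ape::node.depth.edgelength(tree)
  max_rank <- max(depth[seq_len(n_tip)])
  term <- tree$edge[, 2] <= n_tip
  parent_depth <- depth[tree$edge[term, 1]]
  tree$edge.length[term] <- max_rank - parent_depth
  validate_phylo(tree)
}

#' Set every branch length to one
#'
#' The unity-branch transformation used as a robustness check on
#' branch-length assignment: topology is kept, all edges get length 1.
#'
#' @param tree A rooted \code{"phylo"}.
#' @return A \code{"phylo"} with unit branch lengths.
#' @export
unity_branches <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

#' Phylogenetic variance-covariance matrix
#'
#' Under Brownian motion the expected covariance of a trait between two tips
#' is proportional to the shared root-to-MRCA path length, and the variance
#' of a tip to its depth. This wraps the standard construction and checks
#' its invariants.
#'
#' @param tree A rooted \code{"phylo"} with branch lengths.
#' @return A symmetric positive-semidefinite matrix with taxa as dimnames.
#' @export
phylo_vcv <- function(tree) {
  validate_phylo(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Construct an evolution-model descriptor
#'
#' @param kind One of \code{"independent"}, \code{"brownian"}, \code{"ou"},
#'   \code{"lambda"}.
#' @param alpha Selection strength for the Ornstein-Uhlenbeck model
#'   (required, > 0, when \code{kind = "ou"}). Among-species correlation
#'   decays as \code{exp(-alpha * d)} with patristic distance \code{d}.
#' @param lambda Pagel's lambda multiplier on off-diagonal covariances
#'   (required, >= 0, when \code{kind = "lambda"}).
#' @return An object of class \code{"evo_model"}.
#' @export
evo_model <- function(kind = c("independent", "brownian", "ou", "lambda"),
                      alpha = NULL, lambda = NULL) {
  kind <- match.arg(kind)
  if (kind == "ou") {
    if (is.null(alpha) || !is.finite(alpha) || alpha <= 0) {
      stop("OU model requires alpha > 0")
    }
  }
  if (kind == "lambda") {
    if (is.null(lambda) || !is.finite(lambda) || lambda < 0) {
      stop("lambda model requires lambda >= 0")
    }
  }
  structure(list(kind = kind, alpha = alpha, lambda = lambda),
            class = "evo_model")
}

#' @export
print.evo_model <- function(x, ...) {
  cat("Evolution model:", x$kind)
  if (x$kind == "ou") cat(" (alpha =", format(x$alpha), ")")
  if (x$kind == "lambda") cat(" (lambda =", format(x$lambda), ")")
  cat("\n")
  invisible(x)
}

#' Largest admissible lambda for a covariance matrix
#'
#' The lambda transform multiplies off-diagonal covariances; values are
#' admissible up to \code{max(diag(C)) / max(offdiag(C))}, which exceeds 1
#' on any tree whose deepest split is below the root, so estimates slightly
#' above 1 remain interpretable.
#'
#' @param C A phylogenetic covariance matrix.
#' @return Upper bound for lambda.
#' @export
lambda_max <- function(C) {
  off <- C
  diag(off) <- 0
  m <- max(off)
  if (m <= 0) Inf else max(diag(C)) / m
}

#' Transform a phylogenetic covariance under an evolution model
#'
#' \describe{
#'   \item{independent}{keeps only the diagonal of \code{C} (no shared
#'     history).}
#'   \item{brownian}{returns \code{C} unchanged.}
#'   \item{lambda}{multiplies every off-diagonal entry by \code{lambda};
#'     the diagonal is untouched.}
#'   \item{ou}{returns the stationary Ornstein-Uhlenbeck correlation
#'     matrix \code{exp(-alpha * d_ij)} on patristic (tip-to-tip) distances,
#'     with unit diagonal; the stationary variance scale is absorbed into
#'     the residual variance of whatever model uses it.}
#' }
#'
#' @param C A phylogenetic covariance matrix (from \code{\link{phylo_vcv}}).
#' @param model An \code{\link{evo_model}}.
#' @param tree Required for \code{kind = "ou"}: the tree whose patristic
#'   distances define the correlation decay.
#' @return A transformed covariance (or correlation) matrix.
#' @export
transform_covariance <- function(C, model, tree = NULL) {
  stopifnot(inherits(model, "evo_model"), is.matrix(C))
  switch(model$kind,
    independent = {
      out <- diag(diag(C), nrow = nrow(C))
      dimnames(out) <- dimnames(C)
      out
    },
    brownian = C,
    lambda = {
      lmax <- lambda_max(C)
      if (model$lambda > lmax) {
        stop("lambda = ", model$lambda, " exceeds admissible maximum ",
             format(lmax))
      }
      out <- C * model$lambda
      diag(out) <- diag(C)
      out
    },
    ou = {
      D <- if (!is.null(tree)) {
        stats::cophenetic(tree)[rownames(C), colnames(C)]
      } else {
        # patristic distance recovered from the BM covariance:
        # d_ij = C_ii + C_jj - 2 C_ij
        outer(diag(C), diag(C), "+") - 2 * C
      }
      out <- exp(-model$alpha * D)
      dimnames(out) <- dimnames(C)
      out
    }
  )
}

#' Export a covariance matrix as TSV
#'
#' Writes a taxon-labelled square matrix with a header row and a leading
#' taxon column, readable by any spreadsheet or \code{read.delim}.
#'
#' @param C Matrix with taxon dimnames.
#' @param path Output file.
#' @export
write_covariance_tsv <- function(C, path) {
  df <- data.frame(taxon = rownames(C), C, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
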