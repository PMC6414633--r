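#' Parsimony length of an unordered multistate character
#'
#' Minimum number of state changes needed to explain the tip states on the
#' tree under unordered (unit-cost) parsimony. Binary nodes follow the
#' classic set intersection/union rule; polytomies use the exact
#' multifurcating generalization, which keeps the states held by the
#' largest number of child sets and adds one step for each child excluded,
#' so the count stays minimal on arbitrary multifurcations. Branch lengths
#' are ignored: parsimony length depends on topology and states only.
#'
#' @param tree A rooted \code{"phylo"} (polytomies allowed).
#' @param states Character/factor vector named by taxon (or unnamed in tip
#'   order), one state per tip; missing states are an error.
#' @return Integer parsimony length.
#' @examples
#' tr <- parse_tree("((A,B),(C,D));")
#' fitch_length(tr, c(A = "x", B = "x", C = "y", D = "y"))  # 1
#' @export
fitch_length <- function(tree, states) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  n <- length(tree$tip.label)
  nms <- names(states)
  states <- as.character(states)
  if (is.null(nms)) {
    if (length(states) != n) stop("unnamed states must match tip count")
    names(states) <- tree$tip.label
  } else {
    names(states) <- as.character(nms)
  }
  missing_taxa <- setdiff(tree$tip.label, names(states))
  if (length(missing_taxa) || anyNA(states[tree$tip.label])) {
    stop("missing state for tip(s): ",
         paste(utils::head(c(missing_taxa,
           tree$tip.label[is.na(states[tree$tip.label])]), 5), collapse = ", "))
  }
  s <- factor(states[tree$tip.label])
  k <- nlevels(s)
  if (k == 1L) return(0L)
  if (k > 30L) stop("more than 30 states not supported")

  po <- stats::reorder(tree, "postorder")
  edge <- po$edge
  n_node <- tree$Nnode
  sets <- integer(n + n_node)                 # bitmask of candidate states
  sets[seq_len(n)] <- bitwShiftL(1L, as.integer(s) - 1L)
  children <- split(edge[, 2], edge[, 1])
  steps <- 0L
  bits <- bitwShiftL(1L, seq_len(k) - 1L)
  # postorder parent order: every internal child appears as a parent earlier
  for (p in unique(edge[, 1])) {
    ch_sets <- sets[children[[as.character(p)]]]
    cnt <- vapply(bits, function(b) sum(bitwAnd(ch_sets, b) > 0L), integer(1))
    mx <- max(cnt)
    steps <- steps + length(ch_sets) - mx
    sets[p] <- sum(bits[cnt == mx])
  }
  as.integer(steps)
}

#' Simulate a Yule (pure-birth) tree of fixed depth
#'
#' Pure-birth speciation with exponential waiting times between events and
#' a uniformly chosen lineage splitting at each event; the tree is rescaled
#' so every root-to-tip path equals \code{depth}, and tip labels are a
#' random permutation of the supplied taxon set. This is the null topology
#' generator of the permutation tail probability test.
#'
#' @param n_tips Number of tips (>= 2).
#' @param depth Root-to-tip depth of the returned ultrametric tree.
#' @param seed Integer seed; the same seed reproduces the same tree.
#' @param labels Optional character vector of \code{n_tips} taxon labels;
#'   defaults to \code{t1..tN}.
#' @return An ultrametric \code{"phylo"}.
#' @export
yule_tree <- function(n_tips, depth = 10, seed = NULL, labels = NULL) {
  stopifnot(n_tips >= 2, depth > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- paste0("t", seq_len(n_tips))
  stopifnot(length(labels) == n_tips)
  n <- as.integer(n_tips)
  root <- n + 1L
  max_edges <- 2L * n - 2L
  e_par <- integer(max_edges); e_child <- integer(max_edges)
  e_len <- numeric(max_edges); n_edge <- 0L
  # active lineages: parent node and birth time
  act_par <- c(root, root); act_t0 <- c(0, 0)
  t_now <- 0
  next_node <- n + 2L
  for (j in 2:(n - 1L)) {
    if (n == 2L) break
    t_now <- t_now + stats::rexp(1, rate = j)
    i <- sample.int(length(act_par), 1L)
    node <- next_node; next_node <- next_node + 1L
    n_edge <- n_edge + 1L
    e_par[n_edge] <- act_par[i]; e_child[n_edge] <- node
    e_len[n_edge] <- t_now - act_t0[i]
    act_par <- c(act_par[-i], node, node)
    act_t0 <- c(act_t0[-i], t_now, t_now)
  }
  t_present <- t_now + stats::rexp(1, rate = n)
  tip_ids <- sample.int(n)                    # random permutation of labels
  for (i in seq_along(act_par)) {
    n_edge <- n_edge + 1L
    e_par[n_edge] <- act_par[i]; e_child[n_edge] <- tip_ids[i]
    e_len[n_edge] <- t_present - act_t0[i]
  }
  scale <- depth / t_present
  tr <- structure(list(
    edge = cbind(e_par[seq_len(n_edge)], e_child[seq_len(n_edge)]),
    edge.length = e_len[seq_len(n_edge)] * scale,
    tip.label = labels,
    Nnode = n - 1L
  ), class = "phylo")
  stats::reorder(tr, "cladewise")
}

#' Permutation tail probability (PTP) test for categorical signal
#'
#' Compares the observed parsimony length of a character on the study tree
#' to a null distribution of lengths. The default null maps the observed
#' character onto random Yule topologies (uniform pure-birth speciation,
#' tree depth 10, random tip labelling); the classical alternative shuffles
#' tip states on the fixed study topology. The p-value is the proportion of
#' permutations whose length is less than or equal to the observed length;
#' when that count is zero the p-value is reported as
#' \code{10 / n_perm} — the type-I error probability is very small but not
#' zero.
#'
#' @param tree The study \code{"phylo"}.
#' @param states Per-taxon categorical states (named, or in tip order).
#' @param n_perm Number of permutations (999 or 9999 typical).
#' @param seed Integer seed driving all permutations; replicate seeds are
#'   derived by a counter, so results are exactly reproducible.
#' @param null_scheme \code{"random_yule_topology"} (default) or
#'   \code{"shuffle_tip_states"}.
#' @return An object of class \code{"ptp_result"} with
#'   \code{observed_steps}, \code{null_lengths}, \code{n_perm},
#'   \code{p_value}, \code{seed}, \code{null_scheme}.
#' @export
ptp_test <- function(tree, states, n_perm = 999, seed = 1,
                     null_scheme = c("random_yule_topology",
                                     "shuffle_tip_states")) {
  null_scheme <- match.arg(null_scheme)
  stopifnot(n_perm >= 1)
  observed <- fitch_length(tree, states)
  states <- if (is.null(names(states))) {
    stats::setNames(as.character(states), tree$tip.label)
  } else {
    stats::setNames(as.character(states), names(states))
  }
  if (length(unique(states[tree$tip.label])) == 1L) {
    warning("single-state character: parsimony length 0 under any tree; p = 1")
    return(structure(list(observed_steps = 0L,
                          null_lengths = rep(0L, n_perm),
                          n_perm = as.integer(n_perm), p_value = 1,
                          seed = seed, null_scheme = null_scheme),
                     class = "ptp_result"))
  }
  n <- length(tree$tip.label)
  null_lengths <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    rep_seed <- seed + i
    if (null_scheme == "random_yule_topology") {
      null_tree <- yule_tree(n, depth = 10, seed = rep_seed,
                             labels = tree$tip.label)
      null_lengths[i] <- fitch_length(null_tree, states)
    } else {
      set.seed(rep_seed)
      shuffled <- stats::setNames(sample(unname(states[tree$tip.label])),
                                  tree$tip.label)
      null_lengths[i] <- fitch_length(tree, shuffled)
    }
  }
  count <- sum(null_lengths <= observed)
  p <- if (count == 0L) 10 / n_perm else count / n_perm
  structure(list(observed_steps = observed, null_lengths = null_lengths,
                 n_perm = as.integer(n_perm), p_value = p, seed = seed,
                 null_scheme = null_scheme),
            class = "ptp_result")
}

#' @export
print.ptp_result <- function(x, ...) {
  cat("Permutation tail probability (PTP) test\n")
  cat(sprintf("  observed parsimony length: %d steps\n", x$observed_steps))
  cat(sprintf("  null: %s, %d permutations (seed %d)\n",
              x$null_scheme, x$n_perm, x$seed))
  cat(sprintf("  permutations <= observed: %d\n",
              sum(x$null_lengths <= x$observed_steps)))
  cat(sprintf("  p = %s\n", format(x$p_value, digits = 4)))
  invisible(x)
}

#' Export the PTP null-length histogram as TSV
#'
#' Writes the tabulated null parsimony lengths (columns \code{steps},
#' \code{count}) for plotting the permutation distribution.
#'
#' @param x A \code{"ptp_result"}.
#' @param path Output TSV path.
#' @export
write_ptp_histogram <- function(x, path) {
  stopifnot(inherits(x, "ptp_result"))
  tab <- table(x$null_lengths)
  df <- data.frame(steps = as.integer(names(tab)),
                   count = as.integer(tab))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
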