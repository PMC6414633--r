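# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: ordinary least squares by normal equations, and
# parsimony length by exhaustive enumeration of all internal-node state
# assignments.

ols_oracle <- function(y, X) {
  beta <- solve(crossprod(X), crossprod(X, y))
  r <- y - X %*% beta
  list(beta = as.numeric(beta), sigma2_ml = sum(r^2) / length(y))
}

# Exact minimum-change count by brute force: every assignment of states to
# internal nodes is scored; feasible for small trees only.
exhaustive_parsimony <- function(tree, states) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  sts <- sort(unique(as.character(states[tree$tip.label])))
  k <- length(sts)
  if (k == 1L) return(0L)
  tipcode <- match(as.character(states[tree$tip.label]), sts)
  n_assign <- k^m
  stopifnot(n_assign <= 5e5)
  idx <- 0:(n_assign - 1)
  A <- matrix(0L, n_assign, m)
  for (j in seq_len(m)) A[, j] <- (idx %/% k^(j - 1)) %% k + 1L
  full <- cbind(matrix(rep(tipcode, each = n_assign), n_assign, n), A)
  changes <- rowSums(full[, tree$edge[, 2], drop = FALSE] !=
                     full[, tree$edge[, 1], drop = FALSE])
  as.integer(min(changes))
}

# Random rooted binary tree with random multistate tip characters.
random_parsimony_instance <- function(n_tips = 8, n_states = 3, seed = 1) {
  set.seed(seed)
  tr <- ape::rtree(n_tips)
  states <- stats::setNames(sample(letters[seq_len(n_states)], n_tips,
                                   replace = TRUE), tr$tip.label)
  list(tree = tr, states = states)
}

# A small valid trait data frame covering every factor level at least once.
example_trait_df <- function(n = 21) {
  stopifnot(n >= 21)
  data.frame(
    species = sprintf("sp%02d", seq_len(n)),
    cecal_length_cm = seq(0, 20, length.out = n),
    body_mass_g = 10^seq(1, 4, length.out = n),
    diet = rep(cecaphylo::DIET_LEVELS, length.out = n),
    flight = rep(cecaphylo::FLIGHT_LEVELS, length.out = n),
    clade = rep(cecaphylo::CLADE_LEVELS, length.out = n),
    stringsAsFactors = FALSE
  )
}
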