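#' Poisson insertion log likelihood
#'
#' Insertions on branch \eqn{i} follow a Poisson process with rate
#' \eqn{\Phi_i} per Myr, so the branch count \eqn{N_i} is Poisson with mean
#' \eqn{\phi_i = \Phi_i T_i} and the insertion log likelihood over the nine
#' branches is \eqn{\sum_i [-\phi_i + N_i \log\phi_i - \log N_i!]}. Branches
#' with \eqn{N_i = 0} and \eqn{\phi_i = 0} contribute zero; \eqn{\phi_i = 0}
#' with \eqn{N_i > 0} gives \code{-Inf}.
#'
#' @param counts named per-branch insertion counts (see
#'   \code{\link{count_insertions}}).
#' @param rates named per-branch insertion rates \eqn{\Phi_i} per Myr.
#' @param tree an \code{erv_tree} supplying the branch durations.
#' @return log likelihood (scalar).
#' @export
insertion_log_likelihood <- function(counts, rates, tree = erv_tree()) {
  stopifnot(inherits(tree, "erv_tree"))
  if (!all(.BRANCHES %in% names(counts)) || !all(.BRANCHES %in% names(rates)))
    stop("'counts' and 'rates' must be named over the nine branches")
  counts <- counts[.BRANCHES]
  phi <- rates[.BRANCHES] * tree$lengths
  terms <- ifelse(counts == 0 & phi == 0, 0,
                  dpois(counts, phi, log = TRUE))
  sum(terms)
}

#' Log likelihood of one site pattern given its insertion branch
#'
#' Computes \eqn{\log \Pr(U | M_d, T^{(U)})}: the probability of the
#' observed tip states on the subtree consisting of the pattern's insertion
#' branch and its descendants, conditional on one insertion having occurred
#' on that branch. A pruning-style dynamic program sums over the unobserved
#' states (full-length \code{1} or solo-LTR \code{x}) at internal nodes. On
#' the insertion branch the transition 0 -> x integrates the insertion time
#' uniformly (\code{\link{pr_delete_insertion_branch}}); on post-insertion
#' branches only 1 -> 1, 1 -> x and the absorbing x -> x are possible, with
#' probabilities from \code{\link{pr_retain_post_branch}}. Under the Weibull
#' model the program tracks each branch's time window since the
#' insertion-branch origin, because the deletion hazard depends on element
#' age.
#'
#' @param pattern one row of an \code{erv_patterns} object (or the whole
#'   object; a vector of log likelihoods is returned).
#' @param tree an \code{erv_tree}.
#' @param params a \code{deletion_params} object.
#' @return log likelihood(s).
#' @export
pattern_log_likelihood <- function(pattern, tree = erv_tree(), params) {
  pattern <- validate_patterns(pattern)
  stopifnot(inherits(params, "deletion_params"))
  st <- as.matrix(pattern[, .STATE_COLS])
  cache <- new.env(parent = emptyenv())
  vapply(seq_len(nrow(st)), function(i)
    .pattern_ll_one(setNames(st[i, 1:5], .TIPS), tree, params, cache), 0)
}

# `cache` memoizes per-insertion-branch transition tables across patterns
# sharing one parameter value; pass a fresh environment per likelihood
# evaluation.
.pattern_ll_one <- function(states5, tree, params, cache = NULL) {
  b <- .branch_of_support(matrix(states5, nrow = 1,
                                 dimnames = list(NULL, .TIPS)))
  if (is.na(b)) stop("incoherent pattern")
  trans <- if (!is.null(cache) && !is.null(cache[[b]])) cache[[b]]
  else {
    tt <- .transition_table(tree, b, params)
    if (!is.null(cache)) cache[[b]] <- tt
    tt
  }
  log(.subtree_prob(tree, b, states5, trans))
}

# Pre-compute per-branch transition probabilities for a given insertion
# branch: retention probability on every post-insertion branch (with Weibull
# age windows) and the 0->x integral on the insertion branch itself.
.transition_table <- function(tree, insertion_branch, params) {
  post <- post_insertion_branches(tree, insertion_branch)
  t_ins <- tree$lengths[[insertion_branch]]
  p11 <- setNames(numeric(length(post)), post)
  for (bb in post) {
    w <- .branch_window(tree, insertion_branch, bb)
    p11[bb] <- pr_retain_post_branch(params, w[["t1"]], w[["t2"]], t_ins)
  }
  list(p0x = pr_delete_insertion_branch(params, t_ins), p11 = p11)
}

# Probability of the tip data below (and including) the insertion branch.
.subtree_prob <- function(tree, insertion_branch, states5, trans) {
  all_x_below <- function(b) {
    tips <- .tips_below(b)
    all(states5[tips] == "x")
  }
  # f(b, s): Pr(tip data below b | state s at the START of branch b)
  f <- function(b, s) {
    tips <- .tips_below(b)
    if (s == "x") return(as.numeric(all(states5[tips] == "x")))
    p11 <- trans$p11[[b]]
    kids <- tree$children[[b]]
    if (length(kids) == 0) {             # terminal branch
      if (states5[[b]] == "1") p11 else 1 - p11
    } else {
      down1 <- prod(vapply(kids, f, 0, s = "1"))
      downx <- as.numeric(all(vapply(kids, all_x_below, TRUE)))
      p11 * down1 + (1 - p11) * downx
    }
  }
  kids <- tree$children[[insertion_branch]]
  if (length(kids) == 0) {
    if (states5[[insertion_branch]] == "1") 1 - trans$p0x else trans$p0x
  } else {
    (1 - trans$p0x) * prod(vapply(kids, f, 0, s = "1")) +
      trans$p0x * as.numeric(all(vapply(kids, all_x_below, TRUE)))
  }
}

#' Joint log likelihood of a family's site patterns
#'
#' The joint likelihood factorizes into the Poisson insertion term (which
#' depends only on the rates and the branch counts) and the product of
#' per-pattern deletion terms (which depend only on the deletion
#' parameters):
#' \deqn{\Pr(U | M_i, M_d) = \prod_{i=1}^{9}
#'   \frac{e^{-\phi_i}\phi_i^{N_i}}{N_i!}
#'   \prod_{j=1}^{n} \Pr(U^{(j)} | M_d, T^{(j)}).}
#' The two components are reported separately so either convention
#' (with or without the insertion term) can be compared against published
#' log likelihoods; the difference cancels in likelihood-ratio statistics.
#'
#' @param patterns an \code{erv_patterns} object (one family at a time).
#' @param tree an \code{erv_tree}.
#' @param rates named per-branch insertion rates; defaults to the closed
#'   form MLE \eqn{N_i / T_i} for the supplied patterns.
#' @param params a \code{deletion_params} object.
#' @return a list of class \code{erv_loglik} with elements
#'   \code{insertion}, \code{deletion} (sum of per-pattern terms),
#'   \code{per_pattern}, and \code{total}.
#' @export
joint_log_likelihood <- function(patterns, tree = erv_tree(), rates = NULL,
                                 params) {
  patterns <- validate_patterns(patterns)
  counts <- count_insertions(patterns, tree)
  if (is.null(rates)) rates <- fit_insertion_rates(counts, tree)
  ins <- insertion_log_likelihood(counts, rates, tree)
  per <- if (nrow(patterns) > 0)
    pattern_log_likelihood(patterns, tree, params) else numeric(0)
  structure(list(insertion = ins, deletion = sum(per), per_pattern = per,
                 total = ins + sum(per)),
            class = "erv_loglik")
}

#' @export
print.erv_loglik <- function(x, ...) {
  cat(sprintf("log likelihood: %.4f (insertion %.4f + deletion %.4f)\n",
              x$total, x$insertion, x$deletion))
  invisible(x)
}

# Deletion-only log likelihood of a collapsed (unique pattern, count) table;
# the optimizer's objective. Collapsing makes a likelihood evaluation cost
# O(#unique patterns), at most 70 on this tree.
.deletion_ll_collapsed <- function(upat, n, tree, params) {
  cache <- new.env(parent = emptyenv())
  ll <- vapply(seq_len(nrow(upat)), function(i)
    .pattern_ll_one(setNames(unlist(upat[i, ]), .TIPS), tree, params, cache), 0)
  sum(n * ll)
}

.collapse_patterns <- function(patterns) {
  st <- as.data.frame(as.matrix(patterns[, .STATE_COLS])[, 1:5, drop = FALSE],
                      stringsAsFactors = FALSE)
  names(st) <- .TIPS
  key <- do.call(paste, c(st, sep = ""))
  tab <- table(key)
  upat <- st[match(names(tab), key), , drop = FALSE]
  list(upat = upat, n = as.integer(tab), key = names(tab))
}
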