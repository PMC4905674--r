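#' @useDynLib ervphylo, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim optimize qchisq quantile rbinom rpois runif
#'   setNames fisher.test simulate coef logLik confint anova rmultinom
#'   dpois integrate sd pgamma median
#' @importFrom utils read.delim write.table head
NULL

#' Six-taxon primate host chronogram
#'
#' Constructs the fixed nine-branch chronogram relating human (h), chimp (c),
#' gorilla (g), orangutan (o) and macaque (m), rooted at the ancestor of all
#' five ingroup species after the marmoset split (branch \code{hcgom}).
#' Marmoset is the outgroup and carries no branch: site patterns are always
#' coded absent there. Branch lengths are in millions of years (Myr).
#'
#' The default lengths are derived from the published per-family branch
#' insertion counts and maximum likelihood insertion rates (counts divided by
#' rates, combined across families by least squares; see
#' \code{\link{erv_reference_rates}}). The resulting depths are ultrametric
#' over the five ingroup tips to well within 0.2 Myr.
#'
#' @param lengths optional named numeric vector of branch lengths in Myr;
#'   names must be exactly the nine branch labels
#'   \code{c("h","c","g","o","m","hc","hcg","hcgo","hcgom")}. Missing
#'   (\code{NULL}) means use the derived defaults.
#' @return an object of class \code{erv_tree}: a list with elements
#'   \code{branches}, \code{parent}, \code{children}, \code{lengths} (Myr)
#'   and \code{tip_order}.
#' @examples
#' tr <- erv_tree()
#' tr$lengths
#' post_insertion_branches(tr, "hcg")
#' @export
erv_tree <- function(lengths = NULL) {
  if (is.null(lengths)) lengths <- default_branch_lengths()
  if (is.null(names(lengths)) || !setequal(names(lengths), .BRANCHES))
    stop("'lengths' must be named with exactly the nine branch labels: ",
         paste(.BRANCHES, collapse = ", "))
  lengths <- lengths[.BRANCHES]
  if (anyNA(lengths) || any(lengths <= 0))
    stop("all branch lengths must be strictly positive")
  tree <- structure(
    list(branches = .BRANCHES,
         parent = .PARENT,
         children = .children_map(),
         lengths = lengths,
         tip_order = .TIP_ORDER),
    class = "erv_tree")
  tree
}

#' Default branch lengths derived from published insertion counts and rates
#'
#' The chronogram's branch lengths are not distributed as numerals with the
#' reference tables; they are recovered here from the per-family insertion
#' counts \eqn{N_i} and maximum likelihood relative insertion rates
#' \eqn{\Phi_i = N_i / T_i} by least squares over all families with non-zero
#' rate on a branch: \eqn{T_i = \sum_f N_{if} \Phi_{if} / \sum_f \Phi_{if}^2}.
#'
#' @return named numeric vector of nine branch lengths in Myr.
#' @export
default_branch_lengths <- function() {
  counts <- erv_reference_counts()
  rates <- erv_reference_rates()
  Tlen <- rowSums(counts * rates) / rowSums(rates^2)
  round(Tlen, 4)
}

#' @export
print.erv_tree <- function(x, ...) {
  cat("Six-taxon primate chronogram (", length(x$branches), " branches)\n",
      sep = "")
  cat("Tips (observation order):", paste(x$tip_order, collapse = ", "), "\n")
  cat("Branch lengths (Myr):\n")
  print(round(x$lengths, 3))
  invisible(x)
}

#' Load a host chronogram from a configuration list or file
#'
#' Accepts a named list (or a YAML/JSON file parsing to one) with a
#' \code{branch_lengths} entry (or top-level branch entries) naming all nine
#' branches, and validates it against the fixed topology. Arbitrary
#' topologies are rejected: the pattern semantics and the pruning algorithm
#' assume this nine-branch shape.
#'
#' @param config a named list, or path to a YAML or JSON file.
#' @return an \code{erv_tree}.
#' @export
load_tree <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML config requires the 'yaml' package")
      config <- yaml::read_yaml(config)
    } else if (grepl("\\.json$", config, ignore.case = TRUE)) {
      if (!requireNamespace("jsonlite", quietly = TRUE))
        stop("reading JSON config requires the 'jsonlite' package")
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    } else stop("config file must be .yaml/.yml or .json")
  }
  if (!is.list(config)) stop("'config' must be a named list or a file path")
  lens <- config$branch_lengths
  if (is.null(lens)) lens <- config[intersect(names(config), .BRANCHES)]
  lens <- unlist(lens)
  missing <- setdiff(.BRANCHES, names(lens))
  if (length(missing) > 0)
    stop("config is missing branch lengths for: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(lens), .BRANCHES)
  if (length(extra) > 0)
    stop("config names unknown branches: ", paste(extra, collapse = ", "))
  erv_tree(lengths = lens)
}

#' Read the chronogram from a Newick string with named internal nodes
#'
#' Convenience reader: the Newick tree must carry the five ingroup tips
#' (human, chimp, gorilla, orangutan, macaque; marmoset optional and
#' ignored) and map onto the fixed nine-branch shape, otherwise it is
#' rejected.
#'
#' @param newick a Newick string or path to a file containing one.
#' @return an \code{erv_tree}.
#' @export
read_tree_newick <- function(newick) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("read_tree_newick() requires the 'ape' package")
  phy <- if (file.exists(newick)) ape::read.tree(newick)
         else ape::read.tree(text = newick)
  if (is.null(phy)) stop("could not parse Newick input")
  phy$tip.label <- tolower(phy$tip.label)
  if ("marmoset" %in% phy$tip.label)
    phy <- ape::drop.tip(phy, "marmoset")
  if (!setequal(phy$tip.label, names(.TIP_LETTER)))
    stop("Newick tree must contain tips: ",
         paste(names(.TIP_LETTER), collapse = ", "))
  lens <- numeric(0)
  for (i in seq_along(phy$edge.length)) {
    node <- phy$edge[i, 2]
    if (node <= length(phy$tip.label)) {
      lab <- .TIP_LETTER[[phy$tip.label[node]]]
    } else {
      tips <- phy$tip.label[unlist(ape::prop.part(phy)[[node - length(phy$tip.label)]])]
      lab <- paste(sort(.TIP_LETTER[tips]), collapse = "")
      lab <- .BRANCHES[match(paste(sort(strsplit(lab, "")[[1]]), collapse = ""),
                             vapply(.BRANCHES, function(b)
                               paste(sort(strsplit(b, "")[[1]]), collapse = ""),
                               ""))]
      if (is.na(lab)) stop("Newick topology does not match the fixed shape")
    }
    lens[lab] <- phy$edge.length[i]
  }
  # root branch (hcgom) has no edge in an unrooted/basal reading; require it
  if (!"hcgom" %in% names(lens)) {
    if (!is.null(phy$root.edge) && phy$root.edge > 0) lens["hcgom"] <- phy$root.edge
    else stop("Newick tree must supply a root edge for branch 'hcgom'")
  }
  if (!setequal(names(lens), .BRANCHES))
    stop("Newick topology does not match the fixed nine-branch shape")
  erv_tree(lengths = lens)
}

#' Branches strictly below an insertion branch
#'
#' Returns the post-insertion branches of a given branch: all strict
#' descendants in the chronogram, the branches on which a full-length
#' element may persist (1 to 1) or be reduced to a solo-LTR (1 to x).
#'
#' @param tree an \code{erv_tree}.
#' @param branch a branch label.
#' @return character vector of descendant branch labels (possibly empty).
#' @export
post_insertion_branches <- function(tree, branch) {
  stopifnot(inherits(tree, "erv_tree"))
  if (!branch %in% tree$branches) stop("unknown branch label: ", branch)
  out <- character(0)
  stack <- tree$children[[branch]]
  while (length(stack) > 0) {
    b <- stack[[1]]; stack <- stack[-1]
    out <- c(out, b)
    stack <- c(stack, tree$children[[b]])
  }
  out
}

.ancestors <- function(tree, branch) {
  out <- character(0)
  p <- tree$parent[[branch]]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- tree$parent[[p]]
  }
  out
}

# Time from the origin (top) of `insertion_branch` to the start and end of
# branch `b` in its subtree. Used by the Weibull model's age tracking.
.branch_window <- function(tree, insertion_branch, b) {
  path <- b
  p <- tree$parent[[b]]
  while (!is.na(p) && p != insertion_branch) {
    path <- c(path, p)
    p <- tree$parent[[p]]
  }
  if (is.na(p)) stop(b, " is not below ", insertion_branch)
  t2 <- tree$lengths[[insertion_branch]] + sum(tree$lengths[path])
  c(t1 = t2 - tree$lengths[[b]], t2 = t2)
}
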