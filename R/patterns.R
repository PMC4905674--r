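#' Construct a set of ERV site patterns
#'
#' A site pattern records, for one orthologous ERV locus, the state of the
#' locus in each of six primates in the fixed observation order human,
#' chimp, gorilla, orangutan, macaque, marmoset: \code{"0"} (absent,
#' pre-integration site), \code{"1"} (present in full-length or partial
#' proviral form) or \code{"x"} (solo-LTR). Only the transitions
#' 0 -> 1 -> x can occur, so the non-absent tips of a valid pattern are
#' exactly the tips descending from one branch of the chronogram (the
#' insertion branch), and marmoset, the outgroup, is always \code{"0"}.
#'
#' @param states a character matrix or data frame with 6 columns (or 5; the
#'   marmoset column may be omitted and is filled with \code{"0"}), one row
#'   per locus, entries in \code{c("0","1","x")}.
#' @param family family label recycled over loci.
#' @param location optional genome-location provenance strings.
#' @return an object of class \code{erv_patterns}: a data frame with columns
#'   \code{family}, \code{u_human} ... \code{u_marmoset}, \code{location}.
#' @examples
#' p <- erv_patterns(rbind(c("x","x","x","1","0")), family = "HERV-H")
#' insertion_branch(p)
#' @export
erv_patterns <- function(states, family = "other", location = NA_character_) {
  states <- as.matrix(states)
  if (ncol(states) == 5)
    states <- cbind(states, rep("0", nrow(states)))
  if (ncol(states) != 6)
    stop("'states' must have 5 or 6 columns (tip order human..marmoset)")
  states[] <- as.character(states)
  df <- data.frame(family = rep_len(as.character(family), nrow(states)),
                   states, location = rep_len(location, nrow(states)),
                   stringsAsFactors = FALSE)
  names(df) <- c("family", .STATE_COLS, "location")
  validate_patterns(df)
}

#' Validate site patterns
#'
#' Checks the state alphabet, the outgroup constraint (marmoset absent), and
#' phylogenetic coherence (the non-absent tips must be exactly the tip set
#' below one branch, so that a 0 -> 1 -> x history exists). Incoherent
#' patterns include those suggesting incomplete lineage sorting, which this
#' framework excludes.
#'
#' @param x a data frame with columns \code{family}, \code{u_human} ...
#'   \code{u_marmoset} and optionally \code{location}.
#' @return \code{x} as a validated \code{erv_patterns} object.
#' @export
validate_patterns <- function(x) {
  if (!all(c("family", .STATE_COLS) %in% names(x)))
    stop("pattern table must have columns 'family' and ",
         paste(.STATE_COLS, collapse = ", "))
  if (!"location" %in% names(x)) x$location <- NA_character_
  x <- as.data.frame(x)[, c("family", .STATE_COLS, "location")]
  st <- as.matrix(x[, .STATE_COLS])
  bad <- !(st %in% c("0", "1", "x"))
  dim(bad) <- dim(st)
  bad_sym <- which(bad, arr.ind = TRUE)
  if (nrow(bad_sym) > 0)
    stop("unknown state symbol(s) ",
         paste(unique(st[bad_sym]), collapse = ", "),
         " in row(s) ", paste(unique(bad_sym[, 1]), collapse = ", "),
         " (alphabet is 0, 1, x)")
  if (any(st[, 6] != "0"))
    stop("marmoset (outgroup) state must be '0' in every pattern; row(s): ",
         paste(which(st[, 6] != "0"), collapse = ", "))
  br <- .branch_of_support(st[, 1:5, drop = FALSE])
  if (anyNA(br))
    stop("phylogenetically incoherent pattern(s) in row(s) ",
         paste(which(is.na(br)), collapse = ", "),
         ": the non-absent tips must be exactly the tips below one branch ",
         "(patterns suggesting incomplete lineage sorting are rejected)")
  class(x) <- c("erv_patterns", "data.frame")
  x
}

# vectorized support-set -> branch lookup; NA where incoherent
.branch_of_support <- function(st5) {
  key <- apply(st5 != "0", 1, function(z) paste(.TIPS[z], collapse = ","))
  .BRANCHES[match(key, .SUPPORT_KEY)]
}

#' Insertion branch of each site pattern
#'
#' The first five positions of a pattern identify, uniquely, the branch of
#' the chronogram on which the ERV first appeared: the branch whose
#' descendant tip set equals the set of non-absent tips.
#'
#' @param patterns an \code{erv_patterns} object (or coercible data frame).
#' @param tree an \code{erv_tree} (topology is fixed; present for interface
#'   symmetry).
#' @return character vector of branch labels, one per pattern.
#' @export
insertion_branch <- function(patterns, tree = erv_tree()) {
  patterns <- validate_patterns(patterns)
  st <- as.matrix(patterns[, .STATE_COLS])
  .branch_of_support(st[, 1:5, drop = FALSE])
}

#' Per-branch insertion counts
#'
#' Tabulates the number of patterns whose insertion branch is each of the
#' nine branches. The counts \eqn{N_i} are the sufficient statistic of the
#' Poisson insertion model.
#'
#' @inheritParams insertion_branch
#' @return named integer vector over the nine branches (sums to the number
#'   of patterns).
#' @export
count_insertions <- function(patterns, tree = erv_tree()) {
  br <- insertion_branch(patterns, tree)
  tab <- table(factor(br, levels = .BRANCHES))
  setNames(as.integer(tab), .BRANCHES)
}

#' Enumerate all coherent site patterns with a given insertion branch
#'
#' Every assignment of \code{"1"}/\code{"x"} to the tips below the insertion
#' branch is achievable under the 0 -> 1 -> x process (deletions on terminal
#' branches act independently), so a branch with \eqn{k} descendant tips has
#' \eqn{2^k} coherent patterns.
#'
#' @param branch a branch label.
#' @param family family label for the generated patterns.
#' @return an \code{erv_patterns} object with \eqn{2^k} rows.
#' @export
enumerate_patterns <- function(branch, family = "other") {
  tips <- .tips_below(branch)
  k <- length(tips)
  grid <- as.matrix(expand.grid(rep(list(c("1", "x")), k),
                                stringsAsFactors = FALSE))
  st <- matrix("0", nrow = nrow(grid), ncol = 5,
               dimnames = list(NULL, .TIPS))
  st[, tips] <- grid
  erv_patterns(st, family = family)
}

#' Read site patterns from the native TSV format
#'
#' The native format is a tab-separated table with header columns
#' \code{family}, \code{u_human}, \code{u_chimp}, \code{u_gorilla},
#' \code{u_orangutan}, \code{u_macaque}, \code{u_marmoset} and optionally
#' \code{location}. Invalid rows abort with a diagnostic naming them;
#' nothing is silently dropped.
#'
#' @param file path to a TSV file.
#' @return an \code{erv_patterns} object.
#' @export
read_patterns <- function(file) {
  df <- read.delim(file, colClasses = "character", check.names = FALSE)
  validate_patterns(df)
}

#' Write site patterns to the native TSV format
#' @param patterns an \code{erv_patterns} object.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_patterns <- function(patterns, file) {
  patterns <- validate_patterns(patterns)
  write.table(patterns, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @export
print.erv_patterns <- function(x, ...) {
  cat("ERV site patterns:", nrow(x), "loci,",
      length(unique(x$family)), "family/ies\n")
  br <- insertion_branch(x)
  print(table(family = x$family, branch = factor(br, levels = .BRANCHES)))
  invisible(x)
}
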