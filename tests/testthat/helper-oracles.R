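# Independent oracles used to cross-check the package's algorithms.
# These deliberately re-derive quantities by brute force / naive methods
# and must not share code paths with the implementation.

# Exhaustive enumeration of internal-state assignments for the probability
# of a site pattern given its insertion branch (checks the pruning DP).
brute_force_pattern_prob <- function(states5, tree, params) {
  support <- names(states5)[states5 != "0"]
  b <- NULL
  for (br in tree$branches) {
    tips <- tree$tip_order[1:5]
    tl <- c(human = "h", chimp = "c", gorilla = "g", orangutan = "o",
            macaque = "m")
    below <- local({
      res <- character(0)
      stack <- br
      while (length(stack)) {
        x <- stack[1]; stack <- stack[-1]
        kids <- tree$children[[x]]
        if (length(kids) == 0) res <- c(res, x) else stack <- c(stack, kids)
      }
      res
    })
    if (setequal(below, support)) { b <- br; break }
  }
  stopifnot(!is.null(b))
  post <- local({
    res <- character(0); stack <- tree$children[[b]]
    while (length(stack)) {
      x <- stack[1]; stack <- stack[-1]
      res <- c(res, x); stack <- c(stack, tree$children[[x]])
    }
    res
  })
  # time window of a branch from the insertion-branch origin
  window <- function(bb) {
    path <- bb
    p <- tree$parent[[bb]]
    while (p != b) { path <- c(path, p); p <- tree$parent[[p]] }
    t2 <- tree$lengths[[b]] + sum(tree$lengths[path])
    c(t1 = t2 - tree$lengths[[bb]], t2 = t2)
  }
  t_ins <- tree$lengths[[b]]
  p0x <- pr_delete_insertion_branch(params, t_ins)
  ptrans <- function(bb, s_from, s_to) {
    if (s_from == "x") return(as.numeric(s_to == "x"))
    w <- window(bb)
    p11 <- pr_retain_post_branch(params, w[["t1"]], w[["t2"]], t_ins)
    if (s_to == "1") p11 else 1 - p11
  }
  # state at the END of each branch; tip states are observed, all other
  # branch ends (including a non-terminal insertion branch) are enumerated
  vars <- setdiff(c(b, post), names(states5))
  grids <- if (length(vars) == 0) data.frame(row.names = 1)
  else {
    g <- expand.grid(rep(list(c("1", "x")), length(vars)),
                     stringsAsFactors = FALSE)
    names(g) <- vars
    g
  }
  total <- 0
  for (g in seq_len(nrow(grids))) {
    assign_state <- function(bb) {
      if (bb %in% vars) as.character(grids[g, bb]) else states5[[bb]]
    }
    pr <- if (assign_state(b) == "1") 1 - p0x else p0x
    for (bb in post) {
      pr <- pr * ptrans(bb, assign_state(tree$parent[[bb]]), assign_state(bb))
      if (pr == 0) break
    }
    total <- total + pr
  }
  total
}

# Naive run-length encoder over matrix columns (checks partition_prepatterns
# before the width filter).
naive_column_runs <- function(codes) {
  m <- ncol(codes)
  runs <- list()
  start <- 1
  for (j in seq_len(m)) {
    if (j == m || !identical(codes[, j], codes[, j + 1])) {
      runs[[length(runs) + 1]] <- c(start = start, end = j)
      start <- j + 1
    }
  }
  do.call(rbind, runs)
}

# Quadratic brute-force window scan over pre-patterns (checks
# scan_candidates).
naive_scan <- function(P, require_outgroup_gap = TRUE) {
  n <- ncol(P)
  out <- list()
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 2):n) {
    if (!all(P[, i] == "d") || !all(P[, j] == "d")) next
    interior <- P[, (i + 1):(j - 1), drop = FALSE]
    common <- FALSE
    for (q in 1:6) {
      r <- interior[q, ]
      if (all(r == r[1]) && grepl("^[sc]-", r[1])) { common <- TRUE; break }
    }
    if (!common) next
    if (!any(apply(interior, 1, function(r) all(r == "g")))) next
    if (require_outgroup_gap && !all(interior[6, ] == "g")) next
    out[[length(out) + 1]] <- c(i = i, j = j)
  }
  if (length(out)) do.call(rbind, out) else
    matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
}

# Second, independent interpreter of the four coding rules (checks
# code_pattern).
naive_code <- function(interior) {
  u <- rep(NA_character_, 6)
  has <- function(q, prefix) any(grepl(paste0("^", prefix, "-"), interior[q, ]))
  for (q in 1:5) if (has(q, "s")) u[q] <- "x"
  for (q in 1:5) if (has(q, "c")) u[q] <- "1"
  one_assigned <- isTRUE(any(u == "1", na.rm = TRUE))
  for (q in 1:5) {
    if (!is.na(u[q])) next
    if (all(interior[q, ] == "g")) u[q] <- "0"
    else u[q] <- if (one_assigned) "1" else "x"
  }
  u[6] <- "0"
  u
}

# random deletion parameter draws for property tests
random_params <- function(model, seed) {
  set.seed(seed)
  if (model == "exponential")
    deletion_params("exponential", psi = exp(runif(1, log(0.02), log(1))))
  else
    deletion_params("weibull", psi = exp(runif(1, log(0.5), log(30))),
                    omega = exp(runif(1, log(0.15), log(2))))
}

state_matrix <- function(patterns)
  as.matrix(patterns[, paste0("u_", c("human", "chimp", "gorilla",
                                      "orangutan", "macaque", "marmoset"))])
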