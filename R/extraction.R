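#' Classify an annotated six-way alignment
#'
#' Combines a six-row multiple alignment with per-species repeat-annotation
#' intervals into a 6 x m classification matrix whose cells are coded
#' \code{"d"} (unannotated nucleotide), \code{"g"} (gap),
#' \code{"s-<family>-<instance>"} (solo-LTR) or
#' \code{"c-<family>-<instance>"} (partial or full-length ERV). Annotation
#' intervals are 0-based half-open in ungapped per-species coordinates and
#' strandless: the pattern state of a locus does not depend on strand.
#' Nested annotations are not modelled; overlapping intervals within a
#' species are an error (outer-element-wins resolution is expected
#' upstream).
#'
#' @param alignment named character vector of six aligned sequences (names
#'   human, chimp, gorilla, orangutan, macaque, marmoset; gaps \code{"-"}),
#'   or a 6 x m character matrix.
#' @param annotations data frame with columns \code{species}, \code{start},
#'   \code{end} (0-based half-open, ungapped), \code{code} (\code{"s"} or
#'   \code{"c"}), \code{family}, and optionally \code{instance} (assigned
#'   sequentially per species when absent).
#' @return an object of class \code{erv_classification}: list with
#'   \code{codes} (6 x m code matrix), \code{alignment} (6 x m base
#'   matrix).
#' @export
classify_alignment <- function(alignment, annotations) {
  aln <- .as_alignment_matrix(alignment)
  m <- ncol(aln)
  codes <- matrix("d", nrow = 6, ncol = m)
  codes[aln == "-"] <- "g"
  rownames(codes) <- rownames(aln) <- .TIP_ORDER
  if (is.null(annotations) || nrow(annotations) == 0)
    return(structure(list(codes = codes, alignment = aln),
                     class = "erv_classification"))
  need <- c("species", "start", "end", "code", "family")
  if (!all(need %in% names(annotations)))
    stop("annotations need columns: ", paste(need, collapse = ", "))
  if (!"instance" %in% names(annotations)) {
    annotations$instance <- stats::ave(seq_len(nrow(annotations)),
                                       annotations$species,
                                       FUN = seq_along)
  }
  for (sp in unique(annotations$species)) {
    if (!sp %in% .TIP_ORDER) stop("unknown species: ", sp)
    row <- match(sp, .TIP_ORDER)
    ungapped_cols <- which(aln[row, ] != "-")
    len <- length(ungapped_cols)
    ann <- annotations[annotations$species == sp, , drop = FALSE]
    ann <- ann[order(ann$start), , drop = FALSE]
    if (nrow(ann) > 1 && any(ann$start[-1] < ann$end[-nrow(ann)]))
      stop("overlapping annotations in species ", sp)
    for (k in seq_len(nrow(ann))) {
      if (ann$end[k] > len || ann$start[k] < 0 || ann$start[k] >= ann$end[k])
        stop("annotation interval [", ann$start[k], ", ", ann$end[k],
             ") out of range for species ", sp, " (length ", len, ")")
      if (!ann$code[k] %in% c("s", "c"))
        stop("annotation code must be 's' or 'c', got: ", ann$code[k])
      cols <- ungapped_cols[(ann$start[k] + 1):ann$end[k]]
      codes[row, cols] <- paste(ann$code[k], ann$family[k],
                                ann$instance[k], sep = "-")
    }
  }
  structure(list(codes = codes, alignment = aln),
            class = "erv_classification")
}

.as_alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    aln <- alignment
  } else {
    if (is.null(names(alignment)))
      names(alignment) <- .TIP_ORDER[seq_along(alignment)]
    alignment <- alignment[.TIP_ORDER]
    if (anyNA(alignment)) stop("alignment must name all six species")
    n <- unique(nchar(alignment))
    if (length(n) != 1) stop("aligned sequences differ in length")
    aln <- do.call(rbind, strsplit(toupper(alignment), ""))
  }
  if (nrow(aln) != 6) stop("alignment must have six rows")
  aln
}

#' Collapse a classification matrix into pre-patterns
#'
#' Partitions the matrix into the minimal number of adjacent column blocks
#' within which every column is identical (a run-length encoding over
#' columns), then drops blocks narrower than \code{min_width} columns
#' (regions too short to interpret reliably; 50 by default). Consecutive
#' retained pre-patterns may be equal after the drop; they are not
#' re-merged, preserving the positional bookkeeping.
#'
#' @param classification an \code{erv_classification} (or a bare 6 x m code
#'   matrix).
#' @param min_width minimum run width in columns.
#' @return an object of class \code{erv_prepatterns}: list with
#'   \code{columns} (6 x n code matrix, one column per retained
#'   pre-pattern), \code{width}, \code{col_start}, \code{col_end}
#'   (alignment column ranges, 1-based inclusive), and the
#'   \code{classification} when one was supplied.
#' @export
partition_prepatterns <- function(classification, min_width = 50) {
  codes <- if (inherits(classification, "erv_classification"))
    classification$codes else classification
  m <- ncol(codes)
  if (m == 0) stop("empty classification matrix")
  key <- apply(codes, 2, paste, collapse = "\r")
  change <- c(TRUE, key[-1] != key[-m])
  starts <- which(change)
  ends <- c(starts[-1] - 1L, m)
  keep <- (ends - starts + 1L) >= min_width
  structure(list(columns = codes[, starts[keep], drop = FALSE],
                 width = (ends - starts + 1L)[keep],
                 col_start = starts[keep], col_end = ends[keep],
                 classification =
                   if (inherits(classification, "erv_classification"))
                     classification else NULL),
            class = "erv_prepatterns")
}

.is_all_d <- function(col) all(col == "d")

#' Scan pre-patterns for candidate ERV loci
#'
#' Identifies windows of pre-patterns that can be interpreted as one
#' orthologous ERV locus: length at least 3, anchored at both ends by
#' all-\code{"d"} pre-patterns, with (i) some row carrying one common
#' solo-LTR or ERV instance across the whole interior, and (ii) some row
#' gapped across the whole interior. By default the outgroup restriction is
#' applied as well: marmoset must be gapped across the interior (the locus
#' arose after the marmoset split). Because an interior all-\code{"d"}
#' pre-pattern defeats the common-instance condition, qualifying windows
#' are exactly those between consecutive all-\code{"d"} anchors.
#'
#' @param prepatterns an \code{erv_prepatterns}.
#' @param require_outgroup_gap apply the marmoset restriction (default
#'   TRUE).
#' @return an object of class \code{erv_candidates}: data frame with
#'   columns \code{i}, \code{j} (anchor indices into the pre-pattern
#'   sequence) and \code{instance} (the common instance code), carrying the
#'   pre-patterns in attribute \code{prepatterns}.
#' @export
scan_candidates <- function(prepatterns, require_outgroup_gap = TRUE) {
  P <- prepatterns$columns
  n <- ncol(P)
  anchors <- which(apply(P, 2, .is_all_d))
  out <- list()
  if (length(anchors) >= 2) {
    for (a in seq_len(length(anchors) - 1)) {
      i <- anchors[a]; j <- anchors[a + 1]
      if (j - i + 1 < 3) next
      interior <- P[, (i + 1):(j - 1), drop = FALSE]
      inst <- .common_instance(interior)
      if (is.na(inst)) next
      if (!any(apply(interior, 1, function(r) all(r == "g")))) next
      if (require_outgroup_gap && !all(interior[6, ] == "g")) next
      out[[length(out) + 1]] <- data.frame(i = i, j = j, instance = inst)
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out)
  else data.frame(i = integer(0), j = integer(0), instance = character(0))
  attr(res, "prepatterns") <- prepatterns
  class(res) <- c("erv_candidates", "data.frame")
  res
}

# the first s-*/c-* instance code shared by every interior pre-pattern in
# some row, or NA
.common_instance <- function(interior) {
  for (q in 1:6) {
    r <- interior[q, ]
    if (all(r == r[1]) && grepl("^[sc]-", r[1])) return(r[1])
  }
  NA_character_
}

#' Code a candidate window into a site pattern
#'
#' Applies the four-rule heuristic per species row over the window's
#' interior pre-patterns: any solo-LTR code gives \code{"x"}; any ERV code
#' gives \code{"1"} (applied after the solo rule, so a row carrying both is
#' coded \code{"1"}); an all-gap row gives \code{"0"}; an all-unannotated
#' row inherits \code{"1"} if a \code{"1"} was assigned by the earlier
#' rules and \code{"x"} otherwise (complete alignment to an annotated
#' sequence lets an unannotated row inherit by homology). Rows mixing only
#' \code{"d"} and \code{"g"} fall to the unannotated rule. Marmoset is
#' always \code{"0"}.
#'
#' @param candidates an \code{erv_candidates} (all rows are coded), or an
#'   \code{erv_prepatterns} plus explicit \code{i}, \code{j}.
#' @param i,j anchor indices when \code{candidates} is an
#'   \code{erv_prepatterns}.
#' @return a character matrix (one row per candidate, 6 columns of states).
#' @export
code_pattern <- function(candidates, i = NULL, j = NULL) {
  if (inherits(candidates, "erv_prepatterns")) {
    P <- candidates$columns
    return(.code_one(P[, (i + 1):(j - 1), drop = FALSE]))
  }
  pp <- attr(candidates, "prepatterns")
  t(vapply(seq_len(nrow(candidates)), function(k) {
    .code_one(pp$columns[, (candidates$i[k] + 1):(candidates$j[k] - 1),
                         drop = FALSE])
  }, character(6)))
}

.code_one <- function(interior) {
  u <- rep(NA_character_, 6)
  for (q in 1:5) {
    r <- interior[q, ]
    if (any(startsWith(r, "s-"))) u[q] <- "x"
    if (any(startsWith(r, "c-"))) u[q] <- "1"
    if (is.na(u[q]) && all(r == "g")) u[q] <- "0"
  }
  any1 <- any(u == "1", na.rm = TRUE)
  u[is.na(u)] <- if (any1) "1" else "x"
  u[6] <- "0"
  u
}

#' Post-filter coded patterns using the backing alignment
#'
#' Removes patterns whose 5' or 3' anchoring flank spans fewer than
#' \code{min_flank} nucleotides or whose inter-flank region is backed by
#' fewer than \code{min_interflank} called nucleotides (in the best-backed
#' row); both thresholds are inclusive. For mixed patterns (both \code{"1"}
#' and \code{"x"} present) the solo-LTR relabelling heuristic is applied:
#' an \code{"x"} becomes \code{"1"} when the fraction of some \code{"1"}
#' row's called inter-flank sequence that the \code{"x"} row matches
#' identically (same base, both called) reaches \code{threshold}
#' (\code{relabel = "identity"}, the default) — i.e. the "solo" call
#' actually spans nearly the whole element. The simpler length-ratio
#' variant (\code{relabel = "length"}: called length of the \code{"x"} row
#' at least \code{threshold} times the \code{"1"} row's) is available for
#' comparison.
#'
#' @param candidates an \code{erv_candidates} whose pre-patterns carry a
#'   classification (alignment backing).
#' @param min_flank minimum flank width, nucleotides.
#' @param min_interflank minimum called backing of the inter-flank region,
#'   nucleotides.
#' @param relabel \code{"identity"}, \code{"length"}, or \code{"none"}.
#' @param threshold relabelling threshold (default 0.85).
#' @return an \code{erv_patterns} object (family taken from the common
#'   instance), with attributes \code{mixed} (logical: pattern contains
#'   both 1 and x after relabelling, flagged for review), \code{dropped}
#'   (counts by reason) and \code{kept} (row indices into
#'   \code{candidates}).
#' @export
postfilter <- function(candidates, min_flank = 100, min_interflank = 250,
                       relabel = c("identity", "length", "none"),
                       threshold = 0.85) {
  relabel <- match.arg(relabel)
  pp <- attr(candidates, "prepatterns")
  if (is.null(pp$classification))
    stop("post-filtering needs alignment backing ",
         "(classify_alignment -> partition_prepatterns)")
  aln <- pp$classification$alignment
  states <- code_pattern(candidates)
  keep <- logical(nrow(candidates))
  dropped <- c(flank5 = 0L, flank3 = 0L, interflank = 0L)
  fams <- character(nrow(candidates))
  for (k in seq_len(nrow(candidates))) {
    i <- candidates$i[k]; j <- candidates$j[k]
    if (pp$width[i] < min_flank) { dropped["flank5"] <- dropped["flank5"] + 1L; next }
    if (pp$width[j] < min_flank) { dropped["flank3"] <- dropped["flank3"] + 1L; next }
    cols <- pp$col_start[i + 1]:pp$col_end[j - 1]
    called <- rowSums(aln[, cols, drop = FALSE] != "-")
    if (max(called) < min_interflank) {
      dropped["interflank"] <- dropped["interflank"] + 1L; next
    }
    keep[k] <- TRUE
    fams[k] <- sub("^[sc]-(.*)-[^-]+$", "\\1", candidates$instance[k])
    if (relabel != "none") {
      u <- states[k, ]
      xs <- which(u == "x"); ones <- which(u == "1")
      if (length(xs) > 0 && length(ones) > 0) {
        for (q in xs) {
          for (r in ones) {
            if (relabel == "identity") {
              both <- aln[q, cols] != "-" & aln[r, cols] != "-"
              num <- sum(both & aln[q, cols] == aln[r, cols])
              den <- sum(aln[r, cols] != "-")
            } else {
              num <- sum(aln[q, cols] != "-")
              den <- sum(aln[r, cols] != "-")
            }
            if (den > 0 && num / den >= threshold) { u[q] <- "1"; break }
          }
        }
        states[k, ] <- u
      }
    }
  }
  st <- states[keep, , drop = FALSE]
  out <- erv_patterns(st, family = fams[keep])
  attr(out, "mixed") <- apply(st, 1, function(u)
    any(u == "1") && any(u == "x"))
  attr(out, "dropped") <- dropped
  attr(out, "kept") <- which(keep)
  out
}

#' Extract site patterns from an annotated alignment
#'
#' The full pipeline: \code{\link{classify_alignment}} ->
#' \code{\link{partition_prepatterns}} -> \code{\link{scan_candidates}} ->
#' \code{\link{code_pattern}} -> \code{\link{postfilter}}. Coded patterns
#' that are phylogenetically incoherent (a support set matching no branch,
#' as expected under incomplete lineage sorting) are dropped with a logged
#' count rather than passed on.
#'
#' @inheritParams classify_alignment
#' @param min_prepattern minimum pre-pattern width (columns).
#' @param min_flank,min_interflank,relabel,threshold see
#'   \code{\link{postfilter}}.
#' @return an \code{erv_patterns} object with attributes \code{mixed},
#'   \code{dropped} (including \code{incoherent}) as in
#'   \code{\link{postfilter}}.
#' @export
extract_patterns <- function(alignment, annotations, min_prepattern = 50,
                             min_flank = 100, min_interflank = 250,
                             relabel = "identity", threshold = 0.85) {
  cl <- classify_alignment(alignment, annotations)
  pp <- partition_prepatterns(cl, min_width = min_prepattern)
  cand <- scan_candidates(pp)
  if (nrow(cand) == 0) {
    out <- erv_patterns(matrix(character(0), 0, 5))
    attr(out, "dropped") <- c(flank5 = 0L, flank3 = 0L, interflank = 0L,
                              incoherent = 0L)
    attr(out, "mixed") <- logical(0)
    return(out)
  }
  filtered <- postfilter(cand, min_flank = min_flank,
                         min_interflank = min_interflank,
                         relabel = relabel, threshold = threshold)
  st <- as.matrix(filtered[, .STATE_COLS])
  coher <- !is.na(.branch_of_support(st[, 1:5, drop = FALSE]))
  out <- validate_patterns(filtered[coher, , drop = FALSE])
  attr(out, "mixed") <- attr(filtered, "mixed")[coher]
  attr(out, "dropped") <- c(attr(filtered, "dropped"),
                            incoherent = sum(!coher))
  out
}

#' Generate a toy annotated alignment with known extraction truth
#'
#' Builds a six-way alignment, its per-species annotation track and the
#' ground-truth site patterns for a list of planted ERV elements, emulating
#' the kind of input an alignment + repeat-annotation pipeline produces.
#' Each plant specifies a state per species: \code{"1"} rows carry
#' LTR-internal-LTR, \code{"x"} rows carry a single LTR aligned to the
#' 5' LTR, \code{"0"} rows are gapped across the element. Plants are
#' separated by unannotated flanks shared by all species. Marmoset is
#' always absent. Optionally, an \code{"x"} row may be made to span a given
#' fraction of the full element while still being annotated as a solo-LTR
#' (\code{solo_span}), to exercise the relabelling heuristic, and per-site
#' substitution noise can be added (\code{divergence}).
#'
#' @param plants list of plant specifications; each a list with elements
#'   \code{pattern} (character vector of 5 or 6 states), \code{family},
#'   and optional \code{ltr} (LTR length, default 300), \code{internal}
#'   (internal length, default 600), \code{solo_span} (named numeric,
#'   fraction of the full element covered by a solo-annotated row).
#' @param flank flank length in bp (default 150).
#' @param divergence per-site substitution probability applied
#'   independently per species (default 0).
#' @param seed integer seed.
#' @return a list: \code{alignment} (named aligned sequences),
#'   \code{annotations} (data frame), \code{truth} (an
#'   \code{erv_patterns} of the planted coherent patterns),
#'   \code{truth_all} (all planted patterns, coherent or not).
#' @export
make_fixture_alignment <- function(plants, flank = 150, divergence = 0,
                                   seed = 1) {
  set.seed(seed)
  rand_seq <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)
  rows <- lapply(1:6, function(i) character(0))
  ann <- list()
  inst_counter <- setNames(rep(0L, 6), .TIP_ORDER)
  truth <- list()
  add_block <- function(block) {
    for (i in 1:6) rows[[i]] <<- c(rows[[i]], block[[i]])
  }
  flank_block <- function() {
    fl <- rand_seq(flank)
    lapply(1:6, function(i) fl)
  }
  add_block(flank_block())
  for (p in plants) {
    pat <- p$pattern
    if (length(pat) == 5) pat <- c(pat, "0")
    if (length(pat) != 6 || any(!pat %in% c("0", "1", "x")))
      stop("plant pattern must be 5 or 6 states over 0/1/x")
    if (pat[6] != "0") stop("marmoset must be absent in planted elements")
    ltr <- p$ltr %||% 300L
    internal <- p$internal %||% 600L
    full_len <- 2L * ltr + internal
    ltr_seq <- rand_seq(ltr)
    int_seq <- rand_seq(internal)
    elem <- c(ltr_seq, int_seq, ltr_seq)
    seg2_present <- any(pat == "1")
    block <- vector("list", 6)
    for (i in 1:6) {
      sp <- .TIP_ORDER[i]
      span <- full_len                      # columns carrying sequence
      if (pat[i] == "1") {
        seq_i <- elem
      } else if (pat[i] == "x") {
        frac <- if (!is.null(p$solo_span) && sp %in% names(p$solo_span))
          p$solo_span[[sp]] else ltr / full_len
        span <- as.integer(max(1, round(frac * full_len)))
        seq_i <- elem[seq_len(span)]
      } else {
        span <- 0L
        seq_i <- character(0)
      }
      width <- if (seg2_present) full_len else
        as.integer(max(c(1, vapply(seq_along(pat), function(k) {
          if (pat[k] == "x") {
            spk <- .TIP_ORDER[k]
            fr <- if (!is.null(p$solo_span) && spk %in% names(p$solo_span))
              p$solo_span[[spk]] else ltr / full_len
            max(1, round(fr * full_len))
          } else 0
        }, numeric(1)))))
      block[[i]] <- c(seq_i, rep("-", width - span))
      if (pat[i] %in% c("1", "x")) {
        inst_counter[sp] <- inst_counter[sp] + 1L
        start0 <- sum(rows[[i]] != "-")
        ann[[length(ann) + 1]] <- data.frame(
          species = sp, start = start0, end = start0 + span,
          code = if (pat[i] == "x") "s" else "c",
          family = p$family %||% "other",
          instance = inst_counter[sp])
      }
    }
    add_block(block)
    add_block(flank_block())
    truth[[length(truth) + 1]] <- data.frame(
      family = p$family %||% "other",
      t(setNames(pat, .STATE_COLS)), location = NA_character_,
      check.names = FALSE)
  }
  aln <- vapply(rows, paste, "", collapse = "")
  names(aln) <- .TIP_ORDER
  if (divergence > 0) {
    for (i in 1:6) {
      ch <- strsplit(aln[i], "")[[1]]
      idx <- which(ch != "-" & runif(length(ch)) < divergence)
      ch[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
      aln[i] <- paste(ch, collapse = "")
    }
  }
  truth_all <- do.call(rbind, truth)
  st <- as.matrix(truth_all[, .STATE_COLS])
  coher <- !is.na(.branch_of_support(st[, 1:5, drop = FALSE])) &
    st[, 6] == "0" & rowSums(st != "0") > 0
  list(alignment = aln,
       annotations = do.call(rbind, ann),
       truth = validate_patterns(truth_all[coher, , drop = FALSE]),
       truth_all = truth_all)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
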