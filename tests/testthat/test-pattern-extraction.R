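test_that("classification codes nucleotides, gaps and annotations", {
  # unannotated gapless alignment is all-d
  aln <- setNames(rep(strrep("ACGT", 25), 6),
                  c("human", "chimp", "gorilla", "orangutan", "macaque",
                    "marmoset"))
  cl <- classify_alignment(aln, NULL)
  expect_true(all(cl$codes == "d"))
  # gaps propagate to g cells; annotated interval maps through gaps
  aln2 <- aln
  aln2["chimp"] <- paste0(strrep("-", 20), substr(aln2["chimp"], 21, 100))
  ann <- data.frame(species = "human", start = 10, end = 40, code = "c",
                    family = "HERV-H", instance = 1)
  cl2 <- classify_alignment(aln2, ann)
  expect_true(all(cl2$codes[2, 1:20] == "g"))
  expect_true(all(cl2$codes[1, 11:40] == "c-HERV-H-1"))
  expect_true(all(cl2$codes[1, c(1:10, 41:100)] == "d"))
  # interval past the ungapped length is rejected
  expect_error(classify_alignment(aln2, data.frame(
    species = "chimp", start = 60, end = 90, code = "s", family = "f",
    instance = 1)), "out of range")
  expect_error(classify_alignment(aln, data.frame(
    species = "human", start = c(0, 5), end = c(10, 15),
    code = c("c", "s"), family = "f", instance = 1:2)), "overlapping")
})

test_that("pre-pattern partition is a width-filtered run-length encoding", {
  # constant matrix collapses to a single pre-pattern
  const <- matrix("d", 6, 200)
  pp <- partition_prepatterns(const)
  expect_identical(ncol(pp$columns), 1L)
  expect_identical(pp$width, 200L)
  # widths 60 / 49 / 70: the 49-column run is dropped
  m <- cbind(matrix("d", 6, 60),
             matrix(c("g", rep("d", 5)), 6, 49),
             matrix(c("g", "g", rep("d", 4)), 6, 70))
  pp2 <- partition_prepatterns(m)
  expect_identical(ncol(pp2$columns), 2L)
  expect_identical(pp2$width, c(60L, 70L))
  # random matrices: unfiltered run widths always recover the column count
  set.seed(61)
  for (r in 1:20) {
    mm <- matrix(sample(c("d", "g"), 6 * 50, TRUE,
                        prob = c(0.8, 0.2)), 6)
    runs <- naive_column_runs(mm)
    pp3 <- partition_prepatterns(mm, min_width = 1)
    expect_identical(sum(pp3$width), 50L)
    expect_identical(length(pp3$width), nrow(runs))
    expect_identical(as.integer(pp3$col_start), as.integer(runs[, "start"]))
  }
})

test_that("candidate scan equals the quadratic brute-force window check", {
  mk <- function(...) matrix(c(...), nrow = 6)
  # the worked single-candidate example
  P <- mk(rep("d", 6),
          c("s-F-1", "s-F-1", "s-F-1", "c-F-1", "g", "g"),
          rep("d", 6))
  pp <- structure(list(columns = P, width = c(100L, 300L, 100L),
                       col_start = c(1L, 101L, 401L),
                       col_end = c(100L, 400L, 500L),
                       classification = NULL),
                  class = "erv_prepatterns")
  cand <- scan_candidates(pp)
  expect_identical(nrow(cand), 1L)
  expect_identical(c(cand$i, cand$j), c(1L, 3L))
  # no all-gap row in the interior: condition fails
  P2 <- P; P2[5:6, 2] <- c("d", "g")
  # interior has marmoset gapped but no other row gapped... still one row
  # (marmoset) is all-g, so the window passes; remove that too
  P3 <- P; P3[5:6, 2] <- c("d", "d")
  pp3 <- pp; pp3$columns <- P3
  expect_identical(nrow(scan_candidates(pp3)), 0L)
  # randomized sequences against the O(n^2) oracle
  set.seed(71)
  alphabet <- c("d", "g", "s-A-1", "s-A-2", "c-B-1", "c-B-2")
  for (r in 1:25) {
    n <- sample(5:40, 1)
    P <- matrix(sample(alphabet, 6 * n, TRUE,
                       prob = c(0.35, 0.25, 0.1, 0.1, 0.1, 0.1)), 6, n)
    # seed some all-d anchors so windows exist
    P[, sample(n, max(2, n %/% 4))] <- "d"
    ppr <- structure(list(columns = P, width = rep(60L, n),
                          col_start = seq_len(n), col_end = seq_len(n),
                          classification = NULL),
                     class = "erv_prepatterns")
    got <- scan_candidates(ppr, require_outgroup_gap = FALSE)
    want <- naive_scan(P, require_outgroup_gap = FALSE)
    expect_identical(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_identical(as.integer(got$i), as.integer(want[, "i"]))
      expect_identical(as.integer(got$j), as.integer(want[, "j"]))
    }
    got_m <- scan_candidates(ppr, require_outgroup_gap = TRUE)
    want_m <- naive_scan(P, require_outgroup_gap = TRUE)
    expect_identical(nrow(got_m), nrow(want_m))
  }
})

test_that("coding rules follow the published order on the worked example", {
  interior <- matrix(c("s-F-1", "s-F-1", "s-F-1", "c-F-1", "g", "g"), 6, 1)
  P <- cbind(rep("d", 6), interior, rep("d", 6))
  pp <- structure(list(columns = P, width = c(100L, 300L, 100L),
                       col_start = c(1L, 101L, 401L),
                       col_end = c(100L, 400L, 500L),
                       classification = NULL),
                  class = "erv_prepatterns")
  expect_identical(code_pattern(pp, i = 1, j = 3),
                   c("x", "x", "x", "1", "0", "0"))
  # all-gap rows 2-5 with an ERV in row 1
  interior2 <- matrix(c("c-F-1", "g", "g", "g", "g", "g"), 6, 1)
  pp$columns <- cbind(rep("d", 6), interior2, rep("d", 6))
  expect_identical(code_pattern(pp, i = 1, j = 3),
                   c("1", "0", "0", "0", "0", "0"))
  # unannotated row inherits 1 when a 1 exists, x otherwise
  interior3 <- matrix(c("d", "c-F-1", "g", "g", "g", "g"), 6, 1)
  pp$columns <- cbind(rep("d", 6), interior3, rep("d", 6))
  expect_identical(code_pattern(pp, i = 1, j = 3)[1:2], c("1", "1"))
  interior4 <- matrix(c("d", "s-F-1", "g", "g", "g", "g"), 6, 1)
  pp$columns <- cbind(rep("d", 6), interior4, rep("d", 6))
  expect_identical(code_pattern(pp, i = 1, j = 3)[1:2], c("x", "x"))
  # a row with both solo and ERV codes resolves to 1 (rule order)
  interior5 <- cbind(c("s-F-1", "g", "g", "g", "g", "g"),
                     c("c-F-1", "g", "g", "g", "g", "g"))
  pp$columns <- cbind(rep("d", 6), interior5, rep("d", 6))
  expect_identical(code_pattern(pp, i = 1, j = 4)[1], "1")
})

test_that("coding rules equal an independent rule interpreter", {
  set.seed(81)
  alphabet <- c("d", "g", "s-A-1", "c-B-1")
  for (r in 1:40) {
    w <- sample(1:4, 1)
    interior <- matrix(sample(alphabet, 6 * w, TRUE), 6, w)
    P <- cbind(rep("d", 6), interior, rep("d", 6))
    pp <- structure(list(columns = P, width = rep(100L, w + 2),
                         col_start = seq_len(w + 2),
                         col_end = seq_len(w + 2),
                         classification = NULL),
                    class = "erv_prepatterns")
    expect_identical(code_pattern(pp, i = 1, j = w + 2),
                     naive_code(interior))
  }
})

test_that("post-filters drop thin flanks and thin backing", {
  fx <- make_fixture_alignment(list(
    list(pattern = c("x", "x", "x", "1", "0"), family = "HERV-H")),
    flank = 150, seed = 5)
  cl <- classify_alignment(fx$alignment, fx$annotations)
  pp <- partition_prepatterns(cl)
  cand <- scan_candidates(pp)
  expect_identical(nrow(cand), 1L)
  # flank threshold is inclusive at 100; the 150 bp flank passes, and
  # raising the threshold just past it drops the pattern
  kept <- postfilter(cand, min_flank = 150)
  expect_identical(nrow(kept), 1L)
  dropped <- postfilter(cand, min_flank = 151)
  expect_identical(nrow(dropped), 0L)
  expect_identical(sum(attr(dropped, "dropped")), 1L)
  # inter-flank backing threshold is inclusive as well
  backing <- 2 * 300 + 600
  expect_identical(nrow(postfilter(cand, min_interflank = backing)), 1L)
  expect_identical(nrow(postfilter(cand, min_interflank = backing + 1)), 0L)
})

test_that("the 85% heuristic relabels near-full-length solo calls only", {
  fx <- make_fixture_alignment(list(
    list(pattern = c("x", "1", "0", "0", "0"), family = "F",
         solo_span = c(human = 0.9)),
    list(pattern = c("x", "1", "0", "0", "0"), family = "F")),
    seed = 6)
  got <- extract_patterns(fx$alignment, fx$annotations)
  st <- state_matrix(got)
  # the 90%-span solo is relabelled full-length; the true solo is kept
  expect_identical(unname(st[1, 1:2]), c("1", "1"))
  expect_identical(unname(st[2, 1:2]), c("x", "1"))
  # the length-ratio variant behaves the same way on this fixture
  got_len <- extract_patterns(fx$alignment, fx$annotations,
                              relabel = "length")
  expect_identical(state_matrix(got_len)[, 1], st[, 1])
  # with relabelling off both stay solo
  got_none <- extract_patterns(fx$alignment, fx$annotations,
                               relabel = "none")
  expect_identical(unname(state_matrix(got_none)[, 1]), c("x", "x"))
})

test_that("extraction recovers planted patterns exactly (recall = precision = 1)", {
  set.seed(91)
  branches <- c("h", "c", "g", "o", "m", "hc", "hcg", "hcgo", "hcgom")
  plants <- lapply(1:30, function(i) {
    b <- sample(branches, 1)
    en <- state_matrix(enumerate_patterns(b))
    list(pattern = unname(en[sample(nrow(en), 1), ]),
         family = sample(c("HERV-H", "ERV9"), 1))
  })
  fx <- make_fixture_alignment(plants, seed = 17)
  got <- extract_patterns(fx$alignment, fx$annotations)
  expect_identical(nrow(got), length(plants))
  want <- state_matrix(fx$truth)
  have <- state_matrix(got)
  expect_identical(unname(have), unname(want))
  expect_identical(got$family, fx$truth$family)
  expect_identical(attr(got, "dropped")[["incoherent"]], 0L)
})

test_that("sub-50 bp remnants leave no pattern", {
  fx <- make_fixture_alignment(list(
    list(pattern = c("x", "0", "0", "0", "0"), family = "F", ltr = 40,
         internal = 0)),
    seed = 7)
  got <- extract_patterns(fx$alignment, fx$annotations)
  expect_identical(nrow(got), 0L)
})

test_that("marmoset-present windows are excluded by the outgroup rule", {
  # build a pre-pattern sequence where marmoset carries sequence across the
  # interior; the default scan must reject it
  P <- cbind(rep("d", 6),
             c("c-F-1", "g", "g", "g", "g", "d"),
             rep("d", 6))
  pp <- structure(list(columns = P, width = c(100L, 300L, 100L),
                       col_start = 1:3, col_end = 1:3,
                       classification = NULL),
                  class = "erv_prepatterns")
  expect_identical(nrow(scan_candidates(pp)), 0L)
  expect_identical(nrow(scan_candidates(pp, require_outgroup_gap = FALSE)),
                   1L)
})
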