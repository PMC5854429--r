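# Structural observables: unwrapped-bp counting, contact ratios against the
# brute-force scan, end-asymmetry normalization, and stage stitching.

test_that("unwrapping needs > threshold displacement pointing outward", {
  ref <- toy_reference()
  frame <- ref$coords
  expect_equal(count_unwrapped(frame, ref)$total, 0)
  # outermost end1 unit displaced radially outward just over threshold
  f1 <- frame
  f1["u6", ] <- f1["u6", ] * (1 + 4.0001 / 10)
  expect_equal(unlist(count_unwrapped(f1, ref)[c("n_end1", "n_end2")]),
               c(n_end1 = 1, n_end2 = 0))
  # exactly 4.0 A is not unwrapped (strict inequality)
  f2 <- frame
  f2["u6", ] <- f2["u6", ] * (1 + 4.0 / 10)
  expect_equal(count_unwrapped(f2, ref)$total, 0)
  # radially inward displacement of the same magnitude does not count
  f3 <- frame
  f3["u6", ] <- f3["u6", ] * (1 - 4.1 / 10)
  expect_equal(count_unwrapped(f3, ref)$total, 0)
  expect_equal(count_unwrapped(f3, ref, mode = "displacement")$total, 1)
  # missing units are reported by id
  expect_error(count_unwrapped(frame[-3, ], ref), "u3")
})

test_that("per-end counts are contiguous from the end inward", {
  ref <- toy_reference()
  frame <- ref$coords
  out <- function(f, id, by = 5) { f[id, ] <- f[id, ] * (1 + by / 10); f }
  # u6 (outermost) and u4 displaced, u5 wrapped: contiguous count stops at 1
  f <- out(out(frame, "u6"), "u4")
  cu <- count_unwrapped(f, ref)
  expect_equal(cu$n_end1, 1)
  expect_equal(attr(cu, "any_count"), 2)
  # non-contiguous mode counts both
  expect_equal(count_unwrapped(f, ref, contiguous = FALSE)$n_end1, 2)
  # monotone in threshold: loosening the cutoff can only add units
  f5 <- out(out(out(frame, "u6"), "u5"), "v6")
  for (thr in c(6, 4, 2)) {
    lo <- count_unwrapped(f5, ref, threshold = thr)$total
    hi <- count_unwrapped(f5, ref, threshold = thr + 2)$total
    expect_gte(lo, hi)
  }
})

test_that("contact ratios match the brute-force scan bit-exactly", {
  set.seed(19)
  n_frames <- 100L
  ids_A <- paste0("a", 1:6)
  ids_B <- paste0("b", 1:8)
  frames <- replicate(n_frames, {
    m <- matrix(stats::runif(14 * 3, 0, 12), ncol = 3)
    rownames(m) <- c(ids_A, ids_B)
    m
  }, simplify = FALSE)
  groups <- list(res1 = ids_A[1:3], res2 = ids_A[4:6])
  w <- stats::rexp(n_frames); w <- w / sum(w)
  strat <- sample(0:2, n_frames, replace = TRUE)
  ct <- contact_ratio(frames, groups, ids_B, cutoff = 4.0, weights = w,
                      stratify_by = strat)
  # brute force: per frame, all-pairs distances
  for (s in 0:2) for (g in names(groups)) {
    sel <- which(strat == s)
    ind <- vapply(sel, function(i) {
      A <- frames[[i]][groups[[g]], , drop = FALSE]
      B <- frames[[i]][ids_B, , drop = FALSE]
      dmin <- min(sqrt(outer(rowSums(A^2), rowSums(B^2), `+`) -
                         2 * A %*% t(B)))
      dmin <= 4.0
    }, logical(1L))
    expect_identical(ct$probability[ct$residue == g & ct$stratum == s],
                     sum(w[sel][ind]) / sum(w[sel]))
  }
  expect_true(all(ct$probability >= 0 & ct$probability <= 1 + 1e-15))
})

test_that("contact cutoff is inclusive at exactly 4 A", {
  mk <- function(dist) {
    m <- rbind(a1 = c(0, 0, 0), b1 = c(dist, 0, 0))
    m
  }
  just_in <- contact_ratio(list(mk(3.99)), list(r = "a1"), "b1")
  just_out <- contact_ratio(list(mk(4.01)), list(r = "a1"), "b1")
  at_cut <- contact_ratio(list(mk(4.0)), list(r = "a1"), "b1")
  expect_equal(just_in$probability, 1)
  expect_equal(just_out$probability, 0)
  expect_equal(at_cut$probability, 1)   # "within 4 A" is inclusive
})

test_that("asymmetry columns are normalized and reflect end symmetry", {
  # symmetric frames: all mass at difference 0
  sym <- asymmetry_distribution(cbind(c(2, 3, 1), c(2, 3, 1)))
  expect_true(all(sym$difference == 0))
  expect_equal(sym$probability, rep(1, 3))
  # mirrored one-sided frames split evenly at +/- total
  mir <- asymmetry_distribution(rbind(c(5, 0), c(0, 5)))
  expect_equal(sort(mir$difference), c(-5, 5))
  expect_equal(mir$probability, c(0.5, 0.5))
  # every populated total column sums to one
  set.seed(4)
  counts <- cbind(sample(0:4, 300, TRUE), sample(0:4, 300, TRUE))
  w <- stats::rexp(300); w <- w / sum(w)
  am <- asymmetry_distribution(counts, w)
  sums <- tapply(am$probability, am$total, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_error(asymmetry_distribution(cbind(-1, 2)), "counts >= 0")
})

test_that("stage stitching sums free-energy changes with metadata", {
  st <- stitch_stage_profiles(c(5.5, 6.0))
  expect_equal(st$total, 11.5)
  expect_equal(st$stages$cumulative_kcal_mol, c(5.5, 11.5))
  expect_equal(stitch_stage_profiles(3.2)$total, 3.2)
  expect_equal(stitch_stage_profiles(c(2, 7))$total,
               stitch_stage_profiles(c(7, 2))$total)
})
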