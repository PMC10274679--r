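mkPsm <- function(sequence = "PEPTIDEK", var_mods = "", offset_label = "",
                  offset_mass = 0, offset_pos = NA_integer_, score = 10,
                  is_decoy = FALSE, scan = "s1") {
  data.frame(scan = scan, charge = 2L, sequence = sequence, pf_id = 1L,
             var_mods = var_mods, offset_label = offset_label,
             offset_mass = offset_mass, offset_pos = offset_pos,
             score = score, matched_peaks = 5L, precursor_delta = 0,
             is_decoy = is_decoy, parent_accession = "P1",
             stringsAsFactors = FALSE)
}

test_that("group assignment separates unmodified, assigned and other PSMs", {
  assigned <- "M:15.9949,n:42.0106"
  ## fixed carbamidomethyl never counts as a modification: the PSM table
  ## carries no var mods and no offset for a Cys peptide
  expect_equal(assignGroups(mkPsm("ACDEFGHK"), assigned), "unmodified")
  ## Met-ox only: assigned
  expect_equal(assignGroups(mkPsm("MPEPTIDEK", var_mods = "M1/15.9949"),
                            assigned), "assigned")
  ## N-terminal acetylation is in the default assigned list
  expect_equal(assignGroups(mkPsm("MPEPTIDEK", var_mods = "N-term/42.0106"),
                            assigned), "assigned")
  ## Met-ox AND Trp dioxidation: one unlisted modification forces "other"
  expect_equal(assignGroups(
    mkPsm("MWPTIDEK", var_mods = "M1/15.9949",
          offset_label = "Dioxidation", offset_mass = 31.9898,
          offset_pos = 2L), assigned), "other")
  ## unlocalized non-zero offset is "other"
  expect_equal(assignGroups(
    mkPsm("MWPTIDEK", offset_label = "Dioxidation", offset_mass = 31.9898),
    assigned), "other")
  ## Met oxidation identified as a localized offset still matches M:15.9949
  expect_equal(assignGroups(
    mkPsm("AMPTIDEK", offset_label = "Oxidation", offset_mass = 15.9949,
          offset_pos = 2L), assigned), "assigned")
})

test_that("q-values match an independent brute-force estimator", {
  set.seed(406)
  for (rep in 1:8) {
    n <- sample(10:60, 1L)
    score <- round(stats::rnorm(n, 10, 3), sample(c(1L, 3L), 1L))
    isDecoy <- stats::runif(n) < 0.4
    if (!any(!isDecoy)) isDecoy[1L] <- FALSE
    q <- computeQvalues(score, isDecoy)
    expect_equal(q, naiveQvalues(score, isDecoy), tolerance = 1e-12)
    ## q is non-increasing in score
    o <- order(score, decreasing = TRUE)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
  ## 10 targets above all decoys: top target q = 0
  q <- computeQvalues(c(20:11, 5:1), c(rep(FALSE, 10L), rep(TRUE, 5L)))
  expect_equal(q[1L], 0)
  ## all-decoy group: q = 1 throughout
  expect_equal(computeQvalues(c(3, 2), c(TRUE, TRUE)), c(1, 1))
})

test_that("group filtering equals pooled filtering on single-group data", {
  set.seed(407)
  psms <- do.call(rbind, lapply(1:80, function(i)
    mkPsm(scan = paste0("s", i), score = stats::rnorm(1L, 10, 3),
          is_decoy = i %% 3 == 0)))
  g <- groupFdrFilter(psms, threshold = 0.05)
  r <- regularFdrFilter(psms, threshold = 0.05)
  expect_equal(g$q_value, r$q_value)
  expect_equal(g$passes, r$passes)
  ## threshold 1.0: every target passes
  expect_true(all(groupFdrFilter(psms, threshold = 1)$passes ==
                    !psms$is_decoy))
  ## empty input passes through
  expect_equal(nrow(groupFdrFilter(psms[0L, ])), 0L)
  expect_equal(nrow(regularFdrFilter(psms[0L, ])), 0L)
})

test_that("grouped and pooled filtering agree when score distributions match", {
  ## identical score/decoy patterns in each group: thresholds coincide
  set.seed(408)
  base <- data.frame(score = c(sort(stats::rnorm(30, 12, 2),
                                    decreasing = TRUE)),
                     is_decoy = rep(c(FALSE, FALSE, TRUE), 10L))
  psms <- do.call(rbind, lapply(1:2, function(g) {
    do.call(rbind, lapply(seq_len(nrow(base)), function(i)
      mkPsm(scan = sprintf("g%d_s%d", g, i),
            sequence = if (g == 1L) "PEPTIDEK" else "MPEPTIDEK",
            var_mods = if (g == 1L) "" else "M1/15.9949",
            score = base$score[i], is_decoy = base$is_decoy[i])))
  }))
  g <- groupFdrFilter(psms, threshold = 0.2)
  r <- regularFdrFilter(psms, threshold = 0.2)
  expect_equal(g$passes, r$passes)
})

test_that("rare-modification group needs a higher score threshold when its
          score distribution is contaminated", {
  ## modified PSMs drawn with a larger false-hit (decoy) tail emulate the
  ## larger effective search space of the rare-modification group
  set.seed(409)
  mkGroup <- function(n, decoyShift, prefix, mods) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      dec <- i %% 2 == 0
      mkPsm(scan = paste0(prefix, i),
            sequence = if (nzchar(mods)) "MWPTIDEK" else "PEPTIDEK",
            var_mods = mods,
            offset_label = if (nzchar(mods)) "Dioxidation" else "",
            offset_mass = if (nzchar(mods)) 31.9898 else 0,
            offset_pos = if (nzchar(mods)) 2L else NA_integer_,
            score = stats::rnorm(1L, if (dec) 6 + decoyShift else 12, 1.5),
            is_decoy = dec)
    }))
  }
  psms <- rbind(mkGroup(300L, 0, "u", ""),
                mkGroup(120L, 4.5, "o", "M1/15.9949"))
  g <- groupFdrFilter(psms, threshold = 0.01)
  thr <- attr(g, "thresholds")
  expect_gt(thr[["other"]], thr[["unmodified"]])
  ## grouped filtering removes more contaminated-group PSMs than pooled
  r <- regularFdrFilter(psms, threshold = 0.01)
  expect_lte(sum(g$passes & g$group == "other"),
             sum(r$passes & r$group == "other"))
})
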