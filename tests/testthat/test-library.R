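test_that("fragment filter enforces m/z range, ordinal, and top-6 ranking", {
  cand <- data.frame(
    series = c("y", "b", "y", "y", "b", "y", "b", "y", "b", "y", "b", "y"),
    ordinal = c(2, 3, 4, 5, 6, 7, 3, 4, 5, 6, 7, 8),
    fragment_charge = 1L,
    mz = c(500, 299.9, 1800.5, 300, 1800, 700, 700, 650, 600, 550, 500, 450),
    intensity = c(999, 998, 997, 100, 90, 80, 70, 70, 60, 50, 40, 30),
    stringsAsFactors = FALSE)
  out <- filter_fragments(cand)
  expect_false(any(out$mz < 300 | out$mz > 1800))   # 299.9 and 1800.5 removed
  expect_true(all(out$ordinal >= 3))                 # the y2 ion removed
  expect_true(all(c(300, 1800) %in% out$mz))         # boundaries are inclusive
  expect_equal(nrow(out), 6)                         # 10 pass, top 6 kept
  expect_true(all(diff(out$intensity) <= 0))
  # intensity tie at 70 resolved by lower m/z first
  tie <- out[out$intensity == 70, ]
  expect_equal(tie$mz, c(650, 700))
  expect_equal(nrow(filter_fragments(cand[0, ])), 0)
})

test_that("consensus iRT is the run-order-free median", {
  expect_equal(consensus_irt(c(10, 11, 30)), 11)
  expect_equal(consensus_irt(c(10, 20)), 15)
  expect_equal(consensus_irt(7), 7)
  expect_equal(consensus_irt(c(30, 10, 11)), consensus_irt(c(11, 30, 10)))
  expect_error(consensus_irt(numeric(0)), class = "irtnorm_input_error")
})

test_that("fragment m/z matches independent monoisotopic sums", {
  # A + G + proton
  expect_equal(fragment_mz("AGK", "b", 2, 1), 71.03711 + 57.02146 + 1.00728,
               tolerance = 1e-3 / 129)
  # K + water + proton
  expect_equal(fragment_mz("AGK", "y", 1, 1), 128.09496 + 18.01056 + 1.00728,
               tolerance = 1e-3 / 147)
  # full-length y equals full-length b plus water
  expect_equal(fragment_mz("AGK", "y", 3, 1),
               fragment_mz("AGK", "b", 3, 1) + 18.010564684,
               tolerance = 1e-3 / 300)
  expect_error(fragment_mz("AXG", "b", 2, 1), regexp = "X",
               class = "irtnorm_input_error")
})

test_that("b/y fragments conserve the precursor mass", {
  set.seed(5)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:5) {
    L <- sample(6:15, 1)
    seqn <- paste(c(sample(aas, L - 1, replace = TRUE), sample(c("K", "R"), 1)),
                  collapse = "")
    mh <- precursor_mz(seqn, 1)  # neutral mass + 1 proton
    for (k in seq_len(L - 1)) {
      bk <- fragment_mz(seqn, "b", k, 1)
      yl <- fragment_mz(seqn, "y", L - k, 1)
      expect_equal(bk + yl, mh + 1.00727646688, tolerance = 1e-3 / 1000)
    }
  }
})

make_library_fixture <- function(shift_slope = 1, shift_intercept = 0) {
  set.seed(21)
  n_cal <- 250
  cal <- data.frame(precursor_id = sprintf("CAL%03d/2", 1:n_cal),
                    irt = sort(runif(n_cal, -20, 120)),
                    stringsAsFactors = FALSE)
  class(cal) <- c("calibration_set", "data.frame")
  rt1 <- function(irt) 10 + 0.8 * irt            # run 1 gradient
  rt2 <- function(irt) shift_slope * rt1(irt) + shift_intercept
  test_ids <- sprintf("TEST%02d/2", 1:12)
  test_irt <- seq(0, 100, length.out = 12)
  psms <- rbind(
    data.frame(run_id = "run1",
               precursor_id = c(cal$precursor_id, test_ids),
               modified_sequence = c(cal$precursor_id, test_ids),
               sequence = "PEPTIDEK", charge = 2L,
               rt_apex = rt1(c(cal$irt, test_irt)),
               stringsAsFactors = FALSE),
    data.frame(run_id = "run2",
               precursor_id = c(cal$precursor_id, test_ids),
               modified_sequence = c(cal$precursor_id, test_ids),
               sequence = "PEPTIDEK", charge = 2L,
               rt_apex = rt2(c(cal$irt, test_irt)),
               stringsAsFactors = FALSE))
  frags <- do.call(rbind, lapply(c(cal$precursor_id, test_ids),
                                 passing_fragments))
  list(psms = psms, frags = frags, cal = cal, test_ids = test_ids,
       test_irt = test_irt)
}

test_that("library assembly converts per-run RT to consistent iRT across an affine shift", {
  fx <- make_library_fixture(shift_slope = 1.1, shift_intercept = 3)
  lib <- assemble_library(fx$psms, fx$frags, fx$cal, min_anchors = 200)
  # per-run iRTs agree despite run2's distorted gradient
  test_entries <- lib$entries[lib$entries$precursor_id %in% fx$test_ids, ]
  expect_equal(nrow(test_entries), 12)
  expect_lt(max(abs(test_entries$irt - fx$test_irt)), 0.1)
})

test_that("precursors need three surviving fragments and get the median iRT", {
  cal <- data.frame(precursor_id = sprintf("CAL%03d/2", 1:60),
                    irt = seq(0, 100, length.out = 60), stringsAsFactors = FALSE)
  rtof <- function(irt) 5 + irt
  mk_run <- function(run, irts) {
    ids <- c(cal$precursor_id, "POOR/2", "RICH/2")
    data.frame(run_id = run, precursor_id = ids, modified_sequence = ids,
               sequence = "PEPTIDEK", charge = 2L,
               rt_apex = rtof(c(cal$irt, irts)), stringsAsFactors = FALSE)
  }
  psms <- rbind(mk_run("r1", c(42.0, 42.0)), mk_run("r2", c(42.4, 42.4)),
                mk_run("r3", c(60.0, 60.0)))
  frags <- rbind(do.call(rbind, lapply(cal$precursor_id, passing_fragments)),
                 passing_fragments("POOR/2", n = 2),   # below the minimum
                 passing_fragments("RICH/2", n = 9))
  lib <- assemble_library(psms, frags, cal, min_anchors = 50)
  expect_false("POOR/2" %in% lib$entries$precursor_id)
  expect_true("RICH/2" %in% lib$entries$precursor_id)
  rich <- lib$entries[lib$entries$precursor_id == "RICH/2", ]
  expect_equal(rich$irt, 42.4, tolerance = 1e-6)  # median of {42.0, 42.4, 60.0}
  expect_equal(rich$n_fragments, 6)               # truncated from 9

  # library-wide invariants
  expect_true(all(lib$fragments$mz >= 300 & lib$fragments$mz <= 1800))
  expect_true(all(lib$fragments$ordinal >= 3))
  expect_true(all(lib$entries$n_fragments >= 3 & lib$entries$n_fragments <= 6))
  expect_false(any(duplicated(lib$entries$precursor_id)))
})

test_that("library assembly is invariant to run order", {
  fx <- make_library_fixture(shift_slope = 1.05, shift_intercept = 2)
  lib_a <- assemble_library(fx$psms, fx$frags, fx$cal, min_anchors = 200)
  shuffled <- fx$psms[rev(seq_len(nrow(fx$psms))), ]
  lib_b <- assemble_library(shuffled, fx$frags, fx$cal, min_anchors = 200)
  a <- lib_a$entries[order(lib_a$entries$precursor_id), ]
  b <- lib_b$entries[order(lib_b$entries$precursor_id), ]
  expect_equal(a$precursor_id, b$precursor_id)
  expect_equal(a$irt, b$irt)
})

test_that("assembly fails clearly without calibration overlap", {
  psms <- data.frame(run_id = "r1", precursor_id = "A/2",
                     modified_sequence = "A/2", sequence = "PEPTIDEK",
                     charge = 2L, rt_apex = 30, stringsAsFactors = FALSE)
  cal <- data.frame(precursor_id = "Z/9", irt = 50, stringsAsFactors = FALSE)
  expect_error(assemble_library(psms, passing_fragments("A/2"), cal),
               class = "irtnorm_cannot_build")
})

test_that("OpenSWATH-style transition list round-trips", {
  fx <- make_library_fixture()
  lib <- assemble_library(fx$psms, fx$frags, fx$cal, min_anchors = 200)
  path <- tempfile(fileext = ".tsv")
  write_library(lib, path)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(header, c("PrecursorMz", "ProductMz", "LibraryIntensity",
                         "NormalizedRetentionTime", "PeptideSequence",
                         "ModifiedPeptideSequence", "PrecursorCharge",
                         "FragmentType", "FragmentSeriesNumber",
                         "FragmentCharge", "ProteinId"))
  lib2 <- read_library(path)
  expect_equal(nrow(lib2$entries), nrow(lib$entries))
  expect_equal(nrow(lib2$fragments), nrow(lib$fragments))
  i <- match(lib$entries$modified_sequence, lib2$entries$modified_sequence)
  expect_false(anyNA(i))
  expect_equal(lib2$entries$irt[i], lib$entries$irt)
  expect_equal(lib2$entries$precursor_mz[i], lib$entries$precursor_mz)
})
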