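test_that("the default profile encodes the observed residue space", {
  prof <- nbeta_profile()
  expect_s3_class(prof, "nbeta_profile")
  expect_equal(prof$length, 11L)
  expect_equal(prof$core_span, 4:11)
  # positions 1-3 are wildcards
  for (p in 1:3) expect_setequal(prof$allowed[[p]], AA20_TEST)
  expect_true(all(c("S", "E", "D", "A") %in% prof$allowed[[8]]))
  expect_setequal(prof$allowed[[9]], c("S", "A"))
  expect_setequal(prof$allowed[[4]], "E")
  expect_setequal(prof$allowed[[10]], c("E", "D"))
  # the canonical motif satisfies every core position
  expect_equal(score_window(canonical_nbeta(), prof), 8)
})

test_that("score_window counts satisfied core positions", {
  expect_equal(score_window("ESGSSSEP"), 8)
  expect_equal(score_window("ESGSDSEP"), 8)  # D allowed at position 8
  expect_equal(score_window("KKKKKKKK"), 0)
  expect_equal(score_window("ESGSSSEA"), 7)  # A not allowed at 11
  expect_equal(score_window("XXXXXXXX"), 0)  # X matches nothing
  expect_error(score_window("ESGSS"), "8")
})

test_that("named variants apply the documented edits", {
  expect_equal(nbeta_variant("canonical"), canonical_nbeta())
  expect_equal(nbeta_variant("S9A"), "AAAESGSSAEP")
  expect_equal(nbeta_variant("S5G"), "AAAEGGSSSEP")
  expect_equal(nbeta_variant("S8D"), "AAAESGSDSEP")
  expect_equal(nbeta_variant("A5E8_mito"), "AAAEAGSESEP")
  expect_equal(nbeta_variant("minus3"), "ESGSSSEP")
  expect_equal(nchar(nbeta_variant("minus3")), 8)
  expect_equal(nbeta_variant("minus6"), "SSSEP")
  expect_equal(nbeta_variant("inverted"), reverse_string(canonical_nbeta()))
  expect_error(nbeta_variant("S1W"))
})

test_that("the synthetic NaTrxh-like fixture yields exactly one strict match at 17-27", {
  hits <- scan_proteins(natrxh_fixture())
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 17L)
  expect_equal(hits$end, 27L)
  expect_equal(hits$quarter, "P1")
  expect_equal(hits$orientation, "forward")
  expect_false(hits$at_c_terminus)
})

test_that("a reversed canonical motif is found as a single inverted match", {
  recs <- protein_records("inv", reverse_string(canonical_nbeta()))
  hits <- scan_proteins(recs)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$orientation, "inverted")
  expect_equal(hits$start, 1L)
  expect_equal(hits$end, 11L)
  expect_true(hits$at_c_terminus)
  # without inverted scanning it is invisible
  expect_equal(nrow(scan_proteins(recs, allow_inverted = FALSE)), 0)
})

test_that("scanner output equals brute-force window enumeration", {
  withr::with_seed(11, {
    for (i in 1:100) {
      len <- sample(20:500, 1)
      seq <- random_protein(len)
      if (i %% 2 == 0 && len >= 60) {
        variant <- sample(c("canonical", "S8D", "A5E8_mito", "inverted"), 1)
        seq <- plant_motif(seq, nbeta_variant(variant),
                           sample(0:(len - 12), 1))
      }
      min_score <- sample(c(6L, 8L), 1)
      expect_equal(
        scan_normalised(seq, min_score = min_score),
        brute_force_scan(seq, min_score = min_score),
        info = paste("sequence", i)
      )
    }
  })
})

test_that("planted canonical motifs are always recovered at the planted start", {
  withr::with_seed(23, {
    for (i in 1:50) {
      len <- sample(60:400, 1)
      s0 <- sample(0:(len - 11), 1)
      seq <- plant_motif(random_protein(len), canonical_nbeta(), s0)
      hits <- scan_proteins(protein_records("p", seq), min_score = 8)
      expect_true(any(hits$start == s0 + 1 & hits$score == 8),
                  info = paste("plant at", s0))
    }
  })
})

test_that("forward matches mirror inverted matches of the reversed sequence", {
  withr::with_seed(31, {
    for (i in 1:20) {
      len <- sample(40:300, 1)
      seq <- plant_motif(random_protein(len), canonical_nbeta(),
                         sample(0:(len - 11), 1))
      fwd <- scan_normalised(seq, min_score = 6)
      rev_inv <- scan_normalised(reverse_string(seq), min_score = 6)
      fwd_f <- dplyr::filter(fwd, orientation == "forward")
      mirrored <- dplyr::filter(rev_inv, orientation == "inverted") |>
        dplyr::mutate(start0 = len - start0 - width,
                      orientation = "forward") |>
        dplyr::arrange(start0, width)
      expect_equal(fwd_f, mirrored)
    }
  })
})

test_that("lowering min_score never removes a match", {
  withr::with_seed(41, {
    for (i in 1:20) {
      seq <- plant_motif(random_protein(150), nbeta_variant("S8E"), 40)
      strict <- scan_normalised(seq, min_score = 8)
      relaxed <- scan_normalised(seq, min_score = 6)
      loose <- scan_normalised(seq, min_score = 4)
      key <- function(x) paste(x$start0, x$width, x$orientation)
      expect_true(all(key(strict) %in% key(relaxed)))
      expect_true(all(key(relaxed) %in% key(loose)))
    }
  })
})

test_that("quarter assignment follows floor(4 * start / length), clamped", {
  expect_equal(quarter_of(16, 150), "P1")
  expect_equal(quarter_of(0, 11), "P1")
  expect_equal(quarter_of(75, 100), "P4")
  expect_equal(quarter_of(37, 150), "P1")
  expect_equal(quarter_of(38, 150), "P2")
  expect_error(quarter_of(0, 0), "positive")
  expect_error(quarter_of(100, 100), "outside")
})

test_that("short sequences give empty results, not errors", {
  expect_equal(nrow(scan_proteins(protein_records("s", "ESGSSS"))), 0)
  # a bare 8-residue core is matched via the core-only path
  hits <- scan_proteins(protein_records("c", "ESGSSSEP"))
  expect_true(any(hits$is_core_only & hits$score == 8))
})
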