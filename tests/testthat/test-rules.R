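make_match <- function(seq, ...) {
  hits <- scan_proteins(protein_records("x", seq), ...)
  hits[which.max(hits$score), ]
}

gfp_body <- function() motif_free_segment(120, seed = 101L)

test_that("net charge counts basic minus acidic residues, histidine neutral", {
  expect_equal(net_charge(""), 0L)
  expect_equal(net_charge(canonical_nbeta()), -2L)
  expect_equal(net_charge("KKDD"), 0L)
  expect_equal(net_charge("HHHH"), 0L)
  expect_equal(net_charge(c("KRKR", "DEDE")), c(4L, -4L))
})

test_that("mean hydropathy follows the Kyte-Doolittle scale", {
  expect_equal(mean_hydropathy("IIIII"), 4.5)
  expect_equal(mean_hydropathy("RRRRR"), -4.5)
  expect_lt(mean_hydropathy("ESGSSSEP"), 0)  # the core is hydrophilic
  expect_equal(mean_hydropathy("IXI"), 4.5)  # X excluded
  expect_error(mean_hydropathy("XXX"), "all-X")
  expect_error(mean_hydropathy(""), "empty")
  # independent oracle: the published scale as archived in seqinr's aaindex
  data("aaindex", package = "seqinr", envir = environment())
  kd <- aaindex[["KYTJ820101"]]$I
  names(kd) <- vapply(names(kd), seqinr::a, character(1))
  for (res in names(kd)) {
    expect_equal(mean_hydropathy(res), unname(kd[[res]]))
  }
})

test_that("single-match classification follows the rule cascade", {
  cfg <- rule_config()
  body <- gfp_body()

  secreted <- paste0("M", canonical_nbeta(), body)
  res <- classify_match(secreted, make_match(secreted), cfg)
  expect_equal(res$compartment, "secreted")
  expect_false(any(res$trace$fired))
  expect_equal(res$trace$rule, c("R1", "R2", "R3", "R4", "R5", "R7"))

  s9a <- paste0("M", nbeta_variant("S9A"), body)
  res <- classify_match(s9a, make_match(s9a), cfg)
  expect_equal(res$compartment, "cytoplasmic")
  expect_equal(res$trace$rule[res$trace$fired], "R4")

  mito <- paste0("M", nbeta_variant("A5E8_mito"), body)
  res <- classify_match(mito, make_match(mito), cfg)
  expect_equal(res$compartment, "mitochondrial_candidate")
  expect_true(res$trace$fired[res$trace$rule == "R6"])

  s8e <- paste0("M", nbeta_variant("S8E"), body)
  res <- classify_match(s8e, make_match(s8e), cfg)
  expect_equal(res$compartment, "cytoplasmic")  # Glu-8 without Ala-5

  interior <- paste0(motif_free_segment(109, seed = 202L),
                     canonical_nbeta(), body)
  res <- classify_match(interior, make_match(interior), cfg)
  expect_equal(res$compartment, "cytoplasmic")
  expect_equal(res$trace$rule[res$trace$fired], "R2")

  kdel <- paste0(body, canonical_nbeta(), "KDEL")
  res <- classify_match(kdel, make_match(kdel), cfg)
  expect_equal(res$compartment, "er_retained")
  expect_equal(res$trace$rule, "R1")
})

test_that("a positively charged motif-like window is rejected by the charge rule", {
  # replace the wildcard prefix with arginines: profile still matches (score
  # 8) but the window carries net charge +1
  charged <- "RRRESGSSSEP"
  expect_equal(net_charge(charged), 1L)
  seq <- paste0("M", charged, gfp_body())
  res <- classify_match(seq, make_match(seq), rule_config())
  expect_equal(res$compartment, "cytoplasmic")
  expect_equal(res$trace$rule[res$trace$fired], "R7")
})

test_that("animal mode requires glutamate at position 8 and flags the hypothesis", {
  cfg <- rule_config(taxon_mode = "animal")
  body <- gfp_body()

  e8 <- paste0("M", nbeta_variant("A5E8_mito"), body)
  res <- classify_match(e8, make_match(e8), cfg)
  expect_equal(res$compartment, "secreted")
  expect_match(res$trace$detail[res$trace$rule == "R5"], "hypothesis")

  s8 <- paste0("M", canonical_nbeta(), body)  # serine-8: plant signal
  res <- classify_match(s8, make_match(s8), cfg)
  expect_equal(res$compartment, "cytoplasmic")

  d8 <- paste0("M", nbeta_variant("S8D"), body)
  res <- classify_match(d8, make_match(d8), cfg)
  expect_equal(res$compartment, "cytoplasmic")
})

test_that("inverted matches are classified on the reversed window", {
  seq <- paste0("M", nbeta_variant("inverted"), gfp_body())
  m <- make_match(seq)
  expect_equal(m$orientation, "inverted")
  res <- classify_match(seq, m, rule_config())
  expect_equal(res$compartment, "secreted")
})

test_that("predict_localisation picks the best-placed match and is deterministic", {
  # motif-free protein
  withr::with_seed(5, {
    calls <- predict_localisation(protein_records("bg", random_protein(200)))
    expect_equal(calls$compartment, "cytoplasmic")
    expect_equal(calls$fired_rules, "no_motif")
  })

  # interior and N-terminal copies: the N-terminal (secreted) call wins
  body <- gfp_body()
  seq <- paste0("M", canonical_nbeta(), body, canonical_nbeta(), body)
  calls <- predict_localisation(protein_records("two", seq))
  expect_equal(calls$compartment, "secreted")
  expect_equal(calls$start, 2L)

  # determinism: identical calls and traces on repeated evaluation
  a <- predict_localisation(natrxh_fixture())
  b <- predict_localisation(natrxh_fixture())
  expect_identical(a, b)
  expect_equal(a$compartment, "secreted")
  expect_gt(nrow(a$trace[[1]]), 0)
})

test_that("appending KDEL flips every secreted construct to ER-retained", {
  panel <- paper_constructs()
  secreted <- panel[panel$expected == "secreted", ]
  retained <- dplyr::mutate(secreted,
                            sequence = paste0(sequence, "KDEL"),
                            expected = "er_retained")
  out <- evaluate_constructs(retained)
  expect_true(all(out$predicted == "er_retained"))
})

test_that("the wildcard prefix is dispensable but the core is not", {
  body <- gfp_body()
  canon <- canonical_nbeta()
  for (d in 0:3) {
    seq <- paste0("M", substr(canon, d + 1, 11), body)
    call <- predict_localisation(protein_records("v", seq))
    expect_equal(call$compartment, "secreted", info = paste("deletion", d))
  }
  for (d in 4:6) {
    seq <- paste0("M", substr(canon, d + 1, 11), body)
    call <- predict_localisation(protein_records("v", seq))
    expect_equal(call$compartment, "cytoplasmic", info = paste("deletion", d))
  }
})

test_that("a motif and its reversal at the N-terminus receive the same call", {
  body <- gfp_body()
  for (v in c("canonical", "S5G", "S9A", "S8D", "A5E8_mito")) {
    fwd <- predict_localisation(
      protein_records("f", paste0("M", nbeta_variant(v), body))
    )
    inv <- predict_localisation(
      protein_records("r", paste0("M", reverse_string(nbeta_variant(v)), body))
    )
    expect_equal(fwd$compartment, inv$compartment, info = v)
  }
})

test_that("every cytoplasmic call carries at least one fired blocking rule", {
  panel <- paper_constructs()
  recs <- protein_records(panel$name, panel$sequence)
  calls <- predict_localisation(recs)
  cyto <- calls[calls$compartment == "cytoplasmic", ]
  expect_gt(nrow(cyto), 0)
  for (i in seq_len(nrow(cyto))) {
    tr <- cyto$trace[[i]]
    expect_true(any(tr$fired), info = cyto$id[[i]])
  }
})

test_that("classify_match validates its inputs", {
  seq <- paste0("M", canonical_nbeta(), gfp_body())
  m <- make_match(seq)
  expect_error(classify_match("MAAA", m), "does not correspond")
  expect_error(classify_match(seq, m[0, ]), "one match")
})
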