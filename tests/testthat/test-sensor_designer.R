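test_that("a toy 9-nt design matches the manual base-pairing oracle", {
  tr <- toy_transcript()  # GATCCAATG, CCA at offset 3
  site <- scan_cca(tr)
  d <- design_sensor(tr, site, length = 9L)
  expect_true(d$accepted)
  expect_equal(d$sensor_seq, "CATTAGATC")   # revcomp is CATTGGATC, central G->A
  expect_equal(d$uag_offset, 3L)
  expect_equal(d$peptide, "H*I")
  expect_equal(nrow(d$mismatches), 1L)
  expect_equal(d$mismatches$target_base, "C")
  # simulated editing restores the perfect duplex and a Trp codon
  edited <- simulate_edit(d)
  expect_equal(edited, "CATTGGATC")
  expect_equal(substr(edited, d$uag_offset + 1L, d$uag_offset + 3L), "TGG")
  expect_equal(translate_seq(edited), "HWI")
})

test_that("default designs are 75 nt with the UAG at codon 13", {
  d <- std_design()
  expect_true(d$accepted)
  expect_equal(nchar(d$sensor_seq), 75L)
  expect_equal(d$uag_offset, 36L)
  expect_equal(d$uag_offset / 3L + 1L, 13L)
  expect_equal(substr(d$sensor_seq, 37L, 39L), "TAG")
  # exactly one stop in frame 0, at codon 13
  stops <- gregexpr("\\*", d$peptide)[[1]]
  expect_equal(as.integer(stops), 13L)
  # 51-nt short preset
  d51 <- std_design(length = 51L)
  expect_true(d51$accepted)
  expect_equal(d51$uag_offset, 24L)
  expect_error(design_sensor(std_trigger(), scan_cca(std_trigger())[1, ],
                             length = 60L), "length")
})

test_that("window boundary violations and N windows are handled", {
  tr <- transcript("t", paste0("CCA", strrep("G", 100L)))
  expect_error(design_sensor(tr, scan_cca(tr)[1, ], 75L), "bounds")
  trn <- transcript("t", paste0(strrep("G", 40L), "CCANG", strrep("G", 40L)))
  d <- design_sensor(trn, scan_cca(trn)[1, ], 75L)
  expect_false(d$accepted)
  expect_match(d$reason, "N")
})

test_that("designs are deterministic and revert to the exact window complement", {
  d1 <- std_design()
  d2 <- std_design()
  expect_identical(d1, d2)
  for (seed in 1:10) {
    d <- std_design(seed)
    if (!d$accepted) next
    tr <- std_trigger(seed)
    window <- substr(tr$seq, d$window["start"] + 1L, d$window["end"])
    expect_identical(simulate_edit(d), revcomp(window))
    expect_equal(nrow(d$mismatches), 1L)
    expect_true(validate_design(d, tr)$pass)
  }
})

test_that("allstop converts exactly the in-frame-alignable CCAs", {
  # hand-built target: central CCA plus one extra CCA aligned to the sensor
  # frame and one misaligned; arm = 3 keeps the example small (L = 9 is too
  # small for extras, so construct a 15-nt design: L = 15 -> arm = 6)
  # window: [x x x][C C A][C C A][x x x] with the second CCA central
  win <- paste0("GAT", "CCA", "CCA", "TGA", "GTT")  # L = 15, central at offset 6
  tr <- transcript("t", win)
  sites <- scan_cca(tr)
  central <- sites[sites$motif_start == 6L, ]
  d_single <- design_sensor(tr, central, length = 15L)
  d_all <- design_allstop(tr, central, length = 15L)
  expect_true(d_all$accepted)
  # extra CCA at offset 3 opposes sensor triplet at 15-3-3 = 9: in frame
  expect_equal(nrow(d_all$mismatches), 2L)
  stops <- gregexpr("\\*", d_all$peptide)[[1]]
  expect_length(as.integer(stops), 2L)
  expect_equal(length(d_all$skipped_cca), 0L)
  # degenerate case: only the central CCA -> identical to single_stop
  tr2 <- std_trigger()
  s2 <- scan_cca(tr2)
  extra_in_window <- abs(s2$motif_start - s2$motif_start[s2$name == "CCA60"]) <= 36L
  if (sum(extra_in_window) == 1L) {
    a <- design_allstop(tr2, s2[s2$name == "CCA60", ])
    b <- design_sensor(tr2, s2[s2$name == "CCA60", ])
    expect_equal(a$sensor_seq, b$sensor_seq)
  }
  # misaligned extra CCA is skipped and reported
  win3 <- paste0("GACC", "AT", "CCA", "GTTTAA")   # CCA at 2 (misaligned) and 6
  tr3 <- transcript("t3", win3)
  s3 <- scan_cca(tr3)
  d3 <- design_allstop(tr3, s3[s3$motif_start == 6L, ], length = 15L)
  expect_true(d3$accepted)
  expect_equal(nrow(d3$mismatches), 1L)
  expect_equal(d3$skipped_cca, 2L)
})

test_that("allstop mismatch count equals converted CCA count across seeds", {
  for (seed in 1:8) {
    tr <- make_trigger(sim_spec(seed = seed, planted_cca = c(60L, 70L)))
    sites <- scan_cca(tr)
    d <- design_allstop(tr, sites[sites$name == "CCA60", ])
    if (!d$accepted) next
    n_tag <- lengths(gregexpr("TAG", d$sensor_seq, fixed = TRUE))
    expect_gte(nrow(d$mismatches), 1L)
    stops <- lengths(regmatches(d$peptide, gregexpr("\\*", d$peptide)))
    expect_equal(stops, nrow(d$mismatches))
    expect_identical(simulate_edit(d),
                     revcomp(substr(tr$seq, d$window["start"] + 1L,
                                    d$window["end"])))
  }
})

test_that("SNV sensors discriminate alleles through a single central mismatch", {
  spec <- sim_spec(seed = 11L, planted_cca = 90L, cds_len = 900L,
                   utr3_len = 60L)
  pair <- make_snv_pair(spec)
  expect_equal(pair$variant, "c.91T>C")
  # the variant creates exactly one new CCA at the locus
  new_sites <- setdiff(scan_cca(pair$mut)$motif_start,
                       scan_cca(pair$wt)$motif_start)
  expect_length(new_sites, 1L)
  d <- design_snv_sensor(pair$wt, pair$variant)
  expect_true(d$accepted)
  expect_equal(d$mode, "snv_discrimination")
  expect_equal(d$mismatches_vs_wt, 0L)   # A:T pair protects the wild type
  expect_equal(d$mismatches_vs_mut, 1L)  # editable A:C against the mutant
  # a variant that cannot create a CCA is rejected up front
  expect_error(design_snv_sensor(pair$wt, "c.10G>A"), "inapplicable")
})

test_that("variant parsing and application validate against the transcript", {
  expect_equal(parse_variant("c.658T>C"), list(pos = 658L, ref = "T", alt = "C"))
  expect_error(parse_variant("g.100A>T"), "parse")
  tr <- transcript("t", paste0(strrep("G", 6L), "ATGTTTTAA"),
                   data.frame(kind = "cds", start = 6L, end = 15L))
  mut <- apply_variant(tr, "c.4T>A")
  expect_equal(substr(mut$seq, 10L, 10L), "A")
  expect_error(apply_variant(tr, "c.4A>G"), "mismatch")
  expect_error(apply_variant(transcript("t", "ACGTACGT"), "c.1A>G"), "CDS")
})

test_that("validate_design flags residual stops and passes edited designs", {
  d <- std_design()
  tr <- std_trigger()
  rep <- validate_design(d, tr)
  expect_true(rep$pass)
  expect_equal(rep$stop_count, 1L)
  expect_equal(rep$edited_stop_count, 0L)
  # corrupt the design with an extra in-frame TGA
  bad <- d
  substr(bad$sensor_seq, 4L, 6L) <- "TGA"
  rep_bad <- validate_design(bad, tr)
  expect_false(rep_bad$pass)
  expect_match(paste(rep_bad$reasons, collapse = "; "), "stop")
})
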