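test_that("bundled component fixtures load with their metadata", {
  comps <- load_components()
  expect_true(all(c("cmv_promoter", "tagbfp", "p2a", "mneongreen", "mcp",
                    "adar2dd_e488q", "nes", "ms2_hairpin", "bgh_terminator",
                    "adar1_p150") %in% names(comps)))
  expect_equal(nchar(comps$p2a$seq), 66L)
  expect_equal(nchar(comps$ms2_hairpin$seq), 19L)
  expect_false(comps$p2a$synthetic)
  expect_true(comps$tagbfp$synthetic)
  expect_true(comps$tagbfp$coding)
  expect_false(comps$cmv_promoter$coding)
})

test_that("hairpin placement preserves frame and respects spacers", {
  d <- std_design()
  mod <- place_hairpins(d, "C", 9L, 9L)
  expect_equal(nrow(mod$hairpins), 2L)
  expect_equal(nchar(mod$seq) %% 3L, 0L)
  bl <- mod$hairpins$end[1] - mod$hairpins$start[1]
  expect_equal(bl %% 3L, 0L)
  # left block ends 9 nt 5' of the UAG; right block starts 9 nt 3' of it
  expect_equal(mod$uag_offset - mod$hairpins$end[1], 9L)
  expect_equal(mod$hairpins$start[2] - (mod$uag_offset + 3L), 9L)
  # the UAG itself is untouched
  expect_equal(substr(mod$seq, mod$uag_offset + 1L, mod$uag_offset + 3L), "TAG")
  # no stop beyond the designed one
  pep <- translate_seq(mod$seq)
  expect_equal(lengths(regmatches(pep, gregexpr("\\*", pep))), 1L)
  # degenerate spacers: blocks abut the UAG codon
  mod0 <- place_hairpins(d, "C", 0L, 0L)
  expect_equal(mod0$hairpins$end[1], mod0$uag_offset)
  expect_equal(mod0$hairpins$start[2], mod0$uag_offset + 3L)
  # L and R put both blocks on one side
  modL <- place_hairpins(d, "L", 9L, 9L)
  expect_true(all(modL$hairpins$end <= modL$uag_offset))
  modR <- place_hairpins(d, "R", 9L, 9L)
  expect_true(all(modR$hairpins$start >= modR$uag_offset + 3L))
  expect_error(place_hairpins(d, "C", 100L, 9L), "insertion point")
})

test_that("closed-loop assembly has four 2A-insulated coding parts and one internal TAG", {
  lay <- assemble(std_design(), "closed_loop")
  checks <- lay$orf_checks
  expect_equal(checks$n_coding_components, 4L)
  expect_equal(checks$n_2a, 3L)
  expect_equal(checks$internal_tag_count, 1L)
  expect_equal(checks$internal_stop_count, 1L)
  expect_true(checks$frame_ok)
  expect_true(checks$terminal_stop)
  expect_equal(nrow(lay$sensor_module$hairpins), 2L)
  expect_equal(lay$total_length, nchar(lay$seq))
})

test_that("control topologies have the expected structure", {
  d <- std_design()
  stopless <- assemble(d, "stopless_backbone")
  expect_equal(stopless$orf_checks$internal_tag_count, 0L)
  expect_equal(stopless$orf_checks$internal_stop_count, 0L)
  basic <- assemble(d, "basic_no_adar")
  expect_equal(basic$orf_checks$n_coding_components, 3L)
  expect_equal(nrow(basic$sensor_module$hairpins), 0L)
  trans <- assemble(NULL, "open_loop_adar_trans")
  expect_equal(trans$components$role,
               c("promoter", "mcp_adar", "stop", "terminator"))
  ol <- assemble(d, "open_loop_sensor")
  expect_false("mcp_adar" %in% ol$components$role)
  expect_error(assemble(NULL, "closed_loop"), "design")
  comps <- load_components()
  comps$tagbfp <- NULL
  expect_error(assemble(d, "closed_loop", components = comps), "missing component")
})

test_that("editing the assembled closed loop yields one run-through ORF; unedited truncates in the sensor", {
  d <- std_design()
  lay <- assemble(d, "closed_loop")
  comps <- load_components()
  coding <- lay$components[lay$components$coding, ]
  orf <- substr(lay$seq, min(coding$start) + 1L, max(coding$end))
  # unedited: translation terminates inside the sensor module
  pep <- translate_seq(orf)
  first_stop_nt <- min(coding$start) + (regexpr("\\*", pep) - 1L) * 3L
  smod <- lay$components[lay$components$role == "sensor_module", ]
  expect_gte(first_stop_nt, smod$start)
  expect_lt(first_stop_nt, smod$end)
  # edited: single uninterrupted ORF containing marker, payload, MCP-ADAR
  edited <- lay$seq
  u <- smod$start + lay$sensor_module$uag_offset
  expect_equal(substr(edited, u + 1L, u + 3L), "TAG")
  substr(edited, u + 2L, u + 2L) <- "G"
  orf_ed <- substr(edited, min(coding$start) + 1L, max(coding$end))
  pep_ed <- translate_seq(orf_ed)
  expect_equal(lengths(regmatches(pep_ed, gregexpr("\\*", pep_ed))), 1L)  # terminal stop only
  marker_pep <- translate_seq(comps$tagbfp$seq)
  payload_pep <- translate_seq(comps$mneongreen$seq)
  mcp_pep <- translate_seq(comps$mcp$seq)
  i_marker <- regexpr(marker_pep, pep_ed, fixed = TRUE)
  i_payload <- regexpr(payload_pep, pep_ed, fixed = TRUE)
  i_mcp <- regexpr(mcp_pep, pep_ed, fixed = TRUE)
  expect_true(all(c(i_marker, i_payload, i_mcp) > 0L))
  expect_true(i_marker < i_payload && i_payload < i_mcp)
})

test_that("assembly is deterministic and order-stable", {
  a <- assemble(std_design(), "closed_loop")
  b <- assemble(std_design(), "closed_loop")
  expect_identical(a$seq, b$seq)
  expect_identical(a$components, b$components)
})

test_that("size budget counts promoter and terminator against capacity", {
  lay <- assemble(std_design(), "closed_loop")
  budget <- size_budget(lay)
  expect_equal(budget$total_nt, lay$total_length)
  expect_true(budget$within_budget)
  expect_lt(budget$total_nt, 5000L)
  p150 <- single_component_layout(load_components()$adar1_p150)
  bp <- size_budget(p150)
  expect_gt(bp$fraction_of_capacity, 0.70)
  empty <- structure(
    list(components = data.frame(name = character(), role = character(),
                                 start = integer(), end = integer(),
                                 coding = logical())),
    class = "dv_layout")
  be <- size_budget(empty)
  expect_equal(be$total_nt, 0L)
  expect_equal(be$fraction_of_capacity, 0)
})

test_that("GenBank output round-trips sequence, length, and feature coordinates", {
  lay <- assemble(std_design(), "closed_loop")
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(lay, path)
  gb <- read_genbank(path)
  expect_equal(gb$length, lay$total_length)
  expect_equal(gb$seq, lay$seq)
  # one feature per component + source + sensor UAG annotation
  expect_equal(nrow(gb$features), nrow(lay$components) + 2L)
  payload <- lay$components[lay$components$role == "payload", ]
  feat <- gb$features[!is.na(gb$features$label) &
                      gb$features$label == "mneongreen", ]
  expect_equal(feat$start, payload$start + 1L)
  expect_equal(feat$end, payload$end)
  uag <- gb$features[!is.na(gb$features$label) &
                     gb$features$label == "sensor_UAG", ]
  expect_equal(uag$end - uag$start + 1L, 3L)
  expect_equal(substr(gb$seq, uag$start, uag$end), "TAG")
})
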