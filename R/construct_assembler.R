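#' Load the bundled construct component fixtures
#'
#' Returns the component sequences used to assemble sensor expression
#' constructs: promoter, TagBFP transfection marker, P2A self-cleaving
#' peptide, mNeonGreen payload, MCP (MS2 coat protein), ADAR2 deaminase
#' domain (E488Q), nuclear export signal, 19-nt wild-type MS2 stem-loop,
#' terminator, and a full-length ADAR1 p150 CDS for size comparisons. The
#' P2A and MS2 stem-loop are the published sequences; the remaining bundled
#' sequences are synthetic stand-ins generated at the real components'
#' lengths (flagged `synthetic=true` in the FASTA headers) — users supply
#' their own FASTA to build constructs with real parts.
#'
#' @param path FASTA of components with headers
#'   `>name coding=true|false ...`; defaults to the bundled fixture file.
#' @return named list of components, each `list(name, seq, coding, synthetic)`.
#' @export
load_components <- function(path = system.file("extdata",
                                               "components_synthetic.fa",
                                               package = "dartvadar")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("component fixture file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    hdr <- names(set)[i]
    name <- sub("\\s.*$", "", hdr)
    kv <- regmatches(hdr, gregexpr("\\w+=\\S+", hdr))[[1L]]
    kv <- stats::setNames(sub("^\\w+=", "", kv), sub("=.*$", "", kv))
    list(name = name, seq = as.character(set[[i]]),
         coding = identical(tolower(kv[["coding"]]), "true"),
         synthetic = identical(tolower(kv[["synthetic"]]), "true"))
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Insert MS2 hairpins around the sensor's UAG codon
#'
#' The MCP-ADAR fusion is recruited to the edit site through MS2 stem-loops
#' placed near the sensor UAG. Two hairpin blocks are inserted into the
#' sensor sequence in one of three configurations: `"C"` (one on each side
#' of the UAG, at the given spacers), `"L"` (both 5' of the UAG) or `"R"`
#' (both 3'). Spacers count nucleotides between the UAG codon and the
#' nearest hairpin block edge. Each block is the hairpin padded with
#' AAC-repeat linker bases to a multiple of 3, so the reading frame of the
#' downstream payload is preserved; if a block would create an in-frame stop
#' it is auto-shifted by prepending up to 3 single neutral bases (with
#' padding recomputed), and assembly fails if no stop-free shift exists.
#'
#' @param design accepted `dv_sensor_design` (or a list with `sensor_seq`,
#'   `uag_offset`, `mismatches`).
#' @param config `"C"`, `"L"` or `"R"`.
#' @param spacer_left,spacer_right nucleotides between the UAG and the
#'   left/right hairpin block (defaults 9/9).
#' @param hairpin hairpin sequence; default the bundled 19-nt MS2 stem-loop.
#' @return list of class `dv_sensor_module`: `seq`, `uag_offset` (updated),
#'   `hairpins` (data.frame `start`, `end`, 0-based half-open within the
#'   module), `n_designed_stops`.
#' @export
place_hairpins <- function(design, config = c("C", "L", "R"),
                           spacer_left = 9L, spacer_right = 9L,
                           hairpin = NULL) {
  config <- match.arg(config)
  if (is.null(hairpin)) hairpin <- load_components()[["ms2_hairpin"]]$seq
  stopifnot(spacer_left >= 0L, spacer_right >= 0L)
  sensor <- design$sensor_seq
  uag <- design$uag_offset
  n_stops <- nrow(design$mismatches)
  left_at <- uag - as.integer(spacer_left)
  right_at <- uag + 3L + as.integer(spacer_right)
  points <- switch(config,
    C = c(left_at, right_at),
    L = c(left_at, left_at),
    R = c(right_at, right_at))
  if (any(points < 0L) || any(points > nchar(sensor))) {
    stop("hairpin insertion point outside the sensor (spacers too large)",
         call. = FALSE)
  }
  for (shift in 0:3) {
    block <- make_hairpin_block(hairpin, shift)
    mod <- insert_blocks(sensor, points, block)
    n_left <- sum(points <= uag)
    uag_new <- uag + n_left * nchar(block)
    pep <- translate_seq(mod$seq, 0L)
    found <- lengths(regmatches(pep, gregexpr("\\*", pep)))
    if (found == n_stops) {
      return(structure(list(seq = mod$seq, uag_offset = uag_new,
                            hairpins = mod$blocks, block_shift = shift,
                            n_designed_stops = n_stops),
                       class = "dv_sensor_module"))
    }
  }
  stop("assembly error: no stop-free hairpin padding found within 3 shifts",
       call. = FALSE)
}

make_hairpin_block <- function(hairpin, shift) {
  block <- paste0(strrep("A", shift), hairpin)
  pad <- (3L - nchar(block) %% 3L) %% 3L
  paste0(block, substr(strrep("AAC", 2L), 1L, pad))
}

# insert the same block at the given 0-based points of seq (points refer to
# the original coordinates); returns new seq plus block intervals
insert_blocks <- function(seq, points, block) {
  points <- sort(as.integer(points))
  bl <- nchar(block)
  out <- seq
  blocks <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_along(points)) {
    p <- points[i] + (i - 1L) * bl
    out <- paste0(substr(out, 1L, p), block,
                  substr(out, p + 1L, nchar(out)))
    blocks <- rbind(blocks, data.frame(start = p, end = p + bl))
  }
  list(seq = out, blocks = blocks)
}

#' Assemble a sensor expression construct
#'
#' Builds one of five single-transcript topologies from the component
#' fixtures and an (optional) sensor design:
#' \describe{
#'   \item{closed_loop}{the autocatalytic design: promoter, marker (TagBFP),
#'     2A, sensor module with MS2 hairpins, 2A, payload (mNeonGreen), 2A,
#'     MCP-ADAR (MCP + ADAR2 deaminase domain E488Q + NES), stop,
#'     terminator — four coding components insulated by self-cleaving 2A
#'     peptides, with the editing enzyme downstream of its own edit-gated
#'     stop codon.}
#'   \item{open_loop_sensor}{the sensor transcript without the enzyme
#'     (pair with `open_loop_adar_trans`).}
#'   \item{open_loop_adar_trans}{separate promoter–MCP-ADAR–stop–terminator
#'     cassette for constitutive expression in trans.}
#'   \item{basic_no_adar}{marker, sensor (no hairpins), payload; relies on
#'     endogenous ADAR only.}
#'   \item{stopless_backbone}{the closed-loop layout with every sensor TAG
#'     pre-edited to TGG — the maximum-expression control.}
#' }
#'
#' @param design `dv_sensor_design`, required for sensor-bearing topologies.
#' @param topology one of the five topology names above.
#' @param components component list from [load_components()].
#' @param hairpin_config `"C"`, `"L"`, `"R"` or `"none"`; default `"C"` for
#'   closed-loop-style topologies, `"none"` for `basic_no_adar`.
#' @param spacer_left,spacer_right hairpin spacers, see [place_hairpins()].
#' @return object of class `dv_layout`: `topology`, `components`
#'   (data.frame `name`, `role`, `start`, `end`, `coding`), `seq`,
#'   `sensor_module`, `orf_checks`, `total_length`.
#' @export
assemble <- function(design = NULL,
                     topology = c("closed_loop", "open_loop_sensor",
                                  "open_loop_adar_trans", "basic_no_adar",
                                  "stopless_backbone"),
                     components = load_components(),
                     hairpin_config = NULL,
                     spacer_left = 9L, spacer_right = 9L) {
  topology <- match.arg(topology)
  need <- c("cmv_promoter", "tagbfp", "p2a", "mneongreen", "mcp",
            "adar2dd_e488q", "nes", "ms2_hairpin", "bgh_terminator")
  missing <- setdiff(need, names(components))
  if (length(missing)) {
    stop("configuration error: missing component fixture(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cseq <- function(n) components[[n]]$seq
  mcp_adar <- paste0(cseq("mcp"), cseq("adar2dd_e488q"), cseq("nes"))

  if (topology == "open_loop_adar_trans") {
    parts <- list(
      list(name = "cmv_promoter", role = "promoter", seq = cseq("cmv_promoter"), coding = FALSE),
      list(name = "mcp_adar", role = "mcp_adar", seq = mcp_adar, coding = TRUE),
      list(name = "stop", role = "stop", seq = "TAA", coding = TRUE),
      list(name = "bgh_terminator", role = "terminator", seq = cseq("bgh_terminator"), coding = FALSE))
    return(build_layout(topology, parts, sensor_module = NULL))
  }

  if (is.null(design)) {
    stop("a sensor design is required for topology '", topology, "'",
         call. = FALSE)
  }
  stopifnot(inherits(design, "dv_sensor_design"))
  if (!design$accepted) {
    stop("cannot assemble a rejected design: ", design$reason, call. = FALSE)
  }
  if (topology == "stopless_backbone") {
    design$sensor_seq <- simulate_edit(design)
    design$mismatches <- design$mismatches[0, , drop = FALSE]
  }
  if (is.null(hairpin_config)) {
    hairpin_config <- if (topology == "basic_no_adar") "none" else "C"
  }
  if (hairpin_config == "none") {
    smod <- structure(list(seq = design$sensor_seq,
                           uag_offset = design$uag_offset,
                           hairpins = data.frame(start = integer(0), end = integer(0)),
                           n_designed_stops = nrow(design$mismatches)),
                      class = "dv_sensor_module")
  } else {
    smod <- place_hairpins(design, hairpin_config, spacer_left, spacer_right,
                           hairpin = components[["ms2_hairpin"]]$seq)
  }

  parts <- list(
    list(name = "cmv_promoter", role = "promoter", seq = cseq("cmv_promoter"), coding = FALSE),
    list(name = "tagbfp", role = "marker", seq = cseq("tagbfp"), coding = TRUE),
    list(name = "p2a", role = "linker_2a", seq = cseq("p2a"), coding = TRUE),
    list(name = "sensor_module", role = "sensor_module", seq = smod$seq, coding = TRUE),
    list(name = "p2a", role = "linker_2a", seq = cseq("p2a"), coding = TRUE),
    list(name = "mneongreen", role = "payload", seq = cseq("mneongreen"), coding = TRUE))
  if (topology %in% c("closed_loop", "stopless_backbone")) {
    parts <- c(parts, list(
      list(name = "p2a", role = "linker_2a", seq = cseq("p2a"), coding = TRUE),
      list(name = "mcp_adar", role = "mcp_adar", seq = mcp_adar, coding = TRUE)))
  }
  parts <- c(parts, list(
    list(name = "stop", role = "stop", seq = "TAA", coding = TRUE),
    list(name = "bgh_terminator", role = "terminator", seq = cseq("bgh_terminator"), coding = FALSE)))

  build_layout(topology, parts, smod)
}

build_layout <- function(topology, parts, sensor_module) {
  seqs <- vapply(parts, `[[`, character(1), "seq")
  ends <- cumsum(nchar(seqs))
  comp <- data.frame(
    name = vapply(parts, `[[`, character(1), "name"),
    role = vapply(parts, `[[`, character(1), "role"),
    start = c(0L, utils::head(ends, -1L)),
    end = ends,
    coding = vapply(parts, `[[`, logical(1), "coding"),
    stringsAsFactors = FALSE)
  full <- paste0(seqs, collapse = "")
  layout <- structure(
    list(topology = topology, components = comp, seq = full,
         sensor_module = sensor_module, total_length = nchar(full)),
    class = "dv_layout")
  layout$orf_checks <- orf_checks(layout)
  if (!is.null(layout$orf_checks$error)) {
    stop("assembly error: ", layout$orf_checks$error, call. = FALSE)
  }
  layout
}

orf_checks <- function(layout) {
  comp <- layout$components
  coding <- comp[comp$coding, , drop = FALSE]
  orf <- substr(layout$seq, min(coding$start) + 1L, max(coding$end))
  frame_ok <- nchar(orf) %% 3L == 0L
  pep <- translate_seq(orf, 0L)
  term_ok <- substr(pep, nchar(pep), nchar(pep)) == "*"
  internal_pep <- substr(pep, 1L, nchar(pep) - 1L)
  internal_stops <- lengths(regmatches(internal_pep, gregexpr("\\*", internal_pep)))
  codons <- substring(orf, seq(1L, nchar(orf) - 3L, 3L),
                      seq(3L, nchar(orf) - 1L, 3L))
  internal_tag <- sum(codons[-length(codons)] == "TAG")
  expected <- if (is.null(layout$sensor_module)) 0L
              else layout$sensor_module$n_designed_stops
  err <- NULL
  if (!frame_ok) err <- "coding region length is not a multiple of 3"
  else if (!term_ok) err <- "ORF does not end in a stop codon"
  else if (internal_stops != expected) {
    err <- sprintf("unexpected internal stop count %d (expected %d); check junctions",
                   internal_stops, expected)
  }
  list(frame_ok = frame_ok, terminal_stop = term_ok,
       internal_stop_count = as.integer(internal_stops),
       internal_tag_count = as.integer(internal_tag),
       n_coding_components = sum(!coding$role %in% c("linker_2a", "stop")),
       n_2a = sum(coding$role == "linker_2a"),
       error = err)
}

#' @export
print.dv_layout <- function(x, ...) {
  cat(sprintf("<dv_layout> %s: %d nt, %d components, %d internal TAG\n",
              x$topology, x$total_length, nrow(x$components),
              x$orf_checks$internal_tag_count))
  invisible(x)
}

#' Vector size budget of a construct
#'
#' Clinically deployable vectors (AAV) cap the cassette near 5 kb including
#' promoter and terminator; this reports the assembled construct's total
#' length against that capacity.
#' @param layout a `dv_layout`.
#' @param capacity_nt packaging capacity; default 5000.
#' @return list `total_nt`, `fraction_of_capacity`, `within_budget`.
#' @export
size_budget <- function(layout, capacity_nt = 5000L) {
  total <- if (is.null(layout$components) || nrow(layout$components) == 0L) 0L
           else sum(layout$components$end - layout$components$start)
  list(total_nt = as.integer(total),
       fraction_of_capacity = total / capacity_nt,
       within_budget = total < capacity_nt)
}

#' Wrap a single component as a minimal layout (for size comparisons)
#' @param component one element of [load_components()].
#' @return `dv_layout` with that single component.
#' @export
single_component_layout <- function(component) {
  structure(
    list(topology = "single_component",
         components = data.frame(name = component$name, role = "component",
                                 start = 0L, end = nchar(component$seq),
                                 coding = component$coding,
                                 stringsAsFactors = FALSE),
         seq = component$seq, sensor_module = NULL,
         total_length = nchar(component$seq),
         orf_checks = NULL),
    class = "dv_layout")
}

#' Write a construct layout as a GenBank flat file
#'
#' One feature per component (`CDS` for coding parts, `misc_feature`
#' otherwise) with 1-based inclusive coordinates, plus a `misc_feature` on
#' the sensor UAG when present.
#' @param layout `dv_layout`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(layout, path) {
  comp <- layout$components
  con <- file(path, "w")
  on.exit(close(con))
  name <- substr(gsub("[^A-Za-z0-9_]", "_", layout$topology), 1L, 16L)
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   SYN %s",
                     name, layout$total_length,
                     toupper(format(Sys.Date(), "%d-%b-%Y"))), con)
  writeLines(sprintf("DEFINITION  %s sensor construct.", layout$topology), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", layout$total_length), con)
  for (i in seq_len(nrow(comp))) {
    type <- if (comp$coding[i]) "CDS" else "misc_feature"
    writeLines(sprintf("     %-15s %d..%d", type, comp$start[i] + 1L, comp$end[i]), con)
    writeLines(sprintf("                     /label=\"%s\"", comp$name[i]), con)
  }
  if (!is.null(layout$sensor_module)) {
    srow <- comp[comp$role == "sensor_module", , drop = FALSE]
    if (nrow(srow) == 1L) {
      u <- srow$start[1L] + layout$sensor_module$uag_offset
      writeLines(sprintf("     misc_feature    %d..%d", u + 1L, u + 3L), con)
      writeLines("                     /label=\"sensor_UAG\"", con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(layout$seq)
  for (p in seq(1L, nchar(s), 60L)) {
    line <- substr(s, p, min(p + 59L, nchar(s)))
    chunks <- substring(line, seq(1L, nchar(line), 10L),
                        pmin(seq(1L, nchar(line), 10L) + 9L, nchar(line)))
    writeLines(sprintf("%9d %s", p, paste(chunks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read back a GenBank flat file written by [write_genbank()]
#' @param path GenBank file.
#' @return list `length`, `features` (data.frame `type`, `start`, `end`,
#'   `label`; 1-based inclusive), `seq`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- regmatches(lines[1L], regexec("\\s(\\d+) bp", lines[1L]))[[1L]]
  len <- as.integer(locus[2L])
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  feats <- data.frame(type = character(), start = integer(), end = integer(),
                      label = character(), stringsAsFactors = FALSE)
  i <- fstart + 1L
  while (i < ostart) {
    m <- regexec("^     (\\S+)\\s+(\\d+)\\.\\.(\\d+)", lines[i])[[1L]]
    if (m[1L] != -1L) {
      g <- regmatches(lines[i], regexec("^     (\\S+)\\s+(\\d+)\\.\\.(\\d+)", lines[i]))[[1L]]
      label <- NA_character_
      if (i + 1L < ostart && grepl("/label=", lines[i + 1L])) {
        label <- sub('.*?/label="(.*)".*', "\\1", lines[i + 1L])
      }
      feats <- rbind(feats, data.frame(type = g[2L], start = as.integer(g[3L]),
                                       end = as.integer(g[4L]), label = label,
                                       stringsAsFactors = FALSE))
    }
    i <- i + 1L
  }
  seq_lines <- lines[(ostart + 1L):(length(lines))]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
  list(length = len, features = feats, seq = seq)
}
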