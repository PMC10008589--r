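#' Design an ADAR-activatable sensor against an edit site
#'
#' The sensor is the reverse complement of a window of the target transcript
#' centered on the CCA motif, with a single designed substitution: the base
#' opposite the central C of the CCA is changed G -> A, creating a central
#' in-frame TAG (UAG in the RNA) whose A sits in an A:C mismatch. Upon
#' hybridization with the target, ADAR deaminates that A to inosine (read as
#' G), converting the amber stop to a tryptophan codon and licensing
#' translation of the downstream payload.
#'
#' Window lengths must satisfy `length %% 6 == 3` so that `(length - 3) / 2`
#' is a multiple of 3 and the central triplet sits on a codon boundary of the
#' sensor insert (frame 0). The default is 75 nt; 51 nt is the short preset.
#' A design whose frame-0 translation contains any stop codon other than the
#' designed central TAG is rejected (recoding the sensor would break
#' complementarity to the target), with the reason recorded; callers then
#' move to the next-ranked site.
#'
#' @param x a [transcript()].
#' @param site one row of the `dv_sites` frame from [scan_cca()] (or any list
#'   with `motif_start`).
#' @param length sensor window length; `length %% 6 == 3`. Default 75.
#' @return object of class `dv_sensor_design` with fields `sensor_seq`,
#'   `uag_offset` (0-based offset of the T of the central TAG), `mismatches`
#'   (data.frame `sensor_offset`, `sensor_base`, `target_base`), `window`
#'   (0-based half-open on the target), `peptide`, `mode`, `accepted`,
#'   `reason`.
#' @export
design_sensor <- function(x, site, length = 75L) {
  d <- design_core(x, site, length)
  d$mode <- "single_stop"
  finalize_design(d)
}

design_core <- function(x, site, length) {
  stopifnot(inherits(x, "dv_transcript"))
  length <- as.integer(length)
  if (length %% 6L != 3L) {
    stop("sensor length must satisfy length %% 6 == 3 (e.g. 51, 75); got ",
         length, call. = FALSE)
  }
  m <- as.integer(site$motif_start[1L])
  if (substr(x$seq, m + 1L, m + 3L) != "CCA") {
    stop("no CCA motif at offset ", m, " of transcript ", x$id, call. = FALSE)
  }
  arm <- (length - 3L) %/% 2L
  win_start <- m - arm
  win_end <- win_start + length
  if (win_start < 0L || win_end > nchar(x$seq)) {
    stop("sensor window [", win_start, ", ", win_end,
         ") out of transcript bounds (length ", nchar(x$seq), ")",
         call. = FALSE)
  }
  window <- substr(x$seq, win_start + 1L, win_end)
  uag_offset <- arm
  d <- list(
    site = as.list(site)[c("transcript_id", "motif_start", "anchored_pos",
                           "name", "context")],
    window = c(start = win_start, end = win_end),
    length = length,
    target_window = window,
    uag_offset = uag_offset,
    accepted = TRUE, reason = NA_character_)
  if (grepl("N", window, fixed = TRUE)) {
    d$accepted <- FALSE
    d$reason <- "window contains N; pairing cannot be guaranteed"
    d$sensor_seq <- NA_character_
    d$mismatches <- mismatch_frame()
    d$peptide <- NA_character_
    return(d)
  }
  sensor <- revcomp(window)
  # the base opposite the central C of the CCA is the middle of the sensor's
  # central triplet (revcomp of CCA is TGG); G -> A creates the TAG
  mid <- uag_offset + 1L
  stopifnot(substr(sensor, uag_offset + 1L, uag_offset + 3L) == "TGG")
  substr(sensor, mid + 1L, mid + 1L) <- "A"
  d$sensor_seq <- sensor
  d$mismatches <- data.frame(
    sensor_offset = mid, sensor_base = "A",
    target_base = opposing_base(window, length, mid),
    stringsAsFactors = FALSE)
  d
}

mismatch_frame <- function() {
  data.frame(sensor_offset = integer(), sensor_base = character(),
             target_base = character(), stringsAsFactors = FALSE)
}

# target-window base opposite sensor offset i (both 0-based)
opposing_base <- function(window, length, i) {
  substr(window, length - i, length - i)
}

finalize_design <- function(d) {
  if (d$accepted) {
    d$peptide <- translate_seq(d$sensor_seq, 0L)
    n_tag <- nrow(d$mismatches)
    stops <- gregexpr("*", d$peptide, fixed = TRUE)[[1L]]
    n_stop <- if (stops[1L] == -1L) 0L else length(stops)
    expected <- if (d$mode == "allstop") n_tag else 1L
    if (n_stop != expected) {
      d$accepted <- FALSE
      d$reason <- sprintf(
        "residual in-frame stop: %d stop(s) in sensor frame 0, expected %d",
        n_stop, expected)
    }
  }
  class(d) <- "dv_sensor_design"
  d
}

#' @export
print.dv_sensor_design <- function(x, ...) {
  cat(sprintf("<dv_sensor_design> %s site %s, %d nt, mode %s, %s\n",
              x$site$transcript_id, x$site$name, x$length, x$mode,
              if (x$accepted) "accepted" else paste("REJECTED:", x$reason)))
  if (x$accepted) {
    cat(" sensor:  ", x$sensor_seq, "\n", " peptide: ", x$peptide, "\n", sep = "")
  }
  invisible(x)
}

#' All-stop sensor variant
#'
#' Starting from the single-stop design, every additional CCA of the target
#' window whose opposing sensor triplet falls on a frame-0 codon boundary is
#' also converted TGG -> TAG, giving multiple editable amber codons per
#' sensor. CCAs whose opposing triplet is out of frame are left as perfect
#' TGG pairs (converting them would put the stop out of frame) and reported
#' in `skipped_cca`.
#'
#' @inheritParams design_sensor
#' @return `dv_sensor_design` with `mode = "allstop"` and a `skipped_cca`
#'   field (0-based window-relative offsets of out-of-frame CCAs).
#' @export
design_allstop <- function(x, site, length = 75L) {
  d <- design_core(x, site, length)
  d$mode <- "allstop"
  d$skipped_cca <- integer(0)
  if (!d$accepted) return(finalize_design(d))
  win <- d$target_window
  L <- d$length
  central <- d$uag_offset  # window-relative offset of the central CCA
  for (t in motif_offsets(win, "CCA")) {
    if (t == central) next
    s <- L - 3L - t   # sensor offset of the opposing triplet (TGG)
    if (s < 0L) next
    if (s %% 3L == 0L) {
      if (substr(d$sensor_seq, s + 1L, s + 3L) != "TGG") next  # overlaps an edit
      substr(d$sensor_seq, s + 2L, s + 2L) <- "A"
      d$mismatches <- rbind(d$mismatches, data.frame(
        sensor_offset = s + 1L, sensor_base = "A",
        target_base = opposing_base(win, L, s + 1L),
        stringsAsFactors = FALSE))
    } else {
      d$skipped_cca <- c(d$skipped_cca, t)
    }
  }
  d$mismatches <- d$mismatches[order(d$mismatches$sensor_offset), , drop = FALSE]
  rownames(d$mismatches) <- NULL
  finalize_design(d)
}

#' Parse an HGVS-like coding variant specification
#' @param spec string like `"c.658T>C"`.
#' @return list with `pos` (1-based CDS position), `ref`, `alt`.
#' @export
parse_variant <- function(spec) {
  m <- regmatches(spec, regexec("^c\\.(\\d+)([ACGTU])>([ACGTU])$", spec))[[1L]]
  if (length(m) != 4L) {
    stop("cannot parse variant spec '", spec, "'; expected e.g. c.658T>C",
         call. = FALSE)
  }
  list(pos = as.integer(m[2L]), ref = chartr("U", "T", m[3L]),
       alt = chartr("U", "T", m[4L]))
}

#' Apply a coding variant to a transcript
#' @param x a [transcript()] with an annotated CDS.
#' @param spec variant spec accepted by [parse_variant()].
#' @return the mutant transcript (id suffixed with the variant).
#' @export
apply_variant <- function(x, spec) {
  v <- parse_variant(spec)
  cs <- cds_start(x)
  if (is.na(cs)) stop("transcript has no annotated CDS; c. coordinates undefined",
                      call. = FALSE)
  off <- cs + v$pos - 1L
  if (off >= nchar(x$seq)) stop("variant position beyond transcript end", call. = FALSE)
  have <- substr(x$seq, off + 1L, off + 1L)
  if (have != v$ref) {
    stop("reference allele mismatch at c.", v$pos, ": transcript has ", have,
         ", spec says ", v$ref, call. = FALSE)
  }
  seq <- x$seq
  substr(seq, off + 1L, off + 1L) <- v$alt
  transcript(paste0(x$id, "_", spec), seq, x$regions, x$localization, x$secreted)
}

#' Design a single-nucleotide-variant discrimination sensor
#'
#' For a variant whose ALT allele creates a CCA motif (wild-type local
#' context C-T-A becoming mutant C-C-A), a sensor centered on the created
#' CCA discriminates the two alleles: it is fully complementary to the
#' wild-type window — the sensor's central A pairs A:T with the wild-type
#' base, so the adenosine is protected from ADAR — while against the mutant
#' it forms exactly one mismatch, the editable central A opposite the mutant
#' C. The design is verified against both alleles before being returned.
#'
#' @param x_wt wild-type [transcript()] with annotated CDS.
#' @param variant_spec variant spec like `"c.658T>C"`.
#' @param length sensor length; default 75.
#' @return `dv_sensor_design` with `mode = "snv_discrimination"` and fields
#'   `mismatches_vs_wt` / `mismatches_vs_mut` (counts).
#' @export
design_snv_sensor <- function(x_wt, variant_spec, length = 75L) {
  v <- parse_variant(variant_spec)
  x_mut <- apply_variant(x_wt, variant_spec)
  var_off <- cds_start(x_wt) + v$pos - 1L
  new_sites <- setdiff(motif_offsets(x_mut$seq, "CCA"),
                       motif_offsets(x_wt$seq, "CCA"))
  # the editable A must oppose the variant base, so the variant must be the
  # central C of the created motif
  central <- new_sites[new_sites + 1L == var_off]
  if (length(central) != 1L) {
    stop("variant ", variant_spec, " does not create a CCA motif with the ",
         "ALT base as its central C; SNV discrimination mode is inapplicable",
         call. = FALSE)
  }
  sites <- scan_cca(x_mut)
  site <- sites[sites$motif_start == central, , drop = FALSE]
  d <- design_sensor(x_mut, site, length)
  d$mode <- "snv_discrimination"
  if (!d$accepted) return(d)
  wt_window <- substr(x_wt$seq, d$window["start"] + 1L, d$window["end"])
  d$mismatches_vs_wt <- duplex_mismatches(d$sensor_seq, wt_window)
  d$mismatches_vs_mut <- duplex_mismatches(d$sensor_seq, d$target_window)
  if (d$mismatches_vs_wt != 0L) {
    stop("internal consistency error: SNV sensor is not fully complementary ",
         "to the wild-type window (", d$mismatches_vs_wt, " mismatch(es))",
         call. = FALSE)
  }
  if (d$mismatches_vs_mut != 1L) {
    stop("internal consistency error: SNV sensor forms ", d$mismatches_vs_mut,
         " mismatches against the mutant window, expected exactly 1",
         call. = FALSE)
  }
  d
}

# number of non-Watson-Crick positions when sensor pairs antiparallel with window
duplex_mismatches <- function(sensor_seq, window) {
  sum(strsplit(sensor_seq, "")[[1L]] != strsplit(revcomp(window), "")[[1L]])
}

#' Simulate ADAR editing of a sensor design
#'
#' Replaces the middle A of every designed TAG by G (A-to-I editing read as
#' G), restoring the exact reverse complement of the target window; the
#' central codon becomes TGG (Trp) and translation runs through.
#' @param design a `dv_sensor_design`.
#' @return the edited sensor sequence.
#' @export
simulate_edit <- function(design) {
  stopifnot(inherits(design, "dv_sensor_design"), design$accepted)
  seq <- design$sensor_seq
  for (i in seq_len(nrow(design$mismatches))) {
    off <- design$mismatches$sensor_offset[i]
    stopifnot(substr(seq, off + 1L, off + 1L) == "A")
    substr(seq, off + 1L, off + 1L) <- "G"
  }
  seq
}

#' Validate a sensor design
#'
#' Aggregates the design constraints into a report: duplex mismatch map
#' against the target window, in-frame stop count, frame compatibility
#' (length divisible by 3), and a central-codon edit simulation (every TAG
#' must become TGG and the edited sensor must be stop-free and identical to
#' the reverse complement of the window).
#'
#' @param design `dv_sensor_design`.
#' @param x the target [transcript()].
#' @return list of class `dv_design_report` with `pass`, `reasons`,
#'   `stop_count`, `mismatches`, `frame_ok`, `edited_stop_count`.
#' @export
validate_design <- function(design, x) {
  stopifnot(inherits(design, "dv_sensor_design"))
  reasons <- character(0)
  if (!design$accepted) {
    reasons <- c(reasons, design$reason)
    rep <- list(pass = FALSE, reasons = reasons, stop_count = NA_integer_,
                mismatches = design$mismatches, frame_ok = NA,
                edited_stop_count = NA_integer_)
    class(rep) <- "dv_design_report"
    return(rep)
  }
  window <- substr(x$seq, design$window["start"] + 1L, design$window["end"])
  frame_ok <- design$length %% 3L == 0L
  if (!frame_ok) reasons <- c(reasons, "sensor length not a multiple of 3")
  pep <- translate_seq(design$sensor_seq, 0L)
  stop_count <- lengths(regmatches(pep, gregexpr("\\*", pep)))
  n_designed <- nrow(design$mismatches)
  if (stop_count != n_designed) {
    reasons <- c(reasons, "residual in-frame stop")
  }
  edited <- simulate_edit(design)
  edited_pep <- translate_seq(edited, 0L)
  edited_stop_count <- lengths(regmatches(edited_pep, gregexpr("\\*", edited_pep)))
  if (edited_stop_count != 0L) reasons <- c(reasons, "edited sensor retains a stop")
  if (edited != revcomp(window)) {
    reasons <- c(reasons, "edited sensor is not the exact reverse complement of the window")
  }
  central <- substr(edited, design$uag_offset + 1L, design$uag_offset + 3L)
  if (central != "TGG") reasons <- c(reasons, "edited central codon is not TGG (Trp)")
  rep <- list(pass = length(reasons) == 0L, reasons = reasons,
              stop_count = as.integer(stop_count),
              mismatches = design$mismatches, frame_ok = frame_ok,
              edited_stop_count = as.integer(edited_stop_count))
  class(rep) <- "dv_design_report"
  rep
}

#' @export
print.dv_design_report <- function(x, ...) {
  cat(sprintf("<dv_design_report> %s; stops: %s; mismatches: %d\n",
              if (x$pass) "PASS" else paste("FAIL:", paste(x$reasons, collapse = "; ")),
              x$stop_count, nrow(x$mismatches)))
  invisible(x)
}
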