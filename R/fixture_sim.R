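#' Specification for the synthetic-data generator
#'
#' Collects the parameters of the simulators that stand in for the wet-lab
#' inputs of a sensor experiment: a trigger transcript with CCA motifs
#' planted at known start-codon-anchored positions, amplicon reads with
#' planted per-position A-to-G editing probabilities, and per-cell
#' fluorescence tables drawn from log-normal populations (the natural model
#' when geometric-mean statistics are the readout). All generators are
#' seed-deterministic.
#'
#' @param seed integer RNG seed; fully determines all outputs.
#' @param utr5_len,cds_len,utr3_len region layout of the trigger (nt);
#'   `cds_len` must be a multiple of 3.
#' @param planted_cca 1-based start-codon-anchored positions of the first C
#'   of each planted CCA motif; must be >= 4 apart.
#' @param read_depth number of amplicon reads to simulate.
#' @param editing_prob named numeric vector: per-position editing
#'   probabilities, names = 1-based reference positions (must be reference-A
#'   positions).
#' @param error_rate uniform per-base sequencing error rate; default 0 so
#'   that recovery oracles are exact.
#' @param n_cells cells per population; default 2000 (the minimum cell count
#'   used for fold-change estimates).
#' @param mean_log_on,mean_log_off,sd_log log-scale parameters of the
#'   reporter intensity populations (natural log).
#' @param marker_mean_log,marker_sd_log transfection-marker intensity model.
#' @return list of class `dv_sim_spec`.
#' @export
sim_spec <- function(seed = 1L, utr5_len = 60L, cds_len = 300L,
                     utr3_len = 140L, planted_cca = c(60L, 150L),
                     read_depth = 5000L, editing_prob = NULL,
                     error_rate = 0, n_cells = 2000L,
                     mean_log_on = log(900), mean_log_off = log(100),
                     sd_log = 0.8, marker_mean_log = log(1000),
                     marker_sd_log = 1.0) {
  stopifnot(cds_len %% 3L == 0L, sd_log > 0, n_cells >= 1L,
            error_rate >= 0, error_rate <= 1)
  if (!is.null(editing_prob)) {
    stopifnot(all(editing_prob >= 0), all(editing_prob <= 1),
              !is.null(names(editing_prob)))
  }
  if (length(planted_cca) > 1L && any(diff(sort(planted_cca)) < 4L)) {
    stop("planted CCA positions must be at least 4 nt apart", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), utr5_len = as.integer(utr5_len),
                 cds_len = as.integer(cds_len), utr3_len = as.integer(utr3_len),
                 planted_cca = as.integer(planted_cca),
                 read_depth = as.integer(read_depth),
                 editing_prob = editing_prob, error_rate = error_rate,
                 n_cells = as.integer(n_cells), mean_log_on = mean_log_on,
                 mean_log_off = mean_log_off, sd_log = sd_log,
                 marker_mean_log = marker_mean_log,
                 marker_sd_log = marker_sd_log),
            class = "dv_sim_spec")
}

#' Simulate a trigger transcript with planted CCA motifs
#'
#' Generates a random-background transcript (5'UTR + CDS + 3'UTR) containing
#' a CCA motif exactly at each planted start-codon-anchored position and
#' nowhere else: background CCA occurrences are removed by rejection-style
#' resampling of the offending bases. The CDS begins with ATG, ends with a
#' stop codon, and contains no internal in-frame stops. Planted sites are
#' additionally made sensor-designable: within the default 75-nt design
#' window around each planted motif (when it fits the transcript), target
#' triplets whose reverse complement would be an in-frame stop in the sensor
#' (TTA, CTA, TCA aligned to the sensor frame) are scrubbed, so a centered
#' sensor at each planted site carries its designed UAG and no residual
#' stop. Optionally writes the FASTA and a 1-based inclusive region TSV.
#'
#' @param spec a [sim_spec()].
#' @param fasta,regions optional output paths.
#' @return a [transcript()] with regions annotated.
#' @export
make_trigger <- function(spec, fasta = NULL, regions = NULL) {
  stopifnot(inherits(spec, "dv_sim_spec"))
  set.seed(spec$seed)
  total <- spec$utr5_len + spec$cds_len + spec$utr3_len
  plant_off <- spec$utr5_len + spec$planted_cca - 1L  # anchored pos 1 = cds start
  if (any(plant_off < 0L) || any(plant_off + 3L > total)) {
    stop("infeasible spec: planted CCA positions fall outside the transcript",
         call. = FALSE)
  }
  if (3L * length(plant_off) > total) {
    stop("infeasible spec: too many planted motifs for transcript length",
         call. = FALSE)
  }
  for (attempt in 1:100) {
    chars <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
    # enforce a clean ORF: ATG ... internal non-stop codons ... terminal stop
    cds_i <- (spec$utr5_len + 1L):(spec$utr5_len + spec$cds_len)
    chars[cds_i[1:3]] <- c("A", "T", "G")
    chars[utils::tail(cds_i, 3L)] <- c("T", "A", "A")
    seq <- paste0(chars, collapse = "")
    seq <- plant_motifs(seq, plant_off)
    for (round in 1:20) {
      seq <- scrub_motifs(seq, "CCA", keep = plant_off, spec = spec)
      seq <- plant_motifs(seq, plant_off)
      seq <- scrub_antisense_stops(seq, plant_off)
      seq <- scrub_internal_stops(seq, spec$utr5_len, spec$cds_len, plant_off)
      if (trigger_ok(seq, spec, plant_off)) break
    }
    if (trigger_ok(seq, spec, plant_off)) break
    if (attempt == 100L) stop("infeasible spec: could not satisfy motif/ORF ",
                              "constraints", call. = FALSE)
  }
  reg <- data.frame(
    kind = c("five_prime_utr", "cds", "three_prime_utr"),
    start = c(0L, spec$utr5_len, spec$utr5_len + spec$cds_len),
    end = c(spec$utr5_len, spec$utr5_len + spec$cds_len, total))
  reg <- reg[reg$end > reg$start, , drop = FALSE]
  tr <- transcript(sprintf("trigger_seed%d", spec$seed), seq, reg)
  if (!is.null(fasta)) write_fasta(tr, fasta)
  if (!is.null(regions)) {
    utils::write.table(
      data.frame(kind = reg$kind, start = reg$start + 1L, end = reg$end),
      regions, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  tr
}

#' Simulate a wild-type / variant transcript pair for SNV discrimination
#'
#' Takes a planted (sensor-designable) CCA site of a simulated trigger and
#' reverts its central C to T, giving a wild-type transcript with a C-T-A
#' local context; the coding variant `c.<pos>T>C` then recreates the CCA, so
#' [design_snv_sensor()] applies. The planted site must lie inside the CDS.
#'
#' @param spec a [sim_spec()].
#' @param which_plant index into `spec$planted_cca`; default 1.
#' @return list `wt` (wild-type [transcript()]), `variant` (spec string),
#'   `mut` (the mutant transcript, equal to the plain simulated trigger).
#' @export
make_snv_pair <- function(spec, which_plant = 1L) {
  mut <- make_trigger(spec)
  m <- cds_start(mut) + spec$planted_cca[which_plant] - 1L  # motif start offset
  central <- m + 1L
  cds <- mut$regions[mut$regions$kind == "cds", ]
  if (central < cds$start || central >= cds$end) {
    stop("planted site ", which_plant, " is not inside the CDS", call. = FALSE)
  }
  wt_seq <- mut$seq
  substr(wt_seq, central + 1L, central + 1L) <- "T"
  wt <- transcript(paste0(mut$id, "_wt"), wt_seq, mut$regions,
                   mut$localization, mut$secreted)
  variant <- sprintf("c.%dT>C", central - cds_start(mut) + 1L)
  list(wt = wt, variant = variant, mut = mut)
}

# resample single bases to destroy unwanted occurrences of a motif
scrub_motifs <- function(seq, motif, keep, spec) {
  protected <- unique(c(outer(keep, 0:2, `+`)))
  for (round in 1:50) {
    offs <- setdiff(motif_offsets(seq, motif), keep)
    if (length(offs) == 0L) return(seq)
    for (o in offs) {
      pos <- o + 1L  # mutate the central C (0-based o+1), unless protected
      cand <- setdiff(o + 0:2, protected)
      if (length(cand) == 0L) next
      pos <- cand[length(cand) %/% 2L + 1L]
      repl <- sample(setdiff(c("A", "G", "T"),
                             substr(seq, pos + 1L, pos + 1L)), 1L)
      substr(seq, pos + 1L, pos + 1L) <- repl
    }
  }
  seq
}

plant_motifs <- function(seq, offsets) {
  for (o in offsets) substr(seq, o + 1L, o + 3L) <- "CCA"
  seq
}

# target triplets whose reverse complement is a sensor-frame stop codon
ANTISENSE_STOP_TRIPLETS <- c("TTA", "CTA", "TCA")

# within the 75-nt design window around each planted motif, destroy in-frame
# triplets that would become residual sensor stops (G never forms part of a
# CCA, so the fix cannot recreate the motif)
scrub_antisense_stops <- function(seq, plant_off, arm = 36L) {
  protected <- unique(c(outer(plant_off, 0:2, `+`)))
  for (m in plant_off) {
    lo <- m - arm; hi <- m + arm + 3L     # window is [lo, hi)
    if (lo < 0L || hi > nchar(seq)) next   # window does not fit; skip
    for (t in seq.int(lo, m + arm, by = 3L)) {
      if (t == m) next
      trip <- substr(seq, t + 1L, t + 3L)
      if (trip %in% ANTISENSE_STOP_TRIPLETS) {
        cand <- setdiff(t + 0:2, protected)
        if (length(cand) == 0L) next
        pos <- cand[min(2L, length(cand))]   # prefer the middle base
        substr(seq, pos + 1L, pos + 1L) <- "G"
      }
    }
  }
  seq
}

trigger_ok <- function(seq, spec, plant_off) {
  if (!identical(motif_offsets(seq, "CCA"), sort(plant_off))) return(FALSE)
  pep <- translate_seq(substr(seq, spec$utr5_len + 1L,
                              spec$utr5_len + spec$cds_len))
  if (!identical(gregexpr("\\*", pep)[[1L]][1L], nchar(pep))) return(FALSE)
  arm <- 36L
  for (m in plant_off) {
    lo <- m - arm
    if (lo < 0L || m + arm + 3L > nchar(seq)) next
    for (t in seq.int(lo, m + arm, by = 3L)) {
      if (t == m) next
      if (substr(seq, t + 1L, t + 3L) %in% ANTISENSE_STOP_TRIPLETS) return(FALSE)
    }
  }
  TRUE
}

scrub_internal_stops <- function(seq, utr5_len, cds_len, protected_off) {
  protected <- unique(c(outer(protected_off, 0:2, `+`)))
  for (round in 1:50) {
    cds <- substr(seq, utr5_len + 1L, utr5_len + cds_len)
    pep <- translate_seq(cds)
    stops <- gregexpr("\\*", pep)[[1L]]
    internal <- stops[stops != -1L & stops != nchar(pep)]
    if (length(internal) == 0L) return(seq)
    for (cod in internal) {
      base_off <- utr5_len + (cod - 1L) * 3L   # 0-based offset of codon start
      cand <- setdiff(base_off + 0:2, protected)
      if (length(cand) == 0L) next
      pos <- cand[1L]
      substr(seq, pos + 1L, pos + 1L) <- "C"   # C never completes a stop codon
    }
  }
  seq
}

#' Simulate amplicon reads with planted editing rates
#'
#' Draws `read_depth` full-length copies of the reference; at each
#' reference-A position listed in `spec$editing_prob` the base is converted
#' to G independently per read with its planted probability, then uniform
#' substitution errors are applied at `spec$error_rate` (default 0, keeping
#' recovery oracles exact). Optionally written as FASTQ with constant
#' quality.
#'
#' @param reference reference sequence (string or [transcript()]).
#' @param spec a [sim_spec()]; positions named in `editing_prob` must hold A
#'   in the reference.
#' @param fastq optional output FASTQ path.
#' @return character vector of reads (invisibly when `fastq` is given).
#' @export
simulate_reads <- function(reference, spec, fastq = NULL) {
  stopifnot(inherits(spec, "dv_sim_spec"))
  if (inherits(reference, "dv_transcript")) reference <- reference$seq
  reference <- normalize_seq(reference)
  set.seed(spec$seed + 1L)
  L <- nchar(reference)
  n <- spec$read_depth
  ref_chars <- strsplit(reference, "")[[1L]]
  mat <- matrix(ref_chars, nrow = n, ncol = L, byrow = TRUE)
  if (!is.null(spec$editing_prob)) {
    pos <- as.integer(names(spec$editing_prob))
    if (any(ref_chars[pos] != "A")) {
      stop("editing probabilities must sit at reference-A positions",
           call. = FALSE)
    }
    for (i in seq_along(pos)) {
      hit <- stats::runif(n) < spec$editing_prob[i]
      mat[hit, pos[i]] <- "G"
    }
  }
  if (spec$error_rate > 0) {
    err <- which(matrix(stats::runif(n * L) < spec$error_rate, n, L))
    if (length(err)) {
      cur <- mat[err]
      mat[err] <- vapply(cur, function(b) sample(setdiff(c("A","C","G","T"), b), 1L),
                         character(1))
    }
  }
  reads <- apply(mat, 1L, paste0, collapse = "")
  names(reads) <- sprintf("read_%06d", seq_len(n))
  if (!is.null(fastq)) {
    set <- Biostrings::DNAStringSet(reads)
    qual <- Biostrings::PhredQuality(strrep("I", L))
    qset <- Biostrings::QualityScaledDNAStringSet(set, rep(qual, n))
    Biostrings::writeXStringSet(qset, fastq, format = "fastq",
                                qualities = Biostrings::quality(qset))
    return(invisible(reads))
  }
  reads
}

#' Simulate per-cell fluorescence intensity tables
#'
#' Draws log-normal reporter intensities for an ON (trigger-present) and an
#' OFF (no-trigger) population plus a shared log-normal transfection-marker
#' channel; the planted true fold-change is
#' `exp(mean_log_on - mean_log_off)`. Optionally written as CSV
#' (`cell`, `population`, `marker`, `reporter`).
#'
#' @param spec a [sim_spec()].
#' @param csv optional output path.
#' @return data.frame with `cell`, `population` ("on"/"off"), `marker`,
#'   `reporter`; attribute `true_fc`.
#' @export
simulate_cells <- function(spec, csv = NULL) {
  stopifnot(inherits(spec, "dv_sim_spec"))
  set.seed(spec$seed + 2L)
  n <- spec$n_cells
  df <- data.frame(
    cell = sprintf("cell_%05d", seq_len(2L * n)),
    population = rep(c("on", "off"), each = n),
    marker = stats::rlnorm(2L * n, spec$marker_mean_log, spec$marker_sd_log),
    reporter = c(stats::rlnorm(n, spec$mean_log_on, spec$sd_log),
                 stats::rlnorm(n, spec$mean_log_off, spec$sd_log)),
    stringsAsFactors = FALSE)
  attr(df, "true_fc") <- exp(spec$mean_log_on - spec$mean_log_off)
  if (!is.null(csv)) utils::write.table(df, csv, sep = ",", quote = FALSE,
                                        row.names = FALSE)
  df
}
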