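#' Per-position base counts and A-to-G editing fractions
#'
#' A-to-I editing reads out as A-to-G substitutions in sequencing, so the
#' editing fraction at a reference-A position is `G / (A + G)` over the read
#' bases piled up there (sequencing errors to C/T do not deflate the
#' estimate). Input is either a SAM file of alignments to the reference
#' (converted and piled up through Rsamtools; reverse-strand records are
#' already reference-oriented in SAM) or raw fixed-length amplicon reads
#' (FASTQ path, `DNAStringSet`, or character vector) placed by a built-in
#' ungapped minimum-mismatch aligner over all offsets; reads exceeding the
#' mismatch ceiling are discarded and counted.
#'
#' @param x SAM path, FASTQ path, `DNAStringSet`, or character vector of reads.
#' @param reference reference sequence (string or [transcript()]).
#' @param reference_id name of the reference (SAM `@SQ SN`); defaults to the
#'   transcript id or `"amplicon"`.
#' @param min_depth minimum `A + G` depth for an editing fraction to be
#'   reported (below it the fraction is `NA`); default 100.
#' @param max_mismatch_frac ungapped-alignment mismatch ceiling as a fraction
#'   of read length; default 0.2.
#' @return data.frame of class `dv_editing_table`: `pos` (1-based), `ref`,
#'   `A`, `C`, `G`, `T`, `N`, `depth`, `editing_fraction`; attribute
#'   `n_discarded` for the FASTQ path.
#' @export
pileup <- function(x, reference, reference_id = NULL, min_depth = 100L,
                   max_mismatch_frac = 0.2) {
  if (inherits(reference, "dv_transcript")) {
    if (is.null(reference_id)) reference_id <- reference$id
    reference <- reference$seq
  }
  if (is.null(reference_id)) reference_id <- "amplicon"
  reference <- normalize_seq(reference)

  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      tolower(tools::file_ext(x)) == "sam") {
    counts <- pileup_sam(x, reference, reference_id)
    n_discarded <- 0L
  } else {
    reads <- read_input_reads(x)
    res <- pileup_ungapped(reads, reference, max_mismatch_frac)
    counts <- res$counts
    n_discarded <- res$n_discarded
  }
  build_editing_table(counts, reference, reference_id, min_depth, n_discarded)
}

read_input_reads <- function(x) {
  if (inherits(x, "DNAStringSet")) return(as.character(x))
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    set <- Biostrings::readDNAStringSet(x, format = "fastq")
    return(as.character(set))
  }
  if (is.character(x)) return(toupper(chartr("U", "T", x)))
  stop("unsupported read input of class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

pileup_sam <- function(path, reference, reference_id) {
  hdr <- grep("^@SQ", readLines(path, n = 200L), value = TRUE)
  sn <- sub(".*SN:([^\t]+).*", "\\1", hdr)
  ln <- as.integer(sub(".*LN:([0-9]+).*", "\\1", hdr))
  i <- match(reference_id, sn)
  if (is.na(i) || ln[i] != nchar(reference)) {
    stop("SAM header does not match reference '", reference_id, "' (",
         nchar(reference), " nt)", call. = FALSE)
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  pp <- Rsamtools::PileupParam(max_depth = 1000000L, min_base_quality = 0L,
                               min_mapq = 0L, min_nucleotide_depth = 0L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  res <- Rsamtools::pileup(bam, pileupParam = pp)
  res <- res[as.character(res$seqnames) == reference_id, , drop = FALSE]
  counts <- matrix(0L, nrow = nchar(reference), ncol = 5L,
                   dimnames = list(NULL, DNA_ALPHABET))
  nuc <- as.character(res$nucleotide)
  keep <- nuc %in% DNA_ALPHABET
  res <- res[keep, , drop = FALSE]
  nuc <- nuc[keep]
  for (b in unique(nuc)) {
    sel <- nuc == b
    counts[res$pos[sel], b] <- counts[res$pos[sel], b] + res$count[sel]
  }
  counts
}

pileup_ungapped <- function(reads, reference, max_mismatch_frac) {
  if (length(reads) == 0L) {
    warning("empty read input; returning empty editing table", call. = FALSE)
    return(list(counts = matrix(0L, nchar(reference), 5L,
                                dimnames = list(NULL, DNA_ALPHABET)),
                n_discarded = 0L))
  }
  ref_chars <- strsplit(reference, "")[[1L]]
  L <- length(ref_chars)
  counts <- matrix(0L, nrow = L, ncol = 5L, dimnames = list(NULL, DNA_ALPHABET))
  n_discarded <- 0L
  for (len in unique(nchar(reads))) {
    grp <- reads[nchar(reads) == len]
    if (len > L) { n_discarded <- n_discarded + length(grp); next }
    mat <- matrix(unlist(strsplit(grp, ""), use.names = FALSE),
                  nrow = length(grp), byrow = TRUE)
    offsets <- 0:(L - len)
    mm <- vapply(offsets, function(o) {
      rowSums(mat != matrix(ref_chars[(o + 1L):(o + len)],
                            nrow = nrow(mat), ncol = len, byrow = TRUE))
    }, numeric(nrow(mat)))
    mm <- matrix(mm, nrow = nrow(mat))
    best <- max.col(-mm, ties.method = "first")
    best_mm <- mm[cbind(seq_len(nrow(mat)), best)]
    ok <- best_mm <= max_mismatch_frac * len
    n_discarded <- n_discarded + sum(!ok)
    for (o in unique(best[ok])) {
      sel <- ok & best == o
      sub <- mat[sel, , drop = FALSE]
      off <- offsets[o]
      for (b in DNA_ALPHABET) {
        counts[(off + 1L):(off + len), b] <-
          counts[(off + 1L):(off + len), b] + colSums(sub == b)
      }
    }
  }
  list(counts = counts, n_discarded = n_discarded)
}

build_editing_table <- function(counts, reference, reference_id, min_depth,
                                n_discarded) {
  ref_chars <- strsplit(reference, "")[[1L]]
  depth <- as.integer(rowSums(counts))
  ag <- counts[, "A"] + counts[, "G"]
  frac <- ifelse(ref_chars == "A" & ag >= min_depth, counts[, "G"] / ag, NA_real_)
  tab <- data.frame(pos = seq_along(ref_chars), ref = ref_chars,
                    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
                    T = counts[, "T"], N = counts[, "N"],
                    depth = depth, editing_fraction = frac,
                    stringsAsFactors = FALSE)
  attr(tab, "reference_id") <- reference_id
  attr(tab, "n_discarded") <- n_discarded
  class(tab) <- c("dv_editing_table", "data.frame")
  tab
}

#' Position-by-base frequency matrix for sequence-logo rendering
#'
#' Column-normalized A/C/G/T frequencies over a window of the reference
#' (each column sums to 1); an unedited sample gives a point mass on the
#' reference base at every position, while edited samples show the A/G split
#' at the edit site. Zero-depth columns are `NA`.
#' @param table `dv_editing_table` from [pileup()].
#' @param window integer vector of 1-based positions (default: all).
#' @return 4 x length(window) matrix, rows A/C/G/T, columns named by position.
#' @export
logo_matrix <- function(table, window = table$pos) {
  stopifnot(all(window %in% table$pos))
  sub <- table[match(window, table$pos), , drop = FALSE]
  m <- t(as.matrix(sub[, c("A", "C", "G", "T")]))
  tot <- colSums(m)
  freq <- sweep(m, 2L, tot, "/")
  freq[, tot == 0L] <- NA_real_
  colnames(freq) <- window
  freq
}

#' Bin cells by transfection-marker intensity at half-log intervals
#'
#' Cells are assigned to log10 bins of the given width anchored at
#' `10^0 = 1` (bin k covers `[10^(k*w), 10^((k+1)*w))`), mirroring the
#' practice of binning cell populations by transfection level at half-log
#' intervals before computing summary statistics. Non-positive intensities
#' are excluded and counted.
#'
#' @param marker numeric vector of per-cell marker intensities.
#' @param log10_bin_width bin width in log10 units; default 0.5 (half-log).
#' @return data.frame `bin` (integer index), `lo`, `hi` (intensity edges),
#'   `n`; attribute `n_excluded`.
#' @export
bin_by_marker <- function(marker, log10_bin_width = 0.5) {
  stopifnot(log10_bin_width > 0)
  ok <- is.finite(marker) & marker > 0
  n_excluded <- sum(!ok)
  m <- marker[ok]
  idx <- floor(log10(m) / log10_bin_width)
  tab <- table(idx)
  bins <- as.integer(names(tab))
  out <- data.frame(bin = bins,
                    lo = 10^(bins * log10_bin_width),
                    hi = 10^((bins + 1L) * log10_bin_width),
                    n = as.integer(tab))
  attr(out, "n_excluded") <- n_excluded
  attr(out, "assignment") <- idx
  out
}

#' Fold-change of geometric-mean fluorescence, with bootstrap CI
#'
#' The sensor readout is the ratio of the geometric mean of reporter
#' fluorescence in the presence (ON) and absence (OFF) of trigger. The 95%
#' confidence interval is a seeded percentile bootstrap over cells.
#'
#' @param on_cells,off_cells positive per-cell intensities.
#' @param n_boot bootstrap replicates; default 1000.
#' @param seed RNG seed for the bootstrap.
#' @return list of class `dv_fold_change`: `geo_mean_on`, `geo_mean_off`,
#'   `fold_change`, `ci95` (lo, hi), `n_on`, `n_off`.
#' @export
fold_change <- function(on_cells, off_cells, n_boot = 1000L, seed = 1L) {
  if (length(on_cells) == 0L || length(off_cells) == 0L) {
    stop("both populations must be non-empty", call. = FALSE)
  }
  if (any(on_cells <= 0) || any(off_cells <= 0)) {
    stop("non-positive intensities present; floor or filter them upstream ",
         "(geometric means are undefined at <= 0)", call. = FALSE)
  }
  lon <- log(on_cells); loff <- log(off_cells)
  gm_on <- exp(mean(lon)); gm_off <- exp(mean(loff))
  fc <- gm_on / gm_off
  old <- .Random.seed_safe()
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    exp(mean(lon[sample.int(length(lon), replace = TRUE)]) -
        mean(loff[sample.int(length(loff), replace = TRUE)]))
  }, numeric(1))
  .Random.seed_restore(old)
  ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  structure(list(geo_mean_on = gm_on, geo_mean_off = gm_off,
                 fold_change = fc, ci95 = c(lo = ci[1L], hi = ci[2L]),
                 n_on = length(on_cells), n_off = length(off_cells)),
            class = "dv_fold_change")
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.dv_fold_change <- function(x, ...) {
  cat(sprintf("<dv_fold_change> FC = %.3g (95%% CI %.3g-%.3g), n = %d/%d\n",
              x$fold_change, x$ci95["lo"], x$ci95["hi"], x$n_on, x$n_off))
  invisible(x)
}

#' Closed-loop vs open-loop performance ratios
#'
#' Compares matched sensor variants measured under the autocatalytic
#' (closed-loop, CL) and constitutive-enzyme (open-loop, OL) topologies:
#' `log10(FC_CL / FC_OL)` (positive = the sensor performs better with
#' autocatalysis) and `log10(OFF_CL / OFF_OL)` (negative = reduced
#' background activation under the closed loop).
#'
#' @param cl,ol `dv_fold_change` results for the closed- and open-loop
#'   topologies of the same sensor.
#' @return list `log10_fold_change_ratio`, `log10_basal_ratio`,
#'   `better_with_autocatalysis`.
#' @export
topology_ratios <- function(cl, ol) {
  stopifnot(inherits(cl, "dv_fold_change"), inherits(ol, "dv_fold_change"))
  if (ol$fold_change <= 0 || ol$geo_mean_off <= 0) {
    stop("open-loop denominators must be positive", call. = FALSE)
  }
  fcr <- log10(cl$fold_change / ol$fold_change)
  basal <- log10(cl$geo_mean_off / ol$geo_mean_off)
  list(log10_fold_change_ratio = fcr,
       log10_basal_ratio = basal,
       better_with_autocatalysis = fcr > 0)
}
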