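#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement translate consensusMatrix quality QualityScaledDNAStringSet
#'   PhredQuality
#' @importFrom stats rbinom rlnorm runif quantile setNames
#' @importFrom utils read.table write.table head tail
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
REGION_KINDS <- c("five_prime_utr", "cds", "three_prime_utr")

#' Construct an annotated transcript
#'
#' A transcript is the design substrate: a nucleotide sequence with optional
#' region annotation (5'UTR / CDS / 3'UTR), a subcellular localization flag,
#' and a flag marking products routed to the secretory pathway. Sequences are
#' stored in the DNA alphabet (U is normalized to T on input); positions are
#' held internally as 0-based half-open intervals while all user-facing
#' positions are 1-based and, when a CDS is annotated, anchored at the start
#' codon (the A of AUG is position +1).
#'
#' @param id transcript identifier.
#' @param seq nucleotide string (A/C/G/T/N; U accepted and converted to T).
#' @param regions data.frame with columns `kind` (one of `five_prime_utr`,
#'   `cds`, `three_prime_utr`), `start`, `end` in 0-based half-open
#'   transcript coordinates. May be empty.
#' @param localization one of `"cytoplasmic"`, `"nuclear"`, `"unknown"`.
#'   Nuclear transcripts are refused by the site ranker: ADAR-sensor editing
#'   is cytoplasmic and nuclear targets do not activate sensors.
#' @param secreted logical; `TRUE` if the encoded product carries a signal
#'   peptide (ER-targeted/secreted). CDS sites on such transcripts are
#'   classified `cds_secreted` and ranked highest.
#' @return object of class `dv_transcript`.
#' @export
transcript <- function(id, seq, regions = empty_regions(),
                       localization = c("unknown", "cytoplasmic", "nuclear"),
                       secreted = FALSE) {
  localization <- match.arg(localization)
  seq <- normalize_seq(seq)
  regions <- validate_regions(regions, nchar(seq))
  obj <- structure(
    list(id = as.character(id), seq = seq, regions = regions,
         localization = localization, secreted = isTRUE(secreted)),
    class = "dv_transcript")
  obj
}

empty_regions <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

normalize_seq <- function(seq) {
  seq <- toupper(gsub("\\s", "", as.character(seq)))
  seq <- chartr("U", "T", seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (nchar(bad) > 0) {
    stop("invalid nucleotide character(s): ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "), call. = FALSE)
  }
  seq
}

validate_regions <- function(regions, seq_len) {
  stopifnot(is.data.frame(regions))
  if (nrow(regions) == 0L) return(empty_regions())
  regions <- regions[, c("kind", "start", "end")]
  regions$kind <- as.character(regions$kind)
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (!all(regions$kind %in% REGION_KINDS)) {
    stop("unknown region kind(s): ",
         paste(setdiff(regions$kind, REGION_KINDS), collapse = ", "),
         call. = FALSE)
  }
  if (any(regions$start < 0L) || any(regions$end > seq_len) ||
      any(regions$end <= regions$start)) {
    stop("region outside sequence bounds [0, ", seq_len, ")", call. = FALSE)
  }
  regions <- regions[order(regions$start), , drop = FALSE]
  if (nrow(regions) > 1L &&
      any(regions$start[-1L] < regions$end[-nrow(regions)])) {
    stop("regions overlap", call. = FALSE)
  }
  cds <- regions[regions$kind == "cds", , drop = FALSE]
  if (nrow(cds) > 1L) stop("multiple CDS regions are not supported", call. = FALSE)
  if (nrow(cds) == 1L) {
    len <- cds$end - cds$start
    if (len %% 3L != 0L) {
      stop("CDS length ", len, " is not a multiple of 3", call. = FALSE)
    }
  }
  rownames(regions) <- NULL
  regions
}

#' @export
print.dv_transcript <- function(x, ...) {
  cat(sprintf("<dv_transcript> %s: %d nt, %d region(s), %s%s\n",
              x$id, nchar(x$seq), nrow(x$regions), x$localization,
              if (x$secreted) ", secreted" else ""))
  invisible(x)
}

#' 0-based transcript offset of the A of the start codon, or NA
#' @param x a `dv_transcript`.
#' @return integer offset, or `NA_integer_` when no CDS is annotated.
#' @export
cds_start <- function(x) {
  cds <- x$regions[x$regions$kind == "cds", , drop = FALSE]
  if (nrow(cds) == 0L) NA_integer_ else cds$start[1L]
}

#' Convert a 0-based transcript offset to the 1-based anchored position
#'
#' When a CDS is annotated, position +1 is the A of the start codon and
#' positions upstream of it are negative (there is no position 0). Without a
#' CDS, the plain 1-based transcript position is returned.
#' @param x a `dv_transcript`.
#' @param offset 0-based transcript offset(s).
#' @return integer vector of 1-based anchored positions.
#' @export
anchored_position <- function(x, offset) {
  cs <- cds_start(x)
  if (is.na(cs)) return(as.integer(offset) + 1L)
  rel <- as.integer(offset) - cs
  ifelse(rel >= 0L, rel + 1L, rel)
}

#' Inverse of [anchored_position()]
#' @param x a `dv_transcript`.
#' @param pos 1-based anchored position(s); never 0.
#' @return 0-based transcript offset(s).
#' @export
anchored_to_offset <- function(x, pos) {
  pos <- as.integer(pos)
  if (any(pos == 0L)) stop("anchored position 0 does not exist", call. = FALSE)
  cs <- cds_start(x)
  if (is.na(cs)) return(pos - 1L)
  ifelse(pos > 0L, cs + pos - 1L, cs + pos)
}

#' Read transcripts from a FASTA file
#'
#' @param path FASTA file (multi-record allowed). U is normalized to T and
#'   case is normalized; records come back with empty region annotation.
#' @return list of [transcript()] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # BStringSet first: RNA records (U) are legal input and normalized below
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) {
                    stop("malformed FASTA in ", path, ": ", conditionMessage(e),
                         call. = FALSE)
                  })
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    transcript(ids[i], as.character(set[[i]]))
  })
}

#' Write transcripts to FASTA
#' @param transcripts list of `dv_transcript` (or a single one).
#' @param path output file.
#' @param as_rna render the sequence in the RNA alphabet (T -> U).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path, as_rna = FALSE) {
  if (inherits(transcripts, "dv_transcript")) transcripts <- list(transcripts)
  seqs <- vapply(transcripts, function(t) t$seq, character(1))
  if (as_rna) seqs <- chartr("T", "U", seqs)
  set <- Biostrings::DNAStringSet(if (as_rna) chartr("U", "T", seqs) else seqs)
  names(set) <- vapply(transcripts, function(t) t$id, character(1))
  if (as_rna) {
    # Biostrings insists on DNA for DNAStringSet; write RNA rendering by hand
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(seqs)) {
      writeLines(c(paste0(">", names(set)[i]), seqs[i]), con)
    }
  } else {
    Biostrings::writeXStringSet(set, path)
  }
  invisible(path)
}

#' Attach region annotation to transcripts
#'
#' Accepts GFF3 (feature types `CDS`, `five_prime_UTR`, `three_prime_UTR`
#' in transcript-space coordinates, seqid matching the transcript id) or a
#' 3-column TSV `kind<TAB>start<TAB>end` with 1-based inclusive coordinates
#' (a 4-column variant with a leading transcript id column is accepted for
#' multi-transcript tables). Coordinates are converted to 0-based half-open
#' and the transcript invariants (in-bounds, non-overlapping, CDS length a
#' multiple of 3) are enforced.
#'
#' @param path annotation file (.gff/.gff3 or TSV).
#' @param transcripts list of `dv_transcript`.
#' @return the list with `regions` filled in.
#' @export
read_annotation <- function(path, transcripts) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  single <- inherits(transcripts, "dv_transcript")
  if (single) transcripts <- list(transcripts)
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext %in% c("gff", "gff3")) read_regions_gff3(path)
         else read_regions_tsv(path)
  out <- lapply(transcripts, function(tr) {
    rows <- if (is.na(tab$seqid[1L]) && length(transcripts) == 1L) tab
            else tab[tab$seqid == tr$id | is.na(tab$seqid), , drop = FALSE]
    if (nrow(rows) == 0L) return(tr)
    regions <- data.frame(kind = rows$kind,
                          start = rows$start - 1L,   # 1-based incl -> 0-based half-open
                          end = rows$end,
                          stringsAsFactors = FALSE)
    transcript(tr$id, tr$seq, regions, tr$localization, tr$secreted)
  })
  if (single) out[[1L]] else out
}

read_regions_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  map <- c(CDS = "cds", five_prime_UTR = "five_prime_utr",
           three_prime_UTR = "three_prime_utr")
  keep <- type %in% names(map)
  gr <- gr[keep]
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             kind = unname(map[as.character(gr$type)]),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

read_regions_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) == 3L) {
    data.frame(seqid = NA_character_, kind = tolower(tab[[1L]]),
               start = as.integer(tab[[2L]]), end = as.integer(tab[[3L]]),
               stringsAsFactors = FALSE)
  } else if (ncol(tab) >= 4L) {
    data.frame(seqid = as.character(tab[[1L]]), kind = tolower(tab[[2L]]),
               start = as.integer(tab[[3L]]), end = as.integer(tab[[4L]]),
               stringsAsFactors = FALSE)
  } else {
    stop("region TSV needs 3 columns (kind, start, end) or 4 (id, kind, start, end)",
         call. = FALSE)
  }
}

#' Reverse complement of a nucleotide string
#' @param seq string over A/C/G/T/N (U accepted).
#' @return reverse-complemented string (DNA alphabet; N maps to N).
#' @export
revcomp <- function(seq) {
  seq <- normalize_seq(seq)
  if (nchar(seq) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a nucleotide sequence (standard genetic code)
#'
#' Stops render as `*`; codons containing N render as `X`; a trailing
#' partial codon is ignored.
#' @param seq nucleotide string.
#' @param frame_offset 0, 1 or 2: number of bases skipped before the first codon.
#' @return peptide string.
#' @export
translate_seq <- function(seq, frame_offset = 0L) {
  stopifnot(frame_offset %in% 0:2)
  seq <- normalize_seq(seq)
  seq <- substr(seq, frame_offset + 1L, nchar(seq))
  n_codon <- nchar(seq) %/% 3L
  if (n_codon == 0L) return("")
  seq <- substr(seq, 1L, n_codon * 3L)
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     if.fuzzy.codon = "X"))
}

#' Codon number of a CDS position
#'
#' Maps a 1-based CDS nucleotide position to its 1-based codon number,
#' `ceiling(position / 3)`; e.g. the c.658 variant of p53 falls in codon 220
#' (the Y220 codon).
#' @param cds_position_1based integer position(s), >= 1.
#' @return integer codon number(s).
#' @export
codon_index <- function(cds_position_1based) {
  pos <- as.integer(cds_position_1based)
  if (any(pos < 1L)) stop("CDS positions are 1-based (>= 1)", call. = FALSE)
  as.integer(ceiling(pos / 3))
}

# positions (0-based offsets) of every occurrence of a fixed motif, overlaps allowed
motif_offsets <- function(seq, motif) {
  hits <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits) - 1L
}
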