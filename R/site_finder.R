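#' Enumerate editable CCA sites on a transcript
#'
#' ADAR-activatable sensors place their editable UAG opposite a CCA triplet
#' on the target: the sensor A sits in an A:C mismatch with a 5'-U neighbour,
#' the substrate ADAR prefers. Every CCA occurrence is therefore a candidate
#' edit site. Sites are named `CCA<n>` where `n` is the 1-based position of
#' the first C of the motif, anchored at the start codon when a CDS is
#' annotated (position +1 = the A of AUG) and at the transcript 5' end
#' otherwise. The anchor base within the motif is configurable
#' (`number_from`), since site-naming conventions in the field differ.
#'
#' @param x a [transcript()].
#' @param number_from which motif base the site number refers to:
#'   `"first_c"` (default), `"central_c"`, or `"a"`.
#' @return data.frame of class `dv_sites`: `transcript_id`, `motif_start`
#'   (0-based), `anchored_pos`, `name`, `context`, in ascending position.
#' @export
scan_cca <- function(x, number_from = c("first_c", "central_c", "a")) {
  stopifnot(inherits(x, "dv_transcript"))
  number_from <- match.arg(number_from)
  offs <- motif_offsets(x$seq, "CCA")
  shift <- switch(number_from, first_c = 0L, central_c = 1L, a = 2L)
  pos <- anchored_position(x, offs + shift)
  sites <- data.frame(
    transcript_id = rep(x$id, length(offs)),
    motif_start = offs,
    anchored_pos = pos,
    name = if (length(offs)) paste0("CCA", pos) else character(0),
    stringsAsFactors = FALSE)
  sites$context <- vapply(sites$motif_start, function(m) {
    classify_context_at(m, x)
  }, character(1))
  class(sites) <- c("dv_sites", "data.frame")
  sites
}

#' Classify the sequence context of an edit site
#'
#' Ribosome-free contexts make better ADAR targets: translating ribosomes
#' unwind the sensor:trigger duplex. Sites are classed by the annotated
#' region containing the motif start: `three_prime_utr`, `five_prime_utr`,
#' `cds_translated`, or `cds_secreted` when the transcript is flagged
#' secreted (ribosomes stall early on ER-targeted messages, leaving the CDS
#' relatively ribosome-free). Sites outside any annotated region are
#' `noncoding` (with a warning if the transcript does have annotation).
#'
#' @param site one row of a `dv_sites` frame (or a list with `motif_start`).
#' @param x the [transcript()] the site was found on.
#' @return context string.
#' @export
classify_context <- function(site, x) {
  classify_context_at(site$motif_start[1L], x)
}

classify_context_at <- function(motif_start, x) {
  reg <- x$regions
  if (nrow(reg) == 0L) return("noncoding")
  hit <- reg[reg$start <= motif_start & motif_start < reg$end, , drop = FALSE]
  if (nrow(hit) == 0L) {
    warning("site at offset ", motif_start,
            " lies outside annotated regions; classified noncoding",
            call. = FALSE)
    return("noncoding")
  }
  kind <- hit$kind[1L]
  if (kind == "cds") {
    if (x$secreted) "cds_secreted" else "cds_translated"
  } else {
    kind
  }
}

#' Default context ranking policy
#'
#' Priority order for target contexts, best first. Secreted-protein CDS
#' outranks 3'UTR, which outranks 5'UTR, which outranks translated CDS;
#' unannotated (noncoding) sites rank last.
#' @return character vector of contexts, best first.
#' @export
default_rank_policy <- function() {
  c("cds_secreted", "three_prime_utr", "five_prime_utr", "cds_translated",
    "noncoding")
}

#' Rank edit sites for sensor design
#'
#' Orders sites by context priority (see [default_rank_policy()]), ties
#' broken by ascending transcript position, and assigns an ordinal
#' `rank_score` (1 = best). Nuclear-localized transcripts yield an empty
#' ranking with an advisory attribute: nuclear targets do not activate
#' sensors (editing is cytoplasmic), so no site is usable.
#'
#' @param sites `dv_sites` frame from [scan_cca()].
#' @param x the [transcript()].
#' @param policy character vector of contexts, best first.
#' @return `dv_sites` frame ordered by rank with a `rank_score` column;
#'   empty with `attr(, "advisory")` set for nuclear transcripts.
#' @export
rank_sites <- function(sites, x, policy = default_rank_policy()) {
  stopifnot(inherits(x, "dv_transcript"))
  if (identical(x$localization, "nuclear")) {
    out <- sites[0, , drop = FALSE]
    out$rank_score <- integer(0)
    attr(out, "advisory") <- paste0(
      "transcript '", x$id, "' is nuclear-localized: ADAR sensor editing is ",
      "cytoplasmic and nuclear targets do not activate sensors; no site ranked")
    return(out)
  }
  if (nrow(sites) == 0L) {
    sites$rank_score <- integer(0)
    return(sites)
  }
  prio <- match(sites$context, policy)
  prio[is.na(prio)] <- length(policy) + 1L
  ord <- order(prio, sites$motif_start)
  out <- sites[ord, , drop = FALSE]
  out$rank_score <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
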