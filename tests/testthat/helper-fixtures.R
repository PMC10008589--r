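# shared fixtures, built in code at test time

toy_transcript <- function() transcript("toy", "GATCCAATG")

std_spec <- function(seed = 7L, ...) {
  sim_spec(seed = seed, planted_cca = c(60L, 150L), ...)
}

std_trigger <- function(seed = 7L) make_trigger(std_spec(seed))

std_design <- function(seed = 7L, length = 75L) {
  tr <- std_trigger(seed)
  sites <- scan_cca(tr)
  design_sensor(tr, sites[sites$name == "CCA60", ], length = length)
}

# independent brute-force sliding-window motif oracle
brute_cca <- function(seq) {
  n <- nchar(seq)
  offs <- integer(0)
  for (i in seq_len(max(0L, n - 2L))) {
    if (substr(seq, i, i + 2L) == "CCA") offs <- c(offs, i - 1L)
  }
  offs
}

random_seq <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_toy_sam <- function(path, reference_id, reference, reads, pos = NULL) {
  if (is.null(pos)) pos <- rep(1L, length(reads))
  lines <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", reference_id, nchar(reference)),
    sprintf("r%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
            seq_along(reads), reference_id, pos, nchar(reads), reads))
  writeLines(lines, path)
  path
}
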