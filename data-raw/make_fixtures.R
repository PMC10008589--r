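# one-off generator for inst/extdata/components_synthetic.fa
# synthetic stand-ins at the real components' documented lengths;
# P2A and the 19-nt wild-type MS2 stem-loop are the real sequences
set.seed(20260923)

codons <- apply(expand.grid(c("T","C","A","G"), c("T","C","A","G"),
                            c("T","C","A","G")), 1, paste0, collapse = "")
nonstop <- setdiff(codons, c("TAA", "TAG", "TGA"))

syn_cds <- function(n_nt, start_atg = TRUE, terminal_stop = FALSE) {
  stopifnot(n_nt %% 3 == 0)
  n_cod <- n_nt / 3 - as.integer(start_atg) - as.integer(terminal_stop)
  body <- paste0(sample(nonstop, n_cod, replace = TRUE), collapse = "")
  paste0(if (start_atg) "ATG" else "", body, if (terminal_stop) "TAA" else "")
}
syn_nc <- function(n_nt) paste0(sample(c("A","C","G","T"), n_nt, TRUE), collapse = "")

p2a <- "GGAAGCGGAGCTACTAACTTCAGCCTGCTGAAGCAGGCTGGAGACGTGGAGGAGAACCCTGGACCT"
ms2 <- "ACATGAGGATCACCCATGT"
stopifnot(nchar(p2a) == 66, nchar(ms2) == 19)

recs <- list(
  cmv_promoter  = list(seq = syn_nc(584), coding = FALSE, synthetic = TRUE),
  tagbfp        = list(seq = syn_cds(699), coding = TRUE, synthetic = TRUE),
  p2a           = list(seq = p2a, coding = TRUE, synthetic = FALSE),
  mneongreen    = list(seq = syn_cds(711), coding = TRUE, synthetic = TRUE),
  mcp           = list(seq = syn_cds(390), coding = TRUE, synthetic = TRUE),
  adar2dd_e488q = list(seq = syn_cds(1182, start_atg = FALSE), coding = TRUE, synthetic = TRUE),
  nes           = list(seq = syn_cds(33, start_atg = FALSE), coding = TRUE, synthetic = TRUE),
  ms2_hairpin   = list(seq = ms2, coding = FALSE, synthetic = FALSE),
  bgh_terminator = list(seq = syn_nc(225), coding = FALSE, synthetic = TRUE),
  adar1_p150    = list(seq = syn_cds(3681, terminal_stop = TRUE), coding = TRUE, synthetic = TRUE)
)

con <- file("inst/extdata/components_synthetic.fa", "w")
for (nm in names(recs)) {
  r <- recs[[nm]]
  cat(sprintf(">%s coding=%s synthetic=%s length=%d\n", nm,
              tolower(r$coding), tolower(r$synthetic), nchar(r$seq)), file = con)
  s <- r$seq
  cat(paste0(substring(s, seq(1, nchar(s), 70), pmin(seq(1, nchar(s), 70) + 69, nchar(s))),
             collapse = "\n"), "\n", sep = "", file = con)
}
close(con)
cat("written\n")
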