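# Shared internal helpers: residue validation and deterministic TSV formatting.

# the 20 standard one-letter codes; ambiguity codes (B, Z, X, U) are rejected
# because the sequon rule is undefined when X occupies the N or S/T position
.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.checkResidues <- function(sequence, id = NULL) {
  bad <- regexpr("[^ARNDCQEGHILKMFPSTWYV]", sequence)
  if (bad > 0L) {
    who <- if (is.null(id)) "" else sprintf(" in record '%s'", id)
    stop(sprintf("illegal residue '%s' at position %d%s",
                 substr(sequence, bad, bad), as.integer(bad), who),
         call. = FALSE)
  }
  invisible(TRUE)
}

# fixed 6-significant-digit rendering so result tables diff byte-for-byte
.fmtNum <- function(x) {
  out <- sprintf("%.6g", x)
  out[is.na(x)] <- "NA"
  out
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
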