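# Internal helpers shared across modules.

# Round half away from zero, the convention used for reported peptide means
# (base round() rounds half to even, which would print 2.25 as 2.2).
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# Uppercase 20-residue alphabet with optional bracketed modification
# annotations, e.g. "PEPTIDEK" or "PEPT[+79.97]IDEK".
.peptide_regex <- "^([ACDEFGHIKLMNPQRSTVWY]|\\[[^][]*\\])+$"

is_valid_peptide <- function(x) {
  !is.na(x) & nzchar(x) & grepl(.peptide_regex, x)
}

`%na%` <- function(a, b) ifelse(is.na(a), b, a)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
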