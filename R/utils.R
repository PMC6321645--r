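# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' @noRd
revcomp <- function(x) {
  vapply(x, function(s) {
    b <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1]])
    cc <- COMPLEMENT[b]
    if (anyNA(cc)) stop("non-IUPAC character in sequence: ", s)
    paste(cc, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @noRd
complement_base <- function(x) {
  cc <- COMPLEMENT[toupper(x)]
  if (anyNA(cc)) stop("non-IUPAC base")
  unname(cc)
}

# TRUE where concrete base `base` is compatible with IUPAC code `code`
#' @noRd
iupac_matches <- function(base, code) {
  if (length(base) == 0) return(logical(0))
  mapply(function(b, cd) {
    exp <- IUPAC_EXPAND[[toupper(cd)]]
    if (is.null(exp)) stop("invalid IUPAC code: ", cd)
    toupper(b) %in% exp
  }, base, code, USE.NAMES = FALSE)
}

#' @noRd
site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

# Deterministic fan-out of one user seed into per-stage seeds (kept < 2^31).
#' @noRd
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
gc_content <- function(seq) {
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  mean(b %in% c("G", "C"))
}

#' @noRd
random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
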